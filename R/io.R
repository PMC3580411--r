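# Plain-TSV serialization of pair-level results, shared by the command
# line interface and scripted pipelines.

#' Serialize / load delta-T tables
#'
#' A delta-T TSV has columns `pair_id`, `tumor_normalized`,
#' `normal_normalized`, `delta_t`, `pseudocount_used`.
#'
#' @param x A `delta_t_record` or list of them.
#' @param file TSV path.
#' @return `write_delta_tsv` returns the path invisibly; `read_delta_tsv`
#'   returns a data frame.
#' @export
write_delta_tsv <- function(x, file) {
  if (inherits(x, "delta_t_record")) x <- list(x)
  tab <- do.call(rbind, lapply(x, function(d)
    data.frame(pair_id = d$pair_id, tumor_normalized = d$tumor_normalized,
               normal_normalized = d$normal_normalized, delta_t = d$delta_t,
               pseudocount_used = d$pseudocount_used)))
  write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_delta_tsv
#' @export
read_delta_tsv <- function(file) {
  tab <- read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("pair_id", "delta_t") %in% names(tab)))
    stop("delta TSV must have columns pair_id and delta_t", call. = FALSE)
  tab
}

#' Serialize telomere calls
#'
#' @param calls A `telomere_calls` data frame from [classify_samples()].
#' @param file TSV path.
#' @export
write_calls_tsv <- function(calls, file) {
  stopifnot(is.data.frame(calls))
  write.table(calls, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
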