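#' Count telomere-motif reads in a sample
#'
#' Applies the read filters, then counts retained reads containing the
#' telomeric motif in either orientation. Each read is counted at most
#' once, however many motif occurrences it contains: the tally answers
#' "how many reads contain the repeat", not "how many repeats are there".
#' `total_reads` and `total_bases` cover retained reads only, so the same
#' filtered stream feeds both the telomere count and the coverage estimate.
#'
#' @param reads Either a path to a FASTQ/SAM/BAM file (see [read_reads()])
#'   or a read-record data frame as returned by [read_reads()] /
#'   [simulate_reads()].
#' @param spec A [motif_spec()].
#' @param filters A [read_filters()].
#' @param sample_id Sample label carried into downstream tables; defaults
#'   to the file name (or `"sample"` for in-memory input).
#' @param ... Passed to [read_reads()] when `reads` is a path (`format`,
#'   `reference`).
#' @return An object of class `telomere_count`: a list with
#'   `telomeric_reads`, `total_reads`, `total_bases`,
#'   `total_aligned_bases`, `sample_id`, and the `spec` and `filters`
#'   applied (recorded so that tumor/normal consistency can be verified by
#'   [delta_t()]).
#' @examples
#' reads <- simulate_reads(read_sim_params(n_reads = 200,
#'   telomere_fraction = 0.1, seed = 1))$reads
#' count_telomeric_reads(reads)
#' @export
count_telomeric_reads <- function(reads, spec = motif_spec(),
                                  filters = read_filters(),
                                  sample_id = NULL, ...) {
  if (is.character(reads) && length(reads) == 1L) {
    if (is.null(sample_id))
      sample_id <- sub("\\.(fastq|fq|sam|bam|cram)(\\.gz)?$", "",
                       basename(reads), ignore.case = TRUE)
    reads <- read_reads(reads, ...)
  }
  if (is.null(sample_id)) sample_id <- "sample"
  stopifnot(is.data.frame(reads), "sequence" %in% names(reads))
  kept <- .apply_filters(reads, filters)
  lens <- nchar(kept$sequence)
  structure(
    list(sample_id = sample_id,
         telomeric_reads = sum(contains_telomere_motif(kept$sequence, spec)),
         total_reads = nrow(kept),
         total_bases = sum(as.numeric(lens)),
         total_aligned_bases =
           if ("mapped_length" %in% names(kept))
             sum(as.numeric(kept$mapped_length)) else 0,
         spec = spec, filters = filters),
    class = "telomere_count")
}

#' @export
print.telomere_count <- function(x, ...) {
  cat(sprintf(
    "telomere_count [%s]: %d telomeric / %d reads (%.0f bases scanned)\n",
    x$sample_id, x$telomeric_reads, x$total_reads, x$total_bases))
  invisible(x)
}

#' @rdname count_telomeric_reads
#' @param x A `telomere_count` (or list of them) to serialize.
#' @param file Output TSV path.
#' @export
write_counts_tsv <- function(x, file) {
  if (inherits(x, "telomere_count")) x <- list(x)
  tab <- do.call(rbind, lapply(x, function(ct)
    data.frame(sample_id = ct$sample_id,
               telomeric_reads = ct$telomeric_reads,
               total_reads = ct$total_reads,
               total_bases = ct$total_bases,
               total_aligned_bases = ct$total_aligned_bases)))
  write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname count_telomeric_reads
#' @export
read_counts_tsv <- function(file) {
  tab <- read.delim(file, stringsAsFactors = FALSE)
  need <- c("sample_id", "telomeric_reads", "total_reads", "total_bases")
  if (!all(need %in% names(tab)))
    stop("counts TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (is.null(tab$total_aligned_bases)) tab$total_aligned_bases <- 0
  tab
}
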