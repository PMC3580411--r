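#' Average genomic coverage of a sample
#'
#' Mean fold coverage = total sequenced (or aligned) bases divided by the
#' reference genome length. The default basis, `all_read_bases`, divides
#' the total bases of all retained reads by the genome length; this treats
#' tumor and normal identically and does not penalize telomeric reads for
#' failing to align. `aligned_bases` instead sums the reference-aligned
#' bases of mapped reads (BAM workflows).
#'
#' @param count A `telomere_count` from [count_telomeric_reads()], or any
#'   list/data frame row with `total_bases` (and `total_aligned_bases` for
#'   the aligned basis).
#' @param genome_length Reference genome length in bp (e.g. `3.1e9` for
#'   human, or [genome_length_from_fai()]).
#' @param basis `"all_read_bases"` (default) or `"aligned_bases"`.
#' @return An object of class `coverage_estimate` with `mean_coverage`
#'   (fold), `genome_length`, and `basis`.
#' @examples
#' average_coverage(list(total_bases = 3e5), genome_length = 1e6)
#' @export
average_coverage <- function(count, genome_length,
                             basis = c("all_read_bases", "aligned_bases")) {
  basis <- match.arg(basis)
  genome_length <- as.numeric(genome_length)
  if (length(genome_length) != 1L || is.na(genome_length) || genome_length <= 0)
    stop("`genome_length` must be a single positive number", call. = FALSE)
  bases <- if (basis == "all_read_bases") count$total_bases
           else count$total_aligned_bases
  if (is.null(bases) || is.na(bases))
    stop("count record lacks the base total for basis '", basis, "'",
         call. = FALSE)
  structure(list(mean_coverage = as.numeric(bases) / genome_length,
                 genome_length = genome_length, basis = basis),
            class = "coverage_estimate")
}

#' @export
print.coverage_estimate <- function(x, ...) {
  cat(sprintf("coverage_estimate: %.3fx over %.4g bp (%s)\n",
              x$mean_coverage, x$genome_length, x$basis))
  invisible(x)
}

#' Genome length from a FASTA index
#'
#' Sums the contig lengths (second column) of a samtools `.fai` index.
#'
#' @param fai Path to a `.fai` file.
#' @return Total reference length in bp.
#' @export
genome_length_from_fai <- function(fai) {
  tab <- read.delim(fai, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("not a .fai index: ", fai, call. = FALSE)
  sum(as.numeric(tab[[2L]]))
}

#' Coverage-normalized telomere content
#'
#' Divides the telomeric read count by mean fold coverage, yielding
#' "telomeric reads per fold coverage" — the per-sample quantity whose
#' tumor/normal log ratio is delta-T.
#'
#' @param raw A `telomere_count` from [count_telomeric_reads()].
#' @param coverage A `coverage_estimate` from [average_coverage()].
#' @return An object of class `normalized_content` with `sample_id`,
#'   `normalized_count`, and the `raw` and `coverage` inputs.
#' @export
normalize_count <- function(raw, coverage) {
  stopifnot(inherits(coverage, "coverage_estimate"))
  if (coverage$mean_coverage <= 0)
    stop("mean coverage is zero; the sample has no retained bases, so ",
         "telomere content cannot be normalized (check filters and input)",
         call. = FALSE)
  structure(list(sample_id = raw$sample_id,
                 normalized_count = raw$telomeric_reads / coverage$mean_coverage,
                 raw = raw, coverage = coverage),
            class = "normalized_content")
}

#' @export
print.normalized_content <- function(x, ...) {
  cat(sprintf("normalized_content [%s]: %.2f telomeric reads per fold coverage\n",
              x$sample_id, x$normalized_count))
  invisible(x)
}

.settings_match <- function(a, b) {
  if (is.null(a) || is.null(b)) return(TRUE)  # bare-number input: nothing to check
  identical(a$spec[c("unit", "copies", "both_strands")],
            b$spec[c("unit", "copies", "both_strands")]) &&
    identical(unclass(a$filters), unclass(b$filters))
}

#' Tumor-vs-normal telomere content change (delta-T)
#'
#' \deqn{\Delta T = \log_2(N_{tumor} / N_{normal})}
#' where \eqn{N} is the coverage-normalized telomeric read count. A
#' positive value is a relative gain of telomeric DNA in the tumor, a
#' negative value a loss. If either normalized count is exactly zero, the
#' `pseudocount` is added to both numerator and denominator (and flagged),
#' keeping the ratio finite without biasing nonzero pairs.
#'
#' Both samples must have been counted with the same motif and filter
#' settings; a mismatch is an error, because the ratio is only meaningful
#' when numerator and denominator measure the same thing.
#'
#' @param tumor,normal `normalized_content` objects from
#'   [normalize_count()], or bare non-negative numbers (settings check then
#'   skipped).
#' @param pseudocount Value added to both terms when a zero occurs
#'   (default 0.5). With `pseudocount = 0` a zero normal count is an error.
#' @param pair_id Label for the pair; defaults to the tumor sample id.
#' @return An object of class `delta_t_record` with `pair_id`, `delta_t`,
#'   `tumor_normalized`, `normal_normalized`, `pseudocount_used`.
#' @examples
#' delta_t(40, 20)  # exactly 1.0
#' @export
delta_t <- function(tumor, normal, pseudocount = 0.5, pair_id = NULL) {
  t_obj <- if (inherits(tumor, "normalized_content")) tumor else NULL
  n_obj <- if (inherits(normal, "normalized_content")) normal else NULL
  tv <- if (is.null(t_obj)) as.numeric(tumor) else t_obj$normalized_count
  nv <- if (is.null(n_obj)) as.numeric(normal) else n_obj$normalized_count
  if (length(tv) != 1L || length(nv) != 1L || is.na(tv) || is.na(nv) ||
      tv < 0 || nv < 0)
    stop("normalized counts must be single non-negative numbers", call. = FALSE)
  if (!.settings_match(if (is.null(t_obj)) NULL else t_obj$raw,
                       if (is.null(n_obj)) NULL else n_obj$raw))
    stop("tumor and normal were counted with different motif/filter ",
         "settings; recount both with identical settings", call. = FALSE)
  if (is.null(pair_id))
    pair_id <- if (!is.null(t_obj)) t_obj$sample_id else "pair"
  used <- tv == 0 || nv == 0
  if (used) {
    if (pseudocount <= 0)
      stop("normalized count of zero with no pseudocount; set ",
           "`pseudocount` > 0 to obtain a finite delta-T", call. = FALSE)
    tv <- tv + pseudocount
    nv <- nv + pseudocount
  }
  structure(list(pair_id = pair_id, delta_t = log2(tv / nv),
                 tumor_normalized = if (used) tv - pseudocount else tv,
                 normal_normalized = if (used) nv - pseudocount else nv,
                 pseudocount_used = used),
            class = "delta_t_record")
}

#' @export
print.delta_t_record <- function(x, ...) {
  cat(sprintf("delta_t_record [%s]: dT = %+.3f (tumor %.2f / normal %.2f)%s\n",
              x$pair_id, x$delta_t, x$tumor_normalized, x$normal_normalized,
              if (x$pseudocount_used) " [pseudocount]" else ""))
  invisible(x)
}

#' End-to-end telomere content for one sample
#'
#' Convenience wrapper: count motif reads, estimate coverage, normalize.
#'
#' @inheritParams count_telomeric_reads
#' @inheritParams average_coverage
#' @return A `normalized_content` object.
#' @export
telomere_content <- function(reads, genome_length, spec = motif_spec(),
                             filters = read_filters(),
                             basis = c("all_read_bases", "aligned_bases"),
                             sample_id = NULL, ...) {
  ct <- count_telomeric_reads(reads, spec = spec, filters = filters,
                              sample_id = sample_id, ...)
  normalize_count(ct, average_coverage(ct, genome_length, basis))
}
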