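#' Read-filter settings for aligned input
#'
#' Which flagged records to drop before counting. Defaults follow standard
#' WGS practice: duplicates, QC failures, and secondary/supplementary
#' alignments are excluded; unmapped reads are kept, because genuine
#' telomeric reads frequently fail to align to the reference. FASTQ input
#' carries no flags, so all filters are no-ops there.
#'
#' @param drop_duplicates Drop PCR/optical duplicate records. Default `TRUE`.
#' @param drop_qc_fail Drop reads failing platform/vendor QC. Default `TRUE`.
#' @param drop_secondary Drop secondary and supplementary alignment records
#'   (so each read is seen at most once). Default `TRUE`.
#' @param drop_unmapped Drop unmapped reads. Default `FALSE`.
#' @return An object of class `read_filters`.
#' @export
read_filters <- function(drop_duplicates = TRUE, drop_qc_fail = TRUE,
                         drop_secondary = TRUE, drop_unmapped = FALSE) {
  structure(list(drop_duplicates = isTRUE(drop_duplicates),
                 drop_qc_fail = isTRUE(drop_qc_fail),
                 drop_secondary = isTRUE(drop_secondary),
                 drop_unmapped = isTRUE(drop_unmapped)),
            class = "read_filters")
}

# SAM flag bits
.FLAG_UNMAPPED  <- 0x4L
.FLAG_SECONDARY <- 0x100L
.FLAG_QCFAIL    <- 0x200L
.FLAG_DUP       <- 0x400L
.FLAG_SUPPL     <- 0x800L

# reference-consuming width of a CIGAR's query-aligned portion:
# bases of the read aligned to the reference (M, =, X ops)
.cigar_aligned_bases <- function(cigar) {
  out <- integer(length(cigar))
  ok <- !is.na(cigar) & cigar != "*"
  if (!any(ok)) return(out)
  m <- gregexpr("(\\d+)([MIDNSHP=X])", cigar[ok])
  out[ok] <- vapply(regmatches(cigar[ok], m), function(ops) {
    if (length(ops) == 0L) return(0L)
    n <- as.integer(sub("[MIDNSHP=X]$", "", ops))
    op <- sub("^\\d+", "", ops)
    sum(n[op %in% c("M", "=", "X")])
  }, integer(1L))
  out
}

.guess_format <- function(file) {
  low <- tolower(sub("\\.gz$", "", file))
  ext <- tools::file_ext(low)
  switch(ext,
         fastq = , fq = "fastq",
         sam = "sam",
         bam = "bam",
         cram = "cram",
         stop("cannot guess format of '", file,
              "'; pass `format` explicitly", call. = FALSE))
}

#' Load sequencing reads as a read-record table
#'
#' Reads a FASTQ (plain or gzip) or SAM/BAM/CRAM file into a data frame of
#' read records: one row per record with the uppercased sequence and the
#' alignment flags used by [count_telomeric_reads()]. FASTQ records get all
#' flags `FALSE` and `mapped_length = 0`.
#'
#' @param file Path to the input file.
#' @param format One of `"auto"`, `"fastq"`, `"sam"`, `"bam"`, `"cram"`.
#'   `"auto"` guesses from the extension.
#' @param reference Optional reference FASTA path, required by some CRAM
#'   inputs (passed through to Rsamtools).
#' @return A data frame with columns `read_id`, `sequence`, `is_duplicate`,
#'   `is_qc_fail`, `is_secondary_or_supplementary`, `is_unmapped`,
#'   `mapped_length`.
#' @export
read_reads <- function(file, format = c("auto", "fastq", "sam", "bam", "cram"),
                       reference = NULL) {
  format <- match.arg(format)
  if (!file.exists(file))
    stop("input file not found: ", file, call. = FALSE)
  if (format == "auto") format <- .guess_format(file)
  if (format == "fastq") .read_fastq(file) else .read_bam(file, format, reference)
}

.read_fastq <- function(file) {
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(file, format = "fastq", use.names = TRUE),
    error = function(e)
      stop("failed to read FASTQ '", file, "' (truncated or malformed?): ",
           conditionMessage(e), call. = FALSE))
  n <- length(seqs)
  ids <- sub("\\s.*$", "", names(seqs))
  if (is.null(ids)) ids <- sprintf("read%06d", seq_len(n))
  data.frame(read_id = ids,
             sequence = toupper(as.character(seqs)),
             is_duplicate = logical(n),
             is_qc_fail = logical(n),
             is_secondary_or_supplementary = logical(n),
             is_unmapped = logical(n),
             mapped_length = integer(n),
             stringsAsFactors = FALSE, row.names = NULL)
}

.read_bam <- function(file, format, reference = NULL) {
  if (format == "sam") {
    dest <- tempfile(fileext = "")
    file <- tryCatch(
      Rsamtools::asBam(file, dest, overwrite = TRUE, indexDestination = FALSE),
      error = function(e)
        stop("failed to parse SAM '", file, "': ", conditionMessage(e),
             call. = FALSE))
  }
  bf <- Rsamtools::BamFile(file)  # htslib dispatches on BAM/CRAM magic
  param <- Rsamtools::ScanBamParam(what = c("qname", "flag", "seq", "cigar"))
  res <- tryCatch(Rsamtools::scanBam(bf, param = param)[[1L]],
                  error = function(e)
                    stop("failed to read alignments from '", file, "': ",
                         conditionMessage(e), call. = FALSE))
  flag <- res$flag
  n <- length(flag)
  data.frame(read_id = if (n) res$qname else character(0),
             sequence = if (n) toupper(as.character(res$seq)) else character(0),
             is_duplicate = bitwAnd(flag, .FLAG_DUP) > 0L,
             is_qc_fail = bitwAnd(flag, .FLAG_QCFAIL) > 0L,
             is_secondary_or_supplementary =
               bitwAnd(flag, bitwOr(.FLAG_SECONDARY, .FLAG_SUPPL)) > 0L,
             is_unmapped = bitwAnd(flag, .FLAG_UNMAPPED) > 0L,
             mapped_length = ifelse(bitwAnd(flag, .FLAG_UNMAPPED) > 0L, 0L,
                                    .cigar_aligned_bases(res$cigar)),
             stringsAsFactors = FALSE, row.names = NULL)
}

.apply_filters <- function(reads, filters) {
  stopifnot(inherits(filters, "read_filters"))
  keep <- rep(TRUE, nrow(reads))
  if (filters$drop_duplicates) keep <- keep & !reads$is_duplicate
  if (filters$drop_qc_fail) keep <- keep & !reads$is_qc_fail
  if (filters$drop_secondary) keep <- keep & !reads$is_secondary_or_supplementary
  if (filters$drop_unmapped) keep <- keep & !reads$is_unmapped
  reads[keep, , drop = FALSE]
}
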