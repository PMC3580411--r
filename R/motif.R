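#' Telomeric motif specification
#'
#' Describes the search pattern used to label a read as telomeric: `copies`
#' contiguous, exact repeats of `unit` (default the human telomeric repeat
#' `TTAGGG` repeated four times), optionally searched in both orientations
#' (the reverse complement of `(TTAGGG)4` is `(CCCTAA)4`).
#'
#' Matching is exact: no mismatches, no interruptions, and `N` never matches
#' any base. A single occurrence of either orientation anywhere in the read
#' is sufficient.
#'
#' @param unit Repeat unit, a non-empty DNA string over `A`, `C`, `G`, `T`
#'   (no `N`). Default `"TTAGGG"`.
#' @param copies Number of contiguous exact copies required (positive
#'   integer). Default `4`.
#' @param both_strands Search the reverse complement pattern as well?
#'   Default `TRUE`.
#' @return An object of class `motif_spec`: a list with the validated
#'   fields plus the two effective search patterns (`pattern_fwd`,
#'   `pattern_rev`).
#' @examples
#' spec <- motif_spec()
#' spec$pattern_fwd  # "TTAGGG" repeated 4 times
#' @export
motif_spec <- function(unit = "TTAGGG", copies = 4L, both_strands = TRUE) {
  if (!is.character(unit) || length(unit) != 1L || is.na(unit) || !nzchar(unit))
    stop("`unit` must be a single non-empty DNA string", call. = FALSE)
  unit <- toupper(unit)
  if (grepl("[^ACGT]", unit))
    stop("`unit` may contain only A, C, G, T (no N or IUPAC codes)",
         call. = FALSE)
  copies <- as.integer(copies)
  if (is.na(copies) || copies < 1L)
    stop("`copies` must be a positive integer", call. = FALSE)
  structure(
    list(unit = unit, copies = copies, both_strands = isTRUE(both_strands),
         pattern_fwd = strrep(unit, copies),
         pattern_rev = strrep(revcomp(unit), copies)),
    class = "motif_spec")
}

#' @export
print.motif_spec <- function(x, ...) {
  cat(sprintf("motif_spec: (%s)%d%s\n", x$unit, x$copies,
              if (x$both_strands)
                sprintf(" or (%s)%d", revcomp(x$unit), x$copies) else ""))
  invisible(x)
}

#' Reverse complement of DNA sequences
#'
#' Vectorized reverse complement over the alphabet `A`, `C`, `G`, `T`, `N`
#' (`N` maps to `N`). Input is uppercased first.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @examples
#' revcomp("TTAGGG")  # "CCCTAA"
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  x <- toupper(x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad))
    stop("non-ACGTN character in sequence(s): ",
         paste(utils::head(which(bad), 3L), collapse = ", "), call. = FALSE)
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1L),
         USE.NAMES = FALSE)
}

#' Does a read contain the telomeric motif?
#'
#' Tests each sequence for an exact, contiguous occurrence of the motif
#' pattern (`unit` repeated `copies` times) in either orientation. A read
#' with several occurrences, or with both orientations, still yields a
#' single `TRUE`.
#'
#' @param sequences Character vector of read sequences (any case; `N`
#'   allowed and never matches).
#' @param spec A [motif_spec()].
#' @return Logical vector, one element per sequence.
#' @examples
#' contains_telomere_motif(c(strrep("TTAGGG", 4), "ACGTACGT"))
#' @export
contains_telomere_motif <- function(sequences, spec = motif_spec()) {
  stopifnot(inherits(spec, "motif_spec"))
  if (length(sequences) == 0L) return(logical(0))
  sequences <- toupper(as.character(sequences))
  hit <- grepl(spec$pattern_fwd, sequences, fixed = TRUE)
  if (spec$both_strands)
    hit <- hit | grepl(spec$pattern_rev, sequences, fixed = TRUE)
  hit
}
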