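#' Mann-Whitney rank-sum comparison of two groups
#'
#' Unpaired two-sample rank test (Wilcoxon rank-sum / Mann-Whitney U).
#' Uses exact enumeration when the combined sample size is at most 20 and
#' there are no ties, otherwise the tie-corrected normal approximation
#' with continuity correction. An empty group yields a not-applicable
#' result (`U` and `p` both `NA`) rather than an error, matching how
#' cohort strata with no telomere-gain samples are reported.
#'
#' @param x,y Numeric vectors (either may be empty).
#' @param alternative `"two_sided"`, `"greater"` (x tends larger), or
#'   `"less"`.
#' @param paired Use the paired signed-rank variant instead (requires
#'   equal lengths). Default `FALSE`.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact branch;
#'   `NULL` (default) applies the rule above.
#' @return An object of class `rank_sum_test`: list with `statistic`
#'   (Mann-Whitney U, i.e. rank-sum of `x` minus its minimum), `p_value`,
#'   `n_x`, `n_y`, `method`, `applicable`.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))  # exact p = 0.1
#' @export
rank_sum_test <- function(x, y,
                          alternative = c("two_sided", "greater", "less"),
                          paired = FALSE, exact = NULL) {
  alternative <- match.arg(alternative)
  alt <- sub("_", ".", alternative, fixed = TRUE)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L)
    return(structure(list(statistic = NA_real_, p_value = NA_real_,
                          n_x = length(x), n_y = length(y),
                          method = "not applicable (empty group)",
                          applicable = FALSE),
                     class = "rank_sum_test"))
  if (paired && length(x) != length(y))
    stop("paired test requires equal-length vectors", call. = FALSE)
  if (length(unique(c(x, y))) == 1L)  # fully tied pool: no evidence either way
    return(structure(list(statistic = length(x) * length(y) / 2, p_value = 1,
                          n_x = length(x), n_y = length(y),
                          method = "rank sum (all values tied)",
                          applicable = TRUE),
                     class = "rank_sum_test"))
  if (is.null(exact))
    exact <- !paired && (length(x) + length(y)) <= 20L &&
      !anyDuplicated(c(x, y))
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = alt, paired = paired, exact = exact,
                correct = TRUE))
  structure(list(statistic = unname(wt$statistic), p_value = wt$p.value,
                 n_x = length(x), n_y = length(y), method = wt$method,
                 applicable = TRUE),
            class = "rank_sum_test")
}

#' @export
print.rank_sum_test <- function(x, ...) {
  if (!x$applicable) {
    cat("rank_sum_test: P = NA (not applicable - empty group)\n")
  } else {
    cat(sprintf("rank_sum_test: U = %g, P = %.4g (n = %d vs %d)\n  %s\n",
                x$statistic, x$p_value, x$n_x, x$n_y, x$method))
  }
  invisible(x)
}

.check_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  if (!"call" %in% names(cohort))
    stop("cohort table needs a `call` column (gain/loss/no_change)",
         call. = FALSE)
  bad <- !as.character(cohort$call) %in% c("gain", "loss", "no_change")
  if (any(bad))
    stop("unknown telomere call(s): ",
         paste(unique(cohort$call[bad]), collapse = ", "), call. = FALSE)
  invisible(cohort)
}

#' Mutation / SV burden by telomere status
#'
#' Per-status medians of a somatic burden (structural-variation or
#' non-silent mutation counts) plus a rank-sum test of the `gain` group
#' against everything else (`loss` and `no_change` pooled). Strata with no
#' gain samples — as happens for hematopoietic malignancies — report
#' `P = NA` (not applicable) instead of failing.
#'
#' @param cohort Data frame with columns `call` and the burden column
#'   (`sv_count` or `nonsilent_mutation_count`), optionally
#'   `disease_group`.
#' @param burden `"sv"` or `"mutation"`.
#' @param groups Optional subset of `disease_group` values to keep before
#'   testing.
#' @return A one-row data frame: per-status medians and sample counts,
#'   the Mann-Whitney `U` and `p_value` of gain vs rest (`NA` when not
#'   applicable).
#' @export
burden_by_status <- function(cohort, burden = c("sv", "mutation"),
                             groups = NULL) {
  burden <- match.arg(burden)
  .check_cohort(cohort)
  col <- if (burden == "sv") "sv_count" else "nonsilent_mutation_count"
  if (!col %in% names(cohort))
    stop("cohort table lacks column `", col, "`", call. = FALSE)
  if (!is.null(groups)) {
    if (!"disease_group" %in% names(cohort))
      stop("no `disease_group` column to filter on", call. = FALSE)
    cohort <- cohort[cohort$disease_group %in% groups, , drop = FALSE]
  }
  v <- as.numeric(cohort[[col]])
  if (any(v < 0, na.rm = TRUE))
    stop("burden counts must be non-negative", call. = FALSE)
  cl <- as.character(cohort$call)
  med <- function(status) if (any(cl == status)) median(v[cl == status]) else NA_real_
  gain <- v[cl == "gain"]
  other <- v[cl != "gain"]
  rt <- rank_sum_test(gain, other, alternative = "two_sided")
  data.frame(burden = burden,
             n_gain = sum(cl == "gain"), n_loss = sum(cl == "loss"),
             n_no_change = sum(cl == "no_change"),
             median_gain = med("gain"), median_loss = med("loss"),
             median_no_change = med("no_change"),
             median_other = if (length(other)) median(other) else NA_real_,
             U = rt$statistic, p_value = rt$p_value,
             stringsAsFactors = FALSE)
}

#' Telomere-status fractions per disease group
#'
#' Counts and percentages of gain / loss / no-change calls, overall or
#' within each level of a grouping column (e.g. `disease_group` or a
#' disease label). Percentages within a group sum to 100 before rounding.
#'
#' @param cohort Data frame with a `call` column.
#' @param by Optional name of a grouping column.
#' @return Data frame with `group`, `call`, `n`, `percent`.
#' @examples
#' co <- data.frame(call = c("gain", "gain", "loss", "no_change"))
#' status_fractions(co)
#' @export
status_fractions <- function(cohort, by = NULL) {
  .check_cohort(cohort)
  if (nrow(cohort) == 0L) stop("cohort is empty", call. = FALSE)
  grp <- if (is.null(by)) rep("all", nrow(cohort)) else {
    if (!by %in% names(cohort))
      stop("no column `", by, "` in cohort", call. = FALSE)
    as.character(cohort[[by]])
  }
  lv <- c("gain", "loss", "no_change")
  pieces <- split(as.character(cohort$call), grp)
  out <- do.call(rbind, lapply(names(pieces), function(g) {
    calls <- pieces[[g]]
    n <- vapply(lv, function(s) sum(calls == s), integer(1))
    data.frame(group = g, call = lv, n = n,
               percent = 100 * n / length(calls), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
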