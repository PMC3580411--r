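#' Call telomere gain / loss / no change from a two-component fit
#'
#' Under the BIC-selected two-component model of cohort delta-T values,
#' the lower-mean component collects tumors that lost telomeric DNA and
#' the higher-mean component those that gained it. A sample is called
#' `gain` when it rejects the lower component through its upper tail at
#' significance `alpha` (delta-T above `gain_boundary = mu_low +
#' z_{1-alpha} * sigma_low`), `loss` when it rejects the upper component
#' through its lower tail (delta-T below `loss_boundary = mu_high -
#' z_{1-alpha} * sigma_high`), and `no_change` otherwise. With the default
#' `alpha = 0.01`, `z_{0.99} = 2.326`.
#'
#' When the two components are separated by more than `2 * z * sigma`, the
#' boundaries cross and a delta-T between them rejects both components; such
#' samples are assigned by maximum posterior probability (lower component
#' to `loss`, upper to `gain`) with a warning.
#'
#' @param delta_ts Numeric vector of delta-T values to call.
#' @param fit A `mixture_fit` with exactly two components; equal variance
#'   expected (a per-component-variance fit is accepted with a warning,
#'   using each component's own sigma in its boundary).
#' @param alpha One-sided significance level in (0, 0.5); default 0.01.
#' @param pair_ids Optional sample labels.
#' @param two_sided Use two-sided tails (`z_{1-alpha/2}`)? Default `FALSE`
#'   (one-sided).
#' @return A data frame of class `telomere_calls`: `pair_id`, `delta_t`,
#'   `call` (factor `loss < no_change < gain`), `p_vs_lower_component`,
#'   `p_vs_upper_component`, `gain_boundary`, `loss_boundary`.
#' @examples
#' fit <- mixture_fit(means = c(-0.6, 0.4), variances = 0.25)
#' classify_samples(c(0, 0.8, -1), fit)
#' @export
classify_samples <- function(delta_ts, fit, alpha = 0.01, pair_ids = NULL,
                             two_sided = FALSE) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (fit$n_components != 2L)
    stop("classification requires a two-component fit (got G = ",
         fit$n_components, "); pass the BIC-selected G = 2 model",
         call. = FALSE)
  if (fit$variance_model == "unequal" &&
      abs(diff(fit$variances)) > 1e-12)
    warning("unequal-variance fit: boundaries use each component's own sigma")
  if (!(alpha > 0 && alpha < 0.5))
    stop("alpha must be in (0, 0.5)", call. = FALSE)
  x <- as.numeric(delta_ts)
  if (anyNA(x) || any(!is.finite(x)))
    stop("delta-T values must be finite", call. = FALSE)
  if (is.null(pair_ids)) pair_ids <- sprintf("sample%03d", seq_along(x))

  mu <- fit$means
  sd2 <- sqrt(fit$variances)
  z <- qnorm(1 - if (two_sided) alpha / 2 else alpha)
  gain_boundary <- mu[1L] + z * sd2[1L]
  loss_boundary <- mu[2L] - z * sd2[2L]

  p_lower <- pnorm(x, mu[1L], sd2[1L], lower.tail = FALSE)
  p_upper <- pnorm(x, mu[2L], sd2[2L], lower.tail = TRUE)
  above_gain <- x > gain_boundary
  below_loss <- x < loss_boundary

  call <- rep("no_change", length(x))
  call[above_gain & !below_loss] <- "gain"
  call[below_loss & !above_gain] <- "loss"
  both <- above_gain & below_loss
  if (any(both)) {
    warning(sum(both), " sample(s) reject both components ",
            "(boundaries cross for well-separated fits); ",
            "assigned by maximum posterior")
    post_low <- log(fit$weights[1L]) + dnorm(x[both], mu[1L], sd2[1L], log = TRUE)
    post_high <- log(fit$weights[2L]) + dnorm(x[both], mu[2L], sd2[2L], log = TRUE)
    call[both] <- ifelse(post_low >= post_high, "loss", "gain")
  }

  structure(
    data.frame(pair_id = pair_ids, delta_t = x,
               call = factor(call, levels = c("loss", "no_change", "gain")),
               p_vs_lower_component = p_lower,
               p_vs_upper_component = p_upper,
               gain_boundary = gain_boundary, loss_boundary = loss_boundary,
               stringsAsFactors = FALSE),
    class = c("telomere_calls", "data.frame"))
}

#' Concordance of WGS telomere calls with an external assay
#'
#' Validation-style agreement between the WGS ternary calls and an
#' external measurement:
#' * `mode = "qpcr"` — the external value is a log-ratio of tumor vs
#'   normal telomere quantity. Only WGS `gain`/`loss` samples are
#'   assessed (a `no_change` call is ambiguous on a continuous scale);
#'   a sample is concordant when the sign of the external log-ratio
#'   matches the call.
#' * `mode = "fish"` — the external assay reports `normal` / `abnormal`
#'   only. WGS `gain` maps to `abnormal`; `loss` and `no_change` map to
#'   `normal`; concordance is plain percent agreement.
#'
#' @param calls A `telomere_calls` data frame (or any data frame with
#'   `pair_id` and `call`).
#' @param external A data frame with `pair_id` plus `log_ratio` (qpcr
#'   mode) or `label` with values `normal`/`abnormal` (fish mode).
#' @param mode `"qpcr"` or `"fish"`.
#' @return Percent concordance in `[0, 100]` (scalar), with the number of
#'   samples assessed as attribute `n`.
#' @export
concordance <- function(calls, external, mode = c("qpcr", "fish")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(calls), is.data.frame(external),
            all(c("pair_id", "call") %in% names(calls)))
  merged <- merge(calls[, c("pair_id", "call")], external, by = "pair_id")
  if (nrow(merged) == 0L)
    stop("no overlapping sample ids between WGS calls and external assay",
         call. = FALSE)
  cl <- as.character(merged$call)
  if (mode == "qpcr") {
    if (is.null(merged$log_ratio))
      stop("qpcr mode needs a `log_ratio` column", call. = FALSE)
    keep <- cl %in% c("gain", "loss")
    if (!any(keep)) {
      warning("no gain/loss calls among overlapping samples; ",
              "qPCR concordance undefined")
      return(structure(NA_real_, n = 0L))
    }
    agree <- (cl[keep] == "gain" & merged$log_ratio[keep] > 0) |
             (cl[keep] == "loss" & merged$log_ratio[keep] < 0)
    structure(100 * mean(agree), n = sum(keep))
  } else {
    if (is.null(merged$label))
      stop("fish mode needs a `label` column (normal/abnormal)", call. = FALSE)
    pred <- ifelse(cl == "gain", "abnormal", "normal")
    structure(100 * mean(pred == tolower(as.character(merged$label))),
              n = nrow(merged))
  }
}
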