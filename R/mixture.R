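# Gaussian mixture modeling of cohort delta-T values.
#
# One-dimensional EM with either a shared (equal) or per-component
# (unequal) variance, canonicalized so component means are ascending.
# BIC uses the model-based-clustering convention 2*LL - p*ln(n): larger
# is better.

.gmm_free_params <- function(G, variance_model) {
  (G - 1L) + G + if (variance_model == "equal") 1L else G
}

.gmm_loglik <- function(x, means, vars, weights) {
  G <- length(means)
  ld <- matrix(0, length(x), G)
  for (g in seq_len(G))
    ld[, g] <- log(weights[g]) - 0.5 * log(2 * pi * vars[g]) -
      (x - means[g])^2 / (2 * vars[g])
  m <- ld[, 1L]
  if (G > 1L) for (g in 2:G) m <- pmax(m, ld[, g])
  e <- exp(ld - m)
  rs <- rowSums(e)
  list(ll = sum(m + log(rs)), resp = e / rs)
}

#' Construct a mixture fit from known parameters
#'
#' Builds a `mixture_fit` object directly from component means, variances
#' and weights, e.g. to classify samples under a previously published or
#' externally fitted model. Components are reordered so means ascend.
#'
#' @param means Numeric vector of component means (log2 delta-T units).
#' @param variances Numeric vector of component variances; a single value
#'   is recycled and marks the model as equal-variance.
#' @param weights Mixing weights; default uniform. Must sum to 1 (they are
#'   renormalized if off by rounding).
#' @param n_samples Number of observations behind the fit, if known
#'   (needed only for BIC).
#' @param log_likelihood Optional log-likelihood (for BIC).
#' @return A `mixture_fit` object.
#' @examples
#' mixture_fit(means = c(-0.6, 0.4), variances = 0.25)
#' @export
mixture_fit <- function(means, variances, weights = NULL, n_samples = NA_integer_,
                        log_likelihood = NA_real_) {
  G <- length(means)
  variance_model <- if (length(variances) == 1L) "equal" else "unequal"
  variances <- rep_len(as.numeric(variances), G)
  if (any(variances <= 0)) stop("variances must be positive", call. = FALSE)
  if (is.null(weights)) weights <- rep(1 / G, G)
  weights <- weights / sum(weights)
  o <- order(means)
  fit <- structure(
    list(n_components = G, means = as.numeric(means)[o],
         variance_model = variance_model, variances = variances[o],
         weights = weights[o], log_likelihood = log_likelihood,
         bic = NA_real_, n_samples = as.integer(n_samples),
         converged = NA, seed = NA_integer_, ll_trace = numeric(0)),
    class = "mixture_fit")
  if (is.finite(log_likelihood) && !is.na(n_samples)) fit$bic <- mixture_bic(fit)
  fit
}

#' Fit a univariate Gaussian mixture to delta-T values by EM
#'
#' Expectation-maximization with `n_restarts` initializations (the first
#' from evenly spaced quantiles, the rest from random draws, each refined
#' by one-dimensional k-means), keeping the restart with the best final
#' log-likelihood. The log-likelihood is non-decreasing within each EM
#' run; convergence is declared when its relative change falls below
#' `tol`. Variances are floored at `var_floor` to prevent a component
#' collapsing onto a single point. `G = 1` uses the closed-form maximum
#' likelihood solution (sample mean, biased sample variance).
#'
#' @param x Numeric vector of delta-T values (finite, no `NA`).
#' @param G Number of components.
#' @param variance_model `"equal"` (one shared variance) or `"unequal"`.
#' @param seed Integer seed controlling the restarts.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per restart.
#' @param n_restarts Number of initializations.
#' @param var_floor Lower bound on component variances.
#' @return A `mixture_fit` with fields `n_components`, `means` (ascending),
#'   `variance_model`, `variances`, `weights`, `log_likelihood`, `bic`,
#'   `n_samples`, `converged`, `seed`, and the winning restart's `ll_trace`.
#' @examples
#' set.seed(3)
#' x <- c(rnorm(70, -0.5, 0.3), rnorm(30, 1.0, 0.3))
#' fit_mixture(x, G = 2)
#' @export
fit_mixture <- function(x, G, variance_model = c("equal", "unequal"),
                        seed = 1L, tol = 1e-8, max_iter = 1000L,
                        n_restarts = 10L, var_floor = 1e-6) {
  variance_model <- match.arg(variance_model)
  x <- as.numeric(x)
  if (anyNA(x) || any(!is.finite(x)))
    stop("delta-T values must be finite with no NA/NaN", call. = FALSE)
  n <- length(x)
  G <- as.integer(G)
  if (G < 1L) stop("G must be >= 1", call. = FALSE)
  if (n < 2L * G)
    stop("need at least 2*G = ", 2L * G, " values to fit G = ", G,
         " components (got ", n, ")", call. = FALSE)
  if (G >= 2L && length(unique(x)) == 1L)
    stop("all delta-T values are identical; a ", G,
         "-component mixture is degenerate", call. = FALSE)

  if (G == 1L) {
    mu <- mean(x)
    v <- max(mean((x - mu)^2), var_floor)
    ll <- sum(dnorm(x, mu, sqrt(v), log = TRUE))
    fit <- mixture_fit(mu, v, 1, n_samples = n, log_likelihood = ll)
    fit$variance_model <- variance_model
    fit$bic <- mixture_bic(fit)
    fit$converged <- TRUE
    fit$seed <- as.integer(seed)
    fit$ll_trace <- ll
    return(fit)
  }

  # Initial hard partitions for every restart: quantile centers for the
  # first, random draws for the rest, each refined by 1-D k-means. Restarts
  # whose k-means partition coincides would retrace the same EM path, so
  # only unique partitions are iterated (identical init => identical fit).
  inits <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    set.seed(as.integer(seed) + r - 1L)
    centers <- if (r == 1L)
      quantile(x, probs = (seq_len(G) - 0.5) / G, names = FALSE)
    else sample(x, G)
    centers <- sort(centers + runif(G, -1e-9, 1e-9))  # kmeans needs distinct centers
    inits[[r]] <- tryCatch(kmeans(x, centers = centers)$cluster,
                           error = function(e)
                             max.col(-abs(outer(x, centers, "-"))))
  }
  inits <- unique(inits)

  best <- NULL
  for (assign in inits) {
    mu <- vapply(seq_len(G), function(g)
      if (any(assign == g)) mean(x[assign == g]) else mean(x), numeric(1))
    vv <- vapply(seq_len(G), function(g)
      if (sum(assign == g) > 1L) mean((x[assign == g] - mu[g])^2)
      else mean((x - mean(x))^2), numeric(1))
    if (variance_model == "equal") vv <- rep(mean(vv), G)
    vv <- pmax(vv, var_floor)
    w <- pmax(tabulate(assign, G) / n, 1 / (2 * n))
    w <- w / sum(w)

    es <- .gmm_loglik(x, mu, vv, w)
    ll <- es$ll
    trace <- numeric(max_iter + 1L)
    trace[1L] <- ll
    nt <- 1L
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      resp <- es$resp
      nk <- colSums(resp)
      w <- nk / n
      mu <- colSums(resp * x) / nk
      for (g in seq_len(G)) vv[g] <- sum(resp[, g] * (x - mu[g])^2)
      vv <- if (variance_model == "equal")
        rep(max(sum(vv) / n, var_floor), G) else pmax(vv / nk, var_floor)
      es <- .gmm_loglik(x, mu, vv, w)
      nt <- nt + 1L
      trace[nt] <- es$ll
      if (abs(es$ll - ll) <= tol * (abs(ll) + .Machine$double.eps)) {
        converged <- TRUE
        ll <- es$ll
        break
      }
      ll <- es$ll
    }
    if (is.null(best) || ll > best$ll)
      best <- list(ll = ll, mu = mu, vv = vv, w = w, trace = trace[seq_len(nt)],
                   converged = converged)
  }

  o <- order(best$mu)
  fit <- structure(
    list(n_components = G, means = best$mu[o], variance_model = variance_model,
         variances = best$vv[o], weights = best$w[o],
         log_likelihood = best$ll, bic = NA_real_, n_samples = n,
         converged = best$converged, seed = as.integer(seed),
         ll_trace = best$trace),
    class = "mixture_fit")
  fit$bic <- mixture_bic(fit)
  fit
}

#' Bayesian information criterion of a mixture fit
#'
#' `2 * logLik - p * ln(n)` with `p` the number of free parameters
#' (`G - 1` weights, `G` means, and one shared or `G` per-component
#' variances). Larger values indicate a better model, as in model-based
#' clustering.
#'
#' @param fit A fitted `mixture_fit` with finite log-likelihood and known
#'   `n_samples`.
#' @return The BIC value.
#' @export
mixture_bic <- function(fit) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (!is.finite(fit$log_likelihood) || is.na(fit$n_samples))
    stop("fit lacks a finite log-likelihood or sample size", call. = FALSE)
  p <- .gmm_free_params(fit$n_components, fit$variance_model)
  2 * fit$log_likelihood - p * log(fit$n_samples)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("mixture_fit: G = %d (%s variance)%s\n", x$n_components,
              x$variance_model,
              if (isTRUE(x$converged)) "" else " [not converged]"))
  cat("  means:    ", paste(sprintf("%.4f", x$means), collapse = "  "), "\n")
  cat("  sds:      ", paste(sprintf("%.4f", sqrt(x$variances)), collapse = "  "), "\n")
  cat("  weights:  ", paste(sprintf("%.3f", x$weights), collapse = "  "), "\n")
  if (is.finite(x$bic)) cat(sprintf("  BIC: %.2f (n = %d)\n", x$bic, x$n_samples))
  invisible(x)
}

#' Select the mixture model by BIC
#'
#' Fits every combination of component count in `G_range` and variance
#' structure in `variance_models` and returns the fit with the largest
#' BIC. Exact ties break toward fewer components, then toward the
#' equal-variance model (parsimony). `G = 1` is fitted once (the two
#' variance structures coincide).
#'
#' @inheritParams fit_mixture
#' @param G_range Integer vector of candidate component counts.
#' @param variance_models Candidate variance structures.
#' @param ... Passed to [fit_mixture()] (`tol`, `max_iter`, `n_restarts`,
#'   `var_floor`).
#' @return The winning `mixture_fit`, with the full candidate grid as a
#'   data frame in `attr(fit, "model_grid")`.
#' @examples
#' set.seed(3)
#' x <- c(rnorm(160, -0.5, 0.3), rnorm(75, 1.0, 0.3))
#' fit <- select_model(x, seed = 3)
#' attr(fit, "model_grid")
#' @export
select_model <- function(x, G_range = 1:4,
                         variance_models = c("equal", "unequal"),
                         seed = 1L, ...) {
  grid <- expand.grid(G = sort(unique(as.integer(G_range))),
                      variance_model = variance_models,
                      stringsAsFactors = FALSE)
  grid <- grid[!(grid$G == 1L & duplicated(grid$G)), , drop = FALSE]
  fits <- vector("list", nrow(grid))
  errs <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    fits[[i]] <- tryCatch(
      fit_mixture(x, G = grid$G[i], variance_model = grid$variance_model[i],
                  seed = seed, ...),
      error = function(e) { errs[i] <<- conditionMessage(e); NULL })
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok))
    stop("no candidate mixture model could be fitted: ",
         paste(unique(errs[nzchar(errs)]), collapse = "; "), call. = FALSE)
  tab <- data.frame(G = grid$G, variance_model = grid$variance_model,
                    bic = vapply(fits, function(f)
                      if (is.null(f)) NA_real_ else f$bic, numeric(1)),
                    converged = vapply(fits, function(f)
                      if (is.null(f)) NA else f$converged, logical(1)))
  idx <- which(ok)
  # max BIC; break exact ties toward smaller G, then equal variance
  ord <- order(-tab$bic[idx], tab$G[idx], tab$variance_model[idx] != "equal")
  best <- fits[[idx[ord[1L]]]]
  attr(best, "model_grid") <- tab
  best
}
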