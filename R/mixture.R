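#' @include AllClasses.R
NULL

# log-likelihood of a 1-D Gaussian mixture
gmmLogLik <- function(x, w, mu, sd) {
  dens <- vapply(seq_along(w), function(j) {
    w[j] * stats::dnorm(x, mu[j], sd[j])
  }, numeric(length(x)))
  dens <- if (is.matrix(dens)) rowSums(dens) else sum(dens)
  sum(log(pmax(dens, .Machine$double.xmin)))
}

# one EM run from a given initialisation (compiled); returns
# parameters + loglik
emRun <- function(x, k, mu0, maxIter = 500L, tol = 1e-8,
                  varFloor = 1e-6) {
  .emFit(x, as.integer(k), as.numeric(mu0), as.integer(maxIter), tol,
         varFloor)
}

#' Fit a 1-D Gaussian mixture to pooled delta-r values, selecting k by BIC
#'
#' Expectation-maximisation fits with k = 1..`kMax` components are
#' compared by the Bayesian information criterion
#' (`BIC = -2 logL + (3k - 1) log n`); the reported model minimises BIC,
#' with ties broken toward smaller k. Each k is fit from `nRestarts`
#' random initialisations under a deterministic seed schedule (component
#' means initialised at randomly drawn data points). Component variances
#' are floored at `varFloor` (with a warning) so EM cannot collapse onto
#' a single observation. The `matchComponent` is the component whose
#' mean lies nearest zero.
#'
#' @param deltaRs Numeric vector of delta-r values pooled over
#'   electrodes and day pairs within one group (>= 10 finite values).
#' @param kMax Largest number of components considered (default 5).
#' @param seed Seed for the restart schedule.
#' @param nRestarts Random restarts per k (default 10).
#' @param varFloor Variance floor (default 1e-6).
#' @return A [MixtureFit-class].
#' @examples
#' x <- c(rnorm(200, 0, 0.05), rnorm(100, -1, 0.1))
#' fitDeltaRMixture(x, seed = 1)
#' @export
fitDeltaRMixture <- function(deltaRs, kMax = 5L, seed = 1L,
                             nRestarts = 10L, varFloor = 1e-6) {
  x <- sort(deltaRs[is.finite(deltaRs)]) # order-invariant fits
  abortIf(length(x) < 10L,
          "insufficient data: need at least 10 finite delta-r values")
  n <- length(x)
  kMax <- as.integer(kMax)

  best <- vector("list", kMax)
  anyFloored <- FALSE
  for (k in seq_len(kMax)) {
    if (k == 1L) {
      mu <- mean(x)
      v <- max(mean((x - mu)^2), varFloor)
      best[[1L]] <- list(
        w = 1, mu = mu, sd = sqrt(v),
        logLik = sum(stats::dnorm(x, mu, sqrt(v), log = TRUE)),
        floored = FALSE
      )
      next
    }
    fits <- lapply(seq_len(nRestarts), function(r) {
      mu0 <- withSeed(deriveSeed(seed, k, r), sample(x, k))
      emRun(x, k, mu0, varFloor = varFloor)
    })
    best[[k]] <- fits[[which.max(vapply(fits, `[[`, numeric(1), "logLik"))]]
  }
  anyFloored <- any(vapply(best, `[[`, logical(1), "floored"))
  if (anyFloored) {
    warning("EM component variance floored at ", varFloor)
  }

  bic <- vapply(seq_len(kMax), function(k) {
    -2 * best[[k]]$logLik + (3 * k - 1) * log(n)
  }, numeric(1))
  kSel <- which.min(bic) # first minimum: ties break toward smaller k
  fit <- best[[kSel]]
  ord <- order(fit$mu)
  new("MixtureFit",
    k = as.integer(kSel),
    weights = as.numeric(fit$w[ord]) / sum(fit$w),
    means = as.numeric(fit$mu[ord]),
    sds = as.numeric(fit$sd[ord]),
    bicByK = data.frame(
      k = seq_len(kMax),
      logLik = vapply(best, `[[`, numeric(1), "logLik"),
      bic = bic
    ),
    matchComponent = as.integer(which.min(abs(fit$mu[ord]))),
    logLik = fit$logLik,
    n = as.integer(n)
  )
}

#' Assign a five-way change category to a delta-r value
#'
#' Categories are defined by one and two standard deviations of the
#' mixture's match component (mean `mu`, SD `sigma`): `match` when
#' `|delta_r - mu| <= sigma`; `small_increase` / `small_decrease` when
#' the deviation lies between one and two sigma; `large_increase` /
#' `large_decrease` beyond two sigma. The five categories tile the real
#' line with no gaps or overlaps.
#'
#' @param deltaR Numeric vector of delta-r values.
#' @param fit A [MixtureFit-class].
#' @return Factor with levels `large_decrease`, `small_decrease`,
#'   `match`, `small_increase`, `large_increase`.
#' @export
categorizeDeltaR <- function(deltaR, fit) {
  mc <- matchComponent(fit)
  z <- (deltaR - mc["mean"]) / mc["sd"]
  lev <- c("large_decrease", "small_decrease", "match", "small_increase",
           "large_increase")
  out <- character(length(deltaR))
  out[z < -2] <- "large_decrease"
  out[z >= -2 & z < -1] <- "small_decrease"
  out[abs(z) <= 1] <- "match"
  out[z > 1 & z <= 2] <- "small_increase"
  out[z > 2] <- "large_increase"
  factor(out, levels = lev)
}
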