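#' Fit a two-Gaussian mixture to a scaling-exponent distribution
#'
#' The distribution of sliding-window scaling exponents pooled over a
#' condition is bimodal: one component near alpha = 1 (diffusive windows)
#' and one near alpha = 2 (directed windows). This fits a two-component
#' Gaussian mixture with unequal variances by maximum likelihood and places
#' the classification cutoff between the two means.
#'
#' Two cutoff rules are available. `"pooled"` (the default) solves the
#' equal-weighted-density condition after assigning both components their
#' pooled width `sqrt(w1 s1^2 + w2 s2^2)`; for components of comparable
#' width this coincides with the plain equal-density point, but it remains
#' mid-valley when the window population contains boundary windows of
#' intermediate exponent, which inflate the diffusive component's width
#' while the directed component stays narrow and would otherwise drag the
#' equal-density point onto the directed component's shoulder.
#' `"equal_density"` is the classical rule: the point between the means
#' where the weighted component densities are equal (the smaller root when
#' two such points lie between the means).
#'
#' @param alphas Numeric vector of scaling exponents (at least 50 finite
#'   values spanning both motion modes).
#' @param seed Integer seed controlling the (subset) initialization for
#'   large inputs; the fit is deterministic given `alphas` and `seed`.
#' @param cutoff_method `"pooled"` or `"equal_density"` (see Details).
#' @param init_subset_max Above this sample size, the mixture is
#'   initialized from a random subset of this size.
#' @return An object of class `two_gaussian_model`: list with `weights`,
#'   `means`, `sds` (components ordered by increasing mean: diffusive
#'   first), `cutoff`, `loglik` and `n`.
#' @importFrom mclust Mclust mclustBIC
#' @export
fit_alpha_distribution <- function(alphas, seed = 1L,
                                   cutoff_method = c("pooled", "equal_density"),
                                   init_subset_max = 5000L) {
  cutoff_method <- match.arg(cutoff_method)
  x <- alphas[is.finite(alphas)]
  if (length(x) < 50L) {
    stop("need at least 50 finite alpha values to fit the mixture (got ",
         length(x), ")", call. = FALSE)
  }
  init <- NULL
  if (length(x) > init_subset_max) {
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(seed)
    init <- list(subset = sample.int(length(x), init_subset_max))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  fit <- Mclust(x, G = 2, modelNames = "V", initialization = init,
                verbose = FALSE)
  if (is.null(fit)) stop("two-component mixture fit failed", call. = FALSE)
  w <- as.numeric(fit$parameters$pro)
  mu <- as.numeric(fit$parameters$mean)
  sd <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
  if (length(sd) == 1L) sd <- rep(sd, 2L)  # mclust collapses equal variances
  ord <- order(mu)
  w <- w[ord]; mu <- mu[ord]; sd <- sd[ord]
  if (any(w < 0.02)) {
    stop("degenerate mixture: a component carries weight ",
         signif(min(w), 3), " < 2%", call. = FALSE)
  }
  if (any(sd < 1e-4)) {
    stop("degenerate mixture: a component standard deviation collapsed",
         call. = FALSE)
  }
  cutoff <- if (cutoff_method == "pooled") {
    pooled_cutoff(w, mu, sd)
  } else {
    mixture_cutoff(w, mu, sd)
  }
  model <- list(weights = w, means = mu, sds = sd,
                cutoff = cutoff, cutoff_method = cutoff_method,
                loglik = fit$loglik, n = length(x))
  class(model) <- "two_gaussian_model"
  model
}

# Equal weighted-density point under a common (pooled) component width:
# (m1+m2)/2 + s^2 log(w1/w2) / (m2-m1), clamped strictly inside (m1, m2).
pooled_cutoff <- function(w, mu, sd) {
  s2 <- sum(w * sd^2)
  x <- mean(mu) + s2 * log(w[1] / w[2]) / (mu[2] - mu[1])
  eps <- 1e-6 * (mu[2] - mu[1])
  min(max(x, mu[1] + eps), mu[2] - eps)
}

# Equal weighted-density point between the two component means. Solves
# w1 N(x; m1, s1) = w2 N(x; m2, s2), a quadratic in x; the smaller root in
# (m1, m2) is chosen when two roots fall in the interval.
mixture_cutoff <- function(w, mu, sd) {
  a <- 1 / (2 * sd[2]^2) - 1 / (2 * sd[1]^2)
  b <- mu[1] / sd[1]^2 - mu[2] / sd[2]^2
  cc <- mu[2]^2 / (2 * sd[2]^2) - mu[1]^2 / (2 * sd[1]^2) +
    log(w[1] * sd[2] / (w[2] * sd[1]))
  eps <- sqrt(.Machine$double.eps)
  roots <- if (abs(a) < eps) {
    if (abs(b) < eps) numeric(0) else -cc / b
  } else {
    disc <- b * b - 4 * a * cc
    if (disc < 0) numeric(0)
    else (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  }
  inside <- roots[roots > mu[1] & roots < mu[2]]
  if (length(inside)) return(min(inside))
  # No equal-density point strictly between the means (extreme weight
  # imbalance); fall back to the interior point of closest densities.
  grid <- seq(mu[1], mu[2], length.out = 513)[-c(1, 513)]
  gap <- abs(log(w[1]) + stats::dnorm(grid, mu[1], sd[1], log = TRUE) -
               log(w[2]) - stats::dnorm(grid, mu[2], sd[2], log = TRUE))
  grid[which.min(gap)]
}

#' @export
print.two_gaussian_model <- function(x, ...) {
  cat("Two-Gaussian scaling-exponent mixture (n =", x$n, ")\n")
  cat(sprintf("  diffusive component: weight %.3f, mean %.3f, sd %.3f\n",
              x$weights[1], x$means[1], x$sds[1]))
  cat(sprintf("  directed component:  weight %.3f, mean %.3f, sd %.3f\n",
              x$weights[2], x$means[2], x$sds[2]))
  cat(sprintf("  cutoff alpha = %.3f\n", x$cutoff))
  invisible(x)
}
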