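#' Empirical-Bayes moderated one-sample t-test
#'
#' Tests the replicate values of each unit against mu = 0 with a variance
#' shrunken towards a prior: s~^2 = (d0 s0^2 + (R-1) s^2) / (d0 + R - 1),
#' t = mean / (s~ / sqrt(R)), two-sided p from a t distribution with
#' d0 + R - 1 degrees of freedom. When \code{params = "estimate"}, the prior
#' degrees of freedom d0 and prior variance s0^2 are estimated across units
#' by moment matching on the log sample variances, using the closed-form
#' digamma/trigamma identities of the scaled-F model for sample variances
#' (Smyth 2004): with z = log s^2 and e = z - digamma(df/2) + log(df/2),
#' E[e] = log s0^2 - digamma(d0/2) + log(d0/2) and
#' Var[e] = trigamma(df/2) + trigamma(d0/2).
#'
#' @param x numeric matrix, units x replicates (R >= 2). A plain vector is a
#'   single unit.
#' @param params \code{"estimate"}, or a list with elements \code{d0}
#'   (possibly \code{Inf}) and \code{s02}.
#' @return list with vectors \code{t}, \code{p}, \code{mean}, \code{s2},
#'   \code{s2_post}, and scalars \code{d0}, \code{s02}, \code{df_total}.
#' @export
moderated_t_test <- function(x, params = "estimate") {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  R <- ncol(x)
  if (R < 2) stop("need >= 2 replicates")
  xbar <- rowMeans(x)
  s2 <- apply(x, 1, stats::var)
  df <- R - 1
  if (identical(params, "estimate")) {
    fit <- fit_variance_prior(s2, df)
    d0 <- fit$d0; s02 <- fit$s02
  } else {
    if (!is.list(params) || is.null(params$d0) || is.null(params$s02))
      stop("params must be \"estimate\" or list(d0=, s02=)")
    d0 <- params$d0; s02 <- params$s02
    if (s02 <= 0 || (!is.infinite(d0) && d0 <= 0))
      stop("require d0 > 0 (or Inf) and s02 > 0")
  }
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2))
  else (d0 * s02 + df * s2) / (d0 + df)
  t <- xbar / sqrt(s2_post / R)
  df_total <- d0 + df
  p <- 2 * stats::pt(-abs(t), df = df_total)
  list(t = t, p = p, mean = xbar, s2 = s2, s2_post = s2_post,
       d0 = d0, s02 = s02, df_total = df_total)
}

#' Moment estimation of the variance prior (d0, s0^2)
#'
#' Closed-form estimators on the log sample variances; zero or missing
#' sample variances are excluded from estimation. If every variance is zero
#' the prior collapses to d0 = Inf with a small pooled epsilon variance, with
#' a warning.
#'
#' @param s2 sample variances across units.
#' @param df residual degrees of freedom per unit (replicates - 1).
#' @return list with \code{d0} and \code{s02}.
#' @export
fit_variance_prior <- function(s2, df) {
  s2 <- pmax(s2[is.finite(s2)], 0)
  if (length(s2) == 0 || stats::median(s2) == 0) {
    warning("half or more of the sample variances are zero; using d0 = Inf with epsilon prior")
    return(list(d0 = Inf, s02 = 1e-8))
  }
  # floor tiny variances before taking logs (numerical guard on the log scale)
  s2 <- pmax(s2, 1e-5 * stats::median(s2))
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- if (n > 1) sum((e - emean)^2) / (n - 1) - trigamma(df / 2) else -1
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(emean)
  }
  list(d0 = d0, s02 = s02)
}

# Newton inversion of the trigamma function (monotone decreasing on (0, Inf))
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}
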