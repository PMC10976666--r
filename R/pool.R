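#' Rubin's-rules pooling of per-imputation estimates
#'
#' Combines point estimates and variances across imputed datasets on a
#' declared scale — identity (calibration slope, CITL), log (E/O ratios,
#' odds ratios) or logit (proportions, C statistics) — and back-transforms
#' the point estimate and confidence interval for reporting. Total variance
#' is within + (1 + 1/m) x between; degrees of freedom follow Barnard-Rubin
#' when a finite complete-data df is supplied, and the classical large-sample
#' formula otherwise.
#'
#' Proportions exactly 0 or 1 cannot be pooled on the logit scale; when `n`
#' is supplied they are pulled in by the continuity correction `0.5 / (n + 1)`
#' so the transform stays finite.
#'
#' @param est numeric vector of per-imputation point estimates (natural scale)
#' @param var numeric vector of their variances (natural scale)
#' @param scale `"identity"`, `"log"` or `"logit"`
#' @param conf confidence level (default 0.95)
#' @param dfcom complete-data degrees of freedom (default `Inf`)
#' @param n sample size behind a proportion, for the logit boundary
#'   correction
#' @return An object of class `pooled_estimate`: list with `estimate`
#'   (back-transformed), `ci`, `m`, `within`, `between`, `total_var`
#'   (pooling-scale variances), `df`, `scale`.
#' @export
#' @examples
#' pool_rubin(c(0.6, 0.8), c(0.01, 0.01), scale = "identity")
pool_rubin <- function(est, var, scale = c("identity", "log", "logit"),
                       conf = 0.95, dfcom = Inf, n = NULL) {
  scale <- match.arg(scale)
  if (length(est) != length(var)) stop("est and var must have equal length")
  if (length(est) < 1) stop("need at least one estimate")
  if (any(!is.finite(var) | var < 0)) stop("variances must be finite and >= 0")

  if (scale == "log" && any(est <= 0))
    stop("log-scale pooling requires positive estimates")
  if (scale == "logit") {
    bad <- est <= 0 | est >= 1
    if (any(bad)) {
      if (is.null(n))
        stop("proportion at the logit boundary; supply n for the ",
             "0.5/(n+1) continuity correction")
      eps <- 0.5 / (n + 1)
      est <- pmin(pmax(est, eps), 1 - eps)
    }
  }

  tr <- switch(scale,
    identity = list(f = identity, inv = identity, d = function(x) 1),
    log = list(f = log, inv = exp, d = function(x) 1 / x),
    logit = list(f = stats::qlogis, inv = stats::plogis,
                 d = function(x) 1 / (x * (1 - x))))
  q <- tr$f(est)
  u <- var * tr$d(est)^2
  m <- length(est)

  qbar <- mean(q)
  W <- mean(u)
  B <- if (m > 1) stats::var(q) else 0
  Tv <- W + (1 + 1 / m) * B

  if (m == 1 || B == 0) {
    df <- dfcom
  } else {
    r <- (1 + 1 / m) * B / W
    lambda <- (1 + 1 / m) * B / Tv
    df_old <- (m - 1) * (1 + 1 / r)^2
    if (is.finite(dfcom)) {
      df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
      df <- 1 / (1 / df_old + 1 / df_obs)
    } else {
      df <- df_old
    }
  }
  tcrit <- if (is.finite(df)) stats::qt(1 - (1 - conf) / 2, df)
           else stats::qnorm(1 - (1 - conf) / 2)
  ci <- tr$inv(qbar + c(-1, 1) * tcrit * sqrt(Tv))

  out <- list(estimate = tr$inv(qbar), ci = ci, m = m, within = W,
              between = B, total_var = Tv, df = df, scale = scale,
              conf = conf)
  class(out) <- "pooled_estimate"
  out
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("Pooled estimate (%s scale, m = %d): %.4g [%g%% CI %.4g, %.4g]\n",
              x$scale, x$m, x$estimate, 100 * x$conf, x$ci[1], x$ci[2]))
  invisible(x)
}
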