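#' Box-Cox transformation parameter by maximum likelihood
#'
#' Profile log-likelihood estimate of the Box-Cox lambda for a strictly
#' positive sample (no regression structure: location/scale Gaussian model on
#' the transformed scale with the Jacobian term).
#'
#' @param x strictly positive numeric vector (length >= 2)
#' @param interval search interval for lambda
#' @return The MLE of lambda.
#' @export
boxcox_lambda <- function(x, interval = c(-2, 3)) {
  x <- x[!is.na(x)]
  if (length(x) < 2) stop("need at least two observed values")
  if (any(x <= 0)) stop("Box-Cox requires strictly positive values")
  n <- length(x)
  if (stats::var(x) < 1e-12) return(1)  # constant sample: transform irrelevant
  slx <- sum(log(x))
  prof <- function(l) {
    y <- if (abs(l) < 1e-8) log(x) else (x^l - 1) / l
    s2 <- stats::var(y) * (n - 1) / n
    -n / 2 * log(s2) + (l - 1) * slx
  }
  stats::optimize(prof, interval, maximum = TRUE)$maximum
}

.boxcox <- function(x, lambda) {
  if (abs(lambda) < 1e-8) log(x) else (x^lambda - 1) / lambda
}

# Bayesian linear regression draw (as used under chained-equation PMM):
# returns beta_hat, a posterior draw beta_star, and sigma_star
.norm_draw <- function(X, y) {
  qrX <- qr(X)
  beta_hat <- qr.coef(qrX, y)
  beta_hat[is.na(beta_hat)] <- 0
  res <- y - X %*% beta_hat
  df <- max(length(y) - qrX$rank, 1)
  sigma2_star <- sum(res^2) / stats::rchisq(1, df)
  R <- qr.R(qrX)[seq_len(qrX$rank), seq_len(qrX$rank), drop = FALSE]
  keep <- qrX$pivot[seq_len(qrX$rank)]
  z <- stats::rnorm(qrX$rank)
  beta_star <- beta_hat
  beta_star[keep] <- beta_hat[keep] + sqrt(sigma2_star) * backsolve(R, z)
  list(beta_hat = beta_hat, beta_star = beta_star)
}

# type-1 predictive mean matching of missing cells to observed donors
.pmm_match <- function(yhat_obs, yhat_mis, y_obs, donors) {
  ord <- order(yhat_obs)
  ys <- yhat_obs[ord]
  yo <- y_obs[ord]
  n_obs <- length(ys)
  k <- min(donors, n_obs)
  vapply(yhat_mis, function(v) {
    i <- findInterval(v, ys)
    lo <- max(1L, i - k)
    hi <- min(n_obs, i + k)
    window <- lo:hi
    d <- abs(ys[window] - v)
    cand <- window[order(d)[seq_len(k)]]
    yo[sample(cand, 1L)]
  }, numeric(1))
}

#' Multiple imputation of lab predictors by chained equations
#'
#' Imputes `platelet`, `gfr` and `inr` with chained equations using
#' predictive mean matching (Bayesian parameter draws, donor pool of 5) on a
#' transformed scale per variable: GFR on the shifted-log scale
#' (`log(gfr + shift)`), INR on the Box-Cox scale with lambda estimated by
#' maximum likelihood from the observed INRs, and platelets on the raw scale.
#' The conditional model for each lab regresses its transformed value on all
#' score predictors, the bleeding-outcome indicator, and the other two
#' (transformed) labs. Because PMM returns observed donor values, every
#' imputation is automatically strictly positive and within the observed
#' support.
#'
#' @param cohort cohort with `NA`s only in `platelet`, `gfr` (and
#'   `creatinine`), `inr`
#' @param m number of completed datasets (default 20)
#' @param seed RNG seed
#' @param iterations burn-in sweeps of the chained equations per dataset
#'   (default 10)
#' @param donors PMM donor-pool size (default 5)
#' @param gfr_shift shift constant of the GFR log transform (default 1)
#' @return An object of class `imputation_set`: a list with elements
#'   `m`, `data` (list of completed cohorts), `mask` (logical data frame of
#'   originally missing cells), `lambda` (per-dataset Box-Cox lambda for
#'   INR), `shift`, `seed`.
#' @export
impute_chained <- function(cohort, m = 20, seed = 1L, iterations = 10,
                           donors = 5, gfr_shift = 1) {
  vars <- c("platelet", "gfr", "inr")
  n <- nrow(cohort)
  mask <- as.data.frame(lapply(cohort[vars], is.na))
  other_na <- setdiff(names(cohort)[vapply(cohort, anyNA, logical(1))],
                      c(vars, "creatinine", "bleed_day"))
  if (length(other_na))
    stop("only platelet, gfr and inr may be missing; also missing: ",
         paste(other_na, collapse = ", "))
  for (v in vars) {
    obs <- cohort[[v]][!mask[[v]]]
    if (length(obs) == 0) stop("cannot impute: ", v, " is entirely missing")
    if (any(obs <= 0)) stop("non-positive observed ", v,
                            " values are outside the transform domain")
  }

  set.seed(seed)
  if (!any(unlist(mask))) {
    out <- list(m = m, data = replicate(m, cohort, simplify = FALSE),
                mask = mask, lambda = rep(NA_real_, m), shift = gfr_shift,
                seed = seed)
    class(out) <- "imputation_set"
    return(out)
  }

  # fixed regressors: score predictors + outcome indicator
  pred <- data.frame(
    age = cohort$age,
    male = cohort$sex == "male",
    ulcer = cohort$active_ulcer,
    bleed_3mo = cohort$bleed_3mo,
    icu_ccu = cohort$icu_ccu,
    cvc = cohort$cvc,
    rheumatic = cohort$rheumatic,
    cancer = cohort$cancer,
    outcome = cohort$any_bleed
  )
  Xfixed <- cbind(1, as.matrix(data.matrix(pred)))

  trans <- list(
    platelet = list(fwd = identity),
    gfr = list(fwd = function(x) log(x + gfr_shift)),
    inr = NULL # set per run (Box-Cox lambda re-estimated)
  )
  lambda_runs <- numeric(m)
  completed <- vector("list", m)

  for (run in seq_len(m)) {
    lambda <- boxcox_lambda(cohort$inr[!mask$inr])
    lambda_runs[run] <- lambda
    trans$inr <- list(fwd = function(x) .boxcox(x, lambda))

    filled <- cohort
    for (v in vars) {
      if (any(mask[[v]]))
        filled[[v]][mask[[v]]] <- sample(cohort[[v]][!mask[[v]]],
                                         sum(mask[[v]]), replace = TRUE)
    }
    for (it in seq_len(iterations)) {
      for (v in vars) {
        mis <- mask[[v]]
        if (!any(mis)) next
        others <- setdiff(vars, v)
        Z <- cbind(Xfixed,
                   trans[[others[1]]]$fwd(filled[[others[1]]]),
                   trans[[others[2]]]$fwd(filled[[others[2]]]))
        y_obs_raw <- cohort[[v]][!mis]
        y_obs <- trans[[v]]$fwd(y_obs_raw)
        dr <- .norm_draw(Z[!mis, , drop = FALSE], y_obs)
        yhat_obs <- drop(Z[!mis, , drop = FALSE] %*% dr$beta_hat)
        yhat_mis <- drop(Z[mis, , drop = FALSE] %*% dr$beta_star)
        filled[[v]][mis] <- .pmm_match(yhat_obs, yhat_mis, y_obs_raw, donors)
      }
    }
    if ("creatinine" %in% names(filled) && any(mask$gfr))
      filled$creatinine[mask$gfr] <-
        .creatinine_from_gfr(filled$gfr[mask$gfr], filled$age[mask$gfr],
                             filled$sex[mask$gfr])
    completed[[run]] <- filled
  }

  out <- list(m = m, data = completed, mask = mask, lambda = lambda_runs,
              shift = gfr_shift, seed = seed)
  class(out) <- "imputation_set"
  out
}

#' @export
print.imputation_set <- function(x, ...) {
  cat("Imputation set: m =", x$m, "completed datasets,",
      sum(unlist(x$mask)), "imputed cells\n")
  invisible(x)
}

#' Write an imputation set to disk
#'
#' One CSV per completed dataset plus a JSON manifest recording `m`, the
#' seed, the Box-Cox lambdas and the log-shift.
#'
#' @param imp an `imputation_set`
#' @param dir output directory (created if needed)
#' @return Invisibly, the manifest path.
#' @export
write_imputation_set <- function(imp, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(imp$m))
    utils::write.csv(imp$data[[i]],
                     file.path(dir, sprintf("imputed_%02d.csv", i)),
                     row.names = FALSE)
  manifest <- list(m = imp$m, seed = imp$seed, lambda = imp$lambda,
                   shift = imp$shift)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
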