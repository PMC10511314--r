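#' Specify a change-on-change model
#'
#' Settings for the linear regression of one-year outcome change on
#' pivot-coordinate behavior change: which obesity indicator is the outcome,
#' the optional season / follow-up adjustment, and the optional exclusion of
#' participants reporting more than `sleep_threshold` hours of sleep per
#' night before retirement.
#'
#' @param outcome `"bmi"` (kg/m2) or `"wc"` (waist circumference, cm).
#' @param adjust_season Add measurement-season dummies (winter reference).
#' @param adjust_followup Add follow-up time in days as a covariate.
#' @param exclude_long_sleepers Drop participants with self-reported
#'   pre-retirement sleep above `sleep_threshold` hours/night.
#' @param sleep_threshold Hours/night defining a long sleeper (default 9).
#' @return A `model_spec` list.
#' @export
model_spec <- function(outcome = c("bmi", "wc"),
                       adjust_season = FALSE,
                       adjust_followup = FALSE,
                       exclude_long_sleepers = FALSE,
                       sleep_threshold = 9) {
  outcome <- match.arg(outcome)
  stopifnot(sleep_threshold > 0)
  structure(list(outcome = outcome,
                 adjust_season = isTRUE(adjust_season),
                 adjust_followup = isTRUE(adjust_followup),
                 exclude_long_sleepers = isTRUE(exclude_long_sleepers),
                 sleep_threshold = sleep_threshold),
            class = "model_spec")
}

#' Build the design matrix for the change-on-change model
#'
#' Response: outcome change (post minus pre). Predictors: the change in the
#' three pivot coordinates (post perturbation-minus pre, equivalently the
#' difference of pivot coordinates), the baseline (pre-retirement) pivot
#' coordinates, the baseline outcome, age, a sex dummy (woman = 1) and an
#' occupation dummy (manual = 1); optionally season dummies (winter
#' reference) and follow-up days. Rows with missing required fields are
#' dropped (complete case) and counted.
#'
#' @param records Participant table ([read_participants()] layout).
#' @param basis A [pivot_basis()].
#' @param spec A [model_spec()].
#' @return List with `y`, `X` (including intercept column), `labels`,
#'   `n_used`, `n_dropped`, `rows_used` and the `basis`/`spec` used.
#' @export
build_design <- function(records, basis = pivot_basis("sleep"),
                         spec = model_spec("bmi")) {
  records <- validate_participants(records)
  if (spec$adjust_season && !"season_pre" %in% names(records)) {
    stop("model spec requires season_pre, absent from the data", call. = FALSE)
  }
  if (spec$adjust_followup && !"followup_days" %in% names(records)) {
    stop("model spec requires followup_days, absent from the data", call. = FALSE)
  }
  if (spec$exclude_long_sleepers && !"selfreport_sleep_pre" %in% names(records)) {
    stop("model spec requires selfreport_sleep_pre, absent from the data",
         call. = FALSE)
  }
  keep <- rep(TRUE, nrow(records))
  if (spec$exclude_long_sleepers) {
    keep <- keep & !is.na(records$selfreport_sleep_pre) &
      records$selfreport_sleep_pre <= spec$sleep_threshold
  }
  if (spec$adjust_season) keep <- keep & !is.na(records$season_pre)
  if (spec$adjust_followup) keep <- keep & !is.na(records$followup_days)
  df <- records[keep, , drop = FALSE]
  if (nrow(df) == 0L) stop("no rows left after model-spec exclusions", call. = FALSE)

  z_pre <- pivot_coord_matrix(wave_minutes(df, "pre"), basis)
  z_post <- pivot_coord_matrix(wave_minutes(df, "post"), basis)
  d_z <- z_post - z_pre
  y <- df[[paste0(spec$outcome, "_post")]] - df[[paste0(spec$outcome, "_pre")]]

  X <- cbind(1, d_z, z_pre,
             df[[paste0(spec$outcome, "_pre")]],
             df$age,
             as.numeric(df$sex == "woman"),
             as.numeric(df$occupation == "manual"))
  labels <- c("(Intercept)", paste0("d_z", 1:3), paste0("base_z", 1:3),
              paste0(spec$outcome, "_pre"), "age", "sex_woman", "occ_manual")
  if (spec$adjust_season) {
    season <- factor(df$season_pre, levels = c("winter", "spring", "summer", "autumn"))
    for (lev in c("spring", "summer", "autumn")) {
      X <- cbind(X, as.numeric(season == lev))
      labels <- c(labels, paste0("season_", lev))
    }
  }
  if (spec$adjust_followup) {
    X <- cbind(X, df$followup_days)
    labels <- c(labels, "followup_days")
  }
  colnames(X) <- labels
  list(y = y, X = X, labels = labels,
       n_used = nrow(X), n_dropped = nrow(records) - nrow(X),
       rows_used = which(keep), basis = basis, spec = spec)
}

#' Fit the change-on-change model by ordinary least squares
#'
#' QR-based least squares with classical homoskedastic inference:
#' `vcov = (X'X)^-1 * RSS / (n - p)`, confidence intervals and two-sided
#' p-values from the t distribution on `n - p` degrees of freedom. The first
#' change-pivot coefficient (`d_z1`) is the published "pivot behavior versus
#' remaining, difference" effect.
#'
#' @param design Output of [build_design()].
#' @param conf_level Confidence level for intervals (default 0.95).
#' @return A `change_fit`: coefficients, covariance matrix, residual
#'   variance, degrees of freedom, fitted values, residuals, R-squared,
#'   `n_used`, the pivot part, and `first_pivot` (beta, se, ci, p).
#' @export
fit_ols <- function(design, conf_level = 0.95) {
  X <- design$X
  y <- design$y
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more observations than predictors", call. = FALSE)
  fit <- stats::lm.fit(X, y)
  if (fit$rank < p) {
    bad <- design$labels[fit$qr$pivot[(fit$rank + 1):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  coef <- fit$coefficients
  res <- fit$residuals
  df_res <- n - p
  sigma2 <- sum(res^2) / df_res
  piv <- fit$qr$pivot
  xtx_inv <- matrix(NA_real_, p, p)
  xtx_inv[piv, piv] <- chol2inv(qr.R(fit$qr))
  vcov <- sigma2 * xtx_inv
  dimnames(vcov) <- list(design$labels, design$labels)
  fitted <- drop(X %*% coef)
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df_res)
  b1 <- coef[["d_z1"]]
  se1 <- sqrt(vcov["d_z1", "d_z1"])
  structure(list(
    pivot_part = design$basis$pivot_part,
    basis = design$basis,
    spec = design$spec,
    n_used = n,
    coefficients = stats::setNames(coef, design$labels),
    vcov = vcov,
    sigma2 = sigma2,
    df_residual = df_res,
    fitted = fitted,
    residuals = res,
    r_squared = r2,
    conf_level = conf_level,
    first_pivot = c(beta = b1, se = se1,
                    ci_low = b1 - tcrit * se1, ci_high = b1 + tcrit * se1,
                    p = 2 * stats::pt(-abs(b1 / se1), df_res))
  ), class = "change_fit")
}

#' @export
print.change_fit <- function(x, ...) {
  fp <- x$first_pivot
  cat(sprintf("Change-on-change fit, %s-first pivot basis (%s outcome, n = %d)\n",
              x$pivot_part, x$spec$outcome, x$n_used))
  cat(sprintf("  %s vs remaining, difference: beta = %.3f (%.0f%% CI %.3f to %.3f), p = %.3f\n",
              x$pivot_part, fp["beta"], 100 * x$conf_level,
              fp["ci_low"], fp["ci_high"], fp["p"]))
  cat(sprintf("  R-squared: %.4f\n", x$r_squared))
  invisible(x)
}

#' Fit the model in all four behavior-first pivot bases
#'
#' The same regression re-expressed in each behavior-first basis: fitted
#' values, residuals and R-squared are identical across the four fits (an
#' orthogonal reparameterization), while the first change-pivot coefficient
#' gives each behavior's "versus the remaining behaviors" effect.
#'
#' @param records Participant table.
#' @param spec A [model_spec()].
#' @param conf_level Confidence level for the summary intervals.
#' @return A `pivot_fits` list: `fits` (one `change_fit` per behavior),
#'   `summary` (behavior, beta, ci_low, ci_high, p), `outcome`, `n_used`.
#' @export
fit_all_pivots <- function(records, spec = model_spec("bmi"),
                           conf_level = 0.95) {
  fits <- lapply(behaviors(), function(b) {
    fit_ols(build_design(records, pivot_basis(b), spec), conf_level)
  })
  names(fits) <- behaviors()
  summary <- do.call(rbind, lapply(fits, function(f) {
    data.frame(behavior = f$pivot_part,
               beta = unname(f$first_pivot["beta"]),
               ci_low = unname(f$first_pivot["ci_low"]),
               ci_high = unname(f$first_pivot["ci_high"]),
               p = unname(f$first_pivot["p"]),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  structure(list(fits = fits, summary = summary,
                 outcome = spec$outcome, n_used = fits[[1]]$n_used),
            class = "pivot_fits")
}

#' @export
print.pivot_fits <- function(x, ...) {
  cat(sprintf("Change-on-change model (%s outcome, n = %d), first pivot coordinates:\n",
              x$outcome, x$n_used))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-5s vs remaining, difference: %6.2f (%6.2f to %6.2f), p = %.3f\n",
                s$behavior[i], s$beta[i], s$ci_low[i], s$ci_high[i], s$p[i]))
  }
  invisible(x)
}

#' Basis-free clr representation of the behavior-change effect
#'
#' Converts the four first-pivot "versus remaining" coefficients into the
#' centred log-ratio coefficient vector `a = sqrt(3)/2 * beta` (for 4 parts),
#' which sums to zero and lets predictions be written as
#' `a . (clr(new) - clr(reference))` regardless of basis.
#'
#' @param x A `pivot_fits` object, or a numeric 4-vector of first-pivot
#'   coefficients in canonical behavior order.
#' @return Named numeric 4-vector of clr coefficients.
#' @export
clr_coefficients <- function(x) {
  betas <- if (inherits(x, "pivot_fits")) {
    vapply(x$fits, function(f) unname(f$first_pivot["beta"]), numeric(1))
  } else {
    stopifnot(is.numeric(x), length(x) == 4L)
    x
  }
  stats::setNames(sqrt(3) / 2 * as.numeric(betas), behaviors())
}

#' Serialize fits to a JSON-ready list
#'
#' @param fits A `pivot_fits` object.
#' @return A plain list (coefficients, covariance row-major, n, summary) that
#'   `jsonlite::write_json()` can emit.
#' @export
fits_to_list <- function(fits) {
  stopifnot(inherits(fits, "pivot_fits"))
  list(
    outcome = fits$outcome,
    n_used = fits$n_used,
    summary = fits$summary,
    fits = lapply(fits$fits, function(f) {
      list(pivot_part = f$pivot_part,
           coefficients = as.list(f$coefficients),
           vcov = as.vector(t(f$vcov)),
           labels = names(f$coefficients),
           sigma2 = f$sigma2,
           df_residual = f$df_residual,
           r_squared = f$r_squared)
    })
  )
}
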