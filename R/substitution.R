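#' One-to-one time reallocation
#'
#' Moves `minutes` from one behavior to another at a reference composition,
#' holding the 1440-minute day fixed; the building block of compositional
#' isotemporal substitution.
#'
#' @param reference A `composition` (or positive 4-vector of minutes).
#' @param from,to Distinct behavior names.
#' @param minutes Nonnegative minutes to move; must leave the donor behavior
#'   strictly positive.
#' @return A `composition`.
#' @export
reallocate <- function(reference, from, to, minutes) {
  from <- match.arg(tolower(from), behaviors())
  to <- match.arg(tolower(to), behaviors())
  if (from == to) stop("from and to must differ", call. = FALSE)
  ref <- closure(reference)
  mins <- as_minutes(ref)
  if (minutes < 0) stop("minutes must be nonnegative", call. = FALSE)
  if (minutes >= mins[[from]]) {
    stop(sprintf("infeasible reallocation: moving %.0f min exceeds the %.0f min available in %s",
                 minutes, mins[[from]], from), call. = FALSE)
  }
  mins[[from]] <- mins[[from]] - minutes
  mins[[to]] <- mins[[to]] + minutes
  composition(mins, day_minutes = attr(ref, "day_minutes"))
}

#' Default per-pair reallocation cap
#'
#' Reallocations involving MVPA are capped at 60 min; reallocations among
#' sleep, SED and LPA at 120 min, reflecting the range of behavior change
#' actually observed across the retirement transition.
#'
#' @param from,to Behavior names.
#' @return Cap in minutes (60 or 120).
#' @export
default_cap <- function(from, to) {
  if ("mvpa" %in% tolower(c(from, to))) 60 else 120
}

#' Predict outcome change for a reallocation from a fitted model
#'
#' Expresses the reallocated and reference compositions in the fit's pivot
#' basis and applies the change-coefficient block: the predicted change is
#' `gamma_d . (z(new) - z(ref))`; intercept, baseline-composition and
#' covariate terms cancel because only the change coordinates move. The
#' confidence interval is the delta-method linear form on the
#' change-coefficient covariance block.
#'
#' @param fit A `change_fit` (any pivot basis; predictions are basis
#'   invariant).
#' @param reference Reference `composition` (minutes), typically the
#'   pre-retirement compositional mean.
#' @param from,to Behavior names.
#' @param minutes Minutes reallocated.
#' @return A one-row data.frame: `from`, `to`, `minutes`, `estimate`,
#'   `ci_low`, `ci_high`, `outcome`.
#' @export
predict_change_from_fit <- function(fit, reference, from, to, minutes) {
  stopifnot(inherits(fit, "change_fit"))
  ref <- closure(reference)
  new <- if (minutes == 0) ref else reallocate(ref, from, to, minutes)
  dz <- pivot_coord(new, fit$basis) - pivot_coord(ref, fit$basis)
  idx <- paste0("d_z", 1:3)
  est <- sum(fit$coefficients[idx] * dz)
  se <- sqrt(drop(t(dz) %*% fit$vcov[idx, idx] %*% dz))
  tcrit <- stats::qt(1 - (1 - fit$conf_level) / 2, fit$df_residual)
  data.frame(from = tolower(from), to = tolower(to), minutes = minutes,
             estimate = est, ci_low = est - tcrit * se,
             ci_high = est + tcrit * se,
             outcome = fit$spec$outcome, stringsAsFactors = FALSE)
}

#' Predict outcome change from published first-pivot coefficients
#'
#' Reconstruction path when only the four "versus remaining, difference"
#' coefficients are available (no covariance, so no interval): converts them
#' to the clr coefficient vector `a = sqrt(3)/2 * beta` and returns
#' `a . (clr(reallocated) - clr(reference))`.
#'
#' @param betas Numeric 4-vector of first-pivot coefficients in canonical
#'   behavior order (sleep, SED, LPA, MVPA). Warns when they do not sum to
#'   approximately zero (tolerance 0.05), as exact coefficients must.
#' @param reference Reference `composition` (minutes).
#' @param from,to Behavior names.
#' @param minutes Minutes reallocated.
#' @return Predicted outcome change (scalar, outcome units).
#' @export
predict_change_from_betas <- function(betas, reference, from, to, minutes) {
  stopifnot(is.numeric(betas), length(betas) == 4L)
  if (abs(sum(betas)) > 0.05) {
    warning("first-pivot coefficients should sum to ~0 (got ",
            round(sum(betas), 3), "); check their order and scale")
  }
  a <- clr_coefficients(betas)
  ref <- closure(reference)
  new <- if (minutes == 0) ref else reallocate(ref, from, to, minutes)
  sum(a * (clr(new) - clr(ref)))
}

#' Reallocation grid for one or more behavior pairs
#'
#' Predicted outcome changes on a signed minute grid (-cap .. +cap in `step`
#' increments; negative minutes reallocate in the reverse direction),
#' skipping infeasible points where the donor behavior would be exhausted.
#' The zero point is always included and its estimate is exactly zero.
#'
#' @param model A `change_fit`, a `pivot_fits` object (its sleep-first fit is
#'   used; predictions are basis invariant), or a numeric 4-vector of
#'   published first-pivot coefficients.
#' @param reference Reference `composition` (minutes).
#' @param pairs 2-column character matrix or data.frame of (from, to) pairs;
#'   default all six unordered behavior pairs read as from->to.
#' @param step Grid step in minutes (default 10).
#' @param caps Optional named override of per-pair caps; default
#'   [default_cap()] per pair.
#' @return Data.frame of `from`, `to`, `minutes` (signed), `estimate` and,
#'   for fitted models, `ci_low`/`ci_high` and `outcome`.
#' @export
substitution_table <- function(model, reference,
                               pairs = NULL, step = 10, caps = NULL) {
  if (inherits(model, "pivot_fits")) model <- model$fits[["sleep"]]
  if (is.null(pairs)) {
    b <- behaviors()
    pairs <- t(utils::combn(b, 2))
  }
  pairs <- as.matrix(pairs)
  ref <- closure(reference)
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    from <- tolower(pairs[i, 1]); to <- tolower(pairs[i, 2])
    cap <- if (is.null(caps)) default_cap(from, to) else caps[[paste(from, to, sep = ":")]]
    grid <- seq(-cap, cap, by = step)
    for (m in grid) {
      f <- if (m >= 0) from else to
      t_ <- if (m >= 0) to else from
      feasible <- abs(m) < as_minutes(ref)[[f]]
      if (!feasible) next
      if (inherits(model, "change_fit")) {
        row <- predict_change_from_fit(model, ref, f, t_, abs(m))
        row$minutes <- m
        row$from <- from; row$to <- to
      } else {
        est <- predict_change_from_betas(model, ref, f, t_, abs(m))
        row <- data.frame(from = from, to = to, minutes = m, estimate = est,
                          stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
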