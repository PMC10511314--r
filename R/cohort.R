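#' Read a participant table
#'
#' Reads and validates the participant CSV dialect used throughout the
#' package: one row per participant with pre- and post-retirement behavior
#' minutes, obesity indicators at both waves, and covariates.
#'
#' Mandatory columns: `id`, `sleep_min_pre`, `sed_min_pre`, `lpa_min_pre`,
#' `mvpa_min_pre`, `sleep_min_post`, `sed_min_post`, `lpa_min_post`,
#' `mvpa_min_post`, `bmi_pre`, `bmi_post`, `wc_pre`, `wc_post`, `age`,
#' `sex` (`woman`/`man`), `occupation` (`manual`/`non_manual`).
#' Optional: `season_pre` (`winter`/`spring`/`summer`/`autumn`),
#' `followup_days` (positive), `selfreport_sleep_pre` (hours/night).
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @return A validated `data.frame`, one row per participant.
#' @export
read_participants <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_participants(df)
}

#' Validate a participant table
#'
#' @param df A data.frame in the [read_participants()] layout.
#' @return The validated data.frame (invisibly unchanged apart from checks).
#' @export
validate_participants <- function(df) {
  required <- c("id", behavior_cols("pre"), behavior_cols("post"),
                "bmi_pre", "bmi_post", "wc_pre", "wc_post",
                "age", "sex", "occupation")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  problems <- character(0)
  note <- function(rows, msg) {
    if (length(rows)) {
      problems <<- c(problems, paste0("row ", rows, ": ", msg))
    }
  }
  for (col in c(behavior_cols("pre"), behavior_cols("post"))) {
    bad <- which(!is.finite(df[[col]]) | df[[col]] <= 0)
    note(bad, paste0("behavior minutes must be > 0 in ", col,
                     " (zero or missing time in a 24-h behavior is not allowed)"))
  }
  for (col in c("bmi_pre", "bmi_post", "wc_pre", "wc_post", "age")) {
    bad <- which(!is.finite(df[[col]]) | df[[col]] <= 0)
    note(bad, paste0(col, " must be a positive number"))
  }
  bad <- which(!df$sex %in% c("woman", "man"))
  note(bad, "sex must be one of {woman, man}")
  bad <- which(!df$occupation %in% c("manual", "non_manual"))
  note(bad, "occupation must be one of {manual, non_manual}")
  if ("season_pre" %in% names(df)) {
    bad <- which(!is.na(df$season_pre) &
                   !df$season_pre %in% c("winter", "spring", "summer", "autumn"))
    note(bad, "season_pre must be one of {winter, spring, summer, autumn}")
  }
  if ("followup_days" %in% names(df)) {
    bad <- which(!is.na(df$followup_days) & df$followup_days <= 0)
    note(bad, "followup_days must be positive when present")
  }
  if (length(problems)) {
    stop("invalid participant table:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  df
}

behavior_cols <- function(wave = c("pre", "post")) {
  wave <- match.arg(wave)
  paste0(behaviors(), "_min_", wave)
}

# n x 4 minutes matrix for one wave of a participant table.
wave_minutes <- function(df, wave = c("pre", "post")) {
  wave <- match.arg(wave)
  m <- as.matrix(df[, behavior_cols(wave)])
  colnames(m) <- behaviors()
  m
}

#' Apply the valid-day rules to daily wear records
#'
#' A measurement day is valid when waking wear time is at least `min_hours`
#' (default 10 h); a participant is excluded when either wave holds fewer
#' than `min_days` (default 3) valid days.
#'
#' @param days Data.frame with columns `id`, `wave` (`pre`/`post`),
#'   `wear_hours_waking` and the four behavior-minute columns `sleep_min`,
#'   `sed_min`, `lpa_min`, `mvpa_min` (a `date` column is carried through if
#'   present).
#' @param min_hours Minimum waking wear hours for a valid day.
#' @param min_days Minimum valid days required in each wave.
#' @return A list with `valid_days` (the valid subset of `days`), `summary`
#'   (per id: valid-day counts per wave and an `excluded` flag) and
#'   `excluded_ids`.
#' @export
filter_valid_days <- function(days, min_hours = 10, min_days = 3) {
  if (nrow(days) == 0L) {
    return(list(valid_days = days,
                summary = data.frame(id = character(0),
                                     valid_pre = integer(0),
                                     valid_post = integer(0),
                                     excluded = logical(0)),
                excluded_ids = character(0)))
  }
  stopifnot(all(c("id", "wave", "wear_hours_waking") %in% names(days)),
            all(days$wave %in% c("pre", "post")),
            all(days$wear_hours_waking >= 0 & days$wear_hours_waking <= 24))
  valid <- days$wear_hours_waking >= min_hours
  ids <- unique(days$id)
  count <- function(w) {
    vapply(ids, function(i)
      sum(valid & days$id == i & days$wave == w), integer(1))
  }
  summary <- data.frame(id = ids,
                        valid_pre = count("pre"),
                        valid_post = count("post"),
                        row.names = NULL, stringsAsFactors = FALSE)
  summary$excluded <- summary$valid_pre < min_days | summary$valid_post < min_days
  list(valid_days = days[valid, , drop = FALSE],
       summary = summary,
       excluded_ids = summary$id[summary$excluded])
}

#' Average behavior minutes across valid days
#'
#' Arithmetic mean of each behavior's minutes across the supplied days,
#' then closure: the wave-level composition assigned to a participant.
#'
#' @param valid_days Data.frame of one participant-wave's valid days with
#'   columns `sleep_min`, `sed_min`, `lpa_min`, `mvpa_min`.
#' @return A `composition`.
#' @export
average_behaviors <- function(valid_days) {
  cols <- paste0(behaviors(), "_min")
  if (nrow(valid_days) == 0L) {
    stop("no valid days to average", call. = FALSE)
  }
  stopifnot(all(cols %in% names(valid_days)))
  composition(colMeans(as.matrix(valid_days[, cols])))
}

#' Classify a one-year outcome change
#'
#' BMI change is classified with a 0.5 kg/m2 cutpoint and waist circumference
#' with a 3.0 cm cutpoint: absolute change below the cutpoint is `no_change`;
#' ties at the cutpoint go to `decrease`/`increase`.
#'
#' @param delta Finite outcome change(s) (post minus pre).
#' @param outcome `"bmi"` or `"wc"`.
#' @return Character vector in `{decrease, no_change, increase}`.
#' @export
classify_change <- function(delta, outcome = c("bmi", "wc")) {
  outcome <- match.arg(outcome)
  cut <- change_cutpoint(outcome)
  stopifnot(all(is.finite(delta)))
  ifelse(abs(delta) < cut, "no_change",
         ifelse(delta <= -cut, "decrease", "increase"))
}

change_cutpoint <- function(outcome) {
  switch(outcome, bmi = 0.5, wc = 3.0,
         stop("unknown outcome: ", outcome, call. = FALSE))
}

#' Three-part subcomposition
#'
#' Closure of three selected behaviors; used to project 4-part compositional
#' changes into the ternary diagrams.
#'
#' @param x A `composition` or positive 4-vector.
#' @param keep Three distinct behavior names.
#' @return Named closed 3-vector.
#' @export
subcomposition <- function(x, keep) {
  keep <- tolower(keep)
  if (length(keep) != 3L || anyDuplicated(keep) ||
      !all(keep %in% behaviors())) {
    stop("keep must name 3 distinct behaviors among {",
         paste(behaviors(), collapse = ", "), "}", call. = FALSE)
  }
  v <- unclass(closure(x))[keep]
  v / sum(v)
}

#' Planar coordinates for a ternary plot
#'
#' Maps a closed 3-part vector onto the unit-side triangle with part 1 at the
#' bottom-left vertex (0, 0), part 2 at the bottom-right (1, 0) and part 3 at
#' the apex (1/2, sqrt(3)/2).
#'
#' @param p Closed 3-vector, or a matrix with one closed 3-vector per row.
#' @return Numeric `c(x, y)` (or a 2-column matrix).
#' @export
ternary_xy <- function(p) {
  if (is.matrix(p)) {
    cbind(x = p[, 2] + p[, 3] / 2, y = sqrt(3) / 2 * p[, 3])
  } else {
    c(x = p[2] + p[3] / 2, y = sqrt(3) / 2 * p[3])
  }
}

#' Ternary change coordinates by change group
#'
#' Per-participant compositional differences (post relative to pre), labelled
#' by the outcome change group and projected into a chosen 3-part
#' subcomposition: the plot-ready series behind the ternary change diagrams.
#'
#' @param records Participant table ([read_participants()] layout).
#' @param outcome `"bmi"` or `"wc"` (sets the change-group labels).
#' @param keep Three behaviors defining the subcomposition (default drops
#'   sleep).
#' @return Data.frame with `id`, `group`, the three closed subcomposition
#'   parts and ternary `x`, `y`.
#' @export
ternary_changes <- function(records, outcome = c("bmi", "wc"),
                            keep = c("sed", "lpa", "mvpa")) {
  outcome <- match.arg(outcome)
  records <- validate_participants(records)
  delta <- records[[paste0(outcome, "_post")]] - records[[paste0(outcome, "_pre")]]
  group <- classify_change(delta, outcome)
  diffs <- wave_minutes(records, "post") / wave_minutes(records, "pre")
  keep <- tolower(keep)
  sub <- diffs[, keep, drop = FALSE]
  sub <- sub / rowSums(sub)
  xy <- ternary_xy(sub)
  out <- data.frame(id = records$id, group = group, sub, xy,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Cohort descriptives
#'
#' Per-wave summary of the analytic sample: mean (SD) age, BMI and waist
#' circumference, BMI category counts (normal weight below 25 kg/m2 with
#' underweight below 18.5 tallied separately inside it, overweight 25-29.9,
#' obese 30 or more; half-open bins), sex and occupation counts, and the
#' compositional mean of the four behaviors in minutes/day.
#'
#' @param records Participant table ([read_participants()] layout).
#' @return A `cohort_summary` list with `n`, `sex`, `occupation`, and per-wave
#'   blocks carrying the summaries above.
#' @export
describe_cohort <- function(records) {
  records <- validate_participants(records)
  if (nrow(records) == 0L) stop("empty cohort", call. = FALSE)
  mean_sd <- function(v) {
    s <- if (length(v) > 1L) stats::sd(v) else 0
    c(mean = mean(v), sd = s)
  }
  bmi_bins <- function(bmi) {
    c(normal = sum(bmi < 25),
      underweight = sum(bmi < 18.5),
      overweight = sum(bmi >= 25 & bmi < 30),
      obese = sum(bmi >= 30))
  }
  wave_block <- function(w) {
    bmi <- records[[paste0("bmi_", w)]]
    wc <- records[[paste0("wc_", w)]]
    list(bmi = mean_sd(bmi),
         wc = mean_sd(wc),
         bmi_categories = bmi_bins(bmi),
         comp_mean_min = as_minutes(comp_mean(wave_minutes(records, w))))
  }
  structure(list(
    n = nrow(records),
    age = mean_sd(records$age),
    sex = table(factor(records$sex, c("woman", "man"))),
    occupation = table(factor(records$occupation, c("manual", "non_manual"))),
    pre = wave_block("pre"),
    post = wave_block("post")
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  fmt <- function(v, d = 1) sprintf("%.*f (%.*f)", d, v["mean"], d, v["sd"])
  cat(sprintf("Cohort of %d participants\n", x$n))
  cat(sprintf("  Age, mean (SD): %s\n", fmt(x$age)))
  cat(sprintf("  Women: %d (%d%%)   Manual workers: %d (%d%%)\n",
              x$sex[["woman"]], round(100 * x$sex[["woman"]] / x$n),
              x$occupation[["manual"]],
              round(100 * x$occupation[["manual"]] / x$n)))
  for (w in c("pre", "post")) {
    b <- x[[w]]
    cat(sprintf("  [%s] BMI %s kg/m2 | WC %s cm\n", w, fmt(b$bmi), fmt(b$wc)))
    cat(sprintf("  [%s] BMI categories n: normal %d (underweight %d), overweight %d, obese %d\n",
                w, b$bmi_categories[["normal"]], b$bmi_categories[["underweight"]],
                b$bmi_categories[["overweight"]], b$bmi_categories[["obese"]]))
    cat(sprintf("  [%s] compositional mean sleep/SED/LPA/MVPA: %s min\n",
                w, paste(round(b$comp_mean_min), collapse = ", ")))
  }
  invisible(x)
}
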