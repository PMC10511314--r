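test_that("participant tables are read and validated with row-level messages", {
  df <- small_cohort(3)
  path <- write_participants_csv(df)
  got <- read_participants(path)
  expect_equal(nrow(got), 3)
  expect_equal(got$id, df$id)

  bad <- df; bad$mvpa_min_pre[2] <- 0
  expect_error(read_participants(write_participants_csv(bad)), "row 2.*mvpa")

  bad <- df; bad$sex[1] <- "female"
  expect_error(read_participants(write_participants_csv(bad)), "woman, man")

  bad <- df[, setdiff(names(df), "bmi_post")]
  expect_error(read_participants(write_participants_csv(bad)), "bmi_post")

  expect_error(read_participants(tempfile()), "not found")
})

test_that("valid-day filtering applies the 10-h and 3-day rules", {
  mk_day <- function(id, wave, wear) {
    data.frame(id = id, wave = wave, date = "2017-03-01",
               wear_hours_waking = wear,
               sleep_min = 480, sed_min = 600, lpa_min = 280, mvpa_min = 80)
  }
  days <- rbind(
    do.call(rbind, lapply(c(9.5, 12, 11, 10), mk_day, id = "A", wave = "pre")),
    do.call(rbind, lapply(c(12, 12, 12), mk_day, id = "A", wave = "post")),
    do.call(rbind, lapply(c(11, 12), mk_day, id = "B", wave = "pre")),
    do.call(rbind, lapply(c(11, 12, 13, 12, 14), mk_day, id = "B", wave = "post")))
  res <- filter_valid_days(days)
  s <- res$summary
  # the 9.5-h day is invalid; 10 h exactly is valid (boundary inclusive)
  expect_equal(s$valid_pre[s$id == "A"], 3L)
  expect_false(s$excluded[s$id == "A"])      # (3, 3) retained
  expect_equal(s$valid_pre[s$id == "B"], 2L)
  expect_true(s$excluded[s$id == "B"])       # (2, 5) excluded
  expect_equal(res$excluded_ids, "B")
  expect_false(any(res$valid_days$wear_hours_waking < 10))

  # filtering never increases counts; exclusion monotone in min_days
  stricter <- filter_valid_days(days, min_days = 4)
  expect_true(all(stricter$summary$excluded >= s$excluded))
  expect_equal(nrow(filter_valid_days(days[0, ])$summary), 0)
})

test_that("behavior averaging is the arithmetic day mean then closure", {
  one <- data.frame(sleep_min = 480, sed_min = 600, lpa_min = 280, mvpa_min = 80)
  expect_equal(as_minutes(average_behaviors(one)),
               c(sleep = 480, sed = 600, lpa = 280, mvpa = 80),
               tolerance = 1e-12)
  two <- data.frame(sleep_min = c(400, 500), sed_min = c(640, 600),
                    lpa_min = c(300, 260), mvpa_min = c(100, 80))
  expect_equal(as_minutes(average_behaviors(two)),
               c(sleep = 450, sed = 620, lpa = 280, mvpa = 90),
               tolerance = 1e-12)
  expect_equal(average_behaviors(two[2:1, ]), average_behaviors(two))
  expect_error(average_behaviors(two[0, ]), "no valid days")
})

test_that("outcome change groups follow the 0.5 kg/m2 and 3.0 cm cutpoints", {
  expect_equal(classify_change(0.4, "bmi"), "no_change")
  expect_equal(classify_change(-0.5, "bmi"), "decrease")   # tie goes out of band
  expect_equal(classify_change(0.5, "bmi"), "increase")
  expect_equal(classify_change(3.2, "wc"), "increase")
  expect_equal(classify_change(-2.99, "wc"), "no_change")
  expect_error(classify_change(1, "weight"))

  # monotone in delta, symmetric no-change band
  d <- seq(-2, 2, by = 0.05)
  lab <- classify_change(d, "bmi")
  ord <- c(decrease = 1, no_change = 2, increase = 3)
  expect_true(all(diff(ord[lab]) >= 0))
  expect_equal(lab, rev(ifelse(lab == "decrease", "increase",
                               ifelse(lab == "increase", "decrease", lab))))
})

test_that("subcompositions renormalize the kept parts", {
  s <- subcomposition(c(0.2, 0.2, 0.3, 0.3), c("sed", "lpa", "mvpa"))
  expect_equal(unname(s), c(0.25, 0.375, 0.375), tolerance = 1e-12)
  expect_equal(unname(subcomposition(rep(0.25, 4), c("sleep", "sed", "lpa"))),
               rep(1 / 3, 3), tolerance = 1e-12)
  expect_error(subcomposition(rep(0.25, 4), c("sed", "sed", "lpa")), "distinct")

  # invariant to the scale of the dropped part
  x <- c(sleep = 400, sed = 600, lpa = 300, mvpa = 140)
  y <- x; y["sleep"] <- 40
  expect_equal(subcomposition(x, c("sed", "lpa", "mvpa")),
               subcomposition(y, c("sed", "lpa", "mvpa")), tolerance = 1e-12)
})

test_that("ternary projection maps vertices and inverts barycentrically", {
  expect_equal(unname(ternary_xy(c(1, 1, 1) / 3)), c(0.5, sqrt(3) / 6),
               tolerance = 1e-12)
  expect_equal(unname(ternary_xy(c(1, 0, 0))), c(0, 0))
  expect_equal(unname(ternary_xy(c(0, 1, 0))), c(1, 0))
  expect_equal(unname(ternary_xy(c(0, 0, 1))), c(0.5, sqrt(3) / 2))

  set.seed(9)
  p <- matrix(rexp(300), ncol = 3)
  p <- p / rowSums(p)
  xy <- ternary_xy(p)
  p3 <- xy[, "y"] / (sqrt(3) / 2)
  p2 <- xy[, "x"] - p3 / 2
  expect_equal(cbind(1 - p2 - p3, p2, p3), p, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("cohort descriptives summarize both waves", {
  df <- small_cohort(60, seed = 2)
  s <- describe_cohort(df)
  expect_equal(s$n, 60)
  expect_equal(unname(s$age["mean"]), mean(df$age))
  expect_equal(sum(s$pre$bmi_categories[c("normal", "overweight", "obese")]), 60)
  expect_equal(sum(s$pre$comp_mean_min), 1440, tolerance = 1e-9)

  one <- df[1, , drop = FALSE]
  s1 <- describe_cohort(one)
  expect_equal(unname(s1$pre$bmi), c(one$bmi_pre, 0))
  expect_equal(s1$pre$comp_mean_min,
               c(sleep = one$sleep_min_pre, sed = one$sed_min_pre,
                 lpa = one$lpa_min_pre, mvpa = one$mvpa_min_pre) /
                 (one$sleep_min_pre + one$sed_min_pre + one$lpa_min_pre +
                    one$mvpa_min_pre) * 1440,
               tolerance = 1e-9)

  # 25-29.9 bin is half-open [25, 30)
  edge <- df[1:2, ]
  edge$bmi_pre <- c(29.95, 30)
  s2 <- describe_cohort(edge)
  expect_equal(unname(s2$pre$bmi_categories["overweight"]), 1)
  expect_equal(unname(s2$pre$bmi_categories["obese"]), 1)
})

test_that("ternary change coordinates carry per-outcome group labels", {
  df <- small_cohort(30, seed = 8)
  tc <- ternary_changes(df, "bmi")
  expect_equal(nrow(tc), 30)
  expect_true(all(tc$group %in% c("decrease", "no_change", "increase")))
  expect_equal(tc$group,
               classify_change(df$bmi_post - df$bmi_pre, "bmi"))
  expect_equal(rowSums(tc[, c("sed", "lpa", "mvpa")]), rep(1, 30),
               tolerance = 1e-12)
  # an unchanged composition projects to the triangle centroid
  same <- df[1, ]
  for (b in behaviors()) {
    same[[paste0(b, "_min_post")]] <- same[[paste0(b, "_min_pre")]]
  }
  tc1 <- ternary_changes(same, "bmi")
  expect_equal(c(tc1$x, tc1$y), c(0.5, sqrt(3) / 6), tolerance = 1e-12)
})
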