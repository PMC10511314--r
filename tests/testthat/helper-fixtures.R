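# Shared fixtures: random compositions and small participant tables built in
# code at test time.

# Table 1 anchor values reused across tests
PRE_MEAN_MIN <- c(sleep = 497, sed = 584, lpa = 282, mvpa = 77)
POST_MEAN_MIN <- c(sleep = 520, sed = 572, lpa = 272, mvpa = 76)
BMI_BETAS <- c(1.34, -0.09, -0.66, -0.60)
WC_BETAS <- c(1.51, 2.39, -1.76, -2.14)

# n random strictly positive 4-part compositions (rows, closed)
rand_comp_matrix <- function(n, seed = 1, sd = 1) {
  set.seed(seed)
  m <- exp(matrix(rnorm(4 * n, sd = sd), ncol = 4))
  colnames(m) <- behaviors()
  m / rowSums(m)
}

small_cohort <- function(n = 40, seed = 11, ...) {
  generate_cohort(generator_params(n = n, seed = seed, ...))
}

write_participants_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# analytic substitution oracle: clr-difference dot product
oracle_predict <- function(betas, ref_min, from, to, minutes) {
  a <- sqrt(3) / 2 * betas
  new <- ref_min
  new[from] <- new[from] - minutes
  new[to] <- new[to] + minutes
  lclr <- function(x) log(x) - mean(log(x))
  sum(a * (lclr(new) - lclr(ref_min)))
}
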