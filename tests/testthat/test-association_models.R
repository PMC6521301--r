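make_fit_inputs <- function(n = 120, seed = 61, noise_sd = 10,
                            beta_grs = 5) {
  set.seed(seed)
  dos <- matrix(rbinom(n * 6, 2, 0.3), n, 6)
  gm <- make_gm(dos)
  w <- data.frame(rsid = gm$snps$rsid,
                  direction = c(1L, -1L, 1L, 0L, 1L, -1L))
  grs <- compute_grs(gm, w)
  ph <- make_phenotypes(rep(0, n), seed = seed + 1)
  ph$tg_post <- ph$tg_pre + beta_grs * grs$score + rnorm(n, 0, noise_sd)
  list(gm = gm, w = w, grs = grs, ph = classify_responders(ph))
}

test_that("a noiseless linear outcome yields 100% variance explained", {
  x <- make_fit_inputs(noise_sd = 0)
  ph <- x$ph
  # constant covariates: no nuisance variance to absorb
  ph$age <- 30; ph$bmi <- 25; ph$sex <- "female"
  f <- suppressWarnings(fit_grs_model(ph, x$grs))
  expect_equal(f$grs_percent_variance, 100, tolerance = 1e-6)
  expect_equal(f$r2_full, 1, tolerance = 1e-9)
  expect_lt(f$grs_p, 1e-20)
})

test_that("incremental R2 is non-negative, nested-consistent and equals
           the squared semipartial correlation", {
  for (seed in c(62, 63, 64)) {
    x <- make_fit_inputs(seed = seed, noise_sd = 15)
    f <- fit_grs_model(x$ph, x$grs)
    expect_gte(f$r2_full, f$r2_covariates_only)
    expect_equal(f$grs_percent_variance,
                 100 * (f$r2_full - f$r2_covariates_only))
    # closed form: squared semipartial correlation of the score
    d <- merge(x$ph, x$grs[, c("participant_id", "score")],
               by = "participant_id")
    d$sex_male <- as.integer(d$sex == "male")
    e_score <- resid(lm(score ~ age + sex_male + bmi, data = d))
    expect_equal(f$grs_percent_variance / 100,
                 cor(d$delta_tg, e_score)^2, tolerance = 1e-10)
    # partial eta2 reading
    expect_equal(f$grs_partial_eta2,
                 (f$r2_full - f$r2_covariates_only) /
                   (1 - f$r2_covariates_only))
  }
})

test_that("fit is invariant to affine rescaling of covariates", {
  x <- make_fit_inputs(seed = 65)
  f1 <- fit_grs_model(x$ph, x$grs)
  ph2 <- x$ph
  ph2$age <- ph2$age * 12 + 3      # months
  ph2$bmi <- ph2$bmi / 100 - 0.2
  f2 <- fit_grs_model(ph2, x$grs)
  expect_equal(f1$grs_percent_variance, f2$grs_percent_variance,
               tolerance = 1e-9)
  expect_equal(f1$grs_p, f2$grs_p, tolerance = 1e-9)
  # sex reference choice does not change the score statistics
  ph3 <- x$ph
  ph3$sex <- ifelse(ph3$sex == "male", "female", "male")
  f3 <- fit_grs_model(ph3, x$grs)
  expect_equal(f1$grs_percent_variance, f3$grs_percent_variance,
               tolerance = 1e-9)
})

test_that("a constant score is flagged inestimable, not an error", {
  x <- make_fit_inputs(seed = 66)
  g0 <- compute_grs(x$gm, transform(x$w, direction = 0L))
  f <- fit_grs_model(x$ph, g0)
  expect_true(f$inestimable)
  expect_true(is.na(f$grs_percent_variance))
})

test_that("permuting the score against the outcome gives uniform p", {
  x <- make_fit_inputs(seed = 67, noise_sd = 20, beta_grs = 0)
  set.seed(68)
  ps <- vapply(1:300, function(i) {
    g <- x$grs
    g$score <- sample(g$score)
    fit_grs_model(x$ph, g)$grs_p
  }, numeric(1))
  rate <- mean(ps < 0.05)
  expect_gt(rate, 0.05 - 2.6 * sqrt(0.05 * 0.95 / 300))
  expect_lt(rate, 0.05 + 2.6 * sqrt(0.05 * 0.95 / 300))
})

test_that("stepwise selection agrees with the exhaustive-refit oracle", {
  for (seed in c(71, 72, 73, 74, 75)) {
    set.seed(seed)
    n <- 60
    dos <- matrix(rbinom(n * 4, 2, 0.35), n, 4)
    gm <- make_gm(dos)
    # one real signal among the four candidates
    delta <- 6 * dos[, 2] + rnorm(n, -5, 10)
    ph <- classify_responders(make_phenotypes(delta, seed = seed))
    sw <- stepwise_select(ph, gm, entry_p = 0.15, stay_p = 0.15)
    d <- ph
    d$sex_male <- as.integer(d$sex == "male")
    d <- cbind(d, as.data.frame(dos,
                                col.names = gm$snps$rsid))
    names(d)[(ncol(d) - 3):ncol(d)] <- gm$snps$rsid
    want <- oracle_stepwise(d, gm$snps$rsid, 0.15, 0.15)
    expect_identical(sw$selected, want$selected)
    if (!is.null(want$log)) {
      expect_identical(sw$log$action, want$log$action)
      expect_identical(sw$log$rsid, want$log$rsid)
      expect_equal(sw$log$p, want$log$p, tolerance = 1e-12)
    } else {
      expect_equal(nrow(sw$log), 0)
    }
  }
})

test_that("stepwise thresholds behave at their extremes", {
  set.seed(76)
  n <- 80
  dos <- matrix(rbinom(n * 5, 2, 0.3), n, 5)
  gm <- make_gm(dos)
  ph <- classify_responders(make_phenotypes(rnorm(n, -5, 15), seed = 77))
  all_in <- stepwise_select(ph, gm, entry_p = 0.999, stay_p = 0.999)
  expect_setequal(all_in$selected, gm$snps$rsid)
  none <- stepwise_select(ph, gm, entry_p = 1e-9, stay_p = 1e-9)
  expect_length(none$selected, 0)
  expect_error(stepwise_select(ph, gm, entry_p = 0), "between 0 and 1")
})

test_that("stepwise finds a strongly planted SNP among null candidates", {
  hits <- vapply(1:40, function(s) {
    set.seed(s)
    n <- 500
    dos <- matrix(rbinom(n * 21, 2, 0.3), n, 21)
    gm <- make_gm(dos)
    g <- dos[, 1] - mean(dos[, 1])
    # planted SNP explains ~20% of the outcome variance
    sd_noise <- sqrt(var(g) * 0.8 / 0.2)
    ph <- classify_responders(
      make_phenotypes(5 * g + rnorm(n, 0, 5 * sd_noise), seed = s))
    sw <- stepwise_select(ph, gm)
    "rs1" %in% sw$selected
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("refined-panel refit delegates to the full fit machinery", {
  coh <- simulate_cohort(simulation_config(seed = 81))
  ph <- classify_responders(coh$phenotypes)
  w <- compute_weights(coh$genotypes, ph)
  full <- fit_grs_model(ph, compute_grs(coh$genotypes, w))
  same <- refit_refined_grs(coh$genotypes, ph, coh$genotypes$snps$rsid, w)
  expect_equal(same$grs_percent_variance, full$grs_percent_variance)
  expect_equal(same$grs_p, full$grs_p)
  expect_error(refit_refined_grs(coh$genotypes, ph, character(0), w),
               "non-empty")
})

test_that("noise SNPs dilute a fixed-weight full-panel score", {
  # data-independent weights isolate the dilution property from
  # in-sample direction estimation (which inflates a wide panel's
  # apparent R2; see the methods vignette)
  better <- vapply(1:40, function(s) {
    coh <- simulate_cohort(simulation_config(seed = 200 + s))
    ph <- classify_responders(coh$phenotypes)
    rsids <- coh$genotypes$snps$rsid
    dir <- ifelse(seq_along(rsids) %% 2 == 0, 1L, -1L)
    dir[match(coh$truth$causal$rsid, rsids)] <- coh$truth$causal$direction
    w <- data.frame(rsid = rsids, direction = dir)
    full <- fit_grs_model(ph, compute_grs(coh$genotypes, w))
    refined <- refit_refined_grs(coh$genotypes, ph,
                                 coh$truth$causal$rsid, w)
    refined$grs_percent_variance >= full$grs_percent_variance
  }, logical(1))
  expect_gt(mean(better), 0.5)
})
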