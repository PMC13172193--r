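test_that("the frozen 12-observation fixture matches the grid-search oracle", {
  d <- lmm_fixture_12()
  fit <- fit_random_intercept_lmm(d, mean_speed_nm_s ~ stimulation)
  X <- model.matrix(~ stimulation, d)
  orc <- reml_grid_oracle(d$mean_speed_nm_s, X, d$subject)
  expect_equal(unname(fit$coefficients$beta), unname(orc$beta),
               tolerance = 1e-6)
  expect_equal(fit$sigma2_resid, orc$sigma2_resid, tolerance = 1e-6)
  expect_equal(fit$sigma2_subject, orc$sigma2_subject, tolerance = 1e-6)
})

test_that("REML estimates agree with lme4/lmerTest on random fixtures", {
  skip_if_not_installed("lmerTest")
  set.seed(2024)
  for (rep in 1:8) {
    truth <- lmm_truth(sigma_subject = runif(1, 20, 90),
                       sigma_resid = runif(1, 30, 70),
                       n_subjects_per_condition = sample(4:8, 1))
    d <- simulate_motility_dataset(truth, seed = 5000 + rep)
    form <- if (rep %% 2 == 0) mean_speed_nm_s ~ sirna * stimulation + noco
      else mean_speed_nm_s ~ sirna + noco + stimulation
    fit <- fit_random_intercept_lmm(d, form)
    lf <- suppressMessages(lmerTest::lmer(
      update(form, . ~ . + (1 | subject)), data = d))
    sm <- summary(lf)$coefficients
    expect_equal(fit$coefficients$beta, unname(sm[, "Estimate"]),
                 tolerance = 1e-4)
    expect_equal(fit$coefficients$se, unname(sm[, "Std. Error"]),
                 tolerance = 1e-4)
    expect_equal(fit$coefficients$df, unname(sm[, "df"]),
                 tolerance = 1e-2)
    vc <- as.data.frame(lme4::VarCorr(lf))
    expect_equal(fit$sigma2_subject,
                 vc$vcov[vc$grp == "subject"], tolerance = 1e-4)
    expect_equal(fit$sigma2_resid,
                 vc$vcov[vc$grp == "Residual"], tolerance = 1e-4)
  }
})

test_that("profiled REML restarts agree (unimodal lambda profile)", {
  d <- simulate_motility_dataset(lmm_truth(n_subjects_per_condition = 5),
                                 seed = 77)
  ss <- peroxdyn:::lmm_suffstat(
    d$mean_speed_nm_s, model.matrix(~ sirna + noco + stimulation,
                                    peroxdyn:::transform_records(d)),
    d$subject)
  obj <- function(l) peroxdyn:::lmm_profile_obj(ss, l)
  opts <- vapply(list(c(1e-4, 10), c(0.1, 100), c(1e-3, 1e3)),
                 function(iv) optimize(obj, iv, tol = 1e-12)$minimum,
                 numeric(1))
  expect_lt(max(obj(opts[1]), obj(opts[2]), obj(opts[3])) -
              min(obj(opts[1]), obj(opts[2]), obj(opts[3])), 1e-8)
})

test_that("singleton subjects reduce to OLS with residual df", {
  set.seed(9)
  d <- data.frame(subject = sprintf("S%02d", 1:24),
                  g = rep(c("a", "b"), each = 12))
  d$y <- (d$g == "b") * 5 + rnorm(24)
  expect_warning(fit <- fit_random_intercept_lmm(d, y ~ g), "single observation")
  ols <- lm(y ~ g, d)
  expect_equal(fit$coefficients$beta, unname(coef(ols)), tolerance = 1e-10)
  expect_equal(fit$sigma2_subject, 0)
  expect_equal(fit$coefficients$df, rep(22, 2))
  expect_equal(fit$coefficients$se, unname(sqrt(diag(vcov(ols)))),
               tolerance = 1e-10)
})

test_that("noise-free balanced groups give exact group means and zero subject variance", {
  d <- data.frame(subject = rep(sprintf("S%d", 1:6), each = 2),
                  g = rep(c("a", "b"), each = 6))
  d$y <- ifelse(d$g == "a", 10, 14) + rep(c(-1, 1), 6) * 0.5
  fit <- fit_random_intercept_lmm(d, y ~ g)
  expect_equal(fit$coefficients$beta, c(10, 4), tolerance = 1e-8)
  expect_equal(fit$sigma2_subject, 0, tolerance = 1e-8)
})

test_that("balanced between-subject design recovers the classical ANOVA df", {
  set.seed(41)
  n_subj <- 12; k_obs <- 3
  d <- data.frame(subject = rep(sprintf("S%02d", 1:n_subj), each = k_obs),
                  g = rep(rep(c("a", "b", "c"), each = n_subj / 3),
                          each = k_obs))
  d$y <- rnorm(n_subj)[rep(1:n_subj, each = k_obs)] * 2 +
    rnorm(nrow(d)) + (d$g == "b") * 1.5
  fit <- fit_random_intercept_lmm(d, y ~ g)
  L <- rbind(c(0, 1, 0), c(0, 0, 1))
  ft <- contrast_f_test(fit, L)
  expect_equal(ft$df_num, 2)
  expect_equal(ft$df_den, n_subj - 3, tolerance = 1e-4)
})

test_that("a contrast on an exactly-zero coefficient gives F = 0, p = 1", {
  set.seed(6)
  base <- rnorm(8, 400, 40)
  d <- data.frame(subject = rep(sprintf("S%d", 1:8), each = 3),
                  stimulation = rep(c("EGTA", "histamine", "Ca"), 8),
                  mean_speed_nm_s = rep(base, each = 3))
  fit <- fit_random_intercept_lmm(d, mean_speed_nm_s ~ stimulation)
  ft <- contrast_f_test(fit, rbind(c(0, 1, 0), c(0, 0, 1)))
  expect_equal(ft$F, 0, tolerance = 1e-16)
  expect_equal(ft$p, 1)
  expect_error(contrast_f_test(fit, matrix(0, 1, 3)), "rank zero")
})

test_that("rank-deficient designs error naming the aliased terms", {
  d <- simulate_motility_dataset(lmm_truth(n_subjects_per_condition = 3),
                                 seed = 2)
  d <- d[d$stimulation == "EGTA", ]   # stimulation has one observed level
  d$stimulation <- factor(d$stimulation,
                          levels = c("EGTA", "histamine", "Ca"))
  expect_error(fit_random_intercept_lmm(d, mean_speed_nm_s ~ sirna +
                                          stimulation),
               "aliased.*stimulation")
})

test_that("p-values are invariant to subject relabeling and row order", {
  d <- simulate_motility_dataset(lmm_truth(n_subjects_per_condition = 4),
                                 seed = 15)
  fit1 <- fit_random_intercept_lmm(d, mean_speed_nm_s ~ sirna + noco +
                                     stimulation)
  d2 <- d[rev(seq_len(nrow(d))), ]
  d2$subject <- paste0("Z_", d2$subject)
  fit2 <- fit_random_intercept_lmm(d2, mean_speed_nm_s ~ sirna + noco +
                                     stimulation)
  expect_equal(fit1$coefficients$p, fit2$coefficients$p, tolerance = 1e-5)
  expect_equal(fit1$sigma2_subject, fit2$sigma2_subject, tolerance = 1e-5)
})

test_that("backward reduction is deterministic and records every step", {
  d <- simulate_motility_dataset(lmm_truth(), seed = 42)
  r1 <- backward_reduce(d)
  r2 <- backward_reduce(d)
  expect_identical(r1$steps, r2$steps)
  expect_identical(r1$final_label, r2$final_label)
  expect_equal(nrow(r1$steps), 5)
  expect_true(all(c("F", "df_num", "df_den", "p", "decision") %in%
                    names(r1$steps)))
})

test_that("reduction retains a strong siRNA:stimulation interaction", {
  truth <- lmm_truth(beta = c(`(Intercept)` = 390, sirnasiACBD5 = 139.1,
                              noconoco = 95.7, stimulationhistamine = -69.7,
                              stimulationCa = -69.7,
                              `sirnasiACBD5:stimulationCa` = -200),
                     n_subjects_per_condition = 10)
  d <- simulate_motility_dataset(truth, seed = 77)
  r <- backward_reduce(d)
  step3 <- r$steps[r$steps$step == 3, ]
  expect_equal(step3$decision, "retain")
  expect_lt(step3$p, 0.05)
  expect_equal(r$final_label, "full interaction")
})

test_that("pooling equal stimulation effects barely moves the other effects", {
  deltas <- vapply(1:25, function(i) {
    d <- simulate_motility_dataset(lmm_truth(), seed = 3000 + i)
    no_int <- fit_random_intercept_lmm(d, mean_speed_nm_s ~ sirna + noco +
                                         stimulation)
    d$stimulated <- factor(ifelse(d$stimulation == "EGTA", "EGTA",
                                  "stimulated"),
                           levels = c("EGTA", "stimulated"))
    pooled <- fit_random_intercept_lmm(d, mean_speed_nm_s ~ sirna + noco +
                                         stimulated)
    pooled$coefficients$beta[2] - no_int$coefficients$beta[2]
  }, numeric(1))
  expect_lt(abs(mean(deltas)), 3 * sd(deltas) / sqrt(length(deltas)) + 1e-8)
})
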