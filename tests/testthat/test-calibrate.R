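test_that("noise-free data recover the generating parameters exactly", {
  d <- sim_dataset(30, noise_sd = 0, seed = 1)
  fit <- fit_loss_model(d$ratios, d$chems)
  expect_true(fit$converged)
  expect_equal(unname(fit$estimate), c(4, 1.29, 6.18, -1), tolerance = 1e-3)
  expect_lt(fit$sse, 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-8)
})

test_that("goodness of fit follows the squared-correlation and n-1 forms", {
  expect_equal(goodness_of_fit(c(0.2, 0.5, 0.8), c(0.2, 0.5, 0.8))$r2, 1)
  expect_equal(goodness_of_fit(c(0.2, 0.5, 0.8), c(0.2, 0.5, 0.8))$rmse, 0)
  # hand computation: collinear but offset vectors
  g <- goodness_of_fit(c(0.2, 0.5, 0.8), c(0.1, 0.5, 0.9))
  expect_equal(g$r2, 1)
  expect_equal(g$rmse, sqrt(0.02 / 2))   # n - 1 denominator -> 0.1
  expect_equal(g$rmse, 0.1)
  # affine invariance of the squared correlation
  pred <- c(0.1, 0.3, 0.45, 0.7, 0.9)
  expect_equal(goodness_of_fit(pred, 0.2 + 3 * pred)$r2, 1)
  expect_warning(g0 <- goodness_of_fit(rep(0.5, 4), c(0.1, 0.2, 0.3, 0.4)),
                 "zero variance")
  expect_true(is.na(g0$r2))
  expect_error(goodness_of_fit(1:2, 1:3), "equal length")
})

test_that("every fit satisfies the RMSE-SSE consistency invariant", {
  for (seed in c(3, 17, 42)) {
    d <- sim_dataset(25, noise_sd = 0.05, seed = seed)
    fit <- suppressWarnings(fit_loss_model(d$ratios, d$chems))
    expect_equal(fit$rmse^2 * (fit$n_obs - 1), fit$sse,
                 tolerance = 1e-9)
    expect_equal(fit$dof, fit$n_obs - 4)
    expect_gte(fit$r2, 0)
    expect_lte(fit$r2, 1)
  }
})

test_that("fitting never increases the SSE relative to the start", {
  start <- starting_params()
  for (seed in c(5, 23)) {
    d <- sim_dataset(30, noise_sd = 0.08, seed = seed)
    fit <- suppressWarnings(fit_loss_model(d$ratios, d$chems,
                                           start = start))
    df <- merge(as.data.frame(d$ratios)[c("name", "ratio")],
                as.data.frame(d$chems)[c("name", "log_kow", "log_hlc")])
    sse_start <- sum((df$ratio -
                      predict_ratio(df, start, warn_missing = FALSE))^2)
    expect_lte(fit$sse, sse_start + 1e-12)
  }
})

test_that("too few distinct records is an explicit error", {
  d <- sim_dataset(4, noise_sd = 0, seed = 9)
  expect_error(fit_loss_model(d$ratios, d$chems), "insufficient data")
  # five copies of one chemical are just as insufficient
  one <- chemicals("only", 3, -4)
  recs <- as_ratio_records(data.frame(name = rep("only", 5),
                                      ratio = rep(0.4, 5)))
  expect_error(fit_loss_model(recs, one, average_replicates = FALSE),
               "insufficient data")
})

test_that("replicate records are averaged before fitting", {
  d <- sim_dataset(12, noise_sd = 0, seed = 31)
  dup <- as.data.frame(d$ratios)
  dup2 <- rbind(dup, transform(dup, ratio = pmin(ratio + 0.04, 1)))
  f_avg <- suppressWarnings(fit_loss_model(as_ratio_records(dup2), d$chems))
  avg <- transform(dup, ratio = (ratio + pmin(ratio + 0.04, 1)) / 2)
  f_ref <- suppressWarnings(fit_loss_model(as_ratio_records(avg), d$chems))
  expect_equal(f_avg$estimate, f_ref$estimate, tolerance = 1e-8)
  expect_equal(f_avg$n_obs, 12)
})

test_that("prediction bounds contain the point prediction and stay in [0,1]", {
  d <- sim_dataset(35, noise_sd = 0.05, seed = 8)
  fit <- suppressWarnings(fit_loss_model(d$ratios, d$chems))
  pb <- prediction_bounds(fit, d$chems)
  expect_true(all(pb$lwr <= pb$fit & pb$fit <= pb$upr))
  expect_true(all(pb$lwr >= 0 & pb$upr <= 1))
  expect_error(prediction_bounds(fit, d$chems, level = 1.2), "in \\(0, 1\\)")
})

test_that("prediction bounds cover fresh observations near nominal rate", {
  # Monte-Carlo oracle: with well-specified Gaussian noise away from the
  # clip boundaries, empirical coverage of 95% bounds should be ~0.95
  truth <- truth_params()
  chems <- generate_chemicals(60, kow_range = c(1.5, 6.5),
                              hlc_range = c(-9, -4), seed = 77)
  obs <- simulate_ratios(chems, truth, noise_sd = 0.04, seed = 78)
  fit <- suppressWarnings(fit_loss_model(obs, chems))
  covs <- vapply(1:12, function(i) {
    fresh <- simulate_ratios(chems, truth, noise_sd = 0.04, seed = 100 + i)
    pb <- prediction_bounds(fit, chems)
    mean(fresh$ratio >= pb$lwr & fresh$ratio <= pb$upr)
  }, numeric(1))
  expect_gte(mean(covs), 0.90)
  expect_lte(mean(covs), 0.99)
})

test_that("cross-validation is deterministic given the seed", {
  d <- sim_dataset(30, noise_sd = 0.05, seed = 11)
  cv1 <- suppressMessages(cross_validate(d$ratios, d$chems, n_reps = 20,
                                         seed = 7))
  cv2 <- suppressMessages(cross_validate(d$ratios, d$chems, n_reps = 20,
                                         seed = 7))
  expect_identical(cv1, cv2)
  cv3 <- suppressMessages(cross_validate(d$ratios, d$chems, n_reps = 20,
                                         seed = 8))
  expect_false(identical(cv1$mean_r2, cv3$mean_r2))
})

test_that("cross-validation on noise-free data is essentially perfect", {
  d <- sim_dataset(30, noise_sd = 0, seed = 13)
  cv <- suppressMessages(cross_validate(d$ratios, d$chems, n_reps = 30,
                                        seed = 3))
  expect_gt(cv$mean_r2, 0.999)
  expect_lt(cv$mean_sse, 1e-4)
  # bounds collapse to zero width on exact fits; floating-point dust can
  # push the odd exact prediction marginally outside
  expect_gte(cv$frac_in_bounds, 0.95)
})

test_that("large calibration fractions degenerate toward the full-data fit", {
  d <- sim_dataset(30, noise_sd = 0, seed = 19)
  cv <- suppressMessages(cross_validate(d$ratios, d$chems, n_reps = 5,
                                        calib_frac = 0.9, seed = 2))
  expect_lt(cv$mean_sse, 1e-6)
  full <- fit_loss_model(d$ratios, d$chems)
  expect_equal(unname(full$estimate), c(4, 1.29, 6.18, -1),
               tolerance = 1e-3)
})

test_that("k-fold mode scores every chemical exactly once per cycle", {
  d <- sim_dataset(30, noise_sd = 0.03, seed = 21)
  cv <- suppressMessages(cross_validate(d$ratios, d$chems, n_reps = 2,
                                        calib_frac = 0.8, seed = 4,
                                        method = "kfold"))
  expect_equal(cv$n_eval, 2 * 30)
  expect_true(all(cv$eval_events == 2))
})

test_that("outlier attribution ranks persistent outliers correctly", {
  d <- sim_dataset(25, noise_sd = 0.02, seed = 15)
  # force one strongly-lost chemical far off the curve so that it falls
  # outside the bounds in every split that holds it out
  df <- as.data.frame(d$ratios)
  truth_r <- predict_ratio(d$chems, truth_params(), warn_missing = FALSE)
  target <- d$chems$name[which.min(truth_r)]
  df$ratio[df$name == target] <- 0.95
  cv <- suppressMessages(cross_validate(as_ratio_records(df), d$chems,
                                        n_reps = 60, seed = 6))
  attr_tab <- outlier_attribution(cv)
  expect_equal(attr_tab$name[1], target)
  expect_gt(attr_tab$share[1], 0.5)
  expect_equal(sum(attr_tab$share), 1)
  # no events -> empty attribution
  cv0 <- suppressMessages(cross_validate(
    sim_dataset(20, noise_sd = 0, seed = 25)$ratios,
    generate_chemicals(20, seed = 25), n_reps = 3, seed = 1))
  expect_equal(nrow(outlier_attribution(cv0)), 0)
})

test_that("censoring-aware noise estimate recovers the true noise SD", {
  d <- sim_dataset(60, noise_sd = 0.05, seed = 55)
  fit <- suppressWarnings(fit_loss_model(d$ratios, d$chems))
  naive <- suppressWarnings(fit_loss_model(d$ratios, d$chems,
                                           sigma_method = "sse_dof"))
  # plain SSE/dof is shrunk by boundary censoring; the moment-matched
  # estimate should sit closer to the generating SD
  expect_lt(sqrt(naive$sigma2), 0.05)
  expect_lt(abs(sqrt(fit$sigma2) - 0.05), abs(sqrt(naive$sigma2) - 0.05))
  # point estimates and SSE are identical; only the variance scale moves
  expect_identical(fit$estimate, naive$estimate)
  expect_identical(fit$sse, naive$sse)
})
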