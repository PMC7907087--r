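test_that("chemical generation is seeded, bounded and well-spread", {
  expect_equal(nrow(generate_chemicals(0)), 0)
  a <- generate_chemicals(50, seed = 5)
  b <- generate_chemicals(50, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a, generate_chemicals(50, seed = 6)))
  big <- generate_chemicals(10000, seed = 7)
  expect_true(all(big$log_kow >= -4.15 & big$log_kow <= 6.5))
  expect_true(all(big$log_hlc >= -12.1 & big$log_hlc <= -1.3))
  # law of large numbers: mean within 3 standard errors of the midpoint
  se_kow <- (6.5 - -4.15) / sqrt(12) / sqrt(10000)
  expect_lt(abs(mean(big$log_kow) - (6.5 - 4.15) / 2), 3 * se_kow)
})

test_that("correlated sampling couples volatility to hydrophobicity", {
  cc <- generate_chemicals(2000, seed = 8, correlated = TRUE)
  expect_gt(cor(cc$log_kow, cc$log_hlc), 0.5)
  expect_true(all(cc$log_hlc >= -12.1 & cc$log_hlc <= -1.3))
})

test_that("simulated ratios follow the forward model plus bounded noise", {
  chems <- generate_chemicals(30, seed = 9)
  p <- truth_params()
  exact <- simulate_ratios(chems, p, noise_sd = 0, seed = 1)
  expect_equal(exact$ratio, predict_ratio(chems, p, warn_missing = FALSE))
  # clipping keeps everything in [0, 1] however large the noise
  wild <- simulate_ratios(chems, p, noise_sd = 5, seed = 2)
  expect_true(all(wild$ratio >= 0 & wild$ratio <= 1))
  # seeded determinism
  expect_identical(simulate_ratios(chems, p, noise_sd = 0.05, seed = 3),
                   simulate_ratios(chems, p, noise_sd = 0.05, seed = 3))
})

test_that("noise SD is faithful away from the clip boundaries", {
  # one mid-curve chemical (true ratio 0.5) replicated many times
  p <- truth_params()
  mid <- chemicals(rep("mid", 5000), rep(p$p1, 5000), rep(-20, 5000))
  obs <- simulate_ratios(mid, p, noise_sd = 0.05, seed = 10)
  expect_equal(sd(obs$ratio), 0.05, tolerance = 0.05)
  # logit-normal variant also respects the bounds without clipping mass
  lg <- simulate_ratios(mid, p, noise_sd = 0.3, seed = 11,
                        noise = "logit_normal")
  expect_true(all(lg$ratio > 0 & lg$ratio < 1))
})

test_that("in-text fixture chemicals are frozen", {
  fx <- intext_chemicals()
  expect_equal(fx$name,
               c("difenoconazole", "2,4-di-tert-butylphenol",
                 "naphthalene", "propiconazole", "3,4-dichloroaniline"))
  expect_equal(fx$log_kow, c(4.3, 5.19, 3.3, 3.72, 2.69))
  expect_equal(fx$log_hlc, c(-11.05, -5.43, -3.36, NA, -5.98))
  design <- attr(fx, "design")
  expect_equal(design$times_h, c(0, 4, 24))
  expect_equal(design$volumes_ml, c(1, 2))
  expect_setequal(design$covers,
                  c("plastic_lid", "adhesive_foil", "aluminium_foil"))
  # volatility split at the legacy threshold
  expect_warning(cls <- classify_volatility(fx$log_hlc), "missing")
  expect_equal(cls, c("non_volatile", "volatile", "volatile",
                      "non_volatile", "non_volatile"))
})

test_that("simulation design validates its inputs", {
  d <- simulation_design()
  expect_equal(d$n_chemicals, 40)
  expect_equal(d$noise_sd, 0.05)
  expect_equal(c(d$true_params$p1, d$true_params$p2,
                 d$true_params$p3, d$true_params$p4),
               c(4, 1.29, 6.18, -1))
  expect_error(simulation_design(noise_sd = -1), ">= 0")
  expect_error(simulation_design(kow_range = c(2, 1)), "ordered")
})

test_that("end-to-end recovery: fits cover the truth at near-nominal rate", {
  # generate -> simulate -> fit; each parameter's own 95% CI should cover
  # its generating value in at least 90% of seeded repeats
  truth <- truth_params()
  tp <- c(4, 1.29, 6.18, -1)
  n_rep <- 200
  hits <- matrix(NA, n_rep, 4)
  for (i in seq_len(n_rep)) {
    chems <- generate_chemicals(40, seed = 7000 + i)
    obs <- simulate_ratios(chems, truth, noise_sd = 0.02, seed = 8000 + i)
    fit <- tryCatch(suppressWarnings(fit_loss_model(obs, chems)),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    hits[i, ] <- fit$ci95[, "lower"] <= tp & tp <= fit$ci95[, "upper"]
  }
  coverage <- colMeans(hits, na.rm = TRUE)
  expect_true(all(coverage >= 0.90))
  expect_gt(mean(!is.na(hits[, 1])), 0.95)   # almost all fits usable
})
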