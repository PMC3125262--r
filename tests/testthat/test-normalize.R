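make_controls <- function(dg, ln_i) {
  data.frame(probe_id = names(dg), intensity = exp(ln_i))
}

test_that("noiseless collinear controls are recovered exactly", {
  dg <- setNames(seq(-35, -15, length.out = 11), paste0("c", 1:11))
  controls <- make_controls(dg, 5 - 0.15 * dg)
  fit <- fit_control_model(controls, dg)
  expect_equal(fit$alpha, 5, tolerance = 1e-9)
  expect_equal(fit$beta, -0.15, tolerance = 1e-9)
  expect_equal(fit$resid_sd, 0, tolerance = 1e-9)
  ai <- adjust_intensities(controls, fit, dg)
  expect_equal(ai$ai, rep(0, 11), tolerance = 1e-9)
})

test_that("slope matches the closed-form two-point OLS oracle", {
  dg <- c(a = -30, b = -25, c = -20)
  controls <- make_controls(dg, c(9, 8, 7))
  fit <- fit_control_model(controls, dg)
  # collinear: slope -1/5, intercept 9 - (-0.2)(-30) = 3
  expect_equal(fit$beta, -0.2, tolerance = 1e-12)
  expect_equal(fit$alpha, 3, tolerance = 1e-12)
  expect_equal(fit$n_controls, 3L)
})

test_that("simulated controls recover generative parameters within 3 SE", {
  set.seed(303)
  dg <- setNames(unname(delta_g37(rand_seqs(1000, 25))), paste0("c", 1:1000))
  controls <- make_controls(dg, 5 - 0.15 * dg + rnorm(1000, 0, 0.3))
  fit <- fit_control_model(controls, dg)
  expect_lt(abs(fit$beta - (-0.15)), 3 * fit$se_beta)
  expect_equal(fit$resid_sd, 0.3, tolerance = 0.1)
})

test_that("median control AI is zero under the package median convention", {
  set.seed(9)
  for (n in c(11, 12)) {  # odd: exact; even: midpoint mean, fp tolerance
    dg <- setNames(rnorm(n, -25, 3), paste0("c", 1:n))
    controls <- make_controls(dg, rnorm(n, 6, 1))
    fit <- fit_control_model(controls, dg)
    ai <- adjust_intensities(controls, fit, dg)
    if (n %% 2 == 1) expect_identical(median(ai$ai), 0)
    else expect_lt(abs(median(ai$ai)), 1e-9)
  }
})

test_that("adding a constant to log intensities shifts alpha and shift, not AI", {
  set.seed(31)
  dg <- setNames(rnorm(50, -25, 3), paste0("c", 1:50))
  y <- 5 - 0.15 * dg + rnorm(50, 0, 0.3)
  f0 <- fit_control_model(make_controls(dg, y), dg)
  f1 <- fit_control_model(make_controls(dg, y + 2.5), dg)
  expect_equal(f1$alpha, f0$alpha + 2.5, tolerance = 1e-9)
  expect_equal(f1$beta, f0$beta, tolerance = 1e-9)
  expect_equal(f1$shift, f0$shift + 2.5, tolerance = 1e-9)
  a0 <- adjust_intensities(make_controls(dg, y), f0, dg)
  a1 <- adjust_intensities(make_controls(dg, y + 2.5), f1, dg)
  expect_equal(a1$ai, a0$ai, tolerance = 1e-9)
})

test_that("OLS residuals decouple from dG37; median centering happens after", {
  set.seed(77)
  dg <- setNames(rnorm(200, -25, 3), paste0("c", 1:200))
  y <- 5 - 0.15 * dg + rnorm(200, 0, 0.3)
  controls <- make_controls(dg, y)
  fit <- fit_control_model(controls, dg)
  ols_resid <- y - fit$alpha - fit$beta * dg
  expect_lt(abs(unname(coef(lm(ols_resid ~ dg))[2])), 1e-9)
  # the AI centering is a median shift, distinct from the OLS intercept
  ai <- adjust_intensities(controls, fit, dg)
  expect_lt(abs(median(ai$ai)), 1e-9)
  expect_equal(ai$ai - ols_resid, rep(fit$alpha - fit$shift, 200),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("degenerate designs and bad intensities are rejected", {
  dg <- c(a = -25, b = -25, c = -25)
  expect_error(fit_control_model(make_controls(dg, c(1, 2, 3)), dg),
               "distinct")
  dg2 <- c(a = -30, b = -25, c = -20)
  bad <- data.frame(probe_id = names(dg2), intensity = c(10, 0, 10))
  expect_error(fit_control_model(bad, dg2), "probe b")
  fit <- fit_control_model(make_controls(dg2, c(9, 8, 7)), dg2)
  expect_error(adjust_intensities(
    data.frame(probe_id = "zz", intensity = 5), fit, dg2), "zz")
})

test_that("theil-sen option resists a gross outlier", {
  dg <- setNames(seq(-35, -16, by = 1), paste0("c", 1:20))
  y <- 5 - 0.15 * dg
  y[3] <- y[3] + 50
  fit <- fit_control_model(make_controls(dg, y), dg, method = "theil-sen")
  expect_equal(fit$beta, -0.15, tolerance = 1e-9)
})

test_that("replicate chips combine to geometric means before fitting", {
  intensities <- data.frame(
    probe_id = rep(c("p1", "p2"), each = 2),
    chip_id = rep(c("x_1", "x_2"), times = 2),
    intensity = c(100, 400, 10, 1000)
  )
  chips <- data.frame(chip_id = c("x_1", "x_2"), species = "x",
                      replicate = 1:2)
  out <- collapse_replicates(intensities, chips)
  expect_equal(out$intensity[out$probe_id == "p1"], 200)  # sqrt(100*400)
  expect_equal(out$intensity[out$probe_id == "p2"], 100)
})

test_that("combine_replicates averages per-chip AI and is a brute-force mean", {
  t1 <- data.frame(probe_id = "p1", ai = 1.0)
  t2 <- data.frame(probe_id = "p1", ai = 3.0)
  expect_equal(combine_replicates(list(t1, t2), "x")$ai, 2.0)
  expect_equal(combine_replicates(list(t1), "x")$ai, 1.0)

  set.seed(5)
  ids <- paste0("p", 1:100)
  tabs <- lapply(1:3, function(k) {
    data.frame(probe_id = sample(ids), ai = rnorm(100))
  })
  got <- combine_replicates(tabs, "x")
  want <- vapply(got$probe_id, function(id) {
    mean(vapply(tabs, function(t) t$ai[t$probe_id == id], numeric(1)))
  }, numeric(1))
  expect_equal(got$ai, unname(want))

  t3 <- data.frame(probe_id = c("p1", "q9"), ai = c(1, 2))
  expect_error(combine_replicates(list(t1, t3), "x"), "1 asymmetric")
})

test_that("per-species and per-chip modes both center controls at zero", {
  sim <- small_sim(seed = 101)
  for (per_chip in c(FALSE, TRUE)) {
    res <- normalize_experiment(sim$intensities, sim$chips, sim$probes,
                                per_chip = per_chip)
    ctl <- sim$probes$probe_id[sim$probes$category == "control"]
    for (sp in unique(res$ai$species)) {
      m <- median(res$ai$ai[res$ai$species == sp & res$ai$probe_id %in% ctl])
      expect_lt(abs(m), if (per_chip) 0.2 else 1e-9)
    }
  }
})
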