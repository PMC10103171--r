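test_that("gamma = 0 returns the initial weights exactly with zero work", {
  p <- tiny_problem(3)
  pred <- predict_peptide_uptake(p$features, c(0.6, 0.3, 0.1), beta_params(),
                                 p$rates, p$peptides, p$exposures)
  tgt <- as_target(pred, p$peptides)
  w0 <- c(0.5, 0.25, 0.25)
  rw <- reweight(p$features, p$rates, beta_params(), tgt, gamma = 0, w0 = w0)
  expect_identical(rw$weights, w0)
  expect_identical(rw$W_app, 0)
  expect_identical(rw$mse_initial, rw$mse_final)
})

test_that("a self-consistent target leaves uniform weights unchanged at any gamma", {
  p <- tiny_problem(4)
  w0 <- rep(0.25, 4)
  pred <- predict_peptide_uptake(p$features, w0, beta_params(), p$rates,
                                 p$peptides, p$exposures)
  tgt <- as_target(pred, p$peptides)
  for (g in c(0.1, 10, 1000)) {
    rw <- reweight(p$features, p$rates, beta_params(), tgt, gamma = g, w0 = w0)
    expect_equal(rw$weights, w0, tolerance = 1e-6)
    expect_lt(rw$W_app, 1e-9)
  }
})

test_that("optimized weights match the exhaustive simplex grid oracle", {
  for (nf in c(2, 3)) {
    p <- tiny_problem(nf)
    # target = frame 1's own prediction, so weight should drift to frame 1
    e1 <- sprintf("f%d", 1)
    w_target <- as.numeric(seq_len(nf) == 1)
    w_target <- 0.9 * w_target + 0.1 / nf
    pred <- predict_peptide_uptake(p$features, w_target, beta_params(),
                                   p$rates, p$peptides, p$exposures)
    tgt <- as_target(pred, p$peptides)
    w0 <- rep(1 / nf, nf)
    step <- if (nf == 2) 1e-3 else 2e-3
    setup <- oracle_grid_setup(p$features, p$rates, beta_params(), tgt,
                               p$peptides, w0, step = step)
    for (g in c(0.5, 5, 50)) {
      rw <- reweight(p$features, p$rates, beta_params(), tgt, gamma = g,
                     w0 = w0)
      oracle <- oracle_grid_reweight(setup, g)
      expect_equal(rw$weights, oracle$w, tolerance = 2 * step,
                   info = sprintf("nf=%d gamma=%g", nf, g))
    }
  }
})

test_that("a perfectly matching frame absorbs the weight as gamma grows", {
  p <- tiny_problem(2)
  pred1 <- predict_peptide_uptake(p$features, c(1, 0), beta_params(),
                                  p$rates, p$peptides, p$exposures)
  tgt <- as_target(pred1, p$peptides)
  rw <- reweight(p$features, p$rates, beta_params(), tgt, gamma = 1e5,
                 w0 = c(0.5, 0.5))
  expect_gt(rw$weights[1], 0.99)
  expect_lt(rw$mse_final, 1e-6)
})

test_that("the apparent work reproduces the closed-form KL values", {
  expect_equal(apparent_work(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(apparent_work(c(1, 0), c(0.5, 0.5), temperature_K = 298),
               0.008314462618 * 298 * log(2), tolerance = 1e-12)
})

test_that("reweighting is invariant to duplicating a frame with split weight", {
  p <- tiny_problem(3)
  pred <- predict_peptide_uptake(p$features, c(0.7, 0.2, 0.1), beta_params(),
                                 p$rates, p$peptides, p$exposures)
  tgt <- as_target(pred, p$peptides)
  rw <- reweight(p$features, p$rates, beta_params(), tgt, gamma = 20,
                 w0 = rep(1 / 3, 3))

  # duplicate frame 1 with its initial weight split in half
  dup <- p$features[p$features$frame_id == "f1", ]
  dup$frame_id <- "f1b"
  feats4 <- rbind(p$features, dup)
  w04 <- c(1 / 6, 1 / 3, 1 / 3, 1 / 6)
  rw4 <- reweight(feats4, p$rates, beta_params(), tgt, gamma = 20, w0 = w04)
  expect_equal(rw4$weights[1] + rw4$weights[4], rw$weights[1],
               tolerance = 1e-6)
  expect_equal(rw4$weights[2:3], rw$weights[2:3], tolerance = 1e-6)
})

test_that("the gamma scan selects the largest work not exceeding the budget", {
  p <- tiny_problem(2)
  pred1 <- predict_peptide_uptake(p$features, c(0.95, 0.05), beta_params(),
                                  p$rates, p$peptides, p$exposures)
  tgt <- as_target(pred1, p$peptides)
  scan <- suppressWarnings(
    gamma_scan(p$features, p$rates, beta_params(), tgt,
               gammas = 10^seq(-2, 4, by = 0.5), W_target = 0.5))
  tr <- scan$scan_trace
  expect_true(all(diff(tr$W_app) >= -1e-10))
  expect_true(all(diff(tr$mse) <= 1e-10))
  expect_lte(scan$W_app, 0.5)
  under <- tr$W_app[tr$W_app <= 0.5]
  expect_equal(scan$W_app, max(under))

  # an unreachable budget returns the largest gamma with a warning
  expect_warning(
    big <- gamma_scan(p$features, p$rates, beta_params(), tgt,
                      gammas = c(1e-3, 1e-2), W_target = 50),
    "largest gamma")
  expect_equal(big$gamma, 1e-2)
})

test_that("degenerate reweighting inputs are rejected", {
  p <- tiny_problem(2)
  pred <- predict_peptide_uptake(p$features, c(0.5, 0.5), beta_params(),
                                 p$rates, p$peptides, p$exposures)
  tgt <- as_target(pred, p$peptides)
  raw <- uptake_table(as.data.frame(tgt), p$peptides, normalized = FALSE)
  expect_error(reweight(p$features, p$rates, beta_params(), raw, gamma = 1),
               "normalized")
  expect_error(reweight(p$features, p$rates, beta_params(), tgt, gamma = 1,
                        w0 = c(0.5, 0.2)), "sum to 1|entries")
  expect_error(reweight(p$features, p$rates, beta_params(), tgt, gamma = 1,
                        w0 = c(1, 0)), "strictly positive")
})
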