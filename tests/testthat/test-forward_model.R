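test_that("log protection factors follow the weighted linear feature model", {
  # zero features -> lnPF 0, PF 1
  f0 <- data.frame(frame_id = "f1", residue = 2:4, N_C = 0L, N_H = 0L)
  pf0 <- protection_factors(f0, 1, beta_params())
  expect_equal(pf0$lnPF, rep(0, 3))

  # single frame, N_C = 10, N_H = 2 with the default betas
  f1 <- data.frame(frame_id = "f1", residue = 2L, N_C = 10L, N_H = 2L)
  expect_equal(protection_factors(f1, 1, beta_params(0.35, 2.0))$lnPF, 7.5)

  # two equally weighted frames averaging lnPF contributions 2 and 4
  f2 <- data.frame(frame_id = c("a", "b"), residue = 2L,
                   N_C = c(0L, 0L), N_H = c(1L, 2L))
  expect_equal(protection_factors(f2, c(0.5, 0.5), beta_params(0, 2))$lnPF, 3)

  # linearity: doubling both betas doubles lnPF exactly
  p <- tiny_problem(3)
  l1 <- protection_factors(p$features, rep(1 / 3, 3), beta_params(0.35, 2))$lnPF
  l2 <- protection_factors(p$features, rep(1 / 3, 3), beta_params(0.70, 4))$lnPF
  expect_identical(l2, 2 * l1)

  expect_error(protection_factors(f2, 1, beta_params()), "weights")
})

test_that("residue deuteration follows EX2 kinetics with its limits", {
  rates <- structure(setNames(log(2), "2"), class = "intrinsic_rates")
  pf <- structure(data.frame(residue = 2L, lnPF = 0), class = "data.frame")
  # k t / PF = ln 2 at t = 60 s -> D = 0.5
  expect_equal(residue_deuteration(pf, rates, 60)$D, 0.5)
  expect_equal(residue_deuteration(pf, rates, 0)$D, 0)
  pf_inf <- data.frame(residue = 2L, lnPF = 700)
  expect_lt(residue_deuteration(pf_inf, rates, 1e6)$D, 1e-10)
  expect_error(residue_deuteration(pf, rates, -5), "non-negative")
})

test_that("peptide deuteration averages exchange-competent residues", {
  rd <- data.frame(residue = rep(2:4, 2), exposure_s = rep(c(30, 300), each = 3),
                   D = c(0.2, 0.4, 0.6, 0.3, 0.5, 0.7))
  pm <- peptide_map("pep", 1L, 4L, "AAAA")
  out <- peptide_deuteration(rd, pm, first_residue_skip = 1L)
  expect_equal(out$D, c(0.4, 0.5))  # residue 1 excluded, mean of rest

  # a peptide with no exchange-competent residues is excluded with a warning
  pm2 <- peptide_map(c("ok", "empty"), c(1L, 10L), c(4L, 11L), c("AAAA", "PP"))
  expect_warning(out2 <- peptide_deuteration(rd, pm2), "excluded")
  expect_equal(unique(out2$peptide_id), "ok")
})

test_that("predictions stay in [0,1], rise with time, and ignore frame order", {
  p <- tiny_problem(4)
  w <- c(0.1, 0.2, 0.3, 0.4)
  pred <- predict_peptide_uptake(p$features, w, beta_params(), p$rates,
                                 p$peptides, c(10, 60, 600, 7200))
  expect_true(all(pred$D >= 0 & pred$D <= 1))
  for (s in split(pred, pred$peptide_id))
    expect_true(all(diff(s$D[order(s$exposure_s)]) >= 0))

  # permute frames together with weights: identical predictions
  perm <- c(3, 1, 4, 2)
  frames <- unique(p$features$frame_id)
  feats_p <- p$features[order(match(p$features$frame_id, frames[perm])), ]
  pred2 <- predict_peptide_uptake(feats_p, w[perm], beta_params(), p$rates,
                                  p$peptides, c(10, 60, 600, 7200))
  expect_equal(pred2$D, pred$D)

  # beta = (0,0): intrinsic-rate-only closed form
  pred0 <- predict_peptide_uptake(p$features, w, beta_params(0, 0), p$rates,
                                  p$peptides, 60)
  k <- as.numeric(p$rates[as.character(3:4)])
  expect_equal(pred0$D[pred0$peptide_id == "pep1"],
               mean(1 - exp(-k * 1)))
})

test_that("MaxD normalization divides by the peptide's mean MaxD uptake", {
  pm <- peptide_map(c("a", "b"), c(2, 8), c(6, 12), c("KTAYI", "KQRQI"))
  raw <- uptake_table(data.frame(
    peptide_id = c("a", "a", "b", "b"), state = "apo",
    exposure_s = c(30, 300, 30, 300), replicate = 1L,
    uptake = c(2.0, 3.0, -0.1, 1.0)), pm)
  maxd <- uptake_table(data.frame(
    peptide_id = c("a", "a", "b"), state = "MaxD", exposure_s = 3600,
    replicate = c(1L, 2L, 1L), uptake = c(3.9, 4.1, 4.0)), pm)
  norm <- normalize_to_maxd(raw, maxd)
  expect_true(is_normalized(norm))
  expect_equal(norm$uptake[norm$peptide_id == "a"], c(0.5, 0.75))
  expect_equal(norm$uptake[norm$peptide_id == "b"], c(-0.025, 0.25))

  # idempotence: MaxD normalized against itself is 1 everywhere
  self <- normalize_to_maxd(maxd, maxd)
  expect_equal(tapply(self$uptake, self$peptide_id, mean),
               c(a = 1, b = 1), tolerance = 1e-12, ignore_attr = TRUE)

  # peptide missing from MaxD is dropped with a warning
  maxd_a <- uptake_table(maxd[maxd$peptide_id == "a", ], pm)
  expect_warning(n2 <- normalize_to_maxd(raw, maxd_a), "MaxD")
  expect_equal(unique(n2$peptide_id), "a")
  expect_error(normalize_to_maxd(norm, maxd), "already normalized")
})

test_that("filtering drops out-of-span and negative-mean peptides, keeping the rest", {
  pm <- peptide_map(c("nterm", "neg", "good", "cterm"),
                    c(1, 100, 100, 476), c(5, 110, 110, 485),
                    c("MKTAY", strrep("A", 11), strrep("A", 11), strrep("A", 10)))
  pm <- pm[!duplicated(pm$peptide_id), ]
  recs <- do.call(rbind, lapply(seq_len(nrow(pm)), function(i)
    data.frame(peptide_id = pm$peptide_id[i], state = "apo",
               exposure_s = c(30, 300), replicate = 1L,
               uptake = c(0.4, 0.6))))
  recs$uptake[recs$peptide_id == "neg" & recs$exposure_s == 30] <- -0.02
  tab <- uptake_table(recs, pm, normalized = TRUE)
  msgs <- capture_messages(out <- filter_peptides(tab, c(6, 478)))
  expect_setequal(unique(out$peptide_id), "good")
  expect_true(any(grepl("nterm.*span", msgs)))
  expect_true(any(grepl("neg.*negative", msgs)))
  expect_true(any(grepl("cterm.*span", msgs)))
})
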