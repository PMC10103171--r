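test_that("state populations are summed weights, invariant to relabeling order", {
  pop <- populations(c(0.3, 0.2, 0.25, 0.25), c("OF", "OF", "IF", "IF"))
  expect_equal(pop$fraction[pop$state == "OF"], 0.5)
  expect_equal(pop$fraction[pop$state == "IF"], 0.5)
  expect_equal(sum(pop$fraction), 1)

  one <- populations(c(1, 0, 0), c("OF", "IF", "IF"))
  expect_equal(one$fraction[one$state == "OF"], 1)

  # uniform weights over a 50/50 split give the candidate 0.5/0.5 mixture
  u <- populations(rep(1 / 10, 10), rep(c("OF", "IF"), each = 5))
  expect_equal(u$fraction, c(0.5, 0.5))

  perm <- sample(4)
  pop2 <- populations(c(0.3, 0.2, 0.25, 0.25)[perm],
                      c("OF", "OF", "IF", "IF")[perm])
  expect_equal(pop2, pop)
  expect_error(populations(c(0.5, 0.5), c("OF", NA)), "label")
  expect_error(populations(c(0.6, 0.6), c("OF", "IF")), "sum to 1")
})

test_that("systematic subsampling partitions frames by stride and reports SD", {
  spec <- small_spec(seed = 21)
  syn <- make_target_uptake(spec)
  tgt <- suppressMessages(filter_peptides(
    normalize_to_maxd(syn$raw, syn$maxd), c(1, spec$n_residues)))
  rates <- intrinsic_rates(spec$sequence)
  sub <- suppressWarnings(
    subsample_uncertainty(syn$ensemble$features, syn$ensemble$state,
                          rates, beta_params(), tgt, k = 2,
                          gammas = 10^seq(-1, 2, by = 0.5)))
  expect_equal(attr(sub, "n_subsamples"), 2)
  expect_true(all(sub$sd >= 0))
  expect_equal(sum(sub$fraction), 1, tolerance = 1e-9)
  runs <- attr(sub, "runs")
  expect_length(runs, 2)

  # identical frames in every subset -> SD exactly 0
  feats1 <- syn$ensemble$features[
    syn$ensemble$features$frame_id %in% c("OF_001", "IF_001"), ]
  clones <- do.call(rbind, lapply(1:6, function(i) {
    f <- feats1
    f$frame_id <- paste0(f$frame_id, "_c", i)
    f
  }))
  labs <- rep(rep(c("OF", "IF"), 6), each = length(unique(feats1$residue)))
  labs <- sub("_.*", "", unique(clones$frame_id))
  sub0 <- suppressWarnings(
    subsample_uncertainty(clones, labs, rates, beta_params(), tgt,
                          k = 3, gammas = c(0.1, 1)))
  expect_equal(sub0$sd, c(0, 0), tolerance = 1e-8)
})

test_that("reweighted histograms carry the frame weights as bin masses", {
  x <- c(1.5, 2.5, 3.5, 4.5)
  h <- reweighted_distribution(x, rep(0.25, 4), breaks = 1:5)
  expect_equal(h$mass, rep(0.25, 4))
  expect_equal(sum(h$mass), 1)

  h1 <- reweighted_distribution(x, c(0, 0, 1, 0), breaks = 1:5)
  expect_equal(h1$mass, c(0, 0, 1, 0))

  set.seed(8)
  xs <- runif(50, 0, 10)
  ws <- runif(50); ws <- ws / sum(ws)
  hh <- reweighted_distribution(xs, ws, breaks = seq(0, 10, 0.5))
  mids <- (hh$bin_lo + hh$bin_hi) / 2
  expect_equal(sum(hh$mass * mids), sum(ws * xs), tolerance = 0.3)
  expect_error(reweighted_distribution(xs, ws, breaks = 2:8), "cover")
})

test_that("interdomain centroid distances respond to structure opening", {
  f <- tempfile(fileext = ".pdb")
  writeLines(make_toy_pdb(12, "extended", n_models = 2), f)
  ens <- read_ensemble_pdb(f, "X")
  d <- interdomain_distance(ens, 1:3, 10:12)
  expect_length(d, 2)
  expect_equal(d[1], d[2], tolerance = 1e-3)  # rigid copies (PDB 3-decimal coords)
  expect_gt(d[1], 20)                         # extended chain is long
})

test_that("per-peptide RMSE matches its closed forms and flags the worst peptide", {
  p <- tiny_problem(2)
  pred <- predict_peptide_uptake(p$features, c(0.5, 0.5), beta_params(),
                                 p$rates, p$peptides, p$exposures)
  tgt <- as_target(pred, p$peptides)
  r0 <- peptide_rmse(pred, pred, tgt)
  expect_equal(r0$rmse_after, c(0, 0))

  off <- pred
  off$D <- off$D + ifelse(off$peptide_id == "pep2", 0.07, 0.02)
  r1 <- peptide_rmse(pred, off, tgt)
  expect_equal(r1$peptide_id[1], "pep2")   # sorted by descending after-RMSE
  expect_equal(r1$rmse_after, c(0.07, 0.02), tolerance = 1e-12)

  # brute-force check of the top-ranked value
  cells <- merge(off, as.data.frame(tgt)[c("peptide_id", "exposure_s", "uptake")])
  worst <- cells[cells$peptide_id == "pep2", ]
  expect_equal(r1$rmse_after[1], sqrt(mean((worst$D - worst$uptake)^2)))

  bad <- pred[-1, ]
  expect_error(peptide_rmse(bad, off, tgt), "grid")
})

test_that("excluding a corrupted peptide moves the recovery toward the truth", {
  # full-length protein so the peptide map is redundant enough that one
  # outlier peptide can be dropped without losing coverage
  spec <- synthetic_spec(seed = 31, noise_sd = 0, n_frames = 30)
  syn <- make_target_uptake(spec)
  tgt <- suppressMessages(filter_peptides(
    normalize_to_maxd(syn$raw, syn$maxd), c(1, spec$n_residues)))
  rates <- intrinsic_rates(spec$sequence)
  pm <- peptides_of(tgt)

  corrupt_id <- pm$peptide_id[2]
  corr <- tgt
  corr$uptake[corr$peptide_id == corrupt_id] <-
    corr$uptake[corr$peptide_id == corrupt_id] + 0.35
  corr <- uptake_table(as.data.frame(corr), pm, normalized = TRUE)

  gam <- 10^seq(-1, 2.5, by = 0.5)
  res <- suppressWarnings(
    exclusion_robustness(syn$ensemble$features, syn$ensemble$state,
                         rates, beta_params(), corr,
                         exclude = corrupt_id, gammas = gam))
  truth <- spec$true_mixture["OF"]
  of0 <- res$original$fraction[res$original$state == "OF"]
  of1 <- res$excluded$fraction[res$excluded$state == "OF"]
  expect_lt(abs(of1 - truth), abs(of0 - truth))

  # excluding a peptide whose fit is already perfect changes little
  clean <- suppressWarnings(
    exclusion_robustness(syn$ensemble$features, syn$ensemble$state,
                         rates, beta_params(), tgt,
                         exclude = pm$peptide_id[3], gammas = gam))
  expect_equal(clean$excluded$fraction, clean$original$fraction,
               tolerance = 0.02)

  expect_error(exclusion_robustness(syn$ensemble$features, syn$ensemble$state,
                                    rates, beta_params(), tgt,
                                    exclude = "nope", gammas = gam),
               "not in target")
  expect_error(exclusion_robustness(syn$ensemble$features, syn$ensemble$state,
                                    rates, beta_params(), tgt,
                                    exclude = pm$peptide_id, gammas = gam),
               "empties")
})
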