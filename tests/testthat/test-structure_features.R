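make_frame <- function(...) {
  # rows: list(elety, resno, resid, element, x, y, z)
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(elety = r[[1]], resno = as.integer(r[[2]]), resid = r[[3]],
               element = r[[4]], x = r[[5]], y = r[[6]], z = r[[7]],
               stringsAsFactors = FALSE)))
}

test_that("contact counting respects the cutoff and exclusion window", {
  # amide N of residue 5 with one carbon at 6.4 A and one at 6.6 A
  fr <- make_frame(
    list("N", 1, "ALA", "N", -10, 0, 0), list("CA", 1, "ALA", "C", -11, 0, 0),
    list("N", 5, "ALA", "N", 0, 0, 0), list("CA", 5, "ALA", "C", 1.5, 0, 0),
    list("CB", 9, "ALA", "C", 6.4, 0, 0), list("CB", 10, "ALA", "C", 6.6, 0, 0)
  )
  expect_equal(compute_contacts(fr, 5, cutoff = 6.5, exclusion_window = 2), 1)
  # everything inside the exclusion window -> 0
  fr2 <- make_frame(
    list("N", 1, "ALA", "N", -3.8, 0, 0), list("CA", 1, "ALA", "C", -2.6, 0, 0),
    list("N", 2, "ALA", "N", 0, 0, 0), list("CA", 2, "ALA", "C", 1.5, 0, 0),
    list("C", 2, "ALA", "C", 2.5, 0, 0)
  )
  expect_equal(compute_contacts(fr2, 2, cutoff = 6.5, exclusion_window = 2), 0)
  expect_warning(v <- compute_contacts(fr, 1, 6.5, 2), "amide")
  expect_true(is.na(v))
})

test_that("hydrogen-bond counting respects the O...H cutoff", {
  fr <- make_frame(
    list("N", 1, "ALA", "N", -3.8, 0, 0), list("C", 1, "ALA", "C", -2.0, 1.0, 0),
    list("O", 1, "ALA", "O", 0, 2.3, 0),
    list("N", 2, "ALA", "N", 0, -1.01, 0), list("H", 2, "ALA", "H", 0, 0, 0),
    list("CA", 2, "ALA", "C", 1.5, -1.5, 0)
  )
  expect_equal(compute_hbonds(fr, 2, h_cutoff = 2.4), 1)
  expect_equal(compute_hbonds(fr, 2, h_cutoff = 2.2), 0)
})

test_that("feature counts equal the all-pairs oracle on toy conformers", {
  for (conf in c("helix", "extended")) {
    f <- tempfile(fileext = ".pdb")
    writeLines(make_toy_pdb(20, conf, proline_at = 7L), f)
    ens <- read_ensemble_pdb(f, "X")
    feats <- featurize_ensemble(ens)
    frame <- ens$coords[[1]]
    for (r in feats$residue) {
      expect_equal(feats$N_C[feats$residue == r],
                   oracle_contacts(frame, r, 6.5, 2),
                   info = sprintf("%s residue %d N_C", conf, r))
      expect_equal(feats$N_H[feats$residue == r],
                   oracle_hbonds(frame, r, 2.4),
                   info = sprintf("%s residue %d N_H", conf, r))
    }
  }
})

test_that("helix geometry gives N_H = 1 from residue 5 on; extended gives 0", {
  f <- tempfile(fileext = ".pdb")
  writeLines(make_toy_pdb(16, "helix"), f)
  feats <- featurize_ensemble(read_ensemble_pdb(f, "X"))
  expect_true(all(feats$N_H[feats$residue >= 5] == 1))
  expect_true(all(feats$N_H[feats$residue < 5] == 0))
  writeLines(make_toy_pdb(16, "extended"), f)
  fe <- featurize_ensemble(read_ensemble_pdb(f, "X"))
  expect_true(all(fe$N_H == 0))
  expect_true(all(fe$N_C == 0))
})

test_that("features are invariant under rigid-body transforms", {
  f <- tempfile(fileext = ".pdb")
  writeLines(make_toy_pdb(15, "helix", n_models = 5), f)  # models are rigid copies
  ens <- read_ensemble_pdb(f, "X")
  feats <- featurize_ensemble(ens)
  per_frame <- split(feats[c("N_C", "N_H")], feats$frame_id)
  for (k in 2:5)
    expect_identical(per_frame[[k]], per_frame[[1]], ignore_attr = TRUE)

  # random rotations applied directly to one frame
  set.seed(9)
  frame <- ens$coords[[1]]
  base_c <- oracle_contacts(frame, 8, 6.5, 2)
  base_h <- oracle_hbonds(frame, 8, 2.4)
  for (i in 1:5) {
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    xyz <- as.matrix(frame[c("x", "y", "z")]) %*% q
    rf <- frame
    rf$x <- xyz[, 1] + 10 * i; rf$y <- xyz[, 2] - 3; rf$z <- xyz[, 3]
    expect_equal(compute_contacts(rf, 8, 6.5, 2), base_c)
    expect_equal(compute_hbonds(rf, 8, 2.4), base_h)
  }
})

test_that("feature counts are monotone in their cutoffs", {
  f <- tempfile(fileext = ".pdb")
  writeLines(make_toy_pdb(20, "helix"), f)
  frame <- read_ensemble_pdb(f, "X")$coords[[1]]
  for (r in c(6, 10, 14)) {
    nc <- vapply(c(4, 5, 6.5, 8, 10),
                 function(cc) compute_contacts(frame, r, cc, 2), integer(1))
    expect_true(all(diff(nc) >= 0))
    nh <- vapply(c(1.5, 2.0, 2.4, 3.5, 5),
                 function(cc) compute_hbonds(frame, r, cc), integer(1))
    expect_true(all(diff(nh) >= 0))
  }
})

test_that("first residue and prolines are excluded; precomputed features pass through", {
  f <- tempfile(fileext = ".pdb")
  writeLines(make_toy_pdb(10, "extended", n_models = 3, proline_at = 6L), f)
  ens <- read_ensemble_pdb(f, "X")
  feats <- featurize_ensemble(ens)
  expect_equal(nrow(feats), 3 * 8)            # 10 residues - first - 1 Pro
  expect_false(any(feats$residue %in% c(1, 6)))

  spec <- small_spec()
  fens <- make_feature_ensemble(spec)
  expect_identical(featurize_ensemble(fens), fens$features)
})

test_that("a missing amide H is reconstructed geometrically or errors when disabled", {
  f <- tempfile(fileext = ".pdb")
  writeLines(make_toy_pdb(8, "helix"), f)
  frame <- read_ensemble_pdb(f, "X")$coords[[1]]
  noH <- frame[frame$elety != "H", ]
  expect_error(compute_hbonds(noH, 5, reconstruct_H = FALSE), "reconstruction")
  expect_silent(nh <- compute_hbonds(noH, 5, reconstruct_H = TRUE))
  expect_true(nh >= 0)
})
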