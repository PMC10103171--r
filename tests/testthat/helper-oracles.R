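# Independent brute-force oracles and small fixtures shared across the
# suite. The oracles deliberately use explicit scalar loops, separate
# from the package's vectorized implementations.

# all-pairs heavy-atom contact count around the amide N
oracle_contacts <- function(frame, residue, cutoff, window) {
  nrow_f <- nrow(frame)
  ni <- which(frame$resno == residue & frame$elety == "N")[1]
  count <- 0L
  for (i in seq_len(nrow_f)) {
    if (frame$element[i] %in% c("H", "D")) next
    if (abs(frame$resno[i] - residue) <= window) next
    d2 <- (frame$x[i] - frame$x[ni])^2 + (frame$y[i] - frame$y[ni])^2 +
      (frame$z[i] - frame$z[ni])^2
    if (d2 <= cutoff^2) count <- count + 1L
  }
  count
}

# all-pairs O-acceptor count around the amide H
oracle_hbonds <- function(frame, residue, cutoff) {
  hi <- which(frame$resno == residue & frame$elety %in% c("H", "HN"))[1]
  count <- 0L
  for (i in seq_len(nrow(frame))) {
    if (frame$element[i] != "O") next
    if (frame$resno[i] == residue) next
    d2 <- (frame$x[i] - frame$x[hi])^2 + (frame$y[i] - frame$y[hi])^2 +
      (frame$z[i] - frame$z[hi])^2
    if (d2 <= cutoff^2) count <- count + 1L
  }
  count
}

# explicit-loop recomputation of peptide deuterated fractions from raw
# features: ensemble-average lnPF, EX2 residue deuteration, unweighted
# peptide mean skipping the first residue
oracle_peptide_D <- function(features, weights, beta_C, beta_H, rates,
                             peptides, exposures, skip = 1L) {
  frames <- unique(features$frame_id)
  out <- data.frame()
  for (p in seq_len(nrow(peptides))) {
    span <- (peptides$start[p] + skip):peptides$end[p]
    span <- span[span %in% features$residue &
                   span %in% as.integer(names(rates))]
    for (t in exposures) {
      ds <- numeric(0)
      for (r in span) {
        lnpf <- 0
        for (j in seq_along(frames)) {
          row <- features[features$frame_id == frames[j] &
                            features$residue == r, ]
          lnpf <- lnpf + weights[j] * (beta_C * row$N_C + beta_H * row$N_H)
        }
        k <- as.numeric(rates[as.character(r)])
        ds <- c(ds, 1 - exp(-k * (t / 60) / exp(lnpf)))
      }
      out <- rbind(out, data.frame(peptide_id = peptides$peptide_id[p],
                                   exposure_s = t, D = mean(ds)))
    }
  }
  out
}

# scalar-loop intrinsic-rate calculator, coded independently of the
# package's vectorized version (same published reference constants)
oracle_kint <- function(sequence, pD = 7.4, temperature_K = 298) {
  adj <- list(
    A = c(0, 0, 0, 0), R = c(-0.59, -0.32, 0.08, 0.22),
    N = c(-0.58, -0.13, 0.49, 0.32), D = c(0.9, 0.58, 0.1, -0.18),
    C = c(-0.54, -0.46, 0.62, 0.55), Q = c(-0.47, -0.27, 0.06, 0.2),
    E = c(-0.9, 0.31, -0.11, -0.15), G = c(-0.22, 0.22, 0.27, 0.17),
    H = c(-0.8, -0.51, 0.8, 0.83), I = c(-0.91, -0.59, -0.73, -0.23),
    L = c(-0.57, -0.13, -0.58, -0.21), K = c(-0.56, -0.29, -0.04, 0.12),
    M = c(-0.64, -0.28, -0.01, 0.11), F = c(-0.52, -0.43, -0.24, 0.06),
    P = c(0, -0.19, 0, -0.24), S = c(-0.44, -0.39, 0.37, 0.3),
    T = c(-0.79, -0.47, -0.07, 0.2), W = c(-0.4, -0.44, -0.41, -0.11),
    Y = c(-0.41, -0.37, -0.27, 0.05), V = c(-0.74, -0.3, -0.7, -0.14))
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  Rg <- 0.0019872
  arrh <- function(Ea) exp(-Ea / Rg * (1 / temperature_K - 1 / 293))
  out <- numeric(0)
  for (i in 2:n) {
    if (aa[i] == "P") next
    la <- adj[[aa[i]]][1] + adj[[aa[i - 1]]][2]
    lb <- adj[[aa[i]]][3] + adj[[aa[i - 1]]][4]
    if (i == 2) { la <- la - 1.32; lb <- lb + 1.62 }
    if (i == n) { la <- la + 0.96; lb <- lb - 1.80 }
    ka <- 10^(2.04 + la - pD) * arrh(14)
    kb <- 10^(10.36 + lb + pD - 15.05) * arrh(17)
    kw <- 10^(-1.5 + lb) * arrh(19)
    out[as.character(i)] <- ka + kb + kw
  }
  out
}

# Exhaustive simplex grid search over the reweighting objective for
# 2- or 3-frame ensembles. Evaluates the forward model and objective
# directly from the definitions (independent of the package's
# optimizer); returns the misfit and entropy terms per grid point so
# several gammas can reuse one sweep.
oracle_grid_setup <- function(features, rates, betas, target, peptides,
                              w0, step = 1e-3, skip = 1L) {
  frames <- unique(features$frame_id)
  residues <- sort(unique(features$residue))
  n <- length(frames)
  B <- matrix(0, n, length(residues))
  for (j in seq_len(n)) for (r in seq_along(residues)) {
    row <- features[features$frame_id == frames[j] &
                      features$residue == residues[r], ]
    B[j, r] <- betas$beta_C * row$N_C + betas$beta_H * row$N_H
  }
  k <- as.numeric(rates[as.character(residues)])
  cells <- aggregate(uptake ~ peptide_id + exposure_s, data = target,
                     FUN = mean)

  g1 <- seq(0, 1, by = step)
  if (n == 2) {
    W <- cbind(g1, 1 - g1)
  } else if (n == 3) {
    W <- do.call(rbind, lapply(g1, function(w1)
      cbind(w1, g2 <- seq(0, 1 - w1, by = step), 1 - w1 - g2)))
    W[, 3][abs(W[, 3]) < 1e-12] <- 0
  } else stop("oracle supports 2 or 3 frames")

  L <- W %*% B                    # grid x residues
  ssr <- numeric(nrow(W))
  for (ci in seq_len(nrow(cells))) {
    pi <- match(cells$peptide_id[ci], peptides$peptide_id)
    span <- (peptides$start[pi] + skip):peptides$end[pi]
    ridx <- match(intersect(span, residues), residues)
    t_min <- cells$exposure_s[ci] / 60
    D <- rowMeans(1 - exp(-sweep(exp(-L[, ridx, drop = FALSE]), 2,
                                 k[ridx] * t_min, `*`)))
    ssr <- ssr + (D - cells$uptake[ci])^2
  }
  logw <- ifelse(W > 0, log(sweep(W, 2, w0, `/`)), 0)
  kl <- rowSums(W * logw)
  list(W = W, ssr = ssr, kl = kl)
}

oracle_grid_reweight <- function(setup, gamma) {
  val <- gamma * 0.5 * setup$ssr + setup$kl
  i <- which.min(val)
  list(w = as.numeric(setup$W[i, ]), value = val[i])
}

# small fast synthetic study for unit tests
small_spec <- function(seed = 42L, ...) {
  synthetic_spec(n_residues = 20L, n_frames = 10L, seed = seed, ...)
}

# tiny normalized target + features for reweighting tests: nf frames,
# 5 competent residues, 2 peptides, 2 exposures
tiny_problem <- function(nf = 2, seed = 3L) {
  set.seed(seed)
  residues <- 2:6
  features <- expand.grid(frame_id = sprintf("f%d", seq_len(nf)),
                          residue = residues, KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
  features$N_C <- rpois(nrow(features), 6) + 2 * as.integer(
    factor(features$frame_id))
  features$N_H <- rbinom(nrow(features), 2, 0.5)
  features <- features[order(features$frame_id, features$residue), ]
  peptides <- peptide_map(c("pep1", "pep2"), c(2L, 4L), c(4L, 6L),
                          c("AAA", "AAA"))
  rates <- structure(setNames(rep(c(50, 200), length.out = 5), residues),
                     class = "intrinsic_rates")
  list(features = features, peptides = peptides, rates = rates,
       exposures = c(30, 300))
}

# normalized uptake_table from a prediction grid (one replicate)
as_target <- function(pred, peptides, state = "target") {
  uptake_table(
    data.frame(peptide_id = pred$peptide_id, state = state,
               exposure_s = pred$exposure_s, replicate = 1L,
               uptake = pred$D, stringsAsFactors = FALSE),
    peptides, normalized = TRUE)
}
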