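# Self-contained synthetic inputs emulating a two-state (OF/IF)
# transporter HDX-MS study: per-state per-residue feature statistics,
# toy multi-model PDBs with known contact geometry, and replicate
# uptake tables with a MaxD control and known mixture fractions.

DEFAULT_SEQ60 <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQAPILSRVGDGTQDNLSGAEKAVQVKVK"

#' Specification of a synthetic two-state HDX-MS study
#'
#' Defines the statistical structure the analysis assumes: two
#' conformational states with block-wise distinct per-residue contact
#' rates (`lambda_C`, Poisson means) and hydrogen-bond probabilities
#' (`p_H`, per bond, two bonds max), mirroring an alternating-access
#' transporter whose extracellular face is open (weakly protected) in
#' one state and closed in the other. Defaults: 60 residues, 100
#' frames per state, truth 80/20 OF/IF, 3 replicates, exposures
#' \{30, 300, 3600\} s, replicate noise SD 0.01 on normalized uptake.
#'
#' @param n_residues protein length (default 60).
#' @param sequence one-letter sequence of length `n_residues`.
#' @param n_frames frames per state.
#' @param states state labels (first label = the `open-extracellular`
#'   state).
#' @param true_mixture named per-state fractions summing to 1.
#' @param noise_sd replicate noise SD on the normalized-uptake scale.
#' @param replicates replicate measurements per cell.
#' @param exposures labeling times in seconds.
#' @param lambda_open,lambda_closed,lambda_core Poisson contact means
#'   for open-face, closed-face and core residue blocks.
#' @param p_open,p_closed,p_core per-bond H-bond probabilities for the
#'   same blocks.
#' @param seed integer RNG seed; all generators are pure functions of
#'   (spec, seed).
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_residues = 60L,
                           sequence = substr(DEFAULT_SEQ60, 1, n_residues),
                           n_frames = 100L,
                           states = c("OF", "IF"),
                           true_mixture = c(OF = 0.8, IF = 0.2),
                           noise_sd = 0.01,
                           replicates = 3L,
                           exposures = c(30, 300, 3600),
                           lambda_open = 6, lambda_closed = 13,
                           lambda_core = 10,
                           p_open = 0.4, p_closed = 0.85, p_core = 0.7,
                           seed = 1L) {
  stopifnot(nchar(sequence) == n_residues, length(states) == 2,
            setequal(names(true_mixture), states),
            abs(sum(true_mixture) - 1) < 1e-9,
            noise_sd >= 0, replicates >= 1, all(exposures > 0),
            lambda_open >= 0, lambda_closed >= 0, lambda_core >= 0,
            p_open >= 0, p_open <= 1, p_closed >= 0, p_closed <= 1,
            p_core >= 0, p_core <= 1)
  n <- as.integer(n_residues)
  res <- seq_len(n)
  third <- max(2L, floor(n / 3))
  block <- ifelse(res <= third, "extra",
                  ifelse(res > n - third, "intra", "core"))
  # mild deterministic per-residue modulation so residues differ
  modC <- 1 + 0.15 * sin(res)
  modH <- pmin(1, pmax(0, 1 + 0.10 * sin(res + 1)))
  prof <- function(open_face) {
    lam <- ifelse(block == "core", lambda_core,
                  ifelse(block == open_face, lambda_open, lambda_closed))
    ph <- ifelse(block == "core", p_core,
                 ifelse(block == open_face, p_open, p_closed))
    list(lambda_C = lam * modC, p_H = pmin(1, ph * modH))
  }
  profiles <- stats::setNames(list(prof("extra"), prof("intra")), states)
  structure(list(
    n_residues = n, sequence = toupper(sequence), n_frames = as.integer(n_frames),
    states = states, true_mixture = true_mixture[states],
    noise_sd = noise_sd, replicates = as.integer(replicates),
    exposures = as.numeric(exposures), profiles = profiles,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

# exchange-competent residues of a spec: drop residue 1 and prolines
competent_residues <- function(spec) {
  aa <- strsplit(spec$sequence, "")[[1]]
  setdiff(which(aa != "P"), 1L)
}

#' Generate a feature-bearing synthetic ensemble
#'
#' Per frame and exchange-competent residue, draws
#' `N_C ~ Poisson(lambda_C[state][residue])` and
#' `N_H ~ Binomial(2, p_H[state][residue])`. Frames are labeled
#' `<state>_<index>`; initial weights are uniform, so equal frame
#' counts give the 50:50 candidate mixture used for reweighting.
#'
#' @param spec a [synthetic_spec()].
#' @return a feature-bearing [hdx_ensemble()].
#' @export
make_feature_ensemble <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  res <- competent_residues(spec)
  with_seed(spec$seed, {
    tabs <- lapply(spec$states, function(s) {
      lam <- spec$profiles[[s]]$lambda_C[res]
      ph <- spec$profiles[[s]]$p_H[res]
      ids <- sprintf("%s_%03d", s, seq_len(spec$n_frames))
      data.frame(
        frame_id = rep(ids, each = length(res)),
        residue = rep(res, times = spec$n_frames),
        N_C = stats::rpois(length(res) * spec$n_frames, rep(lam, spec$n_frames)),
        N_H = stats::rbinom(length(res) * spec$n_frames, 2L,
                            rep(ph, spec$n_frames)),
        stringsAsFactors = FALSE
      )
    })
    features <- do.call(rbind, tabs)
    hdx_ensemble(
      frame_id = unique(features$frame_id),
      state = rep(spec$states, each = spec$n_frames),
      features = features
    )
  })
}

#' Weights realizing the spec's true mixture over its frames
#'
#' Uniform within each state, per-state sums equal to `true_mixture`.
#' @param spec a [synthetic_spec()].
#' @export
true_mixture_weights <- function(spec) {
  rep(spec$true_mixture / spec$n_frames, each = spec$n_frames)
}

#' Deterministic peptide map tiling the synthetic protein
#'
#' Overlapping peptides (lengths cycling 6-12, overlap ~5) covering
#' residues 1..n, as a proteolytic digest would.
#' @param spec a [synthetic_spec()].
#' @export
make_peptide_map <- function(spec) {
  lens <- c(8L, 10L, 7L, 12L, 9L, 6L, 11L)
  start <- 1L
  k <- 0L
  rows <- list()
  while (start <= spec$n_residues - 3L) {
    len <- lens[k %% length(lens) + 1L]
    end <- min(start + len - 1L, spec$n_residues)
    rows[[length(rows) + 1L]] <- c(start, end)
    start <- start + max(2L, len - 6L)
    k <- k + 1L
  }
  st <- vapply(rows, `[`, integer(1), 1)
  en <- vapply(rows, `[`, integer(1), 2)
  peptide_map(sprintf("p%02d_%02d", st, en), st, en,
              substring(spec$sequence, st, en))
}

#' Synthetic target uptake tables with known ground truth
#'
#' Computes noiseless peptide deuteration under the spec's true
#' mixture via the forward model, converts fractions to daltons with a
#' static per-peptide back-exchange retention factor (drawn once,
#' uniform 0.6-0.9, as a quench/LC loss that MaxD normalization
#' cancels), and emits replicate raw tables plus a consistent MaxD
#' control with Gaussian replicate noise of SD `noise_sd` on the
#' normalized scale.
#'
#' @param spec a [synthetic_spec()].
#' @param betas a [beta_params()] used as ground truth.
#' @param rates optional [intrinsic_rates()]; default computed from
#'   the spec sequence at pD 7.4, 298 K.
#' @param state_label state name for the raw table (default "target").
#' @return list: `raw` and `maxd` ([uptake_table()]s in Da),
#'   `peptides`, `ensemble` (the feature ensemble), and `truth`
#'   (list: `mixture`, `weights`, `noiseless` prediction,
#'   `backexchange`, `n_exchangeable`).
#' @export
make_target_uptake <- function(spec, betas = beta_params(), rates = NULL,
                               state_label = "target") {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(rates)) rates <- intrinsic_rates(spec$sequence)
  ens <- make_feature_ensemble(spec)
  peptides <- make_peptide_map(spec)
  w_true <- true_mixture_weights(spec)
  pred <- predict_peptide_uptake(ens$features, w_true, betas, rates,
                                 peptides, spec$exposures)
  res_have <- sort(unique(ens$features$residue))
  n_ex <- vapply(seq_len(nrow(peptides)), function(p)
    length(intersect((peptides$start[p] + 1L):peptides$end[p], res_have)),
    integer(1))
  names(n_ex) <- peptides$peptide_id

  with_seed(spec$seed + 1000L, {
    bx <- stats::runif(nrow(peptides), 0.6, 0.9)
    names(bx) <- peptides$peptide_id
    scale_Da <- n_ex * bx  # peptide-wise Da per unit deuterated fraction

    raw_rows <- do.call(rbind, lapply(seq_len(spec$replicates), function(rep) {
      d <- pred
      sc <- scale_Da[d$peptide_id]
      data.frame(peptide_id = d$peptide_id, state = state_label,
                 exposure_s = d$exposure_s, replicate = rep,
                 uptake = d$D * sc + stats::rnorm(nrow(d), 0, spec$noise_sd * sc),
                 stringsAsFactors = FALSE)
    }))
    maxd_rows <- do.call(rbind, lapply(seq_len(spec$replicates), function(rep) {
      sc <- as.numeric(scale_Da)
      data.frame(peptide_id = peptides$peptide_id, state = "MaxD",
                 exposure_s = max(spec$exposures), replicate = rep,
                 uptake = sc + stats::rnorm(length(sc), 0, spec$noise_sd * sc),
                 stringsAsFactors = FALSE)
    }))
    list(
      raw = uptake_table(raw_rows, peptides, normalized = FALSE),
      maxd = uptake_table(maxd_rows, peptides, normalized = FALSE),
      peptides = peptides,
      ensemble = ens,
      truth = list(mixture = spec$true_mixture, weights = w_true,
                   noiseless = pred, backexchange = bx,
                   n_exchangeable = n_ex)
    )
  })
}

# ---------------------------------------------------------------------
# Toy PDB generator with known contact/H-bond geometry

#' Multi-model toy PDB text with known feature geometry
#'
#' Builds ideal-geometry conformers for the structure-feature tests:
#' `"helix"` places each residue on a helix (rise 1.5 A, twist 100
#' degrees) with the carbonyl O of residue i exactly 2.3 A from the
#' amide H of residue i+4, so every residue from 5 on has N_H = 1 by
#' construction; `"extended"` spaces residues 3.8 A apart along the
#' axis with all O...H distances > 2.4 A, so N_H = 0 everywhere.
#' Hydrogens are included (prolines, if any, carry none). Additional
#' models are rigid-body rotated/translated copies, which leaves every
#' feature count unchanged.
#'
#' @param n_residues chain length (<= 50).
#' @param conformer `"helix"` or `"extended"`.
#' @param n_models number of MODEL blocks to emit.
#' @param proline_at residue numbers written as proline.
#' @return character vector of PDB lines.
#' @export
make_toy_pdb <- function(n_residues = 12L, conformer = c("helix", "extended"),
                         n_models = 1L, proline_at = integer(0)) {
  conformer <- match.arg(conformer)
  stopifnot(n_residues >= 2, n_residues <= 50)
  n <- as.integer(n_residues)
  resnames <- ifelse(seq_len(n) %in% proline_at, "PRO", "ALA")

  atoms <- list()
  add <- function(name, resno, pos, element) {
    atoms[[length(atoms) + 1L]] <<- list(name = name, resno = resno,
                                         pos = pos, element = element)
  }
  if (conformer == "helix") {
    r <- 2.3; rise <- 1.5; tw <- 100 * pi / 180
    npos <- function(i) c(r * cos(tw * i), r * sin(tw * i), rise * i)
    hpos <- function(i) c((r + 1.01) * cos(tw * i),
                          (r + 1.01) * sin(tw * i), rise * i)
    for (i in seq_len(n)) {
      add("N", i, npos(i), "N")
      if (resnames[i] != "PRO") add("H", i, hpos(i), "H")
      add("CA", i, c((r + 0.8) * cos(tw * i + 0.35),
                     (r + 0.8) * sin(tw * i + 0.35), rise * i + 0.5), "C")
      o <- if (i + 4L <= n && resnames[i + 4L] != "PRO") {
        # exactly 2.3 A inside the i+4 amide H along the radial direction
        c((r + 1.01 - 2.3) * cos(tw * (i + 4)),
          (r + 1.01 - 2.3) * sin(tw * (i + 4)), rise * (i + 4))
      } else { # park the tail carbonyls far from every amide H
        c((r + 5) * cos(tw * i), (r + 5) * sin(tw * i), rise * i)
      }
      add("C", i, o + c(0, 0, 1.0), "C")
      add("O", i, o, "O")
    }
  } else {
    for (i in seq_len(n)) {
      x <- 3.8 * i
      add("N", i, c(x, 0, 0), "N")
      if (resnames[i] != "PRO") add("H", i, c(x, -1.01, 0), "H")
      add("CA", i, c(x + 1.2, 0.8, 0), "C")
      add("C", i, c(x + 2.4, 0, 0), "C")
      add("O", i, c(x + 2.4, 1.23, 0), "O")
    }
  }

  rot <- function(k) { # deterministic per-model rigid transform
    a <- 0.7 * k; b <- 0.4 * k; c2 <- 1.1 * k
    Rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, TRUE)
    Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3, TRUE)
    list(R = Rz %*% Ry, t = c(5 * k, -3 * k, c2))
  }
  fmt_atom <- function(serial, name, resname, resno, pos, element) {
    nm <- if (nchar(name) < 4) paste0(" ", name) else name
    sprintf("ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            serial, nm, resname, resno, pos[1], pos[2], pos[3], element)
  }
  lines <- character(0)
  for (m in seq_len(n_models)) {
    tr <- rot(m - 1L)
    if (n_models > 1L) lines <- c(lines, sprintf("MODEL     %4d", m))
    for (s in seq_along(atoms)) {
      a <- atoms[[s]]
      p <- as.numeric(tr$R %*% a$pos + tr$t)
      lines <- c(lines, fmt_atom(s, a$name, resnames[a$resno], a$resno, p,
                                 a$element))
    }
    lines <- c(lines, "TER")
    if (n_models > 1L) lines <- c(lines, "ENDMDL")
  }
  c(lines, "END")
}
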