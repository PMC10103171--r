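# Quantification of the reweighted ensemble: state populations,
# subsampling uncertainty, reweighted observable distributions,
# per-peptide RMSE and peptide-exclusion robustness.

#' Fractional state populations from frame weights
#'
#' The fractional population of a conformational state is the summed
#' final weight of the frames carrying its label.
#'
#' @param weights per-frame weights on the simplex.
#' @param labels per-frame state labels.
#' @return data.frame of class `population_estimate` with columns
#'   `state`, `fraction` (and `sd`, `NA` here, filled by
#'   [subsample_uncertainty()]).
#' @export
populations <- function(weights, labels) {
  if (length(weights) != length(labels))
    stop_hdx("dimension", "one label per weight is required")
  if (any(is.na(labels)) || !length(labels))
    stop_hdx("validation", "unknown (missing) state label")
  if (abs(sum(weights) - 1) > 1e-9)
    stop_hdx("validation", "weights must sum to 1")
  fr <- tapply(weights, labels, sum)
  structure(
    data.frame(state = names(fr), fraction = as.numeric(fr),
               sd = NA_real_, stringsAsFactors = FALSE),
    n_subsamples = 0L,
    class = c("population_estimate", "data.frame"))
}

#' Population uncertainty by systematic subsampling
#'
#' Partitions the candidate frames into `k` interleaved subsets
#' (stride `k`, offsets `0..k-1`), reruns the full gamma-scan
#' reweighting on each subset with identical settings, and reports the
#' mean and standard deviation of each state's fractional population
#' over the `k` independent analyses (default `k = 3`). Subsets missing
#' a state entirely are skipped with a warning. A seeded random
#' partition is available as an alternative to the systematic one.
#'
#' @param features feature table for the full candidate ensemble.
#' @param labels per-frame state labels, aligned with the frame order
#'   of `features`.
#' @param rates,betas,target,peptides,gammas,W_target,temperature_K,first_residue_skip,control
#'   passed to [gamma_scan()].
#' @param k number of subsamples (>= 2).
#' @param scheme `"systematic"` (interleaved, deterministic) or
#'   `"random"` (seeded random partition).
#' @param seed RNG seed for `scheme = "random"`.
#' @return a `population_estimate` with per-state mean fraction and SD;
#'   attribute `n_subsamples`; attribute `runs` holds the per-subset
#'   population tables.
#' @export
subsample_uncertainty <- function(features, labels, rates, betas, target,
                                  peptides = peptides_of(target),
                                  k = 3L, gammas = default_gamma_grid(),
                                  W_target = 5, temperature_K = 298,
                                  first_residue_skip = 1L,
                                  scheme = c("systematic", "random"),
                                  seed = 1L, control = list()) {
  scheme <- match.arg(scheme)
  stopifnot(k >= 2)
  frames <- unique(features$frame_id)
  n <- length(frames)
  if (length(labels) != n)
    stop_hdx("dimension", "one state label per frame is required")
  part <- if (scheme == "systematic") (seq_len(n) - 1L) %% k
  else with_seed(seed, sample(rep(seq_len(k) - 1L, length.out = n)))

  runs <- list()
  for (off in 0:(k - 1L)) {
    sub_frames <- frames[part == off]
    sub_labels <- labels[part == off]
    if (length(unique(sub_labels)) < length(unique(labels))) {
      warning(sprintf("subset %d lacks a state; skipped", off + 1L))
      next
    }
    sub_feat <- features[features$frame_id %in% sub_frames, , drop = FALSE]
    rw <- gamma_scan(sub_feat, rates, betas, target, peptides,
                     gammas = gammas, W_target = W_target,
                     state = sub_labels, temperature_K = temperature_K,
                     first_residue_skip = first_residue_skip,
                     control = control)
    runs[[length(runs) + 1L]] <- populations(rw$weights, sub_labels)
  }
  if (!length(runs))
    stop_hdx("validation", "no usable subsets for subsampling")
  states <- sort(unique(labels))
  fr <- vapply(runs, function(p) p$fraction[match(states, p$state)],
               numeric(length(states)))
  fr <- matrix(fr, nrow = length(states))
  structure(
    data.frame(state = states,
               fraction = rowMeans(fr),
               sd = apply(fr, 1, stats::sd),
               stringsAsFactors = FALSE),
    n_subsamples = length(runs), runs = runs,
    class = c("population_estimate", "data.frame"))
}

#' Reweighted distribution of a per-frame observable
#'
#' Weighted histogram of a scalar observable (e.g. an interdomain
#' centroid distance in Angstrom): each bin's mass is the summed weight
#' of the frames falling in it, so masses sum to 1.
#'
#' @param observable one scalar per frame.
#' @param weights per-frame weights on the simplex.
#' @param breaks histogram bin edges covering the full data range.
#' @return data.frame `bin_lo, bin_hi, mass`.
#' @export
reweighted_distribution <- function(observable, weights, breaks) {
  if (length(observable) != length(weights))
    stop_hdx("dimension", "one weight per observable value is required")
  if (min(observable) < min(breaks) || max(observable) > max(breaks))
    stop_hdx("validation", "breaks do not cover the observable range")
  bins <- cut(observable, breaks, include.lowest = TRUE, labels = FALSE)
  mass <- vapply(seq_len(length(breaks) - 1L),
                 function(b) sum(weights[bins == b]), numeric(1))
  data.frame(bin_lo = utils::head(breaks, -1),
             bin_hi = utils::tail(breaks, -1), mass = mass)
}

#' Interdomain centroid distance per frame
#'
#' Distance between the centroids of two residue groups' heavy atoms,
#' one value per frame; a generic "openness" observable for
#' alternating-access transporters.
#'
#' @param ensemble a coordinate-bearing [hdx_ensemble()].
#' @param group_a,group_b integer vectors of residue numbers.
#' @return numeric vector, Angstrom, one per frame.
#' @export
interdomain_distance <- function(ensemble, group_a, group_b) {
  stopifnot(inherits(ensemble, "hdx_ensemble"), !is.null(ensemble$coords))
  vapply(ensemble$coords, function(f) {
    heavy <- !is_hydrogen(f$element)
    ca <- colMeans(f[heavy & f$resno %in% group_a, c("x", "y", "z")])
    cb <- colMeans(f[heavy & f$resno %in% group_b, c("x", "y", "z")])
    sqrt(sum((ca - cb)^2))
  }, numeric(1))
}

#' Per-peptide RMSE before and after reweighting
#'
#' Root-mean-square error over exposures between predicted and target
#' deuterated fractions, per peptide, for the candidate-ensemble
#' prediction before and after reweighting; sorted descending by the
#' after-reweighting RMSE to flag error-prone peptides.
#'
#' @param pred_before,pred_after data.frames
#'   `peptide_id, exposure_s, D` on the same grid.
#' @param target a normalized [uptake_table()] (replicates are averaged
#'   per cell).
#' @return data.frame `peptide_id, rmse_before, rmse_after`.
#' @export
peptide_rmse <- function(pred_before, pred_after, target) {
  cells <- uptake_cells(target)
  key <- function(d) paste(d$peptide_id, d$exposure_s)
  kb <- key(pred_before); ka <- key(pred_after); kt <- key(cells)
  if (!setequal(kb, kt) || !setequal(ka, kt))
    stop_hdx("validation", "prediction and target grids do not match")
  cells$before <- pred_before$D[match(kt, kb)]
  cells$after <- pred_after$D[match(kt, ka)]
  rmse <- function(x, y) sqrt(mean((x - y)^2))
  out <- do.call(rbind, lapply(split(cells, cells$peptide_id), function(s)
    data.frame(peptide_id = s$peptide_id[1],
               rmse_before = rmse(s$before, s$uptake),
               rmse_after = rmse(s$after, s$uptake),
               stringsAsFactors = FALSE)))
  out <- out[order(-out$rmse_after), ]
  rownames(out) <- NULL
  out
}

#' Robustness of populations to peptide exclusion
#'
#' Reruns the full gamma-scan reweighting with the stated peptides
#' removed from the target and reports the resulting populations next
#' to the original, for comparison heatmaps of error-prone peptides'
#' influence.
#'
#' @inheritParams subsample_uncertainty
#' @param exclude character vector of peptide_ids to omit.
#' @return list with elements `original` and `excluded`
#'   (`population_estimate`s) and `excluded_peptides`.
#' @export
exclusion_robustness <- function(features, labels, rates, betas, target,
                                 exclude,
                                 peptides = peptides_of(target),
                                 gammas = default_gamma_grid(), W_target = 5,
                                 temperature_K = 298,
                                 first_residue_skip = 1L, control = list()) {
  pm <- peptides_of(target)
  bad <- setdiff(exclude, pm$peptide_id)
  if (length(bad))
    stop_hdx("validation", "peptide(s) not in target: %s",
             paste(bad, collapse = ", "))
  keep <- setdiff(pm$peptide_id, exclude)
  if (!length(keep))
    stop_hdx("validation", "exclusion empties the target")
  if (length(keep) == 1L)
    warning("only one peptide left after exclusion; fit is fragile")
  reduced <- uptake_table(target[target$peptide_id %in% keep, , drop = FALSE],
                          pm[pm$peptide_id %in% keep, , drop = FALSE],
                          normalized = is_normalized(target))
  run <- function(tgt) {
    rw <- gamma_scan(features, rates, betas, tgt, gammas = gammas,
                     W_target = W_target, state = labels,
                     temperature_K = temperature_K,
                     first_residue_skip = first_residue_skip,
                     control = control)
    populations(rw$weights, labels)
  }
  list(original = run(target), excluded = run(reduced),
       excluded_peptides = exclude)
}
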