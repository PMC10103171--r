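# Forward model: weighted ensemble features -> per-residue protection
# factors -> time-dependent residue deuteration -> peptide-level
# deuterated fractions; plus MaxD normalization and peptide filtering
# of experimental tables.

#' Scaling parameters of the protection-factor model
#'
#' `ln PF_i = < beta_C * N_C(i) + beta_H * N_H(i) >_w` with defaults
#' beta_C = 0.35 and beta_H = 2.0 from the original empirical
#' parameterization against soluble-protein HDX data; [fit_betas()]
#' re-optimizes them for a specific dataset.
#'
#' @param beta_C non-negative scaling of the heavy-atom contact count.
#' @param beta_H non-negative scaling of the hydrogen-bond count.
#' @export
beta_params <- function(beta_C = 0.35, beta_H = 2.0) {
  stopifnot(is.finite(beta_C), is.finite(beta_H), beta_C >= 0, beta_H >= 0)
  structure(list(beta_C = beta_C, beta_H = beta_H), class = "beta_params")
}

# internal: features long table -> list(frame_id, residues, NC, NH)
# where NC/NH are frames x residues matrices in frame/residue order.
feature_matrices <- function(features) {
  frames <- unique(features$frame_id)
  residues <- sort(unique(features$residue))
  fi <- match(features$frame_id, frames)
  ri <- match(features$residue, residues)
  if (anyDuplicated(cbind(fi, ri)))
    stop_hdx("validation", "duplicate (frame, residue) feature rows")
  if (nrow(features) != length(frames) * length(residues))
    stop_hdx("structural",
             "feature table is not complete over frames x residues")
  NC <- matrix(0, length(frames), length(residues))
  NH <- matrix(0, length(frames), length(residues))
  NC[cbind(fi, ri)] <- features$N_C
  NH[cbind(fi, ri)] <- features$N_H
  list(frame_id = frames, residues = residues, NC = NC, NH = NH)
}

#' Ensemble-averaged log protection factors
#'
#' `lnPF_i = sum_j w_j (beta_C N_C(i,j) + beta_H N_H(i,j))`: the
#' ensemble average is taken over the exponent, so frame weights act on
#' the per-frame linear combination of features.
#'
#' @param features feature table (`frame_id,residue,N_C,N_H`), complete
#'   over frames x residues.
#' @param weights per-frame weights aligned with the order frames first
#'   appear in `features`; must sum to 1.
#' @param betas a [beta_params()].
#' @return data.frame of class `protection_factors` with columns
#'   `residue`, `lnPF`.
#' @export
protection_factors <- function(features, weights, betas = beta_params()) {
  fm <- feature_matrices(features)
  if (length(weights) != length(fm$frame_id))
    stop_hdx("dimension", "got %d weights for %d frames",
             length(weights), length(fm$frame_id))
  if (abs(sum(weights) - 1) > 1e-9)
    stop_hdx("validation", "weights must sum to 1")
  lnpf <- as.numeric(crossprod(weights,
                               betas$beta_C * fm$NC + betas$beta_H * fm$NH))
  structure(data.frame(residue = fm$residues, lnPF = lnpf),
            class = c("protection_factors", "data.frame"))
}

#' Per-residue deuteration versus exposure time
#'
#' EX2 kinetics with the protected rate `k_int / PF`:
#' `D_i(t) = 1 - exp(-k_int_i * t / PF_i)`, `PF_i = exp(lnPF_i)`.
#'
#' @param pf a [protection_factors()] table.
#' @param rates an [intrinsic_rates()] vector (per minute) covering
#'   every residue in `pf`.
#' @param exposures exposure times in seconds (non-negative).
#' @return data.frame `residue, exposure_s, D`.
#' @export
residue_deuteration <- function(pf, rates, exposures) {
  exposures <- as.numeric(exposures)
  if (any(exposures < 0))
    stop_hdx("validation", "exposures must be non-negative")
  miss <- setdiff(pf$residue, as.integer(names(rates)))
  if (length(miss))
    stop_hdx("validation", "no intrinsic rate for residue(s): %s",
             paste(miss, collapse = ", "))
  k <- as.numeric(rates[as.character(pf$residue)])
  grid <- expand.grid(residue = pf$residue, exposure_s = exposures,
                      KEEP.OUT.ATTRS = FALSE)
  kk <- rep(k, times = length(exposures))
  lnpf <- rep(pf$lnPF, times = length(exposures))
  grid$D <- 1 - exp(-kk * (grid$exposure_s / 60) * exp(-lnpf))
  grid
}

#' Peptide-level deuterated fractions
#'
#' Per peptide and exposure, the unweighted mean of residue deuteration
#' over the peptide's exchange-competent residues: the peptide's first
#' `first_residue_skip` residue(s) are dropped (fast back-exchange) and
#' prolines/residue 1 are already absent from the residue table.
#' Peptides left with no exchange-competent residue are excluded with a
#' warning.
#'
#' @param residue_D output of [residue_deuteration()].
#' @param peptides a [peptide_map()].
#' @param first_residue_skip leading residues of each peptide excluded
#'   from the mean (0-2, default 1).
#' @return data.frame `peptide_id, exposure_s, D` (predicted fraction).
#' @export
peptide_deuteration <- function(residue_D, peptides, first_residue_skip = 1L) {
  stopifnot(first_residue_skip %in% 0:2)
  exposures <- sort(unique(residue_D$exposure_s))
  have <- sort(unique(residue_D$residue))
  out <- lapply(seq_len(nrow(peptides)), function(p) {
    span <- (peptides$start[p] + first_residue_skip):peptides$end[p]
    span <- intersect(span, have)
    if (!length(span)) {
      warning(sprintf("peptide %s has no exchange-competent residues; excluded",
                      peptides$peptide_id[p]))
      return(NULL)
    }
    sub <- residue_D[residue_D$residue %in% span, ]
    d <- tapply(sub$D, sub$exposure_s, mean)
    data.frame(peptide_id = peptides$peptide_id[p],
               exposure_s = as.numeric(names(d)), D = as.numeric(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(match(out$peptide_id, peptides$peptide_id), out$exposure_s), ,
      drop = FALSE]
}

#' One-call prediction of peptide uptake from features
#'
#' Convenience wrapper chaining [protection_factors()],
#' [residue_deuteration()] and [peptide_deuteration()].
#'
#' @inheritParams protection_factors
#' @inheritParams residue_deuteration
#' @inheritParams peptide_deuteration
#' @export
predict_peptide_uptake <- function(features, weights, betas, rates,
                                   peptides, exposures,
                                   first_residue_skip = 1L) {
  pf <- protection_factors(features, weights, betas)
  rd <- residue_deuteration(pf, rates, exposures)
  peptide_deuteration(rd, peptides, first_residue_skip)
}

#' Normalize raw uptake against a maximally deuterated control
#'
#' Divides each raw (Da) uptake value by the peptide's mean MaxD
#' uptake, yielding absolute deuterated fractions in which static
#' back-exchange losses cancel. Values outside \[0, 1\] (noise) are
#' preserved; downstream, [filter_peptides()] removes peptides with
#' negative mean deuteration. Peptides missing from the MaxD table or
#' with non-positive MaxD mean are dropped with a warning.
#'
#' @param raw an [uptake_table()] in Da.
#' @param maxd an [uptake_table()] in Da for the MaxD control.
#' @return a normalized [uptake_table()].
#' @export
normalize_to_maxd <- function(raw, maxd) {
  if (is_normalized(raw))
    stop_hdx("validation", "raw table is already normalized")
  md <- tapply(maxd$uptake, maxd$peptide_id, mean)
  peps <- unique(raw$peptide_id)
  keep <- peps[peps %in% names(md) & md[peps] > 0]
  dropped <- setdiff(peps, keep)
  if (length(dropped))
    warning(sprintf("dropping peptide(s) without usable MaxD: %s",
                    paste(dropped, collapse = ", ")))
  rec <- raw[raw$peptide_id %in% keep, , drop = FALSE]
  rec$uptake <- rec$uptake / as.numeric(md[rec$peptide_id])
  pm <- peptides_of(raw)
  uptake_table(rec, pm[pm$peptide_id %in% keep, , drop = FALSE],
               normalized = TRUE)
}

#' Exclude structurally uncovered and negative-uptake peptides
#'
#' Removes (a) peptides overlapping residues outside `structure_span`
#' (residues unresolved in the candidate structures cannot be
#' predicted) and (b) peptides whose mean normalized deuteration is
#' negative at any exposure (experimental noise). Every exclusion is
#' logged with its reason.
#'
#' @param table a normalized [uptake_table()].
#' @param structure_span integer vector `c(first, last)` of residues
#'   resolvable in the candidate structures.
#' @return the filtered [uptake_table()].
#' @export
filter_peptides <- function(table, structure_span) {
  stopifnot(length(structure_span) == 2, structure_span[1] <= structure_span[2])
  pm <- peptides_of(table)
  drop <- character(0)
  for (p in seq_len(nrow(pm))) {
    id <- pm$peptide_id[p]
    if (pm$start[p] < structure_span[1] || pm$end[p] > structure_span[2]) {
      message(sprintf("excluding peptide %s: outside structure span %d-%d",
                      id, structure_span[1], structure_span[2]))
      drop <- c(drop, id)
      next
    }
    sub <- table[table$peptide_id == id, ]
    mu <- tapply(sub$uptake, sub$exposure_s, mean)
    if (any(mu < 0)) {
      message(sprintf("excluding peptide %s: negative mean deuteration", id))
      drop <- c(drop, id)
    }
  }
  keep <- setdiff(pm$peptide_id, drop)
  if (!length(keep)) warning("all peptides excluded by filtering")
  uptake_table(table[table$peptide_id %in% keep, , drop = FALSE],
               pm[pm$peptide_id %in% keep, , drop = FALSE],
               normalized = is_normalized(table))
}

# internal: collapse an uptake table to per-(peptide, exposure) means,
# in a stable order (peptide map order, then exposure).
uptake_cells <- function(table) {
  pm <- peptides_of(table)
  agg <- stats::aggregate(uptake ~ peptide_id + exposure_s, data = table,
                          FUN = mean)
  agg <- agg[order(match(agg$peptide_id, pm$peptide_id), agg$exposure_s), ]
  rownames(agg) <- NULL
  agg
}
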