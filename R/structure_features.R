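# Per-frame, per-residue amide features: heavy-atom contact counts N_C
# around the amide nitrogen and hydrogen-bond counts N_H at the amide
# hydrogen. These drive the empirical protection-factor model
# ln PF_i = beta_C * N_C(i) + beta_H * N_H(i) (ensemble averaged).

#' Default feature settings
#'
#' `contact_cutoff_A` (6.5) and `hbond_cutoff_A` (2.4) follow the
#' published contact/H-bond parameterization of the empirical
#' protection-factor model; `exclusion_window` excludes residues
#' i-2..i+2 from the contact count.
#'
#' @param contact_cutoff_A heavy-atom contact cutoff around the amide N.
#' @param hbond_cutoff_A O...H distance cutoff for amide hydrogen bonds.
#' @param exclusion_window half-width (in residues) of the window
#'   around residue i whose atoms are excluded from N_C.
#' @param reconstruct_H place a missing amide hydrogen geometrically
#'   (1.01 A from N, opposite the bisector of its bonded heavy atoms).
#' @export
feature_settings <- function(contact_cutoff_A = 6.5, hbond_cutoff_A = 2.4,
                             exclusion_window = 2L, reconstruct_H = TRUE) {
  stopifnot(contact_cutoff_A > 0, hbond_cutoff_A > 0, exclusion_window >= 0)
  list(contact_cutoff_A = contact_cutoff_A, hbond_cutoff_A = hbond_cutoff_A,
       exclusion_window = as.integer(exclusion_window),
       reconstruct_H = isTRUE(reconstruct_H))
}

is_hydrogen <- function(element) element %in% c("H", "D")

amide_exchanges <- function(frame, residue) {
  first <- min(frame$resno)
  if (residue == first) return(FALSE)
  resid <- frame$resid[frame$resno == residue][1]
  !is.na(resid) && resid != "PRO"
}

#' Heavy-atom contact count at an amide nitrogen
#'
#' Counts non-hydrogen atoms within `cutoff` of the amide N of
#' `residue`, excluding every atom belonging to residues within
#' `exclusion_window` of it (itself included). Proline and the
#' protein's first residue carry no exchange-relevant amide and return
#' `NA` with a warning.
#'
#' @param frame one frame's atom data.frame
#'   (`elety,resno,resid,element,x,y,z`).
#' @param residue 1-based residue sequence number.
#' @param cutoff contact cutoff in Angstrom.
#' @param exclusion_window residues i-w..i+w are excluded.
#' @return integer count, or `NA_integer_` for non-exchanging residues.
#' @export
compute_contacts <- function(frame, residue, cutoff = 6.5,
                             exclusion_window = 2L) {
  if (!amide_exchanges(frame, residue)) {
    warning(sprintf("residue %d has no exchange-relevant amide", residue))
    return(NA_integer_)
  }
  nsel <- frame$resno == residue & frame$elety == "N"
  if (!any(nsel))
    stop_hdx("structural", "residue %d lacks a backbone N atom", residue)
  npos <- as.numeric(frame[which(nsel)[1], c("x", "y", "z")])
  cand <- !is_hydrogen(frame$element) &
    abs(frame$resno - residue) > exclusion_window
  if (!any(cand)) return(0L)
  dx <- frame$x[cand] - npos[1]
  dy <- frame$y[cand] - npos[2]
  dz <- frame$z[cand] - npos[3]
  sum(dx * dx + dy * dy + dz * dz <= cutoff^2)
}

# Geometric placement of a missing amide hydrogen: 1.01 A from N along
# the direction opposite the bisector of the N's bonded heavy atoms
# (CA of residue i and C of residue i-1).
reconstruct_amide_h <- function(frame, residue) {
  get_atom <- function(resno, elety) {
    sel <- frame$resno == resno & frame$elety == elety
    if (!any(sel)) return(NULL)
    as.numeric(frame[which(sel)[1], c("x", "y", "z")])
  }
  n <- get_atom(residue, "N")
  ca <- get_atom(residue, "CA")
  cprev <- get_atom(residue - 1L, "C")
  if (is.null(n) || is.null(ca) || is.null(cprev)) return(NULL)
  u1 <- (ca - n) / sqrt(sum((ca - n)^2))
  u2 <- (cprev - n) / sqrt(sum((cprev - n)^2))
  bis <- u1 + u2
  nb <- sqrt(sum(bis^2))
  if (nb < 1e-8) return(NULL)
  n - 1.01 * bis / nb
}

#' Hydrogen-bond count at an amide hydrogen
#'
#' Counts oxygen acceptor atoms within `h_cutoff` of the amide hydrogen
#' of `residue`, excluding atoms of the residue itself. If the frame
#' carries no amide H (common for crystal-derived models) it is placed
#' geometrically when `reconstruct_H` is `TRUE`, otherwise an error is
#' raised. Acceptors are oxygens only (backbone carbonyl and side-chain
#' O); waters are assumed absent from the frame.
#'
#' @inheritParams compute_contacts
#' @param h_cutoff O...H cutoff in Angstrom.
#' @param reconstruct_H place a missing amide H geometrically.
#' @return integer count, or `NA_integer_` for non-exchanging residues.
#' @export
compute_hbonds <- function(frame, residue, h_cutoff = 2.4,
                           reconstruct_H = TRUE) {
  if (!amide_exchanges(frame, residue)) {
    warning(sprintf("residue %d has no exchange-relevant amide", residue))
    return(NA_integer_)
  }
  hsel <- frame$resno == residue & frame$elety %in% c("H", "HN", "D") &
    is_hydrogen(frame$element)
  if (any(hsel)) {
    hpos <- as.numeric(frame[which(hsel)[1], c("x", "y", "z")])
  } else if (reconstruct_H) {
    hpos <- reconstruct_amide_h(frame, residue)
    if (is.null(hpos))
      stop_hdx("feature",
               "cannot reconstruct amide H for residue %d", residue)
  } else {
    stop_hdx("feature",
             "residue %d lacks an amide H and reconstruction is disabled",
             residue)
  }
  cand <- frame$element == "O" & frame$resno != residue
  if (!any(cand)) return(0L)
  dx <- frame$x[cand] - hpos[1]
  dy <- frame$y[cand] - hpos[2]
  dz <- frame$z[cand] - hpos[3]
  sum(dx * dx + dy * dy + dz * dz <= h_cutoff^2)
}

#' Compute the feature table of a structural ensemble
#'
#' One row per (frame, exchange-competent residue): N_C and N_H under
#' the given settings. Prolines and the protein's first residue are
#' excluded (no exchange-relevant backbone amide / instant
#' back-exchange). An ensemble that already carries precomputed
#' features is returned unchanged.
#'
#' @param ensemble an [hdx_ensemble()].
#' @param settings a [feature_settings()] list.
#' @return data.frame with columns `frame_id,residue,N_C,N_H`.
#' @export
featurize_ensemble <- function(ensemble, settings = feature_settings()) {
  stopifnot(inherits(ensemble, "hdx_ensemble"))
  if (!is.null(ensemble$features)) return(ensemble$features)
  if (is.null(ensemble$coords))
    stop_hdx("validation", "ensemble carries neither coordinates nor features")
  res_all <- sort(unique(ensemble$coords[[1]]$resno))
  out <- lapply(seq_along(ensemble$frame_id), function(j) {
    frame <- ensemble$coords[[j]]
    keep <- res_all[vapply(res_all, function(r) amide_exchanges(frame, r),
                           logical(1))]
    data.frame(
      frame_id = ensemble$frame_id[j],
      residue = keep,
      N_C = vapply(keep, function(r)
        compute_contacts(frame, r, settings$contact_cutoff_A,
                         settings$exclusion_window), integer(1)),
      N_H = vapply(keep, function(r)
        compute_hbonds(frame, r, settings$hbond_cutoff_A,
                       settings$reconstruct_H), integer(1)),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' @rdname featurize_ensemble
#' @param features a feature table.
#' @param path output CSV path.
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(features[c("frame_id", "residue", "N_C", "N_H")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname featurize_ensemble
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(frame_id = "character"))
  need <- c("frame_id", "residue", "N_C", "N_H")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_hdx("format", "feature CSV is missing column(s): %s",
             paste(miss, collapse = ", "))
  if (any(df$N_C < 0) || any(df$N_H < 0))
    stop_hdx("validation", "feature counts must be non-negative")
  df
}
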