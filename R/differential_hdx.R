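# Differential HDX between two protein states: the hybrid significance
# test (global confidence-interval threshold on delta-uptake, confirmed
# by a per-cell Welch's t-test) and a per-residue protection summary.

#' Hybrid significance test for differential HDX
#'
#' For every shared (peptide, exposure) cell, computes the uptake
#' difference `state B - state A` and flags it significant when both
#' criteria hold: (1) |delta| exceeds a global threshold
#' `t_crit(alpha, pooled df) * sqrt(s_A^2/n_A + s_B^2/n_B)` built from
#' the pooled per-state replicate variances (99% confidence interval at
#' the default `alpha = 0.01`), and (2) a per-cell Welch's t-test with
#' Welch-Satterthwaite degrees of freedom gives p < alpha. Cells with
#' fewer than two replicates in either state are reported untestable.
#' No multiple-testing correction is applied beyond the conjunction.
#'
#' @param a,b [uptake_table()]s for the two states (same units).
#' @param alpha significance level (default 0.01, i.e. a 99% CI
#'   threshold).
#' @param pool `"global"` pools replicate variances over all cells
#'   (one threshold); `"per_exposure"` pools within each exposure.
#' @return data.frame of class `hybrid_test` with columns `peptide_id,
#'   exposure_s, delta, threshold, welch_p, testable, significant`.
#' @export
hybrid_test <- function(a, b, alpha = 0.01,
                        pool = c("global", "per_exposure")) {
  pool <- match.arg(pool)
  stopifnot(alpha > 0, alpha < 1)
  summarize <- function(x) {
    out <- stats::aggregate(uptake ~ peptide_id + exposure_s, data = x,
                            FUN = function(v) c(n = length(v), m = mean(v),
                                                v = stats::var(v)))
    data.frame(peptide_id = out$peptide_id, exposure_s = out$exposure_s,
               n = out$uptake[, "n"], m = out$uptake[, "m"],
               s2 = out$uptake[, "v"], stringsAsFactors = FALSE)
  }
  sa <- summarize(a)
  sb <- summarize(b)
  cells <- merge(sa, sb, by = c("peptide_id", "exposure_s"),
                 suffixes = c("_a", "_b"))
  if (!nrow(cells))
    stop_hdx("validation", "states share no (peptide, exposure) cells")
  testable <- cells$n_a >= 2 & cells$n_b >= 2

  pooled <- function(sub) {
    dfa <- sum(sub$n_a - 1)
    dfb <- sum(sub$n_b - 1)
    s2a <- sum((sub$n_a - 1) * sub$s2_a) / dfa
    s2b <- sum((sub$n_b - 1) * sub$s2_b) / dfb
    na <- mean(sub$n_a)
    nb <- mean(sub$n_b)
    stats::qt(1 - alpha / 2, dfa + dfb) * sqrt(s2a / na + s2b / nb)
  }
  tcells <- cells[testable, , drop = FALSE]
  if (!nrow(tcells)) {
    warning("no testable cells (need >= 2 replicates per state)")
    cells$threshold <- NA_real_
  } else if (pool == "global") {
    cells$threshold <- pooled(tcells)
  } else {
    th <- vapply(split(tcells, tcells$exposure_s), pooled, numeric(1))
    cells$threshold <- th[as.character(cells$exposure_s)]
  }

  cells$delta <- cells$m_b - cells$m_a
  se2 <- cells$s2_a / cells$n_a + cells$s2_b / cells$n_b
  tval <- cells$delta / sqrt(se2)
  dfw <- se2^2 / ((cells$s2_a / cells$n_a)^2 / (cells$n_a - 1) +
                    (cells$s2_b / cells$n_b)^2 / (cells$n_b - 1))
  welch_p <- 2 * stats::pt(-abs(tval), dfw)
  cells$welch_p <- ifelse(testable, welch_p, NA_real_)
  cells$testable <- testable
  cells$significant <- testable &
    abs(cells$delta) > cells$threshold & cells$welch_p < alpha
  out <- cells[c("peptide_id", "exposure_s", "delta", "threshold",
                 "welch_p", "testable", "significant")]
  out <- out[order(out$peptide_id, out$exposure_s), ]
  rownames(out) <- NULL
  structure(out, alpha = alpha, class = c("hybrid_test", "data.frame"))
}

#' Per-residue protection classification from hybrid-test results
#'
#' Maps each residue to `protected` (covered by significant peptides
#' with decreased uptake), `deprotected` (increased uptake),
#' `nonsignificant`, or `no-coverage`. A peptide is significant if any
#' exposure passes; its direction is the sign of the mean delta over
#' its significant exposures. Residues with equal protected and
#' deprotected votes are `nonsignificant`.
#'
#' @param results a [hybrid_test()] result.
#' @param peptides the [peptide_map()] the results refer to.
#' @param n_residues classify residues `1..n_residues`; defaults to the
#'   largest peptide end.
#' @return data.frame `residue, class`.
#' @export
woods_summary <- function(results, peptides, n_residues = max(peptides$end)) {
  dir <- vapply(split(results, results$peptide_id), function(sub) {
    sig <- sub[which(sub$significant), , drop = FALSE]
    if (!nrow(sig)) return(0)
    sign(mean(sig$delta))
  }, numeric(1))
  cls <- rep("no-coverage", n_residues)
  for (r in seq_len(n_residues)) {
    cover <- peptides$peptide_id[peptides$start <= r & peptides$end >= r]
    cover <- intersect(cover, names(dir))
    if (!length(cover)) next
    votes <- dir[cover]
    n_prot <- sum(votes < 0)
    n_depr <- sum(votes > 0)
    cls[r] <- if (n_prot > n_depr) "protected"
      else if (n_depr > n_prot) "deprotected"
      else "nonsignificant"
  }
  data.frame(residue = seq_len(n_residues), class = cls,
             stringsAsFactors = FALSE)
}
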