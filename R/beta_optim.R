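# Re-optimization of the protection-factor scaling parameters
# (beta_C, beta_H) against an experimental dataset, with frame weights
# held fixed: coarse grid pre-scan followed by Nelder-Mead refinement.

#' Fit the protection-factor scaling parameters to uptake data
#'
#' Minimizes the mean squared deviation between predicted peptide
#' deuteration (frame weights fixed at `w`) and the target fractions
#' over `(beta_C, beta_H)` within `bounds` (default \[0,2\] x \[0,10\]).
#' A coarse `grid_n` x `grid_n` pre-scan avoids local minima; the best
#' grid point and `init` both seed a restarted Nelder-Mead local
#' search (derivative-free), and the better solution is kept.
#' Deterministic given `init` and the grid. Solutions on the boundary
#' are flagged; a parameter with no influence on the objective (e.g.
#' beta_H when every frame has N_H = 0) is reported non-identifiable
#' rather than given an arbitrary value.
#'
#' @param features feature table (`frame_id,residue,N_C,N_H`).
#' @param rates an [intrinsic_rates()] vector.
#' @param target normalized, filtered [uptake_table()].
#' @param peptides peptide map (default from `target`).
#' @param w fixed frame weights (default uniform).
#' @param init starting [beta_params()].
#' @param bounds list of `c(lo, hi)` for beta_C and beta_H.
#' @param grid_n grid points per axis in the pre-scan (default 21).
#' @param first_residue_skip see [peptide_deuteration()].
#' @return object of class `beta_fit`: `betas` ([beta_params()]),
#'   `objective_value`, `trace` (data.frame `beta_C, beta_H,
#'   objective`), `boundary`, `non_identifiable` (character vector).
#' @export
fit_betas <- function(features, rates, target,
                      peptides = peptides_of(target), w = NULL,
                      init = beta_params(), bounds = list(c(0, 2), c(0, 10)),
                      grid_n = 21L, first_residue_skip = 1L) {
  stopifnot(init$beta_C >= bounds[[1]][1], init$beta_C <= bounds[[1]][2],
            init$beta_H >= bounds[[2]][1], init$beta_H <= bounds[[2]][2])
  prob <- reweight_problem(features, rates, beta_params(1, 0), target,
                           peptides, first_residue_skip)
  # reuse the cell machinery with raw N_C / N_H matrices
  fmx <- feature_matrices(features)
  n <- length(prob$frame_id)
  if (is.null(w)) w <- rep(1 / n, n)
  if (length(w) != n)
    stop_hdx("dimension", "w has %d entries for %d frames", length(w), n)
  wNC <- as.numeric(crossprod(fmx$NC, w))
  wNH <- as.numeric(crossprod(fmx$NH, w))

  objective <- function(b) {
    if (any(!is.finite(b))) return(Inf)
    L <- b[1] * wNC + b[2] * wNH
    a <- prob$A0 * exp(-L)
    Dpep <- prob$M %*% (1 - exp(-a))
    val <- mean((Dpep[prob$cell_idx] - prob$target)^2)
    if (!is.finite(val))
      stop_hdx("validation", "non-finite objective at beta = (%g, %g)",
               b[1], b[2])
    val
  }

  # flat-direction detection: a parameter whose feature column is
  # identically zero cannot be identified from the data
  non_id <- character(0)
  if (all(fmx$NC == 0)) non_id <- c(non_id, "beta_C")
  if (all(fmx$NH == 0)) non_id <- c(non_id, "beta_H")

  g1 <- seq(bounds[[1]][1], bounds[[1]][2], length.out = grid_n)
  g2 <- seq(bounds[[2]][1], bounds[[2]][2], length.out = grid_n)
  grid <- expand.grid(beta_C = g1, beta_H = g2, KEEP.OUT.ATTRS = FALSE)
  grid$objective <- apply(grid, 1, function(r) objective(as.numeric(r)))
  best_grid <- as.numeric(grid[which.min(grid$objective), 1:2])

  clamp <- function(b) pmin(pmax(b, c(bounds[[1]][1], bounds[[2]][1])),
                            c(bounds[[1]][2], bounds[[2]][2]))
  polish <- function(start) {
    b <- start
    for (i in 1:3) { # restarted Nelder-Mead for tight convergence
      fit <- stats::optim(b, function(p) objective(clamp(p)),
                          method = "Nelder-Mead",
                          control = list(maxit = 2000L, reltol = 1e-14))
      b <- clamp(fit$par)
    }
    list(par = b, value = objective(b))
  }
  cand <- list(polish(best_grid),
               polish(c(init$beta_C, init$beta_H)))
  best <- cand[[which.min(vapply(cand, function(x) x$value, numeric(1)))]]

  # a non-identifiable parameter is reported at its initial value
  par <- best$par
  if ("beta_C" %in% non_id) par[1] <- init$beta_C
  if ("beta_H" %in% non_id) par[2] <- init$beta_H

  eps <- 1e-9
  on_bound <- (par[1] <= bounds[[1]][1] + eps || par[1] >= bounds[[1]][2] - eps ||
                 par[2] <= bounds[[2]][1] + eps || par[2] >= bounds[[2]][2] - eps)
  if (on_bound && !length(non_id))
    warning("beta fit converged on a bound; widen the bounds or inspect data")
  if (length(non_id))
    warning(sprintf("non-identifiable parameter(s): %s",
                    paste(non_id, collapse = ", ")))

  structure(list(
    betas = beta_params(par[1], par[2]),
    objective_value = objective(par),
    trace = grid,
    boundary = on_bound,
    non_identifiable = non_id
  ), class = "beta_fit")
}

#' @export
print.beta_fit <- function(x, ...) {
  cat(sprintf("beta_fit: beta_C = %.4g, beta_H = %.4g, MSE = %.4g%s\n",
              x$betas$beta_C, x$betas$beta_H, x$objective_value,
              if (length(x$non_identifiable))
                paste0(" (non-identifiable: ",
                       paste(x$non_identifiable, collapse = ", "), ")")
              else ""))
  invisible(x)
}
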