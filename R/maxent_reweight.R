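# Maximum-entropy ensemble reweighting: fit candidate-frame weights to
# MaxD-normalized experimental uptake by minimizing
#
#   G(w) = gamma * (1/2) * sum_cells (D_pred(w) - D_target)^2
#        + sum_j w_j log(w_j / w0_j)
#
# over the probability simplex, where D_pred(w) is the protection-factor
# forward model under weights w. The relative-entropy penalty times
# k_B T is the "apparent work" W_app spent biasing the ensemble; a
# gamma scan selects the tightness of fit whose W_app matches a stated
# work budget (~5 kJ/mol by default) to avoid overfitting.

#' Default gamma grid for the reweighting scan
#'
#' Log-spaced from 1e-2 to 1e3 with 6 points per decade.
#' @export
default_gamma_grid <- function() 10^seq(-2, 3, by = 1 / 6)

#' Apparent work of a reweighting
#'
#' `W_app = k_B T sum_j w_j log(w_j / w0_j)` in kJ/mol; zero-weight
#' frames contribute zero.
#'
#' @param w,w0 final and initial weights on the simplex.
#' @param temperature_K temperature for k_B T (default 298).
#' @export
apparent_work <- function(w, w0, temperature_K = 298) {
  stopifnot(length(w) == length(w0))
  pos <- w > 0
  if (any(pos & w0 <= 0)) return(Inf)
  KB_KJ_MOL_K * temperature_K * sum(w[pos] * log(w[pos] / w0[pos]))
}

# internal: precompute everything the objective needs.
# Returns B (frames x residues), A0 (residues x times, k*t in the
# forward model's per-minute units), peptide membership matrix M
# (peptides x residues, rows scaled by 1/n_residues), cell indices into
# the peptides x times grid, and the target vector.
reweight_problem <- function(features, rates, betas, target, peptides,
                             first_residue_skip = 1L) {
  if (!is_normalized(target))
    stop_hdx("validation", "reweighting target must be MaxD-normalized")
  if (!nrow(target))
    stop_hdx("validation", "reweighting target is empty")
  fm <- feature_matrices(features)
  B <- betas$beta_C * fm$NC + betas$beta_H * fm$NH  # frames x residues
  residues <- fm$residues
  miss <- setdiff(residues, as.integer(names(rates)))
  if (length(miss))
    stop_hdx("validation", "no intrinsic rate for residue(s): %s",
             paste(miss, collapse = ", "))
  k <- as.numeric(rates[as.character(residues)])

  cells <- uptake_cells(target)
  pm <- peptides %||% peptides_of(target)
  pm <- pm[pm$peptide_id %in% unique(cells$peptide_id), , drop = FALSE]
  times <- sort(unique(cells$exposure_s))
  A0 <- outer(k, times / 60)                        # residues x times

  memb <- matrix(0, nrow(pm), length(residues))
  for (p in seq_len(nrow(pm))) {
    span <- intersect((pm$start[p] + first_residue_skip):pm$end[p], residues)
    if (!length(span))
      stop_hdx("validation", "peptide %s has no exchange-competent residues",
               pm$peptide_id[p])
    memb[p, match(span, residues)] <- 1 / length(span)
  }
  pi <- match(cells$peptide_id, pm$peptide_id)
  ti <- match(cells$exposure_s, times)
  list(B = B, A0 = A0, M = memb, frame_id = fm$frame_id,
       cell_idx = cbind(pi, ti), target = cells$uptake, cells = cells)
}

# predicted deuterated fractions at every (peptide, time) cell
predict_cells <- function(prob, w) {
  L <- as.numeric(crossprod(prob$B, w))      # residues
  a <- prob$A0 * exp(-L)                     # residues x times
  Dres <- 1 - exp(-a)
  Dpep <- prob$M %*% Dres                    # peptides x times
  Dpep[prob$cell_idx]
}

# objective and gradient in softmax coordinates w = w0 e^theta / Z
reweight_objfun <- function(prob, w0, gamma) {
  wt <- function(theta) {
    lw <- log(w0) + theta
    lw <- lw - max(lw)
    e <- exp(lw)
    e / sum(e)
  }
  fn <- function(theta) {
    w <- wt(theta)
    L <- as.numeric(crossprod(prob$B, w))
    a <- prob$A0 * exp(-L)
    Dpep <- prob$M %*% (1 - exp(-a))
    r <- Dpep[prob$cell_idx] - prob$target
    pos <- w > 0
    gamma * 0.5 * sum(r * r) + sum(w[pos] * log(w[pos] / w0[pos]))
  }
  gr <- function(theta) {
    w <- wt(theta)
    L <- as.numeric(crossprod(prob$B, w))
    a <- prob$A0 * exp(-L)
    Dpep <- prob$M %*% (1 - exp(-a))
    r <- Dpep[prob$cell_idx] - prob$target
    # scatter gamma * r back onto the peptide x time grid
    Rmat <- matrix(0, nrow(prob$M), ncol(prob$A0))
    Rmat[prob$cell_idx] <- Rmat[prob$cell_idx] + gamma * r
    Gres <- crossprod(prob$M, Rmat)          # residues x times
    gL <- rowSums(Gres * (-a * exp(-a)))     # dObj/dL_i
    gw <- as.numeric(prob$B %*% gL) + log(w / w0) + 1
    w * (gw - sum(w * gw))                   # softmax chain rule
  }
  list(fn = fn, gr = gr, wt = wt)
}

run_bfgs <- function(obj, theta0, control) {
  theta <- theta0
  w_prev <- obj$wt(theta)
  v_prev <- obj$fn(theta)
  converged <- FALSE
  iterations <- 0L
  for (rep in seq_len(control$max_restarts)) {
    fit <- stats::optim(theta, obj$fn, obj$gr, method = "BFGS",
                        control = list(maxit = control$maxit,
                                       reltol = control$reltol))
    theta <- fit$par
    iterations <- iterations + fit$counts[["function"]]
    w_new <- obj$wt(theta)
    delta <- max(abs(w_new - w_prev) / pmax(w_prev, 1e-12))
    dv <- v_prev - fit$value
    w_prev <- w_new
    v_prev <- fit$value
    # stationary either in the weights or in the objective
    if (delta < control$wtol || dv < 1e-13 * max(1, abs(fit$value))) {
      converged <- TRUE
      break
    }
  }
  list(theta = theta, w = w_prev, value = v_prev,
       converged = converged, iterations = iterations)
}

default_reweight_control <- function(control = list()) {
  utils::modifyList(list(maxit = 2000L, reltol = 1e-15, wtol = 1e-8,
                         max_restarts = 20L), control)
}

#' Maximum-entropy reweighting at a fixed gamma
#'
#' Minimizes the relative-entropy-regularized misfit (see module
#' header) with a BFGS quasi-Newton optimizer on log-weights (softmax
#' parameterization keeps iterates on the simplex), analytic gradient,
#' restarted until the maximum relative weight change falls below
#' `1e-8`. `gamma = 0` returns the initial weights exactly.
#'
#' @param features feature table (`frame_id,residue,N_C,N_H`).
#' @param rates an [intrinsic_rates()] vector.
#' @param betas a [beta_params()].
#' @param target normalized, filtered [uptake_table()].
#' @param peptides unused if `target` carries a peptide map; kept for
#'   symmetry with the forward model (default `peptides_of(target)`).
#' @param gamma non-negative tightness-of-fit coefficient.
#' @param w0 initial weights (default: uniform).
#' @param state optional per-frame state labels, stored in the result.
#' @param temperature_K temperature for the apparent work (default 298).
#' @param first_residue_skip see [peptide_deuteration()].
#' @param control optimizer settings
#'   (`maxit`, `reltol`, `wtol`, `max_restarts`).
#' @param theta0 internal warm start (log-weight offsets).
#' @return object of class `hdx_reweight`: `weights`, `gamma`, `W_app`
#'   (kJ/mol), `mse_initial`, `mse_final` (mean squared deviation of
#'   predicted vs target fractions), `frame_id`, `state`,
#'   `initial_weights`, `converged`, `iterations`.
#' @export
reweight <- function(features, rates, betas, target,
                     peptides = peptides_of(target), gamma,
                     w0 = NULL, state = NULL, temperature_K = 298,
                     first_residue_skip = 1L, control = list(),
                     theta0 = NULL) {
  stopifnot(gamma >= 0)
  control <- default_reweight_control(control)
  prob <- reweight_problem(features, rates, betas, target, peptides,
                           first_residue_skip)
  n <- length(prob$frame_id)
  if (is.null(w0)) w0 <- rep(1 / n, n)
  if (length(w0) != n)
    stop_hdx("dimension", "w0 has %d entries for %d frames", length(w0), n)
  if (any(w0 <= 0))
    stop_hdx("validation", "initial weights must be strictly positive")
  if (abs(sum(w0) - 1) > 1e-9)
    stop_hdx("validation", "initial weights must sum to 1")

  r0 <- predict_cells(prob, w0) - prob$target
  mse0 <- mean(r0^2)

  if (gamma == 0) {
    w <- w0
    converged <- TRUE
    iterations <- 0L
  } else {
    obj <- reweight_objfun(prob, w0, gamma)
    if (is.null(theta0)) {
      # gamma continuation from weaker biases: a cold start at large
      # gamma can overshoot into the flat region of the softmax where
      # gradients vanish; warming up along gamma/1000..gamma/10 keeps
      # the iterates in the well-conditioned part of the simplex
      theta0 <- rep(0, n)
      for (gk in gamma * 10^(-3:-1)) {
        pre <- run_bfgs(reweight_objfun(prob, w0, gk), theta0,
                        utils::modifyList(control, list(max_restarts = 3L)))
        theta0 <- pre$theta
      }
    }
    fit <- run_bfgs(obj, theta0, control)
    if (!fit$converged)
      stop_hdx("convergence",
               "reweighting did not converge (gamma = %g, %d evaluations)",
               gamma, fit$iterations)
    # never accept a point worse than the start
    if (fit$value > obj$fn(rep(0, n))) fit$w <- w0
    w <- fit$w
    converged <- fit$converged
    iterations <- fit$iterations
  }
  r1 <- predict_cells(prob, w) - prob$target
  structure(list(
    frame_id = prob$frame_id,
    state = state %||% rep(NA_character_, n),
    initial_weights = w0,
    weights = w,
    gamma = gamma,
    W_app = apparent_work(w, w0, temperature_K),
    mse_initial = mse0,
    mse_final = mean(r1^2),
    temperature_K = temperature_K,
    converged = converged,
    iterations = iterations
  ), class = "hdx_reweight")
}

#' @export
print.hdx_reweight <- function(x, ...) {
  cat(sprintf(
    "hdx_reweight: %d frames, gamma = %g, W_app = %.4g kJ/mol, MSE %.4g -> %.4g\n",
    length(x$weights), x$gamma, x$W_app, x$mse_initial, x$mse_final))
  invisible(x)
}

#' Gamma scan with an apparent-work stopping rule
#'
#' Runs [reweight()] over an ascending gamma grid (warm-starting each
#' gamma from the previous solution, then cross-polishing every
#' solution from any other gamma's solution that lowers its objective)
#' and selects the result whose apparent work is closest to `W_target`
#' without exceeding it. The full `scan_trace` (gamma, W_app, MSE) is
#' retained for a work/fit decision plot. If every W_app falls below
#' `W_target` the largest-gamma result is returned with a warning; if
#' even the smallest gamma overshoots, the smallest-gamma result is
#' returned with a warning.
#'
#' @inheritParams reweight
#' @param gammas ascending gamma grid (default [default_gamma_grid()]).
#' @param W_target apparent-work budget in kJ/mol (default 5).
#' @return the selected `hdx_reweight`, with extra fields `scan_trace`
#'   (data.frame `gamma, W_app, mse`) and `scan_weights` (list of
#'   weight vectors along the grid).
#' @export
gamma_scan <- function(features, rates, betas, target,
                       peptides = peptides_of(target),
                       gammas = default_gamma_grid(), W_target = 5,
                       w0 = NULL, state = NULL, temperature_K = 298,
                       first_residue_skip = 1L, control = list()) {
  stopifnot(length(gammas) >= 1, !is.unsorted(gammas), W_target > 0)
  control <- default_reweight_control(control)
  prob <- reweight_problem(features, rates, betas, target, peptides,
                           first_residue_skip)
  n <- length(prob$frame_id)
  if (is.null(w0)) w0 <- rep(1 / n, n)

  thetas <- vector("list", length(gammas))
  theta <- rep(0, n)
  for (g in seq_along(gammas)) {
    obj <- reweight_objfun(prob, w0, gammas[g])
    fit <- run_bfgs(obj, theta, control)
    theta <- fit$theta
    thetas[[g]] <- theta
  }

  # candidate-exchange polish: re-optimize any gamma whose objective is
  # beaten by another gamma's solution; repeat until stable. Guarantees
  # the pairwise optimality relations that make W_app non-decreasing
  # and MSE non-increasing along the grid.
  for (sweep in seq_len(6L)) {
    improved <- FALSE
    for (g in seq_along(gammas)) {
      obj <- reweight_objfun(prob, w0, gammas[g])
      vals <- vapply(thetas, obj$fn, numeric(1))
      cur <- vals[g]
      best <- which.min(vals)
      if (vals[best] < cur - 1e-14 * max(1, abs(cur))) {
        fit <- run_bfgs(obj, thetas[[best]], control)
        if (fit$value < cur) { thetas[[g]] <- fit$theta; improved <- TRUE }
      }
    }
    if (!improved) break
  }

  mkres <- function(g) {
    reweight(features, rates, betas, target, peptides, gamma = gammas[g],
             w0 = w0, state = state, temperature_K = temperature_K,
             first_residue_skip = first_residue_skip, control = control,
             theta0 = thetas[[g]])
  }
  results <- lapply(seq_along(gammas), mkres)
  trace <- data.frame(
    gamma = gammas,
    W_app = vapply(results, function(r) r$W_app, numeric(1)),
    mse = vapply(results, function(r) r$mse_final, numeric(1))
  )

  under <- which(trace$W_app <= W_target)
  if (!length(under)) {
    warning(sprintf(
      "smallest gamma already exceeds W_target = %g kJ/mol; returning it",
      W_target))
    sel <- 1L
  } else {
    sel <- under[which.max(trace$W_app[under])]
    if (max(trace$W_app) <= W_target && sel == nrow(trace))
      warning(sprintf(
        "no gamma reaches W_target = %g kJ/mol; returning largest gamma",
        W_target))
  }
  out <- results[[sel]]
  out$scan_trace <- trace
  out$scan_weights <- lapply(results, function(r) r$weights)
  out$W_target <- W_target
  out
}

#' @rdname gamma_scan
#' @param scan an `hdx_reweight` returned by `gamma_scan`.
#' @param path output CSV path for the decision-plot trace.
#' @export
write_scan_trace <- function(scan, path) {
  utils::write.csv(scan$scan_trace, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
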