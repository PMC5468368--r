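#' Block model parameters
#'
#' Container for the parameters of a (degree-corrected) stochastic block
#' model: cluster fractions `gamma`, the symmetric q x q affinity matrix
#' `omega` of pair-connection probabilities (O(1/N) in sparse networks), and
#' optional per-vertex degree-correction factors `theta`.
#'
#' @param q number of clusters.
#' @param gamma length-q probability vector (defaults to uniform).
#' @param omega symmetric q x q matrix with entries in \[0, 1\].
#' @param theta optional per-vertex non-negative propensities; presence
#'   switches `model_kind` to `"degree_corrected"`.
#' @return An object of class `block_model_params`.
#' @export
block_model_params <- function(q, gamma = NULL, omega, theta = NULL) {
  q <- as.integer(q)
  if (is.null(gamma)) gamma <- rep(1 / q, q)
  omega <- as.matrix(omega)
  stopifnot(q >= 1, length(gamma) == q, all(gamma >= 0),
            abs(sum(gamma) - 1) < 1e-8,
            nrow(omega) == q, ncol(omega) == q,
            all(omega >= 0), all(omega <= 1),
            isTRUE(all.equal(omega, t(omega), tolerance = 1e-10)))
  if (!is.null(theta)) stopifnot(all(theta >= 0))
  structure(list(q = q, gamma = gamma, omega = omega, theta = theta,
                 model_kind = if (is.null(theta)) "standard"
                              else "degree_corrected"),
            class = "block_model_params")
}

#' @export
print.block_model_params <- function(x, ...) {
  cat(sprintf("block_model_params: q = %d (%s)\n", x$q, x$model_kind))
  cat("gamma:", signif(x$gamma, 4), "\n")
  invisible(x)
}

theta_or_ones <- function(params, n) {
  if (is.null(params$theta)) rep(1, n) else params$theta
}

#' Initialize BP cavity messages
#'
#' Each cavity bias is the uniform 1/q vector perturbed by multiplicative
#' noise and renormalized; with `noise = 0` the state is exactly the
#' symmetric (factorized) point. When `params` is supplied, marginals and the
#' non-edge field are computed consistently from the messages.
#'
#' @param network an `sbm_network`.
#' @param q number of clusters.
#' @param seed integer seed (same seed, same state).
#' @param params optional `block_model_params` to populate marginals/field.
#' @param noise multiplicative perturbation magnitude.
#' @return An object of class `bp_state`: `cav` (2L x q; row e is the message
#'   i->j for edge row e, row e + L the reverse), `marginal` (N x q), `h`
#'   (length q field), `logZi` (per-vertex log normalizers), plus diagnostics.
#' @export
init_messages <- function(network, q, seed, params = NULL, noise = 0.1) {
  q <- as.integer(q)
  set.seed(as.integer(seed))
  m <- 2L * network$L
  cav <- matrix(1 / q, m, q)
  if (noise > 0 && q > 1) {
    cav <- cav * (1 + noise * (matrix(stats::runif(m * q), m, q) - 0.5))
    cav <- cav / rowSums(cav)
  }
  state <- structure(list(cav = cav, marginal = NULL, h = NULL, logZi = NULL,
                          iterations = 0L, max_change = NA_real_,
                          resets = 0L),
                     class = "bp_state")
  if (!is.null(params)) state <- compute_marginals(state, network, params)
  state
}

#' @export
print.bp_state <- function(x, ...) {
  cat(sprintf("bp_state: %d cavity messages over %d clusters", nrow(x$cav),
              ncol(x$cav)))
  if (!is.na(x$max_change))
    cat(sprintf("; last sweep max change %.3g", x$max_change))
  cat("\n")
  invisible(x)
}

bp_call <- function(state, network, params, damping, tol, max_iter,
                    inc = NULL) {
  if (is.null(inc)) inc <- network_incidence(network)
  res <- bp_run_cpp(network$n, params$q, inc$src, inc$dst,
                    inc$in_msg, inc$in_ptr,
                    params$gamma, params$omega,
                    theta_or_ones(params, network$n),
                    state$cav, damping, tol, as.integer(max_iter))
  structure(list(cav = res$cav, marginal = res$marginal, h = res$h,
                 logZi = res$logZi, iterations = res$iterations,
                 max_change = res$max_change,
                 resets = state$resets + res$resets),
            class = "bp_state")
}

#' One asynchronous BP sweep
#'
#' Updates all 2L cavity messages once, visiting vertices in a seeded random
#' order, with the non-edge field maintained incrementally. The update is
#' `psi^{i->j} \\propto gamma_sigma e^{-h_sigma} prod_{k in di\\j}
#' sum_{sk} psi^{k->i} omega_{sk sigma}` (degree-corrected models substitute
#' `theta_i omega theta_j` for `omega` and weight the field by theta).
#'
#' @param state a `bp_state`.
#' @param network an `sbm_network`.
#' @param params a `block_model_params`.
#' @param damping fraction d in \[0, 1): new = (1 - d) update + d old.
#' @return A list with `state` (updated) and `max_change` (largest absolute
#'   single-entry message change).
#' @export
bp_sweep <- function(state, network, params, damping = 0) {
  st <- bp_call(state, network, params, damping, tol = 0, max_iter = 1L)
  list(state = st, max_change = st$max_change)
}

#' Run BP to convergence
#'
#' Repeated sweeps until the maximum message change drops below `tol` or
#' `max_iter` sweeps have been made.
#'
#' @inheritParams bp_sweep
#' @param tol convergence threshold on the max message change.
#' @param max_iter sweep budget.
#' @param inc optional precomputed incidence structure (internal reuse).
#' @return The converged (or budget-exhausted) `bp_state`; `$iterations`
#'   holds the sweep count and `$max_change` the final change.
#' @export
run_bp <- function(state, network, params, tol = 1e-6, max_iter = 500,
                   damping = 0, inc = NULL) {
  bp_call(state, network, params, damping, tol, max_iter, inc)
}

#' Recompute marginals, field, and vertex normalizers from cavity messages
#'
#' `psi^i \\propto gamma_sigma e^{-h_sigma} prod_{k in di} sum psi^{k->i}
#' omega`; `Z^i` is the normalizer of the unnormalized vector. Isolated
#' vertices get the field-only marginal `gamma_sigma e^{-h_sigma}`.
#'
#' @inheritParams bp_sweep
#' @return The `bp_state` with `marginal`, `h`, `logZi` filled in.
#' @export
compute_marginals <- function(state, network, params) {
  bp_call(state, network, params, damping = 0, tol = 0, max_iter = 0L)
}

# log pair normalizers log Z^{ij} for every edge, and the cavity matrices
edge_quantities <- function(network, state, params) {
  L <- network$L
  if (L == 0L)
    return(list(F = NULL, B = NULL, logZij = numeric(0), Zij0 = numeric(0)))
  Fm <- state$cav[seq_len(L), , drop = FALSE]        # psi^{i->j}
  Bm <- state$cav[L + seq_len(L), , drop = FALSE]    # psi^{j->i}
  Zij0 <- rowSums((Fm %*% params$omega) * Bm)
  lth <- if (is.null(params$theta)) numeric(network$n) else log(params$theta)
  logZij <- log(Zij0) + lth[network$edges[, 1L]] + lth[network$edges[, 2L]]
  list(F = Fm, B = Bm, logZij = logZij, Zij0 = Zij0)
}

#' Two-point (pair) marginal on an edge
#'
#' `psi^{ij}_{ss'} = psi^{i->j}_s omega_{ss'} psi^{j->i}_{s'} / Z^{ij}` with
#' `Z^{ij} = sum_{ss'} psi^{i->j}_s omega_{ss'} psi^{j->i}_{s'}` (times
#' `theta_i theta_j` in the degree-corrected model).
#'
#' @param state a `bp_state`.
#' @param network an `sbm_network`.
#' @param edge integer vector `c(i, j)` which must be an edge of the network.
#' @param params a `block_model_params`.
#' @return A list with `table` (q x q probability table) and `Zij`.
#' @export
pair_marginal <- function(state, network, edge, params) {
  i <- min(edge); j <- max(edge)
  e <- which(network$edges[, 1L] == i & network$edges[, 2L] == j)
  if (length(e) != 1L) stop("pair is not an edge of the network")
  f <- state$cav[e, ]; b <- state$cav[network$L + e, ]
  th <- theta_or_ones(params, network$n)
  tab <- outer(f, b) * params$omega
  Z0 <- sum(tab)
  if (Z0 <= 0) stop("degenerate pair normalizer (Z^ij = 0)")
  list(table = tab / Z0, Zij = Z0 * th[i] * th[j])
}

#' EM parameter update (M-step)
#'
#' `gamma_hat_s = mean_i psi^i_s`;
#' `omega_hat_{ss'} = sum_E omega_{ss'} (psi^{i->j}_s psi^{j->i}_{s'} +
#' psi^{j->i}_s psi^{i->j}_{s'}) / Z^{ij} / (N^2 gamma_s gamma_{s'})`.
#' Clusters whose updated fraction falls below `1e-8` are declared empty and
#' their affinity rows are frozen at the incoming values. In the
#' degree-corrected model `theta` is re-identified from degrees:
#' `theta_i = d_i / mean(d)` within the current argmax block (block mean 1).
#'
#' @param network an `sbm_network`.
#' @param state a converged (or budget-exhausted) `bp_state`.
#' @param params_in current `block_model_params`.
#' @return Updated `block_model_params`; attribute `"empty"` lists clusters
#'   whose fraction hit the floor.
#' @export
m_step <- function(network, state, params_in) {
  q <- params_in$q; n <- network$n
  gamma_new <- colMeans(state$marginal)
  eq <- edge_quantities(network, state, params_in)
  if (network$L > 0L) {
    W <- eq$B / eq$Zij0
    S <- params_in$omega * (crossprod(eq$F, W) + crossprod(W, eq$F))
  } else S <- matrix(0, q, q)
  empty <- which(gamma_new < 1e-8)
  gsafe <- pmax(gamma_new, 1e-8)
  omega_new <- S / (n^2 * outer(gsafe, gsafe))
  omega_new <- (omega_new + t(omega_new)) / 2
  omega_new <- pmin(omega_new, 1)
  if (length(empty)) {
    omega_new[empty, ] <- params_in$omega[empty, ]
    omega_new[, empty] <- params_in$omega[, empty]
  }
  theta_new <- NULL
  if (params_in$model_kind == "degree_corrected") {
    blk <- max.col(state$marginal, ties.method = "first")
    dbar <- stats::ave(network$degrees, blk, FUN = mean)
    theta_new <- ifelse(dbar > 0, network$degrees / dbar, 0)
  }
  out <- block_model_params(q, gamma_new / sum(gamma_new), omega_new,
                            theta_new)
  attr(out, "empty") <- empty
  out
}

param_change <- function(old, new, n) {
  max(max(abs(old$gamma - new$gamma)), n * max(abs(old$omega - new$omega)))
}

#' Bethe free energy per vertex
#'
#' `f_Bethe = -(1/N) sum_i log Z^i + (1/N) sum_E log Z^{ij} - c/2` with
#' `c = 2L/N`. This is BP's approximation of the negative marginal
#' log-likelihood per vertex; EM restarts are ranked by it.
#'
#' @inheritParams bp_sweep
#' @return A scalar.
#' @export
bethe_free_energy <- function(network, state, params) {
  eq <- edge_quantities(network, state, params)
  c_avg <- 2 * network$L / network$n
  -mean(state$logZi) + sum(eq$logZij) / network$n - c_avg / 2
}

default_em_opts <- function(opts = list()) {
  defaults <- list(restarts = 10L, max_bp_iter = 500L, max_em_iter = 100L,
                   tol = 1e-6, em_tol = 1e-6, damping = 0, seed = 1L,
                   model_kind = "standard", noise = 0.1,
                   init_params = NULL, learn = TRUE)
  defaults[names(opts)] <- opts
  defaults
}

random_init_params <- function(network, q, model_kind) {
  c_avg <- max(2 * network$L / network$n, 1e-8)
  g <- stats::runif(q, 0.5, 1.5); g <- g / sum(g)
  eps <- stats::runif(1, 0.05, 0.9)
  s2 <- sum(g^2)
  om_in <- min(1, c_avg / (network$n * (s2 + eps * (1 - s2))))
  om <- matrix(eps * om_in, q, q); diag(om) <- om_in
  theta <- NULL
  if (model_kind == "degree_corrected")
    theta <- network$degrees / mean(network$degrees)
  block_model_params(q, g, om, theta)
}

# closed-form q = 1 result (no message passing needed)
em_q1 <- function(network, model_kind) {
  n <- network$n; L <- network$L; d <- network$degrees
  omega <- 2 * L / n^2
  c_avg <- 2 * L / n
  if (model_kind == "degree_corrected") {
    theta <- if (L > 0) d / mean(d) else rep(1, n)
    params <- block_model_params(1L, 1, matrix(omega, 1, 1), theta)
    h <- sum(theta) * omega
    lth <- ifelse(theta > 0, log(theta), 0)
    sum_log_theta_nb <- numeric(n)
    if (L > 0) {
      e <- network$edges
      sum_log_theta_nb <- unname(
        tapply(c(lth[e[, 2L]], lth[e[, 1L]]), c(e[, 1L], e[, 2L]), sum)[
          as.character(seq_len(n))])
      sum_log_theta_nb[is.na(sum_log_theta_nb)] <- 0
    }
    logZi <- -theta * h + d * (log(omega) + lth) + sum_log_theta_nb
    logZij <- log(omega) + lth[network$edges[, 1L]] + lth[network$edges[, 2L]]
  } else {
    params <- block_model_params(1L, 1, matrix(omega, 1, 1))
    logZi <- -n * omega + d * log(omega)
    logZij <- rep(log(omega), L)
  }
  state <- structure(list(cav = matrix(1, 2L * L, 1L),
                          marginal = matrix(1, n, 1L),
                          h = if (model_kind == "degree_corrected")
                            sum(params$theta) * omega else n * omega,
                          logZi = logZi, iterations = 0L, max_change = 0,
                          resets = 0L),
                     class = "bp_state")
  f <- -mean(logZi) + sum(logZij) / n - c_avg / 2
  list(params = params, state = state, f_bethe = f)
}

#' EM inference of a block model by belief propagation
#'
#' For each restart: initialize messages, alternate BP sweeps to convergence
#' with M-step parameter updates until the parameter change falls below
#' `em_tol`, and keep the restart with the lowest Bethe free energy. `q = 1`
#' is returned in closed form. The cluster-inference step always minimizes
#' the Bethe free energy; model selection across q is done separately from
#' the cross-validation errors.
#'
#' @param network an `sbm_network`.
#' @param q input (maximum) number of clusters; the number that is actually
#'   populated can be smaller.
#' @param opts list of engine options overriding the defaults
#'   `restarts = 10`, `max_bp_iter = 500`, `max_em_iter = 100`, `tol = 1e-6`
#'   (message change), `em_tol = 1e-6` (parameter change), `damping = 0`,
#'   `seed = 1`, `model_kind = "standard"` (`"degree_corrected"` for the
#'   DC-SBM), `noise = 0.1`, `init_params = NULL` (random restarts), and
#'   `learn = TRUE` (set `FALSE` to run pure BP at fixed `init_params`).
#' @return An object of class `em_result`: `params`, `state` (messages,
#'   marginals, normalizers), `f_bethe`, `bp_iterations` (per EM step),
#'   `converged`, `restart_index`, `seed`, `assignment` (marginal argmax),
#'   `n_effective` (clusters actually populated).
#' @export
run_em <- function(network, q, opts = list()) {
  o <- default_em_opts(opts)
  q <- as.integer(q)
  if (q == 1L) {
    r <- em_q1(network, o$model_kind)
    return(structure(list(params = r$params, state = r$state,
                          f_bethe = r$f_bethe, bp_iterations = 0L,
                          converged = TRUE, restart_index = 1L,
                          seed = o$seed,
                          assignment = rep(1L, network$n), n_effective = 1L),
                     class = "em_result"))
  }
  inc <- network_incidence(network)
  best <- NULL
  for (r in seq_len(o$restarts)) {
    seed_r <- (as.integer(o$seed) + 104729L * (r - 1L)) %% 2147483647L
    set.seed(seed_r)
    params <- if (!is.null(o$init_params)) o$init_params
              else random_init_params(network, q, o$model_kind)
    state <- init_messages(network, q, seed = seed_r, params = params,
                           noise = o$noise)
    iters <- integer(0)
    converged_em <- FALSE
    for (step in seq_len(o$max_em_iter)) {
      state <- run_bp(state, network, params, tol = o$tol,
                      max_iter = o$max_bp_iter, damping = o$damping,
                      inc = inc)
      iters <- c(iters, state$iterations)
      if (!o$learn) { converged_em <- TRUE; break }
      new_params <- m_step(network, state, params)
      delta <- param_change(params, new_params, network$n)
      params <- new_params
      if (delta < o$em_tol) {
        state <- run_bp(state, network, params, tol = o$tol,
                        max_iter = o$max_bp_iter, damping = o$damping,
                        inc = inc)
        iters <- c(iters, state$iterations)
        converged_em <- TRUE
        break
      }
    }
    f <- bethe_free_energy(network, state, params)
    cand <- list(params = params, state = state, f_bethe = f,
                 bp_iterations = iters,
                 converged = converged_em && state$max_change <= o$tol,
                 restart_index = r, seed = seed_r)
    if (is.null(best) || (is.finite(f) && f < best$f_bethe)) best <- cand
  }
  assignment <- max.col(best$state$marginal, ties.method = "first")
  best$assignment <- assignment
  best$n_effective <- length(unique(assignment))
  structure(best, class = "em_result")
}

#' @export
print.em_result <- function(x, ...) {
  cat(sprintf(
    "em_result: q = %d (%s), f_Bethe = %.6f, %s, restart %d, %d effective cluster(s)\n",
    x$params$q, x$params$model_kind, x$f_bethe,
    if (x$converged) "converged" else "NOT converged",
    x$restart_index, x$n_effective))
  invisible(x)
}

#' Serialize an EM result to JSON
#'
#' @param result an `em_result`.
#' @param network the `sbm_network` it was fitted to (for vertex labels).
#' @param path optional output path; when `NULL` the JSON string is returned.
#' @export
em_result_json <- function(result, network, path = NULL) {
  doc <- list(
    q = result$params$q,
    model_kind = result$params$model_kind,
    gamma = result$params$gamma,
    omega = result$params$omega,
    theta = result$params$theta,
    f_bethe = result$f_bethe,
    converged = result$converged,
    bp_iterations = result$bp_iterations,
    restart_index = result$restart_index,
    seed = result$seed,
    n_effective = result$n_effective,
    assignment = stats::setNames(as.list(result$assignment), network$labels))
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
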