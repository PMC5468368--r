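# Analytic LOOCV edge-prediction errors from BP cavity messages.
#
# All errors are cross-entropies per edge (nats), normalized so the leading
# constant is 1 in sparse networks; the non-edge contribution reduces to that
# constant, so every estimator is a sum over observed edges only. Reports
# also carry the constant-stripped value (the convention used for plotting,
# where the constant and O(1/N) terms are dropped).

se_of <- function(terms) {
  if (length(terms) < 2L) return(0)
  stats::sd(terms) / sqrt(length(terms))
}

# log(theta_i * omega * theta_j) decomposed: log-omega matrix plus per-edge
# endpoint offsets (zero for the standard model)
edge_log_offsets <- function(network, params) {
  if (is.null(params$theta)) return(numeric(network$L))
  lth <- ifelse(params$theta > 0, log(params$theta), -Inf)
  lth[network$edges[, 1L]] + lth[network$edges[, 2L]]
}

# sum_{ss'} F_{e s} B_{e s'} M_{ss'} for every edge, guarding 0 * log(0)
bilinear_terms <- function(Fm, Bm, M) {
  rowSums((Fm %*% M) * Bm)
}

log_omega_guarded <- function(omega) {
  lw <- log(omega)
  lw[omega == 0] <- 0   # zero-mass entries contribute 0; mass is checked
  lw
}

zero_mass_flag <- function(Fm, Bm, omega) {
  if (!any(omega == 0)) return(FALSE)
  any(bilinear_terms(Fm, Bm, (omega == 0) * 1) > 0)
}

#' Bayes prediction error (LOOCV)
#'
#' `E_Bayes = 1 - (1/L) sum_E log Z^{ij}`: the cavity identity
#' `p(sigma_i, sigma_j | A^{\\(i,j)}) = psi^{i->j} psi^{j->i}` makes the BP
#' pair normalizer the posterior predictive probability of each observed
#' edge, so the LOOCV estimate needs no refitting.
#'
#' @param network an `sbm_network`.
#' @param state a `bp_state` (cavity messages available).
#' @param params a `block_model_params`.
#' @return A list with `value`, `se` (per-edge standard error), and the
#'   per-edge `terms` `1 - log Z^{ij}`.
#' @export
bayes_error <- function(network, state, params) {
  eq <- edge_quantities(network, state, params)
  if (any(eq$Zij0 <= 0)) stop("non-positive pair normalizer Z^ij")
  terms <- 1 - eq$logZij
  list(value = mean(terms), se = se_of(terms), terms = terms)
}

#' Gibbs prediction error (LOOCV)
#'
#' `E_Gibbs = 1 - (1/L) sum_E sum_{ss'} psi^{i->j}_s psi^{j->i}_{s'}
#' log omega_{ss'}` (degree-corrected: `log(theta_i omega theta_j)`): the
#' cluster pair is drawn from the leave-one-out posterior and the edge scored
#' at those fixed assignments.
#'
#' @inheritParams bayes_error
#' @return A list with `value`, `se`, per-edge `terms`, and `infinite_mass`
#'   (TRUE when message mass sits on a zero affinity entry, making the error
#'   infinite).
#' @export
gibbs_error <- function(network, state, params) {
  L <- network$L
  Fm <- state$cav[seq_len(L), , drop = FALSE]
  Bm <- state$cav[L + seq_len(L), , drop = FALSE]
  flag <- zero_mass_flag(Fm, Bm, params$omega)
  terms <- 1 - bilinear_terms(Fm, Bm, log_omega_guarded(params$omega)) -
    edge_log_offsets(network, params)
  if (flag) terms <- rep(Inf, L)
  list(value = mean(terms), se = se_of(terms), terms = terms,
       infinite_mass = flag)
}

#' MAP estimate of the Gibbs prediction error
#'
#' [gibbs_error()] with each cavity bias replaced by the indicator of its
#' argmax cluster; ties break toward the lowest cluster index.
#'
#' @inheritParams bayes_error
#' @return As [gibbs_error()].
#' @export
map_error <- function(network, state, params) {
  L <- network$L; q <- params$q
  onehot <- function(m) {
    idx <- max.col(m, ties.method = "first")
    out <- matrix(0, nrow(m), q)
    out[cbind(seq_len(nrow(m)), idx)] <- 1
    out
  }
  Fm <- onehot(state$cav[seq_len(L), , drop = FALSE])
  Bm <- onehot(state$cav[L + seq_len(L), , drop = FALSE])
  flag <- zero_mass_flag(Fm, Bm, params$omega)
  terms <- 1 - bilinear_terms(Fm, Bm, log_omega_guarded(params$omega)) -
    edge_log_offsets(network, params)
  if (flag) terms <- rep(Inf, L)
  list(value = mean(terms), se = se_of(terms), terms = terms,
       infinite_mass = flag)
}

#' Gibbs training error
#'
#' `E_training = 1 - (1/L) sum_E sum_{ss'} [psi^{i->j}_s omega_{ss'}
#' psi^{j->i}_{s'} / Z^{ij}] log omega_{ss'}`: the average is over the
#' full-data pair posterior, so this measures goodness of fit, not
#' prediction.
#'
#' @inheritParams bayes_error
#' @return As [gibbs_error()].
#' @export
training_error <- function(network, state, params) {
  L <- network$L
  eq <- edge_quantities(network, state, params)
  flag <- any(params$omega == 0) &&
    any(bilinear_terms(eq$F, eq$B, params$omega * (params$omega == 0)) > 0)
  terms <- 1 -
    bilinear_terms(eq$F, eq$B, params$omega * log_omega_guarded(params$omega)) /
      eq$Zij0 -
    edge_log_offsets(network, params)
  list(value = mean(terms), se = se_of(terms), terms = terms,
       infinite_mass = flag)
}

#' Leave-one-vertex-out Bayes prediction error
#'
#' `E^v_Bayes = -(1/L) sum_i log Z^i`: hiding a vertex with all its incident
#' pair observations, the BP vertex normalizer is the predictive probability
#' of that whole star. Satisfies the exact identity
#' `f_Bethe = (c/2) (E^v_Bayes + 1 - E_Bayes) - c/2`.
#'
#' @param network an `sbm_network`.
#' @param state a `bp_state` with `logZi` populated (see
#'   [compute_marginals()]).
#' @return A scalar.
#' @export
lovo_bayes_error <- function(network, state) {
  if (is.null(state$logZi)) stop("state has no vertex normalizers")
  -sum(state$logZi) / network$L
}

#' q = 1 baseline errors
#'
#' With a single cluster all four errors coincide. Standard model:
#' `1 - log omega` with `omega = 2L / (N (N - 1))`. Degree-corrected null
#' (the configuration-style null with `p_ij = d_i d_j / 2L`):
#' `1 - (1/L) sum_i d_i log d_i + log(2L)` (with `0 log 0 = 0`); the two
#' coincide on regular graphs.
#'
#' @param network an `sbm_network` with `L >= 1`.
#' @param model_kind `"standard"` or `"degree_corrected"`.
#' @return A list with `value`, `se`, and per-edge `terms`.
#' @export
q1_baseline <- function(network, model_kind = c("standard",
                                                "degree_corrected")) {
  model_kind <- match.arg(model_kind)
  stopifnot(network$L >= 1)
  if (model_kind == "standard") {
    omega <- 2 * network$L / (network$n * (network$n - 1))
    terms <- rep(1 - log(omega), network$L)
  } else {
    d <- network$degrees
    e <- network$edges
    terms <- 1 - log(d[e[, 1L]] * d[e[, 2L]] / (2 * network$L))
  }
  list(value = mean(terms), se = se_of(terms), terms = terms)
}

#' Factorized (undetectable-regime) closed forms for the planted partition
#'
#' At the factorized point `psi^{i->j} = gamma` with affinity
#' `omega = (omega_in - omega_out) I + omega_out`:
#' `E_Bayes = 1 - log omega_out - log(1 + ((omega_in - omega_out)/omega_out)
#' sum gamma^2)` (equal to the q = 1 value, since the mean connection
#' probability is `omega_out + (omega_in - omega_out) sum gamma^2`), and
#' `E_Gibbs = 1 - log omega_out - log(omega_in/omega_out) sum gamma^2`
#' (strictly above the q = 1 value for 0 < epsilon < 1, by
#' `log(1 + x y) > y log(1 + x)`).
#'
#' @param spec a [planted_partition_params()] object (or any list with
#'   `omega_in`, `omega_out`).
#' @param gamma cluster fractions; defaults to the spec's.
#' @return A list with `e_bayes_factorized`, `e_gibbs_factorized`, and the
#'   matching `e_bayes_q1` (`= e_bayes_factorized`) and `e_gibbs_q1`
#'   baselines. `epsilon = 0` gives explicit `Inf`.
#' @export
planted_closed_forms <- function(spec, gamma = NULL) {
  if (is.null(gamma)) gamma <- spec$gamma
  oin <- spec$omega_in; oout <- spec$omega_out
  s2 <- sum(gamma^2)
  if (oout == 0) {
    return(list(e_bayes_factorized = Inf, e_gibbs_factorized = Inf,
                e_bayes_q1 = Inf, e_gibbs_q1 = Inf))
  }
  omega_bar <- oout + (oin - oout) * s2
  # 1 - log(oout) - log(1 + s2 (oin - oout)/oout) collapses to 1 - log(omega_bar)
  list(e_bayes_factorized = 1 - log(omega_bar),
       e_gibbs_factorized = 1 - log(oout) - s2 * log(oin / oout),
       e_bayes_q1 = 1 - log(omega_bar),
       e_gibbs_q1 = 1 - log(omega_bar))
}

#' Assemble the per-q cross-validation report
#'
#' Computes all four LOOCV errors, the leave-one-vertex-out Bayes error, the
#' Bethe free energy (with a per-vertex standard error from its
#' prediction-error decomposition), and convergence diagnostics for one
#' fitted model.
#'
#' @param network an `sbm_network`.
#' @param result an `em_result` from [run_em()].
#' @return A one-row `data.frame` with columns `q`, `e_bayes`, `se_bayes`,
#'   `e_gibbs`, `se_gibbs`, `e_map`, `se_map`, `e_training`, `se_training`,
#'   `e_v_bayes`, `f_bethe`, `se_f_bethe`, `converged`, `bp_iter_median`,
#'   `n_effective`; the constant-stripped convention is the same table minus
#'   1 on each error column (attribute `"stripped"`).
#' @export
cv_report <- function(network, result) {
  state <- result$state; params <- result$params
  eb <- bayes_error(network, state, params)
  eg <- gibbs_error(network, state, params)
  em <- map_error(network, state, params)
  et <- training_error(network, state, params)
  ev <- lovo_bayes_error(network, state)
  f <- bethe_free_energy(network, state, params)
  # per-vertex decomposition of f for a spread estimate:
  # f = mean_i t_i - c/2 with t_i = -log Z^i + (1/2) sum_{j in di} log Z^{ij}
  eqq <- edge_quantities(network, state, params)
  tv <- -state$logZi
  if (network$L > 0L) {
    half <- c(eqq$logZij, eqq$logZij) / 2
    idx <- c(network$edges[, 1L], network$edges[, 2L])
    agg <- tapply(half, idx, sum)
    tv[as.integer(names(agg))] <- tv[as.integer(names(agg))] + agg
  }
  out <- data.frame(
    q = params$q,
    e_bayes = eb$value, se_bayes = eb$se,
    e_gibbs = eg$value, se_gibbs = eg$se,
    e_map = em$value, se_map = em$se,
    e_training = et$value, se_training = et$se,
    e_v_bayes = ev,
    f_bethe = f, se_f_bethe = se_of(tv),
    converged = result$converged,
    bp_iter_median = stats::median(as.numeric(result$bp_iterations)),
    n_effective = result$n_effective)
  attr(out, "stripped") <-
    transform(out, e_bayes = e_bayes - 1, e_gibbs = e_gibbs - 1,
              e_map = e_map - 1, e_training = e_training - 1)
  out
}
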