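# Brute-force enumeration oracle for tiny graphs (N <= 10): exact
# posteriors, marginals, free energy, and exact leave-one-out predictive
# probabilities under the full dense block-model likelihood
#   p(A, sigma) = prod_i gamma_{sigma_i}
#                 prod_{i<j} w_{ij}^{A_ij} (1 - w_ij)^{1 - A_ij},
# with w_ij = omega_{sigma_i sigma_j} (times theta_i theta_j when degree
# corrected). Used as the ground-truth test oracle for the BP engine, which
# replaces the non-edge product by the mean-field term e^{-h}.

oracle_max_n <- 10L

# q^N assignment matrix and per-assignment log-likelihood pieces
oracle_enumerate <- function(network, params, include_nonedges = TRUE) {
  n <- network$n; q <- params$q
  if (n > oracle_max_n)
    stop("oracle refuses N > ", oracle_max_n, " (q^N enumeration)")
  grid <- as.matrix(expand.grid(rep(list(seq_len(q)), n)))
  th <- theta_or_ones(params, n)
  A <- matrix(FALSE, n, n)
  A[network$edges] <- TRUE
  A <- A | t(A)
  logp <- colSums(matrix(log(params$gamma)[t(grid)], nrow = n))
  # per-pair factor contributions, kept so they can be removed one at a time
  pair_terms <- list()
  pairs <- which(upper.tri(A), arr.ind = TRUE)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    w <- th[i] * params$omega * th[j]
    w[w > 1] <- 1
    term <- if (A[i, j]) {
      log(w)[cbind(grid[, i], grid[, j])]
    } else if (include_nonedges) {
      log1p(-w)[cbind(grid[, i], grid[, j])]
    } else rep(0, nrow(grid))
    pair_terms[[r]] <- term
    logp <- logp + term
  }
  list(grid = grid, logp = logp, pairs = pairs, pair_terms = pair_terms,
       A = A, theta = th)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Exact posterior marginals by enumeration
#'
#' Sums the full likelihood over all q^N assignments; marginals, pair
#' marginals, and the free energy `f = -(1/N) log sum_sigma p(A, sigma)`
#' follow by exact summation. Refuses N > 10.
#'
#' @param network an `sbm_network` with at most 10 vertices.
#' @param params a `block_model_params`.
#' @param include_nonedges include the `(1 - omega)` non-edge factors
#'   (the default, full dense likelihood); `FALSE` drops them (edge factors
#'   and prior only), which is the model BP solves exactly on trees when the
#'   field is negligible.
#' @return An object of class `oracle_result`: `marginal` (N x q),
#'   `pair_marginal(i, j)` accessor, `f` (free energy per vertex), `logZ`.
#' @export
exact_posterior <- function(network, params, include_nonedges = TRUE) {
  en <- oracle_enumerate(network, params, include_nonedges)
  lz <- logsumexp(en$logp)
  w <- exp(en$logp - lz)
  n <- network$n; q <- params$q
  marg <- matrix(0, n, q)
  for (i in seq_len(n))
    marg[i, ] <- vapply(seq_len(q),
                        function(s) sum(w[en$grid[, i] == s]), 0)
  pair_marginal <- function(i, j) {
    tab <- matrix(0, q, q)
    for (s in seq_len(q)) for (s2 in seq_len(q))
      tab[s, s2] <- sum(w[en$grid[, i] == s & en$grid[, j] == s2])
    tab
  }
  structure(list(marginal = marg, pair_marginal = pair_marginal,
                 f = -lz / n, logZ = lz, enum = en),
            class = "oracle_result")
}

#' Exact leave-one-out predictive probabilities and errors
#'
#' For each vertex pair, removes the (i, j) likelihood factor (parameters
#' held fixed, no refit), recomputes the pair posterior by enumeration, and
#' forms the posterior predictive `p(A_ij = 1 | A^{\\(i,j)}) =
#' sum omega-weighted pair posterior`. Also returns the exact
#' leave-one-vertex-out star predictives `p({A_ij}_j | A^{\\i})`.
#'
#' @inheritParams exact_posterior
#' @return A list: `predictive` (data.frame over all pairs: i, j, is_edge,
#'   p1 = p(A_ij = 1 | rest)), per-edge error terms and totals
#'   (`e_bayes_edges`, `e_gibbs_edges`, `e_map_edges`, `e_training_edges`,
#'   restricted to edges with the leading 1), `e_bayes_full` (the
#'   cross-entropy over edges and non-edges, normalized by L), `e_v_bayes`
#'   (exact
#'   leave-one-vertex-out error), and `cavity_pair(i, j)` giving the exact
#'   `p(sigma_i, sigma_j | A^{\\(i,j)})` table.
#' @export
exact_loocv <- function(network, params, include_nonedges = TRUE) {
  en <- oracle_enumerate(network, params, include_nonedges)
  q <- params$q; n <- network$n; L <- network$L
  th <- en$theta
  lzfull <- logsumexp(en$logp)
  wfull <- exp(en$logp - lzfull)
  npairs <- nrow(en$pairs)
  p1 <- numeric(npairs); is_edge <- logical(npairs)
  bayes_t <- gibbs_t <- map_t <- train_t <- numeric(npairs)
  cav_tabs <- vector("list", npairs)
  for (r in seq_len(npairs)) {
    i <- en$pairs[r, 1L]; j <- en$pairs[r, 2L]
    w_ij <- th[i] * params$omega * th[j]
    w_ij[w_ij > 1] <- 1
    lcav <- en$logp - en$pair_terms[[r]]
    lzc <- logsumexp(lcav)
    wc <- exp(lcav - lzc)
    tab <- matrix(0, q, q)
    for (s in seq_len(q)) for (s2 in seq_len(q))
      tab[s, s2] <- sum(wc[en$grid[, i] == s & en$grid[, j] == s2])
    cav_tabs[[r]] <- tab
    p1[r] <- sum(tab * w_ij)
    is_edge[r] <- en$A[i, j]
    lw <- log(w_ij); lw[w_ij == 0] <- 0
    gibbs_t[r] <- 1 - sum(tab * lw)
    mi <- which.max(rowSums(tab)); mj <- which.max(colSums(tab))
    map_t[r] <- 1 - lw[mi, mj]
    # full-data pair posterior for the training error
    ptab <- matrix(0, q, q)
    for (s in seq_len(q)) for (s2 in seq_len(q))
      ptab[s, s2] <- sum(wfull[en$grid[, i] == s & en$grid[, j] == s2])
    train_t[r] <- 1 - sum(ptab * lw)
    bayes_t[r] <- 1 - log(p1[r])
  }
  # exact leave-one-vertex-out: remove all factors involving vertex i
  ev_terms <- numeric(n)
  for (i in seq_len(n)) {
    drop <- which(en$pairs[, 1L] == i | en$pairs[, 2L] == i)
    lminus <- en$logp
    for (r in drop) lminus <- lminus - en$pair_terms[[r]]
    ev_terms[i] <- lzfull - logsumexp(lminus)  # log p({A_ij}_j | A^{\i})
  }
  e_full <- -(sum(log(p1[is_edge])) + sum(log(1 - p1[!is_edge]))) / max(L, 1)
  list(predictive = data.frame(i = en$pairs[, 1L], j = en$pairs[, 2L],
                               is_edge = is_edge, p1 = p1),
       e_bayes_edges = mean(bayes_t[is_edge]),
       e_gibbs_edges = mean(gibbs_t[is_edge]),
       e_map_edges = mean(map_t[is_edge]),
       e_training_edges = mean(train_t[is_edge]),
       terms = data.frame(bayes = bayes_t, gibbs = gibbs_t, map = map_t,
                          training = train_t)[is_edge, , drop = FALSE],
       e_bayes_full = e_full,
       e_v_bayes = -sum(ev_terms) / max(L, 1),
       cavity_pair = function(i, j) {
         r <- which(en$pairs[, 1L] == min(i, j) &
                    en$pairs[, 2L] == max(i, j))
         cav_tabs[[r]]
       })
}

#' Kullback-Leibler divergence
#'
#' `D_KL(p || r) = sum p log(p / r)`, requiring `r > 0` wherever `p > 0`;
#' non-negative and zero iff the distributions coincide.
#'
#' @param p,r non-negative vectors (or matrices) summing to 1 on the same
#'   support.
#' @return A scalar.
#' @export
kl_divergence <- function(p, r) {
  p <- as.vector(p); r <- as.vector(r)
  stopifnot(length(p) == length(r))
  if (any(p > 0 & r == 0)) stop("support violation: p > 0 where r = 0")
  pos <- p > 0
  sum(p[pos] * log(p[pos] / r[pos]))
}
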