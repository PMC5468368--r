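# Fixtures are generated in code: random trees, tiny block-model parameter
# sets at sparse scale, random message states, and label-matching helpers.

# random tree on n vertices (each vertex attaches to a uniform earlier one)
rand_tree_net <- function(n, seed) {
  set.seed(seed)
  edges <- cbind(2:n, vapply(2:n, function(i) sample.int(i - 1L, 1L), 1L))
  network_from_pairs(edges, n = n)
}

# connected sparse random graph: a tree plus `extra` random chords
rand_graph_net <- function(n, extra, seed) {
  set.seed(seed)
  edges <- cbind(2:n, vapply(2:n, function(i) sample.int(i - 1L, 1L), 1L))
  more <- cbind(sample.int(n, extra, replace = TRUE),
                sample.int(n, extra, replace = TRUE))
  network_from_pairs(rbind(edges, more), n = n)
}

# generic (asymmetric-in/out) block-model parameters at a given omega scale;
# scale ~1e-10 keeps the mean-field non-edge term negligible on tiny graphs
tiny_params <- function(q, seed, scale = 1e-10) {
  set.seed(seed)
  g <- stats::runif(q, 0.5, 1.5); g <- g / sum(g)
  om <- matrix(stats::runif(q * q, 1, 3), q, q)
  om <- (om + t(om)) / 2
  diag(om) <- diag(om) + 2
  block_model_params(q, g, om * scale)
}

# random valid message state (rows on the simplex) for a network
random_state <- function(network, q, seed) {
  set.seed(seed)
  cav <- matrix(stats::rgamma(2 * network$L * q, shape = 1), 2 * network$L, q)
  cav <- cav / rowSums(cav)
  structure(list(cav = cav, marginal = NULL, h = NULL, logZi = NULL,
                 iterations = 0L, max_change = NA_real_, resets = 0L),
            class = "bp_state")
}

# converged BP at fixed params
converged_state <- function(network, params, seed = 1, noise = 0.1,
                            tol = 1e-12, max_iter = 500) {
  st <- init_messages(network, params$q, seed = seed, params = params,
                      noise = noise)
  run_bp(st, network, params, tol = tol, max_iter = max_iter)
}

label_permutations <- function(q) {
  if (q == 1) return(list(1L))
  out <- list()
  for (p in label_permutations(q - 1))
    for (pos in 0:(q - 1))
      out[[length(out) + 1]] <- append(p, q, after = pos)
  out
}

# best overlap between an inferred assignment and the planted one
best_overlap <- function(assignment, sigma, q) {
  max(vapply(label_permutations(q),
             function(p) mean(p[assignment] == sigma), 0))
}

# deterministic graph with a given number of vertices and edges (first
# `L` pairs in lexicographic order): only N and L matter for q = 1 baselines
fixed_size_net <- function(n, L) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ord <- order(pairs[, 1], pairs[, 2])
  network_from_pairs(pairs[ord[seq_len(L)], c(1, 2)], n = n)
}
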