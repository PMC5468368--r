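#' Planted-partition parametrization
#'
#' Builds the affinity parameters of a planted-partition stochastic block
#' model: `omega_in` on the diagonal, `omega_out = epsilon * omega_in` off the
#' diagonal, scaled so that the expected mean degree (averaged over planted
#' assignments) equals `c`. For equal block sizes this reduces to
#' `omega_in = q * c / (N * (1 + (q - 1) * epsilon))`.
#'
#' @param q number of planted clusters.
#' @param block_sizes integer vector of per-cluster vertex counts (length q).
#' @param c target expected mean degree, > 0.
#' @param epsilon ratio `omega_out / omega_in` in \[0, 1\]; 0 gives fully
#'   disconnected clusters, 1 the uniform random graph.
#' @return An object of class `planted_partition_spec` with fields `q_star`,
#'   `block_sizes`, `n`, `gamma`, `c`, `epsilon`, `omega_in`, `omega_out`,
#'   `omega` (the q x q affinity matrix), `epsilon_star` (detectability
#'   threshold for the equal-block-size formula), and `sigma` (the planted
#'   assignment, blocks laid out contiguously).
#' @export
planted_partition_params <- function(q, block_sizes, c, epsilon) {
  stopifnot(q >= 1, length(block_sizes) == q, all(block_sizes >= 1),
            c > 0, epsilon >= 0, epsilon <= 1)
  n <- sum(block_sizes)
  gamma <- block_sizes / n
  s2 <- sum(gamma^2)
  # E[degree] = N * (omega_in * s2 + omega_out * (1 - s2)) for a random vertex
  omega_in <- c / (n * (s2 + epsilon * (1 - s2)))
  if (omega_in > 1)
    stop("mean degree too large for this size: omega_in > 1")
  omega_out <- epsilon * omega_in
  omega <- matrix(omega_out, q, q)
  diag(omega) <- omega_in
  structure(
    list(q_star = as.integer(q), block_sizes = as.integer(block_sizes),
         n = as.integer(n), gamma = gamma, c = c, epsilon = epsilon,
         omega_in = omega_in, omega_out = omega_out, omega = omega,
         epsilon_star = if (length(unique(block_sizes)) == 1L)
           detectability_threshold(q, c, quiet = TRUE) else NA_real_,
         sigma = rep.int(seq_len(q), block_sizes)),
    class = "planted_partition_spec"
  )
}

#' @export
print.planted_partition_spec <- function(x, ...) {
  cat(sprintf(
    "planted partition: q* = %d, N = %d, c = %g, epsilon = %.3g (epsilon* = %.3g)\n",
    x$q_star, x$n, x$c, x$epsilon, x$epsilon_star))
  cat(sprintf("  omega_in = %.4g, omega_out = %.4g\n", x$omega_in, x$omega_out))
  invisible(x)
}

#' Detectability threshold of the planted partition
#'
#' For q equal-size clusters with mean degree c, solves the threshold
#' condition `c_in - c_out = q * sqrt(c)` together with
#' `c = (c_in + (q - 1) * c_out) / q` and returns
#' `epsilon_star = c_out / c_in`, the ratio above which the planted structure
#' is statistically undetectable in the sparse limit.
#'
#' @param q number of equal-size clusters.
#' @param c mean degree, > 1.
#' @param quiet suppress the warning when no positive solution exists.
#' @return `epsilon_star` in \[0, 1\); 0 (with a warning) when `q * sqrt(c)`
#'   exceeds `q * c` so no positive `c_out` solves the system.
#' @export
detectability_threshold <- function(q, c, quiet = FALSE) {
  stopifnot(q >= 1, c > 0)
  gap <- q * sqrt(c)                 # c_in - c_out at the threshold
  c_out <- (q * c - gap) / q
  if (c_out <= 0) {
    if (!quiet) warning("no positive solution: threshold clamped to 0")
    return(0)
  }
  c_in <- c_out + gap
  c_out / c_in
}

#' Sample a planted-partition SBM network
#'
#' Each unordered vertex pair (i, j), i != j, is an edge independently with
#' probability `omega[sigma_i, sigma_j]`. Sampling is done per block pair by
#' drawing a Binomial count of edges and then sampling that many distinct
#' pairs, so the cost is O(N + L) rather than O(N^2).
#'
#' @param spec a [planted_partition_params()] object.
#' @param seed integer seed; the draw is bit-reproducible given the seed.
#' @return A list with `network` (an `sbm_network`) and `sigma` (planted
#'   assignments).
#' @export
sample_sbm <- function(spec, seed) {
  sample_dcsbm(spec, theta = NULL, seed = seed)
}

#' Sample a degree-corrected planted-partition network
#'
#' Pair (i, j) is an edge with probability `min(1, theta_i * omega * theta_j)`.
#' `theta` is normalized so that its mean within each planted block is 1
#' (the conventional identifiability constraint: `omega` carries the
#' block-pair scale). With `theta = NULL` (or all ones) the draw is identical,
#' including the random stream, to [sample_sbm()].
#'
#' @param spec a [planted_partition_params()] object.
#' @param theta per-vertex propensities, length N, non-negative; `NULL` for
#'   the standard model.
#' @param seed integer seed.
#' @return A list with `network`, `sigma`, and the block-normalized `theta`.
#' @export
sample_dcsbm <- function(spec, theta, seed) {
  stopifnot(inherits(spec, "planted_partition_spec"))
  n <- spec$n; sigma <- spec$sigma; q <- spec$q_star
  uniform_theta <- is.null(theta)
  if (!uniform_theta) {
    stopifnot(length(theta) == n, all(theta >= 0))
    # normalize: mean theta within each planted block = 1
    bm <- vapply(seq_len(q), function(b) mean(theta[sigma == b]), 0)
    if (any(bm == 0)) stop("a planted block has all-zero theta")
    theta <- theta / bm[sigma]
    if (all(theta == 1)) uniform_theta <- TRUE
  }
  if (!uniform_theta) {
    tmax_blk <- vapply(seq_len(q), function(b) max(theta[sigma == b]), 0)
    # count pairs whose clipped probability theta_i omega theta_j > 1
    nclip <- clipped_pair_count(theta, sigma, spec$omega)
    if (nclip > 0) {
      if (nclip > 0.01 * n * (n - 1) / 2)
        stop("theta_i * omega * theta_j > 1 for more than 1% of pairs")
      warning(sprintf("%d pair probabilities clipped at 1", nclip))
    }
  }
  block_of <- split(seq_len(n), sigma)
  set.seed(as.integer(seed))
  acc_i <- integer(0); acc_j <- integer(0)
  for (a in seq_len(q)) for (b in a:q) {
    va <- block_of[[a]]; vb <- block_of[[b]]
    om <- spec$omega[a, b]
    if (om <= 0) next
    # proposal probability bounding theta_i * om * theta_j over the block pair
    p_cap <- if (uniform_theta) om else min(1, om * tmax_blk[a] * tmax_blk[b])
    if (a == b) {
      m <- length(va)
      npair <- m * (m - 1) / 2
      if (npair == 0) next
      k <- stats::rbinom(1L, npair, p_cap)
      if (k == 0) next
      idx <- sample.int(npair, k)
      pr <- pair_from_index(idx, m)
      pi <- va[pr[, 1L]]; pj <- va[pr[, 2L]]
    } else {
      npair <- length(va) * length(vb)
      k <- stats::rbinom(1L, npair, p_cap)
      if (k == 0) next
      idx <- sample.int(npair, k) - 1L
      pi <- va[idx %/% length(vb) + 1L]
      pj <- vb[idx %% length(vb) + 1L]
    }
    if (!uniform_theta) {
      # thin candidates down to min(1, theta_i om theta_j)
      p_true <- pmin(1, theta[pi] * om * theta[pj])
      keep <- stats::runif(length(pi)) < p_true / p_cap
      pi <- pi[keep]; pj <- pj[keep]
    }
    acc_i <- c(acc_i, pi); acc_j <- c(acc_j, pj)
  }
  net <- network_from_pairs(cbind(acc_i, acc_j), n = n)
  list(network = net, sigma = sigma,
       theta = if (uniform_theta) rep(1, n) else theta)
}

# number of unordered pairs with theta_i * omega_{sigma_i sigma_j} * theta_j > 1,
# computed blockwise via sorted thresholds (no N^2 scan)
clipped_pair_count <- function(theta, sigma, omega) {
  q <- nrow(omega); total <- 0
  th_blk <- split(theta, sigma)
  for (a in seq_len(q)) for (b in a:q) {
    om <- omega[a, b]
    if (om <= 0) next
    ta <- sort(th_blk[[a]]); tb <- sort(th_blk[[b]])
    # pairs with ta_i * tb_j > 1/om
    thr <- 1 / om
    cnt <- sum(vapply(ta, function(x) {
      if (x <= 0) return(0L)
      length(tb) - findInterval(thr / x, tb)
    }, 0L))
    if (a == b) {
      diag_cnt <- sum(ta * ta > thr)
      cnt <- (cnt - diag_cnt) / 2
    }
    total <- total + cnt
  }
  total
}

# map linear indices 1..m(m-1)/2 to (row < col) pairs of 1..m, row-major
pair_from_index <- function(idx, m) {
  cum <- cumsum(c(0, seq(m - 1, 1)))          # pairs before each row
  i <- findInterval(idx - 0.5, cum)
  j <- i + (idx - cum[i])
  cbind(as.integer(i), as.integer(j))
}

#' Write a generated network and its planted assignment
#'
#' Writes the edge list and a two-column TSV (vertex_label, planted_cluster).
#'
#' @param sample a list as returned by [sample_sbm()].
#' @param edge_path path for the edge list.
#' @param sigma_path path for the planted-assignment TSV.
#' @export
write_planted_sample <- function(sample, edge_path, sigma_path) {
  write_edge_list(sample$network, edge_path)
  utils::write.table(
    data.frame(vertex_label = sample$network$labels,
               planted_cluster = sample$sigma),
    sigma_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
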