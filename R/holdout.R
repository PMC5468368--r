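# Holdout and K-fold cross-validation via BP that ignores the cavity
# messages sent by held-out edges: the held-out pairs are removed from the
# training network (they enter no neighbour product and are felt only
# through the generic non-edge field term), then scored with the messages
# their endpoints would send into the pair.

#' Select a holdout edge set
#'
#' Uniformly random subset of `round(fraction * L)` edges (at least one).
#' With `non_adjacent = TRUE` the edges are picked greedily from a random
#' permutation so that no two held-out edges share a vertex; failure to
#' reach the requested size is an error.
#'
#' @param network an `sbm_network`.
#' @param fraction holdout fraction in (0, 1).
#' @param non_adjacent forbid held-out edges sharing a vertex.
#' @param seed integer seed.
#' @param repeats number of independent re-draws used by [holdout_errors()].
#' @return An object of class `holdout_plan`: `held_out` (edge-row indices),
#'   `edges` (the pairs), `fraction`, `K = 1`, `non_adjacent`, `repeats`,
#'   `seed`.
#' @export
select_holdout <- function(network, fraction, non_adjacent = FALSE, seed = 1,
                           repeats = 1) {
  stopifnot(fraction > 0, fraction < 1, network$L >= 1)
  size <- max(1L, as.integer(round(fraction * network$L)))
  set.seed(as.integer(seed))
  held <- draw_holdout(network, size, non_adjacent)
  structure(list(held_out = held,
                 edges = network$edges[held, , drop = FALSE],
                 fraction = fraction, K = 1L, non_adjacent = non_adjacent,
                 repeats = as.integer(repeats), seed = as.integer(seed)),
            class = "holdout_plan")
}

draw_holdout <- function(network, size, non_adjacent) {
  if (!non_adjacent) return(sort(sample.int(network$L, size)))
  perm <- sample.int(network$L)
  used <- logical(network$n)
  held <- integer(0)
  for (e in perm) {
    i <- network$edges[e, 1L]; j <- network$edges[e, 2L]
    if (used[i] || used[j]) next
    held <- c(held, e); used[i] <- TRUE; used[j] <- TRUE
    if (length(held) == size) break
  }
  if (length(held) < size)
    stop("cannot select ", size, " pairwise non-adjacent held-out edges")
  sort(held)
}

# network with the given edge rows removed (vertex set unchanged)
drop_edges <- function(network, held) {
  network_from_pairs(network$edges[-held, , drop = FALSE], n = network$n,
                     labels = network$labels)
}

# score a held-out edge set from a model fitted on the reduced network:
# the marginals of the endpoints in the reduced network play the role of the
# cavity biases into the unobserved pair
score_holdout <- function(network, held, fit) {
  params <- fit$params; marg <- fit$state$marginal
  th <- theta_or_ones(params, network$n)
  lw <- log_omega_guarded(params$omega)
  q <- params$q
  vals <- vapply(held, function(e) {
    i <- network$edges[e, 1L]; j <- network$edges[e, 2L]
    f <- marg[i, ]; b <- marg[j, ]
    lth <- if (th[i] > 0 && th[j] > 0) log(th[i]) + log(th[j]) else -Inf
    Z0 <- sum(outer(f, b) * params$omega)
    bayes <- 1 - (log(Z0) + lth)
    gibbs <- 1 - sum(outer(f, b) * lw) - lth
    fi <- which.max(f); bi <- which.max(b)
    mape <- 1 - lw[fi, bi] - lth
    nu <- outer(f, b) * params$omega / Z0
    train <- 1 - sum(nu * lw) - lth
    c(bayes, gibbs, mape, train)
  }, numeric(4))
  rowMeans(matrix(vals, nrow = 4))
}

#' Holdout cross-validation errors via BP
#'
#' For each repeat, draws (or reuses) a held-out edge set, fits the model on
#' the network with those edges removed, and evaluates the four
#' cross-entropy errors over the held-out edges only; results are averaged
#' over repeats with across-repeat standard errors. For q = 1 all errors
#' equal the baseline regardless of the plan.
#'
#' @param network an `sbm_network`.
#' @param plan a [select_holdout()] plan.
#' @param q number of clusters.
#' @param opts engine options for [run_em()] (use `init_params` +
#'   `learn = FALSE` for fixed-parameter scoring).
#' @return A data.frame with one row per error (`bayes`, `gibbs`, `map`,
#'   `training`): mean `value`, across-repeat `se`, plus attributes
#'   `"per_repeat"` and `"n_holdout"`.
#' @export
holdout_errors <- function(network, plan, q, opts = list()) {
  per <- matrix(NA_real_, plan$repeats, 4)
  for (r in seq_len(plan$repeats)) {
    held <- if (r == 1L) plan$held_out else {
      set.seed((plan$seed + 613L * r) %% 2147483647L)
      draw_holdout(network, length(plan$held_out), plan$non_adjacent)
    }
    reduced <- drop_edges(network, held)
    fit <- run_em(reduced, q, opts)
    per[r, ] <- score_holdout(network, held, fit)
  }
  out <- data.frame(
    error = c("bayes", "gibbs", "map", "training"),
    value = colMeans(per),
    se = if (nrow(per) > 1) apply(per, 2, stats::sd) / sqrt(nrow(per))
         else rep(0, 4))
  attr(out, "per_repeat") <- per
  attr(out, "n_holdout") <- length(plan$held_out)
  out
}

#' K-fold cross-validation errors via BP
#'
#' Randomly partitions the edge set into K folds; each fold is held out in
#' turn (BP ignoring its cavity messages, as in [holdout_errors()]) and the
#' per-fold errors are averaged. Dependence among connected unobserved edges
#' is deliberately ignored; the number of adjacent held-out pairs per fold
#' is reported so the approximation can be judged.
#'
#' @param network an `sbm_network`.
#' @param K fold count, >= 2 (K = L reduces to per-edge holdout).
#' @param q number of clusters.
#' @param opts engine options for [run_em()].
#' @param seed integer seed for the fold assignment.
#' @return A data.frame as in [holdout_errors()], with attributes
#'   `"per_fold"` and `"adjacent_heldout_pairs"` (per fold).
#' @export
kfold_errors <- function(network, K, q, opts = list(), seed = 1) {
  stopifnot(K >= 2, K <= network$L)
  set.seed(as.integer(seed))
  fold <- sample(rep_len(seq_len(K), network$L))
  per <- matrix(NA_real_, K, 4)
  adj <- integer(K)
  for (k in seq_len(K)) {
    held <- which(fold == k)
    verts <- as.vector(network$edges[held, , drop = FALSE])
    adj[k] <- sum(duplicated(verts))
    reduced <- drop_edges(network, held)
    fit <- run_em(reduced, q, opts)
    per[k, ] <- score_holdout(network, held, fit)
  }
  out <- data.frame(
    error = c("bayes", "gibbs", "map", "training"),
    value = colMeans(per),
    se = apply(per, 2, stats::sd) / sqrt(K))
  attr(out, "per_fold") <- per
  attr(out, "adjacent_heldout_pairs") <- adj
  out
}

#' Serialize a holdout plan
#'
#' @param plan a `holdout_plan`.
#' @param network the network it refers to.
#' @param path output JSON path.
#' @export
write_holdout_plan <- function(plan, network, path) {
  doc <- list(fraction = plan$fraction, K = plan$K,
              non_adjacent = plan$non_adjacent, repeats = plan$repeats,
              seed = plan$seed,
              held_out_edges = data.frame(
                from = network$labels[plan$edges[, 1L]],
                to = network$labels[plan$edges[, 2L]]))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, dataframe = "rows"),
             path)
  invisible(path)
}
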