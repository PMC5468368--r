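test_that("all errors collapse to 1 - log omega at q = 1", {
  net <- rand_graph_net(20, 10, seed = 1)
  om <- 0.07
  params <- block_model_params(1, 1, matrix(om, 1, 1))
  st <- compute_marginals(init_messages(net, 1, seed = 1), net, params)
  expected <- 1 - log(om)
  expect_equal(bayes_error(net, st, params)$value, expected, tolerance = 1e-12)
  expect_equal(gibbs_error(net, st, params)$value, expected, tolerance = 1e-12)
  expect_equal(map_error(net, st, params)$value, expected, tolerance = 1e-12)
  expect_equal(training_error(net, st, params)$value, expected,
               tolerance = 1e-12)
  # leave-one-vertex-out closed form: (N^2 omega - 2L log omega) / L
  expect_equal(lovo_bayes_error(net, st),
               (net$n^2 * om - 2 * net$L * log(om)) / net$L,
               tolerance = 1e-9)
})

test_that("one-hot messages make Gibbs, MAP, and training coincide", {
  net <- rand_graph_net(14, 6, seed = 3)
  params <- tiny_params(3, seed = 2, scale = 1e-3)
  st <- random_state(net, 3, seed = 4)
  idx <- max.col(st$cav)
  st$cav[] <- 0
  st$cav[cbind(seq_len(nrow(st$cav)), idx)] <- 1
  g <- gibbs_error(net, st, params)
  m <- map_error(net, st, params)
  t <- training_error(net, st, params)
  expect_equal(g$value, m$value, tolerance = 1e-12)
  expect_equal(g$value, t$value, tolerance = 1e-12)
  expect_equal(g$terms, m$terms, tolerance = 1e-12)
})

test_that("MAP tie-breaking picks the lowest cluster index", {
  net <- network_from_pairs(cbind(1, 2), n = 2)
  om <- matrix(c(4e-3, 1e-3, 1e-3, 2e-3), 2, 2)
  params <- block_model_params(2, c(0.5, 0.5), om)
  st <- init_messages(net, 2, seed = 1, noise = 0)  # exactly uniform: a tie
  expect_equal(map_error(net, st, params)$value, 1 - log(om[1, 1]),
               tolerance = 1e-12)
})

test_that("the inequality chain holds exactly at arbitrary message states", {
  net <- rand_graph_net(9, 3, seed = 6)   # >= 10 edges
  for (r in 1:100) {
    params <- tiny_params(2 + r %% 2, seed = 1000 + r, scale = 1e-3)
    st <- random_state(net, params$q, seed = r)
    eb <- bayes_error(net, st, params)$value
    eg <- gibbs_error(net, st, params)$value
    et <- training_error(net, st, params)$value
    expect_lte(et, eb + 1e-12)
    expect_lte(eb, eg + 1e-12)
  }
})

test_that("the Bethe identity links the two Bayes errors exactly", {
  net <- rand_graph_net(22, 9, seed = 8)
  params <- tiny_params(3, seed = 5, scale = 2e-3)
  st <- converged_state(net, params, seed = 3)
  cavg <- 2 * net$L / net$n
  f <- bethe_free_energy(net, st, params)
  eb <- bayes_error(net, st, params)$value
  ev <- lovo_bayes_error(net, st)
  expect_equal(f, (cavg / 2) * (ev + 1 - eb) - cavg / 2, tolerance = 1e-12)
})

test_that("all criteria are invariant under cluster-label permutation", {
  net <- rand_graph_net(16, 7, seed = 9)
  params <- tiny_params(3, seed = 7, scale = 1e-3)
  st <- random_state(net, 3, seed = 11)
  st <- compute_marginals(st, net, params)
  base <- c(bayes_error(net, st, params)$value,
            gibbs_error(net, st, params)$value,
            map_error(net, st, params)$value,
            training_error(net, st, params)$value,
            lovo_bayes_error(net, st))
  p <- c(3, 1, 2)
  pp <- block_model_params(3, params$gamma[p], params$omega[p, p])
  stp <- st
  stp$cav <- st$cav[, p]
  stp <- compute_marginals(stp, net, pp)
  perm <- c(bayes_error(net, stp, pp)$value,
            gibbs_error(net, stp, pp)$value,
            map_error(net, stp, pp)$value,
            training_error(net, stp, pp)$value,
            lovo_bayes_error(net, stp))
  expect_equal(perm, base, tolerance = 1e-10)
})

test_that("per-edge standard errors behave like standard errors", {
  net <- rand_graph_net(20, 10, seed = 12)
  params <- tiny_params(2, seed = 3, scale = 1e-3)
  st <- random_state(net, 2, seed = 13)
  for (f in list(bayes_error, gibbs_error, map_error, training_error)) {
    r <- f(net, st, params)
    expect_gte(r$se, 0)
    expect_equal(r$se, stats::sd(r$terms) / sqrt(net$L), tolerance = 1e-12)
  }
  # identical per-edge terms give SE = 0
  b <- q1_baseline(net, "standard")
  expect_equal(b$se, 0)
})

test_that("q = 1 baselines match their closed forms", {
  karate_sized <- fixed_size_net(34, 78)
  b <- q1_baseline(karate_sized, "standard")
  expect_equal(round(b$value - 1, 2), 1.97)   # the -log omega term

  # regular graph: degree-corrected null coincides with 1 - 2 log d + log 2L
  ring <- network_from_pairs(cbind(1:12, c(2:12, 1)), n = 12)
  dc <- q1_baseline(ring, "degree_corrected")
  expect_equal(dc$value, 1 - 2 * log(2) + log(2 * ring$L), tolerance = 1e-12)
  std <- q1_baseline(ring, "standard")
  # the two null models differ only via N vs N - 1 in the pair count
  expect_lt(abs(std$value - dc$value), log(ring$n / (ring$n - 1)) + 1e-12)

  tiny <- network_from_pairs(cbind(1, 2), n = 2)
  expect_equal(q1_baseline(tiny, "standard")$value, 1)
})

test_that("factorized messages reproduce the planted-partition closed forms", {
  spec <- planted_partition_params(3, c(40, 30, 30), 5, 0.3)
  net <- sample_sbm(spec, seed = 5)$network
  g <- spec$gamma
  params <- block_model_params(3, g, spec$omega)
  st <- init_messages(net, 3, seed = 1, params = params, noise = 0)
  st$cav <- matrix(g, 2 * net$L, 3, byrow = TRUE)
  cf <- planted_closed_forms(spec)
  expect_equal(bayes_error(net, st, params)$value, cf$e_bayes_factorized,
               tolerance = 1e-12)
  expect_equal(gibbs_error(net, st, params)$value, cf$e_gibbs_factorized,
               tolerance = 1e-12)
})

test_that("undetectable-regime equalities and inequalities hold over epsilon", {
  for (eps in seq(0.05, 0.95, by = 0.05)) {
    spec <- planted_partition_params(2, rep(500, 2), 8, eps)
    cf <- planted_closed_forms(spec)
    expect_equal(cf$e_bayes_factorized, cf$e_bayes_q1, tolerance = 0)
    expect_gt(cf$e_gibbs_factorized, cf$e_gibbs_q1)
  }
  one <- planted_partition_params(2, rep(500, 2), 8, 1)
  cf1 <- planted_closed_forms(one)
  expect_equal(cf1$e_gibbs_factorized, 1 - log(one$omega_in), tolerance = 1e-12)
  expect_equal(cf1$e_bayes_factorized, 1 - log(one$omega_in), tolerance = 1e-12)
  zero <- planted_partition_params(2, rep(500, 2), 8, 0)
  expect_identical(planted_closed_forms(zero)$e_bayes_factorized, Inf)
})

test_that("degree-corrected errors substitute theta omega theta throughout", {
  net <- rand_graph_net(12, 6, seed = 15)
  q <- 2
  set.seed(16)
  theta <- stats::runif(net$n, 0.5, 1.5)
  om <- matrix(c(3, 1, 1, 2), 2, 2) * 1e-3
  pdc <- block_model_params(q, c(0.6, 0.4), om, theta)
  st <- random_state(net, q, seed = 17)
  st <- compute_marginals(st, net, pdc)
  lth <- log(theta[net$edges[, 1]]) + log(theta[net$edges[, 2]])
  pstd <- block_model_params(q, c(0.6, 0.4), om)
  st_std <- st
  st_std <- compute_marginals(st_std, net, pstd)
  # same cavity messages: DC per-edge terms are the standard ones shifted by
  # -log(theta_i theta_j)
  g_dc <- gibbs_error(net, st, pdc)$terms
  g_std <- gibbs_error(net, st_std, pstd)$terms
  expect_equal(g_dc, g_std - lth, tolerance = 1e-12)
  b_dc <- bayes_error(net, st, pdc)$terms
  b_std <- bayes_error(net, st_std, pstd)$terms
  expect_equal(b_dc, b_std - lth, tolerance = 1e-12)
  # chain still holds
  expect_lte(training_error(net, st, pdc)$value,
             bayes_error(net, st, pdc)$value + 1e-12)
  expect_lte(bayes_error(net, st, pdc)$value,
             gibbs_error(net, st, pdc)$value + 1e-12)
})

test_that("cv_report assembles consistent rows with both conventions", {
  spec <- planted_partition_params(2, rep(50, 2), 4, 0.2)
  s <- sample_sbm(spec, seed = 7)
  res <- run_em(s$network, 2, list(restarts = 1, max_bp_iter = 60,
                                   max_em_iter = 10, seed = 5))
  rep <- cv_report(s$network, res)
  expect_equal(rep$q, 2)
  stripped <- attr(rep, "stripped")
  expect_equal(stripped$e_bayes, rep$e_bayes - 1)
  expect_equal(rep$f_bethe, res$f_bethe)
  expect_true(all(is.finite(unlist(rep[, sapply(rep, is.numeric)]))))
})
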