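test_that("path coefficients recover generating coefficients on raw scale", {
  # single cross-link 1 -> 2 at lag 1, coefficient 0.5; innovations unit
  # variance, so the raw-scale regression coefficient estimates 0.5
  m <- make_var_model(2, data.frame(source = 1, target = 2, lag = 1,
                                    coefficient = 0.5))
  s <- preprocess(simulate_process(m, 2000, seed = 31), standardize = FALSE)
  g <- run_pcmci(preprocess(s), tau_max = 2, alpha = 0.01)
  phi <- fit_path_coefficients(s, g)
  expect_equal(phi$phi[2, 1, 2], 0.5, tolerance = 0.05)
  expect_true(all(phi$phi[, , 1] == 0))  # no contemporaneous coefficients
  # zero where no link was discovered
  expect_true(all(phi$phi[1, 2, ] == 0))

  sa <- preprocess(simulate_process(ar1_model(0.6), 2000, seed = 32),
                   standardize = FALSE)
  ga <- run_pcmci(preprocess(sa), tau_max = 2, alpha = 0.01)
  phia <- fit_path_coefficients(sa, ga)
  expect_equal(phia$phi[1, 1, 2], 0.6, tolerance = 0.05)
})

test_that("an empty graph yields an all-zero coefficient array", {
  s <- preprocess(simulate_process(make_var_model(3), 300, seed = 33))
  g <- run_pcmci(s, tau_max = 2, alpha = 1e-12)  # retain nothing
  phi <- fit_path_coefficients(s, g)
  expect_true(all(phi$phi == 0))
  psi <- causal_effect_matrices(phi)
  expect_equal(psi$psi[, , 1], diag(3), ignore_attr = TRUE)
  expect_true(all(psi$psi[, , -1] == 0))
})

test_that("effect accumulation reproduces hand-computed path products", {
  # single link: effect equals the coefficient at its lag, nothing later
  phi1 <- array(0, dim = c(2, 2, 2)); phi1[2, 1, 2] <- 0.5
  psi1 <- causal_effect_matrices(phi1, tau_max = 4)$psi
  expect_equal(psi1[2, 1, 2], 0.5)
  expect_true(all(psi1[2, 1, 3:5] == 0))
  # chain: product of the branch coefficients at the summed lag
  psi_c <- causal_effect_matrices(chain_phi())$psi
  expect_equal(psi_c[3, 1, 3], 0.2)
  # autolink route: 1 -> 1 -> 2 contributes phi_auto * phi_cross at lag 2
  phi2 <- array(0, dim = c(2, 2, 2))
  phi2[1, 1, 2] <- 0.7; phi2[2, 1, 2] <- 0.5
  psi2 <- causal_effect_matrices(phi2, tau_max = 2)$psi
  expect_equal(psi2[2, 1, 3], 0.35)
})

test_that("recursion agrees with the impulse-propagation oracle", {
  for (r in 1:25) {
    m <- random_stable_model(sample(2:5, 1), sample(1:5, 1),
                             n_cross = sample(2:6, 1), seed = 100 + r)
    phi <- causalts:::phi_array(m)
    tau_max <- 6
    psi <- causal_effect_matrices(phi, tau_max)$psi
    expect_lt(max(abs(psi - impulse_response_oracle(phi, tau_max))), 1e-10)
  }
})

test_that("blocking a mediator removes exactly the mediated share", {
  # chain: everything 1 -> 3 flows through 2
  mk <- mediated_causal_effect(chain_phi(), 2)
  expect_equal(mk$mce[3, 1, 3], mk$psi[3, 1, 3])
  expect_equal(mk$psi_blocked[3, 1, 3], 0)
  # node 1 is on no path between 2 and 3
  mk1 <- mediated_causal_effect(chain_phi(), 1)
  expect_true(all(mk1$mce[3, 2, ] == 0))
  # diamond: per-branch products, summing to the total
  mk2 <- mediated_causal_effect(diamond_phi(), 2, tau_max = 2)
  mk3 <- mediated_causal_effect(diamond_phi(), 3, tau_max = 2)
  expect_equal(mk2$mce[4, 1, 3], 0.20)
  expect_equal(mk3$mce[4, 1, 3], 0.12)
  total <- causal_effect_matrices(diamond_phi(), tau_max = 2)$psi[4, 1, 3]
  expect_equal(mk2$mce[4, 1, 3] + mk3$mce[4, 1, 3], total)
})

test_that("negative effects keep their sign end-to-end", {
  phi <- array(0, dim = c(3, 3, 2))
  phi[2, 1, 2] <- -0.5; phi[3, 2, 2] <- 0.4
  psi <- causal_effect_matrices(phi, tau_max = 2)$psi
  expect_equal(psi[3, 1, 3], -0.2)
  mk <- mediated_causal_effect(phi, 2, tau_max = 2)
  expect_equal(mk$mce[3, 1, 3], -0.2)
  med <- mediation_graph(phi, 1, 3, 2)
  expect_equal(med$ce, -0.2)
  expect_equal(med$nodes$mce[med$nodes$component == 2], -0.2)
})

test_that("aggregates match brute-force enumeration over the effect matrices", {
  set.seed(34)
  phi <- array(0, dim = c(4, 4, 4))
  phi[, , 2:4] <- rbinom(48, 1, 0.3) * runif(48, -0.5, 0.5)
  for (s in 2:4) diag(phi[, , s]) <- diag(phi[, , s]) * 0.5
  tau_max <- 5
  agg <- aggregate_measures(phi, tau_max)
  psi <- causal_effect_matrices(phi, tau_max)$psi
  ce_max <- matrix(0, 4, 4)
  for (j in 1:4) for (i in 1:4) ce_max[j, i] <- max(abs(psi[j, i, 2:6]))
  expect_equal(unname(agg$ce_max), ce_max)
  for (i in 1:4) {
    expect_equal(unname(agg$ace[i]), mean(ce_max[setdiff(1:4, i), i]))
    expect_equal(unname(agg$acs[i]), mean(ce_max[i, setdiff(1:4, i)]))
  }
})

test_that("ACE/ACS place a single link's influence where it belongs", {
  phi <- array(0, dim = c(3, 3, 2)); phi[2, 1, 2] <- 0.5
  agg <- aggregate_measures(phi, tau_max = 2)
  expect_equal(unname(agg$ace), c(0.25, 0, 0))
  expect_equal(unname(agg$acs), c(0, 0.25, 0))
  # chain: only the middle node mediates
  aggc <- aggregate_measures(chain_phi(), tau_max = 2)
  expect_gt(aggc$amce[2], 0)
  expect_equal(unname(aggc$amce[c(1, 3)]), c(0, 0))
  expect_equal(unname(aggc$c_k_cardinality), c(0L, 1L, 0L))
  expect_error(aggregate_measures(array(0.1, c(1, 1, 2))), "at least 2")
})

test_that("mediation subgraphs contain exactly the on-path structure", {
  med <- mediation_graph(chain_phi(), 1, 3, 2)
  expect_equal(med$ce, 0.2)
  expect_equal(nrow(med$nodes), 3)
  expect_equal(med$nodes$offset, c(2, 1, 0))
  expect_equal(nrow(med$edges), 2)
  # no connecting path: empty result, zero effect, not an error
  none <- mediation_graph(chain_phi(), 3, 1, 2)
  expect_equal(none$ce, 0)
  expect_equal(nrow(none$nodes), 0)
  expect_equal(igraph::vcount(mediation_igraph(none)), 0)
  # diamond: both branches present with per-branch mediated effects
  medd <- mediation_graph(diamond_phi(), 1, 4, 2)
  expect_setequal(medd$nodes$component, 1:4)
  expect_equal(medd$nodes$mce[medd$nodes$component == 2], 0.20)
  expect_equal(medd$nodes$mce[medd$nodes$component == 3], 0.12)
  ig <- mediation_igraph(medd)
  expect_equal(igraph::vcount(ig), 4)
  expect_equal(igraph::ecount(ig), 4)
})

test_that("decomposed transfer entropy follows the graph's condition sets", {
  # single Gaussian link 1 -> 2 at lag 1 with correlation rho: the lag-1
  # term estimates -0.5 * log(1 - rho^2), other lags are ~0
  c0 <- 0.75  # gives corr rho = c0 / sqrt(1 + c0^2) ~ 0.6
  m <- make_var_model(2, data.frame(source = 1, target = 2, lag = 1,
                                    coefficient = c0))
  s <- preprocess(simulate_process(m, 800, seed = 35))
  g <- run_pcmci(s, tau_max = 3, alpha = 0.01)
  rho2 <- c0^2 / (1 + c0^2)
  out <- decomposed_transfer_entropy(s, g, 1, 2, tau_star = 3,
                                     knn = knn_config(k = 10, seed = 2))
  expect_lt(abs(out$terms$cmi[1] - (-0.5 * log(1 - rho2))), 0.07)
  expect_lt(sum(abs(out$terms$cmi[2:3])), 0.1)
  # absent coupling: DTE ~ 0
  out0 <- decomposed_transfer_entropy(s, g, 2, 1, tau_star = 3,
                                      knn = knn_config(k = 10, seed = 2))
  expect_lt(abs(out0$dte), 0.1)
})

test_that("irrelevant components do not change the transfer entropy", {
  set.seed(36)
  c0 <- 0.75
  m2 <- make_var_model(2, data.frame(source = 1, target = 2, lag = 1,
                                     coefficient = c0))
  s2 <- preprocess(simulate_process(m2, 600, seed = 37))
  g2 <- run_pcmci(s2, tau_max = 2, alpha = 0.01)
  d2 <- decomposed_transfer_entropy(s2, g2, 1, 2, 2,
                                    knn = knn_config(k = 10, seed = 3))
  # the same realization plus an unconnected AR(1) bystander component
  bys <- preprocess(simulate_process(ar1_model(0.5), 600, seed = 38))
  s3 <- roi_ts(cbind(s2$values, bys$values), c("X1", "X2", "X3"))
  g3 <- run_pcmci(s3, tau_max = 2, alpha = 0.01)
  d3 <- decomposed_transfer_entropy(s3, g3, 1, 2, 2,
                                    knn = knn_config(k = 10, seed = 3))
  expect_equal(d3$dte, d2$dte, tolerance = 0.08)
})
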