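test_that("fixation probability reproduces the diffusion formula and limits", {
  expect_equal(fixation_probability(100, 0), 1 / 200)
  expect_equal(fixation_probability(1000, 0), 1 / 2000)
  expect_equal(fixation_probability(100, 0.01), 0.02017, tolerance = 1e-3)
  ## strongly beneficial: P_fix -> 2 df
  expect_equal(fixation_probability(1e6, 0.01) / 0.02, 1, tolerance = 1e-2)
  expect_identical(fixation_probability(100, Inf), 1)
  expect_identical(fixation_probability(100, -Inf), 0)
  ## continuity across the series switch
  eps <- c(-1e-7, -1e-9, 0, 1e-9, 1e-7)
  p <- fixation_probability(100, eps)
  expect_true(all(diff(p) > 0))
  expect_equal(p, rep(1 / 200, 5), tolerance = 1e-4)
})

test_that("rate matrix reduces to the mutation generator at neutrality", {
  bm <- baseline_binding()
  for (theta in c(0, 0.15)) {
    mut <- mutation_model(theta = theta)
    U <- unclass(combined_rate_matrix(7, mut))
    R <- build_rate_matrix(bm, fitness_spec(0), mut, make_pop(0))
    expect_equal(unclass(as.matrix(R)), U, ignore_attr = TRUE,
                 tolerance = 1e-15)
  }
})

test_that("rate matrix is a generator with selection-driven asymmetry", {
  bm <- baseline_binding()
  for (Ns in c(-100, 0, 10, 100)) for (theta in c(0, 0.15)) {
    R <- build_rate_matrix(bm, fitness_spec(Ns / 1000),
                           mutation_model(theta = theta), make_pop(Ns))
    expect_equal(colSums(as.matrix(R)), rep(0, 8), ignore_attr = TRUE,
                 tolerance = 1e-9)
    offd <- as.matrix(R); diag(offd) <- 0
    expect_true(all(offd >= 0))
  }
  R <- build_rate_matrix(bm, fitness_spec(0.1), mutation_model(), make_pop(100))
  expect_gt(R[2, 3] / R[3, 2], 1e10)  # beneficial 2->1 vs deleterious 1->2
})

test_that("stationary distribution: neutral binomial and weak-selection closed form", {
  bm <- baseline_binding()
  mut <- mutation_model(theta = 0)
  psi0 <- stationary_distribution(
    build_rate_matrix(bm, fitness_spec(0), mut, make_pop(0)))
  expect_equal(psi0, dbinom(0:7, 7, 3 / 4), ignore_attr = TRUE,
               tolerance = 1e-12)
  pop <- make_pop(100, N = 1e12)
  R <- build_rate_matrix(bm, fitness_spec(pop$s), mut, pop)
  expect_equal(stationary_distribution(R),
               stationary_closed_form(bm, fitness_spec(pop$s), pop),
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("stationary distribution is bimodal below the selection threshold", {
  bm <- baseline_binding()
  pop <- make_pop(2, N = 1e8)   # just below the n log(2)/2 ~ 2.4 threshold
  psi <- stationary_distribution(
    build_rate_matrix(bm, fitness_spec(pop$s), mutation_model(theta = 0), pop))
  locmax <- which(diff(sign(diff(c(-1, psi, -1)))) == -2) - 1L
  expect_length(locmax, 2L)
  expect_lte(locmax[1], 1L)            # fit attractor near k = 0
  expect_true(locmax[2] %in% 4:6)      # entropy attractor near 3n/4
})

test_that("propagation conserves probability and relaxes to stationarity", {
  bm <- baseline_binding()
  mut <- mutation_model(theta = 0.15)
  pop <- make_pop(100)
  R <- build_rate_matrix(bm, fitness_spec(pop$s), mut, pop)
  psi_hat <- stationary_distribution(R)
  expect_equal(propagate(R, 5, 0), replace(numeric(8), 6, 1),
               ignore_attr = TRUE)
  traj <- propagate(R, 5, c(0.001, 0.01, 0.1, 1, 1000))
  expect_equal(colSums(traj), rep(1, 5), ignore_attr = TRUE, tolerance = 1e-9)
  expect_lt(sum(abs(traj[, 5] - psi_hat)), 1e-6)
  kl <- apply(traj, 2L, kl_divergence, q = psi_hat)
  expect_true(all(diff(kl) < 0))       # monotone approach in KL divergence
})

test_that("convergence rate matches the two-state closed form", {
  r <- 0.37
  expect_equal(convergence_rate(matrix(c(-r, r, r, -r), 2)), 2 * r)
})

test_that("relaxation slows with binding site length", {
  mut <- mutation_model(theta = 0.15)
  l2 <- vapply(c(7, 9, 11), function(n) {
    pop <- make_pop(100)
    convergence_rate(build_rate_matrix(binding_model(n, 2, 4),
                                       fitness_spec(pop$s), mut, pop))
  }, numeric(1))
  expect_true(all(diff(l2) < 0))
})

test_that("hitting times solve the first-passage system", {
  bm <- baseline_binding()
  mut <- mutation_model(theta = 0)
  pop <- make_pop(100)
  R <- build_rate_matrix(bm, fitness_spec(pop$s), mut, pop)
  ht <- hitting_times(R, 0:1)
  expect_equal(ht$times[1:2], c(0, 0), ignore_attr = TRUE)
  expect_true(all(diff(ht$times[3:8]) > 0))  # farther classes take longer
  ## two-state chain with rate r into the target waits 1/r
  r <- 0.2
  R2 <- matrix(c(-1e-9, 1e-9, r, -r), 2)
  expect_equal(hitting_times(R2, 0)$times[2], 1 / r, ignore_attr = TRUE)
  ## arbitrary single-class targets are supported
  h01 <- hitting_times(R, 0)
  expect_gt(h01$times[2], 0)
})

test_that("exact, tridiagonal and shortest-path solvers agree", {
  bm <- baseline_binding()
  mut <- mutation_model(theta = 0)
  ## gain under positive, loss under negative selection
  pop <- make_pop(100)
  R <- build_rate_matrix(bm, fitness_spec(pop$s), mut, pop)
  ex <- hitting_times(R, 0:1)$times[3:8]
  td <- hitting_times_tridiagonal(R, target = 0:1)$times[3:8]
  expect_equal(td, ex, tolerance = 1e-10)
  popn <- make_pop(-100)
  Rn <- build_rate_matrix(bm, fitness_spec(popn$s), mut, popn)
  exl <- hitting_times(Rn, 3:7)$times[1:3]
  tdl <- hitting_times_tridiagonal(Rn, target = 3:7)$times[1:3]
  expect_equal(tdl, exl, tolerance = 1e-10)
  ## shortest path approaches the exact times as selection strengthens
  pop4 <- make_pop(1e4, N = 1e6)
  R4 <- build_rate_matrix(bm, fitness_spec(pop4$s), mut, pop4)
  sp <- hitting_times_shortest_path(R4, 0:1)$times[3:8]
  ex4 <- hitting_times(R4, 0:1)$times[3:8]
  expect_equal(sp / ex4, rep(1, 6), ignore_attr = TRUE, tolerance = 5e-3)
  expect_error(hitting_times_tridiagonal(
    build_rate_matrix(bm, fitness_spec(0.1), mutation_model(theta = 0.15),
                      make_pop(100)), target = 0:1), "tridiagonal")
})

test_that("detailed balance holds for tridiagonal chains", {
  bm <- baseline_binding()
  mut <- mutation_model(theta = 0)
  for (Ns in c(0, 10, 100)) {
    pop <- make_pop(Ns)
    R <- build_rate_matrix(bm, fitness_spec(pop$s), mut, pop)
    psi <- stationary_distribution(R)
    flux <- vapply(1:7, function(k)
      R[k + 1, k] * psi[k] - R[k, k + 1] * psi[k + 1], numeric(1))
    expect_equal(flux, rep(0, 7), ignore_attr = TRUE, tolerance = 1e-10)
  }
})

test_that("strong-selection threshold formulas evaluate correctly", {
  th <- ns_strong_selection_threshold(7)
  expect_equal(th$linear, 7 * log(2) / 2, tolerance = 1e-12)
  expect_equal(th$linear, 2.426, tolerance = 1e-3)
  expect_equal(th$full, 2.162, tolerance = 1e-3)
  th_big <- ns_strong_selection_threshold(200)
  expect_equal(th_big$full / th_big$linear, 1, tolerance = 0.02)
})

test_that("bimodality threshold matches a hand-solved toy chain and scales with n", {
  mut <- mutation_model(theta = 0)
  ## n = 1 step landscape: non-strong mass 3 e^{-4 Ns pi(0)} / (1 + same),
  ## solvable by hand for the 5% threshold
  bm1 <- binding_model(1, 4, 2)
  expect_equal(bimodality_threshold(bm1, mut, power_law_gamma = Inf),
               log(3 * 19) / (4 * occupancy(0, bm1)), tolerance = 1e-3)
  thr <- vapply(seq(5, 15, 2), function(n)
    bimodality_threshold(binding_model(n, 2, 4), mut), numeric(1))
  slope <- stats::coef(stats::lm(thr ~ seq(5, 15, 2)))[[2]]
  expect_equal(slope, log(2) / 2, tolerance = 0.3)
  ## at double the threshold the non-strong mass is well under 5%
  bm <- baseline_binding()
  thr7 <- bimodality_threshold(bm, mut)
  pop <- population_params(1e8, 2 * thr7 / 1e8)
  psi <- stationary_distribution(
    build_rate_matrix(bm, fitness_spec(pop$s), mut, pop))
  expect_lt(sum(psi[3:8]), 0.05)
})
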