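test_that("occupancy follows the thermodynamic sigmoid", {
  bm <- baseline_binding()
  expect_equal(occupancy(2, bm), 0.5)                     # midpoint eps*k = mu
  expect_equal(occupancy(0, bm), 1 / (1 + exp(-4)), tolerance = 1e-6)
  pi_k <- occupancy(0:7, bm)
  expect_true(all(diff(pi_k) < 0))
  expect_true(all(pi_k > 0 & pi_k < 1))
  ## occupancy increases with chemical potential
  bm6 <- binding_model(7, 2, 6)
  expect_true(all(occupancy(0:7, bm6) > pi_k))
  expect_error(occupancy(8, bm), "out of range")
})

test_that("site energy is additive and equals eps * hamming in mismatch mode", {
  bm <- binding_model(4, 2, 4)
  expect_identical(site_energy(bm$consensus, bm), 0)
  ## exhaustive over all 4^4 windows
  cons <- strsplit(bm$consensus, "")[[1L]]
  for (w in apply(expand.grid(rep(list(c("A", "C", "G", "T")), 4)),
                  1L, paste, collapse = "")) {
    expect_equal(site_energy(w, bm),
                 2 * sum(strsplit(w, "")[[1L]] != cons))
  }
  expect_error(site_energy("ACG", bm), "window length")
  expect_error(site_energy("ACGN", bm), "non-ACGT")
})

test_that("energy-matrix mode sums the sampled column entries", {
  set.seed(71)
  xi <- gaussian_energy_matrix(7, 2, 0.5)
  bm <- binding_model(7, mu = 4, energy_matrix = xi)
  expect_identical(site_energy(bm$consensus, bm), 0)
  ## perturb two columns away from consensus; energy = sum of those entries
  x <- match(strsplit(bm$consensus, "")[[1L]], c("A", "C", "G", "T"))
  others1 <- setdiff(1:4, x[2])[1]
  others2 <- setdiff(1:4, x[5])[1]
  w <- x; w[2] <- others1; w[5] <- others2
  wseq <- paste(c("A", "C", "G", "T")[w], collapse = "")
  expect_equal(site_energy(wseq, bm), xi[others1, 2] + xi[others2, 5],
               ignore_attr = TRUE)
})

test_that("cooperative occupancy reduces to independent binding at E_c = 0", {
  bm <- baseline_binding()
  coop0 <- cooperativity_params(0)
  for (kc in c(0, 3, 7))
    expect_equal(occupancy_cooperative(0:7, kc, bm, coop0),
                 occupancy(0:7, bm), tolerance = 1e-15)
})

test_that("a strong partner with favorable E_c boosts focal occupancy", {
  bm <- baseline_binding()
  expect_equal(occupancy_cooperative(4, 0, bm, cooperativity_params(-3)),
               0.2656, tolerance = 1e-3)
  expect_gt(occupancy_cooperative(4, 0, bm, cooperativity_params(-3)),
            occupancy(4, bm))
  ## E_c -> -Inf with a perfect partner forces occupancy toward 1
  expect_gt(occupancy_cooperative(4, 0, bm, cooperativity_params(-60)), 0.999)
})

test_that("binding classes and the presite are located correctly", {
  cl <- classify_binding(baseline_binding())
  expect_identical(cl, list(k_S = 1L, k_W = 3L, presite = 2L))
  ## only the consensus binds for very specific TFs
  expect_identical(classify_binding(binding_model(7, 50, 4))$k_S, 0L)
  ## raising mu can only widen the strong class
  for (eps in c(1, 2, 3)) {
    k1 <- classify_binding(binding_model(7, eps, 4))$k_S
    k2 <- classify_binding(binding_model(7, eps, 8))$k_S
    expect_gte(k2, k1)
  }
  expect_error(classify_binding(binding_model(7, 2, -20)), "cannot bind")
})

test_that("single-site fitness scales occupancy and supports power-law tails", {
  bm <- baseline_binding()
  expect_identical(single_site_fitness(0:7, fitness_spec(0), bm), rep(0, 8))
  expect_equal(single_site_fitness(2, fitness_spec(1), bm), 0.5)
  ## step landscape: zero beyond k_S
  f_step <- single_site_fitness(0:7, fitness_spec(1, power_law_gamma = Inf), bm)
  expect_equal(f_step[3:8], rep(0, 6))
  expect_equal(f_step[1:2], occupancy(0:1, bm))
  ## finite gamma: thermodynamic head, monotone decaying positive tail
  f_pl <- single_site_fitness(0:7, fitness_spec(1, power_law_gamma = 2), bm)
  expect_equal(f_pl[1:2], occupancy(0:1, bm))
  expect_true(all(f_pl[3:8] > 0) && all(diff(f_pl[3:8]) < 0))
})

test_that("promoter fitness matches the brute-force window oracle", {
  bm <- baseline_binding()
  set.seed(72)
  for (r in 1:5) {
    s <- random_sequence(25)
    po <- oracle_window_occ(s, bm)
    expect_equal(promoter_fitness(s, fitness_spec(0.3), bm), 0.3 * sum(po))
    expect_equal(promoter_fitness(s, fitness_spec(0.3, "strongest"), bm),
                 0.3 * max(po))
    top2 <- sort(po, decreasing = TRUE)[1:2]
    expect_equal(
      promoter_fitness(s, fitness_spec(0.3, "synergistic_pair"), bm),
      0.3 * prod(top2))
  }
  ## a single window equals the single-site value
  expect_equal(promoter_fitness(bm$consensus, fitness_spec(1), bm),
               occupancy(0, bm))
  expect_error(promoter_fitness("ACG", fitness_spec(1), bm), "shorter")
})

test_that("two planted sites dominate the additive promoter fitness", {
  bm <- baseline_binding()
  set.seed(73)
  s <- plant_site(strrep("T", 30), bm$consensus, 2, 0)
  s <- plant_site(s, bm$consensus, 20, 0)
  f <- promoter_fitness(s, fitness_spec(1), bm)
  expect_gt(f, 2 * occupancy(0, bm))          # two consensus sites ...
  expect_lt(f, 2 * occupancy(0, bm) + 0.5)    # ... plus a small tail
  expect_equal(promoter_fitness(s, fitness_spec(1, "strongest"), bm),
               occupancy(0, bm), tolerance = 1e-9)
})
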