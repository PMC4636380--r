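## shared model fixtures: the baseline eukaryotic-like parameter set
## (n = 7 bp, epsilon = 2 kBT, mu = 4 kBT) used throughout
baseline_binding <- function() binding_model(7, 2, 4)

## population realizing a given Ns; large N puts the chain in the
## weak-selection regime where the closed forms are exact
make_pop <- function(Ns, N = 1000) population_params(N, Ns / N)

## empirical mismatch-class kernel from explicit indel events: plants k
## mismatches on a random consensus, applies one forced indel via the
## sequence editor, and tabulates the resulting class
mc_indel_kernel <- function(n, k, samples, mut = mutation_model(theta = 0.15)) {
  forced <- mutation_model(u = mut$u, theta = 1e12,
                           indel_lengths = mut$indel_lengths,
                           alpha = mut$alpha)
  counts <- integer(n + 1L)
  for (s in seq_len(samples)) {
    cons <- random_sequence(n)
    seq0 <- plant_site(cons, cons, 1L, k)
    res <- mutate_sequence(seq0, forced)
    k2 <- sum(strsplit(res$seq, "")[[1L]] != strsplit(cons, "")[[1L]])
    counts[k2 + 1L] <- counts[k2 + 1L] + 1L
  }
  counts / samples
}

## brute-force window-by-window promoter occupancy oracle (independent of
## the vectorized scan in the package)
oracle_window_occ <- function(seq, bm) {
  L <- nchar(seq)
  n <- bm$n
  vapply(seq_len(L - n + 1L), function(i) {
    w <- substr(seq, i, i + n - 1L)
    occupancy(sum(strsplit(w, "")[[1L]] !=
                    strsplit(bm$consensus, "")[[1L]]), bm)
  }, numeric(1))
}
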