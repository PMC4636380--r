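## Internal population state: distinct haplotypes as integer-coded sequences,
## with per-haplotype counts, cached fitness and a cached summary statistic
## (mismatch class for single-site runs, strong-site count for promoters).

wf_state <- function(seqs_int, counts, hap_eval) {
  ev <- lapply(seqs_int, hap_eval)
  list(seqs = seqs_int, counts = as.integer(counts),
       fit = vapply(ev, `[[`, numeric(1), "fit"),
       stat = vapply(ev, `[[`, numeric(1), "stat"))
}

## One Wright-Fisher generation: mutation (Poisson number of events over the
## whole population), then multinomial resampling of 2N haplotypes with
## weights count * exp(fitness).
wf_step <- function(st, mut, hap_eval, twoN, L) {
  lam <- twoN * L * mut$u * (1 + mut$theta)
  m <- if (lam > 0) stats::rpois(1L, lam) else 0L
  if (m > 0L) {
    for (j in seq_len(m)) {
      i <- sample.int(length(st$counts), 1L, prob = pmax(st$counts, 0))
      st$counts[i] <- st$counts[i] - 1L
      res <- mutate_int(st$seqs[[i]], mut)
      ev <- hap_eval(res$x)
      st$seqs <- c(st$seqs, list(res$x))
      st$counts <- c(st$counts, 1L)
      st$fit <- c(st$fit, ev$fit)
      st$stat <- c(st$stat, ev$stat)
    }
  }
  w <- st$counts * exp(st$fit - max(st$fit))
  if (all(w == 0)) stop("all-zero selection weights")
  newc <- stats::rmultinom(1L, twoN, w)[, 1L]
  keep <- newc > 0L
  list(seqs = st$seqs[keep], counts = as.integer(newc[keep]),
       fit = st$fit[keep], stat = st$stat[keep])
}

#' Wright-Fisher population of regulatory sequences
#'
#' A population of `2N` haplotypes (diploid bookkeeping with genic selection,
#' equivalent to a haploid population of `2N`), each an ACGT sequence of fixed
#' length `L`.
#'
#' @param seq0 A single ACGT string (monomorphic start) or a character vector
#'   of `2N` haplotype sequences of equal length.
#' @param N Diploid population size.
#' @return An object of class `wf_population`.
#' @export
wf_population <- function(seq0, N) {
  stopifnot(is.character(seq0), N >= 1)
  twoN <- 2L * as.integer(N)
  if (length(seq0) == 1L) {
    seqs <- list(seq_to_int(seq0))
    counts <- twoN
  } else {
    if (length(seq0) != twoN)
      stop("seq0 must be one sequence or exactly 2N sequences")
    tab <- table(seq0)
    seqs <- lapply(names(tab), seq_to_int)
    counts <- as.integer(tab)
  }
  L <- length(seqs[[1L]])
  if (any(vapply(seqs, length, 1L) != L)) stop("sequences differ in length")
  structure(list(seqs = seqs, counts = counts, fit = NULL, stat = NULL,
                 N = as.integer(N), L = L, generation = 0L),
            class = "wf_population")
}

#' @export
print.wf_population <- function(x, ...) {
  cat(sprintf(
    "wf_population: 2N = %d haplotypes, L = %d bp, %d distinct, generation %d\n",
    2L * x$N, x$L, length(x$seqs), x$generation))
  invisible(x)
}

#' Advance a Wright-Fisher population by one generation
#'
#' Applies mutation (point rate `u` and indel rate `theta * u` per bp per
#' haplotype, via the editing rules of [mutate_sequence()]) and then samples
#' `2N` offspring multinomially with weights proportional to `exp(f)` per
#' haplotype (genic selection, no dominance). Population size is constant.
#'
#' @param pop A [wf_population()].
#' @param binding A [binding_model()].
#' @param fitness A [fitness_spec()].
#' @param mut A [mutation_model()].
#' @param coop Optional [cooperativity_params()].
#' @return The updated `wf_population` (fitness cached per haplotype).
#' @export
wf_generation <- function(pop, binding, fitness, mut, coop = NULL) {
  stopifnot(inherits(pop, "wf_population"))
  he <- promoter_hap_eval(binding, fitness, coop)
  st <- if (is.null(pop$fit))
    wf_state(pop$seqs, pop$counts, he)
  else
    pop[c("seqs", "counts", "fit", "stat")]
  st <- wf_step(st, mut, he, 2L * pop$N, pop$L)
  pop[c("seqs", "counts", "fit", "stat")] <- st
  pop$generation <- pop$generation + 1L
  pop
}

## haplotype evaluator for promoter-scale runs: fitness per the fitness_spec
## and the raw count of strong (occupancy > 2/3) windows as the statistic
promoter_hap_eval <- function(binding, fitness, coop = NULL) {
  force(binding); force(fitness); force(coop)
  function(x) {
    pi_w <- window_occupancies(x, binding, coop)
    g <- switch(fitness$mode,
      additive = sum(pi_w),
      strongest = max(pi_w),
      synergistic_pair = if (length(pi_w) == 1L) pi_w else
        prod(sort(pi_w, decreasing = TRUE)[1:2]))
    list(fit = fitness$s * g, stat = sum(pi_w > 2 / 3))
  }
}

#' Count strong binding sites in a sequence
#'
#' Counts windows whose (optionally cooperativity-adjusted) occupancy exceeds
#' 2/3. The raw overlap-allowed count `z` is primary (promoter fitness is
#' overlap-blind); a greedy non-overlapping count is also reported, built by
#' accepting windows in decreasing order of occupancy.
#'
#' @param seq ACGT string of length `L >= n`.
#' @param binding A [binding_model()].
#' @param coop Optional [cooperativity_params()].
#' @return List with `z` (raw count), `z_greedy` (non-overlapping count) and
#'   `occupancy` (per-window vector, windows indexed 1..L-n+1).
#' @export
count_strong_sites <- function(seq, binding, coop = NULL) {
  x <- seq_to_int(seq)
  if (length(x) < binding$n) stop("sequence shorter than site length n")
  pi_w <- window_occupancies(x, binding, coop)
  strong <- which(pi_w > 2 / 3)
  z_greedy <- 0L
  taken <- integer(0)
  for (i in strong[order(pi_w[strong], decreasing = TRUE)]) {
    if (!any(abs(taken - i) < binding$n)) {
      z_greedy <- z_greedy + 1L
      taken <- c(taken, i)
    }
  }
  list(z = length(strong), z_greedy = z_greedy, occupancy = pi_w)
}

#' Expected sweep sojourn to majority frequency
#'
#' The origin-fixation chain counts a substitution at the origination of the
#' successful mutant, whereas a forward simulation records the population-
#' level event when the new allele's frequency crosses `majority`. Conditioned
#' on fixation, a beneficial allele grows quasi-logistically at rate
#' `delta_f`, so the crossing lags the origination by approximately
#' `log(2 * N * P_fix(N, delta_f) * majority / (1 - majority)) / delta_f`
#' generations. Valid for strongly selected sweeps (`4 * N * delta_f >> 1`);
#' returns `NA` otherwise.
#'
#' @param N Diploid population size.
#' @param delta_f Fitness advantage of the sweeping allele (> 0).
#' @param majority Frequency threshold of the recorded event (default 0.5).
#' @return Expected sojourn in generations (multiply by `u` for `1/u` units).
#' @export
sweep_sojourn <- function(N, delta_f, majority = 0.5) {
  if (delta_f <= 0 || 4 * N * delta_f < 10) return(NA_real_)
  log(2 * N * fixation_probability(N, delta_f) *
        majority / (1 - majority)) / delta_f
}

#' Empirical gain/loss times for an isolated binding site
#'
#' Forward Wright-Fisher simulation of an isolated site (`L = n`): each
#' replicate starts monomorphic at a random sequence with `k0` mismatches and
#' runs until the combined frequency of the `target` mismatch classes first
#' exceeds `majority` (distinct genotypes within a class are selectively
#' equivalent, so the class-level frequency defines the population event).
#' Times are reported in units of `1/u`. When comparing against the
#' origin-fixation hitting times note that the recorded crossing lags the
#' chain's substitution clock by the sweep sojourn ([sweep_sojourn()]).
#'
#' @param binding A [binding_model()].
#' @param fitness A [fitness_spec()].
#' @param mut A [mutation_model()].
#' @param pop A [population_params()].
#' @param k0 Initial mismatch class.
#' @param target Integer vector of target classes (0-based); e.g. `0:k_S` for
#'   gain, `k_W:n` for loss.
#' @param replicates Number of replicate populations.
#' @param t_max Time cap per replicate in units of `1/u`; replicates that do
#'   not reach the target are reported as censored at `t_max`.
#' @param majority Population frequency defining the population-level event
#'   (default 0.5; 0.9 for a stricter definition).
#' @param seed Optional integer seed.
#' @return List with `times` (1/u), `censored` (logical), `mean`, `sem`,
#'   `rate` (= 1/mean) and the run parameters.
#' @export
simulate_single_site <- function(binding, fitness, mut, pop, k0,
                                 target, replicates = 200L, t_max = 1,
                                 majority = 0.5, seed = NULL) {
  stopifnot(inherits(pop, "population_params"))
  if (!is.null(seed)) set.seed(seed)
  n <- binding$n
  target <- parse_target(target, n + 1L)
  cons <- seq_to_int(binding$consensus)
  f_tab <- single_site_fitness(0:n, fitness, binding)
  hap_eval <- function(x) {
    k <- sum(x != cons)
    list(fit = f_tab[k + 1L], stat = k)
  }
  twoN <- 2L * as.integer(pop$N)
  max_gen <- ceiling(t_max / mut$u)
  times <- numeric(replicates)
  censored <- logical(replicates)
  for (r in seq_len(replicates)) {
    x0 <- plant_mismatches(cons, k0)
    if (k0 %in% target) { times[r] <- 0; next }
    st <- wf_state(list(x0), twoN, hap_eval)
    g <- 0L
    repeat {
      g <- g + 1L
      st <- wf_step(st, mut, hap_eval, twoN, n)
      ## class-level majority: distinct genotypes in the target class are
      ## selectively equivalent, so the population-level event is their
      ## combined frequency crossing the threshold
      if (sum(st$counts[st$stat %in% target]) > majority * twoN) {
        times[r] <- g * mut$u
        break
      }
      if (g >= max_gen) {
        times[r] <- t_max
        censored[r] <- TRUE
        break
      }
    }
  }
  m <- mean(times)
  list(times = times, censored = censored, mean = m,
       sem = stats::sd(times) / sqrt(replicates), rate = 1 / m,
       k0 = k0, target = target, replicates = replicates,
       Ns = pop$Ns, Nu = pop$N * mut$u)
}

#' Ensemble simulation of promoter-scale TFBS accumulation
#'
#' Simulates `replicates` independent populations, each starting monomorphic
#' at its own initial `L`-bp sequence, and records the count of strong sites
#' `z` on a time grid; reports newly evolved sites `z(t) - z(0)`.
#'
#' Two engines are provided. `method = "fixed_state"` (default) simulates the
#' origin-fixation process directly on sequence space: mutations enter the
#' (monomorphic) population at rate `2N * L * u * (1 + theta)` per generation
#' and each fixes instantly with probability [fixation_probability()] of its
#' fitness effect. This is the regime in which the analytic theory lives and
#' is fast. `method = "wright_fisher"` runs the full forward simulation via
#' [wf_generation()]'s machinery and records the population-mean `z`; its
#' trajectories additionally carry the sojourn time of selective sweeps
#' (roughly `log(4 N df) / df` generations), which delays the recorded gains
#' relative to the origin-fixation clock at small `t`.
#'
#' @inheritParams simulate_single_site
#' @param L Sequence length in bp (`>= n`).
#' @param t_grid Increasing sample times in units of `1/u`.
#' @param seq0 Optional initial sequences: a function `function(r)` returning
#'   an ACGT string for replicate `r`, or a character vector of length
#'   `replicates`; defaults to i.i.d. uniform random sequences.
#' @param coop Optional [cooperativity_params()]; used for both fitness and
#'   strong-site counting.
#' @param ancient Optional [ancient_site_spec()]: each replicate's initial
#'   sequence carries one planted site with `k_ancient` mismatches at a
#'   uniform position, then decays neutrally for `t_prime` (fixed-state
#'   neutral substitutions) before the selective phase starts.
#' @param method Simulation engine, `"fixed_state"` or `"wright_fisher"`.
#' @return An object of class `wf_trajectory`: list with `t`, `z` (replicates
#'   x times matrix), `z0`, `newly` (mean newly evolved sites per time),
#'   `sem` and run metadata.
#' @export
simulate_promoter <- function(binding, fitness, mut, pop, L, t_grid,
                              replicates = 200L, seq0 = NULL, coop = NULL,
                              ancient = NULL,
                              method = c("fixed_state", "wright_fisher"),
                              seed = NULL) {
  stopifnot(inherits(pop, "population_params"), L >= binding$n,
            all(diff(t_grid) > 0), all(t_grid >= 0))
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  he <- promoter_hap_eval(binding, fitness, coop)
  N <- pop$N
  twoN <- 2L * as.integer(N)
  gens <- t_grid / mut$u
  zmat <- matrix(NA_real_, replicates, length(t_grid))
  z0 <- numeric(replicates)
  make_seq0 <- function(r) {
    if (is.function(seq0)) return(seq_to_int(seq0(r)))
    if (is.character(seq0)) return(seq_to_int(seq0[r]))
    x <- sample.int(4L, L, replace = TRUE)
    if (!is.null(ancient)) {
      pos <- sample.int(L - binding$n + 1L, 1L)
      site <- plant_mismatches(seq_to_int(binding$consensus),
                               ancient$k_ancient)
      x[pos:(pos + binding$n - 1L)] <- site
      ## neutral fixed-state decay: substitutions accrue at the mutation rate
      m <- stats::rpois(1L, L * ancient$t_prime * (1 + mut$theta))
      for (j in seq_len(m)) x <- mutate_int(x, mut)$x
    }
    x
  }
  prop_rate <- twoN * L * mut$u * (1 + mut$theta)  # proposals per generation
  for (r in seq_len(replicates)) {
    if (method == "fixed_state") {
      x <- make_seq0(r)
      ev <- he(x)
      z0[r] <- ev$stat
      g_next <- stats::rexp(1L, prop_rate)
      for (ti in seq_along(gens)) {
        while (g_next <= gens[ti]) {
          cand <- mutate_int(x, mut)
          ev2 <- he(cand$x)
          if (stats::runif(1) < fixation_probability(N, ev2$fit - ev$fit)) {
            x <- cand$x
            ev <- ev2
          }
          g_next <- g_next + stats::rexp(1L, prop_rate)
        }
        zmat[r, ti] <- ev$stat
      }
    } else {
      st <- wf_state(list(make_seq0(r)), twoN, he)
      z0[r] <- st$stat[1L]
      g <- 0L
      for (ti in seq_along(gens)) {
        while (g < gens[ti]) {
          st <- wf_step(st, mut, he, twoN, L)
          g <- g + 1L
        }
        zmat[r, ti] <- sum(st$counts * st$stat) / twoN
      }
    }
  }
  newly <- sweep(zmat, 1L, z0)
  structure(list(t = t_grid, z = zmat, z0 = z0,
                 newly = colMeans(newly),
                 sem = apply(newly, 2L, stats::sd) / sqrt(replicates),
                 replicates = replicates, L = L, Ns = pop$Ns,
                 Nu = pop$N * mut$u, theta = mut$theta),
            class = "wf_trajectory")
}

#' @export
print.wf_trajectory <- function(x, ...) {
  cat(sprintf(
    "wf_trajectory: %d replicates, L = %d bp, Ns = %.3g, Nu = %.3g, theta = %.3g\n",
    x$replicates, x$L, x$Ns, x$Nu, x$theta))
  print(data.frame(t = x$t, newly_evolved = signif(x$newly, 4),
                   sem = signif(x$sem, 3)))
  invisible(x)
}
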