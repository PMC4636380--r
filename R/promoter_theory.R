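#' Ancient (decayed) binding site scenario
#'
#' Describes a formerly functional site that has been decaying neutrally:
#' `k_ancient` is its mismatch class at the start of the decay and `t_prime`
#' the decay duration in units of `1/u`.
#'
#' @param k_ancient Mismatch class of the ancient site at its origin.
#' @param t_prime Neutral decay duration in units of `1/u` (>= 0).
#' @return An object of class `ancient_site_spec`.
#' @export
ancient_site_spec <- function(k_ancient, t_prime) {
  stopifnot(k_ancient >= 0, k_ancient == round(k_ancient), t_prime >= 0)
  structure(list(k_ancient = as.integer(k_ancient), t_prime = t_prime),
            class = "ancient_site_spec")
}

#' Expected strong-site count under constant gain and loss rates
#'
#' Solution of `dz/dt = lambda_gain * (z_max - z) - lambda_loss * z`:
#' `z(t) = (z0 - B/A) * exp(-A*t) + B/A` with `A = lambda_gain + lambda_loss`
#' and `B = z_max * lambda_gain`. `A = 0` degenerates to constant `z0`.
#'
#' @param t Time(s) in units of `1/u` (>= 0).
#' @param z0 Initial strong-site count.
#' @param z_max Site capacity of the sequence (`L - n + 1` if overlap is
#'   allowed, about `L/n` if packed).
#' @param lambda_gain,lambda_loss Per-site gain and loss rates in units of
#'   `u` (>= 0).
#' @return Expected `z(t)`, vectorized over `t`.
#' @export
z_of_t <- function(t, z0, z_max, lambda_gain, lambda_loss = 0) {
  stopifnot(all(t >= 0), z0 <= z_max, lambda_gain >= 0, lambda_loss >= 0)
  A <- lambda_gain + lambda_loss
  B <- z_max * lambda_gain
  if (A == 0) return(rep(z0, length(t)))  # both rates zero: z is constant
  (z0 - B / A) * exp(-A * t) + B / A
}

#' Expected newly evolved sites under strong selection
#'
#' With loss negligible and an initial mismatch-class distribution `psi` in
#' the promoter background,
#' `z(t) - z0 = (1 - exp(-lambda_gain * t)) * z_max * sum_{k > k_S} psi_k`.
#'
#' @param t Time(s) in `1/u`.
#' @param z_max Site capacity.
#' @param lambda_gain Per-site gain rate in units of `u`.
#' @param psi Class distribution of the background (length `n + 1`).
#' @param k_S Strong-class boundary (see [classify_binding()]).
#' @return Expected newly evolved site count, vectorized over `t`.
#' @export
newly_evolved <- function(t, z_max, lambda_gain, psi, k_S) {
  stopifnot(all(t >= 0))
  nonstrong <- sum(psi[-seq_len(k_S + 1L)])
  (1 - exp(-lambda_gain * t)) * z_max * nonstrong
}

#' Presite-limited gain rate
#'
#' Early-epoch per-site gain rate dominated by presites (class `k_S + 1`),
#' the fastest class to evolve strong binding:
#' `lambda = psi_presite / <t>_{S <- presite} / sum_{k not in S} psi_k`.
#' Pairs naturally with capacity `z_max = L - n + 1`.
#'
#' @param hitting A `hitting_time_table` of gain times (target `0:k_S`).
#' @param psi Background class distribution (length `n + 1`).
#' @return Gain rate in units of `u`.
#' @export
gain_rate_presite <- function(hitting, psi) {
  stopifnot(inherits(hitting, "hitting_time_table"))
  k_S <- max(hitting$target)
  nonstrong <- sum(psi[-seq_len(k_S + 1L)])
  if (psi[k_S + 2L] == 0) return(0)
  unname(psi[k_S + 2L] / hitting$times[k_S + 2L] / nonstrong)
}

#' All-class gain rate
#'
#' Late-epoch per-site gain rate with contributions from every non-strong
#' class: `lambda = sum_{k not in S} psi_k / <t>_{S <- k}`, normalized by the
#' non-strong mass. Pairs naturally with the packed capacity
#' `z_max ~ floor(L / n)`.
#'
#' @inheritParams gain_rate_presite
#' @return Gain rate in units of `u`.
#' @export
gain_rate_all <- function(hitting, psi) {
  stopifnot(inherits(hitting, "hitting_time_table"))
  k_S <- max(hitting$target)
  idx <- (k_S + 2L):length(psi)
  nonstrong <- sum(psi[idx])
  unname(sum(psi[idx] / hitting$times[idx]) / nonstrong)
}

#' Background class distribution biased by an ancient site
#'
#' Mixture distribution of mismatch classes across the `L - n + 1` windows of
#' a promoter containing one decayed ancient site:
#' `Psi = psi(t') / (L - n + 1) + phi * (L - n) / (L - n + 1)`, where
#' `psi(t')` propagates a delta at `k_ancient` under the neutral chain
#' (`R = U`) for `t_prime`, and `phi` is the binomial background.
#'
#' @param ancient An [ancient_site_spec()].
#' @param L Promoter length in bp.
#' @param binding A [binding_model()].
#' @param mut A [mutation_model()].
#' @return Named probability vector over classes `0..n`.
#' @export
ancient_initial_distribution <- function(ancient, L, binding, mut) {
  stopifnot(inherits(ancient, "ancient_site_spec"), L >= binding$n)
  n <- binding$n
  U <- combined_rate_matrix(n, mut)
  psi_t <- propagate(U, ancient$k_ancient, ancient$t_prime)
  phi <- stats::dbinom(0:n, n, mut$alpha)
  W <- L - n + 1L
  out <- psi_t / W + phi * (W - 1L) / W
  names(out) <- 0:n
  out
}

#' Analytic promoter accumulation curves
#'
#' Evaluates the expected number of newly evolved strong sites at times `t`
#' in both limiting regimes: the early epoch (presite-limited rate, capacity
#' `L - n + 1`) and the late epoch (all-class rate, packed capacity
#' `floor(L / n)`). The background distribution is binomial, or the ancient-
#' site mixture when `ancient` is given.
#'
#' @param binding A [binding_model()].
#' @param fitness A [fitness_spec()].
#' @param mut A [mutation_model()].
#' @param pop A [population_params()].
#' @param L Promoter length in bp.
#' @param t Time(s) in `1/u`.
#' @param ancient Optional [ancient_site_spec()].
#' @return A data.frame with columns `t`, `z_presite_limit`,
#'   `z_allclass_limit`.
#' @export
promoter_prediction <- function(binding, fitness, mut, pop, L, t,
                                ancient = NULL) {
  n <- binding$n
  k_S <- classify_binding(binding)$k_S
  R <- build_rate_matrix(binding, fitness, mut, pop)
  ht <- hitting_times(R, 0:k_S)
  psi <- if (is.null(ancient)) stats::dbinom(0:n, n, mut$alpha)
         else ancient_initial_distribution(ancient, L, binding, mut)
  lam_pre <- gain_rate_presite(ht, psi)
  lam_all <- gain_rate_all(ht, psi)
  data.frame(
    t = t,
    z_presite_limit = newly_evolved(t, L - n + 1L, lam_pre, psi, k_S),
    z_allclass_limit = newly_evolved(t, floor(L / n), lam_all, psi, k_S))
}

#' Expected newly evolved sites with an ancient site in the background
#'
#' Convenience wrapper: [promoter_prediction()] with the ancient-site mixture
#' as the background distribution.
#'
#' @inheritParams promoter_prediction
#' @param ancient An [ancient_site_spec()].
#' @return A data.frame as in [promoter_prediction()].
#' @export
ancient_site_prediction <- function(ancient, L, binding, fitness, mut, pop,
                                    t) {
  promoter_prediction(binding, fitness, mut, pop, L, t, ancient = ancient)
}
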