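#' Population-genetic parameters
#'
#' @param N Diploid population size (integer >= 1).
#' @param s Selection strength (fitness of strongest vs weakest binding).
#' @return An object of class `population_params` with derived element `Ns`.
#' @export
population_params <- function(N, s) {
  stopifnot(is.numeric(N), length(N) == 1L, N >= 1,
            is.numeric(s), length(s) == 1L)
  structure(list(N = N, s = s, Ns = N * s), class = "population_params")
}

#' Fixation probability of a new mutation (diffusion approximation)
#'
#' `P_fix(N, df) = (1 - exp(-2*df)) / (1 - exp(-4*N*df))` for a mutation with
#' fitness difference `df` in a diploid population of size `N` (genic
#' selection). The neutral limit is `1/(2N)`; a second-order series is used
#' for `|4*N*df| < 1e-8` to avoid 0/0. For `N*df >> 1` the value approaches
#' `2*df`.
#'
#' @param N Diploid population size.
#' @param delta_f Fitness difference(s) of the mutant; vectorized, `+/-Inf`
#'   allowed.
#' @return Fixation probabilities.
#' @export
fixation_probability <- function(N, delta_f) {
  x <- 4 * N * delta_f
  out <- ifelse(abs(x) < 1e-8,
                (1 + (2 * N - 1) * delta_f / 2) / (2 * N),
                -expm1(-2 * delta_f) / -expm1(-x))
  out[delta_f == Inf] <- 1
  out[delta_f == -Inf] <- 0
  out
}

#' Origin-fixation substitution rate matrix over mismatch classes
#'
#' Builds the `(n+1) x (n+1)` generator of the fixed-state Markov chain:
#' `R[k',k] = 2N * U[k',k] * P_fix(N, f(k') - f(k))` off the diagonal, where
#' `U` is the combined mutation rate matrix (in units of `u`, see
#' [combined_rate_matrix()]) and `f` the single-site fitness. Columns sum to
#' zero. All rates are in units of the point mutation rate `u`; times derived
#' from `R` are in units of `1/u`.
#'
#' @param binding A [binding_model()].
#' @param fitness A [fitness_spec()].
#' @param mut A [mutation_model()].
#' @param pop A [population_params()].
#' @return A `rate_matrix`: a matrix with attributes `n` and `params`.
#' @export
build_rate_matrix <- function(binding, fitness, mut, pop) {
  stopifnot(inherits(binding, "binding_model"),
            inherits(fitness, "fitness_spec"),
            inherits(mut, "mutation_model"),
            inherits(pop, "population_params"))
  n <- binding$n
  U <- unclass(combined_rate_matrix(n, mut))
  diag(U) <- 0
  f <- single_site_fitness(0:n, fitness, binding)
  df <- outer(f, f, "-")         # df[k', k] = f(k') - f(k)
  R <- 2 * pop$N * U * fixation_probability(pop$N, df)
  diag(R) <- -colSums(R)
  dimnames(R) <- list(k_to = 0:n, k_from = 0:n)
  structure(R, n = n, class = c("rate_matrix", "matrix"),
            params = list(epsilon = binding$epsilon, mu = binding$mu,
                          N = pop$N, s = pop$s, Ns = pop$Ns,
                          theta = mut$theta, mode = fitness$mode))
}

as_generator <- function(R) {
  R <- unclass(as.matrix(R))
  if (nrow(R) != ncol(R)) stop("rate matrix must be square")
  R
}

is_tridiagonal <- function(R, tol = 1e-12) {
  R <- as_generator(R)
  idx <- abs(row(R) - col(R)) > 1L
  all(abs(R[idx]) <= tol * max(abs(R)))
}

#' Stationary distribution of the fixed-state chain
#'
#' Null-space vector of the generator `R` (acting on column distributions),
#' normalized to sum to 1. Tridiagonal (point-mutation-only) chains are solved
#' exactly through the detailed-balance product of rate ratios; general chains
#' through the eigenvector of the eigenvalue closest to zero, with a fallback
#' linear solve of the normalization-augmented system. Tiny negative entries
#' (>= -1e-12) are clipped to zero and the vector renormalized.
#'
#' For point mutations alone the result matches the closed form
#' [stationary_closed_form()] in the weak-selection limit.
#'
#' @param R A generator from [build_rate_matrix()] (or any square generator
#'   with columns summing to zero).
#' @return Named numeric vector of probabilities over classes `0..n`.
#' @export
stationary_distribution <- function(R) {
  R <- as_generator(R)
  m <- nrow(R)
  if (is_tridiagonal(R)) {
    ## birth-death chain: psi_{k+1}/psi_k = R[k+1,k]/R[k,k+1]
    lr <- cumsum(c(0, log(R[cbind(2:m, 1:(m - 1))]) -
                      log(R[cbind(1:(m - 1), 2:m)])))
    psi <- exp(lr - max(lr))
  } else {
    e <- eigen(R)
    i0 <- which.min(abs(e$values))
    psi <- Re(e$vectors[, i0])
    if (sum(psi) < 0) psi <- -psi
    if (max(abs(R %*% psi)) > 1e-8 * max(abs(R)) || any(psi < -1e-8)) {
      ## fallback: least-squares solve of [R; 1] x = [0; 1]
      psi <- qr.solve(rbind(R, 1), c(rep(0, m), 1))
    }
  }
  if (any(psi < -1e-12 * max(psi)))
    warning("stationary solve produced negative entries beyond tolerance")
  psi <- pmax(psi, 0)
  psi <- psi / sum(psi)
  names(psi) <- 0:(m - 1L)
  psi
}

#' Closed-form stationary distribution (point mutations, weak selection)
#'
#' `psi_hat_k` proportional to `exp(F(k,N) + H(k))` with `F = 4*N*f(k)` and
#' mutational entropy `H = log phi_k(n, alpha)`, the log binomial redundancy
#' of class `k`. Exact for the tridiagonal (theta = 0) chain in the
#' weak-selection limit (`s -> 0` at fixed `Ns`); at finite `s` the exact
#' chain carries an additional `O(s)` factor per step from the fixation-
#' probability ratio `exp((4N-2) df)`.
#'
#' @param binding A [binding_model()].
#' @param fitness A [fitness_spec()].
#' @param pop A [population_params()].
#' @param alpha Background mismatch probability (default 3/4).
#' @return Named probability vector over classes `0..n`.
#' @export
stationary_closed_form <- function(binding, fitness, pop, alpha = 3 / 4) {
  n <- binding$n
  k <- 0:n
  lw <- 4 * pop$N * single_site_fitness(k, fitness, binding) +
    stats::dbinom(k, n, alpha, log = TRUE)
  psi <- exp(lw - max(lw))
  psi <- psi / sum(psi)
  names(psi) <- k
  psi
}

#' Propagate a class distribution forward in time
#'
#' `psi(t) = expm(R * t) %*% psi0`, with `t` in units of `1/u`. Probability is
#' conserved and `psi(t)` converges to the stationary distribution as
#' `t -> Inf`.
#'
#' @param R A generator (units of `u`).
#' @param psi0 Initial distribution over classes `0..n`, or a single integer
#'   class (delta distribution).
#' @param t Nonnegative time(s) in units of `1/u`.
#' @return If `t` is scalar, a probability vector; otherwise a matrix with one
#'   column per time (columns named by `t`).
#' @export
propagate <- function(R, psi0, t) {
  R <- as_generator(R)
  m <- nrow(R)
  if (length(psi0) == 1L) {
    k0 <- as.integer(psi0)
    stopifnot(k0 >= 0, k0 <= m - 1L)
    psi0 <- replace(numeric(m), k0 + 1L, 1)
  }
  stopifnot(length(psi0) == m, all(psi0 >= 0),
            abs(sum(psi0) - 1) < 1e-8, all(t >= 0))
  out <- vapply(t, function(ti) {
    p <- as.numeric(Matrix::expm(Matrix::Matrix(R * ti)) %*% psi0)
    pmax(p, 0) / sum(pmax(p, 0))
  }, numeric(m))
  rownames(out) <- 0:(m - 1L)
  if (length(t) == 1L) out[, 1L] else `colnames<-`(out, t)
}

#' Kullback-Leibler divergence between class distributions
#'
#' Natural-log KL divergence; classes with zero mass in `p` contribute zero by
#' continuity.
#'
#' @param p,q Probability vectors of equal length.
#' @return Scalar divergence (nats).
#' @export
kl_divergence <- function(p, q) {
  stopifnot(length(p) == length(q))
  i <- p > 0
  sum(p[i] * (log(p[i]) - log(q[i])))
}

#' Spectral convergence rate of the chain
#'
#' Absolute value of the nonzero eigenvalue of `R` closest to zero, `|lambda_2|`,
#' in units of `u`; its inverse is the relaxation time to the stationary
#' distribution.
#'
#' @param R A generator.
#' @param tol Relative tolerance below which the spectral gap is flagged as
#'   degenerate.
#' @return `|lambda_2|` (scalar).
#' @export
convergence_rate <- function(R, tol = 1e-10) {
  R <- as_generator(R)
  ev <- eigen(R, only.values = TRUE)$values
  ev <- ev[order(abs(ev))]
  if (abs(ev[1L]) > 1e-6 * max(abs(ev)))
    warning("smallest eigenvalue is not numerically zero; R may not be a generator")
  l2 <- ev[2L]
  if (length(ev) > 2L && abs(abs(ev[3L]) - abs(l2)) < tol * abs(l2))
    message("near-degenerate subdominant spectrum")
  abs(l2)
}

parse_target <- function(target, m) {
  target <- as.integer(target)
  if (!length(target) || any(target < 0L | target > m - 1L))
    stop("target classes must be a nonempty subset of 0..n")
  sort(unique(target))
}

new_hitting_table <- function(times, target, method) {
  names(times) <- seq_along(times) - 1L
  structure(list(target = target, times = times, method = method),
            class = "hitting_time_table")
}

#' @export
print.hitting_time_table <- function(x, ...) {
  cat(sprintf("hitting times (method = %s) to classes {%s}, units 1/u:\n",
              x$method, paste(x$target, collapse = ",")))
  print(signif(x$times, 4))
  invisible(x)
}

#' Mean first-hitting times to a target class set
#'
#' Solves the mean first-passage linear system of the fixed-state chain: for
#' transient classes `k` the times satisfy `t(R_sub) %*% tau = -1` where
#' `R_sub` deletes the target rows and columns. Times are zero on the target
#' and in units of `1/u`. Gain times use `target = 0:k_S`, loss times
#' `target = k_W:n`; arbitrary targets (e.g. a single class) are supported.
#'
#' @param R A generator (units of `u`).
#' @param target Integer vector of target classes (0-based).
#' @return A `hitting_time_table` with elements `target`, `times`, `method`.
#' @export
hitting_times <- function(R, target) {
  R <- as_generator(R)
  m <- nrow(R)
  target <- parse_target(target, m)
  keep <- setdiff(seq_len(m), target + 1L)
  times <- numeric(m)
  if (length(keep)) {
    sol <- tryCatch(
      solve(t(R[keep, keep, drop = FALSE]), rep(-1, length(keep))),
      error = function(e) stop("hitting-time system is singular: ",
                               "target unreachable from some classes"))
    times[keep] <- sol
  }
  new_hitting_table(times, target, "exact")
}

#' Tridiagonal closed form for gain and loss times
#'
#' For point-mutation-only (tridiagonal) chains the mean gain time from class
#' `k` down to the strong classes `{0..k_S}` is
#' `sum_{i=k_S+1..k} (1 - Psi_{i-1}) / (R[i-1,i] * psi_i)` and the loss time
#' up to `{k_W..n}` is `sum_{i=k+1..k_W} Psi_{i-1} / (R[i-1,i] * psi_i)`,
#' where `psi` is the stationary distribution and `Psi` its cumulative sum.
#' Exact for any birth-death generator; serves as an independent cross-check
#' of [hitting_times()].
#'
#' @param R A tridiagonal generator.
#' @param psi_hat Stationary distribution of `R`; computed if `NULL`.
#' @param target Either `0:k_S` (a gain target: contiguous from class 0) or
#'   `k_W:n` (a loss target: contiguous to class n).
#' @return A `hitting_time_table`.
#' @export
hitting_times_tridiagonal <- function(R, psi_hat = NULL, target) {
  R <- as_generator(R)
  if (!is_tridiagonal(R))
    stop("closed form requires a tridiagonal (theta = 0) rate matrix")
  m <- nrow(R)
  target <- parse_target(target, m)
  if (is.null(psi_hat)) psi_hat <- stationary_distribution(R)
  Psi <- cumsum(psi_hat)
  ## upper-tail sums computed directly: 1 - Psi cancels catastrophically when
  ## the stationary mass concentrates in the strong classes
  Tail <- rev(cumsum(rev(psi_hat)))
  times <- numeric(m)
  if (target[1L] == 0L) {                      # gain: target = 0..k_S
    k_S <- max(target)
    if (!identical(target, 0:k_S)) stop("gain target must be contiguous 0..k_S")
    step <- vapply((k_S + 1L):(m - 1L), function(i)
      Tail[i + 1L] / (R[i, i + 1L] * psi_hat[i + 1L]), numeric(1))
    times[(k_S + 2L):m] <- cumsum(step)
  } else if (target[length(target)] == m - 1L) {  # loss: target = k_W..n
    k_W <- min(target)
    if (!identical(target, k_W:(m - 1L)))
      stop("loss target must be contiguous k_W..n")
    step <- vapply(1:k_W, function(i)
      Psi[i] / (R[i, i + 1L] * psi_hat[i + 1L]), numeric(1))
    times[1:k_W] <- rev(cumsum(rev(step)))
  } else stop("target must touch class 0 (gain) or class n (loss)")
  new_hitting_table(times, target, "tridiagonal")
}

#' Shortest-path approximation to gain and loss times
#'
#' Under strong selection the first-passage time reduces to the sum of inverse
#' one-step rates along the monotone path into the target: for gain,
#' `sum 1/R[i-1,i]` over the downward steps; for loss, `sum 1/R[i,i-1]` over
#' the upward steps. Approaches the exact times as selection strengthens.
#'
#' @inheritParams hitting_times_tridiagonal
#' @return A `hitting_time_table`.
#' @export
hitting_times_shortest_path <- function(R, target) {
  R <- as_generator(R)
  m <- nrow(R)
  target <- parse_target(target, m)
  times <- numeric(m)
  if (target[1L] == 0L) {                      # gain: downward rates
    k_S <- max(target)
    rates <- R[cbind((k_S + 1L):(m - 1L), (k_S + 2L):m)]  # R[i-1, i]
    if (any(rates <= 0)) stop("zero rate on the shortest path")
    times[(k_S + 2L):m] <- cumsum(1 / rates)
  } else if (target[length(target)] == m - 1L) {  # loss: upward rates
    k_W <- min(target)
    rates <- R[cbind(2:(k_W + 1L), 1:k_W)]               # R[i, i-1]
    if (any(rates <= 0)) stop("zero rate on the shortest path")
    times[1:k_W] <- rev(cumsum(rev(1 / rates)))
  } else stop("target must touch class 0 (gain) or class n (loss)")
  new_hitting_table(times, target, "shortest_path")
}

#' Strong-selection threshold in Ns
#'
#' The selection strength separating the bimodal (weak-selection) from the
#' unimodal (strong-selection) stationary regime:
#' full expression `(1/4) * (n*log(4) - (1/2)*log(2*pi*alpha*(1-alpha)*n))`
#' and its linear approximation `n * log(2) / 2`.
#'
#' @param n Site length in bp.
#' @param alpha Background mismatch probability (default 3/4).
#' @return List with elements `full` and `linear`.
#' @export
ns_strong_selection_threshold <- function(n, alpha = 3 / 4) {
  stopifnot(n >= 1)
  list(full = (n * log(4) - 0.5 * log(2 * pi * alpha * (1 - alpha) * n)) / 4,
       linear = n * log(2) / 2)
}

#' Empirical bimodality threshold in Ns
#'
#' Finds, by bisection over `Ns`, the selection strength at which a fraction
#' `mass` (default 5%) of the stationary distribution lies outside the strong
#' classes `{0..k_S}`. Comparable to [ns_strong_selection_threshold()].
#'
#' @param binding A [binding_model()].
#' @param mut A [mutation_model()].
#' @param ns_range Length-2 numeric bracketing interval for `Ns`; non-strong
#'   mass must be monotone (decreasing) across it.
#' @param mass Target non-strong probability mass (default 0.05).
#' @param N Population size used to realize each `Ns` (default `1e8`, i.e.
#'   effectively the weak-selection limit).
#' @param tol Bisection tolerance on `Ns`.
#' @param power_law_gamma Optional landscape-tail exponent passed to
#'   [fitness_spec()].
#' @return The threshold `Ns` value.
#' @export
bimodality_threshold <- function(binding, mut, ns_range = c(0.1, 50),
                                 mass = 0.05, N = 1e8, tol = 1e-3,
                                 power_law_gamma = NULL) {
  k_S <- classify_binding(binding)$k_S
  nonstrong <- function(ns) {
    pop <- population_params(N, ns / N)
    R <- build_rate_matrix(binding,
                           fitness_spec(pop$s, power_law_gamma = power_law_gamma),
                           mut, pop)
    psi <- stationary_distribution(R)
    sum(psi[-(1:(k_S + 1L))])
  }
  f <- function(ns) nonstrong(ns) - mass
  lo <- ns_range[1L]; hi <- ns_range[2L]
  if (f(lo) < 0 || f(hi) > 0)
    stop("ns_range does not bracket the ", mass, " non-strong-mass threshold")
  stats::uniroot(f, lower = lo, upper = hi, tol = tol)$root
}
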