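#' Thermodynamic model of sequence-specific TF binding
#'
#' Constructs the biophysical model that maps an `n`-bp DNA window to a binding
#' energy, a thermodynamic occupancy, and (via [fitness_spec()]) a fitness.
#' In the default *mismatch mode* every non-consensus base contributes the same
#' energy penalty `epsilon` ("specificity"), so a window is fully characterized
#' by its mismatch class `k` (Hamming distance to the consensus) and has energy
#' `E = k * epsilon`. Supplying a 4 x n `energy_matrix` switches to the general
#' additive-energy model in which column `j` of the matrix gives the energetic
#' contribution of each base at position `j` (consensus entry 0 per column).
#'
#' @param n Integer site length in bp (>= 1).
#' @param epsilon Per-mismatch binding energy penalty in units of kB*T (> 0).
#'   Ignored for energy computations when `energy_matrix` is supplied.
#' @param mu Chemical potential in kB*T; sets the occupancy midpoint
#'   (occupancy is 1/2 where binding energy equals `mu`). Related to the log
#'   free TF concentration.
#' @param beta Inverse temperature in 1/(kB*T); default 1 so that energies are
#'   read directly in kB*T.
#' @param energy_matrix Optional 4 x n numeric matrix with rows named
#'   A, C, G, T; entries in kB*T, nonnegative, exactly one zero (consensus)
#'   entry per column.
#' @param consensus Optional consensus sequence (length-`n` ACGT string). In
#'   mismatch mode it defaults to a cycled `"ACGT..."` pattern (minimal
#'   self-overlap); in energy-matrix mode it is derived from the zero entries
#'   and must not be supplied.
#'
#' @return An object of class `binding_model`.
#' @seealso [occupancy()], [site_energy()], [classify_binding()],
#'   [promoter_fitness()]
#' @examples
#' bm <- binding_model(n = 7, epsilon = 2, mu = 4)
#' occupancy(0:7, bm)
#' @export
binding_model <- function(n, epsilon = 2, mu = 4, beta = 1,
                          energy_matrix = NULL, consensus = NULL) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1, n == round(n))
  n <- as.integer(n)
  stopifnot(is.numeric(mu), length(mu) == 1L,
            is.numeric(beta), length(beta) == 1L, beta > 0)
  if (is.null(energy_matrix)) {
    stopifnot(is.numeric(epsilon), length(epsilon) == 1L, epsilon > 0)
    ## default consensus cycles ACGT: deterministic and with minimal
    ## self-overlap, so shifted copies of a site do not spuriously bind
    if (is.null(consensus))
      consensus <- substr(strrep("ACGT", ceiling(n / 4)), 1L, n)
    consensus <- toupper(consensus)
    if (nchar(consensus) != n || grepl("[^ACGT]", consensus))
      stop("'consensus' must be a length-", n, " ACGT string")
  } else {
    energy_matrix <- validate_energy_matrix(energy_matrix, n)
    if (!is.null(consensus))
      stop("'consensus' is derived from 'energy_matrix'; do not supply both")
    consensus <- paste(DNA_BASES[apply(energy_matrix, 2L, which.min)],
                       collapse = "")
    if (is.null(epsilon)) epsilon <- mean(energy_matrix[energy_matrix > 0])
  }
  structure(
    list(n = n, epsilon = epsilon, mu = mu, beta = beta,
         energy_matrix = energy_matrix, consensus = consensus),
    class = "binding_model")
}

DNA_BASES <- c("A", "C", "G", "T")

validate_energy_matrix <- function(xi, n) {
  xi <- as.matrix(xi)
  if (nrow(xi) != 4L || ncol(xi) != n)
    stop("energy matrix must be 4 x n (n = ", n, ")")
  if (is.null(rownames(xi))) rownames(xi) <- DNA_BASES
  xi <- xi[DNA_BASES, , drop = FALSE]
  if (any(xi < 0)) stop("energy matrix entries must be nonnegative (kB*T)")
  nz <- colSums(xi == 0)
  if (any(nz != 1L))
    stop("energy matrix must have exactly one zero (consensus) entry per column")
  xi
}

#' @export
print.binding_model <- function(x, ...) {
  mode <- if (is.null(x$energy_matrix)) "mismatch" else "energy matrix"
  cat(sprintf("binding_model: n = %d bp, mode = %s\n", x$n, mode))
  cat(sprintf("  epsilon = %.3g kB*T, mu = %.3g kB*T, beta = %.3g\n",
              x$epsilon, x$mu, x$beta))
  cat(sprintf("  consensus: %s\n", x$consensus))
  cl <- tryCatch(classify_binding(x), error = function(e) NULL)
  if (!is.null(cl))
    cat(sprintf("  classes: k_S = %d, presite = %d, k_W = %d\n",
                cl$k_S, cl$presite, cl$k_W))
  invisible(x)
}

#' Cooperative interaction between two bound TFs
#'
#' Parameters of the pairwise cooperative interaction: two TFs bound within
#' `window` bp of each other gain an interaction energy `E_c` (negative =
#' favorable), which acts like a local increase of the chemical potential at
#' the focal site.
#'
#' @param E_c Interaction energy in kB*T; `E_c <= 0` is favorable cooperativity
#'   and `E_c = 0` recovers independent binding.
#' @param window Maximum gap in bp between the two (non-overlapping) sites for
#'   the interaction to act; default 3.
#' @return An object of class `cooperativity_params`.
#' @export
cooperativity_params <- function(E_c, window = 3L) {
  stopifnot(is.numeric(E_c), length(E_c) == 1L,
            is.numeric(window), length(window) == 1L, window >= 0)
  structure(list(E_c = E_c, window = as.integer(window)),
            class = "cooperativity_params")
}

#' Fitness specification for binding-driven gene expression
#'
#' Fitness is `s` times a proxy for gene expression computed from TF
#' occupancies. For a promoter the proxy is, depending on `mode`, the sum of
#' window occupancies (`"additive"`, the default), the occupancy of the
#' strongest window (`"strongest"`), or the joint occupancy of the two
#' strongest windows (`"synergistic_pair"`, a toy model of synergistic
#' activation against nucleosomal competition).
#'
#' `power_law_gamma` modifies the tail of the *single-site* mismatch landscape:
#' fitness follows the thermodynamic occupancy for `k <= k_S` and then decays
#' as a power law with exponent `gamma` (`Inf` gives a step landscape that is
#' zero beyond `k_S`).
#'
#' @param s Selection strength: fitness difference between strongest and
#'   weakest binding (may be negative for directional selection against
#'   binding).
#' @param mode One of `"additive"`, `"strongest"`, `"synergistic_pair"`.
#' @param power_law_gamma Optional positive exponent (or `Inf`) for the
#'   modified single-site landscape tail.
#' @return An object of class `fitness_spec`.
#' @export
fitness_spec <- function(s, mode = c("additive", "strongest",
                                     "synergistic_pair"),
                         power_law_gamma = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(s), length(s) == 1L)
  if (!is.null(power_law_gamma))
    stopifnot(is.numeric(power_law_gamma), length(power_law_gamma) == 1L,
              power_law_gamma > 0)
  structure(list(s = s, mode = mode, power_law_gamma = power_law_gamma),
            class = "fitness_spec")
}

seq_to_int <- function(seq) {
  x <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1L]], DNA_BASES)
  if (anyNA(x)) stop("sequence contains non-ACGT characters")
  x
}

int_to_seq <- function(x) paste(DNA_BASES[x], collapse = "")

#' Additive binding energy of a sequence window
#'
#' Sum of per-position energy contributions of an `n`-bp window. In mismatch
#' mode this equals `epsilon` times the Hamming distance to the consensus.
#'
#' @param seq_window Length-`n` ACGT string.
#' @param model A [binding_model()].
#' @return Binding energy in kB*T (consensus = 0).
#' @export
site_energy <- function(seq_window, model) {
  stopifnot(inherits(model, "binding_model"))
  x <- seq_to_int(seq_window)
  if (length(x) != model$n)
    stop("window length ", length(x), " != site length n = ", model$n)
  if (is.null(model$energy_matrix)) {
    cons <- seq_to_int(model$consensus)
    model$epsilon * sum(x != cons)
  } else {
    sum(model$energy_matrix[cbind(x, seq_len(model$n))])
  }
}

occupancy_from_energy <- function(E, model) {
  1 / (1 + exp(model$beta * (E - model$mu)))
}

#' Thermodynamic occupancy of a site by mismatch class
#'
#' Equilibrium binding probability `1 / (1 + exp(beta * (epsilon*k - mu)))`
#' for a site with `k` mismatches from the consensus. Strictly decreasing in
#' `k`, strictly increasing in `mu`, and equal to 1/2 where
#' `epsilon * k = mu`.
#'
#' @param k Integer vector of mismatch counts in `0..n`.
#' @param model A [binding_model()].
#' @return Occupancy values in (0, 1).
#' @export
occupancy <- function(k, model) {
  stopifnot(inherits(model, "binding_model"))
  if (any(k < 0 | k > model$n)) stop("mismatch class k out of range 0..n")
  occupancy_from_energy(model$epsilon * k, model)
}

## Two-site partition function on the energy scale. Favorable (negative) E_c
## increases the joint-occupancy weight exp(-beta*(E + E_partner + E_c - 2*mu)).
coop_occupancy_energy <- function(E, E_partner, model, coop) {
  b <- model$beta
  ## exponents of the four states: empty, focal, partner, joint
  ex <- cbind(0,
              -b * (E - model$mu),
              -b * (E_partner - model$mu),
              -b * (E + E_partner + coop$E_c - 2 * model$mu))
  m <- apply(ex, 1L, max)
  w <- exp(ex - m)
  (w[, 2L] + w[, 4L]) / rowSums(w)
}

#' Occupancy of a site with a cooperative partner
#'
#' Focal-site marginal occupancy from the two-site partition function: states
#' (empty, focal bound, partner bound, both bound) with the joint state
#' receiving the additional interaction energy `E_c`. Reduces exactly to
#' [occupancy()] at `E_c = 0`; a strongly bound partner acts as a local shift
#' of the chemical potential at the focal site.
#'
#' @param k Mismatch class of the focal site.
#' @param k_c Mismatch class of the cooperating partner site.
#' @param model A [binding_model()].
#' @param coop A [cooperativity_params()].
#' @return Focal-site occupancy in (0, 1); vectorized over `k`/`k_c`.
#' @export
occupancy_cooperative <- function(k, k_c, model, coop) {
  stopifnot(inherits(model, "binding_model"),
            inherits(coop, "cooperativity_params"))
  if (any(k < 0 | k > model$n) || any(k_c < 0 | k_c > model$n))
    stop("mismatch class out of range 0..n")
  kk <- cbind(k, k_c)  # recycle
  unname(coop_occupancy_energy(model$epsilon * kk[, 1L],
                               model$epsilon * kk[, 2L], model, coop))
}

#' Single-site fitness over mismatch classes
#'
#' `f(k) = s * pi(k)` where `pi` is the thermodynamic occupancy, optionally
#' with the tail beyond the strong-class boundary `k_S` replaced by a power
#' law of exponent `power_law_gamma` (see [fitness_spec()]): the landscape
#' equals the thermodynamic value for `k <= k_S` and
#' `pi(k_S) * (k - k_S + 1)^(-gamma)` beyond, with `gamma = Inf` giving a step
#' landscape.
#'
#' @param k Integer vector of mismatch classes in `0..n`.
#' @param spec A [fitness_spec()].
#' @param model A [binding_model()].
#' @return Fitness values.
#' @export
single_site_fitness <- function(k, spec, model) {
  stopifnot(inherits(spec, "fitness_spec"), inherits(model, "binding_model"))
  pi_k <- occupancy(k, model)
  if (!is.null(spec$power_law_gamma)) {
    ks <- classify_binding(model)$k_S
    tail_idx <- k > ks
    if (any(tail_idx)) {
      g <- spec$power_law_gamma
      base <- occupancy(ks, model)
      pi_k[tail_idx] <- if (is.infinite(g)) 0 else
        base * (k[tail_idx] - ks + 1) ^ (-g)
    }
  }
  spec$s * pi_k
}

## Mismatch count of every n-window of an integer-coded sequence against the
## model consensus (1-based window starts 1..L-n+1).
window_mismatches <- function(x, cons) {
  n <- length(cons)
  W <- length(x) - n + 1L
  m <- integer(W)
  for (j in seq_len(n)) m <- m + (x[j:(j + W - 1L)] != cons[j])
  m
}

## Binding energy of every n-window (mismatch or matrix mode).
window_energies <- function(x, model) {
  if (is.null(model$energy_matrix)) {
    model$epsilon * window_mismatches(x, seq_to_int(model$consensus))
  } else {
    n <- model$n
    W <- length(x) - n + 1L
    E <- numeric(W)
    for (j in seq_len(n))
      E <- E + model$energy_matrix[cbind(x[j:(j + W - 1L)], j)]
    E
  }
}

## Per-window occupancies, cooperativity-adjusted if coop is given. For each
## focal window the partner is the non-overlapping window within `coop$window`
## bp (start-to-end gap) with the lowest energy; ties go to the leftmost.
window_occupancies <- function(x, model, coop = NULL) {
  E <- window_energies(x, model)
  if (is.null(coop)) return(occupancy_from_energy(E, model))
  n <- model$n
  W <- length(E)
  Ep <- rep(NA_real_, W)
  for (i in seq_len(W)) {
    js <- c(seq(i - n - coop$window, i - n, by = 1L),
            seq(i + n, i + n + coop$window, by = 1L))
    js <- js[js >= 1L & js <= W]
    if (length(js)) Ep[i] <- E[js[which.min(E[js])]]
  }
  out <- occupancy_from_energy(E, model)
  has <- !is.na(Ep)
  if (any(has))
    out[has] <- coop_occupancy_energy(E[has], Ep[has], model, coop)
  out
}

#' Promoter fitness from window occupancies
#'
#' Scans all `L - n + 1` windows (1-based, single strand) of a regulatory
#' sequence and maps their occupancies to fitness according to the mode of the
#' [fitness_spec()]: `"additive"` sums the occupancies, `"strongest"` takes the
#' maximum, `"synergistic_pair"` uses the product (joint occupancy) of the two
#' strongest windows. With `coop`, each window's occupancy is adjusted for its
#' best (lowest-energy) cooperative partner within the allowed gap.
#'
#' @param seq Length-`L` ACGT string with `L >= n`.
#' @param spec A [fitness_spec()].
#' @param model A [binding_model()].
#' @param coop Optional [cooperativity_params()].
#' @return Scalar fitness.
#' @export
promoter_fitness <- function(seq, spec, model, coop = NULL) {
  stopifnot(inherits(spec, "fitness_spec"), inherits(model, "binding_model"))
  x <- seq_to_int(seq)
  if (length(x) < model$n) stop("sequence shorter than site length n")
  pi_w <- window_occupancies(x, model, coop)
  g <- switch(spec$mode,
    additive = sum(pi_w),
    strongest = max(pi_w),
    synergistic_pair = if (length(pi_w) == 1L) pi_w else
      prod(sort(pi_w, decreasing = TRUE)[1:2]))
  spec$s * g
}

#' Strong/weak binding class boundaries
#'
#' Partitions mismatch classes into strong binding (occupancy > 2/3) and weak
#' binding (occupancy < 1/3). `k_S` is the largest class still binding
#' strongly, `k_W` the smallest class binding weakly, and the *presite* class
#' is `k_S + 1` (one mutation away from strong binding).
#'
#' @param model A [binding_model()].
#' @return List with integer elements `k_S`, `k_W`, `presite`.
#' @export
classify_binding <- function(model) {
  stopifnot(inherits(model, "binding_model"))
  pi_k <- occupancy(0:model$n, model)
  strong <- which(pi_k > 2 / 3)
  if (!length(strong))
    stop("no mismatch class has occupancy > 2/3: ",
         "TF cannot bind strongly at this mu/epsilon")
  k_S <- max(strong) - 1L
  weak <- which(pi_k < 1 / 3)
  k_W <- if (length(weak)) min(weak) - 1L else model$n
  list(k_S = as.integer(k_S), k_W = as.integer(k_W),
       presite = as.integer(k_S + 1L))
}
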