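## integer-level helper: plant exactly k mismatches (random positions, random
## non-consensus bases) onto a consensus window
plant_mismatches <- function(cons, k) {
  n <- length(cons)
  if (k > n) stop("k exceeds site length")
  x <- cons
  if (k > 0) {
    pos <- sample.int(n, k)
    for (p in pos)
      x[p] <- sample.int(4L, 1L, prob = as.numeric(seq_len(4L) != cons[p]))
  }
  x
}

#' Random ACGT sequence
#'
#' @param L Sequence length (>= 1).
#' @param composition Base probabilities in A, C, G, T order (default
#'   uniform).
#' @return An ACGT string; reproducible under `set.seed()`.
#' @export
random_sequence <- function(L, composition = rep(0.25, 4)) {
  stopifnot(L >= 1, length(composition) == 4L, all(composition >= 0),
            sum(composition) > 0)
  int_to_seq(sample.int(4L, L, replace = TRUE, prob = composition))
}

#' Plant a binding site at a given mismatch distance
#'
#' Replaces the window `[position, position + n - 1]` of `seq` by a copy of
#' `consensus` carrying exactly `k` mismatches at uniformly chosen positions
#' (without replacement), each mutated to a uniformly chosen different base.
#'
#' @param seq ACGT string of length `L`.
#' @param consensus ACGT string of length `n <= L`.
#' @param position 1-based start of the planted site
#'   (`position + n - 1 <= L`).
#' @param k Number of mismatches to plant (`0..n`).
#' @return The modified sequence string.
#' @export
plant_site <- function(seq, consensus, position, k) {
  x <- seq_to_int(seq)
  cons <- seq_to_int(consensus)
  n <- length(cons)
  if (position < 1L || position + n - 1L > length(x))
    stop("planted site does not fit in the sequence")
  x[position:(position + n - 1L)] <- plant_mismatches(cons, k)
  int_to_seq(x)
}

#' Random energy matrix with Gaussian mismatch penalties
#'
#' Builds a 4 x n energy matrix with one consensus (zero) entry per column at
#' a uniformly chosen base and the three non-consensus entries drawn i.i.d.
#' from a Normal(`mean_eps`, `sd`) truncated at zero (the consensus must stay
#' the minimum-energy base). `sd = 0` recovers the uniform-mismatch model.
#'
#' @param n Site length in bp.
#' @param mean_eps Mean mismatch penalty in kB*T (default 2).
#' @param sd Standard deviation in kB*T (default 0.5).
#' @return A 4 x n matrix with rows named A, C, G, T.
#' @export
gaussian_energy_matrix <- function(n, mean_eps = 2, sd = 0.5) {
  stopifnot(n >= 1, sd >= 0)
  xi <- matrix(0, 4L, n, dimnames = list(DNA_BASES, NULL))
  cons <- sample.int(4L, n, replace = TRUE)
  for (j in seq_len(n)) {
    others <- setdiff(1:4, cons[j])
    if (sd == 0) {
      xi[others, j] <- mean_eps
    } else {
      ## inverse-CDF sampling from Normal truncated to (0, Inf)
      p0 <- stats::pnorm(0, mean_eps, sd)
      q <- stats::runif(3L, p0, 1)
      xi[others, j] <- stats::qnorm(q, mean_eps, sd)
    }
  }
  xi
}
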