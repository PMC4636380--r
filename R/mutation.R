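#' Point and indel mutation process
#'
#' Parameters of the sequence-level mutation process: point mutations at rate
#' `u` per bp per generation, and short insertions/deletions at rate
#' `theta * u` per bp, with lengths drawn from `indel_lengths` (relative
#' frequencies, renormalized internally) and insertions/deletions equally
#' likely. `alpha` is the probability that a random base mismatches the
#' consensus (3/4 for uniform base composition).
#'
#' @param u Point mutation rate per bp per generation (> 0).
#' @param theta Ratio of indel to point mutation rate (>= 0); typical values
#'   0 (none) or 0.15.
#' @param indel_lengths Named numeric vector mapping indel length (bp) to
#'   relative frequency; defaults to `c("1" = 0.45, "2" = 0.18)`, the reported
#'   frequencies of 1- and 2-bp indels, renormalized to sum to 1.
#' @param alpha Background mismatch probability; default 3/4.
#' @return An object of class `mutation_model`.
#' @export
mutation_model <- function(u = 1e-5, theta = 0,
                           indel_lengths = c("1" = 0.45, "2" = 0.18),
                           alpha = 3 / 4) {
  stopifnot(is.numeric(u), length(u) == 1L, u >= 0,
            is.numeric(theta), length(theta) == 1L, theta >= 0,
            is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  if (is.null(names(indel_lengths)))
    names(indel_lengths) <- seq_along(indel_lengths)
  if (any(indel_lengths <= 0)) stop("indel length frequencies must be positive")
  indel_lengths <- indel_lengths / sum(indel_lengths)
  lens <- as.integer(names(indel_lengths))
  if (anyNA(lens) || any(lens < 1L))
    stop("indel lengths must be positive integers (names of 'indel_lengths')")
  structure(list(u = u, theta = theta, indel_lengths = indel_lengths,
                 alpha = alpha), class = "mutation_model")
}

#' @export
print.mutation_model <- function(x, ...) {
  cat(sprintf("mutation_model: u = %.3g /bp/gen, theta = %.3g, alpha = %.3g\n",
              x$u, x$theta, x$alpha))
  cat("  indel lengths:",
      paste(sprintf("%s bp (%.2f)", names(x$indel_lengths), x$indel_lengths),
            collapse = ", "), "\n")
  invisible(x)
}

new_mismatch_kernel <- function(P, flavor) {
  dimnames(P) <- list(k_to = 0:(nrow(P) - 1L), k_from = 0:(ncol(P) - 1L))
  structure(P, flavor = flavor, class = c("mismatch_kernel", "matrix"))
}

#' Point-mutation kernel over mismatch classes
#'
#' Probability that a single point mutation in an `n`-bp site moves it from
#' mismatch class `k` (column) to `k'` (row): up `1 - k/n`, down `k/(3n)`,
#' unchanged `2k/(3n)`. Columns sum to 1.
#'
#' @param n Site length in bp.
#' @return An `(n+1) x (n+1)` column-stochastic `mismatch_kernel`.
#' @export
point_kernel <- function(n) {
  stopifnot(n >= 1)
  n <- as.integer(n)
  P <- matrix(0, n + 1L, n + 1L)
  for (k in 0:n) {
    if (k < n) P[k + 2L, k + 1L] <- 1 - k / n
    if (k > 0) P[k, k + 1L] <- k / (3 * n)
    P[k + 1L, k + 1L] <- 2 * k / (3 * n)
  }
  new_mismatch_kernel(P, "point")
}

#' Indel-mutation kernel over mismatch classes
#'
#' Analytic probability that an indel at a uniform position `i` within the
#' site moves it from class `k` to `k'`. The segment on the anchored side of
#' the indel keeps its mismatches (`X ~ Binomial(i-1, k/n)`), while the
#' segment within and beyond the indel is replaced by effectively random
#' sequence (`Y ~ Binomial(n-i+1, alpha)`); `P(k'|k)` is the position-averaged
#' convolution. The kernel is independent of indel length.
#'
#' @param n Site length in bp.
#' @param model A [mutation_model()] (only `alpha` is used).
#' @return An `(n+1) x (n+1)` column-stochastic `mismatch_kernel`.
#' @export
indel_kernel <- function(n, model = mutation_model()) {
  stopifnot(n >= 1, inherits(model, "mutation_model"))
  n <- as.integer(n)
  alpha <- model$alpha
  P <- matrix(0, n + 1L, n + 1L)
  for (k in 0:n) {
    col <- numeric(n + 1L)
    for (i in seq_len(n)) {
      px <- stats::dbinom(0:(i - 1L), i - 1L, k / n)
      py <- stats::dbinom(0:(n - i + 1L), n - i + 1L, alpha)
      for (a in seq_along(px))
        col[(a - 1L) + seq_along(py)] <-
          col[(a - 1L) + seq_along(py)] + px[a] * py
    }
    P[, k + 1L] <- col / n
  }
  new_mismatch_kernel(P, "indel")
}

#' Combined mutation rate matrix over mismatch classes
#'
#' Generator of the mutation process on mismatch classes, in units of the
#' point mutation rate `u`:
#' `U[k',k] = n * (P_point[k',k] + theta * P_indel[k',k])` off the diagonal,
#' with the diagonal closing each column to zero.
#'
#' @param n Site length in bp.
#' @param model A [mutation_model()].
#' @return An `(n+1) x (n+1)` `mismatch_kernel` of flavor `"rate"` (units of
#'   `u`; columns sum to 0).
#' @export
combined_rate_matrix <- function(n, model = mutation_model()) {
  Pp <- point_kernel(n)
  U <- n * unclass(Pp)
  if (model$theta > 0)
    U <- U + n * model$theta * unclass(indel_kernel(n, model))
  diag(U) <- 0
  diag(U) <- -colSums(U)
  new_mismatch_kernel(U, "rate")
}

#' Export a mismatch kernel as TSV
#'
#' Writes the matrix with a header row and a leading column of `k` indices
#' (rows = destination class, columns = source class).
#'
#' @param kernel A `mismatch_kernel`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_kernel_tsv <- function(kernel, path) {
  df <- data.frame(k = rownames(kernel), as.data.frame(unclass(kernel)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Single mutation event on an integer-coded sequence. Returns list(x, event).
## The sequence is anchored at its final (right) position: insertions push
## existing bases left and trim the distal (index-1) end; deletions pull in
## random bases at the distal end. Length is always preserved.
mutate_int <- function(x, model) {
  L <- length(x)
  type <- if (model$theta > 0 &&
              stats::runif(1) < model$theta / (1 + model$theta))
    "indel" else "point"
  if (type == "point") {
    p <- sample.int(L, 1L)
    x[p] <- sample.int(4L, 1L, prob = as.numeric(seq_len(4L) != x[p]))
    return(list(x = x, event = list(type = "point", pos = p)))
  }
  lens <- as.integer(names(model$indel_lengths))
  d <- lens[sample.int(length(lens), 1L, prob = model$indel_lengths)]
  if (d >= L) stop("indel length d >= sequence length L")
  if (stats::runif(1) < 0.5) {
    ## insertion of d random bases after position p (p = L appends at the
    ## anchored end); keep the last L bases
    p <- sample.int(L, 1L)
    y <- append(x, sample.int(4L, d, replace = TRUE), after = p)
    list(x = y[(d + 1L):(L + d)],
         event = list(type = "insertion", pos = p, d = d))
  } else {
    ## deletion of d bases starting at p; pad the distal end with random bases
    p <- sample.int(L - d + 1L, 1L)
    list(x = c(sample.int(4L, d, replace = TRUE), x[-(p:(p + d - 1L))]),
         event = list(type = "deletion", pos = p, d = d))
  }
}

#' Apply one mutation event to a sequence
#'
#' Draws the event type (point with probability `1/(1+theta)`, indel with
#' `theta/(1+theta)`) and applies it. The sequence is anchored at its final
#' position: an insertion of length `d` inserts `d` random bases after a
#' uniform position and trims `d` bases from the distal (index-1) end; a
#' deletion removes `d` bases and pads `d` random bases at the distal end.
#' Output length always equals input length.
#'
#' @param seq ACGT string.
#' @param model A [mutation_model()].
#' @return List with elements `seq` (mutated string) and `event` (list with
#'   `type`, `pos` and, for indels, `d`).
#' @export
mutate_sequence <- function(seq, model) {
  stopifnot(inherits(model, "mutation_model"))
  res <- mutate_int(seq_to_int(seq), model)
  list(seq = int_to_seq(res$x), event = res$event)
}
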