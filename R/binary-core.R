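#' Hamming distance between two bitstrings
#'
#' The number of positions at which two equal-length bitstrings differ. This
#' is the distance notion under which the binary quantum-behaved swarm
#' contracts toward its mean best position.
#'
#' @param a,b Bitstrings (see [as_bits()]) of equal length.
#' @return A non-negative integer count.
#' @examples
#' hamming("1011001010", "0010010110") # 5
#' @export
hamming <- function(a, b) {
  a <- as_bits(a)
  b <- as_bits(b)
  if (length(a) != length(b)) {
    stop(
      "hamming distance requires equal lengths (got ",
      length(a), " and ", length(b), ")",
      call. = FALSE
    )
  }
  sum(a != b)
}

#' Mean best position of the swarm
#'
#' Builds `mbest` by a per-bit majority vote over all particles' personal best
#' positions: bit j of `mbest` is 1 when 1 occurs strictly more often than 0
#' at bit j across the personal bests, 0 when it occurs strictly less often,
#' and is drawn uniformly at random (probability 0.5 for either state) on an
#' exact tie. Ties are resolved freshly on every call from R's global random
#' stream.
#'
#' @param pbest_list A non-empty list of equal-length bitstrings, or a matrix
#'   with one personal best per row.
#' @return A bitstring of the common length.
#' @examples
#' set.seed(1)
#' get_mbest(list("111", "111", "000")) # "111": strict majority at every bit
#' @export
get_mbest <- function(pbest_list) {
  if (is.matrix(pbest_list)) {
    pbest_list <- lapply(seq_len(nrow(pbest_list)), function(i) pbest_list[i, ])
  }
  if (!is.list(pbest_list) || length(pbest_list) == 0L) {
    stop("pbest_list must be a non-empty list of bitstrings", call. = FALSE)
  }
  pb <- lapply(pbest_list, as_bits)
  lens <- lengths(pb)
  if (any(lens != lens[1L])) {
    stop("all personal bests must have equal length", call. = FALSE)
  }
  ones <- Reduce(`+`, pb)
  n <- length(pb)
  out <- integer(lens[1L])
  out[2L * ones > n] <- 1L
  tie <- 2L * ones == n
  if (any(tie)) out[tie] <- as.integer(stats::runif(sum(tie)) < 0.5)
  out
}

#' Local attractor by crossover of personal and global best
#'
#' The point toward which a particle is perturbed. It is produced by crossover
#' of the particle's personal best with the swarm's global best — one-point by
#' default, two-point under `mode = "multipoint"` — and one of the two
#' offspring is returned uniformly at random. Every bit of the result equals
#' the corresponding bit of one parent, so the attractor always lies between
#' the parents in Hamming distance.
#'
#' @param pbest,gbest Equal-length bitstrings.
#' @param mode `"one-point"` (default) or `"multipoint"` (two cut points).
#' @return A bitstring of the common length.
#' @export
get_local_attractor <- function(pbest, gbest, mode = c("one-point", "multipoint")) {
  mode <- match.arg(mode)
  pbest <- as_bits(pbest)
  gbest <- as_bits(gbest)
  l <- length(pbest)
  if (l != length(gbest)) {
    stop("pbest and gbest must have equal length", call. = FALSE)
  }
  if (l == 1L) {
    return(if (stats::runif(1) < 0.5) pbest else gbest)
  }
  n_cuts <- if (mode == "one-point") 1L else min(2L, l - 1L)
  cuts <- sort(sample.int(l - 1L, n_cuts))
  # segment s takes bits from parent A when s is odd, parent B when even
  seg <- cumsum(seq_len(l) %in% (cuts + 1L)) %% 2L
  from_gbest <- seg == 1L
  child <- pbest
  child[from_gbest] <- gbest[from_gbest]
  if (stats::runif(1) < 0.5) {
    other <- gbest
    other[from_gbest] <- pbest[from_gbest]
    child <- other
  }
  child
}

#' Jump length and mutation probability toward the mean best
#'
#' Draws the particle's Hamming jump length
#' `b = ceiling(ce * d_H(x, mbest) * ln(1/mu))` with `mu` uniform on the open
#' interval (0, 1), then converts it into a per-bit mutation probability
#' `pr = min(b / l, 1)` for a substring of length `l`. The ceiling is applied
#' to the full product so that `b` is an integer; `b = 0` exactly when the
#' particle already sits on `mbest`.
#'
#' @param x,mbest Equal-length bitstrings.
#' @param ce_coefficient Positive contraction-expansion coefficient scaling
#'   the jump (default 1).
#' @param mu Optional fixed value in (0, 1) replacing the uniform draw
#'   (useful for deterministic checks of the arithmetic).
#' @return A list of class `jump_draw` with fields `mu`, `b`, and `pr`.
#' @export
jump_length <- function(x, mbest, ce_coefficient = 1, mu = NULL) {
  stopifnot(is.numeric(ce_coefficient), ce_coefficient > 0)
  d <- hamming(x, mbest)
  l <- length(as_bits(x))
  if (is.null(mu)) {
    mu <- stats::runif(1)
    while (mu <= 0 || mu >= 1) mu <- stats::runif(1)
  }
  stopifnot(is.numeric(mu), length(mu) == 1L, mu > 0, mu < 1)
  b <- as.integer(ceiling(ce_coefficient * d * log(1 / mu)))
  structure(list(mu = mu, b = b, pr = min(b / l, 1)), class = "jump_draw")
}

#' Probabilistic mutation of the local attractor
#'
#' Flips each bit of `p` independently with probability `draw$pr`. With
#' `pr = b / l` the expected Hamming displacement of the result from `p` is
#' `b`, realizing the jump-length contract of the binary quantum-behaved
#' update; `pr = 0` leaves `p` unchanged and `pr = 1` returns its complement.
#'
#' @param p A bitstring (typically a local attractor).
#' @param draw A `jump_draw` from [jump_length()], or a bare probability in
#'   \[0, 1\].
#' @return A bitstring of the same length as `p`.
#' @export
mutate_toward <- function(p, draw) {
  p <- as_bits(p)
  pr <- if (inherits(draw, "jump_draw")) draw$pr else draw
  stopifnot(is.numeric(pr), length(pr) == 1L, pr >= 0, pr <= 1)
  if (pr == 0) return(p)
  flip <- stats::runif(length(p)) < pr
  p[flip] <- 1L - p[flip]
  p
}
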