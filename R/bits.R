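#' Bitstring positions
#'
#' Candidate gene subsets are encoded as fixed-length 0/1 vectors: bit j is 1
#' when gene j of the (prefiltered) search space is included in the subset.
#' Internally a bitstring is a plain integer vector of 0s and 1s; for logs and
#' serialized reports it is rendered as a compact character string such as
#' `"1011001010"`.
#'
#' @param x A numeric/integer vector of 0s and 1s, a logical vector, or a
#'   single character string of `"0"`/`"1"` digits.
#' @return An integer vector of 0s and 1s.
#' @examples
#' as_bits("1011001010")
#' bits_to_string(c(1L, 0L, 1L))
#' @export
as_bits <- function(x) {
  if (is.character(x)) {
    stopifnot(length(x) == 1L, nzchar(x))
    x <- as.integer(strsplit(x, "", fixed = TRUE)[[1L]])
  }
  if (is.logical(x)) x <- as.integer(x)
  x <- as.integer(x)
  if (length(x) == 0L || anyNA(x) || !all(x == 0L | x == 1L)) {
    stop("a bitstring must be a non-empty sequence of 0s and 1s", call. = FALSE)
  }
  x
}

#' @rdname as_bits
#' @export
bits_to_string <- function(x) paste(as_bits(x), collapse = "")

#' Particle layout
#'
#' A particle position may be partitioned into `D` decision variables
#' (substrings); its total length is the sum of the substring lengths. The
#' gene-selection application uses a single decision variable whose length
#' equals the number of candidate genes (50 after the default prefilter).
#'
#' @param substring_lengths Positive integer vector of per-variable lengths.
#' @return An object of class `particle_layout` with fields `num_variables`,
#'   `substring_lengths`, and `total_length`.
#' @examples
#' particle_layout(50)
#' @export
particle_layout <- function(substring_lengths = 50L) {
  substring_lengths <- as.integer(substring_lengths)
  stopifnot(length(substring_lengths) >= 1L, all(substring_lengths >= 1L))
  structure(
    list(
      num_variables = length(substring_lengths),
      substring_lengths = substring_lengths,
      total_length = sum(substring_lengths)
    ),
    class = "particle_layout"
  )
}

#' @export
print.particle_layout <- function(x, ...) {
  cat(
    "particle layout: ", x$num_variables, " variable(s), total length ",
    x$total_length, "\n",
    sep = ""
  )
  invisible(x)
}
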