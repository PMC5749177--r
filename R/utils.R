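#' @importFrom rlang abort warn inform %||% .data :=
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_dbl map_int map_chr
#' @importFrom stats median rnorm runif rbinom cor cor.test plogis qlogis
#'   setNames sd
#' @importFrom utils head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

# integer base codes: 0 = ambiguous/N, 1..4 = A,C,G,T
encode_codes <- function(seq_string) {
  chars <- strsplit(toupper(seq_string), "", fixed = TRUE)[[1]]
  codes <- match(chars, DNA_BASES)
  codes[is.na(codes)] <- 0L
  as.integer(codes)
}

decode_codes <- function(codes) {
  paste(c("N", DNA_BASES)[codes + 1L], collapse = "")
}

#' One-hot encode a DNA window
#'
#' Converts a base-code vector or DNA string into an L x 4 binary matrix with
#' columns ordered A, C, G, T. Ambiguous bases (anything outside ACGT, e.g. N)
#' become all-zero rows, keeping the encoding strictly binary.
#'
#' @param x Integer base codes (0 = ambiguous, 1..4 = A,C,G,T), a character
#'   string of bases, or a `dna_window`.
#' @return An L x 4 numeric 0/1 matrix with `colnames` A,C,G,T.
#' @export
one_hot <- function(x) {
  if (inherits(x, "dna_window")) x <- x$codes
  if (is.character(x)) x <- encode_codes(x)
  L <- length(x)
  m <- matrix(0, L, 4, dimnames = list(NULL, DNA_BASES))
  hit <- x > 0L
  m[cbind(which(hit), x[hit])] <- 1
  m
}

#' Decode a one-hot matrix back to a DNA string
#'
#' Inverse of [one_hot()]: all-zero rows decode to `"N"`.
#'
#' @param m An L x 4 one-hot matrix (columns A,C,G,T).
#' @return A single character string of length L.
#' @export
decode_one_hot <- function(m) {
  stopifnot(is.matrix(m), ncol(m) == 4)
  codes <- as.integer(m %*% (1:4))
  codes[rowSums(m) == 0] <- 0L
  decode_codes(codes)
}

# reverse complement on codes (0 stays 0; A<->T, C<->G)
revcomp_codes <- function(codes) {
  comp <- c(0L, 4L, 3L, 2L, 1L)
  rev(comp[codes + 1L])
}

# column-wise max of a matrix without matrixStats
col_max <- function(m) {
  out <- m[1L, ]
  if (nrow(m) > 1L) for (r in 2:nrow(m)) out <- pmax(out, m[r, ])
  out
}

# sample() treats a length-1 numeric first argument as 1:n; this helper
# always samples from the elements of x
sample1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

check_probability_vector <- function(x, what = "background") {
  if (length(x) != 4 || any(!is.finite(x)) || any(x <= 0)) {
    abort(sprintf("%s must be a 4-vector of strictly positive frequencies", what))
  }
  if (abs(sum(x) - 1) > 1e-6) {
    abort(sprintf("%s must sum to 1 (got %.6f)", what, sum(x)))
  }
  invisible(x)
}
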