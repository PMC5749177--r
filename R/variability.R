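#' Per-individual inter-individual variability statistic
#'
#' For a phenotype matrix with loci in rows and individuals in columns,
#' computes for each individual `n`
#' \deqn{V_n = \frac{N}{L (N - 1)} \sum_{l=1}^{L}
#'       \frac{(\chi_{nl} - \bar\chi_l)^2}{\bar\chi_l^2}}
#' the average squared relative distance from the per-locus mean, scaled by
#' the unbiased-variance correction. Loci with zero mean are dropped before
#' `L` is counted (with a message); the statistic is invariant to rescaling
#' all values by a non-zero constant. Under i.i.d. noise with per-locus
#' coefficient of variation sigma, mean `V_n` approaches sigma^2.
#'
#' @param x Numeric matrix (loci x individuals) or a data frame whose
#'   numeric columns are individuals.
#' @return Tibble with `sample`, `v_n` and `log2_vn` (`-Inf` when
#'   `v_n` is 0).
#' @export
variability <- function(x) {
  if (is.data.frame(x)) {
    num <- vapply(x, is.numeric, logical(1))
    x <- as.matrix(x[, num, drop = FALSE])
  }
  if (!is.numeric(x)) abort("x must be a numeric loci-by-individuals matrix")
  n <- ncol(x)
  if (n < 2) abort("need at least 2 individuals")
  means <- rowMeans(x)
  drop <- !is.finite(means) | means == 0
  if (any(drop)) {
    inform(sprintf("dropping %d locus/loci with zero or non-finite mean", sum(drop)))
    x <- x[!drop, , drop = FALSE]
    means <- means[!drop]
  }
  l <- nrow(x)
  if (l == 0) abort("all loci dropped; no finite non-zero locus means")
  rel_sq <- sweep(x, 1, means, "-")^2 / means^2
  v_n <- n / (l * (n - 1)) * colSums(rel_sq)
  tibble(sample = colnames(x) %||% sprintf("sample_%d", seq_len(n)),
         v_n = unname(v_n),
         log2_vn = log2(unname(v_n)))
}
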