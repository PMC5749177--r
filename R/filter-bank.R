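#' Build a frozen convolutional filter bank from PWMs
#'
#' Log-transforms every PWM against a shared background, zero-pads all
#' filters on the right to the maximum motif width, and (by default)
#' augments each filter with its reverse complement. Under the
#' `"rc_max"` strand policy, downstream scoring takes the positionwise
#' maximum of the forward and reverse-complement scores for each TF, so
#' accessibility scoring is strand-symmetric. Padded positions have zero
#' weight and therefore contribute exactly nothing to any dot product.
#'
#' Duplicate `tf_id`s (e.g. the same factor curated from two sources) are
#' disambiguated by suffixing the source name.
#'
#' @param pwms List of [new_pwm()] objects (non-empty).
#' @param strand_policy `"rc_max"` (default) or `"forward_only"`.
#' @param background 4-vector of base frequencies for the log transform.
#' @param pseudocount Pseudocount for the log transform.
#' @return An object of class `filter_bank`.
#' @export
build_filter_bank <- function(pwms, strand_policy = c("rc_max", "forward_only"),
                              background = rep(0.25, 4), pseudocount = 1e-3) {
  strand_policy <- match.arg(strand_policy)
  if (length(pwms) == 0) abort("cannot build a filter bank from an empty PWM list")
  check_probability_vector(background)

  tf_ids <- map_chr(pwms, "tf_id")
  if (anyDuplicated(tf_ids)) {
    dup <- duplicated(tf_ids) | duplicated(tf_ids, fromLast = TRUE)
    tf_ids[dup] <- paste(tf_ids[dup], map_chr(pwms, "source")[dup], sep = "_")
    if (anyDuplicated(tf_ids)) tf_ids <- make.unique(tf_ids, sep = "_")
  }
  widths <- map_int(pwms, pwm_width)
  if (any(widths < 4)) {
    warn(sprintf("%d PWM(s) narrower than 4 bp included in filter bank",
                 sum(widths < 4)))
  }
  wmax <- max(widths)
  n_tf <- length(pwms)

  fwd <- map(pwms, log_transform, background = background, pseudocount = pseudocount)
  # reverse complement: reverse positions, swap A<->T and C<->G columns
  rc <- map(fwd, function(w) {
    m <- w[rev(seq_len(nrow(w))), 4:1, drop = FALSE]
    colnames(m) <- DNA_BASES
    m
  })
  filters <- if (strand_policy == "rc_max") c(fwd, rc) else fwd
  n_col <- length(filters)

  # position-indexed lookup tables for the code-gather convolution:
  # lut[[w]] is a 5 x n_col matrix (rows: N,A,C,G,T); padded positions are 0
  lut <- map(seq_len(wmax), function(w) {
    m <- matrix(0, 5, n_col)
    for (f in seq_len(n_col)) {
      if (w <= nrow(filters[[f]])) m[2:5, f] <- filters[[f]][w, ]
    }
    m
  })

  structure(list(
    tf_ids = tf_ids,
    tf_names = map_chr(pwms, "tf_name"),
    widths = widths,
    wmax = wmax,
    n_tf = n_tf,
    strand_policy = strand_policy,
    background = background,
    pseudocount = pseudocount,
    forward = setNames(fwd, tf_ids),
    revcomp = setNames(rc, tf_ids),
    lut = lut
  ), class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf("<filter_bank> %d TFs, widths %d-%d (padded to %d), strand policy %s\n",
              x$n_tf, min(x$widths), max(x$widths), x$wmax, x$strand_policy))
  invisible(x)
}

# practical bit-level fingerprint of the frozen weights (no digest available;
# exact weight copies are compared with identical() in tests)
filter_bank_checksum <- function(bank) {
  w <- unlist(bank$forward, use.names = FALSE)
  paste(format(c(length(w), sum(w), sum(w * w),
                 sum(w * seq_along(w))), digits = 22), collapse = "|")
}

# first-layer scores from integer base codes; returns (L - wmax + 1) x n_col
# matrix BEFORE strand reduction (n_col = 2*n_tf under rc_max)
conv1_scores_codes <- function(bank, codes) {
  L <- length(codes)
  lout <- L - bank$wmax + 1L
  if (lout < 1L) abort(sprintf("sequence length %d shorter than padded filter width %d",
                               L, bank$wmax))
  s <- matrix(0, lout, length(bank$lut[[1]][1, ]))
  idx0 <- seq_len(lout)
  for (w in seq_len(bank$wmax)) {
    s <- s + bank$lut[[w]][codes[idx0 + (w - 1L)] + 1L, , drop = FALSE]
  }
  s
}

# same scores from an arbitrary L x 4 matrix input (used for non-binary
# DeepLIFT reference inputs)
conv1_scores_matrix <- function(bank, x) {
  L <- nrow(x)
  lout <- L - bank$wmax + 1L
  if (lout < 1L) abort("input shorter than padded filter width")
  n_col <- ncol(bank$lut[[1]])
  s <- matrix(0, lout, n_col)
  idx0 <- seq_len(lout)
  for (w in seq_len(bank$wmax)) {
    s <- s + x[idx0 + (w - 1L), , drop = FALSE] %*% bank$lut[[w]][2:5, , drop = FALSE]
  }
  s
}

# strand reduction: positionwise max over the forward/RC filter pair per TF
strand_reduce <- function(bank, scores) {
  if (bank$strand_policy == "forward_only") return(scores)
  n <- bank$n_tf
  pmax(scores[, seq_len(n), drop = FALSE],
       scores[, n + seq_len(n), drop = FALSE])
}

#' First-layer pre-activations for one window
#'
#' Returns the strand-reduced pre-activation grid of the frozen PWM layer:
#' one score per TF per valid offset. Under `"forward_only"` this equals the
#' sliding-window dot product of each log-transformed PWM ([pwm_scan()]).
#'
#' @param bank A [build_filter_bank()] object.
#' @param window A `dna_window`, base-code vector, or DNA string.
#' @return (L - Wmax + 1) x n_tf matrix, columns named by `tf_id`.
#' @export
conv1_preact <- function(bank, window) {
  if (inherits(window, "dna_window")) window <- window$codes
  if (is.character(window)) window <- encode_codes(window)
  out <- strand_reduce(bank, conv1_scores_codes(bank, window))
  colnames(out) <- bank$tf_ids
  out
}

# pooled fixed features: ReLU then non-overlapping max-pool of width `pool`
# over positions; returns P1 x n_tf matrix
pool_features <- function(act, pool) {
  lout <- nrow(act)
  p1 <- lout %/% pool
  u <- matrix(0, p1, ncol(act))
  used <- p1 * pool
  for (f in seq_len(ncol(act))) {
    u[, f] <- col_max(matrix(act[seq_len(used), f], pool, p1))
  }
  u
}

# featurize one window -> pooled feature vector (length P1 * n_tf,
# filter-major column-major layout)
featurize_window <- function(bank, codes, pool) {
  act <- pmax(strand_reduce(bank, conv1_scores_codes(bank, codes)), 0)
  as.vector(pool_features(act, pool))
}

# featurize a list of windows -> N x (P1 * n_tf) matrix
featurize_windows <- function(bank, windows, pool) {
  get_codes <- function(w) if (inherits(w, "dna_window")) w$codes else w
  len <- length(get_codes(windows[[1]]))
  nfeat <- (len - bank$wmax + 1L) %/% pool * bank$n_tf
  feats <- vapply(windows, function(w) featurize_window(bank, get_codes(w), pool),
                  numeric(nfeat))
  t(feats)
}
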