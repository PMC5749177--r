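# full forward pass of one window keeping every intermediate needed for
# DeepLIFT propagation; input is a code vector or an L x 4 matrix
full_forward <- function(model, input) {
  bank <- model$bank
  dims <- model$dims
  raw <- if (is.matrix(input)) conv1_scores_matrix(bank, input)
         else conv1_scores_codes(bank, input)
  pre <- strand_reduce(bank, raw)
  a1 <- pmax(pre, 0)
  used <- dims$p1 * dims$pool
  u <- matrix(0, dims$p1, dims$n_tf)
  parg <- matrix(0L, dims$p1, dims$n_tf)
  for (f in seq_len(dims$n_tf)) {
    m <- matrix(a1[seq_len(used), f], dims$pool, dims$p1)
    a <- max.col(t(m), ties.method = "first")        # row within bin
    parg[, f] <- (seq_len(dims$p1) - 1L) * dims$pool + a
    u[, f] <- a1[cbind(parg[, f], f)]
  }
  fw <- net_forward(model$weights, matrix(as.vector(u), 1), model$pidx, dims,
                    head = model$config$head, keep = TRUE)
  list(a1 = a1, u = u, parg = parg,
       z2 = matrix(fw$z2, dims$p2, dims$k),
       h2 = matrix(fw$h2, dims$p2, dims$k),
       g = fw$g[1, ], amax = fw$amax[1, ],
       z3 = fw$z3[1, ], h3 = fw$h3[1, ], z4 = fw$z4[1, ], s = fw$s[1, ])
}

reference_input <- function(model, window, reference_spec) {
  len <- model$dims$window_len
  switch(reference_spec,
    background = matrix(rep(model$bank$background, each = len), len, 4,
                        dimnames = list(NULL, DNA_BASES)),
    zeros = matrix(0, len, 4, dimnames = list(NULL, DNA_BASES)),
    shuffled = NULL)
}

output_mask <- function(model, target) {
  nout <- model$dims$nout
  if (model$config$output != "category") {
    if (!identical(target, model$config$output)) {
      abort(sprintf("binary model predicts '%s'; target must match", model$config$output))
    }
    return(1)
  }
  if (is.numeric(target)) {
    if (!target %in% 1:7) abort("category target must be in 1..7")
    mask <- numeric(7); mask[target] <- 1
  } else if (target %in% CELLTYPES) {
    mask <- numeric(7); mask[CELLTYPE_CATEGORIES[[target]]] <- 1
  } else {
    abort("target must be a category in 1..7 or one of 'ipsc', 'lcl', 'cm'")
  }
  mask
}

ratio_or <- function(dy, dx, fallback, eps = 1e-9) {
  out <- fallback
  ok <- abs(dx) > eps
  out[ok] <- dy[ok] / dx[ok]
  out
}

# multiplier through a max unit: route to the argmax of the actual input;
# when its delta vanishes but the output delta does not, distribute over all
# non-zero input deltas proportionally so summation-to-delta is preserved
max_multiplier <- function(m_out, dy, dx_vec, argmax_idx, eps = 1e-9) {
  m <- numeric(length(dx_vec))
  if (abs(m_out) < .Machine$double.xmin && abs(dy) < eps) return(m)
  da <- dx_vec[argmax_idx]
  if (abs(da) > eps) {
    m[argmax_idx] <- m_out * dy / da
  } else if (abs(dy) > eps) {
    ss <- sum(dx_vec^2)
    if (ss > 0) m <- m_out * dy * dx_vec / ss
  }
  m
}

#' DeepLIFT importance of each TF filter at each position
#'
#' Propagates DeepLIFT (Rescale rule) contributions from a target output
#' down to the post-ReLU activations of the frozen first convolutional
#' layer, yielding one score per TF per scan position relative to a
#' reference input. Contributions satisfy summation-to-delta: their sum
#' equals `f(x) - f(reference)` for the targeted output.
#'
#' For a cell-type target on the 7-way model, the attributed scalar is the
#' (unnormalized) sum of the sigmoid scores of the categories containing
#' that cell type, which keeps the output head linear in the sigmoid units.
#'
#' @param model A `pwmnet_model` with the default sigmoid head.
#' @param window A `dna_window` or base-code vector.
#' @param target A category in 1..7 or one of `"ipsc"`, `"lcl"`, `"cm"`.
#' @param reference_spec `"background"` (rows equal to the bank's background
#'   frequencies; default), `"zeros"`, or `"shuffled"` (a seeded permutation
#'   of the window's own bases, preserving base composition).
#' @param shuffle_seed Seed for the `"shuffled"` reference.
#' @return A `pwmnet_importance` object: TF x position score matrix plus
#'   `f_x`, `f_ref`, the target and the reference spec. `tidy()` returns the
#'   long form.
#' @export
deeplift_scores <- function(model, window, target,
                            reference_spec = c("background", "zeros", "shuffled"),
                            shuffle_seed = 1L) {
  reference_spec <- match.arg(reference_spec)
  if (model$config$head != "sigmoid") {
    abort("DeepLIFT propagation is implemented for the sigmoid head only")
  }
  codes <- if (inherits(window, "dna_window")) window$codes else as.integer(window)
  dims <- model$dims

  x <- full_forward(model, codes)
  ref_in <- if (reference_spec == "shuffled") {
    withr::with_seed(shuffle_seed, sample(codes))
  } else {
    reference_input(model, window, reference_spec)
  }
  r <- full_forward(model, ref_in)

  mask <- output_mask(model, target)
  f_x <- sum(mask * x$s)
  f_ref <- sum(mask * r$s)

  # sigmoid
  dz4 <- x$z4 - r$z4
  ds <- x$s - r$s
  m_z4 <- mask * ratio_or(ds, dz4, x$s * (1 - x$s))
  # output dense
  m_h3 <- as.vector(model$weights$W4 %*% m_z4)
  # ReLU
  m_z3 <- m_h3 * ratio_or(x$h3 - r$h3, x$z3 - r$z3, as.numeric(x$z3 > 0))
  # dense
  m_g <- as.vector(model$weights$W3 %*% m_z3)
  # global max-pool
  m_h2 <- matrix(0, dims$p2, dims$k)
  dg <- x$g - r$g
  for (k in seq_len(dims$k)) {
    m_h2[, k] <- max_multiplier(m_g[k], dg[k], x$h2[, k] - r$h2[, k], x$amax[k])
  }
  # ReLU
  m_z2 <- m_h2 * ratio_or(x$h2 - r$h2, x$z2 - r$z2, (x$z2 > 0) * 1)
  # learnable convolution (linear): push onto the pooled feature grid
  m_patch <- m_z2 %*% t(model$weights$W2)            # p2 x (w2 * n_tf)
  acc <- rowsum(as.vector(m_patch), group = as.vector(model$pidx))
  m_u <- numeric(dims$p1 * dims$n_tf)
  m_u[as.integer(rownames(acc))] <- acc
  m_u <- matrix(m_u, dims$p1, dims$n_tf)
  # first max-pool
  m_a1 <- matrix(0, dims$lout, dims$n_tf)
  du <- x$u - r$u
  for (f in seq_len(dims$n_tf)) {
    for (p in seq_len(dims$p1)) {
      if (m_u[p, f] == 0 && abs(du[p, f]) < 1e-9) next
      rr <- ((p - 1L) * dims$pool + 1L):(p * dims$pool)
      m_a1[rr, f] <- m_a1[rr, f] +
        max_multiplier(m_u[p, f], du[p, f], x$a1[rr, f] - r$a1[rr, f],
                       x$parg[p, f] - (p - 1L) * dims$pool)
    }
  }
  contrib <- m_a1 * (x$a1 - r$a1)
  scores <- t(contrib)
  rownames(scores) <- model$bank$tf_ids

  if (abs(f_x - f_ref) < 1e-12 && all(contrib == 0)) {
    warn("dead target: zero delta everywhere; returning an all-zero profile")
  }
  structure(list(scores = scores, target = target, reference_spec = reference_spec,
                 f_x = f_x, f_ref = f_ref,
                 locus = list(chrom = if (inherits(window, "dna_window")) window$chrom else NA,
                              start = if (inherits(window, "dna_window")) window$start else NA)),
            class = "pwmnet_importance")
}

#' @export
print.pwmnet_importance <- function(x, ...) {
  cat(sprintf("<pwmnet_importance> %d TFs x %d positions, target %s, ref %s\n",
              nrow(x$scores), ncol(x$scores), format(x$target), x$reference_spec))
  cat(sprintf("  sum of contributions %.6f = f(x) - f(ref) = %.6f - %.6f\n",
              sum(x$scores), x$f_x, x$f_ref))
  invisible(x)
}

#' Assign the key TF of a locus from its importance profile
#'
#' Aggregates each TF's contributions over positions (sum of positive
#' scores by default, or positionwise max) and returns the TF with the
#' highest aggregate. Exact ties break lexicographically by `tf_id`. If no
#' TF has a positive aggregate, an `NA` sentinel row is returned with a
#' warning.
#'
#' @param profile A `pwmnet_importance` object.
#' @param method `"sum_positive"` (default) or `"max"`.
#' @return One-row tibble with `tf_id` and `score`.
#' @export
key_tf <- function(profile, method = c("sum_positive", "max")) {
  method <- match.arg(method)
  agg <- switch(method,
    sum_positive = rowSums(pmax(profile$scores, 0)),
    max = apply(profile$scores, 1, max))
  if (all(agg <= 0)) {
    warn("no TF with positive aggregate importance; returning NA sentinel")
    return(tibble(tf_id = NA_character_, score = NA_real_))
  }
  best <- agg[agg == max(agg)]
  winner <- sort(names(best))[1]
  if (length(best) > 1) {
    inform(sprintf("key-TF tie among {%s}; kept '%s' (lexicographic rule)",
                   paste(sort(names(best)), collapse = ", "), winner))
  }
  tibble(tf_id = winner, score = unname(agg[winner]))
}

#' Aggregate key TFs per accessibility category
#'
#' Restricts to loci whose predicted category equals the true category,
#' then tabulates, per category, the fraction of those loci explained by
#' each key TF. Loci with the `NA` none-sentinel stay in the denominator
#' but receive no row, so fractions per category sum to at most 1.
#'
#' @param assignments Tibble with one row per locus: `category`,
#'   `predicted_category`, `tf_id` (from [key_tf()]).
#' @return Tibble with `category`, `tf_id`, `n_loci`, `fraction`, sorted by
#'   decreasing fraction within category.
#' @export
aggregate_key_tfs <- function(assignments) {
  correct <- filter(assignments, .data$predicted_category == .data$category)
  missing_cats <- setdiff(sort(unique(assignments$category)), unique(correct$category))
  if (length(missing_cats) > 0) {
    warn(sprintf("no correctly predicted loci for category/ies %s; row(s) omitted",
                 paste(missing_cats, collapse = ", ")))
  }
  denom <- count(correct, .data$category, name = "n_total")
  correct %>%
    filter(!is.na(.data$tf_id)) %>%
    count(.data$category, .data$tf_id, name = "n_loci") %>%
    left_join(denom, by = "category") %>%
    mutate(fraction = .data$n_loci / .data$n_total) %>%
    select("category", "tf_id", "n_loci", "fraction") %>%
    arrange(.data$category, desc(.data$fraction))
}

#' In-silico saturation mutagenesis of one window
#'
#' For every position `p` and base `b`, computes
#' `delta[p, b] = f(window with position p set to b) - f(window)`,
#' i.e. the marginal change in the model prediction caused by that single
#' substitution (1500 extra forward passes for a 500-bp window, computed
#' with an incremental convolution update and a batched pass through the
#' learnable layers). The delta at the reference base is exactly 0.
#' All-zero (masked) rows are mutated against the zero row and flagged.
#'
#' For a cell-type target the prediction is the renormalized open
#' probability `p_t`; for a category target it is the sigmoid score `s_O`.
#'
#' @param model A `pwmnet_model`.
#' @param window A `dna_window` or base-code vector.
#' @param target A category in 1..7 or one of `"ipsc"`, `"lcl"`, `"cm"`.
#' @return A `pwmnet_mutagenesis` object with the 500 x 4 `delta` matrix;
#'   `tidy()` returns the long form (position, base, delta).
#' @export
saturation_mutagenesis <- function(model, window, target) {
  codes <- if (inherits(window, "dna_window")) window$codes else as.integer(window)
  bank <- model$bank
  dims <- model$dims
  len <- length(codes)
  stopifnot(len == dims$window_len)

  pred_fun <- mutagenesis_predictor(model, target)

  base_a1 <- pmax(strand_reduce(bank, conv1_scores_codes(bank, codes)), 0)
  base_u <- pool_features(base_a1, dims$pool)
  f0 <- pred_fun(matrix(as.vector(base_u), 1))

  muts <- list()
  for (p in seq_len(len)) {
    for (b in 1:4) {
      if (b == codes[p]) next
      muts[[length(muts) + 1L]] <- c(p, b)
    }
  }
  mut_mat <- do.call(rbind, muts)
  umat <- matrix(0, nrow(mut_mat), dims$p1 * dims$n_tf)
  for (i in seq_len(nrow(mut_mat))) {
    umat[i, ] <- mutated_features(bank, dims, codes, base_a1, base_u,
                                  mut_mat[i, 1], mut_mat[i, 2])
  }
  f_mut <- pred_fun(umat)

  delta <- matrix(0, len, 4, dimnames = list(NULL, DNA_BASES))
  delta[mut_mat] <- f_mut - f0
  structure(list(delta = delta, target = target, f_reference = f0,
                 masked = which(codes == 0L),
                 locus = list(chrom = if (inherits(window, "dna_window")) window$chrom else NA,
                              start = if (inherits(window, "dna_window")) window$start else NA)),
            class = "pwmnet_mutagenesis")
}

# scalar prediction used by mutagenesis, applied to a feature matrix
mutagenesis_predictor <- function(model, target) {
  if (model$config$output != "category") {
    if (!identical(target, model$config$output)) {
      abort(sprintf("binary model predicts '%s'; target must match", model$config$output))
    }
    return(function(feat) model_scores(model, feat)[, 1])
  }
  if (is.numeric(target)) {
    if (!target %in% 1:7) abort("category target must be in 1..7")
    function(feat) model_scores(model, feat)[, target]
  } else if (target %in% CELLTYPES) {
    cats <- CELLTYPE_CATEGORIES[[target]]
    function(feat) {
      s <- model_scores(model, feat)
      rowSums(s[, cats, drop = FALSE]) / rowSums(s)
    }
  } else {
    abort("target must be a category in 1..7 or one of 'ipsc', 'lcl', 'cm'")
  }
}

# pooled feature vector after a single-base substitution, updating only the
# convolution offsets and pool bins the mutation can reach
mutated_features <- function(bank, dims, codes, base_a1, base_u, p, b) {
  io <- max(1L, p - bank$wmax + 1L):min(dims$lout, p)
  codes_mut <- codes
  codes_mut[p] <- b
  s <- matrix(0, length(io), ncol(bank$lut[[1]]))
  for (w in seq_len(bank$wmax)) {
    s <- s + bank$lut[[w]][codes_mut[io + (w - 1L)] + 1L, , drop = FALSE]
  }
  a1_sub <- pmax(strand_reduce(bank, s), 0)

  bins <- unique((io - 1L) %/% dims$pool + 1L)
  bins <- bins[bins <= dims$p1]
  u <- base_u
  for (pb in bins) {
    rr <- ((pb - 1L) * dims$pool + 1L):(pb * dims$pool)
    block <- base_a1[rr, , drop = FALSE]
    common <- intersect(io, rr)
    block[match(common, rr), ] <- a1_sub[match(common, io), , drop = FALSE]
    u[pb, ] <- col_max(block)
  }
  as.vector(u)
}

#' @export
print.pwmnet_mutagenesis <- function(x, ...) {
  cat(sprintf("<pwmnet_mutagenesis> %d x 4 delta map, target %s, f(ref seq) = %.4f\n",
              nrow(x$delta), format(x$target), x$f_reference))
  cat(sprintf("  largest |delta| %.4g at position %d\n",
              max(abs(x$delta)), which.max(apply(abs(x$delta), 1, max))))
  invisible(x)
}
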