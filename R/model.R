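#' Configuration for a PWM-anchored accessibility network
#'
#' The architecture is a fixed four-layer skeleton: a frozen convolutional
#' layer whose filters are the log-transformed PWMs, ReLU, non-overlapping
#' max-pooling, a learnable convolutional layer, ReLU, global max-pooling, a
#' dense layer, ReLU, and an output layer of independent sigmoid units (one
#' per accessibility category, or a single unit for a binary cell-type
#' model). Only the sizes of the learnable layers are configurable.
#'
#' @param conv2_filters Number of learnable convolution filters (default 64).
#' @param conv2_width Width of the learnable convolution, in pooled
#'   positions (default 8).
#' @param pool_width Max-pool width/stride after the frozen layer (default 8).
#' @param dense_units Dense layer size (default 128).
#' @param output `"category"` for the 7-way head, or one of `"ipsc"`,
#'   `"lcl"`, `"cm"` for a binary single-cell-type model.
#' @param head `"sigmoid"` (default; independent per-unit sigmoids with
#'   per-unit cross-entropy) or `"softmax"`.
#' @param rho,epsilon,lr ADADELTA decay rate, conditioning constant and
#'   learning-rate multiplier (defaults 0.95, 1e-6, 1.0 — the original
#'   algorithm's settings).
#' @param epochs,batch_size Training schedule (defaults 15 and 64).
#' @param seed Integer seed from which all training randomness (weight
#'   initialization, shuffling) flows.
#' @return A `pwmnet_config` list.
#' @export
pwmnet_config <- function(conv2_filters = 64L, conv2_width = 8L, pool_width = 8L,
                          dense_units = 128L, output = "category",
                          head = c("sigmoid", "softmax"),
                          rho = 0.95, epsilon = 1e-6, lr = 1.0,
                          epochs = 15L, batch_size = 64L, seed = 1L) {
  head <- match.arg(head)
  if (!output %in% c("category", CELLTYPES)) {
    abort("output must be 'category' or one of 'ipsc', 'lcl', 'cm'")
  }
  structure(list(conv2_filters = as.integer(conv2_filters),
                 conv2_width = as.integer(conv2_width),
                 pool_width = as.integer(pool_width),
                 dense_units = as.integer(dense_units),
                 output = output, head = head,
                 rho = rho, epsilon = epsilon, lr = lr,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "pwmnet_config")
}

# network dimensions implied by a bank + config + window length
net_dims <- function(bank, config, window_len = 500L) {
  lout <- window_len - bank$wmax + 1L
  p1 <- lout %/% config$pool_width
  p2 <- p1 - config$conv2_width + 1L
  if (p2 < 1L) abort("conv2_width exceeds the pooled feature length")
  nout <- if (config$output == "category") 7L else 1L
  list(window_len = window_len, lout = lout, p1 = p1, p2 = p2,
       n_tf = bank$n_tf, k = config$conv2_filters, d = config$dense_units,
       w2 = config$conv2_width, pool = config$pool_width, nout = nout)
}

# patch index matrix: row j holds the feature-vector indices feeding conv2
# position j; column order is (tf-major, within-tf offset) matching W2 rows
patch_index <- function(dims) {
  idx <- matrix(0L, dims$p2, dims$w2 * dims$n_tf)
  for (t in seq_len(dims$n_tf)) {
    for (d in seq_len(dims$w2)) {
      idx[, (t - 1L) * dims$w2 + d] <- (t - 1L) * dims$p1 + seq_len(dims$p2) + d - 1L
    }
  }
  idx
}

# gather conv2 input patches for a batch of feature rows
# feat: B x (p1*n_tf); returns (B*p2) x (w2*n_tf); linear gather indices are
# cached per batch size since they only depend on (B, pidx)
gather_patches <- function(feat, pidx, dims, cache = NULL) {
  b <- nrow(feat)
  key <- as.character(b)
  lin <- if (!is.null(cache)) cache[[key]] else NULL
  if (is.null(lin)) {
    # element (r, c) of the patch matrix is feat[s(r), pidx[j(r), c]] with
    # s(r) = ceiling(r / p2), j(r) = (r - 1) %% p2 + 1
    samp <- rep(rep.int(seq_len(b), rep.int(dims$p2, b)), times = ncol(pidx))
    colv <- as.vector(pidx[rep.int(seq_len(dims$p2), b), ])
    lin <- (colv - 1L) * b + samp
    if (!is.null(cache)) cache[[key]] <- lin
  }
  matrix(feat[lin], nrow = b * dims$p2)
}

# trainable-layer forward pass; returns output scores and (optionally) the
# intermediates needed for backprop
net_forward <- function(wts, feat, pidx, dims, head = "sigmoid", keep = FALSE,
                        cache = NULL) {
  b <- nrow(feat)
  patches <- gather_patches(feat, pidx, dims, cache)
  z2 <- sweep(patches %*% wts$W2, 2, wts$b2, "+")
  h2 <- pmax(z2, 0)
  g <- matrix(0, b, dims$k)
  amax <- matrix(0L, b, dims$k)
  for (k in seq_len(dims$k)) {
    tm <- t(matrix(h2[, k], dims$p2, b))
    a <- max.col(tm, ties.method = "first")
    amax[, k] <- a
    g[, k] <- tm[cbind(seq_len(b), a)]
  }
  z3 <- sweep(g %*% wts$W3, 2, wts$b3, "+")
  h3 <- pmax(z3, 0)
  z4 <- sweep(h3 %*% wts$W4, 2, wts$b4, "+")
  s <- if (head == "softmax") {
    e <- exp(z4 - apply(z4, 1, max))
    e / rowSums(e)
  } else {
    plogis(z4)
  }
  if (!keep) return(list(s = s))
  list(s = s, patches = patches, z2 = z2, h2 = h2, g = g, amax = amax,
       z3 = z3, h3 = h3, z4 = z4)
}

# gradients of the mean loss w.r.t. the learnable tensors
net_backward <- function(wts, fw, y, dims) {
  b <- nrow(y)
  dz4 <- (fw$s - y) / b                 # BCE+sigmoid and CE+softmax share this
  gW4 <- crossprod(fw$h3, dz4)
  gb4 <- colSums(dz4)
  dz3 <- (dz4 %*% t(wts$W4)) * (fw$z3 > 0)
  gW3 <- crossprod(fw$g, dz3)
  gb3 <- colSums(dz3)
  dg <- dz3 %*% t(wts$W3)               # B x K
  dz2 <- matrix(0, b * dims$p2, dims$k)
  base <- (seq_len(b) - 1L) * dims$p2
  for (k in seq_len(dims$k)) {
    rows <- base + fw$amax[, k]
    live <- fw$z2[cbind(rows, k)] > 0
    dz2[cbind(rows[live], k)] <- dg[live, k]
  }
  gW2 <- crossprod(fw$patches, dz2)
  gb2 <- colSums(dz2)
  list(W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3, W4 = gW4, b4 = gb4)
}

adadelta_step <- function(wts, grads, state, rho, eps, lr) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$Eg2[[nm]] <- rho * state$Eg2[[nm]] + (1 - rho) * g * g
    dx <- -sqrt(state$Ex2[[nm]] + eps) / sqrt(state$Eg2[[nm]] + eps) * g
    state$Ex2[[nm]] <- rho * state$Ex2[[nm]] + (1 - rho) * dx * dx
    wts[[nm]] <- wts[[nm]] + lr * dx
  }
  list(wts = wts, state = state)
}

batch_loss <- function(s, y, head) {
  eps <- 1e-12
  if (head == "softmax") {
    -mean(rowSums(y * log(s + eps)))
  } else {
    -mean(rowSums(y * log(s + eps) + (1 - y) * log(1 - s + eps)))
  }
}

target_matrix <- function(data, config) {
  if (config$output == "category") {
    y <- matrix(0, nrow(data), 7)
    y[cbind(seq_len(nrow(data)), data$category)] <- 1
  } else {
    y <- matrix(as.numeric(data[[config$output]]), ncol = 1)
  }
  y
}

#' Train a PWM-anchored accessibility network
#'
#' Minimizes per-unit sigmoid cross-entropy of the 7-way category target
#' (or of a single cell type's open flag for binary models) with ADADELTA.
#' The first convolutional layer is the frozen filter bank: it is never
#' updated, and its checksum is recorded so frozen-layer integrity can be
#' verified after training.
#'
#' @param data Labeled locus tibble with a `window` list-column plus
#'   `category` (and `ipsc`/`lcl`/`cm` flags for binary models).
#' @param bank A [build_filter_bank()] object.
#' @param config A [pwmnet_config()].
#' @param features Optional precomputed feature matrix from
#'   [pwmnet_features()] (rows must align with `data`), so several models
#'   can share one featurization pass.
#' @return A `pwmnet_model` with weights, per-epoch loss history, the
#'   training-set category prior, and the frozen-layer checksum.
#' @export
pwmnet_train <- function(data, bank, config = pwmnet_config(), features = NULL) {
  if (nrow(data) == 0) abort("empty training set")
  if (config$output == "category" && length(unique(data$category)) < 2) {
    abort("training set must contain at least 2 categories")
  }
  window_len <- length(data$window[[1]]$codes)
  dims <- net_dims(bank, config, window_len)
  pidx <- patch_index(dims)
  if (is.null(features)) features <- pwmnet_features(data, bank, config)
  stopifnot(nrow(features) == nrow(data), ncol(features) == dims$p1 * dims$n_tf)
  y <- target_matrix(data, config)
  checksum <- filter_bank_checksum(bank)
  gcache <- new.env(parent = emptyenv())

  wts <- withr::with_seed(config$seed, list(
    W2 = matrix(rnorm(dims$w2 * dims$n_tf * dims$k, sd = sqrt(2 / (dims$w2 * dims$n_tf))),
                dims$w2 * dims$n_tf, dims$k),
    b2 = numeric(dims$k),
    W3 = matrix(rnorm(dims$k * dims$d, sd = sqrt(2 / dims$k)), dims$k, dims$d),
    b3 = numeric(dims$d),
    W4 = matrix(rnorm(dims$d * dims$nout, sd = sqrt(2 / dims$d)), dims$d, dims$nout),
    b4 = numeric(dims$nout)
  ))
  state <- list(Eg2 = lapply(wts, function(w) w * 0),
                Ex2 = lapply(wts, function(w) w * 0))

  n <- nrow(features)
  history <- numeric(config$epochs)
  order_seeds <- withr::with_seed(config$seed, sample.int(.Machine$integer.max %/% 2L,
                                                          config$epochs))
  for (ep in seq_len(config$epochs)) {
    ord <- withr::with_seed(order_seeds[ep], sample.int(n))
    starts <- seq(1L, n, by = config$batch_size)
    ep_loss <- 0
    for (st in starts) {
      sel <- ord[st:min(st + config$batch_size - 1L, n)]
      fw <- net_forward(wts, features[sel, , drop = FALSE], pidx, dims,
                        head = config$head, keep = TRUE, cache = gcache)
      loss <- batch_loss(fw$s, y[sel, , drop = FALSE], config$head)
      if (!is.finite(loss)) {
        abort(sprintf(paste("NaN/Inf loss at epoch %d; try a smaller lr",
                            "(current %.3g) or larger epsilon (%.3g)"),
                      ep, config$lr, config$epsilon))
      }
      ep_loss <- ep_loss + loss * length(sel)
      grads <- net_backward(wts, fw, y[sel, , drop = FALSE], dims)
      upd <- adadelta_step(wts, grads, state, config$rho, config$epsilon, config$lr)
      wts <- upd$wts
      state <- upd$state
    }
    history[ep] <- ep_loss / n
  }

  prior <- if (config$output == "category") {
    tabulate(data$category, 7) / nrow(data)
  } else {
    mean(y)
  }
  structure(list(bank = bank, config = config, dims = dims, pidx = pidx,
                 gcache = gcache, weights = wts,
                 history = tibble(epoch = seq_len(config$epochs), loss = history),
                 checksum = checksum, prior = prior),
            class = "pwmnet_model")
}

#' @export
print.pwmnet_model <- function(x, ...) {
  cat(sprintf("<pwmnet_model> %s head (%s), %d frozen TF filters, conv2 %dx%d, dense %d\n",
              x$config$output, x$config$head, x$dims$n_tf, x$dims$w2, x$dims$k, x$dims$d))
  cat(sprintf("  trained %d epochs, final loss %.4f\n",
              nrow(x$history), tail(x$history$loss, 1)))
  invisible(x)
}

#' Pooled frozen-layer features for a set of windows
#'
#' Runs the frozen PWM convolution, ReLU and first max-pool once per window
#' and returns the flattened feature matrix consumed by the learnable
#' layers. Useful to share one featurization pass across several models.
#'
#' @param data Tibble with a `window` list-column, or a list of windows.
#' @param bank A [build_filter_bank()] object.
#' @param config A [pwmnet_config()] (only `pool_width` is used).
#' @return Numeric matrix, one row per window.
#' @export
pwmnet_features <- function(data, bank, config = pwmnet_config()) {
  windows <- if (is.data.frame(data)) data$window else data
  featurize_windows(bank, windows, config$pool_width)
}

# scores for a feature matrix, chunked to bound memory
model_scores <- function(model, features, chunk = 2048L) {
  n <- nrow(features)
  out <- matrix(0, n, model$dims$nout)
  for (st in seq(1L, n, by = chunk)) {
    sel <- st:min(st + chunk - 1L, n)
    out[sel, ] <- net_forward(model$weights, features[sel, , drop = FALSE],
                              model$pidx, model$dims, head = model$config$head,
                              cache = model$gcache)$s
  }
  out
}

scores_to_tibble <- function(model, s) {
  if (model$config$output == "category") {
    colnames(s) <- paste0("s_", 1:7)
    out <- as_tibble(s)
    tot <- rowSums(s)
    for (ct in CELLTYPES) {
      out[[paste0("p_", ct)]] <- rowSums(s[, CELLTYPE_CATEGORIES[[ct]], drop = FALSE]) / tot
    }
    out$predicted_category <- max.col(s, ties.method = "first")
  } else {
    out <- tibble(!!paste0("p_", model$config$output) := s[, 1])
  }
  out
}

#' Predict accessibility for new windows
#'
#' For the 7-way model, returns the per-category sigmoid scores
#' `s_1..s_7`, the renormalized per-cell-type open probabilities
#' `p_ipsc`, `p_lcl`, `p_cm` (sum of category scores containing the cell
#' type, divided by the sum of all scores), and the argmax
#' `predicted_category`. Binary models return a single `p_<celltype>`.
#'
#' @param object A `pwmnet_model`.
#' @param newdata Tibble with a `window` list-column, a list of windows, or
#'   a precomputed feature matrix.
#' @param ... Unused.
#' @return A tibble with one row per window.
#' @export
predict.pwmnet_model <- function(object, newdata, ...) {
  features <- if (is.matrix(newdata)) newdata else
    pwmnet_features(newdata, object$bank, object$config)
  scores_to_tibble(object, model_scores(object, features))
}

# Mann-Whitney / rank-sum AUC
auc_ranksum <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-cell-type AUC evaluation, including cross-cell-type application
#'
#' Computes the rank-sum (Mann-Whitney) AUC of each predicted open
#' probability against each cell type's binary open flag. The diagonal
#' (score and label from the same cell type) is the model's own accuracy;
#' off-diagonal entries measure how well the score for one cell type
#' predicts open chromatin in another. Cell types with a single class in
#' the test set yield `NA` with a message.
#'
#' @param model A `pwmnet_model`.
#' @param data Labeled locus tibble with `window` and the three open flags.
#' @param features Optional precomputed feature matrix.
#' @return Tibble with `score_celltype`, `label_celltype`, `auc`,
#'   `n_open`, `n_closed`.
#' @export
evaluate_auc <- function(model, data, features = NULL) {
  if (is.null(features)) features <- pwmnet_features(data, model$bank, model$config)
  pred <- scores_to_tibble(model, model_scores(model, features))
  score_cols <- grep("^p_", names(pred), value = TRUE)
  out <- tidyr::expand_grid(score_celltype = sub("^p_", "", score_cols),
                            label_celltype = CELLTYPES)
  out <- mutate(out,
    n_open = map_int(.data$label_celltype, ~ sum(data[[.x]])),
    n_closed = map_int(.data$label_celltype, ~ sum(!data[[.x]])),
    auc = purrr::map2_dbl(.data$score_celltype, .data$label_celltype, function(sc, lc) {
      auc_ranksum(pred[[paste0("p_", sc)]], data[[lc]])
    })
  )
  if (any(is.na(out$auc))) {
    inform("AUC undefined (single class) for some cell type(s); reported as NA")
  }
  select(out, "score_celltype", "label_celltype", "auc", "n_open", "n_closed")
}
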