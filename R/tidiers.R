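#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a trained model's training history
#'
#' @param x A `pwmnet_model`.
#' @param ... Unused.
#' @return Tibble with one row per epoch (`epoch`, `loss`).
#' @export
tidy.pwmnet_model <- function(x, ...) x$history

#' One-row summary of a trained model
#'
#' @param x A `pwmnet_model`.
#' @param ... Unused.
#' @return Tibble with output head, layer sizes, parameter count, epochs,
#'   final loss and the frozen-layer checksum.
#' @export
glance.pwmnet_model <- function(x, ...) {
  tibble(output = x$config$output, head = x$config$head,
         n_tf = x$dims$n_tf, conv2_filters = x$dims$k,
         dense_units = x$dims$d,
         n_parameters = sum(lengths(x$weights)),
         epochs = nrow(x$history),
         final_loss = tail(x$history$loss, 1),
         frozen_checksum = x$checksum)
}

#' Tidy an importance profile into long form
#'
#' @param x A `pwmnet_importance`.
#' @param ... Unused.
#' @return Tibble with `tf_id`, `position`, `score`.
#' @export
tidy.pwmnet_importance <- function(x, ...) {
  tibble(tf_id = rep(rownames(x$scores), times = ncol(x$scores)),
         position = rep(seq_len(ncol(x$scores)), each = nrow(x$scores)),
         score = as.vector(x$scores))
}

#' Summation-to-delta summary of an importance profile
#'
#' @param x A `pwmnet_importance`.
#' @param ... Unused.
#' @return One-row tibble with the contribution sum, `f_x`, `f_ref` and the
#'   completeness residual.
#' @export
glance.pwmnet_importance <- function(x, ...) {
  tibble(target = format(x$target), reference = x$reference_spec,
         sum_contrib = sum(x$scores), f_x = x$f_x, f_ref = x$f_ref,
         residual = sum(x$scores) - (x$f_x - x$f_ref))
}

#' Tidy a mutagenesis map into long form
#'
#' @param x A `pwmnet_mutagenesis`.
#' @param ... Unused.
#' @return Tibble with `position`, `base`, `delta`.
#' @export
tidy.pwmnet_mutagenesis <- function(x, ...) {
  as_tibble(x$delta) %>%
    mutate(position = dplyr::row_number()) %>%
    tidyr::pivot_longer(-"position", names_to = "base", values_to = "delta")
}

#' Tidy an imbalance comparison into its matched scatter table
#'
#' @param x A `pwmnet_imbalance_cor`.
#' @param ... Unused.
#' @return Tibble of matched SNPs with `delta_median`, `imbalance`,
#'   `observed_effect`.
#' @export
tidy.pwmnet_imbalance_cor <- function(x, ...) as_tibble(x$data)

#' One-row summary of an imbalance comparison
#'
#' @param x A `pwmnet_imbalance_cor`.
#' @param ... Unused.
#' @return Tibble with `r`, `p_value`, `n`, `n_dropped`, `method`,
#'   `transform`.
#' @export
glance.pwmnet_imbalance_cor <- function(x, ...) {
  tibble(r = x$r, p_value = x$p_value, n = x$n, n_dropped = x$n_dropped,
         method = x$method, transform = x$transform)
}
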