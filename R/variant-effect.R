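#' Filter candidate caQTL loci on posterior probabilities
#'
#' Keeps records with `pi_l > threshold` AND `pi_s > threshold` (strict
#' inequalities, following the printed filter), where `pi_l` is the
#' posterior probability that the locus is a caQTL and `pi_s` the posterior
#' probability that the SNP is the causal variant given the locus is a
#' caQTL. The number of dropped records is reported.
#'
#' @param candidates Tibble with `pi_l` and `pi_s` columns (e.g. read from
#'   a TSV with chrom, pos, ref, alt, pi_l, pi_s).
#' @param threshold Posterior threshold (default 0.99).
#' @return The filtered tibble (possibly empty, with a warning).
#' @export
select_causal <- function(candidates, threshold = 0.99) {
  if (!all(c("pi_l", "pi_s") %in% names(candidates))) {
    abort("candidates must have pi_l and pi_s columns")
  }
  if (any(candidates$pi_l < 0 | candidates$pi_l > 1 |
          candidates$pi_s < 0 | candidates$pi_s > 1, na.rm = TRUE)) {
    abort("pi_l and pi_s must lie in [0, 1]")
  }
  kept <- filter(candidates, .data$pi_l > threshold & .data$pi_s > threshold)
  inform(sprintf("select_causal: kept %d of %d record(s) at threshold %g",
                 nrow(kept), nrow(candidates), threshold))
  if (nrow(kept) == 0) warn("no candidate passed the posterior filter")
  kept
}

#' Predicted allelic effect of a caQTL SNP from haplotype predictions
#'
#' Scores every haplotype window with the model, partitions haplotypes by
#' the allele they carry at the focal SNP, and reports, per cell type, the
#' difference in the median predicted chromatin activity between the
#' alternate- and reference-allele groups
#' (`delta_median = median(alt) - median(ref)`). Activity is measured on
#' the log-odds scale of the per-cell-type open probability by default
#' (the standard unbounded effect-size scale; probability differences
#' compress near 0 and 1), or on the probability scale with
#' `scale = "response"`. Exactly antisymmetric under swapping the allele
#' labels.
#'
#' @param model A `pwmnet_model`.
#' @param haplotypes A `haplotype_set` from [build_haplotypes()].
#' @param scale `"logit"` (default) or `"response"`.
#' @return Tibble with `celltype`, `delta_median`, `n_ref`, `n_alt` (one
#'   row per cell type scored by the model).
#' @export
haplotype_effect <- function(model, haplotypes, scale = c("logit", "response")) {
  scale <- match.arg(scale)
  n_ref <- sum(haplotypes$allele == "ref")
  n_alt <- sum(haplotypes$allele == "alt")
  if (n_ref == 0 || n_alt == 0) {
    abort("focal SNP is monomorphic across haplotypes; both alleles required")
  }
  pred <- predict(model, haplotypes)
  p_cols <- grep("^p_", names(pred), value = TRUE)
  trans <- if (scale == "logit") {
    function(p) qlogis(pmin(pmax(p, 1e-12), 1 - 1e-12))
  } else {
    identity
  }
  map(p_cols, function(col) {
    act <- trans(pred[[col]])
    tibble(celltype = sub("^p_", "", col),
           delta_median = median(act[haplotypes$allele == "alt"]) -
                          median(act[haplotypes$allele == "ref"]),
           n_ref = n_ref, n_alt = n_alt)
  }) %>% bind_rows()
}

#' Correlate predicted allelic effects with observed allelic imbalance
#'
#' Matches predicted per-SNP effects to observed allelic-imbalance records,
#' transforms the observed alternate-allele fraction (default: centered at
#' 0.5), and reports the correlation between `delta_median` and the
#' transformed imbalance, with its p-value and the matched scatter table.
#'
#' @param effects Tibble with `snp_id` and `delta_median` (one cell type).
#' @param observed Tibble with `snp_id` and either an `imbalance` fraction
#'   in (0,1) or `ref_count`/`alt_count` columns.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param transform `"centered"` (fraction - 0.5; default), `"raw"`, or
#'   `"logit"`.
#' @return A `pwmnet_imbalance_cor` object; `glance()` gives the one-row
#'   summary (r, p, n), `tidy()` the matched scatter table.
#' @export
compare_to_imbalance <- function(effects, observed,
                                 method = c("pearson", "spearman"),
                                 transform = c("centered", "raw", "logit")) {
  method <- match.arg(method)
  transform <- match.arg(transform)
  if (!"imbalance" %in% names(observed)) {
    if (!all(c("ref_count", "alt_count") %in% names(observed))) {
      abort("observed needs an 'imbalance' fraction or ref_count/alt_count columns")
    }
    observed <- mutate(observed,
      imbalance = .data$alt_count / (.data$ref_count + .data$alt_count))
  }
  if (any(observed$imbalance <= 0 | observed$imbalance >= 1)) {
    abort("observed imbalance fractions must lie strictly in (0, 1)")
  }
  matched <- inner_join(effects, observed, by = "snp_id")
  n_dropped <- nrow(effects) - nrow(matched)
  if (n_dropped > 0) {
    inform(sprintf("%d effect record(s) had no matching imbalance record", n_dropped))
  }
  if (nrow(matched) < 3) abort("need at least 3 matched SNPs to correlate")
  matched$observed_effect <- switch(transform,
    centered = matched$imbalance - 0.5,
    raw = matched$imbalance,
    logit = qlogis(matched$imbalance))
  if (stats::sd(matched$delta_median) == 0 || stats::sd(matched$observed_effect) == 0) {
    warn("zero variance in predictions or observations; correlation undefined")
    ct <- list(estimate = NA_real_, p.value = NA_real_)
  } else {
    ct <- cor.test(matched$delta_median, matched$observed_effect, method = method,
                   exact = FALSE)
  }
  structure(list(r = unname(ct$estimate), p_value = ct$p.value,
                 n = nrow(matched), n_dropped = n_dropped,
                 method = method, transform = transform, data = matched),
            class = "pwmnet_imbalance_cor")
}

#' @export
print.pwmnet_imbalance_cor <- function(x, ...) {
  cat(sprintf("<pwmnet_imbalance_cor> %s r = %.3f (p = %.3g) over %d matched SNPs\n",
              x$method, x$r, x$p_value, x$n))
  invisible(x)
}
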