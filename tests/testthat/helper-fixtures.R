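# small shared fixtures, built once per test run

fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- force(expr)
  fixture_env[[name]]
}

tiny_config <- function(...) {
  defaults <- list(loci_per_category = 30L, n_caqtl = 20L, n_decoys = 20L,
                   n_samples = 10L, seed = 11L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

tiny_pwms <- function() memo("tiny_pwms", simulate_pwms(tiny_config()))

tiny_bank <- function() memo("tiny_bank", build_filter_bank(tiny_pwms()))

tiny_bank_fwd <- function() {
  memo("tiny_bank_fwd", build_filter_bank(tiny_pwms(), strand_policy = "forward_only"))
}

# small trained 7-way model on a planted dataset (shared across test files)
tiny_model <- function() {
  memo("tiny_model", {
    cfg <- tiny_config()
    d <- simulate_dataset(cfg, tiny_pwms())
    pwmnet_train(d, tiny_bank(),
                 pwmnet_config(conv2_filters = 16L, dense_units = 32L,
                               epochs = 4L, seed = 5L))
  })
}

random_codes <- function(n = 500L, allow_n = FALSE) {
  pool <- if (allow_n) 0:4 else 1:4
  sample(pool, n, replace = TRUE)
}

# write a tiny single-chromosome FASTA and return a DNAStringSet
write_tmp_fasta <- function(seqs) {
  path <- withr::local_tempfile(fileext = ".fa", .local_envir = parent.frame())
  writeLines(unlist(lapply(names(seqs), function(n) c(paste0(">", n), seqs[[n]]))),
             path)
  path
}
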