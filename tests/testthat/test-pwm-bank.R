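test_that("JASPAR counts normalize exactly and MEME files parse in order", {
  jaspar <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c(">M1 toyTF",
               "4 0",
               "0 4",
               "0 0",
               "0 0"), jaspar)
  p <- read_pwms(jaspar, dialect = "jaspar")
  expect_length(p, 1)
  expect_equal(p[[1]]$matrix,
               matrix(c(1, 0, 0, 1, 0, 0, 0, 0), 2, 4,
                      dimnames = list(NULL, c("A", "C", "G", "T"))))

  meme <- withr::local_tempfile(fileext = ".meme")
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "MOTIF M1 first",
               "letter-probability matrix: alength= 4 w= 2 nsites= 10",
               "0.7 0.1 0.1 0.1", "0.1 0.7 0.1 0.1",
               "MOTIF M2 second",
               "letter-probability matrix: alength= 4 w= 3 nsites= 10",
               "0.25 0.25 0.25 0.25", "0.1 0.1 0.1 0.7", "0.4 0.2 0.2 0.2",
               "MOTIF M3 third",
               "letter-probability matrix: alength= 4 w= 2 nsites= 10",
               "0.9 0.05 0.03 0.02", "0.02 0.03 0.05 0.9"), meme)
  p <- read_pwms(meme, dialect = "meme")
  expect_equal(purrr::map_chr(p, "tf_id"), c("M1", "M2", "M3"))
  expect_equal(purrr::map_int(p, ~ nrow(.x$matrix)), c(2L, 3L, 2L))
  expect_true(all(abs(purrr::map_dbl(p, ~ max(abs(rowSums(.x$matrix) - 1)))) < 1e-6))
})

test_that("TRANSFAC counts gain the configured pseudocount", {
  tf <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("ID TOY1", "NA toyTF",
               "01  3 1 0 0 A",
               "02  0 0 4 0 G",
               "03  1 1 1 1 N",
               "04  4 0 0 0 A",
               "//"), tf)
  p <- read_pwms(tf, dialect = "transfac", pseudocount = 1)
  expect_equal(p[[1]]$matrix[1, ], c(A = 4 / 8, C = 2 / 8, G = 1 / 8, T = 1 / 8))
  expect_equal(unname(p[[1]]$matrix[3, ]), rep(0.25, 4))
})

test_that("malformed and zero-sum matrix rows are rejected with context", {
  bad <- withr::local_tempfile(fileext = ".meme")
  writeLines(c("MOTIF M1",
               "letter-probability matrix: alength= 4 w= 2",
               "0.7 0.1 0.1", "0.1 0.7 0.1 0.1"), bad)
  expect_error(read_pwms(bad, dialect = "meme"), "numeric fields")
  expect_error(new_pwm(matrix(0, 4, 4), "Z"), "zero-sum")
  expect_error(new_pwm(matrix(-1, 4, 4), "Z"), "non-negative")
})

test_that("log transform evaluates the log2-odds formula and keeps signs stable", {
  uni <- new_pwm(matrix(0.25, 6, 4), "U")
  expect_equal(log_transform(uni), matrix(0, 6, 4, dimnames = list(NULL, c("A", "C", "G", "T"))))

  sharp <- new_pwm(matrix(c(1, 0, 0, 0), 4, 4, byrow = TRUE), "S")
  w <- log_transform(sharp, pseudocount = 1e-3)
  expect_equal(unname(w[1, "A"]), log2(1.001 / 0.251))
  expect_equal(unname(w[1, "C"]), log2(0.001 / 0.251))
  expect_true(all(is.finite(w)))

  # doubling the pseudocount never flips signs for entries away from background
  p <- new_pwm(matrix(c(0.7, 0.1, 0.1, 0.1), 5, 4, byrow = TRUE), "P")
  s1 <- sign(log_transform(p, pseudocount = 1e-3))
  s2 <- sign(log_transform(p, pseudocount = 2e-3))
  expect_equal(s1, s2)

  expect_error(log_transform(uni, background = c(0.5, 0.5, 0, 0)), "positive")
  expect_error(log_transform(uni, pseudocount = 0), "pseudocount")
})

test_that("filter bank pads to a common width and keeps a total tf index", {
  pwms <- list(new_pwm(matrix(0.25, 8, 4), "A8"),
               new_pwm(matrix(c(0.9, 0.04, 0.03, 0.03), 12, 4, byrow = TRUE), "B12"))
  bank <- suppressWarnings(build_filter_bank(pwms))
  expect_equal(bank$wmax, 12L)
  expect_setequal(bank$tf_ids, c("A8", "B12"))
  # padding neutrality: padded positions contribute exactly 0
  codes <- withr::with_seed(1, random_codes(40))
  pre <- conv1_preact(build_filter_bank(pwms, "forward_only"), codes)
  scan8 <- pwm_scan(one_hot(codes), log_transform(pwms[[1]]))
  expect_equal(pre[, "A8"], scan8[seq_len(nrow(pre))], tolerance = 1e-12)

  expect_error(build_filter_bank(list()), "empty")

  # duplicate ids are disambiguated
  dup <- list(new_pwm(matrix(0.25, 6, 4), "X", source = "TRANSFAC"),
              new_pwm(matrix(0.25, 6, 4), "X", source = "HT-SELEX"))
  b2 <- build_filter_bank(dup)
  expect_equal(anyDuplicated(b2$tf_ids), 0L)
})

test_that("first-layer pre-activations equal the sliding-window oracle", {
  bank <- tiny_bank_fwd()
  withr::with_seed(7, {
    for (i in 1:10) {
      codes <- random_codes(500, allow_n = (i %% 3 == 0))
      pre <- conv1_preact(bank, codes)
      f <- sample(bank$n_tf, 1)
      scan <- pwm_scan(one_hot(codes), bank$forward[[f]])
      expect_equal(pre[, f], scan[seq_len(nrow(pre))], tolerance = 1e-6)
    }
  })
})

test_that("consensus maximizes the scan and all-N windows score zero", {
  pwm <- tiny_pwms()[[1]]
  w <- log_transform(pwm)
  consensus <- one_hot(apply(pwm$matrix, 1, which.max))
  expect_equal(which.max(pwm_scan(consensus, w)), 1L)
  allN <- matrix(0, 30, 4)
  expect_equal(pwm_scan(allN, w), rep(0, 30 - nrow(w) + 1))
  expect_error(pwm_scan(one_hot(1:3), w), "shorter")
})

test_that("rc_max scoring is invariant to reverse complementing the window", {
  # equal-width filters, so every match position is scanned on both strands
  cfg <- tiny_config(motif_width_range = c(10L, 10L))
  bank <- build_filter_bank(simulate_pwms(cfg))
  withr::with_seed(3, {
    for (i in 1:5) {
      codes <- random_codes(80)
      a <- conv1_preact(bank, codes)
      b <- conv1_preact(bank, revcomp_codes(codes))
      # per-TF maxima over positions are strand-symmetric
      expect_equal(apply(a, 2, max), apply(b, 2, max), tolerance = 1e-9)
    }
  })
})

test_that("a palindromic PWM scores both strands identically everywhere", {
  # ACGT-palindrome: reverse complement of the consensus equals itself
  m <- matrix(0.04, 4, 4)
  m[cbind(1:4, c(1, 2, 3, 4))] <- 0.88   # consensus ACGT
  pal <- new_pwm(m, "PAL")
  bank <- build_filter_bank(list(pal), strand_policy = "rc_max")
  # the reverse-complement filter of a palindrome is the forward filter, so
  # forward and RC scores agree at every position
  expect_equal(bank$revcomp[["PAL"]], bank$forward[["PAL"]], tolerance = 1e-12)
  codes <- withr::with_seed(9, random_codes(60))
  pre_rc <- conv1_preact(bank, codes)
  pre_f <- conv1_preact(build_filter_bank(list(pal), "forward_only"), codes)
  expect_equal(pre_rc, pre_f, tolerance = 1e-12)
})
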