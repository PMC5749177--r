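test_that("DeepLIFT contributions satisfy summation-to-delta", {
  m <- tiny_model()
  withr::with_seed(19, {
    for (i in 1:6) {
      codes <- random_codes(500)
      target <- if (i %% 2 == 0) sample(1:7, 1) else sample(c("ipsc", "lcl", "cm"), 1)
      ref <- c("background", "zeros", "shuffled")[(i %% 3) + 1]
      pr <- deeplift_scores(m, codes, target, reference_spec = ref)
      delta <- pr$f_x - pr$f_ref
      expect_lt(abs(sum(pr$scores) - delta), 1e-4 * max(abs(delta), 1e-3))
    }
  })
})

test_that("a window identical to its reference has an all-zero profile", {
  m <- tiny_model()
  # the all-ambiguous window one-hot-encodes to the zero matrix = zeros reference
  blank <- rep(0L, 500)
  expect_warning(pr <- deeplift_scores(m, blank, target = 7, reference_spec = "zeros"),
                 "dead target")
  expect_true(all(pr$scores == 0))
  expect_equal(pr$f_x, pr$f_ref)
})

test_that("key TF assignment takes the argmax with a lexicographic tie rule", {
  mkprofile <- function(scores) {
    structure(list(scores = scores, target = 4, reference_spec = "background",
                   f_x = 1, f_ref = 0), class = "pwmnet_importance")
  }
  s <- rbind(TFA = c(1, 2, -1), TFB = c(0.5, 0.1, 0.2), TFC = c(-5, -5, -5))
  expect_equal(key_tf(mkprofile(s))$tf_id, "TFA")
  # brute-force oracle: sum of positive entries per row
  agg <- apply(pmax(s, 0), 1, sum)
  expect_equal(key_tf(mkprofile(s))$score, max(agg))

  tie <- rbind(TFB = c(1, 1), TFA = c(2, 0))   # equal aggregates, order scrambled
  expect_message(k <- key_tf(mkprofile(tie)), "tie")
  expect_equal(k$tf_id, "TFA")

  allneg <- rbind(TFA = c(-1, -2), TFB = c(-3, -1))
  expect_warning(k2 <- key_tf(mkprofile(allneg)), "sentinel")
  expect_true(is.na(k2$tf_id))

  # max-over-positions aggregation variant
  expect_equal(key_tf(mkprofile(s), method = "max")$score, 2)
})

test_that("key-TF aggregation counts only correctly predicted loci", {
  asg <- tibble::tibble(
    locus_id = sprintf("l%02d", 1:20),
    category = rep(c(4L, 2L), each = 10),
    predicted_category = c(rep(4L, 8), 2L, 2L, rep(2L, 8), 4L, 4L),
    tf_id = c(rep("POU", 6), "GATA", NA, "POU", "POU",
              rep("NFKB", 7), "IRF", "NFKB", "NFKB"))
  tab <- aggregate_key_tfs(asg)
  # category 4: 8 correct, 6 POU + 1 GATA + 1 NA -> fractions 6/8, 1/8
  expect_equal(tab$fraction[tab$category == 4 & tab$tf_id == "POU"], 6 / 8)
  expect_equal(tab$fraction[tab$category == 4 & tab$tf_id == "GATA"], 1 / 8)
  expect_true(all(tapply(tab$fraction, tab$category, sum) <= 1))
  # a category with zero correct predictions is omitted with a warning
  asg2 <- dplyr::mutate(asg, predicted_category = ifelse(category == 2, 4L,
                                                         predicted_category))
  expect_warning(tab2 <- aggregate_key_tfs(asg2), "omitted")
  expect_false(2 %in% tab2$category)
})

test_that("mutagenesis maps are zero at the reference base and match
           single-mutation forward passes", {
  m <- tiny_model()
  codes <- withr::with_seed(23, random_codes(500))
  mm <- saturation_mutagenesis(m, codes, target = "ipsc")
  # identity mutations are exactly zero
  expect_equal(mm$delta[cbind(seq_len(500), codes)], rep(0, 500))

  # direct forward-pass oracle on a sample of entries
  base_p <- predict(m, list(structure(list(codes = codes), class = "dna_window")))$p_ipsc
  withr::with_seed(24, picks <- cbind(sample(500, 30), sample(4, 30, TRUE)))
  for (r in seq_len(nrow(picks))) {
    p <- picks[r, 1]; b <- picks[r, 2]
    mut <- codes; mut[p] <- b
    direct <- predict(m, list(structure(list(codes = mut), class = "dna_window")))$p_ipsc
    expect_equal(unname(mm$delta[p, b]), direct - base_p, tolerance = 1e-10)
  }

  # the allelic delta of a SNP is the map entry at the alternate base
  p <- picks[1, 1]
  alt <- setdiff(1:4, codes[p])[1]
  mutw <- codes; mutw[p] <- alt
  alt_p <- predict(m, list(structure(list(codes = mutw), class = "dna_window")))$p_ipsc
  expect_equal(unname(mm$delta[p, alt]), alt_p - base_p, tolerance = 1e-10)
})

test_that("mutagenesis against masked rows is computed and flagged", {
  m <- tiny_model()
  codes <- withr::with_seed(25, random_codes(500))
  codes[100] <- 0L
  mm <- saturation_mutagenesis(m, codes, target = 3)
  expect_equal(mm$masked, 100L)
  expect_equal(sum(mm$delta[100, ] != 0), 4L)  # all four bases differ from N
})

test_that("planted motif positions dominate the mutagenesis signal", {
  m <- tiny_model()
  cfg <- tiny_config()
  d <- simulate_dataset(cfg, tiny_pwms())
  gt <- attr(d, "ground_truth")
  loci <- dplyr::filter(d, category == 4)[1:5, ]
  ratios <- vapply(seq_len(nrow(loci)), function(i) {
    mm <- saturation_mutagenesis(m, loci$window[[i]], target = "ipsc")
    rows <- dplyr::filter(gt, locus_id == loci$locus_id[i])
    motif_pos <- unlist(lapply(seq_len(nrow(rows)), function(r) {
      w <- pwm_width(tiny_pwms()[[rows$tf_id[r]]])
      rows$start[r]:(rows$start[r] + w - 1L)
    }))
    mean(abs(mm$delta[motif_pos, ])) / mean(abs(mm$delta[-motif_pos, ]))
  }, numeric(1))
  expect_gt(mean(ratios > 1), 0.5)
})

test_that("importance and mutagenesis objects tidy into long tibbles", {
  m <- tiny_model()
  codes <- withr::with_seed(26, random_codes(500))
  pr <- deeplift_scores(m, codes, "lcl")
  td <- tidy(pr)
  expect_equal(nrow(td), nrow(pr$scores) * ncol(pr$scores))
  expect_lt(abs(glance(pr)$residual), 1e-8)
  mm <- saturation_mutagenesis(m, codes, 2)
  expect_equal(nrow(tidy(mm)), 2000L)
  expect_s3_class(autoplot(pr), "ggplot")
  expect_s3_class(autoplot(mm, positions = 1:50), "ggplot")
})
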