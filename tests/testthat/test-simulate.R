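test_that("simulated PWM sharpness follows the planting strength", {
  cfg1 <- sim_config(strength_range = c(1, 1), seed = 2)
  p1 <- simulate_pwms(cfg1)
  expect_true(all(vapply(p1, function(p) all(apply(p$matrix, 1, max) == 1), logical(1))))

  cfg0 <- sim_config(strength_range = c(0.25, 0.25), seed = 2)
  p0 <- simulate_pwms(cfg0)
  expect_true(all(vapply(p0, function(p) max(abs(p$matrix - 0.25)) < 1e-12, logical(1))))
  expect_equal(mean(pwm_ic(p0[[1]])), 0, tolerance = 1e-12)

  # information content increases monotonically with strength
  ic <- vapply(c(0.5, 0.7, 0.9), function(s) {
    mean(unlist(lapply(simulate_pwms(sim_config(strength_range = c(s, s), seed = 2)),
                       pwm_ic)))
  }, numeric(1))
  expect_true(all(diff(ic) > 0))

  expect_error(sim_config(motif_width_range = c(2, 5)), "at least 4")
  expect_error(sim_config(strength_range = c(0.1, 0.9)), "0.25")
})

test_that("dataset planting follows the category-to-motif map", {
  cfg <- tiny_config()
  d <- simulate_dataset(cfg, tiny_pwms())
  expect_equal(nrow(d), 7L * cfg$loci_per_category)
  expect_equal(unname(table(d$category)), rep(cfg$loci_per_category, 7),
               ignore_attr = TRUE)
  gt <- attr(d, "ground_truth")

  # category 7 loci carry motifs of all three cell-type sets plus the shared one
  l7 <- d$locus_id[d$category == 7][1:5]
  for (l in l7) {
    expect_setequal(gt$tf_id[gt$locus_id == l],
                    c("IPSC_A", "IPSC_B", "LCL_A", "LCL_B", "CM_A", "CM_B", "SHARED"))
  }
  # category 2 (LCL alone) loci carry only LCL motifs plus shared
  l2 <- d$locus_id[d$category == 2][1]
  expect_setequal(gt$tf_id[gt$locus_id == l2], c("LCL_A", "LCL_B", "SHARED"))

  # every planted motif lies inside its window
  widths <- vapply(tiny_pwms(), pwm_width, integer(1))
  expect_true(all(gt$start >= 1 & gt$start + widths[gt$tf_id] - 1 <= 500))
})

test_that("re-scanning planted windows recovers every motif instance", {
  cfg <- tiny_config()
  d <- simulate_dataset(cfg, tiny_pwms())
  gt <- attr(d, "ground_truth")
  bank <- tiny_bank()
  hits <- 0L; total <- 0L
  for (i in seq_len(20)) {
    pre <- conv1_preact(bank, d$window[[i]])
    rows <- gt[gt$locus_id == d$locus_id[i], ]
    for (r in seq_len(nrow(rows))) {
      total <- total + 1L
      # the planted position should score above the window's 90th percentile
      # for the generating TF (rc_max makes strand irrelevant)
      col <- pre[, rows$tf_id[r]]
      pos <- min(rows$start[r], nrow(pre))
      if (col[pos] >= stats::quantile(col, 0.9)) hits <- hits + 1L
    }
  }
  expect_gt(hits / total, 0.9)
})

test_that("unplanted datasets carry no learnable signal", {
  cfg <- tiny_config(plant = FALSE)
  d <- simulate_dataset(cfg, tiny_pwms())
  expect_equal(nrow(attr(d, "ground_truth") %||% data.frame()), 0L)
  sp <- split_dataset(d, 0.25, seed = 3)
  m <- pwmnet_train(sp$train, tiny_bank(),
                    pwmnet_config(conv2_filters = 8L, dense_units = 16L,
                                  epochs = 6L, seed = 5L))
  a <- evaluate_auc(m, sp$test)
  own <- a$auc[a$score_celltype == a$label_celltype]
  expect_equal(mean(own), 0.5, tolerance = 0.08)
})

test_that("caQTL panels encode motif-disrupting SNPs with known direction", {
  cfg <- tiny_config()
  panel <- simulate_caqtl_panel(cfg, tiny_pwms())
  expect_equal(nrow(panel$truth), cfg$n_caqtl)
  expect_equal(nrow(panel$causal), cfg$n_caqtl + cfg$n_decoys)
  expect_true(all(panel$truth$magnitude > 0))
  expect_true(all(panel$truth$p_eff < 0.5))
  # select_causal retains exactly the planted set
  kept <- suppressMessages(select_causal(panel$causal))
  expect_setequal(kept$snp_id, panel$truth$snp_id)

  # the reference genome carries the motif consensus at each focal SNP
  for (i in 1:5) {
    tr <- panel$truth[i, ]
    chrom_seq <- as.character(panel$genome[[tr$chrom]])
    ref_base <- substr(chrom_seq, tr$pos, tr$pos)
    expect_equal(ref_base, panel$causal$ref[i])
    pwm <- tiny_pwms()[[tr$tf_id]]
    expect_equal(match(ref_base, c("A", "C", "G", "T")),
                 pwm_consensus_codes(pwm)[tr$motif_column])
  }
})

test_that("panel VCFs round-trip and genotype counts match the written file", {
  cfg <- tiny_config()
  panel <- simulate_caqtl_panel(cfg, tiny_pwms())
  dir <- withr::local_tempdir()
  write_caqtl_panel(panel, dir)
  genome <- read_genome(file.path(dir, "ref.fa"))
  snp <- panel$causal[3, ]
  hs <- build_haplotypes(genome, file.path(dir, "panel.vcf"), snp$chrom, snp$pos)
  expect_equal(nrow(hs), 2L * cfg$n_samples)
  # alt-allele dosage in the haplotype set equals the dosage written to the VCF
  gt_row <- panel$genotypes[snp$snp_id, ]
  expect_equal(sum(hs$allele == "alt"),
               sum(unlist(strsplit(gt_row, "|", fixed = TRUE)) == "1"))
  expect_true(sum(hs$allele == "ref") >= 1 && sum(hs$allele == "alt") >= 1)
})

test_that("identical seeds give byte-identical simulation outputs", {
  cfg <- tiny_config(n_caqtl = 10L, n_decoys = 5L, n_samples = 6L,
                     loci_per_category = 5L)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$window, d2$window)

  dirs <- replicate(2, withr::local_tempdir())
  for (dir in dirs) {
    write_caqtl_panel(simulate_caqtl_panel(cfg), dir)
    write_dataset_fasta(simulate_dataset(cfg), file.path(dir, "windows.fa"))
  }
  for (f in c("ref.fa", "panel.vcf", "causal.tsv", "imbalance.tsv", "windows.fa")) {
    expect_identical(readBin(file.path(dirs[1], f), "raw", 1e7),
                     readBin(file.path(dirs[2], f), "raw", 1e7),
                     label = f)
  }

  # a different seed changes the data
  d3 <- simulate_dataset(tiny_config(seed = 99L))
  expect_false(identical(d1$window[[1]]$codes, d3$window[[1]]$codes))
})

test_that("zero-effect imbalance sampling is centered at one half", {
  cfg <- tiny_config(imbalance_scale = 0, n_caqtl = 100L)
  panel <- simulate_caqtl_panel(cfg, tiny_pwms())
  expect_true(all(panel$truth$p_eff == 0.5))
  frac <- panel$imbalance$alt_count /
    (panel$imbalance$ref_count + panel$imbalance$alt_count)
  expect_lt(abs(mean(frac) - 0.5), 3 * 0.5 / sqrt(cfg$depth * 100))
})
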