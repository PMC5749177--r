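#' Configuration for the synthetic benchmark generator
#'
#' The generator emulates, at desk scale, the inputs of the accessibility
#' study: three cell types each marked by two specific motifs plus one
#' motif shared by all three, loci labeled by the seven-way category,
#' phased diploid haplotype panels around motif-disrupting caQTL SNPs, and
#' allelic imbalance sampled binomially around the planted effects.
#'
#' @param celltype_motifs Named list mapping `ipsc`, `lcl`, `cm` and
#'   `shared` to TF identifiers.
#' @param motif_width_range Motif widths are drawn uniformly from this range.
#' @param strength_range Per-column consensus-base probability range; higher
#'   values give higher information content.
#' @param loci_per_category Loci simulated per category (default 2286, i.e.
#'   ~16k loci over the 7 categories).
#' @param gc Background GC content (default 0.41, human-like); the
#'   background is i.i.d., with no repeat structure.
#' @param plant If `FALSE`, windows are pure background (labels then carry
#'   no sequence signal).
#' @param window_width Window width in bp (default 500).
#' @param n_caqtl,n_decoys True caQTLs and decoy background SNPs in the
#'   caQTL panel (defaults 200 each).
#' @param n_samples Diploid individuals in the phased panel (default 40,
#'   i.e. 80 haplotypes).
#' @param n_extra_snps Neutral (non-motif) common SNVs added per caQTL
#'   window (default 1), so haplotype construction substitutes more than
#'   the focal SNP.
#' @param depth Read depth for binomial sampling of allelic imbalance
#'   (default 50; below 10 triggers a warning).
#' @param imbalance_scale Scale converting the log2-odds motif disruption
#'   into the allelic-imbalance logit (default 0.3).
#' @param seed Master seed; all generator randomness derives from it and it
#'   is recorded in every output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(celltype_motifs = list(ipsc = c("IPSC_A", "IPSC_B"),
                                              lcl = c("LCL_A", "LCL_B"),
                                              cm = c("CM_A", "CM_B"),
                                              shared = "SHARED"),
                       motif_width_range = c(8L, 12L),
                       strength_range = c(0.85, 0.97),
                       loci_per_category = 2286L,
                       gc = 0.41, plant = TRUE, window_width = 500L,
                       n_caqtl = 200L, n_decoys = 200L, n_samples = 40L,
                       n_extra_snps = 1L, depth = 50L,
                       imbalance_scale = 0.3, seed = 1L) {
  stopifnot(all(c("ipsc", "lcl", "cm") %in% names(celltype_motifs)))
  if (min(motif_width_range) < 4) abort("motif widths must be at least 4")
  if (min(strength_range) < 0.25 || max(strength_range) > 1) {
    abort("strength_range must lie within [0.25, 1]")
  }
  if (any(c(loci_per_category, n_caqtl, n_samples, depth) < 1)) {
    abort("counts must be positive")
  }
  if (depth < 10) warn("depth < 10: allelic-imbalance estimates will be unstable")
  structure(list(celltype_motifs = celltype_motifs,
                 motif_width_range = as.integer(motif_width_range),
                 strength_range = strength_range,
                 loci_per_category = as.integer(loci_per_category),
                 gc = gc, plant = plant, window_width = as.integer(window_width),
                 n_caqtl = as.integer(n_caqtl), n_decoys = as.integer(n_decoys),
                 n_samples = as.integer(n_samples),
                 n_extra_snps = as.integer(n_extra_snps),
                 depth = as.integer(depth), imbalance_scale = imbalance_scale,
                 seed = as.integer(seed)),
            class = "sim_config")
}

background_probs <- function(gc) c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)

#' Simulate sparse-consensus PWMs
#'
#' Each motif has a random consensus sequence; every column places
#' probability `s` on the consensus base and `(1 - s) / 3` on the others,
#' with `s` drawn per column from `strength_range`. Information content
#' increases with strength.
#'
#' @param config A [sim_config()].
#' @return Named list of [new_pwm()] objects, one per TF in
#'   `config$celltype_motifs`.
#' @export
simulate_pwms <- function(config) {
  tf_ids <- unique(unlist(config$celltype_motifs, use.names = FALSE))
  withr::with_seed(config$seed, {
    pwms <- lapply(tf_ids, function(tf) {
      w <- sample1(seq(config$motif_width_range[1], config$motif_width_range[2]))
      consensus <- sample.int(4, w, replace = TRUE)
      s <- runif(w, config$strength_range[1], config$strength_range[2])
      m <- matrix((1 - s) / 3, w, 4)
      m[cbind(seq_len(w), consensus)] <- s
      new_pwm(m, tf, source = "simulated")
    })
    setNames(pwms, tf_ids)
  })
}

#' Per-column information content of a PWM (bits)
#'
#' `IC_w = 2 + sum_b p_wb * log2(p_wb)`; uniform columns score 0 bits and a
#' deterministic column 2 bits.
#'
#' @param pwm A [new_pwm()] object.
#' @return Numeric vector of per-column IC values.
#' @export
pwm_ic <- function(pwm) {
  p <- pwm$matrix
  apply(p, 1, function(row) {
    nz <- row > 0
    2 + sum(row[nz] * log2(row[nz]))
  })
}

# sample a motif instance (codes) from a PWM's column distributions
sample_motif_instance <- function(pwm) {
  vapply(seq_len(nrow(pwm$matrix)),
         function(i) sample.int(4, 1, prob = pwm$matrix[i, ]), integer(1))
}

# plant codes into a window at a free position; returns list(codes, start, strand)
plant_motif <- function(codes, instance, occupied, max_tries = 200L) {
  w <- length(instance)
  len <- length(codes)
  strand <- if (runif(1) < 0.5) "+" else "-"
  if (strand == "-") instance <- revcomp_codes(instance)
  for (i in seq_len(max_tries)) {
    st <- sample.int(len - w + 1L, 1)
    if (!any(occupied[st:(st + w - 1L)])) {
      codes[st:(st + w - 1L)] <- instance
      occupied[st:(st + w - 1L)] <- TRUE
      return(list(codes = codes, occupied = occupied, start = st, strand = strand))
    }
  }
  abort("could not place a motif without overlap; window too crowded")
}

#' Simulate a motif-planted labeled dataset
#'
#' Generates `loci_per_category` windows for each of the seven categories.
#' Each window is i.i.d. background sequence; a locus of category `O`
#' carries one instance of every motif assigned to each cell type open in
#' `O`, plus the shared motif(s), each planted at a uniform random
#' non-overlapping position on a random strand. Labels follow the planting
#' deterministically.
#'
#' @param config A [sim_config()].
#' @param pwms Optional motif list from [simulate_pwms()] (regenerated from
#'   `config` when omitted).
#' @return A labeled locus tibble (same shape as [build_dataset()]) with
#'   attributes `ground_truth` (planted TF positions), `pwms`, `config`.
#' @export
simulate_dataset <- function(config, pwms = NULL) {
  if (is.null(pwms)) pwms <- simulate_pwms(config)
  len <- config$window_width
  max_w <- max(map_int(pwms, pwm_width))
  if (max_w > len) abort("motif longer than the window")
  n <- 7L * config$loci_per_category
  categories <- rep(1:7, each = config$loci_per_category)
  flags <- category_flags(categories)
  motif_sets <- lapply(1:7, function(o) {
    open <- CELLTYPES[unlist(CATEGORY_TABLE[o, CELLTYPES])]
    unique(c(unlist(config$celltype_motifs[open], use.names = FALSE),
             config$celltype_motifs$shared))
  })

  withr::with_seed(config$seed + 1L, {
    bg <- matrix(sample.int(4, n * len, replace = TRUE,
                            prob = background_probs(config$gc)), n, len)
    windows <- vector("list", n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      codes <- bg[i, ]
      rows <- NULL
      if (config$plant) {
        occupied <- logical(len)
        for (tf in motif_sets[[categories[i]]]) {
          pl <- plant_motif(codes, sample_motif_instance(pwms[[tf]]), occupied)
          codes <- pl$codes
          occupied <- pl$occupied
          rows <- bind_rows(rows, tibble(locus_idx = i, tf_id = tf,
                                         start = pl$start, strand = pl$strand))
        }
      }
      truth[[i]] <- rows
      windows[[i]] <- structure(
        list(codes = codes, chrom = sprintf("locus_%05d", i),
             start = 0L, end = len, n_mask = integer(0)),
        class = "dna_window")
    }
    out <- tibble(locus_id = sprintf("locus_%05d", seq_len(n)),
                  chrom = sprintf("locus_%05d", seq_len(n)),
                  start = 0L, end = len,
                  ipsc = flags$ipsc, lcl = flags$lcl, cm = flags$cm,
                  category = categories, window = windows)
    gt <- bind_rows(truth)
    if (!is.null(gt) && nrow(gt) > 0) {
      gt$locus_id <- out$locus_id[gt$locus_idx]
      gt <- select(gt, "locus_id", "tf_id", "start", "strand")
    }
    attr(out, "ground_truth") <- gt
    attr(out, "pwms") <- pwms
    attr(out, "config") <- config
    out
  })
}

#' Simulate a caQTL panel with phased haplotypes and allelic imbalance
#'
#' For each true caQTL: a 1-kb chromosome of background sequence carries a
#' planted motif instance (forward strand) whose column `j` sits exactly at
#' the chromosome midpoint; the reference base there is the motif consensus
#' and the alternate allele is a random non-consensus base, so the SNP
#' disrupts the motif. The disruption magnitude is the log2-odds difference
#' of the two bases under the motif column. A phased diploid panel is drawn
#' with allele frequency uniform in \[0.1, 0.9\] (both alleles guaranteed
#' present), plus `n_extra_snps` neutral in-window SNVs. Observed
#' alternate-allele counts are Binomial(`depth`, `p_eff`) with
#' `p_eff = plogis(-imbalance_scale * magnitude)` (clamped to keep both
#' counts positive). Decoy background SNPs with `pi_s < 0.5` are appended
#' to the candidate table.
#'
#' @param config A [sim_config()].
#' @param pwms Optional motif list (regenerated from `config` when omitted).
#' @return A `caqtl_panel` list: `genome` (DNAStringSet), `variants`
#'   (tibble), `genotypes` (phased GT matrix, variants x samples), `causal`
#'   (candidate table with `pi_l`, `pi_s`), `imbalance` (allele counts),
#'   `truth` (planted effects), and `config`.
#' @export
simulate_caqtl_panel <- function(config, pwms = NULL) {
  if (is.null(pwms)) pwms <- simulate_pwms(config)
  chrlen <- 2L * config$window_width
  mid <- chrlen %/% 2L          # SNP at 0-based position `mid` (1-based mid+1)
  n_hap <- 2L * config$n_samples
  sample_ids <- sprintf("NA%05d", seq_len(config$n_samples))

  withr::with_seed(config$seed + 2L, {
    seqs <- character(config$n_caqtl)
    var_rows <- list(); gt_rows <- list()
    causal_rows <- list(); imb_rows <- list(); truth_rows <- list()

    for (i in seq_len(config$n_caqtl)) {
      ct <- CELLTYPES[(i - 1L) %% 3L + 1L]
      tf <- sample1(config$celltype_motifs[[ct]])
      pwm <- pwms[[tf]]
      w <- pwm_width(pwm)
      chrom <- sprintf("caq_%03d", i)
      codes <- sample.int(4, chrlen, replace = TRUE, prob = background_probs(config$gc))

      j <- sample1(seq_len(w))                    # disrupted motif column
      start1 <- mid + 1L - (j - 1L)               # 1-based motif start on chrom
      instance <- sample_motif_instance(pwm)
      consensus <- pwm_consensus_codes(pwm)
      instance[j] <- consensus[j]                 # ref allele = consensus
      codes[start1:(start1 + w - 1L)] <- instance

      ref_code <- consensus[j]
      alt_code <- sample1(setdiff(1:4, ref_code))
      pc <- 1e-3
      magnitude <- log2((pwm$matrix[j, ref_code] + pc) / (pwm$matrix[j, alt_code] + pc))
      p_eff <- plogis(-config$imbalance_scale * magnitude)

      snp_id <- sprintf("snp_%03d", i)
      af <- runif(1, 0.1, 0.9)
      hap <- rbinom(n_hap, 1, af)
      tries <- 0L
      while (length(unique(hap)) < 2L && tries < 100L) {
        hap <- rbinom(n_hap, 1, af); tries <- tries + 1L
      }
      if (length(unique(hap)) < 2L) hap[1] <- 1L - hap[1]

      vars <- tibble(chrom = chrom, pos = mid + 1L, id = snp_id,
                     ref = DNA_BASES[ref_code], alt = DNA_BASES[alt_code], af = af)
      haps <- list(hap)
      # neutral extra SNVs outside the motif, inside the 500-bp window
      win_lo <- mid - config$window_width %/% 2L + 1L   # 1-based window bounds
      win_hi <- mid + config$window_width %/% 2L
      forbidden <- c(start1:(start1 + w - 1L), mid + 1L)
      free <- setdiff(win_lo:win_hi, forbidden)
      if (config$n_extra_snps > 0 && length(free) > 0) {
        extra_pos <- sort(sample(free, min(config$n_extra_snps, length(free))))
        for (k in seq_along(extra_pos)) {
          rc <- codes[extra_pos[k]]
          ac <- sample1(setdiff(1:4, rc))
          af_k <- runif(1, 0.1, 0.9)
          vars <- bind_rows(vars, tibble(
            chrom = chrom, pos = extra_pos[k],
            id = sprintf("%s_bg%d", snp_id, k),
            ref = DNA_BASES[rc], alt = DNA_BASES[ac], af = af_k))
          haps[[length(haps) + 1L]] <- rbinom(n_hap, 1, af_k)
        }
      }
      ord <- order(vars$pos)
      vars <- vars[ord, ]
      haps <- haps[ord]
      gt <- vapply(haps, function(h) {
        paste(h[seq(1, n_hap, 2)], h[seq(2, n_hap, 2)], sep = "|")
      }, character(config$n_samples))
      gt_rows[[i]] <- t(gt)                        # variants x samples
      var_rows[[i]] <- vars

      alt_count <- rbinom(1, config$depth, p_eff)
      alt_count <- min(max(alt_count, 1L), config$depth - 1L)
      seqs[i] <- decode_codes(codes)
      causal_rows[[i]] <- tibble(snp_id = snp_id, chrom = chrom, pos = mid + 1L,
                                 ref = DNA_BASES[ref_code], alt = DNA_BASES[alt_code],
                                 pi_l = 1.0, pi_s = 1.0)
      imb_rows[[i]] <- tibble(snp_id = snp_id, ref_count = config$depth - alt_count,
                              alt_count = alt_count)
      truth_rows[[i]] <- tibble(snp_id = snp_id, chrom = chrom, pos = mid + 1L,
                                celltype = ct, tf_id = tf, motif_column = j,
                                direction = -1, magnitude = magnitude, p_eff = p_eff)
    }

    # decoy background SNPs: candidate records that must fail select_causal
    decoys <- NULL
    if (config$n_decoys > 0) {
      host <- sample.int(config$n_caqtl, config$n_decoys, replace = TRUE)
      decoys <- tibble(
        snp_id = sprintf("decoy_%03d", seq_len(config$n_decoys)),
        chrom = sprintf("caq_%03d", host),
        pos = mid + 1L + sample(c(-1, 1), config$n_decoys, TRUE) *
          sample(60:200, config$n_decoys, TRUE),
        ref = DNA_BASES[sample.int(4, config$n_decoys, TRUE)],
        alt = NA_character_,
        pi_l = runif(config$n_decoys),
        pi_s = runif(config$n_decoys, 0, 0.5))
      decoys$alt <- vapply(decoys$ref, function(r) sample(setdiff(DNA_BASES, r), 1),
                           character(1))
    }

    genome <- Biostrings::DNAStringSet(setNames(seqs, sprintf("caq_%03d",
                                                              seq_len(config$n_caqtl))))
    structure(list(
      genome = genome,
      variants = bind_rows(var_rows),
      genotypes = do.call(rbind, map(seq_len(config$n_caqtl),
                                     ~ `rownames<-`(gt_rows[[.x]], var_rows[[.x]]$id))),
      sample_ids = sample_ids,
      causal = bind_rows(bind_rows(causal_rows), decoys),
      imbalance = bind_rows(imb_rows),
      truth = bind_rows(truth_rows),
      config = config
    ), class = "caqtl_panel")
  })
}

#' @export
print.caqtl_panel <- function(x, ...) {
  cat(sprintf("<caqtl_panel> %d caQTLs + %d decoys, %d diploid samples, depth %d\n",
              x$config$n_caqtl, x$config$n_decoys, x$config$n_samples, x$config$depth))
  invisible(x)
}

#' Monte-Carlo generative correlation of a caQTL panel
#'
#' Independent oracle for the imbalance comparison: repeatedly resamples
#' binomial allele counts around the planted per-locus effects (same
#' clamping as the generator) and returns the mean Pearson correlation
#' between the planted effect (`p_eff - 0.5`) and the sampled imbalance
#' fraction (`- 0.5`).
#'
#' @param panel A `caqtl_panel`.
#' @param n_draws Monte-Carlo replicates (default 10000).
#' @param seed Seed for the resampling.
#' @return Scalar mean correlation.
#' @export
generative_correlation <- function(panel, n_draws = 10000L, seed = 1L) {
  p_eff <- panel$truth$p_eff
  depth <- panel$config$depth
  withr::with_seed(seed, {
    mean(vapply(seq_len(n_draws), function(i) {
      alt <- rbinom(length(p_eff), depth, p_eff)
      alt <- pmin(pmax(alt, 1L), depth - 1L)
      cor(p_eff - 0.5, alt / depth - 0.5)
    }, numeric(1)))
  })
}

#' Write a simulated dataset's windows as FASTA
#'
#' @param data Labeled locus tibble with a `window` list-column.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_dataset_fasta <- function(data, path) {
  seqs <- Biostrings::DNAStringSet(vapply(data$window, function(w)
    decode_codes(w$codes), character(1)))
  names(seqs) <- data$locus_id
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write a caQTL panel to disk as FASTA + VCF + TSVs
#'
#' Emits `ref.fa`, `panel.vcf` (VCF v4.2 with phased GT; no file date, so
#' identical seeds give byte-identical output), `causal.tsv` and
#' `imbalance.tsv` under `dir`.
#'
#' @param panel A `caqtl_panel`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_caqtl_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(panel$genome, file.path(dir, "ref.fa"))

  v <- panel$variants
  header <- c("##fileformat=VCFv4.2",
              sprintf("##source=pwmnet_simulate_seed%d", panel$config$seed),
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Phased genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", panel$sample_ids), collapse = "\t"))
  body <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(v$chrom[i], v$pos[i], v$id[i], v$ref[i], v$alt[i], ".", "PASS",
            sprintf("AF=%.4f", v$af[i]), "GT", panel$genotypes[i, ]),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), file.path(dir, "panel.vcf"))

  utils::write.table(panel$causal, file.path(dir, "causal.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(panel$imbalance, file.path(dir, "imbalance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
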