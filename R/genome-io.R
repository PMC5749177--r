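#' Read a genome or locus set from FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that keeps only the
#' first whitespace-delimited token of each header as the sequence name.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Extract a fixed-width one-hot window centered on a locus
#'
#' The window is `[c - width/2, c + width/2)` in 0-based half-open
#' coordinates, where `c = floor((start + end) / 2)` is the locus center.
#' Bases are upper-cased; any non-ACGT base becomes an all-zero one-hot row
#' recorded in `n_mask`. Windows overhanging a chromosome end are an error —
#' there is no silent clipping.
#'
#' @param genome A named [Biostrings::DNAStringSet] (see [read_genome()]).
#' @param chrom,start,end Locus interval, 0-based half-open.
#' @param width Window width in bp (even; default 500).
#' @return A `dna_window`: list with `codes` (integer base codes), `chrom`,
#'   `start`, `end` (the window interval), and `n_mask` (1-based positions of
#'   ambiguous bases).
#' @export
extract_window <- function(genome, chrom, start, end, width = 500L) {
  if (width %% 2 != 0) abort("window width must be even")
  if (start < 0 || start >= end) abort("need 0 <= start < end")
  if (!chrom %in% names(genome)) abort(sprintf("unknown chromosome: %s", chrom))
  c0 <- (start + end) %/% 2
  w0 <- c0 - width %/% 2          # 0-based inclusive
  w1 <- c0 + width %/% 2          # 0-based exclusive
  chrlen <- Biostrings::width(genome[chrom])
  if (w0 < 0 || w1 > chrlen) {
    abort(sprintf("window [%d,%d) overhangs %s (length %d)", w0, w1, chrom, chrlen))
  }
  seq <- as.character(Biostrings::subseq(genome[[chrom]], start = w0 + 1L, width = width))
  codes <- encode_codes(seq)
  structure(list(codes = codes, chrom = chrom, start = w0, end = w1,
                 n_mask = which(codes == 0L)),
            class = "dna_window")
}

#' @export
print.dna_window <- function(x, ...) {
  cat(sprintf("<dna_window> %s:%d-%d (%d bp, %d ambiguous)\n",
              x$chrom, x$start, x$end, length(x$codes), length(x$n_mask)))
  invisible(x)
}

#' Read BED / narrowPeak intervals into a tibble
#'
#' BED3/BED6 files are parsed with [rtracklayer::import()]; files with ten
#' columns are treated as ENCODE narrowPeak and column 7 (signalValue) is
#' exposed as `fold_enrichment`. Coordinates are returned in the BED
#' convention (0-based half-open), exactly as stored in the file.
#'
#' @param path Path to a BED3+/narrowPeak file.
#' @return A tibble with `chrom`, `start`, `end`, and, when present,
#'   `name`, `score`, `strand`, `fold_enrichment`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("BED file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  nf <- length(strsplit(lines[[1]], "\t", fixed = TRUE)[[1]])
  gr <- if (nf >= 10) {
    rtracklayer::import(path, format = "BED",
                        extraCols = c(signalValue = "numeric", pValue = "numeric",
                                      qValue = "numeric", peak = "integer"))
  } else {
    rtracklayer::import(path, format = "BED")
  }
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # back to 0-based half-open
    end = GenomicRanges::end(gr)
  )
  if (any(out$start >= out$end)) {
    abort(sprintf("%s: %d interval(s) with start >= end", path, sum(out$start >= out$end)))
  }
  mc <- as.data.frame(S4Vectors::mcols(gr))
  if ("name" %in% names(mc)) out$name <- mc$name
  if ("score" %in% names(mc)) out$score <- as.numeric(mc$score)
  if (nf >= 10) out$fold_enrichment <- mc$signalValue
  out
}

#' Read phased genotypes from a VCF
#'
#' Parses a VCF once so many [build_haplotypes()] calls can share it.
#'
#' @param path Path to a VCF (v4.x) file with phased `GT` fields.
#' @return A list with `fix` (tibble: chrom, pos (1-based), ref, alt) and
#'   `gt` (character matrix of GT strings, variants x samples).
#' @export
read_phased_vcf <- function(path) {
  if (!file.exists(path)) abort(sprintf("VCF file not found: %s", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble(
    chrom = vcfR::getCHROM(v),
    pos = as.integer(vcfR::getPOS(v)),
    ref = vcfR::getREF(v),
    alt = vcfR::getALT(v)
  )
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) abort(sprintf("%s has no GT field", path))
  list(fix = fix, gt = gt)
}

#' Construct per-haplotype window sequences around a focal SNP
#'
#' Builds the 500-bp reference window centered on the focal SNP, then, for
#' each phased haplotype of each diploid sample, substitutes the alleles of
#' *all* phased SNVs falling inside the window (not only the focal SNP;
#' restrict with `focal_only = TRUE`). Indels and multiallelic records are
#' skipped with a warning; an unphased genotype at any in-window variant is
#' an error naming the sample.
#'
#' @param genome A named [Biostrings::DNAStringSet].
#' @param vcf Path to a VCF with phased GT, or the result of an internal
#'   VCF read.
#' @param snp_chrom,snp_pos Focal SNP position (`snp_pos` 1-based, as in VCF).
#' @param width Window width (default 500).
#' @param focal_only If `TRUE`, substitute only the focal SNP.
#' @return A `haplotype_set`: tibble with `sample_id`, `haplotype` (0/1),
#'   `allele` (`"ref"`/`"alt"` at the focal SNP) and `window` (list-column of
#'   `dna_window` objects); attributes `focal` and `n_skipped`.
#' @export
build_haplotypes <- function(genome, vcf, snp_chrom, snp_pos, width = 500L,
                             focal_only = FALSE) {
  v <- if (is.character(vcf)) read_phased_vcf(vcf) else vcf
  # 0-based interval of length 1 at the SNP; window centered on it
  ref_win <- extract_window(genome, snp_chrom, snp_pos - 1L, snp_pos, width = width)

  in_win <- v$fix$chrom == snp_chrom & v$fix$pos > ref_win$start & v$fix$pos <= ref_win$end
  fix <- v$fix[in_win, , drop = FALSE]
  gt <- v$gt[in_win, , drop = FALSE]

  is_snv <- nchar(fix$ref) == 1L & nchar(fix$alt) == 1L & !grepl(",", fix$alt)
  n_skipped <- sum(!is_snv)
  if (n_skipped > 0) {
    warn(sprintf("skipping %d indel/multiallelic record(s) in window %s:%d-%d",
                 n_skipped, snp_chrom, ref_win$start, ref_win$end))
  }
  fix <- fix[is_snv, , drop = FALSE]
  gt <- gt[is_snv, , drop = FALSE]

  focal_idx <- which(fix$chrom == snp_chrom & fix$pos == snp_pos)
  if (length(focal_idx) != 1L) {
    abort(sprintf("focal SNP %s:%d absent from VCF (or not a biallelic SNV)",
                  snp_chrom, snp_pos))
  }

  samples <- colnames(gt)
  bad <- samples[apply(gt, 2, function(g) any(!grepl("^[01]\\|[01]$", g)))]
  if (length(bad) > 0) {
    abort(sprintf("unphased or missing genotype in window for sample(s): %s",
                  paste(bad, collapse = ", ")))
  }

  offsets <- fix$pos - ref_win$start          # 1-based position inside window
  alt_codes <- match(toupper(fix$alt), DNA_BASES)
  ref_codes <- match(toupper(fix$ref), DNA_BASES)
  if (any(ref_win$codes[offsets] != ref_codes)) {
    warn("VCF REF allele disagrees with the reference window at some site(s)")
  }

  sub_idx <- if (focal_only) focal_idx else seq_along(offsets)
  rows <- list()
  for (s in samples) {
    alleles <- do.call(rbind, strsplit(gt[, s], "|", fixed = TRUE)) # variants x 2
    storage.mode(alleles) <- "integer"
    for (h in 1:2) {
      codes <- ref_win$codes
      carry <- sub_idx[alleles[sub_idx, h] == 1L]
      codes[offsets[carry]] <- alt_codes[carry]
      win <- structure(list(codes = codes, chrom = ref_win$chrom,
                            start = ref_win$start, end = ref_win$end,
                            n_mask = which(codes == 0L)),
                       class = "dna_window")
      rows[[length(rows) + 1L]] <- tibble(
        sample_id = s, haplotype = h - 1L,
        allele = if (alleles[focal_idx, h] == 1L) "alt" else "ref",
        window = list(win)
      )
    }
  }
  out <- bind_rows(rows)
  structure(out,
            class = c("haplotype_set", class(out)),
            focal = list(chrom = snp_chrom, pos = snp_pos,
                         ref = fix$ref[focal_idx], alt = fix$alt[focal_idx]),
            n_skipped = n_skipped)
}
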