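test_that("window extraction centers, encodes and masks ambiguous bases", {
  seqstr <- paste(rep("ACGT", 150), collapse = "")     # 600 bp
  fa <- write_tmp_fasta(list(chr1 = seqstr))
  genome <- read_genome(fa)

  w <- extract_window(genome, "chr1", 40, 60, width = 20)
  # center c = 50, window [40, 60)
  expect_equal(w$start, 40)
  expect_equal(w$end, 60)
  expect_equal(decode_one_hot(one_hot(w)), substr(seqstr, 41, 60))

  # first four bases encode as the unit rows
  w2 <- extract_window(genome, "chr1", 0, 4, width = 4)
  expect_equal(unname(one_hot(w2)), diag(4))

  # overhang is an error, not a clip
  expect_error(extract_window(genome, "chr1", 0, 100, width = 500), "overhang")
  expect_error(extract_window(genome, "chrX", 40, 60, width = 20), "unknown chromosome")
  expect_error(extract_window(genome, "chr1", 40, 60, width = 21), "even")
})

test_that("N bases become zero rows and round-trip as N", {
  fa <- write_tmp_fasta(list(c1 = "ACGTNNACGTA"))
  genome <- read_genome(fa)
  w <- extract_window(genome, "c1", 2, 8, width = 10)   # spans the NN
  expect_true(all(w$n_mask %in% which(w$codes == 0)))
  oh <- one_hot(w)
  expect_equal(rowSums(oh)[w$n_mask], rep(0, length(w$n_mask)), ignore_attr = TRUE)
  expect_true(all(rowSums(oh) %in% c(0, 1)))
  expect_equal(decode_one_hot(oh), decode_codes(w$codes))
})

test_that("BED and narrowPeak files parse with verbatim coordinates", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t60", "chr2\t0\t25"), bed)
  b <- read_bed(bed)
  expect_equal(b$chrom, c("chr1", "chr2"))
  expect_equal(b$start, c(10L, 0L))
  expect_equal(b$end, c(60L, 25L))

  np <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines(c("chr1\t100\t200\tpeak1\t0\t.\t16.2\t5.1\t3.2\t50",
               "chr1\t300\t400\tpeak2\t0\t.\t14.9\t5.1\t3.2\t50"), np)
  p <- read_bed(np)
  expect_equal(p$fold_enrichment, c(16.2, 14.9))

  empty <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(0), empty)
  expect_equal(nrow(read_bed(empty)), 0L)
})

# tiny phased panel written by hand for haplotype construction
local_hap_fixture <- function(env = parent.frame()) {
  seqstr <- withr::with_seed(21, decode_codes(sample(1:4, 700, TRUE)))
  fa <- write_tmp_fasta(list(chrT = seqstr))
  vcf <- withr::local_tempfile(fileext = ".vcf", .local_envir = env)
  ref_at <- function(pos1) substr(seqstr, pos1, pos1)
  alt_of <- function(r) setdiff(c("A", "C", "G", "T"), r)[1]
  # focal SNP at 1-based 350; second SNV at 300; an indel to be skipped
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    sprintf("chrT\t300\tv1\t%s\t%s\t.\tPASS\t.\tGT\t0|1\t1|1", ref_at(300), alt_of(ref_at(300))),
    sprintf("chrT\t350\tfocal\t%s\t%s\t.\tPASS\t.\tGT\t0|1\t0|0", ref_at(350), alt_of(ref_at(350))),
    sprintf("chrT\t360\tindel\t%sA\t%s\t.\tPASS\t.\tGT\t0|0\t0|1", ref_at(360), ref_at(360))
  ), vcf)
  list(genome = read_genome(fa), vcf = vcf, seqstr = seqstr,
       ref_at = ref_at, alt_of = alt_of)
}

test_that("haplotype construction substitutes all phased SNVs per haplotype", {
  fx <- local_hap_fixture()
  hs <- suppressWarnings(build_haplotypes(fx$genome, fx$vcf, "chrT", 350))
  expect_equal(nrow(hs), 4L)            # 2 diploid samples -> 4 haplotypes
  expect_equal(attr(hs, "n_skipped"), 1L)  # the indel

  # string-edit oracle: window [99, 599) 0-based; offsets are pos - 99 (1-based)
  win <- substr(fx$seqstr, 100, 599)
  edit <- function(s, pos1, base) { substr(s, pos1 - 99, pos1 - 99) <- base; s }
  alt300 <- fx$alt_of(fx$ref_at(300)); alt350 <- fx$alt_of(fx$ref_at(350))
  s1h1 <- win                                    # S1 hap0: 0 at both SNVs
  s1h2 <- edit(edit(win, 300, alt300), 350, alt350)
  s2h1 <- edit(win, 300, alt300)                 # S2 carries v1 on both haps
  got <- vapply(hs$window, function(w) decode_codes(w$codes), character(1))
  expect_equal(got[1:3], c(s1h1, s1h2, s2h1))
  expect_equal(hs$allele, c("ref", "alt", "ref", "ref"))

  # focal-only mode leaves non-focal SNVs at reference
  hf <- suppressWarnings(build_haplotypes(fx$genome, fx$vcf, "chrT", 350,
                                          focal_only = TRUE))
  expect_equal(decode_codes(hf$window[[2]]$codes), edit(win, 350, alt350))
})

test_that("unphased genotypes and missing focal SNPs are hard errors", {
  fx <- local_hap_fixture()
  expect_error(suppressWarnings(build_haplotypes(fx$genome, fx$vcf, "chrT", 352)),
               "absent")
  bad <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    sprintf("chrT\t350\tfocal\t%s\t%s\t.\tPASS\t.\tGT\t0/1",
            fx$ref_at(350), fx$alt_of(fx$ref_at(350)))
  ), bad)
  expect_error(build_haplotypes(fx$genome, bad, "chrT", 350), "S1")
})
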