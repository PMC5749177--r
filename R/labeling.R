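CATEGORY_TABLE <- data.frame(
  category = 1:7,
  ipsc = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
  lcl  = c(FALSE, TRUE,  TRUE,  FALSE, FALSE, TRUE, TRUE),
  cm   = c(TRUE,  FALSE, TRUE,  FALSE, TRUE, FALSE, TRUE)
)

# categories whose label includes each cell type (used for marginalization)
CELLTYPE_CATEGORIES <- list(
  ipsc = c(4L, 5L, 6L, 7L),
  lcl  = c(2L, 3L, 6L, 7L),
  cm   = c(1L, 3L, 5L, 7L)
)

CELLTYPES <- c("ipsc", "lcl", "cm")

#' Map per-cell-type open flags to the 7-way accessibility category
#'
#' The category encodes which of the three cell types (iPSC, LCL, iPSC-CM)
#' a locus is accessible in: 1 = iPSC-CM alone, 2 = LCL alone, 3 = iPSC-CM
#' and LCL, 4 = iPSC alone, 5 = iPSC and iPSC-CM, 6 = iPSC and LCL,
#' 7 = all three. A locus open in no cell type is rejected.
#'
#' @param ipsc,lcl,cm Logical vectors (recycled to common length).
#' @return Integer category vector in 1..7.
#' @seealso [category_flags()] for the inverse mapping.
#' @export
assign_category <- function(ipsc, lcl, cm) {
  n <- max(length(ipsc), length(lcl), length(cm))
  ipsc <- rep_len(as.logical(ipsc), n)
  lcl <- rep_len(as.logical(lcl), n)
  cm <- rep_len(as.logical(cm), n)
  if (any(!ipsc & !lcl & !cm)) {
    abort("locus accessible in no cell type: all three open flags are FALSE")
  }
  key <- paste(ipsc, lcl, cm)
  lut <- setNames(CATEGORY_TABLE$category,
                  paste(CATEGORY_TABLE$ipsc, CATEGORY_TABLE$lcl, CATEGORY_TABLE$cm))
  unname(lut[key])
}

#' Inverse of [assign_category()]
#'
#' @param category Integer vector in 1..7.
#' @return Tibble with logical columns `ipsc`, `lcl`, `cm`.
#' @export
category_flags <- function(category) {
  if (any(!category %in% 1:7)) abort("category must be in 1..7")
  CATEGORY_TABLE[match(category, CATEGORY_TABLE$category), c("ipsc", "lcl", "cm")]
}

peaks_to_granges <- function(peaks) {
  GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
  )
}

granges_to_tibble <- function(gr) {
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr) - 1L,
         end = GenomicRanges::end(gr))
}

#' Merge per-sample peak sets for one cell type
#'
#' Discards peaks below the fold-change enrichment threshold (default 15x
#' over background) and coalesces the survivors by interval union:
#' overlapping or book-ended peaks become a single merged peak. Merging is
#' idempotent.
#'
#' @param per_sample_peaks A peak tibble (from [read_bed()]) or a list of
#'   them, each with a `fold_enrichment` column.
#' @param min_fold Minimum fold-change enrichment; peaks with
#'   `fold_enrichment < min_fold` are discarded (default 15).
#' @return Tibble of merged intervals (`chrom`, `start`, `end`), 0-based
#'   half-open.
#' @export
merge_peaks <- function(per_sample_peaks, min_fold = 15) {
  if (is.data.frame(per_sample_peaks)) per_sample_peaks <- list(per_sample_peaks)
  peaks <- bind_rows(per_sample_peaks)
  if (nrow(peaks) == 0) return(tibble(chrom = character(), start = integer(), end = integer()))
  if (!"fold_enrichment" %in% names(peaks)) {
    abort("peaks lack a fold_enrichment column (narrowPeak signalValue)")
  }
  peaks <- filter(peaks, .data$fold_enrichment >= min_fold)
  if (nrow(peaks) == 0) return(tibble(chrom = character(), start = integer(), end = integer()))
  granges_to_tibble(GenomicRanges::reduce(peaks_to_granges(peaks)))
}

#' Build the labeled training dataset from three merged peak sets
#'
#' Candidate loci are the union of the three cell types' merged peaks,
#' coalesced across cell types. A union locus is flagged open in cell type
#' `t` iff it overlaps any merged peak of `t` (by at least 1 bp, or by at
#' least `min_overlap_frac` of the locus). A 500-bp window is extracted at
#' each union locus center; loci whose windows would overhang a chromosome
#' end are dropped with a logged count.
#'
#' @param ipsc_peaks,lcl_peaks,cm_peaks Merged peak tibbles ([merge_peaks()]).
#' @param genome A named [Biostrings::DNAStringSet].
#' @param width Window width (default 500).
#' @param min_overlap_frac Minimum fraction of the union locus that must be
#'   covered by a peak of a cell type to count as open there (default 0,
#'   meaning any 1-bp overlap).
#' @return Tibble with `locus_id`, `chrom`, `start`, `end` (the union
#'   locus), `ipsc`, `lcl`, `cm`, `category`, and a `window` list-column.
#' @export
build_dataset <- function(ipsc_peaks, lcl_peaks, cm_peaks, genome, width = 500L,
                          min_overlap_frac = 0) {
  sets <- list(ipsc = ipsc_peaks, lcl = lcl_peaks, cm = cm_peaks)
  all_peaks <- bind_rows(sets)
  if (nrow(all_peaks) == 0) abort("union of the three peak sets is empty")
  union_gr <- GenomicRanges::reduce(peaks_to_granges(all_peaks))
  loci <- granges_to_tibble(union_gr)

  for (ct in CELLTYPES) {
    if (nrow(sets[[ct]]) == 0) {
      loci[[ct]] <- FALSE
      next
    }
    ct_gr <- peaks_to_granges(sets[[ct]])
    ov <- GenomicRanges::findOverlaps(union_gr, ct_gr)
    open <- rep(FALSE, nrow(loci))
    if (length(ov) > 0) {
      inter_w <- GenomicRanges::width(IRanges::pintersect(
        union_gr[S4Vectors::queryHits(ov)], ct_gr[S4Vectors::subjectHits(ov)]))
      locus_w <- GenomicRanges::width(union_gr[S4Vectors::queryHits(ov)])
      ok <- inter_w >= pmax(1, min_overlap_frac * locus_w)
      open[unique(S4Vectors::queryHits(ov)[ok])] <- TRUE
    }
    loci[[ct]] <- open
  }
  loci <- filter(loci, .data$ipsc | .data$lcl | .data$cm)
  loci$category <- assign_category(loci$ipsc, loci$lcl, loci$cm)

  windows <- vector("list", nrow(loci))
  keep <- rep(TRUE, nrow(loci))
  for (i in seq_len(nrow(loci))) {
    w <- tryCatch(extract_window(genome, loci$chrom[i], loci$start[i], loci$end[i],
                                 width = width),
                  error = function(e) NULL)
    if (is.null(w)) keep[i] <- FALSE else windows[[i]] <- w
  }
  if (any(!keep)) {
    inform(sprintf("dropped %d locus/loci whose windows overhang chromosome ends",
                   sum(!keep)))
  }
  loci <- loci[keep, , drop = FALSE]
  loci$window <- windows[keep]
  loci$locus_id <- sprintf("locus_%05d", seq_len(nrow(loci)))
  select(loci, "locus_id", "chrom", "start", "end", all_of(CELLTYPES),
         "category", "window")
}

#' Stratified train/test split of a labeled dataset
#'
#' Randomly assigns a fixed fraction of loci to the held-out test set,
#' stratified by category so per-category proportions are preserved, and
#' reproducible under `seed`.
#'
#' @param loci Labeled locus tibble with a `category` column.
#' @param held_out_fraction Fraction of loci held out (0 < f < 1).
#' @param seed Integer seed controlling the split.
#' @return List with `train` and `test` tibbles (disjoint).
#' @export
split_dataset <- function(loci, held_out_fraction = 0.125, seed = 1L) {
  if (held_out_fraction <= 0 || held_out_fraction >= 1) {
    abort("held_out_fraction must be in (0, 1)")
  }
  counts <- table(loci$category)
  if (any(counts < 2)) {
    abort(paste("every category needs at least 2 loci to split; consider",
                "merging categories or simulating more loci"))
  }
  test_idx <- withr::with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(loci)), loci$category), function(idx) {
      n_test <- max(1L, round(length(idx) * held_out_fraction))
      sample(idx, n_test)
    }), use.names = FALSE)
  })
  list(train = loci[-test_idx, , drop = FALSE],
       test = loci[sort(test_idx), , drop = FALSE])
}

#' Write a dataset manifest as TSV
#'
#' @param loci Labeled locus tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(loci, path) {
  utils::write.table(
    loci[, c("locus_id", "chrom", "start", "end", CELLTYPES, "category")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
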