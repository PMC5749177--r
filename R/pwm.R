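#' Construct a position weight matrix object
#'
#' A PWM is stored as a width x 4 matrix of per-position base probabilities
#' (columns ordered A,C,G,T). Rows are renormalized to sum to one; validation
#' rejects negative entries and zero-sum rows.
#'
#' @param matrix Width x 4 numeric matrix of base probabilities or counts.
#' @param tf_id Unique identifier of the transcription factor.
#' @param tf_name Human-readable TF name (defaults to `tf_id`).
#' @param source Provenance label, e.g. `"MEME"`, `"JASPAR"`, `"TRANSFAC"`,
#'   `"HT-SELEX"` or `"simulated"`.
#' @param pseudocount Added to every entry before row normalization (use > 0
#'   when `matrix` holds raw counts with zero cells).
#' @return An object of class `pwm`.
#' @export
new_pwm <- function(matrix, tf_id, tf_name = tf_id, source = "unknown",
                    pseudocount = 0) {
  m <- as.matrix(matrix)
  if (ncol(m) != 4) abort("PWM matrix must have 4 columns (A,C,G,T)")
  if (nrow(m) < 2) abort("PWM width must be at least 2")
  if (any(!is.finite(m)) || any(m < 0)) abort("PWM entries must be finite and non-negative")
  m <- m + pseudocount
  rs <- rowSums(m)
  if (any(rs <= 0)) {
    abort(sprintf("PWM '%s' has zero-sum row(s): %s", tf_id,
                  paste(which(rs <= 0), collapse = ", ")))
  }
  m <- m / rs
  colnames(m) <- DNA_BASES
  rownames(m) <- NULL
  structure(list(tf_id = tf_id, tf_name = tf_name, matrix = m, source = source),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s (%s), width %d, source %s\n",
              x$tf_id, x$tf_name, nrow(x$matrix), x$source))
  print(round(x$matrix, 3))
  invisible(x)
}

pwm_width <- function(pwm) nrow(pwm$matrix)

pwm_consensus_codes <- function(pwm) {
  as.integer(apply(pwm$matrix, 1, which.max))
}

#' Read transcription-factor PWMs from motif files
#'
#' Supports three common text dialects: MEME minimal motif format, JASPAR
#' count blocks (either plain 4-row blocks or the bracketed `A [ ... ]`
#' style), and TRANSFAC-like count matrices (numbered rows of four counts
#' between `ID`/`//` markers). Counts are converted to probabilities by
#' row-sum division after adding `pseudocount` to each cell.
#'
#' @param path Path to the motif file.
#' @param dialect One of `"meme"`, `"jaspar"`, `"transfac"`.
#' @param pseudocount Added to each count cell before normalization
#'   (default 0; MEME matrices are already probabilities and ignore it).
#' @return A list of [new_pwm()] objects in file order.
#' @export
read_pwms <- function(path, dialect = c("meme", "jaspar", "transfac"),
                      pseudocount = 0) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("motif file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  pwms <- switch(dialect,
    meme = parse_meme(lines, path),
    jaspar = parse_jaspar(lines, path, pseudocount),
    transfac = parse_transfac(lines, path, pseudocount)
  )
  if (length(pwms) == 0) abort(sprintf("no motifs found in %s", path))
  pwms
}

parse_numeric_row <- function(line, lineno, path, n_expected = 4) {
  vals <- suppressWarnings(as.numeric(strsplit(trimws(line), "\\s+")[[1]]))
  if (length(vals) != n_expected || any(is.na(vals))) {
    abort(sprintf("%s line %d: expected %d numeric fields, got '%s'",
                  path, lineno, n_expected, line))
  }
  vals
}

parse_meme <- function(lines, path) {
  pwms <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (grepl("^MOTIF\\b", lines[i])) {
      toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      tf_id <- toks[2]
      tf_name <- if (length(toks) >= 3) toks[3] else tf_id
      j <- i + 1L
      while (j <= length(lines) && !grepl("letter-probability matrix", lines[j])) {
        if (grepl("^MOTIF\\b", lines[j])) {
          abort(sprintf("%s line %d: MOTIF %s has no letter-probability matrix",
                        path, i, tf_id))
        }
        j <- j + 1L
      }
      if (j > length(lines)) {
        abort(sprintf("%s: MOTIF %s has no letter-probability matrix", path, tf_id))
      }
      w <- suppressWarnings(as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[j])))
      rows <- list()
      k <- j + 1L
      while (k <= length(lines) && grepl("^\\s*[0-9.eE+-]+\\s", paste0(lines[k], " "))) {
        if (!nzchar(trimws(lines[k]))) break
        rows[[length(rows) + 1L]] <- parse_numeric_row(lines[k], k, path)
        k <- k + 1L
        if (!is.na(w) && length(rows) == w) break
      }
      if (!is.na(w) && length(rows) != w) {
        abort(sprintf("%s: MOTIF %s declares w=%d but has %d rows",
                      path, tf_id, w, length(rows)))
      }
      pwms[[length(pwms) + 1L]] <-
        new_pwm(do.call(rbind, rows), tf_id, tf_name, source = "MEME")
      i <- k
    } else {
      i <- i + 1L
    }
  }
  pwms
}

parse_jaspar <- function(lines, path, pseudocount) {
  pwms <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (grepl("^>", lines[i])) {
      toks <- strsplit(sub("^>", "", trimws(lines[i])), "\\s+")[[1]]
      tf_id <- toks[1]
      tf_name <- if (length(toks) >= 2) toks[2] else tf_id
      rows <- vector("list", 4)
      for (b in 1:4) {
        lineno <- i + b
        if (lineno > length(lines)) {
          abort(sprintf("%s: motif %s truncated (needs 4 base rows)", path, tf_id))
        }
        ln <- lines[lineno]
        # bracketed style: "A [ 4 0 1 ]"
        ln <- gsub("^\\s*[ACGTacgt]\\s*\\[", "", ln)
        ln <- gsub("\\]\\s*$", "", ln)
        vals <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
        if (length(vals) < 1 || any(is.na(vals))) {
          abort(sprintf("%s line %d: malformed JASPAR count row", path, lineno))
        }
        rows[[b]] <- vals
      }
      if (length(unique(lengths(rows))) != 1) {
        abort(sprintf("%s: motif %s has base rows of unequal width", path, tf_id))
      }
      counts <- t(do.call(rbind, rows)) # width x 4, rows were A,C,G,T
      pwms[[length(pwms) + 1L]] <-
        new_pwm(counts, tf_id, tf_name, source = "JASPAR", pseudocount = pseudocount)
      i <- i + 5L
    } else {
      i <- i + 1L
    }
  }
  pwms
}

parse_transfac <- function(lines, path, pseudocount) {
  pwms <- list()
  tf_id <- NULL
  tf_name <- NULL
  rows <- list()
  flush <- function() {
    if (!is.null(tf_id) && length(rows) > 0) {
      pwms[[length(pwms) + 1L]] <<-
        new_pwm(do.call(rbind, rows), tf_id, tf_name %||% tf_id,
                source = "TRANSFAC", pseudocount = pseudocount)
    }
    tf_id <<- NULL; tf_name <<- NULL; rows <<- list()
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^ID\\s+", ln)) {
      flush()
      tf_id <- strsplit(trimws(ln), "\\s+")[[1]][2]
    } else if (grepl("^NA\\s+", ln)) {
      tf_name <- strsplit(trimws(ln), "\\s+")[[1]][2]
    } else if (grepl("^//", ln)) {
      flush()
    } else if (grepl("^\\d+\\s", ln)) {
      toks <- strsplit(trimws(ln), "\\s+")[[1]]
      # numbered row: NN cA cC cG cT [consensus]
      vals <- suppressWarnings(as.numeric(toks[2:5]))
      if (length(vals) != 4 || any(is.na(vals))) {
        abort(sprintf("%s line %d: expected 4 counts after row number", path, i))
      }
      if (is.null(tf_id)) tf_id <- sprintf("motif%02d", length(pwms) + 1L)
      rows[[length(rows) + 1L]] <- vals
    }
  }
  flush()
  pwms
}

#' Log-transform a PWM against a background model
#'
#' Converts base probabilities into log2-odds weights:
#' `w[i, b] = log2((p[i, b] + pseudocount) / (background[b] + pseudocount))`.
#' A uniform PWM on a uniform background maps to the all-zero matrix, so
#' "no information" scores zero under the frozen convolutional layer.
#'
#' @param pwm A [new_pwm()] object.
#' @param background 4-vector of strictly positive base frequencies summing
#'   to 1 (default uniform).
#' @param pseudocount Positive scalar keeping the log finite at zero
#'   probabilities (default 1e-3).
#' @return Width x 4 numeric matrix of finite log2-odds weights.
#' @export
log_transform <- function(pwm, background = rep(0.25, 4), pseudocount = 1e-3) {
  check_probability_vector(background)
  if (!is.finite(pseudocount) || pseudocount <= 0) {
    abort("pseudocount must be a positive scalar")
  }
  w <- log2(sweep(pwm$matrix + pseudocount, 2, background + pseudocount, "/"))
  colnames(w) <- DNA_BASES
  w
}

#' Slide a weight matrix along a one-hot sequence (brute-force oracle)
#'
#' Plain sliding-window dot product: the score at offset `i` is
#' `sum(filter * onehot[i:(i + W - 1), ])`. This is deliberately the naive
#' O(L*W) implementation; it serves as the independent reference for the
#' model's first convolutional layer.
#'
#' @param onehot L x 4 one-hot matrix (all-zero rows allowed).
#' @param filter W x 4 weight matrix.
#' @return Numeric vector of length `L - W + 1`.
#' @export
pwm_scan <- function(onehot, filter) {
  stopifnot(is.matrix(onehot), ncol(onehot) == 4, is.matrix(filter), ncol(filter) == 4)
  L <- nrow(onehot); W <- nrow(filter)
  if (L < W) abort(sprintf("sequence length %d shorter than filter width %d", L, W))
  vapply(seq_len(L - W + 1L), function(i) {
    sum(filter * onehot[i:(i + W - 1L), , drop = FALSE])
  }, numeric(1))
}
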