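#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement for plain character vectors.
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random DNA sequence
#' @param n length in bp.
#' @return a single character string of length `n`.
#' @keywords internal
rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Hamming distance between two equal-length strings.
mismatches <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(charToRaw(a) != charToRaw(b))
}

# Substring on a circular sequence; start is 1-based, may wrap past the end.
circ_substr <- function(s, start, len) {
  L <- nchar(s)
  stopifnot(len <= L)
  start <- ((start - 1L) %% L) + 1L
  end <- start + len - 1L
  if (end <= L) {
    substr(s, start, end)
  } else {
    paste0(substr(s, start, L), substr(s, 1L, end - L))
  }
}

# Replace bases on a circular sequence starting at `start` (1-based, wraps).
circ_replace <- function(s, start, repl) {
  L <- nchar(s)
  n <- nchar(repl)
  stopifnot(n <= L)
  start <- ((start - 1L) %% L) + 1L
  end <- start + n - 1L
  if (end <= L) {
    substr(s, start, end) <- repl
    s
  } else {
    k <- L - start + 1L
    substr(s, start, L) <- substr(repl, 1L, k)
    substr(s, 1L, end - L) <- substr(repl, k + 1L, n)
    s
  }
}

# Booth's least-rotation algorithm on an integer encoding of a string.
least_rotation_index <- function(v) {
  n <- length(v)
  if (n <= 1L) return(1L)
  s <- c(v, v)
  f <- rep.int(-1L, 2L * n)
  k <- 0L
  for (j in seq.int(2L, 2L * n)) {
    sj <- s[j]
    i <- f[j - k - 1L]
    while (i != -1L && sj != s[k + i + 2L]) {
      if (sj < s[k + i + 2L]) k <- j - i - 2L
      i <- f[i + 1L]
    }
    if (sj != s[k + i + 2L]) {
      if (sj < s[k + 1L]) k <- j - 1L
      f[j - k] <- -1L
    } else {
      f[j - k] <- i + 1L
    }
  }
  k + 1L
}

# Lexicographically least rotation of a string.
least_rotation <- function(s) {
  n <- nchar(s)
  if (n <= 1L) return(s)
  i <- least_rotation_index(utf8ToInt(s))
  circ_substr(s, i, n)
}

#' Canonical form of a circular DNA sequence
#'
#' The lexicographically smallest string among all rotations of the sequence
#' and (optionally) of its reverse complement.  Used to compare assembled
#' circles with the truth regardless of start point and strand.
#'
#' @param s a single DNA sequence.
#' @param strand logical; also consider the reverse complement (default TRUE).
#' @return a single character string.
#' @export
canonical_circular <- function(s, strand = TRUE) {
  a <- least_rotation(s)
  if (!strand) return(a)
  b <- least_rotation(revcomp(s))
  if (a <= b) a else b
}

# Draw fresh sub-seeds (kept below 2^31) from the current RNG stream.
derive_seeds <- function(n) {
  sample.int(.Machine$integer.max - 1L, n)
}

# Per-base depth vector from placements on a (possibly circular) sequence.
depth_vector <- function(pos, len, L, circular = TRUE) {
  d <- integer(L)
  if (length(pos) == 0L) return(d)
  end <- pos + len - 1L
  inb <- end <= L
  if (any(inb)) {
    ir <- IRanges::IRanges(start = pos[inb], end = end[inb])
    cv <- IRanges::coverage(ir, width = L)
    d <- d + as.integer(cv)
  }
  if (circular && any(!inb)) {
    for (i in which(!inb)) {
      d[pos[i]:L] <- d[pos[i]:L] + 1L
      w <- end[i] - L
      d[1:w] <- d[1:w] + 1L
    }
  }
  d
}

# Clamp intervals to [1, L]; error when out of range.
check_intervals <- function(df, L, what = "interval") {
  if (nrow(df) == 0L) return(invisible(df))
  if (any(df$start < 1L) || any(df$end > L) || any(df$end < df$start)) {
    stop(sprintf("%s out of range for genome of length %d", what, L))
  }
  invisible(df)
}
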