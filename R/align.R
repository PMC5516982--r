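# In-process read mapping.
#
# The simulator's error model is substitution-only, so mapping reduces to
# gap-free placement: exact k-mer seeds (Biostrings::PDict/matchPDict, three
# seeds per read) propose candidate placements, which are verified by direct
# Hamming comparison.  Circular subjects are handled by extending the
# subject with a copy of its first (read length - 1) bases.

# Candidate placements for one strand's query set against a subject.
seed_candidates <- function(qs, subj_dna, k) {
  n <- length(qs)
  rl <- nchar(qs)
  offs <- lapply(rl, function(l) {
    if (l < k) return(integer(0))
    unique(c(1L, (l - k) %/% 2L + 1L, l - k + 1L))
  })
  qi <- rep(seq_len(n), lengths(offs))
  off <- unlist(offs, use.names = FALSE)
  if (!length(qi)) return(data.frame(qi = integer(0), pos = integer(0)))
  seeds <- unname(substring(qs[qi], off, off + k - 1L))
  ok <- !grepl("[^ACGT]", seeds)
  qi <- qi[ok]; off <- off[ok]; seeds <- seeds[ok]
  if (!length(seeds)) return(data.frame(qi = integer(0), pos = integer(0)))
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds))
  m <- Biostrings::matchPDict(pd, subj_dna)
  st <- Biostrings::startIndex(m)
  nh <- vapply(st, length, integer(1))
  data.frame(qi = rep(qi, nh), pos = unlist(st, use.names = FALSE) - rep(off, nh) + 1L)
}

#' Map reads to a reference by seeded gap-free alignment
#'
#' Returns every placement of each read (both strands) whose full-length
#' identity meets `min_identity`.  Identity is matches over read length.
#'
#' @param query named character vector of reads.
#' @param subject single reference sequence (character).
#' @param circular treat the subject as circular (wrap permitted).
#' @param min_identity minimum full-length identity (default 0.98).
#' @param seed_k seed k-mer size (default 20).
#' @return data.frame with columns `query`, `pos` (1-based leftmost position
#'   on the forward subject), `strand`, `len`, `mm`, `identity`.
#' @export
map_reads <- function(query, subject, circular = TRUE, min_identity = 0.98,
                      seed_k = 20L) {
  empty <- data.frame(query = character(0), pos = integer(0),
                      strand = character(0), len = integer(0),
                      mm = integer(0), identity = numeric(0))
  if (length(query) == 0L || nchar(subject) == 0L) return(empty)
  q <- toupper(query)
  ids <- names(q) %||% as.character(seq_along(q))
  L <- nchar(subject)
  maxrl <- max(nchar(q))
  ext <- if (circular && L > 1L) {
    paste0(subject, substr(subject, 1L, min(L, maxrl) - 1L))
  } else subject
  ext_len <- nchar(ext)
  subj_dna <- Biostrings::DNAString(ext)
  res <- list()
  for (strand in c("+", "-")) {
    qs <- if (strand == "+") q else revcomp(q)
    cand <- seed_candidates(qs, subj_dna, seed_k)
    if (!nrow(cand)) next
    rl <- nchar(qs)[cand$qi]
    keep <- cand$pos >= 1L & cand$pos + rl - 1L <= ext_len
    if (circular) keep <- keep & cand$pos <= L
    cand <- cand[keep, , drop = FALSE]
    cand <- unique(cand)
    if (!nrow(cand)) next
    rl <- nchar(qs)[cand$qi]
    segs <- substring(ext, cand$pos, cand$pos + rl - 1L)
    mm <- vapply(seq_len(nrow(cand)),
                 function(i) mismatches(qs[cand$qi[i]], segs[i]), integer(1))
    idn <- (rl - mm) / rl
    sel <- idn >= min_identity
    if (!any(sel)) next
    res[[strand]] <- data.frame(query = ids[cand$qi[sel]], pos = cand$pos[sel],
                                strand = strand, len = rl[sel], mm = mm[sel],
                                identity = idn[sel], stringsAsFactors = FALSE)
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Map reads against a set of contigs
#'
#' @param query named character vector of reads.
#' @param subjects named character vector of reference sequences.
#' @param ... passed to [map_reads()] (contigs are linear: `circular=FALSE`).
#' @return data.frame as [map_reads()] plus a `subject` column.
#' @export
map_reads_multi <- function(query, subjects, ...) {
  empty <- data.frame(query = character(0), pos = integer(0),
                      strand = character(0), len = integer(0),
                      mm = integer(0), identity = numeric(0),
                      subject = character(0))
  if (!length(subjects) || !length(query)) return(empty)
  # concatenate subjects with N spacers and map once; placements crossing a
  # boundary (into the spacer) fail verification or are dropped below
  spacer_len <- max(nchar(query)) + 10L
  spacer <- paste(rep("N", spacer_len), collapse = "")
  cat_seq <- paste(subjects, collapse = spacer)
  starts <- cumsum(c(1L, utils::head(nchar(subjects) + spacer_len, -1L)))
  h <- map_reads(query, cat_seq, circular = FALSE, ...)
  if (!nrow(h)) return(empty)
  idx <- findInterval(h$pos, starts)
  local <- h$pos - starts[idx] + 1L
  fits <- local >= 1L & local + h$len - 1L <= nchar(subjects)[idx]
  h <- h[fits, , drop = FALSE]
  if (!nrow(h)) return(empty)
  h$pos <- local[fits]
  h$subject <- names(subjects)[idx[fits]]
  rownames(h) <- NULL
  h
}

# Best placement(s) per read: minimal mismatches; adds n_best (number of
# equally good placements) and unique flag.
best_hits <- function(hits) {
  if (!nrow(hits)) {
    hits$n_best <- integer(0); hits$unique <- logical(0)
    return(hits)
  }
  sp <- split(seq_len(nrow(hits)), hits$query)
  keep <- unlist(lapply(sp, function(ix) {
    mmmin <- min(hits$mm[ix])
    ix[hits$mm[ix] == mmmin]
  }), use.names = FALSE)
  out <- hits[keep, , drop = FALSE]
  nb <- table(out$query)
  out$n_best <- as.integer(nb[out$query])
  out$unique <- out$n_best == 1L
  rownames(out) <- NULL
  out
}
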