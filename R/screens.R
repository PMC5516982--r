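# Annotation-side screens: pseudogene classification, plastid-insertion and
# repeat detection at BLASTn thresholds, ORF inventory and precedence-based
# category accounting.

#' Screen configuration
#'
#' @param evalue_max BLASTn expectation-value ceiling (default 1e-10).
#' @param identity_min BLASTn identity floor (default 0.90).
#' @param orf_min_bp minimum ORF length including the stop codon
#'   (default 89).
#' @param short_coverage_max a candidate covering less than this fraction of
#'   the reference CDS is a truncation pseudogene (default 0.80).
#' @param repeat_min_bp minimum reportable repeat length (default 30).
#' @return a `ScreenConfig` list.
#' @export
screen_config <- function(evalue_max = 1e-10, identity_min = 0.90,
                          orf_min_bp = 89L, short_coverage_max = 0.80,
                          repeat_min_bp = 30L) {
  stopifnot(identity_min > 0, identity_min <= 1,
            short_coverage_max > 0, short_coverage_max <= 1)
  structure(list(evalue_max = evalue_max, identity_min = identity_min,
                 orf_min_bp = as.integer(orf_min_bp),
                 short_coverage_max = short_coverage_max,
                 repeat_min_bp = as.integer(repeat_min_bp)),
            class = "ScreenConfig")
}

#' Classify a gene candidate as intact or pseudogene
#'
#' The candidate is aligned globally (within a local window of the
#' reference) to the reference CDS; the verdict is pseudogene when any of
#' the four criteria triggers: an in-frame internal stop codon, a missing
#' start and/or stop codon, a frameshifting net indel, or aligned coverage
#' below `short_coverage_max` of the reference CDS.
#'
#' @param candidate candidate nucleotide sequence (sense strand).
#' @param reference_cds reference CDS: length a multiple of 3, starting with
#'   ATG (terminal stop codon included).
#' @param cfg a [screen_config()].
#' @return list: `status` ("intact"/"pseudogene"), `triggered` (character
#'   vector of criteria), `coverage_fraction`.
#' @export
classify_pseudogene <- function(candidate, reference_cds,
                                cfg = screen_config()) {
  stopifnot(nchar(reference_cds) %% 3L == 0L,
            substr(reference_cds, 1L, 3L) == "ATG")
  ref_len <- nchar(reference_cds)
  stops <- c("TAA", "TAG", "TGA")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  aln <- try(Biostrings::pairwiseAlignment(candidate, reference_cds,
                                           type = "global-local",
                                           substitutionMatrix = mat,
                                           gapOpening = 6, gapExtension = 2),
             silent = TRUE)
  no_aln <- inherits(aln, "try-error") || Biostrings::score(aln) <= 0
  if (no_aln) {
    return(list(status = "pseudogene", triggered = "short_coverage",
                coverage_fraction = 0))
  }
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  s0 <- Biostrings::start(Biostrings::subject(aln))
  e0 <- Biostrings::end(Biostrings::subject(aln))
  coverage <- (e0 - s0 + 1L) / ref_len
  cand_aln <- paste(p[p != "-"], collapse = "")
  ref_span <- e0 - s0 + 1L
  net_indel <- nchar(cand_aln) - ref_span
  triggered <- character(0)
  # translate the aligned candidate from the first complete reference codon
  lead <- (3L - ((s0 - 1L) %% 3L)) %% 3L
  body <- substr(cand_aln, lead + 1L, nchar(cand_aln))
  n_cod <- nchar(body) %/% 3L
  aas <- if (n_cod > 0L) {
    as.character(Biostrings::translate(
      Biostrings::DNAString(substr(body, 1L, n_cod * 3L)),
      if.fuzzy.codon = "X"))
  } else ""
  internal <- if (nchar(aas) > 1L) substr(aas, 1L, nchar(aas) - 1L) else ""
  if (grepl("*", internal, fixed = TRUE)) triggered <- c(triggered, "inframe_stop")
  # terminal codons are judged on the candidate itself; alignment clipping
  # must not manufacture a missing start/stop
  nc <- nchar(candidate)
  if (substr(candidate, 1L, 3L) != "ATG") {
    triggered <- c(triggered, "missing_start")
  }
  if (nc < 3L || !(substr(candidate, nc - 2L, nc) %in% stops)) {
    triggered <- c(triggered, "missing_stop")
  }
  if (net_indel %% 3L != 0L) triggered <- c(triggered, "frameshift")
  if (coverage < cfg$short_coverage_max) triggered <- c(triggered, "short_coverage")
  list(status = if (length(triggered)) "pseudogene" else "intact",
       triggered = triggered, coverage_fraction = coverage)
}

# Run blastn query-vs-subject and return the tabular hits.
run_blastn <- function(query, subject, evalue, perc_identity, dust = "no") {
  blastn <- Sys.which("blastn")
  if (!nzchar(blastn)) stop("blastn executable not found on PATH")
  qf <- tempfile(fileext = ".fa"); sf <- tempfile(fileext = ".fa")
  on.exit(unlink(c(qf, sf)), add = TRUE)
  write_fasta(c(query = query), qf)
  write_fasta(c(subject = subject), sf)
  out <- system2(blastn, c("-query", qf, "-subject", sf,
                           "-evalue", format(evalue, scientific = TRUE),
                           "-perc_identity", perc_identity * 100,
                           "-dust", dust, "-outfmt",
                           shQuote("6 qstart qend sstart send pident length evalue bitscore")),
                 stdout = TRUE)
  if (!length(out)) {
    return(data.frame(qstart = integer(0), qend = integer(0),
                      sstart = integer(0), send = integer(0),
                      pident = numeric(0), length = integer(0),
                      evalue = numeric(0), bitscore = numeric(0)))
  }
  df <- utils::read.table(text = out, col.names = c("qstart", "qend", "sstart",
                                                    "send", "pident", "length",
                                                    "evalue", "bitscore"))
  df
}

#' Detect plastid-derived insertions in the mitochondrial genome
#'
#' Local alignments of the mitochondrial genome against the chloroplast
#' genome at the configured expectation-value and identity thresholds,
#' projected to mitochondrial coordinates and merged.
#'
#' @param mtdna mitochondrial genome sequence.
#' @param cpdna chloroplast genome sequence.
#' @param cfg a [screen_config()].
#' @return list: `intervals` (data.frame start/end), `total_bp`,
#'   `genome_fraction`.
#' @export
find_plastid_insertions <- function(mtdna, cpdna, cfg = screen_config()) {
  stopifnot(nchar(mtdna) > 0, nchar(cpdna) > 0)
  hits <- run_blastn(mtdna, cpdna, cfg$evalue_max, cfg$identity_min)
  if (!nrow(hits)) {
    return(list(intervals = data.frame(start = integer(0), end = integer(0)),
                total_bp = 0L, genome_fraction = 0))
  }
  ir <- IRanges::reduce(IRanges::IRanges(start = pmin(hits$qstart, hits$qend),
                                         end = pmax(hits$qstart, hits$qend)))
  iv <- data.frame(start = IRanges::start(ir), end = IRanges::end(ir))
  total <- sum(iv$end - iv$start + 1L)
  list(intervals = iv, total_bp = as.integer(total),
       genome_fraction = total / nchar(mtdna))
}

#' Detect repeated regions within the mitochondrial genome
#'
#' Self-alignment with BLASTn at the configured thresholds, excluding the
#' trivial full-length diagonal; each repeat pair is reported once, with
#' kind "inverted" when the hit is on the opposite strand.
#'
#' @param mtdna mitochondrial genome sequence.
#' @param cfg a [screen_config()].
#' @return data.frame: q_start, q_end, s_start, s_end, identity, length,
#'   kind.
#' @export
find_repeats <- function(mtdna, cfg = screen_config()) {
  hits <- run_blastn(mtdna, mtdna, cfg$evalue_max, cfg$identity_min)
  if (!nrow(hits)) return(empty_repeat_table())
  inverted <- hits$sstart > hits$send
  s_lo <- pmin(hits$sstart, hits$send); s_hi <- pmax(hits$sstart, hits$send)
  trivial <- hits$qstart == s_lo & hits$qend == s_hi & !inverted
  hits <- hits[!trivial, , drop = FALSE]
  inverted <- inverted[!trivial]; s_lo <- s_lo[!trivial]; s_hi <- s_hi[!trivial]
  keep <- hits$length >= cfg$repeat_min_bp
  hits <- hits[keep, , drop = FALSE]
  inverted <- inverted[keep]; s_lo <- s_lo[keep]; s_hi <- s_hi[keep]
  if (!nrow(hits)) return(empty_repeat_table())
  out <- data.frame(q_start = hits$qstart, q_end = hits$qend,
                    s_start = s_lo, s_end = s_hi,
                    identity = hits$pident / 100, length = hits$length,
                    kind = ifelse(inverted, "inverted", "direct"),
                    stringsAsFactors = FALSE)
  # mirrored duplicates: canonicalise so the first interval starts lower,
  # then keep each pair once
  swap <- out$q_start > out$s_start
  tmp <- out[swap, c("s_start", "s_end", "q_start", "q_end")]
  out[swap, c("q_start", "q_end", "s_start", "s_end")] <- tmp
  key <- paste(out$q_start, out$q_end, out$s_start, out$s_end, out$kind)
  out <- out[!duplicated(key), , drop = FALSE]
  # drop self-overlapping residue of the diagonal
  out <- out[!(out$q_start == out$s_start & out$q_end == out$s_end &
                 out$kind == "direct"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_repeat_table <- function() {
  data.frame(q_start = integer(0), q_end = integer(0), s_start = integer(0),
             s_end = integer(0), identity = numeric(0), length = integer(0),
             kind = character(0), stringsAsFactors = FALSE)
}

#' ORF inventory by six-frame scan
#'
#' Scans both strands in all three frames for ATG..stop open reading frames
#' of at least `orf_min_bp` (length includes the stop codon); the circular
#' origin may be crossed; ORFs nested in a longer same-frame ORF (later ATG,
#' same stop) are suppressed.
#'
#' @param mtdna genome sequence.
#' @param cfg a [screen_config()].
#' @param circular scan across the origin (default TRUE).
#' @return data.frame: start, end (1-based inclusive, end may be < start for
#'   origin-spanning ORFs on +), strand, length, peptide.
#' @export
find_orfs <- function(mtdna, cfg = screen_config(), circular = TRUE) {
  L <- nchar(mtdna)
  scan_strand <- function(seqs, strand) {
    S <- if (circular) paste0(seqs, seqs) else seqs
    n <- nchar(S)
    rows <- list()
    for (f in 0:2) {
      ncod <- (n - f) %/% 3L
      if (ncod < 2L) next
      st <- f + 1L + 3L * (0:(ncod - 1L))
      cods <- substring(S, st, st + 2L)
      is_stop <- cods %in% c("TAA", "TAG", "TGA")
      is_atg <- cods == "ATG"
      prev_stop <- 0L
      for (k in which(is_stop)) {
        # first ATG after the previous stop
        cand <- which(is_atg[(prev_stop + 1L):(k - 1L)])
        if (length(cand)) {
          a <- prev_stop + cand[1L]
          start_pos <- st[a]
          end_pos <- st[k] + 2L
          len <- end_pos - start_pos + 1L
          if (len >= cfg$orf_min_bp && len <= L && start_pos <= L) {
            rows[[length(rows) + 1L]] <- c(start_pos, end_pos, len)
          }
        }
        prev_stop <- k
      }
    }
    if (!length(rows)) return(NULL)
    m <- do.call(rbind, rows)
    m <- unique(m)
    data.frame(p_start = m[, 1L], p_end = m[, 2L], length = m[, 3L],
               strand = strand)
  }
  fwd <- scan_strand(mtdna, "+")
  rcm <- scan_strand(revcomp(mtdna), "-")
  out <- list()
  if (!is.null(fwd)) {
    fwd$start <- fwd$p_start
    fwd$end <- ((fwd$p_end - 1L) %% L) + 1L
    out[[length(out) + 1L]] <- fwd
  }
  if (!is.null(rcm)) {
    # map positions on the reverse complement back to genome coordinates
    rcm$start <- L - (((rcm$p_end - 1L) %% L) + 1L) + 1L
    rcm$end <- L - rcm$p_start + 1L
    out[[length(out) + 1L]] <- rcm
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), length = integer(0),
                      peptide = character(0)))
  }
  res <- do.call(rbind, out)
  res <- res[!duplicated(res[, c("start", "end", "strand")]), , drop = FALSE]
  # peptide (without the stop)
  res$peptide <- vapply(seq_len(nrow(res)), function(i) {
    nt <- if (res$strand[i] == "+") circ_substr(mtdna, res$start[i], res$length[i])
    else revcomp(circ_substr(mtdna, res$start[i], res$length[i]))
    as.character(Biostrings::translate(
      Biostrings::DNAString(substr(nt, 1L, res$length[i] - 3L)),
      if.fuzzy.codon = "X"))
  }, character(1))
  res <- res[order(res$start, res$end, res$strand), c("start", "end", "strand",
                                                      "length", "peptide")]
  rownames(res) <- NULL
  res
}

#' Category accounting with fixed precedence
#'
#' Attributes every base of the genome to the first category (in the order
#' given) whose track covers it; the remainder is reported as intergenic.
#' Reported base counts always sum exactly to the genome length.
#'
#' @param genome_length circle length in bp.
#' @param tracks named ordered list of interval data.frames (`start`,
#'   `end`, 1-based inclusive), highest precedence first (canonically
#'   A genes < B ORFs < C mitovirus < D plastid-derived < E repeats < F TEs).
#' @return data.frame: category, bp, pct; last row is "intergenic".
#' @export
category_accounting <- function(genome_length, tracks) {
  L <- as.integer(genome_length)
  assigned <- IRanges::IRanges()
  rows <- list()
  for (nm in names(tracks)) {
    tr <- tracks[[nm]]
    if (nrow(tr)) check_intervals(tr, L, paste0("track '", nm, "'"))
    ir <- if (nrow(tr)) IRanges::reduce(IRanges::IRanges(tr$start, tr$end))
    else IRanges::IRanges()
    novel <- IRanges::setdiff(ir, assigned)
    bp <- sum(IRanges::width(novel))
    assigned <- IRanges::reduce(IRanges::union(assigned, ir))
    rows[[length(rows) + 1L]] <- data.frame(category = nm, bp = bp,
                                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  inter <- L - sum(out$bp)
  out <- rbind(out, data.frame(category = "intergenic", bp = inter))
  out$pct <- 100 * out$bp / L
  rownames(out) <- NULL
  out
}
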