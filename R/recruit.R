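# Read recruitment: plastid subtraction, coverage profiling, contig baiting
# and mitochondrial read recruitment (assembly steps a-d).

#' Recruitment configuration
#'
#' @param full_length_identity_min identity floor for end-to-end matches
#'   (default 0.98).
#' @param bait_identity_min local-alignment identity floor for gene baiting
#'   (default 0.70).
#' @param bait_evalue_max expectation-value ceiling for baiting (default
#'   1e-10).
#' @param peak_ratio coverage-peak flag multiplier over the across-contig
#'   median depth (default 1.5).
#' @param min_read_length_bp minimum read length accepted (default 50).
#' @return a `RecruitmentConfig` list.
#' @export
recruitment_config <- function(full_length_identity_min = 0.98,
                               bait_identity_min = 0.70,
                               bait_evalue_max = 1e-10,
                               peak_ratio = 1.5,
                               min_read_length_bp = 50L) {
  stopifnot(full_length_identity_min > 0, full_length_identity_min <= 1,
            bait_identity_min > 0, bait_identity_min <= 1, peak_ratio > 1)
  structure(list(full_length_identity_min = full_length_identity_min,
                 bait_identity_min = bait_identity_min,
                 bait_evalue_max = bait_evalue_max, peak_ratio = peak_ratio,
                 min_read_length_bp = as.integer(min_read_length_bp)),
            class = "RecruitmentConfig")
}

# Which pairs have every mate matching the subject end-to-end at >=
# identity (single-end sets: the read itself).
pair_full_length_match <- function(reads, subject, min_identity,
                                   circular = TRUE) {
  h1 <- map_reads(reads$reads1, subject, circular = circular,
                  min_identity = min_identity)
  hit1 <- reads$meta$id %in% sub("/[12]$", "", h1$query)
  if (!reads$paired) return(hit1)
  h2 <- map_reads(reads$reads2, subject, circular = circular,
                  min_identity = min_identity)
  hit1 & reads$meta$id %in% sub("/[12]$", "", h2$query)
}

subset_readset <- function(reads, keep) {
  reads$reads1 <- reads$reads1[keep]
  if (reads$paired) reads$reads2 <- reads$reads2[keep]
  reads$meta <- reads$meta[keep, , drop = FALSE]
  rownames(reads$meta) <- NULL
  reads
}

#' Discard reads matching the chloroplast genome end-to-end
#'
#' A read is discarded when it aligns end-to-end (100% of the read, either
#' strand, circular wrap permitted) to the chloroplast sequence at identity
#' at or above `full_length_identity_min`; for paired sets the whole pair is
#' discarded only when both mates match, so mitochondrial pairs anchored by
#' a mate outside a shared mt/cp insertion keep the benefit of the doubt.
#' Survivors are returned unchanged and in their original order.
#'
#' @param reads a `ReadSet`.
#' @param cpdna chloroplast genome sequence (character), treated as circular.
#' @param cfg a [recruitment_config()].
#' @return a filtered `ReadSet` with a `report` attribute (id, decision,
#'   reason).
#' @export
filter_plastid_reads <- function(reads, cpdna, cfg = recruitment_config()) {
  if (cfg$full_length_identity_min <= 0) stop("config error: identity threshold <= 0")
  if (length(reads) == 0L) return(reads)
  stopifnot(nchar(cpdna) > 0)
  is_cp <- pair_full_length_match(reads, cpdna, cfg$full_length_identity_min)
  out <- subset_readset(reads, !is_cp)
  attr(out, "report") <- data.frame(
    id = reads$meta$id,
    decision = ifelse(is_cp, "discarded", "retained"),
    reason = ifelse(is_cp, "full_length_cpdna_match", "no_cpdna_match"),
    stringsAsFactors = FALSE)
  out
}

#' Per-contig coverage profile with peak flags
#'
#' Maps reads to each contig and summarises depth; a contig is flagged
#' "peak" when its median depth exceeds `peak_ratio` times the median of the
#' per-contig median depths, the signature of plastid-derived or collapsed
#' duplicated regions.
#'
#' @param contigs named character vector of contig sequences.
#' @param reads a `ReadSet`.
#' @param cfg a [recruitment_config()].
#' @return data.frame: contig, length, mean_depth, median_depth, peak.
#' @export
coverage_profile <- function(contigs, reads, cfg = recruitment_config()) {
  stopifnot(length(contigs) > 0)
  all_reads <- c(reads$reads1, reads$reads2)
  hits <- map_reads_multi(all_reads, contigs,
                          min_identity = cfg$full_length_identity_min)
  out <- data.frame(contig = names(contigs), length = nchar(contigs),
                    mean_depth = 0, median_depth = 0, peak = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (i in seq_len(nrow(out))) {
    h <- hits[hits$subject == out$contig[i], , drop = FALSE]
    d <- depth_vector(h$pos, h$len, out$length[i], circular = FALSE)
    out$mean_depth[i] <- mean(d)
    # summarise depth over the interior plateau: near contig ends reads
    # cannot fit, so depth tapers over one read length on each side
    rl <- if (nrow(h)) as.integer(stats::median(h$len)) else 0L
    lo <- rl; hi <- out$length[i] - rl
    dd <- if (hi > lo) d[(lo + 1L):hi] else d
    out$median_depth[i] <- stats::median(dd)
  }
  # baseline = lower-quartile contig median (an actual observed value, no
  # interpolation): robust when duplicated contigs inflate the plain median
  ref <- stats::quantile(out$median_depth, 0.25, type = 1, names = FALSE)
  if (ref > 0) out$peak <- out$median_depth > cfg$peak_ratio * ref
  out
}

#' Bait mitochondrial contigs with reference gene sequences
#'
#' A contig is retained when any local alignment against any reference gene
#' reaches `bait_identity_min` identity with expectation value at most
#' `bait_evalue_max`.
#'
#' @param contigs named character vector.
#' @param reference_genes named character vector of known mitochondrial gene
#'   sequences.
#' @param cfg a [recruitment_config()].
#' @return the retained subset of `contigs`, with a `report` attribute
#'   holding the best hit per contig.
#' @export
bait_contigs <- function(contigs, reference_genes, cfg = recruitment_config()) {
  stopifnot(length(reference_genes) > 0)
  rep_rows <- list()
  keep <- logical(length(contigs))
  for (i in seq_along(contigs)) {
    best <- NULL
    for (j in seq_along(reference_genes)) {
      hit <- local_hit(contigs[[i]], reference_genes[[j]])
      if (is.null(hit)) next
      if (hit$identity >= cfg$bait_identity_min &&
          hit$evalue <= cfg$bait_evalue_max) {
        if (is.null(best) || hit$evalue < best$evalue) {
          best <- hit
          best$gene <- names(reference_genes)[j] %||% as.character(j)
        }
      }
    }
    if (!is.null(best)) {
      keep[i] <- TRUE
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        contig = names(contigs)[i], gene = best$gene, length = best$length,
        identity = best$identity, evalue = best$evalue,
        stringsAsFactors = FALSE)
    }
  }
  out <- contigs[keep]
  attr(out, "report") <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(contig = character(0), gene = character(0),
               length = integer(0), identity = numeric(0), evalue = numeric(0))
  out
}

# Best local alignment of gene vs contig (both strands); identity is
# matches over alignment length including gaps; expectation value by
# Karlin-Altschul scaling for ungapped seeds (advisory: the identity and
# length thresholds dominate in practice).
local_hit <- function(contig, gene) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  best <- NULL
  for (gseq in c(gene, revcomp(gene))) {
    aln <- Biostrings::pairwiseAlignment(gseq, contig, type = "local",
                                         substitutionMatrix = mat,
                                         gapOpening = 5, gapExtension = 2)
    p <- as.character(Biostrings::alignedPattern(aln))
    s <- as.character(Biostrings::alignedSubject(aln))
    if (nchar(p) == 0L) next
    matches <- sum(strsplit(p, "")[[1]] == strsplit(s, "")[[1]])
    alen <- nchar(p)
    idn <- matches / alen
    # ungapped Karlin-Altschul with lambda~1.33, K~0.62 for match/mismatch 1/-2
    score <- Biostrings::score(aln)
    ev <- 0.62 * nchar(contig) * nchar(gene) * exp(-1.33 * score)
    cand <- list(length = alen, identity = idn, evalue = ev)
    if (is.null(best) || cand$evalue < best$evalue) best <- cand
  }
  best
}

#' Recruit mitochondrial reads against baited contigs
#'
#' Retains pairs where either mate aligns end-to-end to any baited contig at
#' `full_length_identity_min` (pair rescue: the mate of a mapping read is
#' always kept).
#'
#' @param reads a `ReadSet`.
#' @param baited_contigs named character vector.
#' @param cfg a [recruitment_config()].
#' @return a filtered `ReadSet`.
#' @export
recruit_reads <- function(reads, baited_contigs, cfg = recruitment_config()) {
  stopifnot(length(baited_contigs) > 0)
  if (length(reads) == 0L) return(reads)
  all_reads <- c(reads$reads1, reads$reads2)
  hits <- map_reads_multi(all_reads, baited_contigs,
                          min_identity = cfg$full_length_identity_min)
  hit_ids <- unique(sub("/[12]$", "", hits$query))
  keep <- reads$meta$id %in% hit_ids
  subset_readset(reads, keep)
}
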