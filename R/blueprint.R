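# Synthetic circular mitochondrial genomes: blueprint types and builder.
#
# The generator emulates the organisation of a large angiosperm mtDNA master
# circle: a long inverted-repeat pair, a short direct-repeat pair,
# plastid-derived insertions, strand-mixed (partly multi-exon) gene models
# and C-to-U editing sites with per-site editing levels.

#' Construct a genome blueprint
#'
#' A blueprint fully determines a synthetic annotated circular genome:
#' identical blueprint and seed give byte-identical output.
#'
#' @param genome_length circle length in bp.
#' @param gene_specs list of gene specifications; each a list with `name`,
#'   `strand` ("+"/"-"), `exons` (two-column matrix of 1-based genomic
#'   intervals in transcription order) and `kind` ("protein","tRNA","rRNA").
#' @param repeat_specs list of repeat pair specifications; each a list with
#'   `kind` ("inverted"/"direct"), `length`, `pos_a`, `pos_b` (1-based start
#'   of each copy), `divergence` (per-base substitution fraction between the
#'   copies) and `label` (e.g. "LIR").
#' @param insertion_specs list of plastid insertion specs; each a list with
#'   `start`, `length` and `source` tag.
#' @param editing_specs data.frame with columns `gene`, `cds_offset`
#'   (1-based position in the spliced CDS) and `level` (percent in (0,100]).
#' @param seed integer RNG seed.
#' @return an object of class `GenomeBlueprint`.
#' @export
genome_blueprint <- function(genome_length, gene_specs = list(),
                             repeat_specs = list(), insertion_specs = list(),
                             editing_specs = NULL, seed = 1L) {
  stopifnot(genome_length > 0)
  if (is.null(editing_specs)) {
    editing_specs <- data.frame(gene = character(0), cds_offset = integer(0),
                                level = numeric(0))
  }
  stopifnot(all(editing_specs$level > 0), all(editing_specs$level <= 100))
  # repeat copies must not overlap one another
  ivs <- list()
  for (rs in repeat_specs) {
    stopifnot(rs$kind %in% c("inverted", "direct"), rs$length > 0)
    ivs[[length(ivs) + 1L]] <- c(rs$pos_a, rs$pos_a + rs$length - 1L)
    ivs[[length(ivs) + 1L]] <- c(rs$pos_b, rs$pos_b + rs$length - 1L)
  }
  if (length(ivs) > 1L) {
    m <- do.call(rbind, ivs)
    o <- order(m[, 1L])
    m <- m[o, , drop = FALSE]
    if (any(m[-1L, 1L] <= m[-nrow(m), 2L])) {
      stop("structural conflict: repeat copies overlap")
    }
    if (any(m[, 2L] > genome_length) && m[o == 1L, 1L] <= (max(m[, 2L]) %% genome_length)) {
      stop("structural conflict: repeat copies overlap across the origin")
    }
  }
  for (gs in gene_specs) {
    stopifnot(gs$strand %in% c("+", "-"),
              gs$kind %in% c("protein", "tRNA", "rRNA"))
  }
  structure(list(genome_length = as.integer(genome_length),
                 gene_specs = gene_specs, repeat_specs = repeat_specs,
                 insertion_specs = insertion_specs,
                 editing_specs = editing_specs, seed = as.integer(seed)),
            class = "GenomeBlueprint")
}

#' Paired/single read layout
#'
#' @param read_length read length in bp.
#' @param insert_mean,insert_sd fragment size distribution (bp); for
#'   single-end layouts these describe nothing and may be 0.
#' @param n_pairs number of pairs (or single reads).
#' @param orientation "inward" (paired-end), "outward" (mate-pair jumping
#'   library) or "single" (RNA).
#' @param error_rate per-base substitution probability in \[0, 0.1\].
#' @return an object of class `ReadLayout`.
#' @export
read_layout <- function(read_length, insert_mean = 0, insert_sd = 0,
                        n_pairs = 0L, orientation = c("inward", "outward", "single"),
                        error_rate = 0) {
  orientation <- match.arg(orientation)
  stopifnot(error_rate >= 0, error_rate <= 0.1, read_length > 0, n_pairs >= 0)
  if (orientation == "inward" && insert_mean < 2 * read_length) {
    stop("inward paired-end layout requires insert_mean >= 2*read_length")
  }
  structure(list(read_length = as.integer(read_length),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 n_pairs = as.integer(n_pairs), orientation = orientation,
                 error_rate = error_rate),
            class = "ReadLayout")
}

# Paper-styled library presets.

#' @rdname read_layout
#' @param n_pairs number of fragments to simulate.
#' @param error_rate per-base substitution probability.
#' @export
pe_layout <- function(n_pairs, error_rate = 0) {
  read_layout(300L, 600, 60, n_pairs, "inward", error_rate)
}

#' @rdname read_layout
#' @export
mp_layout <- function(n_pairs, error_rate = 0) {
  read_layout(100L, 3500, 350, n_pairs, "outward", error_rate)
}

#' @rdname read_layout
#' @export
rna_layout <- function(n_pairs, error_rate = 0) {
  read_layout(200L, 0, 0, n_pairs, "single", error_rate)
}

#' Build an annotated genome from a blueprint
#'
#' Generates the circular sequence, stamps repeat copies (identical up to the
#' stated divergence), plastid-derived insertions and gene models, and forces
#' a transcript-space C at every requested editing position so the editing
#' specification is realisable.  Deterministic for a fixed blueprint.
#'
#' @param blueprint a [genome_blueprint()].
#' @return an `AnnotatedGenome`: list with `seq`, `length`, `features`
#'   (1-based inclusive feature table), `circular`, plus `truth` attributes
#'   (`editing` table with genomic positions, `plastid_donor` sequence).
#' @export
build_genome <- function(blueprint) {
  stopifnot(inherits(blueprint, "GenomeBlueprint"))
  set.seed(blueprint$seed)
  L <- blueprint$genome_length
  seq <- rand_dna(L)
  feats <- list()
  # plastid donor genome: generated alongside so that insertion intervals in
  # the mtDNA are verbatim copies of a (synthetic) chloroplast sequence
  donor <- NULL
  if (length(blueprint$insertion_specs)) {
    donor_len <- max(20000L, sum(vapply(blueprint$insertion_specs,
                                        function(x) x$length, numeric(1))) * 4L)
    donor <- rand_dna(donor_len)
    off <- 1L
    for (ins in blueprint$insertion_specs) {
      frag <- substr(donor, off, off + ins$length - 1L)
      seq <- circ_replace(seq, ins$start, frag)
      feats[[length(feats) + 1L]] <- data.frame(
        type = "plastid_insertion", id = sprintf("mtpt_%d", length(feats) + 1L),
        gene = NA, start = ins$start, end = ins$start + ins$length - 1L,
        strand = "+", kind = "plastid", label = ins$source %||% "cp",
        exon_rank = NA, note = sprintf("donor_offset=%d", off))
      off <- off + ins$length
    }
  }
  # repeats: copy b is stamped from copy a (reverse complement if inverted)
  for (ri in seq_along(blueprint$repeat_specs)) {
    rs <- blueprint$repeat_specs[[ri]]
    copy <- circ_substr(seq, rs$pos_a, rs$length)
    if (rs$kind == "inverted") copy <- revcomp(copy)
    div <- rs$divergence %||% 0
    if (div > 0) {
      nmut <- stats::rbinom(1L, rs$length, div)
      if (nmut > 0) {
        at <- sample.int(rs$length, nmut)
        b <- strsplit(copy, "")[[1]]
        for (p in at) b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1L)
        copy <- paste(b, collapse = "")
      }
    }
    seq <- circ_replace(seq, rs$pos_b, copy)
    lab <- rs$label %||% ifelse(rs$kind == "inverted", "IR", "DR")
    for (cp in c("a", "b")) {
      pos <- if (cp == "a") rs$pos_a else rs$pos_b
      feats[[length(feats) + 1L]] <- data.frame(
        type = "repeat", id = sprintf("%s_%s", lab, cp), gene = NA,
        start = pos, end = pos + rs$length - 1L,
        strand = if (cp == "b" && rs$kind == "inverted") "-" else "+",
        kind = rs$kind, label = lab, exon_rank = NA, note = NA)
    }
  }
  # gene models: force start/stop codons on protein genes
  for (gs in blueprint$gene_specs) {
    exons <- gs$exons
    exlen <- exons[, 2L] - exons[, 1L] + 1L
    cds_len <- sum(exlen)
    if (gs$kind == "protein") {
      stopifnot(cds_len %% 3L == 0L)
      # write ATG at transcript start, TAA at transcript end
      seq <- write_transcript_bases(seq, gs, 1L, "ATG")
      seq <- write_transcript_bases(seq, gs, cds_len - 2L, "TAA")
      # scrub internal in-frame stops so genes translate cleanly
      tx <- transcript_seq(seq, gs)
      cod <- substring(tx, seq(1L, cds_len - 3L, 3L), seq(3L, cds_len, 3L))
      cod <- cod[-length(cod)]
      bad <- which(cod %in% c("TAA", "TAG", "TGA"))
      for (ci in bad) {
        seq <- write_transcript_bases(seq, gs, (ci - 1L) * 3L + 1L, "C")
      }
    }
    feats[[length(feats) + 1L]] <- data.frame(
      type = "gene", id = gs$name, gene = gs$name,
      start = min(exons[, 1L]), end = max(exons[, 2L]), strand = gs$strand,
      kind = gs$kind, label = NA, exon_rank = NA, note = NA)
    for (e in seq_len(nrow(exons))) {
      feats[[length(feats) + 1L]] <- data.frame(
        type = "exon", id = sprintf("%s_exon%d", gs$name, e), gene = gs$name,
        start = exons[e, 1L], end = exons[e, 2L], strand = gs$strand,
        kind = gs$kind, label = NA, exon_rank = e, note = NA)
    }
  }
  feats <- if (length(feats)) as_features(do.call(rbind, feats)) else empty_features()
  genome <- structure(list(seq = seq, length = L, features = feats,
                           circular = TRUE),
                      class = "AnnotatedGenome")
  # editing sites: force a transcript-space C at each requested offset and
  # record genomic truth
  ed <- blueprint$editing_specs
  if (nrow(ed)) {
    gpos <- integer(nrow(ed)); gstrand <- character(nrow(ed))
    for (i in seq_len(nrow(ed))) {
      gs <- gene_spec(blueprint, ed$gene[i])
      if (is.null(gs)) stop("blueprint error: editing spec names unknown gene ", ed$gene[i])
      cds_len <- sum(gs$exons[, 2L] - gs$exons[, 1L] + 1L)
      if (ed$cds_offset[i] < 1L || ed$cds_offset[i] > cds_len) {
        stop("blueprint error: editing offset outside the spliced CDS")
      }
      genome$seq <- write_transcript_bases(genome$seq, gs, ed$cds_offset[i], "C")
      gpos[i] <- transcript_to_genomic(gs, ed$cds_offset[i])
      gstrand[i] <- gs$strand
    }
    ed$genomic_pos <- gpos
    ed$strand <- gstrand
  } else {
    ed$genomic_pos <- integer(0)
    ed$strand <- character(0)
  }
  attr(genome, "truth") <- list(editing = ed, plastid_donor = donor,
                                blueprint = blueprint)
  genome
}

# Spec for one gene by name.
gene_spec <- function(blueprint, name) {
  for (gs in blueprint$gene_specs) if (gs$name == name) return(gs)
  NULL
}

#' Spliced transcript sequence of a gene model
#'
#' Exons are concatenated in transcription order; minus-strand genes are
#' reverse-complemented so the result is always sense-strand.
#'
#' @param seq genome sequence (character).
#' @param gs gene spec (list with `exons`, `strand`).
#' @return character transcript.
#' @export
transcript_seq <- function(seq, gs) {
  ex <- gs$exons
  pieces <- substring(seq, ex[, 1L], ex[, 2L])
  if (gs$strand == "+") {
    paste(pieces, collapse = "")
  } else {
    paste(rev(revcomp(pieces)), collapse = "")
  }
}

# Map a 1-based transcript offset to the genomic position (1-based).
transcript_to_genomic <- function(gs, off) {
  ex <- gs$exons
  exlen <- ex[, 2L] - ex[, 1L] + 1L
  if (gs$strand == "-") {
    # transcription order: exons as listed, read from the last genomic exon
    ord <- rev(seq_len(nrow(ex)))
    cum <- 0L
    for (e in ord) {
      if (off <= cum + exlen[e]) {
        within <- off - cum
        return(ex[e, 2L] - within + 1L)
      }
      cum <- cum + exlen[e]
    }
  } else {
    cum <- 0L
    for (e in seq_len(nrow(ex))) {
      if (off <= cum + exlen[e]) {
        return(ex[e, 1L] + (off - cum) - 1L)
      }
      cum <- cum + exlen[e]
    }
  }
  stop("transcript offset outside exons")
}

# Write bases at a transcript offset back into the genome (strand-aware).
write_transcript_bases <- function(seq, gs, off, bases) {
  for (k in seq_len(nchar(bases))) {
    g <- transcript_to_genomic(gs, off + k - 1L)
    b <- substr(bases, k, k)
    if (gs$strand == "-") b <- revcomp(b)
    substr(seq, g, g) <- b
  }
  seq
}

#' Desk-scale default blueprint
#'
#' A 10x down-scaled analogue of a large plant mtDNA master circle: 100 kbp
#' circle with a 2.5 kbp inverted-repeat pair, a 320 bp direct-repeat pair,
#' about 20 genes on both strands (two of them two-exon), two plastid-derived
#' insertions and a handful of editing sites.
#'
#' @param seed integer seed.
#' @param genome_length circle length (default 100000).
#' @param ir_len,dr_len repeat copy lengths (defaults 2500 and 320).
#' @param n_genes number of genes (default 20).
#' @param editing_levels percent editing levels to spread over the first
#'   genes (one site each); default a spread emulating observed plant
#'   mitochondrial levels.
#' @return a `GenomeBlueprint`.
#' @export
default_blueprint <- function(seed = 1L, genome_length = 100000L,
                              ir_len = 2500L, dr_len = 320L, n_genes = 20L,
                              editing_levels = c(92, 85, 63, 29, 13, 100)) {
  set.seed(seed)
  L <- as.integer(genome_length)
  # fixed structural layout in fractions of the circle
  ira <- as.integer(L * 0.10); irb <- as.integer(L * 0.55)
  dra <- as.integer(L * 0.35); drb <- as.integer(L * 0.80)
  repeat_specs <- list(
    list(kind = "inverted", length = as.integer(ir_len), pos_a = ira,
         pos_b = irb, divergence = 0, label = "LIR"),
    list(kind = "direct", length = as.integer(dr_len), pos_a = dra,
         pos_b = drb, divergence = 0, label = "SDR"))
  ins_len <- max(500L, as.integer(L * 0.015))
  insertion_specs <- list(
    list(start = as.integer(L * 0.25), length = ins_len, source = "cp"),
    list(start = as.integer(L * 0.70), length = as.integer(ins_len / 2L),
         source = "cp"))
  blocked <- rbind(c(ira, ira + ir_len - 1L), c(irb, irb + ir_len - 1L),
                   c(dra, dra + dr_len - 1L), c(drb, drb + dr_len - 1L),
                   c(as.integer(L * 0.25), as.integer(L * 0.25) + ins_len - 1L),
                   c(as.integer(L * 0.70), as.integer(L * 0.70) + ins_len %/% 2L - 1L))
  gene_specs <- list()
  guard <- 0L
  while (length(gene_specs) < n_genes && guard < 10000L) {
    guard <- guard + 1L
    glen <- 3L * sample(100:500, 1L)
    two_exon <- length(gene_specs) < 2L  # first two genes get an intron
    intron <- if (two_exon) sample(200:600, 1L) else 0L
    span <- glen + intron
    st <- sample.int(L - span - 10L, 1L)
    iv <- c(st, st + span - 1L)
    clash <- any(iv[1L] <= blocked[, 2L] & iv[2L] >= blocked[, 1L])
    if (clash) next
    strand <- if (length(gene_specs) %% 2L == 0L) "+" else "-"
    exons <- if (two_exon) {
      e1 <- 3L * (glen %/% 6L)
      rbind(c(st, st + e1 - 1L), c(st + e1 + intron, st + span - 1L))
    } else {
      rbind(iv)
    }
    if (strand == "-" && nrow(exons) > 1L) {
      # exon list is in transcription order: for minus strand that is the
      # genomically-last exon first
      exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
    }
    gene_specs[[length(gene_specs) + 1L]] <- list(
      name = sprintf("g%02d", length(gene_specs) + 1L), strand = strand,
      exons = exons, kind = "protein")
    blocked <- rbind(blocked, iv)
  }
  editing_levels <- editing_levels[seq_len(min(length(editing_levels),
                                               length(gene_specs)))]
  ed <- data.frame(gene = vapply(gene_specs[seq_along(editing_levels)],
                                 `[[`, character(1), "name"),
                   cds_offset = 3L * (10L + seq_along(editing_levels)) + 2L,
                   level = editing_levels)
  genome_blueprint(L, gene_specs, repeat_specs, insertion_specs, ed,
                   seed = seed)
}
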