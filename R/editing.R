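# RNA-seq analyses: mapping filters, RPKM, coverage breadth, C->U editing
# site calling with editing levels, codon-effect annotation and validation
# of published editing tables.

#' RNA mapping / editing configuration
#'
#' @param map_identity_min gene-level similarity fraction floor
#'   (default 0.98).
#' @param map_length_fraction_min minimal aligned fraction of the read
#'   (default 0.90; `strict = TRUE` in [filter_rna_reads()] requires 1.0).
#' @param min_depth minimum C+U depth for a site call (default 5).
#' @param min_level_percent minimum editing level to report (default 10).
#' @return an `EditingConfig` list.
#' @export
editing_config <- function(map_identity_min = 0.98,
                           map_length_fraction_min = 0.90,
                           min_depth = 5L, min_level_percent = 10) {
  stopifnot(map_identity_min > 0, map_identity_min <= 1,
            map_length_fraction_min > 0, map_length_fraction_min <= 1,
            min_depth >= 1)
  structure(list(map_identity_min = map_identity_min,
                 map_length_fraction_min = map_length_fraction_min,
                 min_depth = as.integer(min_depth),
                 min_level_percent = min_level_percent),
            class = "EditingConfig")
}

#' Filter and place RNA reads on the mitochondrial gene models
#'
#' Stage 1 keeps reads with an end-to-end match to the circular genome or to
#' a spliced gene model (reads spanning intron junctions cannot match the
#' genome full-length).  Stage 2 places the survivors on the spliced gene
#' models requiring aligned fraction at least `map_length_fraction_min` and
#' identity at least `map_identity_min`; a read whose best placement beats
#' every alternative is flagged unique.
#'
#' @param reads a single-end RNA `ReadSet` (or named character vector).
#' @param genome an `AnnotatedGenome` with gene/exon features.
#' @param cfg an [editing_config()].
#' @param strict require full-length gene placements (aligned fraction 1.0).
#' @return an `RnaAlignments` list: `tx_hits` (placements on transcripts),
#'   `counts` (unique read count per gene), `gene_lengths`, `total_unique`,
#'   `genome_intervals` (genome-space covered intervals) and stage totals.
#' @export
filter_rna_reads <- function(reads, genome, cfg = editing_config(),
                             strict = FALSE) {
  rd <- if (inherits(reads, "ReadSet")) reads$reads1 else reads
  specs <- genome_gene_specs(genome)
  gene_names <- vapply(specs, `[[`, character(1), "name")
  txs <- stats::setNames(
    vapply(specs, function(gs) transcript_seq(genome$seq, gs), character(1)),
    gene_names)
  # stage 1: end-to-end evidence the read is mitochondrial
  g_hits <- map_reads(rd, genome$seq, circular = TRUE,
                      min_identity = cfg$map_identity_min)
  tx_full <- map_reads_multi(rd, txs, min_identity = cfg$map_identity_min)
  stage1_ids <- union(unique(g_hits$query), unique(tx_full$query))
  rd1 <- rd[names(rd) %in% stage1_ids]
  # stage 2: gene-model placement; full-length first, then the central core
  # (aligned fraction = map_length_fraction_min) for clipped placements
  hits <- map_reads_multi(rd1, txs, min_identity = cfg$map_identity_min)
  hits$frac <- rep(1, nrow(hits))
  hits$offset <- rep(0L, nrow(hits))
  if (!strict && cfg$map_length_fraction_min < 1) {
    unplaced <- rd1[!names(rd1) %in% hits$query]
    if (length(unplaced)) {
      trim <- floor(nchar(unplaced) * (1 - cfg$map_length_fraction_min) / 2)
      core <- substring(unplaced, trim + 1L, nchar(unplaced) - trim)
      names(core) <- names(unplaced)
      h2 <- map_reads_multi(core, txs, min_identity = cfg$map_identity_min)
      if (nrow(h2)) {
        h2$frac <- h2$len / nchar(unplaced)[h2$query]
        h2$offset <- trim[h2$query]
        hits <- rbind(hits, h2)
      }
    }
  }
  hits <- best_hits(hits)
  names(hits)[names(hits) == "subject"] <- "gene"
  uniq <- hits[hits$unique, , drop = FALSE]
  counts <- table(factor(uniq$gene, levels = gene_names))
  counts <- stats::setNames(as.integer(counts), gene_names)
  # genome-space projection of transcript placements for coverage breadth
  g_iv <- project_tx_intervals(uniq, specs)
  if (nrow(g_hits)) {
    gh <- g_hits[!duplicated(g_hits$query), , drop = FALSE]
    g_iv <- rbind(g_iv, data.frame(start = gh$pos,
                                   end = gh$pos + gh$len - 1L))
  }
  structure(list(tx_hits = hits, counts = counts,
                 gene_lengths = stats::setNames(nchar(txs), gene_names),
                 total_unique = sum(counts),
                 genome_intervals = g_iv,
                 n_input = length(rd), n_stage1 = length(rd1),
                 n_stage2 = length(unique(hits$query))),
            class = "RnaAlignments")
}

# Project transcript-space placements to genome-space covered intervals.
project_tx_intervals <- function(hits, specs) {
  out <- list()
  spec_names <- vapply(specs, `[[`, character(1), "name")
  for (i in seq_len(nrow(hits))) {
    gs <- specs[[match(hits$gene[i], spec_names)]]
    p1 <- hits$pos[i]; p2 <- hits$pos[i] + hits$len[i] - 1L
    gpos <- vapply(c(p1, p2), function(o) transcript_to_genomic(gs, o), integer(1))
    ex <- gs$exons
    for (e in seq_len(nrow(ex))) {
      lo <- max(ex[e, 1L], min(gpos))
      hi <- min(ex[e, 2L], max(gpos))
      if (lo <= hi) out[[length(out) + 1L]] <- c(lo, hi)
    }
  }
  if (!length(out)) return(data.frame(start = integer(0), end = integer(0)))
  m <- do.call(rbind, out)
  data.frame(start = m[, 1L], end = m[, 2L])
}

#' RPKM normalisation
#'
#' Reads Per Kilobase of feature per Million mapped reads:
#' `counts * 1e9 / (total * length)`; only unique mappings should be
#' counted.
#'
#' @param gene_length feature length in bp (vectorised).
#' @param unique_counts unique-mapping read counts (vectorised).
#' @param total_unique_mapped total unique mapped reads in the library.
#' @return numeric RPKM values.
#' @export
rpkm <- function(gene_length, unique_counts, total_unique_mapped) {
  if (any(total_unique_mapped <= 0)) stop("undefined input: zero total mapped reads")
  if (any(gene_length <= 0)) stop("undefined input: non-positive gene length")
  unique_counts * 1e9 / (total_unique_mapped * gene_length)
}

#' Genome coverage breadth of the RNA alignments
#'
#' @param genome an `AnnotatedGenome` (or genome length).
#' @param aln an `RnaAlignments` object from [filter_rna_reads()].
#' @return list: covered_bp, fraction, mean_depth.
#' @export
coverage_breadth <- function(genome, aln) {
  L <- if (inherits(genome, "AnnotatedGenome")) genome$length else as.integer(genome)
  iv <- aln$genome_intervals
  if (!nrow(iv)) return(list(covered_bp = 0L, fraction = 0, mean_depth = 0))
  iv$end <- pmin(iv$end, L)
  d <- depth_vector(iv$start, iv$end - iv$start + 1L, L, circular = FALSE)
  list(covered_bp = sum(d >= 1L), fraction = sum(d >= 1L) / L,
       mean_depth = mean(d))
}

# Per-gene transcript pileup: 4 x L count matrices from unique placements.
pileup_transcripts <- function(aln, reads, genome) {
  rd <- if (inherits(reads, "ReadSet")) reads$reads1 else reads
  specs <- genome_gene_specs(genome)
  spec_names <- vapply(specs, `[[`, character(1), "name")
  uniq <- aln$tx_hits[aln$tx_hits$unique, , drop = FALSE]
  out <- list()
  for (g in unique(uniq$gene)) {
    gs <- specs[[match(g, spec_names)]]
    tl <- sum(gs$exons[, 2L] - gs$exons[, 1L] + 1L)
    mat <- matrix(0L, nrow = 4L, ncol = tl,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
    h <- uniq[uniq$gene == g, , drop = FALSE]
    for (i in seq_len(nrow(h))) {
      q <- rd[[h$query[i]]]
      off <- h$offset[i] %||% 0L
      core <- substr(q, off + 1L, off + h$len[i])
      if (h$strand[i] == "-") core <- revcomp(core)
      b <- strsplit(core, "")[[1]]
      cols <- h$pos[i]:(h$pos[i] + h$len[i] - 1L)
      ok <- b %in% rownames(mat) & cols <= tl
      idx <- cbind(match(b[ok], rownames(mat)), cols[ok])
      for (r in seq_len(nrow(idx))) {
        mat[idx[r, 1L], idx[r, 2L]] <- mat[idx[r, 1L], idx[r, 2L]] + 1L
      }
    }
    out[[g]] <- mat
  }
  out
}

# Translate a DNA/RNA codon to one-letter amino acid ("Stop" for *).
codon_aa <- function(codon) {
  dna <- gsub("U", "T", toupper(codon))
  aa <- Biostrings::GENETIC_CODE[[dna]]
  if (is.null(aa)) stop("malformed codon: ", codon)
  if (aa == "*") "Stop" else aa
}

#' Annotate a single C->U edit in a codon
#'
#' Pure function: replaces the C at `codon_position` with U, translates
#' both codons with the standard genetic code and classifies the effect.
#'
#' @param codon_before three-letter codon (DNA or RNA alphabet); the base at
#'   `codon_position` must be C.
#' @param codon_position 1, 2 or 3.
#' @return list: codon_after (RNA alphabet), aa_before, aa_after, effect
#'   ("synonymous", "missense" or "stop_gain").
#' @export
annotate_edit <- function(codon_before, codon_position) {
  cod <- gsub("T", "U", toupper(codon_before))
  stopifnot(nchar(cod) == 3L, codon_position %in% 1:3)
  if (substr(cod, codon_position, codon_position) != "C") {
    stop("contract violation: base at codon_position is not C")
  }
  after <- cod
  substr(after, codon_position, codon_position) <- "U"
  aa_b <- codon_aa(cod)
  aa_a <- codon_aa(after)
  effect <- if (aa_a == "Stop") "stop_gain" else
    if (aa_a == aa_b) "synonymous" else "missense"
  list(codon_after = after, aa_before = aa_b, aa_after = aa_a,
       effect = effect)
}

#' Call C->U editing sites from transcript pileups
#'
#' For every CDS position whose transcript-space reference base is C, the
#' editing level is `100 * U / (U + C)` over the filtered reads; a site is
#' reported when the C+U depth reaches `min_depth` and the level reaches
#' `min_level_percent`.  Positions are reported 1-based on the genome;
#' minus-strand genes correspond to genomic G->A evidence.
#'
#' @param pileups per-gene pileup matrices from `pileup_transcripts`
#'   (computed internally when `reads` is given).
#' @param genome an `AnnotatedGenome`.
#' @param cfg an [editing_config()].
#' @param aln,reads alternative input: an `RnaAlignments` plus the reads,
#'   from which pileups are computed.
#' @return data.frame of `EditingSite` records: gene, genomic_pos, strand,
#'   exon, cds_offset, codon_before, codon_after, codon_position, aa_before,
#'   aa_after, effect, editing_level, depth.
#' @export
call_editing_sites <- function(pileups = NULL, genome, cfg = editing_config(),
                               aln = NULL, reads = NULL) {
  if (is.null(pileups)) {
    stopifnot(!is.null(aln), !is.null(reads))
    pileups <- pileup_transcripts(aln, reads, genome)
  }
  specs <- genome_gene_specs(genome)
  spec_names <- vapply(specs, `[[`, character(1), "name")
  rows <- list()
  for (g in names(pileups)) {
    gs <- specs[[match(g, spec_names)]]
    if (is.null(gs) || gs$kind != "protein") next
    tx <- transcript_seq(genome$seq, gs)
    mat <- pileups[[g]]
    cpos <- which(strsplit(tx, "")[[1]] == "C")
    n_ex <- nrow(gs$exons)
    for (p in cpos) {
      if (p > ncol(mat)) next
      u <- mat["T", p]; cc <- mat["C", p]
      dep <- u + cc
      if (dep < cfg$min_depth) next
      level <- 100 * u / dep
      if (level < cfg$min_level_percent) next
      cod_i <- (p - 1L) %/% 3L
      cod_pos <- (p - 1L) %% 3L + 1L
      cod <- substr(tx, cod_i * 3L + 1L, cod_i * 3L + 3L)
      ann <- annotate_edit(cod, cod_pos)
      gpos <- transcript_to_genomic(gs, p)
      exon <- if (n_ex > 1L) {
        e <- which(gs$exons[, 1L] <= gpos & gs$exons[, 2L] >= gpos)
        sprintf("exon %d", e[1])
      } else NA_character_
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, genomic_pos = gpos, strand = gs$strand, exon = exon,
        cds_offset = p, codon_before = gsub("T", "U", cod),
        codon_after = ann$codon_after, codon_position = cod_pos,
        aa_before = ann$aa_before, aa_after = ann$aa_after,
        effect = ann$effect, editing_level = level, depth = dep,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(gene = character(0), genomic_pos = integer(0),
                      strand = character(0), exon = character(0),
                      cds_offset = integer(0), codon_before = character(0),
                      codon_after = character(0), codon_position = integer(0),
                      aa_before = character(0), aa_after = character(0),
                      effect = character(0), editing_level = numeric(0),
                      depth = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate and recover a single stop-gain editing site
#'
#' Calibration harness: builds a minimal circular genome carrying one
#' minus-strand CDS whose 40th codon is CGA, simulates `n_reads` single-end
#' reads that all cover that codon's C with the given ground-truth editing
#' level (a CGA->UGA stop-gain in transcript space, G->A on the genome),
#' runs the full filter/pileup/call path and returns the recovered site.
#'
#' @param level ground-truth editing level in percent.
#' @param n_reads number of covering reads to simulate.
#' @param seed integer seed.
#' @param read_length read length (default 200).
#' @return list: `site` (the called row at the simulated position), `sites`
#'   (all calls), `truth` (gene, cds_offset, genomic position, level),
#'   `genome`.
#' @export
simulate_stopgain_site <- function(level, n_reads, seed, read_length = 200L) {
  set.seed(seed)
  code <- Biostrings::GENETIC_CODE
  safe <- setdiff(names(code)[code != "*"], "ATG")
  cods <- sample(safe, 78L, replace = TRUE)
  cods[39L] <- "CGA"                     # codon 40 of the CDS
  gene <- paste0("ATG", paste(cods, collapse = ""), "TAA")  # 240 bp
  cds_offset <- 39L * 3L + 1L            # the C of codon 40
  left <- rand_dna(1000L)
  right <- rand_dna(1000L)
  seq <- paste0(left, revcomp(gene), right)
  feats <- as_features(data.frame(
    type = c("gene", "exon"), id = c("rps3like", "rps3like_exon1"),
    gene = "rps3like", start = 1001L, end = 1240L, strand = "-",
    kind = "protein", label = NA, exon_rank = c(NA, 1L), note = NA))
  genome <- structure(list(seq = seq, length = nchar(seq), features = feats,
                           circular = TRUE), class = "AnnotatedGenome")
  editing <- data.frame(gene = "rps3like", cds_offset = cds_offset,
                        level = level)
  layout <- read_layout(read_length, n_pairs = n_reads,
                        orientation = "single", error_rate = 0)
  reads <- simulate_rna_reads(genome, c(rps3like = 1), layout,
                              seed = seed + 1L, editing = editing)
  aln <- filter_rna_reads(reads, genome)
  sites <- call_editing_sites(genome = genome, aln = aln, reads = reads)
  gpos <- 1000L + (240L - cds_offset) + 1L   # minus-strand projection
  list(site = sites[sites$cds_offset == cds_offset, , drop = FALSE],
       sites = sites,
       truth = list(gene = "rps3like", cds_offset = cds_offset,
                    genomic_pos = gpos, level = level),
       genome = genome)
}

#' Read a published editing-site table
#'
#' Loads a TSV with columns gene, label_sites, position, strand, exon,
#' codon_from, codon_to, codon_position, aa_from, aa_to, level (the layout
#' of published plant mitochondrial editing tables).  The packaged
#' transcription of the source study's table is available via
#' `system.file("extdata", "table5_editing_sites.tsv", package = "mitocircle")`.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_editing_table <- function(path) {
  df <- read_tsv(path)
  need <- c("gene", "position", "strand", "codon_from", "codon_to",
            "codon_position", "aa_from", "aa_to", "level")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("editing table lacks columns: ",
                            paste(missing, collapse = ", "))
  df
}

#' Validate editing-table rows by codon arithmetic
#'
#' A row is consistent when its "to" codon is the single C->U substitution
#' at the stated codon position of the "from" codon and both printed amino
#' acids match the standard-genetic-code translations.
#'
#' @param rows data.frame as returned by [read_editing_table()].
#' @return list: `verdicts` (per-row data.frame with `consistent` and
#'   `reason`), `per_gene` (site counts), `n_total`, `n_inconsistent`.
#' @export
validate_editing_table <- function(rows) {
  n <- nrow(rows)
  consistent <- logical(n); reason <- character(n)
  for (i in seq_len(n)) {
    cf <- gsub("T", "U", toupper(rows$codon_from[i]))
    ct <- gsub("T", "U", toupper(rows$codon_to[i]))
    cp <- as.integer(rows$codon_position[i])
    if (is.na(cp) || !grepl("^[ACGU]{3}$", cf) || !grepl("^[ACGU]{3}$", ct)) {
      stop(sprintf("malformed codon strings in row %d (%s %s)", i,
                   rows$gene[i], rows$position[i]))
    }
    expect <- cf
    ok_target <- substr(cf, cp, cp) == "C"
    if (ok_target) substr(expect, cp, cp) <- "U"
    if (!ok_target || expect != ct) {
      consistent[i] <- FALSE
      reason[i] <- "not a single C->U substitution at the stated position"
      next
    }
    aa_b <- codon_aa(cf); aa_a <- codon_aa(ct)
    pf <- toupper(trimws(rows$aa_from[i])); pt <- toupper(trimws(rows$aa_to[i]))
    if (toupper(aa_b) != pf) {
      consistent[i] <- FALSE
      reason[i] <- sprintf("aa_before mismatch: %s translates to %s, printed %s",
                           cf, aa_b, rows$aa_from[i])
      next
    }
    if (toupper(aa_a) != pt) {
      consistent[i] <- FALSE
      reason[i] <- sprintf("aa_after mismatch: %s translates to %s, printed %s",
                           ct, aa_a, rows$aa_to[i])
      next
    }
    consistent[i] <- TRUE
    reason[i] <- ""
  }
  verdicts <- data.frame(gene = rows$gene, position = rows$position,
                         consistent = consistent, reason = reason,
                         stringsAsFactors = FALSE)
  per_gene <- table(rows$gene)
  list(verdicts = verdicts,
       per_gene = stats::setNames(as.integer(per_gene), names(per_gene)),
       n_total = n, n_inconsistent = sum(!consistent))
}
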