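# Read simulation with machine-readable truth.  Read identifiers are plain
# tags; per-read truth (origin, position, strand, fragment size, source) is
# carried in the ReadSet metadata table and can be exported as a TSV, so the
# downstream recruitment/assembly oracles never need the simulator state.

new_readset <- function(reads1, reads2, meta, layout) {
  structure(list(reads1 = reads1, reads2 = reads2, meta = meta,
                 layout = layout, paired = !is.null(reads2)),
            class = "ReadSet")
}

#' @export
length.ReadSet <- function(x) length(x$reads1)

#' @export
print.ReadSet <- function(x, ...) {
  cat(sprintf("ReadSet: %d %s reads of %d bp (%s)\n", length(x),
              if (x$paired) "paired" else "single", x$layout$read_length,
              x$layout$orientation))
  invisible(x)
}

# Apply iid substitution errors at `rate` to a character vector of reads.
apply_errors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0L) return(reads)
  nuc <- c("A", "C", "G", "T")
  for (i in seq_along(reads)) {
    n <- nchar(reads[i])
    nerr <- stats::rbinom(1L, n, rate)
    if (nerr == 0L) next
    at <- sample.int(n, nerr)
    b <- strsplit(reads[i], "")[[1]]
    for (p in at) b[p] <- sample(setdiff(nuc, b[p]), 1L)
    reads[i] <- paste(b, collapse = "")
  }
  reads
}

#' Simulate paired DNA reads from a circular genome
#'
#' Fragments are drawn uniformly on the circle (wrapping allowed), from
#' either strand, with normally distributed insert sizes.  "inward" produces
#' forward/reverse pairs (paired-end libraries); "outward" produces
#' reverse/forward pairs (jumping mate-pair libraries).
#'
#' @param genome an `AnnotatedGenome` (or plain character sequence).
#' @param layout a [read_layout()].
#' @param seed integer seed.
#' @return a `ReadSet`; `meta` records true fragment position, strand,
#'   fragment length and `source` ("mt").
#' @export
simulate_dna_reads <- function(genome, layout, seed = 1L) {
  seq <- if (inherits(genome, "AnnotatedGenome")) genome$seq else genome
  stopifnot(nchar(seq) > 0)
  L <- nchar(seq)
  if (layout$insert_mean > L) stop("layout error: insert_mean exceeds genome length")
  set.seed(seed)
  n <- layout$n_pairs
  rl <- layout$read_length
  if (n == 0L) {
    return(new_readset(character(0), character(0),
                       data.frame(id = character(0)), layout))
  }
  # fragments shorter than twice the read length give overlapping mates
  # (normal for short-insert libraries); the hard floor is one read length
  flen <- pmax(rl, as.integer(round(
    stats::rnorm(n, layout$insert_mean, layout$insert_sd))))
  flen <- pmin(flen, L)
  fpos <- sample.int(L, n, replace = TRUE)
  fstrand <- sample(c("+", "-"), n, replace = TRUE)
  r1 <- character(n); r2 <- character(n)
  for (i in seq_len(n)) {
    frag <- circ_substr(seq, fpos[i], flen[i])
    if (fstrand[i] == "-") frag <- revcomp(frag)
    a <- substr(frag, 1L, rl)
    b <- revcomp(substr(frag, flen[i] - rl + 1L, flen[i]))
    if (layout$orientation == "outward") {
      a <- revcomp(a)
      b <- revcomp(b)
    }
    r1[i] <- a; r2[i] <- b
  }
  r1 <- apply_errors(r1, layout$error_rate)
  r2 <- apply_errors(r2, layout$error_rate)
  ids <- sprintf("%s_%06d", ifelse(layout$orientation == "inward", "pe", "mp"),
                 seq_len(n))
  names(r1) <- paste0(ids, "/1"); names(r2) <- paste0(ids, "/2")
  meta <- data.frame(id = ids, frag_pos = fpos, frag_strand = fstrand,
                     frag_len = flen, source = "mt",
                     stringsAsFactors = FALSE)
  new_readset(r1, r2, meta, layout)
}

#' Simulate single-end RNA reads from spliced transcripts
#'
#' Reads are drawn from gene transcripts proportional to
#' `abundance x transcript length`.  Each read covering an editing site
#' independently carries the edited base (transcript-space C -> U, written as
#' T in the read) with probability `level/100`; for minus-strand genes the
#' genome-projected change is G -> A.
#'
#' @param genome an `AnnotatedGenome` built by [build_genome()].
#' @param expression named non-negative numeric vector of per-gene relative
#'   abundances (genes absent from the vector get 0).
#' @param layout a [read_layout()] with orientation "single".
#' @param seed integer seed.
#' @param editing editing truth table (`gene`, `cds_offset`, `level`);
#'   defaults to the genome's own truth.
#' @return a `ReadSet` (single-end); `meta` records gene, transcript start
#'   and the number of edited positions per read.
#' @export
simulate_rna_reads <- function(genome, expression, layout, seed = 1L,
                               editing = NULL) {
  stopifnot(inherits(genome, "AnnotatedGenome"))
  truth <- attr(genome, "truth")
  if (is.null(editing)) editing <- truth$editing %||%
      data.frame(gene = character(0), cds_offset = integer(0), level = numeric(0))
  stopifnot(all(expression >= 0), all(editing$level > 0),
            all(editing$level <= 100))
  bp <- truth$blueprint
  specs <- if (!is.null(bp)) bp$gene_specs else genome_gene_specs(genome)
  spec_names <- vapply(specs, `[[`, character(1), "name")
  # editing sites must fall inside exons of the named gene
  for (i in seq_len(nrow(editing))) {
    gs <- specs[[match(editing$gene[i], spec_names)]]
    if (is.null(gs)) stop("blueprint error: editing site names unknown gene")
    cds_len <- sum(gs$exons[, 2L] - gs$exons[, 1L] + 1L)
    if (editing$cds_offset[i] > cds_len) {
      stop("blueprint error: editing site outside any exon")
    }
    base <- substr(transcript_seq(genome$seq, gs), editing$cds_offset[i],
                   editing$cds_offset[i])
    if (base != "C") stop("blueprint error: editing site targets a non-C transcript base")
  }
  set.seed(seed)
  rl <- layout$read_length
  n <- layout$n_pairs
  genes <- spec_names[spec_names %in% names(expression)[expression > 0]]
  if (n == 0L || length(genes) == 0L) {
    return(new_readset(character(0), NULL, data.frame(id = character(0)), layout))
  }
  txs <- lapply(specs[match(genes, spec_names)],
                function(gs) transcript_seq(genome$seq, gs))
  names(txs) <- genes
  txlen <- vapply(txs, nchar, integer(1))
  w <- expression[genes] * txlen
  pick <- sample(genes, n, replace = TRUE, prob = w / sum(w))
  reads <- character(n); starts <- integer(n); nedit <- integer(n)
  for (i in seq_len(n)) {
    g <- pick[i]
    tl <- txlen[[g]]
    len <- min(rl, tl)
    st <- if (tl > len) sample.int(tl - len + 1L, 1L) else 1L
    rd <- substr(txs[[g]], st, st + len - 1L)
    sites <- editing[editing$gene == g, , drop = FALSE]
    ne <- 0L
    for (k in seq_len(nrow(sites))) {
      off <- sites$cds_offset[k]
      if (off >= st && off <= st + len - 1L &&
          stats::runif(1L) < sites$level[k] / 100) {
        substr(rd, off - st + 1L, off - st + 1L) <- "T"
        ne <- ne + 1L
      }
    }
    reads[i] <- rd; starts[i] <- st; nedit[i] <- ne
  }
  reads <- apply_errors(reads, layout$error_rate)
  ids <- sprintf("rna_%06d", seq_len(n))
  names(reads) <- ids
  meta <- data.frame(id = ids, gene = pick, tx_start = starts,
                     n_edited = nedit, source = "mt", stringsAsFactors = FALSE)
  new_readset(reads, NULL, meta, layout)
}

# Recover gene specs from an AnnotatedGenome's feature table (exon rows).
genome_gene_specs <- function(genome) {
  f <- genome$features
  ex <- f[f$type == "exon", , drop = FALSE]
  gn <- f[f$type == "gene", , drop = FALSE]
  lapply(seq_len(nrow(gn)), function(i) {
    g <- gn$gene[i]
    e <- ex[ex$gene == g, , drop = FALSE]
    e <- e[order(e$exon_rank), , drop = FALSE]
    list(name = g, strand = gn$strand[i],
         exons = cbind(e$start, e$end), kind = gn$kind[i])
  })
}

#' Spike foreign-genome reads into a read set
#'
#' Replaces a fraction of the pairs (or single reads) with reads simulated
#' from a foreign genome (e.g. the chloroplast), flagged `source = "foreign"`
#' in the metadata so downstream filters can be scored.
#'
#' @param reads a `ReadSet`.
#' @param foreign_genome character sequence of the contaminant.
#' @param fraction fraction in \[0,1) of reads to replace.
#' @param seed integer seed.
#' @return a `ReadSet` of the same size.
#' @export
spike_foreign_reads <- function(reads, foreign_genome, fraction, seed = 1L) {
  stopifnot(fraction >= 0, fraction < 1)
  if (fraction == 0) return(reads)
  if (nchar(foreign_genome) == 0L) {
    stop("empty foreign genome with positive spike fraction")
  }
  n <- length(reads)
  k <- as.integer(round(n * fraction))
  if (k == 0L) return(reads)
  layout <- reads$layout
  fl <- layout
  fl$n_pairs <- k
  set.seed(seed)
  idx <- sample.int(n, k)
  sub <- if (layout$orientation == "single") {
    # draw single reads from the foreign sequence
    L <- nchar(foreign_genome)
    rl <- layout$read_length
    st <- sample.int(L, k, replace = TRUE)
    strand <- sample(c("+", "-"), k, replace = TRUE)
    rd <- vapply(seq_len(k), function(i) {
      x <- circ_substr(foreign_genome, st[i], rl)
      if (strand[i] == "-") revcomp(x) else x
    }, character(1))
    list(r1 = apply_errors(rd, layout$error_rate), r2 = NULL)
  } else {
    fs <- simulate_dna_reads(foreign_genome, fl, seed = derive_seeds(1L))
    list(r1 = unname(fs$reads1), r2 = unname(fs$reads2))
  }
  reads$reads1[idx] <- sub$r1
  if (reads$paired) reads$reads2[idx] <- sub$r2
  reads$meta$source[idx] <- "foreign"
  reads
}

#' Shred a circular genome into overlapping contigs
#'
#' Cuts the circle at `n` breakpoints and extends each piece by `overlap`
#' bp into its clockwise neighbour, producing the contig set a finishing
#' run starts from.
#'
#' @param genome `AnnotatedGenome` or character sequence.
#' @param n number of contigs.
#' @param overlap terminal overlap in bp.
#' @param seed integer seed; breakpoints are random but never closer than
#'   `2*overlap`.
#' @param avoid optional two-column matrix of intervals (e.g. repeat copies)
#'   that breakpoints must avoid.
#' @return named character vector of contigs (some reverse-complemented at
#'   random to exercise strand handling).
#' @export
shred_contigs <- function(genome, n = 7L, overlap = 120L, seed = 1L,
                          avoid = NULL) {
  seq <- if (inherits(genome, "AnnotatedGenome")) genome$seq else genome
  L <- nchar(seq)
  set.seed(seed)
  ok <- function(b) {
    if (is.null(avoid) || nrow(avoid) == 0L) return(TRUE)
    !any(b >= avoid[, 1L] - overlap & b <= avoid[, 2L] + overlap)
  }
  bps <- integer(0)
  guard <- 0L
  while (length(bps) < n && guard < 20000L) {
    guard <- guard + 1L
    b <- sample.int(L, 1L)
    if (!ok(b)) next
    if (length(bps) && min(pmin(abs(b - bps), L - abs(b - bps))) < 2L * overlap) next
    bps <- c(bps, b)
  }
  if (length(bps) < n) stop("could not place breakpoints")
  bps <- sort(bps)
  out <- character(n)
  for (i in seq_len(n)) {
    st <- bps[i]
    nx <- if (i < n) bps[i + 1L] else bps[1L] + L
    out[i] <- circ_substr(seq, st, nx - st + overlap)
  }
  flip <- sample(c(TRUE, FALSE), n, replace = TRUE)
  out[flip] <- revcomp(out[flip])
  names(out) <- sprintf("ctg%02d", seq_len(n))
  out
}

#' Shred a repeat-bearing circle into unique arcs plus collapsed repeats
#'
#' Emulates the output of a short-read assembler on a genome with long
#' repeats: each repeat family collapses into a single contig, and the
#' unique arcs between repeat copies become separate contigs carrying
#' `overlap` bp of the flanking repeat ends (so overlap joins anchor each
#' arc to the repeat contig).
#'
#' @param genome an `AnnotatedGenome` with `repeat` features.
#' @param overlap bp of repeat sequence retained on arc ends (default 150).
#' @return list with `contigs` (named character vector), `copy_number`
#'   (named integer, 2 for repeat contigs) and `truth` layout table.
#' @export
shred_at_repeats <- function(genome, overlap = 150L) {
  stopifnot(inherits(genome, "AnnotatedGenome"))
  f <- genome$features
  reps <- f[f$type == "repeat", , drop = FALSE]
  stopifnot(nrow(reps) >= 2L)
  L <- genome$length
  reps <- reps[order(reps$start), , drop = FALSE]
  contigs <- character(0); copy_number <- integer(0)
  # one collapsed contig per repeat family, forward-strand copy "a"
  for (lab in unique(reps$label)) {
    a <- reps[reps$label == lab & grepl("_a$", reps$id), , drop = FALSE]
    contigs[lab] <- substr(genome$seq, a$start, a$end)
    copy_number[lab] <- 2L
  }
  # unique arcs between consecutive repeat copies, padded into the repeats
  n <- nrow(reps)
  for (i in seq_len(n)) {
    from <- reps$end[i] - overlap + 1L
    to_i <- if (i < n) i + 1L else 1L
    to <- reps$start[to_i] + overlap - 1L
    len <- (to - from) %% L + 1L
    arc <- circ_substr(genome$seq, from, len)
    nm <- sprintf("arc%02d", i)
    contigs[nm] <- arc
    copy_number[nm] <- 1L
  }
  list(contigs = contigs, copy_number = copy_number,
       repeats = reps)
}

#' Export simulation truth files
#'
#' Writes the genome FASTA, feature GFF3, reads FASTQ and truth TSV tables
#' so that a run is fully reproducible from disk.
#'
#' @param genome an `AnnotatedGenome`.
#' @param readsets named list of `ReadSet`s.
#' @param outdir output directory (created).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(genome, readsets, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(c(genome = genome$seq), file.path(outdir, "genome.fasta"))
  write_gff3(genome$features, file.path(outdir, "features.gff3"),
             genome_length = genome$length)
  truth <- attr(genome, "truth")
  if (!is.null(truth$editing) && nrow(truth$editing)) {
    write_tsv(truth$editing, file.path(outdir, "editing_truth.tsv"))
  }
  if (!is.null(truth$plastid_donor)) {
    write_fasta(c(plastid = truth$plastid_donor),
                file.path(outdir, "plastid.fasta"))
  }
  for (nm in names(readsets)) {
    rs <- readsets[[nm]]
    write_fastq(rs$reads1, file.path(outdir, paste0(nm, "_1.fastq")))
    if (rs$paired) {
      write_fastq(rs$reads2, file.path(outdir, paste0(nm, "_2.fastq")))
    }
    write_tsv(rs$meta, file.path(outdir, paste0(nm, "_truth.tsv")))
  }
  invisible(outdir)
}
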