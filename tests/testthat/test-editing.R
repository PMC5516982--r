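test_that("RPKM arithmetic, edge cases and scale invariance", {
  expect_equal(rpkm(1000, 10, 1e6), 10)
  expect_equal(rpkm(1000, 0, 1e6), 0)
  expect_error(rpkm(1000, 10, 0), "zero total")
  expect_error(rpkm(0, 10, 100), "gene length")
  a <- rpkm(c(500, 2000), c(10, 40), 1e5)
  b <- rpkm(c(500, 2000), c(20, 80), 2e5)
  expect_equal(a[1] / a[2], b[1] / b[2])
})

test_that("codon annotation matches the standard genetic code for every C position", {
  # the published worked examples
  a <- annotate_edit("CCA", 2)
  expect_equal(unlist(a), c(codon_after = "CUA", aa_before = "P",
                            aa_after = "L", effect = "missense"))
  b <- annotate_edit("CGA", 1)
  expect_equal(b$aa_after, "Stop")
  expect_equal(b$effect, "stop_gain")
  d <- annotate_edit("GCC", 3)
  expect_equal(d$codon_after, "GCU")
  expect_equal(d$effect, "synonymous")
  # exhaustive: all codon/position combinations with a C at the position
  nucs <- c("A", "C", "G", "U")
  combos <- 0L
  for (n1 in nucs) for (n2 in nucs) for (n3 in nucs) {
    cod <- paste0(n1, n2, n3)
    for (p in 1:3) {
      if (substr(cod, p, p) != "C") {
        expect_error(annotate_edit(cod, p), "contract violation")
        next
      }
      combos <- combos + 1L
      out <- annotate_edit(cod, p)
      dna_b <- gsub("U", "T", cod)
      dna_a <- gsub("U", "T", out$codon_after)
      want_b <- Biostrings::GENETIC_CODE[[dna_b]]
      want_a <- Biostrings::GENETIC_CODE[[dna_a]]
      expect_equal(out$aa_before, if (want_b == "*") "Stop" else want_b)
      expect_equal(out$aa_after, if (want_a == "*") "Stop" else want_a)
      expect_equal(out$effect,
                   if (want_a == "*") "stop_gain"
                   else if (want_a == want_b) "synonymous" else "missense")
    }
  }
  expect_equal(combos, 48L)
})

test_that("RNA read filtering applies the two-stage identity/length rules", {
  g <- tiny_genome(17, L = 15000L, genes = 5L)
  specs <- attr(g, "truth")$blueprint$gene_specs
  gs <- specs[[1]]
  tx <- transcript_seq(g$seq, gs)
  clean <- substr(tx, 10, 209)
  noisy <- clean
  # 5% mismatches: fails the 98% similarity floor
  at <- seq(5, 200, by = 20)
  for (p in at) substr(noisy, p, p) <- chartr("ACGT", "GTAC", substr(noisy, p, p))
  rs <- c(clean = clean, noisy = noisy)
  aln <- filter_rna_reads(rs, g)
  expect_true("clean" %in% aln$tx_hits$query)
  expect_false("noisy" %in% aln$tx_hits$query)
  hit <- aln$tx_hits[aln$tx_hits$query == "clean", ]
  expect_equal(hit$gene, gs$name)
  expect_true(hit$unique)
})

test_that("reads from a duplicated gene copy are flagged non-unique", {
  # two identical gene copies on a synthetic circle
  set.seed(71)
  gene_seq <- paste0("ATG", random_dna(597))
  backbone <- random_dna(6000)
  seq <- paste0(backbone, gene_seq, random_dna(1000), gene_seq, random_dna(800))
  feats <- rbind(
    data.frame(type = "gene", id = "dupA", gene = "dupA", start = 6001L,
               end = 6600L, strand = "+", kind = "protein", label = NA,
               exon_rank = NA, note = NA),
    data.frame(type = "exon", id = "dupA_exon1", gene = "dupA", start = 6001L,
               end = 6600L, strand = "+", kind = "protein", label = NA,
               exon_rank = 1L, note = NA),
    data.frame(type = "gene", id = "dupB", gene = "dupB", start = 7601L,
               end = 8200L, strand = "+", kind = "protein", label = NA,
               exon_rank = NA, note = NA),
    data.frame(type = "exon", id = "dupB_exon1", gene = "dupB", start = 7601L,
               end = 8200L, strand = "+", kind = "protein", label = NA,
               exon_rank = 1L, note = NA))
  genome <- structure(list(seq = seq, length = nchar(seq),
                           features = mitocircle:::as_features(feats),
                           circular = TRUE), class = "AnnotatedGenome")
  rd <- c(r1 = substr(gene_seq, 100, 299))
  aln <- filter_rna_reads(rd, genome)
  h <- aln$tx_hits[aln$tx_hits$query == "r1", ]
  expect_gte(nrow(h), 2L)
  expect_false(any(h$unique))
})

test_that("coverage breadth reflects the covered fraction", {
  g <- tiny_genome(18, L = 10000L, genes = 4L)
  aln0 <- filter_rna_reads(character(0), g)
  cb0 <- coverage_breadth(g, aln0)
  expect_equal(cb0$covered_bp, 0L)
  expect_equal(cb0$fraction, 0)
  # hand-built alignments tiling exactly half the circle
  aln0$genome_intervals <- data.frame(start = 1L, end = 5000L)
  cb <- coverage_breadth(g, aln0)
  expect_equal(cb$fraction, 0.5)
})

test_that("editing sites are called at simulated levels; T reference and low levels are not", {
  g <- tiny_genome(19, L = 20000L, genes = 6L)
  tr <- attr(g, "truth")$editing
  site <- tr[tr$level == 92, ][1, ]
  expr <- stats::setNames(1, site$gene)
  rs <- simulate_rna_reads(g, expr, rna_layout(1500L), seed = 12)
  aln <- filter_rna_reads(rs, g)
  sites <- call_editing_sites(genome = g, aln = aln, reads = rs)
  got <- sites[sites$genomic_pos == site$genomic_pos, ]
  expect_equal(nrow(got), 1L)
  sd3 <- 3 * sqrt(0.92 * 0.08 / got$depth) * 100
  expect_lt(abs(got$editing_level - 92), sd3)
  expect_equal(got$strand, site$strand)
  expect_equal(got$codon_position,
               (site$cds_offset - 1L) %% 3L + 1L)
  # no site is ever reported at a non-C transcript position
  specs <- attr(g, "truth")$blueprint$gene_specs
  gs <- specs[[match(site$gene, vapply(specs, `[[`, "", "name"))]]
  tx <- transcript_seq(g$seq, gs)
  expect_true(all(substring(tx, sites$cds_offset, sites$cds_offset) == "C"))
  # a 5% site stays below the default 10% report floor
  low <- data.frame(gene = site$gene, cds_offset = site$cds_offset, level = 5)
  rs_low <- simulate_rna_reads(g, expr, rna_layout(1500L), seed = 13,
                               editing = low)
  aln_low <- filter_rna_reads(rs_low, g)
  sites_low <- call_editing_sites(genome = g, aln = aln_low, reads = rs_low)
  expect_false(site$genomic_pos %in% sites_low$genomic_pos)
})

test_that("minus-strand editing corresponds to genomic G-to-A evidence", {
  g <- tiny_genome(19, L = 20000L, genes = 6L)
  tr <- attr(g, "truth")$editing
  minus <- tr[tr$strand == "-", ][1, ]
  expect_identical(substr(g$seq, minus$genomic_pos, minus$genomic_pos), "G")
  expr <- stats::setNames(1, minus$gene)
  rs <- simulate_rna_reads(g, expr, rna_layout(800L), seed = 14)
  # project an edited read back to the genome: the edited base reads A there
  i <- which(rs$meta$n_edited > 0)[1]
  expect_false(is.na(i))
  specs <- attr(g, "truth")$blueprint$gene_specs
  gs <- specs[[match(minus$gene, vapply(specs, `[[`, "", "name"))]]
  off <- minus$cds_offset - rs$meta$tx_start[i] + 1L
  expect_identical(substr(rs$reads1[[i]], off, off), "T")  # U in transcript space
  # genome-projected: reverse complement of T is A at a genomic G position
  expect_identical(rc1(substr(rs$reads1[[i]], off, off)), "A")
})

test_that("edit-free simulations yield zero calls and recovery holds across seeds", {
  # deep coverage (1,500 covering reads) so sampling error stays well
  # inside the +/-5-point recovery band
  called <- 0L; total <- 0L; max_err <- 0
  set.seed(99)
  levels <- sample(20:99, 20)
  for (sd in 1:20) {
    sim <- simulate_stopgain_site(level = levels[sd], n_reads = 1500L,
                                  seed = 6000L + sd)
    total <- total + 1L
    if (nrow(sim$site) == 1L) {
      called <- called + 1L
      max_err <- max(max_err, abs(sim$site$editing_level - levels[sd]))
    }
  }
  expect_equal(total, 20L)
  expect_gte(called / total, 0.95)
  expect_lte(max_err, 5)
  # no false sites at error rate zero on an edit-free simulation
  g0 <- tiny_genome(500L, L = 12000L, genes = 3L)
  specs <- attr(g0, "truth")$blueprint$gene_specs
  expr0 <- stats::setNames(rep(1, 3), vapply(specs, `[[`, "", "name"))
  none <- data.frame(gene = character(0), cds_offset = integer(0),
                     level = numeric(0))
  rs0 <- simulate_rna_reads(g0, expr0, rna_layout(800L), seed = 77,
                            editing = none)
  aln0 <- filter_rna_reads(rs0, g0)
  sites0 <- call_editing_sites(genome = g0, aln = aln0, reads = rs0)
  expect_equal(nrow(sites0), 0L)
})

test_that("the packaged editing table parses, counts and validates as printed", {
  p <- system.file("extdata", "table5_editing_sites.tsv",
                   package = "mitocircle")
  t5 <- read_editing_table(p)
  expect_equal(nrow(t5), 69L)
  v <- validate_editing_table(t5)
  expect_equal(v$n_total, 69L)
  expect_equal(v$per_gene[["nad7"]], 13L)
  expect_equal(v$n_inconsistent, 2L)
  bad <- v$verdicts[!v$verdicts$consistent, ]
  expect_setequal(bad$position, c(726995L, 103757L))
  expect_match(bad$reason[bad$position == 726995L], "aa_before mismatch")
  expect_match(bad$reason[bad$position == 103757L], "not a single C->U")
  # validation flags but never alters the counts
  expect_equal(sum(v$per_gene), 69L)
  # malformed codons are named, not silently skipped
  t5b <- t5[1:2, ]
  t5b$codon_from[2] <- "CXA"
  expect_error(validate_editing_table(t5b), "malformed codon")
})
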