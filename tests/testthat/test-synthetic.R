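test_that("genome building is deterministic and honours the blueprint", {
  bp0 <- genome_blueprint(1000L, seed = 7L)
  g1 <- build_genome(bp0)
  g2 <- build_genome(bp0)
  expect_identical(g1$seq, g2$seq)
  expect_equal(g1$length, 1000L)
  expect_equal(nrow(g1$features), 0L)

  bp <- default_blueprint(seed = 11, genome_length = 20000L, ir_len = 1500L,
                          dr_len = 320L, n_genes = 6L)
  g <- build_genome(bp)
  expect_identical(g$seq, build_genome(bp)$seq)
  expect_identical(g$features, build_genome(bp)$features)
  f <- g$features
  ir <- f[f$type == "repeat" & f$label == "LIR", ]
  a <- substr(g$seq, ir$start[1], ir$end[1])
  b <- substr(g$seq, ir$start[2], ir$end[2])
  expect_identical(a, rc1(b))     # zero-divergence inverted pair
  dr <- f[f$type == "repeat" & f$label == "SDR", ]
  expect_identical(substr(g$seq, dr$start[1], dr$end[1]),
                   substr(g$seq, dr$start[2], dr$end[2]))
})

test_that("overlapping repeat copies raise a structural-conflict error", {
  expect_error(genome_blueprint(
    10000L, repeat_specs = list(list(kind = "direct", length = 500L,
                                     pos_a = 1000L, pos_b = 1200L,
                                     divergence = 0))),
    "structural conflict")
})

test_that("the desk-scale blueprint round-trips through the annotation writer/reader", {
  td <- withr::local_tempdir()
  g <- build_genome(default_blueprint(seed = 3))  # 100 kbp, IR 2.5 kbp, DR 320 bp
  p <- file.path(td, "features.gff3")
  write_gff3(g$features, p, genome_length = g$length)
  back <- read_gff3(p, genome_length = g$length)
  rownames(back) <- rownames(g$features) <- NULL
  expect_equal(back, g$features)
})

test_that("simulated insert sizes and error rates match the layout", {
  g <- build_genome(default_blueprint(seed = 2))
  layout <- pe_layout(10000L)
  rs <- simulate_dna_reads(g, layout, seed = 5)
  expect_equal(length(rs), 10000L)
  m <- rs$meta
  se <- layout$insert_sd / sqrt(nrow(m))
  expect_lt(abs(mean(m$frag_len) - layout$insert_mean), 3 * se + 1)
  # mapped insert size: distance between outer read ends on the genome
  h1 <- map_reads(rs$reads1[1:2000], g$seq)
  h1 <- h1[!duplicated(h1$query), ]
  truth <- merge(data.frame(id = sub("/1$", "", h1$query), pos = h1$pos), m)
  expect_gt(nrow(truth), 1500)
  # error model: compare read bases with the genome at the true origin
  rs_e <- simulate_dna_reads(g, pe_layout(300L, error_rate = 0.01), seed = 6)
  mm <- 0L; n_checked <- 0L
  for (i in seq_len(length(rs_e))) {
    tr <- rs_e$meta[i, ]
    if (tr$frag_strand != "+") next
    s <- tr$frag_pos
    end <- s + tr$frag_len - 1L
    frag <- if (end <= g$length) substr(g$seq, s, end) else
      paste0(substr(g$seq, s, g$length), substr(g$seq, 1, end - g$length))
    r1_true <- substr(frag, 1, 300)
    mm <- mm + sum(charToRaw(r1_true) != charToRaw(rs_e$reads1[[i]]))
    n_checked <- n_checked + 300L
  }
  p_hat <- mm / n_checked
  sd3 <- 3 * sqrt(0.01 * 0.99 / n_checked)
  expect_lt(abs(p_hat - 0.01), sd3 + 1e-4)
})

test_that("zero-pair layouts and oversized inserts behave per contract", {
  g <- build_genome(default_blueprint(seed = 2, genome_length = 20000L,
                                      ir_len = 1200L, n_genes = 4L))
  expect_equal(length(simulate_dna_reads(g, pe_layout(0L), seed = 1)), 0L)
  bad <- read_layout(100L, insert_mean = 50000, insert_sd = 10,
                     n_pairs = 10L, orientation = "outward")
  expect_error(simulate_dna_reads(g, bad, seed = 1), "insert_mean")
  expect_error(read_layout(300L, insert_mean = 400, n_pairs = 1L,
                           orientation = "inward"), "insert_mean")
  expect_error(read_layout(100L, 3500, 350, 10L, "outward", error_rate = 0.5),
               "error_rate")
})

test_that("RNA simulation carries editing at the specified per-site level", {
  g <- tiny_genome(4, L = 20000L, genes = 6L)
  tr <- attr(g, "truth")$editing
  site <- tr[tr$level == 92, ][1, ]
  expr <- stats::setNames(1, site$gene)
  rs <- simulate_rna_reads(g, expr, rna_layout(10000L), seed = 8)
  covering <- 0L; edited <- 0L
  for (i in seq_len(length(rs))) {
    st <- rs$meta$tx_start[i]
    en <- st + nchar(rs$reads1[[i]]) - 1L
    if (site$cds_offset >= st && site$cds_offset <= en) {
      covering <- covering + 1L
      b <- substr(rs$reads1[[i]], site$cds_offset - st + 1L,
                  site$cds_offset - st + 1L)
      if (b == "T") edited <- edited + 1L
    }
  }
  expect_gt(covering, 1000L)
  p_hat <- edited / covering
  sd3 <- 3 * sqrt(0.92 * 0.08 / covering)
  expect_lt(abs(p_hat - 0.92), sd3)
  # zero-abundance genes yield no reads
  g2 <- rs$meta$gene
  expect_true(all(g2 == site$gene))
  # level-100 sites: every covering read edited
  tr100 <- tr[tr$level == 100, ][1, ]
  rs100 <- simulate_rna_reads(g, stats::setNames(1, tr100$gene),
                              rna_layout(500L), seed = 9)
  for (i in seq_len(length(rs100))) {
    st <- rs100$meta$tx_start[i]
    off <- tr100$cds_offset - st + 1L
    if (off >= 1L && off <= nchar(rs100$reads1[[i]])) {
      expect_identical(substr(rs100$reads1[[i]], off, off), "T")
    }
  }
})

test_that("editing specs targeting a non-C transcript base are rejected", {
  g <- tiny_genome(4, L = 20000L, genes = 6L)
  specs <- attr(g, "truth")$blueprint$gene_specs
  gname <- specs[[1]]$name
  tx <- transcript_seq(g$seq, specs[[1]])
  not_c <- which(strsplit(tx, "")[[1]] != "C")[10]
  bad <- data.frame(gene = gname, cds_offset = not_c, level = 50)
  expect_error(simulate_rna_reads(g, stats::setNames(1, gname),
                                  rna_layout(10L), seed = 1, editing = bad),
               "non-C")
  outside <- data.frame(gene = gname, cds_offset = nchar(tx) + 50L, level = 50)
  expect_error(simulate_rna_reads(g, stats::setNames(1, gname),
                                  rna_layout(10L), seed = 1, editing = outside),
               "outside")
})

test_that("foreign spiking replaces the exact fraction and flags origins", {
  g <- tiny_genome(6, L = 15000L)
  cp <- attr(g, "truth")$plastid_donor
  pe <- simulate_dna_reads(g, pe_layout(1000L), seed = 3)
  expect_identical(spike_foreign_reads(pe, cp, 0), pe)
  sp <- spike_foreign_reads(pe, cp, 0.3, seed = 4)
  expect_equal(sum(sp$meta$source == "foreign"), 300L)
  expect_equal(length(sp), 1000L)
  expect_error(spike_foreign_reads(pe, "", 0.1), "empty foreign")
})

test_that("simulation truth files are written for downstream oracles", {
  td <- withr::local_tempdir()
  g <- tiny_genome(7, L = 12000L)
  pe <- simulate_dna_reads(g, pe_layout(50L), seed = 1)
  write_simulation(g, list(pe = pe), td)
  expect_true(file.exists(file.path(td, "genome.fasta")))
  expect_true(file.exists(file.path(td, "features.gff3")))
  expect_true(file.exists(file.path(td, "editing_truth.tsv")))
  expect_true(file.exists(file.path(td, "pe_truth.tsv")))
  tt <- read_tsv(file.path(td, "pe_truth.tsv"))
  expect_equal(nrow(tt), 50L)
  expect_true(all(c("id", "frag_pos", "frag_strand", "source") %in% names(tt)))
})
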