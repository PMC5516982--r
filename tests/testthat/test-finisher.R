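test_that("terminal overlaps are found at the thresholds and not below them", {
  set.seed(41)
  core <- random_dna(5000)
  a <- paste0(random_dna(2000), substr(core, 1, 150))
  b <- paste0(substr(core, 1, 150), random_dna(1800))
  j <- find_terminal_overlaps(c(a = a, b = b))
  expect_equal(nrow(j), 1L)
  expect_equal(j$overlap_length, 150L)
  expect_equal(j$identity, 1)
  expect_setequal(c(paste(j$a, j$a_end), paste(j$b, j$b_end)),
                  c("a R", "b L"))
  # 80 bp shared: below the 100 bp minimum
  a2 <- paste0(random_dna(2000), substr(core, 1, 80))
  j2 <- find_terminal_overlaps(c(a = a2, b = b))
  expect_equal(nrow(j2), 0L)
  # reverse-complement overlap is detected with strand-aware ends
  b_rc <- rc1(b)
  j3 <- find_terminal_overlaps(c(a = a, b = b_rc))
  expect_equal(nrow(j3), 1L)
  expect_equal(j3$overlap_length, 150L)
})

test_that("contigs tiled from a circle give one cycle of joins and the truth circle back", {
  g <- tiny_genome(42, L = 14000L)
  reps <- g$features[g$features$type == "repeat", ]
  ctgs <- shred_contigs(g, n = 7L, overlap = 120L, seed = 2,
                        avoid = cbind(reps$start, reps$end))
  joins <- find_terminal_overlaps(ctgs)
  expect_equal(nrow(joins), 7L)
  graph <- build_scaffold_graph(ctgs, joins)
  st <- graph_stats(graph)
  expect_equal(st$nodes, 7L)
  expect_equal(st$edges, 7L)
  expect_equal(st$dead_ends, 0L)
  expect_equal(st$connected_components, 1L)
  mc <- select_master_circle(graph)
  expect_equal(mc$status, "ok")
  expect_identical(canonical_circular(mc$sequence), canonical_circular(g$seq))
  # conservation: master length = sum of contigs minus overlaps
  expect_equal(nchar(mc$sequence),
               sum(nchar(ctgs)) - sum(joins$overlap_length))
})

test_that("graph statistics match a brute-force recount on random graphs", {
  set.seed(7)
  for (rep in 1:15) {
    n <- sample(3:50, 1)
    ids <- sprintf("n%02d", seq_len(n))
    ne <- sample(0:(2 * n), 1)
    edges <- data.frame(
      a = sample(ids, ne, replace = TRUE), a_end = sample(c("L", "R"), ne, TRUE),
      b = sample(ids, ne, replace = TRUE), b_end = sample(c("L", "R"), ne, TRUE),
      overlap_length = rep(100L, ne), identity = rep(1, ne),
      type = rep("overlap", ne), mp_support = rep(0L, ne),
      weak = rep(FALSE, ne), stringsAsFactors = FALSE)
    graph <- structure(list(
      contigs = stats::setNames(rep("ACGT", n), ids),
      nodes = data.frame(id = ids, length = 4L, copy_number = 1L),
      edges = edges, mp_links = edges[0, 1:4], cfg = finisher_config()),
      class = "ContigGraph")
    got <- graph_stats(graph)
    want <- graph_stats_oracle(ids, edges)
    expect_equal(got$nodes, want$nodes)
    expect_equal(got$edges, want$edges)
    expect_equal(got$dead_ends, want$dead_ends)
    expect_equal(got$connected_components, want$connected_components)
    expect_equal(got$dead_end_fraction, want$dead_ends / (2 * n))
  }
  # spec'd trivial cases
  single <- structure(list(contigs = c(x = "ACGT"),
                           nodes = data.frame(id = "x", length = 4L, copy_number = 1L),
                           edges = data.frame(a = character(0), a_end = character(0),
                                              b = character(0), b_end = character(0)),
                           mp_links = NULL, cfg = finisher_config()),
                      class = "ContigGraph")
  st <- graph_stats(single)
  expect_equal(unlist(st[c("nodes", "edges", "dead_ends", "connected_components")]),
               c(nodes = 1, edges = 0, dead_ends = 2, connected_components = 1))
})

test_that("iterative extension follows the truth sequence and halts at repeat branches", {
  g <- tiny_genome(6, L = 15000L, genes = 5L)
  pe <- simulate_dna_reads(g, pe_layout(1500L), seed = 21)
  reps <- g$features[g$features$type == "repeat", ]
  ir <- reps[reps$label == "LIR", ]
  # a contig interior to a non-repetitive stretch extends along the truth
  lo <- ir$end[1] + 600L
  ctg <- substr(g$seq, lo, lo + 900L)
  ext <- iterative_extend(ctg, pe, max_extend = 400L)
  expect_gt(ext$added_right, 0L)
  expect_identical(ext$sequence,
                   substr(g$seq, lo - ext$added_left, lo + 900L + ext$added_right))
  # a contig ending inside an inverted-repeat copy halts with a branch
  # report exactly at the copy boundary
  ctg2 <- substr(g$seq, ir$start[1] - 1200L, ir$start[1] + 199L)
  ext2 <- iterative_extend(ctg2, pe, max_extend = 2000L)
  expect_equal(unname(ext2$reasons["right"]), "branch")
  br <- ext2$branches[ext2$branches$end == "right", ]
  irlen <- ir$end[1] - ir$start[1] + 1L
  expect_equal(br$offset + 200L, irlen + 1L)
  # zero covering reads: unchanged
  none <- simulate_dna_reads(g, pe_layout(0L), seed = 1)
  ext3 <- iterative_extend(ctg, none)
  expect_identical(ext3$sequence, ctg)
})

test_that("repeat anchoring validation applies the depth, read-count and consensus criteria", {
  g <- tiny_genome(6, L = 15000L, genes = 5L)
  pe <- simulate_dna_reads(g, pe_layout(1500L), seed = 21)
  mp <- simulate_dna_reads(g, mp_layout(800L), seed = 22)
  reps <- g$features[g$features$type == "repeat", ]
  ir <- reps[reps$label == "LIR", ]
  v <- validate_repeat_anchoring(g$seq, c(ir$start[1], ir$end[1]), pe, mp)
  expect_equal(v$status, "accepted")
  expect_true(all(v$criteria))
  expect_gt(v$depth_ratio, 1.5)
  expect_gte(v$pe_spanning, 50L)
  expect_gte(v$mp_spanning, 10L)
  # starving the mate-pair library fails criterion 2
  mp_few <- simulate_dna_reads(g, mp_layout(40L), seed = 23)
  v2 <- validate_repeat_anchoring(g$seq, c(ir$start[1], ir$end[1]), pe, mp_few)
  expect_equal(v2$status, "rejected")
  expect_false(v2$criteria[["anchoring"]])
  # a single-copy region fails the depth criterion
  v3 <- validate_repeat_anchoring(g$seq, c(10500L, 11600L), pe, mp)
  expect_equal(v3$status, "rejected")
  expect_false(v3$criteria[["depth"]])
  # short repeats are resolved by overlaps alone
  v4 <- validate_repeat_anchoring(g$seq, c(5000L, 5200L), pe, mp)
  expect_equal(v4$status, "not_applicable")
})

test_that("depth profile reports coverage and proper-pair fractions", {
  # repeat-free circle: uniform reads, every read has one placement
  circ <- random_dna(10000, seed = 3)
  pe <- simulate_dna_reads(circ, pe_layout(800L), seed = 2)  # ~48x
  dp <- depth_profile(circ, pe_reads = pe)
  expected <- 800 * 600 / 10000   # pairs x insert / genome length
  expect_lt(abs(dp$summary$mean_depth - expected), 0.05 * expected)
  expect_gt(dp$summary$mapped_in_pairs_fraction, 0.98)
  dp0 <- depth_profile(circ)
  expect_true(all(dp0$depth == 0L))
  # a collapsed repeat accumulates the reads of both copies: placing both
  # copies in the reference restores genome-average depth over the repeat
  g <- tiny_genome(3, L = 10000L)
  pe2 <- simulate_dna_reads(g, pe_layout(800L), seed = 2)
  dp2 <- depth_profile(g$seq, pe_reads = pe2)
  ir <- g$features[g$features$type == "repeat" & g$features$label == "LIR", ]
  inrep <- mean(dp2$depth[ir$start[1]:ir$end[1]])
  outrep <- mean(dp2$depth[-unlist(Map(seq, ir$start, ir$end))])
  # multi-placed repeat reads are counted at both copies (documented), so
  # the repeat runs at about twice the unique-region depth
  expect_gt(inrep / outrep, 1.5)
})

test_that("two disjoint cycles are reported as candidates, never as a master circle", {
  set.seed(77)
  circ1 <- random_dna(4000); circ2 <- random_dna(3500)
  shred_circle <- function(s, k, pref) {
    L <- nchar(s)
    bps <- sort(sample.int(L, k))
    out <- character(k)
    for (i in seq_len(k)) {
      st <- bps[i]; nx <- if (i < k) bps[i + 1L] else bps[1L] + L
      len <- nx - st + 120L
      piece <- if (st + len - 1L <= L) substr(s, st, st + len - 1L) else
        paste0(substr(s, st, L), substr(s, 1, st + len - 1L - L))
      out[i] <- piece
    }
    stats::setNames(out, sprintf("%s%02d", pref, seq_len(k)))
  }
  ctgs <- c(shred_circle(circ1, 3, "a"), shred_circle(circ2, 3, "b"))
  graph <- build_scaffold_graph(ctgs, find_terminal_overlaps(ctgs))
  res <- select_master_circle(graph)
  expect_equal(res$status, "no_circle")
  expect_null(res$sequence)
  expect_equal(length(res$candidates), 2L)
  expect_match(res$diagnostic, "2 component")
})

test_that("a repeat-bearing blueprint is finished into the exact truth circle", {
  # one representative blueprint; the 20-seed recovery property lives in
  # the acceptance suite
  g <- tiny_genome(31L, L = 12000L, ir = 1200L, dr = 320L, genes = 4L)
  sh <- shred_at_repeats(g, overlap = 150L)
  mp <- simulate_dna_reads(g, mp_layout(600L), seed = 1031L)
  graph <- build_scaffold_graph(sh$contigs, find_terminal_overlaps(sh$contigs),
                                mp, copy_number = sh$copy_number)
  st <- graph_stats(graph)
  expect_equal(st$nodes, 6L)      # 4 arcs + 2 collapsed repeat contigs
  mc <- select_master_circle(graph)
  expect_equal(mc$status, "ok")
  expect_identical(canonical_circular(mc$sequence), canonical_circular(g$seq))
  # both repeat contigs traversed twice
  expect_equal(sum(mc$path$contig == "LIR"), 2L)
  expect_equal(sum(mc$path$contig == "SDR"), 2L)
})
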