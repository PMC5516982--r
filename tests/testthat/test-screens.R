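test_that("pseudogene criteria trigger on the canonical mutation classes", {
  ref <- make_ref_cds(200L, seed = 1)
  v0 <- classify_pseudogene(ref, ref)
  expect_equal(v0$status, "intact")
  expect_length(v0$triggered, 0L)
  expect_equal(v0$coverage_fraction, 1)
  # internal codon mutated to TAA
  mut <- ref
  substr(mut, 301, 303) <- "TAA"
  v1 <- classify_pseudogene(mut, ref)
  expect_equal(v1$status, "pseudogene")
  expect_true("inframe_stop" %in% v1$triggered)
  # single-base deletion mid-CDS: frameshift
  del <- paste0(substr(ref, 1, 200), substr(ref, 202, nchar(ref)))
  v2 <- classify_pseudogene(del, ref)
  expect_equal(v2$status, "pseudogene")
  expect_true("frameshift" %in% v2$triggered)
  # 40% truncation: short coverage
  tr <- substr(ref, 1, floor(nchar(ref) * 0.6))
  v3 <- classify_pseudogene(tr, ref)
  expect_true("short_coverage" %in% v3$triggered)
  expect_lt(v3$coverage_fraction, 0.80)
  # lost start codon
  ns <- ref
  substr(ns, 1, 3) <- "CTG"
  expect_true("missing_start" %in% classify_pseudogene(ns, ref)$triggered)
  # unalignable candidate
  v4 <- classify_pseudogene(random_dna(300, seed = 4), ref)
  expect_equal(v4$status, "pseudogene")
})

test_that("pseudogene classifier agrees with the translation oracle on 1000 mutated cases", {
  set.seed(99)
  refs <- lapply(1:5, function(i) make_ref_cds(sample(80:250, 1), seed = i))
  agree <- 0L; n <- 1000L
  for (k in seq_len(n)) {
    ref <- refs[[sample(5, 1)]]
    nr <- nchar(ref)
    kind <- sample(c("none", "sub", "del1", "del3", "trunc", "startloss"), 1)
    cand <- ref
    if (kind == "sub") {
      # mutate one interior codon to a random codon
      ci <- sample(2:(nr %/% 3 - 1), 1)
      substr(cand, ci * 3 - 2, ci * 3) <- paste(sample(c("A", "C", "G", "T"), 3,
                                                       TRUE), collapse = "")
    } else if (kind == "del1") {
      p <- sample(10:(nr - 10), 1)
      cand <- paste0(substr(ref, 1, p - 1), substr(ref, p + 1, nr))
    } else if (kind == "del3") {
      ci <- sample(2:(nr %/% 3 - 1), 1)
      cand <- paste0(substr(ref, 1, ci * 3 - 3), substr(ref, ci * 3 + 1, nr))
    } else if (kind == "trunc") {
      cand <- substr(ref, 1, floor(nr * stats::runif(1, 0.3, 0.75)))
    } else if (kind == "startloss") {
      substr(cand, 1, 3) <- "CTG"
    }
    got <- classify_pseudogene(cand, ref)$status
    want <- pseudogene_oracle(cand, ref)
    if (got == want) agree <- agree + 1L
  }
  expect_equal(agree, n)
})

test_that("plastid insertions are recovered, merged and bounded", {
  set.seed(31)
  mt <- random_dna(20000); cp <- random_dna(15000)
  frag <- substr(cp, 3000, 4999)
  mt2 <- paste0(substr(mt, 1, 5000), frag, substr(mt, 7001, 20000))
  fp <- find_plastid_insertions(mt2, cp)
  expect_equal(nrow(fp$intervals), 1L)
  expect_gte(fp$total_bp, 2000L * 0.99)
  expect_equal(fp$genome_fraction, fp$total_bp / nchar(mt2))
  # interval projected to the right place on the mtDNA
  expect_lt(abs(fp$intervals$start - 5001L), 25L)
  # unrelated sequences: empty
  fp0 <- find_plastid_insertions(mt, cp)
  expect_equal(fp0$total_bp, 0L)
  # adjacent overlapping copies merge without double counting
  mt3 <- paste0(substr(mt, 1, 5000), substr(cp, 3000, 4500),
                substr(cp, 4000, 5500), substr(mt, 8002, 20000))
  fp3 <- find_plastid_insertions(mt3, cp)
  expect_equal(nrow(fp3$intervals), 1L)
  expect_lte(fp3$total_bp, 3002L + 10L)
})

test_that("repeat detection reports each pair once with orientation", {
  set.seed(32)
  mt <- random_dna(20000)
  ir <- rc1(substr(mt, 1000, 1999))
  dr <- substr(mt, 3000, 3319)
  mt2 <- paste0(substr(mt, 1, 8000), ir, substr(mt, 9001, 12000), dr,
                substr(mt, 12321, 20000))
  fr <- find_repeats(mt2)
  expect_equal(nrow(fr), 2L)
  inv <- fr[fr$kind == "inverted", ]
  expect_equal(inv$q_start, 1000L)
  expect_equal(inv$s_start, 8001L)
  expect_gte(inv$identity, 0.99)
  dir <- fr[fr$kind == "direct", ]
  expect_equal(dir$length, 320L)
  # repeat-free random sequence: empty at the default thresholds
  expect_equal(nrow(find_repeats(random_dna(10000))), 0L)
})

test_that("ORF inventory matches a brute-force six-frame oracle", {
  # literal example: ATG AAA TAA with a 9 bp floor
  s <- paste0(random_dna(30, seed = 5), "ATGAAATAA", random_dna(30))
  o <- find_orfs(s, screen_config(orf_min_bp = 9L), circular = FALSE)
  hit <- o[o$start == 31L & o$strand == "+", ]
  expect_equal(hit$length, 9L)
  expect_equal(hit$peptide, "MK")
  # strand symmetry
  o_rc <- find_orfs(rc1(s), screen_config(orf_min_bp = 9L), circular = FALSE)
  hit_rc <- o_rc[o_rc$strand == "-" & o_rc$length == 9L, ]
  expect_equal(nrow(hit_rc), 1L)
  expect_equal(hit_rc$peptide, "MK")
  # random sequence against the oracle
  r <- random_dna(8000, seed = 6)
  got <- find_orfs(r, screen_config(orf_min_bp = 60L), circular = TRUE)
  want <- orf_oracle(r, 60L, circular = TRUE)
  expect_equal(got[, c("start", "end", "strand", "length")],
               want[, c("start", "end", "strand", "length")],
               ignore_attr = TRUE)
  # rotation invariance of the peptide multiset on a circular input
  rot <- paste0(substr(r, 3001, 8000), substr(r, 1, 3000))
  got_rot <- find_orfs(rot, screen_config(orf_min_bp = 60L), circular = TRUE)
  expect_setequal(got_rot$peptide, got$peptide)
})

test_that("category accounting follows precedence and conserves the genome exactly", {
  tr <- list(A = data.frame(start = 1L, end = 1000L))
  acc <- category_accounting(10000L, tr)
  expect_equal(acc$bp[acc$category == "A"], 1000L)
  expect_equal(acc$pct[acc$category == "A"], 10)
  expect_equal(acc$bp[acc$category == "intergenic"], 9000L)
  # a repeat fully inside a gene counts under the gene category only
  tr2 <- list(A = data.frame(start = 100L, end = 1099L),
              E = data.frame(start = 400L, end = 499L))
  acc2 <- category_accounting(10000L, tr2)
  expect_equal(acc2$bp[acc2$category == "E"], 0L)
  # random tracks against the per-base oracle; conservation is exact
  set.seed(44)
  for (i in 1:10) {
    L <- sample(500:3000, 1)
    tracks <- lapply(1:4, function(j) {
      k <- sample(0:5, 1)
      if (k == 0) return(data.frame(start = integer(0), end = integer(0)))
      st <- sample.int(L - 50L, k)
      data.frame(start = st, end = pmin(L, st + sample(10:200, k, TRUE)))
    })
    names(tracks) <- c("A", "B", "E", "F")
    acc <- category_accounting(L, tracks)
    expect_equal(sum(acc$bp), L)
    expect_equal(acc$bp, category_oracle(L, tracks), ignore_attr = TRUE)
  }
  expect_error(category_accounting(100L, list(A = data.frame(start = 50L, end = 200L))),
               "out of range")
})
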