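# Fixtures and independent oracles used across the suite.  Oracles are
# deliberately written as naive brute-force routines, sharing no code with
# the implementation paths they check.

tiny_genome <- function(seed, L = 12000L, ir = 1200L, dr = 320L, genes = 4L) {
  build_genome(default_blueprint(seed = seed, genome_length = L, ir_len = ir,
                                 dr_len = dr, n_genes = genes))
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc1 <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# Brute-force six-frame ORF scan: walks every position, checks ATG, walks
# forward codon by codon to the first stop.
orf_oracle <- function(seq, min_len, circular = TRUE) {
  L <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  hits <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc1(seq)
    S <- if (circular) paste0(s, s) else s
    n <- nchar(S)
    claimed_stops <- list("1" = integer(0), "2" = integer(0), "0" = integer(0))
    for (p in seq_len(min(L, n - 2L))) {
      if (substr(S, p, p + 2L) != "ATG") next
      q <- p
      repeat {
        if (q + 2L > n) { q <- NA; break }
        if (substr(S, q, q + 2L) %in% stops) break
        q <- q + 3L
      }
      if (is.na(q)) next
      len <- q + 2L - p + 1L
      if (len < min_len || len > L) next
      fr <- as.character(p %% 3L)
      if ((q %% L) %in% claimed_stops[[fr]]) next  # nested: later ATG, same stop
      claimed_stops[[fr]] <- c(claimed_stops[[fr]], q %% L)
      if (strand == "+") {
        hits[[length(hits) + 1L]] <- c(p, ((q + 2L - 1L) %% L) + 1L, len,
                                       strand = 1L)
      } else {
        gs <- L - (((q + 2L - 1L) %% L) + 1L) + 1L
        ge <- L - p + 1L
        hits[[length(hits) + 1L]] <- c(gs, ge, len, strand = 2L)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), length = integer(0)))
  }
  m <- do.call(rbind, hits)
  out <- data.frame(start = m[, 1L], end = m[, 2L],
                    strand = c("+", "-")[m[, 4L]], length = m[, 3L])
  out <- out[!duplicated(out), , drop = FALSE]
  out[order(out$start, out$end, out$strand), , drop = FALSE]
}

# Per-base category labelling oracle.
category_oracle <- function(L, tracks) {
  lab <- rep("intergenic", L)
  for (nm in rev(names(tracks))) {
    tr <- tracks[[nm]]
    for (i in seq_len(nrow(tr))) lab[tr$start[i]:tr$end[i]] <- nm
  }
  counts <- table(factor(lab, levels = c(names(tracks), "intergenic")))
  as.integer(counts)
}

# Brute-force contig-graph statistics from raw end/edge lists.
graph_stats_oracle <- function(node_ids, edges) {
  dead <- 0L
  for (nd in node_ids) {
    for (e in c("L", "R")) {
      inc <- sum((edges$a == nd & edges$a_end == e) |
                   (edges$b == nd & edges$b_end == e))
      if (inc == 0L) dead <- dead + 1L
    }
  }
  # components by repeated expansion
  comp <- 0L
  remaining <- node_ids
  while (length(remaining)) {
    comp <- comp + 1L
    grp <- remaining[1]
    repeat {
      nb <- unique(c(edges$b[edges$a %in% grp], edges$a[edges$b %in% grp]))
      nb <- intersect(nb, remaining)
      if (all(nb %in% grp)) break
      grp <- unique(c(grp, nb))
    }
    remaining <- setdiff(remaining, grp)
  }
  list(nodes = length(node_ids), edges = nrow(edges), dead_ends = dead,
       connected_components = comp)
}

# Independent intact/pseudogene decision for a candidate derived from `ref`
# by simple mutations: translate and inspect directly.
pseudogene_oracle <- function(candidate, ref) {
  stops <- c("TAA", "TAG", "TGA")
  n <- nchar(candidate)
  if (n < 0.8 * nchar(ref)) return("pseudogene")
  if (n %% 3L != 0L) return("pseudogene")
  if (substr(candidate, 1L, 3L) != "ATG") return("pseudogene")
  if (!substr(candidate, n - 2L, n) %in% stops) return("pseudogene")
  cods <- substring(candidate, seq(1L, n - 3L, 3L), seq(3L, n, 3L))
  internal <- cods[-length(cods)]
  if (any(internal %in% stops)) return("pseudogene")
  "intact"
}

# Reference CDS with start and stop, no internal stops.
make_ref_cds <- function(n_codons, seed) {
  set.seed(seed)
  safe <- setdiff(names(Biostrings::GENETIC_CODE),
                  c("TAA", "TAG", "TGA", "ATG"))
  paste0("ATG", paste(sample(safe, n_codons - 2L, replace = TRUE),
                      collapse = ""), "TAA")
}
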