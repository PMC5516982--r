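# Master-circle finishing: terminal-overlap joins, iterative extension,
# repeat anchoring validation, the contig/scaffold graph and selection of
# the master circle (assembly steps e-g).

#' Finishing configuration
#'
#' Defaults follow the established finishing thresholds for plant
#' mitochondrial master circles: 100 bp / >99% identity terminal overlaps,
#' 10 mate-pair reads per contig joining, 50 PE / 10 MP reads anchoring each
#' long (>300 bp) repeat.
#'
#' @param min_overlap_bp minimum terminal overlap (default 100).
#' @param min_overlap_identity overlap identity floor, exclusive
#'   (default 0.99).
#' @param min_mp_join_support mate-pair support below which an edge is weak
#'   (default 10).
#' @param min_pe_anchor,min_mp_anchor read-anchoring floors per repeat
#'   border (defaults 50 and 10).
#' @param long_repeat_bp repeats longer than this require anchoring
#'   validation (default 300).
#' @param min_depth_ratio repeat/non-repeat median depth ratio required for
#'   the depth criterion (default 1.25, from observed collapsed-repeat
#'   coverage ratios in finished plant mtDNA assemblies).
#' @param min_extend_depth consensus extension halts below this coverage
#'   (default 3).
#' @param branch_fraction a branch is reported when two consensus bases each
#'   carry at least this fraction of the column (default 0.30).
#' @return a `FinisherConfig` list.
#' @export
finisher_config <- function(min_overlap_bp = 100L, min_overlap_identity = 0.99,
                            min_mp_join_support = 10L, min_pe_anchor = 50L,
                            min_mp_anchor = 10L, long_repeat_bp = 300L,
                            min_depth_ratio = 1.25, min_extend_depth = 3L,
                            branch_fraction = 0.30) {
  stopifnot(min_overlap_bp > 0, min_overlap_identity > 0,
            min_mp_join_support > 0, min_pe_anchor > 0, min_mp_anchor > 0,
            long_repeat_bp > 0, min_depth_ratio > 0)
  structure(list(min_overlap_bp = as.integer(min_overlap_bp),
                 min_overlap_identity = min_overlap_identity,
                 min_mp_join_support = as.integer(min_mp_join_support),
                 min_pe_anchor = as.integer(min_pe_anchor),
                 min_mp_anchor = as.integer(min_mp_anchor),
                 long_repeat_bp = as.integer(long_repeat_bp),
                 min_depth_ratio = min_depth_ratio,
                 min_extend_depth = as.integer(min_extend_depth),
                 branch_fraction = branch_fraction),
            class = "FinisherConfig")
}

# Oriented sequence of a contig entered at `end` ("L" or "R").
oriented_seq <- function(seq, enter_end) {
  if (enter_end == "L") seq else revcomp(seq)
}

# Longest suffix(A)/prefix(B) overlap meeting thresholds; anchored k-mer
# candidates keep this fast even for long contigs.
suffix_prefix_overlap <- function(A, B, cfg, k = 20L, self = FALSE) {
  nA <- nchar(A); nB <- nchar(B)
  lmax <- min(nA, nB)
  if (self) lmax <- lmax - 1L   # exclude the trivial identity diagonal
  if (lmax < cfg$min_overlap_bp) return(NULL)
  cand_L <- integer(0)
  for (j in c(0L, k, 2L * k)) {
    if (j + k > nB) break
    kmer <- substr(B, j + 1L, j + k)
    hits <- gregexpr(kmer, A, fixed = TRUE)[[1]]
    if (hits[1] == -1L) next
    cand_L <- c(cand_L, nA - hits + 1L + j)
  }
  cand_L <- sort(unique(cand_L[cand_L >= cfg$min_overlap_bp & cand_L <= lmax]),
                 decreasing = TRUE)
  for (L in cand_L) {
    mm <- mismatches(substr(A, nA - L + 1L, nA), substr(B, 1L, L))
    idn <- (L - mm) / L
    if (idn > cfg$min_overlap_identity) {
      return(list(length = L, identity = idn))
    }
  }
  NULL
}

#' Find terminal overlaps between contigs
#'
#' All suffix/prefix overlaps (both strands) of at least `min_overlap_bp`
#' and identity above `min_overlap_identity`, each end pair recorded once.
#'
#' @param contigs named character vector.
#' @param cfg a [finisher_config()].
#' @return data.frame of joins: a, a_end, b, b_end, overlap_length, identity.
#' @export
find_terminal_overlaps <- function(contigs, cfg = finisher_config()) {
  stopifnot(length(contigs) >= 1)
  nms <- names(contigs)
  rows <- list()
  seen <- character(0)
  for (i in seq_along(contigs)) {
    for (j in seq_along(contigs)) {
      for (ea in c("L", "R")) {
        for (eb in c("L", "R")) {
          if (i == j && ea == eb) next
          key1 <- paste(nms[i], ea, nms[j], eb)
          key2 <- paste(nms[j], eb, nms[i], ea)
          if (key1 %in% seen || key2 %in% seen) next
          # exiting a through ea: oriented A ends at ea
          A <- if (ea == "R") contigs[[i]] else revcomp(contigs[[i]])
          B <- oriented_seq(contigs[[j]], eb)
          ov <- suffix_prefix_overlap(A, B, cfg, self = i == j)
          seen <- c(seen, key1, key2)
          if (!is.null(ov)) {
            rows[[length(rows) + 1L]] <- data.frame(
              a = nms[i], a_end = ea, b = nms[j], b_end = eb,
              overlap_length = ov$length, identity = ov$identity,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(a = character(0), a_end = character(0),
                      b = character(0), b_end = character(0),
                      overlap_length = integer(0), identity = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Collect reads overhanging the right end of `seq`, returning overhang
# strings; reads must anchor with >= min_overlap bases at >= 0.98 identity.
right_overhangs <- function(seq, reads, cfg, tail_bp = 500L) {
  n <- nchar(seq)
  tail_bp <- min(tail_bp, n)
  win <- substr(seq, n - tail_bp + 1L, n)
  out <- character(0)
  for (strand in c("+", "-")) {
    rd <- if (strand == "+") reads else revcomp(reads)
    cand <- seed_candidates(rd, Biostrings::DNAString(win), 20L)
    if (!nrow(cand)) next
    cand <- unique(cand)
    for (r in seq_len(nrow(cand))) {
      qi <- cand$qi[r]
      pos <- cand$pos[r]              # position in window
      rl <- nchar(rd[qi])
      ov <- tail_bp - pos + 1L        # anchored bases within the window
      if (ov >= rl) next              # fully contained, no overhang
      if (ov < cfg$min_overlap_bp) next
      if (pos < 1L) next
      anch <- substr(rd[qi], 1L, ov)
      ref <- substr(win, pos, tail_bp)
      if (nchar(anch) != nchar(ref)) next
      mm <- mismatches(anch, ref)
      if ((ov - mm) / ov < 0.98) next
      out <- c(out, substr(rd[qi], ov + 1L, rl))
    }
  }
  out
}

# Extend the right end of `seq` by overhang consensus until coverage or a
# branch stops it; returns list(seq, added, branch, reason).
extend_right <- function(seq, reads, cfg, max_extend) {
  added <- 0L
  branch <- NULL
  reason <- "max_extend"
  while (added < max_extend) {
    oh <- right_overhangs(seq, reads, cfg)
    oh <- oh[nzchar(oh)]
    if (length(oh) < cfg$min_extend_depth) { reason <- "low_coverage"; break }
    chunk <- character(0)
    stop_now <- FALSE
    maxj <- max(nchar(oh))
    for (j in seq_len(maxj)) {
      bases <- substr(oh[nchar(oh) >= j], j, j)
      # exhausting the current overhang set just ends this round; the outer
      # loop re-anchors reads on the extended end
      if (length(bases) < cfg$min_extend_depth) break
      tab <- sort(table(bases), decreasing = TRUE)
      if (length(tab) >= 2L &&
          tab[2L] / sum(tab) >= cfg$branch_fraction &&
          tab[1L] / sum(tab) >= cfg$branch_fraction) {
        branch <- data.frame(offset = added + length(chunk) + 1L,
                             alleles = paste(names(tab)[1:2], collapse = "/"),
                             support = paste(tab[1:2], collapse = "/"),
                             stringsAsFactors = FALSE)
        reason <- "branch"; stop_now <- TRUE; break
      }
      chunk <- c(chunk, names(tab)[1L])
      if (added + length(chunk) >= max_extend) { stop_now <- TRUE; reason <- "max_extend"; break }
    }
    if (length(chunk)) {
      seq <- paste0(seq, paste(chunk, collapse = ""))
      added <- added + length(chunk)
    } else if (!stop_now) {
      reason <- "low_coverage"
      stop_now <- TRUE
    }
    if (stop_now) break
  }
  list(seq = seq, added = added, branch = branch, reason = reason)
}

#' Iteratively extend a contig by read-consensus mapping
#'
#' Each end is extended by the consensus of reads anchored over the terminal
#' window; extension halts when coverage drops below `min_extend_depth` or
#' when two consensus bases each carry at least `branch_fraction` of a
#' column (a repeat-boundary branch), which is reported.
#'
#' @param contig a single contig sequence.
#' @param reads a `ReadSet` (pairs are flattened).
#' @param cfg a [finisher_config()].
#' @param max_extend per-end extension cap in bp (default 5000).
#' @return list: `sequence`, `added_left`, `added_right`, `branches`
#'   (data.frame with `end`, `offset`, `alleles`, `support`), `reasons`.
#' @export
iterative_extend <- function(contig, reads, cfg = finisher_config(),
                             max_extend = 5000L) {
  rd <- unname(c(reads$reads1, reads$reads2))
  rd <- rd[nchar(rd) >= 20L]
  res_r <- extend_right(contig, rd, cfg, max_extend)
  res_l <- extend_right(revcomp(res_r$seq), rd, cfg, max_extend)
  out_seq <- revcomp(res_l$seq)
  branches <- list()
  if (!is.null(res_r$branch)) {
    b <- res_r$branch; b$end <- "right"; branches[[length(branches) + 1L]] <- b
  }
  if (!is.null(res_l$branch)) {
    b <- res_l$branch; b$end <- "left"; branches[[length(branches) + 1L]] <- b
  }
  list(sequence = out_seq, added_right = res_r$added, added_left = res_l$added,
       branches = if (length(branches)) do.call(rbind, branches) else NULL,
       reasons = c(right = res_r$reason, left = res_l$reason))
}

# The end of `contig` a mapped read points toward, given pair orientation.
pointed_end <- function(strand, orientation) {
  ifelse((strand == "+") == (orientation == "inward"), "R", "L")
}

# Mate-pair links between contig ends: pairs whose mates map uniquely to two
# different contigs, each within insert range of the end it points to.
# `mean_gap` is the implied sequence length between the two ends
# (insert_mean minus the reads' distances to their pointed ends): ~0 for
# directly adjacent ends, ~repeat length for ends flanking a collapsed
# repeat, larger for links that skip further contigs.
mp_link_table <- function(contigs, mp_reads, cfg) {
  empty <- data.frame(a = character(0), a_end = character(0),
                      b = character(0), b_end = character(0),
                      support = integer(0), mean_gap = numeric(0))
  if (is.null(mp_reads) || length(mp_reads) == 0L) return(empty)
  layout <- mp_reads$layout
  maxd <- layout$insert_mean + 3 * layout$insert_sd
  h1 <- best_hits(map_reads_multi(mp_reads$reads1, contigs, min_identity = 0.98))
  h2 <- best_hits(map_reads_multi(mp_reads$reads2, contigs, min_identity = 0.98))
  h1 <- h1[h1$unique, , drop = FALSE]
  h2 <- h2[h2$unique, , drop = FALSE]
  if (!nrow(h1) || !nrow(h2)) return(empty)
  h1$id <- sub("/[12]$", "", h1$query)
  h2$id <- sub("/[12]$", "", h2$query)
  m <- merge(h1, h2, by = "id", suffixes = c("_1", "_2"))
  m <- m[m$subject_1 != m$subject_2, , drop = FALSE]
  if (!nrow(m)) return(empty)
  ori <- layout$orientation
  end1 <- pointed_end(m$strand_1, ori)
  end2 <- pointed_end(m$strand_2, ori)
  len1 <- nchar(contigs[m$subject_1]); len2 <- nchar(contigs[m$subject_2])
  d1 <- ifelse(end1 == "R", len1 - m$pos_1 + 1L, m$pos_1 + m$len_1 - 1L)
  d2 <- ifelse(end2 == "R", len2 - m$pos_2 + 1L, m$pos_2 + m$len_2 - 1L)
  ok <- d1 <= maxd & d2 <= maxd
  m <- m[ok, , drop = FALSE]
  end1 <- end1[ok]; end2 <- end2[ok]
  if (!nrow(m)) return(empty)
  d1 <- d1[ok]; d2 <- d2[ok]
  gap <- layout$insert_mean - d1 - d2
  key <- ifelse(m$subject_1 < m$subject_2 |
                  (m$subject_1 == m$subject_2 & end1 <= end2),
                paste(m$subject_1, end1, m$subject_2, end2, sep = "\r"),
                paste(m$subject_2, end2, m$subject_1, end1, sep = "\r"))
  tab <- table(key)
  gaps <- tapply(gap, key, mean)
  parts <- do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE))
  data.frame(a = parts[, 1L], a_end = parts[, 2L], b = parts[, 3L],
             b_end = parts[, 4L], support = as.integer(tab),
             mean_gap = as.numeric(gaps[names(tab)]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build the contig/scaffold graph
#'
#' Nodes are contigs; edges are terminal-overlap joins plus mate-pair link
#' edges (mate pairs mapping uniquely to two contigs at compatible distance
#' and orientation).  Edges whose mate-pair support is below
#' `min_mp_join_support` are flagged weak (when mate-pair data is present).
#'
#' @param contigs named character vector.
#' @param joins overlap joins from [find_terminal_overlaps()].
#' @param mp_reads mate-pair `ReadSet` (may be NULL).
#' @param cfg a [finisher_config()].
#' @param copy_number named integer vector of expected traversal counts
#'   (default 1 for every contig; 2 for a validated collapsed repeat).
#' @return a `ContigGraph` list: `contigs`, `nodes`, `edges`.
#' @export
build_scaffold_graph <- function(contigs, joins, mp_reads = NULL,
                                 cfg = finisher_config(), copy_number = NULL) {
  if (is.null(copy_number)) {
    copy_number <- stats::setNames(rep(1L, length(contigs)), names(contigs))
  }
  links <- mp_link_table(contigs, mp_reads, cfg)
  gap_tol <- if (!is.null(mp_reads) && length(mp_reads)) {
    3 * mp_reads$layout$insert_sd
  } else Inf
  edge_key <- function(a, ae, b, be) {
    ifelse(a < b | (a == b & ae <= be),
           paste(a, ae, b, be, sep = "\r"), paste(b, be, a, ae, sep = "\r"))
  }
  edges <- joins
  if (nrow(edges)) {
    edges$type <- "overlap"
    edges$mp_support <- 0L
  } else {
    edges <- data.frame(a = character(0), a_end = character(0),
                        b = character(0), b_end = character(0),
                        overlap_length = integer(0), identity = numeric(0),
                        type = character(0), mp_support = integer(0))
  }
  if (nrow(links)) {
    jk <- edge_key(edges$a, edges$a_end, edges$b, edges$b_end)
    lk <- edge_key(links$a, links$a_end, links$b, links$b_end)
    hit <- match(lk, jk)
    for (i in which(!is.na(hit))) {
      # only links whose implied gap matches direct adjacency (the overlap
      # is negative sequence between the ends) corroborate the join
      if (abs(links$mean_gap[i] + edges$overlap_length[hit[i]]) <= gap_tol) {
        edges$mp_support[hit[i]] <- edges$mp_support[hit[i]] + links$support[i]
      }
    }
    new <- links[is.na(hit), , drop = FALSE]
    if (nrow(new)) {
      edges <- rbind(edges, data.frame(
        a = new$a, a_end = new$a_end, b = new$b, b_end = new$b_end,
        overlap_length = NA_integer_, identity = NA_real_, type = "mp",
        mp_support = new$support, stringsAsFactors = FALSE))
    }
  }
  # overlap joins carry sequence evidence and are never weak; mate-pair-only
  # edges are weak below the support floor
  edges$weak <- edges$type == "mp" & edges$mp_support < cfg$min_mp_join_support
  nodes <- data.frame(id = names(contigs), length = nchar(contigs),
                      copy_number = as.integer(copy_number[names(contigs)]),
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(contigs = contigs, nodes = nodes, edges = edges,
                 mp_links = links, cfg = cfg, gap_tol = gap_tol),
            class = "ContigGraph")
}

#' Summary statistics of a contig graph
#'
#' A dead end is a contig end with no incident edge; the fraction is over
#' all 2 x nodes ends.
#'
#' @param graph a `ContigGraph`.
#' @return list: nodes, edges, dead_ends, connected_components,
#'   dead_end_fraction.
#' @export
graph_stats <- function(graph) {
  nodes <- graph$nodes$id
  e <- graph$edges
  n <- length(nodes)
  ends <- c(paste(nodes, "L"), paste(nodes, "R"))
  used <- unique(c(paste(e$a, e$a_end), paste(e$b, e$b_end)))
  dead <- sum(!ends %in% used)
  comp <- if (n == 0L) 0L else {
    g <- igraph::graph_from_data_frame(
      d = if (nrow(e)) data.frame(from = e$a, to = e$b) else
        data.frame(from = character(0), to = character(0)),
      directed = FALSE, vertices = data.frame(name = nodes))
    igraph::count_components(g)
  }
  list(nodes = n, edges = nrow(e), dead_ends = dead,
       connected_components = comp,
       dead_end_fraction = if (n > 0L) dead / (2L * n) else NA_real_)
}

other_end <- function(e) ifelse(e == "L", "R", "L")

# All incident (edge index, neighbour, neighbour entry end) for an end.
incident_edges <- function(edges, contig, end) {
  out <- list()
  for (i in seq_len(nrow(edges))) {
    if (edges$a[i] == contig && edges$a_end[i] == end) {
      out[[length(out) + 1L]] <- list(i = i, nxt = edges$b[i], enter = edges$b_end[i])
    }
    if (edges$b[i] == contig && edges$b_end[i] == end) {
      out[[length(out) + 1L]] <- list(i = i, nxt = edges$a[i], enter = edges$a_end[i])
    }
  }
  out
}

# Exhaustive search for closed walks visiting each contig copy_number times,
# each edge at most once.  Returns list of walks; each walk is a list of
# steps (contig, enter) and the edge indices used (last edge closes).
enumerate_circles <- function(nodes, edges, max_states = 2e5) {
  if (!nrow(edges)) return(list())
  quota <- stats::setNames(nodes$copy_number, nodes$id)
  total <- sum(quota)
  start <- nodes$id[which(nodes$copy_number == 1L)[1]]
  if (is.na(start)) start <- nodes$id[1]
  walks <- list()
  states <- 0L
  rec <- function(cur, exit_end, used_nodes, used_edges, steps, eidx) {
    states <<- states + 1L
    if (states > max_states) return()
    for (cand in incident_edges(edges, cur, exit_end)) {
      if (used_edges[cand$i]) next
      if (cand$nxt == start && cand$enter == "L") {
        if (sum(used_nodes) == total) {
          walks[[length(walks) + 1L]] <<- list(steps = steps, edges = c(eidx, cand$i))
        }
        next
      }
      if (used_nodes[cand$nxt] >= quota[cand$nxt]) next
      un <- used_nodes; un[cand$nxt] <- un[cand$nxt] + 1L
      ue <- used_edges; ue[cand$i] <- TRUE
      rec(cand$nxt, other_end(cand$enter), un, ue,
          c(steps, list(list(contig = cand$nxt, enter = cand$enter))),
          c(eidx, cand$i))
    }
  }
  used_nodes <- stats::setNames(integer(nrow(nodes)), nodes$id)
  used_nodes[start] <- 1L
  rec(start, "R", used_nodes, logical(nrow(edges)),
      list(list(contig = start, enter = "L")), integer(0))
  walks
}

# Score a walk: summed mate-pair support of its junction edges, plus support
# of mate-pair links spanning each multi-copy (repeat) step whose implied
# gap is consistent with the repeat length.
score_walk <- function(walk, graph) {
  e <- graph$edges
  sc <- sum(e$mp_support[walk$edges])
  quota <- stats::setNames(graph$nodes$copy_number, graph$nodes$id)
  node_len <- stats::setNames(graph$nodes$length, graph$nodes$id)
  gap_tol <- graph$gap_tol %||% Inf
  links <- graph$mp_links
  if (!is.null(links) && nrow(links)) {
    steps <- walk$steps
    m <- length(steps)
    for (i in seq_along(steps)) {
      s <- steps[[i]]
      if (quota[s$contig] > 1L) {
        prev <- steps[[if (i == 1L) m else i - 1L]]
        nxt <- steps[[if (i == m) 1L else i + 1L]]
        pe <- other_end(prev$enter)   # exit end of previous contig
        ne <- nxt$enter
        hit <- (links$a == prev$contig & links$a_end == pe &
                  links$b == nxt$contig & links$b_end == ne) |
               (links$b == prev$contig & links$b_end == pe &
                  links$a == nxt$contig & links$a_end == ne)
        hit <- hit & abs(links$mean_gap - node_len[s$contig]) <= gap_tol
        sc <- sc + sum(links$support[hit])
      }
    }
  }
  sc
}

# Mean overlap identity of a walk's junctions (NA-safe).
walk_identity <- function(walk, graph) {
  idn <- graph$edges$identity[walk$edges]
  if (all(is.na(idn))) 0 else mean(idn, na.rm = TRUE)
}

# Stitch the walk into a circular sequence; mate-pair-only junctions become
# runs of `gap_n` Ns (gap closing is out of scope).
walk_sequence <- function(walk, graph, gap_n = 100L) {
  e <- graph$edges
  steps <- walk$steps
  segs <- character(0)
  n_count <- 0L
  seq_out <- oriented_seq(graph$contigs[[steps[[1]]$contig]], steps[[1]]$enter)
  for (i in seq_along(walk$edges)) {
    ei <- walk$edges[i]
    ov <- e$overlap_length[ei]
    last <- i == length(walk$edges)
    nxt_seq <- if (!last) {
      s <- steps[[i + 1L]]
      oriented_seq(graph$contigs[[s$contig]], s$enter)
    } else NULL
    if (e$type[ei] == "overlap") {
      if (last) {
        seq_out <- substr(seq_out, 1L, nchar(seq_out) - ov)
      } else {
        seq_out <- paste0(seq_out, substr(nxt_seq, ov + 1L, nchar(nxt_seq)))
      }
    } else {
      gap <- paste(rep("N", gap_n), collapse = "")
      n_count <- n_count + gap_n
      seq_out <- if (last) paste0(seq_out, gap) else
        paste0(seq_out, gap, nxt_seq)
    }
  }
  list(seq = seq_out, n_count = n_count)
}

#' Select the master circle from a contig graph
#'
#' Searches for a circular walk visiting every single-copy contig exactly
#' once and each multi-copy (validated repeat) contig according to its copy
#' number, maximising total mate-pair support; ties broken by higher mean
#' overlap identity, then by lexicographically smallest canonical sequence.
#' Weak edges are considered only when no strong-edge circle exists, and
#' their use is reported.
#'
#' @param graph a `ContigGraph` (see [build_scaffold_graph()]).
#' @param cfg a [finisher_config()].
#' @return list with `status` ("ok" or "no_circle"), `sequence` (circular
#'   master sequence, or NULL), `n_count` (uncalled N bases), `score`,
#'   `used_weak_edges`, `path` (step table) and, on failure, `candidates`
#'   per component and `diagnostic`.
#' @export
select_master_circle <- function(graph, cfg = graph$cfg %||% finisher_config()) {
  strong <- graph
  strong$edges <- graph$edges[!graph$edges$weak, , drop = FALSE]
  attempt <- function(g, weak_used) {
    walks <- enumerate_circles(g$nodes, g$edges)
    if (!length(walks)) return(NULL)
    scores <- vapply(walks, score_walk, numeric(1), graph = g)
    best <- which(scores == max(scores))
    if (length(best) > 1L) {
      idn <- vapply(walks[best], walk_identity, numeric(1), graph = g)
      best <- best[idn == max(idn)]
    }
    if (length(best) > 1L) {
      canon <- vapply(walks[best], function(w)
        canonical_circular(walk_sequence(w, g)$seq), character(1))
      best <- best[order(canon)][1]
    } else {
      best <- best[1]
    }
    w <- walks[[best]]
    ws <- walk_sequence(w, g)
    path <- data.frame(
      step = seq_along(w$steps),
      contig = vapply(w$steps, `[[`, character(1), "contig"),
      enter = vapply(w$steps, `[[`, character(1), "enter"))
    list(status = "ok", sequence = ws$seq, n_count = ws$n_count,
         score = max(scores), used_weak_edges = weak_used, path = path)
  }
  overlap_only <- graph
  overlap_only$edges <- graph$edges[graph$edges$type == "overlap", , drop = FALSE]
  res <- attempt(overlap_only, FALSE)
  if (is.null(res)) res <- attempt(strong, FALSE)
  if (is.null(res) && any(graph$edges$weak)) res <- attempt(graph, TRUE)
  if (!is.null(res)) return(res)
  # diagnostic path: per-component candidate circles (quota ignored across
  # components), never silently labelled MC
  g <- igraph::graph_from_data_frame(
    d = if (nrow(graph$edges)) data.frame(from = graph$edges$a, to = graph$edges$b)
    else data.frame(from = character(0), to = character(0)),
    directed = FALSE, vertices = data.frame(name = graph$nodes$id))
  memb <- igraph::components(g)$membership
  cands <- list()
  for (cc in unique(memb)) {
    ids <- names(memb)[memb == cc]
    sub <- graph
    sub$nodes <- graph$nodes[graph$nodes$id %in% ids, , drop = FALSE]
    sub$edges <- graph$edges[graph$edges$a %in% ids & graph$edges$b %in% ids, ,
                             drop = FALSE]
    sub$contigs <- graph$contigs[ids]
    r <- attempt(sub, any(sub$edges$weak))
    if (!is.null(r)) cands[[length(cands) + 1L]] <- r
  }
  list(status = "no_circle", sequence = NULL, n_count = NA_integer_,
       score = NA_real_, used_weak_edges = NA, path = NULL,
       candidates = cands,
       diagnostic = sprintf("no circular walk satisfies the copy quotas; %d candidate circle(s) in %d component(s)",
                            length(cands), max(memb)))
}

#' Depth profile of a master circle
#'
#' Per-base depth (all best placements, circular mapping), per-library mean
#' and standard deviation, and the fraction of reads mapped in proper pairs
#' (both mates placed at compatible distance and orientation).
#'
#' @param master circular master sequence (character).
#' @param pe_reads,mp_reads `ReadSet`s (either may be NULL).
#' @return list with `depth` (integer vector, one per base) and a `summary`
#'   data.frame (library, mean_depth, sd_depth, mapped_in_pairs_fraction).
#' @export
depth_profile <- function(master, pe_reads = NULL, mp_reads = NULL) {
  stopifnot(nchar(master) > 0)
  L <- nchar(master)
  depth <- integer(L)
  rows <- list()
  for (lib in list(list(name = "pe", rs = pe_reads),
                   list(name = "mp", rs = mp_reads))) {
    rs <- lib$rs
    if (is.null(rs) || length(rs) == 0L) next
    h1 <- best_hits(map_reads(rs$reads1, master, circular = TRUE))
    h2 <- best_hits(map_reads(rs$reads2, master, circular = TRUE))
    h <- rbind(h1, h2)
    d <- depth_vector(h$pos, h$len, L, circular = TRUE)
    depth <- depth + d
    # proper pairs: some placement combination of the two mates at
    # compatible orientation and distance (repeat reads have several
    # equally good placements; any compatible one counts)
    u1 <- h1; u1$id <- sub("/[12]$", "", u1$query)
    u2 <- h2; u2$id <- sub("/[12]$", "", u2$query)
    m <- merge(u1, u2, by = "id", suffixes = c("_1", "_2"))
    proper <- 0L
    if (nrow(m)) {
      layout <- rs$layout
      span <- pmin(abs(m$pos_2 - m$pos_1), L - abs(m$pos_2 - m$pos_1)) +
        layout$read_length
      okd <- span >= layout$insert_mean - 3 * layout$insert_sd - layout$read_length &
        span <= layout$insert_mean + 3 * layout$insert_sd + layout$read_length
      oks <- m$strand_1 != m$strand_2
      proper <- length(unique(m$id[okd & oks]))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      library = lib$name, mean_depth = mean(d), sd_depth = stats::sd(d),
      mapped_in_pairs_fraction = proper / length(rs),
      stringsAsFactors = FALSE)
  }
  list(depth = depth,
       summary = if (length(rows)) do.call(rbind, rows) else
         data.frame(library = character(0), mean_depth = numeric(0),
                    sd_depth = numeric(0), mapped_in_pairs_fraction = numeric(0)))
}

#' Validate the anchoring of a long repeat
#'
#' Implements the three-way repeat validation used for master-circle
#' finishing: (1) repeat regions must show higher depth than single-copy
#' regions when reads from all copies pile onto one placement
#' (`depth_ratio > min_depth_ratio`); (2) at least `min_pe_anchor` PE and
#' `min_mp_anchor` MP read(-pair)s must support the anchoring of each repeat
#' border; (3) the border consensus rebuilt from spanning reads must
#' reproduce the anchored junction (`consensus_consistent`).  Repeats not
#' longer than `long_repeat_bp` return a not-applicable verdict (they are
#' resolved by plain overlaps).
#'
#' @param master sequence the repeat is anchored in (character, circular).
#' @param repeat_interval integer c(start, end), 1-based inclusive.
#' @param pe_reads,mp_reads `ReadSet`s.
#' @param cfg a [finisher_config()].
#' @param border_bp bases required on each side of a border for a read to
#'   count as spanning (default 20).
#' @return list with `status` ("accepted", "rejected", "not_applicable"),
#'   `criteria` (named logicals), `depth_ratio`, `pe_spanning`,
#'   `mp_spanning` and `consensus_consistent`.
#' @export
validate_repeat_anchoring <- function(master, repeat_interval, pe_reads,
                                      mp_reads, cfg = finisher_config(),
                                      border_bp = 20L) {
  rs <- repeat_interval[1]; re <- repeat_interval[2]
  rlen <- re - rs + 1L
  if (rlen <= cfg$long_repeat_bp) {
    return(list(status = "not_applicable",
                criteria = c(depth = NA, anchoring = NA, consensus = NA),
                depth_ratio = NA_real_, pe_spanning = NA_integer_,
                mp_spanning = NA_integer_, consensus_consistent = NA))
  }
  L <- nchar(master)
  hp <- rbind(map_reads(pe_reads$reads1, master),
              if (pe_reads$paired) map_reads(pe_reads$reads2, master))
  depth <- depth_vector(hp$pos, hp$len, L, circular = TRUE)
  inrep <- seq(rs, re)
  depth_ratio <- stats::median(depth[inrep]) /
    max(1e-9, stats::median(depth[-inrep]))
  borders <- c(rs, re)
  spans <- function(hits, b) {
    sum(hits$pos <= b - border_bp & hits$pos + hits$len - 1L >= b + border_bp)
  }
  pe_span <- vapply(borders, function(b) spans(hp, b), numeric(1))
  # MP pairs: implied fragment covers a border
  hm1 <- best_hits(map_reads(mp_reads$reads1, master))
  hm2 <- best_hits(map_reads(mp_reads$reads2, master))
  hm1$id <- sub("/[12]$", "", hm1$query); hm2$id <- sub("/[12]$", "", hm2$query)
  mp <- merge(hm1, hm2, by = "id", suffixes = c("_1", "_2"))
  mp_span <- c(0L, 0L)
  if (nrow(mp)) {
    lo <- pmin(mp$pos_1, mp$pos_2)
    hi <- pmax(mp$pos_1 + mp$len_1, mp$pos_2 + mp$len_2) - 1L
    w <- hi - lo
    wrap <- w > (mp_reads$layout$insert_mean + 3 * mp_reads$layout$insert_sd)
    for (k in 1:2) {
      b <- borders[k]
      mp_span[k] <- sum(!wrap & lo <= b - border_bp & hi >= b + border_bp)
    }
  }
  # criterion 3: junction consensus reassembly from spanning reads
  consensus_ok <- TRUE
  for (b in borders) {
    win <- seq(b - border_bp, b + border_bp)
    win <- ((win - 1L) %% L) + 1L
    cov_reads <- hp[hp$pos <= min(win) & hp$pos + hp$len - 1L >= max(win), ,
                    drop = FALSE]
    if (!nrow(cov_reads)) { consensus_ok <- FALSE; break }
    cols <- matrix("", nrow = nrow(cov_reads), ncol = length(win))
    for (r in seq_len(nrow(cov_reads))) {
      off <- win - cov_reads$pos[r] + 1L
      rd <- if (cov_reads$strand[r] == "+") {
        # read sequence equals the reference segment up to errors; rebuild
        # the consensus from the mapped read bases
        q <- cov_reads$query[r]
        all_rd <- c(pe_reads$reads1, pe_reads$reads2)
        all_rd[[q]]
      } else {
        q <- cov_reads$query[r]
        all_rd <- c(pe_reads$reads1, pe_reads$reads2)
        revcomp(all_rd[[q]])
      }
      cols[r, ] <- substring(rd, off, off)
    }
    cons <- apply(cols, 2L, function(x) names(sort(table(x), decreasing = TRUE))[1])
    if (paste(cons, collapse = "") != paste(substring(master, win, win), collapse = "")) {
      consensus_ok <- FALSE
      break
    }
  }
  crit <- c(depth = depth_ratio > cfg$min_depth_ratio,
            anchoring = min(pe_span) >= cfg$min_pe_anchor &&
              min(mp_span) >= cfg$min_mp_anchor,
            consensus = consensus_ok)
  list(status = if (all(crit)) "accepted" else "rejected",
       criteria = crit, depth_ratio = depth_ratio,
       pe_spanning = as.integer(min(pe_span)),
       mp_spanning = as.integer(min(mp_span)),
       consensus_consistent = consensus_ok)
}
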