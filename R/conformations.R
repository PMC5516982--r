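# Repeat-mediated recombination: segment model of the master circle and
# breadth-first enumeration of alternative conformations.
#
# A conformation is a set of circular molecules, each an ordered vector of
# oriented segment tokens ("+seg" / "-seg").  Recombination between a
# direct-repeat pair on one circle excises a sub-circle; between copies on
# two circles it fuses them; between an inverted pair it reverses the
# intervening arc.  Circles are canonicalised by rotation only (strand is
# preserved), which makes the two possible arc reversals of an inverted
# pair distinct states.

tok <- function(sign, id) paste0(sign, id)
tok_sign <- function(t) substr(t, 1L, 1L)
tok_id <- function(t) substr(t, 2L, nchar(t))
tok_flip <- function(t) paste0(ifelse(tok_sign(t) == "+", "-", "+"), tok_id(t))

# Reverse a path of oriented tokens (reverse order, flip orientations).
path_reverse <- function(p) rev(vapply(p, tok_flip, character(1)))

canonical_circle <- function(circle) {
  n <- length(circle)
  if (n == 0L) return(character(0))
  s <- paste(circle, collapse = "|")
  rots <- vapply(seq_len(n), function(r)
    paste(c(circle[r:n], if (r > 1L) circle[1:(r - 1L)]), collapse = "|"),
    character(1))
  best <- which(rots == min(rots))[1]
  circle[c(best:n, if (best > 1L) 1:(best - 1L))]
}

conformation_key <- function(conf) {
  keys <- vapply(conf$circles, function(cc)
    paste(canonical_circle(cc), collapse = "|"), character(1))
  paste(sort(keys), collapse = " // ")
}

new_conformation <- function(circles, provenance = list()) {
  circles <- lapply(circles, canonical_circle)
  structure(list(circles = circles, provenance = provenance),
            class = "Conformation")
}

#' @export
print.Conformation <- function(x, ...) {
  cat(sprintf("Conformation: %d circle(s)\n", length(x$circles)))
  for (i in seq_along(x$circles)) {
    cat(sprintf("  [%d] %s\n", i, paste(x$circles[[i]], collapse = " ")))
  }
  invisible(x)
}

#' Partition a master circle into repeat-bounded segments
#'
#' Segment boundaries are the repeat-copy endpoints; each repeat copy
#' becomes a segment sharing the family label, every maximal arc between
#' copies becomes a unique segment.
#'
#' @param master an `AnnotatedGenome` or plain sequence length is taken
#'   from; repeats are supplied separately.
#' @param repeats data.frame with columns `label`, `kind`
#'   ("inverted"/"direct"), `start`, `end`, `copy` ("a"/"b"); copy "b" of an
#'   inverted pair is the reverse-complement placement.
#' @return list with `segments` (table: id, start, end, length, is_repeat,
#'   label) and `conformation` (the initial single-circle state).
#' @export
segment_genome <- function(master, repeats) {
  L <- if (inherits(master, "AnnotatedGenome")) master$length else nchar(master)
  if (nrow(repeats) == 0L) {
    seg <- data.frame(id = "arc1", start = 1L, end = L, length = L,
                      is_repeat = FALSE, label = NA_character_,
                      copy = NA_character_, stringsAsFactors = FALSE)
    return(list(segments = seg,
                conformation = new_conformation(list("+arc1"))))
  }
  stopifnot(L >= max(repeats$end))
  r <- repeats[order(repeats$start), , drop = FALSE]
  if (any(r$start[-1L] <= r$end[-nrow(r)])) {
    stop("structural conflict: repeat copies overlap")
  }
  segs <- list(); circle <- character(0)
  n <- nrow(r)
  for (i in seq_len(n)) {
    lab <- r$label[i]
    segs[[length(segs) + 1L]] <- data.frame(
      id = lab, start = r$start[i], end = r$end[i],
      length = r$end[i] - r$start[i] + 1L, is_repeat = TRUE, label = lab,
      copy = r$copy[i], stringsAsFactors = FALSE)
    sign <- if (r$kind[i] == "inverted" && r$copy[i] == "b") "-" else "+"
    circle <- c(circle, tok(sign, lab))
    a_start <- r$end[i] + 1L
    a_end <- if (i < n) r$start[i + 1L] - 1L else r$start[1L] - 1L + L
    if (a_end >= a_start) {
      aid <- sprintf("arc%d", i)
      segs[[length(segs) + 1L]] <- data.frame(
        id = aid, start = ((a_start - 1L) %% L) + 1L,
        end = ((a_end - 1L) %% L) + 1L, length = a_end - a_start + 1L,
        is_repeat = FALSE, label = NA_character_, copy = NA_character_,
        stringsAsFactors = FALSE)
      circle <- c(circle, tok("+", aid))
    }
  }
  seg_tab <- do.call(rbind, segs)
  rownames(seg_tab) <- NULL
  list(segments = seg_tab,
       conformation = new_conformation(list(circle)))
}

# Occurrences of a repeat label in a conformation: list of (circle index,
# position, sign).
find_copies <- function(conf, label) {
  out <- list()
  for (ci in seq_along(conf$circles)) {
    cc <- conf$circles[[ci]]
    at <- which(vapply(cc, tok_id, character(1)) == label)
    for (p in at) {
      out[[length(out) + 1L]] <- list(circle = ci, pos = p,
                                      sign = tok_sign(cc[p]))
    }
  }
  out
}

#' Apply one repeat-mediated recombination event
#'
#' The action is determined by the geometry of the two copies: same circle
#' and same orientation excises a sub-circle (each product keeps one copy);
#' same circle and opposite orientation reverses an intervening arc (either
#' arc; `which_arc` selects); copies on two circles fuse them (the second
#' circle is flipped first if the orientations disagree).  The segment
#' multiset is conserved.
#'
#' @param conf a `Conformation`.
#' @param label repeat family label.
#' @param which_arc for opposite-orientation copies on one circle: 1
#'   reverses the arc between the copies, 2 the complementary arc.
#' @return a new `Conformation` with the event appended to `provenance`.
#' @export
apply_recombination <- function(conf, label, which_arc = 1L) {
  hits <- find_copies(conf, label)
  if (length(hits) < 2L) stop("event error: repeat copies not found in conformation")
  h1 <- hits[[1]]; h2 <- hits[[2]]
  circles <- conf$circles
  ev <- list(label = label)
  if (h1$circle == h2$circle) {
    cc <- circles[[h1$circle]]
    i <- min(h1$pos, h2$pos); j <- max(h1$pos, h2$pos)
    same_sign <- tok_sign(cc[i]) == tok_sign(cc[j])
    arc1 <- if (j > i + 1L) cc[(i + 1L):(j - 1L)] else character(0)
    arc2 <- c(if (j < length(cc)) cc[(j + 1L):length(cc)] else character(0),
              if (i > 1L) cc[1:(i - 1L)] else character(0))
    if (same_sign) {
      c1 <- c(cc[i], arc1)
      c2 <- c(cc[j], arc2)
      circles[[h1$circle]] <- NULL
      circles <- c(circles, list(c1), list(c2))
      ev$action <- "excision"
    } else {
      # reverse the chosen arc in place; reversing the inclusive sub-path
      # "copy .. arc .. copy" leaves the mutually-inverted copies unchanged
      # and flips the arc
      newc <- if (which_arc == 1L) {
        c(cc[i], path_reverse(arc1), cc[j], arc2)
      } else {
        c(cc[i], arc1, cc[j], path_reverse(arc2))
      }
      circles[[h1$circle]] <- newc
      ev$action <- "inversion"
    }
  } else {
    cc1 <- circles[[h1$circle]]; cc2 <- circles[[h2$circle]]
    rot <- function(cc, p) c(cc[p:length(cc)], if (p > 1L) cc[1:(p - 1L)])
    cc1 <- rot(cc1, h1$pos)
    cc2 <- rot(cc2, h2$pos)
    if (tok_sign(cc1[1]) != tok_sign(cc2[1])) {
      cc2 <- path_reverse(cc2)
      cc2 <- rot(cc2, length(cc2))  # bring the copy back to the front
    }
    fused <- c(cc1, cc2)
    keep <- setdiff(seq_along(circles), c(h1$circle, h2$circle))
    circles <- c(circles[keep], list(fused))
    ev$action <- "fusion"
  }
  new_conformation(circles, c(conf$provenance, list(ev)))
}

# Every applicable event from a conformation, as a list of new states.
neighbour_states <- function(conf, labels) {
  out <- list()
  for (label in labels) {
    hits <- find_copies(conf, label)
    if (length(hits) < 2L) next
    h1 <- hits[[1]]; h2 <- hits[[2]]
    same_circle <- h1$circle == h2$circle
    opposite <- h1$sign != h2$sign
    if (same_circle && opposite) {
      out[[length(out) + 1L]] <- apply_recombination(conf, label, 1L)
      out[[length(out) + 1L]] <- apply_recombination(conf, label, 2L)
    } else {
      out[[length(out) + 1L]] <- apply_recombination(conf, label)
    }
  }
  out
}

#' Enumerate conformations reachable by repeat-mediated recombination
#'
#' Breadth-first closure of [apply_recombination()] to depth `max_events`;
#' states are canonicalised by rotation only and the input state is
#' excluded from the result.
#'
#' @param master master sequence or `AnnotatedGenome` (for segment lengths).
#' @param repeats repeat table as in [segment_genome()].
#' @param max_events maximum number of recombination events (>= 1).
#' @return list with `states` (list of `Conformation`s), `keys`, `segments`
#'   and `n_alternatives`.
#' @export
enumerate_conformations <- function(master, repeats, max_events = 2L) {
  stopifnot(max_events >= 1L)
  sg <- segment_genome(master, repeats)
  labels <- unique(repeats$label)
  start <- sg$conformation
  start_key <- conformation_key(start)
  seen <- stats::setNames(list(start), start_key)
  frontier <- list(start)
  for (d in seq_len(max_events)) {
    nxt <- list()
    for (conf in frontier) {
      for (nb in neighbour_states(conf, labels)) {
        k <- conformation_key(nb)
        if (!k %in% names(seen)) {
          seen[[k]] <- nb
          nxt[[length(nxt) + 1L]] <- nb
        }
      }
    }
    frontier <- nxt
    if (!length(frontier)) break
  }
  keys <- setdiff(names(seen), start_key)
  list(states = seen[keys], keys = keys, segments = sg$segments,
       n_alternatives = length(keys))
}

#' Gene content and length of each circle in a conformation
#'
#' Every gene is assigned to the circle carrying the segment its start lies
#' in; genes spanning a recombination junction (i.e. crossing a segment
#' boundary into a segment on another circle) are reported as split.
#'
#' @param conf a `Conformation`.
#' @param segments segment table from [segment_genome()].
#' @param annotations feature table with `type == "gene"` rows (`gene`,
#'   `start`, `end`).
#' @return data.frame: circle, length_bp, genes (comma-separated), split
#'   (comma-separated genes crossing junctions).
#' @export
subcircle_gene_content <- function(conf, segments, annotations) {
  genes <- annotations[annotations$type == "gene", , drop = FALSE]
  seg_of <- function(pos) {
    wraps <- segments$end < segments$start
    hit <- which((!wraps & segments$start <= pos & segments$end >= pos) |
                   (wraps & (segments$start <= pos | segments$end >= pos)))
    if (length(hit)) segments$id[hit[1]] else NA_character_
  }
  circle_of_seg <- function(seg) {
    for (ci in seq_along(conf$circles)) {
      ids <- vapply(conf$circles[[ci]], tok_id, character(1))
      if (seg %in% ids) return(ci)
    }
    NA_integer_
  }
  out <- data.frame(circle = seq_along(conf$circles),
                    length_bp = vapply(conf$circles, function(cc) {
                      ids <- vapply(cc, tok_id, character(1))
                      sum(segments$length[match(ids, segments$id)])
                    }, numeric(1)),
                    genes = "", split = "", stringsAsFactors = FALSE)
  for (i in seq_len(nrow(genes))) {
    s1 <- seg_of(genes$start[i]); s2 <- seg_of(genes$end[i])
    c1 <- if (!is.na(s1)) circle_of_seg(s1) else NA_integer_
    c2 <- if (!is.na(s2)) circle_of_seg(s2) else NA_integer_
    if (!is.na(c1) && !is.na(c2) && c1 == c2) {
      out$genes[c1] <- paste0(out$genes[c1],
                              if (nzchar(out$genes[c1])) ",", genes$gene[i])
    } else if (!is.na(c1)) {
      out$split[c1] <- paste0(out$split[c1],
                              if (nzchar(out$split[c1])) ",", genes$gene[i])
    }
  }
  out
}
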