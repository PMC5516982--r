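# Readers/writers for the standard formats used across the pipeline.
# All external coordinates are 1-based inclusive (GFF convention).

#' Read a FASTA file
#' @param path file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read a FASTQ file
#' @param path file path.
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write reads to FASTQ
#'
#' Qualities are constant (the simulator does not model quality scores).
#'
#' @param reads named character vector of read sequences.
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads)
  q <- Biostrings::PhredQuality(vapply(nchar(reads), function(n)
    paste(rep("I", n), collapse = ""), character(1)))
  y <- Biostrings::QualityScaledDNAStringSet(x, q)
  Biostrings::writeXStringSet(y, filepath = path, format = "fastq",
                              qualities = q)
  invisible(path)
}

# Canonical feature-table columns used throughout the package.
feature_columns <- function() {
  c("type", "id", "gene", "start", "end", "strand", "kind", "label",
    "exon_rank", "note")
}

empty_features <- function() {
  data.frame(type = character(0), id = character(0), gene = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             kind = character(0), label = character(0),
             exon_rank = integer(0), note = character(0),
             stringsAsFactors = FALSE)
}

as_features <- function(df) {
  need <- feature_columns()
  ints <- c("start", "end", "exon_rank")
  for (cn in setdiff(need, names(df))) {
    df[[cn]] <- if (cn %in% ints) NA_integer_ else NA_character_
  }
  for (cn in need) {
    df[[cn]] <- if (cn %in% ints) as.integer(df[[cn]]) else as.character(df[[cn]])
  }
  rownames(df) <- NULL
  df[, need, drop = FALSE]
}

gff_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x
}

gff_unescape <- function(x) {
  x <- gsub("%3D", "=", x, fixed = TRUE)
  x <- gsub("%3B", ";", x, fixed = TRUE)
  x <- gsub("%25", "%", x, fixed = TRUE)
  x
}

#' Write a feature table to GFF3
#'
#' Features whose `end` exceeds the genome length are taken to span the
#' circular origin and are written as two parts sharing one `ID`; the reader
#' reconstructs them.
#'
#' @param features feature data.frame (see [build_genome()]).
#' @param path output path.
#' @param seqid sequence identifier (default "chrM").
#' @param genome_length circular genome length; `NA` disables origin wrapping.
#' @param header extra `##` header lines.
#' @export
write_gff3 <- function(features, path, seqid = "chrM", genome_length = NA,
                       header = character(0)) {
  f <- as_features(features)
  lines <- c("##gff-version 3", header)
  for (i in seq_len(nrow(f))) {
    r <- f[i, ]
    attrs <- c(
      if (!is.na(r$id)) paste0("ID=", gff_escape(r$id)),
      if (!is.na(r$gene)) paste0("gene=", gff_escape(r$gene)),
      if (!is.na(r$kind)) paste0("kind=", gff_escape(r$kind)),
      if (!is.na(r$label)) paste0("label=", gff_escape(r$label)),
      if (!is.na(r$exon_rank)) paste0("exon_rank=", r$exon_rank),
      if (!is.na(r$note)) paste0("note=", gff_escape(r$note))
    )
    astr <- if (length(attrs)) paste(attrs, collapse = ";") else "."
    spans_origin <- !is.na(genome_length) && r$end > genome_length
    if (spans_origin) {
      p1 <- sprintf("%s\tmitocircle\t%s\t%d\t%d\t.\t%s\t.\t%s", seqid, r$type,
                    r$start, genome_length, r$strand %||% ".", paste0(astr, ";part=1of2"))
      p2 <- sprintf("%s\tmitocircle\t%s\t%d\t%d\t.\t%s\t.\t%s", seqid, r$type,
                    1L, r$end - genome_length, r$strand, paste0(astr, ";part=2of2"))
      lines <- c(lines, p1, p2)
    } else {
      lines <- c(lines, sprintf("%s\tmitocircle\t%s\t%d\t%d\t.\t%s\t.\t%s",
                                seqid, r$type, r$start, r$end,
                                ifelse(is.na(r$strand), ".", r$strand), astr))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a GFF3 file into a feature table
#'
#' Two-part features sharing an `ID` (written by [write_gff3()] for
#' origin-spanning features) are merged back into a single row whose `end`
#' runs past the genome length.
#'
#' @param path file path.
#' @param genome_length circular genome length used to rejoin split features.
#' @return feature data.frame.
#' @export
read_gff3 <- function(path, genome_length = NA) {
  raw <- readLines(path)
  body <- raw[!startsWith(raw, "#") & nzchar(raw)]
  if (!length(body)) return(empty_features())
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 9L)
  if (length(bad)) {
    stop(sprintf("malformed GFF record at line %d of %s",
                 which(raw == body[bad[1]])[1], path))
  }
  m <- do.call(rbind, parts)
  get_attr <- function(a, key) {
    out <- rep(NA_character_, length(a))
    pat <- paste0("(?:^|;)", key, "=([^;]*)")
    mm <- regexpr(pat, a, perl = TRUE)
    ok <- mm > 0
    if (any(ok)) {
      vals <- regmatches(a, mm)
      out[ok] <- gff_unescape(sub(pat, "\\1", vals, perl = TRUE))
    }
    out
  }
  a <- m[, 9L]
  f <- data.frame(type = m[, 3L], id = get_attr(a, "ID"),
                  gene = get_attr(a, "gene"),
                  start = as.integer(m[, 4L]), end = as.integer(m[, 5L]),
                  strand = ifelse(m[, 7L] == ".", NA_character_, m[, 7L]),
                  kind = get_attr(a, "kind"), label = get_attr(a, "label"),
                  exon_rank = suppressWarnings(as.integer(get_attr(a, "exon_rank"))),
                  note = get_attr(a, "note"), stringsAsFactors = FALSE)
  part <- get_attr(a, "part")
  if (any(!is.na(part))) {
    if (is.na(genome_length)) {
      genome_length <- max(f$end)
    }
    keep <- rep(TRUE, nrow(f))
    for (id in unique(f$id[!is.na(part) & part == "1of2"])) {
      i1 <- which(!is.na(f$id) & f$id == id & part == "1of2")[1]
      i2 <- which(!is.na(f$id) & f$id == id & part == "2of2")[1]
      if (!is.na(i1) && !is.na(i2)) {
        f$end[i1] <- genome_length + f$end[i2]
        keep[i2] <- FALSE
      }
    }
    f <- f[keep, , drop = FALSE]
  }
  rownames(f) <- NULL
  f
}

#' Read/write tab-separated tables
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "#")
}

#' @rdname read_tsv
#' @param df data.frame to write.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GenBank flat file
#'
#' Minimal parser extracting the sequence and gene/CDS/tRNA/rRNA features
#' (with strand and `join(...)` exon intervals).  Intended for deposited
#' organellar records.
#'
#' @param path file path.
#' @return an `AnnotatedGenome` (list with `seq`, `length`, `features`).
#' @export
read_genbank <- function(path) {
  raw <- readLines(path)
  locus <- grep("^LOCUS", raw, value = TRUE)
  if (!length(locus)) stop("truncated GenBank record: no LOCUS line")
  declared <- suppressWarnings(as.integer(sub(".*?(\\d+)\\s+bp.*", "\\1", locus[1])))
  ori <- grep("^ORIGIN", raw)
  if (!length(ori)) stop("truncated GenBank record: no ORIGIN section")
  endrec <- grep("^//", raw)
  endrec <- if (length(endrec)) endrec[1] else length(raw) + 1L
  seq_lines <- raw[(ori[1] + 1L):(endrec - 1L)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!is.na(declared) && nchar(seq) != declared) {
    stop(sprintf("GenBank record length %d does not match LOCUS-declared %d",
                 nchar(seq), declared))
  }
  featstart <- grep("^FEATURES", raw)
  feats <- empty_features()
  if (length(featstart)) {
    block <- raw[(featstart[1] + 1L):(ori[1] - 1L)]
    # feature lines start at column 6; qualifiers at column 22
    is_key <- grepl("^\\s{5}\\S", block)
    idx <- which(is_key)
    rows <- list()
    for (j in seq_along(idx)) {
      i <- idx[j]
      key <- sub("^\\s+(\\S+).*", "\\1", block[i])
      if (!key %in% c("gene", "CDS", "tRNA", "rRNA")) next
      to <- if (j < length(idx)) idx[j + 1L] - 1L else length(block)
      loc <- sub("^\\s+\\S+\\s+", "", block[i])
      k <- i + 1L
      while (k <= to && !grepl("^\\s+/", block[k])) {
        loc <- paste0(loc, gsub("\\s", "", block[k])); k <- k + 1L
      }
      quals <- paste(block[k:to], collapse = " ")
      gene <- if (grepl("/gene=", quals)) sub('.*?/gene="?([^"\\s]+)"?.*', "\\1", quals) else NA_character_
      strand <- if (grepl("complement", loc)) "-" else "+"
      nums <- gsub("[^0-9,.]", "", gsub("\\.\\.", ",", loc))
      pieces <- strsplit(nums, ",")[[1]]
      pieces <- suppressWarnings(as.integer(pieces[nzchar(pieces)]))
      if (length(pieces) < 2L || anyNA(pieces)) next
      ivs <- matrix(pieces, ncol = 2L, byrow = TRUE)
      for (e in seq_len(nrow(ivs))) {
        rows[[length(rows) + 1L]] <- data.frame(
          type = if (key == "CDS") "exon" else key, id = paste0(key, "_", j),
          gene = gene, start = ivs[e, 1L], end = ivs[e, 2L], strand = strand,
          kind = switch(key, CDS = "protein", tRNA = "tRNA", rRNA = "rRNA", "gene"),
          label = NA_character_, exon_rank = e, note = NA_character_,
          stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) feats <- do.call(rbind, rows)
  }
  structure(list(seq = seq, length = nchar(seq), features = as_features(feats),
                 circular = TRUE),
            class = "AnnotatedGenome")
}

#' GC content of a sequence
#' @param seq a DNA string.
#' @return fraction in \[0,1\].
#' @export
gc_content <- function(seq) {
  b <- strsplit(toupper(seq), "")[[1]]
  mean(b %in% c("G", "C"))
}
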