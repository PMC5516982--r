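# Umbrella pipeline: recruit -> finish -> conformations -> screens ->
# edit-call, mirroring the staged finishing of a plant mitochondrial
# master circle.

pkg_version <- function() {
  tryCatch(as.character(utils::packageVersion("mitocircle")),
           error = function(e) "0.0.0")
}

config_digest <- function(config) {
  # order-stable digest of the analysis configuration (the output directory
  # is incidental and excluded so reruns are byte-identical)
  config <- config[setdiff(names(config), "outdir")]
  s <- paste(utils::capture.output(utils::str(config[order(names(config))])),
             collapse = "\n")
  sprintf("%08x", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% .Machine$integer.max)
}

stamp_lines <- function(config, seed) {
  c(sprintf("# mitocircle %s", pkg_version()),
    sprintf("# config=%s seed=%s", config_digest(config), seed))
}

write_stamped_tsv <- function(df, path, config, seed) {
  con <- file(path, "w")
  writeLines(stamp_lines(config, seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Run the full pipeline on files
#'
#' Executes chloroplast-read subtraction, contig baiting and read
#' recruitment, master-circle finishing, conformation enumeration,
#' annotation screens and editing-site calling, writing per-stage reports
#' into `config$outdir`.  Missing inputs fail before any computation.
#'
#' @param config list with elements: `outdir`, `seed`, `contigs` (FASTA),
#'   `pe1`,`pe2`,`mp1`,`mp2` (FASTQ), `rna` (FASTQ), `cpdna` (FASTA),
#'   `reference_genes` (FASTA), `genome_fasta` + `gene_models` (FASTA/GFF3
#'   coordinate frame for the RNA stages), and optional per-stage config
#'   blocks `recruitment`, `finisher`, `screens`, `editing`, plus
#'   `max_events` (default 2).
#' @return list of per-stage results (also serialised to
#'   `outdir/summary.json`).
#' @export
run_pipeline <- function(config) {
  needed <- c("outdir", "contigs", "pe1", "pe2", "mp1", "mp2", "rna",
              "cpdna", "reference_genes", "genome_fasta", "gene_models")
  miss <- setdiff(needed, names(config))
  if (length(miss)) {
    stop("configuration error: missing fields: ", paste(miss, collapse = ", "))
  }
  paths <- unlist(config[setdiff(needed, "outdir")])
  absent <- paths[!file.exists(paths)]
  if (length(absent)) {
    stop("configuration error: missing input file(s): ",
         paste(absent, collapse = ", "))
  }
  seed <- config$seed %||% 1L
  set.seed(seed)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  rcfg <- do.call(recruitment_config, config$recruitment %||% list())
  fcfg <- do.call(finisher_config, config$finisher %||% list())
  scfg <- do.call(screen_config, config$screens %||% list())
  ecfg <- do.call(editing_config, config$editing %||% list())
  logf <- file.path(config$outdir, "pipeline.log")
  logmsg <- function(stage, msg) {
    line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
    message(line)
    cat(line, "\n", file = logf, append = TRUE)
  }
  run_stage <- function(stage, expr) {
    logmsg(stage, "start")
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
    logmsg(stage, "done")
    res
  }
  # inputs
  contigs <- read_fasta(config$contigs)
  cpdna <- read_fasta(config$cpdna)[[1]]
  genes_ref <- read_fasta(config$reference_genes)
  pe <- load_pair(config$pe1, config$pe2, pe_layout(0L))
  mp <- load_pair(config$mp1, config$mp2, mp_layout(0L))
  rna <- new_readset(read_fastq(config$rna), NULL, data.frame(), rna_layout(0L))
  genome_seq <- read_fasta(config$genome_fasta)[[1]]
  feats <- read_gff3(config$gene_models, genome_length = nchar(genome_seq))
  genome <- structure(list(seq = genome_seq, length = nchar(genome_seq),
                           features = feats, circular = TRUE),
                      class = "AnnotatedGenome")

  recruit <- run_stage("recruit", {
    pe_f <- filter_plastid_reads(pe, cpdna, rcfg)
    mp_f <- filter_plastid_reads(mp, cpdna, rcfg)
    baited <- bait_contigs(contigs, genes_ref, rcfg)
    list(pe = recruit_reads(pe_f, baited, rcfg),
         mp = recruit_reads(mp_f, baited, rcfg),
         baited = names(baited),
         profile = coverage_profile(contigs, pe_f, rcfg),
         # short mate-pair reads fit inside short collapsed-repeat contigs,
         # so the copy-number profile is taken from the MP library
         profile_mp = coverage_profile(contigs, mp_f, rcfg))
  })
  finish <- run_stage("finish", {
    prof <- recruit$profile_mp
    joins <- find_terminal_overlaps(contigs, fcfg)
    # copy number from two independent signals: a coverage peak, or the
    # overlap-graph structure (a collapsed repeat joins two different
    # neighbours at each end; depth on short repeats is Poisson-noisy)
    deg <- function(ct, e) sum((joins$a == ct & joins$a_end == e) |
                                 (joins$b == ct & joins$b_end == e))
    structural <- vapply(names(contigs), function(ct)
      max(1L, min(deg(ct, "L"), deg(ct, "R"))), integer(1))
    depth_based <- stats::setNames(ifelse(prof$peak, 2L, 1L), prof$contig)
    copy_number <- pmax(depth_based[names(contigs)], structural)
    graph <- build_scaffold_graph(contigs, joins, recruit$mp, fcfg,
                                  copy_number = copy_number)
    mc <- select_master_circle(graph, fcfg)
    list(graph_stats = graph_stats(graph), mc = mc)
  })
  if (finish$mc$status == "ok") {
    write_fasta(c(master_circle = finish$mc$sequence),
                file.path(config$outdir, "mc.fasta"))
  }
  screens <- run_stage("screens", {
    target <- if (finish$mc$status == "ok") finish$mc$sequence else genome_seq
    reps <- find_repeats(target, scfg)
    mtpt <- find_plastid_insertions(target, cpdna, scfg)
    orfs <- find_orfs(target, scfg)
    list(repeats = reps, plastid = mtpt, orfs = orfs)
  })
  confs <- run_stage("conformations", {
    long <- screens$repeats[screens$repeats$length > fcfg$long_repeat_bp, ,
                            drop = FALSE]
    if (nrow(long)) {
      reps <- do.call(rbind, lapply(seq_len(nrow(long)), function(i) {
        data.frame(label = sprintf("R%d", i),
                   kind = rep(long$kind[i], 2L),
                   start = c(long$q_start[i], long$s_start[i]),
                   end = c(long$q_end[i], long$s_end[i]),
                   copy = c("a", "b"), stringsAsFactors = FALSE)
      }))
      target_len <- if (finish$mc$status == "ok") nchar(finish$mc$sequence)
      else nchar(genome_seq)
      enumerate_conformations(paste(rep("N", target_len), collapse = ""),
                              reps, max_events = config$max_events %||% 2L)
    } else {
      list(states = list(), keys = character(0), n_alternatives = 0L)
    }
  })
  editing <- run_stage("edit-call", {
    aln <- filter_rna_reads(rna, genome, ecfg)
    sites <- call_editing_sites(genome = genome, cfg = ecfg, aln = aln,
                                reads = rna)
    breadth <- coverage_breadth(genome, aln)
    expr <- data.frame(gene = names(aln$counts),
                       unique_reads = as.integer(aln$counts),
                       length_bp = as.integer(aln$gene_lengths),
                       rpkm = ifelse(aln$total_unique > 0,
                                     rpkm(aln$gene_lengths, aln$counts,
                                          aln$total_unique), 0))
    list(sites = sites, breadth = breadth, expression = expr)
  })
  write_stamped_tsv(editing$sites, file.path(config$outdir, "editing_sites.tsv"),
                    config, seed)
  write_stamped_tsv(editing$expression, file.path(config$outdir, "expression.tsv"),
                    config, seed)
  summary <- list(version = pkg_version(), config_digest = config_digest(config),
                  seed = seed,
                  recruit = list(pe_kept = length(recruit$pe),
                                 mp_kept = length(recruit$mp),
                                 baited = recruit$baited),
                  graph = finish$graph_stats,
                  mc = list(status = finish$mc$status,
                            length = if (finish$mc$status == "ok")
                              nchar(finish$mc$sequence) else NA,
                            n_count = finish$mc$n_count),
                  conformations = confs$n_alternatives,
                  screens = list(n_repeats = nrow(screens$repeats),
                                 plastid_bp = screens$plastid$total_bp,
                                 n_orfs = nrow(screens$orfs)),
                  editing = list(n_sites = nrow(editing$sites),
                                 breadth_fraction = editing$breadth$fraction))
  jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(recruit = recruit, finish = finish, screens = screens,
                 conformations = confs, editing = editing, summary = summary))
}

# Load a FASTQ pair as a ReadSet (ids from read names, "/1"/"/2" stripped).
load_pair <- function(p1, p2, layout) {
  r1 <- read_fastq(p1)
  r2 <- read_fastq(p2)
  stopifnot(length(r1) == length(r2))
  ids <- sub("/1$", "", names(r1))
  meta <- data.frame(id = ids, source = NA_character_, stringsAsFactors = FALSE)
  new_readset(r1, r2, meta, layout)
}
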