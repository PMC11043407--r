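write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Run the full synthetic discovery pipeline
#'
#' Generates every input with the seeded synthetic-data generators, runs all
#' analysis stages (locus mining, tracrRNA/sgRNA inference, PAM discovery,
#' cut-site calling, genome scanning, SNV targetability) and writes their
#' reports under \code{out_dir}. All randomness derives from named streams of
#' the single seed, so two runs with the same seed produce byte-identical
#' output files.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Global seed.
#' @param config A \code{run_config}.
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(out_dir, seed = 1L, config = default_config(seed)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  cfgs <- config$synthetic
  cfgm <- config$mining
  cfgt <- config$tracr
  cfgp <- config$pam

  ## 1. synthetic MAG-like genome -> mining
  gen <- make_crispr_genome(n_loci = cfgs$n_loci,
                            background_len = cfgs$background_len, seed = seed)
  write_fasta(gen$contigs, p("contigs.fa"))
  write_gff(gen$features, p("annotations.gff3"))
  write_truth(gen$truth, p("genome.truth.json"))

  contigs <- read_fasta(p("contigs.fa"))
  features <- read_gff(p("annotations.gff3"))
  arrays <- list()
  for (i in seq_len(nrow(contigs)))
    arrays <- c(arrays, detect_crispr_arrays(contigs[i, , drop = FALSE], cfgm))
  loci <- assemble_loci(arrays, features, cfgm$max_locus_gap)
  kept <- filter_loci(loci, cfgm$min_cas9_aa, cfgm$max_cas9_aa, cfgm$min_spacers)
  kept <- dedupe_by_coverage(kept, domain_spans = list(),
                             deletion_min_aa = cfgm$deletion_min_aa)
  write_tsv(data.frame(
    contig = vapply(arrays, `[[`, "", "contig_id"),
    start = vapply(arrays, `[[`, 0L, "start"),
    end = vapply(arrays, `[[`, 0L, "end"),
    repeat_consensus = vapply(arrays, `[[`, "", "repeat_consensus"),
    n_repeats = vapply(arrays, `[[`, 0L, "n_repeats"),
    n_spacers = vapply(arrays, `[[`, 0L, "n_spacers")), p("arrays.tsv"))
  write_tsv(locus_report(loci, kept), p("loci.tsv"))

  ## 2. tracrRNA inference and sgRNA scaffolds for surviving loci
  tracr_rows <- list()
  for (lc in kept) {
    seqrow <- contigs[contigs$id == lc$array$contig_id, , drop = FALSE]
    res <- infer_tracr_for_locus(seqrow, lc, cfgt)
    if (!is.null(res)) tracr_rows[[length(tracr_rows) + 1L]] <- res
  }
  tracr_tab <- if (length(tracr_rows)) do.call(rbind, tracr_rows)
  else data.frame()
  write_tsv(tracr_tab, p("tracr.tsv"))

  ## 3. randomized-PAM library -> consensus and cut site
  design <- pam_library_design()
  lib <- make_pam_library(design, builtin_schemes()$cocas9$patterns,
                          cleavage_model(cfgs$p_match, cfgs$p_background,
                                         cfgs$error_rate),
                          n_reads = cfgs$n_reads, seed = seed)
  write_fastq(lib$cleaved, p("cleaved.fastq"))
  write_fastq(lib$control, p("control.fastq"))
  write_truth(lib$truth, p("pamlib.truth.json"))
  cl <- extract_pams(read_fastq(p("cleaved.fastq")), design,
                     cfgp$max_anchor_mismatch)
  co <- extract_pams(read_fastq(p("control.fastq")), design,
                     cfgp$max_anchor_mismatch)
  prof <- position_profile(cl)
  write_tsv(data.frame(base = rownames(prof$freq), round(prof$freq, 6)),
            p("pam.profile.tsv"))
  posn <- select_informative_positions(prof, cfgp$k_informative)
  en <- pam_enrichment(cl, co, posn, cfgp$pseudocount)
  write_tsv(data.frame(en, check.names = FALSE), p("pam.enrichment.tsv"))
  cons <- call_consensus(en, cfgp$consensus_tau, pam_len = cfgp$pam_len)
  writeLines(cons$patterns_full, p("pam.consensus.txt"))
  write_tsv(data.frame(metric = names(attr(cl, "qc")),
                       cleaved = as.integer(attr(cl, "qc")),
                       control = as.integer(attr(co, "qc"))), p("pam.qc.tsv"))

  frags <- make_cut_fragments(n = cfgs$cut_n, noise = cfgs$cut_noise,
                              seed = seed)
  cut <- infer_cut_site(frags, cfgp$min_support)
  write_truth(unclass(cut), p("cutsite.json"))

  ## 4. targeting range and SNV targetability
  schemes <- builtin_schemes()
  edmat <- make_editing_matrix(spacer_len = config$targeting$spacer_len,
                               seed = seed)
  win <- estimate_window(edmat, config$targeting$window_threshold)
  editors <- list(CoABE8e = schemes$cocas9, SaABE8e = schemes$sacas9)
  windows <- list(CoABE8e = win, SaABE8e = win)
  ref <- make_reference_and_snvs(length = cfgs$genome_len,
                                 gc_content = cfgs$gc_content,
                                 n_snv = cfgs$n_snv, schemes = editors,
                                 windows = windows, seed = seed)
  write_fasta(ref$genome, p("reference.fa"))
  write_tsv(ref$snvs, p("snvs.tsv"))
  write_truth(ref$truth, p("reference.truth.json"))

  scans <- lapply(schemes, function(s) scan_genome(ref$genome, s))
  write_tsv(data.frame(
    scheme = vapply(scans, `[[`, "", "scheme"),
    n_scanned = vapply(scans, `[[`, 0, "n_positions_scanned"),
    n_targetable = vapply(scans, `[[`, 0, "n_targetable_positions"),
    fraction = vapply(scans, `[[`, 0, "fraction_targetable")), p("scan.tsv"))

  verd <- sapply(names(editors), function(e) {
    vapply(seq_len(nrow(ref$snvs)), function(i) {
      ctx <- substr(ref$genome$sequence, ref$snvs$pos[i] - 50L,
                    ref$snvs$pos[i] + 50L)
      snv_targetable(ref$snvs[i, ], ctx, editors[[e]], windows[[e]])$targetable
    }, NA)
  })
  write_tsv(data.frame(ref$snvs, verd, check.names = FALSE), p("snv_targets.tsv"))
  excl <- exclusive_targetability(
    lapply(as.data.frame(verd), function(v) ref$snvs$id[v]),
    universe = nrow(ref$snvs))
  write_truth(list(fraction = as.list(excl$fraction),
                   solely_fraction = as.list(excl$solely_fraction),
                   union_fraction = excl$union_fraction), p("exclusive.json"))

  invisible(list(genome = gen, arrays = arrays, loci = loci, kept = kept,
                 tracr = tracr_tab, consensus = cons, cut = cut,
                 scans = scans, window = win, exclusive = excl))
}

locus_report <- function(loci, kept) {
  kept_ids <- vapply(kept, `[[`, "", "locus_id")
  if (!length(loci))
    return(data.frame(locus_id = character(0)))
  data.frame(
    locus_id = vapply(loci, `[[`, "", "locus_id"),
    contig = vapply(loci, function(l) l$array$contig_id, ""),
    array_start = vapply(loci, function(l) l$array$start, 0L),
    array_end = vapply(loci, function(l) l$array$end, 0L),
    repeat_consensus = vapply(loci, function(l) l$array$repeat_consensus, ""),
    n_spacers = vapply(loci, function(l) l$array$n_spacers, 0L),
    cas9_span = vapply(loci, function(l) paste0(l$cas9$start, "-", l$cas9$end), ""),
    cas1_span = vapply(loci, function(l) paste0(l$cas1$start, "-", l$cas1$end), ""),
    cas2_span = vapply(loci, function(l) paste0(l$cas2$start, "-", l$cas2$end), ""),
    cas9_aa = vapply(loci, function(l)
      as.numeric(l$cas9$attributes[[1]]$protein_length_aa %||% NA_real_), 0),
    coverage = vapply(loci, function(l) l$coverage %||% NA_real_, 0),
    passed_filters = vapply(loci, `[[`, "", "locus_id") %in% kept_ids)
}

# anti-repeat search on both locus flanks, candidate construction, FS
# scaffold assembly, fold and module check; returns the best passing row
# (or the best-scoring failing row, marked) for the locus report
infer_tracr_for_locus <- function(contig_row, locus, cfgt) {
  contig <- contig_row$sequence[1L]
  L <- nchar(contig)
  arr <- locus$array
  span_all <- range(c(arr$start, arr$end, locus$cas1$start, locus$cas1$end,
                      locus$cas2$start, locus$cas2$end, locus$cas9$start,
                      locus$cas9$end))
  params <- scoring_params(word_size = cfgt$word_size,
                           gap_open = cfgt$gap_open,
                           gap_extend = cfgt$gap_extend,
                           evalue_max = cfgt$evalue_max,
                           flank_window = cfgt$flank_window)
  hits <- list()
  # the search region spans the locus interior (between components) plus
  # flank_window bp on each side, excluding the array itself
  ws <- max(1L, span_all[1L] - cfgt$flank_window)
  we <- min(L, span_all[2L] + cfgt$flank_window)
  h <- find_anti_repeats(substr(contig, ws, we), arr$repeat_consensus,
                         params, array_span = c(arr$start, arr$end),
                         flank_offset = ws, contig_id = contig_row$id[1L])
  if (!nrow(h)) return(NULL)
  cands <- build_tracr_candidates(contig, h, max_len = cfgt$max_candidate_len,
                                  min_aligned_frac = cfgt$min_aligned_frac)
  best <- NULL
  for (cand in cands) {
    sc <- tryCatch(assemble_sgrna(arr$repeat_consensus, cand, form = "FS",
                                  tetraloop = cfgt$tetraloop,
                                  trim_len = cfgt$trim_len),
                   error = function(e) NULL)
    if (is.null(sc)) next
    pr <- fold(sc$sequence, band = cfgt$band_pairs)
    cm <- check_modules(sc, pr, cfgt$duplex_min_bp, cfgt$nexus_min_stem,
                        cfgt$nexus_max_dist, cfgt$hairpin3_window)
    row <- data.frame(
      locus_id = locus$locus_id,
      anti_start = cand$hit$start, anti_end = cand$hit$end,
      anti_strand = cand$hit$strand, score = cand$hit$score,
      evalue = signif(cand$hit$evalue, 6),
      terminator = if (is.character(cand$terminator)) "polyT"
      else sprintf("%d-%d", cand$span[1L] +
                     (cand$terminator$start - 1L), cand$span[2L]),
      scaffold = sc$sequence,
      modules_pass = cm$pass,
      missing = paste(cm$reasons, collapse = ","),
      structure = pr$dot_bracket[1L])
    if (cm$pass) return(row)
    if (is.null(best)) best <- row
  }
  best
}
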