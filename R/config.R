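#' Default run configuration
#'
#' One nested list with a section per pipeline stage, serializable to YAML.
#' Values are the package defaults; \code{read_config} merges a user file on
#' top of them and validates ranges.
#'
#' @param seed Global seed recorded in the configuration.
#' @return A named list of class \code{run_config}.
#' @export
default_config <- function(seed = 1L) {
  cfg <- list(
    seed = as.integer(seed),
    mining = list(
      min_repeats = 3L, repeat_min = 23L, repeat_max = 47L,
      spacer_min = 26L, spacer_max = 50L, seed_word = 8L,
      max_repeat_mismatches = 1L,
      max_locus_gap = 10000L,
      min_cas9_aa = 950L, max_cas9_aa = 1100L, min_spacers = 6L,
      deletion_min_aa = 5L
    ),
    tracr = list(
      match = 1L, mismatch = 1L, gap_open = 2L, gap_extend = 1L,
      word_size = 8L, evalue_max = 1.0, flank_window = 3000L,
      tetraloop = "GAAA", trim_len = 12L,
      duplex_min_bp = 8L, nexus_min_stem = 2L, nexus_max_dist = 6L,
      hairpin3_window = 60L, band_pairs = 1L, max_candidate_len = 200L,
      min_aligned_frac = 0.7
    ),
    pam = list(
      pam_len = 8L, max_anchor_mismatch = 1L, pseudocount = 1,
      k_informative = 4L, consensus_tau = 0.2, min_support = 10L
    ),
    targeting = list(
      spacer_len = 23L, cut_offset = 3L, window_threshold = 0.10
    ),
    synthetic = list(
      n_loci = 2L, background_len = 30000L, repeat_len = 36L,
      n_spacers = 24L, cas9_aa = 1004L, tracr_mismatches = 2L,
      n_reads = 100000L, p_match = 0.9, p_background = 0.02,
      error_rate = 0.001, genome_len = 100000L, gc_content = 0.41,
      n_snv = 100L, cut_n = 200L, cut_noise = 0.1
    )
  )
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Read a YAML run configuration
#'
#' Values found in the file override the defaults section by section; unknown
#' keys are rejected and numeric parameters are checked against their
#' documented ranges.
#'
#' @param path Path to a YAML config file.
#' @return A validated \code{run_config}.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  user <- yaml::read_yaml(path)
  cfg <- unclass(default_config())
  for (sec in names(user)) {
    if (!sec %in% names(cfg)) stop("unknown config section: ", sec)
    if (sec == "seed") { cfg$seed <- as.integer(user$seed); next }
    for (k in names(user[[sec]])) {
      if (!k %in% names(cfg[[sec]])) stop("unknown config key: ", sec, "/", k)
      cfg[[sec]][[k]] <- user[[sec]][[k]]
    }
  }
  class(cfg) <- c("run_config", "list")
  validate_config(cfg)
  cfg
}

#' Write a run configuration to YAML
#' @param cfg A \code{run_config}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

validate_config <- function(cfg) {
  chk <- function(ok, what) if (!ok) stop("config out of range: ", what)
  m <- cfg$mining
  chk(m$min_repeats >= 2, "mining/min_repeats >= 2")
  chk(m$repeat_min > 0 && m$repeat_min <= m$repeat_max, "mining repeat bounds")
  chk(m$spacer_min > 0 && m$spacer_min <= m$spacer_max, "mining spacer bounds")
  chk(m$max_locus_gap > 0, "mining/max_locus_gap > 0")
  chk(m$min_cas9_aa < m$max_cas9_aa, "mining cas9 length bounds")
  t <- cfg$tracr
  chk(t$word_size >= 4, "tracr/word_size >= 4")
  chk(t$gap_open > 0 && t$gap_extend > 0, "tracr gap penalties positive")
  chk(t$flank_window > 0, "tracr/flank_window > 0")
  p <- cfg$pam
  chk(p$pam_len >= 1, "pam/pam_len >= 1")
  chk(p$consensus_tau > 0 && p$consensus_tau <= 1, "pam/consensus_tau in (0,1]")
  s <- cfg$synthetic
  chk(s$p_background >= 0 && s$p_background < s$p_match && s$p_match <= 1,
      "synthetic cleavage probabilities: 0 <= p_background < p_match <= 1")
  chk(s$error_rate >= 0 && s$error_rate < 1, "synthetic/error_rate in [0,1)")
  chk(s$gc_content > 0 && s$gc_content < 1, "synthetic/gc_content in (0,1)")
  invisible(cfg)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config> seed:", x$seed, "\n")
  for (sec in setdiff(names(x), "seed"))
    cat(" ", sec, ":", length(x[[sec]]), "parameters\n")
  invisible(x)
}
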