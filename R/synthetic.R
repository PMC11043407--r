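GENERATOR_VERSION <- "1.0"

rand_dna <- function(rng, n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(rng$sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

rand_protein <- function(rng, n_aa) {
  paste(rng$sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n_aa,
                   replace = TRUE), collapse = "")
}

mutate_bases <- function(seq, positions, rng) {
  ch <- strsplit(seq, "")[[1]]
  for (p in positions) {
    alt <- setdiff(c("A", "C", "G", "T"), ch[p])
    ch[p] <- alt[rng$sample_int(3L, 1L)]
  }
  paste(ch, collapse = "")
}

# fixed structural elements planted downstream of the anti-repeat: a nexus
# stem-loop and a terminator hairpin with U-tract, joined by A linkers that
# do not pair with anything
TRACR_NEXUS <- "GCGGCTTCGGCCGC"
TRACR_TERMINATOR <- "GGCGCGCCTTCGGGCGCGCCTTTTTT"

#' Generate a synthetic MAG-like genome with planted CRISPR-Cas loci
#'
#' Builds contigs each carrying one planted locus (cas9, cas2, cas1 genes, a
#' tracrRNA between cas1 and the array, and a repeat/spacer array), plus
#' decoy contigs without loci (one plain, one with cas genes but no array),
#' and a machine-readable truth record for scoring recall and precision.
#' The tracrRNA is an imperfect reverse complement of the repeat
#' (\code{tracr_mismatches} substitutions placed away from the termini)
#' followed by a nexus stem-loop and a terminator hairpin with T-tract.
#'
#' @param n_loci Number of locus-bearing contigs.
#' @param background_len Contig length (bp).
#' @param seed Seed for the generator streams.
#' @param locus_spec A list of per-locus overrides, or a single list applied
#'   to all loci; recognized fields: \code{repeat_len} (36), \code{n_spacers}
#'   (24), \code{cas9_aa} (1004), \code{cas1_aa} (300), \code{cas2_aa} (100),
#'   \code{tracr_mismatches} (2), \code{coverage}, \code{drop} (character
#'   vector of components to omit, e.g. \code{"cas1"}), \code{array_cas_gap}
#'   (extra bp inserted between the cas genes and the rest; use > 10000 to
#'   build a gap-violating fixture).
#' @param n_decoys Number of decoy contigs (>= 2 gives one plain and one
#'   cas-genes-without-array decoy).
#' @return List: \code{contigs} (\code{sequence_set}), \code{features}
#'   (\code{feature_set}), \code{truth}.
#' @export
make_crispr_genome <- function(n_loci = 2L, background_len = 30000L, seed = 1L,
                               locus_spec = list(), n_decoys = 2L) {
  defaults <- list(repeat_len = 36L, n_spacers = 24L, cas9_aa = 1004L,
                   cas1_aa = 300L, cas2_aa = 100L, tracr_mismatches = 2L,
                   coverage = NULL, drop = character(0), array_cas_gap = 0L)
  per_locus <- if (length(locus_spec) && is.null(names(locus_spec)))
    locus_spec else rep(list(locus_spec), n_loci)
  if (length(per_locus) < n_loci)
    per_locus <- c(per_locus, rep(list(list()), n_loci - length(per_locus)))

  rng <- rng_stream(seed, "genome")
  contigs_id <- character(0)
  contigs_seq <- character(0)
  feats <- list()
  truth_loci <- list()

  for (i in seq_len(n_loci)) {
    spec <- utils::modifyList(defaults, per_locus[[i]])
    cid <- sprintf("contig%02d", i)
    sp_id <- sprintf("species%02d", i)
    rep_seq <- rand_dna(rng, spec$repeat_len)
    spacers <- vapply(seq_len(spec$n_spacers), function(k)
      rand_dna(rng, 30L + rng$sample_int(11L, 1L) - 1L), "")
    array_seq <- paste0(paste0(rep_seq, spacers, collapse = ""), rep_seq)
    n_repeats <- spec$n_spacers + 1L

    anti <- revcomp(rep_seq)
    if (spec$tracr_mismatches > 0L) {
      lo <- 9L; hi <- spec$repeat_len - 8L
      mmpos <- (lo:hi)[rng$sample_int(hi - lo + 1L, spec$tracr_mismatches)]
      anti <- mutate_bases(anti, mmpos, rng)
    }
    tracr_seq <- paste0(anti, "AA", TRACR_NEXUS, "AA", TRACR_TERMINATOR)

    genes <- list(
      cas9 = list(len = spec$cas9_aa * 3L + 3L, aa = spec$cas9_aa),
      cas2 = list(len = spec$cas2_aa * 3L + 3L, aa = spec$cas2_aa),
      cas1 = list(len = spec$cas1_aa * 3L + 3L, aa = spec$cas1_aa))
    genes <- genes[!names(genes) %in% spec$drop]
    gaps <- 200L + (rng$sample_int(400L, length(genes) + 1L) - 1L)

    parts <- list()
    spans <- list()
    pos <- 1L
    lead <- 1500L + rng$sample_int(1000L, 1L)
    parts[[length(parts) + 1L]] <- rand_dna(rng, lead); pos <- pos + lead
    gi <- 1L
    for (g in names(genes)) {
      parts[[length(parts) + 1L]] <- rand_dna(rng, genes[[g]]$len)
      spans[[g]] <- c(pos, pos + genes[[g]]$len - 1L)
      pos <- pos + genes[[g]]$len
      gap <- gaps[gi]; gi <- gi + 1L
      if (g == names(genes)[length(genes)] && spec$array_cas_gap > 0L)
        gap <- spec$array_cas_gap
      parts[[length(parts) + 1L]] <- rand_dna(rng, gap); pos <- pos + gap
    }
    parts[[length(parts) + 1L]] <- tracr_seq
    spans$tracr <- c(pos, pos + nchar(tracr_seq) - 1L)
    anti_span <- c(pos, pos + spec$repeat_len - 1L)
    term_off <- nchar(anti) + 2L + nchar(TRACR_NEXUS) + 2L
    term_span <- c(pos + term_off, pos + nchar(tracr_seq) - 1L)
    pos <- pos + nchar(tracr_seq)
    g2 <- 60L + rng$sample_int(60L, 1L)
    parts[[length(parts) + 1L]] <- rand_dna(rng, g2); pos <- pos + g2
    parts[[length(parts) + 1L]] <- array_seq
    spans$array <- c(pos, pos + nchar(array_seq) - 1L)
    pos <- pos + nchar(array_seq)
    tail_len <- background_len - (pos - 1L)
    if (tail_len < 0L) stop("background_len too short for the requested locus")
    parts[[length(parts) + 1L]] <- rand_dna(rng, tail_len)
    contig <- paste(parts, collapse = "")

    coverage <- spec$coverage %||% (10 + round(rng$runif(1L, 0, 40), 1))
    for (g in names(genes)) {
      feats[[length(feats) + 1L]] <- list(
        contig_id = cid, start = spans[[g]][1L], end = spans[[g]][2L],
        strand = "+", kind = g,
        attributes = list(ID = paste0(cid, "_", g), species_id = sp_id,
                          protein_length_aa = genes[[g]]$aa,
                          protein_sequence = rand_protein(rng, genes[[g]]$aa),
                          coverage = coverage))
    }
    max_gap <- max_component_gap(spans[c(intersect(names(genes), names(spans)),
                                         "array")])
    pass <- length(genes) == 3L &&
      spec$cas9_aa >= 950L && spec$cas9_aa < 1100L &&
      spec$n_spacers >= 6L && max_gap <= 10000L
    reason <- if (length(genes) < 3L) paste("missing", paste(spec$drop, collapse = ","))
    else if (spec$cas9_aa < 950L) "cas9 shorter than 950 aa"
    else if (spec$cas9_aa >= 1100L) "cas9 not shorter than 1100 aa"
    else if (spec$n_spacers < 6L) "5 or fewer spacers"
    else if (max_gap > 10000L) "component gap exceeds 10 kbp"
    else NA_character_
    truth_loci[[length(truth_loci) + 1L]] <- list(
      contig_id = cid, species_id = sp_id,
      array = list(start = spans$array[1L], end = spans$array[2L],
                   repeat_seq = rep_seq, spacers = spacers,
                   n_repeats = n_repeats, n_spacers = spec$n_spacers),
      genes = spans[names(genes)],
      tracr = list(span = spans$tracr, strand = "+",
                   anti_span = anti_span, terminator_span = term_span,
                   mismatches = spec$tracr_mismatches),
      coverage = coverage, expected_pass = pass, fail_reason = reason)
    contigs_id <- c(contigs_id, cid)
    contigs_seq <- c(contigs_seq, contig)
  }

  for (d in seq_len(n_decoys)) {
    cid <- sprintf("decoy%02d", d)
    contig <- rand_dna(rng, background_len)
    if (d == 2L) {
      # cas operon without any CRISPR array
      pos <- 5000L
      for (g in c("cas9", "cas1", "cas2")) {
        aa <- c(cas9 = 1004L, cas1 = 300L, cas2 = 100L)[[g]]
        len <- aa * 3L + 3L
        feats[[length(feats) + 1L]] <- list(
          contig_id = cid, start = pos, end = pos + len - 1L, strand = "+",
          kind = g,
          attributes = list(ID = paste0(cid, "_", g),
                            species_id = sprintf("decoy_sp%02d", d),
                            protein_length_aa = aa,
                            protein_sequence = rand_protein(rng, aa),
                            coverage = 20))
        pos <- pos + len + 500L
      }
    }
    contigs_id <- c(contigs_id, cid)
    contigs_seq <- c(contigs_seq, contig)
  }

  features <- feature_set(
    contig_id = vapply(feats, `[[`, "", "contig_id"),
    start = vapply(feats, `[[`, 0L, "start"),
    end = vapply(feats, `[[`, 0L, "end"),
    strand = vapply(feats, `[[`, "", "strand"),
    kind = vapply(feats, `[[`, "", "kind"),
    attributes = lapply(feats, `[[`, "attributes"))
  truth <- list(seed = seed, generator_version = GENERATOR_VERSION,
                n_loci = n_loci, n_decoys = n_decoys, loci = truth_loci)
  list(contigs = sequence_set(contigs_id, contigs_seq, moltype = "dna"),
       features = features, truth = truth)
}

max_component_gap <- function(spans) {
  spans <- spans[!vapply(spans, is.null, NA)]
  if (length(spans) < 2L) return(0L)
  g <- 0L
  for (a in seq_along(spans)) for (b in seq_along(spans)) {
    if (a >= b) next
    g <- max(g, interval_gap(spans[[a]][1L], spans[[a]][2L],
                             spans[[b]][1L], spans[[b]][2L]))
  }
  g
}

#' Cleavage model for the randomized-PAM library simulation
#'
#' @param p_match Cleavage (library retention) probability for PAMs matching
#'   the planted consensus.
#' @param p_background Background retention probability for all other PAMs.
#' @param error_rate Per-base substitution sequencing-error rate.
#' @return A list of class \code{cleavage_model}.
#' @export
cleavage_model <- function(p_match = 0.9, p_background = 0.02,
                           error_rate = 0.001) {
  stopifnot(p_background >= 0, p_background < p_match, p_match <= 1,
            error_rate >= 0, error_rate < 1)
  structure(list(p_match = p_match, p_background = p_background,
                 error_rate = error_rate), class = "cleavage_model")
}

# logical vector: does each row of the letter matrix match any full-length
# IUPAC pattern
match_any_pattern <- function(mat, patterns) {
  hit <- rep(FALSE, nrow(mat))
  for (p in patterns) {
    pl <- strsplit(p, "")[[1]]
    m <- rep(TRUE, nrow(mat))
    for (i in seq_along(pl)) {
      if (pl[i] == "N") next
      m <- m & mat[, i] %in% IUPAC_SETS[[pl[i]]]
    }
    hit <- hit | m
  }
  hit
}

#' Simulate cleaved and control randomized-PAM read libraries
#'
#' Control reads carry PAMs drawn uniformly over the 4^8 randomized space;
#' cleaved reads are accepted into the library with probability
#' \code{p_match} when the PAM matches any planted consensus pattern and
#' \code{p_background} otherwise (acceptance sampling stands in for the
#' digestion/ligation/PCR chain, which the downstream analysis only sees as
#' frequencies). Uniform per-base substitution errors are applied to the
#' finished reads.
#'
#' @param design A \code{pam_library_design}.
#' @param patterns Planted consensus patterns (full PAM length, IUPAC).
#' @param model A \code{cleavage_model}.
#' @param n_reads Reads per library (>= 1000).
#' @param seed Generator seed.
#' @return List: \code{cleaved}, \code{control} (\code{sequence_set}s with
#'   qualities) and \code{truth} (patterns, model, realized match fraction).
#' @export
make_pam_library <- function(design, patterns, model = cleavage_model(),
                             n_reads = 100000L, seed = 1L) {
  if (n_reads < 1000L) stop("n_reads must be at least 1000")
  pl <- design$pam_len
  stopifnot(all(nchar(patterns) == pl))
  bases <- c("A", "C", "G", "T")
  rng_ctrl <- rng_stream(seed, "pam_control")
  rng_clv <- rng_stream(seed, "pam_cleaved")
  rng_err <- rng_stream(seed, "pam_errors")

  control_pams <- matrix(bases[rng_ctrl$sample_int(4L, n_reads * pl, replace = TRUE)],
                         n_reads, pl)
  cleaved_pams <- matrix(character(0), 0, pl)
  n_match <- 0L
  while (nrow(cleaved_pams) < n_reads) {
    batch <- max(10000L, ceiling((n_reads - nrow(cleaved_pams)) /
                                   max(0.01, mean_accept(patterns, model, pl)) * 1.2))
    cand <- matrix(bases[rng_clv$sample_int(4L, batch * pl, replace = TRUE)],
                   batch, pl)
    hit <- match_any_pattern(cand, patterns)
    keep <- rng_clv$runif(batch) < ifelse(hit, model$p_match, model$p_background)
    acc <- cand[keep, , drop = FALSE]
    n_match <- n_match + sum(hit & keep)
    cleaved_pams <- rbind(cleaved_pams, acc)
  }
  n_match <- n_match - sum(match_any_pattern(
    cleaved_pams[-seq_len(n_reads), , drop = FALSE], patterns))
  cleaved_pams <- cleaved_pams[seq_len(n_reads), , drop = FALSE]

  assemble <- function(pams, rng, prefix) {
    n <- nrow(pams)
    proto <- strsplit(design$protospacer, "")[[1]]
    backb <- strsplit(design$backbone_context, "")[[1]]
    m <- cbind(matrix(proto, n, length(proto), byrow = TRUE), pams,
               matrix(backb, n, length(backb), byrow = TRUE))
    total <- length(m)
    nerr <- rng$rbinom(1L, total, model$error_rate)
    if (nerr > 0L) {
      idx <- rng$sample_int(total, nerr)
      shift <- rng$sample_int(3L, nerr, replace = TRUE)
      cur <- match(m[idx], bases)
      m[idx] <- bases[((cur - 1L + shift) %% 4L) + 1L]
    }
    reads <- do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
    sequence_set(sprintf("%s_%06d", prefix, seq_len(n)), reads,
                 moltype = "dna", quality = strrep("I", ncol(m)))
  }
  cleaved <- assemble(cleaved_pams, rng_err, "cleaved")
  control <- assemble(control_pams, rng_err, "control")
  truth <- list(seed = seed, generator_version = GENERATOR_VERSION,
                patterns = patterns, model = unclass(model),
                n_reads = n_reads, match_fraction = n_match / n_reads)
  list(cleaved = cleaved, control = control, truth = truth)
}

# expected acceptance probability of a random candidate PAM
mean_accept <- function(patterns, model, pl) {
  p_hit <- pattern_space_fraction(patterns, pl)
  p_hit * model$p_match + (1 - p_hit) * model$p_background
}

# fraction of the 4^pl PAM space matching any pattern (inclusion-exclusion
# by direct enumeration over the informative positions)
pattern_space_fraction <- function(patterns, pl) {
  non_n <- sort(unique(unlist(lapply(patterns, function(p) {
    which(strsplit(p, "")[[1]] != "N")
  }))))
  if (!length(non_n)) return(1)
  combos <- expand.grid(rep(list(c("A", "C", "G", "T")), length(non_n)),
                        stringsAsFactors = FALSE)
  hit <- rep(FALSE, nrow(combos))
  for (p in patterns) {
    pch <- strsplit(p, "")[[1]][non_n]
    m <- rep(TRUE, nrow(combos))
    for (i in seq_along(non_n))
      if (pch[i] != "N") m <- m & combos[[i]] %in% IUPAC_SETS[[pch[i]]]
    hit <- hit | m
  }
  mean(hit)
}

#' Simulate adapter-ligated cut-fragment end positions
#'
#' Per-strand end positions concentrate at the planted cut offset with
#' symmetric positional noise (fraction \code{noise} of reads displaced by
#' +/-1 bp). Overhang geometries displace the plus-strand mode.
#'
#' @param offset Cut offset (bp upstream of the PAM).
#' @param geometry \code{"blunt"}, \code{"five_prime"} or
#'   \code{"three_prime"}.
#' @param overhang Overhang length for non-blunt geometries.
#' @param n Reads per strand.
#' @param noise Fraction of reads displaced by one position.
#' @param seed Generator seed.
#' @return Data.frame (\code{strand}, \code{pos}) with a \code{truth}
#'   attribute.
#' @export
make_cut_fragments <- function(offset = 3L, geometry = c("blunt", "five_prime",
                                                         "three_prime"),
                               overhang = 1L, n = 200L, noise = 0.1,
                               seed = 1L) {
  geometry <- match.arg(geometry)
  rng <- rng_stream(seed, "cutsites")
  top_mode <- offset + if (geometry == "five_prime") overhang else 0L
  bot_mode <- offset + if (geometry == "three_prime") overhang else 0L
  draw <- function(mode) {
    mode + rng$sample(c(-1L, 0L, 1L), n, replace = TRUE,
                      prob = c(noise / 2, 1 - noise, noise / 2))
  }
  out <- data.frame(strand = rep(c("+", "-"), each = n),
                    pos = c(draw(top_mode), draw(bot_mode)))
  attr(out, "truth") <- list(seed = seed, generator_version = GENERATOR_VERSION,
                             offset = offset, geometry = geometry,
                             overhang = if (geometry == "blunt") 0L else overhang,
                             n_per_strand = n, noise = noise)
  out
}

#' Simulate an editing matrix with a planted window
#'
#' Guide-level A>G conversion fractions: in-window positions at \code{peak},
#' out-of-window at \code{off_window}, plus Gaussian guide-level noise
#' truncated to [0, 1].
#'
#' @param window Integer spacer positions forming the true window.
#' @param peak In-window mean editing fraction (>= 0.10).
#' @param off_window Out-of-window mean (< 0.10).
#' @param n_guides Number of guides (rows).
#' @param noise_sd Guide-level Gaussian noise.
#' @param spacer_len Number of spacer positions (columns).
#' @param seed Generator seed.
#' @return Matrix with a \code{truth} attribute.
#' @export
make_editing_matrix <- function(window = 4:8, peak = 0.4, off_window = 0.02,
                                n_guides = 10L, noise_sd = 0.03,
                                spacer_len = 23L, seed = 1L) {
  stopifnot(off_window >= 0, off_window < 0.10, peak >= 0.10, peak <= 1)
  rng <- rng_stream(seed, "editing")
  m <- matrix(off_window, n_guides, spacer_len,
              dimnames = list(sprintf("guide%02d", seq_len(n_guides)),
                              seq_len(spacer_len)))
  m[, window] <- peak
  if (noise_sd > 0)
    m <- m + matrix(rng$rnorm(length(m), 0, noise_sd), n_guides, spacer_len)
  m[m < 0] <- 0
  m[m > 1] <- 1
  attr(m, "truth") <- list(seed = seed, generator_version = GENERATOR_VERSION,
                           window = window, peak = peak,
                           off_window = off_window)
  m
}

#' Simulate a reference genome and SNV table with planted targetability
#'
#' Draws an i.i.d. genome at the requested GC content, places G>A and C>T
#' SNVs at well-separated positions, and for each (SNV, editor) pair plants
#' the intended verdict: positives get a PAM instantiated at a window
#' position on the appropriate strand; negatives are enforced by mutating a
#' discriminative PAM base wherever a chance match would make them
#' targetable. Verdicts are verified with \code{snv_targetable} before
#' returning.
#'
#' @param length Genome length (>= 10 kb).
#' @param gc_content Genome GC fraction.
#' @param n_snv Number of SNVs.
#' @param class_mix Probability that an SNV is G>A (vs C>T).
#' @param schemes Named list of \code{pam_scheme} (one per editor).
#' @param windows Named list of \code{editing_window} (same names).
#' @param seed Generator seed.
#' @param intended Optional n_snv x n_editor logical matrix of intended
#'   verdicts (default: each SNV is targetable by at most one editor, drawn
#'   uniformly over none/each editor).
#' @return List: \code{genome} (\code{sequence_set}), \code{snvs}
#'   (data.frame id, chrom, pos, ref, alt, class) and \code{truth} with the
#'   per-editor intended verdicts.
#' @export
make_reference_and_snvs <- function(length = 100000L, gc_content = 0.41,
                                    n_snv = 100L, class_mix = 0.5,
                                    schemes, windows, seed = 1L,
                                    intended = NULL) {
  if (length < 10000L) stop("genome length must be at least 10 kb")
  stopifnot(identical(sort(names(schemes)), sort(names(windows))))
  editors <- names(schemes)
  rng <- rng_stream(seed, "reference")
  margin <- 80L
  step <- (length - 2L * margin) %/% n_snv
  if (step < 130L) stop("n_snv exceeds placeable positions at this length")
  gch <- strsplit(rand_dna(rng, length, gc = gc_content), "")[[1]]
  pos <- margin + step * (seq_len(n_snv) - 1L) +
    rng$sample_int(step - 120L, n_snv, replace = TRUE)

  cls <- ifelse(rng$runif(n_snv) < class_mix, "G>A", "C>T")
  gch[pos] <- ifelse(cls == "G>A", "G", "C")
  if (is.null(intended)) {
    # at most one positive editor per SNV: overlapping editing windows make
    # simultaneously planting two editors' PAMs around one adenine
    # geometrically infeasible for most window draws
    pick <- rng$sample_int(base::length(editors) + 1L, n_snv, replace = TRUE) - 1L
    intended <- matrix(FALSE, n_snv, base::length(editors),
                       dimnames = list(NULL, editors))
    for (e in seq_along(editors)) intended[pick == e, e] <- TRUE
  }
  # per-position planting constraints: NA = free background; otherwise the
  # IUPAC symbol (plus-strand orientation) the planted feature requires there
  constraint <- rep(NA_character_, length)
  constraint[pos] <- substr(cls, 1L, 1L)

  # plant positives
  for (i in seq_len(n_snv)) {
    for (e in editors[intended[i, ]]) {
      sch <- schemes[[e]]
      wpos <- windows[[e]]$positions
      placed <- FALSE
      for (try in seq_len(20L)) {
        w <- wpos[rng$sample_int(length(wpos), 1L)]
        pat <- sch$patterns[rng$sample_int(length(sch$patterns), 1L)]
        span <- if (cls[i] == "G>A") c(pos[i] + w, pos[i] + w + sch$pam_len - 1L)
        else c(pos[i] - w - sch$pam_len + 1L, pos[i] - w)
        if (span[1L] < 1L || span[2L] > length) next
        pch <- strsplit(pat, "")[[1]]
        # pattern symbols in genomic (plus-strand) orientation
        gpat <- if (cls[i] == "G>A") pch
        else strsplit(revcomp(pat), "")[[1]]
        tgt <- span[1L]:span[2L]
        disc <- gpat != "N"
        # our discriminative bases must be unconstrained; positions held by
        # earlier plantings are only acceptable under our N symbols
        if (any(!is.na(constraint[tgt[disc]]))) next
        held <- !is.na(constraint[tgt])
        inst <- vapply(gpat, function(sym) {
          s <- IUPAC_SETS[[sym]]
          s[rng$sample_int(base::length(s), 1L)]
        }, "")
        gch[tgt[!held]] <- inst[!held]
        constraint[tgt[disc]] <- gpat[disc]
        placed <- TRUE
        break
      }
      if (!placed) stop("could not place a PAM for SNV ", i, " editor ", e)
    }
  }

  # enforce negatives: break chance matches at unprotected discriminative bases
  ctx_of <- function(i) paste(gch[(pos[i] - 50L):(pos[i] + 50L)], collapse = "")
  for (iter in seq_len(50L)) {
    dirty <- FALSE
    for (i in seq_len(n_snv)) {
      for (e in editors[!intended[i, ]]) {
        sch <- schemes[[e]]
        res <- snv_targetable(list(ref = substr(cls[i], 1L, 1L),
                                   alt = substr(cls[i], 3L, 3L)),
                              ctx_of(i), sch, windows[[e]], center = 51L)
        if (!res$targetable) next
        dirty <- TRUE
        for (s in seq_len(nrow(res$sites))) {
          w <- res$sites$window_pos[s]
          span <- if (cls[i] == "G>A") c(pos[i] + w, pos[i] + w + sch$pam_len - 1L)
          else c(pos[i] - w - sch$pam_len + 1L, pos[i] - w)
          # per pattern position, bases allowed by ANY pattern of this
          # scheme; a constrained position may still be re-drawn within its
          # owner's IUPAC symbol if that escapes this scheme's patterns
          fixed <- FALSE
          for (j in seq_len(sch$pam_len)) {
            gpos <- if (cls[i] == "G>A") span[1L] + j - 1L else span[2L] - j + 1L
            pool <- if (is.na(constraint[gpos])) c("A", "C", "G", "T")
            else IUPAC_SETS[[constraint[gpos]]]
            allowed <- unique(unlist(lapply(sch$patterns, function(p)
              IUPAC_SETS[[substr(p, j, j)]])))
            if (cls[i] == "C>T")
              allowed <- vapply(allowed, function(b)
                chartr("ACGT", "TGCA", b), "", USE.NAMES = FALSE)
            forbidden <- setdiff(pool, allowed)
            if (!base::length(forbidden)) next
            gch[gpos] <- forbidden[rng$sample_int(base::length(forbidden), 1L)]
            fixed <- TRUE
            break
          }
          if (!fixed) stop("could not break a chance PAM for SNV ", i,
                           " editor ", e)
        }
      }
    }
    if (!dirty) break
    if (iter == 50L) stop("negative enforcement did not converge")
  }

  genome <- sequence_set("ref1", paste(gch, collapse = ""), moltype = "dna")
  snvs <- data.frame(id = sprintf("snv%04d", seq_len(n_snv)), chrom = "ref1",
                     pos = pos,
                     ref = substr(cls, 1L, 1L), alt = substr(cls, 3L, 3L),
                     class = cls, stringsAsFactors = FALSE)
  # verification against the planted verdicts
  for (i in seq_len(n_snv)) {
    for (e in editors) {
      got <- snv_targetable(snvs[i, ], ctx_of(i), schemes[[e]], windows[[e]],
                            center = 51L)$targetable
      if (got != intended[i, e])
        stop("planted verdict not realized for SNV ", i, " editor ", e)
    }
  }
  truth <- list(seed = seed, generator_version = GENERATOR_VERSION,
                gc_content = gc_content, n_snv = n_snv,
                intended = as.data.frame(intended))
  list(genome = genome, snvs = snvs, truth = truth)
}
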