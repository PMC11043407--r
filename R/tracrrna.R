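#' Anti-repeat search scoring parameters
#'
#' Short-word local-alignment parameters used for anti-repeat detection:
#' match +1, mismatch -1, affine gaps (first gap position costs
#' \code{gap_open}, each further position \code{gap_extend}), exact seeds of
#' \code{word_size} nt, and a permissive e-value cutoff over a
#' \code{flank_window} of up to 3000 bp on each side of the locus.
#'
#' @param match,mismatch,gap_open,gap_extend,word_size,evalue_max,flank_window
#'   Scoring and search parameters.
#' @return A list of class \code{scoring_params}.
#' @export
scoring_params <- function(match = 1, mismatch = 1, gap_open = 2, gap_extend = 1,
                           word_size = 8L, evalue_max = 1.0, flank_window = 3000L) {
  stopifnot(word_size >= 4, match > 0, mismatch > 0, gap_open > 0, gap_extend > 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, word_size = as.integer(word_size),
                 evalue_max = evalue_max, flank_window = as.integer(flank_window)),
            class = "scoring_params")
}

# Karlin-Altschul parameters for the +1/-1 per-position score under match
# probability q (a +/-1 lattice random walk). lambda has the closed form
# log((1-q)/q); K is computed numerically from the lattice formula with the
# correction series truncated at kmax terms.
karlin_altschul <- function(q, kmax = 200L) {
  stopifnot(q > 0, q < 0.5)
  lambda <- log((1 - q) / q)
  H <- lambda * (1 - 2 * q)
  sigma <- 0
  ratio <- (1 - q) / q
  for (k in seq_len(kmax)) {
    x <- 0:k
    s <- 2 * x - k                 # walk value after k steps
    p <- stats::dbinom(x, k, q)
    term <- sum(p[s >= 0]) + sum(p[s < 0] * ratio^(s[s < 0]))
    sigma <- sigma + term / k
  }
  # lattice span of the ladder heights is 1 (+1 steps set each new maximum)
  delta <- 1
  K <- delta * lambda * exp(-2 * sigma) / (H * (1 - exp(-lambda * delta)))
  list(lambda = lambda, K = K, H = H)
}

#' Find anti-repeats in locus-flanking sequence
#'
#' Seed-and-extend local alignment of the array's direct repeat against both
#' strands of a flanking window: exact \code{word_size}-mers seed candidate
#' diagonals, which are rescored by local alignment under the declared
#' scoring (+1/-1, affine gaps). Hits overlapping the CRISPR array or with an
#' e-value estimate (ungapped Karlin-Altschul under the observed flank
#' composition) above \code{evalue_max} are removed.
#'
#' @param flank A DNA string or single-record \code{sequence_set}: one
#'   flanking window of the locus (call once per side).
#' @param repeat_seq The direct-repeat consensus (DNA).
#' @param params A \code{scoring_params}.
#' @param array_span Optional \code{c(start, end)} of the array in the same
#'   coordinates as the output (hits overlapping it are dropped).
#' @param flank_offset Coordinate of the first flank base (for reporting hits
#'   in contig coordinates).
#' @param contig_id Contig name for the report.
#' @return A data.frame of hits (\code{start}, \code{end}, \code{strand},
#'   \code{score}, \code{evalue}, \code{aligned_frac}) sorted by score;
#'   strand \code{"-"} means the reverse complement of the repeat matches the
#'   flank (the usual tracrRNA orientation on the plus strand).
#' @export
find_anti_repeats <- function(flank, repeat_seq, params = scoring_params(),
                              array_span = NULL, flank_offset = 1L,
                              contig_id = "contig") {
  if (inherits(flank, "sequence_set")) {
    contig_id <- flank$id[1L]
    flank <- flank$sequence[1L]
  }
  flank <- toupper(flank)
  repeat_seq <- toupper(repeat_seq)
  w <- params$word_size
  if (nchar(repeat_seq) < w)
    stop("repeat shorter than word_size (", w, ")")
  L <- nchar(flank)
  rl <- nchar(repeat_seq)

  comp <- table(factor(strsplit(flank, "")[[1]], levels = c("A", "C", "G", "T")))
  pf <- as.numeric(comp) / max(1, sum(comp))
  compr <- table(factor(strsplit(repeat_seq, "")[[1]], levels = c("A", "C", "G", "T")))
  pr <- as.numeric(compr) / max(1, sum(compr))
  q <- sum(pf * pr)
  ka <- if (q > 0 && q < 0.5) karlin_altschul(q) else list(lambda = 1e-6, K = 0.1)

  hits <- list()
  for (strand in c("+", "-")) {
    query <- if (strand == "+") repeat_seq else revcomp(repeat_seq)
    qk <- substring(query, 1:(rl - w + 1L), w:rl)
    seeds <- data.frame(qpos = integer(0), fpos = integer(0))
    for (qi in seq_along(qk)) {
      if (grepl("N", qk[qi], fixed = TRUE)) next
      m <- gregexpr(qk[qi], flank, fixed = TRUE)[[1]]
      if (m[1L] != -1L)
        seeds <- rbind(seeds, data.frame(qpos = qi, fpos = as.integer(m)))
    }
    if (!nrow(seeds)) next
    diags <- unique(seeds$fpos - seeds$qpos)
    windows <- unique(vapply(diags, function(d) {
      ws <- max(1L, d + 1L - 10L)
      we <- min(L, d + rl + 10L)
      paste(ws, we)
    }, ""))
    for (wdef in windows) {
      ws <- as.integer(strsplit(wdef, " ")[[1]])[1L]
      we <- as.integer(strsplit(wdef, " ")[[1]])[2L]
      win <- substr(flank, ws, we)
      aln <- Biostrings::pairwiseAlignment(
        query, win, type = "local",
        substitutionMatrix = submat_unit(c("A", "C", "G", "T", "N"),
                                         params$match, -params$mismatch),
        gapOpening = params$gap_open - params$gap_extend,
        gapExtension = params$gap_extend)
      sc <- Biostrings::score(aln)
      if (sc < w) next
      sub <- Biostrings::subject(aln)
      hs <- ws + Biostrings::start(sub) - 1L
      he <- ws + Biostrings::end(sub) - 1L
      pat <- Biostrings::pattern(aln)
      alnfrac <- (Biostrings::end(pat) - Biostrings::start(pat) + 1L) / rl
      hits[[length(hits) + 1L]] <- data.frame(
        start = hs, end = he, strand = strand, score = sc,
        aligned_frac = alnfrac)
    }
  }
  if (!length(hits))
    return(empty_hits(contig_id))
  h <- do.call(rbind, hits)
  h <- h[order(-h$score, h$start), , drop = FALSE]
  # greedy dedupe of overlapping hits (same or different strand)
  keep <- rep(TRUE, nrow(h))
  for (i in seq_len(nrow(h))) {
    if (!keep[i]) next
    if (i < nrow(h)) for (j in (i + 1L):nrow(h)) {
      if (!keep[j]) next
      ov <- min(h$end[i], h$end[j]) - max(h$start[i], h$start[j]) + 1L
      if (ov > 0.5 * min(h$end[i] - h$start[i], h$end[j] - h$start[j]) + 1L)
        keep[j] <- FALSE
    }
  }
  h <- h[keep, , drop = FALSE]
  h$start <- h$start + flank_offset - 1L
  h$end <- h$end + flank_offset - 1L
  if (!is.null(array_span)) {
    ov <- h$start <= array_span[2L] & h$end >= array_span[1L]
    h <- h[!ov, , drop = FALSE]
  }
  h$evalue <- ka$K * rl * (2 * L) * exp(-ka$lambda * h$score)
  h <- h[h$evalue <= params$evalue_max, , drop = FALSE]
  if (!nrow(h)) return(empty_hits(contig_id))
  h <- data.frame(contig_id = contig_id, h[, c("start", "end", "strand", "score")],
                  evalue = h$evalue, aligned_frac = h$aligned_frac,
                  row.names = NULL)
  h[order(-h$score, h$start), , drop = FALSE]
}

empty_hits <- function(contig_id) {
  data.frame(contig_id = character(0), start = integer(0), end = integer(0),
             strand = character(0), score = numeric(0), evalue = numeric(0),
             aligned_frac = numeric(0))
}

dna_pairable <- function(a, b) {
  paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
}

#' Predict Rho-independent terminators
#'
#' Rule-based terminator detection: every maximal hairpin with a stem of at
#' least 5 bp (G.T wobble allowed) and a loop of 3-10 nt, followed within 3 nt
#' by a 6-nt window containing at least 4 T, is reported with score
#' \code{2 * stem + u_tract_len}.
#'
#' @param window A DNA string or single-record \code{sequence_set} (>= 20 nt).
#' @return A data.frame (\code{start}, \code{end}, \code{stem_len},
#'   \code{loop_len}, \code{u_tract_len}, \code{score}), sorted by decreasing
#'   score; \code{end} includes the U-tract window.
#' @export
predict_terminators <- function(window) {
  if (inherits(window, "sequence_set")) window <- window$sequence[1L]
  window <- toupper(window)
  n <- nchar(window)
  if (n < 20L) stop("window shorter than 20 nt")
  ch <- strsplit(window, "")[[1]]
  found <- list()
  for (loop_len in 3:10) {
    for (p in 2:(n - loop_len)) {      # p = loop start
      smax <- 0L
      while (p - smax - 1L >= 1L && p + loop_len + smax <= n &&
             dna_pairable(ch[p - smax - 1L], ch[p + loop_len + smax])) smax <- smax + 1L
      if (smax < 5L) next
      # the maximally extended stem may swallow an A-rich run pairing with the
      # T-tract itself; take the stem length (<= maximal) whose downstream
      # window yields the best-scoring terminator
      best <- NULL
      for (s in smax:5L) {
        hp_start <- p - s
        hp_end <- p + loop_len + s - 1L
        for (t0 in (hp_end + 1L):(hp_end + 4L)) {
          if (t0 > n) break
          wend <- min(n, t0 + 5L)
          nt <- sum(ch[t0:wend] == "T")
          if (nt >= 4L) {
            sc <- 2L * s + nt
            if (is.null(best) || sc > best$score)
              best <- data.frame(start = hp_start, end = wend, stem_len = s,
                                 loop_len = loop_len, u_tract_len = nt, score = sc)
            break
          }
        }
      }
      if (!is.null(best)) found[[length(found) + 1L]] <- best
    }
  }
  if (!length(found))
    return(data.frame(start = integer(0), end = integer(0), stem_len = integer(0),
                      loop_len = integer(0), u_tract_len = integer(0),
                      score = integer(0)))
  d <- do.call(rbind, found)
  d <- d[order(-d$score, d$start), , drop = FALSE]
  d <- d[!duplicated(d[, c("start", "end")]), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Build tracrRNA candidates from anti-repeat hits
#'
#' Each hit is oriented so the transcript contains the anti-repeat at its 5'
#' end (hit strand \code{"-"}: transcript reads along the plus strand from the
#' hit; strand \code{"+"}: transcript is the reverse complement, reading
#' leftward). The candidate runs from the anti-repeat start to the end of the
#' best downstream terminator, or to the first run of >= 4 T when no
#' terminator is found; hits with neither are dropped.
#'
#' @param contig_seq Contig DNA string.
#' @param hits Data.frame from \code{find_anti_repeats} (contig coordinates).
#' @param max_len Maximum candidate length in nt.
#' @param min_aligned_frac Minimum fraction of the repeat covered by the hit
#'   alignment; anti-repeats pair most of the repeat, so short seed-only
#'   chance alignments are not tracrRNA candidates.
#' @return A list of \code{tracr_candidate} objects: \code{sequence} (RNA),
#'   \code{anti_repeat} span within the candidate, \code{terminator} row or
#'   poly-T marker, genomic \code{span} and \code{strand}.
#' @export
build_tracr_candidates <- function(contig_seq, hits, max_len = 200L,
                                   min_aligned_frac = 0.7) {
  if (inherits(contig_seq, "sequence_set")) contig_seq <- contig_seq$sequence[1L]
  L <- nchar(contig_seq)
  out <- list()
  for (i in seq_len(nrow(hits))) {
    if (hits$aligned_frac[i] < min_aligned_frac) next
    anti_len <- hits$end[i] - hits$start[i] + 1L
    if (hits$strand[i] == "-") {
      rs <- hits$start[i]; re <- min(L, hits$start[i] + max_len - 1L)
      region <- substr(contig_seq, rs, re)
      to_genomic <- function(a, b) c(rs + a - 1L, rs + b - 1L)
    } else {
      rs <- max(1L, hits$end[i] - max_len + 1L); re <- hits$end[i]
      region <- revcomp(substr(contig_seq, rs, re))
      to_genomic <- function(a, b) c(re - b + 1L, re - a + 1L)
    }
    term <- tryCatch(predict_terminators(region), error = function(e) NULL)
    if (!is.null(term) && nrow(term)) term <- term[term$start > anti_len, , drop = FALSE]
    end_at <- NA_integer_
    term_rec <- NULL
    if (!is.null(term) && nrow(term)) {
      term_rec <- term[1L, , drop = FALSE]
      end_at <- term_rec$end
    } else {
      m <- regexpr("TTTT+", substr(region, anti_len + 1L, nchar(region)))
      if (m[1L] != -1L) {
        end_at <- anti_len + as.integer(m) + attr(m, "match.length") - 1L
        term_rec <- "polyT"
      }
    }
    if (is.na(end_at)) next
    cand_dna <- substr(region, 1L, end_at)
    gsp <- to_genomic(1L, end_at)
    cand <- structure(list(
      sequence = dna_to_rna(cand_dna),
      anti_repeat = c(1L, anti_len),
      terminator = term_rec,
      span = gsp, strand = ifelse(hits$strand[i] == "-", "+", "-"),
      hit = hits[i, , drop = FALSE]), class = "tracr_candidate")
    out[[length(out) + 1L]] <- cand
  }
  out
}

#' @export
print.tracr_candidate <- function(x, ...) {
  cat(sprintf("<tracr_candidate %d nt, anti-repeat 1-%d, terminator %s>\n",
              nchar(x$sequence), x$anti_repeat[2L],
              if (is.character(x$terminator)) "poly-T"
              else if (is.null(x$terminator)) "none"
              else sprintf("stem %d + %d T", x$terminator$stem_len,
                           x$terminator$u_tract_len)))
  invisible(x)
}

rna_pairable <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

#' Assemble an sgRNA scaffold
#'
#' Fuses the direct repeat (crRNA side) to a tracrRNA candidate through a
#' tetraloop. The repeat:anti-repeat duplex is the best ungapped antiparallel
#' pairing (Watson-Crick + G.U) between repeat and anti-repeat; the repeat's
#' 3'-most paired base is joined via the tetraloop to the anti-repeat's
#' 5'-most paired base. \code{TS} forms trim the duplex to \code{trim_len}
#' pairs nearest the tetraloop; \code{-opt} forms additionally apply a
#' substitution list.
#'
#' @param repeat_seq Direct repeat (DNA or RNA).
#' @param candidate A \code{tracr_candidate}.
#' @param form One of \code{natural}, \code{FS}, \code{FS-opt}, \code{TS},
#'   \code{TS-opt}.
#' @param tetraloop Fusion loop sequence.
#' @param trim_len Duplex length (pairs) for TS forms.
#' @param substitutions Data.frame with columns \code{pos}, \code{base}
#'   (positions on the assembled scaffold); required for \code{-opt} forms.
#' @return An \code{sgrna_scaffold}: RNA sequence with segment annotations
#'   and the duplex pair list in scaffold coordinates.
#' @export
assemble_sgrna <- function(repeat_seq, candidate,
                           form = c("FS", "natural", "FS-opt", "TS", "TS-opt"),
                           tetraloop = "GAAA", trim_len = 12L,
                           substitutions = NULL) {
  form <- match.arg(form)
  if (grepl("-opt$", form) && (is.null(substitutions) || !nrow(substitutions)))
    stop("opt form requires substitutions")
  rep_rna <- dna_to_rna(toupper(repeat_seq))
  cand <- toupper(candidate$sequence)
  anti_span <- candidate$anti_repeat
  anti <- substr(cand, anti_span[1L], anti_span[2L])
  R <- nchar(rep_rna); A <- nchar(anti)
  rch <- strsplit(rep_rna, "")[[1]]
  ach <- strsplit(anti, "")[[1]]

  # best ungapped antiparallel register: pairs (r, a) with r + a = c
  best <- NULL
  for (cc in 2:(R + A)) {
    r <- seq_len(R)
    a <- cc - r
    ok <- a >= 1L & a <= A
    r <- r[ok]; a <- a[ok]
    pb <- vapply(seq_along(r), function(t) rna_pairable(rch[r[t]], ach[a[t]]), NA)
    np <- sum(pb)
    if (is.null(best) || np > best$np ||
        (np == best$np && abs(cc - (R + 1L)) < abs(best$cc - (R + 1L)))) {
      best <- list(cc = cc, np = np, r = r[pb], a = a[pb])
    }
  }
  if (best$np < 8L) stop("no duplex: fewer than 8 pairable positions")

  r_last <- max(best$r); a_first <- min(best$a); a_last <- max(best$a)
  if (form %in% c("TS", "TS-opt") && best$np > trim_len) {
    ord <- order(-best$r)                     # junction-proximal first
    keep <- ord[seq_len(trim_len)]
    r_keep <- best$r[keep]; a_keep <- best$a[keep]
  } else {
    r_keep <- best$r; a_keep <- best$a
  }
  r_lo <- if (form %in% c("TS", "TS-opt")) min(r_keep) else 1L
  a_hi <- max(a_keep)

  tl <- nchar(tetraloop)
  if (form %in% c("TS", "TS-opt")) {
    rep_part <- substr(rep_rna, r_lo, r_last)
    anti_part <- substr(cand, anti_span[1L] + a_first - 1L, anti_span[1L] + a_hi - 1L)
    tail_part <- substr(cand, anti_span[1L] + a_last, nchar(cand))
  } else {
    rep_part <- substr(rep_rna, 1L, r_last)
    anti_part <- substr(cand, anti_span[1L] + a_first - 1L, nchar(cand))
    tail_part <- ""
  }
  seqs <- paste0(rep_part, dna_to_rna(tetraloop), dna_to_rna(anti_part),
                 dna_to_rna(tail_part))
  # scaffold coordinates
  rep_off <- -(r_lo - 1L)
  rep_span <- c(1L, nchar(rep_part))
  tl_span <- c(rep_span[2L] + 1L, rep_span[2L] + tl)
  anti_off <- tl_span[2L] - (a_first - 1L)
  duplex <- cbind(repeat_pos = r_keep + rep_off, anti_pos = a_keep + anti_off)
  duplex <- duplex[order(duplex[, 1L]), , drop = FALSE]
  anti_span_sc <- c(tl_span[2L] + 1L, anti_off + a_hi)

  if (grepl("-opt$", form)) {
    ch <- strsplit(seqs, "")[[1]]
    for (t in seq_len(nrow(substitutions))) {
      p <- substitutions$pos[t]
      if (p < 1L || p > length(ch)) stop("substitution position out of range: ", p)
      ch[p] <- dna_to_rna(toupper(substitutions$base[t]))
    }
    seqs <- paste(ch, collapse = "")
  }
  structure(list(
    form = form, sequence = seqs, tetraloop = dna_to_rna(tetraloop),
    segments = list(repeat_span = rep_span, tetraloop_span = tl_span,
                    anti_span = anti_span_sc,
                    tail_span = c(anti_span_sc[2L] + 1L, nchar(seqs))),
    duplex_pairs = duplex,
    duplex_end = max(duplex[, 2L])), class = "sgrna_scaffold")
}

#' @export
print.sgrna_scaffold <- function(x, ...) {
  cat(sprintf("<sgrna_scaffold %s, %d nt, duplex %d bp>\n",
              x$form, nchar(x$sequence), nrow(x$duplex_pairs)))
  cat(" ", x$sequence, "\n")
  invisible(x)
}

#' Check sgRNA structural modules
#'
#' An sgRNA scaffold passes when some predicted structure simultaneously
#' shows (i) a repeat:anti-repeat duplex of at least \code{duplex_min_bp}
#' pairs between the repeat- and anti-repeat-derived segments, (ii) a nexus
#' stem-loop (stem >= \code{nexus_min_stem}) beginning within
#' \code{nexus_max_dist} nt downstream of the duplex, and (iii) a hairpin
#' wholly within the 3'-terminal \code{hairpin3_window} nt.
#'
#' @param scaffold An \code{sgrna_scaffold}.
#' @param prediction A \code{structure_prediction} computed on
#'   \code{scaffold$sequence}.
#' @param duplex_min_bp,nexus_min_stem,nexus_max_dist,hairpin3_window
#'   Module thresholds.
#' @return A list: \code{pass} (logical) and \code{reasons} (character vector
#'   of missing modules, empty when passing).
#' @export
check_modules <- function(scaffold, prediction, duplex_min_bp = 8L,
                          nexus_min_stem = 2L, nexus_max_dist = 6L,
                          hairpin3_window = 60L) {
  if (is.null(scaffold$duplex_pairs) || is.null(scaffold$segments))
    stop("scaffold lacks segment/duplex annotations")
  if (prediction$n != nchar(scaffold$sequence))
    stop("prediction was not computed on this scaffold")
  n <- prediction$n
  dend <- scaffold$duplex_end
  best <- NULL
  for (pairs in prediction$structures) {
    got <- character(0)
    if (nrow(pairs)) {
      # the duplex module is the specific repeat:anti-repeat register found at
      # assembly, not arbitrary cross-pairing between the two segments: the
      # structure must realize a contiguous helix of annotated register pairs
      # (a genuine anti-repeat with few mismatches always yields a long run;
      # scrambled segments give only scattered coincidental pairs)
      pk <- paste(pairs[, 1L], pairs[, 2L])
      dk <- paste(scaffold$duplex_pairs[, 1L], scaffold$duplex_pairs[, 2L])
      real <- scaffold$duplex_pairs[dk %in% pk, , drop = FALSE]
      if (nrow(real)) {
        run <- max(run_lengths_diag(real))
        if (run >= duplex_min_bp) got <- c(got, "duplex")
      }
      units <- stemloop_units(pairs)
      # units downstream of the duplex only
      nx <- which(units$start > dend &
                    units$start <= dend + nexus_max_dist &
                    units$n_pairs >= nexus_min_stem)
      h3 <- which(units$start >= n - hairpin3_window + 1L &
                    units$start > dend)
      if (length(nx)) got <- c(got, "nexus")
      # the 3' hairpin must be a structural element distinct from the one
      # assigned to the nexus (a short scaffold whose only downstream unit is
      # the nexus has no 3' hairpin)
      if (length(h3) &&
          !(length(nx) == 1L && length(h3) == 1L && nx == h3))
        got <- c(got, "3' hairpin")
    }
    if (is.null(best) || length(got) > length(best)) best <- got
    if (length(got) == 3L)
      return(list(pass = TRUE, reasons = character(0)))
  }
  list(pass = FALSE,
       reasons = setdiff(c("duplex", "nexus", "3' hairpin"), best %||% character(0)))
}

seq2 <- function(a, b) if (b < a) integer(0) else a:b

# lengths of contiguous helix runs in a (repeat_pos, anti_pos) pair matrix:
# consecutive pairs stack when repeat_pos advances by 1 while anti_pos drops by 1
run_lengths_diag <- function(pairs) {
  p <- pairs[order(pairs[, 1L]), , drop = FALSE]
  if (nrow(p) == 1L) return(1L)
  stacked <- diff(p[, 1L]) == 1L & diff(p[, 2L]) == -1L
  r <- rle(stacked)
  c(1L, r$lengths[r$values] + 1L)
}
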