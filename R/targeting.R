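#' Define a nuclease PAM scheme
#'
#' A nuclease's targeting rules: its IUPAC PAM patterns (all of the full PAM
#' length), protospacer length, and blunt-cut offset from the PAM-proximal
#' protospacer end.
#'
#' @param name Scheme name.
#' @param patterns Character vector of IUPAC patterns, equal lengths.
#' @param spacer_len Protospacer length (nt).
#' @param cut_offset Cut position, bp upstream of the PAM.
#' @return A list of class \code{pam_scheme}.
#' @export
pam_scheme <- function(name, patterns, spacer_len = 23L, cut_offset = 3L) {
  patterns <- toupper(patterns)
  if (!length(patterns)) stop("patterns must be non-empty")
  pl <- unique(nchar(patterns))
  if (length(pl) != 1L) stop("all patterns must have the same length")
  bad <- setdiff(unique(unlist(strsplit(patterns, ""))), names(IUPAC_SETS))
  if (length(bad)) stop("non-IUPAC symbols in patterns: ", paste(bad, collapse = ""))
  structure(list(name = name, patterns = patterns, pam_len = pl,
                 spacer_len = as.integer(spacer_len),
                 cut_offset = as.integer(cut_offset)),
            class = "pam_scheme")
}

#' @export
print.pam_scheme <- function(x, ...) {
  cat(sprintf("<pam_scheme %s: %s; spacer %d nt, cut %d bp upstream of PAM>\n",
              x$name, paste(x$patterns, collapse = "/"), x$spacer_len,
              x$cut_offset))
  invisible(x)
}

#' Built-in comparator PAM schemes
#'
#' The compact nuclease discovered by this workflow ("CoCas9", patterns
#' N4GWNT / N4GCDT / N4ATDT) and canonical PAMs of the comparator orthologs:
#' SpCas9 (NGG), SaCas9 (NNGRRT), Nme2Cas9 (N4CC).
#'
#' @return Named list of \code{pam_scheme} objects.
#' @export
builtin_schemes <- function() {
  list(
    cocas9 = pam_scheme("CoCas9", c("NNNNGWNT", "NNNNGCDT", "NNNNATDT"),
                        spacer_len = 23L, cut_offset = 3L),
    spcas9 = pam_scheme("SpCas9", "NGG", spacer_len = 20L, cut_offset = 3L),
    sacas9 = pam_scheme("SaCas9", "NNGRRT", spacer_len = 21L, cut_offset = 3L),
    nme2cas9 = pam_scheme("Nme2Cas9", "NNNNCC", spacer_len = 24L, cut_offset = 3L)
  )
}

# Biostrings match of an IUPAC pattern on a DNAString; positions whose window
# contains a genomic N are kept only where the pattern symbol is N
match_pattern_starts <- function(pattern, subject_dna, subject_chars) {
  m <- Biostrings::matchPattern(pattern, subject_dna, fixed = FALSE)
  starts <- BiocGenerics::start(m)
  if (!length(starts)) return(integer(0))
  pl <- strsplit(pattern, "")[[1]]
  non_n <- which(pl != "N")
  if (length(non_n)) {
    keep <- vapply(starts, function(s)
      !any(subject_chars[s + non_n - 1L] == "N"), NA)
    starts <- starts[keep]
  }
  starts
}

#' Count PAM-targetable positions in a genome
#'
#' A genomic position is targetable when a PAM-pattern match places it as the
#' PAM-proximal protospacer base on the plus or minus strand (immediately 5'
#' of a plus-strand PAM, or immediately 3' of a minus-strand PAM occurrence).
#' Positions within \code{pam_len} of a contig end are excluded from the
#' denominator to avoid edge artifacts.
#'
#' @param genome A \code{sequence_set}, named character vector of contigs, or
#'   path to a FASTA file.
#' @param scheme A \code{pam_scheme}.
#' @return A \code{genome_scan} list: \code{n_positions_scanned},
#'   \code{n_targetable_positions}, \code{per_strand} counts and
#'   \code{fraction_targetable}.
#' @export
scan_genome <- function(genome, scheme) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_fasta(genome)
  seqs <- if (inherits(genome, "sequence_set")) genome$sequence else as.character(genome)
  pl <- scheme$pam_len
  n_scanned <- 0
  n_target <- 0
  plus_count <- 0
  minus_count <- 0
  for (s in seqs) {
    L <- nchar(s)
    if (L < 2L * pl + 1L) next
    lo <- pl + 1L
    hi <- L - pl
    n_scanned <- n_scanned + (hi - lo + 1L)
    dna <- Biostrings::DNAString(s)
    chars <- strsplit(s, "")[[1]]
    plus <- integer(0)
    minus <- integer(0)
    for (p in scheme$patterns) {
      # plus strand: PAM at [m, m+pl-1], protospacer base at m-1
      plus <- c(plus, match_pattern_starts(p, dna, chars) - 1L)
      # minus strand: reverse-complement pattern occurrence at [a, b];
      # the PAM-proximal protospacer base sits at b + 1
      minus <- c(minus, match_pattern_starts(revcomp(p), dna, chars) + pl)
    }
    plus <- unique(plus[plus >= lo & plus <= hi])
    minus <- unique(minus[minus >= lo & minus <= hi])
    plus_count <- plus_count + length(plus)
    minus_count <- minus_count + length(minus)
    n_target <- n_target + length(unique(c(plus, minus)))
  }
  structure(list(
    scheme = scheme$name,
    n_positions_scanned = n_scanned,
    n_targetable_positions = n_target,
    per_strand = c(`+` = plus_count, `-` = minus_count),
    fraction_targetable = if (n_scanned > 0) n_target / n_scanned else 0),
    class = "genome_scan")
}

#' @export
print.genome_scan <- function(x, ...) {
  cat(sprintf("<genome_scan %s: %d/%d positions targetable (%.4f)>\n",
              x$scheme, x$n_targetable_positions, x$n_positions_scanned,
              x$fraction_targetable))
  invisible(x)
}

#' Estimate a base-editing window from an editing matrix
#'
#' The editing window is the set of spacer positions (numbered from the
#' PAM-proximal end) whose across-guide mean editing fraction reaches
#' \code{threshold}.
#'
#' @param matrix Guides x positions matrix of A>G conversion fractions;
#'   column names (or indices) are spacer positions.
#' @param threshold Minimum mean editing fraction.
#' @return An \code{editing_window}: integer positions plus the threshold.
#' @export
estimate_window <- function(matrix, threshold = 0.10) {
  if (is.null(dim(matrix)) || nrow(matrix) == 0L) stop("empty editing matrix")
  if (any(matrix < 0 | matrix > 1)) stop("editing fractions must lie in [0, 1]")
  mean_ed <- colMeans(matrix)
  pos <- if (!is.null(colnames(matrix))) as.integer(colnames(matrix))
  else seq_len(ncol(matrix))
  structure(list(positions = pos[mean_ed >= threshold], threshold = threshold),
            class = "editing_window")
}

#' @export
print.editing_window <- function(x, ...) {
  cat("<editing_window positions",
      if (length(x$positions)) paste(x$positions, collapse = ",") else "(none)",
      "at >=", x$threshold, "mean editing>\n")
  invisible(x)
}

#' Classify an SNV as base-editor targetable
#'
#' For a G>A variant the editable adenine is the variant base on the plus
#' strand and protospacers are enumerated on the plus strand; for C>T the
#' adenine is the complement on the minus strand and protospacers are
#' enumerated on the minus strand. The SNV is targetable when some PAM
#' occurrence places the adenine at a window position of the spacer.
#'
#' @param snv List or one-row data.frame with \code{ref}, \code{alt} (defines
#'   the class G>A or C>T).
#' @param context DNA string centered on the variant position.
#' @param scheme A \code{pam_scheme}.
#' @param window An \code{editing_window} (non-empty).
#' @param center Index of the variant base within \code{context} (defaults to
#'   the middle).
#' @return List: \code{targetable} and \code{sites}, a data.frame of
#'   supporting (pam position in context, window position) pairs.
#' @export
snv_targetable <- function(snv, context, scheme, window,
                           center = (nchar(context) + 1L) %/% 2L) {
  context <- toupper(context)
  cls <- paste0(snv$ref, ">", snv$alt)
  if (!cls %in% c("G>A", "C>T"))
    stop("unsupported SNV class: ", cls, " (expected G>A or C>T)")
  if (!length(window$positions)) stop("empty editing window")
  pl <- scheme$pam_len
  n <- nchar(context)
  sites <- list()
  n_eval <- 0L
  for (w in window$positions) {
    if (cls == "G>A") {
      a <- center + w
      b <- a + pl - 1L
      if (a < 1L || b > n) next
      sub <- substr(context, a, b)
    } else {
      b <- center - w
      a <- b - pl + 1L
      if (a < 1L || b > n) next
      sub <- revcomp(substr(context, a, b))
    }
    n_eval <- n_eval + 1L
    if (any(vapply(scheme$patterns, function(p) iupac_match(sub, p), NA)))
      sites[[length(sites) + 1L]] <- data.frame(pam_pos = a, window_pos = w)
  }
  if (n_eval == 0L) stop("context too short to evaluate any PAM placement")
  sites <- if (length(sites)) do.call(rbind, sites)
  else data.frame(pam_pos = integer(0), window_pos = integer(0))
  list(targetable = nrow(sites) > 0L, sites = sites)
}

#' Exclusive targetability across editors
#'
#' Per-editor targetable fractions, the fraction targetable solely by each
#' editor (its set minus the union of all others), and the union fraction.
#'
#' @param reports Named list: editor -> vector of targetable SNV ids.
#' @param universe Total number of SNVs considered.
#' @return A \code{targetability_report}.
#' @export
exclusive_targetability <- function(reports, universe) {
  if (universe <= 0L) stop("universe must be positive")
  stopifnot(length(names(reports)) == length(reports))
  sets <- lapply(reports, unique)
  solely <- lapply(names(sets), function(e) {
    others <- unlist(sets[setdiff(names(sets), e)], use.names = FALSE)
    setdiff(sets[[e]], others)
  })
  names(solely) <- names(sets)
  un <- unique(unlist(sets, use.names = FALSE))
  structure(list(
    sets = sets,
    fraction = vapply(sets, length, 0L) / universe,
    solely = solely,
    solely_fraction = vapply(solely, length, 0L) / universe,
    union_fraction = length(un) / universe,
    universe = universe), class = "targetability_report")
}

#' @export
print.targetability_report <- function(x, ...) {
  cat("<targetability_report>", x$universe, "SNVs\n")
  for (e in names(x$sets))
    cat(sprintf("  %-12s %5.1f%%  (solely %.1f%%)\n", e,
                100 * x$fraction[[e]], 100 * x$solely_fraction[[e]]))
  cat(sprintf("  union        %5.1f%%\n", 100 * x$union_fraction))
  invisible(x)
}

#' Enumerate guide target sites in a region
#'
#' Every PAM match on either strand yields one site: the
#' \code{spacer_len}-nt protospacer 5' of the PAM and the blunt-cut position
#' \code{cut_offset} bp upstream of the PAM. Sites are reported in 5'-to-3'
#' order on the plus strand, then the minus strand.
#'
#' @param region DNA string.
#' @param scheme A \code{pam_scheme}.
#' @return Data.frame: \code{strand}, \code{protospacer}, \code{pam},
#'   \code{pam_start}, \code{pam_end}, \code{cut_offset}, \code{cut_after}
#'   (cleavage falls between \code{cut_after} and \code{cut_after + 1} on the
#'   plus strand).
#' @export
design_guides <- function(region, scheme) {
  region <- toupper(region)
  L <- nchar(region)
  pl <- scheme$pam_len
  sl <- scheme$spacer_len
  dna <- Biostrings::DNAString(region)
  chars <- strsplit(region, "")[[1]]
  rows <- list()
  for (p in scheme$patterns) {
    for (m in match_pattern_starts(p, dna, chars)) {
      if (m - sl < 1L) next
      rows[[length(rows) + 1L]] <- data.frame(
        strand = "+", protospacer = substr(region, m - sl, m - 1L),
        pam = substr(region, m, m + pl - 1L),
        pam_start = m, pam_end = m + pl - 1L,
        cut_offset = scheme$cut_offset,
        cut_after = m - scheme$cut_offset - 1L)
    }
    for (a in match_pattern_starts(revcomp(p), dna, chars)) {
      b <- a + pl - 1L
      if (b + sl > L) next
      rows[[length(rows) + 1L]] <- data.frame(
        strand = "-", protospacer = revcomp(substr(region, b + 1L, b + sl)),
        pam = revcomp(substr(region, a, b)),
        pam_start = a, pam_end = b,
        cut_offset = scheme$cut_offset,
        cut_after = b + scheme$cut_offset)
    }
  }
  if (!length(rows))
    return(data.frame(strand = character(0), protospacer = character(0),
                      pam = character(0), pam_start = integer(0),
                      pam_end = integer(0), cut_offset = integer(0),
                      cut_after = integer(0)))
  d <- do.call(rbind, rows)
  d <- d[!duplicated(d[, c("strand", "pam_start")]), , drop = FALSE]
  d <- d[order(d$strand, d$pam_start), , drop = FALSE]
  rownames(d) <- NULL
  d
}
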