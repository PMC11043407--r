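IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# TRUE where `seq` matches the IUPAC `pattern` (equal lengths); a genomic N
# matches only the pattern symbol N
iupac_match <- function(seqs, pattern) {
  pl <- strsplit(pattern, "")[[1]]
  vapply(strsplit(seqs, ""), function(ch) {
    if (length(ch) != length(pl)) return(FALSE)
    all(vapply(seq_along(ch), function(i) {
      if (ch[i] == "N") return(pl[i] == "N")
      ch[i] %in% IUPAC_SETS[[pl[i]]]
    }, NA))
  }, NA)
}

#' Randomized-PAM library design
#'
#' Describes the amplicon read layout of a randomized-PAM cleavage library:
#' a fixed anchor (by default the 3' end of the protospacer) immediately 5'
#' of an 8-nt randomized PAM, followed by backbone context.
#'
#' @param protospacer Protospacer sequence (DNA).
#' @param pam_len Randomized PAM length (8 for this library design).
#' @param anchor Sequence immediately 5' of the PAM in the read; defaults to
#'   the protospacer 3' end (>= 10 nt).
#' @param backbone_context Sequence immediately 3' of the PAM.
#' @return A list of class \code{pam_library_design}.
#' @export
pam_library_design <- function(protospacer = "GACGCATAAAGATGAGACGCTGG",
                               pam_len = 8L,
                               anchor = NULL,
                               backbone_context = "CTTCAAGTTGATAACGGACTAGCC") {
  protospacer <- toupper(protospacer)
  if (is.null(anchor)) anchor <- substr(protospacer, nchar(protospacer) - 11L,
                                        nchar(protospacer))
  anchor <- toupper(anchor)
  if (nchar(anchor) < 10L) stop("anchor must be at least 10 nt")
  structure(list(protospacer = protospacer, pam_len = as.integer(pam_len),
                 anchor = anchor, backbone_context = toupper(backbone_context)),
            class = "pam_library_design")
}

# positions (1-based) where `anchor` occurs in `seq` with <= max_mm mismatches
find_anchor <- function(seq, anchor, max_mm) {
  al <- nchar(anchor)
  p <- as.integer(gregexpr(anchor, seq, fixed = TRUE)[[1]])
  if (p[1L] != -1L) return(p[1L])
  if (max_mm == 0L) return(NA_integer_)
  ach <- strsplit(anchor, "")[[1]]
  n <- nchar(seq)
  if (n < al) return(NA_integer_)
  sch <- strsplit(seq, "")[[1]]
  for (s in 1:(n - al + 1L)) {
    if (sum(sch[s:(s + al - 1L)] != ach) <= max_mm) return(s)
  }
  NA_integer_
}

#' Extract PAM counts from reads
#'
#' Locates the anchor in each read (allowing up to \code{max_anchor_mismatch}
#' substitutions) and counts the \code{pam_len} bases immediately 3' of it.
#' Reads with no anchor, an anchor too close to the read end, or non-ACGT
#' bases in the PAM are skipped and tallied in the QC attribute.
#'
#' @param reads A \code{sequence_set} from \code{read_fastq}.
#' @param design A \code{pam_library_design}.
#' @param max_anchor_mismatch Allowed anchor mismatches.
#' @return A \code{pam_counts} object: named integer vector of 8-mer counts
#'   with attributes \code{total} and \code{qc}.
#' @export
extract_pams <- function(reads, design, max_anchor_mismatch = 1L) {
  al <- nchar(design$anchor)
  pl <- design$pam_len
  seqs <- reads$sequence
  n <- length(seqs)
  qc <- c(n_reads = n, no_anchor = 0L, off_end = 0L, non_acgt = 0L, counted = 0L)
  # fast path: exact anchor match
  pos <- rep(NA_integer_, n)
  ex <- regexpr(design$anchor, seqs, fixed = TRUE)
  pos[ex != -1L] <- as.integer(ex[ex != -1L])
  miss <- which(is.na(pos))
  if (length(miss) && max_anchor_mismatch > 0L) {
    pos[miss] <- vapply(seqs[miss], find_anchor, 0L,
                        anchor = design$anchor, max_mm = max_anchor_mismatch,
                        USE.NAMES = FALSE)
  }
  qc["no_anchor"] <- sum(is.na(pos))
  ok <- !is.na(pos)
  fits <- ok & (pos + al + pl - 1L) <= nchar(seqs)
  qc["off_end"] <- sum(ok & !fits)
  pams <- substr(seqs[fits], pos[fits] + al, pos[fits] + al + pl - 1L)
  good <- !grepl("[^ACGT]", pams)
  qc["non_acgt"] <- sum(!good)
  pams <- pams[good]
  qc["counted"] <- length(pams)
  if (!length(pams)) stop("no PAMs extracted")
  tab <- table(pams)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  structure(counts, total = sum(counts), qc = qc, pam_len = pl,
            class = "pam_counts")
}

#' Per-position base frequencies and information content
#'
#' Logo-ready position profile: \code{freq[b, i]} is the frequency of base b
#' at PAM position i, and \code{info[i] = 2 - H_i} bits with \code{H_i} the
#' Shannon entropy of column i.
#'
#' @param counts A \code{pam_counts}.
#' @return A list of class \code{position_profile} with elements \code{freq}
#'   (4 x pam_len matrix) and \code{info}.
#' @export
position_profile <- function(counts) {
  total <- attr(counts, "total")
  if (is.null(total) || total <= 0) stop("empty PAM counts")
  pl <- attr(counts, "pam_len") %||% nchar(names(counts)[1L])
  freq <- matrix(0, 4L, pl, dimnames = list(c("A", "C", "G", "T"), seq_len(pl)))
  for (i in seq_len(pl)) {
    b <- substr(names(counts), i, i)
    agg <- tapply(as.integer(counts), b, sum)
    freq[names(agg), i] <- agg / total
  }
  h <- apply(freq, 2L, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  structure(list(freq = freq, info = 2 - h), class = "position_profile")
}

#' @export
print.position_profile <- function(x, ...) {
  cat("<position_profile>\n")
  print(round(x$freq, 3))
  cat("info (bits):", paste(round(x$info, 3), collapse = " "), "\n")
  invisible(x)
}

#' Select the most informative PAM positions
#'
#' @param profile A \code{position_profile} from the cleaved library.
#' @param k Number of positions.
#' @return Integer positions (genomic order); ties broken leftmost.
#' @export
select_informative_positions <- function(profile, k = 4L) {
  info <- profile$info
  if (k > length(info)) stop("k exceeds PAM length")
  sort(order(-info, seq_along(info))[seq_len(k)])
}

#' PAM enrichment over the informative positions
#'
#' Marginal counts of the 4-mer combinations at the selected positions
#' (summing over the unselected positions) are converted to
#' pseudocount-smoothed frequencies and their cleaved/control ratio is the
#' enrichment displayed in PAM heatmaps.
#'
#' @param cleaved,control \code{pam_counts} for the cleaved and uncleaved
#'   libraries.
#' @param positions The selected positions (e.g. from
#'   \code{select_informative_positions}).
#' @param pseudocount Added to every marginal count.
#' @return A data.frame of class \code{pam_enrichment} with 256 rows:
#'   \code{combo}, counts, frequencies and \code{ratio}; the positions and
#'   pseudocount policy are attached as attributes.
#' @export
pam_enrichment <- function(cleaved, control, positions, pseudocount = 1) {
  stopifnot(attr(cleaved, "total") > 0, attr(control, "total") > 0)
  k <- length(positions)
  combos <- sort(apply(expand.grid(rep(list(c("A", "C", "G", "T")), k),
                                   stringsAsFactors = FALSE)[, k:1, drop = FALSE],
                       1L, paste, collapse = ""))
  marginal <- function(cnt) {
    key <- vapply(positions, function(p) substr(names(cnt), p, p), character(length(cnt)))
    if (is.null(dim(key))) key <- matrix(key, nrow = 1L)
    key <- apply(key, 1L, paste, collapse = "")
    agg <- tapply(as.integer(cnt), key, sum)
    out <- stats::setNames(rep(0L, length(combos)), combos)
    out[names(agg)] <- agg
    out
  }
  mc <- marginal(cleaved)
  mu <- marginal(control)
  nb <- length(combos)
  fc <- (mc + pseudocount) / (attr(cleaved, "total") + nb * pseudocount)
  fu <- (mu + pseudocount) / (attr(control, "total") + nb * pseudocount)
  out <- data.frame(combo = combos, cleaved_count = as.integer(mc),
                    control_count = as.integer(mu),
                    cleaved_freq = as.numeric(fc), control_freq = as.numeric(fu),
                    ratio = as.numeric(fc / fu), row.names = NULL)
  attr(out, "positions") <- positions
  attr(out, "pseudocount") <- pseudocount
  class(out) <- c("pam_enrichment", "data.frame")
  out
}

# all per-position IUPAC products (S1 x .. x Sk) whose expansion lies within
# the enriched set E; returned as list(sets = list of per-position base sets,
# members = character combos)
valid_products <- function(E) {
  k <- nchar(E[1L])
  pos_letters <- lapply(seq_len(k), function(i) sort(unique(substr(E, i, i))))
  subsets <- function(v) {
    out <- list()
    for (m in seq_len(2^length(v) - 1L))
      out[[m]] <- v[bitwAnd(m, 2^(seq_along(v) - 1L)) > 0L]
    out
  }
  choices <- lapply(pos_letters, subsets)
  prods <- list()
  idx <- rep(1L, k)
  grid <- expand.grid(lapply(choices, seq_along))
  for (r in seq_len(nrow(grid))) {
    sets <- lapply(seq_len(k), function(i) choices[[i]][[grid[r, i]]])
    memb <- apply(expand.grid(sets, stringsAsFactors = FALSE), 1L, paste, collapse = "")
    if (all(memb %in% E))
      prods[[length(prods) + 1L]] <- list(sets = sets, members = memb)
  }
  # non-maximal products are kept: the cover objective prefers disjoint
  # partitions, which may use products contained in larger valid ones
  prods
}

sets_to_iupac <- function(sets) {
  paste(vapply(sets, function(s) {
    s <- sort(s)
    for (nm in names(IUPAC_SETS))
      if (length(IUPAC_SETS[[nm]]) == length(s) && all(IUPAC_SETS[[nm]] == s))
        return(nm)
    stop("no IUPAC code for set ", paste(s, collapse = ""))
  }, ""), collapse = "")
}

# Exact minimal cover by DFS over candidate products. The objective is
# lexicographic: fewest patterns; smallest total expansion (a disjoint
# partition beats overlapping products); largest product of pattern
# degeneracies (the most jointly degenerate description of the enriched
# set); then alphabetical patterns.
min_cover_exact <- function(E, prods, upper) {
  sizes <- vapply(prods, function(p) length(p$members), 0L)
  iup <- vapply(prods, function(p) sets_to_iupac(p$sets), "")
  best <- NULL
  solution_key <- function(chosen) {
    list(n = length(chosen), total = sum(sizes[chosen]),
         degen = prod(sizes[chosen]),
         pats = paste(sort(iup[chosen]), collapse = ","))
  }
  better_than <- function(a, b) {
    if (a$n != b$n) return(a$n < b$n)
    if (a$total != b$total) return(a$total < b$total)
    if (a$degen != b$degen) return(a$degen > b$degen)
    a$pats < b$pats
  }
  best_key <- list(n = upper + 1L, total = Inf, degen = 0, pats = "")
  containing <- lapply(E, function(e)
    which(vapply(prods, function(p) e %in% p$members, NA)))
  names(containing) <- E
  max_size <- max(sizes)
  memo <- new.env(parent = emptyenv())
  rec <- function(uncovered, chosen, total) {
    skey <- paste0("k", paste(uncovered, collapse = ""))
    prev <- memo[[skey]]
    cur <- c(length(chosen), total)
    # strict-dominance prune: equal (count, total) re-arrivals are explored
    # so the degeneracy/alphabetical tiebreaks can act
    if (!is.null(prev) &&
        (prev[1L] < cur[1L] || (prev[1L] == cur[1L] && prev[2L] < cur[2L]))) return()
    memo[[skey]] <- cur
    if (!length(uncovered)) {
      key <- solution_key(chosen)
      if (better_than(key, best_key)) {
        best <<- chosen
        best_key <<- key
      }
      return()
    }
    if (length(chosen) + ceiling(length(uncovered) / max_size) > best_key$n)
      return()
    cand <- containing[[uncovered[1L]]]
    cand <- cand[order(-sizes[cand], iup[cand])]
    for (pi in cand)
      rec(setdiff(uncovered, prods[[pi]]$members), c(chosen, pi),
          total + sizes[pi])
  }
  rec(E, integer(0), 0L)
  best
}

#' Call a degenerate PAM consensus
#'
#' Combinations whose enrichment ratio reaches \code{tau} times the maximum
#' ratio form the enriched set E; the consensus is a minimal set of
#' per-position IUPAC product patterns whose expansions lie within and
#' together cover E exactly (lossless cover), found greedily (largest valid
#' product first) with an exhaustive search fallback for small E.
#'
#' @param table A \code{pam_enrichment}.
#' @param tau Relative enrichment threshold in (0, 1].
#' @param pam_len Full PAM length for N-prefixed reporting.
#' @return A \code{pam_consensus} object: \code{patterns} (IUPAC strings over
#'   the selected positions), \code{patterns_full} (N-padded to
#'   \code{pam_len}), the enriched set and the threshold used.
#' @export
call_consensus <- function(table, tau = 0.2, pam_len = 8L) {
  if (!nrow(table) || max(table$ratio) <= 0 || !is.finite(max(table$ratio)))
    stop("no enriched PAMs")
  E <- table$combo[table$ratio >= tau * max(table$ratio)]
  if (!length(E)) stop("no enriched PAMs")
  positions <- attr(table, "positions")
  k <- nchar(E[1L])
  if (length(E) == 4^k) {
    # degenerate: everything enriched
    full <- paste(rep("N", pam_len), collapse = "")
    return(structure(list(patterns = strrep("N", k), patterns_full = full,
                          enriched = sort(E), tau = tau, positions = positions),
                     class = "pam_consensus"))
  }
  prods <- valid_products(E)
  # greedy cover (upper bound; also the answer when E is large)
  uncovered <- E
  chosen <- integer(0)
  while (length(uncovered)) {
    gain <- vapply(prods, function(p) sum(uncovered %in% p$members), 0L)
    size <- vapply(prods, function(p) length(p$members), 0L)
    iup <- vapply(prods, function(p) sets_to_iupac(p$sets), "")
    pick <- order(-gain, size, iup)[1L]
    if (gain[pick] == 0L) stop("cover construction failed")  # cannot happen: singletons are products
    chosen <- c(chosen, pick)
    uncovered <- setdiff(uncovered, prods[[pick]]$members)
  }
  if (length(E) <= 32L && length(prods) <= 2000L) {
    ex <- min_cover_exact(E, prods, upper = length(chosen))
    if (!is.null(ex)) chosen <- ex
  }
  pats <- sort(vapply(prods[chosen], function(p) sets_to_iupac(p$sets), ""))
  expansion <- sort(unique(unlist(lapply(prods[chosen], `[[`, "members"))))
  stopifnot(identical(expansion, sort(E)))   # lossless cover invariant
  positions <- attr(table, "positions")
  full <- vapply(pats, function(p) {
    ch <- rep("N", pam_len)
    ch[positions] <- strsplit(p, "")[[1]]
    paste(ch, collapse = "")
  }, "", USE.NAMES = FALSE)
  structure(list(patterns = pats, patterns_full = full, enriched = sort(E),
                 tau = tau, positions = positions),
            class = "pam_consensus")
}

#' @export
print.pam_consensus <- function(x, ...) {
  cat("<pam_consensus>", length(x$enriched), "enriched combinations, tau =",
      x$tau, "\n  patterns:", paste(x$patterns_full, collapse = ", "), "\n")
  invisible(x)
}

#' Infer cut-site offset and end geometry
#'
#' From per-strand adapter-ligation end positions (measured as the distance
#' from the PAM-proximal protospacer end, counting into the protospacer), the
#' modal position per strand gives the cut offset; coinciding modes mean a
#' blunt cut, otherwise the signed difference is an overhang (top mode
#' greater than bottom = 5' overhang).
#'
#' @param ends Data.frame with columns \code{strand} (\code{"+"}/\code{"-"})
#'   and \code{pos} (bp upstream of the PAM).
#' @param min_support Minimum reads per strand.
#' @return A \code{cut_site_call}: \code{offset_bp}, \code{geometry},
#'   \code{overhang}, \code{support}; geometry \code{"undetermined"} when
#'   support is insufficient.
#' @export
infer_cut_site <- function(ends, min_support = 10L) {
  stopifnot(all(c("strand", "pos") %in% names(ends)))
  sup <- table(factor(ends$strand, levels = c("+", "-")))
  if (any(sup < min_support))
    return(structure(list(offset_bp = NA_integer_, geometry = "undetermined",
                          overhang = NA_integer_, support = as.integer(sum(sup))),
                     class = "cut_site_call"))
  mode_of <- function(x) {
    t <- table(x)
    as.integer(names(t)[order(-t, as.integer(names(t)))][1L])
  }
  top <- mode_of(ends$pos[ends$strand == "+"])
  bot <- mode_of(ends$pos[ends$strand == "-"])
  d <- top - bot
  geometry <- if (d == 0L) "blunt"
  else if (d > 0L) sprintf("five_prime_overhang(%d)", d)
  else sprintf("three_prime_overhang(%d)", -d)
  structure(list(offset_bp = top, geometry = geometry, overhang = abs(d),
                 support = as.integer(sum(sup))),
            class = "cut_site_call")
}

#' @export
print.cut_site_call <- function(x, ...) {
  cat(sprintf("<cut_site_call offset %s bp, %s, support %d>\n",
              format(x$offset_bp), x$geometry, x$support))
  invisible(x)
}
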