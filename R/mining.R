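#' @useDynLib casforge, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# unit +1/-1 substitution matrix over an explicit alphabet
submat_unit <- function(letters, match = 1, mismatch = -1) {
  m <- matrix(mismatch, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- match
  m
}

# Global alignment with the package's declared scoring (+1 match, -1 mismatch,
# -2 per gap position). Returns the two aligned strings and the score.
align_global <- function(a, b, alphabet = NULL) {
  if (is.null(alphabet)) alphabet <- unique(c(strsplit(a, "")[[1]], strsplit(b, "")[[1]]))
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global",
    substitutionMatrix = submat_unit(alphabet),
    gapOpening = 0, gapExtension = 2)
  list(a = as.character(Biostrings::alignedPattern(aln)),
       b = as.character(Biostrings::alignedSubject(aln)),
       score = Biostrings::score(aln))
}

# identity/coverage of a global alignment, excluding terminal gap columns
alignment_identity <- function(a_aln, b_aln, shorter_len) {
  ca <- strsplit(a_aln, "")[[1]]
  cb <- strsplit(b_aln, "")[[1]]
  n <- length(ca)
  first <- 1L
  while (first <= n && (ca[first] == "-" || cb[first] == "-")) first <- first + 1L
  last <- n
  while (last >= first && (ca[last] == "-" || cb[last] == "-")) last <- last - 1L
  if (last < first) return(list(identity = 0, coverage = 0))
  ca <- ca[first:last]; cb <- cb[first:last]
  cols <- length(ca)
  matches <- sum(ca == cb & ca != "-")
  shorter_in <- min(sum(ca != "-"), sum(cb != "-"))
  list(identity = matches / cols, coverage = shorter_in / shorter_len)
}

#' Detect CRISPR arrays in a contig
#'
#' A seed-and-extend repeat finder in the style of CRT/MinCED: exact k-mer
#' recurrences at array-compatible periods seed candidate repeat chains, which
#' are extended outward column-by-column while the copies agree (each copy may
#' accumulate at most \code{max_repeat_mismatches} mismatches against the
#' column consensus), then validated against the MinCED-default length bounds
#' (repeats 23-47 nt, spacers 26-50 nt, at least 3 repeats).
#'
#' @param contig A single-record \code{sequence_set} or a DNA string.
#' @param params Mining parameter list (see \code{default_config()$mining}).
#' @param contig_id Contig name when \code{contig} is a bare string.
#' @return A list of \code{crispr_array} objects with non-overlapping spans,
#'   each carrying the repeat consensus, per-copy repeat spans and spacer
#'   sequences.
#' @export
detect_crispr_arrays <- function(contig, params = default_config()$mining,
                                 contig_id = "contig") {
  if (inherits(contig, "sequence_set")) {
    contig_id <- contig$id[1L]
    s <- contig$sequence[1L]
  } else s <- toupper(as.character(contig))
  L <- nchar(s)
  k <- params$seed_word
  if (L < 2L * params$repeat_min + params$spacer_min) return(list())
  dmin <- params$repeat_min + params$spacer_min
  dmax <- params$repeat_max + params$spacer_max

  starts <- seq_len(L - k + 1L)
  kmers <- substring(s, starts, starts + k - 1L)
  occ <- split(starts, kmers)
  occ <- occ[lengths(occ) >= params$min_repeats]
  if (!length(occ)) return(list())
  occ <- occ[order(vapply(occ, `[`, 0L, 1L))]

  chars <- strsplit(s, "")[[1]]
  candidates <- list()
  seen_spans <- character(0)

  for (P in occ) {
    used <- logical(length(P))
    for (si in seq_along(P)) {
      if (used[si]) next
      chain <- P[si]; used[si] <- TRUE
      # context window after the seed used to tell true repeat copies from
      # chance k-mer recurrences (e.g. inside a spacer) when chaining
      ctx_of <- function(p) chars[p:min(L, p + k + 11L)]
      ctx0 <- ctx_of(P[si])
      repeat {
        nxt <- which(!used & P - chain[length(chain)] >= dmin &
                       P - chain[length(chain)] <= dmax)
        if (!length(nxt)) break
        sim <- vapply(nxt, function(t) {
          cc <- ctx_of(P[t])
          n <- min(length(cc), length(ctx0))
          sum(cc[seq_len(n)] == ctx0[seq_len(n)])
        }, 0L)
        pick <- nxt[order(-sim, P[nxt])][1L]
        used[pick] <- TRUE
        chain <- c(chain, P[pick])
      }
      if (length(chain) < params$min_repeats) next
      arr <- extend_repeat_chain(chars, chain, k, params, L)
      if (is.null(arr)) next
      key <- paste(arr$start, arr$end)
      if (key %in% seen_spans) next
      seen_spans <- c(seen_spans, key)
      arr$contig_id <- contig_id
      candidates[[length(candidates) + 1L]] <- arr
    }
  }
  if (!length(candidates)) return(list())
  # a short chain seeded at, say, a spacer/repeat junction k-mer is a
  # fragment of the full array: accept maximal arrays first, then drop
  # overlapping fragments
  ord <- order(-vapply(candidates, `[[`, 0L, "n_repeats"),
               -vapply(candidates, function(a) a$end - a$start, 0L),
               vapply(candidates, `[[`, 0L, "start"))
  covered <- logical(L)
  arrays <- list()
  for (arr in candidates[ord]) {
    if (any(covered[arr$start:arr$end])) next
    covered[arr$start:arr$end] <- TRUE
    arrays[[length(arrays) + 1L]] <- arr
  }
  arrays <- arrays[order(vapply(arrays, `[[`, 0L, "start"))]
  lapply(arrays, function(a) { class(a) <- "crispr_array"; a })
}

# Extend anchors of a seed chain outward while copies agree; validate bounds.
extend_repeat_chain <- function(chars, anchors, k, params, L) {
  m <- length(anchors)
  budget <- integer(m)
  left <- 0L; right <- 0L
  step <- function(pos, dir) {
    # TRUE if the column at `pos` (one char per copy) extends the repeat.
    # A column where one copy mismatches the consensus is accepted only if
    # that copy still has mismatch budget AND the next column outward is
    # fully conserved -- otherwise chance agreement among few copies would
    # creep the boundary into the spacers.
    if (any(pos < 1L | pos > L)) return(FALSE)
    if (k + left + right + 1L > params$repeat_max) return(FALSE)
    cc <- chars[pos]
    cons_c <- names(which.max(table(cc)))
    mis <- which(cc != cons_c)
    if (length(mis) > 1L) return(FALSE)
    if (length(mis) == 1L) {
      if (budget[mis] >= params$max_repeat_mismatches) return(FALSE)
      nxt <- pos + dir
      if (any(nxt < 1L | nxt > L)) return(FALSE)
      if (length(unique(chars[nxt])) != 1L) return(FALSE)
      budget[mis] <<- budget[mis] + 1L
    }
    TRUE
  }
  while (step(anchors + k + right, +1L)) right <- right + 1L
  while (step(anchors - left - 1L, -1L)) left <- left + 1L

  rep_len <- k + left + right
  if (rep_len < params$repeat_min || rep_len > params$repeat_max) return(NULL)
  rs <- anchors - left
  re <- anchors + k - 1L + right
  # trim copies whose boundary spacers violate the length bounds
  keep_first <- 1L; keep_last <- m
  repeat {
    if (keep_last - keep_first + 1L < params$min_repeats) return(NULL)
    gaps <- rs[(keep_first + 1L):keep_last] - re[keep_first:(keep_last - 1L)] - 1L
    bad <- which(gaps < params$spacer_min | gaps > params$spacer_max)
    if (!length(bad)) break
    if (bad[1L] == 1L) keep_first <- keep_first + 1L
    else if (bad[length(bad)] == length(gaps)) keep_last <- keep_last - 1L
    else return(NULL)
  }
  idx <- keep_first:keep_last
  rs <- rs[idx]; re <- re[idx]
  m <- length(idx)
  cons <- vapply(0:(rep_len - 1L), function(o)
    names(which.max(table(chars[rs + o]))), "")
  spacers <- vapply(seq_len(m - 1L), function(i)
    paste(chars[(re[i] + 1L):(rs[i + 1L] - 1L)], collapse = ""), "")
  list(contig_id = NA_character_, start = rs[1L], end = re[m],
       repeat_consensus = paste(cons, collapse = ""),
       repeat_spans = cbind(start = rs, end = re),
       spacers = spacers, n_repeats = m, n_spacers = m - 1L)
}

#' @export
print.crispr_array <- function(x, ...) {
  cat(sprintf("<crispr_array %s:%d-%d  %d repeats (%d nt), %d spacers>\n",
              x$contig_id, x$start, x$end, x$n_repeats,
              nchar(x$repeat_consensus), x$n_spacers))
  invisible(x)
}

interval_gap <- function(s1, e1, s2, e2) max(0L, max(s1, s2) - min(e1, e2) - 1L)

#' Assemble candidate CRISPR-Cas9 loci
#'
#' Pairs each detected array with cas9/cas1/cas2 annotations on the same
#' contig such that the maximum edge-to-edge gap between any two locus
#' components does not exceed \code{max_locus_gap} (10 kbp). Loci missing any
#' of the four components are not emitted.
#'
#' @param arrays List of \code{crispr_array}.
#' @param features A \code{feature_set} with cas gene annotations.
#' @param max_locus_gap Maximum pairwise component gap in bp.
#' @return A list of \code{crispr_locus} objects (possibly empty).
#' @export
assemble_loci <- function(arrays, features, max_locus_gap = 10000L) {
  loci <- list()
  for (arr in arrays) {
    fc <- features[features$contig_id == arr$contig_id, , drop = FALSE]
    cas9s <- which(fc$kind == "cas9")
    for (i9 in cas9s) {
      comp <- rbind(c(arr$start, arr$end), c(fc$start[i9], fc$end[i9]))
      if (interval_gap(comp[1, 1], comp[1, 2], comp[2, 1], comp[2, 2]) > max_locus_gap) next
      pick <- function(kind) {
        cand <- which(fc$kind == kind)
        if (!length(cand)) return(NA_integer_)
        g <- vapply(cand, function(j)
          interval_gap(arr$start, arr$end, fc$start[j], fc$end[j]), 0L)
        cand[order(g, fc$start[cand])]
      }
      found <- NULL
      for (i1 in pick("cas1")) {
        if (is.na(i1)) break
        for (i2 in pick("cas2")) {
          if (is.na(i2)) break
          idx <- c(i1, i2, i9)
          spans <- rbind(c(arr$start, arr$end),
                         cbind(fc$start[idx], fc$end[idx]))
          ok <- TRUE
          for (a in 1:3) for (b in (a + 1):4)
            if (interval_gap(spans[a, 1], spans[a, 2], spans[b, 1], spans[b, 2]) >
                max_locus_gap) ok <- FALSE
          if (ok) { found <- c(i1, i2); break }
        }
        if (!is.null(found)) break
      }
      if (is.null(found)) next
      a9 <- fc$attributes[[i9]]
      locus <- list(
        array = arr,
        cas1 = fc[found[1L], , drop = FALSE],
        cas2 = fc[found[2L], , drop = FALSE],
        cas9 = fc[i9, , drop = FALSE],
        species_id = a9$species_id %||% arr$contig_id,
        coverage = as.numeric(a9$coverage %||% NA_real_),
        complete = TRUE,
        locus_id = sprintf("%s_%d_%d", arr$contig_id, arr$start, fc$start[i9]))
      class(locus) <- "crispr_locus"
      loci[[length(loci) + 1L]] <- locus
    }
  }
  loci
}

#' @export
print.crispr_locus <- function(x, ...) {
  cat(sprintf("<crispr_locus %s  species %s  cas9 %s aa  %d spacers  coverage %sx>\n",
              x$locus_id, x$species_id,
              format(x$cas9$attributes[[1]]$protein_length_aa %||% NA),
              x$array$n_spacers, format(x$coverage)))
  invisible(x)
}

#' Filter loci on Cas9 length and array size
#'
#' Retains loci whose Cas9 length satisfies
#' \code{min_cas9_aa <= length < max_cas9_aa} (discarding proteins shorter
#' than 950 aa and selecting short proteins below 1100 aa) and whose array has
#' more than 5 spacers (\code{n_spacers >= min_spacers}).
#'
#' @param loci List of \code{crispr_locus}.
#' @param min_cas9_aa,max_cas9_aa Protein-length bounds in amino acids.
#' @param min_spacers Minimum spacer count.
#' @return The surviving loci (a subset of the input; idempotent).
#' @export
filter_loci <- function(loci, min_cas9_aa = 950L, max_cas9_aa = 1100L,
                        min_spacers = 6L) {
  keep <- vapply(loci, function(lc) {
    len <- lc$cas9$attributes[[1]]$protein_length_aa
    if (is.null(len) || is.na(len))
      stop("locus ", lc$locus_id, " lacks a protein_length_aa annotation")
    len >= min_cas9_aa && len < max_cas9_aa && lc$array$n_spacers >= min_spacers
  }, NA)
  loci[keep]
}

# deletion runs (gaps in the member) in reference coordinates
deletion_runs_vs_ref <- function(member, ref) {
  aln <- align_global(member, ref, alphabet = ALPHABETS$protein)
  ca <- strsplit(aln$a, "")[[1]]
  cb <- strsplit(aln$b, "")[[1]]
  refpos <- cumsum(cb != "-")
  r <- rle(ca == "-" & cb != "-")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (!length(runs)) return(matrix(numeric(0), ncol = 3,
                                   dimnames = list(NULL, c("ref_start", "ref_end", "len"))))
  cbind(ref_start = refpos[starts[runs]], ref_end = refpos[ends[runs]],
        len = r$lengths[runs])
}

#' Select one locus per species by coverage
#'
#' Within each species group, member Cas9 proteins are globally aligned to the
#' group reference; members showing a deletion (gap run of at least
#' \code{deletion_min_aa} residues) inside a configured nuclease-domain span
#' are discarded, and of the remainder the locus with the highest sequencing
#' coverage is selected (ties broken by longer protein, then lexicographic
#' locus id).
#'
#' @param loci List of \code{crispr_locus} carrying \code{protein_sequence}
#'   and \code{coverage} attributes on the cas9 feature.
#' @param domain_spans Named list (by species id); each element a list with
#'   optional \code{reference_id} (locus id; default the longest member) and
#'   \code{spans}, a matrix/list of \code{c(start, end)} amino-acid ranges on
#'   the reference protein.
#' @param deletion_min_aa Minimum gap-run length treated as a deletion.
#' @return A list with one locus per species group (groups whose members are
#'   all discarded are dropped, with a message).
#' @export
dedupe_by_coverage <- function(loci, domain_spans = list(), deletion_min_aa = 5L) {
  if (!length(loci)) return(list())
  sp <- vapply(loci, `[[`, "", "species_id")
  out <- list()
  for (g in unique(sp)) {
    members <- loci[sp == g]
    prot <- vapply(members, function(lc) {
      p <- lc$cas9$attributes[[1]]$protein_sequence
      if (is.null(p)) stop("locus ", lc$locus_id, " lacks a protein_sequence annotation")
      p
    }, "")
    ids <- vapply(members, `[[`, "", "locus_id")
    spans <- domain_spans[[g]]
    if (length(members) > 1L && !is.null(spans) && length(spans$spans)) {
      ref_id <- spans$reference_id %||% ids[order(-nchar(prot), ids)][1L]
      ref <- prot[[match(ref_id, ids)]]
      sm <- spans$spans
      if (is.list(sm)) sm <- do.call(rbind, sm)
      ok <- vapply(seq_along(members), function(i) {
        runs <- deletion_runs_vs_ref(prot[i], ref)
        if (!nrow(runs)) return(TRUE)
        for (ri in seq_len(nrow(runs))) {
          if (runs[ri, "len"] < deletion_min_aa) next
          for (si in seq_len(nrow(sm)))
            if (runs[ri, "ref_start"] <= sm[si, 2] && runs[ri, "ref_end"] >= sm[si, 1])
              return(FALSE)
        }
        TRUE
      }, NA)
      if (!any(ok)) {
        message("dedupe_by_coverage: all members of group '", g,
                "' discarded (nuclease-domain deletions)")
        next
      }
      members <- members[ok]; prot <- prot[ok]; ids <- ids[ok]
    }
    cov <- vapply(members, function(lc) lc$coverage %||% NA_real_, 0)
    cov[is.na(cov)] <- -Inf
    pick <- order(-cov, -nchar(prot), ids)[1L]
    out[[g]] <- members[[pick]]
  }
  unname(out)
}

#' Greedy identity clustering of protein sequences
#'
#' CD-HIT-style incremental clustering: sequences are sorted by decreasing
#' length and each joins the first existing centroid with global-alignment
#' identity at least \code{identity} over an alignment covering at least
#' \code{coverage} of the shorter sequence (identity = matches / alignment
#' columns, terminal gaps excluded); otherwise it founds a new cluster.
#'
#' @param records A \code{sequence_set} of proteins.
#' @param identity Identity threshold in (0, 1].
#' @param coverage Coverage threshold in (0, 1].
#' @return A list of \code{sequence_cluster} objects
#'   (\code{centroid_id}, \code{member_ids}, thresholds).
#' @export
cluster_sequences <- function(records, identity, coverage) {
  stopifnot(identity > 0, identity <= 1, coverage > 0, coverage <= 1)
  if (!nrow(records)) return(list())
  ord <- order(-nchar(records$sequence), records$id)
  centroids <- character(0)
  cent_seq <- character(0)
  members <- list()
  for (i in ord) {
    sq <- records$sequence[i]
    placed <- FALSE
    for (ci in seq_along(centroids)) {
      aln <- align_global(sq, cent_seq[ci], alphabet = ALPHABETS$protein)
      m <- alignment_identity(aln$a, aln$b, min(nchar(sq), nchar(cent_seq[ci])))
      if (m$identity >= identity && m$coverage >= coverage) {
        members[[ci]] <- c(members[[ci]], records$id[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      centroids <- c(centroids, records$id[i])
      cent_seq <- c(cent_seq, sq)
      members[[length(centroids)]] <- records$id[i]
    }
  }
  lapply(seq_along(centroids), function(ci) {
    structure(list(centroid_id = centroids[ci], member_ids = members[[ci]],
                   identity_threshold = identity, coverage_threshold = coverage),
              class = "sequence_cluster")
  })
}

#' @export
print.sequence_cluster <- function(x, ...) {
  cat(sprintf("<sequence_cluster centroid %s  %d member(s)  id>=%.2f cov>=%.2f>\n",
              x$centroid_id, length(x$member_ids),
              x$identity_threshold, x$coverage_threshold))
  invisible(x)
}

#' Exclude length outliers from a cluster
#'
#' Removes members whose length lies more than two population standard
#' deviations below the median cluster length (a guard against partial or
#' fragmented sequences).
#'
#' @param cluster A \code{sequence_cluster}.
#' @param member_lengths Named numeric vector of member lengths (aa).
#' @param n_sd Number of standard deviations below the median.
#' @return The cluster with outlying members removed (centroid reassigned to
#'   the longest survivor if the centroid itself is removed).
#' @export
filter_length_outliers <- function(cluster, member_lengths, n_sd = 2) {
  len <- member_lengths[cluster$member_ids]
  if (anyNA(len)) stop("missing lengths for: ",
                       paste(cluster$member_ids[is.na(len)], collapse = ", "))
  sd_pop <- sqrt(mean((len - mean(len))^2))
  thr <- stats::median(len) - n_sd * sd_pop
  keep <- len >= thr
  cluster$member_ids <- cluster$member_ids[keep]
  if (!cluster$centroid_id %in% cluster$member_ids && length(cluster$member_ids)) {
    kl <- len[keep]
    cluster$centroid_id <- cluster$member_ids[order(-kl, cluster$member_ids)][1L]
  }
  cluster
}
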