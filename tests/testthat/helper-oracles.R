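# Independent oracles used by the tests. These deliberately re-derive results
# by brute force / direct dynamic programming, separate from the package's
# implementation paths.

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

oracle_pairable_rna <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

# every nested pair set with hairpin loops >= 3 (no helix-length constraint)
oracle_all_structures <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  rec <- function(i, j) {
    if (i > j) return(list(matrix(integer(0), ncol = 2)))
    out <- list()
    for (s1 in rec(i + 1L, j)) out[[length(out) + 1L]] <- s1
    if (j >= i + 4L) for (k in (i + 4L):j) {
      if (!oracle_pairable_rna(ch[i], ch[k])) next
      for (a in rec(i + 1L, k - 1L)) for (b in rec(k + 1L, j))
        out[[length(out) + 1L]] <- rbind(c(i, k), a, b)
    }
    out
  }
  rec(1L, n)
}

oracle_nolp_ok <- function(m) {
  if (!nrow(m)) return(TRUE)
  key <- paste(m[, 1], m[, 2])
  all(paste(m[, 1] + 1L, m[, 2] - 1L) %in% key |
        paste(m[, 1] - 1L, m[, 2] + 1L) %in% key)
}

# maximum pair count over all no-lonely-pair structures, by enumeration
oracle_max_pairs <- function(seq) {
  ok <- Filter(oracle_nolp_ok, oracle_all_structures(seq))
  max(vapply(ok, nrow, 0L))
}

canonical_pairs <- function(m) {
  if (!nrow(m)) return("")
  o <- order(m[, 1])
  paste(m[o, 1], m[o, 2], collapse = ";")
}

# Smith-Waterman local alignment, match +1 / mismatch -1, affine gaps costing
# gap_open for the first position and gap_extend for each further position;
# returns the maximum local score
oracle_sw_score <- function(a, b, gap_open = 2, gap_extend = 1) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  n <- length(ac); m <- length(bc)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)       # ends in match/mismatch
  X <- matrix(NEG, n + 1, m + 1)     # ends in gap in b (deletion)
  Y <- matrix(NEG, n + 1, m + 1)     # ends in gap in a (insertion)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- if (ac[i - 1] == bc[j - 1]) 1 else -1
    M[i, j] <- max(0, M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
    X[i, j] <- max(M[i - 1, j] - gap_open, X[i - 1, j] - gap_extend)
    Y[i, j] <- max(M[i, j - 1] - gap_open, Y[i, j - 1] - gap_extend)
    best <- max(best, M[i, j], X[i, j], Y[i, j])
  }
  best
}

# global Needleman-Wunsch (+1/-1, linear gap -2) identity excluding terminal
# gap columns, for the clustering oracle
oracle_nw_identity <- function(a, b) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  n <- length(ac); m <- length(bc)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- -2 * (0:n)
  S[1, ] <- -2 * (0:m)
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- if (ac[i - 1] == bc[j - 1]) 1 else -1
    S[i, j] <- max(S[i - 1, j - 1] + s, S[i - 1, j] - 2, S[i, j - 1] - 2)
  }
  # traceback
  i <- n + 1; j <- m + 1
  cola <- character(0); colb <- character(0)
  while (i > 1 || j > 1) {
    if (i > 1 && j > 1 &&
        S[i, j] == S[i - 1, j - 1] + (if (ac[i - 1] == bc[j - 1]) 1 else -1)) {
      cola <- c(ac[i - 1], cola); colb <- c(bc[j - 1], colb)
      i <- i - 1; j <- j - 1
    } else if (i > 1 && S[i, j] == S[i - 1, j] - 2) {
      cola <- c(ac[i - 1], cola); colb <- c("-", colb); i <- i - 1
    } else {
      cola <- c("-", cola); colb <- c(bc[j - 1], colb); j <- j - 1
    }
  }
  first <- 1L
  while (first <= length(cola) && (cola[first] == "-" || colb[first] == "-"))
    first <- first + 1L
  last <- length(cola)
  while (last >= first && (cola[last] == "-" || colb[last] == "-"))
    last <- last - 1L
  sum(cola[first:last] == colb[first:last]) / (last - first + 1L)
}

expand_iupac <- function(p) {
  sets <- casforge:::IUPAC_SETS[strsplit(p, "")[[1]]]
  apply(expand.grid(sets, stringsAsFactors = FALSE), 1, paste, collapse = "")
}

all_kmers <- function(k) {
  sort(apply(expand.grid(rep(list(c("A", "C", "G", "T")), k),
                         stringsAsFactors = FALSE)[, k:1, drop = FALSE],
             1, paste, collapse = ""))
}

# enrichment table stub for consensus tests
toy_enrichment <- function(enriched, hi = 5, lo = 0.1, positions = 5:8) {
  tab <- data.frame(combo = all_kmers(4))
  tab$ratio <- ifelse(tab$combo %in% enriched, hi, lo)
  attr(tab, "positions") <- positions
  class(tab) <- c("pam_enrichment", "data.frame")
  tab
}

default_window <- function(positions = 4:8) {
  structure(list(positions = positions, threshold = 0.1),
            class = "editing_window")
}

mutate_at <- function(seq, pos) {
  comp <- c(A = "C", C = "A", G = "T", T = "G")
  for (p in pos) substr(seq, p, p) <- comp[[substr(seq, p, p)]]
  seq
}
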