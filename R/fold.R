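#' Predict RNA secondary structure
#'
#' The default \code{maxpair} engine is a base-pair-maximization folder
#' (Watson-Crick plus G.U pairs, hairpin loops of at least 3 nt, no
#' pseudoknots, no lonely pairs when \code{noLP}) that returns every structure
#' whose pair count is within \code{band} pairs of the optimum. The
#' \code{external} engine shells out to ViennaRNA's \code{RNAsubopt}
#' (\code{--noLP -e band}) when it is available on the PATH, in which case
#' \code{band} is in kcal/mol and scores are free energies.
#'
#' @param seq An RNA string (alphabet ACGUN; N never pairs).
#' @param engine \code{"maxpair"} (default) or \code{"external"}.
#' @param band Suboptimal band: pairs below optimum (maxpair; default 1) or
#'   kcal/mol above the MFE (external; default 5).
#' @param noLP Disallow isolated base pairs.
#' @param max_structures Cap on the number of reported structures.
#' @return A \code{structure_prediction}: list with \code{structures} (list of
#'   two-column pair matrices, 1-based), \code{scores}, \code{dot_bracket},
#'   \code{engine}, \code{band}, \code{n} and \code{truncated}.
#' @export
fold <- function(seq, engine = c("maxpair", "external"), band = NULL,
                 noLP = TRUE, max_structures = 100L) {
  engine <- match.arg(engine)
  seq <- toupper(seq)
  if (nchar(seq) > 400L) stop("sequence longer than 400 nt")
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), ALPHABETS$rna)
  if (length(bad)) stop("non-RNA characters in sequence: ", paste(bad, collapse = ""))
  if (engine == "maxpair") {
    if (is.null(band)) band <- 1L
    r <- .fold_maxpair(seq, band = as.integer(band), noLP = noLP,
                       max_structures = as.integer(max_structures))
    ord <- order(-r$scores)
    out <- list(structures = r$structures[ord], scores = r$scores[ord],
                max_score = r$max_pairs, truncated = r$truncated)
  } else {
    if (is.null(band)) band <- 5
    if (Sys.which("RNAsubopt") == "")
      stop("external engine requested but RNAsubopt is not on the PATH")
    args <- c("-e", format(band))
    if (noLP) args <- c("--noLP", args)
    lines <- system2("RNAsubopt", args, input = seq, stdout = TRUE)
    lines <- grep("^[.()]+\\s", lines, value = TRUE)
    db <- sub("\\s.*$", "", lines)
    en <- as.numeric(sub("^\\S+\\s+", "", lines))
    if (length(db) > max_structures) {
      keep <- order(en)[seq_len(max_structures)]
      db <- db[keep]; en <- en[keep]
    }
    ord <- order(en)
    out <- list(structures = lapply(db[ord], db_to_pairs),
                scores = en[ord], max_score = min(en), truncated = FALSE)
  }
  out$engine <- engine
  out$band <- band
  out$n <- nchar(seq)
  out$dot_bracket <- vapply(out$structures, pairs_to_db, "", n = nchar(seq))
  class(out) <- "structure_prediction"
  out
}

pairs_to_db <- function(pairs, n) {
  ch <- rep(".", n)
  if (nrow(pairs)) {
    ch[pairs[, 1]] <- "("
    ch[pairs[, 2]] <- ")"
  }
  paste(ch, collapse = "")
}

db_to_pairs <- function(db) {
  ch <- strsplit(db, "")[[1]]
  stack <- integer(0)
  out <- matrix(integer(0), ncol = 2)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      out <- rbind(out, c(stack[length(stack)], i))
      stack <- stack[-length(stack)]
    }
  }
  out[order(out[, 1]), , drop = FALSE]
}

#' @export
print.structure_prediction <- function(x, ...) {
  cat(sprintf("<structure_prediction %s engine, %d structure(s), best score %s>\n",
              x$engine, length(x$structures), format(x$max_score)))
  if (length(x$dot_bracket)) cat(" ", x$dot_bracket[1L], "\n")
  invisible(x)
}

# Group a pair set into stem-loop units. A unit is the maximal chain of
# singly-nested pairs ending in a hairpin loop; returns one row per unit with
# the outermost pair and the number of pairs in the chain.
stemloop_units <- function(pairs) {
  if (!nrow(pairs)) return(data.frame(start = integer(0), end = integer(0),
                                      n_pairs = integer(0)))
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  np <- nrow(pairs)
  parent <- rep(NA_integer_, np)
  nchild <- integer(np)
  for (a in seq_len(np)) {
    enc <- which(pairs[, 1] < pairs[a, 1] & pairs[, 2] > pairs[a, 2])
    if (length(enc)) {
      p <- enc[which.max(pairs[enc, 1])]
      parent[a] <- p
      nchild[p] <- nchild[p] + 1L
    }
  }
  leaves <- which(nchild == 0L)
  units <- lapply(leaves, function(a) {
    size <- 1L
    while (!is.na(parent[a]) && nchild[parent[a]] == 1L) {
      a <- parent[a]
      size <- size + 1L
    }
    c(pairs[a, 1], pairs[a, 2], size)
  })
  u <- do.call(rbind, units)
  data.frame(start = u[, 1], end = u[, 2], n_pairs = u[, 3])
}
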