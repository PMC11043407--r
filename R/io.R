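ALPHABETS <- list(
  dna     = c("A", "C", "G", "T", "N"),
  rna     = c("A", "C", "G", "U", "N"),
  protein = c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "*")
)

#' Construct a set of sequence records
#'
#' The package's working container for sequences is a plain data frame with
#' columns \code{id}, \code{sequence}, \code{moltype} and \code{description}
#' (plus \code{quality} for reads). Sequences are uppercase and restricted to
#' the declared alphabet (DNA \code{ACGTN}, RNA \code{ACGUN}, protein 20
#' letters + \code{X}); ids must be unique.
#'
#' @param id Character vector of unique record ids.
#' @param sequence Character vector of sequences.
#' @param moltype One of \code{"dna"}, \code{"rna"}, \code{"protein"} or
#'   \code{NA} to infer from the alphabet (ambiguous sequences default to DNA;
#'   U and T are never silently interconverted).
#' @param description Free-text description per record.
#' @param quality Optional per-record quality string (FASTQ).
#' @return A \code{data.frame} of class \code{sequence_set}.
#' @export
sequence_set <- function(id, sequence, moltype = NA_character_,
                         description = "", quality = NULL) {
  sequence <- toupper(as.character(sequence))
  id <- as.character(id)
  if (anyDuplicated(id))
    stop("duplicate sequence id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  if (any(!nzchar(sequence)))
    stop("empty sequence for id(s): ", paste(id[!nzchar(sequence)], collapse = ", "))
  moltype <- rep_len(as.character(moltype), length(id))
  infer <- is.na(moltype)
  if (any(infer)) moltype[infer] <- vapply(sequence[infer], infer_moltype, "")
  for (i in seq_along(sequence)) {
    bad <- setdiff(unique(strsplit(sequence[i], "")[[1]]), ALPHABETS[[moltype[i]]])
    if (length(bad))
      stop(sprintf("sequence '%s' contains characters outside the %s alphabet: %s",
                   id[i], moltype[i], paste(bad, collapse = "")))
  }
  out <- data.frame(id = id, sequence = sequence, moltype = moltype,
                    description = rep_len(as.character(description), length(id)),
                    stringsAsFactors = FALSE)
  if (!is.null(quality)) out$quality <- rep_len(as.character(quality), length(id))
  class(out) <- c("sequence_set", "data.frame")
  out
}

infer_moltype <- function(seq) {
  ch <- unique(strsplit(seq, "")[[1]])
  if (all(ch %in% ALPHABETS$dna)) return("dna")
  if (all(ch %in% ALPHABETS$rna)) return("rna")
  if (all(ch %in% ALPHABETS$protein)) return("protein")
  stop("sequence fits no supported alphabet: ", paste(ch, collapse = ""))
}

#' Read a FASTA file
#'
#' Parsing is delegated to \code{Biostrings::readBStringSet}; a validation
#' layer enforces unique ids, non-empty sequences and alphabet membership,
#' reporting the offending line for structural problems.
#'
#' @param path Path to a FASTA file (plain or gzip).
#' @param moltype Force a molecule type, or \code{NA} to infer per record.
#' @return A \code{sequence_set}.
#' @export
read_fasta <- function(path, moltype = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA parse error in '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("FASTA parse error in '", path, "': no records")
  if (any(Biostrings::width(set) == 0L)) {
    idx <- which(Biostrings::width(set) == 0L)[1L]
    stop(sprintf("FASTA parse error in '%s': empty sequence at line %d (record '%s')",
                 path, fasta_header_line(path, idx), names(set)[idx]))
  }
  hdr <- names(set)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])[1L]
    stop(sprintf("FASTA parse error in '%s': duplicate id '%s' at line %d",
                 path, dup, fasta_header_line(path, which(id == dup)[2L])))
  }
  sequence_set(id, as.character(set), moltype = moltype, description = desc)
}

fasta_header_line <- function(path, record_index) {
  ln <- readLines(path, warn = FALSE)
  which(startsWith(ln, ">"))[record_index]
}

#' Write a FASTA file
#' @param records A \code{sequence_set}.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- if (nzchar(records$description[i]))
      paste(records$id[i], records$description[i]) else records$id[i]
    s <- records$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(c(paste0(">", hdr), substring(s, starts, pmin(starts + width - 1L, nchar(s)))),
               con, sep = "\n")
  }
  invisible(path)
}

#' Read a FASTQ file
#'
#' A structural pre-check enforces the 4-line record layout (header \code{@},
#' separator \code{+}, equal sequence/quality lengths) with line-numbered
#' errors; records are then loaded with \code{Biostrings}. Qualities are kept
#' in the \code{quality} column.
#'
#' @param path Path to a FASTQ file (plain or gzip).
#' @return A \code{sequence_set} with a \code{quality} column.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ln <- readLines(path, warn = FALSE)
  if (length(ln) == 0L) {
    out <- data.frame(id = character(), sequence = character(),
                      moltype = character(), description = character(),
                      quality = character(), stringsAsFactors = FALSE)
    class(out) <- c("sequence_set", "data.frame")
    return(out)
  }
  if (length(ln) %% 4L != 0L)
    stop(sprintf("FASTQ parse error in '%s': truncated record at line %d",
                 path, 4L * (length(ln) %/% 4L) + 1L))
  h <- ln[seq(1L, length(ln), by = 4L)]
  s <- ln[seq(2L, length(ln), by = 4L)]
  p <- ln[seq(3L, length(ln), by = 4L)]
  q <- ln[seq(4L, length(ln), by = 4L)]
  if (any(!startsWith(h, "@")))
    stop(sprintf("FASTQ parse error in '%s': header without '@' at line %d",
                 path, 4L * (which(!startsWith(h, "@"))[1L] - 1L) + 1L))
  if (any(!startsWith(p, "+")))
    stop(sprintf("FASTQ parse error in '%s': separator without '+' at line %d",
                 path, 4L * (which(!startsWith(p, "+"))[1L] - 1L) + 3L))
  if (any(nchar(s) != nchar(q)))
    stop(sprintf("FASTQ parse error in '%s': sequence/quality length mismatch at line %d",
                 path, 4L * (which(nchar(s) != nchar(q))[1L] - 1L) + 2L))
  hdr <- sub("^@", "", h)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  sequence_set(id, s, moltype = "dna", description = desc, quality = q)
}

#' Write a FASTQ file
#' @param records A \code{sequence_set} with a \code{quality} column.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_fastq <- function(records, path) {
  stopifnot(!is.null(records$quality))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- ifelse(nzchar(records$description),
                paste(records$id, records$description), records$id)
  writeLines(as.vector(rbind(paste0("@", hdr), records$sequence,
                             "+", records$quality)), con, sep = "\n")
  invisible(path)
}

FEATURE_KINDS <- c("cas1", "cas2", "cas9", "crispr_array", "other")

#' Construct a feature table
#'
#' Features use 1-based inclusive coordinates (GFF3 convention) throughout the
#' package. The \code{attributes} list-column carries key/value pairs such as
#' \code{protein_length_aa}, \code{protein_sequence}, \code{coverage} and
#' \code{species_id}.
#'
#' @param contig_id,start,end,strand,kind Vectors of equal length; \code{kind}
#'   is one of \code{cas1, cas2, cas9, crispr_array, other}.
#' @param attributes A list of named lists (one per feature).
#' @return A \code{data.frame} of class \code{feature_set}.
#' @export
feature_set <- function(contig_id, start, end, strand, kind, attributes = NULL) {
  n <- length(contig_id)
  start <- as.integer(start); end <- as.integer(end)
  if (any(end < start))
    stop("feature end < start at row ", which(end < start)[1L])
  if (any(start < 1L)) stop("feature start < 1")
  kind <- as.character(kind)
  if (any(!kind %in% FEATURE_KINDS))
    stop("unknown feature kind: ", paste(setdiff(kind, FEATURE_KINDS), collapse = ", "))
  if (is.null(attributes)) attributes <- replicate(n, list(), simplify = FALSE)
  out <- data.frame(contig_id = as.character(contig_id), start = start, end = end,
                    strand = as.character(strand), kind = kind,
                    stringsAsFactors = FALSE)
  out$attributes <- attributes
  class(out) <- c("feature_set", "data.frame")
  out
}

# GFF3 type/attribute -> closed feature kind
map_feature_kind <- function(type, attrs) {
  hint <- tolower(paste(type, vapply(attrs, function(a) {
    paste(unlist(a[names(a) %in% c("gene", "Name", "product", "ID")]), collapse = " ")
  }, "")))
  kind <- rep("other", length(type))
  for (k in c("cas9", "cas1", "cas2")) kind[grepl(k, hint)] <- k
  kind[grepl("crispr|repeat_region", hint)] <- "crispr_array"
  kind
}

#' Read a GFF3 annotation file
#'
#' Uses \code{rtracklayer::import} and maps feature types/attributes onto the
#' package's closed kind set (\code{cas1}, \code{cas2}, \code{cas9},
#' \code{crispr_array}, \code{other}).
#'
#' @param path Path to a GFF3 file.
#' @return A \code{feature_set} preserving file order.
#' @export
read_gff <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("GFF3 parse error in '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  md <- S4Vectors::mcols(gr)
  reserved <- c("source", "type", "score", "phase")
  keys <- setdiff(colnames(md), reserved)
  attrs <- lapply(seq_along(gr), function(i) {
    a <- list()
    for (k in keys) {
      v <- md[[k]][i]
      if (methods::is(v, "List") || is.list(v)) v <- unlist(v)
      if (length(v) && !all(is.na(v))) a[[k]] <- as.character(v)
    }
    for (nm in c("protein_length_aa", "coverage"))
      if (!is.null(a[[nm]])) a[[nm]] <- as.numeric(a[[nm]])
    a
  })
  feature_set(as.character(GenomeInfoDb::seqnames(gr)),
              BiocGenerics::start(gr), BiocGenerics::end(gr),
              as.character(BiocGenerics::strand(gr)),
              map_feature_kind(as.character(md$type), attrs), attrs)
}

#' Write a GFF3 annotation file
#' @param features A \code{feature_set}.
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @return \code{path}, invisibly.
#' @export
write_gff <- function(features, path, source = "casforge") {
  type <- ifelse(features$kind == "crispr_array", "repeat_region",
                 ifelse(features$kind == "other", "region", "CDS"))
  esc <- function(x) gsub(";", "%3B", gsub("=", "%3D", gsub("%", "%25", x)))
  attr_str <- vapply(seq_len(nrow(features)), function(i) {
    a <- features$attributes[[i]]
    a$gene <- a$gene %||% features$kind[i]
    if (is.null(a$ID)) a <- c(list(ID = sprintf("feat%04d", i)), a)
    paste(vapply(names(a), function(k) paste0(esc(k), "=", esc(paste(a[[k]], collapse = ","))), ""),
          collapse = ";")
  }, "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("##gff-version 3",
               paste(features$contig_id, source, type, features$start, features$end,
                     ".", features$strand, ".", attr_str, sep = "\t")), con, sep = "\n")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-complement a DNA string
#'
#' Handles the full IUPAC alphabet (R/Y, K/M, B/V, D/H, S, W, N), so
#' degenerate PAM patterns reverse-complement correctly.
#'
#' @param x Character vector of DNA sequences.
#' @return Reverse-complemented sequences.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTUNRYKMBDHVSWacgtunrykmbdhvsw",
           "TGCAANYRMKVHDBSWtgcaanyrmkvhdbsw",
           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, "", USE.NAMES = FALSE)
}

#' Transcribe DNA to RNA (T -> U)
#' @param x Character vector of DNA sequences (coding-strand sense).
#' @return RNA sequences.
#' @export
dna_to_rna <- function(x) chartr("Tt", "Uu", x)
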