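# Domain types for nucleotide sequences and tag sets, FASTA I/O and
# alphabet normalization.  A tag_set is a lightweight S3 container: ids and
# sequences as parallel character vectors.  Ids need not be unique;
# positions are stable.

#' Construct a tag set
#'
#' A tag set is an ordered, named collection of nucleotide sequences: CLIP
#' tags, background controls, or the oligonucleotides used in binding
#' assays.  Sequences are expected in the uppercase RNA alphabet
#' \code{A,C,G,U,N}; use \code{\link{normalize_tags}} to coerce arbitrary
#' input.
#'
#' @param seqs character vector of sequences.
#' @param ids character vector of labels, recycled if length 1; defaults to
#'   \code{names(seqs)} or \code{tag_1 ... tag_n}.
#' @param name label for the whole set.
#' @return An object of class \code{tag_set} with elements \code{name},
#'   \code{id} and \code{seq}.
#' @examples
#' ts <- tag_set(c("UAAACCCUAAA", "ACGU"), name = "example")
#' length(ts)
#' total_length(ts)
#' @export
tag_set <- function(seqs, ids = NULL, name = "tags") {
  nm <- names(seqs)
  seqs <- as.character(seqs)
  if (is.null(ids)) {
    ids <- nm
    if (is.null(ids)) {
      ids <- if (length(seqs)) paste0("tag_", seq_along(seqs)) else character()
    }
  }
  if (length(ids) == 1L && length(seqs) > 1L) ids <- rep(ids, length(seqs))
  stopifnot(length(ids) == length(seqs))
  structure(list(name = as.character(name)[1L],
                 id = as.character(ids),
                 seq = unname(seqs)),
            class = "tag_set")
}

#' @export
length.tag_set <- function(x) length(x$seq)

#' Total number of residues in a tag set
#' @param tags a \code{tag_set}.
#' @return Integer sum of sequence lengths.
#' @export
total_length <- function(tags) {
  stopifnot(inherits(tags, "tag_set"))
  sum(nchar(tags$seq))
}

#' @export
print.tag_set <- function(x, ...) {
  cat(sprintf("tag_set '%s': %d sequences, %d nt total\n",
              x$name, length(x), total_length(x)))
  n <- min(3L, length(x))
  for (i in seq_len(n)) {
    s <- x$seq[i]
    if (nchar(s) > 50) s <- paste0(substr(s, 1, 47), "...")
    cat(sprintf("  %s  %s\n", x$id[i], s))
  }
  if (length(x) > n) cat(sprintf("  ... and %d more\n", length(x) - n))
  invisible(x)
}

#' Normalize a nucleotide sequence to the RNA or DNA alphabet
#'
#' Uppercases, converts T/U to the target alphabet and maps any other
#' character to \code{N}.  Replacements are not fatal: their count is
#' attached as attribute \code{n_replaced} and reported via a message.
#' The operation is idempotent.
#'
#' @param x character vector of sequences.
#' @param target \code{"RNA"} (default; T becomes U) or \code{"DNA"}
#'   (U becomes T).
#' @param quiet suppress the replacement message.
#' @return Character vector of normalized sequences with attribute
#'   \code{n_replaced} (total characters mapped to N).
#' @examples
#' normalize_alphabet("acgt")            # "ACGU"
#' normalize_alphabet("ACGX")            # "ACGN", 1 replacement
#' @export
normalize_alphabet <- function(x, target = c("RNA", "DNA"), quiet = FALSE) {
  target <- match.arg(target)
  x <- toupper(as.character(x))
  x <- if (target == "RNA") gsub("T", "U", x, fixed = TRUE)
       else gsub("U", "T", x, fixed = TRUE)
  alphabet <- if (target == "RNA") "ACGUN" else "ACGTN"
  bad <- gsub(sprintf("[%s]", alphabet), "", x)
  n_replaced <- sum(nchar(bad))
  if (n_replaced > 0) {
    x <- gsub(sprintf("[^%s]", alphabet), "N", x)
    if (!quiet)
      message(sprintf("normalize_alphabet: %d character(s) mapped to N",
                      n_replaced))
  }
  attr(x, "n_replaced") <- n_replaced
  x
}

#' Normalize every sequence of a tag set
#'
#' @inheritParams normalize_alphabet
#' @param tags a \code{tag_set}.
#' @return The tag set with normalized sequences; attribute
#'   \code{n_replaced} carries the total replacement count.
#' @export
normalize_tags <- function(tags, target = c("RNA", "DNA"), quiet = FALSE) {
  stopifnot(inherits(tags, "tag_set"))
  s <- normalize_alphabet(tags$seq, target = target, quiet = quiet)
  out <- tag_set(as.character(s), ids = tags$id, name = tags$name)
  attr(out, "n_replaced") <- attr(s, "n_replaced")
  out
}

#' Read a FASTA file into a tag set
#'
#' Multi-line records are concatenated and record order is preserved.
#' Sequences are normalized to the requested alphabet at ingest (all motif
#' arithmetic in this package is done on RNA).  An empty file yields an
#' empty tag set with a warning.  Sequence content appearing before the
#' first header is a format error reported with its line number.
#'
#' @param path FASTA file.
#' @param alphabet \code{"RNA"} (default), \code{"DNA"}, or \code{"none"}
#'   to keep residues verbatim.
#' @param name label for the set; defaults to the file name.
#' @return A \code{tag_set}.
#' @export
read_fasta <- function(path, alphabet = c("RNA", "DNA", "none"),
                       name = NULL) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (is.null(name)) name <- basename(path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    warning("empty FASTA file: ", path)
    return(tag_set(character(), name = name))
  }
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">"))
    stop(sprintf(
      "malformed FASTA: sequence line before any header at line %d of %s",
      first, path))
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))  # first word of the header
  if (any(!nzchar(ids)))
    stop("malformed FASTA: empty record id in ", path)
  out <- tag_set(as.character(ss), ids = ids, name = name)
  if (alphabet != "none") out <- normalize_tags(out, target = alphabet)
  out
}

#' Write a tag set as FASTA
#'
#' One header and one (unwrapped) sequence line per record, so that
#' \code{read_fasta(write_fasta(x))} reproduces ids and residues exactly.
#'
#' @param tags a \code{tag_set}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(tags, path) {
  stopifnot(inherits(tags, "tag_set"))
  if (length(tags) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  ss <- Biostrings::BStringSet(tags$seq)
  names(ss) <- tags$id
  Biostrings::writeXStringSet(ss, filepath = path, width = 100000L)
  invisible(path)
}
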