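#' Reference pool of equimolar small RNA sequences
#'
#' A `reference_pool` holds the known sequences of an equimolar reference set
#' (e.g. a 962-member miRNA pool) against which library representation is
#' judged.  Sequences are stored uppercase over the DNA alphabet; `U` residues
#' on input are canonicalised to `T` so that RNA references and DNA reads mix
#' freely.
#'
#' @param ids Character vector of unique, non-empty species identifiers.
#' @param sequences Character vector of nucleotide sequences (same length as
#'   `ids`); characters outside `A`, `C`, `G`, `T`, `U` (any case) are an
#'   error.  Every sequence must be at least 6 nt so that terminal
#'   trinucleotide features are defined.
#' @param name Optional pool name.
#'
#' @return An object of class `reference_pool`: a list with elements `ids`,
#'   `sequences` (named by id) and `name`.
#' @export
#' @examples
#' pool <- reference_pool(c("a", "b"), c("uggaauguua", "ACGTACGTAC"))
#' pool$sequences[["a"]]  # "TGGAATGTTA"
reference_pool <- function(ids, sequences, name = "pool") {
  ids <- as.character(ids)
  sequences <- as.character(sequences)
  if (length(ids) != length(sequences))
    stop("`ids` and `sequences` must have the same length")
  if (any(!nzchar(ids)))
    stop("empty species id")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate species id(s): ", paste(unique(dup), collapse = ", "))
  sequences <- canonicalize_sequence(sequences, ids)
  short <- nchar(sequences) < 6L
  if (any(short))
    stop("sequence(s) shorter than 6 nt: ", paste(ids[short], collapse = ", "))
  names(sequences) <- ids
  structure(list(ids = ids, sequences = sequences, name = name),
            class = "reference_pool")
}

# Uppercase, U -> T, and validate the alphabet; `who` names offending records.
canonicalize_sequence <- function(x, who = x) {
  x <- toupper(x)
  x <- chartr("U", "T", x)
  bad <- grepl("[^ACGT]", x)
  if (any(bad))
    stop("non-ACGTU character in sequence(s): ",
         paste(who[bad], collapse = ", "))
  if (any(!nzchar(x)))
    stop("empty sequence for: ", paste(who[!nzchar(x)], collapse = ", "))
  x
}

#' @export
print.reference_pool <- function(x, ...) {
  rng <- range(nchar(x$sequences))
  cat(sprintf("Reference pool '%s': %d species, lengths %d-%d nt\n",
              x$name, length(x$ids), rng[1], rng[2]))
  invisible(x)
}

#' @export
length.reference_pool <- function(x) length(x$ids)

#' Read a reference pool from FASTA
#'
#' Records keep file order; ids are taken as the first whitespace-delimited
#' token of each header.  `U` residues are canonicalised to `T` and lowercase
#' input is accepted.
#'
#' @param path Path to a FASTA file.
#' @param name Pool name; defaults to the file name without extension.
#' @return A [reference_pool()].
#' @export
read_pool_fasta <- function(path, name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  reference_pool(ids, as.character(set), name = name)
}

#' Write a reference pool to FASTA
#'
#' @param pool A [reference_pool()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_pool_fasta <- function(pool, path) {
  stopifnot(inherits(pool, "reference_pool"))
  set <- Biostrings::BStringSet(pool$sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# Base of each pool sequence at an end-anchored position: +1, +2, ... count
# from the 5' end; -1, -2, ... from the 3' end.  Positions must fall inside
# the shortest sequence.
base_at_position <- function(sequences, pos) {
  stopifnot(pos != 0)
  n <- nchar(sequences)
  idx <- if (pos > 0) rep(pos, length(n)) else n + 1L + pos
  bad <- idx < 1L | idx > n
  if (any(bad))
    stop("position ", pos, " outside sequence(s): ",
         paste(names(sequences)[bad], collapse = ", "))
  substring(sequences, idx, idx)
}

revcomp <- function(x) {
  vapply(x, function(s) {
    s <- chartr("ACGTU", "TGCAA", toupper(s))
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
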