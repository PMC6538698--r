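#' Count and abundance tables
#'
#' Count tables are species-by-sample numeric matrices with species ids as
#' row names and sample names as column names.  Raw counts are non-negative
#' integers; corrected pseudo-counts may be non-integer.  Abundance tables
#' share the shape and carry a `"scale"` attribute, either `"cpm"` or
#' `"median_normalized"` (see [cpm_normalize()] and [median_normalize()]).
#'
#' @param values Numeric matrix (or object coercible to one) of non-negative
#'   values.
#' @param species Optional species ids (defaults to `rownames(values)`).
#' @param samples Optional sample names (defaults to `colnames(values)`).
#' @return A validated numeric matrix with dimnames set.
#' @export
count_table <- function(values, species = rownames(values),
                        samples = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(species)) {
    if (nrow(values) == 0L) species <- character(0) else
      stop("species ids are required")
  }
  if (is.null(samples)) samples <- paste0("sample", seq_len(ncol(values)))
  if (anyNA(values)) stop("count table contains missing values")
  if (any(values < 0)) stop("count table contains negative values")
  dimnames(values) <- list(as.character(species), as.character(samples))
  if (anyDuplicated(rownames(values)))
    stop("duplicate species ids in count table")
  values
}

abundance_scale <- function(ab) attr(ab, "scale", exact = TRUE)

set_abundance_scale <- function(ab, scale) {
  attr(ab, "scale") <- match.arg(scale, c("cpm", "median_normalized"))
  ab
}

#' Read a count table from TSV
#'
#' Expects a header row of sample names with the first column holding species
#' ids.  When a `pool` is supplied, the table is checked against it: unknown
#' species are an error, and pool species missing from the file are filled
#' with zero counts (with a message).
#'
#' @param path Path to a tab-separated file.
#' @param pool Optional [reference_pool()] to validate and complete against.
#' @return A [count_table()] matrix.
#' @export
read_count_table <- function(path, pool = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 1L) stop("count table has no columns: ", path)
  ids <- df[[1L]]
  vals <- df[-1L]
  num <- suppressWarnings(
    vapply(vals, function(col) as.numeric(col), numeric(nrow(df))))
  num <- matrix(num, nrow = nrow(df),
                dimnames = list(ids, colnames(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric value at row %d (species '%s'), column '%s'",
                 bad[["row"]], ids[bad[["row"]]],
                 colnames(num)[bad[["col"]]]))
  }
  if (any(num < 0)) {
    bad <- which(num < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative value at row %d (species '%s'), column '%s'",
                 bad[["row"]], ids[bad[["row"]]],
                 colnames(num)[bad[["col"]]]))
  }
  tab <- count_table(num)
  if (!is.null(pool)) {
    unknown <- setdiff(rownames(tab), pool$ids)
    if (length(unknown))
      stop("species not in reference pool: ", paste(unknown, collapse = ", "))
    missing <- setdiff(pool$ids, rownames(tab))
    if (length(missing)) {
      message(length(missing), " pool species absent from table; filled with 0")
      fill <- matrix(0, length(missing), ncol(tab),
                     dimnames = list(missing, colnames(tab)))
      tab <- rbind(tab, fill)
    }
    tab <- tab[pool$ids, , drop = FALSE]
  }
  tab
}

#' Write a count table to TSV
#'
#' Values are serialised at full precision (`format(..., digits = 17)` for
#' non-integers) so that corrected pseudo-counts round-trip losslessly
#' through [read_count_table()].
#'
#' @param table A [count_table()] matrix.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_count_table <- function(table, path) {
  if (nrow(table) == 0L) {
    writeLines(paste(c("id", colnames(table)), collapse = "\t"), path)
    return(invisible(path))
  }
  vals <- apply(table, 2, function(col) {
    ifelse(col == round(col), format(col, scientific = FALSE, trim = TRUE),
           formatC(col, digits = 17, format = "g"))
  })
  vals <- matrix(vals, nrow = nrow(table))
  df <- data.frame(id = rownames(table), vals, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("id", colnames(table))
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("failed to write ", path, ": ", conditionMessage(ok))
  invisible(path)
}

#' Derive a count table from alignments against a reference pool
#'
#' Counts one vote per retained primary alignment.  An alignment is retained
#' when it is mapped, unique, and its aligned query length (soft clips
#' excluded) lies within `[min_len, max_len]` — the 15–40 nt window used for
#' miRNA reference-pool libraries.  Uniqueness is taken from the `NH` tag
#' when present (`NH == 1`), otherwise `MAPQ >= 5`.  Secondary and
#' supplementary alignments are never counted.
#'
#' @param path Path to a SAM or BAM file aligned to the pool sequences.
#' @param pool A [reference_pool()]; alignment reference names must be a
#'   subset of its ids.
#' @param min_len,max_len Inclusive aligned-length filter (defaults 15, 40).
#' @param sample Column name for the resulting one-sample table; defaults to
#'   the file name.
#' @return A one-column [count_table()] over all pool species, with an
#'   attribute `"filter_log"` tallying discarded alignments per filter.
#' @export
counts_from_alignments <- function(path, pool, min_len = 15L, max_len = 40L,
                                   sample = NULL) {
  stopifnot(inherits(pool, "reference_pool"))
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sample)) sample <- sub("\\.[^.]*$", "", basename(path))
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest,
                            overwrite = TRUE, indexDestination = FALSE)
  }
  flags <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flags, what = c("rname", "flag", "mapq", "cigar"),
    tag = "NH")
  res <- Rsamtools::scanBam(bam, param = param)[[1L]]
  n_all <- length(res$flag)
  mapped <- !bitwAnd(res$flag, 4L)
  nh <- res$tag$NH
  unique_aln <- if (!is.null(nh) && any(!is.na(nh))) {
    ifelse(!is.na(nh), nh == 1L, res$mapq >= 5L)
  } else {
    !is.na(res$mapq) & res$mapq >= 5L
  }
  qlen <- aligned_query_length(res$cigar)
  len_ok <- !is.na(qlen) & qlen >= min_len & qlen <= max_len
  keep <- mapped & unique_aln & len_ok
  keep[is.na(keep)] <- FALSE
  log <- c(total = n_all,
           unmapped = sum(!mapped),
           multimapped = sum(mapped & !unique_aln, na.rm = TRUE),
           length_filtered = sum(mapped & unique_aln & !len_ok, na.rm = TRUE),
           kept = sum(keep))
  refs <- as.character(res$rname[keep])
  unknown <- setdiff(unique(refs), pool$ids)
  if (length(unknown))
    stop("alignment reference name(s) not in pool: ",
         paste(unknown, collapse = ", "))
  if (n_all > 0 && all(!mapped))
    warning("no mapped alignments in ", path)
  counts <- table(factor(refs, levels = pool$ids))
  tab <- count_table(matrix(as.numeric(counts), ncol = 1,
                            dimnames = list(pool$ids, sample)))
  attr(tab, "filter_log") <- log
  tab
}

# Aligned query length from CIGAR: M/I/=/X consume query bases that are part
# of the alignment; soft clips (S) are excluded on purpose.
aligned_query_length <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    ops <- gregexpr("\\d+[MIDNSHP=X]", cg)[[1L]]
    toks <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1L]]
    n <- as.integer(sub("[A-Z=]", "", toks))
    op <- sub("\\d+", "", toks)
    sum(n[op %in% c("M", "I", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}
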