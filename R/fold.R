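#' Maximum base-pairing self-fold proxy
#'
#' Scores the potential intramolecular structure of a sequence by the
#' maximum number of nested base pairs (Watson-Crick plus G:U wobble, with
#' a minimum hairpin loop of 3 unpaired bases), computed by the classical
#' base-pair-maximisation dynamic programme.  This is a structure *proxy*,
#' not a thermodynamic free energy: it preserves the ranking of more- versus
#' less-structured sequences, which is all the downstream rank tests use.
#' A thermodynamic engine can be substituted via the `provider` argument of
#' [sequence_factors()].
#'
#' @param seq Nucleotide string (U accepted).
#' @param min_loop Minimum unpaired bases in a hairpin loop (default 3).
#' @return List with `pairs` (maximum pair count), `pairing` (integer
#'   vector, `pairing[i]` = partner of base `i` or `NA`), `free5` and
#'   `free3` (consecutive unpaired terminal bases in one maximal
#'   traceback preferring outermost pairs).
#' @export
self_fold <- function(seq, min_loop = 3L) {
  s <- strsplit(canonicalize_sequence(seq, "sequence"), "", fixed = TRUE)[[1]]
  L <- length(s)
  can_pair <- function(a, b) {
    p <- paste0(a, b)
    p %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  }
  N <- matrix(0L, L, L)
  if (L > min_loop + 1L) {
    for (span in (min_loop + 1L):(L - 1L)) {
      for (i in seq_len(L - span)) {
        j <- i + span
        best <- N[i + 1L, j]
        for (k in (i + min_loop + 1L):j) {
          if (can_pair(s[i], s[k])) {
            inner <- if (k - i > min_loop + 1L) N[i + 1L, k - 1L] else 0L
            outer <- if (k < j) N[k + 1L, j] else 0L
            cand <- 1L + inner + outer
            if (cand > best) best <- cand
          }
        }
        N[i, j] <- best
      }
    }
  }
  pairing <- rep(NA_integer_, L)
  # traceback preferring to pair i, with the outermost partner, on ties
  stack <- if (L >= 2) list(c(1L, L)) else list()
  while (length(stack)) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    if (j - i <= min_loop) next
    target <- N[i, j]
    if (target == 0L) next
    paired <- FALSE
    for (k in rev((i + min_loop + 1L):j)) {
      if (can_pair(s[i], s[k])) {
        inner <- if (k - i > min_loop + 1L) N[i + 1L, k - 1L] else 0L
        outer <- if (k < j) N[k + 1L, j] else 0L
        if (1L + inner + outer == target) {
          pairing[i] <- k; pairing[k] <- i
          if (k - i > min_loop + 1L) stack <- c(stack, list(c(i + 1L, k - 1L)))
          if (k < j) stack <- c(stack, list(c(k + 1L, j)))
          paired <- TRUE
          break
        }
      }
    }
    if (!paired) stack <- c(stack, list(c(i + 1L, j)))
  }
  free5 <- if (L == 0) 0L else {
    u <- which(!is.na(pairing))
    if (!length(u)) L else u[1] - 1L
  }
  free3 <- if (L == 0) 0L else {
    u <- which(!is.na(pairing))
    if (!length(u)) L else L - u[length(u)]
  }
  list(pairs = if (L >= 2) N[1, L] else 0L,
       pairing = pairing, free5 = free5, free3 = free3)
}

#' Adapter/cDNA co-fold proxy
#'
#' Scores the propensity of an adapter to hybridise with the cDNA it must
#' ligate to, as the length of the longest contiguous complementary duplex
#' (antiparallel Watson-Crick) between the two strands.  The cDNA of a
#' species is the reverse complement of its sequence, optionally with the
#' second adapter's reverse complement attached at the cDNA 5' end as in
#' the library geometry.
#'
#' @param adapter_seq Adapter nucleotide string.
#' @param species_seq Species (RNA) nucleotide string.
#' @param r2r_seq Optional second-adapter sequence attached to the cDNA.
#' @return Integer duplex length (0 if no complementary pair exists).
#' @export
co_fold <- function(adapter_seq, species_seq, r2r_seq = NULL) {
  a <- canonicalize_sequence(adapter_seq, "adapter")
  cdna <- revcomp(canonicalize_sequence(species_seq, "species"))
  if (!is.null(r2r_seq))
    cdna <- paste0(revcomp(canonicalize_sequence(r2r_seq, "r2r")), cdna)
  # a duplex between `a` and `cdna` is a common substring of `a` and
  # revcomp(cdna)
  longest_common_substring(a, revcomp(cdna))
}

longest_common_substring <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  if (!length(x) || !length(y)) return(0L)
  prev <- integer(length(y))
  best <- 0L
  for (i in seq_along(x)) {
    cur <- integer(length(y))
    match <- x[i] == y
    cur[match] <- c(1L, prev[-length(prev)] + 1L)[match]
    best <- max(best, cur)
    prev <- cur
  }
  as.integer(best)
}
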