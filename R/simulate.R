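#' Specification of simulated terminal-position bias
#'
#' A `bias_spec` drives the library simulator: per-(position, base) log10
#' effects compose additively on the log scale (i.e. multiplicatively on
#' sampling probability), optionally with a length slope in log10 CPM per
#' nucleotide.  Unspecified (position, base) pairs have effect 0.
#'
#' @param effects Named list mapping a position label (`"+1"`, `"-1"`, ...)
#'   to a named numeric vector of per-base log10 effects, e.g.
#'   `list("-1" = c(G = 0.5, T = -0.5))`.
#' @param length_slope Log10 effect per nucleotide of length (default 0;
#'   0.09 reproduces the weak length dependence seen in reference-pool
#'   libraries).
#' @param depth Total reads per simulated sample (default 1e6, making CPM
#'   and counts commensurate).
#' @param seed Integer RNG seed.
#' @return An object of class `bias_spec`.
#' @export
bias_spec <- function(effects = list(), length_slope = 0, depth = 1e6,
                      seed = 1L) {
  stopifnot(depth >= 1, is.finite(length_slope))
  if (length(effects)) {
    if (is.null(names(effects)) || any(!nzchar(names(effects))))
      stop("effects must be a named list keyed by position label")
    for (p in names(effects)) {
      e <- effects[[p]]
      if (is.null(names(e)) || !all(names(e) %in% c("A", "C", "G", "T", "U")))
        stop("effect vector for position ", p, " must be named by base")
      if (any(!is.finite(e))) stop("non-finite effect at position ", p)
      names(effects[[p]]) <- chartr("U", "T", names(e))
    }
  }
  structure(list(effects = effects, length_slope = length_slope,
                 depth = depth, seed = as.integer(seed)),
            class = "bias_spec")
}

#' Simulate an equimolar reference pool
#'
#' Generates `n` unique random sequences with i.i.d. uniform bases and
#' lengths uniform over `length_range`, emulating an equimolar miRNA
#' reference set.  Reproducible under `seed`.
#'
#' @param n Number of species (default 962, the size of the commercial
#'   miRNA reference pool).
#' @param length_range Inclusive length bounds (default `c(19, 25)`,
#'   spanning mature miRNA sizes).
#' @param seed Integer RNG seed.
#' @return A [reference_pool()] with ids `sim-0001`, `sim-0002`, ...
#' @export
simulate_pool <- function(n = 962, length_range = c(19L, 25L), seed = 1L) {
  stopifnot(n >= 1, length_range[1] >= 6)
  if (log(n) > length_range[1] * log(4))
    stop("n exceeds the number of distinct sequences of the minimum length")
  set.seed(seed)
  seqs <- character(0)
  while (length(seqs) < n) {
    need <- n - length(seqs)
    lens <- sample(seq(length_range[1], length_range[2]), need, replace = TRUE)
    new <- vapply(lens, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1))
    seqs <- unique(c(seqs, new))
  }
  seqs <- seqs[seq_len(n)]
  ids <- sprintf("sim-%04d", seq_len(n))
  reference_pool(ids, seqs, name = "simulated")
}

#' Simulate biased library counts from a pool
#'
#' Species `m` is sampled with probability proportional to
#' `10^(sum_i effect(i, base(m, i)) + length_slope * len_m)`; counts are
#' drawn multinomially with total `depth` per replicate (replicates are
#' independent draws from the same probabilities, the technical-replicate
#' model).  The returned truth records each species' sampling probability
#' and its true deviation from uniform representation,
#' `delta = log10(p * n)`, the quantity the bias model estimates.
#'
#' @param pool A [reference_pool()].
#' @param spec A [bias_spec()].
#' @param replicates Number of replicate samples (default 1).
#' @return List with `counts` (a [count_table()], columns `rep1`, ...) and
#'   `truth` (data frame with `id`, `probability`, `delta`).
#' @export
simulate_counts <- function(pool, spec, replicates = 1L) {
  stopifnot(inherits(pool, "reference_pool"), inherits(spec, "bias_spec"))
  n <- length(pool$ids)
  logp <- rep(0, n)
  for (lab in names(spec$effects)) {
    p <- as.integer(sub("^\\+", "", lab))
    if (is.na(p) || p == 0) stop("bad position label: ", lab)
    b <- base_at_position(pool$sequences, p)
    e <- spec$effects[[lab]]
    hit <- b %in% names(e)
    logp[hit] <- logp[hit] + e[b[hit]]
  }
  logp <- logp + spec$length_slope * nchar(pool$sequences)
  w <- 10^(logp - max(logp))
  prob <- w / sum(w)
  set.seed(spec$seed)
  counts <- stats::rmultinom(replicates, size = spec$depth, prob = prob)
  dimnames(counts) <- list(pool$ids, paste0("rep", seq_len(replicates)))
  truth <- data.frame(id = pool$ids, probability = prob,
                      delta = log10(prob * n), stringsAsFactors = FALSE)
  list(counts = count_table(counts), truth = truth)
}
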