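#' Saturation curve of species detection versus sequencing depth
#'
#' Expands the observed counts to a read multiset, shuffles it under `seed`
#' (sampling without replacement from the library), and consumes it in bins,
#' recording after each bin how many species have accumulated at least
#' `threshold` reads.  Curves are nondecreasing, bounded by the pool size,
#' and plateau at the number of species with at least `threshold` total
#' reads.
#'
#' @param table A [count_table()]; multiple samples are pooled by summing.
#' @param bin_size Reads per bin (default 200).
#' @param threshold Detection threshold in reads (default 10).
#' @param seed RNG seed for the shuffle.
#' @param max_reads Truncate the curve at this many reads (default 3e6).
#' @return Object of class `saturation_curve`: data frame with columns
#'   `reads` (bin boundaries) and `detected`.
#' @export
saturation_curve <- function(table, bin_size = 200L, threshold = 10L,
                             seed = 1L, max_reads = 3e6) {
  if (threshold < 1) stop("threshold must be at least 1")
  totals <- rowSums(as.matrix(table))
  n_reads <- sum(totals)
  if (n_reads < bin_size) stop("fewer total reads than one bin")
  reads <- rep.int(seq_along(totals), totals)
  set.seed(seed)
  reads <- sample(reads)
  n_use <- min(length(reads), max_reads)
  reads <- reads[seq_len(n_use)]
  # read index at which each species reaches its threshold-th read
  detect_at <- vapply(split(seq_len(n_use), reads), function(ix) {
    if (length(ix) >= threshold) ix[threshold] else NA_integer_
  }, integer(1))
  detect_at <- sort(detect_at[!is.na(detect_at)])
  bins <- seq(bin_size, n_use, by = bin_size)
  detected <- findInterval(bins, detect_at)
  structure(data.frame(reads = bins, detected = detected),
            class = c("saturation_curve", "data.frame"),
            pool_size = nrow(table), threshold = threshold, seed = seed)
}

#' Summary statistics of an abundance distribution per sample
#'
#' Quartiles, median deviation from the equimolar expectation, and the
#' central 95% interval of each sample's abundances — the statistics used
#' to rank library methods by how tightly they recover an equimolar pool.
#'
#' @param ab Abundance matrix on the `"cpm"` scale.
#' @param expected Expected CPM per species.
#' @return Data frame, one row per sample: `q1`, `median`, `q3`,
#'   `median_deviation` (median minus expected), `lo95`, `hi95`.
#' @export
abundance_summary <- function(ab, expected) {
  if (!identical(abundance_scale(ab), "cpm"))
    stop("`ab` must be on the cpm scale")
  out <- t(apply(as.matrix(ab), 2, function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75, 0.025, 0.975), names = FALSE)
    c(q1 = q[1], median = q[2], q3 = q[3],
      median_deviation = q[2] - expected, lo95 = q[4], hi95 = q[5])
  }))
  data.frame(sample = colnames(ab), out, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Pairwise replicate correlation
#'
#' Rank-based (Spearman) correlation matrix across samples; a constant
#' column yields missing correlations with a warning.
#'
#' @param table A [count_table()] with at least two samples.
#' @param method Correlation method (default `"spearman"`).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
replicate_correlation <- function(table, method = "spearman") {
  if (ncol(table) < 2L) stop("need at least 2 samples")
  const <- apply(table, 2, function(v) stats::sd(v) == 0)
  if (any(const))
    warning("constant sample(s), correlation undefined: ",
            paste(colnames(table)[const], collapse = ", "))
  suppressWarnings(m <- stats::cor(as.matrix(table), method = method))
  diag(m) <- ifelse(const, NA_real_, 1)
  m
}

#' Per-species sequence factors for outlier analysis
#'
#' Computes, for each pool species, the candidate non-terminal bias factors:
#' length, GC fraction, self-fold score, adapter/cDNA co-fold score, and the
#' numbers of unpaired (free) terminal bases in a maximal self-fold.  Fold
#' scores are base-pair-maximisation proxies (see [self_fold()]); pass a
#' `provider` function to substitute an external (e.g. thermodynamic)
#' engine.
#'
#' @param pool A [reference_pool()].
#' @param adapter_seq Optional adapter sequence; required for co-fold
#'   scores (`co_fold` is `NA` when absent).
#' @param r2r_seq Optional second-adapter sequence prepended to the cDNA for
#'   the co-fold geometry.
#' @param provider Optional function `(sequence) -> list(pairs, free5,
#'   free3)` replacing the built-in self-fold proxy.
#' @return Data frame with columns `id`, `length`, `gc`, `self_fold`,
#'   `co_fold`, `free5`, `free3`.
#' @export
sequence_factors <- function(pool, adapter_seq = NULL, r2r_seq = NULL,
                             provider = NULL) {
  stopifnot(inherits(pool, "reference_pool"))
  seqs <- pool$sequences
  gc <- vapply(seqs, function(s) {
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    mean(b %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
  folds <- lapply(seqs, if (is.null(provider)) self_fold else provider)
  cf <- if (is.null(adapter_seq)) rep(NA_real_, length(seqs)) else
    vapply(seqs, function(s) as.numeric(co_fold(adapter_seq, s, r2r_seq)),
           numeric(1), USE.NAMES = FALSE)
  data.frame(
    id = pool$ids,
    length = nchar(seqs),
    gc = gc,
    self_fold = vapply(folds, function(f) as.numeric(f$pairs), numeric(1)),
    co_fold = cf,
    free5 = vapply(folds, function(f) as.numeric(f$free5), numeric(1)),
    free3 = vapply(folds, function(f) as.numeric(f$free3), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank-sum tests of sequence factors in outlier species
#'
#' For each factor, compares over-represented species against the rest and
#' under-represented species against the rest with a two-sided
#' Wilcoxon/Mann-Whitney rank-sum test (exact for small groups without
#' ties, midranks with normal approximation otherwise).
#'
#' @param factors A [sequence_factors()] data frame.
#' @param labels A [classify_representation()] result covering the same
#'   species.
#' @return Data frame with columns `factor`, `contrast`
#'   (`"over_vs_rest"`/`"under_vs_rest"`), `p_value`.
#' @export
outlier_factor_test <- function(factors, labels) {
  stopifnot(inherits(labels, "representation_labels"))
  lab <- labels$labels[factors$id]
  if (anyNA(lab)) stop("labels missing for some species")
  cols <- c("length", "gc", "self_fold", "co_fold", "free5", "free3")
  res <- list()
  for (grp in c("over", "under")) {
    in_grp <- lab == grp
    if (!any(in_grp)) stop("no ", grp, "-represented species")
    for (col in cols) {
      x <- factors[[col]][in_grp]
      y <- factors[[col]][!in_grp]
      p <- if (all(is.na(x)) || all(is.na(y))) NA_real_ else
        suppressWarnings(
          stats::wilcox.test(x, y, alternative = "two.sided")$p.value)
      res[[length(res) + 1L]] <- data.frame(
        factor = col, contrast = paste0(grp, "_vs_rest"), p_value = p,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}

#' Linear fit of log10 abundance on species length
#'
#' Ordinary least squares of `log10(cpm + pc)` on sequence length, the
#' regression used to quantify the (weak) residual length dependence of
#' representation.
#'
#' @param ab Abundance matrix on the `"cpm"` scale (replicate columns are
#'   averaged on the log scale).
#' @param pool A [reference_pool()] providing the lengths.
#' @param pc Pseudo-count (default 0.5).
#' @return List with `slope` (log10 CPM per nt), `intercept`, `r_squared`.
#' @export
length_abundance_fit <- function(ab, pool, pc = 0.5) {
  stopifnot(inherits(pool, "reference_pool"))
  lens <- nchar(pool$sequences[rownames(ab)])
  if (length(unique(lens)) < 3L)
    stop("need at least 3 distinct lengths")
  y <- rowMeans(log10(as.matrix(ab) + pc))
  fit <- stats::lm(y ~ lens)
  # summary() warns on exact fits; R^2 is still well-defined there
  r2 <- withCallingHandlers(summary(fit)$r.squared,
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2)
}
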