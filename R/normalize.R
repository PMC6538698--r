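#' Counts-per-million normalisation
#'
#' Scales each sample so its column sums to one million:
#' `cpm = count / column_sum * 1e6`.  For an equimolar pool of 962 species
#' sequenced to a depth of 1,000,000 reads the expected value is 1,039.5 CPM
#' per species.
#'
#' @param table A [count_table()] matrix.
#' @return An abundance matrix on the `"cpm"` scale.
#' @export
cpm_normalize <- function(table) {
  sums <- colSums(table)
  zero <- sums == 0
  if (any(zero))
    stop("all-zero sample(s): ", paste(colnames(table)[zero], collapse = ", "))
  ab <- sweep(table, 2, sums, "/") * 1e6
  set_abundance_scale(ab, "cpm")
}

#' Median-of-ratios normalisation
#'
#' Computes per-sample size factors as the median, over species, of the ratio
#' of each count to a pseudo-reference (the per-species geometric mean across
#' samples).  Species with a zero count in any sample are excluded from the
#' factor computation.  Values are counts divided by the sample's size factor.
#'
#' @param table A [count_table()] matrix.
#' @return An abundance matrix on the `"median_normalized"` scale, with the
#'   size factors as attribute `"size_factors"`.
#' @export
median_normalize <- function(table) {
  usable <- rowSums(table == 0) == 0
  if (!any(usable))
    stop("no species with nonzero counts in every sample; cannot compute size factors")
  ref <- exp(rowMeans(log(table[usable, , drop = FALSE])))
  ratios <- sweep(table[usable, , drop = FALSE], 1, ref, "/")
  sf <- apply(ratios, 2, stats::median)
  ab <- sweep(table, 2, sf, "/")
  ab <- set_abundance_scale(ab, "median_normalized")
  attr(ab, "size_factors") <- sf
  ab
}

#' Per-species measurement errors against an equimolar expectation
#'
#' For each species the measurement error is the deviation of observed from
#' expected log10 abundance,
#' `delta = log10(cpm + pc) - log10(expected_cpm)`,
#' with a pseudo-count `pc` keeping zero-count species finite.  When the
#' table has several replicate columns the per-replicate log10 CPM values
#' are averaged on the log scale before subtracting the expectation.
#'
#' @param ab Abundance matrix on the `"cpm"` scale.
#' @param expected_cpm Expected CPM under equimolarity (for a pool of `n`
#'   species at depth `d`, `d / n / d * 1e6 = 1e6 / n`).
#' @param pc Pseudo-count in CPM units (default 0.5).
#' @return A named numeric vector of delta log10 CPM values, one per species,
#'   with attribute `"expected_cpm"`.
#' @export
measurement_errors <- function(ab, expected_cpm, pc = 0.5) {
  if (!identical(abundance_scale(ab), "cpm"))
    stop("`ab` must be on the cpm scale (see cpm_normalize())")
  stopifnot(is.numeric(expected_cpm), expected_cpm > 0)
  logcpm <- log10(ab + pc)
  delta <- rowMeans(logcpm) - log10(expected_cpm)
  attr(delta, "expected_cpm") <- expected_cpm
  delta
}

#' Root-mean-square error of log2 abundances against an expected value
#'
#' `sqrt(mean((log2(value + pc) - log2(expected))^2))` over the chosen
#' species subset (all species by default) and all samples.  Intended for
#' median-normalised counts; a CPM-scale table is accepted with a warning.
#'
#' @param ab Abundance matrix (`"median_normalized"` preferred).
#' @param expected Expected abundance on the same scale.
#' @param subset Optional character vector of species ids to restrict to.
#' @param pc Pseudo-count added inside the log (default 0.5).
#' @return Non-negative scalar RMSE in log2 units.
#' @export
rmse_log2 <- function(ab, expected, subset = NULL, pc = 0.5) {
  sc <- abundance_scale(ab)
  if (identical(sc, "cpm"))
    warning("rmse_log2 computed on cpm-scale values")
  if (!is.null(subset)) {
    missing <- setdiff(subset, rownames(ab))
    if (length(missing))
      stop("subset species not in table: ", paste(missing, collapse = ", "))
    ab <- ab[subset, , drop = FALSE]
  }
  if (nrow(ab) == 0L) stop("empty species subset")
  dev <- log2(ab + pc) - log2(expected)
  sqrt(mean(dev^2))
}

#' Empirical cumulative distribution function as step points
#'
#' @param values Non-empty numeric vector.
#' @return A data frame with columns `x` (sorted unique values) and `F`
#'   (right-continuous cumulative fraction at or below `x`; `F` at the
#'   maximum is 1).
#' @export
ecdf_points <- function(values) {
  if (length(values) == 0L) stop("empty input")
  f <- stats::ecdf(values)
  x <- sort(unique(values))
  data.frame(x = x, F = f(x))
}
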