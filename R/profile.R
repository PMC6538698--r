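#' Positional nucleotide frequencies at sequence ends
#'
#' Computes, at each requested end-anchored position (`+1..+k` from the
#' 5' end, `-k..-1` from the 3' end), the abundance-weighted base frequencies
#' of a pool, the unweighted reference frequencies, and their ratio.  With
#' uniform weights the observed frequencies equal the reference composition
#' and every ratio is 1; reweighting toward species sharing a base at a
#' position raises that base's ratio there.
#'
#' @param pool A [reference_pool()].
#' @param weights Optional non-negative per-species weights named by pool id
#'   (e.g. CPM values); `NULL` means uniform.
#' @param positions Integer vector of positions; default `c(1:6, -(6:1))`,
#'   the twelve terminal positions usually profiled.
#' @return An object of class `bias_profile`: a list with `positions` and
#'   three position-by-base matrices `observed`, `reference`, `ratio`
#'   (bases A, C, G, T), plus the `weighting` used.
#' @export
end_nucleotide_frequencies <- function(pool, weights = NULL,
                                       positions = c(1:6, -(6:1))) {
  stopifnot(inherits(pool, "reference_pool"))
  if (any(positions == 0)) stop("positions are 1-based; 0 is not a position")
  n <- length(pool$ids)
  if (is.null(weights)) {
    w <- rep(1, n)
  } else {
    w <- weights[pool$ids]
    if (anyNA(w)) stop("weights missing for some pool species")
    if (any(w < 0)) stop("negative weights")
    if (sum(w) == 0) stop("weights sum to zero")
  }
  bases <- c("A", "C", "G", "T")
  freq_at <- function(wts) {
    t(vapply(positions, function(p) {
      b <- base_at_position(pool$sequences, p)
      tapply(wts, factor(b, levels = bases), sum, default = 0) / sum(wts)
    }, numeric(4)))
  }
  obs <- freq_at(w)
  ref <- freq_at(rep(1, n))
  labs <- ifelse(positions > 0, paste0("+", positions), as.character(positions))
  dimnames(obs) <- dimnames(ref) <- list(labs, bases)
  ratio <- obs / ref
  ratio[ref == 0] <- NA_real_
  structure(list(positions = positions, observed = obs, reference = ref,
                 ratio = ratio,
                 weighting = if (is.null(weights)) "uniform" else "abundance"),
            class = "bias_profile")
}

#' @export
print.bias_profile <- function(x, digits = 3, ...) {
  cat(sprintf("End-position bias profile (%s weighting)\n", x$weighting))
  cat("observed/reference frequency ratios:\n")
  print(round(x$ratio, digits))
  invisible(x)
}

#' Abundance share of each 3'-terminal base
#'
#' Fraction of total abundance carried by species whose sequence ends in
#' each base.  This is the statistic a compensating 3'-overhang primer mix
#' is designed against.
#'
#' @param ab Abundance (or count) matrix with species rownames.
#' @param pool A [reference_pool()] covering all table species.
#' @return Named numeric vector over A, C, G, T summing to 1.
#' @export
three_prime_composition <- function(ab, pool) {
  stopifnot(inherits(pool, "reference_pool"))
  ids <- rownames(ab)
  missing <- setdiff(ids, pool$ids)
  if (length(missing))
    stop("species not in pool: ", paste(missing, collapse = ", "))
  total <- rowSums(as.matrix(ab))
  if (sum(total) == 0) stop("zero total abundance")
  last <- base_at_position(pool$sequences[ids], -1L)
  shares <- tapply(total, factor(last, levels = c("A", "C", "G", "T")),
                   sum, default = 0)
  stats::setNames(as.numeric(shares / sum(shares)), names(shares))
}

#' Classify species as over-, under-, or normally represented
#'
#' A species is `over`-represented when its measurement error is at least
#' `threshold_sd` standard deviations above the mean error across the pool,
#' `under` when at least that far below, and `normal` otherwise.  A 1-SD
#' threshold flags candidates for end-bias analysis; 2 SD gives the stricter
#' outlier definition used for sequence-factor comparisons.
#'
#' @param errors Named numeric vector of per-species errors (delta log10
#'   CPM, see [measurement_errors()]).
#' @param threshold_sd Positive threshold in standard deviations (default 1).
#' @return An object of class `representation_labels`: list with `labels`
#'   (named factor with levels over/normal/under), `center`, `spread`,
#'   `threshold_sd`.
#' @export
classify_representation <- function(errors, threshold_sd = 1) {
  stopifnot(is.numeric(errors), threshold_sd > 0)
  if (length(errors) < 2L) stop("need at least 2 species")
  m <- mean(errors)
  s <- stats::sd(errors)
  if (!is.finite(s) || s == 0) {
    warning("zero spread in errors; all species labelled normal")
    lab <- rep("normal", length(errors))
  } else {
    lab <- ifelse(errors >= m + threshold_sd * s, "over",
                  ifelse(errors <= m - threshold_sd * s, "under", "normal"))
  }
  labels <- factor(lab, levels = c("over", "normal", "under"))
  names(labels) <- names(errors)
  structure(list(labels = labels, center = m, spread = s,
                 threshold_sd = threshold_sd),
            class = "representation_labels")
}

#' @export
print.representation_labels <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf(
    "Representation at +/-%g SD (center %.3f, spread %.3f): %d over, %d normal, %d under\n",
    x$threshold_sd, x$center, x$spread,
    tab[["over"]], tab[["normal"]], tab[["under"]]))
  invisible(x)
}

#' Principal component analysis of terminal-base features
#'
#' Restricts the one-hot end-feature matrix to the flagged (over- or
#' under-represented) species, centres the columns, and decomposes by
#' singular values.  Separation of the two groups along PC1, and the PC1
#' loadings per (position, base) feature, indicate which terminal bases
#' drive representation.
#'
#' @param features One-hot matrix from [encode_end_features()].
#' @param labels A [classify_representation()] result.
#' @return List with `scores` (flagged species by PC), `loadings` (feature
#'   by PC, orthonormal columns), `var_explained` (fraction per PC), and
#'   `groups` (the over/under factor for the scored species).
#' @export
pca_end_features <- function(features, labels) {
  stopifnot(inherits(labels, "representation_labels"))
  lab <- labels$labels[rownames(features)]
  flagged <- !is.na(lab) & lab != "normal"
  if (sum(flagged) < 2L)
    stop("need at least 2 over/under-represented species for PCA")
  x <- features[flagged, , drop = FALSE]
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  list(scores = p$x,
       loadings = p$rotation,
       var_explained = p$sdev^2 / sum(p$sdev^2),
       groups = droplevels(lab[flagged]))
}
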