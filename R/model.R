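#' One-hot encoding of terminal bases
#'
#' Builds the feature matrix for the end-bias regression: one indicator per
#' (position, base) pair over the requested end-anchored positions, bases in
#' fixed order A, C, G, T.  The default positions are the first and last
#' three bases of each sequence — the region where library end bias
#' concentrates — giving 24 columns; each row sums to the number of
#' positions and each 4-column position block sums to exactly 1.
#'
#' @param pool A [reference_pool()]; every sequence must cover all requested
#'   positions (length >= 6 for the default).
#' @param positions Integer positions (positive from the 5' end, negative
#'   from the 3' end); default `c(1, 2, 3, -3, -2, -1)`.
#' @return Numeric 0/1 matrix, rows named by species id, columns named like
#'   `"+1.A"`, `"-1.G"`.
#' @export
encode_end_features <- function(pool, positions = c(1L, 2L, 3L, -3L, -2L, -1L)) {
  stopifnot(inherits(pool, "reference_pool"))
  bases <- c("A", "C", "G", "T")
  blocks <- lapply(positions, function(p) {
    b <- base_at_position(pool$sequences, p)
    m <- outer(b, bases, "==") * 1
    colnames(m) <- paste0(position_label(p), ".", bases)
    m
  })
  x <- do.call(cbind, blocks)
  rownames(x) <- pool$ids
  x
}

position_label <- function(p) ifelse(p > 0, paste0("+", p), as.character(p))

feature_positions <- function(feature_names) {
  as.integer(sub("^\\+", "", sub("\\.[ACGT]$", "", feature_names)))
}

#' Fit the terminal-sequence bias model
#'
#' Fits a random forest regression of per-species measurement error (delta
#' log10 CPM) on terminal-base indicator features.  The fitted function
#' predicts, for any species, how far its measured log10 abundance deviates
#' from truth because of its end sequences; subtracting the prediction
#' corrects the abundance (see [correct_counts()]).  The fit is fully
#' deterministic given `seed`: refitting with the same data and seed yields
#' bit-identical predictions.
#'
#' @param features One-hot matrix from [encode_end_features()].
#' @param errors Named error vector from [measurement_errors()], covering
#'   the same species.
#' @param ntree Number of trees (default 500).
#' @param mtry Features tried per split; default one third of the feature
#'   count (classical regression-forest default).
#' @param seed Integer RNG seed for the forest (default 20190528).
#' @param min_species Minimum training-set size (default 50); fits on fewer
#'   species are refused as unstable.
#' @return An object of class `bias_model`: list with the fitted `forest`,
#'   `feature_names`, `positions`, per-feature `importance` (mean decrease
#'   in node impurity), training `r_squared`, `fitted` values, `residuals`,
#'   and the `config` used.
#' @seealso [predict.bias_model()], [cross_validate_bias_model()],
#'   [positional_importance()]
#' @export
fit_bias_model <- function(features, errors, ntree = 500, mtry = NULL,
                           seed = 20190528, min_species = 50) {
  ids <- rownames(features)
  if (is.null(ids) || is.null(names(errors)))
    stop("features and errors must be named by species id")
  if (!setequal(ids, names(errors)))
    stop("features and errors cover different species")
  y <- as.numeric(errors[ids])
  if (nrow(features) < min_species)
    stop("need at least ", min_species, " species to fit the bias model")
  if (is.null(mtry)) mtry <- max(1L, floor(ncol(features) / 3))
  if (stats::sd(y) == 0)
    warning("constant error vector; model trains but importances are meaningless")
  set.seed(seed)
  # muffle the engine's advisory about near-constant responses; the
  # degenerate case already warns above
  forest <- withCallingHandlers(
    randomForest::randomForest(
      x = features, y = y, ntree = ntree, mtry = mtry, importance = FALSE),
    warning = function(w) {
      if (grepl("five or fewer unique values", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  fitted <- as.numeric(stats::predict(forest, features))
  names(fitted) <- ids
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  imp <- randomForest::importance(forest, type = 2)[, 1L]
  structure(list(
    forest = forest,
    feature_names = colnames(features),
    positions = unique(feature_positions(colnames(features))),
    importance = imp,
    r_squared = r2,
    fitted = fitted,
    residuals = stats::setNames(y - fitted, ids),
    observed = stats::setNames(y, ids),
    config = list(ntree = ntree, mtry = mtry, seed = seed)),
    class = "bias_model")
}

#' Predict measurement errors for new species
#'
#' @param object A [fit_bias_model()] result.
#' @param features One-hot matrix with the same columns (order included) as
#'   the training features.
#' @param ... Unused.
#' @return Named numeric vector of predicted delta log10 CPM values.
#' @export
predict.bias_model <- function(object, features, ...) {
  if (!identical(colnames(features), object$feature_names))
    stop("feature columns do not match the fitted model")
  p <- as.numeric(stats::predict(object$forest, features))
  names(p) <- rownames(features)
  p
}

#' @export
print.bias_model <- function(x, ...) {
  cat(sprintf(
    "Terminal-sequence bias model: %d species, %d features, %d trees (mtry %d, seed %d)\n",
    length(x$fitted), length(x$feature_names),
    x$config$ntree, x$config$mtry, x$config$seed))
  cat(sprintf("Training R-squared: %.3f\n", x$r_squared))
  invisible(x)
}

#' @export
summary.bias_model <- function(object, ...) {
  pi <- positional_importance(object)
  out <- list(model = object, positional = pi)
  class(out) <- "summary.bias_model"
  out
}

#' @export
print.summary.bias_model <- function(x, ...) {
  print(x$model)
  cat("Relative positional importance:\n")
  print(round(x$positional$per_position, 3))
  cat(sprintf("5' share: %.2f  3' share: %.2f\n",
              x$positional$five_prime_share, x$positional$three_prime_share))
  invisible(x)
}

#' @export
residuals.bias_model <- function(object, ...) object$residuals

#' @export
fitted.bias_model <- function(object, ...) object$fitted

#' @export
coef.bias_model <- function(object, ...) object$importance

#' Predicted versus observed measurement errors
#'
#' @param x A `bias_model`.
#' @param ... Passed to [plot()].
#' @export
plot.bias_model <- function(x, ...) {
  plot(x$observed, x$fitted,
       xlab = "observed delta log10 CPM",
       ylab = "predicted delta log10 CPM", ...)
  graphics::abline(0, 1, col = "red")
  graphics::abline(stats::lm(x$fitted ~ x$observed), col = "blue")
  invisible(x)
}

#' Correct abundances by subtracting predicted end-bias errors
#'
#' Applies the model on the log scale: for each species and sample,
#' `corrected = 10^(log10(cpm + pc) - delta_hat)`, where `delta_hat` is the
#' model's predicted measurement error from the species' terminal bases.
#' Corrected values are non-integer pseudo-counts; set `renormalize = TRUE`
#' to rescale columns back to CPM.
#'
#' @param ab Abundance matrix on the `"cpm"` scale.
#' @param model A [fit_bias_model()] result (a model predicting zero
#'   everywhere leaves the table unchanged up to the pseudo-count).
#' @param pool A [reference_pool()] supplying the terminal sequences of the
#'   table's species.
#' @param pc Pseudo-count in CPM (default 0.5), matching
#'   [measurement_errors()].
#' @param renormalize Rescale corrected columns to sum to 1e6 (default
#'   FALSE).
#' @return Corrected abundance matrix on the `"cpm"` scale.
#' @export
correct_counts <- function(ab, model, pool, pc = 0.5, renormalize = FALSE) {
  if (!identical(abundance_scale(ab), "cpm"))
    stop("`ab` must be on the cpm scale")
  stopifnot(inherits(model, "bias_model"), inherits(pool, "reference_pool"))
  sub <- reference_pool(rownames(ab), pool$sequences[rownames(ab)],
                        name = pool$name)
  feats <- encode_end_features(sub, positions = sort_positions(model$positions))
  feats <- feats[, model$feature_names, drop = FALSE]
  delta <- predict(model, feats)
  corrected <- 10^(log10(ab + pc) - delta)
  if (renormalize)
    corrected <- sweep(corrected, 2, colSums(corrected), "/") * 1e6
  set_abundance_scale(corrected, "cpm")
}

sort_positions <- function(pos) {
  # canonical order: 5' positions ascending, then 3' positions -k..-1
  c(sort(pos[pos > 0]), sort(pos[pos < 0]))
}

#' k-fold cross-validation of the bias model
#'
#' Shuffles the species into `k` folds covering every species exactly once,
#' trains on each complement, and scores held-out predictions by
#' out-of-fold R-squared (1 minus residual over total sum of squares of the
#' held-out errors).
#'
#' @param features,errors As for [fit_bias_model()].
#' @param k Number of folds (default 8).
#' @param seed RNG seed for the partition and per-fold fits.
#' @param ... Passed on to [fit_bias_model()] (e.g. `ntree`).
#' @return List with `fold_r2` (length-`k` numeric), `folds` (named fold
#'   assignment), `mean_r2`.
#' @export
cross_validate_bias_model <- function(features, errors, k = 8,
                                      seed = 20190528, ...) {
  n <- nrow(features)
  if (k < 2) stop("k must be at least 2")
  if (k > n) stop("more folds than species")
  ids <- rownames(features)
  y <- errors[ids]
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  names(fold) <- ids
  r2 <- vapply(seq_len(k), function(f) {
    test <- fold == f
    fit <- fit_bias_model(features[!test, , drop = FALSE], y[!test],
                          seed = seed + f, ...)
    pred <- predict(fit, features[test, , drop = FALSE])
    yt <- y[test]
    1 - sum((yt - pred)^2) / sum((yt - mean(yt))^2)
  }, numeric(1))
  list(fold_r2 = r2, folds = fold, mean_r2 = mean(r2))
}

#' Relative importance of each terminal position
#'
#' Sums the model's per-feature impurity importances within each position
#' and normalises to 1, then splits the total between the 5' (positive) and
#' 3' (negative) positions.
#'
#' @param model A fitted [fit_bias_model()].
#' @return List with `per_position` (named, sums to 1, in canonical position
#'   order), `five_prime_share`, `three_prime_share`.
#' @export
positional_importance <- function(model) {
  stopifnot(inherits(model, "bias_model"))
  pos <- feature_positions(model$feature_names)
  imp <- tapply(model$importance, pos, sum)
  total <- sum(imp)
  if (total <= 0) stop("all feature importances are zero")
  imp <- imp / total
  ord <- sort_positions(as.integer(names(imp)))
  imp <- imp[as.character(ord)]
  names(imp) <- vapply(ord, position_label, character(1))
  list(per_position = imp,
       five_prime_share = sum(imp[ord > 0]),
       three_prime_share = sum(imp[ord < 0]))
}

#' Trinucleotide-frequency reweighting corrector
#'
#' An alternative end-bias corrector: each species is reweighted by the
#' ratio of reference to observed frequency of its 5'-terminal and
#' 3'-terminal trinucleotides,
#' `w = [f_ref(t5)/f_obs(t5)] * [f_ref(t3)/f_obs(t3)]`,
#' with observed frequencies abundance-weighted, reference frequencies
#' uniform over the pool, weights clipped to `[0.1, 10]`, and the output
#' rescaled to preserve total abundance per sample.  This is a
#' reconstruction of the classical read-start trinucleotide reweighting
#' scheme; the random-forest corrector is the preferred method.
#'
#' @param ab Abundance matrix.
#' @param pool A [reference_pool()] (sequences >= 6 nt).
#' @return Reweighted abundance matrix on the same scale.
#' @export
trinucleotide_reweight <- function(ab, pool) {
  stopifnot(inherits(pool, "reference_pool"))
  ids <- rownames(ab)
  seqs <- pool$sequences[ids]
  if (anyNA(seqs)) stop("table species missing from pool")
  t5 <- substring(seqs, 1L, 3L)
  t3 <- substring(seqs, nchar(seqs) - 2L, nchar(seqs))
  f_ref5 <- table(t5) / length(t5)
  f_ref3 <- table(t3) / length(t3)
  out <- ab
  for (j in seq_len(ncol(ab))) {
    a <- ab[, j]
    tot <- sum(a)
    if (tot == 0) next
    f_obs5 <- tapply(a, t5, sum) / tot
    f_obs3 <- tapply(a, t3, sum) / tot
    r5 <- as.numeric(f_ref5[t5]) / as.numeric(f_obs5[t5])
    r3 <- as.numeric(f_ref3[t3]) / as.numeric(f_obs3[t3])
    w <- r5 * r3
    if (any(!is.finite(w))) {
      warning("zero observed trinucleotide frequency; weight clipped")
      w[!is.finite(w)] <- 10
    }
    w <- pmin(pmax(w, 0.1), 10)
    new <- a * w
    out[, j] <- new * (tot / sum(new))
  }
  out
}
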