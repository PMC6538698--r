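#' Template-switching 3'-overhang nucleotide ratio
#'
#' The single-nucleotide 3' DNA overhang of the template-switching starter
#' duplex base-pairs with the RNA's 3'-terminal base; the mix ratio of
#' dA:dC:dG:dT overhangs therefore tunes which 3' ends are captured.
#'
#' @param weights Positive numeric vector named by overhang base
#'   (A, C, G, T), e.g. `c(A = 6.6, C = 0.4, G = 1, T = 1)`.
#' @return Object of class `overhang_ratio`: list with `weights` and
#'   normalised `shares` (summing to 1).
#' @export
overhang_ratio <- function(weights) {
  bases <- c("A", "C", "G", "T")
  if (is.null(names(weights))) names(weights) <- bases
  weights <- weights[bases]
  if (anyNA(weights) || any(weights <= 0))
    stop("overhang weights must be positive for all of A, C, G, T")
  structure(list(weights = weights, shares = weights / sum(weights)),
            class = "overhang_ratio")
}

#' @export
print.overhang_ratio <- function(x, ...) {
  cat("3'-overhang ratio A:C:G:T =",
      paste(format(x$weights, digits = 3), collapse = ":"),
      sprintf("(shares %s)\n",
              paste(sprintf("%.2f", x$shares), collapse = "/")), ...)
  invisible(x)
}

#' Overhang primer-mix presets
#'
#' `NTC`, `NTT`, and `MTT` adapter mixes use equimolar overhangs (they
#' differ in adapter body sequence or in replacing dA by diaminopurine);
#' `NTTR` is the empirically titrated compensating ratio 6.6:0.4:1:1 that
#' nearly eliminates the 3'-end bias on an equimolar miRNA pool.
#'
#' @return Named list of [overhang_ratio()] objects.
#' @export
overhang_presets <- function() {
  list(NTC  = overhang_ratio(c(A = 1, C = 1, G = 1, T = 1)),
       NTT  = overhang_ratio(c(A = 1, C = 1, G = 1, T = 1)),
       MTT  = overhang_ratio(c(A = 1, C = 1, G = 1, T = 1)),
       NTTR = overhang_ratio(c(A = 6.6, C = 0.4, G = 1, T = 1)))
}

# Watson-Crick complement: overhang base -> RNA 3'-end base it captures.
OVERHANG_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Design a compensating 3'-overhang ratio
#'
#' First-order compensation rule: raising the share of a 3'-overhang
#' nucleotide raises the recovery of species with the complementary 3' end,
#' so the new weight for overhang `d` is
#' `current(d) * expected(b) / recovered(b)` with `b` the Watson-Crick
#' complement of `d` (dA pairs U/T-ending RNA, dC pairs G, dG pairs C, dT
#' pairs A).  Ratios are clipped at 10 when a base class is (nearly)
#' unrecovered.  When recovery already matches expectation the design is the
#' identity.  The rule is advisory — the published compensating ratio was
#' found by titration, and this linear model only points in its direction.
#'
#' @param recovered Observed 3'-end base -> abundance-fraction map (see
#'   [three_prime_composition()]); `U` keys accepted.
#' @param expected Target composition, usually the reference pool's own
#'   3'-end composition.
#' @param current The [overhang_ratio()] in use.
#' @return A new [overhang_ratio()] with attribute `"advisory" = TRUE`.
#' @export
design_overhang_ratio <- function(recovered, expected, current) {
  stopifnot(inherits(current, "overhang_ratio"))
  recovered <- normalize_base_map(recovered)
  expected <- normalize_base_map(expected)
  degenerate <- expected == 0 & recovered > 0
  if (any(degenerate))
    stop("expected composition is zero where recovery is positive: ",
         paste(names(recovered)[degenerate], collapse = ", "))
  w <- vapply(names(OVERHANG_COMPLEMENT), function(d) {
    b <- OVERHANG_COMPLEMENT[[d]]
    ratio <- if (recovered[[b]] == 0) 10 else
      min(expected[[b]] / recovered[[b]], 10)
    current$weights[[d]] * ratio
  }, numeric(1))
  out <- overhang_ratio(w)
  attr(out, "advisory") <- TRUE
  out
}

normalize_base_map <- function(x) {
  names(x) <- chartr("U", "T", toupper(names(x)))
  bases <- c("A", "C", "G", "T")
  if (!all(bases %in% names(x)))
    stop("base map must cover A, C, G, T/U")
  x <- x[bases]
  if (any(x < 0) || !all(is.finite(x))) stop("invalid base fractions")
  x
}

#' Screen an adapter for adapter-dimer ligation propensity
#'
#' The thermostable single-stranded ligase that attaches the second adapter
#' prefers A or C, tolerates G, and disfavours T/U at position -3 from the
#' 3' end of the acceptor.  An adapter carrying a favoured base at -3 is
#' itself a good ligation acceptor and therefore prone to forming adapter
#' dimers; inserting a T at -3 (the NTT design) suppresses them.
#'
#' @param adapter_seq Nucleotide string, length >= 3 (U accepted).
#' @return List with `minus3_base` and `dimer_propensity`
#'   (`"high"`, `"medium"`, or `"low"`).
#' @export
adapter_ligation_screen <- function(adapter_seq) {
  s <- canonicalize_sequence(adapter_seq, "adapter")
  if (nchar(s) < 3L) stop("adapter must be at least 3 nt")
  b <- substring(s, nchar(s) - 2L, nchar(s) - 2L)
  prop <- switch(b, A = "high", C = "high", G = "medium", T = "low")
  list(minus3_base = b, dimer_propensity = prop)
}
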