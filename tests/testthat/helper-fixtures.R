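# Shared fixtures and independent oracles, all built in code at test time.

# -- tiny pools -------------------------------------------------------------

toy_pool <- function() {
  reference_pool(
    c("mir-a", "mir-b", "mir-c", "mir-d"),
    c("TGAGGTAGTAGGTTGTATAGTT",
      "TTCAAGTAATCCAGGATAGGCT",
      "AGCAGCATTGTACAGGGCTATGA",
      "CAAAGTGCTTACAGTGCAGGTAG"),
    name = "toy")
}

# study conditions of the simulator: terminal-position effects of the kind
# end-biased libraries show (5' ligase bias at +1..+3, template-switching
# bias at -1), in log10 units
study_bias_effects <- function() {
  list("+1" = c(T = 0.3, A = -0.3),
       "+2" = c(G = 0.3, A = -0.3),
       "+3" = c(G = 0.4, A = -0.4),
       "-1" = c(G = 0.5, T = -0.5))
}

# mark a plain matrix as an abundance table of the given scale
set_scale_for_test <- function(m, scale = "cpm") {
  attr(m, "scale") <- scale
  m
}

# -- toy SAM writer ---------------------------------------------------------

write_toy_sam <- function(path, records,
                          refs = c("mir-x" = 22L, "mir-y" = 20L)) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(refs), refs))
  writeLines(c(hdr, records), path)
  path
}

sam_record <- function(qname, flag, rname, pos, mapq, cigar, seq, nh = NULL) {
  tags <- if (is.null(nh)) character(0) else sprintf("NH:i:%d", nh)
  paste(c(qname, flag, rname, pos, mapq, cigar, "*", 0, 0, seq,
          strrep("I", nchar(seq)), tags), collapse = "\t")
}

# -- exhaustive maximum-pairing oracle --------------------------------------
# Enumerates every nested set of candidate pairs (Watson-Crick + GU, minimum
# hairpin loop `min_loop`) by depth-first search over the candidate-pair
# list, checking pairwise disjointness and non-crossing directly.

enumerate_max_pairs <- function(seq, min_loop = 3L) {
  s <- strsplit(chartr("Uu", "Tt", toupper(seq)), "", fixed = TRUE)[[1]]
  L <- length(s)
  ok <- function(a, b) paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  cand <- list()
  if (L >= 2) {
    for (i in seq_len(L - 1L)) {
      for (j in seq_len(L)) {
        if (j - i > min_loop && ok(s[i], s[j]))
          cand[[length(cand) + 1L]] <- c(i, j)
      }
    }
  }
  compatible <- function(p, q) {
    if (any(p %in% q)) return(FALSE)
    crossing <- (p[1] < q[1] && q[1] < p[2] && p[2] < q[2]) ||
                (q[1] < p[1] && p[1] < q[2] && q[2] < p[2])
    !crossing
  }
  best <- 0L
  rec <- function(idx, chosen) {
    if (length(chosen) > best) best <<- length(chosen)
    if (idx > length(cand)) return(invisible())
    for (ci in idx:length(cand)) {
      p <- cand[[ci]]
      if (all(vapply(chosen, compatible, logical(1), q = p)))
        rec(ci + 1L, c(chosen, list(p)))
    }
  }
  if (length(cand)) rec(1L, list())
  best
}

# -- exact two-sided rank-sum oracle ----------------------------------------
# Enumerates all assignments of the pooled values to the two groups and
# counts assignments at least as extreme (in |U - mn/2|) as observed.

exact_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  m <- length(x); n <- length(y)
  r <- rank(pooled)
  u_of <- function(ix) sum(r[ix]) - m * (m + 1) / 2
  u_obs <- u_of(seq_len(m))
  center <- m * n / 2
  combs <- utils::combn(m + n, m)
  us <- apply(combs, 2, u_of)
  mean(abs(us - center) >= abs(u_obs - center) - 1e-9)
}
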