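# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Commercial rounding used for reported percentages: halves always move away
#' from zero, unlike [base::round()]'s banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(0.25, 1)  # 0.3, where round() gives 0.2
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Percentages as reported in summaries: one decimal at >= 10%, two below.
format_percent <- function(p) {
  ifelse(p >= 10, round_half_up(p, 1), round_half_up(p, 2))
}

#' Derive a stream-specific seed from a master seed
#'
#' All simulator stages draw their randomness from sub-seeds derived
#' deterministically from one master seed, so each stage can be regenerated
#' independently without replaying the stages before it.
#'
#' @param seed Master integer seed.
#' @param stream Integer stream index (>= 0).
#' @return An integer seed < 2^31.
#' @export
derive_seed <- function(seed, stream) {
  s <- (as.numeric(seed) %% 2147483647) * 69069 + as.numeric(stream) * 104729
  as.integer(s %% 2147483647)
}

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Thin policy wrapper around [stats::wilcox.test()]: the exact null
#' distribution is used when both groups have at most `exact_max` values and
#' there are no ties; otherwise the large-sample normal approximation with tie
#' correction (and no continuity correction) is used. When every value in both
#' groups is identical the test is degenerate and p = 1 is returned with a
#' flag.
#'
#' @param x,y Numeric vectors for the two groups.
#' @param exact_max Largest per-group size for the exact path (default 25).
#' @return List with `statistic` (rank-sum W), `p_value`, `exact` (logical),
#'   and `degenerate` (logical).
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 25) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  if (length(unique(c(x, y))) == 1L) {
    return(list(statistic = length(x) * length(y) / 2, p_value = 1,
                exact = FALSE, degenerate = TRUE))
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- !ties && length(x) <= exact_max && length(y) <= exact_max
  res <- if (use_exact) {
    stats::wilcox.test(x, y, exact = TRUE)
  } else {
    suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = FALSE))
  }
  list(statistic = unname(res$statistic), p_value = res$p.value,
       exact = use_exact, degenerate = FALSE)
}
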