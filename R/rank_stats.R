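# Self-contained rank-based tests: Kruskal-Wallis with tie correction,
# Dunn pairwise post-hoc z tests, and Benjamini-Hochberg adjustment.
# Mid-ranks are used for ties throughout; p-values come from the chi-square
# (KW) and normal (Dunn) approximations, appropriate for the large group
# sizes this pipeline produces.

.rank_setup <- function(groups) {
  if (any(vapply(groups, length, 0L) == 0)) stop("empty group supplied")
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), vapply(groups, length, 0L))
  r <- rank(x)  # mid-ranks
  N <- length(x)
  ties <- table(x)
  tie_sum <- sum(ties^3 - ties)
  list(x = x, g = g, r = r, N = N, tie_sum = tie_sum,
       n = vapply(groups, length, 0L),
       rbar = tapply(r, g, mean))
}

#' Kruskal-Wallis rank-sum test
#'
#' H statistic with tie correction and chi-square p-value on k - 1 degrees
#' of freedom. When every observation is tied, H is defined as 0 with a
#' warning.
#'
#' @param groups List of k >= 2 numeric vectors (all non-empty).
#' @return A list of class `rank_test`: `H`, `df`, `p`, `n` (group sizes),
#'   `tie_correction`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(length(groups) >= 2)
  s <- .rank_setup(groups)
  H <- 12 / (s$N * (s$N + 1)) * sum(s$n * s$rbar^2) - 3 * (s$N + 1)
  C <- 1 - s$tie_sum / (s$N^3 - s$N)
  if (C == 0) {
    warning("all observations tied; H defined as 0")
    H <- 0
    C <- 1
  } else {
    H <- H / C
  }
  H <- max(H, 0)  # guard tiny negative rounding
  df <- length(groups) - 1
  structure(list(H = H, df = df, p = stats::pchisq(H, df, lower.tail = FALSE),
                 n = s$n, tie_correction = C),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.4g (n = %s)\n",
              x$H, x$df, x$p, paste(x$n, collapse = "/")))
  invisible(x)
}

#' Dunn pairwise post-hoc comparisons
#'
#' Pairwise z statistics from mean-rank differences with the pooled-variance
#' tie correction, two-sided normal p-values, and Benjamini-Hochberg
#' adjustment across all pairs.
#'
#' @param groups List of k >= 2 numeric vectors (all non-empty); names are
#'   used as group labels.
#' @return data.frame (group1, group2, z, p_raw, p_adjusted).
#' @export
dunn_posthoc <- function(groups) {
  stopifnot(length(groups) >= 2)
  s <- .rank_setup(groups)
  labs <- if (!is.null(names(groups))) names(groups) else
    as.character(seq_along(groups))
  var_term <- s$N * (s$N + 1) / 12 - s$tie_sum / (12 * (s$N - 1))
  pairs <- utils::combn(seq_along(groups), 2)
  z <- apply(pairs, 2, function(ij) {
    (s$rbar[ij[1]] - s$rbar[ij[2]]) /
      sqrt(var_term * (1 / s$n[ij[1]] + 1 / s$n[ij[2]]))
  })
  p_raw <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  data.frame(group1 = labs[pairs[1, ]], group2 = labs[pairs[2, ]],
             z = as.numeric(z), p_raw = p_raw,
             p_adjusted = bh_adjust(p_raw), stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, capped at 1, in the original order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / seq(m, 1) * p[o]))
  adj[ro]
}
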