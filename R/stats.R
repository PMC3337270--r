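#' Odds ratio of a 2x2 contingency table
#'
#' The disproportionality measure `ad / (bc)`: the unexpectedness of the
#' event given exposure, relative to the background arm. Undefined (NA) when
#' `b` or `c` is zero; no continuity correction is applied by default (pass
#' `correct = TRUE` for the Haldane-Anscombe +0.5 on every cell).
#'
#' @param table A `contingency_table` or numeric vector `c(a, b, c, d)`.
#' @param correct Apply the +0.5 continuity correction to all cells.
#' @return A positive number, or `NA_real_` when undefined.
#' @examples
#' odds_ratio(c(339, 1221, 1488, 11031))  # 2.06
#' @export
odds_ratio <- function(table, correct = FALSE) {
  t <- as_contingency(table)
  cells <- c(t$a, t$b, t$c, t$d) + if (correct) 0.5 else 0
  if (cells[2] == 0 || cells[3] == 0) return(NA_real_)
  (cells[1] * cells[4]) / (cells[2] * cells[3])
}

#' Woolf (log-normal) confidence interval for an odds ratio
#'
#' `exp(ln OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. Requires all four cells
#' positive; returns `NA`s otherwise (use `correct = TRUE` for the
#' Haldane-Anscombe correction).
#'
#' @param table A `contingency_table` or numeric vector `c(a, b, c, d)`.
#' @param level Confidence level (default 0.95).
#' @param correct Apply the +0.5 continuity correction to all cells.
#' @return Named numeric vector `c(low, high)`.
#' @examples
#' woolf_ci(c(339, 1221, 1488, 11031))  # 1.80 - 2.35
#' @export
woolf_ci <- function(table, level = 0.95, correct = FALSE) {
  stopifnot(level > 0, level < 1)
  t <- as_contingency(table)
  cells <- c(t$a, t$b, t$c, t$d) + if (correct) 0.5 else 0
  if (any(cells == 0)) return(c(low = NA_real_, high = NA_real_))
  lor <- log((cells[1] * cells[4]) / (cells[2] * cells[3]))
  se <- sqrt(sum(1 / cells))
  z <- qnorm((1 + level) / 2)
  c(low = exp(lor - z * se), high = exp(lor + z * se))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact p-value from the hypergeometric distribution of cell `a` given the
#' table margins. The default two-sided convention sums the point
#' probabilities of all margin-consistent tables no more probable than the
#' observed one; `method = "doubled"` instead doubles the smaller one-sided
#' tail (capped at 1).
#'
#' @param table A `contingency_table` or numeric vector `c(a, b, c, d)`.
#' @param method `"point"` (default) or `"doubled"`.
#' @return The p-value in (0, 1].
#' @examples
#' fisher_exact(c(16, 487, 61, 2831))  # 0.19
#' @export
fisher_exact <- function(table, method = c("point", "doubled")) {
  method <- match.arg(method)
  t <- as_contingency(table)
  a <- t$a; b <- t$b; c <- t$c; d <- t$d
  n <- a + b + c + d
  if (n == 0) abort("empty table")
  m1 <- a + b  # exposed margin
  k <- a + c   # event margin
  support <- max(0, k - (n - m1)):min(k, m1)
  dens <- dhyper(support, m1, n - m1, k)
  p_obs <- dhyper(a, m1, n - m1, k)
  if (method == "point") {
    p <- sum(dens[dens <= p_obs * (1 + 1e-7)])
  } else {
    lower <- sum(dens[support <= a])
    upper <- sum(dens[support >= a])
    p <- min(1, 2 * min(lower, upper))
  }
  min(1, p)
}

#' Probability that cell a is jointly over-counted
#'
#' Entering a patient into cell `a` erroneously requires the condition, drug
#' and event annotations to be false positives simultaneously; under
#' independent per-annotation false-positive rates this probability is the
#' cube of the rate. At a 20% rate it is 0.008 (0.8%).
#'
#' @param fp_rate Per-annotation false-positive probability in \[0, 1\].
#' @return `fp_rate ^ 3`.
#' @examples
#' cell_a_error_probability(0.20)  # 0.008
#' @export
cell_a_error_probability <- function(fp_rate) {
  if (!is.numeric(fp_rate) || any(fp_rate < 0) || any(fp_rate > 1)) {
    abort("fp_rate must lie in [0, 1]")
  }
  fp_rate^3
}

#' Sensitivity adjustment of a 2x2 table for annotation false positives
#'
#' Discounts each cell by the probability that the positive annotations
#' defining it are all true under an independent per-annotation
#' false-positive rate: cell `a` rests on three positive annotations
#' (condition, drug, event), `b` and `c` on two, `d` on one, so the
#' `"annotation-independence"` scheme scales them by `(1-fp)^3`, `(1-fp)^2`,
#' `(1-fp)^2` and `(1-fp)` respectively, rounding to whole patients. Note the
#' odds ratio is invariant under this scheme (the factors cancel in
#' `ad/(bc)`); the interval and p-value widen as the cells shrink. The
#' adjustment is deliberately not idempotent: applying it twice discounts
#' twice.
#'
#' @param table A `contingency_table` or numeric vector `c(a, b, c, d)`.
#' @param fp_rate Per-annotation false-positive probability in \[0, 1\].
#' @param scheme Adjustment scheme; only `"annotation-independence"` is
#'   currently defined.
#' @param level Confidence level for the adjusted interval.
#' @return A list with the adjusted `table` (a `contingency_table`), the
#'   `scheme` identifier, and `odds_ratio`, `ci_low`, `ci_high`, `p_value`
#'   computed on the adjusted table.
#' @export
adjust_false_positive <- function(table, fp_rate,
                                  scheme = "annotation-independence",
                                  level = 0.95) {
  schemes <- "annotation-independence"
  if (!scheme %in% schemes) {
    abort(paste0("unknown scheme '", scheme, "'; available: ",
                 paste(schemes, collapse = ", ")))
  }
  if (!is.numeric(fp_rate) || fp_rate < 0 || fp_rate > 1) {
    abort("fp_rate must lie in [0, 1]")
  }
  t <- as_contingency(table)
  q <- 1 - fp_rate
  adj <- contingency_table(round(t$a * q^3), round(t$b * q^2),
                           round(t$c * q^2), round(t$d * q))
  ci <- woolf_ci(adj, level = level)
  list(table = adj, scheme = scheme, fp_rate = fp_rate,
       odds_ratio = odds_ratio(adj),
       ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
       p_value = fisher_exact(adj))
}
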