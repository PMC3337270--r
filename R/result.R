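#' Bundle a contingency table with its disproportionality statistics
#'
#' @param table A `contingency_table`.
#' @param level Confidence level for the Woolf interval.
#' @param config Optional list echoing the run configuration.
#' @return A `signal_result` object with elements `table`, `excluded`,
#'   `estimate` (odds ratio), `conf.low`, `conf.high`, `p.value`, `level`,
#'   `flags` and `config`.
#' @export
signal_result <- function(table, level = 0.95, config = list()) {
  t <- as_contingency(table)
  cells <- c(t$a, t$b, t$c, t$d)
  flags <- character()
  if (any(cells == 0)) flags <- c(flags, "zero-cell")
  or <- odds_ratio(t)
  if (is.na(or)) flags <- c(flags, "undefined-odds-ratio")
  ci <- woolf_ci(t, level = level)
  p <- if (sum(cells) > 0) fisher_exact(t) else NA_real_
  if (sum(cells) == 0) flags <- c(flags, "empty-table")
  structure(
    list(table = t,
         excluded = t$excluded %||% integer(),
         estimate = or,
         conf.low = unname(ci["low"]),
         conf.high = unname(ci["high"]),
         p.value = p,
         level = level,
         flags = flags,
         config = config),
    class = "signal_result"
  )
}

format_p <- function(p) {
  if (is.na(p)) return("NA")
  if (p < 1e-3) sprintf("%.2e", p) else sprintf("%.2f", p)
}

#' @export
print.signal_result <- function(x, ...) {
  cat("Drug-safety signal test\n")
  print(x$table)
  if (is.na(x$estimate)) {
    cat("odds ratio: undefined\n")
  } else {
    cat(sprintf("odds ratio %.2f, %d%% CI %.2f-%.2f, Fisher p = %s\n",
                x$estimate, round(100 * x$level),
                x$conf.low, x$conf.high, format_p(x$p.value)))
  }
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a signal test result
#'
#' @param x A `signal_result`.
#' @param ... Unused.
#' @return A one-row tibble with the cells, counts of excluded patients, the
#'   odds ratio, interval bounds and p-value.
#' @method tidy signal_result
#' @export
tidy.signal_result <- function(x, ...) {
  tibble(a = x$table$a, b = x$table$b, c = x$table$c, d = x$table$d,
         excluded = sum(x$excluded),
         estimate = x$estimate,
         conf.low = x$conf.low, conf.high = x$conf.high,
         p.value = x$p.value)
}

#' One-row model summary of a signal test
#'
#' @param x A `signal_result`.
#' @param ... Unused.
#' @return A one-row tibble with `estimate`, `conf.low`, `conf.high`,
#'   `p.value`, `n` (patients in the table), `n_excluded` and `level`.
#' @method glance signal_result
#' @export
glance.signal_result <- function(x, ...) {
  tibble(estimate = x$estimate, conf.low = x$conf.low,
         conf.high = x$conf.high, p.value = x$p.value,
         n = x$table$a + x$table$b + x$table$c + x$table$d,
         n_excluded = sum(x$excluded), level = x$level)
}

#' Forest-style plot of a signal test result
#'
#' The odds ratio and its confidence interval on a log scale, with the null
#' at 1 marked.
#'
#' @param object A `signal_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot signal_result
#' @export
autoplot.signal_result <- function(object, ...) {
  df <- tidy(object)
  df$label <- "signal"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", color = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high),
                            height = 0.1) +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}
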