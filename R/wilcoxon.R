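#' Wilcoxon matched-pairs signed-rank test
#'
#' Paired two-sided Wilcoxon signed-rank test on per-protein
#' (ordered, disordered) value pairs. Pairs with an `NA` member are dropped
#' (count reported), zero differences are dropped per the Wilcoxon
#' convention, the exact null distribution is used when the effective n is at
#' most 25 and the absolute differences are tie-free, and the tie- and
#' continuity-corrected normal approximation otherwise. Built on
#' [stats::wilcox.test()].
#'
#' @param x,y Paired numeric vectors (e.g. per-protein ordered and disordered
#'   values); alternatively `x` may be a data frame with columns
#'   `value_ordered` and `value_disordered` and `y` omitted.
#' @param exact_max Largest effective n for which the exact distribution is
#'   used (default 25).
#' @return An object of class `glyco_wilcoxon`: a list with `n_effective`,
#'   `statistic` (W, the positive-rank sum), `p_value`, `method`
#'   (`"exact"` / `"normal_approx"` / `"none"`), `n_dropped_na`,
#'   `n_dropped_zero`. All-zero or empty input yields an `NA` result with a
#'   warning.
#' @export
#' @examples
#' wilcoxon_signed_rank(c(5, 6, 7, 9), c(1, 2, 3, 4))
wilcoxon_signed_rank <- function(x, y = NULL, exact_max = 25L) {
  if (is.data.frame(x)) {
    stopifnot(is.null(y),
              all(c("value_ordered", "value_disordered") %in% names(x)))
    y <- x$value_disordered
    x <- x$value_ordered
  }
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  n_dropped_na <- sum(!ok)
  d <- x[ok] - y[ok]
  n_dropped_zero <- sum(d == 0)
  d <- d[d != 0]
  n_eff <- length(d)
  if (n_eff == 0L) {
    warn("No non-zero differences; Wilcoxon result is NA")
    res <- list(n_effective = 0L, statistic = NA_real_, p_value = NA_real_,
                method = "none", n_dropped_na = n_dropped_na,
                n_dropped_zero = n_dropped_zero)
    class(res) <- "glyco_wilcoxon"
    return(res)
  }
  ties <- anyDuplicated(abs(d)) > 0L
  use_exact <- n_eff <= exact_max && !ties
  ht <- suppressWarnings(
    wilcox.test(d, exact = use_exact, correct = TRUE, alternative = "two.sided")
  )
  res <- list(
    n_effective = n_eff,
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    method = if (use_exact) "exact" else "normal_approx",
    n_dropped_na = n_dropped_na,
    n_dropped_zero = n_dropped_zero
  )
  class(res) <- "glyco_wilcoxon"
  res
}

#' @export
print.glyco_wilcoxon <- function(x, ...) {
  cat("Wilcoxon matched-pairs signed-rank test\n")
  cat(sprintf("  n_effective = %d (dropped: %d NA pair(s), %d zero difference(s))\n",
              x$n_effective, x$n_dropped_na, x$n_dropped_zero))
  cat(sprintf("  W = %s, p = %s  [%s]\n",
              format(x$statistic), format.pval(x$p_value), x$method))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Wilcoxon signed-rank result
#' @param x A `glyco_wilcoxon` object.
#' @param ... Unused.
#' @return A one-row tibble with `n_effective`, `statistic`, `p_value`,
#'   `method`, `n_dropped_na`, `n_dropped_zero`.
#' @export
tidy.glyco_wilcoxon <- function(x, ...) {
  tibble(
    n_effective = x$n_effective, statistic = x$statistic,
    p_value = x$p_value, method = x$method,
    n_dropped_na = x$n_dropped_na, n_dropped_zero = x$n_dropped_zero
  )
}

#' @rdname tidy.glyco_wilcoxon
#' @export
glance.glyco_wilcoxon <- function(x, ...) tidy(x)
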