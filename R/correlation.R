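check_cc_inputs <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L)
    stop("need at least 3 observations", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite values in input", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("degenerate input: zero variance", call. = FALSE)
}

#' Pearson product-moment correlation
#'
#' Written out explicitly (centred cross-product over the product of
#' centred norms) so that `stats::cor` can serve as an independent check.
#'
#' @param x,y numeric vectors of equal length (>= 3), each with nonzero
#'   variance.
#' @return The correlation coefficient in `[-1, 1]`.
#' @export
pearson_cc <- function(x, y) {
  check_cc_inputs(x, y)
  xc <- x - mean(x)
  yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

#' Two-sided p-value for a Pearson correlation
#'
#' Student-t test with `n - 2` degrees of freedom at
#' \eqn{t = cc \sqrt{n-2} / \sqrt{1-cc^2}}; equivalent to
#' `stats::cor.test(..., method = "pearson")`.
#'
#' @param cc correlation coefficient, `|cc| <= 1`.
#' @param n sample size, `n >= 3`.
#' @return Two-sided p-value in `(0, 1]`; exactly 0 when `|cc| = 1`.
#' @export
cc_pvalue <- function(cc, n) {
  if (!is.numeric(cc) || length(cc) != 1L || is.na(cc) || abs(cc) > 1)
    stop("cc must be a single value in [-1, 1]", call. = FALSE)
  if (!is_count(n) || n < 3L)
    stop("n must be an integer >= 3", call. = FALSE)
  if (abs(cc) == 1) return(0)
  t_stat <- cc * sqrt(n - 2) / sqrt(1 - cc^2)
  2 * stats::pt(-abs(t_stat), df = n - 2)
}

#' Per-class correlation of compensated N_E with side-chain size
#'
#' @param ne_results an `ne_table`.
#' @param table matching `aa_table` providing `n_sa` (and `class`).
#' @return Named numeric vector, one correlation per aaRS class.
#' @export
per_class_cc <- function(ne_results, table) {
  merged <- merge(as.data.frame(ne_results)[, c("aa", "class", "ne_compensated")],
                  as.data.frame(table)[, c("aa", "n_sa")], by = "aa")
  out <- vapply(AA_CLASSES, function(cl) {
    sub <- merged[merged$class == cl, ]
    tryCatch(pearson_cc(sub$ne_compensated, sub$n_sa),
             error = function(e)
               stop("class ", cl, ": ", conditionMessage(e), call. = FALSE))
  }, numeric(1))
  names(out) <- AA_CLASSES
  out
}

#' Permutation test for a Pearson correlation
#'
#' Permutes `y` `n_perm` times and reports
#' \eqn{p = (1 + \#\{|cc^*| \ge |cc_{obs}|\}) / (n_{perm} + 1)}.
#' Reproducible for a given seed; the caller's RNG state is untouched.
#'
#' @param x,y as in [pearson_cc()].
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @return Permutation p-value.
#' @export
permutation_test <- function(x, y, n_perm = 9999L, seed = 1L) {
  check_cc_inputs(x, y)
  if (!is_count(n_perm) || n_perm < 1L)
    stop("n_perm must be a positive integer", call. = FALSE)
  n <- length(x)
  xs <- (x - mean(x)) / sqrt(sum((x - mean(x))^2))
  ys <- (y - mean(y)) / sqrt(sum((y - mean(y))^2))
  obs <- abs(sum(xs * ys))
  hits <- with_local_seed(seed, {
    perm <- matrix(0, nrow = n, ncol = n_perm)
    for (j in seq_len(n_perm)) perm[, j] <- ys[sample.int(n)]
    cc_star <- abs(as.vector(crossprod(xs, perm)))
    sum(cc_star >= obs - 1e-12)
  })
  (1 + hits) / (n_perm + 1)
}

#' Correlation between compensated N_E and side-chain size
#'
#' Assembles the full correlation result for an `ne_table` / `aa_table`
#' pair: overall Pearson coefficient on (`ne_compensated`, `n_sa`), its
#' square, the analytic two-sided p-value, per-class coefficients, and
#' optionally a permutation p-value. The compensated values are used
#' throughout: only after circuit compensation do the three pathway groups
#' fall on a single trend.
#'
#' @param ne_results an `ne_table`.
#' @param table matching `aa_table`.
#' @param permutations optional number of permutations for a companion
#'   permutation p-value.
#' @param seed seed for the permutation test.
#' @return Object of class `correlation_result`: list with `n`, `cc`,
#'   `r_squared`, `p_two_sided`, `per_class`, and (when requested)
#'   `p_permutation`, `n_perm`, `seed`.
#' @examples
#' g <- canonical_pathway_graph(); tab <- canonical_aa_table()
#' correlate_ne_nsa(ne_table(g, tab), tab)
#' @export
correlate_ne_nsa <- function(ne_results, table, permutations = NULL,
                             seed = NULL) {
  merged <- merge(as.data.frame(ne_results)[, c("aa", "ne_compensated")],
                  as.data.frame(table)[, c("aa", "n_sa")], by = "aa")
  x <- merged$ne_compensated
  y <- merged$n_sa
  cc <- pearson_cc(x, y)
  out <- list(n = nrow(merged), cc = cc, r_squared = cc^2,
              p_two_sided = cc_pvalue(cc, nrow(merged)),
              per_class = per_class_cc(ne_results, table),
              p_permutation = NULL, n_perm = NULL, seed = NULL)
  if (!is.null(permutations)) {
    out$p_permutation <- permutation_test(x, y, n_perm = permutations,
                                          seed = seed %||% 1L)
    out$n_perm <- as.integer(permutations)
    out$seed <- seed
  }
  structure(out, class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("N_E vs N_SA correlation (n = %d)\n", x$n))
  cat(sprintf("  CC = %.2f, R^2 = %.2f, p = %.2g\n",
              x$cc, x$r_squared, x$p_two_sided))
  cat(sprintf("  per class: I %.2f, II %.2f\n",
              x$per_class[["I"]], x$per_class[["II"]]))
  if (!is.null(x$p_permutation))
    cat(sprintf("  permutation p = %.3g (%d permutations, seed %s)\n",
                x$p_permutation, x$n_perm, format(x$seed)))
  invisible(x)
}
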