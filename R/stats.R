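#' Kruskal-Wallis omnibus test across groups
#'
#' Rank-based one-way comparison with tie correction; the p-value comes
#' from the chi-square approximation with `groups - 1` degrees of freedom
#' (via [stats::kruskal.test]). When every observation is identical there
#' is nothing to rank: H = 0 and p = 1 with a warning.
#'
#' @param groups named list of numeric vectors (one value per animal).
#' @return list with `H`, `p`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  check_groups(groups)
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) == 1L) {
    warning("all values identical; H = 0, p = 1")
    return(list(H = 0, p = 1, df = length(groups) - 1L))
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter))
}

#' Sidak-adjusted significance level
#'
#' `1 - (1 - alpha)^(1/k)` for `k` comparisons: the per-comparison level
#' that keeps the familywise error at `alpha` under independence. The
#' study design compares k = 4 transgenic lines to age-matched wild-type
#' mice.
#'
#' @param alpha nominal familywise level, in (0, 1).
#' @param k number of comparisons, >= 1.
#' @export
sidak_threshold <- function(alpha, k) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (k < 1) stop("k must be at least 1")
  1 - (1 - alpha)^(1 / k)
}

#' Two-sided Mann-Whitney rank-sum test
#'
#' Exact null distribution when the smaller sample has at most 8
#' observations and there are no ties; otherwise the normal approximation
#' with tie and continuity correction (via [stats::wilcox.test]).
#'
#' @param a,b numeric vectors.
#' @return list with `U` (the Mann-Whitney statistic for `a`) and `p`.
#' @export
mann_whitney <- function(a, b) {
  exact <- min(length(a), length(b)) <= 8 &&
    !any(duplicated(c(a, b)))
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)
  )
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Gatekept group comparison for one metric
#'
#' Two-stage procedure: the Kruskal-Wallis omnibus test is evaluated at
#' the Sidak-adjusted level `1 - (1 - alpha)^(1/k)`; only when it passes
#' are pairwise Mann-Whitney tests of each non-reference group against
#' the reference run, flagged `*` (p < 0.05) and `**` (p < 0.01).
#'
#' @param groups named list of per-animal metric vectors; must include
#'   the reference group.
#' @param alpha nominal level (default 0.05).
#' @param k number of planned comparisons for the Sidak adjustment
#'   (default 4).
#' @param reference name of the reference group (default `"WT"`).
#' @return object of class `comparison_result`: list with `H`, `p_omnibus`,
#'   `gate_level`, `gate_passed`, and `pairwise` (data.frame group/U/p/flag,
#'   present only when the gate passed).
#' @export
compare_metric <- function(groups, alpha = 0.05, k = 4, reference = "WT") {
  check_groups(groups)
  if (!reference %in% names(groups))
    stop("reference group '", reference, "' missing")
  kw <- suppressWarnings(kruskal_wallis(groups))
  gate <- sidak_threshold(alpha, k)
  res <- list(H = kw$H, p_omnibus = kw$p, gate_level = gate,
              gate_passed = is.finite(kw$p) && kw$p < gate,
              pairwise = NULL, reference = reference)
  if (res$gate_passed) {
    others <- setdiff(names(groups), reference)
    res$pairwise <- do.call(rbind, lapply(others, function(g) {
      mw <- mann_whitney(groups[[g]], groups[[reference]])
      data.frame(group = g, U = mw$U, p = mw$p,
                 flag = significance_flag(mw$p))
    }))
  }
  class(res) <- "comparison_result"
  res
}

significance_flag <- function(p) {
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis H = %.3f, p = %.4g (gate at %.4g: %s)\n",
              x$H, x$p_omnibus, x$gate_level,
              if (x$gate_passed) "passed" else "not passed"))
  if (!is.null(x$pairwise)) {
    cat("pairwise Mann-Whitney vs ", x$reference, ":\n", sep = "")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups")
  if (any(lengths(groups) < 3L))
    stop("each group needs at least 3 values")
  invisible(groups)
}
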