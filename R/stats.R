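# Inferential layer: SEM, pooled-variance unpaired Student's t-test, one-way
# ANOVA, alpha = 0.05, two-sided throughout.

#' Standard error of the mean
#'
#' Sample SD (n - 1 denominator) divided by sqrt(n). In this package n counts
#' organoids, not cells.
#'
#' @param values numeric vector, length >= 2.
#' @return the SEM.
#' @export
sem <- function(values) {
  if (length(values) < 2) stop("SEM needs n >= 2", call. = FALSE)
  stats::sd(values) / sqrt(length(values))
}

test_result <- function(statistic, p_value, df, alpha, method,
                        degenerate = FALSE) {
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 df = unname(df), alpha = alpha,
                 significant = is.finite(p_value) && p_value < alpha,
                 method = method, degenerate = degenerate),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g (%ssignificant at alpha = %g)%s\n",
              x$method, x$statistic, paste(round(x$df, 2), collapse = ", "),
              x$p_value, if (x$significant) "" else "not ", x$alpha,
              if (x$degenerate) " [degenerate: zero variance]" else ""))
  invisible(x)
}

#' Unpaired two-sided Student's t-test (pooled variance)
#'
#' Equal-variance two-sample t-test, df = n_a + n_b - 2. Degenerate inputs
#' (zero pooled variance) yield t = 0, p = 1 for equal means and p = 0,
#' flagged, for unequal means.
#'
#' @param a,b numeric vectors (each n >= 2).
#' @param alpha significance level (default 0.05).
#' @return A `test_result` (statistic = t).
#' @export
t_test_unpaired <- function(a, b, alpha = 0.05) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs n >= 2", call. = FALSE)
  df <- length(a) + length(b) - 2
  pooled <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) / df
  if (pooled <= 0) {
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(test_result(0, 1, df, alpha, "Student's unpaired t-test", TRUE))
    return(test_result(sign(mean(a) - mean(b)) * Inf, 0, df, alpha,
                       "Student's unpaired t-test", TRUE))
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  test_result(ht$statistic, ht$p.value, ht$parameter, alpha,
              "Student's unpaired t-test")
}

#' One-way ANOVA
#'
#' Classic fixed-effects one-way ANOVA, F = MS_between / MS_within with
#' df = (k - 1, N - k). For two groups F equals the squared pooled t
#' statistic.
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 2).
#' @param alpha significance level (default 0.05).
#' @return A `test_result` (statistic = F, df = c(df1, df2)).
#' @export
one_way_anova <- function(groups, alpha = 0.05) {
  if (length(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs n >= 2", call. = FALSE)
  within_var <- vapply(groups, stats::var, numeric(1))
  k <- length(groups)
  n_tot <- sum(lengths(groups))
  dfs <- c(k - 1, n_tot - k)
  if (all(within_var <= 0)) {
    means <- vapply(groups, mean, numeric(1))
    if (isTRUE(all.equal(max(means), min(means))))
      return(test_result(0, 1, dfs, alpha, "One-way ANOVA", TRUE))
    return(test_result(Inf, 0, dfs, alpha, "One-way ANOVA", TRUE))
  }
  values <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ht <- stats::oneway.test(values ~ g, var.equal = TRUE)
  test_result(ht$statistic, ht$p.value,
              c(ht$parameter[["num df"]], ht$parameter[["denom df"]]),
              alpha, "One-way ANOVA")
}

#' Compare group summaries and write a stats table
#'
#' Runs, for each pair of conditions, the unpaired t-test, plus a one-way
#' ANOVA across all conditions; per-bin comparisons are labelled by bin.
#' Optional Holm adjustment across the pairwise p-values (off by default,
#' matching per-bin reporting without multiplicity correction).
#'
#' @param values named list: condition -> numeric vector of per-organoid
#'   values (one readout, e.g. overall proliferation rate).
#' @param label readout label recorded in the output.
#' @param alpha significance level.
#' @param holm logical: apply Holm adjustment to the pairwise p-values.
#' @return data.frame: comparison, label, test, statistic, df, p_value,
#'   significant.
#' @export
compare_groups <- function(values, label = "", alpha = 0.05, holm = FALSE) {
  stopifnot(is.list(values), length(values) >= 2, !is.null(names(values)))
  cmb <- utils::combn(names(values), 2, simplify = FALSE)
  rows <- lapply(cmb, function(pair) {
    tt <- t_test_unpaired(values[[pair[1]]], values[[pair[2]]], alpha)
    data.frame(comparison = paste(pair, collapse = " vs "), label = label,
               test = "t", statistic = tt$statistic,
               df = paste(tt$df, collapse = ","), p_value = tt$p_value,
               significant = tt$significant)
  })
  out <- do.call(rbind, rows)
  if (holm) {
    out$p_value <- stats::p.adjust(out$p_value, "holm")
    out$significant <- out$p_value < alpha
  }
  if (length(values) > 2) {
    an <- one_way_anova(values, alpha)
    out <- rbind(out, data.frame(
      comparison = paste(names(values), collapse = " vs "), label = label,
      test = "F", statistic = an$statistic,
      df = paste(an$df, collapse = ","), p_value = an$p_value,
      significant = an$significant))
  }
  rownames(out) <- NULL
  out
}
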