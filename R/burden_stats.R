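#' Construct a 2x2 case-control exposure table
#'
#' Cell layout follows the epidemiological convention:
#' `a` = cases exposed, `b` = cases unexposed, `c` = controls exposed,
#' `d` = controls unexposed, so the cross-product odds ratio is `ad / bc`.
#'
#' @param a,b,c,d Non-negative integer counts.
#' @param label Optional description of the exposure.
#' @return List of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d, label = "") {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("cell counts must be non-negative integers")
  structure(list(a = a, b = b, c = c, d = d, label = label),
            class = "contingency_table")
}

as_matrix_2x2 <- function(t) {
  matrix(c(t$a, t$b, t$c, t$d), nrow = 2, byrow = TRUE,
         dimnames = list(group = c("case", "control"),
                         exposure = c("exposed", "unexposed")))
}

#' @export
print.contingency_table <- function(x, ...) {
  if (nzchar(x$label)) cat(x$label, "\n")
  print(as_matrix_2x2(x))
  invisible(x)
}

#' Cross-product (sample) odds ratio of a 2x2 table
#'
#' Returns `ad / bc`. When `b * c = 0` the ratio is not finite: `Inf` when
#' `a * d > 0`, `NaN` for a doubly degenerate table; both are flagged with
#' attribute `degenerate = TRUE` rather than raising an error.
#'
#' @param t A `contingency_table`.
#' @return The odds ratio, possibly `Inf`/`NaN` with attribute `degenerate`.
#' @export
odds_ratio <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  num <- t$a * t$d
  den <- t$b * t$c
  if (den == 0) {
    return(structure(if (num > 0) Inf else NaN, degenerate = TRUE))
  }
  num / den
}

#' Pearson chi-square test without continuity correction
#'
#' For a 2x2 table the statistic equals the closed form
#' `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`; general 2xk tables are supported
#' for cohort-characteristics comparisons. No Yates correction is applied.
#'
#' @param t A `contingency_table`, or a counts matrix for 2xk tables.
#' @return List with `statistic`, `df` and `p`. A table with a zero margin
#'   yields `NA` statistic and p with attribute `degenerate = TRUE`.
#' @export
pearson_chi_square <- function(t) {
  m <- if (inherits(t, "contingency_table")) as_matrix_2x2(t) else as.matrix(t)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    out <- list(statistic = NA_real_, df = NA_real_, p = NA_real_)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Sums the conditional hypergeometric probabilities of all tables (with the
#' observed margins) no more probable than the observed one. Computed by
#' direct enumeration over the support.
#'
#' @param t A `contingency_table`.
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  m1 <- t$a + t$b
  m2 <- t$c + t$d
  n1 <- t$a + t$c
  if (m1 + m2 == 0) return(1)
  support <- max(0, n1 - m2):min(n1, m1)
  probs <- stats::dhyper(support, m1, m2, n1)
  obs <- stats::dhyper(t$a, m1, m2, n1)
  # relative tolerance guards against ties broken by floating-point noise
  min(1, sum(probs[probs <= obs * (1 + 1e-07)]))
}

#' Pooled-variance two-sample t test
#'
#' Student's t with pooled variance (equal-variance assumption), two-sided,
#' as used for continuous cohort characteristics.
#'
#' @param x,y Numeric vectors, each with at least 2 values.
#' @return List with `statistic`, `df`, `p`.
#' @export
two_sample_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 observations")
  tt <- stats::t.test(x, y, var.equal = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Build a proband-level exposure table from classified variants
#'
#' Counts every proband exactly once; exposure is defined by `qualifier`, a
#' predicate receiving the classified-variant rows of that proband's family
#' and returning a single logical ("carries at least one qualifying
#' variant"). Cases are probands with `proband_affected == "epilepsy"`.
#'
#' @param pedigree A `trio_pedigree`.
#' @param classified An `inheritance_calls`-style data frame (or any data
#'   frame with a `family_id` column).
#' @param qualifier Function of one data frame argument returning `TRUE` /
#'   `FALSE`.
#' @param label Table label.
#' @return A `contingency_table`.
#' @export
build_exposure_table <- function(pedigree, classified, qualifier, label = "") {
  stopifnot(inherits(pedigree, "trio_pedigree"))
  if (any(!pedigree$proband_affected %in% c("epilepsy", "no_epilepsy")))
    stop("every proband needs a group label")
  exposed <- vapply(pedigree$family_id, function(fam) {
    isTRUE(qualifier(classified[classified$family_id == fam, , drop = FALSE]))
  }, logical(1))
  case <- pedigree$proband_affected == "epilepsy"
  contingency_table(sum(case & exposed), sum(case & !exposed),
                    sum(!case & exposed), sum(!case & !exposed), label = label)
}

#' Full burden statistics for a 2x2 exposure table
#'
#' Combines the cross-product odds ratio, the exact conditional 95%
#' confidence interval ([exact_or_ci()]), Pearson chi-square and Fisher exact
#' p-values; the conditional maximum-likelihood odds ratio is recorded in
#' `method_notes`.
#'
#' @param t A `contingency_table`.
#' @param ci_level Confidence level (default 0.95).
#' @return List of class `burden_result`.
#' @export
burden_result <- function(t, ci_level = 0.95) {
  or <- odds_ratio(t)
  # a table with an empty margin has no defined OR interval
  ci <- tryCatch(exact_or_ci(t, level = ci_level),
                 error = function(e) c(NA_real_, NA_real_))
  chi <- pearson_chi_square(t)
  structure(list(
    table = t, odds_ratio = as.numeric(or), ci_low = ci[1], ci_high = ci[2],
    ci_level = ci_level, chi2_stat = chi$statistic, chi2_p = chi$p,
    fisher_p = fisher_exact(t),
    method_notes = sprintf(
      "exact conditional CI (noncentral hypergeometric inversion); conditional MLE OR = %.4g",
      conditional_mle_or(t))), class = "burden_result")
}

#' @export
print.burden_result <- function(x, ...) {
  print(x$table)
  cat(sprintf("OR %.3g (%d%% CI %.3g-%.3g); chi2 %.3f p = %.3g; Fisher p = %.3g\n",
              x$odds_ratio, round(100 * x$ci_level), x$ci_low, x$ci_high,
              ifelse(is.na(x$chi2_stat), NaN, x$chi2_stat), x$chi2_p,
              x$fisher_p))
  invisible(x)
}
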