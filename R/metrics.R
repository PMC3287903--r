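# Summary quantities of the two-stage analysis: estimated power,
# conditional/unconditional means, relative selection bias, the
# attenuation factor gamma_TC, and an analytic truncated-normal oracle
# for the winner's curse under the normal approximation.

#' Attenuation factor between causal-SNP and tag-SNP additive effects
#'
#' Under an additive model with a causal effect `beta` per minor allele,
#' the expected slope of the trait regressed on the tag SNP is
#' `gamma_tc * beta`, where
#' `gamma_tc = rho * sqrt(p_C (1 - p_C) / (p_T (1 - p_T)))`
#' is the regression-attenuation factor induced by incomplete linkage
#' disequilibrium.  It is 0 when tag and causal SNP are uncorrelated and
#' 1 when the tag SNP is the causal SNP itself.
#'
#' @param p_t Tag SNP MAF in (0, 0.5].
#' @param p_c Causal SNP MAF in (0, 0.5].
#' @param rho Haplotype-level allelic correlation, feasible under
#'   [rho_max()].
#' @return The dimensionless attenuation factor.
#' @export
gamma_tc <- function(p_t, p_c, rho) {
  spec <- ld_pair_spec(p_t, p_c, rho)   # validates feasibility
  spec$rho * sqrt(p_c * (1 - p_c) / (p_t * (1 - p_t)))
}

#' Estimated power of the stage-1 tag-SNP test
#'
#' The proportion of valid replicate data sets in which the stage-1 tag
#' test is significant under the selection rule.
#'
#' @param records Replicate records `data.frame` (from [run_scenario()]),
#'   with logical columns `valid` and `selected`.
#' @return A fraction in `[0, 1]`.
#' @export
estimated_power <- function(records) {
  v <- records[records$valid, , drop = FALSE]
  if (nrow(v) == 0L) stop("no valid replicate records", call. = FALSE)
  mean(v$selected)
}

#' Conditional/unconditional means and relative selection bias
#'
#' Computes the mean effect estimate over all valid replicates and over
#' the replicates selected at stage 1, and the relative bias
#' `100 * (mean_selected - mean_all) / mean_all` in percent.  The ratio is
#' reported as `NA` (undefined) when no replicate was selected or when
#' `|mean_all|` falls below a stability floor (a small multiple of the
#' pooled estimate SD), in which case both means are still reported.
#'
#' @param records Replicate records `data.frame`.
#' @param which Which stage's estimate to summarize: `"tag"`, `"causal"`
#'   or `"lambda"`.
#' @param stability_floor Multiplier `k` such that the relative bias is
#'   undefined when `|mean_all| <= k * sd(estimates)`; default `1e-3`.
#' @param magnitude Logical; if `TRUE` summarize `|estimate|` instead of
#'   the signed estimate (useful for sign-unstable null configurations).
#' @return A list of class `"bias_summary"`: `mean_all`, `mean_selected`,
#'   `relative_bias_pct`, `estimated_power`, `n_all`, `n_selected`.
#' @export
bias_summary <- function(records, which = c("tag", "causal", "lambda"),
                         stability_floor = 1e-3, magnitude = FALSE) {
  which <- match.arg(which)
  col <- paste0(which, "_estimate")
  if (!col %in% names(records)) {
    stop(sprintf("records carry no `%s` column", col), call. = FALSE)
  }
  v <- records[records$valid & !is.na(records[[col]]), , drop = FALSE]
  if (nrow(v) == 0L) stop("no valid replicate records", call. = FALSE)
  est <- v[[col]]
  if (magnitude) est <- abs(est)
  mean_all <- mean(est)
  n_sel <- sum(v$selected)
  mean_sel <- if (n_sel > 0) mean(est[v$selected]) else NA_real_
  floor <- stability_floor * stats::sd(est)
  rel <- if (n_sel > 0 && is.finite(floor) && abs(mean_all) > floor) {
    100 * (mean_sel - mean_all) / mean_all
  } else {
    NA_real_
  }
  structure(list(which = which, mean_all = mean_all, mean_selected = mean_sel,
                 relative_bias_pct = rel,
                 estimated_power = mean(v$selected),
                 n_all = nrow(v), n_selected = n_sel),
            class = "bias_summary")
}

#' @export
print.bias_summary <- function(x, ...) {
  cat(sprintf("%s estimate: mean over all %d replicates = %.3f; over %d selected = %s\n",
              x$which, x$n_all, x$mean_all,
              x$n_selected,
              ifelse(is.na(x$mean_selected), "undefined",
                     sprintf("%.3f", x$mean_selected))))
  cat(sprintf("  estimated power = %.3f; relative bias = %s\n",
              x$estimated_power,
              ifelse(is.na(x$relative_bias_pct), "undefined",
                     sprintf("%.1f%%", x$relative_bias_pct))))
  invisible(x)
}

#' Correlation between the tag genotype and the collapsing score
#'
#' Sample Pearson correlation between the tag SNP minor-allele count and
#' the `r_i/n_i` burden score, over individuals with a defined score.
#'
#' @param tag_genotype Allele-count vector.
#' @param scores Output of [burden_scores()] or a numeric score vector.
#' @return The Pearson correlation.
#' @export
tag_burden_correlation <- function(tag_genotype, scores) {
  s <- if (is.data.frame(scores)) scores$score else as.numeric(scores)
  ok <- !is.na(tag_genotype) & !is.na(s)
  if (sum(ok) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::var(tag_genotype[ok]) == 0 || stats::var(s[ok]) == 0) {
    stop("correlation undefined: constant input", call. = FALSE)
  }
  stats::cor(tag_genotype[ok], s[ok])
}

#' Analytic winner's-curse oracle: truncated-normal conditional mean
#'
#' For a test statistic `Z ~ Normal(mu, 1)` selected at critical value
#' `c`, returns the expected statistic given selection and the selection
#' probability (the analytic power).  Two-sided selection conditions on
#' `|Z| > c`:
#' `E[Z | |Z| > c] = mu + (phi(c - mu) - phi(c + mu)) /
#'                        (Phi(mu - c) + Phi(-mu - c))`;
#' one-sided conditions on `Z > c`.
#'
#' @param mu Standardized (noncentrality) effect.
#' @param c Positive critical value, e.g. `qnorm(1 - alpha/2)`.
#' @param sided `"two_sided"` or `"one_sided_positive"`.
#' @return A list with `mean` (conditional expectation of Z) and `prob`
#'   (selection probability).
#' @export
truncnorm_conditional_mean <- function(mu, c,
                                       sided = c("two_sided",
                                                 "one_sided_positive")) {
  sided <- match.arg(sided)
  stopifnot(is.numeric(mu), is.numeric(c), c > 0)
  if (sided == "two_sided") {
    prob <- stats::pnorm(mu - c) + stats::pnorm(-mu - c)
    m <- mu + (stats::dnorm(c - mu) - stats::dnorm(c + mu)) / prob
  } else {
    prob <- stats::pnorm(mu - c)
    m <- mu + stats::dnorm(c - mu) / prob
  }
  list(mean = m, prob = prob)
}
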