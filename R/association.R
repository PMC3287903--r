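# Stage-1 / stage-2 estimation: single-SNP additive regressions and the
# r_i/n_i rare-variant collapsing regression.  Fits are delegated to
# stats::lm / stats::glm; what this module owns is the additive contract
# (estimate = coefficient on the allele count or burden score), complete-
# case handling, and explicit degenerate-design / separation errors.

effect_estimate <- function(estimate, std_error, statistic, p_value, n_used) {
  structure(list(estimate = estimate, std_error = std_error,
                 statistic = statistic, p_value = p_value, n_used = n_used),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("effect estimate: %.4g (SE %.4g), Wald stat %.3f, p = %.3g, n = %d\n",
              x$estimate, x$std_error, x$statistic, x$p_value, x$n_used))
  invisible(x)
}

fit_additive <- function(x, y, covariates = NULL,
                         kind = c("quantitative", "binary"), xname = "g") {
  kind <- match.arg(kind)
  if (length(x) != length(y)) {
    stop("predictor and trait lengths differ", call. = FALSE)
  }
  df <- data.frame(.y = y, .g = x)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == length(y))
    df <- cbind(df, covariates)
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  n_par <- ncol(df)   # intercept + genotype + covariates
  if (nrow(df) < n_par + 3L) {
    stop("too few complete observations for the regression", call. = FALSE)
  }
  if (stats::var(df$.g) == 0) {
    stop(sprintf("degenerate design: %s is constant in the complete cases",
                 xname), call. = FALSE)
  }
  if (kind == "quantitative") {
    fit <- stats::lm(.y ~ ., data = df)
    co <- summary(fit)$coefficients[".g", ]
  } else {
    if (length(unique(df$.y)) < 2L) {
      stop("both outcome classes must be present", call. = FALSE)
    }
    fit <- suppressWarnings(stats::glm(.y ~ ., data = df,
                                       family = stats::binomial()))
    eps <- 1e-8
    if (!fit$converged ||
        all(fit$fitted.values > 1 - eps | fit$fitted.values < eps)) {
      stop("logistic fit did not converge: complete or quasi-complete separation",
           call. = FALSE)
    }
    co <- summary(fit)$coefficients[".g", ]
  }
  effect_estimate(estimate = unname(co[1]), std_error = unname(co[2]),
                  statistic = unname(co[3]), p_value = unname(co[4]),
                  n_used = nrow(df))
}

#' Additive linear regression at a single SNP
#'
#' Ordinary least squares of a quantitative trait on the minor-allele
#' count (plus an intercept and optional covariates).  The reported
#' estimate is the genotype coefficient: trait units per minor allele.
#' Individuals with any missing value are dropped (complete-case).
#'
#' @param genotype Allele-count vector in `{0, 1, 2, NA}`.
#' @param trait Continuous trait vector.
#' @param covariates Optional `data.frame`/matrix of adjustment covariates.
#' @return An `effect_estimate`: `estimate`, `std_error`, Wald `statistic`,
#'   two-sided `p_value`, `n_used`.
#' @export
additive_linear <- function(genotype, trait, covariates = NULL) {
  fit_additive(genotype, trait, covariates, "quantitative",
               xname = "the genotype column")
}

#' Additive logistic regression at a single SNP
#'
#' Maximum-likelihood logistic regression of disease status on the
#' minor-allele count with an intercept; the estimate is the log-odds per
#' minor allele.  Complete or quasi-complete separation is reported as an
#' error, never returned as a finite estimate.
#'
#' @param genotype Allele-count vector in `{0, 1, 2, NA}`.
#' @param status Binary 0/1 vector with both classes present.
#' @param covariates Optional adjustment covariates.
#' @return An `effect_estimate` (log-odds scale).
#' @export
additive_logistic <- function(genotype, status, covariates = NULL) {
  fit_additive(genotype, status, covariates, "binary",
               xname = "the genotype column")
}

#' Per-individual rare-variant collapsing (burden) scores
#'
#' For each individual, `r_i` counts the rare SNPs at which the individual
#' carries at least one minor allele (a carrier indicator per locus, not an
#' allele count), `n_i` counts the rare SNPs with a non-missing genotype,
#' and the score is `r_i / n_i`.  Individuals with `n_i = 0` get an `NA`
#' score and are excluded downstream.
#'
#' @param rare_genotypes `n x L` allele-count matrix (`NA` = missing),
#'   `L >= 1`.
#' @param carrier Logical; `TRUE` (default) uses the carrier indicator per
#'   locus, `FALSE` an allele-count variant (`r_i` = total minor alleles,
#'   score then in `[0, 2]`).
#' @return A `data.frame` with columns `score`, `r_i`, `n_i`.
#' @export
burden_scores <- function(rare_genotypes, carrier = TRUE) {
  rare_genotypes <- as.matrix(rare_genotypes)
  if (ncol(rare_genotypes) < 1L) {
    stop("at least one rare locus is required", call. = FALSE)
  }
  n_i <- rowSums(!is.na(rare_genotypes))
  r_i <- if (carrier) {
    rowSums(rare_genotypes >= 1L, na.rm = TRUE)
  } else {
    rowSums(rare_genotypes, na.rm = TRUE)
  }
  score <- ifelse(n_i > 0, r_i / n_i, NA_real_)
  data.frame(score = score, r_i = r_i, n_i = n_i)
}

#' Collapsing (burden) regression of a trait on r_i/n_i
#'
#' Regression of the trait on the per-individual collapsing score; the
#' estimate is the burden effect `lambda`: the genetic effect for an
#' individual carrying the rare allele at each of its `n_i` genotyped rare
#' SNPs.  Linear for quantitative traits, logistic for binary status.
#'
#' @param scores Output of [burden_scores()] (or a numeric score vector).
#' @param trait Trait vector.
#' @param covariates Optional adjustment covariates.
#' @param trait_kind `"quantitative"` or `"binary"`.
#' @return An `effect_estimate` for `lambda`.
#' @export
collapsing_regression <- function(scores, trait, covariates = NULL,
                                  trait_kind = c("quantitative", "binary")) {
  trait_kind <- match.arg(trait_kind)
  s <- if (is.data.frame(scores)) scores$score else as.numeric(scores)
  fit_additive(s, trait, covariates, trait_kind, xname = "the burden score")
}
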