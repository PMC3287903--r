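# Synthetic genotype / covariate / trait generator.  Genotypes are formed
# under Hardy-Weinberg equilibrium as the sum of two independent haplotypes,
# so the genotype-level Pearson correlation between two loci equals the
# haplotype-level allelic correlation that the specs parameterize.

derive_seed <- function(master_seed, replicate_index) {
  # deterministic per-replicate seed, kept inside the 32-bit integer range
  (as.double(master_seed) %% 2147483647 + 999983 * replicate_index) %% 2147483629 + 1
}

#' Sample genotypes for a correlated tag-causal SNP pair
#'
#' Each individual is composed of two haplotypes drawn independently from
#' the table returned by [haplotype_freqs()]; the genotype is the
#' minor-allele count (0/1/2, additive coding).  The empirical genotype
#' correlation converges to `spec$rho` as `n` grows.
#'
#' @param spec An [ld_pair_spec()].
#' @param n Number of individuals (>= 1).
#' @param seed Integer seed; identical seeds give identical matrices.
#' @return An `n x 2` integer matrix with columns `tag` and `causal`.
#' @export
sample_pair_genotypes <- function(spec, n, seed) {
  stopifnot(inherits(spec, "ld_pair_spec"))
  check_n(n)
  f <- haplotype_freqs(spec)
  set.seed(seed)
  # haplotype index 1..4 = (mm, mM, Mm, MM); two draws per individual
  h <- matrix(sample.int(4L, 2L * n, replace = TRUE, prob = f), ncol = 2L)
  tag_allele <- matrix(as.integer(h <= 2L), ncol = 2L)          # minor at tag
  causal_allele <- matrix(as.integer(h == 1L | h == 3L), ncol = 2L)
  g <- cbind(tag = rowSums(tag_allele), causal = rowSums(causal_allele))
  storage.mode(g) <- "integer"
  g
}

#' Sample genotypes for a gene: tag SNP plus multiple rare causal SNPs
#'
#' Haplotypes are generated with the tag allele drawn first and each rare
#' allele drawn conditionally on the tag allele, the rare loci being
#' mutually independent given the tag allele.  Each tag-rare pair thereby
#' attains its target correlation from the spec.  Genotypes are formed
#' under HWE as in [sample_pair_genotypes()].
#'
#' @param spec A [gene_spec()].
#' @param n Number of individuals (>= 1).
#' @param seed Integer seed.
#' @return An `n x (1 + L)` integer matrix, columns `tag`, `rare1` ... `rareL`.
#' @export
sample_gene_genotypes <- function(spec, n, seed) {
  stopifnot(inherits(spec, "gene_spec"))
  check_n(n)
  L <- length(spec$rare_mafs)
  p_t <- spec$tag_maf
  # conditional minor-allele probabilities for each rare locus given the tag
  cond <- lapply(seq_len(L), function(j) {
    f <- haplotype_freqs(ld_pair_spec(p_t, spec$rare_mafs[j],
                                      spec$tag_rare_rho[j]))
    c(given_major = f[["Mm"]] / (1 - p_t), given_minor = f[["mm"]] / p_t)
  })
  set.seed(seed)
  hap_tag <- matrix(stats::rbinom(2L * n, 1L, p_t), ncol = 2L)
  g <- matrix(0L, nrow = n, ncol = 1L + L,
              dimnames = list(NULL, c("tag", paste0("rare", seq_len(L)))))
  g[, 1L] <- rowSums(hap_tag)
  for (j in seq_len(L)) {
    p_cond <- ifelse(hap_tag == 1L, cond[[j]][["given_minor"]],
                     cond[[j]][["given_major"]])
    hap_rare <- matrix(stats::rbinom(2L * n, 1L, p_cond), ncol = 2L)
    g[, 1L + j] <- rowSums(hap_rare)
  }
  storage.mode(g) <- "integer"
  g
}

check_n <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1) {
    stop("`n` must be a positive number of individuals", call. = FALSE)
  }
  invisible(n)
}

#' Simulate Age and Smoking covariates
#'
#' Stand-in covariates for the Q1-like trait model: Age uniform on a
#' configurable range (years), Smoking Bernoulli.
#'
#' @param n Number of individuals (>= 1).
#' @param seed Integer seed.
#' @param age_range Length-2 numeric, default `c(20, 80)` years.
#' @param smoking_prob Smoking probability, default 0.3.
#' @return A `data.frame` with numeric columns `age` and `smoking`.
#' @export
simulate_covariates <- function(n, seed, age_range = c(20, 80),
                                smoking_prob = 0.3) {
  check_n(n)
  stopifnot(length(age_range) == 2L, age_range[1] < age_range[2],
            smoking_prob >= 0, smoking_prob <= 1)
  set.seed(seed)
  data.frame(age = stats::runif(n, age_range[1], age_range[2]),
             smoking = stats::rbinom(n, 1L, smoking_prob))
}

#' Define the trait-generating model
#'
#' Three trait kinds mirror a quantitative trait with covariates (Q1-like),
#' a quantitative trait without covariates (Q2-like), and a binary disease
#' status fit by logistic regression.  Exactly one of `beta` (per-causal-SNP
#' additive effect) or `lambda` (burden-model effect on the `r_i/n_i`
#' collapsing score) drives the genetic contribution.
#'
#' @param kind One of `"quantitative_with_covariates"`, `"quantitative"`,
#'   `"binary"`.
#' @param beta Additive effect per minor allele at each causal SNP (trait
#'   units, or log-odds for the binary kind); scalar or one value per causal
#'   locus.  `NULL` when simulating under the burden model.
#' @param lambda Burden-model effect per unit of `r_i/n_i` (the effect for a
#'   carrier at every genotyped rare SNP); `NULL` when using `beta`.
#' @param sigma Residual standard deviation, quantitative kinds only (> 0).
#' @param intercept Baseline trait mean, or baseline log-odds for the
#'   binary kind.
#' @param covariate_effects Named numeric `c(age = ..., smoking = ...)`,
#'   used by the `quantitative_with_covariates` kind only.
#' @return An object of class `"trait_model"`.
#' @export
trait_model <- function(kind = c("quantitative", "quantitative_with_covariates",
                                 "binary"),
                        beta = NULL, lambda = NULL, sigma = 1, intercept = 0,
                        covariate_effects = c(age = 0.05, smoking = 0.5)) {
  kind <- match.arg(kind)
  if (is.null(beta) == is.null(lambda)) {
    stop("exactly one of `beta` or `lambda` must be set", call. = FALSE)
  }
  if (kind != "binary" && (!is.numeric(sigma) || sigma <= 0)) {
    stop("`sigma` must be > 0 for quantitative traits", call. = FALSE)
  }
  if (kind == "quantitative_with_covariates" &&
      !all(c("age", "smoking") %in% names(covariate_effects))) {
    stop("`covariate_effects` must name `age` and `smoking`", call. = FALSE)
  }
  structure(list(kind = kind, beta = beta, lambda = lambda, sigma = sigma,
                 intercept = intercept, covariate_effects = covariate_effects),
            class = "trait_model")
}

#' Assemble one simulated data set
#'
#' Container for a replicate: genotype matrix (additive 0/1/2 coding,
#' `NA` = missing), per-column locus roles, covariates, and optionally a
#' trait vector.
#'
#' @param genotypes `n x m` matrix of minor-allele counts in `{0, 1, 2, NA}`.
#' @param locus_roles Character vector, one of `"tag"`, `"causal"`,
#'   `"rare_causal"` per column.
#' @param covariates `data.frame` with columns `age` and `smoking`, or `NULL`.
#' @param trait Length-`n` vector (continuous, or 0/1 disease status), or
#'   `NULL` before trait simulation.
#' @return An object of class `"replicate_data"`.
#' @export
replicate_data <- function(genotypes, locus_roles, covariates = NULL,
                           trait = NULL) {
  stopifnot(is.matrix(genotypes))
  vals <- genotypes[!is.na(genotypes)]
  if (!all(vals %in% c(0, 1, 2))) {
    stop("non-missing genotype entries must be in {0, 1, 2}", call. = FALSE)
  }
  if (length(locus_roles) != ncol(genotypes) ||
      !all(locus_roles %in% c("tag", "causal", "rare_causal"))) {
    stop("`locus_roles` must label every genotype column as tag, causal or rare_causal",
         call. = FALSE)
  }
  if (!is.null(trait) && length(trait) != nrow(genotypes)) {
    stop("`trait` length must equal the number of individuals", call. = FALSE)
  }
  structure(list(genotypes = genotypes, locus_roles = locus_roles,
                 covariates = covariates, trait = trait),
            class = "replicate_data")
}

#' Simulate a trait on top of a replicate's genotypes and covariates
#'
#' Quantitative kinds: `trait = intercept + covariate terms + genetic term
#' + N(0, sigma^2)` noise, where the genetic term is `sum(beta_j * G_j)`
#' over causal columns, or `lambda * r_i/n_i` over rare causal columns
#' under the burden model.  Binary kind: Bernoulli with
#' `logit(p) = intercept + genetic term`.
#'
#' @param model A [trait_model()].
#' @param data A [replicate_data()] (its `trait` slot is ignored).
#' @param seed Integer seed.
#' @return The simulated trait vector.
#' @export
simulate_trait <- function(model, data, seed) {
  stopifnot(inherits(model, "trait_model"), inherits(data, "replicate_data"))
  n <- nrow(data$genotypes)
  if (!is.null(model$beta)) {
    causal_cols <- which(data$locus_roles %in% c("causal", "rare_causal"))
    if (length(causal_cols) == 0L) {
      stop("`beta` set but the replicate has no causal columns", call. = FALSE)
    }
    beta <- rep_len(model$beta, length(causal_cols))
    gmat <- data$genotypes[, causal_cols, drop = FALSE]
    gmat[is.na(gmat)] <- 0L     # generation precedes masking in the pipeline
    genetic <- drop(gmat %*% beta)
  } else {
    rare_cols <- which(data$locus_roles == "rare_causal")
    if (length(rare_cols) == 0L) {
      stop("`lambda` requires rare causal columns", call. = FALSE)
    }
    sc <- burden_scores(data$genotypes[, rare_cols, drop = FALSE])
    genetic <- model$lambda * ifelse(is.na(sc$score), 0, sc$score)
  }
  set.seed(seed)
  if (model$kind == "binary") {
    p <- stats::plogis(model$intercept + genetic)
    return(stats::rbinom(n, 1L, p))
  }
  cov_term <- 0
  if (model$kind == "quantitative_with_covariates") {
    if (is.null(data$covariates)) {
      stop("Q1-like trait requires covariates in the replicate", call. = FALSE)
    }
    ce <- model$covariate_effects
    cov_term <- ce[["age"]] * data$covariates$age +
      ce[["smoking"]] * data$covariates$smoking
  }
  model$intercept + cov_term + genetic + stats::rnorm(n, 0, model$sigma)
}

#' Mask genotype entries at random to emulate missing data
#'
#' Sets each genotype entry to `NA` independently with probability `rate`;
#' exercises the `n_i` denominator of the collapsing statistic.
#'
#' @param genotypes Genotype matrix.
#' @param rate Missingness rate in `[0, 1)`.
#' @param seed Integer seed.
#' @return The masked matrix.
#' @export
mask_genotypes <- function(genotypes, rate, seed) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(genotypes)
  set.seed(seed)
  mask <- matrix(stats::runif(length(genotypes)) < rate,
                 nrow = nrow(genotypes))
  genotypes[mask] <- NA
  genotypes
}
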