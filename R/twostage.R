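# The replicate loop of the two-stage design: simulate a data set, test
# the tag SNP at stage 1, apply the selection rule, and record stage-2
# estimates at the causal SNP and/or the rare-variant collapsing
# statistic.  Stage-2 estimates are computed for every replicate and only
# filtered at summary time, so both conditional (selected) and
# unconditional summaries are available from the same records.

trait_fit_kind <- function(model) {
  if (model$kind == "binary") "binary" else "quantitative"
}

stage_covariates <- function(config, covs) {
  # the covariate set is a property of the trait (Q1-like), used in both
  # stage-1 and stage-2 models
  if (config$trait$kind == "quantitative_with_covariates") covs else NULL
}

select_record <- function(estimate, p_two_sided, rule) {
  if (rule$sided == "two_sided") {
    p_two_sided < rule$alpha
  } else {
    estimate > 0 & p_two_sided < 2 * rule$alpha
  }
}

#' Simulate one replicate data set from a run configuration
#'
#' Generates genotypes for the configured locus structure, covariates,
#' and the trait, then applies the configured missingness mask.  The
#' per-replicate seed is derived deterministically from the master seed
#' and the replicate index, so any replicate is reproducible in
#' isolation.
#'
#' @param config A [run_config()].
#' @param replicate_index Replicate number (1-based).
#' @return A [replicate_data()].
#' @export
simulate_replicate <- function(config, replicate_index) {
  stopifnot(inherits(config, "run_config"))
  base <- derive_seed(config$seed, replicate_index)
  if (config$scenario == "S1") {
    g <- sample_pair_genotypes(config$pair, config$n, seed = base + 1)
    roles <- c("tag", "causal")
  } else {
    g <- sample_gene_genotypes(config$gene, config$n, seed = base + 1)
    roles <- c("tag", rep("rare_causal", length(config$gene$rare_mafs)))
  }
  covs <- simulate_covariates(config$n, seed = base + 2,
                              age_range = config$covariates$age_range,
                              smoking_prob = config$covariates$smoking_prob)
  data <- replicate_data(g, roles, covariates = covs)
  data$trait <- simulate_trait(config$trait, data, seed = base + 3)
  if (config$missing_rate > 0) {
    data$genotypes <- mask_genotypes(data$genotypes, config$missing_rate,
                                     seed = base + 4)
  }
  data
}

burden_columns <- function(config, data) {
  cols <- which(data$locus_roles == "rare_causal")
  # a low-MAF tag SNP belongs to the gene's rare set unless explicitly
  # excluded from the collapsing statistic (scenario 3)
  if (!is.null(config$gene) && config$gene$tag_maf < 0.05 &&
      !config$gene$exclude_tag_from_burden) {
    cols <- c(which(data$locus_roles == "tag"), cols)
  }
  cols
}

empty_record <- function(replicate_index) {
  data.frame(replicate = as.integer(replicate_index), valid = TRUE,
             invalid_reason = NA_character_, selected = NA,
             tag_estimate = NA_real_, tag_se = NA_real_,
             tag_stat = NA_real_, tag_p = NA_real_, tag_n = NA_integer_,
             causal_estimate = NA_real_, causal_se = NA_real_,
             causal_p = NA_real_,
             lambda_estimate = NA_real_, lambda_se = NA_real_,
             lambda_p = NA_real_,
             tag_burden_cor = NA_real_,
             stringsAsFactors = FALSE)
}

#' Run one replicate of the two-stage analysis
#'
#' Simulates the replicate, fits the stage-1 additive model at the tag
#' SNP, evaluates the selection rule, and fits the configured stage-2
#' model(s): the causal-SNP regression (scenario S1) or the `r_i/n_i`
#' collapsing regression (S2/S3).  Degenerate replicates (monomorphic
#' tag, no rare carriers, separation) are flagged invalid with a reason
#' rather than aborting the run.
#'
#' @param config A [run_config()].
#' @param replicate_index Replicate number (1-based).
#' @return A one-row `data.frame` record.
#' @export
run_replicate <- function(config, replicate_index) {
  rec <- empty_record(replicate_index)
  kind <- trait_fit_kind(config$trait)
  out <- tryCatch({
    data <- simulate_replicate(config, replicate_index)
    covs <- stage_covariates(config, data$covariates)
    tag_col <- which(data$locus_roles == "tag")
    tag_fit <- fit_additive(data$genotypes[, tag_col], data$trait, covs, kind,
                            xname = "the tag genotype")
    rec$tag_estimate <- tag_fit$estimate
    rec$tag_se <- tag_fit$std_error
    rec$tag_stat <- tag_fit$statistic
    rec$tag_p <- tag_fit$p_value
    rec$tag_n <- tag_fit$n_used
    rec$selected <- select_record(tag_fit$estimate, tag_fit$p_value,
                                  config$selection)
    if (config$scenario == "S1") {
      causal_fit <- fit_additive(data$genotypes[, 2L], data$trait, covs, kind,
                                 xname = "the causal genotype")
      rec$causal_estimate <- causal_fit$estimate
      rec$causal_se <- causal_fit$std_error
      rec$causal_p <- causal_fit$p_value
    } else {
      cols <- burden_columns(config, data)
      sc <- burden_scores(data$genotypes[, cols, drop = FALSE])
      lam <- collapsing_regression(sc, data$trait, covs, kind)
      rec$lambda_estimate <- lam$estimate
      rec$lambda_se <- lam$std_error
      rec$lambda_p <- lam$p_value
      rec$tag_burden_cor <- tag_burden_correlation(
        data$genotypes[, tag_col], sc)
    }
    rec
  }, error = function(e) {
    rec$valid <- FALSE
    rec$invalid_reason <- conditionMessage(e)
    rec$selected <- FALSE
    rec
  })
  out
}

#' Run a full scenario: all replicates plus derived summaries
#'
#' Executes [run_replicate()] for every configured replicate and collects
#' the records into a `scenario_result`, logging the count of invalid
#' (degenerate) replicates, which are excluded from all summaries.
#'
#' @param config A [run_config()].
#' @return An object of class `"scenario_result"` with elements `scenario`,
#'   `config`, `records` (one row per replicate), `n_invalid`, and
#'   `tag_burden_correlation` (mean per-replicate correlation, S2/S3).
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "run_config"))
  records <- do.call(rbind, lapply(seq_len(config$replicates),
                                   function(i) run_replicate(config, i)))
  structure(list(scenario = config$scenario, config = config,
                 records = records,
                 n_invalid = sum(!records$valid),
                 tag_burden_correlation =
                   if (config$scenario == "S1") NA_real_ else
                     mean(records$tag_burden_cor[records$valid])),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("scenario %s: %d replicates (%d invalid), estimated power %.3f\n",
              x$scenario, nrow(x$records), x$n_invalid,
              estimated_power(x$records)))
  if (!is.na(x$tag_burden_correlation)) {
    cat(sprintf("  mean tag-burden correlation: %.3f\n",
                x$tag_burden_correlation))
  }
  invisible(x)
}

#' Re-apply a selection rule to existing replicate records
#'
#' Selection depends only on the recorded stage-1 estimate and two-sided
#' p-value, so records from a single run can be re-thresholded at other
#' significance levels without re-simulating — used by the calibration
#' ladder and by power/bias curves across thresholds.
#'
#' @param records Replicate records `data.frame`.
#' @param rule A [selection_rule()].
#' @return The records with the `selected` column recomputed.
#' @export
apply_selection <- function(records, rule) {
  stopifnot(inherits(rule, "selection_rule"))
  sel <- select_record(records$tag_estimate, records$tag_p, rule)
  records$selected <- ifelse(records$valid, sel, FALSE)
  records
}

#' Choose the stage-1 threshold so that estimated power stays low
#'
#' Walks a discrete ladder of significance thresholds (default 0.05,
#' 0.01, 0.001) and returns the largest threshold whose estimated power
#' over a pilot replicate set is below `power_ceiling`.  Errors, listing
#' the pilot powers, if even the strictest ladder threshold gives power
#' at or above the ceiling.
#'
#' @param config A [run_config()]; its selection sidedness is kept.
#' @param power_ceiling Power ceiling in (0, 1); default 0.2.
#' @param ladder Decreasing vector of candidate thresholds.
#' @param pilot_replicates Number of pilot replicates (default: the
#'   configured replicate count).
#' @return A list with `alpha` (chosen threshold) and `pilot_powers`
#'   (named vector of pilot power at every ladder threshold).
#' @export
calibrate_alpha <- function(config, power_ceiling = 0.2,
                            ladder = c(0.05, 0.01, 0.001),
                            pilot_replicates = NULL) {
  stopifnot(inherits(config, "run_config"),
            power_ceiling > 0, power_ceiling < 1)
  ladder <- sort(ladder, decreasing = TRUE)
  if (!is.null(pilot_replicates)) {
    config$replicates <- as.integer(pilot_replicates)
  }
  pilot <- run_scenario(config)
  powers <- vapply(ladder, function(a) {
    estimated_power(apply_selection(pilot$records,
                                    selection_rule(a, config$selection$sided)))
  }, numeric(1))
  names(powers) <- format(ladder)
  ok <- which(powers < power_ceiling)
  if (length(ok) == 0L) {
    stop(sprintf(
      "no ladder threshold achieves power below %.2g; pilot powers: %s",
      power_ceiling,
      paste(sprintf("alpha %s -> %.3f", names(powers), powers),
            collapse = "; ")), call. = FALSE)
  }
  list(alpha = ladder[ok[1L]], pilot_powers = powers)
}
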