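# Run configuration: a fully serializable description of one scenario run.
# A run is reproducible from its persisted config + seed alone.

#' Stage-1 selection rule
#'
#' @param alpha Significance threshold in (0, 1).
#' @param sided `"two_sided"`, or `"one_sided_positive"` which selects on a
#'   sign-consistent (positive) estimate with two-sided p < 2 * alpha —
#'   equivalent to a one-sided test at level `alpha`.
#' @return An object of class `"selection_rule"`.
#' @export
selection_rule <- function(alpha = 0.05,
                           sided = c("two_sided", "one_sided_positive")) {
  sided <- match.arg(sided)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  }
  structure(list(alpha = alpha, sided = sided), class = "selection_rule")
}

#' Build and validate a scenario run configuration
#'
#' Assembles the generating model for one two-stage scenario run and
#' validates every invariant eagerly: MAF ranges, LD feasibility bounds,
#' and the per-scenario constraints (S1 needs a tag-causal `pair`; S2 a
#' `gene` with a common tag, MAF > 0.05; S3 a `gene` with tag MAF in
#' [0.01, 0.05] and `exclude_tag_from_burden = TRUE`).
#'
#' @param scenario `"S1"`, `"S2"` or `"S3"`.
#' @param n Population size per replicate.
#' @param replicates Number of replicate data sets (default 200).
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @param pair [ld_pair_spec()] or an equivalent named list (S1).
#' @param gene [gene_spec()] or an equivalent named list (S2/S3).
#' @param trait [trait_model()] or an equivalent named list.
#' @param selection [selection_rule()] or an equivalent named list.
#' @param covariates List with `age_range` and `smoking_prob`.
#' @param missing_rate Per-entry genotype missingness rate in [0, 1).
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(scenario = c("S1", "S2", "S3"), n, replicates = 200L,
                       seed = 1L, pair = NULL, gene = NULL, trait,
                       selection = selection_rule(),
                       covariates = list(age_range = c(20, 80),
                                         smoking_prob = 0.3),
                       missing_rate = 0) {
  scenario <- match.arg(scenario)
  check_n(n)
  if (!is.numeric(replicates) || replicates < 1) {
    stop("`replicates` must be >= 1", call. = FALSE)
  }
  if (!is.numeric(missing_rate) || missing_rate < 0 || missing_rate >= 1) {
    stop("`missing_rate` must be in [0, 1)", call. = FALSE)
  }
  if (is.list(pair) && !inherits(pair, "ld_pair_spec")) {
    pair <- do.call(ld_pair_spec, pair)
  }
  if (is.list(gene) && !inherits(gene, "gene_spec")) {
    gene <- do.call(gene_spec, gene)
  }
  if (is.list(trait) && !inherits(trait, "trait_model")) {
    trait <- do.call(trait_model, trait)
  }
  if (is.list(selection) && !inherits(selection, "selection_rule")) {
    selection <- do.call(selection_rule, selection)
  }
  stopifnot(inherits(trait, "trait_model"), inherits(selection, "selection_rule"))
  if (scenario == "S1") {
    if (is.null(pair)) stop("scenario S1 requires a `pair` spec", call. = FALSE)
  } else {
    if (is.null(gene)) {
      stop(sprintf("scenario %s requires a `gene` spec", scenario), call. = FALSE)
    }
    if (scenario == "S2" && gene$tag_maf <= 0.05) {
      stop("scenario S2 requires a common tag SNP (MAF > 0.05)", call. = FALSE)
    }
    if (scenario == "S3") {
      if (gene$tag_maf < 0.01 || gene$tag_maf > 0.05) {
        stop("scenario S3 requires a tag SNP with MAF in [0.01, 0.05]",
             call. = FALSE)
      }
      if (!gene$exclude_tag_from_burden) {
        stop("scenario S3 requires `exclude_tag_from_burden = TRUE`",
             call. = FALSE)
      }
    }
  }
  if (!is.list(covariates) ||
      !all(names(covariates) %in% c("age_range", "smoking_prob"))) {
    stop("`covariates` must be a list with `age_range` and `smoking_prob`",
         call. = FALSE)
  }
  covariates$age_range <- as.numeric(covariates$age_range %||% c(20, 80))
  covariates$smoking_prob <- as.numeric(covariates$smoking_prob %||% 0.3)
  structure(list(scenario = scenario, n = as.integer(n),
                 replicates = as.integer(replicates), seed = as.integer(seed),
                 pair = pair, gene = gene, trait = trait,
                 selection = selection, covariates = covariates,
                 missing_rate = as.numeric(missing_rate)),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("two-stage run config: scenario %s, n = %d, %d replicates, seed %d\n",
              x$scenario, x$n, x$replicates, x$seed))
  cat(sprintf("  trait: %s; selection: alpha = %g (%s); missing rate %g\n",
              x$trait$kind, x$selection$alpha, x$selection$sided,
              x$missing_rate))
  invisible(x)
}

config_schema <- list(
  top = c("scenario", "n", "replicates", "seed", "pair", "gene", "trait",
          "selection", "covariates", "missing_rate"),
  pair = c("p_t", "p_c", "rho"),
  gene = c("tag_maf", "rare_mafs", "tag_rare_rho", "exclude_tag_from_burden"),
  trait = c("kind", "beta", "lambda", "sigma", "intercept",
            "covariate_effects"),
  selection = c("alpha", "sided"),
  covariates = c("age_range", "smoking_prob")
)

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    stop(sprintf("unknown configuration key(s) in %s: %s", where,
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
}

#' Load a run configuration from YAML or JSON
#'
#' Parses the file (format decided by extension: `.yaml`/`.yml` or
#' `.json`), rejects unknown keys (strict schema, no silent typo
#' absorption), and validates all spec invariants eagerly through
#' [run_config()].
#'
#' @param path Path to the configuration file.
#' @return A validated [run_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  # YAML 1.1 would read a bare `n` key (population size) as boolean FALSE;
  # keep single-letter bool-ish tokens as strings, resolve real booleans
  yaml_bool <- function(x) {
    if (x %in% c("n", "N", "y", "Y")) x
    else tolower(x) %in% c("yes", "true", "on")
  }
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path, handlers = list("bool#yes" = yaml_bool,
                                          "bool#no" = yaml_bool))
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config file must be .yaml, .yml or .json", call. = FALSE)
  }
  check_keys(raw, config_schema$top, "the top level")
  for (sec in c("pair", "gene", "trait", "selection", "covariates")) {
    if (!is.null(raw[[sec]])) {
      check_keys(raw[[sec]], config_schema[[sec]], sprintf("`%s`", sec))
    }
  }
  if (!is.null(raw$trait$covariate_effects)) {
    raw$trait$covariate_effects <- unlist(raw$trait$covariate_effects)
  }
  do.call(run_config, raw)
}

#' Persist a run configuration to YAML or JSON
#'
#' @param config A [run_config()].
#' @param path Destination path (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  plain <- list(scenario = config$scenario, n = config$n,
                replicates = config$replicates, seed = config$seed,
                missing_rate = config$missing_rate)
  if (!is.null(config$pair)) plain$pair <- unclass(config$pair)
  if (!is.null(config$gene)) plain$gene <- unclass(config$gene)
  tr <- unclass(config$trait)
  tr$covariate_effects <- as.list(tr$covariate_effects)
  plain$trait <- tr[!vapply(tr, is.null, logical(1))]
  plain$selection <- unclass(config$selection)
  plain$covariates <- config$covariates
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(plain, path, precision = 15)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  } else {
    stop("config file must be .yaml, .yml or .json", call. = FALSE)
  }
  invisible(path)
}
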