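# File input/output: additive genotype matrices (tab-separated and a
# minimal GT-only VCF dialect), Table-shaped CSV summaries, and
# Figure-style long-format distribution exports.  All outputs are plain
# text and byte-deterministic for a fixed (config, seed).

fmt_num <- function(x, digits) {
  ifelse(is.na(x), "", formatC(x, format = "f", digits = digits))
}

#' Write an additive genotype matrix to disk
#'
#' Two formats: `"matrix"` — tab-separated, a header row of locus IDs,
#' one row per individual, entries in `{0, 1, 2, NA}`; `"vcf"` — a
#' minimal biallelic VCF 4.2 dialect with a GT FORMAT field and one
#' sample column per individual, where the coded (counted) allele is
#' written as ALT.
#'
#' @param genotypes `n x m` matrix of minor-allele counts (`NA` missing).
#' @param path Destination file.
#' @param format `"matrix"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(genotypes, path, format = c("matrix", "vcf")) {
  format <- match.arg(format)
  genotypes <- as.matrix(genotypes)
  ids <- colnames(genotypes)
  if (is.null(ids)) ids <- paste0("snp", seq_len(ncol(genotypes)))
  if (format == "matrix") {
    utils::write.table(genotypes, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = ids, na = "NA")
  } else {
    gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    header <- c("##fileformat=VCFv4.2",
                "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT",
                        sprintf("ind%d", seq_len(nrow(genotypes)))),
                      collapse = "\t"))
    body <- vapply(seq_len(ncol(genotypes)), function(j) {
      g <- genotypes[, j]
      gt <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
      paste(c("1", j, ids[j], "A", "T", ".", ".", ".", "GT", gt),
            collapse = "\t")
    }, character(1))
    writeLines(c(header, body), path)
  }
  invisible(path)
}

#' Read genotypes from VCF or a plain additive matrix file
#'
#' Returns minor-allele counts: after reading, each locus is re-oriented
#' so that the coded allele is the minor allele in-sample (ties at
#' frequency 0.5 keep the alternate allele as coded).  Multiallelic VCF
#' records are skipped with a warning and counted in the metadata.
#'
#' @param path Input file.
#' @param format `"vcf"` or `"matrix"`.
#' @return A list with `genotypes` (`n x m` integer matrix, `NA`
#'   missing), and `loci` (`data.frame` with `id`, in-sample `maf`,
#'   `flipped` — whether the file's coded allele was the major allele),
#'   plus `n_skipped` multiallelic records for VCF input.
#' @export
read_genotypes <- function(path, format = c("matrix", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  n_skipped <- 0L
  if (format == "matrix") {
    df <- utils::read.delim(path, check.names = FALSE,
                            colClasses = "numeric")
    g <- as.matrix(df)
    if (!all(g[!is.na(g)] %in% c(0, 1, 2))) {
      stop("matrix entries must be in {0, 1, 2, NA}", call. = FALSE)
    }
  } else {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    multi <- grepl(",", v@fix[, "ALT"], fixed = TRUE)
    if (any(multi)) {
      n_skipped <- sum(multi)
      warning(sprintf("skipped %d multiallelic VCF record(s)", n_skipped))
      v <- v[!multi, ]
    }
    gt <- vcfR::extract.gt(v, element = "GT")
    alt_count <- function(s) {
      s[is.na(s)] <- "."
      vapply(strsplit(gsub("|", "/", s, fixed = TRUE), "/", fixed = TRUE),
             function(a) {
               if (length(a) == 0L || any(a == ".")) NA_integer_
               else sum(a == "1")
             }, integer(1))
    }
    g <- matrix(alt_count(as.vector(gt)), nrow = nrow(gt))  # loci x samples
    rownames(g) <- v@fix[, "ID"]
    g <- t(g)
  }
  storage.mode(g) <- "integer"
  coded_freq <- colMeans(g, na.rm = TRUE) / 2
  flipped <- !is.na(coded_freq) & coded_freq > 0.5
  if (any(flipped)) {
    g[, flipped] <- 2L - g[, flipped]
  }
  maf <- colMeans(g, na.rm = TRUE) / 2
  list(genotypes = g,
       loci = data.frame(id = colnames(g), maf = maf, flipped = flipped,
                         row.names = NULL),
       n_skipped = n_skipped)
}

result_trait_kind <- function(result) result$config$trait$kind

summary_row <- function(result) {
  rec <- result$records
  tag <- bias_summary(rec, "tag")
  s2_which <- if (result$scenario == "S1") "causal" else "lambda"
  s2 <- bias_summary(rec, s2_which)
  data.frame(
    scenario = result$scenario,
    trait_kind = result_trait_kind(result),
    n = result$config$n,
    replicates = result$config$replicates,
    alpha = result$config$selection$alpha,
    sided = result$config$selection$sided,
    n_valid = tag$n_all,
    n_selected = tag$n_selected,
    n_invalid = result$n_invalid,
    estimated_power = fmt_num(tag$estimated_power, 3),
    tag_mean_all = fmt_num(tag$mean_all, 2),
    tag_mean_selected = fmt_num(tag$mean_selected, 2),
    tag_relative_bias_pct = fmt_num(tag$relative_bias_pct, 1),
    tag_burden_correlation = fmt_num(result$tag_burden_correlation, 2),
    stage2 = s2_which,
    stage2_mean_all = fmt_num(s2$mean_all, 2),
    stage2_mean_selected = fmt_num(s2$mean_selected, 2),
    stage2_relative_bias_pct = fmt_num(s2$relative_bias_pct, 1),
    stringsAsFactors = FALSE)
}

#' Write a table-shaped CSV summary of scenario results
#'
#' One row per scenario run, with the estimated power, the mean tag and
#' stage-2 effect estimates over all and over selected replicates, the
#' relative selection biases in percent, and (for gene scenarios) the
#' mean tag-burden correlation — the column layout such studies report
#' per tag SNP and trait.  Floats use fixed precision so identical runs
#' give byte-identical files.
#'
#' @param results A `scenario_result` or a list of them.
#' @param path Destination CSV file.
#' @return The summary `data.frame`, invisibly.
#' @export
write_summary <- function(results, path) {
  if (inherits(results, "scenario_result")) results <- list(results)
  if (length(results) == 0L) stop("no results to summarize", call. = FALSE)
  tab <- do.call(rbind, lapply(results, summary_row))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(tab)
}

#' Export estimate distributions for boxplot-style display
#'
#' Long-format export of the scenario-1 estimate distributions: the four
#' groups are the causal-SNP and tag-SNP estimates over all replicates
#' and over the replicates selected at stage 1.
#'
#' @param result A scenario S1 `scenario_result`.
#' @param path Destination CSV file.
#' @return The long `data.frame` (`group`, `replicate`, `estimate`),
#'   invisibly.
#' @export
write_distributions <- function(result, path) {
  stopifnot(inherits(result, "scenario_result"))
  if (result$scenario != "S1") {
    stop("distribution export is defined for scenario S1 results",
         call. = FALSE)
  }
  rec <- result$records[result$records$valid, , drop = FALSE]
  sel <- rec[rec$selected, , drop = FALSE]
  long <- rbind(
    data.frame(group = "causal_all", replicate = rec$replicate,
               estimate = rec$causal_estimate),
    data.frame(group = "tag_all", replicate = rec$replicate,
               estimate = rec$tag_estimate),
    data.frame(group = "tag_selected", replicate = sel$replicate,
               estimate = sel$tag_estimate),
    data.frame(group = "causal_selected", replicate = sel$replicate,
               estimate = sel$causal_estimate))
  long$estimate <- fmt_num(long$estimate, 6)
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(long)
}

#' Recompute scenario summaries from persisted replicate records
#'
#' Rebuilds the power and bias summaries from a records table written by
#' the command-line `simulate` step (or from `result$records`), optionally
#' re-applying a different selection rule first.
#'
#' @param records Records `data.frame` or path to a records CSV.
#' @param which Stage-2 estimate column: `"causal"` or `"lambda"`.
#' @param rule Optional [selection_rule()] to re-apply.
#' @return A list with `power`, `tag` and `stage2` [bias_summary()] objects.
#' @export
summarize_records <- function(records, which = c("causal", "lambda"),
                              rule = NULL) {
  which <- match.arg(which)
  if (is.character(records)) {
    records <- utils::read.csv(records, stringsAsFactors = FALSE)
  }
  if (!is.null(rule)) records <- apply_selection(records, rule)
  list(power = estimated_power(records),
       tag = bias_summary(records, "tag"),
       stage2 = bias_summary(records, which))
}
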