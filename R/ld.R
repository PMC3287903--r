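#' Upper bound on the allelic correlation between two biallelic loci
#'
#' The Pearson correlation between the minor-allele indicators of two loci
#' on haplotypes cannot be arbitrary: it is bounded by a function of the two
#' minor-allele frequencies, and the bound is small when the frequencies are
#' very different.  This is why a common tag SNP captures little of the
#' variation at a very rare variant.
#'
#' For minor-allele frequencies `p_t` and `p_c` (both in (0, 0.5]) the
#' maximum attainable correlation is
#' `sqrt(p_min * (1 - p_max) / (p_max * (1 - p_min)))`
#' where `p_min = min(p_t, p_c)` and `p_max = max(p_t, p_c)`.  It equals 1
#' exactly when the two frequencies coincide.
#'
#' @param p_t Minor-allele frequency of the tag SNP, in (0, 0.5].
#' @param p_c Minor-allele frequency of the causal SNP, in (0, 0.5].
#' @return The maximum attainable haplotype-level allelic correlation,
#'   a value in (0, 1].
#' @examples
#' rho_max(0.5, 0.5)   # 1: equal MAFs permit perfect correlation
#' rho_max(0.3, 0.1)   # about 0.51
#' rho_max(0.05, 0.001) # a common tag captures little of a very rare SNP
#' @export
rho_max <- function(p_t, p_c) {
  check_maf(p_t, "p_t")
  check_maf(p_c, "p_c")
  p_min <- pmin(p_t, p_c)
  p_max <- pmax(p_t, p_c)
  sqrt(p_min * (1 - p_max) / (p_max * (1 - p_min)))
}

check_maf <- function(p, name) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p > 0.5)) {
    stop(sprintf("`%s` must be a minor-allele frequency in (0, 0.5], got %s",
                 name, paste(format(p), collapse = ", ")), call. = FALSE)
  }
  invisible(p)
}

#' Specify a tag-causal locus pair with a target LD correlation
#'
#' Bundles the tag and causal minor-allele frequencies with the target
#' haplotype-level allelic correlation `rho`, validating feasibility
#' against [rho_max()].  Infeasible correlations are rejected, never
#' silently clipped.  Negative `rho` (minor alleles in repulsion) is
#' allowed; the bound applies to `|rho|`.
#'
#' @param p_t Tag SNP minor-allele frequency, in (0, 0.5].
#' @param p_c Causal SNP minor-allele frequency, in (0, 0.5].
#' @param rho Target allelic correlation on haplotypes (signed).
#' @return An object of class `"ld_pair_spec"`.
#' @seealso [haplotype_freqs()], [sample_pair_genotypes()], [gamma_tc()]
#' @export
ld_pair_spec <- function(p_t, p_c, rho) {
  check_maf(p_t, "p_t")
  check_maf(p_c, "p_c")
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho)) {
    stop("`rho` must be a single finite number", call. = FALSE)
  }
  bound <- rho_max(p_t, p_c)
  if (abs(rho) > bound + 1e-12) {
    stop(sprintf(
      "infeasible correlation: |rho| = %.6g exceeds rho_max(%.4g, %.4g) = %.6g",
      abs(rho), p_t, p_c, bound), call. = FALSE)
  }
  structure(list(p_t = p_t, p_c = p_c, rho = rho), class = "ld_pair_spec")
}

#' @export
print.ld_pair_spec <- function(x, ...) {
  cat(sprintf("tag-causal LD pair: p_T = %.4g, p_C = %.4g, rho = %.4g (max %.4g)\n",
              x$p_t, x$p_c, x$rho, rho_max(x$p_t, x$p_c)))
  invisible(x)
}

#' Two-locus haplotype frequencies realizing a target correlation
#'
#' Converts an [ld_pair_spec()] into the unique 2x2 haplotype-frequency
#' table with the specified marginals and allelic correlation, via
#' `D = rho * sqrt(p_T (1-p_T) p_C (1-p_C))` and
#' `f(minor, minor) = p_T * p_C + D`.
#'
#' @param spec An [ld_pair_spec()].
#' @return Named numeric vector `c(mm, mM, Mm, MM)` giving frequencies of
#'   the (tag, causal) haplotypes, `m` = minor allele, `M` = major allele.
#'   Frequencies are non-negative and sum to 1.
#' @export
haplotype_freqs <- function(spec) {
  stopifnot(inherits(spec, "ld_pair_spec"))
  p_t <- spec$p_t; p_c <- spec$p_c
  d <- spec$rho * sqrt(p_t * (1 - p_t) * p_c * (1 - p_c))
  f <- c(mm = p_t * p_c + d,
         mM = p_t * (1 - p_c) - d,
         Mm = (1 - p_t) * p_c - d,
         MM = (1 - p_t) * (1 - p_c) + d)
  # tolerate rounding at the exact feasibility boundary only
  if (any(f < -1e-10)) {
    stop(sprintf(
      paste0("infeasible haplotype table for p_T = %.4g, p_C = %.4g, ",
             "rho = %.6g: |rho| exceeds the bound rho_max = %.6g"),
      p_t, p_c, spec$rho, rho_max(p_t, p_c)), call. = FALSE)
  }
  f <- pmax(f, 0)
  f / sum(f)
}

#' Specify a gene region: one tag SNP plus multiple rare causal SNPs
#'
#' Describes the locus structure for scenarios in which a single tag SNP
#' is correlated with several rare (MAF < 5%) causal variants in the same
#' gene.  Rare variants are mutually independent conditional on the tag
#' allele, so each tag-rare pair attains its own target correlation.
#'
#' @param tag_maf Tag SNP minor-allele frequency, in (0, 0.5].
#' @param rare_mafs Numeric vector of rare-variant MAFs, each < 0.05.
#' @param tag_rare_rho Target haplotype correlation between the tag allele
#'   and each rare allele; same length as `rare_mafs`, each feasible under
#'   [rho_max()].
#' @param exclude_tag_from_burden Logical; if `TRUE` (required when the tag
#'   itself has MAF < 5% and plays the low-frequency-tag role) the tag
#'   column is excluded from the collapsing statistic `r_i/n_i`.
#' @return An object of class `"gene_spec"`.
#' @export
gene_spec <- function(tag_maf, rare_mafs, tag_rare_rho,
                      exclude_tag_from_burden = FALSE) {
  check_maf(tag_maf, "tag_maf")
  if (length(rare_mafs) < 1L) {
    stop("`rare_mafs` must contain at least one rare variant", call. = FALSE)
  }
  check_maf(rare_mafs, "rare_mafs")
  if (any(rare_mafs >= 0.05)) {
    stop(sprintf("rare variants must have MAF < 0.05; offending MAF(s): %s",
                 paste(format(rare_mafs[rare_mafs >= 0.05]), collapse = ", ")),
         call. = FALSE)
  }
  if (length(tag_rare_rho) != length(rare_mafs)) {
    stop("`tag_rare_rho` must have the same length as `rare_mafs`",
         call. = FALSE)
  }
  bounds <- rho_max(tag_maf, rare_mafs)
  bad <- which(abs(tag_rare_rho) > bounds + 1e-12)
  if (length(bad)) {
    stop(sprintf(
      "infeasible tag-rare correlation at locus %d: |rho| = %.6g > rho_max = %.6g",
      bad[1L], abs(tag_rare_rho[bad[1L]]), bounds[bad[1L]]), call. = FALSE)
  }
  if (!is.logical(exclude_tag_from_burden) || length(exclude_tag_from_burden) != 1L) {
    stop("`exclude_tag_from_burden` must be TRUE or FALSE", call. = FALSE)
  }
  structure(list(tag_maf = tag_maf, rare_mafs = as.numeric(rare_mafs),
                 tag_rare_rho = as.numeric(tag_rare_rho),
                 exclude_tag_from_burden = exclude_tag_from_burden),
            class = "gene_spec")
}

#' @export
print.gene_spec <- function(x, ...) {
  cat(sprintf("gene spec: tag MAF %.4g; %d rare variant(s), MAF %s\n",
              x$tag_maf, length(x$rare_mafs),
              paste(format(x$rare_mafs, digits = 3), collapse = ", ")))
  cat(sprintf("  tag-rare rho: %s; tag excluded from burden: %s\n",
              paste(format(x$tag_rare_rho, digits = 3), collapse = ", "),
              x$exclude_tag_from_burden))
  invisible(x)
}
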