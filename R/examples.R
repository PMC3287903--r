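#' Canonical study conditions for the three two-stage scenarios
#'
#' Ready-made [run_config()]s emulating the study conditions of the three
#' scenarios: (S1) a common tag SNP and a common causal SNP with the tag
#' tested on a quantitative trait at sample size 616; (S2) a common tag
#' SNP and ten rare causal SNPs in one gene at sample size 697, trait
#' generated under the burden model; (S3) as S2 but with a low-frequency
#' tag SNP (MAF 3%) excluded from the collapsing statistic.
#'
#' Effect sizes are fixed in the low-power regime that makes the winner's
#' curse visible: the S1 default gives analytic power near 0.15 at
#' alpha = 0.05 (two-sided), and the gene scenarios give stage-1 power
#' below 0.20 at every ladder threshold, with tag-burden correlation
#' near 0.5.
#'
#' @param scenario `"S1"`, `"S2"` or `"S3"`.
#' @param seed Master seed.
#' @param replicates Number of replicate data sets (default 200).
#' @param rho S1 only: tag-causal correlation (default 1, the tag is the
#'   causal SNP itself).
#' @param beta S1 only: causal effect per minor allele (default 0.057
#'   trait SD units, i.e. standardized noncentrality near 0.92 at
#'   n = 616).
#' @param lambda Gene scenarios: burden-model effect (default 0.7).
#' @param alpha Stage-1 selection threshold (default 0.05).
#' @param sided Selection sidedness (default two-sided).
#' @return A [run_config()].
#' @export
example_config <- function(scenario = c("S1", "S2", "S3"), seed = 1L,
                           replicates = 200L, rho = 1, beta = 0.057,
                           lambda = 0.7, alpha = 0.05,
                           sided = "two_sided") {
  scenario <- match.arg(scenario)
  rule <- selection_rule(alpha, sided)
  if (scenario == "S1") {
    return(run_config("S1", n = 616L, replicates = replicates, seed = seed,
                      pair = ld_pair_spec(0.3, 0.3, rho),
                      trait = trait_model("quantitative", beta = beta,
                                          sigma = 1),
                      selection = rule))
  }
  rare <- seq(0.005, 0.045, length.out = 10)
  tag_maf <- if (scenario == "S2") 0.25 else 0.03
  gene <- gene_spec(tag_maf, rare, 0.6 * rho_max(tag_maf, rare),
                    exclude_tag_from_burden = (scenario == "S3"))
  run_config(scenario, n = 697L, replicates = replicates, seed = seed,
             gene = gene,
             trait = trait_model("quantitative", lambda = lambda, sigma = 1),
             selection = rule)
}
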