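# shared helpers: hand-built records tables and an independent numeric
# maximizer of the allelic correlation over valid haplotype tables

make_records <- function(estimates, selected, which = "tag",
                         valid = rep(TRUE, length(estimates))) {
  df <- data.frame(replicate = seq_along(estimates), valid = valid,
                   selected = selected)
  df[[paste0(which, "_estimate")]] <- estimates
  df
}

# oracle for rho_max: maximize the Pearson correlation of allele
# indicators over the feasible range of the minor-minor haplotype
# frequency, for fixed marginals (independent of the closed form)
rho_max_numeric <- function(p_t, p_c) {
  lo <- max(0, p_t + p_c - 1)
  hi <- min(p_t, p_c)
  corr <- function(f11) {
    (f11 - p_t * p_c) / sqrt(p_t * (1 - p_t) * p_c * (1 - p_c))
  }
  stats::optimize(corr, c(lo, hi), maximum = TRUE, tol = 1e-12)$objective
}
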