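#!/usr/bin/env Rscript
# Step 4 — downstream analyses.
#
# (a) Cross-omics Pearson correlation between protein and mRNA log2 fold
#     changes over signature genes (the study context reports R = 0.5-0.7);
# (b) hypergeometric over-representation of the EGFRi signature in
#     synthetic gene-set collections;
# (c) four-parameter-logistic IC50 fits of simulated dose-response assays
#     (5 technical replicates per dose, as plated in such studies);
# (d) two-arm survival comparison at the reported study scale (10 animals
#     per arm, control median 31 days vs combination 56 days).

library(kinorewire)

out <- "results/downstream"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20260925L

## (a) cross-omics coupling
pairs <- simulate_crossomics_pairs(50, rho = 0.6, seed = seed)
cx <- crossomics_correlation(setNames(pairs$protein_l2fc, pairs$gene),
                             setNames(pairs$mrna_l2fc, pairs$gene))
cat(sprintf("cross-omics Pearson r = %.2f (p = %.2g, n = %d)\n",
            cx$r, cx$p, cx$n))

## (b) over-representation of the EGFRi signature
egfri_file <- "results/acute/acute_signatures.gmt"
if (file.exists(egfri_file)) {
  sigs <- read_signatures(egfri_file)
  query <- signature_genes(sigs, "EGFRi_up")
  background <- sprintf("KIN%04d", 1:299)
  query <- intersect(query, background)
  set.seed(seed %% 2^31)
  collections <- list(
    enriched = unique(c(sample(query, min(8, length(query))),
                        sample(background, 12))),
    unrelated = sample(setdiff(background, query), 20))
  tab <- ora_enrichment(query, collections, background)
  write.table(tab, file.path(out, "ora_egfri_up.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat(sprintf("ORA: '%s' p = %.2g, '%s' p = %.2g\n",
              tab$name[1], tab$p[1], tab$name[2], tab$p[2]))
}

## (c) dose-response IC50
fits <- lapply(c(parental = 0.5, resistant = 4), function(ic50) {
  d <- simulate_dose_response(ic50 = ic50, hill = 1.2, n_doses = 8,
                              noise_sd = 5, seed = seed + round(ic50 * 10))
  fit_4pl(d)
})
for (nm in names(fits))
  cat(sprintf("%s IC50 = %.2f uM (hill %.2f)\n", nm, fits[[nm]]$ic50,
              fits[[nm]]$hill))
cat(sprintf("resistant/parental IC50 ratio = %.1f\n",
            fits$resistant$ic50 / fits$parental$ic50))

## (d) survival at study scale
surv <- simulate_survival_arms(median_ctrl = 31, hazard_ratio = 31 / 56,
                               n_per_arm = 10, seed = seed,
                               arms = c("control", "combination"))
lr <- logrank_test(surv, "combination", "control")
write.table(surv, file.path(out, "survival_arms.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf(
  "survival: combination median %.0f d vs control %.0f d (log-rank p = %.3g)\n",
  lr$median_a, lr$median_b, lr$p))
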