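#!/usr/bin/env Rscript
# Step 1 — simulate the study cohort.
#
# Generates the synthetic analogue of the profiling study: label-free MIB-MS
# proteomes for the parental line (CEv3) and six TKI-resistant derivatives
# under full- and starved-serum culture (~300 kinases, 3 replicates, 2 MS
# batches, detection-limit dropout), a TMT time course (0/4/24/48 h) for
# every line after acute EGFR-inhibitor challenge, and an RNA-seq count
# matrix. Everything is written as the tab-separated formats the readers
# consume, together with the planted ground truth.

library(kinorewire)

seed <- 20260925L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = seed)

lfq <- simulate_lfq_proteome(cfg)
write_protein_groups(lfq$matrix, file.path(out, "lfq_protein_groups.tsv"))
write.table(lfq$matrix$samples, file.path(out, "lfq_metadata.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_truth_table(lfq$truth$membership, file.path(out, "lfq_truth.tsv"))

tmt <- simulate_tmt_timecourse(cfg)
write_protein_groups(tmt$matrix, file.path(out, "tmt_protein_groups.tsv"))
write.table(tmt$matrix$samples, file.path(out, "tmt_metadata.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_truth_table(tmt$truth$membership, file.path(out, "tmt_truth.tsv"))

rna <- simulate_rnaseq_counts(cfg, n_genes = 2000)
write_counts(rna$matrix, file.path(out, "rnaseq_counts.tsv"))
write.table(rna$matrix$samples, file.path(out, "rnaseq_metadata.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

roster <- kinase_roster(rownames(lfq$matrix$values),
                        special = ifelse(rownames(lfq$matrix$values) ==
                                           "hEGFR", "hEGFR", ""))
write.table(roster, file.path(out, "kinase_roster.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("LFQ: %d kinases x %d samples (%.1f%% below detection limit)\n",
            nrow(lfq$matrix$values), ncol(lfq$matrix$values),
            100 * mean(is.na(lfq$matrix$values))))
cat(sprintf("TMT: %d kinases x %d samples, %d planted acute responders\n",
            nrow(tmt$matrix$values), ncol(tmt$matrix$values),
            length(tmt$truth$egfri_up) + length(tmt$truth$egfri_down)))
cat(sprintf("planted: %d BL-unique, %d OL-BL shared, %d up / %d down acute\n",
            length(unlist(lfq$truth$bl_truth)), length(lfq$truth$olbl_truth),
            length(tmt$truth$egfri_up), length(tmt$truth$egfri_down)))
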