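#!/usr/bin/env Rscript
# Step 3 — acute EGFR-inhibitor (EGFRi) branch.
#
# Normalizes each line's TMT time course to its untreated 0 h controls,
# tests 4/24/48 h against 0 h (moderated t, FDR < 0.05), flags temporal DE
# as the union over timepoints, classifies directions by 2-cluster K-means
# on kinome-scaled z-profiles, removes cross-line direction conflicts and
# defines the EGFRi signature as the CEv3-unique responders, split up/down.
# Finally compares EGFRi against the baseline signatures from step 2.

library(kinorewire)

data_dir <- "results/data"
out <- "results/acute"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

roster <- read.delim(file.path(data_dir, "kinase_roster.tsv"))
roster <- kinase_roster(roster$symbol, roster$is_kinase, roster$is_receptor,
                        roster$is_protein_coding, roster$special)
meta <- read.delim(file.path(data_dir, "tmt_metadata.tsv"))
tmt <- read_protein_groups(file.path(data_dir, "tmt_protein_groups.tsv"),
                           roster, meta)

cfg <- run_config(kmeans_seed = 20260925L)
bl_run <- NULL
bl_gmt <- "results/baseline/baseline_signatures.gmt"
run <- run_acute_branch(tmt, cfg)
write_run(run, out, "acute")

n_de <- vapply(run$temporal, function(x) length(x$flagged), integer(1))
cat("temporal DE kinases per line:",
    paste(sprintf("%s=%d", names(n_de), n_de), collapse = ", "), "\n")
up <- signature_genes(run$egfri, "EGFRi_up")
down <- signature_genes(run$egfri, "EGFRi_down")
cat(sprintf("EGFRi signature: %d up, %d down (%d total)\n",
            length(up), length(down), length(up) + length(down)))

truth <- read.delim(file.path(data_dir, "tmt_truth.tsv"))
planted <- truth$gene[truth$role == "parental_only"]
met <- set_metrics(c(up, down), planted)
cat(sprintf("EGFRi recovery vs planted truth: precision %.2f, recall %.2f\n",
            met$precision, met$recall))

if (file.exists(bl_gmt)) {
  bl_sigs <- read_signatures(bl_gmt)
  cmp <- compare_signatures(run$egfri, bl_sigs)
  write.table(cmp, file.path(out, "egfri_vs_baseline_overlap.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("EGFRi x baseline signatures: %d shared kinases in total\n",
              sum(cmp$overlap)))
}
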