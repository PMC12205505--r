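#!/usr/bin/env Rscript
# Step 2 — acquired-resistance (baseline) branch.
#
# Reads the simulated protein-groups tables back from disk, imputes
# left-censored missing values (shift 3, scale 0.3), tests every resistant
# line against CEv3 per culture condition (moderated t, batch in the
# design, FDR < 0.05), partitions DE kinases into unique/shared with upset
# counts, and reconciles the conditions into the per-line BL signatures and
# the direction-consistent OL-BL signature.

library(kinorewire)

data_dir <- "results/data"
out <- "results/baseline"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

roster <- read.delim(file.path(data_dir, "kinase_roster.tsv"))
roster <- kinase_roster(roster$symbol, roster$is_kinase, roster$is_receptor,
                        roster$is_protein_coding, roster$special)
meta <- read.delim(file.path(data_dir, "lfq_metadata.tsv"))
lfq <- read_protein_groups(file.path(data_dir, "lfq_protein_groups.tsv"),
                           roster, meta)

cfg <- run_config(kmeans_seed = 20260925L)
fs <- subset_samples(lfq, lfq$samples$condition == "FS")
ss <- subset_samples(lfq, lfq$samples$condition == "SS")
run <- run_baseline_branch(list(FS = fs, SS = ss), cfg)

for (cc in names(run$partitions)) {
  write.table(run$partitions[[cc]]$upset,
              file.path(out, sprintf("upset_%s.tsv", cc)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  de_n <- vapply(run$de_calls[[cc]], function(r) sum(r$significant),
                 integer(1))
  cat(sprintf("%s: DE kinases per line vs CEv3: %s\n", cc,
              paste(sprintf("%s=%d", names(de_n), de_n), collapse = ", ")))
}

write_run(run, out, "baseline")
bl_sizes <- vapply(run$bl$signatures, nrow, integer(1))
cat("BL signature sizes:",
    paste(sprintf("%s=%d", names(bl_sizes), bl_sizes), collapse = ", "), "\n")
cat(sprintf("OL-BL signature: %d kinases\n", nrow(run$ol_bl$signatures$OL_BL)))
cat(sprintf("exclusions logged: %d (%s)\n",
            nrow(run$bl$exclusions) + nrow(run$ol_bl$exclusions),
            paste(unique(c(run$bl$exclusions$reason,
                           run$ol_bl$exclusions$reason)), collapse = ", ")))

# recovery against the planted truth
truth <- read.delim(file.path(data_dir, "lfq_truth.tsv"))
bl_truth <- unique(truth$gene[truth$role == "unique"])
met <- set_metrics(unlist(lapply(run$bl$signatures, function(s) s$gene)),
                   bl_truth)
cat(sprintf("BL recovery vs planted truth: precision %.2f, recall %.2f\n",
            met$precision, met$recall))
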