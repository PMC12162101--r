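#!/usr/bin/env Rscript
# Step 1 — simulate the full study system: a reference genome with planted
# CpGs, a capture probe panel, per-sample methylomes for two groups across
# tissues, sequenced fragments with a realistic on/off-target mixture, and an
# in-silico MspI digest for the reduced-representation comparison.
# Everything downstream (02-06) reads from results/sim/.

suppressPackageStartupMessages(library(tmskit))
library(Biostrings)

seed <- 20260927
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("Generating reference genome and probe panel ...")
ref <- gen_reference(n_chroms = 2, chrom_length = 3e5, cpg_rate = 0.02,
                     probes_per_chrom = 60, seed = seed)
writeXStringSet(ref$sequences, file.path(out, "reference.fa"))
write_bed(ref$probes, file.path(out, "probes.bed"))
write.table(ref$cpg_sites, file.path(out, "cpg_sites.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("  %d CpG sites, %d probes on %d chromosomes",
                nrow(ref$cpg_sites), nrow(ref$probes), 2))

message("Simulating methylomes (2 groups x 8 samples, ~20x coverage) ...")
sim <- gen_methylome(ref, n_per_group = c(8, 8), delta = 0.2, n_effect = 200,
                     mu_cov = 20, conv_error = 0.005, n_chh = 2000,
                     split_strands = TRUE, seed = seed + 1)
for (s in names(sim$reports))
  write_cytosine_report(sim$reports[[s]],
                        file.path(out, paste0(s, ".CpG_report.txt")))
write.table(sim$truth, file.path(out, "truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
sheet <- data.frame(sample = sim$meta$sample,
                    file = paste0(sim$meta$sample, ".CpG_report.txt"),
                    group = sim$meta$group,
                    tissue = rep(c("liver", "kidney"), each = 8),
                    technology = "TMS")
write.table(sheet, file.path(out, "samples.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("  %d sites x %d samples; %d planted effect sites (delta = 0.2)",
                nrow(sim$M), ncol(sim$M), sum(sim$truth$effect)))

message("Simulating sequenced fragments (on-target prob 0.785) ...")
fr <- gen_fragments(ref$probes, 50000, ref$chrom_lengths,
                    on_target_prob = 0.785, seed = seed + 2)
write_bed(fr, file.path(out, "fragments.bed"))

message("In-silico MspI digest (CCGG, 180-2000 bp size selection) ...")
dig <- msp1_digest(as.character(ref$sequences[[1]]), digest_config(),
                   chrom = "chr1")
write_bed(dig$retained, file.path(out, "digest_retained.bed"))
write.table(dig$covered_cpgs, file.path(out, "digest_covered_cpgs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("  %d/%d fragments retained; %d of %d chr1 CpGs covered (%.1f%%)",
                nrow(dig$retained), nrow(dig$fragments),
                nrow(dig$covered_cpgs),
                sum(ref$cpg_sites$chrom == "chr1"),
                100 * nrow(dig$covered_cpgs) /
                  sum(ref$cpg_sites$chrom == "chr1")))
message("Done; inputs written under ", out)
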