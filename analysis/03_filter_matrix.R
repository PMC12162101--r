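#!/usr/bin/env Rscript
# Step 3 — low-level processing: parse the per-sample cytosine reports,
# collapse CpG strands, assemble the multi-sample count matrix, apply the
# region + coverage/missingness filter (>= 5x in >= 75% of samples within
# the expanded probe target), and summarize methylation by genomic
# annotation.

suppressPackageStartupMessages(library(tmskit))
library(Biostrings)

sim <- "results/sim"
out <- "results/matrix"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sheet <- read_sample_sheet(file.path(sim, "samples.tsv"))
message("Parsing and collapsing ", nrow(sheet), " cytosine reports ...")
reports <- lapply(seq_len(nrow(sheet)), function(i)
  collapse_strands(parse_cytosine_report(file.path(sim, sheet$file[i]))))
names(reports) <- sheet$sample

cm <- assemble_matrix(reports, sheet)
message(sprintf("Assembled %d sites x %d samples", nrow(cm$M), ncol(cm$M)))

genome <- readDNAStringSet(file.path(sim, "reference.fa"))
probes <- parse_bed(file.path(sim, "probes.bed"))
target <- expand_merge(probes, 200, setNames(width(genome), names(genome)))

flt <- filter_matrix(cm, filter_spec(min_cov = 5, min_frac = 0.75,
                                     target = target))
message(sprintf("Filter kept %d/%d sites (%d off-target, %d under-covered)",
                flt$report$n_kept, flt$report$n_input,
                flt$report$n_dropped_region, flt$report$n_dropped_coverage))
write_count_matrix(flt$matrix, file.path(out, "filtered"))

lev <- methylation_levels(flt$matrix)
ss <- site_summary(lev)
message(sprintf("Variable sites (10%% < mean < 90%%): %d (%.1f%%); hypo %d, hyper %d",
                sum(ss$variable), 100 * mean(ss$variable),
                sum(ss$hypo), sum(ss$hyper)))
write.table(cbind(flt$matrix$sites, ss), file.path(out, "site_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# annotation summary over an illustrative island/shore/shelf labeling of the
# densest target regions
lab <- derive_shores_shelves(target[order(-(target$end - target$start)), ][1:10, ],
                             chrom_lengths = setNames(width(genome), names(genome)))
med <- data.frame(chrom = flt$matrix$sites$chrom,
                  pos0 = flt$matrix$sites$pos0, median = ss$median)
ann <- annotation_summary(med, lab)
write.table(ann, file.path(out, "annotation_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("Median methylation by annotation:")
for (i in seq_len(nrow(ann)))
  message(sprintf("  %-12s n=%5d median=%.3f",
                  ann$label[i], ann$n_sites[i], ann$median_meth[i]))
message("Done; tables under ", out)
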