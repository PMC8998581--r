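#!/usr/bin/env Rscript
# Stage 3: physicochemical profiles and per-family summary.
#
# Computes length, Mw, pI, GRAVY, residue-category percentages and the
# hydrophilin flag per protein; then the per-family mean +- SE table with
# Tukey HSD grouping letters (the Table-2-style summary), and the
# residue-percentage vs GRAVY scatter data.

suppressPackageStartupMessages(library(leaprofiler))

set <- read_fasta("results/synthetic/proteome.faa", source = "synthetic")
cls <- read.delim("results/families.tsv")

prof <- physchem_table(set)
write.table(prof, "results/physchem.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

fs <- family_summary(cls, prof)
summary_rows <- do.call(rbind, lapply(names(fs), function(v)
  cbind(variable = v, fs[[v]])))
write.table(summary_rows, "results/family_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("per-family GRAVY (mean +- SE, Tukey letters):\n")
print(fs$gravy, digits = 3)
cat("\nhydrophilins by family:\n")
merged <- merge(cls[, c("id", "family")], prof, by = "id")
print(tapply(merged$hydrophilin, merged$family, sum))

panels <- gly_gravy_table(set)
fig1 <- do.call(rbind, lapply(names(panels), function(p) {
  d <- panels[[p]]
  data.frame(panel = p, id = d$id, pct = d$pct, gravy = d$gravy)
}))
write.table(fig1, "results/fig1_data.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nwrote physchem.tsv, family_summary.tsv, fig1_data.tsv\n")
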