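#!/usr/bin/env Rscript
# Stage 4: motif content, dehydrin segments, amphipathicity, HRSA.
#
# Scans every protein for the 28 family consensus motifs and the
# dehydrin K/Y/S segment grammars, finds each protein's best 11-residue
# amphipathic window (HeliQuest convention) and any hydropathy-based
# transmembrane-helix candidates, and scores hydroxyl-radical scavenging
# ability with the ordinal tier table.

suppressPackageStartupMessages(library(leaprofiler))

set <- read_fasta("results/synthetic/proteome.faa", source = "synthetic")
cls <- read.delim("results/families.tsv")
reg <- load_registry()

hits <- do.call(rbind, lapply(seq_len(nrow(set)), function(i) {
  h <- do.call(rbind, lapply(seq_len(nrow(reg)), function(k)
    scan_motif(set$sequence[i], reg[k, ])))
  if (nrow(h) == 0) NULL else cbind(id = set$id[i], h)
}))
write.table(hits, "results/motif_hits.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("motif hits:", nrow(hits), "across", length(unique(hits$id)),
    "proteins\n")

segs <- do.call(rbind, lapply(seq_len(nrow(set)), function(i) {
  s <- detect_dehydrin_segments(set$sequence[i])
  if (nrow(s) == 0) NULL else cbind(id = set$id[i], s)
}))
write.table(segs, "results/segments.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
deh_ids <- cls$id[cls$family == "DEH"]
cat("K/Y/S segment hits:", nrow(segs), "; dehydrins with a K-segment:",
    length(unique(segs$id[segs$kind == "K" & segs$id %in% deh_ids])),
    "of", length(deh_ids), "\n")

hel <- helix_table(set)
write.table(hel, "results/helix.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
merged <- merge(cls[, c("id", "family")], hel, by = "id")
cat("A-type best windows by family:\n")
print(tapply(merged$a_type, merged$family, sum))

tmh <- do.call(rbind, lapply(seq_len(nrow(set)), function(i) {
  t <- tmh_candidate_scan(set$sequence[i])
  if (nrow(t) == 0) NULL else cbind(id = set$id[i], t)
}))
cat("TMH candidates:", if (is.null(tmh)) 0 else nrow(tmh), "\n")
if (!is.null(tmh))
  write.table(tmh, "results/tmh_candidates.tsv", sep = "\t", quote = FALSE,
              row.names = FALSE)

hr <- hrsa_table(set)
write.table(hr, "results/hrsa.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
m2 <- merge(cls[, c("id", "family")], hr, by = "id")
cat("HRSA (ordinal tier units) range:", round(min(hr$hrsa), 1), "-",
    round(max(hr$hrsa), 1), "\nper-family means:\n")
print(round(tapply(m2$hrsa, m2$family, mean), 1))
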