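#!/usr/bin/env Rscript

# Step 5 -- repertoire usage.
#
# Segment-usage tables at gene and clan level, V(D)J combination counts
# (the tabular Sankey), and the recovery of the configured usage bias
# (heavily skewed J usage) from the annotated reads.

suppressMessages(library(igjunction))

for (locus in c("IGH", "IGK")) {
  prefix <- file.path("results", sprintf("sim_%s", tolower(locus)))
  germ <- classify_germline_set(load_germline(paste0(prefix, "_germline.fasta"),
                        paste0(prefix, "_germline_regions.tsv")))
  reads <- read_sequences(paste0(prefix, ".fasta"))
  recs <- annotate_reads(reads, germ)

  cat(sprintf("\n== %s usage ==\n", locus))
  for (seg in if (locus == "IGH") c("V", "D", "J") else c("V", "J")) {
    u <- usage_frequencies(recs, seg, "gene")
    cat(sprintf("%s usage (assigned %d, unassigned %d):\n", seg,
                attr(u, "n_assigned"), attr(u, "n_unassigned")))
    print(head(as.data.frame(u), 5L), row.names = FALSE)
  }
  u_clan <- usage_frequencies(recs, "V", "clan", germ)
  cat("V clan usage:\n"); print(as.data.frame(u_clan), row.names = FALSE)

  comb <- combination_table(recs, "clan", germ)
  cat("top combinations:\n"); print(head(comb, 5L), row.names = FALSE)
  write.table(comb, file.path("results",
              sprintf("combinations_%s.tsv", tolower(locus))),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
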