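#!/usr/bin/env Rscript

# Step 4 -- somatic hypermutation.
#
# Computes SHM frequency per germline V group, the 12-class substitution
# spectrum, per-site mutation profiles over FR1-FR3 and AID-hotspot
# (WRCY/RGYW) mutation frequencies with their enrichment over non-hotspot
# C/G baselines.

suppressMessages(library(igjunction))

for (locus in c("IGH", "IGK")) {
  prefix <- file.path("results", sprintf("sim_%s", tolower(locus)))
  germ <- classify_germline_set(load_germline(paste0(prefix, "_germline.fasta"),
                        paste0(prefix, "_germline_regions.tsv")))
  reads <- read_sequences(paste0(prefix, ".fasta"))
  recs <- annotate_reads(reads, germ)

  freq <- shm_frequency(recs)
  cat(sprintf("\n== %s SHM ==\noverall frequency: %.2f%%\n", locus,
              freq$overall_pct))
  print(freq$per_gene, row.names = FALSE)

  spec <- substitution_spectrum(recs)
  cat("top substitution classes:\n")
  print(head(spec[order(-spec$percent), ], 4L), row.names = FALSE)
  write.table(spec, file.path("results",
              sprintf("spectrum_%s.tsv", tolower(locus))),
              sep = "\t", quote = FALSE, row.names = FALSE)

  profs <- per_site_profile(recs, germ)
  cdr_fr <- do.call(rbind, lapply(profs, function(p)
    data.frame(region = p$region, frequency = p$frequency)))
  by_region <- tapply(cdr_fr$frequency, grepl("CDR", cdr_fr$region), mean,
                      na.rm = TRUE)
  cat(sprintf("mean per-site frequency, FR: %.4f  CDR: %.4f  (ratio %.2f)\n",
              by_region[["FALSE"]], by_region[["TRUE"]],
              by_region[["TRUE"]] / by_region[["FALSE"]]))

  hot <- hotspot_analysis(recs, germ)
  for (h in hot) {
    cat(sprintf("%s: %d hotspot positions, freq %.4f vs baseline %.4f, enrichment %.2f\n",
                h$motif, h$n_hotspot_positions, h$hotspot$frequency,
                h$baseline$frequency, h$enrichment))
  }
}
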