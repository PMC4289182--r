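# Regenerates the shipped reference fixtures (deterministic; run from the
# package root after installing the package).
library(opsinminer)

panel <- build_synthetic_panel()
write_fasta(stats::setNames(panel$protein, panel$id),
            "inst/extdata/reference_panel_synthetic.fasta")
write.table(panel[, c("id", "name", "family", "is_anchor")],
            "inst/extdata/reference_panel_synthetic.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

write_diagnostic_scheme(diagnostic_scheme(),
                        "inst/extdata/diagnostic_scheme.yaml")
cat("fixtures written\n")
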