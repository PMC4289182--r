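#!/usr/bin/env Rscript
# Stage 7 (optional; needs a one-time network fetch): rerun the
# diagnose + classify stages on the deposited brittle-star opsin
# sequences and report the repertoire counts.  Fetch the input first
# with scripts/fetch_deposited.R.
suppressMessages(library(opsinminer))

path <- "inst/extdata/deposited/af_opsins_aa.fasta"
if (!file.exists(path)) {
  path <- system.file("extdata", "deposited", "af_opsins_aa.fasta",
                      package = "opsinminer")
}
if (!nzchar(path) || !file.exists(path)) {
  cat("deposited sequences not present; run scripts/fetch_deposited.R",
      "(requires network access), then re-run this stage\n")
  quit(status = 0)
}
res <- analyse_deposited(path)
str(res$counts)
write.table(res$classification$table, "results/deposited_classification.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
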