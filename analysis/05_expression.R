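#!/usr/bin/env Rscript
# Stage 5: match arm-transcriptome sequences against the candidate gene
# proteins; a gene counts as detected only when a transcript matches at
# >99.9% identity over >=30 residues (effectively a perfect
# protein-level match).
suppressMessages(library(opsinminer))

genes <- read_fasta("results/candidates.fasta")
tx <- read_fasta("results/synthetic/transcripts.fasta")
calls <- expression_report(match_transcripts(tx, genes))
write.table(calls, "results/expression.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("genes:", nrow(calls), "| detected in transcripts:",
    sum(calls$expressed), "\n")
print(calls[calls$expressed, c("gene_name", "transcript_id", "identity",
                               "aligned_len")], row.names = FALSE)
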