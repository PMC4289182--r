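#!/usr/bin/env Rscript
# Stage 4: assign each candidate to an opsin family by trimmed
# local-alignment similarity against the panel, corroborated by the
# diagnostic triad and by a bootstrapped neighbor-joining placement of
# the 7-TM cores, then name the candidates Sp-style.
suppressMessages(library(opsinminer))

panel <- reference_panel()
genes <- read_fasta("results/candidates.fasta")
reports <- diagnose_candidates(genes, panel)
cls <- classify_candidates(genes, panel, reports,
                           cfg = phylo_config(), with_tree = TRUE,
                           seed = 1L)
write.table(cls$table, "results/classification.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(as.data.frame(unclass(cls$sim)),
            "results/similarity_matrix.tsv", sep = "\t", quote = FALSE)
if (!is.null(cls$tree)) ape::write.tree(cls$tree, "results/tree.nwk")

cat("families called:\n")
print(table(cls$table$family))
cat("consistent calls:", sum(cls$table$confidence == "consistent"),
    "of", nrow(cls$table), "\n")
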