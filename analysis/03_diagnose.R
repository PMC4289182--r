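#!/usr/bin/env Rscript
# Stage 3: map every candidate onto the anchor rhodopsin residue frame
# and call the diagnostic sites: Schiff-base K296 (bona fide status),
# counterions E113/Y113 and E181, D(E)RY, NPxxY(x)6F and its NxQ/HxK
# triad, disulfide and palmitoylation cysteines.
suppressMessages(library(opsinminer))

panel <- reference_panel()
genes <- read_fasta("results/candidates.fasta")
reports <- diagnose_candidates(genes, panel)
m <- motif_matrix(reports)
write.table(m, "results/motif_matrix.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("candidates:", nrow(m), "\n")
cat("Schiff-base lysine present:", sum(m$schiff_base == "present"), "\n")
cat("bona fide:", sum(m$bona_fide == "true"),
    "| indeterminate:", sum(m$bona_fide == "indeterminate"), "\n")
cat("E181:", sum(m$counterion_181 == "present"),
    "| invertebrate Y113:", sum(m$counterion_113_type == "invertebrate"),
    "\n")
print(table(m$triad_class))
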