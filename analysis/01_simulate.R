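#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs with known ground truth --
# a 13-gene opsin repertoire (six rhabdomeric genes, one split RGR gene,
# two neuropsins lacking the Schiff-base lysine, ...) embedded in decoy
# contigs, transcripts for the three expressed genes, and day/night arm
# counts for five light treatments.
suppressMessages(library(opsinminer))
seed <- if (length(a <- commandArgs(TRUE))) as.integer(a[[1]]) else 1L

dir.create("results/synthetic", recursive = TRUE, showWarnings = FALSE)
panel <- reference_panel()

asm <- generate_assembly(seed = seed, panel = panel)
write_fasta(asm$contigs, "results/synthetic/assembly.fasta")
write.table(asm$truth[, setdiff(names(asm$truth), "protein")],
            "results/synthetic/ground_truth.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

tx <- generate_transcripts(asm, noise = 0, seed = seed)
write_fasta(tx, "results/synthetic/transcripts.fasta")

beh <- generate_behaviour_counts(seed = seed)
write_behaviour_tsv(beh, "results/synthetic/behaviour.tsv")

cat("assembly:", length(asm$contigs), "contigs (",
    sum(asm$truth$kind == "opsin"), "gene fragments,",
    sum(asm$truth$kind == "decoy"), "decoy GPCRs,",
    sum(asm$truth$kind == "background"), "background )\n")
cat("transcripts:", length(tx), "| behaviour rows:", nrow(beh), "\n")
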