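panel <- test_panel()
sc <- scoring_scheme()

test_that("an exact CDS copy is found covering the full reference", {
  ref <- panel[panel$name == "Sp-opsin 4", ]
  cds <- withr::with_seed(1, back_translate(ref$protein))
  contig <- paste0("ACGTACGTAA", cds, "TTGACCA")
  hits <- translated_search(c(ctg = contig), panel, min_score = 100, sc)
  best <- hits[which.max(hits$score), ]
  expect_equal(best$reference_name, "Sp-opsin 4")
  expect_equal(best$frame, 2L)             # 10-nt leader puts the CDS in frame +2
  expect_equal(c(best$ref_start, best$ref_end), c(1L, nchar(ref$protein)))
  expect_equal(best$protein, ref$protein)
  # contig coordinates point exactly at the embedded CDS
  expect_equal(c(best$contig_start, best$contig_end),
               c(11L, 10L + nchar(cds)))
})

test_that("reverse-strand hits carry forward-strand coordinates", {
  ref <- panel[panel$name == "Sp-opsin 8", ]
  cds <- withr::with_seed(2, back_translate(ref$protein))
  contig <- paste0("GTTACA", reverse_complement(cds), "ACGGT")
  hits <- translated_search(c(ctg = contig), panel, min_score = 100, sc)
  best <- hits[which.max(hits$score), ]
  expect_lt(best$frame, 0L)
  # re-extract the hit span, reverse-complement, translate: the hit protein
  sub <- substr(contig, best$contig_start, best$contig_end)
  aa <- unname(translate_six_frames(paste0(reverse_complement(sub), "AAA"))["+1"])
  expect_equal(substr(aa, 1, nchar(best$protein)), best$protein)
})

test_that("random contigs yield no hits at half the panel self-score", {
  min_half_self <- min(vapply(panel$protein, function(p)
    local_score(p, p, sc), numeric(1L))) / 2
  set.seed(201)
  contigs <- stats::setNames(
    vapply(1:4, function(i) paste(sample(c("A", "C", "G", "T"), 1500,
                                         replace = TRUE), collapse = ""), ""),
    paste0("junk", 1:4))
  hits <- translated_search(contigs, panel, min_score = min_half_self, sc)
  expect_equal(nrow(hits), 0L)
})

test_that("hydropathy helix calling matches hand-computed runs", {
  p <- paste0(strrep("D", 10), strrep("L", 25), strrep("D", 10))
  h <- predict_tm_helices(p)
  expect_equal(nrow(h), 1L)
  expect_equal(nrow(predict_tm_helices(strrep("D", 60))), 0L)
  expect_warning(out <- predict_tm_helices("MKWV"), "shorter")
  expect_equal(nrow(out), 0L)
})

test_that("the anchor rhodopsin shows seven transmembrane helices", {
  h <- predict_tm_helices(anchor_protein())
  expect_equal(nrow(h), 7L)
  # intervals are disjoint and sorted
  expect_true(all(diff(h$start) > 0))
  expect_true(all(h$start[-1L] > h$end[-nrow(h)]))
})

test_that("fragment merging follows the non-overlap rule", {
  loci <- data.frame(
    contig_id = c("c1", "c2"), frame = c(1L, 1L),
    contig_start = c(1L, 1L), contig_end = c(333L, 333L),
    reference_name = "refA",
    ref_start = c(10L, 200L), ref_end = c(120L, 310L),
    score = c(100, 90), protein = c("M", "M"), stringsAsFactors = FALSE)
  merged <- merge_nonoverlapping_fragments(loci)
  expect_length(merged, 1L)
  expect_equal(nrow(merged[[1L]]$fragments), 2L)

  loci$ref_start <- c(10L, 150L); loci$ref_end <- c(200L, 310L)
  expect_length(merge_nonoverlapping_fragments(loci), 2L)

  loci$reference_name <- c("refA", "refB")
  loci$ref_start <- c(10L, 200L); loci$ref_end <- c(120L, 310L)
  expect_length(merge_nonoverlapping_fragments(loci), 2L)
})

test_that("merging groups fragments without losing any", {
  set.seed(202)
  for (trial in 1:20) {
    n <- sample(2:8, 1)
    starts <- sample(1:300, n)
    loci <- data.frame(
      contig_id = paste0("c", seq_len(n)), frame = 1L,
      contig_start = 1L, contig_end = 100L,
      reference_name = sample(c("r1", "r2"), n, replace = TRUE),
      ref_start = starts, ref_end = starts + sample(20:120, n, replace = TRUE),
      score = runif(n, 60, 300), protein = "M", stringsAsFactors = FALSE)
    merged <- merge_nonoverlapping_fragments(loci)
    expect_equal(sum(vapply(merged, function(m) nrow(m$fragments), 1L)),
                 nrow(loci))
    expect_lte(length(merged), nrow(loci))
    for (m in merged) {
      cov <- m$reference_coverage
      if (nrow(cov) > 1L) {
        o <- order(cov[, "start"])
        expect_true(all(cov[o, "start"][-1L] > cov[o, "end"][-nrow(cov)]))
      }
    }
  }
})

test_that("reciprocal best hit confirms opsins and rejects decoy GPCRs", {
  decoys <- decoy_gpcr_panel()
  # a verbatim panel member is its own best reference, confirmed
  r <- reciprocal_best_hit(panel$protein[panel$name == "Sp-opsin 4"],
                           panel, decoys, sc)
  expect_true(r$rbh_confirmed)
  expect_equal(r$best_reference, "Sp-opsin 4")
  # a melatonin-receptor-like candidate is rejected by the reverse search
  cand <- withr::with_seed(7, opsinminer:::mutate_protein(decoys[[1L]], 0.2))
  r2 <- reciprocal_best_hit(cand, panel, decoys, sc)
  expect_false(r2$rbh_confirmed)
  expect_equal(r2$reverse_top, "melatonin-receptor-like-synthetic")
  expect_error(reciprocal_best_hit("", panel, decoys, sc), "empty")
})

test_that("diverged rhabdomeric candidates stay confirmed with the right family", {
  decoys <- decoy_gpcr_panel()
  ok <- 0L
  set.seed(203)
  for (i in 1:20) {
    cand <- opsinminer:::mutate_protein(
      panel$protein[panel$name == "Sp-opsin 4"], 0.2)
    r <- reciprocal_best_hit(cand, panel, decoys, sc)
    fam <- panel$family[match(r$best_reference, panel$name)]
    if (r$rbh_confirmed && fam == "rhabdomeric") ok <- ok + 1L
  }
  expect_gte(ok, 19L)
})

test_that("candidate tables and GFF3 round out the mining surface", {
  asm <- generate_assembly(default_gene_set()[c(2, 11)], panel = panel,
                           seed = 5)
  cands <- mine_candidates(asm$contigs, panel)
  tab <- candidate_table(cands)
  expect_true(all(c("name", "contig", "start", "end", "frame",
                    "best_reference", "score", "rbh", "tm_count") %in%
                    names(tab)))
  expect_equal(nrow(tab), 3L)   # one single-fragment gene + one split gene
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_candidate_gff3(cands, gff)
  lines <- readLines(gff)
  expect_true(any(grepl("protein_match", lines)))
  reread <- rtracklayer::import(gff)
  expect_equal(length(reread), nrow(tab))
  expect_equal(GenomicRanges::start(reread), tab$start)
  expect_equal(GenomicRanges::end(reread), tab$end)
})
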