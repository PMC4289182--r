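panel <- test_panel()
sc <- scoring_scheme()
scheme <- diagnostic_scheme()

test_that("generation is byte-identical under a fixed seed", {
  a1 <- generate_assembly(seed = 9, panel = panel)
  a2 <- generate_assembly(seed = 9, panel = panel)
  expect_identical(a1$contigs, a2$contigs)
  expect_identical(a1$truth, a2$truth)
  expect_identical(generate_transcripts(a1, seed = 9),
                   generate_transcripts(a2, seed = 9))
  expect_identical(generate_behaviour_counts(seed = 9),
                   generate_behaviour_counts(seed = 9))
  a3 <- generate_assembly(seed = 10, panel = panel)
  expect_false(identical(a1$contigs, a3$contigs))
})

test_that("zero divergence with no knockouts round-trips the exemplar", {
  gs <- gene_spec("g", "rhabdomeric", divergence = 0,
                  c113 = "Y", triad = "HPK")
  g <- withr::with_seed(11, generate_opsin_gene(gs, panel, scheme, sc))
  expect_equal(g$protein, panel$protein[panel$name == "Sp-opsin 4"])
  # back-translation re-translates to the same protein
  aa <- unname(translate_six_frames(g$fragments[[1L]]$cds)["+1"])
  expect_equal(aa, g$protein)
})

test_that("a Schiff-base knockout yields a non-bona-fide gene by construction", {
  gs <- gene_spec("g", "neuropsin", schiff = "R")
  g <- withr::with_seed(12, generate_opsin_gene(gs, panel, scheme, sc))
  rep <- diagnose_candidates(c(g = g$protein), panel, scheme, sc)[[1L]]
  expect_equal(rep$bona_fide, "false")
})

test_that("contradictory fragment intervals are rejected", {
  expect_error(gene_spec("g", "RGR", split_at = list(c(10L, 200L),
                                                     c(150L, 300L))),
               "disjoint")
})

test_that("embedded genes re-extract verbatim from their contigs", {
  asm <- generate_assembly(seed = 13, panel = panel)
  tr <- asm$truth[asm$truth$kind == "opsin", ]
  for (i in seq_len(nrow(tr))) {
    sub <- substr(asm$contigs[[tr$contig[i]]], tr$start[i], tr$end[i])
    if (tr$strand[i] == "-") sub <- reverse_complement(sub)
    aa <- unname(translate_six_frames(paste0(sub, "AAA"))["+1"])
    expect_equal(substr(aa, 1, nchar(tr$protein[i])), tr$protein[i],
                 info = paste(tr$name[i], tr$fragment[i]))
  }
})

test_that("split genes are reunited by the non-overlap merge", {
  asm <- generate_assembly(seed = 14, panel = panel)
  cands <- mine_candidates(asm$contigs, panel)
  split_contigs <- asm$truth$contig[asm$truth$name == "gene07"]
  expect_length(split_contigs, 2L)
  holder <- Filter(function(cd) any(cd$fragments$contig_id %in%
                                      split_contigs), cands)
  expect_length(holder, 1L)
  expect_equal(sort(holder[[1L]]$fragments$contig_id), sort(split_contigs))
})

test_that("the default gene set carries the intended motif census", {
  specs <- default_gene_set()
  expect_length(specs, 13L)
  expect_equal(sum(vapply(specs, function(s) s$schiff == "K", TRUE)), 11L)
  expect_equal(sum(vapply(specs, function(s) s$c181 == "E", TRUE)), 8L)
  expect_equal(sum(vapply(specs, function(s) s$c113 == "Y", TRUE)), 4L)
  expect_equal(sum(vapply(specs, function(s) s$family == "rhabdomeric",
                          TRUE)), 6L)
  expect_equal(sum(vapply(specs, function(s) s$expressed, TRUE)), 3L)
})

test_that("transcript noise perturbs the emitted CDS at the stated rate", {
  asm <- generate_assembly(seed = 15, panel = panel)
  clean <- generate_transcripts(asm, noise = 0, seed = 15)
  noisy <- generate_transcripts(asm, noise = 0.05, seed = 15)
  expect_equal(names(clean), names(noisy))
  rates <- vapply(names(clean), function(nm) {
    a <- strsplit(clean[[nm]], "")[[1L]]
    b <- strsplit(noisy[[nm]], "")[[1L]]
    mean(a != b)
  }, numeric(1L))
  expect_true(all(rates > 0.02 & rates < 0.09))
})

test_that("behaviour counts respect the two-arms-per-animal bound", {
  beh <- generate_behaviour_counts(seed = 16)
  expect_true(all(beh$arm_count >= 0))
  expect_true(all(beh$arm_count <= 36))
  expect_setequal(unique(beh$treatment),
                  c("white", "green", "blue", "red", "none"))
  expect_equal(nrow(beh), 5L * 2L * 8L * 2L)
  # zero effect makes day and night exchangeable in distribution
  null <- generate_behaviour_counts(effects = c(none = 0), seed = 17)
  expect_lt(abs(mean(null$arm_count[null$phase == "day"]) -
                  mean(null$arm_count[null$phase == "night"])), 2.5)
})
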