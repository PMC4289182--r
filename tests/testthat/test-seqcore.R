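sc <- scoring_scheme()

test_that("reverse complement follows the Watson-Crick table and is an involution", {
  expect_equal(reverse_complement("ACGT"), "ACGT")
  expect_equal(reverse_complement("AAAC"), "GTTT")
  expect_equal(reverse_complement("ANT"), "ANT")
  expect_error(reverse_complement("ACGU"), "invalid nucleotide 'U' at position 4")
  set.seed(101)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), sample(3:40, 1),
                      replace = TRUE), collapse = "")
    expect_equal(reverse_complement(reverse_complement(s)), s)
  }
})

test_that("six-frame translation uses the standard code and drops partial codons", {
  fr <- translate_six_frames("ATGAAATAG")
  expect_length(fr, 6L)
  expect_equal(unname(fr["+1"]), "MK*")
  expect_equal(unname(translate_six_frames("ATG")["-1"]), "H")  # revcomp CAT
  expect_error(translate_six_frames("AT"), "shorter than one codon")
  # codons containing N are never called as residues
  expect_equal(unname(translate_six_frames("ATNAAA")["+1"]), "XK")
})

test_that("frame sets of a sequence and its reverse complement are permutations", {
  set.seed(102)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(9:60, 1),
                      replace = TRUE), collapse = "")
    f1 <- translate_six_frames(s)
    f2 <- translate_six_frames(reverse_complement(s))
    expect_setequal(unname(f1), unname(f2))
  }
})

test_that("global alignment reproduces hand-derived scores", {
  aln <- global_align("MKVI", "MKVI", sc)
  expect_equal(aln$score, 18)   # 5 + 5 + 4 + 4 on the BLOSUM62 diagonal
  expect_equal(aln$aligned_query, "MKVI")
  expect_equal(aln$query_span, c(1L, 4L))
  aln2 <- global_align("MK", "MK", sc)
  expect_equal(aln2$aligned_query, "MK")   # gapless optimum for identical strings
  expect_error(global_align("", "MK", sc), "empty")
})

test_that("local alignment returns the empty alignment when nothing scores positive", {
  aln <- local_align("KKKK", "LLLL", sc)   # K/L scores -2
  expect_equal(aln$score, 0)
  expect_equal(aln$aligned_query, "")
  expect_true(all(is.na(aln$query_span)))
})

test_that("a sequence embedded verbatim is found with its exact span and self-score", {
  inner <- "MKWVRQDEL"
  outer <- paste0("GGG", inner, "PPPP")
  aln <- local_align(inner, outer, sc)
  self <- sum(diag(sc$matrix[strsplit(inner, "")[[1L]],
                             strsplit(inner, "")[[1L]]]))
  expect_equal(aln$score, self)
  expect_equal(aln$subject_span, c(4L, 4L + nchar(inner) - 1L))
  expect_equal(aln$query_span, c(1L, nchar(inner)))
})

test_that("DP scores match the exhaustive matching oracle on short random pairs", {
  set.seed(103)
  for (trial in 1:60) {
    a <- random_aa_string(sample(1:8, 1))
    b <- random_aa_string(sample(1:8, 1))
    expect_equal(global_align(a, b, sc)$score,
                 oracle_align_score(a, b, sc, "global"),
                 info = paste(a, b, "global"))
    expect_equal(local_align(a, b, sc)$score,
                 oracle_align_score(a, b, sc, "local"),
                 info = paste(a, b, "local"))
  }
})

test_that("self-alignment scores the diagonal sum with 100% identity", {
  set.seed(104)
  for (i in 1:10) {
    a <- random_aa_string(sample(5:30, 1))
    aln <- global_align(a, a, sc)
    expect_equal(aln$score,
                 sum(diag(sc$matrix[strsplit(a, "")[[1L]],
                                    strsplit(a, "")[[1L]]])))
    pct <- percent_identity_and_similarity(aln, sc)
    expect_equal(unname(pct["identity"]), 100)
    expect_equal(unname(pct["similarity"]), 100)
  }
})

test_that("identity and similarity follow the column-counting rules", {
  # I vs L are different residues in the same aliphatic group
  aln <- global_align("I", "L", sc)
  pct <- percent_identity_and_similarity(aln, sc)
  expect_equal(unname(pct["identity"]), 0)
  expect_equal(unname(pct["similarity"]), 100)
  # one gap column out of 10, 9 identical -> identity 90
  aln10 <- structure(list(query_id = "q", subject_id = "s",
                          aligned_query = "MKWVRQDELA",
                          aligned_subject = "MKWVRQDEL-",
                          score = 0, mode = "global",
                          query_span = c(1L, 10L), subject_span = c(1L, 9L),
                          query_idx = 1:10,
                          subject_idx = c(1:9, 0L)),
                     class = "pairwise_alignment")
  pct10 <- percent_identity_and_similarity(aln10, sc)
  expect_equal(unname(pct10["identity"]), 90)
  expect_error(percent_identity_and_similarity(local_align("KKKK", "LLLL", sc), sc),
               "undefined")
})

test_that("similarity never falls below identity", {
  set.seed(105)
  for (i in 1:40) {
    a <- random_aa_string(sample(4:25, 1))
    b <- random_aa_string(sample(4:25, 1))
    aln <- global_align(a, b, sc)
    pct <- percent_identity_and_similarity(aln, sc)
    expect_gte(pct[["similarity"]], pct[["identity"]])
    expect_gte(local_align(a, b, sc)$score, 0)
  }
})

test_that("molecular weight sums average residue masses plus one water", {
  expect_equal(molecular_weight("G"), 75.07, tolerance = 1e-3)
  expect_equal(molecular_weight("GG"), 132.12, tolerance = 1e-3)
  expect_error(molecular_weight(""), "empty")
  expect_error(molecular_weight("GX"), "invalid residue")
  # cross-check against an independent implementation
  skip_if_not_installed("seqinr")
  set.seed(106)
  for (i in 1:10) {
    p <- random_aa_string(sample(10:60, 1))
    expect_equal(molecular_weight(p), seqinr::pmw(strsplit(p, "")[[1L]]),
                 tolerance = 1e-2)
  }
})

test_that("FASTA round-trips preserve ids and sequences", {
  x <- c(rec1 = "MKWVRQDELAMKWVRQDELAMKWVRQDELAMKWVRQDELAMKWVRQDELAMKWVRQDELAPPP",
         rec2 = "ACDEFGHIKL")
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(x, path)
  expect_equal(read_fasta(path), x)
  # wrapped at 60 columns
  expect_true(max(nchar(readLines(path))) <= 60)
})

test_that("scoring schemes validate their invariants", {
  expect_error(scoring_scheme(gap_open = 0.2, gap_extend = 0.5))
  bad_groups <- default_similarity_groups()
  bad_groups$small <- c("G", "A", "S")   # drops T from the cover
  expect_error(scoring_scheme(similarity_groups = bad_groups), "cover")
  s2 <- scoring_scheme()
  expect_equal(unname(s2$matrix["X", "W"]), 0)   # X is scored neutral
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1),
                   path)
  s3 <- read_scoring_scheme(path)
  expect_equal(s3$gap_open, 11)
})
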