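panel <- test_panel()
sc <- scoring_scheme()

test_that("a verbatim panel member scores 100 in its own column", {
  sim <- build_similarity_matrix(
    c(q = panel$protein[panel$name == "Sp-opsin 4"]), panel, sc)
  expect_equal(unname(sim["q", "Sp-opsin 4"]), 100)
  # no positive-scoring alignment -> flagged NA
  sim2 <- build_similarity_matrix(c(q = strrep("K", 12)),
                                  panel[panel$name == "Sp-opsin 4", ], sc)
  expect_true(is.na(sim2["q", 1L]) ||
                attr(sim2, "aligned_len")["q", 1L] > 0)
})

test_that("a hand-built gapless 40-residue pair gives 87.5% similarity", {
  a <- strsplit(paste0("MKWVRQDELH", "MKWVRQDELH", "MKWVRQDELH",
                       "MKWVRQDELH"), "")[[1L]]
  b <- a
  b[11:15] <- c("L", "R", "F", "I", "K")   # M>L, K>R, W>F, V>I, R>K in-group
  b[21:25] <- c("D", "E", "G", "C", "P")   # dissimilar to M, K, W, V, R
  a <- paste(a, collapse = "")
  b <- paste(b, collapse = "")
  aln <- local_align(a, b, sc)
  expect_equal(aln$query_span, c(1L, 40L))
  expect_false(grepl("-", aln$aligned_query, fixed = TRUE))
  pct <- percent_identity_and_similarity(aln, sc)
  expect_equal(unname(pct["similarity"]), 87.5)   # (30 + 5) / 40
  expect_equal(unname(pct["identity"]), 75)
})

fake_call <- function(name, ref, sim) {
  structure(list(candidate_name = name,
                 evidence = list(best_similarity_reference = ref,
                                 best_similarity = sim)),
            class = "family_call")
}

test_that("family assignment weighs similarity and triad evidence", {
  sim <- matrix(40, nrow = 1L, ncol = nrow(panel),
                dimnames = list("cand", panel$name))
  sim[1, "Sp-opsin 4"] <- 80
  rep_hxk <- structure(list(triad_class = "rhabdomeric"),
                       class = "motif_report")
  fc <- assign_family("cand", sim, panel, rep_hxk)
  expect_equal(fc$family, "rhabdomeric")
  expect_equal(fc$confidence, "consistent")

  sim[1, "Sp-opsin 4"] <- 40
  sim[1, "Sp-opsin 1"] <- 80
  rep_nxq <- structure(list(triad_class = "ciliary"), class = "motif_report")
  fc2 <- assign_family("cand", sim, panel, rep_nxq)
  expect_equal(fc2$family, "ciliary")
  expect_equal(fc2$confidence, "consistent")

  sim[1, "Sp-opsin 1"] <- 40
  sim[1, "Sp-opsin 8"] <- 80
  fc3 <- assign_family("cand", sim, panel, rep_nxq)
  expect_equal(fc3$family, "neuropsin")
  expect_equal(fc3$confidence, "ambiguous")   # ciliary triad disagrees

  # the anchor never wins even at similarity 100
  sim[1, "Rn-rhodopsin"] <- 100
  expect_equal(assign_family("cand", sim, panel, NULL)$family, "neuropsin")
  expect_error(assign_family("missing", sim, panel), "absent")
})

test_that("naming follows the Sp numbering with .1/.2 by descending similarity", {
  calls <- list(fake_call("a", "Sp-opsin 8", 70),
                fake_call("b", "Sp-opsin 8", 85),
                fake_call("c", "Sp-opsin 7", 66))
  nm <- name_candidates(calls)
  expect_equal(nm, c("opsin 8.2", "opsin 8.1", "opsin 7"))

  six <- lapply(1:6, function(i) fake_call(letters[i], "Sp-opsin 4", 90 - i))
  expect_equal(name_candidates(six),
               paste0("opsin 4.", 1:6))
  # deterministic: same input, same names
  expect_equal(name_candidates(six), name_candidates(six))
})

test_that("core truncation keeps reference positions 68-357 and insertions", {
  cfg <- phylo_config(bootstrap_reps = 10L)
  sp1 <- panel$protein[panel$name == "Sp-opsin 1"]
  core <- truncate_to_core(c(`Sp-1` = sp1), cfg, panel, sc)
  expect_equal(nchar(core[["Sp-1"]]), 290L)   # 357 - 68 + 1
  expect_equal(core[["Sp-1"]], substr(sp1, 68, 357))

  expect_warning(
    out <- truncate_to_core(c(short = substr(sp1, 1, 60)), cfg, panel, sc),
    "no core overlap")
  expect_length(out, 0L)

  with_ins <- paste0(substr(sp1, 1, 150), "GGGGG",
                     substr(sp1, 151, nchar(sp1)))
  core_ins <- truncate_to_core(c(ins = with_ins), cfg, panel, sc)
  expect_equal(nchar(core_ins[["ins"]]), 295L)   # core + 5-residue insertion
})

test_that("neighbor joining recovers additive trees exactly", {
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  # tree ((A:1,B:2):1,(C:3,D:4)) with internal edge 1
  d["A", "B"] <- d["B", "A"] <- 3
  d["A", "C"] <- d["C", "A"] <- 5
  d["A", "D"] <- d["D", "A"] <- 6
  d["B", "C"] <- d["C", "B"] <- 6
  d["B", "D"] <- d["D", "B"] <- 7
  d["C", "D"] <- d["D", "C"] <- 7
  tr <- nj_from_dist(d)
  expect_equal(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)], d,
               tolerance = 1e-10)
  # cherry (A,B) present
  splits <- ape::prop.part(tr)
  expect_true(any(vapply(splits, function(s)
    setequal(tr$tip.label[s], c("A", "B")) ||
      setequal(tr$tip.label[s], c("C", "D")), logical(1L))))
})

test_that("three sequences give the unique unrooted topology and duplicates a zero cherry", {
  seqs <- c(a = "MKWVRQDELHMKWVRQDELH", b = "MKWVRQDELHMKWVRQAAAA",
            c = "MKWVAADELHMKWVRQDELH")
  tr <- nj_tree(seqs, sc)
  expect_equal(ape::Ntip(tr), 3L)
  seqs4 <- c(seqs, d = unname(seqs["a"]))
  tr4 <- nj_tree(seqs4, sc)
  dd <- ape::cophenetic.phylo(tr4)
  expect_equal(unname(dd["a", "d"]), 0, tolerance = 1e-10)
  expect_error(nj_tree(seqs[1:2], sc), ">= 3")
})

test_that("perfectly congruent signal earns full bootstrap support", {
  cfg <- phylo_config(bootstrap_reps = 100L)
  sp1 <- panel$protein[panel$name == "Sp-opsin 1"]
  sp4 <- panel$protein[panel$name == "Sp-opsin 4"]
  seqs <- withr::with_seed(31, c(
    a1 = sp1, a2 = opsinminer:::mutate_protein(sp1, 0.05),
    b1 = sp4, b2 = opsinminer:::mutate_protein(sp4, 0.05)))
  tr <- bootstrap_support(seqs, cfg, panel, seed = 5, sc = sc)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(all(stats::na.omit(sup) >= 0.99))
})

test_that("bootstrap support is reproducible under a fixed seed", {
  cfg <- phylo_config(bootstrap_reps = 50L)
  sp1 <- panel$protein[panel$name == "Sp-opsin 1"]
  seqs <- withr::with_seed(32, c(
    a = sp1, b = opsinminer:::mutate_protein(sp1, 0.2),
    c = opsinminer:::mutate_protein(sp1, 0.4),
    d = opsinminer:::mutate_protein(sp1, 0.6)))
  t1 <- bootstrap_support(seqs, cfg, panel, seed = 77, sc = sc)
  t2 <- bootstrap_support(seqs, cfg, panel, seed = 77, sc = sc)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
})

test_that("leave-one-out classification recovers families with multiple exemplars", {
  for (nm in c("Sp-opsin 3.1", "Sp-opsin 3.2")) {
    rest <- panel[panel$name != nm, ]
    class(rest) <- class(panel)
    sim <- build_similarity_matrix(
      stats::setNames(panel$protein[panel$name == nm], nm), rest, sc)
    fc <- assign_family(nm, sim, rest)
    expect_equal(fc$family, "Go", info = nm)
  }
})
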