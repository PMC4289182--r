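panel <- test_panel()
sc <- scoring_scheme()
scheme <- diagnostic_scheme()
anchor <- anchor_protein()

test_that("the anchor maps onto itself as the identity with K at 296", {
  map <- map_to_anchor(anchor, anchor, sc)
  expect_equal(map$pairs$candidate_pos, map$pairs$anchor_pos)
  i <- match(296L, map$pairs$anchor_pos)
  expect_equal(map$pairs$candidate_pos[i], 296L)
  expect_equal(substr(anchor, 296, 296), "K")
  expect_true(all(diff(map$pairs$candidate_pos) > 0))
  expect_true(all(diff(map$pairs$anchor_pos) > 0))
})

test_that("an N-terminal deletion shifts the map by its length", {
  trimmed <- substr(anchor, 11, nchar(anchor))
  map <- map_to_anchor(trimmed, anchor, sc)
  i <- match(296L, map$pairs$anchor_pos)
  expect_equal(map$pairs$candidate_pos[i], 286L)
})

test_that("a fragment covers only its anchor interval", {
  frag <- substr(anchor, 1, 100)
  map <- map_to_anchor(frag, anchor, sc)
  expect_true(all(map$coverage <= 100L))
  expect_false(296L %in% map$coverage)
})

test_that("full diagnostics on the anchor call every site present", {
  rep <- diagnose_candidates(c(anchor = anchor), panel, scheme, sc)[[1L]]
  expect_equal(rep$schiff_base, "present")
  expect_equal(rep$counterion_113_type, "vertebrate")
  expect_equal(rep$counterion_181, "present")
  expect_equal(rep$dry, "present")
  expect_equal(rep$npxxy, "present")
  expect_equal(rep$triad_class, "ciliary")   # NKQ
  expect_equal(rep$disulfide, "present")
  expect_equal(rep$palmitoylation, "present")
  expect_equal(rep$bona_fide, "true")
})

test_that("triad classes resolve from the mapped 310/312 residues", {
  put <- function(p, pos, res) {
    ch <- strsplit(p, "")[[1L]]
    ch[pos] <- strsplit(res, "")[[1L]]
    paste(ch, collapse = "")
  }
  hxk <- put(anchor, 310:312, "HPK")
  rep <- diagnose_candidates(c(x = hxk), panel, scheme, sc)[[1L]]
  expect_equal(rep$triad_class, "rhabdomeric")
  hxs <- put(anchor, 310:312, "HPS")
  expect_equal(diagnose_candidates(c(x = hxs), panel, scheme,
                                   sc)[[1L]]$triad_class, "derived")
  oth <- put(anchor, 310:312, "SGT")
  expect_equal(diagnose_candidates(c(x = oth), panel, scheme,
                                   sc)[[1L]]$triad_class, "other")
})

test_that("bona fide status follows the Schiff-base rule", {
  ch <- strsplit(anchor, "")[[1L]]
  ch[296] <- "R"
  mutated <- paste(ch, collapse = "")
  rep <- diagnose_candidates(c(x = mutated), panel, scheme, sc)[[1L]]
  expect_equal(rep$bona_fide, "false")
  expect_match(rep$schiff_base, "^absent")
  frag <- substr(anchor, 1, 250)
  rep2 <- diagnose_candidates(c(x = frag), panel, scheme, sc)[[1L]]
  expect_equal(rep2$schiff_base, "not_covered")
  expect_equal(rep2$bona_fide, "indeterminate")
})

test_that("insertions between mapped sites do not break the NPxxY(x)6F call", {
  # 4-residue insertion between P303 and Y306 equivalents
  with_ins <- paste0(substr(anchor, 1, 304), "GGGG",
                     substr(anchor, 305, nchar(anchor)))
  rep <- diagnose_candidates(c(x = with_ins), panel, scheme, sc)[[1L]]
  expect_equal(rep$npxxy, "present")
})

test_that("synthetic motif configurations are called back exactly at zero divergence", {
  specs <- default_gene_set(divergence = 0)
  withr::with_seed(42, {
    for (gs in specs[c(1, 2, 5, 10, 12)]) {
      g <- generate_opsin_gene(gs, panel, scheme, sc)
      rep <- diagnose_candidates(
        stats::setNames(g$protein, gs$name), panel, scheme, sc)[[1L]]
      expect_equal(rep$schiff_base == "present", gs$schiff == "K",
                   info = gs$name)
      expect_equal(rep$counterion_181 == "present", gs$c181 == "E",
                   info = gs$name)
      if (gs$c113 == "Y") expect_equal(rep$counterion_113_type,
                                       "invertebrate", info = gs$name)
    }
  })
})

test_that("site-call recovery stays above 95% at 20% divergence", {
  specs <- default_gene_set(divergence = 0.2)
  n_ok <- 0L
  n_tot <- 0L
  withr::with_seed(77, {
    for (trial in 1:8) {
      for (gs in specs[c(2, 5, 7, 13)]) {
        g <- generate_opsin_gene(gs, panel, scheme, sc)
        rep <- diagnose_candidates(
          stats::setNames(g$protein, gs$name), panel, scheme, sc)[[1L]]
        checks <- c(
          (rep$schiff_base == "present") == (gs$schiff == "K"),
          (rep$counterion_181 == "present") == (gs$c181 == "E"),
          rep$counterion_113_type ==
            switch(gs$c113, E = "vertebrate", Y = "invertebrate", "other"),
          (rep$dry == "present") == gs$dry,
          (rep$npxxy == "present") == gs$npxxy,
          (rep$disulfide == "present") == gs$disulfide)
        n_ok <- n_ok + sum(checks)
        n_tot <- n_tot + length(checks)
      }
    }
  })
  expect_gte(n_ok / n_tot, 0.95)
})

test_that("a called triad implies partial NPxxY coverage", {
  frag <- substr(anchor, 250, 348)
  rep <- diagnose_candidates(c(x = frag), panel, scheme, sc)[[1L]]
  if (rep$triad_class != "not_covered") {
    expect_false(rep$npxxy == "not_covered" && rep$triad == "not_covered")
  }
  m <- motif_matrix(diagnose_candidates(
    c(a = anchor, b = frag), panel, scheme, sc))
  expect_equal(nrow(m), 2L)
  expect_true(all(c("schiff_base", "triad_class", "bona_fide") %in% names(m)))
})
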