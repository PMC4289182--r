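# Synthetic-data generator: opsin genes of chosen family / divergence /
# motif content embedded in decoy contigs, transcript copies of an
# expressed subset, and day/night behaviour count tables -- everything
# seeded and carrying ground truth.

# 348-residue mammalian-rhodopsin-like anchor (synthetic consensus; the
# diagnostic sites sit at their canonical positions: C110, E113,
# E134/R135/Y136, E181, C187, K296, N302/P303..Y306..F313 with the NKQ
# triad at 310-312, C322/C323).
ANCHOR_PROTEIN <- paste0(
  "MNGTEGPNFYVPFSNKTGVVRSPFEAPQYYLAEPWQFSMLAAYMFLLIMLGFPINFLTLY",
  "VTVQHKKLRTPLNYILLNLAVADLFMVFGGFTTTLYTSLHGYFVFGPTGCNLEGFFATLG",
  "GEIALWSLVVLAIERYVVVCKPMSNFRFGENHAIMGVAFTWVMALACAAPPLVGWSRYIP",
  "EGMQCSCGIDYYTPHEETNNESFVIYMFVVHFIIPLIVIFFCYGQLVFTVKEAAAQQQES",
  "ATTQKAEKEVTRMVIIMVIAFLICWLPYAGVAFYIFTHQGSDFGPIFMTIPAFFAKTSAV",
  "YNPVIYIMMNKQFRNCMVTTLCCGKNPLGDDEASTTVSKTETSQVAPA")

#' The synthetic anchor rhodopsin
#'
#' @return the 348-residue anchor protein string used as the residue
#'   frame for all diagnostic positions.
#' @export
anchor_protein <- function() ANCHOR_PROTEIN

# positions (anchor numbering) that carry diagnostic information and are
# spared by random divergence
scheme_positions <- function(scheme = diagnostic_scheme()) {
  sort(unique(c(scheme$schiff_base_pos, scheme$counterion_vertebrate_pos,
                scheme$counterion_ancestral_pos,
                scheme$dry_span[1L]:scheme$dry_span[2L],
                scheme$npxxy_span[1L]:scheme$npxxy_span[2L],
                scheme$disulfide_pair, scheme$palmitoylation_pair)))
}

# random substitutions at a given per-site rate, sparing `protect`
mutate_protein <- function(p, divergence, protect = integer(0)) {
  ch <- strsplit(p, "", fixed = TRUE)[[1L]]
  eligible <- setdiff(seq_along(ch), protect)
  hit <- eligible[stats::runif(length(eligible)) < divergence]
  for (i in hit) {
    ch[i] <- sample(setdiff(AA_ALPHABET, ch[i]), 1L)
  }
  paste(ch, collapse = "")
}

random_protein <- function(n) {
  paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# reverse genetic code: residue -> candidate codons
CODONS_OF <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})

#' Back-translate a protein with uniform synonymous codon choice
#'
#' @param p protein string (no stops, no `X`).
#' @return nucleotide CDS string of length `3 * nchar(p)`.
#' @export
back_translate <- function(p) {
  p <- validate_aa(p, "protein", allow_stop = FALSE, allow_x = FALSE)
  ch <- strsplit(p, "", fixed = TRUE)[[1L]]
  paste(vapply(ch, function(a) {
    cods <- CODONS_OF[[a]]
    if (length(cods) == 1L) cods else sample(cods, 1L)
  }, ""), collapse = "")
}

#' Build the synthetic reference panel
#'
#' Constructs the shipped reference panel deterministically: the anchor
#' plus nine family exemplars derived from the anchor scaffold at 35%
#' divergence away from the diagnostic sites, each carrying its
#' family-diagnostic motif states (ciliary NxQ vs rhabdomeric HxK triad,
#' vertebrate E vs invertebrate Y at 113, presence/absence of the
#' Schiff-base lysine -- the peropsin exemplar lacks it and is the
#' panel's pseudo-opsin).  The Go and basal-branch pairs are built from
#' shared family templates so that within-family similarity exceeds
#' between-family similarity.  Exemplar "Sp-opsin 1" carries 15/35
#' N-/C-terminal extension residues so that its own positions 68-357
#' (the core-truncation interval) exist.
#'
#' @param seed integer seed; the shipped fixture uses the default.
#' @return a `reference_panel` data.frame.
#' @export
build_synthetic_panel <- function(seed = 20141128L) {
  withr::with_seed(seed, {
    sch <- diagnostic_scheme()
    protect <- scheme_positions(sch)
    set_at <- function(p, pos, res) {
      ch <- strsplit(p, "", fixed = TRUE)[[1L]]
      ch[pos] <- strsplit(res, "", fixed = TRUE)[[1L]]
      paste(ch, collapse = "")
    }
    # family motif profiles applied at anchor positions
    profile <- function(p, schiff = "K", c113 = "E", c181 = "E",
                        triad = "NKQ") {
      p <- set_at(p, sch$schiff_base_pos, schiff)
      p <- set_at(p, sch$counterion_vertebrate_pos, c113)
      p <- set_at(p, sch$counterion_ancestral_pos, c181)
      p <- set_at(p, sch$triad_span[1L]:sch$triad_span[2L], triad)
      p
    }
    base <- function(div = 0.35) mutate_protein(ANCHOR_PROTEIN, div, protect)
    go_template <- base(0.30)
    exemplars <- list(
      `Sp-opsin 1`   = profile(base(), triad = "NKQ", c113 = "E"),
      `Sp-opsin 2`   = profile(base(), triad = "SGT"),
      `Sp-opsin 3.1` = profile(mutate_protein(go_template, 0.08, protect),
                               triad = "NKQ", c113 = "Y"),
      `Sp-opsin 3.2` = profile(mutate_protein(go_template, 0.08, protect),
                               triad = "NKQ", c113 = "Y"),
      `Sp-opsin 4`   = profile(base(), triad = "HPK", c113 = "Y"),
      `Sp-opsin 5`   = profile(base(), triad = "NKQ"),
      `Sp-opsin 6`   = profile(base(), schiff = "S", triad = "AGT"),
      `Sp-opsin 7`   = profile(base(), triad = "GST", c113 = "Y"),
      `Sp-opsin 8`   = profile(base(), triad = "NKQ")
    )
    # terminal extensions; Sp-opsin 1 is the core-truncation reference
    ext <- function(p, n_n, n_c) {
      paste0(random_protein(n_n), p, random_protein(n_c))
    }
    exemplars[["Sp-opsin 1"]] <- ext(exemplars[["Sp-opsin 1"]], 15L, 35L)
    for (nm in setdiff(names(exemplars), "Sp-opsin 1")) {
      exemplars[[nm]] <- ext(exemplars[[nm]], sample(0:8, 1L),
                             sample(0:8, 1L))
    }
    fam <- c(`Sp-opsin 1` = "ciliary", `Sp-opsin 2` = "basal-branch",
             `Sp-opsin 3.1` = "Go", `Sp-opsin 3.2` = "Go",
             `Sp-opsin 4` = "rhabdomeric", `Sp-opsin 5` = "basal-branch",
             `Sp-opsin 6` = "peropsin", `Sp-opsin 7` = "RGR",
             `Sp-opsin 8` = "neuropsin")
    meta <- data.frame(
      id = c("Rn-rhodopsin-synthetic",
             gsub("[ ]", "_", names(exemplars))),
      name = c("Rn-rhodopsin", names(exemplars)),
      family = c("ciliary", unname(fam[names(exemplars)])),
      is_anchor = c(TRUE, rep(FALSE, length(exemplars))),
      protein = c(ANCHOR_PROTEIN, unname(unlist(exemplars))),
      stringsAsFactors = FALSE)
    class(meta) <- c("reference_panel", "data.frame")
    meta
  })
}

#' Melatonin-receptor-like decoy GPCR panel
#'
#' A synthetic non-opsin GPCR template (anchor scaffold at 60%
#' divergence, Schiff-base lysine removed) plus unrelated random
#' proteins.  The template plays the role of the closest non-opsin GPCR
#' in the reciprocal-best-hit database: decoy-derived candidates hit it
#' in the reverse search and are rejected.
#'
#' @param n_unrelated number of unrelated random proteins to add.
#' @param seed integer seed (fixed default so that the decoy database
#'   and decoy contigs share one template).
#' @return named character vector of decoy proteins; the first element
#'   is the GPCR-like template.
#' @export
decoy_gpcr_panel <- function(n_unrelated = 3L, seed = 20141129L) {
  withr::with_seed(seed, {
    sch <- diagnostic_scheme()
    tpl <- mutate_protein(ANCHOR_PROTEIN, 0.60)
    ch <- strsplit(tpl, "", fixed = TRUE)[[1L]]
    if (ch[sch$schiff_base_pos] == "K") ch[sch$schiff_base_pos] <- "S"
    tpl <- paste(ch, collapse = "")
    out <- c("melatonin-receptor-like-synthetic" = tpl)
    for (i in seq_len(n_unrelated)) {
      out[paste0("unrelated-protein-", i)] <- random_protein(320L)
    }
    out
  })
}

#' Specification of one synthetic opsin gene
#'
#' @param name gene label in the ground truth.
#' @param family opsin family; must have a panel exemplar.
#' @param divergence per-site substitution rate applied outside the
#'   protected diagnostic positions, in `[0, 1]`.
#' @param schiff,c113,c181,triad residues installed at the
#'   anchor-equivalent diagnostic sites (`schiff = "K"` keeps the
#'   Schiff-base lysine, anything else knocks it out; `c113` is `"E"`,
#'   `"Y"` or another residue; `triad` is the 310-312 tripeptide, e.g.
#'   `"NKQ"`, `"HPK"`, `"HPS"`).
#' @param dry,npxxy,disulfide,palmitoylation keep (`TRUE`) or knock out
#'   (`FALSE`) the motif.
#' @param exemplar panel reference the gene is derived from; defaults
#'   to the first panel member of `family`.
#' @param coverage anchor interval covered by the gene (fragments of
#'   incomplete genes), 1-based inclusive; `NULL` for the full exemplar.
#' @param split_at if non-`NULL`, a pair of disjoint anchor intervals:
#'   the gene is emitted as two non-overlapping fragments (the `.A`/`.B`
#'   scenario reunited downstream by the merge rule).
#' @param expressed whether a transcript copy is emitted.
#' @return a `gene_spec` list.
#' @export
gene_spec <- function(name, family, divergence = 0.2, schiff = "K",
                      c113 = "E", c181 = "E", triad = "NKQ", dry = TRUE,
                      npxxy = TRUE, disulfide = TRUE,
                      palmitoylation = TRUE, exemplar = NULL,
                      coverage = NULL, split_at = NULL, expressed = FALSE) {
  stopifnot(divergence >= 0, divergence <= 1)
  if (!is.null(split_at)) {
    stopifnot(length(split_at) == 2L)
    a <- split_at[[1L]]; b <- split_at[[2L]]
    if (a[2L] >= b[1L]) stop("split fragments must be disjoint", call. = FALSE)
  }
  structure(list(name = name, family = family, divergence = divergence,
                 schiff = schiff, c113 = c113, c181 = c181, triad = triad,
                 dry = dry, npxxy = npxxy, disulfide = disulfide,
                 palmitoylation = palmitoylation, exemplar = exemplar,
                 coverage = coverage, split_at = split_at,
                 expressed = expressed),
            class = "gene_spec")
}

#' The default 13-gene synthetic study
#'
#' Mirrors the headline structure of a brittle-star-style opsin
#' repertoire: one ciliary gene on a short fragment missing the
#' Schiff-base site, two basal-branch genes, one Go gene, six
#' rhabdomeric genes (one with the derived HxS triad), one RGR gene
#' split into two non-overlapping fragments, and two neuropsins whose
#' Schiff-base lysine is knocked out.  Nine genes carry K296, eight
#' carry E181, four carry the invertebrate-type Y113, and three genes
#' (one basal-branch, one rhabdomeric, one neuropsin) are expressed.
#'
#' @param divergence per-site divergence applied to every gene.
#' @return list of [gene_spec()]s.
#' @export
default_gene_set <- function(divergence = 0.2) {
  g <- function(...) gene_spec(..., divergence = divergence)
  list(
    g("gene01", "ciliary", coverage = c(60L, 250L)),
    g("gene02", "basal-branch", c181 = "Q", triad = "SGT", dry = FALSE,
      disulfide = FALSE, expressed = TRUE),
    g("gene03", "Go", c181 = "Q", triad = "NKQ", npxxy = FALSE,
      disulfide = FALSE, exemplar = "Sp-opsin 3.1"),
    g("gene04.1", "rhabdomeric", triad = "HPS", npxxy = FALSE, dry = FALSE),
    g("gene04.2", "rhabdomeric", c113 = "Y", triad = "HPK"),
    g("gene04.3", "rhabdomeric", triad = "SGT", npxxy = FALSE, dry = FALSE,
      disulfide = FALSE),
    g("gene04.4", "rhabdomeric", c113 = "Y", triad = "HPK"),
    g("gene04.5", "rhabdomeric", c181 = "Q", triad = "HPK", dry = FALSE,
      disulfide = FALSE, expressed = TRUE),
    g("gene04.6", "rhabdomeric", c181 = "Q", triad = "HPK", dry = FALSE,
      disulfide = FALSE),
    g("gene05", "basal-branch", c113 = "Y", triad = "NKQ",
      exemplar = "Sp-opsin 5"),
    g("gene07", "RGR", c113 = "Y", split_at = list(c(68L, 205L),
                                                   c(245L, 292L))),
    g("gene08.1", "neuropsin", schiff = "R", c181 = "Q", triad = "SGT"),
    g("gene08.2", "neuropsin", schiff = "R", triad = "NKQ",
      expressed = TRUE)
  )
}

# exemplar protein for a family (first panel member of that family,
# anchor and outgroup excluded)
family_exemplar <- function(panel, family) {
  cand <- panel[!panel$is_anchor & panel$family == family, , drop = FALSE]
  if (nrow(cand) == 0L) {
    stop("no panel exemplar for family ", family, call. = FALSE)
  }
  cand[1L, ]
}

#' Generate one synthetic opsin gene
#'
#' Starts from the family exemplar protein, applies random divergence
#' sparing the diagnostic sites, installs the requested motif states at
#' the anchor-equivalent positions, restricts to the requested anchor
#' coverage (or splits into two disjoint fragments), and back-translates
#' each fragment with uniform codon choice.
#'
#' @param spec a [gene_spec()].
#' @param panel a `reference_panel`.
#' @param scheme a [diagnostic_scheme()].
#' @param sc a [scoring_scheme()].
#' @return list with `fragments` (list of `list(protein, cds,
#'   anchor_range)`), `protein` (full mutated protein) and `truth` (the
#'   spec).  Not seeded itself; call inside `withr::with_seed()` or via
#'   [generate_assembly()].
#' @export
generate_opsin_gene <- function(spec, panel, scheme = diagnostic_scheme(),
                                sc = scoring_scheme()) {
  ex <- if (!is.null(spec$exemplar)) {
    hit <- panel[panel$name == spec$exemplar, , drop = FALSE]
    if (nrow(hit) == 0L) stop("exemplar not in panel: ", spec$exemplar,
                              call. = FALSE)
    hit
  } else {
    family_exemplar(panel, spec$family)
  }
  anchor <- panel_anchor(panel)$protein
  map <- map_to_anchor(ex$protein, anchor, sc)
  # exemplar position of each anchor position (NA if unmapped)
  pos_of <- function(anchor_pos) {
    i <- match(anchor_pos, map$pairs$anchor_pos)
    map$pairs$candidate_pos[i]
  }
  ch <- strsplit(ex$protein, "", fixed = TRUE)[[1L]]
  protect <- stats::na.omit(pos_of(scheme_positions(scheme)))
  eligible <- setdiff(seq_along(ch), protect)
  hit <- eligible[stats::runif(length(eligible)) < spec$divergence]
  for (i in hit) ch[i] <- sample(setdiff(AA_ALPHABET, ch[i]), 1L)
  put <- function(anchor_pos, res) {
    p <- pos_of(anchor_pos)
    ok <- !is.na(p)
    ch[p[ok]] <<- strsplit(res, "", fixed = TRUE)[[1L]][ok]
  }
  put(scheme$schiff_base_pos, spec$schiff)
  put(scheme$counterion_vertebrate_pos, spec$c113)
  put(scheme$counterion_ancestral_pos, spec$c181)
  put(scheme$triad_span[1L]:scheme$triad_span[2L], spec$triad)
  if (spec$dry) put(scheme$dry_span[1L]:scheme$dry_span[2L], "ERY")
  else put(scheme$dry_span[1L], "G")
  if (spec$npxxy) {
    np <- scheme$npxxy_span
    put(np[1L], "N"); put(np[1L] + 1L, "P")
    put(np[1L] + 4L, "Y"); put(np[2L], "F")
  } else {
    put(scheme$npxxy_span[1L] + 4L, "L")   # break the Y306-equivalent
  }
  if (spec$disulfide) {
    put(scheme$disulfide_pair[1L], "C"); put(scheme$disulfide_pair[2L], "C")
  } else {
    put(scheme$disulfide_pair[1L], "A")
  }
  if (spec$palmitoylation) {
    put(scheme$palmitoylation_pair[1L], "C")
    put(scheme$palmitoylation_pair[2L], "C")
  } else {
    put(scheme$palmitoylation_pair[1L], "A")
  }
  protein <- paste(ch, collapse = "")

  # cut fragments by anchor coverage
  cut_range <- function(rng) {
    inmap <- map$pairs$anchor_pos >= rng[1L] & map$pairs$anchor_pos <= rng[2L]
    if (!any(inmap)) stop("empty coverage for gene ", spec$name, call. = FALSE)
    idx <- range(map$pairs$candidate_pos[inmap])
    substr(protein, idx[1L], idx[2L])
  }
  ranges <- if (!is.null(spec$split_at)) {
    spec$split_at
  } else if (!is.null(spec$coverage)) {
    list(spec$coverage)
  } else {
    list(NULL)
  }
  fragments <- lapply(ranges, function(rng) {
    p <- if (is.null(rng)) protein else cut_range(rng)
    list(protein = p, cds = back_translate(p), anchor_range = rng)
  })
  list(fragments = fragments, protein = protein, truth = spec)
}

#' Generate a synthetic assembly with ground truth
#'
#' Each gene fragment is back-translated and embedded at a random
#' position and strand in its own background contig of uniform random
#' nucleotides; decoy GPCR sequences (25%-diverged copies of the
#' melatonin-receptor-like template) and pure background contigs are
#' added likewise.
#'
#' @param genes list of [gene_spec()]s, e.g. [default_gene_set()].
#' @param panel a `reference_panel`.
#' @param seed integer seed; fully determines the output.
#' @param n_decoy_gpcrs,n_background_contigs counts of decoy and pure
#'   background contigs.
#' @param background_len length of pure background contigs (nt).
#' @param flank total random flank added around each insert (nt).
#' @param scheme,sc diagnostic scheme and scoring scheme.
#' @return list with `contigs` (named character vector), `truth`
#'   (data.frame of embedded inserts: contig, kind, name, fragment,
#'   strand, start, end, protein) and `genes` (the generated gene
#'   objects, named by gene).
#' @export
generate_assembly <- function(genes = default_gene_set(), panel = NULL,
                              seed = 1L, n_decoy_gpcrs = 3L,
                              n_background_contigs = 4L,
                              background_len = 1500L, flank = 600L,
                              scheme = diagnostic_scheme(),
                              sc = scoring_scheme()) {
  if (is.null(panel)) panel <- reference_panel()
  withr::with_seed(as.integer(seed) , {
    contigs <- character(0)
    truth <- list()
    gene_objs <- list()
    embed <- function(cds, label) {
      pre <- sample.int(flank, 1L)
      post <- flank - pre + 1L
      strand <- sample(c("+", "-"), 1L)
      ins <- if (strand == "+") cds else {
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
      }
      contig <- paste0(random_dna(pre), ins, random_dna(post))
      list(contig = contig, strand = strand, start = pre + 1L,
           end = pre + nchar(cds))
    }
    ci <- 0L
    for (gs in genes) {
      gobj <- generate_opsin_gene(gs, panel, scheme, sc)
      gene_objs[[gs$name]] <- gobj
      for (k in seq_along(gobj$fragments)) {
        fr <- gobj$fragments[[k]]
        ci <- ci + 1L
        cid <- sprintf("contig%03d", ci)
        e <- embed(fr$cds, gs$name)
        contigs[cid] <- e$contig
        truth[[length(truth) + 1L]] <- data.frame(
          contig = cid, kind = "opsin", name = gs$name,
          fragment = if (length(gobj$fragments) > 1L) LETTERS[k] else "",
          family = gs$family, expressed = gs$expressed,
          strand = e$strand, start = e$start, end = e$end,
          protein = fr$protein, stringsAsFactors = FALSE)
      }
    }
    decoys <- decoy_gpcr_panel()
    tpl <- decoys[[1L]]
    for (d in seq_len(n_decoy_gpcrs)) {
      ci <- ci + 1L
      cid <- sprintf("contig%03d", ci)
      dp <- mutate_protein(tpl, 0.25)
      e <- embed(back_translate(dp), "decoy")
      contigs[cid] <- e$contig
      truth[[length(truth) + 1L]] <- data.frame(
        contig = cid, kind = "decoy", name = sprintf("decoy%02d", d),
        fragment = "", family = "", expressed = FALSE,
        strand = e$strand, start = e$start, end = e$end,
        protein = dp, stringsAsFactors = FALSE)
    }
    for (b in seq_len(n_background_contigs)) {
      ci <- ci + 1L
      cid <- sprintf("contig%03d", ci)
      contigs[cid] <- random_dna(background_len)
      truth[[length(truth) + 1L]] <- data.frame(
        contig = cid, kind = "background", name = sprintf("bg%02d", b),
        fragment = "", family = "", expressed = FALSE,
        strand = "", start = NA_integer_, end = NA_integer_,
        protein = "", stringsAsFactors = FALSE)
    }
    list(contigs = contigs, truth = do.call(rbind, truth),
         genes = gene_objs)
  })
}

#' Generate transcripts for the expressed genes
#'
#' Emits one mRNA (CDS copy) per expressed gene, with optional uniform
#' per-base substitution noise; non-expressed genes emit nothing.
#'
#' @param assembly result of [generate_assembly()].
#' @param noise per-base substitution error rate.
#' @param seed integer seed.
#' @return named character vector of transcript sequences
#'   (`transcript_<gene>`).
#' @export
generate_transcripts <- function(assembly, noise = 0, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    out <- character(0)
    for (nm in names(assembly$genes)) {
      g <- assembly$genes[[nm]]
      if (!isTRUE(g$truth$expressed)) next
      cds <- paste(vapply(g$fragments, function(f) f$cds, ""), collapse = "")
      if (noise > 0) {
        ch <- strsplit(cds, "", fixed = TRUE)[[1L]]
        hit <- which(stats::runif(length(ch)) < noise)
        for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
        cds <- paste(ch, collapse = "")
      }
      out[paste0("transcript_", nm)] <- cds
    }
    out
  })
}

#' Generate day/night behaviour count tables
#'
#' Emulates a multi-aquarium photoperiod experiment: `n_animals`
#' brittle stars per treatment, each able to extend at most two arms, so
#' every observation is a count in `[0, 2 * n_animals]`.  Night counts
#' are Binomial(2 * n_animals, `night_p`); day counts use
#' `night_p * (1 - effect)`, so `effect` is the fractional day-time
#' suppression of arm activity for that light treatment.
#'
#' @param effects named numeric vector of suppression effects per
#'   treatment; the default is strong suppression under white, green
#'   and blue light and none under red light or darkness.
#' @param n_days recording days.
#' @param obs_per_phase observations per phase per day.
#' @param n_animals animals per aquarium.
#' @param night_p per-arm extension probability at night.
#' @param seed integer seed.
#' @return data.frame with columns `treatment`, `phase`, `day`, `obs`,
#'   `arm_count`.
#' @export
generate_behaviour_counts <- function(effects = c(white = 0.65, green = 0.7,
                                                  blue = 0.6, red = 0,
                                                  none = 0),
                                      n_days = 8L, obs_per_phase = 2L,
                                      n_animals = 18L, night_p = 0.25,
                                      seed = 1L) {
  stopifnot(all(effects >= 0), all(effects <= 1))
  withr::with_seed(as.integer(seed), {
    rows <- list()
    for (tr in names(effects)) {
      for (phase in c("day", "night")) {
        p <- if (phase == "day") night_p * (1 - effects[[tr]]) else night_p
        counts <- stats::rbinom(n_days * obs_per_phase, 2L * n_animals, p)
        rows[[length(rows) + 1L]] <- data.frame(
          treatment = tr, phase = phase,
          day = rep(seq_len(n_days), each = obs_per_phase),
          obs = rep(seq_len(obs_per_phase), n_days),
          arm_count = counts, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

#' Score a mined/classified run against its ground truth
#'
#' Matches candidates back to the embedded inserts through their contig
#' ids and reports per-gene recovery, family correctness and the number
#' of decoy GPCR inserts admitted as confirmed candidates.
#'
#' @param assembly result of [generate_assembly()].
#' @param candidates list from [mine_candidates()].
#' @param classification classification table from
#'   [classify_candidates()] whose rows are parallel to `candidates`.
#' @return list with `n_true_genes`, `n_recovered` (genes with at least
#'   one confirmed candidate on their contigs), `n_family_correct`,
#'   `decoys_admitted` and the per-gene data.frame `detail`.
#' @export
evaluate_recovery <- function(assembly, candidates, classification) {
  truth <- assembly$truth
  cand_contigs <- lapply(candidates, function(cd) cd$fragments$contig_id)
  genes <- unique(truth$name[truth$kind == "opsin"])
  detail <- do.call(rbind, lapply(genes, function(g) {
    gcontigs <- truth$contig[truth$kind == "opsin" & truth$name == g]
    hit <- which(vapply(cand_contigs, function(x) any(x %in% gcontigs),
                        logical(1L)))
    fam <- truth$family[truth$kind == "opsin" & truth$name == g][1L]
    fam_called <- if (length(hit) > 0L)
      classification$family[hit[1L]] else NA_character_
    data.frame(gene = g, family = fam, recovered = length(hit) > 0L,
               family_called = fam_called,
               family_correct = isTRUE(fam_called == fam),
               n_candidates = length(hit), stringsAsFactors = FALSE)
  }))
  decoy_contigs <- truth$contig[truth$kind == "decoy"]
  decoys_admitted <- sum(vapply(seq_along(candidates), function(k) {
    cd <- candidates[[k]]
    any(vapply(seq_len(nrow(cd$fragments)), function(i) {
      ci <- cd$fragments$contig_id[i]
      if (!ci %in% decoy_contigs) return(FALSE)
      ins <- truth[truth$contig == ci, , drop = FALSE]
      cd$fragments$contig_start[i] <= ins$end[1L] &&
        ins$start[1L] <= cd$fragments$contig_end[i]
    }, logical(1L)))
  }, logical(1L)))
  list(n_true_genes = length(genes),
       n_recovered = sum(detail$recovered),
       n_family_correct = sum(detail$family_correct),
       decoys_admitted = decoys_admitted,
       detail = detail)
}
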