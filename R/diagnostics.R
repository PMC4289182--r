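# Residue-frame mapping onto the anchor rhodopsin and the diagnostic
# site/motif calls that decide bona fide opsin status.

#' Map a candidate onto the anchor residue frame
#'
#' Globally aligns the candidate to the anchor rhodopsin; every column
#' aligning residue to residue yields a (candidate position, anchor
#' position) equivalence pair.  All downstream diagnostic calls use
#' anchor numbering through this map.
#'
#' @param candidate protein string.
#' @param anchor anchor protein string (or a `reference_panel`).
#' @param sc a [scoring_scheme()].
#' @return a `residue_map`: list with `pairs` (data.frame
#'   `candidate_pos`, `anchor_pos`, strictly increasing in both) and
#'   `coverage` (integer vector of mapped anchor positions).
#' @export
map_to_anchor <- function(candidate, anchor, sc = scoring_scheme()) {
  if (inherits(anchor, "reference_panel")) {
    anchor <- panel_anchor(anchor)$protein
  }
  aln <- global_align(candidate, anchor, sc,
                      a_id = "candidate", b_id = "anchor")
  both <- aln$query_idx > 0L & aln$subject_idx > 0L
  pairs <- data.frame(candidate_pos = aln$query_idx[both],
                      anchor_pos = aln$subject_idx[both])
  structure(list(pairs = pairs, coverage = pairs$anchor_pos,
                 alignment = aln),
            class = "residue_map")
}

# candidate residue at a given anchor position, or NA if unmapped
residue_at <- function(map, candidate, anchor_pos) {
  i <- match(anchor_pos, map$pairs$anchor_pos)
  out <- rep(NA_character_, length(anchor_pos))
  ok <- !is.na(i)
  if (any(ok)) {
    out[ok] <- substring(candidate, map$pairs$candidate_pos[i[ok]],
                         map$pairs$candidate_pos[i[ok]])
  }
  out
}

#' Call the diagnostic sites of a candidate
#'
#' Resolves every scheme site through the residue map: the Schiff-base
#' lysine at 296, the counterion sites 113 (E = vertebrate-type, Y =
#' invertebrate-type) and 181, the D(E)RY tripeptide at 134-136, the
#' NPxxY(x)6F pattern (N302, P303, Y306-equivalent, F313-equivalent;
#' internal positions unconstrained, and insertions between mapped sites
#' do not break the call since mapping, not windowing, decides), the
#' 310-312 triad (NxQ ciliary, HxK rhabdomeric, HxS derived), and the
#' disulfide (110/187) and palmitoylation (322/323) cysteine pairs.
#' Sites whose anchor positions fall outside the candidate's coverage
#' are `not_covered`, never errors: fragments are expected.
#'
#' @param map a `residue_map` built against the same anchor as `scheme`.
#' @param candidate the candidate protein the map was built from.
#' @param scheme a [diagnostic_scheme()].
#' @param name candidate name carried into the report.
#' @return a `motif_report`: list of per-site calls (each `present`,
#'   `absent`, `variant:<residues>` or `not_covered`), plus
#'   `triad_class`, `counterion_113_type` and `bona_fide`.
#' @export
call_sites <- function(map, candidate, scheme = diagnostic_scheme(),
                       name = "candidate") {
  at <- function(pos) residue_at(map, candidate, pos)

  site_single <- function(pos, expected) {
    r <- at(pos)
    if (is.na(r)) "not_covered"
    else if (r == expected) "present"
    else paste0("variant:", r)
  }
  schiff <- at(scheme$schiff_base_pos)
  schiff_call <- if (is.na(schiff)) "not_covered"
                 else if (schiff == scheme$schiff_base_expected) "present"
                 else paste0("absent:", schiff)

  c113 <- at(scheme$counterion_vertebrate_pos)
  c113_type <- if (is.na(c113)) "not_covered"
               else if (c113 == "E") "vertebrate"
               else if (c113 == "Y") "invertebrate"
               else "other"
  c113_call <- if (is.na(c113)) "not_covered" else paste0("variant:", c113)

  c181_call <- site_single(scheme$counterion_ancestral_pos,
                           scheme$counterion_ancestral_expected)

  dry <- at(scheme$dry_span[1L]:scheme$dry_span[2L])
  dry_call <- if (anyNA(dry)) "not_covered"
              else if (dry[1L] %in% scheme$dry_134 && dry[2L] == "R" &&
                       dry[3L] %in% scheme$dry_136) "present"
              else paste0("absent:", paste(dry, collapse = ""))

  np <- scheme$npxxy_span
  np_key <- at(c(np[1L], np[1L] + 1L, np[1L] + 4L, np[2L]))
  np_call <- if (anyNA(np_key)) "not_covered"
             else if (np_key[1L] == "N" && np_key[2L] == "P" &&
                      np_key[3L] == "Y" && np_key[4L] == "F") "present"
             else paste0("absent:", paste(np_key, collapse = ""))

  tri <- at(scheme$triad_span[1L]:scheme$triad_span[2L])
  triad_class <- if (is.na(tri[1L]) || is.na(tri[3L])) "not_covered"
                 else if (tri[1L] == "N" && tri[3L] == "Q") "ciliary"
                 else if (tri[1L] == "H" && tri[3L] == "K") "rhabdomeric"
                 else if (tri[1L] == "H" && tri[3L] == "S") "derived"
                 else "other"
  triad_call <- if (triad_class == "not_covered") "not_covered"
                else paste0("variant:",
                            paste(ifelse(is.na(tri), ".", tri), collapse = ""))

  ds <- at(scheme$disulfide_pair)
  ds_call <- if (anyNA(ds)) "not_covered"
             else if (all(ds == "C")) "present"
             else paste0("absent:", paste(ds, collapse = ""))

  pm <- at(scheme$palmitoylation_pair)
  pm_call <- if (anyNA(pm)) "not_covered"
             else if (all(pm == "C")) "present"
             else paste0("absent:", paste(pm, collapse = ""))

  report <- structure(list(
    candidate_name = name,
    schiff_base = schiff_call,
    counterion_113 = c113_call,
    counterion_113_type = c113_type,
    counterion_181 = c181_call,
    dry = dry_call,
    npxxy = np_call,
    triad = triad_call,
    triad_class = triad_class,
    disulfide = ds_call,
    palmitoylation = pm_call
  ), class = "motif_report")
  report$bona_fide <- assign_bona_fide(report)
  report
}

#' Bona fide opsin status from a motif report
#'
#' A candidate is a bona fide opsin iff the Schiff-base lysine is
#' present at the mapped 296-equivalent; it is not bona fide when the
#' site is covered by another residue, and indeterminate when the
#' fragment does not cover the site.
#'
#' @param report a `motif_report`.
#' @return `"true"`, `"false"` or `"indeterminate"`.
#' @export
assign_bona_fide <- function(report) {
  s <- report$schiff_base
  if (s == "present") "true"
  else if (s == "not_covered") "indeterminate"
  else "false"
}

#' Map a candidate to the anchor through its closest reference
#'
#' Two-step position equivalence: the candidate is globally aligned to
#' its best-scoring panel reference and that reference to the anchor;
#' the two pairwise maps are composed.  Each leg runs at a much higher
#' identity than a direct candidate-to-anchor alignment, which makes
#' the mapped diagnostic positions markedly more stable for diverged
#' candidates.
#'
#' @param candidate protein string.
#' @param panel a `reference_panel`.
#' @param sc a [scoring_scheme()].
#' @return a `residue_map` in anchor coordinates.
#' @export
map_via_reference <- function(candidate, panel, sc = scoring_scheme()) {
  anchor <- panel_anchor(panel)$protein
  scores <- vapply(panel$protein, local_score, numeric(1L),
                   a = candidate, sc = sc)
  ref <- panel[which.max(scores), ]
  if (ref$is_anchor) return(map_to_anchor(candidate, anchor, sc))
  m1 <- map_to_anchor(candidate, ref$protein, sc)     # candidate -> ref
  m2 <- map_to_anchor(ref$protein, anchor, sc)        # ref -> anchor
  j <- match(m1$pairs$anchor_pos, m2$pairs$candidate_pos)
  ok <- !is.na(j)
  pairs <- data.frame(candidate_pos = m1$pairs$candidate_pos[ok],
                      anchor_pos = m2$pairs$anchor_pos[j[ok]])
  structure(list(pairs = pairs, coverage = pairs$anchor_pos,
                 guide_reference = ref$name),
            class = "residue_map")
}

#' Run the diagnostics on a set of candidate proteins
#'
#' Each candidate is mapped onto the anchor residue frame and every
#' scheme site called.  By default the mapping is guided through the
#' candidate's closest panel reference ([map_via_reference()]); set
#' `guide = FALSE` for the direct candidate-to-anchor alignment.
#'
#' @param proteins named character vector of candidate proteins.
#' @param panel a `reference_panel` supplying the anchor.
#' @param scheme a [diagnostic_scheme()].
#' @param sc a [scoring_scheme()].
#' @param guide map through the closest reference (default) or
#'   directly to the anchor.
#' @return list of `motif_report`s, named as `proteins`.
#' @export
diagnose_candidates <- function(proteins, panel,
                                scheme = diagnostic_scheme(),
                                sc = scoring_scheme(), guide = TRUE) {
  anchor <- panel_anchor(panel)$protein
  out <- lapply(names(proteins), function(nm) {
    map <- if (guide) map_via_reference(proteins[[nm]], panel, sc)
           else map_to_anchor(proteins[[nm]], anchor, sc)
    call_sites(map, proteins[[nm]], scheme, name = nm)
  })
  stats::setNames(out, names(proteins))
}

#' Combined candidates-by-sites motif matrix
#'
#' @param reports list of `motif_report`s.
#' @return data.frame, one row per candidate, one column per site call
#'   plus `triad_class`, `counterion_113_type` and `bona_fide`.
#' @export
motif_matrix <- function(reports) {
  cols <- c("candidate_name", "schiff_base", "counterion_113",
            "counterion_113_type", "counterion_181", "dry", "npxxy",
            "triad", "triad_class", "disulfide", "palmitoylation",
            "bona_fide")
  out <- do.call(rbind, lapply(reports, function(r) {
    as.data.frame(r[cols], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
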