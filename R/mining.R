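# Stage 1: translated homology search on nucleotide assemblies,
# reciprocal-best-hit validation, hydropathy TM verification, and the
# non-overlap fragment merge.

# Kyte-Doolittle hydropathy; X and * contribute 0
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2, X = 0, `*` = 0)

#' Transmembrane-helix prediction configuration
#'
#' Sliding-window Kyte-Doolittle hydropathy: window positions whose mean
#' hydropathy reaches `threshold` are TM-candidate residues, and maximal
#' runs of at least `min_helix_len` such residues are reported as
#' helices.  The defaults are calibrated so that the anchor rhodopsin
#' yields its seven transmembrane helices and are then frozen.
#'
#' @param window odd window width (residues).
#' @param threshold mean-hydropathy cutoff.
#' @param min_helix_len minimal run length reported as a helix.
#' @return a `tm_config` list.
#' @export
tm_config <- function(window = 19L, threshold = 1.1, min_helix_len = 6L) {
  stopifnot(window %% 2L == 1L, threshold > 0, min_helix_len >= 1L)
  structure(list(window = as.integer(window), threshold = threshold,
                 min_helix_len = as.integer(min_helix_len)),
            class = "tm_config")
}

#' Predict transmembrane helices by hydropathy
#'
#' @param p protein string.
#' @param cfg a [tm_config()].
#' @return data.frame with columns `start`, `end` (1-based inclusive
#'   residue intervals, disjoint and sorted).  A sequence shorter than
#'   the window returns an empty result with a warning (incomplete
#'   fragments are expected, not an error).
#' @export
predict_tm_helices <- function(p, cfg = tm_config()) {
  p <- validate_aa(p, "protein")
  ch <- strsplit(p, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  empty <- data.frame(start = integer(0), end = integer(0))
  if (n < cfg$window) {
    warning("sequence shorter than the hydropathy window; no helices called")
    return(empty)
  }
  h <- unname(KD_SCALE[ch])
  win <- as.numeric(stats::filter(h, rep(1 / cfg$window, cfg$window),
                                  sides = 2))
  tm <- !is.na(win) & win >= cfg$threshold
  r <- rle(tm)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= cfg$min_helix_len
  data.frame(start = starts[keep], end = ends[keep])
}

# forward-strand nucleotide span of residues p1..p2 in frame f of a
# contig of length L (f in +1..+3, -1..-3; 1-based inclusive)
frame_span_to_contig <- function(p1, p2, frame, L) {
  off <- abs(frame) - 1L
  if (frame > 0L) {
    c(off + 3L * (p1 - 1L) + 1L, off + 3L * p2)
  } else {
    c(L - off - 3L * p2 + 1L, L - off - 3L * (p1 - 1L))
  }
}

# Per-column score profile of an alignment under the affine convention
# (first gapped column of a run pays the opening penalty, the rest the
# extension penalty).
alignment_column_scores <- function(aln, sc) {
  qa <- strsplit(aln$aligned_query, "", fixed = TRUE)[[1L]]
  sa <- strsplit(aln$aligned_subject, "", fixed = TRUE)[[1L]]
  n <- length(qa)
  out <- numeric(n)
  in_gap <- FALSE
  for (k in seq_len(n)) {
    if (qa[k] == "-" || sa[k] == "-") {
      out[k] <- if (in_gap) -sc$gap_extend else -sc$gap_open
      in_gap <- TRUE
    } else {
      out[k] <- sc$matrix[qa[k], sa[k]]
      in_gap <- FALSE
    }
  }
  out
}

# Trim marginal terminal segments of a local alignment: drop the longest
# prefix (and suffix) whose average contribution stays below `rate`
# matrix units per column.  Genuine homologous ends accumulate 3-5
# units per column even at 30% divergence; near-zero-rate terminal
# stretches are alignment end noise (junk extensions bridged by cheap
# affine gaps) that would corrupt hit spans and residue mappings.
trim_hit_ends <- function(aln, sc, rate) {
  cs <- alignment_column_scores(aln, sc)
  n <- length(cs)
  if (n == 0L) return(aln)
  k <- seq_len(n)
  pre <- cumsum(cs)
  weak <- pre < rate * k
  lo <- if (any(weak)) max(which(weak)) + 1L else 1L
  suf <- rev(cumsum(rev(cs)))
  weak_s <- suf < rate * rev(k)
  hi <- if (any(weak_s)) min(which(weak_s)) - 1L else n
  if (lo > hi) return(aln)   # nothing substantive left; keep as is
  keep <- lo:hi
  qa <- strsplit(aln$aligned_query, "", fixed = TRUE)[[1L]][keep]
  sa <- strsplit(aln$aligned_subject, "", fixed = TRUE)[[1L]][keep]
  qi <- aln$query_idx[keep]
  si <- aln$subject_idx[keep]
  aln$aligned_query <- paste(qa, collapse = "")
  aln$aligned_subject <- paste(sa, collapse = "")
  aln$query_idx <- qi
  aln$subject_idx <- si
  aln$query_span <- range(qi[qi > 0L])
  aln$subject_span <- range(si[si > 0L])
  aln
}

#' Translated homology search
#'
#' Six-frame translation of every contig followed by local
#' Smith-Waterman alignment of each frame against each reference panel
#' protein.  Hits reaching `min_score` are reported with contig
#' coordinates back-computed from frame and residue offsets; for a given
#' (contig, frame, reference) only the best-scoring local alignment is
#' reported, which collapses overlapping same-frame hits to the same
#' reference.  Hit ends are trimmed of marginal terminal segments
#' (average contribution below `trim_rate` matrix units per column),
#' the translated-search analogue of BLAST-style HSP end trimming.
#'
#' @param contigs named character vector of nucleotide sequences.
#' @param panel a `reference_panel` (or named character vector of
#'   proteins).
#' @param min_score minimal alignment score, in substitution-matrix
#'   units.
#' @param sc a [scoring_scheme()].
#' @param trim_rate end-trimming threshold in matrix units per
#'   column; terminal alignment segments averaging less than this are
#'   dropped from the reported hit.
#' @return data.frame of translated hits: `contig_id`, `frame`,
#'   `contig_start`, `contig_end` (1-based inclusive, forward strand),
#'   `reference_name`, `ref_start`, `ref_end`, `score`, `protein` (the
#'   hit's translated segment).
#' @export
translated_search <- function(contigs, panel, min_score = 100,
                              sc = scoring_scheme(), trim_rate = 1) {
  if (inherits(panel, "reference_panel")) {
    refs <- stats::setNames(panel$protein, panel$name)
  } else {
    refs <- panel
  }
  if (length(refs) == 0L) stop("reference panel is empty", call. = FALSE)
  ref_enc <- lapply(refs, encode_seq, sc = sc)
  hits <- list()
  frame_names <- c(`+1` = 1L, `+2` = 2L, `+3` = 3L,
                   `-1` = -1L, `-2` = -2L, `-3` = -3L)
  for (cid in names(contigs)) {
    L <- nchar(contigs[[cid]])
    if (L < 3L) next
    frames <- translate_six_frames(contigs[[cid]])
    for (fn in names(frames)) {
      faa <- frames[[fn]]
      if (nchar(faa) == 0L) next
      fenc <- encode_seq(faa, sc)
      for (rn in names(refs)) {
        s <- .sw_score_c(fenc, ref_enc[[rn]], sc$matrix,
                         sc$gap_open, sc$gap_extend)
        if (s < min_score) next
        aln <- trim_hit_ends(local_align(faa, refs[[rn]], sc, a_id = cid,
                                         b_id = rn), sc, trim_rate)
        span <- frame_span_to_contig(aln$query_span[1L], aln$query_span[2L],
                                     frame_names[[fn]], L)
        hits[[length(hits) + 1L]] <- data.frame(
          contig_id = cid, frame = frame_names[[fn]],
          contig_start = span[1L], contig_end = span[2L],
          reference_name = rn,
          ref_start = aln$subject_span[1L], ref_end = aln$subject_span[2L],
          score = aln$score,
          protein = substr(faa, aln$query_span[1L], aln$query_span[2L]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(contig_id = character(0), frame = integer(0),
                      contig_start = integer(0), contig_end = integer(0),
                      reference_name = character(0), ref_start = integer(0),
                      ref_end = integer(0), score = numeric(0),
                      protein = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

#' Reduce translated hits to loci
#'
#' Hits on one contig whose nucleotide spans overlap describe the same
#' locus seen against different references (or frames); only the
#' best-scoring hit is kept per locus and its reference becomes the
#' locus's best reference.
#'
#' @param hits data.frame from [translated_search()].
#' @return subset of `hits`, one row per locus.
#' @export
reduce_to_loci <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  keep <- logical(nrow(hits))
  for (cid in unique(hits$contig_id)) {
    idx <- which(hits$contig_id == cid)
    idx <- idx[order(-hits$score[idx])]
    spans <- list()
    for (i in idx) {
      s <- c(hits$contig_start[i], hits$contig_end[i])
      clash <- any(vapply(spans, function(x) s[1L] <= x[2L] && x[1L] <= s[2L],
                          logical(1L)))
      if (!clash) {
        keep[i] <- TRUE
        spans[[length(spans) + 1L]] <- s
      }
    }
  }
  hits[keep, , drop = FALSE]
}

#' Reciprocal best hit validation
#'
#' Forward: the panel member with the top local-alignment score is the
#' candidate's best reference.  Reverse: the candidate is searched
#' against the panel plus a decoy database emulating the online-database
#' side (non-opsin GPCRs and unrelated proteins); the candidate is
#' confirmed iff the reverse top hit is an opsin panel member.
#'
#' @param candidate_protein protein string.
#' @param panel a `reference_panel`.
#' @param decoy_panel named character vector of decoy proteins, e.g.
#'   [decoy_gpcr_panel()].
#' @param sc a [scoring_scheme()].
#' @return list with `best_reference` (panel name), `rbh_confirmed`
#'   (logical) and `reverse_top` (name of the reverse top hit).
#' @export
reciprocal_best_hit <- function(candidate_protein, panel,
                                decoy_panel = decoy_gpcr_panel(),
                                sc = scoring_scheme()) {
  candidate_protein <- validate_aa(candidate_protein, "candidate")
  stopifnot(inherits(panel, "reference_panel"), length(decoy_panel) > 0L)
  fwd <- vapply(panel$protein, local_score, numeric(1L),
                a = candidate_protein, sc = sc)
  best <- panel$name[which.max(fwd)]
  db <- c(stats::setNames(panel$protein, panel$name), decoy_panel)
  rev <- vapply(db, local_score, numeric(1L), a = candidate_protein, sc = sc)
  top <- names(db)[which.max(rev)]
  list(best_reference = best,
       rbh_confirmed = top %in% panel$name,
       reverse_top = top)
}

#' Merge non-overlapping fragments of one gene
#'
#' Loci sharing the same best reference whose reference-coordinate
#' spans are pairwise disjoint are taken as fragments of a single gene
#' and merged into one candidate (fragments retained, suffixed
#' `.A`/`.B`/... in reference order).  Loci against the same reference
#' with overlapping reference spans remain separate candidates
#' (putative paralogs); loci against different references never merge.
#'
#' @param loci data.frame from [reduce_to_loci()].
#' @return list of candidates; each is a list with `fragments` (the loci
#'   rows, in reference order), `best_reference`, `merged_protein` and
#'   `reference_coverage` (two-column matrix of disjoint intervals).
#' @export
merge_nonoverlapping_fragments <- function(loci) {
  out <- list()
  if (nrow(loci) == 0L) return(out)
  for (rn in unique(loci$reference_name)) {
    sub <- loci[loci$reference_name == rn, , drop = FALSE]
    sub <- sub[order(sub$ref_start, sub$ref_end, sub$contig_id), , drop = FALSE]
    groups <- list()   # each: list(rows = indices, spans = list)
    for (i in seq_len(nrow(sub))) {
      s <- c(sub$ref_start[i], sub$ref_end[i])
      placed <- FALSE
      for (gi in seq_along(groups)) {
        clash <- any(vapply(groups[[gi]]$spans,
                            function(x) s[1L] <= x[2L] && x[1L] <= s[2L],
                            logical(1L)))
        if (!clash) {
          groups[[gi]]$rows <- c(groups[[gi]]$rows, i)
          groups[[gi]]$spans <- c(groups[[gi]]$spans, list(s))
          placed <- TRUE
          break
        }
      }
      if (!placed) groups[[length(groups) + 1L]] <- list(rows = i,
                                                         spans = list(s))
    }
    for (g in groups) {
      frag <- sub[g$rows, , drop = FALSE]
      out[[length(out) + 1L]] <- list(
        fragments = frag,
        best_reference = rn,
        merged_protein = paste(frag$protein, collapse = ""),
        reference_coverage = cbind(start = frag$ref_start,
                                   end = frag$ref_end))
    }
  }
  out
}

#' Mine candidate opsin genes from an assembly
#'
#' Runs the full discovery stage: translated search, locus reduction,
#' non-overlap merge, reciprocal-best-hit validation and
#' transmembrane-helix verification.  Candidates failing RBH are
#' dropped; candidates with fewer than seven helices are kept and
#' flagged, since incomplete fragments are expected.
#'
#' @param contigs named character vector of nucleotide contigs.
#' @param panel a `reference_panel`.
#' @param decoy_panel reverse-search decoy database.
#' @param min_score translated-search score threshold.
#' @param sc,tm scoring scheme and [tm_config()].
#' @return list of confirmed candidates; each carries `fragments`,
#'   `best_reference`, `merged_protein`, `reference_coverage`,
#'   `rbh_confirmed`, `reverse_top`, `tm_helix_count`.
#' @export
mine_candidates <- function(contigs, panel, decoy_panel = decoy_gpcr_panel(),
                            min_score = 100, sc = scoring_scheme(),
                            tm = tm_config()) {
  hits <- translated_search(contigs, panel, min_score, sc)
  loci <- reduce_to_loci(hits)
  cands <- merge_nonoverlapping_fragments(loci)
  out <- list()
  for (cd in cands) {
    rbh <- reciprocal_best_hit(cd$merged_protein, panel, decoy_panel, sc)
    cd$rbh_confirmed <- rbh$rbh_confirmed
    cd$reverse_top <- rbh$reverse_top
    cd$rbh_forward_best <- rbh$best_reference
    if (!cd$rbh_confirmed) next
    helices <- suppressWarnings(predict_tm_helices(cd$merged_protein, tm))
    cd$tm_helix_count <- nrow(helices)
    out[[length(out) + 1L]] <- cd
  }
  out
}

#' Tabulate mined candidates
#'
#' @param candidates list from [mine_candidates()].
#' @return data.frame with one row per fragment: `name`, `fragment`,
#'   `contig`, `start`, `end`, `frame`, `best_reference`, `score`,
#'   `rbh`, `tm_count`.
#' @export
candidate_table <- function(candidates) {
  rows <- list()
  for (k in seq_along(candidates)) {
    cd <- candidates[[k]]
    nm <- cd$name %||% sprintf("candidate%02d", k)
    nfrag <- nrow(cd$fragments)
    for (i in seq_len(nfrag)) {
      rows[[length(rows) + 1L]] <- data.frame(
        name = nm,
        fragment = if (nfrag > 1L) LETTERS[i] else "",
        contig = cd$fragments$contig_id[i],
        start = cd$fragments$contig_start[i],
        end = cd$fragments$contig_end[i],
        frame = cd$fragments$frame[i],
        best_reference = cd$best_reference,
        score = cd$fragments$score[i],
        rbh = cd$rbh_confirmed,
        tm_count = cd$tm_helix_count %||% NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(name = character(0), fragment = character(0),
                      contig = character(0), start = integer(0),
                      end = integer(0), frame = integer(0),
                      best_reference = character(0), score = numeric(0),
                      rbh = logical(0), tm_count = integer(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Write candidate loci as GFF3
#'
#' @param candidates list from [mine_candidates()] (named or not).
#' @param path output GFF3 file (1-based inclusive coordinates).
#' @return `path`, invisibly.
#' @export
write_candidate_gff3 <- function(candidates, path) {
  tab <- candidate_table(candidates)
  if (nrow(tab) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = tab$contig,
    ranges = IRanges::IRanges(start = tab$start, end = tab$end),
    strand = ifelse(tab$frame > 0L, "+", "-"))
  gr$type <- "protein_match"
  gr$ID <- ifelse(tab$fragment == "", tab$name,
                  paste(tab$name, tab$fragment, sep = "."))
  gr$Target <- tab$best_reference
  gr$score <- tab$score
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
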