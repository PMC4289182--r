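# Family assignment by trimmed local-alignment similarity, Sp-style
# naming, core truncation, neighbor-joining placement and bootstrap.

#' Similarity matrix of candidates against the reference panel
#'
#' For every candidate/reference pair the local alignment is computed
#' and the similarity percentage taken over its (trimmed, i.e. local)
#' columns; each cell therefore depends on the length of its own local
#' alignment.
#'
#' @param candidates named character vector of candidate proteins.
#' @param panel a `reference_panel`.
#' @param sc a [scoring_scheme()].
#' @return a `similarity_matrix`: numeric matrix (rows = candidates,
#'   cols = references) of similarity percentages, `NA` where no
#'   positive-scoring local alignment exists; attributes `identity` and
#'   `aligned_len` hold matching matrices.
#' @export
build_similarity_matrix <- function(candidates, panel,
                                    sc = scoring_scheme()) {
  stopifnot(length(candidates) > 0L, nrow(panel) > 0L)
  sim <- id <- len <- matrix(
    NA_real_, nrow = length(candidates), ncol = nrow(panel),
    dimnames = list(names(candidates), panel$name))
  for (i in seq_along(candidates)) {
    for (j in seq_len(nrow(panel))) {
      aln <- local_align(candidates[[i]], panel$protein[j], sc)
      if (nchar(aln$aligned_query) == 0L) next
      pcts <- percent_identity_and_similarity(aln, sc)
      sim[i, j] <- pcts[["similarity"]]
      id[i, j] <- pcts[["identity"]]
      len[i, j] <- nchar(aln$aligned_query)
    }
  }
  structure(sim, identity = id, aligned_len = len,
            class = c("similarity_matrix", "matrix"))
}

#' Assign an opsin family to a candidate
#'
#' Primary evidence is the family of the most similar reference (anchor
#' and outgroup excluded); a ciliary (NxQ) or rhabdomeric (HxK) triad
#' and the family of the nearest tree neighbor corroborate.  The call
#' is `consistent` iff all non-missing evidence agrees, otherwise
#' `ambiguous` (minor-group opsins can legitimately carry either triad).
#'
#' @param candidate_name row name in `sim`.
#' @param sim a `similarity_matrix`.
#' @param panel the `reference_panel` the matrix was built against.
#' @param report the candidate's `motif_report`, or `NULL`.
#' @param tree_neighbor family of the nearest tree neighbor, or `NULL`.
#' @return a `family_call`: list with `candidate_name`, `family`,
#'   `evidence` (best reference, its similarity, triad class, tree
#'   neighbor family) and `confidence`.
#' @export
assign_family <- function(candidate_name, sim, panel, report = NULL,
                          tree_neighbor = NULL) {
  if (!candidate_name %in% rownames(sim)) {
    stop("candidate absent from similarity matrix: ", candidate_name,
         call. = FALSE)
  }
  usable <- !panel$is_anchor & panel$family != "outgroup"
  row <- sim[candidate_name, panel$name[usable]]
  if (all(is.na(row))) {
    stop("no alignable reference for candidate ", candidate_name,
         call. = FALSE)
  }
  best <- names(row)[which.max(row)]
  family <- panel$family[match(best, panel$name)]
  triad_family <- NULL
  if (!is.null(report)) {
    triad_family <- switch(report$triad_class,
                           ciliary = "ciliary",
                           rhabdomeric = "rhabdomeric",
                           NULL)
  }
  evidence <- c(list(best_similarity_reference = best,
                     best_similarity = unname(row[best])),
                if (!is.null(triad_family)) list(triad_family = triad_family),
                if (!is.null(tree_neighbor)) list(tree_neighbor_family = tree_neighbor))
  agree <- unique(c(family, triad_family, tree_neighbor))
  structure(list(candidate_name = candidate_name, family = family,
                 evidence = evidence,
                 confidence = if (length(agree) == 1L) "consistent"
                              else "ambiguous"),
            class = "family_call")
}

sp_base_number <- function(reference_name) {
  m <- regmatches(reference_name,
                  regexpr("[0-9]+", reference_name))
  if (length(m) == 0L) stop("reference name carries no number: ",
                            reference_name, call. = FALSE)
  m
}

#' Name candidates after their closest references
#'
#' Base name = the number of the candidate's best (Sp-style) reference.
#' When several distinct genes share a base number they are suffixed
#' `.1`, `.2`, ... by descending similarity; a single gene keeps the
#' plain number.  Non-overlapping fragments of one merged gene keep
#' their `.A`/`.B` letter suffixes at the fragment level, below the
#' gene name.
#'
#' @param calls list of `family_call`s (one per gene, in candidate
#'   order).
#' @param prefix name prefix, e.g. `"opsin"`.
#' @return character vector of gene names, parallel to `calls`.
#' @export
name_candidates <- function(calls, prefix = "opsin") {
  base <- vapply(calls, function(cl)
    sp_base_number(cl$evidence$best_similarity_reference), "")
  simv <- vapply(calls, function(cl)
    cl$evidence$best_similarity, numeric(1L))
  names_out <- character(length(calls))
  for (b in unique(base)) {
    idx <- which(base == b)
    if (length(idx) == 1L) {
      names_out[idx] <- paste0(prefix, " ", b)
    } else {
      ord <- idx[order(-simv[idx])]
      for (k in seq_along(ord)) {
        names_out[ord[k]] <- paste0(prefix, " ", b, ".", k)
      }
    }
  }
  names_out
}

#' Phylogeny configuration
#'
#' @param anchor_for_truncation reference whose own coordinates define
#'   the conserved-core interval.
#' @param core_start,core_end 1-based inclusive interval on the
#'   truncation reference (the 7-TM core).
#' @param bootstrap_reps bootstrap replicates.
#' @param outgroup named character vector of length 1: the non-opsin
#'   GPCR used to root the displayed tree.
#' @return a `phylo_config` list.
#' @export
phylo_config <- function(anchor_for_truncation = "Sp-opsin 1",
                         core_start = 68L, core_end = 357L,
                         bootstrap_reps = 500L,
                         outgroup = decoy_gpcr_panel(n_unrelated = 0L)) {
  stopifnot(core_start < core_end, bootstrap_reps >= 1L)
  structure(list(anchor_for_truncation = anchor_for_truncation,
                 core_start = as.integer(core_start),
                 core_end = as.integer(core_end),
                 bootstrap_reps = as.integer(bootstrap_reps),
                 outgroup = outgroup[1L]),
            class = "phylo_config")
}

#' Truncate sequences to the conserved 7-TM core
#'
#' Each sequence is globally aligned to the truncation reference;
#' residues mapping before `core_start` or after `core_end` (in the
#' reference's own numbering) are removed.  Insertions falling inside
#' the core are retained, since the mapping, not a window, decides.
#' Sequences with no core overlap are excluded with a warning.
#'
#' @param seqs named character vector of proteins.
#' @param cfg a [phylo_config()].
#' @param panel the `reference_panel` containing the truncation
#'   reference.
#' @param sc a [scoring_scheme()].
#' @return named character vector of truncated sequences (dropped
#'   sequences are absent).
#' @export
truncate_to_core <- function(seqs, cfg, panel, sc = scoring_scheme()) {
  ref <- panel$protein[match(cfg$anchor_for_truncation, panel$name)]
  if (is.na(ref)) stop("truncation reference not in panel", call. = FALSE)
  out <- character(0)
  for (nm in names(seqs)) {
    map <- map_to_anchor(seqs[[nm]], ref, sc)
    inside <- map$pairs$anchor_pos >= cfg$core_start &
      map$pairs$anchor_pos <= cfg$core_end
    if (!any(inside)) {
      warning("no core overlap for ", nm, "; excluded")
      next
    }
    rng <- range(map$pairs$candidate_pos[inside])
    out[nm] <- substr(seqs[[nm]], rng[1L], rng[2L])
  }
  out
}

# p-distance matrix from global alignments: 1 - fractional identity
identity_dist <- function(seqs, sc = scoring_scheme(),
                          correction = c("none", "poisson")) {
  correction <- match.arg(correction)
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      aln <- global_align(seqs[[i]], seqs[[j]], sc)
      p <- percent_identity_and_similarity(aln, sc)[["identity"]] / 100
      dij <- 1 - p
      if (correction == "poisson") dij <- -log(1 - dij + 1e-12)
      d[i, j] <- d[j, i] <- dij
    }
  }
  stats::as.dist(d)
}

#' Neighbor-joining tree from protein sequences
#'
#' Pairwise distances are 1 minus fractional identity from global
#' alignments (p-distance; an optional Poisson correction is available
#' and off by default); the tree is the standard neighbor-joining
#' agglomeration, which recovers topology and branch lengths exactly on
#' additive distance matrices.
#'
#' @param seqs named character vector of >= 3 proteins.
#' @param sc a [scoring_scheme()].
#' @param correction `"none"` (p-distance) or `"poisson"`.
#' @return an unrooted `phylo` tree with branch lengths.
#' @export
nj_tree <- function(seqs, sc = scoring_scheme(),
                    correction = c("none", "poisson")) {
  if (length(seqs) < 3L) stop("neighbor joining needs >= 3 sequences",
                              call. = FALSE)
  ape::nj(identity_dist(seqs, sc, correction))
}

#' Stack sequences into an anchor-indexed pseudo-alignment
#'
#' Each sequence is globally aligned to the truncation reference and
#' its residues placed at their mapped reference columns
#' (`core_start..core_end`); unmapped columns are gaps and insertions
#' are dropped.  This deterministic stand-in for a progressive multiple
#' alignment is the substrate for column bootstrapping.
#'
#' @inheritParams truncate_to_core
#' @return character matrix, rows = sequences, columns = reference core
#'   positions.
#' @export
stack_pseudo_alignment <- function(seqs, cfg, panel, sc = scoring_scheme()) {
  ref <- panel$protein[match(cfg$anchor_for_truncation, panel$name)]
  if (is.na(ref)) stop("truncation reference not in panel", call. = FALSE)
  cols <- cfg$core_start:cfg$core_end
  m <- matrix("-", nrow = length(seqs), ncol = length(cols),
              dimnames = list(names(seqs), NULL))
  for (i in seq_along(seqs)) {
    map <- map_to_anchor(seqs[[i]], ref, sc)
    keep <- map$pairs$anchor_pos %in% cols
    ch <- strsplit(seqs[[i]], "", fixed = TRUE)[[1L]]
    m[i, match(map$pairs$anchor_pos[keep], cols)] <-
      ch[map$pairs$candidate_pos[keep]]
  }
  m
}

# p-distance between rows of a character pseudo-alignment
pseudo_alignment_dist <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(both)) {
        d[i, j] <- d[j, i] <- 1
      } else {
        p <- mean(m[i, both] == m[j, both])
        d[i, j] <- d[j, i] <- 1 - p
      }
    }
  }
  stats::as.dist(d)
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds the NJ tree from p-distances on the anchor-stacked
#' pseudo-alignment, then resamples its columns with replacement for
#' each replicate, rebuilds the tree, and reports for every internal
#' edge the fraction of replicates containing the same bipartition.
#' The returned tree is rooted at the outgroup for display when the
#' outgroup is among the sequences.
#'
#' @param seqs named character vector of >= 3 proteins (include the
#'   outgroup under its name to root the display).
#' @param cfg a [phylo_config()]; `bootstrap_reps` replicates.
#' @param panel reference panel (for the truncation reference).
#' @param seed integer seed for the resampling.
#' @param sc a [scoring_scheme()].
#' @return a `phylo` tree whose `node.label` holds bootstrap
#'   proportions in `[0, 1]` (root label empty).
#' @export
bootstrap_support <- function(seqs, cfg, panel, seed = 1L,
                              sc = scoring_scheme()) {
  if (length(seqs) < 3L) stop("neighbor joining needs >= 3 sequences",
                              call. = FALSE)
  m <- stack_pseudo_alignment(seqs, cfg, panel, sc)
  build <- function(x) ape::nj(pseudo_alignment_dist(x))
  tree <- build(m)
  counts <- withr::with_seed(as.integer(seed),
    ape::boot.phylo(tree, m, build, B = cfg$bootstrap_reps,
                    rooted = FALSE, quiet = TRUE))
  tree$node.label <- c("", sprintf("%.3f", counts[-1L] / cfg$bootstrap_reps))
  og <- names(cfg$outgroup)
  if (!is.null(og) && og %in% tree$tip.label) {
    tree <- ape::root(tree, outgroup = og, resolve.root = TRUE,
                      edgelabel = TRUE)
  }
  tree
}

#' Family of the nearest tree neighbor
#'
#' For a candidate tip, the family label of the closest reference tip
#' by patristic distance.
#'
#' @param tree a `phylo` tree containing candidate and reference tips.
#' @param tip candidate tip label.
#' @param panel the `reference_panel` (families of reference tips).
#' @return family string, or `NA` if no reference tip is present.
#' @export
tree_neighbor_family <- function(tree, tip, panel) {
  refs <- intersect(tree$tip.label, panel$name[!panel$is_anchor &
                                                 panel$family != "outgroup"])
  if (length(refs) == 0L || !tip %in% tree$tip.label) return(NA_character_)
  d <- ape::cophenetic.phylo(tree)[tip, refs]
  panel$family[match(names(which.min(d)), panel$name)]
}

#' Classify mined candidates
#'
#' Runs similarity, diagnostics-informed family assignment, tree
#' corroboration and Sp-style naming over a set of candidate gene
#' proteins.
#'
#' @param proteins named character vector of merged candidate proteins
#'   (one per gene).
#' @param panel a `reference_panel`.
#' @param reports list of `motif_report`s named like `proteins`
#'   (optional).
#' @param cfg a [phylo_config()]; set `bootstrap_reps` low for quick
#'   runs.
#' @param with_tree whether to build the corroborating NJ tree.
#' @param seed seed for the bootstrap.
#' @param sc a [scoring_scheme()].
#' @param prefix naming prefix.
#' @return list with `table` (classification data.frame), `calls`,
#'   `sim` (similarity matrix) and `tree` (or `NULL`).
#' @export
classify_candidates <- function(proteins, panel, reports = NULL,
                                cfg = phylo_config(), with_tree = TRUE,
                                seed = 1L, sc = scoring_scheme(),
                                prefix = "opsin") {
  sim <- build_similarity_matrix(proteins, panel, sc)
  tree <- NULL
  neigh <- stats::setNames(rep(NA_character_, length(proteins)),
                           names(proteins))
  if (with_tree && length(proteins) >= 2L) {
    refs <- stats::setNames(panel$protein, panel$name)
    og <- cfg$outgroup
    allseq <- c(proteins, refs[!panel$is_anchor], og)
    core <- truncate_to_core(allseq, cfg, panel, sc)
    if (length(core) >= 3L) {
      tree <- bootstrap_support(core, cfg, panel, seed = seed, sc = sc)
      for (nm in names(proteins)) {
        neigh[nm] <- tree_neighbor_family(tree, nm, panel)
      }
    }
  }
  calls <- lapply(names(proteins), function(nm) {
    assign_family(nm, sim, panel,
                  report = if (!is.null(reports)) reports[[nm]] else NULL,
                  tree_neighbor = if (!is.na(neigh[nm])) neigh[[nm]] else NULL)
  })
  names(calls) <- names(proteins)
  nm_out <- name_candidates(calls, prefix = prefix)
  tab <- data.frame(
    candidate = names(proteins),
    name = nm_out,
    family = vapply(calls, function(x) x$family, ""),
    best_reference = vapply(calls, function(x)
      x$evidence$best_similarity_reference, ""),
    similarity = vapply(calls, function(x)
      x$evidence$best_similarity, numeric(1L)),
    triad = if (!is.null(reports))
      vapply(names(proteins), function(nm) reports[[nm]]$triad_class, "")
      else NA_character_,
    tree_neighbor = unname(neigh),
    confidence = vapply(calls, function(x) x$confidence, ""),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  list(table = tab, calls = calls, sim = sim, tree = tree)
}

#' Neighbor joining from a distance matrix
#'
#' Thin distance-level entry point used by [nj_tree()] and the
#' bootstrap: standard neighbor joining, exact on additive matrices.
#'
#' @param d distance matrix or `dist` object with taxon names.
#' @return an unrooted `phylo` tree.
#' @export
nj_from_dist <- function(d) {
  if (!inherits(d, "dist")) d <- stats::as.dist(d)
  ape::nj(d)
}
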