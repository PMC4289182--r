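# Orchestration: mine -> diagnose -> classify/tree -> expression
# (-> behaviour), with tabular outputs and a run manifest.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Diagnose and classify a set of gene proteins
#'
#' The analysis core shared by the assembly pipeline and by direct
#' protein-level reruns (e.g. on deposited sequences): per-sequence
#' best references, the non-overlap merge of same-reference fragments
#' into genes, diagnostics on the merged proteins and family
#' classification.
#'
#' Fragment handling: each input protein is mapped to its best
#' reference by local alignment; sequences sharing a best reference
#' with disjoint reference spans are merged into one gene.
#'
#' @param proteins named character vector of protein sequences (gene
#'   fragments or full genes).
#' @param panel a `reference_panel`.
#' @param scheme,sc,cfg diagnostic scheme, scoring scheme and
#'   [phylo_config()].
#' @param with_tree build the corroborating NJ tree.
#' @param seed bootstrap seed.
#' @return list with `genes` (merged proteins), `reports`,
#'   `classification` (as [classify_candidates()]) and `counts`
#'   (headline summary, see [headline_counts()]).
#' @export
analyse_proteins <- function(proteins, panel, scheme = diagnostic_scheme(),
                             sc = scoring_scheme(), cfg = phylo_config(),
                             with_tree = FALSE, seed = 1L) {
  stopifnot(length(proteins) > 0L)
  # best reference and reference span per sequence, by local alignment
  loci <- do.call(rbind, lapply(names(proteins), function(nm) {
    scores <- vapply(panel$protein, local_score, numeric(1L),
                     a = proteins[[nm]], sc = sc)
    usable <- !panel$is_anchor & panel$family != "outgroup"
    scores[!usable] <- -Inf
    j <- which.max(scores)
    aln <- local_align(proteins[[nm]], panel$protein[j], sc)
    data.frame(contig_id = nm, frame = NA_integer_,
               contig_start = NA_integer_, contig_end = NA_integer_,
               reference_name = panel$name[j],
               ref_start = aln$subject_span[1L],
               ref_end = aln$subject_span[2L],
               score = aln$score, protein = proteins[[nm]],
               stringsAsFactors = FALSE)
  }))
  cands <- merge_nonoverlapping_fragments(loci)
  genes <- stats::setNames(
    vapply(cands, function(cd) cd$merged_protein, ""),
    vapply(seq_along(cands), function(k) {
      ids <- cands[[k]]$fragments$contig_id
      paste(ids, collapse = "+")
    }, ""))
  reports <- diagnose_candidates(genes, panel, scheme, sc)
  cls <- classify_candidates(genes, panel, reports, cfg,
                             with_tree = with_tree, seed = seed, sc = sc)
  seq_reports <- diagnose_candidates(proteins, panel, scheme, sc)
  list(genes = genes, reports = reports, sequence_reports = seq_reports,
       classification = cls,
       counts = headline_counts(reports, seq_reports, cls$table))
}

#' Headline counts of an opsin repertoire analysis
#'
#' @param gene_reports list of `motif_report`s, one per merged gene.
#' @param sequence_reports list of `motif_report`s, one per input
#'   sequence (fragments counted separately).
#' @param classification classification table.
#' @return named list: number of genes after the merge, sequences with
#'   the Schiff-base lysine, genes with E181, genes with the
#'   invertebrate-type Y113, rhabdomeric genes and neuropsin genes.
#' @export
headline_counts <- function(gene_reports, sequence_reports, classification) {
  list(
    n_genes = length(gene_reports),
    n_schiff_positive_sequences = sum(vapply(
      sequence_reports, function(r) r$schiff_base == "present", logical(1L))),
    n_bona_fide_genes = sum(vapply(
      gene_reports, function(r) r$bona_fide == "true", logical(1L))),
    n_e181 = sum(vapply(
      gene_reports, function(r) r$counterion_181 == "present", logical(1L))),
    n_y113 = sum(vapply(
      gene_reports, function(r) r$counterion_113_type == "invertebrate",
      logical(1L))),
    n_rhabdomeric = sum(classification$family == "rhabdomeric"),
    n_neuropsin = sum(classification$family == "neuropsin")
  )
}

#' Run the full pipeline on an assembly
#'
#' mine -> diagnose -> classify/tree -> expression (-> behaviour when a
#' count table is given); writes every stage table under `out_dir` and
#' a JSON run manifest with per-stage record counts.
#'
#' @param contigs named character vector of contigs (or a FASTA path).
#' @param transcripts named character vector of transcripts (or FASTA
#'   path), or `NULL`.
#' @param behaviour behaviour count table (or TSV path), or `NULL`.
#' @param panel a `reference_panel` (default: the shipped panel).
#' @param out_dir output directory, created if needed; `NULL` to skip
#'   writing.
#' @param min_score translated-search threshold.
#' @param scheme,sc,tm,cfg,expr_cfg stage configurations.
#' @param with_tree build the bootstrap NJ tree.
#' @param seed seed for the bootstrap stage.
#' @param prefix candidate naming prefix.
#' @return list with `candidates`, `candidate_table`, `motifs`
#'   (matrix), `classification`, `sim`, `tree`, `expression`,
#'   `behaviour`, `counts`, `manifest`.
#' @export
run_pipeline <- function(contigs, transcripts = NULL, behaviour = NULL,
                         panel = NULL, out_dir = NULL, min_score = 100,
                         scheme = diagnostic_scheme(),
                         sc = scoring_scheme(), tm = tm_config(),
                         cfg = phylo_config(),
                         expr_cfg = expression_config(),
                         with_tree = FALSE, seed = 1L, prefix = "opsin") {
  if (is.character(contigs) && length(contigs) == 1L && file.exists(contigs)) {
    contigs <- read_fasta(contigs)
  }
  if (is.character(transcripts) && length(transcripts) == 1L &&
      file.exists(transcripts)) {
    transcripts <- read_fasta(transcripts)
  }
  if (is.character(behaviour) && length(behaviour) == 1L &&
      file.exists(behaviour)) {
    behaviour <- read_behaviour_tsv(behaviour)
  }
  if (is.null(panel)) panel <- reference_panel()

  candidates <- if (length(contigs) > 0L) {
    mine_candidates(contigs, panel, min_score = min_score, sc = sc, tm = tm)
  } else {
    list()
  }

  genes <- stats::setNames(
    vapply(candidates, function(cd) cd$merged_protein, ""),
    sprintf("candidate%02d", seq_along(candidates)))
  reports <- if (length(genes) > 0L) {
    diagnose_candidates(genes, panel, scheme, sc)
  } else {
    list()
  }
  cls <- if (length(genes) > 0L) {
    classify_candidates(genes, panel, reports, cfg, with_tree = with_tree,
                        seed = seed, sc = sc, prefix = prefix)
  } else {
    list(table = data.frame(), calls = list(), sim = NULL, tree = NULL)
  }
  if (length(genes) > 0L) {
    for (k in seq_along(candidates)) candidates[[k]]$name <- cls$table$name[k]
  }

  expr <- NULL
  if (!is.null(transcripts) && length(genes) > 0L) {
    gene_named <- stats::setNames(unname(genes), cls$table$name)
    expr <- expression_report(
      match_transcripts(transcripts, gene_named, expr_cfg, sc))
  }

  behav <- if (!is.null(behaviour)) spectral_verdicts(behaviour) else NULL

  seq_reports <- list()
  if (length(candidates) > 0L) {
    frag_prot <- unlist(lapply(candidates, function(cd) {
      nfrag <- nrow(cd$fragments)
      nm <- if (nfrag > 1L)
        paste(cd$name, LETTERS[seq_len(nfrag)], sep = ".") else cd$name
      stats::setNames(cd$fragments$protein, nm)
    }))
    seq_reports <- diagnose_candidates(frag_prot, panel, scheme, sc)
  }
  counts <- headline_counts(reports, seq_reports,
                            if (nrow(cls$table) > 0L) cls$table
                            else data.frame(family = character(0)))

  manifest <- list(
    tool = paste0("opsinminer ",
                  as.character(utils::packageVersion("opsinminer"))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    n_contigs = length(contigs),
    n_candidates = length(candidates),
    n_genes = counts$n_genes,
    n_transcripts = length(transcripts),
    n_expressed = if (!is.null(expr)) sum(expr$expressed) else NA_integer_,
    n_treatments = if (!is.null(behav)) nrow(behav) else NA_integer_)

  out <- list(candidates = candidates,
              candidate_table = candidate_table(candidates),
              motifs = if (length(reports) > 0L) motif_matrix(reports)
                       else data.frame(),
              classification = cls$table, sim = cls$sim, tree = cls$tree,
              expression = expr, behaviour = behav, counts = counts,
              manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(out$candidate_table, file.path(out_dir, "candidates.tsv"))
    write_candidate_gff3(candidates, file.path(out_dir, "candidates.gff3"))
    if (length(genes) > 0L) {
      write_fasta(stats::setNames(unname(genes), cls$table$name),
                  file.path(out_dir, "candidates.fasta"))
      write_tsv(out$motifs, file.path(out_dir, "motif_matrix.tsv"))
      write_tsv(as.data.frame(unclass(cls$sim)),
                file.path(out_dir, "similarity_matrix.tsv"))
      write_tsv(cls$table, file.path(out_dir, "classification.tsv"))
    }
    if (!is.null(cls$tree)) {
      ape::write.tree(cls$tree, file.path(out_dir, "tree.nwk"))
    }
    if (!is.null(expr)) write_tsv(expr, file.path(out_dir, "expression.tsv"))
    if (!is.null(behav)) {
      write_tsv(behav, file.path(out_dir, "behaviour_stats.tsv"))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

#' Analyse a deposited opsin protein set
#'
#' Protein-level rerun of the diagnose + classify stages on externally
#' deposited sequences (a FASTA of translated opsin gene fragments,
#' e.g. fetched with `scripts/fetch_deposited.R`): fragments sharing a
#' best reference with disjoint reference spans are merged into genes,
#' diagnostics and family calls are computed, and the headline counts
#' returned.
#'
#' @param fasta_path protein FASTA of the deposited sequences.
#' @param panel a `reference_panel` (default: the shipped panel; family
#'   calls are only as faithful as the panel references).
#' @return as [analyse_proteins()].
#' @export
analyse_deposited <- function(fasta_path, panel = reference_panel()) {
  proteins <- read_fasta(fasta_path)
  analyse_proteins(proteins, panel)
}
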