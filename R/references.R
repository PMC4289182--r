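OPSIN_FAMILIES <- c("ciliary", "rhabdomeric", "Go", "neuropsin", "peropsin",
                    "RGR", "basal-branch", "outgroup")

#' Diagnostic residue/motif scheme in anchor-rhodopsin numbering
#'
#' The single home of every diagnostic position used by the pipeline,
#' all 1-based in the coordinates of the anchor rhodopsin: the
#' Schiff-base lysine K296 (its presence defines a bona fide opsin),
#' the vertebrate-type counterion site 113 (E = vertebrate, Y =
#' invertebrate), the ancestral counterion E181, the D(E)RY tripeptide
#' 134-136, the NPxxY(x)6F pattern 302-313 whose internal triad 310-312
#' separates ciliary (NxQ) from rhabdomeric (HxK) opsins, the disulfide
#' cysteines C110/C187 and the palmitoylation cysteines C322/C323.
#'
#' @param dry_134,dry_136 accepted residues for the "DRY-like" variants
#'   at positions 134 and 136 (135 must be R).
#' @return an object of class `diagnostic_scheme`.
#' @export
diagnostic_scheme <- function(dry_134 = c("D", "E"),
                              dry_136 = c("Y", "F", "W", "C", "S", "H")) {
  structure(list(
    schiff_base_pos = 296L, schiff_base_expected = "K",
    counterion_vertebrate_pos = 113L,
    counterion_ancestral_pos = 181L, counterion_ancestral_expected = "E",
    dry_span = c(134L, 136L), dry_134 = dry_134, dry_136 = dry_136,
    npxxy_span = c(302L, 313L),
    triad_span = c(310L, 312L),
    disulfide_pair = c(110L, 187L),
    palmitoylation_pair = c(322L, 323L)
  ), class = "diagnostic_scheme")
}

#' Serialise / load a diagnostic scheme
#'
#' @param scheme a [diagnostic_scheme()].
#' @param path YAML file.
#' @return `read_diagnostic_scheme` returns a `diagnostic_scheme`;
#'   `write_diagnostic_scheme` returns `path` invisibly.
#' @export
write_diagnostic_scheme <- function(scheme, path) {
  yaml::write_yaml(unclass(scheme), path)
  invisible(path)
}

#' @rdname write_diagnostic_scheme
#' @export
read_diagnostic_scheme <- function(path) {
  x <- yaml::read_yaml(path)
  sch <- diagnostic_scheme()
  for (k in names(sch)) {
    if (!is.null(x[[k]])) {
      sch[[k]] <- if (is.numeric(x[[k]])) as.integer(x[[k]]) else x[[k]]
    }
  }
  sch
}

#' Load a reference opsin panel
#'
#' A panel is a protein FASTA plus a TSV sidecar with columns `id`,
#' `name`, `family`, `is_anchor`.  Exactly one member must be flagged as
#' the anchor (the mammalian rhodopsin whose residue numbering all
#' diagnostic positions refer to), and every family label must come from
#' the closed set ciliary / rhabdomeric / Go / neuropsin / peropsin /
#' RGR / basal-branch / outgroup.
#'
#' @param fasta_path protein FASTA.
#' @param sidecar_path TSV sidecar; defaults to `fasta_path` with the
#'   extension replaced by `.tsv`.
#' @return a data.frame of class `reference_panel` with columns `id`,
#'   `name`, `family`, `is_anchor`, `protein`.
#' @export
load_reference_panel <- function(fasta_path, sidecar_path = NULL) {
  if (is.null(sidecar_path)) {
    sidecar_path <- sub("\\.[^.]+$", ".tsv", fasta_path)
  }
  seqs <- read_fasta(fasta_path)
  meta <- utils::read.delim(sidecar_path, stringsAsFactors = FALSE)
  need <- c("id", "name", "family", "is_anchor")
  if (!all(need %in% names(meta))) {
    stop("panel sidecar must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(meta$name)) {
    stop("duplicate name in reference panel: ",
         meta$name[duplicated(meta$name)][1L], call. = FALSE)
  }
  miss <- setdiff(names(seqs), meta$id)
  if (length(miss) > 0L) {
    stop("no family label for FASTA record(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(meta$family, OPSIN_FAMILIES)
  if (length(bad) > 0L) {
    stop("unknown family label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  meta$is_anchor <- as.logical(meta$is_anchor)
  if (sum(meta$is_anchor) != 1L) {
    stop("panel must contain exactly one anchor", call. = FALSE)
  }
  meta$protein <- unname(seqs[meta$id])
  if (anyNA(meta$protein)) {
    stop("sidecar id missing from FASTA: ",
         meta$id[is.na(meta$protein)][1L], call. = FALSE)
  }
  for (i in seq_len(nrow(meta))) validate_aa(meta$protein[i], meta$name[i])
  class(meta) <- c("reference_panel", "data.frame")
  meta
}

#' The shipped reference panel
#'
#' Loads the panel distributed with the package: a synthetic mammalian
#' rhodopsin-like anchor (348 residues, all diagnostic sites at their
#' canonical positions) plus nine synthetic sea-urchin-style family
#' exemplars named Sp-opsin 1, 2, 3.1, 3.2, 4, 5, 6, 7 and 8.  The real
#' reference proteins live in online databases; these stand-ins are
#' constructed sequences (see the package vignette) carrying the
#' family-diagnostic motifs at the anchor-equivalent positions.
#'
#' @return a `reference_panel` data.frame (see [load_reference_panel()]).
#' @export
reference_panel <- function() {
  load_reference_panel(
    system.file("extdata", "reference_panel_synthetic.fasta",
                package = "opsinminer"),
    system.file("extdata", "reference_panel_synthetic.tsv",
                package = "opsinminer"))
}

panel_anchor <- function(panel) {
  panel[panel$is_anchor, , drop = FALSE]
}

#' Validate a diagnostic scheme against its anchor
#'
#' Report-only check that the anchor sequence actually carries the
#' expected residues at every diagnostic site (K296, E113, E181, ERY at
#' 134-136, NPxxY(x)6F at 302-313, C110/C187, C322/C323) and that all
#' scheme positions fall inside the anchor.
#'
#' @param scheme a [diagnostic_scheme()].
#' @param anchor the anchor protein string, or a `reference_panel` from
#'   which the anchor row is taken.
#' @return data.frame with columns `site`, `expected`, `observed`,
#'   `pass`; attribute `ok` is TRUE when every row passes.
#' @export
validate_scheme <- function(scheme, anchor) {
  if (inherits(anchor, "reference_panel")) {
    anchor <- panel_anchor(anchor)$protein
  }
  ch <- strsplit(anchor, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  at <- function(p) if (p >= 1L && p <= n) ch[p] else NA_character_
  rows <- list()
  add <- function(site, expected, observed, pass) {
    rows[[length(rows) + 1L]] <<- data.frame(
      site = site, expected = expected,
      observed = ifelse(is.na(observed), "out-of-range", observed),
      pass = pass, stringsAsFactors = FALSE)
  }
  chk <- function(site, pos, expected) {
    obs <- at(pos)
    add(site, expected, obs, identical(obs, expected))
  }
  chk("schiff_base", scheme$schiff_base_pos, scheme$schiff_base_expected)
  chk("counterion_113", scheme$counterion_vertebrate_pos, "E")
  chk("counterion_181", scheme$counterion_ancestral_pos,
      scheme$counterion_ancestral_expected)
  dry <- vapply(scheme$dry_span[1L]:scheme$dry_span[2L], at, "")
  add("dry", "ERY", paste(dry, collapse = ""),
      !anyNA(dry) && dry[1L] %in% scheme$dry_134 && dry[2L] == "R" &&
        dry[3L] %in% scheme$dry_136)
  np <- vapply(scheme$npxxy_span[1L]:scheme$npxxy_span[2L], at, "")
  add("npxxy", "NPxxY(x)6F", paste(np, collapse = ""),
      !anyNA(np) && np[1L] == "N" && np[2L] == "P" && np[5L] == "Y" &&
        np[12L] == "F")
  ds <- vapply(scheme$disulfide_pair, at, "")
  add("disulfide", "CC", paste(ds, collapse = ""),
      !anyNA(ds) && all(ds == "C"))
  pm <- vapply(scheme$palmitoylation_pair, at, "")
  add("palmitoylation", "CC", paste(pm, collapse = ""),
      !anyNA(pm) && all(pm == "C"))
  structural <- max(scheme$schiff_base_pos, scheme$counterion_vertebrate_pos,
                    scheme$counterion_ancestral_pos, scheme$dry_span,
                    scheme$npxxy_span, scheme$disulfide_pair,
                    scheme$palmitoylation_pair) <= n
  out <- do.call(rbind, rows)
  attr(out, "structural_ok") <- structural
  attr(out, "ok") <- structural && all(out$pass)
  out
}
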