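#' @useDynLib opsinminer, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

NT_ALPHABET <- c("A", "C", "G", "T", "N")
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Validate a nucleotide sequence
#'
#' Checks that `s` is a single non-empty string over `{A,C,G,T,N}`.
#' `N` is tolerated as an ambiguity code but is never translated into a
#' residue call (codons containing `N` become `X`).
#'
#' @param s character scalar.
#' @param what label used in error messages.
#' @return `s`, invisibly, uppercased.
#' @export
validate_nt <- function(s, what = "sequence") {
  stopifnot(is.character(s), length(s) == 1L)
  s <- toupper(s)
  if (nchar(s) == 0L) stop(what, " is empty", call. = FALSE)
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- which(!ch %in% NT_ALPHABET)
  if (length(bad) > 0L) {
    stop(sprintf("invalid nucleotide '%s' at position %d in %s",
                 ch[bad[1L]], bad[1L], what), call. = FALSE)
  }
  invisible(s)
}

#' Validate a protein sequence
#'
#' Checks that `s` is a single non-empty string over the 20 amino acids
#' plus `X` (untranslatable codon) and `*` (stop).
#'
#' @inheritParams validate_nt
#' @param allow_stop,allow_x whether `*` / `X` are accepted.
#' @return `s`, invisibly, uppercased.
#' @export
validate_aa <- function(s, what = "protein", allow_stop = TRUE, allow_x = TRUE) {
  stopifnot(is.character(s), length(s) == 1L)
  s <- toupper(s)
  if (nchar(s) == 0L) stop(what, " is empty", call. = FALSE)
  ok <- AA_ALPHABET
  if (allow_x) ok <- c(ok, "X")
  if (allow_stop) ok <- c(ok, "*")
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- which(!ch %in% ok)
  if (length(bad) > 0L) {
    stop(sprintf("invalid residue '%s' at position %d in %s",
                 ch[bad[1L]], bad[1L], what), call. = FALSE)
  }
  invisible(s)
}

#' Reverse complement of a nucleotide sequence
#'
#' Watson-Crick complement, reversed; `N` maps to `N`.
#'
#' @param s nucleotide string over `{A,C,G,T,N}`.
#' @return the reverse-complemented string.
#' @examples
#' reverse_complement("AAAC")   # "GTTT"
#' @export
reverse_complement <- function(s) {
  s <- validate_nt(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Translate a nucleotide sequence in all six reading frames
#'
#' Frames `+1..+3` read the forward strand at offsets 0..2, `-1..-3` the
#' reverse complement likewise.  Translation uses the standard genetic
#' code; trailing incomplete codons are dropped, stop codons are emitted
#' as `*`, and any codon containing `N` becomes `X`.
#'
#' @param s nucleotide string, length >= 3.
#' @return named character vector of 6 protein strings, names
#'   `"+1","+2","+3","-1","-2","-3"` (a frame shorter than one codon is
#'   the empty string).
#' @export
translate_six_frames <- function(s) {
  s <- validate_nt(s)
  if (nchar(s) < 3L) stop("sequence shorter than one codon", call. = FALSE)
  rc <- reverse_complement(s)
  out <- character(6L)
  names(out) <- c("+1", "+2", "+3", "-1", "-2", "-3")
  for (k in 1:3) {
    out[k] <- translate_frame(s, k)
    out[k + 3L] <- translate_frame(rc, k)
  }
  out
}

# translate one forward frame (offset = frame - 1); N-containing codons -> X
translate_frame <- function(s, frame) {
  n <- nchar(s)
  start <- frame
  len <- n - start + 1L
  ncod <- len %/% 3L
  if (ncod < 1L) return("")
  sub <- substr(s, start, start + ncod * 3L - 1L)
  if (grepl("N", sub, fixed = TRUE)) {
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(sub), if.fuzzy.codon = "X"))
  } else {
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(sub)))
  }
  aa
}

#' Amino-acid similarity groups
#'
#' The default conservative-substitution partition used for the
#' similarity percentage of trimmed local alignments: small/hydroxyl
#' `{G,A,S,T}`, aliphatic `{I,L,V,M}`, aromatic `{F,Y,W}`, basic
#' `{K,R,H}`, acidic/amide `{D,E,N,Q}`, and `{C}`, `{P}` on their own.
#'
#' @return named list of character vectors partitioning the 20 residues.
#' @export
default_similarity_groups <- function() {
  list(small    = c("G", "A", "S", "T"),
       aliphatic = c("I", "L", "V", "M"),
       aromatic = c("F", "Y", "W"),
       basic    = c("K", "R", "H"),
       acidic   = c("D", "E", "N", "Q"),
       cysteine = "C",
       proline  = "P")
}

#' Protein scoring scheme
#'
#' Bundles a substitution matrix, affine gap penalties and the
#' similarity-group partition.  A gap of length k costs
#' `gap_open + gap_extend * (k - 1)`.  The default matrix is BLOSUM62
#' (as distributed with Biostrings) with the `X` row/column zeroed so an
#' untranslatable residue neither rewards nor penalises any pairing.
#'
#' @param matrix either a matrix name (`"BLOSUM62"`, `"BLOSUM45"`,
#'   `"BLOSUM80"`, `"PAM250"`) or a symmetric numeric substitution matrix
#'   with residue dimnames.
#' @param gap_open,gap_extend positive gap penalties, `gap_open >=
#'   gap_extend`.
#' @param similarity_groups partition of the 20 amino acids, as
#'   [default_similarity_groups()].
#' @return an object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 10,
                           gap_extend = 0.5,
                           similarity_groups = default_similarity_groups()) {
  if (is.character(matrix)) {
    name <- matrix
    env <- new.env()
    utils::data(list = name, package = "Biostrings", envir = env)
    mat <- get(name, envir = env)
  } else {
    name <- "custom"
    mat <- matrix
  }
  mat <- as.matrix(mat) * 1.0
  stopifnot(!is.null(rownames(mat)), identical(rownames(mat), colnames(mat)))
  if ("X" %in% rownames(mat)) {
    mat["X", ] <- 0
    mat[, "X"] <- 0
  }
  if (!isTRUE(all.equal(mat, t(mat)))) stop("substitution matrix must be symmetric")
  stopifnot(gap_open > 0, gap_extend > 0, gap_open >= gap_extend)
  grp <- unlist(similarity_groups, use.names = FALSE)
  if (anyDuplicated(grp) || !setequal(grp, AA_ALPHABET)) {
    stop("similarity groups must be a disjoint cover of the 20 amino acids")
  }
  group_of <- rep(names(similarity_groups),
                  lengths(similarity_groups))
  names(group_of) <- grp
  structure(list(matrix = mat, matrix_name = name, gap_open = gap_open,
                 gap_extend = gap_extend,
                 similarity_groups = similarity_groups,
                 group_of = group_of),
            class = "scoring_scheme")
}

#' Read a scoring scheme from a YAML config block
#'
#' Recognised keys: `matrix` (name), `gap_open`, `gap_extend`,
#' `similarity_groups` (named map of residue strings, e.g. `small: GAST`).
#'
#' @param path YAML file.
#' @return a [scoring_scheme()].
#' @export
read_scoring_scheme <- function(path) {
  cfg <- yaml::read_yaml(path)
  groups <- default_similarity_groups()
  if (!is.null(cfg$similarity_groups)) {
    groups <- lapply(cfg$similarity_groups,
                     function(x) strsplit(toupper(x), "")[[1L]])
  }
  scoring_scheme(matrix = cfg$matrix %||% "BLOSUM62",
                 gap_open = cfg$gap_open %||% 10,
                 gap_extend = cfg$gap_extend %||% 0.5,
                 similarity_groups = groups)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

encode_seq <- function(s, sc) {
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  idx <- match(ch, rownames(sc$matrix))
  if (anyNA(idx)) {
    stop("residue not present in the substitution matrix: ",
         ch[which(is.na(idx))[1L]], call. = FALSE)
  }
  idx
}

# shared post-processing of the C traceback into a pairwise_alignment
finish_alignment <- function(res, a, b, a_id, b_id, mode) {
  ai <- res$a_idx
  bi <- res$b_idx
  if (length(ai) == 0L) {
    return(structure(list(query_id = a_id, subject_id = b_id,
                          aligned_query = "", aligned_subject = "",
                          score = res$score, mode = mode,
                          query_span = c(NA_integer_, NA_integer_),
                          subject_span = c(NA_integer_, NA_integer_),
                          query_idx = integer(0), subject_idx = integer(0)),
                     class = "pairwise_alignment"))
  }
  ach <- strsplit(a, "", fixed = TRUE)[[1L]]
  bch <- strsplit(b, "", fixed = TRUE)[[1L]]
  qa <- ifelse(ai == 0L, "-", ach[pmax(ai, 1L)])
  sa <- ifelse(bi == 0L, "-", bch[pmax(bi, 1L)])
  qn <- ai[ai > 0L]
  sn <- bi[bi > 0L]
  structure(list(query_id = a_id, subject_id = b_id,
                 aligned_query = paste(qa, collapse = ""),
                 aligned_subject = paste(sa, collapse = ""),
                 score = res$score, mode = mode,
                 query_span = c(min(qn), max(qn)),
                 subject_span = c(min(sn), max(sn)),
                 query_idx = ai, subject_idx = bi),
            class = "pairwise_alignment")
}

#' Global (Needleman-Wunsch) protein alignment
#'
#' Optimal global alignment under affine gap costs
#' (`gap_open + gap_extend * (k - 1)` for a length-k gap); end gaps are
#' penalised.  Traceback ties are resolved deterministically, preferring
#' diagonal over a gap in the subject over a gap in the query.
#'
#' @param a,b protein strings.
#' @param sc a [scoring_scheme()].
#' @param a_id,b_id record ids carried into the result.
#' @return a `pairwise_alignment`: ids, equal-length gapped strings,
#'   `score`, `mode`, and 1-based inclusive `query_span` / `subject_span`
#'   on the ungapped sequences.
#' @export
global_align <- function(a, b, sc = scoring_scheme(),
                         a_id = "query", b_id = "subject") {
  a <- validate_aa(a, "query")
  b <- validate_aa(b, "subject")
  res <- .nw_align_c(encode_seq(a, sc), encode_seq(b, sc), sc$matrix,
                     sc$gap_open, sc$gap_extend)
  finish_alignment(res, a, b, a_id, b_id, "global")
}

#' Local (Smith-Waterman) protein alignment
#'
#' Optimal local alignment under the same affine gap convention as
#' [global_align()]; the empty alignment (score 0) is returned when no
#' positive-scoring residue pair exists.
#'
#' @inheritParams global_align
#' @return a `pairwise_alignment` (see [global_align()]); spans are `NA`
#'   for the empty alignment.
#' @export
local_align <- function(a, b, sc = scoring_scheme(),
                        a_id = "query", b_id = "subject") {
  a <- validate_aa(a, "query")
  b <- validate_aa(b, "subject")
  res <- .sw_align_c(encode_seq(a, sc), encode_seq(b, sc), sc$matrix,
                     sc$gap_open, sc$gap_extend)
  finish_alignment(res, a, b, a_id, b_id, "local")
}

#' Local alignment score only
#'
#' Score of the optimal Smith-Waterman alignment without traceback;
#' used by the translated homology search where only scores above a
#' threshold warrant a full alignment.
#'
#' @inheritParams global_align
#' @return numeric score (0 if no positive-scoring pair exists).
#' @export
local_score <- function(a, b, sc = scoring_scheme()) {
  .sw_score_c(encode_seq(a, sc), encode_seq(b, sc), sc$matrix,
              sc$gap_open, sc$gap_extend)
}

#' Percent identity and similarity of an alignment
#'
#' Identity counts identical columns over all aligned columns (gap
#' columns stay in the denominator); similarity additionally counts
#' columns whose residues share a similarity group, so similarity is
#' never below identity.
#'
#' @param aln a `pairwise_alignment`.
#' @param sc the [scoring_scheme()] supplying the similarity groups.
#' @return named numeric vector `c(identity = , similarity = )`, percent.
#' @export
percent_identity_and_similarity <- function(aln, sc = scoring_scheme()) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  qa <- strsplit(aln$aligned_query, "", fixed = TRUE)[[1L]]
  sa <- strsplit(aln$aligned_subject, "", fixed = TRUE)[[1L]]
  n <- length(qa)
  if (n == 0L) stop("identity of an empty alignment is undefined", call. = FALSE)
  ident <- qa == sa & qa != "-"
  g <- sc$group_of
  sim <- ident | (!is.na(g[qa]) & !is.na(g[sa]) & g[qa] == g[sa])
  sim[is.na(sim)] <- FALSE
  c(identity = 100 * sum(ident) / n, similarity = 100 * sum(sim) / n)
}

# Average residue masses (Da); total protein mass adds one water.
AA_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
             C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
             H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
             M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
             T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.01524

#' Predicted molecular weight of a protein
#'
#' Sum of average residue masses plus one water, in daltons.  Stops and
#' unknown residues (`X`) have no defined mass and raise an error.
#'
#' @param p protein string over the 20 amino acids.
#' @return mass in Da.
#' @examples
#' molecular_weight("G")   # 75.07
#' @export
molecular_weight <- function(p) {
  p <- validate_aa(p, "protein", allow_stop = FALSE, allow_x = FALSE)
  ch <- strsplit(p, "", fixed = TRUE)[[1L]]
  sum(AA_MASS[ch]) + WATER_MASS
}

#' Read a FASTA file
#'
#' @param path FASTA file (nucleotide or protein).
#' @return named character vector of sequences; names are the record ids
#'   up to the first whitespace, preserved verbatim.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA
#'
#' @param x named character vector of sequences.
#' @param path output file; sequence lines are wrapped at 60 columns.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  stopifnot(is.character(x), !is.null(names(x)))
  set <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}
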