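# Independent alignment oracle: maximises the affine-gap score over all
# monotone matchings of residue pairs (every alignment corresponds to a
# matching and vice versa; with gap_open >= gap_extend the optimal
# alignment always consolidates the unmatched residues between two
# matched pairs into one gap run per sequence, whose cost is scored
# directly by run length).  No dynamic-programming gap states are used,
# so this is independent of the Gotoh implementation under test.

oracle_gap_cost <- function(k, open, ext) {
  if (k == 0L) 0 else open + ext * (k - 1L)
}

oracle_align_score <- function(a, b, sc, mode = c("global", "local")) {
  mode <- match.arg(mode)
  A <- strsplit(a, "", fixed = TRUE)[[1L]]
  B <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(A)
  m <- length(B)
  s <- function(i, j) sc$matrix[A[i], B[j]]
  open <- sc$gap_open
  ext <- sc$gap_extend
  g <- function(k) oracle_gap_cost(k, open, ext)

  if (mode == "global") {
    memo <- array(NA_real_, dim = c(n + 1L, m + 1L))
    # best score of the region after a matched pair at (i, j)
    # (i = j = 0 is a virtual match before both sequences)
    best_from <- function(i, j) {
      if (!is.na(memo[i + 1L, j + 1L])) return(memo[i + 1L, j + 1L])
      best <- -g(n - i) - g(m - j)   # no further matches
      if (i < n && j < m) {
        for (i2 in (i + 1L):n) {
          for (j2 in (j + 1L):m) {
            v <- -g(i2 - i - 1L) - g(j2 - j - 1L) + s(i2, j2) +
              best_from(i2, j2)
            if (v > best) best <- v
          }
        }
      }
      memo[i + 1L, j + 1L] <<- best
      best
    }
    return(best_from(0L, 0L))
  }

  # local: free ends, internal gaps charged, empty alignment scores 0
  memo <- array(NA_real_, dim = c(n, m))
  best_local_from <- function(i, j) {
    if (!is.na(memo[i, j])) return(memo[i, j])
    best <- 0   # stop here
    if (i < n && j < m) {
      for (i2 in (i + 1L):n) {
        for (j2 in (j + 1L):m) {
          v <- -g(i2 - i - 1L) - g(j2 - j - 1L) + s(i2, j2) +
            best_local_from(i2, j2)
          if (v > best) best <- v
        }
      }
    }
    memo[i, j] <<- best
    best
  }
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      v <- s(i, j) + best_local_from(i, j)
      if (v > best) best <- v
    }
  }
  best
}

random_aa_string <- function(n) {
  paste(sample(opsinminer:::AA_ALPHABET, n, replace = TRUE), collapse = "")
}

# a small panel + assembly pair shared by several tests
test_panel <- function() reference_panel()
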