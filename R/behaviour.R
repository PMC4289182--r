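# Day/night photo-behaviour analysis: variance-homogeneity and
# normality gating, unpaired two-tailed t-tests, and per-treatment
# spectral-sensitivity verdicts.

#' F test of variance homogeneity
#'
#' Two-tailed F test with the larger sample variance on top, so F >= 1
#' by construction and identical groups give F = 1, p = 1.  Zero
#' variance in either group is flagged degenerate rather than tested.
#'
#' @param a,b numeric count vectors, each of length >= 2.
#' @return list with `F`, `df`, `p` and `degenerate`.
#' @export
f_test_variances <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("F test needs at least two observations per group", call. = FALSE)
  }
  va <- stats::var(a)
  vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    return(list(F = NA_real_, df = c(NA_integer_, NA_integer_),
                p = NA_real_, degenerate = TRUE))
  }
  if (va >= vb) {
    Fv <- va / vb; df <- c(length(a) - 1L, length(b) - 1L)
  } else {
    Fv <- vb / va; df <- c(length(b) - 1L, length(a) - 1L)
  }
  degenerate <- !is.finite(Fv)
  p <- if (degenerate) 0 else
    min(1, 2 * stats::pf(Fv, df[1L], df[2L], lower.tail = FALSE))
  list(F = Fv, df = df, p = p, degenerate = degenerate)
}

#' Shapiro-Wilk normality test
#'
#' @param x numeric vector, 3 <= n <= 50.
#' @return list with `W`, `p` and `degenerate` (TRUE for a constant
#'   vector, where normality is undefined).
#' @export
normality_test <- function(x) {
  n <- length(x)
  if (n < 3L || n > 50L) stop("normality test defined for 3 <= n <= 50",
                              call. = FALSE)
  if (stats::var(x) == 0) {
    return(list(W = NA_real_, p = NA_real_, degenerate = TRUE))
  }
  sw <- stats::shapiro.test(x)
  list(W = unname(sw$statistic), p = sw$p.value, degenerate = FALSE)
}

#' Unpaired two-tailed Student's t test of day vs night counts
#'
#' Classic pooled-variance unpaired t test (df = n1 + n2 - 2), two
#' tailed, annotated with the F test of variance homogeneity and the
#' Shapiro-Wilk normality p-values of both groups.  Welch's correction
#' is available behind `welch = TRUE` but off by default.
#'
#' @param day,night numeric count vectors (length >= 2 each).
#' @param welch use Welch's unequal-variance t test instead.
#' @return a `behaviour_test` list: `t_statistic`, `df`, `p_value`,
#'   `mean_day`, `mean_night`, `variance_f`, `variance_p`,
#'   `normality_p_day`, `normality_p_night`.
#' @export
students_t_test <- function(day, night, welch = FALSE) {
  if (length(day) < 2L || length(night) < 2L) {
    stop("t test needs at least two observations per group", call. = FALSE)
  }
  tt <- stats::t.test(day, night, var.equal = !welch)
  ft <- f_test_variances(day, night)
  ndp <- if (length(day) >= 3L && length(day) <= 50L)
    normality_test(day)$p else NA_real_
  nnp <- if (length(night) >= 3L && length(night) <= 50L)
    normality_test(night)$p else NA_real_
  structure(list(
    t_statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value,
    mean_day = mean(day), mean_night = mean(night),
    variance_f = ft$F, variance_p = ft$p,
    normality_p_day = ndp, normality_p_night = nnp
  ), class = "behaviour_test")
}

#' Daily means of a behaviour count table
#'
#' Averages the within-day observations so that the day becomes the
#' unit of replication.
#'
#' @param df data.frame with columns `treatment`, `phase`, `day`,
#'   `arm_count` (as produced by [generate_behaviour_counts()] or read
#'   with [read_behaviour_tsv()]).
#' @return data.frame `treatment`, `phase`, `day`, `arm_count` (mean).
#' @export
daily_means <- function(df) {
  out <- stats::aggregate(arm_count ~ treatment + phase + day, data = df,
                          FUN = mean)
  out[order(out$treatment, out$phase, out$day), , drop = FALSE]
}

#' Per-treatment spectral-sensitivity verdicts
#'
#' For each light treatment the day and night counts are compared with
#' an unpaired two-tailed t test (on daily means by default, the day
#' being the replication unit).  A treatment is called `sensitive` when
#' the test is significant at `alpha` *and* the day mean is below the
#' night mean -- sensitivity here means daytime suppression of arm
#' activity, so a significant difference in the wrong direction is not
#' evidence of it.  `significant` reports the raw two-tailed outcome.
#'
#' @param df behaviour count table (long format).
#' @param alpha significance level.
#' @param unit `"daily_mean"` (default) or `"observation"`.
#' @return data.frame with one row per treatment: means, t, df, p,
#'   variance/normality gates, `significant`, `verdict`.
#' @export
spectral_verdicts <- function(df, alpha = 0.05,
                              unit = c("daily_mean", "observation")) {
  unit <- match.arg(unit)
  if (unit == "daily_mean") df <- daily_means(df)
  rows <- list()
  for (tr in unique(df$treatment)) {
    day <- df$arm_count[df$treatment == tr & df$phase == "day"]
    night <- df$arm_count[df$treatment == tr & df$phase == "night"]
    tt <- students_t_test(day, night)
    significant <- tt$p_value < alpha
    rows[[length(rows) + 1L]] <- data.frame(
      treatment = tr,
      mean_day = tt$mean_day, mean_night = tt$mean_night,
      t_statistic = tt$t_statistic, df = tt$df, p_value = tt$p_value,
      variance_f = tt$variance_f, variance_p = tt$variance_p,
      normality_p_day = tt$normality_p_day,
      normality_p_night = tt$normality_p_night,
      significant = significant,
      verdict = if (significant && tt$mean_day < tt$mean_night)
        "sensitive" else "not_sensitive",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read / write behaviour count tables
#'
#' TSV with columns `treatment`, `phase` (day/night), `day`, `obs`,
#' `arm_count`.
#'
#' @param path TSV file.
#' @param df behaviour table.
#' @return `read_behaviour_tsv` returns the data.frame;
#'   `write_behaviour_tsv` returns `path` invisibly.
#' @export
read_behaviour_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("treatment", "phase", "day", "arm_count")
  if (!all(need %in% names(df))) {
    stop("behaviour table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  df
}

#' @rdname read_behaviour_tsv
#' @export
write_behaviour_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
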