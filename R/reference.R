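#' Bundled athlete reference table
#'
#' Loads the bundled transcription of the published per-subject table: 36
#' athletes with experimental 75% angular thresholds, psychometric slopes and
#' mean reaction times, the matched simulated values, and the four model
#' parameters found by grid search.  Grouped subjects (printed with ditto
#' marks) share identical simulated values and parameters; the expansion is
#' explicit here, with a `group` column.  Values flagged `suspect` are
#' preserved verbatim from the printed source (see the column description in
#' the file header).
#'
#' @return data frame with 36 rows.
#' @export
reference_table <- function() {
  path <- system.file("extdata", "athlete_reference.csv",
                      package = "kinemotion", mustWork = TRUE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(nrow(df) == 36)
  df
}

#' Spearman rank correlation with average-rank ties and t-approximation p
#'
#' Average ranks are essential here: grouped subjects share identical
#' simulated values, so the simulated columns are heavily tied.
#'
#' @param x,y numeric vectors.
#' @return list with `r_s`, `p`, `n`.
#' @export
spearman_t <- function(x, y) {
  stopifnot(length(x) == length(y), !anyNA(x), !anyNA(y))
  n <- length(x)
  r <- stats::cor(rank(x), rank(y))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r_s = r, p = 2 * stats::pt(-abs(tstat), n - 2), n = n)
}

#' Correlation analysis of experimental versus simulated observers
#'
#' Spearman rank correlations (average-rank tie handling, p-values via the t
#' approximation) between the experimental and simulated columns of the
#' reference table, for the angular threshold, the psychometric slope and
#' the mean reaction time.
#'
#' @param ref a reference table as returned by [reference_table()].
#' @return data frame with columns `measure`, `r_s`, `p`, `n`.
#' @export
correlate_reference <- function(ref = reference_table()) {
  need <- c("thr_exp", "thr_sim", "slope_exp", "slope_sim",
            "rt_exp", "rt_sim")
  if (!all(need %in% names(ref)) || anyNA(ref[need]))
    stop("reference table is incomplete")
  pairs <- list(threshold = c("thr_exp", "thr_sim"),
                slope = c("slope_exp", "slope_sim"),
                rt = c("rt_exp", "rt_sim"))
  out <- do.call(rbind, lapply(names(pairs), function(m) {
    s <- spearman_t(ref[[pairs[[m]][1]]], ref[[pairs[[m]][2]]])
    data.frame(measure = m, r_s = s$r_s, p = s$p, n = s$n)
  }))
  rownames(out) <- NULL
  out
}
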