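#' Median-normalise a two-group miRNA array
#'
#' Divides each array (column) by its own median signal, then rescales
#' by the grand mean of the original per-array medians so the overall
#' signal scale is preserved. Removes multiplicative per-array effects
#' (labelling/scanning intensity); idempotent up to numerical
#' tolerance.
#'
#' @param m an [expr_matrix()].
#' @return The normalised `expr_matrix` (`normalized = TRUE`).
#' @export
median_normalize <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  med <- apply(m$signals, 2, stats::median)
  if (any(med <= 0)) {
    stop_value("zero or negative median in sample: ",
               names(med)[which(med <= 0)[1]])
  }
  sig <- sweep(m$signals, 2, med, `/`) * mean(med)
  expr_matrix(sig, m$groups, normalized = TRUE)
}

#' Group fold changes under the screen's thresholds
#'
#' Summarises each miRNA per group on the normalised linear scale and
#' computes the CH/CS fold change. A miRNA passes the screen when its
#' fold change is at least `up_threshold` or at most `down_threshold`
#' (as printed, the bounds are asymmetric: 1.25-fold up, 0.75-fold
#' down). Records are sorted by `|log fold change|` descending.
#'
#' @param m a median-normalised [expr_matrix()].
#' @param up_threshold up-regulation bound (default 1.25).
#' @param down_threshold down-regulation bound (default 0.75).
#' @param pseudocount added to both group summaries before the ratio
#'   (default 0).
#' @param summary group summary statistic, `"mean"` (conventional array
#'   summary; default) or `"median"`.
#' @return A `data.frame` of class `de_records` with columns
#'   `mirna_id`, `mean_cs`, `mean_ch`, `fold_change`, `direction`
#'   (`up`/`down`/`none`), `passes`.
#' @export
fold_changes <- function(m, up_threshold = 1.25, down_threshold = 0.75,
                         pseudocount = 0, summary = c("mean", "median")) {
  stopifnot(inherits(m, "expr_matrix"))
  summary <- match.arg(summary)
  if (!m$normalized) {
    stop_value("matrix must be median-normalised before fold changes")
  }
  fun <- if (summary == "mean") rowMeans else
    function(x) apply(x, 1, stats::median)
  cs <- fun(m$signals[, m$groups == "CS", drop = FALSE])
  ch <- fun(m$signals[, m$groups == "CH", drop = FALSE])
  denom <- cs + pseudocount
  if (any(denom == 0)) {
    stop_value("zero CS summary (plus pseudocount) for miRNA: ",
               rownames(m$signals)[which(denom == 0)[1]])
  }
  fc <- (ch + pseudocount) / denom
  # thresholds are inclusive; the relative epsilon keeps fold changes
  # landing on a bound up to floating-point rounding (e.g. an exact
  # 0.75-fold construction computed as (0.75*x)/x) on the pass side
  tol <- 1e-9
  direction <- ifelse(fc >= up_threshold * (1 - tol), "up",
                      ifelse(fc <= down_threshold * (1 + tol), "down",
                             "none"))
  df <- data.frame(mirna_id = rownames(m$signals), mean_cs = unname(cs),
                   mean_ch = unname(ch), fold_change = unname(fc),
                   direction = unname(direction),
                   passes = unname(direction != "none"),
                   stringsAsFactors = FALSE)
  df <- df[order(-abs(log(df$fold_change)), df$mirna_id, method = "radix"), ]
  rownames(df) <- NULL
  class(df) <- c("de_records", "data.frame")
  df
}

#' Differentially expressed miRNA set
#'
#' @param records a [fold_changes()] result.
#' @return Character vector of miRNA ids passing the fold-change filter.
#' @export
de_mirna_set <- function(records) {
  records$mirna_id[records$passes]
}
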