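#' Normalise dual-luciferase reporter measurements
#'
#' Per well, Renilla activity (reporter fused to the tested 3'UTR) is
#' divided by Firefly activity (transfection control); the ratios are
#' then divided by the mean ratio of the scramble-transfected wells of
#' the same UTR construct, so the scramble reference of each construct
#' has mean 1 by construction.
#'
#' @param wells data frame with columns `renilla`, `firefly` (positive
#'   numbers), `treatment` (`"scramble"` or `"mimic"`), `construct`
#'   (UTR construct label, e.g. wild type vs seed mutant).
#' @return A list with `wells` (input plus `ratio`, `normalized_ratio`)
#'   and `summary` (per construct x treatment: `mean`, `sem`, `n`).
#' @export
luciferase_normalize <- function(wells) {
  required <- c("renilla", "firefly", "treatment", "construct")
  missing <- setdiff(required, names(wells))
  if (length(missing)) {
    stop_format("well table is missing column(s): ",
                paste(missing, collapse = ", "))
  }
  if (any(wells$firefly <= 0)) {
    stop_value("non-positive firefly activity in well ",
               which(wells$firefly <= 0)[1])
  }
  if (any(wells$renilla <= 0)) {
    stop_value("non-positive renilla activity in well ",
               which(wells$renilla <= 0)[1])
  }
  wells$ratio <- wells$renilla / wells$firefly
  wells$normalized_ratio <- NA_real_
  for (con in unique(wells$construct)) {
    sel <- wells$construct == con
    ref <- sel & wells$treatment == "scramble"
    if (!any(ref)) {
      stop_value("no scramble reference wells for construct '", con, "'")
    }
    wells$normalized_ratio[sel] <- wells$ratio[sel] / mean(wells$ratio[ref])
  }
  keys <- unique(wells[, c("construct", "treatment")])
  summary <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    v <- wells$normalized_ratio[wells$construct == keys$construct[i] &
                                  wells$treatment == keys$treatment[i]]
    data.frame(construct = keys$construct[i], treatment = keys$treatment[i],
               mean = mean(v),
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
               n = length(v), stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(wells = wells, summary = summary)
}

#' Relative expression by the 2^-ddCt method
#'
#' `ddCt = (Ct_target,treated - Ct_ref,treated) - (Ct_target,control -
#' Ct_ref,control)`; the relative expression of the target in treated
#' vs control samples is `2^-ddCt`. Vectorised over wells; swapping
#' treated and control inverts the result.
#'
#' @param ct_target_treated,ct_ref_treated target and reference-gene Ct
#'   in the treated sample.
#' @param ct_target_control,ct_ref_control target and reference-gene Ct
#'   in the control sample.
#' @return Relative expression `2^-ddCt` (positive).
#' @export
ddct <- function(ct_target_treated, ct_ref_treated,
                 ct_target_control, ct_ref_control) {
  cts <- c(ct_target_treated, ct_ref_treated, ct_target_control,
           ct_ref_control)
  if (any(!is.finite(cts))) stop_value("Ct values must be finite")
  dd <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-dd)
}
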