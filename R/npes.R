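#' Rank the gene universe by propagated network effect
#'
#' Descending effect; genes absent from the effect vector score 0; ties
#' are broken lexicographically by gene id (C locale) so rankings are
#' machine-reproducible.
#'
#' @param result a `propagation_result` (or any named effect vector).
#' @param gene_universe character vector of all genes to rank.
#' @return An object of class `ranked_genes`: list with `gene_ids`
#'   (ordered) and `effect` (named vector aligned to `gene_ids`).
#' @export
rank_by_effect <- function(result, gene_universe) {
  if (length(gene_universe) == 0) stop_value("empty gene universe")
  eff <- if (inherits(result, "propagation_result")) result$effect else result
  e <- setNames(numeric(length(gene_universe)), gene_universe)
  common <- intersect(names(eff), gene_universe)
  e[common] <- eff[common]
  ord <- order(-e, names(e), method = "radix")
  structure(list(gene_ids = names(e)[ord], effect = e[ord]),
            class = "ranked_genes")
}

# shared setup for running-sum computations: per-rank increments
npes_increments <- function(ranked, scores, quiet = FALSE) {
  genes <- ranked$gene_ids
  n <- length(genes)
  in_univ <- scores$gene_id %in% genes
  if (!all(in_univ) && !quiet) {
    message("dropping ", sum(!in_univ),
            " scored gene(s) outside the ranked universe")
  }
  sc <- scores[in_univ, , drop = FALSE]
  if (nrow(sc) == 0) stop_value("empty candidate set")
  denom <- sum(abs(sc$log_reliability))
  if (denom == 0) stop_value("all log-reliability weights are zero")
  w <- setNames(sc$log_reliability / denom, sc$gene_id)
  k <- nrow(sc)
  missw <- if (n > k) 1 / (n - k) else 0
  incr <- rep(-missw, n)
  hit <- match(names(w), genes)
  incr[hit] <- w
  list(incr = incr, hit_ranks = sort(hit), n = n, k = k,
       w_norm = unname(w), missw = missw)
}

#' NPES running sum over a ranked gene list
#'
#' Walks the effect-ranked universe; an addiction-scored gene at rank
#' *i* adds its log reliability divided by the summed absolute log
#' reliabilities of all in-universe scored genes, an unscored gene
#' subtracts `1 / (N - N_hit)`. NPES is the maximum of the running sum
#' and `argmax_rank` the first rank attaining it.
#'
#' @param ranked a [rank_by_effect()] result.
#' @param scores a [gene_scores()] data frame.
#' @param quiet suppress the message about scored genes outside the
#'   ranked universe (they are always dropped from the weighting).
#' @return A list with `npes`, `argmax_rank` and the full `curve`.
#' @export
running_sum <- function(ranked, scores, quiet = FALSE) {
  parts <- npes_increments(ranked, scores, quiet = quiet)
  curve <- cumsum(parts$incr)
  argmax <- which.max(curve)
  list(npes = curve[argmax], argmax_rank = as.integer(argmax), curve = curve)
}

# max of the running sum for one random relabelling, given precomputed
# pieces; used by the permutation null
null_npes_once <- function(n, k, w_norm, missw) {
  incr <- rep(-missw, n)
  incr[sample.int(n, k)] <- w_norm
  max(cumsum(incr))
}

#' Permutation p-value for an observed NPES
#'
#' The null reassigns which universe genes carry the reliability labels
#' (uniform sampling without replacement of label positions), recomputes
#' NPES each time, and reports the add-one empirical p-value
#' `(1 + #null >= observed) / (1 + n_permutations)`, so `p >=
#' 1/(n_permutations + 1)` always.
#'
#' @param ranked a [rank_by_effect()] result.
#' @param scores a [gene_scores()] data frame.
#' @param n_permutations number of label permutations (default 1000).
#' @param rng_seed integer seed for the permutation stream.
#' @param quiet suppress the out-of-universe drop message.
#' @return The p-value (scalar in `(0, 1]`).
#' @export
permutation_test <- function(ranked, scores, n_permutations = 1000,
                             rng_seed = 1L, quiet = FALSE) {
  if (n_permutations < 1) stop_value("n_permutations must be >= 1")
  parts <- npes_increments(ranked, scores, quiet = quiet)
  observed <- max(cumsum(parts$incr))
  with_local_seed(rng_seed, {
    hits <- 0L
    for (b in seq_len(n_permutations)) {
      if (null_npes_once(parts$n, parts$k, parts$w_norm, parts$missw) >=
          observed) {
        hits <- hits + 1L
      }
    }
    (1 + hits) / (1 + n_permutations)
  })
}

#' Leading-edge genes of an enrichment
#'
#' The scored (addiction) genes ranked at or before the rank where the
#' running sum peaks.
#'
#' @param ranked a [rank_by_effect()] result.
#' @param scores a [gene_scores()] data frame.
#' @param argmax_rank the peak rank from [running_sum()].
#' @return Character vector of leading-edge gene ids.
#' @export
leading_edge <- function(ranked, scores, argmax_rank) {
  stopifnot(argmax_rank >= 1, argmax_rank <= length(ranked$gene_ids))
  intersect(ranked$gene_ids[seq_len(argmax_rank)], scores$gene_id)
}

#' Screen miRNA families for addiction-gene enrichment
#'
#' Runs the full NPES stage per propagated family: effect ranking,
#' running sum, permutation p-value, Benjamini-Hochberg q-values across
#' families, leading-edge extraction. Only positive enrichment is ever
#' flagged significant.
#'
#' @param results list of `propagation_result` (from [propagate_all()]).
#' @param scores a [gene_scores()] data frame.
#' @param n_permutations permutations per family (default 1000).
#' @param fdr_threshold BH q-value threshold for the `significant` flag
#'   (default 0.05).
#' @param rng_seed integer seed; per-family permutation streams are
#'   derived from it deterministically.
#' @return A `data.frame` of class `enrichment_results` with columns
#'   `family_id`, `npes`, `argmax_rank`, `p_value`, `q_value`,
#'   `significant`, `n_permutations` and list column `leading_edge`,
#'   sorted by ascending q then descending NPES.
#' @export
screen_families <- function(results, scores, n_permutations = 1000,
                            fdr_threshold = 0.05, rng_seed = 1L) {
  if (length(results) == 0) stop_value("no propagation results supplied")
  universe <- names(results[[1]]$effect)
  n_outside <- sum(!(scores$gene_id %in% universe))
  if (n_outside > 0) {
    message("dropping ", n_outside,
            " scored gene(s) outside the ranked universe")
  }
  rows <- lapply(seq_along(results), function(i) {
    res <- results[[i]]
    ranked <- rank_by_effect(res, universe)
    rs <- running_sum(ranked, scores, quiet = TRUE)
    p <- permutation_test(ranked, scores, n_permutations,
                          rng_seed = rng_seed + i - 1L, quiet = TRUE)
    le <- leading_edge(ranked, scores, rs$argmax_rank)
    data.frame(family_id = res$family_id, npes = rs$npes,
               argmax_rank = rs$argmax_rank, p_value = p,
               stringsAsFactors = FALSE,
               leading_edge = I(list(le)))
  })
  df <- do.call(rbind, rows)
  df$q_value <- stats::p.adjust(df$p_value, method = "BH")
  df$significant <- df$q_value <= fdr_threshold & df$npes > 0
  df$n_permutations <- as.integer(n_permutations)
  df <- df[order(df$q_value, -df$npes, df$family_id, method = "radix"),
           c("family_id", "npes", "argmax_rank", "p_value", "q_value",
             "significant", "n_permutations", "leading_edge")]
  rownames(df) <- NULL
  class(df) <- c("enrichment_results", "data.frame")
  df
}
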