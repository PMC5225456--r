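# shared fixtures and independent oracles for the test suite

# naive per-rank NPES loop: the independent reference for running_sum().
# Walks the ranked list one gene at a time, looking each gene up in the
# score table; no vectorisation shared with the implementation.
naive_npes <- function(ranked, scores) {
  genes <- ranked$gene_ids
  sc <- scores[scores$gene_id %in% genes, , drop = FALSE]
  denom <- sum(abs(sc$log_reliability))
  w <- stats::setNames(sc$log_reliability, sc$gene_id)
  n <- length(genes)
  k <- nrow(sc)
  run <- 0
  best <- -Inf
  best_rank <- NA_integer_
  for (i in seq_len(n)) {
    g <- genes[i]
    run <- run + (if (g %in% names(w)) w[[g]] / denom else -(1 / (n - k)))
    if (run > best) {
      best <- run
      best_rank <- i
    }
  }
  list(npes = best, argmax_rank = best_rank)
}

# random directed graph as an edge_list (no self-loops by construction)
random_digraph <- function(n_genes, n_edges) {
  src <- sample.int(n_genes, n_edges, replace = TRUE)
  tgt <- sample.int(n_genes, n_edges, replace = TRUE)
  keep <- src != tgt
  edge_list(paste0("g", src[keep]), paste0("g", tgt[keep]))
}

# random ranked list plus scores over n genes with k scored genes
random_ranked_scores <- function(n, k) {
  genes <- sprintf("g%04d", seq_len(n))
  eff <- stats::setNames(stats::runif(n), genes)
  ranked <- rank_by_effect(eff, genes)
  sc <- gene_scores(sample(genes, k), stats::rlnorm(k, 1, 1))
  list(ranked = ranked, scores = sc)
}

# the hand-worked 5-gene example: hits g1 (log-score 2) and g4
# (log-score 1); curve (2/3, 1/3, 0, 1/3, 0), NPES 2/3 at rank 1
toy_ranked_5 <- function() {
  rank_by_effect(stats::setNames(c(0.5, 0.4, 0.3, 0.2, 0.1),
                                 paste0("g", 1:5)),
                 paste0("g", 1:5))
}

toy_scores_5 <- function() gene_scores(c("g1", "g4"), exp(c(2, 1)))

# toy pipeline inputs small enough to hand-check
toy_target_table <- function() {
  target_table(c("F1", "F2", "F3"),
               list(c("m1a", "m1b"), "m2", "m3"),
               c(2, 2, 2),
               list(c("A", "B"), c("B", "C"), c("C", "D")))
}

extdata <- function(...) {
  system.file("extdata", ..., package = "npscreen", mustWork = TRUE)
}

mir218 <- function() read_fasta(extdata("mir218_mimic.fa"), "DNA")[[1]]

inserts <- function() read_fasta(extdata("mir218_luciferase_inserts.fa"), "DNA")
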