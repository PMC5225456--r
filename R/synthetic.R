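#' Configuration for the synthetic screen-input generator
#'
#' Bundles every knob of the simulated study: a sparse directed
#' TF-to-gene regulatory network with hub regulators, heavy-tailed
#' addiction-gene reliability scores biased toward highly regulated
#' genes, miRNA-family target sets with planted addiction-regulating
#' families, and a two-group log-normal array with planted fold changes
#' and per-array scale factors (which make median normalisation
#' load-bearing).
#'
#' Gene identifiers are `g001..gN`; the first `n_tfs` genes are the
#' transcription factors. Family identifiers are `fam001..`, member
#' miRNAs `fam001a`, `fam001b`, ... Every fourth family starting with
#' the first has two member miRNAs, the rest one, so the candidate
#' miRNA count can exceed the family count as in real family maps.
#' Planted families are the first `planted_family_count` families.
#'
#' @param n_genes number of genes in the regulatory universe.
#' @param n_tfs number of transcription factors (edge sources).
#' @param edges_per_tf outgoing regulatory edges per TF.
#' @param n_families number of miRNA families.
#' @param targets_per_family predicted targets per family.
#' @param n_addiction_genes number of scored addiction genes.
#' @param planted_family_count families planted with addiction-directed
#'   target sets (the recoverable ground truth).
#' @param planted_overlap_fraction fraction of a planted family's
#'   targets drawn from the addiction-enriched pool (addiction genes
#'   plus their upstream TFs), in `[0, 1]`.
#' @param n_mirnas_on_array miRNAs measured on the simulated array
#'   (all family members plus unmapped fillers).
#' @param samples_per_group arrays per group (CS and CH).
#' @param planted_up,planted_down data frames with columns `mirna_id`,
#'   `fold_change` (> 0) giving planted CH/CS fold changes. By default
#'   the first member of each planted family is planted down at 0.5
#'   (the screen's motivating candidate was roughly halved) and nothing
#'   is planted up.
#' @param signal_log_sd sd of per-measurement log-normal signal noise.
#' @param array_scale_sd sd of the per-array log-normal scale factor.
#' @param rng_seed integer seed; all generators are deterministic
#'   functions of the config.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 500, n_tfs = 50, edges_per_tf = 10,
                             n_families = 50, targets_per_family = 30,
                             n_addiction_genes = 100,
                             planted_family_count = 1,
                             planted_overlap_fraction = 0.6,
                             n_mirnas_on_array = 300,
                             samples_per_group = 4,
                             planted_up = NULL, planted_down = NULL,
                             signal_log_sd = 0.25, array_scale_sd = 0.3,
                             rng_seed = 1L) {
  if (n_genes < 1 || n_tfs < 0 || edges_per_tf < 1 || n_families < 1 ||
      targets_per_family < 1 || n_addiction_genes < 1 ||
      planted_family_count < 0 || n_mirnas_on_array < 1 ||
      samples_per_group < 1) {
    stop_config("counts must be positive (planted_family_count may be 0)")
  }
  if (n_tfs > n_genes) stop_config("n_tfs exceeds n_genes")
  if (edges_per_tf >= n_genes) stop_config("edges_per_tf must be < n_genes")
  if (n_addiction_genes > n_genes) {
    stop_config("n_addiction_genes exceeds n_genes")
  }
  if (targets_per_family > n_genes) {
    stop_config("targets_per_family exceeds n_genes")
  }
  if (planted_family_count > n_families) {
    stop_config("planted_family_count exceeds n_families")
  }
  if (planted_overlap_fraction < 0 || planted_overlap_fraction > 1) {
    stop_config("planted_overlap_fraction must be in [0, 1]")
  }
  if (signal_log_sd < 0 || array_scale_sd < 0) {
    stop_config("noise standard deviations must be >= 0")
  }

  gene_ids <- sprintf("g%03d", seq_len(n_genes))
  family_ids <- sprintf("fam%03d", seq_len(n_families))
  # deterministic membership: every 4th family (incl. the planted first
  # family) has two member miRNAs
  members <- lapply(seq_len(n_families), function(i) {
    k <- if ((i - 1L) %% 4L == 0L) 2L else 1L
    paste0(family_ids[i], letters[seq_len(k)])
  })
  names(members) <- family_ids
  member_ids <- unlist(members, use.names = FALSE)
  if (length(member_ids) > n_mirnas_on_array) {
    stop_config("n_mirnas_on_array too small for family members")
  }
  n_fill <- n_mirnas_on_array - length(member_ids)
  array_ids <- c(member_ids,
                 if (n_fill > 0) sprintf("array-mir%03d", seq_len(n_fill)))

  planted_families <- family_ids[seq_len(planted_family_count)]
  if (is.null(planted_down)) {
    planted_down <- if (planted_family_count > 0) {
      data.frame(mirna_id = vapply(members[planted_families], `[[`,
                                   character(1), 1),
                 fold_change = 0.5, stringsAsFactors = FALSE)
    } else {
      data.frame(mirna_id = character(), fold_change = numeric())
    }
  }
  if (is.null(planted_up)) {
    planted_up <- data.frame(mirna_id = character(), fold_change = numeric())
  }
  planted <- rbind(planted_up, planted_down)
  if (nrow(planted)) {
    if (any(planted$fold_change <= 0)) {
      stop_config("planted fold changes must be > 0")
    }
    absent <- setdiff(planted$mirna_id, array_ids)
    if (length(absent)) {
      stop_config("planted miRNA(s) not on array: ",
                  paste(absent, collapse = ", "))
    }
  }

  structure(list(n_genes = n_genes, n_tfs = n_tfs,
                 edges_per_tf = edges_per_tf, n_families = n_families,
                 targets_per_family = targets_per_family,
                 n_addiction_genes = n_addiction_genes,
                 planted_family_count = planted_family_count,
                 planted_overlap_fraction = planted_overlap_fraction,
                 n_mirnas_on_array = n_mirnas_on_array,
                 samples_per_group = samples_per_group,
                 planted_up = planted_up, planted_down = planted_down,
                 signal_log_sd = signal_log_sd,
                 array_scale_sd = array_scale_sd,
                 rng_seed = as.integer(rng_seed),
                 gene_ids = gene_ids, tf_ids = gene_ids[seq_len(n_tfs)],
                 family_ids = family_ids, members = members,
                 array_mirna_ids = array_ids,
                 planted_families = planted_families),
            class = "synthetic_config")
}

#' Generate a directed TF-to-gene regulatory network
#'
#' Each TF emits `edges_per_tf` distinct edges to genes sampled with
#' preferential attachment on current in-degree (weight in-degree + 1),
#' excluding itself. Preferential attachment yields hub target genes
#' regulated by many TFs, which is what gives network propagation a
#' signal to exploit. Deterministic given `rng_seed`.
#'
#' @param config a [synthetic_config()].
#' @return An [edge_list()] with `n_tfs * edges_per_tf` edges.
#' @export
generate_regulatory_network <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$n_tfs == 0) return(edge_list(character(), character()))
  with_local_seed(config$rng_seed + 101L, {
    n <- config$n_genes
    indeg <- rep(0, n)
    src <- character(0)
    tgt <- character(0)
    for (t in seq_len(config$n_tfs)) {
      w <- indeg + 1
      w[t] <- 0
      picks <- sample.int(n, config$edges_per_tf, prob = w)
      indeg[picks] <- indeg[picks] + 1
      src <- c(src, rep(config$gene_ids[t], config$edges_per_tf))
      tgt <- c(tgt, config$gene_ids[picks])
    }
    edge_list(src, tgt)
  })
}

#' Generate addiction-gene reliability scores
#'
#' Samples `n_addiction_genes` genes with probability proportional to
#' in-degree + 1 (highly regulated genes are more likely to be scored),
#' draws log-normal reliabilities (meanlog 1, sdlog 1 — heavy-tailed,
#' as literature evidence scores are) and assigns the larger
#' reliabilities to the higher in-degree genes among those sampled, so
#' propagated mass and reliability ranking are positively coupled.
#'
#' @param config a [synthetic_config()].
#' @param network the [generate_regulatory_network()] output (supplies
#'   in-degrees).
#' @param reliability_sdlog log-scale sd of the reliability draw
#'   (default 1; 0 collapses every reliability to `exp(1)`).
#' @return A [gene_scores()] data frame.
#' @export
generate_gene_scores <- function(config, network, reliability_sdlog = 1) {
  stopifnot(inherits(config, "synthetic_config"))
  with_local_seed(config$rng_seed + 211L, {
    indeg <- table(factor(network$target, levels = config$gene_ids))
    indeg <- as.numeric(indeg)
    picks <- sample.int(config$n_genes, config$n_addiction_genes,
                        prob = indeg + 1)
    rel <- rlnorm(config$n_addiction_genes, meanlog = 1,
                  sdlog = reliability_sdlog)
    # couple reliability rank to in-degree rank (random tie-break)
    ord <- order(indeg[picks], stats::runif(length(picks)), decreasing = TRUE)
    rel_sorted <- sort(rel, decreasing = TRUE)
    reliability <- numeric(length(picks))
    reliability[ord] <- rel_sorted
    gene_scores(config$gene_ids[picks], reliability)
  })
}

#' Generate miRNA-family target sets with planted ground truth
#'
#' Planted families draw `planted_overlap_fraction` of their targets
#' from the addiction-enriched pool (scored addiction genes plus TFs
#' with an edge into a scored gene) and the rest uniformly; background
#' families draw uniformly from all genes. All generated families carry
#' conservation score 2 (at the retention threshold). The planted
#' family ids are attached as attribute `planted_families`.
#'
#' @param config a [synthetic_config()].
#' @param network the generated [edge_list()].
#' @param scores the generated [gene_scores()].
#' @return A [target_table()] with attribute `planted_families`.
#' @export
generate_target_map <- function(config, network, scores) {
  stopifnot(inherits(config, "synthetic_config"))
  with_local_seed(config$rng_seed + 307L, {
    upstream_tfs <- unique(network$source[network$target %in% scores$gene_id])
    pool <- union(scores$gene_id, upstream_tfs)
    planted <- config$planted_families
    targets <- lapply(seq_len(config$n_families), function(i) {
      fid <- config$family_ids[i]
      if (fid %in% planted) {
        k_enr <- min(round(config$planted_overlap_fraction *
                             config$targets_per_family), length(pool))
        enr <- sample(pool, k_enr)
        rest <- sample(setdiff(config$gene_ids, enr),
                       config$targets_per_family - k_enr)
        c(enr, rest)
      } else {
        sample(config$gene_ids, config$targets_per_family)
      }
    })
    tt <- target_table(config$family_ids,
                       config$members[config$family_ids],
                       rep(2, config$n_families), targets)
    attr(tt, "planted_families") <- planted
    tt
  })
}

#' Generate a two-group miRNA expression matrix with planted fold changes
#'
#' Baseline per-miRNA signals are log-normal (meanlog `log(500)`,
#' sdlog 1, spanning the dynamic range of a scanned array);
#' per-measurement noise is log-normal with sd `signal_log_sd`; planted
#' miRNAs have their CH-sample signals multiplied by the planted fold
#' change; and every array is multiplied by its own log-normal scale
#' factor (sd `array_scale_sd`), so per-array median normalisation is
#' required before fold changes are meaningful. Planted miRNA ids are
#' attached as attributes `planted_up` / `planted_down`.
#'
#' @param config a [synthetic_config()].
#' @return An `expr_matrix` (raw, `normalized = FALSE`).
#' @export
generate_expression_matrix <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_local_seed(config$rng_seed + 401L, {
    ids <- config$array_mirna_ids
    n <- length(ids)
    k <- config$samples_per_group
    samples <- c(sprintf("CS%d", seq_len(k)), sprintf("CH%d", seq_len(k)))
    groups <- setNames(rep(c("CS", "CH"), each = k), samples)
    mu <- rlnorm(n, meanlog = log(500), sdlog = 1)
    sig <- matrix(mu, n, 2 * k) *
      matrix(exp(rnorm(n * 2 * k, 0, config$signal_log_sd)), n, 2 * k)
    dimnames(sig) <- list(ids, samples)
    planted <- rbind(config$planted_up, config$planted_down)
    for (i in seq_len(nrow(planted))) {
      sig[planted$mirna_id[i], groups == "CH"] <-
        sig[planted$mirna_id[i], groups == "CH"] * planted$fold_change[i]
    }
    scale <- exp(rnorm(2 * k, 0, config$array_scale_sd))
    sig <- sweep(sig, 2, scale, `*`)
    m <- expr_matrix(sig, groups, normalized = FALSE)
    attr(m, "planted_up") <- config$planted_up$mirna_id
    attr(m, "planted_down") <- config$planted_down$mirna_id
    m
  })
}

#' Generate every input of the screen in one call
#'
#' Convenience wrapper running all four generators and bundling their
#' outputs with the planted ground truth.
#'
#' @param config a [synthetic_config()].
#' @return A list with elements `network`, `scores`, `targets`, `expr`,
#'   `family_map` (miRNA id to family id) and `truth` (list of
#'   `planted_families`, `planted_mirnas`).
#' @export
generate_screen_inputs <- function(config) {
  network <- generate_regulatory_network(config)
  scores <- generate_gene_scores(config, network)
  targets <- generate_target_map(config, network, scores)
  expr <- generate_expression_matrix(config)
  fmap <- family_map(targets)
  list(network = network, scores = scores, targets = targets, expr = expr,
       family_map = fmap,
       truth = list(planted_families = config$planted_families,
                    planted_mirnas = unique(c(config$planted_up$mirna_id,
                                              config$planted_down$mirna_id))))
}
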