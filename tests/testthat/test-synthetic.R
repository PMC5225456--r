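test_that("regulatory network generator: counts, determinism, edge cases", {
  cfg <- synthetic_config(rng_seed = 1)
  net <- generate_regulatory_network(cfg)
  expect_equal(nrow(net), cfg$n_tfs * cfg$edges_per_tf)
  expect_true(all(net$source %in% cfg$tf_ids))
  expect_true(all(net$source != net$target))

  net2 <- generate_regulatory_network(cfg)
  expect_identical(as.data.frame(net), as.data.frame(net2))

  cfg0 <- synthetic_config(n_tfs = 0, rng_seed = 1)
  expect_equal(nrow(generate_regulatory_network(cfg0)), 0)

  expect_error(synthetic_config(n_genes = 10, edges_per_tf = 10),
               class = "npscreen_config_error")
  expect_error(synthetic_config(n_genes = 50, n_addiction_genes = 100),
               class = "npscreen_config_error")
  expect_error(synthetic_config(planted_overlap_fraction = 1.5),
               class = "npscreen_config_error")
})

test_that("gene score generator: domain, determinism, degenerate spread", {
  cfg <- synthetic_config(rng_seed = 2)
  net <- generate_regulatory_network(cfg)
  gs <- generate_gene_scores(cfg, net)
  expect_equal(nrow(gs), cfg$n_addiction_genes)
  expect_true(all(gs$reliability > 0))
  expect_identical(gs, generate_gene_scores(cfg, net))

  flat <- generate_gene_scores(cfg, net, reliability_sdlog = 0)
  expect_equal(flat$reliability, rep(exp(1), cfg$n_addiction_genes))

  # high in-degree genes carry higher scores among the sampled set
  indeg <- table(factor(net$target, levels = cfg$gene_ids))
  sampled_indeg <- as.numeric(indeg[gs$gene_id])
  expect_gt(suppressWarnings(cor(sampled_indeg, gs$reliability,
                                 method = "spearman")), 0)
})

test_that("target map plants overlap with the addiction-enriched pool", {
  cfg <- synthetic_config(rng_seed = 7)
  net <- generate_regulatory_network(cfg)
  gs <- generate_gene_scores(cfg, net)
  tt <- generate_target_map(cfg, net, gs)
  expect_equal(attr(tt, "planted_families"), "fam001")
  expect_true(all(lengths(tt$targets) == cfg$targets_per_family))

  pool <- union(gs$gene_id, unique(net$source[net$target %in% gs$gene_id]))
  overlap <- length(intersect(tt$targets$fam001, pool))
  expect_gte(overlap, round(cfg$planted_overlap_fraction *
                              cfg$targets_per_family))

  # boundary: full overlap
  cfg1 <- synthetic_config(planted_overlap_fraction = 1, rng_seed = 7)
  tt1 <- generate_target_map(cfg1, net, gs)
  expect_true(all(tt1$targets$fam001 %in% pool))

  # no planted families -> empty truth
  cfg0 <- synthetic_config(planted_family_count = 0, rng_seed = 7)
  tt0 <- generate_target_map(cfg0, net, gs)
  expect_length(attr(tt0, "planted_families"), 0)
})

test_that("expression generator: noise-free exactness and determinism", {
  cfg <- synthetic_config(signal_log_sd = 0, array_scale_sd = 0,
                          planted_up = data.frame(mirna_id = "fam002a",
                                                  fold_change = 2),
                          rng_seed = 5)
  m <- generate_expression_matrix(cfg)
  fc <- rowMeans(m$signals[, m$groups == "CH"]) /
    rowMeans(m$signals[, m$groups == "CS"])
  expect_equal(unname(fc["fam002a"]), 2)
  expect_equal(unname(fc["fam001a"]), 0.5)  # default planted-down member
  expect_true(all(abs(fc[setdiff(names(fc), c("fam002a", "fam001a"))] - 1)
                  < 1e-12))

  expect_identical(generate_expression_matrix(cfg)$signals, m$signals)

  expect_error(synthetic_config(planted_up = data.frame(
    mirna_id = "nonexistent", fold_change = 2)),
    class = "npscreen_config_error")
  expect_error(synthetic_config(planted_up = data.frame(
    mirna_id = "fam002a", fold_change = -1)),
    class = "npscreen_config_error")
})

test_that("planted fold changes survive noise and per-array scaling", {
  # a single 4 vs 4 realisation has ~18% sampling error on the fold
  # change, so the recovery property is asserted on the geometric mean
  # across seeds rather than one draw
  fcs <- vapply(1:15, function(seed) {
    cfg <- synthetic_config(rng_seed = seed)
    m <- median_normalize(generate_expression_matrix(cfg))
    planted <- attr(generate_expression_matrix(cfg), "planted_down")
    unname(rowMeans(m$signals[planted, m$groups == "CH", drop = FALSE]) /
             rowMeans(m$signals[planted, m$groups == "CS", drop = FALSE]))
  }, numeric(1))
  expect_equal(exp(mean(log(fcs))), 0.5, tolerance = 0.15)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(generate_screen_inputs(synthetic_config(rng_seed = 4)))
  expect_identical(.Random.seed, before)
})
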