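test_that("ranking is by descending effect with lexicographic tie-break", {
  rk <- rank_by_effect(c(A = 0.5, B = 0.25, C = 0.125), c("A", "B", "C"))
  expect_equal(rk$gene_ids, c("A", "B", "C"))

  # all-zero effects: pure lexicographic order
  rk0 <- rank_by_effect(numeric(0), c("b", "a", "c"))
  expect_equal(rk0$gene_ids, c("a", "b", "c"))

  # tie between two genes resolved lexicographically
  rkt <- rank_by_effect(c(z = 1, y = 1, x = 2), c("x", "y", "z"))
  expect_equal(rkt$gene_ids, c("x", "y", "z"))

  expect_error(rank_by_effect(c(A = 1), character(0)),
               class = "npscreen_value_error")
})

test_that("running sum reproduces the hand-worked example", {
  rs <- running_sum(toy_ranked_5(), toy_scores_5())
  expect_equal(rs$curve, c(2 / 3, 1 / 3, 0, 1 / 3, 0), tolerance = 1e-12)
  expect_equal(rs$npes, 2 / 3, tolerance = 1e-12)
  expect_equal(rs$argmax_rank, 1L)
  expect_equal(leading_edge(toy_ranked_5(), toy_scores_5(), rs$argmax_rank),
               "g1")
})

test_that("all genes scored with equal weights: curve climbs to 1", {
  genes <- paste0("g", 1:8)
  rk <- rank_by_effect(setNames(8:1, genes), genes)
  sc <- gene_scores(genes, rep(exp(1), 8))
  rs <- running_sum(rk, sc)
  expect_equal(rs$curve[8], 1)
  expect_equal(rs$npes, 1)
  expect_equal(leading_edge(rk, sc, 8L), genes)
})

test_that("running sum agrees exactly with the naive per-rank oracle", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(20:300, 1)
    fix <- random_ranked_scores(n, sample.int(max(2, n %/% 4), 1) + 1)
    rs <- running_sum(fix$ranked, fix$scores)
    oracle <- naive_npes(fix$ranked, fix$scores)
    expect_equal(rs$npes, oracle$npes, tolerance = 1e-12)
    expect_equal(rs$argmax_rank, oracle$argmax_rank)
  }
})

test_that("errors: empty candidate set and zero total weight", {
  rk <- toy_ranked_5()
  expect_error(running_sum(rk, gene_scores("zz", 5)),
               "empty candidate set", class = "npscreen_value_error")
  expect_error(running_sum(rk, gene_scores(c("g1", "g2"), c(1, 1))),
               class = "npscreen_value_error")  # log(1) = 0 weights
})

test_that("NPES is invariant to rescaling the log-reliability weights", {
  fix <- local({
    set.seed(3)
    random_ranked_scores(50, 12)
  })
  base <- running_sum(fix$ranked, fix$scores)
  # reliability^c multiplies every log weight by c > 0
  scaled <- gene_scores(fix$scores$gene_id, fix$scores$reliability^3)
  rs <- running_sum(fix$ranked, scaled)
  expect_equal(rs$npes, base$npes, tolerance = 1e-12)
  expect_equal(rs$argmax_rank, base$argmax_rank)
  p1 <- permutation_test(fix$ranked, fix$scores, 200, rng_seed = 9)
  p2 <- permutation_test(fix$ranked, scaled, 200, rng_seed = 9)
  expect_equal(p1, p2)
})

test_that("permutation p-values respect the add-one floor and ceiling", {
  fix <- local({
    set.seed(5)
    random_ranked_scores(40, 8)
  })
  p <- permutation_test(fix$ranked, fix$scores, 100, rng_seed = 1)
  expect_gte(p, 1 / 101)
  expect_lte(p, 1)

  # degenerate constant statistic: all genes scored with equal weights
  genes <- paste0("g", 1:6)
  rk <- rank_by_effect(setNames(6:1, genes), genes)
  sc <- gene_scores(genes, rep(exp(2), 6))
  expect_equal(permutation_test(rk, sc, 50, rng_seed = 1), 1)

  # fixed seed reproducibility
  expect_identical(permutation_test(fix$ranked, fix$scores, 300, rng_seed = 7),
                   permutation_test(fix$ranked, fix$scores, 300, rng_seed = 7))
})

test_that("family screen: BH wiring, ordering, significance flag", {
  set.seed(21)
  uni <- paste0("g", 1:60)
  eff <- lapply(1:4, function(i) {
    structure(list(family_id = paste0("F", i),
                   effect = setNames(runif(60), uni),
                   seed_genes = character(0), iterations_used = 1L,
                   converged = TRUE),
              class = "propagation_result")
  })
  sc <- gene_scores(sample(uni, 15), rlnorm(15, 1, 1))
  res <- screen_families(eff, sc, n_permutations = 200, rng_seed = 2)
  expect_equal(sort(res$family_id), paste0("F", 1:4))
  # BH is a per-element map given the full p multiset, so row order is
  # irrelevant to the check
  expect_equal(res$q_value, stats::p.adjust(res$p_value, "BH"),
               tolerance = 1e-12)
  expect_false(is.unsorted(res$q_value))
  expect_true(all(res$significant == (res$q_value <= 0.05 & res$npes > 0)))
  expect_true(all(vapply(res$leading_edge, function(le)
    all(le %in% sc$gene_id), logical(1))))

  # single family: q equals p
  res1 <- screen_families(eff[1], sc, n_permutations = 100, rng_seed = 2)
  expect_equal(res1$q_value, res1$p_value)
})
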