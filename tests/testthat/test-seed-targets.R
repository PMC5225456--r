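test_that("seed extraction takes positions 2-8 of the mature sequence", {
  expect_equal(seed_of("TTGTGCTTGATCTAACCATGT"), "TGTGCTT")
  expect_equal(seed_of(mir218()), "TGTGCTT")
  expect_equal(seed_of("ACGTACGT"), "CGTACGT")  # 8-mer boundary
  expect_error(seed_of("ACGTACG"), class = "npscreen_value_error")
})

test_that("site motifs are the canonical reverse-complement constructions", {
  m <- site_motifs("TGTGCTT", "DNA")
  expect_equal(m[["7mer-m8"]], "AAGCACA")
  expect_equal(m[["7mer-A1"]], "AGCACAA")
  expect_equal(m[["8mer"]], "AAGCACAA")
  expect_equal(m[["6mer"]], "AGCACA")

  # RNA target alphabet, RNA seed input
  mr <- site_motifs("UGUGCUU", "RNA")
  expect_equal(mr[["7mer-m8"]], "AAGCACA")
  expect_equal(unname(site_motifs("TGTGCTT", "RNA")), unname(mr))

  # seed whose 2-7 subword is its own reverse complement
  mp <- site_motifs("ATGCATC", "DNA")
  expect_equal(mp[["6mer"]], "ATGCAT")
  expect_equal(mp[["6mer"]],
               npscreen:::revcomp_seq(substr("ATGCATC", 1, 6), "DNA"))
})

test_that("scanning the printed inserts finds the expected canonical sites", {
  mir <- mir218()
  sites <- lapply(inserts(), scan_sites, mirna = mir)
  names(sites) <- vapply(inserts(), `[[`, "", "id")
  expect_true(all(vapply(sites, nrow, integer(1)) >= 1))

  mecp2 <- sites$Mecp2
  expect_equal(nrow(mecp2), 1)
  expect_equal(mecp2$site_type, "7mer-m8")
  expect_equal(mecp2$start, 22L)
  expect_equal(mecp2$end, 29L)

  expect_equal(sites$Dnmt3a$site_type, "7mer-A1")
  expect_equal(sites$Ube3a$site_type, "7mer-A1")
  # full 8mer matches subsume their internal 7mers
  expect_equal(sites$Sema6b$site_type, "8mer")
  expect_equal(sites$Gng3$site_type, "8mer")

  # audit mode reports the overlapping shorter types too
  all_types <- scan_sites(inserts()[[which(names(sites) == "Sema6b")]],
                          mir, report_all = TRUE)
  expect_setequal(all_types$site_type, c("8mer", "7mer-m8", "7mer-A1", "6mer"))

  # no complementary heptamer -> empty result
  none <- scan_sites(sequence_record("flat", strrep("AT", 25)), mir)
  expect_equal(nrow(none), 0)
})

test_that("seed-site mutation abolishes pairing and preserves length", {
  mir <- mir218()
  recs <- inserts()
  mecp2 <- recs[[which(vapply(recs, `[[`, "", "id") == "Mecp2")]]
  site <- scan_sites(mecp2, mir)
  mut <- mutate_seed_site(mecp2, site, mir)
  expect_equal(substr(mut$sequence, 23, 29), "TTCGTGT")  # complement of AAGCACA
  expect_equal(nchar(mut$sequence), nchar(mecp2$sequence))
  expect_equal(nrow(scan_sites(mut, mir)), 0)

  # every printed insert can be knocked out
  for (r in recs) {
    m <- mutate_seed_site(r, scan_sites(r, mir), mir)
    expect_equal(nrow(scan_sites(m, mir)), 0)
    expect_equal(nchar(m$sequence), nchar(r$sequence))
  }

  empty <- scan_sites(sequence_record("flat", strrep("AT", 25)), mir)
  expect_error(mutate_seed_site(mecp2, empty, mir),
               class = "npscreen_value_error")
})

test_that("luciferase normalisation anchors the scramble reference at 1", {
  wells <- data.frame(
    renilla = c(10, 12, 11, 5, 6, 5.5, 9, 10, 11, 9.5, 10.5, 10),
    firefly = rep(10, 12),
    treatment = rep(rep(c("scramble", "mimic"), each = 3), 2),
    construct = rep(c("wt", "mut"), each = 6))
  out <- luciferase_normalize(wells)
  s <- out$summary
  get <- function(con, tr) s$mean[s$construct == con & s$treatment == tr]
  expect_equal(get("wt", "scramble"), 1, tolerance = 1e-12)
  expect_equal(get("mut", "scramble"), 1, tolerance = 1e-12)
  # mimic halves the wild-type reporter but leaves the mutant at ~1
  expect_equal(get("wt", "mimic"), 0.5, tolerance = 1e-12)
  expect_equal(get("mut", "mimic"), 1, tolerance = 0.05)
  expect_true(all(s$n == 3))
  expect_true(all(is.finite(s$sem)))

  bad <- wells
  bad$firefly[4] <- 0
  expect_error(luciferase_normalize(bad), class = "npscreen_value_error")
  expect_error(luciferase_normalize(wells[wells$treatment == "mimic", ]),
               "scramble", class = "npscreen_value_error")
})

test_that("ddct arithmetic and antisymmetry", {
  expect_equal(ddct(20, 18, 22, 20), 1)     # ddCt = 0
  expect_equal(ddct(21, 18, 20, 18), 0.5)   # ddCt = 1
  expect_equal(ddct(22, 18, 20, 18), 0.25)  # worked example
  # swapping treated and control inverts the result
  set.seed(2)
  cts <- matrix(runif(40, 15, 30), ncol = 4)
  fwd <- ddct(cts[, 1], cts[, 2], cts[, 3], cts[, 4])
  rev <- ddct(cts[, 3], cts[, 4], cts[, 1], cts[, 2])
  expect_equal(fwd * rev, rep(1, 10))
  expect_error(ddct(NA, 18, 20, 18), class = "npscreen_value_error")
})
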