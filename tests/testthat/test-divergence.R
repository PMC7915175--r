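test_that("the two-parameter distance matches direct formula evaluation", {
  expect_equal(kimura_distance(0, 0, 100)$K, 0)
  # K = -1/2 ln(0.75 * sqrt(0.9))
  expect_equal(kimura_distance(10, 5, 100)$K,
               -0.5 * log(0.75 * sqrt(0.9)), tolerance = 1e-12)
  expect_equal(kimura_distance(10, 5, 100)$p, 0.1)
  expect_equal(kimura_distance(10, 5, 100)$q, 0.05)
  # saturation at the domain boundary 1 - 2p - q <= 0
  sat <- kimura_distance(50, 0, 100)
  expect_true(sat$saturated)
  expect_true(is.na(sat$K))
  expect_true(kimura_distance(0, 50, 100)$saturated)
  expect_error(kimura_distance(1, 1, 0),
               class = "repeatscape_validation_error")
  expect_error(kimura_distance(60, 50, 100),
               class = "repeatscape_validation_error")
})

test_that("K is monotone increasing in p for fixed q within the domain", {
  for (q in c(0, 0.05, 0.1, 0.2)) {
    ps <- seq(0, 0.4, by = 0.02)
    ok <- 1 - 2 * ps - q > 0 & 1 - 2 * q > 0
    K <- kimura_distance(round(ps[ok] * 1000), round(q * 1000), 1000)$K
    expect_true(all(diff(K) > 0))
  }
})

test_that("solve_pq round trips through the closed form to 1e-9", {
  for (K_star in c(0.05, 0.10, 0.17, 0.25, 0.31)) {
    pq <- solve_pq(K_star)
    expect_equal(pq$p / pq$q, 2, tolerance = 1e-6)
    K_back <- -0.5 * log((1 - 2 * pq$p - pq$q) * sqrt(1 - 2 * pq$q))
    expect_lt(abs(K_back - K_star), 1e-9)
  }
})

mk_div <- function(start, end, te_class, family, K) {
  # construct counts realizing K (ts-only would saturate; use solve_pq)
  pq <- solve_pq(K)
  sites <- 10000L
  tibble::tibble(
    seq_id = "s", start = start, end = end, strand = "+",
    consensus_name = "c", te_class = te_class, family = family,
    cons_start = 0L, cons_end = end - start, score = 100L,
    aligned_cols = sites, matches = sites, transitions = round(pq$p * sites),
    transversions = round(pq$q * sites), ambiguous_cols = 0L, gap_cols = 0L,
    trimmed = FALSE) |>
    hit_divergence()
}

test_that("landscape bins are floor(100K) with clamping at 50", {
  d <- mk_div(0L, 400L, "DNA", "hAT-Ac", 0.172)
  ls <- build_landscape(d)
  expect_equal(ls$value[ls$bin == 17], 400)
  expect_equal(sum(ls$value), 400)

  d0 <- mk_div(0L, 100L, "DNA", "hAT-Ac", 0)
  expect_equal(build_landscape(d0)$value[1], 100)

  dd <- dplyr::bind_rows(mk_div(0L, 100L, "DNA", "hAT-Ac", 0.505),
                         mk_div(200L, 500L, "DNA", "hAT-Ac", 0.70))
  lc <- build_landscape(dd)
  expect_equal(lc$value[lc$bin == 50], 400)
})

test_that("landscape conserves divergence-eligible bp incl. saturated copies", {
  sat <- tibble::tibble(
    seq_id = "s", start = 1000L, end = 1300L, strand = "+",
    consensus_name = "c", te_class = "LINE", family = "L2",
    cons_start = 0L, cons_end = 300L, score = 10L, aligned_cols = 300L,
    matches = 100L, transitions = 160L, transversions = 40L,
    ambiguous_cols = 0L, gap_cols = 0L, trimmed = FALSE) |>
    hit_divergence()
  expect_true(sat$saturated)
  d <- dplyr::bind_rows(mk_div(0L, 400L, "DNA", "hAT-Ac", 0.1), sat)
  ls <- build_landscape(d)
  expect_equal(sum(ls$value) + attr(ls, "saturated_bp"),
               attr(ls, "eligible_bp"))
  expect_equal(attr(ls, "saturated_bp"), 300)
})

test_that("trimmed hits are excluded from divergence records", {
  h <- mk_div(0L, 400L, "DNA", "hAT-Ac", 0.1)
  h$trimmed <- TRUE
  expect_equal(nrow(hit_divergence(h)), 0)
})

test_that("percent normalization divides by analyzed length", {
  d <- mk_div(0L, 400L, "DNA", "hAT-Ac", 0.104)
  ls <- build_landscape(d, analyzed_bp = 10000, normalization = "percent")
  expect_equal(ls$value[ls$bin == 10], 4.0)
  expect_error(build_landscape(d, normalization = "percent"),
               class = "repeatscape_validation_error")
})

test_that("main_peak finds planted bursts and prefers the larger one", {
  sim <- simulate_genome(sim_config(
    seed = 83, genome_length = 250000,
    families = list(sim_family("DNA/hAT-Ac", 60, 0.10, 800))))
  ls <- divergence_landscape(sim$genome, sim$library)
  pk <- main_peak(ls)
  expect_true(pk$lo_bin <= 10 && pk$hi_bin >= 10)
  expect_lte(pk$hi_bin - pk$lo_bin + 1, 3)

  sim2 <- simulate_genome(sim_config(
    seed = 84, genome_length = 200000,
    families = list(sim_family("LINE/L2", n_copies = c(20, 70),
                               K = c(0.05, 0.25), consensus_length = 400))))
  ls2 <- divergence_landscape(sim2$genome, sim2$library)
  pk2 <- main_peak(ls2)
  expect_true(pk2$lo_bin <= 25 && pk2$hi_bin >= 25)
  expect_false(pk2$lo_bin <= 5 && pk2$hi_bin >= 5)

  expect_true(is.na(main_peak(ls[0, ])$peak_bin))
  zero <- ls
  zero$value <- 0
  expect_true(is.na(main_peak(zero)$peak_bin))
})

test_that("grouping by TE type conserves totals", {
  d <- dplyr::bind_rows(mk_div(0L, 100L, "DNA", "hAT-Ac", 0.629),
                        mk_div(200L, 350L, "DNA", "Kolobok", 0.1),
                        mk_div(400L, 600L, "LTR", "Gypsy", 0.1),
                        mk_div(700L, 800L, "Satellite", NA, 0.05))
  ls <- build_landscape(d)
  g <- group_by_te_type(ls)
  expect_setequal(unique(g$label), c("DNA", "LTR", "other"))
  expect_equal(sum(g$value), sum(ls$value))
  expect_equal(sum(g$value[g$label == "DNA"]), 250)
  dna_bin10 <- sum(ls$value[ls$bin == 10 &
                              ls$label %in% c("DNA/hAT-Ac", "DNA/Kolobok")])
  expect_equal(g$value[g$label == "DNA" & g$bin == 10], dna_bin10)
  empty <- build_landscape(mk_div(0L, 10L, "DNA", "x", 0.1)[0, ])
  expect_equal(nrow(group_by_te_type(empty)), 0)
})

test_that("self-comparison gives the intra-genome landscape", {
  sim <- simulate_genome(sim_config(
    seed = 85, genome_length = 60000,
    families = list(sim_family("DNA/hAT-Ac", 10, 0.08, 300))))
  intra <- divergence_landscape(sim$genome, sim$library)
  cross <- cross_species_landscape(sim$genome, sim$library)
  expect_equal(tidy(cross), tidy(intra))
  expect_error(cross_species_landscape(sim$genome, sim$library[0, ]),
               class = "repeatscape_validation_error")
})

test_that("parameter recovery: planted copies return their K to ~1e-2", {
  sim <- simulate_genome(sim_config(
    seed = 86, genome_length = 80000,
    families = list(sim_family("DNA/hAT-Ac", 1, 0.10,
                               consensus_length = 10000,
                               indel_rate = 0.005))))
  res <- resolve_overlaps(scan_repeats(sim$genome, sim$library))
  d <- hit_divergence(res)
  expect_equal(nrow(d), 1)
  expect_lt(abs(d$K - sim$truth$K), 0.01)
})
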