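test_that("coverage merges overlaps before dividing", {
  iv <- tibble::tibble(seq_id = "s", start = c(0, 200), end = c(300, 400))
  expect_equal(coverage_pct(iv, 10000), 4.0)
  iv2 <- tibble::tibble(seq_id = "s", start = c(0, 1000), end = c(200, 1300))
  expect_equal(coverage_pct(iv2, 10000), 5.0)
  expect_equal(coverage_pct(iv[0, ], 10000), 0)
  expect_error(coverage_pct(iv, 0), class = "repeatscape_validation_error")
})

test_that("loci density is loci per megabase", {
  expect_equal(loci_per_mb(2, 10000), 200)
  expect_equal(loci_per_mb(0, 10000), 0)
  expect_equal(loci_per_mb(3, 2.5e6), 1.2)
  expect_error(loci_per_mb(3, 0), class = "repeatscape_validation_error")
})

mk_hit <- function(start, end, te_class, family, name = "x") tibble::tibble(
  seq_id = "s", start = start, end = end, strand = "+",
  consensus_name = name, te_class = te_class, family = family,
  cons_start = 0L, cons_end = end - start, score = 100L,
  aligned_cols = end - start, matches = end - start, transitions = 0L,
  transversions = 0L, ambiguous_cols = 0L, gap_cols = 0L, trimmed = FALSE)

test_that("the summary aggregates leaves into parents in scheme order", {
  hits <- dplyr::bind_rows(
    mk_hit(0L, 200L, "DNA", "hAT-Ac"),
    mk_hit(300L, 500L, "DNA", "hAT-Charlie"),
    mk_hit(600L, 800L, "DNA", "hAT-Ac"),
    mk_hit(900L, 1100L, "LTR", "Gypsy"))
  s <- summarize_repeats(hits, analyzed_bp = 1e5)
  row <- function(lab) s[s$group_label == lab, ]
  expect_equal(row("DNA transposons")$n_loci, 3L)
  expect_equal(row("DNA transposons")$coverage_pct, 0.6)
  expect_equal(row("hobo-Activator")$n_loci, 3L)
  expect_equal(row("LTR elements")$n_loci, 1L)
  expect_equal(row("LTR elements")$coverage_pct, 0.2)
  expect_equal(row("Gypsy/DIRS1")$n_loci, 1L)
  expect_equal(row("Retroelements")$n_loci, 1L) # aggregates its LTR child
  expect_equal(row("Retroelements")$coverage_pct, 0.2)
  expect_equal(row("DNA transposons")$nl_per_mb, 30)
  expect_equal(s$group_label, default_scheme()$group_label)
})

test_that("unmatched families fall back; unmatched classes error", {
  s <- summarize_repeats(mk_hit(0L, 100L, "DNA", "Kolobok"),
                         analyzed_bp = 1e4)
  expect_equal(s$n_loci[s$group_label == "Other"], 1L)
  s2 <- summarize_repeats(mk_hit(0L, 100L, "LINE", "Weird"),
                          analyzed_bp = 1e4)
  expect_equal(s2$n_loci[s2$group_label == "LINEs:"], 1L)
  expect_equal(s2$n_loci[s2$group_label == "Retroelements"], 1L)
  expect_error(summarize_repeats(mk_hit(0L, 100L, "Plasmid", NA),
                                 analyzed_bp = 1e4),
               class = "repeatscape_contract_error")
})

test_that("an empty hit set gives an all-zero summary", {
  s <- summarize_repeats(mk_hit(0L, 10L, "DNA", "x")[0, ], analyzed_bp = 1e4)
  expect_true(all(s$n_loci == 0))
  expect_true(all(s$coverage_pct == 0))
})

test_that("SSR and low-complexity rows are filled from their tables", {
  ssr <- tibble::tibble(seq_id = "s", start = c(0, 100), end = c(20, 130),
                        motif = "AC", copies = 10)
  lc <- tibble::tibble(seq_id = "s", start = 500, end = 600)
  s <- summarize_repeats(mk_hit(0L, 10L, "DNA", "x")[0, ], ssr, lc,
                         analyzed_bp = 1e4)
  expect_equal(s$n_loci[s$group_label == "Simple repeats"], 2L)
  expect_equal(s$coverage_pct[s$group_label == "Simple repeats"], 0.5)
  expect_equal(s$n_loci[s$group_label == "Low complexity"], 1L)
  expect_equal(s$coverage_pct[s$group_label == "Low complexity"], 1.0)
})

test_that("per-family locus counts match planted counts on simulator output", {
  sim <- simulate_genome(sim_config(
    seed = 71, genome_length = 150000,
    families = list(sim_family("DNA/hAT-Ac", 12, 0.08, 400),
                    sim_family("LTR/Gypsy", 8, 0.12, 400),
                    sim_family("LINE/L2", 6, 0.10, 400))))
  res <- resolve_overlaps(scan_repeats(sim$genome, sim$library))
  s <- summarize_repeats(res, analyzed_bp = 150000)
  expect_equal(s$n_loci[s$group_label == "hobo-Activator"], 12L)
  expect_equal(s$n_loci[s$group_label == "Gypsy/DIRS1"], 8L)
  expect_equal(s$n_loci[s$group_label == "L2/CR1/Rex"], 6L)
  expect_equal(s$n_loci[s$group_label == "Retroelements"], 14L)
})

test_that("per-sequence summaries pool consistently by length weighting", {
  cons <- withr::with_seed(72, rand_dna(300))
  sim <- simulate_genome(sim_config(
    seed = 73, genome_length = 40000, seq_id = "bacA",
    families = list(sim_family("DNA/hAT-Ac", 6, 0.05, consensus = cons))))
  sim2 <- simulate_genome(sim_config(
    seed = 74, genome_length = 60000, seq_id = "bacB",
    families = list(sim_family("DNA/hAT-Ac", 4, 0.05, consensus = cons))))
  pooled <- genome_tbl(c(sim$genome$seq, sim2$genome$seq),
                       ids = c("bacA", "bacB"))
  hits <- resolve_overlaps(scan_repeats(pooled, sim$library))
  per_a <- summarize_repeats(hits[hits$seq_id == "bacA", ],
                             analyzed_bp = 40000)
  per_b <- summarize_repeats(hits[hits$seq_id == "bacB", ],
                             analyzed_bp = 60000)
  all_s <- summarize_repeats(hits, analyzed_bp = 100000)
  i <- which(all_s$group_label == "DNA transposons")
  expect_equal(all_s$coverage_pct[i],
               (per_a$coverage_pct[i] * 40000 + per_b$coverage_pct[i] * 60000)
               / 100000)
  expect_equal(all_s$nl_per_mb[i],
               (per_a$nl_per_mb[i] * 40000 + per_b$nl_per_mb[i] * 60000)
               / 100000)
})
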