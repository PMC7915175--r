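test_that("an exact planted copy is recovered with a perfect alignment", {
  set.seed(101)
  cons <- rand_dna(200)
  g <- genome_tbl(plant(rand_dna(2000), cons, 800))
  hits <- scan_repeats(g, lib_tbl(cons))
  expect_gte(nrow(hits), 1)
  top <- hits[which.max(hits$score), ]
  expect_equal(top$score, 200L)
  expect_equal(top$start, 800L)
  expect_equal(top$end, 1000L)
  expect_equal(top$transitions, 0L)
  expect_equal(top$transversions, 0L)
  expect_equal(top$matches, 200L)
  expect_equal(top$matches / top$aligned_cols, 1)
})

test_that("substitution columns are classified as planted (ts/tv proportions)", {
  withr::with_seed(202, {
    cons <- rand_dna(500)
    m <- mutate_copy(cons, p = 0.1, q = 0.05, indel_rate = 0)
    g <- genome_tbl(plant(rand_dna(3000), m$seq, 1500))
    hits <- scan_repeats(g, lib_tbl(cons))
    top <- hits[which.max(hits$score), ]
    # realized counts match the simulator truth up to a few columns of
    # chance extension of the local alignment into the flanks
    expect_lte(abs(top$transitions - m$transitions), 5)
    expect_lte(abs(top$transversions - m$transversions), 5)
    # and sit near the planted rates within binomial error (3 sigma)
    expect_lt(abs(top$transitions / top$aligned_cols - 0.1),
              3 * sqrt(0.1 * 0.9 / 500))
    expect_lt(abs(top$transversions / top$aligned_cols - 0.05),
              3 * sqrt(0.05 * 0.95 / 500))
  })
})

test_that("best local score matches the dynamic-programming oracle", {
  skip_if_not_installed("Biostrings")
  withr::with_seed(303, {
    for (case in 1:8) {
      cons <- rand_dna(sample(150:400, 1))
      bg <- rand_dna(sample(800:2000, 1))
      m <- mutate_copy(cons, p = 0.06, q = 0.03, indel_rate = 0.004)
      copy <- if (case %% 2 == 0) revcomp(m$seq) else m$seq
      g <- genome_tbl(plant(bg, copy, sample(100:300, 1)))
      hits <- scan_repeats(g, lib_tbl(cons), scan_params(sensitive = TRUE))
      expect_equal(max(hits$score),
                   oracle_best_local_score(g$seq, cons))
    }
  })
})

test_that("overlap resolution trims by the stated greedy rule", {
  mk <- function(start, end, score, name = "A", ts = 0) tibble::tibble(
    seq_id = "s", start = start, end = end, strand = "+",
    consensus_name = name, te_class = "DNA", family = NA_character_,
    cons_start = 0L, cons_end = end - start, score = score,
    aligned_cols = end - start, matches = end - start - ts, transitions = ts,
    transversions = 0L, ambiguous_cols = 0L, gap_cols = 0L, trimmed = FALSE)

  hits <- dplyr::bind_rows(mk(100L, 300L, 50L), mk(250L, 400L, 40L))
  res <- resolve_overlaps(hits, min_length_bp = 50L)
  expect_equal(res$start, c(100L, 300L))
  expect_equal(res$end, c(300L, 400L))
  expect_equal(res$trimmed, c(FALSE, TRUE))
  # pro-rata rescaling of the trimmed piece: 100/150 of the original
  expect_equal(res$score[2], round(40 * 100 / 150))
  expect_equal(res$aligned_cols[2], res$matches[2] + res$transitions[2] +
                 res$transversions[2] + res$ambiguous_cols[2])

  # remainder shorter than min_length_bp is dropped
  res2 <- resolve_overlaps(dplyr::bind_rows(mk(100L, 300L, 50L),
                                            mk(250L, 400L, 40L)),
                           min_length_bp = 120L)
  expect_equal(nrow(res2), 1)

  # equal score and divergence: lexicographically smaller name wins
  res3 <- resolve_overlaps(dplyr::bind_rows(mk(100L, 300L, 50L, "B"),
                                            mk(100L, 300L, 50L, "A")))
  expect_equal(res3$consensus_name, "A")

  # disjoint input is returned unchanged; resolution is idempotent
  disj <- dplyr::bind_rows(mk(0L, 100L, 30L), mk(200L, 320L, 60L))
  expect_equal(resolve_overlaps(disj), disj)
  expect_equal(resolve_overlaps(res), res)
})

test_that("resolved hits are pairwise disjoint on simulated genomes", {
  sim <- simulate_genome(sim_config(
    seed = 404, genome_length = 60000,
    families = list(sim_family("DNA/hAT-Ac", 10, 0.05, 400),
                    sim_family("LTR/Gypsy", 10, 0.15, 400))))
  res <- resolve_overlaps(scan_repeats(sim$genome, sim$library))
  by_seq <- split(res, res$seq_id)
  for (d in by_seq) {
    d <- d[order(d$start), ]
    if (nrow(d) > 1) expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
  }
})

test_that("scanning the reverse-complemented target mirrors the hit set", {
  set.seed(505)
  cons <- rand_dna(300)
  m <- withr::with_seed(506, mutate_copy(cons, 0.05, 0.02, 0))
  g <- genome_tbl(plant(rand_dna(2500), m$seq, 700))
  L <- nchar(g$seq)
  grc <- genome_tbl(revcomp(g$seq))
  lib <- lib_tbl(cons)
  h1 <- scan_repeats(g, lib)
  h2 <- scan_repeats(grc, lib)
  expect_equal(nrow(h1), nrow(h2))
  mirrored <- tibble::tibble(start = L - h2$end, end = L - h2$start,
                             strand = ifelse(h2$strand == "+", "-", "+"),
                             score = h2$score)
  o1 <- h1[order(h1$start), c("start", "end", "strand", "score")]
  o2 <- mirrored[order(mirrored$start), ]
  expect_equal(o1, o2, ignore_attr = TRUE)
})

test_that("planted copies are recovered with high interval fidelity", {
  sim <- simulate_genome(sim_config(
    seed = 607, genome_length = 120000,
    families = list(sim_family("DNA/hAT-Ac", 15, 0.10, 300),
                    sim_family("LINE/L2", 15, 0.25, 300))))
  res <- resolve_overlaps(scan_repeats(sim$genome, sim$library))
  tr <- sim$truth
  jacc <- vapply(seq_len(nrow(tr)), function(i) {
    ov <- pmin(res$end, tr$end[i]) - pmax(res$start, tr$start[i])
    un <- pmax(res$end, tr$end[i]) - pmin(res$start, tr$start[i])
    if (all(ov <= 0)) 0 else max(ov / un)
  }, numeric(1))
  recall <- mean(jacc > 0)
  expect_gte(recall, 0.95)
  expect_gte(mean(jacc[jacc > 0] >= 0.9), 0.95)
})

test_that("masking lowercases or hardmasks exactly the hit intervals", {
  g <- genome_tbl("ACGTAC", "s")
  h <- tibble::tibble(seq_id = "s", start = 2L, end = 4L)
  expect_equal(mask_repeats(g, h, "soft")$seq, "ACgtAC")
  expect_equal(mask_repeats(g, h, "hard")$seq, "ACNNAC")
  expect_equal(mask_repeats(g, h[0, ], "soft")$seq, "ACGTAC")
  bad <- tibble::tibble(seq_id = "s", start = 2L, end = 10L)
  expect_error(mask_repeats(g, bad, "soft"),
               class = "repeatscape_contract_error")
})

test_that("scan contracts: empty library errors, short records are skipped", {
  g <- genome_tbl("ACGTACGTACGTACGTACGTACGTACGT")
  expect_error(scan_repeats(g, lib_tbl(character(0))),
               class = "repeatscape_validation_error")
  lib <- lib_tbl(c("ACGTAC", paste(rep("ACGT", 20), collapse = "")),
                 names = c("short", "long"))
  expect_warning(scan_repeats(g, lib), "short")
})
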