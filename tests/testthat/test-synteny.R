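fixture_placements <- function() {
  read_placements(system.file("extdata", "table1_placements.tsv",
                              package = "repeatscape"))
}

test_that("the tally reproduces per-BAC gene counts from the fixture", {
  t <- tally_placements(fixture_placements())
  pb <- t$per_bac
  expect_equal(pb$n_genes[pb$bac_id == "36I3"], 2L)
  expect_equal(pb$n_genes[pb$bac_id == "30J4"], 19L)
  expect_equal(pb$n_genes[pb$bac_id == "6P22"], 21L)
  expect_equal(t$n_bacs, 21L)
})

test_that("an empty placement table gives an all-zero tally", {
  t <- tally_placements(fixture_placements()[0, ])
  expect_equal(t$n_bacs, 0L)
  expect_equal(t$n_genes, 0L)
  expect_equal(nrow(t$per_bac), 0)
})

test_that("graph edges count genes per (BAC, species, chromosome)", {
  pl <- tibble::tibble(
    bac_id = "X", gene = c("g1", "g2", "g3", "g4"),
    chromosome_of_origin = "2", arm = "1",
    species = "C", target_chromosome = c("9", "9", "9", "2"))
  sse <- dplyr::mutate(pl, species = "SSE", target_chromosome = "2")
  g <- build_synteny_graph(dplyr::bind_rows(pl, sse))
  e <- dplyr::arrange(g$edges, chromosome_id)
  expect_equal(e$chromosome_id, c("C2", "C9"))
  expect_equal(e$weight, c(1L, 3L))
  expect_equal(g$nodes$home_chromosome[g$nodes$id == "X"], "2")

  # equal chromosome labels in two species stay distinct nodes
  pl2 <- dplyr::mutate(pl, species = "O")
  g2 <- build_synteny_graph(dplyr::bind_rows(pl, pl2, sse))
  expect_setequal(g2$nodes$id[g2$nodes$type == "chromosome"],
                  c("C9", "C2", "O9", "O2"))

  # bipartite: every edge joins a BAC to a chromosome node
  expect_true(all(g2$edges$bac_id %in%
                    g2$nodes$id[g2$nodes$type == "BAC"]))
  expect_true(all(g2$edges$chromosome_id %in%
                    g2$nodes$id[g2$nodes$type == "chromosome"]))
})

test_that("edge weights out of a BAC are bounded by its gene count", {
  sp <- simulate_placements(n_bacs = 8, species = c("C", "S", "O"),
                            n_clusters = 2, genes_per_bac = 5,
                            stray_rate = 0.3, seed = 61)
  g <- build_synteny_graph(sp$placements)
  t <- tally_placements(sp$placements)
  per_sp <- g$edges |>
    dplyr::group_by(bac_id, species) |>
    dplyr::summarise(w = sum(weight), .groups = "drop") |>
    dplyr::left_join(t$per_bac[, c("bac_id", "n_genes")], by = "bac_id")
  expect_true(all(per_sp$w <= per_sp$n_genes))
  expect_true(all(g$edges$weight >= 1))
})

test_that("the layout is deterministic and respects the ideal length", {
  pl <- tibble::tibble(
    bac_id = "X", gene = "g1", chromosome_of_origin = "2", arm = "1",
    species = "C", target_chromosome = "9")
  g <- build_synteny_graph(pl)
  l1 <- layout_fruchterman(g, niter = 2000, seed = 7)
  l2 <- layout_fruchterman(g, niter = 2000, seed = 7)
  expect_identical(l1, l2)
  expect_true(all(is.finite(c(l1$x, l1$y))))
  # two nodes, one edge: separation settles within 20% of k = C = 1
  d <- sqrt(diff(l1$x)^2 + diff(l1$y)^2)
  expect_lt(abs(d - 1), 0.2)
})

test_that("planted clusters are separated by the layout", {
  sp <- simulate_placements(n_bacs = 10, species = c("C", "S"),
                            n_clusters = 2, genes_per_bac = 5,
                            stray_rate = 0, seed = 71)
  g <- build_synteny_graph(sp$placements)
  lay <- layout_fruchterman(g, niter = 3000, seed = 9)
  cluster_of <- function(id) {
    if (startsWith(id, "B")) {
      e <- g$edges[g$edges$bac_id == id, ]
      e$chromosome[1]
    } else sub("^[A-Z]+", "", id)
  }
  lay$cluster <- vapply(lay$id, cluster_of, character(1))
  pts <- as.matrix(lay[, c("x", "y")])
  dd <- as.matrix(dist(pts))
  same <- outer(lay$cluster, lay$cluster, "==")
  diag(same) <- NA
  intra <- mean(dd[same & !is.na(same)])
  inter <- mean(dd[!same & !is.na(same)])
  expect_lt(intra, inter)
})

test_that("degenerate layouts are handled", {
  pl <- tibble::tibble(
    bac_id = c("X", "Y"), gene = "g1", chromosome_of_origin = "2",
    arm = "1", species = c("C", "C"), target_chromosome = c("9", "9"))
  g1 <- build_synteny_graph(pl[1, ])
  g1$nodes <- g1$nodes[g1$nodes$id == "X", ] # single isolated node
  g1$edges <- g1$edges[0, ]
  l <- layout_fruchterman(g1, niter = 10)
  expect_equal(c(l$x, l$y), c(0, 0))

  # a zero-degree node floats free but stays finite
  g2 <- build_synteny_graph(pl)
  g2$nodes <- dplyr::bind_rows(
    g2$nodes, tibble::tibble(id = "lonely", type = "BAC",
                             species = NA, chromosome = NA,
                             home_chromosome = NA))
  l2 <- layout_fruchterman(g2, niter = 500, seed = 3)
  expect_true(all(is.finite(c(l2$x, l2$y))))
})

test_that("graphml export round trips through igraph", {
  sp <- simulate_placements(n_bacs = 6, species = c("C", "S"), seed = 81)
  g <- build_synteny_graph(sp$placements)
  tf <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(g, tf)
  back <- igraph::read_graph(tf, format = "graphml")
  expect_equal(igraph::gorder(back), nrow(g$nodes))
  expect_equal(igraph::gsize(back), nrow(g$edges))
  expect_setequal(igraph::V(back)$name, g$nodes$id)
  expect_equal(sort(igraph::E(back)$weight), sort(g$edges$weight))
})

test_that("tidy/glance accessors summarise graphs and tallies", {
  sp <- simulate_placements(n_bacs = 6, species = c("C", "S"), seed = 91)
  g <- build_synteny_graph(sp$placements)
  expect_equal(glance(g)$n_bacs, 6)
  expect_equal(nrow(tidy(g)), nrow(g$edges))
  t <- tally_placements(sp$placements)
  expect_equal(glance(t)$n_genes, t$n_genes)
})
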