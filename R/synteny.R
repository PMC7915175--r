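#' Tally annotated genes per BAC, arm and chromosome
#'
#' Counts distinct genes per BAC from the home-assignment (`SSE`) rows of a
#' placement table, and aggregates per arm and per chromosome. Arm and
#' chromosome totals count distinct gene symbols, so genes shared by
#' overlapping BACs (adjacent clones annotating the same genes) are counted
#' once, matching how chromosome gene totals are reported.
#'
#' @param placements a validated placement tibble (see [read_placements()]).
#' @return a `synteny_tally` list with tibbles `per_bac`, `per_arm`,
#'   `per_chromosome` and scalars `n_bacs`, `n_genes` (sum of per-chromosome
#'   distinct gene counts).
#' @export
tally_placements <- function(placements) {
  sse <- filter(placements, .data$species == "SSE")
  per_bac <- sse |>
    group_by(.data$bac_id, .data$chromosome_of_origin, .data$arm) |>
    summarise(n_genes = n_distinct(.data$gene), .groups = "drop") |>
    arrange(.data$chromosome_of_origin, .data$arm, .data$bac_id)
  per_arm <- sse |>
    group_by(.data$chromosome_of_origin, .data$arm) |>
    summarise(n_bacs = n_distinct(.data$bac_id),
              n_genes = n_distinct(.data$gene), .groups = "drop")
  per_chromosome <- sse |>
    group_by(.data$chromosome_of_origin) |>
    summarise(n_bacs = n_distinct(.data$bac_id),
              n_genes = n_distinct(.data$gene), .groups = "drop")
  structure(list(per_bac = per_bac, per_arm = per_arm,
                 per_chromosome = per_chromosome,
                 n_bacs = n_distinct(sse$bac_id),
                 n_genes = sum(per_chromosome$n_genes)),
            class = "synteny_tally")
}

#' @export
print.synteny_tally <- function(x, ...) {
  cat(sprintf("Synteny tally: %d BACs, %d genes\n", x$n_bacs, x$n_genes))
  print(x$per_arm)
  invisible(x)
}

#' Build the BAC-chromosome synteny net-graph
#'
#' A bipartite graph linking each BAC to the reference-species chromosomes
#' that carry its genes. One edge per (BAC, species, chromosome) with
#' weight equal to the number of that BAC's genes placed on that
#' chromosome. Chromosome node ids are species-qualified (`C9`-style) so
#' equal chromosome labels in different species stay distinct.
#'
#' @param placements a validated placement tibble with non-`SSE` rows.
#' @return a `synteny_graph` list with tibbles `nodes` (`id`, `type`,
#'   `species`, `chromosome`, `home_chromosome`) and `edges`
#'   (`bac_id`, `chromosome_id`, `species`, `chromosome`, `weight`).
#' @export
build_synteny_graph <- function(placements) {
  ref <- filter(placements, .data$species != "SSE")
  edges <- ref |>
    group_by(.data$bac_id, .data$species, .data$target_chromosome) |>
    summarise(weight = n_distinct(.data$gene), .groups = "drop") |>
    mutate(chromosome_id = paste0(.data$species, .data$target_chromosome)) |>
    select(bac_id = "bac_id", chromosome_id = "chromosome_id",
           species = "species", chromosome = "target_chromosome",
           weight = "weight")
  home <- placements |>
    filter(.data$species == "SSE") |>
    distinct(.data$bac_id, .data$chromosome_of_origin)
  bac_nodes <- distinct(edges, id = .data$bac_id) |>
    left_join(home, by = c(id = "bac_id")) |>
    mutate(type = "BAC", species = NA_character_, chromosome = NA_character_,
           home_chromosome = .data$chromosome_of_origin) |>
    select("id", "type", "species", "chromosome", "home_chromosome")
  chr_nodes <- distinct(edges, id = .data$chromosome_id, .data$species,
                        .data$chromosome) |>
    mutate(type = "chromosome", home_chromosome = NA_character_) |>
    select("id", "type", "species", "chromosome", "home_chromosome")
  structure(list(nodes = bind_rows(bac_nodes, chr_nodes), edges = edges),
            class = "synteny_graph")
}

#' @export
print.synteny_graph <- function(x, ...) {
  cat(sprintf("Synteny net-graph: %d BACs, %d chromosome nodes, %d edges\n",
              sum(x$nodes$type == "BAC"), sum(x$nodes$type == "chromosome"),
              nrow(x$edges)))
  invisible(x)
}

#' Convert a synteny graph to igraph / GraphML
#'
#' @param graph a `synteny_graph`.
#' @return `as_igraph()` returns an [igraph::graph] with node attributes
#'   `type`, `species`, `chromosome` and edge attribute `weight`.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "synteny_graph"))
  igraph::graph_from_data_frame(
    graph$edges[, c("bac_id", "chromosome_id", "weight")],
    directed = FALSE, vertices = graph$nodes)
}

#' @rdname as_igraph
#' @param path output GraphML path.
#' @export
write_graphml <- function(graph, path) {
  g <- as_igraph(graph)
  # igraph cannot serialise NA character attributes; blank them
  for (a in igraph::vertex_attr_names(g)) {
    v <- igraph::vertex_attr(g, a)
    if (is.character(v)) igraph::vertex_attr(g, a) <- ifelse(is.na(v), "", v)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Fruchterman-Reingold layout of a synteny graph
#'
#' The classic force-directed layout on a square of area `n`: ideal edge
#' length `k = C * sqrt(area / n)`, repulsion `k^2 / d` between all node
#' pairs, attraction `d^2 / k` along edges (scaled by `weight / max(weight)`
#' unless `weighted = FALSE`), per-iteration displacement capped at a
#' temperature that decreases linearly from `start_temp` to zero over
#' `niter` iterations. Initial positions are uniform-random from `seed`;
#' the result is deterministic for a fixed graph, seed and parameters.
#'
#' @param graph a `synteny_graph`.
#' @param niter number of iterations.
#' @param start_temp initial temperature; defaults to `sqrt(n_vertices)`.
#' @param seed seed for the initial positions.
#' @param C ideal edge length constant.
#' @param weighted scale attraction by edge weight.
#' @return a tibble `(id, type, x, y)`.
#' @export
layout_fruchterman <- function(graph, niter = 10000, start_temp = NULL,
                               seed = 1, C = 1.0, weighted = TRUE) {
  stopifnot(inherits(graph, "synteny_graph"), niter >= 1)
  nodes <- graph$nodes
  n <- nrow(nodes)
  if (n == 0) stop_validation("graph has no nodes")
  if (n == 1)
    return(tibble(id = nodes$id, type = nodes$type, x = 0, y = 0))
  start_temp <- start_temp %||% sqrt(n)
  if (start_temp <= 0) stop_validation("start_temp must be positive")
  k <- C * 1 # area = n, so k = C * sqrt(n / n)
  side <- sqrt(n)
  pos <- withr::with_seed(seed, matrix(runif(2 * n, 0, side), ncol = 2))
  ei <- match(graph$edges$bac_id, nodes$id)
  ej <- match(graph$edges$chromosome_id, nodes$id)
  w <- if (weighted && nrow(graph$edges) > 0)
    graph$edges$weight / max(graph$edges$weight) else
      rep(1, nrow(graph$edges))
  for (it in seq_len(niter)) {
    t <- start_temp * (1 - (it - 1) / niter)
    dx <- outer(pos[, 1], pos[, 1], "-")
    dy <- outer(pos[, 2], pos[, 2], "-")
    d <- sqrt(dx^2 + dy^2)
    d[d < 1e-9] <- 1e-9
    rep_f <- k^2 / d^2 # repulsion k^2/d divided by d to scale unit vectors
    diag(rep_f) <- 0
    disp_x <- rowSums(dx * rep_f)
    disp_y <- rowSums(dy * rep_f)
    if (length(ei) > 0) {
      ddx <- pos[ei, 1] - pos[ej, 1]
      ddy <- pos[ei, 2] - pos[ej, 2]
      dd <- sqrt(ddx^2 + ddy^2)
      dd[dd < 1e-9] <- 1e-9
      att <- (dd / k) * w # attraction d^2/k, divided by d for unit vectors
      fx <- ddx * att
      fy <- ddy * att
      idx <- c(ei, ej)
      sx <- rowsum(c(-fx, fx), idx)
      sy <- rowsum(c(-fy, fy), idx)
      at <- as.integer(rownames(sx))
      disp_x[at] <- disp_x[at] + sx[, 1]
      disp_y[at] <- disp_y[at] + sy[, 1]
    }
    dl <- sqrt(disp_x^2 + disp_y^2)
    dl[dl < 1e-12] <- 1e-12
    scale <- pmin(dl, t) / dl
    pos[, 1] <- pos[, 1] + disp_x * scale
    pos[, 2] <- pos[, 2] + disp_y * scale
  }
  tibble(id = nodes$id, type = nodes$type, x = pos[, 1], y = pos[, 2])
}
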