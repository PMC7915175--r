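#' Invert the Kimura two-parameter distance
#'
#' Finds transition/transversion proportions `(p, q)` with `p = ratio * q`
#' whose Kimura distance equals `target_K`, by bisection on `q` to
#' `|delta K| <= 1e-10`. Used by the simulator to plant copies at controlled
#' divergence: planting realized substitution proportions makes the truth
#' `K` exactly the closed form of the planted counts.
#'
#' @param target_K desired Kimura distance (>= 0).
#' @param ts_tv_ratio transition/transversion ratio `p/q` (> 0); 2.0 is a
#'   typical vertebrate neutral-site value.
#' @return list with elements `p` and `q`.
#' @details The distance diverges as `1 - 2p - q` approaches 0; `q` is
#'   capped just inside the domain boundary and a `target_K` beyond the
#'   corresponding distance raises an error naming the maximum attainable K.
#' @export
solve_pq <- function(target_K, ts_tv_ratio = 2.0) {
  if (target_K < 0) stop_validation("target_K must be >= 0")
  if (ts_tv_ratio <= 0) stop_validation("ts_tv_ratio must be positive")
  if (target_K == 0) return(list(p = 0, q = 0))
  r <- ts_tv_ratio
  K_of <- function(q) {
    p <- r * q
    -0.5 * log((1 - 2 * p - q) * sqrt(1 - 2 * q))
  }
  q_hi <- (1 - 1e-3) * min(1 / (2 * r + 1), 0.5)
  K_max <- K_of(q_hi)
  if (target_K > K_max)
    stop_validation(
      "target_K = %g is beyond the attainable domain for ts_tv_ratio = %g (max K = %.4f)",
      target_K, r, K_max)
  lo <- 0; hi <- q_hi
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (K_of(mid) < target_K) lo <- mid else hi <- mid
    if (abs(K_of(mid) - target_K) <= 1e-13 || (hi - lo) < 1e-17) break
  }
  q <- (lo + hi) / 2
  list(p = r * q, q = q)
}

#' Mutate a consensus sequence into a diverged copy
#'
#' Per site, a transition is applied with probability `p` and a transversion
#' with probability `q` (the two transversion targets equiprobable). Indels
#' (length 1-3, geometric) occur at `indel_rate` per column: deletions
#' remove sites (and their substitutions) from the truth counts, insertions
#' add random bases that are not counted as sites. `N` sites are never
#' mutated or counted. Draws come from the caller's RNG state; seed with
#' [withr::with_seed()] or [set.seed()] for reproducibility.
#'
#' @param consensus_seq the consensus DNA string.
#' @param p,q transition/transversion probabilities per site (`p + q <= 1`).
#' @param indel_rate indel probability per column.
#' @return list with the mutated `seq` and the realized truth:
#'   `transitions`, `transversions`, `sites`, `p`, `q`, `K`, `saturated`.
#' @export
mutate_copy <- function(consensus_seq, p, q, indel_rate = 0) {
  stopifnot(p >= 0, q >= 0, p + q <= 1)
  chars <- strsplit(toupper(consensus_seq), "", fixed = TRUE)[[1]]
  n <- length(chars)
  is_base <- chars %in% c("A", "C", "G", "T")
  u <- runif(n)
  do_ts <- is_base & u < p
  do_tv <- is_base & u >= p & u < p + q
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  tv1 <- c(A = "C", C = "A", G = "C", T = "A")
  tv2 <- c(A = "T", C = "G", G = "T", T = "G")
  pick2 <- runif(n) < 0.5
  mut <- chars
  mut[do_ts] <- ts_map[chars[do_ts]]
  mut[do_tv] <- ifelse(pick2[do_tv], tv2[chars[do_tv]], tv1[chars[do_tv]])

  deleted <- rep(FALSE, n)
  insert_after <- rep("", n)
  if (indel_rate > 0) {
    iu <- runif(n)
    lens <- pmin(1L + stats::rgeom(n, 0.5), 3L)
    is_del <- iu < indel_rate / 2
    is_ins <- iu >= indel_rate / 2 & iu < indel_rate
    for (i in which(is_del)) {
      to <- min(n, i + lens[i] - 1L)
      deleted[i:to] <- TRUE
    }
    for (i in which(is_ins)) {
      insert_after[i] <- paste(sample(c("A", "C", "G", "T"), lens[i],
                                      replace = TRUE), collapse = "")
    }
  }
  keep <- !deleted
  out <- paste0(mut[keep], insert_after[keep], collapse = "")
  ts_n <- sum(do_ts & keep)
  tv_n <- sum(do_tv & keep)
  sites <- sum(is_base & keep)
  kd <- if (sites > 0) kimura_distance(ts_n, tv_n, sites) else
    tibble(p = 0, q = 0, K = 0, saturated = FALSE)
  list(seq = out, transitions = ts_n, transversions = tv_n, sites = sites,
       p = kd$p, q = kd$q, K = kd$K, saturated = kd$saturated)
}

#' Family and SSR specifications for the simulator
#'
#' `sim_family()` describes one consensus element to plant: its
#' class/family label, the number of copies and the target Kimura
#' divergence. `K` and `n_copies` may be vectors of equal length to plant
#' several bursts of the same element. `sim_ssr()` describes a perfect
#' microsatellite to plant.
#'
#' @param label hierarchical label, `class` or `class/family`
#'   (e.g. `"DNA/hAT-Ac"`).
#' @param n_copies copies per burst.
#' @param K target Kimura divergence per burst.
#' @param consensus_length length of the auto-generated consensus; ignored
#'   when `consensus` is given.
#' @param consensus optional explicit consensus sequence.
#' @param indel_rate indel probability per column.
#' @param ts_tv_ratio transition/transversion ratio used to plant `K`.
#' @return a specification list for [sim_config()].
#' @export
sim_family <- function(label, n_copies, K, consensus_length = 500,
                       consensus = NULL, indel_rate = 0.005,
                       ts_tv_ratio = 2.0) {
  n <- max(length(n_copies), length(K))
  list(label = label, n_copies = rep_len(as.integer(n_copies), n),
       K = rep_len(K, n), consensus_length = as.integer(consensus_length),
       consensus = consensus, indel_rate = indel_rate,
       ts_tv_ratio = ts_tv_ratio)
}

#' @rdname sim_family
#' @param motif SSR motif (1-6 bp).
#' @param copies integer number of motif copies per planted locus.
#' @param n_loci number of loci to plant.
#' @export
sim_ssr <- function(motif, copies, n_loci = 1) {
  stopifnot(nchar(motif) >= 1, nchar(motif) <= 6, copies >= 2)
  list(motif = toupper(motif), copies = as.integer(copies),
       n_loci = as.integer(n_loci))
}

#' Simulation configuration
#'
#' @param seed integer seed; all simulator randomness flows from it.
#' @param genome_length background length in bp.
#' @param gc_fraction background GC content.
#' @param families list of [sim_family()] specifications.
#' @param ssrs list of [sim_ssr()] specifications.
#' @param seq_id id of the simulated sequence.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1, genome_length = 200000, gc_fraction = 0.44,
                       families = list(), ssrs = list(), seq_id = "simchr") {
  stopifnot(genome_length > 0, gc_fraction > 0, gc_fraction < 1)
  structure(list(seed = as.integer(seed),
                 genome_length = as.integer(genome_length),
                 gc_fraction = gc_fraction, families = families, ssrs = ssrs,
                 seq_id = seq_id),
            class = "sim_config")
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Simulate a genome with planted repeats and ground truth
#'
#' Generates i.i.d. background DNA at the configured GC content, plants
#' diverged TE copies (half on the minus strand, placed uniformly without
#' overlap by rejection sampling) and perfect SSRs, and records the exact
#' realized truth for every planted interval. Identical config and seed
#' give byte-identical output.
#'
#' @param config a [sim_config()].
#' @return list with elements `genome` (sequence tibble), `library`
#'   (`repeat_library` of the planted consensus records), `truth` (one row
#'   per planted TE copy: interval, strand, label, realized substitution
#'   counts and `K`) and `ssr_truth`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_genome_impl(config))
}

simulate_genome_impl <- function(config) {
  L <- config$genome_length
  fams <- config$families
  # consensus sequences (generated before anything else for determinism)
  for (i in seq_along(fams)) {
    if (is.null(fams[[i]]$consensus))
      fams[[i]]$consensus <- random_dna(fams[[i]]$consensus_length,
                                        config$gc_fraction)
  }
  est_bp <- sum(vapply(fams, function(f)
    sum(f$n_copies) * nchar(f$consensus), numeric(1))) +
    sum(vapply(config$ssrs, function(s)
      s$n_loci * s$copies * nchar(s$motif), numeric(1)))
  if (est_bp > 0.8 * L)
    stop_validation("planted bp (%d) exceeds 0.8 x genome_length; lower the density",
                    est_bp)

  background <- random_dna(L, config$gc_fraction)

  # realize all copies first (their lengths are needed for placement)
  pieces <- list()
  for (fi in seq_along(fams)) {
    f <- fams[[fi]]
    lab <- split_label(f$label)
    for (bi in seq_along(f$K)) {
      pq <- solve_pq(f$K[bi], f$ts_tv_ratio)
      for (ci in seq_len(f$n_copies[bi])) {
        m <- mutate_copy(f$consensus, pq$p, pq$q, f$indel_rate)
        strand <- sample(c("+", "-"), 1)
        pieces[[length(pieces) + 1L]] <- list(
          kind = "te", family_idx = fi, label = f$label,
          te_class = lab$te_class, family = lab$family, strand = strand,
          seq = if (strand == "-") cpp_revcomp(m$seq) else m$seq,
          ts = m$transitions, tv = m$transversions, sites = m$sites,
          K = m$K, p = m$p, q = m$q)
      }
    }
  }
  for (s in config$ssrs) {
    for (ci in seq_len(s$n_loci)) {
      pieces[[length(pieces) + 1L]] <- list(
        kind = "ssr", label = s$motif, strand = "+",
        seq = strrep(s$motif, s$copies),
        motif = canonical_motif(s$motif), copies = s$copies)
    }
  }

  # uniform non-overlapping placement by rejection sampling
  occupied <- tibble(start = numeric(0), end = numeric(0))
  starts <- integer(length(pieces))
  for (i in seq_along(pieces)) {
    len <- nchar(pieces[[i]]$seq)
    placed <- FALSE
    for (try in seq_len(1000)) {
      s <- sample.int(L - len + 1L, 1L) - 1L
      if (nrow(occupied) == 0 ||
          all(s + len <= occupied$start | s >= occupied$end)) {
        starts[i] <- s
        occupied <- bind_rows(occupied, tibble(start = s, end = s + len))
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop_validation("could not place all repeats without overlap; lower the density")
  }

  genome_seq <- background
  for (i in seq_along(pieces)) {
    s <- starts[i]; piece <- pieces[[i]]$seq
    substr(genome_seq, s + 1L, s + nchar(piece)) <- piece
  }

  is_te <- vapply(pieces, function(pc) pc$kind == "te", logical(1))
  truth <- bind_rows(purrr::map(which(is_te), function(i) {
    pc <- pieces[[i]]
    tibble(copy_id = sprintf("copy_%04d", i), seq_id = config$seq_id,
           start = starts[i], end = starts[i] + nchar(pc$seq),
           strand = pc$strand, label = pc$label, te_class = pc$te_class,
           family = pc$family, transitions = pc$ts, transversions = pc$tv,
           sites = pc$sites, K = pc$K, p = pc$p, q = pc$q)
  }))
  ssr_truth <- bind_rows(purrr::map(which(!is_te), function(i) {
    pc <- pieces[[i]]
    k <- nchar(pc$label) # planted (non-canonical) motif length
    # record the maximal perfect run: background may extend a planted SSR
    # by chance partial copies on either side
    s <- starts[i] + 1L
    e <- starts[i] + nchar(pc$seq)
    n <- nchar(genome_seq)
    while (e < n && substr(genome_seq, e + 1L, e + 1L) ==
           substr(genome_seq, e + 1L - k, e + 1L - k)) e <- e + 1L
    while (s > 1 && substr(genome_seq, s - 1L, s - 1L) ==
           substr(genome_seq, s - 1L + k, s - 1L + k)) s <- s - 1L
    tibble(seq_id = config$seq_id, start = s - 1L, end = e,
           motif = pc$motif, copies = (e - s + 1L) / k)
  }))
  if (nrow(truth) == 0)
    truth <- tibble(copy_id = character(0), seq_id = character(0),
                    start = integer(0), end = integer(0),
                    strand = character(0), label = character(0),
                    te_class = character(0), family = character(0),
                    transitions = integer(0), transversions = integer(0),
                    sites = integer(0), K = numeric(0), p = numeric(0),
                    q = numeric(0))
  if (nrow(ssr_truth) == 0)
    ssr_truth <- tibble(seq_id = character(0), start = integer(0),
                        end = integer(0), motif = character(0),
                        copies = integer(0))

  lib <- new_repeat_library(
    bind_rows(purrr::map(seq_along(fams), function(fi) {
      lab <- split_label(fams[[fi]]$label)
      tibble(name = sprintf("cons%02d_%s", fi,
                            gsub("[^A-Za-z0-9]", "-", fams[[fi]]$label)),
             te_class = lab$te_class, family = lab$family,
             seq = fams[[fi]]$consensus)
    })),
    provenance = "simulated")

  list(genome = tibble(id = config$seq_id, desc = "simulated", seq = genome_seq),
       library = lib, truth = arrange(truth, .data$start),
       ssr_truth = arrange(ssr_truth, .data$start), config = config)
}

#' Write a simulation to disk
#'
#' Writes `genome.fa`, `library.fa`, `truth.bed` (planted TE intervals as
#' BED6 with the family label in the name column), `truth.tsv` and
#' `ssr_truth.tsv` into `dir`.
#'
#' @param sim result of [simulate_genome()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$genome, file.path(dir, "genome.fa"))
  write_repeat_library(sim$library, file.path(dir, "library.fa"))
  bed <- tibble(chrom = sim$truth$seq_id, start = sim$truth$start,
                end = sim$truth$end, name = sim$truth$label, score = 0L,
                strand = sim$truth$strand)
  readr::write_tsv(bed, file.path(dir, "truth.bed"), col_names = FALSE)
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  readr::write_tsv(sim$ssr_truth, file.path(dir, "ssr_truth.tsv"))
  invisible(dir)
}

#' Simulate a pair of species sharing ancestral consensus elements
#'
#' An ancestor consensus set is generated, then mutated into two
#' species-specific consensus sets at `K = D/2` each (substitutions only),
#' so the two species' elements differ by approximately `consensus_divergence
#' = D`. Each species genome is then built from its own consensus set with
#' the per-genome configuration. Annotating one species' genome with the
#' other's library therefore yields copy divergences of roughly the
#' within-genome copy age plus `D` (additivity is approximate).
#'
#' @param config a [sim_config()]; its families define the ancestor set and
#'   the per-genome planting.
#' @param consensus_divergence the consensus-level divergence `D`.
#' @return list with `ancestor_library`, per-species simulations `a` and
#'   `b` (each as [simulate_genome()] returns), and `consensus_divergence`.
#' @export
simulate_species_pair <- function(config, consensus_divergence = 0.08) {
  stopifnot(inherits(config, "sim_config"))
  D <- consensus_divergence
  pq <- solve_pq(D / 2) # also validates the domain
  withr::with_seed(config$seed, {
    fams <- config$families
    for (i in seq_along(fams)) {
      if (is.null(fams[[i]]$consensus))
        fams[[i]]$consensus <- random_dna(fams[[i]]$consensus_length,
                                          config$gc_fraction)
    }
    species <- list()
    for (sp in c("a", "b")) {
      sp_fams <- fams
      for (i in seq_along(sp_fams)) {
        sp_fams[[i]]$consensus <-
          mutate_copy(fams[[i]]$consensus, pq$p, pq$q, 0)$seq
      }
      sp_config <- config
      sp_config$families <- sp_fams
      sp_config$seed <- config$seed + match(sp, c("a", "b"))
      sp_config$seq_id <- paste0(config$seq_id, "_", sp)
      species[[sp]] <- simulate_genome(sp_config)
      attr(species[[sp]]$library, "provenance") <- paste0("species-", sp)
    }
    anc <- new_repeat_library(
      bind_rows(purrr::map(seq_along(fams), function(fi) {
        lab <- split_label(fams[[fi]]$label)
        tibble(name = sprintf("anc%02d", fi), te_class = lab$te_class,
               family = lab$family, seq = fams[[fi]]$consensus)
      })),
      provenance = "ancestor")
    list(ancestor_library = anc, a = species$a, b = species$b,
         consensus_divergence = D)
  })
}

#' Simulate a gene-placement table with planted cluster structure
#'
#' BACs are assigned to clusters; within a reference species every BAC's
#' genes land on its cluster's dominant chromosome, except that each gene
#' strays to a random other chromosome with probability `stray_rate`. Rows
#' for species `SSE` carry the home assignment. The realized edge set
#' (BAC, species, chromosome, weight) is returned as truth.
#'
#' @param n_bacs number of BACs.
#' @param species reference species codes (non-SSE).
#' @param n_clusters number of planted clusters.
#' @param genes_per_bac genes annotated per BAC.
#' @param stray_rate per-gene probability of a stray placement.
#' @param n_decoy_chromosomes extra chromosome labels strays can land on.
#' @param seed integer seed.
#' @return list with `placements` (a valid placement tibble) and
#'   `truth_edges`.
#' @export
simulate_placements <- function(n_bacs = 12, species = c("C", "S", "O", "D"),
                                n_clusters = 2, genes_per_bac = 5,
                                stray_rate = 0, n_decoy_chromosomes = 2,
                                seed = 1) {
  withr::with_seed(seed, {
    cluster <- sort(rep_len(seq_len(n_clusters), n_bacs))
    bac_id <- sprintf("B%02d", seq_len(n_bacs))
    home <- rep_len(c("2", "4"), n_clusters)[cluster]
    labels <- as.character(seq_len(n_clusters + n_decoy_chromosomes))
    rows <- list()
    for (b in seq_len(n_bacs)) {
      genes <- sprintf("g_%s_%d", bac_id[b], seq_len(genes_per_bac))
      rows[[length(rows) + 1L]] <- tibble(
        bac_id = bac_id[b], gene = genes, chromosome_of_origin = home[b],
        arm = "1", species = "SSE", target_chromosome = home[b])
      for (sp in species) {
        dominant <- as.character(cluster[b])
        stray <- runif(genes_per_bac) < stray_rate
        target <- ifelse(stray,
                         sample(setdiff(labels, dominant), genes_per_bac,
                                replace = TRUE),
                         dominant)
        rows[[length(rows) + 1L]] <- tibble(
          bac_id = bac_id[b], gene = genes, chromosome_of_origin = home[b],
          arm = "1", species = sp, target_chromosome = target)
      }
    }
    placements <- bind_rows(rows)
    truth_edges <- placements |>
      filter(.data$species != "SSE") |>
      group_by(.data$bac_id, .data$species, .data$target_chromosome) |>
      summarise(weight = n_distinct(.data$gene), .groups = "drop")
    list(placements = placements, truth_edges = truth_edges)
  })
}
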