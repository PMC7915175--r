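#' Scan parameters for homology-based repeat annotation
#'
#' Scoring and heuristics for the seeded Smith-Waterman scan. A gap of length
#' L costs `gap_open + L * gap_extend` (the first gap column pays both).
#' Ambiguous (`N`) columns score 0 and are never counted as matches or
#' substitutions.
#'
#' @param seed_k exact-match seed length (>= 8). The sensitive preset uses 9.
#' @param match,mismatch unit substitution scores; `match` must be positive
#'   and `mismatch` negative.
#' @param gap_open,gap_extend affine gap penalties (negative).
#' @param xdrop score drop-off terminating ungapped seed extension.
#' @param min_score minimum reported local alignment score.
#' @param min_length_bp minimum reported hit length on the target (>= `seed_k`).
#' @param both_strands scan the reverse complement of each consensus too.
#' @param sensitive convenience flag: lowers `seed_k` to 9 unless `seed_k`
#'   is given explicitly.
#' @return a `scan_params` list.
#' @export
scan_params <- function(seed_k = if (sensitive) 9L else 11L, match = 1L,
                        mismatch = -1L, gap_open = -3L, gap_extend = -1L,
                        xdrop = 12L, min_score = 20L, min_length_bp = 50L,
                        both_strands = TRUE, sensitive = FALSE) {
  p <- list(seed_k = as.integer(seed_k), match = as.integer(match),
            mismatch = as.integer(mismatch), gap_open = as.integer(gap_open),
            gap_extend = as.integer(gap_extend), xdrop = as.integer(xdrop),
            min_score = as.integer(min_score),
            min_length_bp = as.integer(min_length_bp),
            both_strands = isTRUE(both_strands))
  if (p$seed_k < 8 || p$seed_k > 15)
    stop_validation("seed_k must be in [8, 15], got %d", p$seed_k)
  if (p$match <= 0) stop_validation("match score must be positive")
  if (p$mismatch >= 0 || p$gap_open >= 0 || p$gap_extend >= 0)
    stop_validation("mismatch and gap penalties must be negative")
  if (p$xdrop <= 0) stop_validation("xdrop must be positive")
  if (p$min_length_bp < p$seed_k)
    stop_validation("min_length_bp (%d) must be >= seed_k (%d)",
                    p$min_length_bp, p$seed_k)
  structure(p, class = "scan_params")
}

#' Local alignment of two sequences
#'
#' Smith-Waterman local alignment with affine gaps, returning the score,
#' 0-based half-open coordinates of the aligned region on both sequences,
#' and per-column counts (matches, transitions, transversions, ambiguous
#' columns, gap columns). Exposed mainly so downstream code and tests can
#' interrogate single alignments directly.
#'
#' @param a,b DNA strings.
#' @param params a [scan_params()] object (only the scoring fields are used).
#' @return a one-row tibble.
#' @export
local_align <- function(a, b, params = scan_params()) {
  r <- cpp_local_align(a, b, params$match, params$mismatch, params$gap_open,
                       params$gap_extend)
  as_tibble(r[c("score", "a_start", "a_end", "b_start", "b_end", "matches",
                "transitions", "transversions", "ambiguous_cols", "gap_cols",
                "aligned_cols")])
}

#' Annotate target sequences against a consensus repeat library
#'
#' For every consensus x target pair (both strands unless disabled) the scan
#' seeds on exact `seed_k`-mers, extends each seed with an ungapped X-drop
#' walk, merges the candidate regions into refinement windows and re-aligns
#' each window with full affine Smith-Waterman. Substitution columns are
#' classified as transitions (A<->G, C<->T) or transversions; `N` columns are
#' ambiguous. Hits below `min_score` or `min_length_bp` are dropped.
#'
#' @param genome sequence tibble (columns `id`, `seq`).
#' @param library a `repeat_library`; must be nonempty. Records shorter than
#'   `seed_k` are skipped with a warning.
#' @param params a [scan_params()] object.
#' @return a hit tibble sorted by `(seq_id, start, -score)` with coordinates
#'   on target and consensus, strand, class/family, score and alignment
#'   column counts; `trimmed` is `FALSE` for all scan output (see
#'   [resolve_overlaps()]).
#' @export
scan_repeats <- function(genome, library, params = scan_params()) {
  check_genome(genome)
  if (!inherits(params, "scan_params")) stop_validation("invalid scan params")
  if (is.null(library) || nrow(library) == 0)
    stop_validation("repeat library is empty")
  short <- nchar(library$seq) < params$seed_k
  if (any(short)) {
    warn(sprintf("skipping %d library record(s) shorter than seed_k: %s",
                 sum(short), paste(library$name[short], collapse = ", ")))
    library <- library[!short, ]
    if (nrow(library) == 0) stop_validation("no library record is >= seed_k")
  }
  df <- cpp_scan(genome$id, genome$seq, library$name, library$seq,
                 params$seed_k, params$match, params$mismatch, params$gap_open,
                 params$gap_extend, params$xdrop, params$min_score,
                 params$min_length_bp, params$both_strands)
  hits <- as_tibble(df) |>
    left_join(tibble(consensus_name = library$name,
                     te_class = library$te_class, family = library$family),
              by = "consensus_name") |>
    mutate(trimmed = FALSE) |>
    arrange(.data$seq_id, .data$start, desc(.data$score)) |>
    select("seq_id", "start", "end", "strand", "consensus_name", "te_class",
           "family", "cons_start", "cons_end", "score", "aligned_cols",
           "matches", "transitions", "transversions", "ambiguous_cols",
           "gap_cols", "trimmed")
  hits
}

#' Resolve overlapping hits into a disjoint locus set
#'
#' Greedy by descending score (ties: lower divergence proportion, then
#' lexicographic consensus name, then leftmost start). A lower-scoring hit
#' overlapping an accepted hit is trimmed to its non-overlapping remainder
#' and kept only if each remaining piece is at least `min_length_bp` long;
#' alignment column counts and score of trimmed pieces are rescaled pro rata
#' and the piece is flagged `trimmed` (trimmed hits are excluded from
#' divergence landscapes downstream). The output is pairwise disjoint per
#' sequence, so loci are countable without double cover.
#'
#' @param hits a hit tibble from [scan_repeats()].
#' @param min_length_bp minimum length of a kept trimmed piece.
#' @return disjoint hit tibble sorted by `(seq_id, start)`. Idempotent.
#' @export
resolve_overlaps <- function(hits, min_length_bp = 50L) {
  if (nrow(hits) == 0) return(hits)
  div <- divergence_proportion(hits)
  ord <- order(-hits$score, div, hits$consensus_name, hits$start)
  out <- vector("list", nrow(hits))
  accepted <- split(tibble(start = numeric(0), end = numeric(0)),
                    character(0))
  for (i in ord) {
    h <- hits[i, ]
    acc <- accepted[[h$seq_id]]
    if (is.null(acc)) acc <- tibble(start = numeric(0), end = numeric(0))
    pieces <- subtract_interval(h$start, h$end, acc)
    pieces <- pieces[pieces$end - pieces$start >= min_length_bp, , drop = FALSE]
    if (nrow(pieces) == 0) next
    full <- nrow(pieces) == 1 && pieces$start[1] == h$start &&
      pieces$end[1] == h$end
    kept <- if (full) h else rescale_pieces(h, pieces)
    out[[i]] <- kept
    accepted[[h$seq_id]] <- bind_rows(acc, kept[, c("start", "end")])
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) return(hits[0, ])
  arrange(res, .data$seq_id, .data$start)
}

# pro-rata rescaling of alignment counts for trimmed hit pieces
rescale_pieces <- function(h, pieces) {
  frac <- (pieces$end - pieces$start) / (h$end - h$start)
  n <- nrow(pieces)
  res <- h[rep(1L, n), ]
  res$start <- pieces$start
  res$end <- pieces$end
  res$score <- as.integer(round(h$score * frac))
  res$matches <- as.integer(round(h$matches * frac))
  res$transitions <- as.integer(round(h$transitions * frac))
  res$transversions <- as.integer(round(h$transversions * frac))
  res$ambiguous_cols <- as.integer(round(h$ambiguous_cols * frac))
  res$gap_cols <- as.integer(round(h$gap_cols * frac))
  res$aligned_cols <- res$matches + res$transitions + res$transversions +
    res$ambiguous_cols
  res$trimmed <- TRUE
  res
}

#' Mask annotated intervals in target sequences
#'
#' @param genome sequence tibble.
#' @param hits disjoint hit tibble (or any interval table with `seq_id`,
#'   `start`, `end`).
#' @param mode `"soft"` lowercases within hit intervals, `"hard"` replaces
#'   them with `N`; everything else is unchanged.
#' @return the genome tibble with masked `seq`.
#' @export
mask_repeats <- function(genome, hits, mode = c("soft", "hard")) {
  mode <- match.arg(mode)
  check_genome(genome)
  if (nrow(hits) == 0) return(genome)
  if (!all(hits$seq_id %in% genome$id))
    stop_contract("hit references unknown sequence id '%s'",
                  setdiff(hits$seq_id, genome$id)[1])
  lens <- setNames(nchar(genome$seq), genome$id)[hits$seq_id]
  if (any(hits$start < 0 | hits$end > lens))
    stop_contract("hit outside sequence bounds")
  for (i in seq_len(nrow(genome))) {
    hs <- hits[hits$seq_id == genome$id[i], ]
    s <- genome$seq[i]
    for (j in seq_len(nrow(hs))) {
      a <- hs$start[j] + 1L; b <- hs$end[j]
      piece <- if (mode == "soft") tolower(substr(s, a, b))
               else strrep("N", b - a + 1L)
      substr(s, a, b) <- piece
    }
    genome$seq[i] <- s
  }
  genome
}
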