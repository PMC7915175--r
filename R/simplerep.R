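#' Find perfect simple sequence repeats (microsatellites)
#'
#' Detects maximal perfect tandem runs of motifs of length 1-6. Runs are
#' extended into partial trailing/leading copies, so `copies` may be
#' fractional. Motifs are canonicalised to the lexicographically minimal
#' rotation over both strands, making detection strand-symmetric. Runs whose
#' motif is a repetition of a shorter unit are suppressed (an `(ATAT)n`
#' match is reported once as `(AT)n`).
#'
#' @param genome sequence tibble (columns `id`, `seq`).
#' @param min_total_len minimum run length in bp.
#' @param min_copies named vector of minimum copy numbers per motif length.
#' @return tibble `(seq_id, start, end, motif, copies)` sorted by sequence
#'   and start; coordinates 0-based half-open.
#' @export
find_ssrs <- function(genome, min_total_len = 12,
                      min_copies = c(`1` = 12, `2` = 6, `3` = 4, `4` = 3,
                                     `5` = 3, `6` = 3)) {
  check_genome(genome)
  out <- purrr::map(seq_len(nrow(genome)), function(i) {
    runs <- ssr_runs_one(toupper(genome$seq[i]), min_total_len, min_copies)
    if (nrow(runs) > 0) runs$seq_id <- genome$id[i]
    runs
  })
  res <- bind_rows(out)
  if (nrow(res) == 0)
    return(tibble(seq_id = character(0), start = integer(0), end = integer(0),
                  motif = character(0), copies = numeric(0)))
  arrange(res[, c("seq_id", "start", "end", "motif", "copies")],
          .data$seq_id, .data$start)
}

ssr_runs_one <- function(seq, min_total_len, min_copies) {
  n <- nchar(seq)
  found <- list()
  for (k in 1:6) {
    pat <- sprintf("([ACGT]{%d})\\1+", k)
    m <- gregexpr(pat, seq, perl = TRUE)[[1]]
    if (m[1] == -1) next
    lens <- attr(m, "match.length")
    for (idx in seq_along(m)) {
      p <- m[idx]; L <- lens[idx]
      motif <- substr(seq, p, p + k - 1L)
      if (!is_primitive(motif)) next
      # extend into partial copies left and right
      s <- p; e <- p + L - 1L
      while (e < n && substr(seq, e + 1L, e + 1L) ==
             substr(seq, e + 1L - k, e + 1L - k)) e <- e + 1L
      while (s > 1 && substr(seq, s - 1L, s - 1L) ==
             substr(seq, s - 1L + k, s - 1L + k)) s <- s - 1L
      run_len <- e - s + 1L
      if (run_len < min_total_len) next
      if (run_len / k < min_copies[[as.character(k)]]) next
      # suppress if contained in an already-found run whose period divides k
      contained <- FALSE
      for (f in found) {
        if (f$s <= s && f$e >= e && k %% f$k == 0) { contained <- TRUE; break }
      }
      if (contained) next
      found[[length(found) + 1L]] <-
        list(s = s, e = e, k = k, motif = substr(seq, s, s + k - 1L),
             copies = run_len / k)
    }
  }
  if (length(found) == 0)
    return(tibble(start = integer(0), end = integer(0), motif = character(0),
                  copies = numeric(0)))
  tibble(start = vapply(found, function(f) f$s - 1L, integer(1)),
         end = vapply(found, function(f) f$e, integer(1)),
         motif = vapply(found, function(f) canonical_motif(f$motif),
                        character(1)),
         copies = vapply(found, function(f) f$copies, numeric(1)))
}

# a motif is primitive if it is not a whole number of copies of a shorter unit
is_primitive <- function(motif) {
  k <- nchar(motif)
  if (k == 1) return(TRUE)
  for (d in seq_len(k - 1)) {
    if (k %% d != 0) next
    if (strrep(substr(motif, 1, d), k / d) == motif) return(FALSE)
  }
  TRUE
}

# lexicographically minimal rotation over the motif and its reverse complement
canonical_motif <- function(motif) {
  k <- nchar(motif)
  rots <- function(x) vapply(seq_len(k), function(i)
    paste0(substr(x, i, k), substr(x, 1, i - 1)), character(1))
  min(c(rots(motif), rots(cpp_revcomp(motif))))
}

#' Flag low-complexity regions by windowed Shannon entropy
#'
#' Slides a window over each sequence, computes base-2 Shannon entropy of the
#' A/C/G/T frequencies (ignoring `N`), flags windows below the threshold and
#' merges flagged windows that overlap or lie within `merge_gap` bp of each
#' other. Intervals are clipped to the sequence.
#'
#' @param genome sequence tibble.
#' @param window window size in bp (>= 16).
#' @param max_entropy entropy threshold in bits (flag when below).
#' @param merge_gap maximum gap between merged flags.
#' @return tibble `(seq_id, start, end)`, 0-based half-open.
#' @export
find_low_complexity <- function(genome, window = 64, max_entropy = 1.2,
                                merge_gap = 10) {
  check_genome(genome)
  if (window < 16) stop_validation("window must be >= 16")
  out <- purrr::map(seq_len(nrow(genome)), function(i) {
    iv <- lc_one(toupper(genome$seq[i]), window, max_entropy, merge_gap)
    if (nrow(iv) > 0) iv$seq_id <- genome$id[i]
    iv
  })
  res <- bind_rows(out)
  if (nrow(res) == 0)
    return(tibble(seq_id = character(0), start = numeric(0), end = numeric(0)))
  arrange(res[, c("seq_id", "start", "end")], .data$seq_id, .data$start)
}

lc_one <- function(seq, window, max_entropy, merge_gap) {
  n <- nchar(seq)
  empty <- tibble(start = numeric(0), end = numeric(0))
  if (n < window) return(empty)
  chars <- utf8ToInt(seq)
  ent <- window_entropy(chars, window)
  flagged <- which(ent < max_entropy)
  if (length(flagged) == 0) return(empty)
  iv <- tibble(start = flagged - 1, end = pmin(flagged - 1 + window, n))
  merge_with_gap(iv, merge_gap)
}

# merge sorted intervals whose gap is <= `gap`
merge_with_gap <- function(iv, gap) {
  iv <- iv[order(iv$start), , drop = FALSE]
  starts <- iv$start[1]; ends <- iv$end[1]
  if (nrow(iv) > 1) {
    for (i in 2:nrow(iv)) {
      last <- length(ends)
      if (iv$start[i] <= ends[last] + gap) {
        ends[last] <- max(ends[last], iv$end[i])
      } else {
        starts <- c(starts, iv$start[i]); ends <- c(ends, iv$end[i])
      }
    }
  }
  tibble(start = starts, end = ends)
}

# entropy of every length-`window` window via prefix sums; chars are utf8 ints
window_entropy <- function(chars, window) {
  n <- length(chars)
  m <- n - window + 1L
  counts <- matrix(0, nrow = m, ncol = 4)
  for (b in 1:4) {
    code <- utf8ToInt(c("A", "C", "G", "T")[b])
    cs <- c(0L, cumsum(chars == code))
    counts[, b] <- cs[(window + 1L):(n + 1L)] - cs[1:m]
  }
  tot <- rowSums(counts)
  p <- counts / pmax(tot, 1)
  ent <- -rowSums(ifelse(p > 0, p * log2(p), 0))
  ent[tot == 0] <- Inf # all-N windows carry no A/C/G/T signal; never flagged
  ent
}

#' Trim simple-repeat/low-complexity intervals against resolved TE hits
#'
#' TE annotation takes precedence over the simple-repeat categories so that
#' per-category coverages are additive: any part of an SSR or low-complexity
#' interval overlapping a resolved TE hit is removed, and remaining pieces
#' shorter than `min_length_bp` are dropped. When the interval table carries
#' a `motif` column, `copies` is recomputed from the trimmed length.
#'
#' @param intervals SSR or low-complexity interval tibble.
#' @param te_hits disjoint TE hit tibble.
#' @param min_length_bp minimum length of a kept piece.
#' @return trimmed interval tibble.
#' @export
apply_te_precedence <- function(intervals, te_hits, min_length_bp = 12) {
  if (nrow(intervals) == 0 || nrow(te_hits) == 0) return(intervals)
  out <- purrr::map(seq_len(nrow(intervals)), function(i) {
    row <- intervals[i, ]
    acc <- te_hits[te_hits$seq_id == row$seq_id, c("start", "end")]
    pieces <- subtract_interval(row$start, row$end, acc)
    pieces <- pieces[pieces$end - pieces$start >= min_length_bp, , drop = FALSE]
    if (nrow(pieces) == 0) return(NULL)
    res <- row[rep(1L, nrow(pieces)), ]
    res$start <- pieces$start
    res$end <- pieces$end
    if ("motif" %in% names(res) && "copies" %in% names(res))
      res$copies <- (res$end - res$start) / nchar(res$motif)
    res
  })
  res <- bind_rows(out)
  if (nrow(res) == 0) return(intervals[0, ])
  arrange(res, .data$seq_id, .data$start)
}
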