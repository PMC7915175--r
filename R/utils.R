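# Internal helpers shared across modules. All genomic intervals in the package
# are 0-based half-open; conversion to 1-based inclusive happens only in the
# RM-style `.out` writer.

stop_parse <- function(msg, ...) {
  abort(sprintf(msg, ...), class = c("repeatscape_parse_error", "repeatscape_error"))
}

stop_validation <- function(msg, ...) {
  abort(sprintf(msg, ...), class = c("repeatscape_validation_error", "repeatscape_error"))
}

stop_contract <- function(msg, ...) {
  abort(sprintf(msg, ...), class = c("repeatscape_contract_error", "repeatscape_error"))
}

#' Reverse complement of DNA strings
#'
#' Case is preserved (soft-masked lowercase stays lowercase); characters other
#' than `A/C/G/T` map to `N`.
#'
#' @param x character vector of DNA strings.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  vapply(x, cpp_revcomp, character(1), USE.NAMES = FALSE)
}

# Merge overlapping/adjacent-at-zero-gap intervals within one sequence.
# `df` needs columns start, end (0-based half-open); returns the merged set.
merge_intervals <- function(df) {
  if (nrow(df) == 0) return(df[, c("start", "end")])
  df <- df[order(df$start, df$end), , drop = FALSE]
  out_start <- df$start[1]
  out_end <- df$end[1]
  starts <- ends <- numeric(0)
  for (i in seq_len(nrow(df))[-1]) {
    if (df$start[i] <= out_end) {
      out_end <- max(out_end, df$end[i])
    } else {
      starts <- c(starts, out_start); ends <- c(ends, out_end)
      out_start <- df$start[i]; out_end <- df$end[i]
    }
  }
  tibble(start = c(starts, out_start), end = c(ends, out_end))
}

# Total merged base pairs of a (seq_id, start, end) interval table.
merged_bp <- function(intervals) {
  if (is.null(intervals) || nrow(intervals) == 0) return(0)
  if (!"seq_id" %in% names(intervals)) intervals$seq_id <- "*"
  sum(vapply(split(intervals, intervals$seq_id),
             function(d) { m <- merge_intervals(d); sum(m$end - m$start) },
             numeric(1)))
}

# Subtract interval set `b` from interval set `a` (both 0-based half-open,
# same sequence); returns the remaining pieces of `a` as a start/end tibble.
subtract_interval <- function(start, end, b) {
  pieces <- tibble(start = start, end = end)
  if (nrow(b) == 0) return(pieces)
  b <- merge_intervals(b)
  out <- list()
  for (i in seq_len(nrow(pieces))) {
    s <- pieces$start[i]; e <- pieces$end[i]
    cur <- s
    for (j in seq_len(nrow(b))) {
      bs <- b$start[j]; be <- b$end[j]
      if (be <= cur || bs >= e) next
      if (bs > cur) out[[length(out) + 1L]] <- c(cur, bs)
      cur <- max(cur, be)
      if (cur >= e) break
    }
    if (cur < e) out[[length(out) + 1L]] <- c(cur, e)
  }
  if (length(out) == 0) return(tibble(start = numeric(0), end = numeric(0)))
  m <- do.call(rbind, out)
  tibble(start = m[, 1], end = m[, 2])
}

check_genome <- function(genome, arg = "genome") {
  if (!is.data.frame(genome) || !all(c("id", "seq") %in% names(genome)))
    stop_validation("`%s` must be a data frame with columns `id` and `seq`", arg)
  invisible(genome)
}
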