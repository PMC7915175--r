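#' Write repeat hits to BED6 or an RM-style `.out` table
#'
#' Internal coordinates are 0-based half-open throughout the package; the
#' `out` dialect converts to the 1-based inclusive convention of classic
#' repeat-annotation tables (`begin = start + 1`, `end` unchanged).
#'
#' @param hits a hit tibble (from [scan_repeats()] / [resolve_overlaps()]),
#'   sorted by `(seq_id, start)`.
#' @param path output path.
#' @param dialect `"bed"` for 6-column BED or `"out"` for a header-carrying
#'   tab-separated table with columns score, divergence %, query, begin, end,
#'   strand, matching repeat, class/family.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path, dialect = c("bed", "out")) {
  dialect <- match.arg(dialect)
  if (nrow(hits) > 0) {
    o <- order(hits$seq_id, hits$start)
    if (!identical(o, seq_len(nrow(hits))))
      stop_contract("hits must be sorted by (seq_id, start) before writing")
  }
  label <- te_label(hits$te_class, hits$family)
  if (dialect == "bed") {
    bed <- tibble(
      chrom = hits$seq_id, start = hits$start, end = hits$end,
      name = paste0(hits$consensus_name, "#", label),
      score = pmin(pmax(hits$score, 0L), 1000L), strand = hits$strand)
    readr::write_tsv(bed, path, col_names = FALSE)
  } else {
    div <- divergence_proportion(hits)
    out <- tibble(
      score = hits$score,
      divergence_pct = round(100 * div, 4),
      query = hits$seq_id,
      begin = hits$start + 1L,
      end = hits$end,
      strand = hits$strand,
      matching_repeat = hits$consensus_name,
      class_family = label)
    readr::write_tsv(out, path, col_names = TRUE)
  }
  invisible(path)
}

#' Read hits written by [write_hits()]
#'
#' @param path file to read.
#' @param dialect dialect the file was written with.
#' @return a tibble with 0-based half-open `start`/`end` plus the fields the
#'   dialect carries (`consensus_name`, `te_class`, `family`, `score`,
#'   `strand`; the `out` dialect also restores `divergence_pct`).
#' @export
read_hits <- function(path, dialect = c("bed", "out")) {
  dialect <- match.arg(dialect)
  if (dialect == "bed") {
    df <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name",
                                              "score", "strand"),
                          col_types = "ciicic", progress = FALSE)
    lab <- split_label(sub("^[^#]*#?", "", df$name))
    tibble(seq_id = df$chrom, start = df$start, end = df$end,
           strand = df$strand, consensus_name = sub("#.*$", "", df$name),
           te_class = lab$te_class, family = lab$family, score = df$score)
  } else {
    df <- readr::read_tsv(path, col_types = "idciiccc", progress = FALSE)
    lab <- split_label(df$class_family)
    tibble(seq_id = df$query, start = df$begin - 1L, end = df$end,
           strand = df$strand, consensus_name = df$matching_repeat,
           te_class = lab$te_class, family = lab$family, score = df$score,
           divergence_pct = df$divergence_pct)
  }
}

# class/family -> "class" or "class/family" label
te_label <- function(te_class, family) {
  ifelse(is.na(family) | !nzchar(family), te_class,
         paste0(te_class, "/", family))
}

split_label <- function(label) {
  te_class <- sub("/.*$", "", label)
  family <- ifelse(grepl("/", label), sub("^[^/]*/", "", label), NA_character_)
  te_class[!nzchar(te_class)] <- "Unknown"
  list(te_class = te_class, family = family)
}

divergence_proportion <- function(hits) {
  sites <- hits$aligned_cols - hits$ambiguous_cols
  ifelse(sites > 0, (hits$transitions + hits$transversions) / sites, 0)
}
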