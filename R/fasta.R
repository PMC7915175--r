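#' Read a FASTA file into a sequence tibble
#'
#' Sequences are returned in file order as a tibble with one row per record.
#' Lowercase (soft-masked) bases are preserved; Windows line endings are
#' tolerated. The allowed alphabet is `A/C/G/T/N` in either case.
#'
#' @param path path to a FASTA file.
#' @return a tibble with columns `id` (first whitespace-delimited token of the
#'   header), `desc` (remainder of the header, possibly empty) and `seq`.
#' @details Parse problems (empty file, sequence data before the first header,
#'   duplicate ids, illegal characters, empty sequences) raise a classed error
#'   (`repeatscape_parse_error`) identifying the offending line.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">x some description", "ACGT", "acgtn"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_parse("FASTA file not found: %s", path)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  if (length(lines) == 0 || all(!nzchar(trimws(lines))))
    stop_parse("empty FASTA file: %s", path)
  header_at <- which(startsWith(lines, ">"))
  if (length(header_at) == 0)
    stop_parse("%s: no FASTA header ('>') found (line 1)", path)
  pre <- which(nzchar(trimws(lines[seq_len(header_at[1] - 1)])))
  if (length(pre) > 0)
    stop_parse("%s: sequence data before first header (line %d)", path, pre[1])

  headers <- sub("^>", "", lines[header_at])
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(ids))) {
    bad <- header_at[which(!nzchar(ids))[1]]
    stop_parse("%s: empty record id (line %d)", path, bad)
  }
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop_parse("%s: duplicate record id '%s' (line %d)", path, dup,
               header_at[which(ids == dup)[2]])
  }

  block_end <- c(header_at[-1] - 1L, length(lines))
  seqs <- character(length(header_at))
  for (i in seq_along(header_at)) {
    body <- lines[seq(header_at[i] + 1L, length.out = block_end[i] - header_at[i])]
    bad <- grepl("[^ACGTNacgtn]", body)
    if (any(bad))
      stop_parse("%s: illegal character in sequence '%s' (line %d)", path,
                 ids[i], header_at[i] + which(bad)[1])
    seqs[i] <- paste(body, collapse = "")
    if (!nzchar(seqs[i]))
      stop_parse("%s: record '%s' has an empty sequence (line %d)", path,
                 ids[i], header_at[i])
  }
  tibble(id = ids, desc = descs, seq = seqs)
}

#' Write a sequence tibble to FASTA
#'
#' @param seqs tibble with columns `id`, `seq` and optionally `desc`.
#' @param path output path.
#' @param width line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  check_genome(seqs, "seqs")
  desc <- if ("desc" %in% names(seqs)) seqs$desc else rep("", nrow(seqs))
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(seqs))) {
    hdr <- if (nzchar(desc[i])) paste(seqs$id[i], desc[i]) else seqs$id[i]
    body <- gsub(sprintf("(.{%d})", width), "\\1\n", seqs$seq[i])
    body <- sub("\n$", "", body)
    writeLines(c(paste0(">", hdr), body), con, sep = "\n")
  }
  invisible(path)
}
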