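#' Consensus repeat libraries
#'
#' A repeat library is a tibble of consensus elements with one row per record
#' and columns `name`, `te_class`, `family` (`NA` when the label has no
#' family part) and `seq`, carrying a `provenance` attribute (for example
#' `"external"` or `"chr2-derived"`). Headers follow the RepBase-style
#' dialect `name#class/family`; a bare `name` is given class `Unknown`.
#'
#' @param seqs a sequence tibble as returned by [read_fasta()].
#' @param provenance provenance string stored on the result.
#' @return a `repeat_library` tibble.
#' @examples
#' lib <- parse_repeat_library(
#'   tibble::tibble(id = c("HAT1#DNA/hAT-Ac", "SAT-X#Satellite", "elemA"),
#'                  desc = "", seq = c("ACGT", "ACGT", "ACGT")))
#' lib$te_class
#' @export
parse_repeat_library <- function(seqs, provenance = "external") {
  check_genome(seqs, "seqs")
  name <- sub("#.*$", "", seqs$id)
  label <- ifelse(grepl("#", seqs$id), sub("^[^#]*#", "", seqs$id), "")
  lab <- split_label(label)
  if (anyDuplicated(name)) {
    dups <- unique(name[duplicated(name)])
    stop_validation("duplicate consensus name(s) in library: %s",
                    paste(dups, collapse = ", "))
  }
  new_repeat_library(
    tibble(name = name, te_class = lab$te_class, family = lab$family,
           seq = seqs$seq),
    provenance)
}

new_repeat_library <- function(df, provenance = "external") {
  structure(as_tibble(df),
            provenance = provenance,
            class = c("repeat_library", class(as_tibble(df))))
}

#' @rdname parse_repeat_library
#' @param path a library FASTA file with `name#class/family` headers.
#' @export
read_repeat_library <- function(path, provenance = "external") {
  parse_repeat_library(read_fasta(path), provenance)
}

#' Write a repeat library to FASTA with `name#class/family` headers
#'
#' Records with class `Unknown` and no family are written as bare names so
#' that a read/write round trip is the identity.
#'
#' @param library a `repeat_library`.
#' @param path output path.
#' @export
write_repeat_library <- function(library, path) {
  bare <- library$te_class == "Unknown" &
    (is.na(library$family) | !nzchar(library$family))
  id <- ifelse(bare, library$name,
               paste0(library$name, "#", te_label(library$te_class, library$family)))
  write_fasta(tibble(id = id, desc = "", seq = library$seq), path)
}

#' Dereplicate near-identical records of a repeat library
#'
#' Greedy clustering: records are sorted by length descending (ties by name
#' ascending) and each record joins the first retained representative to
#' which its best local alignment (either strand) reaches at least
#' `min_identity` over at least `min_coverage_frac` of the shorter sequence;
#' otherwise it is retained as a new representative. Identity is
#' `matches / alignment columns` with gap columns counted as mismatch
#' columns, so indel-divergent duplicates are penalised.
#'
#' @param library a `repeat_library`.
#' @param min_identity minimum alignment identity in (0, 1].
#' @param min_coverage_frac minimum aligned fraction of the shorter sequence.
#' @param params alignment scoring parameters, see [scan_params()].
#' @return the dereplicated `repeat_library`, representatives kept in sorted
#'   (length-descending) order. Idempotent; an empty library passes through.
#' @export
dereplicate <- function(library, min_identity = 0.95, min_coverage_frac = 0.90,
                        params = scan_params()) {
  stopifnot(min_identity > 0, min_identity <= 1,
            min_coverage_frac > 0, min_coverage_frac <= 1)
  if (nrow(library) == 0) return(library)
  ord <- order(-nchar(library$seq), library$name)
  lib <- library[ord, ]
  keep <- logical(nrow(lib))
  for (i in seq_len(nrow(lib))) {
    absorbed <- FALSE
    for (j in which(keep)) {
      if (aligns_at(lib$seq[i], lib$seq[j], min_identity, min_coverage_frac,
                    params)) {
        absorbed <- TRUE
        break
      }
    }
    keep[i] <- !absorbed
  }
  new_repeat_library(lib[keep, ], attr(library, "provenance") %||% "external")
}

# does `a` align to representative `b` at the given thresholds (either strand)?
aligns_at <- function(a, b, min_identity, min_coverage_frac, params) {
  short_len <- min(nchar(a), nchar(b))
  for (qry in c(a, cpp_revcomp(a))) {
    r <- cpp_local_align(qry, b, params$match, params$mismatch,
                         params$gap_open, params$gap_extend)
    cols <- r$aligned_cols + r$gap_cols
    if (cols == 0) next
    span <- if (nchar(a) <= nchar(b)) r$a_end - r$a_start else r$b_end - r$b_start
    if (r$matches / cols >= min_identity &&
        span >= min_coverage_frac * short_len) return(TRUE)
  }
  FALSE
}

#' Build a per-chromosome custom repeat library from annotation hits
#'
#' Extracts the genomic subsequence of every hit (reverse-complemented for
#' minus-strand hits), names it `origName_seqid_start_end`, inherits the
#' class/family of the matched consensus, and dereplicates the result. This
#' is the custom-library step of the cross-species divergence workflow: a
#' library derived from one chromosome is then used to annotate syntenic
#' regions of other species.
#'
#' @param hits resolved hits on `genome` (see [resolve_overlaps()]).
#' @param genome the sequence tibble the hits refer to.
#' @param label provenance label for the resulting library.
#' @inheritParams dereplicate
#' @return a `repeat_library` with provenance `label`.
#' @export
build_chromosome_library <- function(hits, genome, label,
                                     min_identity = 0.95,
                                     min_coverage_frac = 0.90) {
  check_genome(genome)
  if (nrow(hits) == 0) return(new_repeat_library(
    tibble(name = character(0), te_class = character(0),
           family = character(0), seq = character(0)), label))
  seqs <- setNames(genome$seq, genome$id)
  if (!all(hits$seq_id %in% names(seqs)))
    stop_contract("hit references unknown sequence id '%s'",
                  setdiff(hits$seq_id, names(seqs))[1])
  lens <- nchar(seqs)[hits$seq_id]
  if (any(hits$start < 0 | hits$end > lens | hits$start >= hits$end))
    stop_contract("hit coordinates out of sequence bounds")
  frag <- substr(seqs[hits$seq_id], hits$start + 1L, hits$end)
  frag <- ifelse(hits$strand == "-", revcomp(frag), frag)
  lib <- new_repeat_library(
    tibble(name = sprintf("%s_%s_%d_%d", hits$consensus_name, hits$seq_id,
                          hits$start, hits$end),
           te_class = hits$te_class, family = hits$family, seq = unname(frag)),
    label)
  out <- dereplicate(lib, min_identity, min_coverage_frac)
  attr(out, "provenance") <- label
  out
}
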