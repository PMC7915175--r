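# Shared fixtures and independent oracles used across test files.

# uniform random DNA, caller controls the RNG state
rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

genome_tbl <- function(seqs, ids = sprintf("seq%d", seq_along(seqs))) {
  tibble::tibble(id = ids, desc = "", seq = seqs)
}

lib_tbl <- function(seqs, names = sprintf("cons%d", seq_along(seqs)),
                    te_class = "DNA", family = "hAT-Ac") {
  repeatscape:::new_repeat_library(
    tibble::tibble(name = names, te_class = te_class, family = family,
                   seq = seqs),
    "test")
}

# Independent Smith-Waterman oracle via Biostrings::pairwiseAlignment.
# Same scoring convention as the package: +1/-1, a gap of length L costs
# gap_open + L * gap_extend.
oracle_best_local_score <- function(target, cons, both_strands = TRUE) {
  skip_if_not_installed("Biostrings")
  m <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                baseOnly = TRUE)
  sc <- function(a, b) Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
    substitutionMatrix = m, gapOpening = 3, gapExtension = 1,
    scoreOnly = TRUE)
  best <- sc(target, cons)
  if (both_strands)
    best <- max(best, sc(target, as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(cons)))))
  best
}

# Identity of the best local alignment (matches / columns incl. gap columns),
# and the aligned span on the shorter sequence -- oracle for dereplication.
oracle_identity <- function(a, b) {
  skip_if_not_installed("Biostrings")
  m <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                baseOnly = TRUE)
  best <- NULL
  for (qry in c(a, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(a))))) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(qry), Biostrings::DNAString(b), type = "local",
      substitutionMatrix = m, gapOpening = 3, gapExtension = 1)
    aln_p <- as.character(Biostrings::alignedPattern(pa))
    aln_s <- as.character(Biostrings::alignedSubject(pa))
    cp <- strsplit(aln_p, "")[[1]]
    cs <- strsplit(aln_s, "")[[1]]
    ident <- sum(cp == cs & cp != "-") / length(cp)
    span_p <- sum(cp != "-")
    span_s <- sum(cs != "-")
    span_short <- if (nchar(a) <= nchar(b)) span_p else span_s
    cand <- list(identity = ident,
                 cover = span_short / min(nchar(a), nchar(b)))
    if (is.null(best) || cand$identity > best$identity) best <- cand
  }
  best
}

# plant `copy` into `background` at 0-based `at` by overwriting
plant <- function(background, copy, at) {
  substr(background, at + 1, at + nchar(copy)) <- copy
  background
}
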