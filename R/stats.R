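#' Percent coverage of an interval set
#'
#' Overlapping intervals are merged before summing, so the value is the
#' fraction of analyzed sequence covered at least once, as a percentage.
#'
#' @param intervals tibble with `start`, `end` (and optionally `seq_id`).
#' @param analyzed_bp total analyzed sequence length in bp (> 0).
#' @return coverage percentage in \[0, 100\].
#' @export
coverage_pct <- function(intervals, analyzed_bp) {
  if (!is.numeric(analyzed_bp) || length(analyzed_bp) != 1 || analyzed_bp <= 0)
    stop_validation("analyzed_bp must be a single positive number")
  100 * merged_bp(intervals) / analyzed_bp
}

#' Number of loci per megabase
#'
#' @param n_loci locus count.
#' @param analyzed_bp total analyzed sequence length in bp (> 0).
#' @return `n_loci * 1e6 / analyzed_bp`.
#' @export
loci_per_mb <- function(n_loci, analyzed_bp) {
  if (!is.numeric(analyzed_bp) || length(analyzed_bp) != 1 || analyzed_bp <= 0)
    stop_validation("analyzed_bp must be a single positive number")
  n_loci * 1e6 / analyzed_bp
}

#' Default repeat classification scheme
#'
#' The hierarchy used by the per-class/family summary table: Retroelements
#' split into SINEs (with Penelope as printed child), LINEs
#' (L2/CR1/Rex, R1/LOA/Jockey, R2/R4/NeSL, RTE/Bov-B, L1/CIN4) and LTR
#' elements (BEL/Pao, Ty1/Copia, Gypsy/DIRS1, Retroviral); DNA transposons
#' split into hobo-Activator, Tc1-IS630-Pogo, PiggyBac, Tourist/Harbinger
#' and Other; plus top-level rows for rolling-circle elements, satellites,
#' simple repeats, low complexity and unclassified records. A hit whose
#' family matches no leaf pattern falls into the nearest fallback row of its
#' class ("Other" for DNA transposons, the class row otherwise).
#'
#' @return a tibble with columns `group_label`, `level`, `parent`,
#'   `te_class` (regex on the class), `family_regex` (`NA` marks the
#'   fallback row of the class).
#' @export
default_scheme <- function() {
  tribble_ <- function(...) {
    m <- matrix(c(...), ncol = 5, byrow = TRUE)
    tibble(group_label = m[, 1], level = as.integer(m[, 2]), parent = m[, 3],
           te_class = m[, 4], family_regex = ifelse(m[, 5] == "", NA, m[, 5]))
  }
  tribble_(
    "Retroelements",      1, NA,              "SINE|LINE|LTR", "",
    "SINEs:",             2, "Retroelements", "SINE",          "",
    "Penelope",           3, "SINEs:",        "SINE|LINE",     "Penelope",
    "LINEs:",             2, "Retroelements", "LINE",          "",
    "L2/CR1/Rex",         3, "LINEs:",        "LINE",          "^(L2|CR1|Rex)",
    "R1/LOA/Jockey",      3, "LINEs:",        "LINE",          "^(R1|LOA|Jockey)",
    "R2/R4/NeSL",         3, "LINEs:",        "LINE",          "^(R2|R4|NeSL)",
    "RTE/Bov-B",          3, "LINEs:",        "LINE",          "^(RTE|Bov)",
    "L1/CIN4",            3, "LINEs:",        "LINE",          "^(L1|CIN4)",
    "LTR elements",       2, "Retroelements", "LTR",           "",
    "BEL/Pao",            3, "LTR elements",  "LTR",           "^(BEL|Pao)",
    "Ty1/Copia",          3, "LTR elements",  "LTR",           "^(Ty1|Copia)",
    "Gypsy/DIRS1",        3, "LTR elements",  "LTR",           "^(Gypsy|DIRS)",
    "Retroviral",         3, "LTR elements",  "LTR",           "Retrovir|^ERV",
    "DNA transposons",    1, NA,              "DNA",           "",
    "hobo-Activator",     2, "DNA transposons", "DNA",         "^(hobo|hAT)",
    "Tc1-IS630-Pogo",     2, "DNA transposons", "DNA",         "^(Tc1|TcMar|Tc-?[Mm]ar|IS630|Pogo)",
    "PiggyBac",           2, "DNA transposons", "DNA",         "PiggyBac",
    "Tourist/Harbinger",  2, "DNA transposons", "DNA",         "Tourist|Harbinger|PIF",
    "Other",              2, "DNA transposons", "DNA",         "",
    "Rolling-circles",    1, NA,              "RC",            "",
    "Satellites",         1, NA,              "Satellite",     "",
    "Simple repeats",     1, NA,              "Simple_repeat", "",
    "Low complexity",     1, NA,              "Low_complexity", "",
    "Unclassified",       1, NA,              "Unknown",       "")
}

# assign each hit its leaf row of the scheme; fallback = the class row whose
# family_regex is NA (for DNA that is the "Other" leaf, else the class row)
classify_hits <- function(te_class, family, scheme) {
  leaves <- scheme[!is.na(scheme$family_regex), ]
  out <- character(length(te_class))
  for (i in seq_along(te_class)) {
    row <- NA_character_
    fam <- family[i]
    if (!is.na(fam) && nzchar(fam)) {
      for (j in seq_len(nrow(leaves))) {
        if (grepl(leaves$te_class[j], te_class[i]) &&
            grepl(leaves$family_regex[j], fam, ignore.case = TRUE)) {
          row <- leaves$group_label[j]
          break
        }
      }
    }
    if (is.na(row)) {
      fb <- scheme[is.na(scheme$family_regex) &
                     vapply(scheme$te_class, grepl, logical(1),
                            x = te_class[i]), ]
      fb <- fb[order(-fb$level), ]
      if (nrow(fb) == 0)
        stop_contract("class '%s' is absent from the scheme and has no fallback",
                      te_class[i])
      # prefer the deepest fallback of the exact class ("Other" for DNA)
      row <- fb$group_label[1]
    }
    out[i] <- row
  }
  out
}

#' Summarise repeat content per class and family
#'
#' Computes, for every row of the classification scheme, the number of loci
#' (`n_loci`), the loci density (`nl_per_mb`) and the percent coverage of
#' the analyzed sequence. Parent rows aggregate their children (a hit is
#' counted in its leaf row and all ancestors). TE hits must be disjoint
#' (post [resolve_overlaps()]); SSR and low-complexity intervals should have
#' been trimmed with [apply_te_precedence()] so the category coverages are
#' additive.
#'
#' @param te_hits disjoint TE hit tibble.
#' @param ssr_hits SSR tibble from [find_ssrs()] (or `NULL`).
#' @param lc_intervals low-complexity intervals from [find_low_complexity()]
#'   (or `NULL`).
#' @param analyzed_bp total analyzed sequence length in bp. By convention
#'   this is the full target length including `N` runs.
#' @param scheme classification scheme, see [default_scheme()].
#' @return a `repeat_summary` tibble with one row per scheme node in scheme
#'   order: `group_label`, `n_loci`, `nl_per_mb`, `coverage_pct`.
#' @export
summarize_repeats <- function(te_hits, ssr_hits = NULL, lc_intervals = NULL,
                              analyzed_bp, scheme = default_scheme()) {
  if (!is.numeric(analyzed_bp) || analyzed_bp <= 0)
    stop_validation("analyzed_bp must be positive")
  leaf_of <- if (nrow(te_hits) > 0)
    classify_hits(te_hits$te_class, te_hits$family, scheme) else character(0)

  rows <- scheme
  rows$n_loci <- 0L
  rows$bp <- 0
  for (i in seq_len(nrow(rows))) {
    lab <- rows$group_label[i]
    members <- lab
    repeat {
      kids <- scheme$group_label[!is.na(scheme$parent) &
                                   scheme$parent %in% members]
      new <- setdiff(kids, members)
      if (length(new) == 0) break
      members <- c(members, new)
    }
    sel <- leaf_of %in% members
    rows$n_loci[i] <- sum(sel)
    rows$bp[i] <- merged_bp(te_hits[sel, , drop = FALSE])
  }
  if (!is.null(ssr_hits) && nrow(ssr_hits) > 0) {
    i <- which(rows$group_label == "Simple repeats")
    rows$n_loci[i] <- rows$n_loci[i] + nrow(ssr_hits)
    rows$bp[i] <- rows$bp[i] + merged_bp(ssr_hits)
  }
  if (!is.null(lc_intervals) && nrow(lc_intervals) > 0) {
    i <- which(rows$group_label == "Low complexity")
    rows$n_loci[i] <- rows$n_loci[i] + nrow(lc_intervals)
    rows$bp[i] <- rows$bp[i] + merged_bp(lc_intervals)
  }
  out <- tibble(group_label = rows$group_label,
                n_loci = rows$n_loci,
                nl_per_mb = loci_per_mb(rows$n_loci, analyzed_bp),
                coverage_pct = 100 * rows$bp / analyzed_bp)
  structure(out, analyzed_bp = analyzed_bp,
            class = c("repeat_summary", class(out)))
}
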