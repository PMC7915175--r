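#' Kimura two-parameter distance from substitution counts
#'
#' Given transition and transversion counts over `sites` aligned non-gap,
#' non-ambiguous columns, computes `p = ts/sites`, `q = tv/sites` and
#' `K = -1/2 * log((1 - 2p - q) * sqrt(1 - 2q))`. When `1 - 2p - q <= 0` or
#' `1 - 2q <= 0` the distance is saturated: `saturated` is set and `K` is
#' `NA`.
#'
#' @param transitions,transversions,sites integer vectors (recycled);
#'   `sites` must be positive and `transitions + transversions <= sites`.
#' @return tibble with columns `p`, `q`, `K`, `saturated`.
#' @examples
#' kimura_distance(10, 5, 100) # K = 0.1701...
#' @export
kimura_distance <- function(transitions, transversions, sites) {
  n <- max(length(transitions), length(transversions), length(sites))
  transitions <- rep_len(transitions, n)
  transversions <- rep_len(transversions, n)
  sites <- rep_len(sites, n)
  if (any(sites <= 0)) stop_validation("sites must be positive")
  if (any(transitions + transversions > sites))
    stop_validation("transitions + transversions must not exceed sites")
  p <- transitions / sites
  q <- transversions / sites
  w1 <- 1 - 2 * p - q
  w2 <- 1 - 2 * q
  saturated <- w1 <= 0 | w2 <= 0
  K <- ifelse(saturated, NA_real_, -0.5 * log(w1 * sqrt(w2)))
  tibble(p = p, q = q, K = K, saturated = saturated)
}

#' Per-copy divergence records for a hit set
#'
#' Applies [kimura_distance()] to every untrimmed hit, using
#' `sites = aligned_cols - ambiguous_cols` (gap columns carry no divergence
#' signal under the two-parameter model and are excluded; ambiguous columns
#' likewise). Trimmed hits carry pro-rata approximated counts and are
#' excluded entirely.
#'
#' @param hits a hit tibble (typically post [resolve_overlaps()]).
#' @return the untrimmed hits with columns `sites`, `p`, `q`, `K`,
#'   `saturated` appended.
#' @export
hit_divergence <- function(hits) {
  hits <- hits[!hits$trimmed, , drop = FALSE]
  sites <- hits$aligned_cols - hits$ambiguous_cols
  hits <- hits[sites > 0, , drop = FALSE]
  sites <- sites[sites > 0]
  kd <- kimura_distance(hits$transitions, hits$transversions, sites)
  hits$sites <- sites
  hits$p <- kd$p
  hits$q <- kd$q
  hits$K <- kd$K
  hits$saturated <- kd$saturated
  hits
}

#' Bin per-copy divergences into a repeat landscape
#'
#' Each non-saturated record adds its genomic length (`end - start`) to the
#' percent-K bin `floor(100 * K)` of its class/family; bin 50 collects
#' everything at `K >= 0.50`. Saturated copies are excluded from the bins
#' but their total length is reported in the `saturated_bp` attribute, so
#' binned bp + saturated bp equals the divergence-eligible annotated bp.
#'
#' @param divergence divergence records from [hit_divergence()].
#' @param analyzed_bp analyzed sequence length; required when
#'   `normalization = "percent"`.
#' @param normalization `"bp"` (raw base pairs per bin) or `"percent"`
#'   (percent of `analyzed_bp`).
#' @return a `repeat_landscape` tibble `(label, te_class, bin, value)` with a
#'   complete 0..50 bin grid per label and attributes `normalization`,
#'   `analyzed_bp`, `saturated_bp`, `eligible_bp`.
#' @export
build_landscape <- function(divergence, analyzed_bp = NULL,
                            normalization = c("bp", "percent")) {
  normalization <- match.arg(normalization)
  if (normalization == "percent" &&
      (is.null(analyzed_bp) || analyzed_bp <= 0))
    stop_validation("percent normalization requires a positive analyzed_bp")
  ok <- !divergence$saturated
  d <- divergence[ok, , drop = FALSE]
  saturated_bp <- sum(divergence$end[!ok] - divergence$start[!ok])
  eligible_bp <- sum(divergence$end - divergence$start)
  if (nrow(d) > 0) {
    grid <- tibble(label = te_label(d$te_class, d$family),
                   te_class = d$te_class,
                   bin = pmin(floor(100 * d$K), 50),
                   len = d$end - d$start) |>
      group_by(.data$label, .data$te_class, .data$bin) |>
      summarise(value = sum(.data$len), .groups = "drop") |>
      tidyr::complete(tidyr::nesting(label, te_class), bin = 0:50,
                      fill = list(value = 0)) |>
      arrange(.data$label, .data$bin)
  } else {
    grid <- tibble(label = character(0), te_class = character(0),
                   bin = integer(0), value = numeric(0))
  }
  if (normalization == "percent") grid$value <- 100 * grid$value / analyzed_bp
  structure(grid[, c("label", "te_class", "bin", "value")],
            normalization = normalization, analyzed_bp = analyzed_bp,
            saturated_bp = saturated_bp, eligible_bp = eligible_bp,
            class = c("repeat_landscape", class(grid)))
}

#' Locate the main divergence peak of a landscape
#'
#' Sums the landscape over families per bin, smooths with a centered
#' moving average (edge-truncated), takes the argmax bin (ties resolved to
#' the lower bin) and reports the maximal contiguous run of bins containing
#' the peak whose smoothed value is at least `plateau_frac` of the smoothed
#' maximum. Peaks are reported as ranges because burst ages are better
#' described by a plateau than a single bin.
#'
#' @param landscape a `repeat_landscape`.
#' @param smooth_window centered moving-average window (odd).
#' @param plateau_frac plateau threshold as a fraction of the smoothed max.
#' @return a one-row tibble `(lo_bin, hi_bin, peak_bin, peak_value)`; all
#'   `NA` when the landscape is empty or all-zero (the no-peak result).
#' @export
main_peak <- function(landscape, smooth_window = 3, plateau_frac = 0.8) {
  no_peak <- tibble(lo_bin = NA_integer_, hi_bin = NA_integer_,
                    peak_bin = NA_integer_, peak_value = NA_real_)
  if (nrow(landscape) == 0) return(no_peak)
  totals <- rep(0, 51)
  agg <- landscape |>
    group_by(.data$bin) |>
    summarise(value = sum(.data$value), .groups = "drop")
  totals[agg$bin + 1] <- agg$value
  if (all(totals == 0)) return(no_peak)
  half <- (smooth_window - 1) %/% 2
  sm <- vapply(seq_along(totals), function(i) {
    lo <- max(1, i - half); hi <- min(length(totals), i + half)
    mean(totals[lo:hi])
  }, numeric(1))
  peak <- which.max(sm)
  above <- sm >= plateau_frac * sm[peak]
  lo <- peak
  while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- peak
  while (hi < length(sm) && above[hi + 1]) hi <- hi + 1
  tibble(lo_bin = lo - 1L, hi_bin = hi - 1L, peak_bin = peak - 1L,
         peak_value = sm[peak])
}

#' Annotate a target and build its divergence landscape in one call
#'
#' The composition scan -> overlap resolution -> per-copy Kimura distance ->
#' landscape. Used both within one genome (the library and the target come
#' from the same assembly) and in cross-species mode, where a custom
#' library derived from one species' chromosome (see
#' [build_chromosome_library()]) is applied to syntenic regions of another
#' species; the contract is identical, only the library provenance differs.
#'
#' @param target_genome sequence tibble to annotate.
#' @param source_library the consensus library driving the annotation.
#' @param params scan parameters.
#' @param analyzed_bp analyzed length; defaults to the total target length.
#' @param normalization passed to [build_landscape()].
#' @return a `repeat_landscape` (attributes as in [build_landscape()]).
#' @export
divergence_landscape <- function(target_genome, source_library,
                                 params = scan_params(), analyzed_bp = NULL,
                                 normalization = "bp") {
  check_genome(target_genome, "target_genome")
  analyzed_bp <- analyzed_bp %||% sum(nchar(target_genome$seq))
  scan_repeats(target_genome, source_library, params) |>
    resolve_overlaps(min_length_bp = params$min_length_bp) |>
    hit_divergence() |>
    build_landscape(analyzed_bp = analyzed_bp, normalization = normalization)
}

#' @rdname divergence_landscape
#' @export
cross_species_landscape <- divergence_landscape

#' Group a landscape by top-level TE type
#'
#' Re-keys the landscape rows by TE type (`DNA`, `LTR`, `LINE`, `SINE`,
#' `RC`, `other`) and sums values per bin; totals are conserved.
#'
#' @param landscape a `repeat_landscape`.
#' @return a `repeat_landscape` whose labels are TE types.
#' @export
group_by_te_type <- function(landscape) {
  if (nrow(landscape) == 0) return(landscape)
  type <- ifelse(landscape$te_class %in% c("DNA", "LTR", "LINE", "SINE", "RC"),
                 landscape$te_class, "other")
  grid <- tibble(label = type, te_class = type, bin = landscape$bin,
                 value = landscape$value) |>
    group_by(.data$label, .data$te_class, .data$bin) |>
    summarise(value = sum(.data$value), .groups = "drop") |>
    arrange(.data$label, .data$bin)
  structure(grid, normalization = attr(landscape, "normalization"),
            analyzed_bp = attr(landscape, "analyzed_bp"),
            saturated_bp = attr(landscape, "saturated_bp"),
            eligible_bp = attr(landscape, "eligible_bp"),
            class = c("repeat_landscape", setdiff(class(grid),
                                                  "repeat_landscape")))
}
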