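# broom-style accessors for the package's result objects

#' Tidy and glance methods
#'
#' `tidy()` returns the underlying observations as a plain tibble;
#' `glance()` returns a one-row summary.
#'
#' @param x a `repeat_landscape`, `synteny_graph` or `synteny_tally`.
#' @param ... unused.
#' @return a tibble.
#' @name repeatscape-tidiers
NULL

#' @rdname repeatscape-tidiers
#' @export
tidy.repeat_landscape <- function(x, ...) {
  as_tibble(unclass(x)[c("label", "te_class", "bin", "value")])
}

#' @rdname repeatscape-tidiers
#' @export
glance.repeat_landscape <- function(x, ...) {
  pk <- main_peak(x)
  tibble(n_families = n_distinct(x$label),
         total_value = sum(x$value),
         saturated_bp = attr(x, "saturated_bp") %||% NA_real_,
         eligible_bp = attr(x, "eligible_bp") %||% NA_real_,
         normalization = attr(x, "normalization") %||% "bp",
         peak_bin = pk$peak_bin, peak_lo = pk$lo_bin, peak_hi = pk$hi_bin)
}

#' @rdname repeatscape-tidiers
#' @export
tidy.synteny_graph <- function(x, ...) as_tibble(x$edges)

#' @rdname repeatscape-tidiers
#' @export
glance.synteny_graph <- function(x, ...) {
  tibble(n_bacs = sum(x$nodes$type == "BAC"),
         n_chromosomes = sum(x$nodes$type == "chromosome"),
         n_edges = nrow(x$edges),
         total_weight = sum(x$edges$weight))
}

#' @rdname repeatscape-tidiers
#' @export
tidy.synteny_tally <- function(x, ...) as_tibble(x$per_bac)

#' @rdname repeatscape-tidiers
#' @export
glance.synteny_tally <- function(x, ...) {
  tibble(n_bacs = x$n_bacs, n_genes = x$n_genes)
}
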