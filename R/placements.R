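#' Read a gene-placement table
#'
#' A placement table records, for every annotated BAC gene, where that gene
#' lies in each species: rows with species code `SSE` carry the home
#' assignment of the BAC (chromosome of origin and arm), rows with other
#' species codes carry syntenic placements on reference-species chromosomes.
#'
#' @param path a tab-separated file with header columns `bac_id`, `gene`,
#'   `chromosome_of_origin`, `arm`, `species`, `target_chromosome`.
#' @return a validated tibble. Whitespace is trimmed; gene symbols are kept
#'   verbatim (case preserved).
#' @details Validation failures (missing columns, empty fields, duplicate
#'   `(bac_id, gene, species)` triples, a chromosome of origin other than 2
#'   or 4) raise a `repeatscape_validation_error`.
#' @seealso [tally_placements()], [build_synteny_graph()]; the packaged
#'   example table `system.file("extdata", "table1_placements.tsv",
#'   package = "repeatscape")`.
#' @export
read_placements <- function(path) {
  if (!file.exists(path)) stop_validation("placement table not found: %s", path)
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  required <- c("bac_id", "gene", "chromosome_of_origin", "arm", "species",
                "target_chromosome")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop_validation("placement table is missing column(s): %s",
                    paste(missing, collapse = ", "))
  df <- dplyr::mutate(df, across(all_of(required), trimws))
  empty <- which(apply(is.na(df[required]) | df[required] == "", 1, any))
  if (length(empty) > 0)
    stop_validation("placement table has empty field(s) in row %d", empty[1])
  bad_chr <- which(!df$chromosome_of_origin %in% c("2", "4"))
  if (length(bad_chr) > 0)
    stop_validation("chromosome_of_origin must be 2 or 4 (row %d has '%s')",
                    bad_chr[1], df$chromosome_of_origin[bad_chr[1]])
  key <- paste(df$bac_id, df$gene, df$species, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), ][1, ]
    stop_validation("duplicate placement for (%s, %s, %s)",
                    d$bac_id, d$gene, d$species)
  }
  as_tibble(df[required])
}
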