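# Bundled gene inventory fixture.

#' Terpene synthase gene inventory of *Trichoderma gamsii* T6085
#'
#' The curated 16-gene TS inventory of the *T. gamsii* T6085 genome, with
#' each gene's functional group under the default taxonomy, subtype where
#' applicable, and an (empty by default) `include_override` column honoured
#' by [select_expression_candidates()].
#'
#' @param path Optional path to an alternative inventory TSV.
#' @return Data frame with columns `jgi_id`, `gene`, `putative_function`,
#'   `group`, `subtype`, `include_override`.
#' @examples
#' inv <- ts_gene_inventory()
#' nrow(inv)
#' select_expression_candidates(inv)$gene
#' @export
ts_gene_inventory <- function(path = NULL) {
  path <- path %||% system.file("extdata", "tgamsii_ts_inventory.tsv",
                                package = "tpsinv", mustWork = TRUE)
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = "")
  df
}
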