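#' The 30-gene integrin subunit panel
#'
#' Returns the default gene panel screened by the pipeline: the 18 alpha and
#' 12 beta integrin subunit genes (including the beta-binding proteins
#' ITGB1BP1, ITGB1BP2, ITGB3BP and the beta-like ITGBL1).
#'
#' @return Character vector of 30 HGNC symbols.
#' @export
#' @examples
#' itg_panel()
itg_panel <- function() {
  c("ITGA1", "ITGA10", "ITGA11", "ITGA2", "ITGA2B", "ITGA3", "ITGA4",
    "ITGA5", "ITGA6", "ITGA7", "ITGA8", "ITGA9", "ITGAD", "ITGAE",
    "ITGAL", "ITGAM", "ITGAV", "ITGAX",
    "ITGB1", "ITGB1BP1", "ITGB1BP2", "ITGB2", "ITGB3", "ITGB3BP",
    "ITGB4", "ITGB5", "ITGB6", "ITGB7", "ITGB8", "ITGBL1")
}

# internal: stop with a field-named validation error
.fail_field <- function(field, msg) {
  stop(sprintf("invalid config field '%s': %s", field, msg), call. = FALSE)
}
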