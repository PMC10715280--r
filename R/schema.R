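#' The 11-field address schema
#'
#' The gazetteer presents each property's textual address in 11 named fields.
#' The default schema follows the Royal Mail premise-element set; it can be
#' overridden wherever a `schema` argument is accepted.
#'
#' @return Character vector of the 11 field names, in rendering order
#'   (most specific organisational elements first, postcode last).
#' @examples
#' address_fields()
#' @export
address_fields <- function() {
  c("ORGANISATION_NAME", "DEPARTMENT_NAME", "SUB_BUILDING_NAME",
    "BUILDING_NAME", "BUILDING_NUMBER", "DEPENDENT_THOROUGHFARE",
    "THOROUGHFARE", "DOUBLE_DEPENDENT_LOCALITY", "DEPENDENT_LOCALITY",
    "POST_TOWN", "POSTCODE")
}

# Region-like fields used for subsumption knowledge (child -> parent).
region_fields <- function() {
  c("DOUBLE_DEPENDENT_LOCALITY", "DEPENDENT_LOCALITY", "POST_TOWN")
}

# Layer orders for the two blocking trees. The primary tree starts at
# POSTCODE (one-step descent on a parsed postcode); the secondary starts
# POST_TOWN then THOROUGHFARE (two-step descent when no postcode parses).
# Layers run broad -> specific so each descent shrinks the search space.
primary_layers <- function() {
  c("POSTCODE", "POST_TOWN", "DEPENDENT_LOCALITY",
    "DOUBLE_DEPENDENT_LOCALITY", "THOROUGHFARE", "DEPENDENT_THOROUGHFARE",
    "ORGANISATION_NAME", "DEPARTMENT_NAME", "BUILDING_NAME",
    "SUB_BUILDING_NAME", "BUILDING_NUMBER")
}

secondary_layers <- function() {
  c("POST_TOWN", "THOROUGHFARE", "POSTCODE", "DEPENDENT_LOCALITY",
    "DOUBLE_DEPENDENT_LOCALITY", "DEPENDENT_THOROUGHFARE",
    "ORGANISATION_NAME", "DEPARTMENT_NAME", "BUILDING_NAME",
    "SUB_BUILDING_NAME", "BUILDING_NUMBER")
}
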