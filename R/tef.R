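#' Toxicity equivalency factor from reference toxicity values
#'
#' Scales a compound's applied mass to the avian toxicity of a reference
#' compound. With toxicity expressed as a dose at which an effect occurs
#' (acute LD50 or chronic LOAEL, ng/kg body weight), a *lower* value means a
#' *more* toxic compound, so the equivalency factor for a compound is the
#' reference compound's value divided by the compound's own value. The
#' reference compound (imidacloprid in the packaged table) has TEF 1 exactly.
#'
#' @param reference_value Toxicity value of the reference compound (> 0).
#' @param compound_value Toxicity value of the compound being scaled (> 0).
#' @return Dimensionless TEF at full precision; rounding is presentational
#'   only (see [format_tef()]).
#' @examples
#' compute_tef(152, 2000)   # clothianidin, acute basis: 0.076
#' compute_tef(2820, 12660) # thiamethoxam, chronic basis: 0.2227...
#' @export
compute_tef <- function(reference_value, compound_value) {
  if (!is.numeric(reference_value) || !is.numeric(compound_value)) {
    stop("toxicity values must be numeric", call. = FALSE)
  }
  if (any(reference_value <= 0) || any(compound_value <= 0)) {
    stop("toxicity values must be strictly positive", call. = FALSE)
  }
  reference_value / compound_value
}

#' Display rounding for TEFs
#'
#' TEFs are carried at full precision through the pipeline; published tables
#' quote them at two decimal places. This helper reproduces that display.
#'
#' @param tef Numeric TEF value(s).
#' @param digits Decimal places (default 2).
#' @return Rounded numeric vector.
#' @export
format_tef <- function(tef, digits = 2) round(tef, digits)

#' Build a TEF table from per-compound toxicity reference values
#'
#' @param toxicity Data frame with columns `compound`, `acute_ref`
#'   (acute LD50, ng/kg bw) and `chronic_ref` (chronic LOAEL, ng/kg bw/day).
#' @param reference Compound label whose TEF is fixed at 1 (default `"IMI"`).
#' @return The input with `acute_tef` and `chronic_tef` columns appended.
#' @export
tef_table <- function(toxicity, reference = "IMI") {
  check_columns(toxicity, c("compound", "acute_ref", "chronic_ref"), "tef")
  if (!reference %in% toxicity$compound) {
    stop(sprintf("reference compound '%s' not present in toxicity table", reference),
         call. = FALSE)
  }
  ref <- toxicity[toxicity$compound == reference, ]
  toxicity$acute_tef <- compute_tef(ref$acute_ref, toxicity$acute_ref)
  toxicity$chronic_tef <- compute_tef(ref$chronic_ref, toxicity$chronic_ref)
  toxicity
}

#' Packaged toxicity reference values for the three main seed-treatment
#' neonicotinoids
#'
#' Acute values are oral LD50s for bobwhite quail; chronic values are lowest
#' observed adverse effect levels for a sensitive bird at the 5% tail of the
#' acute species sensitivity distribution. Units: ng/kg body weight (acute),
#' ng/kg body weight/day (chronic).
#'
#' @param reference Compound fixed at TEF 1 (default imidacloprid).
#' @return TEF table (see [tef_table()]).
#' @export
default_tef_table <- function(reference = "IMI") {
  path <- system.file("extdata", "tef_reference.csv", package = "neonicbirds",
                      mustWork = TRUE)
  tef_table(utils::read.csv(path, stringsAsFactors = FALSE), reference = reference)
}
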