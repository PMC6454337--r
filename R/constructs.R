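#' The ten geriatric-syndrome constructs
#'
#' Canonical table of the ten construct categories tagged by the package:
#' two-letter code and human-readable display name. The codes are used
#' throughout as factor levels, BIO tag suffixes, and standoff annotation
#' types.
#'
#' @return A data.frame with columns `code` and `display_name`, one row per
#'   construct, in canonical order.
#' @export
#' @examples
#' constructs()
constructs <- function() {
  data.frame(
    code = c("BC", "DE", "FL", "WL", "ML", "PU", "SS", "UC", "VI", "WD"),
    display_name = c(
      "absence of fecal control",
      "dementia",
      "falls",
      "weight loss",
      "malnutrition",
      "pressure ulcers",
      "lack of social support",
      "severe urinary control issues",
      "visual impairment",
      "walking difficulty"
    ),
    stringsAsFactors = FALSE
  )
}

#' Construct codes in canonical order
#' @return Character vector of the 10 two-letter codes.
#' @export
construct_codes <- function() constructs()$code

#' The BIO tag alphabet
#'
#' `O` plus `B-c`/`I-c` for each construct `c`: 21 tags. Order is fixed
#' (`O` first, then B/I pairs in canonical construct order) and is the
#' tie-break order used by the Viterbi decoder.
#'
#' @return Character vector of length 21.
#' @export
bio_tags <- function() {
  cc <- construct_codes()
  c("O", as.vector(rbind(paste0("B-", cc), paste0("I-", cc))))
}

is_valid_construct <- function(code) code %in% construct_codes()
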