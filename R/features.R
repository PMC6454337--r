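# Token feature extraction for the CRF: the Basic window features, the
# Enhanced token features (stem, Is-ICD9-Code, Is-Medical-Unit,
# Entity-Attributes) and the Global context features (section,
# ICD9-Annotation). Feature values are binary indicators whose name
# encodes the value ("cur:lower=fall", "icd9ann:PU=1"), the convention of
# CRFSuite-lineage feature templates. Extraction is pure and
# deterministic and never consults gold labels.

.bool01 <- function(x) ifelse(x, "1", "0")

# Features of one window position (prefix "prev:", "cur:" or "next:").
.position_features <- function(toks, i, prefix) {
  if (i < 1L) return(paste0(prefix, "BOS"))
  if (i > nrow(toks)) return(paste0(prefix, "EOS"))
  tok <- toks$text[i]
  c(paste0(prefix, "word=", tok),
    paste0(prefix, "lower=", tolower(tok)),
    paste0(prefix, "pos=", toks$pos[i]),
    paste0(prefix, "isnumeric=", .bool01(grepl("^[0-9]+(\\.[0-9]+)?$", tok))),
    paste0(prefix, "isupper=", .bool01(grepl("^[A-Z]+$", tok) && nchar(tok) > 0L)),
    paste0(prefix, "istitle=", .bool01(grepl("^[A-Z][a-z]+$", tok))))
}

#' Basic window features for one token position
#'
#' For each of the previous, current and next token: the raw token form,
#' its lowercase form, its POS tag, and three orthographic indicators
#' (numeric, uppercase, titlecase) — 6 feature types at 3 positions, 18
#' feature types per token. Sentence-edge positions get `prev:BOS` /
#' `next:EOS` boundary markers instead.
#'
#' @param toks sentence token table with columns `text`, `pos`.
#' @param i token position (1-based).
#' @return character vector of feature names.
#' @export
basic_features <- function(toks, i) {
  if (i < 1L || i > nrow(toks)) stop("token index out of range: ", i)
  c(.position_features(toks, i - 1L, "prev:"),
    .position_features(toks, i, "cur:"),
    .position_features(toks, i + 1L, "next:"))
}

#' Stem feature
#' @param token token text.
#' @return `"cur:stem=<porter stem>"`.
#' @export
stem_feature <- function(token) paste0("cur:stem=", porter_stem(token))

#' Is-ICD9-Code membership
#'
#' TRUE iff the token, normalized by stripping surrounding punctuation
#' (internal dot preserved), is a member of the ICD9 code universe.
#'
#' @param token token text.
#' @param icd9_universe character vector of dotted codes.
#' @return logical.
#' @export
is_icd9_code <- function(token, icd9_universe) {
  normalize_icd9_token(token) %in% icd9_universe
}

#' Is-Medical-Unit membership (case-insensitive)
#' @param token token text.
#' @param units lowercased unit lexicon ([load_units()]).
#' @return logical.
#' @export
is_medical_unit <- function(token, units) tolower(token) %in% units

#' Entity-attribute features
#' @param attrs one row of an [entity_attributes()] table.
#' @return three feature names: negation, uncertainty, subject.
#' @export
entity_attribute_features <- function(attrs) {
  c(paste0("cur:neg=", .bool01(attrs$negated)),
    paste0("cur:unc=", .bool01(attrs$uncertain)),
    paste0("cur:subj=", attrs$subject))
}

#' Section feature
#' @param section_name canonical section key for the token's section.
#' @return `"sec=<name>"`.
#' @export
section_feature <- function(section_name) paste0("sec=", section_name)

#' ICD9-Annotation features: 10 binary indicators
#'
#' When the normalized token is a code in the construct map, the indicator
#' of the mapped construct is 1 and the other nine are 0; for an unmapped
#' token all 10 are 0. At most one indicator is ever 1.
#'
#' @param token token text.
#' @param icd9_map an [load_icd9_map()] object.
#' @return character vector of 10 feature names `icd9ann:<code>=<0/1>`.
#' @export
icd9_annotation_features <- function(token, icd9_map) {
  lookup <- attr(icd9_map, "lookup")
  hit <- lookup[normalize_icd9_token(token)]
  codes <- construct_codes()
  vals <- rep("0", 10L)
  if (!is.na(hit)) vals[codes == hit] <- "1"
  paste0("icd9ann:", codes, "=", vals)
}

#' Extract feature sequences for a note
#'
#' Composes the enabled feature families over every sentence of an
#' annotated note. Output ordering is stable; identical input and config
#' give identical output.
#'
#' @param note an annotated `gstag_note`.
#' @param config a [feature_config()].
#' @param lexicons list with `icd9_map`, `icd9_universe`, `units`
#'   ([default_lexicons()]).
#' @return list with one element per sentence: `list(tokens = <token
#'   table>, features = <list of character vectors, one per token>)`.
#' @export
featurize <- function(note, config = feature_config(),
                      lexicons = default_lexicons()) {
  if (is.null(note$sentences)) stop("note must be annotated first")
  lapply(note$sentences, function(sent) {
    toks <- sent$tokens
    feats <- lapply(seq_len(nrow(toks)), function(i) {
      f <- basic_features(toks, i)
      if (isTRUE(config$stem)) f <- c(f, stem_feature(toks$text[i]))
      if (isTRUE(config$is_icd9_code)) {
        f <- c(f, paste0("cur:isicd9=",
                         .bool01(is_icd9_code(toks$text[i],
                                              lexicons$icd9_universe))))
      }
      if (isTRUE(config$is_medical_unit)) {
        f <- c(f, paste0("cur:isunit=",
                         .bool01(is_medical_unit(toks$text[i],
                                                 lexicons$units))))
      }
      if (isTRUE(config$entity_attributes)) {
        f <- c(f, entity_attribute_features(toks[i, ]))
      }
      if (isTRUE(config$section)) {
        f <- c(f, section_feature(toks$section_name[i]))
      }
      if (isTRUE(config$icd9_annotation)) {
        f <- c(f, icd9_annotation_features(toks$text[i], lexicons$icd9_map))
      }
      f
    })
    list(tokens = toks, features = feats)
  })
}
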