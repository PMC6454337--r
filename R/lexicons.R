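# Loaders for the shipped editable lexicon/config files: ICD9 construct
# map and code universe, medical measurement units, and feature
# configuration.

#' Load an ICD9 code → construct map
#'
#' The shipped default (`inst/extdata/icd9_construct_map.tsv`) assigns 295
#' dotted ICD9 codes to the 10 constructs, assembled from the standard
#' diagnostic code families for each syndrome (fall E-codes, 290.x/331.x
#' dementias, 707.x pressure ulcers, ...). Membership is editable config;
#' the per-construct counts of the default file are pinned by tests. A row
#' may give a code range `a-b` over the last dotted component, expanded at
#' load.
#'
#' @param path TSV with columns `code`, `construct` (default: shipped map).
#' @return object of class `icd9_map`: data.frame `code`/`construct` plus
#'   a named lookup vector in attribute `lookup`.
#' @export
load_icd9_map <- function(path = gstag_extdata("icd9_construct_map.tsv")) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("code", "construct") %in% names(raw)))
  rows <- list()
  for (i in seq_len(nrow(raw))) {
    code <- raw$code[i]
    if (grepl("-", code, fixed = TRUE)) {
      parts <- strsplit(code, "-", fixed = TRUE)[[1]]
      a <- strsplit(parts[1], ".", fixed = TRUE)[[1]]
      b <- strsplit(parts[2], ".", fixed = TRUE)[[1]]
      stopifnot(length(a) == 2L, a[1] == b[1] || length(b) == 1L)
      hi <- if (length(b) == 2L) b[2] else parts[2]
      width <- nchar(a[2])
      lo_i <- as.integer(a[2]); hi_i <- as.integer(hi)
      codes <- sprintf(paste0("%s.%0", width, "d"), a[1], lo_i:hi_i)
    } else {
      codes <- code
    }
    rows[[i]] <- data.frame(code = codes, construct = raw$construct[i],
                            stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  if (anyNA(df$code) || any(!nzchar(df$code))) stop("missing code in map")
  if (anyDuplicated(df$code)) {
    stop("duplicate ICD9 code(s) in map: ",
         paste(unique(df$code[duplicated(df$code)]), collapse = ", "))
  }
  if (!all(is_valid_construct(df$construct))) stop("unknown construct in map")
  lookup <- df$construct
  names(lookup) <- df$code
  structure(df, lookup = lookup, class = c("icd9_map", "data.frame"))
}

#' Per-construct code counts of an ICD9 map
#' @param map an `icd9_map`.
#' @return named integer vector over the 10 construct codes.
#' @export
icd9_map_counts <- function(map) {
  counts <- table(factor(map$construct, levels = construct_codes()))
  stats::setNames(as.integer(counts), construct_codes())
}

#' Load the ICD9 code universe
#'
#' The full list of codes used for the Is-ICD9-Code membership feature: the
#' construct-mapped codes plus common non-construct diagnostic codes.
#'
#' @param path one code per line (default: shipped file).
#' @return character vector of dotted codes.
#' @export
load_icd9_universe <- function(path = gstag_extdata("icd9_universe.txt")) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x[nzchar(x) & !startsWith(x, "#")])
  unique(x)
}

#' Load the medical measurement unit lexicon
#' @param path one unit per line (default: shipped file).
#' @return character vector (lowercased) with class attribute retained as
#'   plain character; lookup is exact match after lowercasing.
#' @export
load_units <- function(path = gstag_extdata("units.txt")) {
  x <- readLines(path, warn = FALSE)
  tolower(trimws(x[nzchar(x) & !startsWith(x, "#")]))
}

# Normalize a token for ICD9 lookup: strip surrounding punctuation,
# preserve the internal dot.
normalize_icd9_token <- function(token) {
  gsub("^[^A-Za-z0-9]+|[^A-Za-z0-9.]+$", "", token)
}

#' Feature configuration
#'
#' Flags enabling each feature family. `basic` is always on and cannot be
#' disabled. `icd9_annotation_post` is a decoding-time flag (label
#' post-processing), not a token feature.
#'
#' @param stem,is_icd9_code,is_medical_unit,entity_attributes,section,icd9_annotation,icd9_annotation_post
#'   logical flags.
#' @return a `feature_config` list.
#' @export
feature_config <- function(stem = FALSE, is_icd9_code = FALSE,
                           is_medical_unit = FALSE,
                           entity_attributes = FALSE, section = FALSE,
                           icd9_annotation = FALSE,
                           icd9_annotation_post = FALSE) {
  structure(list(basic = TRUE, stem = stem, is_icd9_code = is_icd9_code,
                 is_medical_unit = is_medical_unit,
                 entity_attributes = entity_attributes, section = section,
                 icd9_annotation = icd9_annotation,
                 icd9_annotation_post = icd9_annotation_post),
            class = "feature_config")
}

#' The full feature configuration of the best-performing model
#'
#' All Enhanced token features plus the ICD9-annotation Global features,
#' without the section feature: the combination selected on validation
#' data in the reference evaluation.
#' @return a `feature_config`.
#' @export
full_feature_config <- function() {
  feature_config(stem = TRUE, is_icd9_code = TRUE, is_medical_unit = TRUE,
                 entity_attributes = TRUE, section = FALSE,
                 icd9_annotation = TRUE, icd9_annotation_post = TRUE)
}

#' Read/write a feature configuration as YAML
#' @param path YAML file of logical flags.
#' @return a `feature_config`.
#' @export
read_feature_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(feature_config, y[setdiff(names(y), "basic")])
}

#' @rdname read_feature_config
#' @param config a `feature_config`.
#' @export
write_feature_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
}

#' Bundle the shipped default lexicons
#' @return list with `icd9_map`, `icd9_universe`, `units`.
#' @export
default_lexicons <- function() {
  list(icd9_map = load_icd9_map(),
       icd9_universe = load_icd9_universe(),
       units = load_units())
}
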