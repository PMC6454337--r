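# Porter stemmer (original 1980 algorithm), used for the stem token feature.
# No stemming package ships with the runtime this package targets, so the
# algorithm is implemented here and pinned by canonical reference vectors in
# the test suite.

# Consonant/vowel flags for a word given as a character vector of letters;
# 'y' is a consonant when word-initial or preceded by a vowel.
.porter_flags <- function(ch) {
  n <- length(ch)
  cons <- logical(n)
  for (i in seq_len(n)) {
    cons[i] <- if (ch[i] %in% c("a", "e", "i", "o", "u")) {
      FALSE
    } else if (ch[i] == "y") {
      if (i == 1L) TRUE else !cons[i - 1L]
    } else TRUE
  }
  cons
}

# Measure m of a stem: number of VC sequences in [C](VC)^m[V].
.porter_m2 <- function(stem) {
  if (!nzchar(stem)) return(0L)
  cons <- .porter_flags(strsplit(stem, "")[[1]])
  runs <- rle(cons)$values
  # number of V runs followed by a C run
  if (length(runs) < 2L) return(0L)
  sum(!runs[-length(runs)] & runs[-1])
}

.porter_has_vowel <- function(stem) {
  if (!nzchar(stem)) return(FALSE)
  any(!.porter_flags(strsplit(stem, "")[[1]]))
}

.porter_double_cons <- function(word) {
  n <- nchar(word)
  if (n < 2L) return(FALSE)
  a <- substr(word, n - 1L, n - 1L); b <- substr(word, n, n)
  if (a != b) return(FALSE)
  flags <- .porter_flags(strsplit(word, "")[[1]])
  flags[n]
}

# *o: stem ends cvc where the final c is not w, x or y.
.porter_cvc <- function(word) {
  n <- nchar(word)
  if (n < 3L) return(FALSE)
  flags <- .porter_flags(strsplit(word, "")[[1]])
  last <- substr(word, n, n)
  flags[n - 2L] && !flags[n - 1L] && flags[n] && !(last %in% c("w", "x", "y"))
}

.ends <- function(word, suf) {
  n <- nchar(word); k <- nchar(suf)
  n >= k && substr(word, n - k + 1L, n) == suf
}

.chop <- function(word, k) substr(word, 1L, nchar(word) - k)

.porter_step1 <- function(w) {
  # 1a
  if (.ends(w, "sses")) w <- .chop(w, 2L)
  else if (.ends(w, "ies")) w <- .chop(w, 2L)
  else if (.ends(w, "ss")) w <- w
  else if (.ends(w, "s")) w <- .chop(w, 1L)
  # 1b
  fix <- FALSE
  if (.ends(w, "eed")) {
    if (.porter_m2(.chop(w, 3L)) > 0L) w <- .chop(w, 1L)
  } else if (.ends(w, "ed") && .porter_has_vowel(.chop(w, 2L))) {
    w <- .chop(w, 2L); fix <- TRUE
  } else if (.ends(w, "ing") && .porter_has_vowel(.chop(w, 3L))) {
    w <- .chop(w, 3L); fix <- TRUE
  }
  if (fix) {
    if (.ends(w, "at") || .ends(w, "bl") || .ends(w, "iz")) {
      w <- paste0(w, "e")
    } else if (.porter_double_cons(w) &&
               !(substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z"))) {
      w <- .chop(w, 1L)
    } else if (.porter_m2(w) == 1L && .porter_cvc(w)) {
      w <- paste0(w, "e")
    }
  }
  # 1c
  if (.ends(w, "y") && .porter_has_vowel(.chop(w, 1L))) {
    w <- paste0(.chop(w, 1L), "i")
  }
  w
}

.step2_rules <- list(
  c("ational", "ate"), c("tional", "tion"), c("enci", "ence"),
  c("anci", "ance"), c("izer", "ize"), c("abli", "able"), c("alli", "al"),
  c("entli", "ent"), c("eli", "e"), c("ousli", "ous"), c("ization", "ize"),
  c("ation", "ate"), c("ator", "ate"), c("alism", "al"), c("iveness", "ive"),
  c("fulness", "ful"), c("ousness", "ous"), c("aliti", "al"),
  c("iviti", "ive"), c("biliti", "ble")
)

.step3_rules <- list(
  c("icate", "ic"), c("ative", ""), c("alize", "al"), c("iciti", "ic"),
  c("ical", "ic"), c("ful", ""), c("ness", "")
)

.apply_rules <- function(w, rules, min_m = 0L) {
  # longest matching suffix wins within a step
  lens <- vapply(rules, function(r) nchar(r[1]), integer(1))
  for (r in rules[order(-lens)]) {
    if (.ends(w, r[1])) {
      stem <- .chop(w, nchar(r[1]))
      if (.porter_m2(stem) > min_m) w <- paste0(stem, r[2])
      return(w)
    }
  }
  w
}

.step4_sufs <- c("ement", "ance", "ence", "able", "ible", "ment", "ant",
                 "ent", "ion", "ism", "ate", "iti", "ous", "ive", "ize",
                 "al", "er", "ic", "ou")

.porter_step4 <- function(w) {
  for (suf in .step4_sufs[order(-nchar(.step4_sufs))]) {
    if (.ends(w, suf)) {
      stem <- .chop(w, nchar(suf))
      if (.porter_m2(stem) > 1L) {
        if (suf == "ion" &&
            !(substr(stem, nchar(stem), nchar(stem)) %in% c("s", "t"))) {
          return(w)
        }
        return(stem)
      }
      return(w)
    }
  }
  w
}

.porter_step5 <- function(w) {
  if (.ends(w, "e")) {
    stem <- .chop(w, 1L)
    m <- .porter_m2(stem)
    if (m > 1L || (m == 1L && !.porter_cvc(stem))) w <- stem
  }
  if (.porter_double_cons(w) && .ends(w, "l") && .porter_m2(.chop(w, 1L)) > 1L) {
    w <- .chop(w, 1L)
  }
  w
}

.porter_one <- function(word) {
  w <- tolower(word)
  if (nchar(w) <= 2L || grepl("[^a-z]", w)) return(w)
  w <- .porter_step1(w)
  w <- .apply_rules(w, .step2_rules, 0L)
  w <- .apply_rules(w, .step3_rules, 0L)
  w <- .porter_step4(w)
  .porter_step5(w)
}

#' Porter stem of tokens
#'
#' Lowercases each token and applies the Porter suffix-stripping algorithm.
#' Tokens of length <= 2 or containing non-letters (numbers, ICD9 codes,
#' punctuation) are returned lowercased but otherwise unchanged.
#'
#' @param tokens character vector of tokens.
#' @return character vector of stems, same length.
#' @export
#' @examples
#' porter_stem(c("walking", "falls", "ambulates"))
porter_stem <- function(tokens) {
  vapply(tokens, .porter_one, character(1), USE.NAMES = FALSE)
}
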