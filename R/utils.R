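# Internal helpers: seeded RNG scoping and logging.

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched. All stochastic code paths in the package go
# through this so that a single integer seed makes them reproducible.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a child seed from a parent seed and a stream label, staying within
# 32-bit integer range.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629L)
}

gstag_log <- function(..., level = "INFO") {
  threshold <- toupper(getOption("gstag.log_level", "WARN"))
  levels <- c(DEBUG = 1L, INFO = 2L, WARN = 3L, ERROR = 4L)
  if (levels[[toupper(level)]] >= levels[[threshold]]) {
    message(sprintf("[gstag %s] %s", level, paste0(...)))
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Path to a shipped configuration/lexicon file.
gstag_extdata <- function(file) {
  path <- system.file("extdata", file, package = "gstag")
  if (!nzchar(path)) stop("shipped data file not found: ", file)
  path
}
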