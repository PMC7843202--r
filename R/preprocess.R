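#' Preprocessing configuration
#'
#' Canonicalization applied to every mention and lexicon synonym before any
#' matching or learning: lowercasing, removal of a small list of common
#' words known to be swept into mention spans by noun-phrase annotation
#' policies, and removal of a few character sequences (possessive markers,
#' hyphens, angle brackets).
#'
#' @param stopwords Character vector of whole words removed after token
#'   splitting. The defaults are the determiners/possessives typically
#'   included in clinical mention spans.
#' @param strip_strings Character sequences removed anywhere in the string,
#'   in the given order. Hyphens are handled per `hyphen_splits`.
#' @param hyphen_splits If `TRUE` (default) a removed hyphen (or en/em dash)
#'   is replaced by a space so its neighbours stay separate word tokens; if
#'   `FALSE` the neighbours are concatenated.
#' @return An object of class `preprocess_config`.
#' @seealso [preprocess_terms()]
#' @export
preprocess_config <- function(stopwords = c("a", "an", "the", "his", "her",
                                            "patient", "patient's", "any",
                                            "your", "this", "that", "these"),
                              strip_strings = c("'s", "'d", "-", "'", ">", "<"),
                              hyphen_splits = TRUE) {
  stopifnot(is.character(stopwords), is.character(strip_strings),
            is.logical(hyphen_splits), length(hyphen_splits) == 1L)
  structure(list(stopwords = tolower(stopwords),
                 strip_strings = strip_strings,
                 hyphen_splits = isTRUE(hyphen_splits)),
            class = "preprocess_config")
}

#' Read a preprocessing configuration from a YAML or JSON file
#'
#' The file may override `stopwords`, `strip_strings` and `hyphen_splits`;
#' omitted fields keep their defaults.
#'
#' @param path Path to a JSON (or single-document YAML mapping with the same
#'   structure, parsed as JSON-compatible) configuration file.
#' @return A `preprocess_config`.
#' @export
read_preprocess_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- preprocess_config()
  for (f in intersect(names(cfg), c("stopwords", "strip_strings", "hyphen_splits")))
    base[[f]] <- if (f == "hyphen_splits") isTRUE(cfg[[f]]) else as.character(cfg[[f]])
  class(base) <- "preprocess_config"
  base
}

#' Canonicalize clinical term strings
#'
#' Lowercases, normalizes curly apostrophes and en/em dashes to their ASCII
#' forms, removes the configured character sequences (hyphen removal joins
#' neighbours with a space by default), drops whole-word stopwords, and
#' collapses whitespace. The result may be an empty string. The operation is
#' idempotent.
#'
#' @param x Character vector of raw terms.
#' @param cfg A [preprocess_config()].
#' @return Character vector of preprocessed terms, same length as `x`.
#' @examples
#' preprocess_terms("The patient's anemia")   # "anemia"
#' @export
preprocess_terms <- function(x, cfg = preprocess_config()) {
  stopifnot(inherits(cfg, "preprocess_config"))
  x <- tolower(as.character(x))
  x <- gsub("[\u2018\u2019\u02bc]", "'", x)
  x <- gsub("[\u2013\u2014\u2212]", "-", x)
  for (s in cfg$strip_strings) {
    repl <- if (s == "-" && cfg$hyphen_splits) " " else ""
    x <- gsub(s, repl, x, fixed = TRUE)
  }
  toks <- strsplit(x, "[[:space:]]+")
  vapply(toks, function(tt) {
    tt <- tt[nzchar(tt) & !(tt %in% cfg$stopwords)]
    paste(tt, collapse = " ")
  }, character(1L))
}
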