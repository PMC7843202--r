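#' Build a concept lexicon from a table of synonym rows
#'
#' A lexicon is the synonym inventory normalization works against: every row
#' states that `term` is a synonym of the concept `cui` (optionally carrying
#' a semantic type `sty` and a `source` vocabulary). Rows are collapsed to
#' the unique (cui, term, sty, source) set; synonyms whose preprocessed form
#' is empty are dropped. Concepts may carry several semantic types (one per
#' row); a missing type is recorded under the reserved label `"unknown"`.
#'
#' @param rows Data frame with columns `cui` and `term`; optional `sty` and
#'   `source`.
#' @param cfg Preprocessing configuration applied to every term.
#' @return An object of class `clinnorm_lexicon` with components
#'   \describe{
#'     \item{concepts}{named list, one entry per CUI, each with `cui`,
#'       `semantic_types`, `synonyms` (raw) and `synonyms_pp` (unique
#'       preprocessed forms);}
#'     \item{term_index}{hashed environment mapping each preprocessed term
#'       to the sorted CUIs listing it;}
#'     \item{type_index}{named list mapping each semantic-type label to its
#'       CUIs;}
#'     \item{rows}{the collapsed row table (for round-trip writing).}
#'   }
#' @export
lexicon <- function(rows, cfg = preprocess_config()) {
  stopifnot(is.data.frame(rows))
  if (!all(c("cui", "term") %in% names(rows)))
    stop("lexicon rows need 'cui' and 'term' columns")
  rows$cui <- as.character(rows$cui)
  rows$term <- as.character(rows$term)
  rows$sty <- if ("sty" %in% names(rows)) as.character(rows$sty) else NA_character_
  rows$sty[is.na(rows$sty) | !nzchar(rows$sty)] <- sty_unknown
  rows$source <- if ("source" %in% names(rows)) as.character(rows$source) else NA_character_
  rows$source[is.na(rows$source)] <- ""
  if (any(is.na(rows$cui) | !nzchar(rows$cui)))
    stop("lexicon rows with missing cui")
  if (any(is.na(rows$term)))
    stop("lexicon rows with missing term")
  rows <- rows[c("cui", "term", "sty", "source")]
  rows <- unique(rows)
  rows <- rows[order(rows$cui, rows$term, rows$sty, rows$source), , drop = FALSE]
  rownames(rows) <- NULL

  pp <- preprocess_terms(rows$term, cfg)
  keep <- nzchar(pp)
  lex_rows <- rows[keep, , drop = FALSE]
  pp <- pp[keep]
  if (nrow(lex_rows) == 0L) stop("lexicon is empty after preprocessing")

  concepts <- lapply(split(seq_len(nrow(lex_rows)), lex_rows$cui), function(i) {
    list(cui = lex_rows$cui[i[1L]],
         semantic_types = sort(unique(lex_rows$sty[i])),
         synonyms = unique(lex_rows$term[i]),
         synonyms_pp = unique(pp[i]))
  })

  term_index <- new.env(parent = emptyenv(), hash = TRUE,
                        size = max(29L, length(pp)))
  for (i in seq_along(pp)) {
    t <- pp[i]
    term_index[[t]] <- c(term_index[[t]], lex_rows$cui[i])
  }
  for (t in ls(term_index, all.names = TRUE))
    term_index[[t]] <- sort(unique(term_index[[t]]))

  ty <- lapply(concepts, `[[`, "semantic_types")
  type_index <- split(rep(names(concepts), lengths(ty)), unlist(ty, use.names = FALSE))
  type_index <- lapply(type_index, function(z) sort(unique(z)))

  structure(list(concepts = concepts, term_index = term_index,
                 type_index = type_index, rows = lex_rows, cfg = cfg),
            class = "clinnorm_lexicon")
}

#' Look up the concepts listing a preprocessed term
#'
#' @param lex A `clinnorm_lexicon`.
#' @param term_pp One preprocessed term string.
#' @return Sorted character vector of CUIs (possibly empty).
#' @export
lookup_term <- function(lex, term_pp) {
  stopifnot(inherits(lex, "clinnorm_lexicon"), length(term_pp) == 1L)
  v <- lex$term_index[[term_pp]]
  if (is.null(v)) character(0) else v
}

#' @export
print.clinnorm_lexicon <- function(x, ...) {
  cat(sprintf("Concept lexicon: %d concepts, %d synonym rows, %d distinct terms, %d semantic types\n",
              length(x$concepts), nrow(x$rows),
              length(ls(x$term_index, all.names = TRUE)),
              length(x$type_index)))
  invisible(x)
}

#' Column specification for pipe-delimited MRCONSO-style lexicon files
#'
#' Maps columns of a header-less, pipe-delimited synonym table by position
#' (defaults follow the MRCONSO layout: CUI first, language second, source
#' twelfth, term fifteenth). When a language column is given, only rows with
#' `lang_keep` are retained.
#'
#' @param cui,term,sty,source,lang 1-based column positions (`NA` = absent).
#' @param lang_keep Language code to keep when `lang` is given.
#' @return A dialect specification list for [read_lexicon()].
#' @export
mrconso_dialect <- function(cui = 1L, term = 15L, sty = NA_integer_,
                            source = 12L, lang = 2L, lang_keep = "ENG") {
  list(sep = "|", header = FALSE, cui = cui, term = term, sty = sty,
       source = source, lang = lang, lang_keep = lang_keep)
}

#' Read a concept lexicon from a delimited file
#'
#' The default dialect is tab-separated with a header naming at least `cui`
#' and `term` (optionally `sty`, `source`). A pipe-delimited positional
#' layout (an MRCONSO-style extract) is read via [mrconso_dialect()].
#'
#' @param path File path (UTF-8).
#' @param dialect `"tsv"` or a specification from [mrconso_dialect()].
#' @param cfg Preprocessing configuration.
#' @return A `clinnorm_lexicon`.
#' @export
read_lexicon <- function(path, dialect = "tsv", cfg = preprocess_config()) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty lexicon file: ", path)
  if (identical(dialect, "tsv")) {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    hdr <- fields[[1L]]
    need <- c("cui", "term")
    if (!all(need %in% hdr))
      stop("lexicon header must name 'cui' and 'term' columns")
    if (length(fields) == 1L) stop("lexicon file has no data rows: ", path)
    body <- fields[-1L]
    bad <- which(lengths(body) < max(match(need, hdr)))
    if (length(bad))
      stop(sprintf("malformed lexicon row at line %d of %s", bad[1L] + 1L, path))
    get_col <- function(nm) {
      j <- match(nm, hdr)
      if (is.na(j)) return(NULL)
      vapply(body, function(f) if (length(f) >= j) f[j] else NA_character_,
             character(1L))
    }
    rows <- data.frame(cui = get_col("cui"), term = get_col("term"),
                       stringsAsFactors = FALSE)
    if (!is.null(get_col("sty"))) rows$sty <- get_col("sty")
    if (!is.null(get_col("source"))) rows$source <- get_col("source")
  } else {
    d <- dialect
    fields <- strsplit(lines, d$sep, fixed = TRUE)
    if (isTRUE(d$header)) fields <- fields[-1L]
    needed <- max(c(d$cui, d$term, d$sty, d$source, d$lang), na.rm = TRUE)
    bad <- which(lengths(fields) < max(d$cui, d$term))
    if (length(bad))
      stop(sprintf("malformed lexicon row at line %d of %s",
                   bad[1L] + as.integer(isTRUE(d$header)), path))
    pick <- function(j) if (is.na(j)) NULL else
      vapply(fields, function(f) if (length(f) >= j) f[j] else "", character(1L))
    rows <- data.frame(cui = pick(d$cui), term = pick(d$term),
                       stringsAsFactors = FALSE)
    if (!is.null(pick(d$sty))) rows$sty <- pick(d$sty)
    if (!is.null(pick(d$source))) rows$source <- pick(d$source)
    if (!is.na(d$lang) && !is.null(d$lang_keep))
      rows <- rows[pick(d$lang) == d$lang_keep, , drop = FALSE]
  }
  if (any(is.na(rows$cui) | !nzchar(rows$cui))) {
    bad <- which(is.na(rows$cui) | !nzchar(rows$cui))[1L]
    stop(sprintf("missing cui at data row %d of %s", bad, path))
  }
  lexicon(rows, cfg = cfg)
}

#' Write a lexicon back to the tab-separated format
#'
#' Writes the collapsed (cui, term, sty, source) row set with a header;
#' `read_lexicon()` of the result reproduces the same rows.
#'
#' @param lex A `clinnorm_lexicon`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lex, path) {
  stopifnot(inherits(lex, "clinnorm_lexicon"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("cui\tterm\tsty\tsource",
               sprintf("%s\t%s\t%s\t%s", lex$rows$cui, lex$rows$term,
                       lex$rows$sty, lex$rows$source)), con)
  invisible(path)
}

#' Read annotated mentions
#'
#' Mentions are one per row in a tab-separated file whose header names a
#' `text` column and, for annotated data, a `gold` column holding either a
#' CUI or the reserved value `"CUI-less"`. A missing gold column (test-time
#' input) is recorded as `NA`, which is distinct from `"CUI-less"`.
#' Multi-span mentions are expected to be already concatenated in reading
#' order, joined by single spaces.
#'
#' @param path File path (UTF-8).
#' @return Data frame with columns `text` and `gold`, in file order.
#' @export
read_mentions <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty mentions file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  hdr <- fields[[1L]]
  if (!("text" %in% hdr)) stop("mentions header must name a 'text' column")
  jt <- match("text", hdr); jg <- match("gold", hdr)
  body <- fields[-1L]
  text <- vapply(body, function(f) if (length(f) >= jt) f[jt] else "", character(1L))
  bad <- which(!nzchar(trimws(text)))
  if (length(bad))
    stop(sprintf("empty mention text at line %d of %s", bad[1L] + 1L, path))
  gold <- if (is.na(jg)) rep(NA_character_, length(body)) else
    vapply(body, function(f) if (length(f) >= jg && nzchar(f[jg])) f[jg]
           else NA_character_, character(1L))
  data.frame(text = text, gold = gold, stringsAsFactors = FALSE)
}

#' Write mentions to the tab-separated format
#' @param mentions Data frame with `text` and optionally `gold`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mentions <- function(mentions, path) {
  gold <- if ("gold" %in% names(mentions)) mentions$gold else NA_character_
  gold[is.na(gold)] <- ""
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("text\tgold", sprintf("%s\t%s", mentions$text, gold)), con)
  invisible(path)
}

#' Add annotated training mentions to a lexicon as extra synonyms
#'
#' Each mention text becomes an additional synonym of its gold concept, so
#' that corpus-specific variations take part in pattern learning. Mentions
#' annotated `"CUI-less"` or lacking a gold are excluded. Gold CUIs absent
#' from the lexicon are added as new single-synonym concepts with the
#' reserved semantic type.
#'
#' @param lex A `clinnorm_lexicon`.
#' @param mentions Data frame from [read_mentions()].
#' @return A new `clinnorm_lexicon`; synonym rows added from mentions carry
#'   source `"training"`.
#' @export
augment_with_training <- function(lex, mentions) {
  stopifnot(inherits(lex, "clinnorm_lexicon"), is.data.frame(mentions))
  m <- mentions[!is.na(mentions$gold) & mentions$gold != cui_less, , drop = FALSE]
  if (nrow(m) == 0L) return(lex)
  sty <- vapply(m$gold, function(cui) {
    e <- lex$concepts[[cui]]
    if (is.null(e)) sty_unknown else e$semantic_types[1L]
  }, character(1L))
  extra <- data.frame(cui = m$gold, term = m$text, sty = sty,
                      source = "training", stringsAsFactors = FALSE)
  lexicon(rbind(lex$rows, extra), cfg = lex$cfg)
}
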