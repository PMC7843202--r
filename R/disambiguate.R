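# Semantic-type disambiguation: when a stage returns several candidate
# concepts, learned rules of the form "whenever the candidates' semantic
# types are exactly this combination, the winner is of this type" select
# one; otherwise the first candidate in canonical (lexicographic CUI) order
# is returned.

concept_types <- function(lex, cui) {
  e <- lex$concepts[[cui]]
  if (is.null(e)) sty_unknown else e$semantic_types
}

combination_key <- function(types) paste(sort(unique(types)), collapse = "+")

#' Learn semantic-type disambiguation rules from training mentions
#'
#' For every training mention the normalizer resolved to two or more
#' candidate CUIs (with the gold among them), the combination of semantic
#' types across the candidates is recorded. A rule is emitted for a
#' combination when, in every such mention, the gold concept bears one
#' particular type that no competing candidate bears — the combination then
#' always identifies the correct concept by that type. Mentions whose gold
#' is `"CUI-less"`, unannotated, or not among the candidates are skipped.
#'
#' @param mentions Annotated mentions (data frame with `text`, `gold`).
#' @param candidates List (parallel to `mentions` rows) of candidate CUI
#'   sets produced by the normalization stages.
#' @param lex A `clinnorm_lexicon`.
#' @param min_support Minimum number of supporting mentions for a rule
#'   (default 1).
#' @return An object of class `clinnorm_rules`: a data frame with columns
#'   `combination` (sorted types joined by `+`), `winner` and `support`.
#' @export
learn_disambiguation_rules <- function(mentions, candidates, lex,
                                       min_support = 1L) {
  stopifnot(nrow(mentions) == length(candidates))
  combs <- character(0); winners <- list()
  for (i in seq_len(nrow(mentions))) {
    gold <- mentions$gold[i]
    cand <- sort(unique(candidates[[i]]))
    if (is.na(gold) || gold == cui_less) next
    if (length(cand) < 2L || !(gold %in% cand)) next
    tysets <- lapply(cand, concept_types, lex = lex)
    comb <- combination_key(unlist(tysets))
    gold_ty <- tysets[[match(gold, cand)]]
    other_ty <- unique(unlist(tysets[cand != gold]))
    # types that single out the gold among these candidates
    w <- setdiff(gold_ty, other_ty)
    combs <- c(combs, comb)
    winners[[length(winners) + 1L]] <- w
  }
  if (length(combs) == 0L)
    return(structure(data.frame(combination = character(0),
                                winner = character(0),
                                support = integer(0),
                                stringsAsFactors = FALSE),
                     class = c("clinnorm_rules", "data.frame")))
  rules <- lapply(split(seq_along(combs), combs), function(idx) {
    w <- Reduce(intersect, winners[idx])
    if (length(w) == 0L || length(idx) < min_support) return(NULL)
    data.frame(combination = combs[idx[1L]], winner = sort(w)[1L],
               support = length(idx), stringsAsFactors = FALSE)
  })
  rules <- do.call(rbind, rules[!vapply(rules, is.null, logical(1L))])
  if (is.null(rules))
    rules <- data.frame(combination = character(0), winner = character(0),
                        support = integer(0), stringsAsFactors = FALSE)
  rules <- rules[order(rules$combination), , drop = FALSE]
  rownames(rules) <- NULL
  structure(rules, class = c("clinnorm_rules", "data.frame"))
}

#' Select one concept from a candidate set
#'
#' A singleton is returned as is. Otherwise, if the candidates' combined
#' semantic-type set matches a learned rule, the candidate bearing the
#' rule's winning type is returned (ties broken by lexicographic CUI);
#' failing that, the first candidate in canonical (lexicographic CUI) order
#' is returned, which is effectively an arbitrary but reproducible choice.
#'
#' @param candidates Non-empty character vector of CUIs.
#' @param rules A `clinnorm_rules` (possibly empty) or `NULL`.
#' @param lex A `clinnorm_lexicon`.
#' @return A single CUI.
#' @export
disambiguate <- function(candidates, rules, lex) {
  cand <- sort(unique(as.character(candidates)))
  if (length(cand) == 0L) stop("cannot disambiguate an empty candidate set")
  if (length(cand) == 1L) return(cand)
  if (!is.null(rules) && nrow(rules) > 0L) {
    tysets <- lapply(cand, concept_types, lex = lex)
    comb <- combination_key(unlist(tysets))
    hit <- match(comb, rules$combination)
    if (!is.na(hit)) {
      w <- rules$winner[hit]
      bearing <- cand[vapply(tysets, function(tt) w %in% tt, logical(1L))]
      if (length(bearing) > 0L) return(bearing[1L])
    }
  }
  cand[1L]
}

#' @export
print.clinnorm_rules <- function(x, ...) {
  cat(sprintf("Semantic-type disambiguation rules: %d\n", nrow(x)))
  if (nrow(x)) print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Write disambiguation rules to a tab-separated file
#' @param rules A `clinnorm_rules`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rules <- function(rules, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("combination\twinner\tsupport",
               sprintf("%s\t%s\t%d", rules$combination, rules$winner,
                       rules$support)), con)
  invisible(path)
}

#' Read disambiguation rules written by [write_rules()]
#' @param path File path.
#' @return A `clinnorm_rules`.
#' @export
read_rules <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L || lines[1L] != "combination\twinner\tsupport")
    stop("not a rules file: ", path)
  if (length(lines) == 1L)
    return(structure(data.frame(combination = character(0),
                                winner = character(0), support = integer(0),
                                stringsAsFactors = FALSE),
                     class = c("clinnorm_rules", "data.frame")))
  f <- do.call(rbind, strsplit(lines[-1L], "\t", fixed = TRUE))
  structure(data.frame(combination = f[, 1L], winner = f[, 2L],
                       support = as.integer(f[, 3L]),
                       stringsAsFactors = FALSE),
            class = c("clinnorm_rules", "data.frame"))
}
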