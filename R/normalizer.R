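# The fitted normalizer: exact matching -> learned edit patterns ->
# subconcept matching -> CUI-less, with semantic-type disambiguation.

#' Exact match against training mentions and the lexicon
#'
#' Returns the union of the CUIs annotated for this exact preprocessed
#' string in the training data and the CUIs listing it as a synonym in the
#' lexicon. Both lookups are hashed, so the match is constant-time.
#'
#' @param term_pp A preprocessed term.
#' @param lex A `clinnorm_lexicon`.
#' @param train_index Hashed environment mapping preprocessed training
#'   mention texts to their gold CUIs (or `NULL`).
#' @return Sorted character vector of CUIs (possibly empty).
#' @export
exact_match <- function(term_pp, lex, train_index = NULL) {
  hits <- lookup_term(lex, term_pp)
  if (!is.null(train_index)) {
    tr <- train_index[[term_pp]]
    if (!is.null(tr)) hits <- c(hits, tr)
  }
  sort(unique(hits))
}

#' Normalize a term with learned edit patterns
#'
#' Applies every pattern in the set (patterns of all semantic types are
#' applied, since the type of an input term is unknown) and collects the
#' concepts whose synonyms the rewrites exactly match.
#'
#' @param term_pp A preprocessed term.
#' @param patterns A `clinnorm_patterns`.
#' @param lex A `clinnorm_lexicon`.
#' @return List with `cuis` (sorted union over all firing patterns) and
#'   `fired` (data frame of the patterns that contributed, with their
#'   rewrites, in descending score order).
#' @export
pattern_match <- function(term_pp, patterns, lex) {
  stopifnot(inherits(patterns, "clinnorm_patterns"))
  pats <- patterns$patterns
  if (length(pats) > 1L) {
    sc <- vapply(pats, function(P) if (is.na(P$score)) -1 else P$score, numeric(1L))
    pats <- pats[order(-sc)]
  }
  cuis <- character(0)
  fired <- list()
  for (P in pats) {
    rew <- apply_pattern(P, term_pp)
    if (length(rew) == 0L) next
    hits <- unlist(lapply(rew, lookup_term, lex = lex), use.names = FALSE)
    if (length(hits) == 0L) next
    ok <- rew[vapply(rew, function(r) length(lookup_term(lex, r)) > 0L, logical(1L))]
    cuis <- c(cuis, hits)
    fired[[length(fired) + 1L]] <-
      data.frame(pattern = render_pattern(P), unit = P$unit,
                 provenance = P$provenance, score = P$score,
                 rewrite = paste(ok, collapse = "; "),
                 stringsAsFactors = FALSE)
  }
  list(cuis = sort(unique(cuis)),
       fired = if (length(fired)) do.call(rbind, fired) else
         data.frame(pattern = character(0), unit = character(0),
                    provenance = character(0), score = numeric(0),
                    rewrite = character(0), stringsAsFactors = FALSE))
}

build_train_index <- function(mentions, cfg) {
  idx <- new.env(parent = emptyenv(), hash = TRUE)
  if (is.null(mentions) || nrow(mentions) == 0L) return(idx)
  keep <- !is.na(mentions$gold) & mentions$gold != cui_less
  texts <- preprocess_terms(mentions$text[keep], cfg)
  golds <- mentions$gold[keep]
  for (i in seq_along(texts)) {
    if (!nzchar(texts[i])) next
    idx[[texts[i]]] <- sort(unique(c(idx[[texts[i]]], golds[i])))
  }
  idx
}

#' Fit a clinical term normalizer
#'
#' Learns every resource the normalization pipeline needs from a concept
#' lexicon and (optionally) annotated training mentions: character- and
#' word-based edit patterns per semantic type from the lexicon's synonym
#' sets, additional patterns from the training mentions, an exact-match
#' index over the training annotations, a subconcept index, and
#' semantic-type disambiguation rules (learned by re-running the stages on
#' the training mentions and recording which semantic type wins among
#' ambiguous candidates).
#'
#' @param lexicon A `clinnorm_lexicon` (see [read_lexicon()]).
#' @param train Optional annotated mentions (see [read_mentions()]).
#' @param config A [learn_config()].
#' @param patterns Optional precomputed `clinnorm_patterns`; when supplied,
#'   pattern learning is skipped.
#' @param rules Optional precomputed `clinnorm_rules`; when supplied, rule
#'   learning is skipped.
#' @param use_subconcept Build the subconcept stage (default `TRUE`).
#' @param min_support Minimum support for a disambiguation rule.
#' @return An object of class `term_normalizer` with [predict][
#'   predict.term_normalizer], [print], [summary] and [evaluate()] methods.
#' @examples
#' syn <- synth_generate(synth_config(seed = 7))
#' fit <- term_normalizer(syn$lexicon, train = syn$train)
#' predict(fit, c("some term"))
#' @export
term_normalizer <- function(lexicon, train = NULL, config = learn_config(),
                            patterns = NULL, rules = NULL,
                            use_subconcept = TRUE, min_support = 1L) {
  stopifnot(inherits(lexicon, "clinnorm_lexicon"))
  cl <- match.call()
  train_index <- build_train_index(train, lexicon$cfg)
  if (is.null(patterns)) {
    patterns <- learn_by_semantic_type(lexicon, config)
    if (!is.null(train) && nrow(train) > 0L)
      patterns <- combine_patterns(patterns,
                                   learn_from_training(lexicon, train, config))
  }
  sub_index <- if (use_subconcept) subconcept_index(lexicon) else NULL
  obj <- structure(list(lexicon = lexicon, train_index = train_index,
                        patterns = patterns, rules = rules,
                        sub_index = sub_index, config = config,
                        min_support = as.integer(min_support), call = cl),
                   class = "term_normalizer")
  if (is.null(rules) && !is.null(train) && nrow(train) > 0L) {
    res <- predict(obj, train$text, disambiguate = FALSE)
    obj$rules <- learn_disambiguation_rules(train, res$candidates,
                                            lexicon, min_support)
  }
  obj
}

normalize_one <- function(object, term_raw, ablate = character(0),
                          use_rules = TRUE) {
  term <- preprocess_terms(term_raw, object$lexicon$cfg)
  cand <- character(0); stage <- "none"
  fired <- NULL
  tr_idx <- if ("training" %in% ablate) NULL else object$train_index
  if (!("exact" %in% ablate)) {
    cand <- exact_match(term, object$lexicon, tr_idx)
    if (length(cand)) stage <- "exact"
  }
  if (length(cand) == 0L && !("patterns" %in% ablate)) {
    pats <- object$patterns
    if ("training" %in% ablate) {
      keep <- vapply(pats$patterns, function(P)
        is.na(P$provenance) || P$provenance != "training", logical(1L))
      pats <- new_pattern_set(pats$patterns[keep], pats$config)
    }
    pm <- pattern_match(term, pats, object$lexicon)
    cand <- pm$cuis; fired <- pm$fired
    if (length(cand)) stage <- "pattern"
  }
  if (length(cand) == 0L && !("subconcept" %in% ablate) &&
      !is.null(object$sub_index)) {
    cand <- subconcept_match(term, object$lexicon, object$sub_index)
    if (length(cand)) stage <- "subconcept"
  }
  out <- if (length(cand) == 0L) cui_less
  else disambiguate(cand, if (use_rules) object$rules else NULL,
                    object$lexicon)
  list(term = term_raw, term_pp = term, output = out, stage = stage,
       candidates = sort(unique(cand)), fired = fired)
}

#' Normalize terms with a fitted normalizer
#'
#' Runs each term through the stage cascade: exact match, then learned edit
#' patterns, then subconcept matching; the first stage producing candidates
#' determines the result, and disambiguation selects a single CUI. Terms no
#' stage can resolve are output as `"CUI-less"`.
#'
#' @param object A fitted [term_normalizer()].
#' @param newdata Character vector of raw terms (multi-span mentions joined
#'   by spaces in reading order).
#' @param disambiguate Apply learned disambiguation rules (default `TRUE`);
#'   when `FALSE` ambiguous candidate sets fall back to canonical order.
#' @param ablate Character vector of stages/resources to disable:
#'   any of `"exact"`, `"patterns"`, `"subconcept"`, `"training"`,
#'   `"disambig"`.
#' @param ... Unused.
#' @return Data frame with one row per term: `term`, `output` (CUI or
#'   `"CUI-less"`), `stage` (`"exact"`, `"pattern"`, `"subconcept"` or
#'   `"none"`), `n_candidates`, and list-columns `candidates` and
#'   `matched_patterns`.
#' @export
predict.term_normalizer <- function(object, newdata, disambiguate = TRUE,
                                    ablate = character(0), ...) {
  stopifnot(is.character(newdata))
  if (length(ablate))
    ablate <- match.arg(ablate,
                        c("exact", "patterns", "subconcept", "training", "disambig"),
                        several.ok = TRUE)
  use_rules <- disambiguate && !("disambig" %in% ablate)
  res <- lapply(newdata, function(tm)
    normalize_one(object, tm, ablate = ablate, use_rules = use_rules))
  out <- data.frame(term = newdata,
                    output = vapply(res, `[[`, character(1L), "output"),
                    stage = vapply(res, `[[`, character(1L), "stage"),
                    n_candidates = vapply(res, function(r)
                      length(r$candidates), integer(1L)),
                    stringsAsFactors = FALSE)
  out$candidates <- lapply(res, `[[`, "candidates")
  out$matched_patterns <- lapply(res, `[[`, "fired")
  out
}

#' @rdname predict.term_normalizer
#' @param terms Character vector of raw terms.
#' @export
normalize_terms <- function(object, terms, ...) {
  predict(object, terms, ...)
}

#' @export
print.term_normalizer <- function(x, ...) {
  cat("Clinical term normalizer\n")
  cat(sprintf("  lexicon: %d concepts, %d synonym rows\n",
              length(x$lexicon$concepts), nrow(x$lexicon$rows)))
  cat(sprintf("  training index: %d exact-match texts\n",
              length(ls(x$train_index, all.names = TRUE))))
  np <- length(x$patterns$patterns)
  un <- vapply(x$patterns$patterns, `[[`, character(1L), "unit")
  cat(sprintf("  edit patterns: %d (%d character-based, %d word-based)\n",
              np, sum(un == "char"), sum(un == "word")))
  cat(sprintf("  disambiguation rules: %d\n",
              if (is.null(x$rules)) 0L else nrow(x$rules)))
  cat(sprintf("  subconcept stage: %s\n",
              if (is.null(x$sub_index)) "disabled" else "enabled"))
  invisible(x)
}

#' @export
summary.term_normalizer <- function(object, ...) {
  df <- as.data.frame(object$patterns)
  structure(list(normalizer = object,
                 pattern_summary = if (nrow(df))
                   aggregate(cbind(count = p) ~ unit + provenance, df, length)
                 else df),
            class = "summary.term_normalizer")
}

#' @export
print.summary.term_normalizer <- function(x, ...) {
  print(x$normalizer)
  if (nrow(x$pattern_summary)) {
    cat("\nRetained patterns by unit level and provenance:\n")
    print.data.frame(x$pattern_summary, row.names = FALSE)
  }
  invisible(x)
}

#' Evaluate normalization accuracy
#'
#' @param object An object to evaluate.
#' @param ... Method arguments.
#' @return See methods.
#' @export
evaluate <- function(object, ...) UseMethod("evaluate")

#' Accuracy of a fitted normalizer on gold-annotated mentions
#'
#' Accuracy is the percentage of mentions normalized correctly — either to
#' the correct CUI or correctly to `"CUI-less"`. In oracle mode a mention
#' counts as correct if any of the candidate CUIs equals the gold (or the
#' gold is `"CUI-less"` and no stage produced candidates), which upper
#' bounds what perfect disambiguation could achieve.
#'
#' @param object A fitted [term_normalizer()].
#' @param mentions Data frame with `text` and gold annotations in `gold`.
#' @param oracle Score in oracle mode (default `FALSE`).
#' @param ablate Stages/resources to disable; see
#'   [predict.term_normalizer()].
#' @param ... Unused.
#' @return An object of class `clinnorm_eval`: list with `accuracy` (in
#'   percent), `n`, `n_correct`, a per-stage `table`, and the per-mention
#'   `results`.
#' @export
evaluate.term_normalizer <- function(object, mentions, oracle = FALSE,
                                     ablate = character(0), ...) {
  stopifnot(is.data.frame(mentions), all(c("text", "gold") %in% names(mentions)))
  if (any(is.na(mentions$gold)))
    stop("evaluate needs a gold annotation for every mention")
  res <- predict(object, mentions$text, ablate = ablate,
                 disambiguate = !("disambig" %in% ablate))
  gold <- mentions$gold
  correct <- if (oracle) {
    mapply(function(cand, g) {
      if (g == cui_less) length(cand) == 0L else g %in% cand
    }, res$candidates, gold)
  } else res$output == gold
  stage_tab <- table(stage = res$stage, correct = correct)
  structure(list(accuracy = 100 * mean(correct), n = length(correct),
                 n_correct = sum(correct), oracle = oracle,
                 table = stage_tab,
                 results = cbind(res, gold = gold, correct = correct)),
            class = "clinnorm_eval")
}

#' @export
print.clinnorm_eval <- function(x, ...) {
  cat(sprintf("Normalization accuracy%s: %.2f%% (%d/%d)\n",
              if (x$oracle) " (oracle)" else "", x$accuracy,
              x$n_correct, x$n))
  print(x$table)
  invisible(x)
}
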