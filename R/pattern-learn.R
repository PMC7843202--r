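# Learning scored, generalized edit patterns from a lexicon's synonym sets.

#' Configuration for edit-pattern learning
#'
#' @param score_threshold Minimum confidence `p/(p+n+1)` a pattern must
#'   exceed to be retained. Default 0.9; learning is not very sensitive to
#'   the exact value but it must be high.
#' @param max_concepts_per_type At most this many concepts are sampled per
#'   semantic type when learning from the lexicon. Default 5000.
#' @param extra_random_concepts Number of additional randomly sampled
#'   concepts mixed in when learning from training data, to drive
#'   generalization and supply negative evidence. Default 3000.
#' @param unit_levels Which unit levels to learn (`"char"`, `"word"`).
#' @param scope `"sampled"` (default) counts positives/negatives only over
#'   the concepts used for learning; `"full"` counts over the whole lexicon.
#' @param random_seed Seed for the concept sampling, recorded with the
#'   learned pattern set.
#' @return An object of class `learn_config`.
#' @export
learn_config <- function(score_threshold = 0.9, max_concepts_per_type = 5000L,
                         extra_random_concepts = 3000L,
                         unit_levels = c("char", "word"),
                         scope = c("sampled", "full"), random_seed = 20201L) {
  stopifnot(score_threshold > 0, score_threshold < 1,
            max_concepts_per_type >= 1L, extra_random_concepts >= 0L,
            all(unit_levels %in% c("char", "word")), length(unit_levels) >= 1L)
  structure(list(score_threshold = score_threshold,
                 max_concepts_per_type = as.integer(max_concepts_per_type),
                 extra_random_concepts = as.integer(extra_random_concepts),
                 unit_levels = unique(unit_levels), scope = match.arg(scope),
                 random_seed = as.integer(random_seed)),
            class = "learn_config")
}

new_pattern_set <- function(patterns, config) {
  structure(list(patterns = patterns, config = config),
            class = "clinnorm_patterns")
}

#' @export
print.clinnorm_patterns <- function(x, ...) {
  if (length(x$patterns) == 0L) {
    cat("Edit pattern set: empty\n")
    return(invisible(x))
  }
  un <- vapply(x$patterns, `[[`, character(1L), "unit")
  pr <- vapply(x$patterns, `[[`, character(1L), "provenance")
  cat(sprintf("Edit pattern set: %d patterns (%d character-based, %d word-based) from %d provenance groups\n",
              length(x$patterns), sum(un == "char"), sum(un == "word"),
              length(unique(pr[!is.na(pr)]))))
  invisible(x)
}

#' @export
as.data.frame.clinnorm_patterns <- function(x, ...) {
  data.frame(unit = vapply(x$patterns, `[[`, character(1L), "unit"),
             provenance = vapply(x$patterns, `[[`, character(1L), "provenance"),
             p = vapply(x$patterns, `[[`, integer(1L), "p"),
             n = vapply(x$patterns, `[[`, integer(1L), "n"),
             score = vapply(x$patterns, `[[`, numeric(1L), "score"),
             pattern = vapply(x$patterns, render_pattern, character(1L)),
             stringsAsFactors = FALSE)
}

#' Seed edit patterns from within-concept synonym pairs
#'
#' For every ordered pair of distinct preprocessed synonyms of each concept,
#' extracts the fully anchored edit pattern converting one into the other.
#' Considering both directions guarantees that the reverse of every seed is
#' also a seed. Duplicates are collapsed.
#'
#' @param concepts List of concept entries (elements of a lexicon's
#'   `concepts`).
#' @param unit `"char"` or `"word"`.
#' @return List of `edit_pattern`s.
#' @export
seed_patterns <- function(concepts, unit = c("char", "word")) {
  unit <- match.arg(unit)
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  out <- list()
  for (con in concepts) {
    syn <- unique(con$synonyms_pp)
    if (length(syn) < 2L) next
    for (i in seq_along(syn)) for (j in seq_along(syn)) {
      if (i == j) next
      ua <- split_units(syn[i], unit)
      if (identical(ua, split_units(syn[j], unit))) next
      P <- extract_edit_pattern(syn[i], syn[j], unit = unit)
      key <- pattern_key(P)
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        out[[length(out) + 1L]] <- P
      }
    }
  }
  out
}

#' Generalization closure of a set of edit patterns
#'
#' Repeatedly generalizes compatible pairs (patterns with identical
#' edit-operation subsequences) until no new pattern arises. The output
#' contains the input patterns and every distinct generalization produced.
#' Patterns are grouped by their edit-operation signature first, since only
#' patterns within a group can generalize.
#'
#' @param seeds List of `edit_pattern`s sharing a unit level.
#' @return List of `edit_pattern`s (deduplicated).
#' @export
generalize_patterns <- function(seeds) {
  if (length(seeds) == 0L) return(list())
  sig <- vapply(seeds, edit_signature, character(1L))
  out <- list()
  for (g in split(seq_along(seeds), sig)) {
    pool <- list()
    keys <- new.env(parent = emptyenv(), hash = TRUE)
    agenda <- seeds[g]
    while (length(agenda) > 0L) {
      P <- agenda[[length(agenda)]]
      agenda[[length(agenda)]] <- NULL
      key <- pattern_key(P)
      if (!is.null(keys[[key]])) next
      keys[[key]] <- TRUE
      for (Q in pool) {
        G <- generalize_pattern(P, Q)
        if (!is.null(G) && is.null(keys[[pattern_key(G)]]))
          agenda[[length(agenda) + 1L]] <- G
      }
      pool[[length(pool) + 1L]] <- P
    }
    out <- c(out, pool)
  }
  out
}

# index of preprocessed term -> CUIs, restricted to the given concepts
scope_term_index <- function(lex, scope_cuis) {
  idx <- new.env(parent = emptyenv(), hash = TRUE)
  for (cui in scope_cuis) {
    for (t in lex$concepts[[cui]]$synonyms_pp)
      idx[[t]] <- c(idx[[t]], cui)
  }
  idx
}

#' Score candidate edit patterns against a lexicon
#'
#' Applies each candidate to every synonym of every in-scope concept. A
#' rewrite that is itself a synonym of the same concept counts as a
#' positive; a rewrite that is a term of some other concept only counts as
#' a negative; rewrites matching nothing in the lexicon count as neither.
#' The score is `p / (p + n + 1)`.
#'
#' @param candidates List of `edit_pattern`s.
#' @param lex A `clinnorm_lexicon`.
#' @param scope Character vector of CUIs over which positives and negatives
#'   are counted (defaults to the whole lexicon).
#' @return The candidates with `p`, `n` and `score` filled in.
#' @export
score_patterns <- function(candidates, lex, scope = names(lex$concepts)) {
  stopifnot(inherits(lex, "clinnorm_lexicon"), all(scope %in% names(lex$concepts)))
  if (length(candidates) == 0L) return(candidates)
  idx <- scope_term_index(lex, scope)
  cuis <- rep(scope, vapply(scope, function(cui)
    length(lex$concepts[[cui]]$synonyms_pp), integer(1L)))
  terms <- unlist(lapply(scope, function(cui) lex$concepts[[cui]]$synonyms_pp),
                  use.names = FALSE)
  lapply(candidates, function(P) {
    src <- pattern_source_units(P)
    cand <- seq_along(terms)
    if (length(src) > 0L) {
      # only terms containing the pattern's contiguous source run can match
      lit <- join_units(src, P$unit)
      cand <- cand[grepl(lit, terms, fixed = TRUE)]
    }
    p <- 0L; n <- 0L
    for (i in cand) {
      rew <- apply_pattern(P, terms[i])
      for (r in rew) {
        owners <- idx[[r]]
        if (is.null(owners)) next
        if (cuis[i] %in% owners) p <- p + 1L else n <- n + 1L
      }
    }
    P$p <- p; P$n <- n; P$score <- pattern_score(p, n)
    P
  })
}

retain_patterns <- function(scored, threshold) {
  Filter(function(P) !is.na(P$score) && P$score > threshold, scored)
}

# union of pattern lists, deduplicated keeping the highest-scoring copy
dedup_max_score <- function(patterns) {
  best <- new.env(parent = emptyenv(), hash = TRUE)
  for (P in patterns) {
    key <- pattern_key(P)
    old <- best[[key]]
    if (is.null(old) || (!is.na(P$score) && (is.na(old$score) || P$score > old$score)))
      best[[key]] <- P
  }
  out <- lapply(sort(ls(best, all.names = TRUE)), function(k) best[[k]])
  out
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

learn_for_scope <- function(lex, scope, cfg, provenance) {
  out <- list()
  for (unit in cfg$unit_levels) {
    seeds <- seed_patterns(lex$concepts[scope], unit = unit)
    cands <- generalize_patterns(seeds)
    score_scope <- if (cfg$scope == "sampled") scope else names(lex$concepts)
    scored <- score_patterns(cands, lex, scope = score_scope)
    kept <- retain_patterns(scored, cfg$score_threshold)
    kept <- lapply(kept, function(P) { P$provenance <- provenance; P })
    out <- c(out, kept)
  }
  out
}

#' Learn edit patterns separately for each semantic type
#'
#' Clinical terms of different semantic types exhibit different variations,
#' so patterns are learned per type: for each semantic-type label, up to
#' `max_concepts_per_type` concepts of that type are sampled, seed patterns
#' are extracted from their within-concept synonym pairs, generalized to
#' closure, scored over the sampled concepts, and retained when the score
#' exceeds the threshold. Retained patterns carry the type as provenance.
#' The union over types is deduplicated keeping the highest-scoring copy.
#'
#' @param lex A `clinnorm_lexicon`.
#' @param cfg A [learn_config()].
#' @return A pattern set (class `clinnorm_patterns`).
#' @export
learn_by_semantic_type <- function(lex, cfg = learn_config()) {
  stopifnot(inherits(lex, "clinnorm_lexicon"))
  with_seed(cfg$random_seed, {
    out <- list()
    for (ty in sort(names(lex$type_index))) {
      cuis <- lex$type_index[[ty]]
      if (length(cuis) > cfg$max_concepts_per_type)
        cuis <- sort(sample(cuis, cfg$max_concepts_per_type))
      out <- c(out, learn_for_scope(lex, cuis, cfg, provenance = ty))
    }
    new_pattern_set(dedup_max_score(out), cfg)
  })
}

#' Learn edit patterns from annotated training mentions
#'
#' Training mention texts are added to the lexicon as extra synonyms of
#' their gold concepts; patterns are then learned over those concepts plus
#' `extra_random_concepts` randomly sampled others (which drive
#' generalization and supply negative evidence), without splitting by
#' semantic type. Retained patterns carry provenance `"training"`.
#'
#' @param lex A `clinnorm_lexicon`.
#' @param mentions Annotated mentions (see [read_mentions()]); `"CUI-less"`
#'   and unannotated mentions are ignored.
#' @param cfg A [learn_config()].
#' @return A pattern set (class `clinnorm_patterns`).
#' @export
learn_from_training <- function(lex, mentions, cfg = learn_config()) {
  stopifnot(inherits(lex, "clinnorm_lexicon"))
  aug <- augment_with_training(lex, mentions)
  gold <- unique(mentions$gold[!is.na(mentions$gold) & mentions$gold != cui_less])
  with_seed(cfg$random_seed, {
    others <- setdiff(names(aug$concepts), gold)
    if (length(others) > cfg$extra_random_concepts)
      others <- sort(sample(others, cfg$extra_random_concepts))
    scope <- sort(c(gold, others))
    new_pattern_set(dedup_max_score(learn_for_scope(aug, scope, cfg,
                                                    provenance = "training")),
                    cfg)
  })
}

#' Combine pattern sets
#'
#' Union of the given pattern sets, deduplicated (identical unit level,
#' anchors and operations) keeping the highest-scoring copy.
#'
#' @param ... Pattern sets (`clinnorm_patterns`).
#' @return A `clinnorm_patterns`.
#' @export
combine_patterns <- function(...) {
  sets <- list(...)
  stopifnot(all(vapply(sets, inherits, logical(1L), "clinnorm_patterns")))
  cfg <- if (length(sets)) sets[[1L]]$config else learn_config()
  new_pattern_set(dedup_max_score(do.call(c, lapply(sets, `[[`, "patterns"))), cfg)
}

#' Write a pattern set to a text file
#'
#' One pattern per line: unit level, provenance, positive count, negative
#' count, score and the rendered pattern, tab-separated.
#'
#' @param ps A `clinnorm_patterns`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_patterns <- function(ps, path) {
  df <- as.data.frame(ps)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("unit\tprovenance\tp\tn\tscore\tpattern",
               sprintf("%s\t%s\t%d\t%d\t%.17g\t%s", df$unit, df$provenance,
                       df$p, df$n, df$score, df$pattern)), con)
  invisible(path)
}

#' Read a pattern set written by [write_patterns()]
#'
#' @param path File path.
#' @param config Learning configuration to attach (metadata only).
#' @return A `clinnorm_patterns`.
#' @export
read_patterns <- function(path, config = learn_config()) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L || lines[1L] != "unit\tprovenance\tp\tn\tscore\tpattern")
    stop("not a pattern file: ", path)
  pats <- lapply(lines[-1L], function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) != 6L) stop("malformed pattern line: ", ln)
    parse_pattern(f[6L], unit = f[1L], provenance = f[2L],
                  p = as.integer(f[3L]), n = as.integer(f[4L]))
  })
  new_pattern_set(pats, config)
}
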