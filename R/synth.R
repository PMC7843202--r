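# Synthetic lexicons with planted term variations. The generator emulates
# the statistical structure normalization learning relies on: concepts whose
# synonym sets instantiate a small library of systematic variations
# (pluralization, spelling variants, word substitutions, trailing markers),
# distractor concepts supplying negative evidence, terms shared across
# concepts (ambiguity), and compositional concepts whose synonyms are built
# from other concepts' terms (for subconcept matching). Vocabulary is
# pronounceable random syllables so cross-concept string collisions are
# rare and every planted effect is attributable.

synth_consonants <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "t", "v", "z")
synth_vowels <- c("a", "e", "i", "o", "u")

#' Library of planted variation rules
#'
#' Analogues of the variation families commonly learned from real
#' terminologies: suffix pluralization (trailing "s"), a spelling variant
#' inserting "u" into a trailing "or" (the "tumour"/"tumor" family), a
#' whole-word substitution pair, and a trailing "nos" marker token. Each
#' rule carries the unit level at which it is learnable and the semantic
#' type its concepts are planted under.
#'
#' @return Named list of rule descriptors (`id`, `level`, `sty`, and the
#'   forward rewrite `f` mapping a base synonym to its variant).
#' @export
synth_rule_library <- function() {
  list(
    plural_s = list(id = "plural_s", level = "char",
                    sty = "disease or syndrome",
                    f = function(x) paste0(x, "s")),
    spell_our = list(id = "spell_our", level = "char",
                     sty = "neoplastic process",
                     f = function(x) sub("or$", "our", x)),
    word_sub = list(id = "word_sub", level = "word",
                    sty = "diagnostic procedure",
                    f = NULL),   # filled in with the generated word pair
    del_nos = list(id = "del_nos", level = "word",
                   sty = "clinical drug",
                   f = function(x) paste(x, "nos"))
  )
}

#' Configuration for the synthetic data generator
#'
#' @param instances_per_rule Concepts instantiating each planted rule; at
#'   least 10 are needed for a zero-negative rule to clear the 0.9 score
#'   threshold (`p/(p+1) > 0.9` requires `p >= 10`). Default 12.
#' @param n_eval_per_rule Pattern-reachable evaluation mentions per rule
#'   (each built from an extra synonym of one rule concept). Must not
#'   exceed `instances_per_rule`.
#' @param n_distractors Single-synonym distractor concepts spread over all
#'   semantic types (negative-evidence pool). Default 60.
#' @param n_ambiguous Terms planted verbatim in two concepts of different
#'   semantic types; half appear (annotated) in training, half in
#'   evaluation. Default 6.
#' @param n_ambiguous_rule Concepts instantiating the planted ambiguous
#'   rewrite (a final-vowel swap that lands on a different concept as often
#'   as on a synonym), which learning must reject. Default 12.
#' @param n_compositional Host concepts whose only synonym is built from
#'   two other concepts' terms, evaluated via subconcept matching.
#'   Default 8.
#' @param n_exact_eval Evaluation mentions that are verbatim lexicon
#'   synonyms. Default 30.
#' @param n_train_exact_eval Evaluation mentions that repeat annotated
#'   training texts (exact-matchable only through the training index).
#'   Default 3.
#' @param n_cuiless_eval Evaluation mentions matching nothing (gold
#'   `"CUI-less"`). Default 15.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(instances_per_rule = 12L, n_eval_per_rule = 6L,
                         n_distractors = 60L, n_ambiguous = 6L,
                         n_ambiguous_rule = 12L, n_compositional = 8L,
                         n_exact_eval = 30L, n_train_exact_eval = 3L,
                         n_cuiless_eval = 15L, seed = 1L) {
  cfg <- list(instances_per_rule = as.integer(instances_per_rule),
              n_eval_per_rule = as.integer(n_eval_per_rule),
              n_distractors = as.integer(n_distractors),
              n_ambiguous = as.integer(n_ambiguous),
              n_ambiguous_rule = as.integer(n_ambiguous_rule),
              n_compositional = as.integer(n_compositional),
              n_exact_eval = as.integer(n_exact_eval),
              n_train_exact_eval = as.integer(n_train_exact_eval),
              n_cuiless_eval = as.integer(n_cuiless_eval),
              seed = as.integer(seed))
  if (cfg$instances_per_rule < 2L)
    stop("instances_per_rule must be at least 2 (generalization needs pairs)")
  if (cfg$n_eval_per_rule > cfg$instances_per_rule)
    stop("n_eval_per_rule cannot exceed instances_per_rule")
  if (cfg$n_exact_eval > cfg$n_distractors)
    stop("n_exact_eval cannot exceed n_distractors")
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic lexicon, training mentions and evaluation set
#'
#' Produces a lexicon with planted variation structure (see
#' [synth_config()]), annotated training mentions (ambiguity resolutions
#' and a training-only word substitution family), an evaluation set whose
#' mentions each belong to a known reachability class, and a ground-truth
#' manifest recording, for every evaluation mention, its gold CUI, class
#' (`exact`, `pattern`, `subconcept`, `cuiless`), the planted rule behind
#' it (if any) and — for pattern-reachable mentions — the lexicon synonym
#' its rewrite must land on.
#'
#' @param cfg A [synth_config()].
#' @return List with components `lexicon` (a `clinnorm_lexicon`), `train`
#'   and `eval` (mention data frames), `manifest` (data frame) and `config`.
#' @export
synth_generate <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    used <- new.env(parent = emptyenv(), hash = TRUE)
    new_word <- function(nsyl = 2L, suffix = "") {
      repeat {
        w <- paste0(paste0(sample(synth_consonants, nsyl, replace = TRUE),
                           sample(synth_vowels, nsyl, replace = TRUE),
                           collapse = ""), suffix)
        if (is.null(used[[w]])) {
          used[[w]] <- TRUE
          return(w)
        }
      }
    }
    cui_n <- 0L
    new_cui <- function() {
      cui_n <<- cui_n + 1L
      sprintf("C%07d", cui_n)
    }
    rows <- list(); train <- list(); manifest <- list()
    add_row <- function(cui, term, sty, source = "synthetic")
      rows[[length(rows) + 1L]] <<- data.frame(cui = cui, term = term,
                                               sty = sty, source = source,
                                               stringsAsFactors = FALSE)
    add_train <- function(text, gold)
      train[[length(train) + 1L]] <<- data.frame(text = text, gold = gold,
                                                 stringsAsFactors = FALSE)
    add_eval <- function(text, gold, class, rule = NA_character_,
                         subtype = NA_character_, target = NA_character_)
      manifest[[length(manifest) + 1L]] <<-
        data.frame(text = text, gold = gold, class = class, rule = rule,
                   subtype = subtype, target = target,
                   stringsAsFactors = FALSE)

    rules <- synth_rule_library()
    # the word-substitution family needs its shared token pair generated
    ws_pair <- c(new_word(2L), new_word(2L))
    rules$word_sub$f <- function(x) {
      toks <- strsplit(x, " ", fixed = TRUE)[[1L]]
      paste(ifelse(toks == ws_pair[1L], ws_pair[2L], toks), collapse = " ")
    }
    gen_base <- function(rule_id, i) {
      switch(rule_id,
             # cycle the final character so the generalization closure always
             # sees pairs with no shared context and reaches the bare rule
             plural_s = new_word(2L, suffix = synth_vowels[(i - 1L) %% 5L + 1L]),
             spell_our = new_word(2L,
                                  suffix = paste0(synth_consonants[(i - 1L) %% 13L + 1L], "or")),
             word_sub = paste(new_word(2L), ws_pair[1L]),
             del_nos = new_word(2L))
    }

    for (r in rules) {
      for (i in seq_len(cfg$instances_per_rule)) {
        cui <- new_cui()
        base <- gen_base(r$id, i)
        variant <- r$f(base)
        used[[variant]] <- TRUE
        add_row(cui, base, r$sty)
        add_row(cui, variant, r$sty)
        if (i <= cfg$n_eval_per_rule) {
          extra <- gen_base(r$id, i + 2L)  # offset keeps endings diverse
          add_row(cui, extra, r$sty)
          mention <- r$f(extra)
          used[[mention]] <- TRUE
          add_eval(mention, cui, class = "pattern", rule = r$id,
                   target = extra)
        }
      }
    }

    # training-only word substitution family: the variant form appears only
    # in annotated training mentions, never in the lexicon
    tr_pair <- c(new_word(2L), new_word(2L))
    tr_f <- function(x) sub(paste0("^", tr_pair[1L], " "),
                            paste0(tr_pair[2L], " "), x)
    for (i in seq_len(cfg$instances_per_rule)) {
      cui <- new_cui()
      base <- paste(tr_pair[1L], new_word(2L))
      add_row(cui, base, "finding")
      add_train(tr_f(base), cui)
      if (i <= cfg$n_train_exact_eval)
        add_eval(tr_f(base), cui, class = "exact", subtype = "training")
    }
    for (j in seq_len(cfg$n_eval_per_rule)) {
      cui <- new_cui()
      base <- paste(tr_pair[1L], new_word(2L))
      add_row(cui, base, "finding")
      mention <- tr_f(base)
      used[[mention]] <- TRUE
      add_eval(mention, cui, class = "pattern", rule = "train_sub",
               target = base)
    }

    # planted ambiguous rewrite: swapping the final vowel lands on another
    # concept as often as on a synonym, so the rule must be rejected
    amb_pairs <- lapply(seq_len(cfg$n_ambiguous_rule), function(i) {
      repeat {
        stem <- new_word(2L, suffix = synth_consonants[(i - 1L) %% 13L + 1L])
        wa <- paste0(stem, "a"); we <- paste0(stem, "e")
        if (is.null(used[[wa]]) && is.null(used[[we]])) {
          used[[wa]] <- TRUE; used[[we]] <- TRUE
          return(c(wa, we))
        }
      }
    })
    for (i in seq_len(cfg$n_ambiguous_rule)) {
      p <- amb_pairs[[i]]
      if (i %% 2L == 1L) {         # synonym pair: positive evidence
        cui <- new_cui()
        add_row(cui, p[1L], "laboratory procedure")
        add_row(cui, p[2L], "laboratory procedure")
      } else {                     # split across concepts: negative evidence
        add_row(new_cui(), p[1L], "laboratory procedure")
        add_row(new_cui(), p[2L], "laboratory procedure")
      }
    }

    # ambiguity injections: one term listed under two concepts of different
    # semantic types; training resolves half, evaluation holds the rest
    for (i in seq_len(cfg$n_ambiguous)) {
      w <- new_word(3L)
      cui_a <- new_cui(); cui_b <- new_cui()
      add_row(cui_a, w, "finding")
      add_row(cui_b, w, "health care activity")
      if (i <= cfg$n_ambiguous %/% 2L) add_train(w, cui_b)
      else add_eval(w, cui_b, class = "exact", subtype = "ambiguous")
    }

    # compositional concepts for subconcept matching: host K's synonym is
    # "<x> <u>"; u and v are synonyms of the same component concept, so the
    # unseen combination "<x> <v>" reaches K only through shared CUIs
    for (i in seq_len(cfg$n_compositional)) {
      x <- new_word(2L); u <- new_word(2L); v <- new_word(2L)
      cui_x <- new_cui()
      add_row(cui_x, x, "body part, organ, or organ component")
      cui_c <- new_cui()
      add_row(cui_c, u, "pharmacologic substance")
      add_row(cui_c, v, "pharmacologic substance")
      cui_k <- new_cui()
      host <- paste(x, u)
      used[[host]] <- TRUE
      add_row(cui_k, host, "therapeutic or preventive procedure")
      mention <- paste(x, v)
      used[[mention]] <- TRUE
      add_eval(mention, cui_k, class = "subconcept")
    }

    # distractor concepts: negative-evidence pool and exact-match evaluation
    stys <- c("disease or syndrome", "neoplastic process",
              "diagnostic procedure", "clinical drug", "laboratory procedure",
              "finding", "health care activity",
              "therapeutic or preventive procedure")
    for (i in seq_len(cfg$n_distractors)) {
      cui <- new_cui()
      w <- new_word(3L)
      add_row(cui, w, stys[(i - 1L) %% length(stys) + 1L])
      if (i <= cfg$n_exact_eval)
        add_eval(w, cui, class = "exact", subtype = "lexicon")
    }

    for (i in seq_len(cfg$n_cuiless_eval))
      add_eval(new_word(3L), cui_less, class = "cuiless")

    lex <- lexicon(do.call(rbind, rows))
    train_df <- do.call(rbind, train)
    man <- do.call(rbind, manifest)
    man <- man[sample.int(nrow(man)), , drop = FALSE]
    rownames(man) <- NULL

    # reachability bookkeeping must be sound: non-exact mentions are not in
    # the lexicon or training texts, exact mentions are
    in_lex <- vapply(preprocess_terms(man$text, lex$cfg),
                     function(t) length(lookup_term(lex, t)) > 0L, logical(1L))
    is_train <- man$text %in% train_df$text
    stopifnot(all(in_lex[man$class == "exact" & man$subtype != "training"] %in% TRUE),
              !any(in_lex[man$class != "exact"]),
              !any(is_train[man$class != "exact"]))

    list(lexicon = lex, train = train_df,
         eval = man[, c("text", "gold")], manifest = man, config = cfg)
  })
}

#' Write a synthetic data set to a directory
#'
#' Writes `lexicon.tsv`, `train.tsv`, `eval.tsv` and the ground-truth
#' manifest as JSON-lines (`manifest.jsonl`).
#'
#' @param synth Result of [synth_generate()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synth <- function(synth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_lexicon(synth$lexicon, file.path(dir, "lexicon.tsv"))
  write_mentions(synth$train, file.path(dir, "train.tsv"))
  write_mentions(synth$eval, file.path(dir, "eval.tsv"))
  con <- file(file.path(dir, "manifest.jsonl"), open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(synth$manifest)))
    writeLines(as.character(jsonlite::toJSON(as.list(synth$manifest[i, ]),
                                             auto_unbox = TRUE, na = "null")),
               con)
  invisible(dir)
}
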