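# small planted lexicon: k concepts with a base/plural synonym pair plus
# distractors; the pluralization rule should be learnable with no negatives
planted_plural_lexicon <- function(k = 10L, distractors = 20L) {
  bases <- paste0("wor", letters[seq_len(k)], rep(c("a", "e", "i", "o", "u"),
                                                  length.out = k))
  rows <- rbind(
    data.frame(cui = sprintf("P%02d", seq_len(k)), term = bases,
               sty = "dsyn", stringsAsFactors = FALSE),
    data.frame(cui = sprintf("P%02d", seq_len(k)), term = paste0(bases, "s"),
               sty = "dsyn", stringsAsFactors = FALSE),
    data.frame(cui = sprintf("D%02d", seq_len(distractors)),
               term = paste0("dis", letters[seq_len(distractors)], "ko"),
               sty = "dsyn", stringsAsFactors = FALSE))
  lexicon(rows)
}

test_that("seed patterns cover both directions of each synonym pair", {
  lex <- lexicon(data.frame(cui = "C1", term = c("anemic", "anemias"),
                            stringsAsFactors = FALSE))
  seeds <- seed_patterns(lex$concepts)
  expect_length(seeds, 2L)
  r <- vapply(seeds, render_pattern, character(1L))
  expect_true(render_pattern(reverse_pattern(seeds[[1L]])) %in% r)
  # one synonym: nothing to pair
  one <- lexicon(data.frame(cui = "C1", term = "anemia", stringsAsFactors = FALSE))
  expect_length(seed_patterns(one$concepts), 0L)
  # synonyms identical after preprocessing: no seeds
  same <- lexicon(data.frame(cui = "C1", term = c("x y", "x  y", "z"),
                             stringsAsFactors = FALSE))
  expect_length(seed_patterns(same$concepts), 2L)  # only the x y <-> z pair
})

test_that("the generalization closure reproduces the suffix-family pattern", {
  closed <- generalize_patterns(fig_seeds())
  rendered <- vapply(closed, render_pattern, character(1L))
  expect_true("SAME m SAME i INSERT a SUBSTITUTE c|s END" %in% rendered)
  # closure includes the seeds themselves
  expect_true(all(vapply(fig_seeds(), render_pattern, character(1L)) %in% rendered))
  expect_identical(anyDuplicated(rendered), 0L)
  # incompatible seeds pass through untouched
  pats <- list(parse_pattern("INSERT s END"), parse_pattern("DELETE q END"))
  expect_length(generalize_patterns(pats), 2L)
  # duplicated seeds do not duplicate outputs
  expect_length(generalize_patterns(c(pats, pats)), 2L)
})

test_that("scoring counts positives and negatives over the scope concepts", {
  lex <- planted_plural_lexicon(k = 7L)
  P <- parse_pattern("INSERT s END")
  scored <- score_patterns(list(P), lex)[[1L]]
  expect_identical(scored$p, 7L)
  expect_identical(scored$n, 0L)
  expect_equal(scored$score, 7 / 8)
  # a pattern whose rewrites never hit the lexicon scores 0/(0+0+1)
  miss <- score_patterns(list(parse_pattern("INSERT q INSERT q END")), lex)[[1L]]
  expect_identical(c(miss$p, miss$n), c(0L, 0L))
  expect_identical(miss$score, 0)
  # a rewrite landing on a different concept counts as a negative
  amb <- lexicon(data.frame(cui = c("A", "B"), term = c("kata", "kate"),
                            stringsAsFactors = FALSE))
  neg <- score_patterns(list(parse_pattern("SUBSTITUTE a|e END")), amb)[[1L]]
  expect_identical(c(neg$p, neg$n), c(0L, 1L))
})

test_that("the score formula behaves as an m-estimate", {
  expect_equal(pattern_score(1148, 2), 1148 / 1151)
  expect_equal(round(pattern_score(1148, 2), 5), 0.99739)
  expect_identical(pattern_score(0, 0), 0)
  # strictly increasing in p; strictly decreasing in n once p > 0
  p <- rep(0:50, each = 11); n <- rep(0:10, times = 51)
  s <- pattern_score(p, n)
  expect_true(all(s >= 0 & s < 1))
  expect_true(all(pattern_score(p + 1, n) > s))
  expect_true(all(pattern_score(p, n + 1)[p > 0] < s[p > 0]))
})

test_that("per-type learning recovers a planted rule and respects the threshold", {
  lex <- planted_plural_lexicon(k = 12L)
  ps <- learn_by_semantic_type(lex, learn_config(unit_levels = "char"))
  stopifnot(length(ps$patterns) > 0L)
  rendered <- vapply(ps$patterns, render_pattern, character(1L))
  expect_true("INSERT s END" %in% rendered)
  expect_true("DELETE s END" %in% rendered)
  expect_true(all(vapply(ps$patterns, `[[`, numeric(1L), "score") > 0.9))
  expect_true(all(vapply(ps$patterns, `[[`, character(1L), "provenance") == "dsyn"))
  # a stricter threshold retains a subset
  hi <- learn_by_semantic_type(lex, learn_config(score_threshold = 0.95,
                                                 unit_levels = "char"))
  expect_true(all(vapply(hi$patterns, render_pattern, character(1L)) %in% rendered))
  # no multi-synonym concepts: nothing to learn
  lone <- lexicon(data.frame(cui = c("C1", "C2"), term = c("aa", "bb"),
                             stringsAsFactors = FALSE))
  expect_length(learn_by_semantic_type(lone)$patterns, 0L)
})

test_that("candidate patterns are closed under reversal before scoring", {
  lex <- synth_fixture()$syn$lexicon
  for (unit in c("char", "word")) {
    seeds <- seed_patterns(lex$concepts[lex$type_index[["disease or syndrome"]]],
                           unit = unit)
    cands <- generalize_patterns(seeds)
    keys <- vapply(cands, function(P) render_pattern(P), character(1L))
    rev_keys <- vapply(cands, function(P) render_pattern(reverse_pattern(P)),
                       character(1L))
    expect_true(all(rev_keys %in% keys))
  }
})

test_that("training-data learning finds corpus-specific substitutions deterministically", {
  syn <- synth_fixture()$syn
  cfg <- learn_config(unit_levels = "word")
  ps1 <- learn_from_training(syn$lexicon, syn$train, cfg)
  expect_gt(length(ps1$patterns), 0L)
  expect_true(all(vapply(ps1$patterns, `[[`, character(1L), "provenance") == "training"))
  # the planted training-only substitution was learned: some retained
  # pattern rewrites a held-out training-style mention onto its target
  man <- syn$manifest
  tr <- man[man$class == "pattern" & man$rule == "train_sub", , drop = FALSE][1L, ]
  hits <- unlist(lapply(ps1$patterns, apply_pattern, term = tr$text))
  expect_true(tr$target %in% hits)
  # rerun with the same seed: identical pattern set
  ps2 <- learn_from_training(syn$lexicon, syn$train, cfg)
  expect_identical(vapply(ps1$patterns, render_pattern, character(1L)),
                   vapply(ps2$patterns, render_pattern, character(1L)))
  # no mentions: patterns come only from the sampled concepts' own synonymy
  ps0 <- learn_from_training(syn$lexicon,
                             data.frame(text = character(0), gold = character(0)),
                             cfg)
  hits0 <- unlist(lapply(ps0$patterns, apply_pattern, term = tr$text))
  expect_false(tr$target %in% hits0)
})

test_that("pattern files round-trip exactly", {
  ps <- learn_by_semantic_type(planted_plural_lexicon(),
                               learn_config(unit_levels = c("char", "word")))
  path <- withr::local_tempfile(fileext = ".txt")
  write_patterns(ps, path)
  back <- read_patterns(path)
  expect_identical(as.data.frame(back), as.data.frame(ps))
  expect_error(read_patterns(withr::local_tempfile(lines = "junk")), "pattern file")
})
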