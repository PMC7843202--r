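write_tsv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("lexicon construction collapses duplicates and indexes terms", {
  lex <- lexicon(data.frame(cui = c("C1", "C1", "C1"),
                            term = c("anemia", "anaemia", "anemia"),
                            sty = "dsyn", stringsAsFactors = FALSE))
  expect_length(lex$concepts, 1L)
  expect_identical(lex$concepts$C1$synonyms, c("anaemia", "anemia"))
  expect_identical(lookup_term(lex, "anaemia"), "C1")
  expect_length(ls(lex$term_index, all.names = TRUE), 2L)
})

test_that("a term shared by two concepts indexes to both", {
  lex <- lexicon(data.frame(cui = c("C1", "C2"), term = c("x", "x"),
                            stringsAsFactors = FALSE))
  expect_identical(lookup_term(lex, "x"), c("C1", "C2"))
  expect_identical(lex$concepts$C1$semantic_types, "unknown")
})

test_that("term index is exhaustively consistent with the stored synonyms", {
  lex <- synth_fixture()$syn$lexicon
  for (cui in names(lex$concepts))
    for (t in lex$concepts[[cui]]$synonyms_pp)
      expect_true(cui %in% lookup_term(lex, t))
  for (t in ls(lex$term_index, all.names = TRUE))
    for (cui in lex$term_index[[t]])
      expect_true(t %in% lex$concepts[[cui]]$synonyms_pp)
})

test_that("lexicon files round-trip and malformed input is rejected by line", {
  path <- write_tsv_lines(c("cui\tterm\tsty\tsource",
                            "C1\tanemia\tdsyn\tSNOMEDCT_US",
                            "C1\tanaemia\tdsyn\tSNOMEDCT_US",
                            "C2\tanemia\tlbtr\tSNOMEDCT_US"))
  lex <- read_lexicon(path)
  expect_identical(lookup_term(lex, "anemia"), c("C1", "C2"))
  out <- withr::local_tempfile(fileext = ".tsv")
  write_lexicon(lex, out)
  expect_identical(read_lexicon(out)$rows, lex$rows)

  expect_error(read_lexicon(write_tsv_lines("cui\tterm")), "no data rows")
  expect_error(read_lexicon(write_tsv_lines(c("term\tsty", "anemia\tdsyn"))),
               "must name")
  expect_error(read_lexicon(write_tsv_lines(c("cui\tterm", "C1"))),
               "line 2")
  expect_error(read_lexicon(write_tsv_lines(character(0))), "empty")
})

test_that("pipe-delimited positional dialects are read with language filtering", {
  path <- write_tsv_lines(c(
    paste(c("C1", "ENG", rep("x", 9), "SNOMEDCT_US", "x", "x", "anemia", "z"), collapse = "|"),
    paste(c("C1", "FRE", rep("x", 9), "SNOMEDCT_US", "x", "x", "anémie", "z"), collapse = "|")))
  lex <- read_lexicon(path, dialect = mrconso_dialect())
  expect_length(lex$concepts, 1L)
  expect_identical(lex$concepts$C1$synonyms, "anemia")
  expect_identical(lex$rows$source, "SNOMEDCT_US")
})

test_that("mentions are read in order with CUI-less distinct from unknown", {
  path <- write_tsv_lines(c("text\tgold",
                            "atrial fibrillation\tC0004238",
                            "left breast biopsy\tCUI-less"))
  m <- read_mentions(path)
  expect_identical(m$gold, c("C0004238", cui_less))
  # absent gold column: unknown, not CUI-less
  m2 <- read_mentions(write_tsv_lines(c("text", "fever")))
  expect_true(is.na(m2$gold))
  expect_error(read_mentions(write_tsv_lines(c("text\tgold", "\tC1"))),
               "line 2")
})

test_that("training mentions become synonyms of their gold concepts", {
  lex <- lexicon(data.frame(cui = "C9", term = "finding", sty = "fndg",
                            stringsAsFactors = FALSE))
  aug <- augment_with_training(lex, data.frame(text = "obs", gold = "C9",
                                               stringsAsFactors = FALSE))
  expect_setequal(aug$concepts$C9$synonyms_pp, c("finding", "obs"))
  # identity on empty and on all-CUI-less mention lists
  expect_identical(augment_with_training(lex, data.frame(text = character(0),
                                                         gold = character(0)))$rows,
                   lex$rows)
  expect_identical(augment_with_training(lex, data.frame(text = "x",
                                                         gold = cui_less))$rows,
                   lex$rows)
  # unknown gold CUIs create new entries with the reserved type
  aug2 <- augment_with_training(lex, data.frame(text = "new thing", gold = "C77",
                                                stringsAsFactors = FALSE))
  expect_identical(aug2$concepts$C77$semantic_types, "unknown")
})
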