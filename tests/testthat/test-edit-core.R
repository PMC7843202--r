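test_that("edit distance matches known clinical term pairs", {
  expect_identical(edit_distance("glycemic", "glycemias"), 2L)
  expect_identical(edit_distance("typical angina", "atypical angina"), 1L)
  expect_identical(edit_distance("cardiac sarcoidosis", "heart sarcoid disease"), 12L)
  expect_identical(edit_distance("x", "x"), 0L)
  expect_identical(edit_distance("cardiac arrest", "heart arrest", "word"), 1L)
})

test_that("edit distance agrees with a brute-force recursive oracle", {
  S <- all_strings(c("a", "b", "c"), 3L)
  for (a in S) for (b in S)
    expect_identical(edit_distance(a, b), bf_edit_distance(a, b))
  # longer random pairs, still within brute-force reach
  set.seed(4)
  for (k in 1:60) {
    a <- paste0(sample(c("a", "b", "c"), sample(0:7, 1L), TRUE), collapse = "")
    b <- paste0(sample(c("a", "b", "c"), sample(0:7, 1L), TRUE), collapse = "")
    expect_identical(edit_distance(a, b), bf_edit_distance(a, b))
  }
})

test_that("scalar and matrix distance paths agree", {
  S <- all_strings(c("a", "b"), 4L)
  D <- edit_distance_matrix(S)
  ij <- expand.grid(i = seq_along(S), j = seq_along(S))
  expect_identical(edit_distance(S[ij$i], S[ij$j]), D[cbind(ij$i, ij$j)])
})

test_that("pattern extraction yields the canonical anchored alignment", {
  expect_identical(
    render_pattern(extract_edit_pattern("anemic", "anemias")),
    "BEGIN SAME a SAME n SAME e SAME m SAME i INSERT a SUBSTITUTE c|s END")
  expect_identical(
    render_pattern(extract_edit_pattern("cardiac arrest", "heart arrest", "word")),
    "BEGIN SUBSTITUTE cardiac|heart SAME arrest END")
  # tie between two 2-edit alignments resolved by the fixed traceback policy
  expect_identical(render_pattern(extract_edit_pattern("ab", "ba")),
                   "BEGIN SUBSTITUTE a|b SUBSTITUTE b|a END")
  expect_error(extract_edit_pattern("x", "x"), "identical")
})

test_that("extraction edit count equals the edit distance and applying recovers the target", {
  set.seed(21)
  for (k in 1:200) {
    pr <- random_synonym_pair()
    P <- extract_edit_pattern(pr[1L], pr[2L])
    expect_identical(sum(P$ops$kind != "SAME"),
                     edit_distance(pr[1L], pr[2L]))
    expect_identical(apply_pattern(P, pr[1L]), pr[2L])
  }
})

test_that("generalization finds the longest common pattern with all edits", {
  s <- fig_seeds()
  g1 <- generalize_pattern(s[[1L]], s[[2L]])
  expect_identical(render_pattern(g1),
                   "SAME e SAME m SAME i INSERT a SUBSTITUTE c|s END")
  g2 <- generalize_pattern(g1, s[[3L]])
  expect_identical(render_pattern(g2),
                   "SAME m SAME i INSERT a SUBSTITUTE c|s END")
  # self-generalization is the identity
  expect_identical(render_pattern(generalize_pattern(g2, g2)),
                   render_pattern(g2))
  # different edit-op subsequences are incompatible
  expect_null(generalize_pattern(parse_pattern("INSERT s END"),
                                 parse_pattern("DELETE s END")))
  # differing SAME context between edit ops is incompatible
  expect_null(generalize_pattern(parse_pattern("INSERT a SAME x INSERT b"),
                                 parse_pattern("INSERT a SAME y INSERT b")))
})

test_that("generalization is commutative and sound for the source terms", {
  set.seed(31)
  for (k in 1:60) {
    p1 <- random_synonym_pair(); p2 <- random_synonym_pair()
    P1 <- extract_edit_pattern(p1[1L], p1[2L])
    P2 <- extract_edit_pattern(p2[1L], p2[2L])
    G12 <- generalize_pattern(P1, P2)
    G21 <- generalize_pattern(P2, P1)
    if (is.null(G12)) {
      expect_null(G21)
    } else {
      expect_identical(render_pattern(G12), render_pattern(G21))
      expect_true(p1[2L] %in% apply_pattern(G12, p1[1L]))
      expect_true(p2[2L] %in% apply_pattern(G12, p2[1L]))
    }
  }
})

test_that("matching respects context, anchors and multiple locations", {
  G <- parse_pattern("SAME m SAME i INSERT a SUBSTITUTE c|s END")
  expect_length(match_pattern(G, "arrhythmic"), 1L)
  expect_identical(apply_pattern(G, "arrhythmic"), "arrhythmias")
  # the less general pattern expects an "e" and must not match
  G1 <- parse_pattern("SAME e SAME m SAME i INSERT a SUBSTITUTE c|s END")
  expect_length(match_pattern(G1, "arrhythmic"), 0L)
  expect_identical(apply_pattern(G1, "arrhythmic"), character(0))
  # an unanchored substitution fires at every occurrence of its source
  P <- parse_pattern("SAME x SUBSTITUTE a|o")
  expect_length(match_pattern(P, "xaxa"), 2L)
  expect_setequal(apply_pattern(P, "xaxa"), c("xoxa", "xaxo"))
  # insertion-only patterns anchor to term boundaries
  expect_identical(apply_pattern(parse_pattern("INSERT s END"), "tumor"),
                   "tumors")
  expect_identical(apply_pattern(parse_pattern("BEGIN INSERT a"), "typical"),
                   "atypical")
})

test_that("the number of rewrites equals the number of match locations", {
  set.seed(41)
  pats <- list(parse_pattern("SUBSTITUTE a|b"),
               parse_pattern("SAME b DELETE a"),
               parse_pattern("INSERT c END"),
               parse_pattern("SAME a INSERT b SAME c"))
  for (k in 1:100) {
    term <- random_word(sample(2:8, 1L))
    for (P in pats) {
      loc <- match_pattern(P, term)
      rew <- apply_pattern(P, term)
      # one rewrite per location, collapsed when two locations happen to
      # produce the same string
      expect_lte(length(rew), length(loc))
      expect_identical(length(rew) > 0L, length(loc) > 0L)
    }
  }
  # distinct contexts give exactly one rewrite per location
  P <- parse_pattern("SUBSTITUTE a|o")
  expect_length(match_pattern(P, "haba"), 2L)
  expect_length(apply_pattern(P, "haba"), 2L)
})

test_that("pattern reversal is an involution that undoes the rewrite", {
  expect_identical(render_pattern(reverse_pattern(parse_pattern("INSERT s END"))),
                   "DELETE s END")
  expect_identical(
    render_pattern(reverse_pattern(parse_pattern("SUBSTITUTE cardiac|heart", "word"))),
    "SUBSTITUTE heart|cardiac")
  set.seed(51)
  for (k in 1:50) {
    pr <- random_synonym_pair()
    P <- extract_edit_pattern(pr[1L], pr[2L])
    expect_identical(render_pattern(reverse_pattern(reverse_pattern(P))),
                     render_pattern(P))
    expect_identical(apply_pattern(reverse_pattern(P), pr[2L]), pr[1L])
  }
})

test_that("rendering and parsing are exact inverses, including space units", {
  strs <- c("BEGIN SAME g SAME l INSERT a SUBSTITUTE c|s END",
            "INSERT u SAME r SAME _space_",
            "DELETE _space_ DELETE n DELETE o DELETE s END",
            "BEGIN SUBSTITUTE cardiac|heart SAME arrest END")
  units <- c("char", "char", "char", "word")
  for (i in seq_along(strs))
    expect_identical(render_pattern(parse_pattern(strs[i], units[i])), strs[i])
  # a pattern containing a literal space character survives the round trip
  P <- extract_edit_pattern("tumor of", "tumour of")
  expect_identical(render_pattern(parse_pattern(render_pattern(P))),
                   render_pattern(P))
  expect_error(parse_pattern("SAME x SAME y"), "edit operation")
  expect_error(parse_pattern("NOPE x"), "malformed")
})
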