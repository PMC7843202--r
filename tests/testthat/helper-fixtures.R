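# Shared fixtures, all built in code.

# brute-force recursive Levenshtein distance: the independent oracle for the
# DP implementation (exponential, so only used on short strings)
bf_edit_distance <- function(a, b) {
  ua <- strsplit(a, "")[[1L]]
  ub <- strsplit(b, "")[[1L]]
  rec <- function(i, j) {
    if (i == 0L) return(j)
    if (j == 0L) return(i)
    min(rec(i - 1L, j - 1L) + (ua[i] != ub[j]),
        rec(i - 1L, j) + 1L,
        rec(i, j - 1L) + 1L)
  }
  rec(length(ua), length(ub))
}

# all strings over `alphabet` up to length `max_len` (including "")
all_strings <- function(alphabet, max_len) {
  unlist(lapply(0:max_len, function(L) {
    if (L == 0L) return("")
    apply(do.call(expand.grid,
                  c(rep(list(alphabet), L), stringsAsFactors = FALSE)),
          1L, paste0, collapse = "")
  }))
}

random_word <- function(len = sample(3:10, 1L)) {
  paste0(sample(letters[1:6], len, replace = TRUE), collapse = "")
}

# random pair of distinct "synonyms": a base string plus a mutated copy
random_synonym_pair <- function() {
  repeat {
    a <- random_word()
    b <- a
    for (k in seq_len(sample(1:3, 1L))) {
      u <- strsplit(b, "")[[1L]]
      op <- sample(c("ins", "del", "sub"), 1L)
      pos <- sample(seq_len(length(u) + (op == "ins")), 1L)
      if (op == "ins") {
        u <- append(u, sample(letters[1:6], 1L), after = pos - 1L)
      } else if (op == "del" && length(u) > 1L) {
        u <- u[-pos]
      } else {
        u[pos] <- sample(setdiff(letters[1:6], u[pos]), 1L)
      }
      b <- paste0(u, collapse = "")
    }
    if (b != a) return(c(a, b))
  }
}

# small hand-built lexicon: anemia spelling pair, a shared synonym, and a
# compositional host for subconcept checks
toy_lexicon <- function() {
  lexicon(data.frame(
    cui = c("C1", "C1", "C2", "C3", "C3",
            "C10", "C11", "C11", "C12"),
    term = c("anemia", "anaemia", "atrial fibrillation", "atrial fibrillation",
             "af finding",
             "nasal", "o2", "oxygen", "oxygen administration by nasal cannula"),
    sty = c("dsyn", "dsyn", "dsyn", "lbtr", "lbtr",
            "bpoc", "phsu", "phsu", "topp"),
    stringsAsFactors = FALSE))
}

# the generalization family: anemic/glycemic/thmic -> *ias
fig_seeds <- function() {
  list(extract_edit_pattern("glycemic", "glycemias"),
       extract_edit_pattern("anemic", "anemias"),
       extract_edit_pattern("thmic", "thmias"))
}

# memoized synthetic benchmark + fitted normalizer (fitting takes a few
# seconds; several test files share it)
.fixtures <- new.env(parent = emptyenv())
synth_fixture <- function(seed = 1L) {
  key <- paste0("synth", seed)
  if (is.null(.fixtures[[key]])) {
    syn <- synth_generate(synth_config(seed = seed))
    fit <- term_normalizer(syn$lexicon, train = syn$train)
    .fixtures[[key]] <- list(syn = syn, fit = fit)
  }
  .fixtures[[key]]
}
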