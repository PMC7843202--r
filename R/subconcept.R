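# Subconcept matching: a term is decomposed into the concepts matched by
# its contiguous word subsequences (n-gram subterms); a concept whose own
# subconcept profile pairs off one-to-one with the term's is a match. This
# catches compositional variation (e.g. "nasal o2" vs "oxygen administration
# by nasal cannula") that neither exact matching nor edit patterns reach,
# because synonymy enters through the shared CUIs of the subterms.

ngram_spans <- function(ntok, max_len = Inf) {
  if (ntok == 0L) return(matrix(integer(0), ncol = 2L))
  out <- list()
  for (i in seq_len(ntok)) for (j in i:min(ntok, i + max_len - 1L))
    out[[length(out) + 1L]] <- c(i, j)
  do.call(rbind, out)
}

profile_obj <- function(subterms, starts, ends, sets) {
  structure(list(subterms = subterms, starts = starts, ends = ends,
                 sets = sets),
            class = "clinnorm_profile")
}

#' @export
print.clinnorm_profile <- function(x, ...) {
  if (length(x$sets) == 0L) {
    cat("Subconcept profile: empty\n")
    return(invisible(x))
  }
  cat(sprintf("Subconcept profile: %d covered subterm(s)\n", length(x$sets)))
  for (i in seq_along(x$sets))
    cat(sprintf("  '%s' -> {%s}\n", x$subterms[i],
                paste(x$sets[[i]], collapse = ", ")))
  invisible(x)
}

#' Subconcept profile of a term
#'
#' Enumerates all contiguous token subsequences (n-grams, including single
#' words) of the term, keeps those that match a lexicon term, and records
#' each with its candidate CUI set. A matched subterm nested inside a longer
#' matched subterm is suppressed: only maximal matched subterms contribute.
#' Subterms with no lexicon match are simply overlooked.
#'
#' @param term A preprocessed term.
#' @param lex A `clinnorm_lexicon`.
#' @param max_ngram Optional cap on subterm length in tokens.
#' @param exclude_full Drop the full-span n-gram before maximal-subterm
#'   suppression (used when profiling a concept's own synonyms, each of
#'   which trivially matches itself in the lexicon).
#' @return A `clinnorm_profile`: the covered subterms, their token spans and
#'   their (non-empty) candidate CUI sets.
#' @export
term_profile <- function(term, lex, max_ngram = Inf, exclude_full = FALSE) {
  stopifnot(inherits(lex, "clinnorm_lexicon"))
  toks <- split_units(term, "word")
  spans <- ngram_spans(length(toks), max_ngram)
  if (nrow(spans) == 0L) return(profile_obj(character(0), integer(0), integer(0), list()))
  if (exclude_full) {
    full <- spans[, 1L] == 1L & spans[, 2L] == length(toks)
    spans <- spans[!full, , drop = FALSE]
    if (nrow(spans) == 0L)
      return(profile_obj(character(0), integer(0), integer(0), list()))
  }
  sub <- vapply(seq_len(nrow(spans)), function(r)
    paste(toks[spans[r, 1L]:spans[r, 2L]], collapse = " "), character(1L))
  hit <- vapply(sub, function(s) !is.null(lex$term_index[[s]]), logical(1L),
                USE.NAMES = FALSE)
  spans <- spans[hit, , drop = FALSE]; sub <- sub[hit]
  if (length(sub) == 0L) return(profile_obj(character(0), integer(0), integer(0), list()))
  maximal <- vapply(seq_along(sub), function(r) {
    !any(spans[, 1L] <= spans[r, 1L] & spans[, 2L] >= spans[r, 2L] &
           (spans[, 1L] != spans[r, 1L] | spans[, 2L] != spans[r, 2L]))
  }, logical(1L))
  spans <- spans[maximal, , drop = FALSE]; sub <- sub[maximal]
  ord <- order(spans[, 1L], spans[, 2L])
  spans <- spans[ord, , drop = FALSE]; sub <- sub[ord]
  profile_obj(sub, spans[, 1L], spans[, 2L],
              lapply(sub, function(s) lex$term_index[[s]]))
}

#' Subconcept profile of a concept
#'
#' The union, over all the concept's synonyms, of the synonyms' subconcept
#' candidate sets, with duplicate sets collapsed. For multi-word synonyms
#' the synonym's own full-span match (every lexicon synonym trivially
#' matches itself) is excluded, so the profile reflects the concept's
#' constituent subconcepts; a synonym contributing nothing otherwise (in
#' particular any single-word synonym) falls back to its full-span set.
#'
#' @param entry A concept entry (an element of `lex$concepts`).
#' @param lex A `clinnorm_lexicon`.
#' @param max_ngram Optional cap on subterm length in tokens.
#' @return A `clinnorm_profile` (spans are not meaningful across synonyms
#'   and are set to `NA`).
#' @export
concept_profile <- function(entry, lex, max_ngram = Inf) {
  subterms <- character(0); sets <- list(); seen <- character(0)
  add_set <- function(s, cuis) {
    key <- paste(cuis, collapse = "\r")
    if (key %in% seen) return(invisible())
    seen <<- c(seen, key)
    subterms <<- c(subterms, s)
    sets[[length(sets) + 1L]] <<- cuis
  }
  for (syn in entry$synonyms_pp) {
    prof <- term_profile(syn, lex, max_ngram, exclude_full = TRUE)
    if (length(prof$sets) == 0L)  # e.g. any single-word synonym
      prof <- term_profile(syn, lex, max_ngram)
    for (i in seq_along(prof$sets)) add_set(prof$subterms[i], prof$sets[[i]])
  }
  profile_obj(subterms, rep(NA_integer_, length(sets)),
              rep(NA_integer_, length(sets)), sets)
}

# perfect one-to-one pairing between two lists of CUI sets, where two sets
# pair iff they intersect (augmenting-path bipartite matching; profiles are
# tiny, so the quadratic edge construction is immaterial)
profiles_pair <- function(sets_a, sets_b) {
  na <- length(sets_a); nb <- length(sets_b)
  if (na != nb || na == 0L) return(FALSE)
  edge <- matrix(FALSE, na, nb)
  for (i in seq_len(na)) for (j in seq_len(nb))
    edge[i, j] <- length(intersect(sets_a[[i]], sets_b[[j]])) > 0L
  match_b <- rep(NA_integer_, nb)
  for (i0 in seq_len(na)) {
    visited <- rep(FALSE, nb)
    augment <- function(i) {
      for (j in which(edge[i, ])) {
        if (visited[j]) next
        visited[j] <<- TRUE
        if (is.na(match_b[j]) || augment(match_b[j])) {
          match_b[j] <<- i
          return(TRUE)
        }
      }
      FALSE
    }
    if (!augment(i0)) return(FALSE)
  }
  TRUE
}

#' Precompute concept profiles and a subconcept inverted index
#'
#' @param lex A `clinnorm_lexicon`.
#' @param max_ngram Optional cap on subterm length.
#' @return An index object used by [subconcept_match()]; building it once
#'   avoids recomputing every concept's profile per query.
#' @export
subconcept_index <- function(lex, max_ngram = Inf) {
  profiles <- lapply(lex$concepts, concept_profile, lex = lex,
                     max_ngram = max_ngram)
  by_cui <- new.env(parent = emptyenv(), hash = TRUE)
  for (cui in names(profiles)) {
    members <- unique(unlist(profiles[[cui]]$sets, use.names = FALSE))
    for (m in members) by_cui[[m]] <- c(by_cui[[m]], cui)
  }
  structure(list(profiles = profiles, by_cui = by_cui, max_ngram = max_ngram),
            class = "clinnorm_subindex")
}

#' Normalize a term by subconcept matching
#'
#' Computes the term's subconcept profile and returns every concept whose
#' own profile has the same number of subconcept sets and pairs off with the
#' term's one-to-one, where two candidate CUI sets pair when they share at
#' least one CUI. Only concepts sharing at least one subconcept CUI with the
#' term are examined.
#'
#' @param term A preprocessed term.
#' @param lex A `clinnorm_lexicon`.
#' @param index Optional precomputed [subconcept_index()].
#' @return Sorted character vector of matching CUIs (possibly empty).
#' @export
subconcept_match <- function(term, lex, index = NULL) {
  if (is.null(index)) index <- subconcept_index(lex)
  tp <- term_profile(term, lex, index$max_ngram)
  if (length(tp$sets) == 0L) return(character(0))
  members <- unique(unlist(tp$sets, use.names = FALSE))
  cand <- unique(unlist(lapply(members, function(m) index$by_cui[[m]]),
                        use.names = FALSE))
  hit <- vapply(cand, function(cui)
    profiles_pair(tp$sets, index$profiles[[cui]]$sets), logical(1L))
  sort(cand[hit])
}
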