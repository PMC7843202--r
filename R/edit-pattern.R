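# Edit patterns: anchored sequences of SAME/INSERT/DELETE/SUBSTITUTE
# operations over characters or whitespace-separated word tokens, derived
# from minimal (Levenshtein) edit alignments between synonym pairs.

op_kinds <- c("SAME", "INSERT", "DELETE", "SUBSTITUTE")

split_units <- function(x, unit) {
  if (unit == "char") strsplit(x, "", fixed = TRUE)[[1L]]
  else {
    u <- strsplit(x, " ", fixed = TRUE)[[1L]]
    u[nzchar(u)]
  }
}

join_units <- function(u, unit) {
  paste(u, collapse = if (unit == "char") "" else " ")
}

unit_encode <- function(u) {
  u <- gsub("|", "_pipe_", u, fixed = TRUE)
  gsub(" ", "_space_", u, fixed = TRUE)
}

unit_decode <- function(u) {
  u <- gsub("_space_", " ", u, fixed = TRUE)
  gsub("_pipe_", "|", u, fixed = TRUE)
}

#' Construct an edit pattern
#'
#' An edit pattern records, unit by unit, how one term is rewritten into
#' another: `SAME` units are required context, `SUBSTITUTE`/`DELETE` units
#' are consumed from the source term, `INSERT`/`SUBSTITUTE` units are
#' produced into the rewritten term. `BEGIN`/`END` anchors pin the pattern
#' to the term boundaries. A valid pattern contains at least one
#' non-`SAME` operation.
#'
#' @param kind Character vector of operation kinds (`"SAME"`, `"INSERT"`,
#'   `"DELETE"`, `"SUBSTITUTE"`), in order.
#' @param source Source unit per operation (`NA` for `INSERT`).
#' @param target Target unit per operation (`NA` for `DELETE`); equal to
#'   `source` for `SAME`.
#' @param unit `"char"` or `"word"`.
#' @param begin,end Anchor flags.
#' @param provenance Semantic-type label, `"training"`, or `NA`.
#' @param p,n Positive/negative counts from scoring (`NA` before scoring).
#' @return An object of class `edit_pattern`. Its `score` is
#'   `p / (p + n + 1)`.
#' @seealso [extract_edit_pattern()], [apply_pattern()], [render_pattern()]
#' @export
edit_pattern <- function(kind, source, target, unit = c("char", "word"),
                         begin = FALSE, end = FALSE, provenance = NA_character_,
                         p = NA_integer_, n = NA_integer_) {
  unit <- match.arg(unit)
  kind <- as.character(kind)
  stopifnot(all(kind %in% op_kinds), length(kind) >= 1L,
            length(source) == length(kind), length(target) == length(kind))
  source <- as.character(source); target <- as.character(target)
  if (!any(kind != "SAME")) stop("an edit pattern needs at least one edit operation")
  if (any(kind == "SAME" & (is.na(source) | is.na(target) | source != target)))
    stop("SAME operations must carry one unit as both source and target")
  if (any(kind == "SUBSTITUTE" & (is.na(source) | is.na(target) | source == target)))
    stop("SUBSTITUTE operations need distinct source and target units")
  if (any(kind == "INSERT" & (!is.na(source) | is.na(target))))
    stop("INSERT operations carry only a target unit")
  if (any(kind == "DELETE" & (is.na(source) | !is.na(target))))
    stop("DELETE operations carry only a source unit")
  structure(list(unit = unit,
                 begin = isTRUE(begin), end = isTRUE(end),
                 ops = data.frame(kind = kind, source = source, target = target,
                                  stringsAsFactors = FALSE),
                 provenance = as.character(provenance),
                 p = as.integer(p), n = as.integer(n),
                 score = pattern_score(p, n)),
            class = "edit_pattern")
}

#' Pattern confidence score
#'
#' `p / (p + n + 1)`: the m-estimate-style confidence of an edit pattern
#' given its positive count `p` (rewrites landing on a synonym of the same
#' concept) and negative count `n` (rewrites landing on a different
#' concept's term). Always in `[0, 1)`; the `+ 1` rewards broad patterns:
#' among zero-negative patterns, higher `p` scores higher.
#'
#' @param p,n Non-negative counts (vectorized).
#' @return Numeric score(s); `NA` when counts are `NA`.
#' @export
pattern_score <- function(p, n) {
  ifelse(is.na(p) | is.na(n), NA_real_, p / (p + n + 1))
}

#' @export
print.edit_pattern <- function(x, ...) {
  sc <- if (is.na(x$score)) "unscored" else sprintf("p=%d n=%d score=%.4f", x$p, x$n, x$score)
  prov <- if (is.na(x$provenance)) "" else paste0(" <", x$provenance, ">")
  cat(sprintf("[%s]%s %s  (%s)\n", x$unit, prov, render_pattern(x), sc))
  invisible(x)
}

#' Render an edit pattern in the standard notation
#'
#' Produces strings such as `"BEGIN SAME g INSERT a SUBSTITUTE c|s END"`.
#' Literal space and pipe characters inside units are written `"_space_"`
#' and `"_pipe_"` so the rendering stays one whitespace-separated line;
#' [parse_pattern()] is the exact inverse.
#'
#' @param P An `edit_pattern`.
#' @return A single string.
#' @export
render_pattern <- function(P) {
  stopifnot(inherits(P, "edit_pattern"))
  ops <- P$ops
  body <- vapply(seq_len(nrow(ops)), function(i) {
    k <- ops$kind[i]
    switch(k,
           SAME = paste("SAME", unit_encode(ops$source[i])),
           INSERT = paste("INSERT", unit_encode(ops$target[i])),
           DELETE = paste("DELETE", unit_encode(ops$source[i])),
           SUBSTITUTE = paste0("SUBSTITUTE ", unit_encode(ops$source[i]),
                               "|", unit_encode(ops$target[i])))
  }, character(1L))
  paste(c(if (P$begin) "BEGIN", body, if (P$end) "END"), collapse = " ")
}

#' Parse an edit pattern from its rendered notation
#'
#' @param s A string as produced by [render_pattern()].
#' @param unit `"char"` or `"word"`.
#' @param provenance,p,n Optional metadata restored onto the pattern.
#' @return An `edit_pattern`; `parse_pattern(render_pattern(P))` recovers
#'   `P` up to metadata.
#' @export
parse_pattern <- function(s, unit = c("char", "word"),
                          provenance = NA_character_,
                          p = NA_integer_, n = NA_integer_) {
  unit <- match.arg(unit)
  toks <- strsplit(trimws(s), " +")[[1L]]
  begin <- length(toks) > 0L && toks[1L] == "BEGIN"
  if (begin) toks <- toks[-1L]
  end <- length(toks) > 0L && toks[length(toks)] == "END"
  if (end) toks <- toks[-length(toks)]
  if (length(toks) %% 2L != 0L) stop("malformed pattern string: ", s)
  kind <- toks[c(TRUE, FALSE)]
  arg <- toks[c(FALSE, TRUE)]
  if (!all(kind %in% op_kinds)) stop("malformed pattern string: ", s)
  src <- tgt <- rep(NA_character_, length(kind))
  for (i in seq_along(kind)) {
    a <- arg[i]
    if (kind[i] == "SUBSTITUTE") {
      halves <- strsplit(a, "|", fixed = TRUE)[[1L]]
      if (length(halves) != 2L) stop("malformed SUBSTITUTE in pattern: ", s)
      src[i] <- unit_decode(halves[1L]); tgt[i] <- unit_decode(halves[2L])
    } else if (kind[i] == "SAME") {
      src[i] <- tgt[i] <- unit_decode(a)
    } else if (kind[i] == "DELETE") {
      src[i] <- unit_decode(a)
    } else {
      tgt[i] <- unit_decode(a)
    }
  }
  edit_pattern(kind, src, tgt, unit = unit, begin = begin, end = end,
               provenance = provenance, p = p, n = n)
}

pattern_key <- function(P) paste(P$unit, render_pattern(P))

#' Levenshtein edit distance over characters or word tokens
#'
#' Minimum number of insertions, deletions and substitutions converting one
#' term into the other, with either single characters or whitespace tokens
#' as the edited units. Vectorized over pairs.
#'
#' @param a,b Character vectors of (preprocessed) terms, recycled.
#' @param unit `"char"` or `"word"`.
#' @return Integer vector of distances.
#' @examples
#' edit_distance("glycemic", "glycemias")                    # 2
#' edit_distance("cardiac arrest", "heart arrest", "word")   # 1
#' @export
edit_distance <- function(a, b, unit = c("char", "word")) {
  unit <- match.arg(unit)
  k <- max(length(a), length(b))
  a <- rep_len(as.character(a), k); b <- rep_len(as.character(b), k)
  vapply(seq_len(k), function(i) {
    ua <- split_units(a[i], unit); ub <- split_units(b[i], unit)
    vocab <- unique(c(ua, ub))
    C_lev_dist(match(ua, vocab), match(ub, vocab))
  }, integer(1L))
}

#' All-pairs character-level edit distances
#'
#' Distance matrix between every string of `a` and every string of `b`,
#' computed in compiled code. Intended for exhaustive equivalence checks and
#' batch screening; byte-oriented (ASCII-safe).
#'
#' @param a,b Character vectors.
#' @return Integer matrix of dimension `length(a)` by `length(b)`.
#' @export
edit_distance_matrix <- function(a, b = a) {
  C_lev_dist_matrix(as.character(a), as.character(b))
}

#' Extract the canonical edit pattern between two synonyms
#'
#' Computes a minimal edit alignment of `a` into `b` and returns it as a
#' fully anchored edit pattern whose non-`SAME` operations number exactly
#' `edit_distance(a, b, unit)`. Ties among minimal alignments are broken by
#' a fixed traceback policy (diagonal over deletion over insertion), so the
#' result is deterministic; applying the returned pattern to `a` yields
#' exactly `b`.
#'
#' @param a,b Two distinct (preprocessed) terms.
#' @param unit `"char"` or `"word"`.
#' @param provenance Optional provenance label stored on the pattern.
#' @return An `edit_pattern` with `BEGIN` and `END` anchors.
#' @export
extract_edit_pattern <- function(a, b, unit = c("char", "word"),
                                 provenance = NA_character_) {
  unit <- match.arg(unit)
  ua <- split_units(a, unit); ub <- split_units(b, unit)
  if (identical(ua, ub))
    stop("cannot extract an edit pattern from identical terms")
  vocab <- unique(c(ua, ub))
  M <- C_lev_align(match(ua, vocab), match(ub, vocab))
  kind <- op_kinds[M[, "kind"] + 1L]
  src <- ifelse(is.na(M[, "source"]), NA_character_, vocab[M[, "source"]])
  tgt <- ifelse(is.na(M[, "target"]), NA_character_, vocab[M[, "target"]])
  edit_pattern(kind, src, tgt, unit = unit, begin = TRUE, end = TRUE,
               provenance = provenance)
}

pattern_source_units <- function(P) {
  P$ops$source[P$ops$kind != "INSERT"]
}

pattern_target_units <- function(P) {
  P$ops$target[P$ops$kind != "DELETE"]
}

#' Locate where an edit pattern matches a term
#'
#' A pattern matches wherever the term is consistent with the presence of
#' all its `SAME`, `SUBSTITUTE` and `DELETE` units, in order and
#' contiguously, respecting `BEGIN`/`END` anchors. A pattern with no source
#' units (insertions only) matches at insertion points.
#'
#' @param P An `edit_pattern`.
#' @param term A (preprocessed) term.
#' @return Integer vector of match start positions in units (possibly
#'   empty), with the consumed source length as attribute `"srclen"`.
#' @export
match_pattern <- function(P, term) {
  stopifnot(inherits(P, "edit_pattern"))
  tu <- split_units(term, P$unit)
  src <- pattern_source_units(P)
  ls <- length(src); lt <- length(tu)
  if (ls == 0L) {
    pos <- if (P$begin && P$end) {
      if (lt == 0L) 1L else integer(0)
    } else if (P$begin) 1L
    else if (P$end) lt + 1L
    else seq_len(lt + 1L)
  } else if (ls > lt) {
    pos <- integer(0)
  } else {
    cand <- if (P$begin) 1L else seq_len(lt - ls + 1L)
    pos <- cand[vapply(cand, function(i) all(tu[i:(i + ls - 1L)] == src),
                       logical(1L))]
    if (P$end) pos <- pos[pos + ls - 1L == lt]
    if (P$begin) pos <- pos[pos == 1L]
  }
  structure(as.integer(pos), srclen = ls)
}

#' Apply an edit pattern to a term
#'
#' Applies all the pattern's edit operations at every match location, each
#' location yielding one rewritten term.
#'
#' @param P An `edit_pattern`.
#' @param term A (preprocessed) term.
#' @return Character vector of distinct rewritten terms (empty when the
#'   pattern does not match); never contains `term` itself.
#' @examples
#' P <- parse_pattern("SAME m SAME i INSERT a SUBSTITUTE c|s END")
#' apply_pattern(P, "arrhythmic")   # "arrhythmias"
#' @export
apply_pattern <- function(P, term) {
  pos <- match_pattern(P, term)
  if (length(pos) == 0L) return(character(0))
  tu <- split_units(term, P$unit)
  tgt <- pattern_target_units(P)
  ls <- attr(pos, "srclen")
  out <- vapply(pos, function(i) {
    pre <- if (i > 1L) tu[seq_len(i - 1L)] else character(0)
    post <- if (i + ls <= length(tu)) tu[(i + ls):length(tu)] else character(0)
    join_units(c(pre, tgt, post), P$unit)
  }, character(1L))
  setdiff(unique(out), term)
}

#' Reverse an edit pattern
#'
#' Swaps insertions with deletions and flips substitution direction, keeping
#' `SAME` context and anchors, so the reverse pattern undoes the original
#' rewrite. Reversal is an involution. Counts and score are reset (the
#' reverse must be scored in its own right).
#'
#' @param P An `edit_pattern`.
#' @return The reversed `edit_pattern`.
#' @export
reverse_pattern <- function(P) {
  stopifnot(inherits(P, "edit_pattern"))
  ops <- P$ops
  kind <- ops$kind
  nk <- ifelse(kind == "INSERT", "DELETE",
               ifelse(kind == "DELETE", "INSERT", kind))
  src <- ifelse(kind == "SAME", ops$source, ops$target)
  tgt <- ifelse(kind == "SAME", ops$target, ops$source)
  edit_pattern(nk, src, tgt, unit = P$unit, begin = P$begin, end = P$end,
               provenance = P$provenance)
}

common_prefix_len <- function(a, b) {
  k <- min(length(a), length(b))
  i <- 0L
  while (i < k && a[i + 1L] == b[i + 1L]) i <- i + 1L
  i
}

edit_signature <- function(P) {
  e <- P$ops[P$ops$kind != "SAME", , drop = FALSE]
  paste(P$unit,
        paste(e$kind, unit_encode(ifelse(is.na(e$source), "", e$source)),
              unit_encode(ifelse(is.na(e$target), "", e$target)),
              sep = "\r", collapse = "\n"),
        sep = "\n")
}

# SAME-unit runs before, between and after the edit operations
pattern_segments <- function(P) {
  k <- P$ops$kind
  ei <- which(k != "SAME")
  bounds <- c(0L, ei, nrow(P$ops) + 1L)
  segs <- lapply(seq_len(length(bounds) - 1L), function(j) {
    lo <- bounds[j] + 1L; hi <- bounds[j + 1L] - 1L
    if (lo > hi) character(0) else P$ops$source[lo:hi]
  })
  list(edit_idx = ei, segs = segs)
}

#' Generalize two edit patterns
#'
#' The generalization of two patterns is their longest contiguous common
#' pattern that still includes all the edit operations: the edit-operation
#' subsequences (kinds and units) must be identical and the `SAME` context
#' between edit operations must agree; the shared context before the first
#' and after the last edit operation is trimmed to what the two patterns
#' have in common, and a `BEGIN`/`END` anchor survives only when it bounds
#' that common run in both patterns. Incompatible patterns generalize to
#' nothing.
#'
#' @param p1,p2 Two `edit_pattern`s with the same unit level.
#' @return An `edit_pattern`, or `NULL` when the patterns are incompatible.
#' @export
generalize_pattern <- function(p1, p2) {
  stopifnot(inherits(p1, "edit_pattern"), inherits(p2, "edit_pattern"))
  if (p1$unit != p2$unit) return(NULL)
  if (edit_signature(p1) != edit_signature(p2)) return(NULL)
  s1 <- pattern_segments(p1); s2 <- pattern_segments(p2)
  k <- length(s1$edit_idx)
  # interior SAME runs must agree exactly for a contiguous common pattern
  # containing every edit operation to exist
  if (k > 1L) {
    for (j in 2L:k) {
      if (!identical(s1$segs[[j]], s2$segs[[j]])) return(NULL)
    }
  }
  pre1 <- s1$segs[[1L]]; pre2 <- s2$segs[[1L]]
  post1 <- s1$segs[[k + 1L]]; post2 <- s2$segs[[k + 1L]]
  npre <- common_prefix_len(rev(pre1), rev(pre2))
  npost <- common_prefix_len(post1, post2)
  pre <- if (npre > 0L) pre1[(length(pre1) - npre + 1L):length(pre1)] else character(0)
  post <- if (npost > 0L) post1[seq_len(npost)] else character(0)
  begin <- p1$begin && p2$begin && npre == length(pre1) && npre == length(pre2)
  end <- p1$end && p2$end && npost == length(post1) && npost == length(post2)

  e <- p1$ops[p1$ops$kind != "SAME", , drop = FALSE]
  kind <- character(0); src <- character(0); tgt <- character(0)
  add_same <- function(u) {
    kind <<- c(kind, rep("SAME", length(u)))
    src <<- c(src, u); tgt <<- c(tgt, u)
  }
  add_same(pre)
  for (j in seq_len(k)) {
    kind <- c(kind, e$kind[j]); src <- c(src, e$source[j]); tgt <- c(tgt, e$target[j])
    if (j < k) add_same(s1$segs[[j + 1L]])
  }
  add_same(post)
  edit_pattern(kind, src, tgt, unit = p1$unit, begin = begin, end = end,
               provenance = p1$provenance)
}
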