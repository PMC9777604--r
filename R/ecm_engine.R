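# Eight-cysteine-motif detection and the spacing grammar that assigns
# nsLTP types. The ECM is C-Xs1-C-Xs2-CC-Xs3-CXC-Xs4-C-Xs5-C: eight
# cysteines whose five variable inter-cysteine spacings carry the type
# signal; the C3C4 pair is adjacent and C5-X-C6 has exactly one spacer.

#' Default per-spacing scan bounds
#'
#' The envelope of spacings admitted by the default grammar: a motif whose
#' spacing falls outside these bounds cannot classify to any shipped type,
#' so the scanner prunes it.
#'
#' @return A 2x5 matrix with rows `min`, `max` and columns `s1`..`s5`.
#' @export
default_bounds <- function() {
  b <- rbind(min = c(6L, 12L, 8L, 21L, 6L),
             max = c(15L, 16L, 22L, 26L, 14L))
  colnames(b) <- paste0("s", 1:5)
  b
}

#' Scan a mature sequence for eight-cysteine motifs
#'
#' Finds every occurrence of the C/C/CC/CXC/C/C cysteine arrangement whose
#' five inter-cysteine spacings fall inside `bounds`. By default the spacer
#' segments must be cysteine-free (classical nsLTPs have exactly eight
#' cysteines); `allow_c_in_spacers = TRUE` lifts that restriction for
#' exploratory scans, at a combinatorial cost.
#'
#' @param mature Mature-protein residue string.
#' @param bounds Per-spacing (min, max) matrix as from [default_bounds()].
#' @param allow_c_in_spacers Logical; permit cysteines inside spacer
#'   segments.
#' @return A list of matches ordered by C1 position (ties by C2, then C3,
#'   ...); each match is a list with `cys_positions` (eight ascending
#'   1-based indices), `spacing` (named integer vector `s1`..`s5`), `span`
#'   (positions of C1 and C8), `pre` and `post` (residue counts flanking
#'   the motif).
#' @export
scan_ecm <- function(mature, bounds = default_bounds(), allow_c_in_spacers = FALSE) {
  stopifnot(is.character(mature), length(mature) == 1L, nzchar(mature))
  n <- nchar(mature)
  cpos <- which(strsplit(mature, "")[[1]] == "C")
  if (length(cpos) < 8L) return(list())
  mk <- function(p) {
    sp <- c(p[2] - p[1] - 1L, p[3] - p[2] - 1L, p[5] - p[4] - 1L,
            p[7] - p[6] - 1L, p[8] - p[7] - 1L)
    names(sp) <- paste0("s", 1:5)
    list(cys_positions = p, spacing = sp, span = c(p[1], p[8]),
         pre = p[1] - 1L, post = n - p[8])
  }
  ok_arrangement <- function(p) {
    p[4] == p[3] + 1L && p[6] == p[5] + 2L &&
      p[2] - p[1] - 1L >= bounds["min", 1] && p[2] - p[1] - 1L <= bounds["max", 1] &&
      p[3] - p[2] - 1L >= bounds["min", 2] && p[3] - p[2] - 1L <= bounds["max", 2] &&
      p[5] - p[4] - 1L >= bounds["min", 3] && p[5] - p[4] - 1L <= bounds["max", 3] &&
      p[7] - p[6] - 1L >= bounds["min", 4] && p[7] - p[6] - 1L <= bounds["max", 4] &&
      p[8] - p[7] - 1L >= bounds["min", 5] && p[8] - p[7] - 1L <= bounds["max", 5]
  }
  if (!allow_c_in_spacers) {
    # spacers C-free => the eight cysteines are consecutive in cpos
    if (length(cpos) < 8L) return(list())
    out <- list()
    for (i in seq_len(length(cpos) - 7L)) {
      p <- cpos[i:(i + 7L)]
      if (ok_arrangement(p)) out[[length(out) + 1L]] <- mk(p)
    }
    return(out)
  }
  # exploratory mode: enumerate ascending 8-subsets of cysteine positions
  # with bound pruning at each level
  out <- list()
  lo <- bounds["min", ]; hi <- bounds["max", ]
  rec <- function(p) {
    k <- length(p)
    if (k == 8L) {
      if (ok_arrangement(p)) out[[length(out) + 1L]] <<- mk(p)
      return(invisible())
    }
    for (q in cpos[cpos > p[k]]) {
      gap <- q - p[k] - 1L
      ok <- switch(k,
                   gap >= lo[1] && gap <= hi[1],          # C1->C2
                   gap >= lo[2] && gap <= hi[2],          # C2->C3
                   gap == 0L,                             # C3->C4 adjacent
                   gap >= lo[3] && gap <= hi[3],          # C4->C5
                   gap == 1L,                             # C5->C6 (CXC)
                   gap >= lo[4] && gap <= hi[4],          # C6->C7
                   gap >= lo[5] && gap <= hi[5])          # C7->C8
      if (ok) rec(c(p, q))
    }
  }
  for (c1 in cpos) rec(c1)
  ord <- order(vapply(out, function(m) m$cys_positions[1], integer(1)),
               vapply(out, function(m) m$cys_positions[2], integer(1)),
               vapply(out, function(m) m$cys_positions[3], integer(1)),
               vapply(out, function(m) m$cys_positions[5], integer(1)),
               vapply(out, function(m) m$cys_positions[7], integer(1)),
               vapply(out, function(m) m$cys_positions[8], integer(1)))
  out[ord]
}

#' The shipped nsLTP type-classification grammar
#'
#' Allowed inter-cysteine spacing sets for the five nsLTP types observed
#' in the common bean family (I, II, IV, V, VIII). A spacing vector
#' belongs to a type iff every component lies in that type's allowed set;
#' the joint sets are pairwise disjoint ([check_disjoint()]), so
#' assignment is unambiguous. Types III, VI, VII, IX, X and XI are absent
#' from the reference family; the grammar is an ordinary list and can be
#' extended with additional types.
#'
#' @return A named list mapping type label to a list of five integer
#'   vectors (`s1`..`s5` allowed values).
#' @export
default_grammar <- function() {
  list(
    I    = list(s1 = 9L,        s2 = 13:16, s3 = c(19L, 22L),
                s4 = c(21L, 22L, 23L, 26L), s5 = c(7L, 10L, 13L, 14L)),
    II   = list(s1 = 7L,        s2 = 13L,   s3 = 8L,
                s4 = c(23L, 26L),           s5 = c(6L, 7L)),
    IV   = list(s1 = 9L,        s2 = 15L,   s3 = 9L,
                s4 = c(22L, 24L),           s5 = 7L),
    V    = list(s1 = c(14L, 15L), s2 = 14L, s3 = c(11L, 12L),
                s4 = 24L,                   s5 = 10L),
    VIII = list(s1 = 6L,        s2 = 12L,   s3 = 12L,
                s4 = 25L,                   s5 = 8L)
  )
}

#' Classify a spacing vector into an nsLTP type
#'
#' @param v Integer vector of five spacings (`s1`..`s5`).
#' @param grammar A type grammar as from [default_grammar()].
#' @return The type label, or `"unclassified"` if no type admits `v`.
#'   More than one admitting type is a grammar defect and raises an error
#'   naming the colliding types.
#' @export
classify_spacing <- function(v, grammar = default_grammar()) {
  v <- as.integer(v)
  stopifnot(length(v) == 5L, all(v >= 1L))
  hit <- vapply(grammar, function(g)
    all(vapply(1:5, function(i) v[i] %in% g[[i]], logical(1))), logical(1))
  labs <- names(grammar)[hit]
  if (length(labs) > 1L)
    stop("ambiguous spacing vector (", paste(v, collapse = ","),
         "): admitted by types ", paste(labs, collapse = ", "))
  if (length(labs) == 0L) "unclassified" else labs
}

#' Verify that a grammar's joint spacing sets are pairwise disjoint
#'
#' Exhaustively intersects the allowed sets of every pair of types. Two
#' types collide iff their allowed sets intersect in every one of the five
#' spacings (the joint allowed sets then share at least one 5-tuple).
#'
#' @param grammar A type grammar.
#' @return A list with `disjoint` (logical) and `collisions`, a data frame
#'   with one row per colliding pair giving an example shared 5-tuple.
#' @export
check_disjoint <- function(grammar) {
  labs <- names(grammar)
  coll <- list()
  if (length(labs) >= 2L) {
    for (a in seq_len(length(labs) - 1L)) for (b in (a + 1L):length(labs)) {
      inter <- lapply(1:5, function(i)
        intersect(grammar[[a]][[i]], grammar[[b]][[i]]))
      if (all(lengths(inter) > 0L)) {
        ex <- vapply(inter, function(x) min(x), integer(1))
        coll[[length(coll) + 1L]] <- data.frame(
          type_a = labs[a], type_b = labs[b],
          example = paste(ex, collapse = ","), stringsAsFactors = FALSE)
      }
    }
  }
  collisions <- if (length(coll)) do.call(rbind, coll)
  else data.frame(type_a = character(), type_b = character(),
                  example = character(), stringsAsFactors = FALSE)
  list(disjoint = nrow(collisions) == 0L, collisions = collisions)
}
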