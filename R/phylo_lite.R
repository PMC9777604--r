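# Cysteine-anchored ECM alignment, p-distances, and neighbor joining.
# The eight motif cysteines are homologous by definition, so alignment
# reduces to padding the seven variable segments (pre, s1..s5, post) to
# their per-segment maxima -- exactly reproducible, no heuristic aligner.

#' Cysteine-anchored alignment of ECM domains
#'
#' Splits each mature segment at its eight motif cysteines into the seven
#' variable segments (pre-C1, the five inter-cysteine spacers, post-C8;
#' the single CXC spacer is fixed at one residue) and right-pads every
#' segment with `-` to the per-segment maximum. The eight anchor columns
#' hold `C` in every row.
#'
#' @param domains A list; each element has `id`, `mature` (residue
#'   string) and `match` (an [scan_ecm()] match into `mature`).
#' @return A list with `ids`, `rows` (aligned strings, equal length),
#'   `anchor_cols` (the eight cysteine column indices) and `width`.
#' @export
anchor_align <- function(domains) {
  stopifnot(length(domains) >= 1L)
  segs <- lapply(domains, function(d) {
    if (is.null(d$match)) stop("domain ", d$id, " has no ECM match")
    p <- d$match$cys_positions
    n <- nchar(d$mature)
    sub <- function(a, b) if (b < a) "" else substr(d$mature, a, b)
    list(pre = sub(1L, p[1] - 1L),
         s1 = sub(p[1] + 1L, p[2] - 1L),
         s2 = sub(p[2] + 1L, p[3] - 1L),
         s3 = sub(p[4] + 1L, p[5] - 1L),
         x  = sub(p[5] + 1L, p[6] - 1L),  # the fixed CXC spacer
         s4 = sub(p[6] + 1L, p[7] - 1L),
         s5 = sub(p[7] + 1L, p[8] - 1L),
         post = sub(p[8] + 1L, n))
  })
  seg_names <- c("pre", "s1", "s2", "s3", "x", "s4", "s5", "post")
  maxlen <- vapply(seg_names, function(s)
    max(vapply(segs, function(g) nchar(g[[s]]), integer(1))), integer(1))
  pad <- function(s, w) paste0(s, strrep("-", w - nchar(s)))
  rows <- vapply(segs, function(g) {
    paste0(pad(g$pre, maxlen["pre"]),
           "C", pad(g$s1, maxlen["s1"]),
           "C", pad(g$s2, maxlen["s2"]),
           "CC", pad(g$s3, maxlen["s3"]),
           "C", pad(g$x, maxlen["x"]),
           "C", pad(g$s4, maxlen["s4"]),
           "C", pad(g$s5, maxlen["s5"]),
           "C", pad(g$post, maxlen["post"]))
  }, character(1))
  anchor_cols <- cumsum(c(maxlen["pre"] + 1L,
                          maxlen["s1"] + 1L,
                          maxlen["s2"] + 1L, 1L,
                          maxlen["s3"] + 1L,
                          maxlen["x"] + 1L,
                          maxlen["s4"] + 1L,
                          maxlen["s5"] + 1L))
  list(ids = vapply(domains, `[[`, character(1), "id"),
       rows = unname(rows), anchor_cols = unname(anchor_cols),
       width = nchar(rows[[1]]))
}

#' Pairwise p-distances over an anchored alignment
#'
#' `d(i, j)` = mismatches / number of columns where neither row carries a
#' gap. An error is raised if a pair shares no comparable column.
#'
#' @param aln An alignment from [anchor_align()].
#' @return A symmetric matrix with zero diagonal, dimnames = taxa ids.
#' @export
p_distance <- function(aln) {
  n <- length(aln$rows)
  chars <- lapply(aln$rows, function(r) strsplit(r, "")[[1]])
  d <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  if (n >= 2L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    a <- chars[[i]]; b <- chars[[j]]
    comp <- a != "-" & b != "-"
    if (!any(comp))
      stop("no comparable columns between ", aln$ids[i], " and ", aln$ids[j])
    d[i, j] <- d[j, i] <- sum(a[comp] != b[comp]) / sum(comp)
  }
  d
}

#' Neighbor-joining tree (Saitou-Nei)
#'
#' Agglomerates the pair minimizing
#' `Q(i, j) = (n - 2) d(i, j) - R_i - R_j` (R = row sums), with ties
#' broken by the smallest (i, j) index pair in the current node order.
#' Branch lengths follow the standard formulas; negative estimates are
#' clamped to zero with a warning. On additive (tree-metric) inputs the
#' generating topology and branch lengths are recovered.
#'
#' @param d Symmetric distance matrix with >= 3 taxa; dimnames give the
#'   tip labels.
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  n0 <- nrow(d)
  if (n0 < 3L) stop("neighbor joining needs at least 3 taxa, got ", n0)
  stopifnot(isSymmetric(unname(d)))
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n0))

  # node bookkeeping in ape convention: tips 1..n0, internals n0+1, ...
  active <- seq_len(n0)          # ape node ids of the live rows of d
  next_node <- 2L * n0 - 2L      # internal ids assigned downward from root? no:
  next_node <- n0 + 2L           # root will be n0+1; internals n0+2..2n0-2
  edges <- NULL
  lens <- NULL

  while (length(active) > 3L) {
    n <- nrow(d)
    R <- rowSums(d)
    q <- (n - 2) * d - outer(R, R, `+`)
    diag(q) <- Inf
    # smallest Q; ties -> smallest (i, j) index pair
    best <- which(q == min(q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]
    li <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    if (li < 0 || lj < 0) {
      warning("negative branch length clamped to 0")
      if (li < 0) { lj <- lj + li; li <- 0 }
      if (lj < 0) { li <- li + lj; lj <- 0 }
    }
    new_id <- next_node; next_node <- next_node + 1L
    edges <- rbind(edges, c(new_id, active[i]), c(new_id, active[j]))
    lens <- c(lens, li, lj)
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    active <- c(active[keep], new_id)
  }

  # final three nodes joined at the (unrooted) root with the three-point
  # formulas
  root <- n0 + 1L
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  if (any(c(la, lb, lc) < 0)) {
    warning("negative branch length clamped to 0")
    la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0)
  }
  edges <- rbind(edges, c(root, active[1]), c(root, active[2]),
                 c(root, active[3]))
  lens <- c(lens, la, lb, lc)

  phy <- list(edge = edges, edge.length = lens, tip.label = labels,
              Nnode = n0 - 2L)
  class(phy) <- "phylo"
  phy <- ape::reorder.phylo(phy, "cladewise")
  phy
}

#' Serialize a tree to a newick file
#'
#' @param tree An `ape::phylo` tree.
#' @param path Output path.
#' @param digits Significant digits for branch lengths.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path, digits = 6) {
  ape::write.tree(tree, file = path, digits = digits)
  invisible(path)
}
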