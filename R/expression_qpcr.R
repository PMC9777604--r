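# Organ expression-profile processing (heatmap-ready matrices) and Livak
# 2^-ddCt quantification with replicate statistics.

#' Average technical replicates into biological replicates
#'
#' Ct tables may carry both biological and technical replicates; technical
#' replicates are averaged into their biological replicate before any
#' statistics, so n = number of biological replicates.
#'
#' @param ct Data frame with columns `gene`, `condition`, `bio_rep`,
#'   `ct_target`, `ct_reference` (and optionally `tech_rep`).
#' @return A data frame with one row per (gene, condition, bio_rep),
#'   columns `gene`, `condition`, `replicate`, `ct_target`, `ct_reference`.
#' @export
average_technical <- function(ct) {
  stopifnot(all(c("gene", "condition", "bio_rep", "ct_target",
                  "ct_reference") %in% names(ct)))
  agg <- stats::aggregate(cbind(ct_target, ct_reference) ~ gene + condition + bio_rep,
                          data = ct, FUN = mean)
  agg <- agg[order(agg$gene, agg$condition, agg$bio_rep), ]
  data.frame(gene = agg$gene, condition = agg$condition,
             replicate = agg$bio_rep, ct_target = agg$ct_target,
             ct_reference = agg$ct_reference, stringsAsFactors = FALSE)
}

#' Relative expression by the Livak 2^-ddCt method
#'
#' Per replicate, dCt = target Ct - reference Ct; ddCt = mean treatment
#' dCt - mean control dCt; fold change = `2^-ddCt`. Replicate spread is
#' summarized by the sd of treatment dCt, propagated to fold-change error
#' bars by recomputing the fold at mean +/- sd. When both groups carry at
#' least two replicates a two-sided Welch t-test on the dCt values gives a
#' p-value against the control.
#'
#' @param treat,control Ct record data frames (columns `gene`,
#'   `ct_target`, `ct_reference`; one row per biological replicate) for
#'   the treatment and control groups of one gene.
#' @return A list with `gene`, `fold`, `ddct`, `sd_dct`, `fold_lo`,
#'   `fold_hi`, and `p_value` (NA with fewer than 2 replicates per group).
#' @export
ddct_fold <- function(treat, control) {
  g <- unique(c(treat$gene, control$gene))
  if (length(g) != 1L)
    stop("treat/control records must be one common gene, got: ",
         paste(g, collapse = ", "))
  dct_t <- treat$ct_target - treat$ct_reference
  dct_c <- control$ct_target - control$ct_reference
  ddct <- mean(dct_t) - mean(dct_c)
  fold <- 2^(-ddct)
  sd_t <- if (length(dct_t) >= 2L) stats::sd(dct_t) else 0
  p <- if (length(dct_t) >= 2L && length(dct_c) >= 2L)
    welch_test(dct_t, dct_c) else NA_real_
  list(gene = g, fold = fold, ddct = ddct, sd_dct = sd_t,
       fold_lo = 2^(-(ddct + sd_t)), fold_hi = 2^(-(ddct - sd_t)),
       p_value = p)
}

#' Two-sided Welch t-test on replicate dCt values
#'
#' @param dct_treat,dct_control Numeric vectors (>= 2 values each).
#' @return The p-value. Two groups with zero variance and equal means
#'   give p = 1.
#' @export
welch_test <- function(dct_treat, dct_control) {
  stopifnot(length(dct_treat) >= 2L, length(dct_control) >= 2L)
  if (stats::sd(dct_treat) == 0 && stats::sd(dct_control) == 0)
    return(if (mean(dct_treat) == mean(dct_control)) 1 else 0)
  stats::t.test(dct_treat, dct_control, var.equal = FALSE)$p.value
}

#' Prepare an expression matrix for heatmap display
#'
#' Applies `log2(x + pseudocount)`, optionally z-scores each row, and
#' orders rows deterministically by complete-linkage hierarchical
#' clustering on Euclidean distances. At every merge node the subtree
#' containing the smallest original row index leads, so the ordering is
#' reproducible, independent of clustering-library defaults, and reduces
#' to the input order when all rows are equidistant.
#'
#' @param m Numeric matrix, genes x samples, non-negative finite FPKM.
#' @param pseudocount Added before the log2 transform.
#' @param row_scale Z-score rows after the transform; constant rows are
#'   set to zero with a warning.
#' @return The transformed matrix with rows reordered; attribute
#'   `row_order` holds the permutation of the input rows.
#' @export
heatmap_prepare <- function(m, pseudocount = 1, row_scale = FALSE) {
  stopifnot(is.matrix(m), all(is.finite(m)), all(m >= 0))
  x <- log2(m + pseudocount)
  if (row_scale) {
    sds <- apply(x, 1, stats::sd)
    const <- sds == 0
    if (any(const)) {
      warning("constant row(s) set to zero under z-scaling: ",
              paste(rownames(x)[const], collapse = ", "))
    }
    x <- t(apply(x, 1, function(r)
      if (stats::sd(r) == 0) rep(0, length(r)) else (r - mean(r)) / stats::sd(r)))
  }
  if (nrow(x) > 2L) {
    hc <- stats::hclust(stats::dist(x), method = "complete")
    ord <- subtree_first_order(hc)
  } else ord <- seq_len(nrow(x))
  out <- x[ord, , drop = FALSE]
  attr(out, "row_order") <- ord
  out
}

# deterministic leaf order: at every merge node the subtree holding the
# smallest original index comes first
subtree_first_order <- function(hc) {
  leaves <- function(node) {
    if (node < 0) return(-node)
    kids <- hc$merge[node, ]
    a <- leaves(kids[1]); b <- leaves(kids[2])
    if (min(a) <= min(b)) c(a, b) else c(b, a)
  }
  leaves(nrow(hc$merge))
}
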