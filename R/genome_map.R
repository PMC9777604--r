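# Chromosome distribution, intron counting and tandem-duplicate cluster
# detection for family members.

#' Count introns in the coding region of a gene model
#'
#' Introns within the primary transcript's CDS: number of CDS segments
#' minus one. UTR introns are ignored.
#'
#' @param model A gene model from [read_gff3()].
#' @return Integer intron count.
#' @export
count_introns <- function(model) {
  n <- nrow(model$cds_spans)
  if (is.null(n) || n == 0L)
    stop("gene model ", model$gene_id, " has no CDS")
  n - 1L
}

#' Per-chromosome member counts
#'
#' @param rows Family table rows with a `chromosome` column.
#' @param chromosomes Optional full chromosome list, to expose
#'   zero-member chromosomes.
#' @return A named integer vector of counts.
#' @export
chromosome_distribution <- function(rows, chromosomes = NULL) {
  chrom <- if (is.null(chromosomes)) rows$chromosome
  else factor(rows$chromosome, levels = chromosomes)
  tab <- table(chrom)
  stats::setNames(as.integer(tab), names(tab))
}

#' Detect tandem-duplicate gene clusters
#'
#' Per chromosome, members are sorted by start position and consecutive
#' members are chained while the intergenic gap (`next start - previous
#' end`) stays at or below `max_gap`; chains of at least `min_size`
#' members are reported as tandem clusters. Overlapping genes (negative
#' gaps) chain. With `same_type = TRUE` a chain breaks wherever the type
#' changes.
#'
#' @param rows Family table rows with `chromosome`, `start`, `end` and
#'   (for `same_type`) `ltp_type`.
#' @param max_gap Maximum intergenic distance in bp (default 100 kb).
#' @param min_size Minimum members per reported cluster.
#' @param same_type Restrict chaining to members of one type.
#' @return A list of clusters; each has `chromosome`, `members` (gene
#'   names or ids in ascending start order), `span` (first start, last
#'   end), `size`, and `types` (member type multiset).
#' @export
find_tandem_clusters <- function(rows, max_gap = 100000L, min_size = 2L,
                                 same_type = FALSE) {
  stopifnot(is.data.frame(rows), max_gap >= 0, min_size >= 1)
  if (nrow(rows) == 0L) return(list())
  label <- if (!is.null(rows$gene_name) && !anyNA(rows$gene_name))
    rows$gene_name else rows$gene_id
  out <- list()
  for (chr in unique(rows$chromosome[chromosome_order(rows$chromosome)])) {
    r <- rows[rows$chromosome == chr, , drop = FALSE]
    lab <- label[rows$chromosome == chr]
    ord <- order(r$start, r$end)
    r <- r[ord, , drop = FALSE]; lab <- lab[ord]
    chain <- 1L
    flush <- function(idx) {
      if (length(idx) >= min_size)
        out[[length(out) + 1L]] <<- list(
          chromosome = chr, members = lab[idx],
          span = c(min(r$start[idx]), max(r$end[idx])),
          size = length(idx), types = sort(r$ltp_type[idx]))
    }
    idx <- 1L
    if (nrow(r) > 1L) for (i in 2L:nrow(r)) {
      gap <- r$start[i] - r$end[i - 1L]
      linked <- gap <= max_gap &&
        (!same_type || r$ltp_type[i] == r$ltp_type[i - 1L])
      if (linked) idx <- c(idx, i)
      else { flush(idx); idx <- i }
    }
    flush(idx)
  }
  out
}
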