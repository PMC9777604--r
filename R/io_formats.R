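# Readers/writers for FASTA, GFF3 and the packaged family table, plus the
# ECM spacing-string notation used throughout.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Read a protein FASTA file
#'
#' Reads a multi-record amino-acid FASTA into a data frame of sequence
#' records. Residues are upper-cased on read; characters outside the
#' 20-letter amino-acid alphabet are rejected unless `allow_x = TRUE`,
#' which passes `X` through (useful for draft proteomes).
#'
#' @param path Path to a FASTA file.
#' @param allow_x Logical; permit the ambiguity code `X` in sequences.
#' @return A data frame with columns `id`, `description`, `residues`,
#'   one row per record, in file order.
#' @export
read_fasta <- function(path, allow_x = FALSE) {
  stopifnot(file.exists(path))
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) {
    warning("empty FASTA file: ", path)
    return(data.frame(id = character(), description = character(),
                      residues = character(), stringsAsFactors = FALSE))
  }
  full <- names(aa)
  id <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  if (anyDuplicated(id))
    stop("duplicate FASTA ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  res <- toupper(as.character(aa))
  allowed <- if (allow_x) c(AA_ALPHABET, "X") else AA_ALPHABET
  bad <- vapply(res, function(s) {
    ch <- unique(strsplit(s, "")[[1]])
    any(!ch %in% allowed)
  }, logical(1))
  if (any(bad))
    stop("non-amino-acid characters in record(s): ",
         paste(id[bad], collapse = ", "))
  if (any(nchar(res) == 0L))
    stop("empty sequence for record(s): ", paste(id[nchar(res) == 0L], collapse = ", "))
  data.frame(id = id, description = desc, residues = unname(res),
             stringsAsFactors = FALSE)
}

#' Write protein records to FASTA
#'
#' @param records Data frame with columns `id`, `residues` and optionally
#'   `description`.
#' @param path Output path. Sequences are wrapped at 60 columns.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "residues") %in% names(records)))
  hdr <- records$id
  if (!is.null(records$description)) {
    has_desc <- !is.na(records$description) & nzchar(records$description)
    hdr[has_desc] <- paste(records$id[has_desc], records$description[has_desc])
  }
  aa <- Biostrings::AAStringSet(records$residues)
  names(aa) <- hdr
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/exon/CDS/UTR features into one gene model per
#' (gene, primary transcript). The primary transcript is the one whose id
#' ends in `.1` if present, otherwise the one with the longest total CDS,
#' ties broken by lexicographically smallest transcript id.
#'
#' @param path Path to a GFF3 file.
#' @return A list of gene models; each is a list with elements `gene_id`,
#'   `transcript_id`, `chromosome`, `strand`, `gene_span` (length-2 integer),
#'   and `exon_spans`, `cds_spans`, `utr_spans` (two-column matrices of
#'   1-based inclusive intervals, sorted by start, ascending genomic
#'   coordinates regardless of strand).
#' @export
read_gff3 <- function(path) {
  stopifnot(file.exists(path))
  g <- as.data.frame(rtracklayer::readGFF(path))
  g$Parent <- vapply(g$Parent, function(p)
    if (length(p)) as.character(p)[1] else NA_character_, character(1))
  genes <- g[g$type == "gene", , drop = FALSE]
  mrnas <- g[g$type == "mRNA", , drop = FALSE]
  feats <- g[g$type %in% c("exon", "CDS", "five_prime_UTR", "three_prime_UTR"), ,
             drop = FALSE]
  cds_orphan <- feats$type == "CDS" & !(feats$Parent %in% mrnas$ID)
  if (any(cds_orphan))
    stop("CDS feature(s) without a parent mRNA: ",
         paste(sprintf("%s:%d-%d", feats$seqid[cds_orphan],
                       feats$start[cds_orphan], feats$end[cds_orphan]),
               collapse = "; "))
  spans_of <- function(tid, type) {
    f <- feats[feats$Parent == tid & feats$type %in% type, , drop = FALSE]
    f <- f[order(f$start), , drop = FALSE]
    cbind(start = as.integer(f$start), end = as.integer(f$end))
  }
  out <- lapply(genes$ID, function(gid) {
    tx <- mrnas[mrnas$Parent == gid, , drop = FALSE]
    if (nrow(tx) == 0L) return(NULL)
    tid <- if (any(grepl("\\.1$", tx$ID))) {
      sort(tx$ID[grepl("\\.1$", tx$ID)])[1]
    } else {
      clen <- vapply(tx$ID, function(t) {
        sp <- spans_of(t, "CDS")
        if (nrow(sp)) sum(sp[, 2] - sp[, 1] + 1L) else 0L
      }, numeric(1))
      tx$ID[order(-clen, tx$ID)][1]
    }
    gi <- genes[genes$ID == gid, ]
    list(gene_id = gid, transcript_id = tid,
         chromosome = as.character(gi$seqid),
         strand = as.character(gi$strand),
         gene_span = c(as.integer(gi$start), as.integer(gi$end)),
         exon_spans = spans_of(tid, "exon"),
         cds_spans = spans_of(tid, "CDS"),
         utr_spans = spans_of(tid, c("five_prime_UTR", "three_prime_UTR")))
  })
  out[!vapply(out, is.null, logical(1))]
}

#' Write gene models to GFF3
#'
#' Serializes gene models produced by [read_gff3()] or
#' [gen_gene_models()] to a minimal GFF3 file (gene, mRNA, exon, CDS).
#'
#' @param models List of gene models.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (m in models) {
    lines <- c(lines, sprintf("%s\tpvltp\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                              m$chromosome, m$gene_span[1], m$gene_span[2],
                              m$strand, m$gene_id))
    lines <- c(lines, sprintf("%s\tpvltp\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                              m$chromosome, m$gene_span[1], m$gene_span[2],
                              m$strand, m$transcript_id, m$gene_id))
    for (i in seq_len(nrow(m$exon_spans)))
      lines <- c(lines, sprintf("%s\tpvltp\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                                m$chromosome, m$exon_spans[i, 1], m$exon_spans[i, 2],
                                m$strand, m$transcript_id))
    for (i in seq_len(nrow(m$cds_spans)))
      lines <- c(lines, sprintf("%s\tpvltp\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
                                m$chromosome, m$cds_spans[i, 1], m$cds_spans[i, 2],
                                m$strand, m$transcript_id))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Load the packaged common bean nsLTP family table
#'
#' Returns the 58-gene PvLTP characterization table shipped with the
#' package: one row per family member with gene ids, chromosome
#' coordinates, strand, CDS length, precursor/signal-peptide/mature-protein
#' lengths, the ECM spacing string, mature-protein molecular weight and
#' theoretical pI, intron count, and nsLTP type. The table is a verbatim
#' transcription of the published characterization, including its internal
#' arithmetic inconsistencies, which [check_table_arithmetic()] reports
#' rather than repairs.
#'
#' @return A 58-row data frame.
#' @export
load_family_table <- function() {
  path <- system.file("extdata", "pvltp_family_table.tsv", package = "pvltp",
                      mustWork = TRUE)
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(
                           gene_name = "character", gene_id = "character",
                           chromosome = "character", start = "integer",
                           end = "integer", strand = "character",
                           cds_length_bp = "integer", aa_total = "integer",
                           sp_len = "integer", mp_len = "integer",
                           ecm_string = "character", mw_da = "numeric",
                           pi = "numeric", intron_count = "integer",
                           ltp_type = "character"))
  if (nrow(d) != 58L)
    stop("family table fixture corrupted: expected 58 rows, got ", nrow(d))
  if (anyNA(d))
    stop("family table fixture corrupted: unparseable cells")
  d
}

#' Parse an ECM spacing string
#'
#' Converts the conventional eight-cysteine-motif notation
#' `C-Xa-C-Xb-CC-Xc-CXC-Xd-C-Xe-C` into its five inter-cysteine spacings
#' `(s1, s2, s3, s4, s5)`: the residue counts between C1-C2, C2-C3, C4-C5
#' and C6-C7, C7-C8. The C3C4 pair is adjacent and C5-X-C6 carries exactly
#' one spacer by definition, so neither appears in the vector.
#'
#' @param s An ECM string such as `"C-X9-C-X14-CC-X19-CXC-X22-C-X7-C"`.
#' @return Integer vector of length 5, named `s1`..`s5`.
#' @seealso [spacing_to_string()] for the inverse.
#' @export
parse_ecm_string <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  toks <- strsplit(s, "-", fixed = TRUE)[[1]]
  expect <- c("C", "X", "C", "X", "CC", "X", "CXC", "X", "C", "X", "C")
  if (length(toks) != 11L)
    stop("malformed ECM string '", s, "': expected 11 '-'-separated tokens, got ",
         length(toks))
  sp <- integer(5)
  k <- 0L
  for (i in seq_along(toks)) {
    if (expect[i] == "X") {
      if (!grepl("^X[0-9]+$", toks[i]))
        stop("malformed ECM string '", s, "': bad spacer token '", toks[i],
             "' at position ", i)
      v <- as.integer(sub("^X", "", toks[i]))
      if (v < 1L)
        stop("malformed ECM string '", s, "': spacer must be positive at position ", i)
      k <- k + 1L
      sp[k] <- v
    } else if (toks[i] != expect[i]) {
      stop("malformed ECM string '", s, "': expected '", expect[i],
           "' at position ", i, ", found '", toks[i], "'")
    }
  }
  stats::setNames(sp, paste0("s", 1:5))
}

#' Render a spacing vector as an ECM string
#'
#' @param v Integer vector of five positive inter-cysteine spacings.
#' @return The `C-Xa-C-Xb-CC-Xc-CXC-Xd-C-Xe-C` string.
#' @export
spacing_to_string <- function(v) {
  v <- as.integer(v)
  stopifnot(length(v) == 5L, all(v >= 1L))
  sprintf("C-X%d-C-X%d-CC-X%d-CXC-X%d-C-X%d-C", v[1], v[2], v[3], v[4], v[5])
}

#' Check the family table's internal arithmetic
#'
#' Verifies, row by row, the two bookkeeping identities the
#' characterization table should satisfy: `aa_total = cds_length_bp/3 - 1`
#' (the CDS encodes the precursor plus a stop codon) and
#' `aa_total = sp_len + mp_len`. Violations are reported, never repaired.
#'
#' @param rows A family table as returned by [load_family_table()].
#' @return A data frame of violations with columns `gene_name`, `rule`,
#'   `observed`, `expected`; zero rows if the table is consistent.
#' @export
check_table_arithmetic <- function(rows) {
  v <- list()
  bad_cds <- rows$cds_length_bp != 3L * (rows$aa_total + 1L)
  if (any(bad_cds))
    v[[length(v) + 1L]] <- data.frame(
      gene_name = rows$gene_name[bad_cds],
      rule = "cds_length_bp == 3*(aa_total + 1)",
      observed = rows$cds_length_bp[bad_cds],
      expected = 3L * (rows$aa_total[bad_cds] + 1L),
      stringsAsFactors = FALSE)
  bad_sum <- rows$sp_len + rows$mp_len != rows$aa_total
  if (any(bad_sum))
    v[[length(v) + 1L]] <- data.frame(
      gene_name = rows$gene_name[bad_sum],
      rule = "sp_len + mp_len == aa_total",
      observed = rows$sp_len[bad_sum] + rows$mp_len[bad_sum],
      expected = rows$aa_total[bad_sum],
      stringsAsFactors = FALSE)
  if (length(v)) do.call(rbind, v)
  else data.frame(gene_name = character(), rule = character(),
                  observed = integer(), expected = integer(),
                  stringsAsFactors = FALSE)
}
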