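# The end-to-end nsLTP candidate filter cascade: redundancy collapse,
# optional homology intake, ECM scan + type classification, signal-peptide
# requirement, hybrid proline-rich (HyPRP) exclusion, an
# inhibitor/storage-protein exclusion hook, and the mature-length cutoff;
# followed by family naming and summary statistics.

#' Pipeline configuration
#'
#' @param max_mature_len Mature proteins longer than this are discarded
#'   ("more than 120 residues" is strict: 120 passes, 121 fails).
#' @param hyprp_proline_fraction Proline fraction over the pre-ECM mature
#'   region at or above which a candidate is called HyPRP.
#' @param hyprp_min_region Minimum pre-ECM region length for the HyPRP
#'   rule to apply.
#' @param require_signal_peptide Reject candidates absent from the
#'   signal-peptide table.
#' @param grammar Type grammar; must pass [check_disjoint()].
#' @param bounds Per-spacing scan bounds for [scan_ecm()].
#' @param homology_evalue_cutoff E-value cutoff applied to an optional
#'   homology hit table supplied to [run_identification()].
#' @return A config list.
#' @export
pipeline_config <- function(max_mature_len = 120L,
                            hyprp_proline_fraction = 0.20,
                            hyprp_min_region = 10L,
                            require_signal_peptide = TRUE,
                            grammar = default_grammar(),
                            bounds = default_bounds(),
                            homology_evalue_cutoff = 1e-5) {
  stopifnot(max_mature_len > 0, hyprp_proline_fraction > 0,
            homology_evalue_cutoff > 0)
  chk <- check_disjoint(grammar)
  if (!chk$disjoint)
    stop("grammar has colliding types: ",
         paste(chk$collisions$type_a, chk$collisions$type_b,
               sep = "/", collapse = ", "))
  list(max_mature_len = as.integer(max_mature_len),
       hyprp_proline_fraction = hyprp_proline_fraction,
       hyprp_min_region = as.integer(hyprp_min_region),
       require_signal_peptide = require_signal_peptide,
       grammar = grammar, bounds = bounds,
       homology_evalue_cutoff = homology_evalue_cutoff)
}

#' Hybrid proline-rich protein rule
#'
#' A candidate is called HyPRP when the mature region upstream of the
#' ECM's first cysteine is at least `min_region` residues long and its
#' proline fraction reaches `threshold`. HyPRPs carry an ECM-like domain
#' fused to a proline-rich N-terminal domain and are excluded from nsLTP
#' families by convention.
#'
#' @param mature Mature residue string.
#' @param ecm_match A match from [scan_ecm()].
#' @param threshold Proline fraction cutoff.
#' @param min_region Minimum pre-ECM region length.
#' @return Logical.
#' @export
is_hyprp <- function(mature, ecm_match, threshold = 0.20, min_region = 10L) {
  c1 <- ecm_match$cys_positions[1]
  if (c1 - 1L < min_region) return(FALSE)
  pre <- substr(mature, 1L, c1 - 1L)
  ch <- strsplit(pre, "")[[1]]
  mean(ch == "P") >= threshold
}

#' Run the identification cascade over a proteome
#'
#' Collapses identical sequences (keeping the lexicographically smallest
#' id), then evaluates each protein against the fixed stage order:
#' homology intake (only when a hit table is supplied), ECM scan and type
#' classification, signal-peptide requirement, HyPRP exclusion, exclusion
#' id-list hook, and the mature-length cutoff. The ECM scan runs on the
#' cleaved mature region when the protein has a signal-peptide entry, else
#' on the full precursor. A protein is accepted when at least one scanned
#' motif classifies to a known type; the leftmost classifiable match is
#' used for reporting.
#'
#' @param proteome Data frame from [read_fasta()].
#' @param sp_table Data frame with columns `id`, `sp_len`: signal-peptide
#'   cleavage annotation (prediction is upstream of this package).
#' @param gene_models List from [read_gff3()]; required to characterize
#'   accepted candidates (coordinates, strand, CDS length, introns).
#'   Matched by transcript id, falling back to gene id.
#' @param config From [pipeline_config()].
#' @param hits Optional homology hit table with columns `id`, `evalue`;
#'   proteins with no hit at or below the cutoff are rejected at intake.
#' @param exclude_ids Optional character vector of ids to drop at the
#'   inhibitor/storage-protein exclusion hook.
#' @param prefix Family name prefix handed to [assign_names()].
#' @return A list with `rows` (the characterized, named family table, in
#'   name order) and `traces` (one row per input protein: `protein_id`,
#'   `final` = accepted/rejected/redundant, `stage`, `reason`).
#' @export
run_identification <- function(proteome, sp_table, gene_models,
                               config = pipeline_config(), hits = NULL,
                               exclude_ids = character(), prefix = "PvLTP") {
  stopifnot(is.data.frame(proteome))
  if (nrow(proteome) == 0L)
    return(list(rows = empty_family_rows(), traces = data.frame(
      protein_id = character(), final = character(), stage = character(),
      reason = character(), stringsAsFactors = FALSE)))
  stopifnot(all(sp_table$id %in% proteome$id))

  # redundancy collapse: identical residue strings -> smallest id survives
  keeper <- tapply(proteome$id, proteome$residues,
                   function(ids) sort(ids)[1])
  keep_ids <- unname(keeper[proteome$residues])
  redundant <- proteome$id != keep_ids

  sp_len_of <- stats::setNames(as.integer(sp_table$sp_len), sp_table$id)
  hit_ok <- NULL
  if (!is.null(hits))
    hit_ok <- unique(hits$id[hits$evalue <= config$homology_evalue_cutoff])

  traces <- vector("list", nrow(proteome))
  acc <- list()
  for (i in seq_len(nrow(proteome))) {
    pid <- proteome$id[i]
    if (redundant[i]) {
      traces[[i]] <- data.frame(protein_id = pid, final = "redundant",
                                stage = "redundancy",
                                reason = paste0("identical to ", keep_ids[i]),
                                stringsAsFactors = FALSE)
      next
    }
    rejected <- function(stage, reason)
      data.frame(protein_id = pid, final = "rejected", stage = stage,
                 reason = reason, stringsAsFactors = FALSE)
    if (!is.null(hit_ok) && !(pid %in% hit_ok)) {
      traces[[i]] <- rejected("homology_intake",
                              sprintf("no hit at E <= %g", config$homology_evalue_cutoff))
      next
    }
    has_sp <- pid %in% names(sp_len_of)
    mature <- if (has_sp)
      cleave_signal(proteome$residues[i], sp_len_of[[pid]])$residues
    else proteome$residues[i]
    matches <- scan_ecm(mature, config$bounds)
    types <- vapply(matches, function(m)
      classify_spacing(m$spacing, config$grammar), character(1))
    classifiable <- which(types != "unclassified")
    if (length(classifiable) == 0L) {
      traces[[i]] <- rejected("ecm_scan",
                              if (length(matches)) "no classifiable ECM"
                              else "no ECM")
      next
    }
    m <- matches[[classifiable[1]]]
    type <- types[classifiable[1]]
    if (config$require_signal_peptide && !has_sp) {
      traces[[i]] <- rejected("signal_peptide", "no signal-peptide annotation")
      next
    }
    if (is_hyprp(mature, m, config$hyprp_proline_fraction,
                 config$hyprp_min_region)) {
      traces[[i]] <- rejected("hyprp_filter", "proline-rich pre-ECM region")
      next
    }
    if (pid %in% exclude_ids) {
      traces[[i]] <- rejected("inhibitor_filter", "on exclusion list")
      next
    }
    if (nchar(mature) > config$max_mature_len) {
      traces[[i]] <- rejected("mature_length",
                              sprintf("mature length %d > %d", nchar(mature),
                                      config$max_mature_len))
      next
    }
    traces[[i]] <- data.frame(protein_id = pid, final = "accepted",
                              stage = "accepted", reason = type,
                              stringsAsFactors = FALSE)
    acc[[length(acc) + 1L]] <- list(id = pid, precursor = proteome$residues[i],
                                    mature = mature,
                                    sp_len = if (has_sp) sp_len_of[[pid]] else NA_integer_,
                                    match = m, type = type)
  }
  traces <- do.call(rbind, traces)
  if (length(acc) == 0L) return(list(rows = empty_family_rows(), traces = traces))

  # characterize accepted candidates from their gene models
  model_of <- list()
  for (gm in gene_models) {
    model_of[[gm$transcript_id]] <- gm
    if (is.null(model_of[[gm$gene_id]])) model_of[[gm$gene_id]] <- gm
  }
  missing <- vapply(acc, function(a) is.null(model_of[[a$id]]), logical(1))
  if (any(missing))
    stop("accepted protein(s) missing a gene model: ",
         paste(vapply(acc[missing], `[[`, character(1), "id"), collapse = ", "))
  rows <- do.call(rbind, lapply(acc, function(a) {
    gm <- model_of[[a$id]]
    data.frame(
      gene_name = NA_character_, gene_id = a$id,
      chromosome = gm$chromosome, start = gm$gene_span[1],
      end = gm$gene_span[2], strand = gm$strand,
      cds_length_bp = sum(gm$cds_spans[, 2] - gm$cds_spans[, 1] + 1L),
      aa_total = nchar(a$precursor), sp_len = a$sp_len,
      mp_len = nchar(a$mature),
      ecm_string = spacing_to_string(a$match$spacing),
      mw_da = molecular_weight(a$mature),
      pi = round_half_up(isoelectric_point(a$mature), 2),
      intron_count = count_introns(gm), ltp_type = a$type,
      stringsAsFactors = FALSE)
  }))
  rows <- assign_names(rows, prefix = prefix)
  list(rows = rows, traces = traces)
}

empty_family_rows <- function() {
  data.frame(gene_name = character(), gene_id = character(),
             chromosome = character(), start = integer(), end = integer(),
             strand = character(), cds_length_bp = integer(),
             aa_total = integer(), sp_len = integer(), mp_len = integer(),
             ecm_string = character(), mw_da = numeric(), pi = numeric(),
             intron_count = integer(), ltp_type = character(),
             stringsAsFactors = FALSE)
}

# natural chromosome order: by trailing number where present, else name
chromosome_order <- function(chrom) {
  num <- suppressWarnings(as.integer(sub("^[^0-9]*", "", chrom)))
  order(is.na(num), num, chrom)
}

#' Assign family names by type and chromosomal order
#'
#' Within each type, members are sorted by chromosome (natural order:
#' `Chr02` before `Chr10`) then start position and numbered from 1;
#' `gene_name` becomes `<prefix><type>.<index>`, e.g. `PvLTPI.1`. Ties on
#' (chromosome, start) break deterministically by gene id.
#'
#' @param rows Family table rows with `ltp_type`, `chromosome`, `start`.
#' @param prefix Name prefix.
#' @return `rows` re-ordered by (type, chromosome, start) with
#'   `gene_name` filled in.
#' @export
assign_names <- function(rows, prefix = "PvLTP") {
  stopifnot(is.data.frame(rows))
  if (nrow(rows) == 0L) return(rows)
  type_rank <- match(rows$ltp_type, unique(rows$ltp_type[order(rows$ltp_type)]))
  chrom_rank <- match(rows$chromosome,
                      unique(rows$chromosome[chromosome_order(rows$chromosome)]))
  ord <- order(type_rank, chrom_rank, rows$start, rows$gene_id)
  rows <- rows[ord, , drop = FALSE]
  idx <- stats::ave(seq_len(nrow(rows)), rows$ltp_type, FUN = seq_along)
  rows$gene_name <- paste0(prefix, rows$ltp_type, ".", idx)
  rownames(rows) <- NULL
  rows
}

# round half away from zero, matching table precision conventions
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Summary statistics over a family table
#'
#' Column statistics of a characterized family table: totals, counts per
#' type / chromosome / intron number, and min/mean/max of mature-protein
#' MW, pI, signal-peptide, mature-protein and CDS lengths. kDa and pI
#' figures are reported half-up to 2 decimals.
#'
#' @param rows A family table (e.g. [load_family_table()]).
#' @param chromosomes Optional full chromosome list; supplying it exposes
#'   zero-member chromosomes in the counts.
#' @return A list with `n_total`, `type_counts`, `chromosome_counts`,
#'   `intron_counts`, and `stats` (data frame with rows min/mean/max).
#' @export
summarize_family <- function(rows, chromosomes = NULL) {
  stopifnot(is.data.frame(rows))
  if (nrow(rows) == 0L) stop("empty family table")
  type_counts <- table(rows$ltp_type)
  chrom <- if (is.null(chromosomes)) rows$chromosome
  else factor(rows$chromosome, levels = chromosomes)
  chromosome_counts <- table(chrom)
  intron_counts <- table(rows$intron_count)
  col_stats <- function(x) c(min = min(x), mean = mean(x), max = max(x))
  stats <- data.frame(
    mw_da = col_stats(rows$mw_da),
    mw_kda = round_half_up(col_stats(rows$mw_da) / 1000, 2),
    pi = round_half_up(col_stats(rows$pi), 2),
    sp_len = col_stats(rows$sp_len),
    mp_len = col_stats(rows$mp_len),
    cds_length_bp = col_stats(rows$cds_length_bp))
  list(n_total = nrow(rows), type_counts = type_counts,
       chromosome_counts = chromosome_counts, intron_counts = intron_counts,
       stats = stats)
}
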