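# Seeded generators for proteomes, gene models, expression matrices and
# qPCR Ct tables with known ground truth, so every pipeline stage can be
# validated without external downloads. All generators are pure functions
# of (parameters, seed).

NON_C_RESIDUES <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "C")
HYDROPHOBIC_POOL <- c("A", "L", "V", "I", "F", "M", "W", "G", "S", "T")

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  code
}

rand_res <- function(n, pool = NON_C_RESIDUES) {
  if (n == 0L) return("")
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

build_ecm <- function(spacing) {
  paste0("C", rand_res(spacing[1]), "C", rand_res(spacing[2]),
         "CC", rand_res(spacing[3]), "C", rand_res(1), "C",
         rand_res(spacing[4]), "C", rand_res(spacing[5]), "C")
}

#' Generate one synthetic nsLTP precursor
#'
#' Builds a signal peptide (length uniform on 16-42, matching the
#' reference family's range, hydrophobic-biased composition, leading M)
#' followed by a mature region: a short pre-offset, a planted ECM with
#' spacings drawn uniformly from the type's allowed sets, and a short
#' post-offset. Spacer and offset residues are cysteine-free, so the
#' planted motif is the only one in the sequence; the mature region never
#' exceeds 120 residues.
#'
#' @param type A type label present in `grammar`.
#' @param seed Integer seed.
#' @param id Record id.
#' @param grammar Type grammar.
#' @return A list with `record` (one-row data frame: `id`, `description`,
#'   `residues`) and `truth` (`id`, `class`, `sp_len`, `spacing`).
#' @export
gen_ltp_protein <- function(type, seed, id = sprintf("SYN_%s_%d", type, seed),
                            grammar = default_grammar()) {
  stopifnot(type %in% names(grammar))
  with_seed(seed, {
    g <- grammar[[type]]
    spacing <- vapply(g, function(v) if (length(v) == 1L) v
                      else sample(v, 1L), integer(1))
    sp_len <- sample(16:42, 1L)
    sp <- paste0("M", rand_res(sp_len - 1L, HYDROPHOBIC_POOL))
    pre <- sample(2:6, 1L)
    post <- sample(0:6, 1L)
    mature <- paste0(rand_res(pre), build_ecm(spacing), rand_res(post))
    stopifnot(nchar(mature) <= 120L)
    list(record = data.frame(id = id, description = paste0("synthetic type ", type),
                             residues = paste0(sp, mature),
                             stringsAsFactors = FALSE),
         truth = list(id = id, class = type, sp_len = sp_len,
                      spacing = stats::setNames(spacing, paste0("s", 1:5))))
  })
}

#' Generate one decoy protein
#'
#' Four decoy classes mirror the cascade's rejection stages: `no_ecm`
#' (at most 7 cysteines), `no_sp` (valid planted ECM, but the record is
#' meant to be withheld from the signal-peptide table), `hyprp` (valid
#' ECM behind a >= 10-residue pre-region with >= 30 % proline) and
#' `oversize` (valid ECM, mature length 121-200).
#'
#' @param kind One of `"no_ecm"`, `"no_sp"`, `"hyprp"`, `"oversize"`.
#' @param seed Integer seed.
#' @param id Record id.
#' @param grammar Type grammar (ECM-bearing decoys plant a random type).
#' @return As [gen_ltp_protein()]; `truth$class` is the decoy kind.
#' @export
gen_decoy <- function(kind = c("no_ecm", "no_sp", "hyprp", "oversize"),
                      seed, id = sprintf("DECOY_%s_%d", kind, seed),
                      grammar = default_grammar()) {
  kind <- match.arg(kind)
  with_seed(seed, {
    sp_len <- sample(16:42, 1L)
    sp <- paste0("M", rand_res(sp_len - 1L, HYDROPHOBIC_POOL))
    type <- sample(names(grammar), 1L)
    g <- grammar[[type]]
    spacing <- vapply(g, function(v) if (length(v) == 1L) v
                      else sample(v, 1L), integer(1))
    mature <- switch(kind,
      no_ecm = {
        body <- strsplit(rand_res(sample(80:110, 1L)), "")[[1]]
        nc <- sample(0:7, 1L)
        if (nc > 0) body[sample(seq_along(body), nc)] <- "C"
        paste(body, collapse = "")
      },
      no_sp = paste0(rand_res(sample(2:6, 1L)), build_ecm(spacing),
                     rand_res(sample(0:6, 1L))),
      hyprp = {
        pre_len <- sample(10:20, 1L)
        pre <- strsplit(rand_res(pre_len), "")[[1]]
        n_p <- ceiling(0.3 * pre_len) + sample(0:2, 1L)
        pre[sample(pre_len, min(n_p, pre_len))] <- "P"
        paste0(paste(pre, collapse = ""), build_ecm(spacing),
               rand_res(sample(0:3, 1L)))
      },
      oversize = {
        core <- paste0(rand_res(2L), build_ecm(spacing))
        target <- sample(121:200, 1L)
        paste0(core, rand_res(max(target - nchar(core), 121L - nchar(core))))
      })
    if (kind == "oversize") stopifnot(nchar(mature) >= 121L)
    list(record = data.frame(id = id, description = paste0("decoy ", kind),
                             residues = paste0(sp, mature),
                             stringsAsFactors = FALSE),
         truth = list(id = id, class = kind, sp_len = sp_len,
                      spacing = if (kind == "no_ecm") NULL
                      else stats::setNames(spacing, paste0("s", 1:5))))
  })
}

#' Generate a mixed synthetic proteome with ground truth
#'
#' Plants `n_ltp` nsLTPs (types cycled over the grammar) and `n_decoy`
#' decoys (kinds cycled), shuffles record order, and assembles the
#' signal-peptide table every record except `no_sp` decoys appears in.
#'
#' @param n_ltp,n_decoy Record counts.
#' @param seed Integer seed.
#' @param grammar Type grammar.
#' @return A list with `proteome` (data frame), `sp_table` (`id`,
#'   `sp_len`) and `truth` (data frame: `id`, `class`, `is_ltp`,
#'   `sp_len`, `ecm_string`).
#' @export
gen_proteome <- function(n_ltp, n_decoy, seed, grammar = default_grammar()) {
  types <- rep(names(grammar), length.out = n_ltp)
  kinds <- rep(c("no_ecm", "no_sp", "hyprp", "oversize"), length.out = n_decoy)
  entries <- with_seed(seed, {
    sub <- sample.int(2^31 - 2L, n_ltp + n_decoy)
    c(lapply(seq_len(n_ltp), function(i)
        c(gen_ltp_protein(types[i], sub[i],
                          id = sprintf("SYNLTP%03d", i), grammar = grammar),
          list(is_ltp = TRUE))),
      lapply(seq_len(n_decoy), function(i)
        c(gen_decoy(kinds[i], sub[n_ltp + i],
                    id = sprintf("SYNDEC%03d", i), grammar = grammar),
          list(is_ltp = FALSE))))
  })
  entries <- with_seed(seed + 1L, sample(entries))
  proteome <- do.call(rbind, lapply(entries, `[[`, "record"))
  truth <- do.call(rbind, lapply(entries, function(e) data.frame(
    id = e$truth$id, class = e$truth$class, is_ltp = e$is_ltp,
    sp_len = e$truth$sp_len,
    ecm_string = if (is.null(e$truth$spacing)) NA_character_
    else spacing_to_string(e$truth$spacing), stringsAsFactors = FALSE)))
  keep_sp <- truth$class != "no_sp"
  list(proteome = proteome,
       sp_table = data.frame(id = truth$id[keep_sp],
                             sp_len = truth$sp_len[keep_sp],
                             stringsAsFactors = FALSE),
       truth = truth)
}

#' Generate gene models arranged in tandem arrays
#'
#' Places genes on chromosomes in the specified order with the specified
#' intergenic gaps; each chromosome entry gives cluster `sizes` (its
#' partition into intended tandem arrays, recorded as truth) and `gaps`
#' (length `sum(sizes) - 1`, the distances between consecutive gene
#' spans). Each gene gets 0 or 1 CDS introns at random.
#'
#' @param members Character vector of gene ids; length must equal the
#'   total gene count of `clusters_spec`.
#' @param clusters_spec A list of `list(chromosome =, sizes =, gaps =)`.
#' @param seed Integer seed.
#' @param origin Start coordinate of the first gene on each chromosome.
#' @return A list with `models` (as [read_gff3()] returns) and `truth`
#'   (data frame: `gene_id`, `chromosome`, `cluster_id` -- NA for
#'   singleton placements -- and `intron_count`).
#' @export
gen_gene_models <- function(members, clusters_spec, seed, origin = 100000L) {
  total <- sum(vapply(clusters_spec, function(cs) sum(cs$sizes), numeric(1)))
  stopifnot(length(members) == total)
  for (cs in clusters_spec) {
    stopifnot(all(cs$sizes >= 1L), length(cs$gaps) == sum(cs$sizes) - 1L)
    if (any(cs$gaps <= 0)) stop("overlapping placements: gaps must be > 0")
  }
  with_seed(seed, {
    models <- list(); truth <- list()
    k <- 0L; cluster_seq <- 0L
    for (cs in clusters_spec) {
      n <- sum(cs$sizes)
      cluster_of <- rep(seq_along(cs$sizes), cs$sizes)
      pos <- origin
      for (i in seq_len(n)) {
        k <- k + 1L
        gid <- members[k]
        introns <- sample(0:1, 1L)
        glen <- sample(350:900, 1L)
        gstart <- as.integer(pos)
        gend <- as.integer(pos + glen - 1L)
        cds <- if (introns == 0L) cbind(start = gstart, end = gend)
        else {
          cut1 <- gstart + as.integer(glen * 0.4)
          cut2 <- cut1 + sample(60:120, 1L)
          cut2 <- min(cut2, gend - 30L)
          cbind(start = c(gstart, cut2), end = c(cut1, gend))
        }
        tid <- paste0(gid, ".1")
        models[[k]] <- list(gene_id = gid, transcript_id = tid,
                            chromosome = cs$chromosome,
                            strand = sample(c("+", "-"), 1L),
                            gene_span = c(gstart, gend),
                            exon_spans = cds, cds_spans = cds,
                            utr_spans = cbind(start = integer(), end = integer()))
        in_cluster <- cs$sizes[cluster_of[i]] >= 2L
        truth[[k]] <- data.frame(
          gene_id = gid, chromosome = cs$chromosome,
          cluster_id = if (in_cluster)
            paste0(cs$chromosome, "_c", cluster_of[i]) else NA_character_,
          intron_count = introns, stringsAsFactors = FALSE)
        if (i < n) pos <- gend + cs$gaps[i] + 1L
      }
    }
    list(models = models, truth = do.call(rbind, truth))
  })
}

#' Generate a qPCR Ct table with planted fold changes
#'
#' Control replicates draw dCt ~ Normal(`base_dct`, `noise_sd`);
#' treatment replicates draw dCt = `base_dct` - log2(fold) +
#' Normal(0, `noise_sd`). The reference-gene Ct is constant, so
#' `ct_target = ct_reference + dCt`. Inverting with [ddct_fold()] at zero
#' noise recovers the planted fold exactly.
#'
#' @param genes Character vector of gene names.
#' @param folds Named numeric vector, gene -> planted fold (> 0).
#' @param noise_sd Replicate noise in cycles.
#' @param n_bio Biological replicates per group.
#' @param seed Integer seed.
#' @param base_dct Baseline dCt of the control group, cycles.
#' @param ref_ct Constant reference-gene Ct.
#' @return A list with `ct` (data frame: `gene`, `condition`
#'   (control/treated), `replicate`, `ct_target`, `ct_reference`) and
#'   `truth` (`gene`, `fold`).
#' @export
gen_qpcr <- function(genes, folds, noise_sd = 0.1, n_bio = 3L, seed = 1L,
                     base_dct = 6, ref_ct = 20) {
  stopifnot(all(genes %in% names(folds)), all(folds > 0), n_bio >= 1L)
  with_seed(seed, {
    rows <- lapply(genes, function(g) {
      dct_c <- base_dct + stats::rnorm(n_bio, 0, noise_sd)
      dct_t <- base_dct - log2(folds[[g]]) + stats::rnorm(n_bio, 0, noise_sd)
      data.frame(
        gene = g,
        condition = rep(c("control", "treated"), each = n_bio),
        replicate = rep(seq_len(n_bio), 2L),
        ct_target = ref_ct + c(dct_c, dct_t),
        ct_reference = ref_ct, stringsAsFactors = FALSE)
    })
    list(ct = do.call(rbind, rows),
         truth = data.frame(gene = genes, fold = unname(folds[genes]),
                            stringsAsFactors = FALSE))
  })
}

#' Generate an organ-structured FPKM matrix
#'
#' Each gene is assigned one of `n_programs` expression programs; a
#' program is a preferred organ in which its genes are boosted
#' `boost`-fold over a log-normal baseline. Mirrors the organ-specific
#' expression structure of real family profiles (one program per
#' organ, cycled).
#'
#' @param n_genes Number of genes.
#' @param organs Sample labels.
#' @param n_programs Number of planted programs (<= length(organs)).
#' @param boost Fold boost of a program's preferred organ.
#' @param seed Integer seed.
#' @return A list with `fpkm` (matrix genes x organs) and `truth`
#'   (`gene`, `program`, `organ`).
#' @export
gen_fpkm <- function(n_genes, organs = c("root", "stem", "leaf", "flower",
                                         "seed", "pod", "nodule"),
                     n_programs = 2L, boost = 8, seed = 1L) {
  stopifnot(n_programs >= 1L, n_programs <= length(organs))
  with_seed(seed, {
    prog <- rep(seq_len(n_programs), length.out = n_genes)
    base <- matrix(stats::rlnorm(n_genes * length(organs), meanlog = 1, sdlog = 0.4),
                   n_genes, length(organs),
                   dimnames = list(sprintf("gene%03d", seq_len(n_genes)), organs))
    for (i in seq_len(n_genes)) base[i, prog[i]] <- base[i, prog[i]] * boost
    list(fpkm = base,
         truth = data.frame(gene = rownames(base),
                            program = paste0("P", prog),
                            organ = organs[prog], stringsAsFactors = FALSE))
  })
}
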