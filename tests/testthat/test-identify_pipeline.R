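# helper: gene models for every id in a proteome, singleton placements
models_for <- function(ids, seed = 99) {
  gen_gene_models(ids, list(list(chromosome = "Chr01",
                                 sizes = rep(1L, length(ids)),
                                 gaps = rep(200000L, length(ids) - 1L))),
                  seed = seed)$models
}

test_that("the cascade accepts planted nsLTPs and names each decoy's rejection stage", {
  g <- gen_proteome(5, 4, seed = 17)
  res <- run_identification(g$proteome, g$sp_table, models_for(g$proteome$id))
  expect_equal(sum(res$traces$final == "accepted"), 5L)
  acc <- res$traces$protein_id[res$traces$final == "accepted"]
  expect_setequal(acc, g$truth$id[g$truth$is_ltp])

  stage_of <- stats::setNames(res$traces$stage, res$traces$protein_id)
  planted <- c(no_ecm = "ecm_scan", no_sp = "signal_peptide",
               hyprp = "hyprp_filter", oversize = "mature_length")
  for (k in names(planted)) {
    ids <- g$truth$id[g$truth$class == k]
    expect_equal(unname(stage_of[ids]), rep(planted[[k]], length(ids)),
                 label = k)
  }
  # accepted rows carry the planted types
  truth_type <- stats::setNames(g$truth$class, g$truth$id)
  expect_equal(res$rows$ltp_type, unname(truth_type[res$rows$gene_id]))
})

test_that("empty proteome, boundary mature length, and redundancy behave", {
  empty <- data.frame(id = character(), description = character(),
                      residues = character(), stringsAsFactors = FALSE)
  res <- run_identification(empty, data.frame(id = character(), sp_len = integer()),
                            list())
  expect_equal(nrow(res$rows), 0L)
  expect_equal(nrow(res$traces), 0L)

  # mature length exactly 120 passes, 121 fails ("more than 120" is strict)
  v <- c(9L, 14L, 19L, 22L, 7L)
  core <- planted_mature(v, pre = 2L, post = 0L)          # 82 residues
  for (target in c(120L, 121L)) {
    mature <- paste0(core, strrep("A", target - nchar(core)))
    prot <- data.frame(id = "px", description = "",
                       residues = paste0("M", strrep("L", 19), mature),
                       stringsAsFactors = FALSE)
    res <- run_identification(prot, data.frame(id = "px", sp_len = 20L),
                              models_for("px"))
    if (target == 120L) expect_equal(res$traces$final, "accepted")
    else expect_equal(res$traces$stage, "mature_length")
  }

  # identical sequences collapse to the lexicographically smallest id
  g <- gen_ltp_protein("IV", seed = 3, id = "bbb")
  prot <- rbind(g$record,
                within(g$record, id <- "aaa"),
                within(g$record, id <- "ccc"))
  sp <- data.frame(id = c("aaa", "bbb", "ccc"), sp_len = g$truth$sp_len)
  res <- run_identification(prot, sp, models_for(prot$id))
  expect_equal(res$traces$final[res$traces$protein_id == "aaa"], "accepted")
  expect_equal(res$traces$final[res$traces$protein_id %in% c("bbb", "ccc")],
               rep("redundant", 2L))
})

test_that("cascade order is stable under input permutation", {
  g <- gen_proteome(6, 6, seed = 23)
  models <- models_for(g$proteome$id)
  res1 <- run_identification(g$proteome, g$sp_table, models)
  perm <- g$proteome[rev(seq_len(nrow(g$proteome))), ]
  res2 <- run_identification(perm, g$sp_table, models)
  expect_equal(res1$rows, res2$rows)
  t1 <- res1$traces[order(res1$traces$protein_id), ]
  t2 <- res2$traces[order(res2$traces$protein_id), ]
  rownames(t1) <- rownames(t2) <- NULL
  expect_equal(t1, t2)
})

test_that("accepted proteins without a gene model raise a listing error", {
  g <- gen_ltp_protein("I", seed = 9, id = "orphan")
  expect_error(
    run_identification(g$record, data.frame(id = "orphan", sp_len = g$truth$sp_len),
                       list()),
    "missing a gene model.*orphan")
})

test_that("HyPRP rule: fraction and length guard", {
  v <- c(9L, 14L, 19L, 22L, 7L)
  mk <- function(pre) paste0(pre, substring(planted_mature(v, pre = 0L), 1))
  m1 <- mk("PPVPPVPPVX")                       # 6/10 prolines
  h1 <- scan_ecm(m1)[[1]]
  expect_true(is_hyprp(m1, h1))
  m2 <- mk("AVAVAVAVAV")                       # zero prolines
  expect_false(is_hyprp(m2, scan_ecm(m2)[[1]]))
  m3 <- mk("PPP")                              # short region, any content
  expect_false(is_hyprp(m3, scan_ecm(m3)[[1]]))
})

test_that("naming follows (type, chromosome, start) order with the family prefix", {
  rows <- data.frame(
    gene_name = NA_character_,
    gene_id = c("g2", "g1", "g3"),
    chromosome = c("Chr02", "Chr01", "Chr10"),
    start = c(50L, 100L, 10L), ltp_type = "I", stringsAsFactors = FALSE)
  named <- assign_names(rows)
  expect_equal(named$gene_name, c("PvLTPI.1", "PvLTPI.2", "PvLTPI.3"))
  expect_equal(named$gene_id, c("g1", "g2", "g3"))   # Chr01 < Chr02 < Chr10

  one <- assign_names(data.frame(gene_name = NA, gene_id = "g", chromosome = "Chr05",
                                 start = 1L, ltp_type = "V", stringsAsFactors = FALSE))
  expect_equal(one$gene_name, "PvLTPV.1")
})

test_that("re-assigning names to the shuffled family table reproduces the published names", {
  tab <- load_family_table()
  set.seed(1)
  shuffled <- tab[sample(nrow(tab)), ]
  shuffled$gene_name <- NA_character_
  named <- assign_names(shuffled)
  named <- named[order(match(named$gene_id, tab$gene_id)), ]
  expect_equal(named$gene_name, tab$gene_name)
})

test_that("synthetic full-pipeline precision and recall are exact over seeds", {
  for (seed in 1:20) {
    g <- gen_proteome(8, 6, seed = seed)
    res <- run_identification(g$proteome, g$sp_table,
                              models_for(g$proteome$id, seed = seed))
    acc <- res$traces$protein_id[res$traces$final == "accepted"]
    expect_setequal(acc, g$truth$id[g$truth$is_ltp])
  }
})

test_that("homology intake and exclusion hook reject at their stages", {
  g <- gen_proteome(3, 0, seed = 77)
  ids <- g$proteome$id
  hits <- data.frame(id = ids[1:2], evalue = c(1e-10, 1e-6))
  res <- run_identification(g$proteome, g$sp_table, models_for(ids),
                            hits = hits)
  expect_equal(res$traces$stage[res$traces$protein_id == ids[3]],
               "homology_intake")
  expect_equal(sum(res$traces$final == "accepted"), 2L)

  res2 <- run_identification(g$proteome, g$sp_table, models_for(ids),
                             exclude_ids = ids[2])
  expect_equal(res2$traces$stage[res2$traces$protein_id == ids[2]],
               "inhibitor_filter")
})
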