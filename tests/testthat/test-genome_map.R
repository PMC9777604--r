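test_that("intron counts come from CDS segmentation", {
  m2 <- list(gene_id = "g", cds_spans = cbind(start = c(1L, 201L),
                                              end = c(100L, 300L)))
  expect_equal(count_introns(m2), 1L)
  m1 <- list(gene_id = "g", cds_spans = cbind(start = 1L, end = 300L))
  expect_equal(count_introns(m1), 0L)
  m0 <- list(gene_id = "g", cds_spans = cbind(start = integer(), end = integer()))
  expect_error(count_introns(m0), "no CDS")

  gm <- gen_gene_models(paste0("g", 1:20),
                        list(list(chromosome = "Chr03", sizes = rep(1L, 20),
                                  gaps = rep(5000L, 19))), seed = 12)
  got <- vapply(gm$models, count_introns, integer(1))
  expect_equal(got, gm$truth$intron_count)
})

test_that("chromosome distribution counts members and exposes zeros on demand", {
  tab <- load_family_table()
  d <- chromosome_distribution(tab)
  expect_equal(unname(d[c("Chr08", "Chr06")]), c(20L, 17L))
  full <- chromosome_distribution(tab, chromosomes = sprintf("Chr%02d", 1:11))
  expect_equal(unname(full["Chr09"]), 0L)
  expect_equal(sum(full), 58L)
  expect_equal(length(chromosome_distribution(tab[0, ])), 0L)
})

test_that("tandem clustering chains by intergenic gap with exact boundary", {
  tab <- load_family_table()
  chr1 <- find_tandem_clusters(tab[tab$chromosome == "Chr01", ])
  expect_length(chr1, 1L)
  expect_equal(chr1[[1]]$size, 4L)
  expect_equal(chr1[[1]]$members, paste0("PvLTPI.", 1:4))

  # single gene: no cluster
  expect_length(find_tandem_clusters(tab[tab$gene_name == "PvLTPV.1", ]), 0L)

  two <- data.frame(gene_name = c("a", "b"), gene_id = c("a", "b"),
                    chromosome = "ChrX", start = c(1000L, 102000L),
                    end = c(1999L, 102999L), ltp_type = "I",
                    stringsAsFactors = FALSE)
  expect_length(find_tandem_clusters(two, max_gap = 100001L), 1L)
  expect_length(find_tandem_clusters(two, max_gap = 100000L), 0L)

  # overlapping genes (negative gap) chain
  two$start[2] <- 1500L; two$end[2] <- 2500L
  expect_length(find_tandem_clusters(two), 1L)
})

test_that("clusters are maximal, disjoint, order-invariant and monotone in max_gap", {
  tab <- load_family_table()
  for (gap in c(20000L, 100000L, 500000L)) {
    cl <- find_tandem_clusters(tab, max_gap = gap)
    members <- unlist(lapply(cl, `[[`, "members"))
    expect_equal(anyDuplicated(members), 0L)
    expect_lte(length(members), nrow(tab))
    # maximality: no adjacent family member can join a cluster
    for (c in cl) {
      r <- tab[tab$chromosome == c$chromosome, ]
      r <- r[order(r$start), ]
      i <- match(c$members, r$gene_name)
      if (min(i) > 1L)
        expect_gt(r$start[min(i)] - r$end[min(i) - 1L], gap)
      if (max(i) < nrow(r))
        expect_gt(r$start[max(i) + 1L] - r$end[max(i)], gap)
    }
  }
  # row-order invariance
  set.seed(4)
  shuf <- tab[sample(nrow(tab)), ]
  expect_equal(find_tandem_clusters(shuf), find_tandem_clusters(tab))
  # monotonicity of clustered-gene count
  gaps <- c(5000L, 20000L, 50000L, 100000L, 1000000L)
  counts <- vapply(gaps, function(g)
    sum(vapply(find_tandem_clusters(tab, max_gap = g), `[[`, integer(1), "size")),
    integer(1))
  expect_true(all(diff(counts) >= 0L))
})

test_that("planted tandem arrays are recovered and split at oversized gaps", {
  gm <- gen_gene_models(paste0("g", 1:4),
                        list(list(chromosome = "Chr01", sizes = 4L,
                                  gaps = c(8000L, 15000L, 28000L))), seed = 2)
  rows <- do.call(rbind, lapply(gm$models, function(m) data.frame(
    gene_name = m$gene_id, gene_id = m$gene_id, chromosome = m$chromosome,
    start = m$gene_span[1], end = m$gene_span[2], ltp_type = "I",
    stringsAsFactors = FALSE)))
  cl <- find_tandem_clusters(rows)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$size, 4L)

  gm2 <- gen_gene_models(paste0("g", 1:4),
                         list(list(chromosome = "Chr01", sizes = c(2L, 2L),
                                   gaps = c(8000L, 150000L, 9000L))), seed = 2)
  rows2 <- do.call(rbind, lapply(gm2$models, function(m) data.frame(
    gene_name = m$gene_id, gene_id = m$gene_id, chromosome = m$chromosome,
    start = m$gene_span[1], end = m$gene_span[2], ltp_type = "I",
    stringsAsFactors = FALSE)))
  cl2 <- find_tandem_clusters(rows2)
  expect_length(cl2, 2L)
  expect_equal(vapply(cl2, `[[`, integer(1), "size"), c(2L, 2L))
})

test_that("same-type chaining splits mixed clusters", {
  rows <- data.frame(gene_name = c("a", "b", "c"), gene_id = c("a", "b", "c"),
                     chromosome = "Chr01",
                     start = c(1000L, 3000L, 5000L),
                     end = c(1999L, 3999L, 5999L),
                     ltp_type = c("I", "II", "II"), stringsAsFactors = FALSE)
  expect_length(find_tandem_clusters(rows), 1L)
  cl <- find_tandem_clusters(rows, same_type = TRUE)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$members, c("b", "c"))
})
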