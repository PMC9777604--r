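domain_from_spacing <- function(id, spacing, pre = 2L, post = 3L, filler = "A") {
  m <- planted_mature(spacing, pre = pre, post = post, filler = filler)
  list(id = id, mature = m, match = scan_ecm(m)[[1]])
}

test_that("cysteine-anchored alignment pads segments to per-segment maxima", {
  d1 <- domain_from_spacing("a", c(9L, 14L, 19L, 22L, 7L))
  d2 <- domain_from_spacing("b", c(9L, 14L, 19L, 22L, 7L))
  aln <- anchor_align(list(d1, d2))
  expect_equal(aln$rows[1], aln$rows[2])
  expect_false(grepl("-", aln$rows[1], fixed = TRUE))

  d3 <- domain_from_spacing("c", c(7L, 14L, 19L, 22L, 7L))
  aln2 <- anchor_align(list(d1, d3))
  expect_equal(nchar(aln2$rows[1]), nchar(aln2$rows[2]))
  # shorter first spacer padded with 2 gaps
  expect_equal(lengths(regmatches(aln2$rows[2], gregexpr("-", aln2$rows[2]))), 2L)
  ch <- strsplit(aln2$rows, "")
  for (col in aln2$anchor_cols)
    expect_true(all(vapply(ch, function(x) x[col] == "C", logical(1))))

  expect_error(anchor_align(list(list(id = "x", mature = "AAA", match = NULL))),
               "no ECM match")
})

test_that("alignment width over the family's spacing vectors equals the padding arithmetic", {
  tab <- load_family_table()
  doms <- lapply(seq_len(nrow(tab)), function(i)
    domain_from_spacing(tab$gene_name[i], parse_ecm_string(tab$ecm_string[i]),
                        pre = 2L, post = 3L))
  aln <- anchor_align(doms)
  sp <- t(vapply(tab$ecm_string, function(s) unname(parse_ecm_string(s)),
                 integer(5)))
  # 8 anchor C + fixed CXC spacer + pre + five spacer maxima + post
  expect_equal(aln$width, 8L + 1L + 2L + sum(apply(sp, 2, max)) + 3L)
  expect_equal(length(unique(nchar(aln$rows))), 1L)
})

test_that("p-distance counts mismatches over gap-free columns", {
  aln <- list(ids = c("a", "b", "c"),
              rows = c("ACGT-", "ACTTA", "TTTT-"))
  d <- p_distance(aln)
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_true(isSymmetric(d))
  expect_equal(d["a", "b"], 1 / 4)       # 4 comparable, 1 mismatch
  expect_equal(d["a", "c"], 3 / 4)
  expect_equal(d["b", "c"], 2 / 4)

  same <- list(ids = c("x", "y"), rows = c("AAAA", "AAAA"))
  expect_equal(p_distance(same)["x", "y"], 0)
  opp <- list(ids = c("x", "y"), rows = c("AAAA", "TTTT"))
  expect_equal(p_distance(opp)["x", "y"], 1)
  nogap <- list(ids = c("x", "y"), rows = c("A---", "-TTT"))
  expect_error(p_distance(nogap), "no comparable")
})

test_that("three-taxon NJ uses the closed-form branch lengths", {
  dm <- matrix(c(0, 5, 9, 5, 0, 8, 9, 8, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(dm)
  expect_equal(ape::Ntip(tr), 3L)
  bl <- stats::setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(bl[c("a", "b", "c")]), c(3, 2, 6))
  expect_error(nj_tree(dm[1:2, 1:2]), "at least 3")
})

test_that("four-taxon topology matches the brute-force quartet oracle", {
  set.seed(99)
  for (i in 1:20) {
    tr <- ape::rtree(4, tip.label = c("a", "b", "c", "d"))
    dm <- stats::cophenetic(tr)[c("a", "b", "c", "d"), c("a", "b", "c", "d")]
    mine <- nj_tree(dm)
    expect_equal(quartet_split(mine, c("a", "b", "c", "d")),
                 best_quartet_split(dm))
  }
})

test_that("NJ recovers topology and branch lengths on additive matrices", {
  for (seed in 1:20) {
    set.seed(seed)
    tr <- ape::rtree(8)
    dm <- stats::cophenetic(tr)
    mine <- nj_tree(dm)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(mine)), 0,
                 ignore_attr = TRUE)
    expect_lt(max(abs(stats::cophenetic(mine)[rownames(dm), colnames(dm)] - dm)),
              1e-9)
  }
})

test_that("NJ agrees in topology with an independent implementation on noisy input", {
  set.seed(5)
  for (i in 1:10) {
    n <- 7L
    tr <- ape::rtree(n)
    dm <- stats::cophenetic(tr)
    noise <- matrix(stats::runif(n * n, 0, 0.02), n)
    noise <- (noise + t(noise)) / 2; diag(noise) <- 0
    dm <- dm + noise
    expect_equal(ape::dist.topo(ape::unroot(nj_tree(dm)),
                                ape::unroot(ape::nj(dm))), 0,
                 ignore_attr = TRUE)
  }
})

test_that("newick round-trips and is invariant to leaf permutation", {
  set.seed(3)
  tr <- ape::rtree(8)
  dm <- stats::cophenetic(tr)
  mine <- nj_tree(dm)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(mine, f)
  back <- ape::read.tree(f)
  expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(back)), 0,
               ignore_attr = TRUE)
  expect_lt(max(abs(stats::cophenetic(back)[rownames(dm), colnames(dm)] -
                    stats::cophenetic(mine)[rownames(dm), colnames(dm)])), 1e-4)

  perm <- sample(rownames(dm))
  tr2 <- nj_tree(dm[perm, perm])
  expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(tr2)), 0,
               ignore_attr = TRUE)
})
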