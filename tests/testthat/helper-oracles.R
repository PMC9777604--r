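# Independent oracles used across the suite.

# Brute-force ECM scan: enumerate every ascending 8-subset of cysteine
# positions and keep those satisfying the C/C/CC/CXC/C/C arrangement and
# spacing bounds. `c_free_spacers` additionally requires that no other
# cysteine falls strictly between consecutive chosen positions.
brute_scan <- function(mature, bounds = default_bounds(), c_free_spacers = TRUE) {
  ch <- strsplit(mature, "")[[1]]
  cpos <- which(ch == "C")
  if (length(cpos) < 8L) return(list())
  keep <- list()
  for (comb in utils::combn(cpos, 8L, simplify = FALSE)) {
    p <- comb
    if (p[4] != p[3] + 1L || p[6] != p[5] + 2L) next
    s <- c(p[2] - p[1], p[3] - p[2], p[5] - p[4], p[7] - p[6], p[8] - p[7]) - 1L
    if (any(s < bounds["min", ] | s > bounds["max", ])) next
    if (c_free_spacers &&
        any(vapply(1:7, function(i) any(cpos > p[i] & cpos < p[i + 1L]),
                   logical(1)))) next
    keep[[length(keep) + 1L]] <- p
  }
  keep
}

# Henderson-Hasselbalch net charge, written independently of the package
# implementation, evaluated on a pH grid to locate the isoelectric point.
grid_pi <- function(residues, step = 0.001) {
  pka <- c(nterm = 7.50, cterm = 3.55, D = 4.05, E = 4.45, C = 9.00,
           Y = 10.00, H = 5.98, K = 10.00, R = 12.00)
  ch <- strsplit(residues, "")[[1]]
  cnt <- table(ch)
  n_of <- function(r) if (r %in% names(cnt)) as.numeric(cnt[[r]]) else 0
  grid <- seq(0, 14, by = step)
  charge <- vapply(grid, function(ph) {
    prot <- function(pk) 1 / (1 + 10^(ph - pk))
    z <- prot(pka["nterm"]) - (1 - prot(pka["cterm"]))
    for (r in c("K", "R", "H")) z <- z + n_of(r) * prot(pka[[r]])
    for (r in c("D", "E", "C", "Y")) z <- z - n_of(r) * (1 - prot(pka[[r]]))
    unname(z)
  }, numeric(1))
  grid[which.min(abs(charge))]
}

# Closed-form four-taxon split test: for taxa in the matrix order
# (a, b, c, d), the true split is the pairing with the largest internal
# branch estimate under the four-point condition.
best_quartet_split <- function(dm) {
  ab_cd <- (dm[1, 3] + dm[2, 4] + dm[1, 4] + dm[2, 3]) / 4 - (dm[1, 2] + dm[3, 4]) / 2
  ac_bd <- (dm[1, 2] + dm[3, 4] + dm[1, 4] + dm[2, 3]) / 4 - (dm[1, 3] + dm[2, 4]) / 2
  ad_bc <- (dm[1, 2] + dm[3, 4] + dm[1, 3] + dm[2, 4]) / 4 - (dm[1, 4] + dm[2, 3]) / 2
  c("ab|cd", "ac|bd", "ad|bc")[which.max(c(ab_cd, ac_bd, ad_bc))]
}

# split of a 4-taxon unrooted ape tree, expressed against the labels
# (a, b, c, d) in matrix order
quartet_split <- function(tree, labels) {
  parts <- ape::prop.part(ape::unroot(tree))
  for (p in parts) {
    tips <- attr(parts, "labels")[p]
    if (length(tips) == 2L) {
      pair <- sort(match(tips, labels))
      return(c("ab|cd", "ac|bd", "ad|bc")[
        which(c(identical(pair, c(1L, 2L)) || identical(pair, c(3L, 4L)),
                identical(pair, c(1L, 3L)) || identical(pair, c(2L, 4L)),
                identical(pair, c(1L, 4L)) || identical(pair, c(2L, 3L))))])
    }
  }
  NA_character_
}

# assemble a mature sequence with one planted ECM from a spacing vector,
# using a fixed C-free filler residue
planted_mature <- function(spacing, pre = 2L, post = 3L, filler = "A") {
  paste0(strrep(filler, pre),
         "C", strrep(filler, spacing[1]),
         "C", strrep(filler, spacing[2]),
         "CC", strrep(filler, spacing[3]),
         "C", filler, "C", strrep(filler, spacing[4]),
         "C", strrep(filler, spacing[5]), "C",
         strrep(filler, post))
}

# random C-free residue string
rand_ncs <- function(n) paste(sample(setdiff(LETTERS[LETTERS %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]], "C"), n, replace = TRUE), collapse = "")
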