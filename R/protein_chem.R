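# Mature-protein derivation and physicochemistry: average molecular
# weight and theoretical isoelectric point (Bjellqvist pKa set, as used by
# the ExPASy Compute pI/Mw tool). Cysteines are treated as free thiols:
# the four disulfide bonds of the folded nsLTP scaffold are a documented
# simplification.

# Average (not monoisotopic) residue masses, Da.
RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)

WATER_MASS <- 18.0153

# Bjellqvist pKa values: termini plus ionizable side chains.
PKA_BJELLQVIST <- c(
  nterm = 7.50, cterm = 3.55,
  D = 4.05, E = 4.45, C = 9.00, Y = 10.00, H = 5.98, K = 10.00, R = 12.00)

#' Cleave the signal peptide from a precursor
#'
#' @param precursor A single residue string, or a one-row record from
#'   [read_fasta()].
#' @param sp_len Signal-peptide length in residues (removed from the
#'   N-terminus).
#' @return A list with `source_id` (NA for bare strings), `residues`
#'   (the mature protein), `sp_len` and `mp_len`.
#' @export
cleave_signal <- function(precursor, sp_len) {
  if (is.data.frame(precursor)) {
    stopifnot(nrow(precursor) == 1L)
    id <- precursor$id
    seq <- precursor$residues
  } else {
    stopifnot(is.character(precursor), length(precursor) == 1L)
    id <- NA_character_
    seq <- precursor
  }
  sp_len <- as.integer(sp_len)
  n <- nchar(seq)
  if (sp_len <= 0L) stop("sp_len must be >= 1, got ", sp_len)
  if (sp_len >= n)
    stop("sp_len (", sp_len, ") must leave a non-empty mature protein (precursor length ",
         n, ")")
  mature <- substr(seq, sp_len + 1L, n)
  list(source_id = id, residues = mature, sp_len = sp_len,
       mp_len = nchar(mature))
}

#' Average molecular weight of a peptide
#'
#' Sum of standard average residue masses plus one water (18.0153 Da).
#'
#' @param residues Residue string over the 20-letter alphabet.
#' @return Mass in Daltons.
#' @export
molecular_weight <- function(residues) {
  stopifnot(is.character(residues), length(residues) == 1L)
  if (!nzchar(residues)) stop("empty sequence")
  ch <- strsplit(residues, "")[[1]]
  bad <- setdiff(unique(ch), names(RESIDUE_MASS))
  if (length(bad)) stop("unknown residue(s): ", paste(bad, collapse = ", "))
  sum(RESIDUE_MASS[ch]) + WATER_MASS
}

# Net charge at a given pH under Henderson-Hasselbalch.
# counts: named counts of ionizable side chains (subset of D,E,C,Y,H,K,R).
net_charge_at <- function(ph, counts, pka = PKA_BJELLQVIST) {
  pos_frac <- function(pk) 1 / (1 + 10^(ph - pk))   # protonated fraction
  chg <- pos_frac(pka["nterm"])                      # N-terminus +
  chg <- chg - (1 - pos_frac(pka["cterm"]))          # C-terminus -
  for (r in c("K", "R", "H"))
    if (!is.na(counts[r]) && counts[r] > 0)
      chg <- chg + counts[r] * pos_frac(pka[r])
  for (r in c("D", "E", "C", "Y"))
    if (!is.na(counts[r]) && counts[r] > 0)
      chg <- chg - counts[r] * (1 - pos_frac(pka[r]))
  unname(chg)
}

#' Theoretical isoelectric point
#'
#' The pH at which the net Henderson-Hasselbalch charge of the peptide is
#' zero, using the Bjellqvist pKa set (D, E, C, Y, H, K, R side chains
#' plus both termini). Net charge is strictly decreasing in pH, so the
#' root is unique; it is found by bisection on `[0, 14]` to a pH
#' tolerance of 0.005.
#'
#' @param residues Residue string.
#' @return pI in pH units.
#' @export
isoelectric_point <- function(residues) {
  stopifnot(is.character(residues), length(residues) == 1L)
  if (!nzchar(residues)) stop("empty sequence")
  ch <- strsplit(residues, "")[[1]]
  bad <- setdiff(unique(ch), names(RESIDUE_MASS))
  if (length(bad)) stop("unknown residue(s): ", paste(bad, collapse = ", "))
  counts <- table(factor(ch, levels = c("D", "E", "C", "Y", "H", "K", "R")))
  counts <- stats::setNames(as.numeric(counts), names(counts))
  lo <- 0; hi <- 14
  while (hi - lo > 0.005) {
    mid <- (lo + hi) / 2
    if (net_charge_at(mid, counts) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
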