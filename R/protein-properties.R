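# Average (not monoisotopic) residue masses in Da, plus one water per chain.
AA_RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.0153

# Bjellqvist pKa set (the one behind the common web pI calculators).
# Side chains, C-terminus, and residue-specific N-terminal values.
PKA_SIDE <- c(C = 9.0, D = 4.05, E = 4.45, H = 5.98, K = 10.0,
              R = 12.0, Y = 10.0)
PKA_CTERM <- 3.55
PKA_NTERM <- c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82,
               V = 7.44, E = 7.7, G = 7.5)
PKA_NTERM_DEFAULT <- 7.5

#' Molecular weight of a peptide
#'
#' Sum of average residue masses plus one water, reported in kDa. `X`
#' residues are an error unless `allow_x = TRUE`, in which case they carry
#' the mean of the twenty standard residue masses.
#'
#' @param sequence Character vector of amino-acid sequences.
#' @param allow_x Treat `X` as an average-mass residue instead of erroring.
#' @return Numeric vector of masses in kDa.
#' @export
#' @examples
#' compute_molecular_weight("G") # 0.0750672 kDa
compute_molecular_weight <- function(sequence, allow_x = FALSE) {
  stopifnot(is.character(sequence))
  if (any(!nzchar(sequence))) abort("compute_molecular_weight: empty sequence")
  masses <- AA_RESIDUE_MASS
  if (allow_x) masses <- c(masses, X = mean(AA_RESIDUE_MASS))
  map_dbl(sequence, function(seq) {
    aa <- strsplit(seq, "", fixed = TRUE)[[1]]
    unknown <- setdiff(aa, names(masses))
    if (length(unknown) > 0L) {
      abort(sprintf("compute_molecular_weight: unknown residue '%s'",
                    unknown[[1]]))
    }
    (sum(masses[aa]) + WATER_MASS) / 1000
  })
}

# Henderson-Hasselbalch net charge of a peptide at a given pH.
peptide_net_charge <- function(counts, first_aa, pH) {
  pka_n <- if (first_aa %in% names(PKA_NTERM)) PKA_NTERM[[first_aa]] else
    PKA_NTERM_DEFAULT
  pos <- 1 / (1 + 10^(pH - pka_n))
  for (aa in c("K", "R", "H")) {
    if (counts[[aa]] > 0) {
      pos <- pos + counts[[aa]] / (1 + 10^(pH - PKA_SIDE[[aa]]))
    }
  }
  neg <- 1 / (1 + 10^(PKA_CTERM - pH))
  for (aa in c("D", "E", "C", "Y")) {
    if (counts[[aa]] > 0) {
      neg <- neg + counts[[aa]] / (1 + 10^(PKA_SIDE[[aa]] - pH))
    }
  }
  pos - neg
}

#' Theoretical isoelectric point
#'
#' The pH at which the Henderson-Hasselbalch net charge of the peptide
#' (termini plus D, E, C, Y, K, R, H side chains under the Bjellqvist pKa
#' set) is zero, found by bisection on \[0, 14\].
#'
#' @param sequence Character vector of amino-acid sequences. `X` residues
#'   carry no charge and are always tolerated.
#' @param tol Bisection tolerance on the net charge (default `1e-4`).
#' @return Numeric vector of pI values in pH units.
#' @export
compute_isoelectric_point <- function(sequence, tol = 1e-4) {
  stopifnot(is.character(sequence))
  if (any(!nzchar(sequence))) {
    abort("compute_isoelectric_point: empty sequence")
  }
  charged <- c("D", "E", "C", "Y", "K", "R", "H")
  map_dbl(sequence, function(seq) {
    aa <- strsplit(seq, "", fixed = TRUE)[[1]]
    counts <- setNames(vapply(charged, function(x) sum(aa == x), 0L), charged)
    lo <- 0; hi <- 14
    # net charge is strictly decreasing in pH
    repeat {
      mid <- (lo + hi) / 2
      q <- peptide_net_charge(counts, aa[[1]], mid)
      if (abs(q) < tol || (hi - lo) < 1e-9) return(mid)
      if (q > 0) lo <- mid else hi <- mid
    }
  })
}
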