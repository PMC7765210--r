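#' Average amino-acid residue masses
#'
#' Average (not monoisotopic) residue masses in Daltons, the convention used
#' by the common pI/Mw web calculators; a peptide's mass is the residue sum
#' plus one water.
#'
#' @return List with `residues` (named numeric, Da) and `water` (Da).
#' @export
amino_acid_masses <- function() {
  list(residues = c(
    A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
    E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
    L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
    S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326),
    water = 18.01524)
}

#' Ionizable-group pKa table (EMBOSS-style constants)
#'
#' Default pKa set for isoelectric-point calculation. Constant-set choice
#' shifts pI by roughly +/-0.2 pH units between common tools, so the table
#' is swappable.
#'
#' @return List with `positive` and `negative` named pKa vectors; names
#'   `Nterm`/`Cterm` denote the termini, single letters the side chains.
#' @export
pka_table <- function() {
  list(positive = c(Nterm = 7.50, H = 5.98, K = 10.00, R = 12.00),
       negative = c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.00, Y = 10.00))
}

#' Protein molecular weight
#'
#' Sum of average residue masses plus one water.
#'
#' @param protein Protein sequence (standard residues only).
#' @param masses Mass table from [amino_acid_masses()].
#' @param unit `"Da"` (default) or `"kDa"` (rounded to 2 decimals, the
#'   reporting convention).
#' @return Numeric molecular weight.
#' @export
molecular_weight <- function(protein, masses = amino_acid_masses(),
                             unit = c("Da", "kDa")) {
  unit <- match.arg(unit)
  s <- strsplit(toupper(protein[[1L]]), "")[[1L]]
  if (length(s) == 0L) stop("empty protein sequence")
  bad <- which(!(s %in% names(masses$residues)))
  if (length(bad) > 0L) {
    stop("non-standard residue '", s[bad[1L]], "' at position ", bad[1L])
  }
  mw <- sum(masses$residues[s]) + masses$water
  if (unit == "kDa") round(mw / 1000, 2L) else mw
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over ionizable groups: each basic group
#' contributes `1/(1+10^(pH-pKa))`, each acidic group `-1/(1+10^(pKa-pH))`.
#' Strictly decreasing in pH.
#'
#' @param protein Protein sequence.
#' @param pH pH value(s); vectorized.
#' @param pkas pKa table from [pka_table()].
#' @return Net charge at each pH.
#' @export
net_charge <- function(protein, pH, pkas = pka_table()) {
  s <- strsplit(toupper(protein[[1L]]), "")[[1L]]
  counts_pos <- c(Nterm = 1,
                  vapply(c("H", "K", "R"), function(a) sum(s == a), numeric(1)))
  counts_neg <- c(Cterm = 1,
                  vapply(c("D", "E", "C", "Y"), function(a) sum(s == a),
                         numeric(1)))
  names(counts_pos) <- names(pkas$positive)
  names(counts_neg) <- names(pkas$negative)
  vapply(pH, function(p) {
    sum(counts_pos / (1 + 10^(p - pkas$positive))) -
      sum(counts_neg / (1 + 10^(pkas$negative - p)))
  }, numeric(1))
}

#' Isoelectric point by bisection
#'
#' Finds the pH in `[0, 14]` where [net_charge()] crosses zero, by bisection
#' to `|charge| < tol`. The charge function is strictly decreasing in pH, so
#' the root exists and is unique.
#'
#' @param protein Protein sequence.
#' @param pkas pKa table from [pka_table()].
#' @param tol Charge tolerance (default 1e-4).
#' @param digits Decimals for the reported pI (default 2; `NA` = unrounded).
#' @return The pI in pH units.
#' @export
isoelectric_point <- function(protein, pkas = pka_table(), tol = 1e-4,
                              digits = 2L) {
  if (nchar(protein[[1L]]) == 0L) stop("empty protein sequence")
  lo <- 0; hi <- 14
  # iterate to interval convergence; this also drives |charge| below tol
  # (the charge criterion alone can stop short of the root on long chains)
  repeat {
    mid <- (lo + hi) / 2
    q <- net_charge(protein, mid, pkas)
    if ((hi - lo) < 1e-7 && abs(q) < tol) break
    if ((hi - lo) < 1e-12) break
    if (q > 0) lo <- mid else hi <- mid
  }
  if (is.na(digits)) mid else round(mid, digits)
}

#' Protein length implied by an ORF length
#'
#' An open reading frame of `orf_bp` nucleotides (including the stop codon)
#' encodes `orf_bp/3 - 1` amino acids.
#'
#' @param orf_bp ORF length(s) in bp; must be multiples of 3 and >= 6.
#' @return Protein length(s) in aa.
#' @export
orf_to_protein_length <- function(orf_bp) {
  if (any(orf_bp %% 3L != 0L)) stop("ORF length not a multiple of 3")
  if (any(orf_bp < 6L)) stop("ORF must cover at least one codon plus stop")
  as.integer(orf_bp / 3L - 1L)
}
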