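#' Scan a protein for the 5-histidine lipoxygenase signature
#'
#' Reports every 38-residue window whose histidines follow the conserved
#' spacing His-(X)4-His-(X)4-His-(X)17-His-(X)8-His, i.e. His at relative
#' positions 1, 6, 11, 29 and 38; the X positions are unconstrained.
#' Overlapping hits are all reported.
#'
#' @param protein A protein sequence (single character string, or a named
#'   length-1 vector as returned by [read_fasta()]).
#' @return data.frame with `aa_start`, `aa_end` (1-based inclusive) and
#'   `his_positions` (comma-separated absolute positions of the five
#'   histidines). Zero rows if no match.
#' @export
scan_five_his <- function(protein) {
  s <- strsplit(toupper(protein[[1L]]), "")[[1L]]
  n <- length(s)
  width <- FIVE_HIS_WIDTH
  if (n < width) {
    return(data.frame(aa_start = integer(0), aa_end = integer(0),
                      his_positions = character(0)))
  }
  offs <- FIVE_HIS_OFFSETS
  starts <- seq_len(n - width + 1L)
  is_h <- s == "H"
  ok <- rep(TRUE, length(starts))
  for (o in offs) ok <- ok & is_h[starts + o - 1L]
  starts <- starts[ok]
  data.frame(
    aa_start = starts,
    aa_end = starts + width - 1L,
    his_positions = vapply(starts, function(st)
      paste(st + offs - 1L, collapse = ","), character(1)))
}

# Relative His offsets within the 38-aa signature (1-based).
FIVE_HIS_OFFSETS <- c(1L, 6L, 11L, 29L, 38L)
#' Width of the 5-histidine signature
#'
#' The conserved His-(X)4-His-(X)4-His-(X)17-His-(X)8-His stretch spans
#' exactly 38 residues: 5 histidines + 4 + 4 + 17 + 8 spacer positions.
#' @return Integer, 38.
#' @export
five_his_width <- function() FIVE_HIS_WIDTH
FIVE_HIS_WIDTH <- 38L

#' Build a position-frequency profile motif
#'
#' A desk-scale stand-in for a profile-HMM domain model: a position-frequency
#' matrix over the 20 standard residues with uniform background. Windows are
#' scored by the summed per-column log-odds `log2(p[res]/bg[res])` and hits
#' are windows at or above `threshold`.
#'
#' @param name Motif name (e.g. `"PLAT"`).
#' @param pfm 20 x L numeric matrix (rows named by residue) with columns
#'   summing to 1, or `NULL` to build one from `consensus`.
#' @param consensus Consensus string used when `pfm` is `NULL`; each column
#'   puts `match_prob` on the consensus residue and spreads the rest
#'   uniformly.
#' @param match_prob Probability mass on the consensus residue per column.
#' @param background Named background frequencies (default uniform 1/20).
#' @param threshold Score threshold in bits; default 0.6 x the consensus
#'   (maximal) score.
#' @return Object of class `profile_motif`.
#' @export
profile_motif <- function(name, pfm = NULL, consensus = NULL,
                          match_prob = 0.7, background = NULL,
                          threshold = NULL) {
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20), AA_STANDARD)
  }
  if (is.null(pfm)) {
    stopifnot(!is.null(consensus))
    cons <- strsplit(toupper(consensus), "")[[1L]]
    stopifnot(all(cons %in% AA_STANDARD))
    L <- length(cons)
    pfm <- matrix((1 - match_prob) / 19, nrow = 20, ncol = L,
                  dimnames = list(AA_STANDARD, NULL))
    pfm[cbind(match(cons, AA_STANDARD), seq_len(L))] <- match_prob
  }
  stopifnot(nrow(pfm) == 20L, ncol(pfm) >= 8L,
            max(abs(colSums(pfm) - 1)) < 1e-8)
  lod <- log2(pfm / background[rownames(pfm)])
  consensus_score <- sum(apply(lod, 2L, max))
  if (is.null(threshold)) threshold <- 0.6 * consensus_score
  structure(list(name = name, pfm = pfm, lod = lod, background = background,
                 length = ncol(pfm), threshold = threshold,
                 consensus_score = consensus_score),
            class = "profile_motif")
}

#' @export
print.profile_motif <- function(x, ...) {
  cat(sprintf("<profile_motif> %s  length %d, threshold %.1f bits (max %.1f)\n",
              x$name, x$length, x$threshold, x$consensus_score))
  invisible(x)
}

#' Scan a protein with a profile motif
#'
#' Scores every window of the motif's length by summed log-odds and reports
#' windows meeting the motif threshold, plus the greedy best-scoring
#' non-overlapping subset.
#'
#' @param protein Protein sequence (character string).
#' @param motif A [profile_motif()].
#' @param threshold Override the motif's own threshold (bits).
#' @return data.frame with `aa_start`, `aa_end`, `score`, and
#'   `non_overlapping` (logical: member of the greedy best non-overlapping
#'   set).
#' @export
scan_profile <- function(protein, motif, threshold = motif$threshold) {
  s <- strsplit(toupper(protein[[1L]]), "")[[1L]]
  n <- length(s)
  L <- motif$length
  empty <- data.frame(aa_start = integer(0), aa_end = integer(0),
                      score = numeric(0), non_overlapping = logical(0))
  if (L > n) return(empty)
  ridx <- match(s, rownames(motif$lod))  # NA for non-standard residues
  nw <- n - L + 1L
  scores <- numeric(nw)
  # worst-column penalty for non-standard residues keeps them from matching
  colmin <- apply(motif$lod, 2L, min)
  for (j in seq_len(L)) {
    v <- motif$lod[cbind(ridx[j:(j + nw - 1L)], j)]
    v[is.na(v)] <- colmin[j]
    scores <- scores + v
  }
  keep <- which(scores >= threshold)
  if (length(keep) == 0L) return(empty)
  hits <- data.frame(aa_start = keep, aa_end = keep + L - 1L,
                     score = scores[keep])
  # greedy selection by score (ties: leftmost) for the non-overlapping set
  ord <- order(-hits$score, hits$aa_start)
  taken <- logical(nrow(hits))
  occupied <- rep(FALSE, n)
  for (i in ord) {
    span <- hits$aa_start[i]:hits$aa_end[i]
    if (!any(occupied[span])) {
      taken[i] <- TRUE
      occupied[span] <- TRUE
    }
  }
  hits$non_overlapping <- taken
  hits[order(hits$aa_start), ]
}

#' Packaged toy domain profiles for synthetic genomes
#'
#' Fixed-consensus profile motifs emulating the PLAT (100 aa) and catalytic
#' LOX (470 aa) domains at desk scale. The consensus strings are arbitrary
#' but fixed (derived from a seeded stream frozen into the package), so the
#' same profiles score generator output and scanner input. The LOX consensus
#' has unconstrained (background) columns where the subfamily archetype
#' block and the 5-histidine signature are planted, so those positions do
#' not dilute the domain score.
#'
#' @return Named list with `PLAT` and `LOX` [profile_motif()] objects, plus
#'   `lox_arch_offset` / `lox_his_offset` giving the 1-based offsets of the
#'   archetype block and 5-His signature inside the LOX domain.
#' @export
toy_domain_profiles <- function() {
  plat_cons <- fixed_consensus(100L, 11L)
  lox_cons <- fixed_consensus(470L, 23L)
  arch_off <- 101L                      # archetype block: 60 aa
  his_off <- 301L                       # 5-His signature: 38 aa
  free <- c(arch_off:(arch_off + 59L), his_off:(his_off + 37L))
  pfm <- matrix((1 - 0.7) / 19, nrow = 20, ncol = 470L,
                dimnames = list(AA_STANDARD, NULL))
  cons <- strsplit(lox_cons, "")[[1L]]
  pfm[cbind(match(cons, AA_STANDARD), seq_len(470L))] <- 0.7
  pfm[, free] <- 1 / 20                 # background columns: score 0
  lox <- profile_motif("LOX", pfm = pfm)
  list(PLAT = profile_motif("PLAT", consensus = plat_cons),
       LOX = lox, lox_arch_offset = arch_off, lox_his_offset = his_off)
}

# Deterministic pseudo-random consensus independent of the session RNG.
fixed_consensus <- function(len, salt) {
  x <- (salt + 1.0) / 7
  out <- character(len)
  for (i in seq_len(len)) {
    x <- (x * 9301 + 49297) %% 233280   # classic LCG, frozen
    out[i] <- AA_STANDARD[1L + (floor(x) %% 20L)]
  }
  paste(out, collapse = "")
}
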