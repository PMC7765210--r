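# Independent oracles and small fixture builders shared across test files.
# Oracles are deliberately naive (loops / enumeration), never reusing the
# package's own computation path.

random_protein <- function(n, letters = c("A", "R", "N", "D", "C", "Q", "E",
                                          "G", "H", "I", "L", "K", "M", "F",
                                          "P", "S", "T", "W", "Y", "V")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Brute-force sliding-window 5-His oracle: explicit per-window check.
oracle_five_his <- function(seq) {
  s <- strsplit(seq, "")[[1L]]
  hits <- integer(0)
  if (length(s) >= 38L) {
    for (st in 1:(length(s) - 37L)) {
      w <- s[st:(st + 37L)]
      if (w[1] == "H" && w[6] == "H" && w[11] == "H" &&
          w[29] == "H" && w[38] == "H") {
        hits <- c(hits, st)
      }
    }
  }
  hits
}

# Brute-force all-window profile scorer (per-window loop over columns).
oracle_profile_scores <- function(seq, motif) {
  s <- strsplit(seq, "")[[1L]]
  L <- motif$length
  if (length(s) < L) return(numeric(0))
  colmin <- apply(motif$lod, 2L, min)
  vapply(1:(length(s) - L + 1L), function(st) {
    total <- 0
    for (j in 1:L) {
      r <- s[st + j - 1L]
      total <- total + if (r %in% rownames(motif$lod)) {
        motif$lod[r, j]
      } else colmin[j]
    }
    total
  }, numeric(1))
}

# Exhaustive global affine-gap alignment score by recursive enumeration.
# Gap of length L costs open + L * ext (matching the engine's convention).
oracle_align_score <- function(a, b, mat, open, ext) {
  A <- strsplit(a, "")[[1L]]
  B <- strsplit(b, "")[[1L]]
  best <- -Inf
  rec <- function(i, j, score, last) {
    if (i > length(A) && j > length(B)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(A) && j <= length(B)) {
      rec(i + 1L, j + 1L, score + mat[A[i], B[j]], "m")
    }
    if (i <= length(A)) {  # gap in b
      pen <- ext + if (last == "gb") 0 else open
      rec(i + 1L, j, score - pen, "gb")
    }
    if (j <= length(B)) {  # gap in a
      pen <- ext + if (last == "ga") 0 else open
      rec(i, j + 1L, score - pen, "ga")
    }
    invisible()
  }
  rec(1L, 1L, 0, "start")
  best
}

# pI oracle: sign-change search on the fixed 1e-5 pH grid (binary search,
# valid because the charge function is strictly decreasing).
oracle_pi_grid <- function(protein, pkas = pka_table()) {
  lo <- 0L
  hi <- 14L * 100000L
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (net_charge(protein, mid / 100000, pkas) > 0) lo <- mid else hi <- mid
  }
  lo / 100000
}

# Random additive distance matrix from a random tree; returns both.
random_additive <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, br = function(k) stats::runif(k, 0.05, 1))
  list(tree = ape::unroot(tr), d = stats::cophenetic(tr))
}

# Small Ct table built by hand (no generator) for arithmetic checks.
manual_ct_table <- function(target_ct_control, target_ct_treated,
                            ref_ct = 20, n = 3) {
  rows <- list()
  for (cond in c("control", "treated")) {
    tct <- if (cond == "control") target_ct_control else target_ct_treated
    for (r in seq_len(n)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = paste0(cond, "_r", r),
        gene_id = c("G1", "REF"), condition = cond, timepoint = 0,
        replicate = r, ct = c(tct, ref_ct))
    }
  }
  as_ct_table(do.call(rbind, rows))
}
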