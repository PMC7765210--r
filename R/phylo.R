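#' Pairwise distances from a multiple alignment
#'
#' p-distance (mismatch proportion over pairwise-complete columns, gaps
#' excluded pairwise) or its Poisson correction `d = -ln(1 - p)`, the
#' classic multiple-hit correction for amino-acid distances.
#'
#' @param aligned Named character vector of equal-length aligned sequences.
#' @param model `"poisson"` (default) or `"p"`.
#' @return Symmetric distance matrix with attribute `model`.
#' @export
distances_from_alignment <- function(aligned, model = c("poisson", "p")) {
  model <- match.arg(model)
  n <- length(aligned)
  stopifnot(n >= 2L, !is.null(names(aligned)))
  lens <- nchar(aligned)
  if (length(unique(lens)) != 1L) stop("sequences are not aligned (unequal lengths)")
  m <- do.call(rbind, strsplit(toupper(aligned), ""))
  rownames(m) <- names(aligned)
  d <- matrix(0, n, n, dimnames = list(names(aligned), names(aligned)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(ok)) stop("no comparable columns for pair ",
                         names(aligned)[i], " / ", names(aligned)[j])
      p <- mean(m[i, ok] != m[j, ok])
      if (model == "poisson") {
        if (p >= 1) stop("p-distance of 1 for pair ", names(aligned)[i],
                         " / ", names(aligned)[j],
                         ": Poisson correction undefined")
        p <- -log(1 - p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  attr(d, "model") <- model
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining on a distance matrix. Negative branch-length
#' estimates (a known NJ artifact) are clamped to zero and counted in the
#' `clamped_branches` attribute.
#'
#' @param d Symmetric distance matrix over >= 3 taxa.
#' @return An [ape::phylo] unrooted tree; attribute `clamped_branches` gives
#'   the number of branches clamped to zero.
#' @export
neighbor_joining <- function(d) {
  if (nrow(as.matrix(d)) < 3L) stop("neighbor joining needs at least 3 taxa")
  tr <- ape::nj(as.matrix(d))
  n_neg <- sum(tr$edge.length < 0)
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "clamped_branches") <- n_neg
  tr
}

#' Bootstrap support for an NJ tree from a multiple alignment
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and reports the percentage of replicates containing each
#' internal bipartition of the full-data tree as internal node labels.
#' Fully seeded and reproducible.
#'
#' @param aligned Named character vector of equal-length aligned sequences.
#' @param model Distance model, see [distances_from_alignment()].
#' @param replicates Bootstrap replicates (conventional default 1000).
#' @param seed Integer RNG seed.
#' @return The NJ tree with `node.label` percentages; attribute
#'   `degenerate` is `TRUE` when all pairwise distances are zero (star-like
#'   data, supports uninformative).
#' @export
bootstrap_support <- function(aligned, model = "poisson",
                              replicates = 1000L, seed = 1L) {
  stopifnot(replicates >= 1L)
  d0 <- distances_from_alignment(aligned, model)
  tree <- neighbor_joining(d0)
  m <- do.call(rbind, strsplit(toupper(aligned), ""))
  rownames(m) <- names(aligned)
  L <- ncol(m)
  reps <- vector("list", replicates)
  old <- .Random.seed_safe()
  set.seed(seed)
  for (r in seq_len(replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    mm <- m[, cols, drop = FALSE]
    al <- apply(mm, 1L, paste, collapse = "")
    dr <- distances_from_alignment(al, model)
    reps[[r]] <- neighbor_joining(dr)
  }
  .Random.seed_restore(old)
  counts <- ape::prop.clades(tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  tree$node.label <- round(100 * counts / replicates, 1L)
  attr(tree, "degenerate") <- all(d0 == 0)
  tree
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Center-star progressive multiple alignment
#'
#' Deterministic multiple alignment built from pairwise global alignments:
#' the center sequence (highest summed pairwise identity; ties to the first
#' id) is aligned pairwise against every other sequence with the same
#' [global_align()] engine, and the pairwise gap patterns are merged into
#' common coordinates ("once a gap, always a gap" on the center). De-gapping
#' any output row restores the corresponding input.
#'
#' @param seqs Named character vector (>= 2 sequences, one alphabet).
#' @param params [alignment_params()].
#' @return Named character vector of equal-length aligned sequences, same
#'   order as the input; attribute `center` names the center sequence.
#' @export
align_progressive <- function(seqs, params = alignment_params("protein")) {
  n <- length(seqs)
  stopifnot(n >= 2L, !is.null(names(seqs)))
  if (length(unique(seqs)) == 1L) {
    out <- seqs
    attr(out, "center") <- names(seqs)[1L]
    return(out)
  }
  pairsums <- numeric(n)
  als <- matrix(list(), n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      al <- global_align(seqs[[i]], seqs[[j]], params)
      als[[i, j]] <- al
      pairsums[i] <- pairsums[i] + al$identity
      pairsums[j] <- pairsums[j] + al$identity
    }
  }
  c_idx <- which.max(pairsums)
  center <- seqs[[c_idx]]
  m <- nchar(center)
  others <- setdiff(seq_len(n), c_idx)
  # per-alignment decomposition against center slots 0..m
  decomp <- list()
  master_gaps <- integer(m + 1L)
  for (k in others) {
    al <- if (k > c_idx) als[[c_idx, k]] else als[[k, c_idx]]
    ca <- strsplit(if (k > c_idx) al$aligned["sa"] else al$aligned["sb"], "")[[1L]]
    oa <- strsplit(if (k > c_idx) al$aligned["sb"] else al$aligned["sa"], "")[[1L]]
    ins <- vector("list", m + 1L)   # residues of other inside center gaps
    match_char <- character(m)      # other char aligned to center residue i
    ci <- 0L
    for (col in seq_along(ca)) {
      if (ca[col] == "-") {
        ins[[ci + 1L]] <- c(ins[[ci + 1L]], oa[col])
      } else {
        ci <- ci + 1L
        match_char[ci] <- oa[col]
      }
    }
    gl <- vapply(ins, length, integer(1))
    master_gaps <- pmax(master_gaps, gl)
    decomp[[as.character(k)]] <- list(ins = ins, match_char = match_char)
  }
  build_row <- function(ins, match_char) {
    out <- character(0)
    for (i in 0:m) {
      run <- if (i == 0L) character(0) else match_char[i]
      gap_run <- c(ins[[i + 1L]],
                   rep("-", master_gaps[i + 1L] - length(ins[[i + 1L]])))
      out <- c(out, run, gap_run)
    }
    paste(out, collapse = "")
  }
  center_chars <- strsplit(center, "")[[1L]]
  rows <- stats::setNames(vector("character", n), names(seqs))
  rows[c_idx] <- build_row(rep(list(character(0)), m + 1L), center_chars)
  for (k in others) {
    dk <- decomp[[as.character(k)]]
    rows[k] <- build_row(dk$ins, dk$match_char)
  }
  attr(rows, "center") <- names(seqs)[c_idx]
  rows
}
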