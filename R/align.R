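#' Global alignment parameters
#'
#' Defaults mirror the common EMBOSS-style settings: BLOSUM62 with gap open
#' 12 / extend 2 for proteins; match +5 / mismatch -4 with gap open 16 /
#' extend 4 for nucleotides. A gap of length L costs `open + L * extend`.
#'
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @param matrix Substitution matrix (residues x residues). Default BLOSUM62
#'   or the +5/-4 nucleotide matrix.
#' @param gap_open,gap_extend Non-negative gap penalties.
#' @return Object of class `alignment_params`.
#' @export
alignment_params <- function(alphabet = c("protein", "nucleotide"),
                             matrix = NULL, gap_open = NULL,
                             gap_extend = NULL) {
  alphabet <- match.arg(alphabet)
  if (is.null(matrix)) {
    matrix <- if (alphabet == "protein") {
      blosum62_matrix()
    } else {
      m <- matrix(-4, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                            c("A", "C", "G", "T")))
      diag(m) <- 5
      m
    }
  }
  if (is.null(gap_open)) gap_open <- if (alphabet == "protein") 12 else 16
  if (is.null(gap_extend)) gap_extend <- if (alphabet == "protein") 2 else 4
  stopifnot(gap_open >= 0, gap_extend >= 0)
  structure(list(alphabet = alphabet, matrix = matrix,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "alignment_params")
}

blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Needleman-Wunsch global alignment with affine gaps
#'
#' Optimal global alignment (via [Biostrings::pairwiseAlignment()]) with
#' percent identity and percent similarity over the full alignment length.
#' Identity counts identical aligned columns; similarity counts columns with
#' a positive substitution score. Ambiguity codes never count as identical
#' or similar. Gap columns count in the denominator only.
#'
#' @param a,b Sequences (character strings) over the same alphabet.
#' @param params [alignment_params()].
#' @return List with `identity` and `similarity` (percent, 2 decimals),
#'   `length` (alignment columns), `score`, and the two `aligned` strings.
#' @export
global_align <- function(a, b, params = alignment_params("protein")) {
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  allowed <- if (params$alphabet == "nucleotide") {
    c("A", "C", "G", "T", "U", "N")
  } else {
    c(rownames(params$matrix), "X", "B", "Z", "U")
  }
  fits <- function(x) all(strsplit(x, "")[[1L]] %in% allowed)
  ok_a <- fits(a[[1L]]); ok_b <- fits(b[[1L]])
  if (xor(ok_a, ok_b)) stop("cannot align sequences from mixed alphabets")
  if (!ok_a) {
    stop("sequences contain characters outside the ", params$alphabet,
         " alphabet")
  }
  pa <- Biostrings::pairwiseAlignment(
    a[[1L]], b[[1L]], type = "global",
    substitutionMatrix = params$matrix,
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  sa <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  sb <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  len <- length(sa)
  known <- rownames(params$matrix)
  both <- sa %in% known & sb %in% known
  ident <- sum(both & sa == sb)
  simil <- sum(params$matrix[cbind(
    match(sa[both], known), match(sb[both], known))] > 0)
  list(identity = round(100 * ident / len, 2L),
       similarity = round(100 * simil / len, 2L),
       length = len, score = Biostrings::score(pa),
       aligned = c(sa = paste(sa, collapse = ""),
                   sb = paste(sb, collapse = "")))
}

#' Pairwise identity/similarity matrices for a sequence set
#'
#' Computes [global_align()] for every unordered pair. Matrices are
#' symmetric with a 100 diagonal.
#'
#' @param seqs Named character vector (>= 2 sequences).
#' @param params [alignment_params()].
#' @return List of class `identity_matrix` with `identity`, `similarity`
#'   and `length` matrices.
#' @export
identity_matrix <- function(seqs, params = alignment_params("protein")) {
  n <- length(seqs)
  stopifnot(n >= 2L, !is.null(names(seqs)))
  ids <- names(seqs)
  mk <- function(fill) matrix(fill, n, n, dimnames = list(ids, ids))
  im <- mk(100); sm <- mk(100); lm <- mk(NA_real_)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      al <- global_align(seqs[[i]], seqs[[j]], params)
      im[i, j] <- im[j, i] <- al$identity
      sm[i, j] <- sm[j, i] <- al$similarity
      lm[i, j] <- lm[j, i] <- al$length
    }
  }
  diag(lm) <- nchar(seqs)
  structure(list(identity = im, similarity = sm, length = lm),
            class = "identity_matrix")
}

#' Write an identity matrix as square TSV with 2-decimal percentages
#' @param m An `identity_matrix`.
#' @param path Output path.
#' @param which `"identity"` or `"similarity"`.
#' @return `path`, invisibly.
#' @export
write_identity_matrix <- function(m, path, which = "identity") {
  x <- format(round(m[[which]], 2L), nsmall = 2L)
  df <- data.frame(id = rownames(m[[which]]), x, check.names = FALSE)
  write_tsv(df, path)
}
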