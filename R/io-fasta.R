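#' Read a FASTA file into a named character vector
#'
#' Sequences are returned as a plain named character vector with an
#' `"alphabet"` attribute (`"nucleotide"` or `"protein"`). Record order is
#' preserved. Duplicate ids and empty sequences are errors, not warnings:
#' downstream stages key everything on the sequence id.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"auto"` (default), `"nucleotide"` or `"protein"`. With
#'   `"auto"` the alphabet is inferred from residue composition.
#' @return Named character vector of sequences with attribute `alphabet`.
#' @export
read_fasta <- function(path, alphabet = c("auto", "nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence for id(s): ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "))
  }
  if (alphabet == "auto") alphabet <- infer_alphabet(seqs)
  check_alphabet(seqs, alphabet)
  attr(seqs, "alphabet") <- alphabet
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width in residues (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(length(seqs) > 0L, !is.null(names(seqs)), width >= 1L)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# Alphabet inference: anything with >90% ACGTN(+ambiguity) is a nucleotide set.
infer_alphabet <- function(seqs) {
  s <- paste(seqs, collapse = "")
  n_nt <- sum(strsplit(s, "")[[1]] %in%
                c("A", "C", "G", "T", "U", "N", "R", "Y", "S", "W",
                  "K", "M", "B", "D", "H", "V", "-"))
  if (n_nt / nchar(s) > 0.9) "nucleotide" else "protein"
}

AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

check_alphabet <- function(seqs, alphabet) {
  allowed <- if (alphabet == "nucleotide") {
    c("A", "C", "G", "T", "U", "N", "R", "Y", "S", "W", "K", "M",
      "B", "D", "H", "V", "-", "*")
  } else {
    c(AA_STANDARD, "X", "B", "Z", "U", "-", "*")
  }
  for (i in seq_along(seqs)) {
    ch <- unique(strsplit(seqs[[i]], "")[[1]])
    bad <- setdiff(ch, allowed)
    if (length(bad) > 0L) {
      stop("sequence ", names(seqs)[i], " contains characters outside the ",
           alphabet, " alphabet: ", paste(bad, collapse = ""))
    }
  }
  invisible(TRUE)
}
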