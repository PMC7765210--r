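#' Gene model constructor
#'
#' A gene model is one locus: scaffold, 1-based inclusive genomic
#' coordinates, strand, and its ordered coding exons. All coordinates in
#' this package are 1-based inclusive; a feature's width is always
#' `end - start + 1`.
#'
#' @param gene_id Gene identifier.
#' @param scaffold Scaffold / pseudochromosome name.
#' @param start,end 1-based inclusive genomic span of the gene.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix (`start`, `end`) of coding exon segments in
#'   genomic coordinates, non-overlapping.
#' @param cds_warning Optional character flag (e.g. CDS length not a multiple
#'   of three).
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, scaffold, start, end, strand, exons,
                       cds_warning = NA_character_) {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(start <= end, strand %in% c("+", "-"))
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, "start"]), , drop = FALSE]
  if (any(exons[, "end"] < exons[, "start"])) {
    stop("gene ", gene_id, ": exon with end < start")
  }
  if (nrow(exons) > 1L &&
      any(exons[-1L, "start"] <= exons[-nrow(exons), "end"])) {
    stop("gene ", gene_id, ": overlapping exons")
  }
  # exon order is 5'->3' on the coding strand
  if (strand == "-") exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
  structure(
    list(gene_id = gene_id, scaffold = scaffold, start = start, end = end,
         strand = strand, exons = exons,
         cds_length = sum(exons[, "end"] - exons[, "start"] + 1L),
         cds_warning = cds_warning),
    class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s  %s:%d-%d (%s)  %d exon(s), CDS %d bp\n",
              x$gene_id, x$scaffold, x$start, x$end, x$strand,
              nrow(x$exons), x$cds_length))
  invisible(x)
}

#' Genomic length of a gene model (1-based inclusive arithmetic)
#' @param model A `gene_model`.
#' @return Integer length in bp, `end - start + 1`.
#' @export
genomic_length <- function(model) {
  model$end - model$start + 1L
}

#' Reverse the strand of a gene model
#'
#' Flips the strand and hence the coding-strand exon order. Applying it twice
#' restores the original model.
#' @param model A `gene_model`.
#' @return The reversed `gene_model`.
#' @export
reverse_strand <- function(model) {
  gene_model(model$gene_id, model$scaffold, model$start, model$end,
             if (model$strand == "+") "-" else "+",
             model$exons, model$cds_warning)
}

#' Read gene models from a GFF3 file
#'
#' Parses `gene`/`mRNA`/`CDS` (and `exon`) features via
#' [rtracklayer::import()] and assembles one [gene_model()] per gene, taking
#' the first mRNA of each gene. The GFF3 phase column is read but intron
#' phases are always recomputed from CDS lengths (see [intron_phases()]),
#' which are authoritative.
#'
#' A CDS whose total length is not a multiple of three is flagged in the
#' model's `cds_warning` field (with a warning) but not dropped. A feature
#' whose `Parent` does not resolve to any `ID` in the file is an error.
#'
#' @param path Path to a GFF3 file.
#' @return Named list of `gene_model` objects (names = gene ids).
#' @export
read_gff3 <- function(path) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$Parent <- vapply(S4Vectors::mcols(gr)$Parent, function(p)
    if (length(p)) p[[1L]] else NA_character_, character(1))
  ids <- df$ID[!is.na(df$ID)]
  orphan <- !is.na(df$Parent) & !(df$Parent %in% ids)
  if (any(orphan)) {
    stop("orphan Parent attribute(s): ",
         paste(unique(df$Parent[orphan]), collapse = ", "))
  }
  genes <- df[df$type == "gene", , drop = FALSE]
  mrnas <- df[df$type == "mRNA", , drop = FALSE]
  cds <- df[df$type == "CDS", , drop = FALSE]
  models <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    tx <- mrnas[!is.na(mrnas$Parent) & mrnas$Parent == g$ID, , drop = FALSE]
    seg <- if (nrow(tx) > 0L) {
      cds[!is.na(cds$Parent) & cds$Parent == tx$ID[1L], , drop = FALSE]
    } else {
      cds[!is.na(cds$Parent) & cds$Parent == g$ID, , drop = FALSE]
    }
    if (nrow(seg) == 0L) {
      # no CDS rows: treat the whole gene span as one segment
      seg <- g
    }
    warn <- NA_character_
    if (sum(seg$end - seg$start + 1L) %% 3L != 0L) {
      warn <- "cds_length_not_multiple_of_3"
      warning("gene ", g$ID, ": CDS length not a multiple of 3")
    }
    models[[g$ID]] <- gene_model(
      g$ID, as.character(g$seqnames), g$start, g$end,
      as.character(g$strand), cbind(seg$start, seg$end), cds_warning = warn)
  }
  models
}

#' Extract the spliced CDS of a gene model from genome sequences
#'
#' Concatenates the exon segments in coding order; minus-strand genes are
#' reverse-complemented. Together with [read_gff3()] this closes the loop
#' genome FASTA + GFF3 -> CDS.
#'
#' @param model A [gene_model()].
#' @param genome Named character vector of scaffold sequences.
#' @return The CDS as a character string.
#' @export
extract_cds <- function(model, genome) {
  if (!model$scaffold %in% names(genome)) {
    stop("scaffold ", model$scaffold, " not in genome")
  }
  gseq <- genome[[model$scaffold]]
  ex <- model$exons[order(model$exons[, "start"]), , drop = FALSE]
  pieces <- substring(gseq, ex[, "start"], ex[, "end"])
  if (model$strand == "+") {
    paste(pieces, collapse = "")
  } else {
    paste(vapply(rev(pieces), revcomp, character(1)), collapse = "")
  }
}

#' Summarize gene models as a data frame
#' @param models List of `gene_model` objects.
#' @return data.frame with one row per gene: id, scaffold, coordinates,
#'   strand, genomic bp, CDS (ORF) bp, exon count.
#' @export
gene_model_table <- function(models) {
  do.call(rbind, lapply(models, function(m) {
    data.frame(gene_id = m$gene_id, scaffold = m$scaffold,
               start = m$start, end = m$end, strand = m$strand,
               genomic_bp = genomic_length(m), orf_bp = m$cds_length,
               n_exons = nrow(m$exons), row.names = NULL)
  }))
}

#' Parse a printed coordinate string
#'
#' Accepts the compact `start:end (strand)` format used in summary tables,
#' e.g. `"5245164:5249140 (-)"`. Both ASCII `-` and the typographic minus
#' sign are accepted for the reverse strand.
#'
#' @param x Character vector of coordinate strings.
#' @return data.frame with `start`, `end`, `strand`, `genomic_bp`.
#' @export
parse_coordinates <- function(x) {
  x <- gsub("−|–", "-", x)
  m <- regmatches(x, regexec("^\\s*(\\d+)\\s*:\\s*(\\d+)\\s*\\(([+-])\\)\\s*$", x))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) stop("unparseable coordinate string(s): ",
                     paste(x[bad], collapse = "; "))
  start <- vapply(m, function(p) as.integer(p[2L]), integer(1))
  end <- vapply(m, function(p) as.integer(p[3L]), integer(1))
  strand <- vapply(m, function(p) p[4L], character(1))
  stopifnot(all(start <= end))
  data.frame(start = start, end = end, strand = strand,
             genomic_bp = end - start + 1L)
}
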