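#' Exon/intron structure and intron phases of a gene model
#'
#' Intron phase i is the cumulative CDS length of exons 1..i (5' to 3' on
#' the coding strand) modulo 3: phase 0 introns fall between codons, phases
#' 1 and 2 interrupt a codon after its first or second nucleotide. Phases
#' are recomputed from CDS lengths, never taken from annotation.
#'
#' @param model A [gene_model()].
#' @return List of class `gene_structure`: `gene_id`, `exon_lengths` (bp,
#'   coding order), `intron_lengths` (bp), `intron_phases` (0/1/2).
#' @export
intron_phases <- function(model) {
  ex <- model$exons              # already 5'->3' on the coding strand
  stopifnot(nrow(ex) >= 1L)
  exon_len <- ex[, "end"] - ex[, "start"] + 1L
  if (model$cds_length %% 3L != 0L) {
    warning("gene ", model$gene_id, ": CDS length ", model$cds_length,
            " is not a multiple of 3; phases may be unreliable")
  }
  genomic_order <- ex[order(ex[, "start"]), , drop = FALSE]
  introns <- if (nrow(ex) > 1L) {
    genomic_order[-1L, "start"] - genomic_order[-nrow(ex), "end"] - 1L
  } else integer(0)
  if (model$strand == "-") introns <- rev(introns)
  phases <- if (nrow(ex) > 1L) {
    as.integer(cumsum(exon_len)[-nrow(ex)] %% 3L)
  } else integer(0)
  structure(list(gene_id = model$gene_id, exon_lengths = as.integer(exon_len),
                 intron_lengths = as.integer(introns),
                 intron_phases = phases),
            class = "gene_structure")
}

#' Gene structures for a set of models, as a tidy table
#' @param models List of `gene_model`s.
#' @return data.frame with one row per gene: exon count and comma-separated
#'   exon lengths, intron lengths, intron phases.
#' @export
gene_structure_table <- function(models) {
  do.call(rbind, lapply(models, function(m) {
    st <- intron_phases(m)
    data.frame(gene_id = st$gene_id, n_exons = length(st$exon_lengths),
               exon_lengths = paste(st$exon_lengths, collapse = ","),
               intron_lengths = paste(st$intron_lengths, collapse = ","),
               intron_phases = paste(st$intron_phases, collapse = ","),
               row.names = NULL)
  }))
}

#' Detect tandem arrays and segmental duplication pairs
#'
#' Tandem arrays: per scaffold, members are sorted by start coordinate and
#' greedily extended into clusters while (a) the total span stays within
#' `window` bp, (b) cluster size stays at most `max_genes`, and (c) the
#' added gene has protein identity of at least `tandem_min_identity` percent
#' to at least one current cluster member. Clusters of two or more genes are
#' tandem calls. Remaining pairs (not co-members of a tandem array) whose
#' similarity exceeds `segmental_min_similarity` percent are segmental
#' calls; tandem membership takes precedence.
#'
#' @param models_df data.frame with `gene_id`, `scaffold`, `start`, `end`
#'   (e.g. from [gene_model_table()]).
#' @param identities An [identity_matrix()] (or list with `identity` and
#'   `similarity` matrices) covering all genes.
#' @param tandem_min_identity Percent identity floor for joining a tandem
#'   cluster (default 70).
#' @param window Maximum tandem span in bp (default 100000).
#' @param max_genes Maximum genes per tandem array (default 5).
#' @param segmental_min_similarity Percent similarity above which a
#'   non-tandem pair is a segmental duplication (default 90).
#' @return data.frame with `kind` (`"tandem"`/`"segmental"`), `members`
#'   (comma-separated gene ids), `scaffold`, `span_bp`, `min_identity`
#'   (tandem) or `similarity` (segmental).
#' @export
detect_duplications <- function(models_df, identities,
                                tandem_min_identity = 70,
                                window = 100000L, max_genes = 5L,
                                segmental_min_similarity = 90) {
  im <- identities$identity
  sm <- identities$similarity
  miss <- setdiff(models_df$gene_id, rownames(im))
  if (length(miss) > 0L) {
    stop("gene(s) missing from identity matrix: ",
         paste(miss, collapse = ", "))
  }
  calls <- list()
  in_tandem_with <- list()  # gene -> co-members
  for (sc in unique(models_df$scaffold)) {
    g <- models_df[models_df$scaffold == sc, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    i <- 1L
    while (i <= nrow(g)) {
      cluster <- i
      j <- i + 1L
      while (j <= nrow(g) && length(cluster) < max_genes) {
        span <- max(g$end[c(cluster, j)]) - min(g$start[c(cluster, j)]) + 1L
        ident_ok <- any(im[g$gene_id[j], g$gene_id[cluster]] >=
                          tandem_min_identity)
        if (span <= window && ident_ok) {
          cluster <- c(cluster, j)
          j <- j + 1L
        } else break
      }
      if (length(cluster) >= 2L) {
        ids <- g$gene_id[cluster]
        pair_id <- utils::combn(ids, 2L)
        calls[[length(calls) + 1L]] <- data.frame(
          kind = "tandem", members = paste(ids, collapse = ","),
          scaffold = sc,
          span_bp = max(g$end[cluster]) - min(g$start[cluster]) + 1L,
          value = min(im[cbind(pair_id[1L, ], pair_id[2L, ])]))
        for (id in ids) {
          in_tandem_with[[id]] <- union(in_tandem_with[[id]], setdiff(ids, id))
        }
      }
      i <- max(cluster) + 1L
    }
  }
  ids <- models_df$gene_id
  if (length(ids) >= 2L) {
    pr <- utils::combn(ids, 2L)
    for (k in seq_len(ncol(pr))) {
      a <- pr[1L, k]; b <- pr[2L, k]
      if (b %in% in_tandem_with[[a]]) next
      if (sm[a, b] > segmental_min_similarity) {
        calls[[length(calls) + 1L]] <- data.frame(
          kind = "segmental", members = paste(c(a, b), collapse = ","),
          scaffold = paste(unique(models_df$scaffold[match(c(a, b), ids)]),
                           collapse = ","),
          span_bp = NA_integer_, value = sm[a, b])
      }
    }
  }
  if (length(calls) == 0L) {
    return(data.frame(kind = character(0), members = character(0),
                      scaffold = character(0), span_bp = integer(0),
                      value = numeric(0)))
  }
  do.call(rbind, calls)
}
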