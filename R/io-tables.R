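#' Read a protein domain-coordinate table
#'
#' Tab-separated, header required, columns `gene_id`, `domain`, `aa_start`,
#' `aa_end` and optionally `source`. Domains are `PLAT`, `LOX` or `5HIS`;
#' coordinates are 1-based inclusive amino-acid positions.
#'
#' @param path Path to a TSV file.
#' @return data.frame of class `domain_table`.
#' @export
read_domain_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "domain", "aa_start", "aa_end")
  if (!all(need %in% names(df))) {
    stop("domain table must have columns: ", paste(need, collapse = ", "))
  }
  if (!"source" %in% names(df)) df$source <- rep(NA_character_, nrow(df))
  as_domain_table(df)
}

#' Validate and class a domain table
#' @param df data.frame with `gene_id`, `domain`, `aa_start`, `aa_end`
#'   (optional `source`).
#' @return The validated data.frame, class `domain_table`.
#' @export
as_domain_table <- function(df) {
  if (nrow(df) > 0L) {
    df$aa_start <- as.integer(df$aa_start)
    df$aa_end <- as.integer(df$aa_end)
    bad <- which(df$aa_start > df$aa_end)
    if (length(bad) > 0L) {
      stop("aa_start > aa_end at row(s): ", paste(bad, collapse = ", "))
    }
    if (any(df$aa_start < 1L)) stop("aa coordinates must be >= 1")
    if (!all(df$domain %in% c("PLAT", "LOX", "5HIS"))) {
      stop("unknown domain name(s): ",
           paste(setdiff(unique(df$domain), c("PLAT", "LOX", "5HIS")),
                 collapse = ", "))
    }
  }
  if (!"source" %in% names(df)) df$source <- rep(NA_character_, nrow(df))
  class(df) <- c("domain_table", "data.frame")
  df
}

#' Check that every 5HIS interval lies inside its gene's LOX interval
#'
#' The 38-residue 5-histidine signature is part of the catalytic LOX domain;
#' a 5HIS row outside the LOX interval indicates a mis-annotated table.
#'
#' @param domains A `domain_table`.
#' @return Logical vector named by gene id (`TRUE` = contained) for genes
#'   that have both a LOX and a 5HIS row.
#' @export
check_5his_containment <- function(domains) {
  genes <- unique(domains$gene_id)
  out <- logical(0)
  for (g in genes) {
    lox <- domains[domains$gene_id == g & domains$domain == "LOX", ]
    his <- domains[domains$gene_id == g & domains$domain == "5HIS", ]
    if (nrow(lox) == 0L || nrow(his) == 0L) next
    ok <- all(his$aa_start >= min(lox$aa_start) & his$aa_end <= max(lox$aa_end))
    out[g] <- ok
  }
  out
}

#' Read a long-format qPCR Ct table
#'
#' Tab-separated with header; columns `sample_id`, `gene_id`, `condition`,
#' `timepoint`, `replicate`, `ct`. Non-positive Ct values are errors.
#' Cells (gene x condition x timepoint) with fewer than two replicates are
#' permitted at load time but flagged via the `"insufficient_replication"`
#' attribute, since group statistics need at least two.
#'
#' @param path Path to a TSV file.
#' @return data.frame of class `ct_table`; attribute
#'   `insufficient_replication` lists offending cells (possibly empty).
#' @export
read_ct_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "gene_id", "condition", "timepoint", "replicate", "ct")
  if (!all(need %in% names(df))) {
    stop("ct table must have columns: ", paste(need, collapse = ", "))
  }
  as_ct_table(df)
}

#' Validate and class a Ct table
#' @param df data.frame with Ct-table columns.
#' @return data.frame of class `ct_table`.
#' @export
as_ct_table <- function(df) {
  df$ct <- as.numeric(df$ct)
  if (any(!is.na(df$ct) & df$ct <= 0)) stop("Ct values must be positive")
  cells <- stats::aggregate(replicate ~ gene_id + condition + timepoint,
                            data = df, FUN = length)
  low <- cells[cells$replicate < 2L, , drop = FALSE]
  attr(df, "insufficient_replication") <- low
  class(df) <- c("ct_table", "data.frame")
  df
}

#' Write a data frame as TSV (tab-separated, header, no quoting)
#' @param df data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Published summary table of the nine duckweed LOX genes
#'
#' The per-gene summary shipped with the package: locus ids, printed genomic
#' coordinates, genomic/ORF/protein lengths, molecular weight, pI and
#' subfamily for the nine Spirodela polyrhiza LOX genes. Used as a reference
#' input for coordinate-arithmetic and duplication checks.
#'
#' @return data.frame with one row per gene.
#' @export
lox_gene_table <- function() {
  path <- system.file("extdata", "splox_genes.tsv", package = "loxfamily",
                      mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  cbind(df, parse_coordinates(df$coordinates))
}

#' Published domain-coordinate table of the nine duckweed LOX proteins
#'
#' PLAT, LOX and 5-histidine intervals (1-based inclusive amino-acid
#' coordinates) for the nine Spirodela LOX proteins.
#'
#' @return A `domain_table`.
#' @export
lox_domain_table <- function() {
  read_domain_table(system.file("extdata", "splox_domains.tsv",
                                package = "loxfamily", mustWork = TRUE))
}

#' Published endogenous jasmonate levels across Lemna minor culture stages
#'
#' Mean endogenous JA (ng/g FW) at day 14 (vegetative), day 21 (apical floral
#' induction) and day 28 (flowering), used for the percent-decline
#' arithmetic during culture aging.
#'
#' @return data.frame with `stage`, `day`, `ja_ng_fw`, `ja_sd`.
#' @export
lemna_ja_levels <- function() {
  utils::read.delim(system.file("extdata", "lemna_ja_levels.tsv",
                                package = "loxfamily", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

#' Percent decline of jasmonate level between successive culture stages
#'
#' @param levels data.frame as returned by [lemna_ja_levels()].
#' @return data.frame with `from_day`, `to_day`, `pct_decrease` (rounded to
#'   whole percent, as conventionally reported).
#' @export
ja_decline <- function(levels = lemna_ja_levels()) {
  stopifnot(nrow(levels) >= 2L)
  levels <- levels[order(levels$day), ]
  n <- nrow(levels)
  data.frame(
    from_day = levels$day[-n],
    to_day = levels$day[-1L],
    pct_decrease = round(100 * (levels$ja_ng_fw[-n] - levels$ja_ng_fw[-1L]) /
                           levels$ja_ng_fw[-n]))
}
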