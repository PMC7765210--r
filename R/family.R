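#' Scan candidate proteins for PLAT, LOX and 5-His domains
#'
#' Runs the packaged (or user-supplied) PLAT and LOX profile motifs plus the
#' 5-histidine signature scanner over a set of candidate proteins and
#' returns the result as a [as_domain_table()] suitable for
#' [bona_fide_filter()]. Only the best non-overlapping profile hits are
#' kept; 5HIS hits are reported only inside a LOX hit interval (hits outside
#' any LOX interval do not make a candidate bona fide, and are dropped here
#' to keep the table interpretable).
#'
#' @param proteins Named character vector of protein sequences.
#' @param profiles List with `PLAT` and `LOX` [profile_motif()]s
#'   (default [toy_domain_profiles()]).
#' @return A `domain_table` with source tag `"scan"`.
#' @export
scan_candidates <- function(proteins, profiles = toy_domain_profiles()) {
  rows <- list()
  for (g in names(proteins)) {
    p <- proteins[[g]]
    lox_iv <- NULL
    for (dom in c("PLAT", "LOX")) {
      h <- scan_profile(p, profiles[[dom]])
      h <- h[h$non_overlapping, , drop = FALSE]
      if (nrow(h) > 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = g, domain = dom, aa_start = h$aa_start, aa_end = h$aa_end,
          source = "scan")
        if (dom == "LOX") lox_iv <- h
      }
    }
    h5 <- scan_five_his(p)
    if (nrow(h5) > 0L && !is.null(lox_iv)) {
      inside <- vapply(seq_len(nrow(h5)), function(i)
        any(h5$aa_start[i] >= lox_iv$aa_start & h5$aa_end[i] <= lox_iv$aa_end),
        logical(1))
      h5 <- h5[inside, , drop = FALSE]
      if (nrow(h5) > 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = g, domain = "5HIS", aa_start = h5$aa_start,
          aa_end = h5$aa_end, source = "scan")
      }
    }
  }
  if (length(rows) == 0L) {
    return(as_domain_table(data.frame(gene_id = character(0),
                                      domain = character(0),
                                      aa_start = integer(0),
                                      aa_end = integer(0),
                                      source = character(0))))
  }
  as_domain_table(do.call(rbind, rows))
}

#' Bona-fide lipoxygenase filter
#'
#' The family decision rule: a candidate is a bona fide LOX gene iff it
#' carries (a) a PLAT domain, (b) a complete LOX domain — operationalized as
#' a LOX interval at least `min_lox_width` residues wide — and (c) at least
#' one correctly spaced 5-histidine signature inside a LOX interval. Every
#' excluded candidate gets an explicit rejection reason.
#'
#' @param candidates Character vector of candidate gene ids.
#' @param domains A `domain_table` (from [scan_candidates()] or
#'   [read_domain_table()]) covering the candidates.
#' @param min_lox_width Minimum width (aa) for a LOX hit to count as a
#'   complete catalytic domain. Default 450, below the narrowest published
#'   family LOX interval (492 aa) and far above truncated fragments.
#' @return data.frame with `gene_id`, `bona_fide` and `reason`
#'   (`"ok"`, `"missing_PLAT"`, `"missing_or_incomplete_LOX"`,
#'   `"missing_5HIS_in_LOX"`).
#' @export
bona_fide_filter <- function(candidates, domains, min_lox_width = 450L) {
  stopifnot(length(candidates) > 0L || is.character(candidates))
  out <- data.frame(gene_id = candidates,
                    bona_fide = logical(length(candidates)),
                    reason = character(length(candidates)))
  for (i in seq_along(candidates)) {
    d <- domains[domains$gene_id == candidates[i], , drop = FALSE]
    plat <- d[d$domain == "PLAT", , drop = FALSE]
    lox <- d[d$domain == "LOX", , drop = FALSE]
    lox <- lox[lox$aa_end - lox$aa_start + 1L >= min_lox_width, , drop = FALSE]
    his <- d[d$domain == "5HIS", , drop = FALSE]
    his_in_lox <- nrow(his) > 0L && nrow(lox) > 0L &&
      any(vapply(seq_len(nrow(his)), function(k)
        any(his$aa_start[k] >= lox$aa_start & his$aa_end[k] <= lox$aa_end),
        logical(1)))
    out$reason[i] <- if (nrow(plat) == 0L) {
      "missing_PLAT"
    } else if (nrow(lox) == 0L) {
      "missing_or_incomplete_LOX"
    } else if (!his_in_lox) {
      "missing_5HIS_in_LOX"
    } else "ok"
    out$bona_fide[i] <- out$reason[i] == "ok"
  }
  out
}

#' Heuristic plastid transit-peptide prediction
#'
#' Plant chloroplast transit peptides are serine/threonine rich, depleted in
#' acidic residues and net positive. The call is positive iff over the
#' N-terminal `window` residues: Ser+Thr fraction >= `min_ST`, Asp+Glu
#' fraction <= `max_DE`, and (Arg+Lys+His) - (Asp+Glu) >= `min_net_charge`.
#' Proteins shorter than the window are evaluated over their full length and
#' flagged.
#'
#' @param protein Protein sequence (character string).
#' @param window N-terminal window in aa (default 60).
#' @param min_ST Minimum Ser+Thr fraction (default 0.25).
#' @param max_DE Maximum Asp+Glu fraction (default 0.08).
#' @param min_net_charge Minimum count excess of basic over acidic residues
#'   (default 0: transit peptides must not be net acidic).
#' @return Logical flag; attribute `"short"` is `TRUE` when the protein was
#'   shorter than the window.
#' @export
predict_transit_peptide <- function(protein, window = 60L, min_ST = 0.25,
                                    max_DE = 0.08, min_net_charge = 0) {
  s <- strsplit(toupper(protein[[1L]]), "")[[1L]]
  short <- length(s) < window
  w <- s[seq_len(min(window, length(s)))]
  n <- length(w)
  st <- sum(w %in% c("S", "T")) / n
  de_n <- sum(w %in% c("D", "E"))
  de <- de_n / n
  net <- sum(w %in% c("R", "K", "H")) - de_n
  res <- st >= min_ST && de <= max_DE && net >= min_net_charge
  attr(res, "short") <- short
  res
}

#' Assign family members to a subfamily by nearest labeled reference
#'
#' Each member is classified to the subfamily of its nearest reference by
#' global-alignment percent identity (ties broken by higher similarity, then
#' lexicographic reference id). 13-LOX members are sub-typed: type II iff a
#' plastid transit peptide is predicted, else type I.
#'
#' @param proteins Named character vector of member protein sequences.
#' @param references Named character vector of reference proteins; names
#'   encode the label as `"id|label"` (e.g. `"REF9|9-LOX"`).
#' @param params [alignment_params()] for the identity computation.
#' @param tp_args Optional list of arguments passed on to
#'   [predict_transit_peptide()].
#' @return data.frame with `gene_id`, `subfamily`, `ref_id`, `identity`,
#'   `similarity`, `transit_peptide`, `lox13_type` (`"I"`, `"II"` or
#'   `NA` for non-13-LOX members).
#' @export
assign_subfamily <- function(proteins, references,
                             params = alignment_params("protein"),
                             tp_args = list()) {
  if (length(references) == 0L) stop("at least one labeled reference required")
  ref_ids <- sub("\\|.*$", "", names(references))
  ref_labels <- sub("^.*\\|", "", names(references))
  if (any(ref_ids == names(references))) {
    stop("reference names must encode labels as 'id|label'")
  }
  out <- lapply(names(proteins), function(g) {
    al <- lapply(references, function(r)
      global_align(proteins[[g]], r, params))
    ident <- vapply(al, `[[`, numeric(1), "identity")
    simil <- vapply(al, `[[`, numeric(1), "similarity")
    best <- order(-ident, -simil, ref_ids)[1L]
    tp <- do.call(predict_transit_peptide,
                  c(list(proteins[[g]]), tp_args))
    lab <- ref_labels[best]
    data.frame(gene_id = g, subfamily = lab, ref_id = ref_ids[best],
               identity = ident[best], similarity = simil[best],
               transit_peptide = as.logical(tp),
               lox13_type = if (lab == "13-LOX") {
                 if (tp) "II" else "I"
               } else NA_character_)
  })
  do.call(rbind, out)
}

#' Ratio of 13-LOX to 9-LOX subfamily sizes
#'
#' @param counts Named vector or table of subfamily counts with entries
#'   `"13-LOX"` and `"9-LOX"`.
#' @return The ratio `n(13-LOX)/n(9-LOX)` rounded to 2 decimals; `NA`
#'   (the undefined marker) when the 9-LOX count is zero.
#' @export
subfamily_ratio <- function(counts) {
  counts <- as.vector(counts[c("13-LOX", "9-LOX")], mode = "numeric")
  counts[is.na(counts)] <- 0
  if (any(counts < 0)) stop("subfamily counts must be non-negative")
  if (counts[2L] == 0) return(NA_real_)
  round(counts[1L] / counts[2L], 2L)
}
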