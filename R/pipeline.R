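#' Published pairwise identities for the duckweed tandem LOX genes
#'
#' Nucleotide and amino-acid percent identities for the published tandem
#' pairs, used to reproduce the duplication classification from in-print
#' numbers.
#'
#' @return data.frame with `gene_a`, `gene_b`, `nt_identity`, `aa_identity`.
#' @export
lox_identity_pairs <- function() {
  utils::read.delim(system.file("extdata", "splox_identities.tsv",
                                package = "loxfamily", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

#' Identity/similarity matrices from published pair values
#'
#' Builds an `identity_matrix`-shaped object over a gene set from a sparse
#' table of published pairwise identities. Unpublished pairs are filled
#' with `background` (set safely below both the tandem-identity and
#' segmental-similarity thresholds); similarity is taken equal to identity,
#' the only scale the printed values provide.
#'
#' @param pairs data.frame as from [lox_identity_pairs()].
#' @param gene_ids All gene ids for the matrix.
#' @param which `"aa_identity"` or `"nt_identity"`.
#' @param background Fill value for unpublished pairs (default 50).
#' @return List of class `identity_matrix` with `identity` and `similarity`.
#' @export
identity_matrix_from_pairs <- function(pairs, gene_ids,
                                       which = "aa_identity",
                                       background = 50) {
  n <- length(gene_ids)
  m <- matrix(background, n, n, dimnames = list(gene_ids, gene_ids))
  diag(m) <- 100
  for (k in seq_len(nrow(pairs))) {
    a <- pairs$gene_a[k]; b <- pairs$gene_b[k]
    if (a %in% gene_ids && b %in% gene_ids) {
      m[a, b] <- m[b, a] <- pairs[[which]][k]
    }
  }
  structure(list(identity = m, similarity = m, length = NULL),
            class = "identity_matrix")
}

#' Build the family report files
#'
#' Writes the per-gene family summary (gene, coordinates, genomic bp
#' recomputed as `end - start + 1`, ORF bp, protein aa, molecular weight,
#' pI, subfamily), the domain-interval table, the per-candidate rejection
#' report, and a plain-text summary with family size and the 13-LOX:9-LOX
#' ratio.
#'
#' @param members data.frame with columns `gene_id`, `scaffold`, `start`,
#'   `end`, `strand`, `orf_bp`, `protein_aa`, and optionally `mw_kda`,
#'   `pi`, `subfamily`. Empty is allowed (headers-only files).
#' @param domains A `domain_table` (may have zero rows).
#' @param rejections data.frame from [bona_fide_filter()] (may be `NULL`).
#' @param outdir Output directory.
#' @return Named vector of written file paths, invisibly; the summary lines
#'   as attribute `"summary"`.
#' @export
build_family_report <- function(members, domains, rejections = NULL,
                                outdir = ".") {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  for (col in c("mw_kda", "pi", "subfamily")) {
    if (!col %in% names(members)) members[[col]] <- rep(NA, nrow(members))
  }
  fam <- data.frame(
    gene_id = members$gene_id,
    coordinates = if (nrow(members)) {
      sprintf("%s:%d-%d (%s)", members$scaffold, members$start,
              members$end, members$strand)
    } else character(0),
    genomic_bp = members$end - members$start + 1L,
    orf_bp = members$orf_bp,
    protein_aa = members$protein_aa,
    mol_wt_kda = members$mw_kda,
    pi = members$pi,
    subfamily = members$subfamily)
  paths <- c(family = file.path(outdir, "family_table.tsv"),
             domains = file.path(outdir, "domain_table.tsv"),
             rejections = file.path(outdir, "rejection_report.tsv"),
             summary = file.path(outdir, "summary.txt"))
  write_tsv(fam, paths[["family"]])
  write_tsv(as.data.frame(domains), paths[["domains"]])
  if (is.null(rejections)) {
    rejections <- data.frame(gene_id = character(0), bona_fide = logical(0),
                             reason = character(0))
  }
  write_tsv(rejections, paths[["rejections"]])
  counts <- table(fam$subfamily)
  ratio <- subfamily_ratio(counts)
  summary_lines <- c(
    sprintf("bona fide family members: %d", nrow(fam)),
    sprintf("subfamily counts: %s",
            paste(sprintf("%s=%d", names(counts), as.integer(counts)),
                  collapse = ", ")),
    sprintf("13-LOX : 9-LOX ratio: %s",
            ifelse(is.na(ratio), "undefined", format(ratio, nsmall = 2))))
  writeLines(summary_lines, paths[["summary"]])
  attr(paths, "summary") <- summary_lines
  invisible(paths)
}

#' Run the full mining pipeline on a synthetic (or pre-generated) bundle
#'
#' Stages, in dependency order: simulate (generate the genome bundle),
#' identify (domain scans + bona-fide filter + subfamily assignment),
#' properties (MW/pI, gene models from GFF3), compare (identity matrices,
#' gene structures, duplication calls), tree (progressive alignment + NJ
#' bootstrap), report. Stage toggles select a prefix of this order.
#' Everything downstream is computed from the stage files, never from
#' generator internals, so the run doubles as a round-trip test of the
#' formats.
#'
#' @param config A [simulation_config()].
#' @param outdir Run directory (created; bundle under `data/`, outputs under
#'   `results/`).
#' @param stages Character vector of stages to run.
#' @param n_bootstrap Bootstrap replicates for the tree stage.
#' @return List with the per-stage results (`manifest`, `identification`,
#'   `members`, `duplications`, `tree`, report `paths`, ...).
#' @export
run_family_pipeline <- function(config = simulation_config(), outdir,
                                stages = c("simulate", "identify",
                                           "properties", "compare",
                                           "tree", "report"),
                                n_bootstrap = 100L) {
  res <- list(config = config)
  data_dir <- file.path(outdir, "data")
  out_dir <- file.path(outdir, "results")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if ("simulate" %in% stages) {
    res$bundle <- generate_genome_bundle(config, data_dir)
    res$manifest <- res$bundle$manifest
  }
  if (!"identify" %in% stages) return(invisible(res))

  proteins <- read_fasta(file.path(data_dir, "proteins.fasta"), "protein")
  scans <- scan_candidates(proteins)
  filt <- bona_fide_filter(names(proteins), scans)
  members <- filt$gene_id[filt$bona_fide]
  assign <- assign_subfamily(proteins[members],
                             archetype_reference_proteins())
  res$identification <- list(scans = scans, filter = filt, subfamily = assign)
  write_tsv(merge(filt, assign[, c("gene_id", "subfamily", "lox13_type",
                                   "transit_peptide")],
                  by = "gene_id", all.x = TRUE, sort = FALSE),
            file.path(out_dir, "family_members.tsv"))

  member_df <- data.frame(gene_id = members)
  if ("properties" %in% stages) {
    models <- read_gff3(file.path(data_dir, "genes.gff3"))
    gm <- gene_model_table(models[members])
    member_df <- merge(member_df, gm, by = "gene_id", sort = FALSE)
    member_df$protein_aa <- orf_to_protein_length(member_df$orf_bp)
    member_df$mw_kda <- vapply(proteins[member_df$gene_id],
                               molecular_weight, numeric(1), unit = "kDa")
    member_df$pi <- vapply(proteins[member_df$gene_id],
                           isoelectric_point, numeric(1))
    member_df$subfamily <- assign$subfamily[match(member_df$gene_id,
                                                  assign$gene_id)]
    member_df$lox13_type <- assign$lox13_type[match(member_df$gene_id,
                                                    assign$gene_id)]
    res$models <- models
    res$members <- member_df
  }
  if ("compare" %in% stages) {
    idm <- identity_matrix(proteins[members], alignment_params("protein"))
    res$identities <- idm
    res$structures <- gene_structure_table(res$models[members])
    res$duplications <- detect_duplications(member_df, idm)
    write_identity_matrix(idm, file.path(out_dir, "identity_matrix.tsv"))
    write_tsv(res$structures, file.path(out_dir, "gene_structures.tsv"))
    write_tsv(res$duplications, file.path(out_dir, "duplications.tsv"))
  }
  if ("tree" %in% stages) {
    msa <- align_progressive(proteins[members], alignment_params("protein"))
    res$msa <- msa
    res$tree <- bootstrap_support(msa, "poisson", replicates = n_bootstrap,
                                  seed = config$seed)
    ape::write.tree(res$tree, file.path(out_dir, "family_tree.nwk"))
  }
  if ("report" %in% stages) {
    dom <- scans[scans$gene_id %in% members, , drop = FALSE]
    res$report <- build_family_report(res$members, dom,
                                      rejections = filt, outdir = out_dir)
    res$summary <- attr(res$report, "summary")
  }
  invisible(res)
}

#' Cross-check recomputed protein properties against published values
#'
#' Given real (externally supplied) protein and optionally CDS sequences
#' named by gene, recomputes molecular weight, pI and the published pairwise
#' identities, and reports agreement with the packaged reference tables at
#' the stated tolerances. Intended as an optional validation when the
#' public assembly sequences are available; in tests it runs on synthetic
#' stand-ins to exercise the harness.
#'
#' @param proteins Named character vector of protein sequences (names
#'   matching `gene_table$gene_name`).
#' @param gene_table Reference per-gene table (default [lox_gene_table()]).
#' @param pairs Published identity pairs (default [lox_identity_pairs()]);
#'   set `NULL` to skip.
#' @param mw_tol Tolerance on molecular weight in kDa (default 0.2).
#' @param pi_tol Tolerance on pI (default 0.3).
#' @param ident_tol Tolerance on identity percent (default 2).
#' @return List with `properties` and `identities` comparison data.frames.
#' @export
external_property_check <- function(proteins,
                                    gene_table = lox_gene_table(),
                                    pairs = lox_identity_pairs(),
                                    mw_tol = 0.2, pi_tol = 0.3,
                                    ident_tol = 2) {
  shared <- intersect(names(proteins), gene_table$gene_name)
  if (length(shared) == 0L) stop("no gene names shared with the reference table")
  gt <- gene_table[match(shared, gene_table$gene_name), ]
  props <- data.frame(
    gene = shared,
    mw_kda = vapply(proteins[shared], molecular_weight, numeric(1),
                    unit = "kDa"),
    mw_ref = gt$mol_wt_kda,
    pi = vapply(proteins[shared], isoelectric_point, numeric(1)),
    pi_ref = gt$pi, row.names = NULL)
  props$mw_ok <- abs(props$mw_kda - props$mw_ref) <= mw_tol
  props$pi_ok <- abs(props$pi - props$pi_ref) <= pi_tol
  idents <- NULL
  if (!is.null(pairs)) {
    keep <- pairs$gene_a %in% shared & pairs$gene_b %in% shared
    pairs <- pairs[keep, , drop = FALSE]
    if (nrow(pairs) > 0L) {
      pp <- alignment_params("protein")
      pairs$aa_computed <- vapply(seq_len(nrow(pairs)), function(k)
        global_align(proteins[[pairs$gene_a[k]]],
                     proteins[[pairs$gene_b[k]]], pp)$identity, numeric(1))
      pairs$aa_ok <- abs(pairs$aa_computed - pairs$aa_identity) <= ident_tol
      idents <- pairs
    }
  }
  list(properties = props, identities = idents)
}
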