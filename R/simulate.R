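#' Configuration for the synthetic genome / qPCR generator
#'
#' Defaults emulate the study system the package is modelled on: a compact
#' aquatic-plant genome carrying a nine-member LOX family (2 x 9-LOX,
#' 7 x 13-LOX, six of the seven 13-LOX carrying a plastid transit peptide),
#' six decoy candidates lacking a complete LOX domain, and two tandem
#' clusters (sizes 2 and 3) within their published span scales; the qPCR
#' design is 2 conditions x timepoints 0/1/3/6/12 h x 3 replicates with
#' 0.2-cycle Gaussian Ct noise and two reference genes.
#'
#' @param seed Integer seed; the single source of randomness for the bundle.
#' @param n_scaffolds,scaffold_length Genome shape (bp).
#' @param n_true_family Number of true family members; must equal
#'   `sum(subfamily_split)`.
#' @param n_decoys Number of decoy candidates.
#' @param decoy_modes Character vector recycled over decoys; each of
#'   `"missing-LOX-domain"`, `"truncated-LOX"`, `"missing-5His"`.
#' @param tandem_clusters List of `list(size =, max_span =)`; sizes in 2..5.
#' @param subfamily_split Named counts for `"9-LOX"` and `"13-LOX"`.
#' @param type2_fraction Fraction of 13-LOX members given a transit peptide.
#' @param mutation_rate Per-site substitution rate applied to planted
#'   domain/archetype copies (default 0.10).
#' @param exon_count_range Integer range of exons per gene.
#' @param conditions,timepoints,replicates qPCR design (first condition is
#'   the control).
#' @param planted_fold_changes data.frame `gene_id`, `condition`,
#'   `timepoint`, `fold` (> 0); unlisted cells have fold 1.
#' @param ct_noise_sd Gaussian Ct noise, in cycles.
#' @param reference_gene_ct Named baseline Cts of the reference genes.
#' @param baseline_ct Baseline Ct of every target gene.
#' @return Validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_scaffolds = 4L,
                              scaffold_length = 800000L,
                              n_true_family = 9L,
                              n_decoys = 6L,
                              decoy_modes = "missing-LOX-domain",
                              tandem_clusters = list(
                                list(size = 2L, max_span = 20000L),
                                list(size = 3L, max_span = 40000L)),
                              subfamily_split = c("9-LOX" = 2L, "13-LOX" = 7L),
                              type2_fraction = 6 / 7,
                              mutation_rate = 0.10,
                              exon_count_range = c(2L, 8L),
                              conditions = c("control", "treated"),
                              timepoints = c(0, 1, 3, 6, 12),
                              replicates = 3L,
                              planted_fold_changes = NULL,
                              ct_noise_sd = 0.2,
                              reference_gene_ct = c(ACT = 20, R18S = 15),
                              baseline_ct = 26) {
  cfg <- as.list(environment())
  stopifnot(seed == as.integer(seed),
            n_true_family == sum(subfamily_split),
            n_decoys >= 0L, replicates >= 2L,
            mutation_rate >= 0, mutation_rate < 0.5,
            type2_fraction >= 0, type2_fraction <= 1,
            length(exon_count_range) == 2L,
            exon_count_range[1L] >= 1L,
            length(reference_gene_ct) >= 1L)
  for (cl in tandem_clusters) {
    if (!(cl$size >= 2L && cl$size <= 5L)) {
      stop("tandem cluster sizes must be in [2, 5]")
    }
  }
  if (sum(vapply(tandem_clusters, `[[`, numeric(1), "size")) > n_true_family) {
    stop("tandem clusters require more genes than n_true_family provides")
  }
  if (!is.null(planted_fold_changes) &&
      any(planted_fold_changes$fold <= 0)) {
    stop("planted fold changes must be > 0")
  }
  if (!all(decoy_modes %in% c("missing-LOX-domain", "truncated-LOX",
                              "missing-5His"))) {
    stop("unknown decoy mode(s)")
  }
  structure(cfg, class = "simulation_config")
}

#' Two divergent subfamily archetype blocks
#'
#' Fixed 60-aa discriminative blocks, one per subfamily, with high mutual
#' divergence so that nearest-reference classification at a 10% per-site
#' mutation rate is unambiguous.
#'
#' @return Named character vector with `"9-LOX"` and `"13-LOX"` blocks.
#' @export
subfamily_archetypes <- function() {
  c("9-LOX" = fixed_consensus(60L, 3L),
    "13-LOX" = fixed_consensus(60L, 17L))
}

#' Deterministic full-length reference proteins per subfamily
#'
#' Pure (unmutated) proteins built from the packaged PLAT/LOX consensus with
#' the subfamily archetype block and a canonical 5-His signature planted at
#' their fixed offsets. These are synthetic constructs serving as the
#' labeled reference panel for [assign_subfamily()].
#'
#' @return Named character vector `c("REF9|9-LOX" = ..., "REF13|13-LOX" = ...)`.
#' @export
archetype_reference_proteins <- function() {
  prof <- toy_domain_profiles()
  arch <- subfamily_archetypes()
  build <- function(block) {
    lox <- strsplit(consensus_string(prof$LOX), "")[[1L]]
    lox[prof$lox_arch_offset:(prof$lox_arch_offset + 59L)] <-
      strsplit(block, "")[[1L]]
    sig <- rep("A", 38L); sig[FIVE_HIS_OFFSETS] <- "H"
    lox[prof$lox_his_offset:(prof$lox_his_offset + 37L)] <- sig
    paste0("M", consensus_string(prof$PLAT), paste(lox, collapse = ""))
  }
  c("REF9|9-LOX" = build(arch[["9-LOX"]]),
    "REF13|13-LOX" = build(arch[["13-LOX"]]))
}

consensus_string <- function(motif) {
  paste(rownames(motif$pfm)[apply(motif$pfm, 2L, which.max)], collapse = "")
}

mutate_seq <- function(chars, rate, alphabet = AA_STANDARD) {
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(alphabet, chars[i]), 1L)
  }
  chars
}

random_residues <- function(n, alphabet = AA_STANDARD) {
  sample(alphabet, n, replace = TRUE)
}

# Transit peptide: fixed Ser/Thr-rich, acid-free composition, shuffled.
make_transit_peptide <- function() {
  pool <- c(rep("S", 14L), rep("T", 8L), rep("R", 5L), rep("K", 4L),
            rep("A", 10L), rep("L", 5L), rep("V", 2L), "P")
  paste(sample(pool), collapse = "")
}

# Linkers avoid D/E/H so transit-peptide windows and 5-His scans stay clean.
LINKER_POOL <- c("A", "G", "L", "V", "P", "S", "N", "Q")

make_five_his_signature <- function() {
  sig <- random_residues(38L, setdiff(AA_STANDARD, "H"))
  sig[FIVE_HIS_OFFSETS] <- "H"
  sig
}

# Derive a protein from an ancestor at a given rate, protecting the
# initiator Met and the planted His positions.
derive_protein <- function(ancestor, rate) {
  chars <- strsplit(ancestor$seq, "")[[1L]]
  protect <- c(1L, ancestor$his_positions)
  hit <- setdiff(which(stats::runif(length(chars)) < rate), protect)
  for (i in hit) chars[i] <- sample(setdiff(AA_STANDARD, chars[i]), 1L)
  list(seq = paste(chars, collapse = ""),
       his_positions = ancestor$his_positions)
}

# Build one synthetic protein. role: "true" or a decoy mode.
# Returns list(seq, his_positions) with absolute planted His coordinates.
build_protein <- function(role, subfamily, transit, profiles, rate) {
  plat <- mutate_seq(strsplit(consensus_string(profiles$PLAT), "")[[1L]], rate)
  lox_cons <- strsplit(consensus_string(profiles$LOX), "")[[1L]]
  arch_span <- profiles$lox_arch_offset:(profiles$lox_arch_offset + 59L)
  his_span <- profiles$lox_his_offset:(profiles$lox_his_offset + 37L)
  make_lox <- function(with_his = TRUE) {
    lox <- mutate_seq(lox_cons, rate)
    if (!is.null(subfamily)) {
      lox[arch_span] <- mutate_seq(
        strsplit(subfamily_archetypes()[[subfamily]], "")[[1L]], rate)
    } else {
      lox[arch_span] <- random_residues(60L)
    }
    lox[his_span] <- if (with_his) {
      make_five_his_signature()
    } else {
      random_residues(38L, setdiff(AA_STANDARD, "H"))
    }
    lox
  }
  linker <- function(n) random_residues(n, LINKER_POOL)
  head_part <- if (isTRUE(transit)) {
    c("M", strsplit(make_transit_peptide(), "")[[1L]])
  } else "M"
  pre <- c(linker(sample(5:20, 1L)), plat, linker(sample(8:15, 1L)))
  body <- switch(role,
    "true" = c(pre, make_lox(TRUE), random_residues(sample(10:30, 1L))),
    "missing-LOX-domain" = c(pre, random_residues(200L),
                             make_five_his_signature(),
                             random_residues(200L)),
    "truncated-LOX" = c(pre, make_lox(FALSE)[1:250],
                        random_residues(sample(10:30, 1L))),
    "missing-5His" = c(pre, make_lox(FALSE),
                       random_residues(sample(10:30, 1L))),
    stop("unknown role: ", role))
  prot <- c(head_part, body)
  if (role == "missing-5His") prot[prot == "H"] <- "Q"
  his_abs <- if (role == "true") {
    length(head_part) + length(pre) + profiles$lox_his_offset - 1L +
      FIVE_HIS_OFFSETS
  } else integer(0)
  list(seq = paste(prot, collapse = ""), his_positions = his_abs)
}

CODON_TABLE <- list(
  A = c("GCT", "GCC", "GCA", "GCG"), R = c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG"),
  N = c("AAT", "AAC"), D = c("GAT", "GAC"), C = c("TGT", "TGC"),
  Q = c("CAA", "CAG"), E = c("GAA", "GAG"), G = c("GGT", "GGC", "GGA", "GGG"),
  H = c("CAT", "CAC"), I = c("ATT", "ATC", "ATA"),
  L = c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"), K = c("AAA", "AAG"),
  M = "ATG", F = c("TTT", "TTC"), P = c("CCT", "CCC", "CCA", "CCG"),
  S = c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
  T = c("ACT", "ACC", "ACA", "ACG"), W = "TGG", Y = c("TAT", "TAC"),
  V = c("GTT", "GTC", "GTA", "GTG"))
STOP_CODONS <- c("TAA", "TAG", "TGA")

reverse_translate <- function(protein) {
  aa <- strsplit(protein, "")[[1L]]
  codons <- vapply(aa, function(a) {
    cs <- CODON_TABLE[[a]]
    cs[sample.int(length(cs), 1L)]
  }, character(1))
  paste0(paste(codons, collapse = ""),
         STOP_CODONS[sample.int(3L, 1L)])
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(x, "")[[1L]]), collapse = ""))
}

#' Generate a synthetic annotated genome bundle with ground truth
#'
#' Writes a genome FASTA, GFF3 gene models, protein and CDS FASTA, and a
#' ground-truth manifest TSV to `dir`. True family members carry a planted
#' PLAT profile copy, a complete LOX profile copy with their subfamily
#' archetype block, and a correctly spaced 5-histidine signature inside the
#' LOX region; each decoy violates exactly its decoy mode. Tandem clusters
#' are placed on one scaffold within their `max_span`. CDS lengths are
#' multiples of three including a stop codon; GFF3 coordinates are 1-based
#' inclusive and consistent with the FASTA. The same config and seed produce
#' byte-identical files.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return List with `paths` (named file paths), `manifest` (data.frame),
#'   `proteins`, `cds` (named character vectors).
#' @export
generate_genome_bundle <- function(config, dir) {
  stopifnot(inherits(config, "simulation_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  old <- .Random.seed_safe()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  profiles <- toy_domain_profiles()

  n_true <- config$n_true_family
  subfams <- rep(names(config$subfamily_split), config$subfamily_split)
  n13 <- sum(subfams == "13-LOX")
  n_type2 <- round(config$type2_fraction * n13)
  type13 <- rep(NA_character_, n_true)
  idx13 <- which(subfams == "13-LOX")
  type13[idx13] <- c(rep("II", n_type2), rep("I", n13 - n_type2))
  modes <- if (config$n_decoys > 0L) {
    rep(config$decoy_modes, length.out = config$n_decoys)
  } else character(0)

  ids <- c(sprintf("SIMLOX%02d", seq_len(n_true)),
           if (config$n_decoys > 0L) sprintf("DECOY%02d", seq_len(config$n_decoys)))
  roles <- c(rep("true", n_true), modes)
  gene_subfam <- c(subfams, rep(NA_character_, config$n_decoys))
  gene_type <- c(type13, rep(NA_character_, config$n_decoys))
  transit <- !is.na(gene_type) & gene_type == "II"

  # tandem-cluster genes descend from a shared ancestor at half the
  # mutation rate (recent duplicates); cluster members share the ancestor's
  # subfamily and transit-peptide status
  cluster_of <- rep(NA_integer_, length(ids))
  pos <- 1L
  for (ci in seq_along(config$tandem_clusters)) {
    sz <- config$tandem_clusters[[ci]]$size
    cluster_of[pos:(pos + sz - 1L)] <- ci
    pos <- pos + sz
  }
  proteins <- stats::setNames(vector("character", length(ids)), ids)
  ancestors <- list()
  for (i in seq_along(ids)) {
    if (!is.na(cluster_of[i])) {
      ci <- cluster_of[i]
      first <- which(cluster_of == ci)[1L]
      if (is.null(ancestors[[as.character(ci)]])) {
        gene_subfam[which(cluster_of == ci)] <- gene_subfam[first]
        transit[which(cluster_of == ci)] <- transit[first]
        gene_type[which(cluster_of == ci)] <- gene_type[first]
        ancestors[[as.character(ci)]] <- build_protein(
          "true", gene_subfam[first], transit[first], profiles,
          config$mutation_rate / 2)
      }
      proteins[i] <- derive_protein(ancestors[[as.character(ci)]],
                                    config$mutation_rate / 2)$seq
    } else {
      proteins[i] <- build_protein(
        if (roles[i] == "true") "true" else roles[i],
        if (is.na(gene_subfam[i])) NULL else gene_subfam[i],
        transit[i], profiles, config$mutation_rate)$seq
    }
  }
  cds <- vapply(proteins, reverse_translate, character(1))

  # exon/intron layout per gene
  layouts <- lapply(cds, function(cs) {
    n_bp <- nchar(cs)
    n_ex <- sample(config$exon_count_range[1L]:config$exon_count_range[2L], 1L)
    n_ex <- min(n_ex, n_bp %/% 30L)  # keep exons comfortably sized
    cuts <- if (n_ex > 1L) sort(sample(seq_len(n_bp - 1L), n_ex - 1L)) else integer(0)
    exon_len <- diff(c(0L, cuts, n_bp))
    intron_len <- if (n_ex > 1L) sample(80:400, n_ex - 1L, replace = TRUE) else integer(0)
    list(exon_len = exon_len, intron_len = intron_len,
         genomic = sum(exon_len) + sum(intron_len))
  })
  glen <- vapply(layouts, `[[`, numeric(1), "genomic")

  # assign genes to clusters / singletons, then to scaffolds
  cluster_id <- rep(NA_integer_, length(ids))
  true_idx <- seq_len(n_true)
  pos <- 1L
  for (ci in seq_along(config$tandem_clusters)) {
    sz <- config$tandem_clusters[[ci]]$size
    cluster_id[true_idx[pos:(pos + sz - 1L)]] <- ci
    pos <- pos + sz
  }
  scaffolds <- sprintf("scaf%02d", seq_len(config$n_scaffolds))
  placements <- data.frame(gene_id = ids, scaffold = NA_character_,
                           start = NA_integer_, end = NA_integer_,
                           strand = NA_character_)
  cursor <- stats::setNames(rep(1L, config$n_scaffolds), scaffolds)
  place_gene <- function(i, sc, gap) {
    start <- cursor[[sc]] + gap
    end <- start + as.integer(glen[i]) - 1L
    if (end > config$scaffold_length) {
      stop("placement infeasible: scaffold_length ", config$scaffold_length,
           " too small for gene ", ids[i], " on ", sc)
    }
    placements$scaffold[i] <<- sc
    placements$start[i] <<- start
    placements$end[i] <<- end
    placements$strand[i] <<- sample(c("+", "-"), 1L)
    cursor[[sc]] <<- end + 1L
  }
  sc_i <- 0L
  for (ci in seq_along(config$tandem_clusters)) {
    sc_i <- sc_i %% config$n_scaffolds + 1L
    members <- which(!is.na(cluster_id) & cluster_id == ci)
    max_span <- config$tandem_clusters[[ci]]$max_span
    slack <- max_span - sum(glen[members])
    if (slack < 2L * (length(members) - 1L)) {
      stop("placement infeasible: tandem cluster ", ci, " genes (",
           sum(glen[members]), " bp) exceed max_span ", max_span)
    }
    gaps <- sample(2:max(2L, slack %/% (2L * length(members))),
                   length(members) - 1L, replace = TRUE)
    for (k in seq_along(members)) {
      place_gene(members[k],
                 scaffolds[sc_i],
                 if (k == 1L) sample(1000:5000, 1L) else gaps[k - 1L])
    }
  }
  for (i in which(is.na(cluster_id))) {
    sc_i <- sc_i %% config$n_scaffolds + 1L
    place_gene(i, scaffolds[sc_i], sample(110000:150000, 1L))
  }

  # scaffold backgrounds, then splice CDS pieces into exon positions
  genome <- stats::setNames(vapply(scaffolds, function(s)
    paste(sample(c("A", "C", "G", "T"), config$scaffold_length,
                 replace = TRUE), collapse = ""), character(1)), scaffolds)
  gff <- c("##gff-version 3")
  exon_records <- list()
  for (i in seq_along(ids)) {
    lay <- layouts[[i]]
    n_ex <- length(lay$exon_len)
    # genomic exon coordinates, ascending
    ex_start <- integer(n_ex); ex_end <- integer(n_ex)
    at <- placements$start[i]
    asc_len <- if (placements$strand[i] == "+") lay$exon_len else rev(lay$exon_len)
    asc_int <- if (placements$strand[i] == "+") lay$intron_len else rev(lay$intron_len)
    for (e in seq_len(n_ex)) {
      ex_start[e] <- at
      ex_end[e] <- at + asc_len[e] - 1L
      at <- ex_end[e] + 1L + if (e < n_ex) asc_int[e] else 0L
    }
    # CDS pieces in coding order; splice into the scaffold
    piece_start <- cumsum(c(1L, lay$exon_len[-n_ex]))
    pieces <- substring(cds[[i]], piece_start,
                        piece_start + lay$exon_len - 1L)
    sc <- placements$scaffold[i]
    gseq <- genome[[sc]]
    for (e in seq_len(n_ex)) {
      coding_e <- if (placements$strand[i] == "+") e else n_ex - e + 1L
      frag <- if (placements$strand[i] == "+") {
        pieces[coding_e]
      } else {
        revcomp(pieces[coding_e])
      }
      substr(gseq, ex_start[e], ex_end[e]) <- frag
    }
    genome[[sc]] <- gseq
    # GFF3 rows (phase from cumulative CDS length, coding order)
    phase <- (3L - c(0L, cumsum(lay$exon_len)[-n_ex]) %% 3L) %% 3L
    asc_phase <- if (placements$strand[i] == "+") phase else rev(phase)
    g <- ids[i]
    gff <- c(gff,
      sprintf("%s\tloxfamily_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              sc, placements$start[i], placements$end[i],
              placements$strand[i], g),
      sprintf("%s\tloxfamily_sim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
              sc, placements$start[i], placements$end[i],
              placements$strand[i], g, g),
      sprintf("%s\tloxfamily_sim\texon\t%d\t%d\t.\t%s\t.\tParent=%s.t1",
              sc, ex_start, ex_end, placements$strand[i], g),
      sprintf("%s\tloxfamily_sim\tCDS\t%d\t%d\t.\t%s\t%d\tParent=%s.t1",
              sc, ex_start, ex_end, placements$strand[i], asc_phase, g))
    exon_records[[i]] <- data.frame(n_exons = n_ex)
  }

  manifest <- data.frame(
    gene_id = ids, role = ifelse(roles == "true", "true", "decoy"),
    decoy_mode = ifelse(roles == "true", NA_character_, roles),
    subfamily = gene_subfam, lox13_type = gene_type,
    transit_peptide = transit,
    cluster_id = cluster_id,
    scaffold = placements$scaffold, start = placements$start,
    end = placements$end, strand = placements$strand,
    genomic_bp = placements$end - placements$start + 1L,
    orf_bp = unname(nchar(cds)), protein_aa = unname(nchar(proteins)),
    n_exons = unname(vapply(exon_records, `[[`, numeric(1), "n_exons")),
    seed = config$seed, row.names = NULL)

  paths <- c(genome = file.path(dir, "genome.fasta"),
             gff3 = file.path(dir, "genes.gff3"),
             proteins = file.path(dir, "proteins.fasta"),
             cds = file.path(dir, "cds.fasta"),
             manifest = file.path(dir, "manifest.tsv"))
  write_fasta(genome, paths[["genome"]])
  writeLines(gff, paths[["gff3"]])
  write_fasta(proteins, paths[["proteins"]])
  write_fasta(cds, paths[["cds"]])
  write_tsv(manifest, paths[["manifest"]])
  list(paths = paths, manifest = manifest, proteins = proteins, cds = cds)
}

#' Generate a long-format qPCR Ct table with planted fold changes
#'
#' Target Ct values are drawn as `baseline - log2(fold) + N(0, sd)`, with
#' fold 1 for all control cells and for cells without a planted fold.
#' Reference genes are unaffected by treatment. The first condition in
#' `config$conditions` is the control.
#'
#' @param config A [simulation_config()]; `planted_fold_changes` provides
#'   the ground truth.
#' @param gene_ids Target gene ids (default: the true-member ids implied by
#'   the config).
#' @return A `ct_table` data.frame; attribute `planted` echoes the planted
#'   folds.
#' @export
generate_ct_table <- function(config, gene_ids = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(gene_ids)) {
    gene_ids <- sprintf("SIMLOX%02d", seq_len(config$n_true_family))
  }
  planted <- config$planted_fold_changes
  if (!is.null(planted) && any(planted$fold <= 0)) {
    stop("planted fold changes must be > 0")
  }
  old <- .Random.seed_safe()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 1013L)
  control <- config$conditions[1L]
  rows <- list()
  for (cond in config$conditions) {
    for (tp in config$timepoints) {
      for (rep_i in seq_len(config$replicates)) {
        sample_id <- sprintf("%s_t%g_r%d", cond, tp, rep_i)
        for (g in gene_ids) {
          fold <- 1
          if (!is.null(planted) && cond != control) {
            hit <- planted$gene_id == g & planted$condition == cond &
              planted$timepoint == tp
            if (any(hit)) fold <- planted$fold[hit][1L]
          }
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sample_id, gene_id = g, condition = cond,
            timepoint = tp, replicate = rep_i,
            ct = config$baseline_ct - log2(fold) +
              stats::rnorm(1L, 0, config$ct_noise_sd))
        }
        for (rg in names(config$reference_gene_ct)) {
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sample_id, gene_id = rg, condition = cond,
            timepoint = tp, replicate = rep_i,
            ct = config$reference_gene_ct[[rg]] +
              stats::rnorm(1L, 0, config$ct_noise_sd))
        }
      }
    }
  }
  out <- as_ct_table(do.call(rbind, rows))
  attr(out, "planted") <- planted
  out
}
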