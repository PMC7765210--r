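test_that("the generator is byte-deterministic under a fixed seed", {
  cfg <- simulation_config(seed = 77)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  b1 <- generate_genome_bundle(cfg, d1)
  b2 <- generate_genome_bundle(cfg, d2)
  for (f in names(b1$paths)) {
    expect_identical(unname(tools::md5sum(b1$paths[[f]])),
                     unname(tools::md5sum(b2$paths[[f]])),
                     label = paste("checksum of", f))
  }
  # a different seed changes the genome
  b3 <- generate_genome_bundle(simulation_config(seed = 78),
                               withr::local_tempdir())
  expect_false(unname(tools::md5sum(b1$paths[["genome"]])) ==
                 unname(tools::md5sum(b3$paths[["genome"]])))
})

test_that("manifest counts and gene composition match the configuration", {
  cfg <- simulation_config(seed = 5)
  b <- generate_genome_bundle(cfg, withr::local_tempdir())
  man <- b$manifest
  expect_identical(nrow(man), cfg$n_true_family + cfg$n_decoys)
  expect_identical(anyDuplicated(man$gene_id), 0L)
  expect_identical(sum(man$role == "true"), cfg$n_true_family)
  expect_identical(sum(man$role == "decoy"), cfg$n_decoys)
  expect_identical(as.integer(table(man$subfamily)[["9-LOX"]]), 2L)
  expect_identical(as.integer(table(man$subfamily)[["13-LOX"]]), 7L)
  cl <- table(man$cluster_id)
  expect_identical(sort(as.integer(cl)), c(2L, 3L))
  # every CDS is a whole number of codons and ends in a stop
  expect_true(all(nchar(b$cds) %% 3L == 0L))
  last <- substring(b$cds, nchar(b$cds) - 2L, nchar(b$cds))
  expect_true(all(last %in% c("TAA", "TAG", "TGA")))
  # ORF / protein arithmetic holds for every gene
  expect_identical(orf_to_protein_length(man$orf_bp), man$protein_aa)
})

test_that("invalid configurations fail with explicit constraint messages", {
  expect_error(simulation_config(tandem_clusters = list(list(size = 6, max_span = 1e5))),
               "\\[2, 5\\]")
  expect_error(simulation_config(n_true_family = 3,
                                 subfamily_split = c("9-LOX" = 1, "13-LOX" = 1)),
               "n_true_family")
  expect_error(simulation_config(planted_fold_changes = data.frame(
    gene_id = "g", condition = "t", timepoint = 1, fold = 0)), "> 0")
  expect_error(
    generate_genome_bundle(simulation_config(scaffold_length = 20000L),
                           withr::local_tempdir()),
    "placement infeasible")
})

test_that("parsing the written bundle reproduces the manifest exactly", {
  b <- generate_genome_bundle(simulation_config(seed = 9),
                              withr::local_tempdir())
  models <- read_gff3(b$paths[["gff3"]])
  gm <- gene_model_table(models)
  man <- b$manifest[match(gm$gene_id, b$manifest$gene_id), ]
  expect_identical(gm$scaffold, man$scaffold)
  expect_identical(gm$start, man$start)
  expect_identical(gm$end, man$end)
  expect_identical(gm$strand, man$strand)
  expect_identical(gm$genomic_bp, man$genomic_bp)
  expect_identical(gm$orf_bp, man$orf_bp)
  expect_identical(gm$n_exons, as.integer(man$n_exons))
  # splicing the genome by the GFF3 models regenerates every CDS
  genome <- read_fasta(b$paths[["genome"]], "nucleotide")
  cds <- read_fasta(b$paths[["cds"]], "nucleotide")
  for (g in names(models)) {
    expect_identical(extract_cds(models[[g]], genome), cds[[g]],
                     label = paste("CDS of", g))
  }
})

test_that("planted 5-His signatures hit all true members and no missing-5His decoy", {
  cfg <- simulation_config(seed = 13,
                           decoy_modes = c("missing-5His", "truncated-LOX",
                                           "missing-LOX-domain"))
  b <- generate_genome_bundle(cfg, withr::local_tempdir())
  man <- b$manifest
  hits <- vapply(b$proteins, function(p) nrow(scan_five_his(p)) > 0, logical(1))
  expect_true(all(hits[man$gene_id[man$role == "true"]]))
  no5 <- man$gene_id[!is.na(man$decoy_mode) & man$decoy_mode == "missing-5His"]
  expect_true(length(no5) >= 1L)
  expect_false(any(hits[no5]))
})

test_that("the bona-fide filter recovers exactly the manifest truth on mixed decoys", {
  cfg <- simulation_config(seed = 29, n_true_family = 12L, n_decoys = 5L,
                           subfamily_split = c("9-LOX" = 4, "13-LOX" = 8),
                           decoy_modes = c("missing-LOX-domain",
                                           "truncated-LOX", "missing-5His"))
  b <- generate_genome_bundle(cfg, withr::local_tempdir())
  pr <- read_fasta(b$paths[["proteins"]], "protein")
  filt <- bona_fide_filter(names(pr), scan_candidates(pr))
  man <- b$manifest
  expect_setequal(filt$gene_id[filt$bona_fide],
                  man$gene_id[man$role == "true"])
  # rejection reasons line up with the planted decoy modes
  reasons <- filt$reason[match(man$gene_id[man$role == "decoy"], filt$gene_id)]
  modes <- man$decoy_mode[man$role == "decoy"]
  expect_true(all(reasons[modes == "missing-LOX-domain"] ==
                    "missing_or_incomplete_LOX"))
  expect_true(all(reasons[modes == "truncated-LOX"] ==
                    "missing_or_incomplete_LOX"))
  expect_true(all(reasons[modes == "missing-5His"] == "missing_5HIS_in_LOX"))
})

test_that("subfamily and type assignments agree with the manifest labels", {
  b <- generate_genome_bundle(simulation_config(seed = 31),
                              withr::local_tempdir())
  man <- b$manifest[b$manifest$role == "true", ]
  asg <- assign_subfamily(b$proteins[man$gene_id],
                          archetype_reference_proteins())
  expect_identical(asg$subfamily, man$subfamily)
  expect_identical(asg$transit_peptide, man$transit_peptide)
  is13 <- man$subfamily == "13-LOX"
  expect_identical(asg$lox13_type[is13], man$lox13_type[is13])
  # the two archetypes themselves are strongly divergent
  arch <- subfamily_archetypes()
  al <- global_align(arch[[1]], arch[[2]], alignment_params("protein"))
  expect_lt(al$identity, 60)
})

test_that("Ct generation reproduces planted folds exactly at zero noise", {
  pf <- data.frame(gene_id = "SIMLOX01", condition = "treated",
                   timepoint = 6, fold = 4)
  cfg <- simulation_config(seed = 3, planted_fold_changes = pf,
                           ct_noise_sd = 0)
  ct <- generate_ct_table(cfg)
  res <- delta_delta_ct(ct, sprintf("SIMLOX%02d", 1:9),
                        c("ACT", "R18S"), "control")
  planted <- res$gene_id == "SIMLOX01" & res$condition == "treated" &
    res$timepoint == 6
  expect_equal(res$fold[planted], 4)
  expect_true(all(abs(res$delta_delta_ct[!planted]) < 1e-12))
  # null config: ddCt identically zero everywhere
  ct0 <- generate_ct_table(simulation_config(seed = 4, ct_noise_sd = 0))
  res0 <- delta_delta_ct(ct0, sprintf("SIMLOX%02d", 1:9),
                         c("ACT", "R18S"), "control")
  expect_true(all(abs(res0$delta_delta_ct) < 1e-12))
})
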