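test_that("intron phases follow cumulative CDS length mod 3", {
  single <- gene_model("g1", "s", 1, 300, "+", cbind(1, 300))
  st <- intron_phases(single)
  expect_identical(st$intron_phases, integer(0))
  expect_identical(st$intron_lengths, integer(0))
  two <- gene_model("g2", "s", 1, 400, "+", cbind(c(1, 251), c(100, 300)))
  st2 <- intron_phases(two)
  expect_identical(st2$exon_lengths, c(100L, 50L))
  expect_identical(st2$intron_lengths, 150L)
  expect_identical(st2$intron_phases, 1L)  # 100 mod 3
  # minus strand: phases computed 5'->3' on the coding strand
  minus <- gene_model("g3", "s", 1, 400, "-", cbind(c(1, 251), c(100, 300)))
  expect_identical(intron_phases(minus)$exon_lengths, c(50L, 100L))
  expect_identical(intron_phases(minus)$intron_phases, 2L)  # 50 mod 3
})

test_that("phases round-trip through written GFF3 on synthetic bundles", {
  dir <- withr::local_tempdir()
  b <- generate_genome_bundle(simulation_config(seed = 11), dir)
  models <- suppressWarnings(read_gff3(b$paths[["gff3"]]))
  for (m in models) {
    st <- intron_phases(m)
    # conservation: total CDS is a whole number of codons
    expect_identical(sum(st$exon_lengths) %% 3L, 0L)
    # independent recomputation from the raw GFF3 text
    raw <- read.delim(b$paths[["gff3"]], header = FALSE, comment.char = "#")
    cdsr <- raw[raw$V3 == "CDS" & grepl(paste0("Parent=", m$gene_id, ".t1"),
                                        raw$V9, fixed = TRUE), ]
    cdsr <- cdsr[order(cdsr$V4), ]
    lens <- cdsr$V5 - cdsr$V4 + 1L
    if (m$strand == "-") lens <- rev(lens)
    n <- length(lens)
    expected <- if (n > 1L) as.integer(cumsum(lens)[-n] %% 3L) else integer(0)
    expect_identical(st$intron_phases, expected)
  }
})

test_that("published coordinates and identities give two tandem arrays, no segmental", {
  tab <- lox_gene_table()
  models_df <- data.frame(
    gene_id = tab$gene_name,
    scaffold = sub("G\\d+$", "", tab$sequence_id),
    start = tab$start, end = tab$end)
  idm <- identity_matrix_from_pairs(lox_identity_pairs(), tab$gene_name,
                                    which = "aa_identity")
  calls <- detect_duplications(models_df, idm)
  tandem <- calls[calls$kind == "tandem", ]
  expect_identical(nrow(tandem), 2L)
  expect_setequal(tandem$members,
                  c("SpLOX1,SpLOX2", "SpLOX6,SpLOX7,SpLOX8"))
  expect_identical(sum(calls$kind == "segmental"), 0L)
  expect_true(all(tandem$span_bp <= 100000L))
})

test_that("distance and identity gates are both enforced", {
  df <- data.frame(gene_id = c("a", "b"), scaffold = "s",
                   start = c(1L, 200001L), end = c(5000L, 205000L))
  idm <- structure(list(
    identity = matrix(c(100, 95, 95, 100), 2, 2,
                      dimnames = list(c("a", "b"), c("a", "b"))),
    similarity = matrix(c(100, 80, 80, 100), 2, 2,
                        dimnames = list(c("a", "b"), c("a", "b")))),
    class = "identity_matrix")
  # 200 kb apart: no tandem despite high identity; similarity below 90: no segmental
  expect_identical(nrow(detect_duplications(df, idm)), 0L)
  # same pair within the window becomes a tandem array
  df2 <- df; df2$start[2] <- 50001L; df2$end[2] <- 55000L
  calls <- detect_duplications(df2, idm)
  expect_identical(calls$kind, "tandem")
  # missing matrix entry is an error
  df3 <- rbind(df2, data.frame(gene_id = "c", scaffold = "s",
                               start = 60000L, end = 61000L))
  expect_error(detect_duplications(df3, idm), "missing")
})

test_that("planted tandem clusters are recovered exactly from the manifest", {
  for (seed in c(101, 102, 103)) {
    dir <- withr::local_tempdir()
    b <- generate_genome_bundle(simulation_config(seed = seed), dir)
    man <- b$manifest[b$manifest$role == "true", ]
    pr <- read_fasta(b$paths[["proteins"]], "protein")[man$gene_id]
    idm <- identity_matrix(pr, alignment_params("protein"))
    calls <- detect_duplications(man, idm)
    expect_identical(calls$kind, rep("tandem", 2L))
    expected <- vapply(split(man$gene_id, man$cluster_id), paste,
                       character(1), collapse = ",")
    expect_setequal(calls$members, unname(expected))
  }
})
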