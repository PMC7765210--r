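test_that("alignment distances match closed forms and a column-count oracle", {
  al <- c(a = "MKLVW", b = "MKLVW")
  expect_true(all(distances_from_alignment(al) == 0))
  al2 <- c(a = "AAAA", b = "AACC")  # p = 0.5
  expect_equal(distances_from_alignment(al2, "p")["a", "b"], 0.5)
  expect_equal(distances_from_alignment(al2, "poisson")["a", "b"],
               -log(0.5), tolerance = 1e-12)
  expect_error(distances_from_alignment(c(a = "AA", b = "CC"), "poisson"),
               "Poisson")
  expect_error(distances_from_alignment(c(a = "AA-", b = "--A")), "comparable")
  # column-by-column oracle on random gapped alignments
  set.seed(31)
  for (k in 1:20) {
    L <- 60
    mk <- function() paste(sample(c("A", "C", "D", "-"), L, TRUE,
                                  prob = c(.3, .3, .3, .1)), collapse = "")
    al3 <- c(x = mk(), y = mk())
    cx <- strsplit(al3[1], "")[[1]]; cy <- strsplit(al3[2], "")[[1]]
    ok <- cx != "-" & cy != "-"
    expect_equal(distances_from_alignment(al3, "p")["x", "y"],
                 sum(cx[ok] != cy[ok]) / sum(ok))
  }
})

test_that("NJ solves the three-taxon system exactly", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)
  expect_identical(ape::Ntip(tr), 3L)
  # three-point formulas: la = (dab + dac - dbc)/2, etc.
  cd <- stats::cophenetic(tr)[c("a", "b", "c"), c("a", "b", "c")]
  expect_equal(cd, d, tolerance = 1e-12)
  expect_error(neighbor_joining(d[1:2, 1:2]), "3 taxa")
})

test_that("NJ recovers random additive matrices exactly (up to 12 taxa)", {
  set.seed(17)
  for (k in 1:12) {
    n <- sample(4:12, 1)
    ad <- random_additive(n)
    tr <- neighbor_joining(ad$d)
    expect_identical(attr(tr, "clamped_branches"), 0L)
    expect_identical(as.integer(ape::dist.topo(tr, ad$tree)), 0L)
    cd <- stats::cophenetic(tr)[rownames(ad$d), colnames(ad$d)]
    expect_equal(cd, ad$d, tolerance = 1e-8)
  }
})

test_that("bootstrap supports separate two deep clades and are reproducible", {
  set.seed(23)
  base1 <- random_protein(120)
  mut <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    i <- sample(length(ch), k)
    ch[i] <- sample(c("A", "R", "N", "D"), k, TRUE)
    paste(ch, collapse = "")
  }
  base2 <- mut(base1, 55)  # ~45% divergent sister clade, Poisson-safe
  al <- c(a1 = mut(base1, 4), a2 = mut(base1, 4), a3 = mut(base1, 4),
          b1 = mut(base2, 4), b2 = mut(base2, 4), b3 = mut(base2, 4))
  tr <- bootstrap_support(al, replicates = 100, seed = 99)
  expect_false(attr(tr, "degenerate"))
  # the a|b bipartition is an edge of the tree with very high support
  parts <- ape::prop.part(tr)
  labs <- attr(parts, "labels")
  grp <- lapply(parts, function(p) sort(labs[p]))
  ab_node <- which(vapply(grp, function(g)
    identical(g, c("a1", "a2", "a3")) || identical(g, c("b1", "b2", "b3")),
    logical(1)))
  expect_true(length(ab_node) >= 1)
  expect_true(all(tr$node.label[ab_node] >= 95))
  # determinism under a fixed seed
  tr2 <- bootstrap_support(al, replicates = 100, seed = 99)
  expect_identical(tr$node.label, tr2$node.label)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
  # degenerate input is flagged
  trd <- bootstrap_support(c(x = "MKL", y = "MKL", z = "MKL"),
                           replicates = 10, seed = 1)
  expect_true(attr(trd, "degenerate"))
})

test_that("bipartition supports do not depend on taxon input order", {
  set.seed(29)
  base1 <- random_protein(100)
  swap <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    i <- sample(length(ch), k)
    ch[i] <- sample(c("A", "R", "N", "D", "G"), k, TRUE)
    paste(ch, collapse = "")
  }
  base2 <- swap(base1, 45)
  al <- c(a1 = swap(base1, 3), a2 = swap(base1, 3),
          b1 = swap(base2, 3), b2 = swap(base2, 3), c1 = swap(base1, 25))
  tr1 <- bootstrap_support(al, replicates = 50, seed = 7)
  tr2 <- bootstrap_support(al[c(3, 5, 1, 4, 2)], replicates = 50, seed = 7)
  sup <- function(tr) {
    parts <- ape::prop.part(tr); labs <- attr(parts, "labels")
    keys <- vapply(parts, function(p) paste(sort(labs[p]), collapse = "+"),
                   character(1))
    setNames(tr$node.label, keys)[order(keys)]
  }
  s1 <- sup(tr1); s2 <- sup(tr2)
  shared <- intersect(names(s1), names(s2))
  expect_gt(length(shared), 0)
  # same bipartitions receive statistically indistinguishable support
  expect_true(all(abs(s1[shared] - s2[shared]) <= 15))
})

test_that("the synthetic family tree splits into the two manifest subfamilies", {
  b <- generate_genome_bundle(simulation_config(seed = 47),
                              withr::local_tempdir())
  man <- b$manifest[b$manifest$role == "true", ]
  msa <- align_progressive(b$proteins[man$gene_id],
                           alignment_params("protein"))
  tr <- neighbor_joining(distances_from_alignment(msa, "poisson"))
  parts <- ape::prop.part(tr)
  labs <- attr(parts, "labels")
  clades <- lapply(parts, function(p) labs[p])
  grp9 <- man$gene_id[man$subfamily == "9-LOX"]
  grp13 <- man$gene_id[man$subfamily == "13-LOX"]
  # one bipartition separates the two subfamilies
  expect_true(any(vapply(clades, setequal, logical(1), grp9)) ||
                any(vapply(clades, setequal, logical(1), grp13)))
})

test_that("center-star alignment honors its contracts", {
  pp <- alignment_params("protein")
  two <- c(x = "MKLVWFHE", y = "MKLVWFHE")
  expect_identical(unname(as.vector(align_progressive(two, pp))),
                   unname(two))
  # single indel: gap placed at the deletion
  pair <- c(x = "MKKKLVWFHE", y = "MKKLVWFHE")
  al <- align_progressive(pair, pp)
  expect_identical(nchar(al[["x"]]), nchar(al[["y"]]))
  expect_identical(sum(strsplit(al[["y"]], "")[[1]] == "-"), 1L)
  # de-gapping restores every input
  set.seed(37)
  seqs <- setNames(vapply(1:6, function(i)
    random_protein(sample(40:70, 1)), character(1)), paste0("s", 1:6))
  al2 <- align_progressive(seqs, pp)
  expect_identical(length(unique(nchar(al2))), 1L)
  for (n in names(seqs)) {
    expect_identical(gsub("-", "", al2[[n]]), seqs[[n]])
  }
})
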