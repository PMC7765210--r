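# Build a 15-candidate domain table mirroring the published situation:
# nine fully equipped genes plus six putatives lacking a complete LOX domain.
fifteen_candidate_table <- function() {
  nine <- as.data.frame(lox_domain_table())
  six <- do.call(rbind, lapply(1:6, function(i) {
    data.frame(gene_id = paste0("putative", i),
               domain = c("PLAT", "LOX", "5HIS"),
               aa_start = c(20L, 150L, 300L),
               aa_end = c(120L, 150L + 199L, 337L),  # LOX only 200 aa wide
               source = "scan")
  }))
  as_domain_table(rbind(nine, six))
}

test_that("15 candidates with 6 incomplete-LOX putatives filter to 9 bona fide", {
  dom <- fifteen_candidate_table()
  res <- bona_fide_filter(unique(dom$gene_id), dom)
  expect_identical(sum(res$bona_fide), 9L)
  expect_setequal(res$gene_id[res$bona_fide], sprintf("SpLOX%d", 1:9))
  expect_true(all(res$reason[!res$bona_fide] == "missing_or_incomplete_LOX"))
  expect_true(all(res$reason[res$bona_fide] == "ok"))
})

test_that("each rejection reason triggers on its own defect", {
  base <- data.frame(gene_id = "g", domain = c("PLAT", "LOX", "5HIS"),
                     aa_start = c(10L, 150L, 400L),
                     aa_end = c(110L, 800L, 437L), source = "x")
  ok <- bona_fide_filter("g", as_domain_table(base))
  expect_true(ok$bona_fide)
  no_plat <- bona_fide_filter("g", as_domain_table(base[-1L, ]))
  expect_identical(no_plat$reason, "missing_PLAT")
  no_lox <- bona_fide_filter("g", as_domain_table(base[-2L, ]))
  expect_identical(no_lox$reason, "missing_or_incomplete_LOX")
  no_his <- bona_fide_filter("g", as_domain_table(base[-3L, ]))
  expect_identical(no_his$reason, "missing_5HIS_in_LOX")
  # 5HIS outside the LOX interval does not rescue the candidate
  out <- base; out$aa_start[3] <- 900L; out$aa_end[3] <- 937L
  expect_identical(bona_fide_filter("g", as_domain_table(out))$reason,
                   "missing_5HIS_in_LOX")
  # empty candidate set
  expect_identical(nrow(bona_fide_filter(character(0),
                                         as_domain_table(base))), 0L)
})

test_that("removing a domain row never converts a rejected candidate to bona fide", {
  dom <- fifteen_candidate_table()
  full <- bona_fide_filter(unique(dom$gene_id), dom)
  set.seed(5)
  for (k in 1:25) {
    drop <- sample(nrow(dom), sample(1:10, 1))
    sub <- bona_fide_filter(unique(dom$gene_id), as_domain_table(dom[-drop, ]))
    was_rejected <- full$gene_id[!full$bona_fide]
    expect_false(any(sub$bona_fide[sub$gene_id %in% was_rejected]))
  }
})

test_that("transit-peptide heuristic follows its compositional rule", {
  expect_true(as.logical(predict_transit_peptide(strrep("S", 80))))
  expect_false(as.logical(predict_transit_peptide(strrep("E", 80))))
  short <- predict_transit_peptide(strrep("S", 30))
  expect_true(as.logical(short))
  expect_true(attr(short, "short"))
  # boundary: exactly at the S+T threshold with positive charge passes
  p <- paste0(strrep("S", 15), strrep("K", 2), strrep("A", 43))
  expect_true(as.logical(predict_transit_peptide(p)))
  # acid content alone disqualifies
  p2 <- paste0(strrep("S", 20), strrep("E", 6), strrep("A", 34))
  expect_false(as.logical(predict_transit_peptide(p2)))
})

test_that("references classify to themselves with 100% identity", {
  refs <- archetype_reference_proteins()
  res <- assign_subfamily(setNames(refs[1], "probe"), refs)
  expect_identical(res$subfamily, "9-LOX")
  expect_identical(res$identity, 100)
  expect_error(assign_subfamily(setNames(refs[1], "p"), character(0)),
               "reference")
})

test_that("subfamily ratio matches the published family compositions", {
  expect_identical(subfamily_ratio(c("13-LOX" = 7, "9-LOX" = 2)), 3.50)
  expect_identical(subfamily_ratio(c("13-LOX" = 2, "9-LOX" = 2)), 1.00)
  expect_true(is.na(subfamily_ratio(c("13-LOX" = 4, "9-LOX" = 0))))
  expect_error(subfamily_ratio(c("13-LOX" = -1, "9-LOX" = 2)),
               "non-negative")
})
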