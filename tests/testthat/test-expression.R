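test_that("ddCt arithmetic matches the closed form", {
  ct <- manual_ct_table(target_ct_control = 25, target_ct_treated = 23)
  res <- delta_delta_ct(ct, "G1", "REF", "control")
  treated <- res[res$condition == "treated", ]
  expect_equal(treated$delta_delta_ct, -2)
  expect_equal(treated$fold, 4)
  # identical groups give fold exactly 1
  ct2 <- manual_ct_table(25, 25)
  res2 <- delta_delta_ct(ct2, "G1", "REF", "control")
  expect_equal(res2$fold[res2$condition == "treated"], 1)
  expect_equal(res2$fold[res2$condition == "control"], 1)
})

test_that("folds are invariant to per-sample Ct shifts (reference normalization)", {
  ct <- manual_ct_table(25, 23)
  shifted <- ct
  pick <- shifted$sample_id == "treated_r2"
  shifted$ct[pick] <- shifted$ct[pick] + 3.7  # global shift of one sample
  r0 <- delta_delta_ct(ct, "G1", "REF", "control")
  r1 <- delta_delta_ct(as_ct_table(shifted), "G1", "REF", "control")
  expect_equal(r1$fold, r0$fold)
})

test_that("missing references and absent control expression are reported", {
  ct <- manual_ct_table(25, 23)
  broken <- as_ct_table(ct[!(ct$sample_id == "treated_r1" &
                               ct$gene_id == "REF"), ])
  expect_error(delta_delta_ct(broken, "G1", "REF", "control"), "treated.*rep1")
  # gene undetected in the control group
  und <- ct
  und$ct[und$condition == "control" & und$gene_id == "G1"] <- NA
  res <- delta_delta_ct(as_ct_table(und), "G1", "REF", "control")
  expect_true(all(res$flag == "not_expressed"))
  expect_true(all(is.na(res$fold)))
})

test_that("with one treatment group Dunnett reduces to the pooled t-test", {
  set.seed(41)
  vals <- c(rnorm(4, 10), rnorm(4, 11))
  grp <- rep(c("ctrl", "trt"), each = 4)
  ad <- anova_dunnett(vals, grp, "ctrl", mc_draws = 200000, seed = 2)
  tt <- t.test(vals[grp == "trt"], vals[grp == "ctrl"], var.equal = TRUE)
  expect_equal(ad$comparisons$p_adj, tt$p.value, tolerance = 0.01)
  expect_equal(ad$comparisons$p_raw, tt$p.value, tolerance = 1e-10)
})

test_that("Dunnett adjusted p is never below raw p and matches multcomp", {
  set.seed(43)
  vals <- c(rnorm(3, 0), rnorm(3, 0.5), rnorm(3, 1.5), rnorm(3, -0.4),
            rnorm(3, 0.1))
  grp <- rep(c("ctrl", "g1", "g2", "g3", "g4"), each = 3)
  ad <- anova_dunnett(vals, grp, "ctrl", mc_draws = 200000, seed = 3)
  expect_true(all(ad$comparisons$p_adj >= ad$comparisons$p_raw - 1e-9))
  # independent oracle: multcomp's closed-form Dunnett adjustment
  df <- data.frame(y = vals, g = relevel(factor(grp), "ctrl"))
  glht <- multcomp::glht(stats::aov(y ~ g, df),
                         linfct = multcomp::mcp(g = "Dunnett"))
  ref <- summary(glht, test = multcomp::adjusted("single-step"))
  ref_p <- as.numeric(ref$test$pvalues)
  ours <- ad$comparisons$p_adj[match(paste0("g", 1:4), ad$comparisons$group)]
  expect_equal(ours, ref_p, tolerance = 0.01)
  # degenerate data is an explicit error
  expect_error(anova_dunnett(rep(1, 6), rep(c("a", "b"), each = 3), "a"),
               "degenerate")
})

test_that("Dunnett family-wise error rate is calibrated at alpha = 0.05", {
  n <- 3L; k <- 4L  # four treatments vs control, triplicates
  df <- (k + 1L) * n - (k + 1L)
  maxt <- dunnett_null_maxt(rep(n, k), n, df, draws = 200000, seed = 5)
  crit <- quantile(maxt, 0.95)
  set.seed(6)
  nsim <- 1000L
  rej <- logical(nsim)
  for (s in seq_len(nsim)) {
    y <- rnorm((k + 1L) * n)
    g <- rep(0:k, each = n)
    means <- tapply(y, g, mean)
    s2 <- sum((y - means[as.character(g)])^2) / df
    t_i <- abs(means[-1] - means[1]) / sqrt(s2 * 2 / n)
    rej[s] <- max(t_i) > crit
  }
  fwer <- mean(rej)
  expect_gte(fwer, 0.03)
  expect_lte(fwer, 0.07)
})

test_that("aging trajectories classify by their stated shape rules", {
  expect_identical(classify_aging_pattern(c(`14` = 1, `21` = 2, `28` = 4)),
                   "monotone-up")
  expect_identical(classify_aging_pattern(c(`14` = 1, `21` = 5, `28` = 2)),
                   "peak-mid")
  expect_identical(classify_aging_pattern(c(`14` = 5, `21` = 3, `28` = 1)),
                   "monotone-down")
  expect_identical(classify_aging_pattern(c(`14` = 1, `21` = 1, `28` = 1)),
                   "static")
  # order of names does not matter
  expect_identical(classify_aging_pattern(c(`28` = 4, `14` = 1, `21` = 2)),
                   "monotone-up")
  expect_error(classify_aging_pattern(c(`14` = 1, `21` = 2)), "three")
})

test_that("treatment responses classify from folds and adjusted p", {
  mk <- function(folds, p) data.frame(fold = folds, p_adj = p)
  expect_identical(classify_treatment_response(
    mk(c(1, 1.1, 0.9, 1), c(0.9, 0.5, 0.7, 0.8))), "static")
  expect_identical(classify_treatment_response(
    mk(c(1, 1.2, 4, 5), c(0.9, 0.4, 0.01, 0.001))), "upregulated")
  expect_identical(classify_treatment_response(
    mk(c(1, 0.3, 0.2, 0.4), c(0.9, 0.01, 0.01, 0.2))), "downregulated")
  expect_identical(classify_treatment_response(
    mk(c(3, 0.3, 0.2, 0.4), c(0.01, 0.01, 0.01, 0.2))), "mixed")
  expect_error(classify_treatment_response(mk(numeric(0), numeric(0))),
               "no timepoints")
})

test_that("planted responses are recovered through the full analysis", {
  pf <- rbind(
    data.frame(gene_id = "SIMLOX01", condition = "treated",
               timepoint = c(6, 12), fold = 4),
    data.frame(gene_id = "SIMLOX02", condition = "treated",
               timepoint = 1, fold = 4),
    data.frame(gene_id = "SIMLOX02", condition = "treated",
               timepoint = c(6, 12), fold = 0.25))
  cfg <- simulation_config(seed = 19, planted_fold_changes = pf)
  ct <- generate_ct_table(cfg, gene_ids = c("SIMLOX01", "SIMLOX02",
                                            "SIMLOX03"))
  ea <- expression_analysis(ct, c("SIMLOX01", "SIMLOX02", "SIMLOX03"),
                            c("ACT", "R18S"), "control",
                            mc_draws = 50000, seed = 1)
  by_gene <- function(g) ea[ea$gene_id == g & ea$condition == "treated", ]
  expect_identical(classify_treatment_response(by_gene("SIMLOX01")),
                   "upregulated")
  expect_identical(classify_treatment_response(by_gene("SIMLOX02")), "mixed")
  expect_identical(classify_treatment_response(by_gene("SIMLOX03")), "static")
})
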