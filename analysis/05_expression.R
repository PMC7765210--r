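#!/usr/bin/env Rscript
# Stage 5: qPCR expression analysis on two simulated designs.
#
# Design A (elicitor treatment): control vs treated at 0/1/3/6/12 h,
# triplicates, with planted inductions/repressions; relative expression by
# 2^-ddCt against two reference genes, one-way ANOVA + Dunnett per
# timepoint, response classification per gene.
# Design B (culture aging): expression at day 14/21/28 with planted
# trajectories; classified into monotone-up / peak-mid / monotone-down.

library(loxfamily)

run_dir <- "results/run"
genes <- sprintf("SIMLOX%02d", 1:9)

## Design A: treatment time course
planted <- rbind(
  data.frame(gene_id = "SIMLOX02", condition = "treated",
             timepoint = c(3, 6, 12), fold = 4),
  data.frame(gene_id = "SIMLOX04", condition = "treated",
             timepoint = c(6, 12), fold = 6),
  data.frame(gene_id = "SIMLOX06", condition = "treated",
             timepoint = c(6, 12), fold = 0.2),
  data.frame(gene_id = "SIMLOX01", condition = "treated",
             timepoint = 1, fold = 3),
  data.frame(gene_id = "SIMLOX01", condition = "treated",
             timepoint = c(6, 12), fold = 0.25))
cfg <- simulation_config(seed = 1, planted_fold_changes = planted)
ct <- generate_ct_table(cfg, gene_ids = genes)
write_tsv(ct, file.path(run_dir, "ct_table_treatment.tsv"))
ea <- expression_analysis(ct, genes, c("ACT", "R18S"), "control",
                          mc_draws = 50000, seed = 1)
write_tsv(ea, file.path(run_dir, "expression_treatment.tsv"))
resp <- vapply(genes, function(g)
  classify_treatment_response(ea[ea$gene_id == g &
                                   ea$condition == "treated", ]),
  character(1))
write_tsv(data.frame(gene_id = genes, response = resp),
          file.path(run_dir, "treatment_response_calls.tsv"))
cat("treatment response calls:\n"); print(table(resp))

## Design B: culture aging
aging_fold <- rbind(
  data.frame(gene_id = "SIMLOX01", condition = c("d21", "d28"),
             timepoint = 0, fold = c(2, 5)),          # monotone-up
  data.frame(gene_id = "SIMLOX03", condition = c("d21", "d28"),
             timepoint = 0, fold = c(6, 2)),          # peak-mid
  data.frame(gene_id = "SIMLOX06", condition = c("d21", "d28"),
             timepoint = 0, fold = c(0.5, 0.2)))      # monotone-down
cfgB <- simulation_config(seed = 2, conditions = c("d14", "d21", "d28"),
                          timepoints = 0,
                          planted_fold_changes = aging_fold)
ctB <- generate_ct_table(cfgB, gene_ids = c("SIMLOX01", "SIMLOX03",
                                            "SIMLOX06"))
resB <- delta_delta_ct(ctB, c("SIMLOX01", "SIMLOX03", "SIMLOX06"),
                       c("ACT", "R18S"), "d14")
patterns <- vapply(unique(resB$gene_id), function(g) {
  m <- resB[resB$gene_id == g, ]
  classify_aging_pattern(setNames(m$fold,
                                  c("14", "21", "28")[match(m$condition,
                                                            c("d14", "d21",
                                                              "d28"))]))
}, character(1))
write_tsv(data.frame(gene_id = names(patterns), pattern = patterns),
          file.path(run_dir, "aging_pattern_calls.tsv"))
cat("aging pattern calls:\n"); print(patterns)
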