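#' Relative quantification by the 2^-ddCt method
#'
#' Per sample (condition x timepoint x replicate), the target Ct is
#' normalized by the arithmetic mean of the reference-gene Cts (equivalent
#' to the geometric mean of reference quantities): `dCt = Ct_target -
#' mean(Ct_refs)`. Per group (condition x timepoint), `ddCt = mean dCt -
#' mean dCt(control condition at the same timepoint)` and fold change is
#' `2^-ddCt`. Per-replicate dCt values are retained (attribute
#' `"replicates"`) for the downstream ANOVA, which is run on the dCt scale.
#'
#' A target with no detectable Ct in the control group is flagged
#' `"not_expressed"` rather than dropped silently. A sample missing a
#' reference gene is an error.
#'
#' @param ct A `ct_table` (see [read_ct_table()]); `NA` Ct = undetected at
#'   the cycle ceiling.
#' @param targets Character vector of target gene ids.
#' @param references Character vector of reference (housekeeping) gene ids.
#' @param control_condition Label of the control condition.
#' @return data.frame with `gene_id`, `condition`, `timepoint`, `n`,
#'   `delta_ct`, `delta_delta_ct`, `fold`, `flag`; attribute `"replicates"`
#'   holds per-replicate dCt values.
#' @export
delta_delta_ct <- function(ct, targets, references, control_condition) {
  stopifnot(length(references) >= 1L)
  ct <- as.data.frame(ct)
  if (!control_condition %in% ct$condition) {
    stop("control condition '", control_condition, "' absent from Ct table")
  }
  samples <- unique(ct[, c("condition", "timepoint", "replicate")])
  reps <- list()
  for (i in seq_len(nrow(samples))) {
    sel <- ct$condition == samples$condition[i] &
      ct$timepoint == samples$timepoint[i] &
      ct$replicate == samples$replicate[i]
    sub <- ct[sel, , drop = FALSE]
    refs <- sub[sub$gene_id %in% references, , drop = FALSE]
    if (!all(references %in% refs$gene_id) || anyNA(refs$ct)) {
      stop("missing reference gene measurement in sample ",
           samples$condition[i], "/", samples$timepoint[i],
           "/rep", samples$replicate[i])
    }
    ref_mean <- mean(refs$ct)
    tg <- sub[sub$gene_id %in% targets, , drop = FALSE]
    if (nrow(tg) == 0L) next
    reps[[i]] <- data.frame(gene_id = tg$gene_id,
                            condition = samples$condition[i],
                            timepoint = samples$timepoint[i],
                            replicate = samples$replicate[i],
                            delta_ct = tg$ct - ref_mean)
  }
  rd <- do.call(rbind, reps)
  out <- list()
  for (g in targets) {
    rg <- rd[rd$gene_id == g & !is.na(rd$delta_ct), , drop = FALSE]
    ctrl <- rg[rg$condition == control_condition, , drop = FALSE]
    groups <- unique(rg[, c("condition", "timepoint")])
    for (k in seq_len(nrow(groups))) {
      sel <- rg$condition == groups$condition[k] &
        rg$timepoint == groups$timepoint[k]
      dct <- mean(rg$delta_ct[sel])
      ctrl_sel <- ctrl$timepoint == groups$timepoint[k]
      if (!any(ctrl_sel)) {
        out[[length(out) + 1L]] <- data.frame(
          gene_id = g, condition = groups$condition[k],
          timepoint = groups$timepoint[k], n = sum(sel), delta_ct = dct,
          delta_delta_ct = NA_real_, fold = NA_real_, flag = "not_expressed")
        next
      }
      ddct <- dct - mean(ctrl$delta_ct[ctrl_sel])
      out[[length(out) + 1L]] <- data.frame(
        gene_id = g, condition = groups$condition[k],
        timepoint = groups$timepoint[k], n = sum(sel), delta_ct = dct,
        delta_delta_ct = ddct, fold = 2^(-ddct), flag = "ok")
    }
  }
  res <- do.call(rbind, out)
  attr(res, "replicates") <- rd
  res
}

#' One-way ANOVA with Dunnett's multiple comparisons against a control
#'
#' The overall p comes from the standard one-way ANOVA F test. Dunnett
#' adjusted p-values are computed from the null distribution of the maximum
#' absolute Dunnett t statistic over all comparisons, estimated by seeded
#' Monte Carlo with the exact pooled-variance correlation structure (shared
#' control mean, shared variance estimate).
#'
#' @param values Numeric response values (e.g. dCt).
#' @param groups Group labels, same length as `values`.
#' @param control Label of the control group.
#' @param mc_draws Monte Carlo draws for the max-|t| null (default 1e5).
#' @param seed RNG seed for the Monte Carlo.
#' @return List with `anova_p`, `df`, and `comparisons` (data.frame:
#'   `group`, `diff`, `t`, `p_raw`, `p_adj`, `stars`).
#' @export
anova_dunnett <- function(values, groups, control, mc_draws = 100000L,
                          seed = 1L) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups), control %in% groups)
  labs <- unique(groups)
  if (length(labs) < 2L) stop("need at least 2 groups")
  ns <- table(groups)
  if (any(ns < 2L)) stop("need at least 2 replicates per group")
  means <- tapply(values, groups, mean)
  sse <- sum((values - means[groups])^2)
  df <- length(values) - length(labs)
  if (sse <= 0) stop("degenerate: zero within-group variance everywhere")
  s2 <- sse / df
  fit <- stats::lm(values ~ factor(groups))
  anova_p <- stats::anova(fit)[["Pr(>F)"]][1L]
  trt <- setdiff(labs, control)
  se <- sqrt(s2 * (1 / ns[trt] + 1 / ns[control]))
  tstat <- (means[trt] - means[control]) / se
  p_raw <- 2 * stats::pt(-abs(tstat), df)
  maxt <- dunnett_null_maxt(ns[trt], ns[[control]], df, mc_draws, seed)
  p_adj <- vapply(abs(tstat), function(tt) mean(maxt >= tt), numeric(1))
  list(anova_p = anova_p, df = df,
       comparisons = data.frame(group = trt,
                                diff = as.numeric(means[trt] - means[control]),
                                t = as.numeric(tstat),
                                p_raw = as.numeric(p_raw),
                                p_adj = p_adj,
                                stars = significance_stars(p_adj),
                                row.names = NULL))
}

#' Monte Carlo null distribution of the maximum absolute Dunnett t
#'
#' Simulates, under the global null, the maximum over comparisons of
#' `|mean_i - mean_0| / (s * sqrt(1/n_i + 1/n_0))` with a shared control
#' mean and a shared chi-square pooled-variance estimate — the correlation
#' structure that makes Dunnett's adjustment less conservative than
#' Bonferroni.
#'
#' @param n_trt Named/unnamed vector of treatment group sizes.
#' @param n_ctrl Control group size.
#' @param df Error degrees of freedom of the pooled variance.
#' @param draws Number of Monte Carlo draws.
#' @param seed RNG seed.
#' @return Numeric vector of `draws` simulated max-|t| values.
#' @export
dunnett_null_maxt <- function(n_trt, n_ctrl, df, draws = 100000L, seed = 1L) {
  k <- length(n_trt)
  old <- .Random.seed_safe()
  set.seed(seed)
  z0 <- stats::rnorm(draws, sd = sqrt(1 / n_ctrl))
  s <- sqrt(stats::rchisq(draws, df) / df)
  maxt <- rep(0, draws)
  for (i in seq_len(k)) {
    zi <- stats::rnorm(draws, sd = sqrt(1 / n_trt[i]))
    ti <- abs(zi - z0) / (s * sqrt(1 / n_trt[i] + 1 / n_ctrl))
    maxt <- pmax(maxt, ti)
  }
  .Random.seed_restore(old)
  maxt
}

#' Significance stars at the conventional thresholds
#' @param p Numeric p-value(s).
#' @return Character vector over `ns`, `*`, `**`, `***`, `****`
#'   (p < 0.05, 0.01, 0.001, 0.0001).
#' @export
significance_stars <- function(p) {
  vapply(p, function(x) {
    if (is.na(x)) NA_character_
    else if (x < 1e-4) "****"
    else if (x < 1e-3) "***"
    else if (x < 1e-2) "**"
    else if (x < 5e-2) "*"
    else "ns"
  }, character(1))
}

#' Full expression analysis: ddCt folds plus ANOVA/Dunnett per timepoint
#'
#' For each target gene and timepoint, runs the ddCt quantification and a
#' one-way ANOVA with Dunnett comparisons of every treatment condition
#' against the control condition, on the dCt scale.
#'
#' @inheritParams delta_delta_ct
#' @param mc_draws,seed Passed to [anova_dunnett()].
#' @return The [delta_delta_ct()] result with `anova_p`, `p_adj` and
#'   `stars` columns merged in (control rows carry `NA`).
#' @export
expression_analysis <- function(ct, targets, references, control_condition,
                                mc_draws = 100000L, seed = 1L) {
  res <- delta_delta_ct(ct, targets, references, control_condition)
  rd <- attr(res, "replicates")
  res$anova_p <- NA_real_; res$p_adj <- NA_real_; res$stars <- NA_character_
  for (g in unique(res$gene_id)) {
    for (tp in unique(res$timepoint[res$gene_id == g])) {
      sub <- rd[rd$gene_id == g & rd$timepoint == tp, , drop = FALSE]
      conds <- unique(sub$condition)
      if (length(conds) < 2L || !control_condition %in% conds) next
      ad <- anova_dunnett(sub$delta_ct, sub$condition, control_condition,
                          mc_draws = mc_draws, seed = seed)
      for (r in seq_len(nrow(ad$comparisons))) {
        sel <- res$gene_id == g & res$timepoint == tp &
          res$condition == ad$comparisons$group[r]
        res$anova_p[sel] <- ad$anova_p
        res$p_adj[sel] <- ad$comparisons$p_adj[r]
        res$stars[sel] <- ad$comparisons$stars[r]
      }
    }
  }
  attr(res, "replicates") <- rd
  res
}

#' Classify an aging expression trajectory over three culture ages
#'
#' Trajectories over days 14/21/28 fall into: monotone-up (rises at both
#' steps), peak-mid (up then down), monotone-down (falls at both steps), or
#' static. Ties break toward static (strict inequalities).
#'
#' @param means Named numeric of length 3: mean expression (fold or dCt
#'   scale, used ordinally) with names giving the three ages in days.
#' @return One of `"monotone-up"`, `"peak-mid"`, `"monotone-down"`,
#'   `"static"`.
#' @export
classify_aging_pattern <- function(means) {
  if (length(means) != 3L || anyNA(means)) {
    stop("need means at exactly three timepoints")
  }
  means <- means[order(as.numeric(names(means)))]
  a <- means[[1L]]; b <- means[[2L]]; c <- means[[3L]]
  if (c > b && b > a) "monotone-up"
  else if (b > a && b > c) "peak-mid"
  else if (a > b && b > c) "monotone-down"
  else "static"
}

#' Classify a treatment response from per-timepoint folds and adjusted p
#'
#' Over a post-treatment time course: `upregulated` if at least one
#' timepoint is significantly above control and none significantly below;
#' `downregulated` symmetrically; `static` if nothing is significant;
#' `mixed` when significant responses go both ways.
#'
#' @param results data.frame for one gene with columns `fold` and `p_adj`
#'   (one row per timepoint).
#' @param alpha Significance threshold on the adjusted p (default 0.05).
#' @return One of `"upregulated"`, `"downregulated"`, `"static"`, `"mixed"`.
#' @export
classify_treatment_response <- function(results, alpha = 0.05) {
  if (nrow(results) == 0L) stop("no timepoints to classify")
  sig <- !is.na(results$p_adj) & results$p_adj < alpha
  up <- any(sig & results$fold > 1)
  down <- any(sig & results$fold < 1)
  if (up && !down) "upregulated"
  else if (down && !up) "downregulated"
  else if (!up && !down) "static"
  else "mixed"
}
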