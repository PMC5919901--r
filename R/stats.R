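#' Descriptive volumetrics: cerebral and cerebellar volumes per group
#'
#' Means and sample standard deviations (n - 1 denominator) of cerebral
#' volume, cerebellar volume and the per-specimen cerebellum/cerebrum
#' ratio (mean of ratios, not ratio of means), by group.
#'
#' @param table data frame with columns `specimen`, `group`, `cerebrum`,
#'   `cerebellum` (volumes; any consistent unit — cc in the fossil tables).
#' @param digits optional rounding applied to the output (e.g. 0 for
#'   volumes and 3 for ratios as printed in fossil studies); default no
#'   rounding.
#' @return data frame: group, n, cerebral_mean, cerebral_sd,
#'   cerebellar_mean, cerebellar_sd, ratio_mean, ratio_sd. Groups of size
#'   1 get NA SDs (flagged by a warning).
#' @export
volume_summary <- function(table, digits = NULL) {
  need <- c("group", "cerebrum", "cerebellum")
  stopifnot(all(need %in% names(table)))
  ratio <- table$cerebellum / table$cerebrum
  gs <- split(seq_len(nrow(table)), table$group)
  if (any(lengths(gs) < 2))
    warning("volume_summary: group of size 1; SD undefined")
  out <- do.call(rbind, lapply(names(gs), function(g) {
    i <- gs[[g]]
    data.frame(
      group = g, n = length(i),
      cerebral_mean = mean(table$cerebrum[i]),
      cerebral_sd = if (length(i) > 1) stats::sd(table$cerebrum[i]) else NA,
      cerebellar_mean = mean(table$cerebellum[i]),
      cerebellar_sd = if (length(i) > 1) stats::sd(table$cerebellum[i]) else NA,
      ratio_mean = mean(ratio[i]),
      ratio_sd = if (length(i) > 1) stats::sd(ratio[i]) else NA,
      stringsAsFactors = FALSE)
  }))
  if (!is.null(digits)) {
    vc <- c("cerebral_mean", "cerebral_sd", "cerebellar_mean", "cerebellar_sd")
    out[vc] <- round(out[vc], digits)
    out[c("ratio_mean", "ratio_sd")] <- round(out[c("ratio_mean", "ratio_sd")],
                                              digits + 3)
  }
  out
}

#' ICV adjustment by pooled residualization
#'
#' Per region, fits `volume = a + b * ICV` pooled across all specimens and
#' returns `residual + grand mean` — adjusted volumes exactly uncorrelated
#' with ICV and invariant to adding a constant to all ICVs.
#'
#' @param table data frame with `volume`, `icv` and a `region` column
#'   (adjustment is done within region); extra columns pass through.
#' @return the table with an added `volume_adj` column.
#' @export
icv_adjust <- function(table) {
  stopifnot(all(c("volume", "icv") %in% names(table)))
  if (stats::var(table$icv) <= 0) stop("icv_adjust: constant ICV")
  region <- if ("region" %in% names(table)) table$region else "all"
  adj <- numeric(nrow(table))
  for (r in unique(region)) {
    i <- which(region == r)
    fit <- stats::lm(volume ~ icv, data = table[i, ])
    adj[i] <- stats::resid(fit) + mean(table$volume[i])
  }
  table$volume_adj <- adj
  table
}

#' One-way ANOVA with Ryan's sequentially rejective pairwise procedure
#'
#' Omnibus one-way ANOVA (error df N - k, matching
#' residualize-then-ANOVA bookkeeping), optionally Bonferroni-corrected
#' across regions (`bonferroni_m`), followed by pairwise comparisons under
#' Ryan's procedure: group means are ordered, and a pair whose means are
#' `r` ranks apart among `k` groups is tested with a pooled-variance t
#' statistic at nominal level `alpha * 2 / (k * (r - 1))`, with the
#' step-down consistency rule that a pair is declared significant only if
#' every enclosing pair is.
#'
#' @param values numeric response (e.g. ICV-adjusted volumes).
#' @param groups group labels (>= 2 groups, each >= 2).
#' @param alpha significance level.
#' @param bonferroni_m number of parallel tests the omnibus alpha is
#'   divided by (default 1).
#' @return list with `omnibus` (F, df1, df2, p, significant) and
#'   `pairwise` data frame (group_i, group_j, rank_span, t, df, p,
#'   alpha_nominal, significant).
#' @export
anova_ryan <- function(values, groups, alpha = 0.05, bonferroni_m = 1) {
  groups <- factor(groups)
  k <- nlevels(groups)
  stopifnot(k >= 2)
  ns <- table(groups)
  if (any(ns == 0)) stop("anova_ryan: empty group")
  N <- length(values)
  fit <- stats::lm(values ~ groups)
  an <- stats::anova(fit)
  Fv <- an[1, "F value"]; df1 <- an[1, "Df"]; df2 <- an[2, "Df"]
  p_om <- an[1, "Pr(>F)"]
  mse <- an[2, "Mean Sq"]
  means <- tapply(values, groups, mean)
  ord <- order(means)
  lev <- levels(groups)[ord]
  pairs <- t(utils::combn(k, 2))
  pw <- data.frame()
  for (row in seq_len(nrow(pairs))) {
    i <- pairs[row, 1]; j <- pairs[row, 2]
    gi <- lev[i]; gj <- lev[j]
    r <- j - i + 1L
    se <- sqrt(mse * (1 / ns[gi] + 1 / ns[gj]))
    tv <- (means[gj] - means[gi]) / se
    pv <- 2 * stats::pt(abs(tv), df2, lower.tail = FALSE)
    a_nom <- alpha * 2 / (k * (r - 1))
    pw <- rbind(pw, data.frame(group_i = gi, group_j = gj, rank_span = r,
                               t = unname(tv), df = df2, p = unname(pv),
                               alpha_nominal = a_nom,
                               raw_sig = pv < a_nom,
                               stringsAsFactors = FALSE))
  }
  # step-down consistency: a pair is significant only if all pairs
  # enclosing it (wider rank span containing both) are raw-significant
  pw$significant <- pw$raw_sig
  pos <- stats::setNames(seq_len(k), lev)
  for (row in seq_len(nrow(pw))) {
    lo <- pos[pw$group_i[row]]; hi <- pos[pw$group_j[row]]
    for (r2 in seq_len(nrow(pw))) {
      lo2 <- pos[pw$group_i[r2]]; hi2 <- pos[pw$group_j[r2]]
      if (lo2 <= lo && hi2 >= hi && !pw$raw_sig[r2])
        pw$significant[row] <- FALSE
    }
  }
  pw$raw_sig <- NULL
  list(omnibus = list(F = Fv, df1 = df1, df2 = df2, p = p_om,
                      significant = p_om < alpha / bonferroni_m),
       pairwise = pw)
}

#' Cohen's d standardized mean difference
#'
#' `d = (mean_a - mean_b) / s_pooled`, pooled SD with
#' `n_a + n_b - 2` denominator.
#'
#' @param a,b numeric vectors (each n >= 2).
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  stopifnot(na >= 2, nb >= 2)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 <= 0) stop("cohens_d: zero pooled SD")
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Cerebellar laterality analysis on symmetrized-atlas volumes
#'
#' Input rows are per specimen x cerebellar region x side under the two
#' atlas variants (the symmetrized atlas and its mirror); the variants are
#' averaged per specimen/region/side, size-adjusted against ICV, then per
#' region: a group x side ANOVA with side as a within-specimen factor,
#' simple main effects of side within each group (paired differences,
#' error pooled across groups, df N - k), and between-group contrasts on
#' each side by Ryan's procedure with the pooled 2N-observation cell model
#' error (df 2N - 2k).
#'
#' @param table data frame: `specimen`, `group`, `region`, `side`
#'   (`"L"`/`"R"`), `volume`, `icv`, `variant` (e.g. `"sym"`, `"mirror"`;
#'   a single variant is allowed).
#' @param alpha significance level.
#' @return list per region: `interaction` (group x side F, df, p),
#'   `simple_side` data frame (group, mean_LR_diff, F, df1, df2, p),
#'   `between_by_side` list of Ryan pairwise tables (sides L and R).
#' @export
laterality_analysis <- function(table, alpha = 0.05) {
  need <- c("specimen", "group", "region", "side", "volume", "icv")
  stopifnot(all(need %in% names(table)))
  if (!"variant" %in% names(table)) table$variant <- "single"
  agg <- stats::aggregate(cbind(volume, icv) ~ specimen + group + region + side,
                          table, mean)
  out <- list()
  for (reg in unique(agg$region)) {
    tr <- agg[agg$region == reg, ]
    tr$region <- reg
    tr <- icv_adjust(tr)
    wide <- merge(tr[tr$side == "L", c("specimen", "group", "volume_adj")],
                  tr[tr$side == "R", c("specimen", "volume_adj")],
                  by = "specimen", suffixes = c("_L", "_R"))
    if (nrow(wide) < nrow(tr) / 2)
      stop("laterality_analysis: specimens missing one side")
    wide$d <- wide$volume_adj_L - wide$volume_adj_R
    grp <- factor(wide$group)
    k <- nlevels(grp)
    N <- nrow(wide)
    # group x side interaction == one-way ANOVA on the paired differences
    if (k >= 2) {
      fit_d <- stats::lm(d ~ grp, data = wide)
      an_d <- stats::anova(fit_d)
      interaction <- list(F = an_d[1, "F value"], df1 = an_d[1, "Df"],
                          df2 = an_d[2, "Df"], p = an_d[1, "Pr(>F)"])
      mse_d <- an_d[2, "Mean Sq"]
    } else {
      interaction <- list(F = NA_real_, df1 = NA_integer_,
                          df2 = N - k, p = NA_real_)
      mse_d <- sum((wide$d - mean(wide$d))^2) / (N - k)
    }
    # simple main effect of side within each group, pooled error df N - k
    simple <- do.call(rbind, lapply(levels(grp), function(g) {
      dg <- wide$d[wide$group == g]
      ng <- length(dg)
      Fv <- ng * mean(dg)^2 / mse_d
      data.frame(group = g, n = ng, mean_LR_diff = mean(dg), F = Fv,
                 df1 = 1, df2 = N - k,
                 p = stats::pf(Fv, 1, N - k, lower.tail = FALSE),
                 stringsAsFactors = FALSE)
    }))
    # between-group contrasts on each side, error from the 2N-cell model
    long <- rbind(
      data.frame(grp = wide$group, side = "L", y = wide$volume_adj_L),
      data.frame(grp = wide$group, side = "R", y = wide$volume_adj_R)
    )
    by_side <- NULL
    if (k >= 2) {
      cellfit <- stats::lm(y ~ interaction(grp, side), data = long)
      mse2 <- sum(stats::resid(cellfit)^2) / (2 * N - 2 * k)
      by_side <- lapply(c(L = "L", R = "R"), function(s) {
        ys <- long$y[long$side == s]
        gsd <- long$grp[long$side == s]
        ryan_pairwise(ys, gsd, mse2, 2 * N - 2 * k, alpha)
      })
    }
    out[[reg]] <- list(interaction = interaction, simple_side = simple,
                       between_by_side = by_side)
  }
  out
}

# Ryan pairwise table with externally supplied pooled error
ryan_pairwise <- function(values, groups, mse, df_err, alpha = 0.05) {
  groups <- factor(groups)
  k <- nlevels(groups)
  ns <- table(groups)
  means <- tapply(values, groups, mean)
  ord <- order(means)
  lev <- levels(groups)[ord]
  pairs <- t(utils::combn(k, 2))
  pw <- data.frame()
  for (row in seq_len(nrow(pairs))) {
    i <- pairs[row, 1]; j <- pairs[row, 2]
    gi <- lev[i]; gj <- lev[j]
    r <- j - i + 1L
    se <- sqrt(mse * (1 / ns[gi] + 1 / ns[gj]))
    tv <- (means[gj] - means[gi]) / se
    pv <- 2 * stats::pt(abs(tv), df_err, lower.tail = FALSE)
    a_nom <- alpha * 2 / (k * (r - 1))
    pw <- rbind(pw, data.frame(group_i = gi, group_j = gj, rank_span = r,
                               t = unname(tv), df = df_err, p = unname(pv),
                               alpha_nominal = a_nom, raw_sig = pv < a_nom,
                               stringsAsFactors = FALSE))
  }
  pw$significant <- pw$raw_sig
  pos <- stats::setNames(seq_len(k), lev)
  for (row in seq_len(nrow(pw))) {
    lo <- pos[pw$group_i[row]]; hi <- pos[pw$group_j[row]]
    for (r2 in seq_len(nrow(pw))) {
      lo2 <- pos[pw$group_i[r2]]; hi2 <- pos[pw$group_j[r2]]
      if (lo2 <= lo && hi2 >= hi && !pw$raw_sig[r2])
        pw$significant[row] <- FALSE
    }
  }
  pw$raw_sig <- NULL
  pw
}

#' Mirror a volume about the mid-sagittal plane
#'
#' Flips the x (left-right) axis about the grid's centre plane. For label
#' volumes, left/right region ids can be swapped according to an atlas
#' table so that anatomical identity follows the flip.
#'
#' @param volume [scalar_volume] or [label_volume].
#' @param table optional atlas table for L/R id swapping.
#' @export
flip_x <- function(volume, table = NULL) {
  d <- volume$grid$shape
  if (inherits(volume, "label_volume")) {
    arr <- volume$labels[d[1]:1, , , drop = FALSE]
    if (!is.null(table)) {
      map <- lr_swap_map(table)
      arr <- array(map[arr + 1L], d)
    }
    label_volume(volume$grid, arr)
  } else {
    scalar_volume(volume$grid, volume$values[d[1]:1, , , drop = FALSE])
  }
}

# id -> mirrored id lookup (index 1 = background 0)
lr_swap_map <- function(table) {
  m <- 0:max(table$region_id)
  for (i in seq_len(nrow(table))) {
    if (table$hemisphere[i] %in% c("L", "R")) {
      opp <- table$region_id[table$lobe_group == table$lobe_group[i] &
                               table$hemisphere ==
                                 setdiff(c("L", "R"), table$hemisphere[i])]
      if (length(opp) == 1) m[table$region_id[i] + 1L] <- opp
    }
  }
  m
}

#' Build a symmetrized atlas via a left-right symmetric template
#'
#' Constructs a symmetric population template from the input images plus
#' their mid-sagittal mirror copies, registers the asymmetric template to
#' it, and pulls the atlas labels into the symmetric frame. The mirrored
#' variant is the x-flip of the symmetrized atlas with left/right region
#' ids swapped.
#'
#' @param images list of [scalar_volume]s (e.g. brain masks) on the
#'   template grid.
#' @param atlas an [atlas_parcellation] in the frame of `template`.
#' @param template the asymmetric template the atlas lives in.
#' @param cfg a [reg_config]; `n_outer` outer template iterations.
#' @return list with `sym_template`, `sym_atlas` ([label_volume]),
#'   `mirror_atlas` ([label_volume]).
#' @export
build_symmetrized_atlas <- function(images, atlas, template,
                                    cfg = reg_config(), n_outer = 2L) {
  both <- c(images, lapply(images, flip_x))
  tb <- build_template(both, cfg, n_outer = n_outer)
  # move the atlas from the asymmetric template frame into the symmetric one
  reg <- register_diffeo(tb$template, template, cfg)
  phi <- exp_velocity(reg$velocity, cfg$squaring_steps)
  sym_atlas <- warp_volume(atlas$labels, phi, mode = "nearest")
  mirror_atlas <- flip_x(sym_atlas, atlas$table)
  list(sym_template = tb$template, sym_atlas = sym_atlas,
       mirror_atlas = mirror_atlas)
}

#' Confound-adjusted cognition regressions
#'
#' Per task, fits `volume ~ score + ICV + age + sex` and reports the score
#' slope, its t statistic on n - 5 degrees of freedom, the p-value and the
#' Bonferroni decision over the number of tasks.
#'
#' @param table data frame from [cognition_table] (columns volume, icv,
#'   age, sex, task_*).
#' @param tasks character vector of task column names (default task_1..7).
#' @param alpha family significance level (Bonferroni over tasks).
#' @return data frame: task, slope, se, t, df, p, p_threshold, significant.
#' @export
cognition_regression <- function(table, tasks = paste0("task_", 1:7),
                                 alpha = 0.05) {
  stopifnot(all(c("volume", "icv", "age", "sex") %in% names(table)),
            all(tasks %in% names(table)))
  n <- nrow(table)
  if (n <= 5) stop("cognition_regression: n too small")
  m <- length(tasks)
  out <- do.call(rbind, lapply(tasks, function(tk) {
    f <- stats::as.formula(paste("volume ~", tk, "+ icv + age + sex"))
    fit <- stats::lm(f, data = table)
    if (fit$df.residual != n - 5)
      warning("cognition_regression: rank-deficient model for ", tk)
    cf <- summary(fit)$coefficients
    data.frame(task = tk, slope = cf[tk, 1], se = cf[tk, 2], t = cf[tk, 3],
               df = fit$df.residual, p = cf[tk, 4],
               p_threshold = alpha / m,
               significant = cf[tk, 4] < alpha / m,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
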