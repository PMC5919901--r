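#!/usr/bin/env Rscript

# Stage 6 — volumetric group statistics.
#
# Three analyses over regional-volume tables:
#  (a) the published fossil volumetrics: group means, SDs and
#      cerebellum/cerebrum ratios from the eight per-specimen volumes;
#  (b) ICV-adjusted lobe-group comparisons on a synthetic three-group
#      cohort: one-way ANOVA per 13 lobe groups (Bonferroni 0.05/13)
#      with Ryan's pairwise follow-up;
#  (c) cerebellar laterality (group x side, side within specimen) and the
#      confound-adjusted cognition regressions with Bonferroni over the
#      seven tasks.

library(paleobrain)

out <- "results/statistics"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

## (a) published fossil volumetrics
fossils <- data.frame(
  specimen = c("Amud1", "LaChapelle1", "LaFerrassie1", "ForbesQuarry1",
               "Qafzeh9", "Skhul5", "Mladec1", "CroMagnon1"),
  group = rep(c("NT", "EH"), each = 4),
  cerebrum = c(1304, 1159, 1268, 912, 1075, 1053, 1205, 1208),
  cerebellum = c(182, 140, 166, 106, 147, 146, 165, 156))
vs <- volume_summary(fossils)
write_table_csv(vs, file.path(out, "fossil_volume_summary.csv"))
message("fossil volumetrics (cc):")
print(vs, digits = 4)

## (b) lobe-group ANOVA with Ryan pairwise on a synthetic cohort
cohort <- sample_cohort(cohort_spec(
  n_per_group = 12, grid_shape = c(32, 32, 32),
  groups = list(MH = list(),
                NT = list(cerebellum_scale = 0.85, right_scale = 0.92),
                EH = list()),
  variation_sd = 0.8, warp_fwhm = 6, seed = 31))
tab <- do.call(rbind, lapply(cohort, function(s) {
  tv <- true_parcel_volumes(s)
  agg <- stats::aggregate(volume_mm3 ~ lobe_group, tv, sum)
  data.frame(specimen = s$id, group = s$group, region = agg$lobe_group,
             volume = agg$volume_mm3, icv = icv(s$tissue))
}))
adj <- icv_adjust(tab)
an_rows <- do.call(rbind, lapply(split(adj, adj$region), function(d) {
  ar <- anova_ryan(d$volume_adj, d$group, bonferroni_m = 13)
  data.frame(region = d$region[1], F = ar$omnibus$F, df1 = ar$omnibus$df1,
             df2 = ar$omnibus$df2, p = ar$omnibus$p,
             significant = ar$omnibus$significant)
}))
write_table_csv(an_rows, file.path(out, "lobe_group_anova.csv"))
message("lobe groups significant after Bonferroni 0.05/13: ",
        paste(an_rows$region[an_rows$significant], collapse = ", "))

## Cohen's d for the cerebellar contrast
cb <- tab[tab$region %in% c("Ce_A", "Ce_P", "Ce_V"), ]
cb_tot <- stats::aggregate(volume ~ specimen + group, cb, sum)
d_nt_mh <- cohens_d(cb_tot$volume[cb_tot$group == "NT"],
                    cb_tot$volume[cb_tot$group == "MH"])
message("Cohen's d, NT vs MH total cerebellum: ", round(d_nt_mh, 2))

## (c) laterality and cognition
lat_tab <- do.call(rbind, lapply(cohort, function(s) {
  tv <- true_parcel_volumes(s)
  do.call(rbind, lapply(c("Ce_A", "Ce_P"), function(rg)
    data.frame(specimen = s$id, group = s$group, region = rg,
               side = c("L", "R"),
               volume = c(tv$volume_mm3[tv$lobe_group == rg &
                                          tv$hemisphere == "L"],
                          tv$volume_mm3[tv$lobe_group == rg &
                                          tv$hemisphere == "R"]),
               icv = icv(s$tissue), variant = "sym")))
}))
la <- laterality_analysis(lat_tab)
for (rg in names(la)) {
  message(rg, " group x side interaction: F = ",
          round(la[[rg]]$interaction$F, 2), ", p = ",
          signif(la[[rg]]$interaction$p, 3))
}

ct <- cognition_table(1095, beta_per_task = c(3, 2.2, 2.3, 2, 2, 1.9, 0.9),
                      noise_sd = 8, seed = 37)
cr <- cognition_regression(ct)
write_table_csv(cr, file.path(out, "cognition_regressions.csv"))
message("cognition tasks significant at Bonferroni 0.05/7: ",
        sum(cr$significant), " of 7 (df = ", unique(cr$df), ")")
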