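# One seeded replicate of the generalist-vs-specialist recovery study,
# shared by the end-to-end property tests. Uses the default study design
# (landscape geometry, species truths, record counts, ensemble settings);
# hypervolume Monte-Carlo sizes are reduced resolution only.
recovery_metrics <- function(seed) {
  cfg <- study_config(seed = seed,
                      hv = list(n_perm = 0, n_mc = 6000, n_uniform = 300))
  stack <- generate_environment(cfg$landscape)
  occ <- contactniche:::simulate_study_occurrences(stack, cfg)
  zones <- lapply(cfg$landscape$zones, `[[`, "area")
  climate_vars <- grep("^clim", names(stack), value = TRUE)
  lc_vars <- setdiff(names(stack), climate_vars)
  pca_c <- fit_pca(rs_values(stack, climate_vars))
  pca_l <- fit_pca(rs_values(stack, lc_vars))

  scores <- function(model, vars, sp, zone = NULL) {
    sel <- occ$species == sp & (if (is.null(zone)) TRUE else occ$area == zone)
    project_scores(model, rs_extract(stack, occ[sel, c("x", "y")], vars))
  }
  hv <- function(sc, tag) build_hypervolume(
    sc, n_mc = cfg$hv$n_mc, n_uniform = cfg$hv$n_uniform,
    seed = child_seed(seed, tag, 0L))

  # (a) climatic niche volumes over the large area
  vol_ratio <- hv(scores(pca_c, climate_vars, "aspis"), "va")$volume /
    hv(scores(pca_c, climate_vars, "latastei"), "vl")$volume

  # (b) within-zone vs cross-zone transfer skill, climatic models
  mcp_of <- function(sp, zone) minimum_convex_polygon(
    occ[occ$species == sp & occ$area == zone, c("x", "y")], buffer = 2)
  within <- c(); cross <- c()
  for (sp in c("aspis", "latastei")) {
    other <- setdiff(c("aspis", "latastei"), sp)
    ens <- list()
    for (z in names(zones))
      ens[[z]] <- suppressWarnings(fit_ensemble(
        occ[occ$species == sp & occ$area == z, c("x", "y")],
        stack, climate_vars, list(mcp_of(other, z)), area = zones[[z]],
        n_rep = cfg$enm$n_rep, keep = cfg$enm$keep,
        seed = child_seed(seed, paste0("ens_", sp, "_", z), 0L)))
    for (z in names(zones)) {
      within <- c(within, mean(ens[[z]]$test_tss[ens[[z]]$kept]))
      for (tg in setdiff(names(zones), z)) {
        tr <- suppressWarnings(evaluate_transfer(
          ens[[z]], stack, occ[occ$species == sp & occ$area == tg, c("x", "y")],
          list(mcp_of(other, tg)), area = zones[[tg]],
          seed = child_seed(seed, paste0("tr_", sp, "_", z, "_", tg), 0L)))
        cross <- c(cross, tr$tss)
      }
    }
  }

  # (c) landcover niche overlap between species, disturbed vs natural zone
  oi_zone <- function(zone, tag) suppressWarnings(pairwise_overlap(
    hv(scores(pca_l, lc_vars, "aspis", zone), paste0(tag, "a")),
    hv(scores(pca_l, lc_vars, "latastei", zone), paste0(tag, "l"))))$OI

  list(vol_ratio = vol_ratio,
       tss_within = mean(within), tss_cross = mean(cross),
       oi_disturbed = oi_zone("OT", "ot"), oi_natural = oi_zone("HE", "he"))
}
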