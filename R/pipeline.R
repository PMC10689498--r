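# End-to-end study orchestration: simulate -> ordinate -> overlap -> model
# -> transfer -> sympatry, from one config, fully seeded.

default_zone_specs <- function() {
  list(
    HE = list(area = study_area("HE", 60, 95, 140, 175),
              climate_offset = 0, disturbance = 0),    # natural landscape
    OT = list(area = study_area("OT", 25, 60, 85, 120),
              climate_offset = 0, disturbance = 0.8),  # intensive agriculture
    TA = list(area = study_area("TA", 110, 145, 20, 55),
              climate_offset = 0, disturbance = 0.4)   # abandoned grazing
  )
}

#' Default ground-truth species set
#'
#' Two focal species with Gaussian niches on four climate axes and two
#' habitat axes (forest and shrub fractions): a generalist (per-axis
#' breadth twice the specialist's) centred on the cool, humid, forested
#' end of the gradients, and a specialist centred on the warm, dry,
#' shrub-dominated end; plus an optional third species restricted to the
#' far north (allopatric), used only as a pseudo-absence source. The
#' niches span several climate variables so the generalist/specialist
#' contrast is expressed in the leading components of the climatic
#' ordination, and the species prefer different habitat classes so
#' habitat segregation can emerge where the landscape is heterogeneous
#' and collapse where disturbance homogenises it.
#'
#' @param generalist_breadth Per-axis sd of the generalist (specialist =
#'   half of it); the last two entries are the forest and shrub fraction
#'   axes.
#' @param third Include the third, allopatric species (default `TRUE`).
#' @return Named list of [species_truth()]s
#'   (`aspis`, `latastei`, optionally `seoanei`).
#' @export
default_truths <- function(generalist_breadth = c(1.6, 1.6, 1.6, 1.6,
                                                  0.25, 0.25),
                           third = TRUE) {
  vars <- c("clim1", "clim2", "clim3", "clim4", "forest", "shrub")
  out <- list(
    aspis = species_truth("aspis", vars,
                          optimum = c(0.8, -0.4, 0.4, -0.4, 0.55, 0.02),
                          breadth = generalist_breadth),
    latastei = species_truth("latastei", vars,
                             optimum = c(-0.8, 0.4, -0.4, 0.4, 0.02, 0.5),
                             breadth = generalist_breadth / 2)
  )
  if (third)
    out$seoanei <- species_truth("seoanei", c("clim1", "clim2"),
                                 optimum = c(2.2, -0.8),
                                 breadth = c(0.7, 0.7),
                                 range = study_area("north", 0, 190, 130, 190))
  out
}

default_counts <- function() {
  list(aspis = c(HE = 52, OT = 133, TA = 50, rest = 186),
       latastei = c(HE = 60, OT = 95, TA = 50, rest = 245),
       seoanei = c(HE = 29, OT = 0, TA = 0, rest = 106))
}

#' Configure a full comparative study
#'
#' Defaults mirror the emulated study design: a 190 x 190 km large area
#' holding three 35 x 35 km contact zones with contrasting landscape
#' disturbance (natural / intensive agriculture / abandoned fields),
#' record counts of 421/450 for the focal species over the large area
#' (52/60, 133/95 and 50/50 inside the zones), hypervolumes at 95% mass
#' with 1000 representative points and 100 permutations, and ensembles of
#' 30 replicates keeping the 10 best.
#'
#' @param landscape A [landscape_config()]; default built from `seed`.
#' @param truths Named list of [species_truth()]s; default
#'   [default_truths()].
#' @param counts Named list of per-area record counts per species (zones
#'   plus `rest` = large area outside the zones).
#' @param hv Hypervolume settings: `quantile`, `n_uniform`, `n_mc`,
#'   `n_perm`, `n_background`, `alpha`.
#' @param enm Ensemble settings: `n_rep`, `keep`, `split`.
#' @param k Ordination components used for hypervolumes (default 3).
#' @param seed Master seed; all stage seeds derive from it via
#'   [child_seed()].
#' @return Object of class `study_config`.
#' @export
study_config <- function(landscape = NULL, truths = NULL, counts = NULL,
                         hv = list(), enm = list(), k = 3, seed = 1) {
  landscape <- landscape %||%
    landscape_config(zones = default_zone_specs(),
                     seed = child_seed(seed, "landscape", 0L))
  truths <- truths %||% default_truths()
  counts <- counts %||% default_counts()
  hv <- utils::modifyList(list(quantile = 0.95, n_uniform = 1000,
                               n_mc = NULL, n_perm = 100,
                               n_background = 2000, alpha = 0.05), hv)
  enm <- utils::modifyList(list(n_rep = 30, keep = 10, split = 0.8), enm)
  zone_names <- names(landscape$zones)
  for (sp in names(counts)) {
    cn <- counts[[sp]]
    if (any(cn < 0)) stop("record counts must be non-negative")
    if (!all(zone_names %in% names(cn)))
      stop("counts for ", sp, " must cover every zone plus `rest`")
  }
  structure(list(landscape = landscape, truths = truths, counts = counts,
                 hv = hv, enm = enm, k = k, seed = as.integer(seed)),
            class = "study_config")
}

#' Enumerate the full modelling design
#'
#' Full factorial crossing of species, variable sets and study areas; the
#' default design is 2 x 3 x 4 = 24 ensembles.
#'
#' @param species,varsets,areas Character vectors, or counts (integers)
#'   which generate placeholder labels.
#' @return Data frame with one row per design cell.
#' @export
#' @examples
#' nrow(enumerate_designs(2, 3, 4))  # 24
enumerate_designs <- function(species = c("aspis", "latastei"),
                              varsets = c("climatic", "landcover",
                                          "climatic+landcover"),
                              areas = c("NIB", "HE", "OT", "TA")) {
  as_labels <- function(x, prefix) {
    if (is.numeric(x)) {
      if (length(x) != 1 || x < 1) stop("counts must be positive scalars")
      paste0(prefix, seq_len(x))
    } else as.character(x)
  }
  species <- as_labels(species, "species")
  varsets <- as_labels(varsets, "varset")
  areas <- as_labels(areas, "area")
  expand.grid(species = species, varset = varsets, area = areas,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

# Simulate the occurrence table: stated counts inside each zone, the
# remainder over the large area outside the zones, tagged by area.
simulate_study_occurrences <- function(stack, config) {
  zones <- lapply(config$landscape$zones, `[[`, "area")
  occ <- list()
  for (sp in names(config$counts)) {
    truth <- config$truths[[sp]]
    if (is.null(truth)) stop("no truth for species ", sp)
    cn <- config$counts[[sp]]
    for (z in names(zones)) {
      if (cn[[z]] > 0)
        occ[[length(occ) + 1L]] <- simulate_occurrences(
          stack, truth, cn[[z]], area = zones[[z]],
          seed = child_seed(config$seed, paste0("occ_", sp, "_", z), 0L))
    }
    if (cn[["rest"]] > 0)
      occ[[length(occ) + 1L]] <- simulate_occurrences(
        stack, truth, cn[["rest"]], exclude = zones,
        seed = child_seed(config$seed, paste0("occ_", sp, "_rest"), 0L))
  }
  assign_areas(do.call(rbind, occ), zones, default = "")
}

overlap_row <- function(scoresA, scoresB, config, tag) {
  hvset <- config$hv
  h1 <- build_hypervolume(scoresA, quantile = hvset$quantile,
                          n_uniform = hvset$n_uniform, n_mc = hvset$n_mc,
                          seed = child_seed(config$seed, paste0(tag, "_A"), 0L))
  h2 <- build_hypervolume(scoresB, quantile = hvset$quantile,
                          n_uniform = hvset$n_uniform, n_mc = hvset$n_mc,
                          seed = child_seed(config$seed, paste0(tag, "_B"), 0L))
  ov <- suppressWarnings(pairwise_overlap(h1, h2))
  if (hvset$n_perm > 0) {
    st <- perm_null_stats(scoresA, scoresB, hvset$n_perm,
                          seed = child_seed(config$seed, paste0(tag, "_perm"), 0L),
                          quantile = hvset$quantile,
                          n_uniform = hvset$n_uniform, n_mc = hvset$n_mc)
    ov$pK <- (1 + sum(st$null[, "K"] <= ov$K)) / (hvset$n_perm + 1)
    ov$pOI <- (1 + sum(st$null[, "OI"] <= ov$OI)) / (hvset$n_perm + 1)
    ov$n_perm <- hvset$n_perm
  }
  ov
}

#' Run the full comparative study
#'
#' Executes every stage of the workflow on a synthetic landscape: raster
#' generation, occurrence simulation, the two ordinations (climatic and
#' landcover, fitted on the large area's cells), the overlap table
#' (environmental variability between zones, each species across zones,
#' and species-vs-species per area, in both spaces, with permutation
#' tests), the factorial ensemble design, cross-area transfer scoring and
#' per-zone sympatry profiles. Every stochastic step is seeded from the
#' master seed, so a rerun with the same config reproduces the report.
#'
#' @param config A [study_config()].
#' @param verbose Print stage progress (default `FALSE`).
#' @return Object of class `study_report` with elements `stack`,
#'   `occurrences`, `pca`, `overlap` (data frame), `enm_summary`,
#'   `ensembles`, `transfer`, `sympatry`, `manifest`, `config`.
#' @export
run_study <- function(config = study_config(), verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  t0 <- Sys.time()
  timings <- list()
  say <- function(...) if (verbose) message(sprintf(...))
  tick <- function(stage, expr) {
    st <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage `%s` failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), st, units = "secs"))
    out
  }

  say("generating landscape")
  stack <- tick("landscape", generate_environment(config$landscape))
  zones <- lapply(config$landscape$zones, `[[`, "area")
  large <- study_area("NIB", stack$xmin,
                      stack$xmin + stack$ncol * stack$cellsize,
                      stack$ymin, stack$ymin + stack$nrow * stack$cellsize)
  areas <- c(list(NIB = large), zones)
  climate_vars <- grep("^clim", names(stack), value = TRUE)
  landcover_vars <- setdiff(names(stack), climate_vars)
  varsets <- list(climatic = climate_vars, landcover = landcover_vars,
                  `climatic+landcover` = c(climate_vars, landcover_vars))

  say("simulating occurrences")
  occ <- tick("occurrences", simulate_study_occurrences(stack, config))

  say("fitting ordinations")
  pca <- tick("pca", list(
    climatic = fit_pca(rs_values(stack, climate_vars)),
    landcover = fit_pca(rs_values(stack, landcover_vars))
  ))

  sp_scores <- function(space, sp, area_name) {
    vars <- if (space == "climatic") climate_vars else landcover_vars
    sel <- occ$species == sp &
      (if (area_name == "NIB") TRUE else occ$area == area_name)
    project_scores(pca[[space]],
                   rs_extract(stack, occ[sel, c("x", "y")], vars),
                   k = config$k)
  }

  say("overlap analyses")
  overlap <- tick("overlap", {
    results <- list()
    blocks <- character()
    zn <- names(zones)
    for (space in c("climatic", "landcover")) {
      bg <- lapply(zn, function(z)
        background_hypervolume(stack, zones[[z]], pca[[space]],
                               n = config$hv$n_background, k = config$k,
                               seed = child_seed(config$seed,
                                                 paste0("bg_", space, "_", z),
                                                 0L))$scores)
      names(bg) <- zn
      for (pair in utils::combn(zn, 2, simplify = FALSE)) {
        nm <- sprintf("%s versus %s|%s", pair[1], pair[2], space)
        results[[nm]] <- overlap_row(bg[[pair[1]]], bg[[pair[2]]], config,
                                     paste0("env_", space, "_",
                                            paste(pair, collapse = "_")))
        blocks <- c(blocks, "environmental variability")
      }
      for (sp in c("aspis", "latastei")) {
        for (pair in utils::combn(zn, 2, simplify = FALSE)) {
          nm <- sprintf("%s %s versus %s|%s", sp, pair[1], pair[2], space)
          results[[nm]] <- overlap_row(sp_scores(space, sp, pair[1]),
                                       sp_scores(space, sp, pair[2]), config,
                                       paste0(sp, "_", space, "_",
                                              paste(pair, collapse = "_")))
          blocks <- c(blocks, sp)
        }
      }
      for (ar in names(areas)) {
        nm <- sprintf("%s aspis versus latastei|%s", ar, space)
        results[[nm]] <- overlap_row(sp_scores(space, "aspis", ar),
                                     sp_scores(space, "latastei", ar), config,
                                     paste0("sp_", space, "_", ar))
        blocks <- c(blocks, ar)
      }
    }
    tab <- overlap_table(results, alpha = config$hv$alpha)
    tab$block <- blocks
    tab
  })

  say("fitting ensembles")
  focal <- c("aspis", "latastei")
  species_mcp <- function(sp, area_name) {
    sel <- occ$species == sp &
      (if (area_name == "NIB") TRUE else occ$area == area_name)
    if (sum(sel) < 3) return(NULL)
    tryCatch(minimum_convex_polygon(occ[sel, c("x", "y")],
                                    buffer = 2 * stack$cellsize),
             error = function(e) NULL)
  }
  competitor_mcps <- function(sp, area_name) {
    other <- setdiff(focal, sp)
    mc <- list(species_mcp(other, area_name))
    # third-species range contributes pseudo-absences in NIB and HE only
    if (area_name %in% c("NIB", "HE") && "seoanei" %in% names(config$truths)) {
      third <- species_mcp("seoanei", area_name)
      if (!is.null(third)) mc <- c(mc, list(third))
    }
    mc <- Filter(Negate(is.null), mc)
    if (!length(mc)) stop("no competitor range available in ", area_name)
    mc
  }
  ensembles <- list()
  enm_rows <- list()
  tick("enm", for (sp in focal) {
    for (ar in names(areas)) {
      pres <- occ[occ$species == sp &
                    (if (ar == "NIB") TRUE else occ$area == ar),
                  c("x", "y")]
      mcps <- competitor_mcps(sp, ar)
      for (vs in names(varsets)) {
        say("  ensemble %s / %s / %s", sp, ar, vs)
        ens <- suppressWarnings(fit_ensemble(
          pres, stack, varsets[[vs]], mcps,
          area = if (ar == "NIB") NULL else areas[[ar]],
          n_rep = config$enm$n_rep, keep = config$enm$keep,
          split = config$enm$split,
          seed = child_seed(config$seed, paste0("enm_", sp, "_", ar, "_", vs),
                            0L),
          label = paste(sp, ar, vs, sep = "/")))
        ensembles[[sp]][[ar]][[vs]] <- ens
        sdv <- as.vector(ens$sd_raster$layers$sd)
        enm_rows[[length(enm_rows) + 1L]] <- data.frame(
          species = sp, area = ar, varset = vs, n_presence = nrow(pres),
          mean_kept_tss = mean(ens$test_tss[ens$kept]),
          sd_kept_tss = stats::sd(ens$test_tss[ens$kept]),
          mean_cell_sd = mean(sdv, na.rm = TRUE))
      }
    }
  })
  enm_summary <- do.call(rbind, enm_rows)

  say("transfer scoring")
  transfer <- tick("transfer", {
    rows <- list()
    for (sp in focal) {
      for (vs in names(varsets)) {
        pairs <- c(lapply(names(zones), function(src)
                     list(src = src,
                          tgt = c(setdiff(names(zones), src), "NIB"))),
                   list(list(src = "NIB", tgt = names(zones))))
        for (pr in pairs) {
          for (tg in pr$tgt) {
            recs <- occ[occ$species == sp &
                          (if (tg == "NIB") TRUE else occ$area == tg),
                        c("x", "y")]
            rep <- suppressWarnings(evaluate_transfer(
              ensembles[[sp]][[pr$src]][[vs]], stack, recs,
              competitor_mcps(sp, tg),
              area = if (tg == "NIB") NULL else areas[[tg]],
              seed = child_seed(config$seed,
                                paste0("tr_", sp, "_", vs, "_", pr$src, "_", tg),
                                0L)))
            rows[[length(rows) + 1L]] <- data.frame(
              species = sp, varset = vs, source = pr$src, target = tg,
              tss = rep$tss, miller_intercept = rep$miller$intercept,
              miller_slope = rep$miller$slope,
              extrapolation_fraction = rep$extrapolation_fraction)
          }
        }
      }
    }
    do.call(rbind, rows)
  })

  say("sympatry profiles")
  sympatry <- tick("sympatry", {
    profiles <- list()
    rows <- list()
    for (z in names(zones)) {
      for (vs in names(varsets)) {
        ra <- rs_crop(ensembles$aspis[[z]][[vs]]$mean_raster, zones[[z]])
        rb <- rs_crop(ensembles$latastei[[z]][[vs]]$mean_raster, zones[[z]])
        co <- fuzzy_intersection(ra, rb)
        tr <- tryCatch(suppressWarnings(auto_transect(co)),
                       error = function(e) NULL)
        if (is.null(tr)) next
        prof <- transect_profile(co, tr)
        key <- paste(z, vs, sep = "|")
        profiles[[key]] <- prof
        rows[[length(rows) + 1L]] <- data.frame(
          zone = z, varset = vs, peak = attr(prof, "peak"),
          peak_distance = attr(prof, "peak_distance"),
          flatness = attr(prof, "flatness"))
      }
    }
    list(profiles = profiles, summary = do.call(rbind, rows))
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("contactniche")),
    r_version = R.version.string,
    master_seed = config$seed,
    timings_sec = timings,
    started = format(t0, "%Y-%m-%d %H:%M:%S"),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  structure(list(stack = stack, occurrences = occ, pca = pca,
                 overlap = overlap, enm_summary = enm_summary,
                 ensembles = ensembles, transfer = transfer,
                 sympatry = sympatry, manifest = manifest, config = config),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat(sprintf("  occurrences: %d records, %d species\n",
              nrow(x$occurrences), length(unique(x$occurrences$species))))
  cat(sprintf("  overlap table: %d rows | ensembles: %d | transfers: %d\n",
              nrow(x$overlap), nrow(x$enm_summary), nrow(x$transfer)))
  cat(sprintf("  sympatry profiles: %d | elapsed %.1f s\n",
              length(x$sympatry$profiles), x$manifest$elapsed_sec))
  invisible(x)
}

#' Write study report tables to a directory
#'
#' Writes the overlap, ensemble, transfer and sympatry summary tables as
#' CSV, occurrences as CSV and the run manifest as JSON. The directory is
#' populated atomically (written to a staging directory, then renamed).
#'
#' @param report A [run_study()] result.
#' @param dir Output directory (must not exist).
#' @export
write_study_report <- function(report, dir) {
  if (dir.exists(dir)) stop("output directory already exists: ", dir)
  staging <- paste0(dir, ".tmp")
  if (dir.exists(staging)) unlink(staging, recursive = TRUE)
  dir.create(staging, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(staging, recursive = TRUE))
  utils::write.csv(report$overlap, file.path(staging, "overlap.csv"),
                   row.names = FALSE)
  utils::write.csv(report$enm_summary, file.path(staging, "enm_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(report$transfer, file.path(staging, "transfer.csv"),
                   row.names = FALSE)
  if (!is.null(report$sympatry$summary))
    utils::write.csv(report$sympatry$summary,
                     file.path(staging, "sympatry_summary.csv"),
                     row.names = FALSE)
  write_occurrences(report$occurrences,
                    file.path(staging, "occurrences.csv"))
  jsonlite::write_json(report$manifest, file.path(staging, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  file.rename(staging, dir)
  ok <- TRUE
  invisible(dir)
}
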