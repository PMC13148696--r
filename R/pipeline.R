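#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end analysis in one validated list.
#' Inputs are either a [make_scenario()] object (synthetic mode) or file
#' paths (occurrence CSV, stack directory, Newick tree, GeoJSON study area).
#' Defaults follow the study design the package implements: 0.95 ellipsoid
#' coverage (5% omission), 3 components, 5 unique localities minimum, a 0.7
#' correlation screen, 100 null replicates and all six weight candidates
#' (three schemes x two distance classes). In synthetic mode the geometric
#' settings are scaled to the 1-km landscape (1-km thinning, 5-km buffer,
#' 10-km assemblage cells - the scaled-down analog of 5-km pixels with
#' one-degree assemblage cells).
#'
#' @param scenario optional [make_scenario()] object.
#' @param paths optional named list: `occurrences`, `stack_dir`, `tree`,
#'   `study_area` (tree and study_area may be `NULL`).
#' @param master_seed integer master seed for all stages.
#' @param out_dir output directory for artifacts (`NULL` = keep in memory).
#' @param ... overrides of the defaults listed above (unknown names error).
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(scenario = NULL, paths = NULL, master_seed = 1,
                       out_dir = NULL, ...) {
  synthetic <- !is.null(scenario)
  cfg <- list(
    scenario = scenario, paths = paths, master_seed = master_seed,
    out_dir = out_dir,
    coverage = 0.95,
    min_decimals = 2,
    thin_km = if (synthetic) 1 else 5,
    buffer_km = if (synthetic) 5 else 25,
    pam_cell_km = if (synthetic) 10 else 110,
    n_components = 3,
    min_records = 5,
    corr_cutoff = 0.7,
    n_null_reps = 100,
    null_types = c("spreading_dye", "property_shuffle"),
    null_predictor_group = "multivariate",
    null_predictors = NULL,
    weight_schemes = c("W", "C", "S"),
    distance_classes = c("min", "max"),
    excluded_layers = character(0),
    layer_map = list(),
    mve_starts = 50,
    evo_models = c("BM", "OU", "EB", "trend"),
    do_comparative = TRUE
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L) {
    stop_ns("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  if (is.null(cfg$scenario) && is.null(cfg$paths)) {
    stop_ns("either a scenario or input paths must be given")
  }
  if (!(cfg$coverage > 0.5 && cfg$coverage <= 1)) {
    stop_ns("coverage must be in (0.5, 1]")
  }
  for (key in c("thin_km", "buffer_km", "pam_cell_km", "n_components",
                "min_records", "corr_cutoff", "n_null_reps")) {
    if (!is_scalar_num(cfg[[key]]) || cfg[[key]] <= 0) {
      stop_ns(key, " must be a positive number")
    }
  }
  class(cfg) <- "run_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes the nine stages in order: occurrence cleaning, PCA of the climate
#' space, ellipsoid niche models, constrained geographic ranges, the
#' presence-absence matrix, niche properties, comparative analysis (trait
#' models + root reconstruction + phylogenetic positions), SAR model
#' selection, and the two null models. All randomness derives from the
#' master seed, so identical configs give identical outputs. When the config
#' has an `out_dir`, every stage writes plain-text artifacts and the returned
#' manifest lists their md5 hashes.
#'
#' @param config a [run_config()].
#' @return an object of class `pipeline_run` with the per-stage results and
#'   a `manifest`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stop_ns("config must be a run_config")
  t_all <- proc.time()[["elapsed"]]
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  stage_times <- c()
  warnings_log <- character(0)
  note <- function(w) warnings_log <<- c(warnings_log, w)
  timed <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop_ns("stage '", name, "' failed: ", conditionMessage(e))
      }),
      warning = function(w) {
        note(paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
    stage_times[[name]] <<- proc.time()[["elapsed"]] - t0
    res
  }
  ms <- config$master_seed

  # ---- inputs ----
  if (!is.null(config$scenario)) {
    scen <- config$scenario
    raw_stack <- scen$landscape
    occs_raw <- scen$occurrences
    tree <- scen$tree
    study_area <- rectangle_polygon(
      scen$landscape$origin[1],
      scen$landscape$origin[1] + ncol(scen$landscape$layers[[1]]) *
        scen$landscape$res_km,
      scen$landscape$origin[2],
      scen$landscape$origin[2] + nrow(scen$landscape$layers[[1]]) *
        scen$landscape$res_km
    )
  } else {
    raw_stack <- read_stack(config$paths$stack_dir)
    occs_raw <- read_occurrences(config$paths$occurrences)
    tree <- if (!is.null(config$paths$tree)) {
      ape::read.tree(config$paths$tree)
    } else {
      NULL
    }
    study_area <- if (!is.null(config$paths$study_area)) {
      read_geojson_polygon(config$paths$study_area)
    } else {
      d <- stack_dim(raw_stack)
      rectangle_polygon(raw_stack$origin[1],
                        raw_stack$origin[1] + d[2] * raw_stack$res_km,
                        raw_stack$origin[2],
                        raw_stack$origin[2] + d[1] * raw_stack$res_km)
    }
  }
  do_comp <- isTRUE(config$do_comparative) && !is.null(tree)
  if (isTRUE(config$do_comparative) && is.null(tree)) {
    note("comparative: no tree supplied; position properties skipped")
  }

  stack <- drop_excluded_layers(raw_stack, config$excluded_layers)
  stack <- mask_to_area(stack, study_area)

  # ---- stage 1: clean ----
  clean <- timed("clean", {
    kept <- list(); excluded <- list()
    i <- 0
    for (sp in names(occs_raw)) {
      i <- i + 1
      o <- filter_precision(occs_raw[[sp]], config$min_decimals)
      o <- dedupe_pixel(o, stack)
      o <- thin_distance(o, min_km = config$thin_km,
                         seed = derive_seed(ms, 11, i))
      if (check_min_records(o, config$min_records)) {
        kept[[sp]] <- o
      } else {
        excluded[[sp]] <- data.frame(
          species = sp, n_unique = nrow(unique(cbind(o$lon, o$lat))),
          reason = "below minimum unique localities")
      }
    }
    if (length(kept) == 0L) stop("no species passed cleaning")
    list(occs = kept,
         exclusions = if (length(excluded)) do.call(rbind, excluded) else
           data.frame(species = character(0), n_unique = integer(0),
                      reason = character(0)))
  })

  # ---- stage 2: pca ----
  pca <- timed("pca", {
    model <- fit_pca(stack, config$n_components)
    list(model = model, pc_stack = project_pca(model, stack),
         reference = env_summary(stack, config$n_components))
  })

  # ---- stage 3: enm ----
  ells <- timed("enm", {
    res <- list()
    i <- 0
    for (sp in names(clean$occs)) {
      i <- i + 1
      env <- extract_env(clean$occs[[sp]], pca$pc_stack)
      res[[sp]] <- fit_mve(env, coverage = config$coverage,
                           seed = derive_seed(ms, 13, i),
                           n_starts = config$mve_starts, species_id = sp)
    }
    res
  })

  # ---- stage 4: ranges ----
  ranges <- timed("ranges", {
    lapply(names(ells), function(sp) {
      pres <- predict_presence(ells[[sp]], pca$pc_stack)
      constrain_range(pres, mcp_buffer(clean$occs[[sp]], config$buffer_km),
                      pca$pc_stack, sp)
    })
  })

  # ---- stage 5: pam ----
  pam <- timed("pam", build_pam(ranges, grid_res_km = config$pam_cell_km,
                                stack = pca$pc_stack))

  # ---- stage 6: properties (breadth, marginality, centroids) ----
  props_stage <- timed("properties", {
    extremes <- lapply(clean$occs, function(o) occurrence_extremes(o, stack))
    list(extremes = extremes,
         table = assemble_property_table(ells, extremes, pca$reference,
                                         layer_map = config$layer_map))
  })
  extremes <- props_stage$extremes
  props <- props_stage$table

  # ---- stage 7: comparative ----
  comparative <- timed("comparative", {
    if (!do_comp) {
      list(skipped = TRUE)
    } else {
      tr <- prune_to_species(tree, props$species)
      in_tree <- props$species[props$species %in% tr$tip.label]
      traits <- list()
      d <- config$n_components
      for (k in seq_len(d)) {
        traits[[paste0("pc", k)]] <- stats::setNames(
          props[[paste0("mv_centroid_", k)]], props$species)[in_tree]
      }
      traits$temp <- stats::setNames(props$temp_centroid,
                                     props$species)[in_tree]
      traits$prec <- stats::setNames(props$prec_centroid,
                                     props$species)[in_tree]
      fits <- list(); roots <- list(); sel <- list()
      ti <- 0
      for (nm in names(traits)) {
        ti <- ti + 1
        mf <- lapply(config$evo_models, function(m) {
          fit_evo_model(tr, traits[[nm]], model = m,
                        seed = derive_seed(ms, 17, ti))
        })
        s <- select_model(mf)
        fits[[nm]] <- mf
        sel[[nm]] <- s
        roots[[nm]] <- reconstruct_root(tr, traits[[nm]], s$best)
      }
      anc_mv <- vapply(paste0("pc", seq_len(d)),
                       function(nm) roots[[nm]]$ancestral_state, numeric(1))
      positions <- data.frame(
        species = in_tree,
        NP = vapply(in_tree, function(sp) {
          phylo_position(ells[[sp]]$centroid, anc_mv, "mahalanobis",
                         ell = ells[[sp]])
        }, numeric(1)),
        TP = abs(traits$temp[in_tree] - roots$temp$ancestral_state),
        PP = abs(traits$prec[in_tree] - roots$prec$ancestral_state),
        stringsAsFactors = FALSE
      )
      list(skipped = FALSE, tree = tr, selections = sel, roots = roots,
           positions = positions, ancestral_mv = anc_mv)
    }
  })
  if (!comparative$skipped) {
    props <- assemble_property_table(
      ells, extremes, pca$reference, positions = comparative$positions,
      layer_map = config$layer_map
    )
  }

  # ---- stage 8: sar ----
  sar <- timed("sar", {
    rich <- richness(pam)
    groups <- list(multivariate = c("NB", "NM", "NP"),
                   univariate_temperature = c("TB", "TM", "TP"),
                   univariate_precipitation = c("PB", "PM", "PP"))
    if (comparative$skipped) {
      groups <- lapply(groups, function(g) setdiff(g, c("NP", "TP", "PP")))
    }
    all_props <- unique(unlist(groups))
    maps <- vapply(all_props,
                   function(pr) map_property(pam, property_vector(props, pr)),
                   numeric(nrow(pam$matrix)))
    cells <- which(rich > 0 & stats::complete.cases(maps))
    if (length(cells) < 10) stop("too few occupied cells for SAR modelling")
    weights_list <- list()
    for (sc in config$weight_schemes) {
      for (dc in config$distance_classes) {
        w <- build_weights(pam$centroids[cells, , drop = FALSE],
                           scheme = sc, distance_class = dc)
        attr(w, "cells") <- cells
        weights_list[[paste0(sc, "/", dc)]] <- w
      }
    }
    group_fits <- list()
    for (gname in names(groups)) {
      model_sets <- screen_predictors(maps[cells, groups[[gname]],
                                           drop = FALSE],
                                      cutoff = config$corr_cutoff)
      fits <- lapply(model_sets, function(preds) {
        sel <- select_sar(rich[cells], maps[cells, preds, drop = FALSE],
                          weights_list)
        list(predictors = preds, selection = sel)
      })
      group_fits[[gname]] <- fits
    }
    list(cells = cells, maps = maps, weights = weights_list,
         groups = groups, fits = group_fits, richness = rich)
  })

  # ---- stage 9: nulls ----
  # The null comparison relates richness to each focal property separately
  # (one marginal SAR per property), mirroring how null slope distributions
  # are reported per property; each marginal model selects its own best
  # weights by AIC and both nulls refit that same specification.
  nulls <- timed("nulls", {
    gname <- config$null_predictor_group
    if (is.null(sar$fits[[gname]])) gname <- names(sar$fits)[1]
    predictors <- config$null_predictors %||% sar$groups[[gname]]
    rich <- richness(pam)
    cells <- sar$cells
    observed <- stats::setNames(numeric(length(predictors)), predictors)
    ens <- stats::setNames(vector("list", length(config$null_types)),
                           config$null_types)
    for (nt in config$null_types) {
      ens[[nt]] <- stats::setNames(vector("list", length(predictors)),
                                   predictors)
    }
    tests <- lapply(ens, function(x) {
      stats::setNames(numeric(length(predictors)), predictors)
    })
    for (p in predictors) {
      sel_p <- select_sar(rich[cells], sar$maps[cells, p, drop = FALSE],
                          sar$weights)
      best_p <- sel_p$best
      w_p <- sar$weights[[paste0(best_p$weights_scheme, "/",
                                 best_p$weights_distance_class)]]
      observed[[p]] <- sar_slope(best_p, p)
      for (nt in config$null_types) {
        e <- null_slope_distribution(pam, props, p, w_p, null_type = nt,
                                     n_reps = config$n_null_reps,
                                     master_seed = derive_seed(ms, 19,
                                                               match(nt, config$null_types)))
        ens[[nt]][[p]] <- e
        tests[[nt]][[p]] <- null_slope_test(observed[[p]], e, p)
      }
    }
    list(group = gname, predictors = predictors, observed = observed,
         ensembles = ens, tests = tests)
  })

  run <- list(config = config, stack = stack, study_area = study_area,
              clean = clean, pca = pca, ellipsoids = ells, ranges = ranges,
              pam = pam, properties = props, comparative = comparative,
              sar = sar, nulls = nulls, warnings = warnings_log)

  manifest <- list(
    package_version = as.character(utils::packageVersion("nichescape")),
    master_seed = ms,
    n_stages = length(stage_times),
    stages = names(stage_times),
    stage_seconds = as.list(round(unlist(stage_times), 3)),
    n_species_in = length(occs_raw),
    n_species_modeled = length(ells),
    warnings = warnings_log,
    artifacts = list()
  )
  if (!is.null(out_dir)) {
    files <- write_run_artifacts(run, out_dir)
    manifest$artifacts <- as.list(tools::md5sum(files))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  manifest$total_seconds <- round(proc.time()[["elapsed"]] - t_all, 3)
  run$manifest <- manifest
  class(run) <- "pipeline_run"
  run
}

write_run_artifacts <- function(run, out_dir) {
  p <- function(...) file.path(out_dir, ...)
  write_occurrences(run$clean$occs, p("occurrences_clean.csv"))
  utils::write.csv(run$clean$exclusions, p("exclusions.csv"),
                   row.names = FALSE)
  write_pca_model(run$pca$model, p("pca_model.json"))
  write_ellipsoids(run$ellipsoids, p("ellipsoids.json"))
  rng <- do.call(rbind, lapply(run$ranges, function(r) {
    data.frame(species = r$species_id,
               n_cells = length(r$cells),
               cells = paste(r$cells, collapse = ";"))
  }))
  utils::write.csv(rng, p("ranges.csv"), row.names = FALSE)
  write_pam(run$pam, p("pam.csv"))
  utils::write.csv(run$properties, p("niche_properties.csv"),
                   row.names = FALSE)
  files <- c(p("occurrences_clean.csv"), p("exclusions.csv"),
             p("pca_model.json"), p("ellipsoids.json"), p("ranges.csv"),
             p("pam.csv"), p("pam.csv.json"), p("niche_properties.csv"))
  if (!run$comparative$skipped) {
    evo <- do.call(rbind, lapply(names(run$comparative$selections),
                                 function(nm) {
      tab <- run$comparative$selections[[nm]]$table
      cbind(trait = nm, tab)
    }))
    utils::write.csv(evo, p("evo_model_selection.csv"), row.names = FALSE)
    roots <- do.call(rbind, lapply(names(run$comparative$roots),
                                   function(nm) {
      r <- run$comparative$roots[[nm]]
      data.frame(trait = nm, ancestral_state = r$ancestral_state, se = r$se,
                 model = r$model_used)
    }))
    utils::write.csv(roots, p("ancestral_states.csv"), row.names = FALSE)
    files <- c(files, p("evo_model_selection.csv"), p("ancestral_states.csv"))
  }
  sar_rows <- list()
  for (gname in names(run$sar$fits)) {
    for (fit in run$sar$fits[[gname]]) {
      b <- fit$selection$best
      co <- b$coefficients
      sar_rows[[length(sar_rows) + 1L]] <- data.frame(
        approach = gname,
        model = paste("richness ~", paste(fit$predictors, collapse = " + ")),
        term = co$term, estimate = co$estimate, se = co$se, p = co$p,
        lambda = b$lambda, AIC = b$AIC,
        weights = paste0(b$weights_scheme, "/", b$weights_distance_class)
      )
    }
  }
  utils::write.csv(do.call(rbind, sar_rows), p("sar_models.csv"),
                   row.names = FALSE)
  null_rows <- list()
  for (nt in names(run$nulls$ensembles)) {
    for (pr in names(run$nulls$ensembles[[nt]])) {
      e <- run$nulls$ensembles[[nt]][[pr]]
      null_rows[[length(null_rows) + 1L]] <- data.frame(
        null_type = nt, replicate = seq_len(e$n_reps), seed = e$seeds,
        predictor = pr, slope = e$slopes[, pr]
      )
    }
  }
  utils::write.csv(do.call(rbind, null_rows), p("null_slopes.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(group = run$nulls$group, observed = as.list(run$nulls$observed),
         p_values = lapply(run$nulls$tests, as.list)),
    p("null_tests.json"), auto_unbox = TRUE, digits = NA
  )
  c(files, p("sar_models.csv"), p("null_slopes.csv"), p("null_tests.json"))
}

#' @export
print.pipeline_run <- function(x, ...) {
  m <- x$manifest
  cat("<pipeline_run> ", m$n_species_modeled, "/", m$n_species_in,
      " species modeled, ", nrow(x$pam$matrix), " assemblage cells\n",
      sep = "")
  cat("  stages: ", paste(m$stages, collapse = " -> "), "\n", sep = "")
  if (length(x$nulls$observed)) {
    cat("  observed slopes (", x$nulls$group, "): ",
        paste(names(x$nulls$observed),
              format(x$nulls$observed, digits = 3), sep = " = ",
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Summary tables and figures for a completed run
#'
#' Writes a coefficient table (approach, model, estimate, p-value per
#' retained predictor), and a PDF with richness and property maps plus
#' null-slope histograms.
#'
#' @param run a [run_pipeline()] result.
#' @param out_dir output directory.
#' @return invisible character vector of written files.
#' @export
report <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (gname in names(run$sar$fits)) {
    for (fit in run$sar$fits[[gname]]) {
      b <- fit$selection$best
      co <- b$coefficients[b$coefficients$term != "(Intercept)", ]
      rows[[length(rows) + 1L]] <- data.frame(
        Approach = gname,
        Model = paste("Richness ~", paste(fit$predictors, collapse = " + ")),
        Predictor = co$term,
        Estimate = co$estimate,
        `p value` = co$p, check.names = FALSE
      )
    }
  }
  tab_path <- file.path(out_dir, "sar_summary.csv")
  utils::write.csv(do.call(rbind, rows), tab_path, row.names = FALSE)

  fig_path <- file.path(out_dir, "maps_and_nulls.pdf")
  grDevices::pdf(fig_path, width = 8, height = 6)
  on.exit(grDevices::dev.off())
  draw_cell_map(run$pam, run$sar$richness, "Species richness")
  for (pr in colnames(run$sar$maps)) {
    draw_cell_map(run$pam, run$sar$maps[, pr],
                  paste("Mean", pr, "per assemblage"))
  }
  for (nt in names(run$nulls$ensembles)) {
    for (pr in names(run$nulls$ensembles[[nt]])) {
      s <- run$nulls$ensembles[[nt]][[pr]]$slopes[, pr]
      s <- s[!is.na(s)]
      graphics::hist(s, breaks = 20, main = paste(nt, "null:", pr),
                     xlab = "null SAR slope", col = "grey80")
      graphics::abline(v = run$nulls$observed[[pr]], col = "red", lwd = 2)
    }
  }
  invisible(c(tab_path, fig_path))
}

draw_cell_map <- function(pam, values, title) {
  m <- matrix(values, nrow = pam$dims[1], ncol = pam$dims[2], byrow = TRUE)
  graphics::image(t(m), main = title, xlab = "x", ylab = "y",
                  col = grDevices::hcl.colors(24, "viridis"), axes = FALSE)
}
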