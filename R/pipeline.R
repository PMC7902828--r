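#' Validate (and default-fill) a pipeline configuration
#'
#' A pipeline configuration selects the input mode (`synthetic` or
#' `files`), the classification thresholds, the statistical settings
#' (phase scheme, anomaly threshold, FRP percentile level, breakpoint
#' candidate range, alpha levels, sensitivity settings), the output
#' directory and the seed. An empty file or `NULL` yields the full
#' default configuration; every invariant is checked and defaults are
#' injected and echoed in the result.
#'
#' @param config a YAML file path, a list, or NULL for defaults.
#' @return object of class `pipeline_config`.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop_af("config file not found: %s", config,
              class = "amazonfire_io_error")
    config <- yaml::read_yaml(config) %||% list()
  }
  config <- config %||% list()
  if (!is.list(config)) stop_af("config must be a YAML mapping or a list",
                                class = "amazonfire_config_error")
  cfg <- list(
    mode = match.arg(config$mode %||% "synthetic", c("synthetic", "files")),
    seed = config$seed %||% 1L,
    outdir = config$outdir %||% "amazonfire-out",
    anomaly_threshold = config$anomaly_threshold %||% 2,
    frp_level = config$frp_level %||% 90,
    breakpoint_candidates =
      config$breakpoint_candidates %||% 2005:2017,
    alpha_trend = config$alpha_trend %||% 0.01,
    alpha_other = config$alpha_other %||% 0.05,
    include_phase_iv = config$include_phase_iv %||% TRUE,
    sensitivity = list(
      target_years = config$sensitivity$target_years %||% c(2007L, 2010L),
      step = config$sensitivity$step %||% 5,
      max_reduction = config$sensitivity$max_reduction %||% 50),
    files = config$files %||% list())
  syn_args <- config$synthetic %||% list()
  if (!is.null(syn_args$type_mix)) syn_args$type_mix <- unlist(syn_args$type_mix)
  if (!is.null(syn_args$drought_multiplier_by_type))
    syn_args$drought_multiplier_by_type <-
      unlist(syn_args$drought_multiplier_by_type)
  if (!is.null(syn_args$tree_cover_mix))
    syn_args$tree_cover_mix <- unlist(syn_args$tree_cover_mix)
  syn_args$seed <- syn_args$seed %||% cfg$seed
  cfg$synthetic <- tryCatch(do.call(synthetic_config, syn_args),
                            error = function(e)
                              stop_af("invalid synthetic config: %s",
                                      conditionMessage(e),
                                      class = "amazonfire_config_error"))
  th_args <- config$thresholds %||% list()
  cfg$thresholds <- tryCatch(do.call(classification_thresholds, th_args),
                             error = function(e)
                               stop_af("invalid thresholds: %s",
                                       conditionMessage(e),
                                       class = "amazonfire_config_error"))
  if (length(cfg$breakpoint_candidates) == 2L)
    cfg$breakpoint_candidates <-
      seq(cfg$breakpoint_candidates[1L], cfg$breakpoint_candidates[2L])
  for (a in c("alpha_trend", "alpha_other"))
    if (cfg[[a]] <= 0 || cfg[[a]] >= 1)
      stop_af("%s must lie in (0, 1)", a, class = "amazonfire_config_error")
  if (cfg$mode == "files") {
    needed <- c("detections", "landscape", "deforestation")
    miss <- setdiff(needed, names(cfg$files))
    if (length(miss))
      stop_af("files mode needs paths: %s", paste(miss, collapse = ", "),
              class = "amazonfire_config_error")
    for (p in unlist(cfg$files))
      if (!file.exists(p))
        stop_af("input file not found: %s", p,
                class = "amazonfire_io_error")
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full decoupling-diagnostics pipeline
#'
#' Orchestrates every stage -- simulate (or load), classify, trend
#' statistics, anomaly extent, FRP intensity, mode decomposition, and
#' [CO] analyses -- writing each product as plain CSV plus a JSON manifest
#' with content hashes, so any consumer can verify results without the
#' package. Stage failure aborts with the failing stage named.
#'
#' @param config a `pipeline_config` (or anything [validate_config()]
#'   accepts).
#' @param stages character vector of stages to run (default all):
#'   `"classify"`, `"trends"`, `"anomalies"`, `"frp"`, `"modes"`, `"co"`.
#'   The simulate/load stage always runs, since everything depends on it.
#' @return (invisibly) the manifest list; written to
#'   `<outdir>/manifest.json`.
#' @export
run_pipeline <- function(config = NULL, stages = "all") {
  cfg <- if (inherits(config, "pipeline_config")) config
         else validate_config(config)
  all_stages <- c("classify", "trends", "anomalies", "frp", "modes", "co")
  if (identical(stages, "all")) stages <- all_stages
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = cfg$seed, mode = cfg$mode, products = list())
  emit <- function(name, files, params = list(), n = NULL) {
    files <- Filter(Negate(is.null), files)
    manifest$products[[name]] <<- list(
      files = lapply(files, function(f)
        list(path = basename(f), md5 = unname(tools::md5sum(f)))),
      parameters = params, n = n)
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_af("stage '%s' failed: %s", name, conditionMessage(e),
              class = "amazonfire_stage_error"))
  }

  # ---- simulate / load ------------------------------------------------
  inputs <- run_stage("simulate", {
    if (cfg$mode == "synthetic") {
      land <- generate_landscape(cfg$synthetic)
      sim <- generate_fire_seasons(cfg$synthetic, land)
      det <- sim$detections
      defor <- landscape_defor_series(land)
      gs <- grid_spec_from_config(cfg$synthetic)
      f_det <- file.path(cfg$outdir, "detections.csv")
      f_land <- file.path(cfg$outdir, "landscape.csv")
      f_def <- file.path(cfg$outdir, "deforestation.csv")
      write_detections(det, f_det)
      write_landscape(land, f_land)
      utils::write.csv(defor, f_def, row.names = FALSE)
      emit("inputs", list(f_det, f_land, f_def),
           params = list(grid = c(land$grid_rows, land$grid_cols),
                         years = range(land$years)),
           n = nrow(det))
      list(detections = det, landscape = land, defor = defor,
           truth = sim$truth, grid = gs)
    } else {
      land <- read_landscape(cfg$files$landscape)
      gs <- grid_spec(land$grid_rows, land$grid_cols)
      det <- read_detections_csv(cfg$files$detections, gs)
      defor <- utils::read.csv(cfg$files$deforestation)
      emit("inputs", list(cfg$files$detections, cfg$files$landscape,
                          cfg$files$deforestation),
           n = nrow(det))
      list(detections = det, landscape = land, defor = defor,
           truth = NULL, grid = gs)
    }
  })
  land <- inputs$landscape
  years <- land$years

  # ---- classify -------------------------------------------------------
  cl <- run_stage("classify", {
    res <- classify_all(inputs$detections, land, cfg$thresholds)
    f1 <- file.path(cfg$outdir, "labeled_detections.csv")
    f2 <- file.path(cfg$outdir, "annual_type_counts.csv")
    write_detections(res$detections, f1)
    utils::write.csv(res$annual_counts, f2, row.names = FALSE)
    emit("type_counts", list(f1, f2),
         params = unclass(cfg$thresholds), n = nrow(res$detections))
    res
  })
  counts <- cl$annual_counts
  fires <- counts[c("year", "total")]

  if ("trends" %in% stages) run_stage("trends", {
    mk <- mann_kendall(fires$year, fires$total, alpha = cfg$alpha_trend)
    sen <- theil_sen(fires$year, fires$total)
    trends <- data.frame(series = "active_fire_counts",
                         sen_slope = sen$slope,
                         sen_lower = sen$lower, sen_upper = sen$upper,
                         mk_S = mk$S, mk_z = mk$z, mk_p = mk$p_value,
                         alpha = mk$alpha, significant = mk$significant)
    f1 <- file.path(cfg$outdir, "annual_counts.csv")
    utils::write.csv(merge(fires, inputs$defor, by = "year"), f1,
                     row.names = FALSE)
    f2 <- file.path(cfg$outdir, "count_trends.csv")
    utils::write.csv(trends, f2, row.names = FALSE)
    emit("annual_counts", list(f1, f2),
         params = list(alpha = cfg$alpha_trend), n = nrow(fires))

    ratio <- fires_per_area_ratio(fires, inputs$defor)
    rfit <- ols_regression(ratio$year, ratio$fires_per_km2)
    f3 <- file.path(cfg$outdir, "ratio_series.csv")
    utils::write.csv(cbind(ratio,
                           trend_slope = rfit$slope,
                           trend_r2 = rfit$r_squared,
                           trend_p = rfit$p_value), f3, row.names = FALSE)
    emit("ratio_series", list(f3),
         params = list(alpha = cfg$alpha_other), n = nrow(ratio))

    ph <- phase_regressions(fires, inputs$defor,
                            ppcdam_phases(cfg$include_phase_iv))
    f4 <- file.path(cfg$outdir, "phase_regressions.csv")
    utils::write.csv(ph, f4, row.names = FALSE)
    emit("phase_regressions", list(f4), n = nrow(ph))
  })

  z_all <- NULL
  if (any(c("anomalies", "modes") %in% stages)) {
    stk <- count_stack(inputs$detections, years, land)
    z_all <- standardize(stk)
  }
  if ("anomalies" %in% stages) run_stage("anomalies", {
    ext <- extent_above(z_all, cfg$anomaly_threshold)
    f1 <- file.path(cfg$outdir, "anomaly_extent.csv")
    utils::write.csv(ext, f1, row.names = FALSE)
    f2 <- file.path(cfg$outdir, "anomaly_z.csv")
    zlong <- do.call(rbind, lapply(seq_along(years), function(k) {
      idx <- which(z_all$mask, arr.ind = TRUE)
      data.frame(year = years[k], row = idx[, 1L], col = idx[, 2L],
                 z = z_all$z[, , k][z_all$mask])
    }))
    utils::write.csv(zlong, f2, row.names = FALSE)
    emit("anomaly_extent", list(f1, f2),
         params = list(threshold = cfg$anomaly_threshold,
                       n_zero_variance = z_all$n_zero_variance),
         n = sum(z_all$mask))
  })

  if ("frp" %in% stages) run_stage("frp", {
    det <- cl$detections
    has_frp <- !is.na(det$frp)
    ptype <- frp_percentile(det$frp[has_frp], det$fire_type[has_frp],
                            cfg$frp_level)
    yr <- as.integer(format(det$date, "%Y"))
    pyear <- frp_percentile(det$frp[has_frp], yr[has_frp], cfg$frp_level)
    f1 <- file.path(cfg$outdir, "frp90_by_type.csv")
    f2 <- file.path(cfg$outdir, "frp90_by_year.csv")
    utils::write.csv(ptype, f1, row.names = FALSE)
    utils::write.csv(pyear, f2, row.names = FALSE)
    bp_years <- as.integer(pyear$group)
    cand <- intersect(cfg$breakpoint_candidates, bp_years)
    bp <- breakpoint_fit(bp_years, pyear$value, cand,
                         alpha = cfg$alpha_other)
    f3 <- file.path(cfg$outdir, "frp90_breakpoint.json")
    jsonlite::write_json(list(
      breakpoint = bp$breakpoint, pre_slope = bp$pre_slope,
      post_slope = bp$post_slope, sse = bp$sse,
      no_break = bp$no_break,
      mk_pre_p = bp$mk_pre$p_value, mk_post_p = bp$mk_post$p_value),
      f3, auto_unbox = TRUE, digits = NA)
    emit("frp_intensity", list(f1, f2, f3),
         params = list(level = cfg$frp_level,
                       candidates = range(cand)),
         n = sum(has_frp))
  })

  if ("modes" %in% stages) run_stage("modes", {
    det <- cl$detections
    decomps <- list()
    for (ty in fire_types()) {
      dty <- det[!is.na(det$fire_type) & det$fire_type == ty, ,
                 drop = FALSE]
      if (!nrow(dty)) next
      sty <- count_stack(dty, years, land)
      zty <- tryCatch(standardize(sty), error = function(e) NULL)
      if (is.null(zty) || sum(zty$mask) < 2L) next
      decomps[[ty]] <- eof_decompose(zty)
    }
    if (!length(decomps)) stop_af("no fire type has enough varying pixels")
    vt <- variance_table(decomps)
    f1 <- file.path(cfg$outdir, "modes_variance.csv")
    utils::write.csv(vt, f1, row.names = FALSE)
    pcs <- do.call(rbind, lapply(names(decomps), function(ty) {
      d <- decomps[[ty]]
      k <- min(12L, d$n_modes)
      data.frame(fire_type = ty,
                 year = rep(d$years, k),
                 mode = rep(seq_len(k), each = length(d$years)),
                 pc = as.numeric(d$pcs[, seq_len(k)]))
    }))
    f2 <- file.path(cfg$outdir, "pc_series.csv")
    utils::write.csv(pcs, f2, row.names = FALSE)
    emit("mode_decomposition", list(f1, f2),
         params = list(types = names(decomps)), n = nrow(vt))
  })

  if ("co" %in% stages) run_stage("co", {
    co <- if (cfg$mode == "synthetic") {
      generate_co_series(cfg$synthetic,
                         stats::setNames(fires$total,
                                         as.character(fires$year)))
    } else {
      if (is.null(cfg$files$co))
        stop_af("files mode needs a 'co' path for the co stage",
                class = "amazonfire_io_error")
      utils::read.csv(cfg$files$co)
    }
    tfit <- ols_regression(co$year, co$co)
    dfit <- co_on_deforestation(co, inputs$defor)
    targets <- intersect(cfg$sensitivity$target_years, co$year)
    scan <- if (length(targets))
      sensitivity_scan(co, targets, cfg$sensitivity$step,
                       cfg$alpha_other, cfg$sensitivity$max_reduction)
    else NULL
    f1 <- file.path(cfg$outdir, "co_series.csv")
    utils::write.csv(co, f1, row.names = FALSE)
    f2 <- file.path(cfg$outdir, "co_analysis.json")
    jsonlite::write_json(list(
      trend = list(slope = tfit$slope, r_squared = tfit$r_squared,
                   p_value = tfit$p_value),
      on_deforestation = list(slope = dfit$slope,
                              r_squared = dfit$r_squared,
                              p_value = dfit$p_value),
      sensitivity = if (!is.null(scan)) list(
        minimal_reduction = scan$minimal_reduction,
        target_years = scan$target_years,
        step = scan$step,
        profile = scan$profile) else NULL),
      f2, auto_unbox = TRUE, digits = NA)
    f3 <- file.path(cfg$outdir, "co_sensitivity_profile.csv")
    if (!is.null(scan))
      utils::write.csv(scan$profile, f3, row.names = FALSE)
    emit("co_emissions", list(f1, f2, if (!is.null(scan)) f3),
         params = list(alpha = cfg$alpha_other), n = nrow(co))
  })

  mpath <- file.path(cfg$outdir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
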