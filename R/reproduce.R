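#' Run all four Braak-stage scenarios end-to-end
#'
#' For each condition (Control, ADI/II, ADIII/IV, ADV/VI): runs the
#' configured number of replicate simulations from the bundled
#' frontal-cortex membrane composition, segments rafts, computes the
#' size/count/area estimators, domain compositions, whole/inside/
#' outside peroxidability, and (optionally) validates against the
#' experimental raft composition with a random-composition ensemble.
#'
#' @param preset `"desk"` (default; reduced scale) or `"paper"` (full
#'   study scale: 200x200, 1000 iterations, 10 replicates, ensemble
#'   100).
#' @param seed Master integer seed; every replicate and ensemble seed
#'   derives from it, so a rerun reproduces all numbers exactly.
#' @param validate Run the random-ensemble validation per condition
#'   (default `TRUE`).
#' @param outdir Optional directory; when given, writes `report.json`,
#'   a per-replicate CSV, and mobility/PI heatmap PNGs.
#' @param config,ensemble_size Override the preset's configuration or
#'   ensemble size.
#' @return List of class `scenario_report`: per-condition results
#'   (replicate tables, means and SDs, validation), the config, seeds,
#'   and package version.
#' @export
reproduce <- function(preset = c("desk", "paper"), seed = 1, validate = TRUE,
                      outdir = NULL, config = NULL, ensemble_size = NULL) {
  preset <- match.arg(preset)
  ps <- sim_preset(preset)
  if (is.null(config)) config <- ps$config
  if (is.null(ensemble_size)) ensemble_size <- ps$ensemble_size
  sc <- scenario_set()
  ff <- build_force_field(sc$cylinders)
  set.seed(seed)
  rep_seeds <- matrix(sample.int(.Machine$integer.max, 4 * config$replicates),
                      nrow = 4)
  ens_seeds <- sample.int(.Machine$integer.max, 4)
  conditions <- sc$conditions
  out <- list()
  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    comp <- sc$membrane[[cond]]
    reps <- vector("list", config$replicates)
    for (r in seq_len(config$replicates)) {
      cfg <- config
      cfg$seed <- rep_seeds[ci, r]
      res <- run_simulation(comp, ff, cfg)
      rs <- raft_stats(res)
      dp <- tryCatch(domain_pi(res$lattice, rs$mask), error = function(e) NULL)
      dc <- tryCatch(domain_composition(res$lattice, rs$mask),
                     error = function(e) NULL)
      reps[[r]] <- list(
        seed = cfg$seed, stats = rs, result = res,
        row = data.frame(
          condition = cond, replicate = r, seed = cfg$seed,
          tau = rs$tau, mean_size = rs$mean_size, sd_size = rs$sd_size,
          count = rs$count, count_labeled = rs$count_labeled,
          area_fraction = rs$area_fraction,
          pi_whole = if (is.null(dp)) NA else dp$pi_whole,
          pi_inside = if (is.null(dp)) NA else dp$pi_inside,
          pi_outside = if (is.null(dp)) NA else dp$pi_outside),
        raft_composition = if (is.null(dc)) NULL else dc$inside)
    }
    tab <- do.call(rbind, lapply(reps, `[[`, "row"))
    num <- c("mean_size", "count", "area_fraction",
             "pi_whole", "pi_inside", "pi_outside")
    summary <- data.frame(
      condition = cond,
      metric = num,
      mean = vapply(num, function(m) mean(tab[[m]], na.rm = TRUE), 0),
      sd = vapply(num, function(m) stats::sd(tab[[m]], na.rm = TRUE), 0),
      row.names = NULL)
    val <- NULL
    if (validate) {
      cfg <- config
      cfg$seed <- ens_seeds[ci]
      ens <- random_reference_ensemble(
        n = ensemble_size, force_field = ff, config = cfg,
        reference_raft = sc$rafts_experimental[[cond]])
      vcfg <- config
      vcfg$seed <- rep_seeds[ci, 1]
      val <- validate_solution(comp, sc$rafts_experimental[[cond]], ens, ff,
                               vcfg)
    }
    out[[cond]] <- list(replicates = tab, summary = summary,
                        validation = val,
                        raft_compositions = lapply(reps, `[[`, "raft_composition"),
                        example = reps[[1]])
  }
  report <- structure(list(conditions = out, preset = preset, seed = seed,
                           config = config, ensemble_size = ensemble_size,
                           version = as.character(utils::packageVersion("raftsim"))),
                      class = "scenario_report")
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

# Serialize a scenario report: JSON summary, replicate CSV, heatmaps.
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tab <- do.call(rbind, lapply(report$conditions, `[[`, "replicates"))
  write.csv(tab, file.path(outdir, "replicates.csv"), row.names = FALSE)
  js <- lapply(report$conditions, function(cc) {
    v <- cc$validation
    list(summary = cc$summary,
         validation = if (is.null(v)) NULL else list(
           observed = as.list(v$observed), ci = v$ci,
           outside_random_interval = v$outside_random_interval,
           below_random_upper = v$below_random_upper))
  })
  jsonlite::write_json(list(preset = report$preset, seed = report$seed,
                            version = report$version, conditions = js),
                       file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  maps <- list()
  for (cond in names(report$conditions)) {
    ex <- report$conditions[[cond]]$example
    safe <- gsub("[^A-Za-z0-9]", "_", cond)
    maps[[paste0("mobility_", safe)]] <- ex$result$mobility
  }
  export_heatmaps(maps, outdir, zlim = c(0, 1))
  pim <- list()
  for (cond in names(report$conditions)) {
    ex <- report$conditions[[cond]]$example
    if (nrow(ex$result$lattice) %% 5 == 0 && ncol(ex$result$lattice) %% 5 == 0) {
      safe <- gsub("[^A-Za-z0-9]", "_", cond)
      pim[[paste0("pi_", safe)]] <- unclass(pi_patch_map(ex$result$lattice))
    }
  }
  if (length(pim)) export_heatmaps(pim, outdir, zlim = c(0, 600))
  invisible(outdir)
}

#' @export
print.scenario_report <- function(x, ...) {
  cat(sprintf("Scenario report (preset '%s', seed %d)\n", x$preset, x$seed))
  for (cond in names(x$conditions)) {
    s <- x$conditions[[cond]]$summary
    g <- function(m) s$mean[s$metric == m]
    cat(sprintf("  %-9s size %6.2f  count %6.1f  area %5.3f  PI whole %6.1f  in %6.1f  out %6.1f\n",
                cond, g("mean_size"), g("count"), g("area_fraction"),
                g("pi_whole"), g("pi_inside"), g("pi_outside")))
  }
  invisible(x)
}
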