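# Cohort experiment runner: configuration, orchestration, artifacts.

#' Default run configuration
#'
#' A plain named list mirroring the YAML config layout: cohort spec,
#' conduction settings, tree growth, scar predicate, scenario filters, site
#' coordinates and export toggles.
#'
#' @param n_hearts,seed,target_edge_length cohort settings.
#' @return list of class `run_config`.
#' @export
default_config <- function(n_hearts = 19, seed = 1, target_edge_length = 2) {
  structure(list(
    cohort = list(n_hearts = n_hearts, seed = seed,
                  target_edge_length = target_edge_length),
    conduction = list(cv_fibre = 0.6, cv_transverse = 0.24, cv_tree = 3,
                      pmj_delay_antero = 10, pmj_delay_retro = 3),
    tree = list(min_pmjs_per_fascicle = 40),
    scar = list(rho = c(0.10, 0.68), phi = c(-1.3, 1.3), tau = c(0, 0.85),
                border_margin = 0.07, border_cv_multiplier = 1),
    scenarios = list(substrates = SUBSTRATE_LEVELS,
                     protocols = PROTOCOL_LEVELS),
    sites = list(PLBBP = list(fraction = 0.1),
                 DLBBP = list(fraction = 0),
                 RVOT_S = list(rho = 0.90), MS = list(rho = 0.50),
                 AS = list(rho = 0.15)),
    export = list(vtk = FALSE, activation_csv = FALSE)),
    class = "run_config")
}

#' Load / save a run configuration as YAML
#'
#' Unknown top-level keys are rejected; omitted keys take their defaults.
#' @param path YAML file.
#' @return a `run_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_config()
  bad <- setdiff(names(raw), names(cfg))
  if (length(bad)) stop("unknown config section(s): ",
                        paste(bad, collapse = ", "))
  for (k in names(raw)) {
    if (is.list(cfg[[k]]) && is.list(raw[[k]])) {
      cfg[[k]][names(raw[[k]])] <- raw[[k]]
    } else cfg[[k]] <- raw[[k]]
  }
  validate_config(cfg)
  cfg
}

#' @rdname load_config
#' @param config a `run_config`.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Validate a run configuration
#'
#' @param config a `run_config`.
#' @return the config invisibly; stops with the offending field on error.
#' @export
validate_config <- function(config) {
  sc <- config$scenarios
  bad <- setdiff(sc$substrates, SUBSTRATE_LEVELS)
  if (length(bad)) stop("unknown substrate(s) in config: ",
                        paste(bad, collapse = ", "))
  bad <- setdiff(sc$protocols, PROTOCOL_LEVELS)
  if (length(bad)) stop("unknown protocol(s) in config: ",
                        paste(bad, collapse = ", "))
  with(config$cohort, {
    stopifnot(n_hearts >= 1, target_edge_length > 0)
  })
  with(config$conduction, {
    stopifnot(cv_fibre > 0, cv_transverse > 0, cv_tree > 0,
              pmj_delay_antero >= 0, pmj_delay_retro >= 0)
  })
  invisible(config)
}

.config_sites <- function(config) {
  s <- config$sites
  out <- list()
  grab <- function(x, f, d) if (!is.null(x[[f]])) x[[f]] else d
  if (!is.null(s$PLBBP))
    out$PLBBP <- pacing_site("TREE_NODE", branch = "LEFT_BUNDLE",
                             fraction = grab(s$PLBBP, "fraction", 0.1))
  if (!is.null(s$DLBBP))
    out$DLBBP <- pacing_site("TREE_NODE", branch = "LV_POSTERIOR_FASCICLE",
                             fraction = grab(s$DLBBP, "fraction", 0))
  for (p in c("RVOT_S", "MS", "AS"))
    if (!is.null(s[[p]]))
      out[[p]] <- pacing_site("MESH_NODE", rho = s[[p]]$rho,
                              phi = grab(s[[p]], "phi", 0))
  out
}

#' Run the full cohort experiment
#'
#' Generates the synthetic cohort, builds each heart's His-Purkinje tree,
#' runs every substrate x protocol scenario and computes the dyssynchrony
#' metrics.  Scenario failures are recorded and do not stop the run.  When
#' `out_dir` is given, writes `metrics.csv`, `summary_table.csv`,
#' `comparisons.csv`, the resolved `config.yaml`, a `manifest.json` and a
#' progress log; re-running with an identical config reproduces the CSVs
#' byte for byte.
#'
#' @param config a `run_config` (see [default_config()], [load_config()]).
#' @param out_dir output directory, or NULL for no artifacts.
#' @param quiet suppress progress messages.
#' @return the metrics data.frame (one row per heart x scenario), with a
#'   `failures` attribute listing failed scenarios.
#' @export
run_cohort <- function(config = default_config(), out_dir = NULL,
                       quiet = FALSE) {
  validate_config(config)
  t_start <- Sys.time()
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    if (!quiet) message(msg)
  }
  co <- config$cohort
  spec <- cohort_spec(n_hearts = co$n_hearts, seed = co$seed,
                      target_edge_length = co$target_edge_length)
  base_cfg <- do.call(conduction_config, config$conduction)
  sspec <- do.call(scar_spec, config$scar)
  sites <- .config_sites(config)
  matrixx <- build_scenario_matrix(config$scenarios$substrates,
                                   config$scenarios$protocols)
  say("cohort run: %d hearts, %d scenarios each, seed %d",
      spec$n_hearts, nrow(matrixx), spec$seed)

  rows <- list(); fails <- list()
  for (hi in seq_len(spec$n_hearts)) {
    heart <- generate_heart(spec, hi)
    tree <- build_tree(heart$mesh, heart$uvc,
                       tree_params(min_pmjs_per_fascicle =
                                     config$tree$min_pmjs_per_fascicle,
                                   seed = spec$seed * 97L + hi))
    regions <- metric_regions(heart$mesh, heart$uvc)
    say("heart %d/%d: %d nodes, %d tree nodes, %d PMJs", hi, spec$n_hearts,
        nrow(heart$mesh$nodes), nrow(tree$nodes), nrow(tree$pmjs))
    scar <- NULL
    if ("SEPTAL_SCAR" %in% matrixx$substrate)
      scar <- map_scar(heart$mesh, heart$uvc, sspec)
    for (sub in unique(matrixx$substrate)) {
      tr <- tree; cfg <- base_cfg; reg_sub <- regions
      if (sub == "LBBB") tr <- apply_lbbb(tr)
      if (sub == "SEPTAL_SCAR") {
        tr <- deactivate_scar_overlap(tr, scar, heart$mesh, heart$uvc)
        cfg <- substrate_config(cfg, scar, nrow(heart$mesh$tets))
        reg_sub <- metric_regions(heart$mesh, heart$uvc, scar)
      }
      med <- conduction_graph(heart$mesh, cfg)
      ug <- .union_igraph(union_arcs(heart$mesh, tr, cfg, mesh_graph = med))
      for (prot in matrixx$protocol[matrixx$substrate == sub]) {
        res <- tryCatch({
          site <- protocol_site(prot, sites)
          stim <- resolve_site(heart$mesh, heart$uvc, tr, site,
                               scar = if (sub == "SEPTAL_SCAR") scar)
          act <- solve_coupled(heart$mesh, tr, cfg,
                               data.frame(kind = stim$kind, node = stim$node,
                                          onset = stim$onset), graph = ug)
          ms <- compute_metrics(act, reg_sub)
          if (!is.null(out_dir) && isTRUE(config$export$vtk)) {
            dir.create(file.path(out_dir, "maps"), showWarnings = FALSE,
                       recursive = TRUE)
            write_mesh(heart$mesh,
                       file.path(out_dir, "maps",
                                 sprintf("heart%02d_%s_%s.vtu", hi, sub,
                                         prot)),
                       format = "vtu", uvc = heart$uvc, activation = act)
          }
          if (!is.null(out_dir) && isTRUE(config$export$activation_csv)) {
            dir.create(file.path(out_dir, "maps"), showWarnings = FALSE,
                       recursive = TRUE)
            write_activation_csv(act,
              file.path(out_dir, "maps",
                        sprintf("heart%02d_%s_%s.csv", hi, sub, prot)))
          }
          cbind(data.frame(heart = hi, substrate = sub, protocol = prot,
                           stim_kind = stim$kind, stim_node = stim$node,
                           status = "ok"), as.data.frame(ms))
        }, error = function(e) {
          fails[[length(fails) + 1L]] <<- list(heart = hi, substrate = sub,
                                               protocol = prot,
                                               error = conditionMessage(e))
          say("heart %d %s/%s FAILED: %s", hi, sub, prot,
              conditionMessage(e))
          NULL
        })
        if (!is.null(res)) rows[[length(rows) + 1L]] <- res
      }
    }
  }
  results <- do.call(rbind, rows)
  attr(results, "failures") <- fails
  elapsed <- as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  say("done: %d scenario rows, %d failures, %.1f s", nrow(results),
      length(fails), elapsed)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(results, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE, quote = FALSE)
    # small-cohort normality warnings are folded into the tables' test column
    tab <- tryCatch(suppressWarnings(cohort_summary_table(results)),
                    error = function(e) NULL)
    if (!is.null(tab))
      utils::write.csv(tab, file.path(out_dir, "summary_table.csv"),
                       row.names = FALSE, quote = TRUE)
    cmps <- tryCatch(suppressWarnings(.all_comparisons(results)),
                     error = function(e) NULL)
    if (!is.null(cmps))
      utils::write.csv(cmps, file.path(out_dir, "comparisons.csv"),
                       row.names = FALSE, quote = FALSE)
    save_config(config, file.path(out_dir, "config.yaml"))
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
    manifest <- c(
      "{",
      sprintf('  "package": "pacedys %s",',
              as.character(utils::packageVersion("pacedys"))),
      sprintf('  "r_version": "%s",', R.version.string),
      sprintf('  "seed": %d,', as.integer(co$seed)),
      sprintf('  "n_hearts": %d,', as.integer(co$n_hearts)),
      sprintf('  "scenario_rows": %d,', nrow(results)),
      sprintf('  "failures": %d,', length(fails)),
      sprintf('  "elapsed_s": %.1f', elapsed),
      "}")
    writeLines(manifest, file.path(out_dir, "manifest.json"))
  }
  invisible(results)
}

.all_comparisons <- function(results) {
  rows <- list()
  for (sub in unique(results$substrate))
    for (met in c("veu", "abs_veu", "lvdi", "bivat90")) {
      cmp <- compare_groups(results, met, sub,
                            COMBINED_GROUPS$COMBINED_LBBP,
                            COMBINED_GROUPS$COMBINED_LCPM)
      rows[[length(rows) + 1L]] <- data.frame(
        substrate = sub, metric = met, group_a = "COMBINED_LBBP",
        group_b = "COMBINED_LCPM", mean_a = cmp$mean_a, sd_a = cmp$sd_a,
        mean_b = cmp$mean_b, sd_b = cmp$sd_b, test = cmp$test,
        p_value = cmp$p_value)
    }
  do.call(rbind, rows)
}

#' Plot an activation map slice
#'
#' Base-graphics scatter of the nodes near a coordinate plane, coloured by
#' activation time.
#'
#' @param x an [activation_map()].
#' @param mesh the mesh the map belongs to.
#' @param plane "y" (default), "x" or "z": the slicing axis.
#' @param value slice coordinate (mm).
#' @param thickness slab half-thickness (mm).
#' @param ... passed to [plot()].
#' @export
plot.activation_map <- function(x, mesh, plane = "y", value = 0,
                                thickness = 2, ...) {
  ax <- match(plane, c("x", "y", "z"))
  keep <- abs(mesh$nodes[, ax] - value) <= thickness &
    is.finite(x$node_time)
  other <- setdiff(1:3, ax)
  tt <- x$node_time[keep]
  pal <- grDevices::hcl.colors(64, "Spectral", rev = TRUE)
  cols <- pal[pmin(64L, 1L + floor(63 * (tt - min(tt)) /
                                     max(max(tt) - min(tt), 1e-9)))]
  plot(mesh$nodes[keep, other[1]], mesh$nodes[keep, other[2]],
       col = cols, pch = 16, cex = 0.5, asp = 1,
       xlab = paste(c("x", "y", "z")[other[1]], "(mm)"),
       ylab = paste(c("x", "y", "z")[other[2]], "(mm)"), ...)
  invisible(x)
}
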