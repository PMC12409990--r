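# End-to-end orchestration: simulate -> residue networks -> essential
# dynamics / free-energy landscape -> global unfolding fits, from a single
# validated YAML (or list) configuration, with a machine-readable manifest.

.config_schema <- list(
  top = c("seed", "out_dir", "ensemble", "rin", "fel", "foldfit"),
  ensemble = c("path", "n_residues", "n_frames", "mode_sds",
               "isotropic_noise_sd", "rigid_jitter", "atoms_per_residue"),
  rin = c("cutoff", "dc_threshold", "bc_threshold", "conservation_path",
          "annotation_path", "weighted"),
  fel = c("fit_selection", "pca_selection", "bins", "temperature",
          "min_separation"),
  foldfit = c("data_path", "preset", "model", "n_starts", "noise_sd_fraction",
              "urea_points")
)

check_keys <- function(block, allowed, where) {
  unknown <- setdiff(names(block), allowed)
  if (length(unknown))
    stop("unknown config key(s) in ", where, ": ",
         paste(unknown, collapse = ", "))
}

#' Validate a pipeline configuration
#'
#' Rejects unknown keys, non-integer seeds and missing referenced paths
#' before any computation runs.
#'
#' @param config list or YAML file path.
#' @return the validated config list, invisibly filled with defaults.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  check_keys(config, .config_schema$top, "top level")
  for (blk in c("ensemble", "rin", "fel", "foldfit"))
    if (!is.null(config[[blk]]))
      check_keys(config[[blk]], .config_schema[[blk]], blk)
  if (is.null(config$seed)) config$seed <- 1L
  if (config$seed != round(config$seed)) stop("seed must be an integer")
  config$seed <- as.integer(config$seed)
  if (is.null(config$out_dir)) stop("config needs an out_dir")
  for (p in c(config$ensemble$path, config$rin$conservation_path,
              config$rin$annotation_path, config$foldfit$data_path))
    if (!is.null(p) && !file.exists(p))
      stop("referenced path does not exist: ", p)
  invisible(config)
}

stage_time <- function(expr) {
  t0 <- proc.time()[["elapsed"]]
  value <- expr
  list(value = value, seconds = proc.time()[["elapsed"]] - t0)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> rin -> fel -> foldfit in dependency order. Stages
#' whose inputs are supplied as files (ensemble `path`, foldfit `data_path`)
#' load them instead of simulating. All artifacts are written under
#' `out_dir` together with `manifest.json` (input hashes, parameter echo,
#' headline outputs); a stage failure halts downstream stages and is recorded
#' in the report.
#'
#' @param config list or YAML path; see [validate_config()].
#' @param quiet suppress progress messages.
#' @return a `run_report` list: `stages`, `params`, `headline`, `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  config <- validate_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  report <- list(stages = list(), params = config, headline = list())
  artifacts <- character(0)
  seed <- config$seed

  run_stage <- function(name, fun) {
    res <- tryCatch(stage_time(fun()), error = function(e) e)
    if (inherits(res, "error")) {
      report$stages[[name]] <<- list(status = paste("failed:",
                                                    conditionMessage(res)))
      say("stage %s FAILED: %s", name, conditionMessage(res))
      FALSE
    } else {
      report$stages[[name]] <<- list(status = "ok", seconds = res$seconds)
      say("stage %s ok (%.1f s)", name, res$seconds)
      TRUE
    }
  }

  env <- new.env()

  ok <- run_stage("simulate", function() {
    ec <- config$ensemble
    if (!is.null(ec$path)) {
      env$ens <- read_ensemble_pdb(ec$path)
      artifacts <<- c(artifacts, ec$path)
    } else {
      spec <- ensemble_spec(
        n_residues = ec$n_residues %||% 30L,
        n_frames = ec$n_frames %||% 120L,
        mode_sds = unlist(ec$mode_sds %||% c(2, 1)),
        atoms_per_residue = ec$atoms_per_residue %||% 2L,
        isotropic_noise_sd = ec$isotropic_noise_sd %||% 0.05,
        rigid_jitter = isTRUE(ec$rigid_jitter),
        seed = seed
      )
      env$ens <- make_toy_ensemble(spec)
      pdb <- file.path(out_dir, "ensemble.pdb")
      write_ensemble_pdb(env$ens, pdb)
      artifacts <<- c(artifacts, pdb)
    }
    nres <- max(env$ens$atoms$resid)
    if (!is.null(config$rin$conservation_path)) {
      env$conservation <- read_conservation_tsv(config$rin$conservation_path)
    } else {
      env$conservation <- make_conservation_table(nres, seed = seed + 1L)
      cons <- file.path(out_dir, "conservation.tsv")
      write_conservation_tsv(env$conservation, cons)
      artifacts <<- c(artifacts, cons)
    }
    if (!is.null(config$rin$annotation_path)) {
      env$region <- read_region_tsv(config$rin$annotation_path)
    } else {
      env$region <- env$ens$region %||% toy_region_classes(nres)
      reg <- file.path(out_dir, "regions.tsv")
      write_region_tsv(env$region, reg)
      artifacts <<- c(artifacts, reg)
    }
    fc <- config$foldfit
    if (is.null(fc$data_path)) {
      preset <- folding_preset(fc$preset %||% "21M")
      grid <- seq(0, 9, length.out = fc$urea_points %||% 25)
      env$folding <- make_unfolding_datasets(
        preset, urea_grid = grid,
        noise_sd_fraction = fc$noise_sd_fraction %||% 0.02,
        seed = seed + 2L)
      env$fold_model <- preset$params$model
      tsv <- file.path(out_dir, "unfolding.tsv")
      write_unfolding_tsv(env$folding, tsv)
      artifacts <<- c(artifacts, tsv)
    } else {
      env$folding <- read_unfolding_tsv(fc$data_path)
      env$fold_model <- fc$model %||% "three_state"
      artifacts <<- c(artifacts, fc$data_path)
    }
    NULL
  })

  if (ok) ok <- run_stage("rin", function() {
    rc <- config$rin
    env$rin <- build_rin(env$ens, cutoff = rc$cutoff %||% 6.0)
    env$metrics <- residue_metrics(env$rin, conservation = env$conservation,
                                   region = env$region,
                                   weighted = !isFALSE(rc$weighted))
    hubs <- classify_hubs(env$metrics,
                          dc_threshold = rc$dc_threshold %||% 20,
                          bc_threshold = rc$bc_threshold %||% 1000)
    report$headline$hubs <<- hubs$hubs
    report$headline$quadrant_counts <<- as.vector(hubs$quadrant_counts)
    report$headline$dc_by_region <<-
      metric_distributions(env$metrics, "region", "DC")$summary
    f_metrics <- file.path(out_dir, "residue_metrics.csv")
    utils::write.csv(env$metrics, f_metrics, row.names = FALSE)
    f_edges <- file.path(out_dir, "rin_edges.tsv")
    f_gml <- file.path(out_dir, "rin.graphml")
    write_rin(env$rin, f_edges, f_gml)
    artifacts <<- c(artifacts, f_metrics, f_edges, f_gml)
    NULL
  })

  if (ok) ok <- run_stage("fel", function() {
    fc <- config$fel
    sup <- superpose(env$ens, selection = fc$fit_selection %||% "CA")
    env$pca <- pca(sup$ensemble, selection = fc$pca_selection %||% "heavy")
    env$proj <- project(sup$ensemble, env$pca, k = 2)
    env$fel <- build_fel(env$proj, bins = fc$bins %||% 32L,
                         temperature = fc$temperature %||% 298.15)
    env$basins <- find_basins(env$fel,
                              min_separation = fc$min_separation %||% 2L)
    report$headline$basins <<- env$basins
    report$headline$breadth <<- landscape_breadth(env$fel)
    f_proj <- file.path(out_dir, "projections.csv")
    utils::write.csv(
      data.frame(frame = seq_len(nrow(env$proj)), env$proj),
      f_proj, row.names = FALSE)
    f_eval <- file.path(out_dir, "eigenvalues.txt")
    utils::write.table(
      data.frame(mode = seq_along(env$pca$values),
                 eigenvalue_A2 = env$pca$values),
      f_eval, row.names = FALSE, quote = FALSE)
    f_fel <- file.path(out_dir, "fel_grid.csv")
    utils::write.csv(fel_as_table(env$fel), f_fel, row.names = FALSE)
    f_bas <- file.path(out_dir, "basins.json")
    jsonlite::write_json(env$basins, f_bas, dataframe = "rows", digits = NA)
    artifacts <<- c(artifacts, f_proj, f_eval, f_fel, f_bas)
    for (b in seq_len(nrow(env$basins))) {
      fr <- representative_frame(env$basins[b, ], env$proj)
      one <- conformational_ensemble(
        env$ens$coords[fr, , , drop = FALSE], env$ens$atoms)
      f_rep <- file.path(out_dir, sprintf("basin%d_frame%d.pdb", b, fr))
      write_ensemble_pdb(one, f_rep)
      artifacts <<- c(artifacts, f_rep)
    }
    NULL
  })

  if (ok) ok <- run_stage("foldfit", function() {
    fc <- config$foldfit
    fit <- global_fit(env$folding, model = fc$model %||% env$fold_model,
                      n_starts = fc$n_starts %||% 25L, seed = seed + 3L)
    env$fit <- fit
    report$headline$dG <<- fit$params$dG
    report$headline$m <<- fit$params$m
    report$headline$dG_total <<- sum(fit$params$dG)
    report$headline$aic <<- fit$aic
    conc <- concentration_dependence_test(env$folding)
    report$headline$concentration_independent <<-
      conc$concentration_independent
    f_fit <- file.path(out_dir, "fit_report.json")
    jsonlite::write_json(
      list(model = fit$model, dG = fit$params$dG, m = fit$params$m,
           se = as.list(fit$se), rss = fit$rss, aic = fit$aic,
           n_parameters = fit$n_parameters, converged = fit$converged,
           seed = fit$seed, baselines = fit$params$baselines,
           concentration_independent = conc$concentration_independent),
      f_fit, auto_unbox = TRUE, digits = NA)
    grid <- seq(min(env$folding$urea_M), max(env$folding$urea_M),
                length.out = 100)
    curves <- do.call(rbind, lapply(names(fit$params$baselines), function(p)
      data.frame(probe = p, urea_M = grid,
                 signal = signal_model(fit$params, grid, p))))
    f_curv <- file.path(out_dir, "fitted_curves.csv")
    utils::write.csv(curves, f_curv, row.names = FALSE)
    artifacts <<- c(artifacts, f_fit, f_curv)
    NULL
  })

  manifest <- list(
    seed = seed,
    files = lapply(stats::setNames(nm = basename(artifacts)), function(b) {
      p <- artifacts[basename(artifacts) == b][1]
      unname(tools::md5sum(p))
    }),
    stages = lapply(report$stages, function(s) s$status)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  report$manifest <- manifest
  class(report) <- "run_report"
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fel_as_table <- function(fel) {
  xc <- (fel$xedges[-1] + fel$xedges[-length(fel$xedges)]) / 2
  yc <- (fel$yedges[-1] + fel$yedges[-length(fel$yedges)]) / 2
  idx <- which(!is.na(fel$G), arr.ind = TRUE)
  data.frame(pc1 = xc[idx[, 1]], pc2 = yc[idx[, 2]],
             count = fel$counts[idx], G = fel$G[idx])
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  for (s in names(x$stages))
    cat(sprintf("  %-10s %s\n", s, x$stages[[s]]$status))
  if (!is.null(x$headline$dG))
    cat(sprintf("  fitted dG: %s kcal/mol (total %.2f)\n",
                paste(round(x$headline$dG, 3), collapse = ", "),
                x$headline$dG_total))
  invisible(x)
}

#' Compare two pipeline runs on a shared metric
#'
#' Mirrors the water-vs-urea contrasts: per-group signed differences of the
#' chosen metric between two run reports.
#'
#' @param report_a,report_b `run_report` objects.
#' @param metric `"breadth"` (landscape area and PC1 span) or
#'   `"dc_by_region"` (median DC per structural region).
#' @return data.frame of per-group values in each report and `difference`
#'   (a minus b).
#' @export
compare_conditions <- function(report_a, report_b,
                               metric = c("breadth", "dc_by_region")) {
  metric <- match.arg(metric)
  if (metric == "breadth") {
    ba <- report_a$headline$breadth; bb <- report_b$headline$breadth
    if (is.null(ba) || is.null(bb)) stop("metric 'breadth' absent from a report")
    keys <- c("occupied_bins", "area", "pc1_span")
    data.frame(group = keys,
               a = unlist(ba[keys]), b = unlist(bb[keys]),
               difference = unlist(ba[keys]) - unlist(bb[keys]),
               row.names = NULL)
  } else {
    da <- report_a$headline$dc_by_region; db <- report_b$headline$dc_by_region
    if (is.null(da) || is.null(db))
      stop("metric 'dc_by_region' absent from a report")
    missing_a <- setdiff(db$group, da$group)
    missing_b <- setdiff(da$group, db$group)
    if (length(missing_a) || length(missing_b))
      stop("mismatched region sets; missing: ",
           paste(unique(c(missing_a, missing_b)), collapse = ", "))
    m <- match(da$group, db$group)
    data.frame(group = da$group, a = da$median, b = db$median[m],
               difference = da$median - db$median[m])
  }
}
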