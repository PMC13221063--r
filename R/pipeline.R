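#' Run the full wadi HSI pipeline
#'
#' Chains the stages end to end: (optionally) simulate a seeded synthetic
#' dataset, fit the suitability curves and composite HSI, classify sites,
#' compute diversity metrics and the bootstrap HSI-diversity correlations,
#' run the validation battery (confusion metrics at a selected threshold,
#' AUC, calibration ratio, Boyce index, LOOCV), and the conservation gap
#' analysis on the grids. All artifacts are written under `out_dir`
#' together with a manifest (inputs, seed, package version, config hash,
#' MD5 of every output). Two runs from the same config are identical. A
#' missing community matrix skips the diversity stage with a notice; any
#' stage failure aborts naming the stage, retaining partial outputs.
#'
#' @param config named list (or path to a YAML/JSON file) with any of:
#'   `seed` (default 1), `n_sites` (default 12), `sites` (path to a site
#'   CSV; otherwise synthetic), `community` (`TRUE` to simulate, `FALSE`
#'   to skip, or a path to a community CSV), `thresholds` (for
#'   [classify_suitability()]), `n_boot` (default 1000),
#'   `grid` (list `n_rows`, `n_cols`, `pa_fraction`), `cell_area_km2`,
#'   `targets`.
#' @param out_dir output directory (created; default `tempdir()` subdir).
#' @return invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        abort("yaml package required to read YAML configs")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  known <- c("seed", "n_sites", "sites", "community", "thresholds",
             "n_boot", "grid", "cell_area_km2", "targets")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    abort("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(
    list(seed = 1, n_sites = 12, sites = NULL, community = TRUE,
         thresholds = "quantile", n_boot = 1000,
         grid = list(n_rows = 60, n_cols = 60, pa_fraction = 0.056),
         cell_area_km2 = 1, targets = c(national_2040 = 7.5, cbd_30x30 = 30)),
    config)
  if (is.null(out_dir))
    out_dir <- file.path(tempdir(), paste0("wadihsi-run-", cfg$seed))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }

  model <- true_model(seed = cfg$seed)
  sites <- stage("simulate", {
    if (is.null(cfg$sites)) simulate_sites(model, n_sites = cfg$n_sites)$sites
    else read_site_table(cfg$sites)
  })
  write_site_table(sites, file.path(out_dir, "sites.csv"))

  fit <- stage("fit", hsi_fit(sites))
  write_curves(fit, file.path(out_dir, "curves.csv"))
  cls <- stage("score", classify_suitability(fit$hsi, cfg$thresholds))
  scores <- data.frame(site = fit$site, hsi = fit$hsi, class = cls$labels,
                       row.names = NULL)
  write.csv(scores, file.path(out_dir, "hsi.csv"), row.names = FALSE)

  diversity <- correlations <- NULL
  if (!isFALSE(cfg$community)) {
    comm <- stage("diversity", {
      if (isTRUE(cfg$community))
        simulate_community(setNames(fit$hsi, fit$site), model,
                           seed = cfg$seed)
      else as.matrix(read.csv(cfg$community, row.names = 1))
    })
    diversity <- diversity_table(comm)
    write.csv(diversity, file.path(out_dir, "diversity.csv"),
              row.names = FALSE)
    write.csv(as.data.frame(bray_curtis_matrix(comm)),
              file.path(out_dir, "bray_curtis.csv"))
    correlations <- lapply(
      c(shannon = "shannon", simpson = "simpson", evenness = "evenness"),
      function(m) {
        y <- diversity[[m]]
        if (anyNA(y)) return(NULL)
        correlate_with_bootstrap(fit$hsi, y, n_boot = cfg$n_boot,
                                 seed = cfg$seed)
      })
  } else message("community matrix absent: diversity stage skipped")

  validation <- stage("validate", {
    obs_pos <- sites$abundance > stats::median(sites$abundance)
    thr <- select_threshold(fit$hsi[obs_pos], fit$hsi[!obs_pos],
                            method = "MaxSS")
    pred_pos <- fit$hsi >= thr$threshold
    list(confusion = confusion_metrics(
           tp = sum(pred_pos & obs_pos), fp = sum(pred_pos & !obs_pos),
           tn = sum(!pred_pos & !obs_pos), fn = sum(!pred_pos & obs_pos)),
         threshold = thr,
         auc = auc(fit$hsi[obs_pos], fit$hsi[!obs_pos]),
         calibration = calibration_ratio(fit$hsi[obs_pos],
                                         fit$hsi[!obs_pos]),
         loocv = loocv_hsi(sites))
  })
  jsonlite::write_json(
    list(auc = validation$auc, threshold = validation$threshold$threshold,
         calibration = validation$calibration,
         tss = validation$confusion$tss,
         loocv_r2 = validation$loocv$r_squared),
    file.path(out_dir, "validation.json"), auto_unbox = TRUE, digits = NA)

  gap <- stage("gap", {
    grids <- simulate_grids(cfg$grid$n_rows, cfg$grid$n_cols,
                            cfg$grid$pa_fraction, seed = cfg$seed)
    hs <- high_suitability_mask(grids$suitability$data)
    pr <- protection_rate(hs$mask, grids$protected$data == 1,
                          cell_area_km2 = cfg$cell_area_km2)
    dens_class <- wadi_density_classify(as.numeric(grids$density$data))
    list(threshold = hs$threshold, protection = pr,
         targets = target_progress(pr$rate, cfg$targets),
         density = density_protection_summary(
           dens_class, as.logical(grids$protected$data)))
  })
  write.csv(gap$targets, file.path(out_dir, "gap_targets.csv"),
            row.names = FALSE)

  outputs <- list.files(out_dir, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest <- list(
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("wadihsi")),
    config_hash = config_hash(cfg),
    outputs = setNames(as.list(unname(tools::md5sum(outputs))),
                       basename(outputs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(sites = sites, fit = fit, classification = cls,
                 diversity = diversity, correlations = correlations,
                 validation = validation, gap = gap, manifest = manifest,
                 out_dir = out_dir))
}

# internal: stable hash of the effective configuration
config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE,
                              digits = NA), f)
  unname(tools::md5sum(f))
}
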