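#' Build and validate a pipeline run configuration
#'
#' A run config drives the full chain: synthetic slides per patient, CVF
#' quantification, cohort simulation keyed to the measured CVF, the
#' cutpoint scan, KM curves for both endpoints, the Cox model ladder, and a
#' complication-rate table computed from supplied counts. Every stochastic
#' stage must carry an explicit seed; a config with any missing seed is
#' refused. Configs round-trip losslessly through YAML.
#'
#' @param n_patients number of simulated patients.
#' @param fragments_per_patient biopsy fragments per patient.
#' @param fragment_area_mm2 tissue area per fragment.
#' @param stain `"trichrome"` or `"afog"`.
#' @param resolution_um_per_px working pixel size.
#' @param opening_radius_px,min_fragment_mm2 morphology parameters.
#' @param endpoint `"composite"` or `"death"` for the scan and ladder.
#' @param imputation_m imputed datasets for the ladder (2 disables nothing;
#'   use larger in real runs).
#' @param cutpoint_lo,cutpoint_hi scan range.
#' @param complication_counts named list of `count`/`n` pairs for the rate
#'   table (printed-count inputs).
#' @param seeds named list with integer seeds `slides`, `cohort`,
#'   `training`, `imputation`.
#' @return list of class `run_config`.
#' @export
run_config <- function(n_patients = 50, fragments_per_patient = 2,
                       fragment_area_mm2 = 1.5,
                       stain = "trichrome",
                       resolution_um_per_px = 4,
                       opening_radius_px = 1, min_fragment_mm2 = 0.01,
                       endpoint = "composite",
                       imputation_m = 5,
                       cutpoint_lo = 5, cutpoint_hi = 95,
                       complication_counts = list(
                         major = list(count = 4, n = 524),
                         minor = list(count = 11, n = 524)
                       ),
                       seeds = list(slides = 11L, cohort = 12L,
                                    training = 13L, imputation = 14L)) {
  cfg <- list(
    n_patients = n_patients, fragments_per_patient = fragments_per_patient,
    fragment_area_mm2 = fragment_area_mm2, stain = stain,
    resolution_um_per_px = resolution_um_per_px,
    opening_radius_px = opening_radius_px,
    min_fragment_mm2 = min_fragment_mm2,
    endpoint = endpoint, imputation_m = imputation_m,
    cutpoint_lo = cutpoint_lo, cutpoint_hi = cutpoint_hi,
    complication_counts = complication_counts,
    seeds = seeds
  )
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  need_seeds <- c("slides", "cohort", "training", "imputation")
  missing_seeds <- setdiff(need_seeds, names(cfg$seeds))
  if (length(missing_seeds) ||
      any(vapply(cfg$seeds[need_seeds], function(s) {
        !is.numeric(s) || length(s) != 1 || is.na(s)
      }, logical(1)))) {
    stop("config refused: every stochastic stage needs an explicit seed (",
         paste(need_seeds, collapse = ", "), ")")
  }
  if (cfg$n_patients <= 0) stop("`n_patients` must be > 0")
  if (!cfg$endpoint %in% c("composite", "death")) {
    stop("`endpoint` must be 'composite' or 'death'")
  }
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @param cfg a `run_config`.
#' @return `read_run_config` returns a validated `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

stage_log <- function(verbose, stage, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full synthetic pipeline into an output directory
#'
#' Executes slide generation, per-patient CVF quantification, cohort
#' simulation (event risk driven by the measured CVF through the
#' change-point hazard), the minimum-p cutpoint scan, KM curves for both
#' endpoints, the CVF-adjusted Cox model ladder, and the
#' complication-rate table. Each stage logs record counts in/out; a failing
#' stage halts with the stage name while earlier outputs persist. A
#' manifest with an MD5 content hash per output file is written last, so a
#' re-run can be verified byte-for-byte.
#'
#' @param config a [run_config()] (or path to a YAML config).
#' @param out_dir output directory (created if needed).
#' @param verbose log stage boundaries (default TRUE).
#' @return invisibly, a list with the in-memory stage results and
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir, verbose = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()
  emit_csv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    outputs <<- c(outputs, p)
    p
  }
  emit_json <- function(x, name) {
    p <- file.path(out_dir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    outputs <<- c(outputs, p)
    p
  }
  fail <- function(stage, e) {
    stop("pipeline halted at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }

  # --- stage: slides + quantification -------------------------------------
  cvf_tab <- tryCatch({
    pal <- stain_palette(config$stain)
    # one shared classifier trained on the first patient's first fragment
    ref <- generate_fragment(
      config$fragment_area_mm2, 30, pal,
      resolution_um_per_px = config$resolution_um_per_px,
      fragment_id = "train-ref", seed = config$seeds$training
    )
    clf <- train_classifier(
      sample_training_pixels(ref, 300, seed = config$seeds$training)
    )
    planted <- withr::with_seed(config$seeds$slides, {
      runif(config$n_patients, 8, 70)
    })
    rows <- list()
    for (i in seq_len(config$n_patients)) {
      frags <- list()
      for (j in seq_len(config$fragments_per_patient)) {
        sl <- generate_fragment(
          config$fragment_area_mm2, planted[i], pal,
          resolution_um_per_px = config$resolution_um_per_px,
          fragment_id = sprintf("P%04d-F%d", i, j),
          seed = config$seeds$slides + i * 1000L + j
        )
        sl <- add_artifacts(sl, n_dust = 4, n_micro_fragments = 2,
                            seed = config$seeds$slides + i * 1000L + j + 500L)
        seg <- quantify_slide(
          sl, clf,
          opening_radius_px = config$opening_radius_px,
          min_fragment_mm2 = config$min_fragment_mm2
        )
        frags[[j]] <- seg
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = sprintf("P%04d", i), fragment_id = sl$fragment_id,
          fibrosis_mm2 = class_mm2(seg, "fibrosis"),
          muscle_mm2 = class_mm2(seg, "muscle"),
          cvf_percent = compute_cvf(class_mm2(seg, "fibrosis"),
                                    class_mm2(seg, "muscle")),
          planted_cvf_percent = planted[i]
        )
      }
      qc <- quality_filter(frags)
      pc <- if (length(qc$retained)) {
        aggregate_patient(sprintf("P%04d", i), qc$retained)
      } else {
        NULL
      }
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = sprintf("P%04d", i), fragment_id = "TOTAL",
        fibrosis_mm2 = if (is.null(pc)) NA else pc$total_fibrosis_mm2,
        muscle_mm2 = if (is.null(pc)) NA else pc$total_muscle_mm2,
        cvf_percent = if (is.null(pc)) NA else pc$cvf_percent,
        planted_cvf_percent = planted[i]
      )
    }
    do.call(rbind, rows)
  }, error = function(e) fail("quantify", e))
  patient_cvf <- cvf_tab[cvf_tab$fragment_id == "TOTAL", ]
  stage_log(verbose, "quantify", "%d patients, %d fragment rows",
            nrow(patient_cvf), sum(cvf_tab$fragment_id != "TOTAL"))
  emit_csv(cvf_tab, "cvf_per_fragment.csv")

  # --- stage: cohort -------------------------------------------------------
  cohort <- tryCatch({
    spec <- cohort_spec(n = config$n_patients, seed = config$seeds$cohort)
    simulate_cohort(spec, cvf_percent = patient_cvf$cvf_percent)
  }, error = function(e) fail("cohort", e))
  stage_log(verbose, "cohort", "%d records, %d composite events",
            nrow(cohort), sum(cohort$event_composite))
  emit_csv(cohort, "cohort.csv")

  # --- stage: cutpoint scan ------------------------------------------------
  scan <- tryCatch(
    scan_cutpoints(cohort, lo = config$cutpoint_lo, hi = config$cutpoint_hi,
                   endpoint = config$endpoint),
    error = function(e) fail("cutpoint", e)
  )
  stage_log(verbose, "cutpoint", "optimal %d%% (p=%.3g)",
            scan$optimal_cutpoint, scan$optimal_p)
  emit_json(list(optimal_cutpoint = scan$optimal_cutpoint,
                 optimal_p = scan$optimal_p, table = scan$table),
            "cutpoint_scan.json")

  # --- stage: KM curves for both endpoints --------------------------------
  tryCatch({
    for (ep in c("composite", "death")) {
      tcol <- if (ep == "composite") "time_composite_years" else
        "time_death_years"
      ecol <- if (ep == "composite") "event_composite" else "event_death_any"
      hi_grp <- cohort$cvf_percent >= scan$optimal_cutpoint
      km_rows <- do.call(rbind, lapply(c(FALSE, TRUE), function(gv) {
        km <- km_estimate(cohort[[tcol]][hi_grp == gv],
                          cohort[[ecol]][hi_grp == gv],
                          group_label = if (gv) "high_cvf" else "low_cvf")
        if (length(km$time) == 0) return(NULL)
        data.frame(group = km$group_label, time = km$time,
                   n_risk = km$n_risk, n_event = km$n_event,
                   survival = km$survival)
      }))
      emit_csv(km_rows, paste0("km_", ep, ".csv"))
    }
  }, error = function(e) fail("km", e))

  # --- stage: group comparison (table-one style) ---------------------------
  tryCatch({
    cohort$cvf_group <- ifelse(cohort$cvf_percent >= scan$optimal_cutpoint,
                               "high", "low")
    spec_vars <- list(age = "mean", bmi = "mean", lvef = "mean",
                      ntprobnp = "median", diabetes = "categorical")
    tone <- do.call(rbind, lapply(names(spec_vars), function(v) {
      cg <- compare_groups(cohort, "cvf_group", v, type = spec_vars[[v]])
      data.frame(variable = v, test = cg$test, p_value = cg$p_value)
    }))
    emit_csv(tone, "group_comparison.csv")
  }, error = function(e) fail("table_one", e))

  # --- stage: model ladder -------------------------------------------------
  ladder <- tryCatch({
    imp <- impute_pmm_bootstrap(
      cohort,
      variables = c("cvf_percent", "age", "bmi", "lvef", "log_ntprobnp",
                    "nyha", "creatinine", "diabetes"),
      m = max(2, config$imputation_m), seed = config$seeds$imputation
    )
    tcol <- if (config$endpoint == "composite") "time_composite_years" else
      "time_death_years"
    ecol <- if (config$endpoint == "composite") "event_composite" else
      "event_death_any"
    two_predictor_ladder(
      imp$datasets,
      predictors = c("age", "bmi", "lvef", "log_ntprobnp", "diabetes"),
      time_col = tcol, event_col = ecol
    )
  }, error = function(e) fail("ladder", e))
  stage_log(verbose, "ladder", "%d predictor rows", nrow(ladder))
  emit_csv(ladder, "model_ladder.csv")

  # --- stage: complication rates (printed-count inputs) --------------------
  comp <- tryCatch({
    do.call(rbind, lapply(names(config$complication_counts), function(nm) {
      cc <- config$complication_counts[[nm]]
      data.frame(category = nm, count = cc$count, n = cc$n,
                 percent = proportion_percent(cc$count, cc$n, 2))
    }))
  }, error = function(e) fail("complications", e))
  emit_csv(comp, "complication_rates.csv")

  # --- manifest ------------------------------------------------------------
  manifest <- data.frame(
    file = basename(outputs),
    md5 = unname(tools::md5sum(outputs)),
    row.names = NULL
  )
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("fibrosurv")),
         seeds = config$seeds, files = manifest),
    mpath, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  stage_log(verbose, "manifest", "%d files hashed", nrow(manifest))

  invisible(list(cvf = cvf_tab, cohort = cohort, scan = scan,
                 ladder = ladder, complications = comp,
                 manifest = manifest, out_dir = out_dir))
}

#' Verify a pipeline run directory against its manifest
#'
#' @param out_dir a directory produced by [run_pipeline()].
#' @return TRUE if every listed file exists with a matching MD5 hash.
#' @export
verify_manifest <- function(out_dir) {
  m <- jsonlite::read_json(file.path(out_dir, "manifest.json"),
                           simplifyVector = TRUE)
  paths <- file.path(out_dir, m$files$file)
  if (!all(file.exists(paths))) return(FALSE)
  all(unname(tools::md5sum(paths)) == m$files$md5)
}
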