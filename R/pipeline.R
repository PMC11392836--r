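#' Pipeline configuration
#'
#' Bundles every tunable of the simulate - spectra - PAF - aggregate - stats
#' chain. The defaults are the analysis constants the rest of the package
#' documents: 1-55 Hz aperiodic fit range, 7-13 Hz alpha band, Huber tuning
#' constant 1.35, 5-s segments with a minimum of 10, 80% Welch overlap at
#' 500 Hz, FDR level 0.05, HC1 robust standard errors.
#'
#' @param cohort A [cohort_sim_config()] used when `simulate = TRUE`.
#' @param simulate Simulate the cohort (default) or read `spectra_csv` /
#'   `metadata_csv`.
#' @param spectra_csv,metadata_csv Input paths when `simulate = FALSE`.
#' @param timeseries_csv Optional long CSV of time series (`subject_id`,
#'   `parcel`, `amplitude` in sample order); when given (with
#'   `simulate = FALSE`), spectra are computed by the segmentation and Welch
#'   stages, and subjects failing the minimum-segment rule are excluded with
#'   a warning while the run continues.
#' @param fit_range,alpha_band Hz intervals, see [band_config()].
#' @param huber_c Huber tuning constant.
#' @param segment_len_s,min_segments,overlap,fs Welch stage parameters
#'   (used when starting from time series).
#' @param baseline Gaussian baseline convention, see [fit_gaussian_peak()].
#' @param fdr_q FDR level.
#' @param se_flavor Robust SE flavor.
#' @param mapping_path Optional TSV overriding [dk_region_mapping()].
#' @param seed Integer seed recorded in the manifest and pushed into the
#'   cohort config.
#'
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_sim_config(), simulate = TRUE,
                            spectra_csv = NULL, metadata_csv = NULL,
                            timeseries_csv = NULL,
                            fit_range = c(1, 55), alpha_band = c(7, 13),
                            huber_c = 1.35, segment_len_s = 5,
                            min_segments = 10, overlap = 0.8, fs = 500,
                            baseline = "fixed1", fdr_q = 0.05,
                            se_flavor = "HC1", mapping_path = NULL,
                            seed = 1L) {
  cohort$seed <- as.integer(seed)
  structure(
    list(cohort = cohort, simulate = simulate, spectra_csv = spectra_csv,
         metadata_csv = metadata_csv, timeseries_csv = timeseries_csv,
         fit_range = fit_range,
         alpha_band = alpha_band, huber_c = huber_c,
         segment_len_s = segment_len_s, min_segments = min_segments,
         overlap = overlap, fs = fs, baseline = baseline, fdr_q = fdr_q,
         se_flavor = se_flavor, mapping_path = mapping_path,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Serialize / parse a pipeline configuration
#'
#' YAML round-trip: `parse_config(serialize_config(cfg))` reproduces `cfg`.
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#'
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   `pipeline_config`.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$cohort <- unclass(x$cohort)
  x$cohort$spectrum <- unclass(x$cohort$spectrum)
  for (nm in c("srs_mean", "srs_sd", "mps_mean", "mps_sd", "ach_mean",
               "ach_sd", "invalid_peak_rate", "paf_baseline")) {
    x$cohort[[nm]] <- as.list(x$cohort[[nm]])  # yaml maps keep names
  }
  x$cohort$age_slope <- list(
    region = rep(rownames(config$cohort$age_slope), 2L),
    group = rep(colnames(config$cohort$age_slope), each = 10L),
    value = as.vector(config$cohort$age_slope)
  )
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  slope <- matrix(unlist(x$cohort$age_slope$value), nrow = 10,
                  dimnames = list(unlist(x$cohort$age_slope$region)[1:10],
                                  unique(unlist(x$cohort$age_slope$group))))
  sp <- do.call(spectrum_sim_config, x$cohort$spectrum)
  co_args <- x$cohort
  co_args$spectrum <- sp
  co_args$age_slope <- slope
  co_args$srs_mean <- unlist(co_args$srs_mean)
  co_args$srs_sd <- unlist(co_args$srs_sd)
  co_args$mps_mean <- unlist(co_args$mps_mean)
  co_args$mps_sd <- unlist(co_args$mps_sd)
  co_args$ach_mean <- unlist(co_args$ach_mean)
  co_args$ach_sd <- unlist(co_args$ach_sd)
  co_args$invalid_peak_rate <- unlist(co_args$invalid_peak_rate)
  co_args$paf_baseline <- unlist(co_args$paf_baseline)
  co_args$age_range_asd <- unlist(co_args$age_range_asd)
  co_args$age_range_td <- unlist(co_args$age_range_td)
  cohort <- do.call(cohort_sim_config, co_args)
  args <- x[setdiff(names(x), "cohort")]
  args$fit_range <- unlist(args$fit_range)
  args$alpha_band <- unlist(args$alpha_band)
  args$cohort <- cohort
  do.call(pipeline_config, args)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) - PAF estimation - regional aggregation -
#' statistics, writing every stage's output plus a manifest
#' (`manifest.json`: seed, configuration, per-stage record counts, content
#' hash) into `out_dir`. Reruns with the same configuration and seed are
#' bit-identical for simulated inputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created; contents overwritten).
#' @param analyses Which moderator scans to run; subset of
#'   `c("age", "srs", "mps", "ach")`.
#'
#' @return `out_dir`, invisibly. Stage outputs: `metadata.csv`,
#'   `spectra.csv`, `parcel_paf.csv`, `region_paf.csv`,
#'   `stats_<analysis>.csv`, `validity_by_diagnosis.csv`,
#'   `validity_by_region.csv`, `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir,
                         analyses = c("age", "srs", "mps", "ach")) {
  stopifnot(inherits(config, "pipeline_config"))
  analyses <- if (length(analyses)) match.arg(analyses, several.ok = TRUE) else character()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()
  message("stage: inputs")
  if (config$simulate) {
    cohort <- simulate_cohort(config$cohort, spectra = TRUE)
    metadata <- cohort$metadata
    spectra <- cohort$spectra
  } else if (!is.null(config$timeseries_csv)) {
    if (is.null(config$metadata_csv)) {
      stop_alphapaf("`timeseries_csv` requires `metadata_csv`",
                    "alphapaf_config_error")
    }
    metadata <- utils::read.csv(config$metadata_csv, stringsAsFactors = FALSE)
    tsd <- utils::read.csv(config$timeseries_csv, stringsAsFactors = FALSE)
    welched <- welch_from_long(tsd, config)
    spectra <- welched$spectra
    if (length(welched$excluded)) {
      warning(sprintf("subjects excluded by the minimum-segment rule: %s",
                      paste(welched$excluded, collapse = ", ")))
      metadata <- metadata[!metadata$subject_id %in% welched$excluded, ,
                           drop = FALSE]
    }
    counts$subjects_excluded <- length(welched$excluded)
  } else {
    if (is.null(config$spectra_csv) || is.null(config$metadata_csv)) {
      stop_alphapaf("simulate = FALSE requires `spectra_csv` and `metadata_csv`",
                    "alphapaf_config_error")
    }
    metadata <- utils::read.csv(config$metadata_csv, stringsAsFactors = FALSE)
    spectra <- utils::read.csv(config$spectra_csv, stringsAsFactors = FALSE)
  }
  utils::write.csv(metadata, file.path(out_dir, "metadata.csv"), row.names = FALSE)
  utils::write.csv(spectra, file.path(out_dir, "spectra.csv"), row.names = FALSE)
  counts$subjects <- nrow(metadata)
  counts$spectra <- nrow(unique(spectra[, c("subject_id", "parcel")]))

  message("stage: paf")
  cfg <- band_config(config$fit_range, config$alpha_band)
  parcel <- estimate_paf_table(spectra, cfg, tuning_constant = config$huber_c,
                               baseline = config$baseline)
  utils::write.csv(parcel, file.path(out_dir, "parcel_paf.csv"), row.names = FALSE)
  counts$parcel_fits <- nrow(parcel)
  counts$valid_fits <- sum(parcel$valid)

  message("stage: aggregate")
  mapping <- if (is.null(config$mapping_path)) {
    dk_region_mapping()
  } else load_mapping(config$mapping_path)
  region <- aggregate_regions(parcel, mapping)
  utils::write.csv(region, file.path(out_dir, "region_paf.csv"), row.names = FALSE)
  counts$region_rows <- nrow(region)

  parcel_md <- merge(parcel, metadata[, c("subject_id", "group")],
                     by = "subject_id")
  parcel_md$diagnosis <- parcel_md$group
  vdiag <- validity_summary(parcel_md, by = "diagnosis")
  vreg <- validity_summary(parcel_md, by = "region", mapping = mapping)
  utils::write.csv(vdiag, file.path(out_dir, "validity_by_diagnosis.csv"),
                   row.names = FALSE)
  utils::write.csv(vreg, file.path(out_dir, "validity_by_region.csv"),
                   row.names = FALSE)

  message("stage: stats")
  moderators <- c(age = "age_months", srs = "srs_total", mps = "mps", ach = "ach")
  for (an in analyses) {
    scan <- region_interaction_scan(
      region, metadata, moderator = moderators[[an]],
      focal = if (an == "srs") "moderator" else "interaction",
      q = config$fdr_q, se_flavor = config$se_flavor
    )
    utils::write.csv(scan$scan, file.path(out_dir, paste0("stats_", an, ".csv")),
                     row.names = FALSE)
  }
  counts$stats_tables <- length(analyses)

  manifest <- list(
    package = "alphapaf",
    version = as.character(utils::packageVersion("alphapaf")),
    seed = config$seed,
    counts = counts,
    config_hash = config_hash(config)
  )
  data_files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest$output_hash <- files_hash(file.path(out_dir, data_files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

# Segment + Welch every subject x parcel series in a long table; a subject
# whose recording fails the minimum-segment rule on any parcel is excluded
# entirely (the rule is a property of the recording length).
welch_from_long <- function(tsd, config) {
  stopifnot(all(c("subject_id", "parcel", "amplitude") %in% names(tsd)))
  excluded <- character()
  blocks <- list()
  for (sid in unique(tsd$subject_id)) {
    sub <- tsd[tsd$subject_id == sid, , drop = FALSE]
    specs <- list()
    rejected <- FALSE
    for (pc in unique(sub$parcel)) {
      ts <- regional_timeseries(sub$amplitude[sub$parcel == pc],
                                fs = config$fs, subject_id = sid, parcel = pc)
      segs <- tryCatch(
        segment_recording(ts, config$segment_len_s, config$min_segments),
        alphapaf_subject_rejection = function(e) NULL
      )
      if (is.null(segs)) {
        rejected <- TRUE
        break
      }
      spec <- welch_psd(segs, fs = config$fs,
                        overlap_fraction = config$overlap,
                        subject_id = sid, parcel = pc)
      specs[[pc]] <- data.frame(subject_id = sid, parcel = pc,
                                freq_hz = spec$freqs, power = spec$power,
                                stringsAsFactors = FALSE)
    }
    if (rejected) {
      excluded <- c(excluded, sid)
    } else {
      blocks[[sid]] <- do.call(rbind, specs)
    }
  }
  if (length(blocks) == 0L) {
    stop_alphapaf("all subjects were excluded by the minimum-segment rule",
                  "alphapaf_config_error")
  }
  spectra <- do.call(rbind, blocks)
  rownames(spectra) <- NULL
  list(spectra = spectra, excluded = excluded)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_config(config, tmp)
  files_hash(tmp)
}

# Content hash without external digest dependencies: sum of a simple
# polynomial rolling hash over the raw bytes of each file.
files_hash <- function(paths) {
  h <- 0
  for (p in paths) {
    bytes <- as.integer(readBin(p, "raw", n = file.info(p)$size))
    if (length(bytes)) {
      mult <- 31^(seq_along(bytes) %% 12)
      h <- (h + sum((bytes + 1) * mult) %% 2147483647) %% 2147483647
    }
  }
  sprintf("%d-%d", length(paths), h)
}

#' Render human-readable report tables from a completed run
#'
#' Reads the stage outputs of [run_pipeline()] (no recomputation: every
#' number in the report traces to a stage file) and writes
#' `report.md` plus `report_<table>.csv` mirrors of the descriptives,
#' per-region regression tables and validity contingency tables.
#'
#' @param run_dir Directory produced by [run_pipeline()].
#'
#' @return Path to `report.md`, invisibly.
#' @export
write_report <- function(run_dir) {
  need <- c("metadata.csv", "region_paf.csv", "validity_by_diagnosis.csv")
  missing <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing)) {
    stop_alphapaf(sprintf("incomplete run; missing stage outputs: %s",
                          paste(missing, collapse = ", ")),
                  "alphapaf_config_error")
  }
  stats_files <- list.files(run_dir, pattern = "^stats_.*\\.csv$")
  if (length(stats_files) == 0L) {
    stop_alphapaf("incomplete run; no stats tables found", "alphapaf_config_error")
  }
  metadata <- utils::read.csv(file.path(run_dir, "metadata.csv"),
                              stringsAsFactors = FALSE)
  desc <- cohort_descriptives(metadata)
  utils::write.csv(desc$continuous, file.path(run_dir, "report_descriptives.csv"),
                   row.names = FALSE)
  lines <- c("# Pipeline report", "",
             sprintf("Subjects: %d ASD, %d TD", desc$n["ASD"], desc$n["TD"]), "",
             "## Descriptives (t oriented TD - ASD)", "",
             md_table(within(desc$continuous, {
               t <- round(t, 3); p <- round(p, 3)
               asd_mean <- round(asd_mean, 1); asd_sd <- round(asd_sd, 1)
               td_mean <- round(td_mean, 1); td_sd <- round(td_sd, 1)
             })), "",
             sprintf("Sex: %% male ASD %.1f vs TD %.1f, chi-square %.3f (p = %.3f)",
                     desc$sex$pct_male_asd, desc$sex$pct_male_td,
                     desc$sex$statistic, desc$sex$p), "")
  vdiag <- utils::read.csv(file.path(run_dir, "validity_by_diagnosis.csv"),
                           stringsAsFactors = FALSE)
  lines <- c(lines, "## Valid PAFs by diagnosis", "", md_table(vdiag), "")
  vreg_path <- file.path(run_dir, "validity_by_region.csv")
  if (file.exists(vreg_path)) {
    vreg <- utils::read.csv(vreg_path, stringsAsFactors = FALSE)
    lines <- c(lines, "## Valid PAFs by region", "", md_table(vreg), "")
  }
  for (f in stats_files) {
    tab <- utils::read.csv(file.path(run_dir, f), stringsAsFactors = FALSE)
    num <- vapply(tab, is.numeric, TRUE)
    tab[num] <- lapply(tab[num], round, 4)
    lines <- c(lines,
               sprintf("## Per-region models: %s", sub("^stats_(.*)\\.csv$", "\\1", f)),
               "", md_table(tab), "")
  }
  path <- file.path(run_dir, "report.md")
  writeLines(lines, path)
  invisible(path)
}

md_table <- function(df) {
  cells <- vapply(df, function(col) format(col, trim = TRUE), character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}
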