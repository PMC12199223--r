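#' Write a FOV's spectra to delimited text
#'
#' Column 1 is the wavenumber axis (cm^-1); each further column is one
#' spectrum of the grid, written with full double precision so the
#' round-trip is lossless to 15 significant digits.
#'
#' @param g A [fov_grid()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(g, path) {
  stopifnot(inherits(g, "fov_grid"))
  m <- cbind(g$spectra[[1]]$wavenumber, grid_intensity_matrix(g))
  colnames(m) <- c("wavenumber",
                   sprintf("s%03d", seq_along(g$spectra)))
  utils::write.csv(format(as.data.frame(m), digits = 17, trim = TRUE,
                          scientific = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_one_spectra_csv <- function(path, fov_id, group, region,
                                 grid_shape = NULL) {
  if (!file.exists(path)) stop("missing spectra file: ", path)
  d <- utils::read.csv(path, check.names = FALSE)
  if (ncol(d) < 2L) stop("spectra CSV needs a wavenumber + >= 1 column: ",
                         path)
  wn <- as.numeric(d[[1]])
  if (any(diff(wn) <= 0))
    stop("non-monotone wavenumber axis in ", path)
  n_spec <- ncol(d) - 1L
  if (is.null(grid_shape)) grid_shape <- c(1L, n_spec)
  spectra <- lapply(seq_len(n_spec), function(i) {
    raman_spectrum(wn, as.numeric(d[[i + 1L]]), region = region,
                   fov_id = fov_id,
                   grid_pos = c((i - 1L) %/% grid_shape[2] + 1L,
                                (i - 1L) %% grid_shape[2] + 1L))
  })
  fov_grid(spectra, fov_id = fov_id, group = group,
           grid_shape = grid_shape)
}

#' Read cohort spectra from a manifest
#'
#' The manifest CSV maps spectra files to FOV metadata with columns
#' `file`, `fov_id`, `group`, `region` (and optionally `grid_rows`,
#' `grid_cols`). Paths are resolved relative to the manifest location.
#'
#' @param manifest_path Manifest CSV path.
#' @return Named list of [fov_grid()] objects, one per manifest row.
#' @export
read_spectra_csv <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop("missing manifest: ", manifest_path)
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("file", "fov_id", "group", "region")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  base <- dirname(manifest_path)
  out <- list()
  for (i in seq_len(nrow(man))) {
    p <- man$file[i]
    if (!file.exists(p)) p <- file.path(base, man$file[i])
    if (!file.exists(p))
      stop(sprintf("manifest row %d: missing file '%s'", i, man$file[i]))
    gs <- if (all(c("grid_rows", "grid_cols") %in% names(man)))
      c(man$grid_rows[i], man$grid_cols[i]) else NULL
    out[[man$fov_id[i]]] <-
      read_one_spectra_csv(p, man$fov_id[i], man$group[i],
                           man$region[i], gs)
  }
  out
}

#' Write a PWS stack as multi-page TIFF with wavelength sidecar
#'
#' One 32-bit float page per wavelength; the sidecar is a plain-text
#' file with one wavelength (nm) per line. The IRF stack is written the
#' same way next to it. Reflectance values must lie in [0, 1] (the TIFF
#' writer's float range).
#'
#' @param stack A [pws_stack()].
#' @param stack_path Output TIFF path for the sample cube.
#' @param sidecar_path Output path of the wavelength sidecar
#'   (default: `stack_path` with a `.wavelengths.txt` suffix).
#' @param irf_path Output TIFF path of the IRF stack (default:
#'   `stack_path` with an `.irf.tif` suffix).
#' @return `stack_path`, invisibly.
#' @export
write_pws_tiff <- function(stack, stack_path,
                           sidecar_path = NULL, irf_path = NULL) {
  stopifnot(inherits(stack, "pws_stack"))
  if (is.null(sidecar_path))
    sidecar_path <- paste0(tools::file_path_sans_ext(stack_path),
                           ".wavelengths.txt")
  if (is.null(irf_path))
    irf_path <- paste0(tools::file_path_sans_ext(stack_path), ".irf.tif")
  if (min(stack$cube) < 0 || max(stack$cube) > 1 ||
      min(stack$irf) < 0 || max(stack$irf) > 1)
    stop("reflectance values must lie in [0, 1] for TIFF storage")
  n_w <- length(stack$wavelengths)
  pages <- lapply(seq_len(n_w), function(k) stack$cube[, , k])
  tiff::writeTIFF(pages, stack_path, bits.per.sample = 32L)
  irf_pages <- lapply(seq_len(n_w), function(k) stack$irf[, , k])
  tiff::writeTIFF(irf_pages, irf_path, bits.per.sample = 32L)
  writeLines(format(stack$wavelengths, digits = 12), sidecar_path)
  invisible(stack_path)
}

#' Read a PWS stack from multi-page TIFF + sidecar
#'
#' @param stack_path Sample-cube TIFF path.
#' @param sidecar_path Wavelength sidecar path (one nm value per line).
#' @param irf_path IRF stack TIFF path.
#' @param fov_id FOV identifier to attach.
#' @return A validated [pws_stack()]; page order follows the sidecar.
#' @export
read_pws_tiff <- function(stack_path, sidecar_path, irf_path,
                          fov_id = NA_character_) {
  for (p in c(stack_path, sidecar_path, irf_path))
    if (!file.exists(p)) stop("missing file: ", p)
  wl <- as.numeric(readLines(sidecar_path))
  pages <- tiff::readTIFF(stack_path, all = TRUE)
  if (length(pages) != length(wl))
    stop(sprintf("page count (%d) does not match sidecar length (%d)",
                 length(pages), length(wl)))
  irf_pages <- tiff::readTIFF(irf_path, all = TRUE)
  if (length(irf_pages) != length(wl))
    stop("IRF page count does not match the sidecar")
  d <- dim(pages[[1]])
  if (!identical(dim(irf_pages[[1]]), d))
    stop("IRF frame shape does not match the sample cube")
  cube <- array(unlist(pages), c(d[1], d[2], length(wl)))
  irf <- array(unlist(irf_pages), c(d[1], d[2], length(wl)))
  pws_stack(wl, cube, irf, fov_id = fov_id)
}

#' Default pipeline configuration
#'
#' All tunable parameters of the end-to-end analysis with their default
#' values: region selection, preprocessing (Savitzky-Golay window,
#' iModPoly orders and stop rule, DBSCAN screening), PWS texture (gray
#' levels, offsets, directions, detrend), band panel, classification
#' (folds, component cap, scaling mode) and the synthetic-cohort block.
#'
#' @param ... Named overrides of defaults; unknown names are rejected.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    region = "FP",
    use_hwvn = FALSE,
    preprocess = preprocess_params(),
    pws = list(levels = 16L, max_offset = 20L,
               directions = c("0", "45", "90", "135"),
               detrend = "mean"),
    bands = list(panel = "gastroesophageal", half_width = 4,
                 adjust = FALSE),
    classify = list(k = 4L, max_components = 10L, seed = 1L,
                    scale = "global"),
    cohort = cohort_config()
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "pipeline_config"
  cfg
}

config_to_yaml <- function(cfg, path) {
  ser <- rapply(unclass(cfg), function(x) {
    if (inherits(x, "peak_spec")) unclass(x) else x
  }, how = "replace")
  # named numeric vectors must round-trip as YAML maps
  for (nm in c("n_fov_per_group", "disorder_amplitude", "effect_map"))
    ser$cohort[[nm]] <- as.list(ser$cohort[[nm]])
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' Run the full hybrid RS-PWS analysis
#'
#' Executes: cohort simulation (or data loading) -> Raman preprocessing
#' -> PWS texture -> band statistics -> multimodal PLS-DA -> report.
#' All numeric outputs (CSV/JSON) are reproduced bit-identically from
#' the same configuration and seed. The output directory receives the
#' band panel CSV, IDM group summary CSV, modality comparison JSON,
#' diagnostic plots, and a run record (config snapshot, seeds, stage
#' timings and warnings).
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param cohort Optional pre-built `rpws_cohort`; by default one is
#'   simulated from `config$cohort`.
#' @param plots Write diagnostic plots (default `TRUE`).
#' @return A list with the per-stage results (`cohort`, `fov_means`,
#'   `idm_summary`, `band_table`, `report`, paths and the run record).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         cohort = NULL, plots = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  timings <- c()
  warnings_log <- character(0)
  stage <- function(name, expr) {
    ts <- Sys.time()
    r <- withCallingHandlers(force(expr), warning = function(w) {
      warnings_log <<- c(warnings_log,
                         sprintf("[%s] %s", name, conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
    timings[name] <<- round(as.numeric(Sys.time() - ts, units = "secs"),
                            3)
    r
  }

  if (is.null(cohort))
    cohort <- stage("simulate", generate_cohort(config$cohort))

  groups <- vapply(cohort$fovs, `[[`, "", "group")
  labels <- as.integer(groups == unique(groups)[2])

  pre <- stage("preprocess", lapply(cohort$fovs, function(f)
    preprocess_fov(f$raman, region = config$region,
                   params = config$preprocess)))
  fov_means <- lapply(pre, `[[`, "fov_mean")

  has_pws <- !is.null(cohort$fovs[[1]]$pws)
  idm_summary <- NULL
  curves <- NULL
  if (has_pws) {
    curves <- stage("texture", lapply(cohort$fovs, function(f) {
      img <- compute_pws_image(f$pws, detrend = config$pws$detrend)
      idm_curve(img, max_offset = config$pws$max_offset,
                levels = config$pws$levels,
                directions = config$pws$directions)
    }))
    idm_summary <- summarize_group_curves(curves, groups)
    utils::write.csv(idm_summary,
                     file.path(out_dir, "idm_group_summary.csv"),
                     row.names = FALSE)
  }

  band_table <- stage("stats", band_test_panel(
    fov_means, groups, bands = band_panel(config$bands$panel),
    half_width = config$bands$half_width,
    adjust = config$bands$adjust))
  utils::write.csv(band_table, file.path(out_dir, "band_panel.csv"),
                   row.names = FALSE)

  report <- NULL
  if (has_pws) {
    report <- stage("classify", {
      rs_x <- t(vapply(fov_means, function(s) s$intensity,
                       numeric(length(fov_means[[1]]$intensity))))
      colnames(rs_x) <- sprintf("rs_%.0f",
                                fov_means[[1]]$wavenumber)
      pws_x <- t(vapply(curves, function(cv) cv$idm,
                        numeric(nrow(curves[[1]]))))
      colnames(pws_x) <- sprintf("idm_off%02d", curves[[1]]$offset)
      ids <- vapply(cohort$fovs, `[[`, "", "fov_id")
      rs_fm <- feature_matrix(rs_x, labels, fov_ids = ids,
                              modality = "rs")
      pws_fm <- feature_matrix(pws_x, labels, fov_ids = ids,
                               modality = "pws")
      compare_modalities(rs_fm, pws_fm, k = config$classify$k,
                         max_components = config$classify$max_components,
                         seed = config$classify$seed,
                         scale = config$classify$scale)
    })
    jsonlite::write_json(
      list(summary = report$summary,
           fused_gain_absolute = report$fused_gain_absolute,
           fused_gain_relative = report$fused_gain_relative),
      file.path(out_dir, "modality_comparison.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }

  if (plots) {
    stage("plots", {
      if (!is.null(idm_summary)) {
        grDevices::png(file.path(out_dir, "idm_curves.png"), 800, 600)
        plot_idm_summary(idm_summary)
        grDevices::dev.off()
      }
      if (!is.null(report)) {
        for (nm in names(report$results)) {
          grDevices::png(file.path(out_dir,
                                   sprintf("plsda_%s.png", nm)),
                         800, 600)
          plot_plsda_fit(report$results[[nm]]$fit, title = nm)
          grDevices::dev.off()
        }
      }
    })
  }

  record <- list(
    package_version = as.character(utils::packageVersion("ramanpws")),
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S"),
    seed = config$cohort$seed,
    classify_seed = config$classify$seed,
    timings_sec = as.list(timings),
    warnings = warnings_log)
  jsonlite::write_json(record, file.path(out_dir, "run_record.json"),
                       auto_unbox = TRUE, digits = NA)
  config_to_yaml(config, file.path(out_dir, "config_used.yaml"))

  invisible(list(cohort = cohort, fov_means = fov_means,
                 idm_summary = idm_summary, band_table = band_table,
                 report = report, out_dir = out_dir, record = record))
}

#' Write a sigma map as single-page TIFF
#'
#' @param img A `pws_image`.
#' @param path Output TIFF path. Values are stored as 32-bit floats and
#'   must lie in [0, 1] (sigma maps are relative fluctuation magnitudes,
#'   well below 1 in practice).
#' @return `path`, invisibly.
#' @export
write_sigma_tiff <- function(img, path) {
  stopifnot(inherits(img, "pws_image"))
  if (min(img$sigma_map) < 0 || max(img$sigma_map) > 1)
    stop("sigma map values must lie in [0, 1] for TIFF storage")
  tiff::writeTIFF(img$sigma_map, path, bits.per.sample = 32L)
  invisible(path)
}

#' Write a cohort to its on-disk formats
#'
#' One spectra CSV and one PWS TIFF trio (stack, IRF, wavelength
#' sidecar) per FOV, a `manifest.csv` tying them together, and a
#' `ground_truth.json` with labels and per-FOV outlier indices.
#'
#' @param cohort An `rpws_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "rpws_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (f in cohort$fovs) {
    csv <- sprintf("%s_raman.csv", f$fov_id)
    write_spectra_csv(f$raman, file.path(dir, csv))
    row <- data.frame(file = csv, fov_id = f$fov_id, group = f$group,
                      region = f$raman$spectra[[1]]$region,
                      grid_rows = f$raman$grid_shape[1],
                      grid_cols = f$raman$grid_shape[2],
                      pws_stack = NA_character_)
    if (!is.null(f$pws)) {
      tif <- sprintf("%s_pws.tif", f$fov_id)
      write_pws_tiff(f$pws, file.path(dir, tif))
      row$pws_stack <- tif
    }
    rows[[f$fov_id]] <- row
  }
  utils::write.csv(do.call(rbind, rows),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(groups = cohort$truth$groups,
         effect_map = as.list(cohort$truth$effect_map),
         outliers = cohort$truth$outliers),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a pipeline configuration from YAML
#'
#' Reads a configuration written by `config_to_yaml()` (or the CLI's
#' `config init`), rebuilding the typed cohort block, and validates it
#' against the known schema.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("missing config file: ", path)
  raw <- yaml::read_yaml(path)
  defaults <- pipeline_config()
  unknown <- setdiff(names(raw), names(unclass(defaults)))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- unclass(defaults)
  for (nm in names(raw)) {
    if (nm == "cohort") next
    if (is.list(cfg[[nm]]) && is.list(raw[[nm]])) {
      bad <- setdiff(names(raw[[nm]]), names(cfg[[nm]]))
      if (length(bad))
        stop(sprintf("unknown config keys in '%s': %s", nm,
                     paste(bad, collapse = ", ")))
      cfg[[nm]][names(raw[[nm]])] <- raw[[nm]]
    } else {
      cfg[[nm]] <- raw[[nm]]
    }
  }
  if (!is.null(raw$cohort)) {
    cb <- raw$cohort
    if (!is.null(cb$peaks))
      cb$peaks <- lapply(cb$peaks, function(p)
        peak_spec(p$center, p$amplitude, p$width, p$shape))
    for (nm in c("n_fov_per_group", "disorder_amplitude",
                 "effect_map")) {
      if (!is.null(cb[[nm]])) cb[[nm]] <- unlist(cb[[nm]])
    }
    cfg$cohort <- do.call(cohort_config, cb)
  }
  class(cfg) <- "pipeline_config"
  cfg
}
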