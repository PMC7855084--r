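#' Read and write voxel volumes as multi-page 8-bit TIFF stacks
#'
#' Volumes are stored as one TIFF page per z-slice, 8-bit: binary volumes as
#' 0/255, grey occupancy volumes quantised to 256 levels. Matrix rows map to
#' the x-axis and columns to the y-axis. `write_stack()` writes the cropped
#' values padded to the full domain; a round trip therefore preserves
#' dimensions and (8-bit) voxel values exactly.
#'
#' @param vol A `voxel_volume`.
#' @param path Output file path.
#' @return `write_stack()` returns `path` invisibly; `read_stack()` returns
#'   a `voxel_volume` with offset zero.
#' @export
write_stack <- function(vol, path) {
  stopifnot(inherits(vol, "voxel_volume"))
  d <- vol$dim_full
  dc <- dim(vol$values)
  off <- vol$offset
  pages <- lapply(seq_len(d[3]), function(k) {
    pg <- matrix(0, d[1], d[2])
    kz <- k - off[3]
    if (kz >= 1 && kz <= dc[3]) {
      pg[off[1] + seq_len(dc[1]), off[2] + seq_len(dc[2])] <- vol$values[, , kz]
    }
    round(pg * 255) / 255
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}

#' @rdname write_stack
#' @param voxel_size Voxel edge in um to attach to the volume read.
#' @export
read_stack <- function(path, voxel_size = 1) {
  if (!file.exists(path)) abort(sprintf("No such TIFF stack: '%s'", path))
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, info = FALSE),
    error = function(e) abort(sprintf("Cannot read '%s' as TIFF: %s", path,
                                      conditionMessage(e)))
  )
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) != 2, TRUE))) {
    abort(sprintf("'%s' is not a single-channel grey stack.", path))
  }
  d <- c(dim(pages[[1]]), length(pages))
  vals <- array(unlist(pages, use.names = FALSE), dim = d)
  binary <- all(vals %in% c(0, 1))
  new_voxel_volume(vals, dim_full = d, offset = c(0L, 0L, 0L),
                   voxel_size = voxel_size, binary = binary,
                   threshold = if (binary) 0.5 else NULL)
}

#' Read a pipeline configuration file
#'
#' The configuration is a YAML file with a top-level `cohorts` list (each
#' entry: `kind`, `n`, `seed`, plus `aspect_ratio` for cylinders or
#' `voxel_size` and `alignment` for ellipsoids, and optional geometry
#' overrides) and optional top-level `supersampling`, `binarise`,
#' `write_stacks` and `thresholds` settings. Defaults match the study
#' conditions: angle category thresholds 67.5/22.5 deg, 2D area cutoff
#' 38 um^2, volumetric lacuna window 50-500 um^3 and canal minimum
#' 1000 um^3.
#'
#' @param path YAML file path.
#' @return A config list with defaults filled in.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such config file: '%s'", path))
  cfg <- yaml::read_yaml(path)
  defaults <- list(
    supersampling = 5, binarise = "midpoint", write_stacks = FALSE,
    thresholds = list(omega = 67.5, theta_lo = 22.5, theta_hi = 67.5,
                      area_cutoff = 38, lacuna_min = 50, lacuna_max = 500,
                      canal_min = 1000)
  )
  cfg <- modifyList(defaults, cfg)
  if (is.null(cfg$cohorts) || length(cfg$cohorts) == 0) {
    abort("Config must declare at least one cohort.")
  }
  bad <- unlist(cfg$thresholds) <= 0
  if (any(bad)) abort("All thresholds must be positive.")
  cfg
}

#' Run the full phantom validation pipeline
#'
#' Generates every configured cohort, analyses it with the 2D and 3D
#' estimators, classifies canal orientations, assembles the agreement
#' tables, and writes all artefacts (per-phantom CSVs, manifest, table
#' analogues, run log) under `out_dir`. Each output CSV carries a
#' provenance header comment with the package version, the config hash and
#' the cohort seeds. Stages run in order; if one fails the artefacts of
#' completed stages are left in place.
#'
#' @param config A config list from [read_pipeline_config()], or a path to
#'   a YAML file.
#' @param out_dir Output directory (created if needed).
#' @return The report list from [build_report()], invisibly; artefacts on
#'   disk.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cfg_hash <- rlang::hash(config)
  log_path <- file.path(out_dir, "run.log")
  logline <- function(...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                sprintf(...)),
        file = log_path, append = TRUE)
  }
  logline("osteovox %s pipeline start; config hash %s",
          as.character(utils::packageVersion("osteovox")), cfg_hash)

  cyl <- list()
  ell <- list()
  for (co in config$cohorts) {
    co$kind <- match.arg(co$kind, c("cylinder", "ellipsoid"))
    args <- co[intersect(names(co), names(formals(generate_cohort)))]
    args$supersampling <- config$supersampling
    if (isTRUE(config$write_stacks)) {
      args$dir <- file.path(out_dir, "stacks")
    }
    manifest <- do.call(generate_cohort, args)
    logline("cohort %s n=%d seed=%d generated", co$kind, nrow(manifest),
            co$seed %||% 1L)
    analysed <- analyse_cohort(manifest, binarise = config$binarise)
    if (co$kind == "cylinder") {
      cyl[[length(cyl) + 1]] <- analysed
    } else {
      ell[[length(ell) + 1]] <- analysed
    }
    tag <- if (co$kind == "cylinder") {
      sprintf("cylinder_ar%s", gsub("[.]", "p", format(co$aspect_ratio %||% 1)))
    } else {
      sprintf("ellipsoid_%s_vs%s", co$alignment %||% "woven",
              gsub("[.]", "p", format(co$voxel_size %||% 1.6)))
    }
    write_csv_prov(drop_list_cols(analysed),
                   file.path(out_dir, paste0(tag, "_objects.csv")),
                   cfg_hash, co$seed %||% 1L)
    logline("cohort %s analysed", tag)
  }

  cylinders <- if (length(cyl)) dplyr::bind_rows(cyl)
  ellipsoids <- if (length(ell)) dplyr::bind_rows(ell)
  report <- build_report(cylinders, ellipsoids)

  if (!is.null(report$orientation)) {
    write_csv_prov(report$orientation,
                   file.path(out_dir, "orientation_agreement.csv"), cfg_hash)
    write_csv_prov(report$classification,
                   file.path(out_dir, "classification_accuracy.csv"), cfg_hash)
    idx <- dplyr::bind_rows(lapply(split(cylinders, cylinders$aspect_ratio),
      function(df) {
        est2 <- categorise_estimates(df$omega_2d, df$theta_2d)
        est3 <- categorise_estimates(df$omega_3d, df$theta_3d)
        dplyr::bind_rows(
          dplyr::bind_cols(tibble(aspect_ratio = df$aspect_ratio[1], method = "2d"),
                           indices_count(est2[!is.na(est2)])),
          dplyr::bind_cols(tibble(aspect_ratio = df$aspect_ratio[1], method = "3d"),
                           indices_count(est3[!is.na(est3)]))
        )
      }))
    write_csv_prov(idx, file.path(out_dir, "orientation_indices.csv"), cfg_hash)
  }
  if (!is.null(report$volumes)) {
    write_csv_prov(report$volumes,
                   file.path(out_dir, "lacunar_volumes.csv"), cfg_hash)
  }
  logline("pipeline complete")
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

drop_list_cols <- function(df) df[, !vapply(df, is.list, TRUE), drop = FALSE]

# CSV with a provenance comment header
write_csv_prov <- function(df, path, cfg_hash, seed = NA) {
  header <- sprintf("# osteovox %s; config_hash=%s; seed=%s",
                    as.character(utils::packageVersion("osteovox")),
                    cfg_hash, as.character(seed))
  writeLines(header, path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a provenance-stamped pipeline CSV
#' @param path CSV written by [run_pipeline()].
#' @return A tibble.
#' @export
read_pipeline_csv <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}
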