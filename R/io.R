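# ---- containers on disk ----------------------------------------------------

#' Save and load package objects with bit-exact round trips
#'
#' Sinograms, scenes and histogram sets are stored as single-file RDS
#' containers (`.rds`), which reproduce arrays bitwise and metadata exactly.
#' Use [export_tiff()] for interoperable image/stack exports and
#' [utils::write.csv()] on tidied tables.
#'
#' @param obj A `lift_sinogram`, `lift_scene`, `lift_tcspc` or other package
#'   object.
#' @param path Destination path ending in `.rds`.
#' @return `save_lift()` returns `path` invisibly; `load_lift()` the object.
#' @export
save_lift <- function(obj, path) {
  if (!grepl("\\.rds$", path, ignore.case = TRUE)) {
    stop("format error: expected an .rds container path, got '",
         basename(path), "'", call. = FALSE)
  }
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_lift
#' @export
load_lift <- function(path) {
  if (!grepl("\\.rds$", path, ignore.case = TRUE)) {
    stop("format error: expected an .rds container path, got '",
         basename(path), "'", call. = FALSE)
  }
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("read error: '", basename(path), "' is not a readable container (",
         conditionMessage(e), ")", call. = FALSE)
  })
  obj
}

#' Export an image or stack as 32-bit float TIFF
#'
#' Multi-page stacks carry one page per plane (e.g. per depth). The TIFF
#' writer stores values in `[0, 1]`, so data outside that range are divided
#' by their maximum before writing; the applied scale is returned so callers
#' can record it (the pipeline manifest does).
#'
#' @param img Matrix, list of matrices, or 3-D array (pages along the third
#'   dimension); nonnegative.
#' @param path Destination `.tif`/`.tiff` path.
#' @return `path`, invisibly, with attribute `scale` (the divisor applied;
#'   1 when the data already fit `[0, 1]`).
#' @export
export_tiff <- function(img, path) {
  if (!grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    stop("format error: expected a .tif path, got '", basename(path), "'",
         call. = FALSE)
  }
  pages <- if (is.list(img)) img
           else if (length(dim(img)) == 3) {
             lapply(seq_len(dim(img)[3]), function(k) img[, , k])
           } else list(as.matrix(img))
  top <- max(vapply(pages, max, numeric(1)), 0)
  low <- min(vapply(pages, min, numeric(1)), 0)
  if (low < 0) stop("TIFF export expects nonnegative data", call. = FALSE)
  scale <- if (top > 1) top else 1
  tiff::writeTIFF(lapply(pages, function(p) p / scale), path,
                  bits.per.sample = 32)
  out <- path
  attr(out, "scale") <- scale
  invisible(out)
}

#' @rdname export_tiff
#' @param simplify Return a matrix when the file has a single page.
#' @export
import_tiff <- function(path, simplify = TRUE) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    p
  })
  if (simplify && length(pages) == 1) pages[[1]] else pages
}

# ---- run configuration ------------------------------------------------------

pipeline_schema <- list(
  geometry = c("N", "K", "Ntheta"),
  scene = c("kind", "seed", "time_bins", "dt_ns", "depths_um", "n_beads",
            "lifetimes_ns", "diameters_um"),
  noise = c("M", "seed"),
  reconstruction = c("method", "mu", "iters", "depth_um"),
  analysis = c("fit_lifetime", "intensity_quantile", "phasor", "n_clusters",
               "seed"),
  output = c("dir")
)

#' Validate a pipeline configuration
#'
#' A configuration is a named list (or YAML file) with blocks `geometry`
#' (required: `N`, `K`, optionally `Ntheta`), `scene`, optional `noise`,
#' `reconstruction`, `analysis` and `output`. Unknown blocks or keys are
#' rejected up front, before any computation.
#'
#' @param config Named list, or path to a YAML file.
#' @return The validated config list, invisibly classed `lift_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or YAML path",
                             call. = FALSE)
  unknown <- setdiff(names(config), names(pipeline_schema))
  if (length(unknown)) {
    stop("schema error: unknown config block(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (blk in names(config)) {
    extra <- setdiff(names(config[[blk]]), pipeline_schema[[blk]])
    if (length(extra)) {
      stop("schema error: unknown key(s) in '", blk, "': ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  if (is.null(config$geometry) || is.null(config$geometry$N) ||
      is.null(config$geometry$K)) {
    stop("schema error: config needs a geometry block with N and K",
         call. = FALSE)
  }
  if (is.null(config$scene) || is.null(config$scene$kind)) {
    stop("schema error: config needs a scene block with kind", call. = FALSE)
  }
  class(config) <- "lift_config"
  invisible(config)
}

#' Run the simulation-to-analysis pipeline
#'
#' Executes the enabled stages in order — phantom generation, forward
#' projection, shot noise, per-bin reconstruction, lifetime fitting, phasor
#' transform — writing each stage's artifact plus a manifest
#' (`manifest.json`) holding the configuration, seeds and per-file MD5
#' checksums. Identical configuration and seeds reproduce identical
#' checksums.
#'
#' @param config See [validate_config()].
#' @param out_dir Output directory (created if missing); overrides
#'   `config$output$dir`.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config <- validate_config(config)
  out_dir <- out_dir %||% config$output$dir %||% stop(
    "no output directory: set output$dir or pass out_dir", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gcf <- config$geometry
  scf <- config$scene
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  geom <- stage("geometry", lift_geometry(
    N = gcf$N, K = gcf$K, Ntheta = gcf$Ntheta %||% gcf$N))
  scene <- stage("scene", {
    if (scf$kind == "beads3d") {
      make_phantom("beads3d", N = gcf$N, seed = scf$seed %||% 1,
                   n_beads = scf$n_beads %||% c(6, 4, 2),
                   lifetimes_ns = scf$lifetimes_ns %||% c(1.5, 3.4, 4.0),
                   diameters_um = scf$diameters_um %||% c(4, 6, 10),
                   depths_um = scf$depths_um %||% 0,
                   time_bins = scf$time_bins %||% 0,
                   dt_ns = scf$dt_ns %||% 0.05)
    } else {
      make_phantom(scf$kind, N = gcf$N, seed = scf$seed %||% 1)
    }
  })
  save_lift(scene, file.path(out_dir, "scene.rds"))
  sino <- stage("forward", forward_sinogram(scene, geom))
  if (!is.null(config$noise)) {
    sino <- stage("noise", apply_shot_noise(
      sino, config$noise$M, seed = config$noise$seed %||% 1))
    # static sinograms go back to scene intensity units; time-resolved data
    # stay in photon counts so lifetime fitting sees count statistics
    if (length(dim(sino$rows)) == 2 && !is.null(sino$meta$photon_scale)) {
      sino$rows <- sino$rows / sino$meta$photon_scale
    }
  }
  save_lift(sino, file.path(out_dir, "sinogram.rds"))
  rcf <- config$reconstruction %||% list()
  method <- rcf$method %||% "fbp"
  s <- depth_to_shear(geom, rcf$depth_um %||% 0)
  recon <- stage("reconstruct", {
    if (method == "fista") {
      if (length(dim(sino$rows)) != 2) {
        stop("fista pipeline reconstruction supports static sinograms")
      }
      suppressWarnings(fista_reconstruct(
        sino, s = s,
        config = recon_config(mu = rcf$mu %||% 0.05,
                              max_iters = rcf$iters %||% 100)))
    } else {
      fbp_reconstruct(sino, s = s)
    }
  })
  if (length(dim(recon)) == 2) {
    export_tiff(pmax(recon, 0), file.path(out_dir, "recon_depth0.tif"))
  } else {
    export_tiff(pmax(recon, 0), file.path(out_dir, "recon_bins.tif"))
  }
  report <- tibble::tibble(stage = c("scene", "forward", "reconstruct"),
                           detail = c(scf$kind, method,
                                      paste0("depth ", rcf$depth_um %||% 0)))
  acf <- config$analysis
  if (!is.null(acf) && isTRUE(acf$fit_lifetime) && length(dim(recon)) == 3) {
    lt <- stage("lifetime", fit_lifetime_map(
      pmax(recon, 0), scene$time_axis_ns,
      intensity_quantile = acf$intensity_quantile %||% 0.1))
    export_tiff(ifelse(lt$mask, lt$tau_ns, 0),
                file.path(out_dir, "lifetime.tif"))
    th <- lifetime_histogram(lt)
    utils::write.csv(th, file.path(out_dir, "lifetime_histogram.csv"),
                     row.names = FALSE)
    report <- dplyr::bind_rows(report, tibble::tibble(
      stage = "lifetime",
      detail = paste0("peaks(ns): ",
                      paste(signif(attr(th, "peaks_ns"), 3),
                            collapse = " "))))
    if (isTRUE(acf$phasor)) {
      cloud <- stage("phasor", phasor_cloud(pmax(recon, 0),
                                            scene$time_axis_ns, "temporal"))
      utils::write.csv(cloud, file.path(out_dir, "phasor_cloud.csv"),
                       row.names = FALSE)
      if (!is.null(acf$n_clusters) && acf$n_clusters >= 2) {
        cl <- stage("cluster", cluster_probabilities(
          cloud, acf$n_clusters, seed = acf$seed %||% 1))
        utils::write.csv(cl, file.path(out_dir, "phasor_clusters.csv"),
                         row.names = FALSE)
      }
    }
  }
  utils::write.csv(report, file.path(out_dir, "report.csv"),
                   row.names = FALSE)
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    config = unclass(config),
    files = as.list(setNames(unname(tools::md5sum(file.path(out_dir, files))),
                             files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
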