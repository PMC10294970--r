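#' Run configuration for the end-to-end pipeline
#'
#' A single structured configuration drives the whole chain (reproducibility
#' over interactivity): input stack or phantom preset, per-structure
#' segmentation settings, meshing, scaling, solidification, splits, fits and
#' print settings. Exactly one of `input` / `preset` must be given.
#'
#' @param preset phantom preset name (see [phantom_preset()]), or `NULL`.
#' @param input path to a multi-page TIFF, or `NULL`.
#' @param voxel_size `(dz, dy, dx)` um; required with `input`.
#' @param channels channel names for `input`.
#' @param structures named list; each element is a list with fields
#'   `channel`, `threshold = c(lo, hi)`, and optionally `fill`
#'   (`list(mode, radius)`), `keep_largest` (default TRUE), `role`
#'   (`"host"`, `"insert"` or `"solid"`), `color`.
#' @param smooth_iterations Taubin smoothing iterations.
#' @param decimate_fraction face-count fraction kept after decimation
#'   (`NULL` = no decimation).
#' @param magnification model magnification M; `NULL` auto-fits the longest
#'   model dimension to `target_size_mm`.
#' @param target_size_mm requested model size used when `magnification` is
#'   `NULL`.
#' @param solidify_thickness uniform offset for the host surface, mm.
#' @param splits list of `list(part = , plane = )` (`plane = NULL` for the
#'   horizontal centroid plane).
#' @param fits list of `list(host = , insert = , clearance = )`.
#' @param print a [print_config()].
#' @param seed RNG seed for the phantom and any stochastic step.
#' @param engine_max_dim voxel-engine grid cap (cells along longest axis).
#' @return A `run_config` object.
#' @export
run_config <- function(preset = NULL, input = NULL, voxel_size = NULL,
                       channels = NULL, structures, smooth_iterations = 10L,
                       decimate_fraction = NULL, magnification = NULL,
                       target_size_mm = 50, solidify_thickness = 1,
                       splits = list(), fits = list(),
                       print = print_config(), seed = 1L,
                       engine_max_dim = 192L) {
  if (is.null(preset) == is.null(input))
    stop("exactly one of preset / input must be given")
  if (is.null(names(structures)) || anyDuplicated(names(structures)))
    stop("structures must be a uniquely named list")
  structure(list(preset = preset, input = input, voxel_size = voxel_size,
                 channels = channels, structures = structures,
                 smooth_iterations = smooth_iterations,
                 decimate_fraction = decimate_fraction,
                 magnification = magnification,
                 target_size_mm = target_size_mm,
                 solidify_thickness = solidify_thickness,
                 splits = splits, fits = fits, print = print,
                 seed = as.integer(seed),
                 engine_max_dim = as.integer(engine_max_dim)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  pc <- do.call(print_config, y$print %||% list())
  y$print <- pc
  y$structures <- lapply(y$structures, function(s) {
    s$threshold <- as.numeric(s$threshold)
    s
  })
  do.call(run_config, y)
}

#' Default pipeline configurations for the phantom presets
#'
#' Encodes the dismountable-model plans of the three archetypes: the
#' epithelial model is a solidified cell surface split into upper and lower
#' halves with the nucleus fitted inside (3 parts); the mesenchymal model
#' keeps f-actin, alpha-SMA and nuclei as three separate solids with the
#' nuclei fitted into the f-actin part (3 parts); the neuron-like model is
#' an f-actin solid hosting the nucleus (2 parts).
#'
#' @param preset preset name.
#' @param seed RNG seed.
#' @return A [run_config()].
#' @export
preset_run_config <- function(preset = c("panc1_like", "hdf_like",
                                         "shsy5y_like"), seed = 1L) {
  preset <- match.arg(preset)
  thr <- c(80, 255)
  if (preset == "panc1_like") {
    run_config(
      preset = preset,
      structures = list(
        cell_surface = list(channel = "TRITC", threshold = thr,
                            fill = list(mode = "volumetric", radius = 3),
                            role = "host", color = "translucent"),
        nucleus = list(channel = "DAPI", threshold = thr,
                       fill = list(mode = "volumetric", radius = 2),
                       role = "insert", color = "blue")),
      magnification = 1000, decimate_fraction = 0.4,
      splits = list(list(part = "cell_surface", plane = NULL)),
      fits = list(list(host = "cell_surface", insert = "nucleus",
                       clearance = 0.3)),
      seed = seed)
  } else if (preset == "hdf_like") {
    run_config(
      preset = preset,
      structures = list(
        f_actin = list(channel = "TRITC", threshold = thr,
                       fill = list(mode = "volumetric", radius = 3),
                       role = "host", color = "red"),
        a_sma = list(channel = "AF647", threshold = thr,
                     fill = list(mode = "volumetric", radius = 2),
                     keep_largest = FALSE, role = "solid", color = "mint"),
        nuclei = list(channel = "DAPI", threshold = thr,
                      fill = list(mode = "volumetric", radius = 2),
                      keep_largest = FALSE, role = "insert", color = "blue")),
      magnification = 200, decimate_fraction = 0.4,
      fits = list(list(host = "f_actin", insert = "nuclei",
                       clearance = 0.3)),
      seed = seed)
  } else {
    run_config(
      preset = preset,
      structures = list(
        f_actin = list(channel = "TRITC", threshold = thr,
                       fill = list(mode = "volumetric", radius = 4),
                       role = "host", color = "red"),
        nucleus = list(channel = "DAPI", threshold = thr,
                       fill = list(mode = "volumetric", radius = 2),
                       role = "insert", color = "blue")),
      magnification = 10000, decimate_fraction = 0.4,
      fits = list(list(host = "f_actin", insert = "nucleus",
                       clearance = 0.3)),
      seed = seed)
  }
}

#' Run the full reconstruction pipeline
#'
#' Executes the stages in order: acquire (read stack or generate phantom),
#' segment (threshold, component selection, fill), measure (morphometry
#' CSV), mesh (iso-surface, smoothing, optional decimation), scale (um to
#' mm), solidify, split and fit (dismountable assembly), and report (STL
#' files, assembly manifest, print report, log). Deterministic for a fixed
#' configuration and seed.
#'
#' @param config a [run_config()].
#' @param output_dir output directory; created if needed.
#' @param model model name prefix for output files (default: preset or
#'   input basename).
#' @return (invisibly) a `cytoprint_run` with elements `assembly`,
#'   `morphometry`, `print_report`, `scale`, `files`, `log`.
#' @export
run_pipeline <- function(config, output_dir, model = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(output_dir, "run.log")
  logf <- function(...) {
    msg <- sprintf(...)
    cat(format(Sys.time(), "%H:%M:%S"), msg, "\n", file = log_path,
        append = TRUE)
    message(msg)
  }
  stage <- function(name, expr) {
    logf("[%s]", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (is.null(model))
    model <- config$preset %||% tools::file_path_sans_ext(
      basename(config$input))

  ## acquire
  stk <- stage("acquire", {
    if (!is.null(config$preset)) {
      logf("  generating phantom preset '%s' (seed %d)", config$preset,
           config$seed)
      ph <- generate_cell_phantom(phantom_preset(config$preset,
                                                 seed = config$seed))
      ph$stack
    } else {
      logf("  reading stack %s", config$input)
      read_stack(config$input, voxel_size = config$voxel_size,
                 channels = config$channels %||% "ch1")
    }
  })
  logf("  stack: %s voxels, voxel size %s um",
       paste(dim(stk$data)[2:4], collapse = "x"),
       paste(signif(stk$voxel_size, 4), collapse = " x "))

  ## segment
  masks <- stage("segment", {
    lapply(config$structures, function(s) {
      m <- threshold_mask(stk, s$channel, s$threshold)
      if (s$keep_largest %||% TRUE) {
        comps <- split_mask(m)
        if (!length(comps)) stop("empty mask for channel ", s$channel)
        m <- comps[[1L]]
      }
      if (!is.null(s$fill))
        m <- fill_mask(m, s$fill$mode %||% "volumetric",
                       s$fill$radius %||% 2)
      m
    })
  })
  for (nm in names(masks))
    logf("  mask '%s': %d voxels (%.0f um^3)", nm, mask_count(masks[[nm]]),
         mask_volume(masks[[nm]]))

  ## morphometry (original um scale)
  morph <- stage("measure", {
    res <- lapply(names(masks), function(nm) {
      r <- measure_objects(masks[[nm]], min_voxels = 50L)
      if (nrow(r)) r$structure <- nm
      r
    })
    do.call(rbind, res[vapply(res, nrow, 0L) > 0])
  })
  morph_csv <- file.path(output_dir, paste0(model, "_morphometry.csv"))
  write_morphometry_csv(morph, morph_csv)
  for (i in seq_len(nrow(morph)))
    logf("  %s #%d: D1 %.1f um, D2 %.1f um, Davg %.1f um",
         morph$structure[i], morph$id[i], morph$D1_um[i], morph$D2_um[i],
         morph$Davg_um[i])

  ## mesh
  meshes <- stage("mesh", {
    lapply(masks, function(m) {
      s <- extract_surface(m)
      s <- smooth_mesh(s, config$smooth_iterations)
      if (!is.null(config$decimate_fraction)) {
        s <- decimate_mesh(s, config$decimate_fraction)
        s <- smooth_mesh(s, 3L)  # relax the remeshed staircase
      }
      s
    })
  })

  ## scale
  sc <- stage("scale", {
    if (!is.null(config$magnification)) {
      make_scale_map(1000, config$magnification)  # M given directly
    } else {
      ext <- max(vapply(meshes, function(m)
        max(apply(m$vertices, 2L, function(v) diff(range(v)))), 0))
      make_scale_map(ext, config$target_size_mm)
    }
  })
  logf("  magnification M = %g (model mm per specimen um x 10^-3)", sc$M)
  meshes <- lapply(meshes, apply_scale, map = sc)

  ## solidify
  parts <- stage("solidify", {
    out <- list()
    for (nm in names(config$structures)) {
      s <- config$structures[[nm]]
      role <- s$role %||% "solid"
      out[[nm]] <- if (identical(role, "host")) {
        solidify(meshes[[nm]], config$solidify_thickness, mode = "filled",
                 resolution = engine_resolution(
                   apply(meshes[[nm]]$vertices, 2L,
                         function(v) diff(range(v))),
                   thickness = config$solidify_thickness,
                   max_dim = config$engine_max_dim),
                 name = nm, color_tag = s$color %||% "white")
      } else {
        solid_part(meshes[[nm]], name = nm,
                   color_tag = s$color %||% "white")
      }
      logf("  part '%s': volume %.1f mm^3", nm,
           mesh_stats(out[[nm]])$volume)
    }
    out
  })

  ## assemble (splits then fits) and write STL parts + manifest
  asm <- stage("assemble", {
    build_assembly(parts, splits = config$splits, fits = config$fits,
                   dir = output_dir, model = model)
  })
  logf("  %d STL part(s): %s", length(asm$files),
       paste(basename(asm$files), collapse = ", "))

  ## print report
  rep <- stage("report", {
    pres <- print_resolution(sc, config$print)
    per_part <- lapply(asm$parts, function(p)
      printability_report(p, config$print))
    list(magnification = sc$M,
         layer_height_mm = config$print$layer_height,
         infill_percent = config$print$infill_percent,
         infill_pattern = config$print$infill_pattern,
         supports = config$print$supports,
         original_scale_resolution_um = pres,
         parts = per_part)
  })
  for (nm in names(rep$parts))
    logf("  part '%s': min wall %.2f mm (%s), fits build volume: %s", nm,
         rep$parts[[nm]]$min_wall,
         if (rep$parts[[nm]]$stable) "stable" else "UNSTABLE",
         rep$parts[[nm]]$fits_build_volume)
  logf("  original-scale resolution: %g um per printed layer",
       rep$original_scale_resolution_um)
  report_json <- file.path(output_dir, paste0(model, "_print_report.json"))
  jsonlite::write_json(rep, report_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  invisible(structure(
    list(assembly = asm, morphometry = morph, print_report = rep,
         scale = sc,
         files = c(asm$files, asm$manifest, morph_csv, report_json,
                   log_path),
         log = log_path),
    class = "cytoprint_run"))
}

#' @export
print.cytoprint_run <- function(x, ...) {
  cat("<cytoprint_run> ", length(x$assembly$parts), " part(s), M = ",
      x$scale$M, "\n", sep = "")
  cat("  outputs:\n")
  for (f in x$files) cat("   ", f, "\n")
  invisible(x)
}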