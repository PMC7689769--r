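#' Read and write field maps as flat CSV
#'
#' The interchange format for measured field maps (e.g. from a robotic
#' mapper): columns `x, y, z` (m) plus either the full vector `Bx, By, Bz`
#' (T) or a single scalar column `B`, taken to be the main-field component.
#'
#' @param path file path.
#' @param b0_axis axis of the main field.
#' @return a `field_map` tibble.
#' @export
read_field_map_csv <- function(path, b0_axis = "z") {
  if (!file.exists(path)) abort(sprintf("field map file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) abort("field map file is empty.")
  has_vec <- all(c("Bx", "By", "Bz") %in% names(df))
  has_scalar <- "B" %in% names(df)
  if (!all(c("x", "y", "z") %in% names(df)) || !(has_vec || has_scalar)) {
    abort("field map needs columns x,y,z plus either B or Bx,By,Bz.")
  }
  cols <- c("x", "y", "z", if (has_vec) c("Bx", "By", "Bz") else "B")
  for (cn in cols) df[[cn]] <- suppressWarnings(as.numeric(df[[cn]]))
  bad <- which(!stats::complete.cases(df[cols]) |
                 !apply(is.finite(as.matrix(df[cols])), 1, all))
  if (length(bad)) {
    abort(sprintf("malformed field map rows (non-numeric/non-finite): %s",
                  paste(bad + 1L, collapse = ", ")))  # +1 for the header line
  }
  iax <- match(b0_axis, c("x", "y", "z"))
  B <- if (has_vec) {
    as.matrix(df[, c("Bx", "By", "Bz")])
  } else {
    m <- matrix(0, nrow(df), 3)
    m[, iax] <- df$B
    m
  }
  new_field_map(as.matrix(df[, c("x", "y", "z")]), B, b0_axis)
}

#' @rdname read_field_map_csv
#' @param field a `field_map` tibble.
#' @export
write_field_map_csv <- function(field, path) {
  write.csv(as.data.frame(field[, c("x", "y", "z", "Bx", "By", "Bz")]),
            path, row.names = FALSE)
  invisible(path)
}

#' Read and write wire sets (CSV paths + JSON manifest)
#'
#' Paths go to `<path>` as CSV (`path_id, x, y, z`); current, wire diameter
#' and coil axis go to `<path>.json`.
#'
#' @param wires a [wire_set()].
#' @param path CSV file path.
#' @export
write_wire_csv <- function(wires, path) {
  stopifnot(inherits(wires, "wire_set"))
  write.csv(as.data.frame(wires$paths), path, row.names = FALSE)
  meta <- list(current = wires$current, wire_diameter = wires$wire_diameter,
               axis = attr(wires, "axis"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_wire_csv
#' @export
read_wire_csv <- function(path) {
  paths <- as_tibble(read.csv(path))
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  ws <- wire_set(paths, current = meta$current %||% 1,
                 wire_diameter = meta$wire_diameter %||% 0.0015)
  attr(ws, "axis") <- meta$axis
  ws
}

#' Serialize magnet and shim designs as JSON
#'
#' The ring table of a Halbach design, or the 15 x 60 ternary state matrix
#' of a shim grid ({0, 1, 2} = absent / aligned / flipped), written in a
#' plain JSON layout.
#'
#' @param design a [halbach_design()].
#' @param path file path.
#' @export
write_design_json <- function(design, path) {
  stopifnot(inherits(design, "halbach_design"))
  jsonlite::write_json(
    list(rings = design$rings, bore_diameter = design$bore_diameter,
         length = design$length, magnet_size = design$magnet_size,
         remanence = design$remanence, layer_gap = design$layer_gap),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_design_json
#' @export
read_design_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  halbach_design(
    n_rings = nrow(j$rings), bore_diameter = j$bore_diameter,
    length = j$length, magnet_size = j$magnet_size, remanence = j$remanence,
    magnets_per_layer = j$rings$n_inner[1], ring_radii = j$rings$r_inner,
    layer_gap = j$layer_gap)
}

#' @rdname write_design_json
#' @param grid a [shim_grid()].
#' @export
write_shim_json <- function(grid, path) {
  stopifnot(inherits(grid, "shim_grid"))
  jsonlite::write_json(
    list(radius = grid$radius, length = grid$length, n_rings = grid$n_rings,
         positions_per_ring = grid$positions_per_ring,
         magnet_size = grid$magnet_size, remanence = grid$remanence,
         state = grid$state),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_design_json
#' @export
read_shim_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  shim_grid(radius = j$radius, length = j$length, n_rings = j$n_rings,
            positions_per_ring = j$positions_per_ring,
            magnet_size = j$magnet_size, remanence = j$remanence,
            state = j$state)
}

#' Load a TSE protocol from YAML/JSON or a named preset
#'
#' Preset protocols shipped with the package (under
#' `inst/protocols/`) carry the reference parameter sets: `t1w_brain`,
#' `t2w_brain`, `ir_brain`, `hires_brain`, `knee_tse`, `phantom_2dse`.
#'
#' @param name_or_path preset name or path to a YAML/JSON protocol file.
#' @return a [tse_params()].
#' @export
read_protocol <- function(name_or_path) {
  path <- name_or_path
  if (!file.exists(path)) {
    path <- system.file("protocols", paste0(name_or_path, ".yaml"),
                        package = "halbachmri")
    if (!nzchar(path)) {
      abort(sprintf("unknown protocol '%s' (not a file or preset).",
                    name_or_path))
    }
  }
  y <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  tse_params(
    fov = unlist(y$fov), matrix = unlist(y$matrix), tr = y$tr, te = y$te,
    etl = y$etl, ti = y$ti, bandwidth = y$bandwidth,
    ordering = y$ordering %||% "center_out",
    elliptical = isTRUE(y$elliptical)
  )
}

#' Write an image volume as NIfTI
#'
#' @param img an [image_volume()].
#' @param path output path (`.nii` / `.nii.gz`).
#' @export
write_image_nifti <- function(img, path) {
  stopifnot(inherits(img, "image_volume"))
  nii <- RNifti::asNifti(img$voxels)
  RNifti::pixdim(nii) <- img$spacing
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Run a design -> simulate -> reconstruct pipeline from a config
#'
#' Executes the requested stages in order and writes every artifact plus a
#' JSON manifest (with the config hash and seed) into `out_dir`. Stages:
#' `design_magnet` (ring-diameter GA), `shim` (ternary shim GA),
#' `design_gradient` (target-field coils), `simulate` (phantom k-space),
#' `recon` (inverse FFT and, when designed coils are available,
#' conjugate-phase) and `report` (distortion metrics CSV). A stage failure
#' halts the run with the stage name after persisting the partial manifest;
#' stages not requested reuse artifacts already in `out_dir`.
#'
#' @param config a named list, or path to a YAML config file. See the
#'   packaged example under `inst/configs/demo_pipeline.yaml`.
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir = tempfile("halbach_run_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  stages <- config$stages %||%
    c("design_magnet", "design_gradient", "simulate", "recon", "report")
  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, digits = NA)
  cfg_hash <- unname(tools::md5sum(cfg_file))
  manifest <- list(config_hash = cfg_hash, seed = seed, stages = stages,
                   artifacts = list(), status = "running")
  persist <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  add <- function(name, file) {
    manifest$artifacts[[name]] <<- file
    persist()
  }
  run_stage <- function(name, fun) {
    if (!(name %in% stages)) return(invisible(NULL))
    tryCatch(fun(), error = function(e) {
      manifest$status <<- paste0("failed at stage ", name)
      persist()
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  persist()

  run_stage("design_magnet", function() {
    mc <- config$magnet %||% list()
    design <- halbach_design(
      n_rings = mc$n_rings %||% 23,
      magnets_per_layer = mc$magnets_per_layer %||% 64,
      ring_radii = mc$ring_radii
    )
    ga <- ga_config(population_size = mc$population %||% 40,
                    generations = mc$generations %||% 40, seed = seed)
    opt <- optimize_ring_diameters(design, config = ga)
    write_design_json(opt$design, file.path(out_dir, "magnet_design.json"))
    jsonlite::write_json(
      list(ppm = opt$ppm, mean_b0_mT = opt$mean_b0 * 1e3),
      file.path(out_dir, "magnet_stats.json"), auto_unbox = TRUE, digits = NA)
    add("magnet_design", "magnet_design.json")
    add("magnet_stats", "magnet_stats.json")
  })

  run_stage("shim", function() {
    sc <- config$shim %||% list()
    if (is.null(sc$field_map_csv)) {
      abort("shim stage needs `shim$field_map_csv` (measured map on the DSV points).")
    }
    fm <- read_field_map_csv(sc$field_map_csv)
    grid <- shim_grid(n_rings = sc$n_rings %||% 15,
                      positions_per_ring = sc$positions_per_ring %||% 60)
    ga <- ga_config(population_size = sc$population %||% 40,
                    generations = sc$generations %||% 40, seed = seed)
    opt <- optimize_shim(fm, grid, config = ga)
    write_shim_json(opt$grid, file.path(out_dir, "shim_state.json"))
    add("shim_state", "shim_state.json")
  })

  run_stage("design_gradient", function() {
    gc <- config$gradient %||% list()
    for (ax in gc$axes %||% "x") {
      ws <- design_gradient_coil(ax,
        n_contours = gc$n_contours %||% 12,
        lambda = gc$lambda %||% 1e-4)
      write_wire_csv(ws, file.path(out_dir, paste0("wires_", ax, ".csv")))
      add(paste0("wires_", ax), paste0("wires_", ax, ".csv"))
    }
  })

  run_stage("simulate", function() {
    pc <- config$phantom %||% list()
    ph <- switch(pc$kind %||% "tube_grid",
      tube_grid = tube_grid_phantom(voxel_mm = pc$voxel_mm %||% 2),
      brain = tissue_phantom("brain", n = pc$n %||% 16,
                             voxel_mm = pc$voxel_mm %||% 12),
      knee = tissue_phantom("knee", n = pc$n %||% 16,
                            voxel_mm = pc$voxel_mm %||% 12)
    )
    proto <- if (!is.null(config$protocol)) {
      read_protocol(config$protocol)
    } else {
      # acquisition matrix may be coarser than the phantom grid
      tse_params(fov = dim(ph$rho) * ph$spacing,
                 matrix = pmin(dim(ph$rho), c(48, 48, 12)), tr = 500,
                 te = 10, etl = 4, elliptical = FALSE)
    }
    sched <- echo_train_schedule(proto)
    maps <- identity_encoding_maps(ph)
    wx <- file.path(out_dir, "wires_x.csv")
    if (file.exists(wx) && isTRUE(config$sim$use_designed_x)) {
      ws <- read_wire_csv(wx)
      co <- voxel_coords(ph) / 1000
      maps$gx <- array(encoding_field_map(ws, co, axis = "x")$coord,
                       dim(ph$rho))
    }
    ks <- simulate_acquisition(ph, maps, sched,
                               acq_config(noise_sd = config$sim$noise_sd %||% 0,
                                          seed = seed))
    saveRDS(list(kspace = ks, phantom_dims = dim(ph$rho),
                 spacing = ph$spacing), file.path(out_dir, "kspace.rds"))
    add("kspace", "kspace.rds")
  })

  run_stage("recon", function() {
    ksf <- file.path(out_dir, "kspace.rds")
    if (!file.exists(ksf)) abort("no k-space artifact; run the simulate stage.")
    ks <- readRDS(ksf)$kspace
    img <- ifft_recon(window_filter(ks))
    write_image_nifti(img, file.path(out_dir, "image.nii.gz"))
    saveRDS(img, file.path(out_dir, "image.rds"))
    add("image", "image.nii.gz")
  })

  run_stage("report", function() {
    imf <- file.path(out_dir, "image.rds")
    if (!file.exists(imf)) abort("no reconstructed image; run the recon stage.")
    img <- readRDS(imf)
    if ((config$phantom$kind %||% "tube_grid") == "tube_grid") {
      met <- distortion_metrics(img, tube_grid_centers())
      write.csv(as.data.frame(met$per_blob),
                file.path(out_dir, "metrics.csv"), row.names = FALSE)
      jsonlite::write_json(list(rms_mm = met$rms_mm,
                                n_detected = met$n_detected),
                           file.path(out_dir, "metrics.json"),
                           auto_unbox = TRUE, digits = NA)
    } else {
      jsonlite::write_json(list(max_intensity = max(img$voxels)),
                           file.path(out_dir, "metrics.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    add("metrics", "metrics.json")
  })

  manifest$status <- "ok"
  persist()
  invisible(manifest)
}
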