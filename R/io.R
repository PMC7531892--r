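#' Read a volume from a multipage TIFF
#'
#' Pages are stacked along the third axis. Voxel sizes are taken from the
#' JSON sidecar written by [write_volume()] (`<path>.json`) or from the
#' `voxel_size` argument; with neither, reading fails.
#'
#' @param path TIFF file.
#' @param voxel_size nm per axis (overrides the sidecar).
#' @return A [volume_image()].
#' @export
read_volume <- function(path, voxel_size = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(unlist(pages), c(dim(pages[[1]])[1:2], length(pages)))
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else NULL
  if (is.null(voxel_size)) {
    if (is.null(meta$voxel_size_nm))
      stop("read_volume: no voxel size; supply `voxel_size` (nm per axis) ",
           "or a metadata sidecar")
    voxel_size <- meta$voxel_size_nm
  }
  if (!is.null(meta$scale)) arr <- arr * meta$scale
  if (!is.null(meta$offset)) arr <- arr + meta$offset
  channel <- if (!is.null(meta$channel)) meta$channel else ""
  volume_image(arr, voxel_size, channel)
}

#' Write a volume to a multipage TIFF with a metadata sidecar
#'
#' Data are stored as 16-bit (intensities, scaled) or 8-bit (label maps);
#' the affine scale needed to recover the original values, the voxel sizes
#' and the channel name go to a JSON sidecar at `<path>.json`, so a
#' write/read round trip reproduces integer data exactly.
#'
#' @param vol a [volume_image()] or array.
#' @param path output TIFF file.
#' @param voxel_size nm per axis (required for a bare array).
#' @param bits 8 or 16.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, voxel_size = NULL, bits = 16L) {
  v <- vol_values(vol)
  voxel <- if (inherits(vol, "volume_image")) vol$voxel_size
           else rep_len(as.numeric(voxel_size), length(dim(v)))
  if (is.null(voxel)) stop("write_volume: voxel_size required")
  channel <- if (inherits(vol, "volume_image")) vol$channel else ""
  lo <- min(v); hi <- max(v)
  maxint <- 2^bits - 1
  int_data <- all(v == round(v)) && (hi - lo) <= maxint
  # unit scale keeps integer data bit-exact through the 1/maxint quantisation
  scale <- if (int_data || hi == lo) 1 else (hi - lo) / maxint
  norm <- (v - lo) / (maxint * scale) # in [0,1] steps of 1/maxint
  if (length(dim(v)) == 2L) dim(norm) <- c(dim(v), 1L)
  pages <- lapply(seq_len(dim(norm)[3]), function(z) norm[, , z])
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  jsonlite::write_json(list(voxel_size_nm = voxel, scale = scale * maxint,
                            offset = lo, channel = channel,
                            shape = dim(v)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Build a validated run configuration
#'
#' Collects every tunable of the pipeline with defaults at the values the
#' analyses assume: 7 chromatin classes, MCNR cutoff 5, 41 nm live pixel,
#' 2 s frame interval, 20-frame window.
#'
#' @param ... overrides of the defaults (unknown names are an error).
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    out_dir = NULL,
    # synthetic inputs
    nucleus = list(),            # nucleus_spec() overrides
    foci = list(),               # foci_spec() overrides
    motion = list(),             # motion_spec() overrides
    # topography
    n_classes = 7L,
    icm_beta = 0.7,
    rim_thickness_nm = 300,
    chromocenter_min_um3 = 0.05,
    # foci mapping
    mcnr_cutoff = 5,
    watershed_tolerance = 0.1,
    # dynamics
    pixel_size_nm = 41,
    frame_interval_s = 2,
    window_frames = 20L,
    # stage toggles
    run_topography = TRUE,
    run_foci = TRUE,
    run_dfcc = TRUE,
    run_hid = TRUE,
    hid_stride = 1L)
  ov <- list(...)
  if (length(ov) == 1L && is.null(names(ov)) && is.list(ov[[1]])) ov <- ov[[1]]
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown))
    stop("run_config: unknown option(s): ", paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_config <- function(path) run_config(yaml::read_yaml(path))

#' Run the full analysis pipeline on synthetic data
#'
#' Generates a synthetic nucleus, marker foci and a live series from the
#' configuration's specs, then runs the enabled stages: chromatin
#' topography (mask, calibration, classification, surface, morphometry),
#' foci mapping (detection, MCNR filter, enrichment, surface distances),
#' flow correlation (per-lag correlation length and smoothness) and
#' per-pixel MSD model maps. Every numeric decision is echoed in the
#' returned `log` (and written to `run.log` when `out_dir` is set, with CSV
#' tables of the results).
#'
#' @param cfg a [run_config()].
#' @return A result bundle list with elements per stage plus `log`.
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  logln <- character(0)
  say <- function(...) logln <<- c(logln, paste0(...))
  say("seed = ", cfg$seed)
  res <- list()
  nspec <- do.call(nucleus_spec, c(cfg$nucleus, list(seed = cfg$seed)))
  sim <- generate_nucleus(nspec)
  res$synthetic <- sim
  say("nucleus: shape = ", paste(nspec$volume_shape, collapse = "x"),
      ", voxel = ", paste(nspec$voxel_size, collapse = "x"), " nm")
  if (cfg$run_topography || cfg$run_foci) {
    mask <- segment_nucleus(sim$dna)
    cal <- calibrate_intensity(sim$dna, mask)
    say("calibration (background mode) = ", signif(cal$calibration, 6))
    cm <- classify_chromatin(cal, mask, n_classes = cfg$n_classes,
                             icm_beta = cfg$icm_beta, seed = cfg$seed)
    say("mixture means = ", paste(signif(cm$mixture$mean, 5), collapse = ", "))
    surf <- extract_ic_surface(cm)
    s2v <- surface_to_volume(cm)
    widths <- measure_cd_widths(cm, min_class = 3L)
    comp <- compartment_masks(cm, cfg$rim_thickness_nm,
                              chromocenter_min_um3 = cfg$chromocenter_min_um3)
    say("surface/volume = ", signif(s2v$ratio_um, 5), " um^-1; ",
        "CD width mean = ", signif(widths$mean_nm, 5), " nm over ",
        widths$n_domains, " domains")
    res$topography <- list(mask = mask, calibrated = cal, classmap = cm,
                           surface = surf, surface_to_volume = s2v,
                           cd_widths = widths, compartments = comp)
  }
  if (cfg$run_foci) {
    fspec <- do.call(foci_spec, c(cfg$foci, list(seed = cfg$seed + 1L)))
    placed <- place_foci(res$topography$classmap$labels, fspec,
                         nspec$voxel_size)
    det <- detect_foci(placed$marker, res$topography$mask,
                       tolerance = cfg$watershed_tolerance)
    say("foci: placed = ", nrow(placed$truth), ", detected = ", nrow(det),
        " at Otsu threshold ", signif(attr(det, "threshold"), 6))
    filt <- filter_mcnr(det, placed$mcnr_map, cutoff = cfg$mcnr_cutoff)
    say("MCNR filter (cutoff ", cfg$mcnr_cutoff, "): removed ",
        attr(filt, "n_removed"))
    filt <- assign_classes(filt, res$topography$classmap)
    out_of_map <- filt$class < 1L
    if (any(out_of_map)) {
      say("dropped ", sum(out_of_map), " foci with centroids outside the ",
          "segmented class map")
      filt <- filt[!out_of_map, , drop = FALSE]
      class(filt) <- c("foci_set", "data.frame")
    }
    enr <- class_enrichment(filt, res$topography$classmap, pseudocount = TRUE)
    dst <- surface_distances(filt, res$topography$surface,
                             res$topography$classmap)
    say("surface distance mean = ", signif(attr(dst, "mean_nm"), 5), " nm")
    res$foci <- list(spec = fspec, truth = placed$truth, detected = det,
                     filtered = dst, enrichment = enr)
  }
  if (cfg$run_dfcc || cfg$run_hid) {
    mspec <- do.call(motion_spec,
                     c(cfg$motion,
                       list(pixel_size = cfg$pixel_size_nm,
                            frame_interval = cfg$frame_interval_s,
                            n_frames = cfg$window_frames,
                            seed = cfg$seed + 2L)))
    ser <- generate_flow_series(mspec)
    res$series <- ser
  }
  if (cfg$run_dfcc) {
    tab <- dfcc_pipeline(ser$frames, pixel_size = cfg$pixel_size_nm,
                         frame_interval = cfg$frame_interval_s,
                         max_lag_frames = 3L)
    say("dfcc: rho_c(dt_1) = ", signif(tab$rho_c_px[1], 5), " px, nu = ",
        signif(tab$nu[1], 5))
    res$dfcc <- tab
  }
  if (cfg$run_hid) {
    maps <- hid_pipeline(ser$frames, pixel_size = cfg$pixel_size_nm,
                         frame_interval = cfg$frame_interval_s,
                         stride = cfg$hid_stride)
    say("hid: model counts = ",
        paste(names(table(maps$model)), table(maps$model),
              sep = ":", collapse = ", "),
        "; unclassified = ", maps$n_unclassified)
    res$hid <- maps
  }
  res$log <- logln
  if (!is.null(cfg$out_dir)) write_bundle(res, cfg)
  res
}

## write result CSVs/TIFFs and the run log
write_bundle <- function(res, cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(cfg$out_dir, f)
  writeLines(res$log, p("run.log"))
  if (!is.null(res$topography)) {
    cm <- res$topography$classmap
    write_volume(volume_image(cm$labels / 1, cm$voxel_size, "classes"),
                 p("classmap.tif"), bits = 8L)
    utils::write.csv(data.frame(class = seq_along(cm$class_volumes),
                                volume_um3 = cm$class_volumes),
                     p("class_volumes.csv"), row.names = FALSE)
    utils::write.csv(data.frame(width_nm = res$topography$cd_widths$widths_nm),
                     p("cd_widths.csv"), row.names = FALSE)
  }
  if (!is.null(res$foci)) {
    utils::write.csv(as.data.frame(res$foci$filtered), p("foci.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(res$foci$enrichment), p("enrichment.csv"),
                     row.names = FALSE)
  }
  if (!is.null(res$dfcc))
    utils::write.csv(res$dfcc, p("dfcc.csv"), row.names = FALSE)
  if (!is.null(res$hid)) {
    utils::write.csv(data.frame(model = as.vector(res$hid$model),
                                D = as.vector(res$hid$D),
                                alpha = as.vector(res$hid$alpha),
                                v = as.vector(res$hid$v)),
                     p("hid_pixels.csv"), row.names = FALSE)
  }
  invisible(cfg$out_dir)
}
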