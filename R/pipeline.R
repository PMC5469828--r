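pipeline_defaults <- function() {
  list(
    seed = 1L,
    phantom = NULL, # phantom_spec() arguments
    input = NULL,   # list(thg =, shg =, fluo =, voxel_size_um =)
    channels = NULL, # phantom channels to render; default THG (+FLUO/+SHG as configured)
    psf = list(mode = "gaussian", fwhm_lateral_um = 0.35, fwhm_axial_um = 1.35,
               candidate_points_um = NULL),
    deconvolution = list(iterations = 20L),
    vesselness = list(scales_um = c(0.3, 0.45, 0.68), alpha = 0.5,
                      beta = 0.5, c = "auto"),
    threshold = list(method = "hysteresis", value = 0.7),
    skeleton = list(prune_um = 0.9, min_component_um = 1.0),
    lacunae = list(method = "otsu", opening_radius_um = 0.6,
                   closing_radius_um = 0.6, min_volume_um3 = 8),
    diameters = list(n_samples = 100L),
    sbr = list(min_distance_um = 1.0),
    lamellar = list(direction = c(0, 1, 0), max_period_um = 8),
    bsu = list(enabled = FALSE, contrast_mode = "negative",
               bridge_radius_um = 2, min_size_um = 100, median_um = 1),
    fluorescence_branch = TRUE,
    # the fluorescence branch sees raw (undeconvolved) 0.57 um tubes and
    # needs the finest Hessian scale that the deconvolved THG branch drops
    fluorescence_scales_um = c(0.2, 0.3, 0.45, 0.68),
    verbose = FALSE
  )
}

merge_config <- function(config) {
  cfg <- pipeline_defaults()
  for (nm in names(config)) {
    if (nm %in% names(cfg) && is.list(cfg[[nm]]) && is.list(config[[nm]]))
      cfg[[nm]] <- modifyList(cfg[[nm]], config[[nm]])
    else cfg[[nm]] <- config[[nm]]
  }
  cfg
}

# coerce YAML-style nested lists into phantom_spec() arguments
coerce_phantom_cfg <- function(ph) {
  as_mat <- function(x) if (is.matrix(x)) x else do.call(rbind, lapply(x, unlist))
  for (f in c("canaliculi", "vascular_channels"))
    if (!is.null(ph[[f]]))
      ph[[f]] <- lapply(ph[[f]], function(e) {
        e$polyline_um <- as_mat(e$polyline_um); e
      })
  if (!is.null(ph$cement_lines))
    ph$cement_lines <- lapply(ph$cement_lines, function(e) {
      e$polyline_yx_um <- as_mat(e$polyline_yx_um); e
    })
  if (!is.null(ph$lacunae))
    ph$lacunae <- lapply(ph$lacunae, function(e) {
      e$center_um <- unlist(e$center_um)
      e$semi_axes_um <- unlist(e$semi_axes_um)
      if (!is.null(e$angles)) e$angles <- unlist(e$angles)
      e
    })
  for (f in c("volume_size_um", "voxel_size_um"))
    if (!is.null(ph[[f]])) ph[[f]] <- unlist(ph[[f]])
  if (!is.null(ph$lamellar)) {
    ph$lamellar <- lapply(ph$lamellar, unlist)
    if (!is.null(ph$lamellar$direction)) ph$lamellar$direction <- as.numeric(ph$lamellar$direction)
  }
  if (!is.null(ph$amplitudes)) ph$amplitudes <- lapply(ph$amplitudes, function(x) if (is.null(x)) NULL else unlist(x))
  ph
}

#' Simulate a multimodal phantom acquisition
#'
#' Builds the phantom of a configuration and renders the requested
#' channels; optionally writes the channels, ground-truth masks and a JSON
#' ground-truth sidecar to a directory.
#'
#' @param config configuration list or YAML path with at least a `phantom`
#'   entry ([phantom_spec()] arguments) and optionally `psf`, `channels`,
#'   `seed`.
#' @param outdir if non-`NULL`, write TIFF channels plus ground truth.
#' @return List with `spec`, `truth`, `psf` and the rendered
#'   `channels` (named list of [lcn_volume()]).
#' @export
simulate_phantom <- function(config, outdir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(config)
  if (is.null(cfg$phantom)) stop("configuration error: no `phantom` section")
  ph <- coerce_phantom_cfg(cfg$phantom)
  if (is.null(ph$seed)) ph$seed <- cfg$seed
  spec <- do.call(phantom_spec, ph)
  truth <- build_phantom(spec)
  psf <- gaussian_psf(cfg$psf$fwhm_lateral_um, cfg$psf$fwhm_axial_um,
                      spec$voxel_size_um)
  channels <- cfg$channels
  if (is.null(channels)) {
    channels <- "THG"
    if (isTRUE(cfg$fluorescence_branch)) channels <- c(channels, "FLUO")
    if (spec$lamellar$amplitude > 0) channels <- c(channels, "SHG")
  }
  out <- list()
  for (ch in channels) {
    out[[ch]] <- switch(ch,
                        THG = render_thg(truth, spec, psf),
                        SHG = render_shg(truth, spec, psf),
                        FLUO = render_fluorescence(truth, spec, psf),
                        stop("unknown channel: ", ch))
  }
  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    for (ch in names(out))
      write_volume(out[[ch]], file.path(outdir, paste0(tolower(ch), ".tif")))
    write_mask(truth$pore_mask, spec$voxel_size_um, file.path(outdir, "truth_pore.tif"))
    write_mask(truth$lacuna_mask, spec$voxel_size_um, file.path(outdir, "truth_lacunae.tif"))
    jsonlite::write_json(
      list(porosity_fractions = as.list(truth$porosity_fractions),
           shg_period_um = truth$shg_period_um,
           voxel_size_um = as.numeric(spec$voxel_size_um),
           volume_size_um = as.numeric(spec$volume_size_um),
           n_lacunae = length(truth$lacunae),
           centerlines = lapply(truth$centerlines, function(cl)
             list(diameter_um = cl$diameter_um, length_um = cl$length_um,
                  polyline_um = apply(cl$polyline_um, 1, as.numeric, simplify = FALSE)))),
      file.path(outdir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  }
  list(spec = spec, truth = truth, psf = psf, channels = out)
}

#' Run the full LCN analysis pipeline
#'
#' Executes, with structured logging of every stage's realized parameters:
#' (optional) phantom simulation, PSF construction or estimation,
#' Richardson-Lucy deconvolution, multiscale vesselness, thresholding, 3D
#' skeletonization, lacuna segmentation, diameter/porosity/SBR
#' quantification, optional SHG lamellar-period and cross-channel
#' correlation measurements, an optional BSU stage, and an optional
#' fluorescence-channel branch that skips deconvolution (lumen-filled
#' contrast needs no edge re-fusion) following the confocal recipe. The
#' fluorescence branch reuses the THG-measured mean diameter for its
#' cylinder-model porosity, as in the reference analysis procedure.
#'
#' @param config configuration list or YAML path; see
#'   `thglcn:::pipeline_defaults()` for the complete structure. Must name
#'   either an `input` (TIFF paths) or a `phantom` simulation fixture.
#' @return An object of class `lcn_report`; the segmentation objects
#'   (masks, skeleton, volumes) are attached as `attr(report, "objects")`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(config)
  log <- character()
  t00 <- proc.time()[3]
  say <- function(stage, fmt, ...) {
    line <- sprintf("[%s +%.1fs] %s", stage, proc.time()[3] - t00, sprintf(fmt, ...))
    log <<- c(log, line)
    if (isTRUE(cfg$verbose)) message(line)
  }
  fail <- function(stage, e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  }
  st <- function(stage, expr) tryCatch(expr, error = function(e) fail(stage, e))

  vols <- list(); truth <- NULL; spec <- NULL
  if (!is.null(cfg$phantom)) {
    sim <- st("simulate", simulate_phantom(cfg))
    vols <- sim$channels; truth <- sim$truth; spec <- sim$spec
    say("simulate", "phantom %s, %d canaliculi, %d lacunae",
        paste(spec$volume_size_um, collapse = "x"),
        length(truth$centerlines), length(truth$lacunae))
  } else if (!is.null(cfg$input)) {
    vsz <- cfg$input$voxel_size_um
    for (ch in intersect(c("thg", "shg", "fluo", "ct"), names(cfg$input))) {
      vols[[toupper(ch)]] <- st("read", read_volume(cfg$input[[ch]], vsz,
                                                    modality = toupper(ch)))
      say("read", "%s: %s", toupper(ch), cfg$input[[ch]])
    }
    if (!length(vols)) stop("configuration error: `input` names no channel files")
  } else {
    stop("configuration error: config must provide either `input` volumes or a `phantom` fixture")
  }
  thg <- vols$THG
  if (is.null(thg)) stop("configuration error: a THG channel is required")
  vs <- thg$voxel_size_um

  # --- PSF
  psf <- st("psf", {
    if (identical(cfg$psf$mode, "estimate") && !is.null(cfg$psf$candidate_points_um)) {
      estimate_psf_from_canaliculi(thg, rbind(cfg$psf$candidate_points_um))
    } else {
      gaussian_psf(cfg$psf$fwhm_lateral_um, cfg$psf$fwhm_axial_um, vs)
    }
  })
  say("psf", "FWHM %.3f x %.3f um (%s)", psf$fwhm_lateral_um, psf$fwhm_axial_um,
      cfg$psf$mode)

  # --- restoration
  dec <- st("deconvolve", richardson_lucy(thg, psf, cfg$deconvolution$iterations))
  say("deconvolve", "Richardson-Lucy, %d iterations", cfg$deconvolution$iterations)

  # --- canalicular segmentation
  vp <- st("vesselness", do.call(vesselness_params, cfg$vesselness))
  ves <- st("vesselness", vesselness(dec, vp))
  say("vesselness", "scales {%s} um, realized c = {%s}",
      paste(vp$scales_um, collapse = ", "),
      paste(sprintf("%.3g", attr(ves, "realized_c")), collapse = ", "))
  vmask <- st("threshold", threshold_mask(ves$data, cfg$threshold$method,
                                          cfg$threshold$value))
  say("threshold", "%s threshold = %.4g (mask fraction %.3f%%)",
      attr(vmask, "method"), attr(vmask, "threshold"), 100 * mean(vmask))
  skel <- st("skeletonize", skeletonize3d(vmask, vs, cfg$skeleton$prune_um,
                                          cfg$skeleton$min_component_um))
  say("skeletonize", "total length %.1f um, %d chains", skel$total_length_um,
      length(skel$chains))

  # --- lacunae
  lmask <- st("lacunae", segment_lacunae(
    thg, list(method = cfg$lacunae$method, value = cfg$lacunae$value),
    cfg$lacunae$opening_radius_um, cfg$lacunae$closing_radius_um,
    cfg$lacunae$min_volume_um3))
  say("lacunae", "threshold %.4g, %.3f%% of volume", attr(lmask, "threshold"),
      100 * mean(lmask))

  # --- quantification
  dia <- NULL
  if (skel$total_length_um > 0) {
    dia <- st("diameters", diameter_distribution(
      thg, skel, cfg$diameters$n_samples, seed = cfg$seed))
    say("diameters", "mean %.3f +/- %.3f um over %d two-edge measurements",
        dia$diameter_mean_um, dia$diameter_sd_um, dia$n_measurements)
  }
  dmean <- if (!is.null(dia) && is.finite(dia$diameter_mean_um))
    dia$diameter_mean_um else NA_real_
  por <- if (!is.na(dmean))
    st("porosity", porosity_fractions(lmask, skel, dmean, vs))
  else c(lacunar = NA, canalicular = NA, total = NA)
  if (!is.na(dmean))
    say("porosity", "lacunar %.3f%%, canalicular %.3f%%, total %.3f%%",
        100 * por[1], 100 * por[2], 100 * por[3])

  sbr <- NULL
  if (skel$total_length_um > 0) {
    sbr <- st("sbr", signal_to_background(thg, skel, vmask | lmask,
                                          cfg$sbr$min_distance_um))
    say("sbr", "canaliculi-to-background %.2f:1", as.numeric(sbr))
  }

  # --- SHG lamellar period
  period <- NULL
  if (!is.null(vols$SHG)) {
    dirv <- if (!is.null(spec)) spec$lamellar$direction else cfg$lamellar$direction
    ext <- dim(vols$SHG$data) * vols$SHG$voxel_size_um
    plen <- 0.85 * sum(abs(dirv) * ext)
    ctr <- ext / 2
    start <- ctr - dirv * plen / 2
    period <- st("lamellar", lamellar_period(vols$SHG, start, dirv, plen,
                                             cfg$lamellar$max_period_um))
    say("lamellar", "period %.2f +/- %.2f um", period$period_mean_um,
        period$period_sd_um)
  }

  # --- cross-channel correlations
  correlations <- list()
  chn <- names(vols)
  if (length(chn) >= 2) {
    for (i in seq_len(length(chn) - 1)) for (j in (i + 1):length(chn)) {
      key <- paste(chn[i], chn[j], sep = "_")
      correlations[[key]] <- st("correlation",
                                image_correlation(vols[[chn[i]]], vols[[chn[j]]]))
      say("correlation", "%s = %.3f", key, correlations[[key]])
    }
  }

  # --- optional BSU stage
  bsu <- NULL
  if (isTRUE(cfg$bsu$enabled)) {
    cem <- st("bsu", detect_cement_lines(thg, cfg$bsu$contrast_mode,
                                         median_um = cfg$bsu$median_um))
    bsu <- st("bsu", label_bsus(cem, voxel_size_um = vs,
                                bridge_radius_um = cfg$bsu$bridge_radius_um,
                                min_size_um = cfg$bsu$min_size_um))
    say("bsu", "%d BSUs", bsu$n_bsus)
  }

  # --- fluorescence branch (confocal recipe: no deconvolution)
  fluo <- NULL
  if (isTRUE(cfg$fluorescence_branch) && !is.null(vols$FLUO)) {
    fv <- vols$FLUO
    fvp <- st("fluo", vesselness_params(scales_um = cfg$fluorescence_scales_um,
                                        alpha = cfg$vesselness$alpha,
                                        beta = cfg$vesselness$beta,
                                        c = cfg$vesselness$c))
    fves <- st("fluo", vesselness(fv, fvp))
    fmask <- st("fluo", threshold_mask(fves$data, cfg$threshold$method,
                                       cfg$threshold$value))
    fskel <- st("fluo", skeletonize3d(fmask, fv$voxel_size_um,
                                      cfg$skeleton$prune_um,
                                      cfg$skeleton$min_component_um))
    flmask <- st("fluo", segment_lacunae(
      fv, list(method = cfg$lacunae$method, value = cfg$lacunae$value),
      cfg$lacunae$opening_radius_um, cfg$lacunae$closing_radius_um,
      cfg$lacunae$min_volume_um3))
    fpor <- if (!is.na(dmean))
      st("fluo", porosity_fractions(flmask, fskel, dmean, fv$voxel_size_um))
    else c(lacunar = NA, canalicular = NA, total = NA)
    fsbr <- if (fskel$total_length_um > 0)
      st("fluo", signal_to_background(fv, fskel, fmask | flmask,
                                      cfg$sbr$min_distance_um))
    else NULL
    say("fluo", "total length %.1f um, total porosity %.3f%%",
        fskel$total_length_um, 100 * fpor[3])
    fluo <- list(total_length_um = fskel$total_length_um,
                 porosity = as.list(fpor),
                 sbr = if (!is.null(fsbr)) as.numeric(fsbr) else NULL,
                 threshold = attr(fmask, "threshold"))
    attr(fluo, "objects") <- list(skeleton = fskel, vessel_mask = fmask,
                                  lacuna_mask = flmask)
  }

  report <- structure(list(
    provenance = list(
      package_version = as.character(utils::packageVersion("thglcn")),
      seed = cfg$seed,
      voxel_size_um = as.numeric(vs),
      dims = dim(thg$data),
      psf = list(mode = cfg$psf$mode, fwhm_lateral_um = psf$fwhm_lateral_um,
                 fwhm_axial_um = psf$fwhm_axial_um),
      rl_iterations = cfg$deconvolution$iterations,
      vesselness = list(scales_um = vp$scales_um, alpha = vp$alpha,
                        beta = vp$beta, c = cfg$vesselness$c,
                        realized_c = as.numeric(attr(ves, "realized_c"))),
      vessel_threshold = attr(vmask, "threshold"),
      lacuna_threshold = attr(lmask, "threshold"),
      config = config,
      log = log),
    diameters = dia,
    porosity = as.list(por),
    canalicular_length_um = skel$total_length_um,
    sbr = if (!is.null(sbr)) as.numeric(sbr) else NULL,
    lamellar = if (!is.null(period))
      list(period_mean_um = period$period_mean_um,
           period_sd_um = period$period_sd_um, aperiodic = period$aperiodic)
    else NULL,
    correlations = correlations,
    bsu = if (!is.null(bsu)) list(n_bsus = bsu$n_bsus, sizes_um = bsu$sizes_um)
    else NULL,
    fluorescence = fluo,
    ground_truth = if (!is.null(truth))
      list(porosity_fractions = as.list(truth$porosity_fractions),
           total_centerline_length_um = sum(vapply(truth$centerlines,
                                                   function(cl) cl$length_um, 1)))
    else NULL),
    class = "lcn_report")
  attr(report, "objects") <- list(
    volumes = vols, deconvolved = dec, vesselness = ves, vessel_mask = vmask,
    skeleton = skel, lacuna_mask = lmask, bsu = bsu, psf = psf, truth = truth)
  report
}

#' @export
print.lcn_report <- function(x, ...) {
  cat("<lcn_report>\n")
  p <- x$provenance
  cat(sprintf("  volume: %s voxels at %s um, seed %s\n",
              paste(p$dims, collapse = " x "),
              paste(signif(p$voxel_size_um, 3), collapse = " x "), p$seed))
  if (!is.null(x$diameters) && length(x$diameters$n_measurements))
    cat(sprintf("  canalicular diameter: %.3f +/- %.3f um (n = %d two-edge)\n",
                x$diameters$diameter_mean_um, x$diameters$diameter_sd_um,
                x$diameters$n_measurements))
  if (!is.null(x$porosity$total) && !is.na(x$porosity$total))
    cat(sprintf("  porosity: lacunar %.3f%%, canalicular %.3f%%, total %.3f%%\n",
                100 * x$porosity$lacunar, 100 * x$porosity$canalicular,
                100 * x$porosity$total))
  cat(sprintf("  canalicular length: %.1f um\n", x$canalicular_length_um))
  if (!is.null(x$sbr)) cat(sprintf("  THG SBR: %.2f:1\n", x$sbr))
  if (!is.null(x$lamellar) && !isTRUE(x$lamellar$aperiodic))
    cat(sprintf("  lamellar period: %.2f +/- %.2f um\n",
                x$lamellar$period_mean_um, x$lamellar$period_sd_um))
  for (nm in names(x$correlations))
    cat(sprintf("  correlation %s: %.3f\n", nm, x$correlations[[nm]]))
  if (!is.null(x$bsu)) cat(sprintf("  BSUs: %d\n", x$bsu$n_bsus))
  if (!is.null(x$fluorescence))
    cat(sprintf("  fluorescence branch: total porosity %.3f%%, length %.1f um\n",
                100 * x$fluorescence$porosity$total,
                x$fluorescence$total_length_um))
  invisible(x)
}

#' @export
summary.lcn_report <- function(object, ...) {
  print(object)
  cat("  stage log:\n")
  for (l in object$provenance$log) cat("   ", l, "\n")
  invisible(object)
}
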