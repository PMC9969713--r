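## Declarative configuration and the end-to-end reconstruction pipeline:
## backproject -> register/colorize -> PassThrough -> statistical filter
## -> PSC transform -> fuse -> traits, with artifacts written per stage.

#' Pipeline configuration
#'
#' Aggregates every tunable of the reconstruction pipeline: per-camera
#' depth and color intrinsics, depth-to-color extrinsics, ROI bounds,
#' statistical-filter parameters, rig geometry, the valid depth range, the
#' colorless-point policy and the RNG seed used by synthetic captures.
#'
#' @slot intrDepth,intrColor lists of two \code{\link{CameraIntrinsics}}.
#' @slot depthToColor list of two \code{\link{RigidTransform}}s mapping
#'   each depth camera's frame into its color camera's frame.
#' @slot roi \code{\link{ROIBounds}}.
#' @slot statParams \code{\link{StatFilterParams}}.
#' @slot statTails \code{"two-sided"} or \code{"upper"}.
#' @slot rig \code{\link{RigGeometry}}.
#' @slot depthRange valid depth interval, mm.
#' @slot dropColorless drop points without a valid color.
#' @slot seed RNG seed for synthetic captures.
#' @slot outputDir artifact directory ("" disables artifacts).
#' @export
setClass("PipelineConfig",
  representation(intrDepth = "list", intrColor = "list",
                 depthToColor = "list", roi = "ROIBounds",
                 statParams = "StatFilterParams", statTails = "character",
                 rig = "RigGeometry", depthRange = "numeric",
                 dropColorless = "logical", seed = "integer",
                 outputDir = "character"))

setValidity("PipelineConfig", function(object) {
  for (s in c("intrDepth", "intrColor")) {
    l <- slot(object, s)
    if (length(l) != 2L || !all(vapply(l, is, TRUE, "CameraIntrinsics")))
      return(sprintf("%s must hold two CameraIntrinsics", s))
  }
  if (length(object@depthToColor) != 2L ||
      !all(vapply(object@depthToColor, is, TRUE, "RigidTransform")))
    return("depthToColor must hold two RigidTransforms")
  if (!object@statTails %in% c("two-sided", "upper"))
    return("statTails must be 'two-sided' or 'upper'")
  if (length(object@depthRange) != 2L ||
      object@depthRange[1L] >= object@depthRange[2L])
    return("depthRange must be (min, max) with min < max")
  TRUE
})

#' @rdname PipelineConfig-class
#' @param intrDepth,intrColor,depthToColor,roi,statParams,statTails,rig,depthRange,dropColorless,seed,outputDir
#'   see slots. Defaults describe the synthetic rig: identical depth/color
#'   cameras and identity extrinsics (the renderer emits aligned rasters).
#' @export
PipelineConfig <- function(intrDepth = list(defaultDepthIntrinsics(),
                                            defaultDepthIntrinsics()),
                           intrColor = intrDepth,
                           depthToColor = list(RigidTransform(),
                                               RigidTransform()),
                           roi = ROIBounds(),
                           statParams = StatFilterParams(),
                           statTails = "two-sided",
                           rig = RigGeometry(),
                           depthRange = c(500, 4000),
                           dropColorless = FALSE, seed = 1L,
                           outputDir = "") {
  new("PipelineConfig", intrDepth = intrDepth, intrColor = intrColor,
      depthToColor = depthToColor, roi = roi, statParams = statParams,
      statTails = statTails, rig = rig,
      depthRange = as.numeric(depthRange),
      dropColorless = as.logical(dropColorless), seed = as.integer(seed),
      outputDir = as.character(outputDir))
}

.intrFromList <- function(x, where) {
  need <- c("fx", "fy", "cx", "cy", "width", "height")
  miss <- setdiff(need, names(x))
  if (length(miss))
    configurationError(sprintf("%s is missing %s", where,
                               paste(miss, collapse = ", ")))
  unknown <- setdiff(names(x), need)
  if (length(unknown))
    configurationError(sprintf("unknown key(s) in %s: %s", where,
                               paste(unknown, collapse = ", ")))
  do.call(CameraIntrinsics, x)
}

.xfFromList <- function(x, where) {
  if (is.null(x)) return(RigidTransform())
  unknown <- setdiff(names(x), c("rotation", "translation"))
  if (length(unknown))
    configurationError(sprintf("unknown key(s) in %s: %s", where,
                               paste(unknown, collapse = ", ")))
  R <- if (is.null(x$rotation)) diag(3)
       else matrix(as.numeric(unlist(x$rotation)), 3L, 3L, byrow = TRUE)
  t_ <- if (is.null(x$translation)) c(0, 0, 0) else as.numeric(x$translation)
  tryCatch(RigidTransform(R, t_), error = function(e)
    configurationError(sprintf("%s: %s", where, conditionMessage(e))))
}

#' Read a pipeline configuration from YAML
#'
#' Parses and validates a declarative YAML configuration. Every nested
#' object's invariants are checked on load and unknown keys are rejected,
#' so a typo fails before any computation.
#'
#' @param path YAML file.
#' @return a \code{\link{PipelineConfig}}.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) configurationError(paste("no such file:", path))
  y <- yaml::read_yaml(path)
  known <- c("cameras", "roi", "filter", "rig", "depth_range",
             "drop_colorless", "seed", "output_dir")
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    configurationError(paste("unknown config key(s):",
                             paste(unknown, collapse = ", ")))
  args <- list()
  if (!is.null(y$cameras)) {
    if (length(y$cameras) != 2L)
      configurationError("cameras must list exactly two cameras")
    args$intrDepth <- lapply(seq_len(2L), function(i)
      .intrFromList(y$cameras[[i]]$intrinsics_depth,
                    sprintf("cameras[%d]$intrinsics_depth", i)))
    args$intrColor <- lapply(seq_len(2L), function(i) {
      ic <- y$cameras[[i]]$intrinsics_color
      if (is.null(ic)) args$intrDepth[[i]]
      else .intrFromList(ic, sprintf("cameras[%d]$intrinsics_color", i))
    })
    args$depthToColor <- lapply(seq_len(2L), function(i)
      .xfFromList(y$cameras[[i]]$extrinsics,
                  sprintf("cameras[%d]$extrinsics", i)))
    for (i in seq_len(2L)) {
      unknown <- setdiff(names(y$cameras[[i]]),
                         c("intrinsics_depth", "intrinsics_color",
                           "extrinsics"))
      if (length(unknown))
        configurationError(sprintf("unknown key(s) in cameras[%d]: %s", i,
                                   paste(unknown, collapse = ", ")))
    }
  }
  if (!is.null(y$roi)) {
    need <- c("x_min", "x_max", "y_min", "y_max", "z_min", "z_max")
    unknown <- setdiff(names(y$roi), need)
    if (length(unknown))
      configurationError(paste("unknown key(s) in roi:",
                               paste(unknown, collapse = ", ")))
    v <- lapply(need, function(k) y$roi[[k]])
    if (any(vapply(v, is.null, TRUE)))
      configurationError("roi must give all six bounds")
    args$roi <- tryCatch(do.call(ROIBounds, setNames(v,
      c("xMin", "xMax", "yMin", "yMax", "zMin", "zMax"))),
      error = function(e) configurationError(
        paste("roi:", conditionMessage(e))))
  }
  if (!is.null(y$filter)) {
    unknown <- setdiff(names(y$filter), c("m", "k", "tails"))
    if (length(unknown))
      configurationError(paste("unknown key(s) in filter:",
                               paste(unknown, collapse = ", ")))
    args$statParams <- StatFilterParams(
      m = if (is.null(y$filter$m)) 35 else y$filter$m,
      k = if (is.null(y$filter$k)) 1.0 else y$filter$k)
    if (!is.null(y$filter$tails)) args$statTails <- y$filter$tails
  }
  if (!is.null(y$rig)) {
    unknown <- setdiff(names(y$rig), c("baseline_mm", "translation_sign"))
    if (length(unknown))
      configurationError(paste("unknown key(s) in rig:",
                               paste(unknown, collapse = ", ")))
    args$rig <- RigGeometry(
      baseline = if (is.null(y$rig$baseline_mm)) 1400 else y$rig$baseline_mm,
      translationSign = if (is.null(y$rig$translation_sign)) 1
                        else y$rig$translation_sign)
  }
  if (!is.null(y$depth_range)) args$depthRange <- as.numeric(y$depth_range)
  if (!is.null(y$drop_colorless)) args$dropColorless <- y$drop_colorless
  if (!is.null(y$seed)) args$seed <- y$seed
  if (!is.null(y$output_dir)) args$outputDir <- y$output_dir
  cfg <- tryCatch(do.call(PipelineConfig, args), error = function(e)
    configurationError(conditionMessage(e)))
  validObject(cfg)
  cfg
}

## run one stage, prefixing errors with the stage name (class preserved)
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    e$message <- sprintf("[stage %s] %s", name, conditionMessage(e))
    stop(e)
  })
}

#' Run the full dual-view reconstruction pipeline
#'
#' Executes, for each of the two views: depth back-projection,
#' registration into the color camera frame, colorization, PassThrough
#' ROI cropping and statistical outlier removal; then maps the secondary
#' view into the reference frame with the PSC transform, splices the two
#' clouds and extracts the trait set. Per-stage filter reports are
#' logged via \code{message()} and, when \code{outputDir} is set,
#' intermediate clouds (raw, filtered, fused) and a traits JSON are
#' written to disk.
#'
#' @param config a \code{\link{PipelineConfig}} or path to its YAML file.
#' @param depth1,depth2 \code{\link{DepthImage}}s or paths to 16-bit
#'   depth PNGs for camera 1 and 2.
#' @param color1,color2 H x W x 3 RGB arrays or paths to 8-bit color
#'   PNGs; \code{NULL} skips colorization for that view.
#' @param quiet suppress per-stage messages.
#' @return a list with \code{model} (the \code{\link{FusedModel}}),
#'   \code{traits} (the \code{\link{TraitSet}}) and \code{reports} (the
#'   per-view \code{\link{FilterReport}}s).
#' @export
runPipeline <- function(config, depth1, color1 = NULL, depth2,
                        color2 = NULL, quiet = FALSE) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(is(config, "PipelineConfig"))
  validObject(config)
  say <- function(...) if (!quiet) message(sprintf(...))

  processView <- function(i, depth, color) {
    if (is.character(depth))
      depth <- .stage(sprintf("read_depth[%d]", i), readDepthPNG(depth))
    if (is.character(color))
      color <- .stage(sprintf("read_color[%d]", i), readColorPNG(color))
    cloud <- .stage(sprintf("backproject[%d]", i),
                    backprojectDepth(depth, config@intrDepth[[i]],
                                     config@depthRange))
    cloud <- .stage(sprintf("register[%d]", i),
                    applyRigidTransform(cloud, config@depthToColor[[i]]))
    if (!is.null(color))
      cloud <- .stage(sprintf("colorize[%d]", i),
                      colorizeCloud(cloud, color, config@intrColor[[i]],
                                    config@dropColorless))
    pt <- .stage(sprintf("passthrough[%d]", i),
                 passthroughFilter(cloud, config@roi))
    say("view %d passthrough: %d -> %d points", i, pt$report@nBefore,
        pt$report@nAfter)
    st <- .stage(sprintf("statistical_filter[%d]", i),
                 statisticalFilter(pt$cloud, config@statParams,
                                   config@statTails))
    say("view %d statistical: %d -> %d points (mu %.2f, sigma %.2f mm)",
        i, st$report@nBefore, st$report@nAfter, st$report@mu,
        st$report@sigma)
    list(raw = cloud, filtered = st$cloud,
         reports = list(passthrough = pt$report, statistical = st$report))
  }

  v1 <- processView(1L, depth1, color1)
  v2 <- processView(2L, depth2, color2)
  v2t <- .stage("psc_transform",
                transformSecondaryCloud(v2$filtered, config@rig))
  model <- .stage("fuse", fuseClouds(v1$filtered, v2t))
  traits <- .stage("traits", computeTraits(model))
  say("fused model: %d points; traits H %.1f W %.1f L %.1f mm, V %.2f cm^3",
      nPoints(model), traits@height, traits@width, traits@length,
      traits@volume)

  if (nzchar(config@outputDir)) {
    dir.create(config@outputDir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config@outputDir, f)
    writePointCloud(v1$raw, out("view1_raw.ply"))
    writePointCloud(v2$raw, out("view2_raw.ply"))
    writePointCloud(v1$filtered, out("view1_filtered.ply"))
    writePointCloud(v2$filtered, out("view2_filtered.ply"))
    writePointCloud(model@cloud, out("fused.ply"))
    jsonlite::write_json(list(
      height_mm = traits@height, width_mm = traits@width,
      length_mm = traits@length, volume_cm3 = traits@volume,
      n_points = nPoints(model)), out("traits.json"),
      auto_unbox = TRUE, digits = NA)
  }
  list(model = model, traits = traits,
       reports = list(view1 = v1$reports, view2 = v2$reports))
}
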