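## Synthetic turntable comparison of the two modeling routes: three views
## 120 degrees apart registered by ICP versus two opposed views fused by
## the closed-form PSC transform.

## render one turntable view and run the per-view part of the pipeline
.captureView <- function(scene, azimuth, rig, intr, noise, noiseSeedOffset,
                         roi, statParams, maxIncidenceDeg) {
  pose <- turntablePose(azimuth, standoff = rig@baseline / 2)
  r <- renderDepthView(scene, pose, intr, maxIncidenceDeg)
  depth <- r$depth
  if (!is.null(noise)) {
    n <- noise
    n@seed <- noise@seed + as.integer(noiseSeedOffset)
    depth <- corruptDepth(depth, n)
  }
  cloud <- backprojectDepth(depth, intr)
  cloud <- passthroughFilter(cloud, roi)$cloud
  if (!is.null(statParams) && nPoints(cloud) > statParams@m)
    cloud <- statisticalFilter(cloud, statParams)$cloud
  list(cloud = cloud, pose = pose)
}

#' Compare PSC fusion with the ICP baseline on synthetic turntable scenes
#'
#' For each seed, generates a procedural plant scene and builds two
#' models: a three-view model from azimuths 120 degrees apart, registered
#' pairwise onto the first view by point-to-point ICP initialised at the
#' nominal turntable pose and refined from there, and a two-view PSC model
#' from the opposed pair fused by the closed-form mirror transform. Each
#' model's synthetic accuracy is scored against the generator's ground
#' truth. Wall-clock modeling times are recorded informationally only --
#' they are hardware-bound and never part of any accuracy contract.
#'
#' When a noise spec is supplied, each rendered view is corrupted with an
#' independent noise stream and the per-view statistical filter is applied
#' (as in the full pipeline); noise-free runs skip the statistical filter
#' so that the comparison isolates the registration step.
#'
#' @param seeds integer seeds, one synthetic scene (one group) per seed.
#' @param spec template \code{\link{PlantSpec}}; its seed is replaced by
#'   each group's seed.
#' @param rig a \code{\link{RigGeometry}}.
#' @param intr depth-camera \code{\link{CameraIntrinsics}}.
#' @param noise optional \code{\link{NoiseSpec}}.
#' @param roi \code{\link{ROIBounds}} applied per view.
#' @param statParams \code{\link{StatFilterParams}} used when noise is
#'   present.
#' @param icpAzimuths the three ICP view azimuths, degrees.
#' @param maxIncidenceDeg rendering incidence cutoff (see
#'   \code{\link{renderDepthView}}).
#' @param icpConfig base \code{\link{ICPConfig}}; its \code{init} is
#'   replaced per pair by the nominal turntable transform.
#' @return a data frame with one row per group: \code{group},
#'   \code{acc_icp}, \code{acc_psc} (percent), \code{time_icp_s},
#'   \code{time_psc_s} (informational seconds).
#' @export
comparePscIcp <- function(seeds = 1:3, spec = PlantSpec(),
                          rig = RigGeometry(),
                          intr = defaultDepthIntrinsics(), noise = NULL,
                          roi = ROIBounds(),
                          statParams = StatFilterParams(),
                          icpAzimuths = c(0, 120, 240),
                          maxIncidenceDeg = 90,
                          icpConfig = ICPConfig()) {
  if (length(seeds) == 0L) configurationError("need at least one seed")
  if (length(icpAzimuths) != 3L)
    configurationError("icpAzimuths must name three views")
  sp <- if (!is.null(noise)) statParams else NULL
  rows <- lapply(seq_along(seeds), function(g) {
    spec@seed <- as.integer(seeds[g])
    scene <- generatePlant(spec)
    truth <- scene@traits

    ## --- ICP route: three views at 120-degree intervals ----------------
    views <- lapply(seq_along(icpAzimuths), function(j)
      .captureView(scene, icpAzimuths[j], rig, intr, noise,
                   10L * g + j, roi, sp, maxIncidenceDeg))
    tIcp <- system.time({
      ref <- views[[1L]]$cloud
      merged <- ref@coords
      for (j in 2:3) {
        cfg <- icpConfig
        cfg@init <- invertRigidTransform(views[[j]]$pose)
        res <- icpRegister(views[[j]]$cloud, ref, cfg)
        merged <- rbind(merged,
                        applyRigidTransform(views[[j]]$cloud,
                                            res@transform)@coords)
      }
      accIcp <- syntheticAccuracy(truth, computeTraits(PointCloud(merged)))
    })[["elapsed"]]

    ## --- PSC route: the opposed pair fused in closed form --------------
    v1 <- .captureView(scene, 0, rig, intr, noise, 10L * g + 4L, roi, sp,
                       maxIncidenceDeg)
    v2 <- .captureView(scene, 180, rig, intr, noise, 10L * g + 5L, roi, sp,
                       maxIncidenceDeg)
    tPsc <- system.time({
      fused <- fuseClouds(v1$cloud, transformSecondaryCloud(v2$cloud, rig))
      accPsc <- syntheticAccuracy(truth, computeTraits(fused))
    })[["elapsed"]]

    data.frame(group = g, acc_icp = accIcp, acc_psc = accPsc,
               time_icp_s = tIcp, time_psc_s = tPsc)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
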