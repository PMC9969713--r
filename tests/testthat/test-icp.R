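test_that("correspondences match an exhaustive nearest-neighbour scan", {
  pc <- randomCloud(60, seed = 2)
  self <- nearestCorrespondences(pc, pc, maxDist = 50)
  expect_equal(self$source, 1:60)
  expect_equal(self$target, 1:60)
  expect_equal(self$distance, rep(0, 60))

  far <- applyRigidTransform(pc, RigidTransform(diag(3), c(1e4, 0, 0)))
  expect_error(nearestCorrespondences(pc, far, maxDist = 50),
               class = "noOverlapError")

  src <- randomCloud(40, seed = 5)
  tgt <- randomCloud(50, seed = 6)
  got <- nearestCorrespondences(src, tgt, maxDist = 1e6)
  D <- as.matrix(dist(rbind(pointCoords(src), pointCoords(tgt))))
  D <- D[1:40, 41:90]
  expect_equal(got$target, unname(apply(D, 1, which.min)))
  expect_equal(got$distance, unname(apply(D, 1, min)), tolerance = 1e-9)
})

test_that("SVD estimation recovers rigid motions and guards reflections", {
  pts <- pointCoords(randomCloud(30, seed = 9))
  id <- estimateRigidTransformSVD(pts, pts)
  expect_lt(max(abs(id@rotation - diag(3))), 1e-9)
  expect_lt(max(abs(id@translation)), 1e-9)

  xf <- randomRigid(4)
  moved <- sweep(pts %*% t(xf@rotation), 2, xf@translation, "+")
  rec <- estimateRigidTransformSVD(pts, moved)
  expect_lt(max(abs(rec@rotation - xf@rotation)), 1e-6)
  expect_lt(max(abs(rec@translation - xf@translation)), 1e-6)

  # mirror-image correspondences still yield a proper rotation
  mirrored <- pts %*% diag(c(-1, 1, 1))
  guard <- estimateRigidTransformSVD(pts, mirrored)
  expect_equal(det(guard@rotation), 1, tolerance = 1e-9)

  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(estimateRigidTransformSVD(line, line),
               class = "degenerateInputError")
  expect_error(estimateRigidTransformSVD(pts[1:2, ], pts[1:2, ]),
               class = "degenerateInputError")
})

test_that("ICP converges immediately on identical clouds", {
  pc <- randomCloud(200, seed = 12)
  res <- icpRegister(pc, pc)
  expect_true(res@converged)
  expect_lte(res@iterations, 2L)
  expect_lt(max(abs(res@transform@rotation - diag(3))), 1e-9)
  expect_lt(utils::tail(res@mseTrace, 1), 1e-12)
})

test_that("ICP recovers a small known motion to sub-mm accuracy", {
  pc <- randomCloud(400, seed = 15, lo = -150, hi = 150)
  xf <- RigidTransform(axisAngle(c(0, 1, 0), 2), c(5, 0, 0))  # 5 mm, 2 deg
  target <- applyRigidTransform(pc, xf)
  res <- icpRegister(pc, target, ICPConfig(maxCorrespondenceDistance = 100))
  relR <- res@transform@rotation %*% t(xf@rotation)
  expect_lt(rotationAngleDeg(relR), 0.1)
  expect_lt(sqrt(sum((res@transform@translation - xf@translation)^2)), 0.5)
})

test_that("ICP error is monotone non-increasing across iterations", {
  for (s in 1:20) {
    pc <- randomCloud(150, seed = s, lo = -100, hi = 100)
    xf <- RigidTransform(axisAngle(c(1, 1, 0), 3), c(4, -3, 6))
    res <- icpRegister(pc, applyRigidTransform(pc, xf),
                       ICPConfig(maxCorrespondenceDistance = 80))
    expect_true(all(diff(res@mseTrace) <= 1e-9))
  }
})

test_that("ICP recovers motions from partially overlapping clouds", {
  # 20 seeded trials on plant-surface clouds whose source and target crops
  # share well over 30% of their points
  rotErr <- transErr <- numeric(20)
  for (s in 1:20) {
    P <- generatePlant(smallPlantSpec(seed = 100 + s, nPoints = 15000,
                                      potPoints = 100))@points
    src <- PointCloud(P[P[, 1] <= 50, ])
    xf <- RigidTransform(axisAngle(c(0, 0, 1), 2), c(3, 4, -2))
    tgt <- PointCloud(sweep(P[P[, 1] >= -50, ] %*% t(xf@rotation), 2,
                            xf@translation, "+"))
    res <- icpRegister(src, tgt, ICPConfig(maxCorrespondenceDistance = 10,
                                           maxIterations = 80))
    rotErr[s] <- rotationAngleDeg(res@transform@rotation %*% t(xf@rotation))
    transErr[s] <- sqrt(sum((res@transform@translation -
                               xf@translation)^2))
  }
  expect_lt(stats::median(rotErr), 0.5)
  expect_lt(stats::median(transErr), 2)
})

test_that("turntable comparison scores both routes against ground truth", {
  tab <- comparePscIcp(seeds = 1:2, spec = smallPlantSpec(nPoints = 20000,
                                                          potPoints = 2000))
  expect_equal(nrow(tab), 2L)                 # one group per requested seed
  expect_true(all(c("acc_icp", "acc_psc", "time_icp_s",
                    "time_psc_s") %in% names(tab)))
  expect_true(all(tab$acc_icp > 95))
  expect_true(all(tab$acc_psc > 95))
})

test_that("PSC fuses opposed views where ICP has no correspondences", {
  # a thin leafless stem rendered with a grazing-incidence cutoff: the two
  # opposed cameras see disjoint front/back arcs separated by more than
  # the correspondence gate, so ICP is powerless while the closed-form
  # fusion still assembles the full cylinder
  sc <- generatePlant(PlantSpec(seed = 2, leafCount = 0, nPoints = 20000,
                                potPoints = 2000))
  cap <- simulateDualCapture(sc, maxIncidenceDeg = 60)
  intr <- defaultDepthIntrinsics()
  v1 <- passthroughFilter(backprojectDepth(cap$view1$depth, intr))$cloud
  v2 <- passthroughFilter(backprojectDepth(cap$view2$depth, intr))$cloud
  v2t <- transformSecondaryCloud(v2)
  expect_error(icpRegister(v1, v2t,
                           ICPConfig(maxCorrespondenceDistance = 3)),
               class = "noOverlapError")
  fused <- fuseClouds(v1, v2t)
  expect_equal(nPoints(fused), nPoints(v1) + nPoints(v2))
  acc <- syntheticAccuracy(sc@traits, computeTraits(fused))
  expect_gt(acc, 95)
})
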