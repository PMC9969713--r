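test_that("plant generation is deterministic and exact in counts", {
  a <- generatePlant(smallPlantSpec(seed = 42))
  b <- generatePlant(smallPlantSpec(seed = 42))
  expect_identical(a@points, b@points)
  expect_identical(a@clutter, b@clutter)
  expect_equal(nrow(a@points), 4000L)          # exactly the requested N

  c_ <- generatePlant(smallPlantSpec(seed = 43))
  expect_false(identical(a@points, c_@points))

  # ground-truth traits are exactly the bounding box of the plant points
  expect_equal(traitValues(a@traits),
               traitValues(computeTraits(PointCloud(a@points))))

  expect_error(PlantSpec(stemHeight = -1), "positive")
})

test_that("a leafless spec degenerates to the stem cylinder", {
  sc <- generatePlant(PlantSpec(seed = 5, leafCount = 0, nPoints = 5000,
                                stemHeight = 250, stemRadius = 5,
                                potPoints = 100))
  expect_true(all(sc@surface == "stem"))
  tv <- traitValues(sc@traits)
  expect_equal(unname(tv["height"]), 250, tolerance = 0.01)
  expect_equal(unname(tv["width"]), 10, tolerance = 0.01)   # diameter
  expect_equal(unname(tv["length"]), 10, tolerance = 0.01)
})

test_that("depth rendering z-buffers nearest points per pixel", {
  intr <- tinyIntrinsics()
  mkScene <- function(pts) {
    n <- nrow(pts)
    new("SceneTruth", points = pts, surface = rep("leaf", n),
        normals = matrix(rep(c(0, 0, -1), each = n), n),
        twoSided = rep(TRUE, n), clutter = matrix(numeric(), 0, 3),
        clutterNormals = matrix(numeric(), 0, 3), poses = list(),
        traits = computeTraits(pts))
  }
  one <- renderDepthView(mkScene(rbind(c(0, 0, 700))), RigidTransform(),
                         intr)
  expect_equal(sum(one$depth@data > 0), 1L)
  expect_equal(one$depth@data[intr@cy, intr@cx], 700)

  both <- renderDepthView(mkScene(rbind(c(0, 0, 600), c(0, 0, 800))),
                          RigidTransform(), intr)
  expect_equal(both$depth@data[intr@cy, intr@cx], 600)

  # full rendered raster vs an exhaustive project-then-min scan
  withr::with_seed(12, pts <- cbind(runif(400, -25, 25),
                                    runif(400, -20, 20),
                                    runif(400, 500, 1200)))
  r <- renderDepthView(mkScene(pts), RigidTransform(), intr)
  oracle <- matrix(0, 8, 8)
  for (i in seq_len(400)) {
    u <- round(intr@cx + intr@fx * pts[i, 1] / pts[i, 3])
    v <- round(intr@cy - intr@fy * pts[i, 2] / pts[i, 3])
    if (u >= 1 && u <= 8 && v >= 1 && v <= 8 &&
        (oracle[v, u] == 0 || pts[i, 3] < oracle[v, u]))
      oracle[v, u] <- pts[i, 3]
  }
  expect_equal(r$depth@data, round(oracle))
})

test_that("depth corruption follows the stated noise law", {
  d <- DepthImage(matrix(c(0, 700, 800, 0), 2, 2))
  # no noise terms: output identical to input
  silent <- NoiseSpec(baseSd = 0, outlierFraction = 0, backgroundFill = 0)
  expect_identical(corruptDepth(d, silent)@data, d@data)
  # determinism under a fixed seed
  ns <- NoiseSpec(seed = 99)
  expect_identical(corruptDepth(d, ns)@data, corruptDepth(d, ns)@data)

  # Monte-Carlo: empirical sd at the image centre approaches the base sd
  # (depths are quantised to mm, adding 1/12 mm^2 of variance)
  base <- 5
  img <- DepthImage(matrix(c(0, 0, 0, 0, 700, 0, 0, 0, 0), 3, 3))
  draws <- vapply(1:4000, function(i) {
    corruptDepth(img, NoiseSpec(baseSd = base, edgeMultiplier = 2,
                                outlierFraction = 0, backgroundFill = 0,
                                seed = i))@data[2, 2]
  }, numeric(1))
  expect_lt(abs(sd(draws - 700) - sqrt(base^2 + 1 / 12)) /
              base, 0.05)

  # edge pixels are noisier than the centre under the radial law
  wide <- DepthImage(matrix(700, 21, 21))
  spread <- vapply(1:300, function(i) {
    cd <- corruptDepth(wide, NoiseSpec(baseSd = 3, edgeMultiplier = 3,
                                       outlierFraction = 0,
                                       backgroundFill = 0, seed = i))@data
    c(centre = cd[11, 11], corner = cd[1, 1])
  }, numeric(2))
  expect_gt(sd(spread["corner", ]), sd(spread["centre", ]))
})

test_that("dual capture is symmetric in the two cameras", {
  sc <- generatePlant(smallPlantSpec(seed = 3, nPoints = 10000))
  cap <- simulateDualCapture(sc)
  intr <- defaultDepthIntrinsics()
  rig <- RigGeometry()
  c1 <- passthroughFilter(backprojectDepth(cap$view1$depth, intr))$cloud
  c2 <- passthroughFilter(backprojectDepth(cap$view2$depth, intr))$cloud
  t12 <- computeTraits(fuseClouds(c1, transformSecondaryCloud(c2, rig)))
  t21 <- computeTraits(fuseClouds(c2, transformSecondaryCloud(c1, rig)))
  # the fusion map is an involution, so the swapped model is the same
  # point set expressed in the other frame: extents match exactly
  expect_equal(traitValues(t21), traitValues(t12), tolerance = 1e-9)

  # camera poses are recorded and consistent with the fusion transform
  expect_equal(cap$scene@poses$camera2@rotation, diag(c(-1, 1, -1)))

  # scenes outside both frusta refuse to render
  far <- sc
  far@points[, 1] <- far@points[, 1] + 1e5
  far@clutter[, 1] <- far@clutter[, 1] + 1e5
  expect_error(simulateDualCapture(far), class = "emptyRenderError")
})

test_that("renders are byte-stable under a fixed seed", {
  sc <- generatePlant(smallPlantSpec(seed = 8))
  n <- NoiseSpec(seed = 4)
  a <- simulateDualCapture(sc, noise = n)
  b <- simulateDualCapture(generatePlant(smallPlantSpec(seed = 8)),
                           noise = n)
  expect_identical(a$view1$depth@data, b$view1$depth@data)
  expect_identical(a$view2$depth@data, b$view2$depth@data)
  # the two views use distinct noise streams
  expect_false(identical(a$view1$depth@data, a$view2$depth@data))
})
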