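test_that("back-projection follows the inverse pinhole model", {
  intr <- tinyIntrinsics()
  d <- matrix(0, 8, 8)
  d[3, 4] <- 1000                      # the principal pixel (cy, cx)
  pc <- backprojectDepth(DepthImage(d), intr)
  expect_equal(nPoints(pc), 1L)
  expect_equal(unname(pointCoords(pc)[1, ]), c(0, 0, 1000))

  # zero depth is the invalid sentinel; out-of-range depths are dropped
  d[5, 5] <- 0
  d[2, 2] <- 10        # below default 500 mm
  d[6, 6] <- 9999      # above default 4000 mm
  pc <- backprojectDepth(DepthImage(d), intr)
  expect_equal(nPoints(pc), 1L)

  # point count equals the count of in-range pixels
  withr::with_seed(4, dd <- matrix(sample(c(0, 100, 700, 5000), 64, TRUE), 8))
  pc2 <- backprojectDepth(DepthImage(dd), intr)
  expect_equal(nPoints(pc2), sum(dd >= 500 & dd <= 4000))
})

test_that("back-projection matches an exhaustive per-pixel scalar oracle", {
  intr <- tinyIntrinsics(fx = 120, fy = 90, cx = 3.5, cy = 4.5)
  withr::with_seed(11, d <- matrix(runif(64, 600, 900), 8, 8))
  d <- round(d)
  pc <- backprojectDepth(DepthImage(d), intr)
  # independent scalar loop over every pixel
  oracle <- NULL
  for (v in 1:8) for (u in 1:8) {
    dep <- d[v, u]
    oracle <- rbind(oracle, c((u - intr@cx) * dep / intr@fx,
                              -(v - intr@cy) * dep / intr@fy, dep))
  }
  got <- pointCoords(pc)
  key <- function(m) m[order(m[, 3], m[, 1], m[, 2]), ]
  expect_equal(unname(key(got)), unname(key(oracle)), tolerance = 1e-12)
  expect_equal(nPoints(pc), 64L)
})

test_that("back-projection validates its inputs", {
  expect_error(backprojectDepth(DepthImage(matrix(0, 4, 4)),
                                tinyIntrinsics()),
               class = "configurationError")
  expect_error(backprojectDepth(DepthImage(matrix(0, 8, 8)),
                                tinyIntrinsics(), depthRange = c(5, 5)),
               class = "configurationError")
  # empty valid set is an empty cloud, not an error
  expect_equal(nPoints(backprojectDepth(DepthImage(matrix(0, 8, 8)),
                                        tinyIntrinsics())), 0L)
})

test_that("rigid transforms move points exactly and keep attributes", {
  pc <- randomCloud(100, seed = 2, colored = TRUE)
  expect_equal(pointCoords(applyRigidTransform(pc, RigidTransform())),
               pointCoords(pc))
  up <- applyRigidTransform(PointCloud(rbind(c(0, 0, 700))),
                            RigidTransform(diag(3), c(0, 0, 100)))
  expect_equal(unname(pointCoords(up)[1, ]), c(0, 0, 800))

  xf <- randomRigid(7)
  moved <- applyRigidTransform(pc, xf)
  # brute-force per-point matrix-vector oracle
  for (i in c(1, 17, 58, 100)) {
    expect_equal(unname(pointCoords(moved)[i, ]),
                 as.vector(xf@rotation %*% pointCoords(pc)[i, ] +
                             xf@translation),
                 tolerance = 1e-9)
  }
  expect_identical(pointColors(moved), pointColors(pc))

  # invariants: distances preserved; inverse restores the cloud
  d0 <- dist(pointCoords(pc)[1:30, ])
  d1 <- dist(pointCoords(moved)[1:30, ])
  expect_lt(max(abs(d0 - d1)), 1e-6)
  back <- applyRigidTransform(moved, invertRigidTransform(xf))
  expect_lt(max(abs(pointCoords(back) - pointCoords(pc))), 1e-6)
})

test_that("improper rotations are rejected", {
  expect_error(RigidTransform(matrix(as.numeric(1:9), 3)), "orthonormal")
  expect_error(RigidTransform(diag(c(1, 1, -1))), "determinant")
  expect_error(applyRigidTransform(randomCloud(5), diag(3)),
               class = "validationError")
})

test_that("projection inverts back-projection on pixel indices", {
  intr <- tinyIntrinsics()
  pc <- PointCloud(rbind(c(0, 0, 1000), c(10, -20, -50)))
  px <- projectPointsToPixels(pc, intr)
  expect_equal(unname(px[1, ]), c(intr@cy, intr@cx))
  expect_true(all(is.na(px[2, ])))          # behind the camera

  withr::with_seed(3, d <- matrix(round(runif(64, 550, 3000)), 8, 8))
  cloud <- backprojectDepth(DepthImage(d), intr)
  rt <- projectPointsToPixels(cloud, intr)
  expect_equal(unname(rt), unname(pixelOrigins(cloud)))
})

test_that("colorization picks the nearest pixel and flags out-of-frame", {
  intr <- tinyIntrinsics()
  red <- array(0L, c(8, 8, 3)); red[, , 1] <- 255L
  pc <- PointCloud(rbind(c(0, 0, 700), c(5000, 0, 700)))
  cc <- colorizeCloud(pc, red, intr)
  expect_equal(unname(pointColors(cc)[1, ]), c(255L, 0L, 0L))
  expect_true(colorFlags(cc)[1])
  expect_false(colorFlags(cc)[2])           # retained but color-invalid
  expect_equal(nPoints(cc), 2L)
  expect_equal(nPoints(colorizeCloud(pc, red, intr, dropColorless = TRUE)),
               1L)

  # checkerboard raster vs exhaustive nearest-pixel scan
  board <- array(0L, c(8, 8, 3))
  for (v in 1:8) for (u in 1:8) board[v, u, ] <- ((v + u) %% 2L) * 255L
  withr::with_seed(5, grid <- cbind(runif(60, -20, 20), runif(60, -15, 15),
                                    runif(60, 600, 800)))
  gc_ <- colorizeCloud(PointCloud(grid), board, intr)
  for (i in seq_len(60)) {
    best <- c(NA, NA); bestD <- Inf
    for (v in 1:8) for (u in 1:8) {
      uu <- intr@cx + intr@fx * grid[i, 1] / grid[i, 3]
      vv <- intr@cy - intr@fy * grid[i, 2] / grid[i, 3]
      dd <- (uu - u)^2 + (vv - v)^2
      if (dd < bestD) { bestD <- dd; best <- c(v, u) }
    }
    if (colorFlags(gc_)[i])
      expect_equal(unname(pointColors(gc_)[i, ]),
                   unname(board[best[1], best[2], ]))
  }
  expect_error(colorizeCloud(pc, board[1:4, , ], intr),
               class = "configurationError")
})
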