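# Shared fixture builders. Everything is generated in code; oracles used in
# tests stay brute-force and independent of the implementation paths they
# check.

# a small camera for hand-checkable projections (integer principal point)
tinyIntrinsics <- function(fx = 100, fy = 100, cx = 4, cy = 3,
                           width = 8, height = 8) {
  CameraIntrinsics(fx, fy, cx, cy, width, height)
}

randomCloud <- function(n, seed = 1, lo = -300, hi = 300, colored = FALSE) {
  withr::with_seed(seed, {
    pc <- matrix(runif(3 * n, lo, hi), ncol = 3)
    cols <- if (colored) matrix(sample(0:255, 3 * n, TRUE), ncol = 3)
  })
  PointCloud(pc, colors = cols)
}

# random proper rotation via QR of a Gaussian matrix
randomRotation <- function(seed = 1) {
  withr::with_seed(seed, A <- matrix(rnorm(9), 3))
  qr_ <- qr(A)
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

randomRigid <- function(seed = 1, tScale = 100) {
  withr::with_seed(seed + 1000, t_ <- runif(3, -tScale, tScale))
  RigidTransform(randomRotation(seed), t_)
}

# a light plant spec for tests that only need plumbing, not fidelity
smallPlantSpec <- function(seed = 1, nPoints = 4000, potPoints = 600, ...) {
  PlantSpec(seed = seed, nPoints = nPoints, potPoints = potPoints, ...)
}

# angle of a rotation matrix, degrees
rotationAngleDeg <- function(R) {
  acos(pmin(pmax((sum(diag(R)) - 1) / 2, -1), 1)) * 180 / pi
}

# axis-angle rotation matrix
axisAngle <- function(axis, angleDeg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angleDeg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}
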