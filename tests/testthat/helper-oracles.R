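# Independent oracles used across the suite.

# Brute-force voxel integration of a segment's mass properties: grid the
# bounding box, keep voxels inside the solid, sum mass/COM/inertia.
# Entirely independent of the closed forms in the package.
voxel_mass_properties <- function(spec, n_per_axis = 100) {
  d <- spec$dims
  box <- switch(spec$shape,
    prism = rbind(-d / 2, d / 2),
    cylinder = rbind(c(-d[1] / 2, -d[2], -d[2]), c(d[1] / 2, d[2], d[2])),
    cone = rbind(c(0, -d[2], -d[2]), c(d[1], d[2], d[2])))
  gx <- seq(box[1, 1], box[2, 1], length.out = n_per_axis + 1)
  gy <- seq(box[1, 2], box[2, 2], length.out = n_per_axis + 1)
  gz <- seq(box[1, 3], box[2, 3], length.out = n_per_axis + 1)
  cx <- (gx[-1] + gx[-length(gx)]) / 2
  cy <- (gy[-1] + gy[-length(gy)]) / 2
  cz <- (gz[-1] + gz[-length(gz)]) / 2
  pts <- expand.grid(x = cx, y = cy, z = cz)
  inside <- switch(spec$shape,
    prism = rep(TRUE, nrow(pts)),
    cylinder = pts$y^2 + pts$z^2 <= d[2]^2,
    cone = {
      r_at <- d[2] * (1 - pts$x / d[1])
      pts$x >= 0 & pts$x <= d[1] & pts$y^2 + pts$z^2 <= r_at^2
    })
  pts <- pts[inside, ]
  dv <- diff(gx)[1] * diff(gy)[1] * diff(gz)[1]
  vol <- nrow(pts) * dv
  mass <- if (is.null(spec$mass)) spec$density * vol else spec$mass
  dm <- mass / nrow(pts)
  com <- c(mean(pts$x), mean(pts$y), mean(pts$z))
  x <- pts$x - com[1]; y <- pts$y - com[2]; z <- pts$z - com[3]
  inertia <- matrix(c(
    sum(y^2 + z^2), -sum(x * y), -sum(x * z),
    -sum(x * y), sum(x^2 + z^2), -sum(y * z),
    -sum(x * z), -sum(y * z), sum(x^2 + y^2)), 3, 3) * dm
  list(mass = mass, com = com, inertia = inertia)
}

# Voxel mass properties in the parent frame (posed segment).
voxel_posed <- function(spec, n_per_axis = 100) {
  v <- voxel_mass_properties(spec, n_per_axis)
  R <- spec$orientation
  list(mass = v$mass,
       com = spec$position + as.numeric(R %*% v$com),
       inertia = R %*% v$inertia %*% t(R))
}

# A random but physically plausible morphology for property tests.
random_morphology <- function() {
  gecko_morphology(
    svl = runif(1, 0.03, 0.12),
    tail_length_ratio = runif(1, 0.4, 3),
    total_mass = runif(1, 1e-3, 2e-2),
    tail_mass_fraction = runif(1, 0.05, 0.25),
    tail_base_diameter = runif(1, 0.002, 0.008),
    torso_width = runif(1, 0.008, 0.02),
    torso_height = runif(1, 0.003, 0.008),
    leg_length = runif(1, 0.008, 0.025),
    leg_radius = runif(1, 0.001, 0.003),
    leg_splay_deg = runif(1, 0, 60))
}

# A random smooth cyclic two-axis tail drive (spline through random
# interior points, pinned to zero at the ends).
random_spline_trajectory <- function(span = 0.5, max_deg = 150) {
  collocation_trajectory(runif(3, -max_deg, max_deg),
                         runif(3, -max_deg, max_deg), span = span)
}

expect_close <- function(actual, expected, tol, label = NULL) {
  expect_lt(max(abs(actual - expected)), tol, label = label)
}

# Angular momentum of the two-segment system computed by numerical
# differentiation of segment poses over a small time window -- independent
# of every analytic velocity formula in the package.
numeric_angular_momentum <- function(morph, quat, omega, q, qd, axes,
                                     h = 1e-6) {
  par <- tailspin:::dyn_params(morph, axes)
  pose <- function(dt) {
    # advance body orientation and joint angles by dt (frozen rates)
    dq <- tailspin:::quat_normalize(
      quat + dt * tailspin:::quat_derivative(quat, omega))
    R1 <- tailspin:::quat_to_rot(dq)
    qi <- q + dt * qd
    R1a <- tailspin:::rot_axis_angle(par$a1, qi[1])
    R2a <- tailspin:::rot_axis_angle(par$a2, qi[2])
    Rj <- R1a %*% R2a
    s <- par$pj + as.numeric(Rj %*% par$d2)   # body COM -> tail COM, body fr.
    r1 <- -(par$m2 / par$Mtot) * as.numeric(R1 %*% s)
    r2 <- (par$m1 / par$Mtot) * as.numeric(R1 %*% s)
    list(r1 = r1, r2 = r2, R1 = R1, R2 = R1 %*% Rj)
  }
  p0 <- pose(-h / 2); p1 <- pose(h / 2)
  v1 <- (p1$r1 - p0$r1) / h
  v2 <- (p1$r2 - p0$r2) / h
  mid <- pose(0)
  w_from <- function(Ra, Rb, R) {
    W <- (Rb - Ra) %*% t(R) / h          # skew(omega_world)
    c(W[3, 2] - W[2, 3], W[1, 3] - W[3, 1], W[2, 1] - W[1, 2]) / 2
  }
  w1 <- w_from(p0$R1, p1$R1, mid$R1)
  w2 <- w_from(p0$R2, p1$R2, mid$R2)
  rc <- (par$m1 * mid$r1 + par$m2 * mid$r2) / par$Mtot
  I1w <- mid$R1 %*% par$I1 %*% t(mid$R1)
  I2w <- mid$R2 %*% par$I2 %*% t(mid$R2)
  par$m1 * tailspin:::cross3(mid$r1 - rc, v1) +
    par$m2 * tailspin:::cross3(mid$r2 - rc, v2) +
    as.numeric(I1w %*% w1) + as.numeric(I2w %*% w2)
}

# short aliases for internal utilities used throughout the tests
quat_normalize_pub <- tailspin:::quat_normalize
rad2deg_pub <- tailspin:::rad2deg
deg2rad_pub <- tailspin:::deg2rad
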