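# Segmented rigid-body morphology of a gliding gecko.
#
# The animal is assembled from uniform-density primitives: a rectangular
# prism torso, four cylindrical legs in a splayed "skydive" posture, and a
# solid conical tail attached at its base centre to the torso's caudal face
# (the vent). The body frame has its origin at the vent, x pointing
# cranially (vent -> snout), z dorsally, y to the animal's left; all units
# are SI (m, kg).

SEGMENT_SHAPES <- c("prism", "cylinder", "cone")

#' Specify a uniform-density rigid segment
#'
#' A segment is a solid primitive with an attachment pose relative to its
#' parent frame. Exactly one of `density` or `mass` must be given.
#'
#' @param shape one of `"prism"`, `"cylinder"`, `"cone"`. Prisms are centred
#'   on their frame; cylinders and cones have their symmetry axis along the
#'   local +x axis, cylinders centred, cones with the base centre at the
#'   origin and the apex at `+length`.
#' @param dims named numeric vector of dimensions in metres: prism
#'   `c(lx, ly, lz)`; cylinder `c(length, radius)`; cone
#'   `c(length, base_radius)`.
#' @param density uniform density, kg/m^3.
#' @param mass total segment mass, kg (alternative to `density`).
#' @param position 3-vector, origin of the segment frame in the parent
#'   frame, m.
#' @param orientation 3x3 rotation matrix, segment frame -> parent frame.
#' @param name optional segment label.
#' @return an object of class `segment_spec`.
#' @export
#' @examples
#' tail <- segment_spec("cone", c(length = 0.0475, base_radius = 0.00225),
#'                      mass = 2.85e-4)
#' segment_mass_properties(tail)
segment_spec <- function(shape, dims, density = NULL, mass = NULL,
                         position = c(0, 0, 0), orientation = diag(3),
                         name = shape) {
  shape <- match.arg(shape, SEGMENT_SHAPES)
  n_dims <- if (shape == "prism") 3L else 2L
  dims <- as.numeric(dims)
  if (length(dims) != n_dims) {
    stop(sprintf("shape '%s' needs %d dimensions, got %d",
                 shape, n_dims, length(dims)), call. = FALSE)
  }
  if (any(!is.finite(dims)) || any(dims <= 0)) {
    stop("invalid geometry: all segment dimensions must be positive and finite",
         call. = FALSE)
  }
  if (is.null(density) == is.null(mass)) {
    stop("give exactly one of 'density' or 'mass'", call. = FALSE)
  }
  if (!is.null(density) && density <= 0) stop("density must be positive", call. = FALSE)
  if (!is.null(mass) && mass <= 0) stop("mass must be positive", call. = FALSE)
  orientation <- as.matrix(orientation)
  if (!all(dim(orientation) == c(3L, 3L)) ||
      max(abs(crossprod(orientation) - diag(3))) > 1e-8) {
    stop("orientation must be a 3x3 rotation matrix", call. = FALSE)
  }
  structure(list(shape = shape, dims = dims, density = density, mass = mass,
                 position = as.numeric(position), orientation = orientation,
                 name = name),
            class = "segment_spec")
}

segment_volume <- function(spec) {
  d <- spec$dims
  switch(spec$shape,
         prism    = prod(d),
         cylinder = pi * d[2]^2 * d[1],
         cone     = pi * d[2]^2 * d[1] / 3)
}

#' Closed-form mass properties of a segment
#'
#' Mass, centre of mass and inertia tensor (about the COM, in the segment
#' frame) of a uniform-density prism, cylinder or solid cone. The cone's COM
#' sits a quarter of its length from the base; its axial moment is
#' `(3/10) m r^2`.
#'
#' @param spec a [segment_spec()].
#' @return an object of class `mass_properties`: list with `mass` (kg),
#'   `com` (3-vector, m, segment frame) and `inertia` (3x3, kg m^2, about
#'   the COM).
#' @export
segment_mass_properties <- function(spec) {
  stopifnot(inherits(spec, "segment_spec"))
  m <- if (is.null(spec$mass)) spec$density * segment_volume(spec) else spec$mass
  d <- spec$dims
  out <- switch(spec$shape,
    prism = list(
      com = c(0, 0, 0),
      inertia = diag(m / 12 * c(d[2]^2 + d[3]^2, d[1]^2 + d[3]^2,
                                d[1]^2 + d[2]^2))),
    cylinder = list(
      com = c(0, 0, 0),
      inertia = diag(c(m * d[2]^2 / 2, rep(m * (3 * d[2]^2 + d[1]^2) / 12, 2)))),
    cone = list(
      com = c(d[1] / 4, 0, 0),
      inertia = diag(c(3 / 10 * m * d[2]^2,
                       rep(m * (3 / 20 * d[2]^2 + 3 / 80 * d[1]^2), 2)))))
  structure(list(mass = m, com = out$com, inertia = out$inertia),
            class = "mass_properties")
}

#' Compose mass properties of several posed segments
#'
#' Expresses every segment's mass properties in the common parent frame
#' (rotating inertia tensors and applying the parallel-axis theorem about
#' the composite centre of mass).
#'
#' @param segments list of [segment_spec()] objects; their `position` and
#'   `orientation` place them in the parent frame.
#' @return `mass_properties` in the parent frame (inertia about the
#'   composite COM).
#' @export
compose_mass_properties <- function(segments) {
  props <- lapply(segments, segment_mass_properties)
  masses <- vapply(props, `[[`, numeric(1), "mass")
  coms <- mapply(function(s, p) s$position + as.numeric(s$orientation %*% p$com),
                 segments, props)
  total <- sum(masses)
  com <- as.numeric(coms %*% masses) / total
  inertia <- matrix(0, 3, 3)
  for (i in seq_along(segments)) {
    R <- segments[[i]]$orientation
    I_par <- R %*% props[[i]]$inertia %*% t(R)
    d <- coms[, i] - com
    inertia <- inertia + I_par +
      masses[i] * (sum(d^2) * diag(3) - tcrossprod(d))
  }
  inertia <- (inertia + t(inertia)) / 2
  structure(list(mass = total, com = com, inertia = inertia),
            class = "mass_properties")
}

#' @export
print.mass_properties <- function(x, ...) {
  cat(sprintf("mass: %.6g kg\ncom:  [%s] m\ninertia (kg m^2):\n",
              x$mass, paste(signif(x$com, 6), collapse = ", ")))
  print(signif(x$inertia, 6))
  invisible(x)
}

leg_orientation <- function(side, splay) {
  # cylinder local +x axis points from the shoulder/hip outward:
  # laterally (+-y) and raised `splay` radians dorsally
  dir <- c(0, side * cos(splay), sin(splay))
  up <- c(1, 0, 0)
  y <- cross3(c(0, 0, 1), dir); y <- y / sqrt(sum(y^2))
  z <- cross3(dir, y)
  R <- cbind(dir, y, z)
  dimnames(R) <- NULL
  R
}

build_segments <- function(svl, tail_length, tail_base_diameter, tail_density,
                           body_density, torso_dims, leg_length, leg_radius,
                           leg_splay) {
  torso <- segment_spec("prism", torso_dims, density = body_density,
                        position = c(svl / 2, 0, 0), name = "torso")
  legs <- list()
  shoulders <- c(0.85, 0.15) * svl
  for (i in 1:2) for (side in c(1, -1)) {
    R <- leg_orientation(side, leg_splay)
    attach <- c(shoulders[i], side * torso_dims[2] / 2, 0)
    nm <- sprintf("leg_%s_%s", c("front", "hind")[i],
                  c("left", "right")[(3 - side) / 2])
    legs[[nm]] <- segment_spec(
      "cylinder", c(length = leg_length, radius = leg_radius),
      density = body_density,
      position = attach + R[, 1] * leg_length / 2, orientation = R,
      name = nm)
  }
  tail <- segment_spec("cone",
                       c(length = tail_length, base_radius = tail_base_diameter / 2),
                       density = tail_density,
                       position = c(0, 0, 0),
                       orientation = rot_axis_angle(c(0, 0, 1), pi),
                       name = "tail")
  c(list(torso = torso), legs, list(tail = tail))
}

#' Construct a segmented gecko morphology
#'
#' Builds the torso + 4 legs + conical tail assembly from high-level
#' measurements. The tail cone is attached base-first at the vent (body
#' frame origin) pointing caudally. Body (torso+legs) density is set so the
#' non-tail mass comes out to `total_mass * (1 - tail_mass_fraction)`; tail
#' density likewise from the tail mass and cone volume.
#'
#' @param svl snout--vent length, m.
#' @param tail_length_ratio tail length / SVL (dimensionless).
#' @param total_mass whole-animal mass, kg.
#' @param tail_mass_fraction tail mass / total mass.
#' @param tail_base_diameter cone base diameter, m.
#' @param torso_width,torso_height prism extents, m.
#' @param leg_length,leg_radius leg cylinder dimensions, m.
#' @param leg_splay_deg dorsal splay angle of the legs in the skydive
#'   posture, degrees.
#' @return an object of class `gecko_morphology`.
#' @export
#' @examples
#' g <- build_default_gecko()
#' morphology_mass_properties(g)$mass   # 0.00285 kg
gecko_morphology <- function(svl,
                             tail_length_ratio,
                             total_mass,
                             tail_mass_fraction = 0.10,
                             tail_base_diameter = 0.0045,
                             torso_width = 0.012,
                             torso_height = 0.0045,
                             leg_length = 0.015,
                             leg_radius = 0.0015,
                             leg_splay_deg = 30) {
  stopifnot(svl > 0, tail_length_ratio > 0, total_mass > 0,
            tail_mass_fraction > 0, tail_mass_fraction < 1,
            tail_base_diameter > 0)
  tail_length <- tail_length_ratio * svl
  tail_mass <- tail_mass_fraction * total_mass
  body_mass <- total_mass - tail_mass
  tail_volume <- pi * (tail_base_diameter / 2)^2 * tail_length / 3
  tail_density <- tail_mass / tail_volume
  torso_dims <- c(svl, torso_width, torso_height)
  body_volume <- prod(torso_dims) + 4 * pi * leg_radius^2 * leg_length
  body_density <- body_mass / body_volume
  m <- structure(list(
    svl = svl, tail_length = tail_length,
    tail_length_ratio = tail_length_ratio,
    tail_base_diameter = tail_base_diameter,
    tail_density = tail_density, body_density = body_density,
    torso_dims = torso_dims,
    leg_length = leg_length, leg_radius = leg_radius,
    leg_splay = deg2rad(leg_splay_deg),
    tail_mass = tail_mass, body_mass = body_mass,
    total_mass = total_mass, tail_mass_fraction = tail_mass_fraction),
    class = "gecko_morphology")
  m$segments <- build_segments(svl, tail_length, tail_base_diameter,
                               tail_density, body_density, torso_dims,
                               leg_length, leg_radius, m$leg_splay)
  m
}

#' Default Hemidactylus platyurus model
#'
#' The default parameterization reproduces the headline measurements of the
#' Asian flat-tailed gecko used throughout the package: total mass 2.85 g,
#' total length (snout to tail tip) 9.86 cm, tail:body length ratio 0.93,
#' and a tail carrying 10% of body mass. Note the total length is
#' interpreted in centimetres; a literal 9.86 mm reading would be
#' dimensionally implausible for a 2.85 g animal.
#'
#' @param total_mass whole-animal mass, kg.
#' @param total_length snout to tail tip, m.
#' @param tail_length_ratio tail length / SVL.
#' @param tail_mass_fraction tail mass / total mass.
#' @param ... further arguments passed to [gecko_morphology()].
#' @return a `gecko_morphology`.
#' @export
build_default_gecko <- function(total_mass = 2.85e-3,
                                total_length = 9.86e-2,
                                tail_length_ratio = 0.93,
                                tail_mass_fraction = 0.10, ...) {
  svl <- total_length / (1 + tail_length_ratio)
  gecko_morphology(svl = svl, tail_length_ratio = tail_length_ratio,
                   total_mass = total_mass,
                   tail_mass_fraction = tail_mass_fraction, ...)
}

#' Composite mass properties of the whole animal
#'
#' @param morph a `gecko_morphology`.
#' @return `mass_properties` in the body (vent-origin) frame.
#' @export
morphology_mass_properties <- function(morph) {
  stopifnot(inherits(morph, "gecko_morphology"))
  compose_mass_properties(morph$segments)
}

#' Rescale the tail, holding base diameter and density constant
#'
#' Lengthens or shortens the tail cone to `new_ratio * svl` while keeping
#' the base diameter and material density fixed, so tail mass scales
#' linearly with tail length. All other segments are untouched.
#'
#' @param morph a `gecko_morphology`.
#' @param new_ratio new tail length / SVL, > 0.
#' @return a new `gecko_morphology`.
#' @export
scale_tail <- function(morph, new_ratio) {
  stopifnot(inherits(morph, "gecko_morphology"))
  if (!is.finite(new_ratio) || new_ratio <= 0) {
    stop("new_ratio must be positive", call. = FALSE)
  }
  m <- morph
  m$tail_length_ratio <- new_ratio
  m$tail_length <- new_ratio * m$svl
  tail_volume <- pi * (m$tail_base_diameter / 2)^2 * m$tail_length / 3
  m$tail_mass <- m$tail_density * tail_volume
  m$total_mass <- m$body_mass + m$tail_mass
  m$tail_mass_fraction <- m$tail_mass / m$total_mass
  m$segments$tail <- segment_spec(
    "cone", c(length = m$tail_length, base_radius = m$tail_base_diameter / 2),
    density = m$tail_density, position = c(0, 0, 0),
    orientation = rot_axis_angle(c(0, 0, 1), pi), name = "tail")
  m
}

#' Truncate the tail, as after autotomy
#'
#' @param morph a `gecko_morphology`.
#' @param fraction_remaining fraction of the original tail length kept,
#'   in (0, 1].
#' @return a new `gecko_morphology` with the shortened tail.
#' @export
autotomize_tail <- function(morph, fraction_remaining) {
  if (!is.finite(fraction_remaining) ||
      fraction_remaining <= 0 || fraction_remaining > 1) {
    stop("fraction_remaining must be in (0, 1]", call. = FALSE)
  }
  scale_tail(morph, morph$tail_length_ratio * fraction_remaining)
}

#' @export
print.gecko_morphology <- function(x, ...) {
  cat(sprintf(paste0(
    "gecko morphology\n",
    "  svl: %.4g cm   tail: %.4g cm (ratio %.3f)\n",
    "  total mass: %.4g g   tail mass fraction: %.3f\n",
    "  segments: %s\n"),
    x$svl * 100, x$tail_length * 100, x$tail_length_ratio,
    x$total_mass * 1000, x$tail_mass_fraction,
    paste(vapply(x$segments, `[[`, character(1), "name"), collapse = ", ")))
  invisible(x)
}

#' Write / read a morphology configuration (YAML)
#'
#' The file stores the high-level parameters together with the derived
#' per-segment description (shape, dimensions in m, density, pose). Lengths
#' are SI metres throughout; the default total length corresponds to the
#' 9.86 cm reading discussed in [build_default_gecko()].
#'
#' @param morph a `gecko_morphology`.
#' @param path file path.
#' @return `write_morphology` invisibly returns `path`; `read_morphology`
#'   returns the rebuilt, validated `gecko_morphology`.
#' @export
write_morphology <- function(morph, path) {
  stopifnot(inherits(morph, "gecko_morphology"))
  pars <- list(
    units = "SI (m, kg); note: the headline 9.86 total length is in cm",
    svl = morph$svl,
    tail_length_ratio = morph$tail_length_ratio,
    total_mass = morph$total_mass,
    tail_mass_fraction = morph$tail_mass_fraction,
    tail_base_diameter = morph$tail_base_diameter,
    torso_width = morph$torso_dims[2],
    torso_height = morph$torso_dims[3],
    leg_length = morph$leg_length,
    leg_radius = morph$leg_radius,
    leg_splay_deg = rad2deg(morph$leg_splay))
  segs <- lapply(morph$segments, function(s) {
    list(shape = s$shape, dims = as.list(s$dims), density = s$density,
         position = as.list(s$position),
         orientation = apply(s$orientation, 1, as.list))
  })
  yaml::write_yaml(list(parameters = pars, segments = segs), path,
                   precision = 15)
  invisible(path)
}

#' @rdname write_morphology
#' @export
read_morphology <- function(path) {
  cfg <- yaml::read_yaml(path)
  p <- cfg$parameters
  need <- c("svl", "tail_length_ratio", "total_mass")
  if (!all(need %in% names(p))) {
    stop("morphology config must provide: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  m <- gecko_morphology(
    svl = p$svl, tail_length_ratio = p$tail_length_ratio,
    total_mass = p$total_mass,
    tail_mass_fraction = p$tail_mass_fraction %||% 0.10,
    tail_base_diameter = p$tail_base_diameter %||% 0.0045,
    torso_width = p$torso_width %||% 0.012,
    torso_height = p$torso_height %||% 0.0045,
    leg_length = p$leg_length %||% 0.015,
    leg_radius = p$leg_radius %||% 0.0015,
    leg_splay_deg = p$leg_splay_deg %||% 30)
  comp <- morphology_mass_properties(m)
  if (abs(comp$mass - m$total_mass) > 1e-9 * m$total_mass) {
    stop("composite mass does not match configured total mass", call. = FALSE)
  }
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
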