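# Wind-tunnel kinematics pipeline: landmark tracks -> body/tail angles ->
# cross-correlation lag, swing segmentation and swing regression; plus a
# synthetic-track generator for closed-loop validation.
#
# Angle conventions: body angle is the direction of the vent->snout line
# in the camera (inertial) frame; tail angle is the signed angle between
# the vent->tail-tip line and the caudal prolongation of the body line, so
# zero means snout, vent and tail tip are collinear with the tail trailing.
# Positive lag means the body signal follows the tail signal (the
# convention natural to aerodynamic forcing by tail position; purely
# inertial coupling is instantaneous and shows zero lag).

TRACK_COLS <- c("snout_x", "snout_y", "vent_x", "vent_y",
                "tailtip_x", "tailtip_y")

#' Read a landmark track table
#'
#' Accepts either the package's flat CSV dialect
#' (`frame,time_s,snout_x,snout_y,vent_x,vent_y,tailtip_x,tailtip_y[,...]`,
#' `time_s` optional when `frame_rate` is given) or a DeepLabCut-style
#' export with three header rows (scorer / bodyparts / coords), which is
#' flattened on load. Frames must be unique and strictly increasing; gaps
#' are reported via the `gaps` attribute, never silently interpolated.
#'
#' @param path CSV file.
#' @param frame_rate frames per second, used to derive `time_s` when the
#'   file has none.
#' @param body_length optional physical snout--vent length; when given,
#'   coordinates are rescaled so the mean tracked body length equals it
#'   (scalar pixel calibration).
#' @return a `track_table` data frame.
#' @export
read_tracks <- function(path, frame_rate = NULL, body_length = NULL) {
  first <- readLines(path, n = 1L)
  if (grepl("^scorer", first)) {
    d <- read_dlc_tracks(path)
  } else {
    d <- read.csv(path, check.names = FALSE)
    names(d) <- sub("^tail_tip_", "tailtip_", names(d))
  }
  missing <- setdiff(TRACK_COLS, names(d))
  if (length(missing) > 0) {
    stop("missing landmark columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"frame" %in% names(d)) d$frame <- seq_len(nrow(d)) - 1L
  dup <- d$frame[duplicated(d$frame)]
  if (length(dup) > 0) {
    stop("duplicated frame(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (is.unsorted(d$frame, strictly = TRUE)) {
    stop("frame indices must be strictly increasing", call. = FALSE)
  }
  if (!"time_s" %in% names(d)) {
    if (is.null(frame_rate)) {
      stop("file has no time_s column; supply frame_rate", call. = FALSE)
    }
    d$time_s <- d$frame / frame_rate
  }
  if (any(!is.finite(as.matrix(d[, TRACK_COLS])))) {
    stop("non-finite landmark coordinates", call. = FALSE)
  }
  gaps <- which(diff(d$frame) > 1)
  if (!is.null(body_length)) {
    px <- mean(sqrt((d$snout_x - d$vent_x)^2 + (d$snout_y - d$vent_y)^2))
    sc <- body_length / px
    d[, TRACK_COLS] <- d[, TRACK_COLS] * sc
    attr(d, "pixel_scale") <- sc
  }
  d <- d[, c("frame", "time_s", TRACK_COLS,
             intersect(names(d), c("confidence_snout", "confidence_vent",
                                   "confidence_tailtip")))]
  attr(d, "gaps") <- d$frame[gaps]
  class(d) <- c("track_table", "data.frame")
  d
}

read_dlc_tracks <- function(path) {
  hdr <- readLines(path, n = 3L)
  parts <- tolower(strsplit(hdr[2], ",")[[1]])
  coords <- tolower(strsplit(hdr[3], ",")[[1]])
  body <- read.csv(path, skip = 3L, header = FALSE)
  out <- data.frame(frame = body[[1]])
  for (j in 2:length(parts)) {
    part <- gsub("[ _]", "", parts[j])
    part <- sub("tailtip|tail_tip", "tailtip", part)
    if (!part %in% c("snout", "vent", "tailtip")) next
    if (coords[j] %in% c("x", "y")) {
      out[[paste0(part, "_", coords[j])]] <- body[[j]]
    } else if (coords[j] == "likelihood") {
      out[[paste0("confidence_", part)]] <- body[[j]]
    }
  }
  out
}

#' Write a track table in the package CSV dialect
#'
#' @param tracks a `track_table` (or the `$tracks` element of
#'   [synth_tracks()] output).
#' @param path destination CSV.
#' @return invisibly, `path`.
#' @export
write_tracks <- function(tracks, path) {
  write.csv(as.data.frame(tracks), path, row.names = FALSE)
  invisible(path)
}

#' Body and tail angles from landmark tracks
#'
#' Body angle: direction of the vent->snout line in the camera frame.
#' Tail angle: signed angle (CCW positive) of the vent->tail-tip line
#' relative to the caudal body direction, zero when the three landmarks
#' are collinear with the tail trailing. Both series are unwrapped.
#'
#' @param tracks a `track_table`.
#' @return an `angle_series` data frame: `time_s`, `body_angle_deg`,
#'   `tail_angle_deg`.
#' @export
compute_angles <- function(tracks) {
  bx <- tracks$snout_x - tracks$vent_x
  by <- tracks$snout_y - tracks$vent_y
  tx <- tracks$tailtip_x - tracks$vent_x
  ty <- tracks$tailtip_y - tracks$vent_y
  bad <- which(bx^2 + by^2 == 0 | tx^2 + ty^2 == 0)
  if (length(bad) > 0) {
    stop("undefined angle: coincident landmarks at frame(s) ",
         paste(tracks$frame[bad], collapse = ", "), call. = FALSE)
  }
  body <- atan2(by, bx)
  # caudal body direction is -b; signed angle from it to the tail vector
  ax <- -bx; ay <- -by
  tail <- atan2(ax * ty - ay * tx, ax * tx + ay * ty)
  out <- data.frame(time_s = tracks$time_s,
                    body_angle_deg = rad2deg(unwrap_angle(body)),
                    tail_angle_deg = rad2deg(unwrap_angle(tail)))
  class(out) <- c("angle_series", "data.frame")
  out
}

#' Cross-correlation lag between tail and body motion
#'
#' Resamples both angle series to a uniform grid (cubic interpolation),
#' removes the mean, and computes the normalized (Pearson) correlation of
#' body against tail over integer shifts up to `max_lag`, with parabolic
#' sub-sample refinement around the magnitude peak. Positive lag means
#' the body follows the tail.
#'
#' @param angles an `angle_series`.
#' @param max_lag largest lag searched, s.
#' @param dt resampling interval, s (default 4 ms).
#' @return a `lag_result`: list with `lag_s`, `peak_correlation` (signed)
#'   and the `curve` data frame (`lag_s`, `correlation`).
#' @export
cross_correlate <- function(angles, max_lag = 0.2, dt = 0.004) {
  span <- diff(range(angles$time_s))
  if (span < 3 * max_lag) {
    stop("insufficient data: series must span at least 3x max_lag",
         call. = FALSE)
  }
  tt <- seq(min(angles$time_s), max(angles$time_s), by = dt)
  tail_u <- splinefun(angles$time_s, angles$tail_angle_deg,
                      method = "natural")(tt)
  body_u <- splinefun(angles$time_s, angles$body_angle_deg,
                      method = "natural")(tt)
  tail_u <- tail_u - mean(tail_u)
  body_u <- body_u - mean(body_u)
  K <- floor(max_lag / dt)
  n <- length(tt)
  if (n - K < 8) stop("insufficient data for the requested max_lag",
                      call. = FALSE)
  shifts <- -K:K
  r <- vapply(shifts, function(k) {
    if (k >= 0) {
      a <- tail_u[1:(n - k)]; b <- body_u[(1 + k):n]
    } else {
      a <- tail_u[(1 - k):n]; b <- body_u[1:(n + k)]
    }
    if (sd(a) == 0 || sd(b) == 0) return(0)
    cor(a, b)
  }, numeric(1))
  i <- which.max(abs(r))
  lag <- shifts[i] * dt
  # parabolic refinement on |r| around the discrete peak
  if (i > 1 && i < length(r)) {
    y1 <- abs(r[i - 1]); y2 <- abs(r[i]); y3 <- abs(r[i + 1])
    denom <- y1 - 2 * y2 + y3
    if (abs(denom) > .Machine$double.eps) {
      lag <- lag + dt * 0.5 * (y1 - y3) / denom
    }
  }
  structure(list(lag_s = lag, peak_correlation = r[i],
                 curve = data.frame(lag_s = shifts * dt, correlation = r)),
            class = "lag_result")
}

#' Segment tail swings
#'
#' A swing is a maximal interval of single-direction tail motion: the
#' smoothed tail angular rate (zero-phase moving average) keeps one sign,
#' and the excursion and duration exceed thresholds.
#'
#' @param angles an `angle_series`.
#' @param min_amplitude_deg minimum tail excursion per swing.
#' @param min_duration_s minimum swing duration.
#' @param smooth_window moving-average width, samples (odd).
#' @return data frame with one row per swing: sample indices, times, and
#'   the tail and body angle changes over the swing.
#' @export
segment_swings <- function(angles, min_amplitude_deg = 10,
                           min_duration_s = 0.05, smooth_window = 5) {
  n <- nrow(angles)
  if (n < smooth_window + 2) return(empty_swings())
  rate <- c(NA, diff(angles$tail_angle_deg) / diff(angles$time_s))
  rate[1] <- rate[2]
  sm <- stats::filter(rate, rep(1 / smooth_window, smooth_window),
                      sides = 2)
  sm[is.na(sm)] <- rate[is.na(sm)]
  s <- sign(as.numeric(sm))
  s[s == 0] <- 1
  breaks <- c(1, which(diff(s) != 0) + 1, n + 1)
  out <- list()
  for (i in seq_len(length(breaks) - 1)) {
    i0 <- breaks[i]; i1 <- breaks[i + 1] - 1
    if (i1 <= i0) next
    dtail <- angles$tail_angle_deg[i1] - angles$tail_angle_deg[i0]
    dur <- angles$time_s[i1] - angles$time_s[i0]
    if (abs(dtail) >= min_amplitude_deg && dur >= min_duration_s) {
      out[[length(out) + 1]] <- data.frame(
        start = i0, end = i1,
        start_s = angles$time_s[i0], end_s = angles$time_s[i1],
        dtail_deg = dtail,
        dbody_deg = angles$body_angle_deg[i1] - angles$body_angle_deg[i0])
    }
  }
  if (length(out) == 0) return(empty_swings())
  do.call(rbind, out)
}

empty_swings <- function() {
  data.frame(start = integer(0), end = integer(0),
             start_s = numeric(0), end_s = numeric(0),
             dtail_deg = numeric(0), dbody_deg = numeric(0))
}

#' Regression of body angle change on tail angle change across swings
#'
#' Least-squares fit of per-swing body angle change against tail angle
#' change; the slope estimates the (negative) inertial coupling ratio.
#'
#' @param swings output of [segment_swings()] (>= 3 swings).
#' @return a `swing_regression`: list with `slope`, `intercept`,
#'   `r_squared`, `n` and the per-swing `data`.
#' @export
swing_regression <- function(swings) {
  if (nrow(swings) < 3) {
    stop("need at least 3 swings for a regression", call. = FALSE)
  }
  if (var(swings$dtail_deg) == 0) {
    stop("degenerate regression: all tail angle changes are equal",
         call. = FALSE)
  }
  fit <- lm(dbody_deg ~ dtail_deg, data = swings)
  # suppressWarnings: exact synthetic couplings trigger lm's
  # perfect-fit warning, which is a legitimate case here
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 n = nrow(swings), data = swings),
            class = "swing_regression")
}

#' @export
print.swing_regression <- function(x, ...) {
  cat(sprintf("swing regression: slope %.3f, R^2 = %.3f, n = %d\n",
              x$slope, x$r_squared, x$n))
  invisible(x)
}

#' Generate synthetic landmark tracks with known coupling
#'
#' Emulates a tracked wind-tunnel glide: the tail performs `n_swings`
#' smooth alternating strokes; the body responds by the chosen coupling
#' pathway and the landmark positions (snout, vent, tail tip) are rendered
#' with additive Gaussian pixel noise.
#'
#' Coupling modes:
#' * `inertial`: body angle = `-coupling * tail angle`, instantaneous
#'   (momentum exchange; expected cross-correlation lag 0);
#' * `aero`: body angle = `-coupling * tail angle delayed by lag_s`
#'   (transport-delay abstraction of the position-driven aerodynamic
#'   pathway, whose integral response trails the tail);
#' * `mixed`: weighted sum, `mix_weight` on the inertial pathway.
#'
#' @param mode coupling pathway.
#' @param n_swings number of single-direction tail strokes.
#' @param amplitude_deg stroke amplitude (peak tail angle magnitude).
#' @param stroke_duration_s duration of each stroke.
#' @param coupling dimensionless body/tail coupling magnitude.
#' @param lag_s programmed aerodynamic lag, s.
#' @param mix_weight inertial weight in `mixed` mode, in \[0, 1\].
#' @param fps rendered frame rate.
#' @param noise_px Gaussian pixel noise SD on every coordinate.
#' @param body_disturbance_deg SD of a smooth low-frequency random body
#'   rotation added on top of the tail-coupled response, emulating
#'   extraneous aerodynamic rotations (feet, posture) that decorrelate
#'   body from tail motion; 0 disables it.
#' @param body_length_px,tail_length_px rendered landmark distances.
#' @param seed integer seed; fixed seed gives identical output.
#' @return list with `tracks` (a `track_table`) and `truth` (programmed
#'   lag, coupling, swing count, mode, fps).
#' @export
synth_tracks <- function(mode = c("inertial", "aero", "mixed"),
                         n_swings = 7, amplitude_deg = 60,
                         stroke_duration_s = 0.3, coupling = 0.15,
                         lag_s = 0.016, mix_weight = 0.5, fps = 250,
                         noise_px = 0.5, body_disturbance_deg = 0,
                         body_length_px = 200,
                         tail_length_px = 186, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(fps > 0, n_swings >= 1, stroke_duration_s > 0)
  if (!is.null(seed)) set.seed(seed)
  lead <- 0.3
  duration <- lead * 2 + n_swings * stroke_duration_s
  tt <- seq(0, duration, by = 1 / fps)
  # alternating stroke targets 0 -> A -> -A -> A ... (cosine-eased)
  targets <- c(0, amplitude_deg * (-1)^(seq_len(n_swings) + 1))
  phi <- numeric(length(tt))
  for (i in seq_len(n_swings)) {
    t0 <- lead + (i - 1) * stroke_duration_s
    tau <- (tt - t0) / stroke_duration_s
    seg <- tau >= 0 & tau <= 1
    ease <- (1 - cos(pi * tau[seg])) / 2
    phi[seg] <- targets[i] + (targets[i + 1] - targets[i]) * ease
    phi[tau > 1] <- targets[i + 1]
  }
  phi_at <- function(t) {
    approx(tt, phi, xout = pmin(pmax(t, 0), duration), rule = 2)$y
  }
  body <- switch(mode,
    inertial = -coupling * phi,
    aero = -coupling * phi_at(tt - lag_s),
    mixed = -coupling * (mix_weight * phi +
                           (1 - mix_weight) * phi_at(tt - lag_s)))
  if (body_disturbance_deg > 0) {
    # smooth low-frequency rotation uncorrelated with the tail program
    w <- max(3L, round(fps * 0.4))
    raw <- stats::filter(rnorm(length(tt) + 2 * w), rep(1 / w, w),
                         sides = 2)
    raw <- raw[(w + 1):(w + length(tt))]
    body <- body + body_disturbance_deg * raw / sd(raw)
  }
  theta_b <- deg2rad(body + 90)          # rendered heading, camera frame
  phi_r <- deg2rad(phi)
  vent <- c(500, 500)
  n <- length(tt)
  d <- data.frame(
    frame = seq_len(n) - 1L,
    time_s = tt,
    snout_x = vent[1] + body_length_px * cos(theta_b),
    snout_y = vent[2] + body_length_px * sin(theta_b),
    vent_x = rep(vent[1], n),
    vent_y = rep(vent[2], n),
    tailtip_x = vent[1] + tail_length_px * cos(theta_b + pi + phi_r),
    tailtip_y = vent[2] + tail_length_px * sin(theta_b + pi + phi_r))
  if (noise_px > 0) {
    for (cn in TRACK_COLS) d[[cn]] <- d[[cn]] + rnorm(n, 0, noise_px)
  }
  class(d) <- c("track_table", "data.frame")
  list(tracks = d,
       truth = list(mode = mode, lag_s = if (mode == "inertial") 0 else lag_s,
                    coupling = coupling, swing_count = n_swings,
                    mix_weight = mix_weight, fps = fps,
                    amplitude_deg = amplitude_deg))
}
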