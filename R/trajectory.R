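# Cyclic two-axis tail trajectories and their optimization.
#
# A candidate tail motion is a cubic spline through six collocation points
# (three per joint axis) at equally spaced knots over a fixed stroke span,
# pinned to zero at both ends so the stroke is cyclic (tail starts and
# finishes parallel to the body). A real-coded genetic algorithm searches
# the six point values for the trajectory whose 1 s body pose best matches
# a target yaw with minimal residual pitch and roll.

#' Natural cubic spline coefficients
#'
#' Computes per-interval cubic coefficients (value, slope, curvature/2,
#' jerk/6 at the left knot) for the natural cubic interpolating spline.
#' Matches `stats::splinefun(method = "natural")` exactly; the explicit
#' coefficient table is what the compiled integrator evaluates.
#'
#' @param x strictly increasing knot locations.
#' @param y values at the knots.
#' @return list with `knots` and an `(n-1) x 4` coefficient matrix.
#' @export
natural_spline_coefs <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 2, length(y) == n, all(diff(x) > 0))
  h <- diff(x)
  M <- numeric(n)                      # second derivatives; natural: ends 0
  if (n > 2) {
    k <- n - 2
    diag_main <- 2 * (h[1:k] + h[2:(k + 1)])
    rhs <- 6 * (diff(y)[2:(k + 1)] / h[2:(k + 1)] - diff(y)[1:k] / h[1:k])
    A <- diag(diag_main, k, k)
    if (k > 1) {
      for (i in 1:(k - 1)) {
        A[i, i + 1] <- h[i + 1]
        A[i + 1, i] <- h[i + 1]
      }
    }
    M[2:(k + 1)] <- solve(A, rhs)
  }
  coef <- matrix(0, n - 1, 4)
  for (i in seq_len(n - 1)) {
    coef[i, 1] <- y[i]
    coef[i, 2] <- (y[i + 1] - y[i]) / h[i] - h[i] * (2 * M[i] + M[i + 1]) / 6
    coef[i, 3] <- M[i] / 2
    coef[i, 4] <- (M[i + 1] - M[i]) / (6 * h[i])
  }
  list(knots = x, coef = coef)
}

eval_spline_coefs <- function(sp, t, deriv = 0) {
  k <- sp$knots
  vapply(t, function(ti) {
    if (ti <= k[1] || ti >= k[length(k)]) return(0)
    i <- findInterval(ti, k, rightmost.closed = TRUE)
    dt <- ti - k[i]
    cf <- sp$coef[i, ]
    if (deriv == 0) {
      cf[1] + dt * (cf[2] + dt * (cf[3] + dt * cf[4]))
    } else {
      cf[2] + dt * (2 * cf[3] + 3 * dt * cf[4])
    }
  }, numeric(1))
}

#' Six-point cyclic collocation trajectory
#'
#' @param pitch_points,roll_points three interior collocation angles per
#'   axis, degrees, each within \[-180, 180\]. ("pitch" and "roll" name the
#'   two tail joint axes; the same container drives any configured axis
#'   pair.)
#' @param span stroke duration over which the six knots are spread, s.
#' @return an object of class `collocation_trajectory`.
#' @export
collocation_trajectory <- function(pitch_points, roll_points, span = 0.5) {
  pitch_points <- as.numeric(pitch_points)
  roll_points <- as.numeric(roll_points)
  if (length(pitch_points) != 3L || length(roll_points) != 3L) {
    stop("three collocation points per axis are required", call. = FALSE)
  }
  pts <- c(pitch_points, roll_points)
  if (any(!is.finite(pts)) || any(abs(pts) > 180)) {
    stop("collocation points must lie within [-180, 180] degrees",
         call. = FALSE)
  }
  stopifnot(span > 0)
  structure(list(pitch_points = pitch_points, roll_points = roll_points,
                 span = span),
            class = "collocation_trajectory")
}

#' Tail trajectory spline from collocation points
#'
#' Builds the natural cubic splines through `0, p1, p2, p3, 0` at equally
#' spaced knots over `[0, span]` for both axes, and returns them as a
#' kinematic [kinematic_drive()] object (angles in radians, held at zero after the
#' stroke so the pose can be read later than the stroke end).
#'
#' The default joint ordering is roll-outer / pitch-inner: the pitch
#' rotation deflects the tail out of the body axis and the roll rotation
#' then sweeps the deflected tail around the body's long axis. (With the
#' opposite nesting, roll would merely spin the axisymmetric cone about
#' its own axis and the tail tip could never leave one plane, so no
#' two-axis maneuver could produce yaw.)
#'
#' @param traj a [collocation_trajectory()].
#' @param axes joint axis pair the point sets drive (matched by name:
#'   `pitch_points` drive a `"pitch"` axis, `roll_points` a `"roll"` or
#'   `"yaw"` axis); the first axis is the outer rotation.
#' @return a `joint_drive` whose `q_fun`/`qd_fun` evaluate both axes and
#'   which carries spline coefficient tables for the compiled integrator.
#' @export
spline_from_points <- function(traj, axes = c("roll", "pitch")) {
  stopifnot(inherits(traj, "collocation_trajectory"))
  knots <- seq(0, traj$span, length.out = 5L)
  pts <- lapply(axes, function(ax) {
    if (ax == "pitch") traj$pitch_points else traj$roll_points
  })
  y1 <- deg2rad(c(0, pts[[1]], 0))
  y2 <- deg2rad(c(0, pts[[2]], 0))
  sp1 <- natural_spline_coefs(knots, y1)
  sp2 <- natural_spline_coefs(knots, y2)
  q_fun <- function(t) c(eval_spline_coefs(sp1, t), eval_spline_coefs(sp2, t))
  qd_fun <- function(t) c(eval_spline_coefs(sp1, t, deriv = 1),
                          eval_spline_coefs(sp2, t, deriv = 1))
  kinematic_drive(q_fun, qd_fun, axes = axes, spline = list(sp1, sp2))
}

#' Objective for the trajectory search
#'
#' Fitness (lower is better) of the body pose at `eval_time`:
#' `|yaw - target_yaw| + w_pitch * |pitch| + w_roll * |roll|`, all in
#' degrees.
#'
#' @param target_yaw desired net body yaw, degrees.
#' @param w_pitch,w_roll penalty weights on residual pitch and roll.
#' @param eval_time time at which the pose is read, s.
#' @return an object of class `objective_spec`.
#' @export
objective_spec <- function(target_yaw = 30, w_pitch = 0.5, w_roll = 0.5,
                           eval_time = 1.0) {
  stopifnot(w_pitch >= 0, w_roll >= 0, eval_time > 0)
  structure(list(target_yaw = target_yaw, w_pitch = w_pitch,
                 w_roll = w_roll, eval_time = eval_time),
            class = "objective_spec")
}

#' Genetic-algorithm configuration
#'
#' Real-coded GA: tournament selection (k = 2), blend (BLX-alpha)
#' crossover, Gaussian mutation, elitism of one. Generation 1 is the
#' evaluated random initial population, so the search costs exactly
#' `population * generations` model evaluations.
#'
#' @param population individuals per generation.
#' @param generations number of generations (including the initial one).
#' @param crossover_rate probability a child is produced by crossover.
#' @param mutation_sd per-gene Gaussian mutation scale, degrees.
#' @param mutation_rate per-gene mutation probability.
#' @param seed integer RNG seed; `NULL` uses the current RNG state.
#' @return an object of class `ga_config`.
#' @export
ga_config <- function(population = 20, generations = 20,
                      crossover_rate = 0.9, mutation_sd = 20,
                      mutation_rate = 0.2, seed = NULL) {
  stopifnot(population > 0, generations > 0)
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_sd = mutation_sd, mutation_rate = mutation_rate,
                 seed = seed),
            class = "ga_config")
}

#' Evaluate one tail trajectory
#'
#' Simulates the maneuver (stroke over `traj$span`, tail then held at
#' neutral) and scores the body pose at the objective's evaluation time.
#'
#' @param traj a [collocation_trajectory()].
#' @param morph a `gecko_morphology`.
#' @param aero an [aero_spring_params()].
#' @param obj an [objective_spec()].
#' @param config a [sim_config()]; its duration must reach
#'   `obj$eval_time`.
#' @param axes joint axis pair.
#' @return list with `fitness`, `yaw`, `pitch`, `roll` (degrees at the
#'   evaluation time) and the `sim_result`.
#' @export
evaluate_trajectory <- function(traj, morph, aero, obj = objective_spec(),
                                config = sim_config(duration = obj$eval_time,
                                                    dt_out = obj$eval_time / 4,
                                                    rtol = 1e-7, atol = 1e-9),
                                axes = c("roll", "pitch")) {
  stopifnot(config$duration >= obj$eval_time - 1e-12)
  drive <- spline_from_points(traj, axes = axes)
  res <- tryCatch(simulate_maneuver(morph, drive, config, aero),
                  error = function(e) e)
  if (inherits(res, "error")) {
    return(list(fitness = 1e6, yaw = NA_real_, pitch = NA_real_,
                roll = NA_real_, result = NULL,
                diagnostic = conditionMessage(res)))
  }
  i <- which.min(abs(res$time - obj$eval_time))
  yaw <- res$yaw_deg[i]; pitch <- res$pitch_deg[i]; roll <- res$roll_deg[i]
  list(fitness = abs(yaw - obj$target_yaw) +
         obj$w_pitch * abs(pitch) + obj$w_roll * abs(roll),
       yaw = yaw, pitch = pitch, roll = roll, result = res)
}

#' Genetic-algorithm search over cyclic tail trajectories
#'
#' Stochastic search of the six collocation point values (two axes, three
#' points each, degrees in \[-180, 180\]) minimizing the pose objective,
#' with and without the aerodynamic restoring springs.
#'
#' @param morph a `gecko_morphology`.
#' @param aero an [aero_spring_params()].
#' @param obj an [objective_spec()].
#' @param cfg a [ga_config()].
#' @param span stroke span, s.
#' @param sim a [sim_config()] used for every candidate evaluation.
#' @param axes joint axis pair.
#' @return an object of class `ga_result`: `best_trajectory`,
#'   `best_fitness`, final pose (`yaw`, `pitch`, `roll`),
#'   `fitness_trace` (best-so-far per generation, non-increasing),
#'   `archive` (every evaluated candidate with its fitness) and
#'   `n_evaluations`.
#' @export
ga_optimize <- function(morph, aero, obj = objective_spec(),
                        cfg = ga_config(), span = 0.5,
                        sim = sim_config(duration = obj$eval_time,
                                         dt_out = obj$eval_time / 4,
                                         rtol = 1e-6, atol = 1e-9),
                        axes = c("roll", "pitch")) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  np <- cfg$population; ng <- cfg$generations
  bounds <- c(-180, 180)
  evals <- 0L
  archive <- matrix(NA_real_, np * ng, 8)
  colnames(archive) <- c(paste0("p", 1:3), paste0("r", 1:3),
                         "fitness", "generation")
  score <- function(genes) {
    traj <- collocation_trajectory(genes[1:3], genes[4:6], span = span)
    evaluate_trajectory(traj, morph, aero, obj, sim, axes)$fitness
  }
  pop <- matrix(runif(np * 6, bounds[1], bounds[2]), np, 6)
  fit <- numeric(np)
  trace <- numeric(ng)
  best_genes <- NULL; best_fit <- Inf
  for (gen in seq_len(ng)) {
    if (gen > 1L) {
      new_pop <- matrix(0, np, 6)
      new_pop[1, ] <- best_genes                      # elitism
      for (i in 2:np) {
        pick <- function() {
          cand <- sample.int(np, 2)
          pop[cand[which.min(fit[cand])], ]
        }
        pa <- pick(); pb <- pick()
        child <- if (runif(1) < cfg$crossover_rate) {
          # BLX-0.5 blend crossover
          lo <- pmin(pa, pb); hi <- pmax(pa, pb); d <- hi - lo
          runif(6, lo - 0.5 * d, hi + 0.5 * d)
        } else pa
        mut <- runif(6) < cfg$mutation_rate
        child[mut] <- child[mut] + rnorm(sum(mut), 0, cfg$mutation_sd)
        new_pop[i, ] <- pmin(bounds[2], pmax(bounds[1], child))
      }
      pop <- new_pop
    }
    for (i in seq_len(np)) {
      fit[i] <- score(pop[i, ])
      evals <- evals + 1L
      archive[evals, ] <- c(pop[i, ], fit[i], gen)
    }
    gb <- which.min(fit)
    if (fit[gb] < best_fit) {
      best_fit <- fit[gb]
      best_genes <- pop[gb, ]
    }
    trace[gen] <- best_fit
  }
  best_traj <- collocation_trajectory(best_genes[1:3], best_genes[4:6],
                                      span = span)
  final <- evaluate_trajectory(best_traj, morph, aero, obj, sim, axes)
  structure(list(best_trajectory = best_traj, best_fitness = best_fit,
                 yaw = final$yaw, pitch = final$pitch, roll = final$roll,
                 fitness_trace = trace,
                 archive = as.data.frame(archive),
                 n_evaluations = evals, config = cfg, axes = axes),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf(paste0(
    "GA trajectory search: %d evaluations\n",
    "  best fitness: %.3f  (yaw %.2f deg, pitch %.2f, roll %.2f)\n",
    "  best points (deg): pitch [%s], roll [%s]\n"),
    x$n_evaluations, x$best_fitness, x$yaw, x$pitch, x$roll,
    paste(sprintf("%.1f", x$best_trajectory$pitch_points), collapse = ", "),
    paste(sprintf("%.1f", x$best_trajectory$roll_points), collapse = ", ")))
  invisible(x)
}

#' Count stroke-direction reversals of a tail trajectory
#'
#' Number of sign changes of the joint angular rate, summed over both
#' axes, ignoring episodes where the rate is below `threshold` times the
#' axis' peak rate. A single out-and-return sweep scores 1 per active
#' axis; figure-eight-like trajectories score higher.
#'
#' @param traj a [collocation_trajectory()].
#' @param n sampling resolution over the stroke span.
#' @param threshold relative rate magnitude below which motion does not
#'   count as a stroke (reversals among sub-threshold jitter are ignored).
#' @return integer reversal count.
#' @export
count_stroke_reversals <- function(traj, n = 1001, threshold = 0.2) {
  drive <- spline_from_points(traj)
  tt <- seq(0, traj$span, length.out = n)
  tt <- tt[-c(1, n)]
  qd <- t(vapply(tt, drive$qd_fun, numeric(2)))
  total <- 0L
  for (ax in 1:2) {
    v <- qd[, ax]
    peak <- max(abs(v))
    if (peak == 0) next
    s <- sign(v)[abs(v) > threshold * peak]
    if (length(s) > 1) total <- total + sum(diff(s) != 0)
  }
  total
}
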