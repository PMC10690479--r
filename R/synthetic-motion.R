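## Ground-truth trajectory simulation for the motion regimes seen in live
## imaging of membrane cargo: immobile particles, Brownian diffusion,
## constant-velocity directed transport, and a bidirectional run-and-pause
## process emulating motor-driven apical/basal movement.

#' Specification of a trajectory simulation
#'
#' @param regime one of "stationary", "diffusive", "directed",
#'   "run_and_pause".
#' @param n_particles number of particles.
#' @param n_frames frames per trajectory.
#' @param frame_interval_s frame interval, seconds.
#' @param D diffusion coefficient, nm^2/s (diffusive regime; per-axis step
#'   variance is 2*D*dt).
#' @param v speed, nm/s (directed regime).
#' @param direction unit vector (x, y) for directed motion.
#' @param dwell_s mean exponential dwell time per state, named
#'   c(apical=, basal=, stationary=) seconds (run_and_pause).
#' @param v_run speed during apical/basal runs, nm/s (run_and_pause); may be
#'   a named vector c(apical=, basal=).
#' @param p_apical probability that a pause ends in an apical run
#'   (run_and_pause); runs always return to the stationary state.
#' @param D_stationary diffusion during pauses, nm^2/s (run_and_pause).
#' @param axis apical unit vector (x, y); default (0, -1), i.e. apical is
#'   toward the image top.
#' @param origin_nm c(x, y) mean initial position, nm.
#' @param origin_spread_nm sd of the initial position around `origin_nm`.
#' @param bounds_nm optional c(xmin, xmax, ymin, ymax) reflecting box, nm;
#'   keeps particles renderable inside an image.
#' @param seed integer RNG seed.
#' @return a `motion_spec` list.
#' @export
motion_spec <- function(regime = c("stationary", "diffusive", "directed",
                                   "run_and_pause"),
                        n_particles = 10L, n_frames = 100L,
                        frame_interval_s = 0.057,
                        D = 1e4, v = 500, direction = c(1, 0),
                        dwell_s = c(apical = 2, basal = 1, stationary = 2),
                        v_run = c(apical = 500, basal = 500),
                        p_apical = 0.5, D_stationary = 0,
                        axis = c(0, -1),
                        origin_nm = NULL, origin_spread_nm = 0,
                        bounds_nm = NULL, seed = 1L) {
  regime <- match.arg(regime)
  stopifnot(n_particles >= 0, n_frames >= 1, frame_interval_s > 0,
            D >= 0, v >= 0, all(v_run >= 0), D_stationary >= 0,
            all(dwell_s > 0), p_apical >= 0, p_apical <= 1)
  direction <- direction / sqrt(sum(direction^2))
  axis <- axis / sqrt(sum(axis^2))
  structure(list(regime = regime, n_particles = as.integer(n_particles),
                 n_frames = as.integer(n_frames),
                 frame_interval_s = frame_interval_s, D = D, v = v,
                 direction = direction, dwell_s = dwell_s, v_run = v_run,
                 p_apical = p_apical, D_stationary = D_stationary,
                 axis = axis, origin_nm = origin_nm,
                 origin_spread_nm = origin_spread_nm,
                 bounds_nm = bounds_nm, seed = as.integer(seed)),
            class = "motion_spec")
}

reflect1 <- function(x, lo, hi) {
  span <- 2 * (hi - lo)
  x <- (x - lo) %% span
  x <- ifelse(x > (hi - lo), span - x, x)
  x + lo
}

## Sample a semi-Markov state sequence at the frame grid: exponential dwell
## per state; apical/basal runs relax to the stationary state, pauses exit
## to apical with probability p_apical, else basal.
sample_state_sequence <- function(n_frames, dt, dwell_s, p_apical) {
  states <- character(n_frames)
  t_now <- 0
  state <- if (runif(1) < p_apical) "apical" else "basal"
  t_next <- rexp(1, 1 / dwell_s[[state]])
  for (i in seq_len(n_frames)) {
    while (t_now >= t_next) {
      state <- if (state == "stationary") {
        if (runif(1) < p_apical) "apical" else "basal"
      } else "stationary"
      t_next <- t_next + rexp(1, 1 / dwell_s[[state]])
    }
    states[i] <- state
    t_now <- t_now + dt
  }
  states
}

#' Simulate ground-truth trajectories
#'
#' Positions are exact (no localization error) and in nanometres. Diffusive
#' steps are Gaussian with per-axis variance 2*D*dt; directed motion adds
#' v*dt along the given direction each frame; the run-and-pause regime
#' switches between apical runs, basal runs and pauses with exponential
#' dwell times. When `bounds_nm` is set, positions are reflected back into
#' the box.
#'
#' @param spec a [motion_spec].
#' @return data.frame with columns track_id, frame, t_s, x_nm, y_nm, state,
#'   with attributes `frame_interval_s` and `motion_spec`.
#' @examples
#' tr <- simulate_trajectories(motion_spec("directed", n_particles = 1,
#'                                         n_frames = 5, v = 500))
#' diff(tr$x_nm)   # 500 * 0.057 = 28.5 nm per frame
#' @export
simulate_trajectories <- function(spec) {
  stopifnot(inherits(spec, "motion_spec"))
  n <- spec$n_particles; nf <- spec$n_frames; dt <- spec$frame_interval_s
  with_seed(spec$seed, {
    out <- vector("list", n)
    origin <- spec$origin_nm %||% c(0, 0)
    for (p in seq_len(n)) {
      x0 <- origin[1] + rnorm(1, 0, spec$origin_spread_nm)
      y0 <- origin[2] + rnorm(1, 0, spec$origin_spread_nm)
      state <- rep("stationary", nf)
      dx <- dy <- numeric(nf - 1)
      if (spec$regime == "diffusive") {
        sdstep <- sqrt(2 * spec$D * dt)
        dx <- rnorm(nf - 1, 0, sdstep); dy <- rnorm(nf - 1, 0, sdstep)
        state <- rep("diffusive", nf)
      } else if (spec$regime == "directed") {
        dx <- rep(spec$v * dt * spec$direction[1], nf - 1)
        dy <- rep(spec$v * dt * spec$direction[2], nf - 1)
        state <- rep("directed", nf)
      } else if (spec$regime == "run_and_pause") {
        state <- sample_state_sequence(nf, dt, spec$dwell_s, spec$p_apical)
        v_run <- if (length(spec$v_run) == 1L)
          c(apical = unname(spec$v_run), basal = unname(spec$v_run)) else spec$v_run
        sdp <- sqrt(2 * spec$D_stationary * dt)
        for (i in seq_len(nf - 1)) {
          s <- state[i]
          if (s == "apical") {
            dx[i] <- v_run[["apical"]] * dt * spec$axis[1]
            dy[i] <- v_run[["apical"]] * dt * spec$axis[2]
          } else if (s == "basal") {
            dx[i] <- -v_run[["basal"]] * dt * spec$axis[1]
            dy[i] <- -v_run[["basal"]] * dt * spec$axis[2]
          } else if (sdp > 0) {
            dx[i] <- rnorm(1, 0, sdp); dy[i] <- rnorm(1, 0, sdp)
          }
        }
      }
      x <- x0 + c(0, cumsum(dx)); y <- y0 + c(0, cumsum(dy))
      if (!is.null(spec$bounds_nm)) {
        b <- spec$bounds_nm
        x <- reflect1(x, b[1], b[2]); y <- reflect1(y, b[3], b[4])
      }
      out[[p]] <- data.frame(track_id = p, frame = seq_len(nf),
                             t_s = (seq_len(nf) - 1) * dt,
                             x_nm = x, y_nm = y, state = state)
    }
    res <- if (n > 0) do.call(rbind, out) else
      data.frame(track_id = integer(0), frame = integer(0), t_s = numeric(0),
                 x_nm = numeric(0), y_nm = numeric(0), state = character(0))
    attr(res, "frame_interval_s") <- dt
    attr(res, "motion_spec") <- spec
    res
  })
}
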