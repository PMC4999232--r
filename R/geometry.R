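# Lissajous curve geometry: self-occlusion phases, occlusion event
# schedules, overlap durations, parameter-relation multipliers, and the
# randomized run schedule.
#
# The projected figure x = r sin(a t), y = r cos(b t + delta) is the
# orthographic projection of the rigid 3D curve
#   (r sin(a t), r cos(b t), r sin(b t))
# rotated by delta about the horizontal (x) axis, with the z coordinate as
# depth. Both depth interpretations (z and -z) project to the same planar
# figure, which is why the rotation direction is ambiguous at every phase.
# A configuration is *self-occluding* when the curve coincides with its
# depth-reversed counterpart point-for-point, i.e. when every dot on the
# figure could equally belong to the front or the back surface. Because
# depth reversal of the rotated curve equals rotating the base curve by
# -2*delta, self-occlusion holds exactly when rotation by 2*delta is a
# symmetry of the base curve; for a = 3, b = 6 this happens at delta = 0
# and 180 degrees only.

.curve3d <- function(params, n) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  r <- params$size_deg / 2
  list(t = t,
       x = r * sin(params$freq_x * t),
       y = r * cos(params$freq_y * t),
       z = r * sin(params$freq_y * t))
}

# rotate (y, z) by phi radians about the x axis
.rotate_yz <- function(y, z, phi) {
  list(y = y * cos(phi) - z * sin(phi),
       z = y * sin(phi) + z * cos(phi))
}

# Depth-ambiguity metric: directed Hausdorff distance from the base curve
# rotated by 2*delta about the x axis to the polyline through the base
# curve samples. Zero exactly at self-occluding phase offsets. The
# point-to-segment form is free of grid-alignment artifacts that a
# point-to-point distance shows at rational rotation angles.
.occl_metric <- function(params, delta_deg, n_pts = 960L, n_seg = n_pts) {
  n_pts <- as.integer(ceiling(n_pts / 12) * 12)  # grid closed under symmetry
  n_seg <- as.integer(ceiling(n_seg / 12) * 12)
  cs <- .curve3d(params, n_seg)
  nxt <- c(seq_len(n_seg)[-1], 1L)
  ax <- cs$x; ay <- cs$y; az <- cs$z
  ux <- cs$x[nxt] - ax; uy <- cs$y[nxt] - ay; uz <- cs$z[nxt] - az
  L2 <- pmax(ux^2 + uy^2 + uz^2, .Machine$double.eps)
  cp <- .curve3d(params, n_pts)
  rot <- .rotate_yz(cp$y, cp$z, 2 * delta_deg * pi / 180)
  px <- cp$x; py <- rot$y; pz <- rot$z
  worst <- 0
  chunk <- max(1L, floor(4e5 / n_seg))
  for (i0 in seq(1L, n_pts, by = chunk)) {
    idx <- i0:min(n_pts, i0 + chunk - 1L)
    # segments as rows so per-segment quantities recycle without sweep()
    dx <- -outer(ax, px[idx], "-")
    dy <- -outer(ay, py[idx], "-")
    dz <- -outer(az, pz[idx], "-")
    tt <- (dx * ux + dy * uy + dz * uz) / L2
    tt[tt < 0] <- 0; tt[tt > 1] <- 1
    d2 <- (dx - tt * ux)^2 + (dy - tt * uy)^2 + (dz - tt * uz)^2
    d2 <- t(d2)
    j <- max.col(-d2, ties.method = "first")
    worst <- max(worst, max(d2[cbind(seq_along(idx), j)]))
  }
  sqrt(worst)
}

#' Sample points on the projected Lissajous curve
#'
#' @param params A [lissajous_params()] object.
#' @param phase_delta Phase offset `delta` in radians.
#' @param n_samples Number of uniformly spaced curve parameters in
#'   `[0, 2*pi)`; must be at least 8.
#' @return An `n_samples` x 2 matrix with columns `x`, `y` in degrees of
#'   visual angle, origin at the figure center, y up. The curve is closed:
#'   the sample at `t = 0` follows the final sample.
#' @examples
#' pts <- curve_points(lissajous_params(size_deg = 2), 0, 64)
#' pts[1, ]  # (0, 1): sin(0) = 0, cos(0) = 1
#' @export
curve_points <- function(params, phase_delta = 0, n_samples = 512L) {
  stopifnot(inherits(params, "stimulus_params"))
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 8L)
    stop("'n_samples' must be a count >= 8", call. = FALSE)
  t <- seq(0, 2 * pi, length.out = n_samples + 1L)[-(n_samples + 1L)]
  r <- params$size_deg / 2
  cbind(x = r * sin(params$freq_x * t),
        y = r * cos(params$freq_y * t + phase_delta))
}

#' Find the self-occlusion phases of a Lissajous figure
#'
#' Scans phase offsets for configurations in which the figure coincides
#' with its depth-reversed interpretation, so that points can no longer be
#' uniquely assigned to the front or the back of the illusory 3D object.
#' The search is a coarse grid scan over `[0, 360)` degrees followed by
#' local refinement of each candidate minimum.
#'
#' @param params A [lissajous_params()] object.
#' @param tol Acceptance tolerance on the depth-ambiguity metric, as a
#'   fraction of figure size (dimensionless).
#' @param grid_deg Coarse scan step in degrees.
#' @param refine_tol_deg Refinement tolerance in degrees.
#' @return Sorted numeric vector of phases in degrees within `[0, 360)`;
#'   empty when no self-occluding configuration exists.
#' @examples
#' self_occlusion_phases(lissajous_params())  # 0 and 180 for a = 3, b = 6
#' @export
self_occlusion_phases <- function(params, tol = 0.01, grid_deg = 0.1,
                                  refine_tol_deg = 1e-3) {
  stopifnot(inherits(params, "stimulus_params"))
  if (!is.finite(tol) || tol <= 0) stop("'tol' must be > 0", call. = FALSE)
  # coarse basin scan at 1 degree, cheap resolution
  coarse <- seq(0, 359, by = 1)
  rel <- vapply(coarse, function(d)
    .occl_metric(params, d, n_pts = 120L, n_seg = 480L), numeric(1)) /
    params$size_deg
  m <- length(rel)
  prv <- c(rel[m], rel[-m]); nxt <- c(rel[-1], rel[1])
  cand <- coarse[rel <= prv & rel < nxt & rel < 0.1]
  if (!length(cand)) return(numeric(0))
  phases <- vapply(cand, function(d0) {
    # local grid at the requested scan step, then golden-section refinement
    loc <- seq(d0 - 1, d0 + 1, by = grid_deg)
    lm <- vapply(loc, function(d)
      .occl_metric(params, d %% 360, n_pts = 240L, n_seg = 720L), numeric(1))
    d1 <- loc[which.min(lm)]
    opt <- stats::optimize(
      function(d) .occl_metric(params, d %% 360),
      lower = d1 - 2 * grid_deg, upper = d1 + 2 * grid_deg,
      tol = refine_tol_deg)
    if (opt$objective / params$size_deg < tol) opt$minimum %% 360 else NA_real_
  }, numeric(1))
  phases <- round(phases[!is.na(phases)] / refine_tol_deg) * refine_tol_deg
  phases <- sort(unique(phases %% 360))
  # merge refinements that converged onto the same minimum (incl. the
  # 0/360 wrap-around)
  if (length(phases) > 1)
    phases <- phases[c(TRUE, diff(phases) > 4 * grid_deg)]
  if (length(phases) > 1 &&
      (360 - phases[length(phases)]) + phases[1] <= 4 * grid_deg)
    phases <- phases[-length(phases)]
  phases
}

#' Schedule of self-occlusion events within a block
#'
#' The phase offset advances as `delta(t) = 360 * f * t mod 360` for a
#' shifting frequency of `f` revolutions per second; occlusion events occur
#' whenever it crosses a self-occlusion phase. With occlusion phases at 0
#' and 180 degrees the event rate is `2 f` per second and the first event
#' falls at the first crossing after block onset.
#'
#' @param condition A [condition_spec()].
#' @param block_duration_s Block duration in seconds.
#' @param occlusion_phases_deg Self-occlusion phases in degrees; the
#'   default is the `a = 3`, `b = 6` result of [self_occlusion_phases()].
#' @return An object of class `occlusion_schedule` with elements
#'   `condition`, `block_duration_s`, `event_times_s` (strictly increasing,
#'   in `(0, block_duration_s]`) and `event_phases_deg`.
#' @export
occlusion_event_times <- function(condition, block_duration_s,
                                  occlusion_phases_deg = c(0, 180)) {
  stopifnot(inherits(condition, "condition_spec"))
  if (!is.finite(block_duration_s) || block_duration_s <= 0)
    stop("'block_duration_s' must be > 0", call. = FALSE)
  f <- condition$shift_freq_rps
  times <- unlist(lapply(occlusion_phases_deg, function(p) {
    t0 <- (p / 360) / f
    tt <- t0 + seq(0L, ceiling(block_duration_s * f) + 1L) / f
    tt[tt > 1e-9 & tt <= block_duration_s + 1e-9]
  }))
  times <- sort(times)
  phases <- (360 * f * times) %% 360
  # snap rounding jitter at the 360 -> 0 wrap
  phases[phases > 360 - 1e-6] <- 0
  structure(list(condition = condition,
                 block_duration_s = block_duration_s,
                 event_times_s = times,
                 event_phases_deg = phases),
            class = "occlusion_schedule")
}

#' @export
print.occlusion_schedule <- function(x, ...) {
  cat(sprintf("<occlusion schedule '%s': %d events in %.0f s (%.2f/s)>\n",
              x$condition$label, length(x$event_times_s),
              x$block_duration_s,
              length(x$event_times_s) / x$block_duration_s))
  invisible(x)
}

#' Duration of a single self-occlusion event
#'
#' At a self-occlusion the two limbs of the figure coincide; as the phase
#' moves on they separate vertically. The event is taken to last while
#' strokes of width `line_width_deg` drawn along the two formerly
#' coincident limbs still overlap, i.e. while the maximal separation
#' between tracked limb-point pairs stays below the line width. Limb pairs
#' are detected on the `delta = 0` configuration (each point paired with
#' its equal-projection, opposite-depth partner) and tracked as the phase
#' offset grows; the phase half-width at which the separation reaches the
#' line width is converted to seconds via the shifting frequency.
#'
#' @param condition A [condition_spec()].
#' @param params A [lissajous_params()]; defaults to the standard figure at
#'   the condition's size.
#' @return Event duration in seconds (identical for both occlusion phases
#'   by symmetry).
#' @export
occlusion_event_duration <- function(condition, params = NULL) {
  stopifnot(inherits(condition, "condition_spec"))
  if (is.null(params)) params <- lissajous_params(size_deg = condition$size_deg)
  w <- params$line_width_deg
  if (w >= params$size_deg)
    stop("degenerate geometry: line width exceeds figure size", call. = FALSE)
  n <- 1440L
  cv <- .curve3d(params, n)
  r <- params$size_deg / 2
  keep <- which(abs(cv$z) > 0.3 * r)
  # pair each point with the opposite-depth point sharing its projection
  opp <- outer(cv$z[keep], cv$z, "*") < 0
  d2 <- outer(cv$x[keep], cv$x, "-")^2 + outer(cv$y[keep], cv$y, "-")^2
  d2[!opp] <- Inf
  partner <- max.col(-d2, ties.method = "first")
  # sanity: at delta = 0 each tracked point must coincide with its partner
  if (max(d2[cbind(seq_along(keep), partner)]) > (1e-6 * r)^2)
    stop("failed to pair occluding limbs at delta = 0", call. = FALSE)
  b <- params$freq_y
  gap <- function(dd) {
    ph <- dd * pi / 180
    y1 <- r * cos(b * cv$t[keep] + ph)
    y2 <- r * cos(b * cv$t[partner] + ph)
    max(abs(y1 - y2))
  }
  up <- 5
  while (gap(up) <= w && up < 90) up <- up + 5
  if (gap(up) <= w)
    stop("degenerate geometry: limbs never separate beyond line width",
         call. = FALSE)
  half_deg <- stats::uniroot(function(dd) gap(dd) - w, c(1e-6, up),
                             tol = 1e-7)$root
  2 * half_deg / (360 * condition$shift_freq_rps)
}

#' Parameter-relation multipliers for a design cell
#'
#' Expresses five stimulus parameters as multiples of their values in the
#' small/slow reference condition: `a` the number of self-occlusion events
#' per block, `b` the duration of a single self-occlusion event, `c` the
#' total occlusion time per block (`c = a * b`), `d` the planar speed of
#' the sinusoids, and `e` the speed of illusory rotation.
#'
#' @param condition A [condition_spec()] drawn from the standard 2x2
#'   design.
#' @return Named numeric vector with elements `a`, `b`, `c`, `d`, `e`.
#' @export
table1_factors <- function(condition) {
  stopifnot(inherits(condition, "condition_spec"))
  f0 <- 0.15; s0 <- 2.05
  f <- condition$shift_freq_rps; s <- condition$size_deg
  ok <- function(x, ref) any(abs(x - ref) < 1e-9)
  if (!ok(f, c(0.15, 0.30)) || !ok(s, c(2.05, 4.10)))
    stop("condition outside the 2x2 design", call. = FALSE)
  c(a = f / f0,
    b = (f0 * s0) / (f * s),
    c = s0 / s,
    d = (f * s) / (f0 * s0),
    e = f / f0)
}

#' Randomized run schedule
#'
#' A run presents each of the four conditions once in an 80-second block,
#' with 5 seconds of fixation before every block and after the last one,
#' for a total of 345 seconds. Block order is uniformly random given the
#' seed.
#'
#' @param conditions List of exactly four distinct [condition_spec()]s.
#' @param seed Integer seed for the block order; `NULL` continues the
#'   current RNG stream.
#' @param block_duration_s Block duration in seconds.
#' @param fixation_s Fixation period duration in seconds.
#' @return An object of class `run_schedule` with a `blocks` data frame
#'   (block, label, shift_freq_rps, size_deg, start_s, end_s), a
#'   `fixation_periods` data frame, `total_duration_s` and `seed`.
#' @export
run_schedule <- function(conditions, seed = NULL, block_duration_s = 80,
                         fixation_s = 5) {
  if (length(conditions) != 4L)
    stop("exactly 4 conditions are required", call. = FALSE)
  labs <- vapply(conditions, `[[`, "", "label")
  if (anyDuplicated(labs))
    stop("conditions must be distinct", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ord <- sample.int(4L)
  starts <- fixation_s + (seq_len(4L) - 1L) * (block_duration_s + fixation_s)
  blocks <- data.frame(
    block = seq_len(4L),
    label = labs[ord],
    shift_freq_rps = vapply(conditions[ord], `[[`, 0, "shift_freq_rps"),
    size_deg = vapply(conditions[ord], `[[`, 0, "size_deg"),
    start_s = starts,
    end_s = starts + block_duration_s,
    stringsAsFactors = FALSE)
  fix_starts <- c(0, blocks$end_s)
  fixations <- data.frame(start_s = fix_starts, end_s = fix_starts + fixation_s)
  structure(list(blocks = blocks,
                 fixation_periods = fixations,
                 total_duration_s = max(fixations$end_s),
                 seed = seed,
                 conditions = conditions[ord]),
            class = "run_schedule")
}

#' @export
print.run_schedule <- function(x, ...) {
  cat(sprintf("<run schedule: %s; %.0f s total>\n",
              paste(x$blocks$label, collapse = " -> "), x$total_duration_s))
  invisible(x)
}
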