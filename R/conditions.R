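# Containers for stimulus parameters and the 2x2 experimental design
# (shifting frequency 0.15/0.30 rps x size 2.05/4.10 deg).

#' Lissajous stimulus parameters
#'
#' The figure is the planar curve `x(t) = (size/2) sin(a t)`,
#' `y(t) = (size/2) cos(b t + delta)` with `t` in `[0, 2*pi)` and a phase
#' offset `delta` that increases continuously during presentation. The
#' default `a = 3`, `b = 6` figure is perceived as a 3D object rotating in
#' depth with ambiguous direction.
#'
#' @param freq_x Integer sinusoid frequency `a` of the horizontal component.
#' @param freq_y Integer sinusoid frequency `b` of the vertical component.
#' @param line_width_deg Stroke width used for rendering, in degrees of
#'   visual angle. Determines how long the two limbs of the figure remain
#'   overlapping around a self-occlusion.
#' @param size_deg Edge length of the square bounding box in degrees of
#'   visual angle.
#' @return An object of class `stimulus_params`.
#' @export
lissajous_params <- function(freq_x = 3L, freq_y = 6L, line_width_deg = 0.10,
                             size_deg = 2.05) {
  freq_x <- as.integer(freq_x)
  freq_y <- as.integer(freq_y)
  if (freq_x < 1L || freq_y < 1L)
    stop("sinusoid frequencies must be positive integers", call. = FALSE)
  if (!is.finite(line_width_deg) || line_width_deg <= 0)
    stop("'line_width_deg' must be > 0", call. = FALSE)
  if (!is.finite(size_deg) || size_deg <= 0)
    stop("'size_deg' must be > 0", call. = FALSE)
  structure(list(freq_x = freq_x, freq_y = freq_y,
                 line_width_deg = line_width_deg, size_deg = size_deg),
            class = "stimulus_params")
}

#' One cell of the 2x2 design
#'
#' @param shift_freq_rps Shifting frequency of the phase offset, in
#'   revolutions per second (0.15 or 0.30 in the standard design).
#' @param size_deg Figure size in degrees (2.05 or 4.10 in the standard
#'   design).
#' @param label Optional condition label; derived from the factor levels
#'   when omitted.
#' @return An object of class `condition_spec`.
#' @export
condition_spec <- function(shift_freq_rps, size_deg, label = NULL) {
  if (!is.finite(shift_freq_rps) || shift_freq_rps <= 0)
    stop("'shift_freq_rps' must be > 0", call. = FALSE)
  if (!is.finite(size_deg) || size_deg <= 0)
    stop("'size_deg' must be > 0", call. = FALSE)
  if (is.null(label)) {
    speed <- if (isTRUE(all.equal(shift_freq_rps, 0.15))) "slow"
             else if (isTRUE(all.equal(shift_freq_rps, 0.30))) "fast"
             else sprintf("f%.3g", shift_freq_rps)
    dim <- if (isTRUE(all.equal(size_deg, 2.05))) "small"
           else if (isTRUE(all.equal(size_deg, 4.10))) "big"
           else sprintf("s%.3g", size_deg)
    label <- paste(speed, dim, sep = "_")
  }
  structure(list(shift_freq_rps = shift_freq_rps, size_deg = size_deg,
                 label = label),
            class = "condition_spec")
}

#' The standard 2x2 design
#'
#' Crosses shifting frequency (0.15 vs 0.30 rps) with figure size (2.05 vs
#' 4.10 degrees), yielding the four conditions presented once per run.
#'
#' @return Named list of four [condition_spec()] objects.
#' @export
study_design <- function() {
  conds <- list(
    condition_spec(0.15, 2.05),
    condition_spec(0.30, 2.05),
    condition_spec(0.15, 4.10),
    condition_spec(0.30, 4.10)
  )
  names(conds) <- vapply(conds, `[[`, "", "label")
  conds
}

#' @export
print.condition_spec <- function(x, ...) {
  cat(sprintf("<condition '%s': %.2f rps, %.2f deg>\n",
              x$label, x$shift_freq_rps, x$size_deg))
  invisible(x)
}

#' @export
print.stimulus_params <- function(x, ...) {
  cat(sprintf("<Lissajous a=%d b=%d, size %.2f deg, line width %.2f deg>\n",
              x$freq_x, x$freq_y, x$size_deg, x$line_width_deg))
  invisible(x)
}

# split a condition label back into factor levels; internal
.condition_factors <- function(shift_freq_rps, size_deg) {
  list(freq = ifelse(shift_freq_rps > 0.2, "fast", "slow"),
       size = ifelse(size_deg > 3, "big", "small"))
}
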