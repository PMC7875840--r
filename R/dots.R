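#' Generate a non-overlapping dot-array stimulus
#'
#' Places `n_dots` dots at random inside a circular field by rejection
#' sampling, subject to the stimulus constraints of the cued-enumeration
#' task: every dot lies fully inside the field, the edge-to-edge gap between
#' any two dots is at least `min_gap` degrees, and dot diameters vary by at
#' most +/- `diameter_var` around the array's base diameter.
#'
#' Two non-numerical control modes are supported. In `size_equated` mode the
#' base diameter is the 0.25 degree default, so the average dot size is the
#' same whatever the numerosity. In `area_equated` mode the drawn diameters
#' are rescaled jointly so that the cumulative dot surface area exactly
#' matches `target_area`, decoupling total area from numerosity; the default
#' target is the area of 15 default-size dots (the midpoint of the 5-30
#' numerosity range).
#'
#' Positions are drawn uniformly over the admissible disc for each dot and
#' rejected on any constraint violation; if `max_attempts` draws are
#' exhausted before all dots are placed, the function fails with an explicit
#' packing error rather than returning an invalid array.
#'
#' @param n_dots Number of dots (>= 1).
#' @param mode `"size_equated"` or `"area_equated"`.
#' @param field_radius Radius of the circular stimulus field, in degrees of
#'   visual angle (degrees are used as abstract units; default 2, a 4-degree
#'   field).
#' @param base_diameter Default dot diameter in degrees.
#' @param diameter_var Maximum relative deviation of a dot's diameter from
#'   the base (default 0.31, i.e. +/- 31%).
#' @param min_gap Minimum edge-to-edge distance between dots, degrees.
#' @param target_area Total dot area for `area_equated` mode, square
#'   degrees.
#' @param max_attempts Cap on total rejection-sampling attempts.
#' @param seed Optional RNG seed; the array is deterministic given the seed.
#' @return Object of class `stimulus_spec`: `positions` (n x 2 matrix of dot
#'   centres), `diameters`, `field_radius`, `mode`, `target_area`.
#' @export
#' @examples
#' spec <- generate_dot_array(12, seed = 1)
#' nrow(spec$positions)
generate_dot_array <- function(n_dots,
                               mode = c("size_equated", "area_equated"),
                               field_radius = 2,
                               base_diameter = 0.25,
                               diameter_var = 0.31,
                               min_gap = 0.15,
                               target_area = NULL,
                               max_attempts = 10000,
                               seed = NULL) {
  mode <- match.arg(mode)
  if (n_dots < 1) stop("`n_dots` must be at least 1.")
  if (field_radius <= 0 || base_diameter <= 0) {
    stop("`field_radius` and `base_diameter` must be positive.")
  }
  if (!is.null(seed)) set.seed(seed)

  u <- stats::runif(n_dots, 1 - diameter_var, 1 + diameter_var)
  if (mode == "size_equated") {
    d <- base_diameter * u
  } else {
    target_area <- target_area %||% (15 * pi * (base_diameter / 2)^2)
    if (target_area <= 0) stop("`target_area` must be positive.")
    scale <- sqrt(target_area / sum(pi * (u * base_diameter / 2)^2))
    d <- scale * u * base_diameter
  }
  if (any(field_radius - d / 2 <= 0)) {
    stop("Dot packing failed: dots are too large for the field.")
  }

  pos <- matrix(NA_real_, n_dots, 2)
  attempts <- 0L
  for (i in seq_len(n_dots)) {
    repeat {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop("Dot packing failed after ", max_attempts, " attempts (",
             i - 1L, " of ", n_dots, " dots placed).")
      }
      rmax <- field_radius - d[i] / 2
      r <- rmax * sqrt(stats::runif(1))
      th <- stats::runif(1, 0, 2 * pi)
      p <- c(r * cos(th), r * sin(th))
      if (i == 1L) break
      dx <- pos[seq_len(i - 1L), 1] - p[1]
      dy <- pos[seq_len(i - 1L), 2] - p[2]
      gaps <- sqrt(dx^2 + dy^2) - (d[seq_len(i - 1L)] + d[i]) / 2
      if (all(gaps >= min_gap)) break
    }
    pos[i, ] <- p
  }

  structure(
    list(positions = pos, diameters = d, field_radius = field_radius,
         mode = mode,
         target_area = if (mode == "area_equated") target_area else NA_real_),
    class = "stimulus_spec"
  )
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf("Dot-array stimulus: %d dots, %s, field radius %g deg\n",
              nrow(x$positions), x$mode, x$field_radius))
  cat(sprintf("  diameters %.3f-%.3f deg, total area %.4f deg^2\n",
              min(x$diameters), max(x$diameters),
              sum(pi * (x$diameters / 2)^2)))
  invisible(x)
}
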