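#' Quantitative canalography analysis of a fluorescein time-lapse stack
#'
#' The main fitting function. Runs the full pipeline on one canalogram:
#' reduces the stack to a macropixel grid of block means, normalizes to
#' percent of the global maximum, builds the perilimbal annulus mask with
#' clock-hour / ring / quadrant assignments, fits a penalized-spline fill
#' curve to every included macropixel, fits the single global model over
#' the 36 perilimbal regions, imputes per-macropixel flow increments,
#' attributes flow to the four quadrants in microliters per minute, and
#' computes per-quadrant first-appearance filling times.
#'
#' @param stack a [canalogram_stack()] (or the list returned by
#'   [generate()], whose stack and geometry are then used).
#' @param geometry an [eye_geometry()]; not needed when `stack` comes from
#'   [generate()].
#' @param grid_rows,grid_cols macropixel grid (default 32 x 32, i.e. 1024
#'   macropixels).
#' @param noise_floor percent of global max below which a macropixel is
#'   classified non-filling (default 5).
#' @param onset_threshold percent of global max defining first appearance
#'   of fluorescence (default 5).
#' @param total_flow_ul_min total flow that quadrant fractions are scaled
#'   to (default 3 ul/min).
#' @param flow_source `"global"` (flow increments from the 36-region global
#'   fit; default) or `"individual"` (from per-macropixel fits).
#' @param fit_macropixels set `FALSE` to skip the per-macropixel fits (the
#'   global fit then also supplies the filling classification); useful for
#'   bulk runs where only regional and quadrant outputs are needed.
#' @param spline_k per-macropixel spline basis dimension cap.
#' @param eye_id,condition labels carried into the report tables.
#' @return An object of class `canaloflow` with components `series`
#'   (percent-normalized macropixel series), `assignment`, `fits`,
#'   `regional`, `increments`, `quadrants` (flows and filling times),
#'   `profile` (per-clock-hour summary), and the call parameters.
#' @examples
#' sp <- preset("whole_eye", seed = 1, rows = 96, cols = 96)
#' sim <- generate(sp, grid_rows = 16, grid_cols = 16)
#' fit <- canaloflow(sim, grid_rows = 16, grid_cols = 16,
#'                   fit_macropixels = FALSE)
#' fit$quadrants
#' @export
canaloflow <- function(stack, geometry = NULL, grid_rows = 32L,
                       grid_cols = 32L, noise_floor = 5,
                       onset_threshold = 5, total_flow_ul_min = 3,
                       flow_source = c("global", "individual"),
                       fit_macropixels = TRUE, spline_k = 10L,
                       eye_id = NA_character_, condition = NA_character_) {
  flow_source <- match.arg(flow_source)
  if (!inherits(stack, "canalogram_stack") && is.list(stack) &&
      inherits(stack$stack, "canalogram_stack")) {
    if (is.null(geometry)) geometry <- stack$geometry
    stack <- stack$stack
  }
  stopifnot(inherits(stack, "canalogram_stack"),
            inherits(geometry, "eye_geometry"))
  if (flow_source == "individual" && !fit_macropixels)
    stop("flow_source = \"individual\" requires fit_macropixels = TRUE")

  series <- normalize_percent(downsample(stack, grid_rows, grid_cols))
  assignment <- build_mask(geometry, series)
  if (sum(assignment$included) == 0L)
    stop("no macropixels inside the analysis annulus")

  fits <- if (fit_macropixels)
    fit_all(series, assignment, noise_floor = noise_floor,
            spline_k = spline_k) else NULL
  regions <- aggregate_regions(series, assignment)
  regional <- fit_global(regions)
  increments <- impute_flow(fits = fits, regional = regional,
                            assignment = assignment, source = flow_source,
                            noise_floor = noise_floor)
  flows <- quadrant_flows(increments, total_flow_ul_min = total_flow_ul_min)
  ftime <- quadrant_filling_time(series, assignment,
                                 onset_threshold = onset_threshold)
  quadrants <- merge(flows, ftime, by = "quadrant", sort = FALSE)
  quadrants <- quadrants[match(c("IN", "SN", "ST", "IT"), quadrants$quadrant), ]
  rownames(quadrants) <- NULL
  quadrants <- cbind(eye_id = eye_id, condition = condition, quadrants,
                     stringsAsFactors = FALSE)

  structure(
    list(series = series, assignment = assignment, fits = fits,
         regions = regions, regional = regional, increments = increments,
         quadrants = quadrants, profile = circumferential_profile(regional),
         params = list(grid_rows = grid_rows, grid_cols = grid_cols,
                       noise_floor = noise_floor,
                       onset_threshold = onset_threshold,
                       total_flow_ul_min = total_flow_ul_min,
                       flow_source = flow_source, spline_k = spline_k),
         eye_id = eye_id, condition = condition,
         laterality = stack$laterality),
    class = "canaloflow")
}

#' @export
print.canaloflow <- function(x, ...) {
  cat("Quantitative canalography fit\n")
  cat(sprintf("  %d x %d macropixels, %d included, flow basis: %s\n",
              x$params$grid_rows, x$params$grid_cols,
              sum(x$assignment$included), x$params$flow_source))
  cat("  quadrant flows (ul/min):\n")
  q <- x$quadrants
  for (i in seq_len(nrow(q)))
    cat(sprintf("    %s: %.2f (fraction %.3f, filling time %.1f min%s)\n",
                q$quadrant[i], q$flow_ul_min[i], q$flow_fraction[i],
                q$filling_time_min[i],
                if (q$censored[i]) ", censored" else ""))
  invisible(x)
}

#' @export
summary.canaloflow <- function(object, ...) {
  x <- object
  tab <- x$regional$table
  s <- list(
    quadrants = x$quadrants,
    n_included = sum(x$assignment$included),
    n_filling = if (!is.null(x$fits)) sum(x$fits$filling) else NA_integer_,
    n_regions = sum(!tab$empty),
    deviance_explained = x$regional$deviance_explained,
    t_half_range_s = range(tab$t_half_s, na.rm = TRUE),
    profile = x$profile)
  class(s) <- "summary.canaloflow"
  s
}

#' @export
print.summary.canaloflow <- function(x, ...) {
  cat("Quantitative canalography summary\n")
  cat(sprintf("  included macropixels: %d (%s filling)\n", x$n_included,
              ifelse(is.na(x$n_filling), "regional-only", x$n_filling)))
  cat(sprintf("  non-empty perilimbal regions: %d / 36\n", x$n_regions))
  cat(sprintf("  global model deviance explained: %.1f%%\n",
              100 * x$deviance_explained))
  cat(sprintf("  region t_half range: %.0f-%.0f s\n",
              x$t_half_range_s[1], x$t_half_range_s[2]))
  print(x$quadrants, digits = 3)
  invisible(x)
}

#' @export
coef.canaloflow <- function(object, ...) {
  stats::setNames(object$quadrants$flow_ul_min, object$quadrants$quadrant)
}

#' Per-macropixel results table of a canalography fit
#'
#' @param x a `canaloflow` object.
#' @param ... unused.
#' @return Data frame with one row per macropixel: grid position, region
#'   labels, inclusion/filling flags, kinetics (when individual fits were
#'   run) and flow columns.
#' @export
as.data.frame.canaloflow <- function(x, ...) {
  base <- x$assignment[, c("grid_row", "grid_col", "radius_px", "angle_deg",
                           "included", "clock_hour", "ring", "quadrant")]
  base$excluded <- !base$included
  if (!is.null(x$fits)) {
    kin <- x$fits[, c("baseline", "I_max", "I_half", "t_half_s",
                      "filling_rate", "dynamic_range", "filling", "failed")]
    base <- cbind(base, kin)
  }
  base$increment_pct_per_frame <- x$increments$increment
  qf <- x$quadrants
  frac <- stats::setNames(qf$flow_fraction, qf$quadrant)
  tot_inc <- sum(x$increments$increment[x$increments$included])
  base$flow_ul_min <- ifelse(
    base$included & tot_inc > 0,
    x$increments$increment / tot_inc * x$params$total_flow_ul_min,
    0)
  base
}
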