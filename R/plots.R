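# perceptually ordered blue -> red ramp used for rate encoding; anchors
# chosen so red-minus-blue grows strictly along the ramp
blue_red_ramp <- function(n = 256) {
  grDevices::colorRampPalette(c("#0571B0", "#92C5DE", "#F7F7F7",
                                "#F4A582", "#CA0020"))(n)
}

map_to_unit <- function(v, lo = min(v), hi = max(v)) {
  if (hi == lo) rep(0.5, length(v)) else pmin(pmax((v - lo) / (hi - lo), 0), 1)
}

#' Dot plot of per-macropixel fill kinetics
#'
#' One marker per included, filling macropixel: marker area grows linearly
#' with the fitted maximum intensity (brighter macropixels draw larger) and
#' color runs along a blue-to-red ramp with the filling rate (faster
#' filling draws redder). Excluded and non-filling macropixels are absent.
#' For display the grid is rotated so that the quadrants appear in the
#' conventional SN, IN, IT, ST clockwise order; analysis coordinates are
#' never rotated.
#'
#' @param fits a `fill_fits` table from [fit_all()].
#' @param assignment the matching `polar_assignment` (unused beyond sanity
#'   checks; the fits table carries its labels).
#' @param draw draw the figure (default TRUE); set FALSE to only build the
#'   spec.
#' @param area_range marker area range in squared character-expansion
#'   units.
#' @return Invisibly, the dot-plot spec: a data frame with `grid_row`,
#'   `grid_col`, `I_max`, `filling_rate`, `marker_area`, `color`.
#' @export
dot_plot <- function(fits, assignment = NULL, draw = TRUE,
                     area_range = c(0.15, 2.5)) {
  sel <- fits$included & fits$filling & !fits$failed &
    !is.na(fits$filling_rate)
  spec <- fits[sel, c("grid_row", "grid_col", "I_max", "filling_rate")]
  if (nrow(spec) > 0) {
    # area (not radius) linear in I_max keeps perceived size honest
    u_area <- map_to_unit(spec$I_max, 0, max(spec$I_max))
    spec$marker_area <- area_range[1] + u_area * diff(area_range)
    ramp <- blue_red_ramp()
    u_col <- map_to_unit(spec$filling_rate)
    spec$color <- ramp[1 + floor(u_col * (length(ramp) - 1))]
  } else {
    spec$marker_area <- numeric(0)
    spec$color <- character(0)
  }
  if (draw) {
    gr <- max(fits$grid_row); gc <- max(fits$grid_col)
    graphics::plot(NA, xlim = c(0.5, gc + 0.5), ylim = c(gr + 0.5, 0.5),
                   asp = 1, xlab = "macropixel column",
                   ylab = "macropixel row", main = "Fill kinetics dot plot")
    if (nrow(spec) > 0)
      graphics::points(spec$grid_col, spec$grid_row, pch = 16,
                       cex = sqrt(spec$marker_area), col = spec$color)
  }
  invisible(spec)
}

#' Ring plot of the 36-region perilimbal model
#'
#' Draws the 12 clock-hour x 3 ring annular sectors twice: colored by time
#' to half-max (left) and by filling rate (right). Empty regions are
#' hatched rather than blank. Hour 12 sits at the top and hours advance
#' clockwise.
#'
#' @param fit a `regional_fit`.
#' @return Invisibly, the region table with the mapped colors.
#' @export
ring_plot <- function(fit) {
  stopifnot(inherits(fit, "regional_fit"))
  tab <- fit$table
  ramp <- blue_red_ramp()
  mapcol <- function(v) {
    ok <- !is.na(v)
    out <- rep(NA_character_, length(v))
    if (any(ok)) {
      u <- map_to_unit(v[ok])
      out[ok] <- ramp[1 + floor(u * (length(ramp) - 1))]
    }
    out
  }
  tab$col_t_half <- mapcol(tab$t_half_s)
  tab$col_rate <- mapcol(tab$filling_rate)

  draw_panel <- function(colname, title) {
    graphics::plot(NA, xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1), asp = 1,
                   axes = FALSE, xlab = "", ylab = "", main = title)
    radii <- seq(0.35, 1, length.out = 4)  # inner hole = cornea
    for (j in seq_len(nrow(tab))) {
      h <- tab$clock_hour[j]; r <- tab$ring[j]
      a0 <- (h * 30 - 15 - 90) * pi / 180  # hour centered, 12 at top
      a1 <- (h * 30 + 15 - 90) * pi / 180
      th <- seq(a0, a1, length.out = 16)
      r0 <- radii[r]; r1 <- radii[r + 1]
      px <- c(r0 * cos(th), rev(r1 * cos(th)))
      py <- -c(r0 * sin(th), rev(r1 * sin(th)))  # flip: clockwise on screen
      if (tab$empty[j] || is.na(tab[[colname]][j])) {
        graphics::polygon(px, py, col = NA, border = "grey40",
                          density = 12, angle = 45)
      } else {
        graphics::polygon(px, py, col = tab[[colname]][j], border = "grey40")
      }
    }
    graphics::text(0, 1.07, "12"); graphics::text(1.07, 0, "3")
    graphics::text(0, -1.07, "6"); graphics::text(-1.07, 0, "9")
  }
  old <- graphics::par(mfrow = c(1, 2), mar = c(1, 1, 3, 1))
  on.exit(graphics::par(old))
  draw_panel("col_t_half", "Time to half-max")
  draw_panel("col_rate", "Filling rate")
  invisible(tab)
}

#' Time-lapse montage of selected frames
#'
#' Displays the frames nearest to the requested times side by side,
#' annotated in minutes.
#'
#' @param stack a `canalogram_stack`.
#' @param times_min times to display, minutes, within the stack duration.
#' @return Invisibly, the 1-based frame indices shown.
#' @export
montage <- function(stack, times_min = c(0, 5, 10, 20)) {
  stopifnot(inherits(stack, "canalogram_stack"))
  tt <- frame_times(stack)
  dur_min <- (tt[length(tt)] - tt[1]) / 60
  if (any(times_min < 0 | times_min > dur_min))
    stop(sprintf("requested time outside stack duration; valid range 0-%g min",
                 dur_min))
  idx <- as.integer(round((times_min * 60 - stack$t0_s) /
                            stack$frame_interval_s)) + 1L
  idx <- pmin(pmax(idx, 1L), length(tt))
  old <- graphics::par(mfrow = c(1, length(idx)), mar = c(0.5, 0.5, 2, 0.5))
  on.exit(graphics::par(old))
  gmax <- max(stack$frames)
  for (j in seq_along(idx)) {
    m <- stack$frames[idx[j], , ]
    graphics::image(t(m[nrow(m):1, ]) / max(gmax, 1),
                    col = grDevices::gray.colors(256, 0, 1), axes = FALSE,
                    main = sprintf("%g min", times_min[j]), useRaster = TRUE)
  }
  invisible(idx)
}

#' Plot method for canalography fits
#'
#' @param x a `canaloflow` object.
#' @param type `"dots"` (per-macropixel dot plot), `"rings"` (36-region
#'   ring plot) or `"profile"` (circumferential t_half profile).
#' @param ... unused.
#' @export
plot.canaloflow <- function(x, type = c("dots", "rings", "profile"), ...) {
  type <- match.arg(type)
  if (type == "dots") {
    if (is.null(x$fits))
      stop("no per-macropixel fits stored; rerun with fit_macropixels = TRUE")
    dot_plot(x$fits, x$assignment)
  } else if (type == "rings") {
    ring_plot(x$regional)
  } else {
    pr <- x$profile
    graphics::plot(pr$clock_hour, pr$t_half_s / 60, type = "b", pch = 16,
                   xlab = "clock hour", ylab = "time to half-max (min)",
                   main = "Circumferential profile", xaxt = "n")
    graphics::axis(1, at = 1:12)
  }
  invisible(x)
}
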