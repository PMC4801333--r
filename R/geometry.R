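#' Per-eye analysis geometry
#'
#' The analysis region is a perilimbal annulus: the corneal disk (and, for
#' anterior segment cultures, the scleral compression ring) is excluded, and
#' only macropixels forming a complete ring around the eye between
#' `corneal_radius_px` and `outer_radius_px` are analyzed. The cornea and any
#' compression ring are identified per eye and supplied here; they are never
#' segmented automatically.
#'
#' Coordinates are 0-based `(row, col)` with row 0 at the image top.
#' `superior_angle_deg` is the image direction of the superior pole, in
#' degrees clockwise from "up" (toward row 0); the default 0 means superior
#' is up.
#'
#' @param center_row,center_col corneal center in pixels (0-based).
#' @param corneal_radius_px radius of the excluded corneal disk, px.
#' @param outer_radius_px outer analysis radius, px, or `NA` to derive it
#'   later with [auto_outer_radius()].
#' @param superior_angle_deg image direction of the superior pole, degrees
#'   clockwise from up (default 0).
#' @param laterality `"OD"` or `"OS"`; decides which image side is nasal.
#' @param ring_inner_radius_px optional inner radius of an excluding
#'   compression-ring annulus (everything at or beyond it is excluded).
#' @return An object of class `eye_geometry`.
#' @export
eye_geometry <- function(center_row, center_col, corneal_radius_px,
                         outer_radius_px = NA_real_, superior_angle_deg = 0,
                         laterality = c("OD", "OS"),
                         ring_inner_radius_px = NA_real_) {
  laterality <- match.arg(laterality)
  if (corneal_radius_px < 0) stop("'corneal_radius_px' must be >= 0")
  if (!is.na(outer_radius_px) && outer_radius_px <= corneal_radius_px)
    stop("'outer_radius_px' must exceed 'corneal_radius_px'")
  structure(
    list(center_row = as.numeric(center_row),
         center_col = as.numeric(center_col),
         corneal_radius_px = as.numeric(corneal_radius_px),
         outer_radius_px = as.numeric(outer_radius_px),
         superior_angle_deg = as.numeric(superior_angle_deg),
         laterality = laterality,
         ring_inner_radius_px = as.numeric(ring_inner_radius_px)),
    class = "eye_geometry")
}

#' @export
print.eye_geometry <- function(x, ...) {
  cat(sprintf("Eye geometry (%s): center (%g, %g), cornea r=%g px, outer r=%s px\n",
              x$laterality, x$center_row, x$center_col, x$corneal_radius_px,
              if (is.na(x$outer_radius_px)) "auto" else format(x$outer_radius_px)))
  invisible(x)
}

#' Read an eye geometry config from YAML or JSON
#'
#' Recognized fields: `center_row`, `center_col`, `corneal_radius_px`,
#' `outer_radius_px` (a number or `"auto"`), `superior_angle_deg`,
#' `laterality`, `ring_inner_radius_px`.
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return An [eye_geometry()].
#' @export
read_geometry <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::fromJSON(path),
                stop("unsupported config format: ", path))
  outer <- cfg$outer_radius_px
  if (is.null(outer) || identical(outer, "auto")) outer <- NA_real_
  eye_geometry(center_row = cfg$center_row, center_col = cfg$center_col,
               corneal_radius_px = cfg$corneal_radius_px,
               outer_radius_px = as.numeric(outer),
               superior_angle_deg = cfg$superior_angle_deg %||% 0,
               laterality = cfg$laterality %||% "OD",
               ring_inner_radius_px = as.numeric(cfg$ring_inner_radius_px %||% NA))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# polar angle of an image point, degrees clockwise from the superior pole
# (image "up" rotated by superior_angle_deg), in [0, 360)
polar_angle_deg <- function(d_row, d_col, superior_angle_deg = 0) {
  ang <- atan2(d_col, -d_row) * 180 / pi - superior_angle_deg
  ang %% 360
}

#' Assign an anatomical quadrant from a polar angle
#'
#' Quadrants are the four 90-degree sectors bounded by the vertical and
#' horizontal meridians through the corneal center: superonasal (SN),
#' inferonasal (IN), inferotemporal (IT), superotemporal (ST). The angle is
#' measured from the superior pole, positive clockwise in the displayed
#' image. For a right eye (OD) the nasal side is image-left; for a left eye
#' (OS) it is image-right, so flipping laterality swaps IN with IT and SN
#' with ST at the same image angle. An angle exactly on a meridian belongs
#' to the clockwise-following sector.
#'
#' @param angle_deg polar angle(s) in degrees from the superior pole,
#'   clockwise positive; wraps modulo 360.
#' @param laterality `"OD"` or `"OS"`.
#' @return Character vector of `"IN"`, `"SN"`, `"ST"`, `"IT"`.
#' @export
assign_quadrant <- function(angle_deg, laterality = c("OD", "OS")) {
  laterality <- match.arg(laterality)
  a <- angle_deg %% 360
  sector <- findInterval(a, c(0, 90, 180, 270))  # 1..4, left-closed
  # sector 1: superior + image-right, 2: inferior + image-right,
  # 3: inferior + image-left, 4: superior + image-left
  od <- c("ST", "IT", "IN", "SN")  # OD: nasal is image-left
  os <- c("SN", "IN", "IT", "ST")  # OS mirror
  if (laterality == "OD") od[sector] else os[sector]
}

# clock hour from polar angle; hour h spans [h*30 - 15, h*30 + 15) degrees,
# hour 12 centered on the superior pole, hours advancing clockwise
clock_hour_from_angle <- function(angle_deg) {
  h <- floor(((angle_deg %% 360) + 15) / 30) %% 12
  ifelse(h == 0, 12L, as.integer(h))
}

#' Derive the largest complete analysis ring
#'
#' Returns the largest outer radius such that the full circle around the
#' corneal center stays inside the image bounds and clear of any
#' compression-ring exclusion, guaranteeing a complete ring around the eye.
#' Image extent is taken as `[-0.5, n - 0.5]` in each axis (pixel centers at
#' integer coordinates).
#'
#' @param geometry an [eye_geometry()] (its `outer_radius_px` may be `NA`).
#' @param image_dim `c(rows, cols)` of the image, or a `canalogram_stack`.
#' @param ring_inner_radius_px optional compression-ring inner radius;
#'   defaults to the geometry's own.
#' @return The outer radius in pixels.
#' @export
auto_outer_radius <- function(geometry, image_dim,
                              ring_inner_radius_px = NULL) {
  if (inherits(image_dim, "canalogram_stack"))
    image_dim <- dim(image_dim$frames)[2:3]
  rim <- ring_inner_radius_px %||% geometry$ring_inner_radius_px
  r <- min(geometry$center_row + 0.5, image_dim[1] - 0.5 - geometry$center_row,
           geometry$center_col + 0.5, image_dim[2] - 0.5 - geometry$center_col)
  if (!is.na(rim)) r <- min(r, rim)
  if (r <= geometry$corneal_radius_px)
    stop("incomplete ring: no radius larger than the cornea fits the image")
  r
}

#' Build the polar macropixel assignment
#'
#' Classifies each macropixel of a grid by its center point: included iff
#' its center lies in the annulus `[corneal_radius_px, outer_radius_px]`
#' around the corneal center, then labelled with its clock hour (1-12, hour
#' 12 superior, clockwise), perilimbal ring (1-3, three equal-radial-width
#' rings from cornea outward; a radius exactly on a ring boundary goes to
#' the inner ring), and anatomical quadrant (IN/SN/ST/IT).
#'
#' @param geometry an [eye_geometry()]; if its `outer_radius_px` is `NA` it
#'   is derived with [auto_outer_radius()] from the grid's image extent.
#' @param grid a [macropixel_series()] (only its geometry is used).
#' @return A `polar_assignment`: a data frame with one row per macropixel
#'   (`grid_row`, `grid_col`, `center_row`, `center_col`, `radius_px`,
#'   `angle_deg`, `included`, `clock_hour`, `ring`, `quadrant`) plus the
#'   geometry as an attribute.
#' @export
build_mask <- function(geometry, grid) {
  stopifnot(inherits(geometry, "eye_geometry"))
  img_dim <- attr(grid, "image_dim") %||% grid$image_dim
  if (is.na(geometry$outer_radius_px)) {
    geometry$outer_radius_px <- auto_outer_radius(geometry, img_dim)
  } else {
    lim <- min(geometry$center_row + 0.5, img_dim[1] - 0.5 - geometry$center_row,
               geometry$center_col + 0.5, img_dim[2] - 0.5 - geometry$center_col)
    if (geometry$outer_radius_px > lim + 1e-9)
      stop("incomplete ring: analysis circle exceeds image bounds")
  }
  ctr <- grid$centers_px
  d_row <- ctr$center_row - geometry$center_row
  d_col <- ctr$center_col - geometry$center_col
  r <- sqrt(d_row^2 + d_col^2)
  ang <- polar_angle_deg(d_row, d_col, geometry$superior_angle_deg)

  r_c <- geometry$corneal_radius_px
  r_o <- geometry$outer_radius_px
  included <- r >= r_c & r <= r_o
  if (!is.na(geometry$ring_inner_radius_px))
    included <- included & r < geometry$ring_inner_radius_px

  # ring boundary goes to the inner ring: ceiling puts r exactly at a
  # boundary into the lower ring; clamp handles r == r_c
  ring <- ifelse(included,
                 pmin(pmax(ceiling(3 * (r - r_c) / (r_o - r_c)), 1L), 3L),
                 NA_integer_)
  hour <- ifelse(included, clock_hour_from_angle(ang), NA_integer_)
  quad <- rep(NA_character_, length(r))
  quad[included] <- assign_quadrant(ang[included], geometry$laterality)

  out <- data.frame(grid_row = ctr$grid_row, grid_col = ctr$grid_col,
                    center_row = ctr$center_row, center_col = ctr$center_col,
                    radius_px = r, angle_deg = ang, included = included,
                    clock_hour = as.integer(hour),
                    ring = as.integer(ring),
                    quadrant = quad,
                    stringsAsFactors = FALSE)
  attr(out, "geometry") <- geometry
  class(out) <- c("polar_assignment", "data.frame")
  out
}

#' @export
print.polar_assignment <- function(x, ...) {
  cat("Polar macropixel assignment:", nrow(x), "macropixels,",
      sum(x$included), "included\n")
  if (any(x$included)) {
    tab <- table(regions = paste0("h", x$clock_hour, "r", x$ring)[x$included])
    cat("  distinct (clock hour, ring) regions:", length(tab), "\n")
    cat("  quadrant counts:",
        paste(names(table(x$quadrant)), table(x$quadrant), collapse = ", "),
        "\n")
  }
  invisible(x)
}
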