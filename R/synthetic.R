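#' Specify a synthetic fluorescein canalogram
#'
#' The generator emulates sector-wise logistic filling of perilimbal
#' vessels around a dark corneal disk: pixel intensity at time `t` is
#' `baseline + A * vesselmask(x, y) / (1 + exp(-(t - t50) / tau)) + noise`,
#' with per-clock-sector logistic parameters, additive Gaussian noise on
#' counts clipped at zero and at the bit depth, and the corneal disk held
#' at baseline. Defaults mirror the acquisition this emulates: 580 x 610 px
#' frames every 30 s for 20 min (41 frames).
#'
#' @param rows,cols image dimensions in pixels.
#' @param n_frames number of frames (41 = one per 30 s for 20 min,
#'   inclusive of t = 0).
#' @param frame_interval_s cadence, seconds.
#' @param center_row,center_col corneal center (defaults: image center).
#' @param corneal_radius_px,outer_radius_px dark corneal disk radius and
#'   outer vessel-annulus radius, px.
#' @param sectors data frame of 12 rows (`clock_hour`, `A`, `t50_s`,
#'   `tau_s`) giving each 30-degree sector's logistic fill parameters
#'   (amplitude in counts, half-rise time and time constant in seconds).
#' @param baseline baseline intensity, counts.
#' @param vessel_pattern `"annulus"` (homogeneous perilimbal annulus) or
#'   `"branches"` (radial vessel branches, display realism only).
#' @param n_branches,branch_width_deg branch count and angular width when
#'   `vessel_pattern = "branches"`.
#' @param ring_inner_radius_px optional compression-ring exclusion radius
#'   (anterior segment cultures); NA for whole eyes.
#' @param noise_sd Gaussian noise standard deviation, counts.
#' @param bit_depth 8 or 16.
#' @param laterality `"OD"` or `"OS"`.
#' @param seed integer; fully determines the generated stack.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(rows = 580L, cols = 610L, n_frames = 41L,
                           frame_interval_s = 30,
                           center_row = (rows - 1) / 2,
                           center_col = (cols - 1) / 2,
                           corneal_radius_px = 0.19 * min(rows, cols),
                           outer_radius_px = 0.46 * min(rows, cols),
                           sectors = NULL, baseline = 2,
                           vessel_pattern = c("annulus", "branches"),
                           n_branches = 24L, branch_width_deg = 6,
                           ring_inner_radius_px = NA_real_,
                           noise_sd = 5, bit_depth = 16L,
                           laterality = c("OD", "OS"), seed = 1L) {
  vessel_pattern <- match.arg(vessel_pattern)
  laterality <- match.arg(laterality)
  if (is.null(sectors))
    sectors <- data.frame(clock_hour = 1:12, A = 100, t50_s = 300, tau_s = 60)
  spec <- list(rows = as.integer(rows), cols = as.integer(cols),
               n_frames = as.integer(n_frames),
               frame_interval_s = frame_interval_s,
               center_row = center_row, center_col = center_col,
               corneal_radius_px = corneal_radius_px,
               outer_radius_px = outer_radius_px,
               sectors = sectors, quadrant_params = NULL,
               baseline = baseline,
               vessel_pattern = vessel_pattern,
               n_branches = as.integer(n_branches),
               branch_width_deg = branch_width_deg,
               ring_inner_radius_px = ring_inner_radius_px,
               noise_sd = noise_sd, bit_depth = as.integer(bit_depth),
               laterality = laterality, seed = as.integer(seed))
  validate_synthetic_spec(spec)
  class(spec) <- "synthetic_spec"
  spec
}

validate_synthetic_spec <- function(spec) {
  bad <- character()
  dur <- (spec$n_frames - 1) * spec$frame_interval_s
  if (spec$n_frames < 2) bad <- c(bad, "n_frames < 2")
  if (spec$frame_interval_s <= 0) bad <- c(bad, "frame_interval_s <= 0")
  if (!is.data.frame(spec$sectors) || nrow(spec$sectors) != 12 ||
      !all(c("clock_hour", "A", "t50_s", "tau_s") %in% names(spec$sectors)))
    bad <- c(bad, "sectors must be a 12-row data frame with clock_hour, A, t50_s, tau_s")
  else {
    if (any(spec$sectors$A < 0)) bad <- c(bad, "sector A < 0")
    if (any(spec$sectors$tau_s <= 0)) bad <- c(bad, "sector tau_s <= 0")
    if (any(spec$sectors$t50_s < 0 | spec$sectors$t50_s > dur))
      bad <- c(bad, "sector t50_s outside [0, duration]")
  }
  if (spec$corneal_radius_px < 0) bad <- c(bad, "corneal_radius_px < 0")
  if (spec$outer_radius_px <= spec$corneal_radius_px)
    bad <- c(bad, "outer_radius_px <= corneal_radius_px")
  if (spec$noise_sd < 0) bad <- c(bad, "noise_sd < 0")
  if (length(bad)) stop("invalid synthetic spec: ", paste(bad, collapse = "; "))
  invisible(spec)
}

# per-quadrant kinetics expanded to the 12 clock sectors; a sector belongs
# to the quadrant containing its center angle
quadrant_sectors <- function(params, laterality = "OD") {
  hours <- 1:12
  ang <- (hours * 30) %% 360
  quad <- assign_quadrant(ang, laterality)
  data.frame(clock_hour = hours,
             A = params[quad, "A"],
             t50_s = params[quad, "t50_s"],
             tau_s = params[quad, "tau_s"],
             row.names = NULL)
}

# per-pixel logistic parameter lookup: clock-sector kinetics by default;
# quadrant-aligned kinetics (boundaries on the meridians) when the spec
# carries quadrant_params
pixel_params <- function(spec, ang) {
  if (!is.null(spec$quadrant_params)) {
    qp <- spec$quadrant_params
    quad <- assign_quadrant(ang, spec$laterality)
    list(A = qp[quad, "A"], t50 = qp[quad, "t50_s"], tau = qp[quad, "tau_s"],
         index = match(quad, rownames(qp)), n_groups = 4L,
         group_A = qp$A, group_t50 = qp$t50_s, group_tau = qp$tau_s)
  } else {
    sec <- clock_hour_from_angle(ang)
    s <- spec$sectors
    list(A = s$A[sec], t50 = s$t50_s[sec], tau = s$tau_s[sec],
         index = sec, n_groups = 12L,
         group_A = s$A, group_t50 = s$t50_s, group_tau = s$tau_s)
  }
}

#' Preset synthetic canalogram scenarios
#'
#' `whole_eye`: all quadrants fill, nasal (IN/SN) sectors at t50 = 300 s
#' and temporal (ST/IT) at 600 s, reflecting preferential nasal drainage.
#' `asc_day1`: an anterior segment culture on day 1 - focal filling
#' confined to the nasal quadrants (temporal amplitudes near zero) with a
#' scleral compression-ring exclusion. `asc_day3`: the same culture two
#' days later - all quadrants active and every sector's t50 strictly
#' smaller than on day 1.
#'
#' @param name `"whole_eye"`, `"asc_day1"` or `"asc_day3"`.
#' @param seed integer seed.
#' @param ... overrides passed to [synthetic_spec()] (e.g. `rows`, `cols`,
#'   `n_frames` to scale the image down).
#' @return A `synthetic_spec`.
#' @export
preset <- function(name = c("whole_eye", "asc_day1", "asc_day3"),
                   seed = 1L, ...) {
  name <- match.arg(name)
  lat <- list(...)$laterality %||% "OD"
  q <- switch(name,
    whole_eye = data.frame(
      row.names = c("IN", "SN", "ST", "IT"),
      A = c(90, 110, 60, 40),
      t50_s = c(300, 300, 600, 600),
      tau_s = c(60, 60, 60, 60)),
    asc_day1 = data.frame(
      row.names = c("IN", "SN", "ST", "IT"),
      A = c(100, 80, 0.5, 0.5),
      t50_s = c(420, 480, 900, 900),
      tau_s = c(80, 80, 80, 80)),
    asc_day3 = data.frame(
      row.names = c("IN", "SN", "ST", "IT"),
      A = c(100, 100, 60, 70),
      t50_s = c(260, 280, 350, 330),
      tau_s = c(60, 60, 60, 60)))
  args <- list(...)
  args$seed <- seed
  if (name != "whole_eye" && is.null(args$ring_inner_radius_px)) {
    rows <- args$rows %||% 580L; cols <- args$cols %||% 610L
    args$ring_inner_radius_px <- 0.47 * min(rows, cols)
  }
  args$sectors <- quadrant_sectors(q, lat)
  spec <- do.call(synthetic_spec, args)
  # presets align kinetic boundaries with the quadrant meridians so the
  # per-quadrant ground truth is exact, not blurred over boundary sectors
  spec$quadrant_params <- q
  spec
}

#' Generate a synthetic canalogram stack with ground truth
#'
#' Renders the stack described by a [synthetic_spec()] and returns, next to
#' it, the analytic ground truth needed to test the analysis pipeline: the
#' per-macropixel noiseless fill curve parameters and half-max crossing,
#' per-quadrant true flow fractions (from noiseless increments) and true
#' onset times. The seed fully determines the output; the caller's RNG
#' state is left untouched.
#'
#' @param spec a `synthetic_spec`.
#' @param grid_rows,grid_cols macropixel grid at which ground truth is
#'   tabulated (default 32 x 32).
#' @param onset_threshold percent of global max defining the true onset
#'   time (default 5, matching the analysis default).
#' @return List with `stack` (a [canalogram_stack()]), `truth` (per
#'   macropixel: effective amplitude, dominant-sector t50/tau, baseline,
#'   vessel fraction, analytic `t_half_s`, noiseless increment, quadrant),
#'   `quadrant_truth` (per quadrant: flow fraction, onset minutes), and
#'   `geometry` (the matching [eye_geometry()]).
#' @export
generate <- function(spec, grid_rows = 32L, grid_cols = 32L,
                     onset_threshold = 5) {
  validate_synthetic_spec(spec)
  tt <- (seq_len(spec$n_frames) - 1) * spec$frame_interval_s
  d_row <- matrix(0:(spec$rows - 1), spec$rows, spec$cols) - spec$center_row
  d_col <- matrix(0:(spec$cols - 1), spec$rows, spec$cols, byrow = TRUE) -
    spec$center_col
  r <- sqrt(d_row^2 + d_col^2)
  ang <- polar_angle_deg(d_row, d_col)
  pp <- pixel_params(spec, as.vector(ang))

  vessel <- r >= spec$corneal_radius_px & r <= spec$outer_radius_px
  if (spec$vessel_pattern == "branches") {
    phase <- (ang * spec$n_branches) %% 360
    in_branch <- phase < spec$branch_width_deg * spec$n_branches / 2 |
      phase > 360 - spec$branch_width_deg * spec$n_branches / 2
    vessel <- vessel & in_branch
  }
  cornea <- r < spec$corneal_radius_px

  amp <- ifelse(vessel, matrix(pp$A, spec$rows, spec$cols), 0)
  t50 <- matrix(pp$t50, spec$rows, spec$cols)
  tau <- matrix(pp$tau, spec$rows, spec$cols)

  maxval <- 2^spec$bit_depth - 1
  frames <- array(0, dim = c(spec$n_frames, spec$rows, spec$cols))
  # seed fully determines the stack; restore the caller's RNG state after
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)
  for (i in seq_len(spec$n_frames)) {
    sig <- spec$baseline + amp / (1 + exp(-(tt[i] - t50) / tau))
    if (spec$noise_sd > 0)
      sig <- sig + matrix(stats::rnorm(spec$rows * spec$cols, 0, spec$noise_sd),
                          spec$rows, spec$cols)
    sig[cornea] <- spec$baseline
    frames[i, , ] <- pmin(pmax(sig, 0), maxval)
  }

  stack <- canalogram_stack(frames, frame_interval_s = spec$frame_interval_s,
                            laterality = spec$laterality,
                            source = sprintf("synthetic(seed=%d)", spec$seed),
                            bit_depth = spec$bit_depth)

  truth <- synthetic_truth(spec, grid_rows, grid_cols, onset_threshold)

  geometry <- eye_geometry(
    center_row = spec$center_row, center_col = spec$center_col,
    corneal_radius_px = spec$corneal_radius_px,
    outer_radius_px = min(spec$outer_radius_px,
                          spec$ring_inner_radius_px, na.rm = TRUE),
    laterality = spec$laterality)

  list(stack = stack, truth = truth$macropixels,
       quadrant_truth = truth$quadrants, geometry = geometry)
}

# analytic ground truth at macropixel resolution: each macropixel's
# noiseless curve is baseline + sum over sectors of (vessel-pixel count /
# block size) * A_s * logistic_s(t); its half-max crossing is solved on the
# continuous curve
synthetic_truth <- function(spec, grid_rows, grid_cols, onset_threshold) {
  er <- block_edges(spec$rows, grid_rows)
  ec <- block_edges(spec$cols, grid_cols)
  d_row <- matrix(0:(spec$rows - 1), spec$rows, spec$cols) - spec$center_row
  d_col <- matrix(0:(spec$cols - 1), spec$rows, spec$cols, byrow = TRUE) -
    spec$center_col
  r <- sqrt(d_row^2 + d_col^2)
  ang <- polar_angle_deg(d_row, d_col)
  pp <- pixel_params(spec, as.vector(ang))
  sector <- matrix(pp$index, spec$rows, spec$cols)
  n_groups <- pp$n_groups
  vessel <- r >= spec$corneal_radius_px & r <= spec$outer_radius_px
  if (spec$vessel_pattern == "branches") {
    phase <- (ang * spec$n_branches) %% 360
    in_branch <- phase < spec$branch_width_deg * spec$n_branches / 2 |
      phase > 360 - spec$branch_width_deg * spec$n_branches / 2
    vessel <- vessel & in_branch
  }

  t_last <- (spec$n_frames - 1) * spec$frame_interval_s
  A <- pp$group_A; T50 <- pp$group_t50; TAU <- pp$group_tau

  n_mp <- grid_rows * grid_cols
  out <- expand.grid(grid_row = seq_len(grid_rows),
                     grid_col = seq_len(grid_cols))
  out$center_row <- ((er[out$grid_row] + er[out$grid_row + 1] - 1) / 2)
  out$center_col <- ((ec[out$grid_col] + ec[out$grid_col + 1] - 1) / 2)
  dr <- out$center_row - spec$center_row
  dc <- out$center_col - spec$center_col
  out$radius_px <- sqrt(dr^2 + dc^2)
  cang <- polar_angle_deg(dr, dc)
  ppc <- pixel_params(spec, cang)
  out$sector <- ppc$index
  out$quadrant <- assign_quadrant(cang, spec$laterality)
  r_out_eff <- min(spec$outer_radius_px, spec$ring_inner_radius_px, na.rm = TRUE)
  out$in_annulus <- out$radius_px >= spec$corneal_radius_px &
    out$radius_px <= r_out_eff
  out$t50_s <- ppc$t50
  out$tau_s <- ppc$tau
  out$baseline <- spec$baseline
  out$amplitude <- NA_real_
  out$vessel_fraction <- NA_real_
  out$t_half_s <- NA_real_
  out$increment <- 0

  # per-block vessel-pixel counts by sector
  counts <- vector("list", n_mp)
  for (i in seq_len(n_mp)) {
    rs <- (er[out$grid_row[i]] + 1):er[out$grid_row[i] + 1]
    cs <- (ec[out$grid_col[i]] + 1):ec[out$grid_col[i] + 1]
    sec_blk <- sector[rs, cs]
    ves_blk <- vessel[rs, cs]
    npix <- length(sec_blk)
    cnt <- tabulate(sec_blk[ves_blk], nbins = n_groups)
    counts[[i]] <- cnt / npix
    out$vessel_fraction[i] <- sum(cnt) / npix
    out$amplitude[i] <- sum(cnt / npix * A)
  }

  curve_of <- function(w) function(t) {
    v <- spec$baseline
    for (s in which(w > 0))
      v <- v + w[s] * A[s] / (1 + exp(-(t - T50[s]) / TAU[s]))
    v
  }

  gmax <- 0
  for (i in seq_len(n_mp))
    if (out$amplitude[i] > 0) gmax <- max(gmax, curve_of(counts[[i]])(t_last))
  if (gmax == 0) gmax <- spec$baseline

  for (i in seq_len(n_mp)) {
    if (out$amplitude[i] <= 0) next
    f <- curve_of(counts[[i]])
    i_max <- f(t_last)  # monotone increasing mixture of logistics
    i_half <- i_max / 2
    th <- if (f(0) >= i_half) 0 else
      stats::uniroot(function(t) f(t) - i_half, c(0, t_last), tol = 1e-6)$root
    out$t_half_s[i] <- th
    n_int <- th / spec$frame_interval_s
    if (out$in_annulus[i] && n_int > 0)
      out$increment[i] <- (i_half - f(0)) / n_int
  }

  quads <- c("IN", "SN", "ST", "IT")
  tot <- sum(out$increment)
  qt <- data.frame(quadrant = quads, flow_fraction = NA_real_,
                   onset_min = NA_real_, stringsAsFactors = FALSE)
  thr <- onset_threshold * gmax / 100
  for (qi in seq_along(quads)) {
    mem <- which(out$quadrant == quads[qi] & out$in_annulus)
    qt$flow_fraction[qi] <- if (tot > 0)
      sum(out$increment[mem]) / tot else NA_real_
    onset <- Inf
    for (i in mem) {
      if (out$amplitude[i] <= 0) next
      f <- curve_of(counts[[i]])
      if (f(t_last) - f(0) > thr) {
        o <- stats::uniroot(function(t) f(t) - f(0) - thr, c(0, t_last),
                            tol = 1e-6)$root
        onset <- min(onset, o)
      }
    }
    qt$onset_min[qi] <- if (is.finite(onset)) onset / 60 else NA_real_
  }
  list(macropixels = out, quadrants = qt)
}
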