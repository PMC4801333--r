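#' Impute per-macropixel flow increments
#'
#' For each included, filling macropixel the flow increment is the rise of
#' the fitted fluorescence curve from the first frame to the time of
#' half-maximal fluorescence, divided by the number of frame intervals
#' taken: `[F(t_half) - F(t_first)] / n_intervals`, in units of percent
#' fluorescence per frame (assuming a percent-normalized series). With
#' `source = "global"` (the default) the curve `F` is the macropixel's
#' region curve from the single global perilimbal fit; with
#' `source = "individual"` it is the macropixel's own fill-curve fit.
#' Non-filling and excluded macropixels contribute 0. A degenerate
#' instantaneous fill (`t_half == t_first`) is defined as 0 and flagged.
#'
#' @param fits a `fill_fits` table from [fit_all()], or NULL when
#'   `source = "global"` (region-level filling classification is then used).
#' @param regional a `regional_fit` from [fit_global()] (required for
#'   `source = "global"`).
#' @param assignment a `polar_assignment` sharing the grid with `fits`.
#' @param source `"global"` or `"individual"` flow basis.
#' @param noise_floor percent of global max used to classify regions as
#'   filling when `fits` is NULL (default 5).
#' @return Data frame, one row per macropixel: `grid_row`, `grid_col`,
#'   `quadrant`, `included`, `filling`, `increment` (percent per frame,
#'   0 for non-filling), `degenerate` flag.
#' @export
impute_flow <- function(fits = NULL, regional = NULL, assignment,
                        source = c("global", "individual"), noise_floor = 5) {
  source <- match.arg(source)
  stopifnot(inherits(assignment, "polar_assignment"))
  if (source == "global" && is.null(regional))
    stop("'regional' fit required for source = \"global\"")
  if (source == "individual" && is.null(fits))
    stop("'fits' required for source = \"individual\"")

  out <- assignment[, c("grid_row", "grid_col", "quadrant", "included")]
  out$filling <- FALSE
  out$increment <- 0
  out$degenerate <- FALSE

  interval <- if (!is.null(regional)) regional$frame_interval_s
              else diff(attr(fits, "times")[1:2])

  if (source == "global") {
    tab <- regional$table
    t_first <- regional$t_first
    # region-level rise and filling classification against the stack's
    # global maximum (100 for a percent-normalized series)
    gmax <- regional$global_max %||% max(tab$I_max, na.rm = TRUE)
    region_filling <- !tab$empty &
      tab$dynamic_range >= noise_floor * gmax / 100 &
      tab$fitted_last > tab$baseline
    key <- paste(tab$clock_hour, tab$ring)
    rise <- (tab$I_half - tab$baseline)
    n_int <- (tab$t_half_s - t_first) / interval
    inc_region <- ifelse(region_filling & n_int > 0, rise / n_int, 0)
    inc_region[is.na(inc_region)] <- 0
    deg_region <- region_filling & !is.na(n_int) & n_int == 0

    mkey <- paste(assignment$clock_hour, assignment$ring)
    idx <- match(mkey, key)
    sel <- out$included & !is.na(idx)
    out$increment[sel] <- inc_region[idx[sel]]
    out$degenerate[sel] <- deg_region[idx[sel]]
    out$filling[sel] <- region_filling[idx[sel]]
    if (!is.null(fits)) {
      # per-macropixel filling gate from the individual fits
      out$filling <- out$filling & fits$filling
      out$increment[!out$filling] <- 0
    }
  } else {
    t_first <- attr(fits, "times")[1]
    sel <- fits$included & fits$filling & !is.na(fits$t_half_s)
    n_int <- (fits$t_half_s - t_first) / interval
    rise <- fits$I_half - fits$baseline
    inc <- ifelse(sel & n_int > 0, rise / n_int, 0)
    inc[is.na(inc)] <- 0
    out$increment <- pmax(inc, 0)
    out$degenerate <- sel & !is.na(n_int) & n_int == 0
    out$filling <- fits$filling
  }
  out$increment <- pmax(out$increment, 0)
  out
}

#' Attribute flow to the four anatomical quadrants in microliters per minute
#'
#' Sums the per-macropixel flow increments within each quadrant, expresses
#' each quadrant's share as a fraction of the total, and converts to
#' microliters per minute by scaling the fractions to the established total
#' aqueous flow (3 ul/min by default, a normalization constant rather than
#' a measurement).
#'
#' @param increments data frame from [impute_flow()].
#' @param total_flow_ul_min total flow the fractions are scaled to
#'   (default 3).
#' @return Data frame of 4 rows in fixed order IN, SN, ST, IT:
#'   `quadrant`, `flow_fraction`, `flow_ul_min`.
#' @export
quadrant_flows <- function(increments, total_flow_ul_min = 3) {
  quads <- c("IN", "SN", "ST", "IT")
  inc <- increments[increments$included & !is.na(increments$quadrant), ]
  tot <- sum(inc$increment)
  if (tot <= 0) stop("no detectable flow: all increments are zero")
  qsum <- vapply(quads, function(q) sum(inc$increment[inc$quadrant == q]), 0)
  frac <- qsum / tot
  data.frame(quadrant = quads, flow_fraction = as.numeric(frac),
             flow_ul_min = as.numeric(frac * total_flow_ul_min),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-quadrant first-appearance filling time
#'
#' The filling time of a quadrant is the elapsed time from the start of the
#' time lapse to the first frame in which any member macropixel's intensity
#' exceeds its own first-frame baseline by more than `onset_threshold`
#' percent of the global maximum - the automated analogue of "first
#' presentation of fluorescence". Quadrants that never cross the threshold
#' are censored at the end of the stack and flagged.
#'
#' @param series a percent-normalized `macropixel_series`.
#' @param assignment a `polar_assignment`.
#' @param onset_threshold onset threshold, percent of global max (default 5).
#' @return Data frame of 4 rows (IN, SN, ST, IT): `quadrant`,
#'   `filling_time_min`, `censored`.
#' @export
quadrant_filling_time <- function(series, assignment, onset_threshold = 5) {
  stopifnot(inherits(series, "macropixel_series"))
  tt <- series_times(series)
  gmax <- max(series$intensity)
  quads <- c("IN", "SN", "ST", "IT")
  out <- data.frame(quadrant = quads, filling_time_min = NA_real_,
                    censored = FALSE, stringsAsFactors = FALSE)
  for (qi in seq_along(quads)) {
    mem <- assignment[assignment$included &
                      !is.na(assignment$quadrant) &
                      assignment$quadrant == quads[qi], ]
    if (nrow(mem) == 0L) {
      out$filling_time_min[qi] <- (tt[length(tt)] - tt[1]) / 60
      out$censored[qi] <- TRUE
      next
    }
    idx <- cbind(rep(seq_along(tt), nrow(mem)),
                 rep(mem$grid_row, each = length(tt)),
                 rep(mem$grid_col, each = length(tt)))
    vals <- matrix(series$intensity[idx], nrow = length(tt))
    delta <- sweep(vals, 2, vals[1, ])
    crossed <- rowSums(delta > onset_threshold * gmax / 100) > 0
    f <- which(crossed)[1]
    if (is.na(f)) {
      out$filling_time_min[qi] <- (tt[length(tt)] - tt[1]) / 60
      out$censored[qi] <- TRUE
    } else {
      out$filling_time_min[qi] <- (tt[f] - tt[1]) / 60
    }
  }
  out
}

#' Paired two-sided comparison of matched per-eye metrics
#'
#' Standard paired t-test on the differences of two matched vectors (e.g.
#' nasal vs temporal filling time per eye). Zero-variance differences are
#' handled explicitly: identical vectors give `t = 0`, `p = 1`; a constant
#' non-zero difference gives an infinite statistic with `p = 0`, flagged as
#' degenerate.
#'
#' @param values_a,values_b matched numeric vectors of equal length >= 2.
#' @return List with `t`, `p`, `df`, `mean_difference`, `degenerate`.
#' @export
paired_compare <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) stop("vectors must be matched")
  if (length(values_a) < 2L) stop("at least 2 pairs required")
  d <- values_a - values_b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0)
      return(list(t = 0, p = 1, df = length(d) - 1L, mean_difference = 0,
                  degenerate = TRUE))
    return(list(t = sign(mean(d)) * Inf, p = 0, df = length(d) - 1L,
                mean_difference = mean(d), degenerate = TRUE))
  }
  ht <- stats::t.test(values_a, values_b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter),
       mean_difference = unname(ht$estimate), degenerate = FALSE)
}
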