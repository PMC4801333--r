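#' Fit a penalized-spline smooth to one intensity time course
#'
#' Fits `intensity ~ s(time)` with a cubic regression spline basis of
#' dimension `k = min(spline_k, n - 1)` and smoothing parameter chosen by
#' generalized cross-validation (GCV), i.e. the minimizer of the residual
#' sum of squares plus a roughness penalty on the second derivative. The
#' fit is deterministic: no random initialization is involved.
#'
#' @param times strictly increasing vector of times, seconds.
#' @param values intensity vector, same length as `times` (at least 4).
#' @param spline_k basis dimension cap (default 10).
#' @return A `fill_curve`: list with `predict(t)` giving the fitted value,
#'   plus `times`, `values`, `rss`, `edf`.
#' @export
fit_curve <- function(times, values, spline_k = 10L) {
  if (length(times) != length(values)) stop("times/values length mismatch")
  if (length(times) < 4L) stop("at least 4 observations required")
  if (any(!is.finite(times)) || any(!is.finite(values)))
    stop("non-finite values in time course")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  k <- min(spline_k, length(times) - 1L)
  dat <- data.frame(t = times, y = values)
  if (stats::var(values) == 0) {
    # flat series: zero-roughness optimum is the constant itself
    const <- values[1]
    fit <- list(predict = function(t) rep(const, length(t)),
                times = times, values = values, rss = 0, edf = 1)
    class(fit) <- "fill_curve"
    return(fit)
  }
  g <- mgcv::gam(y ~ s(t, k = k, bs = "cr"), data = dat, method = "GCV.Cp")
  fit <- list(predict = function(t) {
                as.numeric(mgcv::predict.gam(g, newdata = data.frame(t = t)))
              },
              times = times, values = values,
              rss = sum(stats::residuals(g)^2),
              edf = sum(g$edf) + 1)
  class(fit) <- "fill_curve"
  fit
}

#' Extract half-maximum kinetics from a fitted fill curve
#'
#' Evaluates the fitted smooth on a dense grid, takes the maximum fitted
#' intensity over the observation window as `I_max`, sets
#' `I_half = I_max / 2` (measured from absolute zero, not from baseline),
#' and finds the earliest grid time at which the curve reaches `I_half`,
#' refined by linear interpolation between the bracketing grid points. When
#' the curve crosses `I_half` more than once the earliest crossing wins.
#'
#' @param fit a `fill_curve` (or any object whose `$predict(t)` evaluates
#'   the curve).
#' @param t_first,t_last evaluation window, seconds.
#' @param eval_step_s dense grid step, seconds (default: the fit's frame
#'   interval / 10 when times are available, else 1).
#' @return List with `I_max`, `I_half`, `t_half_s` (NA when the curve never
#'   reaches `I_half`), `baseline` (fitted value at `t_first`), and
#'   `dynamic_range` (max minus min fitted value).
#' @export
extract_half_max <- function(fit, t_first, t_last, eval_step_s = NULL) {
  if (is.null(eval_step_s)) {
    eval_step_s <- if (!is.null(fit$times) && length(fit$times) > 1)
      diff(fit$times[1:2]) / 10 else 1
  }
  if (eval_step_s <= 0) stop("'eval_step_s' must be positive")
  grid <- seq(t_first, t_last, by = eval_step_s)
  if (grid[length(grid)] < t_last) grid <- c(grid, t_last)
  v <- fit$predict(grid)
  i_max <- max(v)
  i_half <- i_max / 2
  idx <- which(v >= i_half)[1]
  t_half <- if (is.na(idx)) {
    NA_real_
  } else if (idx == 1L) {
    grid[1]
  } else {
    # linear interpolation between bracketing grid points
    t0 <- grid[idx - 1L]; t1 <- grid[idx]
    v0 <- v[idx - 1L]; v1 <- v[idx]
    if (v1 == v0) t1 else t0 + (i_half - v0) / (v1 - v0) * (t1 - t0)
  }
  list(I_max = i_max, I_half = i_half, t_half_s = t_half,
       baseline = v[1], dynamic_range = i_max - min(v))
}

#' Classify a macropixel as filling or non-filling
#'
#' A macropixel is considered filling when its fitted dynamic range exceeds
#' a noise floor (a percentage of the stack's global maximum intensity) and
#' its fitted value at the end of the observation window exceeds the fitted
#' value at the start (i.e. the curve rises). Non-filling macropixels carry
#' no half-max time or rate and contribute zero flow.
#'
#' @param dynamic_range fitted max minus min intensity of the macropixel.
#' @param fitted_first,fitted_last fitted values at the window ends.
#' @param noise_floor noise floor as percent of `global_max` (default 5).
#' @param global_max the global maximum intensity of the normalized series
#'   (100 for a percent-normalized stack).
#' @return Logical.
#' @export
classify_filling <- function(dynamic_range, fitted_first, fitted_last,
                             noise_floor = 5, global_max = 100) {
  if (noise_floor < 0 || noise_floor >= 100)
    stop("'noise_floor' must be in [0, 100)")
  (dynamic_range >= noise_floor * global_max / 100) && (fitted_last > fitted_first)
}

#' Fit fill curves for every included macropixel
#'
#' Runs [fit_curve()] and [extract_half_max()] on each included macropixel
#' of a (typically percent-normalized) series and classifies each as
#' filling or not. Individual fit failures are flagged, not fatal. The
#' filling rate follows the half-max definition: the rise from absolute
#' zero to the half-max intensity divided by the time to reach it,
#' `rate = I_half / t_half`.
#'
#' @param series a `macropixel_series` (percent-normalized recommended).
#' @param assignment a `polar_assignment` from [build_mask()]; only
#'   included macropixels are fit.
#' @param noise_floor percent of global max below which a macropixel is
#'   non-filling (default 5).
#' @param spline_k basis dimension cap for [fit_curve()].
#' @param eval_step_s dense evaluation step; default frame interval / 10.
#' @return A `fill_fits` data frame, one row per macropixel: kinetics
#'   columns (`baseline`, `I_max`, `I_half`, `t_half_s`, `filling_rate`,
#'   `dynamic_range`, `rss`, `edf`), flags (`included`, `filling`,
#'   `failed`), and the assignment's region labels. The fitted curves are
#'   attached as attribute `"curves"` (a list indexed like the rows).
#' @export
fit_all <- function(series, assignment, noise_floor = 5, spline_k = 10L,
                    eval_step_s = NULL) {
  stopifnot(inherits(series, "macropixel_series"),
            inherits(assignment, "polar_assignment"))
  if (nrow(assignment) != series$grid_rows * series$grid_cols)
    stop("assignment does not match grid shape")
  tt <- series_times(series)
  t_first <- tt[1]; t_last <- tt[length(tt)]
  gmax <- max(series$intensity)

  out <- assignment[, c("grid_row", "grid_col", "clock_hour", "ring",
                        "quadrant", "included")]
  n <- nrow(out)
  num_na <- rep(NA_real_, n)
  out$baseline <- num_na; out$I_max <- num_na; out$I_half <- num_na
  out$t_half_s <- num_na; out$filling_rate <- num_na
  out$dynamic_range <- num_na; out$rss <- num_na; out$edf <- num_na
  out$filling <- FALSE; out$failed <- FALSE
  curves <- vector("list", n)

  for (i in which(out$included)) {
    y <- series$intensity[, out$grid_row[i], out$grid_col[i]]
    res <- tryCatch({
      fit <- fit_curve(tt, y, spline_k = spline_k)
      hm <- extract_half_max(fit, t_first, t_last, eval_step_s = eval_step_s)
      fitted_last <- fit$predict(t_last)
      filling <- classify_filling(hm$dynamic_range, hm$baseline, fitted_last,
                                  noise_floor = noise_floor, global_max = gmax)
      list(fit = fit, hm = hm, filling = filling)
    }, error = function(e) NULL)
    if (is.null(res)) {
      out$failed[i] <- TRUE
      next
    }
    out$baseline[i] <- res$hm$baseline
    out$rss[i] <- res$fit$rss
    out$edf[i] <- res$fit$edf
    out$dynamic_range[i] <- res$hm$dynamic_range
    out$I_max[i] <- res$hm$I_max
    out$filling[i] <- res$filling
    if (res$filling) {
      out$I_half[i] <- res$hm$I_half
      out$t_half_s[i] <- res$hm$t_half_s
      out$filling_rate[i] <- if (!is.na(res$hm$t_half_s) && res$hm$t_half_s > 0)
        res$hm$I_half / res$hm$t_half_s else NA_real_
    }
    curves[[i]] <- res$fit
  }
  attr(out, "curves") <- curves
  attr(out, "times") <- tt
  attr(out, "global_max") <- gmax
  class(out) <- c("fill_fits", "data.frame")
  out
}

#' @export
print.fill_fits <- function(x, ...) {
  cat("Fill-curve fits:", nrow(x), "macropixels;", sum(x$included),
      "included;", sum(x$filling), "filling;", sum(x$failed), "failed\n")
  if (any(x$filling))
    cat(sprintf("  t_half range %.0f-%.0f s, median rate %.3g per s\n",
                min(x$t_half_s, na.rm = TRUE), max(x$t_half_s, na.rm = TRUE),
                stats::median(x$filling_rate, na.rm = TRUE)))
  invisible(x)
}
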