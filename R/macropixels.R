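# contiguous 1-D block partition of n pixels into g blocks whose sizes
# differ by at most one; larger blocks come first (fixed, documented order)
block_edges <- function(n, g) {
  if (g > n) stop("grid larger than image")
  sizes <- rep(n %/% g, g)
  rem <- n %% g
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  c(0L, cumsum(sizes))  # block b covers pixels edges[b]..edges[b+1]-1 (0-based)
}

#' Reduce a stack to a macropixel grid of per-frame block means
#'
#' Image rows and columns are partitioned into contiguous blocks whose sizes
#' differ by at most one pixel (larger blocks first); each macropixel value
#' is the arithmetic mean intensity of its block in that frame, and its
#' center is the centroid of its block in 0-based pixel coordinates. The
#' default 32 x 32 grid yields 1024 macropixels.
#'
#' @param stack a [canalogram_stack()].
#' @param grid_rows,grid_cols grid dimensions (default 32 x 32).
#' @return A `macropixel_series`: list with `intensity` (time x grid_rows x
#'   grid_cols), `centers_px` (data frame of macropixel centers),
#'   `block_edges_row`/`block_edges_col` (0-based partition edges),
#'   `frame_interval_s`, `t0_s`, `laterality`, and `image_dim`.
#' @export
downsample <- function(stack, grid_rows = 32L, grid_cols = 32L) {
  stopifnot(inherits(stack, "canalogram_stack"))
  d <- dim(stack$frames)
  er <- block_edges(d[2], grid_rows)
  ec <- block_edges(d[3], grid_cols)

  # block means via aggregation matrices: (Ar M t(Ac)) with row-normalized A
  Ar <- matrix(0, grid_rows, d[2])
  for (b in seq_len(grid_rows))
    Ar[b, (er[b] + 1L):er[b + 1L]] <- 1 / (er[b + 1L] - er[b])
  Ac <- matrix(0, grid_cols, d[3])
  for (b in seq_len(grid_cols))
    Ac[b, (ec[b] + 1L):ec[b + 1L]] <- 1 / (ec[b + 1L] - ec[b])

  intensity <- array(0, dim = c(d[1], grid_rows, grid_cols))
  for (i in seq_len(d[1]))
    intensity[i, , ] <- Ar %*% stack$frames[i, , ] %*% t(Ac)

  # centroid of 0-based pixel indices start..end-1 is (start + end - 1) / 2
  cr <- (er[-length(er)] + er[-1] - 1) / 2
  cc <- (ec[-length(ec)] + ec[-1] - 1) / 2
  centers <- expand.grid(grid_row = seq_len(grid_rows),
                         grid_col = seq_len(grid_cols))
  centers$center_row <- cr[centers$grid_row]
  centers$center_col <- cc[centers$grid_col]

  structure(
    list(intensity = intensity,
         grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
         centers_px = centers,
         block_edges_row = er, block_edges_col = ec,
         block_sizes = outer(diff(er), diff(ec)),
         frame_interval_s = stack$frame_interval_s, t0_s = stack$t0_s,
         laterality = stack$laterality,
         image_dim = d[2:3],
         percent = FALSE),
    class = "macropixel_series")
}

#' @export
print.macropixel_series <- function(x, ...) {
  cat("Macropixel series:", x$grid_rows, "x", x$grid_cols, "grid (",
      x$grid_rows * x$grid_cols, "macropixels ),", dim(x$intensity)[1],
      "frames\n")
  cat("  units:", if (x$percent) "percent of global max" else "raw counts", "\n")
  invisible(x)
}

#' Frame times of a macropixel series
#' @param series a `macropixel_series`.
#' @return Numeric vector of frame times in seconds.
#' @export
series_times <- function(series) {
  series$t0_s + (seq_len(dim(series$intensity)[1]) - 1L) * series$frame_interval_s
}

#' Normalize a macropixel series to percent of the global maximum
#'
#' All intensities are divided by the single largest macropixel intensity
#' observed anywhere in the stack and multiplied by 100, so values lie in
#' \[0, 100\] and downstream flow units read "percent fluorescence per
#' frame". Normalization to the global (not per-macropixel) maximum
#' preserves relative brightness between macropixels.
#'
#' @param series a `macropixel_series` in raw counts.
#' @return The series with intensities in percent units.
#' @export
normalize_percent <- function(series) {
  stopifnot(inherits(series, "macropixel_series"))
  if (series$percent) return(series)
  gmax <- max(series$intensity)
  if (gmax <= 0) stop("no signal: all-zero stack cannot be normalized")
  series$intensity <- series$intensity / gmax * 100
  series$global_max_counts <- gmax
  series$percent <- TRUE
  series
}
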