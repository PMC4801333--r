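# shared fixture builders and independent oracles

logistic_fill <- function(t, A = 100, t50 = 300, tau = 60, baseline = 0) {
  baseline + A / (1 + exp(-(t - t50) / tau))
}

# a small stack whose every pixel follows one logistic course
uniform_logistic_stack <- function(rows = 24, cols = 24, n_frames = 41,
                                   interval = 30, A = 100, t50 = 300,
                                   tau = 60, baseline = 0) {
  tt <- (seq_len(n_frames) - 1) * interval
  frames <- array(0, dim = c(n_frames, rows, cols))
  for (i in seq_len(n_frames))
    frames[i, , ] <- logistic_fill(tt[i], A, t50, tau, baseline)
  canalogram_stack(frames, frame_interval_s = interval)
}

constant_stack <- function(value = 7, rows = 16, cols = 16, n_frames = 5,
                           interval = 30) {
  canalogram_stack(array(value, dim = c(n_frames, rows, cols)),
                   frame_interval_s = interval)
}

# geometry whose annulus covers as much of a square grid as possible
full_annulus_geometry <- function(rows, cols, corneal_frac = 0.15) {
  ctr_r <- (rows - 1) / 2; ctr_c <- (cols - 1) / 2
  outer <- min(ctr_r, ctr_c) + 0.5 - 1e-9
  eye_geometry(ctr_r, ctr_c, corneal_radius_px = corneal_frac * min(rows, cols),
               outer_radius_px = outer)
}

# independent brute-force half-max oracle: dense scan, no interpolation
brute_force_t_half <- function(f, t_first, t_last, step) {
  grid <- seq(t_first, t_last, by = step)
  v <- f(grid)
  i_half <- max(v) / 2
  grid[which(v >= i_half)[1]]
}

# random smooth curve built from a few sinusoid + logistic components
random_smooth_curve <- function() {
  a <- runif(1, 20, 100)
  t50 <- runif(1, 100, 1000)
  tau <- runif(1, 30, 150)
  amp <- runif(1, 0, 15)
  per <- runif(1, 300, 1200)
  ph <- runif(1, 0, 2 * pi)
  base <- runif(1, 0, 10)
  function(t) base + a / (1 + exp(-(t - t50) / tau)) +
    amp * sin(2 * pi * t / per + ph)
}
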