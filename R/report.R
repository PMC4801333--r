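#' Write canalography analysis reports as CSV
#'
#' Writes three RFC-4180 CSV files into a directory: `macropixels.csv` (one
#' row per macropixel; excluded macropixels keep their row with
#' `excluded = TRUE` and empty kinetics fields), `quadrants.csv` (four
#' rows: flow in ul/min, flow fraction, filling time, censoring), and
#' `regions.csv` (36 rows of the perilimbal region kinetics). Numeric
#' values are written with 17 significant digits so a round-trip read
#' reproduces them to full float precision.
#'
#' @param fit a `canaloflow` object.
#' @param path output directory (created if missing).
#' @return Invisibly, the paths of the three files written.
#' @export
write_report <- function(fit, path) {
  stopifnot(inherits(fit, "canaloflow"))
  if (!dir.exists(path)) {
    ok <- suppressWarnings(dir.create(path, recursive = TRUE))
    if (!ok) stop("unwritable path: cannot create directory ", path)
  }

  fmt <- function(df) {
    for (nm in names(df))
      if (is.double(df[[nm]]))
        df[[nm]] <- ifelse(is.na(df[[nm]]), NA, sprintf("%.17g", df[[nm]]))
    df
  }

  mp <- as.data.frame(fit)
  f_mp <- file.path(path, "macropixels.csv")
  utils::write.csv(fmt(mp), f_mp, row.names = FALSE, na = "")

  f_q <- file.path(path, "quadrants.csv")
  utils::write.csv(fmt(fit$quadrants), f_q, row.names = FALSE, na = "")

  reg <- fit$regional$table
  reg <- reg[, c("clock_hour", "ring", "empty", "I_max", "I_half",
                 "t_half_s", "filling_rate")]
  f_r <- file.path(path, "regions.csv")
  utils::write.csv(fmt(reg), f_r, row.names = FALSE, na = "")

  invisible(c(macropixels = f_mp, quadrants = f_q, regions = f_r))
}
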