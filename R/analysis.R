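# Comparison statistics over coefficient traces: cycle averages, root mean
# square differences against a reference section, and peak detection.
# Traces are resampled onto a uniform tau grid (linear interpolation) before
# any statistic, so uneven solver time steps cannot bias the results.

resample_trace <- function(data, cols, window, n) {
  if (!"tau" %in% names(data)) abort("series must have a 'tau' column")
  lo <- window[1]; hi <- window[2]
  if (hi <= lo) abort("tau window must have positive length")
  rng <- range(data$tau)
  # grace of one sample spacing at each edge (the first force record sits one
  # step after t = 0); rule-2 interpolation holds the edge value there
  sp <- if (nrow(data) > 1) (rng[2] - rng[1]) / (nrow(data) - 1) else 0
  if (lo < rng[1] - sp - 1e-9 || hi > rng[2] + sp + 1e-9) {
    abort(sprintf("window [%g, %g) lies outside the series tau range [%g, %g]",
                  lo, hi, rng[1], rng[2]))
  }
  taug <- lo + (hi - lo) * (seq_len(n) - 1) / n   # [lo, hi)
  out <- tibble(tau = taug)
  for (cl in cols) out[[cl]] <- approx(data$tau, data[[cl]], xout = taug,
                                       rule = 2)$y
  out
}

#' Time-average of coefficient traces over a tau window
#'
#' Resamples the series to `n` uniform tau points on `[lo, hi)` and returns
#' the arithmetic mean of each requested column. A window that does not span
#' an integer number of flap cycles triggers a warning (averages over partial
#' cycles are biased by the periodic signal).
#'
#' @param data tibble with a `tau` column (e.g. `run$forces`).
#' @param cols columns to average.
#' @param window numeric `c(lo, hi)` in tau units.
#' @param n number of uniform resampling points.
#' @return one-row tibble of means.
#' @export
time_average <- function(data, cols = c("CL", "CD"), window, n = 1600) {
  span <- window[2] - window[1]
  if (abs(span - round(span)) > 1e-9) {
    warning(sprintf("averaging window spans %.4g cycles (not an integer)", span))
  }
  r <- resample_trace(data, cols, window, n)
  tibble::as_tibble(as.list(colMeans(r[cols])))
}

#' Root mean square difference between two traces
#'
#' Both series are resampled onto the same uniform tau grid of `n` points on
#' `[lo, hi)`; the statistic is `sqrt(mean((a_i - ref_i)^2))`.
#'
#' @param data,reference tibbles with `tau` and the compared column.
#' @param col column to compare.
#' @param window numeric `c(lo, hi)` in tau units.
#' @param n number of resampling points.
#' @export
rmsd <- function(data, reference, col = "CL", window, n = 1600) {
  a <- resample_trace(data, col, window, n)
  b <- resample_trace(reference, col, window, n)
  if (nrow(a) != nrow(b)) abort("resampled grids do not match")
  sqrt(mean((a[[col]] - b[[col]])^2))
}

# local maxima of y with prominence above frac * range(y); returns indices
find_peaks <- function(y, prominence_frac = 0.1) {
  n <- length(y)
  if (n < 3) return(integer(0))
  idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  if (!length(idx)) return(integer(0))
  thr <- prominence_frac * diff(range(y))
  keep <- vapply(idx, function(i) {
    # prominence: drop to the higher of the two bounding minima before a
    # taller point is reached (or the series edge)
    left <- y[seq_len(i - 1)]
    right <- y[seq(i + 1, n)]
    taller_l <- which(left > y[i])
    base_l <- min(left[seq(if (length(taller_l)) max(taller_l) else 1, i - 1)])
    taller_r <- which(right > y[i])
    base_r <- min(right[seq_len(if (length(taller_r)) min(taller_r) else length(right))])
    (y[i] - max(base_l, base_r)) >= thr
  }, logical(1))
  idx[keep]
}

#' Count lift-coefficient peaks within one flap cycle
#'
#' Local maxima of the resampled trace with prominence above
#' `prominence * range` over the cycle; the corrugated and smoothed sections
#' characteristically show two peaks per cycle (leading- and trailing-edge
#' vortex shedding) where simpler sections show one.
#'
#' @param data tibble with `tau` and the trace column.
#' @param col trace column, default `"CL"`.
#' @param cycle cycle index: the window is `[cycle, cycle + 1)`.
#' @param prominence prominence threshold as a fraction of the cycle's range.
#' @param n resampling points per cycle.
#' @return tibble with `n_peaks` and a list-column `tau_peaks`.
#' @export
count_lift_peaks <- function(data, col = "CL", cycle, prominence = 0.1,
                             n = 400) {
  r <- resample_trace(data, col, c(cycle, cycle + 1), n)
  pk <- find_peaks(r[[col]], prominence)
  tibble(n_peaks = length(pk), tau_peaks = list(r$tau[pk]))
}

#' Cross-section comparison report
#'
#' Means and RMSDs of CL and CD for a set of runs against a reference run
#' (the corrugated stand-in section in the packaged sweep), mirroring the
#' usual average/RMSD comparison table.
#'
#' @param runs named list of `flap_run` objects (or force tibbles).
#' @param reference name of the reference entry in `runs`.
#' @param window tau window `c(lo, hi)`.
#' @param n resampling points.
#' @param prominence peak prominence threshold.
#' @return tibble with one row per run: `case`, `V_inf`, `mean_CL`,
#'   `mean_CD`, `rmsd_CL`, `rmsd_CD`, `n`, `n_peaks_per_cycle`.
#' @export
build_report <- function(runs, reference, window, n = 1600,
                         prominence = 0.1) {
  if (!reference %in% names(runs)) {
    abort(sprintf("reference case '%s' is not among the runs", reference))
  }
  get_forces <- function(r) if (inherits(r, "flap_run")) r$forces else tibble::as_tibble(r)
  get_vinf <- function(r) if (inherits(r, "flap_run")) r$case$V_inf else NA_real_
  ref <- get_forces(runs[[reference]])
  last_cycle <- floor(window[2] - 1 + 1e-9)
  rows <- lapply(names(runs), function(nm) {
    f <- get_forces(runs[[nm]])
    m <- time_average(f, c("CL", "CD"), window, n)
    pk <- count_lift_peaks(f, "CL", last_cycle, prominence)
    tibble(case = nm, V_inf = get_vinf(runs[[nm]]),
           mean_CL = m$CL, mean_CD = m$CD,
           rmsd_CL = rmsd(f, ref, "CL", window, n),
           rmsd_CD = rmsd(f, ref, "CD", window, n),
           n = n, n_peaks_per_cycle = pk$n_peaks)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("flap_report", class(out))
  out
}

#' Write a comparison report to CSV
#' @param report a `flap_report` from [build_report()].
#' @param path output file.
#' @export
write_report <- function(report, path) {
  write.csv(report[setdiff(names(report), "tau_peaks")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}
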