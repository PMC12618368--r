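#' Time-averaged wall shear stress
#'
#' \eqn{TAWSS = \int_0^T |\tau| dt / \int_0^T dt} by trapezoidal quadrature
#' over the saved time grid of one cardiac cycle.
#'
#' @param x a [wss_record()], or a matrix (stations x times) of signed wall
#'   shear stress (Pa).
#' @param times saved times spanning exactly one cycle (ignored when `x` is a
#'   `wss_record`).
#' @return TAWSS per station (Pa), >= 0.
#' @export
tawss <- function(x, times = NULL) {
  if (inherits(x, "wss_record")) { times <- x$times; x <- x$tau_w }
  x <- rbind(x)
  if (is.null(times) || any(diff(times) <= 0))
    stop("tawss: need strictly increasing times", call. = FALSE)
  unname(apply(abs(x), 1, function(v) trapz_int(times, v))) /
    (max(times) - min(times))
}

trapz_int <- function(t, v) sum(0.5 * (v[-1] + v[-length(v)]) * diff(t))

#' Oscillatory shear index
#'
#' \eqn{OSI = 0.5 (1 - |\int \tau dt| / \int |\tau| dt) \in [0, 0.5]}.
#' In the axisymmetric reduction the shear is a signed axial scalar, so the
#' vector integrals reduce exactly to signed-scalar integrals.  A station
#' with identically zero shear gets OSI = 0 by convention.
#'
#' @inheritParams tawss
#' @return OSI per station, in \[0, 0.5\].
#' @export
osi <- function(x, times = NULL) {
  if (inherits(x, "wss_record")) { times <- x$times; x <- x$tau_w }
  x <- rbind(x)
  if (is.null(times) || any(diff(times) <= 0))
    stop("osi: need strictly increasing times", call. = FALSE)
  unname(apply(x, 1, function(v) {
    denom <- trapz_int(times, abs(v))
    if (denom <= 0) return(0)
    # guard rounding: the ratio is <= 1 analytically
    0.5 * (1 - min(abs(trapz_int(times, v)) / denom, 1))
  }))
}

#' Low-shear vulnerability mask and zones
#'
#' Stations whose TAWSS falls strictly below the threshold (0.4 Pa by
#' default) are flagged as prone to atherosclerotic lesion formation;
#' contiguous flagged runs are summarised as zones.
#'
#' @param tawss_field TAWSS per station (Pa).
#' @param z station positions (m).
#' @param threshold vulnerability threshold (Pa); strict `<` comparison.
#' @return A list with `mask` (logical per station) and `zones` (data.frame
#'   `z_start, z_end, min_tawss`, one row per contiguous zone).
#' @export
vulnerable_zones <- function(tawss_field, z, threshold = 0.4) {
  mask <- tawss_field < threshold
  zones <- data.frame(z_start = numeric(0), z_end = numeric(0),
                      min_tawss = numeric(0))
  if (any(mask)) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (i in which(r$values)) {
      idx <- starts[i]:ends[i]
      zones <- rbind(zones, data.frame(z_start = z[starts[i]],
                                       z_end = z[ends[i]],
                                       min_tawss = min(tawss_field[idx])))
    }
  }
  list(mask = mask, zones = zones)
}

#' Haemodynamic index table of a simulation
#'
#' TAWSS, OSI and the vulnerability mask per station, from the last-cycle
#' wall-shear record of a simulation.
#'
#' @param sim a `hemofsi_sim` from [run_simulation()] or [solve_vessel()].
#' @param threshold vulnerability threshold (Pa).
#' @return A data.frame `z_m, tawss_pa, osi, vulnerable`.
#' @export
index_table <- function(sim, threshold = 0.4) {
  stopifnot(inherits(sim, "hemofsi_sim"))
  ta <- tawss(sim$wss)
  data.frame(z_m = sim$z, tawss_pa = ta, osi = osi(sim$wss),
             vulnerable = ta < threshold)
}

#' Compare two simulation runs
#'
#' Station-matched comparison of wall-shear metrics between two runs sharing
#' the same geometry and schedule: per-station TAWSS/OSI and peak-systole WSS
#' deltas and percentage differences (relative to run B), peak-WSS locations,
#' and whether both runs place the maximum at the same station.
#'
#' @param run_a,run_b `hemofsi_sim` objects on identical geometry/schedule.
#' @return An object of class `run_comparison`: list with `by_station`
#'   (data.frame), `max_wss_a`, `max_wss_b` (value/station/time lists),
#'   `same_argmax_station` flag, and the run modes.
#' @export
compare_runs <- function(run_a, run_b) {
  stopifnot(inherits(run_a, "hemofsi_sim"), inherits(run_b, "hemofsi_sim"))
  if (length(run_a$z) != length(run_b$z) ||
      max(abs(run_a$z - run_b$z)) > 1e-12 ||
      length(run_a$wss$times) != length(run_b$wss$times))
    stop("compare_runs: runs must share geometry and schedule", call. = FALSE)
  peak <- function(run) {
    m <- run$tau_w[, run$last_cycle, drop = FALSE]
    i <- which(m == max(m), arr.ind = TRUE)[1, ]
    list(value = max(m), station = unname(i[1]),
         z = run$z[i[1]], time = run$times[run$last_cycle][i[2]])
  }
  pa <- peak(run_a); pb <- peak(run_b)
  ta <- tawss(run_a$wss); tb <- tawss(run_b$wss)
  oa <- osi(run_a$wss); ob <- osi(run_b$wss)
  wa <- apply(run_a$wss$tau_w, 1, max)
  wb <- apply(run_b$wss$tau_w, 1, max)
  pct <- function(a, b) ifelse(b != 0, (a - b) / b * 100, NA_real_)
  structure(list(
    mode_a = run_a$mode, mode_b = run_b$mode,
    by_station = data.frame(
      z_m = run_a$z,
      tawss_a = ta, tawss_b = tb, tawss_delta = ta - tb,
      tawss_pct = pct(ta, tb),
      osi_a = oa, osi_b = ob, osi_delta = oa - ob,
      peak_wss_a = wa, peak_wss_b = wb, peak_wss_pct = pct(wa, wb)),
    max_wss_a = pa, max_wss_b = pb,
    same_argmax_station = pa$station == pb$station),
    class = "run_comparison")
}

#' @export
print.run_comparison <- function(x, ...) {
  cat(sprintf("Run comparison: A = %s, B = %s\n", x$mode_a, x$mode_b))
  cat(sprintf("  max WSS: A %.4g Pa @ z = %g mm | B %.4g Pa @ z = %g mm (%s)\n",
              x$max_wss_a$value, 1e3 * x$max_wss_a$z,
              x$max_wss_b$value, 1e3 * x$max_wss_b$z,
              if (x$same_argmax_station) "same station" else "different stations"))
  invisible(x)
}
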