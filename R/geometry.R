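#' Vessel geometry as centerline stations
#'
#' A vessel is described by ordered axial stations along its centerline with a
#' circular lumen cross-section and two concentric wall layers at each
#' station.  Stations default to 2 mm spacing; layer thickness defaults are
#' 0.24 mm (intima plus transition zone) and 0.66 mm (media plus adventitia).
#'
#' @param z axial positions (m), strictly increasing, length >= 2.
#' @param radius lumen radius per station (m), > 0.
#' @param t1,t2 inner/outer wall-layer thicknesses (m); recycled per station.
#' @return An object of class `vessel_geometry` (a data.frame with columns
#'   `z_m, radius_m, t1_m, t2_m`).
#' @export
vessel_geometry <- function(z, radius, t1 = 0.24e-3, t2 = 0.66e-3) {
  if (length(z) < 2) stop("vessel_geometry: need at least 2 stations", call. = FALSE)
  if (any(diff(z) <= 0)) stop("vessel_geometry: z must be strictly increasing", call. = FALSE)
  if (any(radius <= 0)) stop("vessel_geometry: radius must be > 0", call. = FALSE)
  if (any(t1 <= 0) || any(t2 <= 0))
    stop("vessel_geometry: layer thicknesses must be > 0", call. = FALSE)
  g <- data.frame(z_m = z, radius_m = radius,
                  t1_m = rep_len(t1, length(z)), t2_m = rep_len(t2, length(z)))
  class(g) <- c("vessel_geometry", "data.frame")
  slope <- max(abs(diff(radius) / diff(z)))
  if (slope >= 0.2)
    warning("vessel_geometry: |dR/dz| = ", signif(slope, 3),
            " exceeds 0.2; the locally-fully-developed flow assumption of ",
            "the quasi-1D solver is strained", call. = FALSE)
  g
}

#' @export
print.vessel_geometry <- function(x, ...) {
  cat(sprintf("Vessel geometry: %d stations, z in [%g, %g] mm\n",
              nrow(x), 1e3 * min(x$z_m), 1e3 * max(x$z_m)))
  cat(sprintf("  lumen radius %g-%g mm; wall layers %g / %g mm\n",
              1e3 * min(x$radius_m), 1e3 * max(x$radius_m),
              1e3 * x$t1_m[1], 1e3 * x$t2_m[1]))
  invisible(x)
}

#' Generate a synthetic vessel
#'
#' Parametric stand-ins for angiography-derived coronary segments: straight
#' tubes, linear tapers, Gaussian-profile stenoses and sinusoidally varying
#' lumens.  All are synthetic shapes, not patient data.
#'
#' @param kind one of `"straight"`, `"tapered"`, `"stenosis"`, `"sinusoid"`.
#' @param length vessel length (m), >= 2 dz.
#' @param base_radius reference lumen radius (m).
#' @param dz station spacing (m), default 2 mm.
#' @param severity stenosis severity in [0, 0.95): minimum radius is
#'   `base_radius * (1 - severity)`.
#' @param center stenosis center (m along z); defaults to mid-length.
#' @param width Gaussian stenosis half-width (m); the default `length/5`
#'   keeps the radius slope within the quasi-1D validity bound for moderate
#'   severities.
#' @param taper_ratio tapered kind: outlet radius / inlet radius.
#' @param amplitude,wavelength sinusoid kind: radius modulation (m) and axial
#'   wavelength (m).
#' @param t1,t2 wall-layer thicknesses (m).
#' @return A [vessel_geometry()].
#' @examples
#' v <- make_vessel("stenosis", length = 0.02, base_radius = 1.5e-3,
#'                  severity = 0.5)
#' @export
make_vessel <- function(kind = c("straight", "tapered", "stenosis", "sinusoid"),
                        length = 0.02, base_radius = 1.5e-3, dz = 2e-3,
                        severity = 0.5, center = NULL, width = NULL,
                        taper_ratio = 0.8, amplitude = 0, wavelength = 0.01,
                        t1 = 0.24e-3, t2 = 0.66e-3) {
  kind <- match.arg(kind)
  if (length < 2 * dz) stop("make_vessel: length must be >= 2*dz", call. = FALSE)
  if (base_radius <= 0 || dz <= 0)
    stop("make_vessel: dimensions must be positive", call. = FALSE)
  z <- seq(0, length, by = dz)
  r <- switch(kind,
    straight = rep(base_radius, length(z)),
    tapered = base_radius * (1 + (taper_ratio - 1) * z / max(z)),
    stenosis = {
      if (severity < 0 || severity >= 0.95)
        stop("make_vessel: stenosis severity must be in [0, 0.95)", call. = FALSE)
      if (is.null(center)) center <- max(z) / 2
      if (is.null(width)) width <- length / 5
      base_radius * (1 - severity * exp(-((z - center) / width)^2))
    },
    sinusoid = base_radius + amplitude * sin(2 * pi * z / wavelength))
  vessel_geometry(z, r, t1, t2)
}

#' Per-station cross-section metrics
#'
#' Lumen area \eqn{\pi R^2} and local taper angle
#' \eqn{\arctan(dR/dz)} from centered differences (one-sided at the ends).
#'
#' @param g a [vessel_geometry()].
#' @return A data.frame with columns `z_m, area_m2, taper_rad`.
#' @export
station_metrics <- function(g) {
  stopifnot(inherits(g, "vessel_geometry"))
  n <- nrow(g)
  drdz <- numeric(n)
  drdz[1] <- (g$radius_m[2] - g$radius_m[1]) / (g$z_m[2] - g$z_m[1])
  drdz[n] <- (g$radius_m[n] - g$radius_m[n - 1]) / (g$z_m[n] - g$z_m[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    drdz[i] <- (g$radius_m[i + 1] - g$radius_m[i - 1]) /
      (g$z_m[i + 1] - g$z_m[i - 1])
  }
  data.frame(z_m = g$z_m, area_m2 = pi * g$radius_m^2, taper_rad = atan(drdz))
}

#' Read / write vessel CSV
#'
#' Columns `z_m, radius_m, t1_m, t2_m`, header required; full double
#' precision, locale-independent.
#'
#' @param path file path.
#' @return `read_vessel_csv`: a [vessel_geometry()].
#' @export
read_vessel_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("z_m", "radius_m", "t1_m", "t2_m")
  if (!all(need %in% names(df)))
    stop("read_vessel_csv: expected columns ", paste(need, collapse = ", "),
         call. = FALSE)
  vessel_geometry(df$z_m, df$radius_m, df$t1_m, df$t2_m)
}

#' @rdname read_vessel_csv
#' @param g a [vessel_geometry()].
#' @export
write_vessel_csv <- function(g, path) {
  stopifnot(inherits(g, "vessel_geometry"))
  df <- as.data.frame(g)
  df[] <- lapply(df, function(col) format(col, digits = 17, scientific = TRUE,
                                          trim = TRUE))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
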