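#' Size-exclusion column geometry
#'
#' @param V0 Void volume (mL); default 8, a Superdex-200 10/300 class
#'   column.
#' @param Vc Geometric column volume (mL); default 24.
#' @return A `ColumnGeometry` list.
#' @export
column_geometry <- function(V0 = 8, Vc = 24) {
  stopifnot(V0 > 0, Vc > V0)
  list(V0 = V0, Vc = Vc)
}

#' Partition coefficient of an elution volume
#'
#' `Kav = (Ve - V0) / (Vc - V0)`; 0 at the void volume, 1 at the total
#' column volume.
#'
#' @param Ve Elution volume (mL), inside `[V0, Vc]`.
#' @param geometry A [column_geometry()].
#' @return Dimensionless partition coefficient.
#' @examples
#' kav(10.2)  # 0.1375 on the default 8/24 mL column
#' @export
kav <- function(Ve, geometry = column_geometry()) {
  if (any(Ve < geometry$V0 | Ve > geometry$Vc)) {
    stop("elution volume outside [V0, Vc] = [", geometry$V0, ", ",
         geometry$Vc, "] mL", call. = FALSE)
  }
  (Ve - geometry$V0) / (geometry$Vc - geometry$V0)
}

#' Fit a SEC calibration curve
#'
#' Least-squares line of the partition coefficient against the decadic
#' logarithm of molecular mass, `Kav = m * log10(mass) + c`. Larger
#' species elute earlier, so a valid calibration has negative slope.
#'
#' @param standards data.frame with columns `mass_kda` and `Ve_ml`
#'   (>= 3 standards with distinct masses).
#' @param geometry A [column_geometry()].
#' @return A `CalibrationCurve` list with `slope`, `intercept`,
#'   `r_squared`, `standards`, `geometry`.
#' @export
fit_calibration <- function(standards, geometry = column_geometry()) {
  stopifnot(is.data.frame(standards),
            all(c("mass_kda", "Ve_ml") %in% names(standards)))
  if (length(unique(standards$mass_kda)) < 3L) {
    stop("need at least 3 standards with distinct masses", call. = FALSE)
  }
  k <- kav(standards$Ve_ml, geometry)
  lmass <- log10(standards$mass_kda)
  fit <- lm(k ~ lmass)
  slope <- unname(coef(fit)[2L])
  if (slope >= 0) {
    stop("calibration slope must be negative (larger species elute ",
         "earlier)", call. = FALSE)
  }
  structure(
    list(slope = slope, intercept = unname(coef(fit)[1L]),
         r_squared = suppressWarnings(summary(fit)$r.squared),
         standards = standards,
         geometry = geometry),
    class = "CalibrationCurve"
  )
}

#' Apparent molecular mass from an elution volume
#'
#' Inverts the calibration line: `mass = 10^((Kav - c) / m)`.
#'
#' @param Ve Elution volume (mL).
#' @param calibration A [fit_calibration()] curve.
#' @param geometry A [column_geometry()]; defaults to the calibration's.
#' @return Apparent mass in kDa.
#' @export
infer_mass <- function(Ve, calibration, geometry = calibration$geometry) {
  k <- kav(Ve, geometry)
  10^((k - calibration$intercept) / calibration$slope)
}

#' Elution volume predicted for a mass on a calibration line
#' @param mass_kda Mass in kDa.
#' @inheritParams infer_mass
#' @return Predicted Ve (mL).
#' @export
predict_ve <- function(mass_kda, calibration,
                       geometry = calibration$geometry) {
  k <- calibration$slope * log10(mass_kda) + calibration$intercept
  geometry$V0 + k * (geometry$Vc - geometry$V0)
}

#' Detect peaks in an elution profile
#'
#' Local maxima above `min_height`, with the apex refined by three-point
#' parabolic interpolation on the sampling grid.
#'
#' @param profile data.frame with columns `volume_ml` (ascending) and
#'   `absorbance` (>= 10 samples).
#' @param min_height Minimum absorbance of a reported peak.
#' @return data.frame with columns `Ve_ml`, `height` (possibly empty).
#' @export
detect_peaks <- function(profile, min_height = 0) {
  stopifnot(is.data.frame(profile),
            all(c("volume_ml", "absorbance") %in% names(profile)),
            nrow(profile) >= 10L)
  v <- profile$volume_ml; y <- profile$absorbance
  n <- length(y)
  idx <- which(y[2:(n - 1L)] > y[1:(n - 2L)] &
                 y[2:(n - 1L)] >= y[3:n]) + 1L
  idx <- idx[y[idx] >= min_height]
  if (length(idx) == 0L) {
    return(data.frame(Ve_ml = numeric(), height = numeric()))
  }
  apex <- vapply(idx, function(i) {
    y1 <- y[i - 1L]; y2 <- y[i]; y3 <- y[i + 1L]
    denom <- y1 - 2 * y2 + y3
    delta <- if (abs(denom) < 1e-12) 0 else 0.5 * (y1 - y3) / denom
    delta <- max(min(delta, 0.5), -0.5)
    c(v[i] + delta * (v[2L] - v[1L]),
      y2 - 0.25 * (y1 - y3) * delta)
  }, numeric(2))
  data.frame(Ve_ml = apex[1L, ], height = apex[2L, ])
}

#' Infer integer complex stoichiometry from an apparent mass
#'
#' Exhaustive search over copy numbers `a, b` in `[1, max_copies]` for
#' two components, minimising `|a * mass1 + b * mass2 - observed|`. Both
#' copy numbers start at 1 because the inference is applied to peaks in
#' which both components were detected; ties are broken by smaller
#' `a + b`, then smaller `a`.
#'
#' @param observed_kda Apparent complex mass (kDa).
#' @param mass1_kda,mass2_kda Component masses (kDa).
#' @param max_copies Largest copy number considered per component.
#' @return A `StoichiometryResult` list with `a`, `b`, `predicted_kda`,
#'   `abs_error_kda`.
#' @examples
#' infer_stoichiometry(228, 91, 20)  # 2:2 heterotetramer
#' @export
infer_stoichiometry <- function(observed_kda, mass1_kda, mass2_kda,
                                max_copies = 4L) {
  stopifnot(observed_kda > 0, mass1_kda > 0, mass2_kda > 0,
            max_copies >= 1L)
  grid <- expand.grid(a = seq_len(max_copies), b = seq_len(max_copies))
  grid$predicted <- grid$a * mass1_kda + grid$b * mass2_kda
  grid$err <- abs(grid$predicted - observed_kda)
  grid <- grid[order(grid$err, grid$a + grid$b, grid$a), ]
  best <- grid[1L, ]
  structure(
    list(a = best$a, b = best$b, predicted_kda = best$predicted,
         abs_error_kda = best$err),
    class = "StoichiometryResult"
  )
}

#' @export
print.StoichiometryResult <- function(x, ...) {
  cat(sprintf("<Stoichiometry> %d:%d, predicted %.1f kDa (|error| %.1f)\n",
              x$a, x$b, x$predicted_kda, x$abs_error_kda))
  invisible(x)
}
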