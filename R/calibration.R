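#' Membrane displacement vs pressure calibration fit
#'
#' Ordinary least-squares fit of membrane displacement (micrometers)
#' against actuation pressure (psi), the empirical line relating the
#' nominal pressure to the mechanical stimulus actually delivered.
#' Deflection is roughly linear with pressure over the device's working
#' range, so a straight line (with intercept by default) is fitted and
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} reported.
#'
#' @param table `data.frame` with columns `pressure_psi` and
#'   `displacement_um`, at least 3 rows and 2 distinct pressures.
#' @param through_origin Force the line through the origin
#'   (default `FALSE`).
#' @return List with `slope` (um/psi), `intercept` (um; 0 when forced
#'   through the origin), `r_squared`, `degenerate` (`TRUE` when the
#'   displacements have zero variance, in which case `r_squared` is
#'   `NA`), `n`, and the underlying `lm` fit.
#' @examples
#' tab <- data.frame(pressure_psi = c(1, 2, 3),
#'                   displacement_um = c(2, 4, 6))
#' calibration_fit(tab)
#' @export
calibration_fit <- function(table, through_origin = FALSE) {
  stopifnot(is.data.frame(table),
            all(c("pressure_psi", "displacement_um") %in% names(table)))
  p <- table$pressure_psi; y <- table$displacement_um
  if (length(p) < 3) stop("need at least 3 calibration points")
  if (any(p < 0)) stop("pressures must be nonnegative")
  if (length(unique(p)) < 2) stop("all pressures identical")
  fit <- if (through_origin) stats::lm(y ~ 0 + p) else stats::lm(y ~ p)
  ss_tot <- if (through_origin) sum(y^2) else sum((y - mean(y))^2)
  degenerate <- ss_tot == 0
  r2 <- if (degenerate) NA_real_ else 1 - sum(stats::resid(fit)^2) / ss_tot
  co <- stats::coef(fit)
  list(slope = unname(if (through_origin) co[1] else co[2]),
       intercept = unname(if (through_origin) 0 else co[1]),
       r_squared = r2, degenerate = degenerate,
       n = length(p), fit = fit)
}

#' Synthetic calibration table
#'
#' Generates a (pressure, displacement) table from a linear model with
#' Gaussian measurement noise, emulating repeated membrane-deflection
#' measurements across a pressure sweep. Synthetic stand-in for a
#' measured table; uses the current RNG state.
#'
#' @param pressures Pressure sweep, psi.
#' @param slope True slope, um/psi.
#' @param intercept True intercept, um.
#' @param noise_sd Measurement noise SD, um.
#' @param replicates Measurements per pressure.
#' @return `data.frame` with `pressure_psi`, `displacement_um`.
#' @export
synthetic_calibration_table <- function(pressures = seq(10, 60, by = 5),
                                        slope = 0.8, intercept = 2,
                                        noise_sd = 1.5, replicates = 4) {
  p <- rep(pressures, each = replicates)
  data.frame(pressure_psi = p,
             displacement_um = intercept + slope * p +
               stats::rnorm(length(p), 0, noise_sd))
}
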