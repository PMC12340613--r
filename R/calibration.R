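#' Stern-Volmer calibration for phosphorescence oxygen sensing
#'
#' Collisional quenching of the phosphorescent probe by oxygen shortens its
#' lifetime according to the Stern-Volmer relation
#' \deqn{1/\tau = 1/\tau_0 + k_q \, \mathrm{pO_2},}
#' where \eqn{\tau_0} is the zero-oxygen lifetime and \eqn{k_q} the quenching
#' constant. Calibration constants are batch-specific and must be supplied by
#' the user (from an oxygen titration) or taken from the simulator's
#' defaults; no literature constants are assumed.
#'
#' @param tau0_us zero-oxygen lifetime in microseconds.
#' @param kq quenching constant in 1/(us * mmHg).
#' @param valid_range pO2 range (mmHg) over which the calibration is trusted.
#' @return an object of class `sv_calibration`.
#' @examples
#' cal <- sv_calibration(tau0_us = 40, kq = 5e-4)
#' po2_to_lifetime(c(0, 60), cal)
#' @export
sv_calibration <- function(tau0_us, kq, valid_range = c(0, 150)) {
  stopifnot(is.numeric(tau0_us), tau0_us > 0, is.numeric(kq), kq > 0)
  structure(
    list(tau0_us = tau0_us, kq = kq, valid_range = valid_range),
    class = "sv_calibration"
  )
}

#' @export
print.sv_calibration <- function(x, ...) {
  cat(sprintf(
    "<sv_calibration> tau0 = %.4g us, kq = %.4g /(us*mmHg), valid pO2 [%g, %g] mmHg\n",
    x$tau0_us, x$kq, x$valid_range[1], x$valid_range[2]
  ))
  invisible(x)
}

#' Fit a Stern-Volmer calibration from an oxygen titration
#'
#' Linear least-squares fit of inverse lifetime against pO2: the slope is the
#' quenching constant and the intercept the inverse zero-oxygen lifetime.
#' With exactly two distinct oxygen levels this reduces to the two-point
#' closed-form solution.
#'
#' @param titration data frame with columns `po2` (mmHg) and `tau_us`
#'   (microseconds), one row per titration measurement.
#' @return an `sv_calibration` with fit metadata (`r_squared`, `n`, standard
#'   errors) attached; retrieve tidy coefficients with [generics::tidy()].
#' @examples
#' cal <- sv_calibration(40, 5e-4)
#' tit <- tibble::tibble(po2 = c(0, 20, 60, 100))
#' tit$tau_us <- po2_to_lifetime(tit$po2, cal)
#' fit_stern_volmer(tit)
#' @export
fit_stern_volmer <- function(titration) {
  stopifnot(is.data.frame(titration), all(c("po2", "tau_us") %in% names(titration)))
  if (length(unique(titration$po2)) < 2L) {
    abort("titration needs at least 2 distinct pO2 levels")
  }
  if (any(titration$tau_us <= 0)) abort("lifetimes must be positive")
  fit <- lm(I(1 / tau_us) ~ po2, data = titration)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  if (slope <= 0) {
    abort("titration is not monotone decreasing in lifetime (fitted kq <= 0)")
  }
  if (intercept <= 0) abort("fitted 1/tau0 is not positive")
  cal <- sv_calibration(
    tau0_us = 1 / intercept, kq = slope,
    valid_range = range(titration$po2)
  )
  s <- summary(fit)
  cal$fit <- list(
    r_squared = s$r.squared,
    n = nrow(titration),
    se = unname(s$coefficients[, "Std. Error"])
  )
  cal
}

#' @export
tidy.sv_calibration <- function(x, ...) {
  tb(
    term = c("tau0_us", "kq"),
    estimate = c(x$tau0_us, x$kq),
    std.error = if (is.null(x$fit)) c(NA_real_, NA_real_) else {
      # delta method for tau0 = 1/intercept
      c(x$fit$se[1] * x$tau0_us^2, x$fit$se[2])
    }
  )
}

#' @export
glance.sv_calibration <- function(x, ...) {
  tb(
    r.squared = if (is.null(x$fit)) NA_real_ else x$fit$r_squared,
    nobs = if (is.null(x$fit)) NA_integer_ else x$fit$n
  )
}

#' Convert lifetime to pO2 (and back) through a Stern-Volmer calibration
#'
#' `lifetime_to_po2()` maps fitted lifetimes to oxygen partial pressure,
#' `po2_to_lifetime()` is its algebraic inverse. The map is strictly
#' decreasing in lifetime. Noise can push estimates slightly past the
#' zero-oxygen lifetime; resulting small negative pressures are clipped to 0
#' (tissue pO2 is nonnegative) and flagged, while lifetimes exceeding
#' `tau0 * (1 + tol)` are flagged out-of-range.
#'
#' @param tau_us lifetime(s) in microseconds.
#' @param calib an [sv_calibration].
#' @param clip clip small negative pO2 values to 0 (default `TRUE`).
#' @param tol relative tolerance on `tau > tau0` before a value is flagged
#'   out-of-range.
#' @return numeric vector of pO2 in mmHg with logical attributes `clipped`
#'   and `out_of_range`.
#' @examples
#' cal <- sv_calibration(40, 5e-4)
#' lifetime_to_po2(po2_to_lifetime(60, cal), cal)
#' @export
lifetime_to_po2 <- function(tau_us, calib, clip = TRUE, tol = 0.05) {
  stopifnot(inherits(calib, "sv_calibration"), all(tau_us > 0 | is.na(tau_us)))
  po2 <- (1 / tau_us - 1 / calib$tau0_us) / calib$kq
  out_of_range <- !is.na(tau_us) & tau_us > calib$tau0_us * (1 + tol)
  clipped <- !is.na(po2) & po2 < 0
  if (clip) po2[clipped] <- 0
  attr(po2, "clipped") <- clipped
  attr(po2, "out_of_range") <- out_of_range
  po2
}

#' @rdname lifetime_to_po2
#' @param po2 oxygen partial pressure(s), mmHg.
#' @export
po2_to_lifetime <- function(po2, calib) {
  stopifnot(inherits(calib, "sv_calibration"))
  1 / (1 / calib$tau0_us + calib$kq * po2)
}
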