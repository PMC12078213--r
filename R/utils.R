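# Angle helpers. Convention throughout: degrees, counter-clockwise positive,
# 0 = rightward, stored in [0, 360).

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles into [0, 360)
#' @param x angles in degrees
#' @return wrapped angles
#' @keywords internal
wrap360 <- function(x) ((x %% 360) + 360) %% 360

#' Wrap angles into (-180, 180]
#' @param x angles in degrees
#' @return wrapped angles
#' @keywords internal
wrap180 <- function(x) {
  y <- wrap360(x)
  ifelse(y > 180, y - 360, y)
}

#' Signed angular difference a - b in (-180, 180]
#' @param a,b angles in degrees
#' @keywords internal
ang_diff <- function(a, b) wrap180(a - b)

unit_vec <- function(theta_deg) {
  t <- deg2rad(theta_deg)
  cbind(cos(t), sin(t))
}

# unbiased-SD correction factor c4(n): E[s] = c4 * sigma for normal samples
c4_factor <- function(n) {
  if (n < 2) return(NA_real_)
  sqrt(2 / (n - 1)) * exp(lgamma(n / 2) - lgamma((n - 1) / 2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
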