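# Linear and curvilinear extrapolation baselines.

#' Linear extrapolation of a moving point
#'
#' Constant-velocity prediction: the displacement from `p_prev` to `p_curr`
#' is repeated, `p_curr + (p_curr - p_prev)`.
#'
#' @param p_prev,p_curr positions at the two most recent time steps
#'   (numeric 2-vectors, or n x 2 matrices treated row-wise).
#' @return predicted position(s) one step ahead.
#' @export
#' @examples
#' linear_extrapolate(c(0, 0), c(1, 0))  # c(2, 0)
linear_extrapolate <- function(p_prev, p_curr) {
  2 * p_curr - p_prev
}

#' Curvilinear (circular-arc) extrapolation of a moving point
#'
#' Constant speed and angular velocity: the signed angle `dtheta` between
#' the two most recent displacements is measured, and the latest
#' displacement, rotated by `dtheta`, is added to the current position. With
#' collinear inputs (`dtheta = 0`) this reduces exactly to
#' [linear_extrapolate()].
#'
#' Degenerate cases: a zero latest displacement returns `p_0` unchanged; a
#' zero previous displacement defines `dtheta = 0`.
#'
#' @param p_2,p_1,p_0 positions at times t-2, t-1, t (numeric 2-vectors).
#' @return predicted position at t+1.
#' @export
#' @examples
#' curvilinear_extrapolate(c(0, 0), c(1, 0), c(1, 1))  # c(0, 1): +90 deg turn
curvilinear_extrapolate <- function(p_2, p_1, p_0) {
  d1 <- p_1 - p_2
  d0 <- p_0 - p_1
  if (sum(d0^2) == 0) return(p_0)
  if (sum(d1^2) == 0) return(p_0 + d0)
  dtheta <- atan2(d1[1] * d0[2] - d1[2] * d0[1], sum(d1 * d0))
  p_0 + rot2(d0, dtheta)
}
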