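# Constant-velocity Kalman filter over box states.
#
# State: (cx, cy, a, h, v_cx, v_cy, v_a, v_h) where (cx, cy) is the box
# center, a = w/h the aspect ratio and h the height, each with a per-frame
# velocity. Process and measurement noise scale with the box height, the
# convention of the tracker family this follows: a pig filling more of the
# image moves more pixels per frame, so uncertainty is proportional to
# apparent size.

KF_STD_POS <- 1 / 20   # position noise as a fraction of box height
KF_STD_VEL <- 1 / 160  # velocity noise as a fraction of box height

kf_transition <- function() {
  F <- diag(8)
  F[cbind(1:4, 5:8)] <- 1  # position += velocity (dt = 1 frame)
  F
}

kf_observation <- function() cbind(diag(4), matrix(0, 4, 4))

box_to_xyah <- function(b) {
  w <- b[["x2"]] - b[["x1"]]
  h <- b[["y2"]] - b[["y1"]]
  c((b[["x1"]] + b[["x2"]]) / 2, (b[["y1"]] + b[["y2"]]) / 2, w / h, h)
}

xyah_to_box <- function(z) {
  # guard: velocity extrapolation over a long unmatched stretch can drive
  # h or a non-positive; clamp to a 1 px extent so the projected box stays
  # a valid rectangle
  h <- max(z[4L], 1)
  w <- max(z[3L] * h, 1)
  box(z[1L] - w / 2, z[2L] - h / 2, z[1L] + w / 2, z[2L] + h / 2)
}

new_kalman_state <- function(mean, cov) {
  structure(list(mean = mean, cov = cov), class = "kalman_state")
}

#' Initialize a Kalman state from a box
#'
#' The mean holds the observed `(cx, cy, a, h)` with zero velocities; the
#' covariance is diagonal, scaled by the box height (position-like terms)
#' with small constants on the dimensionless aspect-ratio terms.
#'
#' @param b A [box()].
#' @return A `kalman_state`: list with an 8-vector `mean` and an 8x8
#'   covariance matrix.
#' @export
kalman_initiate <- function(b) {
  z <- box_to_xyah(b)
  h <- z[4L]
  std <- c(2 * KF_STD_POS * h, 2 * KF_STD_POS * h, 1e-2, 2 * KF_STD_POS * h,
           10 * KF_STD_VEL * h, 10 * KF_STD_VEL * h, 1e-5, 10 * KF_STD_VEL * h)
  new_kalman_state(c(z, 0, 0, 0, 0), diag(std^2))
}

#' Advance a Kalman state one frame
#'
#' Constant-velocity transition (position += velocity) and process-noise
#' inflation of the covariance.
#'
#' @param state A `kalman_state`.
#' @return The predicted `kalman_state`.
#' @export
kalman_predict <- function(state) {
  F <- kf_transition()
  h <- state$mean[4L]
  std <- c(KF_STD_POS * h, KF_STD_POS * h, 1e-2, KF_STD_POS * h,
           KF_STD_VEL * h, KF_STD_VEL * h, 1e-5, KF_STD_VEL * h)
  new_kalman_state(as.numeric(F %*% state$mean),
                   F %*% state$cov %*% t(F) + diag(std^2))
}

#' Correct a predicted Kalman state with an observed box
#'
#' Standard linear-Gaussian update toward the observed `(cx, cy, a, h)`.
#' The posterior covariance never exceeds the prior on the observed
#' components.
#'
#' @param state A predicted `kalman_state`.
#' @param b The observed [box()].
#' @param meas_scale Multiplier on the measurement noise; values below 1
#'   trust the observation more (at 0 the posterior box equals the
#'   observation).
#' @return The corrected `kalman_state`.
#' @export
kalman_update <- function(state, b, meas_scale = 1) {
  H <- kf_observation()
  z <- box_to_xyah(b)
  h <- state$mean[4L]
  std <- c(KF_STD_POS * h, KF_STD_POS * h, 1e-1, KF_STD_POS * h) * meas_scale
  R <- diag(std^2)
  S <- H %*% state$cov %*% t(H) + R
  K <- state$cov %*% t(H) %*% solve(S)
  innov <- z - as.numeric(H %*% state$mean)
  mean_new <- as.numeric(state$mean + K %*% innov)
  cov_new <- (diag(8) - K %*% H) %*% state$cov
  new_kalman_state(mean_new, (cov_new + t(cov_new)) / 2)
}

#' Project a Kalman state back to a box
#'
#' @param state A `kalman_state`.
#' @return The [box()] implied by the state's `(cx, cy, a, h)`.
#' @export
kalman_box <- function(state) {
  xyah_to_box(state$mean[1:4])
}
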