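# Rotation conventions
# --------------------
# Angles are degrees; the rotation matrix acting on column vectors is
#   R = Rx(pitch) %*% Ry(roll) %*% Rz(yaw)
# i.e. yaw (about the supero-inferior z axis) is applied first, then roll
# (about the antero-posterior y axis), then pitch (about the medio-lateral
# x axis). Signs follow the right-hand rule about +x, +y, +z. At the few
# degrees seen in surgical repositioning the decomposition order is a
# second-order effect.

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

rot_x <- function(deg) {
  a <- deg2rad(deg); c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}
rot_y <- function(deg) {
  a <- deg2rad(deg); c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}
rot_z <- function(deg) {
  a <- deg2rad(deg); c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' Build a rotation matrix from pitch / roll / yaw angles
#'
#' @param pitch rotation about the medio-lateral x axis (degrees).
#' @param roll rotation about the antero-posterior y axis (degrees).
#' @param yaw rotation about the supero-inferior z axis (degrees).
#' @return 3x3 proper orthogonal matrix `Rx(pitch) Ry(roll) Rz(yaw)`.
#' @seealso [matrix_to_euler()] for the inverse.
#' @export
euler_to_matrix <- function(pitch, roll, yaw) {
  rot_x(pitch) %*% rot_y(roll) %*% rot_z(yaw)
}

#' Extract pitch / roll / yaw from a rotation matrix
#'
#' Inverts [euler_to_matrix()]. Near `|roll| = 90` degrees the decomposition
#' is singular (gimbal lock); angles are still returned (with yaw set by the
#' atan2 convention) and the `gimbal_lock` flag is raised. Surgical rotations
#' are far below 90 degrees, so the flag indicates corrupt input.
#'
#' @param R 3x3 proper orthogonal matrix.
#' @return List with `pitch`, `roll`, `yaw` (degrees, each in (-180, 180])
#'   and logical `gimbal_lock`.
#' @export
matrix_to_euler <- function(R) {
  s <- max(-1, min(1, R[1, 3]))
  roll <- asin(s)
  lock <- abs(s) > 1 - 1e-9
  if (lock) {
    # only pitch +/- yaw is determined; conventionally put it all in pitch
    pitch <- atan2(R[2, 1], R[2, 2])
    yaw <- 0
  } else {
    pitch <- atan2(-R[2, 3], R[3, 3])
    yaw <- atan2(-R[1, 2], R[1, 1])
  }
  list(pitch = rad2deg(pitch), roll = rad2deg(roll), yaw = rad2deg(yaw),
       gimbal_lock = lock)
}

rotation_angle_deg <- function(R) {
  # geodesic distance of R from the identity
  tr <- max(-1, min(3, sum(diag(R))))
  rad2deg(acos((tr - 1) / 2))
}

#' Translation difference between planned and post-operative triads
#'
#' The barycenter displacement, post-operative minus planned, resolved on
#' the anatomical axes, plus its Euclidean magnitude.
#'
#' @param plan,post matched [fiducial_triad()]s of the same region at the
#'   planned and postop timepoints.
#' @return Object of class `translation_difference`: `region`, `components`
#'   (named dx/dy/dz, mm) and `magnitude` (mm).
#' @export
translation_difference <- function(plan, post) {
  check_matched_triads(plan, post)
  d <- as.numeric(barycenter(post) - barycenter(plan))
  names(d) <- c("dx", "dy", "dz")
  structure(list(region = plan$region, components = d,
                 magnitude = sqrt(sum(d^2))),
            class = "translation_difference")
}

#' Least-squares rotation between two vector triads (Kabsch)
#'
#' Finds the proper rotation `R` minimising `sum_i |R v_plan_i - v_post_i|^2`
#' over the three barycenter-to-screw vectors, by singular value
#' decomposition of the cross-covariance with the reflection branch
#' excluded (orthogonal Procrustes). The post-rotation misfit is reported
#' as an RMSE over the three vectors; it is zero iff the motion between the
#' timepoints was exactly rigid.
#'
#' @param plan_vectors,post_vectors matched [vector_triad()]s of one region.
#' @return Object of class `rotation_estimate`: `region`, `R` (3x3 proper
#'   orthogonal), `transformed_y_axis` (image of the unit +y axis under `R`)
#'   and `residual_rmse` (mm).
#' @export
estimate_rotation <- function(plan_vectors, post_vectors) {
  if (!inherits(plan_vectors, "vector_triad") ||
      !inherits(post_vectors, "vector_triad"))
    stop("inputs must be vector_triad objects (see vector_triad())")
  if (attr(plan_vectors, "region") != attr(post_vectors, "region"))
    stop("region mismatch between vector triads")
  P <- unclass(plan_vectors)
  Q <- unclass(post_vectors)
  H <- t(P) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) stop("degenerate vector triads: rotation is not identifiable")
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  resid <- Q - P %*% t(R)
  structure(list(region = attr(plan_vectors, "region"),
                 R = R,
                 transformed_y_axis = as.numeric(R %*% c(0, 1, 0)),
                 residual_rmse = sqrt(mean(rowSums(resid^2)))),
            class = "rotation_estimate")
}

#' Pitch / roll / yaw angles of a rotation estimate
#'
#' Two conventions are offered. `"standard"` (default) is the full Euler
#' decomposition of the fitted rotation matrix via [matrix_to_euler()]:
#' well defined for every rotation and exactly invertible. `"y_axis_literal"`
#' evaluates the single-axis arctangent formulas sometimes used in the
#' craniofacial literature, which read the angles off the transformed +y
#' axis only: `pitch = atan2(y_z, y_y)`, `roll = atan2(y_x, y_y)`,
#' `yaw = atan2(y_y, y_x)`. That yaw formula returns 90 degrees at the
#' identity and none of the three can sense rotation about y itself, so the
#' literal convention is retained for traceability, not as a default.
#'
#' @param est a [estimate_rotation()] result.
#' @param convention `"standard"` or `"y_axis_literal"`.
#' @return Object of class `rotation_difference`: `region`, `pitch`, `roll`,
#'   `yaw` (degrees), `convention`, `gimbal_lock` flag.
#' @export
rotation_angles <- function(est, convention = c("standard", "y_axis_literal")) {
  if (!inherits(est, "rotation_estimate"))
    stop("`est` must be a rotation_estimate")
  convention <- match.arg(convention)
  if (convention == "standard") {
    e <- matrix_to_euler(est$R)
    ang <- list(pitch = e$pitch, roll = e$roll, yaw = e$yaw)
    lock <- e$gimbal_lock
  } else {
    y <- est$transformed_y_axis
    ang <- list(pitch = rad2deg(atan2(y[3], y[2])),
                roll  = rad2deg(atan2(y[1], y[2])),
                yaw   = rad2deg(atan2(y[2], y[1])))
    lock <- FALSE
  }
  structure(c(list(region = est$region), ang,
              list(convention = convention, gimbal_lock = lock)),
            class = "rotation_difference")
}

#' Full pose difference of one region between planned and post-operative
#'
#' Composes [translation_difference()], [estimate_rotation()] on the
#' [vector_triad()]s, and [rotation_angles()].
#'
#' @inheritParams translation_difference
#' @param convention angle convention, see [rotation_angles()].
#' @return Object of class `pose_difference` with elements `region`,
#'   `translation`, `rotation`, `rotation_estimate`.
#' @export
pose_difference <- function(plan, post,
                            convention = c("standard", "y_axis_literal")) {
  convention <- match.arg(convention)
  check_matched_triads(plan, post)
  est <- estimate_rotation(vector_triad(plan), vector_triad(post))
  structure(list(region = plan$region,
                 translation = translation_difference(plan, post),
                 rotation = rotation_angles(est, convention),
                 rotation_estimate = est),
            class = "pose_difference")
}

#' @export
print.pose_difference <- function(x, ...) {
  cat("<pose_difference>", x$region, "\n")
  cat(sprintf("  translation (mm): dx=%.3f dy=%.3f dz=%.3f  |t|=%.3f\n",
              x$translation$components[1], x$translation$components[2],
              x$translation$components[3], x$translation$magnitude))
  cat(sprintf("  rotation (deg, %s): pitch=%.3f roll=%.3f yaw=%.3f\n",
              x$rotation$convention, x$rotation$pitch, x$rotation$roll,
              x$rotation$yaw))
  cat(sprintf("  rigid-fit residual RMSE: %.4f mm\n",
              x$rotation_estimate$residual_rmse))
  invisible(x)
}

#' One-row data frame serialisation of a pose difference
#'
#' @param x a [pose_difference()].
#' @param row.names,optional,... passed for S3 compatibility, unused.
#' @return data.frame with columns region, dx_mm..dz_mm, magnitude_mm,
#'   pitch_deg, roll_deg, yaw_deg, convention, residual_rmse_mm.
#' @export
as.data.frame.pose_difference <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  data.frame(region = x$region,
             dx_mm = unname(x$translation$components[1]),
             dy_mm = unname(x$translation$components[2]),
             dz_mm = unname(x$translation$components[3]),
             magnitude_mm = x$translation$magnitude,
             pitch_deg = x$rotation$pitch,
             roll_deg = x$rotation$roll,
             yaw_deg = x$rotation$yaw,
             convention = x$rotation$convention,
             residual_rmse_mm = x$rotation_estimate$residual_rmse,
             stringsAsFactors = FALSE)
}
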