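# Shared fixtures and independent oracles for the test suite.

# A well-spread reference triangle (mm) used to build valid triads quickly.
BASE_TRIANGLE <- rbind(c(0, 0, 0), c(34, 5, -3), c(8, 30, 12))

make_triad <- function(points, region = "maxilla", timepoint = "planned") {
  fiducial_triad(points, region = region, timepoint = timepoint)
}

random_triad <- function(region = "maxilla", timepoint = "planned",
                         jitter = 3) {
  make_triad(BASE_TRIANGLE + matrix(stats::rnorm(9, 0, jitter), 3, 3),
             region, timepoint)
}

random_rotation <- function(max_deg = 20) {
  a <- stats::runif(3, -max_deg, max_deg)
  list(R = euler_to_matrix(a[1], a[2], a[3]),
       pitch = a[1], roll = a[2], yaw = a[3])
}

# geodesic angle (degrees) between two rotations
rotation_distance_deg <- function(R1, R2) {
  tr <- max(-1, min(3, sum(diag(R1 %*% t(R2)))))
  (180 / pi) * acos((tr - 1) / 2)
}

# Brute-force rotation oracle: dense grid search over pitch/roll/yaw,
# coarse pass over +/- span then successive local refinements down to a
# final step below 0.1 degrees. Independent of the SVD path it checks.
brute_force_rotation <- function(P, Q, span = 25, coarse = 5) {
  best <- c(0, 0, 0)
  best_cost <- Inf
  sweep_grid <- function(center, half, step) {
    gp <- seq(center[1] - half, center[1] + half, by = step)
    gr <- seq(center[2] - half, center[2] + half, by = step)
    gy <- seq(center[3] - half, center[3] + half, by = step)
    for (p in gp) for (r in gr) for (y in gy) {
      R <- euler_to_matrix(p, r, y)
      cost <- sum((Q - P %*% t(R))^2)
      if (cost < best_cost) {
        best_cost <<- cost
        best <<- c(p, r, y)
      }
    }
  }
  sweep_grid(c(0, 0, 0), span, coarse)
  step <- coarse
  while (step > 0.03) {
    new_step <- step / 5
    sweep_grid(best, step, new_step)
    step <- new_step
  }
  list(R = euler_to_matrix(best[1], best[2], best[3]),
       angles = best, cost = best_cost, final_step = step)
}

# Brute-force rigid fit: rotation by grid search, translation closed-form
# given the rotation (centroid matching). Returns per-screw residuals.
brute_force_rigid_residuals <- function(plan_pts, post_pts, ...) {
  cp <- colMeans(plan_pts)
  cq <- colMeans(post_pts)
  P <- sweep(plan_pts, 2, cp)
  Q <- sweep(post_pts, 2, cq)
  bf <- brute_force_rotation(P, Q, ...)
  fitted <- sweep(P %*% t(bf$R), 2, cq, "+")
  post_pts - fitted
}

# Published accuracy tables used as fixed inputs: Bland-Altman limits with
# CI bounds and the matching RMSD cells, for the overall (three-region) and
# splint analyses, n = 10 specimens. splint rotational RMSD cells are known
# to be inconsistent with their limits (see identity_check flag).
printed_tables <- function() {
  df <- read.csv(text = "
region,component,kind,lower,lower_ci_lo,lower_ci_hi,upper,upper_ci_lo,upper_ci_hi,rmsd,identity_check
skull,mediolateral,translational,-0.08,-0.14,-0.02,0.11,0.05,0.17,0.05,TRUE
skull,anteroposterior,translational,-0.39,-0.61,-0.18,0.29,0.08,0.51,0.17,TRUE
skull,superoinferior,translational,-0.33,-0.58,-0.08,0.46,0.21,0.71,0.20,TRUE
skull,pitch,rotational,-1.52,-2.25,-0.79,0.83,0.10,1.56,0.67,TRUE
skull,roll,rotational,-0.65,-1.05,-0.25,0.64,0.24,1.04,0.31,TRUE
skull,yaw,rotational,-0.22,-0.34,-0.10,0.17,0.05,0.29,0.10,TRUE
mandible,mediolateral,translational,-3.21,-5.63,-0.79,4.56,2.14,6.98,2.00,TRUE
mandible,anteroposterior,translational,-1.82,-3.57,-0.07,3.81,2.06,5.56,1.69,TRUE
mandible,superoinferior,translational,-1.42,-2.73,-0.10,2.80,1.49,4.11,1.23,TRUE
mandible,pitch,rotational,-2.17,-3.50,-0.84,2.09,0.77,3.42,1.03,TRUE
mandible,roll,rotational,-1.16,-1.95,-0.37,1.38,0.59,2.18,0.63,TRUE
mandible,yaw,rotational,-1.35,-2.54,-0.15,2.49,1.30,3.69,1.09,TRUE
maxilla,mediolateral,translational,-2.67,-4.59,-0.75,3.50,1.58,5.42,1.55,TRUE
maxilla,anteroposterior,translational,-1.84,-3.90,0.22,4.77,2.71,6.83,2.17,TRUE
maxilla,superoinferior,translational,-1.55,-2.58,-0.51,1.78,0.74,2.81,0.81,TRUE
maxilla,pitch,rotational,-5.46,-9.81,-1.12,8.49,4.15,12.84,3.70,TRUE
maxilla,roll,rotational,-2.76,-5.09,-0.44,4.72,2.39,7.04,2.06,TRUE
maxilla,yaw,rotational,-1.92,-3.11,-0.72,1.92,0.73,3.12,0.93,TRUE
splint,mediolateral,translational,-2.71,-4.12,-1.30,1.83,0.41,3.24,1.18,TRUE
splint,anteroposterior,translational,-2.23,-4.09,-0.37,3.74,1.88,5.60,1.63,TRUE
splint,superoinferior,translational,-1.63,-2.87,-0.39,2.35,1.11,3.59,1.03,TRUE
splint,pitch,rotational,-9.33,-14.16,-4.49,6.22,1.38,11.06,1.03,FALSE
splint,roll,rotational,-4.60,-6.92,-2.27,2.87,0.54,5.19,0.63,FALSE
splint,yaw,rotational,-1.51,-2.81,-0.22,2.65,1.35,3.94,1.09,FALSE
", stringsAsFactors = FALSE, strip.white = TRUE)
  df$n <- 10L
  df
}

# a difference series with an exactly prescribed sample mean and SD
series_with_stats <- function(mean, sd, n, seed = 7) {
  set.seed(seed)
  x <- stats::rnorm(n)
  mean + sd * (x - base::mean(x)) / stats::sd(x)
}

rot_for_test <- function(pitch, roll, yaw) euler_to_matrix(pitch, roll, yaw)

comp_cols <- c("dx_mm", "dy_mm", "dz_mm", "pitch_deg", "roll_deg", "yaw_deg")
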