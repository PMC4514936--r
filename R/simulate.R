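# Synthetic specimen generator
# ----------------------------
# Emulates the cadaver study design: n specimens, each carrying nine
# fiducial screws (3 skull, 3 maxilla, 3 mandible), a planned maxillary
# transform (advancement + asymmetric impaction), and three error sources
# with known ground truth:
#   * a mandibular (condylar seating) error transform,
#   * an intrinsic splint error transform,
#   * anisotropic per-screw deformation noise.
# Error transforms are parameterised as a rotation about the moving
# region's own barycenter plus a barycenter translation. The maxilla
# receives the composition splint-after-mandible in that parameterisation
# (rotations compose multiplicatively, barycenter translations add), so
# the additive decomposition MxRE = MdRE + SE holds exactly for the
# translation components by construction.

# Fixed template screw coordinates (mm) in the skull-based anatomical
# frame: x medio-lateral (+left), y antero-posterior (+anterior),
# z supero-inferior (+superior). Positions approximate the anatomical
# placement: skull = nasion + both infraorbital rims; maxilla = anterior
# nasal spine + both first-molar roots; mandible = symphysis + both lower
# first-molar roots.
TEMPLATE_POINTS <- list(
  skull    = rbind(c(  0, 85,  35),   # nasion
                   c(-32, 75,  25),   # right infraorbital rim
                   c( 32, 75,  25)),  # left infraorbital rim
  maxilla  = rbind(c(  0, 88,   5),   # below anterior nasal spine
                   c(-28, 55,   2),   # right upper first molar root
                   c( 28, 55,   2)),  # left upper first molar root
  mandible = rbind(c(  0, 82, -35),   # symphysis
                   c(-26, 52, -28),   # right lower first molar root
                   c( 26, 52, -28))   # left lower first molar root
)

# Buttress reference points (mm) used to realise the planned maxillary
# movement: displacements are prescribed at these three points and a rigid
# transform is fitted to them.
BUTTRESS_POINTS <- rbind(
  naso_maxillary_left  = c( 18, 78, 12),
  pterygo_maxillary_left  = c( 38, 42,  8),
  pterygo_maxillary_right = c(-38, 42,  8)
)

#' Template fiducial triads for the synthetic specimen
#'
#' Nine screws in anatomically plausible, fixed positions (skull: nasion
#' and both infraorbital rims; maxilla: anterior nasal spine and first
#' molar roots; mandible: symphysis and lower first molar roots), returned
#' as planned-timepoint triads. The coordinates are shipped constants so
#' that every downstream tolerance is conditioned on reproducible geometry.
#'
#' @return Named list of three [fiducial_triad()]s (skull, maxilla,
#'   mandible), timepoint `"planned"`.
#' @export
default_template <- function() {
  lapply(stats::setNames(REGIONS, REGIONS), function(rg)
    fiducial_triad(TEMPLATE_POINTS[[rg]], region = rg, timepoint = "planned"))
}

kabsch_point_fit <- function(P, Q) {
  # rigid transform x -> R x + t minimising sum |R p_i + t - q_i|^2
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- t(sweep(P, 2, cp)) %*% sweep(Q, 2, cq)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = cq - as.numeric(R %*% cp))
}

#' Rigid transform realising the planned maxillary movement
#'
#' The plan prescribes point displacements, not a transform: advancement of
#' the whole maxilla plus vertical repositioning at three buttress points
#' (superior on the left at the pterygo-maxillary and naso-maxillary
#' buttresses, inferior on the right at the pterygo-maxillary buttress).
#' A rigid transform is least-squares fitted to those three prescribed
#' displacements.
#'
#' @param advancement_mm antero-posterior advancement applied at all
#'   buttress points (default 5).
#' @param impaction_left_ptm_mm superior repositioning at the left
#'   pterygo-maxillary buttress (default 4).
#' @param impaction_left_nm_mm superior repositioning at the left
#'   naso-maxillary buttress (default 3).
#' @param lowering_right_ptm_mm inferior repositioning at the right
#'   pterygo-maxillary buttress (default 3).
#' @return List `R` (3x3 rotation), `t` (length-3 translation, mm), the
#'   affine map `x -> R x + t`.
#' @export
planned_maxillary_transform <- function(advancement_mm = 5,
                                        impaction_left_ptm_mm = 4,
                                        impaction_left_nm_mm = 3,
                                        lowering_right_ptm_mm = 3) {
  P <- BUTTRESS_POINTS
  disp <- rbind(c(0, advancement_mm,  impaction_left_nm_mm),
                c(0, advancement_mm,  impaction_left_ptm_mm),
                c(0, advancement_mm, -lowering_right_ptm_mm))
  kabsch_point_fit(P, P + disp)
}

#' Simulation configuration
#'
#' Holds the study design and the generative error models. Translation SDs
#' are mm on the x/y/z axes; rotation SDs are degrees for pitch/roll/yaw;
#' deformation SDs are per-region, per-axis mm applied independently to
#' every screw coordinate at the post-operative timepoint. Defaults mirror
#' the study design (10 specimens; 5 mm advancement with 4/3/3 mm vertical
#' repositioning) with error magnitudes chosen to be surgically realistic:
#' condylar seating error of order 1 mm / 1 degree, splint error somewhat
#' smaller in translation but with a wide pitch spread, and deformation
#' noise largest on the mandible's antero-posterior axis (the direction
#' loaded by maxillo-mandibular fixation wiring).
#'
#' @param n_heads number of specimens (>= 3).
#' @param advancement_mm,impaction_left_ptm_mm,impaction_left_nm_mm,lowering_right_ptm_mm
#'   planned maxillary movement, see [planned_maxillary_transform()].
#' @param mandible_trans_sd,mandible_rot_sd length-3 SDs of the mandibular
#'   error draws (mm; degrees).
#' @param splint_trans_sd,splint_rot_sd length-3 SDs of the splint error
#'   draws (mm; degrees).
#' @param deformation_sd named list of length-3 per-axis SDs (mm) for
#'   `skull`, `maxilla`, `mandible`.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_heads = 10,
                       advancement_mm = 5,
                       impaction_left_ptm_mm = 4,
                       impaction_left_nm_mm = 3,
                       lowering_right_ptm_mm = 3,
                       mandible_trans_sd = c(1.0, 0.9, 0.6),
                       mandible_rot_sd = c(1.0, 0.6, 0.9),
                       splint_trans_sd = c(0.6, 0.8, 0.5),
                       splint_rot_sd = c(2.0, 1.0, 1.0),
                       deformation_sd = list(
                         skull    = c(0.25, 0.35, 0.30),
                         maxilla  = c(0.40, 0.30, 0.35),
                         mandible = c(0.85, 1.90, 0.65))) {
  cfg <- list(n_heads = as.integer(n_heads),
              advancement_mm = advancement_mm,
              impaction_left_ptm_mm = impaction_left_ptm_mm,
              impaction_left_nm_mm = impaction_left_nm_mm,
              lowering_right_ptm_mm = lowering_right_ptm_mm,
              mandible_trans_sd = as.numeric(mandible_trans_sd),
              mandible_rot_sd = as.numeric(mandible_rot_sd),
              splint_trans_sd = as.numeric(splint_trans_sd),
              splint_rot_sd = as.numeric(splint_rot_sd),
              deformation_sd = lapply(deformation_sd, as.numeric))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_heads < 3L) stop("n_heads must be >= 3")
  sds <- c(cfg$mandible_trans_sd, cfg$mandible_rot_sd,
           cfg$splint_trans_sd, cfg$splint_rot_sd,
           unlist(cfg$deformation_sd))
  if (any(!is.finite(sds)) || any(sds < 0))
    stop("all error-model SDs must be finite and >= 0")
  lens <- c(length(cfg$mandible_trans_sd), length(cfg$mandible_rot_sd),
            length(cfg$splint_trans_sd), length(cfg$splint_rot_sd),
            lengths(cfg$deformation_sd))
  if (any(lens != 3L)) stop("error-model SDs must each have length 3")
  if (!all(REGIONS %in% names(cfg$deformation_sd)))
    stop("deformation_sd must name skull, maxilla and mandible")
  invisible(cfg)
}

# rotate about the point set's own barycenter, then translate
apply_about_barycenter <- function(points, R, t) {
  b <- colMeans(points)
  sweep(sweep(points, 2, b) %*% t(R), 2, b + t, "+")
}

draw_transform <- function(trans_sd, rot_sd) {
  t <- stats::rnorm(3, 0, trans_sd)
  ang <- stats::rnorm(3, 0, rot_sd)
  list(t = t, pitch = ang[1], roll = ang[2], yaw = ang[3],
       R = euler_to_matrix(ang[1], ang[2], ang[3]))
}

#' Simulate a complete synthetic study with known ground truth
#'
#' For each specimen the skull stays put (deformation noise only, mirroring
#' its role as registration reference); the mandible receives a drawn
#' condylar error transform; the maxilla's planned position is the template
#' after the planned advancement/impaction transform, and its
#' post-operative position is that planned position carried through the
#' mandibular error and then the splint error (rotations about the
#' maxilla's own barycenter, translations added), plus deformation noise on
#' every screw. All draws come from R's global RNG, so `set.seed()` before
#' calling (or pass `seed`) makes the output — including the landmark
#' table — bit-reproducible.
#'
#' @param config a [sim_config()].
#' @param seed optional integer; when given, `set.seed(seed)` is called
#'   first.
#' @return List of class `specimen_set`:
#'   * `landmarks` — long data.frame (head_id, timepoint, region,
#'     screw_label, x_mm, y_mm, z_mm), 18 rows per specimen;
#'   * `triads` — nested list `triads[[head]][[region]][[timepoint]]` of
#'     [fiducial_triad()]s;
#'   * `ground_truth` — per specimen, the exact mandible, splint and
#'     maxilla (= splint o mandible) transforms and deformation draws;
#'   * `config`, `seed`.
#' @export
simulate_study <- function(config = sim_config(), seed = NULL) {
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  template <- default_template()
  plan_tf <- planned_maxillary_transform(config$advancement_mm,
                                         config$impaction_left_ptm_mm,
                                         config$impaction_left_nm_mm,
                                         config$lowering_right_ptm_mm)
  maxilla_planned <- sweep(template$maxilla$points %*% t(plan_tf$R),
                           2, plan_tf$t, "+")

  heads <- sprintf("H%02d", seq_len(config$n_heads))
  triads <- vector("list", config$n_heads)
  names(triads) <- heads
  truth <- vector("list", config$n_heads)
  names(truth) <- heads
  rows <- vector("list", config$n_heads)

  for (h in seq_len(config$n_heads)) {
    md <- draw_transform(config$mandible_trans_sd, config$mandible_rot_sd)
    se <- draw_transform(config$splint_trans_sd, config$splint_rot_sd)
    noise <- lapply(stats::setNames(REGIONS, REGIONS), function(rg) {
      sd3 <- config$deformation_sd[[rg]]
      matrix(stats::rnorm(9, 0, rep(sd3, each = 3)), 3, 3)
    })

    plan_pts <- list(skull = template$skull$points,
                     maxilla = maxilla_planned,
                     mandible = template$mandible$points)
    post_pts <- list(
      skull = plan_pts$skull + noise$skull,
      maxilla = apply_about_barycenter(
        apply_about_barycenter(plan_pts$maxilla, md$R, md$t),
        se$R, se$t) + noise$maxilla,
      mandible = apply_about_barycenter(plan_pts$mandible, md$R, md$t) +
        noise$mandible)

    triads[[h]] <- lapply(stats::setNames(REGIONS, REGIONS), function(rg)
      list(planned = fiducial_triad(plan_pts[[rg]], rg, "planned"),
           postop = fiducial_triad(post_pts[[rg]], rg, "postop")))
    truth[[h]] <- list(
      mandible = md[c("t", "pitch", "roll", "yaw", "R")],
      splint = se[c("t", "pitch", "roll", "yaw", "R")],
      maxilla = list(t = md$t + se$t, R = se$R %*% md$R),
      deformation = noise)

    rows[[h]] <- do.call(rbind, lapply(REGIONS, function(rg) {
      rbind(
        data.frame(head_id = heads[h], timepoint = "planned", region = rg,
                   screw_label = c("1", "2", "3"),
                   x_mm = plan_pts[[rg]][, 1], y_mm = plan_pts[[rg]][, 2],
                   z_mm = plan_pts[[rg]][, 3], stringsAsFactors = FALSE),
        data.frame(head_id = heads[h], timepoint = "postop", region = rg,
                   screw_label = c("1", "2", "3"),
                   x_mm = post_pts[[rg]][, 1], y_mm = post_pts[[rg]][, 2],
                   z_mm = post_pts[[rg]][, 3], stringsAsFactors = FALSE))
    }))
  }
  landmarks <- do.call(rbind, rows)
  rownames(landmarks) <- NULL
  structure(list(landmarks = landmarks, triads = triads,
                 ground_truth = truth, config = config, seed = seed),
            class = "specimen_set")
}

#' @export
print.specimen_set <- function(x, ...) {
  cat("<specimen_set>", x$config$n_heads, "specimens,",
      nrow(x$landmarks), "landmark rows",
      if (!is.null(x$seed)) paste0("(seed ", x$seed, ")"), "\n")
  invisible(x)
}

#' Write the full simulation output to a directory
#'
#' Emits the landmark CSV ([write_landmarks()]), the ground-truth transform
#' parameters per specimen (`ground_truth.json`) and the configuration
#' (`sim_config.json`), all seed-stamped.
#'
#' @param sim a [simulate_study()] result.
#' @param dir output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  if (!inherits(sim, "specimen_set")) stop("`sim` must be a specimen_set")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(landmarks = file.path(dir, "landmarks.csv"),
             ground_truth = file.path(dir, "ground_truth.json"),
             config = file.path(dir, "sim_config.json"))
  write_landmarks(sim$landmarks, paths[["landmarks"]])
  gt <- lapply(sim$ground_truth, function(g)
    list(mandible = g$mandible[c("t", "pitch", "roll", "yaw")],
         splint = g$splint[c("t", "pitch", "roll", "yaw")],
         maxilla = list(t = g$maxilla$t)))
  jsonlite::write_json(list(seed = sim$seed, specimens = gt),
                       paths[["ground_truth"]], digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(c(list(seed = sim$seed), unclass(sim$config)),
                       paths[["config"]], digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}
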