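# Landmark file dialect
# ---------------------
# CSV, one row per screw observation:
#   head_id, timepoint(planned|postop), region(skull|maxilla|mandible),
#   screw_label(1|2|3), x_mm, y_mm, z_mm
# header required, decimal point, UTF-8; the writer emits coordinates with
# fixed 6-decimal formatting so write -> read round trips bit-exactly.
# A JSON array of the same row records is accepted as an equivalent dialect.

LANDMARK_COLUMNS <- c("head_id", "timepoint", "region", "screw_label",
                      "x_mm", "y_mm", "z_mm")

AXIS_COMPONENTS <- c(dx_mm = "mediolateral", dy_mm = "anteroposterior",
                     dz_mm = "superoinferior")
ANGLE_COMPONENTS <- c(pitch_deg = "pitch", roll_deg = "roll",
                      yaw_deg = "yaw")

#' Read a landmark table
#'
#' Accepts the landmark CSV dialect or an equivalent JSON array of row
#' records (chosen by file extension). The schema is validated strictly —
#' missing columns, unknown region/timepoint tokens (reported with their
#' row numbers), non-finite coordinates and duplicate
#' (head, timepoint, region, label) rows are all distinct errors — because
#' a silently mis-parsed landmark file corrupts every downstream statistic.
#'
#' @param path file to read (`.csv` or `.json`).
#' @return data.frame with the seven landmark columns.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("landmark file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
    if (!is.data.frame(df))
      stop("landmark JSON must be an array of row records")
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  }
  validate_landmarks(df, source = path)
}

#' Validate a landmark data frame
#'
#' @param df candidate landmark table.
#' @param source label used in error messages.
#' @return The validated data.frame (columns coerced and ordered).
#' @export
validate_landmarks <- function(df, source = "landmarks") {
  miss <- setdiff(LANDMARK_COLUMNS, names(df))
  if (length(miss))
    stop(source, ": missing required columns: ", paste(miss, collapse = ", "))
  df <- df[LANDMARK_COLUMNS]
  df$head_id <- as.character(df$head_id)
  df$timepoint <- as.character(df$timepoint)
  df$region <- as.character(df$region)
  df$screw_label <- as.character(df$screw_label)
  bad_tp <- which(!df$timepoint %in% TIMEPOINTS)
  if (length(bad_tp))
    stop(source, ": unknown timepoint token(s) ",
         paste(unique(df$timepoint[bad_tp]), collapse = ", "),
         " at row(s) ", paste(utils::head(bad_tp, 5), collapse = ", "))
  bad_rg <- which(!df$region %in% REGIONS)
  if (length(bad_rg))
    stop(source, ": unknown region token(s) ",
         paste(unique(df$region[bad_rg]), collapse = ", "),
         " at row(s) ", paste(utils::head(bad_rg, 5), collapse = ", "))
  for (cc in c("x_mm", "y_mm", "z_mm")) {
    df[[cc]] <- as.numeric(df[[cc]])
    if (any(!is.finite(df[[cc]])))
      stop(source, ": non-finite ", cc, " at row(s) ",
           paste(utils::head(which(!is.finite(df[[cc]])), 5), collapse = ", "))
  }
  key <- paste(df$head_id, df$timepoint, df$region, df$screw_label)
  if (anyDuplicated(key))
    stop(source, ": duplicate (head, timepoint, region, label) row(s): ",
         paste(utils::head(unique(key[duplicated(key)]), 5), collapse = "; "))
  df
}

#' Write a landmark table
#'
#' Emits the CSV dialect (or the JSON record array for a `.json` path) with
#' coordinates formatted to exactly 6 decimals, so that writing and
#' re-reading is lossless and byte-stable.
#'
#' @param df landmark data.frame.
#' @param path destination file.
#' @return Invisibly, `path`.
#' @export
write_landmarks <- function(df, path) {
  df <- validate_landmarks(df)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    out <- df
    for (cc in c("x_mm", "y_mm", "z_mm"))
      out[[cc]] <- as.numeric(sprintf("%.6f", out[[cc]]))
    jsonlite::write_json(out, path, dataframe = "rows", digits = 6)
  } else {
    out <- df
    for (cc in c("x_mm", "y_mm", "z_mm"))
      out[[cc]] <- sprintf("%.6f", out[[cc]])
    utils::write.table(out, path, sep = ",", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Assemble validated triads from a landmark table
#'
#' @param df landmark data.frame (validated).
#' @return Nested list `triads[[head]][[region]][[timepoint]]` of
#'   [fiducial_triad()]s; every specimen must have all 6 triads with screw
#'   labels 1..3.
#' @export
landmarks_to_triads <- function(df) {
  df <- validate_landmarks(df)
  heads <- unique(df$head_id)
  out <- lapply(stats::setNames(heads, heads), function(h) {
    lapply(stats::setNames(REGIONS, REGIONS), function(rg) {
      lapply(stats::setNames(TIMEPOINTS, TIMEPOINTS), function(tp) {
        sub <- df[df$head_id == h & df$region == rg & df$timepoint == tp, ]
        if (!identical(sort(sub$screw_label), c("1", "2", "3")))
          stop("specimen ", h, ", region ", rg, ", timepoint ", tp,
               ": expected screws 1,2,3, found {",
               paste(sort(sub$screw_label), collapse = ","), "}")
        sub <- sub[order(sub$screw_label), ]
        fiducial_triad(as.matrix(sub[c("x_mm", "y_mm", "z_mm")]),
                       region = rg, timepoint = tp,
                       labels = sub$screw_label)
      })
    })
  })
  out
}

#' Study analysis configuration
#'
#' @param cutoff_translational_mm accuracy cutoff for translational RMSD
#'   (default 2 mm).
#' @param cutoff_rotational_deg accuracy cutoff for rotational RMSD
#'   (default 4 degrees).
#' @param df_mode degrees of freedom for limit CIs, see [bland_altman()].
#' @param convention rotation-angle convention, see [rotation_angles()].
#' @param frame registration frame: `"skull"` (default; coordinates are
#'   used as given, the skull being the fusion reference) or `"mandible"`
#'   (post-operative coordinates are re-expressed by undoing each
#'   specimen's best-fit mandibular motion first, so maxillary differences
#'   reflect the splint alone).
#' @param digits decimal places for the rendered report tables.
#' @return Object of class `study_config`.
#' @export
study_config <- function(cutoff_translational_mm = 2,
                         cutoff_rotational_deg = 4,
                         df_mode = c("n_minus_1", "n"),
                         convention = c("standard", "y_axis_literal"),
                         frame = c("skull", "mandible"),
                         digits = 2) {
  if (cutoff_translational_mm <= 0 || cutoff_rotational_deg <= 0)
    stop("cutoffs must be positive")
  structure(list(cutoff_translational_mm = cutoff_translational_mm,
                 cutoff_rotational_deg = cutoff_rotational_deg,
                 df_mode = match.arg(df_mode),
                 convention = match.arg(convention),
                 frame = match.arg(frame),
                 digits = digits),
            class = "study_config")
}

to_mandible_frame <- function(head_triads) {
  # undo the specimen's best-fit mandibular rigid motion on every postop
  # triad: x' = R^T (x - b_post) + b_plan
  fit <- rigid_fit(head_triads$mandible$planned,
                   head_triads$mandible$postop)
  lapply(head_triads, function(rt) {
    pts <- sweep(sweep(rt$postop$points, 2, fit$bary_post) %*% fit$R,
                 2, fit$bary_plan, "+")
    list(planned = rt$planned,
         postop = fiducial_triad(pts, rt$postop$region, "postop",
                                 labels = rownames(rt$postop$points)))
  })
}

series_tables <- function(series_df, regions, config) {
  # series_df: head_id, region, six signed components
  n_map <- list()
  rows_rmsd <- list()
  rows_lim <- list()
  comps <- c(AXIS_COMPONENTS, ANGLE_COMPONENTS)
  for (rg in regions) {
    sub <- series_df[series_df$region == rg, , drop = FALSE]
    for (col in names(comps)) {
      kind <- if (col %in% names(AXIS_COMPONENTS)) "translational" else "rotational"
      cutoff <- if (kind == "translational") config$cutoff_translational_mm
                else config$cutoff_rotational_deg
      vals <- sub[[col]]
      r <- rmsd(vals)
      rows_rmsd[[length(rows_rmsd) + 1L]] <- data.frame(
        region = rg, component = comps[[col]], kind = kind, n = length(vals),
        rmsd = r, within_cutoff = classify_accuracy(
          r, kind, c(translational = config$cutoff_translational_mm,
                     rotational = config$cutoff_rotational_deg)),
        cutoff = cutoff, stringsAsFactors = FALSE)
      ba <- bland_altman(vals, config$df_mode)
      rows_lim[[length(rows_lim) + 1L]] <- data.frame(
        region = rg, component = comps[[col]], kind = kind, n = ba$n,
        mean_diff = ba$mean_diff, sd = ba$sd,
        lower = ba$lower_limit, lower_ci_lo = ba$ci_lower_limit[1],
        lower_ci_hi = ba$ci_lower_limit[2],
        upper = ba$upper_limit, upper_ci_lo = ba$ci_upper_limit[1],
        upper_ci_hi = ba$ci_upper_limit[2], stringsAsFactors = FALSE)
    }
  }
  list(rmsd = do.call(rbind, rows_rmsd), limits = do.call(rbind, rows_lim))
}

#' Run the full accuracy analysis
#'
#' From a landmark table (or a [simulate_study()] result) to the complete
#' report: per-specimen pose differences for all three regions, overall
#' RMSD and Bland-Altman limit tables, the splint-error decomposition
#' (SE = MxRE - MdRE per specimen and component) with its own tables, the
#' per-axis screw-deformation RMSD table with deformation fractions, and a
#' limits-to-RMSD consistency self-check. Deterministic given inputs and
#' configuration.
#'
#' @param x landmark data.frame, a `specimen_set`, or a path passed to
#'   [read_landmarks()].
#' @param config a [study_config()].
#' @return Object of class `accuracy_report`: `per_specimen`,
#'   `overall_rmsd`, `overall_limits`, `splint_series`, `splint_rmsd`,
#'   `splint_limits`, `ipd_rmsd`, `consistency`, `n_heads`, `config`.
#' @export
run_analysis <- function(x, config = study_config()) {
  if (!inherits(config, "study_config")) stop("`config` must be a study_config")
  triads <- if (inherits(x, "specimen_set")) x$triads
            else if (is.character(x) && length(x) == 1L)
              landmarks_to_triads(read_landmarks(x))
            else landmarks_to_triads(x)
  heads <- names(triads)
  if (config$frame == "mandible")
    triads <- lapply(triads, to_mandible_frame)

  per_rows <- list()
  ipd_rows <- list()
  for (h in heads) {
    for (rg in REGIONS) {
      pd <- pose_difference(triads[[h]][[rg]]$planned,
                            triads[[h]][[rg]]$postop,
                            convention = config$convention)
      per_rows[[length(per_rows) + 1L]] <-
        cbind(data.frame(head_id = h, stringsAsFactors = FALSE),
              as.data.frame(pd))
      res <- ipd_deformation(triads[[h]][[rg]]$planned,
                             triads[[h]][[rg]]$postop)
      ipd_rows[[length(ipd_rows) + 1L]] <- data.frame(
        head_id = h, region = rg, screw_label = rownames(res),
        res_x_mm = res[, 1], res_y_mm = res[, 2], res_z_mm = res[, 3],
        stringsAsFactors = FALSE)
    }
  }
  per_specimen <- do.call(rbind, per_rows)
  rownames(per_specimen) <- NULL
  ipd_res <- do.call(rbind, ipd_rows)
  rownames(ipd_res) <- NULL

  # per-specimen signed component series, one row per head x region
  series <- per_specimen[c("head_id", "region", POSE_COMPONENTS)]
  overall <- series_tables(series, REGIONS, config)

  se_series <- splint_error(
    series[series$region == "maxilla",
           c("head_id", POSE_COMPONENTS), drop = FALSE],
    series[series$region == "mandible",
           c("head_id", POSE_COMPONENTS), drop = FALSE])
  se_long <- cbind(data.frame(region = "splint",
                              stringsAsFactors = FALSE), se_series)
  splint <- series_tables(se_long, "splint", config)

  res_cols <- c(res_x_mm = "mediolateral", res_y_mm = "anteroposterior",
                res_z_mm = "superoinferior")
  ipd_tab <- do.call(rbind, lapply(REGIONS, function(rg) {
    sub <- ipd_res[ipd_res$region == rg, ]
    do.call(rbind, lapply(names(res_cols), function(col) {
      comp <- res_cols[[col]]
      over <- overall$rmsd$rmsd[overall$rmsd$region == rg &
                                overall$rmsd$component == comp]
      ir <- rmsd(sub[[col]])
      data.frame(region = rg, component = comp, ipd_rmsd = ir,
                 overall_rmsd = over,
                 fraction_pct = if (over > 0) ipd_fraction(ir, over) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))

  consistency <- rbind(
    check_consistency(overall$limits, overall$rmsd, length(heads)),
    check_consistency(splint$limits, splint$rmsd, length(heads)))

  structure(list(per_specimen = per_specimen,
                 ipd_residuals = ipd_res,
                 overall_rmsd = overall$rmsd,
                 overall_limits = overall$limits,
                 splint_series = se_series,
                 splint_rmsd = splint$rmsd,
                 splint_limits = splint$limits,
                 ipd_rmsd = ipd_tab,
                 consistency = consistency,
                 n_heads = length(heads),
                 config = config),
            class = "accuracy_report")
}

#' Cross-check an RMSD table against a limits-of-agreement table
#'
#' For every cell shared by the two tables, recomputes the RMSD implied by
#' the limits through [stats_from_limits()] and reports the absolute
#' discrepancy. On tables produced from one raw series the discrepancy is
#' zero to rounding; on published table pairs it flags cells that cannot
#' have come from the same series.
#'
#' @param limits data.frame with `component`, `lower`, `upper` (and
#'   optionally `region`) columns.
#' @param rmsd_table data.frame with `component` and `rmsd` (and optionally
#'   `region`) columns.
#' @param n specimen count behind the tables.
#' @return data.frame with the join keys, `rmsd`, `implied_rmsd`,
#'   `discrepancy`.
#' @export
check_consistency <- function(limits, rmsd_table, n) {
  keys <- intersect(c("region", "component"),
                    intersect(names(limits), names(rmsd_table)))
  if (!"component" %in% keys)
    stop("both tables need a `component` column to be matched")
  if (!all(c("lower", "upper") %in% names(limits)))
    stop("`limits` needs `lower` and `upper` columns")
  if (!"rmsd" %in% names(rmsd_table))
    stop("`rmsd_table` needs an `rmsd` column")
  merged <- merge(rmsd_table[c(keys, "rmsd")], limits[c(keys, "lower", "upper")],
                  by = keys)
  if (nrow(merged) == 0L) stop("tables share no cells (shape mismatch)")
  merged$implied_rmsd <- vapply(seq_len(nrow(merged)), function(i)
    stats_from_limits(merged$lower[i], merged$upper[i], n)$implied_rmsd,
    numeric(1))
  merged$discrepancy <- abs(merged$implied_rmsd - merged$rmsd)
  merged[order(merged[[keys[1]]]), , drop = FALSE]
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}

render_table <- function(df, digits) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf(paste0("%.", digits, "f"),
                                                 round_half_up(v, digits)))
  lines <- utils::capture.output(print(df, row.names = FALSE))
  lines
}

#' Render an accuracy report as aligned plain text
#'
#' Numbers are rounded to the configured number of decimals (half away from
#' zero) in the rendering only; the report object and the CSVs written by
#' [write_report()] keep full precision.
#'
#' @param report an [run_analysis()] result.
#' @return Character vector of lines.
#' @export
render_report <- function(report) {
  d <- report$config$digits
  c(sprintf("Accuracy report (%d specimens, frame: %s, angles: %s)",
            report$n_heads, report$config$frame, report$config$convention),
    "",
    "Overall accuracy (RMSD):",
    render_table(report$overall_rmsd[c("region", "component", "kind",
                                       "rmsd", "within_cutoff")], d),
    "",
    "Overall accuracy (Bland-Altman limits, 95% CIs):",
    render_table(report$overall_limits[c("region", "component", "lower",
                                         "lower_ci_lo", "lower_ci_hi",
                                         "upper", "upper_ci_lo",
                                         "upper_ci_hi")], d),
    "",
    "Splint accuracy (RMSD):",
    render_table(report$splint_rmsd[c("component", "kind", "rmsd",
                                      "within_cutoff")], d),
    "",
    "Splint accuracy (Bland-Altman limits, 95% CIs):",
    render_table(report$splint_limits[c("component", "lower", "lower_ci_lo",
                                        "lower_ci_hi", "upper", "upper_ci_lo",
                                        "upper_ci_hi")], d),
    "",
    "Screw deformation (per-axis RMSD and share of overall error):",
    render_table(report$ipd_rmsd, d),
    "",
    "Limits-to-RMSD consistency self-check (max abs discrepancy):",
    sprintf("  %.3g", max(report$consistency$discrepancy)))
}

#' Write an accuracy report to a directory
#'
#' Full-precision CSVs for every table plus the rendered `report.txt`.
#'
#' @param report an [run_analysis()] result.
#' @param dir destination directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  if (!inherits(report, "accuracy_report"))
    stop("`report` must come from run_analysis()")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- c("per_specimen", "ipd_residuals", "overall_rmsd", "overall_limits",
            "splint_series", "splint_rmsd", "splint_limits", "ipd_rmsd",
            "consistency")
  paths <- character(0)
  for (tb in tabs) {
    p <- file.path(dir, paste0(tb, ".csv"))
    utils::write.csv(report[[tb]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  txt <- file.path(dir, "report.txt")
  writeLines(render_report(report), txt)
  invisible(c(paths, txt))
}
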