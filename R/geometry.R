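#' Anatomical regions and timepoints recognised by the pipeline
#'
#' The coordinate frame is right-handed with x = medio-lateral (positive
#' toward the specimen's left), y = antero-posterior (positive anterior),
#' z = supero-inferior (positive superior). All coordinates are millimetres.
#'
#' @name conventions
#' @keywords internal
REGIONS <- c("skull", "maxilla", "mandible")
TIMEPOINTS <- c("planned", "postop")

#' Construct a fiducial screw triad
#'
#' A triad is the atom of the geometry: the three labelled bone-screw
#' positions of one anatomical region at one timepoint. Screw labels are
#' stable identities across timepoints (they name physical screws), so a
#' planned and a post-operative triad of the same region correspond
#' point-by-point by label.
#'
#' @param points numeric 3x3 matrix, one screw per row, columns x/y/z in mm.
#' @param region one of `"skull"`, `"maxilla"`, `"mandible"`.
#' @param timepoint one of `"planned"`, `"postop"`.
#' @param labels screw labels for the rows; default `1:3`. Must be unique.
#' @param eps_area minimum triangle area (mm^2) below which the triad is
#'   rejected as collinear/degenerate. Screws sit centimetres apart, so a
#'   near-zero area signals a data-entry error, not a real configuration.
#' @return An object of class `fiducial_triad`.
#' @examples
#' fiducial_triad(rbind(c(0, 0, 0), c(30, 0, 0), c(0, 30, 0)),
#'                region = "skull", timepoint = "planned")
#' @export
fiducial_triad <- function(points, region, timepoint, labels = 1:3,
                           eps_area = 1) {
  points <- as.matrix(points)
  if (!is.numeric(points) || !identical(dim(points), c(3L, 3L)))
    stop("`points` must be a numeric 3x3 matrix (3 screws x 3 coordinates)")
  if (!all(is.finite(points)))
    stop("fiducial coordinates must all be finite (region ", region,
         ", timepoint ", timepoint, ")")
  region <- match.arg(region, REGIONS)
  timepoint <- match.arg(timepoint, TIMEPOINTS)
  labels <- as.character(labels)
  if (length(labels) != 3L || anyDuplicated(labels))
    stop("screw labels must be 3 unique values")
  area <- triangle_area(points)
  if (area <= eps_area)
    stop("degenerate fiducial triad (region ", region, ", timepoint ",
         timepoint, "): triangle area ", format(area),
         " mm^2 <= ", eps_area, " mm^2; screws are collinear or coincident")
  dimnames(points) <- list(labels, c("x", "y", "z"))
  structure(list(points = points, region = region, timepoint = timepoint),
            class = "fiducial_triad")
}

#' @export
print.fiducial_triad <- function(x, ...) {
  cat("<fiducial_triad> region:", x$region, " timepoint:", x$timepoint, "\n")
  print(round(x$points, 3))
  invisible(x)
}

#' Area of the triangle spanned by three points (mm^2)
#' @param points numeric 3x3 matrix, points in rows.
#' @keywords internal
triangle_area <- function(points) {
  a <- points[2, ] - points[1, ]
  b <- points[3, ] - points[1, ]
  cr <- c(a[2] * b[3] - a[3] * b[2],
          a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  0.5 * sqrt(sum(cr^2))
}

stopifnot_triad <- function(x, arg = deparse(substitute(x))) {
  if (!inherits(x, "fiducial_triad"))
    stop("`", arg, "` must be a fiducial_triad (see fiducial_triad())")
  invisible(x)
}

#' Barycenter of a fiducial triad
#'
#' The component-wise arithmetic mean of the three screw positions; the
#' region's rigid-body reference landmark.
#'
#' @param triad a [fiducial_triad()].
#' @return Named numeric vector `c(x, y, z)` in mm, with the triad's region
#'   and timepoint attached as attributes.
#' @examples
#' tr <- fiducial_triad(rbind(c(0, 0, 0), c(30, 0, 0), c(0, 30, 0)),
#'                      "maxilla", "planned")
#' barycenter(tr)  # (10, 10, 0)
#' @export
barycenter <- function(triad) {
  stopifnot_triad(triad)
  b <- colMeans(triad$points)
  attr(b, "region") <- triad$region
  attr(b, "timepoint") <- triad$timepoint
  b
}

#' Barycenter-to-screw vector triad
#'
#' The three vectors from the barycenter to each screw. These mean-centred
#' vectors describe the orientation of the region independently of its
#' position; by construction they sum to the zero vector.
#'
#' @param triad a [fiducial_triad()].
#' @return A 3x3 matrix of class `vector_triad`, one vector per row, carrying
#'   the screw labels as rownames and the region/timepoint as attributes.
#' @export
vector_triad <- function(triad) {
  stopifnot_triad(triad)
  v <- sweep(triad$points, 2, colMeans(triad$points))
  structure(v, region = triad$region, timepoint = triad$timepoint,
            class = c("vector_triad", class(v)))
}

#' Pairwise inter-screw distances of a triad
#'
#' Euclidean distances for the screw pairs (1,2), (1,3), (2,3), in that
#' fixed order. Invariant under any rigid transform, so changes between
#' timepoints indicate non-rigid effects (screw bending).
#'
#' @param triad a [fiducial_triad()].
#' @return Named numeric vector of three distances (mm).
#' @examples
#' # 3-4-5 triangle scaled by 10 to pass the collinearity check
#' tr <- fiducial_triad(rbind(c(0, 0, 0), c(30, 0, 0), c(0, 40, 0)),
#'                      "skull", "planned")
#' inter_point_distances(tr)  # 30, 40, 50
#' @export
inter_point_distances <- function(triad) {
  stopifnot_triad(triad)
  p <- triad$points
  lab <- rownames(p)
  d <- c(sqrt(sum((p[1, ] - p[2, ])^2)),
         sqrt(sum((p[1, ] - p[3, ])^2)),
         sqrt(sum((p[2, ] - p[3, ])^2)))
  names(d) <- c(paste(lab[1], lab[2], sep = "-"),
                paste(lab[1], lab[3], sep = "-"),
                paste(lab[2], lab[3], sep = "-"))
  d
}

check_matched_triads <- function(plan, post) {
  stopifnot_triad(plan, "plan")
  stopifnot_triad(post, "post")
  if (plan$region != post$region)
    stop("region mismatch: planned triad is '", plan$region,
         "', post-operative triad is '", post$region, "'")
  if (plan$timepoint != "planned" || post$timepoint != "postop")
    stop("expected a planned and a postop triad (got '", plan$timepoint,
         "' and '", post$timepoint, "')")
  if (!identical(rownames(plan$points), rownames(post$points)))
    stop("screw labels differ between timepoints for region '", plan$region,
         "'; labels identify physical screws and must match")
  invisible(TRUE)
}
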