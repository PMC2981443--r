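#' Derived wing metrics for a planform
#'
#' Weight `W = M g`, aspect ratio `AR = b^2 / S` and wing loading `W / S`.
#' High aspect ratio marks long, glide-efficient wings; high wing loading
#' implies fast flight.
#'
#' @param pf A [planform()].
#' @return A list of class `wing_metrics` with `weight` (N),
#'   `aspect_ratio` and `wing_loading` (N/m^2).
#' @export
wing_metrics <- function(pf) {
  stopifnot(inherits(pf, "planform"))
  structure(list(weight = pf$weight,
                 aspect_ratio = pf$aspect_ratio,
                 wing_loading = pf$wing_loading),
            class = "wing_metrics")
}

#' Size-normalised ecomorphospace projection of wing morphometrics
#'
#' Principal component analysis of log10-transformed (mass, span, area),
#' centred, on the covariance matrix. The first component is a general
#' size axis (all loadings of one sign); components 2 and 3 are the shape
#' axes used for ecomorphospace plots. Working in log space makes the
#' scores invariant to uniform unit rescaling (a pure translation) and
#' turns allometric power laws into linear structure.
#'
#' @param records A data frame with positive columns `mass`, `span`,
#'   `area` and optionally `label` and `group`.
#' @return An object of class `ecomorph_pca`: `scores` (one row per
#'   record; columns `PC1`..`PC3`), `loadings`, `sdev`, plus the input
#'   labels/groups.
#' @export
ecomorph_pca <- function(records) {
  req <- c("mass", "span", "area")
  if (!all(req %in% names(records)))
    stop("records must have columns mass, span, area")
  if (nrow(records) < 3) stop("at least 3 records are required")
  X <- as.matrix(records[, req])
  if (any(!is.finite(X)) || any(X <= 0))
    stop("mass, span and area must be positive and finite")
  p <- stats::prcomp(log10(X), center = TRUE, scale. = FALSE)
  # orient PC1 as a size axis pointing towards larger animals
  if (sum(p$rotation[, 1]) < 0) {
    p$rotation[, 1] <- -p$rotation[, 1]
    p$x[, 1] <- -p$x[, 1]
  }
  structure(list(
    scores = p$x,
    loadings = p$rotation,
    sdev = p$sdev,
    label = if ("label" %in% names(records)) records$label else NULL,
    group = if ("group" %in% names(records)) records$group else NULL),
    class = "ecomorph_pca")
}

#' Point-in-convex-polygon membership test
#'
#' Tests whether a 2-D score lies inside (or on the boundary of) a convex
#' region of ecomorphospace. The point is inside iff it falls on the same
#' side of — or exactly on — every directed edge of the hull.
#'
#' @param point Numeric length-2 vector of scores.
#' @param hull Two-column matrix of hull vertices in order (either
#'   winding); at least 3 non-collinear vertices.
#' @param tol Numerical tolerance on the edge test.
#' @return `TRUE` if inside or on the boundary.
#' @export
region_membership <- function(point, hull, tol = 1e-9) {
  hull <- as.matrix(hull)
  if (nrow(hull) < 3 || ncol(hull) != 2) stop("hull needs >= 3 x,y vertices")
  n <- nrow(hull)
  cross <- vapply(seq_len(n), function(i) {
    p1 <- hull[i, ]; p2 <- hull[if (i == n) 1 else i + 1, ]
    (p2[1] - p1[1]) * (point[2] - p1[2]) - (p2[2] - p1[2]) * (point[1] - p1[1])
  }, numeric(1))
  scale <- max(abs(hull)) + 1
  if (all(abs(cross) < tol * scale^2)) stop("degenerate (collinear) hull")
  all(cross >= -tol * scale^2) || all(cross <= tol * scale^2)
}
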