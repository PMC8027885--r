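#' Weighted geometric median of geographic points (Weiszfeld's algorithm)
#'
#' Points are projected onto a local planar frame (equirectangular
#' projection about the weighted centroid) and the Weiszfeld fixed-point
#' iteration is run until the update moves less than `tol` degrees or
#' `max_iter` is reached. If an iterate coincides with a data point the
#' standard perturbation rule (offset by a tiny step before continuing) is
#' applied.
#'
#' @param points Matrix or data frame with columns `lat`, `lon` (decimal
#'   degrees).
#' @param weights Non-negative weights, not all zero (default equal).
#' @param tol Convergence tolerance in degrees (default 1e-9).
#' @param max_iter Iteration cap (default 1000).
#' @return Named numeric `c(lat = , lon = )`.
#' @export
geometric_median <- function(points, weights = NULL, tol = 1e-9,
                             max_iter = 1000L) {
  pts <- as.matrix(as.data.frame(points)[, c("lat", "lon")])
  n <- nrow(pts)
  if (n < 1L) stop("need at least one point")
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0) || sum(weights) == 0)
    stop("weights must be non-negative and not all zero")
  if (any(abs(pts[, "lat"]) > 90) || any(abs(pts[, "lon"]) > 180))
    stop("coordinates outside valid lat/lon ranges")
  w <- weights / sum(weights)
  lat0 <- sum(w * pts[, "lat"])
  scale_x <- cos(lat0 * pi / 180)
  xy <- cbind(x = pts[, "lon"] * scale_x, y = pts[, "lat"])
  cur <- colSums(xy * w)
  for (it in seq_len(max_iter)) {
    d <- sqrt((xy[, 1] - cur[1])^2 + (xy[, 2] - cur[2])^2)
    hit <- which(d < 1e-12)
    if (length(hit)) {
      # Weiszfeld perturbation: nudge off the coincident data point
      cur <- cur + c(1e-9, 1e-9)
      d <- sqrt((xy[, 1] - cur[1])^2 + (xy[, 2] - cur[2])^2)
    }
    wd <- w / d
    nxt <- colSums(xy * wd) / sum(wd)
    move <- sqrt(sum((nxt - cur)^2))
    cur <- nxt
    if (move < tol) break
  }
  c(lat = unname(cur[2]), lon = unname(cur[1] / scale_x))
}

#' Great-circle distance between two points, in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km.
#'
#' @param p1,p2 Named numeric `c(lat = , lon = )` in decimal degrees.
#' @return Distance in kilometres.
#' @export
great_circle_distance <- function(p1, p2) {
  for (p in list(p1, p2))
    if (abs(p[["lat"]]) > 90 || abs(p[["lon"]]) > 180)
      stop("coordinates outside valid lat/lon ranges")
  geosphere::distHaversine(c(p1[["lon"]], p1[["lat"]]),
                           c(p2[["lon"]], p2[["lat"]]), r = 6371)
}

#' Pairwise great-circle distance matrix
#' @param points Data frame with `lat`, `lon` and optional rownames.
#' @return Symmetric matrix of kilometre distances.
#' @export
geo_distance_matrix <- function(points) {
  pts <- as.data.frame(points)
  n <- nrow(pts)
  D <- matrix(0, n, n, dimnames = list(rownames(pts), rownames(pts)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    D[i, j] <- D[j, i] <- great_circle_distance(
      c(lat = pts$lat[i], lon = pts$lon[i]),
      c(lat = pts$lat[j], lon = pts$lon[j]))
  D
}
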