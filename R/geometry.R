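## Beam's-eye-view frames, point-in-polygon, convex outline dilation.
##
## Patient axes throughout: x = right-left (RL), y = inferior-superior (IS),
## z = posterior-anterior (PA), millimetres. The gantry rotates in the axial
## (x-z) plane about the isocenter; the beam is modelled as parallel rays.

# Orthonormal beam frame for a gantry angle (degrees).
# u: beam travel direction; e1: crossplane (x in the log-file sense);
# e2: inplane (y), fixed along the patient IS axis.
beam_frame <- function(gantry_angle_deg) {
  th <- gantry_angle_deg * pi / 180
  list(u  = c(sin(th), 0, cos(th)),
       e1 = c(cos(th), 0, -sin(th)),
       e2 = c(0, 1, 0))
}

#' Test points against a simple polygon (boundary-inclusive)
#'
#' Ray-casting point-in-polygon with an explicit on-edge test: a point
#' lying exactly on a vertex or edge counts as inside. This tie-break
#' matters for aperture filtering, where a spot centred on the aperture
#' edge is kept.
#'
#' @param xy Numeric matrix (n x 2) of points.
#' @param poly Numeric matrix (m x 2) of polygon vertices in order
#'   (open or closed ring), m >= 3, non-self-intersecting.
#' @param tol Distance (same units as coordinates) within which a point is
#'   considered on the boundary.
#' @return Logical vector of length n.
#' @export
point_in_polygon <- function(xy, poly, tol = 1e-9) {
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  poly <- as.matrix(poly)
  if (nrow(poly) < 3) abort("degenerate polygon: fewer than 3 vertices")
  # drop a duplicated closing vertex
  if (all(abs(poly[1, ] - poly[nrow(poly), ]) < tol) && nrow(poly) > 3) {
    poly <- poly[-nrow(poly), , drop = FALSE]
  }
  if (polygon_area(poly) < tol^2) abort("degenerate polygon: zero area")
  px <- poly[, 1]; py <- poly[, 2]
  qx <- c(px[-1], px[1]); qy <- c(py[-1], py[1])
  n <- nrow(xy)
  inside <- logical(n)
  for (i in seq_len(n)) {
    x <- xy[i, 1]; y <- xy[i, 2]
    # boundary test: distance to each edge segment
    dx <- qx - px; dy <- qy - py
    len2 <- dx^2 + dy^2
    t <- pmin(1, pmax(0, ((x - px) * dx + (y - py) * dy) / pmax(len2, tol^2)))
    d2 <- (px + t * dx - x)^2 + (py + t * dy - y)^2
    if (any(d2 <= tol^2)) {
      inside[i] <- TRUE
      next
    }
    # ray cast towards +x
    crosses <- ((py > y) != (qy > y)) &
      (x < px + (y - py) * (qx - px) / (qy - py))
    inside[i] <- (sum(crosses) %% 2) == 1
  }
  inside
}

polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

# Convex outline of a 2-D point cloud, dilated outward by a uniform margin.
# Vertices are offset along the bisector of adjacent edge normals (mitre
# join); exact uniform offset for a convex polygon up to the mitre
# approximation at vertices.
convex_outline <- function(xy, margin_mm = 0) {
  xy <- unique(as.matrix(xy))
  if (nrow(xy) < 3) {
    # degenerate cloud: fall back to a small box around the points
    cx <- mean(xy[, 1]); cy <- mean(xy[, 2])
    r <- max(1e-3, max(abs(xy[, 1] - cx)), max(abs(xy[, 2] - cy)))
    xy <- cbind(cx + c(-r, r, r, -r), cy + c(-r, -r, r, r))
  }
  h <- chull(xy)
  poly <- xy[h, , drop = FALSE]          # chull returns clockwise order
  poly <- poly[rev(seq_len(nrow(poly))), , drop = FALSE]  # counter-clockwise
  if (margin_mm == 0) return(poly)
  m <- nrow(poly)
  prv <- poly[c(m, seq_len(m - 1)), , drop = FALSE]
  nxt <- poly[c(seq_len(m - 1) + 1, 1), , drop = FALSE]
  out <- poly
  for (i in seq_len(m)) {
    e1 <- poly[i, ] - prv[i, ]; e2 <- nxt[i, ] - poly[i, ]
    n1 <- c(e1[2], -e1[1]) / sqrt(sum(e1^2))   # outward for CCW ring
    n2 <- c(e2[2], -e2[1]) / sqrt(sum(e2^2))
    b <- n1 + n2
    b <- b / sqrt(sum(b^2))
    cosh2 <- sum(b * n1)                       # cos(half exterior angle)
    out[i, ] <- poly[i, ] + margin_mm * b / max(cosh2, 0.1)
  }
  out
}

# Entry parameter t0 of the parallel ray {origin + t*u} into an axis-aligned
# box [lo, hi]; NA when the ray misses the box.
ray_box_entry <- function(origin, u, lo, hi) {
  t_lo <- rep(-Inf, 3); t_hi <- rep(Inf, 3)
  for (a in 1:3) {
    if (abs(u[a]) < 1e-12) {
      if (origin[a] < lo[a] || origin[a] > hi[a]) return(NA_real_)
    } else {
      t1 <- (lo[a] - origin[a]) / u[a]
      t2 <- (hi[a] - origin[a]) / u[a]
      t_lo[a] <- min(t1, t2); t_hi[a] <- max(t1, t2)
    }
  }
  tmin <- max(t_lo); tmax <- min(t_hi)
  if (tmin > tmax) return(NA_real_)
  tmin
}
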