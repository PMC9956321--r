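#' Exact Tukey halfspace depth of a point in a 2-D cloud
#'
#' The depth of `query` is the minimum, over all closed halfplanes containing
#' `query`, of the number of cloud points in that halfplane. Computed exactly
#' by an angular sweep: the minimising halfplane boundary can be rotated to
#' pass infinitesimally past the direction of some data point, so it suffices
#' to count, for every direction to a data point, the points in the half-open
#' angular arc behind it. Duplicate points count with multiplicity.
#'
#' @param query Numeric length-2 vector.
#' @param cloud Two-column numeric matrix or data frame of points.
#'
#' @return Integer depth in `0:nrow(cloud)`.
#' @export
#' @examples
#' halfspace_depth(c(0, 0), rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)))  # 2
halfspace_depth <- function(query, cloud) {
  cloud <- as_cloud(cloud)
  query <- as.numeric(query)
  if (length(query) != 2 || any(!is.finite(query))) {
    ob_abort("query must be a finite 2-D point", "input")
  }
  d <- cbind(cloud[, 1] - query[1], cloud[, 2] - query[2])
  coincident <- d[, 1] == 0 & d[, 2] == 0
  m <- sum(coincident)
  dd <- d[!coincident, , drop = FALSE]
  if (nrow(dd) == 0L) return(m)
  # cr[j, k] = cross(d_j, d_k); arc (theta_j, theta_j + pi] counts
  # cross > 0 (strict interior) plus antipodal points (cross == 0, dot < 0)
  cr <- outer(dd[, 1], dd[, 2]) - outer(dd[, 2], dd[, 1])
  dt <- tcrossprod(dd)
  cnt <- rowSums(cr > 0 | (cr == 0 & dt < 0))
  as.integer(m + min(cnt))
}

as_cloud <- function(cloud) {
  cloud <- as.matrix(cloud)
  if (ncol(cloud) < 2) ob_abort("cloud must have two coordinate columns", "input")
  cloud <- cloud[, 1:2, drop = FALSE]
  storage.mode(cloud) <- "double"
  if (nrow(cloud) < 1) ob_abort("cloud must be nonempty", "input")
  if (any(!is.finite(cloud))) ob_abort("cloud coordinates must be finite", "input")
  cloud
}

# depth of every cloud point
cloud_depths <- function(cloud) {
  vapply(seq_len(nrow(cloud)),
         function(i) halfspace_depth(cloud[i, ], cloud),
         integer(1))
}

# candidate points for approximating plane-wide depth: the cloud itself plus
# pairwise midpoints (midpoints of boundary points probe the interior, where
# the Tukey median of the plane lives). Pair count is capped for large n.
bag_candidates <- function(cloud, max_pairs = 20000) {
  n <- nrow(cloud)
  src <- seq_len(n)
  if (choose(n, 2) > max_pairs) {
    m <- floor((1 + sqrt(1 + 8 * max_pairs)) / 2)
    src <- unique(round(seq(1, n, length.out = m)))
  }
  pr <- utils::combn(src, 2)
  mids <- (cloud[pr[1, ], , drop = FALSE] + cloud[pr[2, ], , drop = FALSE]) / 2
  rbind(cloud, mids)
}

#' Depth median of a 2-D point cloud
#'
#' Approximates the Tukey median: the centroid of the candidate points
#' attaining maximal halfspace depth. By default the candidates are the
#' cloud points together with all pairwise midpoints, which probes the
#' interior of the cloud and behaves like the depth median of the plane;
#' `of = "cloud"` restricts the maximisation to the data points themselves.
#'
#' @inheritParams halfspace_depth
#' @param of `"plane"` (cloud plus midpoints) or `"cloud"` (data points
#'   only).
#' @return Numeric length-2 vector whose depth is at least the depth of
#'   every data point.
#' @export
depth_median <- function(cloud, of = c("plane", "cloud")) {
  cloud <- as_cloud(cloud)
  of <- match.arg(of)
  cand <- if (of == "plane" && nrow(cloud) > 1) bag_candidates(cloud) else cloud
  dep <- vapply(seq_len(nrow(cand)),
                function(i) halfspace_depth(cand[i, ], cloud), integer(1))
  deepest <- cand[dep == max(dep), , drop = FALSE]
  colMeans(deepest)
}

#' The bag of a bagplot
#'
#' The bag is the central region of a bagplot, covering (about) the deepest
#' half of the points. It is built from halfspace-depth contours of the
#' plane, approximated on the cloud points plus their pairwise midpoints:
#' the convex hulls of the candidates at successive depth levels are
#' computed, the deepest level whose hull still holds at least
#' ceiling(n/2) data points is located, and the bag interpolates radially
#' (about the depth median) between that hull and the next deeper one so
#' that the bag contains at least ceiling(n/2) of the data points.
#'
#' @inheritParams halfspace_depth
#' @param method `"contour"` (depth-contour interpolation, the default used
#'   for outlier detection) or `"deepest_hull"` (plain convex hull of the
#'   ceiling(n/2) deepest data points, ties broken by depth then by
#'   distance to the depth median; a simpler variant whose vertices are
#'   always data points, but which distorts the bag when most points lie on
#'   their own convex hull).
#' @return A polygon: matrix of vertices in counter-clockwise order, with
#'   attributes `depths` (per cloud point) and `median` (depth median).
#' @export
compute_bag <- function(cloud, method = c("contour", "deepest_hull")) {
  cloud <- as_cloud(cloud)
  method <- match.arg(method)
  n <- nrow(cloud)
  if (n < 3 || is_collinear(cloud)) {
    ob_abort("degenerate cloud: fewer than 3 points or all collinear",
             "degenerate_geometry")
  }
  dep <- cloud_depths(cloud)
  n_half <- ceiling(n / 2)

  if (method == "deepest_hull") {
    med <- depth_median(cloud, of = "cloud")
    dist2 <- (cloud[, 1] - med[1])^2 + (cloud[, 2] - med[2])^2
    ord <- order(-dep, dist2)
    sel <- cloud[ord[seq_len(n_half)], , drop = FALSE]
    if (is_collinear(sel)) {
      ob_abort("degenerate bag: deepest points are collinear",
               "degenerate_geometry")
    }
    hull <- unname(sel[rev(grDevices::chull(sel)), , drop = FALSE])
    attr(hull, "depths") <- dep
    attr(hull, "median") <- med
    return(hull)
  }

  cand <- bag_candidates(cloud)
  cdep <- vapply(seq_len(nrow(cand)),
                 function(i) halfspace_depth(cand[i, ], cloud), integer(1))
  med <- colMeans(cand[cdep == max(cdep), , drop = FALSE])

  # convex hull and contained-data count per depth level
  level_hull <- function(d) {
    pts <- cand[cdep >= d, , drop = FALSE]
    if (nrow(pts) < 3 || is_collinear(pts)) {
      return(list(poly = NULL, count = sum(point_in_set(cloud, pts))))
    }
    poly <- unname(pts[rev(grDevices::chull(pts)), , drop = FALSE])
    list(poly = poly, count = sum(in_convex_polygon(cloud, poly)))
  }
  d_star <- 1L
  outer_lvl <- level_hull(1L)  # hull of everything: contains all data
  if (max(cdep) >= 2L) {
    for (d in 2L:max(cdep)) {
      lv <- level_hull(d)
      if (lv$count >= n_half && !is.null(lv$poly)) {
        d_star <- d
        outer_lvl <- lv
      } else {
        break
      }
    }
  }
  inner_lvl <- if (d_star < max(cdep)) level_hull(d_star + 1L) else NULL

  if (is.null(inner_lvl) || outer_lvl$count == n_half) {
    bag <- outer_lvl$poly
  } else {
    cin <- inner_lvl$count
    cout <- outer_lvl$count
    lambda <- if (cout > cin) (n_half - cin) / (cout - cin) else 1
    repeat {
      bag <- interpolate_hulls(inner_lvl$poly, outer_lvl$poly, med, lambda)
      if (lambda >= 1 || sum(in_convex_polygon(cloud, bag)) >= n_half) break
      lambda <- min(1, lambda + 0.05)
    }
  }
  attr(bag, "depths") <- dep
  attr(bag, "median") <- med
  bag
}

# membership of query points in a small point set (coincidence test)
point_in_set <- function(pts, set) {
  vapply(seq_len(nrow(pts)), function(i) {
    any(set[, 1] == pts[i, 1] & set[, 2] == pts[i, 2])
  }, logical(1))
}

# distance from center to the boundary of a convex polygon along each angle;
# center must lie inside (or on) the polygon
radial_function <- function(poly, center, angles) {
  if (is.null(poly)) return(rep(0, length(angles)))
  nv <- nrow(poly)
  vapply(angles, function(th) {
    u <- c(cos(th), sin(th))
    best <- 0
    for (i in seq_len(nv)) {
      a <- poly[i, ] - center
      b <- poly[if (i == nv) 1L else i + 1L, ] - center
      e <- b - a
      den <- u[1] * e[2] - u[2] * e[1]
      if (abs(den) < 1e-14) next
      t <- (a[1] * e[2] - a[2] * e[1]) / den
      s <- (a[1] * u[2] - a[2] * u[1]) / -den
      if (t > best && s >= -1e-9 && s <= 1 + 1e-9) best <- t
    }
    best
  }, numeric(1))
}

# radial interpolation between two nested convex polygons about `center`
interpolate_hulls <- function(inner, outer, center, lambda) {
  va <- if (is.null(inner)) numeric(0) else {
    atan2(inner[, 2] - center[2], inner[, 1] - center[1])
  }
  vb <- atan2(outer[, 2] - center[2], outer[, 1] - center[1])
  angles <- sort(unique(c(va, vb, seq(-pi, pi, length.out = 33)[-33])))
  r_in <- radial_function(inner, center, angles)
  r_out <- radial_function(outer, center, angles)
  r <- (1 - lambda) * r_in + lambda * r_out
  pts <- cbind(center[1] + r * cos(angles), center[2] + r * sin(angles))
  pts <- pts[!duplicated(round(pts, 12)), , drop = FALSE]
  unname(pts[rev(grDevices::chull(pts)), , drop = FALSE])
}

is_collinear <- function(pts, tol = 1e-12) {
  if (nrow(pts) < 3) return(TRUE)
  a <- pts[1, ]
  rel <- sweep(pts, 2, a)
  cr <- rel[, 1] * rel[2, 2] - rel[, 2] * rel[2, 1]
  # if the first two points coincide, try another reference edge
  if (all(rel[2, ] == 0)) {
    i <- which(rowSums(rel^2) > 0)[1]
    if (is.na(i)) return(TRUE)
    cr <- rel[, 1] * rel[i, 2] - rel[, 2] * rel[i, 1]
  }
  scale <- max(abs(rel))
  all(abs(cr) <= tol * max(scale^2, 1))
}

# point-in-convex-polygon (ccw vertices); boundary counts as inside
in_convex_polygon <- function(pts, poly, tol = 1e-9) {
  n <- nrow(poly)
  scale <- max(abs(poly), 1)
  inside <- rep(TRUE, nrow(pts))
  for (i in seq_len(n)) {
    a <- poly[i, ]
    b <- poly[if (i == n) 1L else i + 1L, ]
    cr <- (b[1] - a[1]) * (pts[, 2] - a[2]) - (b[2] - a[2]) * (pts[, 1] - a[1])
    inside <- inside & (cr >= -tol * scale^2)
  }
  inside
}

#' Bagplot outlier detection in two dimensions
#'
#' Computes the bag (the depth-contour region covering the deepest half of
#' the points, see [compute_bag()]), inflates
#' it about the depth median by `factor` to obtain the fence, and flags the
#' points lying strictly outside the fence as outliers. Degenerate clouds
#' (fewer than three points, or all points collinear) yield no flags, with a
#' warning.
#'
#' @inheritParams halfspace_depth
#' @param factor Positive inflation factor for the fence; the conventional
#'   value 2 controls how far a point must sit beyond the bag to be flagged.
#'
#' @return An object of class `bagplot_result`: list with `points` (tibble:
#'   `id`, `x`, `y`, `depth`, `outlier`), `median`, `bag`, `fence`, `factor`.
#' @export
#' @examples
#' th <- seq(0, 2 * pi, length.out = 21)[-21]
#' cloud <- rbind(cbind(cos(th), sin(th)), c(100, 100))
#' which(detect_outliers_bagplot(cloud)$points$outlier)  # 21
detect_outliers_bagplot <- function(cloud, factor = 2) {
  cloud_m <- as_cloud(cloud)
  if (!is.numeric(factor) || length(factor) != 1 || is.na(factor) || factor <= 0) {
    ob_abort("factor must be a positive number", "input")
  }
  ids <- rownames(cloud_m)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(cloud_m)))

  degenerate <- tryCatch({
    bag <- compute_bag(cloud_m)
    FALSE
  }, outlierboot_error_degenerate_geometry = function(e) TRUE)

  if (degenerate) {
    warn("degenerate point cloud: no bagplot outliers flagged")
    pts <- tibble(id = ids, x = cloud_m[, 1], y = cloud_m[, 2],
                  depth = NA_integer_, outlier = FALSE)
    return(structure(list(points = pts, median = NULL, bag = NULL,
                          fence = NULL, factor = factor),
                     class = "bagplot_result"))
  }

  med <- attr(bag, "median")
  dep <- attr(bag, "depths")
  if (is.finite(factor)) {
    fence <- sweep(sweep(bag, 2, med) * factor, 2, med, "+")
    flags <- !in_convex_polygon(cloud_m, fence)
  } else {
    fence <- NULL
    flags <- rep(FALSE, nrow(cloud_m))
  }
  pts <- tibble(id = ids, x = cloud_m[, 1], y = cloud_m[, 2],
                depth = as.integer(dep), outlier = flags)
  structure(list(points = pts, median = med,
                 bag = unname(bag[, 1:2, drop = FALSE]),
                 fence = fence, factor = factor),
            class = "bagplot_result")
}

#' @export
print.bagplot_result <- function(x, ...) {
  cat(sprintf("<bagplot_result> %d points, %d flagged (factor %.3g)\n",
              nrow(x$points), sum(x$points$outlier), x$factor))
  invisible(x)
}

#' @rdname tidy-outlierboot
#' @method tidy bagplot_result
#' @export
tidy.bagplot_result <- function(x, ...) x$points
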