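# Kernel utilisation distributions, 95% home-range contours and habitat
# composition. Densities are bivariate Gaussian kernels on a regular grid;
# contours come from marching squares (grDevices::contourLines) at the
# probability-capturing density threshold.

#' Reference (normal-scale) kernel bandwidth
#'
#' h_ref = sigma_hat * n^(-1/6) with
#' sigma_hat = sqrt(0.5 * (var(x) + var(y))): the bivariate-normal reference
#' smoothing parameter built from the coordinate standard deviations and the
#' number of relocations.
#'
#' @param x,y Relocation coordinates (metres); `y` may be omitted when `x`
#'   is a two-column matrix.
#' @return Bandwidth in metres.
#' @export
href_bandwidth <- function(x, y = NULL) {
  if (is.null(y)) {
    y <- x[, 2]
    x <- x[, 1]
  }
  n <- length(x)
  stopifnot(n >= 10)
  sig <- sqrt(0.5 * (stats::var(x) + stats::var(y)))
  if (sig == 0) stop("all points identical; bandwidth undefined")
  sig * n^(-1 / 6)
}

#' Kernel utilisation distribution on a grid
#'
#' Bivariate Gaussian kernel density of the relocations, evaluated on a
#' regular grid covering the points with a margin, and normalised so that
#' sum(density) * cell_area = 1.
#'
#' @param x,y Relocation coordinates (m); `x` may be a two-column matrix.
#' @param h Bandwidth in metres (> 0); default [href_bandwidth()].
#' @param grid_n Minimum grid cells per axis.
#' @param margin Grid margin beyond the point bounding box, metres
#'   (default 4 h, comfortably past the kernel's practical support).
#' @param cell_max Maximum cell size (default h / 2); the grid is refined
#'   to respect it.
#' @return Object of class `kud`: `gx`, `gy` (cell-centre coordinates),
#'   `z` (density matrix, per m^2, `z[i, j]` at `gx[i], gy[j]`), `h`,
#'   `cell_area`.
#' @export
kernel_ud <- function(x, y = NULL, h = NULL, grid_n = 200, margin = NULL,
                      cell_max = NULL) {
  if (is.null(y)) {
    y <- x[, 2]
    x <- x[, 1]
  }
  if (is.null(h)) h <- href_bandwidth(x, y)
  stopifnot(h > 0)
  if (is.null(margin)) margin <- 4 * h
  if (margin < 3 * h) warning("grid margin < 3 h; density mass may be truncated")
  if (is.null(cell_max)) cell_max <- h / 2
  rx <- range(x) + c(-margin, margin)
  ry <- range(y) + c(-margin, margin)
  nx <- max(grid_n, ceiling(diff(rx) / cell_max))
  ny <- max(grid_n, ceiling(diff(ry) / cell_max))
  gx <- seq(rx[1], rx[2], length.out = nx)
  gy <- seq(ry[1], ry[2], length.out = ny)
  dx <- gx[2] - gx[1]
  dy <- gy[2] - gy[1]
  if (dx > h || dy > h) warning("grid cells coarser than the bandwidth")
  n <- length(x)
  # separable kernel: z = Kx %*% t(Ky) / (2 pi h^2 n)
  Kx <- exp(-outer(gx, x, "-")^2 / (2 * h^2))
  Ky <- exp(-outer(gy, y, "-")^2 / (2 * h^2))
  z <- (Kx %*% t(Ky)) / (2 * pi * h^2 * n)
  cell_area <- dx * dy
  z <- z / (sum(z) * cell_area)  # exact discrete normalisation
  structure(list(gx = gx, gy = gy, z = z, h = h, cell_area = cell_area,
                 n_points = n),
            class = "kud")
}

#' @export
print.kud <- function(x, ...) {
  cat(sprintf("Kernel UD: %d x %d grid, h = %.1f m, cell %.1f m, n = %d\n",
              length(x$gx), length(x$gy), x$h, sqrt(x$cell_area), x$n_points))
  invisible(x)
}

# Density threshold whose superlevel set captures >= level probability.
.ud_threshold <- function(ud, level) {
  p <- sort(as.numeric(ud$z), decreasing = TRUE) * ud$cell_area
  k <- which(cumsum(p) >= level)[1]
  sort(as.numeric(ud$z), decreasing = TRUE)[k]
}

# Signed ring areas with even-odd hole handling: rings nested at odd depth
# subtract.
.rings_area <- function(rings) {
  if (!length(rings)) return(0)
  depth <- vapply(seq_along(rings), function(i) {
    p <- rings[[i]][1, ]
    sum(vapply(seq_along(rings), function(j) {
      j != i && point_in_polygon(p[1], p[2], rings[[j]], boundary_in = FALSE)
    }, TRUE))
  }, 0)
  sum(ifelse(depth %% 2 == 0, 1, -1) *
        vapply(rings, polygon_area, 0))
}

#' Extract a kernel home range contour
#'
#' Finds the smallest density threshold whose superlevel cells capture at
#' least `level` probability, polygonises the corresponding iso-density
#' contour by marching squares, and reports the enclosed area.
#'
#' @param ud A `kud` from [kernel_ud()].
#' @param level Probability level in (0, 1); default 0.95.
#' @param animal_id Optional label carried on the result.
#' @return Object of class `home_range`: `level`, `threshold`, `polygons`
#'   (list of ring matrices), `area_ha`, `area_km2`, `animal_id`.
#' @export
contour_home_range <- function(ud, level = 0.95, animal_id = NA_character_) {
  stopifnot(inherits(ud, "kud"), level > 0, level < 1)
  thr <- .ud_threshold(ud, level)
  cl <- grDevices::contourLines(ud$gx, ud$gy, ud$z, levels = thr)
  rings <- lapply(cl, function(c_) cbind(c_$x, c_$y))
  area_m2 <- .rings_area(rings)
  structure(list(level = level, threshold = thr, polygons = rings,
                 area_ha = area_m2 / 1e4, area_km2 = area_m2 / 1e6,
                 animal_id = animal_id),
            class = "home_range")
}

#' @export
print.home_range <- function(x, ...) {
  cat(sprintf("%d%% kernel home range%s: %.1f ha (%d polygon%s)\n",
              round(100 * x$level),
              if (is.na(x$animal_id)) "" else paste0(" [", x$animal_id, "]"),
              x$area_ha, length(x$polygons),
              if (length(x$polygons) == 1) "" else "s"))
  invisible(x)
}

# Even-odd membership of points in a set of rings.
.in_rings <- function(px, py, rings) {
  inside <- rep(FALSE, length(px))
  for (r in rings) inside <- xor(inside, point_in_polygon(px, py, r))
  inside
}

#' Habitat composition of a home range
#'
#' Overlap analysis: the fraction of home-range area falling in each habitat
#' class of the surface map, evaluated on a fine sampling grid over the
#' home-range polygons. Area covered by no mapped polygon (including area
#' beyond the airfield boundary) is reported as `outside_mapped`.
#'
#' @param hr A `home_range`.
#' @param map A `surface_map` in the same planar frame.
#' @param cell Sampling cell size in metres; default resolves the home-range
#'   extent into ~400 cells per axis.
#' @return Named numeric vector of fractions summing to 1.
#' @export
habitat_composition <- function(hr, map, cell = NULL) {
  stopifnot(inherits(hr, "home_range"), inherits(map, "surface_map"))
  if (!length(hr$polygons)) stop("home range has no polygons")
  allv <- do.call(rbind, hr$polygons)
  rx <- range(allv[, 1])
  ry <- range(allv[, 2])
  if (is.null(cell)) cell <- max(diff(rx), diff(ry)) / 400
  gx <- seq(rx[1] + cell / 2, rx[2], by = cell)
  gy <- seq(ry[1] + cell / 2, ry[2], by = cell)
  pts <- expand.grid(x = gx, y = gy)
  inside <- .in_rings(pts$x, pts$y, hr$polygons)
  px <- pts$x[inside]
  py <- pts$y[inside]
  if (!length(px)) stop("no sampling points fell inside the home range")
  cls <- rep("outside_mapped", length(px))
  unassigned <- rep(TRUE, length(px))
  for (p in map$polygons) {
    if (!any(unassigned)) break
    hit <- unassigned
    hit[unassigned] <- point_in_polygon(px[unassigned], py[unassigned],
                                        p$geometry)
    cls[hit] <- p$habitat_class
    unassigned <- unassigned & !hit
  }
  tab <- table(factor(cls, levels = c(HABITAT_CLASSES, "outside_mapped")))
  out <- as.numeric(tab) / length(px)
  names(out) <- names(tab)
  out
}

#' Per-animal home-range table
#'
#' Convenience wrapper: for each trajectory, fits a kernel UD with the
#' reference bandwidth, extracts the `level` home range and its habitat
#' composition.
#'
#' @param trajs `trajectory_set` or list of trajectories (filtered).
#' @param map A `surface_map`.
#' @param level Contour probability (default 0.95).
#' @param grid_n Grid resolution per axis.
#' @return A list: `home_ranges` (list of `home_range` objects) and `table`
#'   (animal, h_ref, area_ha plus one column per habitat class, in percent).
#' @export
home_range_table <- function(trajs, map, level = 0.95, grid_n = 200) {
  hrs <- lapply(trajs, function(tr) {
    ud <- kernel_ud(tr$fixes$x, tr$fixes$y, grid_n = grid_n)
    hr <- contour_home_range(ud, level = level, animal_id = tr$animal_id)
    hr$h <- ud$h
    hr$habitat <- habitat_composition(hr, map)
    hr
  })
  tab <- do.call(rbind, c(lapply(hrs, function(hr) {
    row <- data.frame(animal_id = hr$animal_id, h_ref = hr$h,
                      area_ha = hr$area_ha, stringsAsFactors = FALSE)
    for (k in names(hr$habitat)) row[[k]] <- 100 * hr$habitat[[k]]
    row
  }), make.row.names = FALSE))
  list(home_ranges = hrs, table = tab)
}
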