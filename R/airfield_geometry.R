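# Classified airfield surface maps: loading, validation, subsetting.

HABITAT_CLASSES <- c("tarmac_runway", "tarmac_taxiway", "tarmac_connecting",
                     "apron", "built_land", "grassland", "service_road",
                     "unknown")
TARMAC_CLASSES <- c("tarmac_runway", "tarmac_taxiway", "tarmac_connecting")
ACTIVITY_STATUSES <- c("active", "semi_operational", "inactive", "not_applicable")

#' Construct a surface map
#'
#' @param polygons List of surface polygons; each element a list with fields
#'   `surface_id`, `geometry` (n x 2 vertex matrix, metres), `habitat_class`,
#'   `activity_status`, `label`.
#' @param boundary Optional airfield perimeter polygon (vertex matrix).
#' @param crs Optional descriptor of the planar frame (list or character).
#' @param validate Run geometry/attribute validation?
#' @return An object of class `surface_map`.
#' @export
new_surface_map <- function(polygons, boundary = NULL, crs = NULL,
                            validate = TRUE) {
  m <- structure(list(polygons = polygons, boundary = boundary, crs = crs),
                 class = "surface_map")
  if (validate) validate_surface_map(m)
  m
}

#' Validate a surface map
#'
#' Checks habitat classes and activity statuses against the recognised
#' vocabularies, rejects self-intersecting or zero-area rings (naming the
#' offending surface ids), requires tarmacked surfaces to carry a real
#' activity status, and refuses positive-area overlap between tarmacked
#' polygons (abutting edges are legal) since overlap would double-count
#' interactions.
#'
#' @param map A `surface_map`.
#' @return The map, invisibly; errors on violation.
#' @export
validate_surface_map <- function(map) {
  stopifnot(inherits(map, "surface_map"))
  for (p in map$polygons) {
    if (!p$habitat_class %in% HABITAT_CLASSES) {
      stop("surface ", p$surface_id, ": unknown habitat_class '",
           p$habitat_class, "'")
    }
    if (!p$activity_status %in% ACTIVITY_STATUSES) {
      stop("surface ", p$surface_id, ": unknown activity_status '",
           p$activity_status, "'")
    }
    if (p$habitat_class %in% TARMAC_CLASSES &&
        p$activity_status == "not_applicable") {
      stop("surface ", p$surface_id,
           ": tarmacked surfaces require an activity status")
    }
    geom <- .close_ring(p$geometry)
    if (.polygon_self_intersects(geom)) {
      stop("surface ", p$surface_id, ": self-intersecting geometry")
    }
    if (nrow(geom) < 3 || polygon_area(geom) <= 0) {
      stop("surface ", p$surface_id, ": degenerate geometry (zero area)")
    }
  }
  tar <- Filter(function(p) p$habitat_class %in% TARMAC_CLASSES, map$polygons)
  nt <- length(tar)
  if (nt > 1) {
    for (i in seq_len(nt - 1)) {
      for (j in (i + 1):nt) {
        if (.polygons_overlap(tar[[i]]$geometry, tar[[j]]$geometry)) {
          stop("tarmacked surfaces overlap: ", tar[[i]]$surface_id, " and ",
               tar[[j]]$surface_id)
        }
      }
    }
  }
  invisible(map)
}

#' @export
print.surface_map <- function(x, ...) {
  cls <- table(vapply(x$polygons, `[[`, "", "habitat_class"))
  cat("Surface map:", length(x$polygons), "polygons\n")
  for (k in names(cls)) cat(sprintf("  %-18s %d\n", k, cls[[k]]))
  invisible(x)
}

#' Load a surface map from GeoJSON
#'
#' Reads an RFC 7946 FeatureCollection whose features carry `surface_id`,
#' `habitat_class`, `activity_status` and optional `label` properties.
#' Coordinates are taken as metres in the local planar frame when the file
#' carries an `x_crs` member describing one; plain longitude/latitude
#' coordinates are projected with `proj` (required in that case).
#'
#' @param path Path to a GeoJSON file.
#' @param proj Optional `tm_projection` used to project lon/lat coordinates.
#' @return A validated `surface_map`.
#' @export
load_surface_map <- function(path, proj = NULL) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("expected a GeoJSON FeatureCollection")
  }
  planar <- !is.null(gj$x_crs)
  crs <- gj$x_crs
  # frame of the file itself, when it records one
  file_proj <- if (planar && !is.null(crs$lon0)) {
    make_projection(crs$lon0, crs$lat0)
  }
  # re-project the file's planar frame into the caller's frame if they differ
  reframe <- planar && !is.null(file_proj) && !is.null(proj) &&
    !(isTRUE(all.equal(proj$lon0, file_proj$lon0)) &&
        isTRUE(all.equal(proj$lat0, file_proj$lat0)))
  if (planar && is.null(proj)) proj <- file_proj
  polys <- lapply(gj$features, function(ft) {
    pr <- ft$properties
    if (is.null(pr$habitat_class) || is.null(pr$surface_id)) {
      stop("feature missing surface_id/habitat_class properties")
    }
    if (is.null(ft$geometry) || ft$geometry$type != "Polygon") {
      stop("surface ", pr$surface_id, ": only Polygon geometries are supported")
    }
    ring <- ft$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(v) c(v[[1]], v[[2]])))
    if (!planar) {
      if (is.null(proj)) stop("lon/lat GeoJSON requires a projection")
      xy <- project_lonlat(m[, 1], m[, 2], proj)
      m <- cbind(xy$x, xy$y)
    } else if (reframe) {
      ll <- unproject_xy(m[, 1], m[, 2], file_proj)
      xy <- project_lonlat(ll$lon, ll$lat, proj)
      m <- cbind(xy$x, xy$y)
    }
    list(surface_id = pr$surface_id,
         geometry = .close_ring(m),
         habitat_class = pr$habitat_class,
         activity_status = if (is.null(pr$activity_status)) "not_applicable"
                           else pr$activity_status,
         label = if (is.null(pr$label)) pr$surface_id else pr$label)
  })
  new_surface_map(polys, crs = crs, validate = TRUE)
}

#' Write a surface map to GeoJSON
#'
#' Planar coordinates (metres) are written verbatim, with an `x_crs` foreign
#' member recording the local frame so [load_surface_map()] round-trips.
#'
#' @param map A `surface_map`.
#' @param path Output path.
#' @param proj Optional `tm_projection` recorded in `x_crs`.
#' @return `path`, invisibly.
#' @export
write_surface_map <- function(map, path, proj = NULL) {
  feats <- lapply(map$polygons, function(p) {
    ring <- .close_ring(p$geometry)
    ring <- rbind(ring, ring[1, ])
    list(type = "Feature",
         properties = list(surface_id = p$surface_id,
                           habitat_class = p$habitat_class,
                           activity_status = p$activity_status,
                           label = p$label),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) as.numeric(ring[i, ])))))
  })
  crs <- if (!is.null(proj)) {
    list(type = "local-transverse-mercator", lon0 = proj$lon0, lat0 = proj$lat0)
  } else if (!is.null(map$crs)) map$crs else list(type = "local-planar")
  obj <- list(type = "FeatureCollection", x_crs = crs, features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' Tarmacked subset of a surface map
#'
#' Keeps only the surfaces where aircraft manoeuvre: runways, taxiways and
#' connecting areas, regardless of activity status (an inactive runway is
#' still a tarmacked area).
#'
#' @param map A `surface_map`.
#' @return A `surface_map` containing only tarmacked polygons.
#' @export
tarmacked_subset <- function(map) {
  stopifnot(inherits(map, "surface_map"))
  keep <- Filter(function(p) p$habitat_class %in% TARMAC_CLASSES, map$polygons)
  structure(list(polygons = keep, boundary = map$boundary, crs = map$crs),
            class = "surface_map")
}

#' Total area of a surface map by habitat class
#'
#' @param map A `surface_map`.
#' @return Named numeric vector of areas (m^2) per habitat class.
#' @export
surface_areas <- function(map) {
  cls <- vapply(map$polygons, `[[`, "", "habitat_class")
  ar <- vapply(map$polygons, function(p) polygon_area(p$geometry), 0)
  tapply(ar, cls, sum)
}
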