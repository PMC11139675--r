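# Synthetic airfield maps and simulated collar datasets with ground truth.
# The simulator emulates the study's collar design: accelerometer-informed
# fix schedule (10 min active / 6 h resting), crepuscular two-state activity
# anchored to sunrise and sunset, home-centred correlated random walks, GPS
# position noise with per-fix accuracy values, and configurable propensity
# to cross tarmacked surfaces.

.rect <- function(cx, cy, w, h) {
  cbind(c(cx - w / 2, cx + w / 2, cx + w / 2, cx - w / 2),
        c(cy - h / 2, cy - h / 2, cy + h / 2, cy + h / 2))
}

# Evaluate expr with a temporary RNG seed, restoring global RNG state.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Default synthetic-airfield layout
#'
#' Three parallel runways (60 m wide) each with a parallel taxiway (35 m)
#' and short connecting strips, grassland islands filling the gaps, and
#' apron / built-land / service-road strips at the margins. Activity
#' statuses mirror a field with one active, one semi-operational and one
#' inactive runway system.
#'
#' @param runway_width,taxiway_width Widths in metres.
#' @param length_m Runway length in metres.
#' @param n_grass_islands Number of seeded grassland islands.
#' @return Layout list consumed by [make_airfield()].
#' @export
airfield_layout <- function(runway_width = 60, taxiway_width = 35,
                            length_m = 3200, n_grass_islands = 14) {
  stopifnot(runway_width > 0, taxiway_width > 0)
  list(runway_width = runway_width, taxiway_width = taxiway_width,
       length_m = length_m, n_grass_islands = n_grass_islands,
       systems = list(
         list(label = "RW-A", status = "active", runway_y = -1200, taxiway_y = -1050),
         list(label = "RW-B", status = "semi_operational", runway_y = 900, taxiway_y = 750),
         list(label = "RW-C", status = "inactive", runway_y = 1500, taxiway_y = 1350)))
}

#' Generate a synthetic airfield surface map
#'
#' Builds a parametric classified airfield from a layout. Deterministic for
#' a given seed/layout (grassland island placement is the only seeded part).
#'
#' @param layout From [airfield_layout()].
#' @param seed Integer seed for island placement.
#' @return A validated `surface_map`.
#' @export
make_airfield <- function(layout = airfield_layout(), seed = 1) {
  L <- layout$length_m
  polys <- list()
  add <- function(id, geom, cls, status, label) {
    polys[[length(polys) + 1]] <<- list(surface_id = id, geometry = geom,
                                        habitat_class = cls,
                                        activity_status = status, label = label)
  }
  for (sys in layout$systems) {
    rw <- layout$runway_width
    tw <- layout$taxiway_width
    add(paste0("runway-", sys$label), .rect(0, sys$runway_y, L, rw),
        "tarmac_runway", sys$status, sys$label)
    add(paste0("taxiway-", sys$label), .rect(0, sys$taxiway_y, L, tw),
        "tarmac_taxiway", sys$status, paste0("taxiway-", sys$label))
    lo <- min(sys$runway_y, sys$taxiway_y) +
      ifelse(sys$runway_y < sys$taxiway_y, rw / 2, tw / 2)
    hi <- max(sys$runway_y, sys$taxiway_y) -
      ifelse(sys$runway_y > sys$taxiway_y, rw / 2, tw / 2)
    for (cx in c(-L * 0.375, 0, L * 0.375)) {
      add(paste0("connect-", sys$label, "-", round(cx)),
          .rect(cx, (lo + hi) / 2, 20, hi - lo),
          "tarmac_connecting", sys$status,
          paste0("connect-", sys$label))
    }
  }
  # seeded grassland islands in the open bands between tarmac groups
  bands <- list(c(-1000, 700), c(-1580, -1260), c(960, 1300), c(1570, 1800))
  .with_seed(seed, {
    k <- 0
    for (b in seq_along(bands)) {
      lo <- bands[[b]][1]; hi <- bands[[b]][2]
      n_b <- ceiling(layout$n_grass_islands *
                       (hi - lo) / sum(vapply(bands, diff, 0)))
      for (i in seq_len(n_b)) {
        k <- k + 1
        w <- stats::runif(1, 300, 700)
        h <- min(stats::runif(1, 150, 500), hi - lo)
        cx <- stats::runif(1, -L / 2 + w / 2, L / 2 - w / 2)
        cy <- stats::runif(1, lo + h / 2, hi - h / 2)
        add(paste0("grass-", k), .rect(cx, cy, w, h), "grassland",
            "not_applicable", paste0("grass-", k))
      }
    }
    # wide grass carpets guaranteeing cover of the main bands
    add("grass-band-mid", .rect(0, -150, L, 1680), "grassland",
        "not_applicable", "grass-band-mid")
    add("grass-band-south", .rect(0, -1420, L, 300), "grassland",
        "not_applicable", "grass-band-south")
  })
  add("apron-1", .rect(-800, -1750, 1400, 120), "apron", "not_applicable", "apron-1")
  add("built-1", .rect(600, -1750, 900, 120), "built_land", "not_applicable", "built-1")
  add("service-1", .rect(0, -1650, L, 12), "service_road", "not_applicable", "service-1")
  add("service-2", .rect(0, 1830, L, 12), "service_road", "not_applicable", "service-2")
  add("unknown-1", .rect(1500, 1750, 300, 100), "unknown", "not_applicable", "unknown-1")
  boundary <- .rect(0, 0, L + 400, 3900)
  new_surface_map(polys, boundary = boundary, validate = TRUE)
}

#' Simulation configuration
#'
#' Parameters of the two-state collar simulator. Defaults emulate the study
#' design: fixes every 10 min when active and every 6 h at rest, crepuscular
#' activity (probability bumps centred on sunrise and sunset), ~2% of fixes
#' with horizontal accuracy worse than 30 m, and home-centred correlated
#' random walk movement.
#'
#' @param animals data.frame with one row per animal: `animal_id`, home
#'   centre `x0`, `y0` (m), `attract` (per-minute pull toward the centre),
#'   `speed_m_min` (active speed), `excursion_per_day` (rate of directed
#'   tarmac excursions), `excursion_mode` (`"through"` or `"touch"`).
#' @param start UTC start instant; `days` simulated duration.
#' @param lat,lon,tz Site for solar anchoring and geographic output.
#' @param dt_min Simulation time step (minutes).
#' @param base_p,bump_p,bump_w_h Activity probability: baseline plus
#'   Gaussian bumps of height `bump_p` and width `bump_w_h` hours at
#'   sunrise/sunset.
#' @param bout_active_min,bout_rest_min Mean bout lengths (minutes).
#' @param fix_active_min,fix_rest_h Fix schedule intervals.
#' @param heading_sd Turning-angle standard deviation per minute (radians).
#' @param gps_noise_sd Position noise sd (m) for good fixes.
#' @param frac_bad_acc Fraction of fixes with accuracy > 30 m.
#' @param excursion_speed Speed during excursions (m/min).
#' @return A `sim_config` list.
#' @export
sim_config <- function(animals,
                       start = as.POSIXct("2021-12-05 00:00:00", tz = "UTC"),
                       days = 30, lat = 53.43, lon = -6.25,
                       tz = "Europe/Dublin", dt_min = 1,
                       base_p = 0.1, bump_p = 0.85, bump_w_h = 1.5,
                       bout_active_min = 60, bout_rest_min = 90,
                       fix_active_min = 10, fix_rest_h = 6,
                       heading_sd = 0.6, gps_noise_sd = 5,
                       frac_bad_acc = 0.02, excursion_speed = 12) {
  stopifnot(is.data.frame(animals), nrow(animals) >= 1,
            days > 0, dt_min > 0, fix_active_min > 0, fix_rest_h > 0,
            base_p >= 0, bump_p >= 0, frac_bad_acc >= 0, frac_bad_acc <= 1)
  structure(as.list(environment()), class = "sim_config")
}

# Nearest tarmac polygon and boundary point for excursion targeting.
.excursion_target <- function(home, map, mode) {
  tar <- tarmacked_subset(map)$polygons
  best <- NULL
  best_d <- Inf
  best_q <- NULL
  for (p in tar) {
    g <- .close_ring(p$geometry)
    n <- nrow(g)
    for (i in seq_len(n)) {
      a <- g[i, ]; b <- g[if (i == n) 1 else i + 1, ]
      ab <- b - a
      tt <- sum((home - a) * ab) / sum(ab * ab)
      tt <- min(1, max(0, tt))
      q <- a + tt * ab
      d <- sqrt(sum((home - q)^2))
      if (d < best_d) {
        best_d <- d; best <- p; best_q <- q
      }
    }
  }
  u <- (best_q - home) / best_d
  if (mode == "touch") return(best_q + 20 * u)
  # "through": march past the far edge of the polygon
  s <- seq(1, 400, by = 1)
  inside <- point_in_polygon(best_q[1] + s * u[1], best_q[2] + s * u[2],
                             best$geometry)
  smax <- if (any(inside)) max(s[inside]) else 0
  best_q + (smax + 30) * u
}

#' Simulate collared hares on a synthetic airfield
#'
#' Simulates each animal's continuous path on a fine time grid with a
#' two-state (active/resting) process whose activation probability is
#' anchored to sunrise and sunset, samples GPS fixes on the state-dependent
#' schedule, adds position noise and per-fix accuracy values, and logs the
#' ground truth: the full path, every true tarmac crossing (connected path
#' interval inside a tarmacked polygon, or a within-step pass-through) and
#' per-day true path lengths.
#'
#' @param map A `surface_map` from [make_airfield()].
#' @param cfg A `sim_config`.
#' @param seed Integer seed; the full output is reproducible from it.
#' @return A list: `fixes` (data.frame: animal_id, timestamp, lon, lat,
#'   h_accuracy, state), `truth` (list with `crossings`, `daily_path_km`,
#'   `paths`), `proj`, `cfg`.
#' @export
simulate_hares <- function(map, cfg, seed = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$days <= 5) stop("simulated period must exceed the 5-day burn-in")
  proj <- make_projection(cfg$lon, cfg$lat)
  n_min <- cfg$days * 24 * 60
  t_utc <- cfg$start + seq(0, n_min - 1) * 60
  lt <- as.POSIXlt(to_local_time(t_utc, cfg$tz))
  hour_frac <- lt$hour + lt$min / 60
  date_local <- as.Date(format(lt, "%Y-%m-%d"))
  udates <- unique(date_local)
  sun <- lapply(udates, function(d) sun_times(d, cfg$lat, cfg$lon, tz = cfg$tz))
  names(sun) <- as.character(udates)
  sr_h <- vapply(sun, function(s) {
    x <- as.POSIXlt(s$sunrise_local); x$hour + x$min / 60
  }, 0)[as.character(date_local)]
  ss_h <- vapply(sun, function(s) {
    x <- as.POSIXlt(s$sunset_local); x$hour + x$min / 60
  }, 0)[as.character(date_local)]
  p_act <- pmin(0.98, cfg$base_p +
                  cfg$bump_p * exp(-(hour_frac - sr_h)^2 / (2 * cfg$bump_w_h^2)) +
                  cfg$bump_p * exp(-(hour_frac - ss_h)^2 / (2 * cfg$bump_w_h^2)))
  tar <- tarmacked_subset(map)$polygons

  .with_seed(seed, {
    all_fixes <- list()
    all_cross <- list()
    all_daily <- list()
    paths <- list()
    for (ai in seq_len(nrow(cfg$animals))) {
      an <- cfg$animals[ai, ]
      home <- c(an$x0, an$y0)
      target_fun <- function() .excursion_target(home, map, an$excursion_mode)
      n_exc <- stats::rpois(1, an$excursion_per_day * cfg$days)
      exc_starts <- sort(sample.int(n_min, min(n_exc, n_min)))
      u_bout <- stats::runif(n_min)
      u_state <- stats::runif(n_min)
      head_noise <- stats::rnorm(n_min, 0, cfg$heading_sd)
      xy <- matrix(0, n_min, 2)
      state <- integer(n_min)  # 1 active, 0 rest
      pos <- home
      heading <- stats::runif(1, 0, 2 * pi)
      cur_active <- FALSE
      exc_phase <- 0L  # 0 none, 1 out, 2 back
      exc_target <- NULL
      next_exc <- 1L
      for (t in seq_len(n_min)) {
        if (exc_phase == 0L && next_exc <= length(exc_starts) &&
            t >= exc_starts[next_exc]) {
          exc_phase <- 1L
          exc_target <- target_fun()
          next_exc <- next_exc + 1L
        }
        if (exc_phase > 0L) {
          goal <- if (exc_phase == 1L) exc_target else home
          dvec <- goal - pos
          dd <- sqrt(sum(dvec^2))
          if (dd < 10) {
            if (exc_phase == 1L) {
              exc_phase <- 2L
            } else {
              exc_phase <- 0L
            }
          } else {
            pos <- pos + cfg$excursion_speed * dvec / dd +
              c(head_noise[t], -head_noise[t])
          }
          cur_active <- TRUE
        } else {
          if (u_bout[t] < 1 / (if (cur_active) cfg$bout_active_min else cfg$bout_rest_min)) {
            cur_active <- u_state[t] < p_act[t]
          }
          if (cur_active) {
            heading <- heading + head_noise[t]
            pos <- pos + an$speed_m_min * c(cos(heading), sin(heading)) +
              an$attract * (home - pos)
          }
        }
        xy[t, ] <- pos
        state[t] <- as.integer(cur_active || exc_phase > 0L)
      }
      # state-dependent fix schedule
      fix_idx <- integer(0)
      last_fix <- 1L
      fix_idx <- 1L
      for (t in 2:n_min) {
        interval <- if (state[t] == 1L) cfg$fix_active_min else cfg$fix_rest_h * 60
        if (t - last_fix >= interval) {
          fix_idx <- c(fix_idx, t)
          last_fix <- t
        }
      }
      nf <- length(fix_idx)
      bad <- stats::runif(nf) < cfg$frac_bad_acc
      acc <- ifelse(bad, stats::runif(nf, 31, 80),
                    stats::rgamma(nf, shape = 3.5, scale = 7.5 / 3.5))
      noise_sd <- ifelse(bad, acc / 2, cfg$gps_noise_sd)
      fx <- xy[fix_idx, 1] + stats::rnorm(nf, 0, noise_sd)
      fy <- xy[fix_idx, 2] + stats::rnorm(nf, 0, noise_sd)
      ll <- unproject_xy(fx, fy, proj)
      all_fixes[[ai]] <- data.frame(
        animal_id = an$animal_id,
        timestamp = format(t_utc[fix_idx], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
        lon = ll$lon, lat = ll$lat,
        h_accuracy = round(acc, 1),
        state = ifelse(state[fix_idx] == 1L, "active", "rest"),
        stringsAsFactors = FALSE)
      # ground truth: crossings of the continuous path
      for (p in tar) {
        inside <- point_in_polygon(xy[, 1], xy[, 2], p$geometry)
        r <- rle(inside)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1
        runs <- which(r$values)
        if (length(runs)) {
          all_cross[[length(all_cross) + 1]] <- data.frame(
            animal_id = an$animal_id, surface_id = p$surface_id,
            t_enter = t_utc[starts[runs]], t_exit = t_utc[ends[runs]],
            stringsAsFactors = FALSE)
        }
        # pass-throughs entirely between path samples
        i <- seq_len(n_min - 1)
        thru <- !inside[i] & !inside[i + 1] &
          segment_intersects_polygon(xy[i, 1], xy[i, 2],
                                     xy[i + 1, 1], xy[i + 1, 2], p$geometry)
        if (any(thru)) {
          w <- which(thru)
          all_cross[[length(all_cross) + 1]] <- data.frame(
            animal_id = an$animal_id, surface_id = p$surface_id,
            t_enter = t_utc[w], t_exit = t_utc[w + 1],
            stringsAsFactors = FALSE)
        }
      }
      stepl <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
      dd <- tapply(stepl, date_local[-1], sum) / 1000
      all_daily[[ai]] <- data.frame(animal_id = an$animal_id,
                                    date = as.Date(names(dd)),
                                    path_km = as.numeric(dd),
                                    stringsAsFactors = FALSE)
      paths[[an$animal_id]] <- xy
    }
    fixes <- do.call(rbind, c(all_fixes, make.row.names = FALSE))
    crossings <- if (length(all_cross)) {
      cr <- do.call(rbind, c(all_cross, make.row.names = FALSE))
      cr[order(cr$animal_id, cr$t_enter, cr$surface_id), , drop = FALSE]
    } else {
      data.frame(animal_id = character(), surface_id = character(),
                 t_enter = as.POSIXct(character(), tz = "UTC"),
                 t_exit = as.POSIXct(character(), tz = "UTC"))
    }
    list(fixes = fixes,
         truth = list(crossings = crossings,
                      daily_path_km = do.call(rbind, c(all_daily, make.row.names = FALSE)),
                      paths = paths),
         proj = proj, cfg = cfg)
  })
}

#' Write simulated fixes to CSV
#'
#' Emits the same dialect [read_gps_table()] reads.
#'
#' @param fixes Fix data.frame from [simulate_hares()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fixes_csv <- function(fixes, path) {
  utils::write.csv(fixes[, c("animal_id", "timestamp", "lon", "lat", "h_accuracy")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Study-like synthetic scenario
#'
#' A desk-scale analogue of the study design: a synthetic airfield and five
#' collared animals over 30 days, two with home ranges adjacent to the
#' semi-operational runway/taxiway system (high configured crossing
#' propensity) and three in distant grassland (low propensity).
#'
#' @param seed Integer seed.
#' @param days Period length in days.
#' @return A list: `map`, `sim` (output of [simulate_hares()]), `fixes_csv`
#'   and `map_geojson` paths (in `dir`), `near_ids`, `far_ids`.
#' @param dir Directory for the emitted CSV/GeoJSON inputs
#'   (default `tempdir()`).
#' @export
scenario_paper_like <- function(seed = 42, days = 30, dir = tempdir()) {
  map <- make_airfield(seed = seed)
  animals <- data.frame(
    animal_id = c("S1", "S2", "S3", "S4", "S5"),
    x0 = c(-300, 400, -600, 300, 900),
    y0 = c(560, 560, -400, -500, -350),
    attract = 0.003,
    speed_m_min = 7,
    excursion_per_day = c(1.5, 1.5, 0.2, 0.2, 0.2),
    excursion_mode = c("through", "through", "touch", "touch", "touch"),
    stringsAsFactors = FALSE)
  cfg <- sim_config(animals, days = days)
  sim <- simulate_hares(map, cfg, seed = seed)
  fixes_csv <- file.path(dir, sprintf("sim_fixes_seed%d.csv", seed))
  map_geojson <- file.path(dir, sprintf("sim_airfield_seed%d.geojson", seed))
  write_fixes_csv(sim$fixes, fixes_csv)
  write_surface_map(map, map_geojson, proj = sim$proj)
  list(map = map, sim = sim, fixes_csv = fixes_csv, map_geojson = map_geojson,
       near_ids = c("S1", "S2"), far_ids = c("S3", "S4", "S5"),
       seed = seed)
}
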