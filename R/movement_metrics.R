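# Step-length, daily distance and cumulative monthly movement summaries.

#' Daily travel distance per animal
#'
#' Sums step lengths per animal per local day (each step assigned wholly to
#' the local date of its earlier fix; steps spanning midnight are not split)
#' and zero-fills every day in each animal's observed span.
#'
#' @param steps Steps data.frame from [build_steps_all()].
#' @return data.frame (animal_id, date, distance_km).
#' @export
daily_distance <- function(steps) {
  if (!nrow(steps)) {
    return(data.frame(animal_id = character(), date = as.Date(character()),
                      distance_km = numeric()))
  }
  steps$date <- as.Date(format(steps$t_local, "%Y-%m-%d"))
  do.call(rbind, c(lapply(split(steps, steps$animal_id), function(s) {
    days <- seq(min(s$date), max(s$date), by = "day")
    km <- tapply(s$length_m, factor(as.character(s$date),
                                    levels = as.character(days)), sum) / 1000
    km[is.na(km)] <- 0
    data.frame(animal_id = s$animal_id[1], date = days,
               distance_km = as.numeric(km), stringsAsFactors = FALSE)
  }), make.row.names = FALSE))
}

#' Cumulative monthly distance
#'
#' Per-animal monthly totals of daily distance. By default a month counts for
#' an animal only when its deployment covers the entire calendar month;
#' months listed in `keep_partial` (e.g. a first month where all collars
#' started a few days in) are retained regardless.
#'
#' @param daily data.frame from [daily_distance()].
#' @param deployments Optional data.frame (animal_id, start, end) of
#'   deployment dates; defaults to each animal's observed date span.
#' @param full_months_only Drop months not fully covered?
#' @param keep_partial Character vector of `"YYYY-MM"` months exempt from the
#'   full-coverage rule.
#' @return A list: `per_animal` (animal_id, month, distance_km),
#'   `collective` (month, distance_km summed over animals, mean/sd of the
#'   contributing daily distances).
#' @export
monthly_cumulative <- function(daily, deployments = NULL,
                               full_months_only = TRUE,
                               keep_partial = character()) {
  if (is.null(deployments)) {
    deployments <- do.call(rbind, c(lapply(split(daily, daily$animal_id),
      function(d) data.frame(animal_id = d$animal_id[1], start = min(d$date),
                             end = max(d$date), stringsAsFactors = FALSE)),
      make.row.names = FALSE))
  }
  daily$month <- format(daily$date, "%Y-%m")
  keep_row <- rep(TRUE, nrow(daily))
  if (full_months_only) {
    for (i in seq_len(nrow(deployments))) {
      id <- deployments$animal_id[i]
      sel <- daily$animal_id == id
      mo <- unique(daily$month[sel])
      for (m in mo) {
        if (m %in% keep_partial) next
        first <- as.Date(paste0(m, "-01"))
        last <- seq(first, by = "month", length.out = 2)[2] - 1
        if (deployments$start[i] > first || deployments$end[i] < last) {
          keep_row[sel & daily$month == m] <- FALSE
        }
      }
    }
  }
  kept <- daily[keep_row, , drop = FALSE]
  if (!nrow(kept)) {
    empty_pa <- data.frame(animal_id = character(), month = character(),
                           distance_km = numeric())
    empty_co <- data.frame(month = character(), distance_km = numeric(),
                           mean_daily_km = numeric(), sd_daily_km = numeric())
    return(list(per_animal = empty_pa, collective = empty_co))
  }
  per_animal <- do.call(rbind, c(lapply(split(kept, list(kept$animal_id, kept$month),
                                              drop = TRUE), function(d) {
    data.frame(animal_id = d$animal_id[1], month = d$month[1],
               distance_km = sum(d$distance_km), stringsAsFactors = FALSE)
  }), make.row.names = FALSE))
  collective <- do.call(rbind, c(lapply(split(kept, kept$month), function(d) {
    data.frame(month = d$month[1], distance_km = sum(d$distance_km),
               mean_daily_km = mean(d$distance_km),
               sd_daily_km = stats::sd(d$distance_km), stringsAsFactors = FALSE)
  }), make.row.names = FALSE))
  ord <- order(per_animal$animal_id, per_animal$month)
  list(per_animal = per_animal[ord, , drop = FALSE],
       collective = collective[order(collective$month), , drop = FALSE])
}

#' Month-wise rank test of daily distances
#'
#' Kruskal-Wallis over daily distances grouped by calendar month, with Dunn
#' post-hoc pairwise comparisons (Benjamini-Hochberg adjusted).
#'
#' @param daily data.frame from [daily_distance()].
#' @param exclude_months Integer month numbers dropped before testing
#'   (e.g. a month covered by a single animal).
#' @return A list: `kw` (`rank_test`), `dunn` (pairwise table).
#' @export
monthly_distance_test <- function(daily, exclude_months = integer()) {
  m <- as.integer(format(daily$date, "%m"))
  keep <- !(m %in% exclude_months)
  groups <- split(daily$distance_km[keep], format(daily$date[keep], "%Y-%m"))
  if (length(groups) < 2) stop("need at least 2 month groups after exclusion")
  list(kw = kruskal_wallis(groups), dunn = dunn_posthoc(groups))
}

#' Step-length summary
#'
#' Mean and standard deviation of step lengths, pooled and per animal,
#' optionally restricted to steps at the fine-schedule sampling interval
#' (default: duration <= 20 min, isolating the 10-min active schedule from
#' long resting gaps).
#'
#' @param steps Steps data.frame.
#' @param max_duration_min Restrict to steps no longer than this many
#'   minutes; `NULL` uses all steps.
#' @return A list: `pooled` (n, mean_m, sd_m, degenerate flag when n < 2)
#'   and `per_animal` data.frame.
#' @export
step_length_summary <- function(steps, max_duration_min = 20) {
  s <- steps
  if (!is.null(max_duration_min)) {
    s <- s[s$duration_s <= max_duration_min * 60, , drop = FALSE]
  }
  summ <- function(v) {
    list(n = length(v), mean_m = if (length(v)) mean(v) else NA_real_,
         sd_m = if (length(v) >= 2) stats::sd(v) else 0,
         degenerate = length(v) < 2)
  }
  per <- do.call(rbind, c(lapply(split(s$length_m, s$animal_id), function(v) {
    u <- summ(v)
    data.frame(n = u$n, mean_m = u$mean_m, sd_m = u$sd_m)
  }), make.row.names = FALSE))
  if (!is.null(per)) per$animal_id <- names(split(s$length_m, s$animal_id))
  list(pooled = summ(s$length_m), per_animal = per)
}
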