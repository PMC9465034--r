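#' Increasing rate against a baseline count
#'
#' `(current - base) / base * 100` (percent). With a zero baseline the rate
#' is undefined: it is returned as `NA` carrying a `flag` attribute,
#' `"new_presence"` when the current count is positive (pests appeared where
#' none were recorded) and `"absent"` otherwise.
#'
#' @param current current count; @param base baseline (cardinal) count.
#' @return Percentage, or flagged `NA`.
#' @export
increasing_rate <- function(current, base) {
  if (base > 0) return((current - base) / base * 100)
  structure(NA_real_, flag = if (current > 0) "new_presence" else "absent")
}

#' Day-on-day increasing rate
#' @param today,yesterday daily counts.
#' @return Percentage (see [increasing_rate()] for the zero-baseline case).
#' @export
day_rate <- function(today, yesterday) increasing_rate(today, yesterday)

#' Cycle-on-cycle increasing rate
#'
#' Rate of today's count against the count on the same day of the previous
#' 7-day cycle; defined only from the second cycle onward.
#'
#' @param today,same_day_prev_cycle daily counts.
#' @return Percentage (see [increasing_rate()]).
#' @export
cycle_rate <- function(today, same_day_prev_cycle)
  increasing_rate(today, same_day_prev_cycle)

#' Pest increasing rate against the level-1 baseline
#' @param n_level_count current-cycle pest count.
#' @param level1_count baseline (first recorded cycle) pest count.
#' @return Percentage (see [increasing_rate()]).
#' @export
pest_increase_rate <- function(n_level_count, level1_count)
  increasing_rate(n_level_count, level1_count)

#' Outbreak grading from pest density and increasing rate
#'
#' Maps the cycle's pest density (insects per trap-day) and pest increasing
#' rate (percent) each onto the five-level cotton-field grading bands and
#' returns the more severe of the two levels. Bands are right-closed: a
#' density of exactly 5 is level 1, exactly 10 level 2, and so on. A
#' negative rate maps to level 1. The published rate bands list ">300%" for
#' both levels 4 and 5; level 5 is taken as rates above 500% so the bands
#' partition, and both band levels are returned for inspection.
#'
#' @param density pest density (>= 0).
#' @param rate pest increasing rate, percent.
#' @param density_breaks,rate_breaks right-closed upper band edges for
#'   levels 1--4 (level 5 is everything above the last edge).
#' @return Integer level 1--5 with attributes `density_level` and
#'   `rate_level`.
#' @export
grade_outbreak <- function(density, rate,
                           density_breaks = c(5, 10, 20, 30),
                           rate_breaks = c(0, 100, 300, 500)) {
  stopifnot(density >= 0)
  band <- function(x, breaks) {
    if (is.na(x)) return(1L)
    as.integer(sum(x > breaks) + 1L)
  }
  dl <- band(density, density_breaks)
  rl <- band(rate, rate_breaks)
  structure(max(dl, rl), density_level = dl, rate_level = rl)
}

#' Warning colour from increasing rates
#'
#' Any defined rate in (0, 100] percent triggers at least a blue warning,
#' (100, 300] orange, above 300 red; the strongest triggered colour wins and
#' non-positive rates trigger nothing. A rate flagged `"new_presence"` (pests
#' appearing over a zero baseline) triggers orange.
#'
#' @param rates numeric vector of rates (IR/DIR/CIR, percent); `NA`s are
#'   ignored unless flagged.
#' @param new_presence set TRUE when a zero-baseline rate had a positive
#'   numerator.
#' @return One of `"none"`, `"blue"`, `"orange"`, `"red"`.
#' @export
warn_color <- function(rates, new_presence = FALSE) {
  flags <- unlist(lapply(rates, attr, "flag"))
  if (!new_presence && !is.null(flags))
    new_presence <- any(flags == "new_presence")
  rates <- unlist(rates)
  rates <- rates[!is.na(rates)]
  colors <- c("none", "blue", "orange", "red")
  level <- if (length(rates) == 0) 1L
  else {
    r <- max(rates)
    if (r > 300) 4L else if (r > 100) 3L else if (r > 0) 2L else 1L
  }
  if (new_presence) level <- max(level, 3L)
  colors[level]
}

#' Analyze a daily count series into a pest outbreak warning report
#'
#' Groups daily trap counts into 7-day cycles (pest emergence takes about a
#' week). In the first cycle each day's increasing rate (IR) is computed
#' against the cardinal count; from the second cycle onward the day-on-day
#' rate (DIR) and the cycle-on-cycle rate (CIR, same weekday of the previous
#' cycle) are computed instead. Each cycle receives a pest density (mean
#' daily count), a pest increasing rate (PIR, cycle total against the first
#' cycle's total) and the outbreak level from [grade_outbreak()]; each day
#' receives the warning colour of its defined rates.
#'
#' @param series data.frame with `date` (consecutive days) and `count`.
#' @param cardinal baseline count for the first cycle's IR; defaults to the
#'   count on day 1.
#' @param cycle_length days per cycle.
#' @return A list of class `warning_report` with `daily` and `cycles`
#'   data.frames, plus `cardinal`.
#' @export
analyze_counts <- function(series, cardinal = NULL, cycle_length = 7L) {
  stopifnot(all(c("date", "count") %in% names(series)), nrow(series) >= 1)
  if (any(series$count < 0)) stop("counts must be non-negative")
  dates <- as.Date(series$date)
  if (nrow(series) > 1 && any(diff(dates) != 1))
    stop("counts must be daily with no gaps")
  n <- nrow(series)
  count <- series$count
  if (is.null(cardinal)) cardinal <- count[1]
  day <- seq_len(n)
  cyc <- (day - 1L) %/% cycle_length + 1L
  ir <- dir <- cir <- rep(NA_real_, n)
  color <- character(n)
  for (d in day) {
    rates <- list()
    if (cyc[d] == 1L) {
      rates$ir <- increasing_rate(count[d], cardinal)
      ir[d] <- as.numeric(rates$ir)
    } else {
      rates$dir <- day_rate(count[d], count[d - 1L])
      dir[d] <- as.numeric(rates$dir)
      rates$cir <- cycle_rate(count[d], count[d - cycle_length])
      cir[d] <- as.numeric(rates$cir)
    }
    color[d] <- warn_color(rates)
  }
  daily <- data.frame(date = dates, count = count, cycle = cyc,
                      ir = ir, dir = dir, cir = cir, color = color,
                      stringsAsFactors = FALSE)
  first_total <- sum(count[cyc == 1L])
  cycles <- do.call(rbind, lapply(unique(cyc), function(cc) {
    idx <- which(cyc == cc)
    total <- sum(count[idx])
    density <- mean(count[idx])
    pir <- if (cc == 1L) 0 else as.numeric(pest_increase_rate(total, first_total))
    lev <- grade_outbreak(density, if (is.na(pir)) 0 else pir)
    data.frame(cycle = cc, days = length(idx), total = total,
               density = density, pir = pir, level = as.integer(lev),
               color = max_color(color[idx]), stringsAsFactors = FALSE)
  }))
  structure(list(daily = daily, cycles = cycles, cardinal = cardinal),
            class = "warning_report")
}

max_color <- function(cols) {
  ord <- c(none = 1, blue = 2, orange = 3, red = 4)
  names(ord)[max(ord[cols])]
}

#' @export
print.warning_report <- function(x, ...) {
  cat(sprintf("<warning_report> %d days, %d cycles, cardinal %d\n",
              nrow(x$daily), nrow(x$cycles), x$cardinal))
  print(x$cycles)
  invisible(x)
}

#' Write a warning report as JSON
#' @param report a `warning_report`; @param path output path.
#' @return `path`, invisibly.
#' @export
write_warning_report <- function(report, path) {
  jsonlite::write_json(list(cardinal = report$cardinal,
                            daily = report$daily, cycles = report$cycles),
                       path, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
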