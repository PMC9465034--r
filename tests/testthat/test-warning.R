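test_that("increasing rates follow the defining formula", {
  expect_equal(increasing_rate(10, 10), 0)
  expect_equal(increasing_rate(20, 10), 100)
  expect_equal(increasing_rate(5, 10), -50)
  expect_equal(day_rate(30, 10), 200)
  expect_equal(cycle_rate(45, 15), 200)
  expect_equal(pest_increase_rate(40, 10), 300)
  expect_equal(pest_increase_rate(7, 7), 0)
  # identical formula across the rate family
  expect_equal(pest_increase_rate(13, 4), increasing_rate(13, 4))
  # zero baselines are flagged, not fabricated
  r <- increasing_rate(5, 0)
  expect_true(is.na(r))
  expect_equal(attr(r, "flag"), "new_presence")
  expect_equal(attr(increasing_rate(0, 0), "flag"), "absent")
})

test_that("grading agrees with the hand-written band lookup exhaustively", {
  for (d in 0:40)
    for (r in c(-50, 0, 50, 150, 350, 600))
      expect_equal(as.integer(grade_outbreak(d, r)), grade_lookup(d, r),
                   label = sprintf("density %d rate %d", d, r))
})

test_that("band boundaries are right-closed and levels monotone", {
  expect_equal(as.integer(grade_outbreak(5, 0)), 1)
  expect_equal(as.integer(grade_outbreak(10, 0)), 2)
  expect_equal(as.integer(grade_outbreak(20, 0)), 3)
  expect_equal(as.integer(grade_outbreak(30, 0)), 4)
  expect_equal(as.integer(grade_outbreak(31, 0)), 5)
  expect_equal(as.integer(grade_outbreak(3, 0)), 1)
  expect_equal(as.integer(grade_outbreak(25, 0)), 4)
  expect_equal(as.integer(grade_outbreak(4, 350)), 4)
  # monotone in both arguments over a grid
  ds <- seq(0, 40, by = 2)
  rs <- c(-10, 0, 40, 100, 101, 250, 300, 301, 450, 500, 501, 900)
  lev <- outer(ds, rs, Vectorize(function(d, r)
    as.integer(grade_outbreak(d, r))))
  expect_true(all(apply(lev, 2, function(x) all(diff(x) >= 0))))
  expect_true(all(apply(lev, 1, function(x) all(diff(x[-1]) >= 0))))
})

test_that("warning colours trigger on the stated rate bands", {
  expect_equal(warn_color(c(0, 0, 0)), "none")
  expect_equal(warn_color(-20), "none")
  expect_equal(warn_color(50), "blue")
  expect_equal(warn_color(100), "blue")
  expect_equal(warn_color(150), "orange")
  expect_equal(warn_color(300), "orange")
  expect_equal(warn_color(301), "red")
  expect_equal(warn_color(500), "red")
  # the strongest triggered colour wins
  expect_equal(warn_color(c(10, 150, 999)), "red")
  # pests appearing over a zero baseline raise orange
  expect_equal(warn_color(list(increasing_rate(5, 0))), "orange")
  expect_equal(warn_color(numeric(0)), "none")
})

test_that("a constant series produces zero rates and no warnings", {
  cs <- make_count_series(count_series_spec(14, 10, 1.0, 0))
  rep <- analyze_counts(cs)
  expect_true(all(rep$daily$color == "none"))
  expect_true(all(rep$daily$ir[rep$daily$cycle == 1] == 0))
  expect_true(all(rep$daily$dir[rep$daily$cycle == 2] == 0))
  expect_true(all(rep$daily$cir[rep$daily$cycle == 2] == 0))
  expect_equal(rep$cycles$level, c(2, 2))  # density 10 sits in band 2
  expect_equal(rep$cycles$pir, c(0, 0))
})

test_that("noiseless geometric growth yields closed-form DIR and CIR", {
  cs <- make_count_series(count_series_spec(14, 1, 2.0, 0))
  rep <- analyze_counts(cs)
  d2 <- rep$daily[rep$daily$cycle == 2, ]
  expect_equal(d2$dir, rep(100, 7))
  expect_equal(d2$cir, rep((2^7 - 1) * 100, 7))
  expect_true(all(d2$color == "red"))  # CIR 12700% exceeds 300%
})

test_that("the first red day matches the geometric crossing day", {
  # counts 10*2^d: IR = (2^d - 1)*100 crosses 300% first at d = 3 (day 4)
  cs <- make_count_series(count_series_spec(7, 10, 2.0, 0))
  rep <- analyze_counts(cs)
  expect_equal(rep$daily$color, c("none", "blue", "orange", rep("red", 4)))
  expect_equal(min(which(rep$daily$color == "red")), 4)
})

test_that("a 7-day series reports IR only, never DIR or CIR", {
  cs <- make_count_series(count_series_spec(7, 5, 1.3, 0))
  rep <- analyze_counts(cs)
  expect_true(all(!is.na(rep$daily$ir)))
  expect_true(all(is.na(rep$daily$dir)))
  expect_true(all(is.na(rep$daily$cir)))
})

test_that("CIR on a linear ramp matches hand arithmetic", {
  cs <- data.frame(date = as.Date("2019-08-03") + 0:8,
                   count = 10 + 2 * (0:8))
  rep <- analyze_counts(cs)
  # day 8 count 24 vs day 1 count 10
  expect_equal(rep$daily$cir[8], (24 - 10) / 10 * 100)
  expect_equal(rep$daily$dir[9], (26 - 24) / 24 * 100)
})

test_that("per-cycle density, PIR and level are assembled correctly", {
  cs <- make_count_series(count_series_spec(14, 4, 1.2, 0))
  rep <- analyze_counts(cs)
  c1 <- rep$cycles[1, ]; c2 <- rep$cycles[2, ]
  counts <- cs$count
  expect_equal(c1$density, mean(counts[1:7]))
  expect_equal(c2$pir,
               (sum(counts[8:14]) - sum(counts[1:7])) / sum(counts[1:7]) * 100)
  expect_equal(c2$level,
               as.integer(grade_outbreak(mean(counts[8:14]), c2$pir)))
})

test_that("gapped or negative series are rejected", {
  bad <- data.frame(date = as.Date("2020-01-01") + c(0, 1, 3),
                    count = c(1, 2, 3))
  expect_error(analyze_counts(bad), "no gaps")
  neg <- data.frame(date = as.Date("2020-01-01") + 0:1, count = c(1, -2))
  expect_error(analyze_counts(neg), "non-negative")
})

test_that("warning reports serialize to JSON", {
  rep <- analyze_counts(make_count_series(count_series_spec(10, 5, 1.5, 0)))
  f <- tempfile(fileext = ".json")
  write_warning_report(rep, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$cardinal, 5)
  expect_length(back$daily, 10)
})
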