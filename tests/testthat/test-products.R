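test_that("exceedance probability is the strict member fraction", {
  expect_equal(exceedance_probability(rep(30, 51), 27), 1)
  expect_equal(exceedance_probability(rep(20, 51), 27), 0)
  members <- c(rep(28, 17), rep(26, 34))       # 17 of 51 above
  expect_equal(exceedance_probability(members, 27), 17 / 51)
  # ties at the threshold do not count
  expect_equal(exceedance_probability(c(27, 27, 28), 27), 1 / 3)
  # raising the threshold never raises the probability
  set.seed(12)
  members <- rnorm(200, 26, 3)
  thr <- seq(15, 35, by = 0.5)
  p <- vapply(thr, function(t) exceedance_probability(members, t), 0)
  expect_true(all(diff(p) <= 0))
  expect_error(exceedance_probability(numeric(0), 27), "empty")
})

test_that("weekly product takes the maximum daily probability per week", {
  # constructed member table: one station, Monday init 2018-06-04
  init <- as.Date("2018-06-04")
  days <- init + 1:34
  n_m <- 10
  wbgt <- rep(20, length(days) * n_m)
  fc <- data.frame(station_id = "S1",
                   valid_date = rep(days, each = n_m),
                   member = rep(1:n_m, length(days)),
                   wbgt_sun = wbgt)
  # spike one day in week 2: 9 of 10 members above 27
  spike_day <- init + 7 + 3
  fc$wbgt_sun[fc$valid_date == spike_day] <- c(rep(30, 9), rep(20, 1))
  out <- weekly_exceedance(fc, init, threshold = 27)
  expect_equal(nrow(out), 4)                   # four upcoming weeks
  expect_equal(out$week, 1:4)
  expect_equal(out$probability, c(0, 0.9, 0, 0))
  expect_true(all(weekdays(out$week_start) == weekdays(init)))  # Mondays
  expect_equal(as.numeric(out$week_end - out$week_start), rep(6, 4))
  # weeks are disjoint and consecutive
  expect_equal(out$week_start[-1], out$week_end[-4] + 1)
  # weekly max >= every constituent daily probability, equal to one of them
  daily <- vapply(split(fc$wbgt_sun, fc$valid_date),
                  function(m) mean(m > 27), 0)
  for (w in 1:4) {
    in_week <- days >= out$week_start[w] & days <= out$week_end[w]
    expect_gte(out$probability[w], max(daily[in_week]) - 1e-12)
    expect_true(out$probability[w] %in% daily[in_week])
  }
  # a constant daily probability is passed through unchanged
  fc2 <- fc; fc2$wbgt_sun <- rep(c(30, 20), length.out = nrow(fc2))
  out2 <- weekly_exceedance(fc2, init, threshold = 27)
  expect_equal(out2$probability, rep(0.5, 4))
})

test_that("week anchoring drops partial leading days", {
  # Thursday init: the four weeks start the following Monday
  init <- as.Date("2018-06-07")
  days <- init + 1:32
  fc <- data.frame(station_id = "S1", valid_date = rep(days, each = 3),
                   member = rep(1:3, length(days)), wbgt_sun = 30)
  # make the pre-Monday days the only hot ones: they must not count
  fc$wbgt_sun[fc$valid_date < as.Date("2018-06-11")] <- 35
  fc$wbgt_sun[fc$valid_date >= as.Date("2018-06-11")] <- 20
  out <- weekly_exceedance(fc, init, threshold = 27)
  expect_equal(out$week_start[1], as.Date("2018-06-11"))
  expect_equal(out$probability, rep(0, 4))
})

test_that("short-term risk assesses five dated days and flags alerts", {
  fx <- small_system()
  init <- as.Date("2018-06-04")
  days <- init + 1:5
  n_m <- 15
  cool <- data.frame(station_id = "ST0001",
                     valid_date = rep(days, each = n_m),
                     member = rep(1:n_m, 5),
                     wbgt_sun = 15, wbgt_shade = 13)
  p <- worker_profile(1.75, 70, "moderate", "sun", station_id = "ST0001")
  st <- short_term_risk(p, cool, init)
  expect_equal(nrow(st$assessments), 5)
  expect_equal(st$assessments$date, days)
  expect_true(all(st$assessments$band == "not_significant"))
  expect_null(st$alert)

  # one moderate day triggers the alert
  warm <- cool
  lim <- ral(p$mr)
  warm$wbgt_sun[warm$valid_date == days[3]] <- lim + 0.5
  st2 <- short_term_risk(p, warm, init)
  expect_false(is.null(st2$alert))
  expect_equal(st2$alert$dates, days[3])
  expect_equal(st2$alert$worst_band, "moderate")
  expect_match(st2$alert$message, "moderate")
  # switching to shade cannot increase the risk on paired values
  p_sh <- worker_profile(1.75, 70, "moderate", "shade",
                         station_id = "ST0001")
  st_sh <- short_term_risk(p_sh, warm, init)
  expect_true(all(st_sh$assessments$risk_pct <= st2$assessments$risk_pct))
  expect_error(short_term_risk(p, cool, init + 30), "cover")
})

test_that("long-term calendar covers lead days 6 to 46", {
  init <- as.Date("2018-06-04")
  days <- init + 1:46
  n_m <- 7
  fc <- data.frame(station_id = "ST0001",
                   valid_date = rep(days, each = n_m),
                   member = rep(1:n_m, length(days)),
                   wbgt_sun = 20, wbgt_shade = 18)
  p <- worker_profile(1.75, 70, "moderate", "sun", station_id = "ST0001")
  cal <- long_term_calendar(p, fc, init)
  expect_equal(nrow(cal), 41)
  expect_equal(cal$lead, 6:46)
  expect_equal(cal$date, init + 6:46)
  expect_identical(cal, long_term_calendar(p, fc, init))  # pure
  # hotter ensemble: no band decreases
  fc_hot <- fc; fc_hot$wbgt_sun <- fc$wbgt_sun + 5
  cal_hot <- long_term_calendar(p, fc_hot, init)
  rank <- function(b) match(b, c("not_significant", "low", "moderate",
                                 "high"))
  expect_true(all(rank(cal_hot$band) >= rank(cal$band)))
})

test_that("alert rule agrees with brute force over all 5-day band patterns", {
  bands <- c("not_significant", "low", "moderate", "high")
  grid <- expand.grid(b1 = bands, b2 = bands, b3 = bands, b4 = bands,
                      b5 = bands, stringsAsFactors = FALSE)
  expect_equal(nrow(grid), 1024)
  d0 <- as.Date("2018-06-01")
  for (i in seq_len(nrow(grid))) {
    combo <- unlist(grid[i, ], use.names = FALSE)
    assessments <- data.frame(date = d0 + 1:5, band = combo)
    got <- alert_check(assessments)
    should_fire <- any(combo %in% c("moderate", "high"))  # oracle
    expect_equal(!is.null(got), should_fire)
    if (should_fire) {
      expect_equal(got$worst_band, bands[max(match(combo, bands))])
      expect_equal(got$dates,
                   (d0 + 1:5)[combo %in% c("moderate", "high")])
    }
  }
})

test_that("nearest station minimizes distance with an altitude penalty", {
  net <- data.frame(id = c("A", "B", "C"),
                    lat = c(46.0, 46.0, 47.0),
                    lon = c(8.0, 8.2, 8.0),
                    altitude = c(300, 1800, 320))
  # querying a station's own location returns it
  expect_equal(nearest_station(46.0, 8.0, 300, net), "A")
  # two equidistant stations: the altitude match wins
  net2 <- data.frame(id = c("A", "B"),
                     lat = c(46.0, 46.2), lon = c(8.0, 8.0),
                     altitude = c(1500, 200))
  expect_equal(nearest_station(46.1, 8.0, 250, net2), "B")
  expect_equal(nearest_station(46.1, 8.0, 1450, net2), "A")
  # exact tie: deterministic break by station id
  net3 <- data.frame(id = c("B", "A"), lat = c(46.0, 46.2),
                     lon = c(8.0, 8.0), altitude = c(500, 500))
  expect_equal(nearest_station(46.1, 8.0, 500, net3), "A")
  expect_error(nearest_station(46, 8, 0, net3[0, ]), "empty")
})
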