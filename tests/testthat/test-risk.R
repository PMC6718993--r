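# The published band table (WBGT boundaries, degC) at the four reference
# metabolic rates: low 180 W, moderate 300 W, high 415 W, very high 520 W.
# Rows: the 80% boundary (upper edge of "not significant" / lower edge of
# "low"), the 100% boundary (start of "moderate") and the 120% boundary
# (start of "high"), for the unacclimatized (RAL) and acclimatized (REL)
# limits.
published_boundaries <- list(
  RAL = rbind(`80`  = c(L = 22.5, M = 20.0, H = 18.5, VH = 17.5),
              `100` = c(L = 28.5, M = 25.0, H = 23.0, VH = 22.0),
              `120` = c(L = 33.5, M = 29.5, H = 27.5, VH = 25.5)),
  REL = rbind(`80`  = c(L = 25.0, M = 23.0, H = 21.5, VH = 20.5),
              `100` = c(L = 31.0, M = 28.5, H = 27.0, VH = 25.5),
              `120` = c(L = 36.5, M = 33.5, H = 31.5, VH = 30.5))
)
reference_mr <- c(L = 180, M = 300, H = 415, VH = 520)

# cells whose printed value agrees exactly with nearest-0.5 rounding of the
# formula; the remainder reflect non-uniform hand-rounding in the published
# table and are held to +-0.5 degC
consistent_cells <- rbind(
  data.frame(limit = "RAL", pct = 80,  cls = c("L", "M", "H", "VH")),
  data.frame(limit = "RAL", pct = 100, cls = c("M", "H")),
  data.frame(limit = "RAL", pct = 120, cls = c("L", "H")),
  data.frame(limit = "REL", pct = 80,  cls = c("H", "VH")),
  data.frame(limit = "REL", pct = 100, cls = c("L", "VH")),
  data.frame(limit = "REL", pct = 120, cls = "VH")
)

test_that("body surface area follows the Du Bois power law", {
  expect_equal(body_surface_area(70, 1.75), 1.848, tolerance = 1e-3)
  expect_gt(body_surface_area(80, 1.75), body_surface_area(70, 1.75))
  expect_gt(body_surface_area(70, 1.85), body_surface_area(70, 1.75))
  expect_equal(body_surface_area(120, 2.2) / body_surface_area(60, 1.1),
               2^(0.425 + 0.725))
  expect_error(body_surface_area(10, 1.75), "weight")
  expect_error(body_surface_area(70, 3.0), "height")
})

test_that("metabolic rate scales with surface area and activity class", {
  expect_equal(metabolic_rate(1.8, 2), 180)
  expect_equal(metabolic_rate(1.8, 1), 90)
  expect_equal(metabolic_rate(2.0, 3), 2 * metabolic_rate(1.0, 3))
  expect_error(metabolic_rate(1.8, 6), "iso_level")
})

test_that("exposure limits match the NIOSH formulas and cross at 17 W", {
  expect_equal(ral(180), 28.09, tolerance = 0.01)
  expect_equal(ral(300), 24.97, tolerance = 0.01)
  expect_equal(ral(100), 59.9 - 28.2)
  expect_equal(rel(180), 30.76, tolerance = 0.01)
  expect_equal(rel(100), 56.7 - 23.0)
  # crossover: 59.9 - 14.1 x = 56.7 - 11.5 x at x = log10(mr) = 3.2/2.6
  mr_cross <- 10^(3.2 / 2.6)
  expect_equal(ral(mr_cross), rel(mr_cross))
  expect_equal(mr_cross, 17.0, tolerance = 0.05)
  expect_gt(rel(17.1), ral(17.1))
  mrs <- c(50, 100, 200, 400, 800)
  gap <- rel(mrs) - ral(mrs)
  expect_true(all(gap > 0))
  expect_true(all(diff(gap) > 0))  # widens with log10(mr)
  expect_error(ral(0), "positive")
  expect_error(rel(-5), "positive")
})

test_that("risk level and banding follow the percentage rule", {
  expect_equal(risk_level(25, 25), 100)
  expect_equal(risk_level(20, 25), 80)
  lim <- ral(300)
  expect_equal(risk_level(lim, lim), 100)
  expect_equal(classify_risk(risk_level(lim, lim)), "moderate")
  # boundaries: <=80 not significant, (80,100) low, [100,120) moderate,
  # >=120 high
  expect_equal(classify_risk(c(0, 80, 80.001, 99.999, 100, 119.999, 120, 150)),
               c("not_significant", "not_significant", "low", "low",
                 "moderate", "moderate", "high", "high"))
  expect_error(risk_level(25, 0), "positive")
  expect_error(classify_risk(-1), ">= 0")
})

test_that("band boundaries reconstruct the published table", {
  for (lim in c("RAL", "REL")) {
    for (pct in c(80, 100, 120)) {
      for (cls in c("L", "M", "H", "VH")) {
        printed <- published_boundaries[[lim]][as.character(pct), cls]
        mr <- reference_mr[[cls]]
        exact <- (pct / 100) * (if (lim == "RAL") ral(mr) else rel(mr))
        reconstructed <- table1_boundary(mr, lim, pct)
        # every printed cell is within half a degree of the exact formula
        expect_lt(abs(exact - printed), 0.5,
                  label = sprintf("|exact - printed| for %s %d%% %s",
                                  lim, pct, cls))
        is_consistent <- any(consistent_cells$limit == lim &
                               consistent_cells$pct == pct &
                               consistent_cells$cls == cls)
        if (is_consistent) {
          expect_equal(reconstructed, unname(printed),
                       label = sprintf("reconstructed %s %d%% %s",
                                       lim, pct, cls))
        } else {
          expect_lte(abs(reconstructed - printed), 0.5)
        }
      }
    }
  }
  expect_error(table1_boundary(180, "RAL", 90), "boundary_pct")
})

test_that("clothing adjustment shifts WBGT additively and monotonically", {
  cav <- default_cav_table()
  expect_equal(effective_wbgt(28, "conventional"), 28)
  expect_equal(effective_wbgt(28, "double_layer"), 31)
  expect_error(effective_wbgt(28, "chain_mail"), "unknown clothing")
  # a larger CAV never lowers the band
  lim <- ral(300)
  bands <- vapply(names(sort(cav)), function(k) {
    classify_risk(max(risk_level(effective_wbgt(24, k, cav), lim), 0))
  }, "")
  ranks <- match(bands, c("not_significant", "low", "moderate", "high"))
  expect_true(all(diff(ranks) >= 0))
})

test_that("recommendations escalate with the band", {
  r_ns <- recommendations("not_significant", 3)
  expect_equal(r_ns$break_code, 1)
  expect_match(r_ns$advisory, "No special precautions")
  r_hi <- recommendations("high", 3)
  expect_equal(r_hi$break_code, 4)
  expect_equal(r_hi$hydration_code, 3)
  expect_match(r_hi$advisory, "1 L/h")
  for (lev in 1:5) {
    codes <- vapply(c("not_significant", "low", "moderate", "high"),
                    function(b) recommendations(b, lev)$break_code, 0L)
    expect_true(all(diff(codes) > 0))
    drops <- vapply(c("not_significant", "low", "moderate", "high"),
                    function(b) recommendations(b, lev)$hydration_code, 0L)
    expect_true(all(diff(drops) >= 0))
  }
  # hydration depends on the metabolic class as well
  expect_lt(recommendations("not_significant", 2)$hydration_code,
            recommendations("not_significant", 4)$hydration_code)
})

test_that("acclimatization flips after exactly five qualifying days", {
  p <- worker_profile(1.75, 70, "moderate", "sun")
  expect_false(p$acclimatized)
  lim_ral <- ral(p$mr)
  hot <- lim_ral + 1            # degenerate ensemble in the moderate band
  d0 <- as.Date("2018-06-01")
  for (i in 1:4) {
    a <- assess_day(p, hot, d0 + i)
    expect_equal(a$limit_type, "RAL")
    expect_gte(a$risk_pct, 100)
    p <- update_acclimatization(p, a)
  }
  expect_false(p$acclimatized)  # four qualifying days are not enough
  a5 <- assess_day(p, hot, d0 + 5)
  p <- update_acclimatization(p, a5)
  expect_true(p$acclimatized)   # fifth day flips the state
  a6 <- assess_day(p, hot, d0 + 6)
  expect_equal(a6$limit_type, "REL")
  # REL > RAL: identical WBGT now carries less risk
  expect_lt(a6$risk_pct, a5$risk_pct)
})

test_that("non-qualifying days never advance the counter; order enforced", {
  p <- worker_profile(1.75, 70, "moderate", "sun")
  cool <- 0.5 * ral(p$mr)
  d0 <- as.Date("2018-06-01")
  for (i in 1:4) {
    p <- update_acclimatization(p, assess_day(p, ral(p$mr) + 1, d0 + i))
  }
  for (i in 5:10) {
    p <- update_acclimatization(p, assess_day(p, cool, d0 + i))
  }
  expect_false(p$acclimatized)
  expect_equal(p$exposure_days, 4L)
  # qualifying days need not be consecutive
  p <- update_acclimatization(p, assess_day(p, ral(p$mr) + 1, d0 + 11))
  expect_true(p$acclimatized)
  # a long gap without qualifying days resets the season
  p <- update_acclimatization(p, assess_day(p, cool, d0 + 50))
  expect_false(p$acclimatized)
  expect_equal(p$exposure_days, 0L)
  # out-of-order processing is an error
  expect_error(update_acclimatization(p, assess_day(p, cool, d0)),
               "date order")
})

test_that("assess_day collapses the ensemble and applies the full chain", {
  p <- worker_profile(1.80, 80, "high", "sun", clothing_key = "double_layer")
  members <- rep(24, 21)
  a <- assess_day(p, members, as.Date("2018-07-01"))
  expect_equal(a$wbgt_raw, 24)              # degenerate ensemble
  expect_equal(a$cav, 3)
  expect_equal(a$wbgt_eff, 27)
  expect_equal(a$limit, ral(p$mr))
  expect_equal(a$risk_pct, 100 * 27 / ral(p$mr))
  expect_equal(a$band, classify_risk(a$risk_pct))
  # risk-averse collapse quantile sits above the median
  p75 <- worker_profile(1.80, 80, "high", "sun",
                        clothing_key = "double_layer",
                        collapse_quantile = 0.75)
  spread <- 24 + seq(-2, 2, length.out = 21)
  expect_gt(assess_day(p75, spread)$wbgt_raw,
            assess_day(p, spread)$wbgt_raw)
  # degenerate ensemble at 1.2 x RAL lands exactly in the high band
  a_hi <- assess_day(worker_profile(1.80, 80, "high", "sun"),
                     rep(1.2 * ral(p$mr), 5))
  expect_equal(a_hi$band, "high")
  expect_error(assess_day(p, numeric(0)), "empty ensemble")
})
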