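test_that("cutoff rule assigns the printed levels, boundaries included", {
  lv <- function(st) as.character(classifyStLevel(st))
  expect_equal(lv(0.25), "e2")
  expect_equal(lv(-0.15), "s1")
  expect_equal(lv(0.0), "IE")
  # boundary inclusions exactly as the inequalities read
  expect_equal(lv(c(0.1, -0.1, 0.2, -0.2)), c("e1", "s1", "e1", "s2"))
  expect_error(classifyStLevel(NaN), "finite")
  expect_error(classifyStLevel(Inf), "finite")
})

test_that("the five intervals partition the line and are monotone in st", {
  grid <- sort(c(seq(-0.5, 0.5, by = 0.001),
                 -0.2, -0.1, 0.1, 0.2))
  lev <- classifyStLevel(grid)
  expect_false(anyNA(lev))
  expect_true(all(as.character(lev) %in% stLevels()))
  ords <- stLevelOrdinal(lev)
  expect_true(all(diff(ords) >= 0))              # non-decreasing in st
  expect_setequal(unique(as.character(lev)), stLevels())
})

test_that("tone map rows match the published tuples, symmetric in |ordinal|", {
  tm <- toneMap(sonifyConfig())
  expect_equal(tm$semitone, c(-8, -5, 0, 4, 7))
  expect_equal(tm$duration_ms, c(100, 80, 50, 80, 100))
  expect_equal(tm$harmonics, c(3, 3, 1, 3, 3))
  expect_equal(tm$level_db, c(15, 5, 0, 5, 15))

  ie <- mapToneParams("IE")
  expect_equal(unlist(ie[, c("semitone", "duration_ms", "harmonics",
                             "level_db")], use.names = FALSE),
               c(0, 50, 1, 0))
  e2 <- mapToneParams("e2")
  expect_equal(unlist(e2[, c("semitone", "duration_ms", "harmonics",
                             "level_db")], use.names = FALSE),
               c(7, 100, 3, 15))
  s2 <- mapToneParams("s2")
  expect_equal(unlist(s2[, c("semitone", "duration_ms", "harmonics",
                             "level_db")], use.names = FALSE),
               c(-8, 100, 3, 15))

  # duration/harmonics/level depend only on |ordinal|; pitch is strictly
  # increasing in ordinal
  for (col in c("duration_ms", "harmonics", "level_db")) {
    expect_equal(tm[[col]][tm$ordinal == -2], tm[[col]][tm$ordinal == 2])
    expect_equal(tm[[col]][tm$ordinal == -1], tm[[col]][tm$ordinal == 1])
  }
  expect_true(all(diff(tm$semitone) > 0))
})

test_that("scan scheduling follows the 8-beat period with the 2-beat L2 lag", {
  beats <- data.frame(index = 0:19, r_time = (0:19) * 0.75)
  s <- scheduleScans(beats)
  expect_equal(s$trigger_index[s$set == "L1"], c(0, 8, 16))
  expect_equal(s$trigger_index[s$set == "L2"], c(2, 10, 18))

  one <- scheduleScans(data.frame(index = 0L, r_time = 0.5))
  expect_equal(one$set, "L1")
  expect_equal(nrow(one), 1)

  beats80 <- data.frame(index = 0:79, r_time = (0:79) * 0.75)
  s80 <- scheduleScans(beats80)
  l1 <- s80[s80$set == "L1", ]
  expect_equal(l1$trigger_time, seq(0, by = 6, length.out = nrow(l1)))
  # consecutive L1 triggers exactly scan_period_beats apart; every L2
  # exactly l2_offset_beats after an L1
  expect_true(all(diff(l1$trigger_index) == 8))
  l2 <- s80[s80$set == "L2", ]
  expect_true(all((l2$trigger_index - 2) %in% l1$trigger_index))

  expect_equal(nrow(scheduleScans(beats[0, ])), 0)
})

test_that("a built scan resolves six tones at 120 ms spacing", {
  trig <- list(index = 0L, r_time = 2)
  sc <- buildScan("L1", trig, rep(0, 6))
  expect_equal(nrow(sc), 6)
  expect_equal(sc$lead, c("aVL", "I", "negAVR", "II", "aVF", "III"))
  expect_true(all(sc$level == "IE"))
  expect_true(all(sc$freq_hz == 554))
  expect_true(all(sc$duration_ms == 50))
  expect_true(all(sc$harmonics == 1))
  expect_true(all(sc$level_db == 0))
  expect_equal(sc$onset, 2 + (0:5) * 0.12)
  expect_equal(sc$onset[6] - sc$onset[1], 0.600)

  sc2 <- buildScan("L2", trig, c(rep(0.3, 4), 0, 0))
  expect_equal(sc2$level, c(rep("e2", 4), "IE", "IE"))
  expect_equal(sc2$semitone, c(rep(7, 4), 0, 0))
  expect_equal(sc2$duration_ms, c(rep(100, 4), 50, 50))
  expect_equal(sc2$harmonics, c(rep(3, 4), 1, 1))
  expect_equal(sc2$level_db, c(rep(15, 4), 0, 0))

  expect_error(buildScan("L1", trig, rep(0, 5)), "exactly 6")
  expect_error(buildScan("L2", trig,
                         data.frame(lead = "V1", st = 0)), "missing")
})

test_that("classify+map composition matches a brute-force oracle", {
  set.seed(42)
  cfg <- sonifyConfig()
  for (i in 1:1000) {
    st <- round(stats::runif(6, -0.5, 0.5), 4)
    set <- if (i %% 2) "L1" else "L2"
    got <- buildScan(set, list(index = i, r_time = i * 0.7), st, cfg)
    want <- oracleScan(set, i * 0.7, st)
    expect_identical(got$level, want$level)
    expect_identical(got$lead, want$lead)
    expect_equal(got$onset, want$onset)
    expect_equal(got$semitone, want$semitone)
    expect_equal(got$freq_hz, want$freq_hz)
    expect_equal(got$duration_ms, want$duration_ms)
    expect_equal(got$harmonics, want$harmonics)
    expect_equal(got$level_db, want$level_db)
  }
})
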