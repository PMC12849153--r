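test_that("delimited-table reader enforces leads, units and sampling", {
  sig <- matrix(rnorm(2500 * 12, sd = 0.1), ncol = 12,
                dimnames = list(NULL, ecgLeads()))
  rec <- EcgRecording(sig, samplingRate = 250)

  # headerless table + explicit rate
  p1 <- withr::local_tempfile(fileext = ".csv")
  writeEcg(rec, p1, timeColumn = FALSE)
  r1 <- readEcg(p1)   # sidecar written alongside
  expect_equal(duration(r1), 10)
  expect_equal(samplingRate(r1), 250)
  expect_equal(r1@signals, rec@signals, tolerance = 1e-8)

  # time_s column carries the rate
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeEcg(rec, p2, timeColumn = TRUE)
  r2 <- readEcg(p2)
  expect_equal(samplingRate(r2), 250, tolerance = 1e-6)

  # missing lead errors by name
  tab <- utils::read.csv(p2)
  tab$V3 <- NULL
  p3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab, p3, row.names = FALSE)
  expect_error(readEcg(p3), "V3")

  # no rate available at all
  p4 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(sig), p4, row.names = FALSE)
  expect_error(readEcg(p4), "sampling rate")

  # non-uniform time axis
  tab2 <- utils::read.csv(p2)
  tab2$time_s[10] <- tab2$time_s[10] + 0.001
  p5 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab2, p5, row.names = FALSE)
  expect_error(readEcg(p5), "non-uniform|non-increasing")
})

test_that("waveform-record write/read round-trips generator output", {
  out <- generateScenario(scenarioSpec("anterior_stemi", "moderate",
                                       total_duration = 6,
                                       transition_time = 2, seed = 7))
  dir <- withr::local_tempdir()
  hea <- writeEcg(out$recording, file.path(dir, "rec01"), format = "record")
  back <- readEcg(hea)
  expect_equal(samplingRate(back), samplingRate(out$recording))
  expect_equal(leadNames(back), leadNames(out$recording))
  # format quantization: gain 1000 adu/mV -> half-step 0.0005 mV
  expect_lt(max(abs(back@signals - out$recording@signals)), 5.1e-4)
  expect_error(readEcg(file.path(dir, "nope.hea")), "not found")
})

test_that("negAVR is the sample-wise inversion of aVR, an involution", {
  out <- generateScenario(scenarioSpec("normal", total_duration = 5))
  rec <- out$recording
  neg <- deriveNegAVR(rec)
  expect_identical(neg, -rec@signals[, "aVR"])
  expect_identical(-neg, rec@signals[, "aVR"])  # involution, exact
  expect_identical(leadSignal(rec, "negAVR"), neg)

  zero <- rec
  zero@signals[, "aVR"] <- 0
  expect_true(all(deriveNegAVR(zero) == 0))
})

test_that("beat detection recovers the synthetic beat train", {
  out <- generateScenario(scenarioSpec("normal", total_duration = 60,
                                       heart_rate = 80))
  beats <- detectBeats(out$recording)
  truth <- out$truth$beats
  # 60 s at 80 bpm: within one beat of 80 (edges trimmed by the template)
  expect_gte(nrow(beats), 78)
  expect_lte(nrow(beats), 81)
  expect_equal(nrow(beats), nrow(truth))
  expect_true(all(diff(beats$r_time) > 0))
  expect_lt(max(abs(beats$r_time - truth$r_time)), 0.050)

  flat <- EcgRecording(matrix(0, 2500, 12,
                              dimnames = list(NULL, ecgLeads())), 250)
  expect_warning(b0 <- detectBeats(flat), "no QRS")
  expect_equal(nrow(b0), 0)

  # supplied annotations bypass detection
  ann <- detectBeats(out$recording, annotations = truth$r_time)
  expect_equal(ann$r_time, truth$r_time)
})

test_that("ST measurement is baseline-referenced, shift-invariant and linear", {
  # spike-only beats: baseline equals ST level exactly
  rec <- spikeRecording(c(1, 2, 3), fs = 500, dur = 4)
  beats <- data.frame(index = 0:2, r_time = c(1, 2, 3))
  m <- measureSt(rec, beats)
  expect_lt(max(abs(m$st)), 1e-6)

  # constant baseline shift leaves st unchanged (to 1e-9)
  shifted <- rec
  shifted@signals <- shifted@signals + 0.5
  m2 <- measureSt(shifted, beats)
  expect_lt(max(abs(m2$st - m$st)), 1e-9)

  # linear recovery of injected offsets on the noiseless template
  offsets <- seq(-0.4, 0.4, by = 0.1)
  est <- vapply(offsets, function(off) {
    out <- generateScenario(
      scenarioSpec("normal", total_duration = 8, transition_time = 0),
      st_offsets = c(V2 = off))
    mm <- measureSt(out$recording, out$truth$beats, leads = "V2")
    mean(mm$st)
  }, numeric(1))
  expect_lt(max(abs(est - offsets)), 0.02)
  slope <- unname(stats::coef(stats::lm(est ~ offsets))[2])
  expect_equal(slope, 1, tolerance = 0.05)

  # window outside the record errors
  expect_error(measureSt(rec, data.frame(index = 0L, r_time = 0.05)),
               "outside")
})
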