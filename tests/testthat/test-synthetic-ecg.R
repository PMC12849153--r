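test_that("ST profiles encode the infarct patterns", {
  expect_true(all(stProfile("normal") == 0))

  ant <- stProfile("anterior_stemi", "severe")
  expect_equal(unname(ant[c("V1", "V2", "V3", "V4")]), rep(0.40, 4))
  expect_true(all(ant[setdiff(names(ant), paste0("V", 1:4))] == 0))
  expect_true(all(classifyStLevel(ant[paste0("V", 1:4)]) == "e2"))

  inf <- stProfile("inferior_stemi", "moderate")
  expect_true(all(inf[c("II", "III", "aVF")] == 0.25))
  expect_true(all(inf[c("I", "aVL")] < 0))          # reciprocal depression
  expect_equal(unname(inf["aVL"]), -0.6 * 0.25)

  # severity grading maps onto the intended levels
  expect_true(all(classifyStLevel(
    stProfile("anterior_stemi", "weak")[paste0("V", 1:4)]) == "e1"))
  expect_true(all(classifyStLevel(
    stProfile("inferior_stemi", "severe")[c("II", "III", "aVF")]) == "e2"))
})

test_that("noiseless scenarios recover injected offsets and levels exactly", {
  cases <- rbind(
    expand.grid(pattern = c("anterior_stemi", "inferior_stemi"),
                severity = c("weak", "moderate", "severe"),
                stringsAsFactors = FALSE),
    data.frame(pattern = "normal", severity = "moderate"))
  for (i in seq_len(nrow(cases))) {
    spec <- scenarioSpec(cases$pattern[i], cases$severity[i],
                         total_duration = 10, transition_time = 0)
    out <- generateScenario(spec)
    m <- measureSt(out$recording, out$truth$beats, leads = ecgLeads())
    truthSt <- out$truth$st_after[m$lead]
    expect_lt(max(abs(m$st - truthSt)), 0.02)
    expect_identical(as.character(classifyStLevel(m$st)),
                     as.character(classifyStLevel(truthSt)))
  }
})

test_that("no beat before the transition carries an offset", {
  spec <- scenarioSpec("anterior_stemi", "severe", total_duration = 40,
                       transition_time = 20)
  out <- generateScenario(spec)
  m <- measureSt(out$recording, out$truth$beats, leads = "V2")
  pre <- m$st[m$r_time < 20]
  post <- m$st[m$r_time >= 20]
  expect_lt(max(abs(pre)), 0.02)
  expect_equal(mean(post), 0.40, tolerance = 0.05)
  expect_true(all(abs(post - 0.40) < 0.02))

  # transition at 0: elevated from the first beat
  out0 <- generateScenario(scenarioSpec("anterior_stemi", "severe",
                                        total_duration = 10,
                                        transition_time = 0))
  m0 <- measureSt(out0$recording, out0$truth$beats, leads = "V3")
  expect_true(all(m0$st > 0.2))
})

test_that("generation is reproducible for a fixed seed", {
  spec <- scenarioSpec("inferior_stemi", "moderate", total_duration = 8,
                       transition_time = 4, noise_sd = 0.05, seed = 11L)
  a <- generateScenario(spec)
  b <- generateScenario(spec)
  expect_identical(a$recording@signals, b$recording@signals)
  expect_identical(a$truth$beats, b$truth$beats)

  c <- generateScenario(scenarioSpec("inferior_stemi", "moderate",
                                     total_duration = 8,
                                     transition_time = 4,
                                     noise_sd = 0.05, seed = 12L))
  expect_false(identical(a$recording@signals, c$recording@signals))
})

test_that("classification stays reliable under measurement noise", {
  # >= 200 beats with 0.02 mV noise: >= 95% per-beat level agreement on
  # the affected leads, moderate and severe severity
  for (sev in c("moderate", "severe")) {
    spec <- scenarioSpec("anterior_stemi", sev, total_duration = 160,
                         transition_time = 0, noise_sd = 0.02, seed = 3L)
    out <- generateScenario(spec)
    expect_gte(nrow(out$truth$beats), 200)
    m <- measureSt(out$recording, out$truth$beats,
                   leads = c("V1", "V2", "V3", "V4"))
    truthLev <- as.character(classifyStLevel(out$truth$st_after[m$lead]))
    gotLev <- as.character(classifyStLevel(m$st))
    expect_gte(mean(gotLev == truthLev), 0.95)
  }
})

test_that("scenario audio flips from isoelectric to elevated scans", {
  cfg <- sonifyConfig()
  res <- endToEndScenarioAudio(
    scenarioSpec("anterior_stemi", "severe", total_duration = 40,
                 transition_time = 20), cfg)
  pre <- res$tones[res$tones$trigger_time < 20, ]
  expect_true(all(pre$level == "IE"))
  expect_true(all(pre$freq_hz == cfg$f0))

  postL2 <- res$tones[res$tones$trigger_time >= 20 & res$tones$set == "L2", ]
  firstL2 <- postL2[postL2$trigger_time == min(postL2$trigger_time), ]
  expect_equal(firstL2$level[1:4], rep("e2", 4))   # V1-V4 slots
  expect_equal(firstL2$freq_hz[1:4], rep(toneFreq(cfg$f0, 7), 4))
  expect_true(all(firstL2$level[5:6] == "IE"))

  # normal scenario: every scan tone at the reference pitch
  resN <- endToEndScenarioAudio(
    scenarioSpec("normal", total_duration = 20, transition_time = 0), cfg)
  expect_true(all(resN$tones$freq_hz == cfg$f0))
})
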