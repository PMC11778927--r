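test_that("deviant duration ladder follows the power law with half-up rounding", {
  d <- oddball_design()
  expect_identical(deviant_duration(d, 0:4), c(300, 357, 425, 506, 602))
  # the conventional printed stimulus set flattens the top level to 600
  expect_identical(deviant_duration(d, 0:3), printed_ladder()[1:4])
  expect_false(deviant_duration(d, 4) == printed_ladder()[5])
  expect_error(deviant_duration(d, 7), "not in design levels")
})

test_that("deviant duration is strictly increasing in n for any lambda > 1", {
  for (lambda in c(1.01, 1.05, 1.19, 1.5, 2)) {
    d <- oddball_design(lambda = lambda, levels_n = 0:6)
    expect_true(all(diff(deviant_duration(d, 0:6)) > 0),
                info = paste("lambda =", lambda))
  }
})

test_that("analysis windows are validated and windowed rates use [start, end)", {
  expect_error(analysis_window("sound_onset", 100, 100), "strictly greater")
  w <- analysis_window("sound_onset", 0, 100)
  expect_equal(windowed_rate(c(0.01, 0.02, 0.05, 0.07, 0.09), 0, w), 50)
  expect_equal(windowed_rate(numeric(), 0, w), 0)
  # spike on the start edge counts, spike on the end edge does not
  expect_equal(windowed_rate(c(0, 0.1), 0, w), 10)
  # vectorised over anchors
  expect_equal(windowed_rate(c(0.05, 1.05), c(0, 1), w), c(10, 10))
})

test_that("outcome labels are a pure function of level and choice", {
  expect_identical(
    outcome_label(c(0, 0, 2, 2), c("no_press", "press", "press", "no_press")),
    c("correct_rejection", "false_alarm", "hit", "miss"))
})

test_that("session JSON round-trip is lossless and deterministic", {
  s <- tiny_oddball(seed = 11)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_session(s, p1)
  s2 <- read_session(p1)
  expect_identical(s2$spike_times, s$spike_times)
  expect_equal(s2$blocks, s$blocks)
  expect_equal(s2$events, s$events)
  expect_equal(unclass(s2$design), unclass(s$design))
  expect_identical(s2$meta$schema, "icdyn-session/1")
  # writing twice, and writing what was read, give byte-identical files
  write_session(s2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))

  r <- suppressWarnings(simulate_reward_session(seed = 5))
  write_session(r, p1)
  r2 <- read_session(p1)
  expect_identical(r2$spike_times, r$spike_times)
  expect_equal(r2$trials, r$trials)
})

test_that("unknown top-level keys survive a round-trip", {
  s <- tiny_oddball(seed = 3)
  p <- withr::local_tempfile(fileext = ".json")
  write_session(s, p)
  txt <- readLines(p, warn = FALSE)
  txt <- sub("^\\{", "{\"lab_notes\":\"probe P3, depth 4.2mm\",", txt)
  writeLines(txt, p)
  s2 <- read_session(p)
  expect_identical(s2$extra$lab_notes, "probe P3, depth 4.2mm")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_session(s2, p2)
  expect_match(paste(readLines(p2, warn = FALSE), collapse = ""), "lab_notes")
})

test_that("validation rejects inconsistent sessions, naming the field", {
  s <- tiny_oddball(seed = 4)

  bad <- s
  bad$spike_times <- rev(bad$spike_times)
  expect_error(validate_session(bad), "`times`")

  bad <- s
  i <- which(bad$blocks$choice == "no_press")[1]
  bad$blocks$press_time_s[i] <- 1.23
  expect_error(validate_session(bad), "press_time_s")

  bad <- s
  i <- which(bad$blocks$outcome == "hit")[1]
  if (!is.na(i)) {
    bad$blocks$outcome[i] <- "miss"
    expect_error(validate_session(bad), "outcome|reward_time_s")
  }

  bad <- s
  bad$spike_times <- c(-1, bad$spike_times)
  expect_error(validate_session(bad), "nonnegative")
})

test_that("write refuses invalid sessions; read reports bad files", {
  s <- tiny_oddball(seed = 4)
  s$blocks$press_time_s[which(s$blocks$choice == "no_press")[1]] <- 0.5
  p <- withr::local_tempfile(fileext = ".json")
  expect_error(write_session(s, p), "validation failed")
  expect_error(read_session(file.path(tempdir(), "nope-missing.json")), "no such file")
  writeLines("{not json", p)
  expect_error(read_session(p), "malformed")
})

test_that("duplicate spike times are flagged but accepted", {
  s <- tiny_oddball(seed = 4)
  s$spike_times <- sort(c(s$spike_times, s$spike_times[5]))
  expect_warning(validate_session(s), "duplicate")
})
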