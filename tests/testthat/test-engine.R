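test_that("withdrawal start is the first frame of the first long-enough run", {
  expect_identical(detect_withdrawal_start(rep("normal", 10), 5), NA_integer_)
  labs <- c(rep("normal", 3), rep("ileocecal", 5), rep("normal", 4))
  expect_identical(detect_withdrawal_start(labs, 5), 3L)
  expect_identical(detect_withdrawal_start(labs, 5), scan_start(labs, 5))
  # an interrupted run does not trigger; the next full run does
  labs2 <- c(rep("ileocecal", 4), "normal", rep("ileocecal", 5))
  expect_identical(detect_withdrawal_start(labs2, 5), 5L)
  expect_identical(detect_withdrawal_start(labs2, 5), scan_start(labs2, 5))
  expect_identical(detect_withdrawal_start(character(0), 5), NA_integer_)
  # property: agrees with the exhaustive scan oracle on random streams
  set.seed(42)
  for (i in 1:25) {
    labs <- sample(c("ileocecal", "normal", "instrument"), 40, TRUE,
                   prob = c(0.4, 0.4, 0.2))
    k <- sample(1:6, 1)
    expect_identical(detect_withdrawal_start(labs, k), scan_start(labs, k))
  }
})

test_that("bucket assignment is disjoint with instrument priority over blur", {
  expect_identical(assign_bucket("instrument", TRUE, TRUE), "time1")
  expect_identical(assign_bucket("normal", TRUE, TRUE), "time2")
  expect_identical(assign_bucket("normal", FALSE, TRUE), "effective")
  expect_identical(assign_bucket("ileocecal", FALSE, TRUE), "effective")
  expect_identical(assign_bucket("ileocecal", FALSE, FALSE), "pre_withdrawal")
  expect_identical(assign_bucket("instrument", FALSE, FALSE), "pre_withdrawal")
})

test_that("engine recovers a hand-computable timing decomposition", {
  # 100 frames at 10 fps, withdrawal from frame 0, 20 instrument frames,
  # 10 blurred mucosa frames -> WT 10 s, Time1 2 s, Time2 1 s, EWT 7 s
  spec <- scenario_spec(data.frame(
    kind = c("ileocecal", "effective", "instrument", "effective", "blurred"),
    duration = c(20, 25, 20, 25, 10)), fps = 10, seed = 5)
  sc <- generate_scenario(spec)
  res <- run_engine(sc$frames, stub_classifier(sc$sidecar),
                    engine_config(fps = 10))
  s <- res$summary
  expect_identical(s$start_frame, 0L)
  expect_equal(s$wt_s, 10.0)
  expect_equal(s$time1_s, 2.0)
  expect_equal(s$time2_s, 1.0)
  expect_equal(s$ewt_s, 7.0)
  # cross-check by summing the generator's truth records
  tl <- sc$timeline
  expect_equal(s$time1_frames, sum(tl$label == "instrument"))
  expect_equal(s$time2_frames, sum(tl$blurred & tl$label != "instrument"))
})

test_that("a stream without an ileocecal run yields zero timers", {
  spec <- scenario_spec(data.frame(kind = c("ileocecal", "effective"),
                                   duration = c(8, 30)), fps = 10, seed = 2)
  sc <- generate_scenario(spec)
  # relabel the ileocecal frames so no run exists downstream
  sidecar <- sc$sidecar
  sidecar$label[sidecar$label == "ileocecal"] <- "normal"
  res <- run_engine(sc$frames, stub_classifier(sidecar), engine_config(fps = 10))
  expect_true(is.na(res$summary$start_frame))
  expect_equal(res$summary$wt_frames, 0)
  expect_equal(res$summary$ewt_s, 0)
  expect_true(all(res$observations$bucket == "pre_withdrawal"))
})

test_that("conservation holds and no frame is counted twice", {
  sc <- cached_scenario()
  res <- run_engine(sc$frames, stub_classifier(sc$sidecar),
                    engine_config(fps = sc$spec$fps))
  s <- res$summary
  expect_identical(s$wt_frames, s$ewt_frames + s$time1_frames + s$time2_frames)
  expect_equal(s$wt_s, s$ewt_s + s$time1_s + s$time2_s)
  # re-sum per-frame buckets against the summary
  b <- table(factor(res$observations$bucket,
                    c("pre_withdrawal", "effective", "time1", "time2")))
  expect_equal(unname(b[["effective"]]), s$ewt_frames)
  expect_equal(unname(b[["time1"]]), s$time1_frames)
  expect_equal(unname(b[["time2"]]), s$time2_frames)
  expect_equal(sum(b), s$frames_total)
})

test_that("engine output is deterministic", {
  sc <- generate_scenario(random_scenario_spec(3))
  cfg <- engine_config(fps = 10)
  r1 <- run_engine(sc$frames, stub_classifier(sc$sidecar), cfg)
  r2 <- run_engine(sc$frames, stub_classifier(sc$sidecar), cfg)
  expect_identical(r1$observations, r2$observations)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_frame_log(r1$observations, f1); write_frame_log(r2$observations, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("adding instrument frames never increases EWT", {
  base <- data.frame(kind = c("ileocecal", "effective"),
                     duration = c(10, 60))
  ewt <- vapply(c(0, 10, 30), function(extra) {
    segs <- if (extra > 0)
      rbind(base, data.frame(kind = "instrument", duration = extra))
    else base
    sc <- generate_scenario(scenario_spec(segs, fps = 10, seed = 9))
    run_engine(sc$frames, stub_classifier(sc$sidecar),
               engine_config(fps = 10))$summary$ewt_frames
  }, numeric(1))
  expect_true(all(diff(ewt) <= 0))
})

test_that("zone occupancy counts processed frames minus the first", {
  sc <- cached_scenario()
  res <- run_engine(sc$frames, stub_classifier(sc$sidecar),
                    engine_config(fps = 10))
  expect_equal(sum(res$summary$zone_occupancy), length(sc$frames) - 1)
  expect_true(is.na(res$observations$hash_dist[1]))
  # a static video sits entirely in the normal zone at distance 0
  static <- rep(list(sc$frames[[1]]), 12)
  sidecar <- data.frame(frame_index = 0:11, label = "normal", confidence = 1)
  rs <- run_engine(static, stub_classifier(sidecar), engine_config(fps = 10))
  expect_true(all(rs$observations$hash_dist[-1] == 0))
  expect_equal(unname(rs$summary$zone_occupancy["normal"]), 11)
  # empty observations give empty occupancy
  expect_equal(sum(summarize_zones(rs$observations[0, ])), 0)
})

test_that("frame stride scales the time accounting", {
  sc <- generate_scenario(scenario_spec(
    data.frame(kind = c("ileocecal", "effective"), duration = c(20, 80)),
    fps = 10, seed = 4))
  full <- run_engine(sc$frames, stub_classifier(sc$sidecar),
                     engine_config(fps = 10))
  strided <- run_engine(sc$frames, stub_classifier(sc$sidecar),
                        engine_config(fps = 10, frame_stride = 2L))
  expect_equal(nrow(strided$observations), 50)
  expect_equal(strided$summary$wt_s, full$summary$wt_s, tolerance = 0.05)
})

test_that("an unconfigured frame rate falls back to 25 fps with a warning", {
  sc <- cached_scenario()
  few <- sc$frames[1:12]
  sidecar <- sc$sidecar[1:12, ]
  expect_warning(res <- run_engine(few, stub_classifier(sidecar),
                                   engine_config()),
                 "25 fps")
  expect_equal(res$summary$fps, 25)
})
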