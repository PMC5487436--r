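test_that("streams sort stably by timestamp and validate geometry", {
  ev <- data.frame(t = c(5, 0, 5, 2), x = c(1, 0, 2, 3), y = c(0, 0, 0, 0),
                   sign = c(1, -1, 1, 1))
  s <- event_stream(ev, 8, 8)
  expect_equal(s$t, c(0, 2, 5, 5))
  # ties keep input order: the x=1 event precedes the x=2 event at t=5
  expect_equal(s$x, c(0, 3, 1, 2))
  expect_equal(ev_duration(s), 5)
  expect_error(event_stream(data.frame(t = 0, x = 8, y = 0, sign = 1), 8, 8),
               class = "spikehist_validation_error")
  expect_error(event_stream(data.frame(t = -1, x = 0, y = 0, sign = 1), 8, 8),
               class = "spikehist_validation_error")
  expect_error(event_stream(data.frame(t = 0, x = 0, y = 0, sign = 2), 8, 8),
               class = "spikehist_validation_error")
})

test_that("ev-csv round-trips losslessly, including empty and signed streams", {
  path <- withr::local_tempfile(fileext = ".csv")
  ev <- data.frame(t = c(0, 5), x = c(1, 0), y = c(2, 0), sign = c(1, -1))
  s <- event_stream(ev, 32, 32)
  write_events(s, path)
  r <- read_events(path)
  expect_equal(as.data.frame(r), as.data.frame(s))
  expect_equal(ev_geometry(r), c(width = 32L, height = 32L))
  expect_gte(ev_duration(r), 5)
  expect_equal(r$sign, c(1, -1))

  empty <- event_stream(NULL, 32, 32)
  write_events(empty, path)
  r2 <- read_events(path)
  expect_equal(nrow(r2), 0L)
  expect_equal(ev_geometry(r2), c(width = 32L, height = 32L))

  set.seed(71)
  big <- random_stream(1000, 16, t_max = 5000)
  write_events(big, path)
  r3 <- read_events(path)
  expect_identical(as.data.frame(r3), as.data.frame(big))
  expect_identical(ev_duration(r3), ev_duration(big))

  # annotated streams keep their sample windows
  ann <- event_stream(ev, 32, 32, samples = tibble::tibble(
    label = c(0L, 1L), t_start = c(0, 3), t_end = c(3, 6)))
  write_events(ann, path)
  expect_equal(ev_samples(read_events(path)), ev_samples(ann))
})

test_that("malformed ev-csv input is rejected with a located parse error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# width=8 height=8 duration_us=10", "t_us,x,y,sign",
               "0,1,1,1", "3,oops,1,1"), path)
  expect_error(read_events(path), "line 4", class = "spikehist_parse_error")
  writeLines(c("t_us,x,y,sign", "0,1,1,1"), path)
  expect_error(read_events(path), class = "spikehist_parse_error")
  writeLines(c("# width=8 height=8 duration_us=10", "t_us,x,y,sign",
               "0,9,1,1"), path)
  expect_error(read_events(path), class = "spikehist_validation_error")
  expect_error(read_events(file.path(tempdir(), "nope.csv")),
               class = "spikehist_io_error")
})

test_that("binary event dialects decode the documented layouts", {
  # N-MNIST 5-byte records: x, y, pol<<7 | t[22:16], t[15:8], t[7:0]
  path <- withr::local_tempfile(fileext = ".bin")
  rec <- function(x, y, pol, t) {
    as.raw(c(x, y, bitwOr(bitwShiftL(pol, 7), bitwShiftR(t, 16)),
             bitwAnd(bitwShiftR(t, 8), 255), bitwAnd(t, 255)))
  }
  writeBin(c(rec(3, 7, 1, 1000), rec(20, 5, 0, 70000)), path)
  s <- read_events(path, "nmnist-bin")
  expect_equal(s$t, c(1000, 70000))
  expect_equal(s$x, c(3, 20))
  expect_equal(s$y, c(7, 5))
  expect_equal(s$sign, c(1, -1))
  expect_equal(read_events(path, "nmnist-bin", rectify = TRUE)$sign, c(1, 1))

  # AEDAT 8-byte records: 32-bit address (pol bit 0, x bits 1-7, y bits
  # 8-14), then 32-bit timestamp, big-endian
  path2 <- withr::local_tempfile(fileext = ".aedat")
  rec2 <- function(x, y, pol, t) {
    addr <- bitwOr(pol, bitwOr(bitwShiftL(x, 1), bitwShiftL(y, 8)))
    as.raw(c(bitwShiftR(addr, 24), bitwAnd(bitwShiftR(addr, 16), 255),
             bitwAnd(bitwShiftR(addr, 8), 255), bitwAnd(addr, 255),
             bitwShiftR(t, 24), bitwAnd(bitwShiftR(t, 16), 255),
             bitwAnd(bitwShiftR(t, 8), 255), bitwAnd(t, 255)))
  }
  con <- file(path2, "wb")
  writeLines("#!AER-DAT1.0", con)
  writeBin(c(rec2(100, 42, 0, 5), rec2(1, 2, 1, 123456)), con)
  close(con)
  s2 <- read_events(path2, "aedat")
  expect_equal(s2$x, c(100, 1))
  expect_equal(s2$y, c(42, 2))
  expect_equal(s2$sign, c(-1, 1))
  expect_equal(s2$t, c(5, 123456))
})

test_that("slicing produces consecutive re-timed windows and flags partials", {
  # 300 ms split into 100 ms slots -> 3 slices
  set.seed(3)
  s <- event_stream(tibble::tibble(t = sort(runif(60, 0, 299999)),
                                   x = 0, y = 0, sign = 1),
                    4, 4, duration_us = 3e5)
  sl <- slice_stream(s, 1e5)
  expect_equal(nrow(sl), 3L)
  expect_true(all(purrr::map_dbl(sl$stream, ev_duration) == 1e5))
  expect_false(any(purrr::map_lgl(sl$stream, attr, "partial")))

  # slice longer than the stream -> single slice equal to the stream
  one <- slice_stream(s, 1e6)
  expect_equal(nrow(one), 1L)
  expect_equal(nrow(one$stream[[1L]]), nrow(s))
  expect_true(attr(one$stream[[1L]], "partial"))

  # uniform 1 event/ms over 10 ms, 2 ms slices -> 5 slices of 2 events
  u <- event_stream(tibble::tibble(t = seq(0, 9000, by = 1000),
                                   x = 0, y = 0, sign = 1)[1:10, ],
                    4, 4, duration_us = 1e4)
  sl2 <- slice_stream(u, 2000)
  expect_equal(nrow(sl2), 5L)
  expect_equal(purrr::map_int(sl2$stream, nrow), rep(2L, 5))
  # each slice re-timed to start at 0
  expect_equal(sl2$stream[[3L]]$t, c(0, 1000))
})

test_that("concatenation offsets samples and de-concatenation recovers them", {
  mk <- function(seed) {
    set.seed(seed)
    random_stream(20, 8, t_max = 255)
  }
  ss <- sample_set(list(mk(1), mk(2)), c(0L, 1L))
  op <- concat_streams(ss, gap_us = 1000)
  ann <- ev_samples(op)
  expect_equal(ann$t_start[2L], ev_duration(ss$stream[[1L]]) + 1000)
  # gap 0: total duration is the sum of durations
  op0 <- concat_streams(ss, gap_us = 0)
  expect_equal(ev_duration(op0),
               sum(purrr::map_dbl(ss$stream, ev_duration)))

  # round trip through boundaries for 10 random samples
  set.seed(99)
  ss10 <- sample_set(lapply(1:10, function(i) random_stream(30, 8, 500)),
                     rep(0:4, 2))
  back <- split_op_stream(concat_streams(ss10, gap_us = 777))
  expect_equal(back$label, ss10$label)
  for (i in 1:10) {
    expect_identical(as.data.frame(back$stream[[i]]),
                     as.data.frame(ss10$stream[[i]]))
  }
})

test_that("slice then concat with gap 0 reconstructs the event multiset", {
  set.seed(17)
  s <- event_stream(tibble::tibble(t = sort(sample(0:9999, 200, TRUE)),
                                   x = sample(0:7, 200, TRUE),
                                   y = sample(0:7, 200, TRUE),
                                   sign = sample(c(-1, 1), 200, TRUE)),
                    8, 8, duration_us = 1e4)
  rebuilt <- concat_streams(slice_stream(s, 2500), gap_us = 0)
  expect_equal(nrow(rebuilt), nrow(s))
  key <- function(x) sort(paste(x$t, x$x, x$y, x$sign))
  expect_equal(key(rebuilt), key(s))
})

test_that("geometry mismatches in sample sets are rejected", {
  a <- event_stream(NULL, 8, 8)
  b <- event_stream(NULL, 16, 16)
  expect_error(sample_set(list(a, b), c(0L, 1L)),
               class = "spikehist_validation_error")
  expect_error(sample_set(list(a), 2L, class_count = 2L),
               class = "spikehist_validation_error")
})
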