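test_that("rr_from_beats differences consecutive beat times", {
  expect_identical(rr_from_beats(numeric(0)), numeric(0))
  expect_identical(rr_from_beats(0.0), numeric(0))
  expect_equal(rr_from_beats(c(0, 1, 2, 3)), c(1, 1, 1))
  expect_equal(rr_from_beats(c(100, 300, 550) / 250), c(0.8, 1.0))
  expect_error(rr_from_beats(c(1, 1, 2)), "increasing")
})

test_that("episodes respect rhythm segment boundaries", {
  # one AF segment covering 40 beats -> one episode of 39 intervals
  bs <- beat_series("a", 1, 0:39,
                    data.frame(start = 0, end = 39, label = "(AFIB"))
  eps <- episodes_from_segments(bs)
  expect_length(eps, 1)
  expect_identical(eps[[1]]$class, "AF")
  expect_length(eps[[1]]$intervals, 39)

  # AFIB then N: the interval spanning the boundary is dropped
  bs2 <- beat_series("b", 1, 0:11,
                     data.frame(start = c(0, 6), end = c(6, 12),
                                label = c("(AFIB", "(N")))
  eps2 <- episodes_from_segments(bs2)
  expect_length(eps2, 2)
  expect_identical(vapply(eps2, `[[`, "", "class"), c("AF", "non-AF"))
  expect_identical(lengths(lapply(eps2, `[[`, "intervals")), c(5L, 5L))

  # atrial flutter is excluded under the AFDB map
  bs3 <- beat_series("c", 1, 0:9,
                     data.frame(start = 0, end = 9, label = "(AFL"))
  expect_length(episodes_from_segments(bs3, default_class_map("afdb")), 0)

  # unmapped labels are excluded with a warning
  bs4 <- beat_series("d", 1, 0:9,
                     data.frame(start = 0, end = 9, label = "(VT"))
  expect_warning(out <- episodes_from_segments(bs4, default_class_map("afdb")),
                 "unmapped")
  expect_length(out, 0)
})

test_that("episode intervals never exceed the available beat intervals", {
  set.seed(42)
  for (rep in 1:20) {
    nb <- sample(5:80, 1)
    times <- cumsum(runif(nb, 0.4, 1.2))
    cuts <- sort(sample(seq(min(times), max(times), length.out = 50),
                        sample(1:4, 1)))
    bounds <- c(min(times) - 0.1, cuts, max(times) + 0.1)
    segs <- data.frame(start = head(bounds, -1), end = bounds[-1],
                       label = sample(c("(AFIB", "(N"), length(bounds) - 1,
                                      replace = TRUE))
    bs <- beat_series("f", 1, round(times * 1000), segs)
    bs$beat_times <- times  # exact times for the conservation count
    eps <- episodes_from_segments(bs)
    expect_lte(sum(lengths(lapply(eps, `[[`, "intervals"))), nb - 1)
  }
})

test_that("windowize emits floor(n/W) complete windows and drops the rest", {
  expect_identical(nrow(windowize(runif(29, 0.5, 1))), 0L)
  w30 <- windowize(seq(0.5, by = 0.01, length.out = 30))
  expect_identical(nrow(w30), 1L)
  expect_equal(unname(unlist(w30[1, paste0("i", 1:30)])),
               seq(0.5, by = 0.01, length.out = 30))
  expect_identical(nrow(windowize(runif(95, 0.5, 1))), 3L)
  # fuzz the exact count over many episode lengths
  set.seed(1)
  for (n in sample(0:500, 60)) {
    expect_identical(nrow(windowize(runif(n, 0.5, 1))), n %/% 30L)
  }
})

test_that("balancing equalizes counts by removing from the larger class", {
  w <- toy_windows(5)                       # 5 / 5 already balanced
  expect_identical(balance_classes(w, seed = 3), w)

  w2 <- toy_windows(8)[-(1:3), ]            # 5 non-AF, 8 AF
  expect_identical(sum(w2$label == 1), 8L)
  key <- function(d) paste(d$record_id, d$window_index)
  for (seed in 1:5) {
    b <- balance_classes(w2, seed = seed)
    expect_identical(sum(b$label == 1), 5L)
    expect_identical(sum(b$label == 0), 5L)
    # all removals from the larger (AF) class: non-AF rows intact
    expect_equal(b[b$label == 0, ], w2[w2$label == 0, ],
                 ignore_attr = TRUE)
    # survivors keep their order
    expect_true(!is.unsorted(match(key(b), key(w2))))
    # idempotent
    expect_identical(balance_classes(b, seed = seed), b)
  }
  only_af <- w2[w2$label == 1, ]
  expect_error(balance_classes(only_af), "non-AF")
})

test_that("splitting hits the requested fraction and partitions the data", {
  w <- toy_windows(50)                      # 100 windows, 100 records
  sp <- split_dataset(w, fraction = 0.76, seed = 1, balance = FALSE)
  expect_identical(nrow(sp$train), 76L)
  expect_identical(nrow(sp$test), 24L)

  # 2 records, fraction 0.5 -> one whole record per side
  w2 <- toy_windows(2)
  w2$record_id <- rep(c("p1", "p2"), 2)
  sp2 <- split_dataset(w2, fraction = 0.5, seed = 9, balance = FALSE)
  expect_identical(length(unique(sp2$train$record_id)), 1L)
  expect_identical(length(unique(sp2$test$record_id)), 1L)

  # record-level split shares no record across sides, any seed
  w3 <- toy_windows(60)
  w3$record_id <- rep(sprintf("p%02d", 1:10), 12)
  for (seed in 1:100) {
    sp3 <- split_dataset(w3, seed = seed, balance = FALSE)
    expect_length(intersect(sp3$train$record_id, sp3$test$record_id), 0)
    expect_identical(nrow(sp3$train) + nrow(sp3$test), nrow(w3))
  }

  # window-level split partitions before balancing
  sp4 <- split_dataset(w, seed = 2, by_record = FALSE, balance = FALSE)
  key <- function(d) paste(d$record_id, d$window_index)
  expect_setequal(c(key(sp4$train), key(sp4$test)), key(w))
  expect_identical(nrow(sp4$train) + nrow(sp4$test), nrow(w))

  # balanced sides are 50/50
  sp5 <- split_dataset(w3, seed = 5)
  expect_identical(sum(sp5$train$label == 1), sum(sp5$train$label == 0))
  expect_identical(sum(sp5$test$label == 1), sum(sp5$test$label == 0))

  w_single <- toy_windows(2)
  w_single$record_id <- "same"
  expect_error(split_dataset(w_single, fraction = 0.5), "2 records")
})

test_that("series-to-windows wrapper stitches the pipeline together", {
  set.seed(8)
  times <- cumsum(runif(130, 0.6, 1.0))
  segs <- data.frame(start = c(0, times[66]), end = c(times[66], times[130]),
                     label = c("(AFIB", "(N"))
  bs <- beat_series("r1", 250, round(times * 250), segs)
  win <- windows_from_series(bs, W = 30)
  expect_true(all(win$label %in% c(0, 1)))
  expect_identical(nrow(win), 4L)   # 64 usable intervals per segment -> 2 + 2
  expect_true(all(windows_to_xy(win)$x > 0))
})
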