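test_that("roaming entropy matches its analytic values", {
  # uniform use of all antennae is maximal entropy
  expect_equal(roaming_entropy(rep(4, 10)), 1)
  # a single antenna all night is zero entropy
  expect_equal(roaming_entropy(c(7, 0, 0, 0)), 0)
  # two of four antennae equally: -2*(1/2 log 1/2)/log 4 = 1/2
  expect_equal(roaming_entropy(c(2, 2, 0, 0)), 0.5)
  # hand evaluation of a non-symmetric case
  p <- c(0.5, 0.25, 0.25)
  expect_equal(roaming_entropy(c(2, 1, 1)), -sum(p * log(p)) / log(3))
})

test_that("roaming entropy flags empty nights and rejects bad inputs", {
  expect_true(is.na(roaming_entropy(c(0, 0, 0))))
  expect_error(roaming_entropy(c(1), k = 1), "k >= 2")
  expect_error(roaming_entropy(c(1, 2), k = 3), "length")
  expect_error(roaming_entropy(c(-1, 2, 1)), "nonnegative")
})

test_that("RE is invariant to antenna relabeling and count scaling", {
  set.seed(301)
  for (i in 1:20) {
    counts <- rpois(12, 3)
    if (sum(counts) == 0) counts[1] <- 1
    base <- roaming_entropy(counts)
    expect_equal(roaming_entropy(sample(counts)), base)
    expect_equal(roaming_entropy(counts * 7L), base)
    expect_gte(base, 0); expect_lte(base, 1)
  }
})

test_that("dark-phase filter implements the midnight wrap rule", {
  ev <- data.frame(
    datetime = as.POSIXct(c("2020-03-01 12:00:00",   # midday: removed
                            "2020-03-01 23:30:00",   # evening: that date
                            "2020-03-02 02:00:00",   # after midnight: prev
                            "2020-03-02 06:00:00"),  # boundary: excluded
                          tz = "UTC"),
    antenna = "a1", mouse = "m1", stringsAsFactors = FALSE)
  out <- dark_phase_filter(ev)
  expect_equal(nrow(out), 2)
  expect_equal(out$night, as.Date(c("2020-03-01", "2020-03-01")))
  # non-wrapping window keeps simple clock logic
  out2 <- dark_phase_filter(ev, "01:00", "07:00")
  expect_equal(nrow(out2), 2)
  expect_equal(out2$night, as.Date(c("2020-03-02", "2020-03-02")))
  expect_error(dark_phase_filter(ev, "18:00", "18:00"), "positive length")
})

test_that("event parsing validates, sorts and applies the antenna policy", {
  topo <- cage_topology(4)
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("datetime,antenna,mouse",
               "2020-01-02T19:30:00,A002,m1",
               "2020-01-01T19:00:00,A001,m1",
               "2020-01-01T20:00:00,XXX,m2"), path)
  expect_warning(ev <- parse_events(path, topo), "outside the topology")
  expect_equal(nrow(ev), 3)
  expect_false(is.unsorted(ev$datetime))
  expect_warning(ev2 <- parse_events(path, topo, unknown_antennae = "drop"),
                 "outside")
  expect_equal(nrow(ev2), 2)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("datetime,antenna,mouse", "not-a-time,A001,m1"), bad)
  expect_error(parse_events(bad), "malformed timestamp at data line 1")
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("datetime,antenna,mouse", empty)
  expect_error(parse_events(empty), "empty")
})

test_that("block means tile the night range and handle missing nights", {
  re <- matrix(0.6, 2, 12, dimnames = list(c("m1", "m2"), NULL))
  bm <- block_means(re, block_length = 3, n_blocks = 4)
  expect_true(all(bm == 0.6))
  # one missing night: mean over the remaining nights of that block
  re[1, 2] <- NA
  re[1, 1] <- 0.9; re[1, 3] <- 0.3
  expect_equal(block_means(re, 3, 4)[1, 1], 0.6)
  # an all-missing block propagates NA
  re[2, 4:6] <- NA
  expect_true(is.na(block_means(re, 3, 4)[2, 2]))
  expect_error(block_means(re, 4, 4), "at least 16")
})

test_that("trajectory slopes equal the closed-form OLS slope", {
  bm <- rbind(const = c(0.5, 0.5, 0.5, 0.5),
              down = c(4, 3, 2, 1),
              up = c(0.1, 0.2, 0.3, 0.4))
  s <- trajectory_slopes(bm)
  expect_equal(s$slope, c(0, -1, 0.1))
  # linearity: slope(a*y + c) = a * slope(y)
  set.seed(11)
  y <- runif(4)
  s1 <- trajectory_slopes(rbind(a = y))$slope
  s2 <- trajectory_slopes(rbind(a = 3 * y + 10))$slope
  expect_equal(s2, 3 * s1)
  # fewer than two observed blocks is flagged
  expect_warning(s3 <- trajectory_slopes(rbind(a = c(0.2, NA, NA, NA))),
                 "NA")
  expect_true(is.na(s3$slope))
})

test_that("silhouette analysis finds two well-separated trajectory groups", {
  set.seed(5)
  blobs <- rbind(matrix(rnorm(40, 0, 0.02), 10),
                 matrix(rnorm(40, 1, 0.02), 10))
  rownames(blobs) <- paste0("m", 1:20)
  res <- choose_k_clusters(blobs, k_range = 2:5, seed = 2)
  expect_equal(res$best_k, 2)
  expect_true(all(res$silhouette["2"] >= res$silhouette))
  # k_range of a single value returns it
  expect_equal(choose_k_clusters(blobs, k_range = 2, seed = 2)$best_k, 2)
  # identical rows are degenerate
  same <- matrix(0.4, 6, 4, dimnames = list(paste0("m", 1:6), NULL))
  expect_error(choose_k_clusters(same, seed = 1), "identical")
  expect_error(choose_k_clusters(blobs[1:2, , drop = FALSE], seed = 1),
               "at least 3")
})

test_that("threshold stratification reproduces the study's worked example", {
  # 38 slopes placed in the reported ranges: 15 down, 2 intermediate,
  # 15 flat, 6 positive
  set.seed(77)
  slopes <- data.frame(
    mouse_id = sprintf("m%02d", 1:38),
    slope = c(seq(-0.049, -0.008, length.out = 15),
              c(-0.0055, -0.0045),
              seq(-0.003, 0.004, length.out = 15),
              seq(0.007, 0.016, length.out = 6)))
  st <- stratify_slopes(slopes, group_size = 15, mode = "threshold")
  counts <- table(st$label)
  expect_equal(unname(counts["down"]), 15L)
  expect_equal(unname(counts["flat"]), 15L)
  expect_equal(unname(counts["excluded_intermediate"]), 2L)
  expect_equal(unname(counts["excluded_positive"]), 6L)
  # boundary behaviour matches the reported ranges
  expect_equal(st$label[st$slope == -0.049], "down")
  lone <- stratify_slopes(
    data.frame(mouse_id = sprintf("m%02d", 1:30),
               slope = c(-0.02, 0, seq(-0.049, -0.006, length.out = 14),
                         seq(-0.003, 0.004, length.out = 14))),
    group_size = 15, mode = "threshold")
  expect_equal(lone$label[lone$slope == -0.02], "down")
  expect_equal(lone$label[lone$slope == 0], "flat")
})

test_that("stratification labels partition the mice in both modes", {
  set.seed(13)
  for (mode in c("threshold", "rank")) {
    slopes <- data.frame(mouse_id = sprintf("m%02d", 1:38),
                         slope = runif(38, -0.05, 0.02))
    st <- suppressWarnings(stratify_slopes(slopes, group_size = 15,
                                           mode = mode))
    expect_equal(nrow(st), 38)
    expect_false(any(is.na(st$label)))
    if (mode == "rank") {
      expect_equal(sum(st$label == "down"), 15)
      expect_equal(sum(st$label == "flat"), 15)
      # rank mode takes the most negative slopes as down
      expect_true(max(st$slope[st$label == "down"]) <=
                    min(st$slope[st$label != "down"]))
    }
  }
  expect_error(stratify_slopes(data.frame(mouse_id = "a", slope = 1),
                               group_size = 15), "at least 30")
})
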