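test_that("edge/middle partition counts are exact", {
  p8 <- partitionEdgeMiddle(8, 8)
  expect_equal(c(nrow(p8$edge), nrow(p8$middle)), c(48L, 16L))
  p5 <- partitionEdgeMiddle(5, 5)
  expect_equal(c(nrow(p5$edge), nrow(p5$middle)), c(24L, 1L))
  expect_equal(unlist(p5$middle), c(row = 3L, col = 3L))
  # 384-format: inner block is (16-4) x (24-4) = 240, edge is the rest
  p384 <- partitionEdgeMiddle(16, 24)
  expect_equal(c(nrow(p384$edge), nrow(p384$middle)), c(144L, 240L))
  expect_error(partitionEdgeMiddle(4, 10), class = "pemscreen_config_error")
})

test_that("uniform plates are left unchanged and uniform edge boost cancels", {
  flat <- makePlateScreen(rep(7, 64), 8, 8)
  out <- normalizePlates(flat)
  expect_equal(measurements(out$screen)$size_normalized, rep(7, 64))

  g <- expand.grid(col = 1:8, row = 1:8)
  edge <- g$row <= 2 | g$row > 6 | g$col <= 2 | g$col > 6
  boosted <- makePlateScreen(ifelse(edge, 130, 100), 8, 8)
  out2 <- normalizePlates(boosted)
  expect_equal(measurements(out2$screen)$size_normalized, rep(100, 64))
  expect_equal(out2$report$edge_factor, 100 / 130)
  expect_equal(out2$report$target, 100)
})

test_that("plates are scaled to the median middle mean", {
  mk <- function(mid, id) makePlateScreen(rep(mid, 64), 8, 8, plate_id = id)
  screen <- bindScreens(mk(80, "p1"), mk(100, "p2"), mk(120, "p3"))
  out <- normalizePlates(screen)
  expect_equal(sort(out$report$plate_scale), sort(c(100 / 80, 1, 100 / 120)))
  m <- as.data.frame(measurements(out$screen))
  g <- expand.grid(col = 1:8, row = 1:8)
  for (p in unique(m$plate_id)) {
    mm <- m[m$plate_id == p, ]
    mid <- !(mm$row <= 2 | mm$row > 6 | mm$col <= 2 | mm$col > 6)
    expect_equal(mean(mm$size_normalized[mid]), 100, tolerance = 1e-12)
  }
})

test_that("normalization matches a hand calculation on a 5x5 plate", {
  # middle = position (3,3) only; put 50 there, edge spots all 200
  sizes <- rep(200, 25)
  sizes[2 * 5 + 3] <- 50  # row 3, col 3 in row-major (row-1)*5 + col
  screen <- makePlateScreen(sizes, 5, 5)
  out <- normalizePlates(screen)
  m <- as.data.frame(measurements(out$screen))
  # f = 50/200, edge -> 200 * 50/200 = 50; M = 50, g = 1
  expect_equal(m$size_normalized, rep(50, 25))
})

test_that("normalization is idempotent and scale-equivariant", {
  set.seed(42)
  for (i in 1:25) {
    rows <- sample(5:12, 1); cols <- sample(5:12, 1)
    n_plates <- sample(2:4, 1)
    screens <- lapply(seq_len(n_plates), function(p)
      makePlateScreen(rlnorm(rows * cols, log(100), 0.3), rows, cols,
                      plate_id = sprintf("p%d", p)))
    screen <- do.call(bindScreens, screens)
    out1 <- normalizePlates(screen)
    m1 <- as.data.frame(measurements(out1$screen))

    # every plate's post-normalization middle mean equals M
    M <- out1$report$target[1]
    for (p in unique(m1$plate_id)) {
      mm <- m1[m1$plate_id == p, ]
      mid <- !(mm$row <= 2 | mm$row > rows - 2 |
                 mm$col <= 2 | mm$col > cols - 2)
      expect_equal(mean(mm$size_normalized[mid]), M, tolerance = 1e-9)
    }

    # idempotence: renormalizing the normalized sizes changes nothing
    m2 <- m1; m2$size <- m2$size_normalized
    out2 <- normalizePlates(ColonyScreen(m2, rows, cols))
    expect_equal(measurements(out2$screen)$size_normalized,
                 m1$size_normalized, tolerance = 1e-9)
    expect_equal(out2$report$edge_factor, rep(1, n_plates),
                 tolerance = 1e-9)
    expect_equal(out2$report$plate_scale, rep(1, n_plates),
                 tolerance = 1e-9)

    # scale equivariance
    m3 <- as.data.frame(measurements(screen)); m3$size <- m3$size * 3.7
    out3 <- normalizePlates(ColonyScreen(m3, rows, cols))
    expect_equal(measurements(out3$screen)$size_normalized,
                 3.7 * m1$size_normalized, tolerance = 1e-9)
  }
})

test_that("middle spots are changed only by the plate-scale step", {
  set.seed(1)
  screen <- bindScreens(
    makePlateScreen(rlnorm(64, log(100), 0.2), 8, 8, plate_id = "p1"),
    makePlateScreen(rlnorm(64, log(90), 0.2), 8, 8, plate_id = "p2"))
  out <- normalizePlates(screen)
  m <- as.data.frame(measurements(out$screen))
  mid <- !(m$row <= 2 | m$row > 6 | m$col <= 2 | m$col > 6)
  scale <- out$report$plate_scale[match(m$plate_id, out$report$plate_id)]
  expect_equal(m$size_normalized[mid], (m$size * scale)[mid],
               tolerance = 1e-12)
})

test_that("all-zero-middle plates are excluded and flagged", {
  g <- expand.grid(col = 1:8, row = 1:8)
  edge <- g$row <= 2 | g$row > 6 | g$col <= 2 | g$col > 6
  dead <- makePlateScreen(ifelse(edge, 100, 0), 8, 8, plate_id = "dead")
  live <- makePlateScreen(rep(100, 64), 8, 8, plate_id = "live")
  out <- normalizePlates(bindScreens(dead, live))
  rep_dead <- out$report[out$report$plate_id == "dead", ]
  expect_true(rep_dead$excluded)
  expect_equal(out$report$target[1], 100)  # median over live plates only
  m <- as.data.frame(measurements(out$screen))
  expect_true(all(is.na(m$size_normalized[m$plate_id == "dead"])))
  expect_true(all(m$size_normalized[m$plate_id == "live"] == 100))
})

test_that("t-statistic normality QC summarizes and guards its input", {
  set.seed(11)
  qc <- qcTstatNormality(rnorm(1000))
  expect_lt(abs(qc$skewness), 0.2)
  expect_gt(qc$shapiro_p, 1e-4)
  expect_error(qcTstatNormality(rep(1, 30)), "zero variance")
  expect_error(qcTstatNormality(rnorm(19)),
               class = "pemscreen_insufficient_data")
})
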