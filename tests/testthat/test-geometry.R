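test_that("electrode distances are Euclidean and rigid-motion invariant", {
  g <- device_geometry(ppg_tip = c(0, 0, 0), ppg_ring = c(0, -18, 0),
                       icd_ring1 = c(0, 41 - 18, 0), icd_ring2 = c(24, 0, 0))
  d <- electrode_distances(g)
  expect_equal(d$d1_mm, 24)
  expect_equal(d$d2_mm, 41)
  same <- device_geometry(c(1, 1, 1), c(1, 1, 1), c(1, 1, 1), c(1, 1, 1))
  expect_equal(electrode_distances(same)$d1_mm, 0)
  # rotate the whole scene about z by 70 degrees and translate
  th <- 70 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  mv <- function(p) as.numeric(R %*% p + c(5, -3, 2))
  g2 <- device_geometry(mv(g$ppg_tip), mv(g$ppg_ring), mv(g$icd_ring1),
                        mv(g$icd_ring2))
  d2 <- electrode_distances(g2)
  expect_equal(d2$d1_mm, d$d1_mm, tolerance = 1e-10)
  expect_equal(d2$d2_mm, d$d2_mm, tolerance = 1e-10)
})

test_that("rotation poses reduce to their distance sums", {
  poses <- data.frame(d1 = c(18.17, 11.92, 7.36, 13.48),
                      d2 = c(26.64, 7.23, 12.79, 16.58),
                      sum = c(44.81, 19.15, 20.15, 30.06))
  for (i in 1:4) {
    g <- geometry_from_distances(poses$d1[i], poses$d2[i])
    dd <- electrode_distances(g)
    expect_equal(dd$d1_mm, poses$d1[i], tolerance = 1e-6)
    expect_equal(dd$d2_mm, poses$d2[i], tolerance = 1e-6)
    expect_equal(rotation_distance_sum(g), poses$sum[i], tolerance = 1e-6)
  }
})

test_that("collinear trade-off conserves the distance sum", {
  expect_equal(collinear_tradeoff(16, 21, 10), 27)
  expect_equal(collinear_tradeoff(16, 21, 16), 21)
  set.seed(3)
  for (i in 1:20) {
    a <- runif(1, 5, 60); b <- runif(1, 5, 60); d <- runif(1, -10, 10)
    expect_equal(collinear_tradeoff(a, b, a - d), b + d)
  }
})

test_that("volume-conductor amplitude decays with distance and obeys symmetry", {
  prog <- pacing_program(3, 0.24, 60)
  g0 <- geometry_from_distances(24, 41)
  # strictly decreasing as the pacemaker moves radially away
  dir <- c(1, 1, 0.5); dir <- dir / sqrt(sum(dir^2))
  amps <- vapply(seq(0, 50, by = 5), function(s) {
    g <- g0
    g$ppg_tip <- g$ppg_tip + s * dir
    g$ppg_ring <- g$ppg_ring + s * dir
    sensed_amplitude(g, prog)
  }, numeric(1))
  expect_true(all(diff(amps) < 0))
  # dipole symmetric about the bisector plane of the sensing pair reads zero
  gs <- device_geometry(ppg_tip = c(15, 30, 0), ppg_ring = c(15, 48, 0),
                        icd_ring1 = c(30, 0, 0), icd_ring2 = c(0, 0, 0))
  expect_lt(sensed_amplitude(gs, prog), 1e-10)
  # reciprocity: swapping source and sink leaves |amplitude| unchanged
  gr <- device_geometry(gs$ppg_ring, gs$ppg_tip, c(28, 3, 1), c(-2, 6, 0))
  gf <- device_geometry(gs$ppg_tip, gs$ppg_ring, c(28, 3, 1), c(-2, 6, 0))
  expect_equal(sensed_amplitude(gr, prog), sensed_amplitude(gf, prog),
               tolerance = 1e-12)
  # doubling the programmed output doubles the field
  expect_equal(sensed_amplitude(g0, pacing_program(6, 0.24, 60)),
               2 * sensed_amplitude(g0, prog), tolerance = 1e-12)
  expect_error(sensed_amplitude(
    device_geometry(c(0, 0, 0), c(18, 0, 0), c(30, 0, 0), c(0, 0, 0)),
    prog), "singularity")
})

test_that("sensed amplitude tracks the distance sum, not the rotation angle", {
  prog <- pacing_program(3, 0.24, 60)
  poses <- data.frame(d1 = c(18.17, 11.92, 7.36, 13.48),
                      d2 = c(26.64, 7.23, 12.79, 16.58))
  poses$sum <- poses$d1 + poses$d2
  amp <- vapply(seq_len(4), function(i)
    sensed_amplitude(geometry_from_distances(poses$d1[i], poses$d2[i]), prog),
    numeric(1))
  o <- order(poses$sum)
  expect_true(all(diff(amp[o]) < 0))
  # poses at a fixed distance sum vary far less than poses spanning the range
  cv <- function(x) stats::sd(x) / mean(x)
  fixed <- vapply(seq(0.3, 0.7, length.out = 12), function(f)
    sensed_amplitude(geometry_from_distances(30 * f, 30 * (1 - f)), prog),
    numeric(1))
  span <- vapply(seq(19.15, 44.81, length.out = 12), function(s)
    sensed_amplitude(geometry_from_distances(0.45 * s, 0.55 * s), prog),
    numeric(1))
  expect_lt(cv(fixed), cv(span))
})

test_that("the lead bipole senses more than ring-can vectors at distance", {
  prog <- pacing_program(3, 0.24, 60)
  set.seed(7)
  amps <- replicate(40, {
    d1 <- runif(1, 15, 60); d2 <- runif(1, 15, 60)
    g <- tryCatch(geometry_from_distances(d1, d2, can_offset_mm = 120),
                  error = function(e) NULL)
    if (is.null(g)) rep(NA_real_, 3)
    else c(sensed_amplitude(g, prog, vector = "ring1-ring2"),
           sensed_amplitude(g, prog, vector = "ring1-can"),
           sensed_amplitude(g, prog, vector = "ring2-can"))
  })
  med <- apply(amps, 1, stats::median, na.rm = TRUE)
  expect_gte(med[1], med[2])
  expect_gte(med[1], med[3])
})
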