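test_that("semi-log size curve interpolates markers and flags extrapolation", {
  std <- size_standard(size = c(1000, 100), migration = c(10, 20))
  curve <- fit_size_curve(std)
  mid <- size_at(curve, 15)
  expect_equal(mid$size, 10^2.5, tolerance = 1e-12)
  expect_false(mid$extrapolated)
  # knots are reproduced exactly
  expect_equal(size_at(curve, c(10, 20))$size, c(1000, 100),
               tolerance = 1e-12)
  out <- size_at(curve, 25)
  expect_equal(out$size, 10^1.5, tolerance = 1e-12)
  expect_true(out$extrapolated)
  # inverse direction
  expect_equal(migration_at(curve, 10^2.5)$migration, 15, tolerance = 1e-12)
  # non-monotone standards are rejected, naming the offenders
  expect_error(size_standard(c(100, 200, 300), c(20, 25, 22)),
               "not strictly monotone")
})

test_that("size curve is monotone over the marker range", {
  std <- size_standard(size = c(100, 250, 600, 1500),
                       migration = c(40, 30, 20, 10))
  curve <- fit_size_curve(std)
  q <- seq(10, 40, by = 0.25)
  s <- size_at(curve, q)$size
  expect_true(all(diff(s) < 0))  # larger migration -> smaller size
})

test_that("anchor calibration is exact at anchors, linear between, flagged outside", {
  a <- anchor_set(migration = c(10, 20), base = c(100, 110),
                  lane_kind = "sequencing_ladder")
  expect_equal(calibrate_bases(a, 15)$base, 105)
  expect_equal(calibrate_bases(a, 12)$base, 102)
  out <- calibrate_bases(a, 25)
  expect_equal(out$base, 115)
  expect_true(out$extrapolated)
  expect_equal(calibrate_bases(a, c(10, 20))$base, c(100, 110))
  expect_false(any(calibrate_bases(a, c(10, 20))$extrapolated))
  # monotone between anchors
  q <- seq(10, 20, by = 0.1)
  expect_true(all(diff(calibrate_bases(a, q)$base) > 0))
  expect_error(anchor_set(10, 100), "2 anchors")
})

test_that("Taq one-base correction applies only to primer-extension lanes", {
  expect_equal(apply_taq_correction(500, "primer_extension"), 499)
  expect_equal(apply_taq_correction(500, "sequencing_ladder"), 500)
  expect_equal(apply_taq_correction(500, "indirect_end_label"), 500)
  trp <- seq_map("TRP1ARS1", 1453)
  expect_equal(apply_taq_correction(1, "primer_extension", map = trp), 1453)
  # bijective on a circular map: +1 undoes it
  p <- 1:20
  expect_equal(wrap_pos(trp, apply_taq_correction(p, "primer_extension",
                                                  map = trp) + 1), p)
})

test_that("band detection finds well-separated Gaussian bands and nothing in flat traces", {
  x <- seq(0, 100, by = 0.2)
  y <- dnorm(x, 30, 2) + 0.8 * dnorm(x, 70, 2)
  b <- detect_bands(lane_trace(x, y), min_prominence = 0.1)
  expect_equal(nrow(b), 2)
  expect_true(all(abs(b$center - c(30, 70)) <= 0.2 + 1e-9))
  expect_true(all(b$prominence <= b$height))
  # flat trace -> empty, not an error
  expect_equal(nrow(detect_bands(lane_trace(x, rep(1, length(x))))), 0)
  # single bump with min_separation wider than the trace still yields one band
  y1 <- dnorm(x, 50, 2)
  expect_equal(nrow(detect_bands(lane_trace(x, y1), min_separation = 1000)),
               1)
  # thinning keeps the higher of two close peaks
  y2 <- dnorm(x, 50, 2) + 0.5 * dnorm(x, 53, 2)
  b2 <- detect_bands(lane_trace(x, y2), min_prominence = 0.01,
                     min_separation = 10)
  expect_equal(nrow(b2), 1)
  expect_lt(abs(b2$center - 50), 1)
})

test_that("band count matches generated bands across seeds (property)", {
  for (seed in 1:10) {
    set.seed(seed)
    k <- sample(2:5, 1)
    centers <- sort(10 + cumsum(runif(k, 15, 25)))
    heights <- runif(k, 0.5, 1)
    x <- seq(0, max(centers) + 15, by = 0.1)
    y <- Reduce(`+`, lapply(seq_len(k), function(i)
      heights[i] * dnorm(x, centers[i], 1.5)))
    b <- detect_bands(lane_trace(x, y), min_prominence = 0.2)
    expect_equal(nrow(b), k)
    expect_true(all(abs(b$center - centers) < 0.5))
  }
})

test_that("calibrated trace resampling recovers per-base intensities", {
  # forward model: base b migrates at x = 2 * b (linear), 20 samples/base
  map <- seq_map("toy", 500)
  bases <- 101:200
  truth <- 1 + abs(sin(bases / 7)) * 10
  x <- seq(2 * 100.5, 2 * 200.49, by = 0.1)
  b_of_x <- x / 2
  y <- approx(bases, truth, xout = b_of_x, rule = 2)$y
  anchors <- anchor_set(migration = c(2 * 110, 2 * 190),
                        base = c(110, 190),
                        lane_kind = "sequencing_ladder")
  grid <- trace_to_base_grid(lane_trace(x, y), anchors, map)
  got <- grid$intensity[match(bases, grid$position)]
  expect_gt(cor(got, truth), 0.99)
  # signal conservation up to binning: sum(values) * dx_per_base ~ integral
  integral <- sum((y[-1] + y[-length(y)]) / 2 * diff(x))
  per_base_width <- 2  # a.u. per base in this forward model
  expect_lt(abs(sum(grid$intensity) * per_base_width - integral) / integral,
            0.02)
  # constant trace -> constant per-base vector
  gflat <- trace_to_base_grid(lane_trace(x, rep(3, length(x))), anchors, map)
  expect_true(all(abs(gflat$intensity - 3) < 1e-12))
  # anchors outside the trace support are an error
  bad <- anchor_set(migration = c(1, 500), base = c(1, 250),
                    lane_kind = "sequencing_ladder")
  expect_error(trace_to_base_grid(lane_trace(x, y), bad, map),
               "outside the trace support")
})

test_that("primer-extension grids land one base below ladder grids", {
  map <- seq_map("toy", 500)
  x <- seq(100, 300, by = 0.1)
  y <- dnorm(x, 200, 1)
  mk <- function(kind) trace_to_base_grid(
    lane_trace(x, y),
    anchor_set(migration = c(120, 280), base = c(120, 280),
               lane_kind = kind),
    map)
  ladder <- mk("sequencing_ladder")
  pe <- mk("primer_extension")
  expect_equal(ladder$position[which.max(ladder$intensity)], 200)
  expect_equal(pe$position[which.max(pe$intensity)], 199)
})

test_that("gel-track correlation handles identity, negation and zero variance", {
  map <- seq_map("toy", 100)
  v <- c(numeric(40), 1:20, numeric(40))
  tr <- stranded_track(map, "cleavage", plus = v)
  grid <- data.frame(position = 1:100, intensity = v)
  r <- correlate_with_track(grid, tr, "plus", window = c(30, 70))
  expect_equal(r$pearson, 1.0)
  grid2 <- data.frame(position = 1:100, intensity = max(v) - v)
  r2 <- correlate_with_track(grid2, tr, "plus", window = c(30, 70))
  expect_equal(r2$pearson, -1.0)
  gflat <- data.frame(position = 1:100, intensity = rep(2, 100))
  r3 <- correlate_with_track(gflat, tr, "plus", window = c(30, 70))
  expect_true(is.na(r3$pearson))
  expect_match(r3$note, "zero variance")
})

test_that("a synthetic gel trace correlates with the cleavage track it encodes", {
  # same dyad, same offsets: the gel lane is a rendering of the track
  map <- seq_map("mini", 600)
  spec <- chromatin_spec(map, dyads = 300, label = "one core")
  reads <- simulate_chemical_reads(spec, n = 3000, seed = 401)
  smoothed <- moving_average(to_cleavage_sites(five_prime_track(reads, map)))
  sig <- combine_strands(smoothed)
  win <- 270:330
  # render the per-base signal as a gel lane: migration = base (identity)
  x <- seq(min(win) - 0.5, max(win) + 0.49, by = 0.05)
  y <- approx(win, sig[win], xout = x, rule = 2)$y
  anchors <- anchor_set(migration = c(280, 320), base = c(280, 320),
                        lane_kind = "sequencing_ladder")
  grid <- trace_to_base_grid(lane_trace(x, y), anchors, map)
  r <- correlate_with_track(grid, smoothed, "combined",
                            window = c(280, 320))
  expect_gt(r$pearson, 0.9)
})
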