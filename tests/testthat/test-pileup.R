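circ <- seq_map("mini", 1453)

test_that("5'-end pileup follows the strand conventions", {
  r <- aligned_records("mini", 101, 50, "plus")
  t1 <- five_prime_track(r, circ)
  expect_equal(t1$plus[101], 1)
  expect_equal(sum(t1$plus), 1)
  expect_equal(sum(t1$minus), 0)
  r2 <- aligned_records("mini", 101, 50, "minus")
  t2 <- five_prime_track(r2, circ)
  expect_equal(t2$minus[150], 1)  # 5' end of a minus read is its right end
  r3 <- aligned_records("mini", rep(7, 10), 30, "plus")
  expect_equal(five_prime_track(r3, circ)$plus[7], 10)
  expect_error(five_prime_track(aligned_records("other", 1, 10, "plus"),
                                circ), "unknown map")
})

test_that("cleavage shift moves mass one base upstream per strand, wrapping", {
  t <- stranded_track(circ, "five_prime",
                      plus = replace(numeric(1453), 101, 1),
                      minus = replace(numeric(1453), 150, 1))
  cl <- to_cleavage_sites(t)
  expect_equal(cl$plus[100], 1)
  expect_equal(cl$minus[151], 1)
  expect_equal(cl$kind, "cleavage")
  # wrap at the origin
  t2 <- stranded_track(circ, "five_prime",
                       plus = replace(numeric(1453), 1, 1))
  expect_equal(to_cleavage_sites(t2)$plus[1453], 1)
  # only five_prime tracks may be shifted
  expect_error(to_cleavage_sites(cl), "five_prime")
})

test_that("shift and smoothing conserve strand mass to floating tolerance", {
  set.seed(21)
  for (i in 1:20) {
    map <- random_map()
    r <- random_records(map, 200)
    fp <- five_prime_track(r, map)
    if (map$topology == "circular") {
      cl <- to_cleavage_sites(fp)
      expect_equal(sum(cl$plus), sum(fp$plus), tolerance = 1e-9)
      expect_equal(sum(cl$minus), sum(fp$minus), tolerance = 1e-9)
      sm <- moving_average(cl, 7)
      expect_lt(abs(sum(combine_strands(sm)) - sum(combine_strands(cl))),
                1e-9)
    }
    expect_equal(sum(fp$plus) + sum(fp$minus), nrow(r))
  }
})

test_that("replicate combination sums element-wise and checks compatibility", {
  a <- stranded_track(circ, "cleavage", plus = replace(numeric(1453), 5, 2))
  b <- stranded_track(circ, "cleavage", plus = replace(numeric(1453), 5, 3))
  expect_equal(combine_tracks(list(a, b))$plus[5], 5)
  z <- stranded_track(circ, "cleavage")
  expect_equal(combine_tracks(list(a, z))$plus, a$plus)
  reps <- lapply(1:3, function(s) {
    r <- simulate_chemical_reads(
      chromatin_spec(circ, 700), n = 500, seed = s)
    to_cleavage_sites(five_prime_track(r, circ))
  })
  tot <- combine_tracks(reps)
  expect_equal(sum(combine_strands(tot)),
               sum(vapply(reps, function(t) sum(combine_strands(t)),
                          numeric(1))))
  wrong <- stranded_track(circ, "occupancy")
  expect_error(combine_tracks(list(a, wrong)), "one map and kind")
})

test_that("moving average spreads unit mass and requires odd windows", {
  t <- stranded_track(circ, "cleavage",
                      plus = replace(numeric(1453), 700, 7))
  sm <- moving_average(t, 7)
  expect_equal(sm$plus[697:703], rep(1, 7))
  expect_equal(sum(sm$plus), 7)
  const <- stranded_track(circ, "cleavage", plus = rep(2.5, 1453))
  expect_equal(moving_average(const, 7)$plus, rep(2.5, 1453))
  expect_error(moving_average(t, 6), "odd")
  # linear maps shrink the window at the edges
  lin <- seq_map("lin", 10, "linear")
  tl <- stranded_track(lin, "cleavage", plus = c(3, numeric(9)))
  expect_equal(moving_average(tl, 3)$plus[1], 1.5)  # mean over 2 bases
})

test_that("smoothing is linear and shift-equivariant on circles", {
  set.seed(31)
  L <- 200
  m <- seq_map("c", L)
  x <- rpois(L, 2)
  tx <- stranded_track(m, "cleavage", plus = x)
  for (s in sample.int(L, 5)) {
    shifted <- x[((seq_len(L) - 1 - s) %% L) + 1]
    a <- moving_average(stranded_track(m, "cleavage", plus = shifted), 7)$plus
    b <- moving_average(tx, 7)$plus[((seq_len(L) - 1 - s) %% L) + 1]
    expect_equal(a, b, tolerance = 1e-12)
  }
  y <- rpois(L, 1)
  both <- moving_average(stranded_track(m, "cleavage", plus = x + y), 7)$plus
  sep <- moving_average(stranded_track(m, "cleavage", plus = x), 7)$plus +
    moving_average(stranded_track(m, "cleavage", plus = y), 7)$plus
  expect_equal(both, sep, tolerance = 1e-12)
})

test_that("strand combination is element-wise and commutes with smoothing", {
  t <- stranded_track(circ, "cleavage",
                      plus = replace(numeric(1453), 10, 1),
                      minus = replace(numeric(1453), 10, 2))
  expect_equal(combine_strands(t)[10], 3)
  expect_equal(combine_strands(stranded_track(circ, "cleavage")),
               numeric(1453))
  sm_then_comb <- combine_strands(moving_average(t, 7))
  comb <- combine_strands(t)
  comb_then_sm <- moving_average(
    stranded_track(circ, "cleavage", plus = comb), 7)$plus
  expect_equal(sm_then_comb, comb_then_sm, tolerance = 1e-12)
})

test_that("occupancy extension follows each read's own 3' direction", {
  r <- aligned_records("mini", 101, 36, "plus")
  occ <- occupancy_track(r, circ, extsize = 100)
  expect_equal(which(occ$plus == 1), 101:200)
  # extsize 1 reproduces the 5'-end pileup
  rr <- random_records(circ, 50)
  expect_equal(occupancy_track(rr, circ, 1)$plus,
               five_prime_track(rr, circ)$plus)
  # two reads facing each other 147 apart share a full-overlap core
  face <- aligned_records("mini", c(301, 301 + 147 - 36), 36,
                          c("plus", "minus"))
  occ2 <- occupancy_track(face, circ, extsize = 147)
  cov <- occ2$plus + occ2$minus
  expect_equal(which(cov >= 1), 301:447)  # 147-bp plateau
  expect_equal(which(cov == 2), 301:447)  # full overlap at the shared core
})

test_that("pileups match the brute-force per-read enumerator exactly", {
  set.seed(41)
  for (i in 1:25) {
    map <- random_map()
    r <- random_records(map, sample(10:120, 1))
    fp <- five_prime_track(r, map)
    o <- oracle_five_prime(r, map)
    expect_identical(fp$plus, o$plus)
    expect_identical(fp$minus, o$minus)
    ext <- sample(c(1, 50, 100, 147), 1)
    occ <- occupancy_track(r, map, ext)
    oo <- oracle_occupancy(r, map, ext)
    expect_identical(occ$plus, oo$plus)
    expect_identical(occ$minus, oo$minus)
    if (map$topology == "circular") {
      cl <- to_cleavage_sites(fp)
      oc <- oracle_cleavage(r, map)
      expect_identical(cl$plus, oc$plus)
      expect_identical(cl$minus, oc$minus)
    }
  }
})

test_that("SAM subset and tab-delimited readers agree on strand and length", {
  sam <- c("@HD\tVN:1.6",
           "@SQ\tSN:mini\tLN:1453",
           "r1\t0\tmini\t101\t60\t36M\t*\t0\t0\tAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA\t*",
           "r2\t16\tmini\t201\t60\t20M5D10M\t*\t0\t0\tAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA\t*",
           "r3\t4\tmini\t0\t0\t*\t*\t0\t0\tAAAA\t*",  # unmapped: skipped
           "r4\t0\tmini\t301\t60\t*\t*\t0\t0\tAAAAAAAAAA\t*")
  f <- tempfile(fileext = ".sam")
  writeLines(sam, f)
  rec <- read_aligned_records(f)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$start, c(101, 201, 301))
  expect_equal(rec$read_length, c(36, 35, 10))  # CIGAR 20M5D10M consumes 35
  expect_equal(rec$strand, c("plus", "minus", "plus"))
  # tab dialect round trip
  f2 <- tempfile(fileext = ".tsv")
  write.table(rec, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_aligned_records(f2), rec)
})

test_that("wiggle and bedGraph writers round-trip values exactly", {
  set.seed(51)
  for (i in 1:10) {
    L <- sample(50:400, 1)
    m <- seq_map(paste0("chr", i), L)
    v <- rpois(L, 0.7) * runif(L)  # sparse, non-integer values
    fw <- tempfile(fileext = ".wig")
    fb <- tempfile(fileext = ".bedgraph")
    write_wiggle(v, fw, m)
    write_bedgraph(v, fb, m)
    expect_identical(read_wiggle(fw, m), v)
    expect_identical(read_bedgraph(fb, m), v)
  }
  # explicit 1-based inclusive -> 0-based half-open conversion
  m <- seq_map("chrom", 10)
  v <- replace(numeric(10), 5, 2)
  fb <- tempfile(fileext = ".bedgraph")
  write_bedgraph(v, fb, m)
  expect_equal(readLines(fb), "chrom\t4\t5\t2")
  # all-zero tracks give header-only / empty files
  fw <- tempfile(fileext = ".wig")
  write_wiggle(numeric(10), fw, m)
  expect_equal(readLines(fw), "variableStep chrom=chrom span=1")
  expect_equal(read_wiggle(fw, m), numeric(10))
  write_bedgraph(numeric(10), fb, m)
  expect_equal(length(readLines(fb)), 0)
})

test_that("track output is readable by an independent importer", {
  suppressPackageStartupMessages(requireNamespace("rtracklayer"))
  m <- seq_map("chrZ", 120)
  v <- replace(numeric(120), c(5, 6, 7, 50), c(1, 1, 2.5, 4))
  fb <- tempfile(fileext = ".bedgraph")
  write_bedgraph(v, fb, m)
  gr <- rtracklayer::import(fb, format = "bedGraph")
  back <- numeric(120)
  s <- GenomicRanges::start(gr); e <- GenomicRanges::end(gr)
  for (k in seq_along(gr)) back[s[k]:e[k]] <- gr$score[k]
  expect_equal(back, v)
  fw <- tempfile(fileext = ".wig")
  write_wiggle(v, fw, m)
  gw <- rtracklayer::import(fw, format = "wig")
  backw <- numeric(120)
  sw <- GenomicRanges::start(gw); ew <- GenomicRanges::end(gw)
  for (k in seq_along(gw)) backw[sw[k]:ew[k]] <- gw$score[k]
  expect_equal(backw, v)
})
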