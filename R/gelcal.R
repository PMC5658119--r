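#' Densitometry trace of a single gel lane
#'
#' Holds a 1-D lane profile as exported by "Plot Profile"-style
#' densitometry: a strictly increasing migration coordinate `x` (arbitrary
#' units, typically pixels along the lane) and the signal intensity `y` at
#' each coordinate.
#'
#' @param x Migration coordinates, strictly increasing, length >= 2.
#' @param y Intensities (>= 0 after any baseline handling), same length.
#' @param label Lane label.
#' @return An object of class `lane_trace`.
#' @export
lane_trace <- function(x, y, label = "") {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 2L)
    stop("`x` and `y` must have equal length >= 2")
  if (any(diff(x) <= 0))
    stop("`x` must be strictly increasing")
  if (any(y < 0))
    stop("`y` must be non-negative")
  structure(list(x = x, y = y, label = as.character(label)),
            class = "lane_trace")
}

#' Read a two-column lane trace from delimited text
#'
#' Accepts tab- or comma-delimited `x, y` pairs with an optional one-line
#' header, the format written by ImageJ's "Plot Profile" export.
#'
#' @param path Path to the trace file.
#' @param label Lane label (defaults to the file name).
#' @return A [lane_trace()].
#' @export
read_lane_trace <- function(path, label = basename(path)) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  has_header <- is.na(suppressWarnings(
    as.numeric(strsplit(trimws(first), if (sep == "") "[\t ]+" else sep)[[1]][1])))
  d <- utils::read.table(path, sep = sep, header = has_header)
  lane_trace(d[[1]], d[[2]], label = label)
}

#' DNA size-marker standard for a gel
#'
#' Pairs of (fragment size in bp, migration in a.u.) from a marker lane.
#' Sizes must be positive and distinct and migration strictly monotone in
#' size (longer fragments migrate less far on a standard gel; the reversed
#' orientation is also accepted).
#'
#' @param size Fragment sizes in bp.
#' @param migration Migration coordinates (a.u.).
#' @return An object of class `size_standard`.
#' @export
size_standard <- function(size, migration) {
  size <- as.numeric(size); migration <- as.numeric(migration)
  if (length(size) != length(migration) || length(size) < 2L)
    stop("need >= 2 (size, migration) pairs")
  if (any(size <= 0) || anyDuplicated(size))
    stop("sizes must be positive and distinct")
  o <- order(size)
  dm <- diff(migration[o])
  if (!(all(dm > 0) || all(dm < 0))) {
    bad <- which(sign(dm) != sign(dm[1])) + 1L
    stop(sprintf(
      "migration is not strictly monotone in size; offending pairs: %s",
      paste(sprintf("(%g bp, %g a.u.)", size[o][bad], migration[o][bad]),
            collapse = ", ")))
  }
  structure(list(size = size[o], migration = migration[o]),
            class = "size_standard")
}

#' Anchor bands tying gel migration to base coordinates
#'
#' Manually assigned (migration, base) pairs for unambiguous bands in a
#' lane, used to interpolate base coordinates for every other migration
#' position. The lane kind records how the lane was produced, which decides
#' whether the one-base Taq correction applies (see
#' [apply_taq_correction()]).
#'
#' @param migration Band migration coordinates (a.u.), strictly monotone.
#' @param base Assigned 1-based local base coordinates, strictly monotone.
#' @param lane_kind `"primer_extension"`, `"sequencing_ladder"` or
#'   `"indirect_end_label"`.
#' @return An object of class `anchor_set`.
#' @export
anchor_set <- function(migration, base,
                       lane_kind = c("primer_extension", "sequencing_ladder",
                                     "indirect_end_label")) {
  lane_kind <- match.arg(lane_kind)
  migration <- as.numeric(migration); base <- as.numeric(base)
  if (length(migration) != length(base) || length(migration) < 2L)
    stop("need >= 2 anchors")
  o <- order(migration)
  migration <- migration[o]; base <- base[o]
  if (any(diff(migration) <= 0))
    stop("anchor migrations must be strictly monotone")
  db <- diff(base)
  if (!(all(db > 0) || all(db < 0)))
    stop("anchor bases must be strictly monotone")
  structure(list(migration = migration, base = base, lane_kind = lane_kind),
            class = "anchor_set")
}

# Piecewise-linear interpolation through (x, y) knots with the terminal
# segments extended beyond the outermost knots; extrapolated queries are
# flagged. x must be strictly increasing.
pl_interp <- function(x, y, xq) {
  n <- length(x)
  value <- stats::approx(x, y, xout = xq, rule = 2)$y
  lo <- xq < x[1]; hi <- xq > x[n]
  if (any(lo)) {
    s <- (y[2] - y[1]) / (x[2] - x[1])
    value[lo] <- y[1] + (xq[lo] - x[1]) * s
  }
  if (any(hi)) {
    s <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
    value[hi] <- y[n] + (xq[hi] - x[n]) * s
  }
  list(value = value, extrapolated = lo | hi)
}

#' Fit a size standard curve for a gel
#'
#' The classic semi-log calibration: migration is modeled piecewise-linear
#' in `log10(size)`, interpolating between flanking markers. Queries beyond
#' the outermost markers extend the terminal segment and are flagged as
#' extrapolated.
#'
#' @param standard A [size_standard()].
#' @return An object of class `size_curve`; query it with [size_at()] and
#'   [migration_at()].
#' @export
fit_size_curve <- function(standard) {
  stopifnot(inherits(standard, "size_standard"))
  o <- order(standard$migration)
  structure(list(migration = standard$migration[o],
                 log_size = log10(standard$size[o])),
            class = "size_curve")
}

#' Fragment size at a migration coordinate
#'
#' @param curve A [fit_size_curve()] result.
#' @param migration Query migration coordinate(s).
#' @return A data frame with columns `migration`, `size` (bp) and
#'   `extrapolated`.
#' @export
size_at <- function(curve, migration) {
  stopifnot(inherits(curve, "size_curve"))
  r <- pl_interp(curve$migration, curve$log_size, as.numeric(migration))
  data.frame(migration = as.numeric(migration), size = 10^r$value,
             extrapolated = r$extrapolated)
}

#' Migration coordinate of a fragment size
#'
#' @param curve A [fit_size_curve()] result.
#' @param size Query fragment size(s) in bp.
#' @return A data frame with columns `size`, `migration` and
#'   `extrapolated`.
#' @export
migration_at <- function(curve, size) {
  stopifnot(inherits(curve, "size_curve"))
  ls <- log10(as.numeric(size))
  o <- order(curve$log_size)
  r <- pl_interp(curve$log_size[o], curve$migration[o], ls)
  data.frame(size = as.numeric(size), migration = r$value,
             extrapolated = r$extrapolated)
}

#' Calibrate migration coordinates to base coordinates
#'
#' Linear interpolation in (migration, base) between the two anchors
#' flanking each query; queries outside the anchor range are linearly
#' extrapolated from the nearest two anchors and flagged. At anchor
#' migrations the assigned anchor bases are reproduced exactly.
#'
#' @param anchors An [anchor_set()].
#' @param query_x Query migration coordinate(s).
#' @return A data frame with columns `migration`, `base` (fractional) and
#'   `extrapolated`.
#' @export
calibrate_bases <- function(anchors, query_x) {
  stopifnot(inherits(anchors, "anchor_set"))
  r <- pl_interp(anchors$migration, anchors$base, as.numeric(query_x))
  data.frame(migration = as.numeric(query_x), base = r$value,
             extrapolated = r$extrapolated)
}

#' One-base correction for primer-extension products
#'
#' Taq polymerase adds a single untemplated nucleotide at the 3' end of an
#' extension product, so primer-extension bands run one base longer than
#' dideoxy-terminated sequencing-ladder controls. Calls from
#' primer-extension lanes are therefore shifted by -1; sequencing-ladder
#' and indirect-end-label calls are unchanged. With a circular `map`, base
#' 1 wraps to `map$length`.
#'
#' @param base Base coordinate(s).
#' @param lane_kind Lane kind as in [anchor_set()].
#' @param map Optional [seq_map()] used to wrap corrected coordinates.
#' @return Corrected base coordinate(s).
#' @export
apply_taq_correction <- function(base,
                                 lane_kind = c("primer_extension",
                                               "sequencing_ladder",
                                               "indirect_end_label"),
                                 map = NULL) {
  lane_kind <- match.arg(lane_kind)
  out <- if (lane_kind == "primer_extension") base - 1 else base
  if (!is.null(map)) out <- wrap_pos(map, out)
  out
}

#' Detect bands in a lane trace
#'
#' Bands are local maxima of the (optionally 3-sample median smoothed)
#' trace whose topographic prominence is at least `min_prominence` times
#' the trace maximum, greedily thinned so no two band centers lie closer
#' than `min_separation` (the higher peak wins). A flat trace yields no
#' bands. The band center is the position of the local maximum by default;
#' `center = "centroid"` instead uses the intensity-weighted centroid of
#' the half-height region, which can be preferable for symmetric,
#' well-resolved bands.
#'
#' @param trace A [lane_trace()].
#' @param min_prominence Minimum prominence as a fraction of the trace
#'   maximum, in (0, 1].
#' @param min_separation Minimum distance between band centers (a.u.).
#' @param smooth Apply a 3-sample running median before peak picking.
#' @param baseline Subtract a rolling-minimum baseline first (off by
#'   default; raw profiles are compared directly in this workflow).
#' @param baseline_window Rolling-minimum window (samples) when `baseline`
#'   is on.
#' @param center `"maximum"` or `"centroid"`.
#' @return A data frame of class `band_calls` with columns `center`,
#'   `height`, `prominence`, `width_at_half_height`, sorted by increasing
#'   migration.
#' @export
detect_bands <- function(trace, min_prominence = 0.05, min_separation = 0,
                         smooth = TRUE, baseline = FALSE,
                         baseline_window = 51L,
                         center = c("maximum", "centroid")) {
  stopifnot(inherits(trace, "lane_trace"))
  center <- match.arg(center)
  if (min_prominence <= 0 || min_prominence > 1)
    stop("`min_prominence` must be in (0, 1]")
  x <- trace$x
  y <- trace$y
  if (baseline) y <- pmax(y - rolling_min(y, baseline_window), 0)
  ys <- if (smooth && length(y) >= 3) as.numeric(stats::runmed(y, 3)) else y
  empty <- data.frame(center = numeric(0), height = numeric(0),
                      prominence = numeric(0),
                      width_at_half_height = numeric(0))
  class(empty) <- c("band_calls", "data.frame")
  if (max(ys) == min(ys)) return(empty)
  n <- length(ys)
  # interior local maxima; a plateau of equal values counts once, at its
  # middle sample (median smoothing flattens symmetric peaks)
  cand <- which(ys[2:(n - 1)] > ys[1:(n - 2)] & ys[2:(n - 1)] >= ys[3:n]) + 1L
  if (!length(cand)) return(empty)
  cand <- vapply(cand, function(i) {
    j <- i
    while (j < n && ys[j + 1L] == ys[i]) j <- j + 1L
    as.integer(i + (j - i) %/% 2L)
  }, integer(1))
  cand <- unique(cand)
  prom <- vapply(cand, function(i) peak_prominence(ys, i), numeric(1))
  keep <- prom >= min_prominence * max(ys)
  cand <- cand[keep]; prom <- prom[keep]
  if (!length(cand)) return(empty)
  # greedy thinning, highest peaks first
  o <- order(ys[cand], decreasing = TRUE)
  kept <- integer(0)
  for (i in o) {
    if (!length(kept) ||
        all(abs(x[cand[i]] - x[cand[kept]]) >= min_separation))
      kept <- c(kept, i)
  }
  cand <- cand[kept]; prom <- prom[kept]
  info <- lapply(seq_along(cand), function(k) {
    i <- cand[k]
    half <- ys[i] / 2
    # walk out to the half-height crossings, interpolating linearly
    l <- i
    while (l > 1 && ys[l - 1] >= half) l <- l - 1
    xl <- if (l == 1 || ys[l] == half) x[l] else {
      f <- (ys[l] - half) / (ys[l] - ys[l - 1]); x[l] - f * (x[l] - x[l - 1])
    }
    r <- i
    while (r < n && ys[r + 1] >= half) r <- r + 1
    xr <- if (r == n || ys[r] == half) x[r] else {
      f <- (ys[r] - half) / (ys[r] - ys[r + 1]); x[r] + f * (x[r + 1] - x[r])
    }
    ctr <- if (center == "centroid") {
      idx <- l:r
      sum(x[idx] * y[idx]) / sum(y[idx])
    } else x[i]
    c(center = ctr, width = xr - xl)
  })
  out <- data.frame(
    center = vapply(info, `[[`, numeric(1), "center"),
    height = ys[cand],
    prominence = prom,
    width_at_half_height = vapply(info, `[[`, numeric(1), "width")
  )
  out <- out[order(out$center), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("band_calls", "data.frame")
  out
}

# Topographic prominence of an interior local maximum: walk out on each
# side until terrain higher than the peak (or the trace edge) is reached,
# tracking the minimum; prominence = height - max(left min, right min).
peak_prominence <- function(y, i) {
  h <- y[i]
  minl <- h
  j <- i - 1L
  while (j >= 1L && y[j] <= h) { minl <- min(minl, y[j]); j <- j - 1L }
  minr <- h
  j <- i + 1L
  while (j <= length(y) && y[j] <= h) { minr <- min(minr, y[j]); j <- j + 1L }
  h - max(minl, minr)
}

rolling_min <- function(y, k) {
  k <- as.integer(k)
  if (k %% 2L == 0L) k <- k + 1L
  h <- (k - 1L) %/% 2L
  n <- length(y)
  vapply(seq_len(n), function(i) min(y[max(1L, i - h):min(n, i + h)]),
         numeric(1))
}

#' Resample a calibrated lane trace onto the base-coordinate grid
#'
#' Every trace sample is calibrated to a fractional base coordinate via the
#' anchor set (with the Taq correction applied for primer-extension lanes),
#' then binned: integer base `b` receives the mean intensity of all samples
#' whose calibrated base falls in `[b - 0.5, b + 0.5)`. Bases inside the
#' covered interval that receive no samples are filled by linear
#' interpolation of the neighboring base values. Trace orientation (whether
#' increasing migration means increasing or decreasing base) is taken from
#' the anchor ordering.
#'
#' @param trace A [lane_trace()].
#' @param anchors An [anchor_set()]; all anchor migrations must lie within
#'   the trace support.
#' @param map Optional [seq_map()]; if circular, the reported canonical
#'   positions wrap.
#' @return An object of class `base_grid`: a data frame with columns `base`
#'   (monotone, unwrapped), `position` (canonical, wrapped if `map` is
#'   circular) and `intensity`.
#' @export
trace_to_base_grid <- function(trace, anchors, map = NULL) {
  stopifnot(inherits(trace, "lane_trace"), inherits(anchors, "anchor_set"))
  if (any(anchors$migration < min(trace$x) |
          anchors$migration > max(trace$x)))
    stop("anchor migrations lie outside the trace support")
  cal <- calibrate_bases(anchors, trace$x)
  b <- apply_taq_correction(cal$base, anchors$lane_kind, map = NULL)
  bin <- floor(b + 0.5)  # [b - 0.5, b + 0.5)
  bases <- seq(min(bin), max(bin))
  mean_y <- tapply(trace$y, factor(bin, levels = bases), mean)
  val <- as.numeric(mean_y)
  if (anyNA(val)) {
    filled <- stats::approx(bases[!is.na(val)], val[!is.na(val)],
                            xout = bases, rule = 2)$y
    val[is.na(val)] <- filled[is.na(val)]
  }
  pos <- if (!is.null(map) && is_circular(map)) wrap_pos(map, bases) else bases
  out <- data.frame(base = bases, position = pos, intensity = val)
  class(out) <- c("base_grid", "data.frame")
  attr(out, "lane_kind") <- anchors$lane_kind
  out
}

#' Correlate a calibrated gel profile with a cleavage track
#'
#' Pearson (and Spearman) correlation between per-base gel intensities and
#' the per-base cleavage counts of a [stranded_track()] on the stated
#' strand, over a coordinate window (clockwise from `window[1]` to
#' `window[2]`, wrapping on circular maps). A zero-variance input yields an
#' undefined correlation, reported as `NA` with a note rather than an
#' error.
#'
#' @param grid A `base_grid` from [trace_to_base_grid()] (or a data frame
#'   with `position` and `intensity` columns).
#' @param track A [stranded_track()].
#' @param strand `"plus"`, `"minus"` or `"combined"`.
#' @param window Length-2 vector of canonical positions.
#' @return A list with `pearson`, `spearman`, `n` and `note`.
#' @export
correlate_with_track <- function(grid, track,
                                 strand = c("combined", "plus", "minus"),
                                 window) {
  strand <- match.arg(strand)
  stopifnot(inherits(track, "stranded_track"), length(window) == 2L)
  map <- track$map
  check_canonical(map, window)
  d <- circular_distance(map, window[1], window[2], "clockwise")
  pos <- wrap_pos(map, window[1] + 0:d)
  tv <- switch(strand,
               combined = track$plus + track$minus,
               plus = track$plus,
               minus = track$minus)[pos]
  gi <- grid$intensity[match(pos, grid$position)]
  ok <- !is.na(gi)
  if (sum(ok) < 3L)
    stop("fewer than 3 overlapping bases between gel profile and track window")
  gv <- gi[ok]; tv <- tv[ok]
  if (stats::sd(gv) == 0 || stats::sd(tv) == 0)
    return(list(pearson = NA_real_, spearman = NA_real_, n = sum(ok),
                note = "undefined: zero variance in at least one input"))
  list(pearson = stats::cor(gv, tv),
       spearman = stats::cor(gv, tv, method = "spearman"),
       n = sum(ok), note = "")
}
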