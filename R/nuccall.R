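#' Cut-site sets
#'
#' Positions of nuclease or chemical cleavage on a map, with a non-negative
#' intensity per site (band intensity, or read-count multiplicity from a
#' pileup). Duplicate positions are aggregated by summing their
#' intensities; sites are kept sorted by position.
#'
#' @param map A [seq_map()].
#' @param position Canonical cut positions.
#' @param intensity Intensity per site (recycled; default 1).
#' @param sample_kind `"naked_mnase"`, `"chromatin_mnase"` or
#'   `"chemical"`.
#' @param strand `"plus"`, `"minus"` or `"combined"`.
#' @param label Free-text label.
#' @return An object of class `cut_site_set`.
#' @export
cut_site_set <- function(map, position, intensity = 1,
                         sample_kind = c("chromatin_mnase", "naked_mnase",
                                         "chemical"),
                         strand = c("combined", "plus", "minus"),
                         label = "") {
  sample_kind <- match.arg(sample_kind)
  strand <- match.arg(strand)
  stopifnot(inherits(map, "seq_map"))
  position <- as.numeric(position)
  check_canonical(map, position)
  intensity <- rep_len(as.numeric(intensity), length(position))
  if (any(intensity < 0)) stop("intensities must be non-negative")
  agg <- tapply(intensity, position, sum)
  pos <- as.numeric(names(agg))
  o <- order(pos)
  structure(
    list(map = map,
         sites = data.frame(position = pos[o],
                            intensity = as.numeric(agg)[o]),
         sample_kind = sample_kind, strand = strand,
         label = as.character(label)),
    class = "cut_site_set"
  )
}

#' @export
print.cut_site_set <- function(x, ...) {
  cat(sprintf("<cut_site_set> %s%s on %s: %d sites, total intensity %.6g\n",
              x$sample_kind,
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              x$map$name, nrow(x$sites), sum(x$sites$intensity)))
  invisible(x)
}

#' Construct a protected region from its bounding cuts
#'
#' A protected region is the stretch between two cut positions within which
#' naked-DNA cut sites are suppressed in chromatin — the nucleosomal
#' footprint. Its length uses the strict-between convention and its
#' midpoint is [map_midpoint()] of the bounding cuts.
#'
#' @param map A [seq_map()].
#' @param left_cut,right_cut Bounding cut positions (clockwise from left to
#'   right).
#' @param suppressed_naked_sites Number of suppressed naked-DNA cut sites
#'   inside the region (`NA` when built directly from printed cut
#'   coordinates).
#' @return One-row data frame of class `protected_region` with columns
#'   `left_cut`, `right_cut`, `length`, `midpoint`,
#'   `suppressed_naked_sites`.
#' @export
protected_region <- function(map, left_cut, right_cut,
                             suppressed_naked_sites = NA_integer_) {
  check_canonical(map, c(left_cut, right_cut))
  out <- data.frame(
    left_cut = left_cut, right_cut = right_cut,
    length = span_length(map, left_cut, right_cut, "strict_between"),
    midpoint = map_midpoint(map, left_cut, right_cut),
    suppressed_naked_sites = suppressed_naked_sites
  )
  class(out) <- c("protected_region", "data.frame")
  out
}

#' Find MNase-protected regions by naked-vs-chromatin comparison
#'
#' A naked-DNA cut site counts as *suppressed* in chromatin when no
#' chromatin cut site within `match_tol` bp carries at least
#' `suppression_ratio` times its normalized band intensity (both sets are
#' normalized to their own total intensity, so differing digestion depths
#' cancel). Intensities are compared at band resolution: a site's
#' effective intensity is its set's summed intensity within `match_tol`
#' bp, the volume a gel band integrates over — single-bp cut multiplicity
#' from a pileup is noisier than what a gel resolves, and band-scale
#' comparison makes suppression calls stable at realistic depths.
#'
#' Regions are bounded by *non-suppressed* chromatin cut positions —
#' chromatin cuts at places where the naked signal is not protected (or
#' where no naked site lies within `match_tol`): each gap between two
#' consecutive eligible bounding cuts that contains a run of at least
#' `min_suppressed` consecutive suppressed naked sites becomes a
#' protected region. Ineligible chromatin cuts (weak cuts inside a
#' footprint) therefore never split a region. On circular maps gaps may
#' cross the origin. Output regions never overlap, by construction.
#'
#' @param naked A [cut_site_set()] from a naked-DNA digest.
#' @param chromatin A [cut_site_set()] from a chromatin digest (must be
#'   non-empty, otherwise no bounding cuts exist).
#' @param suppression_ratio Fraction in (0, 1]; a chromatin site at least
#'   this fraction of the naked normalized intensity rescues the site.
#' @param min_suppressed Minimum length, in suppressed sites, of the
#'   longest consecutive suppressed run a gap must contain.
#' @param match_tol Positional tolerance in bp for matching chromatin to
#'   naked sites.
#' @return A data frame of class `protected_region` (possibly 0 rows).
#' @export
find_protected_regions <- function(naked, chromatin,
                                   suppression_ratio = 0.5,
                                   min_suppressed = 1L, match_tol = 3) {
  stopifnot(inherits(naked, "cut_site_set"),
            inherits(chromatin, "cut_site_set"))
  map <- naked$map
  if (chromatin$map$name != map$name || chromatin$map$length != map$length)
    stop("naked and chromatin cut sets must share one map")
  if (nrow(chromatin$sites) == 0L)
    stop("chromatin cut set is empty: no bounding cuts available")
  empty <- protected_region(map, 1, 1)[0, ]
  if (nrow(naked$sites) == 0L) return(empty)
  np <- naked$sites$position
  cp <- chromatin$sites$position
  # band-resolution intensities: each site carries its set's normalized
  # mass within +/- match_tol
  band_mass <- function(pos, all_pos, all_int) {
    w <- all_int / sum(all_int)
    vapply(pos, function(p) {
      d <- circular_distance(map, all_pos, rep(p, length(all_pos)),
                             "shortest")
      sum(w[d <= match_tol])
    }, numeric(1))
  }
  nw <- band_mass(np, np, naked$sites$intensity)
  cw <- band_mass(cp, cp, chromatin$sites$intensity)
  suppressed <- vapply(seq_along(np), function(i) {
    d <- circular_distance(map, cp, rep(np[i], length(cp)), "shortest")
    !any(cw[d <= match_tol] >= suppression_ratio * nw[i])
  }, logical(1))
  # a chromatin cut may bound a region only where the naked signal is not
  # itself protected: some non-suppressed naked site within match_tol, or
  # no naked site nearby at all
  eligible <- vapply(seq_along(cp), function(j) {
    d <- circular_distance(map, np, rep(cp[j], length(np)), "shortest")
    nearby <- d <= match_tol
    !any(nearby) || any(!suppressed[nearby])
  }, logical(1))
  ecp <- cp[eligible]
  if (length(ecp) < 2L) return(empty)
  gaps <- if (is_circular(map)) {
    cbind(ecp, c(ecp[-1], ecp[1]))  # includes the origin-crossing gap
  } else {
    cbind(ecp[-length(ecp)], ecp[-1])
  }
  out <- lapply(seq_len(nrow(gaps)), function(g) {
    l <- gaps[g, 1]; r <- gaps[g, 2]
    if (l == r) return(NULL)
    d <- span_length(map, l, r, "difference")
    off <- circular_distance(map, rep(l, length(np)), np, "clockwise")
    inside <- off > 0 & off < d
    if (!any(inside)) return(NULL)
    flags <- suppressed[inside][order(off[inside])]
    if (!any(flags)) return(NULL)
    rl <- rle(flags)
    if (max(rl$lengths[rl$values]) < min_suppressed) return(NULL)
    protected_region(map, l, r, suppressed_naked_sites = sum(flags))
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Chemical center of a nucleosome from hydroxyl-radical signal
#'
#' The intensity-weighted centroid of chemical cleavage signal inside a
#' coordinate window, respecting circular wrap-around: positions are
#' unwrapped along the clockwise arc from `window[1]` to `window[2]`, the
#' weighted mean is taken there, and the result is wrapped back and
#' rounded to the nearest base (half-integer ties round toward the lower
#' coordinate). `mode = "argmax"` instead returns the strongest position
#' in the window (ties toward the lower coordinate along the arc).
#'
#' @param x A [cut_site_set()], a [stranded_track()] (strand-combined
#'   signal is used) or a numeric per-base vector (then `map` is
#'   required).
#' @param window Length-2 vector of canonical positions; the window is the
#'   clockwise arc from the first to the second, inclusive.
#' @param map A [seq_map()] for the numeric-vector method.
#' @param mode `"centroid"` or `"argmax"`.
#' @return A canonical integer position.
#' @export
chemical_center <- function(x, window, map = NULL,
                            mode = c("centroid", "argmax")) {
  mode <- match.arg(mode)
  if (inherits(x, "cut_site_set")) {
    map <- x$map
    pos <- x$sites$position
    w <- x$sites$intensity
  } else if (inherits(x, "stranded_track")) {
    map <- x$map
    pos <- seq_len(map$length)
    w <- combine_strands(x)
  } else {
    stopifnot(is.numeric(x), inherits(map, "seq_map"),
              length(x) == map$length)
    pos <- seq_len(map$length)
    w <- x
  }
  if (length(window) != 2L)
    stop("`window` must be a length-2 position vector")
  check_canonical(map, window)
  d <- circular_distance(map, window[1], window[2], "clockwise")
  # unwrap onto the arc starting at window[1]
  off <- circular_distance(map, rep(window[1], length(pos)), pos,
                           "clockwise")
  inside <- off <= d
  if (!any(inside))
    stop("window contains no positions of the input")
  off <- off[inside]; w <- w[inside]
  if (sum(w) == 0)
    stop("zero chemical signal inside the window")
  if (mode == "argmax") {
    o <- order(off)
    off <- off[o]; w <- w[o]
    best <- off[which.max(w)]
    return(wrap_pos(map, window[1] + best))
  }
  ctr <- sum(w * off) / sum(w)
  wrap_pos(map, window[1] + ceiling(ctr - 0.5))  # ties toward lower
}

#' Signed offset between a chemical center and a protected-region midpoint
#'
#' Shortest circular distance, with positive sign when the chemical center
#' lies clockwise of the MNase midpoint. On linear maps it is plainly
#' `chemical_center - midpoint`. The magnitude never exceeds half the map
#' length.
#'
#' @param map A [seq_map()].
#' @param chemical_center Canonical position from [chemical_center()].
#' @param region A `protected_region` row (or a bare midpoint position).
#' @return Signed integer bp offset.
#' @export
center_offset <- function(map, chemical_center, region) {
  mid <- if (is.data.frame(region)) {
    stopifnot(nrow(region) == 1L)
    region$midpoint
  } else region
  check_canonical(map, c(chemical_center, mid))
  if (!is_circular(map)) return(chemical_center - mid)
  d_cw <- circular_distance(map, mid, chemical_center, "clockwise")
  if (d_cw <= map$length / 2) d_cw else d_cw - map$length
}

#' Classify a nucleosome call from its offset and protected length
#'
#' Protection wider than `wide_threshold` makes the precise position
#' ambiguous (the region exceeds a canonical core particle, so the center
#' need not sit at the midpoint): `wide_protection`. Otherwise an absolute
#' chemical-vs-MNase center offset within `consistent_tol` is
#' `consistent`, and anything larger is `shifted`. Independently, a
#' protected length of at most `core_len - 15` bp is flagged
#' `short_protection` — protection substantially below one core particle,
#' as seen for nucleosomes whose flank is invaded by a nuclease-sensitive
#' region.
#'
#' @param offset Signed center offset in bp (see [center_offset()]).
#' @param length Protected-region length in bp (strict-between).
#' @param consistent_tol Offset tolerance in bp (default 20).
#' @param wide_threshold Protection width above which positions are
#'   ambiguous (default 150 bp).
#' @param core_len Canonical core-particle length (default 147 bp).
#' @return A list with `class` (one of `"consistent"`, `"shifted"`,
#'   `"wide_protection"`) and `flags` (character vector, possibly
#'   containing `"short_protection"`).
#' @export
classify_call <- function(offset, length, consistent_tol = 20,
                          wide_threshold = 150, core_len = 147) {
  flags <- character(0)
  cls <- if (length > wide_threshold) "wide_protection"
  else if (abs(offset) <= consistent_tol) "consistent"
  else "shifted"
  if (cls != "wide_protection" && length <= core_len - 15)
    flags <- c(flags, "short_protection")
  list(class = cls, flags = flags)
}

#' Assemble a nucleosome call
#'
#' Combines a chemical center and an MNase protected region into one call
#' row: the signed center offset and the classification.
#'
#' @param map A [seq_map()].
#' @param label Nucleosome label.
#' @param chemical_center Canonical chemical center position.
#' @param region A one-row `protected_region`.
#' @param ... Passed to [classify_call()].
#' @return One-row data frame of class `nucleosome_call`.
#' @export
nucleosome_call <- function(map, label, chemical_center, region, ...) {
  stopifnot(is.data.frame(region), nrow(region) == 1L)
  off <- center_offset(map, chemical_center, region)
  cl <- classify_call(off, region$length, ...)
  out <- data.frame(
    label = label,
    chemical_center = chemical_center,
    left_cut = region$left_cut,
    right_cut = region$right_cut,
    protected_length = region$length,
    mnase_midpoint = region$midpoint,
    center_offset = off,
    classification = cl$class,
    flags = paste(cl$flags, collapse = ";")
  )
  class(out) <- c("nucleosome_call", "data.frame")
  out
}

#' Nucleosome-free-region size between two dyads
#'
#' The edge-to-edge gap left between two nucleosomes whose dyads sit at
#' the given positions, assuming each carries a centered core of
#' `core_len` bp: the clockwise center-to-center distance minus
#' `core_len`, floored at 0. The default core length 147 bp is the
#' canonical histone-octamer particle; cores of 145-147 bp are all
#' compatible with typical gel calls, so the parameter is exposed rather
#' than fixed. Translation-invariant on circular maps.
#'
#' @param map A [seq_map()].
#' @param dyad_a,dyad_b Dyad positions, `dyad_b` clockwise of `dyad_a`.
#' @param core_len Core-particle length in bp (default 147).
#' @return NFR size in bp (>= 0).
#' @examples
#' m <- seq_map("TRP1ARS1", 1453)
#' nfr_size(m, 1308, 104)  # 102
#' @export
nfr_size <- function(map, dyad_a, dyad_b, core_len = 147) {
  stopifnot(core_len >= 1)
  d <- circular_distance(map, dyad_a, dyad_b, "clockwise")
  pmax(d - core_len, 0)
}

#' Enumerate candidate nucleosome frames among cut positions
#'
#' All ordered cut pairs whose strict-between span lies within
#' `target_width +/- tol` are candidate positions ("frames") for a
#' nucleosome; overlapping frames are returned deliberately, since
#' alternative overlapping positions are exactly what multi-frame analysis
#' looks for. On circular maps both arc directions between a pair are
#' considered.
#'
#' @param map A [seq_map()].
#' @param cuts Cut positions (>= 2).
#' @param target_width Target protected width in bp.
#' @param tol Width tolerance in bp.
#' @return A data frame of class `frame_set` with columns `left_cut`,
#'   `right_cut`, `length`, sorted by `left_cut` then `right_cut`.
#' @export
enumerate_frames <- function(map, cuts, target_width, tol) {
  stopifnot(inherits(map, "seq_map"), length(cuts) >= 2L)
  cuts <- sort(unique(as.numeric(cuts)))
  check_canonical(map, cuts)
  if (is_circular(map)) {
    g <- expand.grid(left_cut = cuts, right_cut = cuts)
    g <- g[g$left_cut != g$right_cut, , drop = FALSE]
  } else {
    idx <- utils::combn(length(cuts), 2)
    g <- data.frame(left_cut = cuts[idx[1, ]], right_cut = cuts[idx[2, ]])
  }
  g$length <- span_length(map, g$left_cut, g$right_cut, "strict_between")
  g <- g[abs(g$length - target_width) <= tol, , drop = FALSE]
  g <- g[order(g$left_cut, g$right_cut), , drop = FALSE]
  rownames(g) <- NULL
  class(g) <- c("frame_set", "data.frame")
  g
}

#' Write protected regions as BED
#'
#' 0-based half-open intervals spanning each region's bounding cuts; the
#' BED score is the number of suppressed naked sites. A circular region
#' crossing the origin is written as two intervals sharing one name.
#'
#' @param regions A `protected_region` data frame.
#' @param map A [seq_map()].
#' @param path Output path.
#' @param names Optional region names (default `region_1`, ...).
#' @return The path, invisibly.
#' @export
write_regions_bed <- function(regions, map, path, names = NULL) {
  stopifnot(is.data.frame(regions))
  if (is.null(names)) names <- sprintf("region_%d", seq_len(nrow(regions)))
  lines <- character(0)
  for (i in seq_len(nrow(regions))) {
    l <- regions$left_cut[i]; r <- regions$right_cut[i]
    score <- regions$suppressed_naked_sites[i]
    if (is.na(score)) score <- 0
    if (r >= l) {
      lines <- c(lines, sprintf("%s\t%d\t%d\t%s\t%d", map$name, l - 1, r,
                                names[i], score))
    } else {  # wraps the origin
      lines <- c(lines,
                 sprintf("%s\t%d\t%d\t%s\t%d", map$name, l - 1,
                         map$length, names[i], score),
                 sprintf("%s\t%d\t%d\t%s\t%d", map$name, 0, r, names[i],
                         score))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
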