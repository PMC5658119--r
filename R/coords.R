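#' Reference map for a (circular) minichromosome
#'
#' A `seq_map` is the coordinate frame every other object in the package
#' refers to: a named reference of a given length, either circular (a
#' minichromosome, where position `length + 1` is position 1) or linear,
#' optionally anchored to a genomic source locus via `genomic_offset`, the
#' 1-based chromosomal coordinate that maps to local position 1.
#'
#' All public coordinates are 1-based and inclusive. The canonical local
#' positions are `1..length`.
#'
#' @param name Reference name (used as the chrom field in track output).
#' @param length Reference length in bp (positive integer).
#' @param topology `"circular"` or `"linear"`.
#' @param genomic_offset Optional 1-based genomic coordinate of local
#'   position 1 on `genomic_ref`.
#' @param genomic_ref Optional name of the genomic source sequence.
#' @return An object of class `seq_map`.
#' @examples
#' trp <- seq_map("TRP1ARS1", 1453, "circular", genomic_offset = 461740,
#'                genomic_ref = "chrIV")
#' to_local(trp, 461740)
#' @export
seq_map <- function(name, length, topology = c("circular", "linear"),
                    genomic_offset = NULL, genomic_ref = NULL) {
  topology <- match.arg(topology)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  len <- as.integer(length)
  if (is.na(len) || len < 1L)
    stop("`length` must be a positive integer")
  if (!is.null(genomic_offset)) {
    genomic_offset <- as.numeric(genomic_offset)
    if (length(genomic_offset) != 1L || is.na(genomic_offset) ||
        genomic_offset < 1)
      stop("`genomic_offset` must be a single 1-based coordinate")
  }
  structure(
    list(name = name, length = len, topology = topology,
         genomic_offset = genomic_offset, genomic_ref = genomic_ref),
    class = "seq_map"
  )
}

#' @export
print.seq_map <- function(x, ...) {
  cat(sprintf("<seq_map> %s: %d bp, %s", x$name, x$length, x$topology))
  if (!is.null(x$genomic_offset))
    cat(sprintf(" [%s:%s..%s]", x$genomic_ref %||% "?",
                format(x$genomic_offset, big.mark = ","),
                format(x$genomic_offset + x$length - 1, big.mark = ",")))
  cat("\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_circular <- function(map) {
  stopifnot(inherits(map, "seq_map"))
  map$topology == "circular"
}

#' Canonicalize positions onto a map
#'
#' Wraps arbitrary integer positions onto the canonical range `1..length`
#' of a circular map: `wrap_pos(map, p)` returns `((p - 1) mod length) + 1`.
#' On linear maps out-of-range positions are an error. Wrapping is
#' idempotent.
#'
#' @param map A [seq_map()].
#' @param p Integer position(s), possibly out of range.
#' @return Canonical position(s) in `[1, length]`.
#' @examples
#' m <- seq_map("x", 1453)
#' wrap_pos(m, 1454)  # 1
#' wrap_pos(m, 0)     # 1453
#' @export
wrap_pos <- function(map, p) {
  stopifnot(inherits(map, "seq_map"), is.numeric(p))
  if (is_circular(map))
    return(((p - 1) %% map$length) + 1)
  bad <- p < 1 | p > map$length
  if (any(bad))
    stop(sprintf("position(s) %s outside linear map '%s' [1, %d]",
                 paste(p[bad], collapse = ", "), map$name, map$length))
  p
}

#' Convert a genomic coordinate to a local map position
#'
#' Fixed-offset conversion from the genomic source locus to local
#' coordinates: `chrom_coord - genomic_offset + 1`. Valid only because the
#' minichromosome sequence is colinear with its source locus; no
#' alignment-gap handling is attempted.
#'
#' @param map A [seq_map()] with `genomic_offset` set.
#' @param chrom_coord 1-based genomic coordinate(s) within the locus.
#' @return Local 1-based position(s).
#' @seealso [to_genomic()] for the inverse.
#' @export
to_local <- function(map, chrom_coord) {
  stopifnot(inherits(map, "seq_map"), is.numeric(chrom_coord))
  if (is.null(map$genomic_offset))
    stop(sprintf("map '%s' has no genomic_offset", map$name))
  lo <- map$genomic_offset
  hi <- map$genomic_offset + map$length - 1
  bad <- chrom_coord < lo | chrom_coord > hi
  if (any(bad))
    stop(sprintf(
      "coordinate(s) %s outside the locus [%s, %s] mapped by '%s'",
      paste(format(chrom_coord[bad], scientific = FALSE), collapse = ", "),
      format(lo, scientific = FALSE), format(hi, scientific = FALSE),
      map$name))
  chrom_coord - lo + 1
}

#' Convert a local map position to its genomic coordinate
#'
#' @inheritParams to_local
#' @param p Canonical local position(s).
#' @return Genomic coordinate(s).
#' @export
to_genomic <- function(map, p) {
  stopifnot(inherits(map, "seq_map"), is.numeric(p))
  if (is.null(map$genomic_offset))
    stop(sprintf("map '%s' has no genomic_offset", map$name))
  bad <- p < 1 | p > map$length
  if (any(bad))
    stop(sprintf("position(s) %s outside [1, %d]",
                 paste(p[bad], collapse = ", "), map$length))
  p + map$genomic_offset - 1
}

#' Distance between two positions on a map
#'
#' `"clockwise"` counts single-base steps from `a` to `b` in the direction
#' of increasing coordinate (wrapping on circular maps); `"shortest"` is the
#' minimum of the two directions. `circular_distance(map, a, a)` is 0.
#'
#' @param map A [seq_map()].
#' @param a,b Canonical positions (vectorized, recycled).
#' @param direction `"clockwise"` or `"shortest"`.
#' @return Non-negative integer distance(s) in bp.
#' @examples
#' m <- seq_map("x", 1453)
#' circular_distance(m, 1308, 104)  # 249, across the origin
#' @export
circular_distance <- function(map, a, b,
                              direction = c("clockwise", "shortest")) {
  direction <- match.arg(direction)
  stopifnot(inherits(map, "seq_map"), is.numeric(a), is.numeric(b))
  check_canonical(map, c(a, b))
  if (is_circular(map)) {
    d <- (b - a) %% map$length
    if (direction == "shortest") d <- pmin(d, map$length - d)
    d
  } else {
    if (direction == "shortest") return(abs(b - a))
    d <- b - a
    if (any(d < 0))
      stop("clockwise distance on a linear map requires a <= b")
    d
  }
}

check_canonical <- function(map, p) {
  bad <- p < 1 | p > map$length | p != floor(p)
  if (any(bad))
    stop(sprintf("position(s) %s not canonical on '%s' (expected integers in [1, %d])",
                 paste(p[bad], collapse = ", "), map$name, map$length))
  invisible(TRUE)
}

#' Length of a span between two cut coordinates
#'
#' Gel-mapping conventions measure the stretch between two cut coordinates
#' in three ways, and all three are used side by side in footprinting work:
#' with `d` the clockwise distance from `start` to `end`,
#' \describe{
#'   \item{inclusive}{`d + 1` — both endpoints counted;}
#'   \item{strict_between}{`d - 1` (floored at 0) — only the bases strictly
#'     between the two cuts, the convention for MNase-protected lengths
#'     measured between flanking cut bands;}
#'   \item{difference}{`d` — the plain coordinate difference, the
#'     convention for the width of a chemical-signal region.}
#' }
#'
#' @param map A [seq_map()].
#' @param start,end Canonical positions; on linear maps `start <= end`.
#' @param convention One of `"inclusive"`, `"strict_between"`,
#'   `"difference"`.
#' @return Span length(s) in bp.
#' @examples
#' m <- seq_map("TRP1ARS1", 1453)
#' span_length(m, 1077, 1187, "strict_between")  # 109
#' span_length(m, 1271, 1346, "difference")      # 75
#' @export
span_length <- function(map, start, end,
                        convention = c("inclusive", "strict_between",
                                       "difference")) {
  convention <- match.arg(convention)
  d <- circular_distance(map, start, end, "clockwise")
  switch(convention,
         inclusive = d + 1,
         strict_between = pmax(d - 1, 0),
         difference = d)
}

#' Midpoint of the clockwise arc between two positions
#'
#' Returns `wrap_pos(map, a + floor(d / 2))` where `d` is the clockwise
#' distance from `a` to `b`. When the arc has an even number of steps the
#' half-integer center is rounded toward `a` (the lower/first coordinate);
#' this tie rule only affects spans whose center is not a whole base.
#'
#' @param map A [seq_map()].
#' @param a,b Canonical positions (vectorized, recycled).
#' @return Canonical integer position(s) on the clockwise arc from `a` to
#'   `b`.
#' @examples
#' m <- seq_map("TRP1ARS1", 1453)
#' map_midpoint(m, 1077, 1187)  # 1132
#' @export
map_midpoint <- function(map, a, b) {
  d <- circular_distance(map, a, b, "clockwise")
  wrap_pos(map, a + floor(d / 2))
}
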