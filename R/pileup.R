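#' Aligned-read record tables
#'
#' A minimal aligned-read representation: reference name, 1-based leftmost
#' aligned position, aligned length on the reference, and strand. On
#' circular maps `start + read_length - 1` may run past the reference end;
#' it wraps.
#'
#' @param ref Reference (map) name per read.
#' @param start 1-based leftmost aligned position.
#' @param read_length Aligned length in bp (>= 1).
#' @param strand `"plus"` or `"minus"` per read.
#' @return A data frame with columns `ref`, `start`, `read_length`,
#'   `strand`.
#' @export
aligned_records <- function(ref, start, read_length, strand) {
  start <- as.numeric(start); read_length <- as.numeric(read_length)
  strand <- as.character(strand)
  n <- max(length(ref), length(start), length(read_length), length(strand))
  ref <- rep_len(as.character(ref), n); start <- rep_len(start, n)
  read_length <- rep_len(read_length, n); strand <- rep_len(strand, n)
  if (any(start < 1)) stop("`start` must be >= 1")
  if (any(read_length < 1)) stop("`read_length` must be >= 1")
  if (!all(strand %in% c("plus", "minus")))
    stop("`strand` must be 'plus' or 'minus'")
  data.frame(ref = ref, start = start, read_length = read_length,
             strand = strand)
}

#' Read aligned-read records from SAM or a 4-column table
#'
#' Two plain-text dialects are accepted: a SAM subset (header lines
#' starting with `@` ignored; strand taken from the FLAG field, 0 = plus /
#' forward, 16 = minus / reverse, unmapped reads with flag bit 0x4
#' skipped; aligned length taken from the reference-consumed CIGAR
#' operations M/D/N/=/X when a CIGAR is present, else from the SEQ length)
#' and a headered 4-column tab-delimited table `ref  start  read_length
#' strand`. Paired-end SAM records are treated as independent single-end
#' reads of their own orientation.
#'
#' @param path Path to the file.
#' @param format `"auto"`, `"sam"` or `"tsv"`.
#' @return An [aligned_records()] data frame.
#' @export
read_aligned_records <- function(path, format = c("auto", "sam", "tsv")) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "auto") {
    body <- lines[!startsWith(lines, "@")]
    nf <- length(strsplit(body[1], "\t", fixed = TRUE)[[1]])
    format <- if (nf >= 11L) "sam" else "tsv"
  }
  if (format == "tsv") {
    d <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
    return(aligned_records(d[[1]], d[[2]], d[[3]], d[[4]]))
  }
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  flag <- vapply(fields, function(f) as.integer(f[2]), integer(1))
  keep <- bitwAnd(flag, 4L) == 0L
  fields <- fields[keep]; flag <- flag[keep]
  if (!length(fields))
    return(aligned_records(character(0), numeric(0), numeric(0),
                           character(0)))
  ref <- vapply(fields, `[[`, character(1), 3)
  pos <- vapply(fields, function(f) as.numeric(f[4]), numeric(1))
  len <- vapply(fields, function(f) {
    cigar <- f[6]
    if (!is.na(cigar) && cigar != "*") cigar_ref_length(cigar)
    else nchar(f[10])
  }, numeric(1))
  strand <- ifelse(bitwAnd(flag, 16L) != 0L, "minus", "plus")
  aligned_records(ref, pos, len, strand)
}

# reference-consumed length of a CIGAR string (M, D, N, =, X)
cigar_ref_length <- function(cigar) {
  ops <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  n <- as.numeric(sub("[A-Z=]$", "", toks))
  op <- sub("^[0-9]+", "", toks)
  sum(n[op %in% c("M", "D", "N", "=", "X")])
}

#' Per-base, per-strand signal track
#'
#' A `stranded_track` carries one numeric value per canonical base and
#' strand of its map. `kind` records the processing stage: raw 5'-end
#' counts, inferred cleavage sites, occupancy (extended-read) coverage, or
#' a smoothed signal. Values are stored as non-negative reals so smoothed
#' tracks reuse the type.
#'
#' @param map A [seq_map()].
#' @param kind `"five_prime"`, `"cleavage"`, `"occupancy"` or `"smoothed"`.
#' @param plus,minus Numeric vectors of length `map$length` (default all
#'   zero).
#' @return An object of class `stranded_track`.
#' @export
stranded_track <- function(map, kind = c("five_prime", "cleavage",
                                         "occupancy", "smoothed"),
                           plus = NULL, minus = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(map, "seq_map"))
  L <- map$length
  plus <- if (is.null(plus)) numeric(L) else as.numeric(plus)
  minus <- if (is.null(minus)) numeric(L) else as.numeric(minus)
  if (length(plus) != L || length(minus) != L)
    stop(sprintf("strand vectors must have length %d", L))
  if (any(plus < 0) || any(minus < 0))
    stop("track values must be non-negative")
  structure(list(map = map, plus = plus, minus = minus, kind = kind),
            class = "stranded_track")
}

#' @export
print.stranded_track <- function(x, ...) {
  cat(sprintf("<stranded_track> %s on %s (%d bp): mass + %.6g / - %.6g\n",
              x$kind, x$map$name, x$map$length, sum(x$plus), sum(x$minus)))
  invisible(x)
}

#' Pile up read 5' ends per base and strand
#'
#' Each plus-strand read contributes one count at its leftmost position;
#' each minus-strand read contributes one count at its rightmost aligned
#' base (`wrap(start + read_length - 1)`), which is its 5' end. This is the
#' single-base (extension size 1) pileup used for cleavage-site mapping.
#'
#' @param records An [aligned_records()] data frame.
#' @param map A [seq_map()]; all records must name it.
#' @return A [stranded_track()] of kind `"five_prime"`.
#' @export
five_prime_track <- function(records, map) {
  stopifnot(inherits(map, "seq_map"))
  check_records_map(records, map)
  L <- map$length
  p <- records$strand == "plus"
  fp_plus <- wrap_pos(map, records$start[p])
  fp_minus <- wrap_pos(map, records$start[!p] + records$read_length[!p] - 1)
  stranded_track(map, "five_prime",
                 plus = as.numeric(tabulate(fp_plus, nbins = L)),
                 minus = as.numeric(tabulate(fp_minus, nbins = L)))
}

check_records_map <- function(records, map) {
  stopifnot(is.data.frame(records),
            all(c("ref", "start", "read_length", "strand") %in%
                  names(records)))
  bad <- unique(records$ref[records$ref != map$name])
  if (length(bad))
    stop(sprintf("records reference unknown map(s): %s (expected '%s')",
                 paste(bad, collapse = ", "), map$name))
  invisible(TRUE)
}

#' Shift 5'-end counts one base upstream to the cleavage site
#'
#' The 5'-end nucleotide of a fragment sits one base to its own 3' side of
#' the broken phosphodiester bond, so the cleavage position is one base
#' upstream of the 5' end in the read's own orientation: plus-strand mass
#' at `p` moves to `wrap(p - 1)`, minus-strand mass at `p` moves to
#' `wrap(p + 1)`. Total mass per strand is preserved exactly on circular
#' maps; on linear maps mass shifted past an end is dropped with a warning.
#'
#' The minus-strand direction (+1 in reference coordinates) follows from
#' defining "upstream" relative to the fragment's 5'-to-3' orientation;
#' the convention is isolated in this one function.
#'
#' @param track A [stranded_track()] of kind `"five_prime"`.
#' @return A [stranded_track()] of kind `"cleavage"`.
#' @export
to_cleavage_sites <- function(track) {
  stopifnot(inherits(track, "stranded_track"))
  if (track$kind != "five_prime")
    stop(sprintf("expected a five_prime track, got '%s'", track$kind))
  L <- track$map$length
  if (is_circular(track$map)) {
    plus <- track$plus[c(2:L, 1L)]            # mass at p -> p - 1
    minus <- track$minus[c(L, seq_len(L - 1L))]  # mass at p -> p + 1
  } else {
    dropped <- track$plus[1L] + track$minus[L]
    if (dropped > 0)
      warning(sprintf("%g counts shifted past the ends of linear map '%s'",
                      dropped, track$map$name))
    plus <- c(track$plus[-1L], 0)
    minus <- c(0, track$minus[-L])
  }
  stranded_track(track$map, "cleavage", plus = plus, minus = minus)
}

#' Sum replicate tracks
#'
#' Element-wise per-strand sum of tracks on the same map and of the same
#' kind, the replicate-combination step that merges pileups from several
#' experiments into a combined score.
#'
#' @param tracks A list of [stranded_track()] objects.
#' @return A [stranded_track()].
#' @export
combine_tracks <- function(tracks) {
  stopifnot(is.list(tracks), length(tracks) >= 1L,
            all(vapply(tracks, inherits, logical(1), "stranded_track")))
  ref <- tracks[[1]]
  for (t in tracks[-1]) {
    if (t$map$name != ref$map$name || t$map$length != ref$map$length ||
        t$kind != ref$kind)
      stop("tracks must share one map and kind to be combined")
  }
  stranded_track(ref$map, ref$kind,
                 plus = Reduce(`+`, lapply(tracks, `[[`, "plus")),
                 minus = Reduce(`+`, lapply(tracks, `[[`, "minus")))
}

#' Centered moving-average smoothing
#'
#' Each base receives the mean of the odd-width window centered on it.
#' Circular maps wrap; linear maps shrink the window at the edges (mean
#' over the available bases). The default 7-bp window matches common
#' practice for single-base cleavage tracks. On circular maps the filter
#' conserves total mass and is shift-equivariant.
#'
#' @param track A [stranded_track()].
#' @param window Odd window width in bp (default 7).
#' @return A [stranded_track()] of kind `"smoothed"`.
#' @export
moving_average <- function(track, window = 7L) {
  stopifnot(inherits(track, "stranded_track"))
  window <- as.integer(window)
  if (is.na(window) || window < 1L || window %% 2L == 0L)
    stop("`window` must be an odd integer >= 1")
  sm <- function(x) smooth_vec(x, window, is_circular(track$map))
  stranded_track(track$map, "smoothed", plus = sm(track$plus),
                 minus = sm(track$minus))
}

smooth_vec <- function(x, w, circular) {
  if (w == 1L) return(x)
  if (circular)
    return(as.numeric(stats::filter(x, rep(1 / w, w), sides = 2,
                                    circular = TRUE)))
  h <- (w - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  a <- pmax(1L, seq_len(n) - h)
  b <- pmin(n, seq_len(n) + h)
  (cs[b + 1L] - cs[a]) / (b - a + 1L)
}

#' Collapse a stranded track to a single per-base vector
#'
#' @param track A [stranded_track()].
#' @return Numeric vector `plus + minus` of length `map$length`.
#' @export
combine_strands <- function(track) {
  stopifnot(inherits(track, "stranded_track"))
  track$plus + track$minus
}

#' Extended-read occupancy pileup
#'
#' Each read contributes one count to every base of the `extsize`-long
#' interval that starts at its 5' end and extends in the read's own 3'
#' direction: plus reads cover `[start, start + extsize - 1]`, minus reads
#' cover `[five_prime - extsize + 1, five_prime]`. Circular maps wrap;
#' on linear maps the extension is truncated at the reference boundaries.
#' `extsize = 1` reproduces [five_prime_track()]. Typical extension sizes
#' are 100 bp (to emphasize nucleosome centers) and 147 bp (to show
#' core-particle occupancy).
#'
#' @param records An [aligned_records()] data frame.
#' @param map A [seq_map()].
#' @param extsize Extension size in bp (>= 1).
#' @return A [stranded_track()] of kind `"occupancy"`.
#' @export
occupancy_track <- function(records, map, extsize) {
  stopifnot(inherits(map, "seq_map"))
  check_records_map(records, map)
  extsize <- as.integer(extsize)
  if (is.na(extsize) || extsize < 1L) stop("`extsize` must be >= 1")
  L <- map$length
  cover <- function(s) {
    # s: unwrapped interval starts; interval = [s, s + extsize - 1]
    d <- numeric(L + 1L)
    if (!length(s)) return(numeric(L))
    if (is_circular(map)) {
      if (extsize >= L) return(rep(as.numeric(length(s)), L))
      s <- wrap_pos(map, s)
      e <- s + extsize - 1L
      wrapped <- e > L
      d <- d + tabulate(s, nbins = L + 1L)
      d <- d - tabulate(pmin(e, L) + 1L, nbins = L + 1L)
      if (any(wrapped)) {
        d[1L] <- d[1L] + sum(wrapped)
        d <- d - tabulate(e[wrapped] - L + 1L, nbins = L + 1L)
      }
    } else {
      a <- pmax(1, s)
      b <- pmin(L, s + extsize - 1L)
      ok <- a <= b
      d <- d + tabulate(a[ok], nbins = L + 1L)
      d <- d - tabulate(b[ok] + 1L, nbins = L + 1L)
    }
    cumsum(d)[seq_len(L)]
  }
  p <- records$strand == "plus"
  s_plus <- records$start[p]
  fp_minus <- records$start[!p] + records$read_length[!p] - 1
  s_minus <- fp_minus - extsize + 1
  stranded_track(map, "occupancy", plus = cover(s_plus),
                 minus = cover(s_minus))
}

fmt_num <- function(v) {
  # exact double round trip
  s <- sprintf("%.17g", v)
  ifelse(v == round(v) & abs(v) < 1e15, sprintf("%.0f", v), s)
}

track_values <- function(x, map) {
  if (inherits(x, "stranded_track")) list(v = combine_strands(x), map = x$map)
  else {
    stopifnot(is.numeric(x), inherits(map, "seq_map"),
              length(x) == map$length)
    list(v = x, map = map)
  }
}

#' Write a per-base signal as wiggle (variableStep, span = 1)
#'
#' Positions are 1-based; zero-valued bases are omitted. A
#' [stranded_track()] is written as its strand-combined signal.
#'
#' @param x A numeric per-base vector or a [stranded_track()].
#' @param path Output path.
#' @param map A [seq_map()] (taken from the track when `x` is one).
#' @return The path, invisibly.
#' @export
write_wiggle <- function(x, path, map = NULL) {
  tv <- track_values(x, map)
  keep <- which(tv$v != 0)
  lines <- c(sprintf("variableStep chrom=%s span=1", tv$map$name),
             sprintf("%d\t%s", keep, fmt_num(tv$v[keep])))
  writeLines(lines, path)
  invisible(path)
}

#' Read a variableStep wiggle file onto a map
#'
#' @param path Path to a wiggle written by [write_wiggle()].
#' @param map The [seq_map()] the file refers to.
#' @return Numeric per-base vector of length `map$length` (absent bases
#'   are 0).
#' @export
read_wiggle <- function(path, map) {
  stopifnot(inherits(map, "seq_map"))
  lines <- readLines(path)
  hdr <- grepl("^(variableStep|fixedStep|track)", lines)
  step_hdr <- lines[grepl("^variableStep", lines)]
  if (length(step_hdr)) {
    chrom <- sub(".*chrom=([^ \t]+).*", "\\1", step_hdr[1])
    if (chrom != map$name)
      stop(sprintf("wiggle chrom '%s' does not match map '%s'",
                   chrom, map$name))
  }
  body <- lines[!hdr & nzchar(lines)]
  v <- numeric(map$length)
  if (length(body)) {
    parts <- strsplit(body, "[\t ]+")
    pos <- vapply(parts, function(p) as.integer(p[1]), integer(1))
    val <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
    v[pos] <- val
  }
  v
}

#' Write a per-base signal as bedGraph
#'
#' Intervals are 0-based half-open; runs of adjacent equal values are
#' merged; zero-valued runs are omitted. A [stranded_track()] is written
#' as its strand-combined signal.
#'
#' @inheritParams write_wiggle
#' @return The path, invisibly.
#' @export
write_bedgraph <- function(x, path, map = NULL) {
  tv <- track_values(x, map)
  r <- rle(tv$v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0
  lines <- sprintf("%s\t%d\t%d\t%s", tv$map$name, starts[keep] - 1L,
                   ends[keep], fmt_num(r$values[keep]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph file onto a map
#'
#' @inheritParams read_wiggle
#' @return Numeric per-base vector of length `map$length`.
#' @export
read_bedgraph <- function(path, map) {
  stopifnot(inherits(map, "seq_map"))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|#)", lines)]
  v <- numeric(map$length)
  if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    chrom <- vapply(parts, `[[`, character(1), 1)
    bad <- unique(chrom[chrom != map$name])
    if (length(bad))
      stop(sprintf("bedGraph names unknown chrom(s): %s",
                   paste(bad, collapse = ", ")))
    for (p in parts) {
      s <- as.integer(p[2]); e <- as.integer(p[3])
      v[(s + 1L):e] <- as.numeric(p[4])
    }
  }
  v
}
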