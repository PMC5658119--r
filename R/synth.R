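# Seeded generators for every input the pipeline consumes. All draws go
# through a local RNG scope so a generator never disturbs the caller's
# random stream; identical (seed, parameters) give bit-identical output.

local_seed <- function(seed, code) {
  if (is.null(seed)) stop("a seed is required")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' Ground-truth chromatin description driving the simulators
#'
#' Describes a chromatin substrate as positioned nucleosomes on a map:
#' dyad positions with relative occupancy weights, a core-particle length,
#' and the relative MNase cut rates inside core footprints versus linkers.
#' The core footprint of a dyad is `dyad +/- floor(core_len / 2)`
#' (wrapping on circular maps). An optional A/T preference multiplier
#' models MNase's preference for cutting 5' of A/T base pairs when a
#' sequence is supplied.
#'
#' Default cut rates make linkers ~50x more cleavable than cores
#' (`linker_cut_weight = 1`, `core_cut_weight = 0.02`), the order of
#' magnitude seen in limited digests of positioned arrays.
#'
#' @param map A [seq_map()].
#' @param dyads Canonical dyad positions.
#' @param weights Relative occupancy/cleavage weight per dyad (recycled,
#'   default 1).
#' @param core_len Core-particle length in bp (default 147).
#' @param linker_cut_weight Relative MNase rate per linker base.
#' @param core_cut_weight Relative MNase rate per core base (must not
#'   exceed `linker_cut_weight`).
#' @param at_preference Multiplier for cut probability 5' of A/T when a
#'   sequence is provided (default 1 = no preference).
#' @param label Free-text label.
#' @return An object of class `chromatin_spec`.
#' @export
chromatin_spec <- function(map, dyads, weights = 1, core_len = 147L,
                           linker_cut_weight = 1, core_cut_weight = 0.02,
                           at_preference = 1, label = "") {
  stopifnot(inherits(map, "seq_map"), length(dyads) >= 1L)
  dyads <- as.numeric(dyads)
  check_canonical(map, dyads)
  weights <- rep_len(as.numeric(weights), length(dyads))
  if (any(weights <= 0)) stop("dyad weights must be positive")
  if (core_cut_weight > linker_cut_weight)
    stop("core_cut_weight must not exceed linker_cut_weight")
  structure(list(map = map, dyads = dyads, weights = weights,
                 core_len = as.integer(core_len),
                 linker_cut_weight = linker_cut_weight,
                 core_cut_weight = core_cut_weight,
                 at_preference = at_preference,
                 label = as.character(label)),
            class = "chromatin_spec")
}

#' Strand-specific cleavage-offset model for site-directed chemistry
#'
#' The distribution of chemical cleavage positions relative to the dyad,
#' one table per strand. The default is a symmetric small-offset model,
#' identical on both strands: offsets -2..+2 with probabilities
#' 0.15, 0.2, 0.3, 0.2, 0.15. Site-directed hydroxyl-radical chemistry
#' cleaves near the nucleosome center with strand-specific patterns; the
#' exact per-strand offsets depend on the labeled residue's geometry, so
#' the model is fully configurable and the default makes no claim beyond
#' "near the center".
#'
#' @param plus,minus Data frames with columns `offset` (bp, integer) and
#'   `prob` (summing to 1) for each strand.
#' @return An object of class `chemical_offset_model`.
#' @export
chemical_offset_model <- function(plus = NULL, minus = NULL) {
  default <- data.frame(offset = -2:2,
                        prob = c(0.15, 0.2, 0.3, 0.2, 0.15))
  plus <- if (is.null(plus)) default else plus
  minus <- if (is.null(minus)) default else minus
  for (tab in list(plus, minus)) {
    stopifnot(is.data.frame(tab), all(c("offset", "prob") %in% names(tab)))
    if (abs(sum(tab$prob) - 1) > 1e-9)
      stop("offset probabilities must sum to 1 per strand")
    if (any(tab$prob < 0)) stop("offset probabilities must be non-negative")
  }
  structure(list(plus = plus, minus = minus),
            class = "chemical_offset_model")
}

#' Forward model of gel migration for lane simulation
#'
#' Semi-log migration, `m(size) = intercept - slope * log10(size)`, with
#' Gaussian band spreading and additive white noise. Used to generate lane
#' traces whose band positions are known exactly, for validating the
#' densitometry calibration.
#'
#' @param intercept Migration intercept `a` (a.u.).
#' @param slope Migration slope `b` per decade of size (a.u., > 0).
#' @param band_sd Gaussian band standard deviation (a.u.).
#' @param noise_sd White-noise standard deviation (intensity a.u.).
#' @param samples_per_unit Trace sampling density (samples per a.u.).
#' @return An object of class `gel_model`.
#' @export
gel_model <- function(intercept = 100, slope = 30, band_sd = 0.5,
                      noise_sd = 0, samples_per_unit = 10) {
  if (slope <= 0) stop("`slope` must be positive")
  if (band_sd <= 0) stop("`band_sd` must be positive")
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  structure(list(intercept = intercept, slope = slope, band_sd = band_sd,
                 noise_sd = noise_sd, samples_per_unit = samples_per_unit),
            class = "gel_model")
}

gel_migration <- function(gel, size) gel$intercept - gel$slope * log10(size)

#' Simulate site-directed chemical-cleavage reads
#'
#' Each read picks a dyad (by spec weight), a strand (uniformly), and an
#' offset from that strand's table; the read's 5' end is placed so that the
#' 5'-end pileup followed by the one-base upstream shift recovers a
#' cleavage at `wrap(dyad + offset)` on that strand. Concretely, a plus
#' read's 5' end is `dyad + offset + 1` and a minus read's 5' end is
#' `dyad + offset - 1`; the read extends `read_length` bases in its own 3'
#' direction.
#'
#' @param spec A [chromatin_spec()].
#' @param offsets A [chemical_offset_model()].
#' @param n Number of reads (>= 1).
#' @param read_length Read length in bp.
#' @param seed Integer seed (required).
#' @return An [aligned_records()] data frame with a `dyad` attribute
#'   holding the true dyad per read.
#' @export
simulate_chemical_reads <- function(spec, offsets = chemical_offset_model(),
                                    n, read_length = 50L, seed) {
  stopifnot(inherits(spec, "chromatin_spec"),
            inherits(offsets, "chemical_offset_model"))
  if (length(spec$dyads) == 0L) stop("spec has no dyads")
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be >= 1")
  map <- spec$map
  local_seed(seed, {
    di <- sample.int(length(spec$dyads), n, replace = TRUE,
                     prob = spec$weights)
    strand <- sample(c("plus", "minus"), n, replace = TRUE)
    off <- numeric(n)
    p <- strand == "plus"
    if (any(p))
      off[p] <- sample(offsets$plus$offset, sum(p), replace = TRUE,
                       prob = offsets$plus$prob)
    if (any(!p))
      off[!p] <- sample(offsets$minus$offset, sum(!p), replace = TRUE,
                        prob = offsets$minus$prob)
    dyad <- spec$dyads[di]
    fp <- ifelse(p, dyad + off + 1, dyad + off - 1)
    start <- ifelse(p, fp, fp - read_length + 1)
    rec <- aligned_records(map$name, wrap_pos(map, start), read_length,
                           strand)
    attr(rec, "dyad") <- dyad
    rec
  })
}

#' Simulate MNase cut sites on naked or chromatinized DNA
#'
#' Per-base cut weights: a naked substrate is uniform; a chromatin
#' substrate uses `linker_cut_weight` outside and `core_cut_weight` inside
#' any core footprint (`dyad +/- floor(core_len / 2)`, wrapping). When a
#' sequence is supplied, the weight at position p is multiplied by
#' `at_preference` if the base immediately 5' of the cut (position p - 1
#' on the top strand) is A or T. `n` cuts are drawn from these weights
#' with replacement; multiplicity becomes site intensity.
#'
#' @param spec A [chromatin_spec()].
#' @param substrate `"naked"` or `"chromatin"`.
#' @param n Number of cuts (>= 1).
#' @param seed Integer seed (required).
#' @param sequence Optional character string of length `map$length` (the
#'   top strand) enabling the A/T preference.
#' @return A [cut_site_set()] with `sample_kind` matching the substrate.
#' @export
simulate_mnase_cuts <- function(spec, substrate = c("chromatin", "naked"),
                                n, seed, sequence = NULL) {
  substrate <- match.arg(substrate)
  stopifnot(inherits(spec, "chromatin_spec"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be >= 1")
  map <- spec$map
  L <- map$length
  w <- rep(if (substrate == "naked") 1 else spec$linker_cut_weight, L)
  if (substrate == "chromatin") {
    h <- floor(spec$core_len / 2)
    core <- rep(FALSE, L)
    for (d in spec$dyads)
      core[wrap_pos(map, (d - h):(d + h))] <- TRUE
    w[core] <- spec$core_cut_weight
  }
  if (!is.null(sequence)) {
    s <- toupper(strsplit(sequence, "")[[1]])
    if (length(s) != L)
      stop(sprintf("sequence length %d does not match map length %d",
                   length(s), L))
    prev <- s[wrap_pos(map, seq_len(L) - 1)]
    w[prev %in% c("A", "T")] <- w[prev %in% c("A", "T")] *
      spec$at_preference
  }
  local_seed(seed, {
    pos <- sample.int(L, n, replace = TRUE, prob = w)
    cut_site_set(map, pos,
                 sample_kind = if (substrate == "naked") "naked_mnase"
                               else "chromatin_mnase",
                 label = sprintf("%s simulated %s digest", spec$label,
                                 substrate))
  })
}

#' Simulate a densitometry lane trace with known band centers
#'
#' The trace is the sum, over fragments, of abundance-scaled Gaussian
#' bumps centered at the model migration of each fragment size, plus white
#' noise (clamped at zero). The marker lane's [size_standard()] for the
#' same gel is emitted alongside, as is the ground truth of band centers,
#' so calibration round trips can be tested against truth.
#'
#' @param fragments Data frame with columns `size` (bp, positive) and
#'   `abundance` (> 0). May have zero rows (flat noise trace).
#' @param gel A [gel_model()].
#' @param seed Integer seed (required; used for the noise draw).
#' @param marker_sizes Marker fragment sizes for the emitted standard.
#' @param x_range Optional migration range `c(lo, hi)`; defaults to the
#'   span of all bands and markers plus a 5-sigma margin.
#' @return A list with `trace` ([lane_trace()]), `band_centers` (true
#'   migration of each fragment), and `standard` ([size_standard()]).
#' @export
simulate_gel_lane <- function(fragments, gel = gel_model(), seed,
                              marker_sizes = c(100, 200, 300, 500, 700,
                                               1000, 1500, 2000),
                              x_range = NULL) {
  stopifnot(is.data.frame(fragments),
            all(c("size", "abundance") %in% names(fragments)) ||
              nrow(fragments) == 0L,
            inherits(gel, "gel_model"))
  if (nrow(fragments) && any(fragments$size <= 0))
    stop("fragment sizes must be positive")
  centers <- if (nrow(fragments)) gel_migration(gel, fragments$size)
             else numeric(0)
  marker_m <- gel_migration(gel, marker_sizes)
  if (is.null(x_range)) {
    allm <- c(centers, marker_m)
    x_range <- range(allm) + c(-5, 5) * gel$band_sd
  }
  x <- seq(x_range[1], x_range[2], by = 1 / gel$samples_per_unit)
  y <- numeric(length(x))
  for (i in seq_len(nrow(fragments)))
    y <- y + fragments$abundance[i] *
      stats::dnorm(x, centers[i], gel$band_sd)
  y <- local_seed(seed, pmax(y + stats::rnorm(length(x), 0, gel$noise_sd),
                             0))
  if (max(y) == 0) y[1] <- 0  # keep a valid (flat) trace
  list(trace = lane_trace(x, y, label = "simulated lane"),
       band_centers = centers,
       standard = size_standard(marker_sizes, marker_m))
}

#' The TRP1ARS1 minichromosome fixture
#'
#' The 1,453-bp circular TRP1ARS1 minichromosome — the classic positioned
#' -nucleosome substrate, a circularized EcoRI fragment of S. cerevisiae
#' chromosome IV (coordinates 461,740-463,192; local position 1 is the
#' first adenosine of the GAATTC site) carrying the TRP1 gene and the ARS1
#' origin, organized into seven nucleosomes (I-VII) and two
#' nuclease-hypersensitive regions (HSRA, HSRB).
#'
#' Dyads for nucleosomes II (1,132), III (1,308) and IV (104) are
#' gel-mapped reported values (`source = "reported"`); the remaining dyads
#' are synthetic placeholders at plausible spacings (`source =
#' "placeholder"`) so that whole-minichromosome simulations have a
#' complete substrate — no analysis should treat them as measured truth.
#' HSRB is annotated as the span 1,337 to 62 (wrapping the origin).
#' Printed MNase cut coordinates flanking nucleosomes II-IV from
#' primer-extension gels are attached as named [cut_site_set()]s, and a
#' linear demonstration [anchor_set()] covering the nucleosome II window
#' is included.
#'
#' @return A list with elements `map`, `spec` (a [chromatin_spec()]),
#'   `dyad_table` (data frame: `label`, `dyad`, `source`), `hsrb`
#'   (`c(start, end)`), `cut_sets` (named list of [cut_site_set()]s) and
#'   `anchors` (an [anchor_set()]).
#' @export
trp1ars1_fixture <- function() {
  map <- seq_map("TRP1ARS1", 1453, "circular", genomic_offset = 461740,
                 genomic_ref = "chrIV")
  dyad_table <- data.frame(
    label = c("NucI", "NucII", "NucIII", "NucIV", "NucV", "NucVI",
              "NucVII"),
    dyad = c(955, 1132, 1308, 104, 270, 435, 600),
    source = c("placeholder", "reported", "reported", "reported",
               "placeholder", "placeholder", "placeholder")
  )
  spec <- chromatin_spec(map, dyads = dyad_table$dyad,
                         label = "TRP1ARS1")
  cut_sets <- list(
    nucII_top = cut_site_set(map, c(1077, 1187),
                             sample_kind = "chromatin_mnase",
                             strand = "plus", label = "NucII top-strand"),
    nucII_bottom = cut_site_set(map, c(1077, 1187),
                                sample_kind = "chromatin_mnase",
                                strand = "minus",
                                label = "NucII bottom-strand"),
    nucIII_top = cut_site_set(map, c(1271, 1346),
                              sample_kind = "chromatin_mnase",
                              strand = "plus", label = "NucIII top-strand"),
    nucIII_bottom = cut_site_set(map, c(1268, 1334),
                                 sample_kind = "chromatin_mnase",
                                 strand = "minus",
                                 label = "NucIII bottom-strand"),
    nucIV_top = cut_site_set(map, c(70, 158),
                             sample_kind = "chromatin_mnase",
                             strand = "plus", label = "NucIV top-strand"),
    nucIV_bottom = cut_site_set(map, c(87, 168),
                                sample_kind = "chromatin_mnase",
                                strand = "minus",
                                label = "NucIV bottom-strand")
  )
  anchors <- anchor_set(migration = c(10, 30, 50, 70),
                        base = c(1060, 1100, 1140, 1180),
                        lane_kind = "sequencing_ladder")
  list(map = map, spec = spec, dyad_table = dyad_table,
       hsrb = c(1337, 62), cut_sets = cut_sets, anchors = anchors)
}
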