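#' Validate a pipeline run configuration
#'
#' A run configuration is a plain named list (or a YAML file holding one)
#' with the stage parameters for [run_pipeline()]. Validation happens
#' before any stage runs: a seed must be present whenever a stochastic
#' stage (simulation) is enabled, and any referenced input paths must
#' exist.
#'
#' Recognized fields (all optional unless noted):
#' \describe{
#'   \item{seed}{Integer seed; required when `simulate` is enabled.}
#'   \item{simulate}{List: `n_chemical` (reads), `read_length`, `n_mnase`
#'     (cuts per substrate). Defaults on; set `enabled = FALSE` to supply
#'     cut sets and reads from files instead.}
#'   \item{reads_path, naked_path, chromatin_path}{Input paths used when
#'     simulation is off: an aligned-read table and naked/chromatin
#'     cut-site tables (`position`, `intensity`).}
#'   \item{smooth_window}{Odd moving-average window (default 7).}
#'   \item{callnuc}{List of [find_protected_regions()] /
#'     [classify_call()] parameters: `suppression_ratio`,
#'     `min_suppressed`, `match_tol`, `consistent_tol`, `wide_threshold`,
#'     `core_len`, `center_halfwidth`.}
#' }
#'
#' @param config A named list or a path to a YAML file.
#' @return The validated, default-filled configuration list.
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  sim <- config$simulate %||% list()
  sim$enabled <- sim$enabled %||% TRUE
  sim$n_chemical <- sim$n_chemical %||% 2000L
  sim$read_length <- sim$read_length %||% 50L
  sim$n_mnase <- sim$n_mnase %||% 5000L
  config$simulate <- sim
  if (isTRUE(sim$enabled) && is.null(config$seed))
    stop("config error: `seed` is required when simulation is enabled")
  for (f in c("reads_path", "naked_path", "chromatin_path")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]]))
      stop(sprintf("config error: %s '%s' does not exist", f, config[[f]]))
  }
  cn <- config$callnuc %||% list()
  cn$suppression_ratio <- cn$suppression_ratio %||% 0.5
  cn$min_suppressed <- cn$min_suppressed %||% 1L
  cn$match_tol <- cn$match_tol %||% 3
  cn$consistent_tol <- cn$consistent_tol %||% 20
  cn$wide_threshold <- cn$wide_threshold %||% 150
  cn$core_len <- cn$core_len %||% 147
  cn$center_halfwidth <- cn$center_halfwidth %||% 40
  config$callnuc <- cn
  config$smooth_window <- config$smooth_window %||% 7L
  config
}

#' Run the parallel-mapping pipeline end to end
#'
#' Orchestrates simulate -> pileup -> nucleosome calling on the TRP1ARS1
#' fixture (or a caller-supplied fixture of the same shape): chemical
#' reads are simulated around the fixture dyads, piled up as 5'-end
#' counts, shifted to cleavage sites, smoothed; MNase naked/chromatin cut
#' sets are simulated; chemical centers are estimated per nucleosome; the
#' fixture's printed MNase cut pairs define the protected regions against
#' which centers are compared. Every output file is recorded in a manifest
#' with an MD5 checksum, so a rerun with the same configuration and seed
#' reproduces identical checksums.
#'
#' @param config A configuration list or YAML path (see
#'   [validate_run_config()]).
#' @param outdir Output directory (created if needed); the pipeline writes
#'   nowhere else.
#' @param fixture A fixture list as returned by [trp1ars1_fixture()].
#' @return Invisibly, a list with `calls` (nucleosome-call table),
#'   `regions`, `manifest` (file, md5, n_records) and `tracks`.
#' @export
run_pipeline <- function(config = list(seed = 1L), outdir = tempfile("run"),
                         fixture = trp1ars1_fixture()) {
  config <- validate_run_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  map <- fixture$map
  manifest <- list()
  note <- function(path, n) {
    manifest[[length(manifest) + 1L]] <<-
      data.frame(file = basename(path),
                 md5 = unname(tools::md5sum(path)), n_records = n)
  }

  # --- stage: inputs (simulate or load) ----------------------------------
  stage <- "simulate"
  res <- tryCatch({
    if (isTRUE(config$simulate$enabled)) {
      reads <- simulate_chemical_reads(
        fixture$spec, n = config$simulate$n_chemical,
        read_length = config$simulate$read_length,
        seed = config$seed)
      naked <- simulate_mnase_cuts(fixture$spec, "naked",
                                   n = config$simulate$n_mnase,
                                   seed = config$seed + 1L)
      chromatin <- simulate_mnase_cuts(fixture$spec, "chromatin",
                                       n = config$simulate$n_mnase,
                                       seed = config$seed + 2L)
    } else {
      reads <- read_aligned_records(config$reads_path)
      naked <- read_cut_table(config$naked_path, map, "naked_mnase")
      chromatin <- read_cut_table(config$chromatin_path, map,
                                  "chromatin_mnase")
    }
    p <- file.path(outdir, "chemical_reads.tsv")
    utils::write.table(reads, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note(p, nrow(reads))
    p <- file.path(outdir, "naked_cuts.tsv")
    utils::write.table(naked$sites, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note(p, nrow(naked$sites))
    p <- file.path(outdir, "chromatin_cuts.tsv")
    utils::write.table(chromatin$sites, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note(p, nrow(chromatin$sites))
    list(reads = reads, naked = naked, chromatin = chromatin)
  }, error = function(e) stop(sprintf(
    "stage '%s' failed: %s", stage, conditionMessage(e)), call. = FALSE))

  # --- stage: pileup ------------------------------------------------------
  stage <- "pileup"
  tracks <- tryCatch({
    fp <- five_prime_track(res$reads, map)
    cl <- to_cleavage_sites(fp)
    sm <- moving_average(cl, config$smooth_window)
    p <- file.path(outdir, "cleavage_combined.wig")
    write_wiggle(cl, p); note(p, sum(combine_strands(cl) != 0))
    p <- file.path(outdir, "cleavage_smoothed.bedgraph")
    write_bedgraph(sm, p); note(p, sum(combine_strands(sm) != 0))
    list(five_prime = fp, cleavage = cl, smoothed = sm)
  }, error = function(e) stop(sprintf(
    "stage '%s' failed: %s", stage, conditionMessage(e)), call. = FALSE))

  # --- stage: callnuc -----------------------------------------------------
  stage <- "callnuc"
  called <- tryCatch({
    cn <- config$callnuc
    # regions from the fixture's printed top-strand cut pairs
    region_sets <- list(NucII = fixture$cut_sets$nucII_top,
                        NucIII = fixture$cut_sets$nucIII_top,
                        NucIV = fixture$cut_sets$nucIV_top)
    calls <- list()
    regions <- list()
    for (lab in names(region_sets)) {
      cuts <- region_sets[[lab]]$sites$position
      reg <- protected_region(map, cuts[1], cuts[2])
      dy <- fixture$dyad_table$dyad[
        fixture$dyad_table$label == sub("Nuc", "Nuc", lab)]
      win <- wrap_pos(map, c(dy - cn$center_halfwidth,
                             dy + cn$center_halfwidth))
      ctr <- chemical_center(tracks$smoothed, window = win)
      calls[[lab]] <- nucleosome_call(
        map, lab, ctr, reg, consistent_tol = cn$consistent_tol,
        wide_threshold = cn$wide_threshold, core_len = cn$core_len)
      regions[[lab]] <- reg
    }
    calls <- do.call(rbind, calls)
    regions <- do.call(rbind, regions)
    rownames(calls) <- rownames(regions) <- NULL
    # data-driven protected regions from the simulated MNase comparison
    found <- find_protected_regions(
      res$naked, res$chromatin,
      suppression_ratio = cn$suppression_ratio,
      min_suppressed = cn$min_suppressed, match_tol = cn$match_tol)
    p <- file.path(outdir, "nucleosome_calls.tsv")
    utils::write.table(calls, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note(p, nrow(calls))
    p <- file.path(outdir, "protected_regions.bed")
    write_regions_bed(found, map, p)
    note(p, nrow(found))
    list(calls = calls, regions = regions, found_regions = found)
  }, error = function(e) stop(sprintf(
    "stage '%s' failed: %s", stage, conditionMessage(e)), call. = FALSE))

  manifest <- do.call(rbind, manifest)
  p <- file.path(outdir, "manifest.tsv")
  utils::write.table(manifest, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(calls = called$calls, regions = called$regions,
                 found_regions = called$found_regions,
                 manifest = manifest, tracks = tracks, outdir = outdir))
}

#' Read a cut-site table from delimited text
#'
#' Headered tab-delimited text with columns `position` and `intensity`.
#'
#' @param path Path to the table.
#' @param map A [seq_map()].
#' @param sample_kind Passed to [cut_site_set()].
#' @return A [cut_site_set()].
#' @export
read_cut_table <- function(path, map,
                           sample_kind = c("chromatin_mnase",
                                           "naked_mnase", "chemical")) {
  d <- utils::read.table(path, sep = "\t", header = TRUE)
  cut_site_set(map, d$position, d$intensity, sample_kind = sample_kind,
               label = basename(path))
}
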