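#' Pipeline configuration
#'
#' Exactly one of `input_dir` (containing `genotypes.tsv`, `presence.tsv`,
#' `pedigree.tsv`) or `sim` (a [sim_params()] object, simulation mode)
#' must be given.
#'
#' @param input_dir directory of input TSVs, or `NULL`.
#' @param sim a [sim_params()] for simulation mode, or `NULL`.
#' @param qc a [qc_config()].
#' @param min_male_frac,min_female_frac presence-screen thresholds.
#' @param window_bp heterozygosity window size in bp.
#' @param n_intervals MLH1 profile intervals.
#' @param n_cells simulated cells for the MLH1 stage (0 skips it; only in
#'   simulation mode).
#' @param seed integer seed; expanded into per-stage substreams.
#' @param out_dir output directory.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, sim = NULL,
                            qc = qc_config(), min_male_frac = 0.9,
                            min_female_frac = 0.9, window_bp = 1e6,
                            n_intervals = 10L, n_cells = 0L,
                            seed = 1L, out_dir = tempfile("radlink_run")) {
  .assert(xor(is.null(input_dir), is.null(sim)),
          "exactly one of input_dir and sim must be set")
  if (!is.null(sim)) stopifnot(inherits(sim, "sim_params"))
  structure(list(input_dir = input_dir, sim = sim, qc = qc,
                 min_male_frac = min_male_frac,
                 min_female_frac = min_female_frac, window_bp = window_bp,
                 n_intervals = as.integer(n_intervals),
                 n_cells = as.integer(n_cells),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

# per-stage substream seeds derived from the global seed, so stages can be
# rerun independently with identical results
.stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 11L, foci = 23L)
  (seed * 1000L + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full sex-linkage pipeline
#'
#' Stages: simulate or read inputs -> marker QC -> presence and
#' segregation screens -> boundary estimate -> heterozygosity windows ->
#' per-parent recombination maps -> (optional, simulation mode) MLH1
#' interval profile.  All stage outputs are written under
#' `cfg$out_dir` together with a machine-readable run manifest
#' (`manifest.json`: package version, seed, config hash, stage counts).
#'
#' @param cfg a [pipeline_config()].
#' @param quiet suppress stage logging.
#' @return Object of class `radlink_run`: list with `scan` (the
#'   [sexlink_scan()] fit), `maps` (per-parent [build_map()] results),
#'   `foci_profile` (or `NULL`), `summary` (per-family evidence table),
#'   `manifest`, and `sim` (the simulated dataset in simulation mode).
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  # any stage error aborts naming the stage
  stage <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  sim <- NULL
  if (!is.null(cfg$sim)) {
    say("stage simulate: seed %d", cfg$seed)
    sim <- stage("simulate",
                 simulate_dataset(cfg$sim, seed = .stage_seed(cfg$seed, "simulate")))
    gm <- sim$genotypes; tp <- sim$presence; ped <- sim$pedigree
    write_sim_dataset(sim, file.path(cfg$out_dir, "sim"))
  } else {
    say("stage read: %s", cfg$input_dir)
    stage("read", {
      ped <- read_pedigree(file.path(cfg$input_dir, "pedigree.tsv"))
      gm <- read_genotypes(file.path(cfg$input_dir, "genotypes.tsv"), ped)
      ppath <- file.path(cfg$input_dir, "presence.tsv")
      tp <- if (file.exists(ppath)) read_presence(ppath) else NULL
    })
  }
  say("inputs: %d markers, %d individuals", nrow(gm$markers), length(gm$individuals))

  say("stage qc/screens/boundary")
  scan <- stage("scan",
                sexlink_scan(gm, tp, ped, qc = cfg$qc,
                             min_male_frac = cfg$min_male_frac,
                             min_female_frac = cfg$min_female_frac,
                             window_bp = cfg$window_bp))
  write_qc_audit(scan$qc, file.path(cfg$out_dir, "qc_audit.tsv"))
  write_scan_outputs(scan, cfg$out_dir)
  for (uid in names(scan$qc$retained))
    say("  unit %s: %d markers retained, %d sex-linked", uid,
        length(scan$qc$retained[[uid]]), length(scan$seg_linked[[uid]]))

  say("stage recmap")
  maps <- list()
  units <- scan$qc$units
  stage("recmap", for (u in seq_len(nrow(units))) {
    qm <- scan$qc$matrices[[units$unit_id[u]]]
    for (par in c(units$father_id[u], units$mother_id[u])) {
      partner <- setdiff(c(units$father_id[u], units$mother_id[u]), par)
      im <- informative_markers(qm, par, partner)
      if (nrow(im) < 2L) next
      ph <- phase_and_count_crossovers(qm, par, partner,
                                       units$offspring[[u]], markers = im)
      key <- paste0(units$unit_id[u], ".", par)
      maps[[key]] <- build_map(ph)
      write_recmap(maps[[key]], ph, file.path(cfg$out_dir, "recmap", key))
    }
  })

  prof <- NULL
  if (!is.null(cfg$sim) && cfg$n_cells > 0) {
    say("stage mlh1: %d cells", cfg$n_cells)
    stage("mlh1", {
      set.seed(.stage_seed(cfg$seed, "foci"))
      fd <- simulate_foci(cfg$sim, cfg$n_cells, "male")
      write_foci(fd, file.path(cfg$out_dir, "foci.tsv"))
      prof <- bin_foci(fd, cfg$n_intervals)
      utils::write.table(as.data.frame(prof),
                         file.path(cfg$out_dir, "foci_profile.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    })
  }

  tab <- summary(scan)
  utils::write.table(as.data.frame(tab), file.path(cfg$out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    package = "radlink",
    version = as.character(utils::packageVersion("radlink")),
    seed = cfg$seed,
    config_hash = .config_hash(cfg),
    n_markers_in = nrow(gm$markers),
    n_individuals = length(gm$individuals),
    n_retained = vapply(scan$qc$retained, length, 0L),
    n_seg_linked = vapply(scan$seg_linked, length, 0L),
    n_male_limited = length(scan$male_limited),
    n_female_limited = length(scan$female_limited),
    boundary_bp = scan$boundary[["segregation.all"]]$pos)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  structure(list(scan = scan, maps = maps, foci_profile = prof,
                 summary = tab, manifest = manifest, sim = sim,
                 out_dir = cfg$out_dir),
            class = "radlink_run")
}

# md5 of the deparsed config (written to a temp file; deterministic across
# sessions because deparse of plain lists is).  The seed and output path are
# recorded separately in the manifest and excluded here, so the hash
# identifies the analysis settings.
.config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(unclass(cfg)[setdiff(names(cfg), c("out_dir", "seed"))]), f)
  unname(tools::md5sum(f))
}

#' @export
print.radlink_run <- function(x, ...) {
  cat("radlink pipeline run\n")
  print(x$summary)
  cat(sprintf("outputs in %s\n", x$out_dir))
  invisible(x)
}
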