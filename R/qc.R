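#' Marker retention configuration
#'
#' Reproduces the family-wise RAD marker filters: a call counts as present
#' iff it is non-missing with depth at least `min_depth`; under the
#' stringent rule a marker is retained for a sire-group iff present in the
#' mother, the sire and every one of that sire's offspring; the relaxed
#' rule requires presence in at least half (rounded up) of the offspring
#' only.  Retained markers must additionally reach minor allele frequency
#' `min_maf`, computed from the present calls of the analysis unit (or
#' pooled over units with `pooled_maf = TRUE`).
#'
#' @param preset `"stringent"` (depth >= 12, parents and all offspring) or
#'   `"relaxed"` (depth >= 8, half of the offspring).
#' @param min_depth,presence_rule,min_maf,pooled_maf override individual
#'   fields of the preset.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(preset = c("stringent", "relaxed"),
                      min_depth = NULL, presence_rule = NULL,
                      min_maf = 0.05, pooled_maf = FALSE) {
  preset <- match.arg(preset)
  cfg <- list(
    min_depth = if (!is.null(min_depth)) as.integer(min_depth)
                else if (preset == "stringent") 12L else 8L,
    presence_rule = if (!is.null(presence_rule))
      match.arg(presence_rule, c("parents_and_all_offspring", "half_of_offspring"))
    else if (preset == "stringent") "parents_and_all_offspring" else "half_of_offspring",
    min_maf = min_maf, pooled_maf = isTRUE(pooled_maf), preset = preset)
  .assert(cfg$min_depth >= 1, "min_depth must be >= 1")
  .assert(cfg$min_maf >= 0 && cfg$min_maf <= 0.5, "min_maf must be in [0, 0.5]")
  structure(cfg, class = "qc_config")
}

#' Apply marker QC per sire-group
#'
#' @param gm a [geno_matrix()] covering all pedigree members.
#' @param ped a [pedigree()].
#' @param cfg a [qc_config()].
#' @return Object of class `qc_result`: list with `units` (the
#'   [sire_groups()] table), `retained` (named list unit_id -> marker ids),
#'   `matrices` (named list unit_id -> [geno_matrix()] restricted to the
#'   unit's members and retained markers), `audit` (data frame `marker_id`,
#'   `unit_id`, `family_id`, `verdict`, `reason`) and `config`.
#' @export
apply_qc <- function(gm, ped, cfg = qc_config()) {
  stopifnot(inherits(gm, "geno_matrix"), inherits(ped, "radlink_ped"),
            inherits(cfg, "qc_config"))
  .assert(nrow(gm$markers) > 0, "empty genotype matrix")
  absent <- setdiff(ped$id, gm$individuals)
  .assert(length(absent) == 0L,
          "pedigree individual(s) missing from genotype matrix: %s",
          paste(absent, collapse = ", "))
  units <- sire_groups(ped)
  present <- !is.na(gm$dosage) & gm$depth >= cfg$min_depth

  pooled_ok <- NULL
  if (cfg$pooled_maf) {
    ok <- present[, ped$id, drop = FALSE]
    alt <- rowSums(gm$dosage[, ped$id, drop = FALSE] * ok, na.rm = TRUE)
    tot <- 2 * rowSums(ok)
    f <- ifelse(tot > 0, alt / tot, 0)
    pooled_ok <- pmin(f, 1 - f) >= cfg$min_maf
  }

  retained <- list(); matrices <- list(); audits <- list()
  for (u in seq_len(nrow(units))) {
    uid <- units$unit_id[u]
    off <- units$offspring[[u]]
    members <- c(units$father_id[u], units$mother_id[u], off)
    pu <- present[, members, drop = FALSE]
    if (cfg$presence_rule == "parents_and_all_offspring") {
      pres_ok <- rowSums(pu) == length(members)
    } else {
      need <- ceiling(length(off) / 2)
      pres_ok <- rowSums(pu[, off, drop = FALSE]) >= need
    }
    if (cfg$pooled_maf) {
      maf_ok <- pooled_ok
    } else {
      alt <- rowSums(gm$dosage[, members, drop = FALSE] * pu, na.rm = TRUE)
      tot <- 2 * rowSums(pu)
      f <- ifelse(tot > 0, alt / tot, 0)
      maf_ok <- pmin(f, 1 - f) >= cfg$min_maf
    }
    keep <- pres_ok & maf_ok
    retained[[uid]] <- gm$markers$marker_id[keep]
    matrices[[uid]] <- gm[which(keep), members]
    audits[[uid]] <- data.frame(
      marker_id = gm$markers$marker_id,
      unit_id = uid, family_id = units$family_id[u],
      verdict = ifelse(keep, "retained", "dropped"),
      reason = ifelse(keep, "",
                      ifelse(!pres_ok, "presence", "maf")),
      stringsAsFactors = FALSE)
  }
  structure(list(units = units, retained = retained, matrices = matrices,
                 audit = do.call(rbind, audits), config = cfg),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("Marker QC (%s: depth >= %d, %s, MAF >= %g)\n",
              x$config$preset, x$config$min_depth, x$config$presence_rule,
              x$config$min_maf))
  for (uid in names(x$retained))
    cat(sprintf("  unit %s: %d markers retained\n", uid, length(x$retained[[uid]])))
  invisible(x)
}

#' Write the per-marker QC audit log to TSV
#' @param qc a `qc_result`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_qc_audit <- function(qc, path) {
  utils::write.table(qc$audit, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
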