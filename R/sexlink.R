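# exact rational proportion test: count/n >= frac, avoiding float artefacts
# (frac is scaled to an integer numerator over 1e9)
.frac_ge <- function(count, n, frac) {
  count * 1e9 >= round(frac * 1e9) * n
}

#' Y-limited (male-limited) RADtag screen
#'
#' A tag is called male-limited iff it is completely absent in females and
#' present in at least `min_male_frac` of males, pooled across all
#' sequenced individuals.  Such tags are expected on the ancestral Y or in
#' a fully sex-linked non-recombining segment.
#'
#' @param tp a [tag_presence()].
#' @param ped a [pedigree()] providing sexes.
#' @param min_male_frac minimum fraction of males carrying the tag
#'   (default 0.9); compared as an exact rational proportion.
#' @return Character vector of male-limited tag ids.
#' @export
male_limited_tags <- function(tp, ped, min_male_frac = 0.9) {
  .sex_limited_tags(tp, ped, limited_to = "M", min_frac = min_male_frac)
}

#' Female-limited RADtag screen (false-positive control)
#'
#' Mirror of [male_limited_tags()] with the sexes swapped: tags absent in
#' all males and present in at least `min_female_frac` of females.  In an
#' XY system no true female-limited sequence exists, so hits estimate the
#' screen's false-positive level.
#'
#' @param tp a [tag_presence()].
#' @param ped a [pedigree()].
#' @param min_female_frac minimum fraction of females carrying the tag.
#' @return Character vector of female-limited tag ids.
#' @export
female_limited_tags <- function(tp, ped, min_female_frac = 0.9) {
  .sex_limited_tags(tp, ped, limited_to = "F", min_frac = min_female_frac)
}

.sex_limited_tags <- function(tp, ped, limited_to, min_frac) {
  stopifnot(inherits(tp, "tag_presence"), inherits(ped, "radlink_ped"))
  sex <- ped$sex[match(tp$individuals, ped$id)]
  .assert(!anyNA(sex), "presence matrix column(s) not in pedigree: %s",
          paste(tp$individuals[is.na(sex)], collapse = ", "))
  keep <- sex == limited_to
  .assert(any(keep) && any(!keep), "need both sexes in the dataset")
  n_in <- sum(keep)
  in_count <- rowSums(tp$presence[, keep, drop = FALSE])
  out_count <- rowSums(tp$presence[, !keep, drop = FALSE])
  hit <- out_count == 0L & .frac_ge(in_count, n_in, min_frac)
  tp$tags$tag_id[hit]
}

#' Four-criterion segregation screen for fully sex-linked SNPs
#'
#' Within each sire-group, a marker is fully sex-linked iff it is
#' (i) heterozygous in the father, (ii) homozygous in the mother,
#' (iii) heterozygous in all of that sire's sons and (iv) homozygous for
#' the maternal allele in all of that sire's daughters.  Any missing call
#' among the unit's members fails the marker for that unit (run on
#' QC-filtered matrices, none remain).
#'
#' @param gm a [geno_matrix()] containing at least the unit members; may be
#'   a per-unit QC-filtered matrix.
#' @param ped a [pedigree()].
#' @param detail if `TRUE`, also return the per-criterion verdict table.
#' @return Named list unit_id -> character vector of linked marker ids;
#'   with `detail = TRUE` a list with elements `linked` and `detail`.
#' @export
segregation_screen <- function(gm, ped, detail = FALSE) {
  stopifnot(inherits(gm, "geno_matrix"), inherits(ped, "radlink_ped"))
  units <- sire_groups(ped)
  linked <- list(); details <- list()
  for (u in seq_len(nrow(units))) {
    uid <- units$unit_id[u]
    off <- units$offspring[[u]]
    .assert(length(off) > 0L, "sire-group %s has no offspring", uid)
    members <- c(units$father_id[u], units$mother_id[u], off)
    if (!all(members %in% gm$individuals)) next  # unit absent from this matrix
    sons <- off[ped$sex[match(off, ped$id)] == "M"]
    daughters <- setdiff(off, sons)
    d <- gm$dosage
    fa <- d[, units$father_id[u]]
    mo <- d[, units$mother_id[u]]
    c1 <- !is.na(fa) & fa == 1L
    c2 <- !is.na(mo) & (mo == 0L | mo == 2L)
    ds <- d[, sons, drop = FALSE]
    c3 <- rowSums(is.na(ds)) == 0L & rowSums(ds == 1L, na.rm = TRUE) == length(sons)
    dd <- d[, daughters, drop = FALSE]
    c4 <- rowSums(is.na(dd)) == 0L &
      rowSums(dd == mo, na.rm = TRUE) == length(daughters)
    c4 <- c4 & c2  # "homozygous for the maternal allele" presumes (ii)
    pass <- c1 & c2 & c3 & c4
    linked[[uid]] <- gm$markers$marker_id[pass]
    if (detail)
      details[[uid]] <- data.frame(
        marker_id = gm$markers$marker_id, unit_id = uid,
        family_id = units$family_id[u],
        father_het = c1, mother_hom = c2, sons_het = c3,
        daughters_maternal_hom = c4, linked = pass,
        stringsAsFactors = FALSE)
  }
  if (detail) list(linked = linked, detail = do.call(rbind, details))
  else linked
}

#' Windowed parental heterozygosity
#'
#' For one parent of a pair, computes the proportion of heterozygous sites
#' in non-overlapping windows along each chromosome, restricted to sites
#' called in both members of the parental pair with depth at least
#' `min_depth`.  A collapsed female profile over the proximal segment is
#' the population-genetic signature of an X-specific region.
#'
#' @param gm a [geno_matrix()].
#' @param parent focal parent id.
#' @param partner the other parent of the pair.
#' @param window_bp window size in bp (default 1 Mbp).
#' @param min_depth minimum call depth in both parents (default 8).
#' @return Object of class `het_profile`: data frame with columns `parent`,
#'   `chrom`, `start`, `end`, `n_sites`, `prop_het` (`NA` where a window
#'   has no usable site).
#' @export
window_heterozygosity <- function(gm, parent, partner, window_bp = 1e6,
                                  min_depth = 8) {
  stopifnot(inherits(gm, "geno_matrix"))
  .assert(window_bp > 0, "window_bp must be > 0")
  .assert(all(c(parent, partner) %in% gm$individuals),
          "parent or partner not in genotype matrix")
  ok <- !is.na(gm$dosage[, parent]) & !is.na(gm$dosage[, partner]) &
    gm$depth[, parent] >= min_depth & gm$depth[, partner] >= min_depth
  rows <- list()
  for (chr in intersect(CHROM_LEVELS, unique(gm$markers$chrom))) {
    on_chr <- gm$markers$chrom == chr
    use <- on_chr & ok
    if (!any(on_chr)) next
    max_pos <- max(gm$markers$pos[on_chr])
    n_win <- floor(max_pos / window_bp) + 1L
    win <- floor(gm$markers$pos[use] / window_bp) + 1L  # 1-based window index
    het <- gm$dosage[use, parent] == 1L
    n_sites <- tabulate(win, nbins = n_win)
    n_het <- tabulate(win[het], nbins = n_win)
    rows[[chr]] <- data.frame(
      parent = parent, chrom = chr,
      start = (seq_len(n_win) - 1) * window_bp,
      end = seq_len(n_win) * window_bp,
      n_sites = n_sites,
      prop_het = ifelse(n_sites > 0, n_het / pmax(n_sites, 1L), NA_real_),
      stringsAsFactors = FALSE)
  }
  structure(do.call(rbind, c(rows, make.row.names = FALSE)),
            class = c("het_profile", "data.frame"))
}

#' Most distal fully sex-linked position (boundary estimate)
#'
#' Given a set of fully sex-linked evidence markers or tags, returns the
#' maximum position on the proximal homolog, the size of the evidence set
#' there, and the count of evidence lying on the distal homolog (expected
#' 0 when recombination suppression is confined to the proximal arm).
#' The most distal fully sex-linked position bounds the
#' recombination-suppression boundary from below.
#'
#' @param ids character vector of evidence marker or tag ids.
#' @param positions data frame with id column (`marker_id` or `tag_id`),
#'   `chrom` and `pos` — e.g. `gm$markers` or `tp$tags`.
#' @return List with `chrom`, `pos` (bp; `NA` if no proximal evidence),
#'   `id` of the boundary marker, `n_evidence` (proximal evidence count)
#'   and `n_distal_homolog` (evidence on the distal homolog).
#' @export
estimate_boundary <- function(ids, positions) {
  idcol <- intersect(c("marker_id", "tag_id"), names(positions))[1]
  .assert(!is.na(idcol), "positions must have a marker_id or tag_id column")
  ev <- positions[positions[[idcol]] %in% ids, ]
  prox <- ev[ev$chrom == "proximal_chr7", ]
  if (nrow(prox) == 0L)
    return(list(chrom = "proximal_chr7", pos = NA_real_, id = NA_character_,
                n_evidence = 0L,
                n_distal_homolog = sum(ev$chrom == "distal_chr19")))
  i <- which.max(prox$pos)
  list(chrom = "proximal_chr7", pos = prox$pos[i], id = prox[[idcol]][i],
       n_evidence = nrow(prox),
       n_distal_homolog = sum(ev$chrom == "distal_chr19"))
}

#' Scan family RAD-seq data for a fully sex-linked region
#'
#' The central estimator of this package.  Applies marker QC
#' ([apply_qc()]), the presence/absence screens ([male_limited_tags()],
#' [female_limited_tags()]), the four-criterion segregation screen
#' ([segregation_screen()]) per sire-group, windowed parental
#' heterozygosity, and estimates the recombination-suppression boundary as
#' the position of the most distal fully sex-linked marker, per family and
#' per evidence class.  The headline boundary (`segregation.all`) uses
#' consensus evidence — markers sex-linked in every sire-group where they
#' survived QC — because single-family cosegregation just distal of the
#' shared boundary arises by chance in small sibships.
#'
#' @param gm a [geno_matrix()] of all pedigree members.
#' @param tp a [tag_presence()]; `NULL` skips the presence screens.
#' @param ped a [pedigree()].
#' @param qc a [qc_config()].
#' @param min_male_frac,min_female_frac presence-screen thresholds.
#' @param window_bp heterozygosity window size (bp).
#' @param het_min_depth depth threshold for the heterozygosity profile.
#' @return Object of class `sexlink_scan`; see [summary.sexlink_scan()].
#' @examples
#' sim <- simulate_dataset(sim_params(n_tags = 300), seed = 7)
#' fit <- sexlink_scan(sim$genotypes, sim$presence, sim$pedigree)
#' fit
#' @export
sexlink_scan <- function(gm, tp, ped, qc = qc_config(),
                         min_male_frac = 0.9, min_female_frac = 0.9,
                         window_bp = 1e6, het_min_depth = 8) {
  stopifnot(inherits(gm, "geno_matrix"), inherits(ped, "radlink_ped"))
  qcres <- apply_qc(gm, ped, qc)
  units <- qcres$units

  seg <- list(); seg_detail <- list()
  for (uid in names(qcres$matrices)) {
    sd <- segregation_screen(qcres$matrices[[uid]], ped, detail = TRUE)
    seg[[uid]] <- sd$linked[[uid]]
    seg_detail[[uid]] <- sd$detail
  }

  ml <- fl <- character(0)
  if (!is.null(tp)) {
    ml <- male_limited_tags(tp, ped, min_male_frac)
    fl <- female_limited_tags(tp, ped, min_female_frac)
  }

  # heterozygosity profile per parent pair (per sire-group)
  het <- list()
  for (u in seq_len(nrow(units))) {
    fa <- units$father_id[u]; mo <- units$mother_id[u]
    het[[paste0(units$unit_id[u], ".father")]] <-
      window_heterozygosity(gm, fa, mo, window_bp, het_min_depth)
    het[[paste0(units$unit_id[u], ".mother")]] <-
      window_heterozygosity(gm, mo, fa, window_bp, het_min_depth)
  }

  # consensus evidence: markers fully sex-linked in every sire-group where
  # they survived QC.  A marker can cosegregate with sex in one small
  # family by chance just distal of the true boundary; replication across
  # families removes these, so the consensus set bounds the shared
  # non-recombining region (per-family most-distal positions scatter
  # distally of it).
  any_seg <- unique(unlist(seg, use.names = FALSE))
  unit_fam <- units$family_id[match(names(seg), units$unit_id)]
  consensus <- any_seg[vapply(any_seg, function(id) {
    tested <- vapply(names(seg), function(uid) id %in% qcres$retained[[uid]], TRUE)
    hit <- vapply(names(seg), function(uid) id %in% seg[[uid]], TRUE)
    all(hit[tested]) && length(unique(unit_fam[tested])) >= 2L
  }, TRUE)]

  # boundary per family (segregation evidence) and for the tag screen
  fam_ids <- unique(units$family_id)
  boundary <- list()
  for (fam in fam_ids) {
    in_fam <- units$unit_id[units$family_id == fam]
    ev <- unique(unlist(seg[in_fam], use.names = FALSE))
    boundary[[paste0("segregation.family", fam)]] <-
      estimate_boundary(ev, gm$markers)
  }
  boundary[["segregation.all"]] <- estimate_boundary(consensus, gm$markers)
  if (!is.null(tp))
    boundary[["male_limited_tags"]] <- estimate_boundary(ml, tp$tags)

  structure(list(qc = qcres, seg_linked = seg, seg_consensus = consensus,
                 seg_detail = do.call(rbind, c(seg_detail, make.row.names = FALSE)),
                 male_limited = ml,
                 female_limited = fl, het = het, boundary = boundary,
                 pedigree = ped, markers = gm$markers,
                 settings = list(min_male_frac = min_male_frac,
                                 min_female_frac = min_female_frac,
                                 window_bp = window_bp,
                                 het_min_depth = het_min_depth)),
            class = "sexlink_scan")
}

#' @export
print.sexlink_scan <- function(x, ...) {
  cat("Sex-linkage scan\n")
  cat(sprintf("  male-limited tags: %d (female-limited control: %d)\n",
              length(x$male_limited), length(x$female_limited)))
  for (uid in names(x$seg_linked))
    cat(sprintf("  unit %s: %d fully sex-linked markers\n",
                uid, length(x$seg_linked[[uid]])))
  b <- x$boundary[["segregation.all"]]
  if (!is.na(b$pos))
    cat(sprintf("  most distal fully sex-linked marker: %s at %.1f Mbp (%s)\n",
                b$id, b$pos / 1e6, b$chrom))
  else cat("  no fully sex-linked evidence found\n")
  invisible(x)
}

#' Summarise a sex-linkage scan as a per-family table
#'
#' @param object a [sexlink_scan()] fit.
#' @param ... unused.
#' @return A data frame with one row per evidence class/family: counts of
#'   fully sex-linked tags and the position (Mbp) of the most distal fully
#'   sex-limited tag, in the layout of a classic sex-linkage report table.
#' @export
summary.sexlink_scan <- function(object, ...) {
  rows <- list()
  rows[[1]] <- data.frame(
    approach = "male_limited_tags", family = "all",
    fully_sex_linked = length(object$male_limited),
    most_distal_Mbp = {
      b <- object$boundary[["male_limited_tags"]]
      if (is.null(b) || is.na(b$pos)) NA_real_ else b$pos / 1e6
    }, stringsAsFactors = FALSE)
  fams <- unique(object$qc$units$family_id)
  for (fam in fams) {
    in_fam <- object$qc$units$unit_id[object$qc$units$family_id == fam]
    ev <- unique(unlist(object$seg_linked[in_fam], use.names = FALSE))
    tags <- unique(object$markers$tag_id[object$markers$marker_id %in% ev])
    b <- object$boundary[[paste0("segregation.family", fam)]]
    rows[[length(rows) + 1]] <- data.frame(
      approach = "segregation_pattern", family = fam,
      fully_sex_linked = length(tags),
      most_distal_Mbp = if (is.na(b$pos)) NA_real_ else b$pos / 1e6,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("summary.sexlink_scan", "data.frame")
  out
}

#' @export
print.summary.sexlink_scan <- function(x, ...) {
  cat("Fully sex-linked evidence per approach and family\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Plot a sex-linkage scan
#'
#' Draws the windowed heterozygosity of fathers (solid) and mothers
#' (dashed) along the proximal homolog and marks the estimated boundary.
#'
#' @param x a [sexlink_scan()] fit.
#' @param chrom chromosome to draw.
#' @param ... passed to [graphics::plot()].
#' @export
plot.sexlink_scan <- function(x, chrom = "proximal_chr7", ...) {
  profs <- x$het
  xmax <- max(vapply(profs, function(p) max(p$end[p$chrom == chrom], 0), 0)) / 1e6
  graphics::plot(NA, xlim = c(0, xmax), ylim = c(0, 1),
                 xlab = sprintf("position on %s (Mbp)", chrom),
                 ylab = "proportion heterozygous sites", ...)
  for (nm in names(profs)) {
    p <- profs[[nm]]
    p <- p[p$chrom == chrom & !is.na(p$prop_het), ]
    is_mo <- grepl("mother", nm)
    graphics::lines((p$start + p$end) / 2e6, p$prop_het,
                    lty = if (is_mo) 2 else 1,
                    col = if (is_mo) "magenta3" else "steelblue4")
  }
  b <- x$boundary[["segregation.all"]]
  if (!is.na(b$pos)) graphics::abline(v = b$pos / 1e6, col = "grey40", lty = 3)
  invisible(x)
}

#' Write screen outputs to TSV/BED files
#'
#' Writes `male_limited.tsv`, `female_limited.tsv`, `seg_linked.tsv`
#' (per marker and sire-group: the four criterion verdicts and the linked
#' flag), `het_windows.tsv` and `boundary.bed` (the non-recombining
#' region from 0 to the boundary estimate) into `dir`.
#'
#' @param fit a [sexlink_scan()] fit.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_scan_outputs <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(c("tag_id", fit$male_limited), file.path(dir, "male_limited.tsv"))
  writeLines(c("tag_id", fit$female_limited), file.path(dir, "female_limited.tsv"))
  utils::write.table(fit$seg_detail, file.path(dir, "seg_linked.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  het <- do.call(rbind, c(fit$het, make.row.names = FALSE))
  utils::write.table(het, file.path(dir, "het_windows.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  b <- fit$boundary[["segregation.all"]]
  if (!is.na(b$pos) && b$pos > 0)
    write_region_bed(b$chrom, 0, b$pos, "nonrecombining",
                     file.path(dir, "boundary.bed"))
  invisible(dir)
}
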