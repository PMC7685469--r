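#' Pseudo-testcross informative markers for one parent
#'
#' Markers heterozygous in the focal parent and homozygous in the other
#' parent are the ones whose transmission from the focal parent can be
#' read directly off offspring dosages.  Markers heterozygous in both
#' parents are excluded (their transmission is ambiguous without
#' likelihood phasing), so maps built here are sparser than ones from a
#' full likelihood mapper.
#'
#' @param gm a [geno_matrix()] containing both parents.
#' @param parent focal parent id.
#' @param partner other parent id.
#' @return The markers data frame subset, ordered by (chrom, pos) with the
#'   proximal homolog first.
#' @export
informative_markers <- function(gm, parent, partner) {
  stopifnot(inherits(gm, "geno_matrix"))
  .assert(all(c(parent, partner) %in% gm$individuals),
          "parent '%s' or partner '%s' not in genotype matrix", parent, partner)
  fo <- gm$dosage[, parent]
  ot <- gm$dosage[, partner]
  keep <- !is.na(fo) & !is.na(ot) & fo == 1L & (ot == 0L | ot == 2L)
  m <- gm$markers[keep, , drop = FALSE]
  m[order(match(m$chrom, CHROM_LEVELS), m$pos), , drop = FALSE]
}

#' Infer transmitted alleles, phase markers and count crossovers
#'
#' For each informative marker and offspring, the allele transmitted by
#' the focal parent is the offspring dosage minus the (homozygous) other
#' parent's contribution.  Relative phase of consecutive markers is chosen
#' to minimise the total number of inferred crossovers (the first marker
#' anchors the phase; a tie keeps the previous orientation, which is
#' optimal because flip costs decompose over adjacent marker pairs).
#' Crossovers are reported as intervals between consecutive informative
#' markers where the transmitted-haplotype state switches.
#'
#' @param gm a [geno_matrix()] with parents and offspring called at the
#'   informative markers.
#' @param parent,partner focal and other parent ids.
#' @param offspring character vector of offspring ids.
#' @param markers optional precomputed [informative_markers()] subset.
#' @return Object of class `phase_result`: list with `markers` (ordered
#'   informative markers actually used), `seg` (phase-aligned 0/1
#'   transmission matrix markers x offspring), `crossovers` (data frame
#'   `offspring`, `start`, `end`, `chrom_start`, `chrom_end` — interval
#'   bounds in homolog-local bp), `n_co` (per-offspring counts) and
#'   `skipped` (marker ids with uninferable transmission).
#' @export
phase_and_count_crossovers <- function(gm, parent, partner, offspring,
                                       markers = NULL) {
  if (is.null(markers)) markers <- informative_markers(gm, parent, partner)
  .assert(nrow(markers) >= 2L, "need >= 2 informative markers")
  .assert(length(offspring) >= 1L, "need >= 1 offspring")
  ot <- gm$dosage[markers$marker_id, partner]
  d <- gm$dosage[markers$marker_id, offspring, drop = FALSE]
  # transmitted alt-allele count from the focal parent: dosage minus the
  # other parent's gametic contribution (0 or 1)
  tr <- d - ot / 2
  bad <- rowSums(is.na(tr) | (tr != 0 & tr != 1)) > 0L
  if (any(bad))
    warning(sprintf("%d marker(s) with uninferable transmission skipped", sum(bad)))
  skipped <- markers$marker_id[bad]
  markers <- markers[!bad, , drop = FALSE]
  tr <- tr[!bad, , drop = FALSE]
  .assert(nrow(markers) >= 2L, "fewer than 2 usable informative markers")

  n <- nrow(tr)
  flip <- logical(n)  # phase orientation per marker; first anchored
  for (j in seq_len(n)[-1]) {
    prev <- if (flip[j - 1]) 1 - tr[j - 1, ] else tr[j - 1, ]
    mism_keep <- sum(prev != tr[j, ])
    mism_flip <- sum(prev != (1 - tr[j, ]))
    flip[j] <- mism_flip < mism_keep  # tie keeps current orientation
  }
  seg <- tr
  seg[flip, ] <- 1 - seg[flip, ]

  co <- list()
  for (k in seq_along(offspring)) {
    sw <- which(seg[-1, k] != seg[-n, k])
    if (length(sw))
      co[[length(co) + 1L]] <- data.frame(
        offspring = offspring[k],
        start = markers$pos[sw], end = markers$pos[sw + 1L],
        chrom_start = markers$chrom[sw], chrom_end = markers$chrom[sw + 1L],
        stringsAsFactors = FALSE)
  }
  co <- if (length(co)) do.call(rbind, co) else
    data.frame(offspring = character(0), start = numeric(0), end = numeric(0),
               chrom_start = character(0), chrom_end = character(0))
  n_co <- stats::setNames(tabulate(match(co$offspring, offspring),
                                   nbins = length(offspring)), offspring)
  structure(list(markers = markers, seg = seg, crossovers = co, n_co = n_co,
                 parent = parent, skipped = skipped),
            class = "phase_result")
}

#' Kosambi mapping function
#'
#' Converts a recombination fraction `r` into an additive map distance in
#' centimorgans, `25 * ln((1 + 2r) / (1 - 2r))`, which accounts for
#' (implicit) crossover interference.
#'
#' @param r recombination fraction(s) in `[0, 0.5)`.
#' @return Map distance(s) in cM.
#' @export
kosambi_cm <- function(r) {
  .assert(all(r >= 0 & r < 0.5), "recombination fraction must be in [0, 0.5)")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Inverse Kosambi mapping function
#'
#' @param d map distance(s) in cM.
#' @return Recombination fraction(s); `kosambi_inv(kosambi_cm(r)) == r`.
#' @export
kosambi_inv <- function(d) {
  .assert(all(d >= 0), "map distance must be >= 0")
  tanh(d / 50) / 2
}

#' Build a per-parent cosegregation map with Kosambi distances
#'
#' Adjacent markers with identical phase-aligned transmission vectors join
#' one cosegregation group (estimated recombination fraction 0, one map
#' position); between adjacent groups the recombination fraction is the
#' fraction of recombinant offspring, converted through [kosambi_cm()] and
#' accumulated along the physical order.  A fully sex-linked proximal
#' segment shows up as a single group spanning all proximal markers of a
#' paternal map.
#'
#' @param phased a [phase_and_count_crossovers()] result.
#' @return Object of class `rec_map`: data frame with columns `parent`,
#'   `marker_id`, `chrom`, `pos`, `group`, `cM`.
#' @export
build_map <- function(phased) {
  stopifnot(inherits(phased, "phase_result"))
  seg <- phased$seg
  n <- nrow(seg)
  .assert(ncol(seg) >= 1L, "no offspring in segregation vectors")
  new_grp <- c(TRUE, rowSums(seg[-1, , drop = FALSE] !=
                               seg[-n, , drop = FALSE]) > 0L)
  grp <- cumsum(new_grp)
  cm <- numeric(n)
  for (j in seq_len(n)[-1]) {
    if (new_grp[j]) {
      r <- mean(seg[j, ] != seg[j - 1, ])
      cm[j] <- cm[j - 1] + kosambi_cm(min(r, 0.5 - 1e-12))
    } else cm[j] <- cm[j - 1]
  }
  out <- data.frame(parent = phased$parent,
                    marker_id = phased$markers$marker_id,
                    chrom = phased$markers$chrom, pos = phased$markers$pos,
                    group = grp, cM = cm, stringsAsFactors = FALSE)
  structure(out, class = c("rec_map", "data.frame"))
}

#' @export
print.rec_map <- function(x, ...) {
  cat(sprintf("Recombination map for parent %s: %d markers, %d cosegregation group(s), %.2f cM\n",
              x$parent[1], nrow(x), max(x$group), max(x$cM)))
  invisible(x)
}

#' Write recombination map and crossover tables to TSV
#' @param map a [build_map()] result.
#' @param phased the matching [phase_and_count_crossovers()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_recmap <- function(map, phased, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(as.data.frame(map), file.path(dir, "recmap.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  co <- phased$crossovers
  co$parent <- rep(phased$parent, nrow(co))
  utils::write.table(co[c("parent", "offspring", "start", "end",
                          "chrom_start", "chrom_end")],
                     file.path(dir, "crossovers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
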