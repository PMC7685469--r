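#' Construct a genotype matrix of biallelic RAD markers
#'
#' Genotypes are stored as alt-allele dosages (0, 1, 2 or `NA` for missing)
#' with a parallel per-call sequencing depth matrix.  Coordinates are
#' 0-based base pairs on the homologous reference chromosome named by
#' `chrom` (`proximal_chr7`, `distal_chr19` or `unplaced`).
#'
#' @param markers data frame with columns `marker_id`, `tag_id`, `chrom`,
#'   `pos`, `ref`, `alt`.
#' @param dosage integer matrix, markers x individuals; `NA` = missing call.
#' @param depth integer matrix of the same shape, per-call depth (>= 0).
#' @param individuals character vector of column ids.
#' @return Object of class `geno_matrix`: a list with elements `markers`,
#'   `dosage`, `depth`, `individuals`.
#' @export
geno_matrix <- function(markers, dosage, depth, individuals) {
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  need <- c("marker_id", "tag_id", "chrom", "pos", "ref", "alt")
  .assert(all(need %in% names(markers)), "markers table missing column(s): %s",
          paste(setdiff(need, names(markers)), collapse = ", "))
  markers <- markers[need]
  markers$pos <- as.numeric(markers$pos)
  .assert(!anyDuplicated(markers$marker_id), "duplicate marker_id")
  .assert(all(markers$chrom %in% CHROM_LEVELS),
          "chrom labels must be one of: %s", paste(CHROM_LEVELS, collapse = ", "))
  .assert(all(markers$pos >= 0), "positions must be >= 0")
  dosage <- as.matrix(dosage); depth <- as.matrix(depth)
  .assert(nrow(dosage) == nrow(markers) && ncol(dosage) == length(individuals),
          "dosage dimensions do not match markers x individuals")
  .assert(all(dim(depth) == dim(dosage)), "depth dimensions differ from dosage")
  .assert(all(dosage %in% c(0L, 1L, 2L) | is.na(dosage)),
          "dosage values must be 0, 1, 2 or NA")
  .assert(all(depth >= 0, na.rm = TRUE), "depth must be >= 0")
  storage.mode(dosage) <- "integer"
  storage.mode(depth) <- "integer"
  dimnames(dosage) <- dimnames(depth) <- list(markers$marker_id, individuals)
  structure(list(markers = markers, dosage = dosage, depth = depth,
                 individuals = as.character(individuals)),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d markers x %d individuals (%d tags)\n",
              nrow(x$markers), length(x$individuals),
              length(unique(x$markers$tag_id))))
  tab <- table(factor(x$markers$chrom, levels = CHROM_LEVELS))
  cat("  markers per chrom:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  missing calls: %.2f%%\n", 100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
`[.geno_matrix` <- function(x, i, j) {
  if (missing(i)) i <- seq_len(nrow(x$markers))
  if (missing(j)) j <- seq_along(x$individuals)
  if (is.character(i)) i <- match(i, x$markers$marker_id)
  if (is.character(j)) j <- match(j, x$individuals)
  geno_matrix(x$markers[i, , drop = FALSE],
              x$dosage[i, j, drop = FALSE],
              x$depth[i, j, drop = FALSE],
              x$individuals[j])
}

#' Read a genotype matrix from TSV
#'
#' The dialect has fixed leading columns `marker_id`, `tag_id`,
#' `chrom_label`, `pos_bp`, `ref`, `alt`, followed by one column per
#' individual holding `dosage:depth` cells (dosage `.` = missing, e.g.
#' `1:17` or `.:0`).  Every genotyped column must match a pedigree
#' individual and every pedigree individual must be genotyped.
#'
#' @param path file path.
#' @param ped a [pedigree()]; used to validate the column set.
#' @return A [geno_matrix()].
#' @export
read_genotypes <- function(path, ped) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          colClasses = "character")
  lead <- c("marker_id", "tag_id", "chrom_label", "pos_bp", "ref", "alt")
  .assert(all(lead %in% names(df)), "genotype TSV missing column(s): %s",
          paste(setdiff(lead, names(df)), collapse = ", "))
  ids <- setdiff(names(df), lead)
  unknown <- setdiff(ids, ped$id)
  .assert(length(unknown) == 0L, "genotype column(s) not in pedigree: %s",
          paste(unknown, collapse = ", "))
  absent <- setdiff(ped$id, ids)
  .assert(length(absent) == 0L, "pedigree individual(s) missing from genotypes: %s",
          paste(absent, collapse = ", "))

  n <- nrow(df)
  dosage <- depth <- matrix(NA_integer_, n, length(ids))
  for (k in seq_along(ids)) {
    cell <- df[[ids[k]]]
    parts <- strsplit(cell, ":", fixed = TRUE)
    bad <- which(lengths(parts) != 2L)
    .assert(length(bad) == 0L, "malformed cell '%s' (marker %s, individual %s)",
            cell[bad[1]], df$marker_id[bad[1]], ids[k])
    ds <- vapply(parts, `[`, "", 1L)
    dp <- vapply(parts, `[`, "", 2L)
    bad <- which(!ds %in% c("0", "1", "2", "."))
    .assert(length(bad) == 0L, "dosage '%s' outside {0,1,2,.} (marker %s, individual %s)",
            ds[bad[1]], df$marker_id[bad[1]], ids[k])
    bad <- which(!grepl("^[0-9]+$", dp))
    .assert(length(bad) == 0L, "non-integer depth '%s' (marker %s, individual %s)",
            dp[bad[1]], df$marker_id[bad[1]], ids[k])
    dk <- rep(NA_integer_, n)
    dk[ds != "."] <- as.integer(ds[ds != "."])
    dosage[, k] <- dk
    depth[, k] <- as.integer(dp)
  }
  markers <- data.frame(marker_id = df$marker_id, tag_id = df$tag_id,
                        chrom = df$chrom_label, pos = as.numeric(df$pos_bp),
                        ref = df$ref, alt = df$alt, stringsAsFactors = FALSE)
  geno_matrix(markers, dosage, depth, ids)
}

#' Write a genotype matrix to TSV
#' @param gm a [geno_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path) {
  m <- gm$markers
  out <- data.frame(marker_id = m$marker_id, tag_id = m$tag_id,
                    chrom_label = m$chrom, pos_bp = format(m$pos, scientific = FALSE, trim = TRUE),
                    ref = m$ref, alt = m$alt, stringsAsFactors = FALSE,
                    check.names = FALSE)
  for (k in seq_along(gm$individuals)) {
    ds <- gm$dosage[, k]
    out[[gm$individuals[k]]] <-
      paste0(ifelse(is.na(ds), ".", ds), ":", gm$depth[, k])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype matrix from VCF
#'
#' Maps VCF `GT`/`DP` fields onto the same dosage/depth model as
#' [read_genotypes()].  Only biallelic records are accepted.  The
#' chromosome column must use this package's labels
#' (`proximal_chr7`/`distal_chr19`/`unplaced`); `INFO` field `TAG=` carries
#' the RADtag id (falling back to the marker id).  VCF POS is 1-based and
#' converted to the package's 0-based convention.
#'
#' @param path VCF file path.
#' @param ped a [pedigree()].
#' @return A [geno_matrix()].
#' @export
read_genotypes_vcf <- function(path, ped) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  .assert(!any(grepl(",", fix$ALT, fixed = TRUE)), "multi-allelic VCF records are not supported")
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  ids <- colnames(gt)
  unknown <- setdiff(ids, ped$id)
  .assert(length(unknown) == 0L, "VCF sample(s) not in pedigree: %s",
          paste(unknown, collapse = ", "))
  absent <- setdiff(ped$id, ids)
  .assert(length(absent) == 0L, "pedigree individual(s) missing from VCF: %s",
          paste(absent, collapse = ", "))
  gt_clean <- gsub("|", "/", gt, fixed = TRUE)
  dosage <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dosage[gt_clean %in% c("0/0")] <- 0L
  dosage[gt_clean %in% c("0/1", "1/0")] <- 1L
  dosage[gt_clean %in% c("1/1")] <- 2L
  dp[is.na(dp)] <- 0
  tag <- sub(".*TAG=([^;]+).*", "\\1", vcfR::getINFO(v))
  tag[is.na(tag) | tag == vcfR::getINFO(v)] <- NA
  id <- fix$ID
  id[is.na(id) | id == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(id) | id == "."]
  markers <- data.frame(marker_id = id,
                        tag_id = ifelse(is.na(tag), id, tag),
                        chrom = fix$CHROM,
                        pos = as.numeric(fix$POS) - 1,
                        ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  gm <- geno_matrix(markers, dosage, round(dp), ids)
  gm[, ped$id]
}

#' Construct a tag presence/absence matrix
#'
#' @param tags data frame with columns `tag_id`, `chrom`, `pos`.
#' @param presence logical matrix, tags x individuals.
#' @param individuals character vector of column ids.
#' @return Object of class `tag_presence`.
#' @export
tag_presence <- function(tags, presence, individuals) {
  tags <- as.data.frame(tags, stringsAsFactors = FALSE)[c("tag_id", "chrom", "pos")]
  presence <- as.matrix(presence)
  .assert(!anyDuplicated(tags$tag_id), "duplicate tag_id")
  .assert(nrow(presence) == nrow(tags) && ncol(presence) == length(individuals),
          "presence dimensions do not match tags x individuals")
  storage.mode(presence) <- "logical"
  dimnames(presence) <- list(tags$tag_id, individuals)
  structure(list(tags = tags, presence = presence,
                 individuals = as.character(individuals)),
            class = "tag_presence")
}

#' @export
print.tag_presence <- function(x, ...) {
  cat(sprintf("tag_presence: %d tags x %d individuals (%.2f%% present)\n",
              nrow(x$tags), length(x$individuals), 100 * mean(x$presence)))
  invisible(x)
}

#' Read/write a tag presence matrix (TSV: tag_id, chrom_label, pos_bp, then
#' one 0/1 column per individual).
#' @param path file path.
#' @return A [tag_presence()].
#' @export
read_presence <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  lead <- c("tag_id", "chrom_label", "pos_bp")
  .assert(all(lead %in% names(df)), "presence TSV missing column(s): %s",
          paste(setdiff(lead, names(df)), collapse = ", "))
  ids <- setdiff(names(df), lead)
  pres <- as.matrix(df[ids]) == 1
  tag_presence(data.frame(tag_id = as.character(df$tag_id), chrom = df$chrom_label,
                          pos = as.numeric(df$pos_bp), stringsAsFactors = FALSE),
               pres, ids)
}

#' @rdname read_presence
#' @param tp a [tag_presence()].
#' @export
write_presence <- function(tp, path) {
  out <- data.frame(tag_id = tp$tags$tag_id, chrom_label = tp$tags$chrom,
                    pos_bp = format(tp$tags$pos, scientific = FALSE, trim = TRUE),
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (k in seq_along(tp$individuals))
    out[[tp$individuals[k]]] <- as.integer(tp$presence[, k])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a genomic region as a BED line
#'
#' Coordinates are 0-based half-open, matching the package convention.
#'
#' @param chrom chromosome label.
#' @param start,end region bounds in bp; requires `0 <= start < end`.
#' @param name feature name (fourth BED column).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_region_bed <- function(chrom, start, end, name, path) {
  .assert(start >= 0, "start must be >= 0")
  .assert(start < end, "empty or inverted interval: start (%s) >= end (%s)",
          format(start, scientific = FALSE), format(end, scientific = FALSE))
  line <- paste(chrom, format(start, scientific = FALSE, trim = TRUE),
                format(end, scientific = FALSE, trim = TRUE), name, sep = "\t")
  writeLines(line, path)
  invisible(path)
}

#' Read a BED3+name file back as a data frame
#' @param path BED file path.
#' @return Data frame with columns `chrom`, `start`, `end`, `name`.
#' @export
read_region_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#")
  names(df) <- c("chrom", "start", "end", "name")[seq_len(ncol(df))]
  df$chrom <- as.character(df$chrom)
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  df
}
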