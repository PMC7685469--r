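#' Construct a validated pedigree of full-sib families
#'
#' A pedigree is a data frame with one row per individual and columns
#' `id`, `family_id`, `father_id`, `mother_id` and `sex`.  Parents have
#' `NA` for `father_id`/`mother_id`; offspring must reference a father and
#' a mother present in the same family.  A family has exactly one mother
#' but may have several sires (each offspring names exactly one); all
#' per-father computations in this package iterate over such sire-groups.
#'
#' @param df data frame with columns `id`, `family_id`, `father_id`,
#'   `mother_id`, `sex`.  Sex codes `M`, `F`, `male`, `female` are accepted
#'   case-insensitively; empty strings and `NA` mark absent parent ids.
#' @return An object of class `radlink_ped`: the normalised data frame with
#'   an extra `role` column (`father`, `mother` or `offspring`).
#' @seealso [read_pedigree()], [sire_groups()]
#' @export
pedigree <- function(df) {
  need <- c("id", "family_id", "father_id", "mother_id", "sex")
  .assert(all(need %in% names(df)), "pedigree is missing column(s): %s",
          paste(setdiff(need, names(df)), collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)[need]
  for (nm in need) df[[nm]] <- as.character(df[[nm]])
  df$father_id[!nzchar(df$father_id) | is.na(df$father_id)] <- NA_character_
  df$mother_id[!nzchar(df$mother_id) | is.na(df$mother_id)] <- NA_character_

  dup <- df$id[duplicated(df$id)]
  .assert(length(dup) == 0L, "duplicate individual id(s): %s",
          paste(unique(dup), collapse = ", "))

  sx <- tolower(df$sex)
  bad <- which(!sx %in% c("m", "f", "male", "female"))
  .assert(length(bad) == 0L,
          "unknown sex code %s for individual '%s' (row %d)",
          dQuote(df$sex[bad[1]]), df$id[bad[1]], bad[1])
  df$sex <- ifelse(sx %in% c("m", "male"), "M", "F")

  is_off <- !is.na(df$father_id) | !is.na(df$mother_id)
  bad <- which(is_off & (is.na(df$father_id) | is.na(df$mother_id)))
  .assert(length(bad) == 0L,
          "individual '%s' (row %d) names only one parent", df$id[bad[1]], bad[1])
  for (i in which(is_off)) {
    for (p in c("father_id", "mother_id")) {
      pid <- df[[p]][i]
      j <- match(pid, df$id)
      .assert(!is.na(j), "individual '%s' (row %d) cites absent parent '%s'",
              df$id[i], i, pid)
      .assert(df$family_id[j] == df$family_id[i],
              "parent '%s' of '%s' belongs to a different family", pid, df$id[i])
      .assert(df$sex[j] == if (p == "father_id") "M" else "F",
              "parent '%s' of '%s' has inconsistent sex for role %s",
              pid, df$id[i], p)
    }
  }

  df$role <- ifelse(is_off, "offspring",
                    ifelse(df$sex == "M", "father", "mother"))
  for (fam in unique(df$family_id)) {
    fd <- df[df$family_id == fam, ]
    .assert(sum(fd$role == "mother") == 1L,
            "family '%s' must have exactly one mother", fam)
    .assert(sum(fd$role == "father") >= 1L, "family '%s' has no father", fam)
    for (sire in fd$id[fd$role == "father"])
      .assert(any(fd$father_id == sire, na.rm = TRUE),
              "father '%s' in family '%s' has no offspring", sire, fam)
  }
  structure(df, class = c("radlink_ped", "data.frame"))
}

#' Read a pedigree from TSV
#'
#' Expects a tab-separated file with header columns `id`, `family_id`,
#' `father_id`, `mother_id`, `sex` (lines starting with `#` are comments).
#'
#' @param path file path.
#' @return A [pedigree()] object.
#' @export
read_pedigree <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", colClasses = "character")
  pedigree(df)
}

#' Write a pedigree to TSV
#' @param ped a [pedigree()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  out <- as.data.frame(ped)[c("id", "family_id", "father_id", "mother_id", "sex")]
  out[is.na(out)] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Enumerate sire-groups of a pedigree
#'
#' A sire-group is one father, the family's mother, and the offspring that
#' father sired.  Families with two sires contribute two groups sharing the
#' mother.  This is the analysis unit for QC, the segregation screen and
#' recombination maps.
#'
#' @param ped a [pedigree()] object.
#' @return A data frame with columns `unit_id`, `family_id`, `father_id`,
#'   `mother_id` and a list-column `offspring` of offspring id vectors.
#' @export
sire_groups <- function(ped) {
  stopifnot(inherits(ped, "radlink_ped"))
  units <- list()
  for (fam in unique(ped$family_id)) {
    fd <- ped[ped$family_id == fam, ]
    mother <- fd$id[fd$role == "mother"]
    sires <- fd$id[fd$role == "father"]
    multi <- length(sires) > 1L
    for (k in seq_along(sires)) {
      off <- fd$id[fd$role == "offspring" & fd$father_id == sires[k]]
      uid <- if (multi) paste0(fam, ".", sires[k]) else fam
      units[[length(units) + 1L]] <- data.frame(
        unit_id = uid, family_id = fam, father_id = sires[k],
        mother_id = mother, stringsAsFactors = FALSE)
      units[[length(units)]]$offspring <- list(off)
    }
  }
  do.call(rbind, units)
}

#' @export
print.radlink_ped <- function(x, ...) {
  fams <- unique(x$family_id)
  cat(sprintf("Pedigree: %d individuals in %d family(ies)\n", nrow(x), length(fams)))
  for (fam in fams) {
    fd <- x[x$family_id == fam, ]
    off <- fd[fd$role == "offspring", ]
    cat(sprintf("  family %s: %d sire(s), %d sons, %d daughters\n",
                fam, sum(fd$role == "father"),
                sum(off$sex == "M"), sum(off$sex == "F")))
  }
  invisible(x)
}

#' The default three-family study pedigree
#'
#' Three full-sib families totalling 65 individuals: family 1 with 21 sons
#' and 9 daughters, family 2 with two sires (5 sons + 1 daughter and
#' 4 sons + 3 daughters) sharing one mother, family 3 with 12 sons and
#' 3 daughters.
#'
#' @return A [pedigree()] object with 65 individuals.
#' @export
default_pedigree <- function() {
  rows <- list()
  add <- function(id, fam, fid, mid, sex)
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, family_id = fam, father_id = fid, mother_id = mid, sex = sex,
      stringsAsFactors = FALSE)
  fam_block <- function(fam, sires, counts) {
    # counts: list per sire of c(sons, daughters)
    mid <- paste0("F", fam, "_M")
    add(mid, fam, NA, NA, "F")
    for (k in seq_along(sires)) {
      fid <- sires[k]
      add(fid, fam, NA, NA, "M")
      ns <- counts[[k]][1]; nd <- counts[[k]][2]
      for (i in seq_len(ns))
        add(sprintf("%s_s%02d", fid, i), fam, fid, mid, "M")
      for (i in seq_len(nd))
        add(sprintf("%s_d%02d", fid, i), fam, fid, mid, "F")
    }
  }
  fam_block("1", "F1_P", list(c(21L, 9L)))
  fam_block("2", c("F2_P1", "F2_P2"), list(c(5L, 1L), c(4L, 3L)))
  fam_block("3", "F3_P", list(c(12L, 3L)))
  pedigree(do.call(rbind, rows))
}
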