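# Fixture builders used across test files.  All data is generated in code.

make_ped <- function(n_sons = 2, n_daughters = 1, fam = "1",
                     father = paste0("P", fam), mother = paste0("M", fam)) {
  rows <- data.frame(
    id = c(father, mother,
           if (n_sons) paste0(father, "_s", seq_len(n_sons)),
           if (n_daughters) paste0(father, "_d", seq_len(n_daughters))),
    family_id = fam,
    father_id = c(NA, NA, rep(father, n_sons + n_daughters)),
    mother_id = c(NA, NA, rep(mother, n_sons + n_daughters)),
    sex = c("M", "F", rep("M", n_sons), rep("F", n_daughters)),
    stringsAsFactors = FALSE)
  pedigree(rows)
}

# random genotype fixture: arbitrary dosages/depths, not necessarily Mendelian
rand_geno <- function(ped, n_markers = 10, p_missing = 0.1, max_depth = 30) {
  ids <- ped$id
  pos <- sort(sample.int(2e8, n_markers))
  markers <- data.frame(
    marker_id = sprintf("m%03d", seq_len(n_markers)),
    tag_id = sprintf("t%03d", seq_len(n_markers)),
    chrom = sample(c("proximal_chr7", "distal_chr19"), n_markers, replace = TRUE),
    pos = pos, ref = "A", alt = "T", stringsAsFactors = FALSE)
  dosage <- matrix(sample(c(0L, 1L, 2L), n_markers * length(ids), replace = TRUE),
                   n_markers, length(ids))
  dosage[matrix(runif(length(dosage)) < p_missing, n_markers)] <- NA_integer_
  depth <- matrix(sample.int(max_depth + 1L, length(dosage), replace = TRUE) - 1L,
                  n_markers, length(ids))
  geno_matrix(markers, dosage, depth, ids)
}

# minimal VCF 4.2 writer for reader cross-checks (GT and DP only)
write_fixture_vcf <- function(gm, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=TAG,Number=1,Type=String,Description=\"RADtag id\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", gm$individuals), collapse = "\t"))
  gt_of <- function(d) c("0/0", "0/1", "1/1")[d + 1L]
  lines <- vapply(seq_len(nrow(gm$markers)), function(i) {
    m <- gm$markers[i, ]
    cells <- vapply(seq_along(gm$individuals), function(k) {
      d <- gm$dosage[i, k]
      sprintf("%s:%d", if (is.na(d)) "./." else gt_of(d), gm$depth[i, k])
    }, "")
    paste(c(m$chrom, format(m$pos + 1, scientific = FALSE), m$marker_id,
            m$ref, m$alt, ".", "PASS", paste0("TAG=", m$tag_id),
            "GT:DP", cells), collapse = "\t")
  }, "")
  writeLines(c(hdr, lines), path)
}

# error-free simulation settings: saturating depth, no random dropout
ef_params <- function(...) {
  sim_params(depth_mean = 100, miss_rate = 0, ...)
}
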