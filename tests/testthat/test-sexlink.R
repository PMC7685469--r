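make_presence_fixture <- function(ped, pres_by_tag) {
  # pres_by_tag: list of logical vectors over ped$id
  tags <- data.frame(tag_id = names(pres_by_tag), chrom = "proximal_chr7",
                     pos = seq_along(pres_by_tag) * 1000,
                     stringsAsFactors = FALSE)
  tag_presence(tags, do.call(rbind, pres_by_tag), ped$id)
}

test_that("male-limited tag screen applies the 90% rule as an exact proportion", {
  # 46 males, 19 females as in the three-family study design
  ped <- default_pedigree()
  males <- ped$sex == "M"
  expect_equal(sum(males), 46)
  expect_equal(sum(!males), 19)
  pres <- list(
    all_males = males,                                   # 46/46, absent in females
    male42 = males & cumsum(males) <= 42,                # 42/46 = 0.913
    male41 = males & cumsum(males) <= 41,                # 41/46 = 0.891
    leaky = males | (!males & cumsum(!males) == 1))      # present in 1 female
  tp <- make_presence_fixture(ped, pres)
  got <- male_limited_tags(tp, ped)
  expect_setequal(got, c("all_males", "male42"))
  # raising the threshold never adds tags (monotonicity)
  prev <- male_limited_tags(tp, ped, 0.5)
  for (f in c(0.7, 0.9, 0.92, 1)) {
    cur <- male_limited_tags(tp, ped, f)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
  # exact rational comparison at an integer cutoff: 36/40 males is >= 0.9
  ped40 <- make_ped(39, 2, fam = "9")  # father + 39 sons = 40 males
  m40 <- ped40$sex == "M"
  expect_equal(sum(m40), 40)
  tp40 <- make_presence_fixture(ped40, list(
    exact = m40 & cumsum(m40) <= 36, below = m40 & cumsum(m40) <= 35))
  expect_equal(male_limited_tags(tp40, ped40), "exact")
})

test_that("female-limited screen is the sex-swapped mirror of the male screen", {
  set.seed(51)
  # two single-sire families (a two-sire family cannot be sex-swapped: the
  # mirror pedigree would need two mothers)
  ped <- pedigree(rbind(as.data.frame(make_ped(21, 9, "1")),
                        as.data.frame(make_ped(12, 3, "3"))))
  tags <- data.frame(tag_id = sprintf("t%03d", 1:200), chrom = "proximal_chr7",
                     pos = 1:200 * 1e5, stringsAsFactors = FALSE)
  pres <- matrix(runif(200 * nrow(ped)) > 0.2, 200, nrow(ped))
  tp <- tag_presence(tags, pres, ped$id)
  # swap sexes and parental roles
  swapped <- as.data.frame(ped)
  swapped$sex <- ifelse(ped$sex == "M", "F", "M")
  swapped <- pedigree(swapped[c("id", "family_id", "mother_id", "father_id", "sex")] |>
                        stats::setNames(c("id", "family_id", "father_id",
                                          "mother_id", "sex")))
  expect_identical(female_limited_tags(tp, swapped),
                   male_limited_tags(tp, ped))
  # error-free default simulation yields no female-limited tags
  sim <- simulate_dataset(ef_params(n_tags = 1000), seed = 52)
  expect_length(female_limited_tags(sim$presence, sim$pedigree), 0)
})

test_that("the four segregation criteria are each necessary", {
  ped <- make_ped(5, 3)
  base <- c(1, 0, rep(1, 5), rep(0, 3))  # father, mother, sons, daughters
  mk <- function(d) {
    markers <- data.frame(marker_id = "m", tag_id = "t", chrom = "proximal_chr7",
                          pos = 1000, ref = "A", alt = "T",
                          stringsAsFactors = FALSE)
    geno_matrix(markers, matrix(d, 1), matrix(20L, 1, 10), ped$id)
  }
  expect_equal(segregation_screen(mk(base), ped)[["1"]], "m")
  v <- base; v[3] <- 0   # one son homozygous
  expect_length(segregation_screen(mk(v), ped)[["1"]], 0)
  v <- base; v[2] <- 1   # mother heterozygous
  expect_length(segregation_screen(mk(v), ped)[["1"]], 0)
  v <- base; v[1] <- 2   # father homozygous
  expect_length(segregation_screen(mk(v), ped)[["1"]], 0)
  v <- base; v[8] <- 2   # daughter homozygous for the non-maternal allele
  expect_length(segregation_screen(mk(v), ped)[["1"]], 0)
  v <- base; v[2] <- 2; v[8:10] <- 2; # mother hom alt, daughters match her
  expect_equal(segregation_screen(mk(v), ped)[["1"]], "m")
  v <- base; v[5] <- NA  # missing call fails conservatively
  expect_length(segregation_screen(mk(v), ped)[["1"]], 0)
})

test_that("exhaustive enumeration over a 2-son/1-daughter family finds exactly 2 passing configurations", {
  ped <- make_ped(2, 1)
  markers <- data.frame(marker_id = "m", tag_id = "t", chrom = "proximal_chr7",
                        pos = 1, ref = "A", alt = "T", stringsAsFactors = FALSE)
  passing <- list()
  for (fa in 0:2) for (mo in 0:2) for (s1 in 0:2) for (s2 in 0:2) for (dg in 0:2) {
    gm <- geno_matrix(markers, matrix(c(fa, mo, s1, s2, dg), 1),
                      matrix(20L, 1, 5), ped$id)
    if (length(segregation_screen(gm, ped)[["1"]]))
      passing[[length(passing) + 1]] <- c(fa, mo, s1, s2, dg)
  }
  expect_length(passing, 2)
  expect_setequal(vapply(passing, paste, "", collapse = ""),
                  c("10110", "12112"))
})

test_that("segregation screen matches the brute-force oracle on random fixtures", {
  set.seed(53)
  for (rep in 1:60) {
    ped <- make_ped(sample(1:6, 1), sample(0:4, 1))
    gm <- rand_geno(ped, n_markers = sample(5:20, 1), p_missing = 0.15)
    expect_identical(segregation_screen(gm, ped), oracle_seg_screen(gm, ped))
  }
})

test_that("windowed heterozygosity computes per-window ratios over double-called sites", {
  ped <- make_ped(1, 0)
  n <- 10
  markers <- data.frame(marker_id = sprintf("m%02d", 1:n), tag_id = sprintf("t%02d", 1:n),
                        chrom = "proximal_chr7",
                        pos = c(seq(2.0e6, 2.9e6, length.out = n)),
                        ref = "A", alt = "T", stringsAsFactors = FALSE)
  dos_father <- c(rep(1, 3), rep(0, 7))
  dosage <- cbind(dos_father, rep(0, n), rep(0, n))
  depth <- matrix(20L, n, 3)
  gm <- geno_matrix(markers, dosage, depth, ped$id)
  prof <- window_heterozygosity(gm, ped$id[1], ped$id[2])
  w <- prof[prof$start == 2e6, ]
  expect_equal(w$n_sites, 10)
  expect_equal(w$prop_het, 0.3)
  expect_true(all(prof$n_sites[prof$start != 2e6] == 0))
  expect_true(all(is.na(prof$prop_het[prof$n_sites == 0])))
  # sites with low depth in the partner are excluded
  depth[, 2] <- 5L
  gm2 <- geno_matrix(markers, dosage, depth, ped$id)
  prof2 <- window_heterozygosity(gm2, ped$id[1], ped$id[2])
  expect_true(all(prof2$n_sites == 0))
  # an all-homozygous parent has prop_het 0 in every non-empty window
  prof3 <- window_heterozygosity(gm, ped$id[2], ped$id[1])
  expect_true(all(prof3$prop_het[prof3$n_sites > 0] == 0))
})

test_that("simulated mothers lose heterozygosity proximally but not distally", {
  sim <- simulate_dataset(ef_params(), seed = 54)
  u <- sire_groups(sim$pedigree)
  gm <- sim$genotypes
  B <- sim$truth$B
  for (i in 1:2) {
    prof <- window_heterozygosity(gm, u$mother_id[i], u$father_id[i])
    prox <- prof$chrom == "proximal_chr7" & prof$end <= B & prof$n_sites > 0
    dist <- prof$chrom == "distal_chr19" & prof$n_sites > 0
    expect_lt(mean(prof$prop_het[prox]), mean(prof$prop_het[dist]))
  }
})

test_that("the boundary is the most distal proximal-homolog evidence marker", {
  markers <- data.frame(
    marker_id = c("a", "b", "c", "d"),
    chrom = c("proximal_chr7", "proximal_chr7", "proximal_chr7", "distal_chr19"),
    pos = c(10e6, 50e6, 83.5e6, 5e6), stringsAsFactors = FALSE)
  b <- estimate_boundary(c("a", "b", "c"), markers)
  expect_equal(b$pos, 83.5e6)
  expect_equal(b$id, "c")
  expect_equal(b$n_evidence, 3L)
  expect_equal(b$n_distal_homolog, 0L)
  # empty evidence -> none
  e <- estimate_boundary(character(0), markers)
  expect_true(is.na(e$pos))
  # invariant to permutations of the evidence order
  set.seed(55)
  for (i in 1:5)
    expect_equal(estimate_boundary(sample(c("a", "b", "c")), markers)$pos, 83.5e6)
  # distal-homolog evidence is counted, not used for the position
  b2 <- estimate_boundary(c("a", "d"), markers)
  expect_equal(b2$pos, 10e6)
  expect_equal(b2$n_distal_homolog, 1L)
})

test_that("sexlink_scan ties screens together and reports a per-family table", {
  sim <- simulate_dataset(ef_params(n_tags = 1200), seed = 56)
  fit <- sexlink_scan(sim$genotypes, sim$presence, sim$pedigree)
  tab <- summary(fit)
  expect_true(all(c("approach", "family", "fully_sex_linked", "most_distal_Mbp")
                  %in% names(tab)))
  expect_equal(nrow(tab), 4)  # tag screen + three families
  expect_true(all(tab$fully_sex_linked > 0))
  b <- fit$boundary[["segregation.all"]]
  expect_lte(b$pos, sim$truth$B)
  out <- withr::local_tempdir()
  write_scan_outputs(fit, out)
  expect_true(all(file.exists(file.path(out,
    c("male_limited.tsv", "female_limited.tsv", "seg_linked.tsv",
      "het_windows.tsv", "boundary.bed")))))
  bed <- read_region_bed(file.path(out, "boundary.bed"))
  expect_equal(bed$end, b$pos)
})
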