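#' Parameters of the neo-XY meiosis and RAD genotyping simulator
#'
#' The simulated neo-sex chromosome concatenates a proximal arm (homologous
#' to reference chr7, length `L_prox`) and a distal arm (homologous to
#' chr19, length `L_dist`) on one axis.  In males, crossovers are excluded
#' from `[0, B)` (the non-recombining, fully sex-linked segment) and at
#' least one crossover is drawn distally (`male_co_counts` has no zero
#' class by default, reflecting the obligate chiasma of the neo-PAR).  In
#' females the whole axis recombines.
#'
#' @param L_prox proximal arm length in bp (default 145 Mbp).
#' @param L_dist distal arm length in bp (default 61 Mbp).
#' @param B male non-recombining boundary in bp on the proximal arm
#'   (default 83.5 Mbp); crossovers in males occur only in `[B, L_prox+L_dist)`.
#' @param n_tags number of simulated RADtags (default 5000).
#' @param snps_per_tag SNPs per tag (default 1).
#' @param p_xy_div probability that a marker in `[0, B)` carries a fixed
#'   X-Y allelic difference (default 0.05); such markers are truly
#'   sex-linked.
#' @param pi_prox_X per-site polymorphism of founder X haplotypes in
#'   `[0, B)` (default 5e-4; the X-specific segment is nearly monomorphic).
#' @param pi_background per-site polymorphism elsewhere (default 0.02).
#' @param p_y_null probability that a tag in `[0, B)` is Y-limited, i.e.
#'   carried only by Y haplotypes (default 0.01).
#' @param male_co_counts named probability vector over male crossover
#'   counts in the recombining region (default `c("1" = .98, "2" = .02)`,
#'   mean 1.02 to match observed MLH1 focus counts).
#' @param female_co_mean mean crossovers per female meiosis over the whole
#'   axis (default 1.1; Poisson counts).
#' @param depth_mean mean per-tag sequencing depth (default 20).
#' @param presence_min_depth minimum depth for a tag to be scored present
#'   (default 3).
#' @param miss_rate extra random tag dropout rate (default 0.01).
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(L_prox = 145e6, L_dist = 61e6, B = 83.5e6,
                       n_tags = 5000L, snps_per_tag = 1L,
                       p_xy_div = 0.05, pi_prox_X = 5e-4,
                       pi_background = 0.02, p_y_null = 0.01,
                       male_co_counts = c("1" = 0.98, "2" = 0.02),
                       female_co_mean = 1.1,
                       depth_mean = 20, presence_min_depth = 3L,
                       miss_rate = 0.01) {
  p <- list(L_prox = L_prox, L_dist = L_dist, B = B,
            n_tags = as.integer(n_tags), snps_per_tag = as.integer(snps_per_tag),
            p_xy_div = p_xy_div, pi_prox_X = pi_prox_X,
            pi_background = pi_background, p_y_null = p_y_null,
            male_co_counts = male_co_counts, female_co_mean = female_co_mean,
            depth_mean = depth_mean,
            presence_min_depth = as.integer(presence_min_depth),
            miss_rate = miss_rate)
  .assert(p$L_prox > 0 && p$L_dist > 0, "arm lengths must be positive")
  .assert(p$B > 0 && p$B < p$L_prox, "B must satisfy 0 < B < L_prox")
  for (nm in c("p_xy_div", "pi_prox_X", "pi_background", "p_y_null", "miss_rate"))
    .assert(p[[nm]] >= 0 && p[[nm]] <= 1, "%s must be in [0,1]", nm)
  .assert(p$n_tags >= 1 && p$snps_per_tag >= 1, "n_tags and snps_per_tag must be >= 1")
  .assert(abs(sum(p$male_co_counts) - 1) < 1e-9, "male_co_counts must sum to 1")
  .assert(!is.null(names(p$male_co_counts)) &&
            !anyNA(suppressWarnings(as.integer(names(p$male_co_counts)))),
          "male_co_counts must be named by integer crossover counts")
  .assert(p$female_co_mean >= 0, "female_co_mean must be >= 0")
  .assert(p$depth_mean > 0, "depth_mean must be > 0")
  structure(p, class = "sim_params")
}

# total axis length
.L_total <- function(params) params$L_prox + params$L_dist

# marker/tag layout on the concatenated axis; positions are reported
# homolog-locally (distal arm positions restart at 0 on chr19)
.make_layout <- function(params) {
  tag_axis <- sort(floor(stats::runif(params$n_tags, 0, .L_total(params) - 200)))
  tag_axis <- unique(tag_axis)
  n <- length(tag_axis)
  tag_id <- sprintf("tag%05d", seq_len(n))
  tag_chrom <- ifelse(tag_axis < params$L_prox, "proximal_chr7", "distal_chr19")
  tag_pos <- ifelse(tag_axis < params$L_prox, tag_axis, tag_axis - params$L_prox)
  s <- params$snps_per_tag
  idx <- rep(seq_len(n), each = s)
  off <- rep(seq_len(s) - 1L, times = n) * 7L  # within-tag SNP offsets
  markers <- data.frame(
    marker_id = sprintf("%s_snp%d", tag_id[idx], rep(seq_len(s), times = n)),
    tag_id = tag_id[idx],
    chrom = tag_chrom[idx],
    pos = tag_pos[idx] + off,
    ref = "A", alt = "T",
    axis_pos = tag_axis[idx] + off,
    stringsAsFactors = FALSE)
  list(tags = data.frame(tag_id = tag_id, chrom = tag_chrom, pos = tag_pos,
                         axis_pos = tag_axis, stringsAsFactors = FALSE),
       markers = markers)
}

#' Simulate founder haplotypes for a pedigree
#'
#' Draws marker/tag positions and founder haplotypes: each father gets one
#' X and one Y haplotype, each mother two X haplotypes.  In `[0, B)` all X
#' haplotypes are identical at a site with probability `1 - pi_prox_X`; a
#' marker carries a fixed X-Y difference (and is flagged truly sex-linked)
#' with probability `p_xy_div`.  Outside `[0, B)` X and Y haplotypes are
#' drawn from a common pool at polymorphism `pi_background`.  Proximal
#' tags are flagged Y-limited with probability `p_y_null`.
#'
#' Uses the current R RNG state; call `set.seed()` for reproducibility.
#'
#' @param params a [sim_params()] object.
#' @param ped a [pedigree()]; haplotypes are drawn for its parents.
#' @return A list with elements `markers`, `tags` (layout tables including
#'   the internal `axis_pos` column), `haps` (named list: per parent a
#'   2-row haplotype matrix, rows `X`,`Y` for fathers and `X1`,`X2` for
#'   mothers) and `truth` (`truly_sex_linked` per marker,
#'   `truly_y_limited` per tag, `B`).
#' @export
simulate_founders <- function(params, ped = default_pedigree()) {
  stopifnot(inherits(params, "sim_params"), inherits(ped, "radlink_ped"))
  lay <- .make_layout(params)
  mk <- lay$markers
  n <- nrow(mk)
  prox <- mk$axis_pos < params$B

  y_null <- lay$tags$axis_pos < params$B &
    stats::runif(nrow(lay$tags)) < params$p_y_null
  on_ynull <- y_null[match(mk$tag_id, lay$tags$tag_id)]

  # markers on Y-limited (X-null) tags are hemizygous and cannot carry an
  # X-Y allelic difference: the two truth classes partition
  div <- prox & !on_ynull & stats::runif(n) < params$p_xy_div
  xpoly <- prox & !div & stats::runif(n) < params$pi_prox_X
  bgpoly <- !prox & stats::runif(n) < params$pi_background

  parents <- ped[ped$role %in% c("father", "mother"), ]
  haps <- list()
  for (i in seq_len(nrow(parents))) {
    id <- parents$id[i]
    h <- matrix(0L, 2L, n)
    rownames(h) <- if (parents$sex[i] == "M") c("X", "Y") else c("X1", "X2")
    is_y <- rownames(h) == "Y"
    for (r in 1:2) {
      a <- integer(n)
      a[div] <- if (is_y[r]) 1L else 0L
      a[xpoly] <- stats::rbinom(sum(xpoly), 1L, 0.5)
      a[bgpoly] <- stats::rbinom(sum(bgpoly), 1L, 0.5)
      h[r, ] <- a
    }
    haps[[id]] <- h
  }

  truth <- list(
    truly_sex_linked = stats::setNames(div, mk$marker_id),
    truly_y_limited = stats::setNames(y_null, lay$tags$tag_id),
    B = params$B)
  list(markers = mk, tags = lay$tags, haps = haps, truth = truth)
}

# autosomal founders: every parent carries two ordinary homologs from a
# common pool; nothing is sex-linked
.simulate_founders_autosomal <- function(params, ped) {
  lay <- .make_layout(params)
  mk <- lay$markers
  n <- nrow(mk)
  poly <- stats::runif(n) < params$pi_background
  parents <- ped[ped$role %in% c("father", "mother"), ]
  haps <- list()
  for (i in seq_len(nrow(parents))) {
    h <- matrix(0L, 2L, n, dimnames = list(c("A1", "A2"), NULL))
    for (r in 1:2) h[r, poly] <- stats::rbinom(sum(poly), 1L, 0.5)
    haps[[parents$id[i]]] <- h
  }
  truth <- list(
    truly_sex_linked = stats::setNames(rep(FALSE, n), mk$marker_id),
    truly_y_limited = stats::setNames(rep(FALSE, nrow(lay$tags)), lay$tags$tag_id),
    B = params$B)
  list(markers = mk, tags = lay$tags, haps = haps, truth = truth)
}

#' Simulate one gamete of a parent
#'
#' Chiasmata form at the bivalent level: in males their count is drawn
#' from `male_co_counts` (the distribution of MLH1 foci per spermatocyte;
#' no zero class by default, reflecting the obligate chiasma) with
#' positions uniform on `[B, L_prox+L_dist)`; in females the count is
#' Poisson(`female_co_mean`) with positions uniform over the whole axis.
#' Each chiasma involves two of the four chromatids, so the transmitted
#' chromatid realises each one as a crossover independently with
#' probability 1/2 — recombinant fractions therefore never exceed the
#' Mendelian 50%.  The gamete's identity at position 0 (where the
#' ancestral sex-determining region is attached) is the transmitted sex
#' chromosome, Y-bearing gametes producing sons.
#'
#' @param haps 2-row haplotype matrix (rows `X`,`Y` or `X1`,`X2`; any two
#'   homolog names in autosomal mode).
#' @param parent_sex `"male"` or `"female"`.
#' @param params a [sim_params()].
#' @param axis_pos marker positions on the concatenated axis.
#' @param force_start optionally force the starting haplotype row name
#'   (used to condition a paternal gamete on offspring sex).
#' @param region `"neo_sex"` (default) applies the male recombination
#'   suppression and sex transmission; `"autosomal"` recombines over the
#'   whole axis with transmission independent of offspring sex.
#' @return List with `hap` (allele vector), `transmitted` (`"X"`, `"Y"` or
#'   `NA` for female gametes), `crossovers` (sorted axis positions of the
#'   crossovers realised in this gamete) and `chiasmata` (positions at the
#'   bivalent level).
#' @export
simulate_gamete <- function(haps, parent_sex, params, axis_pos,
                            force_start = NULL, region = c("neo_sex", "autosomal")) {
  parent_sex <- match.arg(parent_sex, c("male", "female"))
  region <- match.arg(region)
  L <- .L_total(params)
  if (parent_sex == "male") {
    k <- as.integer(sample(names(params$male_co_counts), 1L,
                           prob = params$male_co_counts))
    if (region == "neo_sex") {
      stopifnot(all(rownames(haps) == c("X", "Y")))
      chi <- sort(stats::runif(k, params$B, L))
      start <- if (is.null(force_start)) sample(c("X", "Y"), 1L) else force_start
      transmitted <- start
    } else {
      # autosomal bivalent: chiasmata anywhere, transmission carries no
      # sex information
      chi <- sort(stats::runif(k, 0, L))
      start <- if (is.null(force_start)) sample(rownames(haps), 1L) else force_start
      transmitted <- NA_character_
    }
  } else {
    k <- stats::rpois(1L, params$female_co_mean)
    chi <- sort(stats::runif(k, 0, L))
    start <- if (is.null(force_start)) sample(rownames(haps), 1L) else force_start
    transmitted <- NA_character_
    if (region == "neo_sex") stopifnot(all(rownames(haps) == c("X1", "X2")))
  }
  co <- chi[stats::runif(length(chi)) < 0.5]  # chromatid realisation
  seg <- findInterval(axis_pos, co) %% 2L  # 0 = starting haplotype
  i_start <- match(start, rownames(haps))
  i_other <- setdiff(1:2, i_start)
  hap <- ifelse(seg == 0L, haps[i_start, ], haps[i_other, ])
  list(hap = as.integer(hap), transmitted = transmitted, crossovers = co,
       chiasmata = chi)
}

#' Simulate a full RAD-seq dataset for a pedigree
#'
#' Offspring genotypes are unions of simulated parental gametes; the
#' paternal gamete is conditioned on the recorded offspring sex (sons
#' receive the Y).  Per-tag depth is Poisson(`depth_mean`) (halved for
#' hemizygous Y-limited tags); a tag is present in an individual iff its
#' depth reaches `presence_min_depth`, Y-limited tags are absent from
#' X-only individuals, and extra dropout occurs at `miss_rate`.  Calls on
#' absent tags are missing.
#'
#' @param params a [sim_params()].
#' @param ped a [pedigree()] (default: the three-family study pedigree).
#' @param seed optional integer seed (`set.seed` is called when given).
#' @param chromosome_type `"neo_sex"` (default) simulates the neo-sex
#'   chromosome; `"autosomal"` simulates an ordinary autosome of the same
#'   length in the same pedigree — all founder haplotypes drawn from a
#'   common pool at `pi_background`, chiasmata anywhere, transmission
#'   independent of offspring sex; `"unlinked"` makes every marker
#'   segregate independently (RADtags scattered over many autosomes), the
#'   textbook Mendelian null for screen specificity — no marker is
#'   sex-linked by construction and trials are independent across markers.
#' @return An object of class `sim_dataset`: list with `genotypes`
#'   ([geno_matrix()]), `presence` ([tag_presence()]), `truth` (marker and
#'   tag flags, boundary, per-gamete crossovers), `pedigree`, `params`.
#' @export
simulate_dataset <- function(params = sim_params(), ped = default_pedigree(),
                             seed = NULL,
                             chromosome_type = c("neo_sex", "autosomal",
                                                 "unlinked")) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(params, "sim_params"))
  chromosome_type <- match.arg(chromosome_type)
  fo <- if (chromosome_type == "neo_sex") simulate_founders(params, ped)
        else .simulate_founders_autosomal(params, ped)
  mk <- fo$markers
  n_mark <- nrow(mk)
  ids <- ped$id
  n_ind <- length(ids)
  axis <- mk$axis_pos

  dosage <- matrix(NA_integer_, n_mark, n_ind, dimnames = list(mk$marker_id, ids))
  pat_allele <- matrix(NA_integer_, n_mark, n_ind)  # paternal-gamete allele
  co_rec <- list()

  for (i in seq_len(n_ind)) {
    ind <- ped[i, ]
    if (ind$role != "offspring") {
      dosage[, i] <- fo$haps[[ind$id]][1, ] + fo$haps[[ind$id]][2, ]
      if (ind$role == "father" && chromosome_type == "neo_sex")
        pat_allele[, i] <- fo$haps[[ind$id]]["Y", ]
      next
    }
    if (chromosome_type == "unlinked") {
      # each marker on its own chromosome: per-marker iid Mendelian draws
      fh <- fo$haps[[ind$father_id]]; mh <- fo$haps[[ind$mother_id]]
      pick_f <- 1L + (stats::runif(n_mark) < 0.5)
      pick_m <- 1L + (stats::runif(n_mark) < 0.5)
      pat <- list(hap = fh[cbind(pick_f, seq_len(n_mark))],
                  transmitted = NA_character_, crossovers = numeric(0))
      mat <- list(hap = mh[cbind(pick_m, seq_len(n_mark))],
                  transmitted = NA_character_, crossovers = numeric(0))
    } else {
      pat <- simulate_gamete(fo$haps[[ind$father_id]], "male", params, axis,
                             force_start = if (chromosome_type == "neo_sex") {
                               if (ind$sex == "M") "Y" else "X"
                             } else NULL,
                             region = if (chromosome_type == "neo_sex")
                               "neo_sex" else "autosomal")
      mat <- simulate_gamete(fo$haps[[ind$mother_id]], "female", params, axis,
                             region = if (chromosome_type == "neo_sex")
                               "neo_sex" else "autosomal")
    }
    dosage[, i] <- pat$hap + mat$hap
    pat_allele[, i] <- pat$hap
    co_rec[[length(co_rec) + 1L]] <- data.frame(
      offspring = ind$id, parent = ind$father_id, meiosis = "paternal",
      transmitted = pat$transmitted,
      crossovers = I(list(pat$crossovers)), stringsAsFactors = FALSE)
    co_rec[[length(co_rec) + 1L]] <- data.frame(
      offspring = ind$id, parent = ind$mother_id, meiosis = "maternal",
      transmitted = NA_character_,
      crossovers = I(list(mat$crossovers)), stringsAsFactors = FALSE)
  }
  crossovers <- do.call(rbind, co_rec)

  # sequencing depth per tag x individual
  n_tag <- nrow(fo$tags)
  carries_y <- ped$sex == "M"
  y_null <- fo$truth$truly_y_limited
  depth_tag <- matrix(stats::rpois(n_tag * n_ind, params$depth_mean), n_tag, n_ind)
  if (any(y_null)) {
    # hemizygous tags: half coverage in carriers, zero in X-only individuals
    depth_tag[y_null, carries_y] <-
      stats::rpois(sum(y_null) * sum(carries_y), params$depth_mean / 2)
    depth_tag[y_null, !carries_y] <- 0L
  }
  if (params$miss_rate > 0) {
    drop <- matrix(stats::runif(n_tag * n_ind) < params$miss_rate, n_tag, n_ind)
    depth_tag[drop] <- 0L
  }
  present <- depth_tag >= params$presence_min_depth

  tag_idx <- match(mk$tag_id, fo$tags$tag_id)
  depth <- depth_tag[tag_idx, , drop = FALSE]
  # Y-limited tags read as hemizygous: observed genotype is the doubled Y
  # allele in Y carriers, missing elsewhere
  ynull_marker <- y_null[tag_idx]
  if (any(ynull_marker)) {
    for (i in seq_len(n_ind)) {
      if (carries_y[i]) {
        dosage[ynull_marker, i] <- 2L * pat_allele[ynull_marker, i]
      } else {
        dosage[ynull_marker, i] <- NA_integer_
      }
    }
  }
  dosage[!present[tag_idx, , drop = FALSE]] <- NA_integer_

  gm <- geno_matrix(mk[c("marker_id", "tag_id", "chrom", "pos", "ref", "alt")],
                    dosage, depth, ids)
  tp <- tag_presence(fo$tags[c("tag_id", "chrom", "pos")], present, ids)
  truth <- c(fo$truth, list(crossovers = crossovers, params = params))
  structure(list(genotypes = gm, presence = tp, truth = truth,
                 pedigree = ped, params = params),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Simulated RAD-seq family dataset\n")
  print(x$pedigree)
  print(x$genotypes)
  cat(sprintf("  truly sex-linked markers: %d; Y-limited tags: %d; B = %.1f Mbp\n",
              sum(x$truth$truly_sex_linked), sum(x$truth$truly_y_limited),
              x$truth$B / 1e6))
  invisible(x)
}

#' Simulate MLH1 focus positions along the neo-sex chromosome arm
#'
#' Draws per-cell crossover (focus) counts and positions from the same
#' meiotic model as [simulate_gamete()] and expresses positions as
#' fractions of total arm length, mimicking measured distances from the
#' centromere on synaptonemal-complex spreads.
#'
#' @param params a [sim_params()].
#' @param n_cells number of cells (>= 1).
#' @param sex `"male"` or `"female"` meiosis.
#' @param label chromosome-class label for the dataset.
#' @return A [foci_dataset()] with unit arm length.
#' @export
simulate_foci <- function(params, n_cells, sex = c("male", "female"),
                          label = "neo-PAR") {
  sex <- match.arg(sex)
  .assert(n_cells >= 1, "n_cells must be >= 1")
  L <- .L_total(params)
  cells <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    if (sex == "male") {
      k <- as.integer(sample(names(params$male_co_counts), 1L,
                             prob = params$male_co_counts))
      pos <- stats::runif(k, params$B, L) / L
    } else {
      k <- stats::rpois(1L, params$female_co_mean)
      pos <- stats::runif(k, 0, L) / L
    }
    cells[[i]] <- list(cell_id = sprintf("cell%05d", i), arm_length = 1,
                       foci = sort(pos))
  }
  foci_dataset(cells, label = label)
}

#' Write a simulated dataset to disk
#'
#' Writes the genotype TSV, presence TSV, pedigree TSV and a `truth.json`
#' holding parameters, per-marker/tag truth flags and per-gamete crossover
#' positions.
#'
#' @param sim a `sim_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genotypes(sim$genotypes, file.path(dir, "genotypes.tsv"))
  write_presence(sim$presence, file.path(dir, "presence.tsv"))
  write_pedigree(sim$pedigree, file.path(dir, "pedigree.tsv"))
  tr <- sim$truth
  truth <- list(
    params = unclass(sim$params),
    B = tr$B,
    truly_sex_linked = names(which(tr$truly_sex_linked)),
    truly_y_limited = names(which(tr$truly_y_limited)),
    crossovers = lapply(seq_len(nrow(tr$crossovers)), function(i) list(
      offspring = tr$crossovers$offspring[i],
      parent = tr$crossovers$parent[i],
      meiosis = tr$crossovers$meiosis[i],
      positions = tr$crossovers$crossovers[[i]])))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
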