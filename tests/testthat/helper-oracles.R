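# Independent brute-force implementations used as oracles.  Deliberately
# written as plain loops over rows/individuals, sharing no code with the
# package internals.

oracle_qc_retained <- function(gm, ped, cfg) {
  units <- sire_groups(ped)
  out <- list()
  for (u in seq_len(nrow(units))) {
    off <- units$offspring[[u]]
    members <- c(units$father_id[u], units$mother_id[u], off)
    keep <- character(0)
    for (i in seq_len(nrow(gm$markers))) {
      is_pres <- function(id) {
        d <- gm$dosage[i, id]
        !is.na(d) && gm$depth[i, id] >= cfg$min_depth
      }
      if (cfg$presence_rule == "parents_and_all_offspring") {
        ok <- all(vapply(members, is_pres, TRUE))
      } else {
        ok <- sum(vapply(off, is_pres, TRUE)) >= ceiling(length(off) / 2)
      }
      if (!ok) next
      n_alt <- sum(vapply(members, function(id)
        if (is_pres(id)) gm$dosage[i, id] else 0L, 0L))
      n_tot <- 2L * sum(vapply(members, is_pres, TRUE))
      f <- if (n_tot > 0) n_alt / n_tot else 0
      if (min(f, 1 - f) >= cfg$min_maf) keep <- c(keep, gm$markers$marker_id[i])
    }
    out[[units$unit_id[u]]] <- keep
  }
  out
}

oracle_informative <- function(gm, parent, partner) {
  ids <- character(0)
  for (i in seq_len(nrow(gm$markers))) {
    fo <- gm$dosage[i, parent]; ot <- gm$dosage[i, partner]
    if (!is.na(fo) && !is.na(ot) && fo == 1 && (ot == 0 || ot == 2))
      ids <- c(ids, gm$markers$marker_id[i])
  }
  ids
}

oracle_seg_screen <- function(gm, ped) {
  units <- sire_groups(ped)
  out <- list()
  for (u in seq_len(nrow(units))) {
    off <- units$offspring[[u]]
    sex <- ped$sex[match(off, ped$id)]
    keep <- character(0)
    for (i in seq_len(nrow(gm$markers))) {
      fa <- gm$dosage[i, units$father_id[u]]
      mo <- gm$dosage[i, units$mother_id[u]]
      if (is.na(fa) || fa != 1) next
      if (is.na(mo) || mo == 1) next
      ok <- TRUE
      for (k in seq_along(off)) {
        d <- gm$dosage[i, off[k]]
        if (is.na(d)) { ok <- FALSE; break }
        if (sex[k] == "M" && d != 1) { ok <- FALSE; break }
        if (sex[k] == "F" && d != mo) { ok <- FALSE; break }
      }
      if (ok) keep <- c(keep, gm$markers$marker_id[i])
    }
    out[[units$unit_id[u]]] <- keep
  }
  out
}

# groups and cumulative Kosambi positions recomputed by direct looping over
# a phase-aligned transmission matrix
oracle_map <- function(seg) {
  n <- nrow(seg)
  group <- integer(n); cm <- numeric(n)
  group[1] <- 1L
  for (j in 2:n) {
    same <- all(seg[j, ] == seg[j - 1, ])
    group[j] <- group[j - 1] + !same
    r <- min(mean(seg[j, ] != seg[j - 1, ]), 0.5 - 1e-12)  # same guard as the map
    cm[j] <- cm[j - 1] + if (same) 0 else 25 * log((1 + 2 * r) / (1 - 2 * r))
  }
  list(group = group, cM = cm)
}

# exhaustive phase search: minimum total crossovers over all 2^n marker
# orientations (first marker anchored)
oracle_min_crossovers <- function(tr) {
  n <- nrow(tr)
  best <- Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    flips <- c(FALSE, as.logical(bitwAnd(bitwShiftR(mask, 0:(n - 2)), 1L)))
    seg <- tr
    seg[flips, ] <- 1 - seg[flips, ]
    total <- 0
    for (k in seq_len(ncol(seg)))
      total <- total + sum(seg[-1, k] != seg[-n, k])
    best <- min(best, total)
  }
  best
}
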