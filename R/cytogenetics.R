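#' Per-cell MLH1 focus measurements along a chromosome arm
#'
#' Each cell records the arm length and the measured distances of MLH1
#' foci (class-I crossover marks on the synaptonemal complex) from the
#' centromere, in the same measurement units.
#'
#' @param cells list of lists with elements `cell_id`, `arm_length` (> 0)
#'   and `foci` (numeric positions in `[0, arm_length]`).
#' @param label chromosome-class label (e.g. `"neo-PAR"`, `"autosomal arm"`).
#' @return Object of class `foci_dataset`.
#' @export
foci_dataset <- function(cells, label = "unlabelled") {
  for (c in cells) {
    .assert(!is.null(c$cell_id) && !is.null(c$arm_length), "malformed cell record")
    .assert(c$arm_length > 0, "arm_length must be > 0 (cell %s)", c$cell_id)
    .assert(all(c$foci >= 0 & c$foci <= c$arm_length),
            "focus position outside [0, arm_length] in cell %s", c$cell_id)
  }
  structure(list(cells = cells, label = label), class = "foci_dataset")
}

#' @export
print.foci_dataset <- function(x, ...) {
  counts <- vapply(x$cells, function(c) length(c$foci), 0L)
  cat(sprintf("foci_dataset '%s': %d cells, %d foci (mean %.2f per cell)\n",
              x$label, length(x$cells), sum(counts), mean(counts)))
  invisible(x)
}

#' Read MLH1 focus measurements from TSV
#'
#' Expects columns `cell_id`, `label`, `arm_length`, `foci` (comma-separated
#' positions from the centromere; empty = no focus).
#'
#' @param path file path.
#' @return Named list of [foci_dataset()] objects, one per label.
#' @export
read_foci <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", colClasses = "character")
  need <- c("cell_id", "label", "arm_length", "foci")
  .assert(all(need %in% names(df)), "foci TSV missing column(s): %s",
          paste(setdiff(need, names(df)), collapse = ", "))
  out <- list()
  for (lab in unique(df$label)) {
    sub <- df[df$label == lab, ]
    cells <- lapply(seq_len(nrow(sub)), function(i) {
      f <- sub$foci[i]
      pos <- if (is.na(f) || !nzchar(f)) numeric(0) else
        as.numeric(strsplit(f, ",", fixed = TRUE)[[1]])
      list(cell_id = sub$cell_id[i], arm_length = as.numeric(sub$arm_length[i]),
           foci = pos)
    })
    out[[lab]] <- foci_dataset(cells, label = lab)
  }
  out
}

#' Write a foci dataset to TSV
#' @param data a [foci_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_foci <- function(data, path) {
  df <- data.frame(
    cell_id = vapply(data$cells, function(c) c$cell_id, ""),
    label = data$label,
    arm_length = vapply(data$cells, function(c) c$arm_length, 0),
    foci = vapply(data$cells, function(c)
      paste(format(c$foci, scientific = FALSE, trim = TRUE), collapse = ","), ""),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bin MLH1 foci into equal intervals along the arm
#'
#' The arm is divided into `n_intervals` equal intervals from the
#' centromere (interval 1) to the distal telomere (interval
#' `n_intervals`).  A focus at fractional position `f = pos/arm_length`
#' falls into interval `ceiling(f * n)`; `f = 0` maps to interval 1 and
#' foci exactly on an internal boundary go to the higher interval
#' (right-closed), `f = 1` to the last interval.
#'
#' @param data a [foci_dataset()].
#' @param n_intervals number of intervals (default 10).
#' @return Object of class `foci_profile`: data frame with columns `label`,
#'   `interval`, `count` and `freq_per_cell` (foci per cell); total counts
#'   are conserved.
#' @export
bin_foci <- function(data, n_intervals = 10L) {
  stopifnot(inherits(data, "foci_dataset"))
  .assert(n_intervals >= 1, "n_intervals must be >= 1")
  f <- unlist(lapply(data$cells, function(c) c$foci / c$arm_length))
  idx <- pmin(pmax(ceiling(f * n_intervals), 1L), n_intervals)
  counts <- tabulate(idx, nbins = n_intervals)
  structure(data.frame(label = data$label, interval = seq_len(n_intervals),
                       count = counts,
                       freq_per_cell = counts / length(data$cells),
                       stringsAsFactors = FALSE),
            class = c("foci_profile", "data.frame"))
}

#' Mean MLH1 foci per cell
#'
#' @param data a [foci_dataset()].
#' @return List with `mean`, `se` (sd / sqrt(n_cells)) and `n_cells`.
#' @export
mean_foci_per_cell <- function(data) {
  stopifnot(inherits(data, "foci_dataset"))
  .assert(length(data$cells) >= 1, "empty foci dataset")
  counts <- vapply(data$cells, function(c) length(c$foci), 0L)
  list(mean = mean(counts),
       se = if (length(counts) > 1) stats::sd(counts) / sqrt(length(counts)) else 0,
       n_cells = length(counts))
}

#' Compare two binned focus profiles
#'
#' Aligns per-interval focus frequencies (foci per cell) of two profiles
#' and reports their differences and the total-count ratio.  No hypothesis
#' test is attached; the comparison is descriptive.
#'
#' @param a,b [bin_foci()] profiles with equal `n_intervals`.
#' @return Data frame with columns `interval`, `freq_a`, `freq_b`, `diff`,
#'   plus attribute `count_ratio` (total a / total b).
#' @export
compare_profiles <- function(a, b) {
  stopifnot(inherits(a, "foci_profile"), inherits(b, "foci_profile"))
  .assert(nrow(a) == nrow(b), "profiles have different numbers of intervals")
  out <- data.frame(interval = a$interval,
                    freq_a = a$freq_per_cell, freq_b = b$freq_per_cell,
                    diff = a$freq_per_cell - b$freq_per_cell)
  attr(out, "count_ratio") <- sum(a$count) / sum(b$count)
  out
}

#' @export
plot.foci_profile <- function(x, ...) {
  graphics::barplot(x$freq_per_cell, names.arg = x$interval,
                    xlab = "interval (centromere to telomere)",
                    ylab = "MLH1 foci per cell", main = x$label[1], ...)
  invisible(x)
}
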