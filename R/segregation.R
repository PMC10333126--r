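#' GAM segregation tables
#'
#' A segregation table is the primary data object of Genome Architecture
#' Mapping (GAM): a boolean windows-by-samples matrix recording which fixed
#' genomic windows were detected in which sequenced sample (one nuclear
#' profile, or several pooled nuclear profiles in multiplex-GAM). It is
#' represented as a tibble whose first three columns are `chrom`, `start`,
#' `end` (0-based half-open, fixed-width windows) followed by one 0/1 integer
#' column per sample. The number of nuclear profiles pooled into each sample
#' is carried in the `nps` attribute (named numeric vector, default 1).
#'
#' @param windows A data frame with columns `chrom`, `start`, `end`.
#' @param detection A logical or 0/1 matrix, windows x samples, with column
#'   names used as sample identifiers.
#' @param nps Nuclear profiles per sample: a single number or a vector named
#'   by sample id. Default 1.
#' @return A `seg_table` tibble.
#' @examples
#' win <- data.frame(chrom = "chr1", start = c(0, 40000), end = c(40000, 80000))
#' m <- cbind(s1 = c(1, 0), s2 = c(1, 1))
#' seg_table(win, m)
#' @export
seg_table <- function(windows, detection, nps = 1) {
  stopifnot(all(c("chrom", "start", "end") %in% names(windows)))
  detection <- as.matrix(detection)
  if (is.null(colnames(detection))) {
    colnames(detection) <- paste0("sample_", seq_len(ncol(detection)))
  }
  mode(detection) <- "integer"
  if (nrow(detection) != nrow(windows)) {
    abort("detection matrix rows must match number of windows")
  }
  out <- tibble::as_tibble(windows[c("chrom", "start", "end")])
  out$chrom <- as.character(out$chrom)
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  out <- dplyr::bind_cols(out, tibble::as_tibble(detection))
  out <- new_seg_table(out, nps = expand_nps(nps, colnames(detection)))
  validate_seg_table(out)
  out
}

new_seg_table <- function(x, nps) {
  attr(x, "nps") <- nps
  class(x) <- unique(c("seg_table", class(tibble::as_tibble(x))))
  x
}

expand_nps <- function(nps, ids) {
  if (length(nps) == 1 && is.null(names(nps))) nps <- setNames(rep(nps, length(ids)), ids)
  if (is.null(names(nps))) names(nps) <- ids
  if (!all(ids %in% names(nps))) abort("nps must cover every sample id")
  if (any(nps[ids] <= 0)) abort("nps_per_sample must be positive")
  nps[ids]
}

validate_seg_table <- function(x) {
  mat <- seg_matrix(x)
  if (!all(mat %in% c(0L, 1L))) abort("segregation entries must be 0/1")
  if (anyDuplicated(seg_sample_ids(x))) abort("sample ids must be unique")
  win <- seg_windows(x)
  widths <- win$end - win$start
  if (length(unique(widths)) > 1) abort("windows must share one resolution")
  if (any(widths <= 0)) abort("windows must have positive width")
  res <- widths[1]
  if (any(win$start %% res != 0)) abort("window starts must align to the resolution")
  bad <- win |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(unsorted = is.unsorted(.data$start, strictly = TRUE)) |>
    dplyr::filter(.data$unsorted)
  if (nrow(bad) > 0) {
    abort(paste0("windows unsorted or overlapping on ", paste(bad$chrom, collapse = ", ")))
  }
  invisible(x)
}

#' @rdname seg_table
#' @param x A `seg_table`.
#' @export
seg_windows <- function(x) {
  tibble::as_tibble(x)[c("chrom", "start", "end")]
}

#' @rdname seg_table
#' @export
seg_sample_ids <- function(x) setdiff(names(x), c("chrom", "start", "end"))

#' @rdname seg_table
#' @export
seg_matrix <- function(x) {
  ids <- seg_sample_ids(x)
  m <- as.matrix(tibble::as_tibble(x)[ids])
  mode(m) <- "integer"
  rownames(m) <- window_key(seg_windows(x))
  m
}

#' @rdname seg_table
#' @export
seg_nps <- function(x) {
  nps <- attr(x, "nps")
  ids <- seg_sample_ids(x)
  if (is.null(nps)) nps <- setNames(rep(1, length(ids)), ids)
  nps[ids]
}

#' @rdname seg_table
#' @export
seg_resolution <- function(x) {
  win <- seg_windows(x)
  as.integer(win$end[1] - win$start[1])
}

window_key <- function(win) paste0(win$chrom, ":", win$start)

#' Read and write segregation tables
#'
#' The on-disk format is a TSV with header `chrom  start  stop` followed by
#' one 0/1 column per sample. Per-sample nuclear-profile counts are stored in
#' an optional two-column sidecar TSV (`sample  nps`), by default
#' `<path>.nps.tsv`; absent a sidecar every sample is taken to hold one
#' nuclear profile. `write_segregation()` followed by `read_segregation()`
#' is lossless.
#'
#' @param path TSV file path.
#' @param nps_path Optional sidecar path. For reading, defaults to
#'   `<path>.nps.tsv` when that file exists.
#' @return `read_segregation()` returns a [seg_table];
#'   `write_segregation()` invisibly returns `path`.
#' @export
read_segregation <- function(path, nps_path = NULL) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(raw) < 4) abort("segregation TSV needs chrom/start/stop plus sample columns")
  names(raw)[1:3] <- c("chrom", "start", "end")
  ids <- names(raw)[-(1:3)]
  m <- as.matrix(raw[ids])
  if (!all(m %in% c(0, 1))) abort("non-binary entries in segregation table")
  nps <- 1
  if (is.null(nps_path) && file.exists(paste0(path, ".nps.tsv"))) {
    nps_path <- paste0(path, ".nps.tsv")
  }
  if (!is.null(nps_path)) {
    side <- readr::read_tsv(nps_path, show_col_types = FALSE, progress = FALSE)
    nps <- setNames(side[[2]], side[[1]])
  }
  seg_table(raw[1:3], m, nps = nps)
}

#' @rdname read_segregation
#' @param x A [seg_table].
#' @export
write_segregation <- function(x, path, nps_path = NULL) {
  out <- tibble::as_tibble(x)
  names(out)[1:3] <- c("chrom", "start", "stop")
  readr::write_tsv(out, path, progress = FALSE)
  nps <- seg_nps(x)
  if (!is.null(nps_path) || any(nps != 1)) {
    nps_path <- nps_path %||% paste0(path, ".nps.tsv")
    readr::write_tsv(tibble::tibble(sample = names(nps), nps = unname(nps)),
                     nps_path, progress = FALSE)
  }
  invisible(path)
}

#' Call positive windows from read counts
#'
#' Converts a windows-by-samples read-count table into a boolean segregation
#' table: a window is positive in a sample when its read count reaches the
#' threshold (inclusive). A fixed threshold of 4 reads is the standard call
#' for 40-kb windows.
#'
#' @param counts A data frame shaped like a segregation table (`chrom`,
#'   `start`, `end`, then one non-negative integer column per sample).
#' @param threshold Minimum read count for a positive call (default 4).
#' @param nps Nuclear profiles per sample, passed to [seg_table()].
#' @return A [seg_table].
#' @examples
#' counts <- tibble::tibble(chrom = "chr1", start = 0L, end = 40000L,
#'                          s1 = 3L, s2 = 7L)
#' call_positive_windows(counts)
#' @export
call_positive_windows <- function(counts, threshold = 4, nps = 1) {
  ids <- setdiff(names(counts), c("chrom", "start", "end"))
  m <- as.matrix(counts[ids])
  if (any(m < 0)) abort("read counts must be non-negative")
  seg_table(counts[c("chrom", "start", "end")], (m >= threshold) * 1L, nps = nps)
}

#' Merge samples in silico into multiplexed samples
#'
#' Emulates multiplex-GAM from single-NP data: samples are partitioned into
#' disjoint random groups of `group_size` and each group is collapsed into
#' one sample that is positive wherever any member was positive (a tube
#' pooling the group's nuclear profiles). Samples left over when the sample
#' count is not a multiple of `group_size` are dropped, so 480 single-NP
#' columns give exactly 240 two-NP or 160 three-NP samples.
#'
#' @param x A [seg_table].
#' @param group_size Number of samples pooled per output sample (>= 2).
#' @param seed Integer seed for the random grouping.
#' @return A [seg_table] with `floor(n / group_size)` samples whose `nps`
#'   are the sums over each group.
#' @export
insilico_multiplex <- function(x, group_size, seed = NULL) {
  ids <- seg_sample_ids(x)
  n <- length(ids)
  if (group_size < 2) abort("group_size must be at least 2")
  if (group_size > n) abort("group_size exceeds the number of samples")
  n_out <- n %/% group_size
  perm <- with_seed(seed, sample.int(n))
  keep <- perm[seq_len(n_out * group_size)]
  groups <- split(ids[keep], rep(seq_len(n_out), each = group_size))
  m <- seg_matrix(x)
  nps <- seg_nps(x)
  new_m <- vapply(groups, function(g) as.integer(rowSums(m[, g, drop = FALSE]) > 0),
                  integer(nrow(m)))
  colnames(new_m) <- vapply(groups, function(g) paste(g, collapse = "+"), character(1))
  new_nps <- vapply(groups, function(g) sum(nps[g]), numeric(1))
  seg_table(seg_windows(x), new_m, nps = setNames(new_nps, colnames(new_m)))
}

#' Window detection frequency
#'
#' Fraction of samples in which each window is positive, a detectability
#' proxy used to filter over- and under-sampled windows before matrix
#' comparisons.
#'
#' @param x A [seg_table].
#' @return A tibble with `chrom`, `start`, `end`, `detection_frequency`.
#' @export
window_detection_frequency <- function(x) {
  ids <- seg_sample_ids(x)
  if (length(ids) == 0) abort("segregation table has no samples")
  out <- seg_windows(x)
  out$detection_frequency <- unname(rowMeans(seg_matrix(x)))
  out
}

#' Pairwise co-segregation counts
#'
#' Partitions the samples by the joint detection state of two windows:
#' both present, only the first, only the second, neither.
#'
#' @param x A [seg_table].
#' @param window_a,window_b Window identifiers: either row indices or
#'   `"chrom:start"` strings.
#' @return A one-row tibble with `m` (sample count), `k_both`, `k_only_a`,
#'   `k_only_b`, `k_neither`; the four counts sum to `m`.
#' @export
pair_cosegregation_counts <- function(x, window_a, window_b) {
  m <- seg_matrix(x)
  ia <- resolve_window(x, window_a)
  ib <- resolve_window(x, window_b)
  a <- m[ia, ]
  b <- m[ib, ]
  tibble::tibble(
    m = ncol(m),
    k_both = sum(a & b),
    k_only_a = sum(a & !b),
    k_only_b = sum(!a & b),
    k_neither = sum(!a & !b)
  )
}

resolve_window <- function(x, w) {
  if (is.numeric(w)) {
    if (w < 1 || w > nrow(x)) abort("window index out of range")
    return(as.integer(w))
  }
  i <- match(w, window_key(seg_windows(x)))
  if (is.na(i)) abort(paste0("unknown window: ", w))
  i
}

#' Normalized linkage disequilibrium (D') contact matrix
#'
#' For each intra-chromosomal window pair within `max_distance`, computes
#' the normalized linkage disequilibrium of their detection indicators:
#' `D = p_AB - p_A p_B`, scaled by its maximum attainable magnitude given
#' the marginals (`D' = D / Dmax`, with `Dmax = min(p_A (1-p_B), (1-p_A) p_B)`
#' for positive `D` and `min(p_A p_B, (1-p_A)(1-p_B))` otherwise). Windows
#' detected in none or all samples have no defined D' and yield missing
#' entries, which are omitted from the result.
#'
#' @param x A [seg_table].
#' @param max_distance Band limit in base pairs (multiple of the resolution).
#' @return A [contact_tbl] with `value_kind = "dprime"`.
#' @export
linkage_matrix <- function(x, max_distance = 4e6) {
  res <- seg_resolution(x)
  if (max_distance %% res != 0) abort("max_distance must be a multiple of the resolution")
  win <- seg_windows(x)
  m <- seg_matrix(x)
  n_samp <- ncol(m)
  rows <- lapply(split(seq_len(nrow(win)), win$chrom), function(idx) {
    sub <- m[idx, , drop = FALSE]
    p <- rowMeans(sub)
    co <- tcrossprod(sub) / n_samp
    starts <- win$start[idx]
    pairs <- which(upper.tri(co, diag = FALSE), arr.ind = TRUE)
    d_bp <- starts[pairs[, 2]] - starts[pairs[, 1]]
    keep <- d_bp > 0 & d_bp <= max_distance
    pairs <- pairs[keep, , drop = FALSE]
    pa <- p[pairs[, 1]]; pb <- p[pairs[, 2]]
    pab <- co[pairs]
    d <- pab - pa * pb
    dmax <- ifelse(d >= 0, pmin(pa * (1 - pb), (1 - pa) * pb),
                   pmin(pa * pb, (1 - pa) * (1 - pb)))
    dp <- unname(ifelse(pa %in% c(0, 1) | pb %in% c(0, 1) | dmax == 0,
                        NA_real_, d / dmax))
    tibble::tibble(
      chrom = win$chrom[idx[1]],
      bin_a = starts[pairs[, 1]],
      bin_b = starts[pairs[, 2]],
      value = dp
    )
  })
  out <- dplyr::bind_rows(rows) |> dplyr::filter(!is.na(.data$value))
  contact_tbl(out, resolution = res, value_kind = "dprime", max_distance = max_distance)
}

# Run code under a temporary RNG state; NULL seed leaves the stream alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
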