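#' Banded contact matrices in long (COO) form
#'
#' A contact matrix is stored as a long tibble of upper-triangle entries
#' (`chrom`, `bin_a`, `bin_b`, `value`, with `bin_a < bin_b` as window start
#' coordinates) plus attributes: `resolution` (bp), `value_kind` (one of
#' `dprime`, `ligation_count`, `zscore`, `obs_exp`, `delta`, `probability`)
#' and `max_distance` (band limit, bp). Missing entries are simply absent
#' rows. Symmetry is implicit in the triangular storage.
#'
#' @param x A data frame with columns `chrom`, `bin_a`, `bin_b`, `value`.
#' @param resolution Window size in bp.
#' @param value_kind Value-kind tag.
#' @param max_distance Band limit in bp.
#' @return A `contact_tbl` tibble.
#' @export
contact_tbl <- function(x, resolution, value_kind, max_distance = NULL) {
  kinds <- c("dprime", "ligation_count", "zscore", "obs_exp", "delta", "probability")
  value_kind <- match.arg(value_kind, kinds)
  out <- tibble::as_tibble(x)[c("chrom", "bin_a", "bin_b", "value")]
  swap <- out$bin_a > out$bin_b
  if (any(swap)) {
    tmp <- out$bin_a[swap]
    out$bin_a[swap] <- out$bin_b[swap]
    out$bin_b[swap] <- tmp
  }
  if (value_kind == "dprime" && any(abs(out$value) > 1 + 1e-9, na.rm = TRUE)) {
    abort("dprime values must lie in [-1, 1]")
  }
  if (value_kind == "ligation_count" && any(out$value < 0, na.rm = TRUE)) {
    abort("ligation counts must be non-negative")
  }
  if (!is.null(max_distance) && any(out$bin_b - out$bin_a > max_distance)) {
    abort("entries beyond max_distance")
  }
  attr(out, "resolution") <- as.integer(resolution)
  attr(out, "value_kind") <- value_kind
  attr(out, "max_distance") <- max_distance
  class(out) <- unique(c("contact_tbl", class(tibble::as_tibble(out))))
  out
}

#' @rdname contact_tbl
#' @export
contact_resolution <- function(x) attr(x, "resolution")

#' @rdname contact_tbl
#' @export
contact_value_kind <- function(x) attr(x, "value_kind")

#' Read and write COO contact-matrix text files
#'
#' The text format is a headerless four-column TSV
#' (`chrom  binA_start  binB_start  value`) with a JSON sidecar
#' (`<path>.json`) holding `resolution`, `value_kind` and `max_distance`.
#' Missing entries are omitted from the file.
#'
#' @param path TSV path; the sidecar is `<path>.json`.
#' @return `read_contacts()` returns a [contact_tbl]; `write_contacts()`
#'   invisibly returns `path`.
#' @export
read_contacts <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  raw <- readr::read_tsv(path, col_names = c("chrom", "bin_a", "bin_b", "value"),
                         show_col_types = FALSE, progress = FALSE)
  contact_tbl(raw, resolution = meta$resolution, value_kind = meta$value_kind,
              max_distance = meta$max_distance)
}

#' @rdname read_contacts
#' @param x A [contact_tbl].
#' @export
write_contacts <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x)[c("chrom", "bin_a", "bin_b", "value")],
                   path, col_names = FALSE, progress = FALSE)
  jsonlite::write_json(
    list(resolution = contact_resolution(x), value_kind = contact_value_kind(x),
         max_distance = attr(x, "max_distance")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Dense symmetric matrix for one chromosome (bins on a regular grid from 0).
contact_dense <- function(x, chrom, n_bins = NULL) {
  res <- contact_resolution(x)
  sub <- dplyr::filter(tibble::as_tibble(x), .data$chrom == !!chrom)
  n <- n_bins %||% (max(sub$bin_b) / res + 1)
  m <- matrix(NA_real_, n, n)
  ia <- sub$bin_a / res + 1
  ib <- sub$bin_b / res + 1
  m[cbind(ia, ib)] <- sub$value
  m[cbind(ib, ia)] <- sub$value
  m
}

#' @export
autoplot.contact_tbl <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$bin_a, .data$bin_b, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~chrom, scales = "free") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "bin A (bp)", y = "bin B (bp)",
                  fill = contact_value_kind(object))
}
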