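#' Configuration for the nuclear-slicing simulator
#'
#' The geometric simulator realizes the generative assumptions behind
#' SLICE: chromatin is a confined random-flight chain inside an
#' ellipsoidal nucleus, designated locus tuples are co-located (within a
#' contact distance smaller than the slice thickness) with a prescribed
#' interaction probability in each cell, and tubes observe the union of a
#' few random thin slabs, thinned by a detection efficiency.
#'
#' @param n_cells Number of simulated nuclei.
#' @param n_windows Windows per chromosome.
#' @param chroms Chromosome names (default `"chr1"`).
#' @param resolution Window size in bp (for labeling outputs).
#' @param geometry A [nuclear_geometry].
#' @param x_np Integer nuclear profiles per tube.
#' @param detection_efficiency Observation thinning per captured window.
#' @param step Chain step length, um per window.
#' @param interactions A tibble with columns `windows` (list-column of
#'   integer window indices), `pi`, `contact_distance` (um).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cells = 500, n_windows = 50, chroms = "chr1",
                       resolution = 40000, geometry = nuclear_geometry(),
                       x_np = 1, detection_efficiency = 1, step = 0.15,
                       interactions = NULL) {
  if (step > 2 * geometry$radius) abort("step length exceeds the nuclear diameter")
  if (n_cells <= 0 || n_windows <= 0) abort("n_cells and n_windows must be positive")
  structure(list(n_cells = n_cells, n_windows = n_windows, chroms = chroms,
                 resolution = resolution, geometry = geometry, x_np = x_np,
                 detection_efficiency = detection_efficiency, step = step,
                 interactions = interactions),
            class = "sim_config")
}

# semi-axes of the volume-preserving ellipsoid
ellipsoid_axes <- function(geometry) {
  a <- geometry$radius * geometry$epsilon^(-1 / 3)
  c(a, a, geometry$epsilon * a)
}

inside_ellipsoid <- function(p, axes) {
  sum((p / axes)^2) <= 1
}

#' Simulate confined chromatin configurations
#'
#' Per cell and chromosome, grows a random-flight chain of `n_windows`
#' fixed-length steps confined to the nuclear ellipsoid (out-of-volume
#' proposals are resampled). Then, for each interaction specification,
#' with probability `pi` the designated windows are pulled to a common
#' point, scattered within `contact_distance` of one another.
#'
#' @param config A [sim_config].
#' @param seed Integer seed.
#' @return A tibble: `cell`, `chrom`, `window` (1-based index), `x`, `y`,
#'   `z` (um), all coordinates inside the nucleus.
#' @export
simulate_configurations <- function(config, seed = 1L) {
  axes <- ellipsoid_axes(config$geometry)
  step <- config$step
  with_seed(seed, {
    purrr::map_dfr(seq_len(config$n_cells), function(cell) {
      purrr::map_dfr(config$chroms, function(chrom) {
        pos <- matrix(0, config$n_windows, 3)
        # uniform interior start by rejection
        repeat {
          p <- runif(3, -axes, axes)
          if (inside_ellipsoid(p, axes)) break
        }
        pos[1, ] <- p
        if (config$n_windows > 1) {
          for (i in 2:config$n_windows) {
            repeat {
              dir <- rnorm(3)
              cand <- pos[i - 1, ] + step * dir / sqrt(sum(dir^2))
              if (inside_ellipsoid(cand, axes)) break
            }
            pos[i, ] <- cand
          }
        }
        if (!is.null(config$interactions)) {
          for (j in seq_len(nrow(config$interactions))) {
            ispec <- config$interactions[j, ]
            if (runif(1) < ispec$pi) {
              wins <- ispec$windows[[1]]
              anchor <- pos[wins[1], ]
              for (wdx in wins[-1]) {
                repeat {
                  off <- runif(3, -1, 1)
                  if (sum(off^2) <= 1) break
                }
                cand <- anchor + off * ispec$contact_distance / 2
                if (!inside_ellipsoid(cand, axes)) cand <- anchor
                pos[wdx, ] <- cand
              }
            }
          }
        }
        tibble::tibble(cell = cell, chrom = chrom,
                       window = seq_len(config$n_windows),
                       x = pos[, 1], y = pos[, 2], z = pos[, 3])
      })
    })
  })
}

#' Slice simulated cells into a segregation table
#'
#' Each tube pools `x_np` cells drawn without replacement (each nuclear
#' profile comes from a different cell); each cell is cut by one slab of
#' thickness `h` with an isotropic orientation and an offset uniform over
#' the nuclear extent plus `h` along that axis. A window is captured when
#' its coordinate projects into the slab, then observed with probability
#' `detection_efficiency`; the tube row is the union over its profiles.
#'
#' @param cells A [simulate_configurations()] result.
#' @param config The [sim_config] used to generate the cells.
#' @param seed Integer seed.
#' @return A [seg_table] with `floor(n_cells / x_np)` samples.
#' @export
slice_configurations <- function(cells, config, seed = 1L) {
  x_np <- config$x_np
  if (x_np != round(x_np) || x_np < 1) abort("x_np must be a positive integer here")
  geometry <- config$geometry
  axes <- ellipsoid_axes(geometry)
  h <- geometry$h
  eff <- config$detection_efficiency
  cell_ids <- unique(cells$cell)
  n_tubes <- length(cell_ids) %/% x_np
  if (n_tubes == 0) abort("x_np exceeds the number of cells")
  res <- config$resolution
  win <- cells |>
    dplyr::distinct(.data$chrom, .data$window) |>
    dplyr::arrange(.data$chrom, .data$window) |>
    dplyr::mutate(start = (.data$window - 1) * res, end = .data$window * res)
  pos_by_cell <- split(cells, cells$cell)
  with_seed(seed, {
    assignment <- split(sample(cell_ids)[seq_len(n_tubes * x_np)],
                        rep(seq_len(n_tubes), each = x_np))
    mat <- vapply(assignment, function(tube_cells) {
      hit <- rep(FALSE, nrow(win))
      for (cid in tube_cells) {
        cdat <- pos_by_cell[[as.character(cid)]]
        dir <- rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        extent <- sqrt(sum((axes * dir)^2))  # support radius of the ellipsoid
        offset <- runif(1, -extent - h / 2, extent + h / 2)
        proj <- as.matrix(cdat[c("x", "y", "z")]) %*% dir
        captured <- abs(proj - offset) <= h / 2
        if (eff < 1) captured <- captured & (runif(length(captured)) < eff)
        idx <- match(paste(cdat$chrom, cdat$window), paste(win$chrom, win$window))
        hit[idx] <- hit[idx] | captured
      }
      as.integer(hit)
    }, integer(nrow(win)))
    colnames(mat) <- paste0("tube_", seq_len(n_tubes))
    seg_table(win[c("chrom", "start", "end")], mat, nps = x_np)
  })
}

#' Direct sampler of the SLICE pair tube-state distribution
#'
#' Draws `m` tubes from the trinomial (M0, M1, M2) given by
#' [pair_tube_state_probs()] — the fast state-level counterpart of the
#' geometric simulator, used for calibration and recovery tests.
#'
#' @inheritParams pair_tube_state_probs
#' @param m Number of tubes.
#' @param seed Integer seed.
#' @return A one-row tibble with `k0`, `k1`, `k2` summing to `m`.
#' @export
simulate_state_level <- function(v, u, t, pi, m, x_np = 1,
                                 detection_efficiency = 1, seed = 1L) {
  st <- pair_tube_state_probs(v, u, t, pi, x_np, detection_efficiency)
  if (m == 0) return(tibble::tibble(k0 = 0L, k1 = 0L, k2 = 0L))
  k <- with_seed(seed, rmultinom(1, m, c(st$m0, st$m1, st$m2)))
  tibble::tibble(k0 = k[1], k1 = k[2], k2 = k[3])
}

#' Simulate ligation-limited Hi-C from cell configurations
#'
#' Per cell, windows within `capture_radius` of one another are spatial
#' neighbors; each window offers at most `max_partners` ligation slots to
#' neighbors sampled uniformly without replacement, and a pair is ligated
#' (counted once for the cell) only when each selects the other — the
#' competition that dilutes pairwise counts at multiway hubs. With
#' unlimited slots every proximal pair is counted, reproducing brute-force
#' proximity counting.
#'
#' @param cells A [simulate_configurations()] result.
#' @param capture_radius Ligation capture radius (um).
#' @param max_partners Ligation slots per window (`Inf` = unlimited).
#' @param resolution Window size in bp for output bins.
#' @param seed Integer seed.
#' @return A [contact_tbl] of `ligation_count` values.
#' @export
simulate_hic_ligation <- function(cells, capture_radius, max_partners = Inf,
                                  resolution = 40000, seed = 1L) {
  if (capture_radius <= 0) abort("capture_radius must be positive")
  if (max_partners < 1) abort("max_partners must be at least 1")
  counts <- new.env(parent = emptyenv())
  with_seed(seed, {
    for (cdat in split(cells, cells$cell)) {
      pos <- as.matrix(cdat[c("x", "y", "z")])
      n <- nrow(pos)
      d <- as.matrix(stats::dist(pos))
      adj <- d < capture_radius & upper.tri(d)
      nbrs <- lapply(seq_len(n), function(i) which(d[i, ] < capture_radius & seq_len(n) != i))
      chosen <- lapply(seq_len(n), function(i) {
        nb <- nbrs[[i]]
        if (length(nb) <= max_partners) nb
        else nb[sample.int(length(nb), max_partners)]
      })
      pairs <- which(adj, arr.ind = TRUE)
      for (r in seq_len(nrow(pairs))) {
        i <- pairs[r, 1]; j <- pairs[r, 2]
        if (j %in% chosen[[i]] && i %in% chosen[[j]]) {
          key <- paste(cdat$chrom[i], cdat$window[i], cdat$chrom[j], cdat$window[j])
          counts[[key]] <- (counts[[key]] %||% 0L) + 1L
        }
      }
    }
  })
  keys <- ls(counts)
  if (length(keys) == 0) {
    return(contact_tbl(tibble::tibble(chrom = character(), bin_a = numeric(),
                                      bin_b = numeric(), value = numeric()),
                       resolution, "ligation_count"))
  }
  parts <- stringr::str_split_fixed(keys, " ", 4)
  out <- tibble::tibble(
    chrom = parts[, 1],
    bin_a = (as.integer(parts[, 2]) - 1) * resolution,
    bin_b = (as.integer(parts[, 4]) - 1) * resolution,
    value = vapply(keys, function(k) as.numeric(counts[[k]]), numeric(1))
  ) |>
    dplyr::filter(parts[, 1] == parts[, 3])
  out <- out |>
    dplyr::group_by(.data$chrom,
                    lo = pmin(.data$bin_a, .data$bin_b),
                    hi = pmax(.data$bin_a, .data$bin_b)) |>
    dplyr::summarise(value = sum(.data$value), .groups = "drop") |>
    dplyr::rename(bin_a = "lo", bin_b = "hi")
  contact_tbl(out, resolution, "ligation_count")
}

#' Simulate a window feature table with class structure
#'
#' Partitions windows into classes (active, inactive, enhancer,
#' intergenic by default) and draws each feature's presence per window
#' from class-conditional probabilities.
#'
#' @param windows A tibble (`chrom`, `start`, `end`).
#' @param n_features Number of features (default 14).
#' @param class_probs A matrix of class-conditional presence probabilities
#'   (classes x features); defaults to a graded random design.
#' @param class_names Class labels.
#' @param seed Integer seed.
#' @return A list: `features` (a [build_feature_table()]-shaped tibble)
#'   and `classes` (tibble `chrom`, `start`, `class`).
#' @export
simulate_features <- function(windows, n_features = 14, class_probs = NULL,
                              class_names = c("active", "inactive",
                                              "enhancer", "intergenic"),
                              seed = 1L) {
  n_win <- nrow(windows)
  with_seed(seed, {
    classes <- sample(class_names, n_win, replace = TRUE)
    if (is.null(class_probs)) {
      class_probs <- matrix(runif(length(class_names) * n_features, 0.05, 0.6),
                            length(class_names), n_features,
                            dimnames = list(class_names, NULL))
    }
    if (any(class_probs < 0 | class_probs > 1)) abort("probabilities outside [0, 1]")
    feat <- vapply(seq_len(n_features), function(f) {
      as.integer(runif(n_win) < class_probs[classes, f])
    }, integer(n_win))
    colnames(feat) <- paste0("feature_", seq_len(n_features))
    out <- tibble::as_tibble(windows)[c("chrom", "start", "end")]
    list(
      features = dplyr::bind_cols(out, tibble::as_tibble(feat)),
      classes = tibble::tibble(chrom = out$chrom, start = out$start,
                               class = classes)
    )
  })
}
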