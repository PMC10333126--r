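#' Build a window-by-feature presence table
#'
#' Marks each fixed genomic window positive for a feature when at least one
#' of the feature's intervals overlaps it by one base pair or more
#' (`mode = "presence"`), or records the number of overlapping intervals
#' (`mode = "count"`).
#'
#' @param intervals A data frame of feature intervals: `chrom`, `start`,
#'   `end`, `feature` (feature name).
#' @param windows A tibble of windows (`chrom`, `start`, `end`), fixed
#'   width.
#' @param mode `"presence"` (0/1) or `"count"`.
#' @return A tibble: `chrom`, `start`, `end`, then one column per feature.
#' @export
build_feature_table <- function(intervals, windows, mode = c("presence", "count")) {
  mode <- match.arg(mode)
  win <- tibble::as_tibble(windows)[c("chrom", "start", "end")]
  res <- win$end[1] - win$start[1]
  features <- unique(intervals$feature)
  key <- paste(win$chrom, win$start)
  for (f in features) {
    col <- numeric(nrow(win))
    sub <- intervals[intervals$feature == f, , drop = FALSE]
    if (nrow(sub) > 0) {
      if (any(sub$end <= sub$start)) abort("empty or inverted interval")
      # windows are a regular grid: an interval [s, e) hits windows with
      # start in [floor(s/res)*res, floor((e-1)/res)*res]
      hits <- purrr::pmap_dfr(sub[c("chrom", "start", "end")], function(chrom, start, end) {
        tibble::tibble(chrom = chrom,
                       start = seq((start %/% res) * res,
                                   ((end - 1) %/% res) * res, by = res))
      })
      idx <- match(paste(hits$chrom, hits$start), key)
      if (anyNA(idx)) abort("interval beyond the window universe")
      tab <- table(idx)
      col[as.integer(names(tab))] <- as.numeric(tab)
    }
    win[[f]] <- if (mode == "presence") as.integer(col > 0) else col
  }
  win
}

#' Enumerate unordered feature pairs
#'
#' All homotypic and heterotypic pairs of `n` features: `n (n + 1) / 2`
#' pairs (105 for the canonical 14-feature table).
#'
#' @param features Character vector of feature names.
#' @return A tibble with `feature_a`, `feature_b` (`feature_a <= feature_b`
#'   in the input order) and a `pair` label.
#' @export
enumerate_feature_pairs <- function(features) {
  if (length(features) < 1) abort("need at least one feature")
  idx <- which(upper.tri(diag(length(features)), diag = TRUE), arr.ind = TRUE)
  tibble::tibble(
    feature_a = features[idx[, 1]],
    feature_b = features[idx[, 2]],
    pair = paste(features[idx[, 1]], features[idx[, 2]], sep = "--")
  )
}

#' Annotate contacts with the feature pairs at their anchors
#'
#' A contact carries feature pair (i, j) when one anchor window is positive
#' for i and the other for j (either orientation; homotypic pairs need both
#' anchors positive). Contacts carrying no pair are dropped; the dropped
#' count is kept as an attribute.
#'
#' @param contacts A tibble with `chrom`, `bin_a`, `bin_b`.
#' @param feature_table A [build_feature_table()] result (presence mode).
#' @return A tibble with one row per (contact, pair): contact columns plus
#'   `pair`; attribute `n_dropped` counts featureless contacts. The
#'   `contact_id` column indexes rows of the retained input.
#' @export
annotate_contacts <- function(contacts, feature_table) {
  features <- setdiff(names(feature_table), c("chrom", "start", "end"))
  fm <- as.matrix(feature_table[features]) > 0
  rownames(fm) <- paste(feature_table$chrom, feature_table$start)
  ia <- match(paste(contacts$chrom, contacts$bin_a), rownames(fm))
  ib <- match(paste(contacts$chrom, contacts$bin_b), rownames(fm))
  if (anyNA(ia) || anyNA(ib)) abort("contact anchor outside the feature table")
  pairs <- enumerate_feature_pairs(features)
  res <- purrr::map_dfr(seq_len(nrow(contacts)), function(i) {
    fa <- fm[ia[i], ]
    fb <- fm[ib[i], ]
    hit <- (fa[pairs$feature_a] & fb[pairs$feature_b]) |
      (fb[pairs$feature_a] & fa[pairs$feature_b])
    if (!any(hit)) return(NULL)
    tibble::tibble(contact_id = i, pair = pairs$pair[hit])
  })
  n_dropped <- nrow(contacts) - length(unique(res$contact_id))
  out <- dplyr::left_join(
    res,
    dplyr::mutate(tibble::as_tibble(contacts), contact_id = dplyr::row_number()),
    by = "contact_id")
  attr(out, "n_dropped") <- n_dropped
  attr(out, "features") <- features
  out
}

#' Distance-matched permutation backgrounds
#'
#' For each permutation, samples from the universe-minus-foreground, within
#' every (chromosome, distance) stratum, the same number of contacts the
#' foreground holds there (without replacement). Strata where the
#' complement is too small take all available contacts; the shortfall is
#' recorded in the `shortfall` attribute.
#'
#' @param foreground A contact tibble (`chrom`, `bin_a`, `bin_b`).
#' @param universe The full contact universe (same columns), a strict
#'   superset of the foreground.
#' @param n_perm Number of permutations (default 3).
#' @param seed Integer seed.
#' @return A tibble of sampled contacts with a `perm` column.
#' @export
matched_background <- function(foreground, universe, n_perm = 3, seed = 1L) {
  key <- function(d) paste(d$chrom, d$bin_a, d$bin_b)
  pool <- tibble::as_tibble(universe) |>
    dplyr::mutate(distance = .data$bin_b - .data$bin_a) |>
    dplyr::filter(!(key(universe) %in% key(foreground)))
  if (nrow(pool) == 0) abort("universe must strictly exceed the foreground")
  fg_strata <- tibble::as_tibble(foreground) |>
    dplyr::mutate(distance = .data$bin_b - .data$bin_a) |>
    dplyr::count(.data$chrom, .data$distance)
  shortfall <- 0L
  out <- with_seed(seed, {
    purrr::map_dfr(seq_len(n_perm), function(p) {
      drawn <- dplyr::inner_join(pool, fg_strata, by = c("chrom", "distance")) |>
        dplyr::group_by(.data$chrom, .data$distance) |>
        dplyr::group_modify(function(d, g) {
          want <- d$n[1]
          if (nrow(d) < want) shortfall <<- shortfall + (want - nrow(d))
          d[sample.int(nrow(d), min(want, nrow(d))), ]
        }) |>
        dplyr::ungroup() |>
        dplyr::select(-"n")
      dplyr::mutate(drawn, perm = p)
    })
  })
  attr(out, "shortfall") <- shortfall
  out
}

#' Feature-pair frequencies and amplification ratios
#'
#' Per-pair relative occurrence (fraction of annotated contacts carrying
#' the pair) in each contact set, the mean and sd over permutation
#' backgrounds, and the GAM-over-Hi-C amplification ratio. Frequencies
#' need not sum to one: a contact can carry several pairs.
#'
#' @param annotated_sets Named list of [annotate_contacts()] results; names
#'   become set labels. Must include `gam` and `hic` for amplification.
#' @param background Optional annotated background with a `perm` column.
#' @return A tibble: `pair`, one frequency column per set, background mean
#'   and sd, `amplification_gam` (= gam freq / hic freq).
#' @export
pair_frequency_stats <- function(annotated_sets, background = NULL) {
  freq_of <- function(ann) {
    n_contacts <- length(unique(ann$contact_id))
    if (n_contacts == 0) abort("empty annotated set")
    dplyr::count(ann, .data$pair) |>
      dplyr::mutate(freq = .data$n / n_contacts) |>
      dplyr::select("pair", "freq")
  }
  out <- purrr::imap(annotated_sets, function(ann, nm) {
    dplyr::rename(freq_of(ann), !!paste0("freq_", nm) := "freq")
  }) |>
    purrr::reduce(dplyr::full_join, by = "pair")
  if (!is.null(background)) {
    bg <- background |>
      dplyr::group_by(.data$perm) |>
      dplyr::group_modify(function(d, g) freq_of(d)) |>
      dplyr::group_by(.data$pair) |>
      dplyr::summarise(bg_mean = mean(.data$freq), bg_sd = sd(.data$freq))
    out <- dplyr::full_join(out, bg, by = "pair")
  }
  out <- dplyr::mutate(out, dplyr::across(dplyr::starts_with(c("freq_", "bg_")),
                                          ~ dplyr::coalesce(.x, 0)))
  if (all(c("freq_gam", "freq_hic") %in% names(out))) {
    out$amplification_gam <- out$freq_gam / out$freq_hic
  }
  out
}

#' Rank discriminative feature pairs with a random forest
#'
#' Trains a random-forest classifier to tell GAM-specific from
#' Hi-C-specific contacts from their feature-pair presence vectors
#' (500 trees, `mtry = floor(sqrt(p))`, Gini criterion), averaging the mean
#' decrease in Gini impurity over five cross-validation folds. Returns the
#' full importance ranking, the top 10 pairs after an abundance floor
#' (pairs rarer than the floor across the genome are omitted), and the top
#' 3 pairs by Hi-C-over-GAM amplification.
#'
#' @param gam_annotated,hic_annotated [annotate_contacts()] results.
#' @param n_trees Trees per forest (default 500).
#' @param folds Cross-validation folds (default 5).
#' @param seed Integer seed.
#' @param abundance Optional named vector of genome-wide pair abundances
#'   used for the floor; default floor is the median abundance of the
#'   observed pairs (computed from the pooled contact sets when omitted).
#' @param n_top Size of the importance selection (default 10).
#' @return A `rank_pairs_rf` list: `importance` tibble (pair, mean Gini
#'   decrease, rank), `top_importance`, `top_hic_amplified`, `cv_accuracy`.
#' @export
rank_pairs_random_forest <- function(gam_annotated, hic_annotated,
                                     n_trees = 500, folds = 5, seed = 1L,
                                     abundance = NULL, n_top = 10) {
  xg <- pair_presence_matrix(gam_annotated)
  xh <- pair_presence_matrix(hic_annotated)
  all_pairs <- union(colnames(xg), colnames(xh))
  pad <- function(x) {
    miss <- setdiff(all_pairs, colnames(x))
    if (length(miss)) x <- cbind(x, matrix(0L, nrow(x), length(miss),
                                           dimnames = list(NULL, miss)))
    x[, all_pairs, drop = FALSE]
  }
  x <- rbind(pad(xg), pad(xh))
  y <- factor(c(rep("gam", nrow(xg)), rep("hic", nrow(xh))))
  if (nlevels(droplevels(y)) < 2) abort("both classes must be non-empty")
  imp_acc <- matrix(0, length(all_pairs), folds, dimnames = list(all_pairs, NULL))
  acc <- numeric(folds)
  with_seed(seed, {
    fold_id <- sample(rep_len(seq_len(folds), nrow(x)))
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      fit <- randomForest::randomForest(
        x = x[tr, , drop = FALSE], y = y[tr], ntree = n_trees,
        mtry = max(1, floor(sqrt(ncol(x)))), importance = FALSE)
      imp_acc[, f] <- fit$importance[, "MeanDecreaseGini"]
      pred <- stats::predict(fit, x[!tr, , drop = FALSE])
      acc[f] <- mean(pred == y[!tr])
    }
  })
  importance <- tibble::tibble(
    pair = all_pairs,
    gini_importance = rowMeans(imp_acc)
  ) |>
    dplyr::arrange(dplyr::desc(.data$gini_importance)) |>
    dplyr::mutate(rank = dplyr::row_number())
  if (is.null(abundance)) {
    pooled <- dplyr::bind_rows(gam_annotated["pair"], hic_annotated["pair"])
    abundance <- table(pooled$pair)
    abundance <- setNames(as.numeric(abundance), names(abundance))
  }
  floor_val <- median(abundance)
  abundant <- names(abundance)[abundance >= floor_val]
  top_imp <- importance |>
    dplyr::filter(.data$pair %in% abundant) |>
    dplyr::slice_head(n = n_top)
  freq <- pair_frequency_stats(list(gam = gam_annotated, hic = hic_annotated))
  top_hic <- freq |>
    dplyr::filter(.data$freq_hic > 0) |>
    dplyr::arrange(.data$amplification_gam, .data$pair) |>
    dplyr::slice_head(n = 3)
  structure(list(importance = importance, top_importance = top_imp,
                 top_hic_amplified = top_hic, cv_accuracy = mean(acc)),
            class = "rank_pairs_rf")
}

pair_presence_matrix <- function(annotated) {
  ids <- sort(unique(annotated$contact_id))
  pairs <- sort(unique(annotated$pair))
  m <- matrix(0L, length(ids), length(pairs), dimnames = list(NULL, pairs))
  m[cbind(match(annotated$contact_id, ids), match(annotated$pair, pairs))] <- 1L
  m
}

#' Co-occurrence intersection groups of selected feature pairs
#'
#' Each annotated contact is assigned to the exact subset of the selected
#' pairs it carries (UpSet-style intersection groups); counts per group
#' are returned in descending order. Contacts carrying none of the
#' selected pairs form the empty group.
#'
#' @param annotated An [annotate_contacts()] result.
#' @param selected_pairs Character vector of pair labels.
#' @return A tibble: `group` (pair labels joined by `+`, `"(none)"` for the
#'   empty group), `n`.
#' @export
cooccurrence_counts <- function(annotated, selected_pairs) {
  per_contact <- annotated |>
    dplyr::group_by(.data$contact_id) |>
    dplyr::summarise(group = {
      sel <- sort(intersect(.data$pair, selected_pairs))
      if (length(sel) == 0) "(none)" else paste(sel, collapse = "+")
    })
  dplyr::count(per_contact, .data$group, sort = TRUE)
}

#' Class-combination enrichment of significant interactions
#'
#' Compares the observed counts of window-class combinations (for example
#' active-active, active-enhancer) among significant interactions with
#' `n_rand` randomizations that permute the class labels across windows
#' within each chromosome. A combination is flagged enriched (depleted)
#' when its observed count exceeds (falls below) the central 95% of the
#' randomized counts, Bonferroni-corrected across combinations.
#'
#' @param interactions A tibble of interactions: `chrom`, `bin_a`, `bin_b`
#'   (pairs) or also `bin_c` (triplets).
#' @param window_classes A tibble: `chrom`, `start`, `class` (one class
#'   per window).
#' @param n_rand Number of label randomizations (default 500).
#' @param seed Integer seed.
#' @param level Central coverage before correction (default 0.95).
#' @return A tibble per class combination: `combo`, `observed`,
#'   `rand_lo`, `rand_hi` (corrected bounds), `direction`
#'   (`"enriched"`, `"depleted"`, `"ns"`), `flagged`.
#' @export
class_enrichment <- function(interactions, window_classes, n_rand = 500,
                             seed = 1L, level = 0.95) {
  bins <- grep("^bin_", names(interactions), value = TRUE)
  key <- paste(window_classes$chrom, window_classes$start)
  cls <- setNames(as.character(window_classes$class), key)
  combo_of <- function(labels_by_key) {
    lab <- lapply(bins, function(b) labels_by_key[paste(interactions$chrom, interactions[[b]])])
    if (anyNA(unlist(lab))) abort("interaction anchor without a class label")
    apply(do.call(cbind, lab), 1, function(r) paste(sort(r), collapse = "-"))
  }
  observed <- table(combo_of(cls))
  combos <- sort(unique(names(observed)))
  rand_counts <- with_seed(seed, {
    chrom_groups <- split(seq_along(key), window_classes$chrom)
    vapply(seq_len(n_rand), function(i) {
      shuffled <- cls
      for (ii in chrom_groups) shuffled[ii] <- cls[ii][sample.int(length(ii))]
      tab <- table(factor(combo_of(shuffled), levels = combos))
      as.numeric(tab)
    }, numeric(length(combos)))
  })
  k <- length(combos)
  a <- (1 - level) / k  # Bonferroni-widened two-sided bounds
  lo <- apply(rand_counts, 1, quantile, probs = a / 2, type = 7)
  hi <- apply(rand_counts, 1, quantile, probs = 1 - a / 2, type = 7)
  obs <- as.numeric(observed[combos])
  tibble::tibble(
    combo = combos, observed = obs, rand_lo = lo, rand_hi = hi,
    direction = dplyr::case_when(obs > hi ~ "enriched",
                                 obs < lo ~ "depleted",
                                 TRUE ~ "ns"),
    flagged = obs > hi | obs < lo
  )
}
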