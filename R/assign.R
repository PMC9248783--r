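curve_matrix <- function(curves, value) {
  validate_melt_data(curves, value = value)
  ids <- unique(curves$sample_id)
  temps <- unique(curves$temperature)
  m <- matrix(NA_real_, nrow = length(ids), ncol = length(temps),
              dimnames = list(ids, NULL))
  for (k in seq_along(ids)) {
    sub <- curves[curves$sample_id == ids[[k]], ]
    m[k, ] <- sub[[value]][match(temps, sub$temperature)]
  }
  list(m = m, grid = temps)
}

window_cols <- function(grid, window) {
  if (is.null(window)) return(seq_along(grid))
  keep <- which(grid >= window[[1L]] & grid <= window[[2L]])
  if (!length(keep)) keep <- seq_along(grid)  # grid entirely outside window
  keep
}

#' Distance between two melting or difference curves
#'
#' Quantifies curve dissimilarity for classification and clustering
#' (the visual curve comparison of an HRM assay, made numeric).
#' Metrics: `"euclidean"` (root of summed squared pointwise
#' differences, the default), `"max_abs"` (largest absolute pointwise
#' difference), `"tm_delta"` (absolute difference of the two called
#' Tms; requires `temperatures`).
#'
#' @param a,b Numeric value vectors on the same temperature grid, or
#'   two-column data frames (`temperature` + value) with equal grids.
#' @param metric One of `"euclidean"`, `"max_abs"`, `"tm_delta"`.
#' @param temperatures Temperature grid, required for `"tm_delta"`
#'   when `a` and `b` are bare vectors.
#' @return A nonnegative scalar.
#' @export
#' @examples
#' curve_distance(c(0, 0), c(3, 4))             # 5
#' curve_distance(c(0, 0), c(3, 4), "max_abs")  # 4
curve_distance <- function(a, b, metric = c("euclidean", "max_abs",
                                            "tm_delta"),
                           temperatures = NULL) {
  metric <- match.arg(metric)
  pull_curve <- function(x) {
    if (is.data.frame(x)) {
      val <- setdiff(names(x), c("sample_id", "label", "temperature"))[[1L]]
      list(t = x$temperature, y = x[[val]])
    } else {
      list(t = temperatures, y = as.numeric(x))
    }
  }
  ca <- pull_curve(a)
  cb <- pull_curve(b)
  if (length(ca$y) != length(cb$y)) {
    stop("curves have different lengths (", length(ca$y), " vs ",
         length(cb$y), ")", call. = FALSE)
  }
  if (!is.null(ca$t) && !is.null(cb$t) && !isTRUE(all.equal(ca$t, cb$t))) {
    stop("curves are on different temperature grids; regrid first",
         call. = FALSE)
  }
  switch(metric,
    euclidean = sqrt(sum((ca$y - cb$y)^2)),
    max_abs = max(abs(ca$y - cb$y)),
    tm_delta = {
      if (is.null(ca$t)) {
        stop("tm_delta needs temperatures", call. = FALSE)
      }
      ta <- tm_from_curve(ca$t, ca$y)
      tb <- tm_from_curve(cb$t, cb$y)
      if (ta$no_peak || tb$no_peak) {
        stop("tm_delta undefined: a curve has no interior peak",
             call. = FALSE)
      }
      abs(ta$tm - tb$tm)
    })
}

#' Build a reference curve library
#'
#' Averages labeled reference melting curves per label (replicate
#' averaging, unless already averaged) and records the within-replicate
#' distance spread used to calibrate the automatic classification
#' thresholds. Distances are computed on an analysis window (default
#' 70-85 degrees C) so baseline-region noise outside the melt
#' transition does not dominate the comparison.
#'
#' @param curves Curves tibble with a `label` column; multiple samples
#'   per label are averaged.
#' @param value Curve column (default `"dneg"`).
#' @param window Analysis window in degrees C (default `c(70, 85)`);
#'   `NULL` for the full grid.
#' @return An `hrm_library` object: mean curve per label, shared grid,
#'   analysis window, and the within-replicate spread (median Euclidean
#'   distance of each replicate to its label mean over the window; 0
#'   when references carry no replicate structure).
#' @export
build_reference_library <- function(curves, value = "dneg",
                                    window = c(70, 85)) {
  if (!"label" %in% names(curves) || anyNA(curves$label)) {
    stop("every reference curve must be labeled", call. = FALSE)
  }
  validate_melt_data(curves, value = value)
  cm <- curve_matrix(curves, value)
  labels <- distinct(curves, .data$sample_id, .data$label)
  spread <- {
    tmp <- mutate(curves, replicate_group = .data$label)
    replicate_spread(tmp, value = value, window = window)
  }
  mean_curves <- curves |>
    group_by(.data$label, .data$temperature) |>
    summarise(!!value := mean(.data[[value]]), .groups = "drop") |>
    arrange(match(.data$label, unique(labels$label)), .data$temperature)
  structure(
    list(curves = mutate(mean_curves, sample_id = .data$label),
         grid = cm$grid, value = value, window = window, spread = spread,
         n_reference_wells = nrow(labels),
         built_from = paste0(nrow(labels), " reference wells, ",
                             length(unique(labels$label)), " labels")),
    class = "hrm_library")
}

#' @method print hrm_library
#' @export
print.hrm_library <- function(x, ...) {
  cat("<hrm_library> ", length(unique(x$curves$label)), " reference labels; ",
      length(x$grid), "-point grid [", min(x$grid), ", ", max(x$grid),
      "] C\n", sep = "")
  cat("  analysis window: ",
      if (is.null(x$window)) "full grid"
      else paste0("[", x$window[[1L]], ", ", x$window[[2L]], "] C"),
      "; within-replicate spread: ", signif(x$spread, 4), "\n", sep = "")
  invisible(x)
}

#' @method tidy hrm_library
#' @export
tidy.hrm_library <- function(x, ...) {
  call_tm(x$curves, value = x$value) |>
    select(label = "sample_id", "tm", "no_peak")
}

#' @method glance hrm_library
#' @export
glance.hrm_library <- function(x, ...) {
  tibble(n_labels = length(unique(x$curves$label)),
         n_points = length(x$grid),
         t_min = min(x$grid), t_max = max(x$grid),
         spread = x$spread,
         window_low = if (is.null(x$window)) min(x$grid) else x$window[[1L]],
         window_high = if (is.null(x$window)) max(x$grid) else x$window[[2L]])
}

auto_threshold <- function(x, spread, factor) {
  if (identical(x, "auto")) {
    if (!is.finite(spread) || spread <= 0) {
      return(if (factor > 2) Inf else 0)  # degenerate noiseless library
    }
    return(factor * spread)
  }
  stopifnot(is.numeric(x), x >= 0)
  x
}

#' Classify unknown melting curves against a reference library
#'
#' Each query is compared to every library entry by curve distance on
#' the library's analysis window. The best match wins unless (a) its
#' distance exceeds the rejection threshold — the sample is then
#' `unassigned` (no reference taxon melts like this) — or (b) the
#' runner-up is within the ambiguity margin of the best — the sample
#' is then `ambiguous`, with all labels inside the margin listed as
#' candidates (the situation of melt-indistinguishable species, which
#' a follow-up multiplex assay must resolve; see
#' [multiplex_resolve()]). Exact distance ties are ordered by label
#' and reported ambiguous, so classification is deterministic.
#'
#' Thresholds default to `"auto"`: 5x (reject) and 2x (margin) the
#' library's within-replicate distance spread. With a noiseless
#' library (spread 0) auto thresholds degenerate to reject = Inf,
#' margin = 0.
#'
#' @param curves Query curves tibble (same value column as the
#'   library); grids differing from the library's are linearly
#'   regridded when the query range covers it.
#' @param library An [build_reference_library()] object.
#' @param reject,margin `"auto"` or nonnegative numbers.
#' @param metric Distance metric (see [curve_distance()]).
#' @return An `hrm_assignments` tibble: `sample_id`, `status`
#'   (`assigned`/`ambiguous`/`unassigned`), `best_label`, `distance`,
#'   `margin` (best-to-runner-up distance gap), `method`, and a
#'   `candidates` list column of per-label distance tibbles sorted by
#'   ascending distance.
#' @export
classify_curves <- function(curves, library, reject = "auto",
                            margin = "auto", metric = "euclidean") {
  stopifnot(inherits(library, "hrm_library"))
  value <- library$value
  if (!value %in% names(curves) && "dneg" %in% names(curves)) value <- "dneg"
  validate_melt_data(curves, value = value)
  qgrid <- unique(curves$temperature)
  if (!isTRUE(all.equal(qgrid, library$grid))) {
    curves <- regrid_curves(curves, library$grid, value = value)
  }
  reject <- auto_threshold(reject, library$spread, 5)
  margin <- auto_threshold(margin, library$spread, 2)
  qm <- curve_matrix(curves, value)
  lm_ <- curve_matrix(library$curves, library$value)
  cols <- window_cols(library$grid, library$window)
  labs <- rownames(lm_$m)
  rows <- lapply(rownames(qm$m), function(id) {
    d <- sqrt(rowSums((lm_$m[, cols, drop = FALSE] -
                       matrix(qm$m[id, cols], nrow = nrow(lm_$m),
                              ncol = length(cols), byrow = TRUE))^2))
    if (metric == "max_abs") {
      d <- apply(abs(lm_$m[, cols, drop = FALSE] -
                     matrix(qm$m[id, cols], nrow = nrow(lm_$m),
                            ncol = length(cols), byrow = TRUE)), 1L, max)
    }
    ord <- order(d, labs)
    cand <- tibble(label = labs[ord], distance = d[ord])
    best <- cand$distance[[1L]]
    gap <- if (nrow(cand) > 1L) cand$distance[[2L]] - best else Inf
    status <- if (best > reject) {
      "unassigned"
    } else if (gap < margin || gap == 0) {
      "ambiguous"
    } else {
      "assigned"
    }
    in_margin <- cand$distance - best <= max(margin, 0)
    tibble(sample_id = id, status = status,
           best_label = if (status == "unassigned") NA_character_
                        else cand$label[[1L]],
           distance = best, margin = gap, method = "hrm",
           candidates = list(if (status == "ambiguous") cand[in_margin, ]
                             else cand))
  })
  out <- bind_rows(rows)
  class(out) <- c("hrm_assignments", class(out))
  attr(out, "reject") <- reject
  attr(out, "margin_threshold") <- margin
  out
}

#' Resolve ambiguous assignments with a multiplex melt readout
#'
#' For species pairs the primary assay cannot separate, a multiplex
#' reaction amplifies a species-specific secondary product whose Tm
#' falls in a label-specific window. Each ambiguous sample with a
#' multiplex curve gets its multiplex Tm called: inside exactly one
#' candidate's window it becomes `assigned` (method `"multiplex"`); no
#' peak (no amplification of either product) makes it `unassigned`; a Tm
#' outside every window or inside overlapping windows is inconclusive and
#' leaves it `ambiguous`.
#'
#' @param assignments An `hrm_assignments` tibble from
#'   [classify_curves()].
#' @param multiplex_curves Melting curves of the multiplex wells
#'   (`sample_id` matching the ambiguous samples, `temperature`,
#'   `dneg`).
#' @param rule Named list mapping candidate labels to
#'   `c(tm_low, tm_high)` windows, e.g. from
#'   [default_multiplex_rule()] or [read_multiplex_rule()]. Every rule
#'   label must be among the sample's candidates.
#' @return The assignments tibble with resolved rows updated.
#' @export
multiplex_resolve <- function(assignments, multiplex_curves, rule) {
  stopifnot(is.list(rule), !is.null(names(rule)))
  win <- do.call(rbind, lapply(rule, function(w) {
    stopifnot(length(w) == 2L, w[[1L]] < w[[2L]])
    as.numeric(w)
  }))
  tms <- call_tm(multiplex_curves)
  for (i in seq_len(nrow(assignments))) {
    if (assignments$status[[i]] != "ambiguous") next
    id <- assignments$sample_id[[i]]
    j <- match(id, tms$sample_id)
    if (is.na(j)) next  # no multiplex well for this sample
    cand_labels <- assignments$candidates[[i]]$label
    missing <- setdiff(names(rule), cand_labels)
    if (length(missing)) {
      stop("multiplex rule covers label(s) absent from the candidates of ",
           id, ": ", paste(missing, collapse = ", "), call. = FALSE)
    }
    if (tms$no_peak[[j]]) {
      assignments$status[[i]] <- "unassigned"
      assignments$best_label[[i]] <- NA_character_
      assignments$method[[i]] <- "multiplex"
      next
    }
    tm <- tms$tm[[j]]
    inside <- names(rule)[win[, 1L] <= tm & tm <= win[, 2L]]
    if (length(inside) == 1L) {
      assignments$status[[i]] <- "assigned"
      assignments$best_label[[i]] <- inside
      assignments$method[[i]] <- "multiplex"
    }
    # Tm outside every window, or inside overlapping windows: the readout
    # is inconclusive and the sample remains ambiguous
  }
  assignments
}

#' Default multiplex Tm windows for the caliginosa/longa assay
#'
#' Shipped configuration, not hard-coded biology: windows bracket the
#' simulator's model Tms for the two multiplex products (a 116-bp 16S
#' product around 68 degrees C for *Aporrectodea caliginosa*, a 213-bp
#' COI product around 75.5 degrees C for *Apo. longa*). Override with
#' your own windows (or [read_multiplex_rule()]) when calibrating
#' against instrument data.
#'
#' @return Named list of `c(tm_low, tm_high)` windows.
#' @export
default_multiplex_rule <- function() {
  list(Apo_caliginosa = c(66, 70.5), Apo_longa = c(73.5, 77.5))
}

#' Read multiplex Tm windows from a YAML file
#'
#' Expected layout: a mapping from label to a two-element
#' `[tm_low, tm_high]` list.
#'
#' @param path YAML file path.
#' @return Named list of numeric windows.
#' @export
read_multiplex_rule <- function(path) {
  rule <- yaml::read_yaml(path)
  lapply(rule, function(w) {
    w <- as.numeric(unlist(w))
    if (length(w) != 2L || anyNA(w) || w[[1L]] >= w[[2L]]) {
      stop("each multiplex window must be [tm_low, tm_high] with ",
           "tm_low < tm_high", call. = FALSE)
    }
    w
  })
}

#' Cluster difference curves into haplotype groups
#'
#' Agglomerative (average linkage) clustering of curves under the
#' Euclidean curve distance, cut at a fixed height or automatically.
#' The automatic cut is 3x the within-replicate-group distance spread
#' when replicate structure is supplied (`spread`), else 3x the median
#' nearest-neighbour distance — i.e. groups merge only across gaps
#' clearly larger than measurement noise. Group indices are contiguous
#' from 1 and canonically relabeled by first occurrence in the input,
#' so the result is invariant to input order as a partition.
#'
#' @param diffs Difference-curve tibble (`sample_id`, `temperature`,
#'   `delta`), at least 2 curves on one grid.
#' @param cut `"auto"` or a linkage height.
#' @param spread Optional within-replicate spread from
#'   [replicate_spread()] used by the auto cut.
#' @param value Curve column (default `"delta"`).
#' @param window Optional analysis window (default `NULL`, full grid).
#' @return An `hrm_clusters` object; `tidy()` gives `sample_id` /
#'   `group`, `glance()` gives `n_groups` and the cut height.
#' @export
cluster_groups <- function(diffs, cut = "auto", spread = NULL,
                           value = "delta", window = NULL) {
  cm <- curve_matrix(diffs, value)
  if (nrow(cm$m) < 2L) {
    stop("need at least 2 curves to cluster", call. = FALSE)
  }
  cols <- window_cols(cm$grid, window)
  d <- dist(cm$m[, cols, drop = FALSE])
  if (identical(cut, "auto")) {
    dm <- as.matrix(d)
    diag(dm) <- Inf
    nn <- apply(dm, 1L, min)
    base_scale <- if (!is.null(spread) && is.finite(spread) && spread > 0) {
      spread
    } else {
      median(nn)
    }
    cut <- 3 * base_scale
    if (!is.finite(cut) || cut <= 0) cut <- 1e-8  # all-identical degenerate set
  }
  hc <- hclust(d, method = "average")
  raw <- cutree(hc, h = cut)
  first_seen <- unique(raw[rownames(cm$m)])
  groups <- match(raw, first_seen)
  names(groups) <- rownames(cm$m)
  structure(
    list(assignments = tibble(sample_id = rownames(cm$m),
                              group = as.integer(groups)),
         n_groups = length(first_seen), cut = cut, hclust = hc,
         method = "average linkage, euclidean", diffs = diffs,
         value = value),
    class = "hrm_clusters")
}

#' @method print hrm_clusters
#' @export
print.hrm_clusters <- function(x, ...) {
  cat("<hrm_clusters> ", nrow(x$assignments), " curves in ", x$n_groups,
      " group(s); cut height ", signif(x$cut, 4), " (", x$method, ")\n",
      sep = "")
  invisible(x)
}

#' @method tidy hrm_clusters
#' @export
tidy.hrm_clusters <- function(x, ...) x$assignments

#' @method glance hrm_clusters
#' @export
glance.hrm_clusters <- function(x, ...) {
  tibble(n_curves = nrow(x$assignments), n_groups = x$n_groups,
         linkage_height_cut = x$cut, method = x$method)
}
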