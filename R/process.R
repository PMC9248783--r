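#' Savitzky-Golay smoothing of raw fluorescence
#'
#' Local least-squares polynomial smoothing applied per sample to the
#' raw RFU signal *before* differentiation (never to the derivative
#' curve). The default window of 7 grid points with a quadratic fit
#' preserves melt-peak position on a 0.1 degree C ramp while removing
#' well-to-well shot noise. Requires a uniform temperature grid;
#' non-uniform grids must be regridded explicitly first (see
#' [regrid_curves()]) — there is no silent resampling.
#'
#' @param data Long melt tibble (`sample_id`, `temperature`, `rfu`).
#' @param window Odd number of grid points (default 7).
#' @param poly_order Polynomial order (default 2); `window` must be at
#'   least `poly_order + 2`.
#' @param enabled If `FALSE`, return the input unchanged.
#' @return The tibble with `rfu` replaced by its smoothed value.
#' @export
smooth_rfu <- function(data, window = 7L, poly_order = 2L, enabled = TRUE) {
  if (!enabled) return(data)
  validate_melt_data(data)
  window <- as.integer(window)
  if (window %% 2L == 0L || window < poly_order + 2L) {
    stop("smoothing window must be odd and >= poly_order + 2", call. = FALSE)
  }
  temps <- unique(data$temperature)
  if (length(temps) < window) {
    stop("smoothing window (", window, ") larger than series (",
         length(temps), " points)", call. = FALSE)
  }
  steps <- diff(temps)
  if (max(steps) - min(steps) > 1e-6) {
    stop("non-uniform temperature grid (spacing varies by more than 1e-6); ",
         "regrid before smoothing", call. = FALSE)
  }
  data |>
    group_by(.data$sample_id) |>
    mutate(rfu = signal::sgolayfilt(.data$rfu, p = poly_order, n = window)) |>
    ungroup()
}

neg_deriv <- function(f, t) {
  n <- length(f)
  if (n < 3L) stop("need at least 3 points to differentiate", call. = FALSE)
  d <- numeric(n)
  d[1L] <- (f[2L] - f[1L]) / (t[2L] - t[1L])
  d[n] <- (f[n] - f[n - 1L]) / (t[n] - t[n - 1L])
  i <- 2:(n - 1L)
  d[i] <- (f[i + 1L] - f[i - 1L]) / (t[i + 1L] - t[i - 1L])
  -d
}

#' Melting curves: negative first derivative of fluorescence
#'
#' Converts raw RFU series into melting curves, -dF/dT in RFU per
#' degree C: central finite differences at interior points, one-sided
#' differences at the two ends, each negated. Optional Savitzky-Golay
#' smoothing of the raw signal is applied first (on by default).
#'
#' @param data Long melt tibble.
#' @param smooth Apply [smooth_rfu()] first (default `TRUE`).
#' @param smooth_window,smooth_poly Passed to [smooth_rfu()].
#' @return A curves tibble: `sample_id`, `temperature`, `dneg`, plus any
#'   metadata columns (`label`, `replicate_group`, `role`) present in
#'   the input.
#' @export
#' @examples
#' raw <- tibble::tibble(sample_id = "w1",
#'                       temperature = c(65, 65.1, 65.2),
#'                       rfu = c(100, 90, 70))
#' melt_curves(raw, smooth = FALSE)
melt_curves <- function(data, smooth = TRUE, smooth_window = 7L,
                        smooth_poly = 2L) {
  validate_melt_data(data)
  if (smooth) {
    data <- smooth_rfu(data, window = smooth_window, poly_order = smooth_poly)
  }
  meta <- intersect(c("label", "replicate_group", "role"), names(data))
  data |>
    group_by(across(all_of(c("sample_id", meta)))) |>
    arrange(.data$temperature, .by_group = TRUE) |>
    mutate(dneg = neg_deriv(.data$rfu, .data$temperature)) |>
    ungroup() |>
    select(all_of(c("sample_id", meta, "temperature", "dneg")))
}

tm_from_curve <- function(t, y) {
  n <- length(y)
  if (n < 3L) stop("need at least 3 points to call Tm", call. = FALSE)
  peak <- which.max(y)  # which.max breaks ties toward lower temperature
  if (peak == 1L || peak == n) {
    return(list(tm = NA_real_, no_peak = TRUE))
  }
  t3 <- t[(peak - 1L):(peak + 1L)]
  y3 <- y[(peak - 1L):(peak + 1L)]
  co <- tryCatch(stats::coef(stats::lm(y3 ~ t3 + I(t3^2))),
                 error = function(e) c(NA, NA, NA))
  a <- co[[3L]]
  tm <- if (is.finite(a) && a < 0) -co[[2L]] / (2 * a) else t[[peak]]
  if (tm < t3[[1L]] || tm > t3[[3L]]) tm <- t[[peak]]
  list(tm = tm, no_peak = FALSE)
}

#' Call melting temperatures from melting curves
#'
#' The Tm of each sample is the temperature of the global maximum of
#' -dF/dT, refined by the vertex of the parabola through the peak and
#' its two neighbours. Ties break toward lower temperature. A maximum
#' sitting on a boundary grid point means no interior melt peak exists
#' (e.g. no amplification, or Tm outside the ramp); the sample is
#' flagged `no_peak` with `tm = NA`.
#'
#' @param curves Curves tibble with a `dneg` (or `value`) column.
#' @param value Name of the curve column (default `"dneg"`).
#' @return A tibble with one row per sample: `sample_id`, `tm`,
#'   `no_peak`, plus `label` if present in the input.
#' @export
call_tm <- function(curves, value = "dneg") {
  validate_melt_data(curves, value = value)
  meta <- intersect("label", names(curves))
  curves |>
    group_by(across(all_of(c("sample_id", meta)))) |>
    arrange(.data$temperature, .by_group = TRUE) |>
    summarise(res = list(tm_from_curve(.data$temperature, .data[[value]])),
              .groups = "drop") |>
    mutate(tm = vapply(.data$res, `[[`, numeric(1L), "tm"),
           no_peak = vapply(.data$res, `[[`, logical(1L), "no_peak")) |>
    select(-"res")
}

#' Average technical replicates
#'
#' Pointwise arithmetic mean of melting curves within each replicate
#' group (the standard readout is the mean of five technical
#' replicates). Groups of size one pass through unchanged. All curves
#' in a group must share an identical temperature grid.
#'
#' @param curves Curves tibble with a `replicate_group` column (or use
#'   `group_col` to average by any other column, e.g. `label`).
#' @param group_col Column defining the groups (default
#'   `"replicate_group"`).
#' @param value Curve column to average (default `"dneg"`).
#' @return A curves tibble with one sample per group; `sample_id` takes
#'   the group name, and `label`/`role` are retained where they are
#'   constant within the group.
#' @export
average_replicates <- function(curves, group_col = "replicate_group",
                               value = "dneg") {
  if (!group_col %in% names(curves)) {
    stop("no column ", dQuote(group_col), " in curves", call. = FALSE)
  }
  validate_melt_data(curves, value = value)
  grid_by_sample <- curves |>
    group_by(.data$sample_id) |>
    summarise(n = dplyr::n(), .groups = "drop")
  # shared-grid check per group: every member sample must span the same grid
  for (g in unique(curves[[group_col]])) {
    sub <- curves[curves[[group_col]] == g, ]
    grids <- split(sub$temperature, sub$sample_id)
    ref <- grids[[1L]]
    ok <- vapply(grids, function(x) length(x) == length(ref) && all(x == ref),
                 logical(1L))
    if (!all(ok)) {
      stop("mismatched temperature grids within replicate group ",
           dQuote(g), call. = FALSE)
    }
  }
  keep_meta <- function(x) if (length(unique(x)) == 1L) x[[1L]] else NA_character_
  meta <- intersect(c("label", "role"), names(curves))
  out <- curves |>
    group_by(across(all_of(c(group_col, "temperature")))) |>
    summarise(
      !!value := mean(.data[[value]]),
      across(all_of(meta), keep_meta),
      .groups = "drop"
    )
  names(out)[names(out) == group_col] <- "sample_id"
  out <- out[order(match(out$sample_id, unique(curves[[group_col]])),
                   out$temperature), ]
  select(out, all_of(c("sample_id", meta, "temperature", value)))
}

#' Difference curves against a reference mean
#'
#' For each sample the difference curve is the mean melting curve of
#' the reference set minus the sample's own curve (the conventional HRM
#' difference plot, which amplifies small shape differences between
#' genotypes). Curves outside the reference set are differenced against
#' the same mean. Over the reference set itself the difference curves
#' sum to zero at every temperature by construction.
#'
#' @param curves Curves tibble on one shared grid.
#' @param reference Character vector of `sample_id`s forming the
#'   comparison set; default all samples.
#' @param value Curve column (default `"dneg"`; pass a normalized
#'   fluorescence column for the classic normalized-difference mode,
#'   see [normalize_fluorescence()]).
#' @return A tibble `sample_id`, `temperature`, `delta` (plus `label`
#'   if present).
#' @export
#' @examples
#' curves <- tibble::tibble(
#'   sample_id = rep(c("a", "b", "c"), each = 2),
#'   temperature = rep(c(70, 71), 3),
#'   dneg = c(2, 4, 0, 0, 1, 2))
#' difference_curves(curves)
difference_curves <- function(curves, reference = NULL, value = "dneg") {
  validate_melt_data(curves, value = value)
  ids <- unique(curves$sample_id)
  if (is.null(reference)) reference <- ids
  missing_ref <- setdiff(reference, ids)
  if (length(missing_ref)) {
    stop("reference ids not in curves: ", paste(missing_ref, collapse = ", "),
         call. = FALSE)
  }
  ref_mean <- curves |>
    filter(.data$sample_id %in% reference) |>
    group_by(.data$temperature) |>
    summarise(.m = mean(.data[[value]]), .groups = "drop")
  meta <- intersect("label", names(curves))
  curves |>
    left_join(ref_mean, by = "temperature") |>
    mutate(delta = .data$.m - .data[[value]]) |>
    select(all_of(c("sample_id", meta, "temperature", "delta")))
}

#' Interpolate curves onto a new temperature grid
#'
#' Linear interpolation of each sample's series onto `grid`. The target
#' grid must lie inside the source range; extrapolation is refused.
#'
#' @param data Long tibble with a value column.
#' @param grid Strictly increasing numeric vector of target
#'   temperatures.
#' @param value Value column name (default `"rfu"`).
#' @return The regridded tibble (metadata columns preserved).
#' @export
regrid_curves <- function(data, grid, value = "rfu") {
  validate_melt_data(data, value = value)
  if (any(diff(grid) <= 0)) stop("target grid must be strictly increasing",
                                 call. = FALSE)
  rng <- range(data$temperature)
  if (min(grid) < rng[[1L]] || max(grid) > rng[[2L]]) {
    stop("target grid [", min(grid), ", ", max(grid),
         "] outside source range [", rng[[1L]], ", ", rng[[2L]],
         "]; extrapolation refused", call. = FALSE)
  }
  meta <- intersect(c("label", "replicate_group", "role"), names(data))
  data |>
    group_by(across(all_of(c("sample_id", meta)))) |>
    summarise(
      !!value := list(approx(.data$temperature, .data[[value]], xout = grid)$y),
      temperature = list(grid),
      .groups = "drop"
    ) |>
    tidyr::unnest(all_of(c("temperature", value)))
}

#' Classic HRM fluorescence normalization
#'
#' Rescales each raw RFU series to a 0-100 percent helicity-like scale
#' using linear baselines fitted in a pre-melt and a post-melt
#' temperature window (the normalization used by commercial HRM
#' software before plotting difference curves on raw fluorescence).
#' Off the package's default path — difference curves are computed on
#' -dF/dT curves by default — but provided for comparison with
#' instrument software output.
#'
#' @param data Long melt tibble.
#' @param pre_window,post_window Two-element numeric ranges (degrees C)
#'   for the fully double-stranded and fully melted baselines; defaults
#'   65-70 and 90-95.
#' @return The tibble with an added `rfu_norm` column (percent).
#' @export
normalize_fluorescence <- function(data, pre_window = c(65, 70),
                                   post_window = c(90, 95)) {
  validate_melt_data(data)
  norm_one <- function(t, f) {
    pre <- t >= pre_window[[1L]] & t <= pre_window[[2L]]
    post <- t >= post_window[[1L]] & t <= post_window[[2L]]
    if (sum(pre) < 2L || sum(post) < 2L) {
      stop("baseline windows must each contain at least 2 grid points",
           call. = FALSE)
    }
    up <- stats::lm(f[pre] ~ t[pre])$coefficients
    lo <- stats::lm(f[post] ~ t[post])$coefficients
    upper <- up[[1L]] + up[[2L]] * t
    lower <- lo[[1L]] + lo[[2L]] * t
    100 * (f - lower) / (upper - lower)
  }
  meta <- intersect(c("label", "replicate_group", "role"), names(data))
  data |>
    group_by(across(all_of(c("sample_id", meta)))) |>
    arrange(.data$temperature, .by_group = TRUE) |>
    mutate(rfu_norm = norm_one(.data$temperature, .data$rfu)) |>
    ungroup()
}

#' Within-replicate-group curve spread
#'
#' Median Euclidean distance between each curve and its replicate-group
#' mean, the scale used to calibrate classification thresholds and the
#' automatic clustering cut.
#'
#' @param curves Curves tibble with a `replicate_group` column.
#' @param value Curve column (default `"dneg"`).
#' @param window Optional two-element temperature range restricting the
#'   comparison (default `NULL`, all points).
#' @return A single number (0 when all replicates are identical).
#' @export
replicate_spread <- function(curves, value = "dneg", window = NULL) {
  if (!"replicate_group" %in% names(curves)) {
    stop("curves must carry a replicate_group column", call. = FALSE)
  }
  if (!is.null(window)) {
    curves <- filter(curves, .data$temperature >= window[[1L]],
                     .data$temperature <= window[[2L]])
  }
  dists <- curves |>
    group_by(.data$replicate_group, .data$temperature) |>
    mutate(.m = mean(.data[[value]])) |>
    group_by(.data$replicate_group, .data$sample_id) |>
    summarise(d = sqrt(sum((.data[[value]] - .data$.m)^2)), .groups = "drop")
  median(dists$d)
}
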