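test_that("curve distances match hand values and axioms", {
  expect_equal(curve_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(curve_distance(c(0, 0), c(3, 4), "max_abs"), 4)
  x <- rnorm(20)
  expect_equal(curve_distance(x, x), 0)
  expect_equal(curve_distance(x, x, "max_abs"), 0)
  y <- rnorm(20)
  expect_equal(curve_distance(x, y), curve_distance(y, x))
  expect_error(curve_distance(c(1, 2), c(1, 2, 3)), "lengths")
  expect_error(curve_distance(c(1, 2), c(1, 2), "mahalanobis"))

  grid <- ramp_grid()
  tmd <- curve_distance(logistic_dneg(grid, 74), logistic_dneg(grid, 76),
                        "tm_delta", temperatures = grid)
  expect_lt(abs(tmd - 2), 0.1)
})

test_that("a reference library averages labels and records spread", {
  plate <- simulate_melt_plate(setNames(73 + 0.8 * (0:7),
                                        paste0("sp", 1:8)),
                               replicates = 5L, seed = 9L)
  cv <- melt_curves(plate$data)
  lib <- build_reference_library(cv)
  expect_s3_class(lib, "hrm_library")
  expect_equal(length(unique(lib$curves$label)), 8L)
  expect_gt(lib$spread, 0)
  expect_equal(nrow(tidy(lib)), 8L)
  expect_equal(glance(lib)$n_points, 301L)

  single <- build_reference_library(
    dplyr::mutate(curves_tbl(list(w = c(1, 2, 1)), c(70, 71, 72)),
                  label = "only"), window = NULL)
  expect_equal(length(unique(single$curves$label)), 1L)

  unlabeled <- curves_tbl(list(w = c(1, 2, 1)), c(70, 71, 72))
  expect_error(build_reference_library(unlabeled), "labeled")

  diff_grids <- dplyr::bind_rows(
    tibble::tibble(sample_id = "x", label = "A",
                   temperature = c(70, 71), dneg = c(1, 2)),
    tibble::tibble(sample_id = "y", label = "A",
                   temperature = c(70, 72), dneg = c(1, 2)))
  expect_error(build_reference_library(diff_grids), "grid")
})

test_that("classification assigns, abstains, and rejects correctly", {
  grid <- seq(70, 80, by = 0.1)
  mk <- function(tm) logistic_dneg(grid, tm)$dneg
  refs <- curves_tbl(list(A = mk(73), B = mk(76), C = mk(79)), grid)
  refs$label <- refs$sample_id
  lib <- build_reference_library(refs, window = NULL)

  # exact match -> assigned at distance 0
  q <- curves_tbl(list(q1 = mk(73)), grid)
  a <- classify_curves(q, lib, reject = 10, margin = 0.01)
  expect_equal(a$status, "assigned")
  expect_equal(a$best_label, "A")
  expect_equal(a$distance, 0)

  # midpoint curve equidistant to A and B -> ambiguous with 2 candidates
  mid <- curves_tbl(list(qm = (mk(73) + mk(76)) / 2), grid)
  am <- classify_curves(mid, lib, reject = 10, margin = 0.01)
  expect_equal(am$status, "ambiguous")
  expect_equal(sort(am$candidates[[1]]$label), c("A", "B"))

  # farther than the rejection threshold from everything -> unassigned
  far <- curves_tbl(list(qf = mk(73) * 50), grid)
  af <- classify_curves(far, lib, reject = 1, margin = 0.01)
  expect_equal(af$status, "unassigned")
  expect_true(is.na(af$best_label))

  expect_error(classify_curves(q, lib, reject = -1), "x >= 0")
})

test_that("classification is scale-consistent and margin-monotone", {
  grid <- seq(70, 80, by = 0.1)
  mk <- function(tm) logistic_dneg(grid, tm)$dneg
  refs <- curves_tbl(list(A = mk(73), B = mk(76)), grid)
  refs$label <- refs$sample_id
  lib1 <- build_reference_library(refs, window = NULL)
  q <- curves_tbl(list(q = mk(73.4)), grid)
  a1 <- classify_curves(q, lib1, reject = 5, margin = 0.2)

  c_scale <- 4
  refs2 <- dplyr::mutate(refs, dneg = dneg * c_scale)
  lib2 <- build_reference_library(refs2, window = NULL)
  q2 <- dplyr::mutate(q, dneg = dneg * c_scale)
  a2 <- classify_curves(q2, lib2, reject = 5 * c_scale,
                        margin = 0.2 * c_scale)
  expect_equal(a2$status, a1$status)
  expect_equal(a2$best_label, a1$best_label)
  expect_equal(a2$distance, c_scale * a1$distance, tolerance = 1e-9)

  # increasing the margin can only move assigned -> ambiguous, never back
  margins <- c(0, 0.05, 0.2, 1, 5, 50)
  states <- vapply(margins, function(m)
    classify_curves(q, lib1, reject = Inf, margin = m)$status, character(1))
  rank <- c(assigned = 1L, ambiguous = 2L)
  expect_true(all(diff(rank[states]) >= 0))
})

test_that("multiplex melt readout resolves or abstains per Tm window", {
  grid <- seq(70, 80, by = 0.1)
  mk <- function(tm) logistic_dneg(grid, tm)$dneg
  refs <- curves_tbl(list(cal = mk(75.00), lon = mk(75.02)), grid)
  refs$label <- refs$sample_id
  lib <- build_reference_library(refs, window = NULL)
  q <- curves_tbl(list(q1 = mk(75.01)), grid)
  amb <- classify_curves(q, lib, reject = Inf, margin = 1)
  expect_equal(amb$status, "ambiguous")

  rule <- list(cal = c(71, 73), lon = c(76, 78))
  # peak inside the cal window -> assigned cal by multiplex
  mpx <- curves_tbl(list(q1 = mk(72)), grid)
  res <- multiplex_resolve(amb, mpx, rule)
  expect_equal(res$status, "assigned")
  expect_equal(res$best_label, "cal")
  expect_equal(res$method, "multiplex")

  # no peak (monotone curve) -> unassigned
  flat <- curves_tbl(list(q1 = seq(0, 1, length.out = length(grid))), grid)
  res2 <- multiplex_resolve(amb, flat, rule)
  expect_equal(res2$status, "unassigned")

  # Tm between the windows -> stays ambiguous
  between <- curves_tbl(list(q1 = mk(74.5)), grid)
  res3 <- multiplex_resolve(amb, between, rule)
  expect_equal(res3$status, "ambiguous")

  # rule naming a label absent from the candidates -> configuration error
  bad_rule <- list(cal = c(71, 73), other = c(76, 78))
  expect_error(multiplex_resolve(amb, mpx, bad_rule), "absent")
})

test_that("difference-curve clustering recovers planted partitions", {
  # three planted clusters, between-cluster delta-Tm 1.0 C, curve noise
  # sd 0.01 RFU/C added directly to the noiseless melting curves
  set.seed(31)
  grid <- ramp_grid()
  tms <- rep(c(73, 74, 75), each = 4)
  labels <- sprintf("w%02d", seq_along(tms))
  cv <- dplyr::bind_rows(lapply(seq_along(tms), function(i) {
    base <- logistic_dneg(grid, tms[[i]])
    tibble::tibble(sample_id = labels[[i]], temperature = grid,
                   dneg = base$dneg + rnorm(length(grid), sd = 0.01))
  }))
  diffs <- difference_curves(cv)
  cl <- cluster_groups(diffs, cut = "auto")
  expect_equal(cl$n_groups, 3L)
  got <- tidy(cl)
  expect_equal(got$group, rep(1:3, each = 4))

  # permutation invariance as a partition
  shuffled <- diffs[order(rev(match(diffs$sample_id, labels))), ]
  cl2 <- cluster_groups(shuffled, cut = "auto")
  m <- dplyr::inner_join(tidy(cl), tidy(cl2), by = "sample_id")
  expect_equal(length(unique(paste(m$group.x, m$group.y))), 3L)

  ident <- curves_tbl(list(a = c(1, 2), b = c(1, 2), c = c(1, 2)),
                      c(70, 71))
  names(ident)[names(ident) == "dneg"] <- "delta"
  expect_equal(cluster_groups(ident)$n_groups, 1L)
  expect_error(cluster_groups(ident[ident$sample_id == "a", ]),
               "at least 2")
})
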