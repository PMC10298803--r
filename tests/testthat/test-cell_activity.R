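test_that("correlation summary matches hand-computed block structure", {
  t_ax <- seq(0, 8 * pi, length.out = 400)
  a <- sin(t_ax); b <- cos(t_ax)  # orthogonal over whole periods
  traces <- rbind(matrix(rep(a, 10), 10, byrow = TRUE),
                  matrix(rep(b, 10), 10, byrow = TRUE))
  cs <- correlation_summary(traces)
  expect_equal(dim(cs$matrix), c(20, 20))
  expect_equal(diag(cs$matrix), rep(1, 20))
  expect_true(isSymmetric(cs$matrix))
  # per ROI: 9 within-group r = 1, 10 cross r = 0
  expected <- mean(rep(percentile_oracle(c(rep(1, 9), rep(0, 10)), 0.8), 20))
  expect_equal(cs$summary, expected, tolerance = 1e-10)
  # pooled mode uses one percentile over all pairs
  pooled <- correlation_summary(traces, mode = "pooled")
  expect_equal(pooled$summary,
               percentile_oracle(c(rep(1, 2 * 45), rep(0, 100)), 0.8),
               tolerance = 1e-10)
})

test_that("correlation summary is 1 for identical traces and small for noise", {
  tr <- matrix(rep(sin(1:100), 5), 5, byrow = TRUE)
  expect_equal(correlation_summary(tr)$summary, 1)
  set.seed(31)
  white <- matrix(rnorm(20 * 1200), 20)
  expect_lt(abs(correlation_summary(white)$summary), 0.1)
})

test_that("correlation summary is affine invariant and handles flat traces", {
  set.seed(7)
  tr <- matrix(rnorm(6 * 300), 6)
  tr2 <- tr * runif(6, 0.5, 3) + runif(6, -2, 2)
  expect_equal(correlation_summary(tr2)$summary, correlation_summary(tr)$summary)
  tr[3, ] <- 5  # zero variance
  cs <- correlation_summary(tr)
  expect_true(all(is.na(cs$matrix[3, -3])))
  expect_false(is.na(cs$summary))
})

test_that("IHC peaks are assigned to the earliest overlapping ISC event once", {
  mk_ev <- function(s, e) structure(list(
    voxels = data.frame(frame = s:e, row = 1, col = 1),
    start_frame = s, end_frame = e, n_rois = 1), class = "activity_event")
  asg <- assign_ihc_to_isc_events(list(a = c(12, 25)), list(mk_ev(10, 20)))
  expect_equal(asg$per_event$n_ihcs, 1)
  expect_equal(asg$unassigned_peaks, 1)

  # overlapping windows: earliest-starting event wins
  asg2 <- assign_ihc_to_isc_events(list(a = 17),
                                   list(mk_ev(15, 25), mk_ev(10, 20)))
  expect_equal(asg2$per_event$n_ihcs, c(1, 0))
  expect_equal(asg2$per_event$start_frame, c(10, 15))

  # random peaks/events equal an exhaustive double-loop oracle
  set.seed(13)
  evs <- lapply(sort(sample(1:400, 12)), function(s) mk_ev(s, s + sample(5:30, 1)))
  peaks <- lapply(1:15, function(i) sort(sample(1:450, sample(1:6, 1))))
  names(peaks) <- paste0("ihc", 1:15)
  asg3 <- assign_ihc_to_isc_events(peaks, evs)
  starts <- vapply(evs, function(e) e$start_frame, 1)
  ends <- vapply(evs, function(e) e$end_frame, 1)
  oracle_members <- lapply(seq_along(evs), function(e) character(0))
  n_un <- 0
  for (i in seq_along(peaks)) for (p in peaks[[i]]) {
    containing <- which(p >= starts & p <= ends)
    if (!length(containing)) { n_un <- n_un + 1; next }
    e <- containing[which.min(starts[containing])]
    oracle_members[[e]] <- union(oracle_members[[e]], names(peaks)[i])
  }
  expect_equal(asg3$per_event$n_ihcs, lengths(oracle_members))
  expect_equal(asg3$unassigned_peaks, n_un)
  # conservation
  expect_equal(asg3$assigned_peaks + asg3$unassigned_peaks, sum(lengths(peaks)))
})

test_that("ISC-IHC regression recovers exact and planted slopes", {
  x <- c(2, 4, 6, 8, 10)
  r <- suppressWarnings(isc_ihc_regression(x, 0.5 * x + 1))  # perfect-fit lm warning
  expect_equal(r$slope, 0.5)
  expect_equal(r$intercept, 1)
  expect_equal(r$r_squared, 1)
  expect_equal(suppressWarnings(isc_ihc_regression(x, rep(3, 5)))$slope, 0)
  expect_error(isc_ihc_regression(rep(2, 5), 1:5), "distinct")

  set.seed(41)
  xs <- runif(200, 5, 50)
  ys <- 0.3 * xs + rnorm(200, 0, 2)
  fit <- isc_ihc_regression(xs, ys)
  se <- summary(fit$fit)$coefficients[2, 2]
  expect_lt(abs(fit$slope - 0.3), 2 * se)
})

test_that("high-K+ filter keeps responders above the 10% criterion", {
  tr <- rbind(c(rep(0, 90), rep(0.5, 10)),
              c(rep(0, 90), rep(0.05, 10)),
              c(rep(0, 90), rep(0.11, 10)))
  expect_equal(filter_sgn_by_kcl(tr, 91:100), c(1, 3))
  expect_equal(filter_sgn_by_kcl(tr, 91:100, min_response = 0), 1:3)
  expect_error(filter_sgn_by_kcl(tr, integer(0)), "empty")
  expect_error(filter_sgn_by_kcl(tr, 95:120), "outside")

  # graded amplitudes straddling the criterion: equals direct comparison
  set.seed(3)
  amps <- runif(40, 0.02, 0.3)
  tr2 <- cbind(matrix(0, 40, 50), amps)
  expect_equal(filter_sgn_by_kcl(tr2, 51, min_response = 0.10),
               which(amps > 0.10))
})

test_that("pharmacology windows exclude the wash-in gap", {
  r <- pharmacology_window_compare(seq(10, 290, length.out = 10), 300, 900,
                                   washin_delay_s = 90)
  expect_equal(r$rate_before, 10 / 300)
  expect_equal(r$rate_after, 0)
  # events inside the gap count in neither window
  r2 <- pharmacology_window_compare(c(100, 310, 350, 500), 300, 900)
  expect_equal(r2$rate_before, 1 / 300)
  expect_equal(r2$rate_after, 1 / 510)
  expect_warning(pharmacology_window_compare(c(10), 100, 240), "shorter")

  # no drug effect: homogeneous Poisson rates agree over seeds
  set.seed(17)
  ratios <- replicate(50, {
    ev <- sort(runif(400, 0, 1800))
    rr <- pharmacology_window_compare(ev, 900, 1800)
    rr$rate_after / rr$rate_before
  })
  expect_equal(mean(ratios), 1, tolerance = 0.05)
})
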