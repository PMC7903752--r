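# Mesoscale feature extraction: normalisation, phases, events, factors,
# circularity, outliers, culture summaries.

test_that("normalisation divides by the well median of the fifth frame", {
  mk <- function(id, areas) data.frame(organoid_id = id, well_id = "w1",
                                       t_h = (seq_along(areas) - 1) * 0.5,
                                       area_mm2 = areas)
  tr <- rbind(mk("a", c(0.01, 0.01, 0.01, 0.015, 0.02, 0.03)),
              mk("b", c(0.04, 0.04, 0.04, 0.045, 0.05, 0.06)),
              mk("c", c(0.07, 0.07, 0.07, 0.075, 0.08, 0.09)))
  nt <- normalise_traces(tr)
  ## median of fifth-frame areas {0.02, 0.05, 0.08} = 0.05 for every organoid
  expect_equal(nt$area_norm, nt$area_mm2 / 0.05)
  expect_equal(sum(nt$formation_frame), 3L * 4L)
  ## single organoid: fifth frame normalises to exactly 1
  n1 <- normalise_traces(mk("solo", c(0.04, 0.04, 0.04, 0.045, 0.05, 0.06)))
  expect_equal(n1$area_norm[5L], 1)
  ## constant trace stays constant 1
  nc <- normalise_traces(mk("flat", rep(0.03, 8)))
  expect_equal(nc$area_norm, rep(1, 8))
})

test_that("organoids with fewer than five frames are excluded with a message", {
  tr <- data.frame(organoid_id = rep(c("ok", "short"), c(6, 3)),
                   well_id = "w1", t_h = c(0:5, 0:2) * 0.5,
                   area_mm2 = 0.05)
  expect_message(nt <- normalise_traces(tr), "short")
  expect_setequal(unique(nt$organoid_id), "ok")
  expect_equal(attr(nt, "excluded"), "short")
})

test_that("the decline detector applies the 5% rule frame by frame", {
  d <- detect_decline_phases(c(1.0, 1.0, 0.94, 0.90, 0.95))
  expect_equal(nrow(d), 1L)
  expect_equal(d$start_idx, 2L)  # the last peak frame before the drop
  expect_equal(d$end_idx, 4L)    # the trough
  expect_equal(d$depth_frac, 0.1)
  ## strictly increasing: nothing
  expect_equal(nrow(detect_decline_phases(seq(1, 2, by = 0.05))), 0L)
  ## a 4.9% dip is below threshold
  expect_equal(nrow(detect_decline_phases(c(1, 0.951, 0.97, 1, 1.02))), 0L)
  ## staircase decline accumulating past 5% is one phase from the peak
  d2 <- detect_decline_phases(c(1, 0.97, 0.98, 0.93, 0.99))
  expect_equal(nrow(d2), 1L)
  expect_equal(d2$start_idx, 1L)
  expect_equal(d2$end_idx, 4L)
})

test_that("expansion phases respect duration and correlation gates", {
  x <- seq(1, 1.9, by = 0.1)
  e <- detect_expansion_phases(x)
  expect_equal(nrow(e), 1L)
  expect_equal(e$r, 1)
  expect_equal(e$slope, 0.2)  # 0.1 per frame at 0.5 h per frame
  ## too short
  expect_equal(nrow(detect_expansion_phases(c(1, 1.1, 1.2, 1.3))), 0L)
  ## white noise fails the correlation gate
  set.seed(42)
  noise <- 1 + 0.1 * rnorm(10)
  dec <- detect_decline_phases(noise)
  e2 <- detect_expansion_phases(noise, declines = dec)
  expect_true(all(e2$r > 0.9))  # whatever survives must pass the gate
  expect_equal(nrow(e2), 0L)
})

test_that("events pair declines with the immediately following expansion", {
  ## sawtooth with a terminal unrecovered decline
  x <- c(seq(1, 1.5, by = 0.1), 1.0, seq(1.05, 1.55, by = 0.1), 0.9)
  dec <- detect_decline_phases(x)
  ex <- detect_expansion_phases(x, declines = dec)
  ev <- oscillation_events(dec, ex)
  expect_equal(nrow(dec), 2L)
  expect_equal(ev$count, 1L)  # the final decline has no recovery
  ## monotone trace: no events
  m <- seq(1, 2, by = 0.05)
  expect_equal(oscillation_events(detect_decline_phases(m),
                                  detect_expansion_phases(m))$count, 0L)
})

test_that("expansion factors are the mean and max of accepted slopes", {
  ph <- data.frame(start_idx = c(1L, 10L, 20L), end_idx = c(5L, 15L, 30L),
                   start_t = 0, end_t = 1, duration_h = 1,
                   slope = c(0.1, 0.1, 0.2), r = 0.99)
  f <- expansion_factors(ph)
  expect_equal(f$average, mean(c(0.1, 0.1, 0.2)))
  expect_equal(f$maximum, 0.2)
  f1 <- expansion_factors(ph[1L, ])
  expect_equal(f1$average, f1$maximum)
  f0 <- expansion_factors(ph[0L, ])
  expect_true(is.na(f0$average) && is.na(f0$maximum))
})

test_that("circularity matches closed forms and gates bad segmentations", {
  expect_equal(circularity(pi, 2 * pi), 1)              # unit circle
  expect_equal(circularity(1, 4), pi / 4)               # unit square
  expect_equal(circularity(10, 22), 40 * pi / 484)      # 1 x 10 rectangle
  expect_error(circularity(1, 0), "positive")
  expect_lt(circularity(10, 22), 0.6)                   # excluded downstream
  expect_gt(circularity(1, 4), 0.6)                     # retained
})

test_that("circularity never exceeds 1 on random convex polygons", {
  set.seed(7)
  for (k in 1:20) {
    nv <- sample(3:12, 1L)
    ang <- sort(runif(nv, 0, 2 * pi))
    r <- runif(1L, 0.5, 3)
    xs <- r * cos(ang); ys <- r * sin(ang)  # convex: vertices on a circle
    area <- abs(sum(xs * c(ys[-1L], ys[1L]) - c(xs[-1L], xs[1L]) * ys)) / 2
    per <- sum(sqrt(diff(c(xs, xs[1L]))^2 + diff(c(ys, ys[1L]))^2))
    expect_lte(circularity(area, per), 1)
  }
})

test_that("Tukey fences flag exactly the constructed outliers", {
  expect_equal(which(iqr_outliers(c(1, 2, 3, 4, 100))), 5L)
  expect_equal(which(iqr_outliers(c(-100, 1, 2, 3, 100))), c(1L, 5L))
  expect_equal(sum(iqr_outliers(rep(7, 9))), 0L)
})

test_that("feature extraction is invariant to a global area rescaling", {
  we <- make_well_ensemble(n_organoids = 6, seed = 21)
  f1 <- extract_features(we)
  we2 <- we
  we2$area_mm2 <- we2$area_mm2 * 37.5
  we2$perimeter_mm <- we2$perimeter_mm * sqrt(37.5)  # keeps circularity
  f2 <- extract_features(we2)
  expect_equal(f2$oscillation_events, f1$oscillation_events)
  expect_equal(f2$n_declines, f1$n_declines)
  expect_equal(f2$avg_expansion_factor, f1$avg_expansion_factor,
               tolerance = 1e-10)
  ph1 <- attr(f1, "phases"); ph2 <- attr(f2, "phases")
  for (oid in names(ph1)) {
    expect_equal(ph2[[oid]]$declines$start_idx, ph1[[oid]]$declines$start_idx)
    expect_equal(ph2[[oid]]$declines$end_idx, ph1[[oid]]$declines$end_idx)
  }
})

test_that("sawtooth oscillation counting is exact across random fixtures", {
  set.seed(99)
  for (k in 1:25) {
    n_ev <- sample(0:9, 1L)
    drop <- runif(1L, 0.06, 0.9)
    rec <- sample(5:12, 1L)
    tr <- make_sawtooth_trace(n_events = n_ev, drop_fraction = drop,
                              recovery_frames = rec, seed = 1000 + k)
    x <- tr$area_mm2[-(1:4)]
    tt <- tr$t_h[-(1:4)]
    dec <- detect_decline_phases(x, tt)
    ex <- detect_expansion_phases(x, tt, dec)
    expect_equal(oscillation_events(dec, ex)$count, n_ev)
  }
})

test_that("decline boundaries match the brute-force oracle on random traces", {
  mismatches <- 0L
  for (k in 1:200) {
    x <- random_trace(sample(10:100, 1L), seed = 5000 + k)
    imp <- detect_decline_phases(x)
    orc <- oracle_declines(x)
    same <- nrow(imp) == nrow(orc) &&
      all(imp$start_idx == orc[, "start"]) &&
      all(imp$end_idx == orc[, "end"])
    if (!same) mismatches <- mismatches + 1L
  }
  expect_equal(mismatches, 0L)
})

test_that("culture summaries handle identical wells, effects and single wells", {
  mk_well <- function(wid, seed, shift = 0) {
    we <- make_well_ensemble(n_organoids = 8, seed = seed, well_id = wid,
                             area_meanlog = log(0.02) + shift)
    we
  }
  ## three clones of one well: all final normalised areas coincide per rank,
  ## and an all-identical ensemble gives the degenerate H = 0, p = 1
  same <- rbind(mk_well("w1", 5), mk_well("w2", 5), mk_well("w3", 5))
  f_same <- extract_features(same)
  cs <- culture_summary(f_same)
  kw <- cs$test
  expect_true(kw$p_value > 0.9)  # identical distributions
  ident <- do.call(rbind, lapply(c("a", "b"), function(w) {
    we <- make_well_ensemble(n_organoids = 5, heterogeneity = 0, seed = 1,
                             well_id = w)
    we
  }))
  f_ident <- extract_features(ident)
  cs0 <- culture_summary(f_ident)
  expect_equal(cs0$test$H, 0)
  expect_equal(cs0$test$p_value, 1)
  ## constructed shift is detected
  shifted <- rbind(mk_well("w1", 6), mk_well("w2", 7, shift = 3))
  f_sh <- extract_features(shifted)
  ## shift initial areas but compare raw final areas across wells to see it
  kw2 <- stats::kruskal.test(f_sh$final_area, factor(f_sh$well_id))
  expect_lt(kw2$p.value, 0.05)
  ## single well: skipped with a message
  f1 <- extract_features(mk_well("only", 8))
  expect_message(cs1 <- culture_summary(f1), "skipped")
  expect_null(cs1$test)
})
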