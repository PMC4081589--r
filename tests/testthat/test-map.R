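# synthetic characteristic map for interpolation / classification tests
synthetic_map <- function(axial = c(10, 100, 1000, 10000),
                          shear = c(10, 100, 1000),
                          fun = function(a, s) 20 + 5 * log10(a) +
                            3 * log10(s)) {
  grid <- stiffness_grid(axial = axial, shear = shear)
  rows <- expand.grid(k_axial = axial, k_shear = shear,
                      week = c(6, 9, 12))
  rows$day <- rows$week * 7
  rows$k_bend_rel <- fun(rows$k_axial, rows$k_shear)
  rows$v_bo <- 20
  rows$ci <- 1.5
  rows$bridged <- TRUE
  rows$failed <- FALSE
  attr(rows, "grid") <- grid
  attr(rows, "gap_size") <- 3
  class(rows) <- c("characteristic_map", "data.frame")
  rows
}

test_that("a 1x1 sweep equals a direct healing run", {
  cfg <- small_config(horizon = 7, report_times = 7)
  grid <- stiffness_grid(axial = 1500, shear = 400)
  map <- sweep_map(grid, cfg)
  direct <- run_healing(cfg)
  expect_equal(map$k_bend_rel, direct$report$k_bend_rel)
  expect_equal(map$v_bo, direct$report$v_bo)
  expect_equal(map$bridged, direct$report$bridged)
})

test_that("sweep points are independent of execution order", {
  cfg <- small_config(horizon = 5, report_times = 5)
  g1 <- stiffness_grid(axial = c(500, 5000), shear = c(100, 600))
  map <- sweep_map(g1, cfg)
  for (ka in g1$axial) for (ks in g1$shear) {
    cfg2 <- cfg; cfg2$fixation <- fixation_config(ka, ks)
    one <- run_healing(cfg2)
    got <- map[map$k_axial == ka & map$k_shear == ks, ]
    expect_equal(got$k_bend_rel, one$report$k_bend_rel)
  }
})

test_that("sweep caching reproduces uncached results", {
  cfg <- small_config(horizon = 3, report_times = 3)
  grid <- stiffness_grid(axial = c(1000, 5000), shear = 400)
  cache <- tempfile("sweepcache")
  m1 <- sweep_map(grid, cfg, cache_dir = cache)
  m2 <- sweep_map(grid, cfg, cache_dir = cache)  # from cache
  expect_equal(m1$k_bend_rel, m2$k_bend_rel)
  expect_length(list.files(cache), 2)
  unlink(cache, recursive = TRUE)
})

test_that("map interpolation is node-exact and recovers bilinear surfaces", {
  map <- synthetic_map()
  f <- interpolate_map(map, week = 9)
  # node exactness
  expect_equal(as.numeric(f(1000, 100)), 20 + 15 + 6, tolerance = 1e-12)
  # the interpolant is bilinear in log10 axes: recover test function
  expect_equal(as.numeric(f(10^2.5, 10^1.5)), 20 + 5 * 2.5 + 3 * 1.5,
               tolerance = 1e-9)
  # out-of-hull queries are flagged, not extrapolated
  v <- f(5, 100)
  expect_true(is.na(as.numeric(v)[1]))
  expect_true(attr(v, "out_of_domain")[1])
})

test_that("the default grids reproduce the 96-combination sweep layout", {
  g <- stiffness_grid()
  expect_length(g$axial, 12)
  expect_length(g$shear, 8)
  expect_equal(length(g$axial) * length(g$shear), 96)
  expect_error(stiffness_grid(axial = c(5, 2)), "increasing")
})

test_that("region classification is a partition with the expected labels", {
  mk <- function(b6, b9, b12, k6, k9, k12, v6 = 20, v9 = 20, v12 = 20) {
    data.frame(week = c(6, 9, 12), bridged = c(b6, b9, b12),
               k_bend_rel = c(k6, k9, k12), v_bo = c(v6, v9, v12))
  }
  cases <- list(
    III = mk(TRUE, TRUE, TRUE, 85, 86, 86, 25, 25, 25),
    I   = mk(FALSE, FALSE, FALSE, 5, 5, 5),
    II  = mk(FALSE, TRUE, TRUE, 60, 85, 88, 45, 50, 50),
    V   = mk(TRUE, TRUE, TRUE, 60, 62, 63, 5, 5, 5))
  maps <- lapply(seq_along(cases), function(i) {
    d <- cases[[i]]
    cbind(k_axial = i * 100, k_shear = 300, d,
          day = d$week * 7, ci = 1.5, failed = FALSE)
  })
  map <- do.call(rbind, maps)
  attr(map, "grid") <- stiffness_grid(axial = (1:4) * 100, shear = 300)
  attr(map, "gap_size") <- 3
  class(map) <- c("characteristic_map", "data.frame")
  reg <- classify_regions(map)
  expect_equal(as.character(reg$region), names(cases))
  # partition: every point gets exactly one label
  expect_false(anyNA(reg$region))
  expect_equal(nrow(reg), 4)
})

test_that("packaged literature records match the published table", {
  rec <- corroboration_records()
  expect_equal(nrow(rec), 14)
  case3 <- rec[rec$case == 3, ]
  expect_equal(case3$axial_N_mm, 1523)
  expect_equal(case3$shear_N_mm, 374)
  expect_match(case3$device, "Rigid monolateral")
  expect_true(all(rec$axial_N_mm > 0 & rec$shear_N_mm > 0))
  # estimated-shear flags carry the 20% uncertainty convention
  expect_true(rec$shear_estimated[rec$case == 9])
  expect_false(rec$shear_estimated[rec$case == 3])
})

test_that("corroboration evaluates, flags and ranks records", {
  map <- synthetic_map(axial = c(100, 1000, 10000),
                       shear = c(50, 500, 1000))
  rec <- corroboration_records()
  out <- corroborate(map, rec)
  expect_equal(nrow(out), 14)
  # case 7 shear (2500 N/mm) exceeds the map's shear range
  expect_true(out$out_of_grid[out$case == 7])
  expect_false(anyNA(out$k_bend_rel))
  # estimated records carry an uncertainty band
  expect_true(all(!is.na(out$lo[rec$shear_estimated])))
  expect_true(all(is.na(out$lo[!rec$shear_estimated])))
  expect_true(all(out$lo <= out$hi, na.rm = TRUE))
  expect_equal(sort(out$rank)[1], 1)
  # empty record list gives an empty report
  empty <- corroborate(map, rec[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("nearest-grid-point region lookup agrees with brute force", {
  regions <- expand.grid(k_axial = c(100, 1000, 10000),
                         k_shear = c(50, 500))
  regions$region <- factor(c("I", "II", "III", "IV", "V", "VI"))
  ka <- c(120, 4000, 9000); ks <- c(60, 450, 520)
  idx <- callusmap:::nearest_grid_point(ka, ks, regions)
  brute <- vapply(seq_along(ka), function(i) {
    d <- (log10(regions$k_axial) - log10(ka[i]))^2 +
      (log10(regions$k_shear) - log10(ks[i]))^2
    which(d == min(d))[1]
  }, integer(1))
  expect_equal(idx, brute)
})
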