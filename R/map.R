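#' Fixation-stiffness sweep grid
#'
#' Grid of axial and translational-shear fixation stiffness values over
#' which healing simulations are swept to build a characteristic map.  The
#' `"default"` preset is the full 12 x 8 = 96-combination grid; the
#' `"coarse"` preset (4 x 3) spans the same range for quick, test-scale
#' maps.
#'
#' @param axial Axial stiffness values, N/mm (strictly increasing).
#' @param shear Shear stiffness values, N/mm (strictly increasing).
#' @param preset `"default"` or `"coarse"` (ignored when `axial`/`shear`
#'   are given).
#' @return A `stiffness_grid` object.
#' @export
stiffness_grid <- function(axial = NULL, shear = NULL,
                           preset = c("default", "coarse")) {
  preset <- match.arg(preset)
  if (is.null(axial)) {
    axial <- switch(preset,
      default = c(1, 50, 500, 1000, 1500, 2000, 2500, 3000, 3500,
                  5000, 7500, 10000),
      coarse = c(1, 500, 1500, 7500))
  }
  if (is.null(shear)) {
    shear <- switch(preset,
      default = c(1, 100, 200, 300, 400, 500, 600, 1000),
      coarse = c(1, 200, 600))
  }
  if (any(axial <= 0) || any(shear <= 0) ||
      is.unsorted(axial, strictly = TRUE) ||
      is.unsorted(shear, strictly = TRUE)) {
    stop("grid axes must be positive and strictly increasing.",
         call. = FALSE)
  }
  structure(list(axial = axial, shear = shear), class = "stiffness_grid")
}

#' Sweep the stiffness grid and build a characteristic map
#'
#' Runs one healing simulation per grid point (independently of execution
#' order) and collects outcome metrics at every report time.  Results can
#' be cached on disk keyed by a content hash of the full per-point
#' configuration, so interrupted sweeps resume.  A solver failure at one
#' point is recorded (`failed = TRUE`) and the sweep continues.
#'
#' @param grid A [stiffness_grid()].
#' @param base_config A [simulation_config()]; its `fixation` is replaced
#'   at each grid point.
#' @param cache_dir Optional directory for per-point result caching.
#' @param progress Print one line per completed grid point.
#' @return A `characteristic_map`: data.frame in long format with columns
#'   `k_axial`, `k_shear`, `week`, `day`, `k_bend_rel`, `v_bo`, `ci`,
#'   `bridged`, `failed`, carrying the gap size and grid as attributes.
#' @export
sweep_map <- function(grid, base_config = simulation_config(),
                      cache_dir = NULL, progress = FALSE) {
  stopifnot(inherits(grid, "stiffness_grid"))
  if (!is.null(cache_dir) && !dir.exists(cache_dir)) {
    dir.create(cache_dir, recursive = TRUE)
  }
  mesh <- generate_mesh(base_config$geometry,
                        resolution = base_config$resolution,
                        n_theta = base_config$n_theta)
  rows <- list()
  for (ka in grid$axial) {
    for (ks in grid$shear) {
      cfg <- base_config
      cfg$fixation <- fixation_config(ka, ks)
      key <- rlang::hash(cfg[setdiff(names(cfg), "bend_every_step")])
      cache_file <- if (!is.null(cache_dir)) {
        file.path(cache_dir, paste0(key, ".csv"))
      }
      rep <- NULL
      if (!is.null(cache_file) && file.exists(cache_file)) {
        rep <- utils::read.csv(cache_file)
      } else {
        rep <- tryCatch({
          tc <- run_healing(cfg, mesh = mesh)
          tc$report
        }, error = function(e) {
          warning("sweep point (", ka, ", ", ks, ") failed: ",
                  conditionMessage(e), call. = FALSE)
          NULL
        })
        if (!is.null(rep) && !is.null(cache_file)) {
          utils::write.csv(rep, cache_file, row.names = FALSE)
        }
      }
      if (is.null(rep)) {
        rows[[length(rows) + 1L]] <- data.frame(
          k_axial = ka, k_shear = ks, week = NA_real_, day = NA_real_,
          k_bend_rel = NA_real_, v_bo = NA_real_, ci = NA_real_,
          bridged = NA, failed = TRUE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          k_axial = ka, k_shear = ks, week = rep$week, day = rep$day,
          k_bend_rel = rep$k_bend_rel, v_bo = rep$v_bo, ci = rep$ci,
          bridged = rep$bridged, failed = FALSE)
      }
      if (progress) {
        cat(sprintf("sweep point k=(%g, %g) done\n", ka, ks))
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "grid") <- grid
  attr(out, "gap_size") <- base_config$geometry$gap_size
  class(out) <- c("characteristic_map", "data.frame")
  out
}

#' Bilinear map interpolation on log-stiffness axes
#'
#' Builds a continuous surface from the grid values of one metric at one
#' report week: bilinear interpolation in `(log10 k_axial, log10 k_shear)`
#' space.  The interpolant is exact at the grid nodes; queries outside the
#' grid hull return `NA` (no extrapolation).
#'
#' @param map A `characteristic_map` from [sweep_map()].
#' @param week Report week to interpolate (must be present in the map).
#' @param metric Column to interpolate (default `"k_bend_rel"`).
#' @return A function `f(k_axial, k_shear)` (vectorized) returning the
#'   interpolated metric with attribute `"out_of_domain"` marking queries
#'   outside the hull.
#' @export
interpolate_map <- function(map, week, metric = "k_bend_rel") {
  pts <- map[!map$failed & map$week == week, ]
  if (!nrow(pts)) stop("no map values at week ", week, call. = FALSE)
  grid <- attr(map, "grid")
  la <- log10(grid$axial)
  ls <- log10(grid$shear)
  Z <- matrix(NA_real_, length(la), length(ls))
  ia <- match(pts$k_axial, grid$axial)
  is <- match(pts$k_shear, grid$shear)
  Z[cbind(ia, is)] <- pts[[metric]]
  if (anyNA(Z)) stop("map is missing grid points at week ", week,
                     call. = FALSE)
  function(k_axial, k_shear) {
    n <- max(length(k_axial), length(k_shear))
    ka <- log10(rep_len(k_axial, n))
    ks <- log10(rep_len(k_shear, n))
    out_of_domain <- ka < min(la) | ka > max(la) |
      ks < min(ls) | ks > max(ls)
    val <- rep(NA_real_, n)
    ok <- !out_of_domain & is.finite(ka) & is.finite(ks)
    if (any(ok)) {
      val[ok] <- pracma::interp2(x = ls, y = la, Z = Z,
                                 xp = ks[ok], yp = ka[ok],
                                 method = "linear")
    }
    attr(val, "out_of_domain") <- out_of_domain
    val
  }
}

#' Classify qualitative healing regions of a characteristic map
#'
#' Labels every non-failed grid point with the qualitative healing-outcome
#' region of its gap size, from the week-6/9/12 metrics.  For the 3 mm gap
#' seven regions are distinguished (precedence III, IV, II, VI, V, VII on
#' ties; non-union always I): optimal healing (III, bridged at week 6 with
#' high stiffness and moderate callus), slightly delayed with moderate
#' (IV) or large (II) callus, delayed (VI), suboptimal overly rigid (V),
#' unfavorable overly rigid (VII) and non-union (I).  For the 1 mm gap five
#' regions: optimal (IV), quick (III), slightly delayed (II), delayed with
#' high final stiffness (V), and delayed-flexible (I).
#'
#' Verbal callus magnitudes map to `v_bo` thresholds: small < 10%,
#' moderate 10-40%, large > 40%.
#'
#' @param map A `characteristic_map` with weeks 6, 9 and 12 present.
#' @param gap Gap size in mm (3 or 1; default from the map attribute).
#' @param small,large `v_bo` bounds (percent) separating small / moderate /
#'   large callus.
#' @return The map data.frame reduced to one row per grid point with a
#'   `region` factor column.
#' @export
classify_regions <- function(map, gap = attr(map, "gap_size"),
                             small = 10, large = 40) {
  need <- c(6, 9, 12)
  if (!all(need %in% map$week)) {
    stop("region classification needs report weeks 6, 9 and 12.",
         call. = FALSE)
  }
  pts <- unique(map[!map$failed, c("k_axial", "k_shear")])
  get <- function(ka, ks, wk, col) {
    map[[col]][map$k_axial == ka & map$k_shear == ks & map$week == wk]
  }
  lab <- character(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    ka <- pts$k_axial[i]; ks <- pts$k_shear[i]
    b6 <- get(ka, ks, 6, "bridged"); b9 <- get(ka, ks, 9, "bridged")
    b12 <- get(ka, ks, 12, "bridged")
    k6 <- get(ka, ks, 6, "k_bend_rel"); k9 <- get(ka, ks, 9, "k_bend_rel")
    k12 <- get(ka, ks, 12, "k_bend_rel")
    v6 <- get(ka, ks, 6, "v_bo"); v9 <- get(ka, ks, 9, "v_bo")
    v12 <- get(ka, ks, 12, "v_bo")
    lab[i] <- if (gap >= 2) {
      if (!b12) "I"
      else if (b6 && k6 >= 75 && v6 >= small && v6 <= large) "III"
      else if (b9 && k9 >= 75 && v9 >= small && v9 <= large) "IV"
      else if (b9 && k9 >= 80 && v9 > large) "II"
      else if (b12 && k12 >= 85 && v12 > large) "VI"
      else if (b6 && k6 < 75 && k12 < 75 + 5) "V"
      else if (k12 < 70 && v12 < small) "VII"
      else "V"
    } else {
      if (!b12) "I"
      else if (b6 && k6 >= 90 && v6 >= small && v6 <= large) "IV"
      else if (b6 && k6 >= 85) "III"
      else if (b9 && k9 >= 90) "II"
      else if (k12 >= 95 && v12 > large) "I"
      else "V"
    }
  }
  pts$region <- factor(lab, levels = c("I", "II", "III", "IV", "V",
                                       "VI", "VII"))
  attr(pts, "gap_size") <- gap
  pts
}

#' In-vivo fixation-stiffness literature records
#'
#' Reads the packaged table of published ovine osteotomy experiments with
#' characterized fixation stiffness (device, axial and shear stiffness in
#' N/mm, reported healing outcome).  Shear stiffness values that the
#' sources did not measure are estimates from comparable devices and carry
#' a 20% uncertainty band (`shear_estimated`); further flags mark
#' FE-computed stiffness and axial stiffness prior to bony contact.
#'
#' @param file Optional path to an alternative records CSV with the same
#'   columns.
#' @return A data.frame of `corroboration_record`s.
#' @export
corroboration_records <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "fixation_stiffness_literature.csv",
                        package = "callusmap")
  }
  rec <- utils::read.csv(file, stringsAsFactors = FALSE)
  stopifnot(all(c("case", "device", "axial_N_mm", "shear_N_mm",
                  "shear_estimated") %in% names(rec)))
  if (any(rec$axial_N_mm <= 0) || any(rec$shear_N_mm <= 0)) {
    stop("stiffness values in the records must be positive.",
         call. = FALSE)
  }
  rec
}

#' Compare a characteristic map against literature records
#'
#' Evaluates the interpolated week-9 relative bending stiffness of the map
#' at every record's stiffness coordinates.  For records with estimated
#' shear stiffness the surface is additionally evaluated at shear +/- 20%.
#' Records outside the grid hull are flagged `out_of_grid` and evaluated at
#' the clamped (nearest-in-range) coordinates instead.  The report ranks
#' the cases by predicted stiffness.
#'
#' @param map A `characteristic_map` containing week 9.
#' @param records A data.frame from [corroboration_records()].
#' @param week Report week to evaluate (default 9, the usual in-vivo
#'   follow-up).
#' @param regions Optional [classify_regions()] result; each record is then
#'   assigned the qualitative region of its nearest grid point (nearest in
#'   log-stiffness distance).
#' @return A data.frame with per-record predicted `k_bend_rel` (plus
#'   `lo`/`hi` for estimated shear), `out_of_grid` flag, optional `region`,
#'   and predicted rank (1 = stiffest).
#' @export
corroborate <- function(map, records = corroboration_records(), week = 9,
                        regions = NULL) {
  if (!nrow(records)) {
    out <- data.frame(case = integer(0), device = character(0),
                      k_axial = numeric(0), k_shear = numeric(0),
                      k_bend_rel = numeric(0), lo = numeric(0),
                      hi = numeric(0), out_of_grid = logical(0),
                      rank = integer(0))
    return(out)
  }
  f <- interpolate_map(map, week = week)
  grid <- attr(map, "grid")
  clamp <- function(x, rng) pmin(pmax(x, rng[1]), rng[2])
  ka <- records$axial_N_mm
  ks <- records$shear_N_mm
  out_of_grid <- ka < min(grid$axial) | ka > max(grid$axial) |
    ks < min(grid$shear) | ks > max(grid$shear)
  kac <- clamp(ka, range(grid$axial))
  ksc <- clamp(ks, range(grid$shear))
  kb <- as.numeric(f(kac, ksc))
  lo <- as.numeric(f(kac, clamp(ksc * 0.8, range(grid$shear))))
  hi <- as.numeric(f(kac, clamp(ksc * 1.2, range(grid$shear))))
  est <- as.logical(records$shear_estimated)
  lo[!est] <- NA_real_
  hi[!est] <- NA_real_
  out <- data.frame(
    case = records$case, device = records$device,
    k_axial = ka, k_shear = ks,
    k_bend_rel = kb, lo = pmin(lo, hi), hi = pmax(lo, hi),
    out_of_grid = out_of_grid,
    outcome = records$outcome)
  if (!is.null(regions)) {
    out$region <- regions$region[nearest_grid_point(kac, ksc, regions)]
  }
  out$rank <- rank(-out$k_bend_rel, ties.method = "min")
  out
}

# index of the nearest classified grid point in log-stiffness distance
nearest_grid_point <- function(k_axial, k_shear, regions) {
  vapply(seq_along(k_axial), function(i) {
    d2 <- (log10(regions$k_axial) - log10(k_axial[i]))^2 +
      (log10(regions$k_shear) - log10(k_shear[i]))^2
    which.min(d2)
  }, integer(1))
}
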