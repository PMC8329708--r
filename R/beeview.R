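#' Terrain model: height grid with field mask
#'
#' A regular height grid in local metric coordinates with a boolean mask
#' marking the experimental field. Row 1 is the north edge; cells are
#' half-open; a position maps to a pixel by floor division.
#'
#' @param heights numeric matrix of terrain heights (m), row 1 = north.
#' @param origin_xy_m `c(x, y)` of the lower-left (south-west) grid corner.
#' @param cell_m cell size in meters.
#' @param field_mask logical matrix, same shape as `heights`; `TRUE` inside
#'   the field.
#' @return an object of class `terrain_model`.
#' @export
terrain_model <- function(heights, origin_xy_m = c(0, 0), cell_m = 1,
                          field_mask = NULL) {
  heights <- as.matrix(heights)
  if (!all(is.finite(heights))) stop("heights must be finite")
  if (cell_m <= 0) stop("cell_m must be positive")
  if (is.null(field_mask)) {
    field_mask <- matrix(TRUE, nrow(heights), ncol(heights))
  }
  if (!identical(dim(field_mask), dim(heights))) {
    stop("field_mask must match the heights grid")
  }
  structure(
    list(heights = heights, origin_xy_m = origin_xy_m, cell_m = cell_m,
         field_mask = field_mask),
    class = "terrain_model"
  )
}

#' Map world coordinates to grid pixels
#'
#' @param terrain a [terrain_model].
#' @param x,y coordinates in meters.
#' @return data.frame with `row`, `col`; `NA` outside the grid.
#' @export
terrain_pixel <- function(terrain, x, y) {
  nr <- nrow(terrain$heights)
  nc <- ncol(terrain$heights)
  cell <- terrain$cell_m
  col <- floor((x - terrain$origin_xy_m[1]) / cell) + 1
  row <- nr - floor((y - terrain$origin_xy_m[2]) / cell)
  bad <- col < 1 | col > nc | row < 1 | row > nr
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Write / read a terrain height grid as ESRI ASCII
#'
#' Plain-text ESRI-style grid (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `NODATA_value` header, rows north to south). The field mask,
#' if not all `TRUE`, is written alongside as a 0/1 grid with suffix
#' `.mask.asc`.
#'
#' @param terrain a [terrain_model].
#' @param path output `.asc` path.
#' @return `path` invisibly (write); a [terrain_model] (read).
#' @export
write_terrain <- function(terrain, path) {
  write_asc_grid(terrain$heights, terrain$origin_xy_m, terrain$cell_m, path)
  if (!all(terrain$field_mask)) {
    write_asc_grid(terrain$field_mask * 1, terrain$origin_xy_m,
                   terrain$cell_m, paste0(path, ".mask.asc"))
  }
  invisible(path)
}

#' @rdname write_terrain
#' @export
read_terrain <- function(path) {
  g <- read_asc_grid(path)
  mask_path <- paste0(path, ".mask.asc")
  mask <- if (file.exists(mask_path)) {
    read_asc_grid(mask_path)$grid > 0.5
  } else NULL
  terrain_model(g$grid, g$origin_xy_m, g$cell_m, mask)
}

write_asc_grid <- function(grid, origin, cell, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(grid)),
    paste("nrows", nrow(grid)),
    paste("xllcorner", origin[1]),
    paste("yllcorner", origin[2]),
    paste("cellsize", cell),
    paste("NODATA_value", -9999)
  ), con)
  utils::write.table(grid, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_asc_grid <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  vals <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  grid <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(grid) <- NULL
  stopifnot(nrow(grid) == vals["nrows"], ncol(grid) == vals["ncols"])
  list(grid = grid, origin_xy_m = unname(vals[c("xllcorner", "yllcorner")]),
       cell_m = unname(vals["cellsize"]))
}

#' Build a compound-eye ray model
#'
#' Quasi-uniform viewing directions on the unit sphere (Fibonacci lattice)
#' restricted to the eye's field of view: azimuth within
#' `[-h_fov/2, +h_fov/2]` of the heading (bees see ~300 degrees
#' horizontally, leaving a 60-degree rear blind wedge) and elevation within
#' `[-v_fov/2, +v_fov/2]`. Deterministic; exactly `n_ommatidia` directions
#' are returned, each modeling one ommatidium.
#'
#' @param n_ommatidia number of viewing directions (default 5000).
#' @param h_fov_rad horizontal field of view (default 300 degrees).
#' @param v_fov_rad vertical field of view (default 180 degrees).
#' @return object of class `eye_model`: list with `dirs` (n x 3 matrix of
#'   unit vectors in the head frame, +x = heading, +z = up), `n_ommatidia`,
#'   `h_fov_rad`, `v_fov_rad`.
#' @export
build_eye_model <- function(n_ommatidia = 5000, h_fov_rad = 300 * pi / 180,
                            v_fov_rad = pi) {
  if (n_ommatidia < 1) stop("need at least one ommatidium")
  if (h_fov_rad <= 0 || h_fov_rad > 2 * pi) stop("h_fov_rad out of (0, 2*pi]")
  if (v_fov_rad <= 0 || v_fov_rad > pi) stop("v_fov_rad out of (0, pi]")
  golden <- pi * (3 - sqrt(5))
  n_total <- max(n_ommatidia, 16L)
  repeat {
    i <- seq_len(n_total)
    z <- 1 - (2 * i - 1) / n_total
    rho <- sqrt(pmax(0, 1 - z^2))
    phi <- i * golden
    x <- rho * cos(phi)
    y <- rho * sin(phi)
    az <- atan2(y, x)
    el <- asin(pmin(1, pmax(-1, z)))
    ok <- which(abs(az) <= h_fov_rad / 2 & abs(el) <= v_fov_rad / 2)
    if (length(ok) >= n_ommatidia) {
      # thin the in-wedge lattice evenly (it is ordered by elevation) so
      # the returned directions stay quasi-uniform over the whole wedge
      keep <- ok[round(seq(1, length(ok), length.out = n_ommatidia))]
      dirs <- cbind(x[keep], y[keep], z[keep])
      break
    }
    n_total <- ceiling(n_total * 1.5)
  }
  structure(
    list(dirs = dirs, n_ommatidia = n_ommatidia,
         h_fov_rad = h_fov_rad, v_fov_rad = v_fov_rad),
    class = "eye_model"
  )
}

#' Cast eye rays against the terrain
#'
#' Rotates the eye's viewing directions by the pose yaw and marches each ray
#' against the height grid in steps of half a cell, returning the first
#' intersected pixel and its class: `"field"` (hit inside the field mask),
#' `"outside"` (hit outside the mask), or `"none"` (ray leaves the grid or
#' never reaches the surface).
#'
#' @param eye an [eye_model].
#' @param pose list or vector with `x`, `y`, `alt` (m) and `yaw` (rad, ENU
#'   CCW from +x/east).
#' @param terrain a [terrain_model].
#' @param max_range_m maximum march distance (default: grid diagonal plus
#'   altitude).
#' @return data.frame with one row per ommatidium: `row`, `col` (NA for
#'   class "none"), `class`, `dist_m`.
#' @export
raycast <- function(eye, pose, terrain, max_range_m = NULL) {
  pose <- as.list(pose)
  nr <- nrow(terrain$heights)
  nc <- ncol(terrain$heights)
  cell <- terrain$cell_m
  px <- terrain_pixel(terrain, pose$x, pose$y)
  ground_here <- if (!is.na(px$row[1])) {
    terrain$heights[px$row[1], px$col[1]]
  } else min(terrain$heights)
  if (pose$alt <= ground_here) stop("pose is below the ground")
  if (is.null(max_range_m)) {
    max_range_m <- sqrt((nr * cell)^2 + (nc * cell)^2) + pose$alt
  }
  cy <- cos(pose$yaw); sy <- sin(pose$yaw)
  dx <- eye$dirs[, 1] * cy - eye$dirs[, 2] * sy
  dy <- eye$dirs[, 1] * sy + eye$dirs[, 2] * cy
  dz <- eye$dirs[, 3]
  n <- nrow(eye$dirs)

  hit_row <- rep(NA_integer_, n)
  hit_col <- rep(NA_integer_, n)
  hit_dist <- rep(NA_real_, n)
  max_h <- max(terrain$heights)
  # rays that can never descend to the surface
  active <- !(dz >= 0 & pose$alt >= max_h)
  step <- cell / 2
  t_cur <- step
  while (any(active) && t_cur <= max_range_m) {
    ia <- which(active)
    x <- pose$x + t_cur * dx[ia]
    y <- pose$y + t_cur * dy[ia]
    z <- pose$alt + t_cur * dz[ia]
    p <- terrain_pixel(terrain, x, y)
    inside <- !is.na(p$row)
    # rays that left the grid are done ("none")
    active[ia[!inside]] <- FALSE
    ii <- which(inside)
    if (length(ii)) {
      h <- terrain$heights[cbind(p$row[ii], p$col[ii])]
      hit <- z[ii] <= h
      if (any(hit)) {
        gi <- ia[ii[hit]]
        hh <- h[hit]
        # refine the crossing point within the last march step (descending
        # rays cross the cell's height plane at a known parameter)
        t_hit <- rep(t_cur, length(gi))
        desc <- dz[gi] < 0
        t_exact <- (hh - pose$alt) / dz[gi]
        refine <- desc & t_exact >= t_cur - step & t_exact <= t_cur
        t_hit[refine] <- t_exact[refine]
        pr <- terrain_pixel(terrain, pose$x + t_hit * dx[gi],
                            pose$y + t_hit * dy[gi])
        bad <- is.na(pr$row)
        pr$row[bad] <- p$row[ii[hit]][bad]
        pr$col[bad] <- p$col[ii[hit]][bad]
        hit_row[gi] <- pr$row
        hit_col[gi] <- pr$col
        hit_dist[gi] <- t_hit
        active[gi] <- FALSE
      }
    }
    t_cur <- t_cur + step
  }
  cls <- rep("none", n)
  got <- !is.na(hit_row)
  cls[got] <- ifelse(terrain$field_mask[cbind(hit_row[got], hit_col[got])],
                     "field", "outside")
  data.frame(row = hit_row, col = hit_col, class = cls, dist_m = hit_dist,
             stringsAsFactors = FALSE)
}

#' Project spike rates onto the terrain through the eye model
#'
#' For every rate bin (excluding turns when enabled), the pose at the bin
#' center is looked up, the eye is ray-cast against the terrain, and every
#' distinct field-class hit pixel accumulates the bin's spike rate and a
#' count. The activity map's mean is sum/count where count > 0, so pixels
#' seen in several bins carry the mean of the assigned rates.
#'
#' @param session a `bee_session` (or [telemetry_track]) for pose lookup.
#' @param rate_series a `rate_series` of one unit (or pooled units).
#' @param eye an [eye_model].
#' @param terrain a [terrain_model].
#' @param turn_exclusion_rad_s bins with |yaw rate| above this are skipped
#'   (default 0.3 rad/s); `NULL` disables turn exclusion.
#' @return object of class `activity_map`: list with `sum_grid`,
#'   `count_grid`, `mean_grid` (NA where never seen), `n_bins_used`.
#' @export
project_rates <- function(session, rate_series, eye, terrain,
                          turn_exclusion_rad_s = 0.3) {
  stopifnot(inherits(rate_series, "rate_series"))
  nr <- nrow(terrain$heights)
  nc <- ncol(terrain$heights)
  sum_grid <- matrix(0, nr, nc)
  count_grid <- matrix(0L, nr, nc)
  states <- telemetry_at(session, rate_series$t_s)
  used <- 0L
  for (b in seq_along(rate_series$t_s)) {
    if (!is.null(turn_exclusion_rad_s) &&
        abs(states$yaw_rate_rad_s[b]) > turn_exclusion_rad_s) next
    hits <- raycast(eye,
                    list(x = states$x_m[b], y = states$y_m[b],
                         alt = states$alt_m[b], yaw = states$yaw_rad[b]),
                    terrain)
    f <- hits[hits$class == "field", c("row", "col")]
    if (nrow(f) == 0) next
    f <- unique(f)
    idx <- cbind(f$row, f$col)
    sum_grid[idx] <- sum_grid[idx] + rate_series$rates[b]
    count_grid[idx] <- count_grid[idx] + 1L
    used <- used + 1L
  }
  mean_grid <- sum_grid / count_grid
  mean_grid[count_grid == 0L] <- NA_real_
  structure(
    list(sum_grid = sum_grid, count_grid = count_grid,
         mean_grid = mean_grid, n_bins_used = used),
    class = "activity_map"
  )
}

#' Write an activity map as CSV grids
#'
#' @param map an `activity_map`.
#' @param path base path; writes `<path>_mean.csv` and `<path>_count.csv`.
#' @return `path` invisibly.
#' @export
write_activity_map <- function(map, path) {
  utils::write.table(map$mean_grid, paste0(path, "_mean.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(map$count_grid, paste0(path, "_count.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
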