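flat_terrain <- function(extent = 100, cell = 2) {
  gen_terrain(extent_m = extent, cell_m = cell,
              origin_xy_m = c(-extent / 2, -extent / 2), relief_m = 0,
              seed = 1)
}

pixel_center <- function(terrain, row, col) {
  cbind(terrain$origin_xy_m[1] + (col - 0.5) * terrain$cell_m,
        terrain$origin_xy_m[2] +
          (nrow(terrain$heights) - row + 0.5) * terrain$cell_m)
}

test_that("eye model yields unit vectors inside the field of view", {
  eye <- build_eye_model(n_ommatidia = 500)
  expect_equal(nrow(eye$dirs), 500)
  expect_true(all(abs(sqrt(rowSums(eye$dirs^2)) - 1) < 1e-12))
  az <- atan2(eye$dirs[, 2], eye$dirs[, 1])
  expect_true(all(abs(az) <= 150 * pi / 180 + 1e-12))  # 60 deg blind wedge
  expect_error(build_eye_model(10, h_fov_rad = 7), "fov")
  expect_error(build_eye_model(0), "ommatidium")
})

test_that("eye model is deterministic", {
  expect_identical(build_eye_model(321)$dirs, build_eye_model(321)$dirs)
})

test_that("flat-terrain ray casts match closed-form trigonometry", {
  terr <- flat_terrain()
  eye <- build_eye_model(n_ommatidia = 400)
  pose <- list(x = 3, y = -5, alt = 15, yaw = 0.7)
  hits <- raycast(eye, pose, terr)
  cy <- cos(pose$yaw); sy <- sin(pose$yaw)
  dx <- eye$dirs[, 1] * cy - eye$dirs[, 2] * sy
  dy <- eye$dirs[, 1] * sy + eye$dirs[, 2] * cy
  dz <- eye$dirs[, 3]
  down <- which(dz < -0.05 & !is.na(hits$row))
  expect_gt(length(down), 50)
  horiz <- 15 * sqrt(dx[down]^2 + dy[down]^2) / abs(dz[down])
  expect_xy <- cbind(pose$x + horiz * dx[down] / sqrt(dx[down]^2 + dy[down]^2),
                     pose$y + horiz * dy[down] / sqrt(dx[down]^2 + dy[down]^2))
  got <- pixel_center(terr, hits$row[down], hits$col[down])
  err <- sqrt(rowSums((got - expect_xy)^2))
  expect_lt(max(err), terr$cell_m)
})

test_that("horizontal and upward rays over flat ground see nothing", {
  terr <- flat_terrain()
  eye <- build_eye_model(n_ommatidia = 300)
  hits <- raycast(eye, list(x = 0, y = 0, alt = 15, yaw = 0), terr)
  up <- eye$dirs[, 3] >= 0
  expect_true(all(hits$class[up] == "none"))
  expect_error(raycast(eye, list(x = 0, y = 0, alt = -1, yaw = 0), terr),
               "below")
})

test_that("rotating the pose rotates the hit pattern", {
  terr <- flat_terrain()
  eye <- build_eye_model(n_ommatidia = 300)
  h0 <- raycast(eye, list(x = 0, y = 0, alt = 15, yaw = 0), terr)
  h1 <- raycast(eye, list(x = 0, y = 0, alt = 15, yaw = pi / 2), terr)
  ok <- !is.na(h0$row) & !is.na(h1$row)
  p0 <- pixel_center(terr, h0$row[ok], h0$col[ok])
  p1 <- pixel_center(terr, h1$row[ok], h1$col[ok])
  rotated <- cbind(-p0[, 2], p0[, 1])
  expect_lt(max(sqrt(rowSums((rotated - p1)^2))), sqrt(2) * terr$cell_m)
})

test_that("activity maps average rates per pixel and respect turn exclusion", {
  terr <- flat_terrain(60, 2)
  eye <- build_eye_model(n_ommatidia = 200, v_fov_rad = pi / 2)
  # static pose over two bins; rates 10 then 30
  tel <- telemetry_track(t_s = c(0, 0.2), x_m = c(0, 0), y_m = c(0, 0),
                         alt_m = c(12, 12), yaw_rad = c(0, 0),
                         yaw_rate_rad_s = c(0, 0), speed_m_s = c(0, 0))
  rs <- bin_rates(numeric(0), 0, 0.2)
  rs$rates <- c(10, 30)
  map <- project_rates(tel, rs, eye, terr)
  seen <- map$count_grid > 0
  expect_true(all(map$count_grid[seen] == 2))
  expect_true(all(map$mean_grid[seen] == 20))

  # single bin: every assigned pixel carries exactly the bin's rate
  rs1 <- bin_rates(numeric(0), 0, 0.1)
  rs1$rates <- 17
  m1 <- project_rates(tel, rs1, eye, terr)
  expect_true(all(m1$mean_grid[m1$count_grid > 0] == 17))

  # conservation against a brute-force per-bin accumulation
  hits <- raycast(eye, list(x = 0, y = 0, alt = 12, yaw = 0), terr)
  n_field_px <- nrow(unique(hits[hits$class == "field", c("row", "col")]))
  expect_equal(sum(m1$count_grid), n_field_px)

  # turning bins contribute nothing when exclusion is active
  tel_turn <- telemetry_track(t_s = c(0, 0.2), x_m = c(0, 0), y_m = c(0, 0),
                              alt_m = c(12, 12), yaw_rad = c(0, 0.5),
                              yaw_rate_rad_s = c(2.5, 2.5),
                              speed_m_s = c(0, 0))
  m2 <- project_rates(tel_turn, rs, eye, terr, turn_exclusion_rad_s = 0.3)
  expect_equal(sum(m2$count_grid), 0)
  m3 <- project_rates(tel_turn, rs, eye, terr, turn_exclusion_rad_s = NULL)
  expect_gt(sum(m3$count_grid), 0)
})

test_that("terrain ASCII grids round-trip with mask", {
  terr <- gen_terrain(extent_m = 30, cell_m = 3, origin_xy_m = c(5, -4),
                      relief_m = 2,
                      field_polygon = cbind(c(10, 25, 25, 10),
                                            c(0, 0, 15, 15)),
                      seed = 3)
  f <- tempfile(fileext = ".asc")
  write_terrain(terr, f)
  back <- read_terrain(f)
  expect_equal(back$heights, terr$heights, tolerance = 1e-12)
  expect_identical(back$field_mask, terr$field_mask)
  expect_equal(back$origin_xy_m, terr$origin_xy_m)
  expect_equal(back$cell_m, terr$cell_m)
})
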