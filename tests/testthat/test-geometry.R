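test_that("synthetic rat matches the stated body envelope", {
  m <- cached_rat()
  dims <- c(0.2011, 0.1032, 0.1004)
  bb <- apply(m$nodes, 2, function(v) diff(range(v)))
  # bounding box within one element size of the stated dims (y = length)
  expect_lt(abs(bb["y"] - dims[1]), m$resolution + 1e-12)
  expect_lt(abs(bb["x"] - dims[2]), m$resolution + 1e-12)
  expect_lt(abs(bb["z"] - dims[3]), m$resolution + 1e-12)
  # desk scale: far below the full CT mesh, all five tissues present
  expect_lt(nrow(m$elements), 1e5)
  expect_setequal(unique(m$material),
                  c("lung_L", "lung_R", "heart", "rib", "skin_muscle"))
})

test_that("construction is deterministic", {
  a <- build_synthetic_rat(resolution = 0.011, seed = 42L)
  b <- build_synthetic_rat(resolution = 0.011, seed = 42L)
  expect_identical(a$nodes, b$nodes)
  expect_identical(a$elements, b$elements)
  expect_identical(a$material, b$material)
})

test_that("mesh volume approximates the outer ellipsoid", {
  m <- cached_rat()
  vol <- sum(blastrat:::tet_volumes(m$nodes, m$elements))
  analytic <- 4 / 3 * pi * prod(m$body_dims / 2)
  expect_lt(abs(vol / analytic - 1), 0.05)
  expect_true(all(blastrat:::tet_volumes(m$nodes, m$elements) > 0))
})

test_that("exterior surface is watertight", {
  m <- cached_rat()
  f <- m$surface_faces
  ed <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  expect_true(all(table(key) == 2)) # every edge shared by exactly two faces
  V <- length(unique(as.vector(f))); E <- length(unique(key)); F <- nrow(f)
  expect_identical(V - E + F, 2L) # sphere topology
})

test_that("tissue regions are disjoint", {
  m <- cached_rat()
  ctr <- (m$nodes[m$elements[, 1], ] + m$nodes[m$elements[, 2], ] +
          m$nodes[m$elements[, 3], ] + m$nodes[m$elements[, 4], ]) / 4
  an <- blastrat:::rat_anatomy()
  ax <- m$body_dims[2] / 2; by <- m$body_dims[1] / 2; az <- m$body_dims[3] / 2
  hc <- c(0, an$thorax_center_frac * by, az) + an$heart_offset
  lung <- grepl("^lung", m$material)
  in_heart <- ((ctr[, 1] - hc[1]) / an$heart_semi[1])^2 +
    ((ctr[, 2] - hc[2]) / an$heart_semi[2])^2 +
    ((ctr[, 3] - hc[3]) / an$heart_semi[3])^2 <= 1
  expect_false(any(lung & in_heart))
  # lungs stay inside the rib shell
  rho <- sqrt((ctr[, 1] / ax)^2 + ((ctr[, 3] - az) / az)^2)
  expect_true(all(rho[lung] < an$rib_inner_frac))
  # left and right lungs on their own side of the mediastinum
  expect_true(all(ctr[m$material == "lung_L", 1] < 0))
  expect_true(all(ctr[m$material == "lung_R", 1] > 0))
})

test_that("too-coarse resolutions are rejected with the offending layer", {
  expect_error(build_synthetic_rat(resolution = 0.03), "quarter")
  expect_error(build_synthetic_rat(resolution = 0.02), "too coarse.*(skin|rib)")
})

test_that("monitor points are the canonical twelve on the lung surfaces", {
  m <- cached_rat()
  mp <- m$monitor_points
  expect_identical(nrow(mp), 12L)
  expect_identical(sum(duplicated(mp[, c("name", "side")])), 0L)
  for (side in c("L", "R")) {
    sub <- mp[mp$side == side, ]
    expect_setequal(sub$name, c("apex_pulmonis", "middle_lateral",
                                "lower_lateral", "lower_interior",
                                "lower_anterior", "interior"))
    # apex has the maximal vertical coordinate among its side's points
    expect_identical(sub$name[which.max(sub$z)], "apex_pulmonis")
    # every point lies within one element size of a lung-surface face
    lrf <- blastrat:::lung_region_faces(m, side)
    for (i in seq_len(nrow(sub))) {
      d <- sqrt(min(rowSums(sweep(lrf$centroids, 2,
                                  as.numeric(sub[i, c("x", "y", "z")]))^2)))
      expect_lt(d, m$resolution)
    }
  }
})

test_that("monitor placement fails without a lung side", {
  box <- mesh_box(dims = c(0.2, 0.1, 0.1), n = c(4, 2, 2))
  expect_error(place_monitor_points(box), "lung side L")
})
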