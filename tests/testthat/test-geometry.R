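test_that("a single tetrahedron is meshed exactly", {
  s <- st_samples(data.frame(site_id = letters[1:4],
                             x = c(0, 1, 0, 0), y = c(0, 0, 1, 0),
                             t = c(1, 1, 1, 6), w = c(1, 2, 3, 4)))
  m <- build_mesh(s, time_scale(1 / 5))  # c*t: 0.2, 0.2, 0.2, 1.2 -> unit z
  expect_equal(nrow(m$tets), 1L)
  expect_equal(m$volumes, 1 / 6, tolerance = 1e-7)
})

test_that("degenerate clouds are refused with a named degeneracy", {
  cop <- st_samples(data.frame(site_id = letters[1:4],
                               x = c(0, 1, 0, 1), y = c(0, 0, 1, 1),
                               t = 1L, w = 1:4))
  expect_error(build_mesh(cop, time_scale(1)), "coplanar")
  lin <- st_samples(data.frame(site_id = letters[1:4],
                               x = 1:4, y = 2 * (1:4), t = 1L, w = 1:4))
  expect_error(build_mesh(lin, time_scale(1)), "collinear")
  few <- st_samples(data.frame(site_id = c("a", "b", "c"),
                               x = c(0, 1, 0), y = c(0, 0, 1),
                               t = 1L, w = 1:3))
  expect_error(build_mesh(few, time_scale(1)), "at least 4")
})

test_that("duplicate space-time locations are merged by mean", {
  s <- st_samples(data.frame(
    site_id = c("a", "a", "b", "c", "d", "e"),
    x = c(0, 0, 1, 0, 0, 0.4), y = c(0, 0, 0, 1, 0, 0.3),
    t = c(1L, 1L, 1L, 1L, 6L, 2L), w = c(2, 4, 1, 1, 1, 1)))
  expect_warning(m <- build_mesh(s, time_scale(1 / 5)), "1 duplicate")
  expect_equal(nrow(m$points), 5L)
  # the merged vertex carries the mean of the two records
  i <- which(m$t == 1L & abs(m$points[, 1]) < 1e-6 &
               abs(m$points[, 2]) < 1e-6)
  expect_equal(m$values[i], 3)
})

test_that("mesh tetrahedra match an independent Delaunay implementation and
           tile the convex hull", {
  rm_ <- rand_mesh(n = 60, seed = 42)
  m <- rm_$mesh
  sp <- scipy_delaunay(m$points)
  expect_equal(tet_keys(m$tets), sp$keys)
  expect_equal(sum(m$volumes), sp$hull_volume, tolerance = 1e-10)
  # 5 points in general position: 2-3 tetrahedra summing to the hull volume
  s5 <- make_cloud(5, seed = 11)
  m5 <- build_mesh(st_samples(s5), time_scale(0.1))
  sp5 <- scipy_delaunay(m5$points)
  expect_true(nrow(m5$tets) %in% 2:3)
  expect_equal(sum(m5$volumes), sp5$hull_volume, tolerance = 1e-12)
})

test_that("shape weights are the sub-volume ratios of the barycentric
           linear system", {
  withr::with_seed(5, {
    for (rep in 1:20) {
      tet <- matrix(runif(12), 4, 3)
      if (abs(det(rbind(tet[2, ] - tet[1, ], tet[3, ] - tet[1, ],
                        tet[4, ] - tet[1, ]))) < 1e-3) next
      lam <- runif(4); lam <- lam / sum(lam)
      q <- colSums(tet * lam)
      w <- shape_weights(tet, q)
      # oracle: solve the 4x4 barycentric linear system directly
      oracle <- solve(rbind(1, t(tet)), c(1, q))
      expect_equal(unname(w), oracle, tolerance = 1e-9)
      expect_equal(sum(w), 1, tolerance = 1e-12)
    }
  })
  # limit behaviour at the corners and the centroid
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(unname(shape_weights(tet, c(0, 0, 0))), c(1, 0, 0, 0))
  expect_equal(unname(shape_weights(tet, colMeans(tet))), rep(0.25, 4))
  expect_error(shape_weights(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                                   c(1, 1, 0)), c(0.2, 0.2, 0)),
               "degenerate")
})

test_that("point location agrees with a brute-force containment scan", {
  rm_ <- rand_mesh(n = 35, seed = 3)
  m <- rm_$mesh
  withr::with_seed(9, {
    q <- cbind(runif(120, -0.2, 1.2), runif(120, -0.2, 1.2),
               runif(120, 0, 1.2))
  })
  loc <- locate_tetra(m, q)
  for (i in seq_len(nrow(q))) {
    oracle <- brute_inside(m, q[i, ])
    if (is.na(loc$tet[i])) {
      expect_true(is.na(oracle))
    } else {
      expect_false(is.na(oracle))
      expect_gte(min(loc$weights[i, ]), -1e-9)
      expect_equal(sum(loc$weights[i, ]), 1, tolerance = 1e-9)
    }
  }
  # far-outside query and mesh vertices
  expect_true(is.na(locate_tetra(m, cbind(50, 50, 50))$tet))
  vloc <- locate_tetra(m, m$points[1:10, , drop = FALSE])
  expect_false(anyNA(vloc$tet))
})

test_that("the interpolant reproduces vertex values, linear fields, and
           stays within the local value range", {
  f <- function(x, y, t) 3 + 2 * x - 1.5 * y + 0.8 * (0.1 * t)
  rm_ <- rand_mesh(n = 50, seed = 8, value_fn = f)
  m <- rm_$mesh
  # vertex reproduction (up to the documented tie joggle)
  at_vertices <- sf_interpolate(m, rm_$samples)
  expect_equal(at_vertices, rm_$samples$w, tolerance = 1e-6)
  # linear reproduction on interior queries
  withr::with_seed(10, {
    q <- data.frame(x = runif(300, 0.2, 0.8), y = runif(300, 0.2, 0.8),
                    t = sample(2:9, 300, TRUE))
  })
  pred <- sf_interpolate(m, q)
  keep <- !is.na(pred)
  expect_gt(mean(keep), 0.9)
  truth <- f(q$x, q$y, q$t)
  expect_lt(max(abs(pred[keep] - truth[keep]) / abs(truth[keep])), 1e-9)
  # range bound: every result inside the containing tet's value range
  loc <- locate_tetra(m, q[keep, , drop = FALSE])
  vals <- matrix(m$values[m$tets[loc$tet, ]], ncol = 4)
  expect_true(all(pred[keep] >= apply(vals, 1, min) - 1e-9))
  expect_true(all(pred[keep] <= apply(vals, 1, max) + 1e-9))
})

test_that("interpolation is continuous across shared facets", {
  rm_ <- rand_mesh(n = 30, seed = 12)
  m <- rm_$mesh
  found <- 0L
  for (ti in seq_len(nrow(m$tets))) {
    for (s in 1:4) {
      nb <- m$neighbors[ti, s]
      if (nb == 0 || nb <= ti) next
      if (m$degenerate[ti] || m$degenerate[nb]) next
      face <- setdiff(m$tets[ti, ], m$tets[ti, s])
      q <- colMeans(m$points[face, , drop = FALSE])
      va <- sum(shape_weights(m$points[m$tets[ti, ], ], q) *
                  m$values[m$tets[ti, ]])
      vb <- sum(shape_weights(m$points[m$tets[nb, ], ], q) *
                  m$values[m$tets[nb, ]])
      expect_equal(va, vb, tolerance = 1e-9)
      found <- found + 1L
      if (found >= 25L) break
    }
    if (found >= 25L) break
  }
  expect_gte(found, 10L)
})

test_that("results depend on c and t only through the product c*t", {
  s <- make_cloud(40, seed = 21, days = 10)
  s$t <- s$t * 2L  # even day indices
  s2 <- s
  s2$t <- s$t %/% 2L
  m1 <- build_mesh(st_samples(s), time_scale(0.1))
  m2 <- build_mesh(st_samples(s2), time_scale(0.2))
  q1 <- data.frame(x = 0.5, y = 0.5, t = 4L)
  q2 <- data.frame(x = 0.5, y = 0.5, t = 2L)
  expect_equal(sf_interpolate(m1, q1), sf_interpolate(m2, q2))
  expect_equal(tet_keys(m1$tets), tet_keys(m2$tets))
})

test_that("outside-hull queries follow the chosen policy", {
  rm_ <- rand_mesh(n = 25, seed = 14)
  m <- rm_$mesh
  far <- data.frame(x = 10, y = 10, t = 5L)
  expect_true(is.na(sf_interpolate(m, far, outside = "missing")))
  nn_val <- sf_interpolate(m, far, outside = "nearest")
  expect_true(nn_val %in% m$values)
  idw_val <- sf_interpolate(m, far, outside = "idw")
  expect_gte(idw_val, min(m$values))
  expect_lte(idw_val, max(m$values))
  # scale mismatch guard
  expect_error(sf_interpolate(m, far, scale = time_scale(0.5)),
               "mismatch")
})
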