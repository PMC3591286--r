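test_that("regular polygons match closed-form geometry", {
  pent <- regular_polygon_array(5, 5)
  d <- location_distances(pent, flowers_only = TRUE)
  # adjacent sides all equal the requested side length
  sides <- d[cbind(1:5, c(2:5, 1))]
  expect_equal(sides, rep(5, 5), tolerance = 1e-12)
  # circumradius from the nest at the centroid
  expect_equal(unname(location_distances(pent)[1, -1]),
               rep(5 / (2 * sin(pi / 5)), 5), tolerance = 1e-12)
  # diagonals follow the golden ratio
  expect_equal(d[1, 3], 5 * (1 + sqrt(5)) / 2, tolerance = 1e-12)

  # similarity scaling: the 50 m table is exactly 10x the 5 m table
  big <- regular_polygon_array(5, 50)
  expect_equal(big$dist, 10 * pent$dist, tolerance = 1e-12)

  expect_error(regular_polygon_array(2, 1), "at least 3")
  expect_error(regular_polygon_array(5, 0), "positive")
  # a nest on a vertex coincides with flower 1 and is rejected
  expect_error(regular_polygon_array(3, 1, nest_at = "vertex"), "coincides")
  # an offset nest point is fine
  tri <- regular_polygon_array(3, 1, nest_at = c(0, 1))
  expect_s3_class(tri, "flower_array")
})

test_that("random arrays are seeded, bounded and uniform", {
  a <- random_uniform_array(10, 25, seed = 1)
  b <- random_uniform_array(10, 25, seed = 1)
  expect_identical(a$flowers, b$flowers)
  expect_true(all(a$flowers >= 0 & a$flowers <= 25))

  one <- random_uniform_array(1, 10, seed = 3)
  expect_equal(optimal_circuit(one)$length,
               2 * location_distances(one)[1, 2])

  # mean nearest-neighbour distance vs the boundary-corrected expectation
  # for n uniform points in a square (Donnelly's edge correction)
  n <- 10; side <- 25
  nn <- vapply(1:200, function(s) {
    arr <- random_uniform_array(n, side, seed = s)
    d <- location_distances(arr, flowers_only = TRUE)
    diag(d) <- Inf
    mean(apply(d, 1, min))
  }, numeric(1))
  expected <- 0.5 * sqrt(side^2 / n) +
    (0.0514 + 0.041 / sqrt(n)) * (4 * side) / n
  expect_lt(abs(mean(nn) - expected) / expected, 0.05)
})

test_that("patch arrays partition flowers into separated clusters", {
  centres <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  arr <- patch_grid_array(centres, 3, 0.05, nest_at = c(0.5, -0.5), seed = 2)
  expect_equal(n_flowers(arr), 12L)
  expect_equal(as.vector(table(arr$patch)), rep(3L, 4))
  # every flower belongs to exactly one patch
  expect_equal(length(arr$patch), 12L)
  # patches are geometrically disjoint: min between > max within
  d <- location_distances(arr, flowers_only = TRUE)
  same <- outer(arr$patch, arr$patch, "==")
  diag(same) <- NA
  expect_gt(min(d[!same & !is.na(same)]), max(d[same & !is.na(same)],
                                              na.rm = TRUE))
  expect_error(patch_grid_array(centres, 3, 0.6, nest_at = c(0.5, -0.5)),
               "overlap")
})

test_that("array files round-trip exactly through CSV and JSON", {
  arr <- random_uniform_array(6, 3, seed = 11)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  save_array(arr, csv)
  save_array(arr, js)
  expect_identical(load_array(csv)$dist, arr$dist)
  expect_identical(load_array(js)$dist, arr$dist)
  expect_identical(load_array(csv)$flowers, load_array(js)$flowers)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("label,x,y", "F1,0,0", "F2,1,1"), bad)
  expect_error(load_array(bad), "NEST")
  writeLines(c("label,x,y", "NEST,0,0", "F1,1,1", "F1,2,2"), bad)
  expect_error(load_array(bad), "duplicate")
  writeLines(c("label,x,y", "NEST,0,zero", "F1,1,1"), bad)
  expect_error(load_array(bad), "non-numeric|NEST|numeric")
})

test_that("coincident flowers must be declared as co-located", {
  fl <- rbind(c(1, 0), c(1, 0), c(0, 1))
  expect_error(flower_array(c(0, 0), fl), "coincident")
  arr <- flower_array(c(0, 0), fl, colocated = cbind(1, 2))
  expect_s3_class(arr, "flower_array")
  expect_equal(arr$high_reward, c(1L, 2L))
  # the within-pair hop gets the weight of the closest distinct pair and the
  # rows still normalise
  tab <- init_transition_table(arr, model_params())
  expect_equal(unname(rowSums(tab)), rep(1, 4))
  expect_gt(tab[2, 3], 0)
  expect_error(flower_array(c(1, 0), rbind(c(1, 0), c(0, 1))), "nest")
})

test_that("bundled linkage arrays load and validate", {
  for (nm in c("positive", "independent", "negative")) {
    arr <- example_array(nm)
    expect_equal(n_flowers(arr), 10L)
    expect_true(all(arr$dist[upper.tri(arr$dist)] > 0))
  }
})
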