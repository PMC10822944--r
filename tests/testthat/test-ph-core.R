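test_that("geodesic function measures along-network distance to the top", {
  net <- build_network(voxel_set(cbind(0, 0, 0:10)))
  f <- geodesic_function(net)
  expect_equal(f$values, 0:10)

  # custom top set: the deepest voxel reverses the values
  f_rev <- geodesic_function(net, top = which(net$coords[, 3] == 10))
  expect_equal(f_rev$values, 10:0)

  # Y-tree: lateral tip at 5 + 3*sqrt(2), cross-checked against igraph
  net <- build_network(y_tree())
  f <- geodesic_function(net)
  tip <- which(net$coords[, 1] == 3)
  expect_equal(f$values[tip], 5 + 3 * sqrt(2))
  g <- igraph::graph_from_edgelist(net$edges, directed = FALSE)
  d <- igraph::distances(g, v = which(net$coords[, 3] == 0),
                         weights = net$lengths)
  expect_equal(f$values, as.numeric(d[1, ]))
})

test_that("depth function is the straight height above the top plane", {
  net <- build_network(voxel_set(cbind(0, 0, 0:10)))
  expect_equal(depth_function(net)$values, geodesic_function(net)$values)

  # horizontal lateral: constant depth regardless of its length
  net <- build_network(voxel_set(rbind(cbind(0, 0, 0:6), cbind(1:5, 0, 5))))
  dep <- depth_function(net)
  lat <- which(net$coords[, 1] > 0)
  expect_true(all(dep$values[lat] == 5))

  one <- build_network(voxel_set(cbind(3, 4, 7)))
  expect_equal(depth_function(one)$values, 0)
})

test_that("edge values are the minimum of the endpoint values", {
  net <- build_network(voxel_set(cbind(0, 0, 0:3)))
  f <- structure(list(name = "geodesic", values = c(5, 6, 3, 3)),
                 class = "vertex_function")
  expect_equal(edge_values(net, f), c(5, 3, 3))
  f0 <- structure(list(name = "depth", values = rep(0, 4)),
                  class = "vertex_function")
  expect_equal(edge_values(net, f0), c(0, 0, 0))
})

test_that("h0 barcode of simple shapes", {
  net <- build_network(voxel_set(cbind(0, 0, 0:10)))
  bc <- h0_barcode(net, geodesic_function(net))
  expect_equal(n_bars(bc), 1)
  expect_equal(c(bc$birth, bc$death), c(10, 0))

  one <- build_network(voxel_set(cbind(0, 0, 0)))
  bc1 <- h0_barcode(one, geodesic_function(one))
  expect_equal(c(bc1$birth, bc1$death), c(0, 0))

  # Y-tree: two bars; the longer (primary, birth 10) survives to 0, the
  # lateral (birth 5 + 3*sqrt(2)) dies when its first voxel joins the
  # primary (merge edge value 5 + sqrt(2))
  net <- build_network(y_tree())
  bc <- h0_barcode(net, geodesic_function(net))
  expect_equal(n_bars(bc), 2)
  expect_equal(bc$birth, c(10, 5 + 3 * sqrt(2)))
  expect_equal(bc$death, c(0, 5 + sqrt(2)))
})

test_that("alive-bar counts equal brute-force component counts at all levels", {
  # random synthetic trees and perturbed non-tree blobs, both functions
  set.seed(11)
  for (s in 1:12) {
    r <- generate_root(root_spec(primary_length = 30, lateral_count = 3,
                                 lateral_length_mean = 8,
                                 lateral_length_sd = 2), seed = s)
    vs <- if (s %% 3 == 0) perturb_voxels(r$voxels, 0.08, seed = s) else r$voxels
    net <- largest_component(build_network(vs))
    for (f in list(geodesic_function(net), depth_function(net))) {
      bc <- h0_barcode(net, f)
      for (t in 0:ceiling(max(f$values))) {
        expect_equal(bars_alive(bc, t),
                     oracle_superlevel_components(net, f$values, t),
                     info = sprintf("seed %d, %s, level %d", s, f$name, t))
      }
    }
  }
})

test_that("bar count equals tip count on clean trees", {
  for (s in 1:10) {
    r <- generate_root(root_spec(), seed = 100 + s)
    net <- build_network(r$voxels)
    expect_equal(cycle_rank(net), 0L)
    bc <- h0_barcode(net, geodesic_function(net))
    expect_equal(n_bars(bc), r$truth$tip_count)
  }
})

test_that("non-essential bar lengths match branch geodesic lengths on trees", {
  r <- generate_root(root_spec(lateral_count = 4, tortuosity = 0), seed = 2)
  net <- build_network(r$voxels)
  bc <- h0_barcode(net, geodesic_function(net))
  lat <- r$truth$branches[r$truth$branches$branch != "primary", ]
  bar_len <- sort(bc$birth[!bc$essential] - bc$death[!bc$essential])
  # each lateral bar spans tip-to-junction; the junction sits within one
  # voxel diagonal of the insertion point
  expect_equal(length(bar_len), nrow(lat))
  expect_true(all(abs(bar_len - sort(lat$length)) <= sqrt(3) + 1e-9))
})

test_that("bottleneck stability under bounded function perturbation", {
  set.seed(21)
  r <- generate_root(root_spec(primary_length = 40), seed = 3)
  net <- build_network(r$voxels)
  f <- geodesic_function(net)
  for (i in 1:10) {
    eps <- runif(1, 0.1, 2)
    g <- f
    g$values <- pmax(0, f$values + runif(length(f$values), -eps, eps))
    sup <- max(abs(g$values - f$values))
    d <- bottleneck_distance(barcode_to_diagram(h0_barcode(net, f)),
                             barcode_to_diagram(h0_barcode(net, g)))
    expect_lte(d, sup + 1e-9)
  }
})

test_that("disconnected networks are rejected with guidance", {
  net <- build_network(voxel_set(rbind(cbind(0, 0, 0:2), c(9, 9, 9))))
  f <- depth_function(net)
  expect_error(h0_barcode(net, f), "largest_component")
  expect_error(geodesic_function(net), "largest_component|unreachable|disconnected")
})

test_that("barcode/diagram conversion and CSV round trip", {
  net <- build_network(y_tree())
  bc <- h0_barcode(net, geodesic_function(net))
  dg <- barcode_to_diagram(bc)
  expect_s3_class(dg, "persistence_diagram")
  expect_equal(dg$birth, bc$birth)
  expect_equal(dg$death, bc$death)

  csv <- withr::local_tempfile(fileext = ".csv")
  write_barcodes(list(a = bc, b = bc), csv)
  back <- read_barcodes(csv)
  expect_equal(names(back), c("a", "b"))
  expect_equal(back$a$birth, bc$birth)
  expect_equal(back$a$death, bc$death)
})
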