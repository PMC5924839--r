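test_that("map cells at the reference conductance settings carry the
           expected labels", {
  map <- map60_coarse()
  at <- function(x, y) as.character(map_label_at(map, x, y))
  expect_equal(at(0, 0), "tonic")
  expect_equal(at(6, 0), "single")
  expect_equal(at(0, 8), "delayed")
  expect_equal(at(0, 5), "gap")
  expect_equal(at(6, 8), "reluctant")
  # neighbouring-cell contrast: (3,4) and (3,8) share a label while small
  # steps to (3,3.5) or (3.5,4) cross a boundary
  expect_equal(at(3, 4), at(3, 8))
  expect_false(at(3, 3.5) == at(3, 4))
  expect_false(at(3.5, 4) == at(3, 4))
})

test_that("all five labels appear and occupy the expected quadrants", {
  map <- map60_coarse()
  expect_setequal(pattern_labels(),
                  pattern_labels()[sort(unique(as.vector(map$labels)))])
  geom <- region_geometry(map)
  cen <- function(lab) unlist(geom[geom$label == lab,
                                   c("centroid_lt", "centroid_A")])
  expect_true(cen("single")["centroid_lt"] > cen("tonic")["centroid_lt"])
  expect_true(cen("delayed")["centroid_A"] > cen("tonic")["centroid_A"])
  expect_true(all(cen("reluctant") > cen("tonic")))
})

test_that("on the g_KA = 0 transect, raising g_Klt never reverts single
           spiking to tonic", {
  row <- map60_coarse()$labels[, 1]
  first_single <- which(row == 2L)[1]
  expect_false(is.na(first_single))
  expect_true(all(row[first_single:length(row)] != 5L))
})

test_that("a subthreshold stimulus leaves the whole map reluctant", {
  tiny <- build_pattern_map(grid_spec(step = 5), stim_protocol(I_stim = 0))
  expect_true(all(tiny$labels == 1L))
})

test_that("region centroids equal the mean of member node coordinates", {
  map <- map60_coarse()
  geom <- region_geometry(map)
  # brute-force recomputation from the label array
  for (k in 1:5) {
    idx <- which(map$labels == k, arr.ind = TRUE)
    if (nrow(idx) == 0) {
      expect_true(is.na(geom$centroid_lt[k]))
      next
    }
    expect_equal(geom$centroid_lt[k], mean(map$grid$g_lt[idx[, 1]]))
    expect_equal(geom$centroid_A[k], mean(map$grid$g_A[idx[, 2]]))
    expect_equal(geom$n[k], nrow(idx))
  }
  expect_equal(sum(geom$n), length(map$labels))
})

test_that("centroids of synthetic single-cell and rectangular regions", {
  grid <- grid_spec(g_lt_max = 3, g_A_max = 3, step = 1)
  labels <- matrix(1L, 4, 4)
  labels[2, 3] <- 2L           # single cell: (1, 2)
  labels[3:4, 1:2] <- 5L       # rectangle: x in {2,3}, y in {0,1}
  fake <- structure(list(labels = labels, grid = grid,
                         protocol = stim_protocol(), params = neuron_params(),
                         threshold = 0), class = "pattern_map")
  geom <- region_geometry(fake)
  expect_equal(unname(unlist(
    geom[geom$label == "single", c("centroid_lt", "centroid_A")])), c(1, 2))
  expect_equal(unname(unlist(
    geom[geom$label == "tonic", c("centroid_lt", "centroid_A")])),
    c(2.5, 0.5))
  expect_true(is.na(geom$centroid_lt[geom$label == "delayed"]))
})

test_that("grid refinement does not change labels at shared nodes", {
  coarse <- build_pattern_map(grid_spec(g_lt_max = 4, g_A_max = 4, step = 1),
                              stim_protocol(I_stim = 60))
  fine <- build_pattern_map(grid_spec(g_lt_max = 4, g_A_max = 4, step = 0.5),
                            stim_protocol(I_stim = 60))
  expect_equal(coarse$labels, fine$labels[seq(1, 9, 2), seq(1, 9, 2)])
})

test_that("stimulus intensity and pre-pulse shift the pattern of a fixed
           neuron", {
  # same neuron, different I_stim: boundary crossing changes its label
  labs_I <- vapply(seq(50, 80, by = 10), function(I)
    as.character(classify_neuron(neuron_params(3, 4),
                                 stim_protocol(I_stim = I))), character(1))
  expect_gt(length(unique(labs_I)), 1)
  # same neuron, depolarising pre-pulse: A-current inactivation changes it
  labs_pre <- vapply(c(0, 20), function(Ipre)
    as.character(classify_neuron(neuron_params(2, 6),
                                 stim_protocol(I_stim = 60, I_pre = Ipre))),
    character(1))
  expect_gt(length(unique(labs_pre)), 1)
})

test_that("map construction is deterministic and serialises losslessly", {
  g <- grid_spec(g_lt_max = 2, g_A_max = 2, step = 1)
  m1 <- build_pattern_map(g, stim_protocol(I_stim = 60))
  m2 <- build_pattern_map(g, stim_protocol(I_stim = 60))
  expect_identical(m1$labels, m2$labels)
  path <- file.path(withr::local_tempdir(), "map.csv")
  write_pattern_map(m1, path)
  m3 <- read_pattern_map(path)
  expect_identical(m3$labels, m1$labels)
  expect_equal(m3$grid$g_lt, m1$grid$g_lt)
  expect_equal(m3$protocol$I_stim, m1$protocol$I_stim)
  expect_equal(m3$params$gbar_Na, m1$params$gbar_Na)
})

test_that("nearest-node lookup clamps off-grid queries to the domain", {
  map <- map60_coarse()
  expect_equal(as.character(map_label_at(map, -3, -3)),
               as.character(map_label_at(map, 0, 0)))
  expect_equal(as.character(map_label_at(map, 25, 25)),
               as.character(map_label_at(map, 20, 20)))
  # ties and interior points resolve to the nearest node
  expect_equal(as.character(map_label_at(map, 5.9, 0.1)),
               as.character(map_label_at(map, 6, 0)))
})
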