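test_that("rook adjacency on lattices matches grid combinatorics", {
  g <- fx_lattice3()
  deg <- table(c(g$edges))
  # row-major 3x3: corners degree 2, edge cells 3, centre 4
  expect_equal(unname(deg[c("N0001", "N0003", "N0007", "N0009")]),
               rep(2L, 4L), ignore_attr = TRUE)
  expect_equal(unname(deg["N0005"]), 4L, ignore_attr = TRUE)
  # p x q lattice edge-count formula
  for (n in c(6L, 12L, 20L)) {
    gg <- generate_geometry(population_config(n_neighbourhoods = n))
    q <- ceiling(sqrt(n)); p <- ceiling(n / q)
    if (p * q == n) {
      expect_equal(nrow(gg$edges), p * (q - 1L) + q * (p - 1L))
    }
  }
})

test_that("corner-only (queen) contact is not rook adjacency", {
  polys <- list(
    A = rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
    B = rbind(c(1, 1), c(2, 1), c(2, 2), c(1, 2)))  # touches A at (1,1) only
  expect_equal(nrow(rook_adjacency(polys)), 0L)
  expect_equal(nrow(rook_adjacency(polys["A"])), 0L)  # single polygon
})

test_that("invalid geometry is rejected with the offending id", {
  polys <- list(ok = rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
                bad = rbind(c(5, 5), c(5, 5), c(5, 5)))
  expect_error(rook_adjacency(polys), "bad")
})

test_that("buffer selection matches exact dilated-outline membership", {
  g <- fx_lattice3()
  # make the centre cell its own stratum
  a <- g$areas
  a$stratum_id <- ifelse(a$neighbourhood_id == "N0005", "SC", "SO")
  g2 <- area_graph(a, g$polygons, g$edges)
  expect_equal(buffer_select(g2, "SC", 0)$buffer, character(0))
  sel <- buffer_select(g2, "SC", 1000)
  expect_setequal(sel$core, "N0005")
  # oracle: centroid within 1000 m of the centre cell [1000,2000]^2
  cents <- starsae:::graph_centroids(g2)
  others <- setdiff(rownames(cents), "N0005")
  oracle <- others[vapply(others, function(id) {
    rect_distance(cents[id, ], 1000, 2000, 1000, 2000) <= 1000
  }, logical(1L))]
  expect_setequal(sel$buffer, oracle)
  # rook neighbours at 500 m and diagonals at ~707 m are all inside
  expect_setequal(sel$buffer, others)
  # a huge buffer swallows the whole map
  sel_all <- buffer_select(g2, "SC", 1e7)
  expect_setequal(sel_all$estimation, a$neighbourhood_id)
  # a sub-diagonal buffer excludes exactly the diagonals
  sel_small <- buffer_select(g2, "SC", 600)
  expect_setequal(sel_small$buffer, c("N0002", "N0004", "N0006", "N0008"))
  expect_error(buffer_select(g2, "nope", 1000), "unknown stratum")
})

test_that("connect_subgraphs joins nearest centroids until connected", {
  g <- fx_islands()
  expect_equal(nrow(g$edges), 0L)
  gc <- connect_subgraphs(g)
  expect_equal(starsae:::n_components(gc), 1L)
  expect_equal(nrow(gc$added_edges), 2L)  # components - 1
  expect_equal(gc$added_edges,
               starsae:::normalize_edges(rbind(c("A", "B"), c("B", "C"))))
  # already connected graph is returned unchanged
  gc2 <- connect_subgraphs(gc)
  expect_identical(gc2$edges, gc$edges)
  expect_equal(nrow(gc2$added_edges), nrow(gc$added_edges))
})

test_that("distance ties are broken by the smallest id pair", {
  sq <- function(cx, half = 100) rbind(c(cx - half, -half), c(cx + half, -half),
                                       c(cx + half, half), c(cx - half, half))
  # B and C both 1000 m from A (left and right); A < B < C lexicographically
  polys <- list(B = sq(-1000), A = sq(0), C = sq(1000))
  areas <- data.frame(neighbourhood_id = c("B", "A", "C"), district_id = "D",
                      municipality_id = "M", stratum_id = "S",
                      cx = c(-1000, 0, 1000), cy = 0, stringsAsFactors = FALSE)
  g <- area_graph(areas, polys, NULL)
  gc <- connect_subgraphs(g)
  expect_equal(gc$added_edges[1L, ], c(id_s = "A", id_r = "B"))
})

test_that("MRF penalty reproduces the 3x3 lattice matrix", {
  K <- mrf_penalty(fx_lattice3())
  expected <- matrix(c(
     2, -1,  0, -1,  0,  0,  0,  0,  0,
    -1,  3, -1,  0, -1,  0,  0,  0,  0,
     0, -1,  2,  0,  0, -1,  0,  0,  0,
    -1,  0,  0,  3, -1,  0, -1,  0,  0,
     0, -1,  0, -1,  4, -1,  0, -1,  0,
     0,  0, -1,  0, -1,  3,  0,  0, -1,
     0,  0,  0, -1,  0,  0,  2, -1,  0,
     0,  0,  0,  0, -1,  0, -1,  3, -1,
     0,  0,  0,  0,  0, -1,  0, -1,  2), 9L, 9L, byrow = TRUE)
  expect_equal(unclass(K), expected, ignore_attr = TRUE)
  expect_equal(attr(K, "rank_deficiency"), 1L)
})

test_that("MRF penalty degenerate and tiny cases", {
  g1 <- generate_geometry(population_config(n_neighbourhoods = 1L))
  expect_equal(unclass(mrf_penalty(g1)), matrix(0, 1, 1), ignore_attr = TRUE)
  g2 <- generate_geometry(population_config(n_neighbourhoods = 2L))
  expect_equal(unclass(mrf_penalty(g2)),
               matrix(c(1, -1, -1, 1), 2L), ignore_attr = TRUE)
})

test_that("MRF quadratic form equals the sum of squared edge differences", {
  set.seed(7)
  for (rep in 1:5) {
    n <- 20L
    ids <- sprintf("V%02d", 1:n)
    edges <- t(combn(ids, 2L))
    edges <- edges[runif(nrow(edges)) < 0.15, , drop = FALSE]
    areas <- data.frame(neighbourhood_id = ids, district_id = "D",
                        municipality_id = "M", stratum_id = "S",
                        cx = runif(n), cy = runif(n), stringsAsFactors = FALSE)
    g <- area_graph(areas, setNames(vector("list", n), ids), edges)
    K <- unclass(mrf_penalty(g))
    expect_equal(unname(rowSums(K)), rep(0, n))
    gam <- rnorm(n)
    brute <- sum((gam[match(g$edges[, 1L], ids)] -
                    gam[match(g$edges[, 2L], ids)])^2)
    expect_equal(drop(t(gam) %*% K %*% gam), brute, tolerance = 1e-12)
  }
})

test_that("edge CSV and MTX exports round-trip", {
  g <- connect_subgraphs(fx_islands())
  path <- withr::local_tempfile(fileext = ".csv")
  write_edges_csv(g, path)
  back <- read_edges_csv(path)
  expect_equal(back$edges, g$edges)
  expect_equal(back$added_edges, g$added_edges)
  K <- mrf_penalty(fx_lattice3())
  mtx <- withr::local_tempfile(fileext = ".mtx")
  write_penalty_mtx(K, mtx)
  expect_equal(read_penalty_mtx(mtx), unclass(K), ignore_attr = TRUE)
})
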