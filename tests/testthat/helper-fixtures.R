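# Shared fixtures, built once per session and cached.

.fx <- new.env(parent = emptyenv())

fx_cached <- function(key, make) {
  if (is.null(.fx[[key]])) .fx[[key]] <- make()
  .fx[[key]]
}

# 3x3 unit-cell lattice (cell 1000 m), row-major ids N0001..N0009
fx_lattice3 <- function() {
  fx_cached("lattice3", function() {
    generate_geometry(population_config(n_neighbourhoods = 9L, seed = 1L))
  })
}

# mid-sized population with ground truth: 25 neighbourhoods x ~120 persons
fx_pop25 <- function() {
  fx_cached("pop25", function() {
    cfg <- population_config(n_neighbourhoods = 25L,
                             mean_persons_per_neighbourhood = 120,
                             seed = 3L)
    generate_population(cfg, generate_geometry(cfg))
  })
}

fx_spec_lean <- function() {
  model_spec(term_linear("sex"), term_smooth("age", 10L), term_mrf())
}

# REML fit of the lean spec on the full pop25 persons (outcomes known)
fx_fit25 <- function() {
  fx_cached("fit25", function() {
    pop <- fx_pop25()
    fit_star(fx_spec_lean(), pop$persons, outcome = "overweight",
             graph = pop$graph)
  })
}

# small i.i.d. logistic test frame with categorical + smooth structure
fx_logit_frame <- function(n = 500L, seed = 42L, nonlinear = TRUE) {
  set.seed(seed)
  df <- data.frame(
    g1 = sample(c("a", "b", "c"), n, replace = TRUE),
    g2 = sample(c("u", "v"), n, replace = TRUE),
    age = runif(n, 20, 90))
  f <- if (nonlinear) function(a) 1.2 * sin((a - 20) / 18) else
    function(a) 0.02 * (a - 50)
  eta <- -0.2 + 0.4 * (df$g1 == "b") - 0.6 * (df$g1 == "c") +
    0.3 * (df$g2 == "v") + f(df$age)
  df$y <- rbinom(n, 1L, plogis(eta))
  df$f_true <- f(df$age)
  df
}

fx_spec_logit <- function(n_knots = 10L) {
  model_spec(term_linear("g1", levels = c("a", "b", "c")),
             term_linear("g2", levels = c("u", "v")),
             term_smooth("age", n_knots = n_knots))
}

# three detached square polygons with centroids on a line at x = 0, 1, 10 (km)
fx_islands <- function() {
  sq <- function(cx, cy, half = 200) {
    rbind(c(cx - half, cy - half), c(cx + half, cy - half),
          c(cx + half, cy + half), c(cx - half, cy + half))
  }
  polys <- list(A = sq(0, 0), B = sq(1000, 0), C = sq(10000, 0))
  areas <- data.frame(neighbourhood_id = c("A", "B", "C"),
                      district_id = "D1", municipality_id = "M1",
                      stratum_id = "S1",
                      cx = c(0, 1000, 10000), cy = 0,
                      stringsAsFactors = FALSE)
  area_graph(areas, polys, rook_adjacency(polys))
}

# exact distance from a point to an axis-aligned rectangle [x0,x1]x[y0,y1]
rect_distance <- function(p, x0, x1, y0, y1) {
  dx <- max(x0 - p[1L], 0, p[1L] - x1)
  dy <- max(y0 - p[2L], 0, p[2L] - y1)
  sqrt(dx^2 + dy^2)
}
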