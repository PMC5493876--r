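#' @importFrom stats runif rbinom rnorm rgeom plogis qlogis rmultinom
#'   coef glm binomial lm predict quantile sd var cor setNames optim
#'   model.matrix rgamma chisq.test
#' @importFrom utils head tail
NULL

# ---- low-level polygon helpers ---------------------------------------------
# Polygons are plain numeric matrices with columns x, y (metres), one row per
# vertex, ring open (last vertex != first). All helpers assume simple,
# non-self-intersecting rings.

poly_area <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  j <- c(seq_len(nrow(p))[-1L], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

poly_centroid <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  j <- c(seq_len(nrow(p))[-1L], 1L)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(c(mean(x), mean(y)))
  c(sum((x + x[j]) * cr) / (6 * a), sum((y + y[j]) * cr) / (6 * a))
}

point_in_polygon <- function(pt, p) {
  # even-odd ray casting
  n <- nrow(p)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    xi <- p[i, 1L]; yi <- p[i, 2L]; xj <- p[j, 1L]; yj <- p[j, 2L]
    if ((yi > pt[2L]) != (yj > pt[2L]) &&
        pt[1L] < (xj - xi) * (pt[2L] - yi) / (yj - yi) + xi) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

point_segment_distance <- function(pt, a, b) {
  v <- b - a
  len2 <- sum(v * v)
  if (len2 == 0) return(sqrt(sum((pt - a)^2)))
  t <- max(0, min(1, sum((pt - a) * v) / len2))
  sqrt(sum((pt - a - t * v)^2))
}

point_polygon_distance <- function(pt, p) {
  if (point_in_polygon(pt, p)) return(0)
  n <- nrow(p)
  j <- c(seq_len(n)[-1L], 1L)
  min(vapply(seq_len(n), function(i) {
    point_segment_distance(pt, p[i, ], p[j[i], ])
  }, numeric(1L)))
}

# Distance from a point to a union of polygons: zero inside any member,
# else the minimum boundary distance. Equals membership of the union
# dilated by r (Minkowski sum with a disc of radius r) when compared <= r.
point_polygons_distance <- function(pt, polys) {
  min(vapply(polys, function(p) point_polygon_distance(pt, p), numeric(1L)))
}

# ---- synthetic geometry -----------------------------------------------------

#' Generate synthetic area geometry with nested administrative levels
#'
#' Builds `n_neighbourhoods` planar polygons (metre units) arranged on a
#' rectangular lattice of square cells, optionally perturbed into irregular
#' quadrilaterals (`geometry_kind = "irregular"`). Neighbourhoods nest into
#' districts (2 x 2 blocks of cells), districts into municipalities
#' (2 x 2 blocks of districts), and municipalities are partitioned into
#' `n_strata` contiguous strata, mimicking the neighbourhood / district /
#' municipality / health-service-region hierarchy used in Dutch public
#' health reporting. The rook-contiguity edge set is computed on the
#' resulting polygons.
#'
#' @param config a [population_config()] object (fields `n_neighbourhoods`,
#'   `geometry_kind`, `n_strata`, `cell_size_m`, `seed` are used).
#' @return an [area_graph] object.
#' @seealso [rook_adjacency()], [area_graph()]
#' @export
generate_geometry <- function(config) {
  stopifnot(inherits(config, "population_config"))
  n <- config$n_neighbourhoods
  if (n < 1L) stop("n_neighbourhoods must be >= 1")
  cell <- config$cell_size_m
  ncol_ <- ceiling(sqrt(n))
  nrow_ <- ceiling(n / ncol_)

  # vertex grid, possibly jittered (interior vertices only, < cell/2 so the
  # quadrilaterals stay simple and shared edges stay shared)
  vx <- outer(rep(1, nrow_ + 1L), 0:ncol_) * cell
  vy <- outer(nrow_:0, rep(1, ncol_ + 1L)) * cell
  if (identical(config$geometry_kind, "irregular") && nrow_ >= 2L && ncol_ >= 2L) {
    jit <- 0.35 * cell
    with_seed(stage_seed(config$seed, "geometry"), {
      for (i in 2:nrow_) {
        for (j in 2:ncol_) {
          vx[i, j] <- vx[i, j] + runif(1L, -jit, jit)
          vy[i, j] <- vy[i, j] + runif(1L, -jit, jit)
        }
      }
    })
  }

  ids <- sprintf("N%04d", seq_len(n))
  polys <- vector("list", n)
  row_of <- integer(n); col_of <- integer(n)
  k <- 0L
  for (r in seq_len(nrow_)) {
    for (cc in seq_len(ncol_)) {
      k <- k + 1L
      if (k > n) break
      # corners: (r, cc) block in vertex grid, counter-clockwise
      polys[[k]] <- rbind(
        c(vx[r + 1L, cc],      vy[r + 1L, cc]),
        c(vx[r + 1L, cc + 1L], vy[r + 1L, cc + 1L]),
        c(vx[r,      cc + 1L], vy[r,      cc + 1L]),
        c(vx[r,      cc],      vy[r,      cc]))
      row_of[k] <- r; col_of[k] <- cc
    }
  }
  names(polys) <- ids

  district_num <- (row_of - 1L) %/% 2L * ((ncol_ + 1L) %/% 2L) +
    (col_of - 1L) %/% 2L + 1L
  district_id <- sprintf("D%03d", match(district_num, sort(unique(district_num))))
  muni_num <- (row_of - 1L) %/% 4L * ((ncol_ + 3L) %/% 4L) +
    (col_of - 1L) %/% 4L + 1L
  municipality_id <- sprintf("M%03d", match(muni_num, sort(unique(muni_num))))

  # strata: contiguous groups of municipalities ordered by westmost column
  n_strata <- min(config$n_strata, length(unique(municipality_id)))
  mu <- sort(unique(municipality_id))
  mu_col <- vapply(mu, function(m) min(col_of[municipality_id == m]), numeric(1L))
  mu_ord <- mu[order(mu_col, mu)]
  grp <- ceiling(seq_along(mu_ord) / (length(mu_ord) / n_strata))
  stratum_of_mu <- setNames(sprintf("S%02d", grp), mu_ord)
  stratum_id <- unname(stratum_of_mu[municipality_id])

  cents <- t(vapply(polys, poly_centroid, numeric(2L)))
  areas <- data.frame(
    neighbourhood_id = ids, district_id = district_id,
    municipality_id = municipality_id, stratum_id = stratum_id,
    cx = cents[, 1L], cy = cents[, 2L], stringsAsFactors = FALSE)

  edges <- rook_adjacency(polys)
  area_graph(areas, polys, edges)
}

# ---- GeoJSON i/o ------------------------------------------------------------

#' Write area geometry to GeoJSON
#'
#' Polygon features in planar metre coordinates with properties
#' `neighbourhood_id`, `district_id`, `municipality_id`, `stratum_id`.
#'
#' @param graph an [area_graph].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_geojson <- function(graph, path) {
  stopifnot(inherits(graph, "area_graph"))
  feats <- lapply(seq_len(nrow(graph$areas)), function(i) {
    a <- graph$areas[i, ]
    ring <- graph$polygons[[a$neighbourhood_id]]
    ring <- rbind(ring, ring[1L, , drop = FALSE])  # GeoJSON rings are closed
    list(
      type = "Feature",
      properties = list(
        neighbourhood_id = a$neighbourhood_id, district_id = a$district_id,
        municipality_id = a$municipality_id, stratum_id = a$stratum_id),
      geometry = list(type = "Polygon",
                      coordinates = list(lapply(seq_len(nrow(ring)),
                                                function(j) ring[j, ]))))
  })
  json <- jsonlite::toJSON(list(type = "FeatureCollection", features = feats),
                           auto_unbox = TRUE, digits = NA)
  writeLines(json, path)
  invisible(path)
}

#' Read area geometry from GeoJSON
#'
#' Inverse of [write_geojson()]; rook adjacency is recomputed from the
#' polygons so the returned object is a complete [area_graph].
#'
#' @param path GeoJSON file written by [write_geojson()] (or any polygon
#'   FeatureCollection with the same four id properties).
#' @return an [area_graph].
#' @export
read_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) stop("not a FeatureCollection")
  feats <- gj$features
  polys <- vector("list", length(feats))
  props <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    if (!identical(f$geometry$type, "Polygon")) {
      stop("feature ", i, " is not a Polygon")
    }
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1L]],
                                  function(v) as.numeric(unlist(v))[1:2]))
    if (all(ring[1L, ] == ring[nrow(ring), ])) {
      ring <- ring[-nrow(ring), , drop = FALSE]
    }
    polys[[i]] <- ring
    props[[i]] <- f$properties
  }
  areas <- data.frame(
    neighbourhood_id = vapply(props, `[[`, "", "neighbourhood_id"),
    district_id = vapply(props, `[[`, "", "district_id"),
    municipality_id = vapply(props, `[[`, "", "municipality_id"),
    stratum_id = vapply(props, `[[`, "", "stratum_id"),
    stringsAsFactors = FALSE)
  names(polys) <- areas$neighbourhood_id
  cents <- t(vapply(polys, poly_centroid, numeric(2L)))
  areas$cx <- cents[, 1L]; areas$cy <- cents[, 2L]
  area_graph(areas, polys, rook_adjacency(polys))
}
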