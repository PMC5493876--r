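#' Neighbourhood adjacency graph
#'
#' Container for area geometry plus its rook-contiguity graph: the polygon
#' rings, centroids, the nested administrative ids, the undirected edge set
#' and the subset of edges that were inserted afterwards to connect
#' disconnected subgraphs (see [connect_subgraphs()]).
#'
#' @param areas data.frame with columns `neighbourhood_id`, `district_id`,
#'   `municipality_id`, `stratum_id`, `cx`, `cy`.
#' @param polygons named list of open coordinate rings (x/y matrices, metres),
#'   names matching `neighbourhood_id`.
#' @param edges two-column character matrix of unordered neighbour pairs,
#'   stored with `edges[,1] < edges[,2]`.
#' @param added_edges edges inserted by [connect_subgraphs()], same format.
#' @return object of class `area_graph`.
#' @export
area_graph <- function(areas, polygons, edges,
                       added_edges = matrix(character(), ncol = 2L)) {
  stopifnot(is.data.frame(areas),
            all(c("neighbourhood_id", "district_id", "municipality_id",
                  "stratum_id", "cx", "cy") %in% names(areas)))
  if (anyDuplicated(areas$neighbourhood_id)) stop("duplicate neighbourhood ids")
  rownames(areas) <- NULL
  edges <- normalize_edges(edges)
  added_edges <- normalize_edges(added_edges)
  ids <- areas$neighbourhood_id
  if (length(edges) && !all(edges %in% ids)) stop("edge references unknown id")
  if (any(edges[, 1L] == edges[, 2L])) stop("self-loop in edge set")
  g <- structure(list(areas = areas, polygons = polygons, edges = edges,
                      added_edges = added_edges), class = "area_graph")
  g
}

normalize_edges <- function(edges) {
  if (is.null(edges) || length(edges) == 0L) {
    return(matrix(character(), ncol = 2L,
                  dimnames = list(NULL, c("id_s", "id_r"))))
  }
  edges <- matrix(as.character(edges), ncol = 2L)
  swap <- edges[, 1L] > edges[, 2L]
  edges[swap, ] <- edges[swap, c(2L, 1L)]
  edges <- unique(edges)
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  dimnames(edges) <- list(NULL, c("id_s", "id_r"))
  edges
}

#' @export
print.area_graph <- function(x, ...) {
  cat("area_graph:", nrow(x$areas), "neighbourhoods,",
      length(unique(x$areas$district_id)), "districts,",
      length(unique(x$areas$municipality_id)), "municipalities,",
      length(unique(x$areas$stratum_id)), "strata\n")
  cat("  edges:", nrow(x$edges),
      sprintf("(%d added to connect subgraphs)", nrow(x$added_edges)), "\n")
  cat("  components:", n_components(x), "\n")
  invisible(x)
}

#' @export
format.area_graph <- function(x, ...) {
  sprintf("<area_graph: %d areas, %d edges>", nrow(x$areas), nrow(x$edges))
}

graph_ids <- function(graph) graph$areas$neighbourhood_id

graph_centroids <- function(graph) {
  m <- as.matrix(graph$areas[, c("cx", "cy")])
  rownames(m) <- graph$areas$neighbourhood_id
  m
}

as_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    as.data.frame(graph$edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = graph_ids(graph), stringsAsFactors = FALSE))
}

n_components <- function(graph) {
  if (nrow(graph$areas) == 0L) return(0L)
  igraph::components(as_igraph(graph))$no
}

component_labels <- function(graph) {
  m <- igraph::components(as_igraph(graph))$membership
  m[graph_ids(graph)]
}

#' Restrict an area graph to a subset of neighbourhoods
#'
#' Keeps the listed neighbourhoods and the edges among them (induced
#' subgraph); `added_edges` are filtered the same way.
#'
#' @param graph an [area_graph].
#' @param ids character vector of neighbourhood ids to keep.
#' @return an [area_graph].
#' @export
graph_subset <- function(graph, ids) {
  stopifnot(all(ids %in% graph_ids(graph)))
  keep_e <- graph$edges[, 1L] %in% ids & graph$edges[, 2L] %in% ids
  keep_a <- graph$added_edges[, 1L] %in% ids & graph$added_edges[, 2L] %in% ids
  area_graph(graph$areas[graph$areas$neighbourhood_id %in% ids, , drop = FALSE],
             graph$polygons[ids],
             graph$edges[keep_e, , drop = FALSE],
             graph$added_edges[keep_a, , drop = FALSE])
}

# ---- rook contiguity --------------------------------------------------------

# Do two segments share a collinear overlap of positive length?
# tol is both the snap tolerance (metres) and the minimal overlap length.
segments_overlap <- function(a1, a2, b1, b2, tol = 1e-9) {
  u <- a2 - a1
  lu <- sqrt(sum(u * u))
  if (lu <= tol) return(FALSE)
  un <- u / lu
  # both endpoints of b must lie on the line through a (within tol)
  d1 <- abs(un[1L] * (b1[2L] - a1[2L]) - un[2L] * (b1[1L] - a1[1L]))
  d2 <- abs(un[1L] * (b2[2L] - a1[2L]) - un[2L] * (b2[1L] - a1[1L]))
  if (d1 > tol || d2 > tol) return(FALSE)
  t1 <- sum((b1 - a1) * un)
  t2 <- sum((b2 - a1) * un)
  lo <- max(min(t1, t2), 0)
  hi <- min(max(t1, t2), lu)
  (hi - lo) > tol
}

#' Rook-contiguity adjacency from polygons
#'
#' Two areas are adjacent iff their rings share a boundary segment of
#' positive length; corner-only (queen) contact does not count. Candidate
#' pairs are pre-filtered by bounding boxes, then tested by exact
#' collinear-segment overlap with a snap tolerance.
#'
#' @param polygons named list of open coordinate rings.
#' @param tol snap tolerance / minimum shared length, metres.
#' @return two-column character matrix of unordered adjacent id pairs.
#' @export
rook_adjacency <- function(polygons, tol = 1e-9) {
  n <- length(polygons)
  ids <- names(polygons)
  if (is.null(ids) || anyDuplicated(ids)) stop("polygons must have unique names")
  for (i in seq_len(n)) {
    p <- polygons[[i]]
    if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 3L ||
        !all(is.finite(p)) || poly_area(p) <= tol) {
      stop("invalid polygon geometry for id ", ids[i])
    }
  }
  if (n < 2L) return(normalize_edges(NULL))
  bb <- t(vapply(polygons, function(p) {
    c(min(p[, 1L]), max(p[, 1L]), min(p[, 2L]), max(p[, 2L]))
  }, numeric(4L)))
  segs <- lapply(polygons, function(p) {
    j <- c(seq_len(nrow(p))[-1L], 1L)
    list(a = p, b = p[j, , drop = FALSE])
  })
  out <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (bb[i, 1L] > bb[j, 2L] + tol || bb[j, 1L] > bb[i, 2L] + tol ||
          bb[i, 3L] > bb[j, 4L] + tol || bb[j, 3L] > bb[i, 4L] + tol) next
      si <- segs[[i]]; sj <- segs[[j]]
      hit <- FALSE
      for (k in seq_len(nrow(si$a))) {
        for (l in seq_len(nrow(sj$a))) {
          if (segments_overlap(si$a[k, ], si$b[k, ], sj$a[l, ], sj$b[l, ], tol)) {
            hit <- TRUE; break
          }
        }
        if (hit) break
      }
      if (hit) out[[length(out) + 1L]] <- c(ids[i], ids[j])
    }
  }
  normalize_edges(do.call(rbind, out))
}

# ---- buffer selection -------------------------------------------------------

#' Select the estimation region for a stratum: core plus distance buffer
#'
#' The core is the stratum's own neighbourhoods. The buffer contains every
#' other neighbourhood whose centroid lies within `buffer_m` metres of the
#' stratum outline (the union of its polygons) -- i.e. inside the outline
#' dilated by a disc of radius `buffer_m`. Buffer areas contribute their
#' individuals to estimation only, never to prediction.
#'
#' @param graph an [area_graph] over the full map.
#' @param stratum_id stratum to estimate.
#' @param buffer_m buffer radius in metres (default 10000, i.e. 10 km).
#' @return list with `core`, `buffer` and `estimation` id vectors.
#' @export
buffer_select <- function(graph, stratum_id, buffer_m = 10000) {
  stopifnot(buffer_m >= 0)
  if (!stratum_id %in% graph$areas$stratum_id) {
    stop("unknown stratum id: ", stratum_id)
  }
  core <- graph$areas$neighbourhood_id[graph$areas$stratum_id == stratum_id]
  others <- setdiff(graph_ids(graph), core)
  if (buffer_m == 0 || length(others) == 0L) {
    buf <- character()
  } else {
    core_polys <- graph$polygons[core]
    cents <- graph_centroids(graph)
    d <- vapply(others, function(id) {
      point_polygons_distance(cents[id, ], core_polys)
    }, numeric(1L))
    buf <- others[d <= buffer_m]
  }
  list(core = core, buffer = buf, estimation = c(core, buf))
}

# ---- connecting subgraphs ---------------------------------------------------

#' Connect disconnected subgraphs through nearest centroids
#'
#' While the graph has more than one connected component, the globally
#' closest pair of centroids lying in two different components (Euclidean
#' distance) is joined by a new edge; distance ties are broken by the
#' lexicographically smallest `(id_s, id_r)` pair. The inserted edges are
#' recorded in `added_edges`. Exactly `components - 1` edges are added and
#' no edge is ever removed.
#'
#' @param graph an [area_graph] (typically the estimation-set subgraph,
#'   where buffering can strand islands).
#' @return an [area_graph] that is connected.
#' @export
connect_subgraphs <- function(graph) {
  ids <- graph_ids(graph)
  if (length(ids) <= 1L) return(graph)
  comp <- component_labels(graph)
  cents <- graph_centroids(graph)
  new_edges <- list()
  while (length(unique(comp)) > 1L) {
    dd <- as.matrix(stats::dist(cents))
    same <- outer(comp, comp, "==")
    dd[same] <- Inf
    dd[lower.tri(dd, diag = TRUE)] <- Inf
    best <- min(dd)
    cand <- which(dd <= best + 1e-12, arr.ind = TRUE)
    pair_ids <- cbind(ids[cand[, 1L]], ids[cand[, 2L]])
    swap <- pair_ids[, 1L] > pair_ids[, 2L]
    pair_ids[swap, ] <- pair_ids[swap, c(2L, 1L)]
    ord <- order(pair_ids[, 1L], pair_ids[, 2L])
    e <- pair_ids[ord[1L], ]
    new_edges[[length(new_edges) + 1L]] <- e
    comp[comp == comp[match(e[2L], ids)]] <- comp[match(e[1L], ids)]
  }
  if (length(new_edges) == 0L) return(graph)
  add <- normalize_edges(do.call(rbind, new_edges))
  area_graph(graph$areas, graph$polygons,
             rbind(graph$edges, add),
             rbind(graph$added_edges, add))
}

# ---- penalty matrices -------------------------------------------------------

#' Markov-random-field penalty matrix from an adjacency graph
#'
#' Builds the intrinsic-autoregression penalty K with `K[s,s]` = number of
#' neighbours of `s`, `K[s,r] = -1` for adjacent pairs and 0 otherwise, so
#' that the quadratic form equals the sum of squared coefficient
#' differences over adjacent pairs. Rank deficiency equals the number of
#' connected components (one after [connect_subgraphs()]).
#'
#' @param graph an [area_graph].
#' @return dense symmetric matrix of class `penalty_matrix` with attributes
#'   `kind = "mrf"` and `rank_deficiency`; dimnames are neighbourhood ids.
#' @export
mrf_penalty <- function(graph) {
  ids <- graph_ids(graph)
  d <- length(ids)
  K <- matrix(0, d, d, dimnames = list(ids, ids))
  if (nrow(graph$edges)) {
    i <- match(graph$edges[, 1L], ids)
    j <- match(graph$edges[, 2L], ids)
    for (k in seq_along(i)) {
      K[i[k], j[k]] <- K[i[k], j[k]] - 1
      K[j[k], i[k]] <- K[j[k], i[k]] - 1
      K[i[k], i[k]] <- K[i[k], i[k]] + 1
      K[j[k], j[k]] <- K[j[k], j[k]] + 1
    }
  }
  penalty_matrix(K, kind = "mrf", rank_deficiency = max(n_components(graph), 1L))
}

#' Ridge (identity) penalty matrix
#'
#' The exchangeable random-intercept variant: the penalty matrix is the
#' identity, shrinking every coefficient independently toward zero.
#'
#' @param d block size.
#' @return `penalty_matrix` of kind `"ridge"` with zero rank deficiency.
#' @export
ridge_penalty <- function(d) {
  penalty_matrix(diag(d), kind = "ridge", rank_deficiency = 0L)
}

penalty_matrix <- function(K, kind, rank_deficiency) {
  stopifnot(is.matrix(K), nrow(K) == ncol(K),
            max(abs(K - t(K))) < 1e-12)
  structure(K, kind = kind, rank_deficiency = as.integer(rank_deficiency),
            class = c("penalty_matrix", class(K)))
}

#' @export
print.penalty_matrix <- function(x, ...) {
  cat(sprintf("penalty_matrix (%s), %d x %d, rank deficiency %d\n",
              attr(x, "kind"), nrow(x), ncol(x), attr(x, "rank_deficiency")))
  print(unclass(x)[seq_len(min(9L, nrow(x))), seq_len(min(9L, ncol(x))),
                   drop = FALSE], ...)
  if (nrow(x) > 9L) cat("...\n")
  invisible(x)
}

# ---- exports ----------------------------------------------------------------

#' Write the adjacency list as an edge CSV
#'
#' Columns `id_s`, `id_r`, `added_flag` (1 for edges inserted by
#' [connect_subgraphs()]).
#'
#' @param graph an [area_graph].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edges_csv <- function(graph, path) {
  added <- paste(graph$added_edges[, 1L], graph$added_edges[, 2L])
  df <- data.frame(id_s = graph$edges[, 1L], id_r = graph$edges[, 2L],
                   added_flag = as.integer(
                     paste(graph$edges[, 1L], graph$edges[, 2L]) %in% added))
  data.table::fwrite(df, path)
  invisible(path)
}

#' Read an edge CSV written by [write_edges_csv()]
#'
#' @param path edge CSV path.
#' @return list with `edges` and `added_edges` matrices.
#' @export
read_edges_csv <- function(path) {
  df <- data.table::fread(path, colClasses = list(character = c("id_s", "id_r")))
  e <- normalize_edges(cbind(df$id_s, df$id_r))
  a <- normalize_edges(cbind(df$id_s[df$added_flag == 1L],
                             df$id_r[df$added_flag == 1L]))
  list(edges = e, added_edges = a)
}

#' Write a penalty matrix in MatrixMarket format
#'
#' @param K a [penalty_matrix] (or any matrix).
#' @param path output `.mtx` path.
#' @return `path`, invisibly.
#' @export
write_penalty_mtx <- function(K, path) {
  Matrix::writeMM(methods::as(Matrix::Matrix(unclass(K), sparse = TRUE),
                              "generalMatrix"), path)
  invisible(path)
}

#' Read a MatrixMarket penalty matrix
#'
#' @param path `.mtx` path.
#' @return dense base matrix.
#' @export
read_penalty_mtx <- function(path) {
  as.matrix(Matrix::readMM(path))
}
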