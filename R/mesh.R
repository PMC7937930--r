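#' Triangulated cortical surface patch
#'
#' A `cortical_mesh` holds per-vertex 3D coordinates (mm), a triangle list,
#' and the undirected edge graph with Euclidean edge lengths, the metric on
#' which connective-field Gaussian kernels are defined. Vertex ids are
#' 1-based throughout the package; file readers translate from 0-based
#' on-disk conventions.
#'
#' @param coords numeric matrix, vertices x 3, positions in mm.
#' @param triangles integer matrix, faces x 3, 1-based vertex indices.
#' @return An object of class `cortical_mesh` with elements `coords`,
#'   `triangles`, `graph` (an igraph with a `weight` edge attribute in mm),
#'   `n_vertices`, and a per-center geodesic distance cache.
#' @examples
#' m <- cortical_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
#'                    matrix(c(1, 2, 3), nrow = 1))
#' geodesic_distances(m, 1, c(2, 3))
#' @export
cortical_mesh <- function(coords, triangles) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3)
  if (ncol(coords) != 3L) stop("`coords` must be an n x 3 matrix")
  n <- nrow(coords)
  if (any(!is.finite(coords))) stop("vertex coordinates must be finite")
  if (nrow(triangles) < 1L) stop("mesh needs at least one triangle")
  if (any(triangles < 1L) || any(triangles > n))
    stop("triangle references a vertex outside 1..", n)
  if (any(triangles[, 1] == triangles[, 2] |
          triangles[, 1] == triangles[, 3] |
          triangles[, 2] == triangles[, 3]))
    stop("degenerate triangle (repeated vertex)")

  edges <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(1, 3)])
  edges <- t(apply(edges, 1, sort))
  edges <- unique(edges)
  len <- sqrt(rowSums((coords[edges[, 1], , drop = FALSE] -
                       coords[edges[, 2], , drop = FALSE])^2))
  if (any(len <= 0)) stop("edge lengths must be strictly positive (coincident vertices?)")
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, t(edges))
  igraph::E(g)$weight <- len

  structure(
    list(coords = coords, triangles = triangles, graph = g,
         n_vertices = n, .dist_cache = new.env(parent = emptyenv())),
    class = "cortical_mesh")
}

#' @export
print.cortical_mesh <- function(x, ...) {
  cat(sprintf("cortical_mesh: %d vertices, %d triangles, %d edges\n",
              x$n_vertices, nrow(x$triangles), igraph::ecount(x$graph)))
  invisible(x)
}

#' Region of interest on a cortical mesh
#'
#' @param name label string, e.g. "V1".
#' @param vertex_ids integer vector of mesh vertex ids (1-based).
#' @param mesh optional `cortical_mesh`; when given, ids are validated
#'   against it.
#' @return Object of class `cf_roi`.
#' @export
cf_roi <- function(name, vertex_ids, mesh = NULL) {
  vertex_ids <- as.integer(vertex_ids)
  if (length(vertex_ids) == 0L) stop("ROI '", name, "' is empty")
  if (anyDuplicated(vertex_ids)) vertex_ids <- unique(vertex_ids)
  if (!is.null(mesh)) {
    bad <- vertex_ids[vertex_ids < 1L | vertex_ids > mesh$n_vertices]
    if (length(bad))
      stop("ROI '", name, "' references vertices not on the mesh: ",
           paste(head(bad, 5), collapse = ", "))
  }
  structure(list(name = as.character(name), vertex_ids = sort(vertex_ids)),
            class = "cf_roi")
}

#' @export
print.cf_roi <- function(x, ...) {
  cat(sprintf("cf_roi '%s': %d vertices\n", x$name, length(x$vertex_ids)))
  invisible(x)
}

#' Check that an ROI induces a connected subgraph
#'
#' Source regions must be connected so that geodesic distances between any
#' center and any source vertex are finite.
#'
#' @param mesh a `cortical_mesh`.
#' @param roi a `cf_roi`.
#' @return `TRUE` (invisibly) or an error naming the disconnected pieces.
#' @export
assert_roi_connected <- function(mesh, roi) {
  sub <- igraph::induced_subgraph(mesh$graph, roi$vertex_ids)
  comp <- igraph::components(sub)
  if (comp$no > 1L)
    stop("ROI '", roi$name, "' is disconnected on the mesh (",
         comp$no, " components of sizes ",
         paste(comp$csize, collapse = ", "), ")")
  invisible(TRUE)
}

#' Geodesic distances along the mesh edge graph
#'
#' Shortest-path (Dijkstra) distance in mm between a center vertex and a set
#' of target vertices, using 3D Euclidean edge weights. This is the distance
#' entering the connective-field Gaussian kernel. Results are cached per
#' center vertex, so repeated queries are cheap and return identical values.
#'
#' @param mesh a `cortical_mesh`.
#' @param center single vertex id.
#' @param targets vertex ids to measure to; defaults to all vertices.
#' @return Named numeric vector of distances in mm, one per target, in the
#'   order given. `d(center, center)` is 0.
#' @export
geodesic_distances <- function(mesh, center, targets = seq_len(mesh$n_vertices)) {
  center <- as.integer(center)
  targets <- as.integer(targets)
  if (length(center) != 1L || center < 1L || center > mesh$n_vertices)
    stop("`center` must be a single vertex id on the mesh")
  if (any(targets < 1L | targets > mesh$n_vertices))
    stop("target vertex id outside the mesh")
  key <- as.character(center)
  d <- mesh$.dist_cache[[key]]
  if (is.null(d)) {
    d <- as.numeric(igraph::distances(mesh$graph, v = center,
                                      algorithm = "dijkstra"))
    mesh$.dist_cache[[key]] <- d
  }
  out <- d[targets]
  if (any(!is.finite(out))) {
    comp <- igraph::components(mesh$graph)
    bad <- targets[!is.finite(out)]
    stop("vertices ", paste(head(bad, 5), collapse = ", "),
         " are unreachable from center ", center,
         " (center lies in component ", comp$membership[center],
         ", unreachable targets in component(s) ",
         paste(unique(comp$membership[bad]), collapse = ", "), ")")
  }
  names(out) <- targets
  out
}

#' Pairwise geodesic distance matrix over a vertex set
#'
#' @param mesh a `cortical_mesh`.
#' @param vertex_ids vertex ids (typically a source ROI).
#' @return Symmetric matrix of shortest-path distances in mm with
#'   `vertex_ids` as dimnames.
#' @export
geodesic_distance_matrix <- function(mesh, vertex_ids) {
  vertex_ids <- as.integer(vertex_ids)
  D <- igraph::distances(mesh$graph, v = vertex_ids, to = vertex_ids,
                         algorithm = "dijkstra")
  if (any(!is.finite(D)))
    stop("vertex set is disconnected on the mesh; geodesic distances undefined")
  dimnames(D) <- list(vertex_ids, vertex_ids)
  D
}
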