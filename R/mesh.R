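#' Triangle surface mesh
#'
#' Constructs a triangle mesh from vertex coordinates (mm) and 1-based face
#' indices, with validation of the structural invariants required throughout
#' the package: all face indices valid, no degenerate face index triples, and
#' (optionally) edge-manifoldness — each edge shared by at most two faces.
#'
#' @param vertices Numeric N x 3 matrix of vertex coordinates in mm.
#' @param faces Integer M x 3 matrix of 1-based vertex indices.
#' @param validate Check invariants (default TRUE).
#' @return An object of class `triangle_mesh` with elements `vertices`,
#'   `faces`, `n_vertices`, `n_faces`.
#' @export
triangle_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be an N x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an M x 3 matrix")
  n <- nrow(vertices)
  if (validate) {
    if (any(faces < 1L) || any(faces > n)) stop("face indices out of range [1, N]")
    if (any(faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
            faces[, 2] == faces[, 3])) {
      stop("a face repeats a vertex index")
    }
    ek <- edge_keys(faces, n)
    if (any(tabulate(match(ek, unique(ek))) > 2L)) {
      stop("mesh is not edge-manifold: an edge is shared by more than 2 faces")
    }
  }
  structure(list(vertices = vertices, faces = faces,
                 n_vertices = n, n_faces = nrow(faces)),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces\n", x$n_vertices, x$n_faces))
  invisible(x)
}

# Numeric keys (a-1)*N + b, a < b, for all 3 edges of each face.
edge_keys <- function(faces, n) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  a <- pmin(e[, 1], e[, 2]); b <- pmax(e[, 1], e[, 2])
  (as.numeric(a) - 1) * n + b
}

# Unique undirected edges as a 2-column matrix (a < b).
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  a <- pmin(e[, 1], e[, 2]); b <- pmax(e[, 1], e[, 2])
  unique(cbind(a, b))
}

#' Paired pial/white cortical surfaces
#'
#' Couples a pial and a white-matter mesh with one-to-one vertex
#' correspondence: identical vertex counts and an identical face list (shared
#' topology). Vertex `i` of the white mesh is the white-matter point
#' corresponding to pial vertex `i`, so the cortical thickness at `i` is
#' `||w_i - p_i||`, which must be strictly positive.
#'
#' @param pial,white `triangle_mesh` objects sharing topology.
#' @return Object of class `surface_pair`.
#' @export
surface_pair <- function(pial, white) {
  stopifnot(inherits(pial, "triangle_mesh"), inherits(white, "triangle_mesh"))
  if (pial$n_vertices != white$n_vertices) stop("pial/white vertex counts differ")
  if (!identical(pial$faces, white$faces)) stop("pial/white face lists differ")
  thick <- row_norms(white$vertices - pial$vertices)
  if (any(thick <= 0)) {
    stop(sprintf("zero cortical thickness at vertex %d", which(thick <= 0)[1]))
  }
  structure(list(pial = pial, white = white, thickness = thick),
            class = "surface_pair")
}

#' @export
print.surface_pair <- function(x, ...) {
  cat(sprintf("surface_pair: %d vertices, %d faces, thickness %.2f-%.2f mm\n",
              x$pial$n_vertices, x$pial$n_faces,
              min(x$thickness), max(x$thickness)))
  invisible(x)
}

#' Per-face unit normal vectors
#'
#' Normals follow the face winding (right-hand rule over the vertex order).
#'
#' @param mesh A `triangle_mesh`.
#' @return M x 3 matrix of unit normals.
#' @export
face_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cross3(a, b)
  len <- row_norms(n)
  bad <- which(len < 1e-12)
  if (length(bad)) stop(sprintf("degenerate (zero-area) face at index %d", bad[1]))
  n / len
}

#' Per-vertex unit normal vectors
#'
#' The normal at a vertex is the (unnormalized) mean of the unit normals of
#' its adjacent faces, renormalized to unit length — the convention used by
#' the downsampled/original surface-normal orientation estimators.
#'
#' @param mesh A `triangle_mesh`.
#' @return N x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  fn <- face_normals(mesh)
  f <- mesh$faces
  acc <- matrix(0, mesh$n_vertices, 3)
  cnt <- numeric(mesh$n_vertices)
  for (k in 1:3) {
    idx <- f[, k]
    acc[, 1] <- acc[, 1] + unname(tapply_add(fn[, 1], idx, mesh$n_vertices))
    acc[, 2] <- acc[, 2] + unname(tapply_add(fn[, 2], idx, mesh$n_vertices))
    acc[, 3] <- acc[, 3] + unname(tapply_add(fn[, 3], idx, mesh$n_vertices))
    cnt <- cnt + tabulate(idx, nbins = mesh$n_vertices)
  }
  iso <- which(cnt == 0)
  if (length(iso)) stop(sprintf("isolated vertex %d belongs to no face", iso[1]))
  normalize_rows(acc / cnt, label = "mean normal (cancelling face normals)")
}

# Sum values of `x` grouped by integer index `idx` into a length-n vector.
tapply_add <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s
  out
}

#' Vertex adjacency lists
#'
#' @param mesh A `triangle_mesh`.
#' @return List of length N; element i is the sorted integer vector of
#'   vertices sharing an edge with vertex i.
#' @export
vertex_adjacency <- function(mesh) {
  e <- mesh_edges(mesh)
  adj <- split(c(e[, 2], e[, 1]), c(e[, 1], e[, 2]))
  out <- rep(list(integer(0)), mesh$n_vertices)
  out[as.integer(names(adj))] <- lapply(adj, function(v) sort(as.integer(v)))
  out
}

# igraph over mesh edges weighted by Euclidean length
mesh_graph <- function(mesh) {
  e <- mesh_edges(mesh)
  w <- row_norms(mesh$vertices[e[, 1], , drop = FALSE] -
                 mesh$vertices[e[, 2], , drop = FALSE])
  igraph::graph_from_edgelist(e, directed = FALSE) |>
    igraph::set_edge_attr("weight", value = w)
}

#' Geodesic (graph) distances from a seed vertex
#'
#' Shortest-path distances along mesh edges, with edge length equal to the
#' Euclidean distance between its endpoints. Supports the 5 mm Gaussian
#' smoothing kernels used for source patches and the spatial coherence prior.
#'
#' @param mesh A `triangle_mesh`.
#' @param seed_vertex 1-based vertex index.
#' @param radius Maximum distance (mm); vertices farther (or disconnected)
#'   are absent from the result.
#' @return Named numeric vector of distances (names are vertex indices),
#'   including `distance(seed) = 0`.
#' @export
geodesic_distances <- function(mesh, seed_vertex, radius) {
  stopifnot(seed_vertex >= 1, seed_vertex <= mesh$n_vertices, radius >= 0)
  g <- mesh_graph(mesh)
  d <- as.numeric(igraph::distances(g, v = seed_vertex, algorithm = "dijkstra"))
  keep <- which(is.finite(d) & d <= radius)
  setNames(d[keep], keep)
}

# All-pairs geodesic distance matrix (small decimated meshes only).
geodesic_distance_matrix <- function(mesh) {
  igraph::distances(mesh_graph(mesh), algorithm = "dijkstra")
}

#' Correspondence map produced by mesh decimation
#'
#' @param retained Integer vector of original-mesh vertex indices, one per
#'   decimated vertex (decimated vertex i sits at original vertex
#'   `retained[i]`; vertices are removed, never moved).
#' @param decimated_faces Face list of the decimated mesh (indices into the
#'   decimated vertex order).
#' @param n_original Vertex count of the original mesh.
#' @return Object of class `decimation_map`.
#' @export
decimation_map <- function(retained, decimated_faces, n_original) {
  retained <- as.integer(retained)
  if (anyDuplicated(retained)) stop("retained indices must be unique")
  if (any(retained < 1L) || any(retained > n_original)) {
    stop("retained indices out of range of the original mesh")
  }
  structure(list(retained = retained,
                 decimated_faces = decimated_faces,
                 n_original = as.integer(n_original)),
            class = "decimation_map")
}

#' Decimate a pial/white surface pair, preserving vertex correspondence
#'
#' Reduces the shared mesh topology by greedy edge collapse in which every
#' collapse snaps onto an existing original vertex: vertices are removed,
#' never moved, so decimated coordinates are a bit-exact subset of the
#' originals. Collapses are prioritized by smallest quadric (squared
#' point-to-plane) error of the removed vertex against the kept one — the
#' shape-preserving criterion of standard surface simplifiers — with ties and
#' the collapse direction resolved deterministically toward the lowest vertex
#' index; collapses that would break the mesh topology (non-manifold links,
#' duplicated or flipped faces) are skipped. The surviving pial edge structure
#' is copied to the white surface, and the same vertices are removed from it,
#' maintaining the one-to-one vertex correspondence.
#'
#' @param pair A `surface_pair`.
#' @param factor Decimation factor (> 1); target vertex count is
#'   `round(N / factor)`.
#' @return List with `pair` (decimated `surface_pair`) and `map`
#'   (`decimation_map`).
#' @export
decimate_pair <- function(pair, factor = 10) {
  stopifnot(inherits(pair, "surface_pair"), factor >= 1)
  mesh <- pair$pial
  n <- mesh$n_vertices
  target <- round(n / factor)
  if (target < 4) stop("decimation factor would leave fewer than 4 vertices")

  if (target == n) {
    map <- decimation_map(seq_len(n), mesh$faces, n)
    return(list(pair = pair, map = map))
  }

  dec <- edge_collapse_decimate(mesh, target)
  if (abs(length(dec$retained) - target) > 0.1 * target) {
    stop("decimation stalled: could not reach the target vertex count")
  }
  remap <- integer(n)
  remap[dec$retained] <- seq_along(dec$retained)
  dfaces <- matrix(remap[dec$faces], ncol = 3)
  dp <- triangle_mesh(mesh$vertices[dec$retained, , drop = FALSE], dfaces)
  dw <- triangle_mesh(pair$white$vertices[dec$retained, , drop = FALSE], dfaces,
                      validate = FALSE)
  list(pair = surface_pair(dp, dw),
       map = decimation_map(dec$retained, dfaces, n))
}

# Greedy quadric-error edge collapse onto existing vertices. Returns retained
# original indices (ascending) and the surviving face list in original indices.
edge_collapse_decimate <- function(mesh, target) {
  n <- mesh$n_vertices
  verts <- mesh$vertices
  faces <- mesh$faces
  m <- nrow(faces)
  face_alive <- rep(TRUE, m)
  v_alive <- rep(TRUE, n)
  n_alive <- n

  adj <- vertex_adjacency(mesh)
  v2f <- rep(list(integer(0)), n)
  for (k in 1:3) {
    s <- split(seq_len(m), faces[, k])
    v2f[as.integer(names(s))] <- Map(c, v2f[as.integer(names(s))], s)
  }

  # per-vertex quadrics: sum of squared point-to-plane error forms of the
  # incident face planes (standard quadric error metric)
  fn_raw <- face_normals(mesh)
  Qv <- rep(list(matrix(0, 4, 4)), n)
  for (fi in seq_len(m)) {
    nvec <- fn_raw[fi, ]
    d <- -sum(nvec * verts[faces[fi, 1], ])
    q <- c(nvec, d)
    K <- tcrossprod(q)
    for (vv in faces[fi, ]) Qv[[vv]] <- Qv[[vv]] + K
  }
  qem_cost <- function(remove, keep) {
    h <- c(verts[keep, ], 1)
    as.numeric(h %*% (Qv[[remove]] + Qv[[keep]]) %*% h)
  }

  e <- mesh_edges(mesh)
  e_active <- rep(TRUE, nrow(e))
  # cost of an edge: the cheaper of its two collapse directions
  edge_cost <- function(i) min(qem_cost(e[i, 1], e[i, 2]), qem_cost(e[i, 2], e[i, 1]))
  prio <- vapply(seq_len(nrow(e)), edge_cost, numeric(1))
  ekey <- new.env(hash = TRUE, size = 4L * nrow(e))
  for (i in seq_len(nrow(e))) assign(sprintf("%d_%d", e[i, 1], e[i, 2]), i, envir = ekey)
  blocked <- integer(0)

  face_key <- function(tri) paste(sort(tri), collapse = "_")

  tri_normal <- function(tri) {
    a <- verts[tri[2], ] - verts[tri[1], ]
    b <- verts[tri[3], ] - verts[tri[1], ]
    c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
  }

  while (n_alive > target) {
    i <- which.min(prio)
    if (!is.finite(prio[i])) break  # no valid collapses left
    a <- e[i, 1]; b <- e[i, 2]
    c_ab <- qem_cost(a, b); c_ba <- qem_cost(b, a)
    # remove the endpoint with the cheaper error; ties keep the lower index
    if (c_ab < c_ba || (c_ab == c_ba && a > b)) { v <- a; u <- b } else { v <- b; u <- a }

    # validity of collapsing `vv` into `uu`: manifold link condition plus
    # rejection of flipped, degenerate, or duplicated replacement faces
    try_dir <- function(uu, vv) {
      shared <- intersect(v2f[[uu]], v2f[[vv]])
      shared <- shared[face_alive[shared]]
      opp <- setdiff(as.vector(faces[shared, , drop = FALSE]), c(uu, vv))
      common <- intersect(adj[[uu]], adj[[vv]])
      ok <- length(shared) <= 2 && setequal(common, opp)
      moved <- setdiff(v2f[[vv]][face_alive[v2f[[vv]]]], shared)
      if (ok) {
        for (fi in moved) {
          tri_old <- faces[fi, ]
          tri_new <- replace(tri_old, tri_old == vv, uu)
          n_old <- tri_normal(tri_old); n_new <- tri_normal(tri_new)
          if (sqrt(sum(n_new^2)) < 1e-12 || sum(n_old * n_new) <= 0) { ok <- FALSE; break }
        }
      }
      if (ok && length(moved)) {
        new_keys <- vapply(moved, function(fi) {
          face_key(replace(faces[fi, ], faces[fi, ] == vv, uu))
        }, character(1))
        if (anyDuplicated(new_keys)) ok <- FALSE
        if (ok) {
          u_faces <- setdiff(v2f[[uu]][face_alive[v2f[[uu]]]], shared)
          u_keys <- vapply(u_faces, function(fi) face_key(faces[fi, ]), character(1))
          if (any(new_keys %in% u_keys)) ok <- FALSE
        }
      }
      list(ok = ok, shared = shared, opp = opp, moved = moved)
    }

    cand <- try_dir(u, v)
    if (!cand$ok) {  # try the reverse collapse direction before giving up
      tmp <- u; u <- v; v <- tmp
      cand <- try_dir(u, v)
    }
    if (!cand$ok) {
      prio[i] <- Inf
      blocked <- c(blocked, i)
      next
    }
    shared <- cand$shared; opp <- cand$opp; moved <- cand$moved

    # ---- perform the collapse v -> u ----
    face_alive[shared] <- FALSE
    for (fi in moved) faces[fi, faces[fi, ] == v] <- u
    v2f[[u]] <- c(setdiff(v2f[[u]], shared), moved)
    for (w in opp) v2f[[w]] <- setdiff(v2f[[w]], shared)

    nb_v <- setdiff(adj[[v]], u)
    for (w in nb_v) {
      key_vw <- sprintf("%d_%d", min(v, w), max(v, w))
      j <- get(key_vw, envir = ekey)
      if (w %in% adj[[u]]) {
        e_active[j] <- FALSE; prio[j] <- Inf
      } else {
        # rename edge (v,w) -> (u,w)
        rm(list = key_vw, envir = ekey)
        aa <- min(u, w); bb <- max(u, w)
        e[j, ] <- c(aa, bb)
        assign(sprintf("%d_%d", aa, bb), j, envir = ekey)
        adj[[u]] <- c(adj[[u]], w)
        adj[[w]] <- c(adj[[w]], u)
      }
      adj[[w]] <- setdiff(adj[[w]], v)
    }
    j_uv <- get(sprintf("%d_%d", min(u, v), max(u, v)), envir = ekey)
    e_active[j_uv] <- FALSE; prio[j_uv] <- Inf
    adj[[u]] <- setdiff(adj[[u]], v)
    adj[[v]] <- integer(0)
    v2f[[v]] <- integer(0)
    v_alive[v] <- FALSE
    n_alive <- n_alive - 1

    # accumulate the removed vertex's quadric and refresh local costs
    Qv[[u]] <- Qv[[u]] + Qv[[v]]
    for (w in adj[[u]]) {
      j <- get(sprintf("%d_%d", min(u, w), max(u, w)), envir = ekey)
      if (e_active[j]) prio[j] <- edge_cost(j)
    }

    # neighborhoods changed: previously blocked edges may be valid again
    if (length(blocked)) {
      reopen <- blocked[e_active[blocked]]
      prio[reopen] <- vapply(reopen, edge_cost, numeric(1))
      blocked <- integer(0)
    }
  }

  list(retained = which(v_alive),
       faces = faces[face_alive, , drop = FALSE])
}
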