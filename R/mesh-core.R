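#' Triangulated surface mesh
#'
#' The geometric substrate of the package: a triangulated surface with
#' vertices in millimetres. A mesh may be a single closed surface or a rigid
#' group of closed components (see [merge_meshes()]); components are tracked
#' so that inside/outside queries treat the group as the union of its parts.
#'
#' @param vertices numeric matrix (n x 3) of vertex coordinates, mm.
#' @param faces integer matrix (m x 3) of 1-based vertex indices.
#' @param label free-text label carried through transforms.
#' @param repair apply the repair pass (weld exactly duplicated vertices,
#'   drop degenerate faces)? Default `TRUE`.
#' @param provenance source-path string carried into outputs.
#' @param comp optional integer vector (length m) of face component ids.
#'
#' @return an object of class `tri_mesh` with fields `vertices`, `faces`,
#'   `label`, `comp` (per-face component id), `watertight` (logical),
#'   `provenance`.
#' @export
tri_mesh <- function(vertices, faces, label = "", repair = TRUE,
                     provenance = NA_character_, comp = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  infer_comp <- is.null(comp) && repair
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (nrow(faces) == 0L || nrow(vertices) == 0L)
    stop("empty mesh: no vertices or faces")
  if (!all(is.finite(vertices))) stop("non-finite vertex coordinates")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face indices out of range")
  if (is.null(comp)) comp <- rep(1L, nrow(faces))
  comp <- as.integer(comp)
  if (length(comp) != nrow(faces)) stop("comp must have one entry per face")

  if (repair) {
    key <- paste(vertices[, 1], vertices[, 2], vertices[, 3])
    first <- match(key, key)
    keep <- !duplicated(key)
    remap <- cumsum(keep)[first]
    vertices <- vertices[keep, , drop = FALSE]
    faces[] <- remap[faces]
    ok <- faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3] &
      faces[, 1] != faces[, 3]
    ok <- ok & .tri_areas(vertices, faces) > 1e-14
    faces <- faces[ok, , drop = FALSE]
    comp <- comp[ok]
    if (nrow(faces) == 0L)
      stop("mesh is degenerate: no valid triangles after repair")
    used <- sort(unique(as.vector(faces)))
    if (length(used) < nrow(vertices)) {
      vertices <- vertices[used, , drop = FALSE]
      faces[] <- match(faces, used)
    }
  }
  if (infer_comp) comp <- .connected_components(nrow(vertices), faces)
  comp <- match(comp, sort(unique(comp)))  # densify ids
  m <- structure(
    list(vertices = vertices, faces = faces, label = label,
         comp = as.integer(comp), watertight = NA, provenance = provenance),
    class = "tri_mesh")
  m$watertight <- is_watertight(m)
  m
}

.tri_areas <- function(V, F) {
  a <- V[F[, 1], , drop = FALSE]
  e1 <- V[F[, 2], , drop = FALSE] - a
  e2 <- V[F[, 3], , drop = FALSE] - a
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh '%s': %d vertices, %d faces, %d component(s), %s\n",
              x$label, nrow(x$vertices), nrow(x$faces), max(x$comp),
              if (isTRUE(x$watertight)) "watertight" else "not watertight"))
  invisible(x)
}

#' Is every component of a mesh a closed, consistently oriented surface?
#'
#' @param mesh a [tri_mesh()].
#' @return logical.
#' @export
is_watertight <- function(mesh) {
  for (c_id in seq_len(max(mesh$comp))) {
    f <- mesh$faces[mesh$comp == c_id, , drop = FALSE]
    if (nrow(f) == 0L) next
    he <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
    dir_key <- paste(he[, 1], he[, 2])
    und_key <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
    if (anyDuplicated(dir_key) > 0L) return(FALSE)
    if (any(table(und_key) != 2L)) return(FALSE)
  }
  TRUE
}

#' Axis-aligned bounding box of a mesh
#' @param mesh a [tri_mesh()].
#' @return 2 x 3 matrix (rows: min, max).
#' @export
mesh_bbox <- function(mesh) {
  rbind(min = apply(mesh$vertices, 2, min),
        max = apply(mesh$vertices, 2, max))
}

#' Total surface area of a mesh (mm^2)
#' @param mesh a [tri_mesh()].
#' @return numeric scalar.
#' @export
mesh_area <- function(mesh) sum(.tri_areas(mesh$vertices, mesh$faces))

#' Enclosed volume of a mesh (mm^3)
#'
#' For a single watertight component the signed divergence-theorem sum is
#' used (exact). For a multi-component mesh (e.g. the output of
#' [merge_meshes()]), whose components may interpenetrate, the volume of the
#' *union* is estimated on a deterministic grid of cell centres.
#'
#' @param mesh a [tri_mesh()].
#' @param method `"auto"` (default), `"divergence"` or `"grid"`.
#' @param grid_n nominal grid resolution per axis for the grid estimator.
#' @return numeric scalar (>= 0).
#' @export
mesh_volume <- function(mesh, method = c("auto", "divergence", "grid"),
                        grid_n = 48) {
  method <- match.arg(method)
  if (method == "auto") {
    if (isTRUE(mesh$watertight) &&
        (max(mesh$comp) == 1L || .components_disjoint(mesh))) {
      if (max(mesh$comp) == 1L) {
        method <- "divergence"
      } else {
        return(sum(vapply(seq_len(max(mesh$comp)), function(c_id) {
          f <- mesh$faces[mesh$comp == c_id, , drop = FALSE]
          sub <- mesh
          sub$faces <- f
          sub$comp <- rep(1L, nrow(f))
          mesh_volume(sub, method = "divergence")
        }, 0)))
      }
    } else {
      method <- "grid"
    }
  }
  if (method == "divergence") {
    V <- mesh$vertices
    F <- mesh$faces
    a <- V[F[, 1], , drop = FALSE]
    b <- V[F[, 2], , drop = FALSE]
    c <- V[F[, 3], , drop = FALSE]
    vols <- (a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
             a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
             a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
    return(abs(sum(vols)))
  }
  bb <- mesh_bbox(mesh)
  ext <- pmax(bb[2, ] - bb[1, ], 1e-9)
  n_div <- .grid_divisions(ext, grid_n^3)
  d <- ext / n_div
  g <- expand.grid(
    x = bb[1, 1] + (seq_len(n_div[1]) - 0.5) * d[1],
    y = bb[1, 2] + (seq_len(n_div[2]) - 0.5) * d[2],
    z = bb[1, 3] + (seq_len(n_div[3]) - 0.5) * d[3])
  inside <- cpp_points_in_mesh(as.matrix(g), mesh$vertices,
                               mesh$faces - 1L, mesh$comp - 1L)
  sum(inside) * prod(d)
}

# connected components of the face graph (faces sharing a vertex), so meshes
# read from plain files recover their shell structure
.connected_components <- function(n_vertices, faces) {
  parent <- seq_len(n_vertices)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_len(nrow(faces))) {
    a <- find(faces[k, 1]); b <- find(faces[k, 2]); c <- find(faces[k, 3])
    parent[b] <- a
    parent[c] <- a
  }
  roots <- vapply(faces[, 1], find, 1L)
  match(roots, sort(unique(roots)))
}

# are the per-component bounding boxes pairwise disjoint?
.components_disjoint <- function(mesh) {
  nc <- max(mesh$comp)
  if (nc == 1L) return(TRUE)
  boxes <- lapply(seq_len(nc), function(c_id) {
    v <- mesh$vertices[unique(as.vector(
      mesh$faces[mesh$comp == c_id, , drop = FALSE])), , drop = FALSE]
    rbind(apply(v, 2, min), apply(v, 2, max))
  })
  for (i in seq_len(nc - 1L))
    for (j in (i + 1L):nc)
      if (!any(boxes[[i]][2, ] < boxes[[j]][1, ] |
               boxes[[j]][2, ] < boxes[[i]][1, ]))
        return(FALSE)
  TRUE
}

# split a point budget over axes proportionally to extents
.grid_divisions <- function(ext, budget) {
  w <- ext / max(ext)
  base <- (budget / prod(w))^(1 / 3)
  n <- pmax(1L, as.integer(round(base * w)))
  n
}

.rotation_matrix <- function(axis, angle_deg) {
  axis <- as.numeric(axis)
  nrm <- sqrt(sum(axis^2))
  if (!is.finite(nrm) || nrm < 1e-12) stop("rotation axis must be non-zero")
  u <- axis / nrm
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * ct + st * K + (1 - ct) * (u %o% u)
}

#' Rotate 3D points about an arbitrary axis
#'
#' @param points n x 3 matrix (or length-3 vector).
#' @param axis rotation axis (non-zero 3-vector).
#' @param angle_deg rotation angle in degrees (right-hand rule).
#' @param center a point on the rotation axis.
#' @return matrix of the same shape as `points`.
#' @export
rotate_points <- function(points, axis, angle_deg, center = c(0, 0, 0)) {
  vec <- is.null(dim(points))
  p <- if (vec) matrix(points, 1, 3) else as.matrix(points)
  if (!is.finite(angle_deg)) stop("angle must be finite")
  R <- .rotation_matrix(axis, angle_deg)
  out <- sweep(sweep(p, 2, center) %*% t(R), 2, center, "+")
  if (vec) drop(out) else out
}

#' Rigid rotation of a mesh about an arbitrary centre
#'
#' Rotates all vertices by `angle_deg` about the line through `center` along
#' `axis`. Volume is preserved (the transform is rigid).
#'
#' @inheritParams rotate_points
#' @param mesh a [tri_mesh()].
#' @return the rotated `tri_mesh`.
#' @export
rigid_rotate <- function(mesh, axis, angle_deg, center = c(0, 0, 0)) {
  mesh$vertices <- rotate_points(mesh$vertices, axis, angle_deg, center)
  mesh
}

#' Rigid translation of a mesh
#' @param mesh a [tri_mesh()].
#' @param offset length-3 numeric displacement, mm.
#' @return the translated `tri_mesh`.
#' @export
rigid_translate <- function(mesh, offset) {
  mesh$vertices <- sweep(mesh$vertices, 2, as.numeric(offset), "+")
  mesh
}

#' Merge two meshes into one rigid object
#'
#' The result behaves, for all overlap queries, as the union of the inputs:
#' faces are concatenated and the component bookkeeping keeps inside/outside
#' tests correct even where the inputs interpenetrate.
#'
#' @param mesh_a,mesh_b [tri_mesh()] objects; either may be `NULL` (treated
#'   as the empty mesh).
#' @return a `tri_mesh`.
#' @export
merge_meshes <- function(mesh_a, mesh_b) {
  if (is.null(mesh_a)) return(mesh_b)
  if (is.null(mesh_b)) return(mesh_a)
  n_a <- nrow(mesh_a$vertices)
  tri_mesh(
    rbind(mesh_a$vertices, mesh_b$vertices),
    rbind(mesh_a$faces, mesh_b$faces + n_a),
    label = paste0(mesh_a$label, "+", mesh_b$label),
    repair = FALSE,
    provenance = paste(stats::na.omit(c(mesh_a$provenance, mesh_b$provenance)),
                       collapse = ";"),
    comp = c(mesh_a$comp, mesh_b$comp + max(mesh_a$comp)))
}

#' Do two meshes intersect?
#'
#' Exact surface-intersection test (triangle/triangle, with bounding-box
#' pruning) plus a containment probe, so a mesh entirely inside the other is
#' also reported as intersecting. This is the decision used by the bending
#' engine at intersection threshold zero.
#'
#' @param mesh_a,mesh_b [tri_mesh()] objects.
#' @return logical.
#' @export
meshes_intersect <- function(mesh_a, mesh_b) {
  if (.bbox_disjoint(mesh_a, mesh_b)) return(FALSE)
  if (cpp_meshes_intersect(mesh_a$vertices, mesh_a$faces - 1L,
                           mesh_b$vertices, mesh_b$faces - 1L)) return(TRUE)
  .contained_in(mesh_a, mesh_b) || .contained_in(mesh_b, mesh_a)
}

.bbox_disjoint <- function(a, b) {
  ba <- mesh_bbox(a); bb <- mesh_bbox(b)
  any(ba[2, ] < bb[1, ] | bb[2, ] < ba[1, ])
}

# probe slightly inside mesh_a's first face; assumes surfaces do not cross
.contained_in <- function(mesh_a, mesh_b) {
  probe <- .interior_probe(mesh_a)
  if (is.null(probe)) return(FALSE)
  as.logical(cpp_points_in_mesh(matrix(probe, 1, 3), mesh_b$vertices,
                                mesh_b$faces - 1L, mesh_b$comp - 1L))
}

.interior_probe <- function(mesh) {
  f <- mesh$faces[1, ]
  a <- mesh$vertices[f[1], ]; b <- mesh$vertices[f[2], ]; c <- mesh$vertices[f[3], ]
  ctr <- (a + b + c) / 3
  n <- c((b - a)[2] * (c - a)[3] - (b - a)[3] * (c - a)[2],
         (b - a)[3] * (c - a)[1] - (b - a)[1] * (c - a)[3],
         (b - a)[1] * (c - a)[2] - (b - a)[2] * (c - a)[1])
  nn <- sqrt(sum(n^2))
  if (nn < 1e-14) return(NULL)
  eps <- 1e-6 * max(mesh_bbox(mesh)[2, ] - mesh_bbox(mesh)[1, ])
  ctr - n / nn * eps  # outward normals assumed: step inward
}

#' Overlap between two meshes as a fraction of their mean measure
#'
#' Measures the boolean intersection of two meshes and normalizes it by the
#' mean measure (enclosed volume by default, surface area optionally) of the
#' two inputs. Zero when disjoint; 1 for identical meshes. Contact is decided
#' exactly (triangle/triangle tests); the intersection volume, when the
#' surfaces do cross, is estimated on a deterministic grid of cell centres
#' over the overlap of the two bounding boxes.
#'
#' @param mesh_a,mesh_b [tri_mesh()] objects.
#' @param normalization `"volume"` (default: fraction of mean enclosed
#'   volume) or `"area"` (intersection volume over mean surface area, mm).
#' @param grid_n nominal grid resolution per axis for the volume estimate.
#' @param denom optional precomputed normalization denominator (used by the
#'   bending engine to avoid re-measuring static meshes).
#' @return non-negative scalar; 0 when the meshes are disjoint.
#' @export
overlap_fraction <- function(mesh_a, mesh_b,
                             normalization = c("volume", "area"),
                             grid_n = 20, denom = NULL) {
  normalization <- match.arg(normalization)
  if (is.null(denom)) {
    denom <- if (normalization == "volume")
      mean(c(mesh_volume(mesh_a), mesh_volume(mesh_b)))
    else mean(c(mesh_area(mesh_a), mesh_area(mesh_b)))
    if (!is.finite(denom) || denom <= 0)
      stop("overlap normalization is not positive; check input meshes (",
           mesh_a$label, ", ", mesh_b$label, ")")
  }
  intersection_volume(mesh_a, mesh_b, grid_n = grid_n) / denom
}

#' Volume of the boolean intersection of two meshes
#'
#' @inheritParams overlap_fraction
#' @return volume in mm^3 (0 when disjoint).
#' @export
intersection_volume <- function(mesh_a, mesh_b, grid_n = 20) {
  if (.bbox_disjoint(mesh_a, mesh_b)) return(0)
  region <- cpp_intersect_region(mesh_a$vertices, mesh_a$faces - 1L,
                                 mesh_b$vertices, mesh_b$faces - 1L)
  if (region[1] == 0) {
    if (.contained_in(mesh_a, mesh_b)) return(mesh_volume(mesh_a))
    if (.contained_in(mesh_b, mesh_a)) return(mesh_volume(mesh_b))
    return(0)
  }
  # grid over the bounding box of the surface-crossing region (padded): this
  # tracks the penetration lens itself, so the estimate is independent of
  # geometry far from the contact
  lo <- region[2:4]; hi <- region[5:7]
  pad <- pmax(0.25 * (hi - lo), 0.05 * max(hi - lo), 1e-6)
  ba <- mesh_bbox(mesh_a); bb <- mesh_bbox(mesh_b)
  lo <- pmax(lo - pad, ba[1, ], bb[1, ])
  hi <- pmin(hi + pad, ba[2, ], bb[2, ])
  ext <- pmax(hi - lo, 1e-12)
  n_div <- .grid_divisions(ext, grid_n^3)
  cpp_grid_inside_both(mesh_a$vertices, mesh_a$faces - 1L, mesh_a$comp - 1L,
                       mesh_b$vertices, mesh_b$faces - 1L, mesh_b$comp - 1L,
                       lo, hi, as.integer(n_div))
}

#' Cut a mesh by a plane, keeping the side opposite the normal
#'
#' Returns the closed sub-mesh on the negative side of the plane through
#' `plane_point` with outward `plane_normal`; cut cross-sections are re-capped
#' so each kept component stays watertight. Used to truncate neural spines.
#'
#' @param mesh a [tri_mesh()].
#' @param plane_point a point on the cutting plane.
#' @param plane_normal plane normal; material on the positive side is removed.
#' @return a `tri_mesh`.
#' @export
cut_above_plane <- function(mesh, plane_point, plane_normal) {
  n <- as.numeric(plane_normal)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12) stop("plane normal must be non-zero")
  n <- n / nn
  p0 <- as.numeric(plane_point)
  out_v <- NULL; out_f <- NULL; out_c <- NULL
  next_comp <- 0L
  for (c_id in seq_len(max(mesh$comp))) {
    F <- mesh$faces[mesh$comp == c_id, , drop = FALSE]
    if (nrow(F) == 0L) next
    piece <- .cut_component(mesh$vertices, F, p0, n)
    if (is.null(piece)) next
    next_comp <- next_comp + 1L
    off <- if (is.null(out_v)) 0L else nrow(out_v)
    out_v <- rbind(out_v, piece$V)
    out_f <- rbind(out_f, piece$F + off)
    out_c <- c(out_c, rep(next_comp, nrow(piece$F)))
  }
  if (is.null(out_f) || nrow(out_f) == 0L)
    stop("cut plane removes the entire mesh: empty result")
  tri_mesh(out_v, out_f, label = mesh$label, repair = TRUE,
           provenance = mesh$provenance, comp = out_c)
}

# cut one closed component; returns NULL if fully above the plane
.cut_component <- function(V, F, p0, n) {
  d <- as.numeric(sweep(V, 2, p0) %*% n)
  eps <- 1e-9 * max(1, max(abs(V)))
  side <- ifelse(d > eps, 1L, ifelse(d < -eps, -1L, 0L))
  if (all(side >= 0) && any(side > 0)) return(NULL)        # fully above
  if (all(side <= 0)) return(list(V = V, F = F))           # fully below
  verts <- lapply(seq_len(nrow(V)), function(i) V[i, ])
  new_faces <- list()
  cut_edges <- list()   # directed edges (i, j) on the plane, keep-side winding
  edge_cache <- new.env(parent = emptyenv())
  split_point <- function(i, j) {
    key <- paste(min(i, j), max(i, j))
    if (!is.null(edge_cache[[key]])) return(edge_cache[[key]])
    t <- d[i] / (d[i] - d[j])
    verts[[length(verts) + 1L]] <<- verts[[i]] + t * (verts[[j]] - verts[[i]])
    edge_cache[[key]] <- length(verts)
    length(verts)
  }
  kept_onplane <- list()  # directed on-plane edges of kept triangles
  for (k in seq_len(nrow(F))) {
    tri <- F[k, ]
    s <- side[tri]
    if (all(s <= 0)) {                       # keep whole triangle
      new_faces[[length(new_faces) + 1L]] <- tri
      if (sum(s == 0L) >= 2L) {
        ord <- c(1, 2, 3, 1)
        for (e in 1:3)
          if (s[ord[e]] == 0L && s[ord[e + 1]] == 0L)
            kept_onplane[[length(kept_onplane) + 1L]] <-
              c(tri[ord[e]], tri[ord[e + 1]])
      }
      next
    }
    if (all(s >= 0)) next                    # discard whole triangle
    # mixed: walk the triangle boundary, clip against the plane
    poly <- integer(0)
    entry <- NA_integer_; exit <- NA_integer_
    for (e in 1:3) {
      i <- tri[e]; j <- tri[if (e == 3) 1 else e + 1]
      if (s[e] <= 0) poly <- c(poly, i)
      si <- side[i]; sj <- side[j]
      if (si < 0 && sj > 0) {                # leaving the keep side
        q <- split_point(i, j)
        poly <- c(poly, q); exit <- q
      } else if (si > 0 && sj < 0) {         # entering the keep side
        q <- split_point(i, j)
        poly <- c(poly, q); entry <- q
      } else if (si == 0 && sj > 0) {
        exit <- i
      } else if (si > 0 && sj == 0) {
        entry <- j
      }
    }
    if (!is.na(exit) && !is.na(entry) && exit != entry)
      cut_edges[[length(cut_edges) + 1L]] <- c(exit, entry)
    if (length(poly) >= 3)
      for (t in 2:(length(poly) - 1))
        new_faces[[length(new_faces) + 1L]] <- poly[c(1, t, t + 1)]
  }
  # an on-plane edge of a kept triangle is a boundary (needs capping) iff its
  # twin triangle lay above the plane and was removed
  if (length(kept_onplane) > 0) {
    K <- do.call(rbind, kept_onplane)
    fwd <- paste(K[, 1], K[, 2])
    rev <- paste(K[, 2], K[, 1])
    open <- !(rev %in% fwd)
    for (e in which(open))
      cut_edges[[length(cut_edges) + 1L]] <- K[e, ]
  }
  Vn <- do.call(rbind, verts)
  Fn <- do.call(rbind, new_faces)
  # cap each boundary loop with a fan about its centroid
  if (length(cut_edges) > 0) {
    E <- do.call(rbind, cut_edges)
    E <- unique(E)
    nxt <- E[, 2]
    names(nxt) <- as.character(E[, 1])
    used <- rep(FALSE, nrow(E))
    starts <- E[, 1]
    for (si in seq_along(starts)) {
      if (used[si]) next
      loop <- integer(0)
      cur <- starts[si]
      repeat {
        loop <- c(loop, cur)
        used[E[, 1] == cur] <- TRUE
        nx <- nxt[as.character(cur)]
        if (is.na(nx)) break
        cur <- nx
        if (cur == loop[1]) break
        if (length(loop) > nrow(E)) break
      }
      if (length(loop) >= 3 && !is.na(nxt[as.character(loop[length(loop)])]) &&
          nxt[as.character(loop[length(loop)])] == loop[1]) {
        ctr <- colMeans(Vn[loop, , drop = FALSE])
        Vn <- rbind(Vn, ctr)
        ci <- nrow(Vn)
        for (e in seq_along(loop)) {
          a <- loop[e]; b <- loop[if (e == length(loop)) 1 else e + 1]
          Fn <- rbind(Fn, c(ci, b, a))
        }
      }
    }
  }
  list(V = Vn, F = Fn)
}
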