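#' Specification of a parametric synthetic vertebral column
#'
#' Describes a column of idealized trunk vertebrae built from analytic
#' primitives: an elliptical-section centrum with concave (amphicoelous)
#' endplates, a neural arch and spine (boxes), and flat zygapophyseal facet
#' plates whose orientation follows a per-position angle profile (0 deg =
#' horizontal, thoracic-style; 90 deg = vertical, lumbar-style). Because all
#' primitives are analytic, every landmark position, contact angle and strain
#' limit has a closed form, which is what makes the bending engine testable
#' against paper-and-pencil oracles.
#'
#' @param n_vertebrae number of vertebrae (>= 2).
#' @param centrum_width mediolateral centrum semi-axis, mm.
#' @param centrum_height dorsoventral centrum semi-axis, mm.
#' @param centrum_length centrum length, mm.
#' @param concavity_depth depth of the endplate dimple, mm.
#' @param gap optimal joint spacing, mm; scalar or length `n_vertebrae - 1`.
#' @param facet_angle facet angle from horizontal in degrees, scalar or
#'   per-vertebra vector in `[0, 90]`.
#' @param facet_height dorsoventral position of the facet pair centre, mm.
#' @param facet_lateral_offset mediolateral position of the facet pair, mm.
#' @param facet_length,facet_span,facet_thickness facet plate dimensions
#'   (craniocaudal, in-plane height, thickness), mm.
#' @param facet_stagger half-offset of pre/postzygapophyseal plates along the
#'   craniocaudal axis, mm (the facets overlap partially, as in life).
#' @param facet_clearance capsule-space clearance between facet surfaces, mm;
#'   `NULL` uses the anatomical default `2 - 1.2 sin(angle)` (horizontal
#'   thoracic facets have loose, "open" capsules; vertical lumbar facets are
#'   tightly apposed).
#' @param arch_length,arch_height,arch_width neural arch box dimensions, mm
#'   (`arch_height` above the centrum dorsal margin).
#' @param spine_height neural spine height above the arch roof, mm; scalar or
#'   per-vertebra vector; 0 suppresses the spine.
#' @param spine_length,spine_width spine box cross-section, mm.
#' @param spine_rake craniocaudal spine inclination, degrees (positive =
#'   caudal lean); scalar or per-vertebra vector.
#' @param intercentra `NULL`, or a list with elements `outer_radius`,
#'   `inner_radius`, `half_angle_deg` (crescent cross-section), `embed`
#'   (depth sunk into the anterior centrum, mm), `tilt_deg` (caudal-face
#'   inclination so the ventroflexing posterior endplate meets it face-on)
#'   and `clearance` (neutral gap to the posterior endplate, mm), describing
#'   the ventral crescent intercentrum of each joint.
#' @param damage list of `c(vertebra, side)` pairs; the named side loses its
#'   zygapophyses (mesh, landmarks and facet polygons).
#' @param mesh_segments segments for the centrum lathe (multiple of 4).
#' @param species,group,region_pos column metadata (see [column_model()]).
#' @param seed integer seed for optional landmark noise.
#' @param landmark_noise sd of isotropic landmark jitter, mm (default 0:
#'   fully deterministic).
#' @return an object of class `synthetic_column_spec`.
#' @export
synthetic_column_spec <- function(
    n_vertebrae = 8, centrum_width = 10, centrum_height = 7,
    centrum_length = 30, concavity_depth = 0.7, gap = 4, facet_angle = 45,
    facet_height = 10.8, facet_lateral_offset = 5, facet_length = 12,
    facet_span = 6, facet_thickness = 2, facet_stagger = 2.5,
    facet_clearance = NULL, arch_length = 8, arch_height = 8,
    arch_width = 10, spine_height = 10, spine_length = 4, spine_width = 3,
    spine_rake = 0, intercentra = NULL, damage = list(), mesh_segments = 24,
    species = "synthetic", group = "reptile", region_pos = NA_integer_,
    seed = 1L, landmark_noise = 0) {
  if (n_vertebrae < 2) stop("n_vertebrae must be >= 2")
  if (mesh_segments %% 4 != 0) stop("mesh_segments must be a multiple of 4")
  dims <- c(centrum_width, centrum_height, centrum_length, facet_length,
            facet_span, facet_thickness, arch_length, arch_height, arch_width)
  if (any(dims <= 0)) stop("all dimensions must be positive")
  fa <- rep_len(facet_angle, n_vertebrae)
  if (any(fa < 0 | fa > 90)) stop("facet_angle must lie in [0, 90] degrees")
  gaps <- rep_len(gap, n_vertebrae - 1L)
  if (any(gaps <= 0)) stop("gap must be positive")
  spec <- list(
    n_vertebrae = as.integer(n_vertebrae), centrum_width = centrum_width,
    centrum_height = centrum_height, centrum_length = centrum_length,
    concavity_depth = concavity_depth, gap = gaps, facet_angle = fa,
    facet_height = facet_height, facet_lateral_offset = facet_lateral_offset,
    facet_length = facet_length, facet_span = facet_span,
    facet_thickness = facet_thickness, facet_stagger = facet_stagger,
    facet_clearance = facet_clearance, arch_length = arch_length,
    arch_height = arch_height, arch_width = arch_width,
    spine_height = rep_len(spine_height, n_vertebrae),
    spine_length = spine_length, spine_width = spine_width,
    spine_rake = rep_len(spine_rake, n_vertebrae),
    intercentra = intercentra, damage = damage,
    mesh_segments = as.integer(mesh_segments), species = species,
    group = group, region_pos = region_pos, seed = as.integer(seed),
    landmark_noise = landmark_noise)
  class(spec) <- "synthetic_column_spec"
  spec
}

#' @export
print.synthetic_column_spec <- function(x, ...) {
  cat(sprintf(
    "synthetic_column_spec '%s': %d vertebrae, facet angles %.0f-%.0f deg%s\n",
    x$species, x$n_vertebrae, min(x$facet_angle), max(x$facet_angle),
    if (!is.null(x$intercentra)) ", with intercentra" else ""))
  invisible(x)
}

.clearance_for_angle <- function(spec, k) {
  if (!is.null(spec$facet_clearance)) return(spec$facet_clearance)
  2 - 1.2 * sin(spec$facet_angle[k] * pi / 180)
}

# ---- mesh primitives ------------------------------------------------------

# solid of revolution about the x axis; profile runs from the axis (r = 0)
# at one end to the axis at the other
.lathe_x <- function(profile_x, profile_r, nseg) {
  stopifnot(profile_r[1] == 0, profile_r[length(profile_r)] == 0)
  inner <- which(profile_r > 0)
  theta <- 2 * pi * (seq_len(nseg) - 1) / nseg
  ring_y <- cos(theta); ring_z <- sin(theta)
  V <- rbind(c(profile_x[1], 0, 0))
  ring_start <- integer(length(inner))
  for (i in seq_along(inner)) {
    j <- inner[i]
    ring_start[i] <- nrow(V) + 1L
    V <- rbind(V, cbind(profile_x[j], profile_r[j] * ring_y,
                        profile_r[j] * ring_z))
  }
  V <- rbind(V, c(profile_x[length(profile_x)], 0, 0))
  pole1 <- 1L; pole2 <- nrow(V)
  F <- list()
  nxt <- function(i) if (i == nseg) 1L else i + 1L
  r1 <- ring_start[1]
  for (i in seq_len(nseg))  # cranial pole fan
    F[[length(F) + 1L]] <- c(pole1, r1 + i - 1L, r1 + nxt(i) - 1L)
  for (q in seq_len(length(inner) - 1L)) {
    a <- ring_start[q]; b <- ring_start[q + 1L]
    for (i in seq_len(nseg)) {
      F[[length(F) + 1L]] <- c(a + i - 1L, b + i - 1L, b + nxt(i) - 1L)
      F[[length(F) + 1L]] <- c(a + i - 1L, b + nxt(i) - 1L, a + nxt(i) - 1L)
    }
  }
  rl <- ring_start[length(inner)]
  for (i in seq_len(nseg))  # caudal pole fan
    F[[length(F) + 1L]] <- c(pole2, rl + nxt(i) - 1L, rl + i - 1L)
  Fm <- do.call(rbind, F)
  m <- tri_mesh(V, Fm, repair = FALSE)
  .orient_outward(m)
}

# scale the z column for elliptical sections
.scale_z <- function(mesh, sz) {
  mesh$vertices[, 3] <- mesh$vertices[, 3] * sz
  mesh
}

# box with axes given by the columns of R (need not be right-handed)
.oriented_box <- function(center, dims, R = diag(3)) {
  h <- dims / 2
  corners <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  V <- sweep(corners %*% diag(h) %*% t(R), 2, center, "+")
  # faces of the unit cube in expand.grid ordering (1: ---, 2: +--, 3: -+-,
  # 4: ++-, 5: --+, 6: +-+, 7: -++, 8: +++)
  F <- rbind(c(1, 3, 4), c(1, 4, 2), c(5, 6, 8), c(5, 8, 7),
             c(1, 2, 6), c(1, 6, 5), c(3, 7, 8), c(3, 8, 4),
             c(1, 5, 7), c(1, 7, 3), c(2, 4, 8), c(2, 8, 6))
  .orient_outward(tri_mesh(V, F, repair = FALSE))
}

# extruded prism: cross-section polygon (y, z) swept from x0 to x1
.prism_x <- function(poly_yz, x0, x1) {
  n <- nrow(poly_yz)
  ctr <- colMeans(poly_yz)
  V <- rbind(cbind(x0, poly_yz), cbind(x1, poly_yz),
             c(x0, ctr), c(x1, ctr))
  c0 <- 2L * n + 1L; c1 <- 2L * n + 2L
  F <- list()
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    F[[length(F) + 1L]] <- c(c0, j, i)                   # x0 cap
    F[[length(F) + 1L]] <- c(c1, n + i, n + j)           # x1 cap
    F[[length(F) + 1L]] <- c(i, j, n + j)                # side
    F[[length(F) + 1L]] <- c(i, n + j, n + i)
  }
  .orient_outward(tri_mesh(V, do.call(rbind, F), repair = FALSE))
}

# flip all faces if the signed volume is negative (makes normals outward)
.orient_outward <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]; b <- V[F[, 2], , drop = FALSE]
  c <- V[F[, 3], , drop = FALSE]
  s <- sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
           a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
           a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1]))
  if (s < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]
  mesh
}

# ---- vertebra generation --------------------------------------------------

#' Generate one synthetic vertebra
#'
#' Builds the mesh (centrum + arch + spine + facet plates as a rigid group of
#' closed components) and its [landmark_set()] in a local frame with the
#' centrum centred on the x axis, cranial face at `x = -L/2`.
#'
#' @param spec a [synthetic_column_spec()].
#' @param k vertebra position (1-based).
#' @return list with elements `mesh` and `landmarks`.
#' @export
generate_vertebra <- function(spec, k) {
  L <- spec$centrum_length
  rz <- spec$centrum_width; ry <- spec$centrum_height
  d <- spec$concavity_depth
  nseg <- spec$mesh_segments
  if (nseg < 8) stop("mesh resolution too low to represent facets")

  # centrum: lathe of a circular profile (radius ry), z scaled to rz/ry;
  # endplate dimple is a paraboloid of depth d (shallow spherical cap)
  fr <- c(1, 2 / 3, 1 / 3)
  prof_x <- c(-L / 2 + d, -L / 2 + d * (1 - fr[3]^2), -L / 2 + d * (1 - fr[2]^2),
              -L / 2, L / 2, L / 2 - d * (1 - fr[2]^2), L / 2 - d * (1 - fr[3]^2),
              L / 2 - d)
  prof_r <- c(0, ry * fr[3], ry * fr[2], ry, ry, ry * fr[2], ry * fr[3], 0)
  centrum <- .scale_z(.lathe_x(prof_x, prof_r, nseg), rz / ry)

  roof <- ry + spec$arch_height
  arch <- .oriented_box(c(0, (ry - 2 + roof) / 2, 0),
                        c(spec$arch_length, roof - ry + 2, spec$arch_width))
  mesh <- merge_meshes(centrum, arch)

  hs <- spec$spine_height[k]
  if (hs > 0) {
    spine <- .oriented_box(c(0, roof - 0.5 + (hs + 0.5) / 2, 0),
                           c(spec$spine_length, hs + 0.5, spec$spine_width))
    rake <- spec$spine_rake[k]
    if (rake != 0)
      spine$vertices <- rotate_points(spine$vertices, c(0, 0, 1), -rake,
                                      c(0, roof, 0))
    mesh <- merge_meshes(mesh, spine)
  }

  # zygapophyseal facet plates: a vertebra's prezygapophyses articulate with
  # the preceding vertebra's postzygapophyses, so they take the preceding
  # position's facet angle; the per-position profile is thus a per-joint one
  alpha_of <- function(kind) {
    kk <- if (kind == "prezyg") max(k - 1L, 1L) else k
    spec$facet_angle[kk] * pi / 180
  }
  clearance_of <- function(kind) {
    kk <- if (kind == "prezyg") max(k - 1L, 1L) else k
    .clearance_for_angle(spec, kk)
  }
  yz <- spec$facet_height; zo <- spec$facet_lateral_offset
  fl <- spec$facet_length; fh <- spec$facet_span; ft <- spec$facet_thickness
  o <- spec$facet_stagger
  gap_cr <- if (k > 1) spec$gap[k - 1] else spec$gap[1]
  gap_cd <- if (k < spec$n_vertebrae) spec$gap[k] else spec$gap[length(spec$gap)]
  damage_side <- .damage_side(spec, k)

  pts <- list()
  facet_polys <- list()
  for (side in c("left", "right")) {
    sgn <- if (side == "left") 1 else -1
    x_hat <- c(1, 0, 0)
    for (kind in c("prezyg", "postzyg")) {
      alpha <- alpha_of(kind)
      cl <- clearance_of(kind)
      n_hat <- c(0, cos(alpha), sgn * sin(alpha))
      t_hat <- c(0, -sin(alpha), sgn * cos(alpha))
      x_pair <- if (kind == "prezyg") -L / 2 - gap_cr / 2 else L / 2 + gap_cd / 2
      pc <- c(x_pair, yz, sgn * zo)
      sgn_k <- if (kind == "prezyg") -1 else 1
      surface_c <- pc + sgn_k * o * x_hat + sgn_k * (cl / 2) * n_hat
      center <- surface_c + sgn_k * (ft / 2) * n_hat
      lm_cr <- surface_c - (fl / 2) * x_hat
      lm_cd <- surface_c + (fl / 2) * x_hat
      pts[[paste(kind, side, "cranial", sep = "_")]] <- lm_cr
      pts[[paste(kind, side, "caudal", sep = "_")]] <- lm_cd
      corners <- rbind(
        surface_c - (fl / 2) * x_hat - (fh / 2) * t_hat,
        surface_c + (fl / 2) * x_hat - (fh / 2) * t_hat,
        surface_c + (fl / 2) * x_hat + (fh / 2) * t_hat,
        surface_c - (fl / 2) * x_hat + (fh / 2) * t_hat)
      facet_polys[[paste("facet", kind, side, sep = "_")]] <- corners
      if (side != damage_side) {
        # plates are carried as part of the rigid vertebra group; connecting
        # rami are omitted (anatomical realism is out of scope and any
        # connector protruding into the joint space would add spurious
        # contacts)
        plate <- .oriented_box(center, c(fl, fh, ft),
                               R = cbind(x_hat, t_hat, n_hat))
        mesh <- merge_meshes(mesh, plate)
      }
    }
  }

  pts[["endplate_cranial_dorsal"]] <- c(-L / 2, ry, 0)
  pts[["endplate_cranial_ventral"]] <- c(-L / 2, -ry, 0)
  pts[["endplate_cranial_left"]] <- c(-L / 2, 0, rz)
  pts[["endplate_cranial_right"]] <- c(-L / 2, 0, -rz)
  pts[["endplate_caudal_dorsal"]] <- c(L / 2, ry, 0)
  pts[["endplate_caudal_ventral"]] <- c(L / 2, -ry, 0)
  pts[["endplate_caudal_left"]] <- c(L / 2, 0, rz)
  pts[["endplate_caudal_right"]] <- c(L / 2, 0, -rz)
  pts[["arch_apex"]] <- c(0, roof, 0)

  if (damage_side != "none") {
    drop <- grepl(paste0("zyg_", damage_side), names(pts)) |
      grepl(paste0("facet_.*_", damage_side), names(pts))
    pts <- pts[!drop]
    facet_polys <- facet_polys[!grepl(paste0("_", damage_side), names(facet_polys))]
  }

  P <- do.call(rbind, pts)
  rownames(P) <- names(pts)
  if (length(facet_polys) > 0) {
    for (nm in names(facet_polys)) {
      fp <- facet_polys[[nm]]
      rownames(fp) <- paste(nm, 1:4, sep = "_")
      P <- rbind(P, fp)
    }
  }
  if (spec$landmark_noise > 0) {
    set.seed(spec$seed + k)
    P <- P + matrix(stats::rnorm(length(P), sd = spec$landmark_noise),
                    nrow(P), 3)
  }
  lm <- landmark_set(P, centrum_length = L,
                     endplate_area = pi * rz * ry,
                     side_damage = damage_side)
  mesh$label <- sprintf("%s_v%02d", spec$species, k)
  list(mesh = mesh, landmarks = lm)
}

.damage_side <- function(spec, k) {
  for (dmg in spec$damage)
    if (as.integer(dmg[1]) == k) return(match.arg(dmg[2], c("left", "right")))
  "none"
}

# crescent intercentrum for joint k: an annular-sector prism tilted so that
# its caudal face meets the ventroflexing posterior endplate nearly face-on
.intercentrum_mesh <- function(spec, k, x_face) {
  ic <- spec$intercentra
  half <- ic$half_angle_deg * pi / 180
  psi <- seq(-half, half, length.out = 9)
  outer <- cbind(-ic$outer_radius * cos(psi), ic$outer_radius * sin(psi))
  inner <- cbind(-ic$inner_radius * cos(rev(psi)), ic$inner_radius * sin(rev(psi)))
  poly <- rbind(outer, inner)
  g <- spec$gap[k]
  x1 <- x_face + g - ic$clearance   # caudal face, clearance from posterior
  x0 <- x_face - ic$embed           # cranial end embedded in the anterior
  m <- .prism_x(poly, x0, x1)
  if (ic$tilt_deg != 0)
    m$vertices <- rotate_points(m$vertices, c(0, 0, 1), -ic$tilt_deg,
                                c(x1, 0, 0))
  m$label <- sprintf("intercentrum_%02d", k)
  m
}

#' Generate a synthetic column
#'
#' Places `n` generated vertebrae at their optimal spacing, builds the
#' [column_model()], and (optionally) writes meshes (PLY), landmark sidecars
#' and a ready-to-run manifest to `dir`.
#'
#' @param spec a [synthetic_column_spec()].
#' @param dir optional output directory.
#' @return a `column_model` (invisible attribute `manifest` holds the path
#'   when written).
#' @export
generate_column <- function(spec, dir = NULL) {
  n <- spec$n_vertebrae
  L <- spec$centrum_length
  vertebrae <- vector("list", n)
  x_center <- L / 2
  centers <- numeric(n)
  for (k in seq_len(n)) {
    v <- generate_vertebra(spec, k)
    centers[k] <- x_center
    v$mesh <- rigid_translate(v$mesh, c(x_center, 0, 0))
    v$landmarks <- transform_landmarks(v$landmarks, offset = c(x_center, 0, 0))
    vertebrae[[k]] <- v
    if (k < n) x_center <- x_center + L + spec$gap[k]
  }
  intercentra <- NULL
  if (!is.null(spec$intercentra)) {
    intercentra <- vector("list", n - 1L)
    for (k in seq_len(n - 1L))
      intercentra[[k]] <- .intercentrum_mesh(spec, k, centers[k] + L / 2)
  }
  col <- column_model(vertebrae, optimal_spacing = spec$gap,
                      species = spec$species, group = spec$group,
                      region_pos = spec$region_pos, intercentra = intercentra)
  if (!is.null(dir)) .write_column(col, spec, dir)
  col
}

.write_column <- function(col, spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(col$vertebrae)
  rows <- character(n)
  for (k in seq_len(n)) {
    mp <- file.path(dir, sprintf("vertebra_%02d.ply", k))
    lp <- file.path(dir, sprintf("vertebra_%02d.landmarks.txt", k))
    save_mesh(col$vertebrae[[k]]$mesh, mp)
    save_landmarks(col$vertebrae[[k]]$landmarks, lp)
    rows[k] <- sprintf("%s\t%s\t%s", basename(mp), basename(lp),
                       col$vertebrae[[k]]$landmarks$side_damage)
  }
  ic_paths <- ""
  if (!is.null(col$intercentra)) {
    icp <- character(n - 1L)
    for (k in seq_len(n - 1L)) {
      icp[k] <- sprintf("intercentrum_%02d.ply", k)
      save_mesh(col$intercentra[[k]], file.path(dir, icp[k]))
    }
    ic_paths <- paste(icp, collapse = ",")
  }
  manifest <- file.path(dir, "manifest.txt")
  writeLines(c(
    sprintf("#species %s", col$species),
    sprintf("#group %s", col$group),
    sprintf("#units mm"),
    sprintf("#region_pos %s", col$region_pos),
    sprintf("#optimal_spacing %s",
            paste(format(col$optimal_spacing, digits = 12), collapse = ",")),
    sprintf("#intercentra %s", ic_paths),
    "#columns mesh landmarks damage",
    rows), manifest)
  invisible(manifest)
}

#' Load a column from a manifest directory
#'
#' Reads the manifest written by [generate_column()] (one vertebra per row:
#' mesh path, landmark sidecar, damage flag; column-level metadata in `#key
#' value` lines, including units, which rescale to mm on load).
#'
#' @param manifest path to the manifest file.
#' @return a [column_model()].
#' @export
load_column <- function(manifest) {
  dir <- dirname(manifest)
  lines <- readLines(manifest, warn = FALSE)
  meta_l <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (ln in meta_l) {
    parts <- strsplit(sub("^#", "", ln), "\\s+")[[1]]
    kv[[parts[1]]] <- if (length(parts) > 1) paste(parts[-1], collapse = " ") else ""
  }
  scale <- switch(kv[["units"]] %||% "mm", mm = 1, cm = 10, m = 1000,
                  stop("unknown units in manifest: ", kv[["units"]]))
  rows <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  vertebrae <- lapply(rows, function(r) {
    f <- strsplit(r, "\t")[[1]]
    mesh <- load_mesh(file.path(dir, f[1]))
    lm <- load_landmarks(file.path(dir, f[2]))
    if (scale != 1) {
      mesh$vertices <- mesh$vertices * scale
      lm$points <- lm$points * scale
      lm$centrum_length <- lm$centrum_length * scale
      lm$endplate_area <- lm$endplate_area * scale^2
    }
    list(mesh = mesh, landmarks = lm)
  })
  spacing <- as.numeric(strsplit(kv[["optimal_spacing"]], ",")[[1]]) * scale
  intercentra <- NULL
  if (nzchar(kv[["intercentra"]] %||% "")) {
    icp <- strsplit(kv[["intercentra"]], ",")[[1]]
    intercentra <- lapply(icp, function(p) load_mesh(file.path(dir, p)))
    if (scale != 1)
      intercentra <- lapply(intercentra, function(m) {
        m$vertices <- m$vertices * scale; m
      })
  }
  column_model(vertebrae, optimal_spacing = spacing,
               species = kv[["species"]], group = kv[["group"]],
               region_pos = suppressWarnings(as.integer(kv[["region_pos"]])),
               intercentra = intercentra)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Preset column specifications
#'
#' Encodes the comparative morphologies the pipeline is designed to contrast:
#'
#' * `mammal_like` — horizontal ("pre-diaphragmatic", axial-rotation
#'   permitting) facets anteriorly switching sigmoidally to vertical
#'   (lumbar-style) facets at mid-column; wide, dorsoventrally compressed
#'   centra.
#' * `reptile_like` — uniform oblique facets placed high and medial, round
#'   centra: lateroflexion-emphasized throughout.
#' * `cynodont_like` — horizontal anterior facets with reduced posterior
#'   joint spacing (posterior lateral stabilization).
#' * `sailback` — neural spines elongated ~15x at mid-column, fanned
#'   craniocaudally as in a sail.
#' * `tuatara_like` — amphicoelous column with crescent intercentra at every
#'   joint and long, notochordal joint spaces.
#'
#' @param name preset name.
#' @param n_vertebrae number of vertebrae.
#' @return a [synthetic_column_spec()].
#' @export
preset_column_spec <- function(name = c("mammal_like", "reptile_like",
                                        "cynodont_like", "sailback",
                                        "tuatara_like"),
                               n_vertebrae = 8) {
  name <- tryCatch(match.arg(name),
                   error = function(e) stop(
                     "unknown preset; available: mammal_like, reptile_like, ",
                     "cynodont_like, sailback, tuatara_like"))
  n <- n_vertebrae
  mid <- ceiling(n / 2)
  sigmoid <- function(lo, hi, x0, width = 0.2)
    lo + (hi - lo) / (1 + exp(-(seq_len(n) - x0 - 0.5) / width))
  switch(name,
    mammal_like = synthetic_column_spec(
      n_vertebrae = n, facet_angle = sigmoid(5, 85, mid),
      species = "mammal_like", group = "mammal", region_pos = mid),
    reptile_like = synthetic_column_spec(
      n_vertebrae = n, facet_angle = 45, centrum_width = 7,
      facet_lateral_offset = 2, facet_stagger = 2, facet_clearance = 0.8,
      species = "reptile_like", group = "reptile"),
    cynodont_like = synthetic_column_spec(
      n_vertebrae = n, facet_angle = sigmoid(5, 45, mid),
      gap = ifelse(seq_len(n - 1) > mid, 4 * 0.6, 4),
      species = "cynodont_like", group = "NMS", region_pos = mid),
    sailback = synthetic_column_spec(
      n_vertebrae = n,
      spine_height = 22 * (1 + 14 * exp(-((seq_len(n) - mid) / (n / 4))^2)),
      spine_rake = seq(-35, 35, length.out = n),
      species = "sailback", group = "NMS"),
    tuatara_like = synthetic_column_spec(
      n_vertebrae = n, gap = 6, facet_stagger = 4,
      intercentra = list(outer_radius = 7.6, inner_radius = 3,
                         half_angle_deg = 25, embed = 0.5, tilt_deg = 6,
                         clearance = 0.15),
      species = "tuatara_like", group = "reptile"))
}
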