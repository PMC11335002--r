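#' Anatomical joint frame
#'
#' Right-handed orthonormal triad anchored at the centre of rotation (COR):
#' the x axis (craniocaudal, +x caudal) carries axial rotation, the y axis
#' (dorsoventral, +y dorsal) lateral bending, the z axis (mediolateral,
#' +z anatomical left) sagittal bending. Positive z rotation is dorsiflexion,
#' positive y rotation left lateroflexion, positive x rotation left axial
#' rotation.
#'
#' @param cor centre of rotation (length-3 point).
#' @param x_axis,y_axis,z_axis unit axis vectors.
#' @return an object of class `joint_frame`.
#' @export
joint_frame <- function(cor, x_axis = c(1, 0, 0), y_axis = c(0, 1, 0),
                        z_axis = c(0, 0, 1)) {
  A <- rbind(x = as.numeric(x_axis), y = as.numeric(y_axis),
             z = as.numeric(z_axis))
  if (!all(is.finite(cor)) || length(cor) != 3L) stop("invalid COR")
  lens <- sqrt(rowSums(A^2))
  if (any(abs(lens - 1) > 1e-8)) stop("axes must be unit vectors")
  G <- A %*% t(A)
  if (max(abs(G - diag(3))) > 1e-9) stop("axes must be orthonormal")
  if (det(A) < 0) stop("axes must form a right-handed triad")
  structure(list(cor = as.numeric(cor), x_axis = A["x", ],
                 y_axis = A["y", ], z_axis = A["z", ]),
            class = "joint_frame")
}

.frame_axis <- function(frame, axis = c("x", "y", "z")) {
  switch(match.arg(axis), x = frame$x_axis, y = frame$y_axis,
         z = frame$z_axis)
}

#' COR of an amphicoelous/acoelous joint
#'
#' Midpoint of the intervertebral space: the midpoint between the caudal
#' endplate centroid of the anterior vertebra and the cranial endplate
#' centroid of the posterior vertebra.
#'
#' @param lm_anterior,lm_posterior [landmark_set()]s of the two vertebrae,
#'   in articulated position.
#' @return length-3 point.
#' @export
place_cor_amphicoelous <- function(lm_anterior, lm_posterior) {
  a <- endplate_centroid(lm_anterior, "caudal")
  p <- endplate_centroid(lm_posterior, "cranial")
  if (sqrt(sum((a - p)^2)) < 1e-9)
    warning("endplate centroids coincide: zero joint spacing")
  (a + p) / 2
}

#' COR of a procoelous joint by least-squares sphere fit
#'
#' Fits a sphere to points sampled on the condyle and returns its centre.
#'
#' @param condyle_points n x 3 matrix, n >= 4, not coplanar.
#' @return length-3 point with attributes `radius` and `rms` (residual
#'   root-mean-square).
#' @export
place_cor_procoelous <- function(condyle_points) {
  P <- as.matrix(condyle_points)
  if (nrow(P) < 4L) stop("sphere fit needs at least 4 points")
  A <- cbind(2 * P, 1)
  b <- rowSums(P^2)
  qd <- qr(A)
  if (qd$rank < 4L)
    stop("ill-conditioned sphere fit: condyle points are coplanar/collinear")
  sol <- qr.coef(qd, b)
  ctr <- sol[1:3]
  r <- sqrt(sol[4] + sum(ctr^2))
  resid <- sqrt(rowSums(sweep(P, 2, ctr)^2)) - r
  structure(ctr, radius = r, rms = sqrt(mean(resid^2)))
}

#' Assemble an intervertebral joint model
#'
#' Takes two pre-oriented vertebrae (anatomical frame: +x caudal, +y dorsal,
#' +z left), translates the posterior one along x so that the inter-endplate
#' gap equals `optimal_spacing * spacing_multiplier`, places the COR, builds
#' the axis frame, instantiates disc and capsule locator pairs at the
#' endplate and zygapophyseal landmarks, and computes lever arms and centrum
#' metrics.
#'
#' @param anterior,posterior lists with elements `mesh` ([tri_mesh()]) and
#'   `landmarks` ([landmark_set()]).
#' @param optimal_spacing reference joint spacing, mm.
#' @param spacing_multiplier spacing uncertainty factor (grid: 0.9, 1, 1.1).
#' @param joint_index ordinal of the joint (named for the anterior vertebra).
#' @param cor optional explicit COR (e.g. from [place_cor_procoelous()]);
#'   the amphicoelous midpoint rule is used when `NULL`.
#' @param mean_measure optional precomputed mean mesh measure for overlap
#'   normalization (mean enclosed volume of the two vertebrae).
#' @param check_neutral verify that the neutral pose is not interpenetrating
#'   beyond `neutral_tol` (overlap fraction)? Default `TRUE`.
#' @param neutral_tol overlap fraction tolerated at neutral pose.
#' @return an object of class `joint_model`.
#' @export
build_joint <- function(anterior, posterior, optimal_spacing,
                        spacing_multiplier = 1, joint_index = 1L,
                        cor = NULL, mean_measure = NULL,
                        check_neutral = TRUE, neutral_tol = 0.0075) {
  if (!isTRUE(optimal_spacing > 0)) stop("optimal_spacing must be > 0")
  lm_a <- anterior$landmarks
  lm_p <- posterior$landmarks
  gap_now <- endplate_centroid(lm_p, "cranial")[1] -
    endplate_centroid(lm_a, "caudal")[1]
  shift <- c(optimal_spacing * spacing_multiplier - gap_now, 0, 0)
  mesh_p <- rigid_translate(posterior$mesh, shift)
  lm_p <- transform_landmarks(lm_p, offset = shift)

  if (is.null(cor)) cor <- place_cor_amphicoelous(lm_a, lm_p)
  frame <- joint_frame(cor)

  pairs <- .locator_pairs(lm_a, lm_p)
  facets <- .facet_pairs(lm_a, lm_p)

  apex <- .lm_point(lm_a, "arch_apex")
  lever_sag <- if (is.null(apex)) NA_real_ else sqrt(sum((apex - cor)^2))
  lat_names <- c("endplate_caudal_left", "endplate_caudal_right")
  lat_a <- lm_a$points[lat_names, , drop = FALSE]
  lat_p <- lm_p$points[sub("caudal", "cranial", lat_names), , drop = FALSE]
  lever_lat <- mean(sqrt(rowSums(sweep(rbind(lat_a, lat_p), 2, cor)^2)))

  joint <- structure(list(
    anterior = anterior$mesh, posterior = mesh_p,
    landmarks_anterior = lm_a, landmarks_posterior = lm_p,
    frame = frame, locator_pairs = pairs, facet_pairs = facets,
    spacing = optimal_spacing * spacing_multiplier,
    spacing_multiplier = spacing_multiplier,
    lever_sagittal = lever_sag, lever_lateral = lever_lat,
    centrum_area = mean(c(lm_a$endplate_area, lm_p$endplate_area)),
    mean_centrum_length = mean(c(lm_a$centrum_length, lm_p$centrum_length)),
    mean_measure = mean_measure, joint_index = as.integer(joint_index)),
    class = "joint_model")
  if (!isTRUE(joint$lever_sagittal > 0) && !is.na(joint$lever_sagittal))
    stop("non-positive sagittal lever arm")

  if (is.null(mean_measure))
    joint$mean_measure <- mean(c(mesh_volume(anterior$mesh),
                                 mesh_volume(mesh_p)))
  if (check_neutral) {
    frac <- overlap_fraction(joint$anterior, joint$posterior,
                             denom = joint$mean_measure)
    if (frac > neutral_tol)
      stop(sprintf(
        "joint %d interpenetrates at neutral pose (overlap fraction %.4f)",
        joint_index, frac))
  }
  joint
}

# disc pairs join facing endplate landmarks; capsule pairs join the cranial
# and caudal facet extremes on each undamaged side
.locator_pairs <- function(lm_a, lm_p) {
  pairs <- list()
  disc_map <- c(dorsal = "mid", ventral = "mid", left = "left",
                right = "right")
  for (pos in names(disc_map)) {
    a <- .lm_point(lm_a, paste0("endplate_caudal_", pos))
    p <- .lm_point(lm_p, paste0("endplate_cranial_", pos))
    pairs[[length(pairs) + 1L]] <- list(
      anterior = a, posterior = p, tissue = "disc", side = disc_map[[pos]],
      name = paste0("disc_", pos), neutral = sqrt(sum((a - p)^2)))
  }
  for (side in c("left", "right")) {
    if (lm_a$side_damage == side || lm_p$side_damage == side) next
    for (ext in c("cranial", "caudal")) {
      a <- .lm_point(lm_a, paste("postzyg", side, ext, sep = "_"))
      p <- .lm_point(lm_p, paste("prezyg", side, ext, sep = "_"))
      if (is.null(a) || is.null(p)) next
      pairs[[length(pairs) + 1L]] <- list(
        anterior = a, posterior = p, tissue = "capsule", side = side,
        name = paste("capsule", side, ext, sep = "_"),
        neutral = sqrt(sum((a - p)^2)))
    }
  }
  if (any(vapply(pairs, function(x) x$neutral, 0) < 1e-9))
    stop("coincident locator pair (zero neutral distance)")
  pairs
}

.facet_pairs <- function(lm_a, lm_p) {
  out <- list()
  for (side in c("left", "right")) {
    if (lm_a$side_damage == side || lm_p$side_damage == side) next
    post <- .lm_facet(lm_a, "postzyg", side)
    pre <- .lm_facet(lm_p, "prezyg", side)
    if (is.null(post) || is.null(pre)) next
    e1 <- post[2, ] - post[1, ]
    e2 <- post[4, ] - post[1, ]
    n <- c(e1[2] * e2[3] - e1[3] * e2[2], e1[3] * e2[1] - e1[1] * e2[3],
           e1[1] * e2[2] - e1[2] * e2[1])
    n <- n / sqrt(sum(n^2))
    out[[side]] <- list(postzyg = post, prezyg = pre, normal = n)
  }
  out
}

#' @export
print.joint_model <- function(x, ...) {
  cat(sprintf(
    "joint_model %d: spacing %.2f mm (x%.2f), %d locator pairs, %d facet pair(s)\n",
    x$joint_index, x$spacing, x$spacing_multiplier, length(x$locator_pairs),
    length(x$facet_pairs)))
  invisible(x)
}

#' Vertebral column model
#'
#' An ordered set of vertebrae (mesh + landmarks) with assembled joints,
#' taxon metadata and region information. Joint k connects vertebra k and
#' k+1 and is named for the anterior vertebra.
#'
#' @param vertebrae list of lists with elements `mesh` and `landmarks`.
#' @param optimal_spacing per-joint spacing (scalar recycled, or length n-1).
#' @param species,group taxon metadata; `group` is one of `"mammal"`,
#'   `"reptile"`, `"salamander"`, `"NMS"`.
#' @param region_pos boundary position: for mammals the diaphragmatic joint
#'   index; ignored (mid-dorsal rule) otherwise.
#' @param intercentra optional list (length n-1) of intercentrum meshes (or
#'   `NULL` entries).
#' @param spacing_multiplier multiplier applied when assembling the joints.
#' @param check_neutral passed to [build_joint()].
#' @return an object of class `column_model`.
#' @export
column_model <- function(vertebrae, optimal_spacing, species = "synthetic",
                         group = c("mammal", "reptile", "salamander", "NMS"),
                         region_pos = NA_integer_, intercentra = NULL,
                         spacing_multiplier = 1, check_neutral = TRUE) {
  group <- match.arg(group)
  n <- length(vertebrae)
  if (n < 2L) stop("a column needs at least two vertebrae")
  spacing <- rep_len(optimal_spacing, n - 1L)
  measures <- vapply(vertebrae, function(v) mesh_volume(v$mesh), 0)
  joints <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    joints[[k]] <- build_joint(
      vertebrae[[k]], vertebrae[[k + 1L]], optimal_spacing = spacing[k],
      spacing_multiplier = spacing_multiplier, joint_index = k,
      mean_measure = mean(measures[k:(k + 1L)]), check_neutral = check_neutral)
  }
  structure(list(vertebrae = vertebrae, joints = joints,
                 optimal_spacing = spacing, species = species, group = group,
                 region_pos = region_pos, intercentra = intercentra,
                 measures = measures),
            class = "column_model")
}

#' @export
print.column_model <- function(x, ...) {
  cat(sprintf("column_model '%s' (%s): %d vertebrae, %d joints\n",
              x$species, x$group, length(x$vertebrae), length(x$joints)))
  invisible(x)
}

#' Rotate a column at one joint (hierarchical propagation)
#'
#' Rotates everything caudal to the named joint (vertebra meshes, landmarks,
#' and the CORs/frames/locators of more caudal joints) rigidly about the
#' joint's COR along the named frame axis. Cranial elements are unchanged.
#'
#' @param column a [column_model()].
#' @param joint_index joint to rotate at.
#' @param axis `"x"` (axial), `"y"` (lateral) or `"z"` (sagittal).
#' @param angle_deg rotation angle in degrees (sign conventions in
#'   [joint_frame()]).
#' @return the posed `column_model`.
#' @export
apply_joint_rotation <- function(column, joint_index,
                                 axis = c("x", "y", "z"), angle_deg) {
  axis <- match.arg(axis)
  nj <- length(column$joints)
  if (!(joint_index %in% seq_len(nj))) stop("no such joint: ", joint_index)
  j <- column$joints[[joint_index]]
  u <- .frame_axis(j$frame, axis)
  ctr <- j$frame$cor
  rot_p <- function(p) rotate_points(p, u, angle_deg, ctr)
  for (k in (joint_index + 1L):length(column$vertebrae)) {
    column$vertebrae[[k]]$mesh <-
      rigid_rotate(column$vertebrae[[k]]$mesh, u, angle_deg, ctr)
    column$vertebrae[[k]]$landmarks <- transform_landmarks(
      column$vertebrae[[k]]$landmarks, axis = u, angle_deg = angle_deg,
      center = ctr)
  }
  for (k in seq_len(nj)) {
    if (k < joint_index) next
    jk <- column$joints[[k]]
    jk$posterior <- rigid_rotate(jk$posterior, u, angle_deg, ctr)
    jk$landmarks_posterior <- transform_landmarks(
      jk$landmarks_posterior, axis = u, angle_deg = angle_deg, center = ctr)
    for (i in seq_along(jk$locator_pairs))
      jk$locator_pairs[[i]]$posterior <- rot_p(jk$locator_pairs[[i]]$posterior)
    for (s in names(jk$facet_pairs))
      jk$facet_pairs[[s]]$prezyg <- rot_p(jk$facet_pairs[[s]]$prezyg)
    if (k > joint_index) {
      jk$anterior <- rigid_rotate(jk$anterior, u, angle_deg, ctr)
      jk$landmarks_anterior <- transform_landmarks(
        jk$landmarks_anterior, axis = u, angle_deg = angle_deg, center = ctr)
      jk$frame$cor <- rot_p(jk$frame$cor)
      R0 <- .rotation_matrix(u, angle_deg)
      jk$frame$x_axis <- as.numeric(R0 %*% jk$frame$x_axis)
      jk$frame$y_axis <- as.numeric(R0 %*% jk$frame$y_axis)
      jk$frame$z_axis <- as.numeric(R0 %*% jk$frame$z_axis)
      for (i in seq_along(jk$locator_pairs))
        jk$locator_pairs[[i]]$anterior <- rot_p(jk$locator_pairs[[i]]$anterior)
      for (s in names(jk$facet_pairs)) {
        jk$facet_pairs[[s]]$postzyg <- rot_p(jk$facet_pairs[[s]]$postzyg)
        jk$facet_pairs[[s]]$normal <-
          as.numeric(.rotation_matrix(u, angle_deg) %*% jk$facet_pairs[[s]]$normal)
      }
    }
    column$joints[[k]] <- jk
  }
  column
}
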