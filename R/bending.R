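#' Configuration of a digital bending experiment
#'
#' @param step sweep increment, degrees (default 0.5).
#' @param max_angle sweep cap, degrees (default 90; must be a multiple of
#'   `step`). The cap applies to every bending direction.
#' @param intersection_threshold bony intersection threshold as a fraction of
#'   the mean vertebral measure (grid values 0.0025, 0.005, 0.0075). At
#'   exactly 0, any surface contact violates.
#' @param strain_allowance permitted soft-tissue strain: base 0.5 (50% of the
#'   neutral locator distance), scaled by 0.9/1.0/1.1 in the variant grid.
#' @param spacing_multiplier joint-spacing uncertainty factor (0.9/1.0/1.1).
#' @param disc_mode `"both"` (default: tension and compression limited at the
#'   same allowance, as for the capsule) or `"tension"` (tension-only discs).
#' @param normalization overlap normalization, see [overlap_fraction()].
#' @param grid_n grid resolution for intersection-volume estimates.
#' @param seed integer seed recorded with results.
#' @return an object of class `bending_config`.
#' @export
bending_config <- function(step = 0.5, max_angle = 90,
                           intersection_threshold = 0.005,
                           strain_allowance = 0.5, spacing_multiplier = 1,
                           disc_mode = c("both", "tension"),
                           normalization = c("volume", "area"), grid_n = 20,
                           seed = 1L) {
  disc_mode <- match.arg(disc_mode)
  normalization <- match.arg(normalization)
  if (!isTRUE(step > 0)) stop("step must be > 0")
  if (abs(max_angle / step - round(max_angle / step)) > 1e-9)
    stop("max_angle must be a multiple of step")
  if (intersection_threshold < 0) stop("intersection_threshold must be >= 0")
  structure(list(step = step, max_angle = max_angle,
                 intersection_threshold = intersection_threshold,
                 strain_allowance = strain_allowance,
                 spacing_multiplier = spacing_multiplier,
                 disc_mode = disc_mode, normalization = normalization,
                 grid_n = grid_n, seed = as.integer(seed)),
            class = "bending_config")
}

#' The six bending directions
#'
#' Names, frame axes and rotation signs of the six sweeps: dorsoflexion and
#' ventroflexion about z, left/right lateroflexion about y, left/right axial
#' rotation about x.
#'
#' @return data.frame with columns `direction`, `axis`, `sign`.
#' @export
bending_directions <- function() {
  data.frame(
    direction = c("dorsoflexion", "ventroflexion", "lateroflexion_left",
                  "lateroflexion_right", "axial_left", "axial_right"),
    axis = c("z", "z", "y", "y", "x", "x"),
    sign = c(1, -1, 1, -1, 1, -1),
    stringsAsFactors = FALSE)
}

#' The factorial uncertainty grid
#'
#' Full factorial of 3 spacing multipliers x 3 intersection thresholds x 3
#' strain allowances = 27 parameter variants.
#'
#' @param spacing,threshold,strain grid levels.
#' @return data.frame with one row per variant and a `variant` id column.
#' @export
variant_grid <- function(spacing = c(0.9, 1, 1.1),
                         threshold = c(0.0025, 0.005, 0.0075),
                         strain = 0.5 * c(0.9, 1, 1.1)) {
  g <- expand.grid(spacing_mult = spacing, threshold = threshold,
                   strain_allow = strain, KEEP.OUT.ATTRS = FALSE)
  g$variant <- sprintf("s%.2f_t%.4f_a%.3f", g$spacing_mult, g$threshold,
                       g$strain_allow)
  g
}

# pose the posterior side of a joint: rotate mesh, locators and facets
.pose_joint <- function(joint, axis, angle_deg) {
  if (angle_deg == 0) return(joint)
  u <- .frame_axis(joint$frame, axis)
  ctr <- joint$frame$cor
  joint$posterior <- rigid_rotate(joint$posterior, u, angle_deg, ctr)
  for (i in seq_along(joint$locator_pairs))
    joint$locator_pairs[[i]]$posterior <-
      rotate_points(joint$locator_pairs[[i]]$posterior, u, angle_deg, ctr)
  for (s in names(joint$facet_pairs))
    joint$facet_pairs[[s]]$prezyg <-
      rotate_points(joint$facet_pairs[[s]]$prezyg, u, angle_deg, ctr)
  joint
}

.pair_strains <- function(joint) {
  out <- lapply(joint$locator_pairs, function(p) {
    d <- sqrt(sum((p$anterior - p$posterior)^2))
    list(tissue = p$tissue, strain = (d - p$neutral) / p$neutral)
  })
  disc <- vapply(out, function(x) if (x$tissue == "disc") x$strain else NA_real_, 0)
  caps <- vapply(out, function(x) if (x$tissue == "capsule") x$strain else NA_real_, 0)
  worst <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) return(0)
    v[which.max(abs(v))]
  }
  list(disc = worst(disc), capsule = worst(caps),
       disc_all = disc[!is.na(disc)], capsule_all = caps[!is.na(caps)])
}

# raw pose measurements, independent of thresholds
.pose_metrics <- function(joint, axis, angle_deg, config) {
  posed <- .pose_joint(joint, axis, angle_deg)
  contact <- meshes_intersect(posed$anterior, posed$posterior)
  frac <- if (contact)
    overlap_fraction(posed$anterior, posed$posterior,
                     normalization = config$normalization,
                     grid_n = config$grid_n, denom = joint$mean_measure)
  else 0
  st <- .pair_strains(posed)
  list(contact = contact, overlap = frac, disc = st$disc,
       capsule = st$capsule, disarticulated = detect_disarticulation(posed))
}

.violations <- function(metrics, threshold, allowance, disc_mode) {
  v <- character(0)
  bone <- if (threshold <= 0) metrics$contact else metrics$overlap > threshold
  if (bone) v <- c(v, "bone")
  disc_bad <- if (disc_mode == "tension") metrics$disc > allowance
    else abs(metrics$disc) > allowance
  if (disc_bad) v <- c(v, "disc")
  if (abs(metrics$capsule) > allowance) v <- c(v, "capsule")
  v
}

#' Evaluate motion constraints at a pose
#'
#' Applies a rotation about one frame axis of the joint and reports bony
#' overlap, the worst signed disc and capsule strains (relative change of the
#' locator-pair distances), the violated constraint families under the
#' configured threshold and allowance, and the disarticulation flag.
#'
#' @param joint a [build_joint()] model at neutral pose.
#' @param angle_deg pose angle, degrees.
#' @param axis frame axis `"x"`, `"y"` or `"z"`.
#' @param config a [bending_config()].
#' @return list of class `constraint_report` with fields `bone_overlap`,
#'   `bone_contact`, `worst_disc_strain`, `worst_capsule_strain`, `violated`,
#'   `disarticulated`.
#' @export
evaluate_constraints <- function(joint, angle_deg, axis = c("z", "y", "x"),
                                 config = bending_config()) {
  axis <- match.arg(axis)
  m <- .pose_metrics(joint, axis, angle_deg, config)
  structure(list(
    bone_overlap = m$overlap, bone_contact = m$contact,
    worst_disc_strain = m$disc, worst_capsule_strain = m$capsule,
    violated = .violations(m, config$intersection_threshold,
                           config$strain_allowance, config$disc_mode),
    disarticulated = m$disarticulated), class = "constraint_report")
}

#' Detect zygapophyseal disarticulation
#'
#' A pose is disarticulated when the projected overlap area of every left and
#' right facet pair is zero, the projection being along the facet normal at
#' neutral. Joints without facet polygons are never flagged (with a notice on
#' first use).
#'
#' @param joint a (possibly posed) joint model.
#' @return logical.
#' @export
detect_disarticulation <- function(joint) {
  if (length(joint$facet_pairs) == 0) return(FALSE)
  for (s in names(joint$facet_pairs)) {
    fp <- joint$facet_pairs[[s]]
    if (.projected_overlap_area(fp$postzyg, fp$prezyg, fp$normal) > 1e-9)
      return(FALSE)
  }
  TRUE
}

# area of the intersection of two convex polygons projected along `normal`
.projected_overlap_area <- function(poly_a, poly_b, normal) {
  n <- normal / sqrt(sum(normal^2))
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2], n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  pa <- cbind(poly_a %*% e1, poly_a %*% e2)
  pb <- cbind(poly_b %*% e1, poly_b %*% e2)
  .convex_clip_area(pa, pb)
}

.poly_area <- function(p) {
  n <- nrow(p)
  if (is.null(n) || n < 3) return(0)
  j <- c(2:n, 1)
  abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
}

# Sutherland-Hodgman clip of convex polygon a by convex polygon b
.convex_clip_area <- function(a, b) {
  # ensure counter-clockwise clip polygon
  n <- nrow(b)
  j <- c(2:n, 1)
  if (sum(b[, 1] * b[j, 2] - b[j, 1] * b[, 2]) < 0) b <- b[rev(seq_len(n)), ]
  subj <- a
  for (i in seq_len(nrow(b))) {
    if (is.null(subj) || nrow(subj) == 0) return(0)
    p1 <- b[i, ]; p2 <- b[if (i == nrow(b)) 1 else i + 1, ]
    inside <- function(q)
      (p2[1] - p1[1]) * (q[2] - p1[2]) - (p2[2] - p1[2]) * (q[1] - p1[1]) >= 0
    isect <- function(q1, q2) {
      d1 <- q2 - q1; d2 <- p2 - p1
      den <- d1[1] * d2[2] - d1[2] * d2[1]
      t <- ((p1[1] - q1[1]) * d2[2] - (p1[2] - q1[2]) * d2[1]) / den
      q1 + t * d1
    }
    out <- list()
    m <- nrow(subj)
    for (k in seq_len(m)) {
      cur <- subj[k, ]; prv <- subj[if (k == 1) m else k - 1, ]
      if (inside(cur)) {
        if (!inside(prv)) out[[length(out) + 1L]] <- isect(prv, cur)
        out[[length(out) + 1L]] <- cur
      } else if (inside(prv)) {
        out[[length(out) + 1L]] <- isect(prv, cur)
      }
    }
    subj <- if (length(out) > 0) do.call(rbind, out) else NULL
  }
  if (is.null(subj)) 0 else .poly_area(subj)
}

#' Sweep one bending direction
#'
#' Rotates the posterior vertebra in `step` increments until a constraint is
#' violated or the cap is reached. The ROM is the largest swept angle at
#' which no constraint is violated; the limiting constraint is the family
#' first violated one step beyond (`"cap"` when the sweep reaches
#' `max_angle`). The joint is returned to neutral (poses are applied to
#' copies).
#'
#' @param joint a [build_joint()] model at neutral pose.
#' @param direction one of the six names in [bending_directions()].
#' @param config a [bending_config()].
#' @return list with `rom` (degrees), `limiting` (`"bone"`, `"disc"`,
#'   `"capsule"` or `"cap"`), `disarticulation_angle` (degrees or `NA`).
#' @export
sweep_direction <- function(joint, direction, config = bending_config()) {
  prof <- .sweep_profile(joint, direction, config,
                         max_threshold = config$intersection_threshold,
                         max_allowance = config$strain_allowance)
  .rom_from_profile(prof, config$intersection_threshold,
                    config$strain_allowance, config)
}

# incremental sweep recording pose metrics until the most permissive variant
# under consideration is violated (or the cap reached)
.sweep_profile <- function(joint, direction, config, max_threshold,
                           max_allowance) {
  dirs <- bending_directions()
  row <- dirs[dirs$direction == direction, ]
  if (nrow(row) != 1) stop("unknown bending direction: ", direction)
  n_steps <- round(config$max_angle / config$step)
  angle <- numeric(0); contact <- logical(0); overlap <- numeric(0)
  disc <- numeric(0); capsule <- numeric(0); disart <- logical(0)
  for (k in 0:n_steps) {
    a <- k * config$step * row$sign
    m <- .pose_metrics(joint, row$axis, a, config)
    angle <- c(angle, k * config$step)
    contact <- c(contact, m$contact); overlap <- c(overlap, m$overlap)
    disc <- c(disc, m$disc); capsule <- c(capsule, m$capsule)
    disart <- c(disart, m$disarticulated)
    # once the most permissive variant is violated, every variant's first
    # violation lies within the recorded profile
    worst_bone <- if (max_threshold <= 0) m$contact else m$overlap > max_threshold
    worst_strain <- abs(m$disc) > max_allowance || abs(m$capsule) > max_allowance
    if (k > 0 && (worst_bone || worst_strain)) break
  }
  data.frame(angle = angle, contact = contact, overlap = overlap,
             disc = disc, capsule = capsule, disarticulated = disart)
}

.rom_from_profile <- function(prof, threshold, allowance, config) {
  viol <- vapply(seq_len(nrow(prof)), function(i) {
    length(.violations(as.list(prof[i, ]), threshold, allowance,
                       config$disc_mode)) > 0
  }, TRUE)
  first_viol <- which(viol[-1])[1] + 1L  # ignore neutral row for violation
  if (isTRUE(viol[1])) {
    warning("constraint violated at the neutral pose; ROM is 0")
    fam <- .violations(as.list(prof[1, ]), threshold, allowance,
                       config$disc_mode)
    return(list(rom = 0, limiting = fam[1], disarticulation_angle = NA_real_))
  }
  if (is.na(first_viol) || length(first_viol) == 0) {
    rom <- prof$angle[nrow(prof)]
    if (rom >= config$max_angle - 1e-9) {
      lim <- "cap"
      rom <- config$max_angle
    } else {
      # profile stopped early (shared sweep); cannot happen for this variant
      lim <- "cap"
    }
  } else {
    rom <- prof$angle[first_viol - 1L]
    fam <- .violations(as.list(prof[first_viol, ]), threshold, allowance,
                       config$disc_mode)
    lim <- intersect(c("bone", "disc", "capsule"), fam)[1]
  }
  da <- prof$angle[which(prof$disarticulated)[1]]
  list(rom = rom, limiting = lim,
       disarticulation_angle = if (length(da) == 0 || is.na(da)) NA_real_ else da)
}

#' Run the full digital bending experiment
#'
#' For every joint of the column, every bending direction and every variant
#' of the factorial uncertainty grid (27 by default), sweeps to the
#' constraint-limited ROM. Sweeps are shared across thresholds and
#' allowances (the pose metrics do not depend on them), so each joint incurs
#' `3 spacings x 6 directions` incremental sweeps.
#'
#' @param column a [column_model()].
#' @param config a [bending_config()] (its `spacing_multiplier`, `threshold`
#'   and `strain_allowance` are superseded by the grid).
#' @param grid a [variant_grid()].
#' @param out_dir optional directory: per-joint delimited text results are
#'   written there.
#' @param verbose log per-joint runtime?
#' @return data.frame of class `bending_result`: one row per joint x
#'   direction x variant with columns `species`, `joint`, `direction`,
#'   `spacing_mult`, `threshold`, `strain_allow`, `rom_deg`,
#'   `limiting_constraint`, `disarticulated_at`.
#' @export
run_experiment <- function(column, config = bending_config(),
                           grid = variant_grid(), out_dir = NULL,
                           verbose = FALSE) {
  dirs <- bending_directions()$direction
  res <- list()
  for (j in seq_along(column$joints)) {
    t0 <- proc.time()[["elapsed"]]
    jr <- tryCatch(
      .run_joint(column, j, config, grid, dirs),
      error = function(e) {
        warning(sprintf("joint %d failed: %s (recorded as missing)", j,
                        conditionMessage(e)))
        data.frame(species = column$species, joint = j,
                   direction = NA_character_, spacing_mult = NA_real_,
                   threshold = NA_real_, strain_allow = NA_real_,
                   rom_deg = NA_real_,
                   limiting_constraint = paste("error:", conditionMessage(e)),
                   disarticulated_at = NA_real_, stringsAsFactors = FALSE)
      })
    if (verbose)
      message(sprintf("joint %d: %.1f s", j,
                      proc.time()[["elapsed"]] - t0))
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      utils::write.table(
        jr, file.path(out_dir, sprintf("joint_%02d_rom.txt", j)),
        sep = "\t", row.names = FALSE, quote = FALSE)
    }
    res[[j]] <- jr
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("bending_result", "data.frame")
  out
}

.run_joint <- function(column, j, config, grid, dirs) {
  rows <- list()
  for (sm in sort(unique(grid$spacing_mult))) {
    joint <- build_joint(
      column$vertebrae[[j]], column$vertebrae[[j + 1L]],
      optimal_spacing = column$optimal_spacing[j], spacing_multiplier = sm,
      joint_index = j,
      mean_measure = mean(column$measures[j:(j + 1L)]),
      check_neutral = TRUE)
    if (!is.null(column$intercentra) && !is.null(column$intercentra[[j]]))
      joint$anterior <- merge_meshes(joint$anterior, column$intercentra[[j]])
    sub <- grid[grid$spacing_mult == sm, ]
    max_thr <- max(sub$threshold); max_all <- max(sub$strain_allow)
    for (d in dirs) {
      prof <- .sweep_profile(joint, d, config, max_thr, max_all)
      for (r in seq_len(nrow(sub))) {
        rr <- .rom_from_profile(prof, sub$threshold[r], sub$strain_allow[r],
                                config)
        rows[[length(rows) + 1L]] <- data.frame(
          species = column$species, joint = j, direction = d,
          spacing_mult = sm, threshold = sub$threshold[r],
          strain_allow = sub$strain_allow[r], rom_deg = rr$rom,
          limiting_constraint = rr$limiting,
          disarticulated_at = rr$disarticulation_angle,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
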