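#' Remove neural spines from a column
#'
#' Cuts every vertebral mesh with a transverse plane just above the neural
#' arch (at the arch apex height plus `cut_offset`), keeping the material
#' below and re-capping the cut. Landmarks, CORs, locators, spacing, lever
#' arms and the overlap-normalization measures all stay those of the intact
#' vertebrae, so a paired with/without-spines experiment isolates the contact
#' geometry of the spines.
#'
#' @param column a [column_model()].
#' @param cut_offset cut height above the arch apex, mm (default 0).
#' @return the modified `column_model`.
#' @export
remove_neural_spines <- function(column, cut_offset = 0) {
  for (k in seq_along(column$vertebrae)) {
    lm <- column$vertebrae[[k]]$landmarks
    apex <- .lm_point(lm, "arch_apex")
    if (is.null(apex)) stop("vertebra ", k, " lacks an arch_apex landmark")
    ventral <- .lm_point(lm, "endplate_cranial_ventral")
    cut_y <- apex[2] + cut_offset
    if (cut_y <= ventral[2])
      stop("cut plane lies below the centrum of vertebra ", k)
    mesh <- column$vertebrae[[k]]$mesh
    if (max(mesh$vertices[, 2]) > cut_y + 1e-9)
      column$vertebrae[[k]]$mesh <-
        cut_above_plane(mesh, c(apex[1], cut_y, apex[3]), c(0, 1, 0))
  }
  # re-assemble joints with the truncated meshes, keeping original metrics
  rebuilt <- column_model(
    column$vertebrae, optimal_spacing = column$optimal_spacing,
    species = column$species, group = column$group,
    region_pos = column$region_pos, intercentra = column$intercentra,
    check_neutral = FALSE)
  rebuilt$measures <- column$measures
  for (k in seq_along(rebuilt$joints)) {
    rebuilt$joints[[k]]$lever_sagittal <- column$joints[[k]]$lever_sagittal
    rebuilt$joints[[k]]$lever_lateral <- column$joints[[k]]$lever_lateral
    rebuilt$joints[[k]]$mean_measure <- column$joints[[k]]$mean_measure
  }
  rebuilt
}

#' Include or remove intercentra
#'
#' In `"merged"` mode each joint's anterior mesh is combined with its
#' intercentrum, so the posterior vertebra rotates against the merged object;
#' in `"absent"` mode the intercentra are dropped. With `realign = TRUE`,
#' displaced intercentra are translated (pure translation) so their dorsal
#' margin touches the ventral margin of the anterior centrum before merging.
#'
#' @param column a [column_model()] whose `intercentra` list is populated
#'   (for `mode = "merged"`).
#' @param mode `"merged"` or `"absent"`.
#' @param realign translate displaced intercentra into anatomical position?
#' @return the modified `column_model`; in merged mode, joints missing an
#'   intercentrum mesh are recorded in the attribute `skipped` and left
#'   unmodified.
#' @export
attach_intercentra <- function(column, mode = c("merged", "absent"),
                               realign = FALSE) {
  mode <- match.arg(mode)
  if (mode == "absent") {
    column$intercentra <- NULL
    return(column)
  }
  if (is.null(column$intercentra))
    stop("no intercentrum meshes in the column manifest")
  skipped <- integer(0)
  for (k in seq_along(column$joints)) {
    ic <- if (k <= length(column$intercentra)) column$intercentra[[k]] else NULL
    if (is.null(ic)) {
      skipped <- c(skipped, k)
      next
    }
    if (realign) {
      lm <- column$vertebrae[[k]]$landmarks
      ventral <- .lm_point(lm, "endplate_caudal_ventral")
      dorsal_margin <- max(ic$vertices[, 2])
      ic <- rigid_translate(ic, c(0, ventral[2] - dorsal_margin, 0))
      column$intercentra[[k]] <- ic
    }
  }
  if (length(skipped) > 0)
    message("joints without intercentrum mesh (left unmodified): ",
            paste(skipped, collapse = ", "))
  attr(column, "skipped") <- skipped
  column
}

#' Analytic neural-spine contact angle
#'
#' First-contact estimate for the spine tips of adjacent vertebrae under
#' dorsiflexion at a joint: the angle subtended at the COR between the
#' posterior spine's cranial tip corner and the anterior spine's caudal tip
#' corner. `Inf` when the tip radii differ by more than the spine height
#' overlap (the tips then cannot meet under rotation about the COR).
#'
#' @param column a [column_model()].
#' @param joint_index joint to assess.
#' @return contact angle in degrees (possibly `Inf`).
#' @export
spine_contact_angle <- function(column, joint_index) {
  j <- column$joints[[joint_index]]
  cor <- j$frame$cor
  tip <- function(mesh, cranial) {
    v <- mesh$vertices
    top <- v[, 2] > max(v[, 2]) - 1e-6
    cand <- v[top, , drop = FALSE]
    cand[if (cranial) which.min(cand[, 1]) else which.max(cand[, 1]), ]
  }
  a <- tip(column$vertebrae[[joint_index]]$mesh, cranial = FALSE)
  p <- tip(column$vertebrae[[joint_index + 1L]]$mesh, cranial = TRUE)
  ra <- sqrt(sum((a[1:2] - cor[1:2])^2))
  rp <- sqrt(sum((p[1:2] - cor[1:2])^2))
  span_a <- max(column$vertebrae[[joint_index]]$mesh$vertices[, 2]) -
    .lm_point(column$vertebrae[[joint_index]]$landmarks, "arch_apex")[2]
  if (abs(ra - rp) > max(span_a, 1)) return(Inf)
  ang <- function(q) atan2(q[2] - cor[2], q[1] - cor[1])
  deg <- (ang(a) - ang(p)) * 180 / pi
  if (deg <= 0) Inf else deg
}

#' Paired structure-removal experiment
#'
#' Runs the bending experiment on a column and on a modified copy (spines
#' removed, or intercentra merged/absent), returning both result tables
#' tagged by arm. Everything except the named structure (manifest, CORs,
#' locators, spacing) is identical between arms.
#'
#' @param column a [column_model()].
#' @param modification `"spines"` or `"intercentra"`.
#' @param config,grid see [run_experiment()].
#' @param cut_offset see [remove_neural_spines()].
#' @return data.frame: the combined `bending_result` with an `arm` column
#'   (`"with"` / `"without"`).
#' @export
structure_removal_experiment <- function(column,
                                         modification = c("spines",
                                                          "intercentra"),
                                         config = bending_config(),
                                         grid = variant_grid(),
                                         cut_offset = 0) {
  modification <- match.arg(modification)
  if (modification == "spines") {
    with_col <- column
    without_col <- remove_neural_spines(column, cut_offset)
  } else {
    with_col <- attach_intercentra(column, "merged")
    without_col <- attach_intercentra(column, "absent")
  }
  w <- run_experiment(with_col, config, grid)
  wo <- run_experiment(without_col, config, grid)
  w$arm <- "with"
  wo$arm <- "without"
  out <- rbind(w, wo)
  class(out) <- c("bending_result", "data.frame")
  out
}
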