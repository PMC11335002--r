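#' Bending-moment proxy of a joint
#'
#' The moment available in a bending plane is approximated by the lever arm
#' in that plane (COR to arch apex for sagittal bending, COR to the lateral
#' centrum edge for lateral bending) scaled by the centrum area.
#'
#' @param lever lever arm, mm (> 0).
#' @param centrum_area centrum area, mm^2 (> 0).
#' @return moment proxy, mm^3.
#' @export
bending_moment_proxy <- function(lever, centrum_area) {
  if (any(!is.finite(lever)) || any(lever <= 0))
    stop("lever must be positive")
  if (any(!is.finite(centrum_area)) || any(centrum_area <= 0))
    stop("centrum_area must be positive")
  lever * centrum_area
}

#' Relative intervertebral stiffness
#'
#' Ratio of the bending-moment proxy to angular displacement (ROM),
#' size-corrected by the mean centrum length: the moment proxy (mm^3) is
#' divided by the cube of the mean centrum length before dividing by ROM, so
#' the result is dimensionless per degree and invariant under isotropic
#' scaling of the joint. Only relative comparisons are meaningful.
#'
#' @param moment_proxy mm^3 (see [bending_moment_proxy()]).
#' @param rom_deg range of motion, degrees.
#' @param mean_centrum_length mm (> 0).
#' @param size_exponent exponent of the size correction (default 3: a moment
#'   proxy scales with length cubed).
#' @return dimensionless relative stiffness; `Inf` (with a warning) when
#'   `rom_deg` is 0 - such joints are excluded from ratios downstream.
#' @export
relative_stiffness <- function(moment_proxy, rom_deg, mean_centrum_length,
                               size_exponent = 3) {
  if (any(mean_centrum_length <= 0)) stop("centrum length must be positive")
  if (any(rom_deg < 0)) stop("rom must be >= 0")
  if (any(rom_deg == 0))
    warning("zero ROM: infinite-stiffness sentinel returned")
  (moment_proxy / mean_centrum_length^size_exponent) / rom_deg
}

#' Per-joint stiffness table for a column
#'
#' Joins lever arms and centrum metrics of each joint with processed ROM and
#' returns lateral and sagittal relative stiffness.
#'
#' @param column a [column_model()].
#' @param processed a `processed_rom` table (see [process_rom()]).
#' @param size_exponent see [relative_stiffness()].
#' @return data.frame with columns `joint`, `stiffness_lateral`,
#'   `stiffness_sagittal`.
#' @export
compute_stiffness <- function(column, processed, size_exponent = 3) {
  rows <- lapply(seq_len(nrow(processed)), function(i) {
    j <- processed$joint[i]
    jm <- column$joints[[j]]
    lat <- relative_stiffness(
      bending_moment_proxy(jm$lever_lateral, jm$centrum_area),
      processed$lateral[i], jm$mean_centrum_length, size_exponent)
    sag <- relative_stiffness(
      bending_moment_proxy(jm$lever_sagittal, jm$centrum_area),
      processed$sagittal[i], jm$mean_centrum_length, size_exponent)
    data.frame(joint = j, stiffness_lateral = lat, stiffness_sagittal = sag)
  })
  do.call(rbind, rows)
}

#' Stiffness ratio and total
#'
#' Lateral/sagittal stiffness ratio and total (summed) relative stiffness per
#' joint; joints with an infinite or missing component are skipped with a
#' notice. A ratio below 1 means the joint is more compliant in lateral than
#' in sagittal bending.
#'
#' @param records data.frame with columns `joint`, `stiffness_lateral`,
#'   `stiffness_sagittal`.
#' @return data.frame with columns `joint`, `ratio`, `total`.
#' @export
stiffness_summary <- function(records) {
  ok <- is.finite(records$stiffness_lateral) &
    is.finite(records$stiffness_sagittal)
  if (any(!ok))
    message(sum(!ok), " joint(s) skipped (missing or infinite stiffness)")
  r <- records[ok, , drop = FALSE]
  data.frame(joint = r$joint,
             ratio = r$stiffness_lateral / r$stiffness_sagittal,
             total = r$stiffness_lateral + r$stiffness_sagittal)
}
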