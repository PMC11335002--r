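#' Post-process raw ROM into per-joint functional summaries
#'
#' Applies the processing rules used throughout the downstream analyses:
#'
#' * variants at the 0.75% bony intersection threshold are removed before any
#'   aggregation (27 -> 18 variants);
#' * lateroflexion and axial rotation are averaged across left and right and
#'   multiplied by two; if the joint is asymmetrically damaged, the intact
#'   side alone is used and doubled;
#' * sagittal ROM is the sum of dorsoflexion and ventroflexion;
#' * surviving variants are aggregated by their mean.
#'
#' @param raw a `bending_result` table from [run_experiment()].
#' @param damage optional named character vector (joint index -> `"none"`,
#'   `"left"`, `"right"`); unlisted joints are undamaged. A joint damaged on
#'   both sides (entry `"both"`) is excluded with a notice.
#' @param drop_threshold threshold level removed a posteriori (default
#'   0.0075).
#' @return data.frame of class `processed_rom` with columns `joint`,
#'   `lateral`, `axial`, `sagittal` (degrees) and `n_variants`.
#' @export
process_rom <- function(raw, damage = NULL, drop_threshold = 0.0075) {
  raw <- raw[!is.na(raw$direction), , drop = FALSE]
  keep <- abs(raw$threshold - drop_threshold) > 1e-12
  raw <- raw[keep, , drop = FALSE]
  joints <- sort(unique(raw$joint))
  rows <- list()
  for (j in joints) {
    side <- "none"
    if (!is.null(damage)) {
      s <- unname(damage[as.character(j)])
      if (length(s) == 1 && !is.na(s)) side <- s
    }
    if (identical(side, "both")) {
      message("joint ", j, " damaged on both sides: excluded")
      next
    }
    dj <- raw[raw$joint == j, ]
    mean_dir <- function(d) mean(dj$rom_deg[dj$direction == d])
    pick2 <- function(left, right) {
      if (side == "left") 2 * mean_dir(right)
      else if (side == "right") 2 * mean_dir(left)
      else 2 * mean(c(mean_dir(left), mean_dir(right)))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      joint = j,
      lateral = pick2("lateroflexion_left", "lateroflexion_right"),
      axial = pick2("axial_left", "axial_right"),
      sagittal = mean_dir("dorsoflexion") + mean_dir("ventroflexion"),
      n_variants = length(unique(paste(dj$spacing_mult, dj$threshold,
                                       dj$strain_allow))))
  }
  out <- do.call(rbind, rows)
  if (!is.null(out)) class(out) <- c("processed_rom", "data.frame")
  out
}

#' Ternary mobility proportions of a joint
#'
#' Contribution of each bending direction to total ROM. `class` follows the
#' sagittal-lateral rule: `"sagittal-dominant"` when
#' `sagittal / (sagittal + lateral) > 0.5`, otherwise `"lateral-dominant"`
#' (ties are lateral-dominant). `dominant` is the direction with the largest
#' proportion.
#'
#' @param processed a `processed_rom` table (or any data.frame with columns
#'   `joint`, `lateral`, `axial`, `sagittal`).
#' @return data.frame with columns `joint`, `p_lateral`, `p_sagittal`,
#'   `p_axial`, `class`, `dominant`; joints with zero total ROM are excluded.
#' @export
ternary_proportions <- function(processed) {
  tot <- processed$lateral + processed$sagittal + processed$axial
  if (any(tot <= 0)) {
    message(sum(tot <= 0), " joint(s) with zero total ROM excluded")
    processed <- processed[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  p <- data.frame(joint = processed$joint,
                  p_lateral = processed$lateral / tot,
                  p_sagittal = processed$sagittal / tot,
                  p_axial = processed$axial / tot)
  sl <- processed$sagittal / (processed$sagittal + processed$lateral)
  p$class <- ifelse(sl > 0.5, "sagittal-dominant", "lateral-dominant")
  p$dominant <- c("lateral", "sagittal", "axial")[
    max.col(p[, c("p_lateral", "p_sagittal", "p_axial")], ties.method = "first")]
  p
}

#' Assign anterior/posterior region labels
#'
#' Mammals split at the diaphragmatic joint (joints up to and including it
#' are anterior); other groups split at the mid-dorsal position
#' (`floor(n/2)` joints anterior).
#'
#' @param column a [column_model()].
#' @return data.frame with columns `joint`, `region`.
#' @export
assign_regions <- function(column) {
  n <- length(column$joints)
  if (column$group == "mammal") {
    if (is.na(column$region_pos))
      stop("mammal column needs a diaphragmatic position (region_pos)")
    cut <- column$region_pos
  } else {
    cut <- floor(n / 2)
  }
  data.frame(joint = seq_len(n),
             region = ifelse(seq_len(n) <= cut, "anterior", "posterior"))
}

#' Craniocaudal profile by polynomial fit
#'
#' Least-squares polynomial fit of a per-joint quantity against joint
#' position, with the raw points retained alongside. The degree is reduced
#' (with a warning) when there are too few joints.
#'
#' @param joint joint positions.
#' @param values per-joint values.
#' @param degree polynomial degree (default 3).
#' @param n_out number of sampled points on the fitted curve.
#' @return list with `points` (input data), `fit` (data.frame `joint`,
#'   `value`), `degree` (used), `residuals`.
#' @export
craniocaudal_profile <- function(joint, values, degree = 3, n_out = 50) {
  ok <- is.finite(values)
  joint <- joint[ok]; values <- values[ok]
  if (length(joint) < 2) stop("need at least two joints")
  if (length(joint) < degree + 1) {
    degree <- length(joint) - 1
    warning("polynomial degree reduced to ", degree)
  }
  fit <- stats::lm(values ~ stats::poly(joint, degree, raw = TRUE))
  grid <- seq(min(joint), max(joint), length.out = n_out)
  pred <- stats::predict(fit, newdata = data.frame(joint = grid))
  list(points = data.frame(joint = joint, value = values),
       fit = data.frame(joint = grid, value = as.numeric(pred)),
       degree = degree, residuals = stats::residuals(fit))
}

#' Tally of limiting constraints
#'
#' Contingency counts of the limiting constraint family over species and
#' bending direction.
#'
#' @param raw a `bending_result` table.
#' @return data.frame with columns `species`, `direction`, `limiting`, `n`.
#' @export
summarize_constraints <- function(raw) {
  raw <- raw[!is.na(raw$direction), , drop = FALSE]
  tab <- as.data.frame(table(species = raw$species, direction = raw$direction,
                             limiting = raw$limiting_constraint),
                       stringsAsFactors = FALSE)
  names(tab)[4] <- "n"
  tab[tab$n > 0, , drop = FALSE]
}

#' Tidy per-joint functional summary
#'
#' Joins processed ROM, ternary proportions, stiffness and region labels into
#' one tidy table, the input expected by [rrpp_manova()].
#'
#' @param column a [column_model()].
#' @param raw a `bending_result` from [run_experiment()].
#' @param damage see [process_rom()].
#' @return data.frame, one row per joint.
#' @export
joint_function_summary <- function(column, raw, damage = NULL) {
  pr <- process_rom(raw, damage = damage)
  tp <- ternary_proportions(pr)
  st <- compute_stiffness(column, pr)
  rg <- assign_regions(column)
  out <- merge(merge(merge(pr, tp, by = "joint"), st, by = "joint"),
               rg, by = "joint")
  out$species <- column$species
  out$group <- column$group
  out[order(out$joint), ]
}
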