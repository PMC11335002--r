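# Analytic fixtures used across the suite. Everything is built in code so
# contact angles and strain limits have closed forms.

# axis-aligned cube as a tri_mesh
make_cube <- function(origin = c(0, 0, 0), side = 1) {
  V <- as.matrix(expand.grid(0:1, 0:1, 0:1)) * side
  V <- sweep(V, 2, origin, "+")
  F <- rbind(c(1, 3, 4), c(1, 4, 2), c(5, 6, 8), c(5, 8, 7),
             c(1, 2, 6), c(1, 6, 5), c(3, 7, 8), c(3, 8, 4),
             c(1, 5, 7), c(1, 7, 3), c(2, 4, 8), c(2, 8, 6))
  tri_mesh(V, F, label = "cube")
}

# closed circular cylinder along x with flat endplates; a vertex sits exactly
# at the top of each rim (theta = 0), so the analytic face-contact angle
# 2*atan(gap / (2*radius)) is exact for the triangulated fixture
make_cylinder <- function(radius, x0, x1, nseg = 32) {
  theta <- 2 * pi * (seq_len(nseg) - 1) / nseg
  ring <- cbind(radius * cos(theta), radius * sin(theta))
  V <- rbind(c(x0, 0, 0),
             cbind(x0, ring),
             cbind(x1, ring),
             c(x1, 0, 0))
  p1 <- 1L; r0 <- 1L; r1 <- nseg + 1L; p2 <- 2L * nseg + 2L
  nxt <- function(i) if (i == nseg) 1L else i + 1L
  F <- list()
  for (i in seq_len(nseg)) {
    F[[length(F) + 1L]] <- c(p1, r0 + i, r0 + nxt(i))
    F[[length(F) + 1L]] <- c(r0 + i, r1 + i, r1 + nxt(i))
    F[[length(F) + 1L]] <- c(r0 + i, r1 + nxt(i), r0 + nxt(i))
    F[[length(F) + 1L]] <- c(p2, r1 + nxt(i), r1 + i)
  }
  m <- tri_mesh(V, do.call(rbind, F), label = "cylinder")
  # orient outward
  if (mesh_volume(m, "divergence") < pi * radius^2 * (x1 - x0) * 0.5)
    m$faces <- m$faces[, c(1, 3, 2)]
  m$watertight <- is_watertight(m)
  m
}

cylinder_landmarks <- function(radius, x0, x1) {
  P <- rbind(
    endplate_cranial_dorsal = c(x0, radius, 0),
    endplate_cranial_ventral = c(x0, -radius, 0),
    endplate_cranial_left = c(x0, 0, radius),
    endplate_cranial_right = c(x0, 0, -radius),
    endplate_caudal_dorsal = c(x1, radius, 0),
    endplate_caudal_ventral = c(x1, -radius, 0),
    endplate_caudal_left = c(x1, 0, radius),
    endplate_caudal_right = c(x1, 0, -radius),
    arch_apex = c((x0 + x1) / 2, radius, 0))
  landmark_set(P, centrum_length = x1 - x0,
               endplate_area = pi * radius^2)
}

cylinder_vertebra <- function(radius, x0, x1, nseg = 32) {
  list(mesh = make_cylinder(radius, x0, x1, nseg),
       landmarks = cylinder_landmarks(radius, x0, x1))
}

# flat-endplate cylinder joint with gap g: bone contact in sagittal/lateral
# bending at exactly 2*atan(g / (2*r))
cylinder_joint <- function(radius, gap, length = 3 * radius, nseg = 32) {
  build_joint(cylinder_vertebra(radius, -length - gap / 2, -gap / 2, nseg),
              cylinder_vertebra(radius, gap / 2, length + gap / 2, nseg),
              optimal_spacing = gap)
}

# a 2-vertebra cylinder column (one joint) for experiment-level tests
cylinder_column <- function(radius = 10, gap = 2, ...) {
  column_model(list(cylinder_vertebra(radius, -32, -2),
                    cylinder_vertebra(radius, 0, 30)),
               optimal_spacing = gap, species = "cylinder", ...)
}

# bone constraints effectively disabled
no_strain_config <- function(threshold = 0, ...) {
  bending_config(intersection_threshold = threshold, strain_allowance = 1e6,
                 ...)
}

# joint whose only active constraint is a single disc locator pair with
# a = (0,0,0), COR = (1,0,0), p = (2,0,0): under rotation about z through the
# COR the pair distance is 2*cos(theta/2), strain cos(theta/2) - 1
strain_joint <- function() {
  j <- build_joint(
    list(mesh = make_cube(c(-10.5, -0.25, -0.25), 0.5),
         landmarks = cylinder_landmarks(0.25, -10.5, -10)),
    list(mesh = make_cube(c(12, -0.25, -0.25), 0.5),
         landmarks = cylinder_landmarks(0.25, 12, 12.5)),
    optimal_spacing = 22, check_neutral = FALSE)
  j$frame <- joint_frame(c(1, 0, 0))
  j$locator_pairs <- list(list(
    anterior = c(0, 0, 0), posterior = c(2, 0, 0), tissue = "disc",
    side = "mid", name = "disc_fixture", neutral = 2))
  j
}

# unconstrained joint: thin, widely spaced cylinders whose strains stay below
# 50% everywhere in the sweep and whose faces cannot meet within 90 degrees
# (contact at 2*atan(12/2) = 161)
cap_joint <- function() {
  cylinder_joint(radius = 1, gap = 12, length = 9, nseg = 16)
}

# horizontal facet pair for disarticulation tests: unit-half-width squares at
# height h; under axial rotation the projected overlap vanishes at exactly
# 2*atan(1/h) (closed form from z' = h*sin + z*cos)
facet_fixture <- function(h = 10) {
  post <- rbind(c(-1, h + 0.5, -1), c(1, h + 0.5, -1),
                c(1, h + 0.5, 1), c(-1, h + 0.5, 1))
  pre <- rbind(c(-1, h, -1), c(1, h, -1), c(1, h, 1), c(-1, h, 1))
  list(frame = joint_frame(c(0, 0, 0)),
       facet_pairs = list(left = list(postzyg = post, prezyg = pre,
                                      normal = c(0, 1, 0))))
}
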