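## Shared fixture builders; everything is generated in code at test time.

## Small single- or few-type section for fast rendering tests.
tiny_section <- function(types = "IF", n_cells = 4, A = 0.5, seed = 1, ...) {
  lay <- lattice_cells(types, n_cells = n_cells, seed = seed)
  section_spec(lay$cells, lay$width, lay$height,
               type_absorbance = setNames(rep(A, length(types)), types),
               seed = seed, ...)
}

## Hand-built straight vertical double wall: cell 1 occupies the left wall
## band, cell 2 the right one, lumen on both outer sides. Returns map + truth
## in the shape extract_profiles() expects.
straight_double_wall <- function(h = 80, w1_px = 8, w2_px = 8, dA = 0.8,
                                 boundary_col = 40) {
  w <- 2 * boundary_col
  owner <- matrix(0L, h, w)
  wall <- matrix(FALSE, h, w)
  nb <- matrix(0L, h, w)
  c1 <- (boundary_col - w1_px + 1):boundary_col
  c2 <- (boundary_col + 1):(boundary_col + w2_px)
  owner[, 1:boundary_col] <- 1L
  owner[, (boundary_col + 1):w] <- 2L
  wall[, c(c1, c2)] <- TRUE
  nb[, boundary_col + (-1:0)] <- 2L
  nb[, boundary_col + (1:2)] <- 1L
  dAm <- matrix(0, h, w)
  dAm[wall] <- dA
  map <- structure(list(dA = dAm, valid = matrix(TRUE, h, w),
                        pitch_um = 0.179, offset = 0), class = "absorbance_map")
  truth <- list(label = owner, wall = wall, neighbor_id = nb,
                pitch_um = 0.179,
                cells = data.frame(id = 1:2, type = "IF", cx = c(20, 60),
                                   cy = h / 2, r_px = 20,
                                   wall_px = max(w1_px, w2_px)))
  list(map = map, truth = truth)
}

## Uniform absorbance_map over a given truth geometry.
uniform_map <- function(truth, value, pitch_um = 0.179) {
  dA <- matrix(value, nrow(truth$label), ncol(truth$label))
  structure(list(dA = dA, valid = matrix(TRUE, nrow(dA), ncol(dA)),
                 pitch_um = pitch_um, offset = 0), class = "absorbance_map")
}
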