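#' Generate a synthetic per-point measurement table
#'
#' Emulates the adjacency-context measurement design: per genotype and
#' replicate, each cell type has a mean wall absorbance (genotype effect
#' times base, plus between-replicate noise), and points are measured in
#' walls adjacent to the same type ("self") or to each neighbouring type.
#' Cell-to-cell cooperativity is encoded as a mixture: a point of type A
#' adjacent to type B has expected value
#' \code{(1 - w) * m_A + w * m_B} for cooperativity weight \code{w}.
#'
#' @param types character vector of cell types.
#' @param genotype_effects named list: genotype -> named numeric vector of
#'   per-type multipliers of `base_absorbance`.
#' @param n_reps replicates per genotype (>= 2).
#' @param base_absorbance wall absorbance of a multiplier-1 type.
#' @param rep_cv between-replicate coefficient of variation of type means.
#' @param point_cv within-context point-level coefficient of variation.
#' @param n_points points per context (the reference design uses 20 points
#'   of 4 px for adjacency work).
#' @param adjacency data.frame with columns `a`, `b`: unordered type pairs
#'   that share walls. Default: all pairs.
#' @param cooperativity optional data.frame with columns `source`, `target`,
#'   `weight`: the target type's points adjacent to the source are pulled
#'   toward the source's mean with the given weight in \[0, 1\].
#' @param seed RNG seed.
#' @return data.frame (a MeasurementTable): `genotype`, `replicate`,
#'   `cell_type`, `adjacent_to` (`"self"` or a neighbour type), `point_id`,
#'   `absorbance`.
#' @export
make_measurement_sets <- function(types, genotype_effects, n_reps = 5,
                                  base_absorbance = 0.5, rep_cv = 0.10,
                                  point_cv = 0.05, n_points = 20,
                                  adjacency = NULL, cooperativity = NULL,
                                  seed = 1L) {
  if (n_reps < 2) stopf("need at least 2 replicates")
  if (is.null(adjacency)) {
    cmb <- utils::combn(types, 2)
    adjacency <- data.frame(a = cmb[1, ], b = cmb[2, ])
  }
  adj_key <- c(paste(adjacency$a, adjacency$b), paste(adjacency$b, adjacency$a))
  w_of <- function(src, tgt) {
    if (is.null(cooperativity)) return(0)
    hit <- cooperativity$source == src & cooperativity$target == tgt
    if (any(hit)) cooperativity$weight[which(hit)[1]] else 0
  }
  if (!is.null(cooperativity)) {
    bad <- !(paste(cooperativity$source, cooperativity$target) %in% adj_key)
    if (any(bad))
      stopf("cooperativity requested for pair(s) with no shared wall: %s",
            paste(cooperativity$source[bad], cooperativity$target[bad],
                  sep = "->", collapse = ", "))
  }
  set.seed(derive_seed(seed, "measure"))
  rows <- list()
  for (g in names(genotype_effects)) {
    eff <- genotype_effects[[g]]
    for (r in seq_len(n_reps)) {
      m <- base_absorbance * unname(eff[types]) * (1 + rnorm(length(types), 0, rep_cv))
      names(m) <- types
      for (A in types) {
        nbrs <- c("self", adjacency$b[adjacency$a == A], adjacency$a[adjacency$b == A])
        for (ctx in nbrs) {
          w <- if (ctx == "self") 0 else w_of(ctx, A)
          mu <- (1 - w) * m[[A]] + w * (if (ctx == "self") m[[A]] else m[[ctx]])
          v <- mu + rnorm(n_points, 0, point_cv * abs(mu))
          rows[[length(rows) + 1L]] <- data.frame(
            genotype = g, replicate = r, cell_type = A, adjacent_to = ctx,
            point_id = seq_len(n_points), absorbance = v
          )
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default genotype effect panel
#'
#' Eleven lines (wild type plus ten loss-of-function-like genotypes) with
#' per-type multipliers spanning reduced (4cl/ccr-like) and increased
#' (cad-like) coniferaldehyde phenotypes. The per-type patterns differ
#' between lines (fibers strongly affected, protoxylem barely), so type
#' means vary independently enough across lines for correlation work.
#'
#' @param types cell types to cover; the built-in panel is defined for
#'   `PX`, `MX`, `XF`, `IF`, `LP` and recycled column-wise for other labels.
#' @return named list of per-type multiplier vectors.
#' @export
default_genotype_effects <- function(types = c("PX", "MX", "XF", "IF", "LP")) {
  tab <- rbind(
    WT  = c(1.00, 1.00, 1.00, 1.00, 1.00),
    lofA = c(1.00, 0.90, 0.55, 0.45, 0.50),
    lofB = c(1.00, 0.85, 0.40, 0.35, 0.45),
    lofC = c(0.95, 0.60, 0.50, 0.45, 0.55),
    lofD = c(1.00, 0.65, 0.55, 0.75, 0.90),
    lofE = c(1.00, 0.95, 0.90, 0.60, 0.90),
    gofA = c(1.05, 1.05, 1.10, 1.30, 1.20),
    gofB = c(1.00, 1.05, 1.10, 1.35, 1.15),
    gofC = c(1.00, 1.05, 1.00, 1.05, 1.00),
    gofD = c(1.05, 1.20, 1.20, 1.30, 1.25),
    gofE = c(1.30, 1.45, 1.40, 1.50, 1.40)
  )
  lapply(seq_len(nrow(tab)), function(i) {
    setNames(rep_len(tab[i, ], length(types)), types)
  }) |> setNames(rownames(tab))
}
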