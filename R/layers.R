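#' Cell-wall layer classification scheme
#'
#' The double wall between two adjacent cells is split into the compound
#' middle lamella (CML) and the secondary wall layers S1, S2, S3 using a
#' mixed absolute/fractional scheme: CML is the central 500 nm band, S1 the
#' adjacent 500 nm on each side (absolute, in um), while S2 occupies
#' 0.1--0.35 and 0.65--0.9 and S3 0.02--0.1 and 0.9--0.98 of the
#' range-normalised double-wall width. Absolute bands take precedence over
#' fractional ranges where they overlap, and S3 over S2 at range edges;
#' positions between the S2 ranges but outside the absolute bands are S1.
#'
#' @param cml_half_um CML half-width (um); default 0.25 gives a 500 nm band.
#' @param s1_um S1 band width adjacent to the CML on each side (um).
#' @param s2_frac,s3_frac lower fractional range of S2 / S3 (mirrored about
#'   0.5).
#' @return object of class `layer_scheme`.
#' @export
layer_scheme <- function(cml_half_um = 0.25, s1_um = 0.5,
                         s2_frac = c(0.1, 0.35), s3_frac = c(0.02, 0.1)) {
  stopifnot(cml_half_um > 0, s1_um > 0,
            all(s2_frac >= 0 & s2_frac <= 1), all(s3_frac >= 0 & s3_frac <= 1))
  structure(list(cml_half_um = cml_half_um, s1_um = s1_um,
                 s2_frac = sort(s2_frac), s3_frac = sort(s3_frac)),
            class = "layer_scheme")
}

#' Classify positions across a double wall into layers
#'
#' @param norm_pos normalised positions in \[0, 1\] (0 and 1 at the two
#'   lumen edges, 0.5 at the wall midpoint).
#' @param width_um total double-wall width (um); needed for the absolute
#'   CML/S1 bands.
#' @param scheme a [layer_scheme()].
#' @return character vector in `{"CML","S1","S2","S3","unassigned"}`.
#' @export
classify_layer_positions <- function(norm_pos, width_um, scheme = layer_scheme()) {
  if (width_um <= 0) stopf("double-wall width must be positive")
  if (width_um < 2 * (scheme$cml_half_um + scheme$s1_um))
    warning("double wall narrower than the CML + S1 bands; labelling degenerates to CML/S1 only")
  d_um <- abs(norm_pos - 0.5) * width_um
  x <- norm_pos
  in_rng <- function(x, r) (x >= r[1] & x <= r[2]) | (x >= 1 - r[2] & x <= 1 - r[1])
  lab <- rep("unassigned", length(x))
  lab[x >= 0.35 & x <= 0.65] <- "S1" # mid-zone default for wide walls
  lab[in_rng(x, scheme$s2_frac)] <- "S2"
  lab[in_rng(x, scheme$s3_frac)] <- "S3"
  lab[d_um <= scheme$cml_half_um + scheme$s1_um] <- "S1"
  lab[d_um <= scheme$cml_half_um] <- "CML"
  lab[x < 0.02 | x > 0.98] <- "unassigned"
  lab
}

#' Generate synthetic double-wall absorbance profiles
#'
#' Each profile spans a double wall of (jittered) total width, with true
#' absorbance set per layer (base times a layer multiplier, layers defined
#' by the same scheme used for classification), smoothed by a Gaussian
#' optical blur and overlaid with Gaussian measurement noise.
#'
#' @param n number of profiles.
#' @param width_um nominal total double-wall width (um).
#' @param step_um sampling step along the transect (um).
#' @param base base absorbance of a multiplier-1 layer.
#' @param layer_multipliers named vector over `CML`, `S1`, `S2`, `S3`.
#' @param noise_sd additive absorbance noise per sample position.
#' @param blur_sigma_um Gaussian optical blur (um); ~0.15 um matches a
#'   0.75 NA objective at 550 nm.
#' @param width_jitter relative SD of the per-profile width.
#' @param scheme a [layer_scheme()] used to lay down the truth.
#' @param seed RNG seed.
#' @return list of class `wall_profiles`: each element a data.frame with
#'   `position_um`, `norm_pos`, `dA` and a `width_um` attribute; the list
#'   carries the generating parameters as attributes.
#' @export
synth_wall_profiles <- function(n = 50, width_um = 6, step_um = 0.09,
                                base = 0.5,
                                layer_multipliers = c(CML = 1, S1 = 1, S2 = 1, S3 = 1),
                                noise_sd = 0.03, blur_sigma_um = 0.15,
                                width_jitter = 0.03,
                                scheme = layer_scheme(), seed = 1L) {
  set.seed(derive_seed(seed, "profiles"))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    W <- width_um * (1 + rnorm(1, 0, width_jitter))
    pos <- seq(0, W, by = step_um)
    xn <- pos / W
    lab <- classify_layer_positions(xn, W, scheme)
    lab[lab == "unassigned"] <- "S3" # lumen-edge truth continues the S3 layer
    a <- base * unname(layer_multipliers[lab])
    if (blur_sigma_um > 0) {
      kw <- max(1L, ceiling(3 * blur_sigma_um / step_um))
      k <- exp(-0.5 * ((-kw:kw) * step_um / blur_sigma_um)^2)
      k <- k / sum(k)
      apad <- c(rep(a[1], kw), a, rep(a[length(a)], kw))
      a <- as.vector(stats::filter(apad, k, sides = 2))[(kw + 1):(kw + length(pos))]
    }
    a <- a + rnorm(length(a), 0, noise_sd)
    p <- data.frame(position_um = pos, norm_pos = xn, dA = a)
    attr(p, "width_um") <- W
    out[[i]] <- p
  }
  structure(out, class = "wall_profiles", width_um = width_um,
            layer_multipliers = layer_multipliers, base = base)
}

#' Extract double-wall transect profiles from an absorbance map
#'
#' Finds the shared wall between two cells, fits the boundary midline, and
#' samples absorbance along transects perpendicular to it at sub-pixel
#' spacing (bilinear interpolation, step = pitch / 2). Transects whose two
#' single-wall widths differ by more than `width_tol` (relative) are
#' rejected, mirroring the restriction to walls of equal width on both sides
#' of the CML.
#'
#' @param map an [absorbance_map()] (or plain matrix of absorbance).
#' @param truth geometry rasters as returned in `render_pair()$truth`
#'   (`label`, `wall`, `neighbor_id`, `pitch_um`).
#' @param pair length-2 vector of cell ids sharing a wall.
#' @param n number of profiles wanted.
#' @param width_tol relative tolerance on single-wall width equality.
#' @param seed RNG seed for transect placement.
#' @return a `wall_profiles` list (see [synth_wall_profiles()]).
#' @export
extract_profiles <- function(map, truth, pair, n = 50, width_tol = 0.2, seed = 1L) {
  dA <- if (inherits(map, "absorbance_map")) map$dA else map
  pitch <- truth$pitch_um
  own <- truth$label; wall <- truth$wall; nb <- truth$neighbor_id
  bsel <- wall & ((own == pair[1] & nb == pair[2]) | (own == pair[2] & nb == pair[1]))
  if (!any(bsel)) stopf("cells %d and %d share no wall", pair[1], pair[2])
  idx <- which(bsel, arr.ind = TRUE)
  pts <- cbind(x = idx[, 2], y = idx[, 1])
  ctr <- colMeans(pts)
  pc <- prcomp(pts)
  v <- pc$rotation[, 1] # along-boundary
  u <- pc$rotation[, 2] # transect direction
  s_rng <- range((pts[, 1] - ctr[1]) * v[1] + (pts[, 2] - ctr[2]) * v[2])
  set.seed(derive_seed(seed, "transects"))
  anchors <- runif(4 * n, s_rng[1] * 0.9, s_rng[2] * 0.9)
  step <- 0.5 # px; pitch/2 in um
  tmax <- max(truth$cells$wall_px) * 2.5
  ts <- seq(-tmax, tmax, by = step)
  walk <- function(ids, id) {
    ## contiguous run of cell `id` wall pixels outward from the boundary (t=0)
    zero <- which.min(abs(ts))
    half <- function(dirn) {
      k <- zero; run <- 0
      repeat {
        k <- k + dirn
        if (k < 1 || k > length(ts) || is.na(ids[k]) || ids[k] != id) break
        run <- run + 1
      }
      run
    }
    max(half(1L), half(-1L)) * step
  }
  profs <- list(); tried <- 0L
  for (s in anchors) {
    if (length(profs) >= n) break
    tried <- tried + 1L
    px <- ctr[1] + s * v[1] + ts * u[1]
    py <- ctr[2] + s * v[2] + ts * u[2]
    ow <- own[cbind(clamp(round(py), 1, nrow(own)), clamp(round(px), 1, ncol(own)))]
    wl <- wall[cbind(clamp(round(py), 1, nrow(own)), clamp(round(px), 1, ncol(own)))]
    ids <- ifelse(wl, ow, NA_integer_)
    zero <- which.min(abs(ts))
    ## orient so negative t is in cell pair[1]
    side <- ids[c(zero - 2, zero + 2)]
    w1 <- walk(ids, pair[1]); w2 <- walk(ids, pair[2])
    if (w1 < 2 || w2 < 2) next
    if (abs(w1 - w2) / max(w1, w2) > width_tol) next
    sgn <- if (!is.na(side[1]) && side[1] == pair[2]) -1 else 1
    tt <- seq(-w1, w2, by = step) * sgn
    vals <- bilinear_sample(dA, ctr[1] + s * v[1] + tt * u[1],
                            ctr[2] + s * v[2] + tt * u[2])
    if (anyNA(vals)) next
    tpos <- seq(-w1, w2, by = step)
    p <- data.frame(position_um = (tpos + w1) * pitch,
                    norm_pos = (tpos + w1) / (w1 + w2), dA = vals)
    attr(p, "width_um") <- (w1 + w2) * pitch
    profs[[length(profs) + 1L]] <- p
  }
  if (length(profs) < n)
    stopf("only %d of %d admissible transects found for cells %d-%d",
          length(profs), n, pair[1], pair[2])
  structure(profs, class = "wall_profiles", width_um = NA_real_)
}

#' Classify a set of profiles and pool absorbance by layer
#'
#' @param profiles a `wall_profiles` list.
#' @param scheme a [layer_scheme()].
#' @return data.frame: `profile`, `norm_pos`, `dA`, `layer`.
#' @export
classify_profiles <- function(profiles, scheme = layer_scheme()) {
  out <- lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    data.frame(profile = i, norm_pos = p$norm_pos, dA = p$dA,
               layer = classify_layer_positions(p$norm_pos, attr(p, "width_um"), scheme))
  })
  do.call(rbind, out)
}

#' Per-layer percent change between two profile sets
#'
#' @param ref,alt `wall_profiles` lists (reference and comparison group).
#' @param scheme a [layer_scheme()].
#' @return data.frame: `layer`, `mean_ref`, `mean_alt`, `percent_change`
#'   (100 * (alt/ref - 1)).
#' @export
layer_percent_change <- function(ref, alt, scheme = layer_scheme()) {
  cr <- classify_profiles(ref, scheme); ca <- classify_profiles(alt, scheme)
  layers <- c("CML", "S1", "S2", "S3")
  mr <- vapply(layers, function(l) mean(cr$dA[cr$layer == l]), 0)
  ma <- vapply(layers, function(l) mean(ca$dA[ca$layer == l]), 0)
  data.frame(layer = layers, mean_ref = mr, mean_alt = ma,
             percent_change = 100 * (ma / mr - 1), row.names = NULL)
}

#' Per-layer group comparisons (Kruskal--Wallis, Holm-adjusted letters)
#'
#' Pools pixel-level absorbance per layer per group and, within each layer
#' panel, tests all group pairs with Kruskal--Wallis, Holm-adjusts the
#' p-values across the pairs, and assigns a compact letter display.
#'
#' @param groups named list: group label -> `wall_profiles` list.
#' @param scheme a [layer_scheme()].
#' @param alpha significance level.
#' @param min_points minimum pooled points per layer per group.
#' @return list per layer: `letters` (named by group), `pairs` data.frame
#'   with raw and Holm-adjusted p-values. Empty layers are dropped with a
#'   warning.
#' @export
layer_stats <- function(groups, scheme = layer_scheme(), alpha = 0.05,
                        min_points = 5) {
  if (length(groups) < 2) stopf("need at least 2 groups")
  pooled <- lapply(groups, classify_profiles, scheme = scheme)
  layers <- c("CML", "S1", "S2", "S3")
  out <- list()
  for (l in layers) {
    vals <- lapply(pooled, function(d) d$dA[d$layer == l])
    ok <- vapply(vals, length, 0L) >= min_points
    if (!all(ok)) {
      warning(sprintf("layer %s dropped: fewer than %d points in some group", l, min_points))
      next
    }
    out[[l]] <- kruskal_holm(vals, alpha = alpha)
  }
  out
}
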