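#' Absorbance-difference map from a registered pair
#'
#' Converts both frames to grey-intensity absorbance (\code{log10(255/grey)}),
#' resamples the stained frame into the reference frame under the alignment,
#' subtracts unstained from stained per pixel, and removes a scalar
#' background offset: the mean difference over a reference region that is
#' unstained by construction (the non-lignified phloem in real sections).
#'
#' @param unstained,stained 8-bit RGB arrays.
#' @param alignment an `alignment` mapping stained onto unstained.
#' @param background logical matrix marking the unstained reference region.
#' @param labels optional logical matrix of lignified pixels; the background
#'   region must not overlap it.
#' @param pitch_um pixel pitch carried into the map.
#' @return object of class `absorbance_map`: `dA` matrix, `valid` mask,
#'   `pitch_um`, `offset` (the scalar subtracted).
#' @export
difference_map <- function(unstained, stained, alignment = identity_alignment(),
                           background = NULL, labels = NULL, pitch_um = 0.179) {
  if (!is.null(background) && !is.null(labels) && any(background & labels))
    stopf("background reference region overlaps lignified labels")
  a_un <- log10(255 / pmax(to_grey(unstained), 1))
  rs <- resample(stained, alignment)
  g_st <- to_grey(rs$image)
  a_st <- log10(255 / pmax(g_st, 1))
  dA <- a_st - a_un
  valid <- rs$valid & is.finite(dA)
  offset <- 0
  if (!is.null(background)) {
    sel <- background & valid
    if (!any(sel)) stopf("background region is empty or entirely invalid")
    offset <- mean(dA[sel])
    dA <- dA - offset
  }
  dA[!valid] <- NA_real_
  structure(list(dA = dA, valid = valid, pitch_um = pitch_um, offset = offset),
            class = "absorbance_map")
}

#' Sample circular measurement points per cell type
#'
#' Places `n` non-overlapping quasi-circular points of `area_px` pixels
#' uniformly at random (seeded) inside each cell type's wall mask and
#' records the mean absorbance over each point, together with the adjacency
#' context: the neighbouring cell's type where the point touches a shared
#' wall, otherwise `"self"`. The default 50 points of 12 px matches a
#' 0.7 um point diameter at 0.179 um/px.
#'
#' @param map an [absorbance_map()].
#' @param truth geometry as in `render_pair()$truth` (`label`, `type`,
#'   `wall`, `neighbor_id`, `cells`).
#' @param n points per cell type.
#' @param area_px pixels per point.
#' @param seed RNG seed.
#' @param types cell types to sample (default: all present).
#' @return data.frame: `cell_type`, `point_id`, `x`, `y`, `adjacent_to`,
#'   `absorbance`.
#' @export
sample_points <- function(map, truth, n = 50, area_px = 12, seed = 1L,
                          types = NULL) {
  off <- circle_offsets(area_px)
  rad <- max(sqrt(off$dx^2 + off$dy^2))
  wall <- truth$wall & map$valid
  if (is.null(types)) types <- sort(unique(truth$type[truth$wall]))
  set.seed(derive_seed(seed, "points"))
  h <- nrow(map$dA); w <- ncol(map$dA)
  res <- list()
  for (tt in types) {
    cand <- which(wall & !is.na(truth$type) & truth$type == tt)
    ## keep candidates whose whole circle stays in this type's wall
    cy <- (cand - 1) %% h + 1; cx <- (cand - 1) %/% h + 1
    inb <- cx > rad & cx <= w - rad & cy > rad & cy <= h - rad
    cand <- cand[inb]; cx <- cx[inb]; cy <- cy[inb]
    fit <- vapply(seq_along(cand), function(i) {
      ys <- cy[i] + off$dy; xs <- cx[i] + off$dx
      idx <- cbind(ys, xs)
      all(wall[idx]) && all(truth$type[idx] == tt)
    }, TRUE)
    cand <- cand[fit]; cx <- cx[fit]; cy <- cy[fit]
    ord <- sample.int(length(cand))
    taken_x <- numeric(0); taken_y <- numeric(0)
    pts <- 0L
    for (i in ord) {
      if (pts >= n) break
      if (length(taken_x) &&
          any((taken_x - cx[i])^2 + (taken_y - cy[i])^2 < (2 * rad)^2)) next
      ys <- cy[i] + off$dy; xs <- cx[i] + off$dx
      idx <- cbind(ys, xs)
      nbids <- truth$neighbor_id[idx]
      nbid <- nbids[nbids > 0L]
      ctx <- if (length(nbid)) truth$cells$type[Mode_int(nbid)] else "self"
      pts <- pts + 1L
      taken_x <- c(taken_x, cx[i]); taken_y <- c(taken_y, cy[i])
      res[[length(res) + 1L]] <- data.frame(
        cell_type = tt, point_id = pts, x = cx[i], y = cy[i],
        adjacent_to = ctx, absorbance = mean(map$dA[idx])
      )
    }
    if (pts < n)
      stopf("insufficient wall area for cell type '%s': placed %d of %d points",
            tt, pts, n)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

Mode_int <- function(x) {
  tb <- tabulate(x)
  which.max(tb)
}

#' Per-cell-type staining time course
#'
#' @param maps list of [absorbance_map()]s at increasing times.
#' @param times numeric times (s), same length (>= 3).
#' @param truth geometry rasters (`type`, `wall`).
#' @return list: `series` data.frame (`time_s`, `cell_type`, `mean_dA`,
#'   `sd_dA`), `plateau` data.frame (`cell_type`, `plateau_time_s`,
#'   `unreliable`). Plateau = first time reaching 95\% of the series
#'   maximum; series whose maximum barely exceeds their noise floor are
#'   flagged unreliable.
#' @export
time_course <- function(maps, times, truth) {
  if (length(maps) < 3 || length(maps) != length(times)) stopf("need >= 3 timepoints")
  types <- sort(unique(truth$type[truth$wall]))
  rows <- list()
  for (i in seq_along(maps)) {
    for (tt in types) {
      sel <- truth$wall & !is.na(truth$type) & truth$type == tt & maps[[i]]$valid
      rows[[length(rows) + 1L]] <- data.frame(
        time_s = times[i], cell_type = tt,
        mean_dA = mean(maps[[i]]$dA[sel]), sd_dA = sd(maps[[i]]$dA[sel]))
    }
  }
  series <- do.call(rbind, rows)
  plateau <- do.call(rbind, lapply(types, function(tt) {
    s <- series[series$cell_type == tt, ]
    s <- s[order(s$time_s), ]
    mx <- max(s$mean_dA)
    unrel <- mx <= 3 * stats::median(s$sd_dA) / sqrt(50) && mx <= 0.02
    data.frame(cell_type = tt,
               plateau_time_s = s$time_s[which(s$mean_dA >= 0.95 * mx)[1]],
               unreliable = unrel)
  }))
  list(series = series, plateau = plateau)
}

#' Area-weighted total absorbance across cell types
#'
#' @param means named numeric per-type mean absorbances.
#' @param fractions named numeric per-type area fractions (sum to 1).
#' @return scalar weighted total.
#' @export
weighted_total <- function(means, fractions) {
  if (any(fractions < 0)) stopf("area fractions must be non-negative")
  if (abs(sum(fractions) - 1) > 1e-9) stopf("area fractions must sum to 1")
  if (!is.null(names(means)) && !is.null(names(fractions)))
    fractions <- fractions[names(means)]
  sum(unname(means) * unname(fractions))
}

#' False-colour rendering of an absorbance map
#'
#' Absorbance times 255 is clipped to the 8-bit range and mapped through a
#' perceptually uniform colormap (viridis); invalid pixels render black.
#'
#' @param map an [absorbance_map()] or plain matrix.
#' @param palette passed to [grDevices::hcl.colors()].
#' @return list: `rgb` 8-bit array, `index` the 0--255 colormap index,
#'   `legend` data.frame mapping index to absorbance.
#' @export
false_color <- function(map, palette = "viridis") {
  dA <- if (inherits(map, "absorbance_map")) map$dA else map
  idx <- clamp(round(dA * 255), 0, 255)
  cols <- hcl.colors(256, palette)
  rgbm <- col2rgb(cols)
  h <- nrow(dA); w <- ncol(dA)
  out <- array(0L, c(h, w, 3))
  ii <- ifelse(is.na(idx), NA_integer_, idx + 1L)
  for (ch in 1:3) {
    v <- rgbm[ch, ][ii]
    v[is.na(v)] <- 0L
    out[, , ch] <- matrix(as.integer(v), h)
  }
  list(rgb = out, index = idx,
       legend = data.frame(index = c(0L, 128L, 255L),
                           absorbance = c(0, 128, 255) / 255))
}

#' Bin measurement points by distance to the cambium
#'
#' Euclidean point-to-polyline distance, binned into the developmental
#' stages I \[0, 50), II \[50, 100), III \[100, inf) um. Points on the
#' phloem side of the cambium (opposite the xylem reference point) are
#' excluded with a warning count.
#'
#' @param table point table with `x`, `y` (px).
#' @param cambium two-column matrix of polyline vertices (px).
#' @param pitch_um pixel pitch.
#' @param xylem_side length-2 point (px) marking the xylem/pith side.
#' @param breaks_um bin edges (half-open at the left).
#' @return the table with `distance_um` and `stage` columns; excluded rows
#'   dropped, their count in `attr(, "excluded")`.
#' @export
bin_by_cambium_distance <- function(table, cambium, pitch_um = 0.179,
                                    xylem_side = NULL,
                                    breaks_um = c(0, 50, 100, Inf)) {
  if (is.null(dim(cambium)) || nrow(cambium) < 2) stopf("cambium polyline needs >= 2 vertices")
  dseg <- function(px, py) {
    best <- rep(Inf, length(px)); side <- rep(0, length(px))
    for (k in seq_len(nrow(cambium) - 1)) {
      a <- cambium[k, ]; b <- cambium[k + 1, ]
      ab <- b - a
      tt <- clamp(((px - a[1]) * ab[1] + (py - a[2]) * ab[2]) / sum(ab^2), 0, 1)
      qx <- a[1] + tt * ab[1]; qy <- a[2] + tt * ab[2]
      d <- sqrt((px - qx)^2 + (py - qy)^2)
      upd <- d < best
      cr <- ab[1] * (py - a[2]) - ab[2] * (px - a[1])
      side[upd] <- sign(cr[upd])
      best[upd] <- d[upd]
    }
    list(d = best, side = side)
  }
  dd <- dseg(table$x, table$y)
  keep <- rep(TRUE, nrow(table))
  if (!is.null(xylem_side)) {
    ref <- dseg(xylem_side[1], xylem_side[2])$side
    keep <- dd$side == ref | dd$side == 0
    if (any(!keep)) warning(sum(!keep), " point(s) on the phloem side of the cambium excluded")
  }
  out <- table[keep, , drop = FALSE]
  out$distance_um <- dd$d[keep] * pitch_um
  out$stage <- cut(out$distance_um, breaks = breaks_um, right = FALSE,
                   labels = c("I", "II", "III")[seq_len(length(breaks_um) - 1)])
  attr(out, "excluded") <- sum(!keep)
  out
}
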