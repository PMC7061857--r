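## Integer-pixel translation estimate by FFT phase correlation.
phase_correlate <- function(ref, mov) {
  Fr <- stats::fft(ref); Fm <- stats::fft(mov)
  cps <- Fr * Conj(Fm)
  cps <- cps / pmax(Mod(cps), 1e-12)
  cc <- Re(stats::fft(cps, inverse = TRUE))
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  wrap <- function(i, n) ifelse(i - 1 > n / 2, i - 1 - n, i - 1)
  list(dy = -wrap(pk[1], nrow(ref)), dx = -wrap(pk[2], ncol(ref)),
       score = max(cc) / length(cc))
}

## Rigidly transform coordinates: moving-frame position of reference pixel
## (x, y) under (dx, dy, theta) about the image centre.
.rigid_coords <- function(x, y, dx, dy, theta_deg, cx, cy) {
  th <- theta_deg * pi / 180
  xs <- x - cx; ys <- y - cy
  list(x = cos(th) * xs - sin(th) * ys + cx + dx,
       y = sin(th) * xs + cos(th) * ys + cy + dy)
}

## Smoothed gradient magnitude: the structural channel shared by the
## unstained and stained frames (stain changes wall intensity, not wall
## position, so edges are the stable landmarks).
gradient_magnitude <- function(g, sigma = 1) {
  gs <- EBImage::gblur(g, sigma = sigma)
  h <- nrow(gs); w <- ncol(gs)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  gx[, 2:(w - 1)] <- (gs[, 3:w] - gs[, 1:(w - 2)]) / 2
  gy[2:(h - 1), ] <- (gs[3:h, ] - gs[1:(h - 2), ]) / 2
  sqrt(gx^2 + gy^2)
}

## 1 - normalised cross-correlation between the reference gradient image and
## the rigidly resampled moving gradient image (subsampled grid for speed).
.rigid_cost <- function(par, ref, mov, sub = 2L) {
  h <- nrow(ref); w <- ncol(ref)
  gx <- seq(3, w - 2, by = sub); gy <- seq(3, h - 2, by = sub)
  xs <- rep(gx, each = length(gy)); ys <- rep(gy, length(gx))
  cc <- .rigid_coords(xs, ys, par[1], par[2], par[3], (w + 1) / 2, (h + 1) / 2)
  v <- bilinear_sample(mov, cc$x, cc$y)
  r <- ref[cbind(ys, xs)]
  ok <- !is.na(v)
  if (sum(ok) < 100) return(1e9)
  1 - cor(v[ok], r[ok])
}

#' Globally register a moving image onto a reference
#'
#' Rigid (translation + rotation) intensity-based registration of the grey
#' channel: a coarse rotation grid with FFT phase correlation for the
#' translation, then Nelder--Mead refinement of (dx, dy, theta) on the mean
#' squared difference with bilinear resampling. On clean synthetic pairs
#' this recovers translations to ~0.02 px and rotations to ~0.02 degrees
#' for shifts up to 20 px and rotations up to `rot_range` degrees.
#'
#' @param reference,moving 8-bit RGB arrays (or grey matrices) of identical
#'   size.
#' @param rot_range half-width (degrees) of the rotation search; 0 restricts
#'   the model to pure translation.
#' @param rot_step coarse rotation grid step (degrees).
#' @param max_residual convergence guard: if the final mean absolute grey
#'   difference exceeds this, registration is declared failed.
#' @return object of class `alignment`: `dx`, `dy`, `theta_deg`, `residual`
#'   (mean absolute grey difference), `field` (NULL for rigid).
#' @export
register_global <- function(reference, moving, rot_range = 5, rot_step = 1,
                            min_correlation = 0.2) {
  refg <- to_grey(reference); movg <- to_grey(moving)
  if (!all(dim(refg) == dim(movg))) stopf("images must have identical dimensions")
  ref <- gradient_magnitude(refg); mov <- gradient_magnitude(movg)
  thetas <- if (rot_range > 0) seq(-rot_range, rot_range, by = rot_step) else 0
  best <- NULL
  h <- nrow(ref); w <- ncol(ref)
  for (th in thetas) {
    movr <- if (th != 0) {
      cc <- .rigid_coords(rep(seq_len(w), each = h), rep(seq_len(h), w),
                          0, 0, th, (w + 1) / 2, (h + 1) / 2)
      m <- matrix(bilinear_sample(mov, cc$x, cc$y), h)
      m[is.na(m)] <- 0
      m
    } else mov
    pc <- phase_correlate(ref - mean(ref), movr - mean(movr))
    if (is.null(best) || pc$score > best$score)
      best <- list(theta = th, dx = pc$dx, dy = pc$dy, score = pc$score)
  }
  init <- c(best$dx, best$dy, best$theta)
  opt <- optim(init, .rigid_cost, ref = ref, mov = mov,
               method = "Nelder-Mead",
               control = list(maxit = 500, reltol = 1e-12,
                              parscale = c(1, 1, 0.5)))
  par <- opt$par
  if (!is.finite(opt$value) || (1 - opt$value) < min_correlation)
    stopf("registration failed to converge (gradient correlation %.2f)", 1 - opt$value)
  cc <- .rigid_coords(rep(seq_len(w), each = h), rep(seq_len(h), w),
                      par[1], par[2], par[3], (w + 1) / 2, (h + 1) / 2)
  v <- bilinear_sample(movg, cc$x, cc$y)
  resid <- mean(abs(v - as.vector(refg)), na.rm = TRUE)
  structure(list(dx = par[1], dy = par[2], theta_deg = par[3],
                 residual = resid, field = NULL),
            class = "alignment")
}

#' Identity alignment
#' @return an `alignment` with zero transform.
#' @export
identity_alignment <- function() {
  structure(list(dx = 0, dy = 0, theta_deg = 0, residual = 0, field = NULL),
            class = "alignment")
}

#' Resample a moving image into the reference frame
#'
#' Applies an alignment by bilinear interpolation; pixels mapping outside
#' the moving image are flagged invalid and excluded from downstream
#' subtraction.
#'
#' @param moving 8-bit RGB array or grey matrix.
#' @param a an `alignment` from [register_global()] / [register_elastic()].
#' @return list: `image` (same shape as input, floats), `valid` (logical
#'   matrix).
#' @export
resample <- function(moving, a) {
  is3d <- length(dim(moving)) == 3L
  g <- if (is3d) moving[, , 1] else moving
  h <- nrow(g); w <- ncol(g)
  xs <- rep(seq_len(w), each = h); ys <- rep(seq_len(h), w)
  cc <- .rigid_coords(xs, ys, a$dx, a$dy, a$theta_deg, (w + 1) / 2, (h + 1) / 2)
  if (!is.null(a$field)) {
    cc$x <- cc$x + as.vector(a$field$dx)
    cc$y <- cc$y + as.vector(a$field$dy)
  }
  samp1 <- function(m) matrix(bilinear_sample(m, cc$x, cc$y), h)
  if (is3d) {
    out <- array(NA_real_, dim(moving))
    for (ch in seq_len(dim(moving)[3])) out[, , ch] <- samp1(moving[, , ch])
    valid <- !is.na(out[, , 1])
  } else {
    out <- samp1(moving)
    valid <- !is.na(out)
  }
  list(image = out, valid = valid)
}

#' Elastic refinement of an alignment on a region of interest
#'
#' Starting from the rigid alignment, estimates a smooth dense displacement
#' field by block matching on a coarse control grid (local phase correlation
#' with quadratic sub-pixel peak refinement), Gaussian-smooths the control
#' displacements, and bilinearly upsamples to a full-resolution field.
#' Textureless ROIs return the initial alignment unchanged with a warning
#' flag.
#'
#' @param reference,moving images (<= 512 x 512 ROI).
#' @param init initial `alignment` (applied before matching).
#' @param block_px block size for local matching.
#' @param grid_n control points per axis.
#' @param max_disp displacement cap (px) for outlier rejection.
#' @param texture_tol minimum grey SD for a block to be matched.
#' @param n_iter match/warp/re-match composition iterations.
#' @return an `alignment` with a `field` (list of `dx`, `dy` matrices) and a
#'   `degenerate` flag when the ROI was textureless.
#' @export
register_elastic <- function(reference, moving, init = identity_alignment(),
                             block_px = 28, grid_n = 10, max_disp = 8,
                             texture_tol = 2, n_iter = 3) {
  refg <- to_grey(reference)
  if (any(dim(refg) > 512)) stopf("elastic ROI must be <= 512 x 512 px")
  if (sd(refg) < texture_tol) {
    init$degenerate <- TRUE
    warning("textureless ROI; elastic refinement skipped")
    return(init)
  }
  ## match on gradient magnitude: edges are shared between the unstained and
  ## stained frames, wall intensity is not (the stain changes it).
  ref <- gradient_magnitude(refg)
  movg0 <- to_grey(moving)
  h <- nrow(ref); w <- ncol(ref)
  gx <- round(seq(block_px / 2 + 1, w - block_px / 2, length.out = grid_n))
  gy <- round(seq(block_px / 2 + 1, h - block_px / 2, length.out = grid_n))
  hb <- block_px %/% 2
  out <- init
  out$field <- list(dx = matrix(0, h, w), dy = matrix(0, h, w))
  upsample <- function(u) {
    xi <- approx(gx, seq_len(grid_n), xout = clamp(seq_len(w), gx[1], gx[grid_n]))$y
    yi <- approx(gy, seq_len(grid_n), xout = clamp(seq_len(h), gy[1], gy[grid_n]))$y
    matrix(bilinear_sample(u, rep(xi, each = h), rep(yi, w)), h)
  }
  smooth_grid <- function(u) {
    k <- matrix(c(1, 2, 1, 2, 4, 2, 1, 2, 1) / 16, 3)
    up <- rbind(u[1, ], u, u[grid_n, ]); up <- cbind(up[, 1], up, up[, grid_n])
    o <- u
    for (i in seq_len(grid_n)) for (j in seq_len(grid_n))
      o[i, j] <- sum(up[i:(i + 2), j:(j + 2)] * k)
    o
  }
  for (it in seq_len(n_iter)) {
    rs <- resample(movg0, out)
    movg <- rs$image
    movg[is.na(movg)] <- mean(movg, na.rm = TRUE)
    mov <- gradient_magnitude(movg)
    ux <- matrix(NA_real_, grid_n, grid_n); uy <- matrix(NA_real_, grid_n, grid_n)
    for (i in seq_len(grid_n)) for (j in seq_len(grid_n)) {
      ry <- (gy[i] - hb):(gy[i] + hb - 1); rx <- (gx[j] - hb):(gx[j] + hb - 1)
      rb <- ref[ry, rx]; mb <- mov[ry, rx]
      if (sd(rb) < texture_tol || sd(mb) < texture_tol) next
      pc <- phase_correlate(rb - mean(rb), mb - mean(mb))
      d <- c(pc$dx, pc$dy)
      if (any(abs(d) > max_disp)) d <- c(0, 0)
      ## Lucas-Kanade sub-pixel refinement; same convention as resample():
      ## the field is where in the moving frame each reference pixel reads.
      d <- lk_refine(ref, mov, rx, ry, d)
      if (all(is.finite(d)) && all(abs(d) <= max_disp)) {
        ux[i, j] <- d[1]; uy[i, j] <- d[2]
      }
    }
    if (all(is.na(ux))) break
    ## textureless control points inherit an inverse-distance weighted
    ## average of the matched ones instead of biasing the field toward zero
    fill <- function(u) {
      bad <- which(is.na(u), arr.ind = TRUE)
      good <- which(!is.na(u), arr.ind = TRUE)
      for (b in seq_len(nrow(bad))) {
        wgt <- 1 / ((good[, 1] - bad[b, 1])^2 + (good[, 2] - bad[b, 2])^2)
        u[bad[b, 1], bad[b, 2]] <- sum(u[good] * wgt) / sum(wgt)
      }
      u
    }
    ux <- smooth_grid(fill(ux)); uy <- smooth_grid(fill(uy))
    ## additive composition: the increment is estimated on the already
    ## warped image, so it adds to the running field (small-displacement
    ## approximation).
    out$field$dx <- out$field$dx + upsample(ux)
    out$field$dy <- out$field$dy + upsample(uy)
    ## an increment below the matching noise floor means the pair is
    ## aligned; stop instead of accumulating drift
    if (max(abs(c(ux, uy))) < 0.3) break
  }
  out$residual <- elastic_residual(reference, moving, out)
  out$degenerate <- FALSE
  out
}

## Iterative Lucas-Kanade translation estimate for one block: solve the
## normal equations of delta . grad(mov) = (ref - mov) and update until the
## step falls below 0.01 px.
lk_refine <- function(ref, mov, rx, ry, d = c(0, 0), n_iter = 10) {
  xs <- rep(rx, each = length(ry)); ys <- rep(ry, length(rx))
  rb <- as.vector(ref[ry, rx])
  for (k in seq_len(n_iter)) {
    v0 <- bilinear_sample(mov, xs + d[1], ys + d[2])
    gx <- (bilinear_sample(mov, xs + d[1] + 0.5, ys + d[2]) -
             bilinear_sample(mov, xs + d[1] - 0.5, ys + d[2]))
    gy <- (bilinear_sample(mov, xs + d[1], ys + d[2] + 0.5) -
             bilinear_sample(mov, xs + d[1], ys + d[2] - 0.5))
    ok <- !is.na(v0) & !is.na(gx) & !is.na(gy)
    if (sum(ok) < 20) return(c(NA_real_, NA_real_))
    e <- rb[ok] - v0[ok]
    G <- matrix(c(sum(gx[ok]^2), sum(gx[ok] * gy[ok]),
                  sum(gx[ok] * gy[ok]), sum(gy[ok]^2)), 2)
    if (abs(det(G)) < 1e-6) return(c(NA_real_, NA_real_))
    step <- solve(G, c(sum(gx[ok] * e), sum(gy[ok] * e)))
    d <- d + step
    if (max(abs(step)) < 0.01) break
  }
  d
}

#' Structural residual of an alignment
#'
#' Mean absolute difference of the unit-variance-normalised
#' gradient-magnitude images after applying the alignment. The gradient
#' channel is used because staining changes wall intensity but not wall
#' position; normalising removes the stain-dependent edge amplitude so the
#' score reflects geometric mismatch.
#'
#' @param reference,moving images.
#' @param a an `alignment`.
#' @return numeric residual (normalised gradient units).
#' @export
elastic_residual <- function(reference, moving, a = identity_alignment()) {
  ref <- gradient_magnitude(to_grey(reference))
  rs <- resample(to_grey(moving), a)
  g <- rs$image
  g[is.na(g)] <- mean(g, na.rm = TRUE)
  mov <- gradient_magnitude(g)
  mean(abs(mov / sd(mov) - ref / sd(ref))[rs$valid])
}

#' Discrete Laplacian bound of a displacement field
#'
#' Smoothness diagnostic: the maximum absolute 5-point Laplacian over both
#' components of the field.
#'
#' @param field list with `dx`, `dy` matrices.
#' @return numeric maximum absolute Laplacian (px).
#' @export
field_laplacian_max <- function(field) {
  lap <- function(m) {
    h <- nrow(m); w <- ncol(m)
    c0 <- m[2:(h - 1), 2:(w - 1)]
    l <- m[2:(h - 1), 1:(w - 2)] + m[2:(h - 1), 3:w] +
      m[1:(h - 2), 2:(w - 1)] + m[3:h, 2:(w - 1)] - 4 * c0
    max(abs(l))
  }
  max(lap(field$dx), lap(field$dy))
}

#' Serialise an alignment to JSON
#'
#' The rigid parameters go into the JSON document; a dense field, when
#' present, is written as a separate CSV referenced by path.
#'
#' @param a an `alignment`.
#' @param json_path output JSON file.
#' @param field_path CSV path for the dense field (required if present).
#' @return invisibly, `json_path`.
#' @export
write_alignment <- function(a, json_path, field_path = NULL) {
  doc <- list(dx = a$dx, dy = a$dy, theta_deg = a$theta_deg,
              residual = a$residual, field = NULL)
  if (!is.null(a$field)) {
    if (is.null(field_path)) stopf("field_path required for a dense field")
    fd <- data.frame(row = as.vector(row(a$field$dx)),
                     col = as.vector(col(a$field$dx)),
                     dx = as.vector(a$field$dx), dy = as.vector(a$field$dy))
    write.csv(fd, field_path, row.names = FALSE)
    doc$field <- field_path
  }
  jsonlite::write_json(doc, json_path, auto_unbox = TRUE, digits = NA)
  invisible(json_path)
}
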