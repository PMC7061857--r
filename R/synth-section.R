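#' Specify a synthetic stem cross-section
#'
#' Describes a section as annular cells (lumen surrounded by a lignified
#' wall) on a jittered lattice. Tangent cells share boundary pixels, which
#' stand in for the compound middle lamella and define the adjacency
#' structure. Walls carry a per-type true absorbance with mild multiplicative
#' texture (real walls are never optically uniform, and the heterogeneity
#' also dithers the 8-bit quantisation of the rendered images).
#'
#' @param cells data.frame with columns `id`, `type`, `cx`, `cy` (pixel
#'   centres), `r_px` (outer radius), `wall_px` (wall thickness, px). Usually
#'   built by [lattice_cells()].
#' @param width,height image size in pixels.
#' @param pitch_um pixel pitch (um/px). The default 0.179 makes a 12-px
#'   circular point 0.7 um in diameter.
#' @param type_absorbance named numeric vector: true wall absorbance per cell
#'   type; all values >= 0.
#' @param wall_texture_cv coefficient of variation of the multiplicative
#'   within-wall texture (0 disables it).
#' @param layer_multipliers optional named vector (`CML`, `S1`, `S2`, `S3`)
#'   scaling the wall absorbance by radial depth.
#' @param background_od scalar optical density of a residual section pigment
#'   (0 for ethanol-cleared sections); `background_hue` sets its colour.
#' @param background_hue hue (degrees) of the background pigment.
#' @param unstained_od achromatic baseline optical density of the walls,
#'   present in both frames: unstained sections are not featureless (wall
#'   material refracts and absorbs), which is what gives registration its
#'   landmarks; the stained-minus-unstained subtraction cancels it.
#' @param stain_hue hue (degrees) of the stain chromophore; the Wiesner
#'   purple sits near 310--330.
#' @param shift_px length-2 translation (dx, dy) of the stained frame.
#' @param rot_deg rotation (degrees) of the stained frame about the centre.
#' @param elastic_amp_px amplitude of a smooth sinusoidal elastic warp of the
#'   stained frame (0 disables it).
#' @param noise_sd i.i.d. Gaussian sensor noise, in 8-bit grey levels.
#' @param seed RNG seed.
#' @return object of class `section_spec`.
#' @export
section_spec <- function(cells, width, height, pitch_um = 0.179,
                         type_absorbance,
                         wall_texture_cv = 0.05,
                         layer_multipliers = NULL,
                         background_od = 0, background_hue = 60,
                         unstained_od = 0.15, stain_hue = 310,
                         shift_px = c(0, 0), rot_deg = 0, elastic_amp_px = 0,
                         noise_sd = 0, seed = 1L) {
  stopifnot(is.data.frame(cells),
            all(c("id", "type", "cx", "cy", "r_px", "wall_px") %in% names(cells)))
  if (pitch_um <= 0) stopf("pixel pitch must be > 0")
  if (noise_sd < 0) stopf("noise sd must be >= 0")
  if (any(type_absorbance < 0) || any(!is.finite(type_absorbance)))
    stopf("true absorbances must be finite and >= 0")
  miss <- setdiff(unique(cells$type), names(type_absorbance))
  if (length(miss)) stopf("no absorbance given for cell type(s): %s", paste(miss, collapse = ", "))
  structure(list(
    cells = cells, width = as.integer(width), height = as.integer(height),
    pitch_um = pitch_um, type_absorbance = type_absorbance,
    wall_texture_cv = wall_texture_cv, layer_multipliers = layer_multipliers,
    background_od = background_od, background_hue = background_hue,
    unstained_od = unstained_od,
    stain_hue = stain_hue, shift_px = shift_px, rot_deg = rot_deg,
    elastic_amp_px = elastic_amp_px, noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "section_spec")
}

#' Lay out annular cells on a jittered lattice
#'
#' @param types character vector of cell type labels, recycled over the
#'   lattice in shuffled order so that types mix spatially.
#' @param n_cells number of cells.
#' @param r_px outer cell radius (px); scalar or named per type.
#' @param wall_px wall thickness (px); scalar or named per type.
#' @param jitter_px uniform centre jitter.
#' @param seed RNG seed.
#' @param margin_px empty border kept around the lattice.
#' @param ncol_ lattice columns (default: near-square layout).
#' @param arrange `"random"` shuffles types over the lattice; `"stagger"`
#'   places every type in every lattice column (used for wood sections,
#'   where rays and vessels span all developmental distances).
#' @return list with `cells` data.frame and suggested `width`/`height`.
#' @export
lattice_cells <- function(types, n_cells = 4L * length(types), r_px = 22,
                          wall_px = 9, jitter_px = 1.5, seed = 1L,
                          margin_px = 8, ncol_ = NULL,
                          arrange = c("random", "stagger")) {
  arrange <- match.arg(arrange)
  set.seed(derive_seed(seed, "lattice"))
  if (is.null(ncol_)) ncol_ <- ceiling(sqrt(n_cells))
  nrow_ <- ceiling(n_cells / ncol_)
  rmax <- max(r_px)
  spacing <- 2 * rmax - 1 # tangent rings overlap by ~1 px: shared CML
  ij <- expand.grid(i = seq_len(ncol_), j = seq_len(nrow_))[seq_len(n_cells), ]
  type <- if (arrange == "stagger") {
    ## each lattice column carries every type (rays cross all of the xylem)
    types[(ij$i + ij$j) %% length(types) + 1L]
  } else {
    rep(types, length.out = n_cells)[sample.int(n_cells)]
  }
  r <- if (length(r_px) > 1) unname(r_px[type]) else rep(r_px, n_cells)
  w <- if (length(wall_px) > 1) unname(wall_px[type]) else rep(wall_px, n_cells)
  cells <- data.frame(
    id = seq_len(n_cells), type = type,
    cx = margin_px + rmax + (ij$i - 1) * spacing + runif(n_cells, -jitter_px, jitter_px),
    cy = margin_px + rmax + (ij$j - 1) * spacing + runif(n_cells, -jitter_px, jitter_px),
    r_px = r, wall_px = w
  )
  list(cells = cells,
       width = as.integer(ceiling(2 * (margin_px + rmax) + (ncol_ - 1) * spacing)),
       height = as.integer(ceiling(2 * (margin_px + rmax) + (nrow_ - 1) * spacing)))
}

#' Convenience spec mimicking an Arabidopsis stem section
#'
#' Five lignified cell types (PX, MX, XF, IF, LP) with the wild-type
#' relative absorbances used throughout: MX = XF = 1, IF = LP = 0.5,
#' PX = 0.25 (times `base_absorbance`).
#'
#' @param base_absorbance absorbance of the strongest types (MX/XF).
#' @param type_scale named relative scale per type.
#' @param cells_per_type lattice cells per type.
#' @param ... passed on to [section_spec()].
#' @inheritParams section_spec
#' @return a `section_spec`.
#' @export
arabidopsis_spec <- function(base_absorbance = 1,
                             type_scale = c(PX = 0.25, MX = 1, XF = 1, IF = 0.5, LP = 0.5),
                             cells_per_type = 4L, seed = 1L, ...) {
  lay <- lattice_cells(names(type_scale), n_cells = cells_per_type * length(type_scale),
                       seed = seed)
  section_spec(lay$cells, lay$width, lay$height,
               type_absorbance = base_absorbance * type_scale, seed = seed, ...)
}

## Rasterise the cell geometry: per-pixel cell id, neighbour id, and distance
## to own centre. Pixels belong to the nearest centre within its radius.
rasterize_cells <- function(spec) {
  w <- spec$width; h <- spec$height
  xs <- matrix(rep(seq_len(w), each = h), h)
  ys <- matrix(rep(seq_len(h), w), h)
  best <- matrix(Inf, h, w); second <- matrix(Inf, h, w)
  owner <- matrix(0L, h, w); nb <- matrix(0L, h, w)
  for (k in seq_len(nrow(spec$cells))) {
    d <- sqrt((xs - spec$cells$cx[k])^2 + (ys - spec$cells$cy[k])^2)
    closer <- d < best
    second[closer] <- best[closer]; nb[closer] <- owner[closer]
    take2 <- !closer & d < second
    second[take2] <- d[take2]; nb[take2] <- k
    best[closer] <- d[closer]; owner[closer] <- k
  }
  list(owner = owner, neighbor = nb, dist = best, dist2 = second)
}

#' Render a paired unstained/stained image from a section spec
#'
#' The optical model is Beer--Lambert in OD space: the stain's per-channel
#' optical density is the unit stain vector (set by `stain_hue`) scaled so
#' that the grey-intensity absorbance of the rendered pixel equals the
#' encoded true absorbance exactly, which makes
#' `log10(255/grey)` recovery the inverse of the rendering up to 8-bit
#' quantisation. Misregistration (and the optional elastic warp) is applied
#' to the stained frame only; sensor noise is added last; ground truth is
#' returned in the unstained (reference) frame.
#'
#' @param spec a [section_spec()].
#' @return list with `unstained`, `stained` (8-bit RGB arrays), and `truth`:
#'   `label` (cell id raster), `type` (character raster), `a_true` (true
#'   absorbance raster), `neighbor_id` (adjacent cell id per wall pixel, 0
#'   where the nearest context is the cell itself), `type_means` (area-
#'   weighted true mean per type), `adjacency` (cell id pairs sharing wall),
#'   `wall` (logical raster).
#' @export
render_pair <- function(spec) {
  set.seed(derive_seed(spec$seed, "render"))
  ras <- rasterize_cells(spec)
  h <- spec$height; w <- spec$width
  cells <- spec$cells
  r_own <- matrix(0, h, w); wall_own <- matrix(0, h, w)
  inside <- ras$owner > 0L & ras$dist <= cells$r_px[pmax(ras$owner, 1L)]
  owner <- ifelse(inside, ras$owner, 0L)
  r_own[inside] <- cells$r_px[owner[inside]]
  wall_own[inside] <- cells$wall_px[owner[inside]]
  wall <- inside & ras$dist > (r_own - wall_own)
  type <- matrix(NA_character_, h, w)
  type[inside] <- cells$type[owner[inside]]

  for (tt in unique(cells$type)) {
    if (!any(wall & !is.na(type) & type == tt))
      stopf("geometry produced zero wall pixels for declared cell type '%s'", tt)
  }

  ## neighbour context: a wall pixel is "adjacent to" the second-nearest cell
  ## when it also falls inside that cell's wall annulus (shared double wall).
  nb <- ras$neighbor
  nb_ok <- wall & nb > 0L & ras$dist2 <= (cells$r_px[pmax(nb, 1L)] + 1)
  neighbor_id <- matrix(0L, h, w)
  neighbor_id[nb_ok] <- nb[nb_ok]

  a_true <- matrix(0, h, w)
  a_scale <- if ("a_scale" %in% names(cells)) cells$a_scale[owner[wall]] else 1
  a_type <- spec$type_absorbance[cells$type[owner[wall]]] * a_scale
  tex <- if (spec$wall_texture_cv > 0) {
    exp(rnorm(sum(wall), -0.5 * log(1 + spec$wall_texture_cv^2),
              sqrt(log(1 + spec$wall_texture_cv^2))))
  } else 1
  a_true[wall] <- unname(a_type) * tex
  if (!is.null(spec$layer_multipliers)) {
    u <- (r_own[wall] - ras$dist[wall]) / wall_own[wall] # 0 CML side -> 1 lumen
    lm <- spec$layer_multipliers
    mlt <- ifelse(u < 0.08, lm[["CML"]],
                  ifelse(u < 0.25, lm[["S1"]],
                         ifelse(u < 0.9, lm[["S2"]], lm[["S3"]])))
    a_true[wall] <- a_true[wall] * mlt
  }

  ## adjacency list from shared wall pixels
  pr <- cbind(owner[neighbor_id > 0L], neighbor_id[neighbor_id > 0L])
  adjacency <- unique(data.frame(a = pmin(pr[, 1], pr[, 2]), b = pmax(pr[, 1], pr[, 2])))
  adjacency <- adjacency[order(adjacency$a, adjacency$b), , drop = FALSE]
  rownames(adjacency) <- NULL

  ## optics: achromatic wall baseline (both frames) + chromatic stain
  ## (stained frame only); grey-equivalent scaling keeps log10(255/grey)
  ## subtraction an exact inverse of the encoding.
  sv <- stain_vector(spec$stain_hue)
  lut <- grey_equivalent_lut(sv)
  baseline <- matrix(0, h, w)
  baseline[wall] <- spec$unstained_od * (if (length(tex) > 1) tex else 1)
  bg_od <- if (spec$background_od > 0) {
    spec$background_od * stain_vector(spec$background_hue)
  } else c(0, 0, 0)
  unst_float <- array(0, c(h, w, 3))
  st_float <- array(0, c(h, w, 3))
  tA <- matrix(0, h, w)
  tA[wall] <- approx(lut$A, lut$t, pmin(a_true[wall], max(lut$A)), rule = 2)$y
  for (ch in 1:3) {
    unst_float[, , ch] <- 255 * 10^(-(bg_od[ch] + baseline))
    st_float[, , ch] <- 255 * 10^(-(bg_od[ch] + baseline + sv[ch] * tA))
  }

  ## misregistration of the stained frame (inverse warp, bilinear)
  st_warp <- warp_frame(st_float, spec$shift_px, spec$rot_deg, spec$elastic_amp_px,
                        fill = 255 * 10^(-mean(bg_od)))

  quantise <- function(a) {
    if (spec$noise_sd > 0) a <- a + array(rnorm(length(a), 0, spec$noise_sd), dim(a))
    array(as.integer(round(clamp(a, 0, 255))), dim(a))
  }
  unstained <- quantise(unst_float)
  stained <- quantise(st_warp)

  tm <- vapply(split(a_true[wall], type[wall]), mean, 0)
  list(unstained = unstained, stained = stained,
       truth = list(label = owner, type = type, a_true = a_true,
                    neighbor_id = neighbor_id, wall = wall,
                    type_means = tm, adjacency = adjacency,
                    cells = cells, pitch_um = spec$pitch_um,
                    cambium = spec$cambium %||% NULL,
                    shift_px = spec$shift_px, rot_deg = spec$rot_deg))
}

#' Convenience spec mimicking a poplar wood section
#'
#' Vessels, fibers and rays on a lattice next to a vertical cambium line at
#' the left edge, with the wild-type relative absorbances
#' vessels = 1, rays = 0.75, fibers = 0.5 (times `base_absorbance`) and a
#' mild developmental gradient: walls further from the cambium are slightly
#' more absorbing, as maturing xylem keeps incorporating coniferaldehyde.
#' The coarser default pitch reflects the lower magnification used for wood.
#'
#' @param base_absorbance absorbance of vessels.
#' @param type_scale named relative scale per type.
#' @param cells_per_type lattice cells per type.
#' @param pitch_um pixel pitch (um/px).
#' @param gradient range of the developmental multiplier from the cambium to
#'   the far edge (length-2).
#' @param seed RNG seed.
#' @param ... passed on to [section_spec()].
#' @return a `section_spec` whose `cambium` field holds the polyline (px).
#' @export
poplar_spec <- function(base_absorbance = 0.6,
                        type_scale = c(vessel = 1, ray = 0.75, fiber = 0.5),
                        cells_per_type = 8L, pitch_um = 0.5,
                        gradient = c(0.85, 1.15), seed = 1L, ...) {
  n <- cells_per_type * length(type_scale)
  lay <- lattice_cells(names(type_scale), n_cells = n, seed = seed,
                       ncol_ = ceiling(n / 3), arrange = "stagger")
  cambium_x <- 4
  depth <- lay$cells$cx - cambium_x
  lay$cells$a_scale <- gradient[1] +
    (gradient[2] - gradient[1]) * clamp(depth / max(depth), 0, 1)
  sp <- section_spec(lay$cells, lay$width, lay$height, pitch_um = pitch_um,
                     type_absorbance = base_absorbance * type_scale,
                     seed = seed, ...)
  sp$cambium <- cbind(x = c(cambium_x, cambium_x), y = c(1, lay$height))
  sp
}

## Lookup table mapping true grey absorbance A to the stain-vector scale t
## with mean_c 10^(-d_c t) = 10^(-A): rendering through a chromatic stain
## whose grey-intensity absorbance is exactly A.
grey_equivalent_lut <- function(stain_dir) {
  t <- seq(0, 25, by = 0.01)
  A <- -log10((10^(-stain_dir[1] * t) + 10^(-stain_dir[2] * t) + 10^(-stain_dir[3] * t)) / 3)
  list(t = t, A = A)
}

## Inverse-warp a float image: output pixel q samples the source at
## R^-1 (q - c - shift) + c, minus an optional smooth sinusoidal field.
warp_frame <- function(img, shift_px, rot_deg, elastic_amp = 0, fill = 255) {
  if (all(shift_px == 0) && rot_deg == 0 && elastic_amp == 0) return(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  xs <- matrix(rep(seq_len(w), each = h), h) - cx
  ys <- matrix(rep(seq_len(h), w), h) - cy
  th <- -rot_deg * pi / 180
  sx <- cos(th) * (xs - shift_px[1]) - sin(th) * (ys - shift_px[2]) + cx
  sy <- sin(th) * (xs - shift_px[1]) + cos(th) * (ys - shift_px[2]) + cy
  if (elastic_amp > 0) {
    sx <- sx + elastic_amp * sin(2 * pi * ys / (0.9 * h)) * cos(pi * xs / w)
    sy <- sy + elastic_amp * sin(2 * pi * xs / (0.8 * w))
  }
  out <- array(fill, dim(img))
  for (ch in seq_len(dim(img)[3])) {
    v <- bilinear_sample(img[, , ch], as.vector(sx), as.vector(sy))
    v[is.na(v)] <- fill
    out[, , ch] <- matrix(v, h)
  }
  out
}

#' Write a rendered pair and its ground truth to disk
#'
#' Images go out as 8-bit RGB TIFF, the label raster as 16-bit single-channel
#' TIFF, ground-truth summaries as CSV.
#'
#' @param pair result of [render_pair()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_pair <- function(pair, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- c(unstained = file.path(dir, "unstained.tif"),
         stained = file.path(dir, "stained.tif"),
         labels = file.path(dir, "labels.tif"),
         type_means = file.path(dir, "type_means.csv"),
         adjacency = file.path(dir, "adjacency.csv"))
  tiff::writeTIFF(pair$unstained / 255, f[["unstained"]])
  tiff::writeTIFF(pair$stained / 255, f[["stained"]])
  tiff::writeTIFF(pair$truth$label / 65535, f[["labels"]], bits.per.sample = 16L)
  write.csv(data.frame(type = names(pair$truth$type_means),
                       mean_absorbance = unname(pair$truth$type_means)),
            f[["type_means"]], row.names = FALSE)
  write.csv(pair$truth$adjacency, f[["adjacency"]], row.names = FALSE)
  invisible(f)
}
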