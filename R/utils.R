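#' @keywords internal
"_PACKAGE"

#' @importFrom stats aov TukeyHSD approx cor cor.test dist hclust kruskal.test
#'   median optim p.adjust prcomp pt qchisq quantile rnorm runif sd setNames var
#' @importFrom grDevices hsv rgb2hsv hcl.colors col2rgb
#' @importFrom utils head read.csv write.csv
NULL

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Derive a stage-specific RNG seed from a global seed
#'
#' A single pipeline seed is fanned out to stages by mixing in a stage label,
#' so one integer reproduces every stochastic stage while keeping the streams
#' distinct. The result always fits in a 32-bit signed integer.
#'
#' @param seed integer global seed.
#' @param stage character stage label.
#' @return integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 69069 + h * 1013) %% 2147483647)
}

## Convert an RGB array (h x w x 3, values 0..255) to its grey intensity
## (mean of channels), the luminance collapse applied before the absorbance
## formula.
to_grey <- function(img) {
  if (length(dim(img)) == 2L) return(img)
  (img[, , 1] + img[, , 2] + img[, , 3]) / 3
}

## Bilinear sampling of a matrix at fractional (x, y) positions, 1-based
## (x = column, y = row). Positions outside the grid return NA.
bilinear_sample <- function(mat, x, y) {
  nr <- nrow(mat); nc <- ncol(mat)
  out <- rep(NA_real_, length(x))
  ok <- x >= 1 & x <= nc & y >= 1 & y <= nr & is.finite(x) & is.finite(y)
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]
  x0 <- pmin(floor(x), nc - 1L); y0 <- pmin(floor(y), nr - 1L)
  fx <- x - x0; fy <- y - y0
  i00 <- (x0 - 1) * nr + y0
  v <- (1 - fx) * (1 - fy) * mat[i00] +
    fx * (1 - fy) * mat[i00 + nr] +
    (1 - fx) * fy * mat[i00 + 1] +
    fx * fy * mat[i00 + nr + 1]
  out[ok] <- v
  out
}

## Pixel offsets (dx, dy) of a quasi-circular neighbourhood of exactly
## `area_px` pixels, used for circular measurement points. Offsets are the
## `area_px` pixels closest to the centre with a deterministic tie-break.
circle_offsets <- function(area_px) {
  r <- ceiling(sqrt(area_px / pi)) + 1L
  g <- expand.grid(dx = -r:r, dy = -r:r)
  d <- g$dx^2 + g$dy^2
  o <- order(d, abs(g$dx), abs(g$dy), g$dx, g$dy)
  g[o[seq_len(area_px)], , drop = FALSE]
}
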