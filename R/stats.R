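## Compact letter display from a symmetric matrix of pairwise p-values,
## by the standard insert-and-absorb algorithm: start from one letter
## covering all groups; each significant pair splits every letter column
## containing both; columns that become subsets of others are absorbed.
letters_from_pmat <- function(pmat, alpha) {
  k <- nrow(pmat)
  labs <- rownames(pmat)
  cols <- list(rep(TRUE, k))
  sig <- which(pmat < alpha & upper.tri(pmat), arr.ind = TRUE)
  if (nrow(sig)) {
    for (s in seq_len(nrow(sig))) {
      i <- sig[s, 1]; j <- sig[s, 2]
      for (ci in seq_along(cols)) {
        cl <- cols[[ci]]
        if (cl[i] && cl[j]) {
          c1 <- cl; c1[i] <- FALSE
          cols[[ci]] <- c1
          c2 <- cl; c2[j] <- FALSE
          cols[[length(cols) + 1L]] <- c2
        }
      }
      keep <- rep(TRUE, length(cols))
      for (a in seq_along(cols)) {
        for (b in seq_along(cols)) {
          if (a == b || !keep[a] || !keep[b]) next
          if (all(cols[[a]] <= cols[[b]]) && (any(cols[[b]] & !cols[[a]]) || a > b))
            keep[a] <- FALSE
        }
      }
      cols <- cols[keep]
    }
  }
  ord <- order(vapply(cols, function(cl) which(cl)[1], 0L))
  cols <- cols[ord]
  out <- vapply(seq_len(k), function(g)
    paste(letters[which(vapply(cols, function(cl) cl[g], TRUE))], collapse = ""), "")
  setNames(out, labs)
}

## Order groups deterministically: decreasing mean, label as tie-break.
.order_groups <- function(groups) {
  mns <- vapply(groups, mean, 0)
  groups[order(-mns, names(groups))]
}

#' Tukey-HSD compact letter display
#'
#' One-way ANOVA followed by Tukey's honest significant difference on all
#' group pairs; groups sharing a letter are not significantly different at
#' `alpha`.
#'
#' @param groups named list of numeric vectors (>= 2 groups; single-group
#'   input returns letter "a").
#' @param alpha significance level.
#' @return list: `letters` (named, in input order), `pairs` data.frame with
#'   Tukey-adjusted p-values, `means`.
#' @export
tukey_letters <- function(groups, alpha = 0.05) {
  if (length(groups) == 1L)
    return(list(letters = setNames("a", names(groups)),
                pairs = NULL, means = vapply(groups, mean, 0)))
  if (any(vapply(groups, length, 0L) < 2)) stopf("each group needs >= 2 values")
  og <- .order_groups(groups)
  d <- data.frame(y = unlist(og, use.names = FALSE),
                  g = factor(rep(names(og), lengths(og)), levels = names(og)))
  if (all(vapply(og, var, 0) == 0))
    stopf("zero within-group variance everywhere; Tukey HSD undefined")
  fit <- aov(y ~ g, data = d)
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$g
  pmat <- matrix(1, length(og), length(og), dimnames = list(names(og), names(og)))
  prs <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (i in seq_along(prs)) {
    a <- prs[[i]][1]; b <- prs[[i]][2]
    pmat[a, b] <- pmat[b, a] <- tk[i, "p adj"]
  }
  lt <- letters_from_pmat(pmat, alpha)
  list(letters = lt[names(groups)],
       pairs = data.frame(pair = rownames(tk), p_adj = tk[, "p adj"]),
       means = vapply(groups, mean, 0))
}

#' Kruskal--Wallis compact letter display with Holm adjustment
#'
#' Pairwise Kruskal--Wallis tests across all group pairs of a panel,
#' Holm-adjusted, then the same letter assignment as [tukey_letters()].
#'
#' @inheritParams tukey_letters
#' @return list: `letters`, `pairs` (raw and Holm-adjusted p).
#' @export
kruskal_holm <- function(groups, alpha = 0.05) {
  if (length(groups) == 1L)
    return(list(letters = setNames("a", names(groups)), pairs = NULL))
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  og <- .order_groups(groups)
  nm <- names(og)
  cmb <- utils::combn(length(og), 2)
  praw <- apply(cmb, 2, function(ij)
    kruskal.test(list(og[[ij[1]]], og[[ij[2]]]))$p.value)
  padj <- p.adjust(praw, method = "holm")
  pmat <- matrix(1, length(og), length(og), dimnames = list(nm, nm))
  for (i in seq_len(ncol(cmb)))
    pmat[cmb[1, i], cmb[2, i]] <- pmat[cmb[2, i], cmb[1, i]] <- padj[i]
  lt <- letters_from_pmat(pmat, alpha)
  list(letters = lt[names(groups)],
       pairs = data.frame(pair = paste(nm[cmb[1, ]], nm[cmb[2, ]], sep = "-"),
                          p_raw = praw, p_holm = padj))
}

#' Hierarchical clustering of genotypes on range-normalised differences
#'
#' Each column (cell type, or cell type by stage) of the genotype-by-trait
#' matrix of mean differences from the wild type is scaled to \[0, 1\] by
#' its range; genotypes are then clustered on Euclidean distances with
#' average linkage.
#'
#' @param m numeric matrix: rows = genotypes, columns = traits (mean
#'   absorbance difference from WT).
#' @param linkage agglomeration method (recorded in the output).
#' @return list: `hclust` object, `dist`, `dropped` (constant columns),
#'   `linkage`.
#' @export
cluster_genotypes <- function(m, linkage = "average") {
  if (nrow(m) < 3) stopf("need >= 3 genotypes")
  rng <- apply(m, 2, function(x) diff(range(x)))
  keep <- rng > 0
  dropped <- if (is.null(colnames(m))) which(!keep) else colnames(m)[!keep]
  if (any(!keep)) {
    warning("constant column(s) excluded: ", paste(dropped, collapse = ", "))
    m <- m[, keep, drop = FALSE]
  }
  ms <- sweep(sweep(m, 2, apply(m, 2, min)), 2, apply(m, 2, function(x) diff(range(x))), "/")
  d <- dist(ms)
  list(hclust = hclust(d, method = linkage), dist = d,
       dropped = dropped, linkage = linkage)
}

#' PCA with 95\% data ellipses
#'
#' Column-centred (not variance-scaled) principal components; for each
#' group, a bivariate-normal quantile ellipse on the first two scores.
#'
#' @param m numeric matrix of observations x variables.
#' @param groups optional factor of group labels per row.
#' @param level ellipse coverage level.
#' @return list: `pca` (prcomp), `scores`, `explained` (fractions),
#'   `ellipses` (named list of x/y paths).
#' @export
pca_celltypes <- function(m, groups = NULL, level = 0.95) {
  if (nrow(m) < 3) stopf("need >= 3 observations")
  if (qr(scale(m, scale = FALSE))$rank < 2) stopf("input has rank < 2")
  p <- prcomp(m, center = TRUE, scale. = FALSE)
  expl <- p$sdev^2 / sum(p$sdev^2)
  ell <- NULL
  if (!is.null(groups)) {
    ell <- lapply(split(seq_len(nrow(m)), groups), function(ix) {
      s <- p$x[ix, 1:2, drop = FALSE]
      data_ellipse(s, level)
    })
  }
  list(pca = p, scores = p$x, explained = expl, ellipses = ell)
}

#' Bivariate normal quantile ellipse of a 2-D point cloud
#'
#' @param s two-column matrix of points.
#' @param level coverage level.
#' @param k number of path points.
#' @return list: `x`, `y` (closed path), `center`, `cov`, `radius2`
#'   (squared Mahalanobis radius).
#' @export
data_ellipse <- function(s, level = 0.95, k = 181) {
  mu <- colMeans(s)
  S <- stats::cov(s)
  r2 <- qchisq(level, df = 2)
  th <- seq(0, 2 * pi, length.out = k)
  circ <- rbind(cos(th), sin(th)) * sqrt(r2)
  path <- t(chol(S)) %*% circ + mu
  list(x = path[1, ], y = path[2, ], center = mu, cov = S, radius2 = r2)
}

#' Correlation panel between predictor and response series
#'
#' Pearson r, explained variance and two-sided p for each predictor/response
#' pair; pairs with p >= `alpha` carry a display-masking flag (values are
#' retained), pairs with zero variance are flagged undefined.
#'
#' @param pairs named list; each element a list/data.frame with elements
#'   `x` and `y` of equal length (n >= 3).
#' @param alpha masking level.
#' @return data.frame: `pair`, `n`, `r`, `R2`, `p`, `masked`, `undefined`.
#' @export
correlation_panel <- function(pairs, alpha = 0.05) {
  out <- lapply(names(pairs), function(nm) {
    x <- pairs[[nm]]$x; y <- pairs[[nm]]$y
    if (length(x) != length(y) || length(x) < 3) stopf("pair '%s': need paired series, n >= 3", nm)
    if (any(!is.finite(x)) || any(!is.finite(y))) stopf("pair '%s': non-finite values", nm)
    if (sd(x) == 0 || sd(y) == 0)
      return(data.frame(pair = nm, n = length(x), r = NA_real_, R2 = NA_real_,
                        p = NA_real_, masked = TRUE, undefined = TRUE))
    ct <- cor.test(x, y)
    r <- unname(ct$estimate)
    data.frame(pair = nm, n = length(x), r = r, R2 = r^2, p = ct$p.value,
               masked = ct$p.value >= alpha, undefined = FALSE)
  })
  do.call(rbind, out)
}

#' Per-wavenumber correlation between spectra and a response
#'
#' For each wavenumber (column) of a sample-by-wavenumber intensity matrix,
#' the Pearson correlation with a per-sample response (e.g. Wiesner
#' absorbance) across samples.
#'
#' @param spectra numeric matrix, samples x wavenumbers; column names (or
#'   `grid`) give the wavenumber axis.
#' @param response numeric vector, one value per sample (>= 4 samples).
#' @param grid optional numeric wavenumber grid; must match `ncol(spectra)`.
#' @return data.frame: `wavenumber`, `r`, `p`, `undefined`.
#' @export
spectral_correlation_map <- function(spectra, response, grid = NULL) {
  if (is.null(grid)) grid <- as.numeric(colnames(spectra))
  if (length(grid) != ncol(spectra)) stopf("wavenumber grid does not match the spectra")
  if (nrow(spectra) != length(response)) stopf("one response value per sample required")
  if (nrow(spectra) < 4) stopf("need >= 4 samples")
  res <- apply(spectra, 2, function(col) {
    if (sd(col) == 0) return(c(NA_real_, NA_real_, 1))
    ct <- cor.test(col, response)
    c(unname(ct$estimate), ct$p.value, 0)
  })
  data.frame(wavenumber = grid, r = res[1, ], p = res[2, ],
             undefined = res[3, ] == 1, row.names = NULL)
}

#' Rolling-minimum baseline (optional spectral utility)
#'
#' A simple baseline estimate: rolling minimum over a window, then a rolling
#' mean of the same width to smooth the staircase. Off by default everywhere;
#' provided for spectra that arrive without vendor baseline correction.
#'
#' @param y intensity vector.
#' @param window odd window width (points).
#' @return baseline vector, same length.
#' @export
rolling_min_baseline <- function(y, window = 51) {
  n <- length(y); hw <- window %/% 2
  mins <- vapply(seq_len(n), function(i)
    min(y[max(1, i - hw):min(n, i + hw)]), 0)
  vapply(seq_len(n), function(i)
    mean(mins[max(1, i - hw):min(n, i + hw)]), 0)
}
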