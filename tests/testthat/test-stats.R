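test_that("Tukey letters separate a clear outlier group and stay consistent", {
  set.seed(31)
  g <- list(a1 = rnorm(5, 0, 0.1), a2 = rnorm(5, 0, 0.1), b = rnorm(5, 10, 0.1))
  tl <- tukey_letters(g)
  expect_equal(tl$letters[["a1"]], tl$letters[["a2"]])
  expect_false(tl$letters[["b"]] == tl$letters[["a1"]])

  expect_equal(unname(tukey_letters(list(only = 1:5))$letters), "a")
  expect_error(tukey_letters(list(a = c(1, 1), b = c(2, 2))), "zero within-group")

  ## consistency on arbitrary data: significant pairs never share a letter,
  ## non-significant pairs always do
  set.seed(32)
  g2 <- lapply(setNames(seq(0, 2, length.out = 5), paste0("g", 1:5)),
               function(m) rnorm(6, m, 0.5))
  tl2 <- tukey_letters(g2)
  for (i in seq_len(nrow(tl2$pairs))) {
    ab <- strsplit(tl2$pairs$pair[i], "-", fixed = TRUE)[[1]]
    shares <- any(strsplit(tl2$letters[[ab[1]]], "")[[1]] %in%
                    strsplit(tl2$letters[[ab[2]]], "")[[1]])
    expect_equal(shares, tl2$pairs$p_adj[i] >= 0.05)
  }
})

test_that("Kruskal-Wallis letters use Holm-monotone p-values and separate shifted groups", {
  set.seed(33)
  g <- list(lo = rnorm(20), mid = rnorm(20), hi = rnorm(20) + 10)
  kh <- kruskal_holm(g)
  ord <- order(kh$pairs$p_raw)
  expect_true(all(diff(kh$pairs$p_holm[ord]) >= -1e-12))
  expect_true(all(kh$pairs$p_holm >= kh$pairs$p_raw))
  expect_false(kh$letters[["hi"]] == kh$letters[["lo"]])
  expect_equal(kh$letters[["lo"]], kh$letters[["mid"]])
})

test_that("identical groups share a Tukey letter at about the nominal rate", {
  set.seed(34)
  share <- vapply(seq_len(200), function(i) {
    g <- lapply(setNames(1:3, c("a", "b", "c")), function(j) rnorm(5))
    lt <- tukey_letters(g)$letters
    length(unique(lt)) == 1
  }, TRUE)
  expect_gte(mean(share), 0.9)
})

test_that("genotype clustering uses range-normalised distances invariant to column scaling", {
  m <- rbind(WT = c(0, 0), m1 = c(1, 2), m2 = c(1, 2), m3 = c(4, 8))
  cl <- cluster_genotypes(m)
  mrg <- cl$hclust$merge
  h0 <- cl$hclust$height[which(apply(mrg, 1, function(r) all(r < 0)))]
  expect_true(any(h0 < 1e-12)) # duplicate rows merge at height zero

  d1 <- as.matrix(cl$dist)
  m2 <- sweep(sweep(m, 2, c(2, 0.1), "*"), 2, c(5, -3), "+")
  d2 <- as.matrix(cluster_genotypes(m2)$dist)
  expect_equal(d1, d2, tolerance = 1e-12)

  ## one informative column: distances are |x - y| / range
  m3 <- cbind(c(WT = 0, m1 = 1, m2 = 4), c(1, 1, 1))
  expect_warning(cl3 <- cluster_genotypes(m3), "constant")
  expect_equal(as.matrix(cl3$dist)[1, 3], 1, tolerance = 1e-12)
  expect_equal(as.matrix(cl3$dist)[1, 2], 0.25, tolerance = 1e-12)
})

test_that("PCA explains collinear data on one axis and is rotation invariant", {
  x <- rnorm(20)
  m <- cbind(x, 2 * x)
  expect_error(pca_celltypes(m), "rank")
  m2 <- cbind(x, 2 * x + rnorm(20, 0, 1e-5))
  p2 <- pca_celltypes(m2)
  expect_equal(p2$explained[1], 1, tolerance = 1e-8)

  set.seed(36)
  m3 <- matrix(rnorm(60), 20)
  th <- 0.7
  R <- diag(3); R[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  e1 <- pca_celltypes(m3)$explained
  e2 <- pca_celltypes(m3 %*% R)$explained
  expect_equal(e1, e2, tolerance = 1e-9)
})

test_that("correlation panels report r, R-squared and masking flags", {
  x <- 1:20
  cp <- correlation_panel(list(lin = list(x = x, y = 2 * x + 1),
                               anti = list(x = x, y = -(2 * x + 1)),
                               flat = list(x = x, y = rep(3, 20))))
  expect_equal(cp$r[cp$pair == "lin"], 1, tolerance = 1e-9)
  expect_equal(cp$r[cp$pair == "anti"], -1, tolerance = 1e-9)
  expect_equal(cp$R2, cp$r^2, tolerance = 1e-12)
  expect_true(cp$undefined[cp$pair == "flat"])

  set.seed(37)
  a <- rnorm(30); b <- rnorm(30)
  r1 <- correlation_panel(list(p = list(x = a, y = b)))$r
  r2 <- correlation_panel(list(p = list(x = a, y = -b)))$r
  expect_equal(r1, -r2, tolerance = 1e-12)
})

test_that("spectral correlation maps flag the encoded band and ignore sample order", {
  set.seed(38)
  n <- 8; k <- 30
  dA <- runif(n, 0.2, 1)
  spectra <- matrix(rnorm(n * k, 10, 0.01), n, k)
  spectra[, 12] <- 5 * dA
  spectra[, 20] <- 7 # constant band
  colnames(spectra) <- 100 + seq_len(k)
  sm <- spectral_correlation_map(spectra, dA)
  expect_equal(sm$r[12], 1, tolerance = 1e-9)
  expect_true(all(abs(sm$r[-c(12, 20)]) < 0.9))
  expect_true(sm$undefined[20])

  perm <- sample.int(n)
  sm2 <- spectral_correlation_map(spectra[perm, ], dA[perm])
  expect_equal(sm$r, sm2$r, tolerance = 1e-12)
  expect_error(spectral_correlation_map(spectra[, 1:5], dA, grid = 1:4),
               "grid")
})
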