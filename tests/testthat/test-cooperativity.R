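test_that("adjacency datasets aggregate context means and drop incomplete units", {
  tab <- data.frame(genotype = rep(c("WT", "m1", "m2"), each = 8),
                    replicate = rep(c(1, 1, 2, 2), 6),
                    cell_type = "A",
                    adjacent_to = rep(c("self", "B"), 12),
                    absorbance = 0.5)
  tab <- rbind(tab, within(tab, { cell_type <- "B"; adjacent_to <- "self" }))
  ds <- build_adjacency_dataset(tab, data.frame(source = "B", target = "A"))
  expect_true(all(ds$means$mean_dA == 0.5))
  expect_equal(length(ds$units), 6)

  ## a unit missing the adjacent context is dropped for that pair
  tab2 <- tab[!(tab$genotype == "m1" & tab$replicate == 2 &
                  tab$adjacent_to == "B"), ]
  tab2$absorbance <- tab2$absorbance + seq_len(nrow(tab2)) / 100
  ds2 <- build_adjacency_dataset(tab2, data.frame(source = "B", target = "A"))
  e2 <- delta_r(ds2, "B", "A")
  expect_equal(e2$n, 5)

  expect_error(
    build_adjacency_dataset(tab, data.frame(source = "A", target = "B")),
    "no requested pair")
})

test_that("delta_r hits the perfect-correlation and zero-variance corners", {
  set.seed(1)
  units <- expand.grid(genotype = paste0("g", 1:6), replicate = 1:2)
  b <- runif(nrow(units), 0.3, 1)
  mk <- function(type, ctx, val) data.frame(genotype = units$genotype,
                                            replicate = units$replicate,
                                            cell_type = type, adjacent_to = ctx,
                                            absorbance = val)
  tab <- rbind(mk("B", "self", b), mk("A", "B", b), # adjacent-to-B equals B
               mk("A", "self", runif(nrow(units), 0.3, 1)))
  ds <- build_adjacency_dataset(tab, data.frame(source = "B", target = "A"))
  e <- delta_r(ds, "B", "A")
  expect_equal(e$r_adj, 1, tolerance = 1e-12)
  expect_true(e$delta_r >= -2 && e$delta_r <= 2)

  tab0 <- rbind(mk("B", "self", 0.5), mk("A", "B", 0.5), mk("A", "self", 0.5))
  ds0 <- build_adjacency_dataset(tab0, data.frame(source = "B", target = "A"))
  expect_true(delta_r(ds0, "B", "A")$undefined)
})

test_that("williams test: null identity, degenerate input, bootstrap agreement", {
  wt <- williams_test(0.5, 0.5, 0.7, 30)
  expect_equal(wt$t, 0)
  expect_equal(wt$p, 1)
  expect_error(williams_test(1, 0.5, 0.5, 30), "degenerate")

  ## frozen dataset: the t-approximation agrees with a percentile bootstrap
  set.seed(123)
  n <- 30
  z <- rnorm(n); x1 <- 0.5 * z + rnorm(n); x2 <- 0.3 * z + 0.4 * x1 + rnorm(n)
  p_t <- williams_test(cor(x1, z), cor(x2, z), cor(x1, x2), n)$p
  set.seed(99)
  dstar <- replicate(1e4, {
    i <- sample.int(n, replace = TRUE)
    cor(x1[i], z[i]) - cor(x2[i], z[i])
  })
  p_boot <- 2 * min(mean(dstar <= 0), mean(dstar >= 0))
  expect_lt(abs(p_t - p_boot), 0.02)
})

test_that("relative impact is a scale-invariant fold change with guarded denominators", {
  tab <- make_measurement_sets(c("A", "B"), list(WT = c(A = 1, B = 1),
                                                 m = c(A = 0.5, B = 1)),
                               n_reps = 3, rep_cv = 0, point_cv = 0, seed = 1)
  ds <- build_adjacency_dataset(tab, data.frame(source = "B", target = "A"))
  expect_equal(relative_impact(ds, "B", "A"), 1, tolerance = 1e-12)

  tab2 <- tab
  tab2$absorbance[tab2$cell_type == "A" & tab2$adjacent_to == "B"] <-
    2 * tab2$absorbance[tab2$cell_type == "A" & tab2$adjacent_to == "B"]
  ds2 <- build_adjacency_dataset(tab2, data.frame(source = "B", target = "A"))
  expect_equal(relative_impact(ds2, "B", "A"), 2, tolerance = 1e-12)

  tab3 <- tab2; tab3$absorbance <- tab3$absorbance * 7.3
  ds3 <- build_adjacency_dataset(tab3, data.frame(source = "B", target = "A"))
  expect_equal(relative_impact(ds3, "B", "A"),
               relative_impact(ds2, "B", "A"), tolerance = 1e-12)

  tab4 <- tab; tab4$absorbance[tab4$adjacent_to == "self" &
                                 tab4$cell_type == "A"] <- 0
  ds4 <- build_adjacency_dataset(tab4, data.frame(source = "B", target = "A"))
  expect_error(relative_impact(ds4, "B", "A"), "non-positive")
})

test_that("network assembly encodes attributes and round-trips through JSON", {
  e <- structure(list(source = "B", target = "A", n = 10, r_adj = 0.9,
                      r_self = 0.3, r_between = 0.8, undefined = FALSE,
                      t = 3.2, p = 0.01, delta_r = 0.6),
                 class = "cooperativity_edge")
  net <- build_network(list(e), impacts = c("B->A" = 1.4))
  expect_equal(net$edges$significant, TRUE)
  expect_equal(net$edges$impact, 1.4)
  expect_s3_class(net$graph, "igraph")

  tmp <- tempfile(fileext = ".json")
  write_network(net, json_path = tmp)
  back <- read_network(tmp)
  expect_equal(back$edges$delta_r, net$edges$delta_r)
  expect_equal(back$edges$p, net$edges$p)
  expect_equal(back$nodes, net$nodes)
})

test_that("an encoded directed cooperation is detected with the right sign and rank", {
  types <- c("A", "B", "C")
  eff <- default_genotype_effects(types)
  hits <- logical(20); ranks <- logical(20); signs <- logical(20)
  for (s in seq_len(20)) {
    tab <- make_measurement_sets(types, eff, n_reps = 5, seed = 3000 + s,
                                 cooperativity = data.frame(source = "B",
                                                            target = "A",
                                                            weight = 0.5))
    net <- cooperativity_network(tab)
    ed <- net$edges
    i <- ed$source == "B" & ed$target == "A"
    hits[s] <- ed$significant[i] && ed$delta_r[i] > 0
    ranks[s] <- which.max(abs(ed$delta_r)) == which(i)
  }
  expect_gte(mean(hits), 0.9)
  expect_gte(mean(ranks), 0.9)
})
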