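test_that("per-million normalization scales by mapped totals and preserves zeros", {
  cm <- toy_count_matrix(matrix(c(54, 0, 10, 20), 2, 2), n_forg = 1,
                         mapped_totals = c(1e6, 2e6))
  nc <- normalize_counts(cm)
  expect_equal(nc$counts[1, 1], 54)
  expect_equal(nc$counts[2, 1], 0)
  expect_equal(nc$counts[1, 2], 5)   # 10 * 1e6 / 2e6
  # doubling counts and totals leaves values unchanged
  cm2 <- toy_count_matrix(2 * cm$counts, n_forg = 1,
                          mapped_totals = 2 * c(1e6, 2e6))
  expect_equal(normalize_counts(cm2)$counts, nc$counts)
  cm_bad <- cm; cm_bad$mapped_totals[1] <- 0
  expect_error(normalize_counts(cm_bad), "zero")
})

test_that("three-state fit recovers the mixture and is a local likelihood maximum", {
  # degenerate all-zero vector: p0 = 1, no log-normal component
  f0 <- fit_three_state(rep(0, 50))
  expect_equal(f0$p0, 1)
  expect_true(is.na(f0$meanlog))
  expect_error(fit_three_state(c(rep(0, 10), 5, 5, 5)), "distinct")

  # simulation at the stated parameters: estimates close to truth
  set.seed(42)
  n <- 5000
  truth <- list(p0 = 0.3, p1 = 0.1, meanlog = 3, sdlog = 1)
  state <- sample(c("zero", "one", "ln"), n, TRUE,
                  prob = c(truth$p0, truth$p1, 1 - truth$p0 - truth$p1))
  x <- numeric(n)
  x[state == "one"] <- 1
  ln_idx <- which(state == "ln")
  # log-normal truncated to (1, Inf) by inverse-cdf sampling
  u <- runif(length(ln_idx))
  p_lo <- plnorm(1, truth$meanlog, truth$sdlog)
  x[ln_idx] <- qlnorm(p_lo + u * (1 - p_lo), truth$meanlog, truth$sdlog)
  fit <- fit_three_state(x)
  expect_equal(fit$p0, mean(x == 0))
  expect_equal(fit$p1, mean(x == 1))
  expect_lt(abs(fit$meanlog - truth$meanlog), 0.1)
  expect_lt(abs(fit$sdlog - truth$sdlog), 0.05)

  # the fitted (meanlog, sdlog) beat every point of a surrounding 5x5 grid
  ll <- function(m, s) {
    y <- x[x > 1]
    sum(dlnorm(y, m, s, log = TRUE)) - length(y) * log1p(-plnorm(1, m, s))
  }
  base <- ll(fit$meanlog, fit$sdlog)
  for (dm in seq(-0.2, 0.2, length.out = 5)) {
    for (ds in seq(-0.1, 0.1, length.out = 5)) {
      expect_lte(ll(fit$meanlog + dm, fit$sdlog + ds), base + 1e-6)
    }
  }
})

test_that("the diet LRT is near zero under identity and huge under separation", {
  set.seed(9)
  x <- c(rep(0, 300), rep(1, 80), exp(rnorm(620, 3, 1)) + 1)
  f <- fit_three_state(x)
  lrt <- lrt_diets(f, f, fit_three_state(c(x, x)))
  expect_gte(lrt$statistic, 0)
  expect_lt(lrt$statistic, 1)
  expect_gt(lrt$p_value, 0.9)

  # meanlog differing by 2 at 5000 nodes
  gen <- function(meanlog) {
    s <- sample(c(0, 1, 2), 5000, TRUE, prob = c(0.3, 0.1, 0.6))
    v <- numeric(5000); v[s == 1] <- 1
    v[s == 2] <- qlnorm(plnorm(1, meanlog, 1) +
                          runif(sum(s == 2)) * (1 - plnorm(1, meanlog, 1)),
                        meanlog, 1)
    v
  }
  a <- gen(2); b <- gen(4)
  lrt2 <- lrt_diets(fit_three_state(a), fit_three_state(b),
                    fit_three_state(c(a, b)))
  expect_lt(lrt2$p_value, 1e-10)
  # the df = 5 reporting convention is available
  expect_equal(lrt_diets(f, f, fit_three_state(c(x, x)), df = 5)$df, 5)
})

test_that("per-node rank-sum tests handle ties, attain the exact extreme P, and control FDR", {
  # identical values in all animals -> P = 1
  m <- matrix(5, 3, 16, dimnames = list(paste0("N", 1:3), NULL))
  cm <- toy_count_matrix(m)
  nc <- normalize_counts(cm)
  res <- per_node_tests(nc)
  expect_true(all(res$p_value == 1))

  # complete separation in 8 vs 8 without ties: exact two-sided P = 2/12870
  m2 <- rbind(N1 = c(101:108, 1:8),
              N2 = rep(10, 16) + (1:16) %% 2)
  cm2 <- toy_count_matrix(m2, n_forg = 8, mapped_totals = rep(1e6, 16))
  res2 <- per_node_tests(normalize_counts(cm2))
  expect_equal(res2$p_value[res2$node_id == "N1"], 2 / 12870)
  expect_equal(res2$direction[res2$node_id == "N1"], "FORG")

  # all-null matrix: BH keeps the significant fraction near zero
  set.seed(4)
  m3 <- matrix(rpois(1000 * 16, 20), 1000, 16,
               dimnames = list(sprintf("N%04d", 1:1000), NULL))
  res3 <- per_node_tests(normalize_counts(toy_count_matrix(m3)))
  expect_lte(mean(res3$significant), 0.01)
})

test_that("mean-layer contrast computes read-weighted means and calibrated randomization P", {
  layers <- c(N1 = 1L, N2 = 2L, N3 = NA_integer_)
  # FORG reads all on the layer-2 node, CONC all on layer-1
  counts <- rbind(N1 = c(0, 0, 50, 50), N2 = c(50, 50, 0, 0),
                  N3 = c(7, 7, 7, 7))
  cm <- toy_count_matrix(counts, n_forg = 2)
  r <- mean_layer_test(cm, layers, n_rand = 99, seed = 1)
  expect_equal(r$observed, 1.0)
  expect_true(r$p_value > 0 && r$p_value <= 1)
  # identical distributions -> observed 0
  counts2 <- rbind(N1 = rep(10, 4), N2 = rep(20, 4))
  r2 <- mean_layer_test(toy_count_matrix(counts2, n_forg = 2),
                        layers[1:2], n_rand = 99, seed = 1)
  expect_equal(r2$observed, 0)
  expect_equal(r2$p_value, 1)
  # P-values live in (0, 1] and use the add-one estimator
  expect_equal(add_one_pvalue(c(1, 2, 3), 10), 1 / 4)
  expect_equal(add_one_pvalue(c(1, 2, 3), 0), 1)
})

test_that("network statistics match closed forms and a path-enumeration oracle", {
  star <- igraph::make_star(6, mode = "undirected", center = 1)
  igraph::V(star)$name <- paste0("v", 1:6)
  gstar <- list(nodes = data.frame(node_id = paste0("v", 1:6)),
                graph = star)
  class(gstar) <- "metabolic_graph"
  deg <- node_statistic(gstar, "degree")
  expect_equal(unname(deg["v1"]), 5)
  cl <- node_statistic(gstar, "clustering")
  expect_true(all(cl == 0))

  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- paste0("t", 1:3)
  gtri <- structure(list(nodes = data.frame(node_id = paste0("t", 1:3)),
                         graph = tri), class = "metabolic_graph")
  expect_true(all(node_statistic(gtri, "clustering") == 1))

  # path graph: betweenness of node k (0-indexed) is k * (n - 1 - k)
  pg <- igraph::make_ring(5, circular = FALSE)
  igraph::V(pg)$name <- paste0("p", 1:5)
  gpg <- structure(list(nodes = data.frame(node_id = paste0("p", 1:5)),
                        graph = pg), class = "metabolic_graph")
  b <- node_statistic(gpg, "betweenness")
  expect_equal(unname(b), c(0, 3, 4, 3, 0))

  # random graphs vs explicit all-shortest-path enumeration
  for (seed in 1:20) {
    set.seed(seed)
    g <- igraph::sample_gnp(12, 0.3)
    igraph::V(g)$name <- sprintf("r%02d", 1:12)
    gg <- structure(list(nodes = data.frame(node_id = igraph::V(g)$name),
                         graph = g), class = "metabolic_graph")
    expect_equal(node_statistic(gg, "betweenness"),
                 betweenness_enumeration_oracle(g))
  }

  # carbon sum over the node's metabolite set
  db <- tiny_microbial_db()
  g <- build_graph(db, 25)
  cs <- node_statistic(g, "carbon_sum", db = db)
  expect_equal(unname(cs["R1"]), 7)   # A(3) + B(4)
  expect_equal(unname(cs["R4"]), 7)   # ACETATE(2) + C(5)
  expect_error(node_statistic(g, "eigenvector"), "arg")
})

test_that("network-statistic contrasts weight by normalized reads and randomize like the layer test", {
  db <- tiny_microbial_db()
  g <- build_graph(db, 25)
  counts <- matrix(10, nrow(g$nodes), 4,
                   dimnames = list(g$nodes$node_id, NULL))
  counts[, 3:4] <- c(40, 5, 5, 5)  # CONC reads concentrated on R1
  cm <- toy_count_matrix(counts, n_forg = 2)
  r <- network_stat_contrast(cm, g, "degree", n_rand = 99, seed = 1)
  expect_s3_class(r, "randomization_result")
  # identical diets -> observed 0
  counts2 <- matrix(rep(c(10, 20, 5, 1), 4), ncol = 4,
                    dimnames = list(g$nodes$node_id, NULL))
  r2 <- network_stat_contrast(toy_count_matrix(counts2, n_forg = 2), g,
                              "carbon_sum", db = db, n_rand = 99, seed = 1)
  expect_equal(r2$observed, 0)
  expect_error(network_stat_contrast(cm, g, "nope"), "arg")
})

test_that("randomization tests reject near the nominal rate under the multinomial null", {
  # a single shared intensity vector, two groups of pure multinomial
  # sampling noise: P should be roughly uniform
  set.seed(31)
  layers <- setNames(sample(0:3, 60, TRUE), sprintf("N%02d", 1:60))
  intens <- exp(rnorm(60, 2, 1))
  rejections <- 0L
  n_sets <- 60
  for (i in seq_len(n_sets)) {
    counts <- vapply(seq_len(8), function(k)
      as.integer(rmultinom(1, 3000, intens)), integer(60))
    rownames(counts) <- names(layers)
    cm <- toy_count_matrix(counts, n_forg = 4)
    p <- mean_layer_test(cm, layers, n_rand = 199, seed = i)$p_value
    if (p <= 0.05) rejections <- rejections + 1L
  }
  expect_lte(rejections, qbinom(0.999, n_sets, 0.05) + 1)
})

test_that("layer correlation reports per-diet correlation and read proportions per layer", {
  layers <- setNames(c(0L, 1L, 2L, 3L), paste0("N", 1:4))
  # counts strictly decreasing in layer -> negative correlation
  counts <- matrix(rep(c(100, 50, 20, 5), 4), 4, 4,
                   dimnames = list(paste0("N", 1:4), NULL))
  nc <- normalize_counts(toy_count_matrix(counts, n_forg = 2))
  lc <- layer_correlation(nc, layers)
  expect_lt(lc$correlation[["FORG"]], 0)
  expect_lt(lc$correlation[["CONC"]], 0)
  expect_equal(sum(lc$layer_proportions$FORG), 1)
  expect_equal(sum(lc$layer_proportions$CONC), 1)
  expect_error(layer_correlation(nc, setNames(c(0L, 1L, 0L, 1L),
                                              paste0("N", 1:4))),
               "3 layers")
  # counts independent of layer: correlation near zero
  set.seed(8)
  n <- 400
  lay2 <- setNames(sample(0:4, n, TRUE), sprintf("M%03d", 1:n))
  c2 <- matrix(rpois(n * 4, 50), n, 4,
               dimnames = list(names(lay2), NULL))
  nc2 <- normalize_counts(toy_count_matrix(c2, n_forg = 2))
  lc2 <- layer_correlation(nc2, lay2)
  expect_lt(abs(lc2$correlation[["FORG"]]), 2 / sqrt(n))
})

test_that("presence/absence classifies nodes and scores exclusivity by read randomization", {
  set.seed(5)
  counts <- rbind(
    shared = c(5, 6, 4, 7, 5, 6, 4, 7),
    one_read = c(1, 0, 0, 0, 0, 0, 0, 0),
    conc_big = c(0, 0, 0, 0, 80, 70, 75, 75))
  cm <- toy_count_matrix(counts, n_forg = 4,
                         mapped_totals = rep(1000, 8))
  pa <- presence_absence(cm, n_rand = 2000, seed = 2)
  expect_equal(pa$n_observed, 3L)
  expect_equal(pa$n_shared, 1L)
  expect_equal(pa$n_forg_only, 1L)
  expect_equal(pa$n_conc_only, 1L)
  excl <- pa$exclusive
  # a single pooled read can never be significant under a balanced design
  expect_gt(excl$p_value[excl$node_id == "one_read"], 0.01)
  # 300 CONC-only reads are: the randomization P agrees with the closed
  # form (1/2)^300 ~ 0
  expect_lt(excl$p_value[excl$node_id == "conc_big"], 0.01)
  expect_equal(pa$n_conc_significant, 1L)
  expect_equal(pa$max_reads_differential, 300)
})

test_that("variance contrast flags depth-limited animals and detects heteroscedastic diets", {
  # identical matrices per diet -> P = 1
  block <- matrix(rpois(40 * 4, 30), 40, 4)
  cm <- toy_count_matrix(cbind(block, block), n_forg = 4)
  vc <- variance_contrast(cm, subsample_reads = 1000, n_rep = 5, seed = 1)
  expect_equal(vc$p_value, 1)

  # CONC = FORG + strong heteroscedastic noise
  set.seed(12)
  base <- matrix(rpois(200 * 4, 50), 200, 4)
  noisy <- t(apply(base, 1, function(r)
    pmax(0, round(r * exp(rnorm(4, 0, 1.0))))))
  cm2 <- toy_count_matrix(cbind(base, noisy), n_forg = 4)
  vc2 <- variance_contrast(cm2, subsample_reads = sum(base[, 1]),
                           n_rep = 10, seed = 3)
  expect_lt(vc2$p_value, 1e-6)
  expect_true(all(vc2$resampled_p < 1e-3))
  # variances are invariant to animal ordering within diet
  cm3 <- toy_count_matrix(cbind(base[, c(3, 1, 4, 2)], noisy), n_forg = 4)
  vc3 <- variance_contrast(cm3, subsample_reads = sum(base[, 1]),
                           n_rep = 2, seed = 3)
  expect_equal(vc3$var_forg, vc2$var_forg)
})

test_that("VFA correlation reports one-sided Spearman rho per acid", {
  set.seed(21)
  nodes <- sprintf("N%02d", 1:20)
  counts <- matrix(rpois(20 * 10, 30), 20, 10,
                   dimnames = list(nodes, sprintf("A%02d", 1:10)))
  # plant a monotone relationship for "acetate" nodes
  conc <- seq(1, 5, length.out = 10)
  counts[1:4, ] <- round(200 * matrix(conc, 4, 10, byrow = TRUE))
  cm <- toy_count_matrix(counts, n_forg = 5)
  vfa_map <- list(acetate = nodes[1:4], butyrate = nodes[5:6])
  conc_df <- data.frame(animal_id = colnames(counts),
                        acetate = conc,
                        butyrate = rep(2, 10))
  expect_warning(res <- vfa_correlation(cm, vfa_map, conc_df), "constant")
  expect_gt(res$rho[res$vfa == "acetate"], 0.9)
  expect_lt(res$p_value[res$vfa == "acetate"], 0.01)
  expect_true(is.na(res$rho[res$vfa == "butyrate"]))
  # perfectly monotone read fractions give rho = 1
  counts2 <- matrix(1, 2, 6, dimnames = list(c("X1", "X2"), paste0("B", 1:6)))
  counts2[1, ] <- 1:6; counts2[2, ] <- 60
  cm2 <- toy_count_matrix(counts2, n_forg = 3)
  res2 <- vfa_correlation(cm2, list(acetate = "X1"),
                          data.frame(animal_id = paste0("B", 1:6),
                                     acetate = 1:6))
  expect_equal(res2$rho, 1)
  expect_error(vfa_correlation(cm2, list(acetate = "X1"),
                               data.frame(animal_id = paste0("B", 1:3),
                                          acetate = 1:3)),
               "5 paired")
})
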