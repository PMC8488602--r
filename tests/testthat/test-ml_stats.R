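test_that("PCA satisfies the contribution, cos2 and eigenvalue identities", {
  set.seed(5)
  x <- matrix(stats::rnorm(23 * 8), 23, 8,
              dimnames = list(paste0("c", 1:23), paste0("v", 1:8)))
  fit <- pca_fit(x)
  expect_equal(unname(colSums(fit$var_contrib)),
               rep(100, length(fit$eigenvalues)))
  expect_equal(unname(rowSums(fit$ind_cos2)), rep(1, nrow(x)))
  expect_equal(sum(fit$eigenvalues), 8)
  # full reconstruction of the standardized matrix
  loadings <- sweep(fit$var_coord, 2, sqrt(fit$eigenvalues), "/")
  expect_lt(max(abs(fit$ind_coord %*% t(loadings) - fit$standardized)), 1e-8)
  expect_error(pca_fit(x[1, , drop = FALSE]), "at least 2 rows")
})

test_that("two identical columns each contribute 50 to the first component", {
  set.seed(6)
  a <- stats::rnorm(20)
  fit <- pca_fit(cbind(p = a, q = a))
  expect_equal(unname(fit$var_contrib[, 1]), c(50, 50))
  # constant columns are dropped with a warning
  expect_warning(fit2 <- pca_fit(cbind(p = a, q = a, const = rep(2, 20))),
                 "constant")
  expect_equal(fit2$dropped, "const")
})

test_that("pathway aggregation sums and averages contributions per subsystem", {
  model <- make_toy_model()
  idx <- build_subsystem_index(model)
  contrib <- matrix(0, ncol(model$S), 2,
                    dimnames = list(model$rxns, c("Dim.1", "Dim.2")))
  contrib[, 1] <- seq_len(nrow(contrib))
  contrib[, 2] <- 1
  agg <- pathway_pca_aggregate(contrib, idx, rxns = model$rxns)
  gly <- agg[agg$subsystem == "Glycolysis", ]
  jj <- which(model$rxns %in% c("PGA", "PGB"))
  expect_equal(gly$pc1_sum, sum(jj))
  expect_equal(gly$pc1_avg, mean(jj))
  expect_equal(gly$cardinality, 2)
  # multi-membership: GLYK's contribution lands in both split subsystems
  jg <- which(model$rxns == "GLYK")
  expect_equal(agg$pc1_sum[agg$subsystem == "Lipid metabolism"], jg)
  expect_equal(agg$pc1_sum[agg$subsystem == "Cell wall"], jg)
  # total over subsystems = total contributions + one extra copy per
  # additional membership
  n_multi <- sum(lengths(model$subSystems) - 1)
  expect_equal(sum(agg$pc1_sum), sum(contrib[, 1]) + jg * (n_multi > 0))
})

test_that("PC-flux association reproduces the least-squares oracle", {
  set.seed(8)
  pc <- stats::rnorm(24)
  flux <- 3 * pc + 2 + stats::rnorm(24, sd = 0.1)
  out <- pc_flux_association(pc, flux)
  # closed-form normal equations
  slope <- sum((pc - mean(pc)) * (flux - mean(flux))) / sum((pc - mean(pc))^2)
  expect_equal(out$slope, slope)
  expect_equal(out$intercept, mean(flux) - slope * mean(pc))
  expect_equal(out$r, stats::cor(pc, flux))
  exact <- pc_flux_association(pc, 2 * pc)
  expect_equal(exact$r, 1)
  expect_true(is.nan(pc_flux_association(pc, rep(1, 24))$r))
})

test_that("correlation distance matches the 1 - r oracle and its limits", {
  set.seed(9)
  for (i in 1:5) {
    x <- matrix(stats::rnorm(20), 5, 4)
    d <- correlation_distance(x, zscore = FALSE)
    for (a in 1:4) for (b in (a):5) if (b <= 5 && a < b)
      expect_equal(d[a, b], 1 - stats::cor(x[a, ], x[b, ]), tolerance = 1e-12)
  }
  x <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = -c(1, 2, 3, 4))
  d <- correlation_distance(x, zscore = FALSE)
  expect_equal(unname(d["a", "b"]), 0)
  expect_equal(unname(d["a", "c"]), 2)
  expect_warning(correlation_distance(rbind(c(1, 1, 1), c(1, 2, 3)),
                                      zscore = FALSE), "constant")
})

test_that("city-block k-means recovers planted blobs and is deterministic", {
  set.seed(10)
  truth <- rep(1:2, each = 15)
  x <- matrix(stats::rnorm(30 * 4, sd = 0.3), 30, 4) + 5 * (truth - 1)
  km <- kmeans_cluster(x, 2, method = "cityblock", seed = 42)
  expect_equal(adjusted_rand_index(km$labels, truth), 1)
  km2 <- kmeans_cluster(x, 2, method = "cityblock", seed = 42)
  expect_identical(km$labels, km2$labels)
  # centroid of the city-block objective is the coordinate-wise median
  for (cl in 1:2)
    expect_equal(unname(km$centroids[cl, ]),
                 unname(apply(x[km$labels == cl, ], 2, stats::median)))
  expect_error(kmeans_cluster(x, 40), "exceeds")
})

test_that("the silhouette scan finds the true group count on separated profiles", {
  set.seed(12)
  base <- stats::rnorm(10)
  g1 <- t(replicate(10, base + stats::rnorm(10, sd = 0.1)))
  g2 <- t(replicate(10, -base + stats::rnorm(10, sd = 0.1)))
  x <- rbind(g1, g2)
  scan <- silhouette_scan(x, k_range = 2:6, seed = 2)
  expect_equal(scan$best_k, 2)
  expect_true(all(scan$mean_silhouette >= -1 & scan$mean_silhouette <= 1))
  expect_warning(silhouette_scan(x[1:4, ], k_range = 2:10), "skipping")
})

test_that("squared-stress MDS embeds and survives co-located points", {
  set.seed(13)
  pts <- matrix(stats::rnorm(16), 8, 2)
  d <- as.matrix(stats::dist(pts))
  emb <- nonmetric_mds(d, dims = 2, seed = 4)
  expect_equal(ncol(emb$points), 2)
  expect_lt(emb$stress, 0.05)
  # duplicate points force the scalar-retry path yet still embed
  d2 <- as.matrix(stats::dist(pts[c(1, 1, 2:7), ]))
  emb2 <- nonmetric_mds(d2, dims = 2, seed = 4)
  expect_equal(nrow(emb2$points), 8)
})

test_that("LASSO paths start all-zero and the MPC filter retains planted signal", {
  set.seed(14)
  n <- 12; p <- 20
  X <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", 1:p)))
  y <- 2 * X[, 3] + stats::rnorm(n, sd = 0.05)
  fit <- lasso_mpc(X, y)
  expect_equal(length(fit$lambda_path), 100)
  expect_true(all(fit$coef_path[, 1] == 0))       # lambda_max: all zero
  expect_true("x3" %in% fit$retained$predictor)
  expect_gt(fit$retained$mpc[fit$retained$predictor == "x3"], 0)
  expect_true(all(abs(fit$retained$mpc) > 0.01))
  # retained is sorted by MPC descending
  expect_false(is.unsorted(rev(fit$retained$mpc)))
  # prose-variant averaging over nonzero coefficients only
  fit2 <- lasso_mpc(X, y, nonzero_only = TRUE)
  expect_gte(abs(fit2$mpc[["x3"]]), abs(fit$mpc[["x3"]]))
  expect_error(lasso_mpc(X[1:5, ], y), "align")
})

test_that("Pearson r, p and Fisher CI match the textbook oracle", {
  set.seed(15)
  n <- 12
  X <- matrix(stats::rnorm(n * 6), n, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  X[, 6] <- 1   # constant column
  y <- stats::rnorm(n)
  out <- pearson_with_ci(X, y)
  for (j in 1:5) {
    ct <- stats::cor.test(X[, j], y)
    expect_equal(out$r[j], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(out$pval[j], ct$p.value, tolerance = 1e-10)
    z <- atanh(out$r[j]); half <- 1.96 / sqrt(n - 3)
    expect_equal(out$lb95[j], tanh(z - half))
    expect_equal(out$ub95[j], tanh(z + half))
    expect_true(out$lb95[j] <= out$r[j] && out$r[j] <= out$ub95[j])
  }
  expect_true(all(is.nan(unlist(out[6, c("r", "pval", "lb95", "ub95")]))))
  exact <- pearson_with_ci(cbind(a = y, b = -y), y)
  expect_equal(exact$r, c(1, -1))
})

test_that("correlation p-values agree with an exhaustive permutation null at n = 6", {
  set.seed(16)
  x <- stats::rnorm(6)
  y <- x + stats::rnorm(6, sd = 1)
  r_obs <- stats::cor(x, y)
  perms <- combinat_permn <- NULL
  # enumerate all 720 permutations without external packages
  permute_all <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in permute_all(v[-i]))
        out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  rs <- vapply(permute_all(seq_len(6)), function(p) stats::cor(x, y[p]), 0)
  p_perm <- mean(abs(rs) >= abs(r_obs) - 1e-12)
  p_t <- pearson_with_ci(matrix(x), y)$pval
  expect_lt(abs(p_perm - p_t), 0.1)
})

test_that("top-k selection clamps, excludes NaN and breaks ties by id", {
  res <- data.frame(feature = c("a", "b", "c", "d"),
                    r = c(0.9, -0.8, NaN, 0.9),
                    pval = 0, lb95 = 0, ub95 = 0)
  top <- top_k_predictors(res, k = 10)
  expect_equal(top$positive$feature, c("a", "d", "b"))
  expect_equal(top$negative$feature[1], "b")
  expect_false("c" %in% c(top$positive$feature, top$negative$feature))
})

test_that("pathway correlation bins use half-open edges and zero NaN", {
  S <- matrix(0, 1, 4, dimnames = list("m", paste0("R", 1:4)))
  m <- metabolic_model(S, lb = rep(0, 4), ub = rep(1, 4), rxns = colnames(S),
                       subSystems = list("P", "P", "Q", "Q"))
  idx <- build_subsystem_index(m)
  out <- pathway_correlation(c(-0.4, 0.6, NaN, 0.5), idx)
  p <- out[out$subsystem == "P", ]
  expect_equal(p$mean_abs_r, 0.5)
  expect_equal(p[["[-0.5,-0.3)"]], 1L)
  expect_equal(p[["[0.5,0.7)"]], 1L)
  q <- out[out$subsystem == "Q", ]
  expect_equal(q$mean_abs_r, 0.25)             # NaN treated as 0
  expect_equal(q[["[-0.1,0.1)"]], 1L)          # the zeroed NaN
  expect_equal(q[["[0.5,0.7)"]], 1L)           # r = 0.5 on the closed edge
  # bin counts partition the members within [-0.7, 0.7)
  bins <- as.matrix(out[, grep("^\\[", names(out))])
  expect_equal(unname(rowSums(bins) + out$overflow), out$cardinality)
  out2 <- pathway_correlation(c(0.9, -0.75, 0, 0), idx)
  expect_equal(out2$overflow[out2$subsystem == "P"], 2L)
})
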