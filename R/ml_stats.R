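#' Principal component analysis with contributions and cos2
#'
#' PCA under the conventions pinned by the protocol's reference stack:
#' columns are centered and (by default) scaled to unit variance with the
#' population denominator n; the eigen-decomposition is taken of the
#' resulting correlation matrix, so eigenvalues sum to the number of retained
#' (non-constant) variables. Variable coordinates are loadings scaled by the
#' square-rooted eigenvalue, contributions are `100 * coord^2 / eigenvalue`
#' (summing to 100 per component), and individual cos2 values are squared
#' coordinates normalized per row (summing to 1 over all components).
#'
#' Constant columns carry no variance direction and are dropped with a
#' warning before the decomposition.
#'
#' @param x conditions x features numeric matrix.
#' @param standardize scale columns to unit variance (default TRUE).
#' @return A `pca_result`: list with `eigenvalues`, `ind_coord`, `var_coord`,
#'   `var_contrib`, `ind_cos2`, `dropped` (names of constant columns) and
#'   `standardized` (the matrix actually decomposed).
#' @export
pca_fit <- function(x, standardize = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("PCA needs at least 2 rows")
  n <- nrow(x)
  mu <- colMeans(x)
  sd_pop <- sqrt(colMeans(sweep(x, 2, mu)^2))
  keep <- sd_pop > 1e-12
  dropped <- colnames(x)[!keep]
  if (length(dropped))
    warning("dropping ", length(dropped), " constant column(s) before PCA")
  xs <- sweep(x[, keep, drop = FALSE], 2, mu[keep])
  if (standardize) xs <- sweep(xs, 2, sd_pop[keep], "/")
  sv <- svd(xs / sqrt(n))
  pos <- sv$d > max(sv$d) * 1e-10
  d <- sv$d[pos]
  eig <- d^2
  comp <- paste0("Dim.", seq_along(eig))
  ind_coord <- xs %*% sv$v[, pos, drop = FALSE]
  dimnames(ind_coord) <- list(rownames(x), comp)
  var_coord <- sweep(sv$v[, pos, drop = FALSE], 2, sqrt(eig), "*")
  dimnames(var_coord) <- list(colnames(xs), comp)
  var_contrib <- sweep(var_coord^2, 2, eig, "/") * 100
  ind_cos2 <- ind_coord^2 / rowSums(ind_coord^2)
  structure(list(eigenvalues = stats::setNames(eig, comp),
                 ind_coord = ind_coord, var_coord = var_coord,
                 var_contrib = var_contrib, ind_cos2 = ind_cos2,
                 dropped = dropped, standardized = xs),
            class = "pca_result")
}

#' Aggregate PCA contributions by subsystem
#'
#' Sums and averages the first- and second-component variable contributions
#' over the member reactions of every subsystem. Reactions belonging to k
#' subsystems contribute to all k rows; averages divide by the subsystem
#' cardinality. Because PCA may drop constant columns, contributions are
#' matched back to reaction positions by name, with dropped reactions
#' contributing 0.
#'
#' @param contrib features x components contribution matrix (rownames =
#'   reaction ids), typically `pca_result$var_contrib`.
#' @param index a `subsystem_index` from [build_subsystem_index()].
#' @param rxns reaction ids, in model order, aligning with `index`.
#' @return data.frame with columns `subsystem`, `pc1_sum`, `pc1_avg`,
#'   `pc2_sum`, `pc2_avg`, `cardinality`.
#' @export
pathway_pca_aggregate <- function(contrib, index, rxns = rownames(contrib)) {
  contrib <- as.matrix(contrib)
  if (ncol(contrib) < 2) stop("need contributions for at least 2 components")
  full <- matrix(0, length(rxns), 2, dimnames = list(rxns, colnames(contrib)[1:2]))
  hit <- intersect(rxns, rownames(contrib))
  full[hit, ] <- contrib[hit, 1:2]
  out <- data.frame(subsystem = index$names,
                    pc1_sum = 0, pc1_avg = 0, pc2_sum = 0, pc2_avg = 0,
                    cardinality = unname(index$cardinality),
                    stringsAsFactors = FALSE)
  for (i in seq_along(index$names)) {
    mem <- index$membership[[i]]
    if (!length(mem)) {
      warning("subsystem '", index$names[i], "' has no member reactions")
      next
    }
    out$pc1_sum[i] <- sum(full[mem, 1])
    out$pc2_sum[i] <- sum(full[mem, 2])
    out$pc1_avg[i] <- out$pc1_sum[i] / length(mem)
    out$pc2_avg[i] <- out$pc2_sum[i] / length(mem)
  }
  out
}

#' Association between a principal component and a single flux
#'
#' Pearson correlation plus ordinary least-squares line between per-condition
#' component coordinates and the flux of one reaction, used to quantify how
#' well a top-contributing reaction tracks the component across conditions.
#'
#' @param pc per-condition component coordinate vector.
#' @param flux per-condition flux vector.
#' @return list with `r`, `slope`, `intercept`.
#' @export
pc_flux_association <- function(pc, flux) {
  if (length(pc) != length(flux) || length(pc) < 3)
    stop("pc and flux must have equal length >= 3")
  if (stats::sd(pc) == 0 || stats::sd(flux) == 0)
    return(list(r = NaN, slope = NaN, intercept = NaN))
  fit <- stats::lm(flux ~ pc)
  list(r = stats::cor(pc, flux),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}

#' Correlation distance between feature profiles
#'
#' Standardizes each condition column to zero mean/unit variance (sample sd)
#' and returns `1 - r` for every pair of feature rows, the distance the
#' protocol feeds into the silhouette scan. Constant rows have undefined
#' correlation; their pairwise distances are defined as 1 (with a warning).
#'
#' @param x features x conditions matrix.
#' @param zscore standardize columns first (default TRUE).
#' @return A symmetric features x features distance matrix in [0, 2].
#' @export
correlation_distance <- function(x, zscore = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 feature rows")
  if (zscore) {
    x <- scale(x)  # per-column, sample sd
    x[, attr(x, "scaled:scale") == 0] <- 0  # constant column: centered is 0
  }
  rsd <- apply(x, 1, stats::sd)
  d <- 1 - suppressWarnings(stats::cor(t(x)))
  if (any(rsd == 0)) {
    warning(sum(rsd == 0), " constant feature row(s): distances set to 1")
    d[rsd == 0, ] <- 1
    d[, rsd == 0] <- 1
  }
  d[is.na(d)] <- 1
  diag(d) <- 0
  d
}

# squared city-block / correlation assignment helpers --------------------

dist_to_centroids <- function(x, centroids, method) {
  if (method == "cityblock") {
    apply(centroids, 1, function(ct) rowSums(abs(sweep(x, 2, ct))))
  } else { # correlation
    xs <- x - rowMeans(x)
    xs <- xs / sqrt(rowSums(xs^2))
    cs <- centroids - rowMeans(centroids)
    cs <- cs / sqrt(rowSums(cs^2))
    1 - tcrossprod(xs, cs)
  }
}

#' K-means clustering with city-block or correlation distance
#'
#' Lloyd-style k-means under the protocol's distance choices: city-block
#' (Manhattan) with per-coordinate **median** centroid updates (the exact
#' minimizer of within-cluster L1 distance), or correlation distance with
#' mean-then-restandardize updates. `restarts` random initializations are run
#' (default 5) and the solution with the lowest total within-cluster distance
#' kept. A compatibility mode (`centroid = "mean"`) reproduces tools that
#' update city-block centroids with means.
#'
#' @param x features x conditions matrix (rows are clustered).
#' @param k number of clusters (>= 2).
#' @param method `"cityblock"` (default) or `"correlation"`.
#' @param restarts random restarts (default 5).
#' @param seed RNG seed (default 1).
#' @param centroid `"median"` (default, city-block optimal) or `"mean"`.
#' @param max_iter iteration cap per restart.
#' @return list with `labels`, `centroids`, `tot_within`, `method`.
#' @export
kmeans_cluster <- function(x, k, method = c("cityblock", "correlation"),
                           restarts = 5, seed = 1,
                           centroid = c("median", "mean"), max_iter = 100) {
  method <- match.arg(method); centroid <- match.arg(centroid)
  x <- as.matrix(x)
  if (k < 2) stop("k must be >= 2")
  if (k > nrow(x)) stop("k exceeds the number of points")
  best <- NULL
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  for (r in seq_len(restarts)) {
    ctr <- x[sample(nrow(x), k), , drop = FALSE]
    labels <- rep(0L, nrow(x))
    for (it in seq_len(max_iter)) {
      D <- dist_to_centroids(x, ctr, method)
      new_labels <- max.col(-D, ties.method = "first")
      # re-seed clusters that emptied with the worst-assigned points
      for (cl in seq_len(k)) {
        if (!any(new_labels == cl)) {
          far <- which.max(D[cbind(seq_len(nrow(x)), new_labels)])
          new_labels[far] <- cl
        }
      }
      if (identical(new_labels, labels)) break
      labels <- new_labels
      for (cl in seq_len(k)) {
        pts <- x[labels == cl, , drop = FALSE]
        ctr[cl, ] <- if (method == "cityblock" && centroid == "median")
          apply(pts, 2, stats::median) else colMeans(pts)
      }
    }
    D <- dist_to_centroids(x, ctr, method)
    tw <- sum(D[cbind(seq_len(nrow(x)), labels)])
    if (is.null(best) || tw < best$tot_within)
      best <- list(labels = labels, centroids = ctr, tot_within = tw,
                   method = method)
  }
  best
}

#' Silhouette scan over candidate cluster counts
#'
#' For each k in `k_range`, clusters the feature rows with
#' correlation-distance k-means (5 restarts) and computes the mean silhouette
#' width against the correlation distance matrix, the protocol's criterion for
#' choosing the cluster count (scanned over 2..30 by default).
#'
#' @param x features x conditions matrix.
#' @param k_range candidate cluster counts (default `2:30`; values exceeding
#'   `nrow(x) - 1` are skipped with a warning).
#' @param restarts,seed passed to [kmeans_cluster()].
#' @return list with `k` (evaluated counts), `mean_silhouette`, and `best_k`
#'   (argmax).
#' @export
silhouette_scan <- function(x, k_range = 2:30, restarts = 5, seed = 1) {
  x <- as.matrix(x)
  valid <- k_range[k_range >= 2 & k_range <= nrow(x) - 1]
  if (length(valid) < length(k_range))
    warning("skipping k values outside [2, rows-1]")
  d <- correlation_distance(x)
  sil <- vapply(valid, function(k) {
    cl <- kmeans_cluster(x, k, method = "correlation",
                         restarts = restarts, seed = seed + k)
    sw <- cluster::silhouette(cl$labels, dmatrix = d)
    mean(sw[, "sil_width"])
  }, 0)
  list(k = valid, mean_silhouette = sil, best_k = valid[which.max(sil)])
}

#' Nonmetric multidimensional scaling under the squared-stress criterion
#'
#' Embeds a dissimilarity matrix in `dims` dimensions by gradient descent on
#' the normalized squared-stress
#' \eqn{\sum (d_{ij}^2 - \delta_{ij}^2)^2 / \sum \delta_{ij}^4}
#' from a seeded random start. Degenerate configurations (co-located points
#' yield zero dissimilarities) are handled robustly by multiplying the
#' dissimilarities by a scalar (1.01 per retry, up to `retries` times) and
#' re-running -- the same trick the protocol's robust wrapper applies.
#'
#' @param d dissimilarity matrix (or `dist`).
#' @param dims embedding dimensionality (default 2).
#' @param max_iter iteration cap (default 500).
#' @param seed RNG seed for the random start.
#' @param retries scalar-retry attempts on degeneracy (default 10).
#' @return list with `points` (n x dims), `stress`, and `retries_used`.
#' @export
nonmetric_mds <- function(d, dims = 2, max_iter = 500, seed = 1, retries = 10) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("dissimilarity matrix must be square")
  n <- nrow(d)
  run_once <- function(delta, seed) {
    old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
    set.seed(seed)
    off <- delta[upper.tri(delta)]
    if (any(!is.finite(off)) || all(off == 0)) return(NULL)
    norm <- sum(off^4)
    y <- matrix(stats::rnorm(n * dims, sd = stats::sd(off) + 1e-8), n, dims)
    sstress <- function(y) {
      dy <- as.matrix(stats::dist(y))
      sum((dy[upper.tri(dy)]^2 - off^2)^2) / norm
    }
    grad <- function(y) {
      dy <- as.matrix(stats::dist(y))
      w <- 4 * (dy^2 - delta^2) / norm
      g <- matrix(0, n, dims)
      for (k in seq_len(dims)) {
        diffk <- outer(y[, k], y[, k], "-")
        g[, k] <- rowSums(w * diffk)
      }
      g
    }
    s <- sstress(y)
    step <- 0.1
    for (it in seq_len(max_iter)) {
      g <- grad(y)
      gn <- sqrt(sum(g^2))
      if (gn < 1e-12) break
      accepted <- FALSE
      while (step > 1e-12) {
        y2 <- y - step * g / gn
        s2 <- sstress(y2)
        if (s2 < s) { y <- y2; s <- s2; step <- step * 1.2; accepted <- TRUE; break }
        step <- step / 2
      }
      if (!accepted) break
      if (s < 1e-12) break
    }
    dy <- as.matrix(stats::dist(y))
    if (any(dy[upper.tri(dy)] < 1e-10)) return(NULL)  # co-located points
    list(points = y, stress = s)
  }
  scalar <- 1
  for (attempt in 0:retries) {
    res <- run_once(d * scalar, seed + attempt)
    if (!is.null(res)) {
      res$retries_used <- attempt
      return(res)
    }
    scalar <- scalar * 1.01
  }
  stop("nonmetric_mds: configuration still degenerate after ", retries, " retries")
}

#' LASSO with mean predictor coefficients
#'
#' Fits the L1 (alpha = 1) regularization path of growth rate on the omic
#' predictors over a geometric grid of 100 penalties from lambda_max (the
#' smallest penalty with an all-zero solution) down to `lambda_max * 1e-4`.
#' Predictors are standardized internally; coefficients are reported on the
#' original scale. The mean predictor coefficient (MPC) averages each
#' predictor's coefficient over the whole path (zeros included); predictors
#' with `|MPC| > cutoff` are retained, sorted by MPC descending. Setting
#' `nonzero_only = TRUE` instead averages only each predictor's nonzero path
#' coefficients.
#'
#' @param X conditions x predictors matrix.
#' @param y growth-rate response (1/h), aligned with rows of `X`.
#' @param cutoff MPC retention threshold (default 0.01).
#' @param nlambda,lambda_min_ratio penalty-grid shape.
#' @param nonzero_only average only nonzero coefficients (default FALSE).
#' @return A `lasso_result`: list with `lambda_path`, `coef_path`
#'   (predictors x lambdas), `mpc`, and `retained` (data.frame of predictor,
#'   mpc).
#' @export
lasso_mpc <- function(X, y, cutoff = 0.01, nlambda = 100,
                      lambda_min_ratio = 1e-4, nonzero_only = FALSE) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("rows of X must align with y")
  if (nrow(X) < 2) stop("need at least 2 observations")
  n <- nrow(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  # zero-variance predictors carry no information and destabilize the
  # standardized fit; they are excluded and reported with coefficient 0
  sd_pop <- sqrt(colMeans(sweep(X, 2, colMeans(X))^2))
  active <- sd_pop > 1e-12
  Xa <- X[, active, drop = FALSE]
  Xs <- sweep(sweep(Xa, 2, colMeans(Xa)), 2, sd_pop[active], "/")
  lambda_max <- max(abs(crossprod(Xs, y - mean(y)))) / n
  if (lambda_max <= 0) lambda_max <- 1e-3
  grid <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                  length.out = nlambda))
  fit <- glmnet::glmnet(Xa, y, alpha = 1, lambda = grid, standardize = TRUE)
  path_a <- as.matrix(fit$beta)
  coef_path <- matrix(0, ncol(X), ncol(path_a),
                      dimnames = list(colnames(X), colnames(path_a)))
  coef_path[active, ] <- path_a
  mpc <- if (nonzero_only) {
    apply(coef_path, 1, function(b) if (any(b != 0)) mean(b[b != 0]) else 0)
  } else rowMeans(coef_path)
  keep <- which(abs(mpc) > cutoff)
  retained <- data.frame(predictor = rownames(coef_path)[keep],
                         mpc = unname(mpc[keep]), stringsAsFactors = FALSE)
  retained <- retained[order(-retained$mpc), , drop = FALSE]
  rownames(retained) <- NULL
  structure(list(lambda_path = fit$lambda, coef_path = coef_path,
                 mpc = mpc, retained = retained, cutoff = cutoff),
            class = "lasso_result")
}

#' Per-feature Pearson correlation with growth rate
#'
#' For every feature column: the Pearson coefficient against the response,
#' a two-sided p-value from the t statistic `r * sqrt((n-2)/(1-r^2))` with
#' n-2 degrees of freedom, and a 95% confidence interval via the Fisher
#' z-transform (`z +- 1.96 / sqrt(n-3)`, back-transformed). Zero-variance
#' columns return NaN throughout.
#'
#' @param X conditions x features matrix.
#' @param y growth-rate response.
#' @return A `corr_result` data.frame with columns `feature`, `r`, `pval`,
#'   `lb95`, `ub95`.
#' @export
pearson_with_ci <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n != length(y)) stop("rows of X must align with y")
  if (n < 4) stop("need n >= 4 for confidence intervals")
  feats <- if (is.null(colnames(X))) paste0("V", seq_len(ncol(X))) else colnames(X)
  r <- suppressWarnings(as.numeric(stats::cor(X, y)))
  r[apply(X, 2, stats::sd) == 0 | stats::sd(y) == 0] <- NaN
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  pval <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  pval[abs(r) >= 1] <- 0
  z <- atanh(pmin(pmax(r, -1 + 1e-15), 1 - 1e-15))
  half <- 1.96 / sqrt(n - 3)
  out <- data.frame(feature = feats, r = r, pval = pval,
                    lb95 = tanh(z - half), ub95 = tanh(z + half),
                    stringsAsFactors = FALSE)
  out[is.nan(r), c("pval", "lb95", "ub95")] <- NaN
  class(out) <- c("corr_result", class(out))
  out
}

#' Top positively and negatively correlated features
#'
#' Returns the k strongest positive and k strongest negative Pearson
#' correlations (NaN excluded, k clamped to the feature count), with ties
#' broken by feature id for determinism.
#'
#' @param result a `corr_result` from [pearson_with_ci()].
#' @param k number of features per direction (default 10).
#' @return list with data.frames `positive` (descending r) and `negative`
#'   (ascending r).
#' @export
top_k_predictors <- function(result, k = 10) {
  ok <- result[!is.nan(result$r), , drop = FALSE]
  pos <- ok[order(-ok$r, ok$feature), , drop = FALSE]
  neg <- ok[order(ok$r, ok$feature), , drop = FALSE]
  list(positive = utils::head(pos, k), negative = utils::head(neg, k))
}

corr_bin_breaks <- c(-0.7, -0.5, -0.3, -0.1, 0.1, 0.3, 0.5, 0.7)

#' Pathway-level correlation aggregation
#'
#' NaN coefficients are set to 0, then per subsystem: the mean of |r| over
#' member reactions (magnitude of association, direction disregarded) and
#' counts of signed r over seven half-open bins [-0.7,-0.5), ..., [0.5,0.7).
#' Coefficients outside [-0.7, 0.7) land in an `overflow` count rather than
#' vanishing silently.
#'
#' @param r per-reaction correlation coefficients, aligned with model
#'   reaction order.
#' @param index a `subsystem_index`.
#' @return data.frame with `subsystem`, `mean_abs_r`, `cardinality`, the 7
#'   bin-count columns, and `overflow`.
#' @export
pathway_correlation <- function(r, index) {
  r <- as.numeric(r)
  r[is.nan(r) | is.na(r)] <- 0
  bin_labels <- paste0("[", utils::head(corr_bin_breaks, -1), ",",
                       utils::tail(corr_bin_breaks, -1), ")")
  out <- data.frame(subsystem = index$names,
                    mean_abs_r = NA_real_,
                    cardinality = unname(index$cardinality),
                    stringsAsFactors = FALSE)
  counts <- matrix(0L, length(index$names), length(bin_labels) + 1,
                   dimnames = list(NULL, c(bin_labels, "overflow")))
  for (i in seq_along(index$names)) {
    mem <- index$membership[[i]]
    vals <- r[mem]
    out$mean_abs_r[i] <- if (length(vals)) mean(abs(vals)) else 0
    for (b in seq_along(bin_labels)) {
      counts[i, b] <- sum(vals >= corr_bin_breaks[b] & vals < corr_bin_breaks[b + 1])
    }
    counts[i, "overflow"] <- sum(vals < -0.7 | vals >= 0.7)
  }
  cbind(out, as.data.frame(counts, check.names = FALSE))
}
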