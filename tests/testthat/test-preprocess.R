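test_that("filter_unexpressed removes floor-constant genes only", {
  x <- rbind(A = c(1, 2, 3), B = c(0, 0, 0), C = c(4, 0, 5))
  st <- tiny_study(x)
  out <- filter_unexpressed(st)
  expect_equal(rownames(out$values), c("A", "C"))

  st2 <- tiny_study(rbind(A = c(1, 2), B = c(3, 4)))
  expect_identical(filter_unexpressed(st2)$values, st2$values)

  all0 <- tiny_study(matrix(0, 3, 3))
  expect_error(filter_unexpressed(all0), "empty")
})

test_that("forcing a fraction of rows to the floor removes exactly those rows", {
  set.seed(1)
  n <- 200
  x <- matrix(abs(rnorm(n * 6)) + 1, n, 6)
  zero_rows <- sample(n, 0.05 * n)
  x[zero_rows, ] <- 0
  st <- tiny_study(x)
  out <- filter_unexpressed(st)
  expect_equal(nrow(out$values), n - length(zero_rows))
})

test_that("quantile normalization forces the row-mean-of-sorted distribution", {
  st <- tiny_study(cbind(s1 = c(1, 3), s2 = c(2, 4)))
  out <- quantile_normalize(st)$values
  expect_equal(unname(out[, 1]), c(1.5, 3.5))
  expect_equal(unname(out[, 2]), c(1.5, 3.5))

  set.seed(2)
  x <- matrix(rnorm(300), 30, 10)
  qn <- quantile_normalize(tiny_study(x))$values
  expect_lt(diff(range(colMeans(qn))), 1e-12)
  # identical sorted columns
  s <- apply(qn, 2, sort)
  expect_lt(max(abs(s - s[, 1])), 1e-12)
  expect_error(quantile_normalize(tiny_study(matrix(1:3, 3, 1),
                                             pheno = "a")), "2 samples")
})

test_that("tied values share the mean of their reference quantiles", {
  x <- cbind(s1 = c(5, 5, 8), s2 = c(1, 2, 3))
  st <- tiny_study(x)
  out <- quantile_normalize(st)$values
  expect_equal(unname(out), unname(qn_oracle(x)))

  set.seed(3)
  xt <- matrix(sample(1:5, 60, replace = TRUE) + 0, 12, 5)
  expect_equal(unname(quantile_normalize(tiny_study(xt))$values),
               unname(qn_oracle(xt)))
})

test_that("quantile normalization is idempotent and rank-preserving", {
  set.seed(4)
  x <- matrix(rnorm(400), 40, 10)
  st <- tiny_study(x)
  once <- quantile_normalize(st)
  twice <- quantile_normalize(once)
  expect_lt(max(abs(once$values - twice$values)), 1e-12)
  for (j in seq_len(ncol(x)))
    expect_equal(unname(rank(once$values[, j])), rank(x[, j]))
})

test_that("quantile normalization matches the limma reference on tie-free data", {
  set.seed(5)
  x <- matrix(rnorm(500), 50, 10,
              dimnames = list(sprintf("g%d", 1:50), sprintf("s%d", 1:10)))
  ours <- quantile_normalize(tiny_study(x))$values
  ref <- limma::normalizeQuantiles(x)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-12)
})

test_that("TMM factors have the analytic values on simple inputs", {
  x <- matrix(rpois(400, 50) + 1, 100, 4)
  x <- cbind(x[, 1], x[, 1], x[, 1], x[, 1])
  colnames(x) <- paste0("s", 1:4)
  st <- tiny_study(x)
  expect_equal(unname(tmm_factors(st)), rep(1, 4))

  set.seed(6)
  y <- matrix(rpois(200, 100) + 1, 100, 2,
              dimnames = list(sprintf("g%d", 1:100), c("a", "b")))
  y[, 2] <- 2 * y[, 1]
  f <- tmm_factors(tiny_study(y))
  expect_equal(unname(f), c(2^(-0.5), 2^(0.5)), tolerance = 1e-12)
})

test_that("TMM factors have unit geometric mean and are scale-equivariant", {
  set.seed(7)
  x <- matrix(rgamma(600, 3, 0.02), 100, 6)
  x <- round(x) + 1  # tie-free enough after jitter below
  x <- x + matrix(runif(600) * 0.0, 100, 6)
  colnames(x) <- paste0("s", 1:6); rownames(x) <- paste0("g", 1:100)
  st <- tiny_study(x)
  f <- tmm_factors(st)
  expect_lt(abs(exp(mean(log(f))) - 1), 1e-12)

  cmult <- 3.7
  x2 <- x; x2[, 4] <- x2[, 4] * cmult
  f2 <- tmm_factors(tiny_study(x2))
  # ratios to any other sample scale by cmult for the scaled column
  expect_equal(unname(f2[4] / f2[1]), unname(cmult * f[4] / f[1]),
               tolerance = 1e-10)
  expect_equal(unname(f2[2] / f2[1]), unname(f[2] / f[1]), tolerance = 1e-10)
})

test_that("TMM rejects all-zero samples by name", {
  x <- cbind(s1 = c(1, 2, 3), s2 = c(0, 0, 0), s3 = c(2, 3, 4))
  expect_error(tmm_factors(tiny_study(x, pheno = rep("a", 3))), "s2")
})

test_that("log transform triggers on raw-scale values only", {
  logx <- matrix(runif(40, 2, 14), 10, 4)
  st <- tiny_study(logx)
  expect_identical(log_transform_if_needed(st)$values, st$values)

  raw <- matrix(c(1023, rep(5, 7)), 2, 4)
  raw <- rbind(raw, 0)
  st2 <- tiny_study(raw)
  expect_message(out <- log_transform_if_needed(st2), "transformed")
  expect_equal(out$values[1, 1], 10)
  expect_true(all(out$values[3, ] == 0))

  neg <- tiny_study(matrix(c(-5, 100, 3, 4), 2, 2))
  expect_error(log_transform_if_needed(neg), "ambiguous")
})

test_that("PCA separates groups shifted on many genes", {
  set.seed(8)
  x <- matrix(rnorm(100 * 8), 100, 8)
  x[1:60, 5:8] <- x[1:60, 5:8] + 3
  st <- tiny_study(x, pheno = rep(c("a", "b"), each = 4))
  pc <- pca_qc(st)
  groups <- split(pc$scores[, 1], rep(c("a", "b"), each = 4))
  expect_true(max(groups$a) < min(groups$b) || min(groups$a) > max(groups$b))
  expect_true(all(diff(pc$var_explained) <= 1e-12))
  expect_lte(sum(pc$var_explained), 1 + 1e-12)
})

test_that("PCA gives duplicated samples identical scores and rejects constants", {
  set.seed(9)
  x <- matrix(rnorm(50 * 4), 50, 4)
  x <- cbind(x, x[, 1])
  st <- tiny_study(x, pheno = rep("a", 5))
  pc <- pca_qc(st)
  expect_equal(unname(pc$scores[1, ]), unname(pc$scores[5, ]), tolerance = 1e-10)
  expect_error(pca_qc(tiny_study(matrix(1, 5, 4), pheno = rep("a", 4))),
               "no variance")
})

test_that("sample correlation clustering recovers the phenotype bipartition", {
  expect_error(
    sample_correlation_clustering(tiny_study(matrix(rnorm(10), 5, 2))),
    "3 samples")
  x <- matrix(rnorm(40 * 3), 40, 3)
  x[, 3] <- 5  # zero variance
  expect_error(sample_correlation_clustering(tiny_study(x, pheno = rep("a", 3))),
               "s3")

  set.seed(10)
  y <- matrix(rnorm(200 * 8, sd = 0.5), 200, 8)
  y[1:100, 1:4] <- y[1:100, 1:4] + 4   # group a signature genes
  y[101:200, 5:8] <- y[101:200, 5:8] + 4  # group b signature genes
  st <- tiny_study(y, pheno = rep(c("a", "b"), each = 4))
  cl <- sample_correlation_clustering(st)
  expect_true(all(diag(cl$correlation) == 1))
  parts <- stats::cutree(cl$hclust, 2)
  expect_equal(length(unique(parts[1:4])), 1)
  expect_equal(length(unique(parts[5:8])), 1)
  expect_true(parts[1] != parts[5])

  # identical samples merge first at height 0
  z <- matrix(rnorm(60), 20, 3)
  z[, 2] <- z[, 1]
  colnames(z) <- c("a", "b", "c")
  cl2 <- sample_correlation_clustering(tiny_study(z, pheno = rep("x", 3)))
  expect_lt(cl2$hclust$height[1], 1e-12)
  expect_setequal(abs(cl2$hclust$merge[1, ]), c(1, 2))
})
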