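two_group_study <- function(case, control, case_label = "tolDC",
                            control_label = "imDC") {
  x <- rbind(g1 = c(case, control))
  colnames(x) <- sprintf("s%d", seq_len(ncol(x)))
  expression_study(x, rep(c(case_label, control_label),
                          c(length(case), length(control))), "t")
}

test_that("two-group fit reproduces hand-computed sums of squares", {
  st <- two_group_study(c(3, 4, 5), c(1, 2, 3))
  fit <- fit_two_group(st, contrast("tolDC", "imDC"))
  expect_equal(fit$log2_fc, 2)
  expect_equal(fit$s2, 1)
  expect_equal(attr(fit, "df_resid"), 4)
  expect_equal(attr(fit, "se_unit"), sqrt(2 / 3))
})

test_that("fit is label-based: sample order is irrelevant and equal groups give 0", {
  set.seed(1)
  x <- matrix(rnorm(50 * 8), 50, 8,
              dimnames = list(sprintf("g%d", 1:50), sprintf("s%d", 1:8)))
  ph <- rep(c("tolDC", "imDC"), 4)
  st <- expression_study(x, ph, "a")
  perm <- sample(8)
  st2 <- expression_study(x[, perm], ph[perm], "a")
  f1 <- fit_two_group(st, contrast("tolDC", "imDC"))
  f2 <- fit_two_group(st2, contrast("tolDC", "imDC"))
  expect_equal(f1$log2_fc, f2$log2_fc)
  expect_equal(f1$s2, f2$s2)

  xx <- cbind(x, x)
  colnames(xx) <- c(colnames(x), paste0(colnames(x), "b"))
  same <- expression_study(xx, rep(c("tolDC", "imDC"), each = 8), "b")
  expect_true(all(fit_two_group(same, contrast("tolDC", "imDC"))$log2_fc == 0))
})

test_that("undersized groups and missing values are handled", {
  st <- two_group_study(c(3), c(1, 2))
  expect_error(fit_two_group(st, contrast("tolDC", "imDC")), "tolDC")
  x <- matrix(rnorm(20), 5, 4,
              dimnames = list(sprintf("g%d", 1:5), sprintf("s%d", 1:4)))
  x[2, 1] <- NA
  st2 <- expression_study(x, rep(c("tolDC", "imDC"), each = 2), "m")
  expect_message(f <- fit_two_group(st2, contrast("tolDC", "imDC")), "missing")
  expect_equal(nrow(f), 4)
})

test_that("moderation with d0 = 0 reproduces the classical pooled t-test", {
  set.seed(2)
  x <- matrix(rnorm(1000 * 7, sd = rep(runif(1000, 0.3, 2), 7)), 1000, 7,
              dimnames = list(sprintf("g%d", 1:1000), sprintf("s%d", 1:7)))
  st <- expression_study(x, c(rep("tolDC", 4), rep("imDC", 3)), "c")
  de <- run_de(st, contrast("tolDC", "imDC"), moderate = FALSE)
  ref_t <- apply(x, 1, function(v)
    t.test(v[1:4], v[5:7], var.equal = TRUE)$statistic)
  ref_p <- apply(x, 1, function(v)
    t.test(v[1:4], v[5:7], var.equal = TRUE)$p.value)
  expect_lt(max(abs(de$t_mod - ref_t)), 1e-10)
  expect_lt(max(abs(de$p - ref_p)), 1e-10)
})

test_that("constant variances collapse the prior onto the common value", {
  eb <- ebayes_moderate(rep(0.37, 200), df_resid = 6)
  expect_identical(eb$d0, Inf)
  expect_equal(eb$s0_sq, 0.37)
  expect_true(all(eb$s2_post == 0.37))
})

test_that("moment estimator recovers simulated prior df and variance", {
  cfg <- sim_config(n_studies = 1, n_genes = 8000, n_consensus_up = 0,
                    n_consensus_down = 0, n_discordant = 0,
                    d0_sim = 4, s0_sim = 0.05, seed = 31)
  sim <- simulate_bulk_studies(cfg)
  fit <- fit_two_group(sim$studies[[1]], contrast("tolDC", "imDC"))
  eb <- ebayes_moderate(fit$s2, attr(fit, "df_resid"))
  expect_lt(abs(eb$d0 - 4) / 4, 0.15)
  expect_lt(abs(eb$s0_sq - 0.05) / 0.05, 0.15)
})

test_that("posterior variances interpolate between the prior and the observed", {
  set.seed(3)
  s2 <- rchisq(500, 3) / 10
  eb <- ebayes_moderate(s2, 6)
  lo <- pmin(s2, eb$s0_sq); hi <- pmax(s2, eb$s0_sq)
  expect_true(all(eb$s2_post >= lo - 1e-12 & eb$s2_post <= hi + 1e-12))
  expect_warning(ebayes_moderate(rep(0.5, 5), 6), "fewer than 10")
})

test_that("the full stage agrees with the limma reference implementation", {
  cfg <- sim_config(n_studies = 1, n_genes = 3000, seed = 41)
  sim <- simulate_bulk_studies(cfg)
  st <- sim$studies[[1]]
  de <- run_de(st, contrast("tolDC", "imDC"))
  design <- stats::model.matrix(~ factor(st$phenotype,
                                         levels = c("imDC", "tolDC")))
  fit <- limma::eBayes(limma::lmFit(st$values, design))
  idx <- match(de$gene, rownames(st$values))
  expect_equal(attr(de, "d0"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(de, "s0_sq"), fit$s2.prior, tolerance = 1e-6)
  expect_lt(max(abs(de$t_mod - fit$t[idx, 2])), 1e-8)
  expect_lt(max(abs(de$p - fit$p.value[idx, 2])), 1e-8)
})

test_that("moderated t matches the classical oracle on the worked example", {
  st <- two_group_study(c(3, 4, 5), c(1, 2, 3))
  de <- run_de(st, contrast("tolDC", "imDC"), moderate = FALSE)
  expect_equal(de$t_mod, 2.449, tolerance = 1e-3)
  expect_equal(de$df_total, 4)
  expect_equal(de$p, 0.0705, tolerance = 1e-3)

  mt <- moderated_t(log2_fc = 0, s2_post = 1, se_unit = 1, df_total = 4)
  expect_equal(mt$t_mod, 0)
  expect_equal(mt$p, 1)

  a <- moderated_t(2, 1, 1, 4)$t_mod
  b <- moderated_t(2, 2, 1, 4)$t_mod
  expect_equal(a^2 / b^2, 2, tolerance = 1e-12)

  deg <- moderated_t(c(1, 0), c(0, 0), 1, 4)
  expect_equal(deg$p, c(0, 1))
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.005, 0.1, 0.9)), c(0.015, 0.15, 0.9))
  expect_equal(bh_adjust(c(0.04, 0.03, 0.02, 0.01)), rep(0.04, 4))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(4)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_adjust(p), bh_stepup_oracle(p), tolerance = 1e-12)
  }
})

test_that("BH is permutation-equivariant and monotone", {
  set.seed(5)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  adj <- bh_adjust(p)
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-15))
})

test_that("per-study DE counts use the adjusted 0.05 rule", {
  cfg <- sim_config(n_studies = 1, n_genes = 2000, n_consensus_up = 50,
                    n_consensus_down = 50, n_discordant = 0, seed = 51)
  sim <- simulate_bulk_studies(cfg)
  de <- run_de(sim$studies[[1]], contrast("tolDC", "imDC"))
  n_de <- sum(de$p_adj < 0.05)
  expect_gt(n_de, 0)
  # detected genes are overwhelmingly true consensus genes (FDR control)
  detected <- de$gene[de$p_adj < 0.05]
  expect_gt(mean(sim$truth$class[detected] != "null"), 0.9)
  expect_true(all(de$p_adj >= de$p))
  expect_true(all(de$p_adj <= 1) && all(de$p >= 0))
  expect_true(all(sign(de$t_mod) == sign(de$log2_fc) | de$log2_fc == 0))
})
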