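two_group <- function(ctrl, expo) {
  m <- matrix(c(ctrl, expo), nrow = 1,
              dimnames = list("g1", sprintf("s%d", seq_along(c(ctrl, expo)))))
  cond <- rep(c("control", "exposed"), c(length(ctrl), length(expo)))
  list(m = m, cond = cond)
}

test_that("per-gene OLS fit recovers means, pooled variance and df", {
  d <- two_group(c(5, 5), c(7, 7))
  fit <- fit_gene_models(d$m, d$cond)
  expect_equal(fit$log2fc, 2)
  expect_equal(fit$s_g_sq, 0)

  d2 <- two_group(c(4, 6), c(5, 7))
  fit2 <- fit_gene_models(d2$m, d2$cond)
  expect_equal(fit2$log2fc, 1)
  expect_equal(fit2$s_g_sq, 2)   # pooled within-group variance
  expect_equal(fit2$df_g, 2L)
  expect_equal(attr(fit2, "stderr_scale"), 1)

  # matches lm() on the two-group design
  set.seed(4)
  m <- random_matrix(5, 9, seed = 4) + 8
  cond <- rep(c("control", "exposed"), c(4, 5))
  fit3 <- fit_gene_models(m, cond)
  for (i in 1:5) {
    ls <- lm(m[i, ] ~ I(cond == "exposed"))
    expect_equal(fit3$log2fc[i], unname(coef(ls)[2]), tolerance = 1e-12)
    expect_equal(fit3$s_g_sq[i], summary(ls)$sigma^2, tolerance = 1e-12)
  }

  # invariant under sample permutation
  perm <- sample(9)
  fit4 <- fit_gene_models(m[, perm], cond[perm])
  expect_equal(fit4, fit3, ignore_attr = TRUE)

  expect_error(fit_gene_models(m, rep(c("control", "exposed"), c(1, 8))),
               "at least 2")
})

test_that("moderation fit matches the moment equations and its limits", {
  # identical variances: no heterogeneity, complete shrinkage
  p0 <- estimate_moderation(rep(2.5, 50), df_g = 4)
  expect_equal(p0$d0, Inf)
  expect_equal(p0$s0_sq, 2.5, tolerance = 1e-9)

  # two genes with distinct variances: finite positive d0; the fitted d0
  # must solve the trigamma moment equation found by an independent
  # root-finder
  p2 <- estimate_moderation(c(1, 4), df_g = 4)
  expect_true(is.finite(p2$d0) && p2$d0 > 0)
  e <- log(c(1, 4)) - digamma(2) + log(2)
  evar <- var(e) - trigamma(2)
  root <- uniroot(function(x) trigamma(x) - evar, c(1e-3, 1e3),
                  tol = 1e-12)$root
  expect_equal(p2$d0, 2 * root, tolerance = 1e-6)

  # zero-variance genes are excluded from the fit
  pz <- estimate_moderation(c(0, 1, 4), df_g = 4)
  expect_equal(pz$d0, p2$d0)

  # fewer than 2 usable variances: fall back to complete shrinkage
  p1 <- estimate_moderation(c(0, 3), df_g = 4)
  expect_equal(p1$d0, Inf)
  expect_equal(p1$s0_sq, 3)
})

test_that("moderation fit agrees with the reference empirical-Bayes
           implementation", {
  set.seed(10)
  s2 <- 1.3 * rf(500, df1 = 6, df2 = 5)
  mine <- estimate_moderation(s2, df_g = 6)
  ref <- limma::fitFDist(s2, df1 = 6)
  expect_equal(mine$d0, ref$df2, tolerance = 1e-6)
  expect_equal(mine$s0_sq, ref$scale, tolerance = 1e-6)
})

test_that("moderated t obeys the shrinkage formula and its limits", {
  # direct formula: d0 = 4, s0^2 = 1, s_g^2 = 2, df_g = 4 -> s_post^2 = 1.5
  mt <- moderated_t(log2fc = 3, s_g_sq = 2, df_g = 4,
                    params = list(d0 = 4, s0_sq = 1), stderr_scale = 1)
  expect_equal((3 / mt$t_mod)^2, 1.5, tolerance = 1e-12)
  expect_equal(mt$df_total, 8)

  # d0 = 0: ordinary two-sample t, identical to t.test(var.equal = TRUE)
  d <- two_group(c(4.1, 5.3, 4.8), c(6.0, 6.7, 5.9))
  fit <- fit_gene_models(d$m, d$cond)
  mt0 <- moderated_t(fit$log2fc, fit$s_g_sq, fit$df_g,
                     params = list(d0 = 0, s0_sq = 1),
                     stderr_scale = attr(fit, "stderr_scale"))
  tt <- t.test(d$m[1, 4:6], d$m[1, 1:3], var.equal = TRUE)
  expect_equal(mt0$t_mod, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(mt0$p, tt$p.value, tolerance = 1e-12)

  # d0 = Inf: every gene shares the prior variance
  mtI <- moderated_t(c(1, 2), c(0.5, 8), 4,
                     params = list(d0 = Inf, s0_sq = 2), stderr_scale = 1)
  expect_equal(mtI$t_mod, c(1, 2) / sqrt(2), tolerance = 1e-12)

  # zero posterior variance flags infinite t with p = 0
  expect_warning(
    mtz <- moderated_t(1, 0, 4, params = list(d0 = 0, s0_sq = 1),
                       stderr_scale = 1),
    "zero posterior variance")
  expect_equal(mtz$t_mod, Inf)
  expect_equal(mtz$p, 0)
})

test_that("moderated pipeline matches the reference implementation
           end to end", {
  set.seed(77)
  m <- matrix(rnorm(200 * 8, mean = 8, sd = 0.6), 200, 8,
              dimnames = list(sprintf("g%03d", 1:200), sprintf("s%d", 1:8)))
  cond <- rep(c("control", "exposed"), each = 4)
  de <- run_de(m, cond)
  design <- cbind(1, cond == "exposed")
  ref <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(de$log2fc, unname(ref$coefficients[, 2]), tolerance = 1e-10)
  expect_equal(de$t_mod, unname(ref$t[, 2]), tolerance = 1e-6)
  expect_equal(de$p, unname(ref$p.value[, 2]), tolerance = 1e-6)
})

test_that("BH step-up matches hand-computed vectors, the literal-definition
           oracle, and is permutation invariant", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bh_adjust(c(0.005, 0.1)), c(0.01, 0.1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(55)
  for (rep in 1:20) {
    p <- runif(sample(2:40, 1))^sample(1:3, 1)
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_equal(adj, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15), all(adj <= 1))
    # monotone along sorted raw p
    expect_true(!is.unsorted(adj[order(p)]))
    # permutation invariance after mapping back
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm])[order(perm)], adj, tolerance = 1e-15)
  }
})

test_that("the study DE filter keeps FC >= 1.5 at adj p < 0.05 and reports
           near-misses", {
  res <- data.frame(
    gene = c("boundary", "nearmiss", "bigfc_ns", "clear"),
    log2fc = c(log2(1.5), -log2(1.4), log2(3), -1.2),
    fold_change = c(1.5, 1.4, 3.0, 2^1.2),
    direction = c("up", "down", "up", "down"),
    t_mod = 0, df_total = 8,
    p = c(0.01, 0.001, 0.05, 0.001),
    p_adj = c(0.049, 0.01, 0.2, 0.01),
    stringsAsFactors = FALSE)
  out <- de_filter(res)
  expect_setequal(out$gene, c("boundary", "clear"))
  nm <- attr(out, "near_miss")
  expect_equal(nm$gene, "nearmiss")   # significant but FC 1.4 < 1.5
  expect_false("bigfc_ns" %in% c(out$gene, nm$gene))
  # fold change always >= 1 with a direction flag
  expect_true(all(res$fold_change >= 1))
  expect_equal(res$direction == "down", res$log2fc < 0)
})
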