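test_that("shannon diversity matches closed forms and the vegan oracle", {
  expect_equal(shannon_diversity(rep(1, 4)), log(4))
  expect_equal(shannon_diversity(c(0, 5, 0)), 0)
  expect_equal(shannon_diversity(c(0.5, 0.25, 0.25)), 1.039721, tolerance = 1e-6)
  expect_error(shannon_diversity(c(0, 0)), "all-zero")
  set.seed(1)
  x <- rgamma(30, 1)
  expect_equal(shannon_diversity(x), unname(vegan::diversity(x)), tolerance = 1e-12)
})

test_that("richness counts entries above the detection threshold", {
  expect_equal(observed_richness(c(0, 0, 0)), 0)
  expect_equal(observed_richness(c(0.1, 0, 0.9)), 2)
  expect_equal(observed_richness(c(0.1, 0.2, 0.7), threshold = 0.15), 2)
})

test_that("Bray-Curtis matches hand values, bounds, and vegdist", {
  m <- cbind(a = c(0.6, 0.4), b = c(0.4, 0.6))
  expect_equal(bray_curtis(m)["a", "b"], 0.2)
  expect_equal(bray_curtis(cbind(x = 1:3, y = 1:3))["x", "y"], 0)
  expect_equal(bray_curtis(cbind(x = c(1, 0), y = c(0, 1)))["x", "y"], 1)
  set.seed(3)
  mm <- matrix(rgamma(60, 0.5), 6)
  colnames(mm) <- paste0("s", 1:10)
  D <- bray_curtis(mm)
  expect_true(all(D >= 0 & D <= 1))
  expect_equal(unname(D), unname(as.matrix(vegan::vegdist(t(mm), "bray"))),
               tolerance = 1e-12)
  # identity of indiscernibles on normalized columns
  norm <- sweep(mm, 2, colSums(mm), "/")
  norm <- cbind(norm, dup = norm[, 1])
  Dn <- bray_curtis(norm)
  expect_true(all(diag(Dn) == 0))
  expect_equal(Dn["s1", "dup"], 0)
  distinct <- Dn[upper.tri(Dn)]
  expect_true(sum(distinct == 0) == 1)  # only the planted duplicate pair
  # all-zero pair is flagged NA
  expect_warning(Dz <- bray_curtis(cbind(a = c(0, 0), b = c(0, 0), c = c(1, 2))),
                 "all-zero")
  expect_true(is.na(Dz["a", "b"]))
})

test_that("PCoA round-trips Euclidean geometry and matches cmdscale", {
  pts <- matrix(c(0, 0, 3, 0, 0, 4, 3, 4), ncol = 2, byrow = TRUE)
  D <- as.matrix(dist(pts))
  ord <- pcoa_ordination(D)
  expect_equal(as.matrix(dist(ord$points)), D, tolerance = 1e-8,
               ignore_attr = TRUE)
  ref <- stats::cmdscale(D, k = 2, eig = TRUE)
  expect_equal(sort(ord$eigenvalues, decreasing = TRUE)[1:2],
               sort(ref$eig, decreasing = TRUE)[1:2], tolerance = 1e-8)
  # equidistant points: all positive eigenvalues equal
  n <- 5
  De <- matrix(1, n, n) - diag(n)
  eq <- pcoa_ordination(De)
  pos <- eq$eigenvalues[eq$eigenvalues > 1e-9]
  expect_equal(max(pos) - min(pos), 0, tolerance = 1e-10)
  # duplicated sample lands on coincident coordinates
  D2 <- as.matrix(dist(pts[c(1, 1, 2, 3), ]))
  ord2 <- pcoa_ordination(D2)
  expect_equal(ord2$points[1, ], ord2$points[2, ], tolerance = 1e-8)
  expect_error(pcoa_ordination(D[1:2, 1:2]), "at least 3")
})

test_that("PERMANOVA matches its algebraic identities and vegan::adonis2", {
  set.seed(11)
  pts <- matrix(rnorm(40), ncol = 2)
  grp <- rep(c("a", "b"), each = 10)
  D <- as.matrix(dist(pts))
  fit <- permanova(D, grp, n_permutations = 99, seed = 5)
  expect_equal(fit$r2, oracle_permanova_r2(D, grp), tolerance = 1e-10)
  ref <- vegan::adonis2(as.dist(D) ~ grp, permutations = 99)
  expect_equal(fit$r2, ref$R2[1], tolerance = 1e-10)
  expect_equal(fit$f_stat, ref$F[1], tolerance = 1e-10)
  # adjusted R2 equals the Ezekiel formula vegan::RsquareAdj uses
  expect_equal(fit$adjusted_r2,
               1 - (1 - fit$r2) * (nrow(D) - 1) / (nrow(D) - 1 - 1), tolerance = 1e-12)
  # identical point sets in both groups: R2 ~ 0, p ~ 1
  Dnull <- as.matrix(dist(rbind(pts[1:10, ], pts[1:10, ])))
  fit0 <- permanova(Dnull, grp, n_permutations = 199, seed = 2)
  expect_lt(fit0$r2, 0.05)
  expect_gt(fit0$p_value, 0.5)
})

test_that("PERMANOVA guards its design matrix", {
  D <- as.matrix(dist(matrix(rnorm(20), ncol = 2)))
  x <- rnorm(10)
  expect_error(permanova(D, cbind(x, x)), "rank-deficient")
  fit <- permanova(D, cbind(x, x), n_permutations = 49, seed = 1,
                   drop_collinear = TRUE)
  expect_equal(fit$df_model, 1)
  expect_error(permanova(D, rep(1, 10)), "constant|no variation|contrasts")
  expect_error(permanova(D[1:3, 1:3], 1:3), "at least 4")
  expect_error(permanova(D, x, exhaustive = TRUE), "exhaustive")
  expect_error(permanova(D, x, n_permutations = 9), "seed")
})

test_that("exact Wilcoxon equals enumeration and the stats oracle", {
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p_value, 0.1)
  expect_equal(r$statistic, 6)
  set.seed(11)
  x <- rnorm(10); y <- rnorm(10)
  pe <- wilcoxon_rank_sum(x, y, mode = "exact")$p_value
  pn <- wilcoxon_rank_sum(x, y, mode = "normal")$p_value
  expect_lt(abs(pe - pn), 0.01)
  expect_equal(pe, stats::wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
  # identical samples sit at the null center
  expect_gt(wilcoxon_rank_sum(1:5 + 0.5, 1:5 + 0.25, mode = "normal")$p_value, 0.4)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("Kruskal-Wallis matches hand computation and kruskal.test", {
  h <- kruskal_wallis(list(1:3, 4:6, 7:9))
  expect_equal(h$statistic, 7.2)
  same <- kruskal_wallis(list(c(1, 2), c(1, 2), c(1, 2)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  set.seed(4)
  g <- list(rnorm(7), rnorm(5, 1), rnorm(6, -1), c(1, 1, 2, 2))
  ref <- stats::kruskal.test(unlist(g), rep(seq_along(g), lengths(g)))
  mine <- kruskal_wallis(g)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  expect_error(kruskal_wallis(list(1:3, 4:6)), "3 groups")
})

test_that("Student's t matches hand values, symmetry, and t.test", {
  expect_equal(t_test2(c(1, 2, 3), c(2, 3, 4))$statistic, -1.224745, tolerance = 1e-6)
  p0 <- t_test2(c(1, 2, 3), c(1, 2, 3), paired = TRUE)
  expect_equal(p0$statistic, 0)
  expect_equal(p0$p_value, 1)
  set.seed(9)
  x <- rnorm(8); y <- rnorm(9, 0.5)
  mine <- t_test2(x, y)
  ref <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  # scale invariance
  expect_equal(t_test2(10 * x, 10 * y)$statistic, mine$statistic, tolerance = 1e-12)
})

test_that("BH adjustment matches the step-up definition and p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  set.seed(2)
  p <- runif(50)^2
  q <- bh_adjust(p)
  expect_equal(q, stats::p.adjust(p, "BH"), tolerance = 1e-14)
  expect_true(all(q >= p))
  # order invariance
  o <- sample(50)
  expect_equal(bh_adjust(p[o]), q[o], tolerance = 1e-14)
  # NAs preserved, excluded from m
  pn <- c(0.01, NA, 0.04)
  expect_equal(bh_adjust(pn), stats::p.adjust(pn, "BH"), tolerance = 1e-14)
})

test_that("Spearman rho matches rank hand-computation and cor.test", {
  expect_equal(spearman_test(1:5, (1:5)^3)$statistic, 1)
  expect_equal(spearman_test(1:5, -(1:5))$statistic, -1)
  expect_equal(spearman_test(c(1, 2, 3, 4), c(1, 3, 2, 4))$statistic, 0.8)
  set.seed(6)
  x <- rnorm(20); y <- x + rnorm(20)
  mine <- spearman_test(x, y)
  ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  expect_equal(mine$statistic, unname(ref$estimate), tolerance = 1e-12)
  # cor.test uses the exact AS89 distribution here; the t approximation
  # the package implements agrees to a few 1e-4
  expect_lt(abs(mine$p_value - ref$p.value), 5e-3)
  expect_error(spearman_test(rep(1, 5), 1:5), "constant")
})

test_that("exact Wilcoxon equals enumeration for every split of n <= 8", {
  set.seed(13)
  vals <- sample(1:50, 8)
  for (nx in 1:7) {
    x <- vals[seq_len(nx)]
    y <- vals[(nx + 1):8]
    expect_equal(wilcoxon_rank_sum(x, y, mode = "exact")$p_value,
                 enum_wilcoxon_p(x, y), tolerance = 1e-12,
                 info = paste("split", nx))
  }
})

test_that("PERMANOVA p-values are uniform under a permutation null", {
  set.seed(21)
  ps <- vapply(1:10, function(s) {
    pts <- matrix(rnorm(32), ncol = 2)
    grp <- sample(rep(c("a", "b"), each = 8))
    permanova(as.matrix(dist(pts)), grp, n_permutations = 199, seed = s)$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})
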