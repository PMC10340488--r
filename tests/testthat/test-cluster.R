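# PCA projection of 3-class logits and the Dist/SD separability ratio.

test_that("projection preserves planar geometry and orders variance", {
  set.seed(14)
  # points already in a plane through 3-space: pairwise distances preserved
  basis <- qr.Q(qr(matrix(rnorm(9), 3)))[, 1:2]
  uv <- matrix(rnorm(40), 20, 2)
  pts <- uv %*% t(basis)
  colnames(pts) <- c("L1", "L2", "L3")
  pr <- project_logits(as.data.frame(pts))
  d_before <- dist(pts); d_after <- dist(cbind(pr$PC1, pr$PC2))
  expect_equal(as.vector(d_after), as.vector(d_before), tolerance = 1e-9)
  # eigenvalue ordering on random clouds
  cloud <- data.frame(L1 = rnorm(50, sd = 3), L2 = rnorm(50), L3 = rnorm(50, sd = 0.5))
  pr2 <- project_logits(cloud)
  expect_gte(stats::var(pr2$PC1), stats::var(pr2$PC2))
  # rank-1 case: collinear points have zero PC2
  line <- data.frame(L1 = 1:10, L2 = 2 * (1:10), L3 = -(1:10))
  pr3 <- project_logits(line)
  expect_equal(pr3$PC2, rep(0, 10), tolerance = 1e-9)
  # degenerate cloud errors
  same <- data.frame(L1 = rep(1, 5), L2 = rep(2, 5), L3 = rep(3, 5))
  expect_error(project_logits(same), "degenerate")
})

test_that("cluster summary reproduces the published worked example", {
  # pairwise centroid distances 3.94/3.34/2.99 and per-cluster SDs
  # 1.32/1.60/1.33 give totals 10.27 and 2.46 and ratio 12.52
  dist_total <- 3.94 + 3.34 + 2.99
  expect_equal(dist_total, 10.27)
  sd_total <- sqrt(1.32^2 + 1.60^2 + 1.33^2)
  expect_equal(round(sd_total, 2), 2.46)
  # the table's ratio is computed from its printed (2 d.p.) totals
  expect_equal(round(3 * dist_total / round(sd_total, 2), 2), 12.52)

  # the same combiners via summarize_clusters on constructed points:
  # clusters at known centroids with known component SDs
  set.seed(15)
  mk <- function(cx, cy, n = 400) {
    data.frame(PC1 = cx + rnorm(n), PC2 = cy + rnorm(n))
  }
  pts <- rbind(mk(0, 0), mk(5, 0), mk(0, 7))
  pts$label <- rep(1:3, each = 400)
  cs <- summarize_clusters(pts)
  expect_equal(cs$dist_total, sum(cs$pairwise_dists), tolerance = 1e-9)
  expect_equal(cs$sd_total, sqrt(sum(cs$sd_per_cluster^2)), tolerance = 1e-9)
  expect_equal(cs$ratio, 3 * cs$dist_total / cs$sd_total, tolerance = 1e-9)
  expect_equal(unname(cs$pairwise_dists), c(5, sqrt(74), 7), tolerance = 0.2)
  # isotropic unit clusters: sd_c -> sqrt(2)
  expect_equal(unname(cs$sd_per_cluster), rep(sqrt(2), 3), tolerance = 0.1)
})

test_that("zero-spread clusters raise errors", {
  pts <- data.frame(PC1 = rep(c(0, 1, 2), each = 3),
                    PC2 = rep(c(0, 1, 2), each = 3),
                    label = rep(1:3, each = 3))
  cs <- summarize_clusters(pts)
  expect_error(dist_sd_ratio(cs), "zero")
  one <- data.frame(PC1 = c(0, 0, 1, 1, 2), PC2 = 0, label = c(1, 1, 2, 2, 3))
  expect_error(summarize_clusters(one), "insufficient")
})

test_that("the ratio is invariant to rigid motions and scales correctly", {
  lg <- make_logits(logit_sim_params(n_per_class = 60, seed = 16))
  base <- summarize_clusters(project_logits(lg))
  xyz <- as.matrix(lg[, 1:3])
  rot <- qr.Q(qr(matrix(c(1, 2, 0, -1, 1, 3, 2, 0, 1), 3)))
  moved <- as.data.frame(xyz %*% rot + matrix(c(5, -3, 2), nrow(xyz), 3,
                                              byrow = TRUE))
  names(moved) <- c("L1", "L2", "L3"); moved$label <- lg$label
  rotated <- summarize_clusters(project_logits(moved))
  expect_equal(sort(rotated$pairwise_dists), sort(base$pairwise_dists),
               tolerance = 1e-6)
  expect_equal(rotated$sd_total, base$sd_total, tolerance = 1e-6)
  expect_equal(rotated$ratio, base$ratio, tolerance = 1e-6)

  # scaling all points leaves the ratio unchanged; halving SDs doubles it
  scaled <- lg; scaled[, 1:3] <- scaled[, 1:3] * 3.7
  expect_equal(summarize_clusters(project_logits(scaled))$ratio, base$ratio,
               tolerance = 1e-9)
})

test_that("parameters are recovered from synthetic logit clouds", {
  n <- 500; sigma <- 1
  lg <- make_logits(logit_sim_params(n_per_class = n, spread_sd = sigma,
                                     seed = 17))
  cs <- summarize_clusters(project_logits(lg))
  truth <- logit_sim_params()$centroids
  true_d <- c(dist(truth))[c(1, 3, 2)] # (1,2), (2,3), (1,3) ordering
  expect_equal(unname(cs$pairwise_dists), true_d,
               tolerance = 3 * sigma / sqrt(n) * 3)
  # isotropic spread sigma in the plane -> per-cluster sd near sigma*sqrt(2)
  expect_equal(unname(cs$sd_per_cluster), rep(sigma * sqrt(2), 3),
               tolerance = 0.1)
})

test_that("greater true separation raises the expected ratio", {
  seps <- c(2, 5, 10)
  ratios <- sapply(seps, function(s) {
    cen <- rbind(c(s, 0, 0), c(0, s, 0), c(0, 0, s))
    mean(sapply(1:3, function(r) {
      lg <- make_logits(logit_sim_params(centroids = cen, n_per_class = 80,
                                         seed = 20 + r))
      summarize_clusters(project_logits(lg))$ratio
    }))
  })
  expect_true(all(diff(ratios) > 0))
})
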