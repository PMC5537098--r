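test_that("lambda selection follows the within-sigma homogeneity rule", {
  # Gaussian-filled lesion: ~68% of pixels within one sd -> 0.75
  set.seed(1)
  px <- matrix(100, 96, 96)
  m <- disk_mask(96, c(48, 48), 20)
  px[m] <- round(rnorm(sum(m), 40, 8))
  expect_equal(as.numeric(select_lambda(lesion_image(px, m))), 0.75)

  # three-valued 45% / 45% / 10% lesion: fraction within one sd is 0.10
  vals <- c(rep(0, 9), rep(10, 9), rep(5, 2))
  px2 <- matrix(100, 64, 64)
  m2 <- rect_mask(64, 30, 33, 30, 34)   # 20 px
  px2[m2] <- vals
  lam <- select_lambda(lesion_image(px2, m2))
  expect_equal(as.numeric(lam), 0.15)
  expect_equal(attr(lam, "frac_within_sigma"), 0.10)

  # fraction exactly 0.68 sits on the inclusive boundary -> 0.75
  vals3 <- c(rep(0, 8), rep(100, 8), rep(50, 34))
  px3 <- matrix(200, 64, 64)
  m3 <- rect_mask(64, 30, 34, 30, 39)   # 50 px
  px3[m3] <- vals3
  lam3 <- select_lambda(lesion_image(px3, m3))
  expect_equal(attr(lam3, "frac_within_sigma"), 0.68)
  expect_equal(as.numeric(lam3), 0.75)
})

test_that("the thresholding objective reduces correctly at extreme lambda", {
  ph <- similar_lesion_phantom(1, seed = 2, noise_sigma = 3)
  img <- ph$image
  for (T in c(30, 60, 90)) {
    expect_equal(threshold_objective(img, 0, T), j_oracle(img, 0, T))
    expect_equal(threshold_objective(img, 1, T), j_oracle(img, 1, T))
  }
  # noiseless two-level crop: sigma_w = 0, so J = -lambda * |m_l - m_b|
  nl <- similar_lesion_phantom(0, seed = 2, noise_sigma = 0)$image
  J <- threshold_objective(nl, 0.75, 50)
  expect_equal(J, -0.75 * abs(mean(nl$pixels[nl$crop & nl$pixels <= 50]) -
                                mean(nl$pixels[nl$crop & nl$pixels > 50])))
  expect_equal(threshold_objective(nl, 0, 50), 0)
  # a threshold emptying one class yields the +Inf sentinel
  expect_identical(threshold_objective(nl, 0.75, 10000), Inf)
})

test_that("grid optimisation equals brute force and breaks ties low", {
  for (s in 1:3) {
    img <- similar_lesion_phantom(2, seed = s, noise_sigma = 4)$image
    grid <- seq(0, 120, by = 2)
    t_star <- optimize_threshold(img, 0.75, grid)
    j_all <- vapply(grid, function(T) j_oracle(img, 0.75, T), numeric(1))
    expect_equal(as.numeric(t_star), grid[which.min(j_all)])
  }
  # noiseless two-level image: every T strictly between the levels ties;
  # the smallest such grid point must be returned
  nl <- similar_lesion_phantom(0, seed = 1, noise_sigma = 0)$image
  grid <- 20:100
  t_star <- optimize_threshold(nl, 0.75, grid)
  j_all <- vapply(grid, function(T) j_oracle(nl, 0.75, T), numeric(1))
  expect_equal(as.numeric(t_star), min(grid[j_all == min(j_all)]))
  expect_equal(as.numeric(optimize_threshold(nl, 0.75, 55)), 55)
  expect_error(optimize_threshold(nl, 0.75, numeric(0)), "nonempty")
})

test_that("component labelling is 4-connected, filtered and ordered", {
  g <- matrix(FALSE, 40, 40)
  g[5:10, 5:10] <- TRUE          # 36 px
  g[25:30, 25:30] <- TRUE        # 36 px
  comps <- label_components(g, 9)
  expect_length(comps, 2)
  expect_identical(unname(comps[[1]][1, ]), c(5L, 5L))  # scanline order
  # sub-threshold blob dropped
  g2 <- g; g2[35, 35] <- TRUE; g2[35, 36] <- TRUE
  expect_length(label_components(g2, 9), 2)
  expect_length(label_components(g2, 1), 3)
  # diagonal-only adjacency does not connect under 4-connectivity
  d <- matrix(FALSE, 10, 10)
  d[3, 3] <- TRUE; d[4, 4] <- TRUE
  expect_length(label_components(d, 1), 2)
})

test_that("cluster signatures capture contrast and elongation", {
  img <- disk_image(size = 96, radius = 12, level = 100, bg = 50,
                    center = c(48, 48))
  sig <- cluster_signature(img, which(img$mask, arr.ind = TRUE))
  expect_equal(sig$alpha, 50, tolerance = 1e-6)
  expect_lt(sig$beta, 1.1)

  # 40 x 4 rectangle: beta equals the moment-axis ratio from a direct
  # covariance oracle
  m <- rect_mask(96, 21, 60, 40, 43)
  px <- matrix(10, 96, 96); px[m] <- 60
  img_r <- lesion_image(px, m)
  coords <- which(m, arr.ind = TRUE)
  ev <- eigen(cov(coords) * (nrow(coords) - 1) / nrow(coords))$values
  sig_r <- cluster_signature(img_r, coords)
  expect_equal(sig_r$beta, sqrt(ev[1] / ev[2]), tolerance = 1e-9)

  # a cluster indistinguishable from its surround has alpha ~ 0
  px_f <- matrix(77, 64, 64)
  m_f <- disk_mask(64, c(32, 32), 8)
  img_f <- lesion_image(px_f + 0 * m_f, disk_mask(64, c(32, 32), 10))
  sig_f <- cluster_signature(img_f, which(m_f, arr.ind = TRUE))
  expect_equal(sig_f$alpha, 0, tolerance = 1e-9)
})

test_that("the similarity distance is the (alpha, beta) Euclidean metric", {
  s <- function(a, b) structure(list(alpha = a, beta = b, pixel_count = 10),
                                class = "cluster_signature")
  expect_equal(similarity_distance(s(3, 1), s(0, 5)), 5)
  expect_equal(similarity_distance(s(2, 7), s(2, 7)), 0)
  expect_equal(similarity_distance(s(1, 9), s(4, 2)),
               similarity_distance(s(4, 2), s(1, 9)))
})

test_that("similar-lesion counting recovers planted satellites", {
  expect_equal(count_similar_lesions(
    similar_lesion_phantom(3, seed = 5)$image)$count, 3)
  expect_equal(count_similar_lesions(
    similar_lesion_phantom(0, seed = 5)$image)$count, 0)
  res <- count_similar_lesions(
    similar_lesion_phantom(2, n_dissimilar = 2, seed = 5)$image)
  expect_equal(res$count, 2)
  rejected <- dplyr::filter(res$clusters, !accepted, !overlaps_primary)
  expect_true(all(rejected$distance > res$similarity_threshold))
  # the primary lesion itself is never counted
  expect_true(all(!dplyr::filter(res$clusters, overlaps_primary)$accepted))
})

test_that("the count is monotone in the similarity threshold", {
  img <- similar_lesion_phantom(2, n_dissimilar = 2, seed = 8)$image
  counts <- vapply(c(0.001, 1, 10, 25, 100), function(thr) {
    count_similar_lesions(
      img, multiplicity_config(similarity_threshold = thr))$count
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("invalid configurations are rejected", {
  expect_error(multiplicity_config(lambda = 1.5), "0, 1")
  expect_error(multiplicity_config(t_grid = c(3, 2, 1)), "increasing")
  expect_error(multiplicity_config(min_cluster_px = 0), ">= 1")
})
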