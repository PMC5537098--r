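# One moderately sized phantom shared by the dimensional checks.
ph <- similar_lesion_phantom(n_similar = 1, seed = 11, noise_sigma = 2)

test_that("block dimensions conform to the declared layout", {
  cfg <- feature_config()
  expect_length(extract_intensity_block(ph$image, cfg), 6)
  expect_length(extract_texture_block(ph$image, cfg), 376)
  expect_length(extract_shape_block(ph$image, cfg), 20)
  expect_length(extract_histogram_block(ph$image, cfg), 32)
  expect_length(extract_edge_block(ph$image, cfg), 61)
  v495 <- assemble_feature_vector(ph$image)
  v496 <- assemble_feature_vector(ph$image, similar_count = 1)
  expect_length(v495, 495)
  expect_length(v496, 496)
  desc <- feature_descriptors()
  expect_identical(names(v496), desc$name)
  counts <- table(desc$block)
  expect_identical(as.integer(counts[c("intensity", "texture", "shape",
                                       "histogram", "edge",
                                       "multiplicity")]),
                   c(6L, 376L, 20L, 32L, 61L, 1L))
})

test_that("blocks re-extracted separately equal the assembled vector", {
  v <- assemble_feature_vector(ph$image, similar_count = 1)
  parts <- c(extract_intensity_block(ph$image),
             extract_texture_block(ph$image),
             extract_shape_block(ph$image),
             extract_histogram_block(ph$image),
             extract_edge_block(ph$image),
             n_similar_lesions = 1)
  expect_identical(v, parts)
})

test_that("intensity block matches first principles on constant lesions", {
  img <- disk_image(level = 100, bg = 50)
  b <- extract_intensity_block(img, feature_config(proportion_threshold = 75))
  expect_equal(unname(b["intensity_median"]), 100)
  expect_equal(unname(b["intensity_entropy"]), 0)
  expect_equal(unname(b["intensity_prop_thresh"]), 1)
  expect_equal(unname(b[paste0("intensity_diff_r", c(2, 4, 8))]),
               rep(50, 3))
  # 50/50 two-valued lesion has 1 bit of intensity entropy
  img2 <- disk_image()
  vals <- img2$pixels
  idx <- which(img2$mask)
  vals[idx[seq_along(idx) %% 2 == 0]] <- 101
  vals[idx[seq_along(idx) %% 2 == 1]] <- 99
  n_even <- sum(seq_along(idx) %% 2 == 0)
  img2 <- lesion_image(vals, img2$mask)
  expected <- -(n_even / length(idx)) * log2(n_even / length(idx)) -
    ((length(idx) - n_even) / length(idx)) *
    log2((length(idx) - n_even) / length(idx))
  b2 <- extract_intensity_block(img2, feature_config(proportion_threshold = 100))
  expect_equal(unname(b2["intensity_entropy"]), expected, tolerance = 1e-10)
})

test_that("co-occurrence statistics collapse correctly on a constant patch", {
  img <- disk_image()
  tex <- extract_texture_block(img)
  expect_equal(unname(tex[paste0("glcm_contrast_",
                                 c("000", "045", "090", "135"))]),
               rep(0, 4))
  expect_equal(unname(tex[paste0("glcm_energy_",
                                 c("000", "045", "090", "135"))]),
               rep(1, 4))
})

test_that("run-length features match the closed form for a rectangle", {
  # constant 20 x 12 rectangle: 20 runs, one per row, each of length 12,
  # all at gray level 1
  img_px <- matrix(0, 48, 48)
  m <- rect_mask(48, 15, 34, 21, 32)
  img_px[m] <- 70
  img <- lesion_image(img_px, m)
  tex <- extract_texture_block(img)
  h <- 20; w <- 12
  expect_equal(unname(tex["rle_sre"]), 1 / w^2)
  expect_equal(unname(tex["rle_lre"]), w^2)
  expect_equal(unname(tex["rle_gln"]), h)
  expect_equal(unname(tex["rle_rln"]), h)
  expect_equal(unname(tex["rle_rp"]), 1 / w)
  expect_equal(unname(tex["rle_lgre"]), 1)
  expect_equal(unname(tex["rle_hgre"]), 1)
})

test_that("the Gabor channel tuned to a striped pattern dominates", {
  size <- 64
  g <- grid_coords(size)
  # vertical stripes of period 4: intensity varies along the column axis
  px <- 50 + 40 * ((g$c %/% 2) %% 2)
  m <- disk_mask(size, c(32, 32), 14)
  img <- lesion_image(px, m)
  tex <- extract_texture_block(img)
  means <- tex[grepl("^gabor_.*_mean$", names(tex))]
  expect_identical(names(which.max(means)), "gabor_w4_o000_mean")
})

test_that("shape statistics behave on analytic masks", {
  img <- disk_image(radius = 12)
  s <- extract_shape_block(img)
  expect_lt(unname(s["shape_eccentricity"]), 0.1)
  expect_lt(unname(s["radial_sd"]), 0.5)
  expect_equal(unname(s["radial_mean"]), 12, tolerance = 0.1)

  # eccentricity of a 40 x 4 rectangle vs a direct covariance oracle
  px <- matrix(0, 64, 64)
  m <- rect_mask(64, 13, 52, 31, 34)
  px[m] <- 80
  img_r <- lesion_image(px, m)
  ev <- eigen(cov(which(m, arr.ind = TRUE)) *
                (sum(m) - 1) / sum(m))$values
  expect_equal(unname(extract_shape_block(img_r)["shape_eccentricity"]),
               sqrt(1 - ev[2] / ev[1]), tolerance = 1e-9)

  # compactness orders a disk above an equal-area star
  star <- star_mask(64, c(32, 32), 16, 7)
  px_s <- matrix(0, 64, 64); px_s[star] <- 80
  s_star <- extract_shape_block(lesion_image(px_s, star))
  expect_gt(unname(s["shape_compactness"]),
            unname(s_star["shape_compactness"]))
  # the spiky contour is rougher than the convex disk contour
  expect_gt(unname(s_star["shape_roughness"]), unname(s["shape_roughness"]))
})

test_that("histogram block conserves mass and flags flat texture", {
  img <- disk_image(level = 100)
  h <- extract_histogram_block(img)
  bins <- h[grepl("^histbin_", names(h))]
  expect_identical(sum(bins > 0), 1L)
  expect_equal(sum(bins), sum(img$mask))
  # constant lesion: every interior pixel is the all-ones uniform pattern
  expect_equal(unname(h["lbp_u8"]), 1)
  # oracle: enumerate LBP codes of a small textured lesion directly
  set.seed(7)
  px <- matrix(sample(0:200, 48 * 48, TRUE), 48, 48)
  m <- rect_mask(48, 18, 31, 18, 31)
  img2 <- lesion_image(px, m)
  h2 <- extract_histogram_block(img2)
  offs <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
                c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  # naive enumeration over the pixels whose full 8-neighbourhood is in
  # the mask (the 14 x 14 rectangle's interior)
  codes <- c()
  for (r in 19:30) for (cc in 19:30) {
    code <- 0
    for (b in 1:8) {
      code <- code + (px[r + offs[b, 1], cc + offs[b, 2]] >= px[r, cc]) *
        2^(b - 1)
    }
    codes <- c(codes, code)
  }
  expect_equal(unname(h2["lbp_code_mean"]), mean(codes))
  bits <- sapply(codes, function(x) as.integer(intToBits(x)[1:8]))
  trans <- colSums(bits != bits[c(2:8, 1), ])
  expect_equal(unname(h2["lbp_nonuniform"]), mean(trans > 2))
})

test_that("edge sharpness is symmetric on a disk and drops under blur", {
  img <- disk_image(size = 96, radius = 18, level = 120, bg = 20)
  e <- extract_edge_block(img)
  sharp <- e[grepl("^edge_sharp_", names(e))]
  # rotational symmetry: all 60 values agree up to the anisotropy of
  # bilinear sampling across a hard digital edge (diagonal rays see a
  # sqrt(2)-wider transition than axis-aligned ones)
  expect_lt((max(sharp) - min(sharp)) / mean(sharp), 0.5)
  blurred <- lesion_image(
    as.matrix(EBImage::gblur(img$pixels, sigma = 2)), img$mask)
  e_b <- extract_edge_block(blurred)
  expect_lt(mean(e_b[grepl("^edge_sharp_", names(e_b))]), mean(sharp))
})

test_that("profile sharpness equals the direct max finite-difference slope", {
  ramp <- c(0, 0, 1, 3, 7, 9, 10, 10)
  expect_equal(lesionmap:::profile_sharpness(ramp, 0.5),
               max(abs(diff(ramp))) / 0.5)
})

test_that("features are invariant to integer translation", {
  base <- disk_image(size = 96, radius = 14, level = 100, bg = 40,
                     center = c(40, 40))
  shifted_px <- matrix(40, 96, 96)
  shifted_m <- disk_mask(96, c(43, 45), 14)
  shifted_px[shifted_m] <- 100
  shifted <- lesion_image(shifted_px, shifted_m)
  cfg <- feature_config(proportion_threshold = 70)
  expect_equal(assemble_feature_vector(base, cfg = cfg),
               assemble_feature_vector(shifted, cfg = cfg),
               tolerance = 1e-9)
})

test_that("degenerate inputs raise block-specific errors", {
  # mask touching the border
  px <- matrix(0, 64, 64)
  m <- rect_mask(64, 1, 20, 10, 30)
  px[m] <- 50
  img <- lesion_image(px, m)
  expect_error(extract_shape_block(img), "border")
  expect_error(extract_edge_block(img), "border")
  # bounding box below 8 x 8
  m2 <- rect_mask(64, 30, 33, 30, 35)
  px2 <- matrix(0, 64, 64); px2[m2] <- 50
  expect_error(extract_texture_block(lesion_image(px2, m2)),
               "bounding box")
  # contour shorter than the number of profiles
  m3 <- disk_mask(64, c(32, 32), 4)
  px3 <- matrix(0, 64, 64); px3[m3] <- 50
  expect_error(extract_edge_block(lesion_image(px3, m3)), "profile")
  # masks below 16 px or split in two are rejected at construction
  expect_error(lesion_image(px, rect_mask(64, 10, 12, 10, 13)), "16")
  split <- rect_mask(64, 10, 20, 10, 20) | rect_mask(64, 40, 50, 40, 50)
  expect_error(lesion_image(px, split), "single")
})

test_that("z-scoring uses the population convention and is idempotent", {
  tb <- tibble::tibble(sample_id = c("a", "b", "c"),
                       f1 = c(1, 2, 3), f2 = c(5, 5, 5))
  z <- zscore_normalize(tb)
  expect_equal(z$f1, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(z$f2, c(0, 0, 0))
  st <- attr(z, "norm_stats")
  expect_equal(st$mean, c(2, 5))
  expect_equal(st$sd, c(sqrt(2 / 3), 0))
  z2 <- zscore_normalize(z)
  expect_equal(as.matrix(z2[c("f1", "f2")]), as.matrix(z[c("f1", "f2")]),
               tolerance = 1e-8)
  # stored stats are applied verbatim to unseen data
  new <- tibble::tibble(sample_id = "d", f1 = 4, f2 = 9)
  expect_equal(apply_norm_stats(new, st)$f1, (4 - 2) / sqrt(2 / 3))
  expect_equal(apply_norm_stats(new, st)$f2, 0)
  expect_error(zscore_normalize(tb[1, ]), "2 samples")
})
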