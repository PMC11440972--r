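test_that("background mean averages the ROI and validates its size", {
  v <- mk_vol(array(1.0, dim = c(10, 10, 10)), spacing = c(2, 2, 2))
  full <- mk_mask(array(TRUE, dim = c(10, 10, 10)), spacing = c(2, 2, 2))
  expect_equal(background_mean(v, full), 1.0)

  half <- array(1.0, dim = c(10, 10, 10)); half[1:5, , ] <- 3.0
  vh <- mk_vol(half, spacing = c(2, 2, 2))
  expect_equal(background_mean(vh, full), 2.0)

  small <- array(FALSE, dim = c(10, 10, 10)); small[1:10] <- TRUE
  expect_error(background_mean(v, mk_mask(small, spacing = c(2, 2, 2))),
               "50")
  expect_equal(background_mean(v, mk_mask(small, spacing = c(2, 2, 2)),
                               min_voxels = 5), 1.0)
  zero <- mk_vol(array(0, dim = c(10, 10, 10)), spacing = c(2, 2, 2))
  expect_error(background_mean(zero, full), "positive")
})

test_that("sphere ROIs rasterize exactly as voxel-center distance tests", {
  v <- mk_vol(array(1.0, dim = c(16, 16, 16)), spacing = c(2, 2, 2))
  roi <- background_roi(center = c(15, 15, 15), radius = 10)
  m <- rasterize_roi(roi, v)
  # brute force over every voxel center
  n_ref <- 0L
  inside_ref <- array(FALSE, dim = c(16, 16, 16))
  for (k in 1:16) for (j in 1:16) for (i in 1:16) {
    w <- c((i - 1) * 2, (j - 1) * 2, (k - 1) * 2)
    if (sum((w - 15)^2) <= 100) inside_ref[i, j, k] <- TRUE
  }
  expect_identical(m$data, inside_ref)
  expect_gt(sum(m$data), 50)
})

test_that("thresholding keeps exactly the voxels at or above ratio x background", {
  bgval <- 1.0
  img <- array(bgval, dim = c(12, 12, 12))
  v <- mk_vol(img, spacing = c(2, 2, 2))
  dom <- mk_mask(array(TRUE, dim = c(12, 12, 12)), spacing = c(2, 2, 2))
  # uniform image exactly at background: nothing reaches 1.6x
  expect_equal(sum(threshold_delineate(v, bgval, 1.6, dom)$data), 0)
  # ratio 1.0: at-or-above keeps everything, strict keeps nothing
  expect_equal(sum(threshold_delineate(v, bgval, 1.0, dom)$data), 12^3)
  expect_equal(sum(threshold_delineate(v, bgval, 1.0, dom,
                                       strict = TRUE)$data), 0)

  cube <- img; cube[4:7, 4:7, 4:7] <- 2.0
  got <- threshold_delineate(mk_vol(cube, spacing = c(2, 2, 2)), bgval, 1.6,
                             dom)
  want <- array(FALSE, dim = c(12, 12, 12)); want[4:7, 4:7, 4:7] <- TRUE
  expect_identical(got$data, want)
  expect_error(threshold_delineate(v, -1, 1.6, dom), "positive")
})

test_that("delineation is invariant to global positive rescaling", {
  ph <- generate_static(small_spec(noise_sigma = 0.05, psf_fwhm = 5,
                                   seed = 41))
  dom <- build_domain(ph$brain_mask, iterations = 3)
  d1 <- delineate(ph$image, roi_left(), dom)
  scaled <- image_volume(ph$image$data * 7.3, affine = ph$image$affine)
  d2 <- delineate(scaled, roi_left(), dom)
  expect_identical(d1$btv_mask$data, d2$btv_mask$data)
  expect_equal(d2$background_mean, d1$background_mean * 7.3)
})

test_that("component labeling is 26-connected with deterministic ordering", {
  a <- array(FALSE, dim = c(10, 10, 10))
  a[2:3, 2:3, 2:3] <- TRUE                      # 8-voxel cube
  comps <- label_components(mk_mask(a, spacing = c(2, 2, 2)))
  expect_length(comps, 1)
  expect_equal(attr(comps[[1]], "n_voxels"), 8)
  expect_equal(attr(comps[[1]], "volume_ml"), 8 * 8 / 1000)

  # touching only at a corner: one component under 26-connectivity
  b <- array(FALSE, dim = c(10, 10, 10))
  b[2:3, 2:3, 2:3] <- TRUE; b[4:5, 4:5, 4:5] <- TRUE
  expect_length(label_components(mk_mask(b)), 1)

  # separated: two, sorted by descending volume
  cc <- array(FALSE, dim = c(10, 10, 10))
  cc[2, 2, 2] <- TRUE; cc[7:8, 7:8, 7:8] <- TRUE
  comps2 <- label_components(mk_mask(cc))
  expect_length(comps2, 2)
  expect_equal(attr(comps2[[1]], "n_voxels"), 8)
  expect_equal(attr(comps2[[2]], "n_voxels"), 1)

  # equal volumes: tie broken by lowest linear index
  d <- array(FALSE, dim = c(10, 10, 10))
  d[8, 8, 8] <- TRUE; d[2, 2, 2] <- TRUE
  comps3 <- label_components(mk_mask(d))
  expect_equal(attr(comps3[[1]], "first_voxel"), 112L)  # voxel (2,2,2)
  expect_length(label_components(mk_mask(array(FALSE, dim = c(5, 5, 5)))), 0)
})

test_that("component labels agree with a flood-fill oracle on random masks", {
  set.seed(42)
  for (rep in 1:5) {
    a <- array(runif(12^3) < 0.12, dim = c(12, 12, 12))
    comps <- label_components(mk_mask(a))
    oracle <- naive_flood_components(a)
    expect_length(comps, oracle$n)
    # same partition: every package component is exactly one oracle label
    for (cm in comps) {
      labs <- unique(oracle$labels[cm$data])
      expect_length(labs, 1)
      expect_equal(sum(oracle$labels == labs), attr(cm, "n_voxels"))
    }
  }
})

test_that("exclusion masks strip confounders and record removed volume", {
  m <- mk_mask(array(TRUE, dim = c(6, 6, 6)), spacing = c(2, 2, 2))
  expect_identical(apply_exclusions(m, list())$data, m$data)
  res <- apply_exclusions(m, list(m))
  expect_equal(sum(res$data), 0)
  expect_equal(attr(res, "excluded_volume_ml"), 6^3 * 8 / 1000)

  ph <- generate_static(small_spec(
    confounders = list(confounder_spec("vascular_rim", 2.5, 6))))
  dom <- build_domain(ph$brain_mask, iterations = 3)
  with_conf <- delineate(ph$image, roi_left(), dom)
  cleaned <- delineate(ph$image, roi_left(), dom,
                       exclusions = list(ph$confounder_mask))
  expect_gt(with_conf$btv_ml, cleaned$btv_ml)
  expect_identical(cleaned$btv_mask$data, ph$truth_mask$data)
})

test_that("minimum-volume filter drops components at or below the floor", {
  a <- array(FALSE, dim = c(20, 20, 20))
  a[2:11, 2:11, 2:6] <- TRUE          # 500 voxels * 8 mm3 = 4 ml
  a[15, 15, 15] <- TRUE               # 0.008 ml
  comps <- label_components(mk_mask(a, spacing = c(2, 2, 2)))
  expect_length(comps, 2)
  filt <- min_volume_filter(comps, min_ml = 0.1)
  expect_length(filt$components, 1)
  expect_equal(btv_ml(filt$mask), 4)
  expect_equal(filt$removed_volume_ml, 0.008)
  # min_ml = 0 keeps everything
  expect_length(min_volume_filter(comps, 0)$components, 2)
  # a component exactly at the floor is removed (strict inequality)
  exact <- min_volume_filter(comps, min_ml = 0.008)
  expect_length(exact$components, 1)
  expect_equal(attr(exact$components[[1]], "volume_ml"), 4)
})

test_that("full delineation recovers noiseless truth and filters lesions", {
  ph <- generate_static(small_spec())
  dom <- build_domain(ph$brain_mask, iterations = 3)
  del <- delineate(ph$image, roi_left(), dom)
  expect_equal(as.numeric(dsc(del$btv_mask, ph$truth_mask)), 1.0)
  expect_equal(del$background_mean, 1.0)
  expect_equal(del$btv_ml, ph$truth$btv_ml)

  # a TBR 1.5 lesion never reaches the 1.6 threshold
  sub <- generate_static(small_spec(
    lesions = list(lesion_spec(center = c(12, 8, 4), semi_axes = 9,
                               tbr_true = 1.5))))
  del_sub <- delineate(sub$image, roi_left(), dom)
  expect_equal(del_sub$btv_ml, 0)
  expect_equal(sum(del_sub$btv_mask$data), 0)

  # two lesions, one below the volume floor: a single component remains
  two <- generate_static(small_spec(
    lesions = list(lesion_spec(center = c(12, 8, 4), semi_axes = 9),
                   lesion_spec(center = c(-20, -20, -10), semi_axes = 2.5))))
  del_two <- delineate(two$image, roi_left(), dom)
  expect_length(del_two$components, 1)
  expect_equal(del_two$btv_ml, two$truth$btv_ml[1])
})

test_that("every BTV voxel satisfies the threshold inequality", {
  ph <- generate_static(small_spec(noise_sigma = 0.05, psf_fwhm = 5,
                                   seed = 43))
  dom <- build_domain(ph$brain_mask, iterations = 3)
  del <- delineate(ph$image, roi_left(), dom)
  expect_true(all(ph$image$data[del$btv_mask$data] >=
                    1.6 * del$background_mean))
  expect_true(all(del$btv_mask$data <= dom$mask$data))
})

test_that("BTV is non-increasing in the threshold ratio", {
  ph <- generate_static(small_spec(noise_sigma = 0.05, psf_fwhm = 5,
                                   seed = 44))
  dom <- build_domain(ph$brain_mask, iterations = 3)
  ratios <- seq(1.2, 2.5, by = 0.1)
  vols <- vapply(ratios, function(r)
    delineate(ph$image, roi_left(), dom, ratio = r, min_ml = 0)$btv_ml,
    numeric(1))
  expect_true(all(diff(vols) <= 1e-12))
})
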