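test_that("mutual information behaves like an information measure", {
  set.seed(4)
  # integer-valued image on the bin grid: partial-volume weights collapse
  # to hard binning, so MI(a, a) equals the marginal entropy exactly
  a <- matrix(sample(0:31, 64 * 64, replace = TRUE), 64)
  H <- nvkinetics:::joint_histogram(a, a, 32)
  px <- rowSums(H / sum(H))
  entropy <- -sum(px[px > 0] * log2(px[px > 0]))
  expect_equal(mutual_information(a, a), entropy, tolerance = 1e-6)
  b <- matrix(runif(64 * 64), 64)
  expect_equal(mutual_information(a, b), mutual_information(b, a),
               tolerance = 1e-12)
  expect_gte(mutual_information(a, b), 0)
  # destroying spatial correspondence kills the information (8 bins keep
  # the finite-sample plug-in bias well below the threshold)
  au <- matrix(runif(64 * 64), 64)
  perm <- matrix(sample(au), 64)
  expect_lt(mutual_information(au, perm, bins = 8), 0.05)
  expect_warning(z <- mutual_information(matrix(1, 8, 8), au[1:8, 1:8]),
                 "constant")
  expect_equal(z, 0)
})

test_that("rigid 2-D transforms compose, invert and serialize", {
  t1 <- rigid2d(10, c(3, -2), center = c(20, 20))
  t2 <- rigid2d(-4, c(1, 5), center = c(10, 30))
  chain <- compose_chain(list(t1, t2))
  M <- nvkinetics:::rigid2d_matrix(t2) %*% nvkinetics:::rigid2d_matrix(t1)
  expect_equal(nvkinetics:::rigid2d_matrix(chain), M, tolerance = 1e-10)
  # composing with the inverse gives the identity
  ident <- compose_chain(list(t1, rigid2d_invert(t1)))
  expect_equal(ident$rotation, 0, tolerance = 1e-10)
  expect_equal(ident$translation, c(0, 0), tolerance = 1e-10)
  # a single-element chain is that transform (same matrix action)
  expect_equal(nvkinetics:::rigid2d_matrix(compose_chain(list(t1))),
               nvkinetics:::rigid2d_matrix(t1), tolerance = 1e-12)
  expect_error(compose_chain(list()), "empty")
  tmp <- tempfile(fileext = ".json")
  write_transform(t1, tmp)
  t1r <- read_transform(tmp)
  expect_equal(t1r$rotation, t1$rotation)
  expect_equal(t1r$translation, t1$translation)
})

test_that("MI registration recovers identity and a known transform", {
  ph0 <- make_registration_phantoms(seed = 2)
  est0 <- mi_register_2d(ph0$fl, ph0$fl)
  expect_lt(abs(est0$rotation), 0.05)
  expect_lt(max(abs(est0$translation)), 0.1)
  ph <- make_registration_phantoms(seed = 2, rotation = 3,
                                   translation = c(5, 3))
  # identity-requested phantoms share geometry, differ only in contrast
  expect_gt(cor(as.vector(ph0$fl), as.vector(ph0$mra)), 0.8)
  est <- mi_register_2d(ph$fl, ph$mra)
  expect_lt(abs(est$rotation - 3), 0.2)
  expect_lt(max(abs(est$translation - c(5, 3))), 0.5)
  # estimated transform composed with the inverse truth is near identity
  resid <- compose_chain(list(ph$true_transform, rigid2d_invert(est)))
  expect_lt(abs(resid$rotation), 0.2)
  expect_lt(max(abs(resid$translation)), 0.6)
})

test_that("registration error grows monotonically with image noise", {
  errs <- vapply(c(0, 0.05, 0.2), function(ns) {
    ph <- make_registration_phantoms(seed = 5, rotation = 2,
                                     translation = c(4, -2))
    set.seed(99)
    mra <- ph$mra + matrix(rnorm(length(ph$mra), 0, ns), nrow(ph$mra))
    est <- mi_register_2d(ph$fl, mra)
    sqrt(sum((est$translation - c(4, -2))^2)) + abs(est$rotation - 2)
  }, 0)
  expect_lte(errs[1], errs[2] + 0.05)
  expect_lte(errs[2], errs[3] + 0.05)
})

test_that("phantom generation is deterministic in the seed", {
  a <- make_registration_phantoms(seed = 11, rotation = 1,
                                  translation = c(2, 2))
  b <- make_registration_phantoms(seed = 11, rotation = 1,
                                  translation = c(2, 2))
  expect_identical(a, b)
})

test_that("atlas projection keeps superficial layers only", {
  at <- make_mini_atlas(3, c(24, 16, 12), cortex_depth = 12)
  # layer index is nondecreasing with depth in every column
  for (i in c(1, 12, 24)) for (j in c(1, 16))
    expect_true(all(diff(at$layer[i, j, ]) >= 0))
  expect_equal(unname(at$region_names["1"]), "S1FL")
  tpl <- project_atlas_layers(at)
  expect_equal(sort(unique(as.vector(tpl$labels))), 1:3)
  # a region living only in layers 5-6 cannot reach the template
  at2 <- at
  deep <- at2$layer %in% 5:6
  at2$labels[deep] <- 3L
  at2$labels[!deep & at2$labels == 3L] <- 2L
  tpl2 <- project_atlas_layers(at2)
  expect_false(3L %in% tpl2$labels)
  # projection ignores whatever happens in the deep layers (idempotence)
  at3 <- at
  at3$labels[deep] <- 1L
  expect_equal(project_atlas_layers(at3)$labels, tpl$labels)
  # ties resolve to the lowest label id
  at4 <- make_mini_atlas(2, c(4, 4, 4), cortex_depth = 4)
  at4$labels[1, 1, at4$layer[1, 1, ] %in% 1:2] <- 1L
  at4$labels[1, 1, at4$layer[1, 1, ] %in% 3:4] <- 2L
  expect_equal(project_atlas_layers(at4)$labels[1, 1], 1L)
  expect_error(make_mini_atlas(10, c(4, 4, 4)), "too small")
  # single-region atlas projects to its own footprint
  at1 <- make_mini_atlas(1, c(6, 6, 6), cortex_depth = 6)
  expect_true(all(project_atlas_layers(at1)$labels == 1L))
})

test_that("ROI extraction averages the right voxels", {
  vol <- volume4d(array(7, c(20, 10, 14, 3)), c(0.2, 0.2, 0.2), tr = 1)
  tr <- extract_roi_timecourse(vol, c(2, 1, 1.5), 0.6)
  expect_equal(tr$values, rep(7, 3))
  expect_equal(attr(tr, "n_voxels"), 27)   # 3^3 block at 0.2 mm
  expect_error(extract_roi_timecourse(vol, c(9, 1, 1), 0.6), "outside")
  # ROI covering the activated block returns the injected response
  p <- short_paradigm(2)
  volA <- synth_bold_volume(p, dim = c(10, 8, 3), voxel = c(0.3, 0.3, 0.7),
                            activation_center = c(1.65, 1.05, 1.05),
                            noise_sd = 0, seed = 3)
  roi <- extract_roi_timecourse(volA, c(1.65, 1.05, 1.05), 0.6)
  resp <- attr(volA, "response")
  fc <- 100 * (roi$values / mean(roi$values[1:10]) - 1)
  expect_equal(cor(fc, resp), 1, tolerance = 1e-10)
  # image stacks: pixel block averaging at the frame rate
  st <- image_stack(array(2, c(30, 30, 4)), pixel_pitch = 100,
                    frame_rate = 40)
  tr2 <- extract_roi_timecourse(st, c(1.5, 1.5), 0.6)
  expect_equal(tr2$values, rep(2, 4))
  expect_equal(attr(tr2, "n_voxels"), 36)  # 6x6 pixels of 0.1 mm
  expect_equal(tr2$fs, 40)
})

test_that("fluorescence frames follow the response and resolve two points", {
  p <- short_paradigm(2)
  phantom <- matrix(1, 20, 20)
  rmap <- matrix(0, 20, 20); rmap[10, 10] <- 1
  st <- synth_fl_frames(p, phantom, rmap, psf_fwhm = 0, noise_sd = 0,
                        seed = 1)
  px <- st$frames[10, 10, ]
  resp <- attr(st, "response")
  expect_equal(px, 1 + resp, tolerance = 1e-12)
  # zero response map: temporally constant stack
  st0 <- synth_fl_frames(p, phantom, matrix(0, 20, 20), psf_fwhm = 70,
                         noise_sd = 0, seed = 1)
  expect_equal(max(apply(st0$frames, c(1, 2), sd)), 0)
  expect_error(synth_fl_frames(p, phantom, rmap, psf_fwhm = -1), "psf")
  # Rayleigh-style check: two points 70 um apart under a 70 um PSF leave
  # a contrast dip of at least 5% between them (10 um pixels)
  img <- matrix(0, 41, 41)
  img[21, 18] <- 1; img[21, 25] <- 1   # 7 px = 70 um apart
  blurred <- nvkinetics:::blur2d(img, (70 / 2.3548) / 10)
  profile <- blurred[21, ]
  peaks <- max(profile)
  valley <- min(profile[18:25])
  expect_gte((peaks - valley) / peaks, 0.05)
})
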