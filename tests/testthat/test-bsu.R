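# single-slice phantom with straight cement sheets swept along z
cement_section <- function(polylines, contrast = 0.8, size = c(0.2, 30, 30),
                           noise = NULL, seed = 21, thickness = 0.6) {
  phantom_spec(volume_size_um = size, voxel_size_um = 0.2,
               cement_lines = lapply(polylines, function(pl)
                 list(polyline_yx_um = pl, thickness_um = thickness,
                      contrast = contrast)),
               amplitudes = list(interface_amp = 10, matrix_background = 50),
               noise_peak_photons = noise, seed = seed)
}

cement_recall <- function(detected, truth_mask, voxel = 0.2) {
  if (!any(truth_mask)) return(NA_real_)
  dd <- distance_transform(detected | array(FALSE, dim(truth_mask)),
                           rep(voxel, 3))
  mean(dd[truth_mask] <= voxel * 1.5)
}

test_that("cement dips are detected to within one voxel", {
  spec <- cement_section(list(rbind(c(15, 0), c(15, 30))), contrast = 0.8)
  tr <- build_phantom(spec)
  thg <- render_thg(tr, spec, std_psf(), noise = FALSE)
  cem <- detect_cement_lines(thg, "negative")
  expect_gte(cement_recall(cem, tr$cement_mask), 0.8)
})

test_that("a cement-free section yields an empty mask with a warning", {
  spec <- phantom_spec(volume_size_um = c(0.2, 20, 20),
                       amplitudes = list(matrix_background = 50),
                       noise_peak_photons = NULL)
  tr <- build_phantom(spec)
  thg <- render_thg(tr, spec, std_psf(), noise = FALSE)
  expect_warning(cem <- detect_cement_lines(thg, "negative"), "empty cement")
  expect_false(any(cem))
})

test_that("decalcified (positive) contrast detects as well as negative", {
  pl <- list(rbind(c(15, 0), c(15, 30)))
  spec_n <- cement_section(pl, contrast = 0.8)
  tr_n <- build_phantom(spec_n)
  rec_n <- cement_recall(detect_cement_lines(render_thg(tr_n, spec_n, std_psf(),
                                                        noise = FALSE),
                                             "negative"), tr_n$cement_mask)
  spec_p <- cement_section(pl, contrast = 1.25)
  tr_p <- build_phantom(spec_p)
  rec_p <- cement_recall(detect_cement_lines(render_thg(tr_p, spec_p, std_psf(),
                                                        noise = FALSE),
                                             "positive"), tr_p$cement_mask)
  expect_gte(rec_p, rec_n - 0.05)
})

test_that("a closed cement loop partitions the section into two BSUs", {
  th <- seq(0, 2 * pi, length.out = 800)
  loop <- cbind(15 + 8 * cos(th), 15 + 8 * sin(th))
  cem <- array(FALSE, c(1, 150, 150))
  ii <- unique(round(loop / 0.2 + 0.5))
  cem[cbind(1, ii)] <- TRUE
  bsu <- label_bsus(cem, voxel_size_um = 0.2, bridge_radius_um = 0.4,
                    min_size_um = 10)
  expect_equal(bsu$n_bsus, 2L)
})

test_that("an empty cement mask yields a single BSU covering the domain", {
  dom <- array(TRUE, c(1, 60, 60))
  bsu <- label_bsus(array(FALSE, dim(dom)), dom, voxel_size_um = 0.2)
  expect_equal(bsu$n_bsus, 1L)
  expect_true(all(bsu$labels[dom] == 1L))
})

test_that("three BSUs separated by cement sheets are recovered end-to-end", {
  spec <- cement_section(list(rbind(c(10, 0), c(10, 30)),
                              rbind(c(20, 0), c(20, 30))),
                         contrast = 0.75)
  tr <- build_phantom(spec)
  thg <- render_thg(tr, spec, std_psf(), noise = FALSE)
  cem <- detect_cement_lines(thg, "negative")
  bsu <- label_bsus(cem, voxel_size_um = 0.2, bridge_radius_um = 1,
                    min_size_um = 20)
  expect_equal(bsu$n_bsus, 3L)
  # boundary-overlap F1 (1-voxel tolerance) against the true cement sheets
  det <- bsu$cement_mask
  dd <- distance_transform(det, rep(0.2, 3))
  dt <- distance_transform(tr$cement_mask, rep(0.2, 3))
  recall <- mean(dd[tr$cement_mask] <= 0.3)
  precision <- mean(dt[det] <= 0.9) # closing widens the detected boundary
  f1 <- 2 * precision * recall / (precision + recall)
  expect_gte(f1, 0.8)
})

test_that("BSU labeling is idempotent and covers the domain", {
  spec <- cement_section(list(rbind(c(12, 0), c(12, 30)),
                              rbind(c(0, 18), c(30, 18))),
                         contrast = 0.75)
  tr <- build_phantom(spec)
  thg <- render_thg(tr, spec, std_psf(), noise = FALSE)
  cem <- detect_cement_lines(thg, "negative")
  dom <- array(TRUE, dim(cem))
  b1 <- label_bsus(cem, dom, voxel_size_um = 0.2, bridge_radius_um = 1,
                   min_size_um = 20)
  # coverage: every domain voxel is boundary or carries a positive label
  expect_true(all(b1$labels >= 0))
  expect_gte(mean((b1$labels > 0) | b1$cement_mask), 0.999)
  # idempotence: rerunning on the produced boundary reproduces the partition
  b2 <- label_bsus(b1$cement_mask, dom, voxel_size_um = 0.2,
                   bridge_radius_um = 1, min_size_um = 20)
  expect_equal(b2$n_bsus, b1$n_bsus)
  agree <- mean((b2$labels > 0) == (b1$labels > 0))
  expect_gte(agree, 0.999)
})

test_that("an overly dense cement network is rejected with advice", {
  cem <- array(FALSE, c(1, 40, 40))
  cem[1, seq(1, 40, 3), ] <- TRUE
  expect_error(label_bsus(cem, voxel_size_um = 0.2, bridge_radius_um = 2),
               "bridging radius")
})
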