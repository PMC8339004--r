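test_that("box sums match a brute-force window count", {
  set.seed(3)
  arr <- array(rbinom(5 * 6 * 7, 1, 0.5), c(5, 6, 7))
  w <- c(2, 3, 2)
  got <- cxrsim:::box_sum3(arr, w)
  n <- dim(arr) - w + 1
  expect_equal(dim(got), n)
  for (i in seq_len(n[1])) for (j in seq_len(n[2])) for (k in seq_len(n[3]))
    expect_equal(got[i, j, k],
                 sum(arr[i:(i + w[1] - 1), j:(j + w[2] - 1),
                         k:(k + w[3] - 1)]))
})

test_that("sampled positions keep nodule boxes inside the lung, disjoint", {
  ph <- test_phantom(seed = 6, shape = c(96, 96, 96))
  lung <- segment_lung(remove_table(ph$volume))
  expect_identical(sample_positions(lung, list()), list())
  extents <- list(c(10, 10, 10), c(15, 12, 10), c(20, 20, 20))
  pos <- sample_positions(lung, extents, seed = 8)
  expect_length(pos, 3)
  sp <- lung$spacing
  boxes <- list()
  for (i in seq_along(pos)) {
    w <- pmax(ceiling(extents[[i]] / sp), 1)
    lo <- round(pos[[i]] - (w - 1) / 2) + 1   # back to 1-based
    hi <- lo + w - 1
    # brute-force containment: every box voxel is lung
    expect_true(all(lung$voxels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]),
                label = sprintf("nodule %d inside lung", i))
    boxes[[i]] <- rbind(lo, hi)
  }
  for (i in 1:2) for (j in (i + 1):3)
    expect_false(all(boxes[[i]][1, ] <= boxes[[j]][2, ] &
                     boxes[[j]][1, ] <= boxes[[i]][2, ]),
                 label = sprintf("boxes %d,%d disjoint", i, j))
  # determinism
  expect_identical(pos, sample_positions(lung, extents, seed = 8))
})

test_that("impossible placements raise a placement error naming the nodule", {
  # a lung mask thinner than the requested nodule
  mask <- array(FALSE, c(30, 30, 30))
  mask[10:20, 14:16, 10:20] <- TRUE   # 3 voxels = 7.5 mm thick at 2.5 mm
  lung <- structure(list(voxels = mask, spacing = c(2.5, 2.5, 2.5),
                         empty = FALSE), class = "lung_mask")
  expect_error(sample_positions(lung, list(c(20, 20, 20))),
               class = "cxrsim_placement_error")
})

test_that("parallel projection obeys the closed form and linearity", {
  # uniform mu = 0.2 / cm over 250 voxels of 1 mm along the ray: 0.2 * 25 cm
  mu <- array(0.2, c(4, 250, 3))
  proj <- forward_project(mu, spacing = c(2, 1, 2), axis = "AP")
  expect_equal(max(abs(proj$pixels - 5.0)), 0, tolerance = 1e-6)
  expect_equal(dim(proj$pixels), c(4, 3))
  expect_equal(proj$pixel_spacing, c(2, 2))

  set.seed(4)
  A <- array(runif(4 * 5 * 6), c(4, 5, 6))
  B <- array(runif(4 * 5 * 6), c(4, 5, 6))
  sp <- c(1.5, 2, 0.8)
  for (ax in c("AP", "IS", "RL")) {
    pa <- forward_project(A, sp, ax)$pixels
    pb <- forward_project(B, sp, ax)$pixels
    pab <- forward_project(A + B, sp, ax)$pixels
    expect_equal(pab, pa + pb, tolerance = 1e-12, label = ax)
  }
  # total optical depth equals the brute-force triple sum
  ray <- 2; total <- 0
  for (i in 1:4) for (j in 1:5) for (k in 1:6)
    total <- total + A[i, j, k] * sp[ray] / 10
  expect_equal(sum(forward_project(A, sp, "AP")$pixels), total,
               tolerance = 1e-6 * total)
})

test_that("diseased radiograph = clean + nodule projections, with masks", {
  ph <- test_phantom(seed = 7, shape = c(96, 96, 96))
  vol <- remove_table(ph$volume)
  lung <- segment_lung(vol)
  cfg <- sim_config(out_size = 256)
  clean <- make_radiograph(vol, list(), cfg)
  expect_length(clean$gt_masks, 0)
  expect_equal(nrow(clean$records), 0)

  nd1 <- augment(generate_shape(1, 10, 0.2), rotation_deg = 30,
                 target_extent_mm = 12)
  nd2 <- augment(generate_shape(2, 10, 0.2), rotation_deg = 200,
                 target_extent_mm = 18)
  pos <- sample_positions(lung, list(nd1$extent_mm, nd2$extent_mm), seed = 2)
  one <- make_radiograph(vol, list(list(nodule = nd1, position = pos[[1]])),
                         cfg)
  diff1 <- one$raw$pixels - clean$raw$pixels
  expect_gte(min(diff1), -1e-12)
  expect_length(one$gt_masks, 1)
  expect_true(any(one$gt_masks[[1]]))
  # the ground-truth support carries extra optical depth
  expect_gt(min(diff1[one$gt_masks[[1]]]), 0)
  # lesion records sit where the mask says
  com <- one$records[1, ]
  idx <- which(one$gt_masks[[1]], arr.ind = TRUE)
  expect_equal(com$com_y, mean(idx[, 1]) - 1, tolerance = 1e-9)
  expect_equal(com$com_x, mean(idx[, 2]) - 1, tolerance = 1e-9)

  two <- make_radiograph(vol, list(list(nodule = nd1, position = pos[[1]]),
                                   list(nodule = nd2, position = pos[[2]])),
                         cfg)
  only2 <- make_radiograph(vol, list(list(nodule = nd2,
                                          position = pos[[2]])), cfg)
  # linearity: two-nodule excess equals the sum of single-nodule excesses
  expect_equal(two$raw$pixels - clean$raw$pixels,
               diff1 + (only2$raw$pixels - clean$raw$pixels),
               tolerance = 1e-9)
})

test_that("training-mode draws are uniform where they should be", {
  ns <- cxrsim:::with_seed(42, replicate(1000, cxrsim:::draw_training_params(19)$n))
  freq <- tabulate(ns, 6) / 1000
  expect_true(all(abs(freq - 1 / 6) < 0.04))
  pars <- cxrsim:::with_seed(1, cxrsim:::draw_training_params(19))
  expect_true(all(pars$extents >= 8 & pars$extents <= 20))
  expect_true(all(pars$rotation >= 0 & pars$rotation < 360))
})

test_that("training cases are reproducible and honour a 1-shape pool", {
  ph <- test_phantom(seed = 8, shape = c(96, 96, 96))
  vol <- remove_table(ph$volume)
  lung <- segment_lung(vol)
  pool1 <- nodule_pool(1, seed = 3)
  cfg <- sim_config(out_size = 256)
  a <- generate_training_case(vol, pool1, seed = 5, lung = lung, config = cfg)
  b <- generate_training_case(vol, pool1, seed = 5, lung = lung, config = cfg)
  expect_identical(a$raw$pixels, b$raw$pixels)
  expect_identical(a$records, b$records)
  expect_true(all(a$records$shape_id == pool1$shapes[[1]]$id))
})

test_that("inconsistent study compositions fail before generation", {
  expect_error(study_config(n_per_count = c("0" = 1, "1" = 1),
                            size_counts = c("10" = 2)),
               class = "cxrsim_validation_error")
  # needs more healthy volumes than provided
  ph <- test_phantom(seed = 1)
  cfg <- study_config(n_per_count = c("0" = 3, "1" = 1),
                      size_counts = c("10" = 1), out_size = 128)
  expect_error(generate_study(list(v = remove_table(ph$volume)), cfg,
                              nodule_pool(2, seed = 1), seed = 1),
               class = "cxrsim_validation_error")
})

test_that("study sets honour composition, weights and determinism", {
  vols <- lapply(1:3, function(i)
    test_phantom(seed = i, shape = c(96, 96, 96))$volume)
  names(vols) <- paste0("v", 1:3)
  cfg <- study_config(n_per_count = c("0" = 2, "1" = 2, "2" = 2, "3" = 1),
                      size_counts = c("8" = 1, "10" = 3, "15" = 3, "20" = 2),
                      out_size = 256)
  pool <- nodule_pool(3, seed = 2)
  st <- generate_study(vols, cfg, pool, seed = 11, keep_images = TRUE)
  man <- st$manifest
  expect_equal(nrow(man$cases), 7)
  expect_equal(as.vector(table(man$cases$n_lesions)), c(2, 2, 2, 1))
  expect_equal(nrow(man$lesions), 9)
  expect_equal(as.vector(table(man$lesions$diameter_mm)), c(1, 3, 3, 2))
  # equal per-case weights summing to one
  for (cid in unique(man$lesions$case_id)) {
    w <- man$lesions$weight[man$lesions$case_id == cid]
    expect_true(all(w == w[1]))
    expect_equal(sum(w), 1, tolerance = 1e-12)
  }
  # healthy cases use distinct volumes
  healthy <- man$cases[man$cases$n_lesions == 0, ]
  expect_equal(anyDuplicated(healthy$volume_id), 0)

  # byte-identical manifests on re-run
  st2 <- generate_study(vols, cfg, pool, seed = 11, keep_images = FALSE)
  expect_identical(man, st2$manifest)
  d1 <- tempfile(); d2 <- tempfile()
  cxrsim:::write_study(st, d1); cxrsim:::write_study(st2, d2)
  for (f in c("cases.csv", "lesions.csv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))

  # every lesion COM lies inside the projected lung silhouette
  lung_by_vol <- lapply(vols, function(v) segment_lung(remove_table(v)))
  for (ci in seq_len(nrow(man$cases))) {
    rec <- man$lesions[man$lesions$case_id == man$cases$case_id[ci], ]
    if (!nrow(rec)) next
    lv <- lung_by_vol[[man$cases$volume_id[ci]]]
    sil <- forward_project(array(as.numeric(lv$voxels), dim(lv$voxels)),
                           lv$spacing, "AP")$pixels
    pad <- cxrsim:::pad_square(sil)
    sil256 <- cxrsim:::resize_matrix(pad$m, c(256, 256), "area") > 0
    for (li in seq_len(nrow(rec))) {
      px <- round(rec$com_y[li]) + 1; py <- round(rec$com_x[li]) + 1
      expect_true(sil256[px, py],
                  label = sprintf("%s lesion %d in silhouette",
                                  rec$case_id[li], li))
    }
  }

  # manifest round-trips through CSV
  d3 <- tempfile()
  cxrsim:::write_study(st, d3)
  back <- read_study_manifest(d3)
  expect_equal(back$lesions$com_x, man$lesions$com_x, tolerance = 1e-9)
  expect_equal(back$cases$n_lesions, man$cases$n_lesions)
})
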