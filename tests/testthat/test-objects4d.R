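test_that("component labeling handles empty masks and simple blocks", {
  empty <- array(FALSE, c(6, 6, 6))
  expect_identical(nrow(label_components(empty)$table), 0L)
  two <- empty
  two[1:2, 1:2, 1:2] <- TRUE
  two[5:6, 5:6, 5:6] <- TRUE
  tab <- label_components(two, voxel_size_um = c(0.5, 0.2, 0.2))$table
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$volume_vox, c(8L, 8L))
  expect_equal(tab$volume_um3, rep(8 * 0.5 * 0.2 * 0.2, 2))
  # centroid of the 1:2 block: voxel centres 0.5 and 1.5 -> mean 1.0 index units
  expect_equal(tab$centroid_z_um[1], 1.0 * 0.5)
})

test_that("labeling matches a flood-fill oracle for all connectivities", {
  for (s in 1:6) {
    m <- random_mask(c(10, 10, 10), p = 0.3, seed = s + 40)
    for (conn in c(6L, 18L, 26L)) {
      got <- label_components(m, conn)$labels
      expect_true(same_partition(got, oracle_label(m, conn)))
    }
  }
  # diagonal-only touching voxels: connected at 26, separate at 6
  diag2 <- array(FALSE, c(3, 3, 3))
  diag2[1, 1, 1] <- diag2[2, 2, 2] <- TRUE
  expect_identical(nrow(label_components(diag2, 26)$table), 1L)
  expect_identical(nrow(label_components(diag2, 6)$table), 2L)
})

test_that("component volumes sum to the mask voxel count", {
  for (s in 1:5) {
    m <- random_mask(c(12, 12, 12), p = 0.4, seed = s + 90)
    tab <- label_components(m)$table
    expect_identical(sum(tab$volume_vox), sum(m))
  }
})

test_that("noiseless scenes yield the ground-truth object count", {
  sc <- make_scene(uniform_spec(n_vesicles = 7, coloc_fraction = 1, seed = 31))
  pair <- render_scene(sc, noiseless_acq())
  tab <- label_components(segment_red(pair$red, open = FALSE)$mask, 26,
                          sc$spec$voxel_size_um, pair)$table
  # 7 vesicles plus the connected ER tube + perinuclear ring complex
  expect_identical(nrow(tab), 8L)
  ves_rows <- tab[tab$volume_um3 < 1, ]
  expect_identical(nrow(ves_rows), 7L)
  expect_true(all(ves_rows$mean_red == sc$spec$vesicle_intensity))
})

test_that("object overlap fractions follow the masks", {
  sc <- make_scene(uniform_spec(coloc_fraction = 1, seed = 32))
  pair <- render_scene(sc, noiseless_acq())
  or <- label_components(segment_red(pair$red, open = FALSE)$mask, 26,
                         sc$spec$voxel_size_um)
  og <- label_components(segment_green(pair$green)$mask, 26,
                         sc$spec$voxel_size_um)
  ov <- object_overlap(or, og)
  # at f = 1 both channels share every structure voxel exactly
  expect_true(all(ov$overlap_fraction == 1))
  # disjoint masks give all-zero overlap
  a <- array(FALSE, c(4, 6, 6)); a[1:2, 1:3, ] <- TRUE
  b <- array(FALSE, c(4, 6, 6)); b[3:4, 4:6, ] <- TRUE
  ov0 <- object_overlap(label_components(a), label_components(b))
  expect_true(all(ov0$overlap_fraction == 0))
})

test_that("volume-weighted mean overlap equals the mask-level overlap", {
  for (s in c(41, 42)) {
    sc <- make_scene(scene_spec(coloc_fraction = 0.5, seed = s))
    pair <- render_scene(sc, acquisition_spec(seed = s))
    mr <- segment_red(pair$red)
    mg <- segment_green(pair$green)
    or <- label_components(mr, 26, sc$spec$voxel_size_um)
    og <- label_components(mg, 26, sc$spec$voxel_size_um)
    ov <- object_overlap(or, og)
    red_rows <- ov[ov$channel == "red", ]
    agg <- sum(red_rows$overlap_fraction * red_rows$volume_vox) /
      sum(red_rows$volume_vox)
    expect_equal(agg, sum(mr$mask & mg$mask) / sum(mr$mask), tolerance = 1e-12)
  }
})

test_that("micro-segregated vesicle pairs overlap ~0 at sub-micron distance", {
  # an adjacent red-only / green-only vesicle pair: same compartment
  # neighbourhood, no voxel overlap — the regime that depresses image PCC
  sc <- make_scene(scene_spec(coloc_fraction = 0, n_vesicles = 6, seed = 43))
  pair <- render_scene(sc, noiseless_acq())
  or <- label_components(segment_red(pair$red, open = FALSE)$mask, 26,
                         sc$spec$voxel_size_um)
  og <- label_components(segment_green(pair$green)$mask, 26,
                         sc$spec$voxel_size_um)
  ov <- object_overlap(or, og)
  small <- ov[ov$volume_um3 < 1, ]  # vesicles (ER complex excluded)
  expect_true(all(small$overlap_fraction == 0))
})

test_that("masking green over red retains the documented red fraction", {
  sc <- make_scene(scene_spec(seed = 44))
  pair <- render_scene(sc, acquisition_spec(seed = 44))
  d <- dim(pair$red)
  all_true <- array(TRUE, d)
  res <- mask_green_over_red(pair, all_true)
  expect_identical(res$pair$red, pair$red)
  expect_equal(res$retained_red_fraction, 1)
  res0 <- mask_green_over_red(pair, array(FALSE, d))
  expect_true(all(res0$pair$red == 0))
  expect_equal(res0$retained_red_fraction, 0)
  half <- array(FALSE, d); half[, , seq_len(d[3] / 2)] <- TRUE
  uni <- channel_pair_volume(array(2, d), pair$green, pair$voxel_size_um)
  expect_equal(mask_green_over_red(uni, half)$retained_red_fraction, 0.5)
})

test_that("static objects produce one full-length track each", {
  sc <- make_scene(scene_spec(n_vesicles = 5, seed = 45))
  pair <- render_scene(sc, noiseless_acq())
  ot <- label_components(segment_red(pair$red, open = FALSE)$mask, 26,
                         sc$spec$voxel_size_um)
  linked <- link_objects(list(ot, ot, ot), max_step_um = 0.5)
  lens <- table(linked$track_id)
  expect_true(all(lens == 3))
  expect_identical(length(lens), nrow(ot$table))
})

test_that("a disappearing object ends its track without spurious links", {
  mk <- function(centers) {
    data.frame(label_id = seq_len(nrow(centers)),
               centroid_z_um = centers[, 1], centroid_y_um = centers[, 2],
               centroid_x_um = centers[, 3])
  }
  f1 <- mk(rbind(c(1, 1, 1), c(5, 5, 5)))
  f2 <- mk(rbind(c(1, 1, 1.1), c(5, 5, 5.1)))
  f3 <- mk(rbind(c(1, 1, 1.2)))  # second object gone
  linked <- link_objects(list(f1, f2, f3), max_step_um = 0.5)
  t2 <- linked[linked$t == 2, ]
  expect_identical(sort(t2$track_id), c(1L, 2L))
  t3 <- linked[linked$t == 3, ]
  expect_identical(t3$track_id, 1L)
})

test_that("greedy linking recovers >= 95% of seeded vesicle identities", {
  sc <- make_scene(scene_spec(n_vesicles = 10, seed = 46))
  sim_scenes <- list(sc)
  for (t in 2:10)
    sim_scenes[[t]] <- advance_time(sim_scenes[[t - 1]], 0.05,
                                    seed = 300L + t)
  tabs <- lapply(seq_along(sim_scenes), function(t) {
    s <- sim_scenes[[t]]
    ves <- s$objects[s$objects$kind == "vesicle", ]
    # permute row order per frame so linking cannot rely on input position
    ves <- withr::with_seed(11 + t, ves[sample(nrow(ves)), ])
    data.frame(label_id = seq_len(nrow(ves)), true_id = ves$id,
               centroid_z_um = ves$z_um, centroid_y_um = ves$y_um,
               centroid_x_um = ves$x_um)
  })
  linked <- link_objects(tabs, max_step_um = 0.3)
  consistent <- tapply(linked$true_id, linked$track_id,
                       function(x) length(unique(x)) == 1)
  # a correct track follows one true vesicle through all 10 frames
  full <- tapply(linked$t, linked$track_id, length)
  good <- sum(consistent & full == 10)
  expect_gte(good / 10, 0.95)
})
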