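test_that("top-fraction thresholding selects the exact count with deterministic ties", {
  dims <- c(10, 10, 10)
  withr::with_seed(2, vals <- array(runif(1000), dims))
  m <- map_from_values(vals)
  sel <- threshold_top_fraction(m, 0.10)
  expect_equal(sum(sel), 100L)
  # full-sort oracle
  expect_setequal(which(sel), order(-vals)[1:100])
  # all-equal values: lowest linear indices win
  flat <- map_from_values(array(0.5, dims))
  sel2 <- threshold_top_fraction(flat, 0.10)
  expect_equal(which(sel2), 1:100)
  expect_error(threshold_top_fraction(m, 1.2), "0, 1")
})

test_that("grey-matter constraint is an intersection that can split a bridge", {
  dims <- c(9, 3, 3)
  supra <- array(FALSE, dims); supra[2:8, 2, 2] <- TRUE
  gm <- array(TRUE, dims)
  expect_identical(apply_gm_constraint(supra, gm), supra)
  gm[5, 2, 2] <- FALSE    # knock out the bridge voxel
  cut <- apply_gm_constraint(supra, gm)
  expect_equal(label_components(cut, 26)$n_clusters,
               label_components(supra, 26)$n_clusters + 1L)
  withr::with_seed(4, {
    a <- array(runif(27) > 0.5, c(3, 3, 3))
    b <- array(runif(27) > 0.5, c(3, 3, 3))
    expect_identical(apply_gm_constraint(a, b), a & b)
  })
  expect_error(apply_gm_constraint(supra, array(TRUE, c(2, 2, 2))), "grid")
})

test_that("component labelling obeys the connectivity definition", {
  vol <- array(FALSE, c(6, 6, 6))
  vol[1:3, 1:3, 1:3] <- TRUE
  vol[4:6, 4:6, 4:6] <- TRUE      # touches the first block at one corner
  expect_equal(label_components(vol, 26)$n_clusters, 1L)
  expect_equal(label_components(vol, 6)$n_clusters, 2L)
  blk <- array(FALSE, c(6, 7, 7)); blk[1:4, 1:5, 1:5] <- TRUE
  hs <- label_components(blk, 26)
  expect_equal(hs$n_clusters, 1L)
  expect_equal(hs$mean_size, 100)
  empty <- label_components(array(FALSE, c(3, 3, 3)), 6)
  expect_equal(empty$n_clusters, 0L)
  expect_true(is.na(empty$mean_size))
})

test_that("component labelling matches a flood-fill oracle on random volumes", {
  withr::with_seed(21, {
    for (i in 1:6) {
      vol <- array(runif(12^3) < 0.12, c(12, 12, 12))
      for (conn in c(6L, 26L)) {
        hs <- label_components(vol, conn)
        oracle <- flood_fill_labels(vol, conn)
        expect_equal(hs$n_clusters, max(oracle))
        expect_identical(component_signature(hs$labels),
                         component_signature(oracle))
        expect_equal(sort(hs$clusters$size_voxels, decreasing = TRUE),
                     hs$clusters$size_voxels)  # ids ordered by size
      }
    }
  })
})

test_that("cluster ids order by descending size then smallest linear index", {
  vol <- array(FALSE, c(10, 3, 3))
  vol[1:2, 1, 1] <- TRUE          # size 2, earliest index
  vol[5:8, 1, 1] <- TRUE          # size 4
  vol[10, 1, 1] <- TRUE           # size 1
  hs <- label_components(vol, 6)
  expect_equal(hs$clusters$size_voxels, c(4L, 2L, 1L))
  expect_equal(hs$labels[5, 1, 1], 1L)
  expect_equal(hs$labels[1, 1, 1], 2L)
  expect_equal(hs$labels[10, 1, 1], 3L)
})

test_that("size_map averages per-voxel containing-cluster sizes, zeros included", {
  dims <- c(8, 8, 8)
  v1 <- array(FALSE, dims); v1[1:4, 1:5, 1:5] <- TRUE        # size 100
  v2 <- array(FALSE, dims); v2[1:2, 1:5, 1:5] <- TRUE        # size 50
  h1 <- label_components(v1, 26); h2 <- label_components(v2, 26)
  sm1 <- size_map(list(h1))
  expect_equal(sm1[1, 1, 1], 100)
  expect_equal(sm1[8, 8, 8], 0)
  sm <- size_map(list(h1, h2))
  expect_equal(sm[1, 1, 1], 75)    # in both: (100 + 50) / 2
  expect_equal(sm[3, 1, 1], 50)    # in one:  (100 + 0) / 2
  expect_error(size_map(list()), "participant")
})

test_that("network metrics follow the overlap rule with multiplicity", {
  dims <- c(10, 4, 4)
  vol <- array(FALSE, dims); vol[1:10, 1, 1] <- TRUE     # one 10-voxel cluster
  hs <- label_components(vol, 26)
  tmpl <- array(0L, dims)
  tmpl[1:6, 1, 1] <- 1L; tmpl[7:10, 1, 1] <- 2L
  nm <- network_metrics(hs, tmpl)
  expect_equal(nm$n_clusters[1:2], c(1L, 1L))
  expect_equal(nm$mean_overlap_size[1:2], c(6, 4))
  # cluster entirely in unassigned territory contributes nowhere
  tmpl0 <- array(0L, dims)
  nm0 <- network_metrics(hs, tmpl0)
  expect_true(all(nm0$n_clusters == 0L))
  expect_error(network_metrics(hs, array(0L, c(2, 2, 2))), "grid")
})

test_that("network metrics equal an exhaustive per-voxel tally oracle", {
  withr::with_seed(31, {
    vol <- array(runif(10^3) < 0.2, c(10, 10, 10))
    hs <- label_components(vol, 26)
    tmpl <- array(sample(0:8, 1000, replace = TRUE), c(10, 10, 10))
    nm <- network_metrics(hs, tmpl)
    for (net in 1:8) {
      overlaps <- integer(0)
      for (cl in seq_len(hs$n_clusters)) {
        ov <- sum(hs$labels == cl & tmpl == net)
        if (ov > 0) overlaps <- c(overlaps, ov)
      }
      expect_equal(nm$n_clusters[net], length(overlaps))
      expect_equal(nm$total_overlap_voxels[net], sum(overlaps))
      if (length(overlaps))
        expect_equal(nm$mean_overlap_size[net], mean(overlaps))
    }
  })
})

test_that("HRC bookkeeping identities hold across thresholds on a real map", {
  p <- simulate_participant(tiny_config(seed = 14))
  pre <- preprocess_bold(p$bold, p$motion, mask = p$brain_mask)
  map <- compute_reho(pre$bold, p$brain_mask)
  prev_total <- -1
  for (th in c(0.05, 0.10, 0.15, 0.20)) {
    supra <- threshold_top_fraction(map, th)
    constrained <- apply_gm_constraint(supra, p$gm_mask)
    hs <- extract_hrcs(map, th, gm_mask = p$gm_mask)
    expect_identical(sum(hs$clusters$size_voxels), sum(constrained))
    expect_equal(hs$mean_size * hs$n_clusters, hs$total_voxels,
                 tolerance = 1e-12)
    expect_gte(hs$total_voxels, prev_total)   # monotone in threshold
    prev_total <- hs$total_voxels
    # GM constraint only removes volume and never merges components
    unc <- extract_hrcs(map, th)
    expect_gte(unc$total_voxels, hs$total_voxels)
  }
})
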