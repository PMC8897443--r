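test_that("affine fit recovers exact and noisy transforms", {
  set.seed(1)
  pts <- cbind(runif(10, 0, 500), runif(10, 0, 500))
  ident <- fit_transform(pts, pts)
  expect_equal(ident$a, diag(2))
  expect_equal(ident$b, c(0, 0))
  expect_equal(ident$residual, 0)

  shifted <- sweep(pts[1:3, ], 2, c(10, -5), "+")
  tr <- fit_transform(pts[1:3, ], shifted)
  expect_equal(apply_transform(tr, shifted[1, , drop = FALSE]),
               pts[1, , drop = FALSE], ignore_attr = TRUE)
  expect_equal(tr$b, c(-10, 5))

  # noisy landmarks: agree with an lm least-squares oracle
  a_true <- matrix(c(1.02, 0.05, -0.04, 0.98), 2, 2)
  new <- cbind(runif(10, 0, 500), runif(10, 0, 500))
  ref <- new %*% a_true + matrix(rnorm(20, 0, 0.5), 10, 2) +
    matrix(c(3, -2), 10, 2, byrow = TRUE)
  fit <- fit_transform(ref, new)
  oracle <- lm(ref ~ new)
  expect_equal(fit$a, unname(coef(oracle)[2:3, ]), tolerance = 1e-8)
  expect_equal(fit$b, unname(coef(oracle)[1, ]), tolerance = 1e-8)

  col <- cbind(1:5, 2 * (1:5))
  expect_error(fit_transform(col, col), "collinear")
  expect_error(fit_transform(pts[1:2, ], pts[1:2, ]), ">= 3")
})

test_that("identical ROI sets match perfectly with no flags", {
  sc <- generate_roi_scene(30, seed = 2)
  mt <- match_rois(sc$ref, sc$ref)
  expect_equal(nrow(mt$pairs), 30)
  expect_true(all(mt$pairs$overlap == 1))
  expect_true(all(!mt$pairs$duplicate & !mt$pairs$low_overlap &
                    !mt$pairs$far_centroid))
  expect_length(mt$new_cells, 0)
})

test_that("duplicate targets are flagged and accepted matches are injective", {
  # two new ROIs nearest to the same reference ROI
  ref <- roi_set(list(a = disk_mask <- fearcortex:::disk_mask(100, 100, 4),
                      b = fearcortex:::disk_mask(300, 300, 4)))
  new <- roi_set(list(x = fearcortex:::disk_mask(98, 100, 4),
                      y = fearcortex:::disk_mask(103, 100, 4),
                      z = fearcortex:::disk_mask(300, 300, 4)))
  mt <- match_rois(ref, new)
  dup <- mt$pairs[mt$pairs$ref_id == "a", ]
  expect_equal(nrow(dup), 2)
  expect_true(all(dup$duplicate))
  expect_false(any(dup$accepted))
  acc <- mt$pairs[mt$pairs$accepted, ]
  expect_false(any(duplicated(acc$new_id)))
  expect_false(any(duplicated(acc$ref_id)))
})

test_that("rotated jittered scenes are tracked almost perfectly", {
  tr_true <- rotation_transform(5, c(8, -5))
  sc <- generate_roi_scene(200, tr_true, jitter_px = 1, seed = 42)
  fit <- fit_transform(sc$landmarks_ref, sc$landmarks_moved)
  mt <- match_rois(sc$ref, sc$moved, fit)
  truth <- setNames(sc$truth$ref_id, sc$truth$moved_id)
  # every nearest-centroid assignment hits its ground-truth partner
  expect_gte(mean(truth[mt$pairs$new_id] == mt$pairs$ref_id), 0.99)
  acc <- mt$pairs[mt$pairs$accepted, ]
  expect_gte(mean(truth[acc$new_id] == acc$ref_id), 0.99)
})

test_that("matching is invariant to a common rigid motion", {
  sc <- generate_roi_scene(40, rotation_transform(3, c(4, 2)),
                           jitter_px = 0.5, seed = 7)
  fit <- fit_transform(sc$landmarks_ref, sc$landmarks_moved)
  base <- match_rois(sc$ref, sc$moved, fit)

  # integer translation: an exact rigid motion on the pixel grid
  rig <- transform_model(diag(2), c(30, -12))
  move_set <- function(rs) {
    roi_set(lapply(rs$masks, function(m) round(apply_transform(rig, m))),
            rs$image_size, validate = FALSE)
  }
  ref2 <- move_set(sc$ref)
  lm_ref2 <- apply_transform(rig, sc$landmarks_ref)
  fit2 <- fit_transform(lm_ref2, sc$landmarks_moved)
  shifted <- match_rois(ref2, sc$moved, fit2)
  expect_equal(shifted$pairs$ref_id, base$pairs$ref_id)
  expect_equal(shifted$pairs$new_id, base$pairs$new_id)
  expect_equal(shifted$pairs$accepted, base$pairs$accepted)
})

test_that("multi-session merging tracks cells and absorbs duplicates", {
  sc <- generate_roi_scene(25, seed = 3)
  lm <- sc$landmarks_ref
  one <- merge_across_sessions(list(list(rois = sc$ref, landmarks = lm)))
  expect_equal(nrow(one$table), 25)

  twice <- merge_across_sessions(list(list(rois = sc$ref, landmarks = lm),
                                      list(rois = sc$ref, landmarks = lm)))
  expect_equal(nrow(twice$table), 25)   # no new cells from a repeated session
  expect_true(all(!is.na(twice$table$session_2)))
})

test_that("programmed dropout is recovered by the tracked fraction", {
  set.seed(5)
  sc <- generate_roi_scene(60, seed = 9)
  lm <- sc$landmarks_ref
  keep <- sort(sample(60, 45))   # 25% dropout in session 2
  sub <- roi_set(sc$ref$masks[keep], sc$ref$image_size)
  mg <- merge_across_sessions(list(list(rois = sc$ref, landmarks = lm),
                                   list(rois = sub, landmarks = lm)))
  orig <- mg$table[mg$table$track_id %in% paste0("t", 1:60), ]
  tracked <- mean(!is.na(orig$session_2))
  expect_equal(tracked, 45 / 60, tolerance = 0.03)
})

test_that("ROI scenes honour their construction contract", {
  sc0 <- generate_roi_scene(15, jitter_px = 0, seed = 4)
  expect_equal(sc0$moved$centroids, sc0$ref$centroids, ignore_attr = TRUE)

  shift <- transform_model(diag(2), c(10, -5))
  sc1 <- generate_roi_scene(15, shift, jitter_px = 0, seed = 4)
  disp <- sc1$ref$centroids - sc1$moved$centroids
  expect_equal(unname(colMeans(disp)), c(10, -5))
  expect_true(all(abs(sweep(disp, 2, c(10, -5))) < 1e-9))

  expect_error(transform_model(matrix(c(1, 2, 2, 4), 2, 2), c(0, 0)),
               "invertible")
})
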