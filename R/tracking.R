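#' ROI set
#'
#' A session's regions of interest: integer pixel masks plus centroids
#' (the mean x-y position of each mask).
#'
#' @param masks Named list of integer matrices `[n_px, 2]` (x, y pixel
#'   coordinates), one per ROI.
#' @param image_size Length-2 image dimensions in px.
#' @param validate Check that centroids lie within the image bounds
#'   (disable for sets living in a transformed frame).
#' @return An object of class `roi_set` with `masks`, `centroids`
#'   (`n x 2` matrix, rownames = ids), `image_size`.
#' @export
roi_set <- function(masks, image_size = c(512, 512), validate = TRUE) {
  stopifnot(length(masks) >= 1L)
  if (is.null(names(masks))) names(masks) <- sprintf("r%03d", seq_along(masks))
  cent <- t(vapply(masks, colMeans, numeric(2)))
  colnames(cent) <- c("x", "y")
  if (validate &&
      (any(cent < 0) || any(cent[, 1] > image_size[1]) ||
       any(cent[, 2] > image_size[2]))) {
    stop("ROI centroids must lie within the image bounds")
  }
  structure(list(masks = masks, centroids = cent, image_size = image_size),
            class = "roi_set")
}

#' Affine transform model
#'
#' `xy_ref = xy_new %*% A + b` (row vectors); must be invertible.
#'
#' @param a 2x2 linear part.
#' @param b Length-2 translation.
#' @param residual Root-mean-square fit residual in px.
#' @return An object of class `transform_model`.
#' @export
transform_model <- function(a, b, residual = 0) {
  a <- matrix(as.numeric(a), 2, 2)
  if (abs(det(a)) < 1e-10) stop("transform is not invertible")
  structure(list(a = a, b = as.numeric(b), residual = residual),
            class = "transform_model")
}

#' Apply an affine transform to points
#'
#' @param transform A `transform_model`.
#' @param xy `n x 2` matrix of points.
#' @return Transformed `n x 2` matrix.
#' @export
apply_transform <- function(transform, xy) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  sweep(xy %*% transform$a, 2, transform$b, "+")
}

#' Fit an affine registration from landmark pairs
#'
#' Least-squares affine map taking the new session's landmark coordinates
#' onto the reference session's; requires at least 3 non-collinear pairs.
#'
#' @param landmarks_ref,landmarks_new `n x 2` matrices of corresponding
#'   landmark coordinates (`n >= 3`).
#' @return A [transform_model()] mapping new -> ref, with the RMS residual.
#' @export
fit_transform <- function(landmarks_ref, landmarks_new) {
  ref <- matrix(as.numeric(landmarks_ref), ncol = 2)
  new <- matrix(as.numeric(landmarks_new), ncol = 2)
  stopifnot(nrow(ref) == nrow(new))
  if (nrow(ref) < 3L) stop("fit_transform() needs >= 3 landmark pairs")
  design <- cbind(1, new)
  if (qr(design)$rank < 3L) stop("landmarks are collinear")
  coefs <- qr.solve(design, ref)           # 3 x 2: intercept + linear part
  fitted <- design %*% coefs
  rss <- sqrt(mean(rowSums((ref - fitted)^2)))
  transform_model(a = coefs[2:3, ], b = coefs[1, ], residual = rss)
}

mask_overlap <- function(mask_a, mask_b) {
  key <- function(m) paste(m[, 1], m[, 2])
  inter <- length(intersect(key(mask_a), key(mask_b)))
  inter / min(nrow(mask_a), nrow(mask_b))
}

#' Match ROIs across two sessions
#'
#' Transforms the new session's ROIs into the reference frame and assigns
#' each new ROI to the nearest reference centroid. Pairs are flagged for
#' manual review when (a) two new ROIs claim the same reference ROI
#' (`duplicate`), (b) the transformed masks overlap by less than 80%
#' (`low_overlap`; overlap = intersection over the smaller mask), or
#' (c) the centroid distance exceeds the mean matched distance by more
#' than 2 standard deviations (`far_centroid`). Flag-free pairs are
#' accepted; accepted matches are injective by construction.
#'
#' @param ref,new `roi_set`s.
#' @param transform A `transform_model` mapping new -> ref (identity if
#'   omitted).
#' @param max_dist_px New ROIs farther than this from every reference
#'   centroid are declared new cells rather than matches (default 15).
#' @param overlap_min Overlap below which a pair is flagged (default 0.8).
#' @return A list of class `match_table`: `pairs` tibble (`ref_id`,
#'   `new_id`, `distance_px`, `overlap`, `duplicate`, `low_overlap`,
#'   `far_centroid`, `accepted`), and `new_cells` (unmatched new ids).
#' @export
match_rois <- function(ref, new, transform = NULL, max_dist_px = 15,
                       overlap_min = 0.8) {
  stopifnot(inherits(ref, "roi_set"), inherits(new, "roi_set"))
  if (is.null(transform)) transform <- transform_model(diag(2), c(0, 0))
  cent_new <- apply_transform(transform, new$centroids)
  masks_new <- lapply(new$masks, function(m) {
    round(apply_transform(transform, m))
  })
  ref_ids <- rownames(ref$centroids)
  new_ids <- rownames(new$centroids)

  d2 <- outer(rowSums(cent_new^2), rowSums(ref$centroids^2), "+") -
    2 * cent_new %*% t(ref$centroids)
  d2[d2 < 0] <- 0
  nearest <- apply(d2, 1, which.min)
  dist_px <- sqrt(d2[cbind(seq_along(nearest), nearest)])

  matched <- dist_px <= max_dist_px
  new_cells <- new_ids[!matched]
  idx <- which(matched)
  if (length(idx) == 0L) {
    return(structure(list(pairs = tibble::tibble(
      ref_id = character(), new_id = character(), distance_px = numeric(),
      overlap = numeric(), duplicate = logical(), low_overlap = logical(),
      far_centroid = logical(), accepted = logical()),
      new_cells = new_cells), class = "match_table"))
  }
  ov <- vapply(idx, function(i) {
    mask_overlap(masks_new[[i]], ref$masks[[nearest[i]]])
  }, numeric(1))
  target <- ref_ids[nearest[idx]]
  dup <- duplicated(target) | duplicated(target, fromLast = TRUE)
  d <- dist_px[idx]
  # sub-pixel floor keeps floating-point noise in well-aligned scenes from
  # tripping the 2-SD outlier rule
  far <- d > pmax(mean(d) + 2 * stats::sd(d), 0.5)
  if (all(is.na(far))) far <- rep(FALSE, length(d))
  low <- ov < overlap_min
  pairs <- tibble::tibble(ref_id = target, new_id = new_ids[idx],
                          distance_px = d, overlap = ov,
                          duplicate = dup, low_overlap = low,
                          far_centroid = far,
                          accepted = !dup & !low & !far)
  structure(list(pairs = pairs, new_cells = new_cells),
            class = "match_table")
}

#' Track neurons across many sessions
#'
#' Aligns every session to the first via its landmark pairs, matches each
#' session's ROIs against the cumulative catalogue (which grows with each
#' session's new cells), and finally drops catalogued ROIs that overlap
#' each other extensively (mutual overlap above `exclude_overlap`), since
#' those cannot be attributed to a single cell.
#'
#' @param sessions List of lists, each with `rois` (a `roi_set`) and
#'   `landmarks` (`n x 2` matrix of landmark coordinates in that session;
#'   the first session's landmarks define the reference frame).
#' @param max_dist_px,overlap_min Passed to [match_rois()].
#' @param exclude_overlap Mutual-overlap threshold for the final exclusion
#'   of ambiguous catalogue entries (default 0.5).
#' @return A list of class `tracked_neuron_table`: `table` tibble
#'   (`track_id` x session columns holding each session's ROI id or `NA`),
#'   and `excluded` (track ids removed by the overlap rule).
#' @export
merge_across_sessions <- function(sessions, max_dist_px = 15,
                                  overlap_min = 0.8, exclude_overlap = 0.5) {
  stopifnot(length(sessions) >= 1L)
  ref <- sessions[[1]]$rois
  catalogue_masks <- ref$masks
  names(catalogue_masks) <- paste0("t", seq_along(catalogue_masks))
  track_ids <- names(catalogue_masks)
  id_map <- list(stats::setNames(rownames(ref$centroids), track_ids))

  for (s in seq_along(sessions)[-1]) {
    tr <- fit_transform(sessions[[1]]$landmarks, sessions[[s]]$landmarks)
    cat_set <- roi_set(catalogue_masks, ref$image_size, validate = FALSE)
    mt <- match_rois(cat_set, sessions[[s]]$rois, tr,
                     max_dist_px = max_dist_px, overlap_min = overlap_min)
    acc <- mt$pairs[mt$pairs$accepted, ]
    sess_map <- stats::setNames(rep(NA_character_, length(track_ids)), track_ids)
    sess_map[acc$ref_id] <- acc$new_id
    # unmatched (or unaccepted) new ROIs enter the catalogue as new cells
    unassigned <- setdiff(rownames(sessions[[s]]$rois$centroids), acc$new_id)
    for (nid in unassigned) {
      tid <- paste0("t", length(catalogue_masks) + 1L)
      catalogue_masks[[tid]] <-
        round(apply_transform(tr, sessions[[s]]$rois$masks[[nid]]))
      track_ids <- c(track_ids, tid)
      sess_map[tid] <- nid
    }
    # pad earlier sessions' maps with the new track ids
    id_map <- lapply(id_map, function(mp) {
      mp[setdiff(track_ids, names(mp))] <- NA_character_
      mp[track_ids]
    })
    id_map[[s]] <- sess_map[track_ids]
  }

  # exclude catalogue entries that overlap each other extensively
  excluded <- character()
  if (length(catalogue_masks) > 1L) {
    for (i in seq_along(catalogue_masks)[-1]) {
      for (j in seq_len(i - 1L)) {
        if (mask_overlap(catalogue_masks[[i]], catalogue_masks[[j]]) >
            exclude_overlap) {
          excluded <- union(excluded, c(track_ids[i], track_ids[j]))
        }
      }
    }
  }
  keep <- setdiff(track_ids, excluded)
  tab <- tibble::tibble(track_id = keep)
  for (s in seq_along(sessions)) {
    tab[[paste0("session_", s)]] <- unname(id_map[[s]][keep])
  }
  structure(list(table = tab, excluded = excluded),
            class = "tracked_neuron_table")
}

disk_mask <- function(cx, cy, radius) {
  g <- expand.grid(x = seq(floor(cx - radius), ceiling(cx + radius)),
                   y = seq(floor(cy - radius), ceiling(cy + radius)))
  keep <- (g$x - cx)^2 + (g$y - cy)^2 <= radius^2
  as.matrix(g[keep, ])
}

#' Generate a synthetic two-session ROI scene
#'
#' Builds a reference ROI set (disk-shaped somata at random, minimally
#' separated positions), a moved set obtained by applying an affine
#' transform plus independent centroid jitter, and landmark pairs that are
#' exact under the transform. Ground truth: moved ROI `i` is reference ROI
#' `i`.
#'
#' @param n_rois Number of ROIs (>= 1).
#' @param transform A `transform_model` mapping moved -> reference
#'   (identity if omitted). Must be invertible.
#' @param jitter_px SD of the Gaussian centroid jitter added after the
#'   (inverse) transform (default 0).
#' @param seed Optional integer seed.
#' @param image_size Image dimensions (default `c(512, 512)`).
#' @param radius_px Range of ROI radii (default `c(3, 5)`).
#' @param min_sep_px Minimum centroid separation (default 14).
#' @param n_landmarks Number of landmark pairs (default 6).
#' @return A list with `ref` and `moved` (`roi_set`s), `landmarks_ref`,
#'   `landmarks_moved`, and `truth` (tibble `ref_id`, `moved_id`).
#' @export
generate_roi_scene <- function(n_rois, transform = NULL, jitter_px = 0,
                               seed = NULL, image_size = c(512, 512),
                               radius_px = c(3, 5), min_sep_px = 14,
                               n_landmarks = 6) {
  stopifnot(n_rois >= 1L)
  if (is.null(transform)) transform <- transform_model(diag(2), c(0, 0))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  margin <- 40
  cents <- matrix(NA_real_, 0, 2)
  while (nrow(cents) < n_rois) {
    cand <- c(stats::runif(1, margin, image_size[1] - margin),
              stats::runif(1, margin, image_size[2] - margin))
    if (nrow(cents) == 0L ||
        min(sqrt(rowSums(sweep(cents, 2, cand)^2))) >= min_sep_px) {
      cents <- rbind(cents, cand)
    }
  }
  radii <- stats::runif(n_rois, radius_px[1], radius_px[2])
  ref_masks <- lapply(seq_len(n_rois), function(i) {
    disk_mask(cents[i, 1], cents[i, 2], radii[i])
  })
  names(ref_masks) <- sprintf("ref%03d", seq_len(n_rois))
  ref <- roi_set(ref_masks, image_size)

  # moved coordinates live in the second session's frame: the inverse of
  # `transform` maps reference -> moved, then jitter perturbs centroids
  a_inv <- solve(transform$a)
  inv <- transform_model(a_inv, -transform$b %*% a_inv)
  moved_cents <- apply_transform(inv, cents)
  if (jitter_px > 0) {
    moved_cents <- moved_cents +
      matrix(stats::rnorm(2 * n_rois, 0, jitter_px), ncol = 2)
  }
  moved_masks <- lapply(seq_len(n_rois), function(i) {
    round(disk_mask(moved_cents[i, 1], moved_cents[i, 2], radii[i]))
  })
  names(moved_masks) <- sprintf("mov%03d", seq_len(n_rois))
  moved <- roi_set(moved_masks, image_size, validate = FALSE)

  lm_ref <- cbind(stats::runif(n_landmarks, margin, image_size[1] - margin),
                  stats::runif(n_landmarks, margin, image_size[2] - margin))
  lm_moved <- apply_transform(inv, lm_ref)
  list(ref = ref, moved = moved,
       landmarks_ref = lm_ref, landmarks_moved = lm_moved,
       truth = tibble::tibble(ref_id = names(ref_masks),
                              moved_id = names(moved_masks)))
}
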