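#' Segmenter configuration
#'
#' Desk-scale compact 2D U-Net: `depth` is the number of 2x downsamplings,
#' `base` the channel count of the first encoder level (doubling per level).
#' Training is B-scan-wise with per-image Adam updates; the loss is weighted
#' cross-entropy plus a soft-Dice term. Input B-scan dimensions must be
#' divisible by `2^depth`.
#'
#' @param depth Downsampling levels (default 2).
#' @param base Base channel count (default 8).
#' @param lr Adam learning rate.
#' @param max_epochs Maximum training epochs (default 50).
#' @param bce_weight,dice_weight,pos_weight Loss weights.
#' @param threshold Probability threshold for mask binarization.
#' @param seed RNG seed governing init and shuffling (full determinism).
#' @return A `seg_config` list.
#' @export
seg_config <- function(depth = 2L, base = 8L, lr = 1e-3, max_epochs = 50L,
                       bce_weight = 1, dice_weight = 0.5, pos_weight = 3,
                       threshold = 0.5, seed = 1L) {
  stopifnot(max_epochs >= 1, depth >= 1, base >= 1)
  structure(list(depth = as.integer(depth), base = as.integer(base), lr = lr,
                 max_epochs = as.integer(max_epochs),
                 bce_weight = bce_weight, dice_weight = dice_weight,
                 pos_weight = pos_weight, threshold = threshold,
                 seed = as.integer(seed)),
            class = "seg_config")
}

#' Assemble a segmentation dataset
#'
#' @param volumes List of flattened, repeat-averaged [oct_volume()]s.
#' @param masks List of logical `(y, x, z)` ground-truth lesion masks,
#'   shape-aligned with the volumes.
#' @return A `segmentation_dataset`.
#' @export
segmentation_dataset <- function(volumes, masks) {
  stopifnot(length(volumes) == length(masks))
  for (i in seq_along(volumes)) {
    if (!all(dim(volumes[[i]]$voxels) == dim(masks[[i]]))) {
      stop(sprintf("volume/mask shape mismatch at item %d", i))
    }
  }
  structure(list(volumes = volumes, masks = masks), class = "segmentation_dataset")
}

#' @export
length.segmentation_dataset <- function(x) length(x$volumes)

#' Seeded train/validation split
#'
#' Deterministic shuffle; `round(fraction * n)` volumes train, the rest
#' validate. With the emulated protocol's 40 volumes at 0.8 this gives 32/8.
#'
#' @param dataset A `segmentation_dataset` (or an integer count).
#' @param fraction Training fraction (default 0.8).
#' @param seed RNG seed.
#' @return List `train`, `val` of indices.
#' @export
split_dataset <- function(dataset, fraction = 0.8, seed = 1L) {
  n <- if (is.numeric(dataset)) as.integer(dataset) else length(dataset)
  n_train <- round(fraction * n)
  if (n_train >= n) stop("training fraction leaves an empty validation set")
  if (n_train < 1) stop("training fraction leaves an empty training set")
  perm <- with_seed(seed, function() sample.int(n))
  list(train = sort(perm[seq_len(n_train)]),
       val = sort(perm[(n_train + 1):n]))
}

#' Seeded k-fold assignments
#'
#' Near-equal folds that partition the dataset (pairwise disjoint, union
#' complete); the emulated protocol uses k = 10 and k = 5.
#'
#' @param dataset A `segmentation_dataset` or integer count.
#' @param k Number of folds.
#' @param seed RNG seed.
#' @return List of `k` index vectors.
#' @export
make_folds <- function(dataset, k, seed = 1L) {
  n <- if (is.numeric(dataset)) as.integer(dataset) else length(dataset)
  if (k > n) stop(sprintf("cannot make %d folds from %d volumes", k, n))
  perm <- with_seed(seed, function() sample.int(n))
  split(perm, rep(seq_len(k), length.out = n)) |>
    lapply(sort) |> unname()
}

# normalize one B-scan matrix (z, x) to zero mean / unit sd
normalize_bscan <- function(m) {
  s <- stats::sd(m)
  (m - mean(m)) / if (s > 0) s else 1
}

# explode a dataset subset into per-B-scan training items
dataset_bscans <- function(dataset, idx) {
  items <- list()
  k <- 1L
  for (i in idx) {
    v <- dataset$volumes[[i]]$voxels
    m <- dataset$masks[[i]]
    for (y in seq_len(dim(v)[1])) {
      bs <- t(matrix(v[y, , ], dim(v)[2], dim(v)[3]))   # (z, x)
      lb <- t(matrix(m[y, , ], dim(v)[2], dim(v)[3]))
      items[[k]] <- list(x = normalize_bscan(bs), y = lb * 1, volume = i,
                         bscan = y)
      k <- k + 1L
    }
  }
  items
}

#' Train the lesion segmenter
#'
#' B-scan-wise 2D training with Adam on weighted cross-entropy + soft-Dice;
#' per-epoch validation Dice is logged and the best-validation checkpoint is
#' returned (training Dice when no validation split is given). Fully seeded:
#' two runs with the same seed produce identical logs and weights.
#'
#' @param dataset A `segmentation_dataset`.
#' @param config A [seg_config()].
#' @param split Optional list `train`, `val` of indices (default: all train).
#' @return A `lesion_segmenter`: network weights, config, training log tibble
#'   (`epoch`, `mean_loss`, `val_dice`).
#' @export
train_segmenter <- function(dataset, config = seg_config(), split = NULL) {
  stopifnot(inherits(dataset, "segmentation_dataset"))
  if (is.null(split)) split <- list(train = seq_along(dataset), val = integer())
  if (!length(split$train)) stop("empty training split")
  train_items <- dataset_bscans(dataset, split$train)
  if (!any(vapply(train_items, function(it) any(it$y > 0), logical(1)))) {
    stop("no positive (lesion) voxels in the training data")
  }
  d0 <- dim(train_items[[1]]$x)
  if (any(d0 %% 2L^config$depth != 0L)) {
    stop(sprintf("B-scan size %dx%d not divisible by 2^depth = %d",
                 d0[1], d0[2], 2L^config$depth))
  }
  val_items <- if (length(split$val)) dataset_bscans(dataset, split$val) else NULL
  net <- unet_init(config$depth, config$base, seed = config$seed)
  flat <- flatten_params(net)
  st <- adam_init(flat)
  best <- list(dice = -Inf, flat = flat)
  log <- list()
  with_seed(config$seed + 1L, function() {
    for (ep in seq_len(config$max_epochs)) {
      ord <- sample(seq_along(train_items))
      losses <- numeric(length(ord))
      for (ii in seq_along(ord)) {
        it <- train_items[[ord[ii]]]
        H <- nrow(it$x); W <- ncol(it$x)
        net <- assign_params(net, flat)
        fw <- unet_forward(net, matrix(as.vector(it$x), ncol = 1), H, W)
        ls <- seg_loss(fw$logits, as.vector(it$y),
                       pos_weight = config$pos_weight,
                       bce_weight = config$bce_weight,
                       dice_weight = config$dice_weight)
        losses[ii] <- ls$loss
        gr <- unet_backward(net, fw, ls$dlogits)
        upd <- adam_step(flat, flatten_grads(net, gr), st, lr = config$lr)
        flat <<- upd$flat; st <<- upd$state
      }
      net <- assign_params(net, flat)
      eval_items <- if (!is.null(val_items)) val_items else train_items
      vd <- mean(vapply(eval_items, function(it) {
        pr <- predict_bscan(net, it$x)
        dice(pr > config$threshold, it$y > 0)
      }, numeric(1)))
      log[[ep]] <<- tibble::tibble(epoch = ep, mean_loss = mean(losses),
                                   val_dice = vd)
      if (vd > best$dice) best <<- list(dice = vd, flat = flat)
    }
  })
  structure(list(net = assign_params(net, best$flat), config = config,
                 best_val_dice = best$dice, log = dplyr::bind_rows(log)),
            class = "lesion_segmenter")
}

#' @export
print.lesion_segmenter <- function(x, ...) {
  cat(sprintf("<lesion_segmenter> depth %d, base %d, %d epochs trained, best Dice %.3f\n",
              x$config$depth, x$config$base, nrow(x$log), x$best_val_dice))
  invisible(x)
}

predict_bscan <- function(net, bscan_norm) {
  H <- nrow(bscan_norm); W <- ncol(bscan_norm)
  fw <- unet_forward(net, matrix(as.vector(bscan_norm), ncol = 1), H, W)
  matrix(1 / (1 + exp(-fw$logits)), H, W)
}

#' Segment a volume
#'
#' Per-B-scan inference stitched back into a volume: a probability map in
#' `[0, 1]` and its thresholded binary mask.
#'
#' @param model A `lesion_segmenter`.
#' @param volume Flattened, averaged [oct_volume()].
#' @param threshold Override of the config threshold.
#' @return List: `prob` (numeric `(y, x, z)` array), `mask` (logical).
#' @export
segment <- function(model, volume, threshold = NULL) {
  stopifnot(inherits(model, "lesion_segmenter"), inherits(volume, "oct_volume"))
  if (has_repeats(volume)) stop("segment expects an averaged volume")
  thr <- threshold %||% model$config$threshold
  d <- dim(volume$voxels)
  prob <- array(0, d)
  for (y in seq_len(d[1])) {
    bs <- t(matrix(volume$voxels[y, , ], d[2], d[3]))  # (z, x)
    pr <- predict_bscan(model$net, normalize_bscan(bs))
    prob[y, , ] <- t(pr)
  }
  list(prob = prob, mask = prob > thr)
}

#' Dice overlap coefficient
#'
#' \eqn{2|A \cap B| / (|A| + |B|)}; defined as 1 when both masks are empty
#' and 0 when exactly one is empty.
#'
#' @param mask_a,mask_b Logical arrays of equal shape.
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b) {
  stopifnot(all(dim(mask_a) == dim(mask_b)))
  sa <- sum(mask_a); sb <- sum(mask_b)
  if (sa + sb == 0) return(1)
  2 * sum(mask_a & mask_b) / (sa + sb)
}

#' k-fold cross-validation of the segmenter
#'
#' Trains one model per fold on the remaining folds and evaluates per-volume
#' Dice on the held-out fold; every volume is evaluated exactly once.
#'
#' @param dataset A `segmentation_dataset`.
#' @param config A [seg_config()].
#' @param k Number of folds (the emulated protocol uses 5 and 10).
#' @param seed Fold-assignment seed.
#' @return List: `table` (tibble `fold`, `volume`, `dice`), `mean_dice`,
#'   `sd_dice`, `models`.
#' @export
cross_validate <- function(dataset, config = seg_config(), k = 5L, seed = 1L) {
  folds <- make_folds(dataset, k, seed = seed)
  rows <- list(); models <- list()
  for (f in seq_len(k)) {
    train_idx <- sort(unlist(folds[-f]))
    cfg <- config
    cfg$seed <- config$seed + f
    model <- tryCatch(
      train_segmenter(dataset, cfg,
                      split = list(train = train_idx, val = folds[[f]])),
      error = function(e) stop(sprintf("fold %d: %s", f, conditionMessage(e))))
    models[[f]] <- model
    for (v in folds[[f]]) {
      sg <- segment(model, dataset$volumes[[v]])
      rows[[length(rows) + 1L]] <-
        tibble::tibble(fold = f, volume = v,
                       dice = dice(sg$mask, dataset$masks[[v]]))
    }
  }
  tab <- dplyr::bind_rows(rows)
  structure(
    list(table = tab, mean_dice = mean(tab$dice), sd_dice = stats::sd(tab$dice),
         models = models),
    class = "retlesion_cv")
}

#' Per-lesion morphometrics from a 3D mask
#'
#' 26-connected component labeling; per lesion: volume (µm^3), en face
#' footprint area (µm^2), maximum axial thickness (µm) and centroid (µm).
#' Cubes touching only at a corner merge into one component under
#' 26-connectivity.
#'
#' @param mask Logical `(y, x, z)` array.
#' @param pitch_x,pitch_y,pitch_z Voxel pitches, µm.
#' @return Tibble `lesion`, `n_voxels`, `volume_um3`, `area_um2`,
#'   `thickness_um`, `x_um`, `y_um`, `z_um`.
#' @export
lesion_metrics <- function(mask, pitch_x, pitch_y, pitch_z) {
  if (!any(mask)) {
    return(tibble::tibble(lesion = integer(), n_voxels = integer(),
                          volume_um3 = numeric(), area_um2 = numeric(),
                          thickness_um = numeric(), x_um = numeric(),
                          y_um = numeric(), z_um = numeric()))
  }
  lab <- label_components(mask)
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  rows <- lapply(ids, function(id) {
    idx <- which(lab == id, arr.ind = TRUE)
    col_counts <- table(paste(idx[, 1], idx[, 2]))
    tibble::tibble(
      lesion = id, n_voxels = nrow(idx),
      volume_um3 = nrow(idx) * pitch_x * pitch_y * pitch_z,
      area_um2 = length(col_counts) * pitch_x * pitch_y,
      thickness_um = max(col_counts) * pitch_z,
      x_um = mean((idx[, 2] - 0.5) * pitch_x),
      y_um = mean((idx[, 1] - 0.5) * pitch_y),
      z_um = mean((idx[, 3] - 0.5) * pitch_z))
  })
  dplyr::bind_rows(rows)
}

#' Compare manual and automated segmentations
#'
#' Overall Dice, per-lesion matched pairs (components with voxel overlap) and
#' an en face class image: 0 none, 1 manual only, 2 automated only,
#' 3 overlap.
#'
#' @param manual,auto Logical `(y, x, z)` masks of equal shape.
#' @return List: `dice`, `pairs` (tibble `manual_lesion`, `auto_lesion`,
#'   `overlap_voxels`), `class_map` (matrix `(y, x)`).
#' @export
compare_manual_auto <- function(manual, auto) {
  stopifnot(all(dim(manual) == dim(auto)))
  d <- dice(manual, auto)
  man_en <- apply(manual, c(1, 2), any)
  aut_en <- apply(auto, c(1, 2), any)
  class_map <- matrix(0L, nrow(man_en), ncol(man_en))
  class_map[man_en & !aut_en] <- 1L
  class_map[!man_en & aut_en] <- 2L
  class_map[man_en & aut_en] <- 3L
  pairs <- tibble::tibble(manual_lesion = integer(), auto_lesion = integer(),
                          overlap_voxels = integer())
  if (any(manual) && any(auto)) {
    lm <- label_components(manual)
    la <- label_components(auto)
    both <- which(manual & auto)
    if (length(both)) {
      key <- paste(lm[both], la[both])
      tab <- table(key)
      parts <- do.call(rbind, strsplit(names(tab), " "))
      pairs <- tibble::tibble(manual_lesion = as.integer(parts[, 1]),
                              auto_lesion = as.integer(parts[, 2]),
                              overlap_voxels = as.integer(tab))
    }
  }
  list(dice = d, pairs = pairs, class_map = class_map)
}

#' Tidy the cross-validation table
#' @param x Result of [cross_validate()].
#' @param ... Unused.
#' @method tidy retlesion_cv
#' @export
tidy.retlesion_cv <- function(x, ...) x$table

#' Tidy a segmenter's training log
#' @param x A `lesion_segmenter`.
#' @param ... Unused.
#' @method tidy lesion_segmenter
#' @export
tidy.lesion_segmenter <- function(x, ...) x$log

#' One-row segmenter summary
#' @param x A `lesion_segmenter`.
#' @param ... Unused.
#' @method glance lesion_segmenter
#' @export
glance.lesion_segmenter <- function(x, ...) {
  tibble::tibble(depth = x$config$depth, base = x$config$base,
                 epochs = nrow(x$log), best_val_dice = x$best_val_dice)
}
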