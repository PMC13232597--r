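# Multiscale-feature MLP pixel classification and tubule ROI extraction.
#
# Per channel c and scale sigma the feature bank is:
#   gaussian                   G_sigma(c)   (smoothed intensity)
#   gradient_magnitude         |grad G_sigma(c)|          (edges)
#   structure_tensor_coherence (l1-l2)/(l1+l2) of the sigma-integrated
#                              structure tensor             (orientation)
#   hessian_determinant        det H(G_sigma(c))     (blob-like structure)
# Features are z-scored with statistics learned from the training pixels.

FEATURE_KINDS <- c("gaussian", "gradient_magnitude",
                   "structure_tensor_coherence", "hessian_determinant")

#' Feature configuration for the pixel classifier
#'
#' @param kinds Subset of `gaussian`, `gradient_magnitude`,
#'   `structure_tensor_coherence`, `hessian_determinant`.
#' @param scales Gaussian sigmas in pixels (default 1, 2, 4, 8: spans
#'   nucleus-to-tubule structure at typical 20x calibrations).
#' @param channels Channels used; `NULL` means all channels of the
#'   training images.
#' @return An object of class `FeatureConfig`.
#' @export
feature_config <- function(kinds = FEATURE_KINDS,
                           scales = c(1, 2, 4, 8),
                           channels = NULL) {
  kinds <- match.arg(kinds, FEATURE_KINDS, several.ok = TRUE)
  if (!length(kinds)) stop("at least one feature kind required")
  if (!length(scales) || any(scales <= 0)) {
    stop("scales must be positive")
  }
  structure(list(kinds = kinds, scales = as.numeric(scales),
                 channels = channels),
            class = "FeatureConfig")
}

deriv_x <- function(m) {
  EBImage::filter2(m, matrix(c(-0.5, 0, 0.5), nrow = 1),
                   boundary = "replicate")
}
deriv_y <- function(m) {
  EBImage::filter2(m, matrix(c(-0.5, 0, 0.5), ncol = 1),
                   boundary = "replicate")
}

#' Compute the per-pixel feature stack
#'
#' @param img A `CalibratedImage`.
#' @param cfg A `FeatureConfig`; `cfg$channels` must all be present.
#' @return Numeric array `[rows, cols, n_features]`; the third dimension
#'   is named `channel|kind|s<scale>`. Feature count is
#'   `|channels| * |scales| * |kinds|`.
#' @export
compute_feature_stack <- function(img, cfg) {
  stopifnot(inherits(img, "CalibratedImage"), inherits(cfg, "FeatureConfig"))
  channels <- if (is.null(cfg$channels)) img$channel_names else cfg$channels
  missing <- setdiff(channels, img$channel_names)
  if (length(missing)) {
    stop(sprintf("channel missing from image: %s",
                 paste(missing, collapse = ", ")))
  }
  nr <- img$height_px; nc <- img$width_px
  nf <- length(channels) * length(cfg$scales) * length(cfg$kinds)
  out <- array(0, dim = c(nr, nc, nf))
  fnames <- character(nf)
  k <- 0L
  eps <- 1e-8
  for (ch in channels) {
    raw <- img$channels[[ch]]
    for (s in cfg$scales) {
      g <- as.matrix(EBImage::gblur(raw, sigma = s))
      need_grad <- any(cfg$kinds %in%
                         c("gradient_magnitude",
                           "structure_tensor_coherence"))
      if (need_grad) {
        gx <- as.matrix(deriv_x(g)); gy <- as.matrix(deriv_y(g))
      }
      for (kind in cfg$kinds) {
        k <- k + 1L
        fnames[k] <- sprintf("%s|%s|s%g", ch, kind, s)
        out[, , k] <- switch(kind,
          gaussian = g,
          gradient_magnitude = sqrt(gx^2 + gy^2),
          structure_tensor_coherence = {
            jxx <- as.matrix(EBImage::gblur(gx * gx, sigma = s))
            jyy <- as.matrix(EBImage::gblur(gy * gy, sigma = s))
            jxy <- as.matrix(EBImage::gblur(gx * gy, sigma = s))
            tr <- jxx + jyy
            coh <- sqrt((jxx - jyy)^2 + 4 * jxy^2) / (tr + eps)
            coh[tr < eps] <- 0
            coh
          },
          hessian_determinant = {
            gxx <- as.matrix(deriv_x(deriv_x(g)))
            gyy <- as.matrix(deriv_y(deriv_y(g)))
            gxy <- as.matrix(deriv_y(deriv_x(g)))
            gxx * gyy - gxy^2
          })
      }
    }
  }
  dimnames(out) <- list(NULL, NULL, fnames)
  out
}

# forward pass of a 1-hidden-layer logistic/softmax MLP using nnet's
# weight layout: per hidden unit (bias, w_1..w_p), then per output unit
# (bias, v_1..v_H)
mlp_forward <- function(wts, n_in, n_hidden, n_out, X) {
  n1 <- n_hidden * (n_in + 1L)
  W1 <- matrix(wts[seq_len(n1)], nrow = n_in + 1L)
  W2 <- matrix(wts[-seq_len(n1)], nrow = n_hidden + 1L)
  H <- stats::plogis(cbind(1, X) %*% W1)
  A <- cbind(1, H) %*% W2
  A <- A - apply(A, 1, max)
  E <- exp(A)
  E / rowSums(E)
}

#' Train the MLP pixel classifier
#'
#' Annotation pixels are gathered from every image, features are z-scored
#' from the training pixels, and a single-hidden-layer MLP (logistic
#' hidden units, softmax output, cross-entropy loss) is fitted with
#' \pkg{nnet} under a fixed seed, so training is exactly reproducible.
#'
#' @param images List of `CalibratedImage`s sharing one channel set.
#' @param annotations List of `ROISet`s (one per image) whose classes are
#'   the region labels to learn.
#' @param feat_cfg A `FeatureConfig` (default: all kinds, scales 1,2,4,8,
#'   all channels).
#' @param classes Class list the model must cover; a class with zero
#'   annotated pixels across all images is an error.
#' @param hidden Hidden-layer width; default `max(32, 2 * n_features)`.
#' @param max_epochs Optimiser iteration cap (default 300).
#' @param max_px_per_class Per-class cap on training pixels (stratified
#'   subsample; keeps training time bounded).
#' @param decay L2 weight decay passed to \pkg{nnet}.
#' @param seed Training seed (weight initialisation and subsampling).
#' @return A `PixelClassifierModel`; `$train_accuracy` is the accuracy on
#'   all annotation pixels.
#' @export
train_pixel_classifier <- function(images, annotations, feat_cfg = NULL,
                                   classes = c("tubule", "tissue",
                                               "background"),
                                   hidden = NULL, max_epochs = 300L,
                                   max_px_per_class = 2000L,
                                   decay = 1e-4, seed = 1L) {
  stopifnot(is.list(images), is.list(annotations),
            length(images) == length(annotations), length(images) >= 1)
  if (is.null(feat_cfg)) feat_cfg <- feature_config()
  ch0 <- images[[1]]$channel_names
  for (im in images) {
    if (!identical(im$channel_names, ch0)) {
      stop("channel mismatch across training images")
    }
  }
  channels <- if (is.null(feat_cfg$channels)) ch0 else feat_cfg$channels

  feats <- list(); labs <- list()
  for (i in seq_along(images)) {
    stack <- compute_feature_stack(images[[i]], feat_cfg)
    nf <- dim(stack)[3]
    flat <- matrix(stack, ncol = nf)
    ann <- annotations[[i]]
    px <- images[[i]]$pixel_size_um
    d <- c(images[[i]]$height_px, images[[i]]$width_px)
    for (j in seq_len(length(ann))) {
      mask <- rasterize_polygon(ann$polygons[[j]], d, px)
      idx <- which(mask)
      if (!length(idx)) next
      feats[[length(feats) + 1L]] <- flat[idx, , drop = FALSE]
      labs[[length(labs) + 1L]] <- rep(ann$class_label[j], length(idx))
    }
  }
  X <- do.call(rbind, feats)
  y <- unlist(labs)
  counts <- table(factor(y, levels = classes))
  if (any(counts == 0)) {
    stop(sprintf("class with zero annotated pixels: %s",
                 paste(names(counts)[counts == 0], collapse = ", ")))
  }
  extra <- setdiff(unique(y), classes)
  if (length(extra)) {
    stop(sprintf("annotation class not in the class list: %s",
                 paste(extra, collapse = ", ")))
  }

  set.seed(seed)
  keep <- unlist(lapply(classes, function(cl) {
    idx <- which(y == cl)
    if (length(idx) > max_px_per_class) {
      sort(sample(idx, max_px_per_class))
    } else idx
  }))
  Xs <- X[keep, , drop = FALSE]
  ys <- factor(y[keep], levels = classes)

  mu <- colMeans(Xs)
  sdv <- apply(Xs, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
  Z <- sweep(sweep(Xs, 2, mu), 2, sdv, "/")

  nf <- ncol(Z)
  if (is.null(hidden)) hidden <- max(32L, 2L * nf)
  n_wts <- hidden * (nf + 1L) + length(classes) * (hidden + 1L)
  fit <- nnet::nnet(Z, stats::model.matrix(~ ys - 1),
                    size = hidden, softmax = TRUE, maxit = max_epochs,
                    decay = decay, MaxNWts = n_wts + 1L, trace = FALSE)

  model <- structure(list(feature_config = feat_cfg,
                          channel_names = ch0,
                          classes = classes,
                          n_in = nf, n_hidden = hidden,
                          n_out = length(classes),
                          wts = as.numeric(fit$wts),
                          feat_mean = as.numeric(mu),
                          feat_sd = as.numeric(sdv),
                          feature_names = colnames(X),
                          seed = seed),
                     class = "PixelClassifierModel")
  Zall <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  pr <- mlp_forward(model$wts, nf, hidden, length(classes), Zall)
  model$train_accuracy <- mean(classes[max.col(pr)] == y)
  model
}

#' @export
print.PixelClassifierModel <- function(x, ...) {
  cat(sprintf(
    "PixelClassifierModel: %d features -> %d hidden -> %s; channels %s; train acc %.3f\n",
    x$n_in, x$n_hidden, paste(x$classes, collapse = "/"),
    paste(x$channel_names, collapse = ","), x$train_accuracy))
  invisible(x)
}

#' Apply a pixel classifier to an image
#'
#' The image's channel set must equal the model's training channel set
#' exactly (same names, same order); otherwise the model refuses to run.
#' Prediction is deterministic: repeated calls give bit-identical maps.
#'
#' @param model A `PixelClassifierModel`.
#' @param img A `CalibratedImage`.
#' @param chunk_px Pixels per forward-pass chunk (memory bound).
#' @return A `PredictionMap`: `label` (integer matrix indexing
#'   `classes`), `prob` (array `[rows, cols, n_classes]`, rows summing to
#'   1), `classes`, `pixel_size_um`.
#' @export
predict_pixels <- function(model, img, chunk_px = 200000L) {
  stopifnot(inherits(model, "PixelClassifierModel"),
            inherits(img, "CalibratedImage"))
  if (!identical(img$channel_names, model$channel_names)) {
    stop(sprintf(
      "channel set mismatch: model trained on [%s], image has [%s]; train a model per channel set",
      paste(model$channel_names, collapse = ","),
      paste(img$channel_names, collapse = ",")))
  }
  stack <- compute_feature_stack(img, model$feature_config)
  nf <- dim(stack)[3]
  flat <- matrix(stack, ncol = nf)
  rm(stack)
  n_px <- nrow(flat)
  prob <- matrix(NA_real_, n_px, model$n_out)
  for (start in seq(1L, n_px, by = chunk_px)) {
    idx <- start:min(start + chunk_px - 1L, n_px)
    Z <- sweep(sweep(flat[idx, , drop = FALSE], 2, model$feat_mean),
               2, model$feat_sd, "/")
    prob[idx, ] <- mlp_forward(model$wts, model$n_in, model$n_hidden,
                               model$n_out, Z)
  }
  lab <- max.col(prob, ties.method = "first")
  nr <- img$height_px; nc <- img$width_px
  structure(list(label = matrix(as.integer(lab), nr, nc),
                 prob = array(prob, c(nr, nc, model$n_out)),
                 classes = model$classes,
                 pixel_size_um = img$pixel_size_um,
                 image_id = img$image_id),
            class = "PredictionMap")
}

#' @export
print.PredictionMap <- function(x, ...) {
  tb <- table(factor(x$classes[x$label], levels = x$classes))
  cat("PredictionMap:",
      paste(sprintf("%s %.1f%%", names(tb), 100 * tb / sum(tb)),
            collapse = ", "), "\n")
  invisible(x)
}

#' ROI extraction configuration
#'
#' @param min_object_area_um2 Components smaller than this are removed
#'   (applied as keep-if-\eqn{\ge}; default 400 um^2).
#' @param min_hole_area_um2 Interior holes smaller than this are filled
#'   (holes of at least this area are kept; default 200 um^2).
#' @export
roi_extraction_config <- function(min_object_area_um2 = 400,
                                  min_hole_area_um2 = 200) {
  stopifnot(min_object_area_um2 >= 0, min_hole_area_um2 >= 0)
  structure(list(min_object_area_um2 = min_object_area_um2,
                 min_hole_area_um2 = min_hole_area_um2),
            class = "RoiExtractionConfig")
}

#' Extract classed ROIs from a prediction map
#'
#' 8-connected components are built per class, components below the
#' minimum object area are removed, interior holes below the minimum hole
#' area are filled, and each surviving component is traced to a polygon
#' (in um) whose area and perimeter are recorded.
#'
#' @param pred A `PredictionMap` (or an integer label matrix, in which
#'   case `classes` and `pixel_size_um` must be given).
#' @param pixel_size_um Calibration; taken from `pred` when absent.
#' @param cfg A `RoiExtractionConfig`.
#' @param classes Classes to extract; by default every class except
#'   `background`.
#' @return An `ROISet` (possibly empty).
#' @export
extract_rois <- function(pred, pixel_size_um = NULL,
                         cfg = roi_extraction_config(),
                         classes = NULL) {
  if (inherits(pred, "PredictionMap")) {
    lab <- pred$label
    lvls <- pred$classes
    if (is.null(pixel_size_um)) pixel_size_um <- pred$pixel_size_um
    image_id <- pred$image_id
  } else {
    stopifnot(is.matrix(pred), !is.null(pixel_size_um))
    lab <- pred
    lvls <- attr(pred, "classes")
    if (is.null(lvls)) stop("label matrix needs a 'classes' attribute")
    image_id <- "image"
  }
  if (is.null(classes)) classes <- setdiff(lvls, "background")
  px2 <- pixel_size_um^2
  polys <- list(); cls <- character(0); ids <- character(0)
  for (cl in classes) {
    code <- match(cl, lvls)
    mask <- lab == code
    if (!any(mask)) next
    comp <- label8(mask)
    sizes <- tabulate(comp)
    keep <- which(sizes * px2 >= cfg$min_object_area_um2)
    n_cl <- 0L
    for (ci in keep) {
      cm <- comp == ci
      filled <- as.matrix(EBImage::fillHull(cm)) > 0
      holes <- filled & !cm
      if (any(holes)) {
        hcomp <- label8(holes)
        hsizes <- tabulate(hcomp)
        fill_ids <- which(hsizes * px2 < cfg$min_hole_area_um2)
        cm <- cm | (hcomp %in% fill_ids & holes)
        dim(cm) <- dim(filled)
      }
      for (pg in mask_to_polygons(cm, pixel_size_um)) {
        n_cl <- n_cl + 1L
        polys[[length(polys) + 1L]] <- pg
        cls <- c(cls, cl)
        ids <- c(ids, sprintf("%s_%d", cl, n_cl))
      }
    }
  }
  roi_set(polys, cls, image_id = image_id, roi_id = ids)
}

#' Rasterise an ROI set back to a class label map
#'
#' Overlaps are resolved by class priority (first class in `priority`
#' wins); used for round-trip checks and zone rasterisation.
#'
#' @param rois An `ROISet`.
#' @param dim c(rows, cols).
#' @param pixel_size_um Calibration.
#' @param priority Class priority order, highest first.
#' @param classes Level set of the output map.
#' @return Integer label matrix with a `classes` attribute;
#'   unclaimed pixels take the `background` level.
#' @export
rasterize_rois <- function(rois, dim, pixel_size_um,
                           priority = c("tubule", "tissue", "background"),
                           classes = c("tubule", "tissue", "background")) {
  stopifnot(inherits(rois, "ROISet"))
  bg <- match("background", classes)
  lab <- matrix(if (is.na(bg)) 0L else bg, dim[1], dim[2])
  # paint lowest priority first so higher classes overwrite
  for (cl in rev(intersect(priority, unique(rois$class_label)))) {
    code <- match(cl, classes)
    for (i in which(rois$class_label == cl)) {
      m <- rasterize_polygon(rois$polygons[[i]], dim, pixel_size_um)
      lab[m] <- code
    }
  }
  attr(lab, "classes") <- classes
  lab
}

#' Save a pixel classifier to a portable JSON file
#' @param model A `PixelClassifierModel`.
#' @param path Output path.
#' @export
save_pixel_classifier <- function(model, path) {
  stopifnot(inherits(model, "PixelClassifierModel"))
  obj <- unclass(model)
  obj$feature_config <- unclass(obj$feature_config)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a pixel classifier saved by [save_pixel_classifier()]
#' @param path JSON path.
#' @return A `PixelClassifierModel`.
#' @export
load_pixel_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$feature_config <- structure(
    list(kinds = obj$feature_config$kinds,
         scales = obj$feature_config$scales,
         channels = obj$feature_config$channels),
    class = "FeatureConfig")
  structure(obj, class = "PixelClassifierModel")
}
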