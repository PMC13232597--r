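test_that("feature stack has the expected shape and flat-field behaviour", {
  # 64 px sides accommodate the sigma = 8 filter support
  img <- calibrated_image(list(Hoechst = matrix(500, 64, 64)), 0.5)
  st <- compute_feature_stack(img, feature_config())
  expect_equal(dim(st), c(64L, 64L, 16L))  # 1 channel x 4 scales x 4 kinds
  # constant image: all structure features vanish
  for (f in dimnames(st)[[3]]) {
    if (grepl("gradient|coherence|hessian", f)) {
      expect_equal(max(abs(st[, , f])), 0,
                   tolerance = 1e-8, info = f)
    } else {
      expect_equal(unique(as.vector(st[, , f])), 500, tolerance = 1e-6)
    }
  }
  expect_error(compute_feature_stack(
    img, feature_config(channels = "SOX9")), "channel missing")
  expect_error(feature_config(scales = c(0, 2)), "positive")
})

test_that("structure tensor coherence is near 1 along an ideal step edge", {
  m <- matrix(0, 64, 64); m[, 33:64] <- 1000
  img <- calibrated_image(list(ch = m), 0.5)
  st <- compute_feature_stack(
    img, feature_config(kinds = "structure_tensor_coherence", scales = 1))
  expect_gt(min(st[10:54, 31:34, 1]), 0.9)
})

test_that("training is deterministic and refuses degenerate inputs", {
  tr <- fx_training()
  imgs <- tr$images[1:2]
  anns <- tr$annotations[1:2]
  cfg <- feature_config(scales = c(1, 4))
  m1 <- train_pixel_classifier(imgs, anns, feat_cfg = cfg, hidden = 16L,
                               max_epochs = 40L, max_px_per_class = 300L,
                               seed = 3)
  m2 <- train_pixel_classifier(imgs, anns, feat_cfg = cfg, hidden = 16L,
                               max_epochs = 40L, max_px_per_class = 300L,
                               seed = 3)
  expect_identical(m1$wts, m2$wts)
  expect_identical(m1$feat_mean, m2$feat_mean)
  # annotations covering one class only: the others have zero pixels
  one_class <- subset_rois(anns[[1]], anns[[1]]$class_label == "tubule")
  expect_error(train_pixel_classifier(imgs[1], list(one_class),
                                      feat_cfg = cfg),
               "zero annotated pixels")
  # channel mismatch across training images
  img_extra <- fx_scene(21)$image
  img_extra$channels$Extra <- img_extra$channels$Hoechst
  img_extra$channel_names <- c(img_extra$channel_names, "Extra")
  expect_error(train_pixel_classifier(list(imgs[[1]], img_extra),
                                      anns[1:2], feat_cfg = cfg),
               "channel mismatch")
})

test_that("trained model separates regions on annotation pixels and unseen scenes", {
  model <- fx_model()
  expect_gte(model$train_accuracy, 0.95)
  # held-out scene: annotation pixels from its ground truth
  sc <- fx_scene(21)
  pred <- fx_segmentation(21)$pred
  ann <- sparse_annotations_from_truth(sc$truth, seed = 77)
  codes <- c(background = 0L, tissue = 1L, tubule = 2L)
  correct <- 0L; total <- 0L
  for (i in seq_len(length(ann))) {
    m <- rasterize_polygon(ann$polygons[[i]], dim(sc$truth$region),
                           sc$truth$pixel_size_um)
    lab <- pred$classes[pred$label[m]]
    correct <- correct + sum(lab == ann$class_label[i])
    total <- total + sum(m)
  }
  expect_gte(correct / total, 0.95)
})

test_that("prediction is deterministic, probability-coherent and channel-locked", {
  model <- fx_model()
  img <- fx_training()$images[[1]]
  p1 <- predict_pixels(model, img)
  p2 <- predict_pixels(model, img)
  expect_identical(p1$label, p2$label)
  expect_identical(p1$prob, p2$prob)
  # probabilities sum to one; label is the argmax
  sums <- apply(p1$prob, c(1, 2), sum)
  expect_lt(max(abs(sums - 1)), 1e-6)
  amax <- apply(p1$prob, c(1, 2), which.max)
  expect_identical(as.integer(amax), as.integer(p1$label))
  # an extra channel must refuse to run
  img2 <- img
  img2$channels$Extra <- img2$channels$Hoechst
  img2$channel_names <- c(img2$channel_names, "Extra")
  expect_error(predict_pixels(model, img2), "channel set mismatch")
})

test_that("ROI extraction applies the minimum object and hole sizes at their boundaries", {
  px <- 0.5  # 1 px = 0.25 um^2
  lab <- matrix(3L, 200, 200)  # background level
  attr(lab, "classes") <- c("tubule", "tissue", "background")
  # 399 um^2 blob (42 x 38 = 1596 px) and 400 um^2 blob (40 x 40 px)
  lab[11:52, 11:48] <- 1L
  lab[100:139, 100:139] <- 1L
  # with no size filter both blobs survive
  rois <- extract_rois(lab, pixel_size_um = px,
                       cfg = roi_extraction_config(0, 200))
  expect_equal(length(rois), 2L)
  rois400 <- extract_rois(lab, pixel_size_um = px,
                          cfg = roi_extraction_config(400, 200))
  expect_equal(length(rois400), 1L)
  expect_lt(abs(rois400$area_um2 - 400), 2)

  # holes: 150 um^2 (600 px = 24 x 25) filled, 250 um^2 (1000 px) kept
  lab2 <- matrix(3L, 200, 200)
  attr(lab2, "classes") <- c("tubule", "tissue", "background")
  lab2[11:110, 11:110] <- 1L          # 100 x 100 px tubule
  lab2[21:44, 21:45] <- 3L            # 600 px hole -> filled
  lab2[61:100, 61:85] <- 3L           # 1000 px hole -> kept
  rois2 <- extract_rois(lab2, pixel_size_um = px)
  expect_equal(length(rois2), 1L)
  expect_length(rois2$polygons[[1]]$holes, 1L)
  expect_lt(abs(rois2$area_um2 - (2500 - 250)), 3)

  # all-background prediction -> empty set
  lab3 <- matrix(3L, 50, 50)
  attr(lab3, "classes") <- c("tubule", "tissue", "background")
  expect_equal(length(extract_rois(lab3, pixel_size_um = px)), 0L)
})

test_that("ROI extraction is idempotent and monotone in the object-size filter", {
  lab <- matrix(3L, 220, 220)
  attr(lab, "classes") <- c("tubule", "tissue", "background")
  lab[11:80, 11:80] <- 1L      # 1,225 um^2
  lab[31:60, 31:60] <- 3L      # 225 um^2 hole, kept
  lab[100:139, 100:159] <- 1L  # 600 um^2
  lab[170:205, 20:55] <- 2L    # tissue patch 324 um^2
  rois <- extract_rois(lab, pixel_size_um = 0.5)
  relab <- rasterize_rois(rois, dim(lab), 0.5)
  rois2 <- extract_rois(relab, pixel_size_um = 0.5)
  expect_equal(length(rois2), length(rois))
  o <- order(rois$area_um2); o2 <- order(rois2$area_um2)
  expect_equal(rois2$area_um2[o2], rois$area_um2[o], tolerance = 1e-9)
  expect_identical(rois2$class_label[o2], rois$class_label[o])

  # tubule area is non-increasing in min_object_area_um2
  areas <- vapply(c(0, 300, 500, 700, 1500), function(mo) {
    r <- extract_rois(lab, pixel_size_um = 0.5,
                      cfg = roi_extraction_config(mo, 200))
    sum(r$area_um2[r$class_label == "tubule"])
  }, numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("a saved classifier reloads and predicts identically", {
  model <- fx_model()
  path <- file.path(tempdir(), "model.json")
  save_pixel_classifier(model, path)
  back <- load_pixel_classifier(path)
  img <- fx_training()$images[[2]]
  expect_identical(predict_pixels(back, img)$label,
                   predict_pixels(model, img)$label)
})
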