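# Shared, lazily-built fixtures. Expensive objects (scenes, the trained
# pixel classifier, the mitotic-recovery runs) are computed once per test
# session and reused across files.

.fx_cache <- new.env(parent = emptyenv())

fx_get <- function(key, fn) {
  if (!exists(key, envir = .fx_cache)) {
    assign(key, fn(), envir = .fx_cache)
  }
  get(key, envir = .fx_cache)
}

# default analysis scene (768 px, three tubules)
fx_scene <- function(seed = 21) {
  fx_get(paste0("scene_", seed),
         function() generate_scene(scene_spec(seed = seed)))
}

fx_truth_rois <- function(seed = 21) {
  sc <- fx_scene(seed)
  roi_set(sc$truth$tubules,
          rep("tubule", length(sc$truth$tubules)),
          image_id = sc$image$image_id)
}

# detections on the default scene: detected, classified, regions assigned
fx_det <- function(seed = 21) {
  fx_get(paste0("det_", seed), function() {
    sc <- fx_scene(seed)
    rois <- fx_truth_rois(seed)
    det <- detect_cells(sc$image, rois)
    det <- classify_cells(det, classifier_spec(default_class_rules()))
    assign_regions(det, rois)
  })
}

# 512-px training scenes: 2 fully stained + 2 SOX9 controls + 2 MAGE-A
# controls, mirroring the annotate-6-images training design
fx_training_spec <- function(seed) {
  scene_spec(width_px = 512L, height_px = 512L, n_tubules = 2L,
             tubule_radius_um = c(40, 55), seed = seed)
}

fx_training <- function() {
  fx_get("training", function() {
    scenes <- c(
      lapply(list(fx_training_spec(11), fx_training_spec(12)),
             generate_scene),
      lapply(list(fx_training_spec(13), fx_training_spec(14)),
             render_control_image, omit_markers = "SOX9"),
      lapply(list(fx_training_spec(15), fx_training_spec(16)),
             render_control_image, omit_markers = "MAGE-A"))
    anns <- lapply(seq_along(scenes), function(i) {
      sparse_annotations_from_truth(scenes[[i]]$truth, seed = 100 + i)
    })
    list(scenes = scenes,
         images = lapply(scenes, `[[`, "image"),
         annotations = anns)
  })
}

fx_model <- function() {
  fx_get("model", function() {
    tr <- fx_training()
    train_pixel_classifier(tr$images, tr$annotations,
                           max_epochs = 150L, max_px_per_class = 1200L,
                           seed = 5)
  })
}

# prediction + extracted ROIs of the default scene under the fixture model
fx_segmentation <- function(seed = 21) {
  fx_get(paste0("seg_", seed), function() {
    pred <- predict_pixels(fx_model(), fx_scene(seed)$image)
    list(pred = pred, rois = extract_rois(pred))
  })
}

# mitotic-recovery runs: 10 seeds of a larger field, full detection and
# classification on the true tubule outlines; ~180 MAGE-A cells per seed
# (pooled n about 2,000)
fx_mito_spec <- function(seed) {
  scene_spec(width_px = 1152L, height_px = 1152L, n_tubules = 7L,
             tubule_radius_um = c(55, 70), seed = seed)
}

fx_mito_runs <- function() {
  fx_get("mito_runs", function() {
    lapply(61:70, function(seed) {
      sc <- generate_scene(fx_mito_spec(seed))
      rois <- roi_set(sc$truth$tubules,
                      rep("tubule", length(sc$truth$tubules)),
                      image_id = sc$image$image_id)
      det <- detect_cells(sc$image, rois)
      det <- classify_cells(det, classifier_spec(default_class_rules()))
      det <- assign_regions(det, rois)
      attr(det, "nucleus_polygons") <- NULL
      attr(det, "cell_polygons") <- NULL
      list(det = det, truth_cells = sc$truth$cells)
    })
  })
}

fx_mito_det <- function() {
  do.call(rbind, lapply(fx_mito_runs(), `[[`, "det"))
}

# large-tubule scene with clustered luminal MAGE-A cells
fx_cluster_det <- function() {
  fx_get("cluster_det", function() {
    sc <- generate_scene(scene_spec(width_px = 1024L, height_px = 1024L,
                                    n_tubules = 2L,
                                    tubule_radius_um = c(78, 92),
                                    seed = 41))
    rois <- roi_set(sc$truth$tubules,
                    rep("tubule", length(sc$truth$tubules)),
                    image_id = sc$image$image_id)
    det <- detect_cells(sc$image, rois)
    det <- classify_cells(det, classifier_spec(default_class_rules()))
    list(det = assign_regions(det, rois), truth = sc$truth)
  })
}

# one pipeline configuration used by determinism and end-to-end tests
fx_pipeline_config <- function(out_dir) {
  list(simulate = list(n_images = 3, seed = 31, use_truth_rois = TRUE,
                       width_px = 512L, height_px = 512L, n_tubules = 2L,
                       tubule_radius_um = c(40, 55)),
       class_rules = list(
         list(class = "SOX9", channel = "SOX9",
              compartment = "nuclear", threshold_rfu = 2000),
         list(class = "MAGE-A", channel = "MAGE-A",
              compartment = "nuclear", threshold_rfu = 2000)),
       out_dir = out_dir)
}

fx_pipeline_runs <- function() {
  fx_get("pipeline_runs", function() {
    d1 <- file.path(tempdir(), "tubuleseg_run1")
    d2 <- file.path(tempdir(), "tubuleseg_run2")
    res1 <- suppressWarnings(run_pipeline(fx_pipeline_config(d1),
                                          verbose = FALSE))
    res2 <- suppressWarnings(run_pipeline(fx_pipeline_config(d2),
                                          verbose = FALSE))
    list(res1 = res1, res2 = res2, dir1 = d1, dir2 = d2)
  })
}

fx_counts_csv <- function() {
  system.file("extdata", "mitotic_counts_by_region.csv",
              package = "tubuleseg")
}

# brute-force O(n^2) neighbour edges, the independent graph oracle
brute_force_edges <- function(det, radius,
                              unclassified = "unclassified") {
  keep <- which(!is.na(det$class) & det$class != unclassified)
  out <- list()
  for (a in keep) for (b in keep) {
    if (a < b && det$class[a] == det$class[b]) {
      d <- sqrt((det$x_um[a] - det$x_um[b])^2 +
                (det$y_um[a] - det$y_um[b])^2)
      if (d <= radius) {
        out[[length(out) + 1L]] <- c(det$cell_id[a], det$cell_id[b])
      }
    }
  }
  if (!length(out)) return(character(0))
  sort(vapply(out, function(e) paste(sort(e), collapse = "|"),
              character(1)))
}

edge_key <- function(edges) {
  if (!nrow(edges)) return(character(0))
  sort(vapply(seq_len(nrow(edges)), function(i) {
    paste(sort(c(edges$from[i], edges$to[i])), collapse = "|")
  }, character(1)))
}
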