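# Per-image summaries, densities, area-count QC and the pipeline driver.

#' Cell density
#'
#' @param count Number of cells.
#' @param area_mm2 Reference area in mm^2 (> 0).
#' @return Cells per mm^2.
#' @export
cell_density <- function(count, area_mm2) {
  if (any(area_mm2 <= 0)) stop("zero area")
  count / area_mm2
}

#' Summarise one image: counts, tubular area and densities per class
#'
#' @param detections Classified detections of one image.
#' @param rois The image's `ROISet` (tubule areas are summed).
#' @param classes Class level set; defaults to classes present.
#' @return Data.frame, one row per class plus an `all` row: `image_id`,
#'   `class`, `count`, `tubule_area_mm2`, `density_per_mm2`.
#' @export
summarise_image <- function(detections, rois, classes = NULL) {
  stopifnot(inherits(rois, "ROISet"))
  area_mm2 <- sum(rois$area_um2[rois$class_label == "tubule"]) / 1e6
  if (is.null(classes)) classes <- sort(unique(detections$class))
  counts <- c(table(factor(detections$class, levels = classes)),
              all = nrow(detections))
  data.frame(image_id = rep(rois$image_id, length(counts)),
             class = names(counts),
             count = as.integer(counts),
             tubule_area_mm2 = area_mm2,
             density_per_mm2 = if (area_mm2 > 0) {
               as.numeric(counts) / area_mm2
             } else NA_real_,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Linear regression of cell count on tubular area
#'
#' Ordinary least squares of count against area, per class, across
#' images; used to confirm that counts scale with segmented tubular area
#' and to expose images that break the relationship.
#'
#' @param summaries Row-bound output of [summarise_image()] across >= 3
#'   images.
#' @param classes Classes to fit; defaults to all present.
#' @return Data.frame per class: `slope`, `intercept`, `r2`, `p_value`
#'   (two-sided, slope), `n`.
#' @export
area_count_regression <- function(summaries, classes = NULL) {
  stopifnot(is.data.frame(summaries))
  if (is.null(classes)) classes <- unique(summaries$class)
  rows <- list()
  for (cl in classes) {
    s <- summaries[summaries$class == cl, , drop = FALSE]
    if (nrow(s) < 3) stop("need at least 3 images per class")
    if (stats::var(s$tubule_area_mm2) == 0) {
      stop("zero variance in area")
    }
    fit <- stats::lm(count ~ tubule_area_mm2, data = s)
    sm <- summary(fit)
    rows[[length(rows) + 1L]] <- data.frame(
      class = cl,
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r2 = sm$r.squared,
      p_value = unname(sm$coefficients[2, 4]),
      n = nrow(s), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Flag images departing from the area-count relationship
#'
#' Images whose standardised residual from the per-class count-on-area
#' fit exceeds the bound are flagged, never dropped; flags are invariant
#' to area unit changes.
#'
#' @param summaries As for [area_count_regression()].
#' @param class Class whose relationship is checked (default `all`).
#' @param z_bound Standardised-residual bound (default 3).
#' @return Data.frame: `image_id`, `std_residual`, `flagged`.
#' @export
qc_flag_outliers <- function(summaries, class = "all", z_bound = 3) {
  s <- summaries[summaries$class == class, , drop = FALSE]
  if (nrow(s) < 3) stop("need at least 3 images")
  fit <- stats::lm(count ~ tubule_area_mm2, data = s)
  z <- stats::rstandard(fit)
  data.frame(image_id = s$image_id,
             std_residual = unname(z),
             flagged = abs(z) > z_bound,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Default classification rules for the human SOX9/MAGE-A panel
#'
#' Nuclear mean intensity thresholds calibrated to the synthetic marker
#' distributions (positives around 9,000 RFU, negatives at the tissue
#' baseline).
#' @return List of [class_rule()]s.
#' @export
default_class_rules <- function() {
  list(class_rule("SOX9", "SOX9", "nuclear", "mean", 2000),
       class_rule("MAGE-A", "MAGE-A", "nuclear", "mean", 2000))
}

rules_from_config <- function(lst) {
  lapply(lst, function(r) {
    class_rule(r$class, r$channel,
               compartment = if (is.null(r$compartment)) "nuclear"
                             else r$compartment,
               statistic = if (is.null(r$statistic)) "mean"
                           else r$statistic,
               threshold_rfu = r$threshold_rfu)
  })
}

pipeline_log <- function(verbose, stage, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' Stages: load or simulate images; segment tubules (pretrained model,
#' training from annotations, or ROIs supplied directly); detect cells;
#' classify; assign membrane/luminal regions; build neighbour graphs;
#' derive the mitotic gate and index; summarise. Every stage failure
#' aborts with a stage-identified error. Given fixed seeds the whole
#' run, including written CSV output, is byte-reproducible.
#'
#' @param config A list or path to a YAML file. Recognised entries:
#' \describe{
#'   \item{images}{character vector of TIFF paths, or}
#'   \item{simulate}{list(`n_images`, `seed`, plus [scene_spec()]
#'     overrides) for synthetic input (ROIs from the trained model or
#'     from `use_truth_rois = TRUE`).}
#'   \item{model}{path to a saved pixel classifier, or}
#'   \item{train}{list(`images`, `annotations` (GeoJSON paths),
#'     `seed`, `max_epochs`) to train one, or}
#'   \item{rois}{character vector of ROI GeoJSON paths (skip pixel
#'     classification).}
#'   \item{class_rules}{list of rule entries (`class`, `channel`,
#'     `compartment`, `statistic`, `threshold_rfu`); required.}
#'   \item{membrane_depth_um, neighbour_radius_um}{spatial parameters
#'     (defaults 35, 15).}
#'   \item{cycle}{list of [cycle_config()] overrides.}
#'   \item{watershed}{list of [watershed_config()] overrides.}
#'   \item{roi_extraction}{list of [roi_extraction_config()] overrides.}
#'   \item{out_dir}{output directory; when given, ROI GeoJSON, detection
#'     / summary / mitotic CSVs and the edge list are written there.}
#' }
#' @param verbose Log each stage with its parameters to stderr.
#' @return List: `images`, `rois`, `detections`, `graphs`, `summaries`,
#'   `mitotic`, `threshold_rfu`, `regression` (when >= 3 images),
#'   `qc`, `model`, `truth` (for simulated input).
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("%s: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  # ---- input ----------------------------------------------------------
  input <- stage("input", {
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      n <- if (is.null(sim$n_images)) 1L else sim$n_images
      seed0 <- if (is.null(sim$seed)) 1L else sim$seed
      spec_args <- sim[setdiff(names(sim), c("n_images", "seed",
                                             "use_truth_rois"))]
      scenes <- lapply(seq_len(n), function(i) {
        generate_scene(do.call(scene_spec,
                               c(spec_args, list(seed = seed0 + i - 1L))))
      })
      list(imgs = lapply(scenes, `[[`, "image"),
           truth = lapply(scenes, `[[`, "truth"))
    } else if (!is.null(config$images)) {
      list(imgs = lapply(config$images, read_image,
                         pixel_size_override = config$pixel_size_um),
           truth = NULL)
    } else stop("no input: give 'images' or 'simulate'")
  })
  imgs <- input$imgs
  truth <- input$truth
  ids <- vapply(imgs, `[[`, character(1), "image_id")
  if (anyDuplicated(ids)) {
    for (i in seq_along(imgs)) {
      imgs[[i]]$image_id <- sprintf("%s_%d", imgs[[i]]$image_id, i)
    }
    ids <- vapply(imgs, `[[`, character(1), "image_id")
  }
  pipeline_log(verbose, "input", "%d image(s): %s", length(imgs),
               paste(ids, collapse = ", "))

  # ---- tubule segmentation -------------------------------------------
  seg <- stage("segment", {
    if (!is.null(config$rois)) {
      list(rois = lapply(config$rois, read_rois_geojson), model = NULL)
    } else if (!is.null(config$simulate) &&
               isTRUE(config$simulate$use_truth_rois)) {
      list(rois = lapply(seq_along(imgs), function(i) {
        roi_set(truth[[i]]$tubules,
                rep("tubule", length(truth[[i]]$tubules)),
                image_id = ids[i])
      }), model = NULL)
    } else {
      model <- if (!is.null(config$model)) {
        if (inherits(config$model, "PixelClassifierModel")) config$model
        else load_pixel_classifier(config$model)
      } else if (!is.null(config$train)) {
        tr <- config$train
        tr_imgs <- lapply(tr$images, read_image,
                          pixel_size_override = config$pixel_size_um)
        tr_anns <- lapply(tr$annotations, read_rois_geojson)
        train_pixel_classifier(
          tr_imgs, tr_anns,
          max_epochs = if (is.null(tr$max_epochs)) 300L else tr$max_epochs,
          seed = if (is.null(tr$seed)) 1L else tr$seed)
      } else {
        stop("no segmentation source: give 'rois', 'model' or 'train'")
      }
      ex_cfg <- do.call(roi_extraction_config,
                        if (is.null(config$roi_extraction)) list()
                        else config$roi_extraction)
      list(rois = lapply(imgs, function(im) {
        extract_rois(predict_pixels(model, im), cfg = ex_cfg)
      }), model = model)
    }
  })
  rois <- seg$rois
  model <- seg$model
  pipeline_log(verbose, "segment", "%s tubule ROI(s) per image",
               paste(vapply(rois, function(r) {
                 sum(r$class_label == "tubule")
               }, integer(1)), collapse = "/"))

  # ---- cells ----------------------------------------------------------
  ws_cfg <- stage("cells", do.call(watershed_config,
                                   if (is.null(config$watershed)) list()
                                   else config$watershed))
  backend <- if (is.null(config$backend)) "watershed" else config$backend
  dets <- stage("cells", lapply(seq_along(imgs), function(i) {
    detect_cells(imgs[[i]], rois[[i]], backend = backend, cfg = ws_cfg)
  }))
  pipeline_log(verbose, "cells", "backend %s: %s detection(s)", backend,
               paste(vapply(dets, nrow, integer(1)), collapse = "/"))

  # ---- classify -------------------------------------------------------
  dets <- stage("classify", {
    if (is.null(config$class_rules)) {
      stop("class rules missing from config")
    }
    cspec <- classifier_spec(rules_from_config(config$class_rules))
    lapply(dets, classify_cells, spec = cspec)
  })
  # ---- regions --------------------------------------------------------
  depth <- if (is.null(config$membrane_depth_um)) 35
           else config$membrane_depth_um
  dets <- stage("regions", lapply(seq_along(dets), function(i) {
    assign_regions(dets[[i]], rois[[i]], membrane_depth_um = depth)
  }))
  pipeline_log(verbose, "regions", "membrane depth %g um", depth)

  # ---- neighbour graphs ----------------------------------------------
  radius <- if (is.null(config$neighbour_radius_um)) 15
            else config$neighbour_radius_um
  graphs <- stage("spatial", lapply(dets, build_neighbour_graph,
                                    cfg = neighbour_config(radius)))
  pipeline_log(verbose, "spatial", "neighbour radius %g um", radius)

  # ---- cycle ----------------------------------------------------------
  cyc_cfg <- stage("cycle", do.call(cycle_config,
                                    if (is.null(config$cycle)) list()
                                    else config$cycle))
  all_det <- do.call(rbind, dets)
  thr <- stage("cycle", derive_threshold(all_det, cyc_cfg))
  mito <- stage("cycle", mitotic_index(all_det, thr, cyc_cfg))
  pipeline_log(verbose, "cycle", "threshold %.0f RFU (%s mode)", thr,
               cyc_cfg$threshold_mode)

  # ---- report ---------------------------------------------------------
  summaries <- stage("report", do.call(rbind, lapply(
    seq_along(dets), function(i) summarise_image(dets[[i]], rois[[i]]))))
  regression <- NULL; qc <- NULL
  if (length(imgs) >= 3) {
    regression <- stage("report", area_count_regression(summaries))
    qc <- stage("report", qc_flag_outliers(summaries))
  }

  out <- list(images = imgs, rois = rois, detections = dets,
              graphs = graphs, summaries = summaries, mitotic = mito,
              threshold_rfu = thr, regression = regression, qc = qc,
              model = model, truth = truth)

  if (!is.null(config$out_dir)) {
    stage("report", {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      for (i in seq_along(imgs)) {
        write_rois_geojson(rois[[i]], file.path(
          config$out_dir, sprintf("%s_rois.geojson", ids[i])))
      }
      det_out <- all_det
      attr(det_out, "nucleus_polygons") <- NULL
      attr(det_out, "cell_polygons") <- NULL
      write_measurements(det_out,
                         file.path(config$out_dir, "detections.csv"))
      write_measurements(summaries,
                         file.path(config$out_dir, "summaries.csv"))
      write_measurements(mito,
                         file.path(config$out_dir, "mitotic_index.csv"))
      edges <- do.call(rbind, lapply(seq_along(graphs), function(i) {
        e <- graphs[[i]]$edges
        if (nrow(e)) cbind(image_id = ids[i], e) else NULL
      }))
      if (is.null(edges)) {
        edges <- data.frame(image_id = character(0), from = character(0),
                            to = character(0), dist_um = numeric(0))
      }
      write_measurements(edges,
                         file.path(config$out_dir, "neighbour_edges.csv"))
    })
    pipeline_log(verbose, "report", "outputs written to %s",
                 config$out_dir)
  }
  invisible(out)
}
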