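# Hoechst DNA-content profiling and mitotic indexing.
#
# Nuclear counterstain intensity proxies DNA content (2n in G1, up to 4n
# in G2/M). Cells whose nuclear statistic exceeds the threshold (default
# 14,000 RFU, the upper end of the G1 range of the post-mitotic Sertoli
# reference population) are counted as mitotically active; cells at or
# below it as G1.

#' Cell-cycle gating configuration
#'
#' @param channel Counterstain channel (default `Hoechst`).
#' @param statistic Nuclear intensity statistic (default `mean`).
#' @param threshold_mode `fixed` (default) or `reference_percentile`
#'   (threshold set from the reference class's intensity distribution,
#'   the principled analogue of reading the G1 upper range off a
#'   post-mitotic population).
#' @param fixed_threshold_rfu Fixed gate (default 14,000 RFU).
#' @param reference_class Reference population for percentile mode
#'   (default `SOX9`, Sertoli cells: largely post-mitotic).
#' @param reference_percentile Percentile of the reference distribution
#'   used as gate (default 97.5; must be in (50, 100)).
#' @param min_reference_cells Minimum reference population size for
#'   percentile mode.
#' @return An object of class `CycleConfig`.
#' @export
cycle_config <- function(channel = "Hoechst",
                         statistic = c("mean", "max", "sum"),
                         threshold_mode = c("fixed",
                                            "reference_percentile"),
                         fixed_threshold_rfu = 14000,
                         reference_class = "SOX9",
                         reference_percentile = 97.5,
                         min_reference_cells = 50L) {
  statistic <- match.arg(statistic)
  threshold_mode <- match.arg(threshold_mode)
  stopifnot(fixed_threshold_rfu > 0,
            reference_percentile > 50, reference_percentile < 100,
            min_reference_cells >= 1)
  structure(list(channel = channel, statistic = statistic,
                 threshold_mode = threshold_mode,
                 fixed_threshold_rfu = fixed_threshold_rfu,
                 reference_class = reference_class,
                 reference_percentile = reference_percentile,
                 min_reference_cells = as.integer(min_reference_cells)),
            class = "CycleConfig")
}

cycle_stat_column <- function(cfg) {
  paste0(cfg$channel, "_nuc_", cfg$statistic)
}

#' Nuclear intensity histogram of one class/region subset
#'
#' Bins are centred on multiples of `bin_width` so round intensity
#' landmarks (e.g. a 9,000 RFU G1 peak) fall mid-bin.
#'
#' @param detections Classified detections with regions assigned.
#' @param class Class to profile (`NULL` for all).
#' @param region `total`, `membrane` or `luminal`.
#' @param cfg A `CycleConfig` (names the channel/statistic).
#' @param bin_width Histogram bin width in RFU (default 500).
#' @return List: `counts`, `mids`, `breaks`, `peak_rfu` (mid of the
#'   fullest bin), `n`.
#' @export
intensity_profile <- function(detections, class = NULL,
                              region = c("total", "membrane", "luminal"),
                              cfg = cycle_config(), bin_width = 500) {
  region <- match.arg(region)
  col <- cycle_stat_column(cfg)
  if (!col %in% names(detections)) {
    stop(sprintf("column '%s' not measured", col))
  }
  sel <- rep(TRUE, nrow(detections))
  if (!is.null(class)) sel <- sel & detections$class == class
  if (region != "total") sel <- sel & detections$region == region
  v <- detections[[col]][sel]
  v <- v[is.finite(v)]
  if (!length(v)) {
    stop(sprintf("empty subset: class %s, region %s",
                 if (is.null(class)) "<all>" else class, region))
  }
  k <- floor(min(v) / bin_width + 0.5):ceiling(max(v) / bin_width + 0.5)
  breaks <- (c(k, max(k) + 1L) - 0.5) * bin_width
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  list(counts = h$counts, mids = h$mids, breaks = breaks,
       peak_rfu = h$mids[which.max(h$counts)], n = length(v))
}

#' Derive the mitotic intensity threshold
#'
#' @param detections Classified detections (used in percentile mode).
#' @param cfg A `CycleConfig`.
#' @return Threshold in RFU.
#' @export
derive_threshold <- function(detections, cfg = cycle_config()) {
  stopifnot(inherits(cfg, "CycleConfig"))
  if (cfg$threshold_mode == "fixed") return(cfg$fixed_threshold_rfu)
  col <- cycle_stat_column(cfg)
  v <- detections[[col]][detections$class == cfg$reference_class]
  v <- v[is.finite(v)]
  if (length(v) < cfg$min_reference_cells) {
    stop(sprintf(
      "too few reference cells in percentile mode: %d %s cells (need >= %d)",
      length(v), cfg$reference_class, cfg$min_reference_cells))
  }
  unname(stats::quantile(v, cfg$reference_percentile / 100, type = 7))
}

#' Mitotic index per class and tubule region
#'
#' Cells with nuclear statistic strictly above the threshold are
#' mitotic; cells at or below it are G1. Regions are the total tubular
#' area and its membrane-associated/luminal split, so per class
#' `G1 + mitotic = total` in every row and the membrane and luminal
#' totals sum to the total-area totals.
#'
#' @param detections Classified detections with regions assigned.
#' @param threshold Gate in RFU (see [derive_threshold()]).
#' @param cfg A `CycleConfig` (names the channel/statistic).
#' @param classes Classes to tabulate; defaults to all except
#'   `unclassified`.
#' @param unclassified The unclassified label.
#' @return A `MitoticSummary` data.frame with columns `class`, `region`
#'   (`total`/`membrane`/`luminal`), `total`, `g1`, `mitotic`,
#'   `pct_of_class` (region share of the class), `g1_pct`,
#'   `mitotic_index_pct` (all percentages to one decimal). Empty groups
#'   keep zero counts with `NA` percentages and signal a warning.
#' @export
mitotic_index <- function(detections, threshold, cfg = cycle_config(),
                          classes = NULL, unclassified = "unclassified") {
  stopifnot(is.numeric(threshold), length(threshold) == 1)
  col <- cycle_stat_column(cfg)
  if (!col %in% names(detections)) {
    stop(sprintf("column '%s' not measured", col))
  }
  if (is.null(classes)) {
    classes <- setdiff(unique(detections$class), c(unclassified, NA))
  }
  rows <- list()
  for (cl in classes) {
    dcl <- detections[!is.na(detections$class) & detections$class == cl, ,
                      drop = FALSE]
    n_class <- nrow(dcl)
    for (rg in c("total", "membrane", "luminal")) {
      sub <- if (rg == "total") dcl
             else dcl[dcl$region == rg, , drop = FALSE]
      tot <- nrow(sub)
      mit <- sum(sub[[col]] > threshold)
      g1 <- tot - mit
      if (tot == 0) {
        warning(sprintf("empty group: class %s, region %s", cl, rg))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, region = rg, total = tot, g1 = g1, mitotic = mit,
        pct_of_class = if (n_class > 0) round(100 * tot / n_class, 1)
                       else NA_real_,
        g1_pct = if (tot > 0) round(100 * g1 / tot, 1) else NA_real_,
        mitotic_index_pct = if (tot > 0) round(100 * mit / tot, 1)
                            else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    class = character(0), region = character(0), total = integer(0),
    g1 = integer(0), mitotic = integer(0), pct_of_class = numeric(0),
    g1_pct = numeric(0), mitotic_index_pct = numeric(0),
    stringsAsFactors = FALSE)
  class(out) <- c("MitoticSummary", "data.frame")
  out
}

#' Rebuild a minimal detection table from a printed count summary
#'
#' Inverse of the [mitotic_index()] tabulation for worked examples and
#' cross-checks: given per class/region G1 and mitotic counts, emits one
#' synthetic detection row per counted cell, with the nuclear statistic
#' placed on the matching side of the threshold, so the summary
#' arithmetic can be recomputed through the normal code path.
#'
#' @param counts Data.frame with columns `class`, `region`
#'   (`membrane`/`luminal`), `g1`, `mitotic`.
#' @param cfg A `CycleConfig` (names the output column and threshold).
#' @return A detections data.frame with `class`, `region` and the
#'   nuclear statistic column.
#' @export
cells_from_counts <- function(counts, cfg = cycle_config()) {
  stopifnot(all(c("class", "region", "g1", "mitotic") %in% names(counts)))
  thr <- cfg$fixed_threshold_rfu
  col <- cycle_stat_column(cfg)
  rows <- list()
  for (i in seq_len(nrow(counts))) {
    n_g1 <- counts$g1[i]; n_mit <- counts$mitotic[i]
    df <- data.frame(
      class = rep(counts$class[i], n_g1 + n_mit),
      region = rep(counts$region[i], n_g1 + n_mit),
      stringsAsFactors = FALSE)
    df[[col]] <- c(rep(thr * 9 / 14, n_g1), rep(thr * 10 / 7, n_mit))
    rows[[length(rows) + 1L]] <- df
  }
  out <- do.call(rbind, rows)
  out$cell_id <- sprintf("c%06d", seq_len(nrow(out)))
  out
}
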