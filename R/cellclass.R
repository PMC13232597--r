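# Marker/compartment cell classification.
#
# Cells are classified by where a marker lives (nuclear vs cytosolic
# compartment) and how bright it is (statistic over that compartment
# against a threshold); cells meeting no rule are `unclassified`.

#' Define one classification rule
#'
#' @param class Class name assigned when the rule fires (e.g. `SOX9`).
#' @param channel Marker channel measured.
#' @param compartment `nuclear` or `cytosolic` (e.g. SOX9/MAGE-A/PLZF/
#'   COUP-TFII nuclear, MVH cytosolic).
#' @param statistic Intensity statistic: `mean` (default), `max` or
#'   `sum`.
#' @param threshold_rfu Rule fires when the statistic is >= this value.
#' @return An object of class `ClassRule`.
#' @export
class_rule <- function(class, channel,
                       compartment = c("nuclear", "cytosolic"),
                       statistic = c("mean", "max", "sum"),
                       threshold_rfu) {
  compartment <- match.arg(compartment)
  statistic <- match.arg(statistic)
  stopifnot(is.character(class), nzchar(class),
            is.character(channel), nzchar(channel))
  if (!is.numeric(threshold_rfu) || threshold_rfu <= 0) {
    stop("threshold_rfu must be > 0")
  }
  structure(list(class = class, channel = channel,
                 compartment = compartment, statistic = statistic,
                 threshold_rfu = threshold_rfu),
            class = "ClassRule")
}

#' Assemble a cell classifier from rules
#'
#' @param rules List of [class_rule()]s with unique class names.
#' @param tie_break When several rules fire: `max_fold_over_threshold`
#'   (default; the rule with the largest statistic/threshold ratio wins,
#'   ties resolved by rule order) or `rule_order` (first firing rule).
#' @param unclassified Label for cells meeting no rule.
#' @return An object of class `ClassifierSpec`.
#' @export
classifier_spec <- function(rules,
                            tie_break = c("max_fold_over_threshold",
                                          "rule_order"),
                            unclassified = "unclassified") {
  tie_break <- match.arg(tie_break)
  stopifnot(is.list(rules), length(rules) >= 1,
            all(vapply(rules, inherits, logical(1), "ClassRule")))
  cls <- vapply(rules, `[[`, character(1), "class")
  if (anyDuplicated(cls)) stop("class names must be unique")
  structure(list(rules = rules, tie_break = tie_break,
                 unclassified = unclassified),
            class = "ClassifierSpec")
}

rule_column <- function(rule) {
  comp <- c(nuclear = "nuc", cytosolic = "cyt")[[rule$compartment]]
  paste0(rule$channel, "_", comp, "_", rule$statistic)
}

#' Classify detections by marker intensity and location
#'
#' Every detection receives exactly one label: the class of the unique
#' firing rule, the tie-break winner when several fire, or the
#' unclassified label when none fires. Classification is deterministic
#' and depends only on the measured intensity statistics, so identical
#' nucleus/cell masks yield identical labels whatever segmentation
#' backend produced them.
#'
#' @param detections A `CellDetections` data.frame.
#' @param spec A `ClassifierSpec`.
#' @return `detections` with the `class` column filled.
#' @export
classify_cells <- function(detections, spec) {
  stopifnot(is.data.frame(detections), inherits(spec, "ClassifierSpec"))
  n <- nrow(detections)
  k <- length(spec$rules)
  if (!n) {
    detections$class <- character(0)
    return(detections)
  }
  folds <- matrix(NA_real_, n, k)
  for (j in seq_len(k)) {
    col <- rule_column(spec$rules[[j]])
    if (!col %in% names(detections)) {
      stop(sprintf(
        "rule '%s' references unmeasured channel statistic '%s'",
        spec$rules[[j]]$class, col))
    }
    folds[, j] <- detections[[col]] / spec$rules[[j]]$threshold_rfu
  }
  fired <- folds >= 1
  fired[is.na(fired)] <- FALSE
  lab <- rep(spec$unclassified, n)
  any_fired <- rowSums(fired) > 0
  if (any(any_fired)) {
    cls <- vapply(spec$rules, `[[`, character(1), "class")
    pick <- if (spec$tie_break == "max_fold_over_threshold") {
      fm <- folds
      fm[!fired] <- -Inf
      max.col(fm, ties.method = "first")
    } else {
      max.col(fired, ties.method = "first")  # first TRUE in rule order
    }
    lab[any_fired] <- cls[pick[any_fired]]
  }
  detections$class <- lab
  detections
}

#' Count detections by class (optionally by region)
#'
#' @param detections Classified detections.
#' @param by `"class"` or `c("class", "region")`.
#' @param classes Optional class level set (zero counts included);
#'   defaults to the classes present.
#' @return A data.frame of counts; counts always partition the input
#'   (classes plus unclassified sum to the number of detections).
#' @export
class_counts <- function(detections, by = "class", classes = NULL) {
  stopifnot(is.data.frame(detections), all(by %in% c("class", "region")))
  if (anyNA(detections$class)) {
    stop("detections must be classified first")
  }
  if (is.null(classes)) classes <- unique(detections$class)
  f <- list(class = factor(detections$class, levels = classes))
  if ("region" %in% by) {
    f$region <- factor(detections$region)
  }
  tb <- as.data.frame(table(f), stringsAsFactors = FALSE)
  names(tb)[names(tb) == "Freq"] <- "count"
  tb
}
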