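## Classification: assign class names to objects from feature rules or
## feature-range object models. Classification never alters geometry.

need_feature <- function(o, feature) {
  if (!feature %in% names(o$features))
    ol_stop("missing_feature",
            sprintf("object %d lacks feature '%s'", o$id, feature))
  o$features[[feature]]
}

#' Threshold rule constructor
#'
#' @param feature feature name.
#' @param relation one of `"gt"`, `"ge"`, `"lt"`, `"le"`.
#' @param threshold numeric cutoff.
#' @param class_if_true class assigned when the relation holds.
#' @param class_if_false class assigned otherwise; `NULL` keeps the current
#'   class.
#' @export
threshold_rule <- function(feature, relation, threshold, class_if_true,
                           class_if_false = NULL) {
  relation <- match.arg(relation, c("gt", "ge", "lt", "le"))
  list(feature = feature, relation = relation,
       threshold = as.numeric(threshold),
       class_if_true = class_if_true, class_if_false = class_if_false)
}

rule_holds <- function(value, relation, threshold) {
  switch(relation,
         gt = value > threshold, ge = value >= threshold,
         lt = value < threshold, le = value <= threshold)
}

#' Apply a threshold rule to (a scope of) a layer
#'
#' In-scope objects receive `class_if_true` when the relation holds and
#' `class_if_false` (if given) otherwise; out-of-scope objects are untouched.
#'
#' @param layer an `ObjectLayer` with the rule's feature computed in scope.
#' @param rule a [threshold_rule()].
#' @param scope optional character vector of class names; only objects whose
#'   current class is in `scope` are examined (default: all objects).
#' @return the reclassified layer.
#' @export
apply_rule <- function(layer, rule, scope = NULL) {
  for (o in layer$objects) {
    if (!is.null(scope) && !(isTRUE(o$class_name %in% scope))) next
    v <- need_feature(o, rule$feature)
    key <- as.character(o$id)
    if (rule_holds(v, rule$relation, rule$threshold)) {
      layer$objects[[key]]$class_name <- rule$class_if_true
    } else if (!is.null(rule$class_if_false)) {
      layer$objects[[key]]$class_name <- rule$class_if_false
    }
  }
  layer
}

#' Object model constructor
#'
#' An object model describes the ideal object of a class as feature ranges;
#' an object matches when every feature lies inside its closed interval.
#'
#' @param class_name class assigned to matching objects.
#' @param predicates list of `list(feature =, min =, max =)`; `-Inf`/`Inf`
#'   open one side.
#' @export
object_model <- function(class_name, predicates) {
  for (p in predicates)
    stopifnot(is.character(p$feature), p$min <= p$max)
  list(class_name = class_name, predicates = predicates)
}

#' Read an object model from JSON
#'
#' Expects `{"class": name, "predicates": [{"feature", "min", "max"}]}`;
#' missing `min`/`max` default to unbounded.
#'
#' @param path JSON file path.
#' @export
read_object_model <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  preds <- lapply(doc$predicates, function(p) {
    list(feature = p$feature,
         min = if (is.null(p$min)) -Inf else as.numeric(p$min),
         max = if (is.null(p$max)) Inf else as.numeric(p$max))
  })
  object_model(doc$class, preds)
}

#' Apply an object model to a layer
#'
#' Objects satisfying every predicate (closed intervals) are assigned the
#' model's class; all other objects are unchanged.
#'
#' @param layer an `ObjectLayer` with all predicate features computed.
#' @param model an [object_model()].
#' @return the reclassified layer.
#' @export
apply_model <- function(layer, model) {
  for (o in layer$objects) {
    ok <- TRUE
    for (p in model$predicates) {
      v <- need_feature(o, p$feature)
      if (v < p$min || v > p$max) { ok <- FALSE; break }
    }
    if (ok) layer$objects[[as.character(o$id)]]$class_name <- model$class_name
  }
  layer
}

#' Count objects per class
#'
#' @param layer an `ObjectLayer`.
#' @return named integer vector of exact class multiplicities, sorted by
#'   name; unclassified objects are counted under `"unclassified"`. Counts
#'   sum to the number of objects.
#' @export
count_classes <- function(layer) {
  cls <- layer_classes(layer)
  if (length(cls) == 0L) return(stats::setNames(integer(0), character(0)))
  cls[is.na(cls)] <- "unclassified"
  tab <- table(cls)
  stats::setNames(as.integer(tab), names(tab))
}

#' Reclassify source-class objects that contact a target class
#'
#' Source-class objects whose `border_to_<target_class>` feature is strictly
#' positive are reclassified to `new_class`; all other objects (including
#' contacting objects of other classes) are unchanged. Idempotent when
#' `new_class` differs from `source_class`.
#'
#' @param layer an `ObjectLayer` with [relational_features()] computed for
#'   `target_class` on all source-class objects.
#' @param source_class class examined (e.g. `"osteoclast"`).
#' @param target_class contacted class (e.g. `"bone"`).
#' @param new_class class assigned on contact (e.g.
#'   `"osteoclast interacting"`).
#' @return the reclassified layer.
#' @export
classify_interacting <- function(layer, source_class, target_class,
                                 new_class) {
  feat <- paste0("border_to_", target_class)
  for (o in layer$objects) {
    if (!isTRUE(o$class_name == source_class)) next
    if (need_feature(o, feat) > 0)
      layer$objects[[as.character(o$id)]]$class_name <- new_class
  }
  layer
}
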