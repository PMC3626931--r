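## Processing-chain engine. Steps are named, argument-bearing operations
## registered at load time; chains are declarative JSON documents listing
## steps in order. Sequential steps pass their state (image, mask, layer,
## voronoi map, network) forward; the layer is the primary hand-off value.

the_registry <- new.env(parent = emptyenv())

register_step <- function(name, fun, schema, doc) {
  assign(name, list(name = name, fun = fun, schema = schema, doc = doc),
         envir = the_registry)
  the_registry$.order <- c(the_registry$.order, name)
  invisible(name)
}

registry_get <- function(name) {
  if (!exists(name, envir = the_registry, inherits = FALSE)) return(NULL)
  get(name, envir = the_registry, inherits = FALSE)
}

#' List the registered processing steps
#'
#' @return data.frame with `step`, `arguments` (comma-separated schema) and
#'   `doc`, in stable registration order.
#' @export
registry_list <- function() {
  nm <- the_registry$.order
  data.frame(
    step = nm,
    arguments = vapply(nm, function(n) {
      sc <- registry_get(n)$schema
      paste(names(sc), collapse = ", ")
    }, character(1)),
    doc = vapply(nm, function(n) registry_get(n)$doc, character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

## ---- chain parsing ---------------------------------------------------------

#' Parse a processing chain from JSON
#'
#' Chain documents look like
#' `{"name": ..., "seed": ..., "steps": [{"step": name, "args": {...}}]}`.
#' Unknown step names and argument names not in the step's schema are
#' rejected with the offending step index.
#'
#' @param document JSON text, or the path of a JSON file.
#' @return a `ProcessingChain`.
#' @export
parse_chain <- function(document) {
  txt <- if (length(document) == 1L && !grepl("[{\n]", document) &&
             file.exists(document)) {
    paste(readLines(document, warn = FALSE), collapse = "\n")
  } else paste(document, collapse = "\n")
  doc <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  steps <- doc$steps
  if (is.null(steps) || length(steps) == 0L)
    ol_stop("empty_chain", "chain has no steps")
  parsed <- vector("list", length(steps))
  for (i in seq_along(steps)) {
    s <- steps[[i]]
    if (is.null(s$step))
      ol_stop("bad_argument", sprintf("step %d has no 'step' name", i))
    entry <- registry_get(s$step)
    if (is.null(entry))
      ol_stop("unknown_step",
              sprintf("step %d: unknown step '%s'", i, s$step))
    args <- if (is.null(s$args)) list() else s$args
    bad <- setdiff(names(args), names(entry$schema))
    if (length(bad))
      ol_stop("bad_argument", sprintf(
        "step %d ('%s'): unknown argument(s) %s", i, s$step,
        paste(sprintf("'%s'", bad), collapse = ", ")))
    missing <- names(entry$schema)[vapply(entry$schema, function(a)
      isTRUE(a$required), logical(1))]
    missing <- setdiff(missing, names(args))
    if (length(missing))
      ol_stop("bad_argument", sprintf(
        "step %d ('%s'): missing required argument(s) %s", i, s$step,
        paste(sprintf("'%s'", missing), collapse = ", ")))
    parsed[[i]] <- list(step = s$step, args = args)
  }
  structure(list(name = if (is.null(doc$name)) "chain" else doc$name,
                 seed = doc$seed,
                 steps = parsed),
            class = "ProcessingChain")
}

#' Serialize a processing chain to JSON
#'
#' @param chain a `ProcessingChain`.
#' @param path output path.
#' @export
write_chain <- function(chain, path) {
  doc <- list(name = chain$name)
  if (!is.null(chain$seed)) doc$seed <- chain$seed
  doc$steps <- lapply(chain$steps, function(s)
    if (length(s$args)) list(step = s$step, args = s$args)
    else list(step = s$step))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

## ---- chain execution -------------------------------------------------------

resolve_stains <- function(arg) {
  if (is.null(arg) || identical(arg, "hdab")) hdab_matrix()
  else read_stain_matrix(arg)
}

need_state <- function(state, what, step) {
  if (is.null(state[[what]]))
    ol_stop("bad_argument", sprintf(
      "step '%s' needs a %s from an earlier step", step, what))
  state[[what]]
}

#' Run a processing chain on an image
#'
#' Executes the chain's steps in order. Every step's output layer must pass
#' [validate_layer()]; the log records step name, arguments, object count
#' and class counts after each step. Runs are bit-reproducible for identical
#' (chain, image, seed).
#'
#' @param chain a `ProcessingChain` (see [parse_chain()]).
#' @param image numeric H x W x 3 array, values 0..255.
#' @param out_dir directory for exported artifacts (default: a temp dir).
#' @param keep_intermediates write each step's label map and layer JSON into
#'   `out_dir`.
#' @return list with `layer` (final `ObjectLayer`), `log` (per-step
#'   records), `class_counts` (from the last `num_class` step), `network`,
#'   and `results` (data.frame from the last `export` step, if any).
#' @export
run_chain <- function(chain, image, out_dir = NULL,
                      keep_intermediates = FALSE) {
  stopifnot(inherits(chain, "ProcessingChain"))
  if (length(image) == 0L)
    ol_stop("bad_argument", "cannot run a chain on an empty image")
  if (is.null(out_dir)) out_dir <- tempfile("objlayer_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- list(image = image, mask = NULL, layer = NULL, voronoi = NULL,
                network = NULL, class_counts = NULL, results = NULL,
                out_dir = out_dir, log = list())
  body <- function() {
    for (i in seq_along(chain$steps)) {
      s <- chain$steps[[i]]
      entry <- registry_get(s$step)
      state <<- tryCatch(
        entry$fun(state, s$args),
        error = function(e) {
          ol_stop("step", sprintf("step %d ('%s') failed: %s",
                                  i, s$step, conditionMessage(e)))
        })
      if (!is.null(state$layer)) {
        bad <- validate_layer(state$layer)
        if (length(bad))
          ol_stop("step", sprintf(
            "step %d ('%s') produced an invalid layer: %s",
            i, s$step, paste(bad, collapse = "; ")))
      }
      state$log[[i]] <<- list(
        step = s$step, arguments = s$args,
        n_objects = if (is.null(state$layer)) NA_integer_
                    else length(state$layer$objects),
        class_counts = if (is.null(state$layer)) NULL
                       else count_classes(state$layer))
      if (keep_intermediates && !is.null(state$layer)) {
        base <- file.path(out_dir, sprintf("step_%02d_%s", i, s$step))
        write_label_map(state$layer$label_map, paste0(base, "_labels.tif"))
        write_layer_json(state$layer, paste0(base, "_layer.json"))
      }
    }
  }
  if (!is.null(chain$seed)) with_seed(chain$seed, body()) else body()
  list(layer = state$layer, log = state$log,
       class_counts = state$class_counts, network = state$network,
       results = state$results)
}

## ---- step registrations ----------------------------------------------------

image_channel <- function(image, name) {
  k <- match(name, c("R", "G", "B"))
  if (is.na(k))
    ol_stop("bad_argument", sprintf("unknown channel '%s'", name))
  image[, , k]
}

register_all_steps <- function() {
  register_step(
    "otsu_threshold",
    function(state, args) {
      ch <- image_channel(state$image, args$channel)
      state$mask <- threshold_segment(ch, otsu_threshold(ch), "above")
      state
    },
    schema = list(channel = list(required = TRUE,
                                 doc = "R, G or B")),
    doc = "Otsu-threshold one channel into a foreground mask")

  register_step(
    "threshold_segment",
    function(state, args) {
      src <- if (is.null(args$source)) "R" else args$source
      grid <- if (src == "stain_sum") {
        conc <- deconvolve(state$image, resolve_stains(args$matrix))
        conc[[1L]] + conc[[2L]]
      } else image_channel(state$image, src)
      pol <- if (is.null(args$polarity)) "above" else args$polarity
      state$mask <- threshold_segment(grid, args$threshold, pol)
      state
    },
    schema = list(source = list(doc = "R, G, B or stain_sum"),
                  threshold = list(required = TRUE, doc = "cutoff"),
                  polarity = list(doc = "above (default) or below"),
                  matrix = list(doc = "stain matrix: 'hdab' or JSON path")),
    doc = "Fixed-threshold segmentation of a channel or the stain OD sum")

  register_step(
    "connected_components",
    function(state, args) {
      state$layer <- connected_components(need_state(state, "mask",
                                                     "connected_components"))
      state
    },
    schema = list(),
    doc = "Label 8-connected foreground components as an object layer")

  register_step(
    "remove_small",
    function(state, args) {
      state$layer <- remove_small(need_state(state, "layer", "remove_small"),
                                  args$min_area)
      state
    },
    schema = list(min_area = list(required = TRUE,
                                  doc = "minimum pixel count")),
    doc = "Delete objects below an area cutoff")

  register_step(
    "merge_channels",
    function(state, args) {
      specs <- lapply(args$specs, function(s)
        channel_spec(match(s$channel, c("R", "G", "B")), s$class, s$priority))
      min_area <- if (is.null(args$min_area)) 1L else args$min_area
      state$layer <- merge_channel_layers(state$image, specs, min_area)
      state
    },
    schema = list(specs = list(required = TRUE,
                               doc = "list of {channel, class, priority}"),
                  min_area = list(doc = "per-channel area filter")),
    doc = "Otsu-segment channels and merge by priority into a classified layer")

  register_step(
    "voronoi",
    function(state, args) {
      state$voronoi <- voronoi_tessellate(need_state(state, "layer", "voronoi"),
                                          args$max_distance)
      state
    },
    schema = list(max_distance = list(doc = "reach limit in pixels")),
    doc = "Discrete Voronoi tessellation of the current layer")

  register_step(
    "network",
    function(state, args) {
      state$network <- build_network(need_state(state, "layer", "network"),
                                     need_state(state, "voronoi", "network"))
      state
    },
    schema = list(),
    doc = "Build the object neighbourhood network from the Voronoi map")

  register_step(
    "morphometry",
    function(state, args) {
      state$layer <- morphometry(need_state(state, "layer", "morphometry"))
      state
    },
    schema = list(),
    doc = "Area, contour length, form factor and centroid features")

  register_step(
    "channel_intensity",
    function(state, args) {
      state$layer <- channel_intensity(
        need_state(state, "layer", "channel_intensity"), state$image)
      state
    },
    schema = list(),
    doc = "Mean R/G/B intensities per object")

  register_step(
    "stain_intensity",
    function(state, args) {
      state$layer <- stain_intensity(
        need_state(state, "layer", "stain_intensity"), state$image,
        resolve_stains(args$matrix))
      state
    },
    schema = list(matrix = list(doc = "stain matrix: 'hdab' or JSON path")),
    doc = "Mean stain concentrations per object (color deconvolution)")

  register_step(
    "relational",
    function(state, args) {
      state$layer <- relational_features(
        need_state(state, "layer", "relational"),
        need_state(state, "network", "relational"),
        unlist(args$classes))
      state
    },
    schema = list(classes = list(required = TRUE,
                                 doc = "class names to relate against")),
    doc = "border_to/num_neighbouring/num_touching features per class")

  register_step(
    "rule",
    function(state, args) {
      rule <- threshold_rule(args$feature, args$op, args$t, args$true,
                             args$false)
      state$layer <- apply_rule(need_state(state, "layer", "rule"), rule,
                                scope = unlist(args$scope))
      state
    },
    schema = list(feature = list(required = TRUE, doc = "feature name"),
                  op = list(required = TRUE, doc = "gt/ge/lt/le"),
                  t = list(required = TRUE, doc = "threshold"),
                  true = list(required = TRUE, doc = "class if relation holds"),
                  false = list(doc = "class otherwise (default: keep)"),
                  scope = list(doc = "restrict to current classes")),
    doc = "Threshold rule classification")

  register_step(
    "model",
    function(state, args) {
      model <- if (!is.null(args$file)) read_object_model(args$file)
      else object_model(args$class, lapply(args$predicates, function(p)
        list(feature = p$feature,
             min = if (is.null(p$min)) -Inf else as.numeric(p$min),
             max = if (is.null(p$max)) Inf else as.numeric(p$max))))
      state$layer <- apply_model(need_state(state, "layer", "model"), model)
      state
    },
    schema = list(file = list(doc = "object model JSON path"),
                  class = list(doc = "class name (inline model)"),
                  predicates = list(doc = "feature ranges (inline model)")),
    doc = "Feature-range object model classification")

  register_step(
    "num_class",
    function(state, args) {
      state$class_counts <- count_classes(need_state(state, "layer",
                                                     "num_class"))
      state
    },
    schema = list(),
    doc = "Count objects per class")

  register_step(
    "interacting",
    function(state, args) {
      state$layer <- classify_interacting(
        need_state(state, "layer", "interacting"),
        args$source, args$target, args$as)
      state
    },
    schema = list(source = list(required = TRUE, doc = "class examined"),
                  target = list(required = TRUE, doc = "contacted class"),
                  as = list(required = TRUE, doc = "class assigned on contact")),
    doc = "Reclassify source-class objects with border_to_<target> > 0")

  register_step(
    "export",
    function(state, args) {
      fname <- if (is.null(args$file)) "results.csv" else args$file
      path <- if (grepl("^/", fname)) fname else file.path(state$out_dir, fname)
      state$results <- export_csv(need_state(state, "layer", "export"), path)
      state
    },
    schema = list(file = list(doc = "CSV file name (default results.csv)")),
    doc = "Export object id, class and features to CSV")
}

.onLoad <- function(libname, pkgname) {
  if (is.null(the_registry$.order)) register_all_steps()
}

#' Path of a processing chain shipped with the package
#'
#' Two demonstration chains ship with the package: `"ki67_demo"` (H-DAB IHC
#' nucleus segmentation, tumor/normal and Ki67+/- classification, class
#' counting, CSV export) and `"cell_interaction_demo"` (three-channel merge,
#' Voronoi network, bone-contact features, "osteoclast interacting"
#' reclassification, CSV export).
#'
#' @param name chain name (without extension).
#' @return file path.
#' @export
packaged_chain <- function(name = c("ki67_demo", "cell_interaction_demo")) {
  name <- match.arg(name)
  system.file("chains", paste0(name, ".json"), package = "objlayer",
              mustWork = TRUE)
}
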