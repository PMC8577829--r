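# Readers/writers for measurement tables and lineage trees, plus pipeline
# configuration.  Delimited text is CSV (UTF-8, "." decimal, mandatory
# header); trees are JSON node records (lossless) or annotated Newick
# (topology and chronology).  Times are hours throughout.

.required_measurement_cols <- c("cell_id", "raw_red", "raw_green",
                                "background_red", "background_green")

#' Read a per-cell measurement table
#'
#' Reads a CSV of raw per-nucleus integrated densities and backgrounds.
#' Required columns: `cell_id`, `raw_red`, `raw_green`, `background_red`,
#' `background_green`; optional `raw_blue`/`background_blue`, `region` and
#' marker flags such as `red_only`.  Unknown columns are preserved.
#' Malformed records are rejected, not coerced: negative intensities or
#' backgrounds are a validation error.
#'
#' @param path CSV file path.
#' @return data frame of measurements (possibly empty, with a warning for a
#'   header-only file).
#' @export
read_measurement_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.required_measurement_cols, names(tab))
  if (length(missing_cols) > 0L) {
    stop("measurement table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(tab) == 0L) {
    warning("measurement table contains a header but no cells")
    return(tab)
  }
  num_cols <- grep("^(raw|background)_", names(tab), value = TRUE)
  for (col in num_cols) {
    if (!is.numeric(tab[[col]]) || anyNA(tab[[col]])) {
      stop(sprintf("column `%s` must be numeric with no missing values", col),
           call. = FALSE)
    }
    if (any(tab[[col]] < 0)) {
      stop(sprintf("column `%s` contains negative intensities", col),
           call. = FALSE)
    }
  }
  if ("red_only" %in% names(tab)) tab$red_only <- as.logical(tab$red_only)
  tab
}

#' Write a per-cell measurement table
#'
#' @param cells measurement data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurement_table <- function(cells, path) {
  missing_cols <- setdiff(.required_measurement_cols, names(cells))
  if (length(missing_cols) > 0L) {
    stop("refusing to write a table missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  write.csv(cells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.lineage_cols <- c("cell_id", "parent_id", "founder", "birth_time",
                   "division_time", "fate", "generation", "true_divisions",
                   "recombined", "red", "green", "blue")

#' Write a lineage tree
#'
#' JSON (default) stores every node record losslessly.  Newick stores the
#' branching structure and chronology only: labels are cell ids and each edge
#' length is the cell's lifespan (division to division, or to the horizon for
#' terminal cells); fates, labels states and division counts are not
#' representable and are dropped.
#'
#' @param tree an `icount_lineage` data frame.
#' @param path output file.
#' @param format `"json"` or `"newick"`.
#' @return `path`, invisibly.
#' @export
write_lineage_tree <- function(tree, path, format = c("json", "newick")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(tree))
  if (format == "json") {
    nodes <- tree[, intersect(.lineage_cols, names(tree)), drop = FALSE]
    jsonlite::write_json(list(format = "icount_lineage", nodes = nodes),
                         path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    horizon <- attr(tree, "config")$horizon
    if (is.null(horizon)) {
      horizon <- max(c(tree$division_time, tree$birth_time), na.rm = TRUE)
    }
    founders <- tree$cell_id[is.na(tree$parent_id)]
    lines <- vapply(founders, function(f) {
      paste0(.newick_node(tree, f, horizon), ";")
    }, character(1L))
    writeLines(lines, path)
  }
  invisible(path)
}

.newick_node <- function(tree, id, horizon) {
  row <- tree[tree$cell_id == id, ]
  len <- (if (is.na(row$division_time)) horizon else row$division_time) -
    row$birth_time
  kids <- tree$cell_id[!is.na(tree$parent_id) & tree$parent_id == id]
  label <- paste0("c", id)
  if (length(kids) == 0L) {
    sprintf("%s:%g", label, len)
  } else {
    sprintf("(%s)%s:%g",
            paste(vapply(kids, .newick_node, character(1L), tree = tree,
                         horizon = horizon), collapse = ","),
            label, len)
  }
}

#' Read a lineage tree
#'
#' Reads a tree written by [write_lineage_tree()] and validates it: every
#' non-founder must name an existing parent, a child's birth time must equal
#' its parent's division time, and division must not precede birth.  Newick
#' input (parsed with \pkg{ape}) recovers ids, topology, birth and division
#' times; fields Newick cannot carry are `NA`.
#'
#' @param path input file.
#' @param format `"auto"` (by file content), `"json"` or `"newick"`.
#' @return an `icount_lineage` data frame.
#' @export
read_lineage_tree <- function(path, format = c("auto", "json", "newick")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  if (format == "auto") {
    first <- substr(trimws(readLines(path, n = 1L, warn = FALSE)), 1L, 1L)
    format <- if (first == "{") "json" else "newick"
  }
  tree <- if (format == "json") .read_tree_json(path) else
    .read_tree_newick(path)
  .validate_lineage(tree)
  class(tree) <- c("icount_lineage", "data.frame")
  tree
}

.read_tree_json <- function(path) {
  doc <- jsonlite::fromJSON(path)
  if (is.null(doc$nodes)) stop("not a lineage-tree JSON document",
                               call. = FALSE)
  nodes <- as.data.frame(doc$nodes)
  for (col in setdiff(.lineage_cols, names(nodes))) nodes[[col]] <- NA
  nodes[, .lineage_cols]
}

.read_tree_newick <- function(path) {
  trees <- ape::read.tree(path)
  if (inherits(trees, "phylo")) trees <- list(trees)
  rows <- list()
  for (tr in trees) {
    n_tip <- length(tr$tip.label)
    labels <- c(tr$tip.label, tr$node.label)
    ids <- as.integer(sub("^c", "", labels))
    root <- n_tip + 1L
    parent_of <- rep(NA_integer_, length(labels))
    edge_len <- rep(NA_real_, length(labels))
    parent_of[tr$edge[, 2L]] <- tr$edge[, 1L]
    edge_len[tr$edge[, 2L]] <- tr$edge.length
    if (!is.null(tr$root.edge)) edge_len[root] <- tr$root.edge
    birth <- rep(NA_real_, length(labels))
    birth[root] <- 0
    # children after parents in a preorder walk over edges
    ord <- order(ape::node.depth.edgelength(tr)[tr$edge[, 2L]])
    for (e in ord) {
      child <- tr$edge[e, 2L]
      par <- tr$edge[e, 1L]
      birth[child] <- birth[par] + edge_len[par]
    }
    is_internal <- seq_along(labels) > n_tip
    rows[[length(rows) + 1L]] <- data.frame(
      cell_id = ids,
      parent_id = ifelse(is.na(parent_of), NA_integer_, ids[parent_of]),
      birth_time = birth,
      division_time = ifelse(is_internal, birth + edge_len, NA_real_),
      fate = ifelse(is_internal, "divided", NA_character_),
      founder = ids[root], generation = NA_integer_,
      true_divisions = NA_integer_,
      recombined = NA, red = NA_real_, green = NA_real_, blue = NA_real_)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$cell_id), .lineage_cols]
  rownames(out) <- NULL
  out
}

.validate_lineage <- function(tree) {
  if (anyDuplicated(tree$cell_id)) stop("duplicate cell ids", call. = FALSE)
  kids <- !is.na(tree$parent_id)
  idx <- match(tree$parent_id[kids], tree$cell_id)
  if (anyNA(idx)) stop("node references a missing parent", call. = FALSE)
  pdiv <- tree$division_time[idx]
  bad <- is.na(pdiv) | abs(tree$birth_time[kids] - pdiv) > 1e-6
  if (any(bad)) {
    stop("time inversion: a child's birth time must equal its parent's ",
         "division time", call. = FALSE)
  }
  div <- !is.na(tree$division_time)
  if (any(tree$division_time[div] < tree$birth_time[div])) {
    stop("time inversion: division before birth", call. = FALSE)
  }
  invisible(tree)
}

#' Read and validate a pipeline run configuration
#'
#' JSON document with optional blocks `simulate` (arguments of
#' [simulation_config()]), `noise` ([measurement_noise()]), `normalize`
#' (`n_ref`), `infer` (`C`), and a top-level `seed`.
#'
#' @param path JSON file.
#' @return a list of class `icount_run_config` with a fully validated
#'   `sim_config` plus `n_ref`, `C` and `seed`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  doc <- jsonlite::fromJSON(path)
  noise <- do.call(measurement_noise, as.list(doc$noise))
  sim_args <- as.list(doc$simulate)
  if (!is.null(sim_args$cycle_time)) {
    sim_args$cycle_time <- as.list(sim_args$cycle_time)
  }
  sim_args$noise <- noise
  if (is.null(sim_args$seed)) sim_args$seed <- doc$seed
  cfg <- do.call(simulation_config, sim_args)
  structure(list(sim_config = cfg,
                 n_ref = if (is.null(doc$normalize$n_ref)) 10 else
                   doc$normalize$n_ref,
                 C = if (is.null(doc$infer$C)) 1 else doc$infer$C,
                 seed = if (is.null(doc$seed)) cfg$seed else doc$seed),
            class = "icount_run_config")
}

#' Run the full simulate-measure-normalize-infer-evaluate pipeline
#'
#' Chains [simulate_lineages()], [apply_measurement_noise()],
#' [normalize_fixed()], [classify_dataset()] and [evaluate_accuracy()]
#' deterministically from one seed, and writes a manifest, the measurement,
#' truth and per-cell estimate tables, and a JSON summary (accuracy, class
#' histograms of predictions and truth, their total-variation distance, and
#' per-stage counts) to the output directory.  Non-recombined (red-only)
#' cells serve as normalization references and are excluded from
#' classification and accuracy scoring.
#'
#' @param config an `icount_run_config` (see [read_run_config()]) or an
#'   [simulation_config()] (run with defaults `n_ref = 10`, `C = 1`).
#' @param out_dir output directory, created if missing.
#' @param seed integer seed overriding the configured one.
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (inherits(config, "icount_sim_config")) {
    config <- structure(list(sim_config = config, n_ref = 10, C = 1,
                             seed = config$seed),
                        class = "icount_run_config")
  }
  stopifnot(inherits(config, "icount_run_config"))
  if (is.null(seed)) seed <- config$seed
  if (is.null(seed)) stop("a seed is required", call. = FALSE)
  seed <- as.integer(seed)
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
    message("created output directory ", out_dir)
  }

  tree <- simulate_lineages(config$sim_config, seed = seed)
  message(sprintf("simulate: %d cells (%d founders)", nrow(tree),
                  config$sim_config$n_founders))
  measurements <- apply_measurement_noise(tree, config$sim_config$noise,
                                          seed = seed + 1L)
  message(sprintf("measure: %d cells", nrow(measurements)))

  normalized <- normalize_fixed(measurements, n_ref = config$n_ref)
  recombined <- normalized[!normalized$red_only, , drop = FALSE]
  message(sprintf("normalize: %d cells, %d recombined", nrow(normalized),
                  nrow(recombined)))

  cls <- classify_dataset(recombined, C = config$C)
  truth <- ground_truth(tree)
  acc <- evaluate_accuracy(cls$cells, truth)
  message(sprintf("evaluate: %.1f%% of %d events correct",
                  100 * acc$fraction_correct, acc$n_events))

  truth_rec <- truth[truth$cell_id %in% cls$cells$cell_id, ]
  truth_hist <- division_class_histogram(
    .class_of_true(pmin(truth_rec$true_divisions, 4)), group = "truth")
  dist <- withr::with_seed(seed + 2L,
                           compare_distributions(cls$histograms$all,
                                                 truth_hist))

  est <- cls$cells[, c("cell_id", "R", "n_hat")]
  est$div_class <- as.character(cls$cells$div_class)
  write_measurement_table(measurements, file.path(out_dir,
                                                  "measurements.csv"))
  write.csv(truth, file.path(out_dir, "truth.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(est, file.path(out_dir, "estimates.csv"),
            row.names = FALSE, quote = FALSE)

  manifest <- list(
    package = "icountr",
    version = as.character(utils::packageVersion("icountr")),
    seed = seed,
    config = .config_as_list(config))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  summary <- list(
    seed = seed,
    n_cells = nrow(tree),
    n_recombined = nrow(recombined),
    n_excluded_undefined = cls$n_excluded,
    accuracy = list(n_events = acc$n_events, n_correct = acc$n_correct,
                    fraction_correct = acc$fraction_correct),
    predicted_histogram = as.list(cls$histograms$all$counts),
    truth_histogram = as.list(truth_hist$counts),
    tv_distance = dist$tv)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

.config_as_list <- function(config) {
  sc <- config$sim_config
  list(simulate = list(
         n_founders = sc$n_founders, cycle_time = sc$cycle_time,
         recombination_time = sc$recombination_time, flp_time = sc$flp_time,
         horizon = sc$horizon, exit_prob = sc$exit_prob,
         partition = sc$partition, pool_size = sc$pool_size,
         founder_pool = sc$founder_pool,
         recombined_fraction = sc$recombined_fraction),
       noise = unclass(sc$noise),
       normalize = list(n_ref = config$n_ref),
       infer = list(C = config$C))
}
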