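#' On-disk container for a participant recording
#'
#' A container is a directory holding the study design and unit layout as
#' JSON, a JSON metadata file (schema version, seed, ISF, stage
#' provenance, creation timestamp) and one serialized [trial_set()] per
#' session / block / segment class.  Round trips are lossless: arrays read
#' back bit-identical, and re-writing an unchanged container reproduces
#' identical files except for the timestamp field in `meta.json`.
#'
#' @param path directory to create (overwritten if it exists).
#' @param design a [study_design()].
#' @param layout a [unit_layout()].
#' @param trials nested list `trials[[session]][[block]][[segment]]` of
#'   [trial_set()] objects; segments must include `"baseline"` and
#'   `"post"`.
#' @param meta named list of metadata (e.g. `seed`, `isf`, `provenance`).
#' @return `path`, invisibly.
#' @export
write_container <- function(path, design, layout, trials, meta = list()) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  dj <- unclass(design)
  dj$train_durations <- as.list(dj$train_durations)  # keep block names
  jsonlite::write_json(dj, file.path(path, "design.json"),
                       auto_unbox = TRUE, digits = NA)
  edges <- which(layout$adjacency & upper.tri(layout$adjacency),
                 arr.ind = TRUE)
  jsonlite::write_json(
    list(unit_ids = layout$unit_ids,
         coordinates = unname(layout$coordinates),
         edges = unname(edges),
         region_labels = layout$region_labels),
    file.path(path, "layout.json"), auto_unbox = FALSE, digits = NA)
  meta$schema_version <- .container_schema
  meta$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (ses in names(trials)) for (blk in names(trials[[ses]])) {
    seg <- trials[[ses]][[blk]]
    if (!all(c("baseline", "post") %in% names(seg)))
      stop("container requires 'baseline' and 'post' segments for ",
           ses, "/", blk)
    for (cls in names(seg))
      saveRDS(seg[[cls]], file.path(path, paste(ses, blk, cls, "rds",
                                                sep = ".")), version = 3)
  }
  invisible(path)
}

.container_schema <- "tacsalpha-container-1"

#' @rdname write_container
#' @return `read_container()` returns a list with elements `design`,
#'   `layout`, `trials` and `meta`.
#' @export
read_container <- function(path) {
  meta_file <- file.path(path, "meta.json")
  if (!file.exists(meta_file)) stop("not a container: missing meta.json")
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  if (!identical(meta$schema_version, .container_schema))
    stop("container schema mismatch: expected '", .container_schema,
         "', found '", meta$schema_version, "'")
  design <- jsonlite::read_json(file.path(path, "design.json"),
                                simplifyVector = TRUE)
  design <- study_design(design$n_participants, design$trains_per_block,
                         unlist(design$train_durations),
                         design$interval_duration,
                         design$baseline_duration, design$sampling_rate)
  lj <- jsonlite::read_json(file.path(path, "layout.json"),
                            simplifyVector = TRUE)
  n <- length(lj$unit_ids)
  adj <- matrix(FALSE, n, n)
  if (length(lj$edges)) {
    e <- matrix(as.integer(unlist(lj$edges)), ncol = 2, byrow = FALSE)
    if (is.list(lj$edges[[1]]) || !is.matrix(lj$edges)) {
      e <- do.call(rbind, lapply(lj$edges, unlist))
    } else e <- lj$edges
    adj[cbind(e[, 1], e[, 2])] <- TRUE
    adj <- adj | t(adj)
  }
  layout <- unit_layout(do.call(rbind, lapply(seq_len(n), function(i)
    unlist(lj$coordinates[i, , drop = TRUE]))), adj,
    region_labels = if (length(lj$region_labels)) lj$region_labels,
    unit_ids = lj$unit_ids)

  files <- list.files(path, pattern = "\\.rds$")
  trials <- list()
  for (f in files) {
    parts <- strsplit(sub("\\.rds$", "", f), ".", fixed = TRUE)[[1]]
    trials[[parts[1]]][[parts[2]]][[parts[3]]] <-
      readRDS(file.path(path, f))
  }
  for (ses in names(trials)) for (blk in names(trials[[ses]]))
    if (!"baseline" %in% names(trials[[ses]][[blk]]))
      stop("container missing 'baseline' segment for ", ses, "/", blk)
  list(design = design, layout = layout, trials = trials, meta = meta)
}
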