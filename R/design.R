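#' Study design constants
#'
#' Describes one intermittent-stimulation experiment: per session and block,
#' a resting baseline is recorded, then `trains_per_block` stimulation
#' trains, each followed by a fixed stimulation-free interval.  Two sessions
#' (`tacs`, `control`) and two blocks (`train10`, `train30`) make up the
#' full design.
#'
#' @param n_participants number of participants in the cohort.
#' @param trains_per_block number of stimulation trains per block.
#' @param train_durations named numeric, seconds of stimulation per train
#'   for each block.
#' @param interval_duration seconds of stimulation-free interval after each
#'   train.
#' @param baseline_duration seconds of resting baseline preceding the first
#'   train.
#' @param sampling_rate sampling rate in Hz.
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_participants = 24L,
                         trains_per_block = 20L,
                         train_durations = c(train10 = 10, train30 = 30),
                         interval_duration = 15,
                         baseline_duration = 120,
                         sampling_rate = 1000) {
  stopifnot(n_participants >= 1, trains_per_block >= 1)
  if (any(c(train_durations, interval_duration, baseline_duration,
            sampling_rate) <= 0))
    stop("all durations and the sampling rate must be positive")
  if (is.null(names(train_durations)) || any(!nzchar(names(train_durations))))
    stop("'train_durations' must be named by block")
  structure(list(
    n_participants = as.integer(n_participants),
    sessions = c("tacs", "control"),
    blocks = names(train_durations),
    trains_per_block = as.integer(trains_per_block),
    train_durations = train_durations,
    interval_duration = interval_duration,
    baseline_duration = baseline_duration,
    sampling_rate = sampling_rate
  ), class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("<study_design> ", x$n_participants, " participants; ",
      x$trains_per_block, " trains/block (",
      paste(sprintf("%s=%gs", x$blocks, x$train_durations), collapse = ", "),
      "); interval ", x$interval_duration, " s; baseline ",
      x$baseline_duration, " s; fs ", x$sampling_rate, " Hz\n", sep = "")
  invisible(x)
}

#' Spatial layout of recording units
#'
#' A layout holds unit identifiers, coordinates, a symmetric irreflexive
#' adjacency relation and optional region labels
#' (`"somatosensory"`, `"frontal"`, `"other"`).
#'
#' @param coordinates numeric matrix, one row per unit (2 or 3 columns).
#' @param adjacency square logical/0-1 matrix; must be symmetric with an
#'   empty diagonal.
#' @param region_labels optional character vector, one label per unit.
#' @param unit_ids optional character ids; defaults to `u01`, `u02`, ...
#' @return An object of class `unit_layout`.
#' @export
unit_layout <- function(coordinates, adjacency, region_labels = NULL,
                        unit_ids = NULL) {
  coordinates <- as.matrix(coordinates)
  n <- nrow(coordinates)
  adjacency <- matrix(as.logical(adjacency), nrow(adjacency))
  if (nrow(adjacency) != n || ncol(adjacency) != n)
    stop("'adjacency' must be an n x n matrix matching the coordinates")
  if (!isTRUE(all(adjacency == t(adjacency))))
    stop("'adjacency' must be symmetric")
  if (any(diag(adjacency)))
    stop("'adjacency' must be irreflexive (empty diagonal)")
  if (!is.null(region_labels)) {
    if (length(region_labels) != n)
      stop("'region_labels' must cover all units")
    region_labels <- as.character(region_labels)
  }
  if (is.null(unit_ids))
    unit_ids <- sprintf("u%02d", seq_len(n))
  structure(list(unit_ids = unit_ids, coordinates = coordinates,
                 adjacency = adjacency, region_labels = region_labels),
            class = "unit_layout")
}

#' Rectangular lattice layout with 4-neighbour adjacency
#'
#' Units are placed on an `nrow` x `ncol` grid with rook (4-neighbour)
#' adjacency.  A contiguous 3 x 3 patch is labelled `"somatosensory"` and,
#' when the grid is wide enough, a second 3 x 3 patch is labelled
#' `"frontal"`; remaining units are `"other"`.  These patches are the
#' default carriers of simulated stimulation effects.
#'
#' @param nrow,ncol grid dimensions.
#' @param somato_anchor top-left (row, col) of the somatosensory patch, or
#'   `NULL` for no labels.
#' @param frontal_anchor top-left (row, col) of the frontal patch, or `NULL`
#'   to place it automatically (omitted when it does not fit).
#' @param patch integer patch side length.
#' @return A `unit_layout`.
#' @export
grid_layout <- function(nrow = 8L, ncol = 8L, somato_anchor = c(2L, 2L),
                        frontal_anchor = NULL, patch = 3L) {
  stopifnot(nrow >= 2, ncol >= 2)
  rc <- expand.grid(row = seq_len(nrow), col = seq_len(ncol))
  n <- nrow * ncol
  adj <- matrix(FALSE, n, n)
  d1 <- abs(outer(rc$row, rc$row, "-"))
  d2 <- abs(outer(rc$col, rc$col, "-"))
  adj[(d1 + d2) == 1] <- TRUE

  labels <- NULL
  patch_units <- function(anchor) {
    which(rc$row >= anchor[1] & rc$row < anchor[1] + patch &
          rc$col >= anchor[2] & rc$col < anchor[2] + patch)
  }
  if (!is.null(somato_anchor)) {
    labels <- rep("other", n)
    su <- patch_units(somato_anchor)
    if (length(su) < patch^2)
      stop("somatosensory patch does not fit on the grid")
    labels[su] <- "somatosensory"
    if (is.null(frontal_anchor) && ncol >= somato_anchor[2] + 2 * patch)
      frontal_anchor <- c(somato_anchor[1], ncol - patch + 1L)
    if (!is.null(frontal_anchor)) {
      fu <- patch_units(frontal_anchor)
      if (length(fu) < patch^2 || any(labels[fu] != "other"))
        stop("frontal patch does not fit on the grid")
      labels[fu] <- "frontal"
    }
  }
  unit_layout(cbind(x = rc$col, y = rc$row), adj, region_labels = labels)
}

#' Units carrying a region label
#' @param layout a `unit_layout`.
#' @param region label to select, e.g. `"somatosensory"`.
#' @return Integer unit indices.
#' @export
region_units <- function(layout, region = "somatosensory") {
  if (is.null(layout$region_labels)) stop("layout has no region labels")
  which(layout$region_labels == region)
}

#' @export
print.unit_layout <- function(x, ...) {
  cat("<unit_layout> ", length(x$unit_ids), " units, ",
      sum(x$adjacency) / 2, " edges", sep = "")
  if (!is.null(x$region_labels)) {
    tab <- table(x$region_labels)
    cat("; regions: ", paste(names(tab), tab, sep = "=", collapse = ", "),
        sep = "")
  }
  cat("\n")
  invisible(x)
}
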