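test_that("design and layout constructors enforce their invariants", {
  d <- study_design()
  expect_identical(d$trains_per_block, 20L)
  expect_error(study_design(sampling_rate = 0), "positive")
  expect_error(study_design(train_durations = c(10, 30)), "named")

  l <- grid_layout(4, 4)
  expect_true(all(l$adjacency == t(l$adjacency)))
  expect_false(any(diag(l$adjacency)))
  expect_equal(sum(l$adjacency) / 2, 2 * 4 * 3)  # rook edges on a 4x4 grid
  expect_length(l$region_labels, 16)
  expect_equal(sum(l$region_labels == "somatosensory"), 9)

  l8 <- grid_layout(8, 8)
  expect_equal(sum(l8$region_labels == "frontal"), 9)

  bad <- matrix(FALSE, 3, 3); bad[1, 2] <- TRUE
  expect_error(unit_layout(diag(3), bad), "symmetric")
  bad2 <- diag(TRUE, 3)
  expect_error(unit_layout(diag(3), bad2), "irreflexive")
})

test_that("segmentation reproduces the design arithmetic exactly", {
  design <- study_design()
  fs <- design$sampling_rate
  total <- block_duration(design, "train10")
  onsets <- train_onsets(design, "train10")
  # encode the absolute sample index so alignment can be verified
  continuous <- matrix(seq_len(total * fs), nrow = 1)

  segs <- segment_recording(continuous, design, onsets, "train10")
  base <- segs$baseline; post <- segs$post

  # 110 s retained baseline -> 20 epochs of 5.5 s = 5500 samples each
  expect_equal(n_trials(base), 20)
  expect_equal(dim(base$data)[1], 5500)
  expect_equal(diff(ts_time(base))[1], 1 / fs)
  # half-open windows: epoch j starts at sample 5500*(j-1)+1
  expect_equal(base$data[1, 1, 3], 2 * 5500 + 1)

  # post: trimmed window 4.2-9.7 s after train offset, 5500 samples
  expect_equal(n_trials(post), 20)
  expect_equal(dim(post$data)[1], 5500)
  expect_equal(range(ts_time(post)), c(4.2, 9.7 - 1 / fs))
  off1 <- onsets[1] + 10
  expect_equal(post$data[1, 1, 1], round((off1 + 4.2) * fs) + 1)

  # the untrimmed 3.8-10 s window is a 6.2 s epoch
  wide <- segment_recording(continuous, design, onsets, "train10",
                            post_trim = c(3.8, 10))
  expect_equal(dim(wide$post$data)[1], 6200)
})

test_that("segmentation trial counts are exact for randomized onsets", {
  design <- study_design()
  fs <- design$sampling_rate
  set.seed(11)
  for (rep in 1:5) {
    gaps <- runif(design$trains_per_block, 12, 18)
    onsets <- design$baseline_duration +
      cumsum(c(0, rep(10, design$trains_per_block - 1) + gaps[-1]))
    total <- max(onsets) + 10 + 15
    continuous <- matrix(0, nrow = 2, ncol = ceiling(total * fs))
    segs <- segment_recording(continuous, design, onsets, "train10")
    expect_equal(n_trials(segs$baseline), 20)
    expect_equal(n_trials(segs$post), 20)
  }
})

test_that("segmentation errors name the failing segment", {
  design <- study_design()
  short <- matrix(0, 1, 100 * design$sampling_rate)
  expect_error(
    segment_recording(short, design, train_onsets(design, "train10"),
                      "train10"),
    "baseline")
  total <- block_duration(design, "train10") * design$sampling_rate
  cont <- matrix(0, 1, total)
  expect_error(
    segment_recording(cont, design, rev(train_onsets(design, "train10")),
                      "train10"),
    "increasing")
  expect_error(
    segment_recording(cont, design,
                      train_onsets(design, "train10") + 1e5, "train10"),
    "outside")
  # last post window truncated -> error names the post segment
  expect_error(
    segment_recording(cont[, 1:(total - 8000), drop = FALSE], design,
                      train_onsets(design, "train10"), "train10"),
    "post")
})

test_that("artifact flagging matches a direct robust-z oracle", {
  set.seed(42)
  dat <- array(rnorm(400 * 3 * 10), c(400, 3, 10))
  ts <- trial_set(dat, 0, 100, "post")
  expect_equal(sum(flag_artifact_trials(ts, zmax = 8)$rejected), 0)

  spiked <- dat
  spiked[200, 2, 7] <- 50 * max(abs(dat))
  ts2 <- trial_set(spiked, 0, 100, "post")
  flagged <- flag_artifact_trials(ts2, zmax = 8)
  expect_identical(which(flagged$rejected), 7L)

  # oracle: pooled median/MAD z computed directly
  z <- abs(spiked - median(spiked)) / mad(spiked)
  expect_identical(which(apply(z, 3, max) > 8), 7L)

  expect_error(flag_artifact_trials(ts, zmax = 0.001), "no usable trials")
})

test_that("containers round-trip losslessly and validate their schema", {
  design <- small_design()
  layout <- grid_layout(3, 3, somato_anchor = c(1, 1))
  part <- generate_participant(design, layout,
                               effect_spec(seed = 5, isf = 9),
                               blocks = "train10")
  path <- file.path(tempdir(), "container-test")
  write_container(path, design, layout, part$sessions,
                  meta = list(seed = 5, isf = 9))
  back <- read_container(path)

  expect_identical(back$trials$tacs$train10$baseline$data,
                   part$sessions$tacs$train10$baseline$data)
  expect_identical(back$trials$control$train10$post$data,
                   part$sessions$control$train10$post$data)
  expect_equal(back$design$trains_per_block, design$trains_per_block)
  expect_identical(back$layout$adjacency, layout$adjacency)
  expect_identical(back$layout$region_labels, layout$region_labels)
  expect_equal(back$meta$isf, 9)

  # re-write: byte-stable except the timestamp field
  f1 <- file.path(path, "tacs.train10.baseline.rds")
  b1 <- readBin(f1, "raw", file.size(f1))
  write_container(path, design, layout, part$sessions,
                  meta = list(seed = 5, isf = 9))
  b2 <- readBin(f1, "raw", file.size(f1))
  expect_identical(b1, b2)

  # missing baseline group -> error naming it
  file.remove(file.path(path, "tacs.train10.baseline.rds"))
  expect_error(read_container(path), "baseline")

  # schema version mismatch -> error naming both versions
  meta <- jsonlite::read_json(file.path(path, "meta.json"))
  meta$schema_version <- "other-schema"
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE)
  expect_error(read_container(path), "tacsalpha-container-1.*other-schema")
  unlink(path, recursive = TRUE)
})
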