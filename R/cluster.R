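#' Baseline-relative power-change statistic (delta power)
#'
#' At every element (unit, frequency offset, time point) computes the
#' two-sample t statistic between post-stimulation trials and baseline
#' trials,
#' \deqn{\Delta = (\bar p_{post} - \bar p_{base}) / SE_{pooled}}
#' with the pooled standard error
#' \eqn{s_p \sqrt{1/n_1 + 1/n_2}}.  Baseline trial values are expected to
#' be time-averaged already (one value per trial), so when `post` has one
#' more dimension than `baseline` the extra dimension (the 2nd-to-last,
#' i.e. time) is broadcast.  The last dimension of both arrays indexes
#' trials.
#'
#' @param post numeric array with trials in the last dimension, e.g.
#'   `[unit, trial]` or `[offset, time, trial]`.
#' @param baseline numeric array with trials in the last dimension and the
#'   same leading dimensions as `post` minus, optionally, the time
#'   dimension.
#' @param var_type `"pooled"` (classic pooled variance) or `"welch"`.
#' @return Object of class `delta_power_map`: `values` shaped like `post`
#'   without the trial dimension, plus `n_post`, `n_base`.
#' @export
delta_power <- function(post, baseline, var_type = c("pooled", "welch")) {
  var_type <- match.arg(var_type)
  post <- as.array(post); baseline <- as.array(baseline)
  dp <- dim(post); db <- dim(baseline)
  n1 <- dp[length(dp)]; n2 <- db[length(db)]
  if (n1 < 2 || n2 < 2) stop("need at least 2 trials per class")
  shape1 <- dp[-length(dp)]; shape2 <- db[-length(db)]

  mom <- function(x, shape) {
    n <- length(x) / prod(shape)
    m <- matrix(x, prod(shape), n)
    mu <- rowMeans(m)
    v <- rowSums((m - mu)^2) / (n - 1)
    list(mu = mu, v = v)
  }
  m1 <- mom(post, shape1); m2 <- mom(baseline, shape2)

  if (length(shape1) == length(shape2) + 1) {
    # broadcast baseline over the time dimension (2nd-to-last of post)
    tdim <- length(shape1)
    if (!identical(unname(shape1[-tdim]), unname(shape2)))
      stop("baseline dimensions do not match post dimensions")
    rep_each <- function(z) rep(z, times = shape1[tdim])
    m2 <- list(mu = rep_each(m2$mu), v = rep_each(m2$v))
  } else if (!identical(unname(shape1), unname(shape2))) {
    stop("baseline dimensions do not match post dimensions")
  }

  if (var_type == "pooled") {
    sp2 <- ((n1 - 1) * m1$v + (n2 - 1) * m2$v) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    se <- sqrt(m1$v / n1 + m2$v / n2)
  }
  diff <- m1$mu - m2$mu
  tval <- rep(NA_real_, length(diff))
  ok <- is.finite(se) & is.finite(diff)
  zero <- ok & se == 0
  if (any(zero & diff != 0))
    stop("degenerate variance: zero pooled variance with unequal means")
  tval[zero] <- 0
  good <- ok & !zero
  tval[good] <- diff[good] / se[good]
  values <- array(tval, shape1)
  structure(list(values = values, n_post = n1, n_base = n2,
                 var_type = var_type), class = "delta_power_map")
}

#' Pool the two stimulation blocks of a participant
#'
#' Element-wise average of the two blocks' delta-power maps, keeping one
#' map per participant as the group-level paired test requires.
#'
#' @param map10,map30 `delta_power_map` objects (or plain arrays) on
#'   identical axes.
#' @return A `delta_power_map` (or array) of the same shape.
#' @export
pool_blocks <- function(map10, map30) {
  v1 <- if (inherits(map10, "delta_power_map")) map10$values else map10
  v2 <- if (inherits(map30, "delta_power_map")) map30$values else map30
  if (!identical(dim(as.array(v1)), dim(as.array(v2))))
    stop("block maps have mismatching axes")
  out <- (v1 + v2) / 2
  if (inherits(map10, "delta_power_map")) {
    map10$values <- out
    map10$block <- "pooled"
    map10
  } else out
}

#' 4-neighbour adjacency of a rectangular grid of elements
#'
#' Builds the adjacency matrix for elements of a 2-d grid (e.g. frequency
#' offset x time, or modulation frequency x carrier frequency) in
#' column-major flattening order, connecting horizontal and vertical
#' neighbours.
#'
#' @param dims integer vector `c(nrow, ncol)`.
#' @return Logical adjacency matrix of size `prod(dims)`.
#' @export
grid_adjacency <- function(dims) {
  stopifnot(length(dims) == 2)
  idx <- expand.grid(r = seq_len(dims[1]), c = seq_len(dims[2]))
  d <- abs(outer(idx$r, idx$r, "-")) + abs(outer(idx$c, idx$c, "-"))
  m <- d == 1
  diag(m) <- FALSE
  m
}

# connected components of `members` (integer indices) under adjacency
# list `nbrs`; returns list of integer vectors
.components <- function(members, nbrs) {
  if (length(members) == 0) return(list())
  inset <- logical(length(nbrs))
  inset[members] <- TRUE
  seen <- logical(length(nbrs))
  comps <- list()
  for (m in members) {
    if (seen[m]) next
    comp <- integer(0)
    stack <- m
    seen[m] <- TRUE
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      comp <- c(comp, v)
      nb <- nbrs[[v]]
      nb <- nb[inset[nb] & !seen[nb]]
      seen[nb] <- TRUE
      stack <- c(stack, nb)
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}

# suprathreshold clusters of a t vector: list(members, mass, sign)
.form_clusters <- function(tvec, tcrit, nbrs, min_size) {
  out <- list()
  for (s in c(1, -1)) {
    members <- which(s * tvec > tcrit)
    for (comp in .components(members, nbrs)) {
      if (length(comp) < min_size) next
      out[[length(out) + 1]] <-
        list(members = comp, mass = sum(tvec[comp]), sign = s)
    }
  }
  out
}

#' Specification of a cluster-based permutation test
#'
#' @param alpha_form cluster-forming threshold probability (two-tailed).
#' @param min_size minimum number of mutually connected suprathreshold
#'   elements for a candidate cluster.
#' @param n_permutations number of random condition permutations; when
#'   `2^n_participants <= n_permutations` the full sign-flip enumeration
#'   is used instead.
#' @param seed RNG seed for the permutations (recorded in the result).
#' @return A list of class `cluster_test_spec`.
#' @export
cluster_test_spec <- function(alpha_form = 0.05, min_size = 2L,
                              n_permutations = 1000L, seed = 1L) {
  stopifnot(alpha_form > 0, alpha_form < 1, n_permutations >= 1,
            min_size >= 1)
  structure(list(alpha_form = alpha_form, min_size = as.integer(min_size),
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "cluster_test_spec")
}

#' Group-level cluster-based permutation test (paired, two conditions)
#'
#' At every element, a paired t statistic across participants contrasts
#' the two conditions.  Elements exceeding the two-tailed critical value
#' at `alpha_form` are grouped into clusters of connected elements under
#' the supplied adjacency (positive and negative excursions separately);
#' each cluster's statistic is the sum of its member t values.  The null
#' distribution is built by randomly swapping the condition assignment
#' within participants (sign flips of the paired differences), retaining
#' the maximum absolute cluster sum of every permutation.  Cluster p
#' values use the `(1 + k) / (n_perm + 1)` estimator; when
#' `2^n <= n_permutations` all `2^n` sign assignments are enumerated and p
#' is the exact proportion.
#'
#' @param tacs,control lists (one element per participant) of numeric
#'   arrays on identical axes, or matrices `[participant, element]`.
#' @param spec a [cluster_test_spec()].
#' @param adjacency logical adjacency matrix over flattened elements
#'   (e.g. a layout's unit adjacency, or [grid_adjacency()]).
#' @return Object of class `cluster_test`: `clusters` (list of
#'   `members`, `mass`, `sign`, `p`), `t_obs`, `perm_max`, `exhaustive`,
#'   `spec`.
#' @export
cluster_permutation_test <- function(tacs, control, spec, adjacency) {
  stopifnot(inherits(spec, "cluster_test_spec"))
  as_mat <- function(x) {
    if (is.list(x)) t(vapply(x, function(a) as.numeric(a),
                             numeric(length(as.numeric(x[[1]])))))
    else as.matrix(x)
  }
  A <- as_mat(tacs); B <- as_mat(control)
  template_dim <- if (is.list(tacs) && !is.null(dim(tacs[[1]])))
    dim(tacs[[1]]) else NULL
  if (!all(dim(A) == dim(B)))
    stop("'tacs' and 'control' must have identical shapes")
  n <- nrow(A); E <- ncol(A)
  if (n < 2) stop("need at least 2 participants")
  adjacency <- adjacency & !diag(TRUE, nrow(adjacency))
  if (nrow(adjacency) != E || !any(adjacency))
    stop("empty or mismatching adjacency")
  nbrs <- apply(adjacency, 1, which, simplify = FALSE)

  D <- A - B                                  # n x E paired differences
  ss <- colSums(D^2)
  tcrit <- qt(1 - spec$alpha_form / 2, df = n - 1)
  t_of <- function(signs_mat) {
    # paired t for each row of sign assignments; sign flips leave sum of
    # squares invariant, so only the mean changes
    M <- signs_mat %*% D / n                  # P x E means
    V <- sweep(-n * M^2, 2, ss, "+") / (n - 1)
    V[V < 0] <- 0
    Tm <- M / sqrt(V / n)
    Tm[!is.finite(Tm)] <- 0
    Tm
  }
  t_obs <- drop(t_of(matrix(1, 1, n)))
  clusters <- .form_clusters(t_obs, tcrit, nbrs, spec$min_size)

  exhaustive <- 2^n <= spec$n_permutations
  S <- if (exhaustive) {
    as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  } else {
    withr::with_seed(spec$seed,
      matrix(sample(c(1, -1), spec$n_permutations * n, replace = TRUE),
             ncol = n))
  }
  Tperm <- t_of(S)
  perm_max <- vapply(seq_len(nrow(S)), function(j) {
    cl <- .form_clusters(Tperm[j, ], tcrit, nbrs, spec$min_size)
    if (length(cl) == 0) 0 else max(abs(vapply(cl, `[[`, 0, "mass")))
  }, 0)

  for (i in seq_along(clusters)) {
    k <- sum(perm_max >= abs(clusters[[i]]$mass))
    clusters[[i]]$p <- if (exhaustive) k / nrow(S)
                       else (1 + k) / (spec$n_permutations + 1)
  }
  ord <- order(vapply(clusters, function(c) -abs(c$mass), 0))
  if (!is.null(template_dim)) dim(t_obs) <- template_dim
  structure(list(clusters = clusters[ord], t_obs = t_obs,
                 perm_max = perm_max, exhaustive = exhaustive,
                 n_participants = n, spec = spec),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat("<cluster_test> ", length(x$clusters), " cluster(s); ",
      if (x$exhaustive) "exhaustive enumeration"
      else paste0(x$spec$n_permutations, " permutations"),
      ", n = ", x$n_participants, "\n", sep = "")
  for (cl in x$clusters)
    cat(sprintf("  %s cluster: %d elements, sum t = %.3f, p = %.4g\n",
                if (cl$sign > 0) "positive" else "negative",
                length(cl$members), cl$mass, cl$p))
  invisible(x)
}

#' Significant clusters of a test result
#' @param x a `cluster_test`.
#' @param alpha significance level.
#' @return The sublist of clusters with `p < alpha`.
#' @export
significant_clusters <- function(x, alpha = 0.05) {
  Filter(function(cl) cl$p < alpha, x$clusters)
}

#' Region-wise time-frequency cluster tests within a spatial cluster
#'
#' Splits a significant spatial cluster into its region counterparts
#' (e.g. somatosensory and frontal), averages the participants'
#' time-frequency delta-power maps over the cluster units of each region,
#' and runs the time-frequency cluster permutation test per region.
#'
#' @param cluster_units integer unit indices of the significant spatial
#'   cluster.
#' @param region_labels character region label per unit.
#' @param tacs_tf,control_tf lists per participant of arrays
#'   `[offset, time, unit]` of delta power.
#' @param spec a [cluster_test_spec()].
#' @param regions region labels to test.
#' @return Named list of `cluster_test` objects.
#' @export
region_split_test <- function(cluster_units, region_labels, tacs_tf,
                              control_tf, spec,
                              regions = c("somatosensory", "frontal")) {
  out <- list()
  for (reg in regions) {
    units <- intersect(cluster_units, which(region_labels == reg))
    if (length(units) == 0)
      stop("cluster does not intersect region '", reg, "'")
    avg <- function(maps) lapply(maps, function(a)
      apply(a[, , units, drop = FALSE], c(1, 2), mean))
    g <- avg(tacs_tf)[[1]]
    adj <- grid_adjacency(dim(g))
    out[[reg]] <- cluster_permutation_test(avg(tacs_tf), avg(control_tf),
                                           spec, adj)
  }
  out
}

#' Train-duration contrast within the significant cluster
#'
#' For each block, computes the group-level paired t value (tACS vs
#' control across participants) at every unit of the significant spatial
#' cluster, then compares the two blocks' sets of cluster t values with
#' the Wilcoxon rank-sum test.
#'
#' @param cluster_units integer unit indices of the cluster (>= 2).
#' @param maps nested list `maps[[block]]$tacs` / `$control`, each a list
#'   per participant of spatial delta-power vectors.
#' @return List with the rank-sum `statistic`, `p`, and the per-block t
#'   values (`t_values`).
#' @export
block_contrast <- function(cluster_units, maps) {
  if (length(cluster_units) < 2)
    stop("cluster has fewer than 2 elements")
  tvals <- lapply(maps, function(m) {
    D <- t(vapply(seq_along(m$tacs), function(i)
      as.numeric(m$tacs[[i]])[cluster_units] -
        as.numeric(m$control[[i]])[cluster_units],
      numeric(length(cluster_units))))
    n <- nrow(D)
    mu <- colMeans(D)
    se <- sqrt(apply(D, 2, var) / n)
    mu / se
  })
  wt <- suppressWarnings(wilcox.test(tvals[[1]], tvals[[2]]))
  list(statistic = unname(wt$statistic), p = wt$p.value, t_values = tvals,
       blocks = names(maps))
}
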