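#' Cluster phenotypes into species
#'
#' Species delimitation as in the individual-based accounting rule: two
#' points belong to the same species when they are connected by a chain of
#' pairwise distances below `delta` (connected components of the
#' threshold graph, equivalent to single-linkage clustering cut at `delta`).
#'
#' @param points matrix of phenotypes (one per row) or a vector for a single
#'   point.
#' @param delta positive linkage distance (trait units).
#' @return an object of class `cluster_report`: list with `labels` (cluster
#'   id per point, in first-appearance order), `count`, `centroids`
#'   (unweighted mean phenotype per cluster), `sizes` and `linkage_delta`.
#' @examples
#' cluster_species(rbind(c(0, 0), c(0.01, 0), c(1, 1)), delta = 0.1)$count
#' @export
cluster_species <- function(points, delta) {
  stopifnot(delta > 0)
  if (is.null(dim(points))) points <- matrix(points, nrow = 1L)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (nrow(points) == 0L)
    return(structure(list(labels = integer(0), count = 0L,
                          centroids = points, sizes = integer(0),
                          linkage_delta = delta), class = "cluster_report"))
  lab <- cpp_cluster_labels(points, delta)
  k <- max(lab)
  cen <- matrix(0, k, ncol(points))
  sizes <- integer(k)
  for (c in seq_len(k)) {
    idx <- which(lab == c)
    sizes[c] <- length(idx)
    cen[c, ] <- colMeans(points[idx, , drop = FALSE])
  }
  structure(list(labels = lab, count = k, centroids = cen, sizes = sizes,
                 linkage_delta = delta), class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat("<cluster_report> ", x$count, " clusters at delta = ",
      x$linkage_delta, "\n", sep = "")
  invisible(x)
}

# snapshot times + phenotype matrices from either trajectory class
trajectory_snapshots <- function(trajectory) {
  if (inherits(trajectory, "ad_trajectory")) {
    list(times = vapply(trajectory$snapshots, `[[`, 0, "time"),
         points = lapply(trajectory$snapshots,
                         function(s) s$community$phenotypes))
  } else if (inherits(trajectory, "ibm_trajectory")) {
    list(times = trajectory$snapshot_times, points = trajectory$snapshots)
  } else if (is.list(trajectory) && !is.null(trajectory$points)) {
    trajectory
  } else stop("unsupported trajectory object")
}

#' Species-diversity time series with rolling-median smoothing
#'
#' Clustered species count per snapshot plus a trailing rolling median over
#' `window` snapshots, the convention used to report a final cluster count
#' robust to demographic noise.
#'
#' @param trajectory an `ad_trajectory`, `ibm_trajectory`, or a list with
#'   `times` and `points` (list of phenotype matrices).
#' @param delta clustering distance.
#' @param window rolling-median window length in snapshots.
#' @return data frame with `time`, `count` and `smoothed`.
#' @export
diversity_timeseries <- function(trajectory, delta, window = 200L) {
  sn <- trajectory_snapshots(trajectory)
  count <- vapply(sn$points, function(p) cluster_species(p, delta)$count, 0L)
  n <- length(count)
  smoothed <- vapply(seq_len(n), function(i)
    median(count[max(1L, i - window + 1L):i]), 0)
  data.frame(time = sn$times, count = count, smoothed = smoothed)
}

#' Invasion-fitness landscape over trait space
#'
#' Evaluates the community invasion fitness on a regular grid.  Over a
#' saturated evolutionarily stable community the maximum stays at (numerical)
#' zero everywhere; positive regions mark trait space open to invasion.
#'
#' @param community an equilibrated [community()] object.
#' @param model a [model_params()] object.
#' @param n grid nodes per axis.
#' @param box per-axis interval.
#' @param abundances optional abundance override.
#' @return an object of class `fitness_landscape`: list with `x`, `y`,
#'   `fitness` (n x n matrix, rows indexing x), `max`, `argmax`.
#' @export
fitness_landscape <- function(community, model, n = 81L, box = c(-2, 2),
                              abundances = NULL) {
  if (model$d != 2L) stop("landscapes are implemented for d = 2")
  x <- seq(box[1], box[2], length.out = n)
  grid <- cbind(rep(x, times = n), rep(x, each = n))
  f <- invasion_fitness_community(community, grid, model,
                                  abundances = abundances)
  Fm <- matrix(f, n, n)
  i <- which.max(Fm)
  structure(list(x = x, y = x, fitness = Fm, max = max(Fm),
                 argmax = grid[i, ]), class = "fitness_landscape")
}

#' @export
print.fitness_landscape <- function(x, ...) {
  cat("<fitness_landscape> max invasion fitness ", signif(x$max, 4),
      " at (", signif(x$argmax[1], 3), ", ", signif(x$argmax[2], 3), ")\n",
      sep = "")
  invisible(x)
}

# symmetric Hausdorff distance between two point sets (rows)
hausdorff_distance <- function(A, B) {
  if (nrow(A) == 0L || nrow(B) == 0L) return(Inf)
  D <- sqrt(outer(rowSums(A^2), rep(1, nrow(B))) +
            outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B))
  D[!is.finite(D) | D < 0] <- 0
  max(max(apply(D, 1, min)), max(apply(D, 2, min)))
}

# greedy global nearest-neighbour matching of rows of `to` onto rows of
# `from` (equal counts); returns permutation p with to[p[i],] tracking from[i,]
greedy_match <- function(from, to) {
  k <- nrow(from)
  D <- as.matrix(dist(rbind(from, to)))[seq_len(k), k + seq_len(k),
                                        drop = FALSE]
  p <- integer(k)
  for (s in seq_len(k)) {
    i <- which(D == min(D), arr.ind = TRUE)[1, ]
    p[i[1]] <- i[2]
    D[i[1], ] <- Inf
    D[, i[2]] <- Inf
  }
  p
}

#' Detect a phenotypic limit cycle (Red Queen dynamics)
#'
#' Tracks species-cluster centroids through a window of equally spaced
#' snapshots by greedy nearest-neighbour identity linking, then tests each
#' tracked centroid for persistent rotation about its time-averaged position:
#' the winding angle must grow monotonically and the centroid displacement
#' autocorrelation must show a repeated peak.  The period is the mean
#' autocorrelation peak spacing; the direction follows the winding sign
#' (counterclockwise positive).
#'
#' @param trajectory an `ad_trajectory` (or snapshot list, see
#'   [diversity_timeseries()]) whose window covers at least about three
#'   putative periods.
#' @param delta clustering distance for centroid extraction.
#' @param min_turns minimum accumulated turns for a centroid to count as
#'   cycling.
#' @param min_amplitude minimum mean orbit radius (trait units); smaller
#'   excursions are treated as stationary jitter.
#' @return an object of class `cycle_report`: list with `is_cyclic`,
#'   `period` (or NULL), `direction` ("clockwise", "counterclockwise",
#'   "mixed" or "none"), `amplitude` (per tracked cluster) and `n_tracked`.
#' @export
detect_limit_cycle <- function(trajectory, delta = 0.05, min_turns = 1.5,
                               min_amplitude = 0.05) {
  sn <- trajectory_snapshots(trajectory)
  times <- sn$times
  cens <- lapply(sn$points, function(p) cluster_species(p, delta)$centroids)
  counts <- vapply(cens, nrow, 0L)
  k <- counts[length(counts)]
  run <- rev(cumprod(rev(counts == k)))  # longest suffix at constant count
  keep <- which(run == 1)
  none <- list(is_cyclic = FALSE, period = NULL, direction = "none",
               amplitude = numeric(0), n_tracked = 0L)
  class(none) <- "cycle_report"
  if (length(keep) < 8L || k == 0L) return(none)
  times <- times[keep]; cens <- cens[keep]
  nt <- length(keep)

  # identity linking with a max-jump guard of 3x the median step displacement
  paths <- array(NA_real_, c(nt, k, 2))
  paths[1, , ] <- cens[[1]]
  pmat <- function(s) matrix(paths[s, , ], nrow = k)
  steps <- numeric(0)
  for (s in 2:nt) {
    p <- greedy_match(pmat(s - 1), cens[[s]])
    paths[s, , ] <- cens[[s]][p, , drop = FALSE]
    steps <- c(steps, sqrt(rowSums((pmat(s) - pmat(s - 1))^2)))
  }
  jump_bound <- 3 * median(steps)
  if (max(steps) > jump_bound && median(steps) > 0) {
    warning("centroid identity linking ambiguous (jump ",
            signif(max(steps), 3), " > bound ", signif(jump_bound, 3), ")")
    none$direction <- "mixed"
    return(none)
  }

  dt <- median(diff(times))
  windings <- numeric(k); periods <- numeric(0); amp <- numeric(k)
  cyc_dirs <- integer(0)
  for (c in seq_len(k)) {
    xy <- paths[, c, ]
    ctr <- colMeans(xy)
    rel <- sweep(xy, 2, ctr)
    amp[c] <- mean(sqrt(rowSums(rel^2)))
    if (amp[c] < min_amplitude) next
    th <- atan2(rel[, 2], rel[, 1])
    dth <- diff(th)
    dth <- ((dth + pi) %% (2 * pi)) - pi  # unwrap
    tot <- sum(dth)
    windings[c] <- tot / (2 * pi)
    monotone <- mean(sign(dth) == sign(tot)) >= 0.9
    if (!monotone || abs(tot) < min_turns * 2 * pi) next
    # displacement autocorrelation peak spacing
    x <- rel[, 1]
    a <- acf(x, lag.max = nt - 2L, plot = FALSE)$acf[, 1, 1]
    pk <- which(diff(sign(diff(a))) == -2) + 1L   # interior local maxima
    pk <- pk[a[pk] > 0.2]
    if (length(pk) == 0L) next
    lags <- (pk - 1L)
    spacing <- if (length(lags) > 1L) mean(diff(lags)) else lags[1]
    periods <- c(periods, spacing * dt)
    cyc_dirs <- c(cyc_dirs, sign(tot))
  }
  if (length(periods) == 0L) return(none)
  direction <- if (all(cyc_dirs > 0)) "counterclockwise"
    else if (all(cyc_dirs < 0)) "clockwise" else "mixed"
  structure(list(is_cyclic = TRUE, period = mean(periods),
                 direction = direction, amplitude = amp, n_tracked = k),
            class = "cycle_report")
}

#' @export
print.cycle_report <- function(x, ...) {
  if (x$is_cyclic)
    cat("<cycle_report> cyclic, period ", signif(x$period, 4), ", ",
        x$direction, "\n", sep = "")
  else cat("<cycle_report> not cyclic (", x$direction, ")\n", sep = "")
  invisible(x)
}

#' Probe the metastability of a community
#'
#' Perturbs every phenotype by independent Gaussian offsets of scale
#' `perturbation_scale`, runs the mutation-free canonical flow for
#' `probe_time`, and declares the state "returned" when the Hausdorff
#' distance between the final configuration and the reference (minimized
#' over cycle phase when the reference is a snapshot list) falls below
#' `tol`.  Exit from a metastable state requires perturbations significantly
#' larger than those that formed it.
#'
#' @param community the putative metastable [community()].
#' @param perturbation_scale Gaussian perturbation scale (trait units).
#' @param model a [model_params()] object.
#' @param probe_time canonical-flow time of the probe.
#' @param reference reference configuration(s): a community or list of
#'   communities (e.g. snapshots around one cycle); defaults to the
#'   unperturbed community.
#' @param tol return tolerance on the Hausdorff distance.
#' @param n_checkpoints number of distance-trace checkpoints.
#' @param kappa canonical rate constant.
#' @return list with `returned` (logical), `distance` (final), `trace`
#'   (data frame time/distance) and `final` community.
#' @export
metastability_probe <- function(community, perturbation_scale, model,
                                probe_time, reference = NULL, tol = 0.05,
                                n_checkpoints = 20L, kappa = 1) {
  if (is.null(reference)) reference <- list(community)
  if (inherits(reference, "community")) reference <- list(reference)
  refZ <- lapply(reference, `[[`, "phenotypes")
  Z <- community$phenotypes +
    matrix(rnorm(length(community$phenotypes), 0, perturbation_scale),
           nrow = nrow(community$phenotypes))
  co <- community(Z, community$abundances, community$labels)
  dist_to_ref <- function(co)
    min(vapply(refZ, hausdorff_distance, 0, A = co$phenotypes))
  tt <- numeric(n_checkpoints); dd <- numeric(n_checkpoints)
  chunk <- probe_time / n_checkpoints
  for (i in seq_len(n_checkpoints)) {
    co <- canonical_step(co, chunk, model, kappa = kappa)
    tt[i] <- i * chunk
    dd[i] <- dist_to_ref(co)
  }
  list(returned = dd[n_checkpoints] < tol, distance = dd[n_checkpoints],
       trace = data.frame(time = tt, distance = dd), final = co)
}
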