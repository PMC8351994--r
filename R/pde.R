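#' Density field over a trait-space grid
#'
#' State of the deterministic density formulation: a nonnegative density
#' (per unit trait area) on a regular n x n lattice over \eqn{[-L, L]^2},
#' evolved by logistic growth with nonlocal competition plus mutation
#' diffusion.
#'
#' @param n nodes per axis.
#' @param L half-width of the domain (trait units); the viable region decays
#'   well before the default boundary, so no-flux boundaries are used.
#' @param diffusion mutation-diffusion coefficient D (trait units^2 / time).
#' @param values optional n x n matrix of initial densities (default 0).
#' @param noise_floor densities below this are truncated to 0 each step,
#'   preventing the infinite-tail artifact that makes continuous models
#'   branch everywhere.  Default `1e-12 * max(values)` (0 if empty field).
#' @return an object of class `density_field`.
#' @export
density_field <- function(n = 64L, L = 2.5, diffusion = 1e-3, values = NULL,
                          noise_floor = NULL) {
  n <- as.integer(n)
  stopifnot(n >= 4L, n <= 96L, L > 0, diffusion >= 0)
  x <- seq(-L, L, length.out = n)
  if (is.null(values)) values <- matrix(0, n, n)
  values <- as.matrix(values)
  stopifnot(all(dim(values) == n), all(is.finite(values)), all(values >= 0))
  if (is.null(noise_floor)) noise_floor <- 1e-12 * max(values, 0)
  structure(list(x = x, values = values, n = n, L = L,
                 h = x[2] - x[1], diffusion = diffusion,
                 noise_floor = noise_floor, time = 0),
            class = "density_field")
}

#' Gaussian blob initial condition for the density field
#'
#' @param field a [density_field()].
#' @param center blob center (length-2).
#' @param width Gaussian width (trait units).
#' @param mass total integrated density.
#' @return the field with the blob added.
#' @export
field_gaussian_blob <- function(field, center = c(0, 0), width = 0.2,
                                mass = 1) {
  g1 <- exp(-(field$x - center[1])^2 / (2 * width^2))
  g2 <- exp(-(field$x - center[2])^2 / (2 * width^2))
  blob <- outer(g1, g2)
  blob <- blob * mass / (sum(blob) * field$h^2)
  field$values <- field$values + blob
  if (field$noise_floor == 0)
    field$noise_floor <- 1e-12 * max(field$values)
  field
}

# grid nodes as an (n^2) x 2 phenotype matrix, row-major in the first axis
field_nodes <- function(field) {
  cbind(rep(field$x, times = field$n), rep(field$x, each = field$n))
}

# precomputed dense operator: competition quadrature matrix (cell area folded
# in) and carrying capacity at the nodes
pde_operator <- function(field, model) {
  if (model$d != 2L) stop("the density formulation is implemented for d = 2")
  nodes <- field_nodes(field)
  W <- cpp_interaction_matrix(nodes, model$sigma_alpha, model$b,
                              model$printed_form) * field$h^2
  K <- exp(drop(cpp_log_K(nodes, k_kind(model))))
  list(W = W, K = K)
}

# 5-point Laplacian with no-flux (reflecting) boundaries
laplacian_neumann <- function(U, h) {
  n <- nrow(U)
  up    <- U[c(1, seq_len(n - 1)), ]
  down  <- U[c(seq_len(n - 1) + 1, n), ]
  left  <- U[, c(1, seq_len(n - 1))]
  right <- U[, c(seq_len(n - 1) + 1, n)]
  (up + down + left + right - 4 * U) / h^2
}

pde_max_dt <- function(field, model) {
  dt_diff <- if (field$diffusion > 0) field$h^2 / (4 * field$diffusion) else Inf
  min(dt_diff, 0.25 / model$r)
}

#' One explicit time step of the density dynamics
#'
#' Advances \eqn{\partial u/\partial t = r u (1 - (\alpha * u)/K) + D
#' \nabla^2 u}, with the nonlocal competition integral evaluated by
#' rectangle-rule quadrature over the grid, forward-Euler in time, no-flux
#' boundaries, nonnegativity clamping and noise-floor truncation.
#'
#' @param field a [density_field()].
#' @param dt time step; must respect the explicit stability bound (the error
#'   message reports the admissible step).
#' @param model a [model_params()] object.
#' @param op precomputed operator from an earlier step (built on the fly if
#'   missing; reuse it across steps, it is the expensive part).
#' @return the advanced field (operator attached as attribute `"op"`).
#' @export
step_pde <- function(field, dt, model, op = NULL) {
  dt_max <- pde_max_dt(field, model)
  if (dt > dt_max)
    stop("dt = ", dt, " violates the explicit stability bound; use dt <= ",
         signif(dt_max, 4))
  if (is.null(op)) op <- attr(field, "op")
  if (is.null(op)) op <- pde_operator(field, model)
  u <- as.vector(field$values)
  load <- drop(op$W %*% u) / op$K
  du <- model$r * u * (1 - load)
  U <- field$values + dt * (matrix(du, field$n, field$n) +
    field$diffusion * laplacian_neumann(field$values, field$h))
  U[U < 0] <- 0
  U[U < field$noise_floor] <- 0
  field$values <- U
  field$time <- field$time + dt
  attr(field, "op") <- op
  field
}

#' Local density peaks of a field
#'
#' Strict local maxima over the 8-neighborhood exceeding
#' `rel_threshold * max(u)`, clustered (single linkage at `delta`) so a
#' plateau straddling a few nodes counts once.
#'
#' @param field a [density_field()].
#' @param rel_threshold relative height cutoff.
#' @param delta clustering distance; default 2.5 grid spacings.
#' @return list with `count` and `positions` (matrix of peak coordinates).
#' @export
pde_peaks <- function(field, rel_threshold = 1e-3, delta = NULL) {
  U <- field$values
  n <- field$n
  if (max(U) <= 0) return(list(count = 0L, positions = matrix(0, 0, 2)))
  if (is.null(delta)) delta <- 2.5 * field$h
  pad <- matrix(-Inf, n + 2, n + 2)
  pad[2:(n + 1), 2:(n + 1)] <- U
  is_peak <- matrix(TRUE, n, n)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nb <- pad[2:(n + 1) + di, 2:(n + 1) + dj]
    is_peak <- is_peak & (U >= nb)
  }
  is_peak <- is_peak & (U > rel_threshold * max(U))
  idx <- which(is_peak, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(list(count = 0L, positions = matrix(0, 0, 2)))
  pos <- cbind(field$x[idx[, 1]], field$x[idx[, 2]])
  cl <- cluster_species(pos, delta)
  list(count = cl$count, positions = cl$centroids)
}

#' Run the density-formulation simulation
#'
#' Time-steps the reaction-diffusion dynamics to `t_end`, recording snapshot
#' fields at a fixed cadence and reporting the clustered local maxima of the
#' final field as the species count.
#'
#' @param model a [model_params()] object.
#' @param field0 initial [density_field()].
#' @param t_end end time.
#' @param dt time step; default 90% of the stability bound.
#' @param snap_every snapshot cadence in time units; default `t_end / 20`.
#' @return an object of class `pde_trajectory`: list with `times`, `fields`
#'   (snapshot value matrices), `final` field, `peaks` (of the final field),
#'   `model`.
#' @export
run_pde <- function(model, field0, t_end, dt = NULL, snap_every = NULL) {
  if (is.null(dt)) dt <- 0.9 * pde_max_dt(field0, model)
  if (is.null(snap_every)) snap_every <- t_end / 20
  op <- pde_operator(field0, model)
  field <- field0
  mass0 <- sum(field$values) * field$h^2
  times <- numeric(); fields <- list()
  next_snap <- snap_every
  while (field$time < t_end - 1e-9) {
    step <- min(dt, t_end - field$time, next_snap - field$time)
    field <- step_pde(field, step, model, op = op)
    mass <- sum(field$values) * field$h^2
    if (!is.finite(mass) || mass > 1e6 * max(mass0, 1))
      stop("density diverged at t = ", signif(field$time, 5))
    if (field$time >= next_snap - 1e-9) {
      times[length(times) + 1L] <- field$time
      fields[[length(fields) + 1L]] <- field$values
      next_snap <- next_snap + snap_every
    }
  }
  structure(list(times = times, fields = fields, final = field,
                 peaks = pde_peaks(field), model = model),
            class = "pde_trajectory")
}

#' @export
print.pde_trajectory <- function(x, ...) {
  cat("<pde_trajectory> t = ", signif(x$final$time, 5), ", ",
      x$peaks$count, " density peaks\n", sep = "")
  invisible(x)
}
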