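#' Configuration for an adaptive-dynamics run
#'
#' Tuning knobs for the quasi-deterministic evolutionary engine: the
#' canonical-equation trait flow is deterministic, while branching (mutant
#' proposal and admission) is stochastic.
#'
#' @param eps_mut fixed branching offset (trait units): a proposed mutant sits
#'   exactly this far from its parent, in a uniformly random direction.
#' @param sigma_mut Gaussian branching scale; 0 (default) selects fixed-offset
#'   mode, a positive value draws per-axis Gaussian offsets of this scale
#'   instead and must be at least `eps_mut`.
#' @param delta_merge merge distance: species closer than this are collapsed
#'   (transitively) into one.  Must be smaller than `eps_mut` so merging
#'   cannot instantly undo a branching event.
#' @param min_viable extinction threshold, and the abundance at which an
#'   admitted mutant enters.
#' @param epoch_time evolutionary time of canonical flow per mutation attempt.
#' @param n_attempts mutation-attempt budget.
#' @param kappa canonical-equation rate constant (absorbs the mutation rate
#'   and variance prefactor; rescales evolutionary time only).
#' @param seed RNG seed recorded with the run; `run_ad()` seeds from it.
#' @param initial_n number of seeded phenotypes.
#' @param initial_box per-axis interval for uniform initial phenotypes.
#' @param max_disp per-substep trait displacement cap inside the flow.
#' @param flow_tol local error tolerance of the adaptive trait-flow stepper.
#' @param snap_every snapshot cadence in attempts.
#' @param esc_window attempts without an admitted mutant required (together
#'   with small gradients) to declare an evolutionarily stable community.
#' @param esc_grad_tol gradient-norm threshold of the ESC test.
#' @param cluster_delta linkage distance used when counting species for
#'   reporting.
#' @return an object of class `ad_config`.
#' @export
ad_config <- function(eps_mut = 0.02, sigma_mut = 0, delta_merge = 0.005,
                      min_viable = 1e-4, epoch_time = 1, n_attempts = 5000L,
                      kappa = 1, seed = 1L, initial_n = 1L,
                      initial_box = c(-2, 2), max_disp = 0.05,
                      flow_tol = 1e-4, snap_every = 50L, esc_window = 500L,
                      esc_grad_tol = 1e-4, cluster_delta = 0.05) {
  stopifnot(eps_mut > 0, sigma_mut >= 0, delta_merge > 0, min_viable > 0,
            epoch_time > 0, n_attempts >= 1, kappa > 0, initial_n >= 1,
            length(initial_box) == 2L, initial_box[1] < initial_box[2])
  if (sigma_mut > 0 && sigma_mut < eps_mut)
    stop("Gaussian mode needs sigma_mut >= eps_mut")
  if (delta_merge >= eps_mut)
    stop("delta_merge must be smaller than eps_mut")
  structure(list(eps_mut = eps_mut, sigma_mut = sigma_mut,
                 delta_merge = delta_merge, min_viable = min_viable,
                 epoch_time = epoch_time, n_attempts = as.integer(n_attempts),
                 kappa = kappa, seed = as.integer(seed),
                 initial_n = as.integer(initial_n),
                 initial_box = as.numeric(initial_box),
                 max_disp = max_disp, flow_tol = flow_tol,
                 snap_every = as.integer(snap_every),
                 esc_window = as.integer(esc_window),
                 esc_grad_tol = esc_grad_tol, cluster_delta = cluster_delta),
            class = "ad_config")
}

#' Advance a community along the canonical equation of adaptive dynamics
#'
#' Deterministic trait flow \eqn{dz_i/dt = \kappa N_i^* g_i}, where
#' \eqn{N_i^*} are the equilibrium abundances (recomputed at every stage
#' evaluation) and \eqn{g_i} the selection gradients.  Species that become
#' ecologically infeasible during the flow go extinct and are dropped.
#'
#' @param community a [community()] object (equilibrated or not; abundances
#'   are re-equilibrated internally).
#' @param dt evolutionary time to advance.
#' @param params a [model_params()] object.
#' @param kappa canonical rate constant.
#' @param max_disp per-substep displacement cap (trait units).
#' @param tol local error tolerance of the adaptive stepper.
#' @return the advanced, equilibrated community; attribute `"extinct_labels"`
#'   lists labels lost along the way.
#' @export
canonical_step <- function(community, dt, params, kappa = 1,
                           max_disp = 0.05, tol = 1e-4) {
  if (n_species(community) == 0L) return(community)
  fl <- cpp_canonical_flow(community$phenotypes, params$sigma_alpha,
                           params$b, params$printed_form, k_kind(params),
                           kappa, dt, max_disp, tol)
  alive <- drop(fl$alive)
  out <- community(fl$Z, drop(fl$N), community$labels[alive])
  attr(out, "extinct_labels") <- setdiff(community$labels, out$labels)
  out
}

#' Merge phenotypically indistinguishable species
#'
#' Collapses every group of species connected by pairwise distances below
#' `delta_merge` (transitive closure) into a single species whose phenotype is
#' the abundance-weighted mean and whose abundance is the group sum, so total
#' abundance is conserved exactly.  The label of the group's most abundant
#' member is kept.
#'
#' @param community a [community()] object.
#' @param delta_merge merge distance (trait units).
#' @return the merged community.
#' @export
merge_close <- function(community, delta_merge) {
  M <- n_species(community)
  if (M <= 1L) return(community)
  g <- cpp_cluster_labels(community$phenotypes, delta_merge)
  if (max(g) == M) return(community)
  Z <- matrix(0, max(g), ncol(community$phenotypes))
  N <- numeric(max(g))
  lab <- integer(max(g))
  for (c in seq_len(max(g))) {
    idx <- which(g == c)
    w <- community$abundances[idx]
    N[c] <- sum(w)
    Z[c, ] <- if (N[c] > 0)
      colSums(community$phenotypes[idx, , drop = FALSE] * w) / N[c]
    else colMeans(community$phenotypes[idx, , drop = FALSE])
    lab[c] <- community$labels[idx[which.max(w)]]
  }
  community(Z, N, lab)
}

#' Propose a mutant phenotype
#'
#' Picks a parent uniformly at random and displaces its phenotype: in
#' fixed-offset mode (`sigma_mut = 0`) by exactly `eps_mut` in a direction
#' uniform on the sphere; in Gaussian mode by independent per-axis Gaussian
#' deviates of scale `sigma_mut`.
#'
#' @param community a [community()] object with at least one species.
#' @param config an [ad_config()] object.
#' @return list with `parent` (label) and `phenotype` (numeric vector).
#' @export
propose_mutant <- function(community, config) {
  M <- n_species(community)
  if (M < 1L) stop("cannot mutate an empty community")
  p <- if (M == 1L) 1L else sample.int(M, 1L)
  z <- community$phenotypes[p, ]
  d <- length(z)
  if (config$sigma_mut > 0) {
    off <- rnorm(d, 0, config$sigma_mut)
  } else {
    u <- rnorm(d)
    off <- config$eps_mut * u / sqrt(sum(u^2))
  }
  list(parent = community$labels[p], phenotype = z + off)
}

#' Attempt a branching event
#'
#' Admits the proposed mutant if and only if its invasion fitness against the
#' equilibrated resident community is strictly positive; an admitted mutant
#' enters at abundance `min_viable` and the community is re-equilibrated.
#' Mutual invasibility with the parent is evaluated and reported but not
#' enforced (the two criteria coincide at branching points).
#'
#' @param community an equilibrated [community()] object.
#' @param mutant proposal from [propose_mutant()] (or a list with `parent`
#'   label and `phenotype`).
#' @param params a [model_params()] object.
#' @param min_viable entry abundance of an admitted mutant.
#' @param new_label label to assign on admission.
#' @return list with `community` (possibly extended and re-equilibrated),
#'   `admitted`, `fitness` and `mutual` (mutual invasibility with the parent).
#' @export
attempt_branch <- function(community, mutant, params, min_viable = 1e-4,
                           new_label = NULL) {
  f <- invasion_fitness_community(community, mutant$phenotype, params)
  ip <- match(mutant$parent, community$labels)
  mutual <- if (!is.na(ip)) {
    zp <- community$phenotypes[ip, ]
    f > 0 && invasion_fitness(mutant$phenotype, zp, params) > 0
  } else NA
  if (!is.finite(f) || f <= 0)
    return(list(community = community, admitted = FALSE, fitness = f,
                mutual = mutual))
  if (is.null(new_label)) new_label <- max(community$labels) + 1L
  ext <- community(rbind(community$phenotypes, mutant$phenotype),
                   c(community$abundances, min_viable),
                   c(community$labels, as.integer(new_label)))
  ext <- ecological_equilibrium(ext, params)
  list(community = ext, admitted = TRUE, fitness = f, mutual = mutual)
}

#' Run an adaptive-dynamics simulation
#'
#' The evolutionary loop: per mutation attempt, (1) solve the ecological
#' equilibrium, (2) remove species below the minimum viable abundance,
#' (3) advance the canonical trait flow for `epoch_time`, (4) merge species
#' within `delta_merge` of each other, (5) propose a mutant near a random
#' parent, (6) discard it unless its invasion fitness is positive, and
#' (7) repeat until the attempt budget is spent or an evolutionarily stable
#' community is reached (no admission during `esc_window` attempts and all
#' gradient norms below `esc_grad_tol`).
#'
#' @param model a [model_params()] object.
#' @param config an [ad_config()] object.
#' @param init optional starting [community()]; default `initial_n` uniform
#'   phenotypes on the initial box, entering at `min_viable`.
#' @return an object of class `ad_trajectory`: list with `snapshots` (each a
#'   list of `time` and `community`), `events` (data frame: time, kind,
#'   label), `final` community, `termination` ("esc", "budget" or
#'   "extinct"), `attempts`, `model` and `config`.
#' @examples
#' \donttest{
#' mp <- model_params("quartic", sigma_alpha = 0.5)
#' cf <- ad_config(n_attempts = 200, seed = 42)
#' tr <- run_ad(mp, cf)
#' n_species(tr$final)
#' }
#' @export
run_ad <- function(model, config, init = NULL) {
  set.seed(config$seed)
  if (is.null(init)) {
    init <- seed_initial_community(config$initial_n, config$initial_box,
                                   d = model$d,
                                   min_viable = config$min_viable)
  }
  co <- init
  t <- 0
  next_label <- max(co$labels) + 1L
  snapshots <- vector("list", config$n_attempts %/% config$snap_every + 2L)
  n_snap <- 0L
  ev_time <- numeric(); ev_kind <- character(); ev_label <- integer()
  log_event <- function(time, kind, labels) {
    for (l in labels) {
      ev_time[length(ev_time) + 1L] <<- time
      ev_kind[length(ev_kind) + 1L] <<- kind
      ev_label[length(ev_label) + 1L] <<- l
    }
  }
  take_snapshot <- function(time, com) {
    n_snap <<- n_snap + 1L
    snapshots[[n_snap]] <<- list(time = time, community = com)
  }
  last_admit <- 0L
  termination <- "budget"
  attempt <- 0L

  for (attempt in seq_len(config$n_attempts)) {
    # (1) equilibrium + (2) extinction pruning
    before <- co$labels
    co <- ecological_equilibrium(co, model)
    co <- prune_extinct(co, config$min_viable)
    log_event(t, "extinction", setdiff(before, co$labels))
    if (n_species(co) == 0L) { termination <- "extinct"; break }

    # (3) canonical trait flow for one epoch
    co <- canonical_step(co, config$epoch_time, model,
                         kappa = config$kappa, max_disp = config$max_disp,
                         tol = config$flow_tol)
    t <- t + config$epoch_time
    log_event(t, "extinction", attr(co, "extinct_labels"))
    if (n_species(co) == 0L) { termination <- "extinct"; break }

    # (4) merge near-coincident species
    before <- co$labels
    co <- merge_close(co, config$delta_merge)
    co <- ecological_equilibrium(co, model)
    log_event(t, "merge", setdiff(before, co$labels))

    # (5) propose, (6) admit on positive invasion fitness
    prop <- propose_mutant(co, config)
    res <- attempt_branch(co, prop, model, min_viable = config$min_viable,
                          new_label = next_label)
    if (res$admitted) {
      co <- res$community
      log_event(t, "branch", next_label)
      next_label <- next_label + 1L
      last_admit <- attempt
    }

    if (attempt %% config$snap_every == 0L) take_snapshot(t, co)

    # (7) ESC termination test
    if (attempt - last_admit >= config$esc_window) {
      g <- selection_gradient(co, model)
      if (max(sqrt(rowSums(g^2))) < config$esc_grad_tol) {
        termination <- "esc"
        break
      }
    }
  }
  take_snapshot(t, co)
  structure(list(snapshots = snapshots[seq_len(n_snap)],
                 events = data.frame(time = ev_time, kind = ev_kind,
                                     label = ev_label),
                 final = co, termination = termination, attempts = attempt,
                 model = model, config = config),
            class = "ad_trajectory")
}

#' @export
print.ad_trajectory <- function(x, ...) {
  cc <- cluster_species(x$final$phenotypes, x$config$cluster_delta)
  cat("<ad_trajectory> ", x$attempts, " attempts, termination: ",
      x$termination, ", ", n_species(x$final), " phenotypes (",
      cc$count, " species at delta = ", x$config$cluster_delta, ")\n",
      sep = "")
  invisible(x)
}
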