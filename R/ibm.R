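#' Configuration for an individual-based run
#'
#' @param k_max scalar multiplying the carrying capacity: number of
#'   individuals a monomorphic population at the origin equilibrates to
#'   ("richness" of the environment).
#' @param birth_rate fixed per-capita birth rate (events per unit time).
#' @param sigma_mut_ibm per-birth mutation scale: every offspring is displaced
#'   from its parent by independent per-axis Gaussian deviates of this scale
#'   (trait units).
#' @param seed RNG seed recorded with the run.
#' @param initial_individuals number of founding individuals.
#' @param initial_box per-axis interval for uniform founder phenotypes.
#' @param max_events event budget (each event is one birth or one death).
#' @param cluster_delta linkage distance of the species-accounting clustering.
#' @param record_every record population size and cluster count every this
#'   many events.
#' @param keep_snapshots cap on retained full phenotype snapshots (thinned
#'   geometrically when exceeded); 0 disables.
#' @param self_term include the focal individual's own competition term
#'   (alpha = 1) in its death rate, so the monomorphic birth-death balance
#'   lands exactly at `k_max * K(z)`.
#' @param scheduler `"gillespie"` (exact continuous-time, the default) or
#'   `"sequential"` (discrete random-sequential updating, kept for fidelity
#'   comparisons).
#' @return an object of class `ibm_config`.
#' @export
ibm_config <- function(k_max = 200, birth_rate = 1, sigma_mut_ibm = 0.005,
                       seed = 1L, initial_individuals = 1L,
                       initial_box = c(-2, 2), max_events = 1e6,
                       cluster_delta = 0.1, record_every = 1000L,
                       keep_snapshots = 200L, self_term = TRUE,
                       scheduler = c("gillespie", "sequential")) {
  scheduler <- match.arg(scheduler)
  stopifnot(k_max >= 1, birth_rate > 0, sigma_mut_ibm > 0,
            initial_individuals >= 1, max_events >= 1, cluster_delta > 0,
            record_every >= 1)
  structure(list(k_max = k_max, birth_rate = birth_rate,
                 sigma_mut_ibm = sigma_mut_ibm, seed = as.integer(seed),
                 initial_individuals = as.integer(initial_individuals),
                 initial_box = as.numeric(initial_box),
                 max_events = max_events, cluster_delta = cluster_delta,
                 record_every = as.integer(record_every),
                 keep_snapshots = as.integer(keep_snapshots),
                 self_term = isTRUE(self_term), scheduler = scheduler),
            class = "ibm_config")
}

#' A population of individuals in phenotype space
#'
#' The individual-based-model state: a cloud of points, one per individual,
#' plus the elapsed event time.
#'
#' @param phenotypes matrix with one individual phenotype per row.
#' @param time nonnegative elapsed time.
#' @return an object of class `ibm_population`.
#' @export
ibm_population <- function(phenotypes, time = 0) {
  Z <- as.matrix(phenotypes)
  storage.mode(Z) <- "double"
  stopifnot(all(is.finite(Z)), time >= 0)
  structure(list(phenotypes = Z, time = time), class = "ibm_population")
}

#' @export
print.ibm_population <- function(x, ...) {
  cat("<ibm_population> ", nrow(x$phenotypes), " individuals at time ",
      signif(x$time, 6), "\n", sep = "")
  invisible(x)
}

#' Frequency-dependent death rate of individuals
#'
#' Death rate of each individual: its total competition load divided by
#' `k_max * K(z)`, the direct individual-level analogue of the per-capita
#' loss term of the Lotka-Volterra dynamics.  The focal individual's
#' self-term (alpha = 1) is included by default.
#'
#' @param population an [ibm_population()] object.
#' @param model a [model_params()] object.
#' @param config an [ibm_config()] object.
#' @return numeric vector of strictly positive death rates, one per
#'   individual.
#' @export
death_rate <- function(population, model, config) {
  drop(cpp_ibm_death_rates(population$phenotypes, model$sigma_alpha,
                           model$b, model$printed_form, k_kind(model),
                           config$k_max, config$self_term))
}

#' Advance the individual-based model by single events
#'
#' Executes `n` exact Gillespie events (or random-sequential updates,
#' depending on the configured scheduler): the total event rate is the sum of
#' all birth and death rates, one individual-level event is drawn
#' rate-proportionally, and time advances by an exponential increment.  A
#' birth adds one offspring at the parent's phenotype plus per-axis Gaussian
#' mutation; a death removes the individual.
#'
#' @param population an [ibm_population()] object.
#' @param model a [model_params()] object.
#' @param config an [ibm_config()] object.
#' @param n number of events to execute.
#' @return the advanced population; attribute `"extinct"` is TRUE if the
#'   population died out.
#' @export
step_ibm <- function(population, model, config, n = 1L) {
  if (nrow(population$phenotypes) == 0L) stop("population is extinct")
  out <- cpp_run_ibm(population$phenotypes, model$sigma_alpha, model$b,
                     model$printed_form, k_kind(model), config$k_max,
                     config$birth_rate, config$sigma_mut_ibm, n,
                     record_every = n + 1L, cluster_delta =
                       config$cluster_delta, self_term = config$self_term,
                     keep_snapshots = 0L,
                     sequential = config$scheduler == "sequential")
  pop <- ibm_population(out$Z, population$time + out$time)
  attr(pop, "extinct") <- out$extinct
  pop
}

#' Run an individual-based simulation
#'
#' Full stochastic birth-death-mutation simulation.  Reproducible given the
#' seed; records population size and clustered species count at a fixed event
#' cadence and retains a thinned set of full phenotype snapshots.
#'
#' @param model a [model_params()] object.
#' @param config an [ibm_config()] object.
#' @param init optional founding [ibm_population()]; default
#'   `initial_individuals` phenotypes uniform on the initial box.
#' @return an object of class `ibm_trajectory`: list with `records`
#'   (data frame: time, size, clusters), `snapshot_times`, `snapshots`
#'   (phenotype matrices), `final` population, `extinct`, `events`, `model`,
#'   `config`.  The summary statistic `final_clusters` is the median cluster
#'   count over the last 200 records.
#' @export
run_ibm <- function(model, config, init = NULL) {
  set.seed(config$seed)
  if (is.null(init)) {
    Z0 <- matrix(runif(config$initial_individuals * model$d,
                       config$initial_box[1], config$initial_box[2]),
                 ncol = model$d)
    init <- ibm_population(Z0)
  }
  out <- cpp_run_ibm(init$phenotypes, model$sigma_alpha, model$b,
                     model$printed_form, k_kind(model), config$k_max,
                     config$birth_rate, config$sigma_mut_ibm,
                     config$max_events, config$record_every,
                     config$cluster_delta, config$self_term,
                     config$keep_snapshots,
                     config$scheduler == "sequential")
  rec <- data.frame(time = out$times, size = out$sizes,
                    clusters = out$clusters)
  tail_n <- min(nrow(rec), 200L)
  structure(list(records = rec, snapshot_times = out$snapshot_times,
                 snapshots = out$snapshots,
                 final = ibm_population(out$Z, out$time),
                 extinct = out$extinct, events = out$events,
                 final_clusters = median(rec$clusters[
                   seq.int(nrow(rec) - tail_n + 1L, nrow(rec))]),
                 model = model, config = config),
            class = "ibm_trajectory")
}

#' @export
print.ibm_trajectory <- function(x, ...) {
  cat("<ibm_trajectory> ", x$events, " events to time ",
      signif(x$final$time, 6), ", ", nrow(x$final$phenotypes),
      " individuals, final clusters (median of tail): ",
      x$final_clusters, "\n", sep = "")
  invisible(x)
}
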