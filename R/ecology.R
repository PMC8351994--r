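#' Community of distinct phenotypes with abundances
#'
#' The adaptive-dynamics state: M phenotypes (rows of a matrix), their
#' nonnegative abundances, and stable integer labels that survive branching,
#' merging and extinction so lineages can be followed through a run.
#'
#' @param phenotypes numeric matrix, one phenotype per row (a single vector is
#'   taken as one phenotype).
#' @param abundances nonnegative numeric vector, one entry per phenotype;
#'   defaults to the carrying capacity of each phenotype if `params` is given,
#'   otherwise zeros.
#' @param labels unique integer identifiers; defaults to 1..M.
#' @param params optional [model_params()] used only for the abundance
#'   default.
#' @return an object of class `community`.
#' @examples
#' mp <- model_params()
#' co <- community(rbind(c(0, 0), c(1, 0)), params = mp)
#' @export
community <- function(phenotypes, abundances = NULL, labels = NULL,
                      params = NULL) {
  d <- if (!is.null(params)) params$d else if (is.null(dim(phenotypes)))
    length(phenotypes) else ncol(phenotypes)
  Z <- as_phenotype_matrix(phenotypes, d)
  M <- nrow(Z)
  if (is.null(abundances))
    abundances <- if (!is.null(params)) carrying_capacity(Z, params) else
      rep(0, M)
  if (is.null(labels)) labels <- seq_len(M)
  labels <- as.integer(labels)
  if (length(abundances) != M || length(labels) != M)
    stop("phenotypes, abundances and labels must have equal length")
  if (anyDuplicated(labels)) stop("labels must be unique")
  if (any(abundances < 0) || any(!is.finite(abundances)))
    stop("abundances must be finite and nonnegative")
  structure(list(phenotypes = Z, abundances = as.numeric(abundances),
                 labels = labels), class = "community")
}

#' @export
print.community <- function(x, ...) {
  cat("<community> ", nrow(x$phenotypes), " species, total abundance ",
      signif(sum(x$abundances), 5), "\n", sep = "")
  invisible(x)
}

#' Number of species in a community
#' @param community a [community()] object.
#' @return integer count.
#' @export
n_species <- function(community) nrow(community$phenotypes)

subset_community <- function(community, idx) {
  community(community$phenotypes[idx, , drop = FALSE],
            community$abundances[idx], community$labels[idx])
}

#' Lotka-Volterra interaction matrix
#'
#' Matrix of pairwise competition coefficients with entry (i, j) equal to the
#' effect of species j on species i, i.e. the summand of the logistic
#' Lotka-Volterra dynamics; the diagonal is 1.
#'
#' @param community a [community()] object.
#' @param params a [model_params()] object.
#' @return an M x M positive matrix.
#' @export
interaction_matrix <- function(community, params) {
  cpp_interaction_matrix(community$phenotypes, params$sigma_alpha, params$b,
                         params$printed_form)
}

#' Ecological equilibrium with feasibility pruning
#'
#' Solves the linear equilibrium condition
#' \eqn{\sum_j \alpha(z_j, z_i) N_j = K(z_i)} for the community.  Whenever the
#' solution contains a nonpositive abundance the species with the largest
#' violation (most negative abundance) is removed and the reduced system
#' re-solved, until all retained abundances are strictly positive.  The
#' long-time endpoint of [integrate_lv()] is the verification oracle for this
#' shortcut.
#'
#' @param community a [community()] object.
#' @param params a [model_params()] object.
#' @param tol residual tolerance on the per-capita growth rates at the
#'   returned equilibrium.
#' @return the equilibrated (possibly reduced) community, with attribute
#'   `"residual"`; an empty community (0 species, attribute `"empty"`) when no
#'   feasible positive subset exists.  Duplicate phenotypes make the system
#'   singular and raise an error asking for a merge.
#' @export
ecological_equilibrium <- function(community, params, tol = 1e-8) {
  if (n_species(community) == 0L) return(community)
  eq <- cpp_equilibrium(community$phenotypes, params$sigma_alpha, params$b,
                        params$printed_form, k_kind(params))
  if (eq$status == 2L)
    stop("singular interaction matrix: coincident phenotypes, merge required")
  if (eq$status == 1L) {
    out <- community(matrix(numeric(0), 0, ncol(community$phenotypes)),
                     numeric(0), integer(0))
    attr(out, "empty") <- TRUE
    return(out)
  }
  out <- subset_community(community, drop(eq$keep))
  out$abundances <- drop(eq$N)
  res <- max(abs(invasion_fitness_community(out, out$phenotypes, params)))
  if (res > tol)
    warning("equilibrium residual ", signif(res, 3), " exceeds tol")
  attr(out, "residual") <- res
  out
}

#' Integrate the Lotka-Volterra dynamics
#'
#' Adaptive Cash-Karp Runge-Kutta integration of the logistic competition
#' dynamics from given initial abundances, with abundances clamped at 0 (an
#' absorbing state).
#'
#' @param community a [community()] object supplying the phenotypes.
#' @param initial_abundances nonnegative starting abundances.
#' @param t_span integration time.
#' @param params a [model_params()] object.
#' @param nsave number of evenly spaced saved states after t = 0.
#' @param rtol,atol local error tolerances.
#' @return list with `times` and an abundance matrix `N` (rows = saved times).
#' @export
integrate_lv <- function(community, initial_abundances, t_span, params,
                         nsave = 100L, rtol = 1e-8, atol = 1e-10) {
  N0 <- as.numeric(initial_abundances)
  if (length(N0) != n_species(community)) stop("initial abundances mismatch")
  if (any(N0 < 0)) stop("initial abundances must be nonnegative")
  out <- cpp_integrate_lv(community$phenotypes, N0, params$r, t_span,
                          params$sigma_alpha, params$b, params$printed_form,
                          k_kind(params), rtol, atol, as.integer(nsave))
  list(times = drop(out$times), N = out$N)
}

#' Remove species below a minimum viable abundance
#'
#' @param community a [community()] object.
#' @param min_viable extinction threshold (same density units as the
#'   abundances).
#' @return the pruned community; surviving labels are preserved.
#' @export
prune_extinct <- function(community, min_viable) {
  keep <- community$abundances >= min_viable
  if (all(keep)) community else subset_community(community, which(keep))
}
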