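#' Carrying capacity of a phenotype
#'
#' Evaluates the carrying-capacity kernel chosen in `params` at one or more
#' phenotypes.  Both kernels peak at exactly 1 at the origin and decay to 0
#' away from it, imposing stabilizing selection toward the origin.
#'
#' @param z a phenotype (numeric vector of length `params$d`) or a matrix with
#'   one phenotype per row.
#' @param params a [model_params()] object.
#' @param log return log K instead of K (useful against underflow far outside
#'   the viable region).
#' @return numeric vector of carrying capacities in (0, 1].
#' @examples
#' mp <- model_params()
#' carrying_capacity(rbind(c(0, 0), c(1, 1)), mp)
#' @export
carrying_capacity <- function(z, params, log = FALSE) {
  Z <- as_phenotype_matrix(z, params$d)
  lk <- drop(cpp_log_K(Z, k_kind(params)))
  if (log) lk else exp(lk)
}

#' Competition kernel
#'
#' Competitive effect entering the Lotka-Volterra dynamics for a pair of
#' phenotypes.  Equals exactly 1 when `z_i == z_j`; reduces to the Gaussian
#' \eqn{\exp(-|z_i - z_j|^2 / (2\sigma_\alpha^2))} when `b = 0`; generally
#' asymmetric (`competition(z_i, z_j) != competition(z_j, z_i)`) otherwise.
#'
#' @param z_i,z_j phenotypes (vectors, or matrices paired row by row).
#' @param params a [model_params()] object.
#' @return numeric vector of strictly positive kernel values.
#' @export
competition <- function(z_i, z_j, params) {
  Zi <- as_phenotype_matrix(z_i, params$d)
  Zj <- as_phenotype_matrix(z_j, params$d)
  if (nrow(Zi) != nrow(Zj)) stop("z_i and z_j must pair up row by row")
  drop(cpp_alpha_pairs(Zi, Zj, params$sigma_alpha, params$b,
                       params$printed_form))
}

#' Invasion fitness of a mutant against a monomorphic resident
#'
#' Per-capita initial growth rate of a rare mutant with phenotype `z_m`
#' appearing in a resident population of phenotype `z_r` sitting at its
#' ecological equilibrium \eqn{K(z_r)}:
#' \eqn{f(z_r, z_m) = 1 - \alpha(z_r, z_m) K(z_r)/K(z_m)}.
#' Computed through log-K differences so that deep-negative fitness far
#' outside the viable region is returned instead of NaN from underflow.
#'
#' @param z_r resident phenotype.
#' @param z_m mutant phenotype(s), vector or matrix of rows.
#' @param params a [model_params()] object.
#' @return numeric invasion fitness; exactly 0 at `z_m == z_r`.
#' @export
invasion_fitness <- function(z_r, z_m, params) {
  Zr <- as_phenotype_matrix(z_r, params$d)
  if (nrow(Zr) != 1L) stop("`z_r` must be a single phenotype")
  Zm <- as_phenotype_matrix(z_m, params$d)
  Nr <- exp(drop(cpp_log_K(Zr, k_kind(params))))
  f <- drop(cpp_invasion_fitness(Zr, Nr, Zm, params$sigma_alpha, params$b,
                                 params$printed_form, k_kind(params)))
  if (any(f < -1e100))
    warning("carrying capacity underflow: fitness capped at a large ",
            "negative value")
  f
}

#' Invasion fitness of a mutant against a resident community
#'
#' Generalizes [invasion_fitness()] to M residents:
#' \eqn{f(z_m) = 1 - \sum_j \alpha(z_j, z_m) N_j / K(z_m)}.  When the
#' abundances are the exact ecological equilibrium, the fitness is 0 at every
#' resident phenotype.  An empty community gives fitness 1 everywhere (the
#' pure birth rate).
#'
#' @param community a [community()] object; its stored abundances are used
#'   unless `abundances` is supplied.
#' @param z_m mutant phenotype(s), vector or matrix of rows.
#' @param params a [model_params()] object.
#' @param abundances optional replacement abundance vector.
#' @return numeric invasion fitness per mutant phenotype.
#' @export
invasion_fitness_community <- function(community, z_m, params,
                                       abundances = NULL) {
  Zm <- as_phenotype_matrix(z_m, params$d)
  N <- if (is.null(abundances)) community$abundances else abundances
  if (length(N) != nrow(community$phenotypes))
    stop("abundances do not match the community")
  if (any(N < 0)) stop("negative abundances")
  if (length(N) == 0L) return(rep(1, nrow(Zm)))
  f <- drop(cpp_invasion_fitness(community$phenotypes, N, Zm,
                                 params$sigma_alpha, params$b,
                                 params$printed_form, k_kind(params)))
  if (any(f < -1e100))
    warning("carrying capacity underflow: fitness capped at a large ",
            "negative value")
  f
}

#' Selection gradient of every resident (or one resident) in a community
#'
#' Gradient of the community invasion fitness with respect to the mutant
#' phenotype, evaluated at each resident: the local direction of selection
#' that drives the canonical-equation trait flow.  The community should be at
#' (or supplied with) its ecological equilibrium.
#'
#' @param community a [community()] object with equilibrium abundances.
#' @param params a [model_params()] object.
#' @param i optional single species index; default all species.
#' @param method `"analytic"` (closed-form chain rule, the default) or
#'   `"finite_difference"` (central differences, step `h`), the fallback and
#'   cross-validation route.
#' @param h finite-difference step (trait units).
#' @return an M x d matrix of gradients (or a length-d vector when `i` is
#'   given).
#' @export
selection_gradient <- function(community, params, i = NULL,
                               method = c("analytic", "finite_difference"),
                               h = 1e-5) {
  method <- match.arg(method)
  Z <- community$phenotypes
  N <- community$abundances
  M <- nrow(Z)
  if (!is.null(i) && (i < 1L || i > M)) stop("species index out of range")
  if (method == "analytic") {
    G <- cpp_selection_gradients(Z, N, params$sigma_alpha, params$b,
                                 params$printed_form, k_kind(params))
  } else {
    G <- matrix(0, M, params$d)
    for (s in if (is.null(i)) seq_len(M) else i) {
      for (k in seq_len(params$d)) {
        zp <- zm <- Z[s, ]
        zp[k] <- zp[k] + h
        zm[k] <- zm[k] - h
        fp <- invasion_fitness_community(community, zp, params)
        fm <- invasion_fitness_community(community, zm, params)
        G[s, k] <- (fp - fm) / (2 * h)
      }
    }
  }
  if (is.null(i)) G else G[i, ]
}
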