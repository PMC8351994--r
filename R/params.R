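#' Model parameters shared by all three simulation frameworks
#'
#' Bundles the choices that define the ecological model: which carrying
#' capacity to use, the competition scale \eqn{\sigma_\alpha}, the asymmetry
#' coefficients \eqn{b}, the intrinsic growth rate \eqn{r} and the trait-space
#' dimension \eqn{d}.
#'
#' @param carrying carrying-capacity kind, `"quartic"` or `"radial"`.  The
#'   quartic kernel is \eqn{\exp(-\sum z_k^4/4)}; the radially symmetric one
#'   is \eqn{\exp(-(\sum z_k^2/2)^2/2)}.  Both peak at 1 at the origin and
#'   confine viable phenotypes to roughly \eqn{[-2, 2]} per axis.
#' @param sigma_alpha Gaussian competition scale (trait units), must be
#'   positive.  Values below 1 guarantee an evolutionary branching point at
#'   the origin for these quartic-order carrying capacities.
#' @param b d x d matrix of asymmetric-competition coefficients; all zeros
#'   (the default) gives symmetric Gaussian competition.
#' @param r intrinsic per-capita growth rate (1/time).
#' @param d trait-space dimension; the package is exercised at `d = 2`.
#' @param printed_form compatibility switch for the asymmetric exponent.
#'   The default `FALSE` uses \eqn{\sum_{k,l} b_{kl} (z_{ik} - z_{jk}) z_{il}},
#'   which keeps \eqn{\alpha(z, z) = 1} for every phenotype; `TRUE` uses the
#'   variant \eqn{\sum_{k,l} b_{kl} (z_{ik} - z_{jl}) z_{il}}, which does not.
#' @return an object of class `model_params`.
#' @examples
#' mp <- model_params(sigma_alpha = 0.5)
#' carrying_capacity(c(0, 0), mp)
#' @export
model_params <- function(carrying = c("quartic", "radial"), sigma_alpha = 0.5,
                         b = NULL, r = 1, d = 2L, printed_form = FALSE) {
  carrying <- match.arg(carrying)
  d <- as.integer(d)
  stopifnot(d >= 1L)
  if (is.null(b)) b <- matrix(0, d, d)
  b <- as.matrix(b)
  if (!all(dim(b) == c(d, d))) stop("`b` must be a ", d, " x ", d, " matrix")
  if (!is.numeric(sigma_alpha) || length(sigma_alpha) != 1L ||
      !is.finite(sigma_alpha) || sigma_alpha <= 0)
    stop("`sigma_alpha` must be a positive finite scalar")
  if (!is.numeric(r) || r <= 0) stop("`r` must be positive")
  if (any(!is.finite(b))) stop("`b` must be finite")
  structure(list(carrying = carrying, sigma_alpha = sigma_alpha, b = b,
                 r = r, d = d, printed_form = isTRUE(printed_form)),
            class = "model_params")
}

# integer code used by the compiled kernels
k_kind <- function(params) match(params$carrying, c("quartic", "radial")) - 1L

as_phenotype_matrix <- function(z, d) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  z <- as.matrix(z)
  if (ncol(z) != d) stop("phenotypes must have ", d, " coordinates")
  if (!all(is.finite(z))) stop("phenotypes must be finite")
  storage.mode(z) <- "double"
  z
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params> ", x$carrying, " K, sigma_alpha = ", x$sigma_alpha,
      ", r = ", x$r, ", d = ", x$d,
      if (any(x$b != 0)) ", asymmetric b" else ", symmetric (b = 0)",
      "\n", sep = "")
  invisible(x)
}
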