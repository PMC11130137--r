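#' Interaction-strength parameters
#'
#' Means and standard deviation of the Gaussian draws that turn the binary
#' food-web structure into a signed interaction matrix. Defaults follow the
#' study design: the effect of a consumer on its resource, and pairwise
#' competition for a shared basal resource, average \eqn{\mu = -0.1}; the
#' effect of a resource on its consumer averages \eqn{+0.1}; all draws use
#' \eqn{\sigma = 0.05}; every diagonal (self-regulation) element is fixed at
#' \eqn{-1}.
#'
#' @param mu_consumption mean effect of a consumer on its resource.
#' @param mu_benefit mean effect of a resource on its consumer.
#' @param mu_competition mean effect of one basal-resource competitor on the
#'   other (applied in both directions).
#' @param sigma standard deviation of every draw (>= 0).
#' @param diagonal self-regulation entry (< 0).
#' @return A list of class \code{"strength_params"}.
#' @export
strength_params <- function(mu_consumption = -0.1, mu_benefit = 0.1,
                            mu_competition = -0.1, sigma = 0.05,
                            diagonal = -1) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (diagonal >= 0) stop("diagonal self-regulation must be negative")
  structure(list(mu_consumption = mu_consumption, mu_benefit = mu_benefit,
                 mu_competition = mu_competition, sigma = sigma,
                 diagonal = diagonal),
            class = "strength_params")
}

#' Sample a signed interaction matrix for a local web
#'
#' Entry \code{(i, j)} holds the per-capita effect of member \code{j} on
#' member \code{i}. For every trophic link (consumer c, resource r) the
#' effect of c on r is drawn from N(mu_consumption, sigma) and the
#' reciprocal effect of r on c from N(mu_benefit, sigma). For every
#' competition pair both directed effects are drawn from
#' N(mu_competition, sigma). When a directed cell receives both a trophic
#' and a competition contribution (a taxon preying on a competitor), the two
#' independent draws are summed. All remaining off-diagonals are 0 and the
#' diagonal is the fixed self-regulation term.
#'
#' @param web a \code{"local_food_web"}.
#' @param params a \code{"strength_params"}.
#' @return n x n numeric matrix with member ids as dimnames.
#' @export
sample_interaction_matrix <- function(web, params = strength_params()) {
  n <- length(web$members)
  A <- matrix(0, n, n, dimnames = list(web$members, web$members))
  if (nrow(web$links)) {
    ci <- match(web$links$consumer, web$members)
    ri <- match(web$links$resource, web$members)
    # effect of consumer on resource: row = resource, col = consumer
    A[cbind(ri, ci)] <- A[cbind(ri, ci)] +
      stats::rnorm(length(ci), params$mu_consumption, params$sigma)
    # effect of resource on consumer: row = consumer, col = resource
    A[cbind(ci, ri)] <- A[cbind(ci, ri)] +
      stats::rnorm(length(ci), params$mu_benefit, params$sigma)
  }
  if (nrow(web$competition)) {
    ai <- match(web$competition$a, web$members)
    bi <- match(web$competition$b, web$members)
    A[cbind(ai, bi)] <- A[cbind(ai, bi)] +
      stats::rnorm(length(ai), params$mu_competition, params$sigma)
    A[cbind(bi, ai)] <- A[cbind(bi, ai)] +
      stats::rnorm(length(ai), params$mu_competition, params$sigma)
  }
  diag(A) <- params$diagonal
  A
}

#' Community matrix M = D A
#'
#' Scales row i of the signed interaction matrix by the equilibrium relative
#' abundance of member i. Relative abundances make nests of different total
#' abundance comparable: multiplying a matrix by a scalar multiplies all its
#' eigenvalues by that scalar.
#'
#' @param rel_abund named vector of relative abundances (sums to 1).
#' @param A signed interaction matrix from [sample_interaction_matrix()].
#' @return The community matrix \code{diag(rel_abund) \%*\% A}.
#' @export
community_matrix <- function(rel_abund, A) {
  if (length(rel_abund) != nrow(A) || nrow(A) != ncol(A))
    stop("dimension mismatch between rel_abund and A")
  if (abs(sum(rel_abund) - 1) > 1e-8)
    stop("rel_abund must sum to 1")
  rel_abund * A  # row scaling: D %*% A
}

#' Real part of the leading eigenvalue
#'
#' The local asymptotic stability statistic: the maximum real part over all
#' (possibly complex) eigenvalues of the community matrix. Negative values
#' mean the community returns to equilibrium after an infinitesimal
#' perturbation, with more negative values indicating faster return.
#'
#' @param M square numeric matrix.
#' @return \eqn{\Re(\lambda_1)}, a single number.
#' @export
leading_eigen_real <- function(M) {
  if (nrow(M) != ncol(M)) stop("M must be square")
  max(Re(eigen(M, only.values = TRUE)$values))
}

#' Randomly rewire a signed interaction matrix
#'
#' The topology null model: permutes all off-diagonal elements (zeros
#' included) uniformly at random over the off-diagonal positions, leaving
#' the diagonal untouched. The multiset of interaction strengths is
#' conserved exactly; only their arrangement is destroyed.
#'
#' @param A square numeric matrix.
#' @return Rewired matrix of the same dimension.
#' @export
rewire <- function(A) {
  n <- nrow(A)
  if (n != ncol(A)) stop("A must be square")
  off <- which(row(A) != col(A))
  A[off] <- A[sample(off)]
  A
}

#' Scenario specification for stability replicates
#'
#' @param abundance_mode \code{"observed"} (relative abundances from the
#'   nest) or \code{"even"} (all d_i = 1/n).
#' @param topology_mode \code{"observed"} or \code{"randomized"} (off-
#'   diagonal shuffle of the sampled matrix via [rewire()]).
#' @param params a \code{"strength_params"}.
#' @param n_reps replicate interaction matrices per nest (default 50).
#' @param seed optional integer seed.
#' @return A list of class \code{"scenario_spec"} with a \code{scenario}
#'   label \code{"<abundance>_<topology>"}.
#' @export
scenario_spec <- function(abundance_mode = c("observed", "even"),
                          topology_mode = c("observed", "randomized"),
                          params = strength_params(), n_reps = 50,
                          seed = NULL) {
  abundance_mode <- match.arg(abundance_mode)
  topology_mode <- match.arg(topology_mode)
  if (n_reps < 1) stop("n_reps must be >= 1")
  structure(list(abundance_mode = abundance_mode,
                 topology_mode = topology_mode, params = params,
                 n_reps = n_reps, seed = seed,
                 scenario = paste(abundance_mode, topology_mode, sep = "_")),
            class = "scenario_spec")
}

#' Stability of one nest under one scenario
#'
#' Draws \code{n_reps} signed interaction matrices for the nest's local web,
#' optionally rewires each, forms the community matrix with observed or even
#' relative abundances, and records \eqn{\Re(\lambda_1)} per replicate. Nest
#' stability is the mean of the replicate values; the response used in the
#' stability regressions is \code{log(abs(mean))}. Unstable replicates
#' (positive \eqn{\Re(\lambda_1)}) are retained; only a mean of exactly zero
#' is an error because its log-response is undefined.
#'
#' @param web a \code{"local_food_web"}.
#' @param spec a \code{"scenario_spec"}.
#' @return A list of class \code{"stability_result"}: \code{nest_id},
#'   \code{scenario}, \code{replicates} (numeric vector of
#'   \eqn{\Re(\lambda_1)}), \code{mean_re_lambda1}, \code{response},
#'   \code{n} (community size), \code{stable} (mean < 0).
#' @export
nest_stability <- function(web, spec = scenario_spec()) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- community_size(web)
  d <- if (spec$abundance_mode == "even") {
    stats::setNames(rep(1 / n, n), web$members)
  } else web$rel_abund
  reps <- vapply(seq_len(spec$n_reps), function(k) {
    A <- sample_interaction_matrix(web, spec$params)
    if (spec$topology_mode == "randomized") A <- rewire(A)
    leading_eigen_real(community_matrix(d, A))
  }, numeric(1))
  m <- mean(reps)
  if (m == 0) stop("mean Re(lambda1) is exactly zero: log response undefined")
  structure(list(nest_id = web$nest_id, scenario = spec$scenario,
                 replicates = reps, mean_re_lambda1 = m,
                 response = log(abs(m)), n = n, stable = m < 0),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("Nest '%s' [%s]: n = %d, mean Re(lambda1) = %.4f, response = %.3f (%s)\n",
              x$nest_id, x$scenario, x$n, x$mean_re_lambda1, x$response,
              if (x$stable) "stable" else "UNSTABLE"))
  invisible(x)
}

#' Run the four abundance-by-topology scenarios over all nests
#'
#' Full cross of the four scenarios (observed/even abundances times
#' observed/randomized topology), an optional grid of strength parameters
#' (for sensitivity scans over \eqn{\mu}), and every nest. A single root
#' seed spawns a deterministic sub-seed per (nest, scenario, parameter set)
#' so any subset reruns identically in isolation. Per-nest failures are
#' propagated as flagged rows, never aborts.
#'
#' @param webs named list of \code{"local_food_web"} objects.
#' @param params_grid list of \code{"strength_params"} (default one entry
#'   with the standard values).
#' @param n_reps replicates per nest and scenario (default 50).
#' @param seed root integer seed.
#' @return data.frame with one row per nest x scenario x parameter set:
#'   nest_id, scenario, abundance_mode, topology_mode, mu (consumption
#'   mean), sigma, n, mean_re_lambda1, response, stable, error.
#' @export
run_scenarios <- function(webs, params_grid = list(strength_params()),
                          n_reps = 50, seed = 1) {
  stopifnot(length(webs) >= 1)
  scen <- expand.grid(abundance_mode = c("observed", "even"),
                      topology_mode = c("observed", "randomized"),
                      stringsAsFactors = FALSE)
  rows <- list()
  for (p in seq_along(params_grid)) {
    params <- params_grid[[p]]
    for (s in seq_len(nrow(scen))) {
      for (w in seq_along(webs)) {
        sub_seed <- (as.numeric(seed) * 100003 + p * 10007 + s * 1009 + w) %%
          2147483629
        spec <- scenario_spec(scen$abundance_mode[s], scen$topology_mode[s],
                              params = params, n_reps = n_reps,
                              seed = as.integer(sub_seed))
        res <- tryCatch(nest_stability(webs[[w]], spec),
                        error = function(e) conditionMessage(e))
        if (is.character(res)) {
          rows[[length(rows) + 1L]] <- data.frame(
            nest_id = webs[[w]]$nest_id, scenario = spec$scenario,
            abundance_mode = spec$abundance_mode,
            topology_mode = spec$topology_mode,
            mu = params$mu_consumption, sigma = params$sigma,
            n = community_size(webs[[w]]), mean_re_lambda1 = NA_real_,
            response = NA_real_, stable = NA, error = res,
            stringsAsFactors = FALSE)
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            nest_id = res$nest_id, scenario = res$scenario,
            abundance_mode = spec$abundance_mode,
            topology_mode = spec$topology_mode,
            mu = params$mu_consumption, sigma = params$sigma,
            n = res$n, mean_re_lambda1 = res$mean_re_lambda1,
            response = res$response, stable = res$stable,
            error = NA_character_, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
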