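#' Pielou evenness of one community
#'
#' Shannon entropy H (natural log) over the groups with positive counts,
#' divided by log(S) where S is the number of such groups. J is 1 when all
#' present groups are equally abundant and approaches 0 under strong
#' dominance. With fewer than two groups log(S) = 0, so J is flagged
#' undefined rather than silently propagated as NaN.
#'
#' @param counts nonnegative numeric vector of group counts.
#' @param nest_id optional identifier carried into the record.
#' @return List of class \code{"evenness_record"}: \code{nest_id}, \code{S},
#'   \code{H} (nats), \code{J} (NA when undefined), \code{defined}.
#' @examples
#' pielou_evenness(c(5, 5, 5, 5))$J   # 1
#' pielou_evenness(c(75, 25))$J       # 0.8113
#' @export
pielou_evenness <- function(counts, nest_id = NA_character_) {
  if (any(counts < 0)) stop("counts must be nonnegative")
  pos <- counts[counts > 0]
  if (length(pos) == 0L) stop("all counts are zero: evenness undefined")
  S <- length(pos)
  p <- pos / sum(pos)
  H <- -sum(p * log(p))
  defined <- S >= 2L
  structure(list(nest_id = nest_id, S = S, H = H,
                 J = if (defined) H / log(S) else NA_real_,
                 defined = defined),
            class = "evenness_record")
}

#' Evenness of every nest in a dataset
#'
#' @param ds a \code{"study_dataset"}.
#' @return data.frame with nest_id, age_class, connectivity, S, H, J,
#'   defined.
#' @export
evenness_table <- function(ds) {
  recs <- lapply(rownames(ds$abundance), function(id)
    pielou_evenness(ds$abundance[id, ], nest_id = id))
  out <- data.frame(
    nest_id = vapply(recs, `[[`, character(1), "nest_id"),
    S = vapply(recs, `[[`, integer(1), "S"),
    H = vapply(recs, `[[`, numeric(1), "H"),
    J = vapply(recs, `[[`, numeric(1), "J"),
    defined = vapply(recs, `[[`, logical(1), "defined"),
    stringsAsFactors = FALSE)
  merge(ds$metadata[, c("nest_id", "age_class", "connectivity")], out,
        by = "nest_id", sort = FALSE)
}

#' Bray-Curtis dissimilarities between nests
#'
#' d(a, b) = sum |x_a - x_b| / sum (x_a + x_b) over functional groups, on
#' raw counts (no transformation or standardisation). Delegates to
#' \code{vegan::vegdist}.
#'
#' @param abundance nest-by-group count matrix.
#' @return A \code{dist} object labelled by nest id.
#' @export
bray_curtis <- function(abundance) {
  if (nrow(abundance) < 2L) stop("need at least 2 nests")
  zero <- rownames(abundance)[rowSums(abundance) == 0]
  if (length(zero))
    stop("all-zero nest(s): ", paste(zero, collapse = ", "))
  vegan::vegdist(abundance, method = "bray")
}

# Gower-centered inner-product matrix of a distance matrix.
gower_center <- function(D) {
  A <- -0.5 * D^2
  n <- nrow(A)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

# tr(H G) for the hat matrix of model matrix X, via its thin Q factor.
tr_hat_g <- function(X, G) {
  qr_ <- qr(X)
  Q <- qr.Q(qr_)[, seq_len(qr_$rank), drop = FALSE]
  sum(Q * (G %*% Q))
}

#' Distance-based permutational MANOVA
#'
#' Partitions the total sum of squares of a distance matrix sequentially
#' over the model terms (type-I entry order, matching the default of
#' \code{adonis2}) and tests each pseudo-F against free row permutations of
#' the distance matrix. Permutation p-values use the add-one rule
#' \eqn{p = (1 + \#\{F^* \ge F\}) / (1 + n_{perm})} and so are never 0.
#'
#' @param d \code{dist} object (e.g. from [bray_curtis()]).
#' @param design data.frame of nest covariates with a \code{nest_id} column
#'   matching the labels of \code{d}.
#' @param formula RHS-only model formula over design columns; default
#'   \code{~ age_class * connectivity}.
#' @param n_perm number of random permutations (default 999), ignored when
#'   \code{permutations} is supplied.
#' @param seed optional integer seed for the permutations.
#' @param permutations optional matrix of permutation index rows (each row a
#'   permutation of 1..n, typically including the identity) for exact tests;
#'   p is then the fraction of rows with \eqn{F^* \ge F}.
#' @return data.frame of class \code{"permanova"}: one row per term plus
#'   Residual and Total, with df, SS, R2, F and p.
#' @export
permanova <- function(d, design, formula = ~ age_class * connectivity,
                      n_perm = 999, seed = NULL, permutations = NULL) {
  D <- as.matrix(d)
  ids <- rownames(D)
  if (!"nest_id" %in% names(design)) stop("design needs a nest_id column")
  if (!setequal(ids, design$nest_id) || is.null(ids))
    stop("design nest ids do not match the distance matrix labels")
  design <- design[match(ids, design$nest_id), , drop = FALSE]
  n <- nrow(D)
  if (is.null(permutations) && n_perm < 1) stop("n_perm must be >= 1")

  mf <- stats::model.frame(formula, design)
  for (v in names(mf))
    if (length(unique(mf[[v]])) < 2L)
      stop("constant predictor: ", v)
  trm <- attr(stats::terms(formula), "term.labels")
  # cumulative model matrices: intercept, then +term_1, +term_2, ...
  Xs <- vector("list", length(trm) + 1L)
  Xs[[1]] <- matrix(1, n, 1)
  for (k in seq_along(trm)) {
    fk <- stats::reformulate(trm[seq_len(k)])
    Xs[[k + 1]] <- stats::model.matrix(fk, mf)
  }
  ranks <- vapply(Xs, function(X) qr(X)$rank, integer(1))
  df_term <- diff(ranks)
  df_res <- n - ranks[length(ranks)]

  G <- gower_center(D)
  ss_from_G <- function(G) {
    tr <- vapply(Xs, tr_hat_g, numeric(1), G = G)
    ss_total <- sum(diag(G))
    ss_term <- diff(tr)
    ss_res <- ss_total - tr[length(tr)]
    Fs <- (ss_term / df_term) / (ss_res / df_res)
    list(ss_term = ss_term, ss_res = ss_res, ss_total = ss_total, F = Fs)
  }
  obs <- ss_from_G(G)

  if (!is.null(permutations)) {
    Fperm <- apply(permutations, 1L, function(p) ss_from_G(G[p, p])$F)
    Fperm <- matrix(Fperm, nrow = length(trm))
    pvals <- rowMeans(Fperm >= obs$F - 1e-12)
  } else {
    if (!is.null(seed)) set.seed(seed)
    exceed <- rep(0L, length(trm))
    for (b in seq_len(n_perm)) {
      p <- sample.int(n)
      exceed <- exceed + (ss_from_G(G[p, p])$F >= obs$F - 1e-12)
    }
    pvals <- (1 + exceed) / (1 + n_perm)
  }

  out <- data.frame(
    term = c(trm, "Residual", "Total"),
    df = c(df_term, df_res, n - 1),
    SS = c(obs$ss_term, obs$ss_res, obs$ss_total),
    R2 = c(obs$ss_term, obs$ss_res, obs$ss_total) / obs$ss_total,
    F = c(obs$F, NA, NA),
    p = c(pvals, NA, NA),
    stringsAsFactors = FALSE)
  class(out) <- c("permanova", "data.frame")
  out
}

#' Homogeneity of multivariate dispersions (PERMDISP)
#'
#' Distances of nests to their group spatial median in principal-coordinate
#' space, compared across groups by a permutation F test. Delegates to
#' \code{vegan::betadisper} (which applies the standard correction for
#' negative eigenvalues of the semi-metric Bray-Curtis embedding) and
#' \code{vegan::permutest}.
#'
#' @param d \code{dist} object.
#' @param groups factor-like group labels, one per nest in label order.
#' @param n_perm number of permutations (>= 1).
#' @param seed optional integer seed.
#' @return List with \code{F}, \code{p}, \code{n_perm} and the per-group
#'   mean distances to the group median.
#' @export
permdisp <- function(d, groups, n_perm = 999, seed = NULL) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("each group needs at least 2 members")
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  bd <- vegan::betadisper(d, groups, type = "median")
  pt <- vegan::permutest(bd, permutations = n_perm)
  list(F = unname(pt$tab[1, "F"]), p = unname(pt$tab[1, "Pr(>F)"]),
       n_perm = n_perm,
       group_means = tapply(bd$distances, groups, mean))
}

#' Beta regression with a logit mean link and constant precision
#'
#' Maximum-likelihood beta regression for responses in (0, 1) such as
#' Pielou evenness: \eqn{y ~ Beta(\mu\phi, (1-\mu)\phi)} with
#' \eqn{logit(\mu) = X\beta} and a single precision \eqn{\phi}. Responses on
#' the boundary are shrunk by the standard transform
#' \eqn{(y(n-1) + 0.5)/n} and the shrink is recorded. Term significance is
#' assessed with Wald chi-square tests from the observed information.
#'
#' @param y numeric responses in [0, 1].
#' @param design data.frame of covariates.
#' @param formula RHS-only model formula; default
#'   \code{~ age_class * connectivity}.
#' @return List of class \code{"beta_regression"}: \code{coefficients}
#'   (data.frame with estimate, se, wald_chisq, p), \code{terms}
#'   (per-term aggregated Wald tests), \code{phi}, \code{logLik},
#'   \code{fitted}, \code{shrunk}, \code{converged}.
#' @export
beta_regression <- function(y, design, formula = ~ age_class * connectivity) {
  if (any(y < 0 | y > 1)) stop("responses must lie in [0, 1]")
  n <- length(y)
  shrunk <- any(y <= 0 | y >= 1)
  if (shrunk) y <- (y * (n - 1) + 0.5) / n
  X <- stats::model.matrix(formula, design)
  if (nrow(X) != n) stop("design rows do not match responses")
  p <- ncol(X)

  negll <- function(par) {
    eta <- drop(X %*% par[seq_len(p)])
    mu <- stats::plogis(eta)
    mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
    phi <- exp(par[p + 1L])
    -sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
  }
  b0 <- stats::coef(stats::lm.fit(X, stats::qlogis(y)))
  b0[is.na(b0)] <- 0
  fit <- stats::optim(c(b0, log_phi = log(10)), negll, method = "BFGS",
                      hessian = TRUE, control = list(maxit = 500))
  if (fit$convergence != 0)
    stop("beta regression did not converge (optim code ", fit$convergence,
         ", ", fit$counts[1], " function evaluations)")
  est <- fit$par[seq_len(p)]
  V <- tryCatch(solve(fit$hessian), error = function(e)
    stop("beta regression information matrix is singular"))
  se <- sqrt(diag(V)[seq_len(p)])
  wald <- (est / se)^2
  coefs <- data.frame(term = colnames(X), estimate = est, se = se,
                      wald_chisq = wald,
                      p = stats::pchisq(wald, 1, lower.tail = FALSE),
                      stringsAsFactors = FALSE)
  assign_ <- attr(X, "assign")
  labs <- attr(stats::terms(formula), "term.labels")
  term_rows <- lapply(seq_along(labs), function(k) {
    idx <- which(assign_ == k)
    W <- drop(t(est[idx]) %*% solve(V[idx, idx, drop = FALSE]) %*% est[idx])
    data.frame(term = labs[k], df = length(idx), wald_chisq = W,
               p = stats::pchisq(W, length(idx), lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  structure(list(coefficients = coefs, terms = do.call(rbind, term_rows),
                 phi = unname(exp(fit$par[p + 1L])), logLik = -fit$value,
                 fitted = stats::plogis(drop(X %*% est)),
                 shrunk = shrunk, converged = TRUE),
            class = "beta_regression")
}

#' @export
print.beta_regression <- function(x, ...) {
  cat("Beta regression (logit link, constant precision phi =",
      format(x$phi, digits = 4), ")\n")
  print(x$coefficients, row.names = FALSE)
  cat("Wald tests by term:\n")
  print(x$terms, row.names = FALSE)
  invisible(x)
}

#' Rank-abundance summaries by nest age class
#'
#' Per nest, each group's relative abundance (count over nest total); per
#' age class, the mean and standard error of those relative abundances per
#' group. Groups are ordered by decreasing pooled mean relative abundance,
#' ties broken alphabetically by group id. SE is flagged NA for classes with
#' a single nest.
#'
#' @param ds a \code{"study_dataset"}.
#' @param by_age split by age class (default TRUE); FALSE pools all nests
#'   into one class \code{"all"}.
#' @return data.frame: class, group, rank, mean_rel, se.
#' @export
rank_abundance <- function(ds, by_age = TRUE) {
  rel <- ds$abundance / rowSums(ds$abundance)
  cls <- if (by_age) ds$metadata$age_class[match(rownames(rel),
                                                 ds$metadata$nest_id)]
         else rep("all", nrow(rel))
  if (any(table(cls) < 1L) || length(unique(cls)) == 0L)
    stop("each class needs at least one nest")
  pooled <- colMeans(rel)
  ord <- order(-pooled, colnames(rel))
  out <- list()
  for (cl in sort(unique(cls))) {
    sub <- rel[cls == cl, , drop = FALSE]
    m <- colMeans(sub)
    se <- if (nrow(sub) >= 2L)
      apply(sub, 2L, stats::sd) / sqrt(nrow(sub)) else rep(NA_real_, ncol(sub))
    out[[cl]] <- data.frame(class = cl, group = colnames(rel)[ord],
                            rank = seq_along(ord), mean_rel = m[ord],
                            se = se[ord], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
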