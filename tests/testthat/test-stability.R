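test_that("zero-variance draws land exactly on the strength means", {
  p0 <- strength_params(sigma = 0)
  # pure consumer-resource pair
  web <- manual_web(c("pred1", "prey1"),
                    links = data.frame(consumer = "pred1", resource = "prey1"))
  A <- sample_interaction_matrix(web, p0)
  expect_equal(A["prey1", "pred1"], -0.1)  # effect of consumer on resource
  expect_equal(A["pred1", "prey1"], +0.1)  # effect of resource on consumer
  expect_equal(unname(diag(A)), c(-1, -1))

  # a taxon preying on a competitor: trophic and competition draws sum
  web2 <- manual_web(c("a", "b"),
                     links = data.frame(consumer = "a", resource = "b"),
                     competition = data.frame(a = "a", b = "b"))
  A2 <- sample_interaction_matrix(web2, p0)
  expect_equal(A2["b", "a"], -0.2)  # consumption -0.1 plus competition -0.1
  expect_equal(A2["a", "b"], 0.0)   # benefit +0.1 plus competition -0.1
})

test_that("sampled strengths follow N(mu, sigma) per link", {
  set.seed(21)
  web <- manual_web(c("pred1", "prey1"),
                    links = data.frame(consumer = "pred1", resource = "prey1"))
  draws <- replicate(4000, {
    A <- sample_interaction_matrix(web, strength_params())
    c(A["prey1", "pred1"], A["pred1", "prey1"])
  })
  expect_equal(mean(draws[1, ]), -0.1, tolerance = 0.005)
  expect_equal(mean(draws[2, ]), +0.1, tolerance = 0.005)
  expect_equal(sd(draws[1, ]), 0.05, tolerance = 0.005)
})

test_that("community matrix scales rows by relative abundance", {
  A <- matrix(c(-1, 0.1, -0.1, -1), 2, 2)  # column-major
  M <- community_matrix(c(0.5, 0.5), A)
  expect_equal(M, 0.5 * A)
  expect_equal(M[1, 2], -0.05)
  expect_error(community_matrix(c(0.5, 0.5, 0.5), A), "dimension|sum")
  expect_error(community_matrix(c(0.7, 0.5), A), "sum to 1")
  # even abundances: M = A / n exactly, so eigenvalues are eigen(A)/n
  set.seed(3)
  B <- matrix(rnorm(25), 5, 5); diag(B) <- -1
  M2 <- community_matrix(rep(1 / 5, 5), B)
  expect_equal(sort(Re(eigen(M2)$values)), sort(Re(eigen(B)$values) / 5),
               tolerance = 1e-12)
})

test_that("leading eigenvalue real part matches closed forms", {
  expect_equal(leading_eigen_real(-diag(3)), -1)
  M <- matrix(c(-0.5, 0.05, -0.05, -0.5), 2, 2)  # eigenvalues -0.5 +- 0.05i
  expect_equal(leading_eigen_real(M), -0.5)
  expect_equal(leading_eigen_real(diag(c(-0.2, -0.7))), -0.2)
  expect_error(leading_eigen_real(matrix(1, 2, 3)), "square")
})

test_that("rewiring permutes off-diagonals and fixes the diagonal", {
  set.seed(8)
  A <- matrix(rnorm(36), 6, 6); diag(A) <- -1
  off <- row(A) != col(A)
  for (i in 1:20) {
    B <- rewire(A)
    expect_identical(diag(B), diag(A))
    expect_equal(sort(B[off]), sort(A[off]))
  }
  # n = 2: both permutations (swap / stay) occur across seeds
  A2 <- matrix(c(-1, 2, 3, -1), 2, 2)
  outcomes <- replicate(100, rewire(A2)[1, 2])
  expect_setequal(unique(outcomes), c(2, 3))
})

test_that("link-free webs give Re(lambda1) = -min(d) in every replicate", {
  web <- manual_web(c("a", "b", "c", "d"))
  res <- nest_stability(web, scenario_spec("even", "observed",
                                           n_reps = 10, seed = 1))
  expect_true(all(res$replicates == -0.25))
  expect_equal(res$response, log(0.25))
  expect_true(res$stable)
  # uneven abundances: -min(d), replicate-for-replicate
  web2 <- manual_web(c("a", "b", "c"),
                     rel_abund = c(a = 0.7, b = 0.2, c = 0.1))
  res2 <- nest_stability(web2, scenario_spec("observed", "observed",
                                             n_reps = 10, seed = 1))
  expect_true(all(res2$replicates == -0.1))
})

test_that("two-member consumer-resource stability matches a direct oracle", {
  # Oracle: direct simulation of the closed-form 2x2 eigenvalue, written
  # without the package's sampling path. M = A*/2 with diagonal -1 and
  # off-diagonals u ~ N(0.1, 0.05), v ~ N(-0.1, 0.05):
  # lambda1 = (-1 + sqrt(max(uv, 0))) / 2 whenever uv > 0, else -1/2.
  set.seed(77)
  u <- rnorm(2e5, 0.1, 0.05); v <- rnorm(2e5, -0.1, 0.05)
  oracle <- mean(ifelse(u * v > 0, (-1 + sqrt(pmax(u * v, 0))) / 2, -0.5))
  web <- manual_web(c("pred1", "prey1"),
                    links = data.frame(consumer = "pred1", resource = "prey1"))
  res <- nest_stability(web, scenario_spec("even", "observed",
                                           n_reps = 10000, seed = 5))
  se <- sd(res$replicates) / sqrt(10000)
  expect_lt(abs(res$mean_re_lambda1 - oracle), 4 * se + 1e-4)
})

test_that("even plus randomized responses depend only on the value multiset", {
  # two 4-member webs with equal n and link counts but different arrangement
  w1 <- manual_web(c("a", "b", "c", "d"),
                   links = data.frame(consumer = c("a", "c"),
                                      resource = c("b", "d")))
  w2 <- manual_web(c("a", "b", "c", "d"),
                   links = data.frame(consumer = c("a", "a"),
                                      resource = c("b", "c")))
  r1 <- nest_stability(w1, scenario_spec("even", "randomized",
                                         n_reps = 4000, seed = 13))
  r2 <- nest_stability(w2, scenario_spec("even", "randomized",
                                         n_reps = 4000, seed = 14))
  se <- sqrt(var(r1$replicates) / 4000 + var(r2$replicates) / 4000)
  expect_lt(abs(r1$mean_re_lambda1 - r2$mean_re_lambda1), 4 * se + 1e-4)
})

test_that("denser and larger communities are less stable (May's direction)", {
  resp <- vapply(c(6, 10, 14), function(n) {
    nest_stability(clique_web(n),
                   scenario_spec("even", "observed", n_reps = 200,
                                 seed = n))$response
  }, numeric(1))
  expect_true(all(diff(resp) < 0))
})

test_that("scenario runs cross nests, scenarios and parameter grids deterministically", {
  web <- manual_web(c("a", "b", "c"),
                    links = data.frame(consumer = "a", resource = "b"),
                    competition = data.frame(a = "b", b = "c"),
                    rel_abund = c(a = 0.5, b = 0.3, c = 0.2),
                    nest_id = "n1")
  res <- run_scenarios(list(n1 = web), n_reps = 10, seed = 3)
  expect_equal(nrow(res), 4L)
  expect_setequal(res$scenario, c("observed_observed", "observed_randomized",
                                  "even_observed", "even_randomized"))
  grid <- lapply(c(-0.05, -0.1, -0.2), function(m)
    strength_params(mu_consumption = m, mu_benefit = -m, mu_competition = m))
  res3 <- run_scenarios(list(n1 = web), params_grid = grid, n_reps = 10, seed = 3)
  expect_equal(nrow(res3), 12L)
  res3b <- run_scenarios(list(n1 = web), params_grid = grid, n_reps = 10, seed = 3)
  expect_identical(res3, res3b)
  expect_true(all(is.na(res$error)))
})

test_that("scenario spec validates replicate counts", {
  expect_error(scenario_spec(n_reps = 0), "n_reps")
  expect_equal(scenario_spec()$n_reps, 50)
  expect_error(strength_params(sigma = -1), "sigma")
  expect_error(strength_params(diagonal = 0), "negative")
})
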