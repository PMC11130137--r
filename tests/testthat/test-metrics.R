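test_that("Pielou evenness matches hand computations and flags S < 2", {
  expect_equal(pielou_evenness(c(5, 5, 5, 5))$J, 1)
  r <- pielou_evenness(c(75, 25))
  expect_equal(r$H, -(0.75 * log(0.75) + 0.25 * log(0.25)))
  expect_equal(r$J, 0.8112781, tolerance = 1e-6)
  one <- pielou_evenness(c(10, 0, 0))
  expect_false(one$defined)
  expect_true(is.na(one$J))
  expect_equal(one$S, 1L)
  expect_error(pielou_evenness(c(0, 0)), "all counts are zero")
  # invariant to rescaling all counts
  set.seed(1)
  x <- rpois(8, 20) + 1
  expect_equal(pielou_evenness(x)$J, pielou_evenness(7 * x)$J)
})

test_that("Bray-Curtis distances match the defining formula", {
  ab <- rbind(n1 = c(3, 1), n2 = c(1, 3), n3 = c(3, 1), n4 = c(1, 0))
  colnames(ab) <- c("g1", "g2")
  d <- as.matrix(bray_curtis(ab))
  expect_equal(d["n1", "n3"], 0)
  expect_equal(d["n1", "n2"], 0.5)  # (2+2)/(4+4)
  ab2 <- rbind(n1 = c(1, 0), n2 = c(0, 1))
  expect_equal(as.matrix(bray_curtis(ab2))["n1", "n2"], 1)
  ab3 <- rbind(n1 = c(1, 2), n2 = c(0, 0))
  expect_error(bray_curtis(ab3), "all-zero nest")
})

test_that("PERMANOVA matches adonis2 on the observed partition", {
  ds <- generate_dataset(preset_paperlike(seed = 6))
  d <- bray_curtis(ds$abundance)
  res <- permanova(d, ds$metadata, ~ age_class * connectivity,
                   n_perm = 49, seed = 1)
  ref <- vegan::adonis2(d ~ age_class * connectivity, data = ds$metadata,
                        permutations = 49, by = "terms")
  expect_equal(res$SS[1:4], ref$SumOfSqs[1:4], tolerance = 1e-10)
  expect_equal(res$R2[1:4], ref$R2[1:4], tolerance = 1e-10)
  expect_equal(res$F[1:3], ref$F[1:3], tolerance = 1e-10)
  expect_equal(sum(res$R2[1:4]), 1, tolerance = 1e-12)
  expect_true(all(res$p[1:3] > 0))
})

test_that("PERMANOVA on n = 6 equals exhaustive enumeration", {
  counts <- two_group_counts(n_per = 3, shift = 25, seed = 2)
  groups <- rep(c("A", "B"), each = 3)
  D <- as.matrix(bray_curtis(counts))
  design <- data.frame(nest_id = rownames(counts), grp = groups,
                       stringsAsFactors = FALSE)
  perms <- all_perms(6)
  res <- permanova(as.dist(D), design, ~ grp, permutations = perms)
  # observed pseudo-F against the independent direct-SS oracle
  expect_equal(res$F[1], brute_permanova_F(D, groups), tolerance = 1e-10)
  # exact p from full enumeration with the oracle statistic
  Fs <- apply(perms, 1, function(p) brute_permanova_F(D[p, p], groups))
  expect_equal(res$p[1], mean(Fs >= res$F[1] - 1e-12), tolerance = 1e-12)
})

test_that("PERMANOVA validates inputs", {
  counts <- two_group_counts()
  d <- bray_curtis(counts)
  design <- data.frame(nest_id = rownames(counts),
                       grp = rep("same", nrow(counts)),
                       connectivity = seq_len(nrow(counts)))
  expect_error(permanova(d, design, ~ grp), "constant predictor")
  design2 <- data.frame(nest_id = paste0("x", 1:6), grp = rep(1:2, 3))
  expect_error(permanova(d, design2, ~ grp), "do not match")
})

test_that("no between-group signal means R2 near zero and large p", {
  pts <- matrix(rpois(24, 20), 6, 4)
  counts <- rbind(pts, pts)  # identical point clouds per group
  rownames(counts) <- sprintf("n%02d", 1:12)
  d <- bray_curtis(counts + 1)
  design <- data.frame(nest_id = rownames(counts),
                       grp = rep(c("A", "B"), each = 6))
  res <- permanova(d, design, ~ grp, n_perm = 199, seed = 4)
  expect_lt(res$R2[1], 0.05)
  expect_gt(res$p[1], 0.5)
})

test_that("PERMDISP separates dispersion, not location", {
  # equal dispersion: duplicated cloud
  pts <- matrix(rnorm(20), 10, 2)
  X <- rbind(pts, pts + 5)  # shifted copy: same dispersion
  d <- dist(X)
  groups <- rep(c("A", "B"), each = 10)
  res <- permdisp(d, groups, n_perm = 199, seed = 2)
  expect_gt(res$p, 0.2)
  # one group scaled x3 around its centroid: detectable dispersion difference
  Y <- rbind(pts, 3 * pts)
  res2 <- permdisp(dist(Y), groups, n_perm = 999, seed = 2)
  expect_lt(res2$p, 0.05)
  expect_error(permdisp(d, c("A", rep("B", 19))), "at least 2 members")
  expect_error(permdisp(d, groups, n_perm = 0), "n_perm")
})

test_that("beta regression recovers generating coefficients", {
  set.seed(31)
  n <- 200
  age <- factor(sample(c("new", "old"), n, replace = TRUE),
                levels = c("new", "old"))
  eta <- -0.3 + 0.8 * (age == "old")
  mu <- plogis(eta); phi <- 40
  y <- rbeta(n, mu * phi, (1 - mu) * phi)
  fit <- beta_regression(y, data.frame(age_class = age), ~ age_class)
  b_age <- fit$coefficients$estimate[fit$coefficients$term == "age_classold"]
  expect_lt(abs(b_age - 0.8), 0.15)
  expect_equal(fit$phi, 40, tolerance = 0.25 * 40)
  expect_false(fit$shrunk)
})

test_that("beta regression handles boundary responses by shrinking", {
  set.seed(32)
  y <- c(1.0, rbeta(60, 8, 4))
  design <- data.frame(age_class = factor(rep(c("new", "old"), length.out = 61)))
  fit <- beta_regression(y, design, ~ age_class)
  expect_true(fit$shrunk)
  expect_true(fit$converged)
  expect_error(beta_regression(c(0.5, 1.2), design[1:2, , drop = FALSE],
                               ~ age_class), "lie in")
})

test_that("beta regression type-I error is controlled under the null", {
  set.seed(33)
  rejected <- 0; pvals <- numeric(40)
  for (k in 1:40) {
    n <- 80
    age <- factor(rep(c("new", "old"), n / 2), levels = c("new", "old"))
    y <- rbeta(n, 0.6 * 25, 0.4 * 25)  # no age effect
    fit <- beta_regression(y, data.frame(age_class = age), ~ age_class)
    pvals[k] <- fit$terms$p[fit$terms$term == "age_class"]
    rejected <- rejected + (pvals[k] < 0.05)
  }
  expect_lte(rejected, 6)          # binomial(40, 0.05): P(X > 6) < 0.3%
  expect_gt(mean(pvals), 0.3)      # roughly uniform p-values
  expect_lt(mean(pvals), 0.7)
})

test_that("rank-abundance summaries order groups and flag single-nest SE", {
  md <- data.frame(nest_id = "n1", age_class = "old", connectivity = 1,
                   moisture = .4, pH = 4.5, canopy_openness = .3, x = 0, y = 0)
  ab <- matrix(c(2L, 2L), 1, dimnames = list("n1", c("g_b", "g_a")))
  ds1 <- study_dataset(md, ab, adjacency = toy_adjacency(),
                       catalog = data.frame(id = c("g_a", "g_b"),
                                            association = "obligate"))
  ra1 <- rank_abundance(ds1, by_age = FALSE)
  expect_equal(ra1$mean_rel, c(0.5, 0.5))
  expect_true(all(is.na(ra1$se)))
  expect_identical(ra1$group, c("g_a", "g_b"))  # tie broken by group id

  md2 <- rbind(md, within(md, nest_id <- "n2"))
  ab2 <- matrix(c(1L, 3L, 3L, 1L), 2, byrow = TRUE,
                dimnames = list(c("n1", "n2"), c("g_a", "g_b")))
  ds2 <- study_dataset(md2, ab2, adjacency = toy_adjacency(),
                       catalog = data.frame(id = c("g_a", "g_b"),
                                            association = "obligate"))
  ra2 <- rank_abundance(ds2, by_age = FALSE)
  expect_equal(ra2$mean_rel, c(0.5, 0.5))
  expect_equal(ra2$se, c(0.25, 0.25))
})

test_that("evenness table joins nest covariates", {
  ds <- generate_dataset(preset_paperlike(seed = 8))
  ev <- evenness_table(ds)
  expect_equal(nrow(ev), 51L)
  expect_true(all(c("nest_id", "age_class", "S", "H", "J") %in% names(ev)))
  expect_true(all(ev$J[ev$defined] >= 0 & ev$J[ev$defined] <= 1))
})
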