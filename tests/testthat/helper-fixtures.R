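# Shared fixtures and independent oracles for the test suite.

# Tiny 4-group adjacency: one predator-prey pair plus two detritivores
# sharing nest food; prey also eats nest food.
toy_adjacency <- function() {
  general_adjacency(
    data.frame(
      consumer = c("pred1", "prey1", "det1", "det2"),
      resource = c("prey1", "nest_food", "nest_food", "nest_food"),
      stringsAsFactors = FALSE),
    nodes = c("pred1", "prey1", "det1", "det2", "ant_brood", "nest_food"))
}

toy_counts <- function(pred1 = 10, prey1 = 20, det1 = 30, det2 = 40) {
  c(pred1 = pred1, prey1 = prey1, det1 = det1, det2 = det2)
}

toy_thresholds <- function(value = 0) {
  stats::setNames(rep(value, 4), c("pred1", "prey1", "det1", "det2"))
}

# Hand-built local web, bypassing build_local_web, for stability unit tests
# that need full control over links and competition.
manual_web <- function(members, links = NULL, competition = NULL,
                       rel_abund = NULL, nest_id = "manual") {
  if (is.null(links))
    links <- data.frame(consumer = character(0), resource = character(0))
  if (is.null(competition))
    competition <- data.frame(a = character(0), b = character(0))
  if (is.null(rel_abund))
    rel_abund <- stats::setNames(rep(1 / length(members), length(members)),
                                 members)
  structure(list(nest_id = nest_id, members = members, links = links,
                 competition = competition, rel_abund = rel_abund),
            class = "local_food_web")
}

# Full competition clique of n detritivores all sharing nest food.
clique_web <- function(n) {
  members <- sprintf("g%02d", seq_len(n))
  pairs <- utils::combn(members, 2L)
  manual_web(members,
             competition = data.frame(a = pairs[1, ], b = pairs[2, ],
                                      stringsAsFactors = FALSE),
             nest_id = sprintf("clique%d", n))
}

# All permutations of 1..n (for exhaustive permutation tests).
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# Independent one-factor PERMANOVA oracle from the direct sum-of-squares
# decomposition of the distance matrix (no Gower centering, no hat matrices).
brute_permanova_F <- function(D, groups) {
  n <- nrow(D)
  ss_total <- sum(D[lower.tri(D)]^2) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- D[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[lower.tri(sub)]^2) / length(idx)
  }
  k <- length(unique(groups))
  ((ss_total - ss_within) / (k - 1)) / (ss_within / (n - k))
}

# Synthetic nest table for distance-based tests: two compositional groups.
two_group_counts <- function(n_per = 3, shift = 6, seed = 42) {
  set.seed(seed)
  n <- 2 * n_per
  base <- matrix(rpois(n * 4, 20), n, 4)
  base[seq_len(n_per), 1] <- base[seq_len(n_per), 1] + shift
  rownames(base) <- sprintf("n%02d", seq_len(n))
  colnames(base) <- sprintf("g%d", 1:4)
  base
}
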