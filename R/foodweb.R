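#' Per-group rarity thresholds
#'
#' For each functional group, the empirical quantile (linear interpolation,
#' the classic type-7 definition) of its counts across all nests. A group is
#' later dropped from a nest's local web when its count falls strictly below
#' its threshold. Zero counts are included in the quantile by default:
#' "observed nest abundances" is read as all sampled nests, occupied or not;
#' set \code{occupied_only = TRUE} to restrict to nests where the group is
#' present.
#'
#' @param abundance nest-by-group count matrix (as in a
#'   \code{"study_dataset"}).
#' @param q quantile level in (0, 1); default 0.1.
#' @param occupied_only if TRUE, compute each group's quantile over positive
#'   counts only.
#' @return Named numeric vector of thresholds, class \code{"rarity_thresholds"}
#'   with attributes \code{q} and \code{occupied_only}.
#' @examples
#' ab <- cbind(g1 = 1:10, g2 = rep(4L, 10))
#' rownames(ab) <- paste0("n", 1:10)
#' rarity_thresholds(ab, q = 0.1)  # g1 = 1.9, g2 = 4
#' @export
rarity_thresholds <- function(abundance, q = 0.1, occupied_only = FALSE) {
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1)
    stop("q must be a single value strictly inside (0, 1)")
  if (nrow(abundance) < 2L) stop("need at least 2 nests to define thresholds")
  thr <- vapply(colnames(abundance), function(g) {
    x <- abundance[, g]
    if (occupied_only) x <- x[x > 0]
    if (length(x) == 0L) return(0)
    unname(stats::quantile(x, probs = q, type = 7))
  }, numeric(1))
  structure(thr, q = q, occupied_only = occupied_only,
            class = "rarity_thresholds")
}

#' Build one nest's local food web
#'
#' Restricts the general adjacency to the groups present at the nest and not
#' rare there. A group is a member iff its count is positive and at least its
#' rarity threshold ("fell below" is strict: a count equal to the threshold
#' is retained). Trophic links are the induced subgraph among members; basal
#' resources are aggregated out of the dynamical system and act only through
#' the competition pairs they generate (two members compete when their diets
#' share a basal resource). Relative abundances are renormalised over the
#' surviving members.
#'
#' @param counts named abundance vector for one nest (names = group ids).
#' @param adj a \code{"general_adjacency"}.
#' @param thresholds a \code{"rarity_thresholds"} vector (or named numeric).
#' @param nest_id identifier carried through to results.
#' @return An object of class \code{"local_food_web"}: \code{nest_id},
#'   \code{members} (ordered group ids), \code{links} (data.frame
#'   consumer/resource among members), \code{competition} (data.frame of
#'   unordered member pairs sharing a basal resource), \code{rel_abund}
#'   (named, sums to 1).
#' @export
build_local_web <- function(counts, adj, thresholds, nest_id = "nest") {
  groups <- setdiff(adj$nodes, basal_resources())
  miss <- setdiff(groups, names(counts))
  if (length(miss))
    stop("counts missing group(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(groups, names(thresholds))
  if (length(miss))
    stop("thresholds missing group(s): ", paste(miss, collapse = ", "))
  counts <- counts[groups]
  members <- groups[counts > 0 & counts >= thresholds[groups]]
  if (length(members) == 0L)
    stop("empty local web: no functional group survives filtering at nest '",
         nest_id, "'")
  e <- adj$edges
  links <- e[e$consumer %in% members & e$resource %in% members, , drop = FALSE]
  rownames(links) <- NULL
  basal_diets <- lapply(members, function(g)
    intersect(diet_of(adj, g), basal_resources()))
  names(basal_diets) <- members
  comp <- list()
  if (length(members) >= 2L) {
    pairs <- utils::combn(members, 2L)
    share <- apply(pairs, 2L, function(p)
      length(intersect(basal_diets[[p[1]]], basal_diets[[p[2]]])) > 0L)
    comp <- data.frame(a = pairs[1, share], b = pairs[2, share],
                       stringsAsFactors = FALSE)
  } else {
    comp <- data.frame(a = character(0), b = character(0))
  }
  rel <- counts[members] / sum(counts[members])
  structure(list(nest_id = nest_id, members = members, links = links,
                 competition = comp, rel_abund = rel),
            class = "local_food_web")
}

#' @export
print.local_food_web <- function(x, ...) {
  cat("Local food web '", x$nest_id, "': ", length(x$members),
      " members, ", nrow(x$links), " trophic links, ", nrow(x$competition),
      " competition pairs\n", sep = "")
  invisible(x)
}

#' Community size of a local web
#'
#' The number of functional groups retained in the nest's local food web
#' after presence and rarity filtering.
#'
#' @param web a \code{"local_food_web"}.
#' @return Integer count of members.
#' @export
community_size <- function(web) length(web$members)

#' Build local webs for every nest of a dataset
#'
#' @param ds a \code{"study_dataset"}.
#' @param q rarity quantile level; default 0.1.
#' @param occupied_only passed to [rarity_thresholds()].
#' @return Named list of \code{"local_food_web"} objects; nests whose webs
#'   are empty after filtering are dropped with a warning.
#' @export
build_all_webs <- function(ds, q = 0.1, occupied_only = FALSE) {
  thr <- rarity_thresholds(ds$abundance, q = q, occupied_only = occupied_only)
  webs <- list()
  dropped <- character(0)
  for (id in rownames(ds$abundance)) {
    w <- tryCatch(build_local_web(ds$abundance[id, ], ds$adjacency, thr,
                                  nest_id = id),
                  error = function(e) NULL)
    if (is.null(w)) dropped <- c(dropped, id) else webs[[id]] <- w
  }
  if (length(dropped))
    warning("dropped nest(s) with empty local web: ",
            paste(dropped, collapse = ", "))
  webs
}
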