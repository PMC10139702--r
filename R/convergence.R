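#' Define a focal branch set
#'
#' A focal branch set names the branches of the species tree on which
#' convergence is assessed, e.g. the three terminal branches leading to the
#' myrmecophagous lineages, or the terminal branches of their
#' non-myrmecophagous sister species as a control.
#'
#' @param name Label for the set (e.g. `"myrmecophagous-3"`).
#' @param branches Branches identified by their child node: either a
#'   character vector of tip names (terminal branches), or a list whose
#'   elements are single tip names or character vectors of >= 2 tips (the
#'   branch above the most recent common ancestor of those tips).
#' @param mode `"all"` — an event requires the same derived residue on
#'   every branch of the set simultaneously; `"pairwise"` — every unordered
#'   branch pair with a shared derived residue yields an event.
#' @return An object of class `focal_set`.
#' @export
focal_set <- function(name, branches, mode = c("all", "pairwise")) {
  mode <- match.arg(mode)
  if (is.character(branches)) branches <- as.list(branches)
  if (!is.list(branches) || length(branches) < 2L)
    stop("a focal set needs at least 2 branches", call. = FALSE)
  labels <- vapply(branches, function(b) {
    if (length(b) == 1L) b else paste0("mrca(", paste(b, collapse = ","), ")")
  }, character(1))
  structure(list(name = name, branches = branches, labels = labels,
                 mode = mode),
            class = "focal_set")
}

#' @export
print.focal_set <- function(x, ...) {
  cat("Focal branch set '", x$name, "' (mode: ", x$mode, ")\n", sep = "")
  cat(paste0("  - ", x$labels, collapse = "\n"), "\n")
  invisible(x)
}

# Resolve a focal set against a tree: child/parent node ids and edge index
# per branch, with a hard disjointness check (no branch ancestral to
# another, no duplicates).
resolve_focal_set <- function(tree, set) {
  stopifnot(inherits(set, "focal_set"))
  edge <- tree$edge
  n_tip <- length(tree$tip.label)
  child <- vapply(set$branches, function(b) {
    miss <- setdiff(b, tree$tip.label)
    if (length(miss))
      stop("focal tip(s) not in tree: ", paste(miss, collapse = ", "),
           call. = FALSE)
    if (length(b) == 1L) match(b, tree$tip.label)
    else ape::getMRCA(tree, b)
  }, integer(1))
  if (anyDuplicated(child))
    stop("focal set '", set$name, "': duplicate branches", call. = FALSE)
  parent_of <- function(v) edge[match(v, edge[, 2]), 1]
  ancestors <- function(v) {
    out <- integer(0)
    repeat {
      p <- parent_of(v)
      if (is.na(p)) break
      out <- c(out, p); v <- p
    }
    out
  }
  anc <- lapply(child, ancestors)
  for (i in seq_along(child)) {
    if (is.na(parent_of(child[i])))
      stop("focal set '", set$name, "': branch above the root node '",
           set$labels[i], "' does not exist", call. = FALSE)
    for (j in seq_along(child)) {
      if (i != j && child[i] %in% anc[[j]])
        stop("focal set '", set$name, "': branch '", set$labels[i],
             "' is ancestral to '", set$labels[j],
             "'; focal branches must be disjoint", call. = FALSE)
    }
  }
  data.frame(label = set$labels, child = child,
             parent = vapply(child, parent_of, integer(1)),
             edge = match(child, edge[, 2]),
             is_tip = child <= n_tip,
             stringsAsFactors = FALSE)
}

# Sites usable for a branch set: no missing data in any focal terminal
# branch's tip. Shared by observed counting and the expected-count null.
usable_sites <- function(posteriors, res) {
  aln <- posteriors$alignment
  ok <- rep(TRUE, ncol(aln))
  for (i in which(res$is_tip)) {
    tip <- posteriors$tree$tip.label[res$child[i]]
    ok <- ok & (aln[tip, ] %in% AA_CODES)
  }
  which(ok)
}

# Per-branch from/to state matrices (branches x usable sites) plus backing
# posterior probabilities; the vectorized core shared by substitution
# calling and event counting.
focal_state_matrices <- function(posteriors, set) {
  tree <- posteriors$tree
  res <- resolve_focal_set(tree, set)
  usable <- usable_sites(posteriors, res)
  k <- nrow(res); n <- length(usable)
  from <- to <- matrix("", k, n)
  from_prob <- to_prob <- matrix(1, k, n)
  node_row <- function(v) match(paste0("node", v),
                                rownames(posteriors$map_state))
  for (i in seq_len(k)) {
    pr <- node_row(res$parent[i])
    from[i, ] <- posteriors$map_state[pr, usable]
    from_prob[i, ] <- posteriors$map_prob[pr, usable]
    if (res$is_tip[i]) {
      to[i, ] <- posteriors$alignment[tree$tip.label[res$child[i]], usable]
    } else {
      cr <- node_row(res$child[i])
      to[i, ] <- posteriors$map_state[cr, usable]
      to_prob[i, ] <- posteriors$map_prob[cr, usable]
    }
  }
  list(from = from, to = to, from_prob = from_prob, to_prob = to_prob,
       usable = usable, branches = res)
}

#' Call substitutions on focal branches
#'
#' Compares each focal branch's child state with the MAP reconstruction of
#' its parent node, site by site. On terminal branches the child state is
#' the observed tip residue (extant sequences are data, never
#' reconstructed); on internal branches it is the child node's MAP state.
#' Sites with missing data in any focal tip are unusable for the whole
#' branch set and are skipped (the same site set is used by
#' [expected_counts()]).
#'
#' @param posteriors An [ancestral_posteriors()] result.
#' @param set A [focal_set()].
#' @return List with `calls` (data frame: branch, site, from_state,
#'   to_state, from_prob, to_prob), `usable_sites` (integer vector), and
#'   the resolved branch table.
#' @export
branch_substitutions <- function(posteriors, set) {
  stopifnot(inherits(posteriors, "ancestral_posterior"))
  sm <- focal_state_matrices(posteriors, set)
  hit <- which(sm$from != sm$to, arr.ind = TRUE)
  calls <- data.frame(branch = sm$branches$label[hit[, 1]],
                      site = sm$usable[hit[, 2]],
                      from_state = sm$from[hit],
                      to_state = sm$to[hit],
                      from_prob = sm$from_prob[hit],
                      to_prob = sm$to_prob[hit],
                      stringsAsFactors = FALSE)
  calls <- calls[order(calls$site, calls$branch), , drop = FALSE]
  rownames(calls) <- NULL
  list(calls = calls, usable_sites = sm$usable, branches = sm$branches)
}

#' Classify substitution calls at one site into a convergence event
#'
#' Applies the definitional rule: an event requires a shared derived
#' residue — on every branch of the set in `"all"` mode, or on a branch
#' pair in `"pairwise"` mode. The event is *parallel* when all
#' contributing ancestral (from) states are identical and *convergent*
#' when at least two differ.
#'
#' @param calls Data frame of substitution calls at a single site (as
#'   produced by [branch_substitutions()]).
#' @param n_branches Number of branches in the set.
#' @param mode `"all"` or `"pairwise"`.
#' @return Data frame of events (possibly 0 rows): site, derived_state,
#'   category, branches, from_states.
#' @export
classify_site <- function(calls, n_branches, mode = c("all", "pairwise")) {
  mode <- match.arg(mode)
  empty <- data.frame(site = integer(0), derived_state = character(0),
                      category = character(0), branches = character(0),
                      from_states = character(0), stringsAsFactors = FALSE)
  if (is.null(calls) || nrow(calls) == 0L) return(empty)
  if (length(unique(calls$site)) != 1L)
    stop("classify_site expects calls from a single site", call. = FALSE)
  event_row <- function(rows) {
    data.frame(site = rows$site[1], derived_state = rows$to_state[1],
               category = if (length(unique(rows$from_state)) == 1L)
                 "parallel" else "convergent",
               branches = paste(rows$branch, collapse = ","),
               from_states = paste(rows$from_state, collapse = ","),
               stringsAsFactors = FALSE)
  }
  if (mode == "all") {
    if (nrow(calls) == n_branches &&
        length(unique(calls$to_state)) == 1L)
      return(event_row(calls[order(calls$branch), , drop = FALSE]))
    return(empty)
  }
  out <- list()
  ord <- order(calls$branch)
  calls <- calls[ord, , drop = FALSE]
  n <- nrow(calls)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (calls$to_state[i] == calls$to_state[j])
        out[[length(out) + 1L]] <- event_row(calls[c(i, j), , drop = FALSE])
    }
  }
  if (length(out)) do.call(rbind, out) else empty
}

#' Observed convergent and parallel substitution counts for one gene
#'
#' Runs substitution calling and site classification over a gene and tallies
#' observed convergent, parallel, and combined (pooled) event counts.
#'
#' @inheritParams branch_substitutions
#' @return List with `counts` (named vector: convergent, parallel,
#'   combined), `events` (data frame: site, derived_state, category,
#'   branches, from_states), `usable_sites`, `branches`, `set`.
#' @export
count_observed <- function(posteriors, set) {
  stopifnot(inherits(posteriors, "ancestral_posterior"))
  sm <- focal_state_matrices(posteriors, set)
  ord <- order(sm$branches$label)      # events invariant to listing order
  from <- sm$from[ord, , drop = FALSE]
  to <- sm$to[ord, , drop = FALSE]
  labels <- sm$branches$label[ord]
  k <- length(labels)

  events_for <- function(rows) {
    f <- from[rows, , drop = FALSE]; t_ <- to[rows, , drop = FALSE]
    kk <- length(rows)
    changed <- colSums(f != t_) == kk
    shared <- colSums(t_ == rep(t_[1, ], each = kk)) == kk
    cols <- which(changed & shared)
    if (!length(cols)) return(NULL)
    same_from <- colSums(f[, cols, drop = FALSE] ==
                           rep(f[1, cols], each = kk)) == kk
    data.frame(
      site = sm$usable[cols], derived_state = t_[1, cols],
      category = ifelse(same_from, "parallel", "convergent"),
      branches = paste(labels[rows], collapse = ","),
      from_states = do.call(paste,
                            c(asplit(f[, cols, drop = FALSE], 1), sep = ",")),
      stringsAsFactors = FALSE)
  }

  events <- if (set$mode == "all") list(events_for(seq_len(k)))
  else {
    out <- list()
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
      out[[length(out) + 1L]] <- events_for(c(i, j))
    out
  }
  empty <- classify_site(NULL, k, set$mode)
  events <- do.call(rbind, c(Filter(Negate(is.null), events), list(empty)))
  events <- events[order(events$site, events$branches), , drop = FALSE]
  rownames(events) <- NULL
  counts <- c(convergent = sum(events$category == "convergent"),
              parallel = sum(events$category == "parallel"))
  counts["combined"] <- sum(counts)
  list(counts = counts, events = events,
       usable_sites = sm$usable, branches = sm$branches, set = set)
}
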