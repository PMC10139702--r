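#' Prepare a rooted tree for likelihood computation
#'
#' Validates and post-orders a phylogeny: exactly one root (a trifurcating
#' root is accepted and treated as rooted at that node), branch lengths
#' present and nonnegative, unique tip labels. Use [ape::read.tree()] to
#' parse Newick input.
#'
#' @param tree An [ape::phylo] object.
#' @return The tree, reordered postorder, with validation applied.
#' @export
prepare_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object",
                                     call. = FALSE)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; supply them or estimate them",
         call. = FALSE)
  if (any(is.na(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be nonnegative and non-missing", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("tip labels must be unique", call. = FALSE)
  roots <- setdiff(tree$edge[, 1], tree$edge[, 2])
  if (length(roots) != 1L)
    stop("tree must have exactly one root", call. = FALSE)
  stats::reorder(tree, "postorder")
}

# Tip conditional-likelihood matrices: indicator columns for observed
# residues, all-ones columns for missing data ('-', 'X', ...).
tip_partials <- function(enc_row, n_sites) {
  l <- matrix(0, 20L, n_sites)
  obs <- which(enc_row > 0L)
  l[cbind(enc_row[obs], obs)] <- 1
  if (length(obs) < n_sites) l[, setdiff(seq_len(n_sites), obs)] <- 1
  l
}

# Felsenstein pruning over all sites at once.
#
# Returns partials (list by node id, scaled), per-node log scaling factors,
# per-child-node "down" messages D_v = P_v %*% L_v, per-child transition
# matrices, the root id, and per-site log-likelihoods.
peel <- function(tree, enc, model, edge_p = NULL) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  n_sites <- ncol(enc)
  edge <- tree$edge
  root <- n_tip + 1L
  if (!(root %in% edge[, 1]) || root %in% edge[, 2])
    root <- setdiff(edge[, 1], edge[, 2])

  miss <- setdiff(tree$tip.label, rownames(enc))
  if (length(miss))
    stop("tip(s) missing from alignment: ", paste(miss, collapse = ", "),
         call. = FALSE)

  if (is.null(edge_p)) {
    edge_p <- vector("list", n_node)
    for (k in seq_len(nrow(edge)))
      edge_p[[edge[k, 2]]] <- transition_matrix(model, tree$edge.length[k])
  }

  partial <- vector("list", n_node)
  down <- vector("list", n_node)
  logscale <- matrix(0, n_node, n_sites)
  for (i in seq_len(n_tip))
    partial[[i]] <- tip_partials(enc[tree$tip.label[i], ], n_sites)
  for (i in (n_tip + 1L):n_node)
    partial[[i]] <- matrix(1, 20L, n_sites)

  for (k in seq_len(nrow(edge))) {        # postorder: children complete first
    u <- edge[k, 1]; v <- edge[k, 2]
    if (v > n_tip) {                      # rescale completed internal partial
      s <- apply(partial[[v]], 2L, max)
      s[s == 0] <- 1
      partial[[v]] <- partial[[v]] / rep(s, each = 20L)
      logscale[v, ] <- logscale[v, ] + log(s)
    }
    down[[v]] <- edge_p[[v]] %*% partial[[v]]
    partial[[u]] <- partial[[u]] * down[[v]]
    logscale[u, ] <- logscale[u, ] + logscale[v, ]
  }

  rootlik <- colSums(model$frequencies * partial[[root]])
  site_loglik <- ifelse(rootlik > 0, log(rootlik) + logscale[root, ], -Inf)

  list(partial = partial, logscale = logscale, down = down, edge_p = edge_p,
       root = root, n_tip = n_tip, site_loglik = site_loglik)
}

#' Per-site pruning log-likelihood with conditional partials
#'
#' Computes the log-likelihood of one alignment column on a rooted tree
#' under a reversible amino acid model, by Felsenstein's pruning algorithm
#' with per-node rescaling. Sites whose data are entirely missing have
#' likelihood 1 (log-likelihood 0). An impossible column (e.g. conflicting
#' residues joined by zero-length branches) returns `-Inf`.
#'
#' @param tree Rooted [ape::phylo] with branch lengths.
#' @param alignment Character matrix of aligned residues covering the tree's
#'   tips.
#' @param model An [aa_model()].
#' @param site Column index.
#' @return List with `log_likelihood` (scalar) and `partials` (list by node
#'   id of length-20 conditional likelihood vectors, rescaled; the per-node
#'   log scaling factors are in `log_scale`).
#' @export
site_loglik <- function(tree, alignment, model, site) {
  tree <- prepare_tree(tree)
  validate_alignment(alignment)
  if (site < 1L || site > ncol(alignment))
    stop("site index ", site, " out of bounds [1, ", ncol(alignment), "]",
         call. = FALSE)
  enc <- encode_alignment(alignment[, site, drop = FALSE])
  pe <- peel(tree, enc, model)
  list(log_likelihood = pe$site_loglik[1],
       partials = lapply(pe$partial, function(m) m[, 1]),
       log_scale = pe$logscale[, 1])
}

#' Total log-likelihood of a gene alignment
#'
#' Sum of per-site pruning log-likelihoods over all alignment columns.
#' Entirely missing columns contribute 0.
#'
#' @inheritParams site_loglik
#' @return Scalar log-likelihood (`-Inf` if any site is impossible).
#' @export
gene_loglik <- function(tree, alignment, model) {
  tree <- prepare_tree(tree)
  validate_alignment(alignment)
  pe <- peel(tree, encode_alignment(alignment), model)
  sum(pe$site_loglik)
}

#' Maximum likelihood branch lengths on a fixed topology
#'
#' Re-estimates branch lengths for one gene on the fixed species topology by
#' coordinate-wise bracketed one-dimensional optimization (golden
#' section/parabolic interpolation via [stats::optimize()]), sweeping over
#' branches until the log-likelihood gain per full sweep falls below `tol`.
#'
#' Under a reversible model only the sum of the two branches meeting at a
#' bifurcating root is identifiable; those two branches are optimized
#' jointly on their sum, keeping the split proportional to the input tree
#' (50/50 when both input lengths are zero).
#'
#' @inheritParams site_loglik
#' @param t_max Upper bound per branch (expected substitutions/site).
#' @param tol Convergence tolerance on the per-sweep log-likelihood gain.
#' @param max_sweeps Maximum number of full coordinate sweeps; if reached
#'   without convergence the best tree so far is returned with attribute
#'   `converged = FALSE` and a warning.
#' @return The tree with ML branch lengths; attributes `loglik` (final
#'   log-likelihood), `converged`, `sweeps`.
#' @export
estimate_branch_lengths <- function(tree, alignment, model, t_max = 10,
                                    tol = 1e-6, max_sweeps = 50L) {
  tree <- prepare_tree(tree)
  validate_alignment(alignment)
  enc <- encode_alignment(alignment)
  edge <- tree$edge
  n_tip <- length(tree$tip.label)
  root <- setdiff(edge[, 1], edge[, 2])
  root_kids <- which(edge[, 1] == root)
  joint_root <- length(root_kids) == 2L

  ll_for <- function(len) {
    tr <- tree; tr$edge.length <- len
    sum(peel(tr, enc, model)$site_loglik)
  }

  len <- tree$edge.length
  cur <- ll_for(len)
  free_edges <- if (joint_root) setdiff(seq_len(nrow(edge)), root_kids)
                else seq_len(nrow(edge))
  sweeps <- 0L; converged <- FALSE
  repeat {
    sweeps <- sweeps + 1L
    prev <- cur
    for (k in free_edges) {
      f <- function(t) { l <- len; l[k] <- t; ll_for(l) }
      opt <- optimize(f, c(0, t_max), maximum = TRUE, tol = 1e-7)
      if (opt$objective > cur) { len[k] <- opt$maximum; cur <- opt$objective }
    }
    if (joint_root) {
      s0 <- sum(len[root_kids])
      w <- if (s0 > 0) len[root_kids] / s0 else c(0.5, 0.5)
      f <- function(s) { l <- len; l[root_kids] <- s * w; ll_for(l) }
      opt <- optimize(f, c(0, 2 * t_max), maximum = TRUE, tol = 1e-7)
      if (opt$objective > cur) {
        len[root_kids] <- opt$maximum * w
        cur <- opt$objective
      }
    }
    if (cur - prev < tol) { converged <- TRUE; break }
    if (sweeps >= max_sweeps) break
  }
  if (!converged)
    warning("branch length optimization did not converge in ", max_sweeps,
            " sweeps; returning best tree so far")
  tree$edge.length <- len
  attr(tree, "loglik") <- cur
  attr(tree, "converged") <- converged
  attr(tree, "sweeps") <- sweeps
  tree
}
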