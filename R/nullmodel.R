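#' Expected convergent and parallel substitution counts under the model
#'
#' Computes the model-implied expected number of convergent and parallel
#' substitution events on a focal branch set, integrating over the marginal
#' ancestral-state posteriors at each focal branch's parent node and the
#' branch's transition probabilities.
#'
#' For a branch pair with parent posteriors `q1`, `q2` and transition
#' matrices `P1`, `P2`, the per-site expectations are
#' \deqn{E_{par} = \sum_x q_1(x) q_2(x) \sum_{j \ne x} P_1(x,j) P_2(x,j)}
#' \deqn{E_{conv} = \sum_{x_1 \ne x_2} q_1(x_1) q_2(x_2)
#'   \sum_{j \ne x_1, j \ne x_2} P_1(x_1,j) P_2(x_2,j)}
#' In `"all"` mode with k branches the inner sum runs over a single shared
#' derived residue j distinct from every ancestral state, with the product
#' taken over all k branches. Posteriors at distinct parents are treated as
#' independent, which is enforced structurally by requiring disjoint focal
#' branches. Expectations are summed over the same usable site set as the
#' observed counts.
#'
#' @inheritParams branch_substitutions
#' @param model The [aa_model()] used for the reconstruction.
#' @return Named vector `c(convergent, parallel, combined)` of expected
#'   counts, with attribute `per_site` (matrix of per-site combined and
#'   parallel expectations) and `n_usable_sites`.
#' @export
expected_counts <- function(posteriors, model, set) {
  stopifnot(inherits(posteriors, "ancestral_posterior"),
            inherits(model, "aa_model"), inherits(set, "focal_set"))
  tree <- posteriors$tree
  res <- resolve_focal_set(tree, set)
  usable <- usable_sites(posteriors, res)
  n_s <- length(usable)
  k <- nrow(res)

  q_list <- lapply(seq_len(k), function(i)
    posteriors$prob[[res$parent[i]]][, usable, drop = FALSE])
  p_list <- lapply(seq_len(k), function(i)
    transition_matrix(model, tree$edge.length[res$edge[i]]))

  per_site <- expected_site_counts(q_list, p_list, set$mode)
  out <- c(convergent = sum(per_site[, "combined"]) -
             sum(per_site[, "parallel"]),
           parallel = sum(per_site[, "parallel"]))
  out["combined"] <- sum(out)
  # guard tiny negative round-off
  out[out < 0 & out > -1e-12] <- 0
  attr(out, "per_site") <- per_site
  attr(out, "n_usable_sites") <- n_s
  out
}

#' Per-site expected convergence given posteriors and transition matrices
#'
#' Low-level primitive behind [expected_counts()]: takes the parent-node
#' posterior matrix (20 x sites) and the 20 x 20 transition matrix for
#' each branch, and returns the per-site expected counts of combined
#' (shared-derived-residue) and parallel events. `convergent = combined -
#' parallel` since the ancestral-state cases are disjoint.
#'
#' @param q_list List of 20 x n_sites posterior matrices, one per branch
#'   (columns may also be length-20 vectors for a single site).
#' @param p_list List of 20 x 20 transition matrices, one per branch.
#' @param mode `"all"` or `"pairwise"`.
#' @return Matrix with columns `combined`, `parallel`, one row per site.
#' @export
expected_site_counts <- function(q_list, p_list, mode = c("all", "pairwise")) {
  mode <- match.arg(mode)
  stopifnot(length(q_list) == length(p_list), length(q_list) >= 2L)
  q_list <- lapply(q_list, function(q) {
    q <- as.matrix(q)
    if (nrow(q) != 20L) stop("posteriors must have 20 rows", call. = FALSE)
    q
  })
  k <- length(q_list)
  n_s <- ncol(q_list[[1]])

  # Per-branch "changed-to-j" message: B[j,s] = sum_{x != j} q(x) P(x,j).
  b_msg <- function(q, p) crossprod(p, q) - diag(p) * q

  pair_expect <- function(idx) {
    b <- lapply(idx, function(i) b_msg(q_list[[i]], p_list[[i]]))
    combined <- colSums(Reduce(`*`, b))
    w <- Reduce(`*`, p_list[idx])          # elementwise product of P's
    diag(w) <- 0
    r <- Reduce(`*`, q_list[idx])          # product of parent posteriors
    par <- colSums(r * rowSums(w))
    cbind(combined = combined, parallel = par)
  }

  if (mode == "all") return(pair_expect(seq_len(k)))
  per_site <- matrix(0, n_s, 2,
                     dimnames = list(NULL, c("combined", "parallel")))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
    per_site <- per_site + pair_expect(c(i, j))
  per_site
}

#' Exact Poisson tail probabilities
#'
#' Two-sided bookkeeping for the convergence test: `p_upper = P(X >=
#' observed)` (excess, the focal-branch direction) and `p_lower = P(X <=
#' observed)` (deficit, the sister-branch control direction) for `X ~
#' Poisson(lam)`. Computed by exact tail summation; the degenerate `lam =
#' 0` case gives `p_upper = 1` iff `observed = 0` (else 0) and `p_lower =
#' 1`.
#'
#' @param observed Nonnegative integer count.
#' @param lam Nonnegative Poisson mean (the expected count).
#' @return Named vector `c(p_upper, p_lower)`.
#' @export
poisson_tail <- function(observed, lam) {
  if (length(observed) != 1L || is.na(observed) || observed < 0 ||
      observed != round(observed))
    stop("observed must be a single nonnegative integer", call. = FALSE)
  if (length(lam) != 1L || is.na(lam) || lam < 0)
    stop("lam must be a single nonnegative number", call. = FALSE)
  if (lam == 0)
    return(c(p_upper = as.numeric(observed == 0), p_lower = 1))
  c(p_upper = ppois(observed - 1, lam, lower.tail = FALSE),
    p_lower = ppois(observed, lam))
}

#' Genome-wide convergence test over a table of per-gene results
#'
#' Aggregates per-gene observed and expected counts (Poisson expectations
#' are additive across independent genes), tests the aggregate with exact
#' Poisson tails in both directions, and attaches Benjamini-Hochberg
#' adjusted q-values to the per-gene upper-tail p-values (reported, never
#' used to filter).
#'
#' @param results Data frame of per-gene rows as produced by [run_gene()]
#'   (columns gene, set, mode, obs_*, exp_*, p_upper, p_lower,
#'   n_usable_sites). All rows must share one branch set and mode.
#' @return List with `aggregate` (one-row data frame, gene =
#'   `"GENOME_WIDE"`) and `per_gene` (the input with a `q_upper` column).
#' @export
genome_wide_test <- function(results) {
  if (nrow(results) == 0L) stop("no per-gene results", call. = FALSE)
  if (length(unique(results$set)) != 1L ||
      length(unique(results$mode)) != 1L)
    stop("mixed branch sets/modes; aggregate each set separately",
         call. = FALSE)
  obs <- colSums(results[, c("obs_convergent", "obs_parallel",
                             "obs_combined")])
  exp_ <- colSums(results[, c("exp_convergent", "exp_parallel",
                              "exp_combined")])
  tails <- poisson_tail(obs[["obs_combined"]], exp_[["exp_combined"]])
  aggregate <- data.frame(
    gene = "GENOME_WIDE", set = results$set[1], mode = results$mode[1],
    obs_convergent = obs[["obs_convergent"]],
    obs_parallel = obs[["obs_parallel"]],
    obs_combined = obs[["obs_combined"]],
    exp_convergent = exp_[["exp_convergent"]],
    exp_parallel = exp_[["exp_parallel"]],
    exp_combined = exp_[["exp_combined"]],
    p_upper = tails[["p_upper"]], p_lower = tails[["p_lower"]],
    n_usable_sites = sum(results$n_usable_sites),
    n_genes = nrow(results),
    n_genes_with_events = sum(results$obs_combined > 0),
    stringsAsFactors = FALSE)
  per_gene <- results
  per_gene$q_upper <- p.adjust(per_gene$p_upper, method = "BH")
  list(aggregate = aggregate, per_gene = per_gene)
}

#' Contrast a focal branch set against a control set
#'
#' Places the focal excess test and the control deficit test side by side:
#' observed/expected ratios for both sets, the focal upper-tail p-value
#' (excess) and the control lower-tail p-value (deficit), with direction
#' flags at the given significance level.
#'
#' @param focal,control Aggregate rows from [genome_wide_test()] computed
#'   on the same gene set.
#' @param alpha Significance level for the direction flags.
#' @return One-row data frame contrast report.
#' @export
contrast_branch_sets <- function(focal, control, alpha = 0.05) {
  if (!identical(focal$n_genes, control$n_genes))
    stop("focal and control aggregates cover different gene sets (",
         focal$n_genes, " vs ", control$n_genes, " genes)", call. = FALSE)
  ratio <- function(r) if (r$exp_combined > 0)
    r$obs_combined / r$exp_combined else NA_real_
  data.frame(
    focal_set = focal$set, control_set = control$set,
    focal_observed = focal$obs_combined, focal_expected = focal$exp_combined,
    focal_ratio = ratio(focal), focal_p_upper = focal$p_upper,
    control_observed = control$obs_combined,
    control_expected = control$exp_combined,
    control_ratio = ratio(control), control_p_lower = control$p_lower,
    focal_excess = focal$p_upper < alpha,
    control_deficit = control$p_lower < alpha,
    stringsAsFactors = FALSE)
}
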