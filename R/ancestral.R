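#' Marginal (empirical Bayes) ancestral reconstruction
#'
#' Computes, for every internal node and alignment column, the exact
#' posterior distribution over the 20 amino acids given the tip data, the
#' tree with its branch lengths, and the substitution model. A two-pass
#' algorithm is used: a post-order pruning pass collects the conditional
#' likelihoods below each node, and a pre-order pass propagates the
#' "outside" likelihood of the data elsewhere on the tree; the marginal
#' posterior at a node is the normalized elementwise product of the two.
#'
#' The maximum a posteriori (MAP) residue is recorded per node and site,
#' with exact ties broken by alphabetical order of the one-letter codes. A
#' site/node is flagged ambiguous when the top two posterior probabilities
#' differ by less than `tie_delta`, and low-confidence when the MAP
#' probability falls below `low_conf` (flagged in output, never filtered).
#'
#' @inheritParams site_loglik
#' @param tie_delta Gap below which the top two posteriors are flagged as
#'   tied.
#' @param low_conf MAP posterior probability below which a reconstruction
#'   is flagged low-confidence.
#' @return An object of class `ancestral_posterior`: list with `tree` (the
#'   postorder tree used), `nodes` (internal node ids), `prob` (list by
#'   node id of 20 x n_sites posterior matrices), `map_state` / `map_prob` /
#'   `ambiguous` / `low_confidence` (matrices, rows = internal nodes named
#'   `node<id>`), `site_loglik`, and the tip data used.
#' @export
ancestral_posteriors <- function(tree, alignment, model, tie_delta = 1e-9,
                                 low_conf = 0.8) {
  tree <- prepare_tree(tree)
  validate_alignment(alignment)
  enc <- encode_alignment(alignment)
  pe <- peel(tree, enc, model)
  n_tip <- pe$n_tip
  n_node <- n_tip + tree$Nnode
  n_sites <- ncol(enc)
  edge <- tree$edge
  root <- pe$root

  # Pre-order "outside" pass. outside[[v]] is proportional to the
  # likelihood of all data off v's subtree, as a function of v's state;
  # columns are normalized to guard against underflow (posteriors are
  # renormalized anyway).
  outside <- vector("list", n_node)
  outside[[root]] <- matrix(model$frequencies, 20L, n_sites)
  kids_of <- split(seq_len(nrow(edge)), edge[, 1])
  for (k in rev(seq_len(nrow(edge)))) {   # reverse postorder = preorder
    u <- edge[k, 1]; v <- edge[k, 2]
    if (v <= n_tip) next
    acc <- outside[[u]]
    for (j in kids_of[[as.character(u)]]) {
      w <- edge[j, 2]
      if (w != v) acc <- acc * pe$down[[w]]
    }
    o <- crossprod(pe$edge_p[[v]], acc)
    cs <- colSums(o); cs[cs == 0] <- 1
    outside[[v]] <- o / rep(cs, each = 20L)
  }

  internal <- (n_tip + 1L):n_node
  prob <- vector("list", n_node)
  for (v in internal) {
    p <- outside[[v]] * pe$partial[[v]]
    cs <- colSums(p)
    if (any(cs == 0))
      stop("zero posterior mass at node ", v,
           " (impossible site under this tree/model)", call. = FALSE)
    p <- p / rep(cs, each = 20L)
    rownames(p) <- AA_CODES
    prob[[v]] <- p
  }

  # Vectorized MAP with alphabetical tie-break: scan states in alphabetical
  # order so the first maximum encountered is the alphabetically smallest.
  alpha <- order(AA_CODES)
  map_state <- matrix("", length(internal), n_sites,
                      dimnames = list(paste0("node", internal), NULL))
  map_prob <- matrix(0, length(internal), n_sites,
                     dimnames = dimnames(map_state))
  ambiguous <- matrix(FALSE, length(internal), n_sites,
                      dimnames = dimnames(map_state))
  for (i in seq_along(internal)) {
    p <- prob[[internal[i]]][alpha, , drop = FALSE]
    idx <- max.col(t(p), ties.method = "first")
    m1 <- p[cbind(idx, seq_len(n_sites))]
    # ties within tie_delta of the maximum resolve to the alphabetically
    # first residue (robust to round-off in exactly symmetric cases)
    near <- p >= rep(m1 - tie_delta, each = 20L)
    pick <- max.col(t(near), ties.method = "first")
    p2 <- p; p2[cbind(idx, seq_len(n_sites))] <- -Inf
    m2 <- p2[cbind(max.col(t(p2), ties.method = "first"),
                   seq_len(n_sites))]
    map_state[i, ] <- AA_CODES[alpha][pick]
    map_prob[i, ] <- m1
    ambiguous[i, ] <- (m1 - m2) < tie_delta
  }

  structure(
    list(tree = tree, nodes = internal, prob = prob,
         map_state = map_state, map_prob = map_prob,
         ambiguous = ambiguous, low_confidence = map_prob < low_conf,
         site_loglik = pe$site_loglik, alignment = alignment,
         tie_delta = tie_delta, low_conf = low_conf,
         model_name = model$name),
    class = "ancestral_posterior")
}

#' MAP ancestral sequences
#'
#' Extracts the posterior-mode residue string for every internal node from
#' an [ancestral_posteriors()] result.
#'
#' @param posteriors An `ancestral_posterior` object.
#' @return Named character vector of ancestral sequences, one per internal
#'   node (`node<id>` in the tree's node numbering).
#' @export
map_ancestral_sequences <- function(posteriors) {
  stopifnot(inherits(posteriors, "ancestral_posterior"))
  apply(posteriors$map_state, 1L, paste, collapse = "")
}

#' Dump ancestral posteriors to TSV for audit
#'
#' Writes one row per internal node and site: node id, site, MAP state, MAP
#' probability, ambiguity and low-confidence flags, and the 20 posterior
#' probabilities in PAML residue order.
#'
#' @param posteriors An `ancestral_posterior` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_posteriors_tsv <- function(posteriors, path) {
  stopifnot(inherits(posteriors, "ancestral_posterior"))
  rows <- lapply(seq_along(posteriors$nodes), function(i) {
    v <- posteriors$nodes[i]
    p <- t(posteriors$prob[[v]])
    colnames(p) <- paste0("p_", AA_CODES)
    data.frame(node = paste0("node", v), site = seq_len(nrow(p)),
               map_state = posteriors$map_state[i, ],
               map_prob = posteriors$map_prob[i, ],
               ambiguous = posteriors$ambiguous[i, ],
               low_confidence = posteriors$low_confidence[i, ],
               p, check.names = FALSE)
  })
  write_tsv(do.call(rbind, rows), path)
}

#' @export
print.ancestral_posterior <- function(x, ...) {
  cat("Marginal ancestral reconstruction (", x$model_name, ")\n", sep = "")
  cat("  ", length(x$nodes), " internal nodes x ", ncol(x$map_state),
      " sites\n", sep = "")
  cat("  mean MAP probability: ",
      format(mean(x$map_prob), digits = 4), "\n", sep = "")
  invisible(x)
}

# Deterministic TSV writer shared by all outputs.
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}
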