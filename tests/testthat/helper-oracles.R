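# Independent oracles used across the suite. These deliberately avoid the
# package's pruning/posterior/expectation code paths: likelihoods and
# posteriors by explicit enumeration over all internal-node state
# assignments, expectations by Monte Carlo simulation.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Enumerate all internal-state assignments of a small rooted tree and
# return the site likelihood and exact marginal posteriors per internal
# node. `column` is a named character vector of tip residues ('-'/'X'
# allowed as missing).
enum_site <- function(tree, column, model) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  internal <- (n_tip + 1L):n_node
  edge <- tree$edge
  p_edge <- lapply(seq_len(nrow(edge)), function(k)
    aaconv::transition_matrix(model, tree$edge.length[k]))
  tip_state <- match(toupper(column[tree$tip.label]), AA20)  # NA = missing

  grid <- as.matrix(expand.grid(rep(list(1:20), length(internal))))
  colnames(grid) <- as.character(internal)
  root <- setdiff(edge[, 1], edge[, 2])
  lik <- model$frequencies[grid[, as.character(root)]]
  for (k in seq_len(nrow(edge))) {
    u <- grid[, as.character(edge[k, 1])]
    v <- edge[k, 2]
    p <- p_edge[[k]]
    if (v <= n_tip) {
      s <- tip_state[v]
      lik <- lik * if (is.na(s)) 1 else p[cbind(u, s)]
    } else {
      lik <- lik * p[cbind(u, grid[, as.character(v)])]
    }
  }
  total <- sum(lik)
  post <- sapply(as.character(internal), function(nm)
    vapply(1:20, function(x) sum(lik[grid[, nm] == x]), 0) / total)
  rownames(post) <- AA20
  list(likelihood = total, posteriors = post)  # posteriors: 20 x n_internal
}

# Monte-Carlo oracle for expected convergent/parallel counts at one site.
# q_list: per-branch length-20 ancestral posteriors; p_list: per-branch
# transition matrices. Returns means and standard errors for combined and
# parallel event indicators.
mc_expected <- function(q_list, p_list, mode, nrep = 2e5) {
  k <- length(q_list)
  anc <- matrix(0L, k, nrep)
  der <- matrix(0L, k, nrep)
  for (b in seq_len(k)) {
    anc[b, ] <- sample.int(20L, nrep, replace = TRUE, prob = q_list[[b]])
    for (x in unique(anc[b, ])) {
      at <- which(anc[b, ] == x)
      der[b, at] <- sample.int(20L, length(at), replace = TRUE,
                               prob = p_list[[b]][x, ])
    }
  }
  pair_ind <- function(rows) {
    a <- anc[rows, , drop = FALSE]; d <- der[rows, , drop = FALSE]
    shared <- colSums(d == rep(d[1, ], each = length(rows))) == length(rows)
    # given a shared derived residue, "changed on every branch" is exactly
    # "derived differs from every ancestral state"
    comb <- shared & colSums(d != a) == length(rows)
    par <- comb & colSums(a == rep(a[1, ], each = length(rows))) ==
      length(rows)
    cbind(combined = comb, parallel = par)
  }
  ind <- if (mode == "all") pair_ind(seq_len(k)) else {
    acc <- matrix(0, nrep, 2, dimnames = list(NULL, c("combined", "parallel")))
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
      acc <- acc + pair_ind(c(i, j))
    acc
  }
  se <- apply(ind, 2, stats::sd) / sqrt(nrep)
  # floor at the Poisson error of a single event so that a zero-event
  # Monte-Carlo run still yields a usable uncertainty
  list(mean = colMeans(ind), se = pmax(se, 1 / nrep))
}

# Direct-summation oracle for per-site expected counts: explicit loops
# over ancestral-state tuples and the shared derived residue, independent
# of the package's vectorized matrix identities. k = 2 or 3 branches.
sum_expected <- function(q_list, p_list, mode) {
  k <- length(q_list)
  pair <- function(q1, q2, p1, p2) {
    comb <- 0; par <- 0
    for (x1 in 1:20) for (x2 in 1:20) for (j in 1:20) {
      if (j != x1 && j != x2) {
        v <- q1[x1] * q2[x2] * p1[x1, j] * p2[x2, j]
        comb <- comb + v
        if (x1 == x2) par <- par + v
      }
    }
    c(combined = comb, parallel = par)
  }
  if (mode == "pairwise" || k == 2L) {
    out <- c(combined = 0, parallel = 0)
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
      out <- out + pair(q_list[[i]], q_list[[j]], p_list[[i]], p_list[[j]])
    return(out)
  }
  stopifnot(k == 3L)
  comb <- 0; par <- 0
  for (x1 in 1:20) for (x2 in 1:20) for (x3 in 1:20) for (j in 1:20) {
    if (j != x1 && j != x2 && j != x3) {
      v <- q_list[[1]][x1] * q_list[[2]][x2] * q_list[[3]][x3] *
        p_list[[1]][x1, j] * p_list[[2]][x2, j] * p_list[[3]][x3, j]
      comb <- comb + v
      if (x1 == x2 && x2 == x3) par <- par + v
    }
  }
  c(combined = comb, parallel = par)
}

# Random valid reversible model (seeded by the caller).
rand_model <- function() {
  s <- matrix(0, 20, 20)
  s[lower.tri(s)] <- runif(190, 0.05, 2)
  s <- s + t(s)
  f <- rgamma(20, 2, 1); f <- f / sum(f)
  aaconv::build_rate_matrix(s, f, name = "random")
}

# Small random rooted tree with branch lengths in [lo, hi].
rand_tree <- function(n_tip, lo = 0.02, hi = 0.3) {
  tr <- ape::rtree(n_tip, rooted = TRUE)
  tr$edge.length <- runif(nrow(tr$edge), lo, hi)
  tr
}

# Random protein alignment column/matrix for a tree's tips.
rand_alignment <- function(tree, n_sites) {
  m <- matrix(sample(AA20, length(tree$tip.label) * n_sites, replace = TRUE),
              nrow = length(tree$tip.label),
              dimnames = list(tree$tip.label, NULL))
  m
}
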