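#' Default 13-taxon study tree
#'
#' A rooted 13-tip mammal tree with the taxon design of the myrmecophagy
#' study: three focal myrmecophagous tips (anteater, echidna, pangolin) in
#' three disjoint subtrees (Xenarthra, Monotremata, Pholidota), their five
#' designated non-myrmecophagous sister species (dog, cat, giant panda,
#' elephant, platypus), and five further outgroup/reference mammals.
#' Branch lengths are in expected amino acid substitutions per site, at
#' magnitudes typical of mammalian ortholog protein divergence.
#'
#' @return A rooted [ape::phylo] tree with branch lengths.
#' @export
myrmecophagy_tree <- function() {
  nwk <- paste0(
    "((platypus:0.18,echidna:0.18):0.10,(opossum:0.24,((elephant:0.12,",
    "anteater:0.13):0.03,((human:0.08,mouse:0.16):0.03,((cow:0.10,",
    "horse:0.09):0.02,(pangolin:0.12,(dog:0.08,(cat:0.07,",
    "giant_panda:0.07):0.02):0.04):0.02):0.01):0.02):0.09):0.08);")
  ape::read.tree(text = nwk)
}

#' Tip sets of the default study design
#'
#' @return List with `focal` (anteater, echidna, pangolin) and `sisters`
#'   (dog, cat, giant panda, elephant, platypus).
#' @export
myrmecophagy_tips <- function() {
  list(focal = c("anteater", "echidna", "pangolin"),
       sisters = c("dog", "cat", "giant_panda", "elephant", "platypus"))
}

#' Simulation configuration
#'
#' Bundles everything the synthetic ortholog generator needs. The seed
#' fully determines all outputs; each gene is reproducible independently
#' from `(seed, gene index)`.
#'
#' @param tree Rooted [ape::phylo] with branch lengths; default
#'   [myrmecophagy_tree()].
#' @param n_genes Number of ortholog genes to simulate.
#' @param sites_per_gene Single length or `c(min, max)` range from which
#'   per-gene lengths are drawn uniformly.
#' @param model An [aa_model()]; default JTT.
#' @param focal_tips Tips whose terminal branches receive injected
#'   convergent sites.
#' @param n_convergent_sites Number of convergent sites injected per gene
#'   (0 = pure null simulation).
#' @param convergence_target `"uniform"` — the injected derived residue is
#'   drawn uniformly among residues legal at the site; `"biased"` — the
#'   residue in `bias_residue` is used wherever legal (a stress-test
#'   policy).
#' @param bias_residue Residue used by the biased policy.
#' @param seed Integer master seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(tree = myrmecophagy_tree(), n_genes = 100L,
                       sites_per_gene = 300L, model = aa_model("JTT"),
                       focal_tips = myrmecophagy_tips()$focal,
                       n_convergent_sites = 0L,
                       convergence_target = c("uniform", "biased"),
                       bias_residue = "T", seed = 1L) {
  convergence_target <- match.arg(convergence_target)
  tree <- prepare_tree(tree)
  miss <- setdiff(focal_tips, tree$tip.label)
  if (length(miss))
    stop("focal tip(s) not in tree: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (length(sites_per_gene) == 1L)
    sites_per_gene <- rep(sites_per_gene, 2L)
  if (length(sites_per_gene) != 2L || any(sites_per_gene < 1))
    stop("sites_per_gene must be a length or a c(min, max) range",
         call. = FALSE)
  if (n_convergent_sites > min(sites_per_gene))
    stop("n_convergent_sites exceeds sites_per_gene", call. = FALSE)
  if (!bias_residue %in% AA_CODES)
    stop("bias_residue must be a standard one-letter code", call. = FALSE)
  structure(list(tree = tree, n_genes = as.integer(n_genes),
                 sites_per_gene = as.integer(sites_per_gene), model = model,
                 focal_tips = focal_tips,
                 n_convergent_sites = as.integer(n_convergent_sites),
                 convergence_target = convergence_target,
                 bias_residue = bias_residue, seed = as.integer(seed)),
            class = "sim_config")
}

# Deterministic per-gene substream seed (kept below 2^31).
gene_seed <- function(seed, i, salt = 0L) {
  as.integer((as.numeric(seed) * 48271 + i * 69621 + salt * 30269) %%
               2147483399)
}

#' Simulate one ortholog protein alignment with full ground truth
#'
#' Draws the root sequence from the model's equilibrium frequencies and
#' evolves it down every branch by sampling from the branch's transition
#' probability rows, recording the complete substitution history.
#' Deterministic given `(config$seed, gene_index)`. No convergence is
#' injected here; see [inject_convergence()].
#'
#' @param config A [sim_config()].
#' @param gene_index Gene number (1-based).
#' @return List with `gene` (id string), `alignment` (tip character
#'   matrix), `node_seq` (integer state matrix, all nodes x sites, rows
#'   named by node id), `substitutions` (data frame: child node, edge
#'   label, site, from, to), `n_sites`, and `registry` (empty; filled by
#'   injection).
#' @export
simulate_gene <- function(config, gene_index) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(gene_seed(config$seed, gene_index))
  tree <- config$tree
  model <- config$model
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  edge <- tree$edge
  root <- setdiff(edge[, 1], edge[, 2])
  sp <- config$sites_per_gene
  n_sites <- if (sp[1] == sp[2]) sp[1]
             else sample(seq(sp[1], sp[2]), 1L)

  node_seq <- matrix(0L, n_node, n_sites)
  rownames(node_seq) <- c(tree$tip.label, paste0("node", (n_tip + 1L):n_node))
  node_seq[root, ] <- sample.int(20L, n_sites, replace = TRUE,
                                 prob = model$frequencies)

  subs <- list()
  for (k in rev(seq_len(nrow(edge)))) {   # preorder: parents before children
    u <- edge[k, 1]; v <- edge[k, 2]
    p <- transition_matrix(model, tree$edge.length[k])
    parent_states <- node_seq[u, ]
    child_states <- integer(n_sites)
    for (x in unique(parent_states)) {
      at <- which(parent_states == x)
      child_states[at] <- sample.int(20L, length(at), replace = TRUE,
                                     prob = p[x, ])
    }
    node_seq[v, ] <- child_states
    hit <- which(child_states != parent_states)
    if (length(hit))
      subs[[length(subs) + 1L]] <- data.frame(
        child = v, branch = rownames(node_seq)[v], site = hit,
        from = AA_CODES[parent_states[hit]],
        to = AA_CODES[child_states[hit]], stringsAsFactors = FALSE)
  }
  subs <- if (length(subs)) do.call(rbind, subs) else
    data.frame(child = integer(0), branch = character(0), site = integer(0),
               from = character(0), to = character(0),
               stringsAsFactors = FALSE)
  subs <- subs[order(subs$child, subs$site), , drop = FALSE]
  rownames(subs) <- NULL

  alignment <- matrix(AA_CODES[node_seq[seq_len(n_tip), ]], nrow = n_tip,
                      dimnames = list(tree$tip.label, NULL))
  list(gene = sprintf("gene%04d", gene_index), alignment = alignment,
       node_seq = node_seq, substitutions = subs, n_sites = n_sites,
       registry = empty_registry())
}

empty_registry <- function() {
  data.frame(gene = character(0), site = integer(0),
             derived_state = character(0), category = character(0),
             branches = character(0), parent_states = character(0),
             stringsAsFactors = FALSE)
}

#' Inject convergent sites on the focal branches
#'
#' Overwrites, at each selected site, the focal tips' residues with a
#' shared derived residue that differs from each focal parent's true
#' ancestral state (so every focal branch carries a substitution to the
#' same residue). The intended category is recorded: parallel when the
#' true focal-parent states agree, convergent otherwise. Non-focal taxa
#' are untouched and the neutral substitution history is kept as-is.
#'
#' @param sim A gene simulation from [simulate_gene()].
#' @param config The same [sim_config()].
#' @return `sim` with modified `alignment` and a filled `registry`.
#' @export
inject_convergence <- function(sim, config) {
  k <- config$n_convergent_sites
  if (k == 0L) return(sim)
  gene_index <- as.integer(sub("gene", "", sim$gene))
  set.seed(gene_seed(config$seed, gene_index, salt = 1L))
  tree <- config$tree
  edge <- tree$edge
  parent_of <- function(v) edge[match(v, edge[, 2]), 1]
  focal_tip_idx <- match(config$focal_tips, tree$tip.label)
  focal_parents <- vapply(focal_tip_idx, parent_of, integer(1))

  candidates <- sample(seq_len(sim$n_sites))   # random site order
  chosen <- integer(0); rows <- list()
  for (s in candidates) {
    if (length(chosen) == k) break
    parents <- sim$node_seq[focal_parents, s]
    legal <- setdiff(seq_len(20L), parents)
    derived <- if (config$convergence_target == "biased") {
      b <- match(config$bias_residue, AA_CODES)
      if (b %in% legal) b else NA_integer_
    } else if (length(legal)) legal[sample.int(length(legal), 1L)]
      else NA_integer_
    if (is.na(derived)) next                   # resample another site
    sim$alignment[config$focal_tips, s] <- AA_CODES[derived]
    chosen <- c(chosen, s)
    rows[[length(rows) + 1L]] <- data.frame(
      gene = sim$gene, site = s, derived_state = AA_CODES[derived],
      category = if (length(unique(parents)) == 1L) "parallel"
                 else "convergent",
      branches = paste(config$focal_tips, collapse = ","),
      parent_states = paste(AA_CODES[parents], collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (length(chosen) < k)
    stop("could not place ", k, " convergent sites in gene ", sim$gene,
         ": no legal derived residue at remaining sites", call. = FALSE)
  reg <- do.call(rbind, rows)
  reg <- reg[order(reg$site), , drop = FALSE]
  rownames(reg) <- NULL
  sim$registry <- reg
  sim
}

#' Simulate a full synthetic ortholog dataset
#'
#' @param config A [sim_config()].
#' @return List of class `sim_dataset` with `genes` (list of gene
#'   simulations, injection applied), `tree`, `config`, and `registry`
#'   (combined injected-site table).
#' @export
simulate_dataset <- function(config) {
  genes <- lapply(seq_len(config$n_genes), function(i)
    inject_convergence(simulate_gene(config, i), config))
  registry <- do.call(rbind, c(lapply(genes, `[[`, "registry"),
                               list(empty_registry())))
  rownames(registry) <- NULL
  structure(list(genes = genes, tree = config$tree, config = config,
                 registry = registry), class = "sim_dataset")
}

#' Write a simulated dataset to disk
#'
#' Writes one aligned FASTA per gene (`<gene>.fasta`), the tree
#' (`tree.nwk`), the injected-site truth registry
#' (`truth_registry.tsv`), the full per-branch substitution truth
#' (`truth_substitutions.tsv`), and a key=value config echo
#' (`config.txt`). File contents are byte-stable for a fixed seed.
#'
#' @param dataset A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sim_dataset"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir, call. = FALSE)
  for (g in dataset$genes)
    write_alignment(g$alignment, file.path(dir, paste0(g$gene, ".fasta")))
  ape::write.tree(dataset$tree, file.path(dir, "tree.nwk"))
  write_tsv(dataset$registry, file.path(dir, "truth_registry.tsv"))
  truth <- do.call(rbind, lapply(dataset$genes, function(g)
    cbind(gene = g$gene, g$substitutions)))
  write_tsv(truth, file.path(dir, "truth_substitutions.tsv"))
  cfg <- dataset$config
  writeLines(c(
    paste0("n_genes=", cfg$n_genes),
    paste0("sites_per_gene=", paste(cfg$sites_per_gene, collapse = "-")),
    paste0("model=", cfg$model$name),
    paste0("focal_tips=", paste(cfg$focal_tips, collapse = ",")),
    paste0("n_convergent_sites=", cfg$n_convergent_sites),
    paste0("convergence_target=", cfg$convergence_target),
    paste0("bias_residue=", cfg$bias_residue),
    paste0("seed=", cfg$seed)),
    file.path(dir, "config.txt"))
  invisible(dir)
}
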