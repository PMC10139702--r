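#' Run the convergence analysis for one gene
#'
#' Executes the full per-gene pipeline: (optional) per-gene ML branch
#' length estimation on the fixed species topology, marginal ancestral
#' reconstruction, substitution calling and event classification on each
#' focal branch set, model-based expected counts, and exact Poisson tests
#' in both directions.
#'
#' @param alignment Character matrix of aligned residues (see
#'   [read_alignment()]) or a path to an aligned FASTA file.
#' @param tree Rooted species tree ([ape::phylo]) with branch lengths.
#' @param model An [aa_model()].
#' @param sets A [focal_set()] or list of them.
#' @param branch_lengths `"estimate"` (default) — re-estimate branch
#'   lengths for this gene by maximum likelihood; `"fixed"` — use the input
#'   tree's lengths as-is.
#' @param plus_f Replace the model's equilibrium frequencies with this
#'   gene's observed residue frequencies (+F).
#' @param gene Gene id used in the output rows (defaults to the file base
#'   name, or `"gene"`).
#' @return List with `rows` (data frame, one row per branch set: gene, set,
#'   mode, obs_/exp_ convergent, parallel, combined, p_upper, p_lower,
#'   n_usable_sites) and `events` (data frame of convergence events with
#'   gene and set columns).
#' @export
run_gene <- function(alignment, tree, model, sets,
                     branch_lengths = c("estimate", "fixed"),
                     plus_f = FALSE, gene = NULL) {
  branch_lengths <- match.arg(branch_lengths)
  if (is.character(alignment) && length(alignment) == 1L) {
    if (is.null(gene))
      gene <- sub("\\.(fa|fasta|faa)$", "", basename(alignment))
    alignment <- read_alignment(alignment)
  }
  if (is.null(gene)) gene <- "gene"
  if (inherits(sets, "focal_set")) sets <- list(sets)
  if (plus_f)
    model <- build_rate_matrix(model$exchangeabilities,
                               observed_frequencies(alignment),
                               name = paste0(model$name, "+F"))
  tree <- prepare_tree(tree)
  if (branch_lengths == "estimate")
    tree <- estimate_branch_lengths(tree, alignment, model)
  post <- ancestral_posteriors(tree, alignment, model)

  rows <- list(); events <- list()
  for (set in sets) {
    obs <- count_observed(post, set)
    exp_ <- expected_counts(post, model, set)
    tails <- poisson_tail(obs$counts[["combined"]], exp_[["combined"]])
    rows[[set$name]] <- data.frame(
      gene = gene, set = set$name, mode = set$mode,
      obs_convergent = obs$counts[["convergent"]],
      obs_parallel = obs$counts[["parallel"]],
      obs_combined = obs$counts[["combined"]],
      exp_convergent = exp_[["convergent"]],
      exp_parallel = exp_[["parallel"]],
      exp_combined = exp_[["combined"]],
      p_upper = tails[["p_upper"]], p_lower = tails[["p_lower"]],
      n_usable_sites = length(obs$usable_sites),
      stringsAsFactors = FALSE)
    if (nrow(obs$events))
      events[[set$name]] <- cbind(gene = gene, set = set$name, obs$events)
  }
  empty_events <- data.frame(gene = character(0), set = character(0),
                             site = integer(0), derived_state = character(0),
                             category = character(0), branches = character(0),
                             from_states = character(0),
                             stringsAsFactors = FALSE)
  list(rows = do.call(rbind, c(rows, make.row.names = FALSE)),
       events = do.call(rbind, c(events, list(empty_events),
                                 make.row.names = FALSE)))
}

#' Run the convergence analysis over a batch of ortholog genes
#'
#' Applies [run_gene()] to every gene in a directory of aligned FASTA
#' files (or an in-memory named list of alignments), aggregates per branch
#' set with [genome_wide_test()], and builds the "N substitutions in
#' proteins encoded by M genes" summary. A gene-level failure (parse
#' error, tip mismatch, ...) is quarantined into a failures manifest and
#' never aborts the batch.
#'
#' When `out_dir` is given, writes `per_gene.tsv`, `genome_wide.tsv`,
#' `events.tsv`, `summary.tsv`, `failures.tsv`, and a `manifest.txt`
#' config echo. TSV output is bit-identical across reruns with the same
#' inputs and config.
#'
#' @param alignments Directory containing `*.fa`/`*.fasta`/`*.faa` files,
#'   or a named list of alignment matrices.
#' @inheritParams run_gene
#' @param out_dir Optional output directory.
#' @return List with `per_gene` (rows for all genes and sets, with BH
#'   `q_upper` within each set), `genome_wide` (one aggregate row per
#'   set), `events`, `summary` (per set: events, genes with events,
#'   convergent/parallel split), `failures` (data frame gene/error).
#' @export
run_batch <- function(alignments, tree, model, sets,
                      branch_lengths = c("estimate", "fixed"),
                      plus_f = FALSE, out_dir = NULL) {
  branch_lengths <- match.arg(branch_lengths)
  if (inherits(sets, "focal_set")) sets <- list(sets)
  if (is.character(alignments) && length(alignments) == 1L) {
    files <- sort(list.files(alignments, pattern = "\\.(fa|fasta|faa)$",
                             full.names = TRUE))
    if (length(files) == 0L)
      stop("no FASTA files in ", alignments, call. = FALSE)
    names(files) <- sub("\\.(fa|fasta|faa)$", "", basename(files))
    alignments <- as.list(files)
  }
  if (is.null(names(alignments)) || anyDuplicated(names(alignments)))
    stop("alignments must be uniquely named", call. = FALSE)

  rows <- list(); events <- list(); failures <- list()
  for (g in names(alignments)) {
    r <- tryCatch(
      run_gene(alignments[[g]], tree, model, sets,
               branch_lengths = branch_lengths, plus_f = plus_f, gene = g),
      error = function(e) e)
    if (inherits(r, "error")) {
      failures[[g]] <- data.frame(gene = g, error = conditionMessage(r),
                                  stringsAsFactors = FALSE)
    } else {
      rows[[g]] <- r$rows
      if (nrow(r$events)) events[[g]] <- r$events
    }
  }
  if (length(rows) == 0L)
    stop("all genes failed; see failures manifest", call. = FALSE)
  per_gene <- do.call(rbind, c(rows, make.row.names = FALSE))
  events <- if (length(events))
    do.call(rbind, c(events, make.row.names = FALSE))
  else data.frame(gene = character(0), set = character(0),
                  site = integer(0), derived_state = character(0),
                  category = character(0), branches = character(0),
                  from_states = character(0), stringsAsFactors = FALSE)
  failures <- if (length(failures))
    do.call(rbind, c(failures, make.row.names = FALSE))
  else data.frame(gene = character(0), error = character(0),
                  stringsAsFactors = FALSE)

  genome_wide <- list(); per_gene_q <- list()
  for (set in sets) {
    sub <- per_gene[per_gene$set == set$name, , drop = FALSE]
    gw <- genome_wide_test(sub)
    genome_wide[[set$name]] <- gw$aggregate
    per_gene_q[[set$name]] <- gw$per_gene
  }
  genome_wide <- do.call(rbind, c(genome_wide, make.row.names = FALSE))
  per_gene <- do.call(rbind, c(per_gene_q, make.row.names = FALSE))

  summary_df <- data.frame(
    set = genome_wide$set, mode = genome_wide$mode,
    substitutions = genome_wide$obs_combined,
    genes_with_events = genome_wide$n_genes_with_events,
    convergent = genome_wide$obs_convergent,
    parallel = genome_wide$obs_parallel,
    expected = genome_wide$exp_combined,
    p_upper = genome_wide$p_upper, p_lower = genome_wide$p_lower,
    stringsAsFactors = FALSE)

  out <- list(per_gene = per_gene, genome_wide = genome_wide,
              events = events, summary = summary_df, failures = failures)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
      stop("cannot create output directory: ", out_dir, call. = FALSE)
    write_tsv(per_gene, file.path(out_dir, "per_gene.tsv"))
    write_tsv(genome_wide, file.path(out_dir, "genome_wide.tsv"))
    write_tsv(events, file.path(out_dir, "events.tsv"))
    write_tsv(summary_df, file.path(out_dir, "summary.tsv"))
    write_tsv(failures, file.path(out_dir, "failures.tsv"))
    writeLines(c(
      paste0("aaconv_version=", as.character(utils::packageVersion("aaconv"))),
      paste0("model=", model$name),
      paste0("branch_lengths=", branch_lengths),
      paste0("plus_f=", plus_f),
      paste0("branch_sets=", paste(vapply(sets, `[[`, "", "name"),
                                   collapse = ",")),
      paste0("n_genes_attempted=", nrow(failures) +
               length(unique(per_gene$gene))),
      paste0("n_genes_analyzed=", length(unique(per_gene$gene))),
      paste0("n_genes_failed=", nrow(failures))),
      file.path(out_dir, "manifest.txt"))
  }
  out
}
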