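test_that("zero-length branches contribute zero expectation", {
  m <- aa_model("JTT")
  tr <- ape::read.tree(text = "((f1:0.0,a:0.05):0.1,(f2:0.2,b:0.05):0.1);")
  aln <- fixture_alignment()
  post <- ancestral_posteriors(tr, aln, m)
  e <- expected_counts(post, m, fixture_set("all"))
  expect_equal(as.numeric(e), c(0, 0, 0), tolerance = 1e-15)
})

test_that("point-mass ancestors reproduce the equal-rates closed form", {
  # zero-length context branches pin each focal parent to the context
  # tip's residue, so the posterior is an exact point mass
  eq <- aa_model("EQ")
  t1 <- 0.15; t2 <- 0.3
  tr <- ape::read.tree(text = sprintf(
    "((f1:%f,a:0.0):0.1,(f2:%f,b:0.0):0.1);", t1, t2))
  aln <- rbind(f1 = c("A"), a = c("S"), f2 = c("A"), b = c("T"))
  post <- ancestral_posteriors(tr, aln, eq)
  e <- expected_counts(post, eq, fixture_set("all"))
  p <- function(t) (1 / 20) * (1 - exp(-20 * t / 19))
  expect_equal(e[["convergent"]], 18 * p(t1) * p(t2), tolerance = 1e-8)
  expect_equal(e[["parallel"]], 0, tolerance = 1e-15)
})

test_that("expected counts match a Monte-Carlo simulation oracle", {
  set.seed(1234)
  m <- aa_model("JTT")
  q_list <- lapply(1:3, function(i) {
    q <- rgamma(20, 1.5); q / sum(q)
  })
  # lengths long enough that three-branch coincidences are observable in
  # a feasible number of Monte-Carlo replicates
  p_list <- lapply(runif(3, 0.5, 1.2), transition_matrix, model = m)
  for (mode in c("all", "pairwise")) {
    exp_site <- expected_site_counts(lapply(q_list, matrix, nrow = 20),
                                     p_list, mode)
    # direct-summation oracle: exact agreement
    brute <- sum_expected(q_list, p_list, mode)
    expect_equal(unname(exp_site[1, "combined"]), brute[["combined"]],
                 tolerance = 1e-12)
    expect_equal(unname(exp_site[1, "parallel"]), brute[["parallel"]],
                 tolerance = 1e-12)
    # Monte-Carlo oracle: agreement within sampling error
    mc <- mc_expected(q_list, p_list, mode, nrep = 1e5)
    for (col in c("combined", "parallel")) {
      expect_lt(abs(exp_site[1, col] - mc$mean[[col]]),
                3 * mc$se[[col]])
    }
  }
})

test_that("expected combined splits exactly into convergent plus parallel", {
  m <- aa_model("WAG")
  cfg <- sim_config(n_genes = 1, sites_per_gene = 100, seed = 3)
  sim <- simulate_gene(cfg, 1)
  post <- ancestral_posteriors(cfg$tree, sim$alignment, m)
  for (set in list(study_sets()$all3, study_sets()$pw3)) {
    e <- expected_counts(post, m, set)
    expect_equal(e[["combined"]], e[["convergent"]] + e[["parallel"]],
                 tolerance = 1e-12)
    expect_true(all(e >= 0))
  }
})

test_that("expectation is monotone in each focal branch length", {
  m <- aa_model("JTT")
  cfg <- sim_config(n_genes = 1, sites_per_gene = 80, seed = 5)
  sim <- simulate_gene(cfg, 1)
  tr0 <- cfg$tree
  focal_edge <- match(match("anteater", tr0$tip.label), tr0$edge[, 2])
  post <- ancestral_posteriors(tr0, sim$alignment, m)
  vals <- vapply(c(0.05, 0.1, 0.2, 0.4), function(t) {
    tr <- post$tree
    tr$edge.length[focal_edge] <- t
    post2 <- post; post2$tree <- tr    # same posteriors, longer focal branch
    expected_counts(post2, m, study_sets()$all3)[["combined"]]
  }, 0)
  expect_true(all(diff(vals) > 0))
})

test_that("poisson_tail gives exact tail sums and handles lam = 0", {
  expect_equal(poisson_tail(0, 2.7)[["p_upper"]], 1)
  expect_equal(poisson_tail(3, 0.5)[["p_upper"]],
               1 - exp(-0.5) * (1 + 0.5 + 0.125), tolerance = 1e-12)
  expect_equal(poisson_tail(0, 0), c(p_upper = 1, p_lower = 1))
  expect_equal(poisson_tail(2, 0), c(p_upper = 0, p_lower = 1))
  set.seed(8)
  for (rep in 1:10) {
    lam <- runif(1, 0, 10); obs <- rpois(1, lam)
    tails <- poisson_tail(obs, lam)
    expect_equal(tails[["p_upper"]] + tails[["p_lower"]],
                 1 + dpois(obs, lam), tolerance = 1e-12)
    expect_true(all(tails >= 0 & tails <= 1))
  }
  expect_error(poisson_tail(-1, 1), "nonnegative")
  expect_error(poisson_tail(1.5, 1), "integer")
  expect_error(poisson_tail(1, -2), "nonnegative")
})

test_that("genome-wide aggregation is additive in observed and expected", {
  row <- function(gene, obs, expd) data.frame(
    gene = gene, set = "s", mode = "all",
    obs_convergent = obs, obs_parallel = 0, obs_combined = obs,
    exp_convergent = expd, exp_parallel = 0, exp_combined = expd,
    p_upper = NA_real_, p_lower = NA_real_, n_usable_sites = 100L,
    stringsAsFactors = FALSE)
  one <- row("g1", 1L, 0.2)
  one$p_upper <- poisson_tail(1, 0.2)[["p_upper"]]
  gw1 <- genome_wide_test(one)
  expect_equal(gw1$aggregate$obs_combined, 1)
  expect_equal(gw1$aggregate$p_upper, one$p_upper)
  two <- rbind(row("g1", 1L, 0.2), row("g2", 2L, 0.3))
  gw2 <- genome_wide_test(two)
  expect_equal(gw2$aggregate$exp_combined, 0.5)
  expect_equal(gw2$aggregate$p_upper,
               poisson_tail(3, 0.5)[["p_upper"]])
  expect_equal(gw2$aggregate$n_genes_with_events, 2L)
  expect_equal(gw2$per_gene$q_upper,
               p.adjust(gw2$per_gene$p_upper, "BH"))
  expect_error(genome_wide_test(rbind(one, within(one, set <- "t"))),
               "mixed")
})

test_that("observed counts track expected counts on null simulations", {
  sets <- study_sets()$pw3
  cfg <- sim_config(n_genes = 150, sites_per_gene = 300, seed = 613)
  m <- cfg$model
  tot_obs <- 0; tot_exp <- 0
  for (i in seq_len(cfg$n_genes)) {
    sim <- simulate_gene(cfg, i)
    post <- ancestral_posteriors(cfg$tree, sim$alignment, m)
    tot_obs <- tot_obs + count_observed(post, sets)$counts[["combined"]]
    tot_exp <- tot_exp + expected_counts(post, m, sets)[["combined"]]
  }
  expect_lt(abs(tot_obs - tot_exp) / tot_exp, 0.10)
})

test_that("contrast report flags excess and deficit directions", {
  agg <- function(set, obs, expd, n_genes = 10L) {
    tails <- poisson_tail(obs, expd)
    data.frame(gene = "GENOME_WIDE", set = set, mode = "all",
               obs_convergent = obs, obs_parallel = 0L, obs_combined = obs,
               exp_convergent = expd, exp_parallel = 0, exp_combined = expd,
               p_upper = tails[["p_upper"]], p_lower = tails[["p_lower"]],
               n_usable_sites = 1000L, n_genes = n_genes,
               n_genes_with_events = min(obs, n_genes),
               stringsAsFactors = FALSE)
  }
  # identical focal and control: equal ratios, nothing flagged
  same <- contrast_branch_sets(agg("f", 5L, 5), agg("c", 5L, 5))
  expect_equal(same$focal_ratio, same$control_ratio)
  expect_false(same$focal_excess)
  expect_false(same$control_deficit)
  # control observed 0 with expected > 3: deficit flagged (p = e^-lam)
  ct <- contrast_branch_sets(agg("f", 20L, 2), agg("c", 0L, 3.5))
  expect_true(ct$focal_excess)
  expect_true(ct$control_deficit)
  expect_equal(ct$control_p_lower, exp(-3.5), tolerance = 1e-12)
  expect_error(contrast_branch_sets(agg("f", 1L, 1),
                                    agg("c", 1L, 1, n_genes = 3L)),
               "different gene sets")
})
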