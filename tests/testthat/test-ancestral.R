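panel_from_calls <- function(callset, calls_by_site) {
  outgroup_panel(callset$sites[, c("chrom", "pos")],
                 do.call(rbind, calls_by_site))
}

test_that("polarization follows the strict outgroup majority", {
  cs <- somatic_callset(
    data.frame(chrom = "SPA1", pos = 1:4, ref = "A", alt = "T", qual = 100),
    list("S1", "S1", "S1", "S1"))
  calls <- rbind(
    rep("ref", 10),                      # unanimous ref
    c(rep("ref", 5), rep("alt", 5)),     # tie
    c(rep("ref", 7), rep(NA, 3)),        # missing excluded from majority
    c("ref", "ref", rep(NA, 8)))         # below min_calls
  panel <- outgroup_panel(cs$sites[, c("chrom", "pos")], calls)
  pm <- polarize_sites(cs, panel)
  expect_equal(pm$ancestor, c("ref", "ambiguous", "ref", "ambiguous"))
  expect_equal(pm$n_ref[3], 7L)
  # configurable minimum
  pm2 <- polarize_sites(cs, panel, min_calls = 2)
  expect_equal(pm2$ancestor[4], "ref")
  disjoint <- outgroup_panel(data.frame(chrom = "SPE9", pos = 1:2),
                             matrix("ref", 2, 3))
  expect_error(polarize_sites(cs, disjoint), "covers none")
})

test_that("ancestor counts hit their bounds and denominators", {
  # 5 polarized sites, ancestor = ref everywhere; B carries all, A none
  cs <- somatic_callset(
    data.frame(chrom = "SPA1", pos = 1:5, ref = "A", alt = "T", qual = 100),
    replicate(5, c("B", "C"), simplify = FALSE))
  panel <- outgroup_panel(cs$sites[, c("chrom", "pos")], matrix("ref", 5, 10))
  part <- partition_by_sharing(cs, all_clones = c("A", "B", "C"))
  pm <- polarize_sites(cs, panel)
  rep <- ancestor_counts(pm, part)
  pc <- rep$per_clone
  expect_equal(pc$common_count[pc$clone == "A"], 5L)  # carries no derived
  expect_equal(pc$common_count[pc$clone == "B"], 0L)  # carries all derived
  expect_equal(unique(pc$common_denom), 5L)
  # ancestor + derived = polarized sites for every clone
  derived <- 5L - pc$common_count
  expect_equal(pc$common_count + derived, rep(5L, 3))
})

test_that("simulated ancestor counts match the truth-tree bookkeeping", {
  cfg <- simulation_config(n_clones = 16, founder_sizes = c(8, 8), seed = 23,
                           cnv = NULL)
  sim <- simulate_propagation(cfg)
  res <- run_cascade(sim$table,
                     filter_config(replicate_pairs = sim$truth$replicate_pairs))
  part <- partition_by_sharing(res$callset, sim$truth$replicate_map,
                               all_clones = sim$truth$clones)
  pm <- polarize_sites(res$callset, sim$panel)
  rep <- ancestor_counts(pm, part)
  tr <- sim$truth
  shared <- tr$site_branch[tr$site_branch$n_descendants >= 2, ]
  for (cl in tr$clones) {
    on_path <- sum(shared$branch %in% tr$paths[[cl]])
    got <- rep$per_clone$common_count[rep$per_clone$clone == cl]
    expect_equal(got, length(part$common_idx) - on_path)
  }
})

test_that("adding a shared derived mutation never raises the ancestor count", {
  cs <- somatic_callset(
    data.frame(chrom = "SPA1", pos = 1:3, ref = "A", alt = "T", qual = 100),
    list(c("A", "B"), c("B", "C"), c("A", "C")))
  panel <- outgroup_panel(cs$sites[, c("chrom", "pos")], matrix("ref", 3, 10))
  base <- ancestor_counts(polarize_sites(cs, panel),
                          partition_by_sharing(cs))
  # extend A's carried set with one more shared site
  cs2 <- somatic_callset(
    rbind(cs$sites, data.frame(chrom = "SPA1", pos = 4L, ref = "A",
                               alt = "T", qual = 100,
                               mean_carrier_depth = NA_real_)),
    c(cs$carriers, list(c("A", "B"))))
  panel2 <- outgroup_panel(cs2$sites[, c("chrom", "pos")],
                           matrix("ref", 4, 10))
  more <- ancestor_counts(polarize_sites(cs2, panel2),
                          partition_by_sharing(cs2))
  a0 <- base$per_clone$common_count[base$per_clone$clone == "A"]
  a1 <- more$per_clone$common_count[more$per_clone$clone == "A"]
  expect_equal(a1, a0)  # count unchanged, denominator grew
  expect_gt(more$per_clone$common_denom[1], base$per_clone$common_denom[1])
})

test_that("group means stay within member bounds", {
  cfg <- simulation_config(n_clones = 12, founder_sizes = c(6, 6),
                           topology = "star", mu_internal = 8, seed = 3,
                           cnv = NULL)
  sim <- simulate_propagation(cfg)
  res <- run_cascade(sim$table,
                     filter_config(replicate_pairs = sim$truth$replicate_pairs))
  part <- partition_by_sharing(res$callset, sim$truth$replicate_map,
                               all_clones = sim$truth$clones)
  groups <- cluster_clones(build_matrix(part), 2)
  rep <- ancestor_counts(polarize_sites(res$callset, sim$panel), part, groups)
  for (g in rep$group_means$group) {
    members <- rep$per_clone$common_count[rep$per_clone$group == g]
    mu <- rep$group_means$mean_common[rep$group_means$group == g]
    expect_gte(mu, min(members))
    expect_lte(mu, max(members))
  }
  expect_error(ancestor_counts(polarize_sites(res$callset, sim$panel),
                               part,
                               cluster_clones(build_matrix(part)[-1, ], 2)),
               "absent from groups")
})

test_that("ranking orders by common then unique counts", {
  rep <- structure(list(per_clone = data.frame(
    clone = c("A", "B", "C", "D"),
    group = 1L,
    common_count = c(67L, 25L, 40L, 67L),
    common_denom = 71L,
    unique_count = c(10L, 50L, 30L, 12L),
    unique_denom = 600L)), class = "ancestor_count_report")
  expect_equal(rank_closest_to_ancestor(rep), c("D", "A", "C", "B"))
  expect_equal(rank_closest_to_ancestor(rep, focus = c("B", "C")),
               c("C", "B"))
  expect_error(rank_closest_to_ancestor(rep, focus = character(0)), "empty")
  expect_error(rank_closest_to_ancestor(rep, focus = "Z"), "not in report")
})

test_that("the top-ranked clone has the fewest internal-branch mutations", {
  cfg <- simulation_config(founder_sizes = c(6, 6, 6, 6, 6, 6, 5, 5),
                           topology = "star", mu_internal = 12, seed = 5)
  sim <- simulate_propagation(cfg)
  res <- run_cascade(sim$table,
                     filter_config(replicate_pairs = sim$truth$replicate_pairs))
  part <- partition_by_sharing(res$callset, sim$truth$replicate_map,
                               all_clones = sim$truth$clones)
  rep <- ancestor_counts(polarize_sites(res$callset, sim$panel), part)
  top <- rank_closest_to_ancestor(rep)[1]
  tr <- sim$truth
  internal <- tr$site_branch[!tr$site_branch$terminal &
                               tr$site_branch$n_descendants >= 2, ]
  path_load <- vapply(tr$clones, function(cl)
    sum(internal$branch %in% tr$paths[[cl]]), numeric(1))
  expect_equal(unname(path_load[top]), min(path_load))
})
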