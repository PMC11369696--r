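make_partition <- function(carriers, n_pos = length(carriers)) {
  cs <- somatic_callset(
    data.frame(chrom = "SPA1", pos = seq_len(n_pos), ref = "A", alt = "T",
               qual = 100),
    carriers)
  partition_by_sharing(cs)
}

test_that("the incidence matrix transcribes carrier sets", {
  part <- make_partition(list(c("A", "B"), c("B", "C")))
  m <- build_matrix(part)
  expect_equal(m[c("A", "B", "C"), ],
               matrix(c(1L, 1L, 0L, 0L, 1L, 1L), 3, 2,
                      dimnames = dimnames(m[c("A", "B", "C"), ])))
  # clone with no common site keeps an all-zero row
  part2 <- partition_by_sharing(
    somatic_callset(
      data.frame(chrom = "SPA1", pos = 1:2, ref = "A", alt = "T", qual = 100),
      list(c("A", "B"), "D")))
  m2 <- build_matrix(part2)
  expect_true("D" %in% rownames(m2))
  expect_equal(sum(m2["D", ]), 0L)
  expect_error(build_matrix(make_partition(list("A", "B"))), "no common sites")
})

test_that("replicate rows collapse to a single clone row", {
  cs <- somatic_callset(
    data.frame(chrom = "SPA1", pos = 1:2, ref = "A", alt = "T", qual = 100),
    list(c("A0", "A1", "B"), c("A0", "A1", "C")))
  part <- partition_by_sharing(cs, replicate_map = c(A0 = "A", A1 = "A"))
  m <- build_matrix(part)
  expect_false(any(c("A0", "A1") %in% rownames(m)))
  expect_equal(unname(m["A", ]), c(1L, 1L))
})

test_that("cluster-number selection reads the CEV curve", {
  # rank-1 matrix: two archetypes, one of them empty
  m1 <- rbind(A = c(1L, 1L, 0L), B = c(1L, 1L, 0L), C = c(0L, 0L, 0L))
  sel <- select_cluster_number(m1, threshold = 0.5)
  expect_equal(sel$k, 1L)
  expect_equal(select_cluster_number(m1, threshold = 1)$k, 1L)
  # CEV curve is non-decreasing and ends at 1
  set.seed(2)
  m <- matrix(rbinom(60, 1, 0.4), 10, 6,
              dimnames = list(letters[1:10], NULL))
  sel2 <- select_cluster_number(m)
  expect_true(all(diff(sel2$cev) >= -1e-12))
  expect_equal(sel2$cev[length(sel2$cev)], 1, tolerance = 1e-9)
  # threshold 1.0 selects the full non-zero spectrum
  expect_equal(select_cluster_number(m, 1)$k, length(sel2$eigenvalues))
  expect_error(select_cluster_number(m, 0), "threshold")
  expect_error(select_cluster_number(m, 1.2), "threshold")
})

test_that("noise-free lineages select k equal to the signature count", {
  cfg <- simulation_config(founder_sizes = c(6, 6, 6, 6, 6, 6, 5, 5),
                           topology = "star", mu_internal = 12, seed = 5)
  sim <- simulate_propagation(cfg)
  res <- run_cascade(sim$table,
                     filter_config(replicate_pairs = sim$truth$replicate_pairs))
  part <- partition_by_sharing(res$callset, sim$truth$replicate_map,
                               all_clones = sim$truth$clones)
  m <- build_matrix(part)
  oracle_k <- qr(unique(m))$rank  # rank of the deduplicated archetype matrix
  sel <- select_cluster_number(m, 0.95)
  expect_equal(sel$k, oracle_k)
  expect_equal(sel$k, length(unique(sim$truth$founder_of)))
})

test_that("clustering is deterministic and order-invariant", {
  part <- make_partition(list(c("A", "B"), c("A", "B"), c("C", "D"),
                              c("C", "D"), c("E", "F")))
  m <- build_matrix(part)
  res <- cluster_clones(m, 3)
  expect_equal(res$k, 3L)
  expect_equal(unname(res$labels["A"]), unname(res$labels["B"]))
  expect_equal(unname(res$labels["C"]), unname(res$labels["D"]))
  # invariance to row and column permutations
  perm <- m[sample(nrow(m)), sample(ncol(m))]
  res2 <- cluster_clones(perm, 3)
  expect_equal(res2$labels[names(res$labels)], res$labels)
  # degenerate cuts
  expect_equal(cluster_clones(m, 1)$k, 1L)
  expect_equal(length(unique(cluster_clones(m, nrow(m))$labels)), nrow(m))
  expect_error(cluster_clones(m, nrow(m) + 1), "between 1")
})

test_that("group recovery is exact on noise-free simulated lineages", {
  cfg <- simulation_config(founder_sizes = c(6, 6, 6, 6, 6, 6, 5, 5),
                           topology = "star", mu_internal = 12, seed = 5)
  sim <- simulate_propagation(cfg)
  res <- run_cascade(sim$table,
                     filter_config(replicate_pairs = sim$truth$replicate_pairs))
  part <- partition_by_sharing(res$callset, sim$truth$replicate_map,
                               all_clones = sim$truth$clones)
  m <- build_matrix(part)
  k <- select_cluster_number(m, 0.95)$k
  groups <- cluster_clones(m, k)
  truth <- sim$truth$founder_of[rownames(m)]
  expect_equal(mclust::adjustedRandIndex(groups$labels, truth), 1)
})

test_that("identity distances and NJ behave on canonical cases", {
  # identical genotype vectors: distance 0 -> zero-length cherry
  geno <- cbind(A = c("hom_alt", "hom_ref", "hom_alt"),
                B = c("hom_alt", "hom_ref", "hom_alt"),
                C = c("hom_ref", "hom_alt", "hom_ref"),
                O = c("het", "het", "het"))
  vt <- vt_from_codes(geno)
  tree <- identity_tree(vt, "O")
  ab <- ape::cophenetic.phylo(tree)[c("A"), c("B")]
  expect_equal(unname(ab), 0, tolerance = 1e-9)
  allmiss <- geno
  allmiss[, "C"] <- "missing"
  expect_error(identity_tree(vt_from_codes(allmiss), "O"), "all-missing")
})

test_that("NJ recovers a 4-taxon additive topology", {
  # sites inducing additive distances for the split AB|CD
  geno <- cbind(
    A = c(rep("hom_ref", 6), "hom_alt", "hom_ref", "hom_ref", "hom_ref"),
    B = c(rep("hom_ref", 6), "hom_ref", "hom_alt", "hom_ref", "hom_ref"),
    C = c(rep("hom_alt", 6), "hom_ref", "hom_ref", "hom_alt", "hom_ref"),
    D = c(rep("hom_alt", 6), "hom_ref", "hom_ref", "hom_ref", "hom_alt"))
  tree <- identity_tree(vt_from_codes(geno), "D")
  # oracle: among the three unrooted 4-taxon topologies only AB|CD is
  # additive for these distances; rooted on D, A and B must form a clade
  expect_true(ape::is.monophyletic(tree, c("A", "B")))
  d <- ape::cophenetic.phylo(tree)
  expect_lt(d["A", "B"], d["A", "C"])
})

test_that("simulated clones form one clade against a divergent outgroup", {
  sim <- simulate_propagation(simulation_config(
    n_clones = 8, founder_sizes = c(4, 4), seed = 19, cnv = NULL,
    replicate = FALSE))
  vt <- sim$table
  set.seed(1)
  og <- ifelse(runif(n_sites(vt)) < 0.5, "hom_alt", "hom_ref")
  # outgroup diverges at many sites where all clones agree
  flip <- vt$geno[, 1] == og
  og[flip][seq_len(sum(flip))] <- ifelse(
    vt$geno[flip, 1] == "hom_alt", "hom_ref", "hom_alt")
  geno <- cbind(vt$geno, OUT = og)
  vt2 <- variant_table(vt$sites, geno,
                       cbind(vt$depth, OUT = rep(30L, n_sites(vt))))
  tree <- identity_tree(vt2, "OUT")
  expect_true(ape::is.monophyletic(tree, sim$truth$clones))
})
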