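test_that("biallelic stage keeps single-base SNVs only", {
  vt <- vt_from_codes(
    matrix("hom_alt", 3, 2, dimnames = list(NULL, c("S1", "S2"))),
    ref = c("A", "A", "A"), alt = c("T", "T,G", "AT"))
  out <- filter_biallelic(vt)
  expect_equal(n_sites(out), 1L)
  expect_equal(out$sites$alt, "T")
})

test_that("haplotype-specific stage rejects het and all-missing sites", {
  geno <- rbind(c("hom_alt", "hom_ref", "hom_ref"),
                c("hom_alt", "het", "hom_ref"),
                c("missing", "missing", "missing"))
  colnames(geno) <- c("S1", "S2", "S3")
  out <- filter_haplotype_specific(vt_from_codes(geno))
  expect_equal(n_sites(out), 1L)
  # one het call among many suffices for rejection
  many <- matrix("hom_ref", 1, 46, dimnames = list(NULL, sprintf("S%02d", 1:46)))
  many[1, 20] <- "het"
  expect_equal(n_sites(filter_haplotype_specific(vt_from_codes(many))), 0L)
})

test_that("replicate consistency requires identical non-missing codes", {
  geno <- rbind(c("hom_alt", "hom_alt", "hom_ref"),
                c("hom_alt", "hom_ref", "hom_ref"),
                c("hom_alt", "missing", "hom_ref"),
                c("missing", "missing", "hom_ref"))
  colnames(geno) <- c("R1", "R2", "S3")
  out <- filter_replicate_consistent(vt_from_codes(geno),
                                     list(c("R1", "R2")))
  expect_equal(n_sites(out), 1L)
  expect_error(
    filter_replicate_consistent(vt_from_codes(geno), list(c("R1", "nope"))),
    "unknown sample")
})

test_that("depth and quality thresholds act on carrier means and site QUAL", {
  geno <- matrix(rep(c("hom_alt", "hom_alt", "hom_ref"), 3), 3, 3,
                 byrow = TRUE, dimnames = list(NULL, c("S1", "S2", "S3")))
  depth <- rbind(c(30L, 32L, 90L),   # carrier mean 31, high non-carrier ignored
                 c(30L, 32L, 30L),
                 c(55L, 65L, 30L))   # carrier mean 60
  vt <- vt_from_codes(geno, qual = c(85, 79, 100), depth = depth)
  out <- filter_depth_quality(vt, filter_config())
  expect_equal(n_sites(out), 1L)
  expect_equal(out$sites$qual, 85)
  # boundary: quality exactly 80 and carrier mean exactly 50 are retained
  vt2 <- vt_from_codes(geno[1, , drop = FALSE], qual = 80,
                       depth = matrix(c(50L, 50L, 10L), 1))
  expect_equal(n_sites(filter_depth_quality(vt2, filter_config())), 1L)
})

test_that("each stage is idempotent", {
  sim <- simulate_propagation(simulation_config(
    n_clones = 8, founder_sizes = c(4, 4), seed = 21, cnv = NULL))
  aug <- inject_artifacts(sim)$table
  cfg <- filter_config(replicate_pairs = sim$truth$replicate_pairs)
  stages <- list(filter_biallelic,
                 filter_haplotype_specific,
                 function(t) filter_replicate_consistent(t, cfg$replicate_pairs),
                 function(t) filter_depth_quality(t, cfg))
  cur <- aug
  for (f in stages) {
    once <- f(cur)
    expect_identical(f(once)$sites, once$sites)
    cur <- once
  }
})

test_that("the cascade recovers exactly the true somatic sites", {
  sim <- simulate_propagation(simulation_config(seed = 101))
  aug <- inject_artifacts(sim)
  res <- run_cascade(aug$table,
                     filter_config(replicate_pairs = sim$truth$replicate_pairs))
  truth <- sim_truth_keys(sim)
  got <- callset_keys(res$callset)
  expect_setequal(got, truth)
  # per-stage removals partition the rejected artifact classes
  removed <- attr(res$report, "removed")
  side <- aug$sidecar
  side_key <- paste0(side$chrom, ":", side$pos)
  expect_setequal(removed$biallelic,
                  side_key[side$class == "multiallelic"])
  expect_setequal(removed$haplotype_specific, side_key[side$class == "het"])
  expect_setequal(removed$replicate_consistent,
                  side_key[side$class == "replicate_discordant"])
  expect_setequal(removed$depth_quality,
                  side_key[side$class %in% c("high_depth", "low_quality")])
})

test_that("cascade counts are monotone and sample order does not matter", {
  sim <- simulate_propagation(simulation_config(
    n_clones = 10, founder_sizes = c(5, 5), seed = 55))
  aug <- inject_artifacts(sim)$table
  cfg <- filter_config(replicate_pairs = sim$truth$replicate_pairs)
  res <- run_cascade(aug, cfg)
  expect_true(all(diff(res$report$n_sites) <= 0))
  perm <- sample(length(aug$samples))
  shuffled <- variant_table(aug$sites, aug$geno[, perm, drop = FALSE],
                            aug$depth[, perm, drop = FALSE])
  res2 <- run_cascade(shuffled, cfg)
  expect_identical(res$report$n_sites, res2$report$n_sites)
  expect_setequal(callset_keys(res$callset), callset_keys(res2$callset))
})

test_that("empty tables and monomorphic sites are handled", {
  empty <- vt_from_codes(matrix(character(0), 0, 2,
                                dimnames = list(NULL, c("S1", "S2"))),
                         qual = numeric(0),
                         depth = matrix(integer(0), 0, 2),
                         ref = character(0), alt = character(0))
  res <- run_cascade(empty, filter_config())
  expect_equal(nrow(res$callset$sites), 0L)
  expect_true(all(res$report$n_sites == 0))
  # all-carrier sites are reference-base errors under require_polymorphic
  allc <- vt_from_codes(matrix("hom_alt", 1, 3,
                               dimnames = list(NULL, c("S1", "S2", "S3"))))
  expect_equal(nrow(run_cascade(allc, filter_config())$callset$sites), 0L)
  kept <- run_cascade(allc, filter_config(require_polymorphic = FALSE))
  expect_equal(nrow(kept$callset$sites), 1L)
})
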