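test_that("simulation is deterministic under a fixed seed, including written files", {
  cfg <- simulation_config(seed = 7, n_genes = 40, base_rate = 2e-6,
                           decoy_fractions = c(synonymous = 0.1, common = 0.1,
                                               qc_fail = 0.1),
                           polyphen_mix = 0.8)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_equal(s1$variants$variants, s2$variants$variants)
  expect_equal(s1$variants$genotypes, s2$variants$genotypes)
  expect_equal(s1$truth, s2$truth)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_cohort(s1, d1)
  p2 <- write_cohort(s2, d2)
  for (key in names(p1)) {
    expect_identical(readLines(p1[[key]]), readLines(p2[[key]]), info = key)
  }
  # a different seed changes the realization
  s3 <- simulate_cohort(simulation_config(seed = 8, n_genes = 40,
                                          base_rate = 2e-6))
  expect_false(identical(s1$variants$variants$variant_id,
                         s3$variants$variants$variant_id))
})

test_that("cohort roster matches the study design", {
  sim <- simulate_cohort(simulation_config(seed = 1, n_genes = 5,
                                           base_rate = 1e-7))
  expect_length(sim$case_samples, 61)
  expect_length(sim$control_samples, 188)
  ped <- sim$pedigree
  fams <- ped[startsWith(ped$family_id, "F"), ]
  expect_equal(length(unique(fams$family_id)), 8)
  expect_equal(sum(fams$affected == "affected"), 18)
  trios <- ped[startsWith(ped$family_id, "T"), ]
  expect_equal(sum(trios$affected == "affected"), 43)
})

test_that("total qualifying count concentrates around its Poisson expectation", {
  cfg <- simulation_config(seed = 2, n_genes = 100,
                           gene_length_range = c(2000, 2000), base_rate = 5e-6)
  sim <- simulate_cohort(cfg)
  lam_total <- 100 * 5e-6 * 2000 * 2 * (61 + 188)
  total <- sum(sim$truth$label == "qualifying")
  expect_lt(abs(total - lam_total), 4 * sqrt(lam_total))
})

test_that("all records pass the cascade when no decoys are configured", {
  cfg <- simulation_config(seed = 3, n_genes = 60, base_rate = 3e-6)
  sim <- simulate_cohort(cfg)
  for (arm in c("case", "control")) {
    samp <- if (arm == "case") sim$case_samples else sim$control_samples
    vs <- subset_samples(sim$variants, samp)
    res <- apply_filter_cascade(vs, if (arm == "case") sim$pedigree else NULL)
    expect_equal(n_variants(res$variants), n_variants(vs), info = arm)
  }
})

test_that("zero base rate and no decoys yield an empty variant set", {
  sim <- simulate_cohort(simulation_config(seed = 4, n_genes = 10, base_rate = 0))
  expect_equal(n_variants(sim$variants), 0)
  expect_equal(nrow(sim$truth), 0)
})

test_that("funnel removals match the injected decoy counts per label exactly", {
  cfg <- simulation_config(seed = 5, n_genes = 80, base_rate = 4e-6,
                           decoy_fractions = c(synonymous = 0.15, common = 0.1,
                                               qc_fail = 0.12),
                           polyphen_mix = 0.7)
  sim <- simulate_cohort(cfg)
  for (arm in c("case", "control")) {
    samp <- if (arm == "case") sim$case_samples else sim$control_samples
    truth <- sim$truth[sim$truth$cohort == arm, ]
    res <- apply_filter_cascade(subset_samples(sim$variants, samp),
                                if (arm == "case") sim$pedigree else NULL)
    f <- res$funnel
    expect_equal(f$n_removed[f$stage == "consequence"],
                 sum(truth$label == "synonymous"), info = arm)
    expect_equal(f$n_removed[f$stage == "frequency"],
                 sum(truth$label == "common"), info = arm)
    expect_equal(f$n_removed[f$stage == "genotype_qc"],
                 sum(truth$label == "qc_fail"), info = arm)
    expect_equal(f$n_removed[f$stage == "impact"],
                 sum(truth$label == "benign"), info = arm)
    expect_equal(n_variants(res$variants),
                 sum(truth$label == "qualifying"), info = arm)
  }
})

test_that("qc_fail decoys violate exactly one named rule", {
  cfg <- simulation_config(seed = 6, n_genes = 50, base_rate = 5e-6,
                           decoy_fractions = c(qc_fail = 0.3))
  sim <- simulate_cohort(cfg)
  qcf <- sim$truth$variant_id[sim$truth$label == "qc_fail"]
  expect_gt(length(qcf), 5)
  g <- sim$variants$genotypes
  cfgf <- filter_config()
  for (vid in qcf) {
    r <- g[g$variant_id == vid, ]
    fails <- c(
      gq = r$gq < cfgf$min_gq,
      fwd = r$alt_fwd <= cfgf$min_strand_reads,
      rev = r$alt_rev <= cfgf$min_strand_reads,
      fraction = (r$alt_fwd + r$alt_rev) / r$depth <= cfgf$min_alt_fraction
    )
    expect_equal(sum(fails), 1, info = vid)
  }
})

test_that("family scenario generators realize their scenarios exactly", {
  sh <- simulate_family_variants("two_affected_sibs", "shared_by_affected", seed = 1)
  seg <- segregate(sh$variants, sh$pedigree)
  expect_true(seg$shared_by_all_affected)
  expect_equal(seg$transmitting_parent, "SIMFAM_MO")
  expect_equal(seg$unaffected_carriers[[1]], "SIMFAM_MO")

  un <- simulate_family_variants("multiplex", "unshared", seed = 1)
  pri <- prioritize_by_segregation(un$variants, un$pedigree)
  expect_equal(n_variants(pri$variants), 0)

  dn <- simulate_family_variants("trio", "de_novo", seed = 1)
  expect_true(segregate(dn$variants, dn$pedigree)$de_novo)

  ch <- simulate_family_variants("trio", "compound_het", seed = 1)
  pairs <- compound_het_scan(ch$variants, ch$pedigree)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$phase_support, "confirmed_trans")

  expect_error(simulate_family_variants("single_parent", "compound_het"),
               "both parents")
  expect_error(simulate_family_variants("trio", "unshared"),
               "two affected")
})

test_that("invalid simulation configurations are rejected", {
  expect_error(simulation_config(n_genes = 10,
                                 enriched_genes = c(NOSUCHGENE = 3)),
               "not in the simulated gene set")
  expect_error(simulation_config(enriched_genes = c(GENE0001 = -2)), "positive")
  expect_error(simulation_config(decoy_fractions = c(common = -0.1)),
               "non-negative")
  expect_error(evaluate_type1_power(
    simulation_config(n_genes = 1, enriched_genes = c(GENE0001 = 2)), 1
  ), "null gene")
})
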