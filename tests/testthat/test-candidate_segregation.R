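discovery_candidates <- function() {
  vs <- read_vcf(ext_path("table1.vcf"))
  ped <- read_ped(ext_path("ntd_families.ped"))
  filtered <- apply_filter_cascade(vs, ped)$variants
  list(
    vs = select_candidate_variants(filtered, fixture_gene_list()),
    ped = ped
  )
}

test_that("candidate selection keeps only listed genes and partitions by impact", {
  dc <- discovery_candidates()
  expect_setequal(unique(dc$vs$variants$gene),
                  c("MTHFR", "DLC1", "ITGB1", "APAF1", "SHROOM3"))
  expect_false("TTN" %in% dc$vs$variants$gene) # LOF in a non-candidate gene
  expect_true(all(dc$vs$variants$impact == "lof"))
  # empty gene list -> empty output
  expect_equal(n_variants(select_candidate_variants(dc$vs, character())), 0)
})

test_that("published-mutation removal leaves the five novel LOF candidates", {
  dc <- discovery_candidates()
  pub <- read_published_mutations(ext_path("published_mutations_synthetic.tsv"))
  kept <- remove_published(dc$vs, pub)
  expect_equal(n_variants(kept), 5)
  expect_false("SHROOM3" %in% kept$variants$gene)
  # empty published set is the identity
  expect_equal(remove_published(dc$vs, pub[0, ])$variants, dc$vs$variants)
  # removing everything empties the set
  all_pub <- tibble::tibble(gene = dc$vs$variants$gene,
                            cdna_change = dc$vs$variants$cdna_change)
  expect_equal(n_variants(remove_published(dc$vs, all_pub)), 0)
})

test_that("segregation reproduces the narrated family patterns", {
  dc <- discovery_candidates()
  seg <- segregate(dc$vs, dc$ped)

  mthfr <- seg[seg$gene == "MTHFR", ]
  expect_true(mthfr$shared_by_all_affected)
  expect_setequal(mthfr$affected_carriers[[1]], c("224_A1", "224_A2"))
  expect_equal(mthfr$unaffected_carriers[[1]], "224_MO")
  expect_equal(mthfr$transmitting_parent, "224_MO")

  apaf1 <- seg[seg$gene == "APAF1", ]
  expect_false(apaf1$shared_by_all_affected)
  expect_equal(apaf1$affected_carriers[[1]], "270_A1")

  dlc1_3646 <- seg[seg$gene == "DLC1" & seg$family_id == "3646", ]
  expect_true(dlc1_3646$shared_by_all_affected)
  expect_true("3646_B1" %in% dlc1_3646$unaffected_carriers[[1]])
})

test_that("segregation prioritization drops the unshared candidate", {
  dc <- discovery_candidates()
  pub <- read_published_mutations(ext_path("published_mutations_synthetic.tsv"))
  kept <- remove_published(dc$vs, pub)
  pri <- prioritize_by_segregation(kept, dc$ped)
  expect_equal(n_variants(pri$variants), 4)
  expect_false("APAF1" %in% pri$variants$variants$gene)
  expect_setequal(unique(pri$variants$variants$gene), c("MTHFR", "DLC1", "ITGB1"))
})

test_that("a single affected carrier in a trio shares trivially", {
  ped <- trio_pedigree()
  v <- make_variant(consequence = "stop_gained")
  vs <- variant_set(v, make_genotype(v$variant_id, "T1_P"), ped$sample_id)
  seg <- segregate(vs, ped)
  expect_true(seg$shared_by_all_affected)
  expect_true(seg$de_novo) # both parents implicit genotyped non-carriers
})

test_that("an affected member with a missing genotype does not veto sharing", {
  ped <- tibble::tibble(
    family_id = "F", sample_id = c("FA", "MO", "A1", "A2"),
    father_id = c("", "", "FA", "FA"), mother_id = c("", "", "MO", "MO"),
    sex = c("male", "female", "unknown", "unknown"),
    affected = c("unaffected", "unaffected", "affected", "affected"),
    phenotype_label = ""
  )
  v <- make_variant(consequence = "stop_gained")
  g <- dplyr::bind_rows(
    make_genotype(v$variant_id, "A1"),
    make_genotype(v$variant_id, "A2", allele_state = "missing",
                  gq = NA, alt_fwd = NA, alt_rev = NA, depth = NA)
  )
  g$alt_fraction[2] <- NA_real_
  seg <- segregate(variant_set(v, g, ped$sample_id), ped)
  expect_true(seg$shared_by_all_affected)
  expect_true(seg$incomplete)
})

test_that("sharing is genotype-monotone: adding an affected non-carrier can only revoke it", {
  set.seed(11)
  base_ped <- tibble::tibble(
    family_id = "F", sample_id = c("FA", "MO", "A1"),
    father_id = c("", "", "FA"), mother_id = c("", "", "MO"),
    sex = c("male", "female", "unknown"),
    affected = c("unaffected", "unaffected", "affected"),
    phenotype_label = ""
  )
  for (i in 1:20) {
    carriers_extra <- sample(c(TRUE, FALSE), 1)
    v <- make_variant(consequence = "stop_gained")
    g <- make_genotype(v$variant_id, "A1")
    vs <- variant_set(v, g, c(base_ped$sample_id, "A2"))
    ped2 <- dplyr::bind_rows(base_ped, tibble::tibble(
      family_id = "F", sample_id = "A2", father_id = "FA", mother_id = "MO",
      sex = "unknown", affected = "affected", phenotype_label = ""
    ))
    before <- segregate(vs, base_ped)$shared_by_all_affected
    if (carriers_extra) {
      vs$genotypes <- dplyr::bind_rows(vs$genotypes,
                                       make_genotype(v$variant_id, "A2"))
    }
    after <- segregate(vs, ped2)$shared_by_all_affected
    # never flips FALSE -> TRUE
    expect_false(!before && after)
  }
})

test_that("compound-het phase calls follow parental origin", {
  fc <- simulate_family_variants("trio", "compound_het", seed = 2)
  pairs <- compound_het_scan(fc$variants, fc$pedigree)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$phase_support, "confirmed_trans")
  expect_equal(pairs$sample_id, "SIMFAM_P")

  # both variants from the same parent: cis
  ped <- trio_pedigree()
  v <- dplyr::bind_rows(
    make_variant(pos = 1, consequence = "stop_gained"),
    make_variant(pos = 2, consequence = "missense")
  )
  g <- dplyr::bind_rows(
    make_genotype("1:1:A:T", "T1_P"), make_genotype("1:1:A:T", "T1_MO"),
    make_genotype("1:2:A:T", "T1_P"), make_genotype("1:2:A:T", "T1_MO")
  )
  pairs2 <- compound_het_scan(variant_set(v, g, ped$sample_id), ped)
  # mother also carries both hets -> she forms no pair with herself counted once
  p_child <- pairs2[pairs2$sample_id == "T1_P", ]
  expect_equal(p_child$phase_support, "excluded_cis")

  # ungenotyped parents -> possible
  vs3 <- variant_set(v, g[g$sample_id == "T1_P", ],
                     samples = "T1_P")
  ped3 <- ped[ped$sample_id == "T1_P", ]
  pairs3 <- compound_het_scan(vs3, ped3)
  expect_equal(pairs3$phase_support, "possible")
})

test_that("pair count for k het variants in one gene and sample is k(k-1)/2", {
  ped <- trio_pedigree()
  for (k in 2:5) {
    v <- dplyr::bind_rows(lapply(seq_len(k), function(i) {
      make_variant(pos = i, consequence = "missense")
    }))
    g <- dplyr::bind_rows(lapply(v$variant_id, make_genotype, sample_id = "T1_P"))
    pairs <- compound_het_scan(variant_set(v, g, ped$sample_id), ped)
    expect_equal(nrow(pairs), k * (k - 1) / 2)
    expect_false(any(pairs$variant_a == pairs$variant_b))
  }
})

test_that("the discovery cohort fixture has no compound-heterozygous transmission", {
  dc <- discovery_candidates()
  expect_equal(nrow(compound_het_scan(dc$vs, dc$ped)), 0)
})
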