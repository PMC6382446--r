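test_that("consequence filter drops synonymous and noncoding only", {
  v <- dplyr::bind_rows(
    make_variant(pos = 1, consequence = "missense"),
    make_variant(pos = 2, consequence = "synonymous"),
    make_variant(pos = 3, consequence = "frameshift"),
    make_variant(pos = 4, consequence = "noncoding"),
    make_variant(pos = 5, consequence = "splice")
  )
  expect_equal(consequence_filter(v), c(TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_warning(
    consequence_filter(make_variant(consequence = "other")),
    "other"
  )
})

test_that("frequency filter uses the max over sources and keeps novel variants", {
  v <- dplyr::bind_rows(
    make_variant(pos = 1, pop_freqs = c(gnomad = 0.002103, evs = 0.001157)),
    make_variant(pos = 2, pop_freqs = c(gnomad = 0.02)),
    make_variant(pos = 3, pop_freqs = numeric(0)),
    make_variant(pos = 4, pop_freqs = c(gnomad = 0.001, exac = 0.05))
  )
  expect_equal(frequency_filter(v), c(TRUE, FALSE, TRUE, FALSE))
  # boundary: exactly 1% is not "> 1%", so it is kept
  expect_true(frequency_filter(make_variant(pop_freqs = c(gnomad = 0.01))))
})

test_that("genotype QC applies the exclusive read-support thresholds", {
  cfg <- filter_config()
  expect_true(passes_genotype_qc(99, 4, 4, 20, cfg))          # 0.40 fraction
  expect_false(passes_genotype_qc(99, 3, 10, 30, cfg))        # 3 is not > 3
  expect_false(passes_genotype_qc(99, 4, 4, 60, cfg))         # 0.133 <= 0.15
  expect_false(passes_genotype_qc(98, 10, 10, 40, cfg))       # GQ below 99
  expect_false(passes_genotype_qc(99, 10, 10, 0, cfg))        # depth 0: undefined
  expect_false(passes_genotype_qc(99, NA, 10, 30, cfg))       # missing stat
  # boundary fraction: exactly 0.15 fails the exclusive threshold
  expect_false(passes_genotype_qc(99, 4, 5, 60, cfg))
})

test_that("impact class distinguishes LOF and probably-damaging missense", {
  v <- dplyr::bind_rows(
    make_variant(pos = 1, consequence = "stop_gained", polyphen_category = "unknown",
                 polyphen_score = NA_real_),
    make_variant(pos = 2, consequence = "frameshift", polyphen_category = "unknown",
                 polyphen_score = NA_real_),
    make_variant(pos = 3, consequence = "missense",
                 polyphen_category = "probably_damaging", polyphen_score = 0.866),
    make_variant(pos = 4, consequence = "missense", polyphen_category = "benign",
                 polyphen_score = 0.12),
    make_variant(pos = 5, consequence = "missense",
                 polyphen_category = "possibly_damaging", polyphen_score = 0.6)
  )
  expect_equal(impact_class(v),
               c("lof", "lof", "probably_damaging_missense", "other", "other"))

  # score-cutoff fallback for category-free annotation
  cfg <- filter_config(polyphen_rule = "score_cutoff")
  v2 <- make_variant(consequence = "missense", polyphen_category = "unknown",
                     polyphen_score = 0.848)
  expect_equal(impact_class(v2, cfg), "probably_damaging_missense")
  v3 <- make_variant(consequence = "missense", polyphen_category = "unknown",
                     polyphen_score = 0.5)
  expect_equal(impact_class(v3, cfg), "other")
  expect_warning(impact_class(v2), "unknown PolyPhen")
})

test_that("cascade retains a variant only on a passing relevant carrier and clears failures", {
  ped <- trio_pedigree()
  v <- dplyr::bind_rows(
    make_variant(pos = 1, consequence = "stop_gained"),
    make_variant(pos = 2, consequence = "stop_gained"),
    make_variant(pos = 3, consequence = "stop_gained")
  )
  g <- dplyr::bind_rows(
    # variant 1: affected proband passes, unaffected mother fails -> kept, mother cleared
    make_genotype("1:1:A:T", "T1_P"),
    make_genotype("1:1:A:T", "T1_MO", gq = 80L),
    # variant 2: only the unaffected mother carries (passing) -> no affected carrier, dropped
    make_genotype("1:2:A:T", "T1_MO"),
    # variant 3: affected proband fails QC -> dropped
    make_genotype("1:3:A:T", "T1_P", alt_fwd = 2L)
  )
  vs <- variant_set(v, g, ped$sample_id)
  res <- apply_filter_cascade(vs, ped)
  expect_equal(res$variants$variants$variant_id, "1:1:A:T")
  expect_equal(allele_state_of(res$variants, "1:1:A:T", "T1_MO"), "missing")
  expect_equal(allele_state_of(res$variants, "1:1:A:T", "T1_P"), "het")
  # without a pedigree all carriers are relevant: variant 2 survives
  res2 <- apply_filter_cascade(vs)
  expect_setequal(res2$variants$variants$variant_id, c("1:1:A:T", "1:2:A:T"))
})

test_that("funnel arithmetic is conserved and the cascade is idempotent on fixtures", {
  ped <- read_ped(ext_path("ntd_families.ped"))
  for (fx in c("table1.vcf", "table2_wes.vcf", "table2_mips.vcf")) {
    vs <- read_vcf(ext_path(fx))
    use_ped <- if (fx == "table1.vcf") ped else NULL
    res <- apply_filter_cascade(vs, use_ped)
    f <- res$funnel
    expect_equal(f$n_out, f$n_in - f$n_removed, info = fx)
    expect_equal(f$n_in[-1], f$n_out[-nrow(f)], info = fx)
    expect_equal(f$n_in[1], n_variants(vs), info = fx)
    expect_equal(f$n_out[nrow(f)], n_variants(res$variants), info = fx)
    # idempotence: re-filtering the output changes nothing
    res2 <- apply_filter_cascade(res$variants, use_ped)
    expect_equal(res2$variants$variants, res$variants$variants, info = fx)
    expect_equal(res2$variants$genotypes, res$variants$genotypes, info = fx)
    expect_equal(sum(res2$funnel$n_removed), 0, info = fx)
  }
})

test_that("consequence and frequency stages commute", {
  cfg <- filter_config()
  v <- dplyr::bind_rows(
    make_variant(pos = 1, consequence = "synonymous", pop_freqs = c(g = 0.2)),
    make_variant(pos = 2, consequence = "missense", pop_freqs = c(g = 0.2)),
    make_variant(pos = 3, consequence = "synonymous"),
    make_variant(pos = 4, consequence = "missense")
  )
  ab <- frequency_filter(v, cfg) & consequence_filter(v)
  ba <- consequence_filter(v) & frequency_filter(v, cfg)
  expect_equal(ab, ba)
})

test_that("empty input produces an all-zero funnel", {
  res <- apply_filter_cascade(variant_set())
  expect_equal(n_variants(res$variants), 0)
  expect_equal(res$funnel$n_in, rep(0L, 4))
  expect_equal(res$funnel$n_removed, rep(0L, 4))
})

test_that("all-synonymous input retains nothing", {
  v <- dplyr::bind_rows(lapply(1:5, function(i) {
    make_variant(pos = i, consequence = "synonymous")
  }))
  g <- dplyr::bind_rows(lapply(1:5, function(i) {
    make_genotype(paste0("1:", i, ":A:T"), "S1")
  }))
  res <- apply_filter_cascade(variant_set(v, g, "S1"))
  expect_equal(n_variants(res$variants), 0)
  expect_equal(res$funnel$n_removed[1], 5L)
})

test_that("replication filter keeps rare damaging variants only", {
  vs <- read_vcf(ext_path("table2_mips.vcf"))
  filt <- apply_replication_filter(vs)
  expect_equal(n_variants(filt), 6)
  # the >1% decoy and the benign decoy are gone
  expect_false(any(filt$variants$pos %in% c(59500000L, 59501000L)))
})
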