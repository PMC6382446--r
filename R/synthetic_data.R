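#' Simulation configuration
#'
#' Generative description of a synthetic case-control exome cohort with the
#' statistical structure the burden analysis assumes: per-gene qualifying
#' carrier-observation counts drawn as Poisson with mean
#' `rate * n * L * 2`, enrichment of chosen genes by a rate ratio, and
#' optional injection of decoy records that the filter cascade should
#' remove (synonymous, common, genotype-QC-failing, and — when
#' `polyphen_mix < 1` — benign missense).
#'
#' Defaults mirror the discovery cohort design: 61 affected (18 familial
#' affected across 8 multiplex families plus 43 trio probands) against 188
#' unrelated controls; coding lengths 1–4 kb; a base qualifying rate of
#' 1e-6 per allele-basepair (about one control carrier-observation per
#' 2.7 kb gene).
#'
#' @param seed Integer RNG seed; identical configurations give
#'   byte-identical outputs.
#' @param n_cases,n_controls Cohort sizes (defaults 61 and 188).
#' @param n_genes Number of genes (default 2000, desk-scale evaluation).
#' @param gene_length_range Coding-length interval in bp.
#' @param base_rate Qualifying-variant rate per allele-basepair.
#' @param enriched_genes Named numeric vector: rate ratios (> 0) keyed by
#'   gene symbol (symbols must exist in the simulated gene set,
#'   `GENE0001 ... GENE<n_genes>`).
#' @param decoy_fractions Named numeric vector with entries `synonymous`,
#'   `common`, `qc_fail`: expected decoy records per label as a fraction of
#'   the qualifying-record count.
#' @param polyphen_mix Proportion of emitted missense records tagged
#'   probably damaging (default 1; lower values inject benign-missense
#'   decoys that the impact stage removes).
#' @param lof_fraction Proportion of qualifying records that are
#'   loss-of-function rather than damaging missense (default 0.3).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_cases = 61L, n_controls = 188L,
                              n_genes = 2000L,
                              gene_length_range = c(1000, 4000),
                              base_rate = 1e-6,
                              enriched_genes = numeric(0),
                              decoy_fractions = c(synonymous = 0, common = 0,
                                                  qc_fail = 0),
                              polyphen_mix = 1, lof_fraction = 0.3) {
  stopifnot(
    n_cases > 0, n_controls > 0, n_genes >= 1,
    length(gene_length_range) == 2, gene_length_range[1] > 0,
    gene_length_range[2] >= gene_length_range[1],
    base_rate >= 0, polyphen_mix > 0, polyphen_mix <= 1,
    lof_fraction >= 0, lof_fraction <= 1
  )
  df <- c(synonymous = 0, common = 0, qc_fail = 0)
  df[names(decoy_fractions)] <- decoy_fractions
  if (any(df < 0)) stop("decoy fractions must be non-negative", call. = FALSE)
  if (length(enriched_genes)) {
    if (is.null(names(enriched_genes)) || any(!nzchar(names(enriched_genes)))) {
      stop("enriched_genes must be a named vector of rate ratios", call. = FALSE)
    }
    if (any(enriched_genes <= 0)) {
      stop("enrichment rate ratios must be positive", call. = FALSE)
    }
    bad <- setdiff(names(enriched_genes), gene_symbols(n_genes))
    if (length(bad)) {
      stop("enriched gene(s) not in the simulated gene set: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(
      seed = as.integer(seed), n_cases = as.integer(n_cases),
      n_controls = as.integer(n_controls), n_genes = as.integer(n_genes),
      gene_length_range = gene_length_range, base_rate = base_rate,
      enriched_genes = enriched_genes, decoy_fractions = df,
      polyphen_mix = polyphen_mix, lof_fraction = lof_fraction
    ),
    class = "simulation_config"
  )
}

gene_symbols <- function(n) sprintf("GENE%04d", seq_len(n))

# Cohort roster matching the study design: 8 multiplex families holding 18
# affected members, 43 affected trio probands, 188 unrelated controls.
build_cohort_pedigree <- function(config) {
  fam_aff <- c(3, 3, 2, 2, 2, 2, 2, 2) # 18 familial affected in 8 families
  rows <- list()
  for (i in seq_along(fam_aff)) {
    fid <- sprintf("F%02d", i)
    fa <- paste0(fid, "_FA"); mo <- paste0(fid, "_MO")
    kids <- sprintf("%s_A%d", fid, seq_len(fam_aff[i]))
    rows[[length(rows) + 1L]] <- tibble(
      family_id = fid,
      sample_id = c(fa, mo, kids),
      father_id = c("", "", rep(fa, length(kids))),
      mother_id = c("", "", rep(mo, length(kids))),
      sex = c("male", "female", rep("unknown", length(kids))),
      affected = c("unaffected", "unaffected", rep("affected", length(kids))),
      phenotype_label = c("", "", rep("MMC", length(kids)))
    )
  }
  for (i in seq_len(43)) {
    fid <- sprintf("T%02d", i)
    fa <- paste0(fid, "_FA"); mo <- paste0(fid, "_MO")
    pb <- paste0(fid, "_P")
    rows[[length(rows) + 1L]] <- tibble(
      family_id = fid, sample_id = c(fa, mo, pb),
      father_id = c("", "", fa), mother_id = c("", "", mo),
      sex = c("male", "female", "unknown"),
      affected = c("unaffected", "unaffected", "affected"),
      phenotype_label = c("", "", "MMC")
    )
  }
  ctrl <- sprintf("C%03d", seq_len(config$n_controls))
  rows[[length(rows) + 1L]] <- tibble(
    family_id = ctrl, sample_id = ctrl, father_id = "", mother_id = "",
    sex = "unknown", affected = "unaffected", phenotype_label = "control"
  )
  dplyr::bind_rows(rows)
}

#' Simulate a case-control exome cohort
#'
#' Draws per-gene qualifying carrier-observations as Poisson counts at the
#' configured rates (enriched genes at `base_rate * ratio` in cases;
#' controls always at `base_rate`), materialises each observation as a
#' heterozygous variant record with QC-passing genotype statistics, injects
#' the configured decoys (each violating exactly the rule its label names),
#' and labels every record in a truth table.
#'
#' When the configured case count differs from the default roster's 61
#' affected, cases become unrelated affected singletons.
#'
#' @param config A [simulation_config()].
#' @return An object of class `simulated_cohort`: a list with elements
#'   `variants` ([variant_set()] over all cohort samples), `pedigree`,
#'   `gene_models`, `truth` (per-record `variant_id`, `gene`, `cohort`,
#'   `label`), `gene_truth` (per-gene lengths and true rates),
#'   `case_samples`, `control_samples`, and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)

  genes <- gene_symbols(config$n_genes)
  lens <- round(runif(config$n_genes, config$gene_length_range[1],
                      config$gene_length_range[2]))
  starts <- cumsum(c(1, lens[-config$n_genes] + 10000))
  gene_models <- tibble(symbol = genes, transcript = paste0("SIM_", genes),
                        coding_length = as.integer(lens))

  if (config$n_cases == 61L) {
    pedigree <- build_cohort_pedigree(config)
  } else {
    case_ids <- sprintf("A%03d", seq_len(config$n_cases))
    ctrl_ids <- sprintf("C%03d", seq_len(config$n_controls))
    pedigree <- tibble(
      family_id = c(case_ids, ctrl_ids), sample_id = c(case_ids, ctrl_ids),
      father_id = "", mother_id = "", sex = "unknown",
      affected = rep(c("affected", "unaffected"),
                     c(config$n_cases, config$n_controls)),
      phenotype_label = rep(c("MMC", "control"),
                            c(config$n_cases, config$n_controls))
    )
  }
  case_samples <- affected_samples(pedigree)
  control_samples <- pedigree$sample_id[pedigree$phenotype_label == "control"]

  ratio <- setNames(rep(1, config$n_genes), genes)
  ratio[names(config$enriched_genes)] <- config$enriched_genes
  rate_case <- config$base_rate * ratio
  rate_ctrl <- rep(config$base_rate, config$n_genes)

  k_case <- rpois(config$n_genes, rate_case * config$n_cases * lens * 2)
  k_ctrl <- rpois(config$n_genes, rate_ctrl * config$n_controls * lens * 2)

  gene_idx <- c(rep(seq_len(config$n_genes), k_case),
                rep(seq_len(config$n_genes), k_ctrl))
  cohort <- rep(c("case", "control"), c(sum(k_case), sum(k_ctrl)))
  n_q <- length(gene_idx)

  # consequence mix of qualifying records
  is_lof <- runif(n_q) < config$lof_fraction
  label <- rep("qualifying", n_q)

  # decoys: expected counts proportional to the qualifying record count
  base_n <- max(n_q, 1)
  n_syn <- rpois(1, config$decoy_fractions[["synonymous"]] * base_n)
  n_common <- rpois(1, config$decoy_fractions[["common"]] * base_n)
  n_qcf <- rpois(1, config$decoy_fractions[["qc_fail"]] * base_n)
  n_mis_q <- sum(!is_lof)
  n_benign <- if (config$polyphen_mix < 1) {
    rpois(1, n_mis_q * (1 - config$polyphen_mix) / config$polyphen_mix)
  } else 0L
  n_d <- n_syn + n_common + n_qcf + n_benign
  if (n_d > 0) {
    d_lab <- rep(c("synonymous", "common", "qc_fail", "benign"),
                 c(n_syn, n_common, n_qcf, n_benign))
    d_gene <- sample.int(config$n_genes, n_d, replace = TRUE)
    p_case <- config$n_cases / (config$n_cases + config$n_controls)
    d_cohort <- ifelse(runif(n_d) < p_case, "case", "control")
    gene_idx <- c(gene_idx, d_gene)
    cohort <- c(cohort, d_cohort)
    label <- c(label, d_lab)
    is_lof <- c(is_lof, rep(FALSE, n_d))
  }
  n_all <- length(gene_idx)

  if (n_all == 0) {
    sim <- list(
      variants = variant_set(samples = pedigree$sample_id),
      pedigree = pedigree, gene_models = gene_models,
      truth = tibble(variant_id = character(), gene = character(),
                     cohort = character(), label = character()),
      gene_truth = tibble(gene = genes, coding_length = lens,
                          rate_case = unname(rate_case), rate_ctrl = rate_ctrl),
      case_samples = case_samples, control_samples = control_samples,
      config = config
    )
    class(sim) <- "simulated_cohort"
    return(sim)
  }

  # unique positions: consecutive offsets within each gene
  ord <- order(gene_idx)
  within <- sequence(tabulate(gene_idx, nbins = config$n_genes))
  pos <- integer(n_all)
  pos[ord] <- starts[sort(gene_idx)] + within - 1L

  consequence <- ifelse(label != "qualifying",
    ifelse(label == "synonymous", "synonymous", "missense"),
    ifelse(is_lof, "stop_gained", "missense")
  )
  is_mis <- consequence == "missense"
  pp_cat <- ifelse(is_mis & label != "benign", "probably_damaging",
                   ifelse(is_mis, "benign", "unknown"))
  pp_score <- ifelse(pp_cat == "probably_damaging", round(runif(n_all, 0.90, 0.999), 3),
                     ifelse(pp_cat == "benign", round(runif(n_all, 0, 0.4), 3), NA_real_))

  freqs <- vector("list", n_all)
  freqs[] <- list(setNames(numeric(0), character(0)))
  common_i <- which(label == "common")
  for (i in common_i) {
    freqs[[i]] <- c(gnomad = round(runif(1, 0.011, 0.2), 4))
  }

  carrier <- character(n_all)
  case_rows <- cohort == "case"
  carrier[case_rows] <- sample(case_samples, sum(case_rows), replace = TRUE)
  carrier[!case_rows] <- sample(control_samples, sum(!case_rows), replace = TRUE)

  variant_id <- make_variant_id("1", pos, "A", "T")

  variants <- tibble(
    variant_id = variant_id, chrom = "1", pos = pos, ref = "A", alt = "T",
    gene = genes[gene_idx], transcript = paste0("SIM_", genes[gene_idx]),
    cdna_change = paste0("c.", within[order(ord)] * 3 - 2, "A>T"),
    protein_change = "", consequence = consequence,
    polyphen_category = pp_cat, polyphen_score = pp_score,
    pop_freqs = freqs
  )

  # genotype statistics: intended-pass records satisfy every QC rule;
  # qc_fail decoys violate exactly one, cycling through the four rules
  depth <- sample(24:60, n_all, replace = TRUE)
  alt_total <- pmax(8L, round(depth * runif(n_all, 0.38, 0.55)))
  alt_fwd <- pmax(4L, alt_total %/% 2L)
  alt_rev <- pmax(4L, alt_total - alt_fwd)
  gq <- rep(99L, n_all)

  qcf_i <- which(label == "qc_fail")
  if (length(qcf_i)) {
    rule <- rep_len(c("gq", "fwd", "rev", "fraction"), length(qcf_i))
    gq[qcf_i[rule == "gq"]] <- 87L
    alt_fwd[qcf_i[rule == "fwd"]] <- 3L
    alt_rev[qcf_i[rule == "rev"]] <- 2L
    fr <- qcf_i[rule == "fraction"]
    depth[fr] <- 300L
    alt_fwd[fr] <- 20L
    alt_rev[fr] <- 21L # fraction 41/300 = 0.137 <= 0.15; strands still pass
  }

  genotypes <- tibble(
    variant_id = variant_id, sample_id = carrier, allele_state = "het",
    gq = gq, alt_fwd = as.integer(alt_fwd), alt_rev = as.integer(alt_rev),
    depth = as.integer(depth),
    alt_fraction = (alt_fwd + alt_rev) / depth
  )

  sim <- list(
    variants = variant_set(variants, genotypes, pedigree$sample_id),
    pedigree = pedigree, gene_models = gene_models,
    truth = tibble(variant_id = variant_id, gene = genes[gene_idx],
                   cohort = cohort, label = label),
    gene_truth = tibble(gene = genes, coding_length = lens,
                        rate_case = unname(rate_case), rate_ctrl = rate_ctrl),
    case_samples = case_samples, control_samples = control_samples,
    config = config
  )
  class(sim) <- "simulated_cohort"
  sim
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf(
    "<simulated_cohort> %d genes, %d cases / %d controls, %d records (seed %d)\n",
    x$config$n_genes, x$config$n_cases, x$config$n_controls,
    n_variants(x$variants), x$config$seed
  ))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits the same dialects the readers consume: a plain-text VCF, a PED
#' pedigree, a gene-model TSV and the truth table TSV.
#'
#' @param sim A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Named list of file paths (`vcf`, `ped`, `gene_models`, `truth`).
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    vcf = file.path(dir, "cohort.vcf"),
    ped = file.path(dir, "cohort.ped"),
    gene_models = file.path(dir, "gene_models.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_vcf(sim$variants, paths$vcf)
  write_ped(sim$pedigree, paths$ped)
  write_results_tsv(sim$gene_models, paths$gene_models)
  write_results_tsv(sim$truth, paths$truth)
  paths
}

#' Simulate a family realizing one segregation scenario
#'
#' Builds a small pedigree from a named template and emits variant records
#' whose genotypes realize the requested scenario exactly, with QC-passing
#' statistics:
#' * `shared_by_affected` — every affected member is a heterozygous
#'   carrier; the mother carries too (transmitting, unaffected).
#' * `unshared` — the first affected member carries, the other affected do
#'   not (needs >= 2 affected).
#' * `de_novo` — the proband carries; both genotyped parents do not.
#' * `compound_het` — two heterozygous variants in one gene, one inherited
#'   from each parent (needs both parents).
#'
#' Templates: `trio` (parents + affected proband), `two_affected_sibs`
#' (parents + two affected sibs), `multiplex` (parents + three affected
#' children), `single_parent` (mother + affected proband).
#'
#' @param structure Template name.
#' @param scenario Scenario name.
#' @param seed RNG seed (genotype statistics only).
#' @param gene Gene symbol for the emitted records.
#' @return A list with `variants` ([variant_set()]) and `pedigree`.
#' @export
simulate_family_variants <- function(structure = c("trio", "two_affected_sibs",
                                                   "multiplex", "single_parent"),
                                     scenario = c("shared_by_affected",
                                                  "unshared", "de_novo",
                                                  "compound_het"),
                                     seed = 1L, gene = "GENE0001") {
  structure <- match.arg(structure)
  scenario <- match.arg(scenario)
  set.seed(seed)

  fid <- "SIMFAM"
  fa <- "SIMFAM_FA"; mo <- "SIMFAM_MO"
  kids <- switch(structure,
    trio = "SIMFAM_P",
    two_affected_sibs = c("SIMFAM_A1", "SIMFAM_A2"),
    multiplex = c("SIMFAM_A1", "SIMFAM_A2", "SIMFAM_A3"),
    single_parent = "SIMFAM_P"
  )
  has_father <- structure != "single_parent"
  parents <- if (has_father) c(fa, mo) else mo
  pedigree <- tibble(
    family_id = fid,
    sample_id = c(parents, kids),
    father_id = c(rep("", length(parents)), rep(if (has_father) fa else "", length(kids))),
    mother_id = c(rep("", length(parents)), rep(mo, length(kids))),
    sex = c(if (has_father) "male", "female", rep("unknown", length(kids))),
    affected = c(rep("unaffected", length(parents)), rep("affected", length(kids))),
    phenotype_label = c(rep("", length(parents)), rep("MMC", length(kids)))
  )

  if (scenario == "unshared" && length(kids) < 2) {
    stop("scenario 'unshared' needs at least two affected members", call. = FALSE)
  }
  if (scenario == "compound_het" && !has_father) {
    stop("scenario 'compound_het' needs both parents genotyped", call. = FALSE)
  }

  pass_stats <- function(n) {
    depth <- sample(30:50, n, replace = TRUE)
    fwd <- sample(6:12, n, replace = TRUE)
    rev <- sample(6:12, n, replace = TRUE)
    tibble(gq = 99L, alt_fwd = fwd, alt_rev = rev, depth = depth,
           alt_fraction = (fwd + rev) / depth)
  }
  mk_variant <- function(pos, cdna, consequence = "stop_gained") {
    tibble(
      variant_id = make_variant_id("1", pos, "C", "T"),
      chrom = "1", pos = pos, ref = "C", alt = "T", gene = gene,
      transcript = paste0("SIM_", gene), cdna_change = cdna,
      protein_change = "", consequence = consequence,
      polyphen_category = "unknown", polyphen_score = NA_real_,
      pop_freqs = list(setNames(numeric(0), character(0)))
    )
  }
  het_rows <- function(vid, samples) {
    st <- pass_stats(length(samples))
    tibble(variant_id = vid, sample_id = samples, allele_state = "het",
           gq = st$gq, alt_fwd = st$alt_fwd, alt_rev = st$alt_rev,
           depth = st$depth, alt_fraction = st$alt_fraction)
  }

  if (scenario == "compound_het") {
    v1 <- mk_variant(1001L, "c.10C>T")
    v2 <- mk_variant(2002L, "c.200C>T")
    child <- kids[1]
    genotypes <- dplyr::bind_rows(
      het_rows(v1$variant_id, c(fa, child)),
      het_rows(v2$variant_id, c(mo, child))
    )
    variants <- dplyr::bind_rows(v1, v2)
  } else {
    v <- mk_variant(1001L, "c.10C>T")
    carriers <- switch(scenario,
      shared_by_affected = c(mo, kids),
      unshared = kids[1],
      de_novo = kids[1]
    )
    genotypes <- het_rows(v$variant_id, carriers)
    variants <- v
  }

  list(
    variants = variant_set(variants, genotypes, pedigree$sample_id),
    pedigree = pedigree
  )
}
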