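#' Load a run configuration
#'
#' A YAML file with optional sections: `paths` (vcf, ped, gene_lists — a
#' map tag -> path, gene_models, blacklist, published, out_dir), `filter`
#' (any [filter_config()] field), `test` (tail, pseudocount, alpha,
#' n_genes_bonferroni, n_cases, n_controls), and `seed`. Missing entries
#' fall back to the package defaults, which reproduce the discovery
#' analysis's printed parameters.
#'
#' @param path Path to the YAML file, or `NULL` for all defaults.
#' @param overrides Named list merged over the file's values.
#' @return A list of class `run_config`.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  cfg <- if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    yaml::read_yaml(path)
  } else list()
  cfg <- utils::modifyList(cfg, overrides)
  filt <- do.call(filter_config, cfg$filter %||% list())
  test <- utils::modifyList(
    list(tail = "upper", pseudocount = 0.5, alpha = 0.05,
         n_genes_bonferroni = 20389L, n_cases = 61L, n_controls = 188L),
    cfg$test %||% list()
  )
  structure(
    list(paths = cfg$paths %||% list(), filter = filt, test = test,
         sim = cfg$sim %||% list(), seed = cfg$seed %||% 1L),
    class = "run_config"
  )
}

#' Write a run manifest
#'
#' Records everything needed to re-execute a deterministic stage
#' bit-identically: command, seed, configuration, package version and
#' input-file checksums.
#'
#' @param command Command name.
#' @param run_config A [load_run_config()] object.
#' @param out_dir Directory for `manifest.json`.
#' @param inputs Named character vector of input file paths to checksum.
#' @return Path to the manifest, invisibly.
#' @export
write_manifest <- function(command, run_config, out_dir, inputs = character()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- inputs[file.exists(inputs)]
  manifest <- list(
    command = command,
    seed = run_config$seed,
    filter = unclass(run_config$filter),
    test = run_config$test,
    package_version = as.character(utils::packageVersion("ntdburden")),
    input_md5 = as.list(tools::md5sum(inputs))
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

resolve_path <- function(run_config, key, required = TRUE) {
  p <- run_config$paths[[key]]
  if (is.null(p)) {
    if (required) stop("run config is missing path: ", key, call. = FALSE)
    return(NULL)
  }
  if (!all(file.exists(unlist(p)))) {
    stop("configured ", key, " path does not exist: ",
         paste(unlist(p), collapse = ", "), call. = FALSE)
  }
  p
}

#' Run the basic filter stage
#'
#' Reads the configured VCF and PED, applies the filter cascade, and
#' writes the filtered VCF, the funnel as JSON and text, and a manifest.
#'
#' @param run_config A [load_run_config()] object with `paths$vcf`,
#'   `paths$ped` (optional) and `paths$out_dir`.
#' @return List with `variants`, `funnel` and `paths` (outputs), invisibly.
#' @export
run_filter <- function(run_config) {
  vcf_path <- resolve_path(run_config, "vcf")
  ped_path <- resolve_path(run_config, "ped", required = FALSE)
  out_dir <- run_config$paths$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  vs <- read_vcf(vcf_path)
  ped <- if (!is.null(ped_path)) read_ped(ped_path) else NULL
  res <- apply_filter_cascade(vs, pedigree = ped, config = run_config$filter)

  out_vcf <- file.path(out_dir, "filtered.vcf")
  out_json <- file.path(out_dir, "funnel.json")
  write_vcf(res$variants, out_vcf)
  jsonlite::write_json(res$funnel, out_json, auto_unbox = TRUE, pretty = TRUE)
  message(paste(utils::capture.output(print(as.data.frame(res$funnel))),
                collapse = "\n"))
  write_manifest("filter", run_config, out_dir,
                 c(vcf = vcf_path, ped = ped_path %||% character()))
  invisible(list(variants = res$variants, funnel = res$funnel,
                 paths = list(vcf = out_vcf, funnel = out_json)))
}

#' Run candidate-gene prioritization and segregation
#'
#' Filter cascade, candidate-gene restriction, removal of previously
#' published mutations, segregation prioritization and compound-het scan;
#' writes the segregation and compound-het reports as TSV.
#'
#' @param run_config A [load_run_config()] object with `paths$vcf`,
#'   `paths$ped`, `paths$gene_lists` (map tag -> path), and optionally
#'   `paths$published` and `paths$out_dir`.
#' @return List with `candidates` (prioritized `variant_set`),
#'   `segregation`, `compound_het` and `funnel`, invisibly.
#' @export
run_candidates <- function(run_config) {
  vcf_path <- resolve_path(run_config, "vcf")
  ped_path <- resolve_path(run_config, "ped")
  lists <- resolve_path(run_config, "gene_lists", required = FALSE)
  pub_path <- resolve_path(run_config, "published", required = FALSE)
  out_dir <- run_config$paths$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  vs <- read_vcf(vcf_path)
  ped <- read_ped(ped_path)
  filtered <- apply_filter_cascade(vs, pedigree = ped,
                                   config = run_config$filter)$variants

  if (is.null(lists) || !length(lists)) {
    warning("no candidate gene lists supplied; empty report", call. = FALSE)
    gene_list <- tibble(symbol = character(), tags = list())
  } else {
    gene_list <- do.call(merge_gene_lists, lapply(names(lists), function(tag) {
      read_gene_list(lists[[tag]], tag)
    }))
  }
  cand <- select_candidate_variants(filtered, gene_list, run_config$filter)
  if (!is.null(pub_path)) {
    cand <- remove_published(cand, read_published_mutations(pub_path))
  }
  pri <- prioritize_by_segregation(cand, ped)
  ch <- compound_het_scan(cand, ped)

  write_results_tsv(pri$segregation, file.path(out_dir, "segregation.tsv"))
  write_results_tsv(ch, file.path(out_dir, "compound_het.tsv"))
  write_vcf(pri$variants, file.path(out_dir, "candidates.vcf"))
  write_manifest("candidates", run_config, out_dir,
                 c(vcf = vcf_path, ped = ped_path))
  invisible(list(candidates = pri$variants, segregation = pri$segregation,
                 compound_het = ch, all_candidates = cand))
}

#' Run the gene burden scan
#'
#' Filters the case and control VCFs with identical parameters, counts
#' carrier-observations per gene, and writes the burden report as TSV and
#' JSON.
#'
#' @param run_config A [load_run_config()] object with `paths$vcf` (cases),
#'   `paths$control_vcf`, optional `paths$ped`, `paths$gene_models`,
#'   `paths$blacklist`, and `paths$out_dir`; cohort sizes and test options
#'   under `test`.
#' @return The burden-result tibble, invisibly.
#' @export
run_burden <- function(run_config) {
  case_path <- resolve_path(run_config, "vcf")
  ctrl_path <- resolve_path(run_config, "control_vcf")
  ped_path <- resolve_path(run_config, "ped", required = FALSE)
  gm_path <- resolve_path(run_config, "gene_models", required = FALSE)
  bl_path <- resolve_path(run_config, "blacklist", required = FALSE)
  out_dir <- run_config$paths$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  ped <- if (!is.null(ped_path)) read_ped(ped_path) else NULL
  case_vs <- apply_filter_cascade(read_vcf(case_path), pedigree = ped,
                                  config = run_config$filter)$variants
  ctrl_vs <- apply_filter_cascade(read_vcf(ctrl_path),
                                  config = run_config$filter)$variants
  tst <- run_config$test
  res <- gene_burden_scan(
    case_vs, ctrl_vs,
    n_cases = tst$n_cases, n_controls = tst$n_controls,
    case_samples = if (!is.null(ped)) affected_samples(ped) else NULL,
    gene_models = if (!is.null(gm_path)) read_gene_models(gm_path) else NULL,
    blacklist = if (!is.null(bl_path)) read_blacklist(bl_path) else character(),
    alpha = tst$alpha, n_genes_tested = tst$n_genes_bonferroni,
    tail = tst$tail, pseudocount = tst$pseudocount
  )
  write_results_tsv(res, file.path(out_dir, "burden.tsv"))
  jsonlite::write_json(res, file.path(out_dir, "burden.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest("burden", run_config, out_dir,
                 c(case = case_path, control = ctrl_path))
  invisible(res)
}

#' Run the replication-cohort test
#'
#' Applies the replication filter (frequency + probably-damaging impact) to
#' a replication VCF, counts case and control carrier-observations using
#' the sample lists in `run_config$test$case_samples` /
#' `control_samples` (or a PED), and runs the single-gene exact Poisson
#' comparison.
#'
#' @param run_config A [load_run_config()] with `paths$vcf`, sample
#'   assignments, and `test$n_cases` / `test$n_controls` (replication
#'   cohort sizes).
#' @return One-row burden-result tibble, invisibly.
#' @export
run_replicate <- function(run_config) {
  vcf_path <- resolve_path(run_config, "vcf")
  ped_path <- resolve_path(run_config, "ped", required = FALSE)
  out_dir <- run_config$paths$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  vs <- apply_replication_filter(read_vcf(vcf_path), run_config$filter)
  tst <- run_config$test
  if (!is.null(ped_path)) {
    ped <- read_ped(ped_path)
    case_samples <- affected_samples(ped)
    control_samples <- setdiff(ped$sample_id, case_samples)
  } else {
    case_samples <- tst$case_samples
    control_samples <- tst$control_samples
  }
  k_case <- sum(count_carrier_observations(vs, case_samples)$k)
  k_ctrl <- sum(count_carrier_observations(vs, control_samples)$k)
  res <- replication_test(k_case, k_ctrl, tst$n_cases, tst$n_controls,
                          tail = tst$tail, alpha = tst$alpha)
  message(sprintf("replication: k_case=%d k_ctrl=%d p=%.4g",
                  k_case, k_ctrl, res$p_value))
  write_results_tsv(res, file.path(out_dir, "replication.tsv"))
  write_manifest("replicate", run_config, out_dir, c(vcf = vcf_path))
  invisible(res)
}

#' Run cohort simulation / test evaluation
#'
#' @param run_config A [load_run_config()]; simulation parameters under
#'   `run_config$sim` are passed to [simulation_config()] with
#'   `run_config$seed`.
#' @param n_replicates,alphas Passed to [evaluate_type1_power()] by
#'   `run_evaluate`.
#' @return `run_simulate`: the written file paths; `run_evaluate`: the
#'   `burden_evaluation` object. Both invisibly.
#' @export
run_simulate <- function(run_config) {
  out_dir <- run_config$paths$out_dir %||% "."
  sim_cfg <- do.call(simulation_config,
                     c(list(seed = run_config$seed), run_config$sim %||% list()))
  sim <- simulate_cohort(sim_cfg)
  paths <- write_cohort(sim, out_dir)
  write_manifest("simulate", run_config, out_dir)
  invisible(paths)
}

#' @rdname run_simulate
#' @export
run_evaluate <- function(run_config, n_replicates = 10, alphas = 0.05) {
  out_dir <- run_config$paths$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim_cfg <- do.call(simulation_config,
                     c(list(seed = run_config$seed), run_config$sim %||% list()))
  ev <- evaluate_type1_power(sim_cfg, n_replicates = n_replicates,
                             alphas = alphas)
  write_results_tsv(ev$type1, file.path(out_dir, "type1.tsv"))
  if (nrow(ev$power)) write_results_tsv(ev$power, file.path(out_dir, "power.tsv"))
  jsonlite::write_json(
    list(type1 = ev$type1, power = ev$power, ratio_recovery = ev$ratio_recovery),
    file.path(out_dir, "evaluation.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA
  )
  write_manifest("evaluate", run_config, out_dir)
  invisible(ev)
}
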