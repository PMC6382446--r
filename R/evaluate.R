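#' Empirical type-I error, power and rate-ratio recovery of the burden test
#'
#' Runs the full analysis path — cohort simulation, the basic filter
#' cascade on each arm (affected-carrier QC for the case arm, all-carrier
#' QC for controls), and the per-gene exact Poisson burden scan — over
#' replicate cohorts, then summarises:
#' * per significance level, the fraction of null-gene tests with
#'   `p < alpha` (genes with no qualifying variant in either arm count as
#'   non-significant);
#' * per enriched gene and level, the fraction of replicates reaching
#'   significance;
#' * per enriched gene, the mean estimated case/control rate ratio, using a
#'   0.5 continuity pseudocount on both counts.
#'
#' @param config A [simulation_config()] (replicate `r` uses seed
#'   `config$seed + r - 1`).
#' @param n_replicates Number of replicate cohorts (>= 1).
#' @param alphas Numeric vector of significance levels.
#' @param pseudocount Pseudocount for zero control counts inside the scan
#'   (default 0.5).
#' @return An object of class `burden_evaluation`: list with
#'   `type1` (tibble `alpha`, `n_null_tests`, `n_false_positive`,
#'   `empirical_type1`), `power` (tibble `gene`, `ratio`, `alpha`,
#'   `power`), `ratio_recovery` (tibble `gene`, `true_ratio`,
#'   `mean_estimated_ratio`, `relative_error`), `n_replicates`, `alphas`,
#'   and `config`.
#' @export
evaluate_type1_power <- function(config, n_replicates, alphas = 0.05,
                                 pseudocount = 0.5) {
  stopifnot(inherits(config, "simulation_config"), n_replicates >= 1)
  genes <- gene_symbols(config$n_genes)
  enriched <- names(config$enriched_genes)
  null_genes <- setdiff(genes, enriched)
  if (!length(null_genes)) {
    stop("type-I evaluation needs at least one null gene", call. = FALSE)
  }

  fp <- setNames(numeric(length(alphas)), as.character(alphas))
  hits <- if (length(enriched)) {
    matrix(0, nrow = length(enriched), ncol = length(alphas),
           dimnames = list(enriched, as.character(alphas)))
  } else NULL
  ratio_sum <- setNames(numeric(length(enriched)), enriched)

  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    sim <- simulate_cohort(cfg)

    case_vs <- subset_samples(sim$variants, sim$case_samples)
    ctrl_vs <- subset_samples(sim$variants, sim$control_samples)
    case_f <- apply_filter_cascade(case_vs, pedigree = sim$pedigree)
    ctrl_f <- apply_filter_cascade(ctrl_vs)

    scan <- gene_burden_scan(
      case_f$variants, ctrl_f$variants,
      n_cases = config$n_cases, n_controls = config$n_controls,
      pseudocount = pseudocount
    )

    null_rows <- scan[scan$gene %in% null_genes, , drop = FALSE]
    for (j in seq_along(alphas)) {
      fp[j] <- fp[j] + sum(null_rows$p_value < alphas[j])
    }
    for (g in enriched) {
      row <- scan[scan$gene == g, , drop = FALSE]
      k_case <- if (nrow(row)) row$k_case[1] else 0L
      k_ctrl <- if (nrow(row)) row$k_ctrl[1] else 0L
      p <- if (nrow(row)) row$p_value[1] else 1
      for (j in seq_along(alphas)) {
        hits[g, j] <- hits[g, j] + (p < alphas[j])
      }
      est <- ((k_case + 0.5) / (config$n_cases * 2)) /
        ((k_ctrl + 0.5) / (config$n_controls * 2))
      ratio_sum[g] <- ratio_sum[g] + est
    }
  }

  n_null_tests <- length(null_genes) * n_replicates
  type1 <- tibble(
    alpha = alphas,
    n_null_tests = n_null_tests,
    n_false_positive = as.integer(unname(fp)),
    empirical_type1 = unname(fp) / n_null_tests
  )
  power <- if (length(enriched)) {
    tidyr::expand_grid(gene = enriched, alpha = alphas) |>
      dplyr::mutate(
        ratio = unname(config$enriched_genes[.data$gene]),
        power = mapply(function(g, a) hits[g, as.character(a)] / n_replicates,
                       .data$gene, .data$alpha)
      ) |>
      dplyr::select("gene", "ratio", "alpha", "power")
  } else {
    tibble(gene = character(), ratio = double(), alpha = double(),
           power = double())
  }
  recovery <- if (length(enriched)) {
    tibble(
      gene = enriched,
      true_ratio = unname(config$enriched_genes[enriched]),
      mean_estimated_ratio = unname(ratio_sum[enriched]) / n_replicates
    ) |>
      dplyr::mutate(relative_error =
        abs(.data$mean_estimated_ratio - .data$true_ratio) / .data$true_ratio)
  } else {
    tibble(gene = character(), true_ratio = double(),
           mean_estimated_ratio = double(), relative_error = double())
  }

  structure(
    list(type1 = type1, power = power, ratio_recovery = recovery,
         n_replicates = n_replicates, alphas = alphas, config = config),
    class = "burden_evaluation"
  )
}

#' @export
print.burden_evaluation <- function(x, ...) {
  cat(sprintf("<burden_evaluation> %d replicates, %d genes\n",
              x$n_replicates, x$config$n_genes))
  cat("Type-I error:\n"); print(x$type1)
  if (nrow(x$power)) { cat("Power:\n"); print(x$power) }
  if (nrow(x$ratio_recovery)) { cat("Rate-ratio recovery:\n"); print(x$ratio_recovery) }
  invisible(x)
}
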