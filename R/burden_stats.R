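#' Per-allele, per-basepair mutation rate
#'
#' The rate a gene's qualifying-variant count implies:
#' `k / (n * L * 2)` — count divided by cohort size, coding length in bp,
#' and two alleles per individual.
#'
#' @param k Qualifying-variant carrier-observation count (>= 0).
#' @param n Cohort size (> 0).
#' @param L Gene coding length in bp (> 0).
#' @return The rate per allele-basepair.
#' @export
mutation_rate <- function(k, n, L) {
  if (any(n <= 0) || any(L <= 0)) {
    stop("cohort size and gene length must be positive", call. = FALSE)
  }
  if (any(k < 0)) stop("variant count must be non-negative", call. = FALSE)
  k / (n * L * 2)
}

#' Exact Poisson rate-comparison p-value
#'
#' Tests whether the case cohort's qualifying-variant count exceeds what
#' the control cohort's rate predicts. The expected case count under the
#' control rate is `lambda = k_ctrl * E_case / E_ctrl` (exposures in
#' allele-basepairs, or plain allele counts — gene length cancels in the
#' ratio), and the default p-value is the upper tail `P(X >= k_case)` for
#' `X ~ Poisson(lambda)`. A doubled two-sided alternative
#' `min(1, 2 * min(P(X >= k), P(X <= k)))` is available.
#'
#' When `k_ctrl = 0` the control rate is degenerate; with `pseudocount = 0`
#' (the default) the function returns `p = 0` for `k_case > 0` with a
#' warning, otherwise the pseudocount is added to `k_ctrl` before forming
#' `lambda`.
#'
#' @param k_case,k_ctrl Non-negative counts.
#' @param e_case,e_ctrl Positive exposures.
#' @param tail `"upper"` (default) or `"two_sided_doubled"`.
#' @param pseudocount Added to `k_ctrl` only when it is zero (default 0).
#' @return p-value in \[0, 1\].
#' @export
poisson_burden_p <- function(k_case, k_ctrl, e_case, e_ctrl,
                             tail = c("upper", "two_sided_doubled"),
                             pseudocount = 0) {
  tail <- match.arg(tail)
  stopifnot(k_case >= 0, k_ctrl >= 0, e_case > 0, e_ctrl > 0)
  if (k_ctrl == 0 && pseudocount > 0) k_ctrl <- pseudocount
  lambda <- k_ctrl * e_case / e_ctrl
  if (lambda == 0) {
    if (k_case > 0) {
      warning("degenerate lambda = 0 with k_case > 0: p = 0", call. = FALSE)
      return(0)
    }
    return(1)
  }
  upper <- ppois(k_case - 1, lambda, lower.tail = FALSE) # P(X >= k_case)
  if (tail == "upper") return(upper)
  lower <- ppois(k_case, lambda) # P(X <= k_case)
  min(1, 2 * min(upper, lower))
}

#' Bonferroni significance threshold
#'
#' @param alpha Family-wise significance level in (0, 1).
#' @param n_genes Number of genes tested (>= 1).
#' @return `alpha / n_genes`.
#' @export
bonferroni_threshold <- function(alpha, n_genes) {
  stopifnot(alpha > 0, alpha < 1, n_genes >= 1)
  alpha / n_genes
}

#' Count qualifying carrier-observations per gene
#'
#' The burden test's counting unit: one observation per (carrier
#' individual, variant) pair — an individual carrying a variant counts once
#' per variant, and a variant shared by two individuals counts twice.
#'
#' @param vs A filtered [variant_set()].
#' @param samples Optional sample ids to restrict to.
#' @return A tibble with columns `gene` and `k`.
#' @export
count_carrier_observations <- function(vs, samples = NULL) {
  car <- carriers(vs, samples)
  if (!nrow(car)) return(tibble(gene = character(), k = integer()))
  car <- dplyr::left_join(car[, c("variant_id", "sample_id")],
                          vs$variants[, c("variant_id", "gene")],
                          by = "variant_id")
  dplyr::count(car, gene = toupper(.data$gene), name = "k")
}

#' Per-gene exact Poisson burden scan
#'
#' For every gene with at least one qualifying variant in either cohort,
#' compares case and control carrier-observation counts with the exact
#' Poisson rate test at allele-count exposures (`n * 2`; gene length
#' cancels), applies the Bonferroni threshold, and marks blacklisted genes
#' (known misalignment artifacts) as excluded. Genes whose control count
#' exceeds the cross-gene 99.9th percentile are flagged with a warning as
#' possible misalignment artifacts but never auto-excluded.
#'
#' @param case_vs,control_vs Filtered [variant_set()]s for the two cohorts
#'   (filtered with identical parameters).
#' @param n_cases,n_controls Cohort sizes.
#' @param case_samples,control_samples Optional sample restrictions for
#'   counting (defaults: all samples of each set).
#' @param gene_models Optional [read_gene_models()] tibble; when supplied,
#'   per-allele-basepair rates are reported for genes it covers.
#' @param blacklist Character vector of genes to exclude.
#' @param alpha Family-wise significance level (default 0.05).
#' @param n_genes_tested Bonferroni denominator (default 20389, the exome
#'   gene count of the discovery analysis).
#' @param tail Tail convention for [poisson_burden_p()].
#' @param pseudocount Added to zero control counts (default 0.5); flagged
#'   in the `pseudocount_applied` column.
#' @return A tibble of burden results sorted by p-value: columns `gene`,
#'   `k_case`, `k_ctrl`, `e_case`, `e_ctrl`, `rate_case`, `rate_ctrl`,
#'   `lambda`, `p_value`, `alpha_bonferroni`, `significant`,
#'   `excluded_reason`, `pseudocount_applied`.
#' @export
gene_burden_scan <- function(case_vs, control_vs, n_cases, n_controls,
                             case_samples = NULL, control_samples = NULL,
                             gene_models = NULL, blacklist = character(),
                             alpha = 0.05, n_genes_tested = 20389,
                             tail = "upper", pseudocount = 0.5) {
  kc <- count_carrier_observations(case_vs, case_samples)
  kt <- count_carrier_observations(control_vs, control_samples)
  counts <- dplyr::full_join(
    dplyr::rename(kc, k_case = "k"),
    dplyr::rename(kt, k_ctrl = "k"),
    by = "gene"
  )
  counts$k_case[is.na(counts$k_case)] <- 0L
  counts$k_ctrl[is.na(counts$k_ctrl)] <- 0L
  burden_table(counts, n_cases, n_controls, gene_models, blacklist,
               alpha, n_genes_tested, tail, pseudocount)
}

# Shared result assembly for the scan and the replication test.
burden_table <- function(counts, n_cases, n_controls, gene_models = NULL,
                         blacklist = character(), alpha = 0.05,
                         n_genes_tested = 20389, tail = "upper",
                         pseudocount = 0.5) {
  e_case <- n_cases * 2
  e_ctrl <- n_controls * 2
  thr <- bonferroni_threshold(alpha, n_genes_tested)
  blacklist <- toupper(blacklist)

  n <- nrow(counts)
  if (n == 0) {
    return(tibble(
      gene = character(), k_case = integer(), k_ctrl = integer(),
      e_case = double(), e_ctrl = double(), rate_case = double(),
      rate_ctrl = double(), lambda = double(), p_value = double(),
      alpha_bonferroni = double(), significant = logical(),
      excluded_reason = character(), pseudocount_applied = logical()
    ))
  }

  L <- if (!is.null(gene_models)) {
    unname(setNames(gene_models$coding_length, gene_models$symbol)[counts$gene])
  } else rep(NA_real_, n)

  k_case <- counts$k_case
  k_ctrl <- counts$k_ctrl
  pc_applied <- k_ctrl == 0 & pseudocount > 0
  k_eff <- k_ctrl + ifelse(pc_applied, pseudocount, 0)
  lambda <- k_eff * e_case / e_ctrl
  p_upper <- ppois(k_case - 1, lambda, lower.tail = FALSE)
  p <- if (tail == "upper") {
    p_upper
  } else {
    pmin(1, 2 * pmin(p_upper, ppois(k_case, lambda)))
  }
  degen <- lambda == 0
  if (any(degen & k_case > 0)) {
    warning("degenerate lambda = 0 with k_case > 0 for gene(s): ",
            paste(counts$gene[degen & k_case > 0], collapse = ", "),
            call. = FALSE)
  }
  p[degen] <- ifelse(k_case[degen] > 0, 0, 1)

  have_len <- !is.na(L)
  out <- tibble(
    gene = counts$gene, k_case = k_case, k_ctrl = k_ctrl,
    e_case = ifelse(have_len, e_case * L, e_case),
    e_ctrl = ifelse(have_len, e_ctrl * L, e_ctrl),
    rate_case = ifelse(have_len, k_case / (n_cases * L * 2), k_case / e_case),
    rate_ctrl = ifelse(have_len, k_ctrl / (n_controls * L * 2), k_ctrl / e_ctrl),
    lambda = lambda,
    p_value = p,
    alpha_bonferroni = thr,
    significant = NA,
    excluded_reason = ifelse(counts$gene %in% blacklist, "blacklist", ""),
    pseudocount_applied = pc_applied
  )
  out$significant <- out$p_value < out$alpha_bonferroni & out$excluded_reason == ""

  hi <- quantile(out$k_ctrl, 0.999, names = FALSE, type = 1)
  flag <- out$excluded_reason == "" & out$k_ctrl > hi
  if (nrow(out) >= 10 && any(flag)) {
    warning("gene(s) with control count above the 99.9th percentile (possible ",
            "misalignment): ", paste(out$gene[flag], collapse = ", "),
            call. = FALSE)
  }
  dplyr::arrange(out, .data$p_value, .data$gene)
}

#' Single-gene replication test
#'
#' The targeted-resequencing replication comparison: counts from equal-size
#' case and control cohorts at allele-count exposures (`n * 2`; gene length
#' cancels), tested with the exact Poisson rate comparison.
#'
#' @param k_case,k_ctrl Qualifying-variant counts.
#' @param n_cases,n_controls Cohort sizes.
#' @param gene Gene symbol for the report (default `"(replication)"`).
#' @param tail Tail convention (default upper).
#' @param alpha Significance level (default 0.05, single gene: no
#'   multiple-testing division).
#' @param pseudocount Added to a zero control count (default 0).
#' @return A one-row burden-result tibble (see [gene_burden_scan()]).
#' @export
replication_test <- function(k_case, k_ctrl, n_cases, n_controls,
                             gene = "(replication)", tail = "upper",
                             alpha = 0.05, pseudocount = 0) {
  burden_table(
    tibble(gene = gene, k_case = as.integer(k_case), k_ctrl = as.integer(k_ctrl)),
    n_cases, n_controls,
    alpha = alpha, n_genes_tested = 1, tail = tail, pseudocount = pseudocount
  )
}
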