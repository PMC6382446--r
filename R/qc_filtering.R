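#' Filter configuration
#'
#' Thresholds of the basic filter cascade. The defaults reproduce the
#' discovery analysis's printed rules: genotype quality at the conventional
#' 99 cap, strictly more than 3 alternate reads on each strand, alternate
#' read fraction strictly above 0.15, and removal of variants whose maximum
#' population allele frequency exceeds 1%. A variant absent from every
#' population database is treated as novel and kept.
#'
#' @param min_gq Minimum genotype quality (inclusive; default 99).
#' @param min_strand_reads Per-strand alternate-read threshold, exclusive
#'   (default 3: require at least 4 reads on each strand).
#' @param min_alt_fraction Alternate-read fraction threshold, exclusive
#'   (default 0.15).
#' @param max_pop_freq Population-frequency removal threshold, exclusive
#'   (default 0.01: drop variants with any source frequency above 1%).
#' @param polyphen_rule How missense impact is judged: `"category_tag"`
#'   uses the probably-damaging categorical tag; `"score_cutoff"` uses
#'   `polyphen_score_cutoff` for inputs that lack categories.
#' @param polyphen_score_cutoff Score cutoff for the `"score_cutoff"` rule
#'   (default 0.80).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_gq = 99L, min_strand_reads = 3L,
                          min_alt_fraction = 0.15, max_pop_freq = 0.01,
                          polyphen_rule = c("category_tag", "score_cutoff"),
                          polyphen_score_cutoff = 0.80) {
  polyphen_rule <- match.arg(polyphen_rule)
  stopifnot(
    min_gq >= 0, min_strand_reads >= 0,
    min_alt_fraction >= 0, min_alt_fraction <= 1,
    max_pop_freq >= 0, max_pop_freq <= 1,
    polyphen_score_cutoff >= 0, polyphen_score_cutoff <= 1
  )
  structure(
    list(
      min_gq = as.integer(min_gq),
      min_strand_reads = as.integer(min_strand_reads),
      min_alt_fraction = min_alt_fraction,
      max_pop_freq = max_pop_freq,
      freq_missing_policy = "treat_as_novel",
      polyphen_rule = polyphen_rule,
      polyphen_score_cutoff = polyphen_score_cutoff
    ),
    class = "filter_config"
  )
}

#' Consequence-class filter
#'
#' Keep everything except synonymous and noncoding variants. Variants with
#' consequence `other` are kept with a warning.
#'
#' @param variants Variant tibble (the `variants` element of a
#'   [variant_set()]), or a `variant_set`.
#' @return Logical vector: `TRUE` = keep.
#' @export
consequence_filter <- function(variants) {
  v <- if (inherits(variants, "variant_set")) variants$variants else variants
  if (any(v$consequence == "other")) {
    warning("variant(s) with consequence 'other' kept by consequence filter",
            call. = FALSE)
  }
  !(v$consequence %in% c("synonymous", "noncoding"))
}

#' Population-frequency filter
#'
#' Drop a variant when its maximum allele frequency over the available
#' population sources exceeds `max_pop_freq`; a variant absent from all
#' sources is novel and kept.
#'
#' @param variants Variant tibble or `variant_set`.
#' @param config A [filter_config()].
#' @return Logical vector: `TRUE` = keep.
#' @export
frequency_filter <- function(variants, config = filter_config()) {
  v <- if (inherits(variants, "variant_set")) variants$variants else variants
  vapply(v$pop_freqs, function(fr) {
    length(fr) == 0 || max(fr) <= config$max_pop_freq
  }, logical(1))
}

#' Genotype quality-control predicate
#'
#' A carrier genotype passes when genotype quality reaches `min_gq`, both
#' strands carry strictly more than `min_strand_reads` alternate reads, and
#' the alternate-read fraction strictly exceeds `min_alt_fraction`. Zero or
#' missing depth fails (the fraction is undefined); any missing statistic
#' fails.
#'
#' @param gq,alt_fwd,alt_rev,depth Vectors of genotype statistics (recycled
#'   per R rules). Alternatively pass a genotype tibble as `gq`.
#' @param config A [filter_config()].
#' @return Logical vector.
#' @export
passes_genotype_qc <- function(gq, alt_fwd = NULL, alt_rev = NULL,
                               depth = NULL, config = filter_config()) {
  if (is.data.frame(gq)) {
    g <- gq
    gq <- g$gq; alt_fwd <- g$alt_fwd; alt_rev <- g$alt_rev; depth <- g$depth
  }
  frac <- ifelse(!is.na(depth) & depth > 0, (alt_fwd + alt_rev) / depth, NA_real_)
  ok <- gq >= config$min_gq &
    alt_fwd > config$min_strand_reads &
    alt_rev > config$min_strand_reads &
    frac > config$min_alt_fraction
  ok & !is.na(ok)
}

#' Impact class of a variant
#'
#' `lof` for stop-gained, frameshift or splice variants; for missense
#' variants, `probably_damaging_missense` when the PolyPhen-2 category is
#' probably damaging (or, under the score rule, the score reaches the
#' cutoff); everything else is `other`. A missense variant with unknown
#' PolyPhen under the category rule falls to `other` with a warning.
#'
#' @param variants Variant tibble or `variant_set`.
#' @param config A [filter_config()].
#' @return Character vector with values `"lof"`,
#'   `"probably_damaging_missense"` or `"other"`.
#' @export
impact_class <- function(variants, config = filter_config()) {
  v <- if (inherits(variants, "variant_set")) variants$variants else variants
  out <- rep("other", nrow(v))
  out[v$consequence %in% LOF_CONSEQUENCES] <- "lof"
  mis <- v$consequence == "missense"
  if (config$polyphen_rule == "category_tag") {
    damaging <- mis & v$polyphen_category == "probably_damaging"
    unk <- mis & v$polyphen_category == "unknown"
    if (any(unk)) {
      warning(sum(unk), " missense variant(s) with unknown PolyPhen category",
              " classified as 'other'", call. = FALSE)
    }
  } else {
    damaging <- mis & !is.na(v$polyphen_score) &
      v$polyphen_score >= config$polyphen_score_cutoff
  }
  out[damaging] <- "probably_damaging_missense"
  out
}

#' Apply the basic filter cascade
#'
#' Four stages in fixed order: (1) remove synonymous and noncoding
#' variants; (2) remove common variants (population frequency above the
#' threshold in any source); (3) genotype quality control — a variant is
#' retained only if at least one relevant carrier passes the genotype QC
#' predicate, and carriers that fail are cleared to missing; (4) keep only
#' loss-of-function and probably-damaging missense variants. When a
#' pedigree is supplied the relevant carriers of stage 3 are the affected
#' individuals; without one (for example a control cohort) all carriers
#' count.
#'
#' @param vs A [variant_set()].
#' @param pedigree Optional pedigree tibble ([read_ped()]).
#' @param config A [filter_config()].
#' @return A list with elements `variants` (the filtered `variant_set`) and
#'   `funnel` (a tibble with columns `stage`, `n_in`, `n_removed`, `n_out`).
#' @export
apply_filter_cascade <- function(vs, pedigree = NULL, config = filter_config()) {
  stages <- c("consequence", "frequency", "genotype_qc", "impact")
  funnel <- tibble(stage = stages, n_in = NA_integer_,
                   n_removed = NA_integer_, n_out = NA_integer_)
  record_stage <- function(funnel, stage, n_in, n_out) {
    i <- match(stage, funnel$stage)
    funnel$n_in[i] <- n_in
    funnel$n_out[i] <- n_out
    funnel$n_removed[i] <- n_in - n_out
    funnel
  }

  # Stage 1: consequence class
  n_in <- n_variants(vs)
  keep <- suppressWarnings(consequence_filter(vs))
  vs <- subset_variants(vs, vs$variants$variant_id[keep])
  funnel <- record_stage(funnel, "consequence", n_in, n_variants(vs))

  # Stage 2: population frequency
  n_in <- n_variants(vs)
  keep <- frequency_filter(vs, config)
  vs <- subset_variants(vs, vs$variants$variant_id[keep])
  funnel <- record_stage(funnel, "frequency", n_in, n_variants(vs))

  # Stage 3: carrier genotype QC
  n_in <- n_variants(vs)
  qc_samples <- if (!is.null(pedigree)) affected_samples(pedigree) else vs$samples
  g <- vs$genotypes
  is_carrier <- g$allele_state %in% c("het", "hom_alt")
  pass <- passes_genotype_qc(g, config = config)
  fail_carrier <- is_carrier & !pass
  # retained iff >=1 relevant carrier passes QC
  good <- unique(g$variant_id[is_carrier & pass & g$sample_id %in% qc_samples])
  # clear failing carriers on retained records
  clear <- fail_carrier & g$variant_id %in% good
  g$allele_state[clear] <- "missing"
  g$gq[clear] <- NA_integer_
  g$alt_fwd[clear] <- NA_integer_
  g$alt_rev[clear] <- NA_integer_
  g$depth[clear] <- NA_integer_
  g$alt_fraction[clear] <- NA_real_
  vs <- variant_set(vs$variants, g, vs$samples)
  vs <- subset_variants(vs, good)
  funnel <- record_stage(funnel, "genotype_qc", n_in, n_variants(vs))

  # Stage 4: impact prioritization
  n_in <- n_variants(vs)
  cls <- suppressWarnings(impact_class(vs, config))
  keep <- cls %in% c("lof", "probably_damaging_missense")
  vs <- subset_variants(vs, vs$variants$variant_id[keep])
  funnel <- record_stage(funnel, "impact", n_in, n_variants(vs))

  list(variants = vs, funnel = funnel)
}

#' Replication-cohort filter
#'
#' The lighter filter used on targeted-resequencing replication data: keep
#' variants with population frequency below the common-variant threshold
#' (novel variants kept) whose impact class is loss-of-function or
#' probably-damaging missense. No genotype-level QC stage.
#'
#' @param vs A [variant_set()].
#' @param config A [filter_config()].
#' @return A filtered `variant_set`.
#' @export
apply_replication_filter <- function(vs, config = filter_config()) {
  keep_freq <- frequency_filter(vs, config)
  cls <- suppressWarnings(impact_class(vs, config))
  keep <- keep_freq & cls %in% c("lof", "probably_damaging_missense")
  subset_variants(vs, vs$variants$variant_id[keep])
}
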