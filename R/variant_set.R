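#' Construct a variant set
#'
#' The central container of the pipeline: a table of annotated variants plus
#' a sparse table of per-sample genotype entries. One variant row corresponds
#' to one ALT allele at one site (multi-allelic sites are decomposed on
#' input). The genotype table stores only informative entries — heterozygous,
#' homozygous-alternate and missing calls; a cohort sample absent from a
#' variant's genotype rows is an implicit genotyped homozygous-reference
#' call. This keeps simulated cohorts (thousands of variants times hundreds
#' of samples) compact while preserving the carrier/non-carrier/missing
#' distinction segregation analysis needs.
#'
#' @param variants Tibble with columns `variant_id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`, `gene`, `transcript`, `cdna_change`, `protein_change`,
#'   `consequence` (one of `r paste(CONSEQUENCE_LEVELS, collapse = ", ")`),
#'   `polyphen_category`, `polyphen_score` (in \[0,1\] or `NA`), and
#'   `pop_freqs` (list column of named numeric allele frequencies in \[0,1\];
#'   an empty vector means absent from all population databases).
#' @param genotypes Tibble with columns `variant_id`, `sample_id`,
#'   `allele_state` (`het`, `hom_alt` or `missing`), `gq`, `alt_fwd`,
#'   `alt_rev`, `depth`, `alt_fraction`.
#' @param samples Character vector of all cohort sample ids (the VCF sample
#'   columns); defines which implicit entries are homozygous reference.
#'
#' @return An object of class `variant_set`.
#' @export
variant_set <- function(variants = empty_variants(),
                        genotypes = empty_genotypes(),
                        samples = character()) {
  variants <- as_tibble(variants)
  genotypes <- as_tibble(genotypes)
  vs <- structure(
    list(variants = variants, genotypes = genotypes, samples = samples),
    class = "variant_set"
  )
  validate_variant_set(vs)
  vs
}

empty_variants <- function() {
  tibble(
    variant_id = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), gene = character(),
    transcript = character(), cdna_change = character(),
    protein_change = character(), consequence = character(),
    polyphen_category = character(), polyphen_score = double(),
    pop_freqs = list()
  )
}

empty_genotypes <- function() {
  tibble(
    variant_id = character(), sample_id = character(),
    allele_state = character(), gq = integer(),
    alt_fwd = integer(), alt_rev = integer(),
    depth = integer(), alt_fraction = double()
  )
}

validate_variant_set <- function(vs) {
  v <- vs$variants
  g <- vs$genotypes
  stopifnot(
    is.data.frame(v), is.data.frame(g),
    all(c("variant_id", "chrom", "pos", "ref", "alt", "gene", "consequence",
          "polyphen_category", "polyphen_score", "pop_freqs") %in% names(v)),
    all(c("variant_id", "sample_id", "allele_state") %in% names(g))
  )
  if (anyDuplicated(v$variant_id)) {
    stop("duplicate variant_id in variant table", call. = FALSE)
  }
  if (nrow(v)) {
    if (any(v$pos < 1)) stop("variant pos must be >= 1", call. = FALSE)
    if (any(v$ref == v$alt)) stop("ref and alt alleles must differ", call. = FALSE)
    bad <- setdiff(unique(v$consequence), CONSEQUENCE_LEVELS)
    if (length(bad)) {
      stop("unknown consequence class: ", paste(bad, collapse = ", "), call. = FALSE)
    }
    freqs <- unlist(v$pop_freqs, use.names = FALSE)
    if (length(freqs) && (any(freqs < 0) || any(freqs > 1))) {
      stop("population allele frequencies must lie in [0,1]", call. = FALSE)
    }
  }
  if (nrow(g)) {
    bad <- setdiff(unique(g$allele_state), ALLELE_STATES)
    if (length(bad)) {
      stop("unknown allele_state: ", paste(bad, collapse = ", "), call. = FALSE)
    }
    dup <- duplicated(g[, c("variant_id", "sample_id")])
    if (any(dup)) stop("duplicate (variant, sample) genotype entry", call. = FALSE)
    orphan <- setdiff(g$variant_id, v$variant_id)
    if (length(orphan)) {
      stop("genotype rows reference unknown variants: ",
           paste(head(orphan, 3), collapse = ", "), call. = FALSE)
    }
    ad <- g$alt_fwd + g$alt_rev
    over <- !is.na(ad) & !is.na(g$depth) & ad > g$depth
    if (any(over)) stop("alt_fwd + alt_rev exceeds depth", call. = FALSE)
  }
  invisible(vs)
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf(
    "<variant_set> %d variants, %d genotype entries, %d samples\n",
    nrow(x$variants), nrow(x$genotypes), length(x$samples)
  ))
  if (nrow(x$variants)) print(head(x$variants[, 1:6], 5))
  invisible(x)
}

#' Number of variants in a variant set
#' @param vs A `variant_set`.
#' @return Integer count.
#' @export
n_variants <- function(vs) nrow(vs$variants)

#' Cohort sample ids of a variant set
#' @param vs A `variant_set`.
#' @return Character vector.
#' @export
vs_samples <- function(vs) vs$samples

make_variant_id <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Keep a subset of variants
#'
#' @param vs A `variant_set`.
#' @param keep_ids Character vector of `variant_id`s to retain.
#' @return A `variant_set` restricted to those variants (genotype rows of
#'   dropped variants are discarded; the sample roster is unchanged).
#' @export
subset_variants <- function(vs, keep_ids) {
  variant_set(
    variants = vs$variants[vs$variants$variant_id %in% keep_ids, , drop = FALSE],
    genotypes = vs$genotypes[vs$genotypes$variant_id %in% keep_ids, , drop = FALSE],
    samples = vs$samples
  )
}

#' Restrict a variant set to a subset of samples
#'
#' Drops genotype entries of other samples and removes variants left without
#' any carrier among the kept samples.
#'
#' @param vs A `variant_set`.
#' @param samples Sample ids to keep.
#' @param drop_uncarried Drop variants with no remaining carrier (default TRUE).
#' @return A `variant_set`.
#' @export
subset_samples <- function(vs, samples, drop_uncarried = TRUE) {
  g <- vs$genotypes[vs$genotypes$sample_id %in% samples, , drop = FALSE]
  v <- vs$variants
  if (drop_uncarried) {
    carried <- unique(g$variant_id[g$allele_state %in% c("het", "hom_alt")])
    v <- v[v$variant_id %in% carried, , drop = FALSE]
    g <- g[g$variant_id %in% v$variant_id, , drop = FALSE]
  }
  variant_set(v, g, intersect(vs$samples, samples))
}

#' Carrier table of a variant set
#'
#' @param vs A `variant_set`.
#' @param samples Optional sample ids to restrict to.
#' @return Genotype rows whose `allele_state` is `het` or `hom_alt`.
#' @export
carriers <- function(vs, samples = NULL) {
  g <- vs$genotypes[vs$genotypes$allele_state %in% c("het", "hom_alt"), , drop = FALSE]
  if (!is.null(samples)) g <- g[g$sample_id %in% samples, , drop = FALSE]
  g
}

#' Allele state of one sample at one variant
#'
#' Resolves the sparse genotype storage: a cohort sample without an explicit
#' row is homozygous reference; a sample not on the roster is missing.
#'
#' @param vs A `variant_set`.
#' @param variant_id Single variant id.
#' @param sample_id Single sample id.
#' @return One of `"hom_ref"`, `"het"`, `"hom_alt"`, `"missing"`.
#' @export
allele_state_of <- function(vs, variant_id, sample_id) {
  hit <- vs$genotypes$variant_id == variant_id & vs$genotypes$sample_id == sample_id
  if (any(hit)) return(vs$genotypes$allele_state[which(hit)[1]])
  if (sample_id %in% vs$samples) "hom_ref" else "missing"
}

#' Combine variant sets over disjoint variants
#'
#' @param ... `variant_set` objects with pairwise-disjoint variant ids.
#' @return A single `variant_set`; the sample roster is the union.
#' @export
bind_variant_sets <- function(...) {
  sets <- list(...)
  variant_set(
    variants = dplyr::bind_rows(lapply(sets, function(s) s$variants)),
    genotypes = dplyr::bind_rows(lapply(sets, function(s) s$genotypes)),
    samples = unique(unlist(lapply(sets, function(s) s$samples)))
  )
}
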