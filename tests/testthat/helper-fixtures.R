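# Shared fixtures and independent oracles for the test suite.

ext_path <- function(...) system.file("extdata", ..., package = "ntdburden")

fixture_gene_list <- function() {
  merge_gene_lists(
    read_gene_list(ext_path("mouse_ntd_genes_synthetic.tsv"), "mouse_ntd"),
    read_gene_list(ext_path("folate_genes_synthetic.tsv"), "folate")
  )
}

# Build a one-variant tibble with overridable fields.
make_variant <- function(chrom = "1", pos = 100L, ref = "A", alt = "T",
                         gene = "GENEX", consequence = "missense",
                         polyphen_category = "probably_damaging",
                         polyphen_score = 0.95, pop_freqs = numeric(0),
                         cdna_change = "c.1A>T") {
  tibble::tibble(
    variant_id = paste(chrom, pos, ref, alt, sep = ":"),
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    gene = gene, transcript = "", cdna_change = cdna_change,
    protein_change = "", consequence = consequence,
    polyphen_category = polyphen_category, polyphen_score = polyphen_score,
    pop_freqs = list(pop_freqs)
  )
}

make_genotype <- function(variant_id, sample_id, allele_state = "het",
                          gq = 99L, alt_fwd = 8L, alt_rev = 9L, depth = 34L) {
  tibble::tibble(
    variant_id = variant_id, sample_id = sample_id,
    allele_state = allele_state, gq = as.integer(gq),
    alt_fwd = as.integer(alt_fwd), alt_rev = as.integer(alt_rev),
    depth = as.integer(depth),
    alt_fraction = (alt_fwd + alt_rev) / depth
  )
}

trio_pedigree <- function(fid = "T1") {
  tibble::tibble(
    family_id = fid,
    sample_id = paste0(fid, c("_FA", "_MO", "_P")),
    father_id = c("", "", paste0(fid, "_FA")),
    mother_id = c("", "", paste0(fid, "_MO")),
    sex = c("male", "female", "unknown"),
    affected = c("unaffected", "unaffected", "affected"),
    phenotype_label = c("", "", "MMC")
  )
}

# Independent oracle: upper-tail Poisson probability P(X >= k) by direct
# summation of pmf terms exp(j*log(lambda) - lambda - lgamma(j+1)).
pois_upper_oracle <- function(k, lambda) {
  if (lambda == 0) return(if (k <= 0) 1 else 0)
  if (k <= 0) return(1)
  total <- 0
  j <- k
  repeat {
    term <- exp(j * log(lambda) - lambda - lgamma(j + 1))
    total <- total + term
    if (j > lambda && term < total * 1e-18) break
    j <- j + 1
  }
  total
}

pois_lower_oracle <- function(k, lambda) {
  if (k < 0) return(0)
  sum(exp(seq(0, k) * log(lambda) - lambda - lgamma(seq(0, k) + 1)))
}

# Independent brute-force evaluation of the filter-cascade rules, one
# record at a time, without using the package's filter functions.
brute_cascade_keep <- function(vs, config = filter_config(),
                               qc_samples = vs$samples) {
  v <- vs$variants
  g <- vs$genotypes
  vapply(seq_len(nrow(v)), function(i) {
    if (v$consequence[i] %in% c("synonymous", "noncoding")) return(FALSE)
    fr <- v$pop_freqs[[i]]
    if (length(fr) > 0 && max(fr) > config$max_pop_freq) return(FALSE)
    rows <- g[g$variant_id == v$variant_id[i] &
                g$allele_state %in% c("het", "hom_alt") &
                g$sample_id %in% qc_samples, , drop = FALSE]
    qc_ok <- FALSE
    for (j in seq_len(nrow(rows))) {
      r <- rows[j, ]
      if (is.na(r$gq) || is.na(r$alt_fwd) || is.na(r$alt_rev) ||
          is.na(r$depth) || r$depth == 0) next
      if (r$gq >= config$min_gq &&
          r$alt_fwd > config$min_strand_reads &&
          r$alt_rev > config$min_strand_reads &&
          (r$alt_fwd + r$alt_rev) / r$depth > config$min_alt_fraction) {
        qc_ok <- TRUE
        break
      }
    }
    if (!qc_ok) return(FALSE)
    v$consequence[i] %in% c("stop_gained", "frameshift", "splice") ||
      (v$consequence[i] == "missense" &&
         v$polyphen_category[i] == "probably_damaging")
  }, logical(1))
}
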