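#' Restrict to candidate-gene variants
#'
#' Keeps variants whose gene symbol appears in the candidate list
#' (case-insensitive exact match, no alias resolution) and annotates each
#' with its impact class so loss-of-function and probably-damaging missense
#' candidates can be examined separately.
#'
#' @param vs A cascade-filtered [variant_set()].
#' @param gene_list Candidate list from [merge_gene_lists()] (or anything
#'   with a `symbol` column, or a plain character vector of symbols).
#' @param config A [filter_config()] (for the impact rule).
#' @return A `variant_set` whose variant table gains an `impact` column.
#' @export
select_candidate_variants <- function(vs, gene_list, config = filter_config()) {
  symbols <- if (is.character(gene_list)) gene_list else gene_list$symbol
  symbols <- toupper(symbols)
  keep <- toupper(vs$variants$gene) %in% symbols
  out <- subset_variants(vs, vs$variants$variant_id[keep])
  out$variants$impact <- suppressWarnings(impact_class(out$variants, config))
  out
}

#' Remove previously published mutations
#'
#' Drops variants matching a (gene, cDNA change) pair already reported in
#' earlier analyses of the same cohort.
#'
#' @param vs A [variant_set()].
#' @param published Tibble with columns `gene`, `cdna_change`
#'   ([read_published_mutations()]).
#' @return A `variant_set`.
#' @export
remove_published <- function(vs, published) {
  if (is.null(published) || nrow(published) == 0) return(vs)
  key <- function(gene, cdna) paste(toupper(gene), trimws(cdna), sep = "|")
  pub_keys <- key(published$gene, published$cdna_change)
  keep <- !(key(vs$variants$gene, vs$variants$cdna_change) %in% pub_keys)
  subset_variants(vs, vs$variants$variant_id[keep])
}

#' Family segregation analysis
#'
#' For each variant and each family containing at least one carrier,
#' determines whether the variant is shared by all affected members: every
#' affected family member with a non-missing genotype carries the alternate
#' allele and at least one affected carrier exists. Unaffected carriers are
#' listed as a penetrance annotation. The transmitting parent is reported
#' when exactly one genotyped parent of an affected carrier carries the
#' allele; a de novo flag is raised when an affected carrier's two parents
#' are both genotyped non-carriers. A family whose affected members are all
#' ungenotyped at the variant is flagged uninformative. An affected member
#' with a missing genotype does not veto sharing; such families are flagged
#' `incomplete`.
#'
#' @param vs A [variant_set()].
#' @param pedigree Pedigree tibble ([read_ped()]).
#' @param variant_ids Optional subset of variants to analyse.
#' @return A tibble with one row per (variant, family-with-carriers):
#'   columns `variant_id`, `gene`, `family_id`, `shared_by_all_affected`,
#'   `affected_carriers`, `unaffected_carriers` (list columns),
#'   `transmitting_parent`, `de_novo`, `uninformative`, `incomplete`.
#' @export
segregate <- function(vs, pedigree, variant_ids = NULL) {
  ids <- variant_ids %||% vs$variants$variant_id
  fam_split <- split(pedigree, pedigree$family_id)
  gene_of <- setNames(vs$variants$gene, vs$variants$variant_id)
  carrier_tab <- carriers(vs)

  rows <- list()
  for (vid in ids) {
    vcarriers <- carrier_tab$sample_id[carrier_tab$variant_id == vid]
    fams <- unique(pedigree$family_id[pedigree$sample_id %in% vcarriers])
    for (fid in fams) {
      fam <- fam_split[[fid]]
      state <- vapply(fam$sample_id, function(s) allele_state_of(vs, vid, s),
                      character(1))
      is_carrier <- state %in% c("het", "hom_alt")
      genotyped <- state != "missing"
      aff <- fam$affected == "affected"
      unaff <- fam$affected == "unaffected"

      aff_geno <- aff & genotyped
      shared <- any(aff & is_carrier) && all(is_carrier[aff_geno])
      uninformative <- !any(aff_geno)
      incomplete <- any(aff & !genotyped)

      aff_car <- fam$sample_id[aff & is_carrier]
      unaff_car <- fam$sample_id[unaff & is_carrier]

      # transmitting parent: parents of affected carriers, genotyped, carrying
      parent_ids <- unique(c(
        fam$father_id[fam$sample_id %in% aff_car],
        fam$mother_id[fam$sample_id %in% aff_car]
      ))
      parent_ids <- parent_ids[nzchar(parent_ids)]
      parent_state <- state[match(parent_ids, fam$sample_id)]
      parent_carriers <- parent_ids[parent_state %in% c("het", "hom_alt")]
      transmitting <- if (length(parent_carriers) == 1) parent_carriers else ""

      de_novo <- any(vapply(aff_car, function(s) {
        i <- match(s, fam$sample_id)
        f <- fam$father_id[i]; m <- fam$mother_id[i]
        if (!nzchar(f) || !nzchar(m)) return(FALSE)
        sf <- state[match(f, fam$sample_id)]
        sm <- state[match(m, fam$sample_id)]
        sf == "hom_ref" && sm == "hom_ref"
      }, logical(1)))

      rows[[length(rows) + 1L]] <- tibble(
        variant_id = vid,
        gene = unname(gene_of[vid]),
        family_id = fid,
        shared_by_all_affected = shared,
        affected_carriers = list(aff_car),
        unaffected_carriers = list(unaff_car),
        transmitting_parent = transmitting,
        de_novo = de_novo,
        uninformative = uninformative,
        incomplete = incomplete
      )
    }
  }
  if (!length(rows)) {
    return(tibble(
      variant_id = character(), gene = character(), family_id = character(),
      shared_by_all_affected = logical(), affected_carriers = list(),
      unaffected_carriers = list(), transmitting_parent = character(),
      de_novo = logical(), uninformative = logical(), incomplete = logical()
    ))
  }
  dplyr::bind_rows(rows)
}

#' Prioritize variants shared by all affected family members
#'
#' Keeps variants for which at least one carrier family shows sharing by
#' all genotyped affected members (a variant shared in one family but not
#' another is retained; the per-family detail stays in the [segregate()]
#' report).
#'
#' @param vs A [variant_set()].
#' @param pedigree Pedigree tibble.
#' @return A list with `variants` (the prioritized `variant_set`) and
#'   `segregation` (the full [segregate()] table).
#' @export
prioritize_by_segregation <- function(vs, pedigree) {
  seg <- segregate(vs, pedigree)
  keep <- unique(seg$variant_id[seg$shared_by_all_affected])
  list(variants = subset_variants(vs, keep), segregation = seg)
}

#' Compound-heterozygote scan
#'
#' For every sample carrying two or more heterozygous variants in the same
#' gene, emits all pairs with a phase-support call from parental genotypes:
#' `confirmed_trans` when the two variants trace to different single
#' parents, `excluded_cis` when both trace to the same single parent, and
#' `possible` otherwise (parents ungenotyped, both parents carriers, or an
#' apparent de novo allele).
#'
#' @param vs A [variant_set()].
#' @param pedigree Pedigree tibble.
#' @return A tibble with columns `gene`, `sample_id`, `variant_a`,
#'   `variant_b`, `phase_support`.
#' @export
compound_het_scan <- function(vs, pedigree) {
  het <- vs$genotypes[vs$genotypes$allele_state == "het", , drop = FALSE]
  het <- dplyr::left_join(
    het[, c("variant_id", "sample_id")],
    vs$variants[, c("variant_id", "gene")],
    by = "variant_id"
  )
  het <- het[nzchar(het$gene), , drop = FALSE]

  empty <- tibble(gene = character(), sample_id = character(),
                  variant_a = character(), variant_b = character(),
                  phase_support = character())
  if (!nrow(het)) return(empty)

  origin <- function(vid, sample) {
    i <- match(sample, pedigree$sample_id)
    if (is.na(i)) return("unknown")
    f <- pedigree$father_id[i]; m <- pedigree$mother_id[i]
    sf <- if (nzchar(f)) allele_state_of(vs, vid, f) else "missing"
    sm <- if (nzchar(m)) allele_state_of(vs, vid, m) else "missing"
    f_car <- sf %in% c("het", "hom_alt")
    m_car <- sm %in% c("het", "hom_alt")
    if (f_car && !m_car) "father"
    else if (m_car && !f_car) "mother"
    else "unknown"
  }

  out <- list()
  groups <- split(het, paste(het$sample_id, het$gene, sep = "\r"))
  for (grp in groups) {
    vids <- sort(unique(grp$variant_id))
    if (length(vids) < 2) next
    sample <- grp$sample_id[1]
    gene <- grp$gene[1]
    orig <- vapply(vids, origin, character(1), sample = sample)
    cmb <- utils::combn(seq_along(vids), 2)
    for (j in seq_len(ncol(cmb))) {
      oa <- orig[cmb[1, j]]; ob <- orig[cmb[2, j]]
      phase <- if (oa != "unknown" && ob != "unknown" && oa != ob) {
        "confirmed_trans"
      } else if (oa != "unknown" && oa == ob) {
        "excluded_cis"
      } else "possible"
      out[[length(out) + 1L]] <- tibble(
        gene = gene, sample_id = sample,
        variant_a = vids[cmb[1, j]], variant_b = vids[cmb[2, j]],
        phase_support = phase
      )
    }
  }
  if (!length(out)) return(empty)
  dplyr::bind_rows(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
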