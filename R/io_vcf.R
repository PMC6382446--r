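#' VCF field dialect
#'
#' Variant callers differ in how they expose genotype quality, strand-split
#' alternate-read counts and depth, and in which INFO keys carry gene-level
#' annotation. A dialect maps those keys onto the pipeline's domain fields.
#' The shipped default expects FORMAT keys `GQ`, `ADF`/`ADR` (per-allele
#' forward/reverse depths, the reserved VCF keys) and `DP`, and INFO keys
#' `GENE`, `TX`, `CDNA`, `PROT`, `CSQ_CLASS`, `PP_CAT`, `PP_SCORE`, with
#' population allele frequencies in INFO keys prefixed `AF_` (for example
#' `AF_GNOMAD`, `AF_EXAC`, `AF_EVS`).
#'
#' @param gq,adf,adr,depth FORMAT keys for genotype quality, forward-strand
#'   allele depths, reverse-strand allele depths, and total depth.
#' @param gene,transcript,cdna,protein,consequence,polyphen_category,polyphen_score
#'   INFO keys for the annotation fields.
#' @param freq_prefix Prefix marking INFO keys that hold population allele
#'   frequencies; the suffix (lowercased) names the source.
#' @return A named list of class `vcf_dialect`.
#' @export
vcf_dialect <- function(gq = "GQ", adf = "ADF", adr = "ADR", depth = "DP",
                        gene = "GENE", transcript = "TX", cdna = "CDNA",
                        protein = "PROT", consequence = "CSQ_CLASS",
                        polyphen_category = "PP_CAT",
                        polyphen_score = "PP_SCORE",
                        freq_prefix = "AF_") {
  structure(
    list(
      gq = gq, adf = adf, adr = adr, depth = depth,
      gene = gene, transcript = transcript, cdna = cdna, protein = protein,
      consequence = consequence, polyphen_category = polyphen_category,
      polyphen_score = polyphen_score, freq_prefix = freq_prefix
    ),
    class = "vcf_dialect"
  )
}

# Split an INFO string into a named character vector.
parse_info <- function(info) {
  if (is.na(info) || info == "." || info == "") return(character())
  parts <- strsplit(info, ";", fixed = TRUE)[[1]]
  has_eq <- grepl("=", parts, fixed = TRUE)
  keys <- sub("=.*$", "", parts)
  vals <- ifelse(has_eq, sub("^[^=]*=", "", parts), "TRUE")
  setNames(vals, keys)
}

# Pick the a-th element of a possibly comma-joined annotation value
# (Number=A style); scalar values are shared across decomposed alleles.
info_for_allele <- function(val, a) {
  if (is.na(val)) return(NA_character_)
  parts <- strsplit(val, ",", fixed = TRUE)[[1]]
  if (length(parts) >= a) parts[a] else parts[1]
}

#' Read an annotated multi-sample VCF into a variant set
#'
#' Multi-allelic sites are decomposed into one record per ALT allele;
#' coordinates stay 1-based. Samples with a `./.` call at a variant become
#' explicit `missing` genotype entries; homozygous-reference calls are kept
#' implicit (see [variant_set()]).
#'
#' @param path Path to a VCF 4.x file (plain or bgzipped).
#' @param dialect A [vcf_dialect()] naming the FORMAT and INFO keys.
#' @return A [variant_set()].
#' @export
read_vcf <- function(path, dialect = vcf_dialect()) {
  if (!file.exists(path)) stop("VCF file not found: ", path, call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  meta <- vcf@meta
  check_dialect_keys(meta, dialect)

  fix <- vcf@fix
  gt <- vcf@gt
  samples <- if (is.null(gt)) character() else setdiff(colnames(gt), "FORMAT")

  if (nrow(fix) == 0) {
    return(variant_set(samples = samples))
  }

  var_rows <- list()
  gt_rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    info <- parse_info(fix[i, "INFO"])
    fmt_keys <- if (!is.null(gt)) strsplit(gt[i, "FORMAT"], ":", fixed = TRUE)[[1]] else character()
    cells <- if (!is.null(gt)) gt[i, samples, drop = TRUE] else character()
    for (a in seq_along(alts)) {
      rec <- decompose_site(fix[i, ], alts, a, info, dialect)
      var_rows[[length(var_rows) + 1L]] <- rec
      if (length(samples)) {
        ge <- parse_genotypes(rec$variant_id, a, fmt_keys, cells, samples, dialect)
        if (nrow(ge)) gt_rows[[length(gt_rows) + 1L]] <- ge
      }
    }
  }
  variants <- dplyr::bind_rows(var_rows)
  genotypes <- if (length(gt_rows)) dplyr::bind_rows(gt_rows) else empty_genotypes()
  variant_set(variants, genotypes, samples)
}

check_dialect_keys <- function(meta, dialect) {
  fmt_ids <- sub("^##FORMAT=<ID=([^,>]+).*$", "\\1", grep("^##FORMAT=", meta, value = TRUE))
  if (length(fmt_ids)) {
    need <- c(dialect$gq, dialect$adf, dialect$adr, dialect$depth)
    miss <- setdiff(need, fmt_ids)
    if (length(miss)) {
      stop("dialect FORMAT key(s) absent from VCF header: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  invisible(TRUE)
}

decompose_site <- function(fixrow, alts, a, info, dialect) {
  chrom <- fixrow[["CHROM"]]
  pos <- as.integer(fixrow[["POS"]])
  ref <- fixrow[["REF"]]
  alt <- alts[a]
  getinfo <- function(key) {
    if (key %in% names(info)) info_for_allele(info[[key]], a) else NA_character_
  }
  csq <- getinfo(dialect$consequence)
  if (is.na(csq) || !csq %in% CONSEQUENCE_LEVELS) csq <- "other"
  ppc <- getinfo(dialect$polyphen_category)
  if (is.na(ppc) || !ppc %in% POLYPHEN_LEVELS) ppc <- "unknown"
  pps <- suppressWarnings(as.numeric(getinfo(dialect$polyphen_score)))
  freq_keys <- grep(paste0("^", dialect$freq_prefix), names(info), value = TRUE)
  freqs <- setNames(
    vapply(freq_keys, function(k) {
      suppressWarnings(as.numeric(info_for_allele(info[[k]], a)))
    }, numeric(1)),
    tolower(sub(paste0("^", dialect$freq_prefix), "", freq_keys))
  )
  freqs <- freqs[!is.na(freqs)]
  tibble(
    variant_id = make_variant_id(chrom, pos, ref, alt),
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    gene = na_to_empty(getinfo(dialect$gene)),
    transcript = na_to_empty(getinfo(dialect$transcript)),
    cdna_change = na_to_empty(getinfo(dialect$cdna)),
    protein_change = na_to_empty(getinfo(dialect$protein)),
    consequence = csq,
    polyphen_category = ppc,
    polyphen_score = pps,
    pop_freqs = list(freqs)
  )
}

na_to_empty <- function(x) if (is.na(x)) "" else x

parse_genotypes <- function(variant_id, a, fmt_keys, cells, samples, dialect) {
  idx <- function(key) match(key, fmt_keys)
  rows <- lapply(seq_along(samples), function(s) {
    cell <- cells[[s]]
    if (is.na(cell) || cell == "." ) {
      return(tibble(
        variant_id = variant_id, sample_id = samples[s],
        allele_state = "missing", gq = NA_integer_, alt_fwd = NA_integer_,
        alt_rev = NA_integer_, depth = NA_integer_, alt_fraction = NA_real_
      ))
    }
    f <- strsplit(cell, ":", fixed = TRUE)[[1]]
    gtv <- f[idx("GT")]
    alleles <- strsplit(gtv, "[/|]")[[1]]
    if (any(alleles == ".")) {
      state <- "missing"
    } else {
      n_alt <- sum(alleles == as.character(a))
      state <- c("hom_ref", "het", "hom_alt")[pmin(n_alt, 2L) + 1L]
    }
    if (state == "hom_ref") return(NULL)
    pick <- function(key) {
      j <- idx(key)
      if (is.na(j) || j > length(f)) NA_character_ else f[j]
    }
    per_allele <- function(val) {
      if (is.na(val) || val == ".") return(NA_integer_)
      parts <- strsplit(val, ",", fixed = TRUE)[[1]]
      v <- if (length(parts) > 1) parts[a + 1L] else parts[1]
      suppressWarnings(as.integer(v))
    }
    gq <- suppressWarnings(as.integer(pick(dialect$gq)))
    alt_fwd <- per_allele(pick(dialect$adf))
    alt_rev <- per_allele(pick(dialect$adr))
    depth <- suppressWarnings(as.integer(pick(dialect$depth)))
    dp_val <- ifelse(is.na(pick(dialect$depth)) || pick(dialect$depth) == ".",
                     NA_integer_, depth)
    frac <- if (!is.na(alt_fwd) && !is.na(alt_rev) && !is.na(dp_val) && dp_val > 0) {
      (alt_fwd + alt_rev) / dp_val
    } else NA_real_
    tibble(
      variant_id = variant_id, sample_id = samples[s], allele_state = state,
      gq = gq, alt_fwd = alt_fwd, alt_rev = alt_rev, depth = dp_val,
      alt_fraction = frac
    )
  })
  dplyr::bind_rows(Filter(Negate(is.null), rows))
}

#' Write a variant set to a plain-text VCF
#'
#' Emits one biallelic record per variant (decomposed form) using the
#' dialect's FORMAT and INFO keys, so that [read_vcf()] on the output
#' reproduces the input field-for-field. Cohort samples without an explicit
#' genotype entry are written as `0/0` with missing statistics.
#'
#' @param vs A [variant_set()].
#' @param path Output file path.
#' @param dialect A [vcf_dialect()].
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vs, path, dialect = vcf_dialect()) {
  v <- vs$variants
  freq_sources <- sort(unique(toupper(unlist(lapply(v$pop_freqs, names)))))
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf('##INFO=<ID=%s,Number=1,Type=String,Description="Gene symbol">', dialect$gene),
    sprintf('##INFO=<ID=%s,Number=1,Type=String,Description="Transcript accession">', dialect$transcript),
    sprintf('##INFO=<ID=%s,Number=1,Type=String,Description="HGVS cDNA change">', dialect$cdna),
    sprintf('##INFO=<ID=%s,Number=1,Type=String,Description="HGVS protein change">', dialect$protein),
    sprintf('##INFO=<ID=%s,Number=1,Type=String,Description="Consequence class">', dialect$consequence),
    sprintf('##INFO=<ID=%s,Number=1,Type=String,Description="PolyPhen-2 category">', dialect$polyphen_category),
    sprintf('##INFO=<ID=%s,Number=1,Type=Float,Description="PolyPhen-2 score">', dialect$polyphen_score),
    vapply(freq_sources, function(s) {
      sprintf('##INFO=<ID=%s%s,Number=1,Type=Float,Description="%s allele frequency">',
              dialect$freq_prefix, s, s)
    }, character(1)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    sprintf('##FORMAT=<ID=%s,Number=1,Type=Integer,Description="Genotype quality">', dialect$gq),
    sprintf('##FORMAT=<ID=%s,Number=R,Type=Integer,Description="Forward-strand allelic depths">', dialect$adf),
    sprintf('##FORMAT=<ID=%s,Number=R,Type=Integer,Description="Reverse-strand allelic depths">', dialect$adr),
    sprintf('##FORMAT=<ID=%s,Number=1,Type=Integer,Description="Read depth">', dialect$depth),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (length(vs$samples)) c("FORMAT", vs$samples)), collapse = "\t")
  )
  fmt <- paste("GT", dialect$gq, dialect$adf, dialect$adr, dialect$depth, sep = ":")
  gsplit <- split(vs$genotypes, vs$genotypes$variant_id)

  body <- vapply(seq_len(nrow(v)), function(i) {
    info <- c(
      kv(dialect$gene, v$gene[i]),
      kv(dialect$transcript, v$transcript[i]),
      kv(dialect$cdna, v$cdna_change[i]),
      kv(dialect$protein, v$protein_change[i]),
      kv(dialect$consequence, v$consequence[i]),
      kv(dialect$polyphen_category,
         if (v$polyphen_category[i] == "unknown") "" else v$polyphen_category[i]),
      kv(dialect$polyphen_score, num_str(v$polyphen_score[i]))
    )
    fr <- v$pop_freqs[[i]]
    if (length(fr)) {
      info <- c(info, paste0(dialect$freq_prefix, toupper(names(fr)), "=",
                             vapply(fr, num_str, character(1))))
    }
    info <- info[nzchar(info)]
    info_str <- if (length(info)) paste(info, collapse = ";") else "."
    cols <- c(v$chrom[i], v$pos[i], ".", v$ref[i], v$alt[i], ".", "PASS", info_str)
    if (length(vs$samples)) {
      g <- gsplit[[v$variant_id[i]]]
      cells <- vapply(vs$samples, function(s) {
        format_gt_cell(if (is.null(g)) NULL else g[g$sample_id == s, , drop = FALSE])
      }, character(1))
      cols <- c(cols, fmt, cells)
    }
    paste(cols, collapse = "\t")
  }, character(1))

  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

kv <- function(key, val) {
  if (is.null(val) || is.na(val) || !nzchar(val)) "" else paste0(key, "=", val)
}

num_str <- function(x) {
  if (is.null(x) || length(x) == 0 || is.na(x)) "" else
    format(x, scientific = FALSE, trim = TRUE, digits = 15)
}

int_str <- function(x) if (is.na(x)) "." else as.character(x)

format_gt_cell <- function(row) {
  if (is.null(row) || nrow(row) == 0) return("0/0:.:.,.:.,.:.")
  gt <- switch(row$allele_state,
    het = "0/1", hom_alt = "1/1", missing = "./.", "0/0"
  )
  ad <- function(x) if (is.na(x)) ".,." else paste0(".,", x)
  paste(gt, int_str(row$gq), ad(row$alt_fwd), ad(row$alt_rev),
        int_str(row$depth), sep = ":")
}
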