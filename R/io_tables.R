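#' Read a gene list
#'
#' One gene symbol per line, or a TSV whose first column holds symbols.
#' Symbols are uppercased and deduplicated within the file, and tagged with
#' the provenance of the list (for example `"mouse_ntd"` or `"folate"`).
#'
#' @param path Path to the list file.
#' @param source_tag Single string identifying the list's source.
#' @return A tibble with columns `symbol` and `tag`.
#' @export
read_gene_list <- function(path, source_tag) {
  if (!file.exists(path)) stop("gene list not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) {
    warning("gene list is empty: ", path, call. = FALSE)
    return(tibble(symbol = character(), tag = character()))
  }
  symbols <- toupper(vapply(strsplit(lines, "\t", fixed = TRUE),
                            function(x) trimws(x[1]), character(1)))
  tibble(symbol = unique(symbols), tag = source_tag)
}

#' Merge tagged gene lists into a candidate-gene list
#'
#' The union of symbols across lists; a symbol present in several lists
#' accumulates all of their tags. Merging is commutative and associative,
#' and the merged size equals the sum of input sizes exactly when the
#' inputs are disjoint.
#'
#' @param ... Tibbles from [read_gene_list()] (columns `symbol`, `tag`).
#' @return A tibble with columns `symbol` and `tags` (list column of
#'   character vectors, each of length >= 1).
#' @export
merge_gene_lists <- function(...) {
  all <- dplyr::bind_rows(...)
  if (!nrow(all)) return(tibble(symbol = character(), tags = list()))
  all$symbol <- toupper(all$symbol)
  out <- dplyr::summarise(
    dplyr::group_by(all, .data$symbol),
    tags = list(sort(unique(.data$tag))), .groups = "drop"
  )
  dplyr::arrange(out, .data$symbol)
}

#' Read gene models
#'
#' A TSV with header columns `symbol`, `transcript`, `coding_length`
#' (coding length in bp, > 0).
#'
#' @param path Path to the gene-model TSV.
#' @return A tibble with those columns, symbols uppercased.
#' @export
read_gene_models <- function(path) {
  gm <- as_tibble(read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE))
  stopifnot(all(c("symbol", "transcript", "coding_length") %in% names(gm)))
  if (any(gm$coding_length <= 0)) {
    stop("coding_length must be positive", call. = FALSE)
  }
  gm$symbol <- toupper(gm$symbol)
  gm
}

#' Read a published-mutations exclusion table
#'
#' A TSV with header columns `gene` and `cdna_change`: variants already
#' reported by earlier studies of the same cohort, to be removed before
#' declaring new candidates.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `gene` (uppercased) and `cdna_change`.
#' @export
read_published_mutations <- function(path) {
  pub <- as_tibble(read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE))
  stopifnot(all(c("gene", "cdna_change") %in% names(pub)))
  pub$gene <- toupper(pub$gene)
  pub
}

#' Read a gene blacklist
#'
#' One symbol per line: genes excluded from burden testing (typically genes
#' whose apparent mutation excess traces to read misalignment).
#'
#' @param path Path to the file.
#' @return Character vector of uppercased symbols.
#' @export
read_blacklist <- function(path) {
  if (!file.exists(path)) stop("blacklist not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  toupper(unique(lines[nzchar(lines) & !startsWith(lines, "#")]))
}

#' Write a results table as TSV
#'
#' List columns are flattened to comma-joined strings.
#'
#' @param df A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(df, path) {
  flat <- as.data.frame(lapply(df, function(col) {
    if (is.list(col)) {
      vapply(col, function(x) paste(x, collapse = ","), character(1))
    } else col
  }), stringsAsFactors = FALSE, check.names = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(flat, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
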