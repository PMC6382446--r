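#' Read a PED pedigree file
#'
#' Standard whitespace-delimited 6-column PED (family id, individual id,
#' father id, mother id, sex, affection status) with an optional seventh
#' free-text phenotype label (for example "MMC", "anencephaly"). Affection
#' codes map 2 to affected, 1 to unaffected, and 0 or -9 to unknown; sex
#' codes 1/2 to male/female, anything else to unknown. Parent ids `0` mean
#' founder.
#'
#' @param path Path to the PED file.
#' @return A tibble with columns `family_id`, `sample_id`, `father_id`,
#'   `mother_id`, `sex`, `affected`, `phenotype_label`.
#' @export
read_ped <- function(path) {
  if (!file.exists(path)) stop("PED file not found: ", path, call. = FALSE)
  raw <- read.table(path, header = FALSE, sep = "", stringsAsFactors = FALSE,
                    colClasses = "character", comment.char = "#",
                    blank.lines.skip = TRUE)
  if (ncol(raw) < 6) stop("PED file must have at least 6 columns", call. = FALSE)
  ped <- tibble(
    family_id = raw[[1]],
    sample_id = raw[[2]],
    father_id = ifelse(raw[[3]] == "0", "", raw[[3]]),
    mother_id = ifelse(raw[[4]] == "0", "", raw[[4]]),
    sex = c("male", "female")[match(raw[[5]], c("1", "2"))],
    affected = dplyr::case_match(raw[[6]],
      "2" ~ "affected", "1" ~ "unaffected", c("0", "-9") ~ "unknown",
      .default = "unknown"
    ),
    phenotype_label = if (ncol(raw) >= 7) raw[[7]] else ""
  )
  ped$sex[is.na(ped$sex)] <- "unknown"
  validate_pedigree(ped)
  ped
}

validate_pedigree <- function(ped) {
  if (anyDuplicated(ped$sample_id)) {
    stop("duplicate sample ids in pedigree", call. = FALSE)
  }
  members <- paste(ped$family_id, ped$sample_id)
  for (col in c("father_id", "mother_id")) {
    refs <- ped[[col]]
    ok <- refs == "" | paste(ped$family_id, refs) %in% members
    if (any(!ok)) {
      bad <- unique(refs[!ok])
      stop("dangling parent reference(s) in pedigree: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  invisible(ped)
}

#' Write a pedigree as a 7-column PED file
#'
#' @param ped Pedigree tibble as returned by [read_ped()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path) {
  out <- data.frame(
    ped$family_id, ped$sample_id,
    ifelse(ped$father_id == "", "0", ped$father_id),
    ifelse(ped$mother_id == "", "0", ped$mother_id),
    match(ped$sex, c("male", "female"), nomatch = 0L),
    c(affected = 2L, unaffected = 1L, unknown = 0L)[ped$affected],
    ifelse(ped$phenotype_label == "", ".", ped$phenotype_label)
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Affected sample ids of a pedigree
#' @param ped Pedigree tibble.
#' @return Character vector of affected sample ids.
#' @export
affected_samples <- function(ped) ped$sample_id[ped$affected == "affected"]
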