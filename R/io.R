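# Readers and writers for the plain-text interchange formats: meiosis
# tables, crossover-call tables, PLINK-FAM pedigrees with an age sidecar,
# and the filter audit trail.

.meiosis_cols <- c("cohort", "family_id", "parent_id", "child_id", "parent_sex",
                   "parent_age_years", "configuration", "n_crossovers")
.call_cols <- c("cohort", "parent_id", "child_id", "chrom", "start_bp", "end_bp",
                "posterior_prob", "left_snp_index", "right_snp_index")

#' Read or write a per-meiosis crossover-count table (TSV)
#'
#' Columns: `cohort`, `family_id`, `parent_id`, `child_id`, `parent_sex`
#' (M/F), `parent_age_years`, `configuration` (1-6), `n_crossovers`.
#'
#' @param path File path.
#' @param meioses Meiosis table to write.
#' @return `read_meiosis_table()` returns the data frame;
#'   `write_meiosis_table()` returns `path` invisibly.
#' @export
read_meiosis_table <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(.meiosis_cols, names(out))
  if (length(missing)) {
    stop("meiosis table is missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  out
}

#' @rdname read_meiosis_table
#' @export
write_meiosis_table <- function(meioses, path) {
  utils::write.table(meioses[, .meiosis_cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a crossover-call table (TSV)
#'
#' Columns: `cohort`, `parent_id`, `child_id`, `chrom`, `start_bp`,
#' `end_bp` (1-based, inclusive), `posterior_prob`, `left_snp_index`,
#' `right_snp_index` (1-based indices into the cohort SNP map).
#'
#' @param path File path.
#' @param calls Call table to write.
#' @return `read_call_table()` returns the data frame;
#'   `write_call_table()` returns `path` invisibly.
#' @export
read_call_table <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(.call_cols, names(out))
  if (length(missing)) {
    stop("call table is missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  out
}

#' @rdname read_call_table
#' @export
write_call_table <- function(calls, path) {
  utils::write.table(calls[, .call_cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a pedigree as PLINK FAM plus an age/cohort sidecar
#'
#' The FAM file has the usual six columns (`family_id`, `individual_id`,
#' `father_id`, `mother_id`, `sex`, `phenotype = -9`), one row per child
#' and per (known) parent. The transmitting parent comes from the meiosis
#' table; the other parent is emitted as a synthetic spouse id
#' (`<family_id>_SP`) so the pedigree is well formed. The sidecar TSV
#' carries the cohort label and the transmitting parent's age at each
#' child's birth.
#'
#' @param meioses Meiosis table ([read_meiosis_table()] dialect).
#' @param fam_path Path for the FAM file.
#' @param sidecar_path Path for the TSV sidecar.
#' @return Invisibly, a list with both paths.
#' @export
write_fam <- function(meioses, fam_path, sidecar_path) {
  spouse <- paste0(meioses$family_id, "_SP")
  father <- ifelse(meioses$parent_sex == "M", meioses$parent_id, spouse)
  mother <- ifelse(meioses$parent_sex == "F", meioses$parent_id, spouse)
  kids <- data.frame(family_id = meioses$family_id, individual_id = meioses$child_id,
                     father_id = father, mother_id = mother, sex = 0L, phenotype = -9L,
                     stringsAsFactors = FALSE)
  par_sex <- ifelse(meioses$parent_sex == "M", 1L, 2L)
  parents <- unique(data.frame(family_id = meioses$family_id,
                               individual_id = meioses$parent_id,
                               father_id = "0", mother_id = "0",
                               sex = par_sex, phenotype = -9L,
                               stringsAsFactors = FALSE))
  fam <- rbind(parents, kids)
  utils::write.table(fam, fam_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  sidecar <- meioses[, c("cohort", "family_id", "individual_id" = "child_id",
                         "parent_id", "parent_age_years", "configuration")]
  names(sidecar)[names(sidecar) == "child_id"] <- "individual_id"
  utils::write.table(sidecar, sidecar_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(fam = fam_path, sidecar = sidecar_path))
}

#' Read a PLINK FAM pedigree and its age sidecar
#'
#' @param fam_path Path to the FAM file.
#' @param sidecar_path Optional path to the age/cohort sidecar TSV.
#' @return A list with `pedigree` (data frame with the six FAM columns) and
#'   `ages` (the sidecar data frame, or `NULL`).
#' @export
read_fam <- function(fam_path, sidecar_path = NULL) {
  ped <- utils::read.table(fam_path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("family_id", "individual_id", "father_id",
                                         "mother_id", "sex", "phenotype"))
  ages <- if (!is.null(sidecar_path)) utils::read.delim(sidecar_path, stringsAsFactors = FALSE)
  list(pedigree = ped, ages = ages)
}

#' Write the filter audit trail
#'
#' One row per removed call with a `reason` column
#' (`low_prob`, `tight_pair` or `nftools_window`).
#'
#' @param audit Data frame of removed calls, as accumulated by the filters.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_filter_audit <- function(audit, path) {
  utils::write.table(audit, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
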