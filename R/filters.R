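# Post-processing of crossover calls into per-meiosis counts: posterior
# thresholding, double-crossover artifact filters, family-configuration
# classification, monozygotic deduplication and cohort exclusion rules.

#' Keep only crossover calls above a posterior-probability threshold
#'
#' Retains exactly the calls with posterior probability strictly greater
#' than `prob_threshold` (the convention of HMM-based callers: calls at
#' `P = 0.5` are discarded). Row order is preserved.
#'
#' @param calls Crossover-call table ([read_call_table()] dialect).
#' @param prob_threshold Threshold in `[0, 1]`; default 0.5.
#' @return The surviving calls, with attribute `"removed"` holding the
#'   discarded rows (with `reason = "low_prob"`).
#' @export
threshold_calls <- function(calls, prob_threshold = 0.5) {
  stopifnot(prob_threshold >= 0, prob_threshold <= 1)
  keep <- calls$posterior_prob > prob_threshold
  out <- calls[keep, , drop = FALSE]
  removed <- calls[!keep, , drop = FALSE]
  if (nrow(removed)) removed$reason <- "low_prob"
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}

# Pairwise removal engine shared by the SNP-window and informative-marker
# filters. Within one (cohort, parent, child, chrom) group, sorted by
# position, any two consecutive surviving calls whose inner separation
# (left index of the later minus right index of the earlier) is < window
# are BOTH removed; removal cascades left-to-right, re-evaluating
# separations among survivors after each removal. Negative separations
# (overlapping intervals) count as < window.
.pair_filter_group <- function(left, right, window) {
  n <- length(left)
  alive <- rep(TRUE, n)
  idx <- seq_len(n)
  i <- 1L
  while (TRUE) {
    surv <- idx[alive]
    if (length(surv) < 2L || i >= length(surv)) break
    a <- surv[i]; b <- surv[i + 1L]
    if (left[b] - right[a] < window) {
      alive[c(a, b)] <- FALSE
      i <- max(i - 1L, 1L)
    } else {
      i <- i + 1L
    }
  }
  alive
}

.apply_pair_filter <- function(calls, window_for_row, left_col, right_col, reason) {
  if (nrow(calls) == 0L) {
    attr(calls, "removed") <- calls
    return(calls)
  }
  grp <- interaction(calls$cohort, calls$parent_id, calls$child_id, calls$chrom,
                     drop = TRUE)
  ord <- order(grp, calls[[left_col]])
  calls_o <- calls[ord, , drop = FALSE]
  grp_o <- grp[ord]
  keep <- logical(nrow(calls_o))
  for (g in levels(grp_o)) {
    sel <- which(grp_o == g)
    w <- window_for_row(calls_o[sel[1L], ])
    keep[sel] <- .pair_filter_group(calls_o[[left_col]][sel],
                                    calls_o[[right_col]][sel], w)
  }
  out <- calls_o[keep, , drop = FALSE]
  removed <- calls_o[!keep, , drop = FALSE]
  if (nrow(removed)) removed$reason <- reason
  rownames(out) <- NULL
  rownames(removed) <- NULL
  attr(out, "removed") <- removed
  out
}

#' Remove double crossovers within X SNPs of each other
#'
#' Within each meiosis and chromosome, consecutive calls separated by
#' fewer than X SNP indices (the later call's `left_snp_index` minus the
#' earlier call's `right_snp_index`) are interpreted as a single artifact
#' -- typically a genotyping or phasing switch error -- and both members
#' of the pair are removed. X is cohort-specific: the cohort's average
#' number of SNPs per megabase. Removal cascades left to right over the
#' surviving calls. The filter is idempotent.
#'
#' @param calls Crossover-call table.
#' @param x_snps Named numeric vector mapping cohort to its X threshold
#'   (SNPs per megabase); every cohort present in `calls` must have an
#'   entry, and all X must be `>= 1`.
#' @return A list with `calls` (survivors) and `removed_pairs` (the
#'   removed rows, `reason = "tight_pair"`).
#' @export
filter_double_crossovers <- function(calls, x_snps) {
  cohorts <- unique(calls$cohort)
  missing <- setdiff(cohorts, names(x_snps))
  if (length(missing)) {
    stop("no X (SNPs/Mb) entry for cohort(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(x_snps < 1)) stop("all X thresholds must be >= 1", call. = FALSE)
  out <- .apply_pair_filter(
    calls,
    window_for_row = function(row) x_snps[[row$cohort]],
    left_col = "left_snp_index", right_col = "right_snp_index",
    reason = "tight_pair"
  )
  list(calls = out, removed_pairs = attr(out, "removed"))
}

#' Remove double crossovers within a window of informative markers
#'
#' The transmission-phasing analogue of [filter_double_crossovers()]:
#' separations are measured in informative-marker units
#' (`left_marker_index` / `right_marker_index` columns) and the window is
#' five markers by default. Both members of a tight pair are removed, with
#' the same left-to-right cascade.
#'
#' @param calls Call table carrying `left_marker_index` and
#'   `right_marker_index` columns.
#' @param marker_window Window in informative markers; default 5.
#' @return The surviving calls, with attribute `"removed"`
#'   (`reason = "nftools_window"`).
#' @export
nftools_window_filter <- function(calls, marker_window = 5) {
  if (!all(c("left_marker_index", "right_marker_index") %in% names(calls))) {
    stop("calls must carry informative-marker indices ",
         "(`left_marker_index`, `right_marker_index`)", call. = FALSE)
  }
  .apply_pair_filter(
    calls,
    window_for_row = function(row) marker_window,
    left_col = "left_marker_index", right_col = "right_marker_index",
    reason = "nftools_window"
  )
}

#' Classify a family into one of the six configurations
#'
#' Determines the family configuration for crossover calling with respect
#' to one transmitting parent: at least three genotyped children with one
#' or both parents genotyped (configurations 1 and 2), two children with
#' one or both parents (3 and 4), or two children with the transmitting
#' parent's own parents (the grandparents on that side) also genotyped
#' (5 and 6). Configurations 2 and 6 are fully informative. Families with
#' three or more children and genotyped grandparents are assigned the
#' three-children codes (1/2), since the grandparent configurations are
#' defined only for two-child families.
#'
#' @param pedigree Data frame in PLINK FAM dialect (`family_id`,
#'   `individual_id`, `father_id`, `mother_id`, `sex`, `phenotype`); an
#'   individual is considered genotyped iff it has its own row.
#' @param target_parent Individual id of the transmitting parent.
#' @return A list with `code` (1-6) and `fully_informative`
#'   (`TRUE` iff code is 2 or 6).
#' @export
classify_family <- function(pedigree, target_parent) {
  present <- pedigree$individual_id
  if (!(target_parent %in% present)) {
    stop("target parent is not genotyped in this pedigree", call. = FALSE)
  }
  is_child <- pedigree$father_id == target_parent | pedigree$mother_id == target_parent
  children <- pedigree[is_child, , drop = FALSE]
  n_children <- nrow(children)
  if (n_children < 2L) {
    stop("fewer than 2 genotyped children: the parent effect cannot be estimated",
         call. = FALSE)
  }
  other <- unique(ifelse(children$father_id == target_parent,
                         children$mother_id, children$father_id))
  both_parents <- any(other %in% present)
  if (n_children >= 3L) {
    code <- if (both_parents) 2L else 1L
  } else {
    self <- pedigree[pedigree$individual_id == target_parent, , drop = FALSE]
    grandparents <- c(self$father_id[1L], self$mother_id[1L])
    has_gp <- all(grandparents != "0") && all(grandparents %in% present)
    code <- if (has_gp) {
      if (both_parents) 6L else 5L
    } else {
      if (both_parents) 4L else 3L
    }
  }
  list(code = code, fully_informative = code %in% c(2L, 6L))
}

#' Drop one child of each monozygotic pair
#'
#' Monozygotic twins carry the same transmitted haplotypes, so both
#' members of a pair would count the same meiosis twice; exactly one is
#' retained (deterministically, the lexicographically smaller child id).
#' Pairs with a member absent from the table are skipped with a warning.
#'
#' @param meioses Meiosis table.
#' @param mz_pairs Data frame (or two-column matrix) whose rows are the
#'   child ids of each monozygotic pair.
#' @return The deduplicated meiosis table.
#' @export
deduplicate_monozygotic <- function(meioses, mz_pairs) {
  if (is.null(mz_pairs) || nrow(mz_pairs) == 0L) return(meioses)
  drop_ids <- character(0)
  for (i in seq_len(nrow(mz_pairs))) {
    pair <- sort(as.character(unlist(mz_pairs[i, 1:2])))
    if (!all(pair %in% meioses$child_id)) {
      warning("monozygotic pair (", paste(pair, collapse = ", "),
              ") not fully present in the meiosis table; skipped", call. = FALSE)
      next
    }
    drop_ids <- c(drop_ids, pair[2L])  # keep the lexicographically smaller id
  }
  out <- meioses[!(meioses$child_id %in% drop_ids), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply the minimum-meioses exclusion rules
#'
#' With `per_configuration = FALSE`, whole cohorts with fewer than
#' `min_meioses` meioses are dropped (the rule used for the cohort-level
#' models on fully informative meioses). With `per_configuration = TRUE`,
#' individual (cohort, configuration) cells with fewer than `min_meioses`
#' meioses are dropped (the rule used for the configuration-stratified
#' model on all families with two or more children).
#'
#' @param meioses Meiosis table.
#' @param min_meioses Minimum number of meioses; default 20.
#' @param per_configuration Apply the rule per (cohort, configuration)
#'   cell instead of per cohort.
#' @return The filtered meiosis table.
#' @export
apply_exclusion_rules <- function(meioses, min_meioses = 20,
                                  per_configuration = FALSE) {
  if (nrow(meioses) == 0L) return(meioses)
  if (per_configuration) {
    key <- paste(meioses$cohort, meioses$configuration, sep = "\r")
  } else {
    key <- meioses$cohort
  }
  n <- table(key)
  keep_keys <- names(n)[n >= min_meioses]
  out <- meioses[key %in% keep_keys, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate filtered calls into per-meiosis counts
#'
#' Counts the surviving calls per (cohort, parent, child) and joins the
#' meiosis metadata (family, sex, age, configuration). Meioses present in
#' the metadata but with no surviving calls get a count of 0.
#'
#' @param calls Filtered crossover-call table.
#' @param meta Meiosis metadata: a meiosis table whose `n_crossovers`
#'   column (if any) is ignored.
#' @return A meiosis table with `n_crossovers` recomputed from `calls`.
#' @export
calls_to_counts <- function(calls, meta) {
  key_meta <- paste(meta$cohort, meta$parent_id, meta$child_id)
  key_calls <- paste(calls$cohort, calls$parent_id, calls$child_id)
  unknown <- setdiff(unique(key_calls), key_meta)
  if (length(unknown)) {
    stop("calls reference meioses absent from the metadata: ",
         paste(utils::head(unknown, 3), collapse = "; "), call. = FALSE)
  }
  tab <- table(key_calls)
  out <- meta
  out$n_crossovers <- as.integer(tab[key_meta])
  out$n_crossovers[is.na(out$n_crossovers)] <- 0L
  rownames(out) <- NULL
  out
}

#' Mean crossover count by parental-age bin
#'
#' Groups parental ages into fixed-width bins and reports, per bin, the
#' number of meioses, the mean crossover count expressed as a difference
#' from the reference bin's mean, and a normal-theory 95% confidence
#' interval (`mean +/- 1.96 * sd / sqrt(n)`), the reference mean being
#' treated as fixed.
#'
#' @param meioses Meiosis table.
#' @param bin_width Bin width in years; default 5.
#' @param reference_bin Numeric length-2: the `[lo, hi)` bounds of the
#'   reference bin; default `c(20, 25)`.
#' @return Data frame with columns `bin`, `age_lo`, `age_hi`, `n`,
#'   `mean_diff`, `ci_lo`, `ci_hi`.
#' @export
binned_age_summary <- function(meioses, bin_width = 5, reference_bin = c(20, 25)) {
  age <- meioses$parent_age_years
  lo <- floor(min(age) / bin_width) * bin_width
  hi <- ceiling(max(age) / bin_width) * bin_width
  if (hi == max(age)) hi <- hi + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  bin_idx <- findInterval(age, breaks, rightmost.closed = FALSE)
  ref <- age >= reference_bin[1] & age < reference_bin[2]
  if (!any(ref)) stop("the reference age bin is empty", call. = FALSE)
  ref_mean <- mean(meioses$n_crossovers[ref])
  out <- do.call(rbind, lapply(sort(unique(bin_idx)), function(b) {
    sel <- bin_idx == b
    y <- meioses$n_crossovers[sel]
    n <- length(y)
    m <- mean(y)
    half <- if (n > 1) 1.96 * stats::sd(y) / sqrt(n) else 0
    data.frame(
      bin = sprintf("[%g,%g)", breaks[b], breaks[b] + bin_width),
      age_lo = breaks[b], age_hi = breaks[b] + bin_width,
      n = n, mean_diff = m - ref_mean,
      ci_lo = m - half - ref_mean, ci_hi = m + half - ref_mean,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}
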