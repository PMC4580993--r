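# Call post-processing: thresholding, double-crossover filters, family
# classification, deduplication, exclusion rules and the binned summary.

test_that("posterior threshold is strict and order-preserving", {
  calls <- rbind(make_call("P1", "C1", "chr1", 100, 101, p = 0.4),
                 make_call("P1", "C1", "chr1", 300, 301, p = 0.5),
                 make_call("P1", "C1", "chr1", 500, 501, p = 0.6))
  out <- threshold_calls(calls, 0.5)
  expect_equal(nrow(out), 1L)            # only P = 0.6 survives (P > 0.5 strict)
  expect_equal(out$left_snp_index, 500)
  expect_equal(attr(out, "removed")$reason, c("low_prob", "low_prob"))
  expect_equal(nrow(threshold_calls(calls[0, ], 0.5)), 0L)
  # threshold 0 on all-positive P is the identity
  expect_equal(threshold_calls(calls, 0)$left_snp_index, calls$left_snp_index)
})

test_that("double-crossover filter removes both members of a tight pair", {
  tight <- rbind(make_call("P1", "C1", "chr1", 100, 101),
                 make_call("P1", "C1", "chr1", 104, 105))
  out <- filter_double_crossovers(tight, c(T = 5))  # separation 3 < 5
  expect_equal(nrow(out$calls), 0L)
  expect_equal(nrow(out$removed_pairs), 2L)
  expect_true(all(out$removed_pairs$reason == "tight_pair"))

  spread <- rbind(make_call("P1", "C1", "chr1", 100, 101),
                  make_call("P1", "C1", "chr1", 200, 201),
                  make_call("P1", "C1", "chr1", 300, 301))
  out2 <- filter_double_crossovers(spread, c(T = 5))
  expect_equal(nrow(out2$calls), 3L)

  single <- make_call("P1", "C1", "chr1", 100, 101)
  expect_equal(nrow(filter_double_crossovers(single, c(T = 5))$calls), 1L)

  expect_error(filter_double_crossovers(single, c(OTHER = 5)), "no X")
})

test_that("removal cascades left-to-right over the survivors", {
  # after the middle pair is removed, the flanking calls become consecutive
  # but remain far apart, so they survive
  calls <- rbind(make_call("P1", "C1", "chr1", 100, 101),
                 make_call("P1", "C1", "chr1", 500, 501),
                 make_call("P1", "C1", "chr1", 503, 504),
                 make_call("P1", "C1", "chr1", 900, 901))
  out <- filter_double_crossovers(calls, c(T = 10))
  expect_equal(out$calls$left_snp_index, c(100, 900))
  # a chain of three mutually tight calls: the first pair goes, the third
  # is then isolated and survives
  chain <- rbind(make_call("P1", "C1", "chr1", 100, 101),
                 make_call("P1", "C1", "chr1", 105, 106),
                 make_call("P1", "C1", "chr1", 110, 111))
  out2 <- filter_double_crossovers(chain, c(T = 10))
  expect_equal(out2$calls$left_snp_index, 110)
  # overlapping intervals count as separation < X
  over <- rbind(make_call("P1", "C1", "chr1", 100, 120),
                make_call("P1", "C1", "chr1", 110, 130))
  expect_equal(nrow(filter_double_crossovers(over, c(T = 5))$calls), 0L)
})

test_that("filters are idempotent and never mix meioses", {
  calls <- toy_call_table()
  once <- filter_double_crossovers(threshold_calls(calls), c(T = 50))$calls
  twice <- filter_double_crossovers(threshold_calls(once), c(T = 50))$calls
  expect_equal(once, twice, ignore_attr = TRUE)
  # filtering each meiosis separately gives the same survivors
  per_meiosis <- do.call(rbind, lapply(split(calls, calls$parent_id), function(g) {
    filter_double_crossovers(threshold_calls(g), c(T = 50))$calls
  }))
  key <- function(d) sort(paste(d$parent_id, d$chrom, d$left_snp_index))
  expect_identical(key(once), key(per_meiosis))
})

test_that("informative-marker window filter uses marker units", {
  calls <- rbind(make_call("P1", "C1", "chr1", 1000, 1010),
                 make_call("P1", "C1", "chr1", 2000, 2010))
  expect_error(nftools_window_filter(calls), "marker")
  # 3 informative markers apart: both removed
  calls$left_marker_index <- c(10, 14)
  calls$right_marker_index <- c(11, 15)
  expect_equal(nrow(nftools_window_filter(calls, 5)), 0L)
  # 6 markers apart: both kept
  calls$left_marker_index <- c(10, 17)
  calls$right_marker_index <- c(11, 18)
  expect_equal(nrow(nftools_window_filter(calls, 5)), 2L)
  expect_equal(nrow(nftools_window_filter(calls[0, ], 5)), 0L)
})

test_that("family configurations are classified from the pedigree", {
  ped <- function(ids, father, mother) {
    data.frame(family_id = "F1", individual_id = ids, father_id = father,
               mother_id = mother, sex = 0L, phenotype = -9L,
               stringsAsFactors = FALSE)
  }
  # both parents + 3 children -> configuration 2, fully informative
  p2 <- ped(c("dad", "mum", "k1", "k2", "k3"),
            c("0", "0", "dad", "dad", "dad"), c("0", "0", "mum", "mum", "mum"))
  cl <- classify_family(p2, "mum")
  expect_equal(cl$code, 2L); expect_true(cl$fully_informative)
  # one parent + 3 children -> configuration 1
  p1 <- ped(c("mum", "k1", "k2", "k3"),
            c("0", "dad", "dad", "dad"), c("0", "mum", "mum", "mum"))
  expect_equal(classify_family(p1, "mum")$code, 1L)
  # both parents + 2 children -> configuration 4, partially informative
  p4 <- ped(c("dad", "mum", "k1", "k2"),
            c("0", "0", "dad", "dad"), c("0", "0", "mum", "mum"))
  cl4 <- classify_family(p4, "mum")
  expect_equal(cl4$code, 4L); expect_false(cl4$fully_informative)
  # one parent + 2 children -> configuration 3
  p3 <- ped(c("mum", "k1", "k2"), c("0", "dad", "dad"), c("0", "mum", "mum"))
  expect_equal(classify_family(p3, "mum")$code, 3L)
  # two children + both parents + maternal grandparents -> configuration 6
  p6 <- ped(c("gpa", "gma", "dad", "mum", "k1", "k2"),
            c("0", "0", "0", "gpa", "dad", "dad"),
            c("0", "0", "0", "gma", "mum", "mum"))
  cl6 <- classify_family(p6, "mum")
  expect_equal(cl6$code, 6L); expect_true(cl6$fully_informative)
  # same but the other parent is not genotyped -> configuration 5
  p5 <- ped(c("gpa", "gma", "mum", "k1", "k2"),
            c("0", "0", "gpa", "dad", "dad"),
            c("0", "0", "gma", "mum", "mum"))
  cl5 <- classify_family(p5, "mum")
  expect_equal(cl5$code, 5L); expect_false(cl5$fully_informative)
  # >= 3 children with grandparents -> the three-children code wins
  p2g <- ped(c("gpa", "gma", "dad", "mum", "k1", "k2", "k3"),
             c("0", "0", "0", "gpa", "dad", "dad", "dad"),
             c("0", "0", "0", "gma", "mum", "mum", "mum"))
  expect_equal(classify_family(p2g, "mum")$code, 2L)
  # a single child cannot inform the parent effect
  pbad <- ped(c("mum", "k1"), c("0", "dad"), c("0", "mum"))
  expect_error(classify_family(pbad, "mum"), "2 genotyped children")
})

test_that("monozygotic deduplication keeps one child per pair", {
  m <- make_meioses("A", rep("P1", 4), c("c1", "c2", "c3", "c4"),
                    age = c(25, 25, 28, 30), count = c(38, 38, 40, 41))
  out <- deduplicate_monozygotic(m, data.frame(a = "c1", b = "c2"))
  expect_equal(nrow(out), 3L)
  expect_true("c1" %in% out$child_id)   # lexicographically smaller kept
  expect_false("c2" %in% out$child_id)
  # empty pair list is the identity
  expect_identical(deduplicate_monozygotic(m, m[0, 1:2]), m)
  # two disjoint pairs among six children
  m6 <- make_meioses("A", rep("P1", 6), paste0("c", 1:6),
                     age = 25:30, count = rep(38, 6))
  out6 <- deduplicate_monozygotic(m6, data.frame(a = c("c1", "c5"),
                                                 b = c("c2", "c6")))
  expect_equal(nrow(out6), 4L)
  # absent member: warn and skip
  expect_warning(out_w <- deduplicate_monozygotic(m, data.frame(a = "c1", b = "zz")),
                 "skipped")
  expect_equal(nrow(out_w), 4L)
})

test_that("minimum-meioses exclusion rules act at the right level", {
  m <- rbind(
    make_meioses("small7", paste0("p", 1:7), paste0("a", 1:7), 25, 38),
    make_meioses("small11", paste0("q", 1:11), paste0("b", 1:11), 25, 38),
    make_meioses("big25", paste0("r", 1:25), paste0("c", 1:25), 25, 38)
  )
  out <- apply_exclusion_rules(m, min_meioses = 20)
  expect_equal(unique(out$cohort), "big25")
  # all cells at or above the threshold: identity
  expect_identical(apply_exclusion_rules(m, min_meioses = 5), m)
  # per-configuration rule drops only the undersized cell
  m2 <- rbind(
    make_meioses("A", paste0("p", 1:30), paste0("a", 1:30), 25, 38, configuration = 2L),
    make_meioses("A", paste0("q", 1:19), paste0("b", 1:19), 25, 38, configuration = 4L)
  )
  out2 <- apply_exclusion_rules(m2, min_meioses = 20, per_configuration = TRUE)
  expect_equal(nrow(out2), 30L)
  expect_equal(unique(out2$configuration), 2L)
  # the rule never removes a cell at or above the threshold and never adds rows
  expect_lte(nrow(out2), nrow(m2))
})

test_that("binned age summary matches the closed-form normal interval", {
  # reference bin [20, 25); test bin [30, 35) with counts {40, 40, 42, 42}
  m <- rbind(
    make_meioses("A", paste0("p", 1:4), paste0("a", 1:4), c(21, 22, 23, 24), 41),
    make_meioses("A", paste0("q", 1:4), paste0("b", 1:4), c(31, 32, 33, 34),
                 c(40, 40, 42, 42))
  )
  out <- binned_age_summary(m, bin_width = 5, reference_bin = c(20, 25))
  ref <- out[out$age_lo == 20, ]
  tst <- out[out$age_lo == 30, ]
  expect_equal(ref$mean_diff, 0)
  expect_equal(ref$ci_lo, 0)  # constant counts: zero-width interval
  expect_equal(tst$mean_diff, 0)  # both means are 41
  sd_expected <- sd(c(40, 40, 42, 42))
  expect_equal(sd_expected, 1.1547, tolerance = 1e-4)
  expect_equal(tst$ci_hi - tst$mean_diff, 1.96 * sd_expected / 2, tolerance = 1e-10)
  # all counts equal: all differences 0 with zero-width intervals
  m0 <- make_meioses("A", paste0("p", 1:8), paste0("a", 1:8),
                     c(21, 22, 23, 24, 31, 32, 33, 34), 41)
  out0 <- binned_age_summary(m0)
  expect_true(all(out0$mean_diff == 0))
  expect_true(all(out0$ci_hi - out0$ci_lo == 0))
  expect_error(binned_age_summary(m[m$parent_age_years > 30, ]), "reference")
})

test_that("tables round-trip through their TSV writers", {
  sim <- simulate_cohorts(list(cohort_spec("A", c("2" = 5))),
                          default_generative_params(list(cohort_spec("A", c("2" = 5)))),
                          seed = 3)
  tmp <- tempfile(fileext = ".tsv")
  write_meiosis_table(sim$meioses, tmp)
  back <- read_meiosis_table(tmp)
  expect_equal(back$n_crossovers, sim$meioses$n_crossovers)
  expect_equal(back$parent_age_years, sim$meioses$parent_age_years, tolerance = 1e-8)

  ct <- simulate_call_table(sim$meioses, sim$truth, seed = 1)
  tmp2 <- tempfile(fileext = ".tsv")
  write_call_table(ct, tmp2)
  back2 <- read_call_table(tmp2)
  expect_equal(back2$left_snp_index, ct$left_snp_index)

  fam <- tempfile(fileext = ".fam"); side <- tempfile(fileext = ".tsv")
  write_fam(sim$meioses, fam, side)
  ped <- read_fam(fam, side)
  expect_true(all(sim$meioses$child_id %in% ped$pedigree$individual_id))
  expect_true(all(sim$meioses$parent_id %in% ped$pedigree$individual_id))
  expect_equal(nrow(ped$ages), nrow(sim$meioses))
})
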