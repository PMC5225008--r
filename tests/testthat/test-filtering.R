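test_that("support filter keeps exactly the >= threshold predictions", {
  preds <- random_preds(10, seed = 1)
  preds$support <- c(4L, 5L, 1L, 10L, 5L, 4L, 6L, 2L, 30L, 5L)
  out <- filter_support(preds, 5)
  expect_equal(out$sv_id, preds$sv_id[preds$support >= 5])
  rep <- filter_report(out)
  expect_equal(nrow(rep), 10L)
  expect_equal(sum(rep$disposition == "low_support"), 4L)
  # min_support 1 is the identity
  expect_equal(nrow(filter_support(preds, 1)), 10L)
  # all below threshold: empty survivors, full report
  out0 <- filter_support(preds, 1000)
  expect_equal(nrow(out0), 0L)
  expect_equal(nrow(filter_report(out0)), 10L)
  expect_error(filter_support(preds, 0), "min_support")
})

test_that("raising min_support never increases the survivor count", {
  preds <- random_preds(200, seed = 2)
  counts <- purrr::map_int(1:31, function(k) nrow(filter_support(preds, k)))
  expect_true(all(diff(counts) <= 0L))
})

test_that("known-variant filter removes >= 80% overlaps of the same type only", {
  pred <- tibble::tibble(
    sv_id = c("a", "b", "c", "d"),
    type = c("deletion", "deletion", "deletion", "translocation"),
    chrom1 = "chr1", start1 = c(1000L, 5000L, 9000L, 1000L) - 100L,
    end1 = c(1000L, 5000L, 9000L, 1000L) + 100L,
    chrom2 = c("chr1", "chr1", "chr1", "chr9"),
    start2 = c(2000L, 6000L, 10000L, 500L) - 100L,
    end2 = c(2000L, 6000L, 10000L, 500L) + 100L,
    strand1 = "-", strand2 = "+", support = 10L,
    pair_ids = replicate(4, integer(), simplify = FALSE)
  )
  catalogue <- tibble::tibble(
    chrom = "chr1",
    start = c(1000L, 5500L),  # record 1 covers prediction "a" exactly;
    end = c(2000L, 6100L),    # record 2 covers ~half of "b"
    name = "deletion", score = 0, strand = "*"
  )
  out <- filter_known(pred, catalogue, threshold = 0.8)
  expect_equal(out$sv_id, c("b", "c", "d"))
  rep <- dplyr::filter(filter_report(out), stage == "known_variant")
  expect_equal(rep$disposition, c("known_variant", "retained", "retained", "retained"))
  # 50% overlap is retained; identical footprint removed; translocations
  # are never matched by interval records even at full overlap
  cat_t <- tibble::tibble(chrom = "chr1", start = 400L, end = 1600L,
                          name = "translocation", score = 0, strand = "*")
  expect_equal(nrow(filter_known(pred[4, ], cat_t)), 1L)
  expect_error(filter_known(pred, catalogue, threshold = 1.2), "threshold")
})

test_that("threshold 1.0 removes only full containment of the footprint", {
  pred <- random_preds(1, seed = 3)
  pred$type <- "deletion"
  pred$chrom1 <- pred$chrom2 <- "chr1"
  pred$start1 <- 900L; pred$end1 <- 1100L
  pred$start2 <- 4900L; pred$end2 <- 5100L   # footprint 1000..5000
  exact <- tibble::tibble(chrom = "chr1", start = 1000L, end = 5000L,
                          name = "deletion", score = 0, strand = "*")
  short <- tibble::tibble(chrom = "chr1", start = 1001L, end = 5000L,
                          name = "deletion", score = 0, strand = "*")
  expect_equal(nrow(filter_known(pred, exact, threshold = 1.0)), 0L)
  expect_equal(nrow(filter_known(pred, short, threshold = 1.0)), 1L)
})

test_that("known filter matches brute-force dispositions on random cases", {
  preds <- random_preds(300, seed = 4)
  catalogue <- withr::with_seed(5, tibble::tibble(
    chrom = sample(c("chr1", "chr2", "chr3"), 80, TRUE),
    start = sample.int(1e6, 80),
    name = sample(c("deletion", "insertion"), 80, TRUE),
    score = 0, strand = "*"
  ) |>
    dplyr::mutate(end = start + sample(500:25000, 80, TRUE), .after = "start"))
  out <- filter_known(preds, catalogue, threshold = 0.8)
  # brute force: explicit overlap enumeration per prediction x record
  for (i in seq_len(nrow(preds))) {
    p <- preds[i, ]
    removed <- FALSE
    if (p$chrom1 == p$chrom2) {
      lo <- floor((p$start1 + p$end1) / 2)
      hi <- ceiling((p$start2 + p$end2) / 2)
      fp <- gi(p$chrom1, min(lo, hi), max(lo, hi))
      for (j in seq_len(nrow(catalogue))) {
        if (catalogue$name[j] != p$type) next
        shared <- oracle_shared_bases(fp, gi(
          catalogue$chrom[j], catalogue$start[j], catalogue$end[j]
        ))
        if (shared / interval_width(fp) >= 0.8) removed <- TRUE
      }
    }
    expect_equal(!p$sv_id %in% out$sv_id, removed)
  }
})

test_that("patient-specific filter applies positional tolerance on both partners", {
  base <- random_preds(1, seed = 6)
  shift <- function(p, da, db) {
    p$start1 <- p$start1 + da; p$end1 <- p$end1 + da
    p$start2 <- p$start2 + db; p$end2 <- p$end2 + db
    p$sv_id <- paste0(p$sv_id, "s")
    p
  }
  d <- 4000L
  # identical prediction in affected and sibling: removed
  out <- filter_patient_specific(
    list(aff = base, sib = base), "aff", d = d
  )
  expect_equal(nrow(out), 0L)
  # prediction only in the affected member: retained
  out2 <- filter_patient_specific(
    list(aff = base, sib = base[0, ]), "aff", d = d
  )
  expect_equal(nrow(out2), 1L)
  # control offset by d+1 on one partner only: retained (boundary case)
  out3 <- filter_patient_specific(
    list(aff = base, sib = shift(base, 0L, d + 1L)), "aff", d = d
  )
  expect_equal(nrow(out3), 1L)
  # offset exactly d on both partners: still shared
  out4 <- filter_patient_specific(
    list(aff = base, sib = shift(base, d, d)), "aff", d = d
  )
  expect_equal(nrow(out4), 0L)
  expect_error(
    filter_patient_specific(list(aff = base, sib = base), "nobody"),
    "not in the roster"
  )
  expect_error(filter_patient_specific(list(aff = base), "aff"), "two family")
})

test_that("filter chain dispositions partition the input at every stage", {
  preds <- random_preds(100, seed = 8)
  catalogue <- tibble::tibble(
    chrom = "chr1", start = 1L, end = 2e6L,
    name = "deletion", score = 0, strand = "*"
  )
  out <- preds |>
    filter_support(5) |>
    filter_known(catalogue)
  rep <- filter_report(out)
  s1 <- dplyr::filter(rep, stage == "support")
  expect_setequal(s1$sv_id, preds$sv_id)
  s2 <- dplyr::filter(rep, stage == "known_variant")
  expect_setequal(s2$sv_id, s1$sv_id[s1$disposition == "retained"])
  expect_false(any(duplicated(paste(rep$stage, rep$sv_id))))
  expect_setequal(out$sv_id, s2$sv_id[s2$disposition == "retained"])
})
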