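test_that("reference generation is deterministic and honors lengths", {
  cfg <- sim_config(seed = 3, chrom_lengths = c(chrA = 50000, chrB = 30000))
  g1 <- sim_reference(cfg)
  g2 <- sim_reference(cfg)
  expect_equal(as.character(g1), as.character(g2))
  expect_equal(unname(chrom_lengths(g1)), c(50000L, 30000L))
})

test_that("repeat regions are tiled so the motif recurs", {
  cfg <- sim_config(
    seed = 4, chrom_lengths = c(chrA = 20000),
    repeat_regions = tibble::tibble(
      chrom = "chrA", start = 5000L, end = 9999L, motif_length = 300L
    )
  )
  g <- sim_reference(cfg)
  span <- Biostrings::subseq(g[["chrA"]], 5000, 9999)
  motif <- Biostrings::subseq(span, 1, 300)
  hits <- Biostrings::countPattern(as.character(motif), span)
  expect_gte(hits, floor(5000 / 300)) # >= 16 copies in 5 kb
})

test_that("sequence conservation holds through rearrangement", {
  cfg <- tiny_config(10)
  g <- sim_reference(cfg)
  lens <- chrom_lengths(g)
  blunt <- apply_rearrangement(g, rearrangement(
    "reciprocal_translocation", "chrA", 40000, "chrB", 60000
  ))
  dl <- chrom_lengths(blunt$der_genome)
  expect_equal(
    dl[["der(chrA)"]] + dl[["der(chrB)"]],
    lens[["chrA"]] + lens[["chrB"]]
  )
  # 3 bp deletion on the chrA side: total derivative deficit of exactly 3
  del3 <- apply_rearrangement(g, rearrangement(
    "reciprocal_translocation", "chrA", 40000, "chrB", 60000, indel_a = 3
  ))
  dl3 <- chrom_lengths(del3$der_genome)
  expect_equal(
    lens[["chrA"]] + lens[["chrB"]] - (dl3[["der(chrA)"]] + dl3[["der(chrB)"]]),
    3L
  )
  # duplication and insertion add material
  gain <- apply_rearrangement(g, rearrangement(
    "reciprocal_translocation", "chrA", 40000, "chrB", 60000,
    indel_a = -2, ins_b = "GGCC"
  ))
  dlg <- chrom_lengths(gain$der_genome)
  expect_equal(
    (dlg[["der(chrA)"]] + dlg[["der(chrB)"]]) - (lens[["chrA"]] + lens[["chrB"]]),
    2L + 4L
  )
})

test_that("engineered microhomology exists in both reference flanks exactly once in the junction", {
  out <- refined_from_spec(21, list(
    chrom_a = "chrA", pos_a = 40000, chrom_b = "chrB", pos_b = 60000,
    mh_a = 3L, indel_a = 8L, indel_b = 8L
  ))
  expect_true(out$tr$truth$engineered_ok)
  jx <- out$jx
  g <- out$tr$genome
  mh <- jx$mh[1]
  expect_equal(nchar(mh), 3L)
  # the run sits at the end of the chrA prefix and just before the chrB resume
  expect_equal(
    as.character(Biostrings::subseq(g[["chrA"]], 40000 - 2, 40000)), mh
  )
  b2 <- jx$suffix_start[1]
  expect_equal(
    as.character(Biostrings::subseq(g[["chrB"]], b2 - 3, b2 - 1)), mh
  )
  # string-search oracle: in the derivative junction window the k-mer is
  # resolvable as one contiguous run (placement ambiguity, not repetition)
  jseq <- extract_junction_sequence(out$tr$der_genome, "der(chrA)", 40000, w = 60)
  expect_equal(out$der_a$mh, mh)
  expect_equal(out$der_a$ambiguity, 4L)
  expect_true(grepl(mh, jseq, fixed = TRUE))
})

test_that("mate-pair simulation is deterministic and respects insert bounds", {
  cfg <- tiny_config(6, coverage = 5)
  g <- sim_reference(cfg)
  mp1 <- sim_mate_pairs(g, cfg)
  mp2 <- sim_mate_pairs(g, cfg)
  expect_equal(mp1$pairs, mp2$pairs)
  expect_true(all(mp1$origin$insert >= cfg$insert_min))
  expect_true(all(mp1$origin$insert <= cfg$insert_max))
  same <- !is.na(mp1$pairs$insert_size)
  expect_true(all(mp1$pairs$insert_size[same] >= cfg$insert_min))
  expect_true(all(mp1$pairs$insert_size[same] <= cfg$insert_max))
})

test_that("no rearrangement and no duplicates give zero interchromosomal pairs", {
  cfg <- tiny_config(8, coverage = 3, duplicate_rate = 0)
  g <- sim_reference(cfg)
  mp <- sim_mate_pairs(g, cfg)
  expect_equal(sum(mp$pairs$chrom1 != mp$pairs$chrom2), 0L)
})

test_that("junction-spanning pair count matches the binomial expectation", {
  # expected spanning pairs per junction: n * (mean_insert - 2 r) / genome
  lens <- c(chrA = 2e5, chrB = 2e5, chrC = 1e5)
  total <- 0
  n_seeds <- 20
  lambda_sum <- 0
  for (s in 1:n_seeds) {
    cfg <- sim_config(seed = 400 + s, chrom_lengths = lens,
                      coverage = 10, duplicate_rate = 0)
    g <- sim_reference(cfg)
    tr <- apply_rearrangement(g, rearrangement(
      "reciprocal_translocation", "chrA", 100000, "chrB", 120000
    ))
    mp <- sim_mate_pairs(tr, cfg)
    total <- total + sum(!is.na(mp$origin$junction_id))
    n <- round(cfg$coverage * sum(lens) / cfg$insert_mean)
    lambda_sum <- lambda_sum +
      2 * n * (cfg$insert_mean - 2 * cfg$read_length) / sum(lens)
  }
  expect_lt(abs(total - lambda_sum), 3 * sqrt(lambda_sum))
})

test_that("duplicates are exact coordinate copies of emitted pairs", {
  cfg <- tiny_config(9, coverage = 2, duplicate_rate = 0.2)
  g <- sim_reference(cfg)
  mp <- sim_mate_pairs(g, cfg)
  dup <- mp$origin[!is.na(mp$origin$duplicate_of), ]
  expect_gt(nrow(dup), 0)
  for (i in head(seq_len(nrow(dup)), 20)) {
    a <- mp$pairs[mp$pairs$pair_id == dup$pair_id[i], ]
    b <- mp$pairs[mp$pairs$pair_id == dup$duplicate_of[i], ]
    expect_equal(
      a[, c("chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2")],
      b[, c("chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2")]
    )
  }
})

test_that("reads from repeat spans are flagged non-unique at the motif rate", {
  cfg <- sim_config(
    seed = 12, chrom_lengths = c(chrA = 3e5), coverage = 30,
    duplicate_rate = 0,
    repeat_regions = tibble::tibble(
      chrom = "chrA", start = 100000L, end = 109999L, motif_length = 250L
    )
  )
  g <- sim_reference(cfg)
  mp <- sim_mate_pairs(g, cfg)
  in_rep <- mp$pairs$pos1 >= 100000 & mp$pairs$pos1 + cfg$read_length - 1 <= 109999
  out_rep <- !in_rep
  expect_gt(mean(!mp$pairs$unique1[in_rep]), 0.8) # 1 - 1/40 = 0.975
  expect_true(all(mp$pairs$unique1[out_rep]))
})

test_that("known catalogue covers common decoys at >= 80% and spares private ones", {
  decoys <- tibble::tibble(
    chrom = "chrC", start = c(10000L, 50000L), end = c(19999L, 59999L),
    type = "deletion"
  )
  cat <- sim_known_catalogue(decoys, common = c(TRUE, FALSE))
  expect_equal(nrow(cat), 1L)
  fr <- overlap_fraction(decoys[1, ], cat[1, ], mode = "of_a")
  expect_gte(fr, 0.8)
  expect_equal(
    overlap_fraction(decoys[2, ], cat[1, ], mode = "of_a"), 0
  )
  # catalogue round-trips through the BED writer/reader
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(cat, path)
  back <- read_bed(path)
  expect_equal(back$start, cat$start)
  expect_equal(back$end, cat$end)
  expect_equal(back$name, cat$name)
})
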