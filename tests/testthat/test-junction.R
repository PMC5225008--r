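test_that("junction windows come verbatim from the derivative genome", {
  out <- refined_from_spec(41, list(
    chrom_a = "chrA", pos_a = 40000, chrom_b = "chrB", pos_b = 60000
  ))
  tr <- out$tr
  # blunt junction, w = 200: first 100 bases match chrA, last 100 chrB
  jseq <- extract_junction_sequence(tr$der_genome, "der(chrA)", 40000, w = 200)
  expect_equal(
    substr(jseq, 1, 100),
    as.character(Biostrings::subseq(tr$genome[["chrA"]], 39901, 40000))
  )
  expect_equal(
    substr(jseq, 101, 200),
    as.character(Biostrings::subseq(tr$genome[["chrB"]], 60001, 60100))
  )
  # round trip: the window is a substring of the derivative sequence
  expect_true(grepl(jseq, as.character(tr$der_genome[["der(chrA)"]]), fixed = TRUE))
})

test_that("a junction window with an engineered insertion carries it verbatim", {
  out <- refined_from_spec(42, list(
    chrom_a = "chrA", pos_a = 40000, chrom_b = "chrB", pos_b = 60000,
    ins_a = "CATTG"
  ))
  expect_true(out$tr$truth$engineered_ok)
  jseq <- extract_junction_sequence(out$tr$der_genome, "der(chrA)", 40000, w = 40)
  expect_equal(substr(jseq, 21, 25), "CATTG")
})

test_that("refinement decomposes blunt, microhomology and insertion junctions", {
  blunt <- refined_from_spec(43, list(
    chrom_a = "chrA", pos_a = 40000, chrom_b = "chrB", pos_b = 60000,
    indel_a = 6L, indel_b = 6L
  ))
  expect_equal(blunt$der_a$mh, "")
  expect_equal(blunt$der_a$ins, "")
  expect_equal(blunt$der_a$ambiguity, 1L)
  expect_equal(blunt$der_a$prefix_end, 40000L)
  expect_equal(blunt$der_a$suffix_start, 60007L)

  # an engineered TAA microhomology is reported with ambiguity width 4
  g0 <- sim_reference(tiny_config(44))
  want <- "TAA"
  pos_b2 <- 60009L # resume point for indel_b = 8
  g0 <- mateSV:::genome_replace(g0, "chrA", 39998L, want)
  tr <- apply_rearrangement(g0, rearrangement(
    "reciprocal_translocation", "chrA", 40000, "chrB", 60000,
    mh_a = 3L, indel_a = 8L, indel_b = 8L
  ))
  expect_equal(tr$truth$junctions$mh[1], want)
  expect_equal(
    as.character(Biostrings::subseq(tr$genome[["chrB"]], pos_b2 - 3L, pos_b2 - 1L)),
    want
  )
  jseq <- extract_junction_sequence(tr$der_genome, "der(chrA)", 40000, w = 300)
  ref <- refine_junction(jseq, tr$genome, "chrA", "chrB")
  expect_equal(ref$mh, want)
  expect_equal(ref$ambiguity, 4L)

  ins <- refined_from_spec(45, list(
    chrom_a = "chrA", pos_a = 40000, chrom_b = "chrB", pos_b = 60000,
    ins_a = "gc", indel_a = 5L, indel_b = 5L
  ))
  expect_equal(ins$der_a$ins, "GC")
  expect_equal(ins$der_a$mh, "")
  expect_equal(ins$der_a$ambiguity, 1L)
})

test_that("split alignment equals the enumeration oracle on windows <= 300 bp", {
  for (s in 1:30) {
    cfg <- tiny_config(800 + s)
    g <- sim_reference(cfg)
    spec <- sim_random_rearrangement(g, seed = 9000 + s)
    tr <- apply_rearrangement(g, spec)
    jx <- tr$truth$junctions
    for (j in 1:2) {
      w <- 300L
      half <- w %/% 2L
      jseq <- extract_junction_sequence(
        tr$der_genome, jx$junction_id[j], jx$der_junction_pos[j], w = w
      )
      fast <- refine_junction(jseq, tr$genome,
                              jx$prefix_chrom[j], jx$suffix_chrom[j])
      # oracle alignment from the engineered geometry, not from the search
      ins_len <- nchar(jx$ins_requested[j])
      x0 <- jx$prefix_end[j] - half + 1L
      yend <- jx$suffix_start[j] + (w - half) - ins_len - 1L
      orc <- oracle_decompose(
        jseq,
        as.character(tr$genome[[jx$prefix_chrom[j]]]),
        as.character(tr$genome[[jx$suffix_chrom[j]]]),
        x0, yend
      )
      n <- nchar(jseq)
      if (length(orc$blunt_splits) > 0) {
        # admissible placements = the fast refinement's ambiguity interval
        expect_equal(min(orc$blunt_splits), n - (yend - fast$suffix_start + 1L))
        expect_equal(max(orc$blunt_splits), fast$prefix_end - x0 + 1L)
        expect_equal(length(orc$blunt_splits), fast$ambiguity)
        expect_equal(nchar(fast$mh), length(orc$blunt_splits) - 1L)
      } else {
        expect_equal(fast$ins, substr(jseq, orc$L + 1L, n - orc$R))
        expect_equal(fast$prefix_end, x0 + orc$L - 1L)
        expect_equal(fast$suffix_start, yend - orc$R + 1L)
      }
    }
  }
})

test_that("refine + reconcile recovers simulator truth exactly over random specs", {
  for (s in 1:40) {
    out <- NULL
    cfg <- tiny_config(1200 + s)
    g <- sim_reference(cfg)
    spec <- sim_random_rearrangement(g, seed = 1500 + s)
    tr <- apply_rearrangement(g, spec)
    jx <- tr$truth$junctions
    ref <- lapply(1:2, function(j) {
      jseq <- extract_junction_sequence(
        tr$der_genome, jx$junction_id[j], jx$der_junction_pos[j], w = 400
      )
      refine_junction(jseq, tr$genome, jx$prefix_chrom[j], jx$suffix_chrom[j])
    })
    rec <- reconcile_derivatives(ref[[1]], ref[[2]], tr$genome)
    ce <- tr$truth$chrom_events
    expect_equal(rec$mh, jx$mh)
    expect_equal(rec$ins, jx$ins)
    expect_equal(rec$indel_type, ce$indel_type)
    expect_equal(rec$indel_seq, ce$indel_seq)
    expect_equal(rec$bp_start, ce$bp_start)
    expect_equal(rec$bp_end, ce$bp_end)
  }
})

test_that("breakpoint intervals follow the deletion/balanced/duplication widths", {
  # 3 bp deletion between retained flanks: width 5
  del3 <- refined_from_spec(46, list(
    chrom_a = "chrA", pos_a = 40000, chrom_b = "chrB", pos_b = 60000,
    indel_a = 3L, indel_b = 0L
  ))
  row_a <- del3$rec[del3$rec$chrom == "chrA", ]
  expect_equal(row_a$indel_type, "deletion")
  expect_equal(nchar(row_a$indel_seq), 3L)
  expect_equal(row_a$bp_end - row_a$bp_start + 1L, 5L)
  # balanced side: width 2
  row_b <- del3$rec[del3$rec$chrom == "chrB", ]
  expect_equal(row_b$indel_type, "none")
  expect_equal(row_b$bp_end - row_b$bp_start + 1L, 2L)
  # 5 bp deletion, no microhomology: width 7
  del5 <- refined_from_spec(47, list(
    chrom_a = "chrA", pos_a = 40000, chrom_b = "chrB", pos_b = 60000,
    indel_a = 5L, indel_b = 5L
  ))
  row5 <- del5$rec[del5$rec$chrom == "chrA", ]
  expect_equal(row5$bp_end - row5$bp_start + 1L, 7L)
  # 2 bp duplication: the duplicated 2 bp span itself
  dup2 <- refined_from_spec(48, list(
    chrom_a = "chrA", pos_a = 40000, chrom_b = "chrB", pos_b = 60000,
    indel_a = -2L, indel_b = 4L
  ))
  rd <- dup2$rec[dup2$rec$chrom == "chrA", ]
  expect_equal(rd$indel_type, "duplication")
  expect_equal(nchar(rd$indel_seq), 2L)
  expect_equal(rd$bp_end - rd$bp_start + 1L, 2L)
  # a deletion coexisting with microhomology keeps its full length and
  # prints deletion + 2 (the junction-table pattern)
  mixed <- refined_from_spec(49, list(
    chrom_a = "chrA", pos_a = 40000, chrom_b = "chrB", pos_b = 60000,
    mh_a = 1L, mh_b = 2L, indel_a = 3L, indel_b = 3L
  ))
  expect_true(mixed$tr$truth$engineered_ok)
  ra <- mixed$rec[mixed$rec$chrom == "chrA", ]
  expect_equal(nchar(ra$indel_seq), 3L)
  expect_equal(ra$bp_end - ra$bp_start + 1L, 5L)
})

test_that("mismatch-tolerant refinement absorbs sparse sequencing errors", {
  out <- refined_from_spec(50, list(
    chrom_a = "chrA", pos_a = 40000, chrom_b = "chrB", pos_b = 60000,
    mh_a = 2L, indel_a = 6L, indel_b = 6L
  ))
  tr <- out$tr
  jseq <- extract_junction_sequence(tr$der_genome, "der(chrA)", 40000, w = 400)
  # plant one substitution 60 bp from each end, outside the anchors
  flip <- function(s, i) {
    ch <- substr(s, i, i)
    paste0(substr(s, 1, i - 1), setdiff(c("A", "C", "G", "T"), ch)[1],
           substr(s, i + 1, nchar(s)))
  }
  noisy <- flip(flip(jseq, 90L), 310L)
  tol <- refine_junction(noisy, tr$genome, "chrA", "chrB", mismatch_rate = 1 / 50)
  expect_equal(tol$mh, out$der_a$mh)
  expect_equal(tol$prefix_end, out$der_a$prefix_end)
  expect_equal(tol$suffix_start, out$der_a$suffix_start)
  # exact mode stops at the planted mismatches instead
  exact <- refine_junction(noisy, tr$genome, "chrA", "chrB")
  expect_lt(exact$prefix_end, out$der_a$prefix_end)
})

test_that("ambiguous anchors raise an unanchored-junction error", {
  chrB_seq <- withr::with_seed(60, mateSV:::random_bases(200))
  g <- genome(c(
    chrA = strrep("ACGTTGCATGCAATTGGCCA", 30), # 20-mer tiled: every anchor repeats
    chrB = chrB_seq
  ))
  jseq <- paste0(strrep("ACGTTGCATGCAATTGGCCA", 3), substr(chrB_seq, 1, 60))
  expect_error(
    refine_junction(jseq, g, "chrA", "chrB"),
    "unanchored"
  )
})

test_that("family comparison flags any breakpoint or signature difference", {
  out <- refined_from_spec(51, list(
    chrom_a = "chrA", pos_a = 40000, chrom_b = "chrB", pos_b = 60000,
    mh_a = 1L, indel_a = 3L, indel_b = 3L
  ))
  rec <- out$rec
  expect_equal(compare_family(list(m1 = rec, m2 = rec))$verdict, "identical")
  shifted <- rec
  shifted$bp_start[1] <- shifted$bp_start[1] + 1L
  cmp <- compare_family(list(m1 = rec, m2 = shifted))
  expect_equal(cmp$verdict, "discordant")
  expect_equal(nrow(cmp$diffs), 1L)
  expect_equal(cmp$diffs$field, "bp_start")
  other_mh <- rec
  other_mh$mh[1] <- "GGG"
  expect_equal(compare_family(list(m1 = rec, m2 = other_mh))$verdict, "discordant")
  missing <- rec[1, ]
  expect_error(
    compare_family(list(m1 = rec, m2 = missing)),
    "missing junction"
  )
})

test_that("junction rendering marks microhomology and insertions", {
  out <- refined_from_spec(52, list(
    chrom_a = "chrA", pos_a = 40000, chrom_b = "chrB", pos_b = 60000,
    mh_a = 3L, indel_a = 8L, indel_b = 8L
  ))
  lines <- format_junction(out$der_a, out$tr$genome, flank = 20)
  expect_length(lines, 3L)
  expect_match(lines[2], sprintf("\\[%s\\]", out$der_a$mh))
  ins <- refined_from_spec(53, list(
    chrom_a = "chrA", pos_a = 40000, chrom_b = "chrB", pos_b = 60000,
    ins_a = "TT", indel_a = 5L, indel_b = 5L
  ))
  lines2 <- format_junction(ins$der_a, ins$tr$genome, flank = 20)
  expect_match(lines2[2], "tt")
})
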