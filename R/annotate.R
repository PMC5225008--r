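# Breakpoint annotation against gene models, repeat and CNE tracks, and
# repair-mechanism classification of refined junctions.

#' Genes disrupted at a breakpoint
#'
#' A gene is disrupted when its span contains the midpoint of the
#' breakpoint interval. The disrupted element index is computed in
#' transcription order (strand-aware): exon *i* when the midpoint falls in
#' exon *i*, intron *i* when it falls between exons *i* and *i + 1*. All
#' overlapping gene models are reported. Breakpoint intervals straddling an
#' exon boundary are flagged ambiguous.
#'
#' @param bp One-row interval tibble (the refined breakpoint interval).
#' @param gene_models Exon tibble (see [read_gene_models()]).
#' @return Tibble with columns `gene`, `element` (`"exon"`/`"intron"`),
#'   `index`, `ambiguous`; zero rows when intergenic.
#' @export
genes_at_breakpoint <- function(bp, gene_models) {
  validate_intervals(bp)
  stopifnot(nrow(bp) == 1)
  mid <- as.integer(floor((bp$start + bp$end) / 2))
  spans <- gene_models |>
    group_by(.data$gene) |>
    summarise(
      chrom = first(.data$chrom), start = min(.data$start),
      end = max(.data$end), strand = first(.data$strand), .groups = "drop"
    )
  hits <- spans |>
    filter(.data$chrom == bp$chrom, .data$start <= mid, .data$end >= mid)
  if (nrow(hits) == 0) {
    return(tibble(gene = character(), element = character(),
                  index = integer(), ambiguous = logical()))
  }
  list_rbind(map(hits$gene, function(gn) {
    ex <- gene_models |> filter(.data$gene == gn) |> arrange(.data$exon)
    in_exon <- which(ex$start <= mid & ex$end >= mid)
    # does the breakpoint interval straddle any exon boundary?
    amb <- any(
      (bp$start <= ex$start & bp$end >= ex$start) |
        (bp$start <= ex$end & bp$end >= ex$end)
    )
    if (length(in_exon) > 0) {
      return(tibble(gene = gn, element = "exon",
                    index = ex$exon[in_exon[1]], ambiguous = amb))
    }
    # intron index in transcription order: between exon i and exon i + 1
    minus <- ex$strand[1] == "-"
    before_mid <- if (minus) ex$start > mid else ex$end < mid
    tibble(gene = gn, element = "intron",
           index = max(ex$exon[before_mid]), ambiguous = amb)
  }))
}

#' Repeat elements overlapping a breakpoint
#'
#' Strict interval overlap against a repeat track (labels like
#' `"SINE-MIR-MIRb"` are passed through); adjacency does not count.
#'
#' @param bp One-row interval tibble.
#' @param repeats Repeat track tibble (from [read_bed()]).
#' @return The overlapping repeat records.
#' @export
repeats_at_breakpoint <- function(bp, repeats) {
  validate_intervals(bp)
  stopifnot(nrow(bp) == 1)
  if (nrow(repeats) == 0) return(repeats)
  repeats |>
    filter(.data$chrom == bp$chrom, .data$start <= bp$end, .data$end >= bp$start)
}

#' Conserved non-coding elements near a breakpoint
#'
#' Returns CNEs lying wholly within a closed window of `window` bp either
#' side of the breakpoint, with signed distances (negative = upstream of
#' the breakpoint midpoint, 0 = overlapping); the position-effect flag is
#' set when any CNE is returned.
#'
#' @param bp One-row interval tibble.
#' @param cnes CNE track tibble.
#' @param window Window half-width in bp (default 1 Mb, closed at both
#'   ends).
#' @return List with `cnes` (tibble + `distance` column) and
#'   `position_effect` (logical).
#' @export
cne_proximity <- function(bp, cnes, window = 1e6) {
  validate_intervals(bp)
  stopifnot(nrow(bp) == 1, window > 0)
  mid <- floor((bp$start + bp$end) / 2)
  hits <- cnes |>
    filter(
      .data$chrom == bp$chrom,
      .data$start >= mid - window, .data$end <= mid + window
    ) |>
    mutate(distance = case_when(
      .data$end < bp$start ~ .data$end - bp$start,   # upstream: negative
      .data$start > bp$end ~ .data$start - bp$end,   # downstream: positive
      TRUE ~ 0
    ))
  list(cnes = hits, position_effect = nrow(hits) > 0)
}

#' Classify the likely formation mechanism of a refined junction
#'
#' Scans `flank` bp on each side of the two partner breakpoints for a
#' shared homologous stretch (local alignment of length >= `l_min` at
#' identity >= `i_min`): such homology supports non-allelic homologous
#' recombination (NAHR). Failing that, junction microhomology of at least
#' `m_min` bp points to microhomology-mediated repair (MHMR/MMEJ), and a
#' blunt junction, 1 bp homology, an untemplated insertion or small indels
#' point to non-homologous end joining (NHEJ).
#'
#' @param refined One row of a `refined_pair` tibble.
#' @param g Reference genome.
#' @param flank Flank length scanned on each partner (default 500 bp).
#' @param l_min Minimum homology length for NAHR (default 50 bp).
#' @param i_min Minimum homology identity for NAHR (default 0.9).
#' @param m_min Minimum microhomology for MHMR (default 2 bp).
#' @return One-row tibble: `mechanism` (`NAHR`, `MHMR`, `NHEJ`),
#'   `evidence`.
#' @export
classify_mechanism <- function(refined, g, flank = 500L, l_min = 50L,
                               i_min = 0.9, m_min = 2L) {
  pc <- col_or(refined, "prefix_chrom", "chrom")
  sc <- col_or(refined, "suffix_chrom", "partner_chrom")
  pe <- refined$prefix_end
  ss <- col_or(refined, "suffix_start", "partner_start")
  fa <- genome_seq(g, pc, max(1L, pe - flank + 1L),
                   min(length(g[[pc]]), pe + flank), clip = TRUE)
  fb <- genome_seq(g, sc, max(1L, ss - flank),
                   min(length(g[[sc]]), ss + flank - 1L), clip = TRUE)
  hom <- flank_homology(fa, fb)
  if (hom$length >= l_min && hom$identity >= i_min) {
    return(tibble(
      mechanism = "NAHR",
      evidence = sprintf("homologous flanks: %d bp at %.0f%% identity",
                         hom$length, 100 * hom$identity)
    ))
  }
  mh_len <- nchar(refined$mh)
  if (mh_len >= m_min) {
    return(tibble(
      mechanism = "MHMR",
      evidence = sprintf("%d bp junction microhomology ('%s')", mh_len, refined$mh)
    ))
  }
  ev <- if (nzchar(refined$ins)) {
    sprintf("untemplated insertion '%s'", refined$ins)
  } else if (mh_len == 1) {
    "1 bp junction homology"
  } else {
    "blunt junction"
  }
  tibble(mechanism = "NHEJ", evidence = ev)
}

# best shared stretch between two flank sequences, via local alignment
flank_homology <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) return(list(length = 0L, identity = 0))
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2, baseOnly = FALSE
    ),
    gapOpening = 5, gapExtension = 2
  )
  len <- Biostrings::nmatch(al) + Biostrings::nmismatch(al)
  if (length(len) == 0 || len == 0) return(list(length = 0L, identity = 0))
  list(
    length = as.integer(len),
    identity = Biostrings::nmatch(al) / len
  )
}
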