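#' Read / write genomes as FASTA
#'
#' Thin wrappers over [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()] that validate the genome contract
#' (unique names, non-empty A/C/G/T/N sequences).
#'
#' @param path File path.
#' @param g A genome (`DNAStringSet`).
#' @return `read_genome()` returns a genome; `write_genome()` returns `path`
#'   invisibly.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  # keep only the first word of each FASTA header, as aligners do
  names(g) <- sub("\\s.*$", "", names(g))
  genome(g)
}

#' @rdname read_genome
#' @export
write_genome <- function(g, path) {
  Biostrings::writeXStringSet(genome(g), path)
  invisible(path)
}

#' Read / write feature tracks as BED
#'
#' On disk BED is 0-based half-open; in memory everything is 1-based
#' inclusive. The conversion happens exactly once, inside rtracklayer, at
#' this boundary. Track kinds (repeat, CNE, known-SV catalogue) share the
#' same tabular shape; the `name` column carries the record label
#' (e.g. a repeat "class-family-name" string, or an SV type for catalogues).
#'
#' @param path File path.
#' @param x Feature tibble with `chrom`, `start`, `end` and optional `name`,
#'   `score`, `strand` columns.
#' @return `read_bed()` returns a tibble with columns `chrom`, `start`,
#'   `end`, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(),
      name = character(), score = double(), strand = character()
    ))
  }
  gr <- rtracklayer::import(path, format = "BED")
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = as.integer(GenomicRanges::start(gr)),
    end = as.integer(GenomicRanges::end(gr)),
    name = if (!is.null(gr$name)) as.character(gr$name) else NA_character_,
    score = if (!is.null(gr$score)) as.double(gr$score) else NA_real_,
    strand = as.character(GenomicRanges::strand(gr))
  )
  validate_intervals(out, what = basename(path))
  out
}

#' @rdname read_bed
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  name <- if ("name" %in% names(x)) x$name else "."
  score <- if ("score" %in% names(x)) x$score else 0
  strand <- if ("strand" %in% names(x)) x$strand else "*"
  score[is.na(score)] <- 0
  name[is.na(name)] <- "."
  df <- data.frame(
    chrom = x$chrom,
    start = format(x$start - 1L, scientific = FALSE, trim = TRUE),
    end = format(x$end, scientific = FALSE, trim = TRUE),
    name = name, score = score,
    strand = ifelse(strand == "*", ".", strand)
  )
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Read / write gene models as GFF3
#'
#' Gene models are tabular: one row per exon, with the parent gene name,
#' strand and exon rank in transcription order (rank 1 is the 5' exon, so
#' ranks run right-to-left for minus-strand genes).
#'
#' @param path File path.
#' @param x Exon tibble with columns `gene`, `chrom`, `start`, `end`,
#'   `strand`, `exon`.
#' @return `read_gene_models()` returns such a tibble.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  ex <- gr[gr$type == "exon"]
  parent <- as.character(ex$Parent)
  out <- tibble(
    gene = sub("^gene:", "", parent),
    chrom = as.character(GenomicRanges::seqnames(ex)),
    start = as.integer(GenomicRanges::start(ex)),
    end = as.integer(GenomicRanges::end(ex)),
    strand = as.character(GenomicRanges::strand(ex))
  )
  out <- out |>
    group_by(.data$gene) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(exon = if (first(.data$strand) == "-") rev(row_number()) else row_number()) |>
    ungroup() |>
    arrange(.data$gene, .data$exon)
  validate_gene_models(out)
  out
}

validate_gene_models <- function(x) {
  stopifnot(all(c("gene", "chrom", "start", "end", "strand", "exon") %in% names(x)))
  validate_intervals(x, what = "exon")
  chk <- x |>
    group_by(.data$gene) |>
    summarise(ok = all(sort(.data$exon) == seq_len(n())), .groups = "drop")
  if (!all(chk$ok)) {
    abort(sprintf("gene '%s' has non-consecutive exon ranks", chk$gene[!chk$ok][1]))
  }
  invisible(x)
}

#' @rdname read_gene_models
#' @export
write_gene_models <- function(x, path) {
  validate_gene_models(x)
  genes <- x |>
    group_by(.data$gene) |>
    summarise(
      chrom = first(.data$chrom), start = min(.data$start),
      end = max(.data$end), strand = first(.data$strand), .groups = "drop"
    )
  lines <- c(
    "##gff-version 3",
    sprintf(
      "%s\tmateSV\tgene\t%d\t%d\t.\t%s\t.\tID=gene:%s;Name=%s",
      genes$chrom, genes$start, genes$end, genes$strand, genes$gene, genes$gene
    ),
    sprintf(
      "%s\tmateSV\texon\t%d\t%d\t.\t%s\t.\tID=exon:%s.%d;Parent=gene:%s",
      x$chrom, x$start, x$end, x$strand, x$gene, x$exon, x$gene
    )
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read / write SV predictions as BEDPE
#'
#' BEDPE coordinates are 0-based half-open on disk, converted here to the
#' internal 1-based inclusive convention. The `name` field carries the SV
#' type and the `score` field the read-pair support.
#'
#' @param path File path.
#' @param x An SV prediction tibble (see [cluster_discordant()]).
#' @return `read_bedpe()` returns an SV prediction tibble (without pair ids,
#'   which are not representable in BEDPE).
#' @export
read_bedpe <- function(path) {
  empty <- tibble(
    sv_id = character(), type = character(),
    chrom1 = character(), start1 = integer(), end1 = integer(),
    chrom2 = character(), start2 = integer(), end2 = integer(),
    strand1 = character(), strand2 = character(), support = integer()
  )
  if (file.size(path) == 0) return(empty)
  raw <- readr::read_tsv(
    path,
    col_names = c(
      "chrom1", "start1", "end1", "chrom2", "start2", "end2",
      "name", "score", "strand1", "strand2"
    ),
    col_types = "ciiciicicc", progress = FALSE
  )
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    abort(sprintf("%s: malformed BEDPE at line %d", path, prob$row[1]))
  }
  tibble(
    sv_id = sub("\\|.*$", "", raw$name),
    type = sub("^[^|]*\\|", "", raw$name),
    chrom1 = raw$chrom1, start1 = raw$start1 + 1L, end1 = raw$end1,
    chrom2 = raw$chrom2, start2 = raw$start2 + 1L, end2 = raw$end2,
    strand1 = raw$strand1, strand2 = raw$strand2,
    support = as.integer(raw$score)
  )
}

#' @rdname read_bedpe
#' @export
write_bedpe <- function(x, path) {
  df <- data.frame(
    chrom1 = x$chrom1, start1 = x$start1 - 1L, end1 = x$end1,
    chrom2 = x$chrom2, start2 = x$start2 - 1L, end2 = x$end2,
    name = paste0(x$sv_id, "|", x$type), score = x$support,
    strand1 = x$strand1, strand2 = x$strand2
  )
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Read / write aligned mate-pairs as TSV
#'
#' One row per mate-pair: per-mate chromosome, leftmost 1-based position,
#' strand and unique-mapping flag, plus the inferred insert size (`NA` for
#' interchromosomal pairs).
#'
#' @param path File path.
#' @param x Aligned-pair tibble (see [sim_mate_pairs()]).
#' @return `read_pairs()` returns an aligned-pair tibble.
#' @export
read_pairs <- function(path) {
  x <- readr::read_tsv(
    path,
    col_types = readr::cols(
      pair_id = readr::col_integer(),
      chrom1 = readr::col_character(), pos1 = readr::col_integer(),
      strand1 = readr::col_character(), unique1 = readr::col_logical(),
      chrom2 = readr::col_character(), pos2 = readr::col_integer(),
      strand2 = readr::col_character(), unique2 = readr::col_logical(),
      insert_size = readr::col_integer()
    ),
    progress = FALSE
  )
  prob <- readr::problems(x)
  if (nrow(prob) > 0) {
    abort(sprintf("%s: malformed pair record at line %d", path, prob$row[1] + 1L))
  }
  x
}

#' @rdname read_pairs
#' @export
write_pairs <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Ingest aligned mate-pairs from SAM text
#'
#' A minimal adapter from plain-text SAM (as written by `samtools view`) to
#' the aligned-pair tibble: primary alignments are paired by QNAME, mapping
#' uniqueness is taken from MAPQ > 0, and the insert size from TLEN.
#' Binary BAM/CRAM is out of scope.
#'
#' @param path Path to a SAM text file.
#' @param read_length Read length used when TLEN is absent (0).
#' @return An aligned-pair tibble (see [read_pairs()]).
#' @export
read_sam_pairs <- function(path, read_length = 100L) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0) {
    return(read_pairs_empty())
  }
  fields <- stringr::str_split(lines, "\t")
  short <- which(lengths(fields) < 11L)
  if (length(short) > 0) {
    abort(sprintf("%s: truncated SAM record at line %d", path, short[1]))
  }
  rec <- tibble(
    qname = map_chr(fields, 1),
    flag = as.integer(map_chr(fields, 2)),
    chrom = map_chr(fields, 3),
    pos = as.integer(map_chr(fields, 4)),
    mapq = as.integer(map_chr(fields, 5)),
    tlen = as.integer(map_chr(fields, 9))
  ) |>
    filter(bitwAnd(.data$flag, 256L) == 0L, bitwAnd(.data$flag, 2048L) == 0L) |>
    mutate(
      strand = if_else(bitwAnd(.data$flag, 16L) > 0L, "-", "+"),
      first_mate = bitwAnd(.data$flag, 64L) > 0L
    )
  rec |>
    group_by(.data$qname) |>
    filter(n() == 2L) |>
    arrange(dplyr::desc(.data$first_mate), .by_group = TRUE) |>
    summarise(
      chrom1 = .data$chrom[1], pos1 = .data$pos[1], strand1 = .data$strand[1],
      unique1 = .data$mapq[1] > 0L,
      chrom2 = .data$chrom[2], pos2 = .data$pos[2], strand2 = .data$strand[2],
      unique2 = .data$mapq[2] > 0L,
      insert_size = if (.data$chrom[1] == .data$chrom[2]) {
        abs(.data$tlen[1])
      } else {
        NA_integer_
      },
      .groups = "drop"
    ) |>
    mutate(pair_id = row_number(), .before = 1) |>
    select(-"qname")
}

read_pairs_empty <- function() {
  tibble(
    pair_id = integer(),
    chrom1 = character(), pos1 = integer(), strand1 = character(), unique1 = logical(),
    chrom2 = character(), pos2 = integer(), strand2 = character(), unique2 = logical(),
    insert_size = integer()
  )
}
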