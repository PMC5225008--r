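# End-to-end orchestration: simulate a family study, detect and filter SVs
# per member, refine and reconcile the translocation junctions, annotate,
# classify mechanisms, test family concordance, and emit a case report in
# the column layout of nucleotide-level breakpoint tables.

#' Simulate a translocation family study
#'
#' All members carry the same reciprocal translocation (so the family
#' genome, including any engineered microhomology, is shared); decoy
#' intrachromosomal deletions are layered per member: one "common" decoy
#' present in every member and covered by the known-SV catalogue, one
#' "shared" decoy present in every member but absent from the catalogue,
#' and one "private" decoy carried only by the affected member. Annotation
#' tracks (a gene model across one breakpoint, a repeat at the other, a CNE
#' within 1 Mb) are generated alongside.
#'
#' @param config A [sim_config()].
#' @param members Character vector of member names (first = affected by
#'   default).
#' @param affected Name of the affected member.
#' @param translocation Optional [rearrangement()] spec; the default draws
#'   mid-chromosome breakpoints from the seed with 1 and 2 bp
#'   microhomology and 3 bp deletions on both partners, the signature
#'   magnitudes typical of sequenced reciprocal-translocation junctions.
#' @return A list of class `abt_study`.
#' @export
sim_study <- function(config = sim_config(),
                      members = c("affected", "relative"),
                      affected = members[1],
                      translocation = NULL) {
  stopifnot(length(members) >= 2, affected %in% members)
  g0 <- sim_reference(config)
  chroms <- names(g0)
  len <- chrom_lengths(g0)
  if (is.null(translocation)) {
    pos <- with_seed(config$seed + 1L, list(
      a = sample(seq(round(len[1] * 0.3), round(len[1] * 0.7)), 1L),
      b = sample(seq(round(len[2] * 0.3), round(len[2] * 0.7)), 1L)
    ))
    translocation <- rearrangement(
      "reciprocal_translocation",
      chrom_a = chroms[1], pos_a = pos$a,
      chrom_b = chroms[2], pos_b = pos$b,
      mh_a = 1L, mh_b = 2L, indel_a = 3L, indel_b = 3L
    )
  }
  # engineer once so every member shares the rewritten family reference
  tr0 <- apply_rearrangement(g0, translocation)
  g <- tr0$genome

  decoy_chrom <- chroms[length(chroms)]
  decoys <- with_seed(config$seed + 3L, {
    repeat {
      starts <- sort(sample(seq(100000L, round(len[[decoy_chrom]] * 0.6), by = 1000L), 3L))
      if (all(diff(starts) > 20000L)) break
    }
    spans <- sample(6000:15000, 3L)
    tibble(
      chrom = decoy_chrom, start = starts, end = starts + spans - 1L,
      span = spans, role = c("common", "shared", "private")
    )
  })
  decoy_spec <- function(row) {
    rearrangement("deletion", chrom_a = decoys$chrom[row],
                  pos_a = decoys$start[row], span = decoys$span[row])
  }
  member_sims <- setNames(map(members, function(m) {
    roles <- if (m == affected) 1:3 else 1:2
    apply_rearrangements(g, c(list(translocation), map(roles, decoy_spec)))
  }), members)
  member_pairs <- imap(member_sims, function(sim, m) {
    sim_mate_pairs(sim, config,
                   seed = config$seed + 100L + match(m, members))
  })
  catalogue <- sim_known_catalogue(
    decoys |> select("chrom", "start", "end") |> mutate(type = "deletion"),
    common = decoys$role == "common"
  )
  truth <- member_sims[[affected]]$truth
  tracks <- study_tracks(g, truth, seed = config$seed + 4L)
  structure(
    list(
      config = config, genome = g, members = members, affected = affected,
      translocation = translocation, truth = truth, decoys = decoys,
      member_sims = member_sims, member_pairs = member_pairs,
      catalogue = catalogue, tracks = tracks
    ),
    class = "abt_study"
  )
}

# synthetic annotation tracks anchored on the engineered breakpoints
study_tracks <- function(g, truth, seed) {
  jx <- truth$junctions
  bp_a <- jx$prefix_end[1]; chrom_a <- jx$prefix_chrom[1]
  bp_b <- jx$prefix_end[2]; chrom_b <- jx$prefix_chrom[2]
  # a 9-exon minus-strand gene across the chrom_b breakpoint; the exon grid
  # deliberately avoids the breakpoint so the disruption is intronic
  # (between transcription-order exons 4 and 5 on the minus strand)
  exon_w <- 400L
  starts <- bp_b + c(-12000L, -9000L, -6000L, -3000L, -1000L,
                     2000L, 5000L, 8000L, 11000L)
  gene_models <- tibble(
    gene = "GENE1", chrom = chrom_b,
    start = as.integer(starts), end = as.integer(starts + exon_w - 1L),
    strand = "-"
  ) |>
    mutate(exon = rev(row_number()))
  repeats <- tibble(
    chrom = c(chrom_a, chrom_b),
    start = c(bp_a - 120L, bp_b + 5000L),
    end = c(bp_a + 80L, bp_b + 5200L),
    name = c("SINE-MIR-MIRb", "LINE-L1-L1M5"),
    score = 0, strand = "+"
  )
  cnes <- tibble(
    chrom = c(chrom_a, chrom_a),
    start = c(bp_a + 500000L, bp_a + 1500000L),
    end = c(bp_a + 500400L, bp_a + 1500400L),
    name = c("CNE1", "CNE2"), score = 0, strand = "*"
  ) |>
    filter(.data$end <= length(g[[chrom_a]]))
  list(gene_models = gene_models, repeats = repeats, cnes = cnes)
}

#' Run the full breakpoint-mapping pipeline on a simulated study
#'
#' simulate -> dedupe/unique-filter -> classify -> cluster -> support,
#' known-SV and family filters -> junction refinement and reconciliation ->
#' annotation and mechanism -> family concordance -> case report. Fully
#' deterministic given the study seed; all intermediates are written (and
#' re-loadable) when `outdir` is given.
#'
#' @param study An [sim_study()] result, or `NULL` to build one from
#'   `config`.
#' @param config A [sim_config()] used when `study` is `NULL`.
#' @param min_support Minimum read-pair support (default 5).
#' @param overlap_threshold Known-SV overlap fraction (default 0.8).
#' @param window Junction extraction window in bp (default 400).
#' @param outdir Optional output directory for intermediates.
#' @return A list of class `abt_result`: `report` (case-report tibble),
#'   `predictions`, `filtered`, `patient_specific`, `refined` (per
#'   member), `concordance`, `study`.
#' @export
run_pipeline <- function(study = NULL, config = sim_config(),
                         min_support = 5L, overlap_threshold = 0.8,
                         window = 400L, outdir = NULL) {
  if (is.null(study)) study <- sim_study(config)
  stopifnot(inherits(study, "abt_study"))
  cfg <- study$config
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  preds_raw <- list(); preds_filtered <- list(); refined <- list()
  for (m in study$members) {
    pairs <- study$member_pairs[[m]]$pairs
    dd <- pairs_dedupe(pairs)
    cl <- pairs_classify(dd, cfg$convention, cfg$insert_min, cfg$insert_max)
    preds <- cluster_discordant(
      cl, d = cfg$insert_max, convention = cfg$convention,
      read_length = cfg$read_length, insert_max = cfg$insert_max
    )
    preds_raw[[m]] <- preds
    f <- preds |>
      filter_support(min_support) |>
      filter_known(study$catalogue, threshold = overlap_threshold)
    preds_filtered[[m]] <- f
    refined[[m]] <- refine_member(study, m, f, window)
    if (!is.null(outdir)) {
      write_pairs(pairs, file.path(outdir, paste0(m, "_pairs.tsv")))
      write_bedpe(preds, file.path(outdir, paste0(m, "_predictions.bedpe")))
      readr::write_tsv(filter_report(f), file.path(outdir, paste0(m, "_filter_report.tsv")))
      readr::write_tsv(refined[[m]], file.path(outdir, paste0(m, "_refined.tsv")))
    }
  }
  patient_specific <- filter_patient_specific(
    preds_filtered, study$affected, d = cfg$insert_max
  )
  concordance <- compare_family(refined)
  report <- case_report(study, preds_filtered, refined, concordance)
  if (!is.null(outdir)) {
    readr::write_tsv(report, file.path(outdir, "case_report.tsv"))
    write_vcf_bnd(refined[[study$affected]], study$genome,
                  file.path(outdir, "junctions.vcf"))
  }
  structure(
    list(
      report = report, predictions = preds_raw, filtered = preds_filtered,
      patient_specific = patient_specific, refined = refined,
      concordance = concordance, study = study
    ),
    class = "abt_result"
  )
}

# refine both derivative junctions of one member against the truth-located
# junction windows (simulation mode), with cluster intervals as anchors
refine_member <- function(study, member, preds, window) {
  jx <- study$truth$junctions
  sim <- study$member_sims[[member]]
  g <- study$genome
  ref_one <- function(j) {
    tr <- preds |>
      filter(
        .data$type == "translocation",
        .data$chrom1 == jx$prefix_chrom[j], .data$chrom2 == jx$suffix_chrom[j],
        .data$start1 <= jx$prefix_end[j], .data$end1 >= jx$prefix_end[j]
      )
    if (nrow(tr) == 0) {
      abort(sprintf("no translocation cluster recovered junction %s for %s",
                    jx$junction_id[j], member))
    }
    jseq <- extract_junction_sequence(
      sim$der_genome, jx$junction_id[j], jx$der_junction_pos[j], w = window
    )
    refine_junction(
      jseq, g, jx$prefix_chrom[j], jx$suffix_chrom[j],
      region_a = tibble(chrom = tr$chrom1[1], start = tr$start1[1], end = tr$end1[1]),
      region_b = tibble(chrom = tr$chrom2[1], start = tr$start2[1], end = tr$end2[1])
    ) |>
      mutate(
        sv_id = tr$sv_id[1], support = tr$support[1],
        mps_start = tr$start1[1], mps_end = tr$end1[1]
      )
  }
  der_a <- ref_one(1L)
  der_b <- ref_one(2L)
  rec <- reconcile_derivatives(der_a, der_b, g)
  rec |>
    mutate(
      member = member,
      support = c(der_a$support, der_b$support),
      mps_start = c(der_a$mps_start, der_b$mps_start),
      mps_end = c(der_a$mps_end, der_b$mps_end),
      .before = 1
    )
}

fmt_kb <- function(bp) {
  ifelse(bp < 100000, sprintf("%.1fkb", bp / 1000), sprintf("%.0fkb", bp / 1000))
}

fmt_indel <- function(type, seq) {
  dplyr::case_when(
    type == "deletion" ~ sprintf("%dbp-%s del.", nchar(seq), seq),
    type == "duplication" ~ sprintf("%dbp-%s dupl.", nchar(seq), seq),
    TRUE ~ "—"
  )
}

# assemble the per-member, per-derivative case report
case_report <- function(study, preds_filtered, refined, concordance) {
  g <- study$genome
  rows <- list_rbind(map(study$members, function(m) {
    r <- refined[[m]]
    list_rbind(map(seq_len(nrow(r)), function(i) {
      bp <- tibble(chrom = r$chrom[i], start = r$bp_start[i], end = r$bp_end[i])
      genes <- genes_at_breakpoint(bp, study$tracks$gene_models)
      reps <- repeats_at_breakpoint(bp, study$tracks$repeats)
      mech <- classify_mechanism(r[i, ], g)
      tibble(
        member = m,
        derivative = r$derivative[i],
        mps_junction = format_interval(tibble(
          chrom = r$chrom[i], start = r$mps_start[i], end = r$mps_end[i]
        )),
        junction_length = sprintf(
          "%dbp", r$mps_end[i] - r$mps_start[i] + 1L
        ),
        read_pairs = r$support[i],
        breakpoint = breakpoint_intervals(r[i, ]),
        disrupted_genes = if (nrow(genes) > 0) {
          paste(sprintf("%s (%s %d)", genes$gene, genes$element, genes$index),
                collapse = " & ")
        } else {
          "—"
        },
        indels = fmt_indel(r$indel_type[i], r$indel_seq[i]),
        microhomology = if (nzchar(r$mh[i])) r$mh[i] else "—",
        repeats = if (nrow(reps) > 0) paste(reps$name, collapse = ",") else "—",
        mechanism = mech$mechanism
      )
    }))
  }))
  rows$family_concordance <- concordance$verdict
  class(rows) <- c("abt_case_report", class(rows))
  rows
}

#' @export
glance.abt_result <- function(x, ...) {
  tibble(
    members = length(x$study$members),
    predictions = sum(map_int(x$predictions, nrow)),
    filtered = sum(map_int(x$filtered, nrow)),
    patient_specific = nrow(x$patient_specific),
    junctions_refined = sum(map_int(x$refined, nrow)),
    concordance = x$concordance$verdict
  )
}

#' @export
tidy.abt_result <- function(x, ...) x$report

#' @export
autoplot.abt_result <- function(object, ...) {
  df <- object$report |>
    mutate(width = as.integer(sub("bp$", "", .data$junction_length)))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$derivative, y = .data$width, fill = .data$member
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = NULL, y = "junction interval width (bp)",
      title = "Clustered junction intervals by member"
    ) +
    ggplot2::theme_minimal()
}

#' Write refined junctions as VCF breakend (BND) records
#'
#' Each derivative junction emits two reciprocal BND records with bracket
#' ALT notation; microhomology goes to HOMLEN/HOMSEQ and untemplated
#' insertions into the ALT string.
#'
#' @param refined A `refined_pair` tibble (from [reconcile_derivatives()]
#'   or [refine_member] output).
#' @param g Reference genome.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf_bnd <- function(refined, g, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##ALT=<ID=BND,Description=\"Breakend\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate breakend\">",
    "##INFO=<ID=HOMLEN,Number=1,Type=Integer,Description=\"Microhomology length\">",
    "##INFO=<ID=HOMSEQ,Number=1,Type=String,Description=\"Microhomology sequence\">",
    sprintf("##contig=<ID=%s,length=%d>", names(g), chrom_lengths(g)),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  recs <- character()
  for (i in seq_len(nrow(refined))) {
    r <- refined[i, ]
    pc <- col_or(r, "prefix_chrom", "chrom")
    sc <- col_or(r, "suffix_chrom", "partner_chrom")
    pe <- r$prefix_end
    ss <- col_or(r, "suffix_start", "partner_start")
    ref1 <- genome_seq(g, pc, pe, pe)
    ref2 <- genome_seq(g, sc, ss, ss)
    id1 <- sprintf("bnd_%d_1", i)
    id2 <- sprintf("bnd_%d_2", i)
    info_common <- sprintf(
      "SVTYPE=BND;HOMLEN=%d%s", nchar(r$mh),
      if (nzchar(r$mh)) sprintf(";HOMSEQ=%s", r$mh) else ""
    )
    recs <- c(
      recs,
      sprintf("%s\t%d\t%s\t%s\t%s%s[%s:%d[\t.\tPASS\t%s;MATEID=%s",
              pc, pe, id1, ref1, ref1, r$ins, sc, ss, info_common, id2),
      sprintf("%s\t%d\t%s\t%s\t]%s:%d]%s%s\t.\tPASS\t%s;MATEID=%s",
              sc, ss, id2, ref2, pc, pe, r$ins, ref2, info_common, id1)
    )
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Read breakend VCF records back into a junction tibble
#'
#' A minimal reader for the BND records emitted by [write_vcf_bnd()]:
#' bracket ALT notation is parsed into the partner coordinate and
#' orientation, HOMLEN/HOMSEQ into the microhomology, and any untemplated
#' insertion is recovered from the ALT string.
#'
#' @param path VCF path.
#' @return Tibble: `id`, `chrom`, `pos`, `mate_chrom`, `mate_pos`,
#'   `bracket`, `mh`, `ins`, `mate_id`.
#' @export
read_vcf_bnd <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0) {
    return(tibble(
      id = character(), chrom = character(), pos = integer(),
      mate_chrom = character(), mate_pos = integer(), bracket = character(),
      mh = character(), ins = character(), mate_id = character()
    ))
  }
  f <- stringr::str_split(body, "\t")
  short <- which(lengths(f) < 8L)
  if (length(short) > 0) {
    abort(sprintf("%s: truncated VCF record at line %d",
                  path, which(!startsWith(lines, "#"))[short[1]]))
  }
  parse_one <- function(x) {
    alt <- x[5]
    m <- stringr::str_match(alt, "^(?:([A-Za-z]+))?([\\[\\]])([^:]+):([0-9]+)[\\[\\]](?:([A-Za-z]+))?$")
    if (is.na(m[1, 1])) abort(sprintf("unparseable BND ALT '%s'", alt))
    info <- x[8]
    get_info <- function(key) {
      mm <- stringr::str_match(info, paste0("(?:^|;)", key, "=([^;]*)"))
      mm[1, 2]
    }
    left <- m[1, 2] %||% NA_character_
    right <- m[1, 6] %||% NA_character_
    ref <- x[4]
    ins <- if (!is.na(left) && nchar(left) > nchar(ref)) {
      substr(left, nchar(ref) + 1L, nchar(left))
    } else if (!is.na(right) && nchar(right) > nchar(ref)) {
      substr(right, 1L, nchar(right) - nchar(ref))
    } else {
      ""
    }
    tibble(
      id = x[3], chrom = x[1], pos = as.integer(x[2]),
      mate_chrom = m[1, 4], mate_pos = as.integer(m[1, 5]),
      bracket = m[1, 3],
      mh = get_info("HOMSEQ") %||% NA_character_,
      ins = ins,
      mate_id = get_info("MATEID")
    )
  }
  out <- list_rbind(map(f, parse_one))
  out$mh[is.na(out$mh)] <- ""
  out
}

#' Check a printed junction table for internal consistency
#'
#' Recomputes every junction width from its printed coordinates (1-based,
#' inclusive of both endpoints) and compares it with the printed width,
#' then summarises the widths. The bundled fixture transcribes the
#' 18 junction intervals of the source study's breakpoint table.
#'
#' @param path TSV with columns `family`, `member`, `phenotype`,
#'   `junction` (coordinate text), `junction_length_bp`, `read_pairs`,
#'   `breakpoint`, `disrupted_genes`, `indels`, `microhomology`,
#'   `repeats`; defaults to the bundled fixture.
#' @return List: `table` (with `computed_width` and `consistent` columns),
#'   `summary` (tibble: n, min/max width, max width in kb), `mismatches`.
#' @export
check_junction_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "table1_junctions.tsv",
                                package = "mateSV", mustWork = TRUE)
  tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  iv <- parse_interval(tab$junction)
  tab$computed_width <- interval_width(iv)
  tab$consistent <- tab$computed_width == tab$junction_length_bp
  summary <- tibble(
    n_junctions = nrow(tab),
    min_width_bp = min(tab$computed_width),
    max_width_bp = max(tab$computed_width),
    max_width_kb = round(max(tab$computed_width) / 1000, 1)
  )
  list(
    table = tab, summary = summary,
    mismatches = tab[!tab$consistent, , drop = FALSE]
  )
}

#' Bundled junction-table fixture
#'
#' @return The transcribed junction table as a tibble.
#' @export
junction_table <- function() {
  check_junction_table()$table |> select(-"computed_width", -"consistent")
}

#' Read a pipeline configuration from YAML
#'
#' A single document with optional blocks: `simulation` (fields of
#' [sim_config()]), `members` (names), `affected`, and `filtering`
#' (`min_support`, `overlap_threshold`) / `junction` (`window`) parameters.
#' Absent keys fall back to the package defaults, so an empty file is a
#' valid configuration.
#'
#' @param path YAML file path.
#' @param overrides Named list applied on top of the file (e.g. CLI flags).
#' @return A list with `config` ([sim_config()]), `members`, `affected`,
#'   `min_support`, `overlap_threshold`, `window`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  y <- if (file.exists(path)) yaml::read_yaml(path) else list()
  y <- utils::modifyList(y, overrides)
  sim <- y$simulation %||% list()
  if (!is.null(sim$chrom_lengths)) {
    sim$chrom_lengths <- unlist(sim$chrom_lengths)
  }
  list(
    config = do.call(sim_config, sim),
    members = unlist(y$members %||% c("affected", "relative")),
    affected = y$affected %||% unlist(y$members %||% "affected")[1],
    min_support = y$filtering$min_support %||% 5L,
    overlap_threshold = y$filtering$overlap_threshold %||% 0.8,
    window = y$junction$window %||% 400L
  )
}
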