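# Mate-pair simulator: reference genomes, engineered rearrangements with
# junction micro-features, post-alignment mate-pair records, PCR duplicates,
# multimappers and decoy SVs -- all deterministic under a seed, with full
# ground truth for scoring recovery.

#' Simulation configuration
#'
#' Defaults emulate a long-insert mate-pair experiment: 2-4 kb inserts
#' (truncated normal, mean 3000 bp, sd 400 bp) sequenced as 100 bp paired
#' reads, on a small multi-chromosome stand-in genome.
#'
#' @param seed Integer seed; every stochastic operation derives its stream
#'   from it (keep it below 2^31 - 16).
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param insert_mean,insert_sd,insert_min,insert_max Insert-size
#'   distribution (bp): truncated normal with hard bounds.
#' @param read_length Read length in bp; must be below `insert_min`.
#' @param coverage Physical (fragment) coverage target; the pair count is
#'   `coverage * genome_length / insert_mean` unless `n_pairs` is given.
#'   The default of 20 gives a Poisson expectation of about 19
#'   junction-spanning pairs per translocation junction, the support range
#'   observed for sequenced junctions in long-insert mate-pair studies.
#' @param n_pairs Optional explicit mate-pair count.
#' @param duplicate_rate Fraction of extra PCR-duplicate pairs appended as
#'   exact coordinate copies of already-emitted pairs.
#' @param error_rate Per-base sequencing error rate, applied when junction
#'   sequences are extracted in error-bearing mode; alignment coordinates
#'   stay truthful (post-alignment records are simulated, not raw reads).
#' @param convention Mate orientation convention after alignment:
#'   `"outward"` (fragment-start mate on -, fragment-end mate on +, the
#'   processed mate-pair dialect) or `"inward"` (paired-end style).
#' @param repeat_regions Tibble (`chrom`, `start`, `end`, `motif_length`) of
#'   spans filled with a tiled motif; reads starting inside them are flagged
#'   non-unique with probability `1 - 1/copies`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chrA = 2e6, chrB = 2e6, chrC = 2e6),
                       insert_mean = 3000, insert_sd = 400,
                       insert_min = 2000, insert_max = 4000,
                       read_length = 100L,
                       coverage = 20,
                       n_pairs = NULL,
                       duplicate_rate = 0.05,
                       error_rate = 0.001,
                       convention = c("outward", "inward"),
                       repeat_regions = NULL) {
  convention <- match.arg(convention)
  stopifnot(
    insert_min > 0, insert_min <= insert_mean, insert_mean <= insert_max,
    read_length < insert_min, duplicate_rate >= 0, duplicate_rate < 1,
    error_rate >= 0, error_rate < 1, length(chrom_lengths) >= 1,
    !is.null(names(chrom_lengths))
  )
  if (is.null(repeat_regions)) {
    last <- length(chrom_lengths)
    mid <- floor(chrom_lengths[last] * 0.75)
    repeat_regions <- tibble(
      chrom = names(chrom_lengths)[last],
      start = as.integer(mid), end = as.integer(mid + 4999L),
      motif_length = 300L
    )
  }
  structure(
    list(
      seed = as.integer(seed), chrom_lengths = chrom_lengths,
      insert_mean = insert_mean, insert_sd = insert_sd,
      insert_min = as.integer(insert_min), insert_max = as.integer(insert_max),
      read_length = as.integer(read_length), coverage = coverage,
      n_pairs = n_pairs, duplicate_rate = duplicate_rate,
      error_rate = error_rate, convention = convention,
      repeat_regions = repeat_regions
    ),
    class = "sim_config"
  )
}

# Evaluate expr under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

random_bases <- function(n) {
  rawToChar(as.raw(c(65L, 67L, 71L, 84L)[sample.int(4L, n, replace = TRUE)]))
}

#' Generate a random reference genome
#'
#' Chromosomes are i.i.d. uniform A/C/G/T except for declared repeat
#' regions, which are filled with a tiled random motif so that reads from
#' them multimap.
#'
#' @param config A [sim_config()].
#' @return A genome (`DNAStringSet`).
#' @export
sim_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    seqs <- map_chr(names(config$chrom_lengths), function(nm) {
      random_bases(config$chrom_lengths[[nm]])
    })
    names(seqs) <- names(config$chrom_lengths)
    g <- genome(seqs)
    rr <- config$repeat_regions
    if (!is.null(rr) && nrow(rr) > 0) {
      for (i in seq_len(nrow(rr))) {
        span <- rr$end[i] - rr$start[i] + 1L
        motif <- random_bases(rr$motif_length[i])
        tiled <- strrep(motif, ceiling(span / rr$motif_length[i]))
        g <- genome_replace(g, rr$chrom[i], rr$start[i], substr(tiled, 1L, span))
      }
    }
    g
  })
}

#' Describe a rearrangement to engineer
#'
#' For a reciprocal translocation between `chrom_a` (cut after `pos_a`) and
#' `chrom_b` (cut after `pos_b`), the derivative keeping the `chrom_a`
#' prefix is der(A): `A[1..pos_a] + ins_a + B[b2..]`, and der(B) is
#' `B[1..pos_b] + ins_b + A[a2..]`. `indel_a`/`indel_b` offset the resume
#' points on each original chromosome: positive values delete that many
#' bases (retained on neither derivative), negative values duplicate them
#' (retained on both). `mh_a`/`mh_b` request microhomology at the der(A) /
#' der(B) junction, engineered by rewriting reference bases so the two
#' partner references genuinely share the run. Microhomology and an
#' untemplated insertion are mutually exclusive at one junction.
#'
#' Simple intrachromosomal kinds (`deletion`, `tandem_duplication`,
#' `insertion`) use `chrom_a`, `pos_a` and `span`/`ins_a`.
#'
#' @param kind Rearrangement kind.
#' @param chrom_a,pos_a,chrom_b,pos_b Partner chromosomes and breakpoints
#'   (1-based; `pos` is the last base retained by the prefix-keeping
#'   derivative).
#' @param mh_a,mh_b Requested microhomology lengths (bp) per junction.
#' @param ins_a,ins_b Untemplated insertion sequences per junction.
#' @param indel_a,indel_b Per-chromosome indel: `+k` = k bp deleted,
#'   `-k` = k bp duplicated.
#' @param span Width of a simple deletion/duplication.
#' @return A list of class `rearrangement`.
#' @export
rearrangement <- function(kind = c("reciprocal_translocation", "deletion",
                                   "tandem_duplication", "insertion"),
                          chrom_a, pos_a, chrom_b = NULL, pos_b = NULL,
                          mh_a = 0L, mh_b = 0L, ins_a = "", ins_b = "",
                          indel_a = 0L, indel_b = 0L, span = NULL) {
  kind <- match.arg(kind)
  if (kind == "reciprocal_translocation") {
    stopifnot(!is.null(chrom_b), !is.null(pos_b), chrom_a != chrom_b)
    if (mh_a > 0 && nzchar(ins_a)) {
      abort("microhomology and untemplated insertion are mutually exclusive at the der(A) junction")
    }
    if (mh_b > 0 && nzchar(ins_b)) {
      abort("microhomology and untemplated insertion are mutually exclusive at the der(B) junction")
    }
    stopifnot(mh_a >= 0, mh_b >= 0)
  } else {
    stopifnot(kind == "insertion" || (!is.null(span) && span >= 1))
  }
  structure(
    list(
      kind = kind, chrom_a = chrom_a, pos_a = as.integer(pos_a),
      chrom_b = chrom_b, pos_b = if (!is.null(pos_b)) as.integer(pos_b) else NULL,
      mh_a = as.integer(mh_a), mh_b = as.integer(mh_b),
      ins_a = toupper(ins_a), ins_b = toupper(ins_b),
      indel_a = as.integer(indel_a), indel_b = as.integer(indel_b),
      span = if (!is.null(span)) as.integer(span) else NULL
    ),
    class = "rearrangement"
  )
}

#' Sample a random reciprocal-translocation spec
#'
#' Junction features are drawn uniformly: microhomology 0-10 bp, per-side
#' deletions/duplications 0-10 bp, untemplated insertions 0-10 bp
#' (microhomology and insertion never requested together at one junction).
#'
#' @param g Reference genome.
#' @param seed Integer seed.
#' @param chroms Two chromosome names (defaults to the first two).
#' @param max_feature Maximum feature size in bp.
#' @return A [rearrangement()] spec.
#' @export
sim_random_rearrangement <- function(g, seed, chroms = names(g)[1:2],
                                     max_feature = 10L) {
  with_seed(seed, {
    len <- chrom_lengths(g)
    margin <- 2000L
    pos_a <- sample(seq(margin, len[[chroms[1]]] - margin), 1L)
    pos_b <- sample(seq(margin, len[[chroms[2]]] - margin), 1L)
    feat <- function() sample(0:max_feature, 1L)
    mh_a <- feat(); mh_b <- feat()
    ins_a <- ""; ins_b <- ""
    if (runif(1) < 0.3) { ins_a <- random_bases(sample(1:max_feature, 1L)); mh_a <- 0L }
    if (runif(1) < 0.3) { ins_b <- random_bases(sample(1:max_feature, 1L)); mh_b <- 0L }
    indel <- function() sample(c(0L, 1L, -1L), 1L, prob = c(.3, .5, .2)) * sample(0:max_feature, 1L)
    rearrangement(
      "reciprocal_translocation",
      chrom_a = chroms[1], pos_a = pos_a, chrom_b = chroms[2], pos_b = pos_b,
      mh_a = mh_a, mh_b = mh_b, ins_a = ins_a, ins_b = ins_b,
      indel_a = indel(), indel_b = indel()
    )
  })
}

# Maximal forward / backward extension runs at a junction
# prefix = chrom_p[..p_end], insertion ins, suffix = chrom_s[s_start..].
# fwd: how far the derivative continues to match chrom_p past p_end;
# bwd: how far it matches chrom_s before s_start. Capped at `cap` bp.
junction_extents <- function(g, prefix_chrom, prefix_end, ins,
                             suffix_chrom, suffix_start, cap = 150L) {
  lp <- length(g[[prefix_chrom]])
  ls <- length(g[[suffix_chrom]])
  ins_chars <- if (nzchar(ins)) strsplit(ins, "")[[1]] else character()
  ni <- length(ins_chars)
  der_right <- function(i) { # i-th derivative char after the prefix
    if (i <= ni) return(ins_chars[i])
    p <- suffix_start + (i - ni) - 1L
    if (p > ls) return(NA_character_)
    substr(as.character(Biostrings::subseq(g[[suffix_chrom]], p, p)), 1, 1)
  }
  der_left <- function(i) { # i-th derivative char before the suffix (i >= 1)
    if (i <= ni) return(ins_chars[ni - i + 1L])
    p <- prefix_end - (i - ni) + 1L
    if (p < 1L) return(NA_character_)
    substr(as.character(Biostrings::subseq(g[[prefix_chrom]], p, p)), 1, 1)
  }
  fwd <- 0L
  while (fwd < cap) {
    rp <- prefix_end + fwd + 1L
    if (rp > lp) break
    ref <- substr(as.character(Biostrings::subseq(g[[prefix_chrom]], rp, rp)), 1, 1)
    der <- der_right(fwd + 1L)
    if (is.na(der) || der != ref || der == "N") break
    fwd <- fwd + 1L
  }
  bwd <- 0L
  while (bwd < cap) {
    sp <- suffix_start - bwd - 1L
    if (sp < 1L) break
    ref <- substr(as.character(Biostrings::subseq(g[[suffix_chrom]], sp, sp)), 1, 1)
    der <- der_left(bwd + 1L)
    if (is.na(der) || der != ref || der == "N") break
    bwd <- bwd + 1L
  }
  list(fwd = fwd, bwd = bwd)
}

# Realized junction signature from known coordinates (independent of the
# anchor-search refinement): microhomology / insertion after maximal
# extension, with the canonical maximal prefix end and minimal suffix start.
realized_features <- function(g, prefix_chrom, prefix_end, ins,
                              suffix_chrom, suffix_start) {
  ex <- junction_extents(g, prefix_chrom, prefix_end, ins, suffix_chrom, suffix_start)
  ni <- nchar(ins)
  if (ex$fwd + ex$bwd >= ni) {
    mh_len <- ex$fwd + ex$bwd - ni
    # maximal placements absorb the insertion into the flanks
    pe <- prefix_end + ex$fwd
    ss <- suffix_start - ex$bwd
    mh <- if (mh_len > 0) genome_seq(g, prefix_chrom, pe - mh_len + 1L, pe) else ""
    list(
      mh = mh, ins = "",
      prefix_end_max = pe, suffix_start_min = ss,
      fwd = ex$fwd, bwd = ex$bwd
    )
  } else {
    list(
      mh = "", ins = substr(ins, ex$fwd + 1L, ni - ex$bwd),
      prefix_end_max = prefix_end + ex$fwd,
      suffix_start_min = suffix_start - ex$bwd,
      fwd = ex$fwd, bwd = ex$bwd
    )
  }
}

#' Engineer a rearrangement into a genome
#'
#' Returns the derivative genome together with a full truth record. For a
#' reciprocal translocation the two junctions' microhomology is engineered
#' by rewriting reference bases so both partner references share the run,
#' and junction-adjacent bases are adjusted so that, wherever the requested
#' features are jointly feasible, the realized signature equals the request.
#' The truth record always carries the *realized* feature strings, computed
#' by direct maximal extension at the known engineered coordinates (a
#' balanced junction, for instance, physically shares one microhomology
#' string between its two derivatives, whatever was requested).
#'
#' @param g Reference genome.
#' @param spec A [rearrangement()].
#' @return A list of class `sim_rearranged` with elements `genome` (the
#'   possibly rewritten reference), `der_genome`, `segments` (derivative
#'   segment map), and `truth` (list: `junctions`, `chrom_events`, `spec`,
#'   `engineered_ok`).
#' @export
apply_rearrangement <- function(g, spec) {
  stopifnot(inherits(spec, "rearrangement"))
  if (spec$kind != "reciprocal_translocation") {
    return(apply_simple_sv(g, spec))
  }
  a <- spec$pos_a; b <- spec$pos_b
  len_a <- length(g[[spec$chrom_a]]); len_b <- length(g[[spec$chrom_b]])
  del_a <- max(spec$indel_a, 0L); dup_a <- max(-spec$indel_a, 0L)
  del_b <- max(spec$indel_b, 0L); dup_b <- max(-spec$indel_b, 0L)
  a2 <- a + 1L + del_a - dup_a   # der(B) resumes chrom_a here
  b2 <- b + 1L + del_b - dup_b   # der(A) resumes chrom_b here
  margin <- 200L
  if (a - margin < 1L || a2 + margin > len_a || b - margin < 1L || b2 + margin > len_b ||
      a2 < 1L || b2 < 1L) {
    abort("rearrangement breakpoints or indels infeasible for this genome")
  }
  if (del_a >= a || del_b >= b) abort("deletion longer than flank")

  # engineer microhomology: der(B) first (writes chrom_a), then der(A)
  # (writes chrom_b reading the updated chrom_a)
  if (spec$mh_b > 0) {
    g <- genome_replace(g, spec$chrom_a, a2 - spec$mh_b,
                        genome_seq(g, spec$chrom_b, b - spec$mh_b + 1L, b))
  }
  if (spec$mh_a > 0) {
    g <- genome_replace(g, spec$chrom_b, b2 - spec$mh_a,
                        genome_seq(g, spec$chrom_a, a - spec$mh_a + 1L, a))
  }

  # repair loop: break chance homology extensions so that realized ==
  # requested wherever jointly feasible
  g <- enforce_junction_features(g, spec, a, b, a2, b2)

  ra <- realized_features(g, spec$chrom_a, a, spec$ins_a, spec$chrom_b, b2)
  rb <- realized_features(g, spec$chrom_b, b, spec$ins_b, spec$chrom_a, a2)
  # engineered_ok certifies that the realized signature equals the request
  # at the engineered placement (features can shift or be absorbed when
  # the two junction regions physically overlap; truth then records the
  # realized equivalent reading of the same derivative sequences)
  engineered_ok <- (nchar(ra$mh) == spec$mh_a) && (ra$ins == spec$ins_a) &&
    (nchar(rb$mh) == spec$mh_b) && (rb$ins == spec$ins_b) &&
    ra$prefix_end_max == a && ra$suffix_start_min == b2 - nchar(ra$mh) &&
    rb$prefix_end_max == b && rb$suffix_start_min == a2 - nchar(rb$mh)

  der_a <- paste0("der(", spec$chrom_a, ")")
  der_b <- paste0("der(", spec$chrom_b, ")")
  segments <- bind_rows(
    tibble(
      der = der_a, idx = 1:3,
      src_chrom = c(spec$chrom_a, NA, spec$chrom_b),
      src_start = c(1L, NA, b2), src_end = c(a, NA, len_b),
      ins_seq = c(NA, if (nzchar(spec$ins_a)) spec$ins_a else NA, NA)
    ),
    tibble(
      der = der_b, idx = 1:3,
      src_chrom = c(spec$chrom_b, NA, spec$chrom_a),
      src_start = c(1L, NA, a2), src_end = c(b, NA, len_a),
      ins_seq = c(NA, if (nzchar(spec$ins_b)) spec$ins_b else NA, NA)
    )
  ) |>
    filter(!(is.na(.data$src_chrom) & is.na(.data$ins_seq))) |>
    passthrough_segments(g, exclude = c(spec$chrom_a, spec$chrom_b)) |>
    finalize_segments()

  junctions <- tibble(
    junction_id = c(der_a, der_b),
    prefix_chrom = c(spec$chrom_a, spec$chrom_b),
    prefix_end = c(a, b),
    suffix_chrom = c(spec$chrom_b, spec$chrom_a),
    suffix_start = c(b2, a2),
    ins_requested = c(spec$ins_a, spec$ins_b),
    mh_requested = c(spec$mh_a, spec$mh_b),
    mh = c(ra$mh, rb$mh),
    ins = c(ra$ins, rb$ins),
    prefix_end_max = c(ra$prefix_end_max, rb$prefix_end_max),
    suffix_start_min = c(ra$suffix_start_min, rb$suffix_start_min),
    der_junction_pos = c(a, b) # last prefix base, derivative coordinates
  )
  # per-chromosome indels from the *realized* extents, via the same
  # placement-free arithmetic the reconciliation step defines
  sig_a <- chrom_signature(
    g, spec$chrom_a,
    last_hi = ra$prefix_end_max, mh_last = nchar(ra$mh),
    first_lo = rb$suffix_start_min, mh_first = nchar(rb$mh)
  )
  sig_b <- chrom_signature(
    g, spec$chrom_b,
    last_hi = rb$prefix_end_max, mh_last = nchar(rb$mh),
    first_lo = ra$suffix_start_min, mh_first = nchar(ra$mh)
  )
  chrom_events <- tibble(
    chrom = c(spec$chrom_a, spec$chrom_b),
    indel_requested = c(spec$indel_a, spec$indel_b),
    indel_type = c(sig_a$type, sig_b$type),
    indel_seq = c(sig_a$seq, sig_b$seq),
    bp_start = as.integer(c(sig_a$bp[1], sig_b$bp[1])),
    bp_end = as.integer(c(sig_a$bp[2], sig_b$bp[2]))
  )
  der_genome <- build_der_genome(g, segments)
  structure(
    list(
      genome = g, der_genome = der_genome, segments = segments,
      truth = list(
        junctions = junctions, chrom_events = chrom_events,
        spec = spec, engineered_ok = engineered_ok
      )
    ),
    class = "sim_rearranged"
  )
}

# Iteratively mutate junction-adjacent reference bases so the realized
# signature equals the requested one (up to `iter` attempts; infeasible
# requests -- e.g. conflicting microhomology at a balanced junction -- are
# left as realized).
enforce_junction_features <- function(g, spec, a, b, a2, b2, iter = 40L) {
  # deterministic choice keeps apply_rearrangement free of RNG
  alt_base <- function(avoid) setdiff(c("A", "C", "G", "T"), avoid)[1]
  for (k in seq_len(iter)) {
    ra <- realized_features(g, spec$chrom_a, a, spec$ins_a, spec$chrom_b, b2)
    rb <- realized_features(g, spec$chrom_b, b, spec$ins_b, spec$chrom_a, a2)
    ok_a <- nchar(ra$mh) == spec$mh_a && ra$ins == spec$ins_a
    ok_b <- nchar(rb$mh) == spec$mh_b && rb$ins == spec$ins_b
    if (ok_a && ok_b) break
    # Break an unwanted extension by mutating a base that belongs only to
    # this junction's immediate flank (never inside an engineered
    # microhomology source/target), so the fix cannot undo the other
    # junction's features unless the two junctions physically overlap.
    fix <- function(r, pc, pe, ins, sc, ss, mh_req) {
      ni <- nchar(ins)
      if (ni > 0) {
        # break absorption of the insertion into either flank
        if (r$fwd > 0) {
          return(list(chrom = pc, pos = pe + 1L, avoid = substr(ins, 1L, 1L)))
        }
        return(list(chrom = sc, pos = ss - 1L, avoid = substr(ins, ni, ni)))
      }
      if (r$fwd > 0) {
        # forward extension: the first retained suffix base matches the
        # prefix chromosome's continuation
        return(list(chrom = sc, pos = ss,
                    avoid = genome_seq(g, pc, pe + 1L, pe + 1L)))
      }
      # backward extension past the requested run: the prefix base just
      # before the run matches the suffix chromosome
      list(chrom = pc, pos = pe - mh_req,
           avoid = genome_seq(g, sc, ss - mh_req - 1L, ss - mh_req - 1L))
    }
    tgt <- if (!ok_a) {
      fix(ra, spec$chrom_a, a, spec$ins_a, spec$chrom_b, b2, spec$mh_a)
    } else {
      fix(rb, spec$chrom_b, b, spec$ins_b, spec$chrom_a, a2, spec$mh_b)
    }
    if (tgt$pos < 1L || tgt$pos > length(g[[tgt$chrom]])) break
    g <- genome_replace(g, tgt$chrom, tgt$pos, alt_base(tgt$avoid))
  }
  g
}

apply_simple_sv <- function(g, spec) {
  len <- length(g[[spec$chrom_a]])
  p <- spec$pos_a
  segs <- switch(spec$kind,
    deletion = tibble(
      der = spec$chrom_a, idx = 1:2, src_chrom = spec$chrom_a,
      src_start = c(1L, p + spec$span), src_end = c(p - 1L, len),
      ins_seq = NA_character_
    ),
    tandem_duplication = tibble(
      der = spec$chrom_a, idx = 1:3, src_chrom = spec$chrom_a,
      src_start = c(1L, p, p + spec$span), src_end = c(p + spec$span - 1L, p + spec$span - 1L, len),
      ins_seq = NA_character_
    ),
    insertion = tibble(
      der = spec$chrom_a, idx = 1:3,
      src_chrom = c(spec$chrom_a, NA, spec$chrom_a),
      src_start = c(1L, NA, p + 1L), src_end = c(p, NA, len),
      ins_seq = c(NA, spec$ins_a, NA)
    )
  )
  segs <- segs |>
    passthrough_segments(g, exclude = spec$chrom_a) |>
    finalize_segments()
  structure(
    list(
      genome = g, der_genome = build_der_genome(g, segs), segments = segs,
      truth = list(
        junctions = tibble(), chrom_events = tibble(), spec = spec,
        engineered_ok = TRUE
      )
    ),
    class = "sim_rearranged"
  )
}

passthrough_segments <- function(segs, g, exclude) {
  others <- setdiff(names(g), exclude)
  bind_rows(
    segs,
    tibble(
      der = others, idx = 1L, src_chrom = others, src_start = 1L,
      src_end = as.integer(chrom_lengths(g)[others]), ins_seq = NA_character_
    )
  )
}

finalize_segments <- function(segs) {
  segs |>
    mutate(width = if_else(
      is.na(.data$src_chrom), nchar(.data$ins_seq),
      .data$src_end - .data$src_start + 1L
    )) |>
    group_by(.data$der) |>
    arrange(.data$idx, .by_group = TRUE) |>
    mutate(
      der_end = cumsum(.data$width),
      der_start = .data$der_end - .data$width + 1L
    ) |>
    ungroup()
}

build_der_genome <- function(g, segments) {
  ders <- unique(segments$der)
  seqs <- map_chr(ders, function(d) {
    s <- segments[segments$der == d, ]
    paste(map_chr(seq_len(nrow(s)), function(i) {
      if (is.na(s$src_chrom[i])) s$ins_seq[i]
      else genome_seq(g, s$src_chrom[i], s$src_start[i], s$src_end[i])
    }), collapse = "")
  })
  genome(setNames(seqs, ders))
}

#' Apply several rearrangements to one genome
#'
#' The reciprocal translocation (at most one) is applied first; simple
#' intrachromosomal events (any number per chromosome, non-overlapping)
#' are then layered onto the untouched chromosomes.
#'
#' @param g Reference genome.
#' @param specs List of [rearrangement()] specs.
#' @return A `sim_rearranged` list; `truth$decoys` collects the simple
#'   events as an interval tibble.
#' @export
apply_rearrangements <- function(g, specs) {
  kinds <- map_chr(specs, "kind")
  stopifnot(sum(kinds == "reciprocal_translocation") <= 1)
  tr <- specs[kinds == "reciprocal_translocation"]
  simple <- specs[kinds != "reciprocal_translocation"]
  if (length(simple) > 0 && length(tr) == 1) {
    touched <- map_chr(simple, "chrom_a")
    stopifnot(!any(touched %in% c(tr[[1]]$chrom_a, tr[[1]]$chrom_b)))
  }
  out <- if (length(tr) == 1) apply_rearrangement(g, tr[[1]]) else {
    structure(
      list(
        genome = g, der_genome = g,
        segments = passthrough_segments(tibble(), g, exclude = character()) |>
          finalize_segments(),
        truth = list(junctions = tibble(), chrom_events = tibble(),
                     spec = NULL, engineered_ok = TRUE)
      ),
      class = "sim_rearranged"
    )
  }
  decoys <- list()
  by_chrom <- split(simple, map_chr(simple, "chrom_a"))
  for (chrom in names(by_chrom)) {
    segs <- simple_sv_segments(out$genome, chrom, by_chrom[[chrom]])
    out$segments <- out$segments |>
      filter(.data$der != chrom) |>
      bind_rows(segs)
    decoys[[length(decoys) + 1L]] <- list_rbind(map(by_chrom[[chrom]], function(sp) {
      tibble(
        chrom = sp$chrom_a,
        start = sp$pos_a,
        end = sp$pos_a + (sp$span %||% nchar(sp$ins_a)) - 1L,
        type = sp$kind
      )
    }))
  }
  out$segments <- finalize_segments(
    out$segments |> select(-dplyr::any_of(c("width", "der_start", "der_end")))
  )
  out$der_genome <- build_der_genome(out$genome, out$segments)
  out$truth$decoys <- if (length(decoys)) bind_rows(decoys) else
    tibble(chrom = character(), start = integer(), end = integer(), type = character())
  out
}

# segment map for several non-overlapping simple SVs on one chromosome
simple_sv_segments <- function(g, chrom, specs) {
  specs <- specs[order(map_int(specs, "pos_a"))]
  len <- length(g[[chrom]])
  cursor <- 1L
  rows <- list()
  emit <- function(s, e, ins = NA_character_) {
    rows[[length(rows) + 1L]] <<- tibble(
      der = chrom, idx = length(rows) + 1L,
      src_chrom = if (is.na(ins)) chrom else NA_character_,
      src_start = if (is.na(ins)) as.integer(s) else NA_integer_,
      src_end = if (is.na(ins)) as.integer(e) else NA_integer_,
      ins_seq = ins
    )
  }
  for (sp in specs) {
    p <- sp$pos_a
    if (p < cursor + 1L) abort("overlapping simple rearrangements on one chromosome")
    if (sp$kind == "deletion") {
      emit(cursor, p - 1L)
      cursor <- p + sp$span
    } else if (sp$kind == "tandem_duplication") {
      emit(cursor, p + sp$span - 1L)
      emit(p, p + sp$span - 1L)
      cursor <- p + sp$span
    } else { # insertion after p
      emit(cursor, p)
      emit(NA, NA, ins = sp$ins_a)
      cursor <- p + 1L
    }
    if (cursor > len) abort("simple rearrangement extends past chromosome end")
  }
  emit(cursor, len)
  bind_rows(rows)
}

#' Simulate aligned mate-pairs from a (derivative) genome
#'
#' Fragments are drawn uniformly over the derivative genome with truncated
#' normal insert sizes, and each yields one post-alignment mate-pair record
#' against the *reference*: fragments wholly inside one reference segment
#' give concordant pairs, fragments spanning a derivative junction give
#' interchromosomal (or distance-anomalous) pairs. Reads whose alignment
#' would cross a junction are clipped away by the aligner and are not
#' emitted. PCR duplicates are exact coordinate copies appended at the end;
#' reads starting in a repeat span are flagged non-unique with probability
#' `1 - 1/copies` of the motif.
#'
#' @param sim A `sim_rearranged` object (or a plain genome for a
#'   rearrangement-free run).
#' @param config A [sim_config()].
#' @param seed Optional seed override (defaults to `config$seed + 2`).
#' @return List with `pairs` (aligned-pair tibble) and `origin` (per-pair
#'   fragment truth: derivative chromosome, fragment start, insert size,
#'   spanned junction id or `NA`, duplicate-of id or `NA`).
#' @export
sim_mate_pairs <- function(sim, config, seed = NULL) {
  if (methods::is(sim, "DNAStringSet")) {
    sim <- apply_rearrangements(sim, list())
  }
  stopifnot(inherits(sim, "sim_rearranged"), inherits(config, "sim_config"))
  seed <- seed %||% (config$seed + 2L)
  segments <- sim$segments
  der_len <- segments |>
    group_by(.data$der) |>
    summarise(len = max(.data$der_end), .groups = "drop")
  r <- config$read_length
  n <- config$n_pairs %||% round(config$coverage * sum(der_len$len) / config$insert_mean)
  with_seed(seed, {
    ins <- rtruncnorm(n, config$insert_mean, config$insert_sd,
                      config$insert_min, config$insert_max)
    der <- sample(der_len$der, n, replace = TRUE,
                  prob = der_len$len / sum(der_len$len))
    len_of <- setNames(der_len$len, der_len$der)
    start <- 1L + floor(runif(n) * (len_of[der] - ins + 1L))
    m1 <- map_read(segments, der, start, r)
    m2 <- map_read(segments, der, start + ins - r, r)
    keep <- !is.na(m1$chrom) & !is.na(m2$chrom)
    junction <- spanned_junction(sim, der, m1$seg_idx, m2$seg_idx)
    s_start <- if (config$convention == "outward") "-" else "+"
    s_end <- if (config$convention == "outward") "+" else "-"
    pairs <- tibble(
      pair_id = seq_len(n),
      chrom1 = m1$chrom, pos1 = m1$pos, strand1 = s_start,
      unique1 = TRUE,
      chrom2 = m2$chrom, pos2 = m2$pos, strand2 = s_end,
      unique2 = TRUE,
      insert_size = NA_integer_
    )
    same <- !is.na(pairs$chrom1) & !is.na(pairs$chrom2) & pairs$chrom1 == pairs$chrom2
    pairs$insert_size[same] <- as.integer(
      pmax(pairs$pos1[same], pairs$pos2[same]) + r - 1L -
        pmin(pairs$pos1[same], pairs$pos2[same]) + 1L
    )
    origin <- tibble(
      pair_id = seq_len(n), der = der, frag_start = as.integer(start),
      insert = as.integer(ins), junction_id = junction,
      duplicate_of = NA_integer_
    )
    pairs <- pairs[keep, ]
    origin <- origin[keep, ]
    # multimapping flags from repeat spans (on reference coordinates)
    pairs$unique1 <- !nonunique_flag(pairs$chrom1, pairs$pos1, r, config)
    pairs$unique2 <- !nonunique_flag(pairs$chrom2, pairs$pos2, r, config)
    # PCR duplicates: exact copies of already-emitted pairs
    n_dup <- round(config$duplicate_rate * nrow(pairs))
    if (n_dup > 0) {
      src <- sample.int(nrow(pairs), n_dup, replace = TRUE)
      dup <- pairs[src, ]
      dup$pair_id <- max(pairs$pair_id) + seq_len(n_dup)
      dup_origin <- origin[src, ]
      dup_origin$duplicate_of <- origin$pair_id[src]
      dup_origin$pair_id <- dup$pair_id
      pairs <- bind_rows(pairs, dup)
      origin <- bind_rows(origin, dup_origin)
    }
    list(pairs = pairs, origin = origin)
  })
}

rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  round(out[seq_len(n)])
}

# Map reads (der, pos, len) to reference coordinates through the segment
# map; reads crossing a segment boundary or inside an untemplated insertion
# map to NA.
map_read <- function(segments, der, pos, len) {
  n <- length(der)
  chrom <- rep(NA_character_, n)
  out_pos <- rep(NA_integer_, n)
  seg_idx <- rep(NA_integer_, n)
  for (d in unique(der)) {
    s <- segments[segments$der == d, ]
    i <- which(der == d)
    k <- findInterval(pos[i], s$der_start)
    ok <- k >= 1 & (pos[i] + len - 1L) <= s$der_end[k]
    src <- !is.na(s$src_chrom[k]) & ok
    sel <- i[src]
    ksel <- k[src]
    chrom[sel] <- s$src_chrom[ksel]
    out_pos[sel] <- as.integer(s$src_start[ksel] + (pos[sel] - s$der_start[ksel]))
    seg_idx[sel] <- s$idx[ksel]
  }
  list(chrom = chrom, pos = out_pos, seg_idx = seg_idx)
}

# junction id when the two reads flank a translocation junction
spanned_junction <- function(sim, der, seg1, seg2) {
  out <- rep(NA_character_, length(der))
  jx <- sim$truth$junctions
  if (nrow(jx) == 0) return(out)
  for (j in seq_len(nrow(jx))) {
    d <- jx$junction_id[j]
    hit <- !is.na(seg1) & !is.na(seg2) & der == d & seg1 != seg2
    out[hit] <- d
  }
  out
}

nonunique_flag <- function(chrom, pos, r, config) {
  rr <- config$repeat_regions
  flag <- rep(FALSE, length(chrom))
  if (is.null(rr) || nrow(rr) == 0) return(flag)
  for (i in seq_len(nrow(rr))) {
    copies <- max(1, floor((rr$end[i] - rr$start[i] + 1L) / rr$motif_length[i]))
    inside <- !is.na(chrom) & chrom == rr$chrom[i] &
      pos >= rr$start[i] & (pos + r - 1L) <= rr$end[i]
    flag[inside] <- flag[inside] | (runif(sum(inside)) < 1 - 1 / copies)
  }
  flag
}

#' Build a known-SV catalogue covering a subset of decoys
#'
#' Mirrors a common-variant catalogue: every decoy flagged `common` gets a
#' catalogue record overlapping it by at least 80% (the record is the decoy
#' interval padded by 5% per side), private decoys get none, and no record
#' touches the engineered translocation junctions.
#'
#' @param decoys Decoy tibble (`chrom`, `start`, `end`, `type`) as produced
#'   by [apply_rearrangements()].
#' @param common Logical vector: which decoys are in the catalogue.
#' @return A feature tibble (BED-compatible; `name` = SV type).
#' @export
sim_known_catalogue <- function(decoys, common) {
  stopifnot(nrow(decoys) == length(common))
  x <- decoys[common, , drop = FALSE]
  if (nrow(x) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), score = double(), strand = character()))
  }
  pad <- pmax(1L, round(0.05 * (x$end - x$start + 1L)))
  tibble(
    chrom = x$chrom,
    start = pmax(1L, x$start - pad),
    end = x$end + pad,
    name = x$type,
    score = 0, strand = "*"
  )
}
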