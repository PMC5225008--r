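# Nucleotide-level junction refinement: split alignment of a
# junction-spanning sequence against the two partner references, an
# in-silico stand-in for PCR + Sanger sequencing across the junction.

# column fallback: refined_pair rows name the prefix-side columns
# chrom/partner_*, raw refine_junction() rows prefix_*/suffix_*
col_or <- function(x, a, b) if (a %in% names(x)) x[[a]] else x[[b]]

#' Extract a junction-spanning sequence from a derivative genome
#'
#' Returns `w` bases centred on the junction (the last base of the prefix
#' segment), the in-silico analogue of a junction-spanning amplicon.
#' Windows reaching past a chromosome end are truncated with a warning.
#'
#' @param der_genome Derivative genome (`DNAStringSet`).
#' @param der_chrom Derivative chromosome name.
#' @param center Junction position in derivative coordinates (last prefix
#'   base); for simulated data this is `truth$junctions$der_junction_pos`.
#' @param w Window width in bp (default 400); choose at least twice the
#'   largest expected junction feature plus anchor margin.
#' @param error_rate Per-base substitution rate applied to the extracted
#'   sequence (emulates sequencing error; default 0).
#' @return Character scalar of length <= `w`.
#' @export
extract_junction_sequence <- function(der_genome, der_chrom, center, w = 400L,
                                      error_rate = 0) {
  len <- length(der_genome[[der_chrom]])
  half <- w %/% 2L
  start <- center - half + 1L
  end <- center + (w - half)
  if (start < 1L || end > len) {
    warn("junction window exceeds chromosome; truncating")
    start <- max(1L, start)
    end <- min(len, end)
  }
  s <- as.character(Biostrings::subseq(der_genome[[der_chrom]], start, end))
  if (error_rate > 0) {
    ch <- strsplit(s, "")[[1]]
    hit <- which(runif(length(ch)) < error_rate)
    for (i in hit) ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[sample.int(3L, 1L)]
    s <- paste(ch, collapse = "")
  }
  s
}

# vectorized maximal extension with optional mismatch tolerance:
# longest prefix of `x` matching `y` such that the run ends on a match and
# carries at most floor(len * rate) mismatches (N never matches anything)
max_match_run <- function(x, y, rate = 0) {
  n <- min(length(x), length(y))
  if (n == 0) return(0L)
  x <- x[seq_len(n)]; y <- y[seq_len(n)]
  neq <- x != y | x == 78L | y == 78L # 78 = "N"
  mm <- cumsum(neq)
  ok <- which(!neq & mm <= floor(seq_len(n) * rate))
  if (length(ok) == 0) 0L else max(ok)
}

#' Refine a junction sequence to base-pair breakpoints
#'
#' Anchors the start of the junction sequence on the first partner
#' reference and its end on the second, extends both alignments maximally,
#' and decomposes the junction: when the two alignments overlap, the
#' overlap is microhomology (the breakpoint is ambiguous over
#' `microhomology + 1` placements and is reported at its maximal prefix
#' extension together with the ambiguity); when they leave a gap, the gap
#' is an untemplated insertion; when they abut, the junction is blunt.
#'
#' Only the derivative orientation joining a prefix of `chrom_a` to a
#' suffix of `chrom_b` (both plus strand) is modelled; inverted junctions
#' are out of scope.
#'
#' @param jseq Junction-spanning sequence (character).
#' @param g Reference genome.
#' @param chrom_a Partner supplying the junction prefix.
#' @param chrom_b Partner supplying the junction suffix.
#' @param region_a,region_b Optional interval tibbles restricting the
#'   anchor search (e.g. the clustered junction intervals); the whole
#'   chromosome is searched when absent.
#' @param anchor Anchor length in bp (default 20); the first/last `anchor`
#'   bases must match their partner uniquely.
#' @param mismatch_rate Allowed mismatches per bp during extension
#'   (default 0 = exact; use 1/50 for error-bearing sequences).
#' @return One-row tibble: `prefix_chrom`, `prefix_end` (rightmost
#'   admissible last retained base), `suffix_chrom`, `suffix_start`
#'   (leftmost admissible first retained base), `mh`, `ins`, `ambiguity`
#'   (= microhomology length + 1).
#' @export
refine_junction <- function(jseq, g, chrom_a, chrom_b,
                            region_a = NULL, region_b = NULL,
                            anchor = 20L, mismatch_rate = 0) {
  n <- nchar(jseq)
  stopifnot(n >= 2L * anchor)
  jint <- utf8ToInt(jseq)

  find_anchor <- function(chrom, pat, region) {
    subject <- g[[chrom]]
    off <- 0L
    if (!is.null(region)) {
      pad <- n + 50L
      lo <- max(1L, region$start[1] - pad)
      hi <- min(length(subject), region$end[1] + pad)
      subject <- Biostrings::subseq(subject, lo, hi)
      off <- lo - 1L
    }
    m <- Biostrings::matchPattern(pat, subject)
    st <- BiocGenerics::start(m)
    if (length(st) == 0) {
      abort(sprintf("unanchored junction: no match for anchor on %s", chrom))
    }
    if (length(st) > 1) {
      abort(sprintf("unanchored junction: anchor matches %s %d times", chrom, length(st)))
    }
    st + off
  }

  xa <- find_anchor(chrom_a, substr(jseq, 1L, anchor), region_a)
  yb <- find_anchor(chrom_b, substr(jseq, n - anchor + 1L, n), region_b)
  ya_end <- yb + anchor - 1L # rightmost matched base on chrom_b

  ref_a <- utf8ToInt(genome_seq(
    g, chrom_a, xa, min(length(g[[chrom_a]]), xa + n - 1L)
  ))
  L <- anchor + max_match_run(
    jint[(anchor + 1L):n], ref_a[(anchor + 1L):length(ref_a)], mismatch_rate
  )
  ref_b <- utf8ToInt(genome_seq(
    g, chrom_b, max(1L, ya_end - n + 1L), ya_end
  ))
  R <- anchor + max_match_run(
    rev(jint[1:(n - anchor)]), rev(ref_b[1:(length(ref_b) - anchor)]), mismatch_rate
  )

  if (L + R >= n) {
    mh_len <- L + R - n
    mh <- if (mh_len > 0) substr(jseq, n - R + 1L, L) else ""
    ins <- ""
  } else {
    mh <- ""
    ins <- substr(jseq, L + 1L, n - R)
  }
  tibble(
    prefix_chrom = chrom_a,
    prefix_end = as.integer(xa + L - 1L),
    suffix_chrom = chrom_b,
    suffix_start = as.integer(ya_end - R + 1L),
    mh = mh, ins = ins,
    ambiguity = nchar(mh) + 1L
  )
}

#' Reconcile the two refined junctions of a reciprocal translocation
#'
#' Combines der(A) and der(B) refinements to characterize each original
#' chromosome. Each junction's breakpoint is fixed at its canonical
#' placement (maximal prefix extension, with the resume point coupled to
#' it); reference bases between the two canonical breakpoints are a
#' deletion, bases retained by both canonical retentions are a duplication
#' (cross-derivative evidence, which is what distinguishes a duplication
#' from single-junction microhomology), and a balanced adjacency yields
#' neither -- microhomology is reported separately and never shortens an
#' indel. Indel strings are read from the reference plus strand. The
#' per-chromosome breakpoint interval spans from the last base retained by
#' one derivative to the first base retained by the other (so a k bp
#' deletion prints a k+2 bp interval, a balanced junction a 2 bp interval,
#' and a k bp duplication the k bp duplicated span) -- the convention of
#' nucleotide-level junction tables.
#'
#' @param der_a,der_b One-row refinement tibbles from [refine_junction()]
#'   for the two derivatives; `der_a`'s prefix chromosome must be `der_b`'s
#'   suffix chromosome and vice versa.
#' @param g Reference genome.
#' @return A tibble of class `refined_pair` with one row per derivative:
#'   junction signature (`mh`, `ins`), and for the derivative's prefix
#'   chromosome the indel call (`indel_type`, `indel_seq`) and breakpoint
#'   interval (`bp_start`, `bp_end`).
#' @export
reconcile_derivatives <- function(der_a, der_b, g) {
  if (!identical(der_a$prefix_chrom, der_b$suffix_chrom) ||
      !identical(der_b$prefix_chrom, der_a$suffix_chrom)) {
    abort("derivative junctions do not reference the same chromosome pair")
  }
  one_chrom <- function(prefix_j, suffix_j) {
    chrom_signature(
      g, prefix_j$prefix_chrom,
      last_hi = prefix_j$prefix_end, mh_last = nchar(prefix_j$mh),
      first_lo = suffix_j$suffix_start, mh_first = nchar(suffix_j$mh)
    )
  }
  ca <- one_chrom(der_a, der_b) # chromosome supplying der(A)'s prefix
  cb <- one_chrom(der_b, der_a)
  out <- tibble(
    derivative = paste0("der(", c(der_a$prefix_chrom, der_b$prefix_chrom), ")"),
    chrom = c(der_a$prefix_chrom, der_b$prefix_chrom),
    prefix_end = c(der_a$prefix_end, der_b$prefix_end),
    partner_chrom = c(der_a$suffix_chrom, der_b$suffix_chrom),
    partner_start = c(der_a$suffix_start, der_b$suffix_start),
    mh = c(der_a$mh, der_b$mh),
    ins = c(der_a$ins, der_b$ins),
    indel_type = c(ca$type, cb$type),
    indel_seq = c(ca$seq, cb$seq),
    bp_start = as.integer(c(ca$bp[1], cb$bp[1])),
    bp_end = as.integer(c(ca$bp[2], cb$bp[2]))
  )
  class(out) <- c("refined_pair", class(out))
  out
}

# Per-chromosome reconciliation arithmetic shared by the analysis path and
# the simulator truth record. Each junction's breakpoint is taken at its
# canonical placement -- the maximal prefix extension, with the coupled
# resume point `suffix_start_min + mh_first` (microhomology slides both
# sides of one junction together, so the canonical resume sits mh bases
# right of the leftmost admissible one). Bases between the two canonical
# breakpoints are a deletion, bases retained by both canonical retentions
# are a duplication; microhomology is reported separately and never
# shortens an indel. This reproduces printed junction-table widths:
# deletion k -> interval k + 2, balanced -> 2, duplication k -> k.
chrom_signature <- function(g, chrom, last_hi, mh_last, first_lo, mh_first) {
  last <- last_hi                 # canonical last retained base
  first <- first_lo + mh_first    # canonical first resumed base
  if (first > last + 1L) {
    list(type = "deletion",
         seq = genome_seq(g, chrom, last + 1L, first - 1L),
         bp = c(last, first))
  } else if (first <= last) {
    list(type = "duplication",
         seq = genome_seq(g, chrom, first, last),
         bp = c(first, last))
  } else {
    list(type = "none", seq = "", bp = c(last, last + 1L))
  }
}

#' Format per-chromosome breakpoint intervals
#'
#' @param x A `refined_pair` tibble from [reconcile_derivatives()].
#' @param dash Coordinate separator.
#' @return Character vector like `"chr1:18163344–18163348"`, one per row.
#' @export
breakpoint_intervals <- function(x, dash = "–") {
  format_interval(
    tibble(chrom = x$chrom, start = x$bp_start, end = x$bp_end),
    dash = dash
  )
}

#' Compare refined junctions across family members
#'
#' The verdict is `identical` only when breakpoints, microhomology,
#' insertion and indel strings all match exactly between every member;
#' otherwise every differing field is enumerated.
#'
#' @param refined_by_member Named list of `refined_pair` tibbles (one per
#'   member, same derivatives).
#' @return A list of class `concordance_report`: `verdict` (`"identical"`
#'   or `"discordant"`), `diffs` (tibble member/derivative/field/value/
#'   reference value), `members`.
#' @export
compare_family <- function(refined_by_member) {
  stopifnot(length(refined_by_member) >= 2, !is.null(names(refined_by_member)))
  ref_member <- names(refined_by_member)[1]
  ref <- refined_by_member[[ref_member]]
  fields <- c("bp_start", "bp_end", "mh", "ins", "indel_type", "indel_seq")
  diffs <- list()
  for (m in names(refined_by_member)[-1]) {
    x <- refined_by_member[[m]]
    missing_der <- setdiff(ref$derivative, x$derivative)
    if (length(missing_der) > 0) {
      abort(sprintf("member '%s' is missing junction %s", m, missing_der[1]))
    }
    x <- x[match(ref$derivative, x$derivative), ]
    for (f in fields) {
      ne <- which(as.character(x[[f]]) != as.character(ref[[f]]))
      if (length(ne) > 0) {
        diffs[[length(diffs) + 1L]] <- tibble(
          member = m, derivative = ref$derivative[ne], field = f,
          value = as.character(x[[f]][ne]),
          reference = as.character(ref[[f]][ne])
        )
      }
    }
  }
  diffs <- if (length(diffs)) bind_rows(diffs) else
    tibble(member = character(), derivative = character(), field = character(),
           value = character(), reference = character())
  structure(
    list(
      verdict = if (nrow(diffs) == 0) "identical" else "discordant",
      diffs = diffs, members = names(refined_by_member)
    ),
    class = "concordance_report"
  )
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("Family concordance:", x$verdict, "\n")
  cat("Members:", paste(x$members, collapse = ", "), "\n")
  if (nrow(x$diffs) > 0) print(x$diffs)
  invisible(x)
}

#' Render a junction in the three-line style of breakpoint figures
#'
#' Top and bottom lines are the two partner references around the
#' breakpoints, the middle line is the junction sequence. Microhomology is
#' bracketed, untemplated insertions are lower case.
#'
#' @param refined One row of a `refined_pair` (or [refine_junction()])
#'   tibble.
#' @param g Reference genome.
#' @param flank Reference flank length shown on each side (default 30).
#' @return Character vector of three display lines.
#' @export
format_junction <- function(refined, g, flank = 30L) {
  pc <- col_or(refined, "prefix_chrom", "chrom")
  sc <- col_or(refined, "suffix_chrom", "partner_chrom")
  pe <- refined$prefix_end
  ss <- col_or(refined, "suffix_start", "partner_start")
  mh <- refined$mh
  ins <- refined$ins
  top <- genome_seq(g, pc, max(1L, pe - flank + 1L), min(length(g[[pc]]), pe + flank), clip = TRUE)
  bot <- genome_seq(g, sc, max(1L, ss - flank), min(length(g[[sc]]), ss + flank - 1L), clip = TRUE)
  left <- genome_seq(g, pc, max(1L, pe - flank + 1L), pe)
  right <- genome_seq(g, sc, ss, min(length(g[[sc]]), ss + flank - 1L))
  mid <- if (nzchar(mh)) {
    paste0(substr(left, 1L, nchar(left) - nchar(mh)), "[", mh, "]",
           substr(right, nchar(mh) + 1L, nchar(right)))
  } else {
    paste0(left, tolower(ins), right)
  }
  c(
    sprintf("%s  %s", top, pc),
    sprintf("%s  junction", mid),
    sprintf("%s  %s", bot, sc)
  )
}
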