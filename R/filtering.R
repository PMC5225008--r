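# The three-stage reduction of SV predictions to credible, patient-specific
# candidates: read-pair support, known-variant overlap, family comparison.
# Every filter returns the surviving predictions and attaches a disposition
# report (one row per input prediction) retrievable with filter_report().

attach_report <- function(survivors, report, previous = NULL) {
  report <- bind_rows(previous, report)
  attr(survivors, "filter_report") <- report
  class(survivors) <- unique(c("sv_filtered", class(survivors)))
  survivors
}

#' Disposition report of a filter chain
#'
#' @param x Output of [filter_support()], [filter_known()] or
#'   [filter_patient_specific()].
#' @return A tibble with columns `stage`, `sv_id`, `disposition`
#'   (`retained`, `low_support`, `known_variant`, `shared_in_family`).
#' @export
filter_report <- function(x) {
  attr(x, "filter_report") %||%
    tibble(stage = character(), sv_id = character(), disposition = character())
}

#' Filter SV predictions by read-pair support
#'
#' Retains predictions supported by at least `min_support` independent
#' read pairs (duplicates having been removed upstream, every contributing
#' pair is independent).
#'
#' @param preds SV prediction tibble.
#' @param min_support Minimum distinct read-pair count (default 5).
#' @return Surviving predictions, with a disposition report attached (see
#'   [filter_report()]).
#' @export
filter_support <- function(preds, min_support = 5L) {
  if (min_support < 1) abort("min_support must be >= 1")
  keep <- preds$support >= min_support
  report <- tibble(
    stage = "support", sv_id = preds$sv_id,
    disposition = if_else(keep, "retained", "low_support")
  )
  attach_report(preds[keep, ], report, filter_report(preds))
}

# footprint of an intrachromosomal prediction: midpoint of the left
# junction interval to midpoint of the right one
prediction_footprint <- function(preds) {
  tibble(
    chrom = preds$chrom1,
    start = pmin(
      as.integer(floor((preds$start1 + preds$end1) / 2)),
      as.integer(ceiling((preds$start2 + preds$end2) / 2))
    ),
    end = pmax(
      as.integer(floor((preds$start1 + preds$end1) / 2)),
      as.integer(ceiling((preds$start2 + preds$end2) / 2))
    )
  )
}

#' Filter SV predictions against a known-variant catalogue
#'
#' An intrachromosomal prediction is removed when a same-type catalogue
#' record overlaps it by at least `threshold` (fraction of the prediction
#' footprint under `mode = "of_a"`, or reciprocally). Interchromosomal
#' (translocation) predictions are never matched by interval records.
#'
#' @param preds SV prediction tibble.
#' @param catalogue Feature tibble (`chrom`, `start`, `end`, `name` = SV
#'   type), e.g. from [read_bed()] or [sim_known_catalogue()].
#' @param threshold Overlap fraction in (0, 1]; default 0.8.
#' @param mode `"of_a"` (fraction of the prediction covered; default) or
#'   `"reciprocal"`.
#' @return Surviving predictions with disposition report attached.
#' @export
filter_known <- function(preds, catalogue, threshold = 0.8,
                         mode = c("of_a", "reciprocal")) {
  mode <- match.arg(mode)
  if (threshold > 1 || threshold <= 0) abort("threshold must be in (0, 1]")
  fp <- prediction_footprint(preds)
  intra <- preds$chrom1 == preds$chrom2
  hit <- rep(FALSE, nrow(preds))
  if (nrow(catalogue) > 0) {
    cat_type <- catalogue$name %||% rep(NA_character_, nrow(catalogue))
    for (i in which(intra)) {
      same_type <- is.na(cat_type) | cat_type == preds$type[i]
      cand <- catalogue[same_type & catalogue$chrom == fp$chrom[i], , drop = FALSE]
      if (nrow(cand) == 0) next
      fr <- overlap_fraction(fp[i, ], cand, mode = mode)
      hit[i] <- any(fr >= threshold)
    }
  }
  report <- tibble(
    stage = "known_variant", sv_id = preds$sv_id,
    disposition = if_else(hit, "known_variant", "retained")
  )
  attach_report(preds[!hit, ], report, filter_report(preds))
}

#' Extract patient-specific SV predictions within a family
#'
#' Retains the affected member's predictions that have no same-type
#' prediction in any other member within distance `d` on both partners.
#' Positional tolerance (rather than exact coordinates) is used because
#' breakpoint estimates jitter between members even for identical events.
#'
#' @param preds_by_member Named list of SV prediction tibbles, one per
#'   family member.
#' @param affected Name of the affected member (must be in the list).
#' @param d Positional tolerance in bp (default: the clustering distance,
#'   4000).
#' @return The affected member's surviving predictions, with a disposition
#'   report attached.
#' @export
filter_patient_specific <- function(preds_by_member, affected, d = 4000L) {
  if (length(preds_by_member) < 2) abort("need at least two family members")
  if (!affected %in% names(preds_by_member)) {
    abort(sprintf("affected member '%s' not in the roster", affected))
  }
  px <- preds_by_member[[affected]]
  others <- bind_rows(preds_by_member[setdiff(names(preds_by_member), affected)])
  mids <- function(p) list(
    a = (p$start1 + p$end1) / 2, b = (p$start2 + p$end2) / 2
  )
  mp <- mids(px); mo <- mids(others)
  shared <- map_lgl(seq_len(nrow(px)), function(i) {
    any(
      others$type == px$type[i] &
        others$chrom1 == px$chrom1[i] & others$chrom2 == px$chrom2[i] &
        abs(mo$a - mp$a[i]) <= d & abs(mo$b - mp$b[i]) <= d
    )
  })
  report <- tibble(
    stage = "patient_specific", sv_id = px$sv_id,
    disposition = if_else(shared, "shared_in_family", "retained")
  )
  attach_report(px[!shared, ], report, filter_report(px))
}

#' @export
tidy.sv_filtered <- function(x, ...) filter_report(x)

#' @export
glance.sv_filtered <- function(x, ...) {
  rep <- filter_report(x)
  rep |>
    group_by(.data$stage) |>
    summarise(
      input = n(),
      removed = sum(.data$disposition != "retained"),
      survivors = sum(.data$disposition == "retained"),
      .groups = "drop"
    )
}
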