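# Discordant mate-pair classification and clustering into SV predictions
# (the in-house replacement for an SVDetect-style caller).

#' Remove multimapping pairs and PCR duplicates
#'
#' Pairs with any non-uniquely mapping mate are dropped; among pairs with
#' identical coordinates on both mates (chromosome, position and strand)
#' exactly one survives -- the one with the lowest pair id.
#'
#' @param pairs Aligned-pair tibble.
#' @return Filtered aligned-pair tibble.
#' @export
pairs_dedupe <- function(pairs) {
  pairs |>
    filter(.data$unique1, .data$unique2) |>
    arrange(.data$pair_id) |>
    distinct(
      .data$chrom1, .data$pos1, .data$strand1,
      .data$chrom2, .data$pos2, .data$strand2,
      .keep_all = TRUE
    ) |>
    arrange(.data$pair_id)
}

conv_strands <- function(convention) {
  # strand of the fragment-start mate, then the fragment-end mate
  if (convention == "outward") c("-", "+") else c("+", "-")
}

#' Classify mate-pairs as concordant or discordant
#'
#' A pair is `interchromosomal` when its mates map to different
#' chromosomes; otherwise `orientation_anomaly` when the strand pattern
#' violates the library convention; otherwise `insert_anomaly` when the
#' inferred insert size falls outside the configured bounds; otherwise
#' `concordant`.
#'
#' @param pairs Aligned-pair tibble (after [pairs_dedupe()]).
#' @param convention `"outward"` or `"inward"` (see [sim_config()]).
#' @param insert_min,insert_max Expected insert-size bounds in bp.
#' @return The input with a `status` column added.
#' @export
pairs_classify <- function(pairs, convention = "outward",
                           insert_min = 2000L, insert_max = 4000L) {
  st <- conv_strands(convention)
  left_first <- pairs$pos1 <= pairs$pos2
  left_strand <- if_else(left_first, pairs$strand1, pairs$strand2)
  right_strand <- if_else(left_first, pairs$strand2, pairs$strand1)
  ok_orient <- left_strand == st[1] & right_strand == st[2]
  pairs |>
    mutate(status = case_when(
      .data$chrom1 != .data$chrom2 ~ "interchromosomal",
      !ok_orient ~ "orientation_anomaly",
      .data$insert_size < insert_min | .data$insert_size > insert_max ~ "insert_anomaly",
      TRUE ~ "concordant"
    ))
}

#' Cluster discordant pairs into SV predictions
#'
#' Single-linkage clustering of discordant pairs whose mate positions lie
#' within `d` on *both* partners, within groups of identical chromosome
#' pair and orientation (mixed-orientation clusters are never formed, which
#' is what separates the two derivative junctions of a reciprocal
#' translocation). Each cluster's junction intervals are the intersection
#' of the per-pair admissible breakpoint ranges -- each mate constrains its
#' breakpoint to lie between the inner read end and the farthest point the
#' insert could reach -- falling back to the span of inner read ends when
#' the intersection is empty.
#'
#' @param pairs Classified pairs (see [pairs_classify()]).
#' @param d Clustering distance in bp; defaults to `insert_max`, since a
#'   pair cannot span farther than its insert.
#' @param convention Library orientation convention.
#' @param read_length Read length in bp.
#' @param insert_max Upper insert bound in bp.
#' @return An SV prediction tibble of class `sv_predictions`: `sv_id`,
#'   `type`, junction interval columns `chrom1/start1/end1`,
#'   `chrom2/start2/end2` (chrom1 is the partner retaining its prefix on
#'   the derivative for translocations), strands, `support`, and a
#'   list-column `pair_ids`.
#' @export
cluster_discordant <- function(pairs, d = insert_max, convention = "outward",
                               read_length = 100L, insert_max = 4000L) {
  stopifnot("status" %in% names(pairs))
  disc <- pairs |> filter(.data$status != "concordant")
  empty <- tibble(
    sv_id = character(), type = character(),
    chrom1 = character(), start1 = integer(), end1 = integer(),
    chrom2 = character(), start2 = integer(), end2 = integer(),
    strand1 = character(), strand2 = character(),
    support = integer(), pair_ids = list()
  )
  if (nrow(disc) == 0) return(new_sv_predictions(empty))
  st <- conv_strands(convention)

  # canonical mate order: fragment-start (prefix-side) mate first when the
  # convention identifies it, otherwise lower coordinate first
  is_start1 <- disc$strand1 == st[1]
  flip <- (disc$status == "interchromosomal" & !is_start1) |
    (disc$status != "interchromosomal" & disc$pos1 > disc$pos2)
  disc2 <- disc |>
    mutate(
      chromA = if_else(flip, .data$chrom2, .data$chrom1),
      posA = if_else(flip, .data$pos2, .data$pos1),
      strandA = if_else(flip, .data$strand2, .data$strand1),
      chromB = if_else(flip, .data$chrom1, .data$chrom2),
      posB = if_else(flip, .data$pos1, .data$pos2),
      strandB = if_else(flip, .data$strand1, .data$strand2)
    )

  groups <- disc2 |>
    group_by(.data$status, .data$chromA, .data$chromB, .data$strandA, .data$strandB) |>
    dplyr::group_split()
  preds <- list_rbind(map(groups, function(gp) {
    comp <- linkage_components(gp$posA, gp$posB, d)
    list_rbind(map(split(seq_len(nrow(gp)), comp), function(i) {
      cl <- gp[i, ]
      summarise_cluster(cl, read_length, insert_max)
    }))
  }))
  preds <- preds |>
    arrange(.data$chrom1, .data$start1, .data$chrom2, .data$start2) |>
    mutate(sv_id = sprintf("sv%03d", row_number()), .before = 1)
  new_sv_predictions(preds)
}

new_sv_predictions <- function(x) {
  class(x) <- c("sv_predictions", class(x))
  x
}

# single-linkage connected components: pairs i, j linked when both
# |posA_i - posA_j| <= d and |posB_i - posB_j| <= d
linkage_components <- function(posA, posB, d) {
  n <- length(posA)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ord <- order(posA)
  for (ii in seq_len(n - 1)) {
    i <- ord[ii]
    for (jj in (ii + 1):n) {
      j <- ord[jj]
      if (posA[j] - posA[i] > d) break
      if (abs(posB[i] - posB[j]) <= d) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

summarise_cluster <- function(cl, r, insert_max) {
  status <- cl$status[1]
  type <- if (status == "interchromosomal") {
    "translocation"
  } else if (status == "orientation_anomaly") {
    "inversion"
  } else if (all(cl$insert_size > insert_max)) "deletion" else "insertion"
  # prefix side: breakpoint lies at/after the inner read end, and no
  # farther than the largest insert can reach
  a_lo <- max(cl$posA) + r - 1L
  a_hi <- min(cl$posA) + insert_max - r - 1L
  # suffix side: breakpoint at/before the read start, reachable by insert
  b_lo <- max(cl$posB) + 2L * r - insert_max
  b_hi <- min(cl$posB)
  if (a_lo > a_hi) { # fallback: span of inner read ends
    a_lo <- min(cl$posA) + r - 1L
    a_hi <- max(cl$posA) + r - 1L
  }
  if (b_lo > b_hi) {
    b_lo <- min(cl$posB)
    b_hi <- max(cl$posB)
  }
  tibble(
    type = type,
    chrom1 = cl$chromA[1], start1 = as.integer(max(1L, a_lo)), end1 = as.integer(a_hi),
    chrom2 = cl$chromB[1], start2 = as.integer(max(1L, b_lo)), end2 = as.integer(b_hi),
    strand1 = cl$strandA[1], strand2 = cl$strandB[1],
    support = nrow(cl), pair_ids = list(cl$pair_id)
  )
}

#' @export
autoplot.sv_predictions <- function(object, ...) {
  df <- object
  df$junction1 <- format_interval(
    tibble(chrom = df$chrom1, start = df$start1, end = df$end1),
    dash = "-"
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$junction1, y = .data$support, fill = .data$type
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = "junction interval (partner 1)", y = "read-pair support",
      title = "SV predictions from discordant mate-pair clusters"
    ) +
    ggplot2::theme_minimal()
}
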