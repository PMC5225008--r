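# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles deliberately use naive enumeration, not the package's
# fast code paths.

# small repeat-free simulation config (the default repeat span sits on the
# last chromosome; tests that refine junctions keep breakpoints off it)
tiny_config <- function(seed, lens = c(chrA = 1e5, chrB = 1e5, chrC = 5e4), ...) {
  sim_config(seed = seed, chrom_lengths = lens, ...)
}

# brute-force shared-base count by coordinate enumeration
oracle_shared_bases <- function(a, b) {
  if (a$chrom != b$chrom) return(0L)
  length(intersect(seq(a$start, a$end), seq(b$start, b$end)))
}

# brute-force single-linkage clustering: explicit pairwise compatibility
# graph + connected components by label propagation
oracle_cluster <- function(posA, posB, d) {
  n <- length(posA)
  adj <- outer(posA, posA, function(x, y) abs(x - y) <= d) &
    outer(posB, posB, function(x, y) abs(x - y) <= d)
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      nb <- which(adj[i, ])
      m <- min(lab[nb])
      if (m < lab[i]) {
        lab[i] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(lab, unique(lab))
}

# enumeration oracle for junction decomposition: given the window J, the
# two reference chromosomes as plain strings and the *known* alignment of
# the window ends (J[1] sits at refA position x0; J[n] at refB position
# yend), enumerate every prefix + insert + suffix decomposition.
# Returns the set of empty-insert split points (prefix lengths), and the
# maximal prefix/suffix lengths.
oracle_decompose <- function(J, refA, refB, x0, yend) {
  n <- nchar(J)
  pref_ok <- vapply(0:n, function(s) {
    s == 0 || substr(J, 1, s) == substr(refA, x0, x0 + s - 1)
  }, logical(1))
  suff_ok <- vapply(0:n, function(k) { # k = suffix length
    k == 0 || substr(J, n - k + 1, n) == substr(refB, yend - k + 1, yend)
  }, logical(1))
  L <- max(which(pref_ok)) - 1L # maximal prefix length
  R <- max(which(suff_ok)) - 1L # maximal suffix length
  blunt_splits <- which(pref_ok[1:(n + 1)] & rev(suff_ok[1:(n + 1)])) - 1L
  list(L = L, R = R, blunt_splits = blunt_splits)
}

# longest exact common substring of two strings (brute all-substring scan)
oracle_lcs <- function(a, b) {
  na <- nchar(a)
  best <- 0L
  for (i in seq_len(na)) {
    max_len <- na - i + 1L
    if (best + 1L > max_len) break
    for (len in seq(best + 1L, max_len)) {
      if (!grepl(substr(a, i, i + len - 1L), b, fixed = TRUE)) break
      best <- len
    }
  }
  best
}

# engineered translocation plus its refinement inputs, for junction tests
refined_from_spec <- function(seed, spec_args, w = 400) {
  cfg <- tiny_config(seed)
  g <- sim_reference(cfg)
  spec <- do.call(rearrangement, c(list("reciprocal_translocation"), spec_args))
  tr <- apply_rearrangement(g, spec)
  jx <- tr$truth$junctions
  ref <- lapply(1:2, function(j) {
    jseq <- extract_junction_sequence(
      tr$der_genome, jx$junction_id[j], jx$der_junction_pos[j], w = w
    )
    refine_junction(jseq, tr$genome, jx$prefix_chrom[j], jx$suffix_chrom[j])
  })
  list(
    tr = tr, jx = jx, der_a = ref[[1]], der_b = ref[[2]],
    rec = reconcile_derivatives(ref[[1]], ref[[2]], tr$genome)
  )
}

# hand-built aligned-pair tibble (outward convention: start mate "-")
make_pairs <- function(...) {
  rows <- list(...)
  purrr::list_rbind(purrr::map(seq_along(rows), function(i) {
    r <- rows[[i]]
    tibble::tibble(
      pair_id = r$id %||% i,
      chrom1 = r$c1, pos1 = r$p1, strand1 = r$s1 %||% "-",
      unique1 = r$u1 %||% TRUE,
      chrom2 = r$c2, pos2 = r$p2, strand2 = r$s2 %||% "+",
      unique2 = r$u2 %||% TRUE,
      insert_size = if (r$c1 == r$c2) {
        as.integer(r$ins %||% (abs(r$p2 - r$p1) + 100L))
      } else {
        NA_integer_
      }
    )
  }))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# random SV prediction tibble for filter tests
random_preds <- function(n, seed) {
  withr::with_seed(seed, {
    intra <- runif(n) < 0.7
    chrom1 <- sample(c("chr1", "chr2", "chr3"), n, replace = TRUE)
    chrom2 <- ifelse(intra, chrom1, "chrT")
    s1 <- sample.int(1e6, n)
    s2 <- s1 + sample(500:20000, n, replace = TRUE)
    tibble::tibble(
      sv_id = sprintf("sv%04d", seq_len(n)),
      type = ifelse(intra, sample(c("deletion", "insertion"), n, TRUE), "translocation"),
      chrom1 = chrom1, start1 = s1, end1 = s1 + 200L,
      chrom2 = chrom2, start2 = s2, end2 = s2 + 200L,
      strand1 = "-", strand2 = "+",
      support = sample(1:30, n, replace = TRUE),
      pair_ids = replicate(n, integer(), simplify = FALSE)
    )
  })
}
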