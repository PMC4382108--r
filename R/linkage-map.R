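#' Partition markers into linkage groups at a LOD threshold
#'
#' Groups are the connected components of the graph whose edges join marker
#' pairs with `lod >= lod_threshold` — exact single linkage. Singletons are
#' allowed.
#'
#' @param pw a [pairwise_linkage()] object.
#' @param lod_threshold minimum LOD for an edge.
#' @return integer vector of group memberships (1-based, ordered by
#'   decreasing group size), named by marker id.
#' @export
build_groups <- function(pw, lod_threshold) {
  am_check(inherits(pw, "pairwise_linkage"), "'pw' must come from pairwise_linkage()")
  adj <- pw$lod >= lod_threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  memb <- igraph::components(g)$membership
  sz <- table(memb)
  relab <- match(memb, as.integer(names(sort(sz, decreasing = TRUE))))
  stats::setNames(relab, pw$ids)
}

# pairwise co-grouping agreement between a candidate partition and the
# reference map, over contigs present in both (fraction of shared-contig
# pairs whose same-group/different-group status matches)
.reference_agreement <- function(partition, markers, reference) {
  ctg_grp <- tapply(partition, markers$contig_id[match(names(partition),
                                                       markers$marker_id)],
                    function(g) as.integer(names(which.max(table(g)))))
  shared <- intersect(names(ctg_grp), reference$contig_id)
  if (length(shared) < 2L) return(NA_real_)
  ref_lab <- reference$linkage_group[match(shared, reference$contig_id)]
  map_lab <- ctg_grp[shared]
  pairs <- utils::combn(length(shared), 2L)
  same_map <- map_lab[pairs[1L, ]] == map_lab[pairs[2L, ]]
  same_ref <- ref_lab[pairs[1L, ]] == ref_lab[pairs[2L, ]]
  mean(same_map == same_ref)
}

#' Select the mapping LOD threshold
#'
#' Candidate partitions (one per LOD threshold) are scored on how well they
#' reflect the expected chromosome structure: the primary criterion is the
#' number of groups at or above `min_group_size` closest to `target_n`; ties
#' are broken by the highest contig-level co-grouping agreement with the
#' reference map, then by the higher threshold.
#'
#' @param partitions named list of group-membership vectors, one per
#'   threshold (names are the thresholds).
#' @param markers the `marker_set` the partitions were built from (for
#'   marker-to-contig assignment).
#' @param reference optional reference map data frame
#'   (see [read_reference_map()]).
#' @param target_n expected number of chromosomes (default 18).
#' @param min_group_size groups below this marker count are ignored when
#'   counting groups (default 5).
#' @return list with `threshold` (the chosen name, as numeric), `partition`,
#'   and `candidates` (per-threshold group counts and agreement scores).
#' @export
select_threshold <- function(partitions, markers, reference = NULL,
                             target_n = 18, min_group_size = 5) {
  am_check(length(partitions) >= 1L, "no candidate partitions")
  mk <- if (inherits(markers, "marker_set")) markers$markers else markers
  stats_df <- data.frame(threshold = as.numeric(names(partitions)),
                         n_groups = NA_real_, agreement = NA_real_)
  for (i in seq_along(partitions)) {
    sz <- table(partitions[[i]])
    stats_df$n_groups[i] <- sum(sz >= min_group_size)
    if (!is.null(reference))
      stats_df$agreement[i] <- .reference_agreement(partitions[[i]], mk, reference)
  }
  dev <- abs(stats_df$n_groups - target_n)
  cand <- which(dev == min(dev))
  if (length(cand) > 1L && !is.null(reference) && !all(is.na(stats_df$agreement[cand]))) {
    ag <- stats_df$agreement[cand]
    ag[is.na(ag)] <- -Inf
    cand <- cand[ag == max(ag)]
  }
  pick <- cand[which.max(stats_df$threshold[cand])]
  list(threshold = stats_df$threshold[pick],
       partition = partitions[[pick]],
       candidates = stats_df)
}

# canonical bin signature: transmission states up to allele relabelling;
# no-calls are part of the signature (strict identity)
.bin_signature <- function(class, states) {
  variants <- switch(class,
    lm = , np = list(states, c(2L, 1L)[states]),
    hk = list(states, c(3L, 2L, 1L)[states]),
    fi = list(states, c(3L, 4L, 1L, 2L)[states],
              c(2L, 1L, 4L, 3L)[states], c(4L, 3L, 2L, 1L)[states]))
  keys <- vapply(variants, function(v) paste(ifelse(is.na(v), ".", v),
                                             collapse = ","), character(1))
  paste(class, min(keys), sep = ":")
}

#' Collapse co-segregating markers into bins
#'
#' Markers whose informative-transmission vectors are identical up to allele
#' relabelling share no recombination information and are merged into one bin
#' (one non-redundant marker position); all member SNPs are retained and
#' later reported at the bin position. By default no-call patterns must match
#' exactly (strict identity); with `strict = FALSE` a no-call matches either
#' state and markers are merged greedily into the first compatible bin.
#'
#' @param ms a `marker_set`.
#' @param members optional character vector of marker ids to bin (defaults to
#'   all markers).
#' @param strict logical; treat no-calls as part of the signature
#'   (default `TRUE`).
#' @return data frame with `marker_id` and `bin` (integer bin ids, in order
#'   of first appearance).
#' @export
collapse_bins <- function(ms, members = ms$markers$marker_id, strict = TRUE) {
  am_check(inherits(ms, "marker_set"), "'ms' must be a marker_set")
  idx <- match(members, ms$markers$marker_id)
  am_check(!anyNA(idx), "unknown marker ids in 'members'")
  enc <- marker_states(ms)
  sig <- vapply(idx, function(m) .bin_signature(enc$class[m], enc$states[m, ]),
                character(1))
  if (strict) {
    bin <- as.integer(factor(sig, levels = unique(sig)))
  } else {
    # greedy merge: a no-call is a wildcard against the bin's exemplar
    bin <- integer(length(idx))
    ex_class <- character(0); ex_states <- list()
    for (k in seq_along(idx)) {
      m <- idx[k]
      placed <- 0L
      for (b in seq_along(ex_states)) {
        if (ex_class[b] != enc$class[m]) next
        for (v in .state_variants(enc$class[m], enc$states[m, ])) {
          cmp <- ex_states[[b]] == v
          if (all(cmp | is.na(cmp))) { placed <- b; break }
        }
        if (placed) break
      }
      if (!placed) {
        ex_class <- c(ex_class, enc$class[m])
        ex_states[[length(ex_states) + 1L]] <- enc$states[m, ]
        placed <- length(ex_states)
      }
      bin[k] <- placed
    }
  }
  data.frame(marker_id = members, bin = bin, stringsAsFactors = FALSE)
}

.state_variants <- function(class, states) {
  switch(class,
    lm = , np = list(states, c(2L, 1L)[states]),
    hk = list(states, c(3L, 2L, 1L)[states]),
    fi = list(states, c(3L, 4L, 1L, 2L)[states],
              c(2L, 1L, 4L, 3L)[states], c(4L, 3L, 2L, 1L)[states]))
}

# recombination-fraction matrix between bins: member-pair estimates pooled
# by their informative-meiosis counts; `inf` marks bin pairs that share
# informative meioses at all (a P1-only bin against a P2-only bin does not)
.bin_rf <- function(pw, bin_members) {
  B <- length(bin_members)
  D <- matrix(0.5, B, B); diag(D) <- 0
  inf <- matrix(FALSE, B, B)
  N <- matrix(0, B, B)
  for (u in seq_len(B - 1L)) for (v in (u + 1L):B) {
    iu <- bin_members[[u]]; iv <- bin_members[[v]]
    nsub <- pw$n[iu, iv, drop = FALSE]
    if (all(nsub == 0)) next
    rsub <- pw$rf[iu, iv, drop = FALSE]
    D[u, v] <- D[v, u] <- sum(rsub * nsub) / sum(nsub)
    N[u, v] <- N[v, u] <- sum(nsub)
    inf[u, v] <- inf[v, u] <- TRUE
  }
  list(rf = D, inf = inf, n = N)
}

# strongest member-pair LOD between bins
.bin_lod <- function(pw, bin_members) {
  B <- length(bin_members)
  L <- matrix(0, B, B)
  for (u in seq_len(B - 1L)) for (v in (u + 1L):B) {
    L[u, v] <- L[v, u] <- max(pw$lod[bin_members[[u]], bin_members[[v]]])
  }
  L
}

#' Order bins within a group and assign cM positions
#'
#' Bin-level recombination fractions are converted to Haldane cM; bin pairs
#' that share no informative meioses (a P1-only bin against a P2-only bin)
#' get the shortest-path distance through informative pairs. Ordering is a
#' greedy nearest-neighbour chain (with a principal-coordinate seed as an
#' alternative start), refined by 2-opt segment reversals until no swap
#' reduces the total adjacent distance. Positions are cumulative Haldane
#' distances between adjacent bins with the first bin at 0. The orientation
#' is canonical: the terminal bin containing the lexicographically smallest
#' marker id comes first, so the result is invariant to input orientation up
#' to reversal.
#'
#' @param bins data frame from [collapse_bins()] restricted to one group.
#' @param pw the [pairwise_linkage()] object.
#' @return data frame with one row per bin: `bin`, `position`, and
#'   comma-separated `members`.
#' @export
order_and_position <- function(bins, pw) {
  ub <- unique(bins$bin)
  members <- lapply(ub, function(b) match(bins$marker_id[bins$bin == b], pw$ids))
  am_check(!anyNA(unlist(members)), "bin members missing from pairwise object")
  B <- length(ub)
  if (B == 1L) {
    return(data.frame(bin = ub, position = 0,
                      members = paste(bins$marker_id, collapse = ","),
                      stringsAsFactors = FALSE))
  }
  bd <- .bin_rf(pw, members)
  ## Distances from confidently linked pairs only: the two-point cM estimate
  ## is reliable at short range but saturates into noise beyond ~40 cM, so
  ## the distance matrix is completed by shortest paths through
  ## well-supported edges (lod >= 3). If that graph is disconnected the
  ## strongest available edge between components is added back.
  bl <- .bin_lod(pw, members)
  cm <- haldane_cm(pmin(bd$rf, 0.45))
  w <- ifelse(bd$inf & bl >= 3, pmax(cm, 1e-9), 0)
  repeat {
    g <- igraph::graph_from_adjacency_matrix(w, weighted = TRUE,
                                             mode = "undirected")
    comp <- igraph::components(g)$membership
    if (max(comp) == 1L) break
    best <- -Inf; bi <- bj <- NA
    for (i in seq_len(B - 1L)) for (j in (i + 1L):B) {
      if (comp[i] != comp[j] && bd$inf[i, j] && bl[i, j] > best) {
        best <- bl[i, j]; bi <- i; bj <- j
      }
    }
    if (is.na(bi))
      am_stop("disconnected bins within a group: pairwise input incomplete")
    w[bi, bj] <- w[bj, bi] <- pmax(cm[bi, bj], 1e-9)
  }
  D <- igraph::distances(g)
  ## seed order: distance from the most eccentric bin (a chromosome end)
  path_cost <- function(p) sum(D[cbind(p[-length(p)], p[-1L])])
  term <- which.max(apply(D, 1L, max))
  chain <- order(D[term, ])
  ## alternative seeds: greedy nearest-neighbour chain and first principal
  ## coordinate
  M <- D + diag(Inf, B)
  w0 <- which(M == min(M), arr.ind = TRUE)[1L, ]
  alt <- c(w0[1L], w0[2L])
  left <- setdiff(seq_len(B), alt)
  while (length(left)) {
    dl <- D[alt[1L], left]; dr <- D[alt[length(alt)], left]
    if (min(dl) <= min(dr)) {
      alt <- c(left[which.min(dl)], alt)
      left <- left[-which.min(dl)]
    } else {
      alt <- c(alt, left[which.min(dr)])
      left <- left[-which.min(dr)]
    }
  }
  if (path_cost(alt) < path_cost(chain)) chain <- alt
  pco <- suppressWarnings(stats::cmdscale(D, k = 1))
  alt2 <- order(pco[, 1L])
  if (path_cost(alt2) < path_cost(chain)) chain <- alt2
  ## local search: 2-opt segment reversals plus Or-opt segment relocations,
  ## iterated until neither move improves the total adjacent distance
  local_search <- function(chain) {
  improved <- TRUE; pass <- 0L
  while (improved && pass < 200L) {
    improved <- FALSE; pass <- pass + 1L
    for (i in seq_len(B - 1L)) for (j in (i + 1L):B) {
      # cost delta of reversing chain[i..j]
      a <- if (i > 1L) D[chain[i - 1L], chain[i]] else 0
      b <- if (j < B) D[chain[j], chain[j + 1L]] else 0
      a2 <- if (i > 1L) D[chain[i - 1L], chain[j]] else 0
      b2 <- if (j < B) D[chain[i], chain[j + 1L]] else 0
      if (a2 + b2 < a + b - 1e-12) {
        chain[i:j] <- rev(chain[i:j])
        improved <- TRUE
      }
    }
    for (seg in 1:3) {
      if (B <= seg + 1L) next
      for (i in seq_len(B - seg + 1L)) {
        j <- i + seg - 1L
        # cost of removing chain[i..j]
        a <- if (i > 1L) D[chain[i - 1L], chain[i]] else 0
        b <- if (j < B) D[chain[j], chain[j + 1L]] else 0
        br <- if (i > 1L && j < B) D[chain[i - 1L], chain[j + 1L]] else 0
        gain <- a + b - br
        if (gain <= 1e-12) next
        rest <- chain[-(i:j)]
        piece <- chain[i:j]
        nb <- length(rest)
        best_delta <- -1e-12; best_k <- NA
        for (k in 0:nb) {
          if (k == i - 1L) next  # original slot
          l <- if (k >= 1L) D[rest[k], piece[1L]] else 0
          r <- if (k < nb) D[piece[seg], rest[k + 1L]] else 0
          mid <- if (k >= 1L && k < nb) D[rest[k], rest[k + 1L]] else 0
          delta <- gain - (l + r - mid)
          if (delta > best_delta) { best_delta <- delta; best_k <- k }
        }
        if (!is.na(best_k) && best_delta > 1e-12) {
          chain <- append(rest, piece, after = best_k)
          improved <- TRUE
        }
      }
    }
  }
  chain
  }
  ## polish: weighted least-squares positions over all confident pairs
  ## (regression mapping), with inverse-variance weights on the cM scale
  ## (delta-method variance of the Haldane transform,
  ## var(d) = (100/(1-2r))^2 r(1-r)/n); reorder by the fitted positions and
  ## iterate. Pooling every lod >= 3 distance makes the order of nearby
  ## clusters far less sensitive to single noisy estimates than adjacent
  ## sums alone.
  use <- bd$inf & bl >= 3
  rr <- pmin(bd$rf, 0.45)
  W <- ifelse(use, bd$n * (1 - 2 * rr)^2 / pmax(rr * (1 - rr), 1e-4), 0)
  idx <- which(use & upper.tri(use), arr.ind = TRUE)
  polish <- function(chain) {
    if (B <= 2L || nrow(idx) == 0L) return(chain)
    for (it in seq_len(5L)) {
      rk <- match(seq_len(B), chain)
      sgn <- ifelse(rk[idx[, 2L]] > rk[idx[, 1L]], 1, -1)
      d <- sgn * cm[idx]
      w <- W[idx]
      ## solve min sum w (p_j - p_i - d)^2 with p[chain[1]] = 0
      A <- matrix(0, nrow(idx), B)
      A[cbind(seq_len(nrow(idx)), idx[, 2L])] <- 1
      A[cbind(seq_len(nrow(idx)), idx[, 1L])] <- -1
      A <- A[, -chain[1L], drop = FALSE]
      fit <- tryCatch(solve(crossprod(A * sqrt(w)), crossprod(A * sqrt(w),
                                                              d * sqrt(w))),
                      error = function(e) NULL)
      if (is.null(fit)) break
      p <- numeric(B)
      p[setdiff(seq_len(B), chain[1L])] <- fit
      new_chain <- order(p)
      if (identical(new_chain, chain)) break
      chain <- new_chain
    }
    chain
  }
  chain <- local_search(chain)
  chain <- polish(chain)
  chain <- local_search(chain)
  chain <- polish(chain)
  ## canonical orientation
  first_id <- min(bins$marker_id[bins$bin == ub[chain[1L]]])
  last_id <- min(bins$marker_id[bins$bin == ub[chain[B]]])
  if (last_id < first_id) chain <- rev(chain)
  ## positions: cumulative adjacent distances; co-segregating bins (distance
  ## indistinguishable from zero) share one position exactly
  pos <- round(c(0, cumsum(D[cbind(chain[-B], chain[-1L])])), 6)
  data.frame(bin = ub[chain], position = pos,
             members = vapply(chain, function(k)
               paste(sort(bins$marker_id[bins$bin == ub[k]]), collapse = ","),
               character(1)),
             stringsAsFactors = FALSE)
}

#' Fit a linkage map to QC-passed markers
#'
#' The map-construction workhorse: computes all pairwise two-point linkage
#' estimates, partitions markers into groups at each candidate LOD threshold,
#' selects the threshold whose group count (over a minimum group size) best
#' matches the expected chromosome number — with reference-map agreement and
#' the higher threshold as tie-breaks — then collapses co-segregating markers
#' into bins and orders and positions the bins within each group.
#'
#' @param ms a `marker_set` from the QC cascade.
#' @param lod_thresholds candidate LOD thresholds (default `8:18`).
#' @param reference optional reference map (see [read_reference_map()]).
#' @param target_n expected chromosome number (default 18).
#' @param min_group_size minimum markers for a component to count as a
#'   linkage group (default 5); smaller components are left unplaced.
#' @param strict_bins passed to [collapse_bins()]; the map fit defaults to
#'   `FALSE` (no-calls match either state) because at realistic no-call
#'   rates strict identity leaves almost every SNP in its own bin, defeating
#'   the purpose of non-redundant positions.
#' @param pw optionally, a precomputed [pairwise_linkage()] object.
#' @return an object of class `linkage_map` with components `markers` (one
#'   row per placed SNP: marker, contig, group, bin, position), `groups`
#'   (per-group summary), `unplaced` (marker ids in dust components),
#'   `threshold`, `candidates`, and the fitted `pairwise` object.
#' @seealso [summarize_map()], [assign_contigs()], [renumber_groups()]
#' @export
build_linkage_map <- function(ms, lod_thresholds = 8:18, reference = NULL,
                              target_n = 18, min_group_size = 5,
                              strict_bins = FALSE, pw = NULL) {
  am_check(inherits(ms, "marker_set"), "'ms' must be a marker_set")
  if (is.null(pw)) pw <- pairwise_linkage(ms)
  partitions <- lapply(lod_thresholds, function(th) build_groups(pw, th))
  names(partitions) <- lod_thresholds
  sel <- select_threshold(partitions, ms, reference, target_n, min_group_size)
  part <- sel$partition
  sz <- table(part)
  keep_groups <- as.integer(names(sz)[sz >= min_group_size])
  rows <- list()
  group_label <- 0L
  for (g in keep_groups) {
    group_label <- group_label + 1L
    ids <- names(part)[part == g]
    bins <- collapse_bins(ms, ids, strict = strict_bins)
    ord <- order_and_position(bins, pw)
    for (k in seq_len(nrow(ord))) {
      mem <- strsplit(ord$members[k], ",", fixed = TRUE)[[1]]
      rows[[length(rows) + 1L]] <- data.frame(
        marker_id = mem,
        group = sprintf("LG%d", group_label),
        bin = sprintf("LG%d_bin%03d", group_label, k),
        position = ord$position[k], stringsAsFactors = FALSE)
    }
  }
  placed <- do.call(rbind, rows)
  mk <- ms$markers
  placed$contig_id <- mk$contig_id[match(placed$marker_id, mk$marker_id)]
  placed <- placed[, c("marker_id", "contig_id", "group", "bin", "position")]
  groups <- do.call(rbind, lapply(split(placed, placed$group), function(d) {
    data.frame(group = d$group[1L], n_snps = nrow(d),
               n_bins = length(unique(d$bin)),
               length_cm = max(d$position), stringsAsFactors = FALSE)
  }))
  groups <- groups[order(as.integer(sub("LG", "", groups$group))), ]
  rownames(groups) <- NULL
  structure(list(markers = placed, groups = groups,
                 unplaced = names(part)[!part %in% keep_groups],
                 threshold = sel$threshold, candidates = sel$candidates,
                 pairwise = pw, call = match.call()),
            class = "linkage_map")
}

#' @export
print.linkage_map <- function(x, ...) {
  cat(sprintf("Linkage map: %d SNPs in %d groups (LOD threshold %g), %d unplaced\n",
              nrow(x$markers), nrow(x$groups), x$threshold, length(x$unplaced)))
  cat(sprintf("  total length %.1f cM, %d non-redundant positions\n",
              sum(x$groups$length_cm), sum(x$groups$n_bins)))
  invisible(x)
}

#' @export
summary.linkage_map <- function(object, ...) {
  summarize_map(object)
}

#' @export
plot.linkage_map <- function(x, ...) {
  g <- x$groups
  n <- nrow(g)
  graphics::plot(NULL, xlim = c(0.5, n + 0.5), ylim = c(max(g$length_cm), 0),
                 xlab = "linkage group", ylab = "position (cM)", xaxt = "n", ...)
  graphics::axis(1, at = seq_len(n), labels = sub("^LG", "", g$group))
  for (i in seq_len(n)) {
    d <- x$markers[x$markers$group == g$group[i], ]
    graphics::segments(i - 0.3, 0, i - 0.3, g$length_cm[i], lwd = 2)
    graphics::segments(i - 0.38, unique(d$position), i - 0.22, unique(d$position),
                       col = "darkorange")
  }
  invisible(x)
}
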