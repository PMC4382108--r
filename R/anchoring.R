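#' Place contigs on the linkage map
#'
#' Each contig is assigned to the linkage group holding the majority of its
#' SNPs (ties are flagged unresolved); its position is the median of its SNP
#' positions within that group and its span is the largest SNP distance
#' within that group. Contigs with SNPs in more than one group are flagged
#' `multi_group`; contigs whose within-group span exceeds `span_threshold`
#' are flagged `span_gt_threshold` — both patterns are the signature of
#' collapsed repeat sequence in a draft assembly.
#'
#' @param map a `linkage_map` (or its `markers` data frame).
#' @param span_threshold within-contig SNP span flag threshold in cM
#'   (default 10).
#' @return data frame of contig placements: `contig_id`, `group`,
#'   `position`, `n_snps`, `n_snps_majority`, `span`, `multi_group`,
#'   `span_gt_threshold`, `unresolved`.
#' @export
assign_contigs <- function(map, span_threshold = 10) {
  mk <- if (inherits(map, "linkage_map")) map$markers else map
  out <- lapply(split(mk, mk$contig_id), function(d) {
    tab <- table(d$group)
    top <- max(tab)
    tie <- sum(tab == top) > 1L
    grp <- names(tab)[which.max(tab)]
    ing <- d[d$group == grp, ]
    span <- if (nrow(ing) > 1L) max(ing$position) - min(ing$position) else 0
    data.frame(contig_id = d$contig_id[1L], group = grp,
               position = stats::median(ing$position),
               n_snps = nrow(d), n_snps_majority = nrow(ing), span = span,
               multi_group = length(tab) > 1L,
               span_gt_threshold = span > span_threshold,
               unresolved = tie, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Interrogate scaffold structure against the map
#'
#' Joins contig placements to scaffold membership and reports, per scaffold
#' with at least two placed contigs: the median and maximum distance between
#' its contigs within the scaffold's modal group, whether the gap reaches
#' `gap_threshold`, and whether contigs uniquely assigned to single groups
#' land in different groups (`split_groups`). The discordance report carries
#' three tables: contigs whose within-contig SNP span exceeds
#' `span_threshold`, scaffolds with a large internal gap, and scaffolds split
#' across groups.
#'
#' @param placements contig placements from [assign_contigs()].
#' @param scaffolds scaffold membership table (see [read_scaffold_map()]).
#' @param gap_threshold scaffold internal gap flag threshold in cM
#'   (default 20).
#' @param span_threshold within-contig span threshold in cM (default 10).
#' @return list with `scaffolds` (per-scaffold table) and `report` (list of
#'   data frames `contig_spans`, `scaffold_gaps`, `scaffold_splits`).
#' @export
scaffold_concordance <- function(placements, scaffolds, gap_threshold = 20,
                                 span_threshold = 10) {
  sc_of <- scaffolds$scaffold_id[match(placements$contig_id, scaffolds$contig_id)]
  orphan <- is.na(sc_of)
  if (any(orphan)) {
    warning(sprintf("%d placed contigs absent from the scaffold map; treated as singleton scaffolds",
                    sum(orphan)))
    sc_of[orphan] <- paste0("singleton_", placements$contig_id[orphan])
  }
  pl <- cbind(placements, scaffold_id = sc_of, stringsAsFactors = FALSE)
  rows <- lapply(split(pl, pl$scaffold_id), function(d) {
    modal <- names(which.max(table(d$group)))
    ing <- d[d$group == modal, ]
    gaps <- if (nrow(ing) > 1L) diff(sort(ing$position)) else numeric(0)
    uniq <- d[!d$multi_group & !d$unresolved, ]
    data.frame(scaffold_id = d$scaffold_id[1L], n_contigs_placed = nrow(d),
               group = modal,
               position = stats::median(ing$position),
               median_gap = if (length(gaps)) stats::median(gaps) else NA_real_,
               max_gap = if (length(gaps)) max(gaps) else NA_real_,
               gap_ge_threshold = length(gaps) > 0 && max(gaps) >= gap_threshold,
               split_groups = nrow(uniq) > 1L && length(unique(uniq$group)) > 1L,
               stringsAsFactors = FALSE)
  })
  sc <- do.call(rbind, rows)
  rownames(sc) <- NULL
  report <- list(
    contig_spans = placements[placements$span > span_threshold, , drop = FALSE],
    scaffold_gaps = sc[sc$gap_ge_threshold, , drop = FALSE],
    scaffold_splits = sc[sc$split_groups, , drop = FALSE])
  list(scaffolds = sc, report = report)
}

#' Renumber linkage groups to match a reference map
#'
#' Builds the group-by-reference-group matrix of shared contig counts and
#' assigns reference labels by maximum-weight one-to-one bipartite matching,
#' so the map's linkage groups correspond to the literature numbering.
#' Unmatched groups receive fresh labels; with no shared contigs the original
#' labels are kept with a warning.
#'
#' @param map a `linkage_map`.
#' @param reference reference map data frame (see [read_reference_map()]).
#' @return the map with relabelled groups and a `renumbering` component
#'   (data frame `old`, `new`, `shared_contigs`).
#' @export
renumber_groups <- function(map, reference) {
  am_check(inherits(map, "linkage_map"), "'map' must be a linkage_map")
  pl <- assign_contigs(map)
  shared <- intersect(pl$contig_id, reference$contig_id)
  if (!length(shared)) {
    warning("no contigs shared with the reference map; group labels unchanged")
    map$renumbering <- data.frame(old = map$groups$group, new = map$groups$group,
                                  shared_contigs = 0L, stringsAsFactors = FALSE)
    return(map)
  }
  mg <- pl$group[match(shared, pl$contig_id)]
  rg <- reference$linkage_group[match(shared, reference$contig_id)]
  cnt <- table(mg, rg)
  glab <- rownames(cnt); rlab <- colnames(cnt)
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, length(glab)), rep(TRUE, length(rlab))),
    edges = integer(0))
  w <- numeric(0)
  for (i in seq_along(glab)) for (j in seq_along(rlab)) {
    if (cnt[i, j] > 0) {
      g <- igraph::add_edges(g, c(i, length(glab) + j))
      w <- c(w, cnt[i, j])
    }
  }
  mm <- igraph::max_bipartite_match(g, weights = w)$matching
  new_of <- stats::setNames(rep(NA_character_, length(map$groups$group)),
                            map$groups$group)
  for (i in seq_along(glab)) {
    m <- mm[i]
    if (!is.na(m)) new_of[glab[i]] <- rlab[m - length(glab)]
  }
  ## fresh labels for unmatched groups
  used_nums <- suppressWarnings(as.integer(sub("^LG", "", c(rlab, na.omit(new_of)))))
  nxt <- max(c(0L, used_nums), na.rm = TRUE)
  for (gname in names(new_of)[is.na(new_of)]) {
    nxt <- nxt + 1L
    new_of[gname] <- sprintf("LG%d", nxt)
  }
  shared_n <- vapply(names(new_of), function(gname)
    sum(mg == gname & rg == new_of[gname]), integer(1))
  map$markers$group <- unname(new_of[map$markers$group])
  map$markers$bin <- paste0(map$markers$group,
                            sub("^LG[0-9]+", "", map$markers$bin))
  old <- map$groups$group
  map$groups$group <- unname(new_of[map$groups$group])
  map$renumbering <- data.frame(old = old, new = map$groups$group,
                                shared_contigs = unname(shared_n),
                                stringsAsFactors = FALSE)
  map
}

#' Anchor the assembly to the map, integrating reference-only scaffolds
#'
#' Runs contig placement and scaffold concordance, renumbers groups against
#' the reference map when given, and adds scaffolds that carry a reference
#' (microsatellite) anchor but no SNP: their group comes from the reference
#' label and their position is interpolated linearly between the two nearest
#' reference markers that also carry SNP placements (scaffolds with no
#' flanking co-anchored pair are placed at group level only). Provenance per
#' scaffold is `snp`, `microsatellite`, or `both`.
#'
#' @param map a `linkage_map`.
#' @param scaffolds scaffold membership table.
#' @param reference optional reference map.
#' @param gap_threshold,span_threshold discordance thresholds in cM.
#' @return object of class `anchored_map`: the (renumbered) map plus
#'   `contigs`, `scaffolds` (with provenance), `report` (discordance tables)
#'   and `unplaced_reference` (reference scaffolds whose label matches no
#'   group).
#' @export
anchor_map <- function(map, scaffolds, reference = NULL,
                       gap_threshold = 20, span_threshold = 10) {
  am_check(inherits(map, "linkage_map"), "'map' must be a linkage_map")
  if (!is.null(reference)) map <- renumber_groups(map, reference)
  pl <- assign_contigs(map, span_threshold)
  conc <- scaffold_concordance(pl, scaffolds, gap_threshold, span_threshold)
  sc <- conc$scaffolds
  sc$provenance <- "snp"
  unplaced_ref <- NULL
  if (!is.null(reference)) {
    snp_contigs <- unique(pl$contig_id)
    sc$provenance[sc$scaffold_id %in%
      scaffolds$scaffold_id[match(intersect(reference$contig_id, snp_contigs),
                                  scaffolds$contig_id)]] <- "both"
    ## reference markers on scaffolds with no SNP placement at all
    ref_sc <- scaffolds$scaffold_id[match(reference$contig_id, scaffolds$contig_id)]
    snp_sc <- unique(sc$scaffold_id)
    only <- which(!is.na(ref_sc) & !ref_sc %in% snp_sc)
    ## co-anchored support: reference markers whose contig has a SNP placement
    co <- reference[reference$contig_id %in% snp_contigs, , drop = FALSE]
    co$snp_pos <- pl$position[match(co$contig_id, pl$contig_id)]
    co$snp_grp <- pl$group[match(co$contig_id, pl$contig_id)]
    add <- list(); drop <- list()
    for (i in only) {
      lab <- reference$linkage_group[i]
      if (!lab %in% map$groups$group) {
        drop[[length(drop) + 1L]] <- data.frame(
          scaffold_id = ref_sc[i], linkage_group = lab,
          reason = "no_matching_group", stringsAsFactors = FALSE)
        next
      }
      sup <- co[co$linkage_group == lab & co$snp_grp == lab, , drop = FALSE]
      pos <- NA_real_
      if (nrow(sup) >= 2L) {
        x <- reference$position_cm[i]
        if (x >= min(sup$position_cm) && x <= max(sup$position_cm))
          pos <- stats::approx(sup$position_cm, sup$snp_pos, xout = x,
                               ties = mean)$y
      }
      add[[length(add) + 1L]] <- data.frame(
        scaffold_id = ref_sc[i], n_contigs_placed = 0L, group = lab,
        position = pos, median_gap = NA_real_, max_gap = NA_real_,
        gap_ge_threshold = FALSE, split_groups = FALSE,
        provenance = "microsatellite", stringsAsFactors = FALSE)
    }
    if (length(add)) sc <- rbind(sc, unique(do.call(rbind, add)))
    if (length(drop)) unplaced_ref <- unique(do.call(rbind, drop))
  }
  rownames(sc) <- NULL
  structure(list(map = map, contigs = pl, scaffolds = sc,
                 report = conc$report, unplaced_reference = unplaced_ref),
            class = "anchored_map")
}

#' @export
print.anchored_map <- function(x, ...) {
  print(x$map)
  cat(sprintf("  anchored: %d contigs, %d scaffolds (%d by microsatellite only)\n",
              nrow(x$contigs), nrow(x$scaffolds),
              sum(x$scaffolds$provenance == "microsatellite")))
  cat(sprintf("  discordant: %d contig spans > threshold, %d scaffold gaps, %d split scaffolds\n",
              nrow(x$report$contig_spans), nrow(x$report$scaffold_gaps),
              nrow(x$report$scaffold_splits)))
  invisible(x)
}

#' Summarize a map: per-group rows and totals
#'
#' For a fitted map, reports per linkage group the SNP count, the number of
#' non-redundant marker positions (bins), the group length (position of the
#' last bin) and the median inter-bin distance, plus a totals row. The data
#' frame method accepts an already-tabulated per-group summary (columns
#' `linkage_group` or `group`, `snps`, `positions`, `length_cm`) and computes
#' the same totals, so published per-group tables can be reconciled directly.
#'
#' @param x a `linkage_map`, `anchored_map`, or per-group data frame.
#' @param ... unused.
#' @return object of class `map_summary`: list with `per_group` and `totals`
#'   (`total_snps`, `total_positions`, `total_length_cm`, `n_groups`,
#'   `max_snps_group`, `min_positions_group`, and for anchored maps
#'   `n_contigs`, `n_scaffolds`).
#' @export
summarize_map <- function(x, ...) UseMethod("summarize_map")

#' @export
summarize_map.data.frame <- function(x, ...) {
  grp <- x$linkage_group %||% x$group
  am_check(!is.null(grp) && all(c("snps", "positions", "length_cm") %in% names(x)),
           "per-group summary needs columns group/linkage_group, snps, positions, length_cm")
  per <- data.frame(group = grp, snps = x$snps, positions = x$positions,
                    length_cm = x$length_cm, stringsAsFactors = FALSE)
  totals <- list(total_snps = sum(per$snps),
                 total_positions = sum(per$positions),
                 total_length_cm = sum(per$length_cm),
                 n_groups = nrow(per),
                 max_snps_group = per$group[which.max(per$snps)],
                 max_snps = if (nrow(per)) max(per$snps) else NA,
                 min_positions_group = per$group[which.min(per$positions)],
                 min_positions = if (nrow(per)) min(per$positions) else NA)
  structure(list(per_group = per, totals = totals), class = "map_summary")
}

#' @export
summarize_map.linkage_map <- function(x, ...) {
  per <- do.call(rbind, lapply(split(x$markers, x$markers$group), function(d) {
    pos <- sort(unique(d$position))
    data.frame(group = d$group[1L], snps = nrow(d),
               positions = length(unique(d$bin)),
               length_cm = max(d$position),
               median_interbin_cm = if (length(pos) > 1L)
                 stats::median(diff(pos)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  s <- summarize_map(per[, c("group", "snps", "positions", "length_cm")])
  s$per_group <- per
  s
}

#' @export
summarize_map.anchored_map <- function(x, ...) {
  s <- summarize_map(x$map)
  s$totals$n_contigs <- nrow(x$contigs)
  s$totals$n_scaffolds <- length(unique(x$scaffolds$scaffold_id))
  s
}

#' @export
print.map_summary <- function(x, ...) {
  print(x$per_group, row.names = FALSE)
  t <- x$totals
  cat(sprintf("Totals: %d SNPs, %d positions, %.2f cM in %d groups\n",
              t$total_snps, t$total_positions, t$total_length_cm, t$n_groups))
  cat(sprintf("  most SNPs: %s (%d); fewest positions: %s (%d)\n",
              t$max_snps_group, t$max_snps, t$min_positions_group, t$min_positions))
  if (!is.null(t$n_contigs))
    cat(sprintf("  %d contigs from %d scaffolds\n", t$n_contigs, t$n_scaffolds))
  invisible(x)
}
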