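#' Run the full pipeline on a simulated cross
#'
#' End-to-end driver: simulate a cross, write the fixture files, read them
#' back through the package's readers, run the genotype QC cascade, fit and
#' select the linkage map, anchor contigs and scaffolds, place the primer
#' pairs, and write the per-stage output tables plus a run manifest echoing
#' the thresholds and seed. Identical configurations produce identical
#' outputs.
#'
#' @param config a [sim_config()]; the seed inside it drives all randomness.
#' @param out_dir output directory.
#' @param qc a [qc_config()].
#' @param lod_thresholds candidate LOD thresholds (default `8:18`).
#' @return invisibly, a list with `qc`, `map`, `anchored`, `placements`,
#'   `summary` and the file `paths` written.
#' @export
run_pipeline <- function(config = sim_config(), out_dir,
                         qc = qc_config(), lod_thresholds = 8:18) {
  fixture_dir <- file.path(out_dir, "fixture")
  sim <- simulate_cross(config)
  obs <- sample_observed_calls(sim, config)
  paths <- write_fixture(obs, fixture_dir)

  vt <- read_vcf(paths[["vcf"]])
  scf <- read_scaffold_map(paths[["scaffolds"]])
  ref <- read_reference_map(paths[["reference_map"]])
  primers <- utils::read.delim(paths[["primers"]], stringsAsFactors = FALSE)
  hits <- read_blast_tab(paths[["primer_hits"]], primers)

  qcres <- run_qc_cascade(vt, vt$parents, qc)
  map <- build_linkage_map(qcres$markers, lod_thresholds, reference = ref,
                           target_n = config$n_chromosomes)
  anch <- anchor_map(map, scf, ref)
  clen <- stats::setNames(scf$contig_length_bp, scf$contig_id)
  placements <- place_primer_pairs(hits, clen)
  summ <- summarize_map(anch)

  wt <- function(d, f) {
    p <- file.path(out_dir, f)
    utils::write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  mk <- anch$map$markers
  mk$scaffold_id <- scf$scaffold_id[match(mk$contig_id, scf$contig_id)]
  out_paths <- c(paths,
    map = wt(mk[, c("marker_id", "contig_id", "scaffold_id", "group", "bin",
                    "position")], "map.tsv"),
    qc_report = wt(qcres$report, "qc_report.tsv"),
    contigs = wt(anch$contigs, "contig_placements.tsv"),
    scaffolds = wt(anch$scaffolds, "scaffold_placements.tsv"),
    contig_spans = wt(anch$report$contig_spans, "discordant_contigs.tsv"),
    scaffold_gaps = wt(anch$report$scaffold_gaps, "scaffold_gaps.tsv"),
    scaffold_splits = wt(anch$report$scaffold_splits, "scaffold_splits.tsv"),
    primer_placements = wt(placements, "primer_placements.tsv"),
    summary = wt(summ$per_group, "map_summary.tsv"))
  manifest <- list(
    package = "anchormap",
    version = as.character(utils::packageVersion("anchormap")),
    seed = config$seed,
    thresholds = list(min_call_depth = qc$min_call_depth,
                      binomial_alpha = qc$binomial_alpha,
                      min_call_rate = qc$min_call_rate,
                      seg_p_threshold = qc$seg_p_threshold,
                      lod_min = min(lod_thresholds),
                      lod_max = max(lod_thresholds),
                      lod_selected = map$threshold),
    files = as.list(out_paths))
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  out_paths <- c(out_paths, manifest = mf)
  invisible(list(qc = qcres, map = map, anchored = anch,
                 placements = placements, summary = summ, paths = out_paths))
}
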