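## End-to-end pipeline on the synthetic toy genome ----------------------------

#' Run the full analysis pipeline on a synthetic dataset
#'
#' simulate -> merge replicates -> call peaks -> blacklist filter ->
#' union list -> quantify/normalize -> annotate + enrichment ->
#' chromatin states (per-tissue multi-mark and one-mark across-tissues)
#' -> marking groups + expression integration -> dELS linkage ->
#' pairwise differential marking between the first two tissues. Writes
#' every table as TSV under `outdir` and returns the main objects.
#'
#' @param config a [synthetic_config()]
#' @param outdir output directory for TSV surfaces
#' @param k_states states for the per-tissue model
#' @param k_states_across states for the across-tissues model (default
#'   `n_tissues + 2`)
#' @param blacklist optional interval table of excluded regions
#' @param mark_la the lactylation-type mark driving the across-tissues
#'   mode and the differential comparison
#' @return list of intermediate results, invisibly
#' @export
run_pipeline <- function(config, outdir, k_states = 5L,
                         k_states_across = NULL, blacklist = NULL,
                         mark_la = "H3K18la") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ds <- simulate_dataset(config)
  ann <- ds$annotation
  write_synthetic_dataset(ds, file.path(outdir, "simulated"))

  ## peak calling on merged tracks
  peaks <- list()
  for (ts in config$tissues) {
    peaks[[ts]] <- list()
    for (mk in config$marks) {
      p <- call_peaks_stringent(ds$merged[[ts]][[mk]],
                                sample = paste(ts, mk, sep = "_"))
      p <- filter_blacklist(p, blacklist)
      peaks[[ts]][[mk]] <- p
      write_peaks(p, file.path(outdir,
                               sprintf("peaks_%s_%s.bed", ts, mk)))
    }
  }
  master <- union_peaks(unlist(peaks, recursive = FALSE))
  write_bed(master, file.path(outdir, "master_peaks.bed"))

  ## master-list quantification (all tissue/mark merged tracks)
  all_tracks <- list()
  for (ts in config$tissues) for (mk in config$marks)
    all_tracks[[paste(ts, mk, sep = "_")]] <- ds$merged[[ts]][[mk]]
  qm <- quantify(all_tracks, master)
  write_quant(normalize_quant(qm, "CPM"),
              file.path(outdir, "master_cpm.tsv"))

  ## 3000-bp tile MDS over per-replicate tracks
  rep_tracks <- list()
  for (ts in config$tissues) for (mk in config$marks) {
    reps <- ds$tracks[[ts]][[mk]]
    for (r in seq_along(reps))
      rep_tracks[[sprintf("%s_%s_rep%d", ts, mk, r)]] <- reps[[r]]
  }
  tiles <- tile_genome(ann$chrom_sizes, 3000)
  mds <- mds_embed(normalize_quant(quantify(rep_tracks, tiles),
                                   "log2CPM"))
  write_tsv(data.table(sample = rownames(mds$coords),
                       dim1 = mds$coords[, 1], dim2 = mds$coords[, 2]),
            file.path(outdir, "mds_samples.tsv"))

  ## annotation and enrichment for the lactylation mark, first tissue
  catalog <- feature_catalog(ann)
  ts1 <- config$tissues[1]
  p1 <- peaks[[ts1]][[mark_la]]
  write_tsv(annotate_peaks(p1, catalog),
            file.path(outdir, sprintf("annotated_%s_%s.tsv", ts1, mark_la)))
  enr <- vapply(catalog$features, function(f) {
    if (intervals_bp(f) == 0) return(NA_real_)
    feature_fold_enrichment(p1, f, catalog$genome_size)
  }, 0)
  write_tsv(data.table(feature = names(enr), fold_enrichment = enr),
            file.path(outdir, "feature_enrichment.tsv"))
  write_tsv(tss_profile(p1, ann),
            file.path(outdir, "tss_profile.tsv"))

  ## chromatin states: per-tissue multi-mark
  bt <- binarize_tracks(ds$merged[[ts1]])
  model <- fit_hmm(bt, K = k_states, seed = config$seed)
  write_hmm_json(model, file.path(outdir, "hmm_per_tissue.json"))
  seg <- segment_states(model, bt)
  write_tsv(seg, file.path(outdir, "segmentation_per_tissue.tsv"))

  ## across-tissues mode: one mark, channels = tissues
  kx <- k_states_across %||% (config$n_tissues + 2L)
  bt_x <- binarize_tracks(setNames(
    lapply(config$tissues, function(ts) ds$merged[[ts]][[mark_la]]),
    config$tissues))
  model_x <- fit_hmm(bt_x, K = kx, seed = config$seed)
  write_hmm_json(model_x, file.path(outdir, "hmm_across_tissues.json"))
  seg_x <- segment_states(model_x, bt_x)
  els <- ds$truth$elements
  el_sets <- split(els[, .(chrom, start, end)], els$class)
  enr_x <- state_enrichment(seg_x, el_sets)
  write_tsv(data.table(state = rownames(enr_x), as.data.table(enr_x)),
            file.path(outdir, "state_enrichment_across_tissues.tsv"))

  ## marking groups + expression integration, first tissue
  prom <- catalog$promoters
  marking <- build_marking_table(
    data.table(chrom = prom$chrom, start = prom$start, end = prom$end,
               gene_id = prom$gene_id, element_id = prom$gene_id),
    peaks[[ts1]][c(mark_la, "H3K27ac", "H3K4me3")])
  write_tsv(venn_counts(marking), file.path(outdir, "promoter_venn.tsv"))
  groups <- assign_groups(marking)
  expr <- ds$expression[[ts1]]
  expr_tab <- data.table(gene_id = expr$gene_id,
                         log2rpkm = log2(expr$count * 1e9 /
                                           (sum(expr$count) *
                                              expr$length_bp) + 1))
  ebg <- expression_by_group(groups, expr_tab)
  write_tsv(ebg$stats, file.path(outdir, "expression_by_group.tsv"))
  write_tsv(ebg$tests, file.path(outdir, "expression_group_tests.tsv"))

  ## dELS linkage and top-ranked genes
  dels <- els[class %in% c("dELS_shared", "dELS_tissue_specific"),
              .(chrom, start, end)]
  links <- link_dels_to_genes(dels, ann)
  write_tsv(links, file.path(outdir, "dels_gene_links.tsv"))
  dels_qm <- quantify(setNames(list(ds$merged[[ts1]][[mark_la]]), ts1),
                      dels)
  write_tsv(top_ranked_dels(dels_qm, ann, n = min(50, nrow(dels))),
            file.path(outdir, "top_dels_genes.tsv"))

  ## differential marking between the first two tissues
  diff <- NULL
  if (config$n_tissues >= 2L) {
    ts2 <- config$tissues[2]
    pair_master <- union_peaks(list(peaks[[ts1]][[mark_la]],
                                    peaks[[ts2]][[mark_la]]))
    qa <- quantify(setNames(ds$tracks[[ts1]][[mark_la]],
                            paste0(ts1, "_rep",
                                   seq_len(config$replicates))),
                   pair_master)
    qb <- quantify(setNames(ds$tracks[[ts2]][[mark_la]],
                            paste0(ts2, "_rep",
                                   seq_len(config$replicates))),
                   pair_master)
    diff <- differential_regions(qa, qb)
    write_tsv(diff, file.path(outdir, "differential_regions.tsv"))
  }

  invisible(list(dataset = ds, peaks = peaks, master = master,
                 quant = qm, mds = mds, catalog = catalog,
                 model = model, segmentation = seg,
                 model_across = model_x, enrichment_across = enr_x,
                 marking = marking, groups = groups,
                 expression_by_group = ebg, links = links, diff = diff))
}
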