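## Synthetic multi-tissue, multi-mark dataset generator -----------------------
##
## Emulates the statistical structure of sparse-background CUT&Tag
## coverage plus matched RNA-seq on a toy genome: genes with strand-aware
## TSS, CpG islands at housekeeping promoters, ENCODE-style element
## classes (PLS within 200 bp of a TSS, pELS at 200-2000 bp, dELS beyond
## 2000 bp), per-(mark, element-class) occupancy probabilities, Poisson
## micro-bin coverage with a fold-enrichment inside occupied elements,
## and expression whose log-mean follows the planted promoter marking.

#' Default per-(mark, element-class) occupancy probabilities
#'
#' Encodes the planted co-occurrence structure: H3K4me3 at promoters,
#' H3K27ac at active promoters and enhancers, H3K18la at active CGI
#' promoters and (tissue-specifically) at distal enhancers, H3K27me3 at
#' poised promoters. For `dELS_tissue_specific` the probability applies
#' to the owning tissue only; every other tissue's occupancy is 0 by
#' construction.
#'
#' @return data.table with columns mark, element_class, prob
#' @export
default_occupancy <- function() {
  rbindlist(list(
    data.table(mark = "H3K18la",
               element_class = c("CGI_promoter_active", "nonCGI_promoter_active",
                                 "promoter_poised", "pELS", "dELS_shared",
                                 "dELS_tissue_specific"),
               prob = c(0.90, 0.50, 0.05, 0.50, 0.60, 0.90)),
    data.table(mark = "H3K27ac",
               element_class = c("CGI_promoter_active", "nonCGI_promoter_active",
                                 "promoter_poised", "pELS", "dELS_shared",
                                 "dELS_tissue_specific"),
               prob = c(0.85, 0.85, 0.05, 0.80, 0.90, 0.90)),
    data.table(mark = "H3K4me3",
               element_class = c("CGI_promoter_active", "nonCGI_promoter_active",
                                 "promoter_poised", "pELS", "dELS_shared",
                                 "dELS_tissue_specific"),
               prob = c(0.95, 0.90, 0.80, 0.30, 0.05, 0.05)),
    data.table(mark = "H3K27me3",
               element_class = c("CGI_promoter_active", "nonCGI_promoter_active",
                                 "promoter_poised", "pELS", "dELS_shared",
                                 "dELS_tissue_specific"),
               prob = c(0.02, 0.05, 0.90, 0.05, 0.05, 0.05))
  ))
}

#' Build a validated synthetic-dataset configuration
#'
#' Defaults describe the package's standard toy world: 3 chromosomes of
#' 1 Mb, 60 genes, 3 tissues, 4 marks, Poisson background of 1 expected
#' count per 25-bp micro-bin and an 8-fold enrichment inside occupied
#' elements, two replicates per (tissue, mark).
#'
#' @param n_chroms number of chromosomes
#' @param chrom_length chromosome length, bp
#' @param n_genes total gene count (spread evenly over chromosomes)
#' @param frac_housekeeping fraction of genes flagged housekeeping; these
#'   always receive a CpG-island promoter and constitutive marking
#' @param n_tissues number of tissues
#' @param marks character vector of mark names (must appear in `occupancy`)
#' @param occupancy occupancy table, see [default_occupancy()]
#' @param background_rate expected background count per 25-bp micro-bin
#' @param enrichment_fold multiplier applied inside occupied elements
#' @param expression_noise_sd sd of the log2 expression noise
#' @param n_dels total number of distal enhancer-like elements
#' @param frac_dels_tissue_specific fraction of dELS that are
#'   tissue-specific (assigned round-robin to tissues)
#' @param frac_cgi_nonhk fraction of non-housekeeping genes with a CGI
#' @param frac_poised fraction of non-housekeeping genes with a poised
#'   promoter
#' @param replicates replicates per (tissue, mark)
#' @param micro_bin micro-bin width for coverage simulation, bp
#' @param expr_base base log2 expression
#' @param expr_slope slope of log2 expression on planted promoter intensity
#' @param seed master seed
#' @return a validated list of class `synthetic_config`
#' @export
synthetic_config <- function(n_chroms = 3L, chrom_length = 1e6, n_genes = 60L,
                             frac_housekeeping = 0.3, n_tissues = 3L,
                             marks = c("H3K18la", "H3K27ac", "H3K4me3",
                                       "H3K27me3"),
                             occupancy = default_occupancy(),
                             background_rate = 1, enrichment_fold = 8,
                             expression_noise_sd = 1,
                             n_dels = 60L, frac_dels_tissue_specific = 0.5,
                             frac_cgi_nonhk = 0.4, frac_poised = 0.2,
                             replicates = 2L, micro_bin = 25L,
                             expr_base = 3, expr_slope = 2, seed = 1L) {
  cfg <- list(n_chroms = as.integer(n_chroms),
              chrom_length = as.numeric(chrom_length),
              n_genes = as.integer(n_genes),
              frac_housekeeping = frac_housekeeping,
              n_tissues = as.integer(n_tissues),
              tissues = paste0("tissue", seq_len(n_tissues)),
              marks = marks, occupancy = as.data.table(occupancy),
              background_rate = background_rate,
              enrichment_fold = enrichment_fold,
              expression_noise_sd = expression_noise_sd,
              n_dels = as.integer(n_dels),
              frac_dels_tissue_specific = frac_dels_tissue_specific,
              frac_cgi_nonhk = frac_cgi_nonhk, frac_poised = frac_poised,
              replicates = as.integer(replicates),
              micro_bin = as.integer(micro_bin),
              expr_base = expr_base, expr_slope = expr_slope,
              seed = as.integer(seed))
  assert_that(cfg$n_chroms >= 1L && cfg$chrom_length > 0 && cfg$n_genes >= 1L,
              "counts must be positive")
  assert_that(cfg$n_tissues >= 1L && cfg$replicates >= 1L && cfg$n_dels >= 0L,
              "counts must be positive")
  for (f in c("frac_housekeeping", "frac_dels_tissue_specific",
              "frac_cgi_nonhk", "frac_poised"))
    assert_that(cfg[[f]] >= 0 && cfg[[f]] <= 1, "%s must be in [0,1]", f)
  assert_that(cfg$background_rate > 0, "background_rate must be > 0")
  assert_that(cfg$enrichment_fold >= 1, "enrichment_fold must be >= 1")
  assert_that(cfg$expression_noise_sd >= 0, "expression_noise_sd must be >= 0")
  assert_that(all(cfg$occupancy$prob >= 0 & cfg$occupancy$prob <= 1),
              "occupancy probabilities must be in [0,1]")
  assert_that(all(cfg$marks %in% unique(cfg$occupancy$mark)),
              "every mark needs occupancy entries")
  structure(cfg, class = "synthetic_config")
}

## snap a coordinate to the micro-bin grid so planted element boundaries
## coincide with simulation bins
snap <- function(x, bin) round(x / bin) * bin

#' Generate the toy genome: gene models, CGIs, elements, ground truth
#'
#' Genes are laid out on a regular grid of slots so that every gene has
#' room for its promoter window (+/-2000 bp of TSS), a proximal
#' enhancer-like element (pELS, 200-2000 bp from the TSS) and a distal
#' enhancer-like element (dELS, placed > 2000 bp from every TSS).
#' Housekeeping genes always receive a CpG island over the TSS and the
#' `CGI_promoter_active` class; non-housekeeping genes are split into
#' poised and active (CGI or non-CGI) promoters. Tissue-specific dELS
#' are assigned to tissues round-robin so each tissue owns a non-empty
#' specific-enhancer truth set. Occupancy indicators are drawn per
#' (element, mark, tissue): constitutively (one shared draw across
#' tissues) for housekeeping promoters, independently per tissue for
#' other elements, and zero outside the owning tissue for
#' tissue-specific dELS.
#'
#' @param config a [synthetic_config()]
#' @return list with `annotation` (class `GenomeAnnotation`: genes, cgi,
#'   exons, chrom_sizes, elements) and `truth` (elements with classes,
#'   occupancy indicators, per-gene planted promoter intensity per tissue)
#' @export
generate_genome <- function(config) {
  cfg <- config
  set.seed(sub_seed(cfg$seed, "genome"))
  mb <- cfg$micro_bin
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  chrom_sizes <- setNames(rep(cfg$chrom_length, cfg$n_chroms), chroms)

  genes_per_chrom <- diff(round(seq(0, cfg$n_genes,
                                    length.out = cfg$n_chroms + 1)))
  slot <- floor(cfg$chrom_length / pmax(genes_per_chrom, 1L))
  ## a slot must hold promoter (4 kb) + clearance for a dELS > 2 kb from
  ## the two flanking TSS plus element widths
  assert_that(all(slot[genes_per_chrom > 0] >= 16500),
              "chromosome too short to place %d genes with valid element classes",
              max(genes_per_chrom))

  genes <- list(); cgis <- list(); exons <- list()
  pls <- list(); pels <- list()
  gi <- 0L
  for (ci in seq_len(cfg$n_chroms)) {
    ng <- genes_per_chrom[ci]
    if (ng == 0L) next
    for (si in seq_len(ng)) {
      gi <- gi + 1L
      slot_start <- (si - 1L) * slot[ci]
      tss <- snap(slot_start + 3000 + floor(runif(1) * 1000), mb)
      strand <- sample(c("+", "-"), 1L)
      glen <- snap(2000 + floor(runif(1) * 6000), mb)
      if (strand == "+") {
        gstart <- tss; gend <- min(tss + glen, cfg$chrom_length)
      } else {
        gend <- tss; gstart <- max(tss - glen, 0)
      }
      gene_id <- sprintf("gene%03d", gi)
      genes[[gi]] <- data.table(
        gene_id = gene_id, chrom = chroms[ci], strand = strand,
        tss = tss, gene_start = gstart, gene_end = gend,
        length = gend - gstart, biotype = "protein_coding")
      ## three exons spanning the body; UTR features derive from these
      b <- sort(unique(c(gstart, snap(gstart + (gend - gstart) * c(.2, .4, .6, .8), mb), gend)))
      if (length(b) >= 4) {
        e1 <- c(b[1], b[2]); e2 <- c(b[3], b[4])
        e3 <- c(b[length(b) - 1], b[length(b)])
        ex <- data.table(gene_id = gene_id, chrom = chroms[ci],
                         start = c(e1[1], e2[1], e3[1]),
                         end = c(e1[2], e2[2], e3[2]))
        exons[[gi]] <- ex[start < end]
      }
      ## PLS: core promoter element within 200 bp of the TSS
      pls[[gi]] <- data.table(chrom = chroms[ci],
                              start = max(tss - 100, 0), end = tss + 100,
                              gene_id = gene_id)
      ## pELS: 300 bp element 500-1500 bp upstream of the TSS
      off <- snap(500 + floor(runif(1) * 1000), mb)
      pstart <- if (strand == "+") tss - off - 300 else tss + off
      pels[[gi]] <- data.table(chrom = chroms[ci],
                               start = max(pstart, 0),
                               end = max(pstart, 0) + 300,
                               gene_id = gene_id)
    }
  }
  genes <- rbindlist(genes)
  n <- nrow(genes)
  genes[, housekeeping := FALSE]
  hk_n <- round(cfg$frac_housekeeping * n)
  if (hk_n > 0) genes$housekeeping[sample.int(n, hk_n)] <- TRUE

  ## CGI assignment and promoter classes
  genes[, has_cgi := housekeeping | (runif(n) < cfg$frac_cgi_nonhk)]
  poised <- !genes$housekeeping & (runif(n) < cfg$frac_poised)
  genes[, promoter_class := ifelse(poised, "promoter_poised",
                            ifelse(has_cgi, "CGI_promoter_active",
                                   "nonCGI_promoter_active"))]
  cgis <- genes[has_cgi == TRUE,
                .(chrom, start = pmax(tss - 400, 0), end = tss + 400)]

  ## dELS: placed in the clear zone of each slot, > 2000 bp from all TSS
  dels <- list()
  if (cfg$n_dels > 0L) {
    dc <- rep(seq_len(cfg$n_chroms), length.out = cfg$n_dels)
    counter <- integer(cfg$n_chroms)
    for (k in seq_len(cfg$n_dels)) {
      ci <- dc[k]
      ng <- max(genes_per_chrom[ci], 1L)
      counter[ci] <- counter[ci] + 1L
      si <- ((counter[ci] - 1L) %% ng) + 1L
      slot_start <- (si - 1L) * slot[ci]
      lo <- slot_start + 13000
      hi <- min(slot_start + slot[ci] - 3000, cfg$chrom_length - 400)
      assert_that(hi > lo, "chromosome too short to place dELS clear of promoters")
      s <- snap(lo + floor(runif(1) * (hi - lo)), mb)
      dels[[k]] <- data.table(chrom = chroms[ci], start = s, end = s + 350)
    }
    dels <- rbindlist(dels)
    ## class split: shared vs tissue-specific, round-robin ownership
    nspec <- round(cfg$frac_dels_tissue_specific * nrow(dels))
    cls <- c(rep("dELS_tissue_specific", nspec),
             rep("dELS_shared", nrow(dels) - nspec))
    dels[, class := cls]
    dels[, owner_tissue := NA_character_]
    if (nspec > 0)
      dels$owner_tissue[seq_len(nspec)] <-
        rep(cfg$tissues, length.out = nspec)
  } else {
    dels <- data.table(chrom = character(), start = numeric(),
                       end = numeric(), class = character(),
                       owner_tissue = character())
  }
  ## guard: no dELS within 2000 bp of any TSS
  prox <- merge_intervals(genes[, .(chrom, start = pmax(tss - 2000, 0),
                                    end = tss + 2000)])
  assert_that(!any(overlaps_any(dels[, .(chrom, start, end)], prox)),
              "dELS placement violated the >2000 bp promoter clearance")

  ## element truth table
  pls <- rbindlist(pls); pels <- rbindlist(pels)
  promoters <- genes[, .(chrom, start = pmax(tss - 2000, 0),
                         end = pmin(tss + 2000, cfg$chrom_length),
                         gene_id, class = promoter_class)]
  elements <- rbindlist(list(
    promoters[, .(chrom, start, end, class, gene_id,
                  owner_tissue = NA_character_)],
    pls[, .(chrom, start, end, class = "PLS", gene_id,
            owner_tissue = NA_character_)],
    pels[, .(chrom, start, end, class = "pELS", gene_id,
             owner_tissue = NA_character_)],
    dels[, .(chrom, start, end, class, gene_id = NA_character_,
             owner_tissue)]
  ))
  elements[, element_id := sprintf("el%04d", .I)]

  ## occupancy indicators per (element, mark, tissue).
  ## Occupancy classes: PLS inherits its gene's promoter class (it sits
  ## inside the promoter window); pELS of a poised gene inherits the
  ## poised class too - a poised promoter's proximal enhancer is not
  ## active, and both elements lie inside the +/-2000 bp window that
  ## the marking table scores, so an active pELS would contaminate the
  ## planted promoter Venn cell.
  occ_class <- elements$class
  occ_class[elements$class == "PLS"] <-
    genes$promoter_class[match(elements$gene_id[elements$class == "PLS"],
                               genes$gene_id)]
  pels_poised <- elements$class == "pELS" &
    genes$promoter_class[match(elements$gene_id,
                               genes$gene_id)] == "promoter_poised"
  occ_class[which(pels_poised)] <- "promoter_poised"
  probs <- cfg$occupancy
  hk_gene <- elements$gene_id %in% genes$gene_id[genes$housekeeping]
  occ <- list(); oi <- 0L
  for (mk in cfg$marks) {
    pmap <- setNames(probs[mark == mk]$prob, probs[mark == mk]$element_class)
    p_el <- unname(pmap[occ_class]); p_el[is.na(p_el)] <- 0
    ## constitutive draw for housekeeping-gene elements
    const_draw <- runif(nrow(elements)) < p_el
    for (ts in cfg$tissues) {
      draw <- runif(nrow(elements)) < p_el
      draw[hk_gene] <- const_draw[hk_gene]
      spec <- elements$class == "dELS_tissue_specific"
      draw[spec & !is.na(elements$owner_tissue) &
             elements$owner_tissue != ts] <- FALSE
      oi <- oi + 1L
      occ[[oi]] <- data.table(element_id = elements$element_id,
                              mark = mk, tissue = ts,
                              occupied = as.integer(draw))
    }
  }
  occupancy <- rbindlist(occ)

  ## planted promoter intensity per (gene, tissue): weighted sum of the
  ## active-mark indicators at the gene's promoter element
  w <- c(H3K18la = 1.0, H3K27ac = 0.6, H3K4me3 = 0.3)
  prom_ids <- elements[class %in% c("CGI_promoter_active",
                                    "nonCGI_promoter_active",
                                    "promoter_poised") &
                         !is.na(gene_id)]
  pocc <- occupancy[element_id %in% prom_ids$element_id &
                      mark %in% names(w)]
  pocc[, gene_id := prom_ids$gene_id[match(element_id, prom_ids$element_id)]]
  pocc[, weight := w[mark]]
  gene_truth <- pocc[, .(intensity = sum(weight * occupied)),
                     by = .(gene_id, tissue)]
  gene_truth[, true_log2_mean := cfg$expr_base + cfg$expr_slope * intensity]

  annotation <- structure(
    list(genes = genes[, .(gene_id, chrom, strand, tss, gene_start,
                           gene_end, length, biotype, housekeeping)],
         cgi = intervals(cgis$chrom, cgis$start, cgis$end),
         exons = rbindlist(exons),
         chrom_sizes = chrom_sizes,
         elements = elements),
    class = "GenomeAnnotation")
  truth <- list(elements = elements, occupancy = occupancy,
                genes = gene_truth)
  list(annotation = annotation, truth = truth)
}

#' @export
print.GenomeAnnotation <- function(x, ...) {
  cat(sprintf("GenomeAnnotation: %d genes on %d chromosome(s), %d CGIs, %d elements\n",
              nrow(x$genes), length(x$chrom_sizes), nrow(x$cgi),
              nrow(x$elements)))
  invisible(x)
}

#' Simulate a coverage track for one (mark, tissue, replicate)
#'
#' Poisson counts per 25-bp micro-bin with mean `background_rate`,
#' multiplied by `enrichment_fold` inside elements whose planted
#' (mark, class, tissue) occupancy indicator is 1, then run-length
#' aggregated into a bedGraph-style [signal_track()].
#'
#' @param annotation from [generate_genome()]
#' @param truth from [generate_genome()]
#' @param mark,tissue names present in the configuration
#' @param config the [synthetic_config()]
#' @param replicate replicate index (drives the sub-seed)
#' @return a [signal_track()]
#' @export
simulate_coverage <- function(annotation, truth, mark, tissue, config,
                              replicate = 1L) {
  cfg <- config
  assert_that(mark %in% cfg$marks, "unknown mark '%s'", mark)
  assert_that(tissue %in% cfg$tissues, "unknown tissue '%s'", tissue)
  set.seed(sub_seed(cfg$seed, "coverage", mark, tissue, replicate))
  mb <- cfg$micro_bin
  .mark <- mark; .tissue <- tissue
  occ <- truth$occupancy[mark == .mark & tissue == .tissue & occupied == 1L]
  els <- truth$elements[element_id %in% occ$element_id]
  out <- vector("list", length(annotation$chrom_sizes))
  for (i in seq_along(annotation$chrom_sizes)) {
    ch <- names(annotation$chrom_sizes)[i]
    len <- annotation$chrom_sizes[[i]]
    nb <- ceiling(len / mb)
    rate <- rep(cfg$background_rate, nb)
    ech <- els[chrom == ch]
    if (nrow(ech)) {
      for (j in seq_len(nrow(ech))) {
        b0 <- floor(ech$start[j] / mb) + 1L
        b1 <- ceiling(ech$end[j] / mb)
        rate[b0:min(b1, nb)] <- cfg$background_rate * cfg$enrichment_fold
      }
    }
    counts <- rpois(nb, rate)
    r <- rle(counts)
    ends <- cumsum(r$lengths) * mb
    starts <- ends - r$lengths * mb
    ends[length(ends)] <- min(ends[length(ends)], len)
    keep <- r$values > 0
    out[[i]] <- data.table(chrom = ch, start = starts[keep],
                           end = ends[keep], value = r$values[keep])
  }
  signal_track(rbindlist(out), annotation$chrom_sizes)
}

#' Simulate a gene-level expression table for one tissue
#'
#' Log2 mean expression = `expr_base + expr_slope * intensity + N(0, sd)`
#' where `intensity` is the planted promoter-mark intensity from the
#' truth tables (H3K18la-dominated weighted indicator sum). Counts are
#' the rounded linear-scale means, so the map from intensity to
#' expression is exactly monotone when `expression_noise_sd = 0`.
#'
#' @param annotation,truth from [generate_genome()]
#' @param tissue tissue name
#' @param config the [synthetic_config()]
#' @param replicate replicate index
#' @return data.table (class `ExpressionTable`): gene_id, count,
#'   length_bp, tissue, replicate
#' @export
simulate_expression <- function(annotation, truth, tissue, config,
                                replicate = 1L) {
  cfg <- config
  assert_that(tissue %in% cfg$tissues, "unknown tissue '%s'", tissue)
  set.seed(sub_seed(cfg$seed, "expression", tissue, replicate))
  .tissue <- tissue
  gt <- truth$genes[tissue == .tissue]
  gt <- gt[match(annotation$genes$gene_id, gene_id)]
  noise <- rnorm(nrow(gt), 0, cfg$expression_noise_sd)
  log2_mean <- gt$true_log2_mean + noise
  out <- data.table(gene_id = annotation$genes$gene_id,
                    count = round(2^log2_mean),
                    length_bp = annotation$genes$length,
                    tissue = tissue, replicate = as.integer(replicate))
  setattr(out, "class", c("ExpressionTable", class(out)))
  out[]
}

#' Simulate the full dataset: genome, all coverage tracks, expression
#'
#' Convenience wrapper used by the end-to-end pipeline and the test
#' suite. Replicate tracks get distinct sub-seeds; merged tracks (the
#' replicate mean) are what the peak caller and the binarizer consume.
#'
#' @param config a [synthetic_config()]
#' @return list: `annotation`, `truth`, `tracks` (nested
#'   `[[tissue]][[mark]]` list of replicate [signal_track()]s), `merged`
#'   (replicate-mean tracks), `expression` (one table per tissue)
#' @export
simulate_dataset <- function(config) {
  g <- generate_genome(config)
  tracks <- list(); merged <- list()
  for (ts in config$tissues) {
    tracks[[ts]] <- list(); merged[[ts]] <- list()
    for (mk in config$marks) {
      reps <- lapply(seq_len(config$replicates), function(r)
        simulate_coverage(g$annotation, g$truth, mk, ts, config, r))
      tracks[[ts]][[mk]] <- reps
      merged[[ts]][[mk]] <- merge_replicates(reps)
    }
  }
  expr <- lapply(setNames(config$tissues, config$tissues), function(ts)
    simulate_expression(g$annotation, g$truth, ts, config))
  list(annotation = g$annotation, truth = g$truth, tracks = tracks,
       merged = merged, expression = expr, config = config)
}

#' Write a simulated dataset to disk in plain-text formats
#'
#' bedGraph per (tissue, mark, replicate), BED6 element sets with the
#' class in the name field, TSV gene models, expression counts and truth
#' tables, plus a chromosome-sizes file.
#'
#' @param dataset from [simulate_dataset()]
#' @param outdir output directory (created if needed)
#' @return `outdir`, invisibly
#' @export
write_synthetic_dataset <- function(dataset, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ann <- dataset$annotation
  write_tsv(ann$genes, file.path(outdir, "genes.tsv"))
  write_bed(ann$cgi, file.path(outdir, "cgi.bed"))
  els <- ann$elements
  write_bed(intervals(els$chrom, els$start, els$end, name = els$class),
            file.path(outdir, "elements.bed"))
  write_tsv(dataset$truth$occupancy, file.path(outdir, "truth_occupancy.tsv"))
  write_tsv(dataset$truth$genes, file.path(outdir, "truth_genes.tsv"))
  sizes <- data.table(chrom = names(ann$chrom_sizes),
                      size = as.numeric(ann$chrom_sizes))
  data.table::fwrite(sizes, file.path(outdir, "chrom.sizes"), sep = "\t",
                     col.names = FALSE)
  for (ts in names(dataset$tracks))
    for (mk in names(dataset$tracks[[ts]])) {
      reps <- dataset$tracks[[ts]][[mk]]
      for (r in seq_along(reps))
        write_bedgraph(reps[[r]], file.path(
          outdir, sprintf("%s_%s_rep%d.bedgraph", ts, mk, r)))
      write_bedgraph(dataset$merged[[ts]][[mk]], file.path(
        outdir, sprintf("%s_%s_merged.bedgraph", ts, mk)))
    }
  for (ts in names(dataset$expression))
    write_tsv(dataset$expression[[ts]],
              file.path(outdir, sprintf("expression_%s.tsv", ts)))
  invisible(outdir)
}
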