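# End-to-end discovery workflow: profile models -> search -> size /
# core-gene / completeness filters -> de-replication -> protein clustering
# -> clade classification + synteny -> host linkage, with per-stage file
# outputs, a run manifest, and reproducible seeding throughout.

#' Pipeline configuration with the published default thresholds
#'
#' Aggregates every stage parameter: profile-search E-value 1e-6, 30/70
#' model clustering, 95/95 gene and 95/80 contig de-replication, 10 kb HQ
#' size filter, ITR >= 100 bp and circular overlap >= 20 nt, protein-cluster
#' thresholds 30 / 0.01 and the profile-merge disjuncts 90/50 and 99/20/100,
#' prevalence bands 25-60% / <25%, clade collapse 1.2 / 0.8, and the
#' MIMIVIRE 24-30 nt seed with 18-nt repeat unit.
#'
#' @param seed RNG seed used for every stochastic stage.
#' @param ... overrides for any default listed above.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    search_e_cut = 1e-6,
    assign_e_cut = 1e-3,
    model_identity_cut = 0.30,
    model_align_frac = 0.70,
    model_rounds = 2,
    recruit_min_len_nt = 700,
    mcp_mean_aa = 593,
    mcp_sd_aa = 40.1,
    derep_gene_id = 0.95, derep_gene_cov = 0.95,
    derep_contig_id = 0.95, derep_contig_cov = 0.80,
    min_genome_len = 10000,
    min_overlap = 20,
    min_itr = 100,
    itr_window = 5000,
    pc_score_min = 30, pc_e_max = 0.01,
    pc_prob1 = 0.90, pc_cov1 = 0.50,
    pc_prob2 = 0.99, pc_cov2 = 0.20, pc_len2 = 100,
    prevalence_common = c(0.25, 0.60),
    collapse_branch_len = 1.2,
    collapse_support = 0.8,
    bootstrap = 100,
    mimivire_len_range = c(24, 30),
    mimivire_unit_len = 18,
    mimivire_min_copies = 2,
    orf_min_len = 100,
    n_decoys_calibration = 1000
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown pipeline_config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(dots)] <- dots
  class(cfg) <- "pipeline_config"
  cfg
}

stage_record <- function(manifest, name, n_in, n_out, t0, files = character(0)) {
  sums <- if (length(files)) as.character(tools::md5sum(files)) else character(0)
  el <- round(as.numeric(Sys.time() - t0, units = "secs"), 3)
  manifest$stages[[name]] <- list(
    n_in = n_in, n_out = n_out, elapsed_s = el, files = files, md5 = sums)
  if (isTRUE(getOption("lavidascope.verbose", FALSE)))
    message("[lavidascope] ", name, ": ", n_in, " -> ", n_out,
            " (", el, " s)")
  manifest
}

#' Run the discovery pipeline end to end
#'
#' Stages (in order): MCP model building/iteration, profile search of all
#' proteins, MCP completeness, gene-level (95/95) and contig-level (95/80)
#' de-replication, 10 kb size filter, per-contig core-gene assignment,
#' topology detection, quality tiering, protein clustering into VpPCs with
#' categorization, concatenated four-core-gene phylogeny with clade
#' collapse, synteny-block analysis, and (when giant-virus contigs are
#' supplied) MIMIVIRE host linkage. Stage outputs are written before the
#' next stage starts.
#'
#' @param contigs named DNA vector, or a `sim_corpus` (inputs taken from it).
#' @param config a [pipeline_config()].
#' @param annotations optional precomputed gene annotations (with proteins);
#'   ORFs are called when absent.
#' @param seed_alignments named list of per-core-gene seed alignments; names
#'   must start with the core-gene label (e.g. `MCP_L1`). Required.
#' @param habitats optional data.frame `contig_id`, `habitat`.
#' @param giant_contigs,giant_annotations optional giant-virus inputs.
#' @param out_dir output directory for stage files (default: none written).
#' @return list with all stage outputs and a `manifest`.
#' @export
run_discovery <- function(contigs, config = pipeline_config(),
                          annotations = NULL, seed_alignments = NULL,
                          habitats = NULL, giant_contigs = NULL,
                          giant_annotations = NULL, out_dir = NULL) {
  if (inherits(contigs, "sim_corpus")) {
    corpus <- contigs
    contigs <- corpus$contigs
    annotations <- annotations %||% corpus$annotations
    seed_alignments <- seed_alignments %||% corpus$seed_alignments
    habitats <- habitats %||% corpus$habitats
    giant_contigs <- giant_contigs %||% corpus$giant_contigs
    giant_annotations <- giant_annotations %||% corpus$giant_annotations
  }
  if (is.null(seed_alignments))
    stop("seed_alignments are required (per-core-gene seed families)",
         call. = FALSE)
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(obj, fname, writer = write_tsv_file) {
    if (is.null(out_dir)) return(character(0))
    path <- file.path(out_dir, fname)
    writer(obj, path)
    path
  }
  manifest <- list(version = as.character(utils::packageVersion("lavidascope")),
                   seed = config$seed, stages = list())
  set.seed(config$seed)

  # stage: gene calling ----------------------------------------------------
  t0 <- Sys.time()
  if (is.null(annotations)) {
    annotations <- call_orfs_all(contigs, min_len = config$orf_min_len)
  } else {
    ann_orf <- call_orfs_all(contigs[setdiff(names(contigs),
                                             annotations$contig_id)],
                             min_len = config$orf_min_len)
    if (!is.null(ann_orf) && nrow(ann_orf))
      annotations <- rbind(annotations, ann_orf)
  }
  annotations$product <- "other" # labels are discovered, never trusted
  proteins <- annotation_proteins(annotations)
  manifest <- stage_record(manifest, "gene_calling", length(contigs),
                           length(proteins), t0,
                           emit(annotations, "genes.gff3", write_gff3))

  # stage: MCP models ------------------------------------------------------
  t0 <- Sys.time()
  mcp_seeds <- seed_alignments[grepl("^MCP", names(seed_alignments))]
  other_seeds <- seed_alignments[!grepl("^MCP", names(seed_alignments))]
  it <- iterate_models(mcp_seeds, proteins, rounds = config$model_rounds,
                       min_len_nt = config$recruit_min_len_nt,
                       e_cut = config$search_e_cut,
                       n_decoys = config$n_decoys_calibration)
  mcp_models <- it$models
  manifest <- stage_record(manifest, "mcp_models", length(mcp_seeds),
                           length(mcp_models), t0)

  # stage: MCP search -------------------------------------------------------
  t0 <- Sys.time()
  mcp_hits <- do.call(rbind, lapply(mcp_models, profile_search,
                                    proteins = proteins,
                                    e_cut = config$search_e_cut))
  if (is.null(mcp_hits)) mcp_hits <- profile_search(mcp_models[[1]],
                                                    character(0))
  best_hits <- mcp_hits[order(mcp_hits$evalue), , drop = FALSE]
  best_hits <- best_hits[!duplicated(best_hits$protein_id), , drop = FALSE]
  candidate_contigs <- unique(sub("\\|.*$", "", best_hits$protein_id))
  manifest <- stage_record(manifest, "mcp_search", length(proteins),
                           length(candidate_contigs), t0,
                           emit(mcp_hits, "mcp_hits.tsv"))

  # stage: MCP completeness --------------------------------------------------
  t0 <- Sys.time()
  mcp_len <- nchar(proteins[best_hits$protein_id])
  completeness <- data.frame(
    protein_id = best_hits$protein_id, length_aa = as.integer(mcp_len),
    class = mcp_completeness(mcp_len, config$mcp_mean_aa, config$mcp_sd_aa),
    stringsAsFactors = FALSE)
  manifest <- stage_record(manifest, "mcp_completeness", nrow(best_hits),
                           nrow(completeness), t0,
                           emit(completeness, "mcp_completeness.tsv"))

  # stage: de-replication ----------------------------------------------------
  t0 <- Sys.time()
  mcp_prot <- proteins[best_hits$protein_id]
  derep_genes <- dereplicate(mcp_prot, id_thresh = config$derep_gene_id,
                             cov_thresh = config$derep_gene_cov,
                             mode = "gene")
  cand <- contigs[candidate_contigs]
  derep_contigs <- dereplicate(cand, id_thresh = config$derep_contig_id,
                               cov_thresh = config$derep_contig_cov,
                               mode = "contig")
  nr_contigs <- contigs[derep_contigs$representatives]
  manifest <- stage_record(manifest, "dereplication", length(cand),
                           length(nr_contigs), t0)

  # stage: size filter -------------------------------------------------------
  t0 <- Sys.time()
  big <- nr_contigs[nchar(nr_contigs) >= config$min_genome_len]
  manifest <- stage_record(manifest, "size_filter", length(nr_contigs),
                           length(big), t0)

  # stage: core-gene assignment ----------------------------------------------
  t0 <- Sys.time()
  core_models <- list()
  for (g in CORE_PLUS) {
    fams <- seed_alignments[grepl(paste0("^", g, "(_|$)"),
                                  names(seed_alignments))]
    if (g == "MCP") {
      core_models[[g]] <- mcp_models
    } else if (length(fams)) {
      core_models[[g]] <- lapply(seq_along(fams), function(i)
        build_profile(fams[[i]], model_id = sprintf("%s_%02d", g, i),
                      n_decoys = config$n_decoys_calibration))
    }
  }
  ann_cand <- annotations[annotations$contig_id %in% names(nr_contigs), ,
                          drop = FALSE]
  ann_cand <- assign_core_genes_by_contig(ann_cand, core_models,
                                          e_cut = config$assign_e_cut)
  manifest <- stage_record(manifest, "core_genes", nrow(ann_cand),
                           sum(ann_cand$product %in% CORE_GENES), t0,
                           emit(ann_cand, "core_genes.gff3", write_gff3))

  # stage: topology + quality tiers ------------------------------------------
  t0 <- Sys.time()
  topologies <- lapply(names(nr_contigs), function(id)
    detect_topology(nr_contigs[id], min_overlap = config$min_overlap,
                    min_itr = config$min_itr,
                    search_window = config$itr_window))
  names(topologies) <- names(nr_contigs)
  qc <- tier_quality(nr_contigs, ann_cand, topologies,
                     min_len = config$min_genome_len)
  hq_ids <- qc$contig_id[qc$quality %in% c("HQ", "HQ_complete")]
  manifest <- stage_record(manifest, "quality_tiers", length(nr_contigs),
                           length(hq_ids), t0, emit(qc, "qc_report.tsv"))

  # stage: protein clustering -------------------------------------------------
  t0 <- Sys.time()
  ge10_ids <- names(big)
  prot10 <- annotation_proteins(
    ann_cand[ann_cand$contig_id %in% ge10_ids, , drop = FALSE])
  pcres <- NULL
  pc_categories <- NULL
  if (length(prot10) >= 2 && length(hq_ids)) {
    pcres <- cluster_proteins(prot10, score_min = config$pc_score_min,
                              e_max = config$pc_e_max, seed = config$seed,
                              prob1 = config$pc_prob1, cov1 = config$pc_cov1,
                              prob2 = config$pc_prob2, cov2 = config$pc_cov2,
                              len2 = config$pc_len2)
    pc_categories <- categorize_pcs(pcres$pcs, hq_ids)
  }
  manifest <- stage_record(manifest, "protein_clusters", length(prot10),
                           length(pcres$pcs %||% list()), t0,
                           if (!is.null(pc_categories))
                             emit(pc_categories, "vppc_categories.tsv")
                           else character(0))

  # stage: phylogeny + clades --------------------------------------------------
  t0 <- Sys.time()
  clades <- NULL
  tree <- NULL
  if (length(hq_ids) >= 4) {
    per_gene <- list()
    for (g in CORE_GENES) {
      rows <- ann_cand[ann_cand$contig_id %in% hq_ids &
                         ann_cand$product == g, , drop = FALSE]
      seqs <- stats::setNames(rows$protein, rows$contig_id)
      per_gene[[g]] <- trim_alignment(align_proteins(seqs))
    }
    concat <- concatenate_alignments(per_gene)
    tree <- build_tree(concat, bootstrap = config$bootstrap,
                       seed = config$seed)
    clades <- collapse_clades(tree,
                              max_avg_branch_length = config$collapse_branch_len,
                              min_support = config$collapse_support)
    if (!is.null(out_dir))
      ape::write.tree(tree, file.path(out_dir, "core_gene_tree.nwk"))
  }
  manifest <- stage_record(manifest, "clades", length(hq_ids),
                           length(unique(clades$clade_id)), t0,
                           if (!is.null(clades))
                             emit(clades, "clades.tsv") else character(0))

  # stage: synteny --------------------------------------------------------------
  t0 <- Sys.time()
  ann_by_genome <- split(ann_cand[ann_cand$contig_id %in% hq_ids, , drop = FALSE],
                         ann_cand$contig_id[ann_cand$contig_id %in% hq_ids])
  synteny <- if (length(ann_by_genome))
    detect_synteny_blocks(ann_by_genome) else NULL
  manifest <- stage_record(manifest, "synteny", length(ann_by_genome),
                           length(ann_by_genome), t0,
                           if (!is.null(synteny))
                             emit(synteny$blocks, "synteny.tsv")
                           else character(0))

  # stage: host linkage ----------------------------------------------------------
  t0 <- Sys.time()
  links <- NULL
  if (length(giant_contigs)) {
    links <- link_all(big, giant_contigs, giant_annotations,
                      len_range = config$mimivire_len_range,
                      unit_len = config$mimivire_unit_len,
                      min_copies = config$mimivire_min_copies)
  }
  manifest <- stage_record(manifest, "host_linkage",
                           length(giant_contigs %||% character(0)),
                           nrow(links %||% data.frame()), t0,
                           if (!is.null(links)) emit(links, "links.tsv")
                           else character(0))

  res <- list(config = config, manifest = manifest,
              annotations = ann_cand, proteins = proteins,
              mcp_models = mcp_models, mcp_hits = mcp_hits,
              completeness = completeness,
              derep_genes = derep_genes, derep_contigs = derep_contigs,
              qc = qc, hq_ids = hq_ids, topologies = topologies,
              pcs = pcres, pc_categories = pc_categories,
              tree = tree, clades = clades, synteny = synteny,
              links = links, habitats = habitats)
  class(res) <- "discovery_run"
  res
}

write_tsv_file <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summary tables for a discovery run
#'
#' Produces the per-contig QC table, per-clade composition (member count,
#' genome length statistics, habitat mix, dominant synteny signature and its
#' fraction), VpPC category counts, marker table and the host-link table.
#' Tables are well formed (headers only) when a stage had no input.
#'
#' @param run result of [run_discovery()].
#' @param out_dir optional directory to write the TSVs to.
#' @return named list of data.frames.
#' @export
pipeline_report <- function(run, out_dir = NULL) {
  qc <- run$qc
  clade_tab <- NULL
  if (!is.null(run$clades)) {
    hab <- if (!is.null(run$habitats))
      stats::setNames(run$habitats$habitat, run$habitats$contig_id) else NULL
    sig <- if (!is.null(run$synteny))
      stats::setNames(run$synteny$blocks$signature,
                      run$synteny$blocks$genome_id) else NULL
    lens <- stats::setNames(qc$length, qc$contig_id)
    clade_tab <- do.call(rbind, lapply(split(run$clades, run$clades$clade_id),
                                       function(cl) {
      ids <- cl$genome_id
      sg <- if (!is.null(sig)) table(sig[ids]) else table(character(0))
      top <- if (length(sg)) names(sg)[which.max(sg)] else ""
      data.frame(
        clade_id = cl$clade_id[1], n_members = length(ids),
        support = cl$support[1],
        len_mean = mean(lens[ids]), len_min = min(lens[ids]),
        len_max = max(lens[ids]),
        dominant_signature = top,
        signature_fraction = if (length(sg)) max(sg) / length(ids) else NA,
        habitats = if (!is.null(hab))
          paste(sort(unique(hab[ids])), collapse = ",") else "",
        stringsAsFactors = FALSE)
    }))
    rownames(clade_tab) <- NULL
  }
  cat_counts <- if (!is.null(run$pc_categories))
    as.data.frame(table(category = run$pc_categories$category),
                  stringsAsFactors = FALSE)
  else data.frame(category = character(0), Freq = integer(0))
  markers <- NULL
  if (!is.null(run$pcs)) {
    clmap <- if (!is.null(run$clades))
      stats::setNames(run$clades$clade_id, run$clades$genome_id) else NULL
    hbmap <- if (!is.null(run$habitats))
      stats::setNames(run$habitats$habitat, run$habitats$contig_id) else NULL
    markers <- pc_markers(run$pcs$pcs, clmap, hbmap)
  }
  out <- list(qc = qc,
              clades = clade_tab %||%
                data.frame(clade_id = character(0), n_members = integer(0)),
              pc_category_counts = cat_counts,
              markers = markers %||% data.frame(pc_id = character(0)),
              links = run$links %||% data.frame(virophage_id = character(0)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out))
      write_tsv_file(out[[nm]], file.path(out_dir, paste0("report_", nm, ".tsv")))
  }
  out
}
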