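# Synthetic metagenome generator with full ground truth: multi-gene dsDNA
# virophage contigs (core-gene cassettes, circular-overlap / ITR topologies),
# decoy contigs, and giant-virus contigs carrying planted MIMIVIRE seeds.
# Every planted feature is recorded so downstream stages can be scored
# exactly. All randomness flows from the config seed.

#' Configuration for the synthetic metagenome generator
#'
#' Defaults encode the study conditions the package is exercised under:
#' complete virophage genomes of 10.9-42.3 kb carrying the four core genes
#' (MCP, mCP, ATPase, PRO, optionally MTase) in lineage-specific orders,
#' circular genomes closed by a terminal duplication (assembler-overlap
#' convention), linear genomes with inverted terminal repeats of at least
#' 100 bp, and giant-virus contigs sharing a 27-nt MIMIVIRE seed whose 18-nt
#' substring recurs three times inside one giant-virus gene.
#'
#' @param seed integer RNG seed.
#' @param n_virophages,n_decoys,n_giant_viruses contig counts.
#' @param n_lineages number of planted lineages (clades).
#' @param genome_len_range virophage genome length range in bp.
#' @param core_gene_orders list of `list(genes=, strands=)` per lineage;
#'   `NULL` uses three built-in orders (5-gene ancestral block, 4-gene block
#'   with PRO reversed, and the ATPase-mCP-MCP colocalized order).
#' @param within_family_identity range of member identity to the lineage
#'   ancestor, per core gene.
#' @param lineage_identity identity of each lineage ancestor to the gene root;
#'   set to 0 to draw lineage ancestors independently (deep splits).
#' @param topology_mix named fractions `circular`/`itr`/`linear`, summing to 1.
#' @param itr_len_range inverted-terminal-repeat length range (bp).
#' @param circular_overlap_len terminal duplication length for circular
#'   genomes (bp).
#' @param hq_fraction fraction of virophages planted as high quality; the
#'   remainder are planted as partial (undersized or missing one non-MCP core
#'   gene).
#' @param gv_len_range giant-virus contig length range (bp).
#' @param mimivire_seed_len shared-seed length in nt (24-30).
#' @param mimivire_copies total copies of the 18-nt repeat unit inside the
#'   linked giant-virus gene (the seed occurrence plus inserted copies).
#' @param habitat_labels habitat vocabulary; lineages get a home habitat.
#' @param habitat_fidelity probability a virophage is assigned its lineage's
#'   home habitat.
#' @param decoy_len_range decoy contig length range (bp).
#' @param intergenic_len_range spacer length range inside the gene cassette.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_virophages = 50,
                       n_decoys = 100,
                       n_lineages = 3,
                       genome_len_range = c(10900, 42300),
                       core_gene_orders = NULL,
                       within_family_identity = c(0.6, 0.9),
                       lineage_identity = 0.55,
                       topology_mix = c(circular = 0.4, itr = 0.3, linear = 0.3),
                       itr_len_range = c(100, 500),
                       circular_overlap_len = 50,
                       hq_fraction = 0.8,
                       n_giant_viruses = 5,
                       gv_len_range = c(20000, 40000),
                       mimivire_seed_len = 27,
                       mimivire_copies = 3,
                       habitat_labels = c("freshwater", "marine", "soil", "human_gut"),
                       habitat_fidelity = 0.7,
                       decoy_len_range = c(5000, 20000),
                       intergenic_len_range = c(80, 400)) {
  if (length(within_family_identity) == 1)
    within_family_identity <- rep(within_family_identity, 2)
  cfg <- list(seed = seed, n_virophages = n_virophages, n_decoys = n_decoys,
              n_lineages = n_lineages, genome_len_range = genome_len_range,
              core_gene_orders = core_gene_orders,
              within_family_identity = within_family_identity,
              lineage_identity = lineage_identity,
              topology_mix = topology_mix, itr_len_range = itr_len_range,
              circular_overlap_len = circular_overlap_len,
              hq_fraction = hq_fraction,
              n_giant_viruses = n_giant_viruses, gv_len_range = gv_len_range,
              mimivire_seed_len = mimivire_seed_len,
              mimivire_copies = mimivire_copies,
              habitat_labels = habitat_labels,
              habitat_fidelity = habitat_fidelity,
              decoy_len_range = decoy_len_range,
              intergenic_len_range = intergenic_len_range)
  frac <- c(cfg$within_family_identity, cfg$lineage_identity,
            cfg$topology_mix, cfg$hq_fraction, cfg$habitat_fidelity)
  if (any(frac < 0 | frac > 1))
    stop("sim_config parameter error: fractions must lie in [0, 1]",
         call. = FALSE)
  if (abs(sum(cfg$topology_mix) - 1) > 1e-8)
    stop("sim_config parameter error: topology_mix must sum to 1",
         call. = FALSE)
  if (cfg$genome_len_range[1] < 1000)
    stop("sim_config parameter error: genome_len_range min must be >= 1000",
         call. = FALSE)
  if (cfg$mimivire_seed_len < 24 || cfg$mimivire_seed_len > 30)
    stop("sim_config parameter error: mimivire_seed_len must be in [24, 30]",
         call. = FALSE)
  if (is.null(cfg$core_gene_orders))
    cfg$core_gene_orders <- default_gene_orders(cfg$n_lineages)
  class(cfg) <- "sim_config"
  cfg
}

default_gene_orders <- function(n_lineages) {
  base <- list(
    list(genes = c("MTase", "PRO", "ATPase", "mCP", "MCP"),
         strands = c("+", "+", "+", "+", "+")),
    list(genes = c("PRO", "ATPase", "mCP", "MCP"),
         strands = c("-", "+", "+", "+")),
    list(genes = c("ATPase", "mCP", "MCP", "PRO"),
         strands = c("+", "+", "+", "+"))
  )
  base[((seq_len(n_lineages) - 1) %% length(base)) + 1]
}

# protein families --------------------------------------------------------

mutate_protein <- function(seq, identity, keep_first = TRUE) {
  res <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(res)
  k <- round((1 - identity) * L)
  candidates <- if (keep_first) 2:L else seq_len(L)
  k <- min(k, length(candidates))
  if (k > 0) {
    pos <- sample(candidates, k)
    res[pos] <- vapply(res[pos], function(a) sample(setdiff(AA20, a), 1),
                       character(1))
  }
  paste(res, collapse = "")
}

#' Generate a planted protein family
#'
#' Members are derived from a common ancestor by exact-count substitutions
#' (uniform over the 19 alternative residues, no indels), so each member's
#' identity to the ancestor equals `identity` up to rounding.
#'
#' @param ancestor_len ancestor length in aa (>= 30); ignored when `ancestor`
#'   is supplied.
#' @param n_members number of members (0 gives an empty family whose id is
#'   still allocated).
#' @param identity target identity to the ancestor, in (0, 1]; a length-2
#'   vector draws per-member identities uniformly from the range.
#' @param ancestor optional ancestor sequence to mutate from.
#' @param family_id family label (default auto).
#' @param prefix member id prefix.
#' @return list with `family_id`, `ancestor`, named `members`,
#'   and the realized `identities`.
#' @export
sim_protein_family <- function(ancestor_len, n_members, identity,
                               ancestor = NULL, family_id = NULL,
                               prefix = "fam") {
  if (any(identity <= 0) || any(identity > 1))
    stop("parameter error: identity must be in (0, 1]", call. = FALSE)
  if (is.null(ancestor)) {
    if (ancestor_len < 30)
      stop("parameter error: ancestor_len must be >= 30", call. = FALSE)
    ancestor <- random_protein(ancestor_len)
  }
  family_id <- family_id %||% paste0(prefix, "_",
                                     substr(ancestor, 2, 6))
  if (length(identity) == 1) identity <- rep(identity, 2)
  ids <- numeric(0)
  members <- character(0)
  if (n_members > 0) {
    ids <- stats::runif(n_members, identity[1], identity[2])
    members <- vapply(ids, function(p) mutate_protein(ancestor, p),
                      character(1))
    names(members) <- sprintf("%s_m%02d", family_id, seq_len(n_members))
  }
  list(family_id = family_id, ancestor = ancestor, members = members,
       identities = ids)
}

rev_codon_table <- function() {
  tab <- Biostrings::GENETIC_CODE
  split(names(tab), tab)
}

encode_protein <- function(protein) {
  tab <- rev_codon_table()
  res <- strsplit(protein, "", fixed = TRUE)[[1]]
  codons <- vapply(res, function(a) {
    ch <- tab[[a]]
    if (length(ch) == 1) ch else sample(ch, 1)
  }, character(1))
  codons[1] <- "ATG" # ATG-only starts keep the ORF caller faithful
  paste(c(codons, sample(STOP_CODONS, 1)), collapse = "")
}

# lineages ----------------------------------------------------------------

#' Lineage ancestors and gene orders for a configuration
#'
#' Draws one root protein per core gene and one diverged ancestor per
#' lineage. With `lineage_identity = 0` lineage ancestors are independent
#' random proteins (deep splits for phylogeny fixtures).
#'
#' @param config a [sim_config()].
#' @return list with `roots` (per gene) and `ancestors` (per lineage, per
#'   gene) plus the gene `orders`.
#' @export
sim_lineages <- function(config) {
  genes <- unique(unlist(lapply(config$core_gene_orders, `[[`, "genes")))
  genes <- union(CORE_GENES, genes)
  roots <- stats::setNames(
    vapply(CORE_LENGTHS[genes], random_protein, character(1)), genes)
  ancestors <- lapply(seq_len(config$n_lineages), function(li) {
    stats::setNames(vapply(genes, function(g) {
      if (config$lineage_identity > 0)
        mutate_protein(roots[[g]], config$lineage_identity)
      else random_protein(CORE_LENGTHS[[g]])
    }, character(1)), genes)
  })
  list(roots = roots, ancestors = ancestors,
       orders = config$core_gene_orders)
}

# virophage assembly -------------------------------------------------------

place_guard <- function(spacer, at = c("end", "start"), codon) {
  at <- match.arg(at)
  n <- nchar(spacer)
  if (n < 3) return(spacer)
  if (at == "end") paste0(substr(spacer, 1, n - 3), codon)
  else paste0(codon, substr(spacer, 4, n))
}

#' Generate one virophage genome with ground truth
#'
#' Assembles the lineage's core-gene cassette (genes separated by random
#' intergenic DNA, in-frame stop guards flanking each gene so called ORFs
#' match the planted coordinates exactly) into a genome of the configured
#' topology: circular genomes end with an exact duplicate of their first
#' `circular_overlap_len` bases; ITR genomes start and end with exact
#' reverse-complement repeats.
#'
#' @param config a [sim_config()].
#' @param lineage lineage index (1-based).
#' @param lineages output of [sim_lineages()] (generated from `config` if
#'   missing; supply it to share ancestors across genomes).
#' @param id contig id.
#' @param tier planted quality tier: `"HQ"`, `"partial_short"` (< 10 kb) or
#'   `"partial_missing"` (one non-MCP core gene removed).
#' @param topology `"circular"`, `"itr"` or `"linear"`; default drawn from
#'   `config$topology_mix`.
#' @return list with `seq`, `annotations`, and a `truth` record (topology,
#'   planted lengths, gene table, intergenic spans).
#' @export
sim_virophage <- function(config, lineage, lineages = NULL, id = "vp_1",
                          tier = "HQ", topology = NULL) {
  lineages <- lineages %||% sim_lineages(config)
  ord <- lineages$orders[[((lineage - 1) %% length(lineages$orders)) + 1]]
  genes <- ord$genes
  strands <- ord$strands
  if (tier == "partial_missing") {
    drop <- sample(intersect(genes, c("mCP", "ATPase", "PRO")), 1)
    keep <- genes != drop
    genes <- genes[keep]
    strands <- strands[keep]
  }
  anc <- lineages$ancestors[[lineage]]
  wfi <- config$within_family_identity
  proteins <- vapply(genes, function(g)
    mutate_protein(anc[[g]], stats::runif(1, wfi[1], wfi[2])), character(1))
  gene_nt <- vapply(proteins, encode_protein, character(1))
  segs <- ifelse(strands == "-", revcomp(gene_nt), gene_nt)

  nspace <- length(genes) + 1
  sl <- sample(seq(config$intergenic_len_range[1],
                   config$intergenic_len_range[2]), nspace, replace = TRUE)
  spacers <- vapply(sl, random_dna, character(1))
  for (i in seq_along(genes)) {
    if (strands[i] == "+")
      spacers[i] <- place_guard(spacers[i], "end", "TAA")
    else
      spacers[i + 1] <- place_guard(spacers[i + 1], "start", "TTA")
  }
  cassette <- paste0(paste0(spacers[seq_along(genes)], segs, collapse = ""),
                     spacers[nspace])
  clen <- nchar(cassette)

  topology <- topology %||% sample(names(config$topology_mix), 1,
                                   prob = config$topology_mix)
  reserve <- 1600L
  if (tier == "partial_short") {
    lo <- max(clen + reserve, 8000L)
    if (lo > 9900L)
      stop("generation error: cassette too large for a sub-10 kb genome",
           call. = FALSE)
    L <- sample(lo:9900L, 1)
  } else {
    rng <- round(config$genome_len_range)
    if (rng[2] < clen + reserve)
      stop("generation error: genome_len_range too small to hold the cassette",
           call. = FALSE)
    L <- sample(max(rng[1], clen + reserve):rng[2], 1)
  }

  itr_len <- 0L
  overlap <- 0L
  if (topology == "itr") {
    itr_len <- sample(seq(config$itr_len_range[1], config$itr_len_range[2]), 1)
    interior <- L - 2L * itr_len
  } else if (topology == "circular") {
    overlap <- config$circular_overlap_len
    interior <- L - overlap
  } else {
    interior <- L
  }
  pad_total <- interior - clen
  min_left <- if (topology == "circular") max(600L, overlap + 50L) else 500L
  if (pad_total < min_left + 500L)
    stop("generation error: genome too small for padding", call. = FALSE)
  left_pad <- sample(min_left:(pad_total - 500L), 1)
  right_pad <- pad_total - left_pad
  body <- paste0(random_dna(left_pad), cassette, random_dna(right_pad))
  cass_off <- left_pad

  if (topology == "itr") {
    t <- random_dna(itr_len)
    seq <- paste0(t, body, revcomp(t))
    cass_off <- cass_off + itr_len
    # forbid chance single-base extension of the planted repeat
    a <- substr(seq, itr_len + 1L, itr_len + 1L)
    b <- substr(seq, L - itr_len, L - itr_len)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    if (a == comp[[b]]) {
      repl <- setdiff(DNA4, comp[[b]])[1]
      substr(seq, itr_len + 1L, itr_len + 1L) <- repl
    }
  } else if (topology == "circular") {
    seq <- paste0(body, substr(body, 1, overlap))
  } else {
    seq <- body
  }

  # gene coordinates
  off <- cass_off
  rows <- list()
  for (i in seq_along(genes)) {
    off <- off + nchar(spacers[i])
    st <- off + 1L
    en <- off + nchar(segs[i])
    rows[[i]] <- data.frame(
      contig_id = id, gene_id = sprintf("%s_g%d", id, i),
      start = st, end = en, strand = strands[i], product = genes[i],
      protein = unname(proteins[i]), stringsAsFactors = FALSE)
    off <- en
  }
  ann <- do.call(rbind, rows)

  # intergenic spans (inside the cassette), trimmed of the stop guards
  ig <- list()
  off <- cass_off
  for (i in seq_len(nspace)) {
    st <- off + 4L
    en <- off + nchar(spacers[i]) - 3L
    if (en - st + 1 >= 1) ig[[length(ig) + 1]] <- c(st, en)
    off <- off + nchar(spacers[i]) +
      if (i <= length(genes)) nchar(segs[i]) else 0L
  }

  truth <- list(id = id, lineage = lineage, tier = tier, topology = topology,
                length = L, overlap_len = overlap, itr_len = itr_len,
                itr_left = if (itr_len) c(1L, itr_len) else NULL,
                itr_right = if (itr_len) c(L - itr_len + 1L, L) else NULL,
                genes = ann[, c("gene_id", "product", "start", "end", "strand")],
                intergenic = ig)
  list(seq = stats::setNames(seq, id), annotations = ann, truth = truth)
}

# giant viruses and MIMIVIRE links ----------------------------------------

splice_in <- function(x, pos_after, insert) {
  # insert `insert` after character `pos_after` (0 = prepend)
  paste0(substr(x, 1, pos_after), insert,
         substr(x, pos_after + 1, nchar(x)))
}

#' Generate a giant-virus contig, optionally linked to a virophage
#'
#' For a linked contig, a seed of `mimivire_seed_len` nt is copied verbatim
#' from one of the virophage's intergenic regions into one giant-virus gene at
#' a codon boundary, and a codon-aligned 18-nt substring of that seed is
#' inserted `mimivire_copies - 1` additional times into the same gene.
#'
#' @param virophage output of [sim_virophage()], or `NULL` for an unlinked
#'   decoy giant virus.
#' @param config a [sim_config()].
#' @param id contig id.
#' @return list with `seq`, `annotations` and (when linked) a `link` record
#'   (seed, repeat unit, copy count, positions).
#' @export
sim_giant_virus_link <- function(virophage, config, id = "gv_1") {
  L <- sample(seq(config$gv_len_range[1], config$gv_len_range[2]), 1)
  ngenes <- sample(4:8, 1)
  plens <- sample(300:700, ngenes, replace = TRUE)
  gene_nt <- vapply(plens, function(n) encode_protein(random_protein(n)),
                    character(1))

  link <- NULL
  if (!is.null(virophage)) {
    slen <- config$mimivire_seed_len
    spans <- Filter(function(x) x[2] - x[1] + 1 >= slen,
                    virophage$truth$intergenic)
    if (!length(spans))
      stop("generation error: no intergenic region can hold the seed",
           call. = FALSE)
    span <- spans[[sample(length(spans), 1)]]
    p <- sample(span[1]:(span[2] - slen + 1L), 1)
    seed <- substr(virophage$seq[[1]], p, p + slen - 1L)
    a_off <- sample(0:((slen - 18L) %/% 3L), 1)
    unit <- substr(seed, 3L * a_off + 1L, 3L * a_off + 18L)
    gi <- sample(ngenes, 1)
    g <- gene_nt[gi]
    ncod <- nchar(g) %/% 3L
    copies <- config$mimivire_copies
    repeat { # insertion codons at least 8 codons apart
      cuts <- sort(sample(2:(ncod - 2L), copies))
      if (copies < 2 || min(diff(cuts)) >= 8L) break
    }
    cuts <- rev(cuts)
    which_seed <- sample(copies, 1)
    # bases flanking the unit inside the seed; standalone insertions must
    # not recreate them, or a shifted unit would be equally repeated
    pre_ch <- if (a_off > 0) substr(seed, 3L * a_off, 3L * a_off) else NA
    post_ch <- if (3L * a_off + 18L < slen)
      substr(seed, 3L * a_off + 19L, 3L * a_off + 19L) else NA
    for (ci in seq_along(cuts)) {
      at <- 3L * cuts[ci]
      ins <- if (ci == which_seed) seed else unit
      g <- splice_in(g, at, ins)
      if (ci != which_seed) {
        if (!is.na(pre_ch) && substr(g, at, at) == pre_ch)
          substr(g, at, at) <- setdiff(DNA4, pre_ch)[1]
        after <- at + nchar(ins) + 1L
        if (!is.na(post_ch) && substr(g, after, after) == post_ch)
          substr(g, after, after) <- setdiff(DNA4, post_ch)[1]
      }
    }
    # forbid chance single-base extension of the shared seed at either flank
    gpos <- as.integer(regexpr(seed, g, fixed = TRUE))
    vp_left <- if (p > 1) substr(virophage$seq[[1]], p - 1L, p - 1L) else ""
    vp_right <- substr(virophage$seq[[1]], p + slen, p + slen)
    g_left <- if (gpos > 1) substr(g, gpos - 1L, gpos - 1L) else ""
    g_right <- substr(g, gpos + slen, gpos + slen)
    if (nzchar(g_left) && g_left == vp_left)
      substr(g, gpos - 1L, gpos - 1L) <- setdiff(DNA4, vp_left)[1]
    if (nzchar(g_right) && nzchar(vp_right) && g_right == vp_right)
      substr(g, gpos + slen, gpos + slen) <- setdiff(DNA4, vp_right)[1]
    gene_nt[gi] <- g
    observed <- length(gregexpr(unit, g, fixed = TRUE)[[1]])
    link <- list(virophage_id = virophage$truth$id, gv_id = id,
                 gene_index = gi, seed = seed, seed_len = slen,
                 unit = unit, copies = observed, vp_seed_start = p)
  }

  glen <- sum(nchar(gene_nt))
  nspace <- ngenes + 1
  pad_total <- max(L - glen, nspace * 50L)
  cuts <- sort(sample(seq_len(pad_total - 1L), nspace - 1L))
  sl <- diff(c(0L, cuts, pad_total))
  spacers <- vapply(sl, random_dna, character(1))
  seqs <- character(0)
  rows <- list()
  off <- 0L
  for (i in seq_len(ngenes)) {
    off <- off + nchar(spacers[i])
    st <- off + 1L
    en <- off + nchar(gene_nt[i])
    rows[[i]] <- data.frame(
      contig_id = id, gene_id = sprintf("%s_g%d", id, i),
      start = st, end = en, strand = "+", product = "other",
      protein = translate_dna(substr(gene_nt[i], 1, nchar(gene_nt[i]) - 3)),
      stringsAsFactors = FALSE)
    off <- en
  }
  seq <- paste0(paste0(spacers[seq_len(ngenes)], gene_nt, collapse = ""),
                spacers[nspace])
  ann <- do.call(rbind, rows)
  if (!is.null(link)) {
    link$gene_id <- ann$gene_id[link$gene_index]
    link$gv_seed_start <- as.integer(
      regexpr(link$seed, seq, fixed = TRUE))
  }
  list(seq = stats::setNames(seq, id), annotations = ann, link = link)
}

# whole corpus -------------------------------------------------------------

decoy_is_pure <- function(seq, ancestors, id) {
  orfs <- call_orfs(stats::setNames(seq, id), min_len = 100)
  if (!nrow(orfs)) return(TRUE)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B62 <- get("BLOSUM62", envir = environment())
  for (p in orfs$protein) {
    for (a in ancestors) {
      if (shared_kmer_count(p, a, 4) < 2) next
      aln <- Biostrings::pairwiseAlignment(
        p, a, type = "local", substitutionMatrix = B62,
        gapOpening = 11, gapExtension = 1)
      cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
      if (cols == 0) next
      ident <- Biostrings::nmatch(aln) / cols
      frac_p <- cols / nchar(p)
      frac_a <- cols / nchar(a)
      if (ident >= 0.30 && frac_p >= 0.70 && frac_a >= 0.70) return(FALSE)
    }
  }
  TRUE
}

#' Generate a full synthetic metagenome corpus
#'
#' Produces virophage contigs across the configured lineages (HQ and planted
#' partials), decoy contigs of uniform random DNA (rejection-sampled so no
#' decoy ORF resembles a core-gene ancestor at the 30/70 threshold),
#' giant-virus contigs with planted MIMIVIRE links, per-gene/per-lineage seed
#' alignments, habitat labels, and a ground-truth record of every planted
#' feature. Output is byte-identical for a fixed seed.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given, writes `contigs.fasta`,
#'   `annotations.gff3`, `proteins.faa`, `habitats.tsv`,
#'   `giant_contigs.fasta`, `giant_annotations.gff3`, per-gene seed
#'   alignments (`seeds_<gene>_L<lineage>.afa`) and `ground_truth.json`.
#' @return object of class `sim_corpus`.
#' @export
sim_metagenome <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    lineages <- sim_lineages(config)
    genes <- names(lineages$roots)

    seed_alignments <- list()
    for (g in genes) {
      for (li in seq_len(config$n_lineages)) {
        anc <- lineages$ancestors[[li]][[g]]
        rows <- c(anc, mutate_protein(anc, 0.9), mutate_protein(anc, 0.9))
        names(rows) <- sprintf("seed_%s_L%d_%d", g, li, 1:3)
        seed_alignments[[sprintf("%s_L%d", g, li)]] <- rows
      }
    }

    nv <- config$n_virophages
    vps <- list()
    if (nv > 0) {
      lin_of <- ((seq_len(nv) - 1) %% config$n_lineages) + 1
      n_hq <- round(config$hq_fraction * nv)
      tiers <- c(rep("HQ", n_hq),
                 rep(c("partial_short", "partial_missing"),
                     length.out = nv - n_hq))
      for (i in seq_len(nv)) {
        vps[[i]] <- sim_virophage(config, lin_of[i], lineages,
                                  id = sprintf("vp_%04d", i),
                                  tier = tiers[i])
      }
    }

    decoys <- character(0)
    ancestors <- unique(c(unlist(lineages$ancestors), lineages$roots))
    for (i in seq_len(config$n_decoys)) {
      id <- sprintf("decoy_%04d", i)
      repeat {
        len <- sample(seq(config$decoy_len_range[1],
                          config$decoy_len_range[2]), 1)
        s <- random_dna(len)
        if (decoy_is_pure(s, ancestors, id)) break
      }
      decoys[id] <- s
    }

    gvs <- list()
    links <- list()
    for (i in seq_len(config$n_giant_viruses)) {
      vp <- if (i <= length(vps)) vps[[i]] else NULL
      gv <- sim_giant_virus_link(vp, config, id = sprintf("gv_%04d", i))
      gvs[[i]] <- gv
      if (!is.null(gv$link)) links[[length(links) + 1]] <- gv$link
    }

    contigs <- c(unlist(lapply(vps, `[[`, "seq")), decoys)
    annotations <- if (length(vps))
      do.call(rbind, lapply(vps, `[[`, "annotations"))
    else gene_annotation_frame()
    proteins <- annotation_proteins(annotations)

    habs <- character(0)
    home <- config$habitat_labels[
      ((seq_len(config$n_lineages) - 1) %% length(config$habitat_labels)) + 1]
    for (v in vps) {
      h <- if (stats::runif(1) < config$habitat_fidelity)
        home[v$truth$lineage]
      else sample(config$habitat_labels, 1)
      habs[v$truth$id] <- h
    }
    for (id in names(decoys))
      habs[id] <- sample(config$habitat_labels, 1)
    habitats <- data.frame(contig_id = names(habs), habitat = unname(habs),
                           stringsAsFactors = FALSE)

    giant_contigs <- unlist(lapply(gvs, `[[`, "seq"))
    giant_ann <- if (length(gvs))
      do.call(rbind, lapply(gvs, `[[`, "annotations"))
    else gene_annotation_frame()

    families <- do.call(rbind, lapply(vps, function(v) {
      gt <- v$truth$genes
      data.frame(protein_id = paste0(v$truth$id, "|", gt$gene_id),
                 family = gt$product, lineage = v$truth$lineage,
                 stringsAsFactors = FALSE)
    }))

    truth <- list(
      virophages = lapply(vps, `[[`, "truth"),
      decoy_ids = names(decoys),
      links = links,
      families = families,
      habitats = habitats,
      hq_ids = vapply(Filter(function(v) v$truth$tier == "HQ", vps),
                      function(v) v$truth$id, character(1))
    )

    corpus <- list(config = config, contigs = contigs,
                   annotations = annotations, proteins = proteins,
                   habitats = habitats, seed_alignments = seed_alignments,
                   giant_contigs = giant_contigs,
                   giant_annotations = giant_ann, truth = truth,
                   lineages = lineages)
    class(corpus) <- "sim_corpus"
    if (!is.null(out_dir)) write_corpus(corpus, out_dir)
    corpus
  })
}

#' Write a simulated corpus to disk
#' @param corpus a `sim_corpus`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_corpus <- function(corpus, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(x) file.path(out_dir, x)
  write_fasta(corpus$contigs, f("contigs.fasta"))
  write_gff3(corpus$annotations, f("annotations.gff3"))
  if (length(corpus$proteins)) write_fasta(corpus$proteins, f("proteins.faa"))
  write_habitats(corpus$habitats, f("habitats.tsv"))
  if (length(corpus$giant_contigs)) {
    write_fasta(corpus$giant_contigs, f("giant_contigs.fasta"))
    write_gff3(corpus$giant_annotations, f("giant_annotations.gff3"))
  }
  for (nm in names(corpus$seed_alignments))
    write_fasta(corpus$seed_alignments[[nm]],
                f(sprintf("seeds_%s.afa", nm)))
  jsonlite::write_json(corpus$truth, f("ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
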