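# Two-step clustering of predicted proteins into virophage protein clusters
# (VpPCs): all-vs-all Smith-Waterman similarity graph (score >= 30,
# E <= 0.01), InfoMap community detection on the weighted graph, then a
# profile-profile merge of communities using the two published acceptance
# disjuncts (p >= 0.90 & cov >= 0.50, or p >= 0.99 & cov >= 0.20 &
# length >= 100 aa), followed by core/common/accessory categorization.

#' All-vs-all protein similarity edges
#'
#' Smith-Waterman (BLOSUM62, affine gaps 11/1) on every unordered pair;
#' the score is symmetric by construction. E-values come from a Gumbel fit
#' to shuffled-decoy pair scores, scaled by the database size. Edges must
#' reach `score_min` and `e_max`.
#'
#' @param proteins named character vector (>= 2).
#' @param score_min minimum alignment score (default 30).
#' @param e_max maximum E-value (default 0.01).
#' @param min_shared_kmers alignment prefilter: only pairs sharing at least
#'   this many length-5 amino-acid words (inverted-index lookup) are aligned;
#'   0 aligns every pair.
#' @param n_calib number of shuffled decoy pairs for calibration.
#' @return data.frame `a`, `b`, `score`, `evalue` (a < b lexicographically).
#' @export
all_vs_all <- function(proteins, score_min = 30, e_max = 0.01,
                       min_shared_kmers = 1, n_calib = 400) {
  stopifnot(length(proteins) >= 2)
  ids <- sort(names(proteins))
  enc <- lapply(proteins[ids], aa_encode)
  sub <- blosum62()
  # calibration on shuffled pairs of real lengths
  lens <- nchar(proteins)
  dec <- vapply(seq_len(n_calib), function(i) {
    a <- sample.int(20, sample(lens, 1), replace = TRUE)
    b <- sample.int(20, sample(lens, 1), replace = TRUE)
    sw_score_c(a, b, sub, 11, 1)
  }, numeric(1))
  cal <- fit_gumbel(dec)
  N <- length(proteins)
  pairs <- if (min_shared_kmers > 0) {
    candidate_pairs(proteins[ids], k = 5, min_shared = min_shared_kmers)
  } else {
    idx <- utils::combn(ids, 2)
    data.frame(a = idx[1, ], b = idx[2, ], stringsAsFactors = FALSE)
  }
  out <- vector("list", nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    s <- sw_score_c(enc[[pairs$a[r]]], enc[[pairs$b[r]]], sub, 11, 1)
    if (s < score_min) next
    e <- N * exp(-cal$lambda * (s - cal$mu))
    if (e > e_max) next
    out[[r]] <- data.frame(a = pairs$a[r], b = pairs$b[r],
                           score = s, evalue = e, stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(a = character(0), b = character(0),
                      score = numeric(0), evalue = numeric(0)))
  res <- do.call(rbind, out)
  attr(res, "calibration") <- cal
  res
}

#' Detect protein communities on the similarity graph
#'
#' Two-level InfoMap (map-equation) partition of the weighted similarity
#' graph; isolated proteins form their own groups. Deterministic under a
#' fixed seed.
#'
#' @param edges edge data.frame from [all_vs_all()].
#' @param proteins named character vector (defines the vertex set, so
#'   proteins without edges are kept as singleton groups).
#' @param seed RNG seed for the community search.
#' @return named integer vector: protein id -> group id.
#' @export
detect_communities <- function(edges, proteins, seed = 1) {
  ids <- sort(names(proteins))
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (nrow(edges)) {
    g <- igraph::add_edges(g, t(as.matrix(edges[, c("a", "b")])))
    igraph::E(g)$weight <- edges$score
  }
  set.seed(seed)
  if (igraph::ecount(g) > 0) {
    comm <- igraph::cluster_infomap(g, e.weights = igraph::E(g)$weight)
    mem <- igraph::membership(comm)
  } else {
    mem <- stats::setNames(seq_along(ids), ids)
  }
  out <- as.integer(mem)
  names(out) <- ids
  out
}

# profile-profile merge ----------------------------------------------------

group_profile <- function(members, derep_id = 0.90) {
  if (length(members) >= 2) {
    dr <- dereplicate(members, id_thresh = derep_id, cov_thresh = 0.9,
                      mode = "gene")
    members <- members[dr$representatives]
  }
  aln <- if (length(members) >= 2) align_proteins(members) else members
  build_profile(aln, calibrate = FALSE)
}

profile_pair_score <- function(pa, pb) {
  s1 <- pssm_scan_c(pa$scores, aa_encode(pb$consensus))
  s2 <- pssm_scan_c(pb$scores, aa_encode(pa$consensus))
  best <- if (s1$score >= s2$score) s1 else s2
  alen <- best$seq_end - best$seq_start + 1
  list(score = best$score, alen = alen,
       cov = alen / min(pa$length, pb$length))
}

shuffle_profile <- function(p) {
  # column-permuted decoy: same composition and sharpness, no homology
  perm <- sample.int(p$length)
  p$scores <- p$scores[perm, , drop = FALSE]
  cons <- strsplit(p$consensus, "", fixed = TRUE)[[1]]
  p$consensus <- paste(cons[perm], collapse = "")
  p
}

#' Merge protein communities into VpPCs by profile-profile comparison
#'
#' Per group: 90%-identity de-replication, progressive alignment, PSSM. Group
#' pairs are scored consensus-vs-PSSM in both directions (maximum taken);
#' coverage is aligned columns over the shorter profile. The match
#' probability is a logistic map of the score calibrated on shuffled-decoy
#' profile pairs (`p = plogis(lambda * (S - mu) - log(n_comparisons))`).
#' Groups are linked iff `p >= prob1 & cov >= cov1` or
#' `p >= prob2 & cov >= cov2 & aligned length >= len2`; connected components
#' of linked groups become VpPCs. PCs keep only groups of two or more
#' proteins.
#'
#' @param groups named integer vector from [detect_communities()] (or a list
#'   of member-id vectors).
#' @param proteins named character vector.
#' @param prob1,cov1 first acceptance disjunct (default 0.90 / 0.50).
#' @param prob2,cov2,len2 second disjunct (default 0.99 / 0.20 / 100 aa).
#' @param derep_id within-group de-replication identity (default 0.90).
#' @param min_profile_cols groups with fewer consensus columns are kept
#'   unmerged with a warning.
#' @param seed RNG seed for the decoy calibration.
#' @return list with `pcs` (named list `VpPC_001`, ... of member-id vectors),
#'   `table` (data.frame `pc_id`, `protein_id`) and `group_map`.
#' @export
merge_by_profiles <- function(groups, proteins, prob1 = 0.90, cov1 = 0.50,
                              prob2 = 0.99, cov2 = 0.20, len2 = 100,
                              derep_id = 0.90, min_profile_cols = 10,
                              seed = 1) {
  set.seed(seed)
  if (!is.list(groups)) groups <- split(names(groups), groups)
  groups <- lapply(groups, sort)
  names(groups) <- sprintf("g%03d", seq_along(groups))
  profs <- lapply(groups, function(ids)
    group_profile(proteins[ids], derep_id = derep_id))
  degenerate <- vapply(profs, function(p) p$length < min_profile_cols,
                       logical(1))
  if (any(degenerate))
    warning(sum(degenerate), " group(s) with profiles under ",
            min_profile_cols, " columns kept unmerged")

  gn <- names(groups)
  n <- length(gn)
  links <- list()
  if (n >= 2) {
    # candidate group pairs: every pair of multi-member groups, plus pairs
    # whose member proteins share length-5 words (inverted-index lookup) -
    # spurious singleton groups rarely reach the profile comparison.
    multi <- gn[lengths(groups) >= 2]
    cand <- list()
    if (length(multi) >= 2) {
      cmb <- utils::combn(multi, 2)
      cand[[1]] <- data.frame(gi = cmb[1, ], gj = cmb[2, ],
                              stringsAsFactors = FALSE)
    }
    grp_of <- stats::setNames(rep(gn, lengths(groups)),
                              unlist(groups, use.names = FALSE))
    pp <- candidate_pairs(proteins[names(grp_of)], k = 5, min_shared = 2)
    if (nrow(pp)) {
      ga <- unname(grp_of[pp$a])
      gb <- unname(grp_of[pp$b])
      keep <- ga != gb
      if (any(keep)) {
        gi <- pmin(ga[keep], gb[keep])
        gj <- pmax(ga[keep], gb[keep])
        cand[[length(cand) + 1]] <- data.frame(gi = gi, gj = gj,
                                               stringsAsFactors = FALSE)
      }
    }
    pairs <- unique(do.call(rbind, cand)) %||%
      data.frame(gi = character(0), gj = character(0))
    ncomp <- max(nrow(pairs), 1)
    # decoy calibration: scores between shuffled versions of the profiles
    n_dec <- min(200, max(50, 2 * n))
    dec <- vapply(seq_len(n_dec), function(i) {
      pa <- shuffle_profile(profs[[sample(n, 1)]])
      pb <- shuffle_profile(profs[[sample(n, 1)]])
      profile_pair_score(pa, pb)$score
    }, numeric(1))
    cal <- fit_gumbel(dec)
    for (r in seq_len(nrow(pairs))) {
      i <- pairs$gi[r]
      j <- pairs$gj[r]
      if (degenerate[[i]] || degenerate[[j]]) next
      ps <- profile_pair_score(profs[[i]], profs[[j]])
      p <- stats::plogis(cal$lambda * (ps$score - cal$mu) - log(ncomp))
      if ((p >= prob1 && ps$cov >= cov1) ||
          (p >= prob2 && ps$cov >= cov2 && ps$alen >= len2))
        links[[length(links) + 1]] <- c(i, j)
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = gn)
  if (length(links)) g <- igraph::add_edges(g, t(do.call(rbind, links)))
  comp <- igraph::components(g)$membership
  merged <- split(gn, comp)
  pcs <- lapply(merged, function(gs) sort(unlist(groups[gs], use.names = FALSE)))
  pcs <- Filter(function(m) length(m) >= 2, pcs)
  ord <- order(-lengths(pcs), vapply(pcs, `[`, character(1), 1))
  pcs <- pcs[ord]
  names(pcs) <- sprintf("VpPC_%03d", seq_along(pcs))
  tab <- if (length(pcs)) {
    data.frame(pc_id = rep(names(pcs), lengths(pcs)),
               protein_id = unlist(pcs, use.names = FALSE),
               stringsAsFactors = FALSE)
  } else data.frame(pc_id = character(0), protein_id = character(0))
  group_map <- stats::setNames(rep(NA_character_, n), gn)
  for (pc in names(pcs)) {
    gs <- merged[[which(vapply(merged, function(g2)
      any(unlist(groups[g2]) %in% pcs[[pc]]), logical(1)))[1]]]
    group_map[gs] <- pc
  }
  list(pcs = pcs, table = tab, group_map = group_map)
}

#' Categorize VpPCs by genome prevalence
#'
#' Prevalence is the fraction of HQ genomes carrying at least one member.
#' Categories: `core` at prevalence 1.0 (present in all HQ genomes), `common`
#' in \[0.25, 0.60\], `accessory` below 0.25, and `common_high` for the
#' (0.60, 1.0) band the published scheme leaves unnamed.
#'
#' @param pcs named list of member protein ids (`<contig>|<gene>`).
#' @param hq_genomes character vector of HQ genome (contig) ids.
#' @return data.frame `pc_id`, `n_members`, `n_genomes`, `prevalence`,
#'   `category`.
#' @export
categorize_pcs <- function(pcs, hq_genomes) {
  stopifnot(length(hq_genomes) > 0)
  rows <- lapply(names(pcs), function(pc) {
    genomes <- unique(sub("\\|.*$", "", pcs[[pc]]))
    prev <- sum(hq_genomes %in% genomes) / length(hq_genomes)
    cat <- if (prev == 1) "core"
    else if (prev >= 0.25 && prev <= 0.60) "common"
    else if (prev < 0.25) "accessory"
    else "common_high"
    data.frame(pc_id = pc, n_members = length(pcs[[pc]]),
               n_genomes = length(genomes), prevalence = prev,
               category = cat, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Clade and habitat marker VpPCs
#'
#' A PC is a clade (habitat) marker when it is restricted to exactly one
#' clade (habitat) and present in at least two genomes.
#'
#' @param pcs named list of member protein ids.
#' @param genome_clades named vector genome id -> clade id.
#' @param genome_habitats named vector genome id -> habitat.
#' @return data.frame `pc_id`, `n_genomes`, `clades`, `habitats`,
#'   `clade_marker`, `habitat_marker`.
#' @export
pc_markers <- function(pcs, genome_clades = NULL, genome_habitats = NULL) {
  rows <- lapply(names(pcs), function(pc) {
    genomes <- unique(sub("\\|.*$", "", pcs[[pc]]))
    cl <- if (!is.null(genome_clades))
      unique(genome_clades[genomes][!is.na(genome_clades[genomes])])
    else character(0)
    hb <- if (!is.null(genome_habitats))
      unique(genome_habitats[genomes][!is.na(genome_habitats[genomes])])
    else character(0)
    data.frame(pc_id = pc, n_genomes = length(genomes),
               clades = paste(sort(cl), collapse = ","),
               habitats = paste(sort(hb), collapse = ","),
               clade_marker = length(cl) == 1 && length(genomes) >= 2,
               habitat_marker = length(hb) == 1 && length(genomes) >= 2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full two-step protein clustering
#'
#' Convenience wrapper: [all_vs_all()] -> [detect_communities()] ->
#' [merge_by_profiles()].
#'
#' @inheritParams all_vs_all
#' @inheritParams merge_by_profiles
#' @return the [merge_by_profiles()] result plus `edges` and `groups`.
#' @export
cluster_proteins <- function(proteins, score_min = 30, e_max = 0.01,
                             seed = 1, ...) {
  edges <- all_vs_all(proteins, score_min = score_min, e_max = e_max)
  groups <- detect_communities(edges, proteins, seed = seed)
  res <- merge_by_profiles(groups, proteins, seed = seed, ...)
  res$edges <- edges
  res$groups <- groups
  res
}
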