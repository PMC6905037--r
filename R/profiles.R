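# Position-specific scoring models for the MCP bait (and the other core
# genes): 30/70 bidirectional clustering to form model families, PSSM
# construction with Gumbel E-value calibration on shuffled decoys, local
# ungapped profile search, and the two-step iterative model refinement.

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- get("BLOSUM62", envir = e)[AA20, AA20]
    }
    cache
  }
})

pair_identity_cov <- function(a, b, type = "protein") {
  sub <- if (type == "protein") blosum62() else NULL
  aln <- if (type == "protein") {
    Biostrings::pairwiseAlignment(a, b, type = "local",
                                  substitutionMatrix = sub,
                                  gapOpening = 11, gapExtension = 1)
  } else {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
    Biostrings::pairwiseAlignment(a, b, type = "local",
                                  substitutionMatrix = mat,
                                  gapOpening = 5, gapExtension = 2)
  }
  cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
  if (cols == 0)
    return(list(identity = 0, cols = 0, frac_a = 0, frac_b = 0,
                span_a = 0, span_b = 0))
  span_a <- Biostrings::width(Biostrings::pattern(aln))
  span_b <- Biostrings::width(Biostrings::subject(aln))
  list(identity = Biostrings::nmatch(aln) / cols, cols = cols,
       frac_a = span_a / nchar(a), frac_b = span_b / nchar(b),
       span_a = span_a, span_b = span_b)
}

#' Cluster proteins into model families (bidirectional 30/70 rule)
#'
#' Builds a graph with an edge between two proteins iff their local-alignment
#' identity is at least `identity_cut` and the aligned region covers at least
#' `align_frac` of BOTH sequences, then returns the connected components.
#' Singletons are dropped. Family order and membership order are
#' deterministic (lexicographic ids).
#'
#' @param proteins named character vector (>= 2 sequences).
#' @param identity_cut minimum identity over aligned columns.
#' @param align_frac minimum aligned fraction of each sequence.
#' @param min_shared_kmers alignment prefilter: pairs sharing fewer length-4
#'   amino-acid words are not aligned (0 disables).
#' @return list of character vectors of member ids.
#' @export
cluster_for_models <- function(proteins, identity_cut = 0.30,
                               align_frac = 0.70, min_shared_kmers = 0) {
  stopifnot(length(proteins) >= 2)
  ids <- sort(names(proteins))
  n <- length(ids)
  edges <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- proteins[[ids[i]]]
      b <- proteins[[ids[j]]]
      if (min_shared_kmers > 0 &&
          shared_kmer_count(a, b, 4) < min_shared_kmers) next
      pc <- pair_identity_cov(a, b)
      if (pc$identity >= identity_cut && pc$frac_a >= align_frac &&
          pc$frac_b >= align_frac)
        edges[[length(edges) + 1]] <- c(ids[i], ids[j])
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (length(edges))
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  comp <- igraph::components(g)$membership
  fams <- split(names(comp), comp)
  fams <- Filter(function(f) length(f) >= 2, fams)
  fams <- lapply(fams, sort)
  fams[order(vapply(fams, `[`, character(1), 1))]
}

# PSSM construction -------------------------------------------------------

#' Build a calibrated profile model from an aligned protein family
#'
#' Columns with more than 50% gaps are excluded from the consensus. Scores
#' are `log2(p_col / background)` with a +1 pseudocount per residue. E-value
#' calibration fits a Gumbel distribution to maximal-segment scores of
#' shuffled decoys drawn from the members' residue composition.
#'
#' @param alignment character vector of equal-length aligned rows (gap `-`),
#'   at least 2; or a single sequence for an uncalibrated internal profile.
#' @param model_id model label.
#' @param background amino-acid background frequencies (default uniform).
#' @param calibrate fit the Gumbel decoy calibration (required for
#'   [profile_search()]).
#' @param n_decoys number of shuffled decoys (>= 1000 recommended).
#' @return object of class `profile_model` with elements `model_id`,
#'   `length`, `scores` (columns x 20, bits), `consensus`, `background`,
#'   `calibration` (`mu`, `lambda`), `members`, `member_seqs`.
#' @export
build_profile <- function(alignment, model_id = "model_1",
                          background = rep(1 / 20, 20), calibrate = TRUE,
                          n_decoys = 1000) {
  rows <- alignment
  if (length(unique(nchar(rows))) != 1)
    stop("alignment rows must have equal length", call. = FALSE)
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  gap_frac <- colMeans(mat == "-")
  keep <- gap_frac <= 0.5
  if (!any(keep))
    stop("all-gap alignment: no usable columns", call. = FALSE)
  mat <- mat[, keep, drop = FALSE]
  L <- ncol(mat)
  counts <- apply(mat, 2, function(col) {
    tabulate(match(col, AA20), nbins = 20)
  })
  ncol_eff <- colSums(counts)
  p <- sweep(counts + 1, 2, ncol_eff + 20, "/") # +1 pseudocount per residue
  scores <- t(log2(p / background)) # L x 20
  consensus <- paste(AA20[apply(p, 2, which.max)], collapse = "")
  member_seqs <- gsub("-", "", rows, fixed = TRUE)
  model <- list(model_id = model_id, length = L, scores = scores,
                consensus = consensus, background = background,
                calibration = NULL,
                members = names(rows) %||% sprintf("m%d", seq_along(rows)),
                member_seqs = stats::setNames(member_seqs,
                                              names(rows) %||%
                                                sprintf("m%d", seq_along(rows))))
  class(model) <- "profile_model"
  if (calibrate) model <- calibrate_profile(model, n_decoys = n_decoys)
  model
}

calibrate_profile <- function(model, n_decoys = 1000) {
  pool <- unlist(strsplit(model$member_seqs, "", fixed = TRUE))
  pool <- pool[pool %in% AA20]
  len <- round(mean(nchar(model$member_seqs)))
  dec <- vapply(seq_len(n_decoys), function(i) {
    s <- paste(sample(pool, len, replace = TRUE), collapse = "")
    pssm_scan_c(model$scores, aa_encode(s))$score
  }, numeric(1))
  model$calibration <- c(fit_gumbel(dec), list(n_decoys = n_decoys))
  model
}

#' Score one protein against a profile model
#' @param model a `profile_model`.
#' @param protein a protein string.
#' @return list with `score` (bits) and the aligned spans.
#' @export
profile_score <- function(model, protein) {
  pssm_scan_c(model$scores, aa_encode(protein))
}

#' Search a protein set with a calibrated profile model
#'
#' Computes the best local ungapped segment score of every protein against
#' the model PSSM and converts it to an E-value
#' `E = N * exp(-lambda * (S - mu))` with `N` the database size and
#' `(mu, lambda)` the Gumbel decoy calibration. Hits with `E < e_cut` are
#' returned sorted by E-value (ties by protein id).
#'
#' @param model a calibrated `profile_model`.
#' @param proteins named character vector.
#' @param e_cut E-value threshold (default 1e-6, the screening threshold).
#' @return data.frame `model_id`, `protein_id`, `score`, `evalue`,
#'   `start`, `end` (aligned span on the protein).
#' @export
profile_search <- function(model, proteins, e_cut = 1e-6) {
  if (is.null(model$calibration))
    stop("uncalibrated model: run build_profile(calibrate = TRUE)",
         call. = FALSE)
  empty <- data.frame(model_id = character(0), protein_id = character(0),
                      score = numeric(0), evalue = numeric(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  if (!length(proteins)) return(empty)
  N <- length(proteins)
  mu <- model$calibration$mu
  lambda <- model$calibration$lambda
  hits <- lapply(names(proteins), function(id) {
    sc <- pssm_scan_c(model$scores, aa_encode(proteins[[id]]))
    e <- N * exp(-lambda * (sc$score - mu))
    if (e < e_cut)
      data.frame(model_id = model$model_id, protein_id = id,
                 score = sc$score, evalue = e,
                 start = sc$seq_start, end = sc$seq_end,
                 stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits)) return(empty)
  hits <- hits[order(hits$evalue, hits$protein_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Iteratively refine profile models against a protein database
#'
#' Round 1 builds one model per seed alignment. Each further round searches
#' the database with the current models, recruits hits whose gene length is
#' at least `min_len_nt` nucleotides, pools recruits with the current
#' members, re-clusters the pool with the bidirectional 30/70 rule and
#' rebuilds one model per family. A round that recruits nothing new stops
#' the iteration with a warning.
#'
#' @param seed_alignments list of aligned seed families (named character
#'   vectors).
#' @param database_proteins named character vector to search.
#' @param rounds number of build rounds (1 = seeds only).
#' @param min_len_nt recruit length filter on the gene (nt); gene length
#'   defaults to `3 * aa + 3` unless `gene_lengths` provides it.
#' @param e_cut search E-value threshold.
#' @param gene_lengths optional named nt lengths for database proteins.
#' @param n_decoys decoys per model calibration.
#' @return list with `models` (final round), `membership_by_round` (list of
#'   per-model member-id sets per round) and `provenance` (which seeds fed
#'   which final model).
#' @export
iterate_models <- function(seed_alignments, database_proteins, rounds = 2,
                           min_len_nt = 700, e_cut = 1e-6,
                           gene_lengths = NULL, n_decoys = 1000) {
  stopifnot(rounds >= 1)
  build_set <- function(fams, prefix, round) {
    out <- list()
    for (i in seq_along(fams)) {
      id <- sprintf("%s_r%d_%02d", prefix, round, i)
      out[[id]] <- build_profile(fams[[i]], model_id = id,
                                 n_decoys = n_decoys)
    }
    out
  }
  seed_fams <- seed_alignments
  models <- build_set(seed_fams, "mcp", 1)
  membership <- list(lapply(models, `[[`, "members"))
  seed_of <- lapply(models, `[[`, "members")

  r <- 1
  while (r < rounds) {
    r <- r + 1
    member_seqs <- unlist(lapply(models, `[[`, "member_seqs"))
    names(member_seqs) <- unlist(lapply(models, function(m) names(m$member_seqs)))
    hits <- do.call(rbind, lapply(models, profile_search,
                                  proteins = database_proteins,
                                  e_cut = e_cut))
    rec_ids <- unique(hits$protein_id)
    lens <- if (is.null(gene_lengths))
      3 * nchar(database_proteins[rec_ids]) + 3
    else gene_lengths[rec_ids]
    rec_ids <- rec_ids[lens >= min_len_nt]
    new_ids <- setdiff(rec_ids, names(member_seqs))
    if (!length(new_ids)) {
      warning("iteration round ", r, " recruited nothing new; stopping")
      break
    }
    pool <- c(member_seqs, database_proteins[new_ids])
    pool <- pool[!duplicated(names(pool))]
    fams <- cluster_for_models(pool)
    fams <- lapply(fams, function(ids) stats::setNames(pool[ids], ids))
    models <- build_set(fams, "mcp", r)
    membership[[r]] <- lapply(models, `[[`, "members")
  }

  provenance <- lapply(models, function(m) {
    feeders <- names(seed_of)[vapply(seed_of, function(s)
      any(s %in% m$members), logical(1))]
    feeders
  })
  list(models = models, membership_by_round = membership,
       provenance = provenance, rounds_run = r)
}

#' Classify MCP gene completeness from protein length
#'
#' Uses the published average MCP size of 593 aa with standard deviation
#' 40.1: `complete` when the length is at least `mean - sd` (longer-than-
#' average genes are still complete), `ge_half` when at least half the mean,
#' otherwise `partial`.
#'
#' @param length protein length(s) in aa (> 0).
#' @param mean,sd published MCP length statistics.
#' @return character vector over `{"complete", "ge_half", "partial"}`.
#' @export
mcp_completeness <- function(length, mean = 593, sd = 40.1) {
  stopifnot(all(length > 0))
  ifelse(length >= mean - sd, "complete",
         ifelse(length >= 0.5 * mean, "ge_half", "partial"))
}
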