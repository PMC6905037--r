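# Virophage genome filters: circularity via overlapping 5'/3' ends, inverted
# terminal repeats (>= 100 bp), best-hit core-gene labelling, quality tiering
# (>= 10 kb + four core genes = HQ; plus circular/ITR topology = complete),
# and greedy identity/coverage de-replication (95/95 genes, 95/80 contigs).

#' Detect circularity from overlapping contig ends
#'
#' Returns the longest `k >= min_overlap` such that the first `k` bases equal
#' the last `k` bases exactly (the assembler terminal-duplication convention),
#' or `NULL`.
#'
#' @param contig a single DNA string.
#' @param min_overlap minimum overlap length (default 20; the random-match
#'   probability per contig is then below 1e-6).
#' @return integer overlap length, or `NULL`.
#' @export
detect_circularity <- function(contig, min_overlap = 20) {
  s <- toupper(unname(contig[1]))
  L <- nchar(s)
  if (L < 2 * min_overlap) return(NULL)
  anchor <- substr(s, 1, min_overlap)
  m <- gregexpr(anchor, s, fixed = TRUE)[[1]]
  m <- m[m > 1 & m <= L - min_overlap + 1]
  if (!length(m)) return(NULL)
  best <- NULL
  for (q in sort(m)) { # increasing q = decreasing k; first hit is longest
    k <- L - q + 1
    if (substr(s, 1, k) == substr(s, q, L)) {
      best <- k
      break
    }
  }
  best
}

#' Detect inverted terminal repeats
#'
#' Searches the first and last `search_window` bases for the longest block of
#' at least `min_len` bp whose left copy equals the reverse complement of the
#' right copy. With `max_mismatch > 0`, exact blocks on the same diagonal
#' separated by up to that many mismatches are joined.
#'
#' @param contig a single DNA string.
#' @param min_len minimum ITR length (default 100 bp).
#' @param max_mismatch mismatches tolerated when joining blocks (default 0,
#'   exact).
#' @param search_window terminal window size (bp).
#' @return list with `length`, `left = c(start, end)`,
#'   `right = c(start, end)` (1-based genome coordinates), or `NULL`.
#' @export
detect_itr <- function(contig, min_len = 100, max_mismatch = 0,
                       search_window = 5000) {
  s <- toupper(unname(contig[1]))
  L <- nchar(s)
  w <- min(search_window, L)
  left <- substr(s, 1, w)
  right_start <- L - w + 1
  right_rc <- revcomp(substr(s, right_start, L))
  k <- max(20L, min(min_len, 100L))
  mm <- mem_scan(left, right_rc, k)
  if (!nrow(mm)) return(NULL)
  if (max_mismatch > 0) {
    mm$diag <- mm$start_a - mm$start_b
    mm <- mm[order(mm$diag, mm$start_a), , drop = FALSE]
    joined <- list()
    i <- 1
    while (i <= nrow(mm)) {
      cur <- mm[i, ]
      budget <- max_mismatch
      j <- i + 1
      while (j <= nrow(mm) && mm$diag[j] == cur$diag &&
             (gap <- mm$start_a[j] - (cur$start_a + cur$length)) <= budget &&
             gap >= 0) {
        budget <- budget - gap
        cur$length <- mm$start_a[j] + mm$length[j] - cur$start_a
        j <- j + 1
      }
      joined[[length(joined) + 1]] <- cur[, c("start_a", "start_b", "length")]
      i <- j
    }
    mm <- do.call(rbind, joined)
  }
  mm <- mm[mm$length >= min_len, , drop = FALSE]
  if (!nrow(mm)) return(NULL)
  b <- mm[order(-mm$length, mm$start_a), , drop = FALSE][1, ]
  # map the right copy back from revcomp(right window) coordinates
  right_end <- L - (b$start_b - 1)
  right_beg <- right_end - b$length + 1
  list(length = as.integer(b$length),
       left = c(start = as.integer(b$start_a),
                end = as.integer(b$start_a + b$length - 1)),
       right = c(start = as.integer(right_beg), end = as.integer(right_end)))
}

#' Determine a contig's topology record
#' @inheritParams detect_circularity
#' @inheritParams detect_itr
#' @return list(type, overlap_len, itr) where type is one of
#'   `linear`, `circular`, `itr`, `circular+itr`.
#' @export
detect_topology <- function(contig, min_overlap = 20, min_itr = 100,
                            search_window = 5000) {
  ov <- detect_circularity(contig, min_overlap)
  itr <- detect_itr(contig, min_len = min_itr, search_window = search_window)
  type <- if (!is.null(ov) && !is.null(itr)) "circular+itr"
  else if (!is.null(ov)) "circular"
  else if (!is.null(itr)) "itr"
  else "linear"
  list(type = type, overlap_len = ov %||% 0L, itr = itr)
}

# core-gene assignment ----------------------------------------------------

#' Assign core-gene labels by best profile hit
#'
#' Searches every gene product against per-label profile models (several
#' alternative models per label are allowed, e.g. the two mCP variants) at
#' `e_cut` and assigns each label to at most its best-scoring gene. When one
#' gene would win several labels, assignments are resolved greedily by
#' descending score; exact score ties break deterministically by gene
#' coordinate with a warning.
#'
#' @param annotations annotation data.frame for one or more contigs (with
#'   `protein`).
#' @param core_models named list: label -> `profile_model` or list of models.
#' @param e_cut assignment E-value threshold (default 1e-3).
#' @return the annotations with `product` set to the winning core labels
#'   (other genes keep `"other"`).
#' @export
assign_core_genes <- function(annotations, core_models, e_cut = 1e-3) {
  ann <- annotations
  ann$product <- "other"
  prot <- annotation_proteins(ann)
  if (!length(prot)) return(ann)
  cand <- list()
  for (label in names(core_models)) {
    models <- core_models[[label]]
    if (inherits(models, "profile_model")) models <- list(models)
    hits <- do.call(rbind, lapply(models, profile_search,
                                  proteins = prot, e_cut = e_cut))
    if (is.null(hits) || !nrow(hits)) next
    # best model hit per protein
    hits <- hits[order(-hits$score, hits$protein_id), , drop = FALSE]
    hits <- hits[!duplicated(hits$protein_id), , drop = FALSE]
    hits$label <- label
    cand[[label]] <- hits
  }
  if (!length(cand)) return(ann)
  cand <- do.call(rbind, cand)
  key <- paste0(cand$protein_id)
  ord_start <- ann$start[match(key, paste0(ann$contig_id, "|", ann$gene_id))]
  if (anyDuplicated(round(cand$score, 10)) &&
      any(duplicated(cand[, c("label", "score")])))
    warning("exact score tie during core-gene assignment; ",
            "resolved by gene coordinate")
  cand <- cand[order(-cand$score, ord_start, cand$protein_id), , drop = FALSE]
  assigned_label <- character(0)
  assigned_gene <- character(0)
  for (i in seq_len(nrow(cand))) {
    lb <- cand$label[i]
    pid <- cand$protein_id[i]
    if (lb %in% assigned_label || pid %in% assigned_gene) next
    assigned_label <- c(assigned_label, lb)
    assigned_gene <- c(assigned_gene, pid)
    sel <- paste0(ann$contig_id, "|", ann$gene_id) == pid
    ann$product[sel] <- lb
  }
  ann
}

#' Assign core genes per contig
#'
#' Applies [assign_core_genes()] independently within each contig, so each
#' genome gets its own best gene per core label.
#' @inheritParams assign_core_genes
#' @return relabelled annotations.
#' @export
assign_core_genes_by_contig <- function(annotations, core_models,
                                        e_cut = 1e-3) {
  if (!nrow(annotations)) return(annotations)
  parts <- split(annotations, annotations$contig_id)
  out <- lapply(parts, assign_core_genes, core_models = core_models,
                e_cut = e_cut)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# quality tiers ------------------------------------------------------------

#' Tier virophage genomes by the HQ / complete rules
#'
#' `HQ` requires contig length >= `min_len` and presence of all four core
#' genes; `HQ_complete` additionally requires circular or ITR topology;
#' everything else is `partial`. The three tiers partition the input.
#'
#' @param contigs named DNA vector.
#' @param annotations annotations with core `product` labels assigned.
#' @param topologies named list of [detect_topology()] results per contig.
#' @param min_len HQ size threshold (default 10000 bp).
#' @return data.frame `contig_id`, `length`, `n_core`, `topology`, `quality`
#'   plus a `counts` attribute with the per-tier tally.
#' @export
tier_quality <- function(contigs, annotations, topologies, min_len = 10000) {
  ids <- names(contigs)
  rows <- lapply(ids, function(id) {
    a <- annotations[annotations$contig_id == id, , drop = FALSE]
    ncore <- sum(CORE_GENES %in% a$product)
    topo <- topologies[[id]]$type %||% "linear"
    len <- nchar(contigs[[id]])
    hq <- len >= min_len && ncore == 4
    quality <- if (hq && topo %in% c("circular", "itr", "circular+itr"))
      "HQ_complete" else if (hq) "HQ" else "partial"
    data.frame(contig_id = id, length = len, n_core = ncore,
               topology = topo, quality = quality, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||%
    data.frame(contig_id = character(0), length = integer(0),
               n_core = integer(0), topology = character(0),
               quality = character(0), stringsAsFactors = FALSE)
  attr(out, "counts") <- table(factor(out$quality,
                                      levels = c("HQ_complete", "HQ", "partial")))
  out
}

# de-replication ------------------------------------------------------------

diagonal_identity <- function(s, t, k = 16) {
  mm <- mem_scan(s, t, k)
  if (!nrow(mm)) return(list(identity = 0, span = 0))
  diag <- mm$start_a - mm$start_b
  d_len <- tapply(mm$length, diag, sum)
  d <- as.integer(names(d_len)[which.max(d_len)])
  runs <- mm[diag == d, , drop = FALSE]
  lo <- min(runs$start_a)
  hi <- max(runs$start_a + runs$length - 1)
  a <- strsplit(substr(s, lo, hi), "", fixed = TRUE)[[1]]
  b <- strsplit(substr(t, lo - d, hi - d), "", fixed = TRUE)[[1]]
  list(identity = mean(a == b), span = hi - lo + 1)
}

derep_kmer <- function(alphabet) if (alphabet == "dna") 16L else 8L

seq_alphabet <- function(x) {
  ch <- unique(strsplit(paste(substr(x, 1, 200), collapse = ""), "")[[1]])
  if (all(ch %in% DNA_CHARS)) "dna" else "protein"
}

#' Greedy identity/coverage de-replication
#'
#' Items are sorted by length (descending, ties by id); each item joins the
#' first existing representative it matches - local-alignment identity at
#' least `id_thresh` over at least `cov_thresh` of the shorter sequence -
#' otherwise it becomes a new representative. Deterministic; idempotent on
#' its own representative set.
#'
#' Identity is matches / aligned columns; coverage is the aligned span on the
#' shorter sequence divided by its length (BLAST-style usage). Gene mode
#' defaults to the 95/95 rule, contig mode to 95/80.
#'
#' @param items named character vector (DNA or protein).
#' @param id_thresh identity threshold in (0, 1].
#' @param cov_thresh coverage threshold in (0, 1]; defaults by mode.
#' @param mode `"gene"` or `"contig"` (sets the default coverage threshold).
#' @param min_shared_kmers candidate prefilter: representatives sharing fewer
#'   distinct k-mers (k = 16 nt / 8 aa) with the item are not aligned; the
#'   bar is scaled down to 20% of the shorter sequence's word count for
#'   short sequences (0 disables the prefilter). Pairs near the 95%
#'   identity threshold share far more words than either bar.
#' @param max_align_len pairs in which both sequences exceed this length are
#'   compared by anchored-diagonal matching (exact k-mer chains plus
#'   base-by-base comparison of the dominant diagonal) instead of a full
#'   quadratic local alignment; near-duplicates at the 95% threshold are
#'   substitution-dominated, where the two measures agree.
#' @return list with `representatives` (ids) and `members`
#'   (data.frame `id`, `representative`).
#' @export
dereplicate <- function(items, id_thresh = 0.95, cov_thresh = NULL,
                        mode = c("gene", "contig"), min_shared_kmers = 20,
                        max_align_len = 10000) {
  mode <- match.arg(mode)
  cov_thresh <- cov_thresh %||% if (mode == "gene") 0.95 else 0.80
  stopifnot(id_thresh > 0, id_thresh <= 1, cov_thresh > 0, cov_thresh <= 1)
  if (!length(items))
    return(list(representatives = character(0),
                members = data.frame(id = character(0),
                                     representative = character(0))))
  alpha <- seq_alphabet(items)
  k <- derep_kmer(alpha)
  ord <- order(-nchar(items), names(items))
  ids <- names(items)[ord]
  ksets <- if (min_shared_kmers > 0)
    lapply(items, function(s) unique(kmer_starts(s, k)))
  reps <- character(0)
  assign <- character(length(ids))
  names(assign) <- ids
  for (id in ids) {
    s <- items[[id]]
    placed <- FALSE
    for (r in reps) {
      t <- items[[r]]
      if (min_shared_kmers > 0) {
        # sequences at the 95% merge threshold share a large fraction of
        # their words; scale the bar down for short sequences
        bar <- min(min_shared_kmers,
                   max(1, floor(0.2 * min(length(ksets[[id]]),
                                          length(ksets[[r]])))))
        if (sum(ksets[[id]] %in% ksets[[r]]) < bar) next
      }
      if (min(nchar(s), nchar(t)) > max_align_len && alpha == "dna") {
        di <- diagonal_identity(s, t)
        if (di$identity >= id_thresh &&
            di$span / min(nchar(s), nchar(t)) >= cov_thresh) {
          assign[id] <- r
          placed <- TRUE
          break
        }
        next
      }
      pc <- pair_identity_cov(s, t, type = alpha)
      shorter <- if (nchar(s) <= nchar(t)) "a" else "b"
      cov <- if (shorter == "a") pc$span_a / nchar(s) else pc$span_b / nchar(t)
      if (pc$identity >= id_thresh && cov >= cov_thresh) {
        assign[id] <- r
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, id)
      assign[id] <- id
    }
  }
  list(representatives = reps,
       members = data.frame(id = ids, representative = unname(assign[ids]),
                            stringsAsFactors = FALSE))
}
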