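# Progressive multiple alignment for protein families: k-mer guide tree,
# profile-profile Needleman-Wunsch merges (BLOSUM62, affine 11/1), plus
# gappy-column trimming and per-gene block concatenation. An external
# aligner can be slotted behind the same contract.

profile_freqs <- function(rows) {
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  L <- ncol(mat)
  f <- matrix(0, nrow = 21, ncol = L) # 20 aa + gap
  for (a in seq_along(AA20)) f[a, ] <- colMeans(mat == AA20[a])
  f[21, ] <- colMeans(mat == "-")
  f
}

profile_col_scores <- function(fa, fb, sub) {
  # expected substitution score between columns, gap fraction down-weighted
  wa <- 1 - fa[21, ]
  wb <- 1 - fb[21, ]
  pa <- fa[1:20, , drop = FALSE]
  pb <- fb[1:20, , drop = FALSE]
  na <- pmax(colSums(pa), 1e-9)
  nb <- pmax(colSums(pb), 1e-9)
  pa <- sweep(pa, 2, na, "/")
  pb <- sweep(pb, 2, nb, "/")
  S <- t(pa) %*% sub %*% pb
  S * outer(wa, wb)
}

merge_alignments <- function(A, B, sub, gap_open, gap_ext) {
  S <- profile_col_scores(profile_freqs(A), profile_freqs(B), sub)
  path <- nw_affine_path_c(S, gap_open, gap_ext)
  expand <- function(rows, idx) {
    vapply(rows, function(r) {
      ch <- strsplit(r, "", fixed = TRUE)[[1]]
      paste(ifelse(idx == 0, "-", ch[pmax(idx, 1)]), collapse = "")
    }, character(1))
  }
  c(expand(A, path$a), expand(B, path$b))
}

kmer_profile_dist <- function(seqs, k = 3) {
  sets <- lapply(seqs, function(s) unique(kmer_starts(s, k)))
  n <- length(seqs)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- length(intersect(sets[[i]], sets[[j]]))
      denom <- min(length(sets[[i]]), length(sets[[j]]))
      d[i, j] <- d[j, i] <- 1 - shared / max(denom, 1)
    }
  }
  d
}

#' Progressive multiple alignment of a protein family
#'
#' Pairwise and profile-profile Needleman-Wunsch (BLOSUM62, affine gap
#' open 11 / extend 1) merged along a guide tree built from k-mer distances
#' (average linkage). A single sequence is returned as its own trivial
#' alignment. Ungapping any output row reproduces the input sequence.
#'
#' @param seqs named character vector of protein sequences.
#' @param gap_open,gap_ext affine gap penalties.
#' @return named character vector of aligned rows (equal length, gap `-`),
#'   in the input order.
#' @export
align_proteins <- function(seqs, gap_open = 11, gap_ext = 1) {
  n <- length(seqs)
  if (n == 0) return(seqs)
  if (n == 1) return(seqs)
  sub <- blosum62()
  d <- kmer_profile_dist(unname(seqs))
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  # follow the merge order of the guide tree
  alns <- as.list(seq_len(n)) # leaf index sets
  content <- lapply(seqs, function(s) s)
  node_aln <- vector("list", nrow(hc$merge))
  node_idx <- vector("list", nrow(hc$merge))
  get_node <- function(x) {
    if (x < 0) list(aln = unname(seqs[-x]), idx = -x)
    else list(aln = node_aln[[x]], idx = node_idx[[x]])
  }
  for (m in seq_len(nrow(hc$merge))) {
    a <- get_node(hc$merge[m, 1])
    b <- get_node(hc$merge[m, 2])
    node_aln[[m]] <- merge_alignments(a$aln, b$aln, sub, gap_open, gap_ext)
    node_idx[[m]] <- c(a$idx, b$idx)
  }
  final <- node_aln[[nrow(hc$merge)]]
  idx <- node_idx[[nrow(hc$merge)]]
  out <- final[order(idx)]
  names(out) <- names(seqs)
  out
}

#' Remove gappy alignment columns
#'
#' Drops columns whose gap fraction exceeds `max_gap_fraction` (default 0.90,
#' the gappy-column rule). Idempotent; errors if nothing would remain.
#'
#' @param alignment named character vector of equal-length rows.
#' @param max_gap_fraction maximum tolerated gap fraction per column.
#' @return trimmed alignment with a `kept_columns` attribute (original
#'   column indices).
#' @export
trim_alignment <- function(alignment, max_gap_fraction = 0.90) {
  stopifnot(length(alignment) >= 1)
  mat <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  gap_frac <- colMeans(mat == "-")
  keep <- which(gap_frac <= max_gap_fraction)
  if (!length(keep))
    stop("trimming removed all columns; raise max_gap_fraction",
         call. = FALSE)
  out <- apply(mat[, keep, drop = FALSE], 1, paste, collapse = "")
  names(out) <- names(alignment)
  attr(out, "kept_columns") <- keep
  out
}

#' Concatenate per-gene alignments into one genome alignment
#'
#' Each alignment's rows must be named by genome id. Genomes missing any
#' gene are excluded with a warning (the HQ contract expects all four core
#' genes). Partition boundaries are recorded.
#'
#' @param alignments named list of alignments (one per gene, in the desired
#'   block order, e.g. MCP, mCP, ATPase, PRO).
#' @return named character vector of concatenated rows with a `partitions`
#'   attribute (data.frame `gene`, `start`, `end`).
#' @export
concatenate_alignments <- function(alignments) {
  stopifnot(length(alignments) >= 1)
  genomes <- Reduce(intersect, lapply(alignments, names))
  all_ids <- unique(unlist(lapply(alignments, names)))
  missing <- setdiff(all_ids, genomes)
  if (length(missing))
    warning("excluded genome(s) missing a core gene: ",
            paste(missing, collapse = ", "))
  if (!length(genomes))
    stop("no genome has all genes", call. = FALSE)
  genomes <- sort(genomes)
  blocks <- lapply(alignments, function(a) a[genomes])
  widths <- vapply(blocks, function(b) nchar(b[[1]]), numeric(1))
  rows <- do.call(paste0, blocks)
  names(rows) <- genomes
  ends <- cumsum(widths)
  parts <- data.frame(gene = names(alignments) %||%
                        sprintf("block%d", seq_along(alignments)),
                      start = c(1, utils::head(ends, -1) + 1), end = ends)
  attr(rows, "partitions") <- parts
  rows
}
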