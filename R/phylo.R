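# Concatenated core-gene phylogeny: WAG maximum-likelihood pairwise
# distances -> neighbor joining, column-resampling bootstrap supports,
# average-branch-length clade collapse (< 1.2 substitutions/site at
# support >= 0.8), synteny signatures, and the model x habitat profile.

alignment_phydat <- function(alignment) {
  mat <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  rownames(mat) <- names(alignment)
  phangorn::phyDat(mat, type = "AA")
}

nj_wag <- function(mat) {
  pd <- phangorn::phyDat(mat, type = "AA")
  d <- phangorn::dist.ml(pd, model = "WAG")
  tr <- ape::nj(d)
  tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}

#' Build a core-gene tree from a concatenated alignment
#'
#' Neighbor joining on WAG maximum-likelihood pairwise distances, rooted at
#' the midpoint, with node supports from a column-resampling bootstrap
#' (seeded, default 100 replicates). Branch lengths are in substitutions per
#' site; supports in \[0, 1\] are stored in `node.label`. An external ML
#' backend can be substituted behind the same contract.
#'
#' @param alignment named character vector of aligned rows (>= 4).
#' @param method currently `"nj"`.
#' @param bootstrap number of bootstrap replicates (0 disables supports).
#' @param seed RNG seed for resampling.
#' @return a rooted `phylo` tree with `node.label` supports.
#' @export
build_tree <- function(alignment, method = "nj", bootstrap = 100, seed = 1) {
  if (length(alignment) < 4)
    stop("tree inference needs at least 4 sequences", call. = FALSE)
  mat <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  rownames(mat) <- names(alignment)
  tr <- nj_wag(mat)
  tr <- phangorn::midpoint(tr)
  tr$edge.length <- pmax(tr$edge.length, 0)
  nnode <- tr$Nnode
  if (bootstrap > 0) {
    set.seed(seed)
    btrees <- vector("list", bootstrap)
    for (b in seq_len(bootstrap)) {
      cols <- sample.int(ncol(mat), replace = TRUE)
      btrees[[b]] <- nj_wag(mat[, cols, drop = FALSE])
    }
    class(btrees) <- "multiPhylo"
    counts <- ape::prop.clades(tr, btrees, rooted = FALSE)
    counts[is.na(counts)] <- 0
    support <- counts / bootstrap
    support[1] <- 1 # root split is trivial
    tr$node.label <- formatC(support, format = "f", digits = 3)
  } else {
    tr$node.label <- rep("", nnode)
  }
  tr
}

node_supports <- function(tree) {
  s <- suppressWarnings(as.numeric(tree$node.label))
  s[is.na(s)] <- 1
  s
}

#' Collapse a tree into clades by average branch length
#'
#' Finds the maximal subtrees whose mean root-to-leaf path length is below
#' `max_avg_branch_length` substitutions per site and whose support is at
#' least `min_support`; their leaves become one clade each. Leaves not
#' covered become singleton clades (flagged). Clades are numbered `Vp.cl1`,
#' `Vp.cl2`, ... in tree traversal (preorder) order.
#'
#' @param tree rooted `phylo` with supports in `node.label`.
#' @param max_avg_branch_length collapse threshold (default 1.2
#'   substitutions/site).
#' @param min_support minimum support of a collapsed clade (default 0.8).
#' @return data.frame `genome_id`, `clade_id`, `support`, `singleton`.
#' @export
collapse_clades <- function(tree, max_avg_branch_length = 1.2,
                            min_support = 0.8) {
  ntip <- length(tree$tip.label)
  support <- node_supports(tree)
  root <- ntip + 1
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  elen <- stats::setNames(tree$edge.length, tree$edge[, 2])
  # mean depth of leaves under each node
  depth_info <- new.env()
  mean_depth <- function(v) {
    key <- as.character(v)
    if (!is.null(depth_info[[key]])) return(depth_info[[key]])
    res <- if (v <= ntip) c(n = 1, sum = 0) else {
      parts <- vapply(kids[[key]], function(k) {
        r <- mean_depth(k)
        c(r["n"], r["sum"] + r["n"] * elen[[as.character(k)]])
      }, numeric(2))
      c(n = sum(parts[1, ]), sum = sum(parts[2, ]))
    }
    names(res) <- c("n", "sum")
    depth_info[[key]] <- res
    res
  }
  leaves_under <- function(v) {
    if (v <= ntip) return(tree$tip.label[v])
    unlist(lapply(kids[[as.character(v)]], leaves_under))
  }
  clades <- list()
  visit <- function(v) {
    if (v <= ntip) {
      clades[[length(clades) + 1]] <<- list(leaves = tree$tip.label[v],
                                            support = 1, singleton = TRUE)
      return(invisible())
    }
    md <- mean_depth(v)
    sup <- support[v - ntip]
    if ((md["sum"] / md["n"]) < max_avg_branch_length && sup >= min_support) {
      lv <- leaves_under(v)
      clades[[length(clades) + 1]] <<- list(leaves = lv, support = sup,
                                            singleton = length(lv) == 1)
      return(invisible())
    }
    for (k in kids[[as.character(v)]]) visit(k)
  }
  visit(root)
  rows <- lapply(seq_along(clades), function(i) {
    cl <- clades[[i]]
    data.frame(genome_id = cl$leaves, clade_id = paste0("Vp.cl", i),
               support = cl$support, singleton = cl$singleton,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# synteny ------------------------------------------------------------------

#' Canonical core-gene synteny signature of a genome
#'
#' Core genes (plus MTase) in genomic order with strands, canonicalized so
#' the MCP lies on the forward strand (otherwise the order is reversed and
#' strands flipped); circular genomes are additionally rotated so the MCP
#' block comes last, giving one normal form per circular permutation. A
#' genome and its reverse complement map to the same signature. Without an
#' MCP the unoriented signature is returned with `oriented = FALSE`.
#'
#' @param annotations annotations of one genome with core labels assigned.
#' @param circular is the genome circular (rotation allowed)?
#' @param adjacency_max_gap maximum intergenic gap (bp) for two core genes to
#'   count as adjacent.
#' @return list with `signature` (e.g. `"ATPase+|mCP+|MCP+"`), `labels`,
#'   `strands`, `oriented`, `mcp_mcp_adjacent`, `atpase_mcp_mcp_in_order`.
#' @export
synteny_signature <- function(annotations, circular = FALSE,
                              adjacency_max_gap = 1000) {
  a <- annotations[annotations$product %in% CORE_PLUS, , drop = FALSE]
  a <- a[order(a$start), , drop = FALSE]
  if (!nrow(a))
    return(list(signature = "", labels = character(0), strands = character(0),
                oriented = FALSE, mcp_mcp_adjacent = FALSE,
                atpase_mcp_mcp_in_order = FALSE))
  labels <- a$product
  strands <- a$strand
  gaps <- if (nrow(a) > 1) a$start[-1] - a$end[-nrow(a)] - 1 else numeric(0)
  oriented <- "MCP" %in% labels
  if (oriented && strands[match("MCP", labels)] == "-") {
    labels <- rev(labels)
    strands <- rev(ifelse(strands == "+", "-", "+"))
    gaps <- rev(gaps)
  }
  if (oriented && circular && length(labels) > 1) {
    # rotate so MCP is the first gene of the block
    i <- match("MCP", labels)
    rot <- function(x, i) if (i == 1) x else c(x[i:length(x)], x[1:(i - 1)])
    labels <- rot(labels, i)
    strands <- rot(strands, i)
  }
  adj <- function(l1, l2) {
    i <- which(labels == l1)
    j <- which(labels == l2)
    length(i) == 1 && length(j) == 1 && abs(i - j) == 1
  }
  in_order <- function(ls) {
    idx <- match(ls, labels)
    !anyNA(idx) && all(diff(idx) == 1)
  }
  list(signature = paste0(labels, strands, collapse = "|"),
       labels = labels, strands = strands, oriented = oriented,
       mcp_mcp_adjacent = adj("MCP", "mCP"),
       atpase_mcp_mcp_in_order = in_order(c("ATPase", "mCP", "MCP")))
}

#' Count conserved synteny-block templates across genomes
#'
#' Tallies genomes matching the five-gene ancestral block (four core genes
#' plus MTase colocalized), the four-core-gene block, the three-gene
#' truncation without ATPase, and the MCP-mCP adjacency.
#'
#' @param annotations_by_genome named list of per-genome annotations.
#' @param max_gap maximum intergenic gap (bp) within a colocalized block.
#' @return list with per-genome data.frame `blocks` and a `counts` vector.
#' @export
detect_synteny_blocks <- function(annotations_by_genome, max_gap = 1000) {
  rows <- lapply(names(annotations_by_genome), function(id) {
    a <- annotations_by_genome[[id]]
    a <- a[a$product %in% CORE_PLUS, , drop = FALSE]
    a <- a[order(a$start), , drop = FALSE]
    colocal <- function(set) {
      idx <- match(set, a$product)
      if (anyNA(idx)) return(FALSE)
      idx <- sort(idx)
      if (!all(diff(idx) >= 1)) return(FALSE)
      span <- a[min(idx):max(idx), , drop = FALSE]
      if (!all(span$product %in% CORE_PLUS)) return(FALSE)
      gaps <- span$start[-1] - span$end[-nrow(span)] - 1
      all(gaps <= max_gap)
    }
    sig <- synteny_signature(a)
    data.frame(
      genome_id = id,
      five_gene = colocal(CORE_PLUS),
      four_gene = colocal(CORE_GENES) && !colocal(CORE_PLUS),
      three_gene_no_atpase = !("ATPase" %in% a$product) &&
        colocal(c("MCP", "mCP", "PRO")),
      mcp_mcp_adjacent = sig$mcp_mcp_adjacent,
      atpase_mcp_mcp = sig$atpase_mcp_mcp_in_order,
      signature = sig$signature,
      stringsAsFactors = FALSE)
  })
  blocks <- do.call(rbind, rows)
  counts <- c(five_gene = sum(blocks$five_gene),
              four_gene = sum(blocks$four_gene),
              three_gene_no_atpase = sum(blocks$three_gene_no_atpase),
              mcp_mcp_adjacent = sum(blocks$mcp_mcp_adjacent),
              atpase_mcp_mcp = sum(blocks$atpase_mcp_mcp))
  list(blocks = blocks, counts = counts)
}

# habitat profile -----------------------------------------------------------

#' Model x habitat profile with quantile normalization and clustering
#'
#' Converts a hit-count matrix (models x habitats) to per-habitat
#' percentages, quantile-normalizes the habitat columns (each mapped onto
#' the mean sorted profile) and clusters both axes by complete-linkage
#' hierarchical clustering of Euclidean distances. All-zero rows or columns
#' are dropped with a warning.
#'
#' @param counts non-negative matrix, rows = models, columns = habitats.
#' @return list with `matrix` (normalized percentages), `row_hclust`,
#'   `col_hclust`, `row_order`, `col_order`.
#' @export
habitat_profile <- function(counts) {
  m <- as.matrix(counts)
  stopifnot(all(m >= 0))
  zr <- rowSums(m) == 0
  zc <- colSums(m) == 0
  if (any(zr) || any(zc)) {
    warning("dropping all-zero row(s)/column(s): ",
            paste(c(rownames(m)[zr], colnames(m)[zc]), collapse = ", "))
    m <- m[!zr, !zc, drop = FALSE]
  }
  pct <- sweep(m, 2, colSums(m), "/") * 100
  qn <- limma::normalizeQuantiles(pct)
  dimnames(qn) <- dimnames(pct)
  rh <- stats::hclust(stats::dist(qn), method = "complete")
  ch <- stats::hclust(stats::dist(t(qn)), method = "complete")
  list(matrix = qn, row_hclust = rh, col_hclust = ch,
       row_order = rownames(qn)[rh$order], col_order = colnames(qn)[ch$order])
}
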