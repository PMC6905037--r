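# Alignment, trimming, concatenation, tree + clade collapse, synteny
# signatures, and the habitat profile.

test_that("alignment invariants: identity, gaplessness, ungap round trip", {
  set.seed(41)
  s <- random_aa(150)
  aln <- align_proteins(c(a = s, b = s))
  expect_identical(unname(aln), c(s, s))

  fam <- sim_protein_family(200, 5, 0.7)
  aln2 <- align_proteins(fam$members)
  # substitution-only families align without gap columns
  expect_false(any(grepl("-", aln2, fixed = TRUE)))
  for (id in names(fam$members))
    expect_identical(gsub("-", "", aln2[[id]]), fam$members[[id]])
})

test_that("indel families still round-trip through the aligner", {
  set.seed(42)
  base <- random_aa(180)
  with_del <- paste0(substr(base, 1, 80), substr(base, 101, 180))
  aln <- align_proteins(c(full = base, del = with_del))
  expect_identical(gsub("-", "", aln[["del"]]), with_del)
  expect_identical(gsub("-", "", aln[["full"]]), base)
  expect_equal(nchar(aln[["full"]]), nchar(aln[["del"]]))
})

test_that("trimming drops only over-gapped columns and is idempotent", {
  aln <- c(a = "AC-DE", b = "AC-DE", c = "ACKDE")
  tr <- trim_alignment(aln, max_gap_fraction = 0.5)
  expect_identical(as.character(tr), c("ACDE", "ACDE", "ACDE"))
  expect_identical(as.character(trim_alignment(tr, 0.5)), as.character(tr))
  gapless <- c(a = "ACDE", b = "ACDE")
  expect_identical(as.character(trim_alignment(gapless)),
                   as.character(gapless))
  # a column with 95% gaps falls to the 90% rule
  rows <- c(paste0("A", "C"), rep(paste0("-", "C"), 19))
  names(rows) <- paste0("r", 1:20)
  tr2 <- trim_alignment(rows, 0.90)
  expect_identical(as.character(tr2[1]), "C")
  expect_error(trim_alignment(c(a = "-", b = "-"), 0.5), "all columns")
})

test_that("concatenation stitches blocks with recorded partitions", {
  a1 <- c(g1 = strrep("A", 100), g2 = strrep("C", 100), g3 = strrep("D", 100))
  a2 <- c(g1 = strrep("E", 80), g2 = strrep("F", 80), g3 = strrep("G", 80))
  a3 <- c(g1 = strrep("H", 120), g2 = strrep("I", 120), g3 = strrep("K", 120))
  a4 <- c(g1 = strrep("L", 60), g2 = strrep("M", 60), g3 = strrep("N", 60))
  cc <- concatenate_alignments(list(MCP = a1, mCP = a2, ATPase = a3, PRO = a4))
  expect_equal(unique(nchar(cc)), 360)
  parts <- attr(cc, "partitions")
  expect_equal(parts$end[4], 360)
  expect_equal(sum(parts$end - parts$start + 1), 360)
  # row order independent of input order
  cc2 <- concatenate_alignments(list(MCP = a1[c(3, 1, 2)], mCP = a2,
                                     ATPase = a3, PRO = a4))
  expect_identical(cc[sort(names(cc))], cc2[sort(names(cc2))])
  # genomes missing a gene are excluded with a warning
  expect_warning(cc3 <- concatenate_alignments(list(MCP = a1, mCP = a2[1:2],
                                                    ATPase = a3, PRO = a4)),
                 "g3")
  expect_length(cc3, 2)
})

make_lineage_alignments <- function(n_per = 5, genes = c("MCP", "mCP"),
                                    lens = c(300, 200), within = 0.9) {
  lin_anc <- lapply(1:3, function(li)
    lapply(lens, function(L) random_aa(L)))
  per_gene <- list()
  truth <- character(0)
  for (gi in seq_along(genes)) {
    seqs <- character(0)
    for (li in 1:3) {
      for (k in seq_len(n_per)) {
        id <- sprintf("t_L%d_%02d", li, k)
        seqs[id] <- mutate_at(lin_anc[[li]][[gi]], runif(1, within, 0.97), AA_T)
        truth[id] <- li
      }
    }
    per_gene[[genes[gi]]] <- seqs
  }
  list(per_gene = per_gene, truth = truth)
}

test_that("deep planted lineages give monophyletic, well-supported clades", {
  set.seed(43)
  fx <- make_lineage_alignments()
  concat <- concatenate_alignments(lapply(fx$per_gene, align_proteins))
  tree <- build_tree(concat, bootstrap = 100, seed = 1)
  expect_s3_class(tree, "phylo")
  cl <- collapse_clades(tree)
  expect_equal(length(unique(cl$clade_id)), 3)
  expect_true(all(cl$support >= 0.8))
  expect_equal(ari_index(fx$truth[cl$genome_id], cl$clade_id), 1.0)
  # clades partition the leaves
  expect_identical(sort(cl$genome_id), sort(tree$tip.label))
  expect_equal(anyDuplicated(cl$genome_id), 0L)
})

test_that("degenerate trees: <4 rows error; identical rows collapse to one", {
  expect_error(build_tree(c(a = "AC", b = "AC", c = "AC")), "at least 4")
  rows <- setNames(rep(strrep("ACDEFGHIKL", 20), 5), paste0("g", 1:5))
  tree <- build_tree(rows, bootstrap = 10, seed = 1)
  expect_lt(max(tree$edge.length), 1e-8)
  cl <- collapse_clades(tree)
  expect_equal(length(unique(cl$clade_id)), 1)
})

test_that("synteny signatures canonicalize across strand and orientation", {
  mk <- function(labels, strands, starts) {
    data.frame(contig_id = "c", gene_id = paste0("g", seq_along(labels)),
               start = starts, end = starts + 600, strand = strands,
               product = labels, protein = NA, stringsAsFactors = FALSE)
  }
  ann <- mk(c("ATPase", "mCP", "MCP"), c("+", "+", "+"), c(100, 800, 1500))
  sig <- synteny_signature(ann)
  expect_identical(sig$signature, "ATPase+|mCP+|MCP+")
  expect_true(sig$mcp_mcp_adjacent)
  expect_true(sig$atpase_mcp_mcp_in_order)

  # the reverse-complement layout maps to the same signature
  L <- 5000
  ann_rc <- mk(c("MCP", "mCP", "ATPase"), c("-", "-", "-"),
               L - c(1500, 800, 100) - 600)
  sig_rc <- synteny_signature(ann_rc)
  expect_identical(sig_rc$signature, sig$signature)

  # five-gene ancestral block
  ann5 <- mk(c("MTase", "PRO", "ATPase", "mCP", "MCP"), rep("+", 5),
             seq(100, by = 700, length.out = 5))
  bl <- detect_synteny_blocks(list(g = ann5))
  expect_equal(unname(bl$counts["five_gene"]), 1)
  expect_equal(unname(bl$counts["mcp_mcp_adjacent"]), 1)

  # missing MCP: unoriented flag
  sig0 <- synteny_signature(mk(c("mCP", "PRO"), c("+", "+"), c(100, 800)))
  expect_false(sig0$oriented)
})

test_that("habitat profile: quantile normalization and clustering", {
  set.seed(44)
  # continuous counts: quantile normalization makes column distributions
  # identical as multisets only in the absence of ties (ties get averaged)
  m <- matrix(runif(40, 5, 50), nrow = 8,
              dimnames = list(paste0("model", 1:8), paste0("h", 1:5)))
  m[, 5] <- m[, 4] # identical habitats
  hp <- habitat_profile(m)
  ref <- sort(unname(hp$matrix[, 1]))
  for (j in 2:5) expect_equal(sort(unname(hp$matrix[, j])), ref,
                              tolerance = 1e-12)
  # the identical columns join first (distance zero)
  merge1 <- hp$col_hclust$merge[1, ]
  expect_identical(sort(colnames(m)[-merge1]), c("h4", "h5"))
  expect_equal(hp$col_hclust$height[1], 0)
  # all-zero rows are dropped with a warning
  m2 <- m
  m2[3, ] <- 0
  expect_warning(hp2 <- habitat_profile(m2), "model3")
  expect_equal(nrow(hp2$matrix), 7)
})
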