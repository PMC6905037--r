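# MIMIVIRE shared-seed search, repeat-unit counting, translated-motif
# verification, and whole-corpus linking.

test_that("shared seeds match a brute-force enumeration on small contigs", {
  set.seed(51)
  for (rep in 1:3) {
    a <- random_nt(1500)
    b <- random_nt(1500)
    seed <- substr(a, 301, 327)
    b <- paste0(substr(b, 1, 700), seed, substr(b, 728, 1500))
    got <- shared_seeds(a, b)
    fwd <- got[got$gv_strand == "+", ]
    want <- brute_shared(a, b)
    expect_equal(nrow(fwd), nrow(want))
    expect_setequal(fwd$vp_start, want$start)
    expect_setequal(fwd$length, want$len)
  }
})

test_that("random contig pairs share no 24-mer", {
  set.seed(52)
  for (i in 1:20) {
    expect_equal(nrow(shared_seeds(random_nt(5000), random_nt(5000))), 0)
  }
})

test_that("a 31-nt identity is reported once as a maximal match", {
  set.seed(53)
  a <- random_nt(800)
  seed31 <- substr(a, 101, 131)
  b <- paste0(random_nt(300), seed31, random_nt(300))
  got <- shared_seeds(a, b)
  expect_equal(nrow(got), 1)
  expect_gte(got$length, 31)
})

test_that("seeds on the reverse strand are found and remapped", {
  set.seed(54)
  a <- random_nt(900)
  seed <- substr(a, 200, 226)
  b <- paste0(random_nt(150), revcomp(seed), random_nt(150))
  got <- shared_seeds(a, b)
  expect_equal(nrow(got), 1)
  expect_identical(got$gv_strand, "-")
  expect_identical(substr(b, got$gv_start, got$gv_start + got$length - 1),
                   revcomp(got$seed))
})

test_that("repeat-unit counting: copies, boundaries, overlap dedup", {
  set.seed(55)
  seed <- random_nt(27)
  unit <- substr(seed, 4, 21)
  # mismatching flanks around the standalone copies so no shifted unit is
  # equally repeated
  wrap <- function(u) paste0("C", u, "C")
  gene <- paste0(random_nt(90), seed, random_nt(60), wrap(unit),
                 random_nt(45), wrap(unit), random_nt(90))
  rep3 <- repeated_subset(seed, gene)
  expect_identical(rep3$unit, unit)
  expect_equal(rep3$copies, 3)

  gene1 <- paste0(random_nt(90), seed, random_nt(90))
  expect_null(repeated_subset(seed, gene1, min_copies = 2))
  expect_equal(repeated_subset(seed, gene1, min_copies = 1)$copies, 1)

  # period-1 repeat: overlapping occurrences are distinct start positions
  seedA <- strrep("A", 24)
  geneA <- paste0("CGT", strrep("A", 30), "CGT")
  rpA <- repeated_subset(seedA, geneA, unit_len = 18, tol = 2)
  # brute force over distinct starts: a 16-mer of A occurs 30-16+1 = 15
  # times in a run of 30, the maximum over unit lengths 16-20
  expect_equal(rpA$copies, 15)
  expect_equal(nchar(rpA$unit), 16)
})

test_that("translated motifs: DDES pattern and frame agreement", {
  # codon-exact seed encoding DDESDDES plus one more residue
  seed <- "GATGACGAATCTGATGACGAATCTGCA" # DDESDDESA, 27 nt
  tm <- translated_motif_check(seed)
  expect_true(tm$frame_agreement)
  expect_identical(substr(tm$motifs_vp[1], 1, 8), "DDESDDES")
  expect_equal(length(grep("DDES", tm$motifs_vp[1], fixed = TRUE)), 1)

  # identical nucleotides imply agreement even when one side is frameshifted
  vp_region <- seed
  gv_region <- seed
  tm2 <- translated_motif_check(seed, vp_region, gv_region)
  expect_true(tm2$frame_agreement)

  # a seed spanning stops still records motifs
  seed_stop <- paste0("TAATAGTGA", "GATGACGAATCT", "TAA")
  tm3 <- translated_motif_check(seed_stop)
  expect_true(grepl("\\*", tm3$motifs_vp[1]))

  expect_true(translated_motif_check("ACGTACGTACGT")$skipped)
})

test_that("whole-corpus linking recovers every planted link and no decoys", {
  corpus <- tiny_corpus()
  vp <- corpus$contigs[startsWith(names(corpus$contigs), "vp")]
  links <- link_all(vp, corpus$giant_contigs, corpus$giant_annotations)
  truth <- corpus$truth$links
  expect_equal(nrow(links), length(truth))
  for (l in truth) {
    row <- links[links$virophage_id == l$virophage_id &
                   links$gv_id == l$gv_id, ]
    expect_equal(nrow(row), 1)
    expect_true(grepl(l$seed, row$seed, fixed = TRUE) ||
                  grepl(row$seed, l$seed, fixed = TRUE))
    expect_identical(row$unit, l$unit)
    expect_equal(row$copies, l$copies)
    expect_identical(row$gene_id, l$gene_id)
  }
  # decoy cross-pairs yield nothing
  decoy_links <- link_all(corpus$contigs[corpus$truth$decoy_ids],
                          corpus$giant_contigs, corpus$giant_annotations)
  expect_equal(nrow(decoy_links), 0)
  expect_equal(nrow(link_all(vp, character(0), corpus$giant_annotations)), 0)
})

test_that("link set is invariant under reverse-complementing the giant", {
  corpus <- tiny_corpus()
  l <- corpus$truth$links[[1]]
  vp <- corpus$contigs[l$virophage_id]
  gv <- corpus$giant_contigs[l$gv_id]
  ann <- corpus$giant_annotations[
    corpus$giant_annotations$contig_id == l$gv_id, ]
  L <- nchar(gv[[1]])
  ann_rc <- ann
  ann_rc$start <- L - ann$end + 1
  ann_rc$end <- L - ann$start + 1
  ann_rc$strand <- ifelse(ann$strand == "+", "-", "+")
  gv_rc <- setNames(revcomp(gv[[1]]), names(gv))
  fwd <- link_all(vp, gv, ann)
  rev <- link_all(vp, gv_rc, ann_rc)
  expect_equal(nrow(fwd), nrow(rev))
  expect_identical(fwd$copies, rev$copies)
  expect_identical(sort(c(fwd$unit, revcomp(fwd$unit))[1]),
                   sort(c(rev$unit, revcomp(rev$unit))[1]))
})

test_that("same-sample co-occurrence boosts rank", {
  set.seed(56)
  mk_pair <- function(tag) {
    seed <- random_nt(27)
    unit <- substr(seed, 1, 18)
    # fixed mismatching flanks keep seed length and copy count identical
    # across the two pairs, so the rank comparison isolates co-occurrence
    vp <- paste0(random_nt(1000), "A", seed, "A", random_nt(1000))
    gene <- paste0(random_nt(120), "C", seed, "C", random_nt(60),
                   "G", unit, "G", random_nt(120))
    gv <- paste0(random_nt(200), gene, random_nt(200))
    list(vp = vp, gv = gv,
         ann = data.frame(contig_id = paste0("gv", tag),
                          gene_id = paste0("gv", tag, "_g1"),
                          start = 201, end = 200 + nchar(gene), strand = "+",
                          product = "other", protein = NA,
                          stringsAsFactors = FALSE))
  }
  p1 <- mk_pair(1)
  p2 <- mk_pair(2)
  samples <- data.frame(contig_id = c("vp1", "vp2", "gv1", "gv2"),
                        sample = c("lakeA", "lakeB", "lakeX", "lakeB"))
  links <- link_all(c(vp1 = p1$vp, vp2 = p2$vp),
                    c(gv1 = p1$gv, gv2 = p2$gv),
                    rbind(p1$ann, p2$ann), samples = samples)
  expect_equal(nrow(links), 2)
  expect_true(links$co_occurrence[links$virophage_id == "vp2"])
  expect_identical(links$virophage_id[1], "vp2") # co-occurring pair ranks first
})
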