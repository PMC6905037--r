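# Topology detectors, quality tiers, and greedy de-replication (including
# the brute-force oracle equivalence).

test_that("circularity detection on planted and hand-checkable cases", {
  expect_equal(detect_circularity("ACGTACGT", min_overlap = 4), 4)
  corpus <- tiny_corpus()
  circ <- Filter(function(v) v$topology == "circular", corpus$truth$virophages)
  for (v in circ)
    expect_equal(detect_circularity(corpus$contigs[v$id]), v$overlap_len)
  lin <- Filter(function(v) v$topology == "linear", corpus$truth$virophages)
  for (v in lin)
    expect_null(detect_circularity(corpus$contigs[v$id]))
})

test_that("ITR detection returns exact planted lengths and spans", {
  corpus <- tiny_corpus()
  itrs <- Filter(function(v) v$topology == "itr", corpus$truth$virophages)
  expect_gt(length(itrs), 0)
  for (v in itrs) {
    hit <- detect_itr(corpus$contigs[v$id])
    expect_equal(hit$length, v$itr_len)
    expect_equal(unname(hit$left), v$itr_left)
    expect_equal(unname(hit$right), v$itr_right)
  }
})

test_that("a 99-bp terminal repeat stays below the 100-bp ITR floor", {
  set.seed(21)
  t99 <- random_nt(99)
  # explicit boundary mismatch ('A' vs complement 'A' -> 'T') so the planted
  # repeat cannot extend by chance
  s <- paste0(t99, "A", random_nt(6000), "A", revcomp(t99))
  expect_null(detect_itr(s, min_len = 100))
  expect_equal(detect_itr(s, min_len = 90)$length, 99)
})

test_that("a palindromic contig reports a single terminus-spanning ITR", {
  set.seed(22)
  half <- random_nt(600)
  s <- paste0(half, revcomp(half))
  hit <- detect_itr(s, min_len = 100, search_window = 1200)
  # the whole contig is its own reverse complement: one hit spanning the
  # termini, not two mirrored reports
  expect_false(is.null(hit))
  expect_gte(hit$length, 600)
  expect_equal(unname(hit$left["start"]), 1)
  expect_equal(unname(hit$right["end"]), nchar(s))
})

test_that("topology detectors are invariant under relabeling/revcomp", {
  corpus <- tiny_corpus()
  v <- Filter(function(x) x$topology == "itr", corpus$truth$virophages)[[1]]
  s <- corpus$contigs[[v$id]]
  rc <- revcomp(s)
  expect_equal(detect_itr(s)$length, detect_itr(rc)$length)
  names(s) <- "renamed"
  expect_equal(detect_itr(s)$length, v$itr_len)
})

test_that("quality tiers follow the HQ / complete definitions", {
  mk_ann <- function(id, labels) {
    n <- length(labels)
    data.frame(contig_id = id, gene_id = paste0("g", seq_len(n)),
               start = seq(1, by = 1000, length.out = n),
               end = seq(900, by = 1000, length.out = n),
               strand = "+", product = labels, protein = NA,
               stringsAsFactors = FALSE)
  }
  contigs <- c(a = strrep("A", 12000), b = strrep("A", 12000),
               c = strrep("A", 9900))
  ann <- rbind(mk_ann("a", c("MCP", "mCP", "ATPase", "PRO")),
               mk_ann("b", c("MCP", "mCP", "ATPase", "PRO")),
               mk_ann("c", c("MCP", "mCP", "ATPase", "PRO")))
  topo <- list(a = list(type = "linear"), b = list(type = "circular"),
               c = list(type = "linear"))
  qc <- tier_quality(contigs, ann, topo)
  expect_identical(qc$quality, c("HQ", "HQ_complete", "partial"))
  counts <- attr(qc, "counts")
  expect_equal(sum(counts), nrow(qc)) # tiers partition the input
})

test_that("greedy de-replication basics and thresholds", {
  set.seed(23)
  s <- random_nt(2000)
  dr <- dereplicate(c(b = s, a = s), mode = "contig")
  expect_identical(dr$representatives, "a") # lexicographic tie-break
  expect_identical(unique(dr$members$representative), "a")

  # 95% identity over only 79% of the shorter contig: NOT merged at 95/80
  long <- random_nt(4000)
  short <- paste0(mutate_at(substr(long, 1, 2370), 0.96, c("A", "C", "G", "T")),
                  random_nt(630))
  dr2 <- dereplicate(c(L = long, S = short), mode = "contig")
  expect_length(dr2$representatives, 2)
  # the same pair merges once coverage can reach 80%
  short3 <- paste0(mutate_at(substr(long, 1, 2700), 0.97, c("A", "C", "G", "T")),
                   random_nt(300))
  dr3 <- dereplicate(c(L = long, S = short3), mode = "contig")
  expect_length(dr3$representatives, 1)
})

test_that("de-replication is idempotent on its representatives", {
  set.seed(24)
  base <- vapply(1:5, function(i) random_nt(1500), "")
  items <- character(0)
  for (i in 1:5) {
    items[paste0("b", i)] <- base[i]
    items[paste0("c", i)] <- mutate_at(base[i], 0.97, c("A", "C", "G", "T"))
  }
  dr <- dereplicate(items, mode = "contig")
  reps <- items[dr$representatives]
  dr2 <- dereplicate(reps, mode = "contig")
  expect_identical(sort(dr2$representatives), sort(dr$representatives))
})

test_that("greedy clustering equals the exhaustive all-pairs oracle", {
  set.seed(25)
  for (rep in 1:3) {
    base <- vapply(1:6, function(i) random_nt(sample(800:1500, 1)), "")
    items <- character(0)
    k <- 0
    for (i in 1:6) {
      for (j in 1:3) {
        k <- k + 1
        v <- mutate_at(base[i], runif(1, 0.9, 1.0), c("A", "C", "G", "T"))
        if (runif(1) < 0.3) v <- substr(v, 1, round(nchar(v) * runif(1, 0.7, 0.95)))
        items[sprintf("s%02d", k)] <- v
      }
    }
    items <- c(items, s98 = random_nt(1000), s99 = random_nt(1200))
    for (mode in c("gene", "contig")) {
      cov <- if (mode == "gene") 0.95 else 0.80
      got <- dereplicate(items, 0.95, mode = mode)$representatives
      want <- derep_oracle(items, 0.95, cov, "dna")
      expect_identical(sort(got), sort(want), info = paste(rep, mode))
    }
  }
})
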