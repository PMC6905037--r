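# The generator's planted structure must be verifiable by direct string
# inspection, and the whole corpus byte-identical under a fixed seed.

test_that("protein families hit their identity targets", {
  set.seed(3)
  fam <- sim_protein_family(500, 10, 0.6)
  ids <- vapply(fam$members, site_identity, numeric(1), b = fam$ancestor)
  expect_true(all(ids >= 0.55 & ids <= 0.65))
  expect_true(mean(ids) >= 0.55 && mean(ids) <= 0.65)

  same <- sim_protein_family(100, 3, 1.0)
  expect_true(all(same$members == same$ancestor))

  empty <- sim_protein_family(100, 0, 0.8)
  expect_length(empty$members, 0)
  expect_true(nzchar(empty$family_id))

  expect_error(sim_protein_family(100, 3, 1.5), "identity")
  expect_error(sim_protein_family(100, 3, 0), "identity")
})

test_that("planted topologies are verifiable on the raw sequence", {
  corpus <- tiny_corpus()
  for (v in corpus$truth$virophages) {
    s <- corpus$contigs[[v$id]]
    expect_equal(nchar(s), v$length)
    if (v$topology == "circular") {
      ov <- v$overlap_len
      expect_identical(substr(s, 1, ov), substr(s, nchar(s) - ov + 1, nchar(s)))
    }
    if (v$topology == "itr") {
      k <- v$itr_len
      expect_identical(substr(s, 1, k),
                       revcomp(substr(s, nchar(s) - k + 1, nchar(s))))
    }
  }
})

test_that("planted genes and gene orders are encoded faithfully", {
  corpus <- tiny_corpus()
  v <- corpus$truth$virophages[[1]]
  s <- corpus$contigs[[v$id]]
  g <- v$genes
  for (i in seq_len(nrow(g))) {
    seg <- substr(s, g$start[i], g$end[i])
    if (g$strand[i] == "-") seg <- revcomp(seg)
    aa <- translate_dna(substr(seg, 1, nchar(seg) - 3))
    ann <- corpus$annotations
    prot <- ann$protein[ann$contig_id == v$id & ann$gene_id == g$gene_id[i]]
    expect_identical(aa, prot)
    expect_identical(substr(seg, 1, 3), "ATG")
  }
  # gene order in the truth record follows genomic coordinates
  expect_true(all(diff(g$start) > 0))
})

test_that("an ATPase-mCP-MCP lineage yields that synteny signature", {
  corpus <- tiny_corpus()
  lin3 <- Filter(function(v) v$lineage == 3 && v$tier == "HQ",
                 corpus$truth$virophages)
  v <- lin3[[1]]
  ann <- corpus$annotations[corpus$annotations$contig_id == v$id, ]
  sig <- synteny_signature(ann)
  expect_true(sig$atpase_mcp_mcp_in_order)
  expect_true(startsWith(sig$signature, "ATPase+|mCP+|MCP+"))
})

test_that("corpus generation is byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 99, n_virophages = 2, n_decoys = 2,
                    n_giant_viruses = 1, genome_len_range = c(10900, 12000),
                    decoy_len_range = c(5000, 6000))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  sim_metagenome(cfg, out_dir = d1)
  sim_metagenome(cfg, out_dir = d2)
  files <- list.files(d1)
  expect_identical(files, list.files(d2))
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), info = f)
  }
})

test_that("decoys carry no core-gene relatives and no planted seed", {
  corpus <- tiny_corpus()
  expect_length(corpus$truth$decoy_ids, 6)
  seeds <- vapply(corpus$truth$links, `[[`, "", "seed")
  for (id in corpus$truth$decoy_ids) {
    for (sd in seeds)
      expect_false(grepl(sd, corpus$contigs[[id]], fixed = TRUE))
  }
})

test_that("bookkeeping: virophage counts and empty corpus", {
  corpus <- tiny_corpus()
  expect_length(corpus$truth$virophages, 8)
  cfg0 <- sim_config(seed = 5, n_virophages = 0, n_decoys = 2,
                     n_giant_viruses = 0, decoy_len_range = c(5000, 6000))
  c0 <- sim_metagenome(cfg0)
  expect_length(c0$truth$virophages, 0)
  expect_length(c0$truth$hq_ids, 0)
  expect_length(c0$contigs, 2)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(topology_mix = c(circular = 0.5, itr = 0.2,
                                           linear = 0.2)), "sum to 1")
  expect_error(sim_config(genome_len_range = c(500, 900)), ">= 1000")
  expect_error(sim_config(mimivire_seed_len = 31), "24, 30")
  expect_error(sim_config(hq_fraction = 1.2), "fractions")
})

test_that("a cassette that cannot fit raises a generation error", {
  cfg <- sim_config(seed = 1, genome_len_range = c(1000, 1200))
  expect_error(sim_virophage(cfg, 1, id = "x"), "generation error")
})

test_that("planted MIMIVIRE links are recorded with exact copy counts", {
  corpus <- tiny_corpus()
  expect_length(corpus$truth$links, 3)
  for (l in corpus$truth$links) {
    gv <- corpus$giant_contigs[[l$gv_id]]
    vp <- corpus$contigs[[l$virophage_id]]
    expect_true(grepl(l$seed, gv, fixed = TRUE))
    expect_true(grepl(l$seed, vp, fixed = TRUE))
    expect_equal(nchar(l$seed), 27)
    expect_equal(nchar(l$unit), 18)
    expect_equal(l$copies, 3)
  }
})
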