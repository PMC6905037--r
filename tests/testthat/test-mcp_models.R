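# Model family clustering, PSSM construction, E-value calibration, search
# sensitivity/specificity, and the iterative refinement contract.

test_that("bidirectional 30/70 clustering forms the right families", {
  set.seed(10)
  p <- random_aa(200)
  fams <- cluster_for_models(c(a = p, b = p))
  expect_length(fams, 1)
  expect_identical(fams[[1]], c("a", "b"))

  prot <- character(0)
  truth <- character(0)
  for (f in 1:3) {
    fam <- sim_protein_family(250, 4, 0.6, prefix = paste0("T", f))
    prot <- c(prot, fam$members)
    truth <- c(truth, rep(f, 4))
  }
  names(truth) <- names(prot)
  fams <- cluster_for_models(prot)
  expect_length(fams, 3)
  for (f in fams) expect_length(unique(truth[f]), 1)
})

test_that("alignment fraction below 70% on one sequence blocks the edge", {
  set.seed(11)
  a <- random_aa(300)
  # b shares a high-identity region covering only 60% of a
  b <- paste0(mutate_at(substr(a, 1, 180), 0.9, AA_T), random_aa(60))
  fams <- cluster_for_models(c(a = a, b = b))
  expect_length(fams, 0) # both dropped as singletons
})

test_that("profiles from identical members reproduce the sequence", {
  set.seed(12)
  s <- random_aa(120)
  m <- build_profile(c(x = s, y = s), calibrate = FALSE)
  expect_equal(m$length, 120)
  expect_identical(m$consensus, s)
})

test_that("ancestor outscores all of its shuffles", {
  set.seed(13)
  fam <- sim_protein_family(300, 3, 0.9)
  m <- build_profile(fam$members, n_decoys = 500)
  anc_score <- profile_score(m, fam$ancestor)$score
  res <- strsplit(fam$ancestor, "")[[1]]
  shuf <- vapply(1:100, function(i) {
    profile_score(m, paste(sample(res), collapse = ""))$score
  }, numeric(1))
  expect_true(all(anc_score > shuf))
})

test_that("E-value calibration matches its definition on fresh decoys", {
  set.seed(14)
  fam <- sim_protein_family(200, 3, 0.85)
  m <- build_profile(fam$members, n_decoys = 1000)
  n <- 2000
  decoys <- setNames(vapply(1:n, function(i) random_aa(200), ""),
                     paste0("d", 1:n))
  hits1 <- profile_search(m, decoys, e_cut = 1)
  # expected count of decoys at E <= 1 is 1; allow generous Poisson slack
  expect_lte(nrow(hits1), 8)
  hits <- profile_search(m, decoys, e_cut = 1e-6)
  expect_equal(nrow(hits), 0)
})

test_that("search finds the ancestor and errors on uncalibrated models", {
  set.seed(15)
  fam <- sim_protein_family(300, 3, 0.9)
  m <- build_profile(fam$members, n_decoys = 500)
  db <- c(anc = fam$ancestor,
          setNames(vapply(1:50, function(i) random_aa(300), ""),
                   paste0("d", 1:50)))
  hits <- profile_search(m, db)
  expect_identical(hits$protein_id, "anc")
  expect_lt(hits$evalue, 1e-6)
  expect_identical(nrow(profile_search(m, character(0))), 0L)
  m2 <- build_profile(fam$members, calibrate = FALSE)
  expect_error(profile_search(m2, db), "uncalibrated")
})

test_that("model specificity: disjoint families do not cross-hit", {
  set.seed(16)
  f1 <- sim_protein_family(250, 3, 0.8)
  f2 <- sim_protein_family(250, 3, 0.8)
  m1 <- build_profile(f1$members, "m1", n_decoys = 500)
  m2 <- build_profile(f2$members, "m2", n_decoys = 500)
  expect_equal(nrow(profile_search(m1, c(o = f2$ancestor))), 0)
  expect_equal(nrow(profile_search(m2, c(o = f1$ancestor))), 0)
})

test_that("iteration recruits a two-hop homolog in round 2", {
  set.seed(17)
  A <- paste0("M", random_aa(592))
  seeds <- c(s1 = mutate_at(A, 0.92, AA_T), s2 = mutate_at(A, 0.90, AA_T),
             s3 = mutate_at(A, 0.90, AA_T))
  I <- mutate_at(A, 0.60, AA_T)
  H <- mutate_at(I, 0.65, AA_T) # ~40% to the seed family, two hops away
  expect_gt(site_identity(H, A), 0.33)
  expect_lt(site_identity(H, A), 0.47)
  db <- c(I = I, H = H,
          setNames(vapply(1:100, function(i) random_aa(sample(250:600, 1)), ""),
                   paste0("d", 1:100)))
  it <- iterate_models(list(MCP_seed = seeds), db, rounds = 2, n_decoys = 500)
  r1 <- unlist(it$membership_by_round[[1]])
  r2 <- unlist(it$membership_by_round[[2]])
  expect_false("H" %in% r1)
  expect_true("H" %in% r2)
  # monotone membership: round-1 members survive into round 2
  expect_true(all(r1 %in% r2))
  fin <- do.call(rbind, lapply(it$models, profile_search, proteins = db))
  expect_true("H" %in% fin$protein_id)
})

test_that("rounds = 1 is a single build pass over the seeds", {
  set.seed(18)
  fam <- sim_protein_family(240, 3, 0.9)
  db <- setNames(vapply(1:20, function(i) random_aa(240), ""), paste0("d", 1:20))
  it <- iterate_models(list(MCP_seed = fam$members), db, rounds = 1,
                       n_decoys = 200)
  expect_equal(it$rounds_run, 1)
  expect_setequal(unname(unlist(it$membership_by_round[[1]])),
                  names(fam$members))
})

test_that("seeds from disjoint families give family-specific models", {
  set.seed(19)
  f1 <- sim_protein_family(593, 3, 0.9, prefix = "A")
  f2 <- sim_protein_family(593, 3, 0.9, prefix = "B")
  db <- c(a1 = mutate_at(f1$ancestor, 0.8, AA_T),
          a2 = mutate_at(f2$ancestor, 0.8, AA_T))
  it <- iterate_models(list(s1 = f1$members, s2 = f2$members), db,
                       rounds = 2, n_decoys = 400)
  expect_gte(length(it$models), 2)
  hits <- lapply(it$models, profile_search, proteins = db)
  for (m in names(it$models)) {
    h <- hits[[m]]$protein_id
    mem <- it$models[[m]]$members
    if (any(grepl("^A", mem))) expect_false("a2" %in% h)
    if (any(grepl("^B", mem))) expect_false("a1" %in% h)
  }
})

test_that("MCP completeness bands follow the 593 +/- 40.1 rule", {
  expect_identical(mcp_completeness(c(593, 553, 297, 200)),
                   c("complete", "complete", "ge_half", "partial"))
  expect_identical(mcp_completeness(552), "ge_half")
  expect_identical(mcp_completeness(296), "partial")
  expect_identical(mcp_completeness(800), "complete")
})
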