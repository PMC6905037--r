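# Shared fixtures, built once per test run. Sizes are kept small: the tiny
# corpus exercises every planted feature (all three topologies, partial
# tiers, MIMIVIRE links) without full-scale genome lengths.

tiny_config <- function(seed = 11) {
  sim_config(seed = seed, n_virophages = 8, n_decoys = 6,
             n_giant_viruses = 3, genome_len_range = c(10900, 16000),
             decoy_len_range = c(5000, 8000))
}

.fixture_env <- new.env()

tiny_corpus <- function() {
  if (is.null(.fixture_env$corpus))
    .fixture_env$corpus <- sim_metagenome(tiny_config())
  .fixture_env$corpus
}

# adjusted Rand index between two labellings over the same names
ari_index <- function(truth, pred) {
  tab <- table(truth, pred)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  n <- choose(sum(tab), 2)
  exp_a <- b * cc / n
  (a - exp_a) / ((b + cc) / 2 - exp_a)
}

# independent per-site identity between equal-length sequences
site_identity <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  mean(x == y)
}

AA_T <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_aa <- function(n) paste(sample(AA_T, n, replace = TRUE), collapse = "")

random_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

# mutate an equal-length sequence at an exact number of sites
mutate_at <- function(seq, identity, alphabet) {
  x <- strsplit(seq, "")[[1]]
  k <- round((1 - identity) * length(x))
  pos <- sample(length(x), k)
  x[pos] <- vapply(x[pos], function(ch) sample(setdiff(alphabet, ch), 1), "")
  paste(x, collapse = "")
}

# independent greedy de-replication oracle over an exhaustive all-pairs scan
derep_oracle <- function(items, id_thresh, cov_thresh, type) {
  ord <- order(-nchar(items), names(items))
  ids <- names(items)[ord]
  reps <- character(0)
  for (id in ids) {
    placed <- FALSE
    for (r in reps) {
      pc <- lavidascope:::pair_identity_cov(items[[id]], items[[r]],
                                            type = type)
      shorter_len <- min(nchar(items[[id]]), nchar(items[[r]]))
      span <- if (nchar(items[[id]]) <= nchar(items[[r]])) pc$span_a else pc$span_b
      if (pc$identity >= id_thresh && span / shorter_len >= cov_thresh) {
        placed <- TRUE
        break
      }
    }
    if (!placed) reps <- c(reps, id)
  }
  reps
}

# brute-force maximal common-substring oracle (forward strand)
brute_shared <- function(a, b, kmin = 24) {
  hits <- list()
  for (i in seq_len(nchar(a) - kmin + 1)) {
    max_len <- 0
    for (L in seq(kmin, nchar(a) - i + 1)) {
      sub <- substr(a, i, i + L - 1)
      if (grepl(sub, b, fixed = TRUE)) max_len <- L else break
    }
    if (max_len >= kmin)
      hits[[length(hits) + 1]] <- c(start = i, len = max_len)
  }
  if (!length(hits)) return(data.frame(start = integer(0), len = integer(0)))
  h <- as.data.frame(do.call(rbind, hits))
  keep <- rep(TRUE, nrow(h))
  for (i in seq_len(nrow(h))) {
    for (j in seq_len(nrow(h))) {
      if (i != j && h$start[i] >= h$start[j] &&
          h$start[i] + h$len[i] <= h$start[j] + h$len[j]) keep[i] <- FALSE
    }
  }
  h[keep, , drop = FALSE]
}

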