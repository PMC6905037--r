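# Small shared helpers: alphabets, random sequences, k-mers, exact-match
# scanning, Gumbel calibration. Everything here is deterministic given the
# R RNG state.

#' Convert between 1-based inclusive and 0-based half-open coordinates
#'
#' The package stores coordinates 1-based inclusive throughout (the GFF3 and
#' R/Bioconductor convention). These converters are provided for
#' interoperability with 0-based half-open (BED-style) intervals; they are
#' exact inverses of each other.
#'
#' @param start,end interval bounds (vectors allowed).
#' @return a two-column matrix with converted `start`, `end`.
#' @export
to_zero_based <- function(start, end) {
  stopifnot(all(start >= 1), all(end >= start))
  cbind(start = start - 1L, end = end)
}

#' @rdname to_zero_based
#' @export
to_one_based <- function(start, end) {
  stopifnot(all(start >= 0), all(end > start))
  cbind(start = start + 1L, end = end)
}

# residue encoding -------------------------------------------------------

aa_encode <- function(x) {
  idx <- match(strsplit(x, "", fixed = TRUE)[[1]], AA20)
  idx[is.na(idx)] <- 0L
  as.integer(idx)
}

dna_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Reverse complement of DNA strings
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

random_dna <- function(n) {
  paste(sample(DNA4, n, replace = TRUE), collapse = "")
}

random_protein <- function(n, start_met = TRUE) {
  res <- sample(AA20, n, replace = TRUE)
  if (start_met) res[1] <- "M"
  paste(res, collapse = "")
}

#' Translate a DNA string with the standard genetic code
#'
#' Trailing partial codons are dropped; stop codons translate to `*`.
#' @param x a DNA string.
#' @return the amino-acid string.
#' @export
translate_dna <- function(x) {
  n <- nchar(x)
  if (n < 3) return("")
  starts <- seq.int(1L, n - 2L, by = 3L)
  codons <- substring(x, starts, starts + 2L)
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# k-mers and exact matching ----------------------------------------------

kmer_starts <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
}

shared_kmer_count <- function(a, b, k) {
  ka <- unique(kmer_starts(a, k))
  if (!length(ka)) return(0L)
  sum(ka %in% kmer_starts(b, k))
}

#' Maximal exact matches between two strings
#'
#' Anchors all shared k-mers, groups them by diagonal and merges runs of
#' consecutive anchors into maximal exact matches of length >= k. Matches
#' contained in a longer match on the same diagonal are never reported.
#'
#' @param a,b strings.
#' @param k anchor (and minimum match) length.
#' @return data.frame with `start_a`, `start_b` (1-based) and `length`,
#'   ordered by position; zero rows if nothing matches.
#' @keywords internal
mem_scan <- function(a, b, k) {
  empty <- data.frame(start_a = integer(0), start_b = integer(0),
                      length = integer(0))
  ka <- kmer_starts(a, k)
  kb <- kmer_starts(b, k)
  if (!length(ka) || !length(kb)) return(empty)
  idx_b <- split(seq_along(kb), kb)
  hit <- which(ka %in% names(idx_b))
  if (!length(hit)) return(empty)
  pos_a <- rep.int(hit, lengths(idx_b[ka[hit]]))
  pos_b <- unlist(idx_b[ka[hit]], use.names = FALSE)
  d <- pos_a - pos_b
  out <- lapply(split(seq_along(d), d), function(ii) {
    pa <- sort(pos_a[ii])
    runs <- c(0L, cumsum(diff(pa) != 1L))
    do.call(rbind, lapply(split(pa, runs), function(run) {
      c(start_a = run[1], start_b = run[1] - d[ii[1]],
        length = k + length(run) - 1L)
    }))
  })
  out <- as.data.frame(do.call(rbind, out))
  rownames(out) <- NULL
  out[order(out$start_a, out$start_b), , drop = FALSE]
}

#' Candidate sequence pairs sharing k-mers (inverted index)
#'
#' Builds a k-mer -> sequence postings index and returns the unordered pairs
#' of sequence ids sharing at least `min_shared` distinct k-mers. Avoids the
#' quadratic all-pairs scan for sparse similarity structures.
#'
#' @param seqs named character vector.
#' @param k word length.
#' @param min_shared minimum number of shared distinct k-mers.
#' @return data.frame `a`, `b` (ids, a < b).
#' @keywords internal
candidate_pairs <- function(seqs, k = 5, min_shared = 1) {
  ids <- names(seqs)
  sets <- lapply(seqs, function(s) unique(kmer_starts(s, k)))
  post <- split(rep(seq_along(ids), lengths(sets)),
                unlist(sets, use.names = FALSE))
  post <- post[lengths(post) >= 2]
  if (!length(post))
    return(data.frame(a = character(0), b = character(0)))
  pair_keys <- unlist(lapply(post, function(v) {
    v <- sort(unique(v))
    if (length(v) < 2) return(integer(0))
    cmb <- utils::combn(v, 2)
    cmb[1, ] * (length(ids) + 1) + cmb[2, ]
  }), use.names = FALSE)
  tab <- table(pair_keys)
  keep <- as.numeric(names(tab)[tab >= min_shared])
  if (!length(keep))
    return(data.frame(a = character(0), b = character(0)))
  i <- keep %/% (length(ids) + 1)
  j <- keep %% (length(ids) + 1)
  out <- data.frame(a = ids[i], b = ids[j], stringsAsFactors = FALSE)
  out[order(out$a, out$b), , drop = FALSE]
}

# Gumbel calibration -----------------------------------------------------

#' Method-of-moments fit of a Gumbel distribution
#' @param x numeric scores.
#' @return list with location `mu` and rate `lambda` (> 0).
#' @keywords internal
fit_gumbel <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s <= 0) s <- 1e-6
  lambda <- pi / (s * sqrt(6))
  mu <- mean(x) - 0.5772156649 / lambda
  list(mu = mu, lambda = lambda)
}

# misc -------------------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}
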