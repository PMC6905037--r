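# Virophage - giant-virus co-infection prediction via the MIMIVIRE
# criterion: an exact shared sequence of 24-30 nt in both genomes plus a
# repeated ~18-nt subset of it inside one giant-virus gene, with
# translated-motif verification of the shared region.

#' Exact shared seeds between a virophage and a giant-virus contig
#'
#' Reports all maximal exact common substrings of length at least
#' `len_range[1]` (k-mer anchoring at k = 24 with run extension), searching
#' both strands of the giant-virus contig. Matches longer than
#' `len_range[2]` are reported once as a single maximal match (they contain
#' a qualifying 24-30 nt seed).
#'
#' @param vp_seq virophage DNA string.
#' @param gv_seq giant-virus DNA string.
#' @param len_range minimum/maximum seed length (default 24-30).
#' @return data.frame `seed`, `length`, `vp_start`, `gv_start`, `gv_strand`
#'   (positions 1-based on the forward strand of each contig; for `-` strand
#'   matches `gv_start` is the forward-strand start of the matched region).
#' @export
shared_seeds <- function(vp_seq, gv_seq, len_range = c(24, 30)) {
  k <- len_range[1]
  vp <- toupper(unname(vp_seq[1]))
  gv <- toupper(unname(gv_seq[1]))
  res <- list()
  fwd <- mem_scan(vp, gv, k)
  if (nrow(fwd)) {
    fwd$gv_strand <- "+"
    fwd$gv_start <- fwd$start_b
    res[[1]] <- fwd
  }
  rc <- mem_scan(vp, revcomp(gv), k)
  if (nrow(rc)) {
    rc$gv_strand <- "-"
    rc$gv_start <- nchar(gv) - (rc$start_b + rc$length - 1) + 1
    res[[2]] <- rc
  }
  if (!length(res))
    return(data.frame(seed = character(0), length = integer(0),
                      vp_start = integer(0), gv_start = integer(0),
                      gv_strand = character(0), stringsAsFactors = FALSE))
  mm <- do.call(rbind, res)
  out <- data.frame(
    seed = substring(vp, mm$start_a, mm$start_a + mm$length - 1),
    length = mm$length, vp_start = mm$start_a, gv_start = mm$gv_start,
    gv_strand = mm$gv_strand, stringsAsFactors = FALSE)
  out <- out[order(-out$length, out$vp_start, out$gv_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

count_occurrences <- function(unit, s) {
  # distinct start positions, overlapping occurrences included
  pat <- paste0("(?=", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", unit), ")")
  hits <- gregexpr(pat, s, perl = TRUE)[[1]]
  if (hits[1] == -1) 0L else length(hits)
}

#' Find the repeated subset of a seed inside a giant-virus gene
#'
#' Scans every substring of the seed with length `unit_len` +/- `tol` and
#' counts its exact occurrences on the gene's coding strand (overlaps
#' allowed, occurrences deduplicated by start position). Returns the unit
#' with the maximum copy count (ties: length closest to `unit_len`, longer
#' first, then leftmost in the seed) if it reaches `min_copies`, else
#' `NULL`.
#'
#' @param seed shared-seed string.
#' @param gene_seq strand-resolved (coding) gene sequence.
#' @param unit_len nominal repeat-unit length (default 18 nt).
#' @param min_copies minimum copies to call a repeat (default 2: the seed's
#'   own occurrence plus at least one more).
#' @param tol unit-length tolerance (default 2, i.e. 16-20 nt).
#' @return list `unit`, `copies`, or `NULL`.
#' @export
repeated_subset <- function(seed, gene_seq, unit_len = 18, min_copies = 2,
                            tol = 2) {
  best <- NULL
  lens <- seq(unit_len - tol, unit_len + tol)
  lens <- lens[order(abs(lens - unit_len), -lens)]
  for (ul in lens) {
    if (ul > nchar(seed)) next
    starts <- seq_len(nchar(seed) - ul + 1)
    for (st in starts) {
      unit <- substr(seed, st, st + ul - 1)
      n <- count_occurrences(unit, gene_seq)
      if (is.null(best) || n > best$copies)
        best <- list(unit = unit, copies = n)
    }
  }
  if (is.null(best) || best$copies < min_copies) return(NULL)
  best
}

#' Translated-motif check of a shared seed
#'
#' Translates the seed region in all three frames on its strand in each
#' genome; `frame_agreement` is `TRUE` iff some frame pair yields an
#' identical peptide of at least 6 aa (stop codons included as `*`). Seeds
#' under 18 nt are skipped with a flag.
#'
#' @param seed the shared seed (identical in both genomes by construction).
#' @param vp_region,gv_region the seed region as read in each genome
#'   (default: the seed itself).
#' @return list `motifs_vp`, `motifs_gv` (3 frames each), `frame_agreement`,
#'   `skipped`.
#' @export
translated_motif_check <- function(seed, vp_region = seed, gv_region = seed) {
  if (nchar(seed) < 18)
    return(list(motifs_vp = character(0), motifs_gv = character(0),
                frame_agreement = NA, skipped = TRUE))
  frames <- function(s) vapply(1:3, function(f)
    translate_dna(substr(s, f, nchar(s))), character(1))
  mv <- frames(vp_region)
  mg <- frames(gv_region)
  agree <- any(outer(mv, mg, function(x, y)
    x == y & nchar(x) >= 6))
  list(motifs_vp = mv, motifs_gv = mg, frame_agreement = agree,
       skipped = FALSE)
}

gene_coding_seq <- function(contig_seq, gene) {
  s <- substr(contig_seq, gene$start, gene$end)
  if (gene$strand == "-") revcomp(s) else s
}

#' Predict virophage - giant-virus links across two contig sets
#'
#' For every pair, finds shared seeds, locates each seed's giant-virus
#' occurrence inside an annotated gene, requires a repeated ~18-nt subset of
#' the seed within that gene (on its coding strand), and verifies the
#' translated motif. Links are ranked by copy count, seed length, frame
#' agreement and same-sample co-occurrence; ordering is deterministic.
#'
#' @param virophages named DNA vector.
#' @param giants named DNA vector.
#' @param gv_annotations giant-virus gene annotations.
#' @param len_range seed length range.
#' @param unit_len,min_copies,tol repeat-unit parameters
#'   (see [repeated_subset()]).
#' @param samples optional data.frame `contig_id`, `sample` for
#'   co-occurrence flags.
#' @return data.frame, one row per link: ids, gene, seed, unit, copies,
#'   frame agreement, motifs, co-occurrence.
#' @export
link_all <- function(virophages, giants, gv_annotations,
                     len_range = c(24, 30), unit_len = 18, min_copies = 2,
                     tol = 2, samples = NULL) {
  empty <- data.frame(virophage_id = character(0), gv_id = character(0),
                      gene_id = character(0), seed = character(0),
                      seed_len = integer(0), unit = character(0),
                      copies = integer(0), frame_agreement = logical(0),
                      co_occurrence = logical(0), stringsAsFactors = FALSE)
  if (!length(virophages) || !length(giants)) return(empty)
  sample_of <- if (!is.null(samples))
    stats::setNames(samples$sample, samples$contig_id) else NULL
  # pre-screen pairs: a shared seed implies a shared k-mer on some strand
  k <- len_range[1]
  vsets <- lapply(virophages, function(s) unique(kmer_starts(toupper(s), k)))
  gsets <- lapply(giants, function(s) {
    su <- toupper(s)
    unique(c(kmer_starts(su, k), kmer_starts(revcomp(su), k)))
  })
  rows <- list()
  for (v in sort(names(virophages))) {
    for (g in sort(names(giants))) {
      if (!any(vsets[[v]] %in% gsets[[g]])) next
      seeds <- shared_seeds(virophages[[v]], giants[[g]], len_range)
      if (!nrow(seeds)) next
      genes <- gv_annotations[gv_annotations$contig_id == g, , drop = FALSE]
      for (i in seq_len(nrow(seeds))) {
        sd <- seeds[i, ]
        hit <- genes[genes$start <= sd$gv_start &
                       genes$end >= sd$gv_start + sd$length - 1, ,
                     drop = FALSE]
        if (!nrow(hit)) next
        gene <- hit[1, ]
        gseq <- gene_coding_seq(giants[[g]], gene)
        seed_cd <- if (sd$gv_strand == gene$strand) sd$seed else revcomp(sd$seed)
        rep <- repeated_subset(seed_cd, gseq, unit_len = unit_len,
                               min_copies = min_copies, tol = tol)
        if (is.null(rep)) next
        vp_region <- substr(virophages[[v]], sd$vp_start,
                            sd$vp_start + sd$length - 1)
        gv_region <- substr(giants[[g]], sd$gv_start,
                            sd$gv_start + sd$length - 1)
        if (sd$gv_strand == "-") gv_region <- revcomp(gv_region)
        tm <- translated_motif_check(sd$seed, vp_region, gv_region)
        co <- !is.null(sample_of) && !is.na(sample_of[v]) &&
          !is.na(sample_of[g]) && sample_of[v] == sample_of[g]
        rows[[length(rows) + 1]] <- data.frame(
          virophage_id = v, gv_id = g, gene_id = gene$gene_id,
          seed = sd$seed, seed_len = sd$length, unit = rep$unit,
          copies = rep$copies,
          frame_agreement = isTRUE(tm$frame_agreement),
          co_occurrence = co, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  # one best link per pair (max copies, then longest seed)
  out <- out[order(out$virophage_id, out$gv_id, -out$copies, -out$seed_len), ,
             drop = FALSE]
  out <- out[!duplicated(out[, c("virophage_id", "gv_id")]), , drop = FALSE]
  out <- out[order(-out$copies, -out$seed_len, !out$frame_agreement,
                   !out$co_occurrence, out$virophage_id, out$gv_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
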