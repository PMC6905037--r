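# FASTA / GFF3 / TSV readers and writers plus a minimal ORF caller standing
# in for Prodigal on synthetic data. Sequences travel through the package as
# named character vectors (names = record ids, optional "description"
# attribute); gene annotations as plain data.frames.

DNA_CHARS <- c("A", "C", "G", "T", "N")
PROT_CHARS <- c(AA20, "X", "*")

validate_records <- function(ids, seqs, alphabet = c("auto", "dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (any(!nzchar(ids)) || anyNA(ids))
    stop("FASTA format error: empty sequence id", call. = FALSE)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("FASTA format error: duplicate sequence id(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  empty <- ids[!nzchar(seqs)]
  if (length(empty))
    stop("FASTA format error: empty sequence for record(s): ",
         paste(empty, collapse = ", "), call. = FALSE)
  chars <- lapply(strsplit(toupper(seqs), "", fixed = TRUE), unique)
  if (alphabet == "auto") {
    alphabet <- if (all(unlist(chars) %in% DNA_CHARS)) "dna" else "protein"
  }
  legal <- if (alphabet == "dna") DNA_CHARS else PROT_CHARS
  bad <- vapply(chars, function(ch) any(!ch %in% legal), logical(1))
  if (any(bad))
    stop("FASTA format error: illegal ", alphabet, " character(s) in record(s): ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  alphabet
}

#' Read a FASTA file into a named character vector
#'
#' Record ids are the first whitespace-delimited token of each header; the
#' remainder is kept in the `"description"` attribute. Duplicate ids, empty
#' sequences and characters outside the DNA (`ACGTN`) or protein
#' (20 aa + `X` + `*`) alphabet are format errors naming the offending record.
#'
#' @param path file path.
#' @param alphabet `"auto"` (default), `"dna"` or `"protein"`.
#' @return named character vector of sequences with attributes
#'   `description` and `alphabet`.
#' @export
read_fasta <- function(path, alphabet = c("auto", "dna", "protein")) {
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(set))
  alpha <- validate_records(ids, seqs, match.arg(alphabet))
  names(seqs) <- ids
  attr(seqs, "description") <- stats::setNames(desc, ids)
  attr(seqs, "alphabet") <- alpha
  seqs
}

#' Write sequences to FASTA (80-column wrap)
#'
#' @param records named character vector of sequences; an optional
#'   `description` attribute is appended to headers.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  validate_records(names(records), unname(records))
  desc <- attr(records, "description")
  headers <- names(records)
  if (!is.null(desc)) {
    d <- desc[headers]
    headers <- ifelse(!is.na(d) & nzchar(d), paste(headers, d), headers)
  }
  set <- Biostrings::BStringSet(unname(records))
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

# GFF3 -------------------------------------------------------------------

#' Read gene annotations from a GFF3 file
#'
#' Expects 9-column GFF3 with 1-based inclusive coordinates, strand `+`/`-`
#' and `ID=` / `product=` attributes. A start below 1, `end < start` or an
#' unknown strand is a format error.
#'
#' @param path file path.
#' @return data.frame with columns `contig_id`, `gene_id`, `start`, `end`,
#'   `strand`, `product` (and `protein = NA`).
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines))
    return(gene_annotation_frame())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 9))
    stop("GFF3 format error: expected 9 tab-separated columns", call. = FALSE)
  m <- do.call(rbind, parts)
  start <- suppressWarnings(as.integer(m[, 4]))
  end <- suppressWarnings(as.integer(m[, 5]))
  if (anyNA(start) || anyNA(end) || any(start < 1))
    stop("GFF3 format error: coordinates must be integers >= 1 (1-based)",
         call. = FALSE)
  if (any(end < start))
    stop("GFF3 format error: end < start", call. = FALSE)
  strand <- m[, 7]
  if (any(!strand %in% c("+", "-")))
    stop("GFF3 format error: strand must be '+' or '-'", call. = FALSE)
  attr_field <- function(attrs, key) {
    hit <- regmatches(attrs, regexpr(paste0("(^|;)", key, "=[^;]*"), attrs))
    out <- rep(NA_character_, length(attrs))
    found <- vapply(regexpr(paste0("(^|;)", key, "="), attrs), function(x) x > 0,
                    logical(1))
    out[found] <- sub(paste0("^;?", key, "="), "", hit)
    out
  }
  ann <- data.frame(
    contig_id = m[, 1], gene_id = attr_field(m[, 9], "ID"),
    start = start, end = end, strand = strand,
    product = attr_field(m[, 9], "product"),
    protein = NA_character_, stringsAsFactors = FALSE
  )
  ann$product[is.na(ann$product)] <- "other"
  ann
}

gene_annotation_frame <- function() {
  data.frame(contig_id = character(0), gene_id = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             product = character(0), protein = character(0),
             stringsAsFactors = FALSE)
}

#' Write gene annotations as GFF3
#'
#' Emits a `##gff-version 3` header and one `gene` feature per row with
#' `ID=` and `product=` attributes; rows are written in deterministic order
#' (contig, start, end, strand).
#'
#' @param annotations data.frame as returned by [read_gff3()] / [call_orfs()].
#' @param path output path.
#' @param source value of the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotations, path, source = "lavidascope") {
  a <- annotations
  if (nrow(a)) {
    if (any(a$start < 1) || any(a$end < a$start))
      stop("GFF3 format error: invalid coordinates", call. = FALSE)
    if (any(!a$strand %in% c("+", "-")))
      stop("GFF3 format error: strand must be '+' or '-'", call. = FALSE)
    a <- a[order(a$contig_id, a$start, a$end, a$strand), , drop = FALSE]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(a)) {
    writeLines(paste(a$contig_id, source, "gene", a$start, a$end, ".",
                     a$strand, "0",
                     paste0("ID=", a$gene_id, ";product=", a$product),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read / write a two-column habitat table (contig_id TAB habitat)
#' @param path file path.
#' @return data.frame with `contig_id`, `habitat`.
#' @export
read_habitats <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, colClasses = "character")
}

#' @rdname read_habitats
#' @param habitats data.frame with columns `contig_id`, `habitat`.
#' @export
write_habitats <- function(habitats, path) {
  h <- habitats[order(habitats$contig_id), , drop = FALSE]
  utils::write.table(h, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ORF calling ------------------------------------------------------------

STOP_CODONS <- c("TAA", "TAG", "TGA")

orf_scan_strand <- function(s, min_len) {
  n <- nchar(s)
  out <- list()
  for (frame in 0:2) {
    starts <- seq.int(frame + 1L, n - 2L, by = 3L)
    if (length(starts) < min_len + 1L) next
    codons <- substring(s, starts, starts + 2L)
    is_stop <- codons %in% STOP_CODONS
    is_atg <- codons == "ATG"
    seg <- cumsum(c(TRUE, utils::head(is_stop, -1L)))
    stop_idx <- which(is_stop)
    if (!length(stop_idx)) next
    atg_idx <- which(is_atg)
    if (!length(atg_idx)) next
    first_atg <- tapply(atg_idx, seg[atg_idx], min)
    seg_of_stop <- seg[stop_idx]
    hit <- match(as.character(seg_of_stop), names(first_atg))
    ok <- !is.na(hit)
    for (k in which(ok)) {
      a <- first_atg[[hit[k]]]
      st <- stop_idx[k]
      aa_len <- st - a # codons before the stop
      if (aa_len < min_len) next
      prot <- paste(Biostrings::GENETIC_CODE[codons[a:(st - 1L)]],
                    collapse = "")
      out[[length(out) + 1L]] <- list(start = starts[a], end = starts[st] + 2L,
                                      protein = prot)
    }
  }
  out
}

#' Call open reading frames on a DNA contig
#'
#' Reports all maximal `ATG -> stop` ORFs of at least `min_len` amino acids on
#' both strands (standard genetic code, ATG starts only, stop required,
#' non-nested within a frame), ordered by start coordinate then strand.
#' A deliberately simple stand-in for a gene caller on synthetic contigs.
#'
#' @param contig a single named DNA string (or unnamed with `contig_id`).
#' @param min_len minimum protein length in amino acids (default 100).
#' @param contig_id contig id; defaults to `names(contig)`.
#' @return annotation data.frame (columns as in [read_gff3()], plus the
#'   translated `protein`), `product = "other"`.
#' @export
call_orfs <- function(contig, min_len = 100, contig_id = NULL) {
  contig_id <- contig_id %||% names(contig) %||% "contig"
  s <- toupper(unname(contig[1]))
  n <- nchar(s)
  rows <- list()
  for (o in orf_scan_strand(s, min_len)) {
    rows[[length(rows) + 1L]] <- data.frame(
      contig_id = contig_id, gene_id = NA_character_,
      start = o$start, end = o$end, strand = "+",
      product = "other", protein = o$protein, stringsAsFactors = FALSE)
  }
  for (o in orf_scan_strand(revcomp(s), min_len)) {
    rows[[length(rows) + 1L]] <- data.frame(
      contig_id = contig_id, gene_id = NA_character_,
      start = n - o$end + 1L, end = n - o$start + 1L, strand = "-",
      product = "other", protein = o$protein, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(gene_annotation_frame())
  ann <- do.call(rbind, rows)
  ann <- ann[order(ann$start, ann$strand, ann$end), , drop = FALSE]
  ann$gene_id <- sprintf("%s_orf%03d", contig_id, seq_len(nrow(ann)))
  rownames(ann) <- NULL
  ann
}

#' Call ORFs across a set of contigs
#' @param contigs named character vector of DNA sequences.
#' @inheritParams call_orfs
#' @return combined annotation data.frame.
#' @export
call_orfs_all <- function(contigs, min_len = 100) {
  out <- lapply(names(contigs), function(id)
    call_orfs(contigs[id], min_len = min_len, contig_id = id))
  do.call(rbind, out)
}

#' Extract protein sequences from annotations as `<contig>|<gene>` records
#' @param annotations annotation data.frame with a `protein` column.
#' @return named character vector of proteins.
#' @export
annotation_proteins <- function(annotations) {
  a <- annotations[!is.na(annotations$protein), , drop = FALSE]
  if (!nrow(a)) return(stats::setNames(character(0), character(0)))
  stats::setNames(a$protein, paste0(a$contig_id, "|", a$gene_id))
}
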