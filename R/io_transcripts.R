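# GFF3 / sidecar I/O for transcript models.

#' Load transcript models from GFF3
#'
#' Reads a GFF3 file with the usual gene -> mRNA -> exon/CDS hierarchy and
#' returns one validated [transcript_model()] per mRNA. Protein domains may
#' be supplied as a sidecar table (see [read_domain_table()]) and coding
#' sequences as a FASTA file whose record names are transcript IDs.
#'
#' @param path GFF3 file path.
#' @param format Only `"gff3"` is supported.
#' @param domains Optional domain data.frame (columns `transcript_id`,
#'   `domain_name`, `aa_start`, `aa_end`) or path to such a TSV.
#' @param cds_fasta Optional FASTA path with CDS sequences per transcript.
#' @return Named list of `transcript_model` objects (names = transcript IDs).
#' @export
load_transcripts <- function(path, format = "gff3", domains = NULL,
                             cds_fasta = NULL) {
  format <- match.arg(format, "gff3")
  if (!file.exists(path)) stop("no such file: ", path)
  gff <- as.data.frame(rtracklayer::readGFF(path))
  gff$Parent <- vapply(gff$Parent, function(p)
    if (length(p)) as.character(p)[1] else NA_character_, character(1))

  if (is.character(domains) && length(domains) == 1L)
    domains <- read_domain_table(domains)
  seqs <- NULL
  if (!is.null(cds_fasta)) {
    ss <- Biostrings::readDNAStringSet(cds_fasta)
    seqs <- stats::setNames(as.character(ss), names(ss))
  }

  genes <- gff[gff$type == "gene", , drop = FALSE]
  gene_name <- stats::setNames(
    ifelse(is.na(genes$Name), genes$ID, as.character(genes$Name)),
    genes$ID)
  mrnas <- gff[gff$type == "mRNA", , drop = FALSE]
  if (nrow(mrnas) == 0L) stop("no mRNA features in ", path)

  out <- list()
  for (m in seq_len(nrow(mrnas))) {
    tx_id <- as.character(mrnas$ID[m])
    gsym <- if (!is.na(mrnas$Parent[m]) && mrnas$Parent[m] %in% names(gene_name))
      unname(gene_name[mrnas$Parent[m]]) else
      if (!is.na(mrnas$Name[m])) as.character(mrnas$Name[m]) else tx_id
    strand <- as.character(mrnas$strand[m])
    chrom <- as.character(mrnas$seqid[m])
    ex <- gff[gff$type == "exon" & gff$Parent == tx_id, , drop = FALSE]
    cds <- gff[gff$type == "CDS" & gff$Parent == tx_id, , drop = FALSE]
    if (nrow(ex) == 0L || nrow(cds) == 0L)
      stop("transcript ", tx_id, ": missing exon or CDS rows")
    ex <- ex[order(ex$start, decreasing = (strand == "-")), ]
    cds_lo <- min(cds$start); cds_hi <- max(cds$end)
    tx <- transcript_model(
      gene_symbol = gsym, transcript_id = tx_id, chrom = chrom,
      strand = strand,
      exons = data.frame(start = ex$start, end = ex$end),
      cds_start_genomic = if (strand == "+") cds_lo else cds_hi,
      cds_end_genomic = if (strand == "+") cds_hi else cds_lo,
      domains = if (!is.null(domains)) {
        d <- domains[domains$transcript_id == tx_id, , drop = FALSE]
        if (nrow(d)) data.frame(name = d$domain_name, aa_start = d$aa_start,
                                aa_end = d$aa_end) else NULL
      },
      cds_sequence = if (!is.null(seqs) && tx_id %in% names(seqs))
        seqs[[tx_id]] else NULL
    )
    out[[tx_id]] <- tx
  }
  out
}

#' Write transcript models as GFF3
#'
#' Emits a gene -> mRNA -> exon/CDS hierarchy round-trippable by
#' [load_transcripts()].
#'
#' @param transcripts List of [transcript_model()] objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_transcripts_gff3 <- function(transcripts, path) {
  lines <- "##gff-version 3"
  for (tx in transcripts) {
    span <- c(min(tx$exons$start), max(tx$exons$end))
    gid <- paste0("gene:", tx$gene_symbol)
    lines <- c(lines,
      paste(tx$chrom, "ptvburden", "gene", span[1], span[2], ".",
            tx$strand, ".", sprintf("ID=%s;Name=%s", gid, tx$gene_symbol),
            sep = "\t"),
      paste(tx$chrom, "ptvburden", "mRNA", span[1], span[2], ".",
            tx$strand, ".",
            sprintf("ID=%s;Parent=%s;Name=%s", tx$transcript_id, gid,
                    tx$gene_symbol),
            sep = "\t"))
    for (i in seq_len(nrow(tx$exons))) {
      lines <- c(lines,
        paste(tx$chrom, "ptvburden", "exon", tx$exons$start[i],
              tx$exons$end[i], ".", tx$strand, ".",
              sprintf("ID=%s.exon%d;Parent=%s", tx$transcript_id, i,
                      tx$transcript_id),
              sep = "\t"))
    }
    ci <- which(tx$coding_len > 0L)
    for (i in ci) {
      phase <- (3L - (tx$cds_offset[i] %% 3L)) %% 3L
      lines <- c(lines,
        paste(tx$chrom, "ptvburden", "CDS", tx$coding_start[i],
              tx$coding_end[i], ".", tx$strand, phase,
              sprintf("ID=%s.cds%d;Parent=%s", tx$transcript_id, i,
                      tx$transcript_id),
              sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a protein-domain sidecar table
#'
#' TSV with columns `transcript_id`, `domain_name`, `aa_start`, `aa_end`.
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_domain_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "domain_name", "aa_start", "aa_end")
  if (!all(need %in% names(d)))
    stop("domain table must have columns: ", paste(need, collapse = ", "))
  d
}

#' Write a protein-domain sidecar table
#'
#' @param transcripts List of [transcript_model()] objects.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_domain_table <- function(transcripts, path) {
  rows <- do.call(rbind, lapply(transcripts, function(tx) {
    if (nrow(tx$domains) == 0L) return(NULL)
    data.frame(transcript_id = tx$transcript_id,
               domain_name = tx$domains$name,
               aa_start = tx$domains$aa_start,
               aa_end = tx$domains$aa_end)
  }))
  if (is.null(rows))
    rows <- data.frame(transcript_id = character(), domain_name = character(),
                       aa_start = integer(), aa_end = integer())
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write CDS sequences as FASTA
#'
#' @param transcripts List of [transcript_model()] objects carrying
#'   `cds_sequence`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(transcripts, path) {
  seqs <- Filter(Negate(is.null), lapply(transcripts, `[[`, "cds_sequence"))
  ids <- vapply(Filter(function(tx) !is.null(tx$cds_sequence), transcripts),
                `[[`, character(1), "transcript_id")
  ss <- Biostrings::DNAStringSet(unlist(seqs))
  names(ss) <- ids
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
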