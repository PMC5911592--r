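# Transcript models and CDS coordinate arithmetic.
#
# All genomic coordinates are 1-based, closed (VCF/GFF3 convention); internal
# coding coordinates are 1-based from the A of the ATG (HGVS c. numbering,
# stop codon included, so protein length = cds_length/3 - 1).

#' Construct a transcript model
#'
#' A transcript model holds the exon/CDS geometry of one canonical transcript
#' of a panel gene, plus optional protein-domain intervals and the coding
#' sequence. It is the coordinate backbone for consequence calling and the
#' NMD-escape rule.
#'
#' @param gene_symbol Gene symbol, e.g. `"CHEK2"`.
#' @param transcript_id Transcript identifier, e.g. `"NM_007194"`.
#' @param chrom Chromosome / contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with columns `start`, `end` (genomic, 1-based
#'   closed), one row per exon, ordered 5' to 3' in transcript orientation
#'   (descending genomic coordinates on the minus strand).
#' @param cds_start_genomic Genomic position of the first coding base
#'   (the A of ATG).
#' @param cds_end_genomic Genomic position of the last coding base (the last
#'   base of the stop codon).
#' @param domains Optional data.frame with columns `name`, `aa_start`,
#'   `aa_end` (1-based protein positions, closed).
#' @param cds_sequence Optional coding sequence (character, length equal to
#'   the CDS length, transcript strand), used for codon-level consequence
#'   calls.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(gene_symbol, transcript_id, chrom, strand,
                             exons, cds_start_genomic, cds_end_genomic,
                             domains = NULL, cds_sequence = NULL) {
  stopifnot(is.character(gene_symbol), length(gene_symbol) == 1L,
            is.character(transcript_id), length(transcript_id) == 1L)
  if (!strand %in% c("+", "-"))
    stop("transcript ", transcript_id, ": strand must be '+' or '-'")
  exons <- as.data.frame(exons)[, c("start", "end")]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  cds_start_genomic <- as.integer(cds_start_genomic)
  cds_end_genomic <- as.integer(cds_end_genomic)
  if (any(exons$start > exons$end))
    stop("transcript ", transcript_id, ": exon with start > end")
  # transcript orientation: ascending genomic on +, descending on -
  gord <- order(exons$start)
  if (strand == "+") {
    if (!identical(gord, seq_len(nrow(exons))))
      stop("transcript ", transcript_id,
           ": exons not ordered 5'->3' for + strand")
  } else {
    if (!identical(gord, rev(seq_len(nrow(exons)))))
      stop("transcript ", transcript_id,
           ": exons not ordered 5'->3' for - strand")
  }
  sorted <- exons[gord, , drop = FALSE]
  if (nrow(sorted) > 1L &&
      any(sorted$start[-1L] <= sorted$end[-nrow(sorted)]))
    stop("transcript ", transcript_id, ": overlapping exons")

  lo <- min(cds_start_genomic, cds_end_genomic)
  hi <- max(cds_start_genomic, cds_end_genomic)
  in_exon <- function(g) any(g >= exons$start & g <= exons$end)
  if (!in_exon(cds_start_genomic) || !in_exon(cds_end_genomic))
    stop("transcript ", transcript_id, ": CDS boundary outside exons")

  # per-exon coding sub-intervals (genomic), cumulative CDS offsets in
  # transcript orientation
  cstart <- pmax(exons$start, lo)
  cend   <- pmin(exons$end, hi)
  clen   <- pmax(cend - cstart + 1L, 0L)
  clen[cstart > cend] <- 0L
  offset <- cumsum(c(0L, clen))[seq_len(nrow(exons))]
  cds_length <- sum(clen)
  if (cds_length %% 3L != 0L)
    stop("transcript ", transcript_id, ": CDS length ", cds_length,
         " not a multiple of 3")
  protein_length <- cds_length %/% 3L - 1L

  if (!is.null(domains)) {
    domains <- as.data.frame(domains)[, c("name", "aa_start", "aa_end")]
    bad <- domains$aa_start < 1L | domains$aa_end > protein_length |
      domains$aa_start > domains$aa_end
    if (any(bad))
      stop("transcript ", transcript_id, ": domain outside [1, ",
           protein_length, "]: ", paste(domains$name[bad], collapse = ", "))
  } else {
    domains <- data.frame(name = character(), aa_start = integer(),
                          aa_end = integer())
  }
  if (!is.null(cds_sequence)) {
    cds_sequence <- toupper(cds_sequence)
    if (nchar(cds_sequence) != cds_length)
      stop("transcript ", transcript_id, ": cds_sequence length ",
           nchar(cds_sequence), " != CDS length ", cds_length)
  }

  structure(list(
    gene_symbol = gene_symbol, transcript_id = transcript_id,
    chrom = chrom, strand = strand, exons = exons,
    cds_start_genomic = cds_start_genomic,
    cds_end_genomic = cds_end_genomic,
    coding_start = cstart, coding_end = cend, coding_len = clen,
    cds_offset = offset, cds_length = cds_length,
    protein_length = protein_length,
    domains = domains, cds_sequence = cds_sequence
  ), class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model %s (%s) %s:%s  %d exon(s), CDS %d nt, %d aa, %d domain(s)>\n",
              x$transcript_id, x$gene_symbol, x$chrom, x$strand,
              nrow(x$exons), x$cds_length, x$protein_length,
              nrow(x$domains)))
  invisible(x)
}

#' Map a genomic position onto transcript coding coordinates
#'
#' Classifies a genomic position as coding, intronic, UTR-exonic or outside
#' the transcript, and reports the 1-based coding position (`cds_pos`) or the
#' signed HGVS-style intron offset (`+1` = first intronic base after an exon
#' in transcript orientation, `-1` = last intronic base before an exon).
#'
#' @param tx A [transcript_model()].
#' @param gpos Genomic position (scalar).
#' @return A list with elements `kind` (one of `"coding"`, `"intronic"`,
#'   `"utr"`, `"outside"`), `cds_pos`, `exon_index`, `intron_offset`,
#'   `intron_index` (transcript-order index of the upstream exon when
#'   intronic); unused slots are `NA`.
#' @export
genomic_to_cds <- function(tx, gpos) {
  gpos <- as.integer(gpos)
  out <- list(kind = "outside", cds_pos = NA_integer_,
              exon_index = NA_integer_, intron_offset = NA_integer_,
              intron_index = NA_integer_)
  ex <- tx$exons
  if (gpos < min(ex$start) || gpos > max(ex$end)) return(out)
  hit <- which(gpos >= ex$start & gpos <= ex$end)
  if (length(hit) == 1L) {
    i <- hit
    if (tx$coding_len[i] > 0L &&
        gpos >= tx$coding_start[i] && gpos <= tx$coding_end[i]) {
      k <- if (tx$strand == "+") gpos - tx$coding_start[i] + 1L
           else tx$coding_end[i] - gpos + 1L
      out$kind <- "coding"
      out$cds_pos <- tx$cds_offset[i] + k
      out$exon_index <- i
    } else {
      out$kind <- "utr"
      out$exon_index <- i
    }
    return(out)
  }
  # intronic: locate the intron between transcript-order exons i and i+1
  n <- nrow(ex)
  for (i in seq_len(n - 1L)) {
    if (tx$strand == "+") {
      donor <- ex$end[i]; acceptor <- ex$start[i + 1L]
      if (gpos > donor && gpos < acceptor) {
        d_off <- gpos - donor          # +k from donor
        a_off <- gpos - acceptor       # negative
      } else next
    } else {
      donor <- ex$start[i]; acceptor <- ex$end[i + 1L]
      if (gpos < donor && gpos > acceptor) {
        d_off <- donor - gpos
        a_off <- acceptor - gpos       # negative
      } else next
    }
    out$kind <- "intronic"
    out$intron_index <- i
    # report the nearer boundary; ties resolve to the donor side
    out$intron_offset <- if (d_off <= abs(a_off)) d_off else a_off
    return(out)
  }
  out
}

#' Map a coding position back to its genomic position
#'
#' Inverse of [genomic_to_cds()] for coding positions.
#'
#' @param tx A [transcript_model()].
#' @param cds_pos Coding position in `[1, cds_length]`.
#' @return Genomic position (integer).
#' @export
cds_to_genomic <- function(tx, cds_pos) {
  if (cds_pos < 1L || cds_pos > tx$cds_length)
    stop("cds_pos ", cds_pos, " outside [1, ", tx$cds_length, "]")
  i <- max(which(tx$cds_offset < cds_pos & tx$coding_len > 0L))
  k <- cds_pos - tx$cds_offset[i]
  if (tx$strand == "+") tx$coding_start[i] + k - 1L
  else tx$coding_end[i] - k + 1L
}

#' NMD-escape zone of a transcript
#'
#' Returns the coding-coordinate interval in which a premature termination
#' codon is expected to escape nonsense-mediated decay: all coding positions
#' of the last CDS-bearing exon plus the final 55 coding nucleotides of the
#' penultimate CDS-bearing exon (fewer if its coding portion is shorter).
#' For a transcript whose CDS lies in a single exon the whole CDS escapes
#' (there is no exon-exon junction downstream of any stop).
#'
#' @param tx A [transcript_model()].
#' @return Integer vector `c(start, end)` in coding coordinates (closed).
#' @export
nmd_escape_zone <- function(tx) {
  ce <- which(tx$coding_len > 0L)
  L <- tx$cds_length
  if (length(ce) == 1L) return(c(1L, L))
  last <- ce[length(ce)]
  pen  <- ce[length(ce) - 1L]
  a_last <- tx$cds_offset[last] + 1L      # first coding base of last exon
  a_pen  <- tx$cds_offset[pen] + 1L
  c(max(a_pen, a_last - 55L), L)
}

# first coding base of the last CDS-bearing exon (anchor used to evaluate
# final-intron splice variants against the escape zone)
first_cds_of_last_coding_exon <- function(tx) {
  ce <- which(tx$coding_len > 0L)
  tx$cds_offset[ce[length(ce)]] + 1L
}

# transcript-order exon index of the last CDS-bearing exon
last_coding_exon_index <- function(tx) {
  ce <- which(tx$coding_len > 0L)
  ce[length(ce)]
}

#' Protein-domain intervals in coding coordinates
#'
#' Converts the amino-acid domain annotations of a transcript to coding
#' nucleotide intervals (aa i spans cds `[3i-2, 3i]`).
#'
#' @param tx A [transcript_model()].
#' @return data.frame with columns `name`, `cds_start`, `cds_end`.
#' @export
domain_cds_intervals <- function(tx) {
  d <- tx$domains
  data.frame(name = d$name,
             cds_start = 3L * d$aa_start - 2L,
             cds_end = 3L * d$aa_end,
             stringsAsFactors = FALSE)
}
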