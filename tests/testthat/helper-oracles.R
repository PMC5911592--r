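# Independent oracles and shared toy fixtures for the test suite. These
# deliberately re-derive results from first principles (enumeration, literal
# rule text, brute-force scans) rather than reusing package internals.

# Two-sided Fisher p by full hypergeometric enumeration (point-probability
# method): sum the probabilities of all tables with the observed margins
# whose point probability does not exceed the observed one.
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(xs, r1, r2, c1)
  obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# OR and Wald CI from an explicit univariate logistic regression fit on the
# expanded 2x2 data.
oracle_or_glm <- function(a, a_n, b, b_n) {
  y <- c(rep(1, a), rep(0, a_n - a), rep(1, b), rep(0, b_n - b))
  g <- c(rep(1, a_n), rep(0, b_n))
  fit <- stats::glm(y ~ g, family = stats::binomial())
  co <- summary(fit)$coefficients
  est <- co["g", "Estimate"]; se <- co["g", "Std. Error"]
  z <- stats::qnorm(0.975)
  list(odds_ratio = exp(est), ci_low = exp(est - z * se),
       ci_high = exp(est + z * se))
}

# Literal re-statement of the classification rule sentences, operating on
# generator truth (category, evaluation anchor), not on VCF records.
oracle_rule_class <- function(maximum_maf, category, anchor_eval, zone,
                              domain_cds) {
  if (maximum_maf >= 0.01) return(1L)
  if (category %in% c("nonsense", "frameshift", "essential_splice")) {
    if (anchor_eval < zone[1]) return(5L)
    if (nrow(domain_cds) && any(domain_cds$cds_end >= anchor_eval))
      return(5L)
    return(3L)
  }
  3L
}

# transcript-order index of the last CDS-bearing exon, re-derived
last_coding_exon_index_oracle <- function(tx) max(which(tx$coding_len > 0))

# Brute-force spliced-CDS walk: genomic positions of coding bases in
# transcript order, derived directly from exon intervals and the CDS span.
oracle_coding_positions <- function(tx) {
  lo <- min(tx$cds_start_genomic, tx$cds_end_genomic)
  hi <- max(tx$cds_start_genomic, tx$cds_end_genomic)
  out <- integer(0)
  for (i in seq_len(nrow(tx$exons))) {
    s <- max(tx$exons$start[i], lo)
    e <- min(tx$exons$end[i], hi)
    if (s > e) next
    out <- c(out, if (tx$strand == "+") s:e else e:s)
  }
  out
}

# A fixed 3-exon plus-strand toy transcript with a controlled coding
# sequence: coding portions 70 + 200 + 30 = 300 nt, one domain aa 60-70.
# Codon 17 is TGG (one substitution away from two different stops).
toy_cds_sequence <- function() {
  codons <- rep("GCT", 100)          # Ala filler
  codons[1] <- "ATG"
  codons[17] <- "TGG"                # cds 49-51
  codons[40] <- "TGG"                # cds 118-120
  codons[75] <- "TGG"                # cds 223-225, inside the escape zone
  codons[91] <- "TGG"                # cds 271-273, first codon of last exon
  codons[100] <- "TAA"
  paste(codons, collapse = "")
}

toy_transcript <- function(domains = data.frame(name = "D1", aa_start = 60,
                                                aa_end = 70)) {
  transcript_model(
    gene_symbol = "TOY", transcript_id = "TOY_TX", chrom = "chrT",
    strand = "+",
    exons = data.frame(start = c(101, 301, 601), end = c(200, 500, 800)),
    cds_start_genomic = 131, cds_end_genomic = 630,
    domains = domains, cds_sequence = toy_cds_sequence())
}

toy_variant <- function(pos, ref, alt, mafs = c(exac = NA_real_),
                        preds = c(pred1 = "unknown", pred2 = "unknown"),
                        ...) {
  list(chrom = "chrT", pos = pos, ref = ref, alt = alt,
       gene_symbol = "TOY", transcript_id = "TOY_TX", mafs = mafs,
       predictor_verdicts = preds, ...)
}
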