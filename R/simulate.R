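# Synthetic cohort generator. Emulates the statistical structure the burden
# analysis assumes -- per-gene carrier frequencies in cases and control
# cohorts, a recurrent founder frameshift, phenotype margins (bilateral
# fraction, receptor-status margins, age at first diagnosis), gene-specific
# stratum enrichments and the occasional dual-gene carrier -- and records
# every latent parameter in a truth table for recovery tests.

# run code under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# derive a component sub-seed from the global seed (kept below 2^31)
sub_seed <- function(seed, k) (as.integer(seed) %% 100000L) * 10L + 7919L * k

STOP_CODONS <- c("TAA", "TAG", "TGA")
SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

#' Generate a random valid transcript model
#'
#' Builds a synthetic transcript with the requested exon count and CDS
#' length: random exon coding lengths, 5'/3' UTR stubs, random introns, a
#' random coding sequence without internal stop codons, and (optionally)
#' protein domains. Reproducible for a given seed.
#'
#' @param gene_symbol,chrom,strand Identity of the model; `chrom` defaults
#'   to `chr_<gene_symbol>`, `strand` is drawn at random if `NULL`.
#' @param n_exons Number of exons (>= 1).
#' @param cds_length CDS length in nucleotides (multiple of 3, incl. stop).
#' @param domain_layout `"auto"` (one mid-protein and one C-terminal
#'   domain), `NULL` (none), or a data.frame with `name`, `aa_start`,
#'   `aa_end`.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @param transcript_id Defaults to `SYN_<gene_symbol>`.
#' @return A [transcript_model()] with `cds_sequence` set.
#' @export
make_transcript <- function(gene_symbol, n_exons, cds_length,
                            domain_layout = "auto", seed = NULL,
                            chrom = paste0("chr_", gene_symbol),
                            strand = NULL,
                            transcript_id = paste0("SYN_", gene_symbol)) {
  if (cds_length %% 3L != 0L) stop("cds_length must be a multiple of 3")
  if (n_exons < 1L) stop("n_exons must be >= 1")
  if (cds_length < 3L * (n_exons + 2L))
    stop("infeasible geometry: CDS too short for ", n_exons, " exons")
  build <- function() {
    if (is.null(strand)) strand <- sample(c("+", "-"), 1L)
    # partition the CDS over exons
    if (n_exons == 1L) {
      clens <- cds_length
    } else {
      minlen <- max(3L, min(60L, cds_length %/% (3L * n_exons)))
      repeat {
        cuts <- sort(sample(seq_len(cds_length - 1L), n_exons - 1L))
        clens <- diff(c(0L, cuts, cds_length))
        if (all(clens >= minlen)) break
      }
    }
    utr5 <- sample(20:200, 1L)
    utr3 <- sample(50:300, 1L)
    introns <- if (n_exons > 1L) sample(80:400, n_exons - 1L,
                                        replace = TRUE) else integer(0)
    # plus-strand layout, reflected later if needed
    ex_start <- integer(n_exons); ex_end <- integer(n_exons)
    pos <- 1001L
    for (i in seq_len(n_exons)) {
      len <- clens[i] +
        (if (i == 1L) utr5 else 0L) + (if (i == n_exons) utr3 else 0L)
      ex_start[i] <- pos
      ex_end[i] <- pos + len - 1L
      pos <- ex_end[i] + (if (i < n_exons) introns[i] else 0L)
    }
    cds_start <- ex_start[1L] + utr5
    cds_end <- ex_end[n_exons] - utr3
    if (strand == "-") {
      m <- ex_end[n_exons] + 1000L
      new_start <- m - ex_end
      new_end <- m - ex_start
      ex_start <- new_start; ex_end <- new_end
      tmp <- m - cds_start; cds_end <- m - cds_end; cds_start <- tmp
    }
    protein_length <- cds_length %/% 3L - 1L
    seqn <- paste0("ATG",
                   paste(sample(SENSE_CODONS, protein_length - 1L,
                                replace = TRUE), collapse = ""),
                   "TAA")
    domains <- NULL
    if (identical(domain_layout, "auto")) {
      domains <- data.frame(
        name = c("MID_DOMAIN", "CTERM_DOMAIN"),
        aa_start = pmax(1L, c(round(0.35 * protein_length),
                              round(0.82 * protein_length))),
        aa_end = pmin(protein_length, c(round(0.45 * protein_length),
                                        round(0.92 * protein_length))))
    } else if (is.data.frame(domain_layout)) {
      domains <- domain_layout
    }
    transcript_model(gene_symbol = gene_symbol,
                     transcript_id = transcript_id,
                     chrom = chrom, strand = strand,
                     exons = data.frame(start = ex_start, end = ex_end),
                     cds_start_genomic = cds_start,
                     cds_end_genomic = cds_end,
                     domains = domains, cds_sequence = seqn)
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

# genomic positions that are donor-side last exonic bases (to avoid when
# engineering plain coding SNVs)
donor_last_positions <- function(tx) {
  n <- nrow(tx$exons)
  if (n < 2L) return(integer(0))
  if (tx$strand == "+") tx$exons$end[seq_len(n - 1L)]
  else tx$exons$start[seq_len(n - 1L)]
}

# engineer a nonsense SNV at (or near) the requested codon; deterministic
make_nonsense <- function(tx, target_codon) {
  seqn <- tx$cds_sequence
  pl <- tx$protein_length
  avoid <- donor_last_positions(tx)
  deltas <- c(0L, as.vector(rbind(seq_len(pl), -seq_len(pl))))
  for (d in deltas) {
    ci <- target_codon + d
    if (ci < 2L || ci > pl) next
    c0 <- 3L * (ci - 1L) + 1L
    codon <- substr(seqn, c0, c0 + 2L)
    if (translate_codon(codon) == "*") next
    for (w in 1:3) {
      for (alt in c("A", "G", "T", "C")) {
        if (substr(codon, w, w) == alt) next
        nc <- codon
        substr(nc, w, w) <- alt
        if (!nc %in% STOP_CODONS) next
        cpos <- c0 + w - 1L
        g <- cds_to_genomic(tx, cpos)
        if (g %in% avoid) next
        ref_cds <- substr(seqn, cpos, cpos)
        if (tx$strand == "+") {
          return(list(pos = g, ref = ref_cds, alt = alt, anchor = c0))
        } else {
          return(list(pos = g, ref = comp_base(ref_cds),
                      alt = comp_base(alt), anchor = c0))
        }
      }
    }
  }
  stop("could not engineer a nonsense variant near codon ", target_codon)
}

# engineer a 1-bp frameshift deletion anchored at (or near) cds position t
make_frameshift <- function(tx, target_t) {
  seqn <- tx$cds_sequence
  L <- tx$cds_length
  deltas <- c(0L, as.vector(rbind(seq_len(L), -seq_len(L))))
  for (d in deltas) {
    t <- target_t + d
    if (t < 2L || t > L - 1L) next
    g <- cds_to_genomic(tx, t)
    if (tx$strand == "+") {
      if (cds_to_genomic(tx, t - 1L) != g - 1L) next  # spans exon boundary
      ref <- substr(seqn, t - 1L, t)
      return(list(pos = g - 1L, ref = ref, alt = substr(ref, 1L, 1L),
                  anchor = t))
    } else {
      if (cds_to_genomic(tx, t + 1L) != g - 1L) next
      ref <- paste0(comp_base(substr(seqn, t + 1L, t + 1L)),
                    comp_base(substr(seqn, t, t)))
      return(list(pos = g - 1L, ref = ref, alt = substr(ref, 1L, 1L),
                  anchor = t))
    }
  }
  stop("could not engineer a frameshift near cds position ", target_t)
}

# essential splice SNV in the intron after transcript-order exon `junction`
make_splice <- function(tx, junction, off = 1L) {
  pos <- if (tx$strand == "+") tx$exons$end[junction] + off
    else tx$exons$start[junction] - off
  list(pos = pos, ref = "G", alt = "T", junction = junction)
}

# engineer a missense SNV at (or near) the requested codon; deterministic
make_missense <- function(tx, target_codon) {
  seqn <- tx$cds_sequence
  pl <- tx$protein_length
  avoid <- donor_last_positions(tx)
  deltas <- c(0L, as.vector(rbind(seq_len(pl), -seq_len(pl))))
  for (d in deltas) {
    ci <- target_codon + d
    if (ci < 2L || ci > pl) next
    c0 <- 3L * (ci - 1L) + 1L
    codon <- substr(seqn, c0, c0 + 2L)
    aa0 <- translate_codon(codon)
    if (aa0 == "*") next
    for (w in 1:3) {
      for (alt in c("C", "A", "G", "T")) {
        if (substr(codon, w, w) == alt) next
        nc <- codon
        substr(nc, w, w) <- alt
        aa1 <- translate_codon(nc)
        if (aa1 == aa0 || aa1 == "*") next
        cpos <- c0 + w - 1L
        g <- cds_to_genomic(tx, cpos)
        if (g %in% avoid) next
        ref_cds <- substr(seqn, cpos, cpos)
        if (tx$strand == "+") {
          return(list(pos = g, ref = ref_cds, alt = alt, anchor = c0))
        } else {
          return(list(pos = g, ref = comp_base(ref_cds),
                      alt = comp_base(alt), anchor = c0))
        }
      }
    }
  }
  stop("could not engineer a missense variant near codon ", target_codon)
}

# literal truth class of an engineered PTV (rule text, not the engine)
truth_ptv_class <- function(tx, anchor_eval) {
  zone <- nmd_escape_zone(tx)
  if (anchor_eval < zone[1]) return(5L)
  dom <- domain_cds_intervals(tx)
  if (nrow(dom) && any(dom$cds_end >= anchor_eval)) 5L else 3L
}

#' Simulate protein-truncating variants on a transcript
#'
#' Draws `n` PTVs (nonsense / frameshift / essential splice mixture), a
#' configured fraction anchored inside the NMD-escape zone, and returns the
#' VCF-level records together with the generator's own (literal-rule) truth
#' about category, anchor and expected class.
#'
#' @param tx A [transcript_model()] with `cds_sequence`.
#' @param n Number of variants.
#' @param zone_fraction Fraction of variants aimed into the escape zone.
#' @param seed Optional seed.
#' @param type_probs Probabilities for nonsense / frameshift / splice.
#' @return data.frame with `chrom`, `pos`, `ref`, `alt` plus truth columns
#'   `truth_category`, `truth_anchor`, `truth_class`.
#' @export
simulate_ptvs <- function(tx, n, zone_fraction = 0.08, seed = NULL,
                          type_probs = c(nonsense = 0.5, frameshift = 0.3,
                                         splice = 0.2)) {
  run <- function() {
    zone <- nmd_escape_zone(tx)
    L <- tx$cds_length
    last_ci <- last_coding_exon_index(tx)
    n_junc <- sum(tx$coding_len > 0L) - 1L
    rows <- vector("list", n)
    for (k in seq_len(n)) {
      type <- sample(names(type_probs), 1L, prob = type_probs)
      if (type == "splice" && n_junc == 0L) type <- "nonsense"
      in_zone <- stats::runif(1) < zone_fraction
      if (type == "splice") {
        j <- if (in_zone || n_junc == 1L) last_ci - 1L
          else sample(seq_len(n_junc - 1L), 1L)
        vr <- make_splice(tx, j, off = sample(1:2, 1L))
        anchor_eval <- if (j >= last_ci - 1L)
          first_cds_of_last_coding_exon(tx) else 0L
        rows[[k]] <- data.frame(
          chrom = tx$chrom, pos = vr$pos, ref = vr$ref, alt = vr$alt,
          truth_category = "essential_splice", truth_anchor = NA_integer_,
          truth_class = truth_ptv_class(tx, anchor_eval))
      } else {
        tpos <- if (in_zone && zone[1] < L - 3L)
          sample(seq(zone[1], L - 3L), 1L)
        else sample(seq(4L, max(4L, zone[1] - 1L)), 1L)
        vr <- if (type == "nonsense")
          make_nonsense(tx, (tpos - 1L) %/% 3L + 1L)
        else make_frameshift(tx, tpos)
        rows[[k]] <- data.frame(
          chrom = tx$chrom, pos = vr$pos, ref = vr$ref, alt = vr$alt,
          truth_category = type, truth_anchor = vr$anchor,
          truth_class = truth_ptv_class(tx, vr$anchor))
      }
    }
    do.call(rbind, rows)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Default simulation configuration
#'
#' Default parameters place the simulated study at the scale and carrier
#' frequencies of a large BRCA1/2-negative breast-cancer panel study: 5589
#' index cases, three control cohorts (an ExAC-like exome reference of
#' 27,173, a FLOSSIES-like hypernormal cohort of 7325, and 2189
#' geographically matched controls), eight panel genes at their observed
#' deleterious-PTV carrier frequencies (0.05--1.84% in cases), a recurrent
#' CHEK2 founder frameshift keyed `c.1100del`, age at first diagnosis from a
#' truncated normal (mean 46.7, sd 11, range 17--92 years), an 11.3%
#' bilateral fraction, receptor-status margins (ER+ 75.9%, PR+ 70.5%, HER2+
#' 21.2% among the 55.5% with known status), and per-gene stratum effects
#' (odds multipliers) plus age shifts.
#'
#' @param seed Integer seed (mandatory for reproducibility).
#' @param n_cases Number of index cases.
#' @param genes Per-gene parameter data.frame (see the default for columns).
#' @param cohorts Control cohort sizes.
#' @param control_probs Per-gene carrier probabilities per cohort.
#' @param dm_probs Damaging-missense carrier probabilities (cases and the
#'   exome-reference cohort).
#' @param phenotype Phenotype-model parameters.
#' @param effects Per-gene stratum odds multipliers and age shifts.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(
    seed,
    n_cases = 5589L,
    genes = NULL, cohorts = NULL, control_probs = NULL, dm_probs = NULL,
    phenotype = NULL, effects = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  g8 <- c("ATM", "CDH1", "CHEK2", "NBN", "PALB2", "RAD51C", "RAD51D", "TP53")
  if (is.null(genes)) genes <- data.frame(
    gene = g8,
    case_prob = c(71, 7, 103, 12, 64, 9, 5, 3) / 5589,
    n_exons = c(12L, 8L, 8L, 8L, 7L, 6L, 6L, 7L),
    cds_length = c(9171L, 2649L, 1632L, 2265L, 3561L, 1131L, 987L, 1182L),
    zone_fraction = 0.08,
    founder_fraction = c(0, 0, 79 / 103, 0, 0, 0, 0, 0),
    vus_prob = c(322, 22, 196, 22, 76, 17, 17, 22) / 5589,
    dm_case_prob = c(0.002, 0.0005, 80 / 5589, 0.0005, 0.001, 0.0005,
                     0.0005, 23 / 5589),
    common_prob = 0.01,
    stringsAsFactors = FALSE)
  if (is.null(cohorts)) cohorts <- data.frame(
    cohort = c("ExAC", "FLOSSIES", "GMC"),
    n_total = c(27173L, 7325L, 2189L), stringsAsFactors = FALSE)
  if (is.null(control_probs)) control_probs <- data.frame(
    gene = g8,
    ExAC = c(96, 2, 172, 42, 33, 34, 8, 2) / 27173,
    FLOSSIES = c(14, 0, 28, 14, 7, 2, 2, 0) / 7325,
    GMC = c(9, 0, 11, 9, 2, 2, 0, 0) / 2189,
    stringsAsFactors = FALSE)
  if (is.null(dm_probs)) dm_probs <- data.frame(
    gene = g8,
    case = c(0.002, 0.0005, 80 / 5589, 0.0005, 0.001, 0.0005, 0.0005,
             23 / 5589),
    ExAC = c(0.0015, 0.0003, 193 / 27173, 0.0003, 0.0008, 0.0003, 0.0003,
             49 / 27173),
    stringsAsFactors = FALSE)
  if (is.null(phenotype)) phenotype <- list(
    aad_mean = 46.7, aad_sd = 11, aad_range = c(17, 92),
    aad_missing_prob = 49 / 5589,
    bilateral_prob = 629 / 5589, oc_fh_prob = 934 / 5589,
    status_avail_prob = 3104 / 5589,
    er_pos_prob = 2355 / 3104, pr_pos_prob = 2188 / 3104,
    her2_pos_prob = 657 / 3104)
  if (is.null(effects)) effects <- data.frame(
    gene = g8,
    bilateral_or = c(1.11, 1.13, 1.35, 1.0, 2.07, 0.79, 1.58, 3.30),
    er_pos_or = c(3.4, 1.0, 1.7, 1.0, 1.0, 1.0, 1.0, 1.0),
    her2_pos_or = c(1.0, 1.0, 2.5, 1.0, 1.0, 1.0, 1.0, 1.0),
    aad_shift = c(-1.7, -1.6, 0.4, -0.4, -0.9, -1.8, 0.1, -7.0),
    stringsAsFactors = FALSE)
  stopifnot(all(genes$case_prob >= 0 & genes$case_prob <= 1),
            all(phenotype$aad_range >= 10 & phenotype$aad_range <= 110))
  structure(list(seed = as.integer(seed), n_cases = as.integer(n_cases),
                 genes = genes, cohorts = cohorts,
                 control_probs = control_probs, dm_probs = dm_probs,
                 phenotype = phenotype, effects = effects),
            class = "simulation_config")
}

#' Simulate a case cohort with control counts and a truth table
#'
#' Per patient and gene, carrier status is Bernoulli with the configured
#' marginal probability, modulated by stratum effects (odds multipliers for
#' bilateral disease and receptor status, renormalised so the configured
#' per-gene marginal prevalence is preserved). Carriers receive a concrete
#' engineered variant on the gene's synthetic transcript (nonsense /
#' frameshift / essential-splice mixture, a configured fraction landing in
#' the NMD-escape zone, CHEK2 carriers drawing the founder frameshift with
#' the configured probability). Non-qualifying variation (missense VUS,
#' consensus-damaging rare missense, a common benign allele per gene) is
#' generated alongside. Control carrier counts are binomial draws per cohort
#' and gene. Every latent parameter lands in the truth table.
#'
#' @param config A [simulation_config()].
#' @param make_variants If `FALSE`, skip concrete variant construction and
#'   return carrier indicators only (fast path for replicate studies).
#' @return List with `transcripts`, `phenotypes`, `variants` (data.frame or
#'   `NULL`), `controls`, `truth`, `config`.
#' @export
simulate_cohort <- function(config, make_variants = TRUE) {
  stopifnot(inherits(config, "simulation_config"))
  gdf <- config$genes
  G <- nrow(gdf)
  n <- config$n_cases
  ph <- config$phenotype
  eff <- config$effects[match(gdf$gene, config$effects$gene), ]

  # --- transcripts (regenerate if the founder anchor falls in the zone) ---
  transcripts <- with_seed(sub_seed(config$seed, 1L), {
    out <- list()
    for (i in seq_len(G)) {
      attempt <- 0L
      repeat {
        tx <- make_transcript(gdf$gene[i], gdf$n_exons[i], gdf$cds_length[i],
                              seed = NULL)
        if (gdf$founder_fraction[i] == 0 ||
            nmd_escape_zone(tx)[1] > 1103L) break
        attempt <- attempt + 1L
        if (attempt > 50L) stop("could not place founder upstream of zone")
      }
      out[[tx$transcript_id]] <- tx
    }
    out
  })
  tx_of <- stats::setNames(names(transcripts), gdf$gene)

  # --- phenotypes ---
  phen <- with_seed(sub_seed(config$seed, 2L), {
    bilateral <- stats::runif(n) < ph$bilateral_prob
    oc_fh <- stats::runif(n) < ph$oc_fh_prob
    avail <- stats::runif(n) < ph$status_avail_prob
    er <- ifelse(avail, ifelse(stats::runif(n) < ph$er_pos_prob,
                               "positive", "negative"), "unknown")
    pr <- ifelse(avail, ifelse(stats::runif(n) < ph$pr_pos_prob,
                               "positive", "negative"), "unknown")
    her2 <- ifelse(avail, ifelse(stats::runif(n) < ph$her2_pos_prob,
                                 "positive", "negative"), "unknown")
    data.frame(patient_id = sprintf("S%05d", seq_len(n)),
               bilateral = bilateral, oc_family_history = oc_fh,
               er = er, pr = pr, her2 = her2, stringsAsFactors = FALSE)
  })

  # --- carrier draws, stratum-modulated with preserved marginals ---
  carrier <- with_seed(sub_seed(config$seed, 3L), {
    m <- matrix(FALSE, n, G, dimnames = list(NULL, gdf$gene))
    for (i in seq_len(G)) {
      f <- rep(1, n)
      f <- f * ifelse(phen$bilateral, eff$bilateral_or[i], 1)
      f <- f * ifelse(phen$er == "positive", eff$er_pos_or[i], 1)
      f <- f * ifelse(phen$her2 == "positive", eff$her2_pos_or[i], 1)
      e_f <- (ph$bilateral_prob * eff$bilateral_or[i] +
                (1 - ph$bilateral_prob)) *
        (ph$status_avail_prob *
           (ph$er_pos_prob * eff$er_pos_or[i] + (1 - ph$er_pos_prob)) +
           (1 - ph$status_avail_prob)) *
        (ph$status_avail_prob *
           (ph$her2_pos_prob * eff$her2_pos_or[i] + (1 - ph$her2_pos_prob)) +
           (1 - ph$status_avail_prob))
      p_i <- pmin(gdf$case_prob[i] * f / e_f, 1)
      m[, i] <- stats::runif(n) < p_i
    }
    m
  })

  # --- age at first diagnosis ---
  phen$aad_years <- with_seed(sub_seed(config$seed, 4L), {
    aad <- rtrunc_norm(n, ph$aad_mean, ph$aad_sd,
                       ph$aad_range[1], ph$aad_range[2])
    for (i in seq_len(G)) {
      idx <- which(carrier[, i])
      aad[idx] <- pmin(pmax(aad[idx] + eff$aad_shift[i], ph$aad_range[1]),
                       ph$aad_range[2])
    }
    aad[stats::runif(n) < ph$aad_missing_prob] <- NA_real_
    round(aad)
  })

  # --- concrete variants ---
  variants <- NULL
  if (make_variants) {
    variants <- with_seed(sub_seed(config$seed, 5L), {
      rows <- list()
      vid <- 0L
      add <- function(patient, gene, tx, pos, ref, alt, cdot = NA_character_,
                      maf_exac = NA_real_, pred1 = "unknown",
                      pred2 = "unknown",
                      truth_category = NA_character_,
                      truth_anchor = NA_integer_,
                      truth_class = NA_integer_) {
        vid <<- vid + 1L
        rows[[vid]] <<- data.frame(
          variant_id = sprintf("v%06d", vid), patient_id = patient,
          gene = gene, transcript_id = tx$transcript_id, chrom = tx$chrom,
          pos = pos, ref = ref, alt = alt, cdot = cdot,
          maf_exac = maf_exac, pred1 = pred1, pred2 = pred2,
          truth_category = truth_category, truth_anchor = truth_anchor,
          truth_class = truth_class, stringsAsFactors = FALSE)
      }
      for (i in seq_len(G)) {
        tx <- transcripts[[tx_of[[gdf$gene[i]]]]]
        founder <- if (gdf$founder_fraction[i] > 0)
          make_frameshift(tx, 1100L) else NULL
        carriers_i <- which(carrier[, i])
        if (length(carriers_i)) {
          ptvs <- simulate_ptvs(tx, length(carriers_i),
                                zone_fraction = gdf$zone_fraction[i])
          use_founder <- !is.null(founder) &
            stats::runif(length(carriers_i)) < gdf$founder_fraction[i]
          for (k in seq_along(carriers_i)) {
            pid <- phen$patient_id[carriers_i[k]]
            if (use_founder[k]) {
              add(pid, gdf$gene[i], tx, founder$pos, founder$ref,
                  founder$alt, cdot = "c.1100del",
                  truth_category = "frameshift",
                  truth_anchor = founder$anchor,
                  truth_class = truth_ptv_class(tx, founder$anchor))
            } else {
              add(pid, gdf$gene[i], tx, ptvs$pos[k], ptvs$ref[k],
                  ptvs$alt[k],
                  truth_category = ptvs$truth_category[k],
                  truth_anchor = ptvs$truth_anchor[k],
                  truth_class = ptvs$truth_class[k])
            }
          }
        }
        # missense VUS (mixed predictor verdicts)
        vus_idx <- which(stats::runif(n) < gdf$vus_prob[i])
        for (k in vus_idx) {
          mv <- make_missense(tx, sample(seq(2L, tx$protein_length - 1L), 1L))
          add(phen$patient_id[k], gdf$gene[i], tx, mv$pos, mv$ref, mv$alt,
              maf_exac = signif(stats::runif(1, 0, 5e-4), 3),
              pred1 = sample(c("damaging", "tolerated"), 1L),
              pred2 = "tolerated",
              truth_category = "missense", truth_anchor = mv$anchor,
              truth_class = 3L)
        }
        # consensus-damaging rare missense
        dm_idx <- which(stats::runif(n) < gdf$dm_case_prob[i])
        for (k in dm_idx) {
          mv <- make_missense(tx, sample(seq(2L, tx$protein_length - 1L), 1L))
          add(phen$patient_id[k], gdf$gene[i], tx, mv$pos, mv$ref, mv$alt,
              maf_exac = signif(stats::runif(1, 0, 5e-4), 3),
              pred1 = "damaging", pred2 = "damaging",
              truth_category = "missense", truth_anchor = mv$anchor,
              truth_class = 3L)
        }
        # one common benign allele per gene
        cv <- make_missense(tx, max(2L, tx$protein_length %/% 2L))
        common_idx <- which(stats::runif(n) < gdf$common_prob[i])
        for (k in common_idx) {
          add(phen$patient_id[k], gdf$gene[i], tx, cv$pos, cv$ref, cv$alt,
              maf_exac = 0.02, pred1 = "tolerated", pred2 = "tolerated",
              truth_category = "missense", truth_anchor = cv$anchor,
              truth_class = 1L)
        }
      }
      do.call(rbind, rows)
    })
  }

  # --- control cohorts ---
  controls <- with_seed(sub_seed(config$seed, 6L), {
    rows <- list()
    for (j in seq_len(nrow(config$cohorts))) {
      ch <- config$cohorts$cohort[j]
      nt <- config$cohorts$n_total[j]
      probs <- config$control_probs[[ch]]
      for (i in seq_len(G)) {
        rows[[length(rows) + 1L]] <- data.frame(
          cohort = ch, n_total = nt, gene = gdf$gene[i],
          carriers = stats::rbinom(1L, nt, probs[i]), metric = "ptv",
          stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        cohort = ch, n_total = nt, gene = "ALL",
        carriers = stats::rbinom(1L, nt, 1 - prod(1 - probs)),
        metric = "ptv", stringsAsFactors = FALSE)
      ci <- which(gdf$gene == "CHEK2")
      if (length(ci) && gdf$founder_fraction[ci] > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          cohort = ch, n_total = nt, gene = "CHEK2_c1100del",
          carriers = stats::rbinom(1L, nt,
                                   probs[ci] * gdf$founder_fraction[ci]),
          metric = "ptv", stringsAsFactors = FALSE)
      }
      if ("ExAC" %in% names(config$dm_probs) && ch == "ExAC") {
        for (i in seq_len(G)) {
          rows[[length(rows) + 1L]] <- data.frame(
            cohort = ch, n_total = nt, gene = gdf$gene[i],
            carriers = stats::rbinom(1L, nt, config$dm_probs$ExAC[i]),
            metric = "damaging_missense", stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })

  # --- truth table ---
  true_log_or <- lapply(stats::setNames(config$cohorts$cohort,
                                        config$cohorts$cohort), function(ch) {
    p1 <- gdf$case_prob
    p0 <- config$control_probs[[ch]]
    stats::setNames(log((p1 / (1 - p1)) / (p0 / (1 - p0))), gdf$gene)
  })
  truth <- list(carrier = carrier,
                case_prob = stats::setNames(gdf$case_prob, gdf$gene),
                control_probs = config$control_probs,
                true_log_or = true_log_or,
                n_dual_carriers = sum(rowSums(carrier) >= 2L))

  phen <- phen[, c("patient_id", "aad_years", "bilateral",
                   "oc_family_history", "er", "pr", "her2")]
  list(transcripts = transcripts, phenotypes = phen, variants = variants,
       controls = controls, truth = truth, config = config)
}

#' Classified table implied by the generator's truth
#'
#' Builds a minimal classified-variant data.frame straight from the latent
#' carrier indicators (every carrier holds one deleterious PTV in the gene).
#' Used for estimator-recovery studies where the concrete VCF layer is not
#' the quantity under test.
#'
#' @param sim Output of [simulate_cohort()].
#' @return Classified-variant data.frame.
#' @export
truth_classified <- function(sim) {
  idx <- which(sim$truth$carrier, arr.ind = TRUE)
  genes <- colnames(sim$truth$carrier)[idx[, 2]]
  data.frame(
    variant_id = sprintf("t%05d", seq_len(nrow(idx))),
    patient_id = sim$phenotypes$patient_id[idx[, 1]],
    gene = genes, transcript_id = paste0("SYN_", genes),
    chrom = paste0("chr_", genes), pos = seq_len(nrow(idx)),
    ref = "A", alt = "T", cdot = NA_character_,
    category = "nonsense", splice_detail = NA_character_,
    cds_anchor = 1L, is_ptv = TRUE, iarc_class = 5L,
    rationale = "ptv_class5", damaging_missense = FALSE,
    note = NA_character_, stringsAsFactors = FALSE)
}
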