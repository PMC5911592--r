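# Rule-based variant classification: consequence calling, PTV determination,
# NMD-escape demotion with domain rescue, MAF-based benign assignment,
# overrides, five-tier class assignment and the consensus damaging-missense
# flag.

COMP <- c(A = "T", C = "G", G = "C", T = "A")

comp_base <- function(x) unname(COMP[x])

revcomp <- function(x) {
  paste(rev(unname(COMP[strsplit(x, "")[[1]]])), collapse = "")
}

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

# normalise a variant to a plain list with canonical fields
as_variant <- function(variant) {
  v <- as.list(variant)
  v$ref <- toupper(v$ref); v$alt <- toupper(v$alt)
  if (identical(v$ref, v$alt)) stop("variant with ref == alt")
  v
}

#' Call the molecular consequence of a variant on a transcript
#'
#' SNVs in the coding region are classified by codon translation when the
#' coding sequence is available (nonsense / missense / synonymous); indels
#' whose net length change is not a multiple of 3 are frameshifts, otherwise
#' in-frame indels. Substitutions or deletions touching the invariant +-1/+-2
#' intronic dinucleotides, or the last exonic base on the donor side of an
#' exon, are essential splice-site variants. Without a coding sequence, SNVs
#' fall back to a supplied HGVS p. annotation if present, else `"other"`.
#'
#' @param variant List or one-row data.frame with at least `chrom`, `pos`,
#'   `ref`, `alt`; optionally `hgvs_p`.
#' @param tx A [transcript_model()].
#' @param cds_sequence Coding sequence to use; defaults to the transcript's
#'   own `cds_sequence` if present.
#' @return A list (`consequence_call`) with `category` (one of `nonsense`,
#'   `frameshift`, `essential_splice`, `missense`, `synonymous`,
#'   `inframe_indel`, `other`), `cds_anchor` (coding position of the first
#'   altered codon, or `NA`), `splice_detail` (`donor_plus1`, `donor_plus2`,
#'   `acceptor_minus1`, `acceptor_minus2`, `exon_last_base`, or `NA`) and
#'   `splice_junction` (transcript-order index of the upstream exon of the
#'   affected junction, or `NA`).
#' @export
call_consequence <- function(variant, tx, cds_sequence = NULL) {
  v <- as_variant(variant)
  if (!identical(as.character(v$chrom), tx$chrom))
    stop("variant chrom ", v$chrom, " does not match transcript chrom ",
         tx$chrom)
  if (is.null(cds_sequence)) cds_sequence <- tx$cds_sequence
  res <- list(category = "other", cds_anchor = NA_integer_,
              splice_detail = NA_character_, splice_junction = NA_integer_)
  pos <- as.integer(v$pos)
  n_ref <- nchar(v$ref); n_alt <- nchar(v$alt)

  if (n_ref == 1L && n_alt == 1L) {
    loc <- genomic_to_cds(tx, pos)
    if (loc$kind == "intronic" && abs(loc$intron_offset) <= 2L) {
      res$category <- "essential_splice"
      res$splice_detail <- if (loc$intron_offset > 0L)
        paste0("donor_plus", loc$intron_offset) else
        paste0("acceptor_minus", -loc$intron_offset)
      res$splice_junction <- loc$intron_index
      return(res)
    }
    if (loc$kind == "coding") {
      # donor-side last exonic base counts as an essential splice site
      i <- loc$exon_index
      donor_base <- if (tx$strand == "+") tx$exons$end[i] else tx$exons$start[i]
      if (i < nrow(tx$exons) && pos == donor_base) {
        res$category <- "essential_splice"
        res$splice_detail <- "exon_last_base"
        res$splice_junction <- i
        return(res)
      }
      if (!is.null(cds_sequence)) {
        cpos <- loc$cds_pos
        cds_ref <- if (tx$strand == "+") v$ref else comp_base(v$ref)
        cds_alt <- if (tx$strand == "+") v$alt else comp_base(v$alt)
        seq_ref <- substr(cds_sequence, cpos, cpos)
        if (seq_ref != cds_ref)
          stop("reference allele mismatch at ", v$chrom, ":", pos,
               " (CDS position ", cpos, ": expected ", seq_ref,
               ", variant has ", cds_ref, ")")
        codon_i <- (cpos - 1L) %/% 3L + 1L
        c0 <- 3L * (codon_i - 1L) + 1L
        codon <- substr(cds_sequence, c0, c0 + 2L)
        within <- cpos - c0 + 1L
        new_codon <- codon
        substr(new_codon, within, within) <- cds_alt
        aa_old <- translate_codon(codon)
        aa_new <- translate_codon(new_codon)
        res$cds_anchor <- c0
        res$category <-
          if (identical(aa_old, aa_new)) "synonymous"
          else if (identical(aa_new, "*")) "nonsense"
          else if (identical(aa_old, "*")) "other"   # stop-loss
          else "missense"
        if (res$category == "other") res$cds_anchor <- NA_integer_
        return(res)
      }
      # no sequence: fall back to HGVS p. annotation
      hp <- v$hgvs_p
      if (!is.null(hp) && !is.na(hp) && nzchar(hp)) {
        aa_num <- suppressWarnings(as.integer(sub("^p\\.[A-Za-z*]+(\\d+).*$",
                                                  "\\1", hp)))
        anchor <- if (!is.na(aa_num)) 3L * (aa_num - 1L) + 1L else NA_integer_
        if (grepl("Ter|\\*$|\\*[0-9]*$", hp) && !grepl("ext", hp)) {
          res$category <- "nonsense"; res$cds_anchor <- anchor
        } else if (grepl("=", hp, fixed = TRUE)) {
          res$category <- "synonymous"; res$cds_anchor <- anchor
        } else {
          res$category <- "missense"; res$cds_anchor <- anchor
        }
        return(res)
      }
      return(res)
    }
    return(res)  # utr / outside -> other
  }

  # --- indel ---
  net <- n_alt - n_ref
  if (net == 0L) return(res)  # MNV: not classified beyond 'other'
  if (net < 0L) {
    # deletion, VCF left-anchored: deleted genomic bases pos+1 .. pos+n_ref-1
    del <- (pos + 1L):(pos + n_ref - 1L)
    locs <- lapply(del, genomic_to_cds, tx = tx)
    # splice check first
    for (k in seq_along(locs)) {
      l <- locs[[k]]
      if (l$kind == "intronic" && abs(l$intron_offset) <= 2L) {
        res$category <- "essential_splice"
        res$splice_detail <- if (l$intron_offset > 0L)
          paste0("donor_plus", l$intron_offset) else
          paste0("acceptor_minus", -l$intron_offset)
        res$splice_junction <- l$intron_index
        return(res)
      }
      if (l$kind == "coding") {
        i <- l$exon_index
        donor_base <- if (tx$strand == "+") tx$exons$end[i]
          else tx$exons$start[i]
        if (i < nrow(tx$exons) && del[k] == donor_base) {
          res$category <- "essential_splice"
          res$splice_detail <- "exon_last_base"
          res$splice_junction <- i
          return(res)
        }
      }
    }
    cds_hit <- vapply(locs, function(l)
      if (l$kind == "coding") l$cds_pos else NA_integer_, integer(1))
    if (all(is.na(cds_hit))) return(res)
    res$category <- if ((-net) %% 3L == 0L) "inframe_indel" else "frameshift"
    res$cds_anchor <- min(cds_hit, na.rm = TRUE)
    return(res)
  }
  # insertion between pos and pos+1
  l1 <- genomic_to_cds(tx, pos)
  l2 <- genomic_to_cds(tx, pos + 1L)
  flanks <- c(if (l1$kind == "coding") l1$cds_pos,
              if (l2$kind == "coding") l2$cds_pos)
  if (length(flanks) < 2L) return(res)  # boundary insertions left as 'other'
  res$category <- if (net %% 3L == 0L) "inframe_indel" else "frameshift"
  res$cds_anchor <- max(flanks)  # first transcript position shifted downstream
  res
}

#' Is a consequence protein-truncating?
#'
#' PTVs are nonsense, frameshift or essential splice-site variants (the
#' invariant +-1/+-2 intronic positions or the last exonic base of a donor
#' side).
#'
#' @param consequence A consequence call from [call_consequence()].
#' @param tx Unused; kept for interface symmetry.
#' @return Logical.
#' @export
is_ptv <- function(consequence, tx = NULL) {
  consequence$category %in% c("nonsense", "frameshift", "essential_splice")
}

max_maf <- function(v) {
  m <- v$mafs
  if (is.null(m) || length(m) == 0L) return(0)
  m <- unlist(m)
  m <- m[!is.na(m)]
  if (length(m) == 0L) return(0)
  if (any(m < 0 | m > 1)) stop("MAF outside [0,1]")
  max(m)
}

#' Consensus damaging-missense flag
#'
#' A missense variant is flagged when every reported reference-population MAF
#' is below `rare_threshold` (an unobserved frequency counts as rare) and
#' both configured in-silico predictors call it damaging.
#'
#' @param variant Variant list with `mafs` (named numeric) and
#'   `predictor_verdicts` (named character, two predictors, values
#'   `damaging` / `tolerated` / `unknown`).
#' @param consequence A consequence call.
#' @param rare_threshold MAF cutoff, default 0.001 (0.1%).
#' @return Logical.
#' @export
flag_damaging_missense <- function(variant, consequence,
                                   rare_threshold = 0.001) {
  v <- as.list(variant)
  if (!identical(consequence$category, "missense")) return(FALSE)
  if (max_maf(v) >= rare_threshold) return(FALSE)
  pv <- unlist(v$predictor_verdicts)
  if (length(pv) < 2L) return(FALSE)
  all(pv[1:2] == "damaging")
}

# match an override entry; returns a one-row data.frame or NULL
match_override <- function(v, overrides) {
  if (is.null(overrides) || nrow(overrides) == 0L) return(NULL)
  keys <- character(0)
  if (!is.null(v$cdot) && !is.na(v$cdot) && nzchar(v$cdot))
    keys <- c(keys, paste0(v$gene_symbol, ":", v$cdot), v$cdot)
  keys <- c(keys, paste(v$chrom, v$pos, v$ref, v$alt, sep = ":"))
  hit <- which(overrides$key %in% keys)
  if (length(hit) == 0L) return(NULL)
  overrides[hit[1L], , drop = FALSE]
}

#' Assign the five-tier class of a variant
#'
#' Applies the classification rules in precedence order: (1) a per-variant
#' override forces its class; (2) any reference-population MAF at or above
#' `maf_threshold` (default 1%) makes the variant benign (class 1); (3) a PTV
#' whose truncation anchor lies upstream of the NMD-escape zone is
#' pathogenic (class 5); (4) a PTV anchored inside the zone is demoted to VUS
#' (class 3) unless the truncated region `[anchor, CDS end]` intersects a
#' known functional domain, which restores class 5; (5) everything else is
#' VUS (class 3). Essential splice variants are never demoted by the zone
#' rule unless they affect the final coding junction, in which case they are
#' evaluated at the first coding base of the last coding exon (noted in the
#' output). Class 4 is reachable only through overrides.
#'
#' @param variant Variant list (see [call_consequence()]) with `mafs`,
#'   `predictor_verdicts`, optional `cdot`.
#' @param consequence Consequence call for the same variant/transcript pair.
#' @param tx A [transcript_model()].
#' @param maf_threshold Benign MAF cutoff, default 0.01 (1%).
#' @param overrides Optional override table from [read_overrides()].
#' @param rare_threshold Damaging-missense MAF cutoff, default 0.001.
#' @param domain_mode `"intersect"` (default): the domain is disrupted when
#'   truncation removes any part of it; `"contained"`: only when the whole
#'   domain is removed.
#' @return A list (`classified_variant`) with `iarc_class` (1-5), `is_ptv`,
#'   `rationale` (character vector of rule tags, in application order),
#'   `damaging_missense` and `note`.
#' @export
assign_class <- function(variant, consequence, tx, maf_threshold = 0.01,
                         overrides = NULL, rare_threshold = 0.001,
                         domain_mode = c("intersect", "contained")) {
  domain_mode <- match.arg(domain_mode)
  v <- as_variant(variant)
  ptv <- is_ptv(consequence)
  dm <- flag_damaging_missense(v, consequence, rare_threshold)
  tags <- character(0)
  note <- NA_character_
  cls <- NA_integer_

  ov <- match_override(v, overrides)
  if (!is.null(ov)) {
    cls <- as.integer(ov$forced_class)
    tags <- "override"
  } else if (max_maf(v) >= maf_threshold) {
    cls <- 1L
    tags <- "maf_benign"
  } else if (ptv) {
    zone <- nmd_escape_zone(tx)
    anchor <- consequence$cds_anchor
    if (consequence$category == "essential_splice") {
      j <- consequence$splice_junction
      last_ci <- last_coding_exon_index(tx)
      if (!is.na(j) && j >= last_ci - 1L) {
        # final coding junction (or beyond): evaluate at the first coding
        # base of the last coding exon
        anchor <- first_cds_of_last_coding_exon(tx)
        note <- "final_intron_splice_evaluated_at_last_exon_start"
      } else {
        anchor <- 0L  # upstream junction: always truncating before the zone
      }
    }
    if (is.na(anchor)) anchor <- 0L
    if (length(which(tx$coding_len > 0L)) == 1L && anchor >= zone[1]) {
      if (is.na(note)) note <- "single_coding_exon_whole_cds_escape"
    }
    if (anchor < zone[1]) {
      cls <- 5L
      tags <- "ptv_class5"
    } else {
      dom <- domain_cds_intervals(tx)
      rescued <- if (nrow(dom) == 0L) FALSE else {
        if (domain_mode == "intersect")
          any(dom$cds_end >= anchor & dom$cds_start <= tx$cds_length)
        else
          any(dom$cds_start >= anchor)
      }
      if (rescued) {
        cls <- 5L
        tags <- c("ptv_class5", "domain_rescue")
      } else {
        cls <- 3L
        tags <- "nmd_escape_vus"
      }
    }
  } else {
    cls <- 3L
    tags <- "default_vus"
    if (identical(consequence$category, "missense"))
      tags <- c(tags, "missense_vus")
  }
  if (dm) tags <- c(tags, "damaging_missense_flag")

  list(iarc_class = cls, is_ptv = ptv, rationale = tags,
       damaging_missense = dm, note = note)
}

#' Read a per-variant override table
#'
#' TSV with columns `gene`, `key`, `forced_class`, `reason`. `key` is either
#' a `gene:c.` notation (e.g. `CHEK2:c.470C>T`) or `chrom:pos:ref:alt`.
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_overrides <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "key", "forced_class", "reason")
  if (!all(need %in% names(d)))
    stop("override table must have columns: ", paste(need, collapse = ", "))
  if (any(!d$forced_class %in% 1:5))
    stop("forced_class must be in 1..5")
  d
}

#' Classify a table of variants
#'
#' Data-frame-level engine behind [classify_vcf()]. Each row is one
#' variant-allele observation; MAF columns are any columns named `maf_*`,
#' predictor verdicts come from `pred1` / `pred2`.
#'
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `gene`, `transcript_id`; optional `variant_id`, `patient_id`, `cdot`,
#'   `hgvs_p`, `maf_*`, `pred1`, `pred2`.
#' @param transcripts Named list of [transcript_model()] objects.
#' @param overrides Optional override table.
#' @param maf_threshold,rare_threshold,domain_mode Passed to [assign_class()].
#' @return A list with `classified` (data.frame, one row per input row that
#'   matched a known transcript) and `summary` (list of counts).
#' @export
classify_variants <- function(variants, transcripts, overrides = NULL,
                              maf_threshold = 0.01, rare_threshold = 0.001,
                              domain_mode = "intersect") {
  variants <- as.data.frame(variants)
  maf_cols <- grep("^maf_", names(variants), value = TRUE)
  n <- nrow(variants)
  skipped <- 0L
  rows <- vector("list", n)
  for (r in seq_len(n)) {
    row <- variants[r, , drop = FALSE]
    tx_id <- as.character(row$transcript_id)
    tx <- transcripts[[tx_id]]
    if (is.null(tx)) {
      warning("unknown transcript_id '", tx_id, "' at ", row$chrom, ":",
              row$pos, "; record skipped", call. = FALSE)
      skipped <- skipped + 1L
      next
    }
    mafs <- stats::setNames(as.numeric(row[1, maf_cols]),
                            sub("^maf_", "", maf_cols))
    v <- list(chrom = as.character(row$chrom), pos = as.integer(row$pos),
              ref = as.character(row$ref), alt = as.character(row$alt),
              gene_symbol = as.character(row$gene),
              transcript_id = tx_id,
              mafs = mafs,
              predictor_verdicts = c(
                pred1 = if ("pred1" %in% names(row))
                  as.character(row$pred1) else "unknown",
                pred2 = if ("pred2" %in% names(row))
                  as.character(row$pred2) else "unknown"),
              cdot = if ("cdot" %in% names(row))
                as.character(row$cdot) else NA_character_,
              hgvs_p = if ("hgvs_p" %in% names(row))
                as.character(row$hgvs_p) else NA_character_)
    cons <- call_consequence(v, tx)
    cl <- assign_class(v, cons, tx, maf_threshold = maf_threshold,
                       overrides = overrides,
                       rare_threshold = rare_threshold,
                       domain_mode = domain_mode)
    rows[[r]] <- data.frame(
      variant_id = if ("variant_id" %in% names(row))
        as.character(row$variant_id) else paste0("var", r),
      patient_id = if ("patient_id" %in% names(row))
        as.character(row$patient_id) else NA_character_,
      gene = v$gene_symbol, transcript_id = tx_id,
      chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
      cdot = v$cdot,
      category = cons$category,
      splice_detail = cons$splice_detail,
      cds_anchor = cons$cds_anchor,
      is_ptv = cl$is_ptv,
      iarc_class = cl$iarc_class,
      rationale = paste(cl$rationale, collapse = ";"),
      damaging_missense = cl$damaging_missense,
      note = cl$note,
      stringsAsFactors = FALSE)
  }
  classified <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(classified)) classified <- empty_classified()
  summary <- list(
    n_input = n,
    n_classified = nrow(classified),
    n_skipped = skipped,
    by_class = as.list(table(factor(classified$iarc_class, levels = 1:5))),
    by_gene = as.list(table(classified$gene)),
    n_ptv = sum(classified$is_ptv),
    n_damaging_missense = sum(classified$damaging_missense)
  )
  list(classified = classified, summary = summary)
}

empty_classified <- function() {
  data.frame(variant_id = character(), patient_id = character(),
             gene = character(), transcript_id = character(),
             chrom = character(), pos = integer(), ref = character(),
             alt = character(), cdot = character(), category = character(),
             splice_detail = character(), cds_anchor = integer(),
             is_ptv = logical(), iarc_class = integer(),
             rationale = character(), damaging_missense = logical(),
             note = character(), stringsAsFactors = FALSE)
}
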