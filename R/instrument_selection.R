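#' Restrict eQTL records to the cis window
#'
#' Keeps associations within 1 Mb of the transcription start site (inclusive
#' at both edges). Uses the \code{tss_distance} column when present; rows
#' with missing \code{tss_distance} fall back to \code{pos} against a
#' supplied per-gene TSS table.
#'
#' @param eqtls eQTL data.frame (see \code{\link{readEqtlTable}}).
#' @param window half-width of the cis window in base pairs.
#' @param tss optional data.frame with columns gene_id, tss.
#' @return the filtered data.frame.
#' @export
cisFilter <- function(eqtls, window = 1e6, tss = NULL) {
  d <- eqtls$tss_distance
  if (is.null(d)) d <- rep(NA_real_, nrow(eqtls))
  if (any(is.na(d))) {
    if (is.null(tss))
      stop("rows lack tss_distance and no TSS table was supplied", call. = FALSE)
    t <- stats::setNames(tss$tss, tss$gene_id)[eqtls$gene_id]
    d[is.na(d)] <- eqtls$pos[is.na(d)] - t[is.na(d)]
  }
  eqtls[abs(d) <= window, , drop = FALSE]
}

.empty_members <- function() {
  data.frame(variant_id = character(0), chrom = character(0),
             pos = numeric(0), effect_allele = character(0),
             other_allele = character(0), gene_id = character(0),
             tissue = character(0), beta_x = numeric(0), se_x = numeric(0),
             pvalue_x = numeric(0), eaf_x = numeric(0))
}

# canonical member columns carried through selection
.as_members <- function(df) {
  if (!nrow(df)) return(.empty_members())
  keep <- intersect(c("variant_id", "chrom", "pos", "effect_allele",
                      "other_allele", "gene_id", "tissue",
                      "beta_x", "se_x", "pvalue_x", "eaf_x"), names(df))
  out <- df[, keep, drop = FALSE]
  rownames(out) <- NULL
  out
}

.members_from_eqtl <- function(eqtls) {
  data.frame(variant_id = eqtls$variant_id, chrom = eqtls$chrom,
             pos = eqtls$pos, effect_allele = eqtls$effect_allele,
             other_allele = eqtls$other_allele, gene_id = eqtls$gene_id,
             tissue = eqtls$tissue, beta_x = eqtls$beta, se_x = eqtls$se,
             pvalue_x = eqtls$pvalue, eaf_x = eqtls$eaf,
             stringsAsFactors = FALSE)
}

# deterministic ordering used by every argmin: smallest p, then largest
# |beta_x|, then lexicographic tie-breaks
.rank_order <- function(m) {
  order(m$pvalue_x, -abs(m$beta_x), m$gene_id, m$tissue, m$variant_id)
}

# dedup by variant keeping the best-ranked record
.dedup_variants <- function(m) {
  m <- m[.rank_order(m), , drop = FALSE]
  m <- m[!duplicated(m$variant_id), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Select cross-tissue instruments for one gene
#'
#' Within each tissue the single most significant eligible cis-eQTL
#' (p below \code{p_threshold}, strict) is taken; the union over tissues is
#' then deduplicated by variant, keeping the statistics from the most
#' significant tissue. This mimics a cross-tissue overall gene-expression
#' exposure while maximizing instrument strength.
#'
#' @param eqtls cis-filtered eQTL records for a single gene.
#' @param p_threshold eQTL significance cutoff (default 1e-5).
#' @return an \linkS4class{InstrumentSet} with \code{grouping = "gene"};
#'   empty if no tissue has an eligible eQTL.
#' @export
selectGeneIVs <- function(eqtls, p_threshold = 1e-5) {
  gene <- unique(eqtls$gene_id)
  if (length(gene) > 1)
    stop("selectGeneIVs expects records for a single gene", call. = FALSE)
  m <- .members_from_eqtl(eqtls)
  m <- m[m$pvalue_x < p_threshold, , drop = FALSE]
  if (nrow(m)) {
    m <- m[.rank_order(m), , drop = FALSE]
    m <- m[!duplicated(m$tissue), , drop = FALSE]  # top hit per tissue
    m <- .dedup_variants(m)                        # cross-tissue dedup
  }
  new("InstrumentSet", grouping = "gene",
      label = if (length(gene)) gene else "", members = .as_members(m),
      clumped = FALSE)
}

#' Aggregate gene-level instruments into a pathway instrument set
#'
#' Takes the union of per-gene instrument sets (built by
#' \code{\link{selectGeneIVs}}) to mimic an aggregate pathway-level
#' expression effect, deduplicates variants shared between genes keeping the
#' smallest exposure p (ties: larger |beta|, then lexicographic gene id),
#' and applies LD clumping to the unclumped union so no independent variant
#' is lost to a per-gene pass.
#'
#' @param gene_sets list of gene-level \linkS4class{InstrumentSet}s.
#' @param ld an \linkS4class{LdReference}.
#' @param clump_r2 clumping threshold; retained pairs have r2 strictly below.
#' @param label pathway identifier for the returned set.
#' @return a clumped \linkS4class{InstrumentSet} with
#'   \code{grouping = "pathway"}.
#' @export
selectPathwayIVs <- function(gene_sets, ld, clump_r2 = 0.01,
                             label = "pathway") {
  members <- do.call(rbind, lapply(gene_sets, instrumentMembers))
  if (is.null(members) || !nrow(members)) {
    return(new("InstrumentSet", grouping = "pathway", label = label,
               members = .empty_members(), clumped = TRUE))
  }
  members <- .dedup_variants(members)
  s <- new("InstrumentSet", grouping = "pathway", label = label,
           members = members, clumped = FALSE)
  clumpInstruments(s, ld, clump_r2)
}

#' Select instruments within a single tissue
#'
#' Per gene, the most significant cis-eQTL within this tissue; union over
#' the pathway's genes, deduplicated by variant, then LD-clumped. One column
#' of the gene-by-tissue selection grid.
#'
#' @param eqtls cis-filtered eQTL records for all pathway genes in one tissue.
#' @param p_threshold eQTL significance cutoff.
#' @param ld an \linkS4class{LdReference}.
#' @param clump_r2 clumping threshold.
#' @return a clumped \linkS4class{InstrumentSet} with
#'   \code{grouping = "tissue"}.
#' @export
selectTissueIVs <- function(eqtls, p_threshold = 1e-5, ld, clump_r2 = 0.01) {
  tis <- unique(eqtls$tissue)
  if (length(tis) > 1)
    stop("selectTissueIVs expects records for a single tissue", call. = FALSE)
  m <- .members_from_eqtl(eqtls)
  m <- m[m$pvalue_x < p_threshold, , drop = FALSE]
  if (nrow(m)) {
    m <- m[.rank_order(m), , drop = FALSE]
    m <- m[!duplicated(m$gene_id), , drop = FALSE]  # top hit per gene
    m <- .dedup_variants(m)
  }
  s <- new("InstrumentSet", grouping = "tissue",
           label = if (length(tis)) tis else "", members = .as_members(m),
           clumped = FALSE)
  clumpInstruments(s, ld, clump_r2)
}

#' LD-based greedy clumping
#'
#' Sorts candidates by ascending exposure p-value and accepts each in turn
#' iff its r2 with every already-accepted variant is strictly below
#' \code{r2_threshold}. The retained set is pairwise independent at the
#' threshold and the survivor of any LD clique is its smallest-p member.
#'
#' @param candidates an \linkS4class{InstrumentSet}.
#' @param ld an \linkS4class{LdReference}.
#' @param r2_threshold independence threshold (default 0.01, strict).
#' @return the clumped \linkS4class{InstrumentSet}.
#' @export
clumpInstruments <- function(candidates, ld, r2_threshold = 0.01) {
  m <- instrumentMembers(candidates)
  if (nrow(m) > 1) {
    m <- m[.rank_order(m), , drop = FALSE]
    keep <- integer(0)
    for (i in seq_len(nrow(m))) {
      if (!length(keep)) { keep <- i; next }
      r2 <- ldR2(ld, m$variant_id[i], m$variant_id[keep], quiet = TRUE)
      if (all(r2 < r2_threshold)) keep <- c(keep, i)
    }
    m <- m[keep, , drop = FALSE]
    rownames(m) <- NULL
  }
  initialize(candidates, members = m, clumped = TRUE)
}

#' Find a proxy variant in the outcome GWAS
#'
#' When an instrument is absent from the outcome table, returns the outcome
#' variant in highest LD with it, provided r2 strictly exceeds
#' \code{r2_min}; ties are broken by the lexicographically smaller id.
#'
#' @param missing_id variant id absent from the outcome table.
#' @param outcome GWAS data.frame (see \code{\link{readGwasTable}}).
#' @param ld an \linkS4class{LdReference}.
#' @param r2_min minimum LD with the original instrument (default 0.8).
#' @return the proxy's variant id, or \code{NA_character_} if none qualifies.
#' @export
findProxy <- function(missing_id, outcome, ld, r2_min = 0.8) {
  ids <- setdiff(unique(outcome$variant_id), missing_id)
  if (!length(ids)) return(NA_character_)
  r2 <- ldR2(ld, missing_id, ids, quiet = TRUE)
  ok <- r2 > r2_min
  if (!any(ok)) return(NA_character_)
  ids <- ids[ok]; r2 <- r2[ok]
  ids <- ids[order(-r2, ids)]
  ids[1]
}

# classify the orientation of an outcome allele pair against the exposure's.
# returns flip = +1 (same orientation), -1 (swapped), or NA (unresolvable)
.allele_orientation <- function(EA, OA, ea, oa) {
  if (ea == EA && oa == OA) return(1)
  if (ea == OA && oa == EA) return(-1)
  cea <- .revcomp(ea); coa <- .revcomp(oa)
  if (cea == EA && coa == OA) return(1)   # strand flip only
  if (cea == OA && coa == EA) return(-1)  # strand flip + swap
  NA_real_
}

#' Harmonize exposure instruments against an outcome GWAS
#'
#' Matches instruments to the outcome table by variant id (substituting a
#' high-LD proxy via \code{\link{findProxy}} when one is absent and an LD
#' reference is supplied), aligns outcome effects to the exposure effect
#' allele (negating the outcome beta when alleles are swapped, allowing a
#' strand complement), and drops ambiguous records: palindromic variants
#' (A/T or C/G pairs) whose allele frequency on either side is missing or
#' inside \code{0.5 +/- palindromic_eaf_band}, and allele pairs that cannot
#' be reconciled by swap or complement. Every drop is itemized in the
#' \code{drops} attribute.
#'
#' For a proxy, the original variant's exposure statistics are retained and
#' paired with the proxy's outcome statistics; the proxy's sign is phased by
#' the LD panel's signed dosage correlation when available, otherwise the
#' proxy is used only if non-palindromic and its allele pair matches the
#' original's by identity or complement.
#'
#' @param exposure an \linkS4class{InstrumentSet} or its members data.frame.
#' @param outcome GWAS data.frame (one row per variant; duplicated ids are a
#'   fatal data error).
#' @param ld optional \linkS4class{LdReference} enabling proxy substitution.
#' @param palindromic_eaf_band half-width of the ambiguous-frequency band
#'   around 0.5 (default 0.08).
#' @param proxy_r2 minimum LD for proxy substitution (default 0.8, strict).
#' @return data.frame with one row per usable instrument: variant_id,
#'   effect_allele, other_allele, gene_id, tissue, b_X, se_X, pvalue_X, b_Y,
#'   se_Y, pvalue_Y, proxy_of; dropped instruments in \code{attr(., "drops")}.
#' @export
harmonizeInstruments <- function(exposure, outcome, ld = NULL,
                                 palindromic_eaf_band = 0.08,
                                 proxy_r2 = 0.8) {
  m <- if (is(exposure, "InstrumentSet")) instrumentMembers(exposure) else exposure
  if (anyDuplicated(outcome$variant_id))
    stop("duplicate variant_id in outcome table", call. = FALSE)
  o <- outcome
  rownames(o) <- o$variant_id

  rows <- vector("list", nrow(m))
  drops <- list()
  drop <- function(id, reason)
    drops[[length(drops) + 1]] <<- data.frame(variant_id = id, reason = reason)

  for (i in seq_len(nrow(m))) {
    x <- m[i, ]
    proxy_of <- ""
    flip_extra <- 1
    if (x$variant_id %in% o$variant_id) {
      y <- o[x$variant_id, ]
    } else if (!is.null(ld)) {
      pid <- findProxy(x$variant_id, o, ld, r2_min = proxy_r2)
      if (is.na(pid)) { drop(x$variant_id, "absent_from_outcome_no_proxy"); next }
      y <- o[pid, ]
      proxy_of <- x$variant_id
      s <- .ld_sign(ld, x$variant_id, pid)
      if (!is.na(s) && s != 0) {
        # phase known: orient the proxy's outcome beta by the dosage
        # correlation sign and skip the allele comparison (different variant)
        flip_extra <- s
        b_Y <- flip_extra * y$beta
        rows[[i]] <- data.frame(
          variant_id = y$variant_id, effect_allele = x$effect_allele,
          other_allele = x$other_allele, gene_id = x$gene_id,
          tissue = x$tissue, b_X = x$beta_x, se_X = x$se_x,
          pvalue_X = x$pvalue_x, b_Y = b_Y, se_Y = y$se,
          pvalue_Y = y$pvalue, proxy_of = proxy_of)
        next
      }
      if (.is_palindromic(y$effect_allele, y$other_allele)) {
        drop(x$variant_id, "proxy_palindromic_phase_unknown"); next
      }
      # fall through to allele-pair comparison against the original
    } else {
      drop(x$variant_id, "absent_from_outcome"); next
    }

    flip <- .allele_orientation(x$effect_allele, x$other_allele,
                                y$effect_allele, y$other_allele)
    if (is.na(flip)) { drop(x$variant_id, "allele_mismatch"); next }

    if (.is_palindromic(x$effect_allele, x$other_allele) && proxy_of == "") {
      eaf_x <- if ("eaf_x" %in% names(x)) x$eaf_x else NA_real_
      eaf_y <- y$eaf
      amb <- function(f) is.na(f) | abs(f - 0.5) <= palindromic_eaf_band
      if (amb(eaf_x) || amb(eaf_y)) {
        drop(x$variant_id, "palindromic_ambiguous_eaf"); next
      }
      # for a palindromic pair swap and strand flip are indistinguishable
      # from the alleles alone; use frequency concordance instead
      eaf_y_o <- if (flip == 1) eaf_y else 1 - eaf_y
      flip <- if ((eaf_x - 0.5) * (eaf_y_o - 0.5) > 0) flip else -flip
    }

    b_Y <- flip * y$beta
    rows[[i]] <- data.frame(
      variant_id = x$variant_id, effect_allele = x$effect_allele,
      other_allele = x$other_allele, gene_id = x$gene_id, tissue = x$tissue,
      b_X = x$beta_x, se_X = x$se_x, pvalue_X = x$pvalue_x,
      b_Y = b_Y, se_Y = y$se, pvalue_Y = y$pvalue, proxy_of = proxy_of)
  }

  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(variant_id = character(0), effect_allele = character(0),
                      other_allele = character(0), gene_id = character(0),
                      tissue = character(0), b_X = numeric(0),
                      se_X = numeric(0), pvalue_X = numeric(0),
                      b_Y = numeric(0), se_Y = numeric(0),
                      pvalue_Y = numeric(0), proxy_of = character(0))
  rownames(out) <- NULL
  attr(out, "drops") <- if (length(drops)) do.call(rbind, drops) else
    data.frame(variant_id = character(0), reason = character(0))
  out
}
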