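#' @importFrom data.table fread fwrite as.data.table setnames
NULL

.EQTL_REQUIRED <- c("gene_id", "tissue", "variant_id", "chrom", "pos",
                    "effect_allele", "other_allele", "beta", "se")
.EQTL_OPTIONAL <- c("pvalue", "eaf", "tss_distance")
.GWAS_REQUIRED <- c("variant_id", "chrom", "pos", "effect_allele",
                    "other_allele", "beta", "se")
.GWAS_OPTIONAL <- c("pvalue", "eaf", "n")

# apply a dialect (canonical_name = file_column) and check requirements
.apply_dialect <- function(dt, dialect, required, what) {
  if (!is.null(dialect)) {
    hit <- dialect[dialect %in% names(dt)]
    setnames(dt, old = unname(hit), new = names(hit))
  }
  miss <- setdiff(required, names(dt))
  if (length(miss))
    stop(sprintf("%s table lacks required column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  dt
}

.check_alleles <- function(ea, oa) {
  ok <- !is.na(ea) & !is.na(oa) & nzchar(ea) & nzchar(oa) &
    grepl("^[ACGT]+$", ea) & grepl("^[ACGT]+$", oa) & ea != oa
  ok
}

# fill missing p from a normal approximation; never overwrite a stored p
.fill_pvalue <- function(dt) {
  if (!"pvalue" %in% names(dt)) dt$pvalue <- NA_real_
  idx <- is.na(dt$pvalue) & !is.na(dt$beta) & !is.na(dt$se) & dt$se > 0
  if (any(idx)) dt$pvalue[idx] <- .z_pvalue(dt$beta[idx], dt$se[idx])
  dt
}

.reject <- function(df, ok, reasons) {
  rej <- data.frame(row = which(!ok), reason = reasons[!ok],
                    stringsAsFactors = FALSE)
  out <- df[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rej
  out
}

#' Rows rejected by a reader
#'
#' Readers validate every row against the type invariants and drop offenders;
#' the dropped rows, with their 1-based row numbers and a reason, are attached
#' to the returned table and retrieved with this accessor.
#'
#' @param x a table returned by \code{\link{readEqtlTable}} or
#'   \code{\link{readGwasTable}}.
#' @return data.frame with columns \code{row} and \code{reason}.
#' @export
rejectedRows <- function(x) {
  r <- attr(x, "rejected")
  if (is.null(r)) data.frame(row = integer(0), reason = character(0)) else r
}

#' GTEx-style column dialect for eQTL tables
#'
#' Column-name mapping for tables exported in the GTEx association format
#' (\code{slope}/\code{slope_se}/\code{pval_nominal}), usable as the
#' \code{dialect} argument of \code{\link{readEqtlTable}}.
#'
#' @return named character vector, canonical name = file column name.
#' @export
gtexDialect <- function() {
  c(beta = "slope", se = "slope_se", pvalue = "pval_nominal",
    eaf = "maf", tss_distance = "tss_distance")
}

#' Read a cis-eQTL summary-statistics table
#'
#' Reads a (possibly gzipped) TSV of per-variant, per-gene, per-tissue
#' expression association statistics and validates every row. Canonical
#' columns are \code{gene_id, tissue, variant_id, chrom, pos, effect_allele,
#' other_allele, beta, se, pvalue, eaf, tss_distance}; other naming schemes
#' are mapped through \code{dialect}. A missing p-value is recomputed as the
#' two-sided normal tail of \code{beta/se}; a stored p-value is never
#' overwritten. Rows violating the invariants (\code{se > 0}, p in (0, 1],
#' valid distinct alleles, \code{pos >= 1}, eaf in [0, 1]) are dropped and
#' reported via \code{\link{rejectedRows}}.
#'
#' @param path file path (TSV, optionally gzip-compressed).
#' @param dialect optional named character vector mapping canonical column
#'   names to the file's column names, e.g. \code{gtexDialect()}.
#' @param verbose report accepted/rejected counts.
#' @return data.frame of accepted records with a \code{rejected} attribute.
#' @export
readEqtlTable <- function(path, dialect = NULL, verbose = TRUE) {
  if (!file.exists(path)) stop("cannot read eQTL table: ", path, call. = FALSE)
  dt <- fread(path, sep = "\t", header = TRUE, data.table = TRUE)
  dt <- .apply_dialect(dt, dialect, .EQTL_REQUIRED, "eQTL")
  dt <- as.data.frame(.fill_pvalue(dt))
  if (!"eaf" %in% names(dt)) dt$eaf <- NA_real_
  if (!"tss_distance" %in% names(dt)) dt$tss_distance <- NA_real_
  dt$effect_allele <- toupper(as.character(dt$effect_allele))
  dt$other_allele <- toupper(as.character(dt$other_allele))

  reasons <- rep(NA_character_, nrow(dt))
  bad_all <- !.check_alleles(dt$effect_allele, dt$other_allele)
  reasons[bad_all] <- "invalid or identical alleles"
  bad_pos <- is.na(dt$pos) | dt$pos < 1
  reasons[bad_pos & is.na(reasons)] <- "pos < 1 or missing"
  bad_se <- is.na(dt$se) | dt$se <= 0
  reasons[bad_se & is.na(reasons)] <- "se <= 0 or missing"
  bad_p <- is.na(dt$pvalue) | dt$pvalue <= 0 | dt$pvalue > 1
  reasons[bad_p & is.na(reasons)] <- "pvalue outside (0, 1]"
  bad_eaf <- !is.na(dt$eaf) & (dt$eaf < 0 | dt$eaf > 1)
  reasons[bad_eaf & is.na(reasons)] <- "eaf outside [0, 1]"
  bad_tss <- !is.na(dt$tss_distance) & !is.finite(dt$tss_distance)
  reasons[bad_tss & is.na(reasons)] <- "non-finite tss_distance"

  out <- .reject(dt[, c(.EQTL_REQUIRED, .EQTL_OPTIONAL)], is.na(reasons), reasons)
  .msg("readEqtlTable: %d accepted, %d rejected", nrow(out),
       nrow(rejectedRows(out)), verbose = verbose)
  out
}

#' Read an outcome GWAS summary-statistics table
#'
#' Same contract as \code{\link{readEqtlTable}} for per-variant outcome
#' association statistics; canonical columns \code{variant_id, chrom, pos,
#' effect_allele, other_allele, beta, se, pvalue, eaf, n}.
#'
#' @inheritParams readEqtlTable
#' @return data.frame of accepted records with a \code{rejected} attribute.
#' @export
readGwasTable <- function(path, dialect = NULL, verbose = TRUE) {
  if (!file.exists(path)) stop("cannot read GWAS table: ", path, call. = FALSE)
  dt <- fread(path, sep = "\t", header = TRUE, data.table = TRUE)
  dt <- .apply_dialect(dt, dialect, .GWAS_REQUIRED, "GWAS")
  dt <- as.data.frame(.fill_pvalue(dt))
  if (!"eaf" %in% names(dt)) dt$eaf <- NA_real_
  if (!"n" %in% names(dt)) dt$n <- NA_integer_
  dt$effect_allele <- toupper(as.character(dt$effect_allele))
  dt$other_allele <- toupper(as.character(dt$other_allele))

  reasons <- rep(NA_character_, nrow(dt))
  bad_all <- !.check_alleles(dt$effect_allele, dt$other_allele)
  reasons[bad_all] <- "invalid or identical alleles"
  bad_se <- is.na(dt$se) | dt$se <= 0
  reasons[bad_se & is.na(reasons)] <- "se <= 0 or missing"
  bad_p <- is.na(dt$pvalue) | dt$pvalue <= 0 | dt$pvalue > 1
  reasons[bad_p & is.na(reasons)] <- "pvalue outside (0, 1]"
  bad_eaf <- !is.na(dt$eaf) & (dt$eaf < 0 | dt$eaf > 1)
  reasons[bad_eaf & is.na(reasons)] <- "eaf outside [0, 1]"
  bad_n <- !is.na(dt$n) & dt$n < 1
  reasons[bad_n & is.na(reasons)] <- "n < 1"

  out <- .reject(dt[, c(.GWAS_REQUIRED, .GWAS_OPTIONAL)], is.na(reasons), reasons)
  .msg("readGwasTable: %d accepted, %d rejected", nrow(out),
       nrow(rejectedRows(out)), verbose = verbose)
  out
}

#' Read gene sets in GMT format
#'
#' Parses standard MSigDB-style GMT lines
#' (\code{name<TAB>description<TAB>gene1<TAB>gene2...}). Duplicate genes
#' within a line are deduplicated preserving first occurrence; lines with
#' fewer than three fields, or with no genes after deduplication, are
#' rejected with their line number (as a warning).
#'
#' @param path GMT file path.
#' @return named list of pathway definitions, each a list with
#'   \code{pathway_id}, \code{name} and \code{gene_ids}.
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("cannot read GMT file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      warning(sprintf("GMT line %d has fewer than 3 fields; rejected", i),
              call. = FALSE)
      next
    }
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) {
      warning(sprintf("GMT line %d has an empty gene list; rejected", i),
              call. = FALSE)
      next
    }
    out[[f[1]]] <- list(pathway_id = f[1], name = f[2], gene_ids = genes)
  }
  out
}

#' Write gene sets to a GMT file
#'
#' @param pathways named list as returned by \code{\link{readGmt}}.
#' @param path output path.
#' @export
writeGmt <- function(pathways, path) {
  lines <- vapply(pathways, function(p)
    paste(c(p$pathway_id, p$name, p$gene_ids), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Build an LD reference panel
#'
#' From either a pairwise \code{(id1, id2, r2)} table or a sample-by-variant
#' dosage matrix (dosages in [0, 2], column names = variant ids). From
#' genotypes, r2 is the squared Pearson correlation of dosage columns within
#' each chromosome, and the signed correlation is kept for proxy phasing.
#' A monomorphic variant has r2 defined as 0 with all partners (warning).
#'
#' @param source data.frame with columns id1, id2, r2 — or a numeric matrix
#'   of dosages.
#' @param variant_info optional data.frame with columns variant_id and chrom;
#'   enables the cross-chromosome shortcut (r2 = 0 by convention).
#' @return an \linkS4class{LdReference}.
#' @export
buildLdReference <- function(source, variant_info = NULL) {
  env <- new.env(parent = emptyenv(), hash = TRUE)
  chrom <- character(0)
  if (!is.null(variant_info)) {
    chrom <- stats::setNames(as.character(variant_info$chrom),
                             variant_info$variant_id)
  }
  store <- function(a, b, r2, r = NA_real_) {
    k <- if (a < b) paste(a, b, sep = "\r") else paste(b, a, sep = "\r")
    assign(k, c(r2 = r2, r = r), envir = env)
  }
  if (is.matrix(source)) {
    if (is.null(colnames(source)))
      stop("genotype matrix needs variant ids as column names", call. = FALSE)
    if (length(source) && (min(source, na.rm = TRUE) < 0 ||
                           max(source, na.rm = TRUE) > 2))
      stop("dosages must lie in [0, 2]", call. = FALSE)
    ids <- colnames(source)
    sds <- apply(source, 2, stats::sd)
    mono <- sds == 0 | is.na(sds)
    if (any(mono))
      warning("monomorphic variant(s): ", paste(ids[mono], collapse = ", "),
              "; their r2 is defined as 0", call. = FALSE)
    grp <- if (length(chrom)) chrom[ids] else rep("1", length(ids))
    grp[is.na(grp)] <- "1"
    for (g in unique(grp)) {
      cols <- which(grp == g)
      if (length(cols) < 2) next
      cc <- suppressWarnings(stats::cor(source[, cols, drop = FALSE]))
      for (i in seq_along(cols)[-length(cols)]) {
        for (j in (i + 1):length(cols)) {
          r <- cc[i, j]
          if (is.na(r)) r <- 0   # monomorphic partner
          store(ids[cols[i]], ids[cols[j]], r^2, r)
        }
      }
    }
    if (!length(chrom))
      chrom <- stats::setNames(grp, ids)
    return(new("LdReference", pairs = env, chrom = chrom,
               provenance = "genotypes"))
  }
  if (!all(c("id1", "id2", "r2") %in% names(source)))
    stop("pairwise LD source needs columns id1, id2, r2", call. = FALSE)
  if (any(source$r2 < 0 | source$r2 > 1))
    stop("r2 values must lie in [0, 1]", call. = FALSE)
  for (i in seq_len(nrow(source)))
    store(source$id1[i], source$id2[i], source$r2[i])
  new("LdReference", pairs = env, chrom = chrom, provenance = "pairwise_table")
}

.ld_lookup <- function(ld, a, b, quiet = FALSE) {
  if (a == b) return(c(r2 = 1, r = 1))
  ca <- if (a %in% names(ld@chrom)) ld@chrom[[a]] else NA_character_
  cb <- if (b %in% names(ld@chrom)) ld@chrom[[b]] else NA_character_
  if (!is.na(ca) && !is.na(cb) && ca != cb) return(c(r2 = 0, r = 0))
  k <- if (a < b) paste(a, b, sep = "\r") else paste(b, a, sep = "\r")
  if (exists(k, envir = ld@pairs, inherits = FALSE))
    return(get(k, envir = ld@pairs, inherits = FALSE))
  if (!quiet)
    warning(sprintf("unknown same-chromosome pair (%s, %s); assuming r2 = 0",
                    a, b), call. = FALSE)
  c(r2 = 0, r = NA_real_)
}

#' Query pairwise LD
#'
#' @param ld an \linkS4class{LdReference}.
#' @param a,b variant ids (recycled to a common length).
#' @param quiet suppress the unknown same-chromosome pair warning.
#' @return numeric vector of r2 values in [0, 1].
#' @export
ldR2 <- function(ld, a, b, quiet = FALSE) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  vapply(seq_len(n), function(i) .ld_lookup(ld, a[i], b[i], quiet)[["r2"]],
         numeric(1))
}

# signed dosage correlation where available (genotype provenance), else NA
.ld_sign <- function(ld, a, b) {
  r <- .ld_lookup(ld, a, b, quiet = TRUE)[["r"]]
  if (is.na(r)) NA_real_ else sign(r)
}

.RESULT_LEAD <- c("exposure", "outcome", "method", "nsnp", "beta", "se", "pvalue")

#' Write an MR results table
#'
#' TSV with the lead columns \code{exposure, outcome, method, nsnp, beta,
#' se, pvalue} followed by whatever diagnostic columns are present, in a
#' deterministic order. Values round-trip through
#' \code{\link{readResultsTable}} to at least 12 significant digits.
#'
#' @param rows data.frame of result rows (may be empty).
#' @param path output TSV path.
#' @export
writeResultsTable <- function(rows, path) {
  rows <- as.data.frame(rows)
  for (col in setdiff(.RESULT_LEAD, names(rows)))
    rows[[col]] <- if (col == "nsnp") integer(0)[seq_len(nrow(rows))] else
      rep(NA, nrow(rows))
  extra <- sort(setdiff(names(rows), .RESULT_LEAD))
  rows <- rows[, c(.RESULT_LEAD, extra), drop = FALSE]
  fwrite(rows, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read back an MR results table
#'
#' @param path TSV written by \code{\link{writeResultsTable}}.
#' @return data.frame.
#' @export
readResultsTable <- function(path) {
  as.data.frame(fread(path, sep = "\t", header = TRUE, na.strings = "NA"))
}
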