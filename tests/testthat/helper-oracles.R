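# Independent oracles and small fixture builders used across the suite.
# Oracles deliberately avoid the package's own code paths: selection uses
# exhaustive argmin scans, regression fits go through stats::lm, and LD
# checks enumerate pairs directly.

# random eQTL table over a gene x tissue x SNP grid
random_eqtl_grid <- function(n_genes, n_tissues, n_snps, seed) {
  set.seed(seed)
  grid <- expand.grid(gene = sprintf("G%d", seq_len(n_genes)),
                      tissue = sprintf("T%d", seq_len(n_tissues)),
                      snp = sprintf("rs%d", seq_len(n_snps)),
                      stringsAsFactors = FALSE)
  data.frame(
    gene_id = grid$gene, tissue = grid$tissue, variant_id = grid$snp,
    chrom = "chr1", pos = match(grid$snp, sprintf("rs%d", seq_len(n_snps))),
    effect_allele = "A", other_allele = "G",
    beta = stats::rnorm(nrow(grid), 0, 0.4),
    se = stats::runif(nrow(grid), 0.03, 0.1),
    pvalue = stats::runif(nrow(grid))^4,   # skew small so some pass 1e-2
    eaf = stats::runif(nrow(grid), 0.05, 0.95),
    tss_distance = 0, stringsAsFactors = FALSE)
}

# exhaustive cross-tissue selection for one gene: argmin p per tissue,
# then per-variant argmin p over the selected records
oracle_gene_selection <- function(eqtls, p_threshold) {
  e <- eqtls[eqtls$pvalue < p_threshold, , drop = FALSE]
  if (!nrow(e)) return(character(0))
  tops <- do.call(rbind, lapply(split(e, e$tissue), function(t)
    t[order(t$pvalue, -abs(t$beta), t$variant_id)[1], , drop = FALSE]))
  best <- do.call(rbind, lapply(split(tops, tops$variant_id), function(v)
    v[order(v$pvalue)[1], , drop = FALSE]))
  best[order(best$pvalue), c("variant_id", "tissue", "pvalue")]
}

# per-gene argmin within one tissue (column-wise selection)
oracle_tissue_selection <- function(eqtls, p_threshold) {
  e <- eqtls[eqtls$pvalue < p_threshold, , drop = FALSE]
  if (!nrow(e)) return(character(0))
  tops <- do.call(rbind, lapply(split(e, e$gene_id), function(g)
    g[order(g$pvalue, -abs(g$beta), g$variant_id)[1], , drop = FALSE]))
  unique(tops$variant_id)
}

# small instrument set wrapper around a members table
make_iset <- function(members, grouping = "pathway", label = "PW",
                      clumped = FALSE) {
  new("InstrumentSet", grouping = grouping, label = label,
      members = members, clumped = clumped)
}

members_frame <- function(variant_id, pvalue_x,
                          beta_x = rep(0.3, length(variant_id)),
                          gene_id = rep("G1", length(variant_id)),
                          tissue = rep("T1", length(variant_id)),
                          chrom = rep("chr1", length(variant_id))) {
  data.frame(variant_id = variant_id, chrom = chrom,
             pos = seq_along(variant_id), effect_allele = "A",
             other_allele = "G", gene_id = gene_id, tissue = tissue,
             beta_x = beta_x, se_x = 0.05, pvalue_x = pvalue_x,
             eaf_x = 0.3, stringsAsFactors = FALSE)
}

# LD reference from an explicit pairwise list (chrom optional)
ld_from_pairs <- function(id1, id2, r2, chrom_map = NULL) {
  vi <- if (!is.null(chrom_map))
    data.frame(variant_id = names(chrom_map), chrom = unname(chrom_map))
  buildLdReference(data.frame(id1 = id1, id2 = id2, r2 = r2), vi)
}

# connected components of the LD graph at a threshold; used to check the
# smallest-p-per-clique clumping property
ld_components <- function(ids, r2mat, thr) {
  n <- length(ids)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && r2mat[i, j] >= thr && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  split(ids, comp)
}

random_harmonized <- function(J, seed, theta = 0.1, se_y = 0.05) {
  set.seed(seed)
  bx <- stats::rnorm(J, 0, 0.4)
  data.frame(variant_id = sprintf("rs%d", seq_len(J)),
             b_X = bx, se_X = stats::runif(J, 0.02, 0.08),
             b_Y = theta * bx + stats::rnorm(J, 0, se_y),
             se_Y = rep(se_y, J), stringsAsFactors = FALSE)
}

write_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "NA")
  path
}

fixture_gwas_names <- function(fx)
  grep("^gwas_", names(fx), value = TRUE)

fixture_config <- function(fx, ...) {
  gw <- lapply(fixture_gwas_names(fx), function(n) fx[[n]])
  names(gw) <- sub("^gwas_", "", fixture_gwas_names(fx))
  runConfig(eqtl = fx$eqtl, gwas = gw, pathways = fx$gmt, ld = fx$ld,
            variant_info = fx$variant_info, ...)
}
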