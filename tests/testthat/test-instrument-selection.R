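test_that("cross-tissue gene selection carries the most significant tissue's statistics", {
  # the same SNP tops two tissues; the stronger tissue's record must win
  e <- rbind(
    data.frame(gene_id = "G1", tissue = "tissue_1", variant_id = "SNP_11",
               chrom = "chr1", pos = 11, effect_allele = "A",
               other_allele = "G", beta = 0.5, se = 0.08, pvalue = 1e-9,
               eaf = 0.3, tss_distance = 0),
    data.frame(gene_id = "G1", tissue = "tissue_2", variant_id = "SNP_12",
               chrom = "chr1", pos = 12, effect_allele = "A",
               other_allele = "G", beta = 0.3, se = 0.08, pvalue = 1e-6,
               eaf = 0.3, tss_distance = 0),
    data.frame(gene_id = "G1", tissue = "tissue_3", variant_id = "SNP_11",
               chrom = "chr1", pos = 11, effect_allele = "A",
               other_allele = "G", beta = 0.4, se = 0.08, pvalue = 1e-7,
               eaf = 0.3, tss_distance = 0))
  s <- selectGeneIVs(e)
  m <- instrumentMembers(s)
  expect_equal(sort(m$variant_id), c("SNP_11", "SNP_12"))
  sel <- m[m$variant_id == "SNP_11", ]
  expect_equal(sel$tissue, "tissue_1")
  expect_equal(sel$pvalue_x, 1e-9)
  expect_equal(sel$beta_x, 0.5)
})

test_that("a single eligible eQTL yields a singleton set; none yields an empty set", {
  e <- data.frame(gene_id = "G1", tissue = "T1", variant_id = "rs1",
                  chrom = "chr1", pos = 1, effect_allele = "A",
                  other_allele = "G", beta = 0.4, se = 0.08, pvalue = 1e-6,
                  eaf = 0.3, tss_distance = 0)
  expect_equal(nInstruments(selectGeneIVs(e)), 1)
  e$pvalue <- 1e-4
  expect_equal(nInstruments(selectGeneIVs(e)), 0)
  # strict threshold: p exactly at the cutoff is not eligible
  e$pvalue <- 1e-5
  expect_equal(nInstruments(selectGeneIVs(e)), 0)
})

test_that("gene and tissue selection agree with exhaustive argmin oracles", {
  thr <- 1e-2   # lenient so random tables have eligible rows
  for (seed in 1:20) {
    e <- random_eqtl_grid(n_genes = 5, n_tissues = 6, n_snps = 10, seed = seed)
    for (g in unique(e$gene_id)) {
      sub <- e[e$gene_id == g, ]
      got <- instrumentMembers(selectGeneIVs(sub, p_threshold = thr))
      want <- oracle_gene_selection(sub, thr)
      if (is.character(want)) {
        expect_equal(nrow(got), 0)
      } else {
        expect_setequal(got$variant_id, want$variant_id)
        # carried statistics come from the most significant tissue
        m <- merge(got, want, by = "variant_id")
        expect_equal(m$pvalue_x, m$pvalue)
      }
    }
    for (t in unique(e$tissue)) {
      sub <- e[e$tissue == t, ]
      ld0 <- buildLdReference(data.frame(id1 = "x", id2 = "y", r2 = 0))
      got <- instrumentMembers(
        selectTissueIVs(sub, p_threshold = thr, ld = ld0, clump_r2 = 2))
      want <- oracle_tissue_selection(sub, thr)
      if (is.character(want) && !length(want)) {
        expect_equal(nrow(got), 0)
      } else {
        expect_setequal(got$variant_id, want)
      }
    }
  }
})

test_that("pathway union dedups shared instruments keeping the smallest p", {
  g1 <- make_iset(members_frame(c("rs1", "rs2", "rs3"), c(1e-8, 1e-7, 1e-6)),
                  grouping = "gene", label = "G1")
  g2 <- make_iset(members_frame(c("rs4", "rs5"), c(1e-9, 1e-6),
                                gene_id = rep("G2", 2)),
                  grouping = "gene", label = "G2")
  ld0 <- ld_from_pairs("rs1", "rs2", 0,
                       chrom_map = setNames(rep("chr1", 5),
                                            sprintf("rs%d", 1:5)))
  pw <- selectPathwayIVs(list(g1, g2), ld0, clump_r2 = 2)
  expect_equal(nInstruments(pw), 5)
  expect_true(isClumped(pw))

  shared <- make_iset(members_frame("rs1", 1e-6, gene_id = "G2"),
                      grouping = "gene", label = "G2")
  pw2 <- selectPathwayIVs(list(g1, shared), ld0, clump_r2 = 2)
  m <- instrumentMembers(pw2)
  expect_equal(sum(m$variant_id == "rs1"), 1)
  expect_equal(m$gene_id[m$variant_id == "rs1"], "G1")  # p = 1e-8 wins
  expect_equal(m$pvalue_x[m$variant_id == "rs1"], 1e-8)
})

test_that("greedy clumping keeps the declared set on the worked example", {
  mem <- members_frame(c("s1", "s2", "s3"), c(1e-8, 1e-7, 1e-6))
  ld <- ld_from_pairs(c("s1", "s1", "s2"), c("s2", "s3", "s3"),
                      c(0.5, 0.001, 0.002),
                      chrom_map = c(s1 = "chr1", s2 = "chr1", s3 = "chr1"))
  got <- instrumentMembers(clumpInstruments(make_iset(mem), ld, 0.01))
  expect_equal(got$variant_id, c("s1", "s3"))

  # all pairwise zero: everything retained
  ld0 <- ld_from_pairs(c("s1", "s1", "s2"), c("s2", "s3", "s3"), c(0, 0, 0),
                       chrom_map = c(s1 = "chr1", s2 = "chr1", s3 = "chr1"))
  expect_equal(nInstruments(clumpInstruments(make_iset(mem), ld0, 0.01)), 3)

  # perfect LD: smaller-p survivor only
  mem2 <- members_frame(c("a", "b"), c(1e-6, 1e-9))
  ld1 <- ld_from_pairs("a", "b", 1, chrom_map = c(a = "chr1", b = "chr1"))
  got2 <- instrumentMembers(clumpInstruments(make_iset(mem2), ld1, 0.01))
  expect_equal(got2$variant_id, "b")
})

test_that("clumping is a subset operation, idempotent, pairwise independent, and keeps each LD component's smallest-p member", {
  thr <- 0.1
  for (seed in 1:15) {
    set.seed(seed)
    n <- sample(3:8, 1)
    ids <- sprintf("v%d", seq_len(n))
    r2m <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      r2m[i, j] <- r2m[j, i] <- sample(c(0, 0.05, 0.3, 0.9), 1,
                                       prob = c(0.5, 0.2, 0.2, 0.1))
    diag(r2m) <- 1
    pr <- which(upper.tri(r2m), arr.ind = TRUE)
    ld <- ld_from_pairs(ids[pr[, 1]], ids[pr[, 2]], r2m[pr],
                        chrom_map = setNames(rep("chr1", n), ids))
    mem <- members_frame(ids, runif(n)^3)
    cl <- clumpInstruments(make_iset(mem), ld, thr)
    got <- instrumentMembers(cl)

    expect_true(all(got$variant_id %in% mem$variant_id))
    # pairwise independence at the threshold
    if (nrow(got) > 1) {
      for (i in seq_len(nrow(got) - 1)) for (j in (i + 1):nrow(got))
        expect_lt(r2m[got$variant_id[i], got$variant_id[j]], thr)
    }
    # re-clumping a clumped set is the identity
    re <- instrumentMembers(clumpInstruments(cl, ld, thr))
    expect_equal(re, got)
    # the smallest-p member of every LD component survives
    comps <- ld_components(ids, r2m, thr)
    for (cc in comps) {
      best <- cc[which.min(mem$pvalue_x[match(cc, mem$variant_id)])]
      expect_true(best %in% got$variant_id)
    }
  }
})

test_that("proxy lookup applies the strict r2 rule, argmax and the lexicographic tie-break", {
  out <- data.frame(variant_id = c("p1", "p2", "p3"), chrom = "chr1",
                    pos = 1:3, effect_allele = "A", other_allele = "G",
                    beta = 0.1, se = 0.05, pvalue = 0.5, eaf = 0.4, n = 100L)
  cm <- c(m = "chr1", p1 = "chr1", p2 = "chr1", p3 = "chr1")
  ld <- ld_from_pairs(rep("m", 3), c("p1", "p2", "p3"),
                      c(0.95, 0.85, 0.2), chrom_map = cm)
  expect_equal(findProxy("m", out, ld), "p1")

  ld2 <- ld_from_pairs(rep("m", 3), c("p1", "p2", "p3"),
                       c(0.79, 0.5, 0.2), chrom_map = cm)
  expect_true(is.na(findProxy("m", out, ld2)))
  # boundary is strict: r2 exactly 0.8 does not qualify
  ld3 <- ld_from_pairs("m", "p1", 0.8, chrom_map = cm)
  expect_true(is.na(findProxy("m", out, ld3)))

  ld4 <- ld_from_pairs(rep("m", 2), c("p2", "p1"), c(0.9, 0.9), chrom_map = cm)
  expect_equal(findProxy("m", out, ld4), "p1")
})

gwas_row <- function(id, ea, oa, beta, eaf = 0.3) {
  data.frame(variant_id = id, chrom = "chr1", pos = 1, effect_allele = ea,
             other_allele = oa, beta = beta, se = 0.05, pvalue = 0.5,
             eaf = eaf, n = 100L, stringsAsFactors = FALSE)
}

test_that("harmonization resolves all eight allele orientations per the truth table", {
  ex <- members_frame("rs1", 1e-8)  # exposure alleles A/G, beta_x 0.3
  cases <- list(
    list(ea = "A", oa = "G", flip = +1),   # identical
    list(ea = "G", oa = "A", flip = -1),   # swapped
    list(ea = "T", oa = "C", flip = +1),   # strand complement
    list(ea = "C", oa = "T", flip = -1),   # complement + swap
    list(ea = "A", oa = "C", flip = NA),   # half-match -> unresolvable
    list(ea = "T", oa = "G", flip = NA),   # complement half-match
    list(ea = "C", oa = "G", flip = NA),   # different pair entirely
    list(ea = "A", oa = "T", flip = NA))   # palindromic pair != exposure's
  for (cs in cases) {
    out <- gwas_row("rs1", cs$ea, cs$oa, beta = 0.05)
    h <- harmonizeInstruments(make_iset(ex), out)
    if (is.na(cs$flip)) {
      expect_equal(nrow(h), 0)
      expect_equal(attr(h, "drops")$reason, "allele_mismatch")
    } else {
      expect_equal(nrow(h), 1)
      expect_equal(h$b_Y, cs$flip * 0.05)
    }
  }
})

test_that("palindromic instruments are dropped in the ambiguous band and aligned by frequency outside it", {
  ex <- members_frame("rs1", 1e-8)
  ex$effect_allele <- "A"; ex$other_allele <- "T"; ex$eaf_x <- 0.2
  # ambiguous frequency: dropped
  h <- harmonizeInstruments(make_iset(ex), gwas_row("rs1", "A", "T", 0.05, eaf = 0.5))
  expect_equal(nrow(h), 0)
  expect_equal(attr(h, "drops")$reason, "palindromic_ambiguous_eaf")
  # missing frequency: dropped
  h <- harmonizeInstruments(make_iset(ex), gwas_row("rs1", "A", "T", 0.05, eaf = NA))
  expect_equal(nrow(h), 0)
  # band edge is inclusive: eaf = 0.58 with band 0.08 is still ambiguous
  h <- harmonizeInstruments(make_iset(ex), gwas_row("rs1", "A", "T", 0.05, eaf = 0.58))
  expect_equal(nrow(h), 0)
  # concordant frequencies (both minor on the effect allele): kept as-is
  h <- harmonizeInstruments(make_iset(ex), gwas_row("rs1", "A", "T", 0.05, eaf = 0.2))
  expect_equal(h$b_Y, 0.05)
  # discordant frequencies imply the outcome is reported on the other
  # orientation: beta is negated
  h <- harmonizeInstruments(make_iset(ex), gwas_row("rs1", "A", "T", 0.05, eaf = 0.8))
  expect_equal(h$b_Y, -0.05)
})

test_that("harmonization is involution-safe and rejects duplicated outcome variants", {
  ex <- members_frame(c("rs1", "rs2"), c(1e-8, 1e-7))
  out <- rbind(gwas_row("rs1", "A", "G", 0.05), gwas_row("rs2", "G", "A", 0.02))
  h1 <- harmonizeInstruments(make_iset(ex), out)
  # rebuild an outcome table from the aligned result and harmonize again
  out2 <- data.frame(variant_id = h1$variant_id, chrom = "chr1", pos = 1:2,
                     effect_allele = h1$effect_allele,
                     other_allele = h1$other_allele, beta = h1$b_Y,
                     se = h1$se_Y, pvalue = h1$pvalue_Y, eaf = 0.3, n = 100L)
  h2 <- harmonizeInstruments(make_iset(ex), out2)
  expect_equal(h2$b_Y, h1$b_Y)
  expect_equal(h2$variant_id, h1$variant_id)

  dup <- rbind(out, gwas_row("rs1", "A", "G", 0.01))
  expect_error(harmonizeInstruments(make_iset(ex), dup), "duplicate")
})

test_that("proxy substitution pairs original exposure statistics with phased proxy outcome statistics", {
  set.seed(5)
  # rs_orig absent from outcome; rs_proxy present, in high positive LD
  n <- 3000
  g1 <- rbinom(n, 2, 0.4)
  flip_mask <- rbinom(n, 1, 0.03)
  g2 <- ifelse(flip_mask == 1, 2 - g1, g1)       # r ~ +0.9
  g3 <- 2 - g2                                   # negatively phased copy
  geno <- cbind(rs_orig = g1, rs_proxy = g2, rs_neg = g3)
  vi <- data.frame(variant_id = colnames(geno), chrom = "chr1")
  ld <- buildLdReference(geno, vi)

  ex <- members_frame("rs_orig", 1e-8)
  out_pos <- gwas_row("rs_proxy", "A", "G", 0.07)
  h <- harmonizeInstruments(make_iset(ex), out_pos, ld = ld)
  expect_equal(nrow(h), 1)
  expect_equal(h$proxy_of, "rs_orig")
  expect_equal(h$variant_id, "rs_proxy")
  expect_equal(h$b_X, 0.3)          # exposure side kept from the original
  expect_equal(h$b_Y, 0.07)         # positive phase: sign kept

  out_neg <- gwas_row("rs_neg", "A", "G", 0.07)
  h2 <- harmonizeInstruments(make_iset(ex), out_neg, ld = ld)
  expect_equal(h2$b_Y, -0.07)       # negative phase: sign flipped

  # no proxy above the threshold: itemized drop
  far <- gwas_row("rs_far", "A", "G", 0.07)
  ld_far <- ld_from_pairs("rs_orig", "rs_far", 0.5,
                          chrom_map = c(rs_orig = "chr1", rs_far = "chr1"))
  h3 <- harmonizeInstruments(make_iset(ex), far, ld = ld_far)
  expect_equal(nrow(h3), 0)
  expect_equal(attr(h3, "drops")$reason, "absent_from_outcome_no_proxy")
})
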