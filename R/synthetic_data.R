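# Synthetic two-sample and individual-level data with known truth,
# generated under the pathway-exposure model the analysis assumes.

.BASES_NONPAL <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                      c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
.BASES_PAL <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

#' Construct a pathway-exposure generative model
#'
#' Defaults describe the study conditions the generator emulates: strong
#' cis-eQTL effects (0.25–0.7 SD of expression per allele, signs random),
#' homogeneous per-gene outcome effects (h_j = 1), modest tissue sharing
#' noise, and no horizontal pleiotropy unless requested.
#'
#' @param n_genes number of pathway genes.
#' @param beta_e pathway-average causal effect on the outcome.
#' @param het_ratios per-gene effect ratios (mean 1); default all 1.
#' @param eqtl_beta per-gene shared SNP-expression effects; default drawn
#'   uniformly on ±[0.25, 0.7] using the current RNG state.
#' @param tau SD of tissue-specific deviation of the eQTL effect.
#' @param pleiotropy_mean,pleiotropy_sd direct SNP-outcome effect
#'   distribution (oriented to the expression-increasing allele).
#' @param covariate_effect_y,covariate_effect_e,noise_sd_y,noise_sd_e
#'   covariate and residual parameters for individual-level simulation.
#' @param positive_eqtl force all shared eQTL effects positive (useful when
#'   studying directional pleiotropy, where the Egger intercept is defined
#'   on the oriented scale).
#' @return a \linkS4class{PathwayExposureModel}.
#' @export
pathwayModel <- function(n_genes, beta_e = 0, het_ratios = rep(1, n_genes),
                         eqtl_beta = NULL, tau = 0.05,
                         pleiotropy_mean = 0, pleiotropy_sd = 0,
                         covariate_effect_y = 0.2, covariate_effect_e = 0.1,
                         noise_sd_y = 1, noise_sd_e = 1,
                         positive_eqtl = FALSE) {
  if (is.null(eqtl_beta)) {
    mag <- stats::runif(n_genes, 0.25, 0.7)
    sgn <- if (positive_eqtl) 1 else sample(c(-1, 1), n_genes, replace = TRUE)
    eqtl_beta <- mag * sgn
  }
  new("PathwayExposureModel", beta_e = beta_e, het_ratios = het_ratios,
      eqtl_beta = eqtl_beta, tau = tau,
      covariate_effect_y = covariate_effect_y,
      covariate_effect_e = covariate_effect_e,
      noise_sd_y = noise_sd_y, noise_sd_e = noise_sd_e,
      pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd)
}

#' Construct the simulation truth for one synthetic study
#'
#' @param model a \linkS4class{PathwayExposureModel}.
#' @param genes gene ids (default GENE_01...).
#' @param n_tissues tissues with eQTL statistics (default 5).
#' @param snps_per_gene cis-variants per gene block (default 10).
#' @param causal_index block position of the causal variant (default centre).
#' @param ld_rho AR(1) dosage correlation between adjacent variants.
#' @param maf matrix of effect-allele frequencies (genes x snps); default
#'   drawn uniformly on [0.05, 0.5].
#' @param palindromic allow strand-ambiguous allele pairs (default FALSE).
#' @return a \linkS4class{SimTruth}.
#' @export
simTruth <- function(model, genes = NULL, n_tissues = 5, snps_per_gene = 10,
                     causal_index = ceiling(snps_per_gene / 2), ld_rho = 0.5,
                     maf = NULL, palindromic = FALSE) {
  G <- length(model@eqtl_beta)
  if (is.null(genes)) genes <- sprintf("GENE_%02d", seq_len(G))
  if (is.null(maf))
    maf <- matrix(stats::runif(G * snps_per_gene, 0.05, 0.5), nrow = G)
  new("SimTruth", model = model, genes = genes, n_tissues = n_tissues,
      snps_per_gene = snps_per_gene, causal_index = causal_index,
      ld_rho = ld_rho, maf = maf, palindromic = palindromic)
}

# per-variant allele pairs, deterministic under the current RNG state
.draw_alleles <- function(n, palindromic) {
  pool <- if (palindromic) c(.BASES_NONPAL, .BASES_PAL) else .BASES_NONPAL
  idx <- sample(length(pool), n, replace = TRUE)
  do.call(rbind, pool[idx])
}

#' Simulate two-sample summary statistics with known truth
#'
#' Generates an eQTL summary table (gene x tissue x variant), one outcome
#' GWAS table, a pairwise LD table and a truth record, all conforming to the
#' package's canonical schemas. Per gene g and tissue t the causal-variant
#' effect is \code{beta_s(g) + N(0, tau^2)}; a non-causal cis variant at
#' AR(1) distance d inherits \code{rho^d} of the causal effect. Summary
#' estimates add sampling noise with
#' \code{se = 1/sqrt(2 maf (1-maf) n)} (unit trait variance). The per-variant
#' true outcome effect is \code{beta_e * h_g * (cross-tissue exposure
#' effect) + pleiotropy}, the pleiotropy draw oriented to the
#' expression-increasing allele.
#'
#' The truth record includes the expected IVW and Egger fits on the
#' generated causal-variant statistics, computed by an independent weighted
#' \code{stats::lm} oracle.
#'
#' @param truth a \linkS4class{SimTruth}.
#' @param n_exposure per-tissue eQTL sample size (default 500).
#' @param n_outcome outcome GWAS sample size (default 20000).
#' @param seed integer seed; the run is fully reproducible.
#' @return list: eqtl (data.frame), gwas (data.frame), ld (data.frame
#'   id1/id2/r2), variant_info (variant_id/chrom), truth (list).
#' @export
simulateTwoSample <- function(truth, n_exposure = 500, n_outcome = 20000,
                              seed = 1) {
  set.seed(as.integer(.substream(seed, "two_sample")))
  m <- truth@model
  G <- length(truth@genes)
  S <- truth@snps_per_gene
  ci <- truth@causal_index
  rho <- truth@ld_rho

  eqtl <- vector("list", G)
  gwas <- vector("list", G)
  ld <- vector("list", G)
  true_bx <- matrix(0, G, S)
  true_by <- matrix(0, G, S)

  for (g in seq_len(G)) {
    ids <- sprintf("rs%d_%d", g, seq_len(S))
    chrom <- sprintf("chr%d", g)
    pos <- 1000000 + seq_len(S) * 1000
    al <- .draw_alleles(S, truth@palindromic)
    maf <- truth@maf[g, ]
    rfac <- rho^abs(seq_len(S) - ci)          # signed dosage correlation
    bx_true <- m@eqtl_beta[g] * rfac          # cross-tissue exposure effect
    pleio <- stats::rnorm(S, m@pleiotropy_mean, m@pleiotropy_sd) *
      sign(bx_true)
    by_true <- m@beta_e * m@het_ratios[g] * bx_true + pleio
    true_bx[g, ] <- bx_true
    true_by[g, ] <- by_true

    se_x <- 1 / sqrt(2 * maf * (1 - maf) * n_exposure)
    tiss <- lapply(seq_len(truth@n_tissues), function(t) {
      bs_t <- (m@eqtl_beta[g] + stats::rnorm(1, 0, m@tau)) * rfac
      bhat <- bs_t + stats::rnorm(S, 0, se_x)
      data.frame(gene_id = truth@genes[g], tissue = sprintf("tissue_%d", t),
                 variant_id = ids, chrom = chrom, pos = pos,
                 effect_allele = al[, 1], other_allele = al[, 2],
                 beta = bhat, se = se_x, pvalue = .z_pvalue(bhat, se_x),
                 eaf = maf, tss_distance = (seq_len(S) - ci) * 1000,
                 stringsAsFactors = FALSE)
    })
    eqtl[[g]] <- do.call(rbind, tiss)

    se_y <- 1 / sqrt(2 * maf * (1 - maf) * n_outcome)
    byhat <- by_true + stats::rnorm(S, 0, se_y)
    gwas[[g]] <- data.frame(variant_id = ids, chrom = chrom, pos = pos,
                            effect_allele = al[, 1], other_allele = al[, 2],
                            beta = byhat, se = se_y,
                            pvalue = .z_pvalue(byhat, se_y), eaf = maf,
                            n = n_outcome, stringsAsFactors = FALSE)

    ld[[g]] <- if (S >= 2) {
      pr <- t(utils::combn(S, 2))
      data.frame(id1 = ids[pr[, 1]], id2 = ids[pr[, 2]],
                 r2 = rho^(2 * abs(pr[, 1] - pr[, 2])),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(id1 = character(0), id2 = character(0), r2 = numeric(0))
    }
  }

  eqtl <- do.call(rbind, eqtl)
  gwas <- do.call(rbind, gwas)
  ld <- do.call(rbind, ld)
  vinfo <- unique(gwas[, c("variant_id", "chrom")])

  # expected estimates at the causal variants, via an independent lm oracle
  causal_ids <- sprintf("rs%d_%d", seq_len(G), ci)
  ce <- gwas$variant_id %in% causal_ids
  bx_hat <- vapply(causal_ids, function(id) {
    rows <- eqtl[eqtl$variant_id == id, ]
    rows$beta[which.min(rows$pvalue)]
  }, numeric(1))
  by_hat <- gwas$beta[match(causal_ids, gwas$variant_id)]
  w <- 1 / gwas$se[match(causal_ids, gwas$variant_id)]^2
  expected <- list()
  if (G >= 2) {
    ivw_fit <- stats::lm(by_hat ~ 0 + bx_hat, weights = w)
    expected$ivw_beta <- unname(stats::coef(ivw_fit)[1])
  }
  if (G >= 3) {
    or <- ifelse(bx_hat < 0, -1, 1)
    eg_fit <- stats::lm(I(by_hat * or) ~ I(bx_hat * or), weights = w)
    expected$egger_intercept <- unname(stats::coef(eg_fit)[1])
    expected$egger_slope <- unname(stats::coef(eg_fit)[2])
  }

  list(eqtl = eqtl, gwas = gwas, ld = ld, variant_info = vinfo,
       truth = list(
         beta_e = m@beta_e, het_ratios = m@het_ratios,
         eqtl_beta = m@eqtl_beta, tau = m@tau,
         pleiotropy_mean = m@pleiotropy_mean,
         pleiotropy_sd = m@pleiotropy_sd,
         causal_variants = causal_ids, ld_rho = rho,
         true_bx = true_bx, true_by = true_by,
         n_exposure = n_exposure, n_outcome = n_outcome,
         expected = expected, seed = seed))
}

# P(Z < a, W < b) for bivariate standard normal with correlation r,
# by one-dimensional quadrature (keeps dependencies to base R)
.pbinorm <- function(a, b, r) {
  if (abs(r) < 1e-12) return(stats::pnorm(a) * stats::pnorm(b))
  f <- function(z) stats::dnorm(z) *
    stats::pnorm((b - r * z) / sqrt(1 - r^2))
  stats::integrate(f, -Inf, a, rel.tol = 1e-10)$value
}

# latent normal correlation that makes two thresholded Bernoulli indicators
# (success probabilities p1, p2) correlate at the target level
.calibrate_latent_rho <- function(target, p1, p2) {
  if (target <= 0) return(0)
  q1 <- stats::qnorm(p1); q2 <- stats::qnorm(p2)
  ind_cor <- function(rz) {
    p11 <- .pbinorm(q1, q2, rz)
    (p11 - p1 * p2) / sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  }
  if (ind_cor(0.9999) <= target) return(0.9999)
  stats::uniroot(function(rz) ind_cor(rz) - target, c(0, 0.9999),
                 tol = 1e-6)$root
}

# samples x snps dosages with AR(1) dosage correlation and Binomial(2, maf)
# margins. Each dosage is the sum of two independent thresholded Gaussian
# chains, so the adjacent-dosage correlation equals the adjacent indicator
# correlation, which is calibrated to the configured rho.
.sim_dosages <- function(n, maf, rho) {
  S <- length(maf)
  rz <- if (S > 1)
    vapply(seq_len(S - 1), function(k)
      .calibrate_latent_rho(rho, maf[k], maf[k + 1]), numeric(1)) else
    numeric(0)
  one_chain <- function() {
    Z <- matrix(0, n, S)
    Z[, 1] <- stats::rnorm(n)
    if (S > 1) for (k in 2:S)
      Z[, k] <- rz[k - 1] * Z[, k - 1] +
        sqrt(1 - rz[k - 1]^2) * stats::rnorm(n)
    Z
  }
  Z1 <- one_chain(); Z2 <- one_chain()
  D <- matrix(0, n, S)
  for (k in seq_len(S)) {
    q <- stats::qnorm(maf[k])
    D[, k] <- (Z1[, k] < q) + (Z2[, k] < q)
  }
  D
}

#' Simulate an individual-level dataset under the pathway model
#'
#' Genotypes are Binomial(2, maf) dosages with AR(1) latent correlation
#' inside each gene block (independent across blocks). Expression follows
#' \code{E_ij = beta_s SNP_ij + x_i alpha_j + eps_ij} with the block's
#' causal variant as SNP; the outcome follows
#' \code{Y = beta_e sum_j h_j E_j + X alpha + eps}. Covariates are one
#' standard-normal column and one two-level batch factor. Optional strata
#' get stratum-specific values of beta_e.
#'
#' @param truth a \linkS4class{SimTruth}.
#' @param n number of samples.
#' @param strata optional named numeric vector of per-stratum beta_e values;
#'   samples are assigned to strata uniformly.
#' @param seed integer seed.
#' @return list: data (an \linkS4class{IndividualDataset}) and truth (list).
#' @export
simulateIndividual <- function(truth, n, strata = NULL, seed = 1) {
  set.seed(as.integer(.substream(seed, "individual")))
  m <- truth@model
  G <- length(truth@genes)
  S <- truth@snps_per_gene
  ci <- truth@causal_index

  covs <- data.frame(age_std = stats::rnorm(n),
                     batch = factor(sample(c("b1", "b2"), n, replace = TRUE)))
  xnum <- covs$age_std + (as.integer(covs$batch) - 1.5)

  group <- character(0)
  beta_e_i <- rep(m@beta_e, n)
  if (!is.null(strata)) {
    group <- sample(names(strata), n, replace = TRUE)
    beta_e_i <- unname(strata[group])
  }

  geno <- matrix(0, n, G * S)
  expr <- matrix(0, n, G)
  ids <- character(G * S)
  vinfo <- vector("list", G)
  ysig <- rep(0, n)
  for (g in seq_len(G)) {
    cols <- (g - 1) * S + seq_len(S)
    D <- .sim_dosages(n, truth@maf[g, ], truth@ld_rho)
    geno[, cols] <- D
    ids[cols] <- sprintf("rs%d_%d", g, seq_len(S))
    vinfo[[g]] <- data.frame(variant_id = ids[cols],
                             chrom = sprintf("chr%d", g),
                             pos = 1000000 + seq_len(S) * 1000,
                             gene_id = truth@genes[g],
                             stringsAsFactors = FALSE)
    e <- m@eqtl_beta[g] * D[, ci] + m@covariate_effect_e * xnum +
      stats::rnorm(n, 0, m@noise_sd_e)
    expr[, g] <- e
    ysig <- ysig + m@het_ratios[g] * e
  }
  colnames(geno) <- ids
  colnames(expr) <- truth@genes
  y <- beta_e_i * ysig + m@covariate_effect_y * xnum +
    stats::rnorm(n, 0, m@noise_sd_y)

  data <- individualDataset(
    genotypes = geno, expression = expr,
    phenotypes = data.frame(trait = y),
    covariates = covs, group = group,
    variantInfo = do.call(rbind, vinfo))
  list(data = data,
       truth = list(beta_e = m@beta_e, strata = strata,
                    causal_variants = sprintf("rs%d_%d", seq_len(G), ci),
                    seed = seed))
}

.SCENARIOS <- c("null", "causal", "directional_pleiotropy", "single_outlier",
                "tissue_heterogeneity", "paper_shape")

# synthetic pathway rosters; the focal set is sized so that, at roughly one
# independent cis signal per gene, it yields ~30 clumped instruments
.PATHWAY_GENES <- list(
  HEME_BIOSYNTHESIS = c("ALAS1", "ALAD", "HMBS", "UROS", "UROD", "CPOX",
                        "PPOX", "FECH", "ABCB6", "GATA1",
                        sprintf("HEMEB_%02d", 11:30)),
  HEME_DEGRADATION = c("HMOX1", "HMOX2", "BLVRA", "BLVRB", "SLCO2B1",
                       "ALB", "CD163", "HP", sprintf("HEMED_%02d", 9:15)),
  HEME_SIGNALING = sprintf("HSG_%02d", 1:20),
  IRON_UPTAKE_TRANSPORT = c("TFRC", "TF", "SLC11A2", "SLC40A1", "FTH1",
                            "FTL", "ACO1", "IREB2", "CYBRD1", "HEPH",
                            "CP", "HFE", sprintf("IRONU_%02d", 13:20)))

.OUTCOMES <- c("ahi", "avg_spo2", "min_spo2", "pct_sleep_spo2_lt90")

#' Write a self-contained synthetic fixture bundle
#'
#' Emits the file set a discovery run consumes — \code{eqtl.tsv},
#' \code{gwas_<trait>.tsv} per outcome, \code{pathways.gmt}, \code{ld.tsv},
#' \code{variant_info.tsv}, \code{truth.json} and a README — deterministic
#' per seed (identical seeds give byte-identical files).
#'
#' Scenarios: \code{null} (no effect anywhere), \code{causal} (the first
#' pathway causally raises every outcome), \code{directional_pleiotropy}
#' (mu_alpha = 0.02), \code{single_outlier} (one instrument's outcome effect
#' grossly inflated), \code{tissue_heterogeneity} (large tissue-specific
#' eQTL deviations) and \code{paper_shape} (4 pathways x 4 outcomes, the
#' focal pathway sized to yield roughly 30 clumped instruments).
#'
#' @param scenario one of the names above.
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @return invisibly, a list of the written paths plus the truth list.
#' @export
makeFixtureBundle <- function(scenario, seed = 1, dir = tempfile("fixture_")) {
  if (!scenario %in% .SCENARIOS)
    stop("unknown scenario '", scenario, "'; valid: ",
         paste(.SCENARIOS, collapse = ", "), call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(.substream(seed, paste0("fixture_", scenario))))

  genes_by_pathway <- .PATHWAY_GENES
  if (scenario != "paper_shape") {
    # single-pathway scenarios still ship a 4-pathway GMT so the discovery
    # grid has its full shape; only the first pathway carries the scenario
    G1 <- if (scenario %in% c("directional_pleiotropy", "single_outlier"))
      15 else 10
    genes_by_pathway$HEME_BIOSYNTHESIS <- sprintf("GENE_%02d", seq_len(G1))
  }

  outcome_effects <- matrix(0, nrow = 4, ncol = length(.OUTCOMES),
                            dimnames = list(names(genes_by_pathway), .OUTCOMES))
  pleio <- c(0, 0); tau <- 0.05; outlier <- FALSE; pos_eqtl <- FALSE
  if (scenario == "causal") outcome_effects[1, ] <- 0.05
  if (scenario == "paper_shape")
    outcome_effects[1, ] <- c(0.007, -0.008, -0.008, 0.012)
  if (scenario == "directional_pleiotropy") { pleio <- c(0.02, 0.005); pos_eqtl <- TRUE }
  if (scenario == "single_outlier") outlier <- TRUE
  if (scenario == "tissue_heterogeneity") tau <- 0.15

  eqtl <- list(); gwas <- stats::setNames(vector("list", length(.OUTCOMES)),
                                          .OUTCOMES)
  ld <- list(); vinfo <- list(); truth_rec <- list()
  goff <- 0
  for (pw in names(genes_by_pathway)) {
    genes <- genes_by_pathway[[pw]]
    first_pw <- pw == names(genes_by_pathway)[1]
    model <- pathwayModel(length(genes), beta_e = 0,
                          pleiotropy_mean = if (first_pw) pleio[1] else 0,
                          pleiotropy_sd = if (first_pw) pleio[2] else 0,
                          tau = tau, positive_eqtl = pos_eqtl)
    tr <- simTruth(model, genes = genes)
    G <- length(genes); S <- tr@snps_per_gene

    # exposure side (eQTL table, LD, alleles) is simulated once per pathway;
    # every outcome reuses the same genetic architecture, as in a real study
    base <- simulateTwoSample(tr, seed = as.integer(.substream(seed, pw)))
    relabel <- function(ids)
      paste0(pw, "_", ids)
    rechrom <- function(ids)
      sprintf("chr%d", goff + as.integer(sub("^rs(\\d+)_.*", "\\1", ids)))
    base$eqtl$chrom <- rechrom(base$eqtl$variant_id)
    base$eqtl$variant_id <- relabel(base$eqtl$variant_id)
    base$ld$id1 <- relabel(base$ld$id1)
    base$ld$id2 <- relabel(base$ld$id2)
    vi <- base$variant_info
    vi$chrom <- rechrom(vi$variant_id)
    vi$variant_id <- relabel(vi$variant_id)
    eqtl[[pw]] <- base$eqtl
    ld[[pw]] <- base$ld
    vinfo[[pw]] <- vi

    true_bx <- base$truth$true_bx                 # G x S, gene-major rows
    hmat <- matrix(model@het_ratios, nrow = G, ncol = S)
    gtmpl <- base$gwas
    gtmpl$chrom <- rechrom(gtmpl$variant_id)
    gtmpl$variant_id <- relabel(gtmpl$variant_id)

    per_outcome <- list()
    for (oc in .OUTCOMES) {
      be <- outcome_effects[pw, oc]
      set.seed(as.integer(.substream(seed, paste(pw, oc, sep = "|"))))
      pl <- matrix(stats::rnorm(G * S, model@pleiotropy_mean,
                                model@pleiotropy_sd), G, S) * sign(true_bx)
      by_true <- be * hmat * true_bx + pl
      g <- gtmpl
      g$beta <- as.vector(t(by_true)) + stats::rnorm(nrow(g), 0, g$se)
      if (outlier && first_pw && oc == .OUTCOMES[1]) {
        # plant a gross pleiotropic outlier at the first causal variant
        tgt <- relabel(base$truth$causal_variants[1])
        g$beta[g$variant_id == tgt] <- g$beta[g$variant_id == tgt] +
          10 * max(abs(g$beta))
      }
      g$pvalue <- .z_pvalue(g$beta, g$se)
      gwas[[oc]][[pw]] <- g
      per_outcome[[oc]] <- list(beta_e = be)
    }
    truth_rec[[pw]] <- list(
      genes = genes, outcomes = per_outcome,
      causal_variants = relabel(base$truth$causal_variants),
      pleiotropy = pleio, tau = tau)
    goff <- goff + G
  }

  eqtl <- do.call(rbind, eqtl); rownames(eqtl) <- NULL
  ld <- do.call(rbind, ld); rownames(ld) <- NULL
  vinfo <- do.call(rbind, vinfo); rownames(vinfo) <- NULL

  paths <- list(dir = dir)
  p <- file.path(dir, "eqtl.tsv")
  data.table::fwrite(eqtl, p, sep = "\t", quote = FALSE)
  paths$eqtl <- p
  for (oc in .OUTCOMES) {
    gdf <- do.call(rbind, gwas[[oc]]); rownames(gdf) <- NULL
    p <- file.path(dir, paste0("gwas_", oc, ".tsv"))
    data.table::fwrite(gdf, p, sep = "\t", quote = FALSE)
    paths[[paste0("gwas_", oc)]] <- p
  }
  p <- file.path(dir, "pathways.gmt")
  writeGmt(lapply(names(genes_by_pathway), function(pw)
    list(pathway_id = pw, name = paste("synthetic", tolower(pw)),
         gene_ids = genes_by_pathway[[pw]])), p)
  paths$gmt <- p
  p <- file.path(dir, "ld.tsv")
  data.table::fwrite(ld, p, sep = "\t", quote = FALSE)
  paths$ld <- p
  p <- file.path(dir, "variant_info.tsv")
  data.table::fwrite(vinfo, p, sep = "\t", quote = FALSE)
  paths$variant_info <- p
  p <- file.path(dir, "truth.json")
  jsonlite::write_json(list(scenario = scenario, seed = seed,
                            outcomes = .OUTCOMES, pathways = truth_rec),
                       p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths$truth <- p
  writeLines(c(
    sprintf("Synthetic fixture bundle: scenario '%s', seed %d.", scenario, seed),
    "Files: eqtl.tsv, gwas_<trait>.tsv, pathways.gmt, ld.tsv,",
    "variant_info.tsv, truth.json. All data are simulated; no real",
    "GTEx, GWAS or cohort records are included."),
    file.path(dir, "README"))
  paths$truth_record <- truth_rec
  invisible(paths)
}
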