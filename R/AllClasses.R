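#' @import methods
NULL

#' Linkage-disequilibrium reference panel
#'
#' Queryable store of pairwise LD between variants. Built either from a
#' pairwise \code{(id1, id2, r2)} table or from a sample-by-variant dosage
#' matrix (see \code{\link{buildLdReference}}). When built from genotypes the
#' signed dosage correlation \code{r} is retained as well, which lets proxy
#' substitution infer allele phase; pairwise tables carry only \code{r2}.
#'
#' Conventions: \code{r2(a, a) = 1}; pairs on different chromosomes are 0 by
#' construction; a same-chromosome pair absent from the store is treated as 0
#' with a warning, since it usually means the panel is incomplete.
#'
#' @slot pairs environment hashing sorted id pairs to c(r2, r) (r may be NA).
#' @slot chrom named character vector mapping variant_id to chromosome label.
#' @slot provenance "pairwise_table" or "genotypes".
#' @export
setClass("LdReference",
  representation(
    pairs = "environment",
    chrom = "character",
    provenance = "character"
  )
)

setValidity("LdReference", function(object) {
  if (!object@provenance %in% c("pairwise_table", "genotypes"))
    return("provenance must be 'pairwise_table' or 'genotypes'")
  TRUE
})

#' Set of instrumental variables for one exposure grouping
#'
#' Container for the candidate instruments of one gene, tissue or pathway.
#' Members carry exposure-side statistics only; the outcome side is attached
#' by \code{\link{harmonizeInstruments}}. Each member's statistics come from
#' the tissue in which the variant was the most significant cis-eQTL.
#'
#' @slot grouping one of "gene", "tissue", "pathway".
#' @slot label the gene/tissue/pathway identifier.
#' @slot members data.frame with columns variant_id, chrom, pos,
#'   effect_allele, other_allele, gene_id, tissue, beta_x, se_x, pvalue_x and
#'   optionally eaf_x.
#' @slot clumped TRUE once LD clumping has been applied.
#' @export
setClass("InstrumentSet",
  representation(
    grouping = "character",
    label = "character",
    members = "data.frame",
    clumped = "logical"
  )
)

setValidity("InstrumentSet", function(object) {
  msg <- character(0)
  if (!object@grouping %in% c("gene", "tissue", "pathway"))
    msg <- c(msg, "grouping must be one of 'gene', 'tissue', 'pathway'")
  m <- object@members
  need <- c("variant_id", "gene_id", "tissue", "beta_x", "se_x", "pvalue_x")
  miss <- setdiff(need, names(m))
  if (length(miss))
    msg <- c(msg, paste0("members lacks columns: ", paste(miss, collapse = ", ")))
  if (nrow(m)) {
    if (anyDuplicated(m$variant_id))
      msg <- c(msg, "duplicate variant_id among members")
    if ("se_x" %in% names(m) && any(m$se_x <= 0))
      msg <- c(msg, "all se_x must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' Individual-level genotype/expression/phenotype dataset
#'
#' Holds the aligned blocks needed for summary-level one-sample MR: a dosage
#' matrix, an expression matrix, phenotype and covariate tables, and an
#' optional stratum label (e.g. ancestry group). All blocks share the sample
#' dimension (rows).
#'
#' @slot genotypes numeric matrix, samples x variants, dosages in [0, 2].
#' @slot expression numeric matrix, samples x genes.
#' @slot phenotypes data.frame, samples x traits.
#' @slot covariates data.frame, samples x covariates (numeric or factor).
#' @slot group character vector of per-sample stratum labels (length 0 if none).
#' @slot variantInfo data.frame describing genotype columns (variant_id,
#'   chrom, pos, gene_id of the instrumented gene).
#' @export
setClass("IndividualDataset",
  representation(
    genotypes = "matrix",
    expression = "matrix",
    phenotypes = "data.frame",
    covariates = "data.frame",
    group = "character",
    variantInfo = "data.frame"
  )
)

setValidity("IndividualDataset", function(object) {
  msg <- character(0)
  n <- nrow(object@genotypes)
  if (nrow(object@expression) != n)
    msg <- c(msg, "expression and genotypes disagree on sample count")
  if (nrow(object@phenotypes) != n)
    msg <- c(msg, "phenotypes and genotypes disagree on sample count")
  if (ncol(object@covariates) > 0 && nrow(object@covariates) != n)
    msg <- c(msg, "covariates and genotypes disagree on sample count")
  if (length(object@group) && length(object@group) != n)
    msg <- c(msg, "group labels and genotypes disagree on sample count")
  if (length(object@genotypes) && (min(object@genotypes) < 0 ||
                                   max(object@genotypes) > 2))
    msg <- c(msg, "dosages must lie in [0, 2]")
  if (length(msg)) msg else TRUE
})

#' Generative model for a pathway's effect on an outcome
#'
#' Parameterizes the pathway-exposure model used by the synthetic-data
#' generator: the outcome is
#' \deqn{Y = \beta_e \sum_j h_j E_j + X\alpha + \epsilon,}
#' where \eqn{E_j} is the expression of the j-th pathway gene,
#' \eqn{\beta_e} the pathway-average causal effect and \eqn{h_j = \beta_j /
#' \beta_e} per-gene heterogeneity ratios (mean fixed to 1 so that
#' \eqn{\beta_e} is identified). Expression follows
#' \deqn{E_{ij} = \beta_s SNP_{ij} + x_i \alpha_j + \epsilon_{ij},}
#' with per-gene SNP effects \eqn{\beta_s} shared across tissues up to a
#' tissue-specific deviation with SD \code{tau}. Direct SNP-on-outcome
#' (pleiotropic) effects are drawn with mean \code{pleiotropy_mean} and SD
#' \code{pleiotropy_sd}, oriented to the expression-increasing allele.
#'
#' @slot beta_e numeric(1), pathway-average causal effect on the outcome.
#' @slot het_ratios per-gene ratios h_j, mean 1.
#' @slot eqtl_beta per-gene shared SNP-on-expression effects (SD units).
#' @slot tau SD of the tissue-specific deviation of the eQTL effect.
#' @slot covariate_effect_y covariate effect on the outcome (alpha).
#' @slot covariate_effect_e covariate effect on each expression (alpha_j).
#' @slot noise_sd_y residual SD of the outcome (epsilon).
#' @slot noise_sd_e residual SD of expression (epsilon_ij).
#' @slot pleiotropy_mean mean of direct SNP-outcome effects (mu_alpha).
#' @slot pleiotropy_sd SD of direct SNP-outcome effects (sigma_alpha).
#' @export
setClass("PathwayExposureModel",
  representation(
    beta_e = "numeric",
    het_ratios = "numeric",
    eqtl_beta = "numeric",
    tau = "numeric",
    covariate_effect_y = "numeric",
    covariate_effect_e = "numeric",
    noise_sd_y = "numeric",
    noise_sd_e = "numeric",
    pleiotropy_mean = "numeric",
    pleiotropy_sd = "numeric"
  )
)

setValidity("PathwayExposureModel", function(object) {
  msg <- character(0)
  if (length(object@het_ratios) != length(object@eqtl_beta))
    msg <- c(msg, "het_ratios and eqtl_beta must have one entry per gene")
  if (length(object@het_ratios) &&
      abs(mean(object@het_ratios) - 1) > 1e-8)
    msg <- c(msg, "het_ratios must average to 1 (identifiability of beta_e)")
  for (s in c("tau", "noise_sd_y", "noise_sd_e", "pleiotropy_sd")) {
    if (any(slot(object, s) < 0))
      msg <- c(msg, paste0(s, " must be >= 0"))
  }
  if (length(msg)) msg else TRUE
})

#' Full simulation truth for one synthetic study
#'
#' Bundles a \linkS4class{PathwayExposureModel} with the genetic architecture
#' needed to simulate summary statistics or individual-level data: one causal
#' cis-variant per gene inside an AR(1) LD block, per-variant allele
#' frequencies, and block correlation. LD is zero across gene blocks (each
#' gene sits on its own chromosome label), which is enough structure to
#' exercise clumping and proxy lookup.
#'
#' @slot model the generative \linkS4class{PathwayExposureModel}.
#' @slot genes character vector of gene ids.
#' @slot n_tissues number of tissues with eQTL summary statistics.
#' @slot snps_per_gene cis-variants simulated per gene block.
#' @slot causal_index position of the causal variant inside each block.
#' @slot ld_rho AR(1) dosage correlation between adjacent block variants.
#' @slot maf numeric matrix (genes x snps) of effect-allele frequencies.
#' @slot palindromic if TRUE allele pairs may be strand-ambiguous (A/T, C/G).
#' @export
setClass("SimTruth",
  representation(
    model = "PathwayExposureModel",
    genes = "character",
    n_tissues = "numeric",
    snps_per_gene = "numeric",
    causal_index = "numeric",
    ld_rho = "numeric",
    maf = "matrix",
    palindromic = "logical"
  )
)

setValidity("SimTruth", function(object) {
  msg <- character(0)
  if (length(object@genes) != length(object@model@eqtl_beta))
    msg <- c(msg, "genes must match model's per-gene parameter length")
  if (any(object@maf <= 0) || any(object@maf > 0.5))
    msg <- c(msg, "maf must lie in (0, 0.5]")
  if (object@ld_rho < 0 || object@ld_rho >= 1)
    msg <- c(msg, "ld_rho must lie in [0, 1)")
  if (object@causal_index < 1 || object@causal_index > object@snps_per_gene)
    msg <- c(msg, "causal_index must index into the block")
  if (length(msg)) msg else TRUE
})
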