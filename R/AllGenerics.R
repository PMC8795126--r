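#' Accessors for pathwayMR classes
#'
#' @param x an object.
#' @param ... unused.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("instrumentMembers", function(x, ...) standardGeneric("instrumentMembers"))

#' @rdname accessors
#' @export
setGeneric("grouping", function(x, ...) standardGeneric("grouping"))

#' @rdname accessors
#' @export
setGeneric("isClumped", function(x, ...) standardGeneric("isClumped"))

#' @rdname accessors
#' @export
setGeneric("nInstruments", function(x, ...) standardGeneric("nInstruments"))

#' @rdname accessors
#' @export
setMethod("instrumentMembers", "InstrumentSet", function(x, ...) x@members)

#' @rdname accessors
#' @export
setMethod("grouping", "InstrumentSet", function(x, ...) x@grouping)

#' @rdname accessors
#' @export
setMethod("isClumped", "InstrumentSet", function(x, ...) x@clumped)

#' @rdname accessors
#' @export
setMethod("nInstruments", "InstrumentSet", function(x, ...) nrow(x@members))

setMethod("show", "InstrumentSet", function(object) {
  cat(sprintf("InstrumentSet (%s-level) '%s': %d instrument%s%s\n",
              object@grouping, object@label, nrow(object@members),
              if (nrow(object@members) == 1) "" else "s",
              if (object@clumped) ", LD-clumped" else ""))
  if (nrow(object@members)) {
    p <- object@members$pvalue_x
    cat(sprintf("  genes: %d | tissues: %d | min p: %.3g\n",
                length(unique(object@members$gene_id)),
                length(unique(object@members$tissue)), min(p)))
  }
})

setMethod("show", "LdReference", function(object) {
  cat(sprintf("LdReference (%s): %d stored pairs, %d variants with chromosome info\n",
              object@provenance, length(ls(object@pairs)), length(object@chrom)))
})

setMethod("show", "IndividualDataset", function(object) {
  cat(sprintf(
    "IndividualDataset: %d samples, %d variants, %d genes, %d traits, %d covariates%s\n",
    nrow(object@genotypes), ncol(object@genotypes), ncol(object@expression),
    ncol(object@phenotypes), ncol(object@covariates),
    if (length(object@group))
      sprintf(", %d strata", length(unique(object@group))) else ""))
})

setMethod("show", "PathwayExposureModel", function(object) {
  cat(sprintf(
    "PathwayExposureModel: %d genes, beta_e = %.4g, tau = %.3g, pleiotropy N(%.3g, %.3g^2)\n",
    length(object@eqtl_beta), object@beta_e, object@tau,
    object@pleiotropy_mean, object@pleiotropy_sd))
})

setMethod("show", "SimTruth", function(object) {
  cat(sprintf(
    "SimTruth: %d genes x %d tissues, %d SNPs/gene (causal at %d), AR(1) rho = %.2f\n",
    length(object@genes), object@n_tissues, object@snps_per_gene,
    object@causal_index, object@ld_rho))
})
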