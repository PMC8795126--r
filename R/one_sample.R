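# Summary-level one-sample MR: per-variant association statistics computed
# from individual-level data, then fed to the same IVW estimator as the
# two-sample stage.

#' Construct an IndividualDataset
#'
#' @param genotypes samples x variants dosage matrix (named columns).
#' @param expression samples x genes matrix (named columns).
#' @param phenotypes data.frame of traits.
#' @param covariates data.frame of covariates (numeric or factor).
#' @param group optional per-sample stratum labels.
#' @param variantInfo optional data.frame describing genotype columns.
#' @return an \linkS4class{IndividualDataset}.
#' @export
individualDataset <- function(genotypes, expression, phenotypes,
                              covariates = data.frame(),
                              group = character(0),
                              variantInfo = data.frame()) {
  new("IndividualDataset", genotypes = genotypes, expression = expression,
      phenotypes = as.data.frame(phenotypes),
      covariates = as.data.frame(covariates),
      group = as.character(group), variantInfo = as.data.frame(variantInfo))
}

# expand a covariate data.frame to a design matrix (no intercept column);
# errors naming the collinear columns if the design is singular
.design_matrix <- function(covariates, n) {
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0)
    return(matrix(numeric(0), nrow = n, ncol = 0))
  X <- stats::model.matrix(~ ., data = as.data.frame(covariates))[, -1, drop = FALSE]
  full <- cbind(1, X)
  qrX <- qr(full)
  if (qrX$rank < ncol(full)) {
    dropped <- colnames(full)[qrX$pivot[(qrX$rank + 1):ncol(full)]]
    stop("singular covariate design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  X
}

#' Fully-adjusted two-stage rank normalization
#'
#' Stage 1 regresses the values on the covariates by ordinary least squares
#' and takes residuals r. Stage 2 applies the rank-based inverse-normal
#' transform with the Blom offset,
#' \deqn{z_i = \Phi^{-1}((\mathrm{rank}(r_i) - 3/8)/(n + 1/4)),}
#' using average ranks for ties, and rescales by the sample SD of r so the
#' transformed values keep the residual scale. Downstream association
#' models re-adjust for the same covariates (the "fully adjusted" variant).
#'
#' @param values numeric vector.
#' @param covariates optional data.frame (categoricals expanded to
#'   indicators).
#' @return numeric vector of transformed values.
#' @export
twoStageRankNormalize <- function(values, covariates = NULL) {
  n <- length(values)
  X <- .design_matrix(covariates, n)
  if (n <= ncol(X) + 1)
    stop("need more observations than covariate columns + 1", call. = FALSE)
  r <- if (ncol(X)) stats::lm.fit(cbind(1, X), values)$residuals else
    values - mean(values)
  z <- stats::qnorm((rank(r, ties.method = "average") - 3 / 8) / (n + 1 / 4))
  z * stats::sd(r)
}

#' Per-variant association statistics from individual-level data
#'
#' Computes the IV-side summary statistics one-sample MR consumes. An
#' expression target is preprocessed by replacing zero counts with half the
#' minimum positive observed value, log-transforming, and applying
#' \code{\link{twoStageRankNormalize}} with the covariates; a phenotype
#' target is rank-normalized directly. The transformed target is then
#' regressed on each listed variant's dosage jointly with the covariates, and the
#' dosage coefficient's estimate, SE and p-value are reported. Monomorphic
#' variants are skipped with a log entry.
#'
#' @param data an \linkS4class{IndividualDataset}.
#' @param variants variant ids (columns of the genotype matrix).
#' @param target a gene (expression column) or trait (phenotype column).
#' @param covariates character vector of covariate column names (default:
#'   all covariate columns).
#' @param log_transform_expression log-transform expression targets
#'   (default TRUE).
#' @param samples optional logical/integer subset of samples (for
#'   stratified runs).
#' @param verbose report skipped variants.
#' @return data.frame: variant_id, target, beta, se, pvalue, n.
#' @export
computeAssociations <- function(data, variants, target,
                                covariates = colnames(data@covariates),
                                log_transform_expression = TRUE,
                                samples = NULL, verbose = TRUE) {
  idx <- if (is.null(samples)) seq_len(nrow(data@genotypes)) else samples
  geno <- data@genotypes[idx, , drop = FALSE]
  covs <- if (length(covariates))
    data@covariates[idx, covariates, drop = FALSE] else NULL
  # drop covariate columns constant within the analysis stratum
  if (!is.null(covs)) {
    keep <- vapply(covs, function(v) length(unique(v)) > 1, logical(1))
    covs <- covs[, keep, drop = FALSE]
    if (!ncol(covs)) covs <- NULL
  }

  if (target %in% colnames(data@expression)) {
    y <- data@expression[idx, target]
    if (log_transform_expression) {
      pos <- y[y > 0]
      if (!length(pos))
        stop("expression target '", target, "' has no positive values",
             call. = FALSE)
      y[y <= 0] <- min(pos) / 2
      y <- log(y)
    }
  } else if (target %in% colnames(data@phenotypes)) {
    y <- data@phenotypes[idx, target]
  } else {
    stop("target '", target, "' not found in expression or phenotypes",
         call. = FALSE)
  }
  y <- twoStageRankNormalize(y, covs)
  X <- .design_matrix(covs, length(y))

  rows <- lapply(variants, function(v) {
    if (!v %in% colnames(geno))
      stop("variant '", v, "' absent from genotype matrix", call. = FALSE)
    g <- geno[, v]
    if (stats::sd(g) == 0) {
      .msg("computeAssociations: %s monomorphic in stratum; skipped", v,
           verbose = verbose)
      return(NULL)
    }
    D <- cbind(1, g, X)
    fit <- stats::lm.fit(D, y)
    res <- fit$residuals
    df <- length(y) - fit$rank
    sigma2 <- sum(res^2) / df
    XtXinv <- chol2inv(chol(crossprod(D)))
    se <- sqrt(sigma2 * XtXinv[2, 2])
    beta <- fit$coefficients[2]
    p <- 2 * stats::pt(-abs(beta / se), df = df)
    data.frame(variant_id = v, target = target, beta = beta, se = se,
               pvalue = max(p, .Machine$double.xmin), n = length(y),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(variant_id = character(0), target = character(0),
                      beta = numeric(0), se = numeric(0), pvalue = numeric(0),
                      n = integer(0))
  rownames(out) <- NULL
  out
}

#' Summary-level one-sample MR
#'
#' Pairs per-variant IV-exposure and IV-outcome association statistics
#' (computed from the same genotype matrix, so allele orientation is shared
#' by construction) and delegates to the two-sample estimators: IVW for two
#' or more shared variants, the Wald ratio for a single one.
#'
#' @param exposure_assocs data.frame from \code{\link{computeAssociations}}
#'   for the exposure side.
#' @param outcome_assocs data.frame for the outcome side.
#' @param instruments optional variant ids restricting the analysis.
#' @param dispersion IVW dispersion model.
#' @return list with the estimate fields plus the heterogeneity half from
#'   IVW (cochran_q etc.) when applicable.
#' @export
oneSampleMr <- function(exposure_assocs, outcome_assocs, instruments = NULL,
                        dispersion = "mre") {
  shared <- intersect(exposure_assocs$variant_id, outcome_assocs$variant_id)
  if (!is.null(instruments)) shared <- intersect(shared, instruments)
  if (!length(shared))
    stop("no shared variants between exposure and outcome associations",
         call. = FALSE)
  ex <- exposure_assocs[match(shared, exposure_assocs$variant_id), ]
  ou <- outcome_assocs[match(shared, outcome_assocs$variant_id), ]
  h <- data.frame(variant_id = shared, b_X = ex$beta, se_X = ex$se,
                  b_Y = ou$beta, se_Y = ou$se, stringsAsFactors = FALSE)
  if (nrow(h) >= 2) mrIVW(h, dispersion = dispersion) else waldRatio(h)
}
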