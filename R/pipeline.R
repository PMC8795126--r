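# Orchestration: the pathways x outcomes discovery grid, the multiple-testing
# rule, the sensitivity battery for flagged pathways, gene/tissue
# decomposition, one-sample validation and the outcome screen.

#' Effective number of independent traits
#'
#' Li–Ji eigenvalue count for correlated outcomes: with eigenvalues
#' \eqn{\lambda_i} of the trait correlation matrix,
#' \deqn{M_{eff} = \sum_i [ 1(\lambda_i \ge 1) + (\lambda_i -
#' \lfloor \lambda_i \rfloor) ].}
#' An identity matrix gives the trait count; perfectly correlated traits
#' collapse to one.
#'
#' @param trait_correlations square symmetric correlation matrix with unit
#'   diagonal.
#' @return list with \code{meff} (unrounded) and \code{meff_floor}
#'   (rounded down, used for thresholding; never below 1).
#' @export
effectiveTests <- function(trait_correlations) {
  C <- as.matrix(trait_correlations)
  if (nrow(C) != ncol(C) || !isSymmetric(C, tol = 1e-8))
    stop("trait correlation matrix must be square and symmetric",
         call. = FALSE)
  if (any(abs(diag(C) - 1) > 1e-8))
    stop("trait correlation matrix must have unit diagonal", call. = FALSE)
  lambda <- pmax(eigen(C, symmetric = TRUE, only.values = TRUE)$values, 0)
  meff <- sum(ifelse(lambda >= 1, 1, 0) + (lambda - floor(lambda)))
  list(meff = meff, meff_floor = max(1L, as.integer(floor(meff))))
}

#' Multiple-testing significance threshold
#'
#' \code{alpha / (effective_traits * n_pathways)}: the family-wise level
#' divided by the number of effectively independent outcome traits times
#' the number of pathways tested. With 2 effective traits and 4 pathways at
#' alpha 0.05 this gives 6.25e-3.
#'
#' @param alpha family-wise level.
#' @param effective_traits effectively independent outcome count.
#' @param n_pathways pathways tested in the family.
#' @return the per-test threshold.
#' @export
significanceThreshold <- function(alpha, effective_traits, n_pathways) {
  if (alpha <= 0 || effective_traits <= 0 || n_pathways <= 0)
    stop("alpha, effective_traits and n_pathways must all be positive",
         call. = FALSE)
  alpha / (effective_traits * n_pathways)
}

#' Z-score correlation between outcome GWAS
#'
#' Spearman correlation of per-variant z-scores across the variants shared
#' by all supplied GWAS tables — a summary-level stand-in for the phenotype
#' correlation matrix when individual-level traits are unavailable.
#'
#' @param gwas_list named list of GWAS data.frames.
#' @return correlation matrix with unit diagonal.
#' @export
traitZCorrelation <- function(gwas_list) {
  shared <- Reduce(intersect, lapply(gwas_list, function(g) g$variant_id))
  if (length(shared) < 3)
    stop("fewer than 3 variants shared across outcome tables", call. = FALSE)
  Z <- vapply(gwas_list, function(g) {
    g <- g[match(shared, g$variant_id), ]
    g$beta / g$se
  }, numeric(length(shared)))
  C <- stats::cor(Z, method = "spearman")
  diag(C) <- 1
  C
}

#' Assemble a discovery run configuration
#'
#' Inputs may be in-memory objects or file paths (read through the
#' summary_io readers). Thresholds default to the pipeline's standard
#' settings: cis-eQTL p < 1e-5 within 1 Mb of the TSS, clumping at
#' r2 < 0.01, proxy substitution at r2 > 0.8, family-wise alpha 0.05.
#'
#' @param eqtl eQTL table (data.frame) or path.
#' @param gwas named list of outcome GWAS tables or paths.
#' @param pathways pathway list (as from \code{\link{readGmt}}) or GMT path.
#' @param ld \linkS4class{LdReference}, pairwise-table data.frame, or path
#'   to a pairwise TSV.
#' @param variant_info optional data.frame/path with variant_id, chrom for
#'   the LD chromosome shortcut.
#' @param eqtl_p,cis_window,clump_r2,proxy_r2,alpha analysis thresholds.
#' @param palindromic_eaf_band ambiguity band for palindromic variants.
#' @param trait_cor optional trait correlation matrix; computed from
#'   z-scores when absent and more than one outcome is supplied.
#' @param ivw_dispersion "mre" or "fixed".
#' @param presso_nsim MR-PRESSO replicates.
#' @param seed run-level seed (drives all simulation substreams).
#' @param out_dir optional directory for the result tables.
#' @param force_battery run the sensitivity battery for every pathway, not
#'   just flagged ones.
#' @param verbose emit progress messages.
#' @return a RunConfig list.
#' @export
runConfig <- function(eqtl, gwas, pathways, ld, variant_info = NULL,
                      eqtl_p = 1e-5, cis_window = 1e6, clump_r2 = 0.01,
                      proxy_r2 = 0.8, alpha = 0.05,
                      palindromic_eaf_band = 0.08, trait_cor = NULL,
                      ivw_dispersion = "mre", presso_nsim = 1000, seed = 0,
                      out_dir = NULL, force_battery = FALSE, verbose = FALSE) {
  stopifnot(eqtl_p > 0, eqtl_p <= 1, clump_r2 > 0, clump_r2 <= 1,
            proxy_r2 >= 0, proxy_r2 <= 1, alpha > 0, alpha <= 1,
            cis_window > 0, presso_nsim >= 100)
  structure(list(
    eqtl = eqtl, gwas = gwas, pathways = pathways, ld = ld,
    variant_info = variant_info, eqtl_p = eqtl_p, cis_window = cis_window,
    clump_r2 = clump_r2, proxy_r2 = proxy_r2, alpha = alpha,
    palindromic_eaf_band = palindromic_eaf_band, trait_cor = trait_cor,
    ivw_dispersion = ivw_dispersion, presso_nsim = presso_nsim, seed = seed,
    out_dir = out_dir, force_battery = force_battery, verbose = verbose),
    class = "RunConfig")
}

.load_table <- function(x, reader) if (is.character(x)) reader(x) else x

.load_inputs <- function(config) {
  eqtl <- .load_table(config$eqtl, function(p)
    readEqtlTable(p, verbose = config$verbose))
  gwas <- lapply(config$gwas, function(g)
    .load_table(g, function(p) readGwasTable(p, verbose = config$verbose)))
  pathways <- if (is.character(config$pathways)) readGmt(config$pathways) else
    config$pathways
  vinfo <- if (is.character(config$variant_info))
    as.data.frame(data.table::fread(config$variant_info)) else
      config$variant_info
  ld <- config$ld
  if (is.character(ld)) ld <- as.data.frame(data.table::fread(ld))
  if (!is(ld, "LdReference")) ld <- buildLdReference(ld, vinfo)
  list(eqtl = eqtl, gwas = gwas, pathways = pathways, ld = ld)
}

.fit_grid_row <- function(h, dispersion) {
  if (nrow(h) == 0)
    return(list(method = NA_character_, beta = NA_real_, se = NA_real_,
                pvalue = NA_real_, nsnp = 0L))
  if (nrow(h) == 1) waldRatio(h) else mrIVW(h, dispersion = dispersion)
}

#' Run the two-sample discovery analysis
#'
#' For each pathway: build the cross-tissue instrument set (per-gene top
#' cis-eQTLs, pathway union, LD clumping), harmonize against each outcome
#' GWAS (with proxy substitution), and estimate the causal effect by IVW
#' (Wald ratio for a single instrument). Pathway-outcome pairs whose IVW p
#' falls below \code{\link{significanceThreshold}} — computed from the
#' Li–Ji effective trait count — are flagged, and flagged pathways receive
#' the full sensitivity battery (Egger, Q, Q', mean F, I2_GX,
#' leave-one-out, MR-PRESSO) plus per-gene and per-tissue decomposition.
#'
#' @param config a \code{\link{runConfig}} list.
#' @return a DiscoveryReport list: \code{grid} (one row per pathway x
#'   outcome, including nsnp = 0 rows), \code{threshold}, \code{meff},
#'   \code{battery}, \code{leave_one_out}, \code{gene_mr},
#'   \code{tissue_mr}, \code{instruments}, \code{instrument_report},
#'   \code{drops}.
#' @export
runDiscovery <- function(config) {
  inp <- .load_inputs(config)
  eqtl <- cisFilter(inp$eqtl, window = config$cis_window)
  gwas <- inp$gwas
  if (is.null(names(gwas)) || any(!nzchar(names(gwas))))
    stop("outcome GWAS list must be named", call. = FALSE)

  # pathway instrument sets
  sets <- list(); gene_sets <- list()
  for (pw in names(inp$pathways)) {
    genes <- inp$pathways[[pw]]$gene_ids
    gs <- lapply(genes, function(g)
      selectGeneIVs(eqtl[eqtl$gene_id == g, , drop = FALSE],
                    p_threshold = config$eqtl_p))
    gs <- gs[vapply(gs, nInstruments, integer(1)) > 0]
    gene_sets[[pw]] <- gs
    sets[[pw]] <- selectPathwayIVs(gs, inp$ld, clump_r2 = config$clump_r2,
                                   label = pw)
    .msg("pathway %s: %d genes with instruments, %d clumped IVs", pw,
         length(gs), nInstruments(sets[[pw]]), verbose = config$verbose)
  }

  # multiple-testing rule
  C <- config$trait_cor
  if (is.null(C) && length(gwas) > 1)
    C <- traitZCorrelation(gwas)
  meff <- if (is.null(C)) list(meff = 1, meff_floor = 1L) else
    effectiveTests(C)
  threshold <- significanceThreshold(config$alpha, meff$meff_floor,
                                     length(inp$pathways))

  # discovery grid
  grid <- list(); harm <- list(); drops <- list(); report <- list()
  for (pw in names(sets)) {
    harm[[pw]] <- list()
    for (oc in names(gwas)) {
      h <- harmonizeInstruments(sets[[pw]], gwas[[oc]], ld = inp$ld,
                                palindromic_eaf_band = config$palindromic_eaf_band,
                                proxy_r2 = config$proxy_r2)
      harm[[pw]][[oc]] <- h
      d <- attr(h, "drops")
      if (nrow(d)) {
        d$exposure <- pw; d$outcome <- oc
        drops[[paste(pw, oc)]] <- d
      }
      fit <- .fit_grid_row(h, config$ivw_dispersion)
      grid[[paste(pw, oc)]] <- data.frame(
        exposure = pw, outcome = oc, method = fit$method, nsnp = fit$nsnp,
        beta = fit$beta, se = fit$se, pvalue = fit$pvalue,
        stringsAsFactors = FALSE)
      if (nrow(h)) {
        rep_rows <- data.frame(
          variant_id = h$variant_id, gene_id = h$gene_id, tissue = h$tissue,
          b_X = h$b_X, se_X = h$se_X, pvalue_X = h$pvalue_X, b_Y = h$b_Y,
          se_Y = h$se_Y, proxy_of = h$proxy_of, exposure = pw, outcome = oc,
          drop_reason = "", stringsAsFactors = FALSE)
        report[[paste(pw, oc)]] <- rep_rows
      }
    }
  }
  grid <- do.call(rbind, grid); rownames(grid) <- NULL
  grid$flag <- !is.na(grid$pvalue) & grid$pvalue < threshold
  drops <- if (length(drops)) do.call(rbind, drops) else
    data.frame(variant_id = character(0), reason = character(0),
               exposure = character(0), outcome = character(0))
  rownames(drops) <- NULL

  flagged <- unique(grid$exposure[grid$flag])
  if (config$force_battery) flagged <- names(sets)

  battery <- list(); loo <- list(); gene_mr <- list(); tissue_mr <- list()
  for (pw in flagged) {
    for (oc in names(gwas)) {
      h <- harm[[pw]][[oc]]
      if (nrow(h) >= 3) {
        battery[[paste(pw, oc)]] <- sensitivityBattery(
          h, outcome = oc, exposure = pw,
          dispersion = config$ivw_dispersion,
          presso_nsim = config$presso_nsim,
          seed = .substream(config$seed, paste("presso", pw, oc)))
        l <- leaveOneOut(h, dispersion = config$ivw_dispersion)
        l$exposure <- pw; l$outcome <- oc
        loo[[paste(pw, oc)]] <- l
      }
      # per-gene decomposition: each gene's (clumped) instruments alone
      for (gs in gene_sets[[pw]]) {
        gh <- harmonizeInstruments(
          clumpInstruments(gs, inp$ld, config$clump_r2), gwas[[oc]],
          ld = inp$ld, palindromic_eaf_band = config$palindromic_eaf_band,
          proxy_r2 = config$proxy_r2)
        if (!nrow(gh)) next
        fit <- .fit_grid_row(gh, config$ivw_dispersion)
        gene_mr[[paste(pw, oc, gs@label)]] <- data.frame(
          exposure = pw, outcome = oc, group = gs@label, method = fit$method,
          nsnp = fit$nsnp, beta = fit$beta, se = fit$se, pvalue = fit$pvalue,
          stringsAsFactors = FALSE)
      }
      # per-tissue decomposition: column-wise selection then MR
      pw_eqtl <- eqtl[eqtl$gene_id %in% inp$pathways[[pw]]$gene_ids, ,
                      drop = FALSE]
      for (tis in unique(pw_eqtl$tissue)) {
        ts <- selectTissueIVs(pw_eqtl[pw_eqtl$tissue == tis, , drop = FALSE],
                              p_threshold = config$eqtl_p, ld = inp$ld,
                              clump_r2 = config$clump_r2)
        if (!nInstruments(ts)) next
        th <- harmonizeInstruments(ts, gwas[[oc]], ld = inp$ld,
                                   palindromic_eaf_band = config$palindromic_eaf_band,
                                   proxy_r2 = config$proxy_r2)
        if (!nrow(th)) next
        fit <- .fit_grid_row(th, config$ivw_dispersion)
        tissue_mr[[paste(pw, oc, tis)]] <- data.frame(
          exposure = pw, outcome = oc, group = tis, method = fit$method,
          nsnp = fit$nsnp, beta = fit$beta, se = fit$se, pvalue = fit$pvalue,
          stringsAsFactors = FALSE)
      }
    }
  }
  bind <- function(x) if (length(x)) {
    r <- do.call(rbind, x); rownames(r) <- NULL; r
  } else NULL

  out <- list(grid = grid, threshold = threshold, meff = meff,
              flagged = flagged, battery = bind(battery),
              leave_one_out = bind(loo), gene_mr = bind(gene_mr),
              tissue_mr = bind(tissue_mr), instruments = sets,
              instrument_report = bind(report), drops = drops,
              seed = config$seed)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    writeResultsTable(grid, file.path(config$out_dir, "discovery_grid.tsv"))
    if (!is.null(out$battery))
      writeResultsTable(out$battery, file.path(config$out_dir,
                                               "sensitivity_battery.tsv"))
    for (nm in c("gene_mr", "tissue_mr")) {
      if (!is.null(out[[nm]]))
        data.table::fwrite(out[[nm]], file.path(config$out_dir,
                                                paste0(nm, ".tsv")),
                           sep = "\t", quote = FALSE, na = "NA")
    }
    if (!is.null(out$instrument_report))
      data.table::fwrite(out$instrument_report,
                         file.path(config$out_dir, "instrument_report.tsv"),
                         sep = "\t", quote = FALSE, na = "NA")
    data.table::fwrite(drops, file.path(config$out_dir, "drops.tsv"),
                       sep = "\t", quote = FALSE, na = "NA")
    jsonlite::write_json(
      list(threshold = threshold, meff = meff$meff, flagged = flagged,
           seed = config$seed),
      file.path(config$out_dir, "results.json"), auto_unbox = TRUE,
      digits = NA, pretty = TRUE)
  }
  out
}

#' One-sample validation of discovery instruments
#'
#' Recomputes IV-exposure associations (each instrument against its gene's
#' expression, log-transformed and two-stage rank-normalized) and
#' IV-outcome associations from an individual-level dataset, then runs
#' summary-level IVW per outcome — pooled and, when the dataset carries
#' stratum labels, within each stratum (dropping the stratum indicator from
#' the covariates). Instruments absent from the genotype matrix are listed
#' and the run proceeds with the remainder.
#'
#' @param dataset an \linkS4class{IndividualDataset}.
#' @param instruments data.frame with variant_id and gene_id (the same IVs
#'   used in discovery).
#' @param outcomes phenotype column names (default: all).
#' @param covariates covariate column names (default: all).
#' @param discovery optional discovery grid (data.frame with outcome, beta)
#'   for a direction-concordance summary.
#' @param dispersion IVW dispersion model.
#' @param verbose emit messages.
#' @return list: \code{estimates} (outcome x stratum rows),
#'   \code{concordance} (when discovery estimates supplied),
#'   \code{missing_instruments}.
#' @export
runValidation <- function(dataset, instruments,
                          outcomes = colnames(dataset@phenotypes),
                          covariates = colnames(dataset@covariates),
                          discovery = NULL, dispersion = "mre",
                          verbose = FALSE) {
  present <- instruments$variant_id %in% colnames(dataset@genotypes)
  missing <- instruments$variant_id[!present]
  if (length(missing))
    .msg("runValidation: %d instrument(s) absent from genotypes: %s",
         length(missing), paste(missing, collapse = ", "), verbose = verbose)
  instruments <- instruments[present, , drop = FALSE]
  if (!nrow(instruments))
    stop("no instruments present in the genotype matrix", call. = FALSE)

  strata <- if (length(dataset@group)) unique(dataset@group) else character(0)
  runs <- c(list(pooled = NULL),
            stats::setNames(lapply(strata, function(s) dataset@group == s),
                            strata))

  rows <- list()
  for (run in names(runs)) {
    idx <- runs[[run]]
    # exposure associations: each SNP against its own gene's expression
    ex <- do.call(rbind, lapply(seq_len(nrow(instruments)), function(i)
      computeAssociations(dataset, instruments$variant_id[i],
                          instruments$gene_id[i], covariates = covariates,
                          samples = idx, verbose = verbose)))
    for (oc in outcomes) {
      ou <- computeAssociations(dataset, instruments$variant_id, oc,
                                covariates = covariates, samples = idx,
                                verbose = verbose)
      fit <- tryCatch(
        oneSampleMr(ex, ou, dispersion = dispersion),
        error = function(e) NULL)
      if (is.null(fit)) next
      rows[[paste(run, oc)]] <- data.frame(
        outcome = oc, stratum = run, method = fit$method, nsnp = fit$nsnp,
        beta = fit$beta, se = fit$se, pvalue = fit$pvalue,
        stringsAsFactors = FALSE)
    }
  }
  est <- do.call(rbind, rows); rownames(est) <- NULL

  concordance <- NULL
  if (!is.null(discovery)) {
    pooled <- est[est$stratum == "pooled", ]
    shared <- intersect(pooled$outcome, discovery$outcome)
    if (length(shared)) {
      d <- discovery[match(shared, discovery$outcome), ]
      v <- pooled[match(shared, pooled$outcome), ]
      concordance <- data.frame(
        outcome = shared, discovery_beta = d$beta, validation_beta = v$beta,
        concordant = sign(d$beta) == sign(v$beta), stringsAsFactors = FALSE)
    }
  }
  list(estimates = est, concordance = concordance,
       missing_instruments = missing)
}

#' Screen a pathway's instruments against additional outcomes
#'
#' Runs the IVW and MR-Egger pair for each user-supplied extra outcome GWAS
#' (e.g. blood disorders, blood-cell traits, comorbidities). A missing file
#' is skipped with a log entry and the remaining outcomes are processed.
#'
#' @param instruments an \linkS4class{InstrumentSet} (pathway-level).
#' @param extra_gwas named list of GWAS data.frames or file paths.
#' @param ld an \linkS4class{LdReference}.
#' @param config optional \code{\link{runConfig}}-style list for thresholds
#'   (palindromic band, proxy r2, dispersion).
#' @return data.frame with one IVW and one Egger-slope row per outcome.
#' @export
runOutcomeScreen <- function(instruments, extra_gwas, ld, config = NULL) {
  band <- if (is.null(config)) 0.08 else config$palindromic_eaf_band
  pr2 <- if (is.null(config)) 0.8 else config$proxy_r2
  disp <- if (is.null(config)) "mre" else config$ivw_dispersion
  rows <- list()
  for (oc in names(extra_gwas)) {
    g <- extra_gwas[[oc]]
    if (is.character(g)) {
      if (!file.exists(g)) {
        message("runOutcomeScreen: file missing for '", oc, "'; skipped")
        next
      }
      g <- readGwasTable(g, verbose = FALSE)
    }
    h <- harmonizeInstruments(instruments, g, ld = ld,
                              palindromic_eaf_band = band, proxy_r2 = pr2)
    if (!nrow(h)) next
    fit <- .fit_grid_row(h, disp)
    rows[[paste(oc, "ivw")]] <- data.frame(
      exposure = instruments@label, outcome = oc, method = fit$method,
      nsnp = fit$nsnp, beta = fit$beta, se = fit$se, pvalue = fit$pvalue,
      stringsAsFactors = FALSE)
    if (nrow(h) >= 3) {
      eg <- mrEgger(h)
      rows[[paste(oc, "egger")]] <- data.frame(
        exposure = instruments@label, outcome = oc,
        method = "egger_slope", nsnp = eg$nsnp, beta = eg$slope$beta,
        se = eg$slope$se, pvalue = eg$slope$pvalue, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(exposure = character(0), outcome = character(0),
                      method = character(0), nsnp = integer(0),
                      beta = numeric(0), se = numeric(0),
                      pvalue = numeric(0))
  rownames(out) <- NULL
  out
}
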