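#' Benjamini-Hochberg FDR rejection flags
#'
#' Step-up procedure at level q: with sorted p-values `p_(1) <= ... <=
#' p_(m)`, reject the hypotheses with the `k*` smallest p-values where
#' `k* = max { k : p_(k) <= q k / m }`; tied p-values are rejected
#' together. Implemented through the adjusted p-values of
#' [stats::p.adjust()], which realize the same rule. Flags depend only on
#' the p-value multiset (permutation invariant).
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @param q Target false discovery rate (default 0.05).
#' @return Logical rejection flags, aligned with the input.
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  stats::p.adjust(pvalues, method = "BH") <= q
}

#' Study configuration for the MR pipeline
#'
#' Binds dataset files to design roles and collects the analysis
#' thresholds. All thresholds default to the values used throughout the
#' pipeline: clumping at r2 < 0.001 within 10 Mb; genome-wide univariable
#' instrument selection (no p-value truncation); multivariable instrument
#' p-value ceiling 1e-4 on the minimum across exposures; marker filters
#' (trait meta p <= 5e-8, CAD p <= 0.05, LDL-C/ApoB p >= 1e-3);
#' genetic-correlation screening threshold 0.8; FDR 0.05.
#'
#' @param datasets Named list; each element a list with at least `path`
#'   and `trait`, plus optional `name`, `overlap_tags`, `trait_scale`,
#'   `population`, `columns` (column map overrides).
#' @param roles Named list mapping design roles (`selection`, `exposure`,
#'   `outcome`, ...) to dataset names.
#' @param traits Optional list with `subfractions` and `reference` trait
#'   vectors.
#' @param ld_panel Optional list with `meta` and `cor` file paths.
#' @param thresholds Named overrides of the defaults.
#' @param seed Integer seed.
#' @return List of class `study_config`.
#' @export
study_config <- function(datasets = list(), roles = list(), traits = list(),
                         ld_panel = NULL, thresholds = list(), seed = 1) {
  defaults <- list(clump_r2 = 0.001, clump_window_bp = 1e7,
                   selection_p = NULL, mvmr_selection_p = 1e-4,
                   marker_trait_p = 5e-8, marker_cad_p = 0.05,
                   marker_ldl_p = 1e-3, rg_threshold = 0.8, fdr_q = 0.05)
  bad <- setdiff(names(thresholds), names(defaults))
  if (length(bad) > 0) stop("unknown thresholds: ", paste(bad, collapse = ", "))
  defaults[names(thresholds)] <- thresholds
  num <- !vapply(defaults, is.null, logical(1))
  if (any(unlist(defaults[num]) <= 0)) stop("thresholds must be positive")
  structure(list(datasets = datasets, roles = roles, traits = traits,
                 ld_panel = ld_panel, thresholds = defaults,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Read a study configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [study_config()]. Dataset paths
#' are resolved relative to the config file's directory. Every referenced
#' file must exist.
#'
#' @param path Path to the YAML config.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (is.null(p) || file.exists(p)) p else file.path(base, p)
  for (nm in names(cfg$datasets)) {
    cfg$datasets[[nm]]$path <- resolve(cfg$datasets[[nm]]$path)
    if (!file.exists(cfg$datasets[[nm]]$path))
      stop("dataset file not found: ", cfg$datasets[[nm]]$path)
  }
  if (!is.null(cfg$ld_panel)) {
    cfg$ld_panel$meta <- resolve(cfg$ld_panel$meta)
    cfg$ld_panel$cor <- resolve(cfg$ld_panel$cor)
    if (!file.exists(cfg$ld_panel$meta) || !file.exists(cfg$ld_panel$cor))
      stop("LD panel files not found")
  }
  study_config(datasets = cfg$datasets %||% list(), roles = cfg$roles %||% list(),
               traits = cfg$traits %||% list(), ld_panel = cfg$ld_panel,
               thresholds = cfg$thresholds %||% list(), seed = cfg$seed %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a configured dataset
#'
#' @param config A `study_config`.
#' @param dataset_name Name of the dataset entry.
#' @return A [summary_dataset()].
#' @export
load_dataset <- function(config, dataset_name) {
  d <- config$datasets[[dataset_name]]
  if (is.null(d)) stop("dataset '", dataset_name, "' not in config")
  cmap <- do.call(default_column_map, as.list(unlist(d$columns %||% list())))
  read_summary(d$path, column_map = cmap, trait = d$trait,
               name = d$name %||% dataset_name,
               population = d$population %||% NA_character_,
               overlap_tags = unlist(d$overlap_tags %||% character()),
               trait_scale = d$trait_scale %||% "per-SD")
}

#' Univariable genome-wide MR analysis
#'
#' The full three-sample univariable workflow: validate the design (the
#' selection GWAS must be sample-disjoint from both estimation GWAS),
#' clump the selection GWAS with no p-value truncation (genome-wide mode,
#' unless `p_max` is set), harmonize the three datasets at the selected
#' instruments, then fit RAPS (primary) plus IVW and weighted-median
#' (sensitivity), with the modified Cochran's Q and residual diagnostics
#' attached. Every filtering step's SNP count is logged in `funnel`.
#'
#' @param selection,exposure,outcome [summary_dataset()]s.
#' @param panel An [ld_panel()] for clumping.
#' @param r2_max,window_bp,p_max Clumping thresholds (see [ld_clump()]).
#' @param loss [robust_loss()] for RAPS.
#' @param palindromic_policy Passed to [harmonize()].
#' @param diagnostics Compute residual diagnostics (default TRUE).
#' @param seed Seed for the weighted-median bootstrap.
#' @return List of class `mr_analysis`: `raps`, `ivw`, `weighted_median`,
#'   `q` (at the RAPS estimate), `diagnostics`, `input`, `design`,
#'   `funnel` (named SNP counts), `low_instruments` flag.
#' @export
run_univariable <- function(selection, exposure, outcome, panel,
                            r2_max = 0.001, window_bp = 1e7, p_max = NULL,
                            loss = robust_loss("huber"),
                            palindromic_policy = "drop", diagnostics = TRUE,
                            seed = 1) {
  design <- validate_three_sample(selection, exposure, outcome,
                                  estimator_allows_overlap = FALSE)
  clumped <- ld_clump(selection, panel, r2_max = r2_max, window_bp = window_bp,
                      p_max = p_max)
  htab <- harmonize(list(exposure, outcome), palindromic_policy = palindromic_policy)
  keep <- htab$snp_ids %in% clumped$snp_id
  idx <- which(keep)
  funnel <- c(selection_snps = nrow(selection$records), clumped = nrow(clumped),
              harmonized = length(htab$snp_ids), analyzed = length(idx))
  if (length(idx) < 3) stop("fewer than 3 instruments survive; funnel: ",
                            paste(names(funnel), funnel, collapse = ", "))
  sel_p <- clumped$pval[match(htab$snp_ids[idx], clumped$snp_id)]
  input <- mr_input(htab$beta[idx, 1], htab$se[idx, 1],
                    htab$beta[idx, 2], htab$se[idx, 2],
                    snp_id = htab$snp_ids[idx], selection_pval = sel_p,
                    datasets = c(selection = selection$name,
                                 exposure = exposure$name, outcome = outcome$name))
  low <- input$n_snps < 10
  if (low) warning("only ", input$n_snps, " instruments; results flagged low-instrument")
  raps <- mr_raps(input, loss = loss)
  ivw <- mr_ivw(input)
  wm <- if (input$n_snps >= 3) mr_weighted_median(input, seed = seed) else NULL
  q <- cochran_q(input, raps$beta)
  diag_b <- if (diagnostics) residual_diagnostics(input, raps, loss = loss) else NULL
  structure(list(raps = raps, ivw = ivw, weighted_median = wm, q = q,
                 diagnostics = diag_b, input = input, design = design,
                 funnel = funnel, low_instruments = low),
            class = "mr_analysis")
}

#' Select multivariable MR instruments by minimum p-value
#'
#' Ranks each SNP by its minimum selection p-value across the exposures,
#' keeps SNPs with rank key at or below `p_max`, and clumps in rank-key
#' order with the standard thresholds.
#'
#' @param selection_datasets List of [summary_dataset()]s, one per
#'   exposure, from the selection GWAS.
#' @param panel An [ld_panel()].
#' @param p_max Minimum-p ceiling (default 1e-4).
#' @param r2_max,window_bp Clumping thresholds.
#' @return The [ld_clump()] result over the min-p pseudo-statistics
#'   (pval = per-SNP minimum across exposures).
#' @export
select_mvmr_instruments <- function(selection_datasets, panel, p_max = 1e-4,
                                    r2_max = 0.001, window_bp = 1e7) {
  stopifnot(length(selection_datasets) >= 2)
  shared <- Reduce(intersect, lapply(selection_datasets, function(d) d$records$snp_id))
  if (length(shared) == 0) stop("no shared SNPs across selection datasets")
  pmin_tab <- do.call(pmin, lapply(selection_datasets, function(d) {
    d$records$pval[match(shared, d$records$snp_id)]
  }))
  ref <- selection_datasets[[1]]$records
  ref <- ref[match(shared, ref$snp_id), ]
  pseudo <- summary_dataset(data.frame(snp_id = shared, chrom = ref$chrom,
                                       pos = ref$pos,
                                       effect_allele = ref$effect_allele,
                                       other_allele = ref$other_allele,
                                       beta = ref$beta, se = ref$se,
                                       pval = pmin_tab, stringsAsFactors = FALSE),
                            trait = "min-p rank key", name = "mvmr_selection")
  out <- ld_clump(pseudo, panel, r2_max = r2_max, window_bp = window_bp,
                  p_max = p_max)
  if (nrow(out) == 0) stop("no SNP passes the multivariable selection threshold")
  out
}

#' Multivariable MR analysis
#'
#' The full multivariable workflow: instruments from
#' [select_mvmr_instruments()] on the selection datasets; exposure
#' associations from the estimation exposure datasets; outcome
#' associations from the outcome GWAS; noise-correlation matrix from the
#' genome-wide null SNPs of the harmonized estimation datasets (the
#' estimator therefore tolerates exposure-outcome sample overlap);
#' profile-likelihood fit by [grapple_fit()]; per-exposure instrument
#' strength by [modified_q()].
#'
#' @param selection_datasets List of [summary_dataset()]s (one per
#'   exposure) used for instrument selection; must be sample-disjoint from
#'   the estimation datasets.
#' @param exposure_datasets List of [summary_dataset()]s (one per
#'   exposure) for the instrument-exposure associations, in the exposure
#'   order of the analysis.
#' @param outcome [summary_dataset()] for the outcome.
#' @param panel An [ld_panel()].
#' @param p_max,r2_max,window_bp Selection thresholds.
#' @param loss,overdispersion Passed to [grapple_fit()].
#' @param palindromic_policy Passed to [harmonize()].
#' @return List of class `mvmr_analysis`: `estimate`, `q` (per-exposure
#'   modified Q table), `R` (noise correlation), `input`, `funnel`.
#' @export
run_multivariable <- function(selection_datasets, exposure_datasets, outcome,
                              panel, p_max = 1e-4, r2_max = 0.001,
                              window_bp = 1e7, loss = robust_loss("huber"),
                              overdispersion = TRUE, palindromic_policy = "drop") {
  for (sel in selection_datasets) {
    for (est in c(exposure_datasets, list(outcome))) {
      validate_three_sample(sel, est, outcome, estimator_allows_overlap = TRUE)
    }
  }
  instruments <- select_mvmr_instruments(selection_datasets, panel,
                                         p_max = p_max, r2_max = r2_max,
                                         window_bp = window_bp)
  htab <- harmonize(c(list(outcome), exposure_datasets),
                    palindromic_policy = palindromic_policy)
  # null SNPs judged by the sample-disjoint selection GWAS, so the
  # truncation is independent of the estimation datasets' noise
  sel_p <- Reduce(pmin, lapply(selection_datasets, function(d) {
    d$records$pval[match(htab$snp_ids, d$records$snp_id)]
  }))
  names(sel_p) <- htab$snp_ids
  R <- estimate_noise_correlation(htab, selection_pval = sel_p)
  idx <- which(htab$snp_ids %in% instruments$snp_id)
  K <- length(exposure_datasets)
  funnel <- c(candidates = nrow(instruments), harmonized = length(htab$snp_ids),
              analyzed = length(idx))
  if (length(idx) < K + 2) stop("fewer than K + 2 instruments survive")
  input <- mvmr_input(htab$beta[idx, -1, drop = FALSE],
                      htab$se[idx, -1, drop = FALSE],
                      htab$beta[idx, 1], htab$se[idx, 1], R = R,
                      snp_id = htab$snp_ids[idx],
                      selection_pval = instruments$pval[
                        match(htab$snp_ids[idx], instruments$snp_id)])
  est <- grapple_fit(input, loss = loss, overdispersion = overdispersion)
  q <- modified_q(input)
  structure(list(estimate = est, q = q, R = R, input = input, funnel = funnel),
            class = "mvmr_analysis")
}

#' Threshold-based genetic-marker discovery
#'
#' Finds independent SNPs associated with at least one target trait but
#' not with the LDL pathway, and with the disease: per target trait the
#' two lipidome GWAS are meta-analyzed by inverse-variance weighting; a
#' SNP passes when (i) its meta p-value is at or below `trait_p` for at
#' least one target trait, (ii) its disease p-value is at or below
#' `cad_p`, and (iii) its LDL-C and ApoB p-values are both at or above
#' `ldl_p` (a SNP missing from the disease or LDL/ApoB datasets cannot be
#' certified and is excluded, logged). Survivors are clumped to
#' independence by their minimum meta p-value.
#'
#' @param lipidome_a,lipidome_b Named lists of [summary_dataset()]s (one
#'   per target trait, same names) from the two lipidome GWAS.
#' @param cad,ldl,apob [summary_dataset()]s for the disease and the two
#'   LDL-pathway filters.
#' @param panel An [ld_panel()].
#' @param trait_p,cad_p,ldl_p Filter thresholds (defaults 5e-8, 0.05,
#'   1e-3).
#' @param r2_max,window_bp Clumping thresholds for marker independence.
#' @return data.frame of class `marker_hits`: one row per independent
#'   marker with per-trait meta z and p columns, disease beta and p,
#'   LDL-C and ApoB p, and the filter record.
#' @export
discover_markers <- function(lipidome_a, lipidome_b, cad, ldl, apob, panel,
                             trait_p = 5e-8, cad_p = 0.05, ldl_p = 1e-3,
                             r2_max = 0.001, window_bp = 1e7) {
  stopifnot(identical(names(lipidome_a), names(lipidome_b)))
  traits <- names(lipidome_a)
  metas <- lapply(traits, function(tr) meta_analyze_ivw(lipidome_a[[tr]], lipidome_b[[tr]]))
  names(metas) <- traits

  all_ids <- unique(unlist(lapply(metas, function(m) m$records$snp_id)))
  meta_p <- sapply(metas, function(m) {
    m$records$pval[match(all_ids, m$records$snp_id)]
  })
  meta_z <- sapply(metas, function(m) {
    r <- m$records[match(all_ids, m$records$snp_id), ]
    r$beta / r$se
  })
  min_meta_p <- apply(meta_p, 1, min, na.rm = TRUE)
  pass_trait <- apply(meta_p <= trait_p, 1, any, na.rm = TRUE)

  lookup <- function(ds, ids) ds$records[match(ids, ds$records$snp_id), ]
  cad_rec <- lookup(cad, all_ids)
  ldl_rec <- lookup(ldl, all_ids)
  apob_rec <- lookup(apob, all_ids)
  pass_cad <- !is.na(cad_rec$pval) & cad_rec$pval <= cad_p
  pass_ldl <- !is.na(ldl_rec$pval) & ldl_rec$pval >= ldl_p &
    !is.na(apob_rec$pval) & apob_rec$pval >= ldl_p
  pass <- pass_trait & pass_cad & pass_ldl

  if (!any(pass)) {
    out <- data.frame(snp_id = character(), stringsAsFactors = FALSE)
    class(out) <- c("marker_hits", class(out))
    return(out)
  }
  surv_ids <- all_ids[pass]
  first_meta <- metas[[1]]$records
  surv_rec <- first_meta[match(surv_ids, first_meta$snp_id), ]
  pseudo <- summary_dataset(
    data.frame(snp_id = surv_ids, chrom = surv_rec$chrom, pos = surv_rec$pos,
               effect_allele = surv_rec$effect_allele,
               other_allele = surv_rec$other_allele,
               beta = surv_rec$beta, se = surv_rec$se,
               pval = min_meta_p[pass], stringsAsFactors = FALSE),
    trait = "marker candidates", name = "markers")
  clumped <- ld_clump(pseudo, panel, r2_max = r2_max, window_bp = window_bp)
  hit_ids <- clumped$snp_id
  i <- match(hit_ids, all_ids)
  out <- data.frame(snp_id = hit_ids, stringsAsFactors = FALSE)
  for (tr in traits) {
    out[[paste0("z_", tr)]] <- meta_z[i, tr]
    out[[paste0("p_", tr)]] <- meta_p[i, tr]
  }
  out$cad_beta <- cad_rec$beta[i]
  out$cad_p <- cad_rec$pval[i]
  out$ldl_p <- ldl_rec$pval[i]
  out$apob_p <- apob_rec$pval[i]
  out$min_meta_p <- min_meta_p[i]
  class(out) <- c("marker_hits", class(out))
  out
}

#' Paired winner's-curse experiment
#'
#' Demonstrates why the three-sample design exists: on the same simulated
#' truth, instruments are selected at a p-value threshold either in the
#' same cohort whose estimates enter the MR (selection = exposure GWAS) or
#' in an independent cohort (three-sample split), and the IVW estimate is
#' computed against a common outcome GWAS. Selecting and estimating in one
#' cohort conditions on noise that inflates the selected exposure
#' associations (winner's curse), biasing the estimate; the split removes
#' the bias. Each replicate yields the paired absolute biases.
#'
#' @param n_reps Number of paired replicates.
#' @param panel An [ld_panel()] (default: 4,000 SNPs, 20-SNP blocks, so the
#'   instrument count keeps the paired estimator noise below the
#'   selection-induced bias being demonstrated).
#' @param beta True causal effect.
#' @param p_max Selection p-value threshold (default 1e-3). Winner's curse
#'   grows with the share of selections driven by sampling noise, so the
#'   demonstration uses a permissive threshold and a moderately sized
#'   selection cohort; stricter thresholds on larger cohorts show the same
#'   effect more weakly.
#' @param N Cohort size used for all cohorts (default 10,000).
#' @param seed Integer seed.
#' @param ... Passed to [simulate_three_sample_study()].
#' @return List: `bias_same`, `bias_split` (signed, per replicate),
#'   `fraction_split_smaller` (share of pairs with |bias_split| <
#'   |bias_same|).
#' @export
winners_curse_experiment <- function(n_reps = 200, panel = NULL, beta = 0.3,
                                     p_max = 1e-3, N = 10000, seed, ...) {
  if (is.null(panel)) panel <- simulate_ld_panel(M = 4000, block_size = 20, rho = 0.5)
  bias_same <- bias_split <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    study <- simulate_three_sample_study(panel, beta = beta, N = rep(N, 3),
                                         seed = seed + r, ...)
    run_ivw <- function(selection) {
      clumped <- ld_clump(selection, panel, p_max = p_max)
      htab <- harmonize(list(study$exposure, study$outcome))
      idx <- which(htab$snp_ids %in% clumped$snp_id)
      if (length(idx) < 2) return(NA_real_)
      mr_ivw(mr_input(htab$beta[idx, 1], htab$se[idx, 1],
                      htab$beta[idx, 2], htab$se[idx, 2]))$beta
    }
    bias_split[r] <- run_ivw(study$selection) - beta
    bias_same[r] <- run_ivw(study$exposure) - beta
  }
  ok <- !is.na(bias_same) & !is.na(bias_split)
  list(bias_same = bias_same, bias_split = bias_split,
       fraction_split_smaller = mean(abs(bias_split[ok]) < abs(bias_same[ok])))
}

#' Write an MR estimate table as tab-separated text
#'
#' Fixed column order: trait, method, beta, se, ci_low, ci_high, OR,
#' OR_ci_low, OR_ci_high, tau2, n_snps, Q, Q_pval.
#'
#' @param analyses Named list of `mr_analysis` objects (names = traits).
#' @param path Output file.
#' @return The assembled data.frame, invisibly.
#' @export
write_mr_estimates <- function(analyses, path) {
  rows <- lapply(names(analyses), function(tr) {
    a <- analyses[[tr]]
    ests <- Filter(Negate(is.null),
                   list(a$raps, a$ivw, a$weighted_median))
    do.call(rbind, lapply(ests, function(e) {
      data.frame(trait = tr, method = e$method, beta = e$beta, se = e$se,
                 ci_low = e$ci95[1], ci_high = e$ci95[2], OR = e$odds_ratio,
                 OR_ci_low = e$or_ci95[1], OR_ci_high = e$or_ci95[2],
                 tau2 = e$tau2, n_snps = e$n_snps, Q = a$q$Q, Q_pval = a$q$pval,
                 stringsAsFactors = FALSE)
    }))
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
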