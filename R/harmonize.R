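#' @keywords internal
flip_strand <- function(a) {
  chartr("ACGT", "TGCA", a)
}

is_palindromic <- function(ea, oa) flip_strand(ea) == oa

#' Harmonize summary datasets to a common effect allele
#'
#' Aligns two or more summary datasets on their shared SNPs so that every
#' effect is expressed per copy of the first dataset's effect allele. For
#' each non-reference dataset, alleles are compared directly and after
#' strand complementation (A<->T, C<->G); when effect and other alleles are
#' swapped relative to the reference the effect sign is flipped (and the
#' effect-allele frequency reflected). SNPs whose alleles cannot be matched
#' are dropped with a logged reason.
#'
#' Palindromic SNPs (A/T or G/C pairs), for which a strand flip is
#' indistinguishable from an allele swap, are dropped under the default
#' policy. Under `"keep_if_eaf_informative"` they are retained only when
#' every dataset reports an effect-allele frequency outside [0.42, 0.58]
#' and, after label alignment, all frequencies agree on which allele is the
#' minor one.
#'
#' @param datasets List of two or more [summary_dataset()] objects.
#' @param palindromic_policy `"drop"` (default) or `"keep_if_eaf_informative"`.
#' @return An object of class `harmonized_table`: list with `snp_ids`,
#'   `chrom`, `pos`, `effect_allele`, `other_allele` (reference
#'   orientation), matrices `beta`, `se`, `pval`, `n`, `eaf` (one column per
#'   trait, identical SNP order), `traits`, `names`, and `dropped`
#'   (data.frame of `snp_id`, `reason`).
#' @export
harmonize <- function(datasets, palindromic_policy = c("drop", "keep_if_eaf_informative")) {
  palindromic_policy <- match.arg(palindromic_policy)
  stopifnot(length(datasets) >= 2)
  lapply(datasets, function(d) stopifnot(inherits(d, "summary_dataset")))
  traits <- vapply(datasets, function(d) d$trait, character(1))
  dnames <- vapply(datasets, function(d) d$name, character(1))
  colnames_out <- make.unique(traits)

  shared <- Reduce(intersect, lapply(datasets, function(d) d$records$snp_id))
  if (length(shared) == 0) stop("no shared SNPs between datasets")

  ref <- datasets[[1]]$records
  ref <- ref[match(shared, ref$snp_id), ]
  K <- length(datasets)
  nsnp <- length(shared)
  beta <- se <- pval <- nmat <- eaf <- matrix(NA_real_, nsnp, K,
                                              dimnames = list(shared, colnames_out))
  beta[, 1] <- ref$beta; se[, 1] <- ref$se; pval[, 1] <- ref$pval
  nmat[, 1] <- ref$n; eaf[, 1] <- ref$eaf
  keep <- rep(TRUE, nsnp)
  reason <- rep(NA_character_, nsnp)

  for (k in seq_len(K)[-1]) {
    rec <- datasets[[k]]$records
    rec <- rec[match(shared, rec$snp_id), ]
    same <- rec$effect_allele == ref$effect_allele & rec$other_allele == ref$other_allele
    swap <- rec$effect_allele == ref$other_allele & rec$other_allele == ref$effect_allele
    fea <- flip_strand(rec$effect_allele); foa <- flip_strand(rec$other_allele)
    fsame <- fea == ref$effect_allele & foa == ref$other_allele
    fswap <- fea == ref$other_allele & foa == ref$effect_allele
    pal <- is_palindromic(ref$effect_allele, ref$other_allele)
    # for palindromic SNPs same==fswap and swap==fsame; treat as label match
    sign <- ifelse(same | (!pal & fsame), 1,
                   ifelse(swap | (!pal & fswap), -1,
                          ifelse(pal & (same | swap), ifelse(same, 1, -1), NA_real_)))
    mism <- is.na(sign)
    keep[mism] <- FALSE
    reason[mism & is.na(reason)] <- "allele_mismatch"
    beta[, k] <- sign * rec$beta
    se[, k] <- rec$se
    pval[, k] <- rec$pval
    nmat[, k] <- rec$n
    eaf[, k] <- ifelse(sign == 1, rec$eaf, 1 - rec$eaf)
  }

  pal <- is_palindromic(ref$effect_allele, ref$other_allele)
  if (any(pal)) {
    if (palindromic_policy == "drop") {
      bad <- pal & keep
      keep[bad] <- FALSE
      reason[bad] <- "palindromic"
    } else {
      informative <- rep(TRUE, nsnp)
      for (k in seq_len(K)) {
        informative <- informative & !is.na(eaf[, k]) &
          (eaf[, k] < 0.42 | eaf[, k] > 0.58)
      }
      minor_agree <- apply(eaf < 0.5, 1, function(r) all(r) || all(!r))
      minor_agree[is.na(minor_agree)] <- FALSE
      bad <- pal & keep & !(informative & minor_agree)
      keep[bad] <- FALSE
      reason[bad] <- "palindromic_uninformative_eaf"
    }
  }

  dropped <- data.frame(snp_id = shared[!keep], reason = reason[!keep],
                        stringsAsFactors = FALSE)
  idx <- which(keep)
  structure(list(snp_ids = shared[idx], chrom = ref$chrom[idx], pos = ref$pos[idx],
                 effect_allele = ref$effect_allele[idx],
                 other_allele = ref$other_allele[idx],
                 beta = beta[idx, , drop = FALSE], se = se[idx, , drop = FALSE],
                 pval = pval[idx, , drop = FALSE], n = nmat[idx, , drop = FALSE],
                 eaf = eaf[idx, , drop = FALSE],
                 traits = traits, names = dnames, dropped = dropped),
            class = "harmonized_table")
}

#' @export
print.harmonized_table <- function(x, ...) {
  cat("Harmonized table:", length(x$snp_ids), "SNPs x", length(x$traits),
      "traits (", paste(x$traits, collapse = ", "), ")\n")
  cat("  dropped:", nrow(x$dropped), "SNPs\n")
  invisible(x)
}

#' Convert one column of a harmonized table back to a summary dataset
#'
#' @param htab A `harmonized_table`.
#' @param k Column index.
#' @return A [summary_dataset()] in the harmonized (reference) orientation.
#' @export
harmonized_column <- function(htab, k) {
  stopifnot(inherits(htab, "harmonized_table"))
  summary_dataset(data.frame(snp_id = htab$snp_ids, chrom = htab$chrom,
                             pos = htab$pos, effect_allele = htab$effect_allele,
                             other_allele = htab$other_allele,
                             beta = htab$beta[, k], se = htab$se[, k],
                             pval = htab$pval[, k], n = htab$n[, k],
                             eaf = htab$eaf[, k], stringsAsFactors = FALSE),
                  trait = htab$traits[k], name = htab$names[k])
}

#' Write a harmonized table as tab-separated text
#'
#' @param htab A `harmonized_table`.
#' @param path Output path; the drop-log is written alongside as
#'   `<path>.droplog.tsv`.
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(htab, path) {
  df <- data.frame(snp_id = htab$snp_ids, chrom = htab$chrom, pos = htab$pos,
                   effect_allele = htab$effect_allele,
                   other_allele = htab$other_allele, stringsAsFactors = FALSE)
  for (k in seq_along(htab$traits)) {
    df[[paste0("beta_", colnames(htab$beta)[k])]] <- htab$beta[, k]
    df[[paste0("se_", colnames(htab$beta)[k])]] <- htab$se[, k]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(htab$dropped, paste0(path, ".droplog.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
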