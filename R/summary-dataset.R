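#' GWAS summary-statistics dataset
#'
#' Container for one GWAS's per-SNP association statistics plus study
#' metadata. The per-SNP table (`records`) has one row per variant with
#' columns `snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#' `beta`, `se`, `pval`, `n`, `eaf`. Effects are per standard deviation of
#' the trait for quantitative traits and log-odds for disease traits.
#'
#' Invariants enforced at construction: `se > 0`, unique `snp_id`, alleles
#' in A/C/G/T, `pval` in (0, 1]. Missing p-values are recomputed as the
#' two-sided normal p-value of `beta/se`; stored p-values are kept as-is.
#'
#' @param records data.frame of per-SNP statistics (see Details). Extra
#'   columns (e.g. provenance flags) are carried along untouched.
#' @param trait Trait name, using the field's subfraction nomenclature
#'   (e.g. `"M-HDL-P"` = concentration of medium HDL particles).
#' @param name Dataset name (e.g. the consortium), used by the sample-overlap
#'   bookkeeping. Defaults to `trait`.
#' @param population Population label.
#' @param n_total Study sample size; defaults to the maximum per-SNP `n`.
#' @param overlap_tags Character vector of names of other datasets sharing
#'   samples with this one.
#' @param trait_scale `"per-SD"` or `"log-odds"`.
#' @return An object of class `summary_dataset` with elements `trait`,
#'   `name`, `records`, `population`, `n_total`, `overlap_tags`,
#'   `trait_scale`, and `dropped` (a data.frame logging rejected rows).
#' @export
summary_dataset <- function(records, trait, name = trait, population = NA_character_,
                            n_total = NULL, overlap_tags = character(),
                            trait_scale = c("per-SD", "log-odds")) {
  trait_scale <- match.arg(trait_scale)
  req <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele", "beta", "se")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols) > 0)
    stop("records is missing columns: ", paste(missing_cols, collapse = ", "))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (is.null(records$pval)) records$pval <- NA_real_
  if (is.null(records$n)) records$n <- NA_real_
  if (is.null(records$eaf)) records$eaf <- NA_real_
  records$snp_id <- as.character(records$snp_id)
  records$chrom <- as.character(records$chrom)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))

  dropped <- data.frame(snp_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  drop_rows <- function(bad, reason) {
    if (any(bad)) {
      dropped <<- rbind(dropped, data.frame(snp_id = records$snp_id[bad],
                                            reason = reason,
                                            stringsAsFactors = FALSE))
      records <<- records[!bad, , drop = FALSE]
    }
  }
  drop_rows(is.na(records$beta) | is.na(records$se), "missing beta or se")
  drop_rows(records$se <= 0, "se <= 0")
  drop_rows(!(records$effect_allele %in% c("A", "C", "G", "T")) |
              !(records$other_allele %in% c("A", "C", "G", "T")),
            "invalid allele")
  if (anyDuplicated(records$snp_id))
    stop("duplicate snp_id in summary data: ",
         paste(unique(records$snp_id[duplicated(records$snp_id)])[1:5], collapse = ", "))

  miss_p <- is.na(records$pval)
  records$pval[miss_p] <- 2 * stats::pnorm(-abs(records$beta[miss_p] / records$se[miss_p]))
  drop_rows(records$pval < 0 | records$pval > 1, "pval outside [0,1]")
  # extreme associations underflow double precision; clamp to the smallest
  # normal double rather than rejecting genuine genome-wide hits
  records$pval <- pmax(records$pval, .Machine$double.xmin)

  rownames(records) <- NULL
  if (is.null(n_total)) {
    n_total <- if (all(is.na(records$n))) NA_real_ else max(records$n, na.rm = TRUE)
  }
  structure(list(trait = trait, name = name, records = records,
                 population = population, n_total = n_total,
                 overlap_tags = unique(overlap_tags), trait_scale = trait_scale,
                 dropped = dropped),
            class = "summary_dataset")
}

#' @export
print.summary_dataset <- function(x, ...) {
  cat("GWAS summary dataset:", x$name,
      sprintf("(trait %s, %s scale)\n", x$trait, x$trait_scale))
  cat("  SNPs:", nrow(x$records), " dropped at read:", nrow(x$dropped), "\n")
  if (length(x$overlap_tags) > 0)
    cat("  sample overlap with:", paste(x$overlap_tags, collapse = ", "), "\n")
  invisible(x)
}

#' Default column mapping for summary-statistics files
#'
#' Maps the standard internal field names to the column names found in the
#' input file header. Keys: `snp`, `chr`, `pos`, `ea`, `oa`, `beta`, `se`,
#' `p`, `n`, `eaf`; `p`, `n` and `eaf` may be `NA` when absent from the file.
#'
#' @param ... Named overrides, e.g. `snp = "rsid"`.
#' @return Named character vector.
#' @export
default_column_map <- function(...) {
  map <- c(snp = "snp_id", chr = "chrom", pos = "pos", ea = "effect_allele",
           oa = "other_allele", beta = "beta", se = "se", p = "pval",
           n = "n", eaf = "eaf")
  over <- c(...)
  map[names(over)] <- over
  map
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a tab- or whitespace-delimited file with a header row, renames
#' columns according to `column_map`, and returns a validated
#' [summary_dataset()]. Rows with missing `beta`/`se` or `se <= 0` are
#' dropped and logged in the `dropped` element; a missing p-value column is
#' recomputed from the z-score.
#'
#' @param path Path to the file.
#' @param column_map Named map from internal keys to file column names; see
#'   [default_column_map()]. May also be given as the `columns:` block of a
#'   study config.
#' @inheritParams summary_dataset
#' @return A [summary_dataset()].
#' @export
read_summary <- function(path, column_map = default_column_map(), trait,
                         name = trait, population = NA_character_,
                         n_total = NULL, overlap_tags = character(),
                         trait_scale = c("per-SD", "log-odds")) {
  if (!file.exists(path)) stop("cannot read summary file: ", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (is.list(column_map)) column_map <- unlist(column_map)
  needed <- c("snp", "chr", "pos", "ea", "oa", "beta", "se")
  absent <- setdiff(column_map[needed][!is.na(column_map[needed])], names(dt))
  if (length(absent) > 0)
    stop("mapped columns not found in ", path, ": ", paste(absent, collapse = ", "))
  out <- data.frame(snp_id = dt[[column_map[["snp"]]]],
                    chrom = dt[[column_map[["chr"]]]],
                    pos = dt[[column_map[["pos"]]]],
                    effect_allele = dt[[column_map[["ea"]]]],
                    other_allele = dt[[column_map[["oa"]]]],
                    beta = as.numeric(dt[[column_map[["beta"]]]]),
                    se = as.numeric(dt[[column_map[["se"]]]]),
                    stringsAsFactors = FALSE)
  for (key in c("p", "n", "eaf")) {
    col <- column_map[[key]]
    nm <- c(p = "pval", n = "n", eaf = "eaf")[[key]]
    out[[nm]] <- if (!is.na(col) && col %in% names(dt)) as.numeric(dt[[col]]) else NA_real_
  }
  summary_dataset(out, trait = trait, name = name, population = population,
                  n_total = n_total, overlap_tags = overlap_tags,
                  trait_scale = trait_scale)
}

#' Write a summary dataset as tab-separated text
#'
#' Writes the records table with the standard column order; the file
#' round-trips through [read_summary()] with the default column map.
#'
#' @param dataset A [summary_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(dataset, path) {
  stopifnot(inherits(dataset, "summary_dataset"))
  cols <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
            "beta", "se", "pval", "n", "eaf")
  extra <- setdiff(names(dataset$records), cols)
  utils::write.table(dataset$records[, c(cols, extra), drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
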