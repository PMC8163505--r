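#' Block-structured LD reference panel
#'
#' Represents pairwise allelic correlations among panel SNPs as a
#' block-diagonal structure: SNPs are partitioned into disjoint contiguous
#' blocks (never spanning chromosomes), correlations within a block come
#' from the block's correlation matrix, and correlations across blocks are
#' exactly zero. This keeps desk-scale memory bounded while supporting the
#' r-squared lookups, LD scores and clumping the pipeline needs.
#'
#' @param snp_ids Character vector of SNP identifiers, ordered by
#'   (chromosome, position).
#' @param chrom Chromosome labels.
#' @param pos Base-pair positions (1-based).
#' @param block Integer block index per SNP; blocks must be contiguous runs.
#' @param block_cor List of within-block correlation matrices, one per
#'   distinct block index, each symmetric with unit diagonal.
#' @return An object of class `ld_panel`.
#' @export
ld_panel <- function(snp_ids, chrom, pos, block, block_cor) {
  stopifnot(length(snp_ids) == length(chrom), length(chrom) == length(pos),
            length(pos) == length(block))
  if (anyDuplicated(snp_ids)) stop("duplicate snp_id in panel")
  ord <- order(chrom, pos)
  if (!identical(ord, seq_along(snp_ids))) {
    snp_ids <- snp_ids[ord]; chrom <- chrom[ord]; pos <- pos[ord]; block <- block[ord]
  }
  if (any(block != cummax(block)) || any(diff(unique(block)) != 1))
    stop("blocks must be contiguous runs with consecutive indices")
  sizes <- tabulate(block)
  if (length(block_cor) != max(block))
    stop("need one correlation matrix per block")
  for (b in seq_along(block_cor)) {
    R <- block_cor[[b]]
    if (!is.matrix(R) || nrow(R) != sizes[b] || ncol(R) != sizes[b])
      stop("block ", b, ": correlation matrix dimension mismatch")
    if (max(abs(R - t(R))) > 1e-8) stop("block ", b, ": matrix not symmetric")
    if (max(abs(diag(R) - 1)) > 1e-8) stop("block ", b, ": diagonal not 1")
    if (length(unique(chrom[block == b])) != 1)
      stop("block ", b, " spans chromosomes")
  }
  structure(list(snp_ids = snp_ids, chrom = chrom, pos = pos, block = block,
                 block_cor = block_cor),
            class = "ld_panel")
}

#' @export
print.ld_panel <- function(x, ...) {
  cat("LD panel:", length(x$snp_ids), "SNPs in", max(x$block), "blocks on",
      length(unique(x$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Pairwise squared allelic correlation from an LD panel
#'
#' @param panel An [ld_panel()].
#' @param a,b SNP identifiers (must be in the panel).
#' @return `r^2` in [0, 1]; exactly 0 for SNPs in different blocks or on
#'   different chromosomes; 1 when `a == b`.
#' @export
ld_r2 <- function(panel, a, b) {
  i <- match(a, panel$snp_ids)
  j <- match(b, panel$snp_ids)
  if (is.na(i)) stop("unknown SNP: ", a)
  if (is.na(j)) stop("unknown SNP: ", b)
  if (panel$block[i] != panel$block[j]) return(0)
  bl <- panel$block[i]
  off <- min(which(panel$block == bl)) - 1L
  panel$block_cor[[bl]][i - off, j - off]^2
}

#' Per-SNP LD scores
#'
#' The LD score of SNP j is the sum of squared correlations with every
#' panel SNP, `ell_j = sum_k r_jk^2`, including the self term (so
#' `ell_j >= 1`). With a block-diagonal panel the sum runs over the SNP's
#' block.
#'
#' @param panel An [ld_panel()].
#' @return Object of class `ld_scores`: list with `snp_ids`, `ell`, and `M`
#'   (panel size).
#' @export
ld_scores <- function(panel) {
  stopifnot(inherits(panel, "ld_panel"))
  ell <- unlist(lapply(panel$block_cor, function(R) rowSums(R^2)),
                use.names = FALSE)
  structure(list(snp_ids = panel$snp_ids, ell = ell, M = length(panel$snp_ids)),
            class = "ld_scores")
}

#' Greedy p-value-ordered LD clumping
#'
#' Orders SNPs by ascending association p-value (ties broken by
#' lexicographic `snp_id` for reproducibility) and selects them greedily: a
#' SNP is kept iff its squared correlation with every already-selected SNP
#' within `window_bp` on the same chromosome is below `r2_max`. SNPs
#' farther apart than the window (or in different panel blocks) are treated
#' as independent. With `p_max` given, only SNPs at or below that p-value
#' are considered; in genome-wide mode (`p_max = NULL`) the full list is
#' clumped with no p-value truncation.
#'
#' @param stats A [summary_dataset()].
#' @param panel An [ld_panel()]; SNPs absent from the panel are dropped and
#'   logged.
#' @param r2_max Squared-correlation ceiling between selected SNPs
#'   (default 0.001).
#' @param window_bp Window within which the r-squared constraint is
#'   enforced (default 10 Mb).
#' @param p_max Optional p-value ceiling for candidacy.
#' @return data.frame of selected SNPs with columns `rank`, `snp_id`,
#'   `chrom`, `pos`, `pval`, `r2_nearest` (largest r-squared with any
#'   previously selected in-window SNP); attribute `"dropped"` logs SNPs
#'   absent from the panel.
#' @export
ld_clump <- function(stats, panel, r2_max = 0.001, window_bp = 1e7, p_max = NULL) {
  stopifnot(inherits(stats, "summary_dataset"), inherits(panel, "ld_panel"))
  rec <- stats$records
  if (nrow(rec) == 0) stop("empty summary dataset")
  in_panel <- rec$snp_id %in% panel$snp_ids
  dropped <- data.frame(snp_id = rec$snp_id[!in_panel],
                        reason = rep("not_in_panel", sum(!in_panel)),
                        stringsAsFactors = FALSE)
  rec <- rec[in_panel, , drop = FALSE]
  if (!is.null(p_max)) rec <- rec[rec$pval <= p_max, , drop = FALSE]
  if (nrow(rec) == 0) {
    out <- data.frame(rank = integer(), snp_id = character(), chrom = character(),
                      pos = numeric(), pval = numeric(), r2_nearest = numeric(),
                      stringsAsFactors = FALSE)
    attr(out, "dropped") <- dropped
    return(out)
  }
  ord <- order(rec$pval, rec$snp_id)
  rec <- rec[ord, , drop = FALSE]
  pidx <- match(rec$snp_id, panel$snp_ids)
  blk <- panel$block[pidx]
  pos <- panel$pos[pidx]
  block_offset <- c(0L, cumsum(tabulate(panel$block)))[blk] # 0-based offset of block start
  within <- pidx - block_offset

  sel <- integer(0)
  r2n <- numeric(0)
  # cross-block r2 is exactly 0 < r2_max, so only same-block selected SNPs
  # can violate the constraint
  sel_by_block <- vector("list", max(panel$block))
  for (i in seq_len(nrow(rec))) {
    b <- blk[i]
    prev <- sel_by_block[[b]]
    best <- 0
    ok <- TRUE
    if (length(prev) > 0) {
      inwin <- abs(pos[prev] - pos[i]) <= window_bp
      if (any(inwin)) {
        r2s <- panel$block_cor[[b]][within[prev[inwin]], within[i]]^2
        best <- max(r2s)
        ok <- best < r2_max
      }
    }
    if (ok) {
      sel <- c(sel, i)
      r2n <- c(r2n, best)
      sel_by_block[[b]] <- c(prev, i)
    }
  }
  out <- data.frame(rank = seq_along(sel), snp_id = rec$snp_id[sel],
                    chrom = rec$chrom[sel], pos = pos[sel], pval = rec$pval[sel],
                    r2_nearest = r2n, stringsAsFactors = FALSE)
  attr(out, "dropped") <- dropped
  out
}

#' Read an LD panel from delimited text
#'
#' `meta_path` holds one row per SNP with header columns `chrom`, `pos`,
#' `snp_id`, `block_id`; `cor_path` holds the within-block correlations in
#' long format with header `block_id`, `i`, `j`, `r` (1-based indices
#' within the block; missing pairs default to 0 off-diagonal, 1 on the
#' diagonal; symmetric completion applied).
#'
#' @param meta_path,cor_path File paths.
#' @return An [ld_panel()].
#' @export
read_ld_panel <- function(meta_path, cor_path) {
  meta <- data.table::fread(meta_path, header = TRUE, data.table = FALSE)
  cors <- data.table::fread(cor_path, header = TRUE, data.table = FALSE)
  blocks <- sort(unique(meta$block_id))
  block <- match(meta$block_id, blocks)
  sizes <- tabulate(block)
  block_cor <- lapply(seq_along(blocks), function(b) {
    R <- diag(sizes[b])
    rows <- cors[cors$block_id == blocks[b], , drop = FALSE]
    for (r in seq_len(nrow(rows))) {
      R[rows$i[r], rows$j[r]] <- rows$r[r]
      R[rows$j[r], rows$i[r]] <- rows$r[r]
    }
    R
  })
  ld_panel(meta$snp_id, as.character(meta$chrom), meta$pos, block, block_cor)
}

#' Write a clump result as plain text
#'
#' One SNP per line with rank, p-value, and the largest r-squared with any
#' previously selected neighbour.
#'
#' @param clumped Result of [ld_clump()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clump <- function(clumped, path) {
  utils::write.table(clumped, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
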