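#' Combined significance score for gene ranking
#'
#' `pi = log2fc * (-log10 p)`: odd in the fold change, increasing in
#' magnitude as the p-value shrinks. Genes are ranked by this score before
#' preranked gene-set enrichment.
#'
#' @param log2fc log2 fold changes (finite).
#' @param pvalue p-values in (0, 1]. Zeros are clamped to the smallest
#'   positive double with a warning when `clamp_zero = TRUE` (default),
#'   otherwise rejected.
#' @param clamp_zero how to treat `p = 0` from upstream tools.
#' @return numeric vector of pi scores.
#' @examples
#' pi_score(1, 0.1)    # 1
#' pi_score(-0.5, 0.01) # -1
#' @export
pi_score <- function(log2fc, pvalue, clamp_zero = TRUE) {
  if (!all(is.finite(log2fc))) stop("log2fc must be finite")
  if (any(pvalue < 0 | pvalue > 1, na.rm = TRUE) || anyNA(pvalue))
    stop("pvalue must be in (0, 1]")
  if (any(pvalue == 0)) {
    if (!clamp_zero) stop("pvalue = 0; enable clamp_zero or fix upstream")
    warning("p-values of 0 clamped to the smallest positive double")
    pvalue[pvalue == 0] <- .Machine$double.xmin
  }
  log2fc * (-log10(pvalue))
}

#' Rank genes by the pi significance score
#'
#' Sorted by decreasing pi; exact ties broken lexicographically by gene id,
#' so the ranking is a deterministic function of the table regardless of
#' input order.
#'
#' @param stats data.frame with columns `gene`, `log2fc`, `pvalue` (unique
#'   gene ids).
#' @param clamp_zero passed to [pi_score()].
#' @return data.frame of class `ranked_genes` with columns `gene`, `pi`,
#'   ordered.
#' @export
rank_genes <- function(stats, clamp_zero = TRUE) {
  stopifnot(all(c("gene", "log2fc", "pvalue") %in% names(stats)))
  gene <- as.character(stats$gene)
  if (anyDuplicated(gene)) stop("duplicate gene ids")
  pi <- pi_score(stats$log2fc, stats$pvalue, clamp_zero)
  o <- order(-pi, gene, method = "radix")
  out <- data.frame(gene = gene[o], pi = pi[o], stringsAsFactors = FALSE)
  class(out) <- c("ranked_genes", "data.frame")
  out
}

# Core weighted running-sum statistic from sorted hit positions.
# stats_sorted: pi scores in ranking order; hit_idx: positions of set
# members. Returns list(es, arg_idx, top, bot, idx).
running_sum_es <- function(stats_sorted, hit_idx, weight_exponent = 1) {
  N <- length(stats_sorted)
  m <- length(hit_idx)
  if (m == 0L || m == N)  # no members, or set = whole universe: no contrast
    return(list(es = 0, degenerate = TRUE, idx = sort(hit_idx)))
  idx <- sort(hit_idx)
  w <- abs(stats_sorted[idx])^weight_exponent
  nr <- sum(w)
  if (nr == 0) { w <- rep(1, m); nr <- m }
  cw <- cumsum(w) / nr
  mstep <- (idx - seq_len(m)) / (N - m)
  top <- cw - mstep            # running sum at each hit
  bot <- c(0, cw[-m]) - mstep  # running sum just before each hit
  hi <- max(top); lo <- min(bot, 0)
  if (hi >= -lo) {
    list(es = hi, at = idx[which.max(top)], sign = 1L,
         degenerate = FALSE, idx = idx)
  } else {
    list(es = lo, at = idx[which.min(bot)], sign = -1L,
         degenerate = FALSE, idx = idx)
  }
}

#' Enrichment score of a gene set on a ranked list
#'
#' Weighted Kolmogorov-Smirnov-like running sum: walking down the ranking,
#' the sum rises by `|pi|^weight_exponent` (normalized) at set members and
#' falls by `1/(N - N_hit)` at non-members; the enrichment score is the
#' signed maximum deviation. The leading edge contains the members at or
#' before (after, for negative ES) the extremum. A set with no members in
#' the ranking, or covering the whole ranking, carries no contrast and is
#' flagged degenerate with `es = 0`.
#'
#' @param ranked a [rank_genes()] result (or data.frame with `gene`, `pi`).
#' @param gene_set character vector of member gene ids.
#' @param weight_exponent exponent on `|pi|` (default 1; 0 gives the equal
#'   weights of the classic KS statistic).
#' @return list with `es`, `size` (members in the ranking),
#'   `leading_edge` (character vector), `degenerate`.
#' @export
enrichment_score <- function(ranked, gene_set, weight_exponent = 1) {
  stopifnot(all(c("gene", "pi") %in% names(ranked)))
  hit_idx <- which(ranked$gene %in% gene_set)
  r <- running_sum_es(ranked$pi, hit_idx, weight_exponent)
  le <- character(0)
  if (!r$degenerate) {
    le <- if (r$sign > 0) ranked$gene[r$idx[r$idx <= r$at]]
          else ranked$gene[r$idx[r$idx >= r$at]]
  }
  list(es = r$es, size = length(hit_idx), leading_edge = le,
       degenerate = isTRUE(r$degenerate))
}

#' Preranked gene-set enrichment with permutation NES and FDR
#'
#' For each gene set, the observed enrichment score is compared with a null
#' distribution obtained by drawing random gene sets of the same size from
#' the ranked universe (`n_perm` draws, shared across sets of equal size).
#' NES is the ES divided by the mean |null ES| of matching sign; the FDR q
#' value follows the standard preranked procedure (ratio of the null and
#' observed tail fractions at the set's NES, per sign, capped at 1).
#'
#' @param ranked a [rank_genes()] result.
#' @param collections named list of gene sets (e.g. from [read_gmt()]).
#' @param n_perm permutations (>= 100).
#' @param seed integer seed; results are reproducible given the seed.
#' @param weight_exponent exponent on `|pi|` (default 1).
#' @param min_size,max_size sets with fewer/more members in the ranking are
#'   excluded (recorded in the `excluded` attribute).
#' @return data.frame of class `gsea_result`: `set`, `size`, `es`, `nes`,
#'   `pval`, `fdr_q`, `leading_edge` (comma-separated ids).
#' @export
gsea_preranked <- function(ranked, collections, n_perm = 1000, seed = 1,
                           weight_exponent = 1, min_size = 5, max_size = 500) {
  stopifnot(all(c("gene", "pi") %in% names(ranked)), n_perm >= 100)
  N <- nrow(ranked)
  sizes <- vapply(collections, function(s) sum(ranked$gene %in% s), integer(1))
  keep <- sizes >= min_size & sizes <= max_size & sizes < N
  excluded <- names(collections)[!keep]
  collections <- collections[keep]; sizes <- sizes[keep]
  if (!length(collections)) {
    out <- data.frame(set = character(0), size = integer(0), es = numeric(0),
                      nes = numeric(0), pval = numeric(0), fdr_q = numeric(0),
                      leading_edge = character(0))
    class(out) <- c("gsea_result", "data.frame")
    attr(out, "excluded") <- excluded
    return(out)
  }

  obs <- lapply(collections, function(s)
    enrichment_score(ranked, s, weight_exponent))
  es <- vapply(obs, `[[`, numeric(1), "es")

  set.seed(as.integer(seed))
  null_by_size <- list()
  for (sz in sort(unique(sizes))) {
    null_by_size[[as.character(sz)]] <- vapply(seq_len(n_perm), function(b) {
      running_sum_es(ranked$pi, sample.int(N, sz), weight_exponent)$es
    }, numeric(1))
  }

  nes <- numeric(length(es)); null_nes_all <- NULL
  mean_pos <- list(); mean_neg <- list()
  for (sz in names(null_by_size)) {
    ne <- null_by_size[[sz]]
    mp <- mean(ne[ne >= 0]); mn <- mean(abs(ne[ne < 0]))
    if (!is.finite(mp) || mp == 0) mp <- NA_real_
    if (!is.finite(mn) || mn == 0) mn <- NA_real_
    mean_pos[[sz]] <- mp; mean_neg[[sz]] <- mn
    nn <- ifelse(ne >= 0, ne / mp, ne / mn)
    null_nes_all <- c(null_nes_all, nn[is.finite(nn)])
  }
  pval <- numeric(length(es))
  for (i in seq_along(es)) {
    sz <- as.character(sizes[i]); ne <- null_by_size[[sz]]
    if (es[i] >= 0) {
      nes[i] <- if (is.na(mean_pos[[sz]])) NA_real_ else es[i] / mean_pos[[sz]]
      pval[i] <- (1 + sum(ne >= es[i])) / (1 + sum(ne >= 0))
    } else {
      nes[i] <- if (is.na(mean_neg[[sz]])) NA_real_ else es[i] / mean_neg[[sz]]
      pval[i] <- (1 + sum(ne <= es[i])) / (1 + sum(ne < 0))
    }
  }

  fdr <- vapply(seq_along(nes), function(i) {
    if (!is.finite(nes[i])) return(NA_real_)
    if (nes[i] >= 0) {
      denom_null <- sum(null_nes_all >= 0)
      num <- if (denom_null) sum(null_nes_all >= nes[i]) / denom_null else 0
      den <- sum(nes >= nes[i], na.rm = TRUE) / max(1, sum(nes >= 0, na.rm = TRUE))
    } else {
      denom_null <- sum(null_nes_all < 0)
      num <- if (denom_null) sum(null_nes_all <= nes[i]) / denom_null else 0
      den <- sum(nes <= nes[i], na.rm = TRUE) / max(1, sum(nes < 0, na.rm = TRUE))
    }
    min(1, if (den > 0) num / den else 0)
  }, numeric(1))

  out <- data.frame(set = names(collections), size = sizes, es = es,
                    nes = nes, pval = pval, fdr_q = fdr,
                    leading_edge = vapply(obs, function(o)
                      paste(o$leading_edge, collapse = ","), character(1)),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-abs(out$nes)), , drop = FALSE]
  class(out) <- c("gsea_result", "data.frame")
  attr(out, "excluded") <- excluded
  out
}

#' @export
print.gsea_result <- function(x, ...) {
  cat("Preranked enrichment:", nrow(x), "sets\n")
  y <- as.data.frame(x)
  y$leading_edge <- NULL
  print(utils::head(y, 10), row.names = FALSE)
  ex <- attr(x, "excluded")
  if (length(ex)) cat("excluded (size filter):", paste(ex, collapse = ", "), "\n")
  invisible(x)
}

#' Read / write GMT gene-set files
#'
#' GMT: one set per line, tab-separated `name`, `description`, members.
#'
#' @param path file path.
#' @return `read_gmt`: named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  out
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param description description field (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(length(names(sets)) == length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a ranked list as a GSEA-compatible .rnk file
#'
#' Two tab-separated columns, gene and pi score, no header.
#'
#' @param ranked a [rank_genes()] result.
#' @param path output path.
#' @export
write_rnk <- function(ranked, path) {
  write.table(ranked[, c("gene", "pi")], path, sep = "\t",
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a differential-expression summary table
#'
#' Tab-separated with columns `gene`, `log2fc`, `pvalue` (the summary format
#' produced by count-based DE tools).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_de_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "log2fc", "pvalue")
  if (!all(need %in% names(d)))
    stop("DE table must have columns: ", paste(need, collapse = ", "))
  d
}
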