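#' Ground truth for a synthetic differential-expression table
#'
#' Null genes draw their log2 fold change from `N(0, null_lfc_sd)` and their
#' p-value from `Uniform(0, 1)`; genes in planted sets draw log2 fold change
#' from `N(effect_size, null_lfc_sd)` and p-values from
#' `Beta(planted_p_shape, 1)` (skewed toward 0). Planted sets occupy
#' disjoint consecutive blocks of the gene universe, so membership is a
#' deterministic function of the parameters.
#'
#' @param n_genes size of the gene universe.
#' @param planted_sets named integer vector of set sizes (may be empty).
#' @param effect_size log2-fold-change shift of planted genes (sign
#'   respected).
#' @param null_lfc_sd standard deviation of null log2 fold changes.
#' @param planted_p_shape Beta shape-1 parameter for planted p-values
#'   (< 1 skews to 0).
#' @return object of class `de_truth` with `gene_ids` and resolved
#'   `planted_sets` (named list of member ids).
#' @export
de_truth <- function(n_genes = 1000, planted_sets = c(SET1 = 50),
                     effect_size = 2, null_lfc_sd = 0.5,
                     planted_p_shape = 0.25) {
  stopifnot(n_genes >= 1, null_lfc_sd > 0, planted_p_shape > 0)
  planted_sets <- planted_sets[planted_sets > 0]
  if (sum(planted_sets) > n_genes)
    stop("planted sets exceed the gene universe")
  ids <- sprintf("g%05d", seq_len(n_genes))
  sets <- list(); at <- 1L
  for (nm in names(planted_sets)) {
    k <- planted_sets[[nm]]
    sets[[nm]] <- ids[at:(at + k - 1L)]
    at <- at + k
  }
  structure(list(gene_ids = ids, planted_sets = sets,
                 effect_size = effect_size, null_lfc_sd = null_lfc_sd,
                 planted_p_shape = planted_p_shape, n_genes = n_genes),
            class = "de_truth")
}

#' Generate a synthetic DE summary table
#'
#' @param truth a [de_truth()] object.
#' @param seed integer seed; the table is a deterministic function of
#'   `(truth, seed)`.
#' @return data.frame with `gene`, `log2fc`, `pvalue` and attribute
#'   `planted_sets` (named list of member gene ids, GMT-ready).
#' @export
generate_de_table <- function(truth, seed = 1) {
  stopifnot(inherits(truth, "de_truth"))
  if (length(truth$planted_sets) && truth$effect_size == 0)
    warning("effect_size is 0: planted sets are indistinguishable from null")
  set.seed(as.integer(seed))
  n <- truth$n_genes
  planted <- truth$gene_ids %in% unlist(truth$planted_sets)
  log2fc <- rnorm(n, 0, truth$null_lfc_sd)
  log2fc[planted] <- rnorm(sum(planted), truth$effect_size, truth$null_lfc_sd)
  pvalue <- runif(n)
  pvalue[planted] <- rbeta(sum(planted), truth$planted_p_shape, 1)
  pvalue <- pmax(pvalue, .Machine$double.xmin)
  out <- data.frame(gene = truth$gene_ids, log2fc = log2fc, pvalue = pvalue,
                    stringsAsFactors = FALSE)
  attr(out, "planted_sets") <- truth$planted_sets
  out
}

#' Write a DE table (TSV) and its companion GMT of planted sets
#'
#' @param de result of [generate_de_table()].
#' @param path output path without extension; writes `<path>.tsv` and, when
#'   planted sets exist, `<path>.gmt`.
#' @return invisibly, the paths written.
#' @export
write_de_table <- function(de, path) {
  tsv <- paste0(path, ".tsv")
  write.table(de, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  paths <- tsv
  ps <- attr(de, "planted_sets")
  if (length(ps)) {
    gmt <- paste0(path, ".gmt")
    write_gmt(ps, gmt, description = "planted")
    paths <- c(paths, gmt)
  }
  invisible(paths)
}
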