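# Transcriptome preprocessing: quantile normalization, one-way ANOVA
# screening on log2 intensities, fold-change/p-value gene selection, PCA of
# samples, and projection of gene-level changes onto reactions through GPR
# rules.

#' Assemble an expression matrix with group labels
#'
#' @param intensities Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids); raw positive intensities.
#' @param groups Character/factor vector of condition labels (strain x
#'   carbon source), one per sample.
#' @return List of class `"expression_matrix"` with `intensities` and
#'   `groups`.
#' @export
expression_matrix <- function(intensities, groups) {
  stopifnot(is.matrix(intensities), is.numeric(intensities))
  if (is.null(rownames(intensities)) || is.null(colnames(intensities))) {
    stop("intensities must carry gene rownames and sample colnames")
  }
  if (any(intensities <= 0)) stop("intensities must be positive")
  if (length(groups) != ncol(intensities)) {
    stop("one group label per sample required (got ", length(groups),
         " for ", ncol(intensities), " samples)")
  }
  groups <- as.character(groups)
  if (min(table(groups)) < 2L) {
    stop("every group needs >= 2 replicates for the testing procedures")
  }
  structure(list(intensities = intensities,
                 groups = stats::setNames(groups, colnames(intensities))),
            class = "expression_matrix")
}

.intensities <- function(x) {
  if (inherits(x, "expression_matrix")) x$intensities else x
}

#' Quantile normalization
#'
#' Forces every sample (column) onto the identical empirical distribution:
#' the row-wise mean of the sorted columns. Ties are resolved by averaging
#' over tied positions, and row order is preserved. Idempotent.
#'
#' @param x Numeric matrix (genes x samples) or an `"expression_matrix"`.
#' @return Object of the same shape with normalized intensities.
#' @export
quantile_normalize <- function(x) {
  mat <- .intensities(x)
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  if (inherits(x, "expression_matrix")) {
    x$intensities <- out
    x
  } else {
    out
  }
}

#' One-way ANOVA screen across condition groups
#'
#' Fixed-effects one-way ANOVA per gene on log2-transformed intensities.
#' Genes whose within-group variance is zero get p = 1 when the group means
#' are equal too (no evidence of regulation by convention) and p = 0 when
#' the means differ with zero noise.
#'
#' @param x Matrix or `"expression_matrix"` of positive intensities.
#' @param groups Group labels (defaulting to the object's own).
#' @return Named vector of p-values, one per gene.
#' @export
anova_screen <- function(x, groups = NULL) {
  mat <- .intensities(x)
  if (is.null(groups)) {
    if (!inherits(x, "expression_matrix")) {
      stop("groups must be supplied for a bare matrix")
    }
    groups <- x$groups
  }
  groups <- as.character(groups)
  if (length(groups) != ncol(mat)) stop("one group label per sample required")
  if (length(unique(groups)) < 2L) stop("need >= 2 groups")
  if (min(table(groups)) < 2L) stop("need >= 2 replicates per group")
  lmat <- log2(mat)
  n <- ncol(lmat)
  k <- length(unique(groups))
  g <- factor(groups)
  counts <- as.vector(table(g))
  gm <- rowMeans(lmat)
  # group means per gene: genes x groups
  means <- matrix(0, nrow(lmat), k)
  for (j in seq_len(k)) {
    means[, j] <- rowMeans(lmat[, g == levels(g)[j], drop = FALSE])
  }
  ssb <- as.vector((means - gm)^2 %*% counts)
  ssw <- rowSums((lmat - means[, as.integer(g), drop = FALSE])^2)
  df1 <- k - 1L
  df2 <- n - k
  f <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  # zero within-group variance: no noise estimate; equal means -> p = 1
  degenerate <- ssw < 1e-12
  p[degenerate & ssb < 1e-12] <- 1
  p[degenerate & ssb >= 1e-12] <- 0
  stats::setNames(p, rownames(mat))
}

#' Log2 fold changes between two condition groups
#'
#' @param x Matrix or `"expression_matrix"` of positive intensities.
#' @param groups Group labels (defaulting to the object's own).
#' @param group_a,group_b The two groups to contrast; positive values mean
#'   higher expression in `group_b`.
#' @return Named vector of log2 fold changes per gene.
#' @export
log2_fold_change <- function(x, groups = NULL, group_a, group_b) {
  mat <- .intensities(x)
  if (is.null(groups)) groups <- x$groups
  groups <- as.character(groups)
  for (gg in c(group_a, group_b)) {
    if (!gg %in% groups) stop("no samples in group '", gg, "'")
  }
  lmat <- log2(mat)
  rowMeans(lmat[, groups == group_b, drop = FALSE]) -
    rowMeans(lmat[, groups == group_a, drop = FALSE])
}

#' Differential-expression table for a two-group contrast
#'
#' Combines the ANOVA screen (across all groups supplied) with the log2 fold
#' change between two named groups and applies the significance cut-off.
#'
#' @inheritParams log2_fold_change
#' @param fc_threshold Fold-change cut-off (default 2-fold).
#' @param p_threshold ANOVA p-value cut-off (default 0.005).
#' @return Data frame with `gene`, `log2fc`, `p_value`, `regulated`.
#' @export
diff_expression <- function(x, groups = NULL, group_a, group_b,
                            fc_threshold = 2, p_threshold = 0.005) {
  if (is.null(groups)) groups <- x$groups
  keep <- as.character(groups) %in% c(group_a, group_b)
  mat <- .intensities(x)[, keep, drop = FALSE]
  g <- as.character(groups)[keep]
  p <- anova_screen(mat, g)
  fc <- log2_fold_change(mat, g, group_a, group_b)
  d <- data.frame(gene = rownames(.intensities(x)), log2fc = fc, p_value = p,
                  stringsAsFactors = FALSE, row.names = NULL)
  d$regulated <- d$gene %in% select_regulated(d, fc_threshold, p_threshold)
  d
}

#' Select significantly regulated genes
#'
#' A gene is called regulated when |log2 FC| >= log2(fc_threshold) AND
#' p < p_threshold (both criteria, matching a 2-fold / p < 0.005 cut-off at
#' the defaults).
#'
#' @param dtable Data frame with `gene`, `log2fc` and `p_value` columns (as
#'   from [diff_expression()]).
#' @param fc_threshold Fold-change cut-off (> 0), on the natural scale.
#' @param p_threshold p-value cut-off (> 0).
#' @return Character vector of selected gene ids.
#' @export
select_regulated <- function(dtable, fc_threshold = 2, p_threshold = 0.005) {
  if (fc_threshold <= 0 || p_threshold <= 0) {
    stop("thresholds must be positive")
  }
  sel <- abs(dtable$log2fc) >= log2(fc_threshold) &
    dtable$p_value < p_threshold
  dtable$gene[sel]
}

#' Principal component analysis of samples
#'
#' PCA of the samples on gene-centered log2 data (each gene centred across
#' samples), as commonly drawn for microarray condition maps.
#'
#' @param x Matrix or `"expression_matrix"` of positive intensities.
#' @param log2_transform Log2-transform before centering (default `TRUE`).
#' @return List with `scores` (samples x components), `explained` (variance
#'   fractions, non-increasing, summing to <= 1) and `loadings`.
#' @export
pca_samples <- function(x, log2_transform = TRUE) {
  mat <- .intensities(x)
  if (ncol(mat) < 2L) stop("PCA needs >= 2 samples")
  lmat <- if (log2_transform) log2(mat) else mat
  keep <- apply(lmat, 1L, stats::sd) > 0
  if (!any(keep)) {
    return(list(scores = matrix(0, ncol(mat), 0,
                                dimnames = list(colnames(mat), NULL)),
                explained = numeric(0),
                loadings = matrix(0, nrow(mat), 0)))
  }
  pc <- stats::prcomp(t(lmat[keep, , drop = FALSE]), center = TRUE,
                      scale. = FALSE)
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  nz <- explained > 1e-12
  list(scores = pc$x[, nz, drop = FALSE],
       explained = explained[nz],
       loadings = pc$rotation[, nz, drop = FALSE])
}

#' Map gene-level expression changes onto reactions through GPR rules
#'
#' For a complex (`and`) the subunit with the smallest absolute change is
#' limiting and supplies the reaction-level change; for isozymes (`or`) the
#' member with the most extreme change dominates (flagged when member signs
#' disagree). Reactions without a GPR provide no expression evidence.
#' Significance travels with the gene whose change is adopted.
#'
#' @param model A `metabolic_model`.
#' @param log2fc Named vector of per-gene log2 fold changes.
#' @param significant Named logical vector (or vector of p-values, converted
#'   with `p < p_threshold`) per gene.
#' @param p_threshold Used only when `significant` is numeric.
#' @return Data frame with `reaction_id`, `d_expression`, `significant`,
#'   `ambiguous_sign`, `has_evidence`.
#' @export
reaction_expression_change <- function(model, log2fc, significant,
                                       p_threshold = 0.005) {
  if (is.numeric(significant)) significant <- significant < p_threshold
  genes <- names(log2fc)
  if (is.null(genes)) stop("log2fc must be a named vector")
  unmapped <- new.env(parent = emptyenv())
  eval_node <- function(node) {
    # returns c(change, significant, ambiguous) or NULL for no evidence
    if (is.null(node)) return(NULL)
    if (is.character(node)) {
      if (!node %in% genes) {
        assign(node, TRUE, envir = unmapped)
        return(NULL)
      }
      return(c(change = unname(log2fc[[node]]),
               significant = as.numeric(isTRUE(significant[[node]])),
               ambiguous = 0))
    }
    vals <- Filter(Negate(is.null), lapply(node$args, eval_node))
    if (!length(vals)) return(NULL)
    ch <- vapply(vals, `[[`, 0, "change")
    sig <- vapply(vals, `[[`, 0, "significant")
    amb <- vapply(vals, `[[`, 0, "ambiguous")
    i <- if (node$op == "and") which.min(abs(ch)) else which.max(abs(ch))
    amb_here <- node$op == "or" &&
      length(unique(sign(ch[ch != 0]))) > 1L
    c(change = ch[i], significant = sig[i],
      ambiguous = max(amb[i], as.numeric(amb_here)))
  }
  rows <- lapply(model$reactions, function(r) {
    ev <- eval_node(parse_gpr(r$gpr))
    data.frame(reaction_id = r$id,
               d_expression = if (is.null(ev)) NA_real_ else ev[["change"]],
               significant = if (is.null(ev)) FALSE
                             else ev[["significant"]] > 0,
               ambiguous_sign = if (is.null(ev)) FALSE
                                else ev[["ambiguous"]] > 0,
               has_evidence = !is.null(ev),
               stringsAsFactors = FALSE)
  })
  un <- ls(unmapped)
  if (length(un)) {
    warning("GPR genes without expression values ignored: ",
            paste(utils::head(sort(un), 10), collapse = ", "),
            if (length(un) > 10) ", ..." else "")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
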