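# Post-discovery analyses: correlation structure of RS genes, hierarchical
# clustering of patients on an RS gene panel with per-cluster radiotherapy
# survival comparison, and the extreme-survivor expression contrast.

#' Pairwise correlation of RS genes with strength categories
#'
#' @param cohort A `cohort_dataset`.
#' @param genes Gene ids (>= 2).
#' @param thresholds |r| cuts separating weak / moderate / strong (default
#'   `c(0.3, 0.8)`).
#' @return List with `r` (symmetric correlation matrix, unit diagonal) and
#'   `category` (character matrix of the same shape).
#' @export
rs_correlation <- function(cohort, genes, thresholds = c(0.3, 0.8)) {
  stopifnot(length(genes) >= 2)
  missing <- setdiff(genes, rownames(cohort$expression))
  if (length(missing)) stop("gene(s) absent from expression: ",
                            paste(missing, collapse = ", "))
  for (g in genes) {
    if (length(unique(cohort$expression[g, ])) < 2)
      stop("degenerate gene (constant expression): ", g)
  }
  x <- t(cohort$expression[genes, , drop = FALSE])
  r <- cor(x, method = "pearson")
  a <- abs(r)
  category <- matrix(ifelse(a > thresholds[2], "strong",
                            ifelse(a > thresholds[1], "moderate", "weak")),
                     nrow = nrow(r), dimnames = dimnames(r))
  list(r = r, category = category)
}

#' Cluster patients on an RS-gene panel
#'
#' Expression of the panel genes is standardized per gene (z-score across
#' patients), patients are clustered by agglomerative hierarchical
#' clustering (Euclidean distance, complete linkage — the defaults of the
#' heatmap tools used for this analysis) and the tree is cut into k
#' clusters. Genes with extreme expression can be excluded explicitly; no
#' automatic exclusion rule is applied.
#'
#' @param cohort A `cohort_dataset`.
#' @param gene_panel Gene ids to cluster on.
#' @param k Number of clusters (default 2).
#' @param exclusions Genes removed from the panel before clustering.
#' @param method,metric Linkage method and distance metric passed to
#'   [stats::hclust()] / [stats::dist()].
#' @return Object of class `cluster_result`: `labels` (named integer vector
#'   in 1..k), `sizes`, `genes`, `method`, `metric`, `tree` (the `hclust`
#'   object).
#' @export
cluster_patients <- function(cohort, gene_panel, k = 2, exclusions = character(0),
                             method = "complete", metric = "euclidean") {
  genes <- setdiff(gene_panel, exclusions)
  if (length(genes) < 2) stop("panel needs >= 2 genes after exclusions")
  missing <- setdiff(genes, rownames(cohort$expression))
  if (length(missing)) stop("gene(s) absent from expression: ",
                            paste(missing, collapse = ", "))
  x <- cohort$expression[genes, , drop = FALSE]
  if (ncol(x) < k) stop("fewer patients than clusters")
  sds <- apply(x, 1, sd)
  if (any(sds == 0)) stop("degenerate gene (constant expression): ",
                          paste(genes[sds == 0], collapse = ", "))
  z <- t((x - rowMeans(x)) / sds)  # patients x genes, per-gene z-score
  tree <- hclust(dist(z, method = metric), method = method)
  labels <- cutree(tree, k = k)
  structure(list(labels = labels, sizes = as.vector(table(labels)),
                 genes = genes, method = method, metric = metric, k = k,
                 tree = tree),
            class = "cluster_result")
}

#' Per-cluster radiotherapy survival comparison
#'
#' Within each patient cluster, compares radiotherapy vs no-radiotherapy
#' overall survival by Kaplan-Meier curves and the log-rank test. A cluster
#' with an empty treatment-by-cluster cell is reported not evaluable. The
#' radio-sensitive cluster, when one exists, is the cluster where the
#' radiotherapy benefit is significant while it is not in any other.
#'
#' @param cohort A `cohort_dataset`.
#' @param clusters A `cluster_result` (or named integer vector of labels).
#' @param alpha Significance level for the per-cluster log-rank tests.
#' @return List with `per_cluster` (`data.frame`: cluster, n, n_rt, n_nrt,
#'   logrank chi-square, p, evaluable), `km` (per-cluster list of RT/NRT
#'   curves), and `rs_cluster` (integer label or `NA`).
#' @export
compare_cluster_survival <- function(cohort, clusters, alpha = 0.05) {
  labels <- if (inherits(clusters, "cluster_result")) clusters$labels else clusters
  clin <- cohort$clinical
  lab <- labels[clin$sample_id]
  if (anyNA(lab)) stop("cluster labels missing for some cohort samples")
  ks <- sort(unique(lab))
  rows <- list(); km <- list()
  for (k in ks) {
    idx <- lab == k
    cl <- clin[idx, , drop = FALSE]
    cell <- table(factor(cl$radiotherapy, levels = c(0, 1)))
    if (any(cell == 0) || sum(cl$os_event) == 0) {
      rows[[as.character(k)]] <- data.frame(cluster = k, n = sum(idx),
                                            n_rt = cell[["1"]], n_nrt = cell[["0"]],
                                            chisq = NA_real_, p = NA_real_,
                                            evaluable = FALSE)
      km[[as.character(k)]] <- NULL
      next
    }
    lr <- logrank_test(cl$os_time, cl$os_event,
                       ifelse(cl$radiotherapy == 1, "RT", "NRT"))
    rows[[as.character(k)]] <- data.frame(cluster = k, n = sum(idx),
                                          n_rt = cell[["1"]], n_nrt = cell[["0"]],
                                          chisq = lr$statistic, p = lr$p,
                                          evaluable = TRUE)
    km[[as.character(k)]] <- km_estimate(cl$os_time, cl$os_event,
                                         ifelse(cl$radiotherapy == 1, "RT", "NRT"))
  }
  per_cluster <- do.call(rbind, rows)
  rownames(per_cluster) <- NULL
  sig <- per_cluster$evaluable & !is.na(per_cluster$p) & per_cluster$p < alpha
  rs_cluster <- if (sum(sig) == 1) per_cluster$cluster[sig] else NA_integer_
  list(per_cluster = per_cluster, km = km, rs_cluster = rs_cluster)
}

#' Extreme-survivor expression contrast
#'
#' Within one treatment stratum, contrasts per-gene expression between
#' long-term survivors (followed beyond `long_cut`, alive at that point
#' whatever happened later) and early deaths (deceased before `short_cut`)
#' by two-sided Wilcoxon rank-sum tests.
#'
#' @param cohort A `cohort_dataset`.
#' @param genes Gene ids to test.
#' @param rt_status 1 to restrict to irradiated patients, 0 to
#'   non-irradiated.
#' @param long_cut,short_cut Survival cuts (in the cohort's time unit)
#'   defining the alive and dead groups; `long_cut` must exceed `short_cut`.
#' @return `data.frame`: gene, median expression in each group, Wilcoxon
#'   statistic and p, with group sizes in attributes `n_alive` / `n_dead`.
#' @export
extreme_survivor_contrast <- function(cohort, genes, rt_status, long_cut,
                                      short_cut) {
  if (long_cut <= short_cut) stop("long_cut must exceed short_cut")
  clin <- cohort$clinical
  stratum <- clin$radiotherapy == rt_status
  alive <- stratum & clin$os_time > long_cut
  dead <- stratum & clin$os_event == 1 & clin$os_time < short_cut
  if (!any(alive)) stop("no survivors beyond long_cut = ", long_cut)
  if (!any(dead)) stop("no deaths before short_cut = ", short_cut)
  missing <- setdiff(genes, rownames(cohort$expression))
  if (length(missing)) stop("gene(s) absent from expression: ",
                            paste(missing, collapse = ", "))
  alive_ids <- clin$sample_id[alive]
  dead_ids <- clin$sample_id[dead]
  rows <- lapply(genes, function(g) {
    xa <- cohort$expression[g, alive_ids]
    xd <- cohort$expression[g, dead_ids]
    wt <- wilcoxon_ranksum(xa, xd)
    data.frame(gene = g, median_alive = median(xa), median_dead = median(xd),
               statistic = wt$statistic, p = wt$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_alive") <- length(alive_ids)
  attr(out, "n_dead") <- length(dead_ids)
  out
}
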