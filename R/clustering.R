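#' @include AllClasses.R utils.R
NULL

#' Seeded two-group k-means
#'
#' Partitions the rows of a feature matrix into two clusters under the
#' squared-Euclidean criterion. Ten restarts are drawn with
#' k-means++-style seeding from one seeded generator and the restart with
#' the lowest within-cluster sum of squares wins; rows are canonically
#' ordered before initialization, so the result is invariant to row
#' permutation and fully deterministic given (features, seed).
#'
#' @param features numeric matrix (models x features), >= 2 distinct rows,
#'   no missing values.
#' @param seed integer seed.
#' @param nRestarts number of k-means++ restarts.
#' @return integer vector of per-row cluster ids in \{0, 1\}; cluster 0 is
#'   the one containing the canonically first row. The winning objective is
#'   attached as attribute \code{"tot.withinss"}.
#' @export
kmeansTwo <- function(features, seed = 1L, nRestarts = 10L) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  if (nrow(x) < 2) stop("need at least 2 rows to form two clusters")
  if (anyNA(x)) stop("missing values in the feature matrix")
  ord <- do.call(order, as.data.frame(x))
  xs <- x[ord, , drop = FALSE]
  if (nrow(unique(xs)) < 2)
    stop("degenerate domain: all feature rows are identical")
  best <- NULL
  withSeed(seed, {
    for (r in seq_len(nRestarts)) {
      init <- kmeansPlusPlusInit(xs)
      fit <- tryCatch(
        suppressWarnings(stats::kmeans(xs, centers = init,
                                       algorithm = "Lloyd", iter.max = 100)),
        error = function(e) NULL)
      if (is.null(fit)) next
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  if (is.null(best)) stop("k-means failed on all restarts")
  cl <- integer(nrow(x))
  cl[ord] <- best$cluster
  # canonical labels: cluster of the canonically first row is 0
  cl0 <- cl[ord[1]]
  out <- ifelse(cl == cl0, 0L, 1L)
  attr(out, "tot.withinss") <- best$tot.withinss
  out
}

# k-means++ initial centers for k = 2: first center uniform, second
# sampled with probability proportional to squared distance to the first.
kmeansPlusPlusInit <- function(x) {
  n <- nrow(x)
  i1 <- sample.int(n, 1)
  d2 <- rowSums(sweep(x, 2, x[i1, ], "-")^2)
  if (sum(d2) == 0) stop("degenerate domain: all feature rows are identical")
  i2 <- sample.int(n, 1, prob = d2)
  x[c(i1, i2), , drop = FALSE]
}

#' Label the two clusters native / mirror
#'
#' Each model's score is the sum of its (standardized) selected-term
#' values; the cluster with the lower mean score is called native -- lower
#' energies mean more stable, natively oriented structures. In the
#' single-term case this reduces to comparing cluster means of that term.
#' An exact tie assigns native to cluster 0 with a warning.
#'
#' @param assignments integer vector of cluster ids in \{0, 1\}.
#' @param features the (standardized) feature matrix the clustering used.
#' @return character vector of per-model labels
#'   (\code{"native"}/\code{"mirror"}).
#' @export
labelClusters <- function(assignments, features) {
  x <- as.matrix(features)
  stopifnot(length(assignments) == nrow(x), all(assignments %in% 0:1))
  if (!any(assignments == 0) || !any(assignments == 1))
    stop("both clusters must be non-empty")
  score <- rowSums(x)
  m0 <- mean(score[assignments == 0])
  m1 <- mean(score[assignments == 1])
  if (m0 == m1) {
    warning("exact tie of cluster means; assigning native to cluster 0")
    nativeCluster <- 0L
  } else nativeCluster <- if (m0 < m1) 0L else 1L
  ifelse(assignments == nativeCluster, "native", "mirror")
}

#' Confusion-matrix evaluation of a two-cluster partition
#'
#' Native is the positive class: TP are native models placed in the
#' native-labeled cluster, TN mirror models in the mirror cluster, FP
#' mirror models in the native cluster, FN native models in the mirror
#' cluster. Reports accuracy, sensitivity (TP rate), specificity (TN
#' rate), Matthews correlation coefficient and F1 (harmonic mean of
#' precision and sensitivity). Empty denominators yield 0 by convention.
#' \code{asPrinted = TRUE} swaps the sensitivity and specificity columns,
#' reproducing the transposed labeling some published tables use.
#'
#' @param tp,tn,fp,fn non-negative counts (total > 0).
#' @param asPrinted swap SN and SPC in the output.
#' @return one-row data.frame: tp, tn, fp, fn, acc, spc, sn, mcc, f1.
#' @export
evaluateMetrics <- function(tp, tn, fp, fn, asPrinted = FALSE) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  tot <- tp + tn + fp + fn
  if (tot == 0) stop("empty confusion table")
  sdiv <- function(num, den) if (den == 0) 0 else num / den
  acc <- (tp + tn) / tot
  sn <- sdiv(tp, tp + fn)
  spc <- sdiv(tn, tn + fp)
  mccden <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mccden == 0) 0 else (tp * tn - fp * fn) / mccden
  f1 <- sdiv(2 * tp, 2 * tp + fp + fn)
  if (asPrinted) { tmp <- sn; sn <- spc; spc <- tmp }
  data.frame(tp = tp, tn = tn, fp = fp, fn = fn,
             acc = acc, spc = spc, sn = sn, mcc = mcc, f1 = f1)
}

#' Cluster one domain's models and evaluate against ground truth
#'
#' Builds the feature matrix from the selected terms of the domain's
#' energy-profile table, z-score standardizes each column when two or more
#' terms are selected (single-term clustering uses raw values, which is
#' monotone-equivalent), runs \code{\link{kmeansTwo}}, labels the clusters
#' by the lower-mean rule and, when ground truth is available, fills the
#' confusion counts. Domains with fewer than 3 native or 3 mirror models
#' are skipped for evaluation, as are domains with degenerate (constant)
#' features.
#'
#' @param profiles per-domain energy-profile data.frame.
#' @param selection a feature selection as returned by
#'   \code{\link{selectFeatures}}, or a character vector of term names.
#' @param truth optional per-model ground-truth labels.
#' @param seed integer seed for the clustering.
#' @param asPrinted passed to \code{\link{evaluateMetrics}}.
#' @return list with \code{domainId}, \code{strategy},
#'   \code{selectedTerms}, \code{assignments}, \code{predictedLabels},
#'   \code{evaluation} (data.frame or NULL), or -- when ineligible --
#'   \code{skipped = TRUE} with a \code{reason} code.
#' @export
clusterDomain <- function(profiles, selection, truth = NULL, seed = 1L,
                          asPrinted = FALSE) {
  if (is.character(selection))
    selection <- list(strategy = "custom", selectedTerms = selection)
  terms <- selection$selectedTerms
  if (!all(terms %in% names(profiles)))
    stop("profile table lacks term column(s): ",
         paste(setdiff(terms, names(profiles)), collapse = ", "))
  dom <- unique(profiles$domain_id)
  dom <- if (length(dom) == 1) dom else NA_character_
  skip <- function(reason)
    list(domainId = dom, strategy = selection$strategy,
         selectedTerms = terms, skipped = TRUE, reason = reason)
  if (!is.null(truth)) {
    stopifnot(length(truth) == nrow(profiles))
    if (sum(truth == "native") < 3 || sum(truth == "mirror") < 3)
      return(skip("fewer than 3 native or 3 mirror models"))
  }
  x <- as.matrix(profiles[, terms, drop = FALSE])
  sds <- apply(x, 2, stats::sd)
  if (all(sds == 0)) return(skip("degenerate features (all constant)"))
  if (length(terms) >= 2) {
    xz <- scale(x)
    xz[, sds == 0] <- 0
  } else xz <- x
  assignments <- tryCatch(kmeansTwo(xz, seed = seed),
                          error = function(e) NULL)
  if (is.null(assignments)) return(skip("degenerate features"))
  pred <- labelClusters(assignments, xz)
  evaluation <- NULL
  if (!is.null(truth)) {
    tp <- sum(truth == "native" & pred == "native")
    tn <- sum(truth == "mirror" & pred == "mirror")
    fp <- sum(truth == "mirror" & pred == "native")
    fn <- sum(truth == "native" & pred == "mirror")
    evaluation <- evaluateMetrics(tp, tn, fp, fn, asPrinted = asPrinted)
  }
  list(domainId = dom, strategy = selection$strategy, selectedTerms = terms,
       assignments = as.integer(assignments), predictedLabels = pred,
       evaluation = evaluation, skipped = FALSE)
}

#' Mean clustering metrics per domain group
#'
#' Unweighted means of acc/spc/sn/mcc/f1 over the evaluated domains of each
#' group (e.g. structural classes). Skipped or unevaluated domains are
#' excluded; empty groups are omitted with a warning.
#'
#' @param reports list of reports from \code{\link{clusterDomain}}.
#' @param grouping optional named character vector mapping domainId to a
#'   group label; unmapped domains form the group \code{"all"}.
#' @return data.frame: group, n_domains, acc, spc, sn, mcc, f1.
#' @export
summarizeByGroup <- function(reports, grouping = NULL) {
  ev <- Filter(function(r) !isTRUE(r$skipped) && !is.null(r$evaluation),
               reports)
  if (!length(ev)) stop("no evaluated domain reports to summarize")
  ids <- vapply(ev, function(r) r$domainId, character(1))
  grp <- if (is.null(grouping)) rep("all", length(ev))
         else ifelse(ids %in% names(grouping), grouping[ids], "all")
  metrics <- do.call(rbind, lapply(ev, function(r)
    r$evaluation[, c("acc", "spc", "sn", "mcc", "f1")]))
  if (!is.null(grouping)) {
    empty <- setdiff(unique(grouping), grp)
    if (length(empty))
      warning("group(s) with no evaluated domains omitted: ",
              paste(empty, collapse = ", "))
  }
  out <- do.call(rbind, lapply(split(seq_along(ev), grp), function(i)
    data.frame(group = grp[i[1]], n_domains = length(i),
               t(colMeans(metrics[i, , drop = FALSE])))))
  rownames(out) <- NULL
  out
}
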