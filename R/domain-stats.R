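#' @include AllClasses.R
NULL

#' Compare one energy term between native and mirror groups
#'
#' Per-domain two-group comparison with normality gating: each group is
#' screened with Shapiro-Wilk at 0.05; if both pass, a two-sided Welch
#' t-test compares means (summary statistic = mean), otherwise a two-sided
#' Mann-Whitney U test compares the groups and medians summarize them. The
#' native/mirror energy ratio RET = summary(native) / summary(mirror) is
#' reported alongside: RET < 1 means natively oriented models score lower
#' (more stable).
#'
#' @param nativeValues,mirrorValues numeric vectors, each of length >= 3.
#' @param alpha significance level.
#' @param term optional term name recorded in the output.
#' @return one-row data.frame: term, n_native, n_mirror, test_used
#'   (\code{"welch_t"} or \code{"mann_whitney"}), p_value, significant,
#'   ret, summary_statistic, sign_conflict (TRUE when the two summaries
#'   have opposite signs; ret is NA when the mirror summary is ~0).
#' @export
compareGroups <- function(nativeValues, mirrorValues, alpha = 0.05,
                          term = NA_character_) {
  if (length(nativeValues) < 3 || length(mirrorValues) < 3)
    stop("each group needs at least 3 values")
  out <- data.frame(term = term, n_native = length(nativeValues),
                    n_mirror = length(mirrorValues), test_used = NA_character_,
                    p_value = NA_real_, significant = NA, ret = NA_real_,
                    summary_statistic = NA_character_, sign_conflict = FALSE)
  both <- c(nativeValues, mirrorValues)
  if (length(unique(both)) == 1L) {
    # zero-variance identical groups: no evidence of any difference
    out$test_used <- "mann_whitney"; out$p_value <- 1
    out$significant <- FALSE; out$ret <- 1
    out$summary_statistic <- "median"
    return(out)
  }
  swp <- function(x) {
    if (length(unique(x)) == 1L) return(0)  # constant: not plausibly normal
    tryCatch(stats::shapiro.test(x)$p.value, error = function(e) 0)
  }
  normal <- swp(nativeValues) > 0.05 && swp(mirrorValues) > 0.05
  if (normal) {
    out$test_used <- "welch_t"
    out$p_value <- stats::t.test(nativeValues, mirrorValues,
                                 var.equal = FALSE)$p.value
    sn <- mean(nativeValues); sm <- mean(mirrorValues)
    out$summary_statistic <- "mean"
  } else {
    out$test_used <- "mann_whitney"
    out$p_value <- suppressWarnings(
      stats::wilcox.test(nativeValues, mirrorValues)$p.value)
    sn <- stats::median(nativeValues); sm <- stats::median(mirrorValues)
    out$summary_statistic <- "median"
  }
  out$significant <- out$p_value < alpha
  if (abs(sm) < 1e-12) out$ret <- NA_real_
  else {
    out$ret <- sn / sm
    out$sign_conflict <- (sn * sm) < 0
  }
  out
}

#' Per-domain term comparisons for a profile table
#'
#' Runs \code{\link{compareGroups}} for every term column of a per-domain
#' energy-profile table, given ground-truth orientation labels. Domains or
#' terms whose groups are too small are skipped.
#'
#' @param profiles data.frame with model rows and term columns (the
#'   energy-profile schema); must belong to a single domain.
#' @param truth character vector of per-model labels
#'   (\code{"native"}/\code{"mirror"}) aligned with \code{profiles} rows.
#' @param terms term columns to compare (default: every numeric column
#'   except identifiers).
#' @param alpha significance level.
#' @param adjust optional p-value adjustment method across terms within the
#'   domain (e.g. \code{"BH"}); default none, matching the per-term
#'   reporting convention.
#' @return data.frame with one row per term (plus a domain_id column).
#' @export
compareDomainTerms <- function(profiles, truth, terms = NULL, alpha = 0.05,
                               adjust = "none") {
  stopifnot(nrow(profiles) == length(truth))
  if (is.null(terms))
    terms <- setdiff(names(profiles)[vapply(profiles, is.numeric,
                                            logical(1))],
                     c("model_id", "domain_id"))
  nat <- truth == "native"
  if (sum(nat) < 3 || sum(!nat) < 3)
    stop("domain needs at least 3 native and 3 mirror models")
  res <- do.call(rbind, lapply(terms, function(t)
    compareGroups(profiles[[t]][nat], profiles[[t]][!nat], alpha, term = t)))
  if (adjust != "none") {
    res$p_value <- stats::p.adjust(res$p_value, method = adjust)
    res$significant <- res$p_value < alpha
  }
  dom <- unique(profiles$domain_id)
  res <- cbind(domain_id = if (length(dom) == 1) dom else NA_character_, res)
  res
}

#' Fraction of domains where a term differentiates the groups
#'
#' The share of domains whose native/mirror comparison for the given term
#' is statistically significant -- the cross-domain usability measure used
#' to rank and select energy terms.
#'
#' @param comparisons data.frame of stacked per-domain comparison rows (as
#'   from \code{\link{compareDomainTerms}}).
#' @param term term name.
#' @return numeric(1) fraction in [0, 1].
#' @export
differentiatingFraction <- function(comparisons, term) {
  rows <- comparisons[comparisons$term == term & !is.na(comparisons$term), ]
  if (!nrow(rows)) stop("no domains with a comparison for term '", term, "'")
  mean(rows$significant)
}

#' Select energy-term features for clustering
#'
#' Strategies: \code{all} (every term), \code{sig60} (terms significantly
#' different for more than 60\% of domains), \code{top2} / \code{top1}
#' (terms ranked by differentiating fraction, ties broken alphabetically),
#' \code{common3} (the fixed cross-class trio hack_elec, p_aa_pp, rama) and
#' \code{total_only} (the weighted total alone).
#'
#' @param strategy one of \code{"all"}, \code{"sig60"}, \code{"top2"},
#'   \code{"top1"}, \code{"common3"}, \code{"total_only"}.
#' @param fractions named numeric vector of per-term differentiating
#'   fractions (required for \code{all}, \code{sig60}, \code{top2},
#'   \code{top1}).
#' @return list with \code{strategy} and \code{selectedTerms}.
#' @export
selectFeatures <- function(strategy = c("all", "sig60", "top2", "top1",
                                        "common3", "total_only"),
                           fractions = NULL) {
  strategy <- match.arg(strategy)
  ranked <- function() {
    stopifnot(!is.null(fractions), !is.null(names(fractions)))
    names(fractions)[order(-fractions, names(fractions))]
  }
  sel <- switch(strategy,
    all = ranked(),
    sig60 = {
      r <- ranked()
      r <- r[fractions[r] > 0.60]
      if (!length(r)) {
        warning("no term differentiates > 60% of domains; falling back to top1")
        ranked()[1]
      } else r
    },
    top2 = utils::head(ranked(), 2),
    top1 = ranked()[1],
    common3 = c("hack_elec", "p_aa_pp", "rama"),
    total_only = "total")
  list(strategy = strategy, selectedTerms = sel)
}
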