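#' Two-sided Fisher exact p for a 2x2 table
#'
#' Conditional on both margins, sums the hypergeometric point probabilities
#' of every table at most as probable as the observed one (the conventional
#' two-sided definition; probabilities equal up to a 1e-7 relative tolerance
#' count as ties).
#'
#' @param tab 2x2 integer matrix.
#' @return list with \code{p} and \code{oddsRatio} (sample odds ratio
#'   \code{ad/bc}; \code{NA} with \code{orDefined = FALSE} on a degenerate
#'   margin).
#' @examples
#' fisherExact2x2(matrix(c(3, 1, 1, 3), 2))$p
#' @export
fisherExact2x2 <- function(tab) {
  stopifnot(all(dim(tab) == c(2L, 2L)), all(tab >= 0))
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  orDefined <- all(rowSums(tab) > 0) && all(colSums(tab) > 0)
  oddsRatio <- if (!orDefined) NA_real_ else
    (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  if (m == 0 || n == 0 || k == 0 || k == m + n) {
    return(list(p = 1, oddsRatio = oddsRatio, orDefined = orDefined))
  }
  support <- max(0, k - n):min(k, m)
  d <- stats::dhyper(support, m, n, k)
  dObs <- stats::dhyper(tab[1, 1], m, n, k)
  p <- min(1, sum(d[d <= dObs * (1 + 1e-7)]))
  list(p = p, oddsRatio = oddsRatio, orDefined = orDefined)
}

#' Phenotype co-occurrence across tumors
#'
#' For every pair of phenotypes, cross-tabulates per-tumor presence calls
#' into a 2x2 table and tests association with the two-sided Fisher exact
#' test; p values are Benjamini-Hochberg adjusted across the pairs. A
#' phenotype present (or absent) in every tumor gives a degenerate margin:
#' the odds ratio is flagged undefined and p = 1.
#'
#' @param compositions a [TumorComposition-class] (>= 2 tumors).
#' @param level \code{"tumor"} (default) tests per-tumor presence;
#'   \code{"tile"} treats each tile-level composition row as the unit, for
#'   exploratory use only (rows are then pseudo-replicated within tumors).
#' @return data.frame with one row per phenotype pair: the 2x2 cell counts
#'   (\code{n11} both present ... \code{n00} both absent), odds ratio,
#'   \code{or_defined}, \code{p}, \code{p_adj}.
#' @export
cooccurrenceTest <- function(compositions, level = c("tumor", "tile")) {
  level <- match.arg(level)
  df <- compositions@table
  if (nrow(df) < 2L) stop("need at least 2 tumors")
  levs <- phenotypeLevels()
  pairs <- utils::combn(levs, 2)
  res <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- df[[paste0("present.", pairs[1, j])]]
    b <- df[[paste0("present.", pairs[2, j])]]
    tab <- matrix(c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)), 2,
                  byrow = TRUE)
    ft <- fisherExact2x2(tab)
    data.frame(phenotype_a = pairs[1, j], phenotype_b = pairs[2, j],
               n11 = tab[1, 1], n10 = tab[1, 2], n01 = tab[2, 1],
               n00 = tab[2, 2], odds_ratio = ft$oddsRatio,
               or_defined = ft$orDefined, p = ft$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Predominant-phenotype shifts between slides of the same tumor
#'
#' Considers only tumors with at least two slides; a shift is recorded when
#' the slides disagree on the predominant phenotype.
#'
#' @param perSlide a [TumorComposition-class] built with
#'   \code{composeTumors(..., by = "slide")}.
#' @return list with \code{shifts} (data.frame tumor_id, from, to — one row
#'   per shifted tumor, ordered slide pairs), \code{nMultiSlide} (the
#'   denominator) and \code{nConserved}.
#' @export
detectShifts <- function(perSlide) {
  df <- perSlide@table
  if (is.null(df$slide_id)) stop("perSlide must carry slide ids (by = 'slide')")
  multi <- names(which(table(df$tumor_id) >= 2))
  shifts <- list()
  for (tu in multi) {
    sub <- df[df$tumor_id == tu, , drop = FALSE]
    sub <- sub[order(sub$slide_id), , drop = FALSE]
    doms <- sub$predominant
    if (length(unique(doms)) > 1L) {
      shifts[[tu]] <- data.frame(tumor_id = tu, from = doms[1],
                                 to = doms[length(doms)],
                                 stringsAsFactors = FALSE)
    }
  }
  shifts <- if (length(shifts)) do.call(rbind, shifts) else
    data.frame(tumor_id = character(0), from = character(0), to = character(0))
  rownames(shifts) <- NULL
  list(shifts = shifts, nMultiSlide = length(multi),
       nConserved = length(multi) - nrow(shifts))
}

.asSurvDF <- function(records) {
  df <- as.data.frame(records)
  stopifnot(all(c("time_months", "event") %in% names(df)))
  if (any(df$time_months <= 0)) stop("survival times must be positive")
  df
}

#' Kaplan-Meier curves and log-rank test for a binary grouping
#'
#' @param records data.frame of survival records with \code{time_months},
#'   \code{event} and the grouping column.
#' @param group name of the grouping column (coerced to factor, 2 levels).
#' @return list with \code{curves} (data.frame group, time, survival,
#'   at-risk, events), \code{median} (named per-group median survival, NA if
#'   never reached), \code{chisq}, \code{df} and \code{p} (NA with a message
#'   when no events are observed).
#' @export
kmLogrank <- function(records, group) {
  df <- .asSurvDF(records)
  g <- factor(df[[group]])
  if (nlevels(g) != 2L) stop("grouping must have exactly 2 levels")
  if (any(table(g) == 0L)) stop("one group is empty")
  s <- survival::Surv(df$time_months, df$event)
  fit <- survival::survfit(s ~ g)
  sm <- summary(fit)
  curves <- data.frame(group = sub("^g=", "", as.character(sm$strata)),
                       time = sm$time, survival = sm$surv,
                       at_risk = sm$n.risk, events = sm$n.event,
                       stringsAsFactors = FALSE)
  med <- summary(fit)$table[, "median"]
  names(med) <- sub("^g=", "", names(med))
  if (sum(df$event) == 0L) {
    return(list(curves = curves, median = med, chisq = NA_real_, df = 1L,
                p = NA_real_, note = "no events observed"))
  }
  lr <- survival::survdiff(s ~ g)
  p <- stats::pchisq(lr$chisq, df = 1, lower.tail = FALSE)
  list(curves = curves, median = med, chisq = unname(lr$chisq), df = 1L, p = p)
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with Breslow tie handling; reports per
#' covariate the hazard ratio, Wald 95% CI and p.
#'
#' @param records data.frame of survival records.
#' @param covariates character; column names entered into the model (binary
#'   or numeric).
#' @return data.frame with \code{covariate}, \code{coef}, \code{hr},
#'   \code{ci_lower}, \code{ci_upper}, \code{p}.
#' @export
coxFit <- function(records, covariates) {
  df <- .asSurvDF(records)
  miss <- setdiff(covariates, names(df))
  if (length(miss)) stop("missing covariate(s): ", paste(miss, collapse = ", "))
  for (cv in covariates) {
    v <- as.numeric(df[[cv]])
    if (stats::var(v) == 0) stop("constant covariate: ", cv)
    df[[cv]] <- v
  }
  if (sum(df$event) < length(covariates)) {
    stop("fewer events than covariates")
  }
  fml <- stats::as.formula(paste("survival::Surv(time_months, event) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(fml, data = df, ties = "breslow"),
    warning = function(w) {
      stop("Cox fit unstable (possible separation or collinearity): ",
           conditionMessage(w))
    })
  s <- summary(fit)
  data.frame(covariate = rownames(s$coefficients),
             coef = s$coefficients[, "coef"],
             hr = s$coefficients[, "exp(coef)"],
             ci_lower = s$conf.int[, "lower .95"],
             ci_upper = s$conf.int[, "upper .95"],
             p = s$coefficients[, "Pr(>|z|)"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Double-scorer H-score concordance
#'
#' Correlation between two raters' H-scores over the same cases (Pearson by
#' default; Spearman for a rank-based check).
#'
#' @param scoresA,scoresB numeric vectors of equal length >= 3.
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @return list with \code{r}, \code{p}, \code{n}, \code{method}.
#' @export
scorerConcordance <- function(scoresA, scoresB,
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(scoresA) != length(scoresB)) stop("score vectors differ in length")
  if (length(scoresA) < 3L) stop("need at least 3 paired scores")
  if (stats::sd(scoresA) == 0 || stats::sd(scoresB) == 0) {
    stop("zero variance in scores")
  }
  ct <- suppressWarnings(stats::cor.test(scoresA, scoresB, method = method))
  list(r = unname(ct$estimate), p = ct$p.value, n = length(scoresA),
       method = method)
}
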