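#' Rank-based AUC of a score predicting a binary label
#'
#' Mann-Whitney AUC: the probability that a randomly chosen positive case
#' outscores a randomly chosen negative one, ties counted half.
#'
#' @param score numeric predictor.
#' @param label logical or 0/1; \code{TRUE} is the positive class.
#' @return AUC in [0, 1]; \code{NA} when one class is empty.
#' @export
rankAUC <- function(score, label) {
  label <- as.logical(label)
  n1 <- sum(label); n0 <- sum(!label)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' In-silico marker screening against a subtype signature
#'
#' For each candidate marker: the Pearson correlation of its expression with
#' the continuous signature score (oriented so positive r = classical
#' direction when the score is a classicalness score), and the Mann-Whitney
#' AUC of the marker as a ranking predictor of the binary subtype label.
#'
#' @param expression cases x markers numeric matrix (colnames = markers).
#' @param signatureScore numeric per-case continuous score.
#' @param subtypeLabel logical/0-1 per case (positive class per marker
#'   orientation chosen by the caller).
#' @return data.frame with \code{marker}, \code{r} (NA for constant
#'   markers), \code{auc} (NA when labels are single-class).
#' @export
signatureScreen <- function(expression, signatureScore, subtypeLabel) {
  expression <- as.matrix(expression)
  if (nrow(expression) < 3L) stop("need at least 3 cases")
  if (nrow(expression) != length(signatureScore) ||
      nrow(expression) != length(subtypeLabel)) {
    stop("cases must match between expression, score and labels")
  }
  res <- lapply(colnames(expression), function(m) {
    v <- expression[, m]
    r <- if (stats::sd(v) == 0) NA_real_ else stats::cor(v, signatureScore)
    data.frame(marker = m, r = r, auc = rankAUC(v, subtypeLabel),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' TMA specificity filter for a candidate subtype marker
#'
#' Applies the three antibody-selection rules to per-case TMA records
#' (maximum intensity class per case): (i) major expression in the target
#' subtype — at least 50% of target-subtype cases at moderate/strong
#' intensity (>= 2); (ii) lack of expression in the opposite subtype — by
#' default the conjunction: zero strong (intensity 3) cases and at most one
#' moderate (intensity 2) case (set \code{ruleTwoDisjunctive = TRUE} for the
#' reading where either condition alone suffices); (iii) restriction to
#' tumor cells — no record with stromal expression.
#'
#' @param records data.frame with columns \code{marker}, \code{case_id},
#'   \code{subtype} (\code{"classical"} or \code{"basal"}), \code{intensity}
#'   (0-3) and \code{stromal_expression} (logical).
#' @param target the subtype the marker is meant to flag.
#' @param ruleTwoDisjunctive see above (default FALSE, the stricter
#'   conjunctive reading).
#' @return one-row data.frame: \code{marker}, \code{target}, \code{pass},
#'   per-rule flags, and a \code{reason} naming the first violated rule
#'   (empty when passing).
#' @export
tmaSpecificityFilter <- function(records, target = c("classical", "basal"),
                                 ruleTwoDisjunctive = FALSE) {
  target <- match.arg(target)
  stopifnot(all(records$intensity %in% 0:3))
  opposite <- setdiff(c("classical", "basal"), target)
  if (!any(records$subtype == target) || !any(records$subtype == opposite)) {
    stop("records must cover both subtype groups")
  }
  marker <- unique(records$marker)
  if (length(marker) != 1L) stop("records must describe a single marker")
  tgt <- records[records$subtype == target, ]
  opp <- records[records$subtype == opposite, ]
  rule1 <- mean(tgt$intensity >= 2) >= 0.5
  nStrong <- sum(opp$intensity == 3)
  nModerate <- sum(opp$intensity == 2)
  rule2 <- if (ruleTwoDisjunctive) (nStrong < 1) || (nModerate < 2) else
    (nStrong < 1) && (nModerate < 2)
  rule3 <- !any(records$stromal_expression)
  pass <- rule1 && rule2 && rule3
  reason <- if (pass) "" else if (!rule1) {
    sprintf("rule (i): only %.0f%% of %s cases at moderate/strong intensity",
            100 * mean(tgt$intensity >= 2), target)
  } else if (!rule2) {
    sprintf("rule (ii): opposite subtype shows %d strong and %d moderate cases",
            nStrong, nModerate)
  } else {
    "rule (iii): expression in stromal cells"
  }
  data.frame(marker = marker, target = target, pass = pass,
             rule1_major_expression = rule1,
             rule2_opposite_lack = rule2,
             rule3_tumor_restricted = rule3,
             reason = reason, stringsAsFactors = FALSE)
}

#' IHC-RNA concordance keep/drop rule
#'
#' Correlates per-case H-scores with matched mRNA levels; a marker is kept
#' when the correlation is significant at \code{alpha} (two-sided).
#'
#' @param hscores,rna paired numeric vectors (>= 3 cases).
#' @param alpha significance level (default 0.05).
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @return one-row data.frame: \code{r}, \code{p}, \code{n}, \code{keep},
#'   \code{reason}.
#' @export
ihcRnaConcordance <- function(hscores, rna, alpha = 0.05,
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(hscores) != length(rna)) stop("unpaired input lengths")
  if (length(hscores) < 3L) stop("need at least 3 paired cases")
  if (stats::sd(hscores) == 0 || stats::sd(rna) == 0) {
    stop("zero variance input")
  }
  ct <- suppressWarnings(stats::cor.test(hscores, rna, method = method))
  keep <- ct$p.value < alpha
  data.frame(r = unname(ct$estimate), p = ct$p.value, n = length(hscores),
             keep = keep,
             reason = if (keep) "" else
               sprintf("IHC-RNA correlation nonsignificant (r = %.2f, p = %.2g)",
                       unname(ct$estimate), ct$p.value),
             stringsAsFactors = FALSE)
}
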