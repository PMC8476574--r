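#' 3x3 confusion matrix of stained vs assigned phenotypes
#'
#' Cross-tabulates staining-derived (true) phenotypes against
#' classifier-assigned phenotypes in the fixed order excluded, ignored,
#' inflamed (rows = truth, columns = assignment). Pairs with an unassigned or
#' missing assignment are dropped with a message; any other label errors.
#'
#' @param truth,assigned Equal-length label vectors.
#' @return A `confusion_matrix3` (integer matrix) with attribute `n_dropped`.
#' @export
#' @examples
#' confusion_matrix3(rep(phenotype_levels(), each = 3),
#'                   rep(phenotype_levels(), each = 3))
confusion_matrix3 <- function(truth, assigned) {
  if (length(truth) != length(assigned)) {
    abort_input("`truth` and `assigned` must have equal length")
  }
  if (length(truth) == 0L) abort_input("empty label vectors")
  phen <- phenotype_levels()
  bad <- !truth %in% phen
  if (any(bad)) {
    abort_input("`truth` contains label(s) outside the phenotype set: ",
                paste(unique(truth[bad]), collapse = ", "))
  }
  drop <- is.na(assigned) | assigned == "unassigned"
  bad <- !drop & !assigned %in% phen
  if (any(bad)) {
    abort_input("`assigned` contains label(s) outside the phenotype set: ",
                paste(unique(assigned[bad]), collapse = ", "))
  }
  if (any(drop)) message("dropping ", sum(drop), " unassigned sample(s)")
  cm <- table(factor(truth[!drop], levels = phen),
              factor(assigned[!drop], levels = phen))
  cm <- matrix(as.integer(cm), 3, 3, dimnames = list(truth = phen, assigned = phen))
  structure(cm, n_dropped = sum(drop), class = c("confusion_matrix3", class(cm)))
}

#' Coerce a 3x3 count matrix to a confusion matrix
#'
#' @param x Numeric 3x3 matrix of non-negative counts, rows = stained truth,
#'   columns = assignment, both in the order excluded, ignored, inflamed.
#' @return A `confusion_matrix3`.
#' @export
as_confusion_matrix3 <- function(x) {
  x <- as.matrix(x)
  if (!all(dim(x) == c(3L, 3L))) abort_input("need a 3x3 matrix")
  if (any(x < 0) || any(x != trunc(x))) abort_input("counts must be non-negative integers")
  m <- matrix(as.integer(x), 3, 3,
              dimnames = list(truth = phenotype_levels(),
                              assigned = phenotype_levels()))
  structure(m, n_dropped = 0L, class = c("confusion_matrix3", class(m)))
}

#' @export
print.confusion_matrix3 <- function(x, ...) {
  print(unclass(x))
  invisible(x)
}

#' @export
tidy.confusion_matrix3 <- function(x, ...) {
  tibble::tibble(
    truth = rep(rownames(x), times = 3),
    assigned = rep(colnames(x), each = 3),
    n = as.integer(x)
  )
}

#' Per-class metrics of a 3x3 confusion matrix
#'
#' Sensitivity (recall) is the diagonal over the row total. The quantity
#' published alongside it as "specificity" in this field's classifier tables
#' is mathematically the column-wise *precision* (correct assignments over
#' all samples assigned to the class); it is reported here as
#' `specificity_paper` for fidelity, next to the conventional
#' `specificity_true` (1 - false positive rate). Margins of zero yield `NA`,
#' never 0.
#'
#' @param cm A `confusion_matrix3`.
#' @return Tibble with one row per phenotype: `phenotype`, `n_true`,
#'   `n_assigned`, `sensitivity`, `specificity_paper`, `specificity_true`.
#' @seealso [accuracy()]
#' @export
confusion_metrics <- function(cm) {
  if (!inherits(cm, "confusion_matrix3")) cm <- as_confusion_matrix3(cm)
  total <- sum(cm)
  if (total == 0L) abort_input("confusion matrix is empty")
  d <- unname(diag(cm))
  rs <- unname(rowSums(cm))
  cs <- unname(colSums(cm))
  safe_div <- function(a, b) ifelse(b > 0, a / b, NA_real_)
  tn <- total - rs - cs + d
  tibble::tibble(
    phenotype = phenotype_levels(),
    n_true = as.integer(rs),
    n_assigned = as.integer(cs),
    sensitivity = safe_div(d, rs),
    specificity_paper = safe_div(d, cs),
    specificity_true = safe_div(tn, tn + (cs - d))
  )
}

#' Overall accuracy of a confusion matrix
#'
#' Trace over total. `n_total` overrides the denominator, e.g. with the full
#' cohort size when samples without an assignment are counted as incorrect
#' (the convention behind some published headline accuracies whose table
#' margins sum to less than the cohort).
#'
#' @param cm A `confusion_matrix3` (or 3x3 count matrix).
#' @param n_total Denominator; defaults to the matrix total.
#' @return A single number in `[0, 1]`.
#' @export
accuracy <- function(cm, n_total = NULL) {
  if (!inherits(cm, "confusion_matrix3")) cm <- as_confusion_matrix3(cm)
  n_total <- n_total %||% sum(cm)
  if (n_total <= 0) abort_input("`n_total` must be positive")
  sum(diag(cm)) / n_total
}

#' @export
glance.confusion_matrix3 <- function(x, ...) {
  tibble::tibble(accuracy = accuracy(x), n = sum(x),
                 n_dropped = attr(x, "n_dropped") %||% 0L)
}

#' 2x2 response table for the inflamed-phenotype dichotomy
#'
#' Dichotomizes phenotypes into the cold group (excluded + ignored) versus
#' inflamed and cross-tabulates against anti-PD1 response. Row order is
#' fixed (`excluded_ignored`, `inflamed`), column order
#' (`nonresponder`, `responder`).
#'
#' @param phenotype Phenotype labels (3-level, or already
#'   `excluded_ignored`/`inflamed`); unassigned/`NA` dropped with a message.
#' @param response `responder`/`nonresponder` labels.
#' @return A `two_by_two` integer matrix.
#' @export
response_table <- function(phenotype, response) {
  if (length(phenotype) != length(response)) {
    abort_input("`phenotype` and `response` must have equal length")
  }
  drop <- is.na(phenotype) | phenotype == "unassigned" | is.na(response)
  if (any(drop)) message("dropping ", sum(drop), " sample(s) without phenotype/response")
  phenotype <- phenotype[!drop]
  response <- response[!drop]
  grp <- ifelse(phenotype == "inflamed", "inflamed", "excluded_ignored")
  bad <- !phenotype %in% c(phenotype_levels(), "excluded_ignored", "inflamed")
  if (any(bad)) abort_input("unknown phenotype label(s)")
  if (!all(response %in% c("responder", "nonresponder"))) {
    abort_input("`response` must be responder/nonresponder")
  }
  tab <- table(factor(grp, levels = c("excluded_ignored", "inflamed")),
               factor(response, levels = c("nonresponder", "responder")))
  m <- matrix(as.integer(tab), 2, 2,
              dimnames = list(group = c("excluded_ignored", "inflamed"),
                              outcome = c("nonresponder", "responder")))
  structure(m, class = c("two_by_two", class(m)))
}

#' @rdname response_table
#' @param x 2x2 count matrix (rows: excluded_ignored, inflamed; columns:
#'   nonresponder, responder).
#' @export
as_two_by_two <- function(x) {
  x <- as.matrix(x)
  if (!all(dim(x) == c(2L, 2L))) abort_input("need a 2x2 matrix")
  if (any(x < 0)) abort_input("counts must be >= 0")
  m <- matrix(as.integer(x), 2, 2,
              dimnames = list(group = c("excluded_ignored", "inflamed"),
                              outcome = c("nonresponder", "responder")))
  structure(m, class = c("two_by_two", class(m)))
}

#' Negative and positive predictive value of the inflamed dichotomy
#'
#' With inflamed as test-positive and response as condition-positive:
#' PPV = responders among inflamed / all inflamed; NPV = nonresponders among
#' excluded+ignored / all excluded+ignored. Values are returned unrounded;
#' round only at presentation.
#'
#' @param t A `two_by_two` table (see [response_table()]).
#' @return Tibble with columns `npv`, `ppv` (NA on a zero group total).
#' @export
#' @examples
#' npv_ppv(as_two_by_two(matrix(c(35, 4, 4, 6), 2, byrow = TRUE)))
npv_ppv <- function(t) {
  if (!inherits(t, "two_by_two")) t <- as_two_by_two(t)
  n_cold <- sum(t["excluded_ignored", ])
  n_infl <- sum(t["inflamed", ])
  tibble::tibble(
    npv = if (n_cold > 0) t["excluded_ignored", "nonresponder"] / n_cold else NA_real_,
    ppv = if (n_infl > 0) t["inflamed", "responder"] / n_infl else NA_real_
  )
}

#' Cross-product odds ratio of a 2x2 table
#'
#' Closed-form odds ratio of response for inflamed versus excluded+ignored;
#' equals the univariate logistic-regression OR on the binary group
#' indicator.
#'
#' @param t A `two_by_two` table.
#' @return A single number.
#' @export
odds_ratio_2x2 <- function(t) {
  if (!inherits(t, "two_by_two")) t <- as_two_by_two(t)
  (t["excluded_ignored", "nonresponder"] * t["inflamed", "responder"]) /
    (t["excluded_ignored", "responder"] * t["inflamed", "nonresponder"])
}

#' ROC curve and AUC
#'
#' Thresholds are all midpoints between consecutive distinct scores plus
#' +/-Inf; tied scores therefore move along diagonal segments, which makes
#' the trapezoidal area and the Mann-Whitney pair statistic (ties credited
#' 0.5) identical -- both are computed and their equality asserted to 1e-12.
#' `direction = "lower"` declares that lower scores predict the positive
#' class (the scores are negated internally and the orientation recorded).
#'
#' @param scores Numeric predictor.
#' @param labels Outcome; logical, 0/1, or labels with `positive` naming the
#'   positive class (`responder` recognized by default).
#' @param positive Positive class label for character/factor `labels`.
#' @param direction `"higher"` (default) or `"lower"`: which end of the score
#'   predicts the positive class.
#' @return A `roc_result`: list with `thresholds`, `tpr`, `fpr`, `auc`,
#'   `auc_mann_whitney`, `direction`, `n_pos`, `n_neg`.
#' @export
#' @examples
#' r <- roc_auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
#' r$auc
roc_auc <- function(scores, labels, positive = NULL,
                    direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  y <- as_binary(labels, positive, "labels")
  if (length(scores) != length(y)) {
    abort_input("`scores` and `labels` must have equal length")
  }
  if (anyNA(scores) || anyNA(y)) abort_input("missing values not allowed")
  n_pos <- sum(y)
  n_neg <- sum(!y)
  if (n_pos == 0L || n_neg == 0L) {
    abort_input("both classes must be present")
  }
  s <- if (direction == "lower") -scores else scores

  r <- rank(s, ties.method = "average")
  auc_mw <- (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  us <- sort(unique(s), decreasing = TRUE)
  thr <- c(Inf, if (length(us) > 1) (us[-1] + us[-length(us)]) / 2, -Inf)
  tpr <- vapply(thr, function(t) sum(s[y] > t) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(s[!y] > t) / n_neg, numeric(1))
  auc_trap <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  if (abs(auc_trap - auc_mw) > 1e-12) {
    stop("internal: trapezoid and Mann-Whitney AUC disagree")
  }
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr,
                 auc = auc_trap, auc_mann_whitney = auc_mw,
                 direction = direction, n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> AUC = ", format(x$auc, digits = 4),
      " (", x$n_pos, " positive / ", x$n_neg, " negative, direction = ",
      x$direction, ")\n", sep = "")
  invisible(x)
}

#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg,
                 direction = x$direction)
}

#' @export
tidy.roc_result <- function(x, ...) {
  tibble::tibble(threshold = x$thresholds, tpr = x$tpr, fpr = x$fpr)
}

#' Univariate logistic regression odds ratio (IRLS)
#'
#' Fits `logit P(outcome = 1) = a + b * score` by iteratively reweighted
#' least squares (tolerance 1e-10, at most `max_iter` iterations) and reports
#' the per-unit odds ratio `exp(b)` with a Wald confidence interval on the
#' logit scale. Perfect separation is detected as a diverging slope and
#' reported as non-converged. `scale = "sd"` standardizes the score first,
#' giving a per-standard-deviation OR.
#'
#' @param score Numeric covariate.
#' @param outcome Binary outcome (see [roc_auc()] for accepted encodings).
#' @param positive Positive class for label outcomes.
#' @param conf_level Confidence level for the Wald interval (default 0.95).
#' @param scale `"unit"` (default) or `"sd"`.
#' @param tol IRLS convergence tolerance on the coefficients.
#' @param max_iter Iteration cap.
#' @return One-row tibble: `odds_ratio`, `conf_low`, `conf_high`, `log_or`,
#'   `std_error`, `n`, `converged`.
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(200)
#' y <- runif(200) < plogis(x)
#' logistic_or(x, y)
logistic_or <- function(score, outcome, positive = NULL, conf_level = 0.95,
                        scale = c("unit", "sd"), tol = 1e-10,
                        max_iter = 100L) {
  scale <- match.arg(scale)
  y <- as.numeric(as_binary(outcome, positive))
  if (length(score) != length(y)) {
    abort_input("`score` and `outcome` must have equal length")
  }
  if (!all(is.finite(score))) abort_input("`score` must be finite")
  if (all(y == 1) || all(y == 0)) abort_input("both outcomes must be present")
  x <- if (scale == "sd") score / stats::sd(score) else score
  X <- cbind(1, x)

  beta <- c(0, 0)
  converged <- FALSE
  separated <- FALSE
  fisher <- NULL
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    w <- pmax(p * (1 - p), .Machine$double.eps)
    z <- eta + (y - p) / w
    fisher <- crossprod(X * sqrt(w))
    beta_new <- drop(solve(fisher, crossprod(X * w, z)))
    step <- max(abs(beta_new - beta))
    beta <- beta_new
    if (abs(beta[2]) > 30) { # slope diverging: (quasi-)separation
      separated <- TRUE
      break
    }
    if (step < tol) {
      converged <- TRUE
      break
    }
  }
  if (separated) {
    warning("perfect or quasi-perfect separation: odds ratio diverges")
  }
  beta <- unname(beta)
  se <- unname(sqrt(solve(fisher)[2, 2]))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    odds_ratio = exp(beta[2]),
    conf_low = exp(beta[2] - zq * se),
    conf_high = exp(beta[2] + zq * se),
    log_or = beta[2],
    std_error = se,
    n = length(y),
    converged = converged && !separated
  )
}

#' Average expression of a gene set per sample
#'
#' The score of a gene set is the unweighted mean of the available listed
#' genes' log2 values in each sample; listed genes absent from the matrix are
#' dropped with a warning.
#'
#' @param expr Expression tibble or `expression_cohort`.
#' @param genes Character vector of gene ids.
#' @return Tibble `sample_id`, `score`.
#' @export
gene_set_score <- function(expr, genes) {
  if (inherits(expr, "expression_cohort")) expr <- expr$expression
  m <- expr_matrix(expr)
  present <- intersect(genes, rownames(m))
  if (length(present) == 0L) abort_input("none of the listed genes are present")
  absent <- setdiff(genes, present)
  if (length(absent)) {
    warning(length(absent), " gene(s) absent from `expr`: ",
            paste(head(absent, 5), collapse = ", "))
  }
  tibble::tibble(sample_id = colnames(m),
                 score = unname(colMeans(m[present, , drop = FALSE])))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment with monotonicity
#' enforcement; stable under permutation of the input. `NA`s are preserved
#' and excluded from the effective number of tests.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(p) {
  if (!is.numeric(p)) abort_input("`p` must be numeric")
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort_input("p-values must lie in [0, 1]")
  out <- p
  ok <- !is.na(p)
  q <- p[ok]
  n <- length(q)
  if (n == 0L) return(out)
  o <- order(q, decreasing = TRUE)
  ro <- order(o)
  out[ok] <- pmin(1, cummin(n / (n:1) * q[o]))[ro]
  out
}
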