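# Thresholded categorization of X-gene trajectories and the associated
# exact/rank-based tests.

#' Categorize a stage-transition delta
#'
#' Classifies the change of a gene's pre-leptotene-normalized expression
#' between consecutive stages: a delta above the upper threshold is
#' \emph{reduced silencing}, below the lower threshold \emph{increased
#' silencing}, and anything in between -- boundaries included -- is
#' \emph{unaltered}.
#'
#' @param delta numeric vector of transition deltas (log-units); must be
#'   finite.
#' @param thresholds a [CategoryThresholds()].
#' @return Factor with levels \code{reduced}, \code{unaltered},
#'   \code{increased}.
#' @examples
#' categorizeTransition(c(1.5, 1, 0, -1, -1.2))
#' @export
categorizeTransition <- function(delta, thresholds = CategoryThresholds()) {
  if (any(!is.finite(delta)))
    stop("non-finite transition delta", call. = FALSE)
  out <- ifelse(delta > thresholds@transitionHi, "reduced",
                ifelse(delta < thresholds@transitionLo, "increased",
                       "unaltered"))
  factor(out, levels = .CATEGORY_LEVELS)
}

#' Categorize the severity of a silencing defect
#'
#' Classifies the mutant-minus-wild-type difference of pre-leptotene-
#' normalized expression at the final (pachytene) stage: above the strong
#' threshold is a \emph{strong} defect, between the mild and strong
#' thresholds (both included) \emph{mild}, and below the mild threshold
#' \emph{no defect}.
#'
#' @param diff numeric vector of final-stage genotype differences
#'   (log-units); must be finite.
#' @param thresholds a [CategoryThresholds()].
#' @return Factor with levels \code{none}, \code{mild}, \code{strong}.
#' @examples
#' categorizeSeverity(c(3, 2.5, 1, 0.9, 0))
#' @export
categorizeSeverity <- function(diff, thresholds = CategoryThresholds()) {
  if (any(!is.finite(diff)))
    stop("non-finite severity difference", call. = FALSE)
  out <- ifelse(diff > thresholds@severityStrong, "strong",
                ifelse(diff >= thresholds@severityMild, "mild", "none"))
  factor(out, levels = .SEVERITY_LEVELS)
}

#' Build a genotype x category contingency table
#'
#' Tallies gene counts per transition category for two genotypes. Both
#' genotypes must categorize the same gene set (checked via names when
#' available), so each row sums to the informative-gene count.
#'
#' @param catA,catB category factors (levels reduced/unaltered/increased) for
#'   the same genes in the two genotypes; name them by gene to enable the
#'   gene-set check.
#' @param genotypes row labels.
#' @return A 2 x 3 integer matrix, rows = genotypes, columns = categories.
#' @export
buildContingency <- function(catA, catB, genotypes = c("WT", "MUT")) {
  if (length(catA) != length(catB))
    stop("gene sets differ between genotypes (unequal lengths)",
         call. = FALSE)
  if (!is.null(names(catA)) && !is.null(names(catB)) &&
      !identical(sort(names(catA)), sort(names(catB))))
    stop("gene sets differ between genotypes", call. = FALSE)
  catA <- factor(catA, levels = .CATEGORY_LEVELS)
  catB <- factor(catB, levels = .CATEGORY_LEVELS)
  tab <- rbind(table(catA), table(catB))
  rownames(tab) <- genotypes
  tab
}

# log probability of a table under the multivariate hypergeometric null
.logProbTable <- function(tab, lfRow, lfCol, lfN) {
  lfRow + lfCol - lfN - sum(lgamma(tab + 1))
}

#' Fisher's exact test for an r x c table
#'
#' Exact conditional test with both margins fixed: the p-value is the total
#' multivariate hypergeometric probability of all margin-preserving tables
#' whose probability does not exceed that of the observed table (with a 1e-7
#' relative slack absorbing floating-point ties). Tables are enumerated
#' exhaustively over the free cells, so the result is exact for the 2 x 3
#' genotype-by-category tables this package produces (and any table of
#' moderate total count).
#'
#' @param tab nonnegative integer matrix, at least 2 x 2.
#' @return The exact p-value. A table with a zero row or column margin is
#'   degenerate: p = 1 with a warning.
#' @examples
#' fisherExactRxC(rbind(c(4, 43, 185), c(74, 134, 24)))
#' @export
fisherExactRxC <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("table must be at least 2 x 2", call. = FALSE)
  if (any(tab < 0) || any(tab != floor(tab)))
    stop("table entries must be nonnegative integers", call. = FALSE)
  # an all-zero column is an unobserved category: it carries no information
  # and is dropped before enumeration
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  rs <- rowSums(tab)
  cs <- colSums(tab)
  if (any(rs == 0) || ncol(tab) < 2) {
    warning("zero margin: degenerate table, p = 1 by convention",
            call. = FALSE)
    return(1)
  }
  lfRow <- sum(lgamma(rs + 1))
  lfCol <- sum(lgamma(cs + 1))
  lfN <- lgamma(sum(tab) + 1)
  logObs <- .logProbTable(tab, lfRow, lfCol, lfN)
  cutoff <- logObs + log1p(1e-7)

  r <- nrow(tab); cc <- ncol(tab)
  psum <- 0
  cur <- matrix(0L, r, cc)
  # enumerate tables row by row; within a row, cell by cell
  recurse <- function(i, j, rowLeft, colLeft) {
    if (i == r) {                      # last row forced by column margins
      cur[r, ] <<- colLeft
      lp <- .logProbTable(cur, lfRow, lfCol, lfN)
      if (lp <= cutoff) psum <<- psum + exp(lp)
      return(invisible())
    }
    if (j == cc) {                     # last cell of row i forced
      if (rowLeft > colLeft[cc]) return(invisible())
      cur[i, cc] <<- rowLeft
      colLeft[cc] <- colLeft[cc] - rowLeft
      recurse(i + 1L, 1L, rs[i + 1L], colLeft)
      return(invisible())
    }
    for (v in 0:min(rowLeft, colLeft[j])) {
      cur[i, j] <<- v
      cl <- colLeft
      cl[j] <- cl[j] - v
      recurse(i, j + 1L, rowLeft - v, cl)
    }
  }
  recurse(1L, 1L, rs[1L], cs)
  min(1, psum)
}

#' Ordered trend of baseline expression across severity groups
#'
#' Jonckheere--Terpstra test for an increasing trend of pre-leptotene
#' expression across ordered severity groups (none < mild < strong): the
#' statistic sums, over ordered group pairs, the number of value pairs in
#' increasing order (ties count one half). The one-sided p-value uses the
#' exact permutation distribution when the total sample size is at most 12
#' and otherwise a normal approximation with tie-corrected variance and
#' continuity correction. Per-group medians and quartiles are reported for
#' the boxplot-style summary.
#'
#' @param values numeric vector (e.g. per-gene pre-leptotene mean
#'   expression).
#' @param groups ordered grouping (coerced to factor; level order = trend
#'   order). At least two groups must be nonempty.
#' @return A list with \code{statistic} (J), \code{p.value} (one-sided,
#'   increasing), \code{method} and \code{groupSummary}.
#' @export
severityBaselineTrend <- function(values, groups) {
  groups <- if (is.factor(groups)) droplevels(groups) else factor(groups)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(groups[keep])
  k <- nlevels(groups)
  if (k < 2L)
    stop("need at least two nonempty groups for a trend test", call. = FALSE)
  N <- length(values)
  split_ <- split(values, groups)

  jstat <- function(v, g) {
    s <- 0
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      a <- v[g == levels(g)[i]]
      b <- v[g == levels(g)[j]]
      cmp <- outer(a, b, "<")
      eq <- outer(a, b, "==")
      s <- s + sum(cmp) + 0.5 * sum(eq)
    }
    s
  }
  J <- jstat(values, groups)
  sizes <- tabulate(groups)

  summ <- do.call(rbind, lapply(seq_len(k), function(i) {
    q <- stats::quantile(split_[[i]], c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(group = levels(groups)[i], n = sizes[i], q1 = q[1],
               median = q[2], q3 = q[3], stringsAsFactors = FALSE)
  }))

  if (N <= 12L) {
    # exact permutation distribution over all distinct group assignments
    perms <- .groupAssignments(N, sizes)
    stats <- apply(perms, 2L, function(lab)
      jstat(values, factor(levels(groups)[lab], levels = levels(groups))))
    p <- mean(stats >= J - 1e-12)
    method <- "exact permutation"
  } else {
    mean_ <- (N^2 - sum(sizes^2)) / 4
    t_ <- table(values)
    u_ <- sizes
    v1 <- (N * (N - 1) * (2 * N + 5) -
             sum(t_ * (t_ - 1) * (2 * t_ + 5)) -
             sum(u_ * (u_ - 1) * (2 * u_ + 5))) / 72
    v2 <- sum(t_ * (t_ - 1) * (t_ - 2)) * sum(u_ * (u_ - 1) * (u_ - 2)) /
      (36 * N * (N - 1) * (N - 2))
    v3 <- sum(t_ * (t_ - 1)) * sum(u_ * (u_ - 1)) / (8 * N * (N - 1))
    var_ <- v1 + v2 + v3
    if (var_ <= 0) {
      p <- 1
    } else {
      z <- (J - mean_ - 0.5) / sqrt(var_)
      p <- stats::pnorm(z, lower.tail = FALSE)
    }
    method <- "normal approximation"
  }
  list(statistic = J, p.value = p, method = method, groupSummary = summ)
}

# All distinct assignments of N items to groups with the given sizes,
# as an N x (number of assignments) matrix of group indices.
.groupAssignments <- function(N, sizes) {
  build <- function(avail, gi) {
    if (gi == length(sizes)) {
      m <- matrix(0L, N, 1L)
      m[avail, 1L] <- gi
      return(m)
    }
    picks <- utils::combn(avail, sizes[gi])
    cols <- lapply(seq_len(ncol(picks)), function(ci) {
      rest <- build(setdiff(avail, picks[, ci]), gi + 1L)
      rest[picks[, ci], ] <- gi
      rest
    })
    do.call(cbind, cols)
  }
  build(seq_len(N), 1L)
}

#' Pseudobulk Pearson correlation between cell groups
#'
#' Averages log-normalized expression over all genes within each cell group
#' (for example every stage x genotype combination) and returns the Pearson
#' correlation matrix of the group profiles -- a compact similarity summary
#' of the cluster/genotype structure.
#'
#' @param sce a \code{SingleCellExperiment} with \code{logcounts}.
#' @param groupBy character vector of \code{colData} columns defining the
#'   groups (default stage and genotype).
#' @return Symmetric correlation matrix with unit diagonal. Groups with a
#'   zero-variance profile yield \code{NA} for their pairs, with a warning.
#' @export
pseudobulkCorrelation <- function(sce, groupBy = c("stage", "genotype")) {
  lc <- .assayOrStop(sce, "logcounts")
  cd <- SummarizedExperiment::colData(sce)
  miss <- setdiff(groupBy, colnames(cd))
  if (length(miss)) stop("colData column(s) missing: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  grp <- interaction(as.list(cd[, groupBy, drop = FALSE]), drop = TRUE,
                     sep = ".")
  if (nlevels(grp) < 2L) stop("need at least two groups", call. = FALSE)
  prof <- sapply(levels(grp), function(g)
    Matrix::rowMeans(lc[, grp == g, drop = FALSE]))
  sds <- apply(prof, 2L, stats::sd)
  if (any(sds == 0))
    warning("zero-variance group profile(s): ",
            paste(colnames(prof)[sds == 0], collapse = ", "),
            "; correlations reported as NA", call. = FALSE)
  suppressWarnings(cm <- stats::cor(prof))
  diag(cm) <- 1
  cm
}

#' Categorize all informative genes and test genotype contrasts
#'
#' Runs the full categorization of a trajectory set: per-gene transition
#' categories for every genotype and transition, per-gene severity from the
#' final-stage genotype difference, one genotype x category contingency
#' table with its exact Fisher p-value per transition, and the ordered trend
#' of baseline (pre-leptotene) expression across severity groups when a
#' baseline profile is supplied. Per-transition p-values are reported
#' without multiple-testing correction across transitions.
#'
#' @param trajectory output of [normalizeToPreleptotene()] for two
#'   genotypes.
#' @param thresholds a [CategoryThresholds()].
#' @param plMeans optional named numeric: per-gene baseline expression used
#'   for the severity trend test (e.g. pre-leptotene means of the first
#'   genotype).
#' @return A list: \code{transitions} (long data.frame gene/genotype/
#'   transition/delta/category), \code{severity} (gene/diff/severity),
#'   \code{contingency} (list of 2 x 3 matrices per transition),
#'   \code{fisher} (named p-value vector), \code{trend} (or \code{NULL}).
#' @export
categorizeGenes <- function(trajectory, thresholds = CategoryThresholds(),
                            plMeans = NULL) {
  stages <- attr(trajectory, "stages")
  genos <- attr(trajectory, "genotypes")
  if (length(genos) != 2L)
    stop("categorization requires exactly two genotypes", call. = FALSE)
  dl <- trajectory$deltas
  dcols <- grep("^delta_", colnames(dl), value = TRUE)
  transitions <- sub("^delta_", "", dcols)

  long <- do.call(rbind, lapply(seq_along(dcols), function(i) {
    data.frame(gene = dl$gene, genotype = dl$genotype,
               transition = transitions[i], delta = dl[[dcols[i]]],
               category = categorizeTransition(dl[[dcols[i]]], thresholds),
               stringsAsFactors = FALSE)
  }))

  conting <- list()
  fisher <- numeric(length(transitions))
  names(fisher) <- transitions
  for (i in seq_along(transitions)) {
    tr <- transitions[i]
    sub <- long[long$transition == tr, ]
    cA <- sub$category[sub$genotype == genos[1L]]
    names(cA) <- sub$gene[sub$genotype == genos[1L]]
    cB <- sub$category[sub$genotype == genos[2L]]
    names(cB) <- sub$gene[sub$genotype == genos[2L]]
    conting[[tr]] <- buildContingency(cA, cB, genos)
    fisher[tr] <- fisherExactRxC(conting[[tr]])
  }

  lastDiff <- trajectory$diffs[[paste0("diff_", stages[length(stages)])]]
  severity <- data.frame(gene = trajectory$diffs$gene, diff = lastDiff,
                         severity = categorizeSeverity(lastDiff, thresholds),
                         stringsAsFactors = FALSE)

  trend <- NULL
  if (!is.null(plMeans)) {
    v <- plMeans[severity$gene]
    trend <- severityBaselineTrend(unname(v), severity$severity)
  }
  list(transitions = long, severity = severity, contingency = conting,
       fisher = fisher, trend = trend)
}
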