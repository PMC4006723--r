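#' Origins-by-marks distance matrix for discriminant analysis
#'
#' One row per timing-labeled origin, one column per chromatin mark holding
#' the linear distance (bp, 0 = overlap) from the origin to the nearest peak
#' of that mark, plus the `group` column collapsing the six timing categories
#' to early (1-2), mid (3-4) and late (5-6).  Rows with any undefined
#' distance or no timing label are dropped; their count is kept in the
#' `"n_dropped"` attribute.
#'
#' @param origins Origin tibble with `timing_category` (see
#'   [assign_timing()]).
#' @param marks Named list of non-empty mark interval tibbles.
#' @param timing_col Column of `origins` holding timing categories 1..6.
#' @return Tibble: `name`, `group`, one numeric column per mark.
#' @export
build_distance_matrix <- function(origins, marks, timing_col = "timing_category") {
  if (!timing_col %in% names(origins)) {
    abort(paste0("`origins` lacks a `", timing_col, "` column."))
  }
  empty <- vapply(marks, function(m) nrow(m) == 0, logical(1))
  if (any(empty)) {
    abort(paste0("empty mark track: ", paste(names(marks)[empty],
                                             collapse = ", "), "."))
  }
  out <- tibble(name = if ("name" %in% names(origins)) origins$name
                else sprintf("ori_%05d", seq_len(nrow(origins))),
                group = category_group(origins[[timing_col]]))
  for (m in names(marks)) out[[m]] <- distance_to_nearest(origins, marks[[m]])
  keep <- stats::complete.cases(out)
  res <- out[keep, ]
  attr(res, "n_dropped") <- sum(!keep)
  res
}

#' Linear discriminant analysis of origin-to-mark distances
#'
#' Finds the linear combinations of mark distances that best separate the
#' timing groups: axes maximising the between- over within-group variance,
#' obtained from the eigendecomposition of the within-whitened between-group
#' covariance.  Axes are scaled to unit pooled within-group variance and
#' ordered by discriminating power; classical LDA yields at most
#' `n_groups - 1` informative axes.  The sign of each axis is fixed so that
#' its largest-magnitude variable correlation is negative — distances
#' *decrease* along every axis — making outputs reproducible run to run.
#'
#' @param data Tibble from [build_distance_matrix()] (or any tibble with a
#'   group column and numeric predictors).
#' @param group_col Name of the group column (default `"group"`).
#' @param vars Predictor columns (default: all numeric columns).
#' @param log1p Use `log(1 + distance)` — distance distributions are
#'   heavy-tailed (default `FALSE`, matching raw-bp distances).
#' @param n_axes Number of axes to report (capped at `min(n_groups - 1,
#'   n_vars)`).
#' @param regularize Ridge added to the within-group covariance as a fraction
#'   of its mean diagonal, for singular cases (default 0).
#' @return An `origin_lda` object: list with `scores` (tibble: name, group,
#'   DA1..DAk), `correlations` (variable x axis Pearson correlations),
#'   `scalings`, `eigenvalues`, `prop_trace`, `group_means`, `counts`.
#'   Supports `tidy()`, `glance()`, `augment()`, `autoplot()` and
#'   [lda_classify()].
#' @export
run_lda <- function(data, group_col = "group", vars = NULL, log1p = FALSE,
                    n_axes = NULL, regularize = 0) {
  if (!group_col %in% names(data)) {
    abort(paste0("no `", group_col, "` column in `data`."))
  }
  g <- factor(data[[group_col]])
  vars <- vars %||% names(data)[vapply(data, is.numeric, logical(1))]
  vars <- setdiff(vars, group_col)
  X <- as.matrix(data[vars])
  if (log1p) X <- log1p(X)
  n <- nrow(X); p <- ncol(X); k <- nlevels(g)
  if (k < 2) abort("need at least 2 groups.")
  if (any(table(g) < 2)) abort("every group needs at least 2 rows.")
  grand <- colMeans(X)
  Xc <- sweep(X, 2, grand)
  means <- rowsum(Xc, g) / as.vector(table(g))
  W <- matrix(0, p, p, dimnames = list(vars, vars))
  for (lv in levels(g)) {
    Z <- sweep(Xc[g == lv, , drop = FALSE], 2, means[lv, ])
    W <- W + crossprod(Z)
  }
  W <- W / (n - k)
  if (regularize > 0) W <- W + regularize * mean(diag(W)) * diag(p)
  R <- tryCatch(chol(W), error = function(e)
    abort(paste0("within-group covariance is singular; retry with ",
                 "`regularize` > 0 (", conditionMessage(e), ").")))
  B <- crossprod(sqrt(as.vector(table(g))) * means) / (k - 1)
  Ri <- backsolve(R, diag(p))
  M <- t(Ri) %*% B %*% Ri
  eig <- eigen((M + t(M)) / 2, symmetric = TRUE)
  r <- min(k - 1, p)
  n_axes <- min(n_axes %||% r, r)
  scalings <- Ri %*% eig$vectors[, seq_len(n_axes), drop = FALSE]
  scores <- Xc %*% scalings
  cors <- suppressWarnings(cor(X, scores))
  for (j in seq_len(n_axes)) {
    top <- which.max(abs(cors[, j]))
    if (isTRUE(cors[top, j] > 0)) {
      scalings[, j] <- -scalings[, j]
      scores[, j] <- -scores[, j]
      cors[, j] <- -cors[, j]
    }
  }
  axes <- paste0("DA", seq_len(n_axes))
  colnames(scalings) <- colnames(scores) <- colnames(cors) <- axes
  score_tbl <- tibble(name = if ("name" %in% names(data)) data$name
                      else as.character(seq_len(n)),
                      group = as.character(g))
  score_tbl <- dplyr::bind_cols(score_tbl, as_tibble(scores))
  centroids <- rowsum(scores, g) / as.vector(table(g))
  structure(list(scores = score_tbl,
                 correlations = as_tibble(cors, rownames = "variable"),
                 scalings = scalings,
                 eigenvalues = pmax(eig$values[seq_len(n_axes)], 0),
                 prop_trace = pmax(eig$values[seq_len(n_axes)], 0) /
                   sum(pmax(eig$values[seq_len(r)], 0)),
                 group_means = centroids,
                 grand_mean = grand, vars = vars, log1p = log1p,
                 counts = table(g)),
            class = "origin_lda")
}

#' @export
print.origin_lda <- function(x, ...) {
  cat(sprintf("origin_lda: %d origins, %d groups, %d axes\n",
              nrow(x$scores), length(x$counts), length(x$eigenvalues)))
  cat("  proportion of trace:",
      paste(sprintf("%s %.2f", colnames(x$scalings), x$prop_trace),
            collapse = ", "), "\n")
  invisible(x)
}

#' @rdname run_lda
#' @param x An `origin_lda` object.
#' @return `tidy()`: one row per variable x axis with the Pearson correlation
#'   between the (possibly transformed) distances and the axis coordinates,
#'   plus the raw scaling weight.
#' @export
tidy.origin_lda <- function(x, ...) {
  cors <- tidyr::pivot_longer(x$correlations, -"variable",
                              names_to = "axis", values_to = "correlation")
  sc <- tidyr::pivot_longer(as_tibble(x$scalings, rownames = "variable"),
                            -"variable", names_to = "axis",
                            values_to = "scaling")
  left_join(cors, sc, by = c("variable", "axis"))
}

#' @rdname run_lda
#' @export
glance.origin_lda <- function(x, ...) {
  tibble(n = nrow(x$scores), n_groups = length(x$counts),
         n_axes = length(x$eigenvalues),
         separation = sum(x$eigenvalues),
         prop_trace_1 = x$prop_trace[1])
}

#' @rdname run_lda
#' @export
augment.origin_lda <- function(x, ...) {
  mutate(x$scores, .fitted_group = lda_classify(x))
}

#' Nearest-centroid classification on discriminant axes
#'
#' @param fit An `origin_lda` object.
#' @param newdata Optional tibble with the fit's predictor columns; default
#'   classifies the training origins.
#' @return Character vector of predicted group labels.
#' @export
lda_classify <- function(fit, newdata = NULL) {
  if (is.null(newdata)) {
    sc <- as.matrix(fit$scores[colnames(fit$scalings)])
  } else {
    X <- as.matrix(newdata[fit$vars])
    if (fit$log1p) X <- log1p(X)
    sc <- sweep(X, 2, fit$grand_mean) %*% fit$scalings
  }
  d2 <- vapply(rownames(fit$group_means), function(lv) {
    rowSums(sweep(sc, 2, fit$group_means[lv, ])^2)
  }, numeric(nrow(sc)))
  if (nrow(sc) == 1) d2 <- matrix(d2, nrow = 1,
                                  dimnames = list(NULL,
                                                  rownames(fit$group_means)))
  colnames(d2)[max.col(-d2)]
}
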