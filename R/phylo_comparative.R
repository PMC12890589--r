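#' Read a phylogeny from a newick file
#'
#' Thin wrapper over `ape::read.tree` that normalizes tip labels (spaces
#' become underscores), and validates tip-name uniqueness and non-negative
#' branch lengths.
#'
#' @param path Path to a newick file.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  tree <- tryCatch(suppressWarnings(ape::read.tree(path)),
                   error = function(e)
    stop("malformed newick in '", path, "': ", conditionMessage(e),
         call. = FALSE))
  if (is.null(tree))
    stop("malformed newick in '", path, "'", call. = FALSE)
  tree$tip.label <- gsub("[ ]+", "_", gsub("['\"]", "", tree$tip.label))
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels after normalization", call. = FALSE)
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed", call. = FALSE)
  tree
}

#' Brownian-motion variance-covariance matrix of a tree
#'
#' Under Brownian trait evolution the expected covariance between two tips
#' equals the shared root-to-MRCA path length, and each tip's variance its
#' root-to-tip depth. Computed with `ape::vcv`, optionally restricted and
#' reordered to a tip subset.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param tips Optional character vector of tip labels to keep (in order).
#' @return A symmetric positive-semidefinite matrix.
#' @export
brownian_vcv <- function(tree, tips = NULL) {
  V <- ape::vcv(tree)
  if (!is.null(tips)) {
    missing <- setdiff(tips, rownames(V))
    if (length(missing))
      stop("tip(s) absent from tree: ", paste(missing, collapse = ", "),
           call. = FALSE)
    V <- V[tips, tips, drop = FALSE]
  }
  V
}

# Cholesky of V with the documented ridge guard
chol_with_ridge <- function(V, ridge = 1e-10) {
  ev_min <- min(eigen(V, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < 1e-12) {
    V <- V + diag(ridge, nrow(V))
    ev_min <- min(eigen(V, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min <= 0)
      stop("covariance matrix singular even after ridge; increase `ridge`",
           call. = FALSE)
  }
  chol(V)
}

#' Generalized least squares with a fixed covariance structure
#'
#' Closed-form GLS of a response on one or more predictors under a given
#' (typically Brownian phylogenetic) covariance matrix, the frequentist
#' analogue of a phylogenetic multilevel regression with the tree as a
#' group-level effect. With the identity covariance this reduces exactly to
#' ordinary least squares. Near-singular covariance matrices receive a
#' small diagonal ridge (added when the smallest eigenvalue drops below
#' 1e-12).
#'
#' @param response Numeric response vector.
#' @param predictors Numeric vector, matrix or data frame of predictors
#'   (an intercept is added automatically).
#' @param vcv Covariance matrix (n x n), e.g. from [brownian_vcv()];
#'   `NULL` means the identity (ordinary least squares).
#' @param level Two-sided interval level; the default 0.90 reports the
#'   5-95% interval.
#' @param ridge Diagonal ridge used when `vcv` is near-singular.
#' @return An object of class `"cr_gls"`: a list with a `coefficients`
#'   data frame (`term`, `estimate`, `se`, `ci_low`, `ci_high`), `sigma2`
#'   (residual variance on the covariance scale), `df_residual`, `level`.
#' @export
gls_fit <- function(response, predictors, vcv = NULL, level = 0.90,
                    ridge = 1e-10) {
  y <- as.numeric(response)
  X <- if (is.null(predictors)) {
    matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    P <- as.matrix(as.data.frame(predictors))
    if (is.null(colnames(P)))
      colnames(P) <- paste0("x", seq_len(ncol(P)))
    cbind("(Intercept)" = 1, P)
  }
  n <- length(y)
  if (nrow(X) != n) stop("response/predictor lengths differ", call. = FALSE)
  if (is.null(vcv)) {
    Ly <- y
    LX <- X
  } else {
    if (!all(dim(vcv) == c(n, n)))
      stop("vcv must be n x n with n = length(response)", call. = FALSE)
    U <- chol_with_ridge(vcv, ridge)
    # whiten: solve t(U) z = . so that cov of transformed errors is identity
    Ly <- backsolve(U, y, transpose = TRUE)
    LX <- backsolve(U, X, transpose = TRUE)
  }
  fit <- stats::lm.fit(LX, Ly)
  beta <- fit$coefficients
  df <- n - ncol(X)
  sigma2 <- sum(fit$residuals^2) / df
  XtX_inv <- chol2inv(chol(crossprod(LX)))
  se <- sqrt(sigma2 * diag(XtX_inv))
  tq <- qt(1 - (1 - level) / 2, df)
  structure(list(
    coefficients = data.frame(term = colnames(X),
                              estimate = unname(beta),
                              se = unname(se),
                              ci_low = unname(beta - tq * se),
                              ci_high = unname(beta + tq * se)),
    sigma2 = sigma2, df_residual = df, level = level,
    vcv_used = !is.null(vcv)),
    class = "cr_gls")
}

#' @export
print.cr_gls <- function(x, ...) {
  cat(sprintf("<cr_gls> %s, %d residual df, %.0f%% intervals\n",
              if (x$vcv_used) "phylogenetic covariance" else "identity covariance",
              x$df_residual, 100 * x$level))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Fit the same GLS across multiple trees
#'
#' Mirrors validation against a sample of posterior trees: fits
#' [gls_fit()] once per tree and stacks the coefficient tables with a
#' `tree_id` column so the spread of estimates across trees can be
#' summarized.
#'
#' @param response,predictors As in [gls_fit()].
#' @param trees A list of trees or an `ape::multiPhylo`; alternatively a
#'   directory path containing newick files.
#' @param tips Tip labels matching the rows of `response` (used to order
#'   each tree's covariance matrix).
#' @param ... Passed on to [gls_fit()].
#' @return A data frame of per-tree coefficient estimates.
#' @export
gls_fit_trees <- function(response, predictors, trees, tips, ...) {
  if (is.character(trees) && length(trees) == 1 && dir.exists(trees)) {
    files <- list.files(trees, pattern = "\\.(nwk|tre|tree|txt)$",
                        full.names = TRUE)
    if (!length(files)) stop("no newick files found in ", trees, call. = FALSE)
    trees <- lapply(files, read_newick)
    names(trees) <- basename(files)
  }
  if (inherits(trees, "phylo")) trees <- list(trees)
  ids <- if (is.null(names(trees))) seq_along(trees) else names(trees)
  out <- Map(function(tree, id) {
    fit <- gls_fit(response, predictors, brownian_vcv(tree, tips), ...)
    cbind(tree_id = id, fit$coefficients)
  }, trees, ids)
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Phylogenetic-signal summary via residual standard deviations
#'
#' Compares the residual standard deviation of an intercept-only GLS under
#' the Brownian covariance against the ordinary (identity-covariance)
#' standard deviation. A trait with strong phylogenetic structure has a
#' much smaller Brownian-scaled SD than its raw SD on a deep tree; a
#' white-noise trait on a star tree gives equal values.
#'
#' @param response Numeric trait vector.
#' @param vcv Brownian covariance matrix from [brownian_vcv()].
#' @return A list with `sd_brownian`, `sd_identity` and their `ratio`.
#' @export
phylo_signal_variance <- function(response, vcv) {
  fb <- gls_fit(response, predictors = NULL, vcv = vcv)
  fi <- gls_fit(response, predictors = NULL, vcv = NULL)
  list(sd_brownian = sqrt(fb$sigma2),
       sd_identity = sqrt(fi$sigma2),
       ratio = sqrt(fb$sigma2 / fi$sigma2))
}
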