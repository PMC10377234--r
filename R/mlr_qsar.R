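# Multiple-linear-regression QSAR: descriptor filtering, OLS with
# validation statistics, exhaustive best-subset search, and the packaged
# three-descriptor Cx43 model.

#' Drop descriptors that are constant across all compounds
#'
#' Descriptors taking a single value over the whole dataset carry no
#' information for regression and are removed before model search. Column
#' order is preserved.
#'
#' @param m numeric matrix (compounds x descriptors) with column names.
#' @return the matrix restricted to columns with at least two distinct
#'   values.
#' @export
drop_constant_descriptors <- function(m) {
  m <- as.matrix(m)
  stopifnot(nrow(m) >= 1)
  keep <- apply(m, 2, function(col) length(unique(col)) >= 2L)
  m[, keep, drop = FALSE]
}

new_mlr_model <- function(descriptor_names, coefficients, intercept) {
  stopifnot(length(descriptor_names) == length(coefficients))
  structure(list(descriptor_names = descriptor_names,
                 coefficients = stats::setNames(as.numeric(coefficients),
                                                descriptor_names),
                 intercept = as.numeric(intercept)),
            class = "mlr_model")
}

#' @export
print.mlr_model <- function(x, ...) {
  terms <- paste(sprintf("%+.4g*%s", x$coefficients, x$descriptor_names),
                 collapse = " ")
  cat("linear QSAR model: -log(pIC50) =", terms,
      sprintf("%+.4g", x$intercept), "\n")
  invisible(x)
}

#' The packaged three-descriptor Cx43 QSAR model
#'
#' The published linear model for Cx43 gap-junction inhibition:
#' \deqn{-\log(pIC_{50}) = -4.87\,SpMin5\_Bhm + 5.67\,SpMax3\_Bhi
#'       - 5.70\,minHBd - 7.24}
#' SpMin5_Bhm and SpMax3_Bhi are Burden-matrix eigenvalue descriptors
#' (mass- and ionization-potential-weighted); minHBd is the minimum
#' E-state value over hydrogen-bond donor atoms.
#'
#' @return an \code{mlr_model}.
#' @export
cx43_qsar_model <- function() {
  new_mlr_model(CX43_DESCRIPTORS, c(-4.87, 5.67, -5.70), -7.24)
}

#' Validation statistics for observed vs predicted activity
#'
#' Pearson correlation R, coefficient of determination R^2 = R squared, and
#' adjusted R^2 = 1 - (1 - R^2)(n - 1)/(n - k - 1) for k predictors.
#'
#' @param observed numeric vector of measured activities.
#' @param predicted numeric vector of model predictions, same length.
#' @param n_predictors number of predictors k used by the model.
#' @return a \code{fit_stats} list: \code{r}, \code{r2}, \code{r2_adj},
#'   \code{n_obs}, \code{n_predictors}.
#' @export
validation_stats <- function(observed, predicted, n_predictors) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 3)
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0)
    stop("zero variance in observed or predicted values")
  n <- length(observed)
  r <- stats::cor(observed, predicted)
  r2 <- r^2
  structure(list(r = r, r2 = r2,
                 r2_adj = 1 - (1 - r2) * (n - 1) / (n - n_predictors - 1),
                 n_obs = n, n_predictors = n_predictors),
            class = "fit_stats")
}

#' @export
print.fit_stats <- function(x, ...) {
  cat(sprintf("R = %.4f, R2 = %.4f, R2adj = %.4f (n = %d, k = %d)\n",
              x$r, x$r2, x$r2_adj, x$n_obs, x$n_predictors))
  invisible(x)
}

#' Ordinary least squares fit of activity on a descriptor subset
#'
#' Fits \eqn{y = a_1 x_1 + \dots + a_k x_k + b} by QR-based least squares
#' (numerically stable for correlated descriptors) and returns the model
#' with its validation statistics on the training data.
#'
#' @param x numeric matrix (compounds x descriptors) with column names, or
#'   a data.frame of numeric columns.
#' @param y numeric activity vector (\eqn{-\log_{10}} molar potency).
#' @return list with elements \code{model} (\code{mlr_model}) and
#'   \code{stats} (\code{fit_stats}).
#' @export
fit_ols <- function(x, y) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  k <- ncol(x)
  n <- length(y)
  stopifnot(nrow(x) == n)
  if (n <= k + 1)
    stop("need more observations than predictors + 1 (n = ", n,
         ", k = ", k, ")")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(k))
  xm <- cbind(`(Intercept)` = 1, x)
  q <- qr(xm)
  if (q$rank < ncol(xm)) {
    dropped <- colnames(xm)[q$pivot[(q$rank + 1):ncol(xm)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  beta <- qr.coef(q, y)
  fitted <- drop(xm %*% beta)
  model <- new_mlr_model(colnames(x), beta[-1], beta[1])
  st <- validation_stats(y, fitted, n_predictors = k)
  list(model = model, stats = st, fitted = fitted, residuals = y - fitted)
}

#' Predict activity with a linear QSAR model
#'
#' @param object an \code{mlr_model}.
#' @param newdata named list, named numeric vector, data.frame or matrix
#'   containing every descriptor the model uses (extra columns ignored).
#' @param ... unused.
#' @return numeric vector of \eqn{-\log_{10}} molar predictions.
#' @examples
#' m <- cx43_qsar_model()
#' predict(m, c(SpMin5_Bhm = 0.81, SpMax3_Bhi = 3.11, minHBd = 0.67))
#' @export
predict.mlr_model <- function(object, newdata, ...) {
  if (is.numeric(newdata) && !is.matrix(newdata))
    newdata <- as.data.frame(as.list(newdata))
  newdata <- as.data.frame(newdata)
  missing_d <- setdiff(object$descriptor_names, names(newdata))
  if (length(missing_d) > 0)
    stop("missing descriptor(s): ", paste(missing_d, collapse = ", "))
  x <- as.matrix(newdata[object$descriptor_names])
  drop(x %*% object$coefficients) + object$intercept
}

#' Exhaustive best-subset search over descriptor combinations
#'
#' Evaluates an OLS fit for every size-\code{k} subset of descriptor
#' columns and ranks subsets by training R^2 (descending), breaking ties
#' lexicographically by the descriptor-name tuple so that results are
#' deterministic. Rank-deficient subsets are skipped with a warning rather
#' than aborting the search. The default \code{k = 3} matches the
#' overfitting guard used for small congeneric datasets.
#'
#' @param m numeric matrix (compounds x descriptors) with column names.
#' @param y numeric activity vector.
#' @param k subset size (default 3).
#' @param top_n keep fitted models only for the best \code{top_n} subsets
#'   (statistics are kept for all); default 10.
#' @return a \code{subset_search_result}: list with \code{table} (a
#'   data.frame of subset, r2, r, r2_adj, best-first), \code{models}
#'   (named list of \code{mlr_model} for the top subsets),
#'   \code{n_evaluated}, and \code{skipped} (rank-deficient subsets).
#' @export
exhaustive_subset_search <- function(m, y, k = 3, top_n = 10) {
  m <- as.matrix(m)
  stopifnot(k >= 1, ncol(m) >= k)
  if (is.null(colnames(m))) colnames(m) <- paste0("x", seq_len(ncol(m)))
  subsets <- utils::combn(colnames(m), k, simplify = FALSE)
  r2 <- r <- r2a <- rep(NA_real_, length(subsets))
  skipped <- character(0)
  fits <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    fit <- tryCatch(fit_ols(m[, subsets[[i]], drop = FALSE], y),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      skipped <- c(skipped, paste(subsets[[i]], collapse = "+"))
      next
    }
    r2[i] <- fit$stats$r2
    r[i] <- fit$stats$r
    r2a[i] <- fit$stats$r2_adj
    fits[[i]] <- fit$model
  }
  if (length(skipped) > 0)
    warning("skipped ", length(skipped), " rank-deficient subset(s): ",
            paste(utils::head(skipped, 5), collapse = "; "),
            if (length(skipped) > 5) " ..." else "")
  key <- vapply(subsets, paste, character(1), collapse = "\r")
  ord <- order(-r2, key, na.last = TRUE)
  tab <- data.frame(
    subset = vapply(subsets, paste, character(1), collapse = "+")[ord],
    r2 = r2[ord], r = r[ord], r2_adj = r2a[ord],
    stringsAsFactors = FALSE)
  top <- ord[seq_len(min(top_n, length(ord)))]
  top <- top[!is.na(r2[top])]
  models <- stats::setNames(fits[top],
                            vapply(subsets[top], paste, character(1),
                                   collapse = "+"))
  structure(list(table = tab, models = models,
                 n_evaluated = sum(!is.na(r2)), skipped = skipped),
            class = "subset_search_result")
}

#' @export
print.subset_search_result <- function(x, n = 5, ...) {
  cat("best-subset search:", x$n_evaluated, "subset(s) evaluated",
      if (length(x$skipped)) paste0("(", length(x$skipped), " skipped)"),
      "\n")
  print(utils::head(x$table, n))
  invisible(x)
}

#' Write / read a linear QSAR model as plain text
#'
#' Key-value serialization with a format version line, so fitted models can
#' be exchanged between runs and inspected by eye.
#'
#' @param model an \code{mlr_model}.
#' @param path file path.
#' @return \code{write_mlr_model}: the path, invisibly;
#'   \code{read_mlr_model}: an \code{mlr_model}.
#' @export
write_mlr_model <- function(model, path) {
  lines <- c("gjqsar-mlr-model 1",
             paste("descriptors", paste(model$descriptor_names,
                                        collapse = ",")),
             paste("coefficients",
                   paste(formatC(model$coefficients, format = "g",
                                 digits = 17), collapse = ",")),
             paste("intercept",
                   formatC(model$intercept, format = "g", digits = 17)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_mlr_model
#' @export
read_mlr_model <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "gjqsar-mlr-model"))
    stop("not a gjqsar model file: ", path)
  kv <- strsplit(lines[-1], " ", fixed = TRUE)
  get <- function(key) {
    hit <- vapply(kv, function(p) p[1] == key, logical(1))
    if (!any(hit)) stop("model file missing field: ", key)
    strsplit(kv[[which(hit)[1]]][2], ",", fixed = TRUE)[[1]]
  }
  new_mlr_model(get("descriptors"), as.numeric(get("coefficients")),
                as.numeric(get("intercept")))
}
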