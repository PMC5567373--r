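#' Leverage of query points against a training matrix
#'
#' \eqn{h_i = x_i^T (X^T X)^{-1} x_i}, the hat-matrix diagonal for training
#' rows. `X` is the raw n x k matrix of the k selected descriptors for the n
#' training metabolites, with no appended intercept column. A singular
#' \eqn{X^T X} is a hard error naming the offending (collinear) columns,
#' because applicability-domain statistics under rank deficiency are
#' misleading; `pseudo_inverse = TRUE` is available as a diagnostic mode.
#'
#' @param X_train Numeric n x k training matrix, full column rank.
#' @param X_query Matrix (or vector, taken as one row) of query points;
#'   defaults to the training rows themselves.
#' @param pseudo_inverse Use a Moore-Penrose pseudo-inverse instead of
#'   erroring on singular cross-products (diagnostic only).
#' @return Numeric vector of leverages, one per query row.
#' @export
leverage <- function(X_train, X_query = X_train, pseudo_inverse = FALSE) {
  X <- as.matrix(X_train)
  if (is.vector(X_query)) X_query <- matrix(X_query, nrow = 1L)
  Q <- as.matrix(X_query)
  if (ncol(Q) != ncol(X))
    stop("query and training matrices must share columns", call. = FALSE)
  XtX <- crossprod(X)
  qr_ <- qr(XtX)
  if (qr_$rank < ncol(X)) {
    if (!pseudo_inverse) {
      bad <- colnames(X)[qr_$pivot[seq(qr_$rank + 1L, ncol(X))]]
      if (is.null(bad)) bad <- paste("column", qr_$pivot[seq(qr_$rank + 1L, ncol(X))])
      stop(sprintf("X'X is singular; collinear columns: %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    s <- svd(XtX)
    pos <- s$d > max(s$d) * 1e-12
    inv <- s$v[, pos, drop = FALSE] %*%
      (t(s$u[, pos, drop = FALSE]) / s$d[pos])
  } else {
    inv <- solve(XtX)
  }
  rowSums((Q %*% inv) * Q)
}

#' Leverage control threshold
#'
#' The warning leverage \eqn{h^* = 3k/n} for a model with k descriptors fitted
#' on n training samples.
#'
#' @param k Number of descriptors.
#' @param n Number of training samples.
#' @return `3 * k / n`.
#' @export
leverage_threshold <- function(k, n) {
  stopifnot_scalar_number(k, "k", positive = TRUE)
  stopifnot_scalar_number(n, "n", positive = TRUE)
  3 * k / n
}

#' Williams-plot data (leverage vs standardized residual)
#'
#' For every training and test sample: its leverage against the training
#' matrix, its residual standardized by the RMSE of the training residuals,
#' and the in-domain flag `h <= h*` and `|standardized residual| <= 3`.
#'
#' @param model A fitted model supporting `predict()` on descriptor rows
#'   (e.g. a `metaconc_svr`).
#' @param X_train,y_train Training matrix (the k selected descriptors) and
#'   observed response.
#' @param X_test,y_test Optional held-out samples (an empty test set yields a
#'   train-only report).
#' @param residual_limit Standardized-residual band (default 3).
#' @param ids Optional row identifiers (train then test).
#' @return data.frame of class `leverage_report`: `id`, `role`, `leverage`,
#'   `std_residual`, `in_domain`, with attributes `h_star`, `k`, `n`.
#' @export
williams_data <- function(model, X_train, y_train, X_test = NULL,
                          y_test = NULL, residual_limit = 3, ids = NULL) {
  X_train <- as.matrix(X_train)
  k <- ncol(X_train)
  n <- nrow(X_train)
  h_star <- leverage_threshold(k, n)
  pred_tr <- predict(model, X_train)
  res_tr <- y_train - pred_tr
  s <- sqrt(mean(res_tr^2))
  if (s == 0) s <- 1  # perfectly interpolated training set: residuals all 0
  h_tr <- leverage(X_train)
  out <- data.frame(role = "train", leverage = h_tr,
                    std_residual = res_tr / s, stringsAsFactors = FALSE)
  if (!is.null(X_test) && nrow(as.matrix(X_test)) > 0L) {
    X_test <- as.matrix(X_test)
    res_te <- y_test - predict(model, X_test)
    out <- rbind(out, data.frame(role = "test",
                                 leverage = leverage(X_train, X_test),
                                 std_residual = res_te / s))
  }
  out$in_domain <- out$leverage <= h_star &
    abs(out$std_residual) <= residual_limit
  out <- cbind(id = if (is.null(ids)) seq_len(nrow(out)) else ids, out)
  attr(out, "h_star") <- h_star
  attr(out, "k") <- k
  attr(out, "n") <- n
  class(out) <- c("leverage_report", "data.frame")
  out
}

#' Write a leverage report / draw a Williams plot
#'
#' @param report A `leverage_report` from [williams_data()].
#' @param path TSV output path (report) or image path (plot; device chosen
#'   from the extension, png or svg).
#' @return `path`, invisibly.
#' @export
write_leverage_report <- function(report, path) {
  df <- as.data.frame(report)
  attr(df, "h_star") <- NULL
  write_tsv_det(df, path)
  invisible(path)
}

#' @rdname write_leverage_report
#' @param residual_limit Guide lines for the standardized-residual band.
#' @export
williams_plot <- function(report, path = NULL, residual_limit = 3) {
  draw <- function() {
    cols <- ifelse(report$role == "train", "black", "magenta")
    pch <- ifelse(report$role == "train", 1, 17)
    ylim <- range(c(report$std_residual, -residual_limit, residual_limit))
    xlim <- range(c(report$leverage, attr(report, "h_star")))
    graphics::plot(report$leverage, report$std_residual, col = cols, pch = pch,
                   xlab = "Leverage", ylab = "Standardized residual",
                   xlim = xlim * c(0, 1.05), ylim = ylim * 1.1,
                   main = "Williams plot")
    graphics::abline(h = c(-residual_limit, residual_limit), lty = 2)
    graphics::abline(v = attr(report, "h_star"), lty = 2)
    graphics::legend("topright", legend = c("train", "test"),
                     col = c("black", "magenta"), pch = c(1, 17), bty = "n")
  }
  if (is.null(path)) {
    draw()
  } else {
    if (grepl("\\.svg$", path)) grDevices::svg(path)
    else grDevices::png(path, width = 800, height = 600)
    on.exit(grDevices::dev.off())
    draw()
  }
  invisible(path)
}
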