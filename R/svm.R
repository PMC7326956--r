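#' Train a linear soft-margin SVM
#'
#' Fits the linear C-SVM `min 0.5 ||w||^2 + c * sum hinge` (LIBSVM, via
#' \pkg{e1071}, no feature scaling) and returns the primal decision rule
#' under a fixed class convention: `sign(w . x + b) > 0` predicts
#' `positive_class`, with ties (exactly 0) resolved to the negative class —
#' conservative for feedback, where the rest class drives no reward motion.
#'
#' @param X features x samples numeric matrix.
#' @param y Character (or factor) labels, exactly two classes, aligned with
#'   the columns of `X`.
#' @param c Regularization constant (default 1, the value standard in
#'   motor-imagery decoding).
#' @param positive_class Which label is the positive class. Default: the task
#'   condition when the other class is `REST`, otherwise `LGO`.
#' @return A `linear_svm`: list with `weights`, `bias`, `positive_class`,
#'   `negative_class`, `c`.
#' @examples
#' X <- cbind(c(1, 0), c(-1, 0))
#' m <- train_linear_svm(X, c("LGO", "REST"), positive_class = "LGO")
#' round(m$weights, 3)  # (1, 0)
#' @export
train_linear_svm <- function(X, y, c = 1, positive_class = NULL) {
  stopifnot(is.matrix(X), c > 0)
  y <- as.character(y)
  if (length(y) != ncol(X))
    stop("length(y) must equal ncol(X)")
  if (any(!is.finite(X))) stop("non-finite values in feature matrix")
  classes <- unique(y)
  if (length(classes) != 2L)
    stop("need exactly two classes, got: ", paste(classes, collapse = ", "))
  if (is.null(positive_class)) {
    positive_class <- if ("REST" %in% classes)
      setdiff(classes, "REST") else
        if ("LGO" %in% classes) "LGO" else classes[1L]
  }
  stopifnot(positive_class %in% classes)
  negative_class <- setdiff(classes, positive_class)

  fit <- e1071::svm(x = t(X), y = factor(y, levels = c(negative_class,
                                                       positive_class)),
                    type = "C-classification", kernel = "linear",
                    cost = c, scale = FALSE)
  w <- as.numeric(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  # LIBSVM orients decision values so that positive means the class that is
  # internally first (fit$labels[1]); renormalize to our convention
  first <- fit$levels[fit$labels[1L]]
  if (!identical(first, positive_class)) {
    w <- -w
    b <- -b
  }
  structure(list(weights = w, bias = b,
                 positive_class = positive_class,
                 negative_class = negative_class, c = c),
            class = "linear_svm")
}

#' @export
print.linear_svm <- function(x, ...) {
  cat("Linear SVM (", x$negative_class, " vs ", x$positive_class,
      "): ", length(x$weights), " features, c = ", x$c,
      ", bias = ", signif(x$bias, 4), "\n", sep = "")
  invisible(x)
}

#' @export
coef.linear_svm <- function(object, ...) {
  c(bias = object$bias, stats::setNames(object$weights,
                                        paste0("w", seq_along(object$weights))))
}

#' Decision value of a linear model
#'
#' Returns `w . x + b`, positive for the model's positive class.
#'
#' @param model A `linear_svm`.
#' @param x Feature vector, or a features x samples matrix (one value per
#'   column).
#' @return Numeric scalar or vector.
#' @export
decision_value <- function(model, x) {
  stopifnot(inherits(model, "linear_svm"))
  if (is.matrix(x)) {
    if (nrow(x) != length(model$weights))
      stop("feature dimension mismatch: model has ", length(model$weights),
           ", x has ", nrow(x))
    return(as.numeric(crossprod(x, model$weights)) + model$bias)
  }
  if (length(x) != length(model$weights))
    stop("feature dimension mismatch: model has ", length(model$weights),
         ", x has ", length(x))
  sum(model$weights * x) + model$bias
}

#' @export
predict.linear_svm <- function(object, newdata, ...) {
  d <- decision_value(object, newdata)
  ifelse(d > 0, object$positive_class, object$negative_class)
}

#' Drift-correct a decision-value trace
#'
#' Removes slow linear drift from a within-run sequence of classifier outputs
#' while preserving its level: the cumulative streaming linear fit (the same
#' algorithm as [detrend_update()]) is subtracted and the cumulative running
#' mean added back, so only the linear drift component is removed and the
#' class separation encoded in the level survives. The first two positions
#' are emitted unchanged (no drift estimate exists yet). Labels are
#' re-thresholded at 0 (ties to the negative class). The correction at
#' position `n` uses only values `1..n`, so it is valid in real time.
#'
#' @param raw Numeric vector of raw decision values (length >= 1).
#' @param positive_class,negative_class Labels used for thresholding.
#' @return A `decision_trace`: list with `raw`, `corrected`, `labels`,
#'   `volume_index`.
#' @export
detrend_decisions <- function(raw, positive_class = "task",
                              negative_class = "rest") {
  stopifnot(length(raw) >= 1L, all(is.finite(raw)))
  n <- length(raw)
  corrected <- raw
  if (n >= 3L) {
    t <- seq_len(n)
    st <- cumsum(t); stt <- cumsum(t^2)
    sy <- cumsum(raw); sty <- cumsum(t * raw)
    k <- 3:n
    denom <- k * stt[k] - st[k]^2
    b <- (k * sty[k] - st[k] * sy[k]) / denom
    a <- (sy[k] - b * st[k]) / k
    corrected[k] <- raw[k] - (a + b * k) + sy[k] / k
  }
  structure(list(raw = raw, corrected = corrected,
                 labels = ifelse(corrected > 0, positive_class,
                                 negative_class),
                 volume_index = seq_len(n) - 1L),
            class = "decision_trace")
}

#' Scatter model weights into image space
#'
#' @param model A `linear_svm`.
#' @param mask Logical 3D array whose `TRUE` count equals the model's feature
#'   count (the mask the features were extracted with).
#' @return 3D numeric array; out-of-mask voxels are 0.
#' @export
weight_map <- function(model, mask) {
  stopifnot(inherits(model, "linear_svm"), is.logical(mask),
            !is.null(dim(mask)))
  if (sum(mask) != length(model$weights))
    stop("mask selects ", sum(mask), " voxels but model has ",
         length(model$weights), " weights")
  grid <- array(0, dim = dim(mask))
  grid[mask] <- model$weights
  grid
}

#' Serialize / deserialize a linear model as JSON
#'
#' @param model A `linear_svm`.
#' @param path File path.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "linear_svm"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(weights = as.numeric(obj$weights), bias = obj$bias,
                 positive_class = obj$positive_class,
                 negative_class = obj$negative_class, c = obj$c),
            class = "linear_svm")
}
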