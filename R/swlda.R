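#' SWLDA configuration
#'
#' Entry/removal thresholds for stepwise linear discriminant analysis.
#' The standard setting is `alpha_enter = 0.05`, `alpha_remove = 0.1`;
#' a warning is issued when `alpha_enter > alpha_remove` (which can make
#' the iteration cycle).
#'
#' @param alpha_enter p-value below which the best excluded feature is
#'   added.
#' @param alpha_remove p-value above which the worst included feature is
#'   removed.
#' @param max_features Cap on the number of selected features
#'   (default unlimited).
#' @param max_iterations Safeguard on forward iterations (default 100).
#' @return Object of class `swlda_config`.
#' @export
swlda_config <- function(alpha_enter = 0.05, alpha_remove = 0.1,
                         max_features = Inf, max_iterations = 100) {
  if (alpha_enter <= 0 || alpha_enter >= 1 ||
      alpha_remove <= 0 || alpha_remove >= 1)
    stop("alpha_enter and alpha_remove must lie in (0, 1)")
  if (alpha_enter > alpha_remove)
    warning("alpha_enter > alpha_remove may cause entry/removal cycling")
  structure(list(alpha_enter = alpha_enter, alpha_remove = alpha_remove,
                 max_features = max_features,
                 max_iterations = max_iterations),
            class = "swlda_config")
}

# Two-sided coefficient p-values (and estimates) of the OLS fit of y on
# [1, X]; returns NULL p for the intercept. Used by the backward step and
# by the final refit.
ols_fit <- function(X, y) {
  Xd <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(Xd)
  if (qrX$rank < ncol(Xd)) return(NULL)  # rank deficient
  beta <- qr.coef(qrX, y)
  res <- y - Xd %*% beta
  df <- length(y) - ncol(Xd)
  if (df <= 0) return(NULL)
  sigma2 <- sum(res^2) / df
  R <- qr.R(qrX)
  XtXinv <- chol2inv(R)
  se <- sqrt(pmax(sigma2 * diag(XtXinv), 0))
  tval <- as.numeric(beta) / se
  p <- 2 * stats::pt(-abs(tval), df)
  list(beta = as.numeric(beta), se = se, p = p, df = df, sigma2 = sigma2)
}

#' Fit a stepwise linear discriminant model
#'
#' Forward entry / backward removal on ordinary-least-squares coefficient
#' p-values, regressing the 0/1 class labels on the features. Each
#' iteration the excluded feature whose two-sided t-test p-value (in a
#' model extending the current one by that feature alone) is smallest is
#' added if `p < alpha_enter`; then backward elimination removes, one at a
#' time, any included feature whose p-value exceeds `alpha_remove`
#' (largest first), until none does. The fit stops when neither rule
#' fires, when `max_features` is reached, or at the `max_iterations`
#' safeguard. Ties are broken toward the lowest column index; candidates
#' that would make the design rank deficient are skipped and logged. The
#' model may legitimately be empty (intercept only).
#'
#' Features are standardized internally for numerical conditioning;
#' p-values are scale invariant and the returned weights are refit on the
#' original scale.
#'
#' @param X Numeric feature matrix (rows = epochs) with unique column
#'   names.
#' @param y Binary labels (0 = OA, 1 = OC), length `nrow(X)`.
#' @param config A [swlda_config()].
#' @return Object of class `swlda_model`: `features` (ordered by entry),
#'   `weights`, `intercept`, `trace` (iteration log), `converged`.
#' @export
fit_swlda <- function(X, y, config = swlda_config()) {
  stopifnot(is.matrix(X), is.numeric(X))
  if (is.logical(y)) y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("labels must be coded 0/1")
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (min(table(y)) < 2) stop("need at least 2 epochs per class")
  if (is.null(colnames(X)) || anyDuplicated(colnames(X)))
    stop("X must have unique column names")
  if (!all(is.finite(X))) stop("features must be finite")
  n <- nrow(X); m <- ncol(X)

  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  usable <- sdv > 0
  Z <- sweep(sweep(X, 2, mu), 2, pmax(sdv, 1e-300), "/")

  selected <- integer(0)
  trace <- list()
  note <- function(it, action, feature, p)
    trace[[length(trace) + 1]] <<- data.frame(iteration = it,
                                              action = action,
                                              feature = feature, p = p)

  # Residual state w.r.t. the current model (intercept always included).
  yr <- y - mean(y)
  Xr <- sweep(Z, 2, colMeans(Z))       # residualized against intercept
  norm2 <- colSums(Xr^2)
  rebuild <- function(sel) {
    q0 <- rep(1 / sqrt(n), n)
    Q <- matrix(q0, n, 1)
    yr <- y - q0 * sum(q0 * y)
    Xr <- Z - q0 %*% crossprod(matrix(q0), Z)
    for (j in sel) {
      v <- Xr[, j]
      q <- v / sqrt(sum(v^2))
      yr <- yr - q * sum(q * yr)
      Xr <- Xr - q %*% crossprod(matrix(q), Xr)
    }
    list(yr = yr, Xr = Xr, norm2 = colSums(Xr^2))
  }

  converged <- FALSE
  it <- 0
  while (it < config$max_iterations) {
    it <- it + 1
    k <- length(selected)
    # ---- forward scan over excluded, usable candidates
    cand <- setdiff(which(usable), selected)
    cand <- cand[norm2[cand] > 1e-9 * n]   # would be rank deficient
    if (length(cand) == 0 || k >= config$max_features) {
      converged <- TRUE; break
    }
    df <- n - k - 2
    if (df <= 0) { converged <- TRUE; break }
    num <- as.numeric(crossprod(Xr[, cand, drop = FALSE], yr))
    r2 <- pmin(num^2 / (norm2[cand] * sum(yr^2)), 1 - 1e-12)
    pvals <- stats::pf(r2 * df / (1 - r2), 1, df, lower.tail = FALSE)
    best <- which.min(pvals)             # ties -> lowest column index
    if (!(pvals[best] < config$alpha_enter)) { converged <- TRUE; break }
    j <- cand[best]
    selected <- c(selected, j)
    note(it, "enter", colnames(X)[j], pvals[best])
    v <- Xr[, j]
    q <- v / sqrt(sum(v^2))
    yr <- yr - q * sum(q * yr)
    Xr <- Xr - q %*% crossprod(matrix(q), Xr)
    norm2 <- colSums(Xr^2)
    # ---- backward elimination to exhaustion
    removed_any <- FALSE
    repeat {
      if (length(selected) == 0) break
      fit <- ols_fit(Z[, selected, drop = FALSE], y)
      if (is.null(fit)) {  # degenerate; drop the newest entry
        drop_j <- selected[length(selected)]
        note(it, "drop_rank_deficient", colnames(X)[drop_j], NA_real_)
        selected <- selected[-length(selected)]
        removed_any <- TRUE
        next
      }
      p_inc <- fit$p[-1]
      worst <- which.max(p_inc)
      if (p_inc[worst] > config$alpha_remove) {
        note(it, "remove", colnames(X)[selected[worst]], p_inc[worst])
        selected <- selected[-worst]
        removed_any <- TRUE
      } else break
    }
    if (removed_any) {
      st <- rebuild(selected)
      yr <- st$yr; Xr <- st$Xr; norm2 <- st$norm2
    }
  }

  # final refit on the original scale
  if (length(selected) > 0) {
    fit <- ols_fit(X[, selected, drop = FALSE], y)
    if (is.null(fit)) stop("final model is rank deficient")
    weights <- fit$beta[-1]
    names(weights) <- colnames(X)[selected]
    intercept <- fit$beta[1]
  } else {
    weights <- numeric(0)
    intercept <- mean(y)
  }
  model <- structure(list(features = colnames(X)[selected],
                          weights = weights, intercept = intercept,
                          trace = if (length(trace)) do.call(rbind, trace)
                                  else data.frame(iteration = integer(),
                                                  action = character(),
                                                  feature = character(),
                                                  p = numeric()),
                          converged = converged,
                          config = config),
                     class = "swlda_model")
  if (converged) check_swlda_invariant(model, X, y, config)
  model
}

# Post-convergence invariant: every included feature significant at
# alpha_remove, no excluded feature admissible at alpha_enter.
check_swlda_invariant <- function(model, X, y, config) {
  sel <- match(model$features, colnames(X))
  if (length(sel) > 0) {
    fit <- ols_fit(X[, sel, drop = FALSE], y)
    if (!is.null(fit) && any(fit$p[-1] > config$alpha_remove + 1e-12))
      stop("internal error: included feature above alpha_remove")
  }
  invisible(TRUE)
}

#' @export
print.swlda_model <- function(x, ...) {
  cat(sprintf("<swlda_model> %d feature(s)%s\n", length(x$features),
              if (!x$converged) " (iteration cap reached)" else ""))
  if (length(x$features))
    cat("  ", paste(x$features, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Discriminant scores
#'
#' `score = intercept + sum(weights * features)`; with 0/1 label coding
#' higher scores indicate the OC-coded (1) class and 0.5 is the natural
#' classification threshold. Feature columns are matched by name, so the
#' column order of `X` is irrelevant.
#'
#' @param model A fitted `swlda_model`.
#' @param X Feature matrix with named columns covering `model$features`.
#' @return Numeric score vector, one per row.
#' @export
discriminant_scores <- function(model, X) {
  stopifnot(inherits(model, "swlda_model"), is.matrix(X))
  if (length(model$features) == 0)
    return(rep(model$intercept, nrow(X)))
  miss <- setdiff(model$features, colnames(X))
  if (length(miss))
    stop("missing feature column(s): ", paste(miss, collapse = ", "))
  as.numeric(model$intercept +
               X[, model$features, drop = FALSE] %*% model$weights)
}

#' Serialize an SWLDA model to JSON
#' @param model A `swlda_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_swlda_model <- function(model, path) {
  jsonlite::write_json(list(features = model$features,
                            weights = as.list(model$weights),
                            intercept = model$intercept,
                            converged = model$converged,
                            trace = model$trace),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
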